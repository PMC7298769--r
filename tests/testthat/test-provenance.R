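rec_fixture <- function(task = "A", idx = 0L, status = "success",
                        params = c(value = "x"), returns = c(count = "x"),
                        sv = NULL, ts = "2026-01-01T00:00:00.000000Z",
                        deps = character()) {
  log_record(task_id = task, subtask_index = idx, module = "stamp",
             module_version = 1L,
             fingerprint = subtask_fingerprint(task, "stamp", 1L, params),
             params = params, returns = returns, status = status,
             executor = "local", software_version = sv, dependencies = deps,
             timestamp = ts)
}

test_that("records append as parseable JSON lines and round-trip with field equality", {
  dir <- scratch_dir()
  log <- file.path(dir, "x.resume")
  r1 <- rec_fixture("A", params = c(value = "1"))
  r2 <- rec_fixture("B", params = c(value = "2"), sv = "tool 1.0", deps = "A")
  r3 <- rec_fixture("C", params = c(value = "3"), status = "failure")
  for (r in list(r1, r2, r3)) append_record(log, r)
  lines <- readLines(log)
  expect_length(lines, 3L)
  for (l in lines) expect_silent(jsonlite::fromJSON(l))
  back <- load_log(log)
  expect_equal(back[[2]]$software_version, "tool 1.0")
  expect_equal(back[[2]]$dependencies, "A")
  expect_equal(back[[1]], r1)
  expect_equal(back[[3]]$status, "failure")
  # a record without a version flag has the field absent in the JSON
  expect_false(grepl("software_version", lines[1]))
})

test_that("appended records are durable immediately: visible to a fresh load", {
  dir <- scratch_dir()
  log <- file.path(dir, "x.resume")
  append_record(log, rec_fixture("A"))
  expect_length(load_log(log), 1L)
})

test_that("a truncated final line is dropped with a warning; corrupt middle lines are an error", {
  dir <- scratch_dir()
  log <- file.path(dir, "x.resume")
  append_record(log, rec_fixture("A"))
  append_record(log, rec_fixture("B"))
  # simulate a crash mid-write: half a JSON object, no newline
  cat('{"timestamp":"2026-01-01T00:00:02Z","task_id":"C","subt',
      file = log, append = TRUE)
  expect_warning(recs <- load_log(log), "truncated final line")
  expect_length(recs, 2L)

  bad <- file.path(dir, "bad.resume")
  good_lines <- readLines(log, warn = FALSE)
  writeLines(c(good_lines[1], "garbage", good_lines[2]), bad)
  expect_error(load_log(bad), "line 2")

  expect_equal(load_log(file.path(dir, "absent.resume")), list())
  file.create(empty <- file.path(dir, "empty.resume"))
  expect_equal(load_log(empty), list())
})

test_that("an empty log plans everything and a complete log plans nothing", {
  dir <- scratch_dir()
  fx <- make_resume_pair(file.path(dir, "fx"))
  mods <- load_modules(fx$modules)
  wf <- read_workflow(fx$v1)
  subs <- expand_workflow(wf, mods)

  plan0 <- resume_plan(subs, wf, list())
  expect_setequal(plan0$run, names(subs))
  expect_length(plan0$reuse, 0L)

  res <- run_workflow(wf, mods, test_opts(dir))
  expect_equal(res$exit_status, 0L)
  plan1 <- resume_plan(expand_workflow(wf, mods), wf, load_log(res$log))
  expect_length(plan1$run, 0L)
  expect_setequal(plan1$reuse, names(subs))
})

test_that("the two-version scenario replans exactly the modified, new and dependent work", {
  dir <- scratch_dir()
  fx <- make_resume_pair(file.path(dir, "fx"))
  mods <- load_modules(fx$modules)
  res <- run_workflow(read_workflow(fx$v1), mods, test_opts(dir))
  expect_equal(unname(res$counts["succeeded"]), 6L)

  wf2 <- read_workflow(fx$v2)
  plan <- resume_plan(expand_workflow(wf2, mods), wf2, load_log(res$log))
  expect_setequal(plan$run,
                  c("B[0]", "C[0]", "D[2]", "D[3]", "E[0]", "F[0]", "Z[0]"))
  expect_setequal(plan$reuse, c("A[0]", "D[0]", "D[1]"))
})

test_that("the run set is closed under dependency and minimal over reusable successes", {
  dir <- scratch_dir()
  fx <- make_resume_pair(file.path(dir, "fx"))
  mods <- load_modules(fx$modules)
  res <- run_workflow(read_workflow(fx$v1), mods, test_opts(dir))
  wf2 <- read_workflow(fx$v2)
  subs <- expand_workflow(wf2, mods)
  records <- load_log(res$log)
  plan <- resume_plan(subs, wf2, records)
  run_tasks <- unique(vapply(subs[plan$run], `[[`, "", "task_id"))
  # soundness: every dependent of a rerun task is itself fully rerun
  for (id in dependents_closure(wf2, run_tasks)) {
    keys <- names(subs)[vapply(subs, `[[`, "", "task_id") == id]
    expect_true(all(keys %in% plan$run), info = id)
  }
  # minimality: nothing reused lacks a success record
  succ_fps <- vapply(Filter(function(r) r$status == "success", records),
                     `[[`, "", "fingerprint")
  for (key in plan$reuse) {
    s <- subs[[key]]
    if (!s$late_bound) expect_true(s$fingerprint %in% succ_fps, info = key)
  }
})

test_that("the latest success record wins for a repeated fingerprint", {
  dir <- scratch_dir()
  log <- file.path(dir, "x.resume")
  append_record(log, rec_fixture("A", returns = c(count = "old")))
  append_record(log, rec_fixture("A", returns = c(count = "new"),
                                 ts = "2026-01-01T00:00:01.000000Z"))
  recs <- load_log(log)
  rbt <- shepherd:::returns_by_task(recs)
  expect_equal(rbt$A[["count"]], "new")
})

test_that("removed tasks and removed dependency edges are warned about, never blocking", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)
  log <- file.path(dir, "x.resume")
  append_record(log, rec_fixture("A"))
  append_record(log, rec_fixture("B", deps = "A"))
  wf_no_b <- workflow(list(stamp_task("A", "x")), executors = local_executors())
  expect_warning(msgs <- warn_removed(load_log(log), wf_no_b), "task B")
  expect_length(msgs, 1L)

  wf_no_edge <- workflow(list(stamp_task("A", "x"), stamp_task("B", "x")),
                         executors = local_executors())
  expect_warning(msgs <- warn_removed(load_log(log), wf_no_edge), "B -> A")

  wf_same <- workflow(list(stamp_task("A", "x"), stamp_task("B", "x", deps = "A")),
                      executors = local_executors())
  expect_silent(msgs <- warn_removed(load_log(log), wf_same))
  expect_length(msgs, 0L)
})
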