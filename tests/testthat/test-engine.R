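test_that("an all-success chain completes with every subtask succeeded", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)
  wf <- chain_workflow(5, dir)
  res <- run_workflow(wf, mods, test_opts(dir))
  expect_equal(res$exit_status, 0L)
  expect_equal(unname(res$counts["succeeded"]), 5L)
  expect_equal(unname(res$counts["failed"]) + unname(res$counts["skipped"]), 0L)
  expect_equal(readLines(file.path(dir, "t5.txt")), "v5")
  # dispatch order respects the chain
  expect_equal(dispatched_keys(res), paste0("t", 1:5, "[0]"))
})

test_that("a mid-chain failure skips exactly the transitive dependents while other branches finish", {
  dir <- scratch_dir()
  mdir <- file.path(dir, "modules")
  make_toy_module(mdir, "stamp", "emit_return")
  make_toy_module(mdir, "alwaysfail", "fail_n_times", n = 999L)
  mods <- load_modules(mdir)
  dir.create(file.path(dir, "markers"))

  wf <- workflow(list(
    stamp_task("ok1", "a", out = file.path(dir, "ok1.txt")),
    task_def("boom", "alwaysfail", "local",
             params = c(marker = file.path(dir, "markers", "boom")),
             dependencies = "ok1"),
    stamp_task("down1", "b", deps = "boom"),
    stamp_task("down2", "c", deps = "down1"),
    stamp_task("side", "d", deps = "ok1", out = file.path(dir, "side.txt"))),
    executors = local_executors())
  res <- run_workflow(wf, mods, test_opts(dir))
  expect_equal(res$exit_status, 1L)
  expect_equal(unname(res$statuses[c("ok1[0]", "side[0]")]),
               c("succeeded", "succeeded"))
  expect_equal(unname(res$statuses["boom[0]"]), "failed")
  expect_equal(unname(res$statuses[c("down1[0]", "down2[0]")]),
               c("skipped", "skipped"))
  expect_true(file.exists(file.path(dir, "side.txt")))
})

test_that("a diamond join dispatches the sink only after both branches succeeded", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)
  wf <- workflow(list(
    stamp_task("A", "a"),
    stamp_task("B", "b", deps = "A"),
    stamp_task("C", "c", deps = "A"),
    stamp_task("D", "d", deps = c("B", "C"))),
    executors = local_executors())
  res <- run_workflow(wf, mods, test_opts(dir))
  expect_equal(res$exit_status, 0L)
  seqs <- vapply(res$trace, `[[`, 0L, "seq")
  ev <- vapply(res$trace, `[[`, "", "event")
  key <- vapply(res$trace, `[[`, "", "key")
  d_dispatch <- seqs[ev == "dispatch" & key == "D[0]"]
  b_success <- seqs[ev == "success" & key == "B[0]"]
  c_success <- seqs[ev == "success" & key == "C[0]"]
  expect_true(d_dispatch > b_success && d_dispatch > c_success)
})

test_that("executor slot limits bound concurrency", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)
  # 3 independent sleeping subtasks on a 1-slot executor: strictly serial,
  # each dispatch happens only after the previous success
  wf <- workflow(list(
    stamp_task("S", "[I]", block = process_block("list", columns = "I",
                                                 rows = list("1", "2", "3")))),
    executors = local_executors(slots = 1L))
  res <- run_workflow(wf, mods, test_opts(dir))
  ev <- vapply(res$trace, `[[`, "", "event")
  expect_equal(ev[ev != "skip"],
               c("dispatch", "success", "dispatch", "success", "dispatch", "success"))
})

test_that("failed existence checks fail the subtask before dispatch instead of crashing the loop", {
  dir <- scratch_dir()
  mdir <- file.path(dir, "modules")
  make_toy_module(mdir, "copy", "copy")
  mods <- load_modules(mdir)
  wf <- workflow(list(task_def("T", "copy", "local",
                               params = c(`in` = file.path(dir, "nope.txt"),
                                          out = file.path(dir, "out.txt")))),
                 executors = local_executors())
  res <- run_workflow(wf, mods, test_opts(dir))
  expect_equal(res$exit_status, 1L)
  expect_equal(unname(res$statuses["T[0]"]), "failed")
  recs <- load_log(res$log)
  expect_equal(recs[[1]]$status, "failure")
})

test_that("detach with only spool jobs outstanding snapshots immediately and reattach is idempotent", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)
  spool <- file.path(dir, "spool")
  wf0 <- workflow(list(
    task_def("S", "stamp", "cluster",
             params = c(value = "s", out = file.path(dir, "s.txt"), delay = "1"))),
    executors = list(executor_def("cluster", "spool", max_slots = 2,
                                  spool_dir = spool)))
  wfp <- file.path(dir, "wf.xml")
  write_workflow(wf0, wfp)
  detach_file <- file.path(dir, "detach.now")
  file.create(detach_file)  # requested before the loop even starts
  snap <- file.path(dir, "snap.json")
  res <- run_workflow(read_workflow(wfp), mods,
                      test_opts(dir, detach_file = detach_file, snapshot = snap,
                                module_dirs = file.path(dir, "modules")))
  expect_equal(res$exit_status, 3L)
  expect_true(res$detached)
  s <- read_snapshot(snap)
  expect_length(s$jobs, 1L)
  # snapshot round-trips
  expect_identical(read_snapshot(snap), s)

  r1 <- reattach(snap, list(poll = 0.02))
  expect_equal(r1$exit_status, 0L)
  expect_equal(readLines(file.path(dir, "s.txt")), "s")
  # second reattach on the same snapshot: jobs already consumed, idempotent
  r2 <- reattach(snap, list(poll = 0.02))
  expect_equal(r2$exit_status, 0L)
  expect_equal(unname(r2$counts["succeeded"]), 1L)
})

test_that("detach after completion reports the run complete with an empty job list", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)
  wf <- chain_workflow(2, dir)
  # the sentinel appears once t2 is done; engine notices during the same run
  # simplest deterministic variant: pre-create it and use a local-only
  # workflow that is already fully reused
  log <- file.path(dir, "run.resume")
  run_workflow(wf, mods, test_opts(dir))
  detach_file <- file.path(dir, "detach.now"); file.create(detach_file)
  snap <- file.path(dir, "snap.json")
  res <- run_workflow(wf, mods, test_opts(dir, resume = log, snapshot = snap,
                                          detach_file = detach_file))
  expect_equal(res$exit_status, 0L)
  expect_length(read_snapshot(snap)$jobs, 0L)
})

test_that("a repeated detach request during the drain is ignored with a warning", {
  st <- new.env()
  st$detach_requested <- FALSE
  st$opt <- list(quiet = TRUE)
  expect_true(request_detach(st))
  expect_warning(request_detach(st), "already requested")
})
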