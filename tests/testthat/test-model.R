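test_that("version ranges validate their bounds and membership", {
  expect_error(version_range(3, 2), "min_version")
  expect_error(parameter_def("p", "integer", default = "abc"), "does not parse")
  expect_error(parameter_def("p", "string", check_existence = TRUE), "file/folder")
})

test_that("interface resolution includes exactly the elements whose range covers the version", {
  mod <- module_descriptor(
    "align", max_version = 3L,
    commands = list(list(range = version_range(), tokens = c("sh", "run.sh"))),
    parameters = list(
      parameter_def("always"),
      parameter_def("late", range = version_range(min_version = 2)),
      parameter_def("early", range = version_range(max_version = 1)),
      parameter_def("window", range = version_range(2, 2))),
    returns = list(return_value_def("hits", range = version_range(min_version = 3))))

  expect_setequal(names(resolve_interface(mod, 1)$parameters), c("always", "early"))
  expect_setequal(names(resolve_interface(mod, 2)$parameters),
                  c("always", "late", "window"))
  expect_setequal(names(resolve_interface(mod, 3)$parameters), c("always", "late"))
  expect_equal(names(resolve_interface(mod, 3)$returns), "hits")
  expect_error(resolve_interface(mod, 99), "outside the supported range")
  expect_error(resolve_interface(mod, 0), "positive integer")
})

test_that("an unbounded element is valid for all versions and membership is contiguous", {
  mod <- module_descriptor(
    "m", max_version = 6L,
    commands = list(list(range = version_range(), tokens = "x")),
    parameters = list(parameter_def("free"),
                      parameter_def("mid", range = version_range(2, 4))))
  for (el in c("free", "mid")) {
    included <- which(vapply(1:6, function(v) {
      el %in% names(resolve_interface(mod, v)$parameters)
    }, TRUE))
    expect_equal(included, seq(min(included), max(included)))
  }
  expect_true("free" %in% names(resolve_interface(mod, 1)$parameters))
  expect_true("free" %in% names(resolve_interface(mod, 6)$parameters))
})

test_that("a module authored without ranges exposes its full interface at version 1", {
  mod <- module_descriptor(
    "plain", commands = list(list(range = version_range(), tokens = "x")),
    parameters = list(parameter_def("a"), parameter_def("b")),
    returns = list(return_value_def("r")))
  iface <- resolve_interface(mod, 1)
  expect_equal(names(iface$parameters), c("a", "b"))
  expect_equal(names(iface$returns), "r")
})

test_that("constant substitution is single-pass and names missing constants", {
  consts <- c(BASE = "/tmp", TRICKY = "${BASE}")
  expect_equal(substitute_constants("${BASE}/out", consts), "/tmp/out")
  expect_equal(substitute_constants("no placeholder", consts), "no placeholder")
  expect_error(substitute_constants("${MISSING}", character(), context = "task t9"),
               "MISSING.*task t9")
  # values are not re-scanned: a value containing ${...} survives verbatim
  expect_equal(substitute_constants("${TRICKY}", consts), "${BASE}")
})

test_that("constant substitution is idempotent when values contain no placeholder syntax", {
  set.seed(7)
  consts <- c(A = "alpha", B = "b-2", C = "/data/c")
  for (i in 1:25) {
    bits <- sample(c("${A}", "${B}", "${C}", "plain", "x/y", "${A}${B}"), 4,
                   replace = TRUE)
    once <- substitute_constants(paste(bits, collapse = "/"), consts)
    expect_identical(substitute_constants(once, consts), once)
  }
})

test_that("workflow validation flags cycles, dangling references and missing parameters", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)

  cyc <- workflow(list(stamp_task("A", "x", deps = "B"),
                       stamp_task("B", "y", deps = "A")),
                  executors = local_executors())
  f <- validate_workflow(cyc, mods)
  expect_true(any(grepl("cycle", f$message[f$level == "error"])))

  bad_exec <- workflow(list(task_def("A", "stamp", "nowhere", params = c(value = "x"))),
                       executors = local_executors())
  f <- validate_workflow(bad_exec, mods)
  expect_true(any(grepl("unknown executor", f$message)))

  # required parameter missing vs. required-with-default
  missing_req <- workflow(list(task_def("A", "stamp", "local")),
                          executors = local_executors())
  f <- validate_workflow(missing_req, mods)
  expect_true(any(grepl("required parameter 'value'", f$message)))

  # 'delay' is required by nobody and has a default: omitting it is fine
  ok <- workflow(list(stamp_task("A", "x")), executors = local_executors())
  expect_equal(nrow(validate_workflow(ok, mods)), 0L)

  unknown_dep <- workflow(list(stamp_task("A", "x", deps = "GHOST")),
                          executors = local_executors())
  expect_true(any(grepl("unknown task", validate_workflow(unknown_dep, mods)$message)))
})

test_that("a task omitting the version attribute resolves against version 1", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir, versions = 2L)
  # 'extra' exists only from version 2 on
  v1_task <- workflow(list(task_def("A", "stamp", "local",
                                    params = c(value = "x", extra = "boom"))),
                      executors = local_executors())
  f <- validate_workflow(v1_task, mods)
  expect_true(any(grepl("'extra' is not part of the version-1 interface", f$message)))

  v2_task <- workflow(list(task_def("A", "stamp", "local", module_version = 2L,
                                    params = c(value = "x", extra = "fine"))),
                      executors = local_executors())
  expect_equal(nrow(validate_workflow(v2_task, mods)), 0L)

  too_new <- workflow(list(task_def("A", "stamp", "local", module_version = 9L,
                                    params = c(value = "x"))),
                      executors = local_executors())
  expect_true(any(grepl("no version 9", validate_workflow(too_new, mods)$message)))
})

test_that("return-value references must name a dependency that declares the value", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)
  not_dep <- workflow(list(stamp_task("A", "a"),
                           stamp_task("B", "$[A.count]")),  # no depends on A
                      executors = local_executors())
  f <- validate_workflow(not_dep, mods)
  expect_true(any(grepl("does not name a dependency", f$message)))

  bad_name <- workflow(list(stamp_task("A", "a"),
                            stamp_task("B", "$[A.nosuch]", deps = "A")),
                       executors = local_executors())
  f <- validate_workflow(bad_name, mods)
  expect_true(any(grepl("declares no return value 'nosuch'", f$message)))
})
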