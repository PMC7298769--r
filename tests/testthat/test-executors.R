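test_that("command building substitutes the template and composes wrappers container-outermost", {
  dir <- scratch_dir()
  mods <- stamp_setup(dir)
  s <- expand_task(stamp_task("A", "x"), character(), mods$stamp)[[1]]

  plain <- build_command(s, mods$stamp, executor_def("local", "local"))
  expect_equal(plain[1:2], c("sh", file.path(mods$stamp$module_dir, "stamp.sh")))
  expect_true(all(c("--value", "x") %in% plain))

  wrappers <- list(pm = wrapper_def("pm", "prefix", prefix = "pm-run"),
                   ct = wrapper_def("ct", "prefix", prefix = "ct-run"))
  ex <- executor_def("local", "local", package_manager = "pm", container = "ct")
  wrapped <- build_command(s, mods$stamp, ex, wrappers)
  # container prefix outermost, package manager inner, then the base command
  expect_equal(wrapped[1], "ct-run")
  expect_equal(wrapped[2], "pm-run")
  expect_equal(wrapped[-(1:2)], plain)

  # pure: identical token list on repeat
  expect_identical(build_command(s, mods$stamp, ex, wrappers), wrapped)

  bad <- executor_def("local", "local", package_manager = "ghost")
  expect_error(build_command(s, mods$stamp, bad, wrappers), "undefined wrapper")
})

test_that("version-specific environment files outrank the default and may be absent", {
  dir <- scratch_dir()
  mdir <- file.path(dir, "foo"); dir.create(mdir)
  expect_null(resolve_env_file(mdir, "foo", 1))
  writeLines("name: foo", file.path(mdir, "foo.conda.yml"))
  expect_equal(basename(resolve_env_file(mdir, "foo", 2)), "foo.conda.yml")
  writeLines("name: foo-v2", file.path(mdir, "foo.v2.conda.yml"))
  expect_equal(basename(resolve_env_file(mdir, "foo", 2)), "foo.v2.conda.yml")
  expect_equal(basename(resolve_env_file(mdir, "foo", 1)), "foo.conda.yml")
})

test_that("package-manager and container wrappers emit deploy commands from module-side files", {
  dir <- scratch_dir()
  mdir <- file.path(dir, "modules")
  make_toy_module(mdir, "tool", "emit_return")
  mods <- load_modules(mdir)
  s <- expand_task(task_def("T", "tool", "local", params = c(value = "v")),
                   character(), mods$tool)[[1]]
  wrappers <- list(conda = wrapper_def("conda", "package_manager", command = "conda"),
                   dock = wrapper_def("dock", "container", runtime = "docker"))
  ex <- executor_def("local", "local", package_manager = "conda", container = "dock")

  # no env file, no image file: wrappers are silently skipped
  bare <- build_command(s, mods$tool, ex, wrappers)
  expect_equal(bare[1], "sh")

  writeLines("name: tool-env", file.path(mods$tool$module_dir, "tool.conda.yml"))
  writeLines("quay.io/biocontainers/tool:1.0", file.path(mods$tool$module_dir, "tool.image"))
  full <- build_command(s, mods$tool, ex, wrappers)
  expect_equal(full[1:3], c("docker", "run", "--rm"))
  expect_true("quay.io/biocontainers/tool:1.0" %in% full)
  conda_at <- which(full == "conda")
  expect_true(length(conda_at) == 1 && full[conda_at + 1] == "run")
  # conda (inner) appears after the container runtime (outer)
  expect_gt(conda_at, which(full == "docker"))
})

test_that("auto-mount lists exactly the existing file/folder parameter paths", {
  dir <- scratch_dir()
  exists1 <- file.path(dir, "in.txt"); file.create(exists1)
  iface <- list(parameters = list(
    a = parameter_def("a", "file"),
    b = parameter_def("b", "file"),
    c = parameter_def("c", "folder"),
    d = parameter_def("d", "string")))
  params <- c(a = exists1, b = file.path(dir, "missing.txt"), c = dir,
              d = exists1)  # d is string-typed: never mounted
  expect_equal(auto_mount_paths(params, iface), c(exists1, dir))
  # duplicates collapse to one mount
  params2 <- c(a = exists1, b = exists1)
  expect_equal(auto_mount_paths(params2, iface), exists1)
})

test_that("container auto-mount can be disabled and mounts appear exactly once", {
  dir <- scratch_dir()
  mdir <- file.path(dir, "modules")
  make_toy_module(mdir, "copy", "copy")
  mods <- load_modules(mdir)
  writeLines("img:1", file.path(mods$copy$module_dir, "copy.image"))
  input <- file.path(dir, "in.txt"); writeLines("data", input)
  s <- expand_task(task_def("T", "copy", "local",
                            params = c(`in` = input, out = file.path(dir, "out"))),
                   character(), mods$copy)[[1]]
  on_w <- list(w = wrapper_def("w", "container", runtime = "docker", auto_mount = TRUE))
  off_w <- list(w = wrapper_def("w", "container", runtime = "docker", auto_mount = FALSE))
  ex <- executor_def("local", "local", container = "w")
  tok_on <- build_command(s, mods$copy, ex, on_w)
  expect_equal(sum(tok_on == paste0(input, ":", input)), 1L)
  tok_off <- build_command(s, mods$copy, ex, off_w)
  expect_false(any(tok_off == "-v"))
})

test_that("local jobs run detached, report exit codes, and polling never blocks", {
  dir <- scratch_dir()
  h0 <- local_submit(c("sh", "-c", "exit 0"), file.path(dir, "j0"))
  h3 <- local_submit(c("sh", "-c", "exit 3"), file.path(dir, "j3"))
  wait_done <- function(h) {
    for (i in 1:300) {
      r <- local_poll(h)
      if (r$state == "done") return(r)
      Sys.sleep(0.01)
    }
    stop("job never finished")
  }
  expect_equal(wait_done(h0)$exit_code, 0L)
  expect_equal(wait_done(h3)$exit_code, 3L)

  hs <- local_submit(c("sleep", "0.5"), file.path(dir, "js"))
  expect_equal(local_poll(hs)$state, "running")
})

test_that("spool jobs get distinct ids, poll via the filesystem, and flag vanished jobs", {
  dir <- scratch_dir()
  spool <- file.path(dir, "spool")
  id1 <- spool_submit(c("sh", "-c", "exit 0"), spool)
  id2 <- spool_submit(c("sleep", "0.4"), spool)
  expect_false(id1 == id2)
  expect_equal(spool_poll(spool, id2)$state, "running")
  for (i in 1:300) {
    if (spool_poll(spool, id1)$state == "done") break
    Sys.sleep(0.01)
  }
  expect_equal(spool_poll(spool, id1)$exit_code, 0L)
  expect_equal(spool_poll(spool, "never-submitted")$state, "lost")
})

test_that("software version capture reads the probe output, skips, or degrades to unknown", {
  dir <- scratch_dir()
  make_toy_module(file.path(dir, "m1"), "probed", "emit_return",
                  version_string = "toytool 3.1.4")
  make_toy_module(file.path(dir, "m2"), "silent", "emit_return")
  make_toy_module(file.path(dir, "m3"), "hangs", "emit_return",
                  version_string = "HANG")
  mods <- load_modules(file.path(dir, c("m1", "m2", "m3")))

  expect_equal(capture_software_version(mods$probed, 1), "toytool 3.1.4")
  expect_null(capture_software_version(mods$silent, 1))
  expect_equal(capture_software_version(mods$hangs, 1, timeout = 1), "unknown")
})
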