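# Programmatic fixtures: portable toy modules, a two-version workflow
# pair exercising resume planning (modified parameter, added samples,
# added tasks), and a kill harness that runs the engine as a separate
# process and force-kills it mid-run. Everything is generated in code;
# nothing is downloaded and the footprint stays in the kilobyte range.

#' Create a toy module on disk
#'
#' Writes a module directory (descriptor `module.xml` plus a portable
#' POSIX-shell script) implementing one of five behaviors:
#' \describe{
#'   \item{copy}{`--in F --out G`: copies a file byte-for-byte (`in` has an
#'     existence check);}
#'   \item{concat}{`--a F --b G --out H`: concatenates two files;}
#'   \item{emit_return}{`--value V [--out F] [--delay S]`: writes `V` to the
#'     optional output file and reports return value `count = V` through
#'     the return-value file — deterministic and distinguishable output;}
#'   \item{fail_n_times}{`--marker F`: exits nonzero on the first `n`
#'     invocations (counted in the marker file), succeeds afterwards;}
#'   \item{sleep}{`--seconds S`: sleeps (default baked into the descriptor).}
#' }
#'
#' @param dir Directory under which the module directory is created.
#' @param name Module name (also the directory name).
#' @param behavior One of the five behaviors.
#' @param n For `fail_n_times`: number of failing invocations.
#' @param seconds Default sleep for the `sleep` behavior.
#' @param versions Number of module versions; with `versions > 1` an
#'   optional parameter `extra` is introduced at version 2, exercising
#'   version-ranged interfaces.
#' @param version_string When non-`NULL`, the script answers a
#'   `--version` probe with this string and the descriptor declares the
#'   version flag; the special value `"HANG"` makes the probe hang
#'   (for timeout behavior).
#' @return The module directory path.
#' @export
make_toy_module <- function(dir, name,
                            behavior = c("copy", "concat", "emit_return",
                                         "fail_n_times", "sleep"),
                            n = 1L, seconds = 0.1, versions = 1L,
                            version_string = NULL) {
  behavior <- match.arg(behavior)
  mdir <- file.path(dir, name)
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  script <- file.path(mdir, paste0(name, ".sh"))

  probe <- if (!is.null(version_string)) {
    if (identical(version_string, "HANG")) {
      c('if [ "$1" = "--version" ]; then sleep 600; exit 0; fi')
    } else {
      c(paste0('if [ "$1" = "--version" ]; then echo ', shQuote(version_string),
               '; exit 0; fi'))
    }
  } else character()

  body <- switch(behavior,
    copy = 'cp "$P_in" "$P_out"',
    concat = 'cat "$P_a" "$P_b" > "$P_out"',
    emit_return = paste(
      '[ -n "$P_delay" ] && [ "$P_delay" != "0" ] && sleep "$P_delay"',
      'if [ -n "$P_out" ]; then printf "%s\\n" "$P_value" > "$P_out"; fi',
      'if [ -n "$SHEPHERD_RETURN_FILE" ]; then',
      '  printf "count\\t%s\\n" "$P_value" > "$SHEPHERD_RETURN_FILE"',
      'fi',
      'exit 0', sep = "\n"),
    fail_n_times = paste(
      'c=0',
      '[ -f "$P_marker" ] && c=$(wc -l < "$P_marker" | tr -d " ")',
      'echo run >> "$P_marker"',
      sprintf('if [ "$c" -lt %d ]; then exit 1; fi', as.integer(n)),
      'exit 0', sep = "\n"),
    sleep = 'sleep "$P_seconds"')

  writeLines(c(
    "#!/bin/sh",
    probe,
    'while [ $# -gt 0 ]; do',
    '  case "$1" in',
    '    --*) key=${1#--}; shift; eval "P_$key=\\$1";;',
    '  esac',
    '  shift',
    'done',
    body), script)

  params <- switch(behavior,
    copy = list(parameter_def("in", "file", required = TRUE, check_existence = TRUE),
                parameter_def("out", "string", required = TRUE)),
    concat = list(parameter_def("a", "file", required = TRUE, check_existence = TRUE),
                  parameter_def("b", "file", required = TRUE, check_existence = TRUE),
                  parameter_def("out", "string", required = TRUE)),
    emit_return = list(parameter_def("value", "string", required = TRUE),
                       parameter_def("out", "string"),
                       parameter_def("delay", "double", default = "0")),
    fail_n_times = list(parameter_def("marker", "string", required = TRUE)),
    sleep = list(parameter_def("seconds", "double",
                               default = format(seconds, scientific = FALSE))))
  if (versions > 1) {
    params <- c(params, list(
      parameter_def("extra", "string", range = version_range(min_version = 2L))))
  }
  returns <- if (behavior == "emit_return") {
    list(return_value_def("count", "string"))
  } else list()

  mod <- module_descriptor(
    name = name, max_version = as.integer(versions),
    commands = list(list(range = version_range(),
                         tokens = c("sh", paste0("{MODULE_DIR}/", name, ".sh")))),
    parameters = params, returns = returns,
    version_flag = if (!is.null(version_string)) "--version" else NULL,
    module_dir = mdir)
  write_module(mod, file.path(mdir, "module.xml"))
  invisible(mdir)
}

#' Create the two-version resume scenario workflow pair
#'
#' Version 1 is a five-task workflow over a deterministic stamping module
#' (`emit_return` behavior): `A`; `B <- A`; `C <- B` (consuming `B`'s
#' return value, so it is late-bound); `D <- A` with a two-row sample
#' process block; `E <- D`. Version 2 modifies one of `B`'s parameter
#' values, grows `D`'s block to four samples, and adds task `F <- E` plus
#' an independent task `Z`. Resuming v2 against v1's log must therefore
#' execute exactly `{B, C, D[2], D[3], E, F, Z}` and reuse
#' `{A, D[0], D[1]}`.
#'
#' `F`'s dependency on `E` and `Z`'s independence are this fixture's own
#' reconstruction (the scenario specifies only that a dependent and an
#' independent task are added); they exercise both cases.
#'
#' @param dir Scratch directory for modules, data and workflows.
#' @param spool Put tasks `D` and `E` on a spool (cluster-style) executor?
#' @param delay_d Seconds each `D` subtask sleeps (used to hold `D` busy
#'   for detach scenarios).
#' @param version_string Version string the stamping module reports
#'   (`NULL` disables software-version capture).
#' @return List with paths: `v1`, `v2` (workflow XMLs), `modules`, `data`,
#'   `spool` (or `NULL`).
#' @export
make_resume_pair <- function(dir, spool = FALSE, delay_d = 0,
                                 version_string = "toytool 3.1.4") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  modules_dir <- file.path(dir, "modules")
  data_dir <- file.path(normalizePath(dir), "data")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  make_toy_module(modules_dir, "stamp", "emit_return",
                  version_string = version_string)
  spool_dir <- if (spool) file.path(normalizePath(dir), "spool") else NULL

  executors <- c(list(executor_def("local", "local", max_slots = 2L)),
                 if (spool) list(executor_def("cluster", "spool", max_slots = 4L,
                                              spool_dir = spool_dir)))
  exec_de <- if (spool) "cluster" else "local"
  stamp_task <- function(id, value, deps = character(), executor = "local",
                         block = NULL, out = paste0("${DATA}/", id, ".txt"),
                         delay = NULL) {
    params <- c(value = value, out = out)
    if (!is.null(delay)) params <- c(params, delay = format(delay, scientific = FALSE))
    task_def(id, module = "stamp", executor = executor, params = params,
             dependencies = deps, block = block)
  }
  mk <- function(b_value, d_samples, extra_tasks) {
    tasks <- c(list(
      stamp_task("A", "alpha"),
      stamp_task("B", b_value, deps = "A"),
      stamp_task("C", "$[B.count]-c", deps = "B"),
      stamp_task("D", "[SAMPLE]", deps = "A", executor = exec_de,
                 out = "${DATA}/D_[SAMPLE].txt", delay = delay_d,
                 block = process_block("list", columns = "SAMPLE",
                                       rows = as.list(d_samples))),
      stamp_task("E", "epsilon", deps = "D", executor = exec_de)),
      extra_tasks)
    workflow(tasks, constants = c(DATA = data_dir), executors = executors)
  }
  v1 <- mk("beta-one", c("s1", "s2"), list())
  v2 <- mk("beta-two", c("s1", "s2", "s3", "s4"),
           list(stamp_task("F", "phi", deps = "E"),
                stamp_task("Z", "zeta")))
  v1_path <- file.path(dir, "workflow-v1.xml")
  v2_path <- file.path(dir, "workflow-v2.xml")
  write_workflow(v1, v1_path)
  write_workflow(v2, v2_path)
  list(v1 = v1_path, v2 = v2_path, modules = modules_dir, data = data_dir,
       spool = spool_dir)
}

#' Run the engine as a separate process, killing it mid-run
#'
#' Launches the command-line entry point in a detached child process,
#' watches the provenance log, and sends `SIGKILL` as soon as
#' `kill_after` success records have appeared (with `kill_after = 0` the
#' engine is killed immediately). Returns the artifacts needed for a
#' follow-up resume. If the workflow completes before the threshold is
#' reached the engine simply exits and nothing is killed.
#'
#' @param workflow_path,modules_dir Workflow XML and modules directory.
#' @param log Provenance log path the engine writes.
#' @param kill_after Number of success records to wait for before killing.
#' @param args Extra CLI arguments (e.g. `c("--resume", log)`).
#' @param poll Engine poll interval (seconds).
#' @param timeout Give up waiting after this many seconds.
#' @return List: `log`, `exit_code` (`NA` when killed), `killed`.
#' @export
chaos_run <- function(workflow_path, modules_dir, log, kill_after,
                      args = character(), poll = 0.05, timeout = 60) {
  eng <- spawn_engine(c("run", workflow_path, "--modules", modules_dir,
                        "--log", log, "--poll-interval", format(poll), args))
  deadline <- Sys.time() + timeout
  killed <- FALSE
  repeat {
    if (file.exists(eng$ec_file)) break
    nsucc <- if (file.exists(log)) {
      sum(grepl('"status":"success"', readLines(log, warn = FALSE), fixed = TRUE))
    } else 0L
    if (nsucc >= kill_after) {
      tools::pskill(eng$pid, tools::SIGKILL)
      killed <- TRUE
      break
    }
    if (Sys.time() > deadline) stop("chaos_run: engine did not progress in time")
    Sys.sleep(0.01)
  }
  if (!killed) wait_engine(eng, timeout)
  list(log = log, exit_code = if (killed) NA_integer_ else read_exit_code(eng),
       killed = killed)
}

# -- background engine process helpers (shared by chaos and detach tests) ----

cli_script_path <- function() {
  system.file("exec", "shepherd.R", package = "shepherd", mustWork = FALSE)
}

#' Launch the CLI engine as a detached background process
#'
#' @param args Character vector of CLI arguments.
#' @param workdir Working directory for the child.
#' @return List: `pid` of the engine process, `ec_file` (appears with the
#'   exit code when the engine terminates on its own), `out`, `err`.
#' @export
spawn_engine <- function(args, workdir = tempfile("engine-")) {
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  cli <- cli_script_path()
  if (!nzchar(cli) || !file.exists(cli)) {
    # running from a source tree (not installed): fall back to exec/
    cli <- file.path(find.package("shepherd"), "exec", "shepherd.R")
  }
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- file.path(workdir, "out"); err <- file.path(workdir, "err")
  pid_file <- file.path(workdir, "pid"); ec_file <- file.path(workdir, "ec")
  wrapper <- file.path(workdir, "wrapper.sh")
  writeLines(c(
    "#!/bin/sh",
    paste0("cd ", shQuote(workdir)),
    # the child must resolve the same package libraries as this process
    paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = ":"))),
    "export R_LIBS",
    paste0(paste(shQuote(c(rscript, cli, args)), collapse = " "),
           " > ", shQuote(out), " 2> ", shQuote(err), " &"),
    paste0("echo $! > ", shQuote(pid_file)),
    "wait $!",
    paste0("echo $? > ", shQuote(ec_file))), wrapper)
  system(paste("nohup sh", shQuote(wrapper), "> /dev/null 2>&1 &"))
  for (i in 1:500) {
    if (file.exists(pid_file) && length(readLines(pid_file, warn = FALSE))) break
    Sys.sleep(0.01)
  }
  list(pid = as.integer(readLines(pid_file, warn = FALSE)[1]),
       ec_file = ec_file, out = out, err = err, workdir = workdir)
}

#' Wait for a background engine to terminate on its own
#' @param eng Handle from [spawn_engine()].
#' @param timeout Seconds.
#' @return The exit code.
#' @export
wait_engine <- function(eng, timeout = 60) {
  deadline <- Sys.time() + timeout
  while (!file.exists(eng$ec_file)) {
    if (Sys.time() > deadline) stop("engine did not terminate within ", timeout, " s")
    Sys.sleep(0.02)
  }
  read_exit_code(eng)
}

read_exit_code <- function(eng) {
  for (i in 1:100) {
    ln <- tryCatch(readLines(eng$ec_file, warn = FALSE), error = function(e) character())
    if (length(ln)) return(as.integer(ln[1]))
    Sys.sleep(0.01)
  }
  NA_integer_
}
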