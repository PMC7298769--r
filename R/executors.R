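# Executor contract and the two implementations.
#
# Both executors run a subtask as a small POSIX-shell driver script that
# executes the command, captures stdout/stderr, and atomically writes an
# exit-status file (write to .tmp, then mv). Polling reads only the
# filesystem, so it is non-blocking and works from any process.
#
# * local: drivers live under the engine's run directory.
# * spool: drivers live in the executor's spool directory under a stable
#   job id (files <id>.cmd/.out/.err/.status/.ret). The worker is spawned
#   detached (nohup + background, spawning shell exits immediately), so
#   spool jobs survive the death of the engine process — the property the
#   detach/reattach mode relies on.

#' Build the final command token list for a subtask
#'
#' The base command comes from the module's version-specific template:
#' `{MODULE_DIR}` and `{param}` slots inside tokens are substituted, and
#' any resolved parameter not referenced by the template is appended as a
#' `--name value` pair (in interface order). The executor's
#' package-manager wrapper is then applied innermost and its container
#' wrapper outermost, so a package manager can run inside a container.
#' Wrappers whose module-side file (conda environment / image name) is
#' absent are skipped silently; `identity` wrappers are no-ops.
#'
#' @param subtask A resolved (non-late-bound) subtask.
#' @param module Its [module_descriptor()].
#' @param executor_def The executor running it.
#' @param wrappers Named list of [wrapper_def()]s from the workflow.
#' @return Character vector of command tokens.
#' @export
build_command <- function(subtask, module, executor_def, wrappers = list()) {
  stopifnot(!isTRUE(subtask$late_bound))
  tokens <- base_command(module, subtask$module_version, subtask$params)
  iface <- resolve_interface(module, subtask$module_version)
  for (role in c("package_manager", "container")) {
    wname <- executor_def[[role]]
    if (is.null(wname)) next
    w <- wrappers[[wname]]
    if (is.null(w)) stop("executor ", executor_def$name, " references undefined wrapper ",
                         sQuote(wname), call. = FALSE)
    tokens <- apply_wrapper(w, tokens, module, subtask$module_version,
                            subtask$params, iface)
  }
  tokens
}

base_command <- function(module, version, params, drop_unfilled = FALSE) {
  tokens <- command_for_version(module, version)
  tokens <- gsub("{MODULE_DIR}", module$module_dir, tokens, fixed = TRUE)
  used <- character()
  for (nm in names(params)) {
    slot <- paste0("{", nm, "}")
    if (any(grepl(slot, tokens, fixed = TRUE))) {
      tokens <- gsub(slot, params[[nm]], tokens, fixed = TRUE)
      used <- c(used, nm)
    }
  }
  if (drop_unfilled) {
    tokens <- tokens[!grepl("\\{[A-Za-z_][A-Za-z0-9_]*\\}", tokens)]
  }
  rest <- setdiff(names(params), used)
  c(tokens, unlist(lapply(rest, function(nm) c(paste0("--", nm), params[[nm]]))))
}

apply_wrapper <- function(w, tokens, module, version, params = character(),
                          iface = NULL) {
  switch(w$kind,
    identity = tokens,
    prefix = c(strsplit(w$settings$prefix, " +")[[1]], tokens),
    package_manager = {
      env <- resolve_env_file(module$module_dir, module$name, version)
      if (is.null(env)) tokens
      else c(w$settings$command, "run", "--file", env, "--", tokens)
    },
    container = {
      img <- resolve_image_file(module$module_dir, module$name, version)
      if (is.null(img)) return(tokens)
      image <- trimws(readLines(img, n = 1L, warn = FALSE))
      mounts <- if (isTRUE(w$settings$auto_mount)) {
        auto_mount_paths(params, iface)
      } else character()
      c(w$settings$runtime, "run", "--rm",
        unlist(lapply(mounts, function(p) c("-v", paste0(p, ":", p)))),
        image, tokens)
    })
}

#' Paths a container wrapper auto-mounts for a subtask
#'
#' The existing absolute paths among the subtask's file/folder-typed
#' parameter values, deduplicated, in parameter order.
#'
#' @param params Named character vector of resolved parameters.
#' @param iface Effective interface (from [resolve_interface()]).
#' @return Character vector of paths (possibly empty).
#' @export
auto_mount_paths <- function(params, iface) {
  typed <- names(Filter(function(p) p$value_type %in% c("file", "folder"),
                        iface$parameters))
  vals <- unname(params[intersect(names(params), typed)])
  unique(vals[substr(vals, 1, 1) == "/" & file.exists(vals)])
}

#' Locate the environment file of a module version
#'
#' Prefers the version-specific `<module>.v<version>.conda.yml` in the
#' module directory, falls back to the default `<module>.conda.yml`, and
#' returns `NULL` when neither exists (the package-manager wrapper is then
#' skipped for this module).
#'
#' @param module_dir,module_name,version Module directory, name, version.
#' @return Path or `NULL`.
#' @export
resolve_env_file <- function(module_dir, module_name, version) {
  for (f in file.path(module_dir,
                      c(sprintf("%s.v%d.conda.yml", module_name, as.integer(version)),
                        paste0(module_name, ".conda.yml")))) {
    if (file.exists(f)) return(f)
  }
  NULL
}

# analogous lookup for the container image-name file
resolve_image_file <- function(module_dir, module_name, version) {
  for (f in file.path(module_dir,
                      c(sprintf("%s.v%d.image", module_name, as.integer(version)),
                        paste0(module_name, ".image")))) {
    if (file.exists(f)) return(f)
  }
  NULL
}

## ---- job drivers -----------------------------------------------------------

write_driver <- function(cmd_file, tokens, out, err, status, ret, workdir) {
  lines <- c(
    "#!/bin/sh",
    paste0("cd ", shQuote(workdir)),
    paste0("SHEPHERD_RETURN_FILE=", shQuote(ret)),
    "export SHEPHERD_RETURN_FILE",
    paste0(paste(shQuote(tokens), collapse = " "),
           " > ", shQuote(out), " 2> ", shQuote(err)),
    "ec=$?",
    paste0("echo $ec > ", shQuote(paste0(status, ".tmp"))),
    paste0("mv ", shQuote(paste0(status, ".tmp")), " ", shQuote(status)))
  writeLines(lines, cmd_file)
  invisible(cmd_file)
}

spawn_detached <- function(cmd_file) {
  rc <- system(paste("nohup sh", shQuote(cmd_file), "> /dev/null 2>&1 &"))
  if (rc != 0) stop("failed to spawn job driver ", cmd_file, call. = FALSE)
  invisible(rc)
}

#' Submit a command to the local executor
#'
#' @param tokens Command token list.
#' @param job_dir Directory for this job's driver and capture files
#'   (created if needed).
#' @param workdir Working directory for the command.
#' @return An opaque handle for [local_poll()].
#' @export
local_submit <- function(tokens, job_dir, workdir = job_dir) {
  dir.create(job_dir, recursive = TRUE, showWarnings = FALSE)
  h <- list(kind = "local", dir = job_dir,
            cmd = file.path(job_dir, "cmd.sh"),
            out = file.path(job_dir, "out"),
            err = file.path(job_dir, "err"),
            status = file.path(job_dir, "status"),
            ret = file.path(job_dir, "ret"))
  write_driver(h$cmd, tokens, h$out, h$err, h$status, h$ret, workdir)
  tryCatch(spawn_detached(h$cmd),
           error = function(e) writeLines("127", h$status))
  h
}

#' Poll a local job (non-blocking)
#' @param handle Handle from [local_submit()].
#' @return `list(state = "running")` or
#'   `list(state = "done", exit_code = , ...capture paths)`.
#' @export
local_poll <- function(handle) {
  if (!file.exists(handle$status)) return(list(state = "running"))
  list(state = "done",
       exit_code = as.integer(readLines(handle$status, n = 1L, warn = FALSE)),
       out = handle$out, err = handle$err, ret = handle$ret)
}

#' Submit a command to a spool executor
#'
#' Writes `<job_id>.cmd` into the spool directory and spawns a detached
#' worker that executes it and atomically writes `<job_id>.status` (plus
#' `.out`, `.err` and the `.ret` return-value file). The worker survives
#' the engine process, emulating a cluster workload manager.
#'
#' @param tokens Command token list.
#' @param spool_dir Spool directory (created if needed).
#' @param job_id Unique, stable job identifier; generated when `NULL`.
#' @param workdir Working directory for the command.
#' @return The job id.
#' @export
spool_submit <- function(tokens, spool_dir, job_id = NULL, workdir = spool_dir) {
  dir.create(spool_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(job_id)) {
    job_id <- sprintf("job-%d-%s", Sys.getpid(),
                      paste(sample(c(letters, 0:9), 10, replace = TRUE), collapse = ""))
  }
  p <- function(ext) file.path(spool_dir, paste0(job_id, ".", ext))
  write_driver(p("cmd"), tokens, p("out"), p("err"), p("status"), p("ret"), workdir)
  spawn_detached(p("cmd"))
  job_id
}

#' Poll a spool job by id (filesystem only)
#'
#' @param spool_dir Spool directory.
#' @param job_id Job id from [spool_submit()] or a detach snapshot.
#' @return `list(state = "running")`, `list(state = "done", exit_code = , ...)`,
#'   or `list(state = "lost")` when the job vanished from the spool (no
#'   status and no command file) — treated as failed by the engine.
#' @export
spool_poll <- function(spool_dir, job_id) {
  p <- function(ext) file.path(spool_dir, paste0(job_id, ".", ext))
  if (file.exists(p("status"))) {
    return(list(state = "done",
                exit_code = as.integer(readLines(p("status"), n = 1L, warn = FALSE)),
                out = p("out"), err = p("err"), ret = p("ret")))
  }
  if (file.exists(p("cmd"))) return(list(state = "running"))
  list(state = "lost")
}

## ---- software version capture ----------------------------------------------

#' Capture the third-party software version behind a module
#'
#' After a subtask succeeds, the module's base command is invoked with the
#' module's version flag (no task parameters) under the same wrappers as
#' the task, and the first non-empty output line, stripped, is taken as
#' the version string. A nonzero exit, a timeout, or empty output degrade
#' to `"unknown"`. Returns `NULL` (capture skipped) when the module
#' declares no version flag.
#'
#' @param module A [module_descriptor()].
#' @param version Module version used by the subtask.
#' @param executor_def,wrappers Executor and wrapper definitions (the probe
#'   runs under the task's wrapper environment).
#' @param timeout Seconds before the probe is abandoned (default 30).
#' @return Version string, `"unknown"`, or `NULL`.
#' @export
capture_software_version <- function(module, version, executor_def = NULL,
                                     wrappers = list(), timeout = 30) {
  if (is.null(module$version_flag)) return(NULL)
  tokens <- base_command(module, version, character(), drop_unfilled = TRUE)
  tokens <- c(tokens, module$version_flag)
  if (!is.null(executor_def)) {
    for (role in c("package_manager", "container")) {
      wname <- executor_def[[role]]
      if (!is.null(wname) && !is.null(wrappers[[wname]])) {
        tokens <- apply_wrapper(wrappers[[wname]], tokens, module, version)
      }
    }
  }
  out <- tryCatch(
    suppressWarnings(system2(tokens[1], shQuote(tokens[-1]),
                             stdout = TRUE, stderr = FALSE, timeout = timeout)),
    error = function(e) structure(character(), status = 126L))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) return("unknown")
  out <- trimws(out)
  out <- out[nzchar(out)]
  if (!length(out)) "unknown" else out[[1]]
}
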