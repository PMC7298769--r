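# The scheduler. One single-threaded poll loop per engine process:
#
#   absorb finished jobs -> (maybe) notice a detach request ->
#   dispatch ready subtasks -> check termination -> sleep(poll)
#
# Subtask statuses: waiting, running, succeeded, failed, skipped
# (the last three terminal). A subtask is ready when every subtask of
# every task it depends on has succeeded. On a failure, all transitive
# dependents are marked skipped; independent branches continue. A success
# becomes durable (and visible to dependents) only after its log record is
# flushed.
#
# Detach: after a request (sentinel file or SIGINT), no further dispatch
# to local executors while spool dispatch continues; once local work has
# drained the outstanding spool jobs are snapshotted and the engine exits
# with the distinct "detached" status. Reattach restores the snapshot,
# adopts the recorded spool jobs, and resumes the normal loop — from any
# working directory, since all recorded paths are absolute.

ENGINE_OK <- 0L; ENGINE_FAILED <- 1L; ENGINE_INVALID <- 2L; ENGINE_DETACHED <- 3L

default_options <- function() {
  list(log = NULL, resume = NULL, poll = 1, run_dir = NULL,
       detach_file = NULL, snapshot = NULL, auto_detach = FALSE,
       probe_timeout = 30, dry_run = FALSE, attach_jobs = list(),
       module_dirs = character(), quiet = TRUE)
}

#' Run a workflow
#'
#' Validates, expands, optionally applies a resume plan from a prior log,
#' and drives the scheduling loop to a terminal state. Every subtask
#' success is appended to the provenance log (with resolved parameters,
#' return values, module version and captured software version) before it
#' is considered succeeded.
#'
#' @param wf A [workflow()] (or path to one).
#' @param modules Named list of module descriptors ([load_modules()]).
#' @param options Named list, merged over the defaults:
#'   \describe{
#'     \item{log}{provenance log path (default: `<workflow>.<timestamp>.resume`
#'       next to the workflow file, or under `run_dir`);}
#'     \item{resume}{path of a prior log to resume from (appends to it when
#'       `log` is not given separately);}
#'     \item{poll}{poll interval in seconds (default 1);}
#'     \item{run_dir}{directory for local job drivers and capture files;}
#'     \item{detach_file}{sentinel path; its appearance requests a detach
#'       (SIGINT does too);}
#'     \item{snapshot}{detach snapshot path (default `<log>.detach.json`);}
#'     \item{auto_detach}{run a single auto-detach cycle (absorb finished
#'       jobs, dispatch, snapshot, terminate) instead of the full loop;}
#'     \item{probe_timeout}{software-version probe timeout in seconds;}
#'     \item{dry_run}{plan only, execute nothing;}
#'     \item{attach_jobs}{internal: spool jobs adopted by [reattach()].}
#'   }
#' @return A `shepherd_run` object: exit status (0 complete, 1 failures
#'   present, 3 detached), per-status counts, per-subtask statuses, the
#'   ordered dispatch/completion trace, and the log/snapshot paths.
#' @export
run_workflow <- function(wf, modules, options = list()) {
  if (is.character(wf)) wf <- read_workflow(wf)
  opt <- default_options()
  opt[names(options)] <- options
  findings <- validate_workflow(wf, modules)
  errs <- findings[findings$level == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("workflow is invalid:\n  ",
         paste(sprintf("[%s] %s", ifelse(is.na(errs$task), "-", errs$task),
                       errs$message), collapse = "\n  "), call. = FALSE)
  }
  if (is.null(opt$log)) {
    base <- attr(wf, "path") %||% file.path(opt$run_dir %||% ".", "workflow")
    opt$log <- if (!is.null(opt$resume)) opt$resume else
      paste0(base, ".", format(Sys.time(), "%Y%m%d%H%M%S", tz = "UTC"), ".resume")
  }
  if (is.null(opt$run_dir)) opt$run_dir <- file.path(tempdir(), "shepherd-run")
  if (is.null(opt$snapshot)) opt$snapshot <- paste0(opt$log, ".detach.json")
  dir.create(opt$run_dir, recursive = TRUE, showWarnings = FALSE)

  st <- new.env(parent = emptyenv())
  st$wf <- wf; st$modules <- modules; st$opt <- opt
  st$subtasks <- expand_workflow(wf, modules)
  st$status <- stats::setNames(rep("waiting", length(st$subtasks)), names(st$subtasks))
  st$handles <- list()          # key -> executor handle
  st$trace <- list()            # ordered dispatch/terminal events
  st$returns <- list()          # task id -> merged return values
  st$detach_requested <- FALSE
  st$spool_poll_enabled <- TRUE
  st$seq <- 0L

  # resume: reuse everything the plan says has already run
  if (!is.null(opt$resume)) {
    records <- load_log(opt$resume)
    warn_removed(records, wf)
    plan <- resume_plan(st$subtasks, wf, records)
    logged <- returns_by_task(records)
    for (key in plan$reuse) {
      st$status[[key]] <- "succeeded"
      id <- st$subtasks[[key]]$task_id
      st$returns[[id]] <- merge_returns(st$returns[[id]], logged[[id]])
    }
    st$plan <- plan
  }

  if (isTRUE(opt$dry_run)) {
    return(run_result(st, ENGINE_OK, dry_run = TRUE))
  }

  # jobs adopted from a detach snapshot: mark running with their handles
  for (job in opt$attach_jobs) {
    key <- paste0(job$task_id, "[", job$subtask_index, "]")
    if (!key %in% names(st$status) || st$status[[key]] != "waiting") next
    st$handles[[key]] <- list(kind = "spool", spool_dir = job$spool_dir,
                              job_id = job$job_id)
    st$status[[key]] <- "running"
  }

  engine_loop(st)
}

merge_returns <- function(old, new) {
  out <- c(old %||% character(), new %||% character())
  out[!duplicated(names(out), fromLast = TRUE)]
}

trace_event <- function(st, event, key) {
  st$seq <- st$seq + 1L
  st$trace[[st$seq]] <- list(seq = st$seq, event = event, key = key)
}

engine_say <- function(st, ...) if (!isTRUE(st$opt$quiet)) message("[shepherd] ", ...)

engine_loop <- function(st) {
  auto <- isTRUE(st$opt$auto_detach)
  if (auto) {
    absorb(st)                      # one absorb pass of already-finished jobs
    st$spool_poll_enabled <- FALSE  # within the cycle, spool jobs are not re-polled
  }
  repeat {
    absorb(st)
    if (!is.null(st$opt$detach_file) && file.exists(st$opt$detach_file)) {
      request_detach(st)
    }
    dispatch(st)
    running <- names(st$status)[st$status == "running"]
    kinds <- vapply(running, function(k) st$handles[[k]]$kind, "")
    local_running <- running[kinds == "local"]
    spool_running <- running[kinds == "spool"]

    if (st$detach_requested && !length(local_running)) {
      if (!any(st$status %in% c("waiting", "running"))) {
        write_snapshot(st, list())  # detach after completion: empty job list
        return(run_result(st, summary_status(st)))
      }
      write_snapshot(st, spool_jobs(st, spool_running))
      for (k in spool_running) st$status[[k]] <- "waiting"  # reattach re-adopts
      return(run_result(st, ENGINE_DETACHED, detached = TRUE))
    }
    if (auto && !length(local_running) && !dispatchable_exists(st)) {
      # a cycle waits for local work only; once nothing more can be
      # started it snapshots the outstanding spool jobs and terminates
      if (length(spool_running)) {
        write_snapshot(st, spool_jobs(st, spool_running))
        for (k in spool_running) st$status[[k]] <- "waiting"
        return(run_result(st, ENGINE_DETACHED, detached = TRUE))
      }
      if (any(st$status == "waiting")) {
        for (k in names(st$status)[st$status == "waiting"]) st$status[[k]] <- "skipped"
        warning("deadlocked subtasks marked skipped", call. = FALSE)
      }
      return(run_result(st, summary_status(st)))
    }
    if (!any(st$status %in% c("waiting", "running"))) {
      return(run_result(st, summary_status(st)))
    }
    if (!length(running) && !dispatchable_exists(st) && !st$detach_requested) {
      # nothing running, nothing dispatchable, but waiting subtasks remain:
      # their dependencies can never be satisfied
      for (k in names(st$status)[st$status == "waiting"]) st$status[[k]] <- "skipped"
      warning("deadlocked subtasks marked skipped", call. = FALSE)
      return(run_result(st, summary_status(st)))
    }
    interrupted <- tryCatch({ Sys.sleep(st$opt$poll); FALSE },
                            interrupt = function(e) TRUE)
    if (interrupted) request_detach(st)
  }
}

#' Request a detach of the running engine
#'
#' Normally triggered by the detach sentinel file or SIGINT during
#' [run_workflow()]. After the request, nothing new is dispatched to
#' local executors while spool submission continues; once local work has
#' drained, the outstanding spool jobs are written to the detach snapshot
#' and the engine terminates with the detached exit status. A second
#' request during the drain is ignored with a warning.
#'
#' @param state Internal engine state.
#' @export
request_detach <- function(state) {
  if (isTRUE(state$detach_requested)) {
    warning("detach already requested; ignoring repeated request", call. = FALSE)
    return(invisible(FALSE))
  }
  state$detach_requested <- TRUE
  engine_say(state, "detach requested: draining local executors")
  invisible(TRUE)
}

task_state <- function(st, id) {
  stat <- st$status[vapply(st$subtasks, `[[`, "", "task_id")[names(st$status)] == id]
  if (!length(stat) || all(stat == "succeeded")) return("succeeded")
  if (any(stat == "failed")) return("failed")
  if (any(stat == "skipped")) return("skipped")
  "pending"
}

ready_keys <- function(st) {
  keys <- names(st$status)[st$status == "waiting"]
  keep <- vapply(keys, function(k) {
    deps <- st$wf$tasks[[st$subtasks[[k]]$task_id]]$dependencies
    all(vapply(deps, function(d) task_state(st, d) == "succeeded", TRUE))
  }, TRUE)
  keys[keep]
}

#' Compute the ready set of a scheduler state
#'
#' The waiting subtasks all of whose dependency tasks have every subtask
#' succeeded (late-bound subtasks are resolved at dispatch, after their
#' dependencies' return values are available).
#'
#' @param state Internal engine state (as passed to [request_detach()]).
#' @return List of ready subtasks.
#' @export
ready_set <- function(state) state$subtasks[ready_keys(state)]

dispatchable_exists <- function(st) {
  keys <- ready_keys(st)
  if (st$detach_requested) {
    keys <- keys[vapply(keys, function(k) {
      st$wf$executors[[st$subtasks[[k]]$executor]]$kind == "spool"
    }, TRUE)]
  }
  length(keys) > 0
}

dispatch <- function(st) {
  for (key in ready_keys(st)) {
    s <- st$subtasks[[key]]
    ex <- st$wf$executors[[s$executor]]
    if (st$detach_requested && ex$kind != "spool") next
    slots_used <- sum(vapply(names(st$status)[st$status == "running"],
                             function(k) st$subtasks[[k]]$executor == s$executor, TRUE))
    if (slots_used >= ex$max_slots) next
    tryCatch({
      if (isTRUE(s$late_bound)) {
        s <- resolve_late_bindings(s, st$returns)
        st$subtasks[[key]] <- s
      }
      check_param_existence(s, st$modules[[s$module]])
      tokens <- build_command(s, st$modules[[s$module]], ex, st$wf$wrappers)
      trace_event(st, "dispatch", key)
      st$handles[[key]] <- if (ex$kind == "local") {
        h <- local_submit(tokens,
                          job_dir = file.path(st$opt$run_dir, "jobs",
                                              paste0(s$task_id, "_", s$subtask_index,
                                                     "_", st$seq)),
                          workdir = st$opt$run_dir)
        h$spool_dir <- NULL; h$kind <- "local"; h
      } else {
        job_id <- sprintf("%s-%d-%s", s$task_id, s$subtask_index,
                          substr(s$fingerprint, 1, 12))
        list(kind = "spool", spool_dir = ex$spool_dir,
             job_id = spool_submit(tokens, ex$spool_dir, job_id = job_id,
                                   workdir = st$opt$run_dir))
      }
      st$status[[key]] <- "running"
      engine_say(st, "dispatched ", key, " on ", s$executor)
    }, error = function(e) {
      complete_subtask(st, key, s, exit_code = NA_integer_,
                       reason = conditionMessage(e))
    })
  }
}

check_param_existence <- function(s, module) {
  iface <- resolve_interface(module, s$module_version)
  for (p in iface$parameters) {
    if (p$check_existence && p$name %in% names(s$params) &&
        !file.exists(s$params[[p$name]])) {
      stop("parameter ", p$name, " of ", subtask_key(s), ": path ",
           s$params[[p$name]], " does not exist", call. = FALSE)
    }
  }
}

absorb <- function(st) {
  for (key in names(st$status)[st$status == "running"]) {
    h <- st$handles[[key]]
    res <- if (h$kind == "local") local_poll(h) else {
      if (!st$spool_poll_enabled) next
      spool_poll(h$spool_dir, h$job_id)
    }
    if (res$state == "running") next
    s <- st$subtasks[[key]]
    if (res$state == "lost") {
      complete_subtask(st, key, s, exit_code = NA_integer_,
                       reason = "job vanished from spool")
    } else {
      complete_subtask(st, key, s, exit_code = res$exit_code, ret_file = res$ret)
    }
  }
}

complete_subtask <- function(st, key, s, exit_code, ret_file = NULL, reason = NULL) {
  ok <- !is.na(exit_code) && exit_code == 0L
  module <- st$modules[[s$module]]
  returns <- character()
  if (ok && !is.null(ret_file) && length(module$returns)) {
    declared <- names(resolve_interface(module, s$module_version)$returns)
    all_ret <- tryCatch(parse_return_file(ret_file), error = function(e) character())
    returns <- all_ret[intersect(names(all_ret), declared)]
  }
  sv <- if (ok) {
    capture_software_version(module, s$module_version,
                             st$wf$executors[[s$executor]], st$wf$wrappers,
                             timeout = st$opt$probe_timeout)
  } else NULL
  rec <- log_record(task_id = s$task_id, subtask_index = s$subtask_index,
                    module = s$module, module_version = s$module_version,
                    fingerprint = s$fingerprint %||% NA_character_,
                    params = s$params, returns = returns,
                    status = if (ok) "success" else "failure",
                    executor = s$executor, software_version = sv,
                    dependencies = st$wf$tasks[[s$task_id]]$dependencies)
  append_record(st$opt$log, rec)   # durable before the status flips
  st$status[[key]] <- if (ok) "succeeded" else "failed"
  st$handles[[key]] <- NULL
  trace_event(st, if (ok) "success" else "failure", key)
  if (ok) {
    st$returns[[s$task_id]] <- merge_returns(st$returns[[s$task_id]], returns)
    engine_say(st, key, " succeeded")
  } else {
    engine_say(st, key, " failed",
               if (!is.null(reason)) paste0(" (", reason, ")") else
                 paste0(" (exit ", exit_code, ")"))
    skip_dependents(st, s$task_id)
  }
  invisible(rec)
}

skip_dependents <- function(st, failed_task) {
  doomed <- dependents_closure(st$wf, failed_task)
  for (key in names(st$status)) {
    if (st$status[[key]] == "waiting" && st$subtasks[[key]]$task_id %in% doomed) {
      st$status[[key]] <- "skipped"
      trace_event(st, "skip", key)
    }
  }
}

summary_status <- function(st) {
  if (any(st$status %in% c("failed", "skipped"))) ENGINE_FAILED else ENGINE_OK
}

spool_jobs <- function(st, keys) {
  lapply(keys, function(k) {
    s <- st$subtasks[[k]]
    h <- st$handles[[k]]
    list(job_id = h$job_id, spool_dir = h$spool_dir, task_id = s$task_id,
         subtask_index = s$subtask_index, fingerprint = s$fingerprint,
         executor = s$executor)
  })
}

write_snapshot <- function(st, jobs) {
  snap <- list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"),
               workflow = as.character(attr(st$wf, "path") %||% NA),
               module_dirs = as.character(st$opt$module_dirs),
               log = normalizePath(st$opt$log, mustWork = FALSE),
               run_dir = normalizePath(st$opt$run_dir, mustWork = FALSE),
               options = list(poll = st$opt$poll,
                              probe_timeout = st$opt$probe_timeout),
               jobs = jobs)
  ok <- tryCatch({
    jsonlite::write_json(snap, st$opt$snapshot, auto_unbox = TRUE, null = "null")
    TRUE
  }, error = function(e) {
    warning("cannot write detach snapshot ", st$opt$snapshot, ": ",
            conditionMessage(e), call. = FALSE)
    FALSE
  })
  if (ok) st$snapshot_written <- st$opt$snapshot
  ok
}

#' Read a detach snapshot
#' @param path Snapshot path (JSON).
#' @return The snapshot as a list.
#' @export
read_snapshot <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Reattach to a detached workflow execution
#'
#' Restores the workflow, modules and provenance log recorded in the
#' snapshot, adopts the outstanding spool jobs (their status is read from
#' the spool directory, so completions that happened while the engine was
#' down are logged normally), and resumes the scheduling loop. Works from
#' any working directory: all snapshot paths are absolute. A job that
#' vanished from its spool directory is treated as failed.
#'
#' @param snapshot Path to a detach snapshot.
#' @param options Option overrides, as in [run_workflow()].
#' @return A `shepherd_run` object.
#' @export
reattach <- function(snapshot, options = list()) {
  snap <- read_snapshot(snapshot)
  wf <- read_workflow(snap$workflow)
  modules <- load_modules(unlist(snap$module_dirs))
  opts <- utils::modifyList(
    list(log = snap$log, resume = snap$log, run_dir = snap$run_dir,
         poll = snap$options$poll %||% 1,
         probe_timeout = snap$options$probe_timeout %||% 30,
         module_dirs = unlist(snap$module_dirs),
         attach_jobs = snap$jobs),
    options)
  run_workflow(wf, modules, opts)
}

run_result <- function(st, exit_status, detached = FALSE, dry_run = FALSE) {
  counts <- table(factor(st$status,
                         levels = c("waiting", "running", "succeeded",
                                    "failed", "skipped")))
  structure(list(exit_status = exit_status,
                 counts = counts,
                 statuses = st$status,
                 trace = st$trace,
                 plan = st$plan %||% NULL,
                 log = st$opt$log,
                 snapshot = st$snapshot_written %||% NULL,
                 detached = detached, dry_run = dry_run),
            class = "shepherd_run")
}

#' @export
print.shepherd_run <- function(x, ...) {
  cat("<shepherd run> exit status ", x$exit_status,
      if (x$detached) " (detached)", if (x$dry_run) " (dry run)", "\n", sep = "")
  c <- x$counts[x$counts > 0]
  cat("  ", paste(sprintf("%s: %d", names(c), as.integer(c)), collapse = ", "), "\n")
  if (!is.null(x$plan)) {
    cat("  resume plan: run {", paste(x$plan$run, collapse = ", "),
        "}, reuse {", paste(x$plan$reuse, collapse = ", "), "}\n", sep = "")
  }
  cat("  log: ", x$log, "\n", sep = "")
  if (!is.null(x$snapshot)) cat("  snapshot: ", x$snapshot, "\n", sep = "")
  invisible(x)
}
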