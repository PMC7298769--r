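# Crash-safe provenance log (JSON Lines, `.resume` extension) and resume
# planning.
#
# Durability rule: a record line is written and flushed before the engine
# considers the subtask succeeded, so after a crash the log never claims a
# success that is not fully recorded. A truncated final line (the crash
# artifact) is dropped with a warning on load; its subtask simply replans
# for execution.

#' Construct a provenance log record
#'
#' @param task_id,subtask_index,module,module_version,executor Identity of
#'   the (sub)task and where it ran.
#' @param fingerprint Identity fingerprint ([subtask_fingerprint()]).
#' @param params,returns Named character vectors of resolved input
#'   parameters and return values.
#' @param status `"success"` or `"failure"`.
#' @param software_version Captured third-party software version, or
#'   `NULL` when the module declares no version flag.
#' @param dependencies Task ids this task depended on (used for
#'   removed-edge warnings on resume).
#' @param timestamp ISO-8601 UTC; defaults to now.
#' @return A `shepherd_log_record`.
#' @export
log_record <- function(task_id, subtask_index, module, module_version,
                       fingerprint, params, returns = character(),
                       status = c("success", "failure"),
                       executor = NA_character_, software_version = NULL,
                       dependencies = character(),
                       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS6Z",
                                          tz = "UTC")) {
  status <- match.arg(status)
  structure(list(timestamp = timestamp, task_id = task_id,
                 subtask_index = as.integer(subtask_index),
                 module = module, module_version = as.integer(module_version),
                 fingerprint = fingerprint,
                 params = as_named_chr(params), returns = as_named_chr(returns),
                 software_version = software_version,
                 status = status, executor = executor,
                 dependencies = as.character(dependencies)),
            class = "shepherd_log_record")
}

record_to_json <- function(rec) {
  x <- unclass(rec)
  x$params <- as.list(x$params)
  x$returns <- as.list(x$returns)
  if (is.null(x$software_version)) x$software_version <- NULL
  jsonlite::toJSON(x, auto_unbox = TRUE, null = "null")
}

json_to_record <- function(x) {
  log_record(task_id = x$task_id, subtask_index = x$subtask_index,
             module = x$module, module_version = x$module_version,
             fingerprint = x$fingerprint,
             params = unlist(x$params) %||% character(),
             returns = unlist(x$returns) %||% character(),
             status = x$status, executor = x$executor %||% NA_character_,
             software_version = x$software_version,
             dependencies = unlist(x$dependencies) %||% character(),
             timestamp = x$timestamp)
}

#' Append one record to a provenance log
#'
#' The record is serialized to a single JSON line, written, and flushed
#' before the function returns; writes from one engine are line-atomic.
#'
#' @param path Log file path (created on first append).
#' @param record A [log_record()].
#' @export
append_record <- function(path, record) {
  con <- file(path, open = "ab")
  on.exit(close(con))
  writeLines(record_to_json(record), con, useBytes = TRUE)
  flush(con)
  invisible(path)
}

#' Load a provenance log
#'
#' An absent file is an empty (fresh-run) log. All complete lines are
#' parsed; a final line that fails to parse — the artifact of a crash
#' mid-write — is dropped with a warning. A corrupt line anywhere else is
#' an error naming the line number.
#'
#' @param path Log file path.
#' @return List of [log_record()]s.
#' @export
load_log <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    parsed <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                       error = function(e) NULL)
    if (is.null(parsed)) {
      if (i == length(lines)) {
        warning("dropping truncated final line ", i, " of log ", path,
                call. = FALSE)
        out[[i]] <- NULL
        return(out[!vapply(out, is.null, TRUE)])
      }
      stop("corrupt record at line ", i, " of log ", path, call. = FALSE)
    }
    out[[i]] <- json_to_record(parsed)
  }
  out
}

# latest success record per fingerprint (later records win, supporting
# forced reruns); returns an environment keyed by fingerprint
success_by_fingerprint <- function(records) {
  env <- new.env(parent = emptyenv())
  for (r in records) {
    if (identical(r$status, "success") && !is.na(r$fingerprint)) {
      assign(r$fingerprint, r, envir = env)
    }
  }
  env
}

# merged return values per task id, in subtask-index order (later indices
# overwrite), from the latest success record of each (task, index)
returns_by_task <- function(records) {
  latest <- list()
  for (r in records) {
    if (identical(r$status, "success")) {
      latest[[paste0(r$task_id, "\r", r$subtask_index)]] <- r
    }
  }
  out <- list()
  ord <- order(vapply(latest, `[[`, 0L, "subtask_index"))
  for (r in latest[ord]) {
    out[[r$task_id]] <- c(out[[r$task_id]] %||% character(), r$returns)
    dup <- duplicated(names(out[[r$task_id]]), fromLast = TRUE)
    out[[r$task_id]] <- out[[r$task_id]][!dup]
  }
  out
}

#' Plan a resumed execution
#'
#' A subtask must run iff its identity fingerprint has no success record
#' in the prior log; on top of that base set, every subtask of any task
#' that transitively depends on a task with at least one to-run subtask is
#' rerun as well (whole-task granularity for dependents). Late-bound
#' subtasks are fingerprinted against the logged return values of their
#' dependencies; if those are unavailable or the dependency itself reruns,
#' the subtask must run. Everything else is reused: its logged return
#' values are made available to late binding without execution.
#'
#' @param subtasks Expansion of the current workflow ([expand_workflow()]).
#' @param wf The current [workflow()].
#' @param records Prior log ([load_log()]).
#' @return `list(run = , reuse = )`: character vectors of subtask keys
#'   (`task[index]`).
#' @export
resume_plan <- function(subtasks, wf, records) {
  succ <- success_by_fingerprint(records)
  logged_returns <- returns_by_task(records)
  run_task <- character()     # tasks with >= 1 subtask in the run set
  run <- character()

  for (id in topo_order(wf)) {
    for (s in subtasks[vapply(subtasks, `[[`, "", "task_id") == id]) {
      key <- subtask_key(s)
      must_run <- FALSE
      if (isTRUE(s$late_bound)) {
        deps_rerun <- any(wf$tasks[[id]]$dependencies %in% run_task)
        s2 <- if (!deps_rerun) {
          tryCatch(resolve_late_bindings(s, logged_returns), error = function(e) NULL)
        } else NULL
        if (is.null(s2)) must_run <- TRUE else s <- s2
      }
      if (!must_run) must_run <- !exists(s$fingerprint, envir = succ)
      if (must_run) {
        run <- c(run, key)
        run_task <- union(run_task, id)
      }
    }
  }
  # closure: whole-task rerun of every transitive dependent of a rerun task
  affected <- dependents_closure(wf, run_task)
  for (s in subtasks) {
    if (s$task_id %in% affected) run <- union(run, subtask_key(s))
  }
  list(run = unique(run), reuse = setdiff(names(subtasks), unique(run)))
}

#' Warn about tasks or dependency edges removed since a prior run
#'
#' Removing (sub)tasks or dependencies after a workflow has run may leave
#' results computed from stale inputs; the warnings flag this but never
#' block execution.
#'
#' @param records Prior log.
#' @param wf Current workflow.
#' @return Character vector of warning messages (also raised as warnings).
#' @export
warn_removed <- function(records, wf) {
  msgs <- character()
  latest_deps <- list()
  for (r in records) latest_deps[[r$task_id]] <- r$dependencies
  for (id in names(latest_deps)) {
    if (!id %in% names(wf$tasks)) {
      msgs <- c(msgs, paste0("task ", id,
                             " was executed previously but is no longer in the workflow"))
    } else {
      gone <- setdiff(latest_deps[[id]], wf$tasks[[id]]$dependencies)
      for (d in gone) {
        msgs <- c(msgs, paste0("dependency ", id, " -> ", d,
                               " was removed since the previous run"))
      }
    }
  }
  for (m in msgs) warning(m, call. = FALSE)
  invisible(msgs)
}
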