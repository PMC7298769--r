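# Task expansion: multiply tasks over process blocks into resolved
# subtasks, substitute placeholders, and compute the identity fingerprint
# used by resume planning.
#
# A subtask's identity is the SHA-256 digest of a canonical serialization
# of (task id, module name, module version, sorted resolved parameters).
# Including task id, module and version alongside the parameter
# combination prevents stale reuse when two tasks share a module and
# parameter values: strictly more reruns, never a wrong reuse.

#' Compute a subtask identity fingerprint
#'
#' The canonical serialization is
#' `task_id US module US version US name=value US ...` with parameters
#' sorted by name and `US` the ASCII unit separator (0x1F); the digest is
#' SHA-256 over the UTF-8 bytes of that string. The digest is stable
#' across runs and platforms and independent of the order in which
#' parameters were supplied.
#'
#' @param task_id,module Identifiers.
#' @param version Module version (positive integer).
#' @param params Named character vector of fully resolved parameters.
#' @return Lowercase hex digest (64 characters).
#' @export
subtask_fingerprint <- function(task_id, module, version, params) {
  if (length(params)) params <- params[order(names(params), method = "radix")]
  canon <- paste(c(task_id, module, as.character(as.integer(version)),
                   if (length(params)) paste0(names(params), "=", unname(params))),
                 collapse = "\x1f")
  digest::digest(enc2utf8(canon), algo = "sha256", serialize = FALSE)
}

new_subtask <- function(task, index, params, late_bound) {
  fp <- if (late_bound) NA_character_ else
    subtask_fingerprint(task$id, task$module, task$module_version, params)
  structure(list(task_id = task$id, subtask_index = index,
                 module = task$module, module_version = task$module_version,
                 params = params, executor = task$executor,
                 fingerprint = fp, late_bound = late_bound),
            class = "shepherd_subtask")
}

subtask_key <- function(s) paste0(s$task_id, "[", s$subtask_index, "]")

#' @export
print.shepherd_subtask <- function(x, ...) {
  cat("<subtask ", subtask_key(x), "> module ", x$module, " v", x$module_version,
      if (x$late_bound) " (late-bound)" else paste0(" ", substr(x$fingerprint, 1, 12)),
      "\n", sep = "")
  for (nm in names(x$params)) cat("  ", nm, " = ", x$params[[nm]], "\n", sep = "")
  invisible(x)
}

#' Expand one task into its resolved subtasks
#'
#' Without a process block the task yields exactly one subtask (index 0).
#' A `list` block yields one subtask per row with `[COLUMN]` placeholders
#' substituted; a `folder` block yields one subtask per file matching the
#' glob, in lexicographic order, with `[FILE]` bound to the absolute path
#' (zero matches is a warning, not an error). Constants are substituted
#' and defaults filled for unset optional parameters. Subtasks whose
#' values still reference upstream return values (`$[task.NAME]`) are
#' flagged `late_bound` and carry no fingerprint until
#' [resolve_late_bindings()] runs.
#'
#' @param task A [task_def()] (already validated).
#' @param constants Named character vector.
#' @param module The task's [module_descriptor()].
#' @return Ordered list of subtasks.
#' @export
expand_task <- function(task, constants, module) {
  iface <- resolve_interface(module, task$module_version)
  params <- task$params
  for (p in iface$parameters) {
    if (!p$name %in% names(params) && !is.null(p$default)) {
      params[[p$name]] <- p$default
    }
  }
  # order parameters by interface declaration (stable fingerprint input order
  # is irrelevant, but command building and logs read better)
  params <- params[intersect(names(iface$parameters), names(params))]
  params[] <- substitute_constants(unname(params), constants,
                                   context = paste0("task ", task$id))

  rows <- if (is.null(task$block)) {
    list(stats::setNames(character(), character()))
  } else if (task$block$kind == "list") {
    lapply(task$block$rows, function(r) stats::setNames(r, task$block$columns))
  } else {
    files <- Sys.glob(file.path(task$block$base, task$block$pattern))
    files <- files[order(basename(files), method = "radix")]
    if (!length(files)) {
      warning("folder process block of task ", task$id, " (", task$block$pattern,
              " under ", task$block$base, ") matched no files", call. = FALSE)
    }
    lapply(files, function(f) c(FILE = normalizePath(f)))
  }

  lapply(seq_along(rows), function(i) {
    vals <- params
    for (col in names(rows[[i]])) {
      vals[] <- gsub(paste0("[", col, "]"), rows[[i]][[col]], vals, fixed = TRUE)
    }
    left <- setdiff(unlist(lapply(vals, bracket_placeholders)), character())
    if (length(left)) {
      stop("task ", task$id, ": unresolved process-block placeholder [",
           left[1], "]", call. = FALSE)
    }
    late <- any(grepl(RETURN_RE, vals, perl = TRUE))
    new_subtask(task, i - 1L, vals, late)
  })
}

#' Expand a whole workflow
#'
#' @param wf A [workflow()].
#' @param modules Named list of module descriptors.
#' @return Named list of subtasks keyed by `task[index]`, in task order.
#' @export
expand_workflow <- function(wf, modules) {
  out <- list()
  for (t in wf$tasks) {
    subs <- expand_task(t, wf$constants, modules[[t$module]])
    for (s in subs) out[[subtask_key(s)]] <- s
  }
  out
}

#' Resolve upstream return-value references of a late-bound subtask
#'
#' Every `$[taskId.NAME]` placeholder is replaced by the named return
#' value logged for the dependency task; the subtask's fingerprint is then
#' computed over the fully resolved parameters, so resume identity
#' reflects the actual inputs the command saw. Subtasks without
#' placeholders are returned unchanged.
#'
#' @param subtask A subtask from [expand_task()].
#' @param upstream_returns Named list: task id -> named character vector of
#'   return values (a task that expanded into several subtasks has its
#'   return maps merged in subtask-index order, later subtasks winning).
#' @return The resolved subtask, `late_bound` cleared.
#' @export
resolve_late_bindings <- function(subtask, upstream_returns) {
  if (!isTRUE(subtask$late_bound)) return(subtask)
  vals <- subtask$params
  for (i in seq_along(vals)) {
    refs <- parse_return_refs(vals[[i]])
    for (ref in refs) {
      rets <- upstream_returns[[ref$task]]
      if (is.null(rets) || !ref$name %in% names(rets)) {
        stop("subtask ", subtask_key(subtask), ": no return value ",
             sQuote(ref$name), " available from task ", ref$task, call. = FALSE)
      }
      vals[[i]] <- gsub(paste0("$[", ref$task, ".", ref$name, "]"),
                        rets[[ref$name]], vals[[i]], fixed = TRUE)
    }
  }
  subtask$params <- vals
  subtask$late_bound <- FALSE
  subtask$fingerprint <- subtask_fingerprint(subtask$task_id, subtask$module,
                                             subtask$module_version, vals)
  subtask
}
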