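# Domain types for workflows and module descriptors, plus the three core
# model operations: interface resolution by module version, constant
# substitution, and whole-workflow validation.

PARAM_TYPES <- c("string", "integer", "double", "boolean", "file", "folder")

#' Version range of a module-interface element
#'
#' Parameters, return values and command templates of a module may be
#' restricted to a contiguous range of module versions. An absent bound
#' means the element is valid in all versions on that side.
#'
#' @param min_version,max_version Positive integers or `NA` (unbounded).
#' @return A `shepherd_version_range` object.
#' @export
version_range <- function(min_version = NA_integer_, max_version = NA_integer_) {
  min_version <- as_opt_version(min_version, "min_version")
  max_version <- as_opt_version(max_version, "max_version")
  if (!is.na(min_version) && !is.na(max_version) && min_version > max_version) {
    stop("invalid version range: min_version (", min_version,
         ") > max_version (", max_version, ")", call. = FALSE)
  }
  structure(list(min_version = min_version, max_version = max_version),
            class = "shepherd_version_range")
}

as_opt_version <- function(x, what) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NA_integer_)
  v <- suppressWarnings(as.integer(x))
  if (is.na(v) || v < 1) stop(what, " must be a positive integer, got ", x, call. = FALSE)
  v
}

range_contains <- function(range, version) {
  (is.na(range$min_version) || version >= range$min_version) &&
    (is.na(range$max_version) || version <= range$max_version)
}

#' Module parameter definition
#'
#' @param name Identifier, unique within an effective interface.
#' @param value_type One of `string`, `integer`, `double`, `boolean`,
#'   `file`, `folder`.
#' @param required Is the parameter mandatory?
#' @param default Optional default literal (character). Must parse as
#'   `value_type`.
#' @param range A [version_range()].
#' @param check_existence For `file`/`folder` parameters: check that the
#'   path exists before the subtask is dispatched.
#' @export
parameter_def <- function(name, value_type = "string", required = FALSE,
                          default = NULL, range = version_range(),
                          check_existence = FALSE) {
  check_identifier(name, "parameter name")
  value_type <- match.arg(value_type, PARAM_TYPES)
  if (check_existence && !value_type %in% c("file", "folder")) {
    stop("check_existence is only meaningful for file/folder parameters (", name, ")",
         call. = FALSE)
  }
  if (!is.null(default) && !literal_parses_as(default, value_type)) {
    stop("default ", dQuote(default), " of parameter ", name,
         " does not parse as ", value_type, call. = FALSE)
  }
  structure(list(name = name, value_type = value_type,
                 required = isTRUE(required),
                 default = if (is.null(default)) NULL else as.character(default),
                 range = range, check_existence = isTRUE(check_existence)),
            class = "shepherd_parameter")
}

#' Module return-value definition
#' @inheritParams parameter_def
#' @export
return_value_def <- function(name, value_type = "string", range = version_range()) {
  check_identifier(name, "return value name")
  value_type <- match.arg(value_type, PARAM_TYPES)
  structure(list(name = name, value_type = value_type, range = range),
            class = "shepherd_return")
}

literal_parses_as <- function(x, type) {
  x <- as.character(x)
  switch(type,
    string = , file = , folder = TRUE,
    integer = grepl("^[+-]?[0-9]+$", x),
    double = !is.na(suppressWarnings(as.numeric(x))),
    boolean = x %in% c("true", "false", "TRUE", "FALSE"))
}

check_identifier <- function(x, what) {
  if (!is.character(x) || length(x) != 1 || !grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", x)) {
    stop(what, " must be a single identifier, got ",
         paste(deparse(x), collapse = ""), call. = FALSE)
  }
  invisible(x)
}

#' Module descriptor
#'
#' A reusable tool wrapper: the command templates (one per version range),
#' parameter and return-value interface with version ranges, the optional
#' flag used to probe the wrapped software's version, and the directory
#' the module lives in.
#'
#' @param name Module name.
#' @param max_version Highest supported module version (>= 1). Raised
#'   automatically if any element declares a higher `min_version`.
#' @param commands List of `list(range = version_range(), tokens = character())`.
#'   Tokens may contain `{param}` slots and the reserved `{MODULE_DIR}`.
#' @param parameters,returns Lists of [parameter_def()] / [return_value_def()].
#' @param version_flag Literal flag (e.g. `"--version"`) used for software
#'   version capture, or `NULL` to skip capture.
#' @param module_dir Directory containing the module.
#' @export
module_descriptor <- function(name, max_version = 1L, commands,
                              parameters = list(), returns = list(),
                              version_flag = NULL, module_dir = ".") {
  check_identifier(name, "module name")
  max_version <- as_opt_version(max_version, "max_version")
  if (is.na(max_version)) max_version <- 1L
  bounds <- unlist(lapply(c(commands, parameters, returns), function(el) {
    r <- if (!is.null(el$range)) el$range else el
    c(r$min_version, r$max_version)
  }))
  bounds <- bounds[!is.na(bounds)]
  if (length(bounds)) max_version <- max(max_version, bounds)
  if (length(commands) == 0) stop("module ", name, " declares no command template", call. = FALSE)
  mod <- structure(
    list(name = name, max_version = max_version, commands = commands,
         parameters = parameters, returns = returns,
         version_flag = version_flag,
         module_dir = normalizePath(module_dir, mustWork = FALSE)),
    class = "shepherd_module")
  for (v in seq_len(max_version)) command_for_version(mod, v)  # must resolve
  for (set in list(parameters, returns)) {
    nm <- vapply(set, `[[`, "", "name")
    if (anyDuplicated(nm)) {
      stop("module ", name, ": duplicate element name ", nm[duplicated(nm)][1], call. = FALSE)
    }
  }
  mod
}

command_for_version <- function(module, version) {
  for (cmd in module$commands) {
    if (range_contains(cmd$range, version)) return(cmd$tokens)
  }
  stop("module ", module$name, " has no command template for version ", version,
       call. = FALSE)
}

#' Resolve the effective interface of a module version
#'
#' An element (parameter or return value) is part of the effective
#' interface of version `v` iff its version range contains `v`; an absent
#' bound is unbounded on that side, so an element without any range is
#' valid for all module versions.
#'
#' @param module A [module_descriptor()].
#' @param version Positive integer, `1 <= version <= module$max_version`.
#' @return `list(parameters = , returns = )`, both named lists.
#' @export
resolve_interface <- function(module, version) {
  version <- as_opt_version(version, "version")
  if (is.na(version) || version > module$max_version) {
    stop("module ", module$name, ": requested version ", version,
         " is outside the supported range 1..", module$max_version, call. = FALSE)
  }
  keep <- function(set) {
    set <- Filter(function(el) range_contains(el$range, version), set)
    stats::setNames(set, vapply(set, `[[`, "", "name"))
  }
  list(parameters = keep(module$parameters), returns = keep(module$returns))
}

#' @export
print.shepherd_module <- function(x, ...) {
  cat("<module ", x$name, "> versions 1..", x$max_version,
      ", ", length(x$parameters), " parameter(s), ",
      length(x$returns), " return value(s)",
      if (!is.null(x$version_flag)) paste0(", version flag ", sQuote(x$version_flag)),
      "\n", sep = "")
  invisible(x)
}

## ---- workflow-side types ---------------------------------------------------

WRAPPER_KINDS <- c("identity", "prefix", "package_manager", "container")

#' Execution-wrapper definition
#'
#' Wrappers rewrite a subtask's command to provision its software
#' environment. `package_manager` wrappers are applied innermost,
#' `container` wrappers outermost, so a package manager can be used inside
#' a container. `prefix` is a generic token-prefix wrapper (used by the
#' test-suite in place of real conda/docker), `identity` a no-op.
#'
#' @param name Wrapper name.
#' @param kind One of `identity`, `prefix`, `package_manager`, `container`.
#' @param ... Kind-specific settings: `prefix` (token string) for prefix
#'   wrappers; `command` for package managers (default `"conda"`);
#'   `runtime` (default `"docker"`) and `auto_mount` (default `TRUE`) for
#'   containers.
#' @export
wrapper_def <- function(name, kind = WRAPPER_KINDS, ...) {
  check_identifier(name, "wrapper name")
  kind <- match.arg(kind)
  settings <- list(...)
  if (kind == "prefix" && is.null(settings$prefix)) {
    stop("prefix wrapper ", name, " needs a 'prefix' setting", call. = FALSE)
  }
  if (kind == "package_manager" && is.null(settings$command)) settings$command <- "conda"
  if (kind == "container") {
    if (is.null(settings$runtime)) settings$runtime <- "docker"
    if (is.null(settings$auto_mount)) settings$auto_mount <- TRUE
  }
  structure(list(name = name, kind = kind, settings = settings),
            class = "shepherd_wrapper")
}

#' Executor definition
#'
#' @param name Executor name.
#' @param kind `"local"` (subprocesses on the scheduler host) or `"spool"`
#'   (a spool-directory executor emulating a cluster workload manager:
#'   jobs are detached processes that outlive the scheduler).
#' @param max_slots Maximum number of concurrently running subtasks.
#' @param package_manager,container Optional wrapper names (at most one of
#'   each role).
#' @param spool_dir Spool directory (required for `spool` executors).
#' @export
executor_def <- function(name, kind = c("local", "spool"), max_slots = 1L,
                         package_manager = NULL, container = NULL,
                         spool_dir = NULL) {
  check_identifier(name, "executor name")
  kind <- match.arg(kind)
  max_slots <- as_opt_version(max_slots, "max_slots")
  if (kind == "spool" && is.null(spool_dir)) {
    stop("spool executor ", name, " needs a spool_dir", call. = FALSE)
  }
  structure(list(name = name, kind = kind, max_slots = max_slots,
                 package_manager = package_manager, container = container,
                 spool_dir = spool_dir),
            class = "shepherd_executor")
}

#' Process block: multiply a task over samples or parameter combinations
#'
#' A `list` block carries named columns and rows of values; each row
#' yields one subtask with `[COLUMN]` placeholders substituted. A `folder`
#' block yields one subtask per file matching `pattern` under `base`
#' (lexicographic order), with `[FILE]` bound to the absolute path.
#'
#' @param kind `"list"` or `"folder"`.
#' @param columns Character vector of column names (`list` kind).
#' @param rows List of character vectors, each of arity `length(columns)`.
#' @param base,pattern Folder and glob pattern (`folder` kind).
#' @export
process_block <- function(kind = c("list", "folder"), columns = NULL,
                          rows = NULL, base = NULL, pattern = NULL) {
  kind <- match.arg(kind)
  if (kind == "list") {
    if (is.null(columns) || anyDuplicated(columns)) {
      stop("list process block needs unique column names", call. = FALSE)
    }
    rows <- lapply(rows, as.character)
    bad <- which(vapply(rows, length, 0L) != length(columns))
    if (length(bad)) {
      stop("process block row ", bad[1], " has arity ", length(rows[[bad[1]]]),
           ", expected ", length(columns), call. = FALSE)
    }
    structure(list(kind = kind, columns = as.character(columns), rows = rows),
              class = "shepherd_process_block")
  } else {
    if (is.null(base) || is.null(pattern)) {
      stop("folder process block needs base and pattern", call. = FALSE)
    }
    structure(list(kind = kind, base = base, pattern = pattern,
                   columns = "FILE"),
              class = "shepherd_process_block")
  }
}

#' Task definition
#'
#' @param id Task identifier (unique in the workflow).
#' @param module Module name; `module_version` defaults to 1, the rule that
#'   keeps workflows written before a new module version was introduced
#'   working unchanged.
#' @param executor Executor name.
#' @param params Named character vector of raw parameter assignments; values
#'   may contain `${CONSTANT}`, `[COLUMN]` and `$[taskId.RETURN]`
#'   placeholders.
#' @param dependencies Character vector of task ids this task depends on.
#' @param block Optional [process_block()].
#' @param name Free-text display name.
#' @export
task_def <- function(id, module, executor, params = character(),
                     dependencies = character(), module_version = 1L,
                     block = NULL, name = id) {
  check_identifier(id, "task id")
  structure(list(id = id, name = name, module = module,
                 module_version = as_opt_version(module_version, "module_version"),
                 executor = executor,
                 params = as_named_chr(params),
                 dependencies = as.character(dependencies),
                 block = block),
            class = "shepherd_task")
}

as_named_chr <- function(x) {
  x <- unlist(x)
  if (length(x) == 0) return(stats::setNames(character(), character()))
  stats::setNames(as.character(x), names(x))
}

#' Workflow
#'
#' @param tasks List of [task_def()] (order preserved).
#' @param constants Named character vector, referenced as `${NAME}`.
#' @param wrappers,executors Lists of [wrapper_def()] / [executor_def()].
#' @export
workflow <- function(tasks, constants = character(), wrappers = list(),
                     executors = list()) {
  name_by <- function(set) stats::setNames(set, vapply(set, `[[`, "", "name"))
  wrappers <- name_by(wrappers)
  executors <- name_by(executors)
  constants <- as_named_chr(constants)
  for (what in list(c("constant", "constants"), c("wrapper", "wrappers"),
                    c("executor", "executors"))) {
    nm <- names(get(what[2]))
    if (anyDuplicated(nm)) stop("duplicate ", what[1], " name: ", nm[duplicated(nm)][1],
                                call. = FALSE)
  }
  ids <- vapply(tasks, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate task id: ", ids[duplicated(ids)][1], call. = FALSE)
  structure(list(constants = constants, wrappers = wrappers,
                 executors = executors, tasks = stats::setNames(tasks, ids)),
            class = "shepherd_workflow")
}

#' @export
print.shepherd_workflow <- function(x, ...) {
  cat("<workflow> ", length(x$tasks), " task(s), ", length(x$constants),
      " constant(s), ", length(x$executors), " executor(s)\n", sep = "")
  for (t in x$tasks) {
    cat("  ", t$id, " [", t$module, " v", t$module_version, " @", t$executor, "]",
        if (length(t$dependencies)) paste0(" <- ", paste(t$dependencies, collapse = ", ")),
        if (!is.null(t$block)) sprintf(" (x%s)", if (t$block$kind == "list")
          length(t$block$rows) else paste0("glob:", t$block$pattern)),
        "\n", sep = "")
  }
  invisible(x)
}

## ---- constant substitution -------------------------------------------------

CONST_RE <- "\\$\\{([A-Za-z_][A-Za-z0-9_]*)\\}"

#' Substitute `${NAME}` constant references
#'
#' Single pass: replacement values are not re-scanned for further
#' placeholders, so substitution cannot recurse or expand unboundedly and
#' is idempotent on its own output whenever constant values contain no
#' `${` sequences.
#'
#' @param text Character vector of raw strings.
#' @param constants Named character vector.
#' @param context Optional label (e.g. a task id) used in error messages.
#' @return `text` with every `${NAME}` replaced by the constant's value.
#' @export
substitute_constants <- function(text, constants, context = NULL) {
  m <- gregexpr(CONST_RE, text, perl = TRUE)
  hits <- regmatches(text, m)
  missing <- setdiff(unique(sub(CONST_RE, "\\1", unlist(hits), perl = TRUE)),
                     names(constants))
  if (length(missing)) {
    stop("undefined constant(s) ", paste(missing, collapse = ", "),
         if (!is.null(context)) paste0(" referenced in ", context), call. = FALSE)
  }
  regmatches(text, m) <- lapply(hits, function(h) {
    unname(constants[sub(CONST_RE, "\\1", h, perl = TRUE)])
  })
  text
}

## ---- workflow validation ---------------------------------------------------

finding <- function(level, message, task = NA_character_) {
  data.frame(level = level, task = task, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a workflow against a set of module descriptors
#'
#' Returns findings rather than throwing: an empty error set means the
#' workflow is executable — every module/executor/wrapper reference
#' resolves, requested module versions are supported, all required
#' parameters of each task's effective interface are assigned or have a
#' default, assigned parameters exist in the effective interface, constant
#' and return-value references resolve, and the dependency graph is
#' acyclic.
#'
#' @param wf A [workflow()].
#' @param modules Named list of [module_descriptor()]s.
#' @return A data.frame of findings with columns `level` (`"error"` /
#'   `"warning"`), `task`, `message`.
#' @export
validate_workflow <- function(wf, modules) {
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- finding(...)
  ids <- names(wf$tasks)

  for (t in wf$tasks) {
    mod <- modules[[t$module]]
    if (is.null(mod)) {
      add("error", paste0("unknown module ", sQuote(t$module)), t$id)
      next
    }
    if (t$module_version > mod$max_version) {
      add("error", sprintf("module %s has no version %d (max %d)",
                           t$module, t$module_version, mod$max_version), t$id)
      next
    }
    iface <- resolve_interface(mod, t$module_version)
    unknown <- setdiff(names(t$params), names(iface$parameters))
    for (p in unknown) {
      add("error", sprintf(
        "parameter %s is not part of the version-%d interface of module %s",
        sQuote(p), t$module_version, t$module), t$id)
    }
    for (p in iface$parameters) {
      if (p$required && is.null(p$default) && !p$name %in% names(t$params)) {
        add("error", sprintf("required parameter %s of module %s is not assigned",
                             sQuote(p$name), t$module), t$id)
      }
    }
    # placeholder references
    cols <- if (!is.null(t$block)) t$block$columns else character()
    for (nm in names(t$params)) {
      v <- t$params[[nm]]
      refs <- unique(sub(CONST_RE, "\\1",
                         unlist(regmatches(v, gregexpr(CONST_RE, v, perl = TRUE))),
                         perl = TRUE))
      miss <- setdiff(refs, names(wf$constants))
      for (r in miss) add("error", paste0("undefined constant ${", r, "}"), t$id)
      for (ref in parse_return_refs(v)) {
        if (!ref$task %in% t$dependencies) {
          add("error", sprintf(
            "return-value reference $[%s.%s] does not name a dependency of this task",
            ref$task, ref$name), t$id)
        } else if (ref$task %in% ids) {
          dep <- wf$tasks[[ref$task]]
          depmod <- modules[[dep$module]]
          if (!is.null(depmod) && dep$module_version <= depmod$max_version) {
            depret <- resolve_interface(depmod, dep$module_version)$returns
            if (!ref$name %in% names(depret)) {
              add("error", sprintf(
                "task %s (module %s v%d) declares no return value %s",
                ref$task, dep$module, dep$module_version, sQuote(ref$name)), t$id)
            }
          }
        }
      }
      bare <- setdiff(bracket_placeholders(v), cols)
      for (b in bare) add("error", paste0("unresolved process-block placeholder [", b, "]"), t$id)
    }
    if (!t$executor %in% names(wf$executors)) {
      add("error", paste0("unknown executor ", sQuote(t$executor)), t$id)
    } else {
      ex <- wf$executors[[t$executor]]
      for (w in c(ex$package_manager, ex$container)) {
        if (!is.null(w) && !w %in% names(wf$wrappers)) {
          add("error", paste0("executor ", ex$name, " references undefined wrapper ",
                              sQuote(w)), t$id)
        }
      }
    }
    for (d in t$dependencies) {
      if (!d %in% ids) add("error", paste0("dependency on unknown task ", sQuote(d)), t$id)
    }
  }

  cyc <- find_cycle(lapply(wf$tasks, `[[`, "dependencies"))
  if (!is.null(cyc)) {
    add("error", paste0("dependency cycle: ", paste(cyc, collapse = " -> ")))
  }
  if (length(out)) do.call(rbind, out) else finding(character(), character(), character())
}

# $[taskId.NAME] references to upstream return values
RETURN_RE <- "\\$\\[([A-Za-z_][A-Za-z0-9_.-]*)\\.([A-Za-z_][A-Za-z0-9_.-]*)\\]"

parse_return_refs <- function(text) {
  hits <- unlist(regmatches(text, gregexpr(RETURN_RE, text, perl = TRUE)))
  lapply(unique(hits), function(h) {
    list(task = sub(RETURN_RE, "\\1", h, perl = TRUE),
         name = sub(RETURN_RE, "\\2", h, perl = TRUE))
  })
}

# bare [NAME] placeholders (process-block columns); excludes $[t.r] references
bracket_placeholders <- function(text) {
  text <- gsub(RETURN_RE, "", text, perl = TRUE)
  re <- "\\[([A-Za-z_][A-Za-z0-9_]*)\\]"
  unique(sub(re, "\\1",
             unlist(regmatches(text, gregexpr(re, text, perl = TRUE))), perl = TRUE))
}

# Kahn topological check; returns NULL or one cycle as a vector of ids
find_cycle <- function(deps) {
  ids <- names(deps)
  indeg <- vapply(deps, function(d) length(intersect(d, ids)), 0L)
  queue <- ids[indeg == 0]
  seen <- character()
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- c(seen, v)
    for (w in ids) {
      if (v %in% deps[[w]]) {
        indeg[[w]] <- indeg[[w]] - 1L
        if (indeg[[w]] == 0L) queue <- c(queue, w)
      }
    }
  }
  rest <- setdiff(ids, seen)
  if (!length(rest)) return(NULL)
  # walk the remaining subgraph to print one concrete cycle
  v <- rest[1]; path <- character()
  while (!v %in% path) {
    path <- c(path, v)
    v <- intersect(deps[[v]], rest)[1]
  }
  c(path[which(path == v):length(path)], v)
}

topo_order <- function(wf) {
  deps <- lapply(wf$tasks, `[[`, "dependencies")
  ids <- names(deps)
  order <- character()
  placed <- character()
  while (length(placed) < length(ids)) {
    remaining <- setdiff(ids, placed)
    ready <- remaining[vapply(deps[remaining],
                              function(d) all(intersect(d, ids) %in% placed), TRUE)]
    if (!length(ready)) stop("dependency cycle in workflow", call. = FALSE)
    order <- c(order, ready)
    placed <- c(placed, ready)
  }
  order
}

# reverse-transitive closure: all tasks that (transitively) depend on `roots`
dependents_closure <- function(wf, roots) {
  deps <- lapply(wf$tasks, `[[`, "dependencies")
  out <- character()
  repeat {
    more <- names(deps)[vapply(deps, function(d) any(d %in% c(roots, out)), TRUE)]
    more <- setdiff(more, out)
    if (!length(more)) break
    out <- c(out, more)
  }
  setdiff(out, roots)
}
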