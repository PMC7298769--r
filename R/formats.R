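# Readers and writers for the three XML dialects (workflow, module
# descriptor, module documentation), the TAB-separated return-value files
# written by module runs, and the documentation-template extractor.
#
# Every dialect ships with an XSD under inst/schema/ and is validated on
# read; structural findings abort the read and always name the file.

schema_path <- function(which) {
  system.file("schema", paste0(which, ".xsd"), package = "shepherd", mustWork = TRUE)
}

read_validated_xml <- function(path, which, root) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ok <- xml2::xml_validate(doc, xml2::read_xml(schema_path(which)))
  if (!isTRUE(ok)) {
    stop("schema violations in ", path, ":\n  ",
         paste(attr(ok, "errors"), collapse = "\n  "), call. = FALSE)
  }
  if (xml2::xml_name(doc) != root) {
    stop(path, ": expected root element <", root, ">", call. = FALSE)
  }
  doc
}

xattr <- function(node, name, default = NULL) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

xattr_bool <- function(node, name, default = FALSE) {
  v <- xattr(node, name)
  if (is.null(v)) default else v %in% c("true", "1")
}

node_range <- function(node) {
  version_range(xattr(node, "minVersion", NA), xattr(node, "maxVersion", NA))
}

## ---- workflow --------------------------------------------------------------

#' Read a workflow XML file
#'
#' The file is validated against the shipped workflow schema; parameter
#' values keep their raw placeholders (`${CONSTANT}`, `[COLUMN]`,
#' `$[task.RETURN]`) — resolution happens at expansion time.
#'
#' @param path Path to the workflow XML.
#' @return A [workflow()] with the source path in `attr(, "path")`.
#' @export
read_workflow <- function(path) {
  doc <- read_validated_xml(path, "workflow", "workflow")
  consts <- vapply(xml2::xml_find_all(doc, "./settings/constants/constant"),
                   xml2::xml_text, "")
  names(consts) <- vapply(xml2::xml_find_all(doc, "./settings/constants/constant"),
                          function(n) xml2::xml_attr(n, "name"), "")
  wrappers <- lapply(xml2::xml_find_all(doc, "./settings/wrappers/wrapper"), function(n) {
    kind <- xml2::xml_attr(n, "kind")
    args <- list(name = xml2::xml_attr(n, "name"), kind = kind)
    if (kind == "prefix") args$prefix <- xattr(n, "prefix")
    if (kind == "package_manager") args$command <- xattr(n, "command", "conda")
    if (kind == "container") {
      args$runtime <- xattr(n, "runtime", "docker")
      args$auto_mount <- xattr_bool(n, "autoMount", TRUE)
    }
    do.call(wrapper_def, args)
  })
  executors <- lapply(xml2::xml_find_all(doc, "./settings/executors/executor"), function(n) {
    executor_def(xml2::xml_attr(n, "name"), xml2::xml_attr(n, "kind"),
                 max_slots = as.integer(xattr(n, "maxSlots", "1")),
                 package_manager = xattr(n, "packageManager"),
                 container = xattr(n, "container"),
                 spool_dir = xattr(n, "spoolDir"))
  })
  tasks <- lapply(xml2::xml_find_all(doc, "./tasks/task"), function(n) {
    pnodes <- xml2::xml_find_all(n, "./param")
    params <- stats::setNames(vapply(pnodes, xml2::xml_text, ""),
                              vapply(pnodes, function(p) xml2::xml_attr(p, "name"), ""))
    if (anyDuplicated(names(params))) {
      stop(path, ": task ", xml2::xml_attr(n, "id"), " assigns parameter ",
           names(params)[duplicated(names(params))][1], " twice", call. = FALSE)
    }
    bnode <- xml2::xml_find_first(n, "./processBlock")
    block <- NULL
    if (!inherits(bnode, "xml_missing")) {
      kind <- xml2::xml_attr(bnode, "kind")
      block <- if (kind == "list") {
        process_block("list",
                      columns = vapply(xml2::xml_find_all(bnode, "./column"), xml2::xml_text, ""),
                      rows = lapply(xml2::xml_find_all(bnode, "./row"), function(r) {
                        vapply(xml2::xml_find_all(r, "./cell"), xml2::xml_text, "")
                      }))
      } else {
        if (is.null(xattr(bnode, "base")) || is.null(xattr(bnode, "pattern"))) {
          stop(path, ": folder process block of task ", xml2::xml_attr(n, "id"),
               " needs base and pattern attributes", call. = FALSE)
        }
        process_block("folder", base = xml2::xml_attr(bnode, "base"),
                      pattern = xml2::xml_attr(bnode, "pattern"))
      }
    }
    task_def(id = xml2::xml_attr(n, "id"),
             name = xattr(n, "name", xml2::xml_attr(n, "id")),
             module = xml2::xml_attr(n, "module"),
             module_version = as.integer(xattr(n, "version", "1")),
             executor = xml2::xml_attr(n, "executor"),
             params = params,
             dependencies = vapply(xml2::xml_find_all(n, "./depends"), xml2::xml_text, ""),
             block = block)
  })
  wf <- tryCatch(workflow(tasks, constants = consts, wrappers = wrappers,
                          executors = executors),
                 error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
  attr(wf, "path") <- normalizePath(path)
  wf
}

#' Write a workflow XML file (canonical form)
#'
#' Writing is canonical: defaulted attributes are emitted explicitly, so
#' `write(read(x))` re-read equals `x` and writing twice yields
#' byte-identical files.
#'
#' @param wf A [workflow()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_workflow <- function(wf, path) {
  doc <- xml2::xml_new_root("workflow")
  settings <- xml2::xml_add_child(doc, "settings")
  cs <- xml2::xml_add_child(settings, "constants")
  for (nm in names(wf$constants)) {
    xml2::xml_add_child(cs, "constant", wf$constants[[nm]], name = nm)
  }
  ws <- xml2::xml_add_child(settings, "wrappers")
  for (w in wf$wrappers) {
    attrs <- c(list(ws, "wrapper", name = w$name, kind = w$kind),
               lapply(w$settings[intersect(names(w$settings),
                                           c("prefix", "command", "runtime"))],
                      as.character))
    node <- do.call(xml2::xml_add_child, attrs)
    if (w$kind == "container") {
      xml2::xml_attr(node, "autoMount") <- tolower(as.character(w$settings$auto_mount))
    }
  }
  es <- xml2::xml_add_child(settings, "executors")
  for (e in wf$executors) {
    node <- xml2::xml_add_child(es, "executor", name = e$name, kind = e$kind,
                                maxSlots = as.character(e$max_slots))
    if (!is.null(e$package_manager)) xml2::xml_attr(node, "packageManager") <- e$package_manager
    if (!is.null(e$container)) xml2::xml_attr(node, "container") <- e$container
    if (!is.null(e$spool_dir)) xml2::xml_attr(node, "spoolDir") <- e$spool_dir
  }
  ts <- xml2::xml_add_child(doc, "tasks")
  for (t in wf$tasks) {
    node <- xml2::xml_add_child(ts, "task", id = t$id, name = t$name,
                                module = t$module,
                                version = as.character(t$module_version),
                                executor = t$executor)
    for (d in t$dependencies) xml2::xml_add_child(node, "depends", d)
    for (nm in names(t$params)) {
      xml2::xml_add_child(node, "param", t$params[[nm]], name = nm)
    }
    if (!is.null(t$block)) {
      if (t$block$kind == "list") {
        b <- xml2::xml_add_child(node, "processBlock", kind = "list")
        for (col in t$block$columns) xml2::xml_add_child(b, "column", col)
        for (row in t$block$rows) {
          r <- xml2::xml_add_child(b, "row")
          for (cell in row) xml2::xml_add_child(r, "cell", cell)
        }
      } else {
        xml2::xml_add_child(node, "processBlock", kind = "folder",
                            base = t$block$base, pattern = t$block$pattern)
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

## ---- module descriptor -----------------------------------------------------

#' Read a module descriptor
#'
#' @param path Path to the descriptor XML, inside the module directory
#'   (`module_dir` is set to the containing directory). The module's
#'   `max_version` is raised to cover any element bound above the declared
#'   maximum.
#' @return A [module_descriptor()].
#' @export
read_module <- function(path) {
  doc <- read_validated_xml(path, "module", "module")
  commands <- lapply(xml2::xml_find_all(doc, "./command"), function(n) {
    list(range = node_range(n),
         tokens = vapply(xml2::xml_find_all(n, "./arg"), xml2::xml_text, ""))
  })
  parameters <- lapply(xml2::xml_find_all(doc, "./parameter"), function(n) {
    parameter_def(xml2::xml_attr(n, "name"),
                  value_type = xattr(n, "type", "string"),
                  required = xattr_bool(n, "required"),
                  default = xattr(n, "default"),
                  range = node_range(n),
                  check_existence = xattr_bool(n, "checkExistence"))
  })
  returns <- lapply(xml2::xml_find_all(doc, "./return"), function(n) {
    return_value_def(xml2::xml_attr(n, "name"),
                     value_type = xattr(n, "type", "string"),
                     range = node_range(n))
  })
  tryCatch(
    module_descriptor(xml2::xml_attr(doc, "name"),
                      max_version = as.integer(xattr(doc, "maxVersion", "1")),
                      commands = commands, parameters = parameters,
                      returns = returns,
                      version_flag = xattr(doc, "versionFlag"),
                      module_dir = dirname(normalizePath(path))),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' Write a module descriptor XML file
#' @param module A [module_descriptor()].
#' @param path Output path.
#' @export
write_module <- function(module, path) {
  doc <- xml2::xml_new_root("module", name = module$name,
                            maxVersion = as.character(module$max_version))
  if (!is.null(module$version_flag)) {
    xml2::xml_attr(doc, "versionFlag") <- module$version_flag
  }
  set_range <- function(node, range) {
    if (!is.na(range$min_version)) xml2::xml_attr(node, "minVersion") <- as.character(range$min_version)
    if (!is.na(range$max_version)) xml2::xml_attr(node, "maxVersion") <- as.character(range$max_version)
  }
  for (cmd in module$commands) {
    n <- xml2::xml_add_child(doc, "command")
    set_range(n, cmd$range)
    for (a in cmd$tokens) xml2::xml_add_child(n, "arg", a)
  }
  for (p in module$parameters) {
    n <- xml2::xml_add_child(doc, "parameter", name = p$name, type = p$value_type,
                             required = tolower(as.character(p$required)),
                             checkExistence = tolower(as.character(p$check_existence)))
    if (!is.null(p$default)) xml2::xml_attr(n, "default") <- p$default
    set_range(n, p$range)
  }
  for (r in module$returns) {
    n <- xml2::xml_add_child(doc, "return", name = r$name, type = r$value_type)
    set_range(n, r$range)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Load all module descriptors under one or more directories
#'
#' A module directory is any directory containing a `module.xml`
#' descriptor. Each given path may be a module directory itself or a root
#' whose immediate subdirectories are module directories.
#'
#' @param paths Character vector of directories.
#' @return Named list of [module_descriptor()]s, keyed by module name.
#' @export
load_modules <- function(paths) {
  files <- character()
  for (p in paths) {
    own <- file.path(p, "module.xml")
    if (file.exists(own)) files <- c(files, own)
    files <- c(files, Filter(file.exists,
                             file.path(list.dirs(p, recursive = FALSE), "module.xml")))
  }
  mods <- lapply(unique(files), read_module)
  nm <- vapply(mods, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate module name ", nm[duplicated(nm)][1], " under ",
         paste(paths, collapse = ", "), call. = FALSE)
  }
  stats::setNames(mods, nm)
}

## ---- return-value files ----------------------------------------------------

#' Parse a module return-value file
#'
#' One `name<TAB>value` pair per line (UTF-8); a later duplicate name
#' overwrites an earlier one; an empty (or absent) file yields an empty
#' mapping.
#'
#' @param path Path to the file written by a module run.
#' @return Named character vector.
#' @export
parse_return_file <- function(path) {
  out <- stats::setNames(character(), character())
  if (!file.exists(path)) return(out)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  for (i in seq_along(lines)) {
    tab <- regexpr("\t", lines[[i]], fixed = TRUE)
    if (tab < 1) {
      stop("return-value file ", path, ": line ", i, " has no TAB separator",
           call. = FALSE)
    }
    out[[substr(lines[[i]], 1, tab - 1)]] <- substring(lines[[i]], tab + 1)
  }
  out
}

## ---- module documentation --------------------------------------------------

#' Module documentation object
#'
#' @param module Module name (must match a descriptor name).
#' @param description Short description shown in the reference book.
#' @param paper_description Prose template for the methods report; may
#'   contain `%PARAM:name%` and `%SOFTWARE_VERSION%` placeholders, which
#'   are preserved verbatim by the readers/writers. `NULL` if the module
#'   has no paper description (the report then emits a fallback sentence).
#' @param dependencies List of `list(software =, version =)`.
#' @param pmids Integer vector of PubMed IDs.
#' @param categories,authors Character vectors.
#' @param param_docs,return_docs Named lists of per-element documentation:
#'   `list(description =, default =, range =)` / `list(description =, range =)`.
#' @export
module_doc <- function(module, description = "", paper_description = NULL,
                       dependencies = list(), pmids = integer(),
                       categories = character(), authors = character(),
                       param_docs = list(), return_docs = list()) {
  check_identifier(module, "module name")
  pmids <- as.integer(pmids)
  if (any(is.na(pmids) | pmids < 1)) stop("pmids must be positive integers", call. = FALSE)
  structure(list(module = module, description = description,
                 paper_description = paper_description,
                 dependencies = dependencies, pmids = pmids,
                 categories = as.character(categories),
                 authors = as.character(authors),
                 param_docs = param_docs, return_docs = return_docs),
            class = "shepherd_module_doc")
}

#' Read a module documentation XML file
#' @param path Path to the documentation XML.
#' @return A [module_doc()].
#' @export
read_module_doc <- function(path) {
  doc <- read_validated_xml(path, "moduledoc", "moduleDocumentation")
  first_text <- function(xp) {
    n <- xml2::xml_find_first(doc, xp)
    if (inherits(n, "xml_missing")) NULL else xml2::xml_text(n)
  }
  entry_docs <- function(xp) {
    nodes <- xml2::xml_find_all(doc, xp)
    stats::setNames(lapply(nodes, function(n) {
      e <- list(description = xml2::xml_text(n), range = node_range(n))
      d <- xattr(n, "default")
      if (!is.null(d)) e$default <- d
      e
    }), vapply(nodes, function(n) xml2::xml_attr(n, "name"), ""))
  }
  module_doc(module = xml2::xml_attr(doc, "module"),
             description = first_text("./description") %||% "",
             paper_description = first_text("./paperDescription"),
             dependencies = lapply(xml2::xml_find_all(doc, "./dependency"), function(n) {
               list(software = xml2::xml_attr(n, "software"),
                    version = xattr(n, "version"))
             }),
             pmids = as.integer(vapply(xml2::xml_find_all(doc, "./pmid"), xml2::xml_text, "")),
             categories = vapply(xml2::xml_find_all(doc, "./category"), xml2::xml_text, ""),
             authors = vapply(xml2::xml_find_all(doc, "./author"), xml2::xml_text, ""),
             param_docs = entry_docs("./paramDoc"),
             return_docs = entry_docs("./returnDoc"))
}

#' Write a module documentation XML file
#' @param doc A [module_doc()].
#' @param path Output path.
#' @export
write_module_doc <- function(doc, path) {
  x <- xml2::xml_new_root("moduleDocumentation", module = doc$module)
  xml2::xml_add_child(x, "description", doc$description)
  if (!is.null(doc$paper_description)) {
    xml2::xml_add_child(x, "paperDescription", doc$paper_description)
  }
  for (d in doc$dependencies) {
    n <- xml2::xml_add_child(x, "dependency", software = d$software)
    if (!is.null(d$version)) xml2::xml_attr(n, "version") <- d$version
  }
  for (p in doc$pmids) xml2::xml_add_child(x, "pmid", as.character(p))
  for (categ in doc$categories) xml2::xml_add_child(x, "category", categ)
  for (a in doc$authors) xml2::xml_add_child(x, "author", a)
  emit_entries <- function(tag, entries) {
    for (nm in names(entries)) {
      e <- entries[[nm]]
      n <- xml2::xml_add_child(x, tag, e$description %||% "", name = nm)
      if (!is.null(e$default)) xml2::xml_attr(n, "default") <- e$default
      r <- e$range %||% version_range()
      if (!is.na(r$min_version)) xml2::xml_attr(n, "minVersion") <- as.character(r$min_version)
      if (!is.na(r$max_version)) xml2::xml_attr(n, "maxVersion") <- as.character(r$max_version)
    }
  }
  emit_entries("paramDoc", doc$param_docs)
  emit_entries("returnDoc", doc$return_docs)
  xml2::write_xml(x, path)
  invisible(path)
}

#' Generate a documentation template for a module
#'
#' The template contains one empty documentation stub per parameter and
#' return value of the union of all module versions, each annotated with
#' its version range, plus empty description / paperDescription / PMID
#' slots. Module developers only fill in the prose; parsing the template
#' back yields a [module_doc()] whose entry names equal the descriptor's
#' element names.
#'
#' @param module A [module_descriptor()].
#' @return The template as a single XML string.
#' @export
extract_doc_template <- function(module) {
  stub <- function(el) {
    e <- list(description = "", range = el$range)
    if (!is.null(el$default)) e$default <- el$default
    e
  }
  doc <- module_doc(
    module = module$name,
    description = "",
    paper_description = "",
    param_docs = stats::setNames(lapply(module$parameters, stub),
                                 vapply(module$parameters, `[[`, "", "name")),
    return_docs = stats::setNames(lapply(module$returns, stub),
                                  vapply(module$returns, `[[`, "", "name")))
  tmp <- tempfile(fileext = ".xml")
  on.exit(unlink(tmp))
  write_module_doc(doc, tmp)
  paste(readLines(tmp, warn = FALSE), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load all module documentation files under one or more directories
#'
#' Documentation lives next to the descriptor as `doc.xml` in the module
#' directory.
#'
#' @param paths Directories (module directories or roots of module
#'   directories).
#' @return Named list of [module_doc()]s keyed by module name.
#' @export
load_module_docs <- function(paths) {
  files <- character()
  for (p in paths) {
    own <- file.path(p, "doc.xml")
    if (file.exists(own)) files <- c(files, own)
    files <- c(files, Filter(file.exists,
                             file.path(list.dirs(p, recursive = FALSE), "doc.xml")))
  }
  docs <- lapply(unique(files), read_module_doc)
  nm <- vapply(docs, `[[`, "", "module")
  if (anyDuplicated(nm)) {
    stop("duplicate module documentation for ", nm[duplicated(nm)][1], call. = FALSE)
  }
  stats::setNames(docs, nm)
}
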