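# Automated reporting: a step-by-step methods report drafted from the
# provenance log plus module documentation, and a static, searchable
# reference book of modules. Both outputs are deterministic: the same log
# and documentation yield byte-identical files on repeated generation.

#' Generate the step-by-step methods report
#'
#' One paragraph per executed task (>= 1 success record), ordered by the
#' timestamp of the task's first success. Each paragraph is the module's
#' `paperDescription` with `%PARAM:name%` replaced by the task's resolved
#' parameter value (for multi-subtask tasks: the unique values in
#' first-occurrence order, comma-joined) and `%SOFTWARE_VERSION%` by the
#' logged software version. Modules without a paper description yield the
#' fallback sentence
#' `No short description given in documentation of module <name>.`
#' With `pubmed = TRUE` the module's PubMed IDs are appended in
#' parentheses. Tasks with only failure records are listed in a trailing
#' "Failed steps" note.
#'
#' @param records Log records ([load_log()]).
#' @param docs Named list of [module_doc()]s keyed by module name.
#' @param pubmed Append PubMed IDs?
#' @return The report as a single Markdown string.
#' @export
generate_report <- function(records, docs = list(), pubmed = FALSE) {
  succ <- Filter(function(r) identical(r$status, "success"), records)
  fail <- Filter(function(r) identical(r$status, "failure"), records)
  by_task <- split(succ, vapply(succ, `[[`, "", "task_id"))
  first_ts <- vapply(by_task, function(rs) min(vapply(rs, `[[`, "", "timestamp")), "")
  first_ln <- vapply(by_task, function(rs) {
    min(match(vapply(rs, `[[`, "", "fingerprint"),
              vapply(succ, `[[`, "", "fingerprint")))
  }, 0)
  order_ids <- names(by_task)[order(first_ts, first_ln)]

  paras <- vapply(order_ids, function(id) {
    rs <- by_task[[id]]
    module <- rs[[1]]$module
    doc <- docs[[module]]
    pd <- if (!is.null(doc)) doc$paper_description else NULL
    text <- if (is.null(pd) || !nzchar(pd)) {
      sprintf("No short description given in documentation of module %s.", module)
    } else {
      substitute_report_placeholders(pd, rs, id)
    }
    if (isTRUE(pubmed) && !is.null(doc) && length(doc$pmids)) {
      text <- paste0(text, " (PMID: ", paste(doc$pmids, collapse = ", "), ")")
    }
    text
  }, "")

  body <- paste(paras, collapse = "\n\n")
  failed_ids <- setdiff(unique(vapply(fail, `[[`, "", "task_id")), names(by_task))
  if (length(failed_ids)) {
    notes <- vapply(sort(failed_ids), function(id) {
      mod <- fail[[match(id, vapply(fail, `[[`, "", "task_id"))]]$module
      sprintf("- task %s (module %s) failed and is not part of the analysis.", id, mod)
    }, "")
    body <- paste0(body, if (nzchar(body)) "\n\n", "## Failed steps\n\n",
                   paste(notes, collapse = "\n"))
  }
  paste0(body, if (nzchar(body)) "\n")
}

# %PARAM:name% and %SOFTWARE_VERSION% substitution; multi-subtask tasks
# aggregate unique values in first-occurrence (subtask-index) order
substitute_report_placeholders <- function(text, rs, task_id) {
  rs <- rs[order(vapply(rs, `[[`, 0L, "subtask_index"))]
  agg <- function(vals) paste(unique(vals), collapse = ", ")
  sv <- unlist(lapply(rs, function(r) r$software_version %||% NULL))
  text <- gsub("%SOFTWARE_VERSION%",
               if (length(sv)) agg(sv) else "unknown", text, fixed = TRUE)
  re <- "%PARAM:([A-Za-z_][A-Za-z0-9_.-]*)%"
  m <- gregexpr(re, text, perl = TRUE)
  hits <- regmatches(text, m)[[1]]
  for (h in unique(hits)) {
    nm <- sub(re, "\\1", h, perl = TRUE)
    vals <- unlist(lapply(rs, function(r) {
      if (nm %in% names(r$params)) r$params[[nm]]
    }))
    if (is.null(vals)) {
      warning("report: task ", task_id, " has no parameter ", sQuote(nm),
              " for placeholder ", h, call. = FALSE)
      repl <- paste0("<missing:", nm, ">")
    } else {
      repl <- agg(vals)
    }
    text <- gsub(h, repl, text, fixed = TRUE)
  }
  text
}

## ---- reference book --------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Generate the static module reference book
#'
#' Writes a fully self-contained `index.html` (inline CSS and JavaScript,
#' no network requests): an overview of module boxes (name, author,
#' category, short description) filterable by a client-side text search
#' over title, author, category and description, and a detail view per
#' module with dependencies, parameters with their types and version
#' ranges, return values, and citation information (PubMed IDs).
#' Regeneration is idempotent: the same documentation set yields the same
#' bytes.
#'
#' @param docs List of [module_doc()]s.
#' @param out_dir Output directory (created if needed).
#' @return Path of the written `index.html`.
#' @export
generate_refbook <- function(docs, out_dir) {
  nm <- vapply(docs, `[[`, "", "module")
  if (anyDuplicated(nm)) {
    stop("duplicate module name in documentation set: ", nm[duplicated(nm)][1],
         call. = FALSE)
  }
  docs <- docs[order(nm, method = "radix")]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  box <- function(d) {
    hay <- tolower(paste(d$module, paste(d$authors, collapse = " "),
                         paste(d$categories, collapse = " "), d$description))
    sprintf(paste0(
      '<div class="box" data-search="%s">',
      '<h3><a href="#mod-%s">%s</a></h3>',
      '<p class="meta">%s%s</p><p>%s</p></div>'),
      html_escape(hay), html_escape(d$module), html_escape(d$module),
      html_escape(paste(d$authors, collapse = ", ")),
      if (length(d$categories))
        paste0(" &middot; ", html_escape(paste(d$categories, collapse = ", "))) else "",
      html_escape(d$description))
  }

  entry_rows <- function(entries) {
    paste(vapply(names(entries), function(n) {
      e <- entries[[n]]
      r <- e$range %||% version_range()
      rng <- paste0(if (is.na(r$min_version)) "1" else r$min_version, "..",
                    if (is.na(r$max_version)) "*" else r$max_version)
      sprintf("<tr><td><code>%s</code></td><td>%s</td><td>%s</td><td>%s</td></tr>",
              html_escape(n), rng,
              html_escape(e$default %||% ""), html_escape(e$description %||% ""))
    }, ""), collapse = "\n")
  }

  detail <- function(d) {
    deps <- if (length(d$dependencies)) {
      paste0("<ul>", paste(vapply(d$dependencies, function(x) {
        sprintf("<li>%s%s</li>", html_escape(x$software),
                if (!is.null(x$version)) paste0(" ", html_escape(x$version)) else "")
      }, ""), collapse = ""), "</ul>")
    } else "<p>none</p>"
    cite <- if (length(d$pmids)) {
      sprintf("<p>PMID: %s</p>", paste(d$pmids, collapse = ", "))
    } else "<p>none</p>"
    sprintf(paste0(
      '<details id="mod-%s"><summary>%s</summary>',
      '<p>%s</p><h4>Dependencies</h4>%s',
      '<h4>Parameters</h4><table><tr><th>name</th><th>versions</th>',
      '<th>default</th><th>description</th></tr>%s</table>',
      '<h4>Return values</h4><table><tr><th>name</th><th>versions</th>',
      '<th>default</th><th>description</th></tr>%s</table>',
      '<h4>Citation</h4>%s</details>'),
      html_escape(d$module), html_escape(d$module), html_escape(d$description),
      deps, entry_rows(d$param_docs), entry_rows(d$return_docs), cite)
  }

  html <- c(
    "<!DOCTYPE html>",
    '<html lang="en"><head><meta charset="utf-8"/>',
    "<title>Module reference book</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em;max-width:60em}",
    ".box{border:1px solid #ccc;border-radius:6px;padding:0.5em 1em;margin:0.5em 0}",
    ".meta{color:#666;font-size:smaller}",
    "table{border-collapse:collapse}td,th{border:1px solid #ddd;padding:0.2em 0.6em}",
    "#search{width:100%;padding:0.4em;margin-bottom:1em}",
    "</style></head><body>",
    "<h1>Module reference book</h1>",
    sprintf("<p>%d module(s).</p>", length(docs)),
    '<input id="search" type="text" placeholder="filter by name, author, category or description"/>',
    '<div id="boxes">',
    vapply(docs, box, ""),
    "</div>",
    "<h2>Module details</h2>",
    vapply(docs, detail, ""),
    "<script>",
    "document.getElementById('search').addEventListener('input', function () {",
    "  var q = this.value.toLowerCase();",
    "  document.querySelectorAll('#boxes .box').forEach(function (b) {",
    "    b.style.display = b.dataset.search.indexOf(q) >= 0 ? '' : 'none';",
    "  });",
    "});",
    "</script></body></html>")
  out <- file.path(out_dir, "index.html")
  writeLines(html, out, useBytes = TRUE)
  out
}
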