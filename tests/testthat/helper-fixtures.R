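# Shared fixture builders. Everything is generated in code under a fresh
# temporary directory per test; no files are shipped.

scratch_dir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# fast engine options for tests
test_opts <- function(dir, ...) {
  utils::modifyList(
    list(log = file.path(dir, "run.resume"), poll = 0.02,
         run_dir = file.path(dir, "run"), quiet = TRUE),
    list(...))
}

# a stamping module (emit_return behavior) plus a simple workflow factory
stamp_setup <- function(dir, version_string = NULL, versions = 1L) {
  mdir <- file.path(dir, "modules")
  make_toy_module(mdir, "stamp", "emit_return", versions = versions,
                  version_string = version_string)
  load_modules(mdir)
}

stamp_task <- function(id, value, deps = character(), executor = "local",
                       block = NULL, out = NULL, version = 1L) {
  params <- c(value = value)
  if (!is.null(out)) params <- c(params, out = out)
  task_def(id, module = "stamp", executor = executor, params = params,
           dependencies = deps, block = block, module_version = version)
}

local_executors <- function(slots = 4L) list(executor_def("local", "local",
                                                          max_slots = slots))

# chain t1 -> t2 -> ... -> tn of stamp tasks
chain_workflow <- function(n, dir = NULL) {
  tasks <- lapply(seq_len(n), function(i) {
    stamp_task(paste0("t", i), paste0("v", i),
               deps = if (i > 1) paste0("t", i - 1) else character(),
               out = if (!is.null(dir)) file.path(dir, paste0("t", i, ".txt")))
  })
  workflow(tasks, executors = local_executors())
}

dispatched_keys <- function(res) {
  vapply(Filter(function(e) e$event == "dispatch", res$trace), `[[`, "", "key")
}

trace_events <- function(res, event) {
  vapply(Filter(function(e) e$event == event, res$trace), `[[`, "", "key")
}

# every file under a data directory, as a named list of line vectors
snapshot_outputs <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  stats::setNames(lapply(file.path(dir, files), readLines), files)
}

# random DAG workflow over a stamping module and an always-failing module;
# returns the workflow plus which tasks were set up to fail
random_dag_workflow <- function(modules_dir, n_tasks, fail_frac = 0) {
  ids <- paste0("t", seq_len(n_tasks))
  failing <- ids[stats::runif(n_tasks) < fail_frac]
  tasks <- lapply(seq_len(n_tasks), function(i) {
    deps <- if (i > 1) {
      cand <- ids[seq_len(i - 1)]
      cand[stats::runif(length(cand)) < 0.35]
    } else character()
    nsub <- sample(1:4, 1, prob = c(0.5, 0.25, 0.15, 0.1))
    block <- if (nsub > 1) {
      process_block("list", columns = "S",
                    rows = as.list(paste0("s", seq_len(nsub))))
    } else NULL
    if (ids[i] %in% failing) {
      task_def(ids[i], module = "alwaysfail", executor = "local",
               params = c(marker = paste0("${MARK}/", ids[i],
                                          if (!is.null(block)) "_[S]" else "")),
               dependencies = deps, block = block)
    } else {
      stamp_task(ids[i], if (!is.null(block)) paste0(ids[i], "-[S]") else ids[i],
                 deps = deps, block = block)
    }
  })
  list(wf = workflow(tasks,
                     constants = c(MARK = file.path(modules_dir, "..", "markers")),
                     executors = local_executors(slots = 3L)),
       failing = failing)
}
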