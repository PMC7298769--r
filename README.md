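# shepherd

A headless workflow-management engine for bioinformatics pipelines
(RNA-seq, ChIP-seq and similar multi-step, multi-sample analyses), built for
reproducibility: it runs XML-defined workflows over reusable, versioned tool
modules and records everything needed to *re-run only what changed*, to
*reconstruct the methods section* of an analysis, and to *walk away from a
running cluster workload and come back later, on another machine*.

Who it is for: anyone who strings command-line tools into sample-parallel
pipelines and needs (a) incremental re-execution after modifying parameters
or adding samples, (b) a provenance log with resolved parameters and
third-party software versions, and (c) a scheduler that can be killed,
crashed, or detached without corrupting state.

## The model

* **Modules** wrap a tool: a command template, typed parameters and return
  values, each optionally restricted to a range of module versions, and an
  optional version flag used to probe the wrapped software's version. A task
  that names no version uses version 1, so old workflows survive module
  evolution.
* **Workflows** are XML: constants (`${NAME}`), execution wrappers (package
  manager inner, container outer), executors (local, or a cluster-style
  *spool* executor whose jobs outlive the scheduler), and tasks with
  dependencies. A **process block** multiplies a task over samples — one
  *subtask* per row or per matching file.
* **Identity**: every subtask has a SHA-256 fingerprint over
  `task_id | module | version | sorted(name=value, ...)`. A success record in
  the provenance log (JSON Lines, `.resume`) keyed by this fingerprint is
  what excuses a subtask from re-execution.
* **Resume**: subtasks without a matching success record run; every subtask
  of every task transitively depending on a rerun task runs too; the rest is
  reused, its logged return values feeding downstream `$[task.NAME]`
  references without execution.
* **Durability**: a success is logged and flushed *before* it counts, so a
  SIGKILL at any point loses at most one truncated log line — and resuming
  reproduces an uninterrupted run's outputs byte for byte.
* **Detach/reattach**: on request the engine drains local work, keeps
  submitting to spool executors, snapshots the outstanding jobs and exits
  (status 3); the snapshot reattaches from any working directory or host
  that sees the same paths. An auto-detach mode runs one
  absorb/dispatch/snapshot cycle and terminates, for periodic invocation.
* **Reporting**: a methods-section draft generated from the log (module
  `paperDescription` templates with `%PARAM:name%` / `%SOFTWARE_VERSION%`
  placeholders, PubMed IDs on request), and a self-contained searchable HTML
  reference book of module documentation.

## Worked example

The built-in fixture generator creates a five-task workflow (`A; B←A; C←B;
D←A` over two samples; `E←D`) and a modified second version (one of `B`'s
parameters changed, `D` grown to four samples, new tasks `F←E` and `Z`):

```r
library(shepherd)
dir <- file.path(tempdir(), "demo")
fx <- make_resume_pair(dir)
modules <- load_modules(fx$modules)

wf <- read_workflow(fx$v1)
print(wf)
#> <workflow> 5 task(s), 1 constant(s), 1 executor(s)
#>   A [stamp v1 @local]
#>   B [stamp v1 @local] <- A
#>   C [stamp v1 @local] <- B
#>   D [stamp v1 @local] <- A (x2)
#>   E [stamp v1 @local] <- D

res <- run_workflow(wf, modules,
                    list(log = file.path(dir, "run.resume"), poll = 0.1))
print(res)
#> <shepherd run> exit status 0
#>    succeeded: 6
#>   log: /tmp/.../demo/run.resume
```

Six subtasks succeeded (`D` expanded into two). Resuming the *modified*
workflow against that log executes only the changed and dependent work —
`B` (modified parameter), `C` (depends on `B`), `D[2]`/`D[3]` (new samples),
`E` (depends on `D`), and the new tasks `F` and `Z` — while `A`, `D[0]`,
`D[1]` are reused without running:

```r
res2 <- run_workflow(read_workflow(fx$v2), modules,
                     list(resume = res$log, poll = 0.1))
print(res2)
#> <shepherd run> exit status 0
#>    succeeded: 10
#>   resume plan: run {Z[0], B[0], D[2], D[3], C[0], F[0], E[0]}, reuse {A[0], D[0], D[1]}
#>   log: /tmp/.../demo/run.resume
```

The same log yields a methods draft; values in parentheses are the software
versions the engine probed after each success:

```r
docs <- list(stamp = module_doc(
  "stamp",
  description = "Stamps a value into a file.",
  paper_description = "Stamped %PARAM:value% (%SOFTWARE_VERSION%).",
  pmids = 31088905L))
cat(generate_report(load_log(res$log), docs, pubmed = TRUE))
#> Stamped alpha (toytool 3.1.4). (PMID: 31088905)
#>
#> Stamped beta-one, beta-two (toytool 3.1.4). (PMID: 31088905)
#>
#> Stamped s1, s2, s3, s4 (toytool 3.1.4). (PMID: 31088905)
#> ...
```

The same operations are available from the shell through the installed
script (`exec/shepherd.R`): `run` (with `--resume`, `--dry-run`,
`--auto-detach`, `--detach-file`), `reattach`, `report`, `refbook`,
`doc-template` and `validate`. Exit statuses: 0 success, 1 task failures,
2 invalid input, 3 detached.

## Documentation

The package vignette (`vignettes/execution-model.Rmd`) describes the
execution model, the identity and durability rules, the detach automaton,
and every tunable with its default and rationale.
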