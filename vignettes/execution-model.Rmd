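---
title: "The shepherd execution model: versioned modules, resume planning, and detachable scheduling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The shepherd execution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shepherd)
```

shepherd is a headless workflow-management engine of the kind used to drive
sequence-analysis pipelines (RNA-seq, ChIP-seq and similar): a workflow is an
XML document listing tasks, each task wraps a reusable *module* (a tool
descriptor plus an entry script), and the scheduler runs tasks across
executors while writing a provenance log that later drives incremental
re-execution, automated methods reporting, and detachable scheduling. This
vignette explains the model, the identity scheme behind resume planning, and
the design decisions a maintainer would want spelled out.

## Modules and version-ranged interfaces

A module descriptor declares a command template, parameters, return values,
and an optional *version flag*. Every element may carry a version range
(`minVersion`/`maxVersion`); an element without bounds is valid in all module
versions. The *effective interface* of version $v$ is the set of elements
whose range contains $v$, which by construction is a contiguous interval of
versions per element. A task that does not name a version uses version 1 —
the rule that keeps workflows written before a module grew a new version
running unchanged. Validation rejects a task that assigns a parameter outside
its version's effective interface, so a v2-only parameter cannot leak into a
v1 task.

The command template is an ordered token list. Tokens may embed `{param}`
slots and the reserved `{MODULE_DIR}`; parameters not referenced by any token
are appended as `--name value` pairs in interface order. This keeps toy
modules trivial to write while allowing arbitrary call shapes.

## Subtask identity and resume planning

A task with a *process block* expands into one subtask per row (list blocks)
or per matching file (folder blocks, enumerated lexicographically so indices
are reproducible). Each resolved subtask is identified by a SHA-256
fingerprint over the canonical string

```
task_id <US> module <US> version <US> name=value <US> ...
```

with parameters sorted by name and `<US>` the ASCII unit separator. Identity
deliberately includes the task id, module name and module version in addition
to the parameter combination: two tasks sharing a module and parameters then
never alias each other in the log. The cost is an occasional extra rerun
(e.g. after renaming a task); the benefit is that stale reuse is impossible,
which is the safer trade for a provenance system.

Resume planning loads the prior log and computes:

1. the base run set — every subtask whose fingerprint has no success record
   (the latest record wins when a fingerprint appears repeatedly, which is
   what makes forced reruns possible);
2. the dependent closure — every subtask of every task that transitively
   depends on a task with at least one subtask in the run set.

The closure is whole-task: when two new samples are added to a multi-sample
task, only the new subtasks run, but a downstream aggregating task is
repeated entirely, since its inputs changed as a set. Values referencing
upstream return values (`$[task.NAME]`) are *late-bound*: such a subtask is
fingerprinted only after resolution, so resume identity reflects the inputs
the command actually saw. During planning, late bindings are resolved against
the logged return values of the dependencies; if those are unavailable, or a
dependency is itself rerunning, the subtask conservatively runs. Removing
tasks or dependency edges after a run is warned about (stale inputs may
otherwise be consumed silently) but never blocks execution.

Constant references (`${NAME}`) are substituted in a single pass and
replacement values are never re-scanned, so substitution cannot recurse or
expand unboundedly; nested constant references are deliberately unsupported.

## The scheduling loop and crash durability

The engine is a single-threaded poll loop: absorb finished jobs, notice a
detach request, dispatch ready subtasks, sleep. A subtask is ready when every
subtask of every dependency task has succeeded; dependency granularity is the
task, not the subtask, because a downstream task cannot generally know which
upstream sample maps to which of its own inputs. On a failure, all transitive
dependents are marked `skipped` while independent branches continue — this
maximizes useful work and composes with resume, which will pick the skipped
work up once the failure is fixed. A dependent of a partially failed
multi-subtask task never runs: all subtasks must succeed.

The durability rule that makes crash-resume sound is ordering: a success
record is serialized to one JSON line, written and flushed *before* the
subtask is considered succeeded, so the log never claims more than what
happened and dependents never start on unlogged state. Conversely, a crash
can leave at most one truncated final line, which the loader drops with a
warning; that subtask simply replans. Killing the engine with SIGKILL after
any number of successes and resuming therefore reproduces the uninterrupted
run's outputs byte for byte, which the test suite asserts for every kill
point of a six-subtask workflow.

## Executors, detach/reattach, and the auto-detach cycle

Two executor kinds are built in. The *local* executor runs each subtask as a
small POSIX-shell driver that captures stdout/stderr and atomically writes an
exit-status file. The *spool* executor uses the same driver mechanics inside
a spool directory under a stable job id, with the worker spawned fully
detached — it survives the engine process, which is exactly the contract of a
cluster workload manager (SGE/SLURM bindings themselves are out of scope; the
spool executor reproduces their scheduling-relevant behavior so every
detach/reattach property is testable on one machine). Polling reads only the
filesystem and therefore works from any process and any working directory.

On a detach request (SIGINT or a sentinel file), the engine stops dispatching
to local executors, keeps submitting to spool executors, waits for local work
to drain, snapshots the outstanding spool jobs (job id, spool directory,
subtask identity) to a JSON file, and exits with the distinct status 3.
Reattaching — on any machine that can see the same absolute spool and log
paths — re-adopts the recorded jobs, logs completions that happened while the
engine was down, and resumes the loop. The *auto-detach* cycle is the
periodic variant: absorb already-finished jobs once, dispatch what is ready
(local work completes within the cycle; spool jobs are submitted and not
re-polled), snapshot, terminate. Repeated invocation converges for any finite
workflow: a three-task spool chain takes exactly four cycles (three
dispatches plus a final absorb).

## Execution wrappers and software-version capture

Wrappers rewrite a subtask's command to provision its environment. The
package-manager wrapper is applied innermost and the container wrapper
outermost, so a package manager can run inside a container. Both are driven
by module-side files: `<module>.conda.yml` (version-specific
`<module>.v<N>.conda.yml` preferred) and `<module>.image` /
`<module>.v<N>.image` holding the image name; a missing file silently skips
the wrapper for that module, so workflows without environments are
unaffected. The container wrapper auto-mounts the existing absolute paths
among file/folder-typed parameter values (each exactly once; the option can
be disabled). The generic `prefix` wrapper simply prepends tokens — the test
suite uses it so no conda or docker installation is ever required, while the
conda/docker adapters emit `conda run --file …` / `docker run --rm …`
token sequences.

After a subtask succeeds, if its module declares a version flag, the module's
base command is invoked with that flag under the same wrappers (so a
containerized tool reports its in-container version), synchronously on the
scheduler host — the spool executor emulates a cluster on the same machine,
so "the computer that executed the task" and the probing host coincide here.
The first non-empty output line is logged as the software version; a nonzero
exit, empty output or a timeout (default 30 s, configurable) degrades to
`"unknown"`, and a module without a version flag simply has no
`software_version` field in its records. The probe runs after success and
before the log record is written, so the record is complete when it becomes
durable.

## Reporting

The report generator turns a log into a step-by-step methods draft: one
paragraph per executed task, ordered by the timestamp of the task's first
success. A paragraph is the module documentation's `paperDescription` with
`%PARAM:name%` and `%SOFTWARE_VERSION%` placeholders substituted from the
log; a task that expanded into several subtasks aggregates the unique values
in first-occurrence order, comma-joined (per-task prose reads better than
per-sample repetition). A module without a paper description contributes the
exact sentence `No short description given in documentation of module
<name>.` so gaps are visible rather than silent. PubMed IDs are appended in
parentheses on request. Tasks with only failure records are listed in a
trailing "Failed steps" note — a deliberate extension, flagged as such, so a
report is never mistaken for a complete analysis when steps failed.

The reference book is a single self-contained HTML page (inline CSS and
JavaScript, no network requests): module boxes with name, author, category
and description, client-side text filtering over those fields, and a detail
section per module with dependencies, parameters, version ranges, return
values and citation info. Regeneration is byte-idempotent.

## What the fixtures emulate — and what they do not

The fixture generator builds portable shell-script modules (copy, concat,
value-stamping with a return value, fail-n-times, sleep) and a two-version
workflow pair: version 1 is `A; B←A; C←B; D←A (two samples); E←D`, version 2
modifies one of `B`'s parameters, grows `D` to four samples and adds `F←E`
plus an independent `Z`. Resuming version 2 against version 1's log must
execute exactly `{B, C, D[2], D[3], E, F, Z}`. The choice that `F` depends on
`E` while `Z` is independent is this package's own reconstruction of "a
dependent and an independent task are added", and is documented at the
fixture. `C` consumes `B`'s return value, so the late-binding path is
exercised by the standard scenario rather than only by unit tests.

These fixtures emulate the *scheduling-relevant* properties of real
pipelines: dependency structure, multi-sample expansion, deterministic
outputs, long-running cluster jobs (via sleeps), crashes (via SIGKILL) and
environment deployment (via prefix wrappers). They do not emulate real
sequencing data, real tool runtimes, network filesystems' latency, or a real
workload manager's queueing policy — a passing suite therefore demonstrates
the engine's correctness contracts, not performance or robustness against
filesystem semantics weaker than POSIX rename atomicity (the status-file
protocol relies on atomic `mv` within one filesystem).

## Numerical and operational choices

* **Poll interval**: default 1 s; the suite shrinks it to 10–50 ms. Polling
  is O(running jobs) per tick and purely filesystem-based.
* **Probe timeout**: 30 s default, 1 s in tests that exercise the hang path.
* **Hash**: SHA-256; the fingerprint of a fixed canonical string is pinned in
  the tests against an independently computed digest.
* **Log format**: JSON Lines, UTF-8, one record per line, `.resume`
  extension; field names are fixed by `log_record()`. Executor name is
  recorded but excluded from identity, so moving a task to another executor
  does not force a rerun (results should not depend on where a task ran).
* **Record extension**: each record also stores the task's dependency ids;
  this is what makes removed-edge warnings possible on resume.
* **Tie-breaks**: report paragraphs order by (first success timestamp, first
  log line); folder blocks enumerate lexicographically by filename; merged
  return maps of multi-subtask tasks resolve duplicates by subtask-index
  order, later subtasks winning.
* **Problem sizes in the checks**: the resume scenario uses the six-subtask
  workflow above; crash-resume is asserted at every kill point 0–5 of that
  workflow; scheduling safety over 100 random DAGs of up to 12 tasks and 4
  subtasks each with injected always-failing tasks in a third of the
  instances. These sizes give full coverage of the interleavings that matter
  (joins, partial multi-subtask completion, failure closure) while keeping
  the whole suite in the tens of seconds.

## Known limitations

Dependencies are task-level, not subtask-level, so a per-sample chain of two
multi-sample tasks synchronizes at the task boundary. Process blocks cover
list and folder multiplication only (no tables or chained compute blocks).
Parameter types are a fixed six-kind vocabulary without enum or range
restrictions. The conda/docker adapters emit command prefixes but are not
integration-tested against real installations. SSH remote executors, email
notification and any web interface are out of scope by design.
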