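---
title: "Modeling and querying hospital processes with medmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and querying hospital processes with medmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medmod)
```

## The problem

Clinical processes resist the strict control-flow languages used for
administrative workflows: the order of bedside steps is only loosely
defined, activities repeat an unpredictable number of times, and episodes
end when a doctor decides to end them, not when a token reaches a final
node. `medmod` implements a small process-modeling language built for this
setting, together with a query language over its runtime data that a
non-programmer could operate: spreadsheet-style filters over *slices* —
transactions of a process — with single-number answers and instance tables.

## The modeling language

A model is a set of **activities** (named tasks in time, each with typed
attributes: Integer, Real, String, Boolean, DateTime, or an enumeration)
connected by four kinds of oriented relations:

* **follows** — the target can start only after the source ends. Several
  outgoing follows edges are *exclusive* (XOR): one run-time instance takes
  exactly one of them. Several ingoing edges are inclusive.
* **composition** — an *aggregate* activity consists of *component*
  activities, each bounded by a cardinality (`1`, `0..1`, `1..*`, `*`).
* **interruption** — executing the target *suspends* the aggregate source:
  no new components may start, but running components finish normally. This
  is how an episode that would otherwise wait forever for more components is
  ended from outside.
* **extension** — the target may be called *during* the execution of the
  source, guarded by an extension-point condition ("second opinion is
  necessary").

Exactly one activity is the **master**; every one of its run-time instances
roots a transaction. The set of instances reachable from one master
instance is a **slice**, and slices never share instances — the invariant
that makes linear-time query evaluation possible. `validate_model()` checks
the well-formedness rules (V1–V7), `validate_trace()` the runtime
conformance rules (T1–T8); both return violation records rather than
throwing, so a user can see *all* problems at once.

```{r}
m <- demo_model()
print(m)
nrow(validate_model(m))
```

## The query language

A query is evaluated against a **dataset** — the slices whose master
instance starts in a chosen half-open time window `[start, end)`. Keying
window membership on the master's start time is a design choice: the
language only says slices "correspond to" the interval, and the
transaction's birth is the one unambiguous anchor; half-open windows make
disjoint windows partition the slices.

Three kinds of filtering conditions apply, all returning *whole* slices:

* **comparison** conditions on attribute values (`=`, `!=`, `>`, `<`,
  `>=`, `<=` for ordered types; `contains`, `begins_with`, `ends_with` for
  strings; equality for booleans and enumerations), with at most one extra
  AND/OR term evaluated on the *same instance*;
* **slice aggregates** — conditions on the per-slice `Sum`/`Average` of an
  attribute or the `Count` of instances of one activity;
* **partitioning** — `Top`/`Bottom` *k* slices by an attribute's per-slice
  extreme value.

Separate conditions combine with slice-level AND semantics: a slice passing
two conditions need not contain a single instance satisfying both. Within
one two-term condition, both terms bind to one instance. Partitions apply
to the dataset left by the other conditions, and several partitions
intersect.

```{r}
d <- simulate_trace(m, demo_config(n_slices = 300, seed = 7))
q <- pql_query(
  conditions = list(
    pql_comparison("Doctor sets diagnosis", "diagnosis", "=", "Pneumonia"),
    pql_aggregate("Procedure is executed", "Average", ">", 100,
                  attribute = "cost")),
  partitions = list(
    pql_partition("Clinical process in ward", "total_expenses", "Top", 10)),
  retrievals = list(
    pql_retrieval("average", "Procedure is executed", "cost")))
apply_query(d, q)
```

### Numerical and tie-break choices

* Comparisons use exact IEEE semantics — no tolerance; strings are
  case-sensitive; DateTime constants are ISO-8601, compared as absolute
  instants. A comparison against an absent value is false.
* A `Sum`/`Average`/`Count` condition on an activity absent from a slice
  *fails* the slice (the filter asks for slices containing instances of the
  filtered type); `Sum` is not silently 0. Retrieval aggregates over a
  dataset behave differently: `Sum` of nothing is 0, `Count` 0, `Average`
  undefined (`NA`).
* Partitioning ranks slices by their extreme instance value (max for Top,
  min for Bottom), breaking ties by ascending slice id and taking a strict
  first *k*. An alternative instance-level reading (take the k extreme
  *instances* and return their slices, possibly fewer than k) is plausible
  from the language description; the slice-level reading matches the worked
  "10 slices where total expenses are the largest" usage and is what we
  implement. `k` is capped (`k_max`, default 100, configurable) to keep
  evaluation effectively linear.
* Time intervals pair each start instance with the earliest not-yet-paired
  end instance at or after it ("adjacent in time" is otherwise undefined),
  optionally within classes of a pairing equality (e.g. matching procedure
  codes); durations are therefore never negative. Self-pairing of an
  instance with itself is excluded so start/end activities may coincide.
  Interval values become derived, multi-valued attributes of the master
  instance and can be used in later conditions under the interval's name.
* Grouping merges slices sharing an attribute value; a slice holding
  several key values goes to the key of its *earliest* keyed instance —
  single membership preserves slice disjointness. Group-slices may hold
  several master instances, so grouped datasets are reported on, not
  re-validated.

### The cost contract

Every filter instruments the number of instance inspections it performs
(`inspections()`, accumulated in `apply_query()`'s `inspection_count`). A
single comparison condition inspects at most `n` instances — the scan
leaves a slice at its first matching instance — and a partition at most
`k * n`. The test suite asserts these bounds on every run; they are the
package's formulation of the linear-time evaluation claim.

## The synthetic-data generator

`simulate_trace()` executes a model stochastically from a closed
distribution vocabulary (constant, uniform, uniform integer, exponential,
categorical). Follows successors start after their predecessor ends with a
sampled gap; XOR branches are drawn from configured weights; aggregates
spawn components at sampled intervals until the interruption instance is
sampled strictly later than every spawn; extensions fire within the host's
span. Conformance is therefore guaranteed by construction, and the test
suite verifies zero violations across 50 seeds. All timestamps are rounded
to whole seconds so the JSON/CSV wire forms round-trip bit for bit;
identical seeds give byte-identical traces.

The defaults in `demo_config()` state one fixed world: admissions every
30 minutes on average; 1–5 procedure assignments per ward episode (mean
2.9), each later executed at an inherited procedure code and a cost of
20–300 whole currency units; 1–4 diagnoses (mean 2.3); a second opinion
with probability 0.3 per diagnosis; discharge vs transfer weighted
0.7/0.3. The expected slice size is then ≈ 12.8 instances, so 5000 slices
give roughly 64,000 instances — the scale the engine is exercised at.
These values were chosen once as plausible for a mid-size ward and are not
tuned.

What the generator does *not* emulate: correlations present in real data
(costs independent of diagnosis and of the episode's total expenses),
resource constraints (beds, shifts), seasonal arrival patterns, and missing
or corrupted fields. A green test therefore establishes the *semantics* of
the engine on conformant data, not robustness to real hospital exports —
import from hospital information systems is explicitly out of scope.

## Known limitations

* Only the prose well-formedness rules are enforced; the language's fuller
  constraint set (the omitted OCL layer) is unknown, so V1–V7 are a lower
  bound on strictness.
* Whether a follows successor may be checked against an open-ended
  (suspended) predecessor is undefined; we flag it as a T4 *warning*.
* Interval values of a grouped dataset attach to the group-slice as a
  whole; attributing them to individual merged masters is unspecified.
* The CLI re-evaluates queries declaratively; the interactive "immediate
  response" of a graphical front end is approximated by cheap full
  re-evaluation, and no editor or GUI is provided.
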