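# medmod

Hospital process modeling and slice-based process querying in R.

Clinical processes are only loosely ordered: activities repeat, episodes
end when a doctor decides, and strict workflow languages fit them badly.
`medmod` implements a small domain-specific process modeling language for
this setting and a companion query language over its runtime data, aimed at
the kind of ad-hoc questions a clinician-manager asks — *"How many patients
had diagnosis Pneumonia and Stroke?"*, *"Which ten ward episodes cost the
most?"* — without writing code against a database schema.

## The model and the query semantics

A **process model** is a set of activities with typed attributes (Integer,
Real, String, Boolean, DateTime, enumerations) and four relation kinds:
*follows* (successor starts after predecessor ends; multiple out-edges are
XOR), *composition* (aggregate/component containment with cardinalities),
*interruption* (suspends an aggregate: no new components, running ones
finish), and *extension* (a guarded call during a host activity). Exactly
one activity is the **master**; the instances reachable from one master
instance form a **slice** (one transaction), and slices are disjoint.

Queries filter a dataset of slices with three condition kinds, always
returning whole slices:

* comparison conditions on attribute values, with at most one extra AND/OR
  term bound to the same instance;
* per-slice aggregate conditions — `Sum`/`Average` of an attribute or
  `Count` of instances of one activity within the slice;
* `Top`/`Bottom`-*k* partitioning by a per-slice extreme value.

Retrievals compute `Count`/`Sum`/`Average` indicators, time intervals
between paired instances (optionally matched on an attribute equality, e.g.
the same procedure code), grouping of slices by a shared attribute value,
and instance tables. Evaluation is instrumented: a comparison condition
inspects at most *n* instances (the dataset size) and a partition at most
*k·n* — the linear-time contract is asserted on every test run.

A stochastic simulator executes any valid model into a conformant synthetic
trace (identical seeds give byte-identical traces); `demo_model()` ships a
nine-activity hospital example with enumerated procedure and diagnosis
codes, costs and patient attributes.

## Worked example

```r
library(medmod)

m <- demo_model()
nrow(validate_model(m))        # 0 — well-formed
d <- simulate_trace(m, demo_config(n_slices = 300, seed = 7))
d
#> MedMod dataset on model 'hospital': 300 slices, 3760 instances

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
#> PQL result: 10 slices, 128 instances (inspections: 6191)
#>   Patient enters the hospital                   10
#>   Patient admitted to hospital ward             10
#>   Clinical process in ward                      10
#>   Doctor assigns procedure                      30
#>   Procedure is executed                         30
#>   Doctor sets diagnosis                         23
#>   Patient consulted by second doctor            5
#>   Patient discharged from hospital              7
#>   Patient transferred to another ward           3
#>   average(Procedure is executed.cost) = 164.633
```

The result is the ten most expensive ward episodes among patients with a
Pneumonia diagnosis whose average procedure cost exceeded 100, with the
per-activity instance counts of the filtered dataset (the query diagram's
indicator boxes) and the requested average. The 6191 instance inspections
sit well under the `(2 + 10) × 3760` bound of the cost contract.

Manual association rules come from the same machinery:

```r
condA <- pql_comparison("Doctor sets diagnosis", "diagnosis", "=", "Pneumonia")
condB <- pql_comparison("Doctor sets diagnosis", "diagnosis", "=", "Stroke")
implication_probability(d, condA, condB)
#> [1] 0.1176471    # P(Stroke | Pneumonia) in this dataset
```

## Command line

The same engine drives a CLI (installed at `exec/medmod`):

```sh
medmod simulate --n-slices 100 --seed 1 --out trace.json
medmod validate-trace --model model.json --trace trace.json
medmod query --model model.json --trace trace.json --query query.json \
             --window-start 2012-01-01T00:00:00Z \
             --window-end 2012-02-01T00:00:00Z --out-dir results/
medmod export-table --model model.json --trace trace.json \
             --activity "Procedure is executed" --out procedures.csv
```

JSON schemas for the model, trace and query dialects are under
`inst/schemas/`; traces also round-trip through a flat CSV dialect. Errors
are emitted as machine-readable JSON with a non-zero exit status.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package: it simulates the demo hospital model at the experimental
scale (5000 slices, ~64,000 instances), verifies model and trace
conformance, executes a three-condition query with a top-10 partition under
the instrumented inspection bounds, and writes the JSON manifest to
`--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/process-querying.Rmd` for the full account of the language
semantics, the evaluation strategy, the simulator's stated world, and known
limitations.
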