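---
title: "Partition-parallel anonymization: models, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partition-parallel anonymization: models, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p4anon)
```

## The problem

Health microdata — one record per person, a handful of demographic and
socio-economic attributes — cannot be shared as-is: combinations of
*quasi-identifiers* (age, sex, zip) act as near-unique keys that link
records to external sources, and *sensitive* attributes (a diagnosis)
must not become attributable to an individual. Syntactic anonymization
transforms the quasi-identifiers until a set of declared privacy models
holds, while giving up as little analytical value as possible.

`p4anon` implements this as **full-domain generalization with record
suppression**: every quasi-identifier has a user-defined generalization
hierarchy (age 34 → "30-34" → "30-39" → "\*"), and a *generalization
scheme* assigns one hierarchy level per attribute. Records sharing a
generalized quasi-identifier tuple form an *equivalence class*; the
privacy models constrain those classes. The engine searches the lattice
of all schemes for the valid node with the highest data fidelity. On
top of the direct anonymizer sits the four-step partition-parallel
procedure: large inputs are split into partitions that are anonymized
independently and in parallel, then recombined under explicit
correctness controls. The price of parallelism is utility: each
partition is optimized without seeing the rest of the data.

## Privacy models

Eleven class- and dataset-level models are supported; all are pure
functions of class statistics, so verdicts are reproducible by
construction.

| model | level | requirement | boundary |
|---|---|---|---|
| k-anonymity | class | class size ≥ k | inclusive |
| distinct ℓ-diversity | class | ≥ ℓ distinct sensitive values | inclusive |
| entropy ℓ-diversity (Shannon / Grassberger) | class | entropy ≥ ln ℓ | inclusive |
| recursive (c, ℓ)-diversity | class | r₁ < c·(r_ℓ+…+r_m) | strict |
| t-closeness (equal / ordered) | class | EMD(class, reference) ≤ t | inclusive |
| δ-disclosure | class | max |ln(p/q)| < δ | strict |
| β-likeness (basic / enhanced) | class | (p−q)/q ≤ β resp. min(β, −ln q) | inclusive |
| average risk | dataset | #classes / #records ≤ threshold | inclusive |
| sample uniqueness | dataset | singleton records / records ≤ threshold | inclusive |

Boundary conventions follow each model's canonical statement: recursive
(c, ℓ)-diversity and δ-disclosure are strict, everything else is
inclusive. Inclusive comparisons carry a numerical guard of `1e-9` so
that a boundary case such as an earth-mover's distance of exactly `t`
is not rejected through floating-point round-off; the two strict
comparisons carry no guard (their statistics are ratios of integer
counts, so exact ties are meaningful). Entropies and δ-disclosure use
natural logarithms; the δ-disclosure base is a constructor argument for
installations that state δ in bits.

The Grassberger entropy estimator is the bias-corrected form
`ln n − (1/n) Σ nᵢ G(nᵢ)` with
`G(x) = ψ(x) + ((−1)ˣ/2)·(ψ((x+1)/2) − ψ(x/2))`. Because correction
variants differ between sources, the estimator is isolated in
`grassberger_entropy()` and `entropy_l_diversity(estimator_fn =)`
accepts a drop-in replacement.

For ordered-distance t-closeness a total order over the sensitive
values is required. When no explicit `order` is configured, the
codepoint-sorted support of the reference distribution is used — the
only ordering derivable without extra metadata, and deterministic.

### Monotonicity

A model is *monotonic* when merging equivalence classes that satisfy it
always yields a satisfying class. This is what decides whether merged
partitions need re-checking. The registry:

* monotonic: k-anonymity, distinct ℓ-diversity, Shannon entropy
  ℓ-diversity, recursive (c, ℓ)-diversity, average risk, sample
  uniqueness;
* non-monotonic: t-closeness (both variants), δ-disclosure, β-likeness
  (both), Grassberger entropy ℓ-diversity.

t-closeness is the canonical non-monotonic case. The
reference-distribution models (δ-disclosure, β-likeness) are flagged
non-monotonic *conservatively*: during partition-parallel runs each
partition is checked against its own local distribution, which differs
from the global one, so per-partition verdicts do not transfer to the
merged dataset. Grassberger is conservative because the estimator's
behaviour under class merging is not established. A conservative flag
only adds compliance checking; it never weakens the guarantee. The
registry is property-tested by merging random passing classes.

## Data fidelity

Utility is *domain coverage*: a cell generalized to a value covering
`c` of the `D` leaves of its hierarchy scores `1 − (c−1)/(D−1)`
(1 for an untouched leaf, 0 for the all-covering `"*"`; single-leaf
domains score 1). Record fidelity is the mean over quasi-identifier
cells, suppressed records score 0, and dataset fidelity is the mean
over records. The verbal definition of coverage-based fidelity admits
several normalizations; this one is pinned by tests and kept in a
single function so an alternative (say `c/D`) can be substituted
deliberately. The same metric is both the search objective and the
reported utility — there is no separate optimization metric.

Because record fidelities average, the record-weighted mean of
per-partition fidelities equals the fidelity of the concatenated
output (asserted to `1e-12` at finalization). Fidelity is
anti-monotone under scheme coarsening, which the optimizer exploits
only implicitly; suppression can make a *coarser* node score higher,
so no fidelity-based pruning is done.

## The lattice search

`search_optimal()` enumerates the full lattice (`Π(Lₐ+1)` nodes,
guarded by `lattice_node_cap`, default 10⁶) in the deterministic order
(sum of levels, then lexicographic). At each node, classes failing any
class-level model are marked suppressed; the node is valid when the
suppressed fraction is within `suppression_limit` and the
dataset-level models hold on the surviving classes. Among valid nodes
the highest fidelity wins; ties go to the smaller level sum, then the
lexicographically smaller vector — realized by the traversal order, so
the search is reproducible bit for bit. Exhaustive enumeration is
deliberate: at the intended desk scale it is verifiable against a
brute-force oracle, and an optional monotonicity-based pruning
(`prune = TRUE`) skips privacy re-checks for nodes dominated by an
already-valid suppression-free node without ever changing the chosen
node (tested by running both).

`suppression_limit` defaults to 1: suppression is always permitted and
penalized only through fidelity, which keeps every configuration
feasible and lets the metric arbitrate between suppressing outliers
and generalizing everyone. If no node is valid under a stricter limit,
the top node with forced suppression is used when the limit allows it;
otherwise the run aborts with an explicit infeasibility error rather
than silently degrading.

Local transformation (`local_recoding()`) is iterative
re-anonymization: iteration 1 is the global search; records in passing
classes are frozen at that node's generalization, and the suppressed
residual is re-anonymized in the next iteration, typically at a
coarser scheme. After the last iteration (default 10) the residual is
fully suppressed. Since iteration 1 equals the global result and later
iterations only recover fidelity from records that would otherwise be
suppressed, local fidelity is never below global fidelity on the same
input. The iteration scheme is this package's own construction — the
simplest mechanism that realizes "different transformations in
different parts of the data" — and is declared as such.

## The four-step parallel procedure

1. **Partition and anonymize.** Records are stably sorted by their
   quasi-identifier tuple (configured attribute order, codepoint
   comparison) and cut into `P` contiguous chunks differing by at most
   one record. Each partition is anonymized independently with the
   same settings. Ties at partition boundaries may split records with
   identical tuples across partitions; correctness is preserved by the
   later steps, so no boundary adjustment is made.
2. **Harmonize (global mode).** The per-partition schemes are combined
   per attribute — mean rounded half-up (default), minimum, or lower
   median — and partitions not already at the harmonized scheme are
   re-generalized at exactly that scheme. Classes that now fail a
   class-level model are suppressed *regardless of the suppression
   limit*: once the scheme is fixed, suppression is the only remaining
   lever and privacy is not negotiable. Half-up rounding and the lower
   median keep the harmonized level integral and within the
   per-attribute range of the inputs.
3. **Compliance check.** Needed only when a non-monotonic model is
   configured. The non-suppressed records of all partitions are pooled
   and grouped by generalized tuple, and *every* pooled class is
   evaluated against every non-monotonic class-level model using the
   global reference distribution; failing classes are suppressed.
   Checking all pooled classes (not only those spanning partitions) is
   required here because per-partition verdicts for
   reference-dependent models were taken against partition-local
   distributions.
4. **Finalize.** Partitions are concatenated in sorted order (the
   carried `.row_id` restores input order on demand). Monotonic
   class-level models are defensively re-verified — a violation is an
   internal error, never a silent pass. Dataset-level models are
   re-checked: compliance suppression removes whole classes and can
   push the class-count ratio of the remainder above an average-risk
   threshold, so a violation here is repaired by suppressing the
   smallest surviving classes (ties to the lexicographically first
   key) until the models hold. Pooled fidelity is cross-checked
   against the whole-output computation.

### Reference distributions

The package must decide which distribution the reference-dependent
models see at each stage. The choice made: per-partition anonymization
uses the partition-local sensitive distribution (that is what
*independent* anonymization means, and it is exactly why those models
are non-monotonic across partitions); compliance checking and the
final verification use the global input distribution, computed once up
front. This makes the end-to-end guarantee well-defined: *the merged
output satisfies every configured model under the global reference*,
which an independently implemented checker (`check_privacy()`, a
separate code path sharing nothing with the engine) verifies in the
test suite across randomized configurations covering all model kinds,
partition counts 1–8, and both transformation modes.

### Determinism

The anonymization engine draws no random numbers; all iteration orders
are canonical (codepoint-sorted keys, fixed lattice order), and
partition results are collected by index. Outputs are therefore
identical for any worker count and across repeated runs, which the
suite asserts. Randomness is confined to the synthetic-data module and
always flows through an explicit seed.

## Suppression encoding and degenerate inputs

A suppressed record carries `"*"` in every quasi-identifier cell —
also the conventional top of a hierarchy — and keeps its sensitive and
insensitive cells. All consumers (classing, fidelity, the checker)
treat all-`"*"` rows as suppressed and exclude them from risk
computations; a record *generalized* to an all-`"*"` tuple is
indistinguishable from a suppressed one, which is harmless because
both receive fidelity 0 and identical checking. Attributes with role
`identifier` are unconditionally replaced by `"*"`. Empty strings are
ordinary values and must appear in hierarchies; nothing is imputed.
Empty partitions (only possible when `P > n`) contribute nothing and
are skipped during harmonization. Single-leaf hierarchies have
fidelity 1 at every level.

## The synthetic-data generators

`generate_dataset()` emulates the shape of demographic survey
microdata: independent categorical quasi-identifiers with Zipf-like
marginals (`skew = 0` is uniform), a sensitive attribute with
controllable imbalance, and balanced interval hierarchies from
`generate_hierarchy()`. `plant_m` plants an exact equivalence-class
structure for worked examples. `extrapolate_dataset()` is a documented
stand-in for record-level extrapolation — seeded resampling with
replacement, adequate for size-scaling studies, not for distributional
realism — and sits behind one interface so a faithful scheme can
replace it. What the generators do *not* emulate: correlations between
quasi-identifiers, attribute-dependent missingness, longitudinal
structure, and realistic marginal shapes. Passing tests therefore
demonstrate the engine's correctness contracts on controllably
structured data, not utility figures transferable to any particular
real dataset.

`generate_scenario()` drives the randomized end-to-end suite: model
kinds cycled so all eleven occur, partition counts from {1, 2, 4, 8},
both modes, record counts drawn log-uniformly from 10²–10⁴ (the
package's chosen desk-scale study size; the parallelism-trend check
uses twenty datasets of 5×10⁴ records at P = 1 versus P = 16).

## Known limitations

* Exhaustive lattice search is intended for the moderate-dimensional
  settings where full-domain generalization is used; very many
  quasi-identifiers with deep hierarchies exceed the node cap by
  design rather than silently thrashing.
* k-map-style models with population estimators, δ-presence,
  profitability-based models, hierarchical-distance t-closeness and
  differential privacy are out of scope, as are microaggregation of
  continuous values and on-the-fly hierarchy induction.
* Parallelism is process-level on one machine (`parallel::mclapply`);
  multi-machine or disk-based partitioning is not attempted.
* The dataset-level repair at finalization suppresses smallest classes
  first, which is a greedy (not provably minimal) repair.
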