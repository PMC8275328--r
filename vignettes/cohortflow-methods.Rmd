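---
title: "Methods: longitudinal cohort blocks, flows and variability scores"
author: "cohortflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal cohort blocks, flows and variability scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortflow)
```

## The data model

cohortflow targets cohorts in which every patient contributes an ordered
series of tumor samples (2–4 timepoints is typical for
resection/recurrence studies) plus dated clinical events such as drug
treatments. A `Cohort` holds the patients in input order, a sample table
with integer dates relative to a per-patient reference (the cBioPortal
convention — no calendar parsing), an event table, and a registry of
typed `Feature`s (binary, categorical, ordinal or continuous, at sample,
patient or event level).

A *timepoint* is defined as the ordinal sample index per patient: the
default view aligns every patient's first available sample in timepoint
block 0. This is the only definition that needs no clinical judgement
and is the alignment the view model implies; calendar binning of
sampling dates is deliberately out of scope. Flexible alignment then
operates on top of it: `shiftPatients()` moves whole per-patient sample
sequences by integer block offsets, and `alignToEvent()` places each
matching patient's first on-or-after-event sample into a common
reference block (the maximum such index over matching patients, so all
shifts are forward and no negative block index can arise).

### Event blocks

With `includeEvents = TRUE`, event blocks are interleaved between
timepoint blocks. An event belongs to the interval whose flanking sample
dates enclose its start date, treated as left-open and right-closed
`(prev, cur]` so every event has exactly one home; stop dates do not
affect assignment (cBioPortal permits missing `STOP_DATE`, and such
open-ended events are treated as point events at their start date).
Events dated before a patient's first or after their last sample go to
the event block immediately before/after that patient's occupied range —
materialized as leading/trailing blocks when the range touches the grid
edge — so no event is silently dropped. Event blocks carry only
event-level features (binary predicates on event type and attributes,
e.g. `TREATMENT` with `AGENT = TMZ`), evaluated per patient per
interval; repeating sample-level features inside event blocks would have
no well-defined value there.

## Variability scores

Row scores measure dispersion *within* a timepoint block across
patients; column scores measure change *across* timepoints within a
patient. With $n$ non-missing observations, modal frequency $f_m$ and
$K$ observed categories:

* **ModVR** (Freeman's standardized variation ratio)
  $\mathrm{ModVR} = \dfrac{K\,(n - f_m)}{n\,(K-1)}$, defined as 0 when
  $K = 1$. It is 0 iff the multiset is constant and 1 iff it is exactly
  uniform over $K \ge 2$ categories. $K$ counts categories *observed in
  the scored multiset*, not the declared domain: a domain level that
  never occurs should not change the dispersion of what was observed.
* **Coefficient of unalikeability**
  $u = 1 - \sum_k p_k^2$, the fraction of ordered observation pairs
  (self-pairs included) that differ; bounded by $1 - 1/K$. The
  $n(n-1)$-denominator variant differs by a factor $n/(n-1)$ and is not
  used.
* **Coefficient of variation** $\mathrm{sd}/\bar{x}$ with the $n-1$
  standard deviation. A zero mean yields a missing score with a
  warning; a negative mean returns $|\mathrm{sd}/\bar{x}|$ flagged via
  an attribute, preserving the usual CV < 1 / CV > 1 reading.
* **Variance**: the $n-1$ sample variance.
* **Rate of change** (column score): for categorical series, changed
  transitions over valid adjacent transitions; for continuous series,
  the mean absolute step divided by the cohort-wide observed range
  (0 by convention for a constant feature). Pairs with a missing member
  or spanning a block gap are excluded from numerator and denominator —
  bridging a gap would fabricate a transition that was never observed.

Every score requires at least 2 usable observations and returns missing
otherwise (never 0: "no evidence of variability" must stay
distinguishable from "observed constancy"). Per-block or per-patient
scores are aggregated by a user-chosen minimum, maximum or mean,
ignoring missing entries; the same user-chosen aggregation is applied
when collapsing per-patient column scores across patients, since no
separate rule is specified anywhere and one knob is easier to reason
about than two. Ranking (`rankFeatures()`) is descending — more
variable is rank 1 — for all score families, with ties sharing the
minimum rank and unscorable features placed after all scored ones.

## Feature transforms

All transforms are deterministic, operate through a single dispatcher
and append exactly one record to the cohort's operation log, so
`replayOpLog()` rebuilds identical feature state from a raw cohort; this
log replaces interactive undo/redo in a scripted setting and is embedded
in every exported figure's metadata sidecar.

Choices where more than one convention exists:

* **Binning**: a value equal to a threshold goes to the upper bin
  (`v >= edge`), matching the "<150" / "≥150" reading of a mutation-count
  cut at 150.
* **Log transform**: base 10 by default (configurable), optional
  pseudocount; a nonpositive shifted value is an error listing the
  offending sample ids rather than a silent drop.
* **Boolean combination**: fold over non-missing inputs; an all-missing
  row stays missing; an `AND` whose observed inputs are all 1 but with a
  missing member is missing (a hidden 0 could flip it), while an
  observed 0 (`AND`) or 1 (`OR`) decides regardless of missing members.
  This maximizes usable data while never asserting what the data cannot
  support.
* **Gene-set aggregation**: arithmetic mean of non-missing inputs.
  Median or max would be defensible; mean is the single implemented
  choice.
* Renames and color-scale changes are metadata edits, still logged.

## Layout

Per-block sorting is a stable re-sort of the *current* order, so
repeated sorting by different keys retains the previous order among
ties; multidimensional sorting applies the keys from least to most
significant and therefore equals a brute-force lexicographic sort with
the prior order as final tiebreaker (property-tested against an
independent oracle). Values sort by domain order (ordinal/categorical)
or numerically; missing values sort after values and gaps last, under
both directions.

Grouping partitions a block's present patients by a categorical,
ordinal or binary primary feature — continuous features must be binned
first, and the error says so. Group order follows the feature's domain
order (not group size) so that the same group appears in the same
position in every block; patients with a missing primary value form an
explicit `"(missing)"` group rendered last, conserving patients.
Nested summaries use exact counts for categorical features and a
five-number summary with linear-interpolation quartiles
(`quantile type 7`) for continuous ones — chosen so summaries are
bit-reproducible across runs and platforms.

Flows between adjacent blocks connect the timepoint blocks plus any
*grouped* event blocks; an ungrouped event block is transparent, so
flows connect the flanking timepoint blocks directly. Grouped–grouped
pairs produce counted group-to-group flows over patients present on
both sides (entries/exits are reported separately); the conservation
property — row/column sums equal group sizes restricted to shared
patients — is enforced by construction and property-tested. Band order
within a group follows the opposite end's group order; no
crossing-minimization heuristic is applied.

## Synthetic cohorts

`generateSyntheticCohort()` is first-class, tested code: it is the
package's offline stand-in for a recurrence-sampled glioma cohort and
the parameter-recovery surface for the scores. Defaults, chosen once:

* 23 patients with 2/3/4 timepoints weighted 0.5/0.3/0.2 — most
  recurrence cohorts are dominated by two-sample patients; inter-sample
  gaps are uniform on 180–540 days.
* a grade-like categorical feature evolving as a per-patient first-order
  Markov chain that switches to a *different* category with probability
  `p` (default 0.3), so the expected categorical rate of change equals
  `p` exactly;
* a mutation-count-like random walk (baseline mean 60, sd 20, drift +5
  per step, step noise sd 15, floored at 0) **capped below the
  hypermutation threshold of 150** unless the planted effect fires —
  the cap makes "value in the high bin" a sound identifier of the
  planted effect, which is what the end-to-end checks need;
* one treatment event (`TREATMENT`/`AGENT=TMZ`) per patient with
  probability 0.5, placed strictly inside a random inter-timepoint
  interval; with probability `q` (default 0.7) the following timepoint's
  mutation count is drawn above the threshold (1.3–4× threshold);
* binary mutation features for MLH1/MSH6/MSH3 at 5% background and 90%
  in affected samples, mimicking mismatch-repair co-mutation.

All randomness flows from the single config seed and the global RNG
state is restored afterwards. What the generator does *not* emulate:
correlated clinical covariates, informative censoring of follow-up,
measurement error in mutation counts, or per-patient trends in switch
probability. Passing tests therefore demonstrate correctness of the
computations, not robustness to every failure mode of real cohort data.

## Rendering

Both views are laid out as a scene graph and serialized to SVG with
fixed two-decimal number formatting, so identical inputs give
byte-identical SVG; this determinism is the contract the tests assert.
PNG/PDF export re-draws the same scene on a `grDevices` device (device
bytes may embed library versions and are not asserted byte-identical).
Gap cells (no sample) draw as light hatched rectangles, missing
measurements as neutral grey — two visually distinct glyphs for two
different facts. Connection curvature uses cubic Béziers with control
points at the vertical midpoint; palettes are fixed lists assigned in
domain order so colors reproduce run to run. Continuous nested
summaries default to a boxplot glyph, with a gradient alternative
selectable in `renderSpec()`.

## Problem sizes used by the checks

The shipped checks use sizes chosen to make each property decisive yet
quick: 1,000 random vectors of up to 50 observations for the
unalikeability pair-counting oracle; 500 random instances (≤ 30
patients, ≤ 4 keys) for the lexicographic sorting oracle; 200 random
cohorts for flow conservation; balanced 1,000-patient constructions for
the orthogonal within/across variability patterns; and 200 patients ×
3 transitions for Markov switch-probability recovery at
p ∈ {0, 0.25, 0.5} (within three binomial standard errors).

## Known limitations

* The cBioPortal REST client covers clinical, timeline and mutation
  endpoints sufficient for cohort assembly; CNA/expression profile
  download is limited to what the generic clinical-data endpoints
  expose. Responses are cached on disk so a fetched study can be
  re-analyzed offline.
* Grid reshaping (shifting/aligning) resets per-block sort and group
  state; alignment is part of cohort preparation, styling comes after.
* MAF handling is presence/absence per gene and sample; variant-class
  filtering is out of scope.
* No crossing minimization or interactive layout; the package renders
  the state it is given.
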