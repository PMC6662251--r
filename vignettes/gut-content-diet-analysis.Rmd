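---
title: "Gut-content diet analysis: indices, overlap and feeding strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gut-content diet analysis: indices, overlap and feeding strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutdiet)
```

## The problem

Sympatric benthivorous fishes often eat from the same pool of
macroinvertebrate prey, and whether they partition that food resource — and
whether the partitioning shifts with season — is read off a small set of
classical gut-content statistics. `gutdiet` implements that toolkit as a
tested pipeline: specimen filtering, the prey-importance triplet, Levins'
niche breadth, Schoener's pairwise overlap, and the modified Costello
(Amundsen) feeding-strategy diagram. The package grew around a two-season
study of four sympatric gudgeon species (Gobioninae) in the upper Yangtze
River, whose published summary tables ship as fixtures
(`gudgeon_specimens()`, `gudgeon_diet_composition()`); the individual-level
records behind those tables were never deposited, which shapes several
design choices below.

## The statistics

For one group (a species in a season), with $N$ the number of fish whose
gut holds any content, $N_i$ the number holding prey $i$, $S_i$ the weight
of prey $i$, $S_t$ the total content weight, and $St_i$ the total content
weight of just those guts containing prey $i$:

$$F_i = 100\,\frac{N_i}{N},\qquad
  A_i = 100\,\frac{S_i}{S_t},\qquad
  P_i = 100\,\frac{S_i}{St_i}.$$

$F_i$ is the frequency of occurrence, $A_i$ the relative abundance, and
$P_i$ the prey-specific abundance — the share prey $i$ takes of the diets
of the fish that actually eat it, so $P_i \ge A_i$ always, with equality
exactly when every non-empty gut holds prey $i$. Empty guts stay in
specimen summaries but are excluded from $N$.

Diet similarity between two groups with percent-by-weight proportion
vectors $p$ and $q$ uses Schoener's index,

$$D = 100 - \tfrac12 \sum_i |p_i - q_i| \;=\; \sum_i \min(p_i, q_i),$$

the second form holding when both vectors sum to 100. $D$ runs 0–100 and
overlap above 60 is conventionally called biologically significant (both
the percent scale and the threshold are the field's reporting convention,
even though the index is sometimes described on a 0–1 scale; the package
standardises on percent). Niche breadth is Levins' index
$B = 1/\sum_i p_i^2$ on the fraction scale: 1 for monophagy, up to $S$
(the number of prey used) for a perfectly uniform diet.

The feeding-strategy diagram plots $P_i$ (y) against $F_i$ (x) per prey:
dominant prey sit top-right, rare prey bottom-left, prey in the upper-left
(eaten heavily by few individuals) indicate a high between-phenotype
component (BPC) of niche width, and lower-right prey a high
within-phenotype component (WPC). A group with any prey in the upper half
is feeding as a specialist; all prey in the lower half marks a generalist.

## Specimen handling

`exclusion_policy()` bundles three published filtering rules:
unidentifiable material is weighed but never analysed; probable parasites
(cestodes) are not prey; and age-0 juveniles are excluded by species-wise
minimum standard lengths — 96, 139, 79 and 114 mm for the four gudgeons in
`default_exclusion_policy()`. "Bigger than" is implemented as a strict
inequality, the literal reading; both thresholds and strictness semantics
are configurable by supplying a different policy. A fish whose only
contents were excluded categories is kept as a specimen (it was caught and
measured) but becomes an empty gut, carried as a marker row with a missing
prey category and zero weight; this is also how the long delimited format
represents naturally empty guts, so a fish never silently disappears from
specimen accounting. Filtering is idempotent and never alters surviving
rows.

## Numerical choices

* **Weight basis.** Proportions for $D$ and $B$ are computed by weight (the
  $A_i$ basis), matching the index definitions used in the study this
  package mirrors; counts are carried through the record format but unused
  by default.
* **Renormalisation.** Published $A_i$ columns rounded to 2 decimals sum to
  99.99–100.01; `diet_proportions()` rescales to exactly 100 by default so
  the two algebraic forms of $D$ coincide, with `renormalize = FALSE`
  available for auditing printed columns exactly as they stand.
* **Alignment.** Two groups are compared over the union of their prey
  categories, absent prey contributing 0.
* **Rounding.** Report writers round half-up at 2 decimals, the convention
  of printed diet tables; base R's round-half-to-even would disagree with
  print on exact halves. Full precision is kept internally and available
  with `digits = NA`.
* **Ties and degenerate input.** Diagram points exactly on a threshold go
  to the upper/dominant side, so classification is deterministic. A group
  with no non-empty gut raises an error rather than returning NaN; a
  single-fish group reports a standard error of 0 with a warning.
* **Quadrant thresholds.** The diagram's interpretation is qualitative and
  no numeric boundaries are canonical, so `classify_points()` defaults to
  the plot midpoints (50, 50), configurable; narrative descriptions of
  "rare" prey eaten by under 20% of individuals motivate an optional lower
  F threshold, which users can set directly. The continuous importance
  ranking along the main diagonal is the coordinate mean $(F_i + P_i)/2$;
  a distance-from-origin alternative gives the same ordering up to a
  factor on this diagonal and was not worth a second code path.
* **Group strategy label.** The classifier emits the binary
  specialized/generalized label (any point at or above the y threshold
  versus none); raising the threshold can only move a group from
  specialized towards generalized, a monotonicity the tests assert.

## The synthetic generator

Because the study's raw specimen records are unavailable, the package
ships a generative model rather than a static dataset. A
`species_profile()` draws each fish's gut in two stages: every prey
category is present independently with an occupancy probability $f_i$, and
present prey receive log-normal conditional weights parameterised by mean
and coefficient of variation. The log-normal gives strictly positive,
right-skewed weights — milligram insect larvae alongside occasional
gram-scale crabs — which matches contents weighed to 0.0001 g. Population
heterogeneity enters only through phenotype mixtures (sub-groups with
different occupancy vectors), the simplest structure that realises both
WPC and BPC regimes; within a phenotype, presences are independent
Bernoulli draws. Empty guts arise naturally when every draw fails rather
than through a separate parameter. Absolute weight scales are arbitrary —
only proportions are identified by the published tables — so profile
weights are in nominal grams.

`make_archetype()` encodes three canonical regimes (specialist,
generalist, and a two-phenotype mixture); `gudgeon_study_design()` wires
eight groups with the published sample sizes (260, 226, 65, 96, 105, 50,
61, 73 — 936 fish) and size models, using the published length means,
dispersions and ranges as a truncated-normal model. Its diet profiles
follow the narrative seasonal regimes (high shared mussel use in spring;
two species diversifying and two tightening in autumn), **not** fitted
parameters: recovering the true generative parameters from the printed
percentages is under-determined, and the design deliberately makes no such
claim.

The oracle for recovery tests, `expected_indices()`, uses the closed form
$F_i = 100\,\Pr(\text{prey } i)/\Pr(\text{non-empty})$ under the mixture
(a present prey implies a non-empty gut), and batched Monte-Carlo for the
abundance expectations, which are ratios of correlated sums with no
tractable closed form.

### What passing tests do and do not show

The generator emulates occupancy, conditional weight, phenotype structure
and seasonal regime shifts. It does not emulate prey-size selectivity,
within-season temporal trends, spatial structure among sampling sites,
digestion-state biases, or count data. Recovery tests therefore certify
the estimators' algebra and sampling behaviour under the stated model —
they cannot certify that the model captures any particular river.

## Problem sizes and reproducibility

The test suite exercises the estimators at $n = 500$ fish per group (20
random profiles for frequency recovery, with a 19/20 pass criterion at 3
binomial standard errors), 500 random matrices for the $P \ge A$
invariant, and 1,000 random simplex pairs for the equality of the two
overlap forms at $10^{-9}$; these sizes make the Monte-Carlo bands tight
enough to detect systematic errors while keeping the default suite quick.
All simulation entry points take explicit seeds and are bitwise
reproducible; multi-group designs derive independent per-group streams
from one master seed.

## Known limitations

Recomputing pairwise overlap from *printed, 2-dp-rounded* composition
tables reproduces published overlap values only to within the rounding
budget of the inputs; with many shared prey categories the accumulated
discrepancy can exceed a few hundredths and occasionally a full unit,
because the original values were computed from raw weights. The packaged
composition table is therefore an input for recomputation, not a target
the pipeline claims to regenerate exactly. The indices themselves carry
the usual caveats of weight-based diet analysis: they ignore prey counts,
digestion rates and energetic value, and the 60% significance line is a
convention, not a test.
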