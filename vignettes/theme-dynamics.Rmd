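---
title: "Linking reused sequence segments to dynamic elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking reused sequence segments to dynamic elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(themedyn)
```

## The question the package answers

Protein space is full of "themes": sub-domain sequence segments of 35 or
more residues that recur across otherwise unrelated proteins, detected by
profile-sequence similarity alone. Independently, a protein domain's slow
collective motions partition its chain into "dynamic elements" (DEs):
consecutive stretches that move as one rigid-ish part, separated by hinges.
If domains arose by mixing and matching themes, the themes should fit
together not only geometrically but also dynamically — which predicts that
theme boundaries should coincide with DE boundaries far more often than
chance allows. `themedyn` implements the machinery to test that prediction
on any domain: elastic-network modes, DE segmentation, theme-combination
tiling, chance-adjusted mutual information, and a Monte-Carlo null.

## The model and its assumptions

**Gaussian network model.** The domain is reduced to its C-alpha trace.
Residues closer than a cutoff `rc` interact through identical Hookean
springs; the connectivity (Kirchhoff) matrix is the graph Laplacian of this
contact graph, with off-diagonal entries of -1 for contacts and degrees on
the diagonal. Equilibrium fluctuation covariances are proportional to its
pseudo-inverse; the eigenvectors are orthogonal modes of motion, eigenvalues
ascending, and the slowest non-zero modes carry the most collective motions.
We keep the conventional `rc = 10` angstrom, and set the spring-constant
prefactor to 1 because only the *signs* and relative magnitudes of the
eigenvector components are consumed downstream. The contact graph must be
connected (exactly one zero eigenvalue); disconnection is a hard error
because a DE decomposition across components is meaningless.

**Dynamic elements.** Within one mode, the normalized residue-residue
correlation is just the sign product of the eigenvector components: the
chain splits into a positive-sense and a negative-sense part. Projected onto
the sequence, maximal constant-sense runs are *dynamic segments*. Runs
shorter than `min_len = 15` residues are merged into a neighboring longer
run until all runs reach 15; the surviving runs are the DEs. The merge
sentence leaves order ambiguous, so we fix it: repeatedly take the shortest
run below threshold (ties: most N-terminal), merge it into its longer
neighbor (boundary runs have one neighbor; interior ties prefer the
preceding neighbor), re-coalesce equal-sense neighbors, repeat. Any fixed
order is defensible; this one is stated so results are bit-reproducible,
and an exhaustive comparison against a residue-level re-implementation over
all short run patterns guards the determinization. A mode with no run of 15
residues at all has no DE decomposition and is reported N/A, never zero.
Analysis is restricted to the seven slowest modes, where collective motion
dominates and short fragments are still rare.

**Theme combinations.** Themes overlap each other, while DEs tile the
domain, so the two cannot be compared directly. We therefore enumerate
*combinations*: orderings of themes, sorted by start, in which consecutive
themes overlap by at most `max_overlap` residues or leave a gap of at most
`max_gap`, ends strictly increase (a contained theme adds no coverage), and
the terminal gaps also respect `max_gap`. The three presets of record are
(3, 8), (5, 10) and (5, 15). Enumeration is exhaustive depth-first — the
goal is all combinations, not a sample — with a capped uniform-sampling
fallback (default cap 100,000, logged when hit). To compare a combination
with a DE partition it is "partitionized": overlaps go to the N-terminal
theme, interior gap residues to the nearer flanking theme (ties to the
preceding one), and terminal residues to the first/last theme. Nothing
external fixes these two conventions; both are package decisions, localized
in `combination_partition()` so sensitivity checks are easy.

**Scoring.** For a DE partition D (k clusters) and a theme partition T
(l clusters) over the same n residues we compute natural-log mutual
information from the k-by-l contingency table. Raw MI has no significance
scale, so two chance-adjusted variants are used, both under the
fixed-marginal permutation null in which cluster sizes are held fixed and
the pairing is random (each cell count is then hypergeometric):

* `AMI = (MI - EMI) / (max(H_D, H_T) - EMI)` — 1 for identical partitions,
  0 at chance. The max-entropy normalizer matches the published code family
  for this statistic; other normalizers are deliberately not exposed.
* `SMI = (MI - EMI) / sd(MI)` — the number of null standard deviations
  above chance; undefined (NA) when the null variance is zero.

`EMI` is the exact hypergeometric expectation. The exact null variance is
computed from the second moment by splitting cell pairs into same-cell,
same-row, same-column and disjoint-cell terms; the two-cells-in-a-row law is
multivariate hypergeometric, and the disjoint-cell law uses the exact
conditional chain n_ij, then n_iq given n_ij, then n_pq given n_iq (given a
row's composition, the remaining labels are exchangeable). All mass
functions are evaluated through `stats::dhyper` in log space. Because
transcriptions of these formulas are error-prone, the package treats a
direct permutation simulation as the arbiter: tests draw 200,000 tables
from the null (vectorized nested-hypergeometric sampler) and require the
analytic EMI and sd(MI) to sit within three Monte-Carlo standard errors,
with the SE of the sd taken from the fourth moment since the null MI is
skewed.

**Per-domain reporting.** For each mode and threshold preset we report the
mean, minimum and maximum AMI and SMI over all combinations. N/A modes stay
N/A and are excluded from any averaging.

**Monte-Carlo p-values.** AMI/SMI already adjust for chance pairing, but a
second, independent axis of significance asks: could *randomly placed*
segments do as well as the real themes? Per domain, 1000 random sets of 30
segments with uniform lengths in 30-175 residues (the dataset-wide theme
statistics) are drawn; a set is valid only if at least one combination
covers the domain (checked by graph reachability without enumerating), and
invalid sets are rejection-sampled with the acceptance rate logged. For
each mode, `x` is the maximum raw MI over real-theme combinations and `y_s`
the same maximum for random set `s`. Two p-values are reported:
`p_parametric = 1 - T_cdf((x - mean y)/sd y; df = S - 1)`, standardizing
against the null sample in the spirit of the original tooling's CDF call
(whose degrees of freedom are not documented — our df = S - 1 is a stated
choice), and the assumption-free add-one estimator
`p_empirical = (1 + #{y_s >= x})/(S + 1)`, which is the primary criterion.
P-values are raw, per mode; no multiple-testing correction is applied,
matching the reporting convention of the field.

## The synthetic-data generator

Real structure downloads are deliberately not required anywhere in the test
suite. `synth_domain()` builds connected, compact C-alpha chains with
consecutive spacing 3.8 ± 0.1 angstrom:

* `helix_bundle` — ideal alpha-helical segments (rise 1.5 angstrom/residue,
  100 degrees/residue, radius 2.3 angstrom; seeded lengths of 13-23
  residues) packed side by side with alternating direction and joined by
  equal-chord arc loops. This is the default architecture: it yields the
  multi-element slow modes typical of folded domains.
* `collapsed_walk` — a self-avoiding 3.8-angstrom-step walk with centroid
  bias and 4.0 angstrom minimum separation; globular but irregular.
* `straight_chain` — a degenerate control with a closed-form contact graph.

`plant_themes()` is the positive control: themes laid exactly on the DE
boundaries of a chosen mode, so at zero boundary jitter the full-coverage
combination is *identical* to the DE partition and AMI is exactly 1;
increasing Gaussian jitter degrades the correspondence monotonically in
expectation. `random_themes()` is the negative control, the same sampler as
the p-value null. Default sizes are chosen once as the study conditions: a
mid-size domain of 250 residues, 30 themes of 30-175 residues.

What the generator does *not* emulate: real side-chain packing, secondary
structure other than helices, beta sheets' long-range contact order, or
evolutionary correlation between sequence and structure. Passing controls
therefore demonstrate that the pipeline's statistics behave correctly
(exact positives detected, nulls calibrated), not that real proteins show
the theme-DE correspondence — that claim needs real structures and real
theme annotations, which `read_domain()` and `read_themes()` accept.

## Numerical choices and degenerate inputs

* Zero-eigenvalue tolerance: `1e-8 * max(lambda)`; zero-component tolerance
  for eigenvector nodes: `1e-8` on unit-normalized vectors. Node components
  inherit the preceding residue's sense (a leading node takes the following
  sense); hinge placement at an exact node is thereby deterministic.
* Near-degenerate eigenvalues (gap below 1e-6) are flagged with a message:
  sense vectors are then basis-dependent and the affected modes should be
  interpreted with care. Modes are taken in solver order.
* The overall sign of an eigenvector is arbitrary; every downstream
  quantity is invariant under the flip (tested).
* Negative analytic variances beyond -1e-10 abort; tiny negatives from
  floating cancellation clamp to zero. `0 ln 0 = 0` throughout.
* Duplicate theme rows are dropped with a warning; out-of-range intervals
  are errors naming the row.
* Single-cluster partitions give MI = EMI = 0, AMI = 0 by convention
  (or 1 when both partitions are the trivial one) and SMI = NA.

## Problem sizes used by the tests and acceptance run

Chosen to exercise every code path on one CPU in minutes, and stated here
as the package's own choices: positive and negative controls on 200-residue
bundles — beyond the reach of a single 175-residue segment, so the max-MI
statistic has no mass point; below that size, sets whose only full cover is
one segment produce exact ties at MI = 0 and distort both controls. The
positive control runs 100 replicates with 60 null sets each (the add-one
floor 1/61 is well below the 0.05 call); the negative control checks
uniformity of the empirical p-value over 60 domains with a
Kolmogorov-Smirnov test at alpha 0.01; EMI/sd(MI) validated on 50 random
30-residue tables against 200,000 permutation draws; enumeration validated
against subset brute force on 100 instances of up to 15 themes. The
acceptance script runs the full pipeline at the default study conditions
(250-residue bundle, 1000 null sets).

## Known limitations

* SMI's exact variance costs O(k^2 l^2) hypergeometric sums per
  combination; for very fragmented partitions on long domains this is the
  slowest step (skippable via `exact_var = FALSE` when only MI/AMI are
  needed, e.g. in the p-value null).
* The Student-t form of the p-value inherits its distributional assumption
  from the original tooling; the empirical p-value is the one to trust, and
  the two are reported side by side.
* Anisotropic network models, B-factor comparisons, and spring-constant
  variants are out of scope, as are theme discovery and dataset curation —
  themes are inputs.

## A worked example

```{r example, eval = FALSE}
library(themedyn)

dom <- synth_domain(n = 250, architecture = "helix_bundle", seed = 42)
modes <- gnm_modes(dom, rc = 10)
elements <- dynamic_elements(modes, 1:7, min_len = 15)

themes <- plant_themes(elements, target_mode = 7)
combos <- enumerate_combinations(themes, nrow(dom), max_overlap = 3, max_gap = 8)
parts <- combination_partitions(combos, themes, nrow(dom))
scores <- score_combinations(de_partitions(elements), parts)
mode_theme_summary(scores)

plot_de_tracks(elements, themes)
```
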