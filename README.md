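# themedyn

Do the evolutionary building blocks of protein domains move as units?

Protein space reuses sub-domain segments — "themes" of ≥ 35 residues that
recur across unrelated proteins, found by sequence-profile similarity
alone. Independently, a domain's slow collective motions split its chain
into *dynamic elements* (DEs): contiguous stretches that fluctuate in the
same sense within one normal mode, separated by hinges. If domains arose by
mixing and matching themes, theme boundaries should line up with DE
boundaries more often than chance allows. `themedyn` implements the full
pipeline to quantify that correspondence for one domain, for researchers in
structural bioinformatics and protein evolution.

## What it computes

Given a Cα trace and a theme annotation table (domain-local coordinates):

1. **Gaussian network model.** Kirchhoff (connectivity) matrix
   Γ<sub>ij</sub> = −1 for Cα pairs within r<sub>c</sub> = 10 Å, diagonal =
   contact degree; eigendecomposition Γ = U Λ Uᵀ gives n − 1 modes, slowest
   first. Within mode *k* the normalized residue correlation is
   sign([u<sub>k</sub>]<sub>i</sub>[u<sub>k</sub>]<sub>j</sub>), so each
   mode splits the chain into two opposite-sense parts.
2. **Dynamic elements.** Maximal constant-sense runs (dynamic segments) are
   smoothed: runs < 15 residues merge into a longer neighbor until all runs
   are ≥ 15. Modes with no run ≥ 15 are reported N/A. The seven slowest
   modes are analyzed.
3. **Theme combinations.** All orderings of themes tiling the domain with
   pairwise overlap ≤ *o* and gaps ≤ *g* (presets (3,8), (5,10), (5,15)),
   enumerated exhaustively with a capped sampling fallback, then converted
   to residue partitions.
4. **Chance-adjusted scores.** For each mode × combination, from the k×l
   contingency table: MI (nats), exact expected MI and exact MI variance
   under the fixed-marginal hypergeometric null, and
   - AMI = (MI − EMI) / (max(H<sub>D</sub>, H<sub>T</sub>) − EMI),
   - SMI = (MI − EMI) / sd(MI),
   summarized per mode as mean/min/max over combinations.
5. **Monte-Carlo p-values.** 1000 random sets of 30 segments (lengths
   30–175) that admit a full-coverage combination; per mode, the real
   themes' max MI is compared with the null's max-MI distribution
   (empirical add-one p-value, plus a Student-t standardized form).

A synthetic-domain generator (helix bundles, collapsed self-avoiding walks)
plus planted/random theme generators make the entire pipeline testable with
no downloads, with exact positive controls (planted themes ⇒ AMI = 1) and
calibrated negative controls (random themes ⇒ uniform p-values).

## Worked example

```r
library(themedyn)

dom      <- synth_domain(n = 250, architecture = "helix_bundle", seed = 42)
modes    <- gnm_modes(dom, rc = 10)
elements <- dynamic_elements(modes, 1:7, min_len = 15)

themes <- plant_themes(elements, target_mode = 7)   # positive control
combos <- enumerate_combinations(themes, nrow(dom), max_overlap = 3, max_gap = 8)
parts  <- combination_partitions(combos, themes, nrow(dom))
scores <- score_combinations(de_partitions(elements), parts)
mode_theme_summary(scores)
```

```
# A tibble: 7 × 8
   mode n_combinations mean_ami min_ami max_ami mean_smi min_smi max_smi
  <int>          <int>    <dbl>   <dbl>   <dbl>    <dbl>   <dbl>   <dbl>
1     1              1    0.278   0.278   0.278     68.9    68.9    68.9
2     2              1    0.559   0.559   0.559     95.4    95.4    95.4
3     3              1    0.548   0.548   0.548     74.8    74.8    74.8
4     4              1    0.612   0.612   0.612     76.7    76.7    76.7
5     5              1    0.543   0.543   0.543     64.5    64.5    64.5
6     6              1    0.589   0.589   0.589     72.8    72.8    72.8
7     7              1    1       1       1        116.    116.    116.
```

The themes were planted on the boundaries of mode 7's DEs, and
there AMI is exactly 1: the single full-coverage combination induces the
identical residue partition. The other modes score well below 1 — their
hinges sit elsewhere — while SMI shows that even those partitions are far
from random pairings (tens of standard deviations, because cluster-size
marginals are highly structured). `plot_de_tracks(elements, themes)` draws
the per-mode DE bars with the themes underneath;
`run_domain_analysis(run_config(...), out_dir)` runs everything end to end
and writes TSV tables plus a JSON manifest. For real data, read the
structure with `read_domain("file.pdb", chain = "A", range = c(5, 260))`
and the annotation with `read_themes("themes.tsv", n)`.

`scripts/run_domain.R` wraps the pipeline for shell use.

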