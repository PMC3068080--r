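---
title: "Normalization and seed-based off-target analysis of RNAi screens"
author: "rnaiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalization and seed-based off-target analysis of RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaiscreen)
```

## The problem

Large arrayed siRNA screens read out one phenotype per well and assume that
the phenotype reflects knockdown of the intended gene. In practice a
substantial fraction of library siRNAs also silence unintended mRNAs through
microRNA-like pairing: a "seed" match between positions 2–8 of the loaded
strand and a complementary heptamer in a transcript's 3'UTR. When the assay
readout is steeply dose-sensitive to one or two genes — in the motivating
case, the two TGF-β receptors upstream of a SMAD2 nuclear-translocation
reporter — such off-target silencing can dominate the entire hit list.

`rnaiscreen` packages the complete analysis chain needed to detect and
dissect this situation:

1. **Screen normalization** — per-plate standardization, removal of a
   cell-density artefact by local linear regression, cross-plate
   re-standardization, hit calling at an SD cutoff.
2. **Seed matching** — heptamer/hexamer site scanning of guide and passenger
   strands against annotated transcript regions, with G:U-wobble-tolerant
   matching and the auxiliary pairing features of the miRNA targeting
   literature (t1A anchor, position-9, 3' pairing, position-16).
3. **Enrichment statistics** — per-motif enrichment factors with exact
   tests, rank and positional profiles, conservation-filtered enrichment,
   per-position base-composition ratios, and a transcriptome-wide scan for
   the most off-targeted gene.
4. **Synthetic data** — a seeded generator for libraries, transcripts with
   planted sites, conservation tracks and raw plates, so the whole pipeline
   is testable against known ground truth with no external downloads.

## The normalization model

The raw per-well readout is a nuclear:cytosolic (N:C) intensity ratio. Two
artefacts are modelled:

* **Plate effects** — each plate is standardized to mean 0, SD 1 (sample SD,
  $n-1$; the convention of standard statistical software).
* **Cell-density bias** — N:C ratios vary systematically with the number of
  imaged cells $N$, and imaged counts fall off towards plate edges. For each
  well a local linear bias $\mathrm{nc} \approx A\,N + B$ is estimated by
  weighted least squares over the well's $k$ nearest retained library wells
  on the same plate and subtracted.

Choices the procedure description leaves open, fixed here:

* **Neighbourhood** ($k = 24$, i.e. the 5×5 block minus the well itself away
  from borders): the fit is **leave-one-out** — a well's own observation
  never enters its own bias fit. This matters: if the well itself is
  included, a strong true effect combines its outlying response with its
  count leverage and the robust fit can chase it, absorbing real signal into
  the "bias". With leave-one-out, a well's bias estimate comes only from its
  neighbours, and neighbours discard the outlier through the robust weights.
* **Kernel and robustness**: tricube distance weights, two rounds of
  Tukey-bisquare re-weighting ($c = 4.685$, MAD scale). Degenerate
  neighbourhoods (all counts equal) fall back to $A=0$, $B=$ robustly
  re-weighted local mean, and are flagged.
* **Filtering**: wells imaged with fewer than 400 cells (strict `<`) are
  removed after plate standardization and before the bias fit; removed wells
  never influence any fit. The threshold is configurable.
* **Order**: plate standardization → low-count filter → bias fit/correction
  → global standardization, following the order in which the corrections are
  described.
* **Final standardization**: the source procedure states only that corrected
  values were standardized to σ = 1 across plates; whether the mean is
  re-centred is unstated. This implementation also re-centres to mean 0,
  since hit calling is symmetric around the mean either way.
* **Controls** are excluded from all fitted statistics (plate moments, bias
  observation pools, the final moments) but are corrected and reported.

Hits are called at ±2.5 SD by default (strict decrease/increase at
`z <= -2.5` / `z >= 2.5`). Validated hits with measured receptor knockdowns
are classified by the loose `> 25%` rule into receptor-1-only /
receptor-2-only / both / none, and strict `>= 40%` per-receptor lists are
emitted for sequence analysis (an siRNA strict on both receptors appears in
both lists).

## The seed-matching model

All pairing arithmetic is fixed by one register convention: a site of length
$L$ starting at 0-based region index $i$ pairs strand position $p$ with
target index $i + (L+1) - p$. For a heptamer ($L=7$, positions 2–8) this
means the exact site is the reverse complement of the seed, the **t1 anchor**
is the target base immediately 3' of the site (index $i+7$), position 9
pairs index $i-1$ and position 16 pairs index $i-8$. Features requiring
indices outside the region are `FALSE`.

* **Wobbles**: at most one G:U pair per site (strand G opposite target U or
  strand U opposite target G), restricted to configured (position, base)
  pairs. Two presets are provided, reflecting two signals that disagree on
  which positions matter: `"site"` (U at 2 and 4, G at 3 and 8 — from
  wobble-containing matched sites; the default) and `"composition"` (U at
  2, 4, 5, 7, G at 3 and 6 — from hit-strand base composition). Neither is
  privileged; both are exposed.
* **True hexamers**: a hexamer match "not part of a heptamer match" is
  operationalized per siRNA as: at least one exact hexamer site and no exact
  heptamer site in the region (any heptamer site anywhere contains an
  extending hexamer at its own anchor, so the two phrasings coincide at the
  per-siRNA level used in the analysis).
* **3' pairing** is implemented as two separate features, because the
  analysis uses both definitions: a contiguous 3/4-mer of positions 12–19
  pairing with a register offset of at most 2 nt, and a contiguous 4/5-mer
  of positions 10–19 pairing exactly in register. Bulges inside the paired
  block are not modelled. The position-16 match is always to the in-register
  target base, and is "isolated" when positions 17 and 18 do not also pair.
* **N** never matches anything, including N (conservative site calling).
* **Strand designation** is taken from the library table; no thermodynamic
  re-assignment is attempted.
* Overlapping sites are all reported; "multiple heptamers" counts distinct
  anchors.

## Enrichment statistics

All cohort enrichment is **per siRNA** (an siRNA either carries the motif or
not), matching the "percentage of siRNAs" convention of the source analysis;
site-level counts feed only the positional profiles. The enrichment factor
is $r = (k_\mathrm{hits}/n_\mathrm{hits}) / (k_\mathrm{non}/n_\mathrm{non})$,
reported as `Inf` with a flag when the non-hit frequency is zero. P-values
are two-sided Fisher exact probabilities computed by the minimum-likelihood
rule (the dominant software convention); the adjustment method is
Benjamini–Hochberg by default with Bonferroni available, and the choice is
recorded in output metadata because the original adjustment method is not
recoverable.

Other fixed numerical choices:

* Rank curves use a centred moving mean (default window 500) truncated at
  both ends.
* The 3'UTR hotspot profile smooths per-position site-start counts (default
  window 50), adds a pseudocount of 0.5 to both smoothed counts, converts to
  per-siRNA fractions, and takes the hit/non-hit ratio. The profile is
  per-site; cohort-level enrichment stays per-siRNA (the source figure is
  ambiguous on this point).
* A site is "conserved" when the **mean** conservation score over its bases
  reaches the threshold (default 0.5); an all-bases rule is available. The
  mean-vs-all choice is configurable because unstated in the source.
* The transcriptome scan counts, per transcript, cohort siRNAs with at least
  one exact heptamer site in the 3'UTR (strands guide, passenger, or their
  union), tests each 2×2 table exactly, adjusts, and ranks by adjusted then
  raw p. Default cohorts are the top 200 screen ranks versus ranks
  12,001–17,000, both overridable; on screens smaller than the rank band the
  pipeline falls back to the rear 60% of the ranking.

## The synthetic world

The generator's defaults encode the screen's stated design:

* **Library rules** (guide strand): A/U at positions 1 and 9 and/or G/C at
  position 19; at least three A/U among positions 1–7; all guides unique;
  19-mers with the dTdT overhang never represented in coordinates. The
  passenger strand is the exact reverse complement of the guide; the real
  library's strand-insertion chemistry is represented only by the
  guide/passenger labels.
* **Plates**: 384-well geometry by default; the benchmark presets use
  smaller plates (two 12×16 plates for `"small"`) so the suite stays fast.
  Imaged cell counts are high in the interior (700 ± 25) and drop by 50% in
  a two-well border band — so edge wells fall below the 400-cell filter, as
  in the real screen; the direction of the gradient is a parameter because
  the settling mechanism behind it is narrative, not measured. The raw
  N:C value is `base + A_p N + B_p + effect + noise` with per-plate
  coefficients (default A = −4×10⁻⁴: ratios fall as counts rise, the
  observed direction) and Gaussian well noise (default SD 0.02 against a
  baseline of 1.6).
* **Planted sites** are written as exact reverse complements of the planned
  seeds, with planned wobbles, t1A anchors (forced to A, or away from A so
  the truth table is exact either way), 3'-pairing blocks (guide positions
  12–15 in register) and position-16 matches with non-pairing flanks. The
  background is then rejection-sampled until no unplanned site remains:
  exact guide-strand sites are purged from every transcript, wobble-tolerant
  sites from every transcript that carries planted sites.
* **Effects** map planted z-shifts linearly into N:C units (default 0.05
  per SD); hit siRNAs in the benchmark carry shifts of −5 to −7. Planted
  effect siRNAs are placed on interior wells in a greedy maximin scatter, so
  the low-count filter cannot remove them and no local-regression
  neighbourhood contains several of them — with 16 planted hits among 368
  wells the benchmark is far denser in hits than a real screen (~1%), and
  clustered placement would otherwise let the local bias fit absorb real
  signal.
* **Conservation tracks** are block-constant (0.9 conserved / 0.05
  background) with conserved blocks covering planted sites.

What a green benchmark test does establish: the scanner finds exactly the
planted sites and features (closure, zero false positives on purged
backgrounds), normalization removes the planted bias exactly in noiseless
data and tracks an oracle normalizer under noise, and the enrichment chain
recovers the planted off-target gene and motif directions. What it does not
establish: performance on real image-derived data — real screens have
heavier-tailed noise, spatially structured artefacts beyond a linear count
law, sequence composition bias, and transcript collections with correlated
UTRs. The generator makes no attempt to simulate microscopy or realistic
count distributions beyond the parametric field.

## Interpreting recovery under noise

With noiseless wells the pipeline's z is exactly proportional to the planted
effect (Pearson ≥ 0.99, and exactly 0 for null screens). With well noise the
correlation against the *planted* z is bounded by the irreducible noise
floor, not by normalization quality — at the benchmark's stated noise the
observed value is ≈ 0.96. The acceptance suite therefore also compares the
pipeline against an oracle normalizer that subtracts the true planted bias
before standardizing: under noise the pipeline tracks that oracle at
Pearson ≥ 0.99, which is the part normalization can control.

## Known limitations

* No thermodynamic duplex scoring, target accessibility or secondary
  structure; no bulged or multi-wobble seeds.
* One transcript per gene; no isoform merging.
* The local bias model is linear in cell count; curvature in the density
  artefact would be only locally approximated.
* Counts printed by the original study that depend on its unpublished
  per-siRNA measurements (full well table, per-hit knockdowns and
  sequences) cannot be recomputed offline; the packaged knockdown table is a
  synthetic stand-in constructed from the published marginal counts and is
  labelled as such.
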