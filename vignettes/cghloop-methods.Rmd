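---
title: "CNV discovery from dye-swap loop array CGH: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNV discovery from dye-swap loop array CGH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghloop)
```

## The measurement model

Two-color array CGH co-hybridizes a Cy3-labelled test DNA and a Cy5-labelled
reference DNA to a genome-tiling oligo array. At each probe the expected
log2 intensity ratio is the log copy-number ratio of the two samples:
a heterozygous deletion against a diploid partner sits at
$\log_2(1/2) = -1$, a single-copy duplication at $\log_2(3/2) \approx
+0.58$. Real measurements add three nuisance terms that the pipeline removes
or cancels:

* **dye bias** -- a channel-level offset that does *not* change sign when
  the dyes are swapped;
* **spatial artifact** -- a smooth position-dependent field over the
  physical array grid $(x, y)$;
* **probe noise** -- approximately Gaussian in log2 space.

In a *dye-swap loop design*, every animal is hybridized against two other
animals (its neighbours on a ring), and every pair is run in both dye
orientations. True copy-number signal flips sign on the swap mate; dye
artifacts do not. Two hybridization pairs share at most one animal, so two
concordant aberrations attribute the variant to the single shared animal,
and simultaneously decide gain vs loss: the shared animal is either
relatively up in all supporting pairs (gain) or relatively down (loss).

## Pipeline stages and defaults

| Stage | Method | Key parameters (default) |
|---|---|---|
| Spatial correction | two-pass loess surface over $(x,y)$, subtracted from log2 ratios, centred | `span = 0.3` |
| Normalization | q-spline: monotone cubic (Hyman) spline through paired quantiles of each channel vs the geometric-mean pseudo-reference | `n_quantiles = 100` |
| Segmentation | exact least-squares dynamic programming (penalized optimal partitioning) | `penalty = 2 sigma^2 log n` |
| Candidate filter | retain segments with \|mean\| >= 0.4 and >= 5 consecutive probes | `ratio_threshold = 0.4`, `min_probes = 5` |
| Dye-swap concordance | opposite raw signs + 50% reciprocal overlap; interval = intersection | `min_overlap = 0.5` |
| Loop attribution | >= 2 pairs, exactly one shared animal, consistent direction; interval = union | `min_overlap = 0.5` |
| CNVR merge | single-linkage union of >= 1 bp overlaps, gains and losses separately | -- |
| Enrichment | length- and chromosome-preserving random re-placement, gap-aware | `n_perm = 10000` |

### Notes on individual choices

**Order of spatial correction and normalization.** Spatial correction runs
first (it is an artifact of the scanned image, upstream of any
between-channel distortion), but it is estimated on log2 *ratios* -- the
artifact is visible there directly, and the original platform software
does not document its working scale. Because q-spline
normalization recomputes ratios from channels, the fitted surface is also
divided out of the test channel so the correction survives normalization.

**q-spline.** The monotone map is anchored at paired empirical quantiles of
each channel's log intensity against the geometric-mean pseudo-reference,
interpolated with a Hyman-filtered cubic spline and extended linearly with
the end slopes beyond the anchor range, so the map is monotone everywhere.
Monotonicity guarantees the normalization never reorders intensities; any
smooth monotone channel distortion (including a constant dye bias) is
removed.

**Segmentation.** The segmentation engine minimizes
$\sum_k \mathrm{SS}(\text{segment}_k) + \lambda \cdot K$ exactly by dynamic
programming ($O(n^2)$, compiled), or the optimal $K$-segmentation when a
segment cap is given. Ties in breakpoint placement are broken leftmost for
determinism. The default penalty is the classical changepoint BIC
$\lambda = 2\hat\sigma^2 \log n$, with $\hat\sigma$ the median-absolute
successive difference estimator ($\mathrm{mad}(\Delta x)/\sqrt2$), which is
insensitive to the aberrant segments themselves. A halved penalty
($\hat\sigma^2\log n$) was evaluated and rejected: at probe noise 0.2 it
visibly over-splits true aberrations, and the fragments then fail the 50%
reciprocal-overlap dye-swap matching (loss recall drops from 1.0 to ~0.88
on the reference simulation).

**Reciprocal overlap 0.5.** No boundary-agreement rule is published for the
concordance step; 50% reciprocal overlap is the common structural-variant
convention and is exposed as a parameter. Pair-call intervals take the
conservative intersection of the two mates; per-animal calls take the union
of their supporting pair calls, consistent with the "handle overlaps as a
whole" philosophy used for CNVRs.

**CNVR merging.** Gains and losses are merged independently and never
combined into a mixed class, and bookended-but-disjoint calls are not
merged (overlap means a shared base pair). Merging is idempotent and
order-independent; summary statistics report mean = content/count rounded
to bp and percent of genome to 3 decimals.

**False positive rates.** On male-vs-female arrays every chrX probe carries
dosage signal in a known direction; only *wrong-direction* chrX segments
count as false-positive territory (same-direction excursions are expected
dosage). The reported percent is **truncated** to two decimals rather than
rounded: the canonical worked example (25,694,212 bp over 8 arrays of an
88,516,663 bp chrX = 3.6284%) is printed as 3.62% in the source material,
as is its companion computation (3.21/88.52 Mb = 3.6263% -> 3.62%), so
truncation is demonstrably the printed convention. The full-precision rate
is always carried alongside. Aberrant length is measured on filtered
candidate segments by default; both the self-self FPR stringencies
(single-array and dye-swap-concordant) are reported, and concordance can
only lower the rate.

**Permutation tests.** Each permutation re-places every CNVR independently,
uniformly at random on its own chromosome with length preserved, avoiding
assembly gaps; placements may overlap each other. The empirical p-value
uses the +1 correction, $p = (1 + \#\{T_\text{null} \ge T_\text{obs}\}) /
(1 + N)$, so $p$ is never 0 and "p < 0.001" at 10,000 permutations means at
most 9 exceedances. Two statistics are available: the count of CNVRs
touching any feature (default, matches the field's reporting style) and
total overlap base pairs. The count statistic is integer-valued, so for
small catalogues its p-values are lumpy: valid and conservative, but not
exactly uniform -- the calibration suite therefore applies the strict
Kolmogorov-Smirnov uniformity check to the effectively continuous bp
statistic and a no-anti-conservatism bound to the count statistic.

**Scalar tests.** The exact binomial test uses the minimum-likelihood
two-sided convention (sum the null probabilities of all outcomes no more
likely than observed, with a $1+10^{-7}$ relative tolerance). The Wilcoxon
rank-sum test uses midranks; for combined $n \le 20$ the null is
enumerated over all ${N \choose m}$ assignments of the *observed* midranks
(exact even under ties), otherwise a normal approximation with tie and
continuity corrections is used. Both are checked against brute-force
enumeration in the test suite. For dN/dS by CNV class the summary is the
median of per-gene ratios over genes with $dS > 0$ (robust to $dS \to 0$);
mean and ratio-of-sums are available behind a flag. Genes only partially
inside a CNVR are classed as non-polymorphic.

## What the synthetic generator emulates -- and what it does not

The generator builds a genome model (chromosome lengths, optional assembly
gaps occupying a configurable fraction, default era-realistic 5.8%), tiles
probes at a 301 bp median start-to-start spacing (60-mer oligos, optional
jitter, gaps avoided), arranges animals on a ring with both dye
orientations per pair, plants >= 1 kb CNVs (log-uniform sizes; loss
probability 0.664, the loss share of the reference catalogue: 202 of 304
regions), and emits two channels per probe: a log-normal reference channel
times the copy ratio, a constant dye bias, a smooth random quadratic field
over the grid, and Gaussian log2 noise (default sd 0.2). Sex enters only
through chrX dosage (male = 1 copy); there is no chrY model. Planted CNVs
are globally disjoint by default so that loop attribution is identifiable.

Features of real data *not* emulated: intensity-dependent (curved) dye
bias, probe-sequence effects (GC waves), saturation, replicate probes,
segmental-duplication cross-hybridization, relatedness between animals, and
shared CNVs in loop-adjacent animals. The last is a genuine blind spot of
the design itself: a CNV identical in two ring neighbours cancels in their
mutual hybridization and cannot be attributed. A green end-to-end test
therefore establishes that the pipeline recovers isolated planted variants
under Gaussian noise and removable artifacts -- not that it would match a
wet-lab catalogue.

## Numerical and degenerate-input policy

* All internal coordinates are 0-based half-open; BED I/O keeps that
  dialect, 1-based-closed input can be declared at read time, and every
  written file carries a dialect header comment.
* Probes with missing or non-positive intensities are dropped with a
  message (never imputed); a non-positive intensity reaching the q-spline
  is an error naming the probe.
* A flat (zero-variance) ratio profile skips the loess fit -- there is
  nothing to correct, and a robust loess on exact zeros is degenerate.
* Segmentation ties are leftmost; identical seeds give byte-identical
  pipeline outputs end to end.
* Contradictory attribution directions at one locus drop the locus with a
  warning rather than guessing.
* An empty CNVR set summarises to zero counts and errors in GC comparison
  unless explicitly allowed.

## Known limitations

* The original platform's segmentation internals are unpublished; the DP
  here is *a* least-squares segmentation with a defensible penalty, so
  exact segment boundaries of any real historical catalogue are not
  reproducible (and are not claimed).
* The self-self false-positive rate of real arrays (printed as 0.0085%)
  depends on real noise characteristics and is deliberately not a numeric
  target; only its structural properties (concordant <= single-array; zero
  at zero noise) are asserted.
* Attribution requires exactly one shared animal across supporting pairs;
  loci where >= 3 pairs overlap without a unique common animal are left
  uncalled rather than split heuristically.
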