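# cghloop

Copy-number-variant (CNV) discovery from two-color array comparative
genomic hybridization (array CGH) experiments laid out as a **dye-swap loop
design**, with a complete synthetic-data generator so every stage is
testable without array data.

## Who this is for

Groups analysing tiling oligo CGH arrays (or teaching/benchmarking CNV
callers) who need a transparent, fully tested reference pipeline for the
classic loop-design analysis: per-array artifact removal, segmentation,
dye-swap/loop calling, merging of per-animal calls into copy-number
variable regions (CNVRs), quality control via sex-mismatched and self-self
hybridizations, and permutation tests for association of CNVRs with
genomic features (segmental duplications, assembly gaps, genes, conserved
elements).

## The model in brief

At probe $i$ the measured log ratio of the Cy3 (test) over Cy5 (reference)
channel is

$$
y_i \;=\; \log_2\frac{c^{\text{test}}_i}{c^{\text{ref}}_i}
\;+\; \beta_{\text{dye}} \;+\; f(x_i, y_i) \;+\; \varepsilon_i,
\qquad \varepsilon_i \sim N(0, \sigma^2),
$$

where $c$ are copy numbers (a loss is $\log_2(1/2) = -1$, a gain
$\log_2(3/2) = 0.58$), $\beta_{\text{dye}}$ is dye bias and $f$ a smooth
spatial field over the array grid. The pipeline removes $f$ by loess on
$(x,y)$, removes $\beta_{\text{dye}}$ (and any smooth monotone channel
distortion) by q-spline quantile normalization, segments each chromosome's
profile by **exact least-squares dynamic programming**, and keeps segments
with mean $|\log_2|\ge 0.4$ over $\ge 5$ consecutive probes. A CNV is
called only when (1) both dye-swap mates of a pair show the aberration with
**opposite raw signs** (true signal flips under the swap, dye artifacts do
not) and (2) at least two different pairs sharing **exactly one animal**
agree on that animal's direction -- which simultaneously names the carrier
and decides gain vs loss. Overlapping same-type calls across animals merge
into CNVRs.

## Worked example

Simulate an 8-animal dye-swap loop (16 arrays) over two 0.8 Mb
chromosomes, 4 planted CNVs per animal, probe noise 0.2, then run the full
caller:

```r
library(cghloop)

exp0 <- sim_experiment(n_animals = 8, genome = sim_genome(c(8e5, 8e5), seed = 1),
                       n_per_animal = 4, size_range = c(2500, 20000),
                       noise_sd = 0.2, seed = 11)
res <- call_cnvs(exp0$tables, exp0$design, pipeline_config(seed = 11))
head(res$calls[, 1:6], 4)
#>   animal_id chrom  start    end state n_pairs
#> 1       A01  chr1 447543 457251  loss       2
#> 2       A01  chr1 696589 698794  loss       2
#> 3       A01  chr2  72301  83114  gain       2
#> 4       A01  chr2 687769 693129  gain       2

cnvr_summary(res$cnvrs, genome_length(exp0$genome))
#>  type count mean_size median_size min_size max_size content_bp percent_genome
#>  loss    24      7365        6650     2205    17123     176753         11.047
#>  gain     8     10344        9580     4861    18073      82749          5.172
#>   all    32      8109        7722     2205    18073     259502         16.219

evaluate_calls(res$calls, exp0$truth)[c("recall_loss", "recall_gain")]
#> $recall_loss
#> [1] 1
#> $recall_gain
#> [1] 1
```

Every planted variant is recovered, attributed to the right animal with the
right direction. Each call's `n_pairs >= 2` records the loop evidence; the
summary table is the standard catalogue characterisation (counts, sizes,
genome fraction per gain/loss class).

QC worked example -- the sex-mismatch false-positive rate from 8 arrays of
an 88,516,663 bp chrX with 25,694,212 bp of wrong-direction signal, and the
loss/gain imbalance test for a catalogue of 202 losses among 304 regions:

```r
sex_mismatch_fpr(chrx_length = 88516663, n_arrays = 8, aberrant_bp = 25694212)
#> <cgh_fpr> sex_mismatch: 25694212 / (88516663 x 8) = 3.62%

exact_binomial(202, 304, 0.5)
#> <cgh_test> exact binomial: statistic = 202, p = 1.012e-08 (two.sided)
```

Enrichment of CNVRs in a feature set uses length- and chromosome-preserving
random re-placement (gap-aware, 10,000 permutations by default):

```r
permutation_test(cnvrs, features, genome, n_perm = 10000, seed = 1)
```

A command-line front end for simulate/run/stats/fpr lives at
`inst/cli/cghloop.R`.

## Documentation

The methods vignette (`vignettes/cghloop-methods.Rmd`) describes the
measurement model, every stage's parameters and defaults, what the
synthetic generator does and does not emulate, numerical/degenerate-input
policy, and known limitations. Function-level documentation is in the
roxygen comments in `R/`.
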