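---
title: "Methods: replication-timing profiling, switching-segment detection and fiber analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replication-timing profiling, switching-segment detection and fiber analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rtswitch` implements a genome-wide replication-timing (Repli-seq) analysis
pipeline: from binned early/late S-phase read counts to smoothed timing
profiles, fixed 200-kb segment summaries, statistically controlled calls of
early-to-late (EtoL) and late-to-early (LtoE) switching segments, integration
of those calls with ChIP-seq and expression changes, and a DNA-combing module
for fork speed and inter-origin distances. This vignette explains the models
and the numerical and design choices, in the order data flows through the
package.

## The measurement model

Repli-seq sorts S-phase cells into early and late fractions, enriches newly
replicated (BrdU-substituted) DNA, and sequences each fraction. After
alignment, reads are counted in fixed 5-kb bins. The quantity of interest per
bin is the log2 ratio of early to late read density: positive values replicate
early, negative late. Mammalian genomes organize this signal into Mb-sized
replication domains that alternate along each chromosome arm.

All coordinates in the package are 0-based half-open (`[start, end)`, the BED
convention; bedGraph intervals are read the same way). Bins and 200-kb
segments are fixed-position tilings of each chromosome; the final partial
interval at a chromosome end is kept and flagged rather than dropped, so
coverage accounting stays exact.

## From counts to profiles

1. **Per-million scaling.** Each fraction's counts are scaled by
   `1e6 / total`, removing library-size differences between fractions and
   replicates.
2. **Log2 ratio.** `log2((early + c) / (late + c))` with pseudocount `c = 1`
   per-million unit. The pseudocount keeps zero-count bins finite; since it is
   fixed on the per-million scale, its attenuating effect shrinks as per-bin
   scaled counts grow. Bins with fewer than `min_reads = 10` raw early+late
   reads are masked outright — at that coverage the ratio is noise, and an
   explicit mask is more honest than a shrunk value. Masks propagate through
   every downstream stage.
3. **Smoothing.** Profiles are smoothed by local linear regression with
   tricube weights over a fixed 300-kb genomic window centred on each bin,
   per chromosome. We deliberately fix the *genomic* span rather than a
   global point fraction: with masked bins, a point fraction would let the
   effective genomic window balloon in sparse regions. Degree 1 and tricube
   weights are the common local-regression defaults; no robustness
   iterations are applied. Masked bins are excluded from every fit and stay
   masked; a window with fewer than two usable bins yields a masked value
   (no line is determined by one point); a chromosome with fewer than two
   usable bins is fully masked with a warning. The implementation computes
   the exact per-bin weighted-least-squares solution via rolling kernel
   sums, and the test suite checks it against a brute-force per-bin WLS
   oracle (1e-8) and against `stats::loess` on an unmasked regular grid
   where the two constructions coincide at interior bins.
4. **Segment averaging.** For the statistics, the *unsmoothed* 5-kb ratios
   are averaged into fixed 200-kb segments. Smoothing is a display/profile
   operation: averaging smoothed values into segments would smear a real
   200-kb switch into its neighbours (a 300-kb window reaches 150 kb into
   each flanking segment), inflating the apparent extent of every switching
   region. A segment needs at least `min_valid_fraction = 0.5` of its bins
   unmasked, otherwise it is masked; this mirrors how genome-wide segment
   counts shrink from the nominal tiling to the analyzed subset in real
   data, where mappability gaps mask bins.

## Switching-segment detection

Replication timing changes of interest are subtle, so the test must separate
condition differences from replicate noise. For each segment we compute the
between-group statistic

\[ d_i = | \bar{x}^{B}_i - \bar{x}^{A}_i | \]

the absolute difference of replicate-mean timing between conditions. The
null distribution comes from the replicates themselves: all within-group
pairwise absolute differences \(|x^{g}_{ij} - x^{g}_{ik}|\), pooled across
segments and both groups.

**Calibration.** A within-pair difference has variance \(2\sigma^2\) while
the between-group mean difference has variance
\(\sigma^2 (1/n_A + 1/n_B)\). The pooled pair differences are therefore
scaled by \(\sqrt{(1/n_A + 1/n_B)/2}\) (for 2 vs 2 replicates, \(1/\sqrt2\))
so that the null pool is variance-matched to the statistic. Without this
factor the p-values are conservative by a factor \(\sqrt2\) in scale and
visibly non-uniform under the null; with it, null p-values pass
Kolmogorov–Smirnov uniformity checks at study scale (10,000 segments).
`segment_distances(scale_null = FALSE)` retains the raw pool for
conservative use. Because every segment contributes both its statistic and
its null pairs, segment-to-segment variance differences (e.g. extreme-timing
segments have noisier ratios) enter the statistic and the pooled null as the
same mixture, which keeps the marginal null p-value distribution uniform.

**P-values and FDR.** Empirical p-values use the add-one rule
\(p_i = (1 + \#\{null \ge d_i\}) / (1 + N)\), so no p is ever zero. Q-values
follow Storey's estimator: \(\hat\pi_0 = \#\{p > \lambda\} / ((1-\lambda) m)\)
with fixed \(\lambda = 0.5\) (capped into \([1/m, 1]\)), then the step-up
\(q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j\). The fixed-\(\lambda\)
estimate is simple and reproducible; the spline-smoothed \(\pi_0\) variant is
out of scope. `pi0_method = "bh"` fixes \(\pi_0 = 1\), making the q-values
exactly Benjamini–Hochberg adjusted p-values — used as an oracle route in the
tests. High-confidence switching segments use `q <= 0.01`, lower-confidence
sets `q <= 0.05`.

**Classification.** Zero on the log2(early/late) scale is the early/late
boundary, applied to replicate-averaged means. A significant segment with an
early control mean that moved later is EtoL; late control mean moved earlier
is LtoE. Non-significant segments (and significant same-direction shifts,
e.g. early-to-earlier) keep their endpoint class EtoE or LtoL by the sign of
the control mean. Both switch directions are tested jointly through the one
two-sided statistic; there is no per-direction multiplicity split. Adjacent
same-class segments merge into domains (`merge_to_domains()`), with the
domain q the minimum member q. Overlap between switch sets from different
comparisons is scored by an upper-tail hypergeometric test plus the expected
overlap under independence; the choice of a hypergeometric reference is a
package decision, with the expected count reported alongside so readers are
not hostage to it.

## The synthetic-data generator

Every stage is validated against generated data with known truth; the
generator's defaults define the simulated study conditions:

- **Landscape** (`simulate_rt_landscape()`): domain boundaries from a Poisson
  process with mean domain length 1,500 kb — mid-range for the Mb-sized
  replication domains of mouse ES cells — and per-domain timing drawn from a
  two-component mixture centred at +1.5 and −1.5 (sd 0.5), matching the
  alternating early/late band structure and typical log2 dynamic range of
  ES-cell Repli-seq profiles.
- **Counts** (`simulate_counts()`): a per-replicate latent timing
  `rt + N(0, 0.3)` maps through the logit link `p = 1/(1 + 2^-rt)` to the
  early-read probability, so the simulator's timing lives on the same
  log2(early/late) scale the pipeline estimates and parameter recovery is
  directly assertable. Early/late counts are Poisson at library sizes drawn
  within ±20% of nominal. Replicate noise perturbs the latent timing, not
  the counts: that is the biological replicate variation the within-group
  null must absorb. Default depth is 20 reads/bin/fraction.
- **Switches** (`plant_switches()`): whole 200-kb segments shifted by ∓1.5.
  Only segments with |mean timing| ≥ 0.5 are eligible: a switch that does
  not cross the early/late boundary has no meaningful direction label. The
  returned table records the edits exactly and is recoverable by diffing
  the two truths.
- **Omics** (`simulate_omics()`): per-segment ChIP deltas constructed as
  `r·z + sqrt(1−r²)·noise` against the standardized RT delta, so the
  population correlation is exactly the requested coupling; gene TSSs are
  placed uniformly (length-weighted across chromosomes) and log2 fold
  changes carry the same coupling.
- **Fibers** (`simulate_fibers()`): origins along each molecule from a
  gamma renewal process (shape 10, mean 150 kb — quasi-regular spacing in
  the 40–150+ kb range reported for mammalian cells), all firing at the
  start of the first pulse; forks progress at 1.5 kb/min and converging
  forks stop at their meeting point. DNA replicated in the first/second
  20-min pulse carries the first/second label. Lengths convert to
  micrometers at 2.32 kb/µm and receive N(0, 0.3 µm) measurement jitter.
  λ calibration molecules are N(48.5/2.32, 1) µm, which reproduces a
  ±0.11 kb/µm spread in the calibrated factor. Molecules default to
  1,500 kb (10× the origin spacing): on short fibers, long inter-origin
  gaps are preferentially censored at the ends, and the resulting length
  bias (≈ −σ²/(L−µ)) would dominate recovery at 3× spacing.

What the generator does *not* emulate: mappability and GC bias, copy-number
differences, FACS gate contamination between fractions, asynchronous origin
firing within S phase, and fragmented/undetected fiber labels. Passing the
synthetic checks therefore demonstrates the statistical machinery is correct
and calibrated under the stated noise model — not that real libraries meet
that model.

## DNA-combing analysis

The stretch factor is calibrated as `48.5 kb / mean(λ length)`; its sd
follows by the delta method and its s.e. by `sd/sqrt(n)`. Fork speed is
measured only on second-label tracks bounded by a first-label track on
exactly one side and open DNA on the other: such a fork ran the entire
second pulse, so `speed = length × stretch / pulse_minutes`. Second-label
tracks bounded by first-label on both sides are fused converging forks, and
any track touching a molecule end is censored; both are excluded. Origins
are called at midpoints of first-label tracks flanked by second-label tracks
on both sides (the bidirectional signature under first-then-second
labeling), and inter-origin distances are centre-to-centre within a
molecule. Because the calibrated stretch multiplies every converted length,
its relative s.e. is a *shared* error term: recovery checks propagate it
alongside the per-track sampling s.e. The fiber table carries a
`start_um` column (track position along the molecule) in addition to label
and length, since centre-to-centre distances are not computable from lengths
alone when tracks are separated by unlabeled gaps.

## Integration analyses

ChIP enrichment changes are consumed as a precomputed per-segment table on
the same 200-kb tiling (peak calling and read processing are out of scope).
Expression data enter as a gene table with TSS coordinates; genes map to the
segment containing their TSS — a single deterministic assignment, in
preference to overlap-weighted gene bodies. The module provides Pearson
correlation between per-segment deltas, box-plot five-number summaries per
switch class (quartiles of type 7, 1.5·IQR whiskers, empty classes reported
with n = 0), top 1/5/10% gain/loss segment selections (`ceiling(p·n)`
segments, coordinate-order tie-break for determinism), and a two-sided
Fisher exact test for enrichment of a gene set (e.g. >two-fold upregulated)
in a region class (e.g. LtoE), with a Haldane-corrected odds ratio when a
cell is empty. Fold-change summaries default to the log2 scale for symmetry;
pass linear-scale values if the non-log convention is wanted.

## Numerical choices and degenerate inputs

- Empirical p-values are computed with a sorted null pool and
  `findInterval`, matching the brute-force count exactly, including ties.
- `storey_qvalues()` errors on p outside (0, 1]; q-values are clamped to
  (0, 1] and are invariant to input order.
- All-zero count tracks, empty null pools, empty gene lists, and fewer than
  3 correlation pairs raise immediate errors rather than propagating NaN.
- Bins not covered by any bedGraph interval read as 0 for count tracks and
  as masked (`NA`) for value tracks (`missing =` argument), matching the
  writer's convention of omitting masked bins.
- Every generator takes an integer seed and is fully deterministic given it;
  seeds never leak into the global RNG state (`withr::with_seed`).

## Problem sizes used in validation

The packaged checks run the switching analysis at 10,000 segments (a 2-Gb
genome at 200-kb segments, matching the order of the mouse genome's
~13,000-segment tiling) over 10 simulation replicates for the FDR, power and
null-calibration properties; profile recovery uses a 50-Mb chromosome at
5-kb bins; omics coupling uses 10,000 segments; fiber recovery uses 200
molecules of 1,500 kb plus 100 λ molecules. These sizes make the Monte-Carlo
error small relative to the tolerances being asserted while keeping a full
validation run in the low minutes on one core.

## Known limitations

- The distance statistic assumes comparable replicate noise in both groups
  (the pooled null mixes them); strongly heteroscedastic designs would need
  a per-group null.
- With exactly one replicate pair per group, the pooled null has two values
  per segment; the fixed-λ π0 estimate is coarse for very small segment
  counts (it is capped into [1/m, 1]).
- Smoothed profiles are biased across domain boundaries by construction
  (any local smoother is); boundary-accurate segmentation (HMM/changepoint
  methods) is explicitly out of scope.
- The fiber module assumes synchronous origin firing at the first pulse
  start; origins firing mid-pulse produce shorter first-label tracks that
  the origin caller still centres correctly, but fork-speed tracks then
  include partially-timed forks. At the default simulation settings this
  does not arise.
- The hypergeometric overlap test conditions on set sizes and ignores
  genomic autocorrelation of switch calls; treat small overlap p-values on
  strongly clustered call sets with care.
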