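---
title: "Methods and design choices in perinet"
author: "perinet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in perinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`perinet` reconstructs a perinatal cardiomyocyte regulatory network from
three quantified assays: element-by-sample ATAC-seq counts over four
perinatal time points (two replicates each), 10-kb binned H3K27ac HiChIP
contact maps at two of those time points (three replicates each), and
gene-by-sample RNA-seq counts (two replicates per time point). This
vignette is the package's own account of the statistics it implements,
the parameters that matter, and the choices made where more than one
reasonable design existed.

## Differential counts: TMM + exact conditional NB test

All count testing (accessibility, expression, and per-loop differential
contacts) goes through one engine.

**Normalization.** `tmm_factors()` implements the trimmed mean of
M-values: pairwise log-ratios against a reference sample (the one whose
upper-quartile count fraction is closest to the sample mean) are trimmed
two-sidedly — 30% on the log-ratio (M) axis, 5% on the mean-abundance (A)
axis — and combined by inverse-variance weights; factors are centred to
geometric mean 1. The trim fractions are the canonical defaults for this
estimator. Effective library size is `colSums(counts) * factor`, and the
per-sample size factors passed to the tests are these effective sizes
rescaled to geometric mean 1, so normalized counts stay on the raw-count
scale.

**The test.** `nb_exact_test()` conditions on the two-group total
`T = S_A + S_B`. With common dispersion `phi` and effective sizes `N_A`,
`N_B`:

* at `phi = 0`, `S_A | T ~ Binomial(T, N_A / (N_A + N_B))`;
* at `phi > 0`, `P(S_A = s | T)` is proportional to
  `f_NB(s; n_A/phi, T p_A) * f_NB(T - s; n_B/phi, T p_B)`, normalized
  over `s = 0..T` (the exact conditional law of a sum of i.i.d. NB
  variables per group).

The two-sided p-value doubles the smaller tail (observed point included
in both) and caps at 1, so a perfectly balanced split returns exactly 1.
The log2 fold-change is computed from normalized group means with a
pseudo-count of 0.5, which keeps zero-count groups finite.

**Dispersion.** With two replicates per group, per-feature
method-of-moments dispersions are extremely noisy (one residual degree of
freedom per group), and truncating them at zero biases any simple
location summary. `estimate_dispersions()` therefore keeps the raw
(possibly negative) per-feature moment estimates, averages them into an
unbiased pooled common dispersion, and moderates each feature toward that
pool with a prior weight of 20 residual df — at two replicates per group
the common component carries ~90% of the weight. On null two-group NB
data (2,000 features, mean 100, dispersion 0.05) this keeps the fraction
of `p < 0.05` calls between 0.047 and 0.063 across seeds; the test itself,
run at the true dispersion, matches the reference exact test in `edgeR`
(checked in the test suite, where `edgeR` serves only as an oracle).

**Gates.** Accessibility: FDR < 0.01 (Benjamini–Hochberg within each
pairwise time-point comparison) and |log2FC| > 1; an element is *dynamic*
if any comparison passes, and the dynamic set is the union over all
pairwise comparisons. Expression: FDR < 0.05 and |log2FC| > 1.
Differential loops: raw p < 0.05 and |log2FC| > 1 — deliberately no FDR,
matching the stated convention for this stage.

## Trajectory clustering

Dynamic elements are summarized by per-time-point replicate means of the
TMM-normalized matrix (replicate means rather than individual replicates:
the clustering should group temporal shapes, not replicate noise),
z-scored per element with the population standard deviation, and
partitioned by k-means with k-means++ seeding, 10 restarts, and a seeded
private RNG stream. `k = 4` by default — the design anticipates four
shapes (decreasing, transient, increasing, other); `k` is a parameter
because the number of planted shapes in real data is unknown. Clusters
are *named* by their centroid: monotone non-increasing with a net drop is
"down", monotone non-decreasing with a net rise is "up", an interior peak
is "transient", anything else "other". Ties in k-means are broken by the
restart with the smallest total within-cluster sum of squares.

## Contact maps

**Balancing.** `ice_balance()` runs the symmetric Sinkhorn-style
iterative correction: biases are updated by the square root of each bin's
relative row sum until all unmasked row sums of `count / (b_i b_j)` agree
within `tol` (default 1e-4, max 200 iterations — non-convergence is an
error that reports the last residual). Bins with zero marginal are masked
(bias `NA`) and never re-enter. Biases are normalized to mean 1 over
unmasked bins and are invariant to a global rescaling of the counts.

**Distance decay.** `fit_distance_decay()` estimates the background
contact probability per bin pair in 50 distance strata chosen to hold
near-equal total contact mass (fine resolution near the diagonal where
the mass is), as `stratum counts / (total counts x possible pairs in the
stratum)`, then enforces monotone non-increase with weighted
pool-adjacent-violators. A stepwise equal-occupancy estimate replaces
spline smoothing: it is simpler, directly testable (uniform maps give an
exactly constant estimate), and plays the same null role. The stepwise
approximation is slightly generous to pairs at the near edge of wide
far-distance strata; the null calibration below bounds the consequence.

**Loop calling.** Candidates are all pairs with at least one contact and
span within 20 kb–2 Mb (zero-count pairs can never be significant under
the binomial, so they are not enumerated). `p = P(X >= c)` with
`X ~ Binomial(N, p(d) b_i b_j)` capped at probability 1; `N` is the total
contact count in the fitted span range of the combined map. Passing loops
satisfy `p < 1e-4` and combined count strictly greater than 8. Calling is
performed on the replicate-combined map; the count gate therefore applies
to combined counts. On a pure-decay 20 Mb map with ~2e6 contacts, the
fraction of candidates reaching `p < 0.01` is ~0.7–0.8% (bounded at 2% in
the acceptance suite).

**Differential loops.** Per-sample counts at passing loop anchor pairs
(absent pair = 0) are normalized by per-sample total intra-chromosomal
counts (raw, unbalanced matrices — the NB test models counts, and
balancing would destroy the count scale) and tested with the same exact
NB machinery; "weakened" / "enhanced" follow the sign of the later-time
log2FC.

**APA.** For each loop with all four window corners inside the map and
far enough from the diagonal, the (2·10+1)² window of observed/expected
values is accumulated; P2LL is the centre of the mean window over the
mean of its 6x6 lower-left (short-distance) block. Radius 10 and corner 6
are the convention for 10-kb data. Windows whose span would cross the
diagonal are skipped rather than clipped.

**Virtual 4C.** The anchor bin's matrix row (optionally balanced), scaled
to contacts per million map total, written as a per-bin profile.

## Linking

Genes map to bins by their TSS bin only (loops are promoter-anchored in
this analysis; using gene bodies would let long genes absorb unrelated
anchors). An anchor bin that carries both a TSS window and a distal
element counts as a promoter anchor for classification (P > D > other
precedence), but its distal elements still form links from the partner
anchor. Per-link correlation uses per-time-point replicate means on both
sides over the time points shared by both assays (n = 4 here) — replicate
means rather than replicates because the two assays' replicates are not
paired. The randomized-pair null re-pairs elements and genes drawn from
the observed link anchors (1,000 seeded draws); links with a constant
accessibility or expression vector are excluded and counted. With only
four shared time points a single link's correlation is weak evidence;
the inference rests on the distribution of link correlations against the
null, compared by Wilcoxon on |r|.

## Motifs and regulatome

PWMs are probability matrices (zero cells lifted by 0.001 before
log-odds); scanning scores every offset on both strands with
`sum log2(p_col(base) / 0.25)` and calls a hit at or above 0.8 of the
maximum attainable score. `N` bases score as the worst base of their
column, so undetermined sequence can only hurt a match. Enrichment is the
one-sided hypergeometric upper tail on element counts (an element counts
once however many hits it carries) against the non-target element
universe — a deliberate divergence from genome-wide scrambled
backgrounds: the universe here is the element set itself, which is the
exchangeable unit in this design. Regulatome edges require all three
conditions (dynamic element with a hit; differential gene; proximal or
looped relation), so the edge set is always a subset of links x DEGs.

## The synthetic study

The generator emulates the deposited design: one 20 Mb chromosome at
10 kb resolution, 300 genes on a jittered regular grid, 1,000 elements
(half placed ≥ 20 kb from every TSS, half overlapping a TSS ± 2.5 kb
window), four time points (E18.5, P1, P3, P7) with two ATAC and two RNA
replicates, and HiChIP at E18.5 and P3 with three replicates. Planted
structure, all recorded in a ground-truth channel:

* **Trajectories**: 15% / 10% / 15% of elements decrease / peak
  transiently / increase with amplitude 2 log2 units (so a "down" element
  falls 4x from E18.5 to P7); NB counts at mean 100 per element and
  sample, dispersion 0.05, ±20% per-sample depth jitter.
* **Loops**: 80 distal-element-to-promoter bin pairs at spans 40 kb–1.5 Mb,
  contact multiplier 4 over a Poisson `d^-1` decay background scaled to
  ~2e6 contacts per sample; 30% are dynamic — 8x at one time point, 2x at
  the other, so the change is 4-fold while the combined-map enrichment
  stays at the stable loops' level. Poisson rather than NB contacts:
  replicate overdispersion enters only through depth jitter, which is
  sufficient for testing the callers and keeps the background exactly the
  model the caller assumes.
* **Coupling**: each linked gene's log2 mean expression follows
  `baseline + beta * z(element trajectory)` with `beta = 1`; half of the
  dynamic promoter-overlapping elements drive their own nearest gene
  (proximal links), distal elements drive their looped genes.
* **Motifs**: MEF2-like consensus `CTAAAAATAG` planted in 80% of "down"
  elements, AP1-like `TGACTCA` in "up" elements, random strand and
  offset, uniform background sequence.
* **Enhancer sets**: 292 positives overlapping elements at rate 0.822 and
  1,305 negatives at 0.365 (per-interval Bernoulli), mirroring the scale
  of the published validated-enhancer contingency analysis.

Every stage draws from a seed derived from the master seed by a fixed
offset (genome +0, accessibility +1, contacts +2, expression +3,
sequences +4, enhancer sets +5; clustering, the correlation null and the
random APA anchors use +10, +11, +12), so stages are individually
reproducible and byte-identical across runs.

**What the simulation does not model** — and therefore what passing tests
do not certify on real data: mappability and GC bias, peak-calling
uncertainty, fragment-level noise, NB overdispersion of contact counts,
inter-chromosomal contacts, TADs and compartments (the decay background
is globally smooth), motif information-content variation, and genes
regulated by several elements at once. The recovery metrics say the
algorithms find what the model plants at realistic depths; they do not
say real data are this clean.

## Problem sizes and numerical choices

The default study (2,000 bins, ~2e6 contacts per sample, 1,000 elements,
300 genes) runs the full pipeline in about a minute on one core; the test
suite and the acceptance script use these sizes, with a 4 Mb variant for
unit fixtures. Tolerances: ICE 1e-4 on relative row sums; k-means 10
restarts; PWM zero-cell lift 0.001; the exact NB enumeration is linear in
the pair total (fine for loop and element counts at these depths).
Degenerate inputs fail loudly and early: all-zero samples, constant rows
under z-scoring, empty enhancer sets, anchors outside the map,
single-link correlation nulls, fewer dynamic elements than clusters.

Known limitations: the stepwise decay estimate slightly inflates
significance at the near edge of wide distance strata (visible as extra
loop calls hugging planted anchors at shallow depth, bounded by the null
calibration); the exact NB enumeration is quadratic in the worst case if
loop totals grow very large; and the regulatome inherits every upstream
threshold, so its edge sensitivity compounds the stage sensitivities.
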