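---
title: "Methods: oat grain metabolomics and nitrogen-response statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oat grain metabolomics and nitrogen-response statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groatlab)
```

`groatlab` implements the statistical core of a multi-trial winter-oat
nitrogen-response study: grain metabolite profiling by LC-MS and GC-MS,
and plot-level agronomy. This vignette is the package's own account of the
models, the tunable parameters, the synthetic-data design, and the
numerical choices — the reference a maintainer or reviewer should read
before trusting or changing a default.

## 1. Feature-table processing

The unit of analysis is a `feature_table`: a features × samples matrix of
EIC areas with per-feature (m/z, RT) and per-sample design metadata
(trial, variety, applied N in kg/ha, replicate, role ∈ {experimental, qa,
blank}, run order). Processing stages are pure row filters — surviving
rows are bitwise unchanged and every removal is logged with a reason —
followed by column-wise normalisation.

* **Retention-window exclusion** (default 36–40 min) removes column-wash
  and re-equilibration peaks. The interval is closed on both ends: a peak
  at exactly 36.0 min is an equilibration artefact, and an open boundary
  would make removal depend on floating-point representation of the
  cut-off.
* **Blank exclusion**: a feature is blank-derived when mean(blank) >
  fold × mean(experimental), default fold = 3. The threshold is a package
  choice (any fold ≥ 1 is accepted); 3× is the conventional
  "clearly dominant in blanks" cut in untargeted QC practice.
* **Normalisation**: TIC for LC-MS (every column divided by its sum, so
  normalised columns sum to exactly 1) or internal standard for GC-MS
  (ribitol/sorbitol spike; the IS row becomes all 1). Columns summing to 1
  rather than to the mean TIC is a pure rescaling; all rank- and
  correlation-based statistics downstream are invariant to the constant.
* **QA-RSD filter**: RSD = 100·sd/mean per feature over the pooled-QA
  injections (sample sd, n−1 denominator), threshold 25%. A feature absent
  from all QAs (mean 0) has undefined RSD and is removed rather than
  producing 0/0. The filter is idempotent. At least 3 QA injections are
  required for the sd to be meaningful.

Stage order in `run_metabolomics()` follows acquisition practice:
retention/blank filtering and adduct/isotope annotation operate on the
*raw* deconvolved areas; TIC normalisation and the RSD filter are applied
to the collapsed table before statistics. Grouping on raw areas matters:
TIC normalisation couples features through the shared denominator and can
shrink the between-sample variance that correlation grouping relies on.

## 2. Adduct/isotope annotation and identification

Within each RT–m/z group (single-linkage components of the graph with
edges |ΔRT| ≤ `rt_tol` and Pearson r ≥ `r_min`; defaults 0.05 min and 0.8,
computed across experimental samples only), pairwise m/z relations are
searched at a ppm tolerance (default 5 ppm) against

* the ¹³C isotopologue ladder, +k × 1.00336 Da chained from the parent
  (k ≤ 3), and
* adduct shifts from the editable table in
  `system.file("extdata", "adducts.csv", package = "groatlab")`, computed
  from monoisotopic atomic masses including the electron mass, so that
  m/z = M + Δ for singly charged ions. Only singly charged species are
  annotated. The deprotonated formate adduct is encoded as [M+HCOOH−H]⁻
  (Δ = +44.99820 Da).

The **parent** is the most intense member that, read as the primary ion
form ([M+H]⁺ or [M−H]⁻), explains at least one other member; ties break by
lowest m/z, and a group with no internal evidence keeps its most intense
member as parent by default. This is deterministic and matches how adduct
families present in practice: the protonated/deprotonated molecule is
normally the base form. Known limitation: if a family lacks its primary
ion entirely (e.g. only [M+Na]⁺ plus isotopes), the computed neutral mass
is shifted by the difference between the true adduct and the primary
shift; the ppm evidence column exposes such cases.

Neutral masses are matched to compound libraries with an inclusive
boundary (|Δ| ≤ 5 ppm exactly). GC-MS identification requires both a
retention-index match (|ΔRI| ≤ 10) and a spectral cosine score strictly
greater than 800 on the conventional 0–1000 scale (unit-m/z binning;
symmetric; invariant to intensity rescaling); a hit is reported at MSI
confidence level 1, otherwise the feature stays level 4 (unknown).

## 3. Chemometrics

**PCA** is computed by SVD of the centred (optionally unit-variance or
Pareto scaled) matrix. Component signs follow a fixed convention — the
largest-magnitude loading of each component is positive — so outputs are
deterministic. Unit-variance scaling suits GC-MS profiles (few features,
comparable dynamic range); Pareto is the usual compromise for LC-MS where
intense lipid features would otherwise dominate; both are exposed.

**Multiblock hierarchical (consensus) PCA.** Samples are split into blocks
by the blocking factor — one block per variety to expose the common
nitrogen trend, or one block per nitrogen level to expose varietal
differences — with rows aligned within blocks on the remaining design
cells, so the consensus score is a trajectory over those cells. Per
component the iteration is

    p_b = X_b' t / (t' t), normalised;  t_b = X_b p_b
    T = [t_1 … t_B];  w = T' t / (t' t), normalised;  t ← T w

to relative tolerance 1e-10 (cap 500 iterations; non-convergence warns and
returns the partial model — near-degenerate singular values make the
power-iteration rate approach 1, which is informative in itself). Each
block is then deflated by its own t_b p_b′ (the consensus-PCA variant;
recorded in the model). Feature selection uses the block-weighted average
loading Σ w_b p_b. Blocks are centred per column; the `block_scaling`
option divides each block by √(feature count) — because all blocks share
one feature axis this only rescales scores, never re-weights blocks, and
`"none"` recovers ordinary PCA exactly in the single-block limit (a
property the test suite asserts to 1e-6 on random matrices).

**Nonparametric nitrogen screen.** Spearman ρ per feature against applied
N (mid-rank ties; undefined for constant features, reported `NA`).
Friedman tests per feature for the nitrogen effect (blocks = varieties,
treatments = N levels) and the variety effect (roles swapped); replicates
are averaged within block × treatment cells first, then the mid-rank,
tie-corrected statistic is referred to χ² with k−1 df. A fully tied layout
returns statistic 0, p = 1 by convention (the tie-corrected ratio is 0/0).
The χ² approximation is conservative at small block counts: with 4 blocks
and 6 treatments its exact size at nominal 0.05 is ≈ 0.029 (Monte-Carlo,
200k draws) — worth remembering when comparing rejection counts across
designs. BH-FDR control uses the step-up q-values at q ≤ 0.05.

**Clustergrams and heatmaps.** Feature–feature distance 1 − ρ (Spearman),
average linkage by default (configurable); the display matrix is
per-feature standardised and clipped to [−3, 3]. Because both distances
and leaf order depend only on ranks, the dendrogram is invariant to
strictly monotone transforms. Heatmap matrices are log₁₀ transformed
(zeros imputed at half the smallest positive value — preserves order and
keeps the log finite), standardised per feature (constant features map to
0), clipped to [−3, 3].

## 4. Agronomy

* **Lodging index** = % lodged + % leaning / 2, a 0–100 composite.
* **Yield components**: grains/m² = yield (t/ha) × 100 (g·m⁻²/t·ha⁻¹) ×
  dm_fraction / TGW (g) × 1000, with dm_fraction defaulting to 0.85
  because yields are recorded at 15% moisture. The moisture basis of TGW
  (as-is vs dry) shifts grains/m² by a constant factor; it is surfaced as
  the `dm_fraction` argument rather than silently assumed.
* **Split-plot ANOVA**: blocks; nitrogen on main plots tested against the
  block × nitrogen stratum; variety and the interaction on sub-plots
  against the residual. Balanced complete designs only — unbalanced input
  is an explicit error, never imputed. Letters come from Fisher's
  protected LSD: no letters are differentiated unless the omnibus F is
  significant; then means sorted ascending share a letter exactly when
  their range is within LSD = t₍₁₋α/₂,df₎ √(2·MS_error/n). Per-trial error
  terms are used (the alternative, pooling across trials, changes letters
  only when error variances differ strongly between sites).
* **Linear-plus-exponential response** y(N) = a + b·rᴺ + c·N with
  r ∈ (0, 1). For fixed r the model is linear in (a, b, c), so the fit
  profiles the SSE over an r grid (coarse to 0.95, fine 0.0015 steps up to
  0.9995 — response curvature concentrates near r = 1 for doses in
  kg N/ha), refines by golden-section search and polishes with a bounded
  Gauss–Newton step. The fit is exact on noiseless data. Identifiability
  caveat: with realistic noise the exponential and linear terms trade off,
  so b and especially c (t/ha per kg N, magnitude ~0.003) carry large
  relative standard errors even at the maximum-likelihood solution — the
  information bound for c at noise sd 0.1 t/ha and 6×12 plots is ~11% of
  |c| even with r known. Point estimates of N_opt are far better behaved
  than c itself because the profit surface is flat in the trade-off
  direction.
* **Economic optimum**: N_opt solves y′(N) = k′ with k′ = k/1000 in t/ha
  per kg N (breakeven k = 5 by default, i.e. 5 kg grain pays for 1 kg N).
  Closed form N_opt = ln((k′−c)/(b ln r))/ln r, validated against a
  0.01-step grid search of the profit function. When the marginal yield
  never falls to k′ within the dose range — yields still rising at the top
  dose, as happens in real trials — the optimum is *undefined with a
  recorded reason*, not an error and not an extrapolation. N_opt is
  computed on applied N; residual soil N can be added by the caller as a
  constant offset.

## 5. The synthetic-data generator

The generator defines the conditions under which the pipeline is tested;
its defaults are fixed once and mirror the three-trial study design: one
5-level trial (0–200 kg N/ha) and two 6-level trials (to 250 and
280 kg N/ha), 4 varieties (one dwarf, lodging-resistant), 3 replicate
blocks, and per trial an injection sequence of blanks, 8 conditioning QAs,
3 lead-in QAs, a QA after every 8 experimental injections, and 3 terminal
QAs.

Intensities are multiplicative and positive by construction:

    true(compound, sample) = base × variety_factor × exp(n_effect × N)
    observed = true × rel_ab(ion form) × bio(compound, plot) × exp(N(0, σ_tech))

* dose response is **linear in applied N on the log scale** (n_effect in
  log-units per kg N, defaults ±0.002–0.008), which keeps Spearman
  monotonicity exact and is the simplest shape consistent with monotone
  trends;
* technical noise is log-normal with σ = √log(1+cv²) so that the
  theoretical RSD equals the requested CV exactly;
* **biological variation** (`biological_cv`, default 0.3) is a
  per-(compound, plot) log-normal factor shared by all ion forms of a
  compound. It models between-plot variability of field-grown grain and is
  what makes same-compound features correlate strongly while different
  compounds with similar dose responses do not. QA injections are drawn
  from the pooled mean of the experimental samples with technical noise
  only — a pooled physical QA has no biological variance;
* compound retention times sit on a jittered grid with ≥ ~0.3 min
  separation (deconvolved features of distinct compounds are
  chromatographically resolved); co-eluting forms of one compound are
  jittered by 0.002 min;
* blank features are 20-fold more intense in blank extracts than in
  experimental samples; void features elute in the 36–40 min window;
  every feature id belongs to exactly one provenance category
  (compound-derived / blank / void);
* run order is recorded; no drift is simulated by default (a linear
  log-scale drift per injection is available via `drift` but off, since no
  drift correction stage exists downstream);
* GC-MS features are 1:1 with compounds, carry retention indices and
  reference EI spectra, and include an internal standard with constant
  true abundance;
* agronomy plots follow y(N) = a + b·rᴺ + c·N per variety, scaled by a
  per-trial productivity factor (1 / 0.75 / 0.45 — site-season effects),
  with additive Gaussian yield noise (default sd 0.25 t/ha), TGW and
  grains-per-panicle structure per variety, and lodging that grows with N
  above 100 kg/ha in proportion to a per-variety propensity (0 for the
  dwarf variety). Within-plot variance components are module parameters,
  not claims about any particular field study.

What the generator does **not** emulate — and therefore what passing tests
do not certify on real data: retention-time drift and batch effects,
correlated (matrix-dependent) mass errors, in-source fragments, missing
values/censoring at the detection limit, unbalanced designs from lost
plots, and non-monotone dose responses.

## 6. Problem sizes and reproducibility

All simulations in the test suite and acceptance script are seeded; rerun
with the same seed they are bit-identical, and every pipeline output file
carries the seed in a comment header. Simulation sizes were chosen to keep
the full suite in the tens-of-seconds range on a single core while leaving
Monte-Carlo error well below the asserted margins: 20-seed recovery runs
for annotation (50 compounds, 6 N levels × 4 varieties × 3 replicates) and
for the N-response fit (6 doses × 12 plots), a 2000-feature Friedman null
calibration, 10,000-shuffle permutation checks on 3×3 layouts, and 300
null split-plot ANOVAs for the uniformity check.
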