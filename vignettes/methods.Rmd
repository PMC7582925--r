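---
title: "Cross-species brain deconvolution: models, parameters and design choices"
author: "crossdeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species brain deconvolution: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossdeconv)
```

# Overview

`crossdeconv` estimates the cell-type composition of bulk brain
expression samples from single-cell reference profiles, with the twist
that incomplete human references are completed with mouse cell types
through homolog mapping. This vignette documents the statistical models
the package implements, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

# The mixture model

A bulk sample $T \in \mathbb{R}^G$ over $G$ genes is modelled as a
linear combination of $c$ cell-type expression profiles
$E_1, \dots, E_c$ (columns of the signature matrix $E$):

$$T = \sum_{i=1}^{c} E_i \alpha_i + \varepsilon.$$

The default estimator is ordinary least squares followed by clipping of
negative coefficients at zero and renormalization so that
$\alpha \ge 0$ and $\sum_i \alpha_i = 1$. Two alternatives exist:

* **NNLS** (`nonneg = TRUE`): non-negative least squares solved
  directly (via an active-set solver), then renormalized. OLS with
  clipping is the default because it is the simplest faithful reading
  of the linear-model formulation; NNLS usually agrees closely.
* **NMF regression (NMFR)**: $E$ is factorized as $E \approx WH$ with
  $k$ non-negative components (multiplicative updates under the
  Frobenius objective, seeded random initialization, convergence when
  the relative error change drops below $10^{-6}$ or after 1000
  iterations). The sample is regressed on $W$ giving $\beta$, and
  proportions are recovered by solving $H\alpha = \beta$ in the least
  squares sense, then clipped and renormalized. With $k = c$, an exact
  factorization and invertible $H$, NMFR reproduces OLS exactly; with
  the approximate factorizations obtained in practice (and the column
  shift needed to make z-scored signatures non-negative) it is strictly
  noisier, which is why the ordinary linear model is the package
  default.

How negative raw coefficients are handled is not prescribed by the
linear model itself; clipping + renormalization was chosen so that
proportions are comparable across samples, and the raw coefficients are
retained on every `proportion_estimate` for inspection. A sample whose
raw coefficients are all non-positive is flagged `degenerate` rather
than renormalized.

Rank-deficient signature matrices abort with the offending collinear
columns named; per-sample failures inside `deconvolve()` flag the
sample and continue, so one degenerate microarray cannot abort a
dataset run.

# Normalization

All expression matrices are normalized **sample-wise**: each column is
converted to z-scores using its own mean and standard deviation. The
population SD (divisor $n$) is used by default and the choice is
exposed (`sd_type`), since nothing in the method depends on it beyond a
constant factor. Constant columns (degenerate control samples occur on
real arrays) are set to all-zero with a warning instead of erroring.
Whether z-scoring should happen in log space is left to the caller; the
package z-scores values as given.

Z-scoring both the reference cells and the bulk samples puts the two
platforms on a comparable scale, at a price worth stating: a z-scored
bulk sample is an affine, not linear, transform of the underlying
mixture, so the fitted coefficients estimate $\alpha_i$ only up to
per-type scale factors. Per-type *correlations* across samples — the
quantity every downstream analysis consumes — are unaffected, but
absolute proportion values should be read with this caveat in mind.

# Feature selection

Four stages, applied in order; each stage only removes genes:

1. **Noise model** (`noise_model_select`): on the raw count reference,
   regress $\log \mathrm{CV}$ on $\log \mathrm{mean}$ across expressed
   genes and keep genes with residual above `residual_threshold`
   (default 0, i.e. more variable than the trend). The log-log CV-mean
   regression is the standard scRNA-seq noise model; the threshold is a
   config knob rather than a constant.
2. **mRMR** (`mrmr_select`): greedy selection with the difference
   criterion. Relevance is the one-way F statistic of the gene across
   cell types; redundancy is the mean $|r|$ (Pearson) with genes
   already selected; each step picks
   $\arg\max(\text{relevance} - \text{redundancy})$. The difference
   (MID-style) variant is the common default among mRMR variants. Ties
   are broken by input order, making the selection deterministic; with
   untied scores the output is invariant to gene order. Note that with
   an unbounded F statistic a perfect duplicate of an already selected
   gene can still be selected when its relevance exceeds every
   competitor's by more than the redundancy penalty of 1 — the
   criterion controls redundancy, it does not forbid it.
3. **Homolog matching** (`match_homologs`): genes are paired through an
   explicit mouse-human map (two-column TSV; identity on uppercased
   symbols in the synthetic data). The one-to-one policy rejects
   ambiguous maps by name; orthology inference is out of scope.
4. **Rank concordance** (`concordance_select`): for each (signature
   column, sample) pair, both vectors are ranked (average ties),
   the ranks z-scored with the population SD, and genes kept when the
   two rank z-scores differ by at most `band_width` (default **0.9**).
   Being rank-based, the filter is symmetric and invariant to monotone
   transforms of either side. The band is interpreted in z-scored
   *rank* units; an interpretation on z-scored expression values would
   not be monotone-invariant, which is why the rank reading was
   implemented.

Because deconvolution needs one design matrix per sample, the final
per-sample gene set is the **union** of the survivors over the $c$
cell-type signatures (an intersection mode is available). A sample for
which fewer features survive than there are cell types is flagged and
skipped.

# Signature construction and cross-species completion

The signature of a cell type is the per-gene mean over its annotated
cells. `complete_with_mouse()` keeps human columns untouched wherever
the human reference has the type and appends mouse columns (translated
to human gene symbols) for the missing ones, restricting rows to the
homolog-shared gene set; column provenance is recorded and survives the
TSV round trip. Both references are z-scored sample-wise first, which
is the only cross-species scale adjustment applied — no anchor-based
integration or batch correction, by design. Human datasets that do not
resolve the interneuron / S1-pyramidal split can declare a merged
"cortical neuron" type through the type map used by
`crossdataset_correlations()`; a merged column is only comparable to
another column covering the identical type set, and unresolvable
combinations are reported as missing rather than guessed.

# Pseudo-bulk validation

`run_validation()` repeats, `n_repeats` times: a stratified 50/50 cell
split; signature construction on one half; `n_mixtures` pseudo-bulk
mixtures (per-gene means over sampled cells) from the other half; and
estimation with each method. The true composition of a mixture is its
per-type cell-count fraction. Per repeat and cell type, the Pearson
correlation between true and estimated proportions across mixtures is
recorded; two methods are compared with a paired Wilcoxon signed-rank
test over the per-repeat mean PCCs (the test is not named in most
treatments of this comparison; the signed-rank pairing over repeats is
the conservative nonparametric default).

A single aggregated mixture per repeat would leave the per-type PCC
undefined, so the package draws 30 mixtures per repeat by default, each
with a uniformly random number of cells per type — a documented design
choice that makes the correlation well-defined while preserving the
50/50 split structure. Mixtures and the reference are z-scored by
default (`zscore = TRUE`), matching the full workflow; the raw-count
path is available for exact-recovery sanity checks.

# Spatial analyses

* **Smoothing**: each sample's proportion is replaced by the maximum
  over its 5 nearest samples in 3-D Euclidean space. The sample itself
  is included in its own neighborhood — the convention makes smoothing
  idempotent on constant fields and guarantees smoothed $\ge$ original
  — and the output is deliberately not renormalized (it serves
  visualization, not further modelling).
* **Clustering**: PCA on the composition matrix, then K-means with
  $k = 3$ (the three major brain regions) on the component scores.
  `stats::kmeans` (Hartigan-Wong) with 10 seeded restarts is used;
  k-means++ initialization is not available in base R and multiple
  restarts serve the same robustness purpose. Cluster-to-region
  assignment is chosen by exhaustive search over the $3! = 6$
  permutations — exact and simpler than a general assignment solver at
  this size — and scored by accuracy, per-region sensitivity and
  specificity.
* **Confounders**: a MANOVA with (sensitivity, specificity) as joint
  responses and dataset, donor and region as factors; Pillai's trace is
  reported per factor as the most robust of the standard MANOVA
  statistics.
* **Donor consistency**: per donor, location-mean composition vectors
  over the locations shared by all donors, concatenated across cell
  types, and correlated between donor pairs. All shared locations are
  used (not only cerebral ones). The negative control randomly picks a
  donor, permutes its location labels, and averages the shuffled
  donor's PCC against all real donors, 100 times.

# Region hierarchy and ratio reconciliation

`assign_major_region()` walks the anatomical tree breadth-first from
each major-region root; regions outside all three subtrees map to
`"other"` and are excluded from projection-volume averages. Per tracer
experiment, connectivity is the sum of injection and target volumes;
per region, the mean over experiments.

The nuclei-based neuron/non-neuron ratio is defined as
$\mathrm{NeuN^+} / (\mathrm{DAPI^+} - \mathrm{NeuN^+})$ — the natural
neuron-to-non-neuron analog when only total and neuronal nuclei counts
are available. mRNA-based ratios are computed per sample from the
estimated proportions (neuronal sum over non-neuronal sum), averaged
per (dataset, donor, region), and correlated with the nuclei ratios
before and after dividing by the region's mean projection volume. The
replicated (dataset $\times$ donor) layout is kept — each region
contributes one nuclei value matched against all its ratio estimates —
rather than averaging estimates per region first. Correlations are
invariant to a global rescaling of the volumes, which the tests
enforce.

# AD cohort analysis

Proportions estimated on the cohort's bulk samples are correlated
(Pearson, two-sided t-based p) with the three severity measures — CDR,
Plaque Mean and Braak stage — for the three neuron types and microglia
by default. Constant traits yield flagged undefined correlations, not
errors.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with known
truth:

* **References**: counts are negative binomial with a log-normal
  per-gene baseline (meanlog $\log 3$, sdlog 1), overdispersion 0.4
  (variance $\mu + 0.4\mu^2$; dispersion 0 degrades to Poisson), and
  marker genes elevated 5-fold in their own type (20 markers per type
  out of 600 genes by default). Dropout zeros counts independently at
  rate 0.3. NB-with-dropout is the scRNA-seq convention; none of these
  values is prescribed by the workflow itself, and they were fixed once
  at magnitudes typical of cortical scRNA-seq data. The "HumN"-like
  dataset lacks all six glial types, the "HumNG"-like dataset lacks
  ependymal cells; the mouse dataset is complete.
* **Homologs**: identity on the uppercased symbol with a configurable
  unmapped fraction — a caricature of symbol-based ortholog matching.
* **Spatial bulk**: nine anatomic locations across cerebrum, brainstem
  and cerebellum, each with its own composition vector (neuron-rich
  cortex, glia/endothelium-rich brainstem, and so on — coarse
  caricatures of known regional enrichment). Per-sample compositions
  are Dirichlet draws centered on the location's composition
  (concentration 100; lower per-donor concentrations emulate an
  atypical donor), mixed through the raw-scale signatures with additive
  Gaussian noise (SD 5% of the mean signature scale) and clamped at
  zero, so raw bulk expression stays non-negative. Coordinates are
  three well-separated Gaussian blobs in arbitrary units — no attempt
  at a standard anatomical space. Donors are i.i.d. replicates of one
  region map.
* **Connectivity / nuclei**: per-location projection volumes are
  log-normal around region-specific means (8, 2.5 and 0.8 mm³ for
  cerebrum, brainstem, cerebellum — long-range cortical projections
  dwarf cerebellar ones). Nuclei counts are constructed so that the
  mRNA ratio equals the nuclei ratio times
  $\text{volume}^{\text{coupling}}$ up to log-normal noise:
  `coupling = 1` builds in the volume confounding that the adjustment
  is meant to remove, `coupling = 0` makes nuclei and mRNA ratios agree
  directly — in which case dividing by the (still region-structured)
  volume cannot help and typically hurts, so the correct null
  expectation is "no systematic improvement", assessed one-sided.
* **AD cohort**: a latent severity $s \sim U(0,1)$ per sample drives
  (i) three independently noisy monotone transforms into CDR (ordinal
  0–3), Plaque Mean (non-negative continuous) and Braak stage (ordinal
  0–6), and (ii) a linear composition shift — neurons down, microglia
  up, total shift `severity_effect` (default 0.25) between $s=0$ and
  $s=1$ — before Dirichlet sampling and mixing.

**What the generator does not emulate**: platform/probe effects and
batch structure beyond additive Gaussian noise, spatial autocorrelation
of composition within a location, realistic anatomical coordinates,
cell-cell interaction effects on expression, and the sample-level noise
characteristics of real microarray data (the noise SD is a free knob,
not calibrated against any dataset). Passing tests therefore
demonstrate correctness of the algorithms and internal consistency of
the workflow under a realistic generative model — not performance on
real microarray or RNA-seq data.

# Numerical choices and degenerate inputs

* OLS via QR; rank deficiency detected from the QR decomposition with
  collinear columns named.
* NMF multiplicative updates guard denominators with $10^{-12}$; the
  Frobenius error is non-increasing over iterations and the trace is
  kept on the fitted object.
* Rank z-scoring uses average ranks for ties and the population SD.
* K-means degenerate input (all samples identical) errors with "no
  variation"; constant bulk columns z-score to zero with a warning;
  all-neuron compositions make the neuron/non-neuron ratio undefined
  (`NA`), not an error.
* Seeds: every stochastic routine takes an explicit seed and restores
  the caller's RNG state; dataset labels are hashed into the stream so
  different references drawn from one config seed are independent.
  `run_pipeline()` reruns bit-identically for a fixed config, verified
  by MD5 checksums in its manifest.

# Problem sizes

The shipped tests validate at sizes chosen to keep the full suite
comfortably interactive while preserving the study's structure: the
pseudo-bulk comparison runs 100 split repeats with 30 mixtures each on
a 9-type, 100-cells-per-type reference; region clustering uses a
600-sample three-region set; the MANOVA, ratio-adjustment and
donor-consistency properties use 100, 100 and 50 seeded replicates
respectively; the AD analysis uses a 500-sample cohort. The acceptance
script (`scripts/acceptance.R`) recomputes the same quantities at 50
validation repeats from a fresh seed.

# Known limitations

* Proportions on the z-scored scale are identified up to per-type
  scale; cross-type comparisons of absolute proportions inherit that
  distortion (correlation-based conclusions do not).
* The linear model ignores cell-cell interaction and cell-size effects
  beyond the explicit projection-volume adjustment.
* Complete (reference-free) deconvolution and covariate-weighted
  ensemble estimators are deliberately out of scope; `deconvolve()`'s
  design accepts any externally computed signature matrix, so such
  methods can be compared against it from outside.
* The homolog map is an input; no orthology inference is performed.
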