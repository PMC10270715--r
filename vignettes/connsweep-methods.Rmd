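---
title: "connsweep: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{connsweep: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connsweep)
```

# The model and its assumptions

`connsweep` analyses structural brain networks whose nodes are atlas
parcels and whose edges are white-matter connections reconstructed by
tractography. Two matrices per participant are taken as given: the
streamline count $NS_{ij}$ and the mean radial diffusivity $RD_{ij}$
along the connecting tracts (mm$^2$/s). The package makes no attempt to
model the MRI or tractography that produced them; it starts where those
pipelines end.

**Thresholding.** Edges recovered with fewer than $NS_{thr}$ streamlines
are treated as unreliable and removed; an edge is retained iff
$NS_{ij} \ge NS_{thr}$ and $NS_{ij} > 0$ ("fewer than" read strictly, so
thresholds 0 and 1 are equivalent). The retained edge set depends only on
the counts — never on RD — which is what makes node degree independent of
the edge weighting. Because any single threshold is arbitrary, the
analysis is repeated over thresholds calibrated to cohort-mean network
density targets. We follow the connectomics usage in which this density
is called *sparsity*: the fraction of possible edges retained, averaged
over participants (mean of per-participant densities, not the density of
a group-average network). `calibrateThreshold()` returns the smallest
integer threshold whose cohort-mean sparsity is at or below target, found
by bisection over the (provably monotone) sparsity-vs-threshold curve and
verified against brute-force scans in the tests.

**Edge weights.** Retained edges carry $w_{ij} = 1/RD_{ij}$ (s/mm$^2$).
Radial diffusivity is sensitive (non-specifically) to myelination and
axonal density, so lower RD is read as a stronger connection.

**Graph metrics.** Per node: degree $k_i$ (count of nonzero incident
weights), strength $s_i = \sum_j w_{ij}$, and the weighted clustering
coefficient. The source literature computes metrics with the Brain
Connectivity Toolbox without naming the weighted-clustering variant; we
adopt that toolbox's convention for undirected weighted graphs, the
Onnela geometric-mean form on max-normalised weights
$$ c_i = \frac{2}{k_i(k_i-1)} \sum_{j<h}
   (\hat w_{ij}\,\hat w_{ih}\,\hat w_{jh})^{1/3},
   \qquad \hat w = w / \max(w), $$
with $c_i = 0$ when $k_i < 2$ and all zeros for an empty network (the
normaliser is undefined). This form is bounded in $[0,1]$, reduces to the
binary clustering coefficient when all nonzero weights are equal, and is
invariant under global rescaling of the weights — properties the test
suite asserts. A `"binary"` variant is selectable. `igraph` was not used
here because its weighted transitivity is the Barrat form, not this one;
the matrix implementation is instead validated against exhaustive
brute-force triple enumeration on all graphs of up to 5 nodes over a
fixed weight grid.

**Subnetworks.** Metrics are computed on *induced* subgraphs — extraction
first, metrics second — so degree counts only intra-subnetwork edges.
Subnetwork means are plain arithmetic means over member nodes with
isolated members included at value 0 (they remain members of the system;
a `dropIsolated` flag provides the alternative). The four analysed
systems are the default-mode, sensorimotor, visual and auditory networks.
Published parcellations do not fix their memberships, so the packaged
defaults are explicit reconstructions from conventional resting-state
assignments; they are guaranteed to contain the regions reported as
correlation drivers in the motivating analyses (which is why, e.g.,
middle frontal gyrus appears in the AAL sensorimotor set and the thalamus
in the default-mode sets), and any membership can be overridden by a JSON
config of the shape `atlas -> subnetwork -> [labels]`. Unknown labels are
an error naming the label, never a silent drop or reorder.

**Collinearity screen.** Within each subnetwork, Pearson correlations are
computed among the three mean metrics across participants; a metric is
dropped when its |r| with an already-retained metric exceeds 0.85, with
fixed retention priority degree > clustering > strength so the screen is
deterministic, and a metric dropped in any subnetwork leaves the whole
analysis family. Under the default generator this reproduces the expected
outcome: mean strength tracks mean degree above the cutoff and is
removed.

# The association analysis

For each retained metric × subnetwork at each swept threshold:

1. **Outlier exclusion.** Cook's distances are computed from an OLS
   regression of the metric, and observations with $D_i$ above 4× the
   mean $D$ are excluded in a single pass (no iteration).
2. **Partial correlation.** On the kept rows, the metric and the trait
   score are each residualised on an intercept, age, and sex (0 = male,
   1 = female; point-biserial treatment), and the residuals correlated.
   Two-sided p values come from the t transform with $n - 2 - k$ degrees
   of freedom ($k = 2$ covariates). The residual-projection implementation
   is checked to $10^{-10}$ against the inverse-correlation-matrix closed
   form.
3. **FDR.** Benjamini–Hochberg adjustment is applied over the family of
   all retained metrics × all subnetworks *at that threshold* (2 × 4 = 8
   tests by default): the per-threshold reading matches how significance
   is marked per threshold in the motivating work; pooling across
   thresholds remains possible by adjusting the exported tables.
4. **Persistence.** A pair is *robust* when q < 0.05 at ≥ 80% of sweep
   targets, else *nominal* when p < 0.05 at ≥ 80%, else *none*. The
   motivating text says only "persisted across thresholds"; 0.8 is our
   quantification, it is configurable, and both fractions are always
   reported so the classification is auditable. When two density targets
   calibrate to the same integer threshold, the result block is counted
   once per target, so fractions are fractions of the stated sweep.
5. **Drivers.** For flagged pairs, each member node's metric is tested
   the same way (same covariates, the subnetwork-level exclusion set
   reused) at the threshold calibrated nearest density 0.3 — the density
   at which the motivating analyses display per-node results. A node
   "drives" the subnetwork correlation at uncorrected p < 0.05;
   deliberately exploratory, no multiplicity correction.

## Which regression for Cook's distance? (a deliberate choice)

The exclusion rule is stated in the source material as "Cook's distance
greater than four times the mean", without naming the regression. The
obvious candidate — the association model itself, metric ~ intercept +
score + age + sex — turns out to be statistically unsound as an exclusion
device: because the distances condition on the relation being tested,
points that weaken the observed correlation are preferentially removed,
and re-testing on the kept rows inflates the null rejection rate roughly
twofold (0.109 instead of 0.050 per test at $n = 100$ in a pure-Gaussian
simulation; at the family level, the fraction of null cohorts with any
FDR-significant result rises to ~0.23). The source analyses describe
their excluded points as data-quality anomalies — participants with
isolated subnetwork nodes or outlying degree distributions — i.e.
features of the metric itself, not of its relation to the score.
`connsweep` therefore computes Cook's distance from the covariate-only
model (metric ~ intercept + age + sex) by default, which flags exactly
such metric anomalies, is independent of the score under the null, and
empirically restores the nominal false-positive rate (the acceptance
suite holds the null family-positive replicate rate at ≤ 0.08). The
association-model variant remains available via
`excludeOutliers(model = "association")` / `runPipeline(cooksModel =
"association")` for comparison.

# The synthetic cohort: what it emulates, what it does not

The generator stands in for undeposited MRI cohorts and provides planted
ground truth.

* **Trait scores.** Nine subscales with the real instrument's item counts
  (9, 8, 7, 9, 7, 9, 9, 8, 8 — totalling 74 items scored 0/1), per-item
  endorsement probability 0.17 by default, giving totals with mean ≈ 12.6
  of a hard maximum 74 — close to the reference cohort's reported mean
  12.4. The reported sample moments (SD 10.1, range 0–43) are *targets
  for optional moment-matching, not obligations*: a binomial item model
  underdisperses relative to real SPQ totals (real subscale endorsements
  are correlated within person); matching the variance exactly would
  require a latent-trait model the analysis does not need.
* **Demographics.** Age uniform on 19–55 years, sex Bernoulli(92/140),
  both independent of the score by construction — so the demographic
  screen is truly null in this world.
* **Connectomes.** A template drawn once per world fixes per-edge
  existence probabilities (Beta around the requested density,
  concentration 10), expected streamline counts (log-normal around a
  median of 30), and the RD distribution. Per participant, edges exist
  Bernoulli; counts where present are shifted negative binomial
  (overdispersed, ≥ 1, dispersion 5); RD is truncated normal with mean
  0.6e-3 and SD 0.05e-3 mm$^2$/s — a physiologically plausible
  white-matter scale. All draws descend from one integer seed with fixed
  per-stage offsets, so identical configurations are bit-identical down
  to the written files.
* **Planted effect.** The score is standardised within the cohort to $z$;
  on every edge incident to a target node, `betaEdge` shifts the
  edge-existence log-odds by `betaEdge`·$z$ and `betaWeight` shifts the
  RD mean by `betaWeight`·$z$ (negative values raise the 1/RD weight).
  `betaEdge = betaWeight = 0` is the global null. The validation world
  plants `betaEdge = 0.55` on two of six sensorimotor nodes of a 20-node
  toy atlas at template density 0.5; a one-off large-$n$ ($n = 6000$)
  measurement put the induced true partial correlation between score and
  sensorimotor mean degree at ≈ 0.31 at the reporting density 0.3
  (stronger at weaker thresholds, ≈ 0.29 at density 0.25, because count
  thresholding attenuates an edge-probability effect). The anchor density
  0.3 was chosen once — it is where per-node results are conventionally
  displayed — and not revisited.

What a green test does **not** establish: the generator has no spatial
geometry, no distance-dependent connection probabilities, no
tract-length or partial-volume structure, no atlas-specific degree
profile, and its RD values are independent across edges. Recovery of a
planted effect here validates the statistical machinery, not claims about
real brains.

# Numerical choices and degenerate inputs

* Counts must be exactly symmetric integers with a zero diagonal; RD read
  from files may carry float noise, so asymmetry up to $10^{-12}$
  relative is tolerated and resolved by averaging — anything larger is an
  error. RD must be finite-positive exactly where counts are positive.
* A permutation of node labels between the counts and RD files is
  rejected, never silently reordered.
* Zero-variance metric cells and rank-deficient covariates produce
  explicit NA result rows carrying the failure message ("degenerate:
  ..."), never silent omission; constancy is detected on the raw inputs
  (exact `var == 0`) because projection residuals of a constant are only
  numerically zero.
* Exact-leverage points ($h_{ii} = 1$) get infinite Cook's distance and
  are always excluded; exclusion that would leave $n \le k + 3$ is an
  error rather than a silent small-sample test.
* The persistence rule is evaluated exactly as stated: 10 of 13
  thresholds is 0.769 < 0.8 and therefore *not* robust.
* CSV outputs are sorted on fixed keys and matrices written with 17
  significant digits, so identical configurations produce byte-identical
  result files.

# Known limitations

* The per-threshold FDR family (8 tests) treats thresholds as separate
  analyses; no correction spans the sweep, exactly as in the motivating
  design. Persistence classification is the guard against
  threshold-hacking, and its 0.8 fraction is a convention.
* Node-driver p values are uncorrected by design and should be read as
  exploratory.
* The default subnetwork memberships are reconstructions; results on real
  data will depend on the memberships chosen, which is why they are
  config-overridable and echoed into every run manifest.
* The generator's independence assumptions (edges, RD values, subscales)
  make it a calibration instrument, not a realistic connectome simulator.
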