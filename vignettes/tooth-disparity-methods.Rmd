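---
title: "Tooth-outline disparity through time: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tooth-outline disparity through time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analytical problem

Isolated fossil teeth are often the only abundant, time-resolved record a
vertebrate clade leaves. Comparing dental shape variety across a
stratigraphic boundary — here, geochronological stages bracketing a mass
extinction — turns into a chain of geometric-morphometric steps, each with
tunable choices: digitized outlines must be standardized, superimposed,
ordinated, and summarized as per-bin disparity with honest uncertainty.
`toothdisp` packages that chain so that every step is testable in
isolation, and pairs it with a generator of synthetic tooth assemblages
whose ground truth is known, so the whole pipeline can be validated
end to end without any fossil data.

# Landmark scheme and conventions

A tooth is represented by k ordered planar landmarks: three fixed anchors
(mesial crown–root junction, apex, distal crown–root junction) and two
open curves of sliding semilandmarks along the mesial and distal crown
edges. Under the standard k = 160 scheme the semilandmarks split 79
(mesial) / 78 (distal); for general k the k − 3 semilandmarks split with
the smaller partition distal, which reproduces that split exactly.

Conventions the package fixes (the literature leaves them open):

- **Traversal order**: mesial junction, mesial semilandmarks
  (junction → apex), apex, distal semilandmarks (apex → distal junction),
  distal junction. One canonical order makes slider tables and mirroring
  deterministic.
- **Slider indices** are 1-based both on disk (the common 3-column
  curves-file dialect) and in memory — this is an R package, so no
  off-by-one conversion layer exists at the I/O boundary.
- **Lingual views** are mirrored into labial-equivalent orientation with
  the traversal order reversed, so mesial stays mesial. The statistical
  equivalence of the two views can additionally be tested with
  `procrustes_lm(shape ~ view)`.
- **Orientation**: `normalize_orientation()` rotates each configuration so
  the junction-midpoint-to-apex axis points in the −x direction
  ("apex left"). Rotation is later removed by superimposition anyway; the
  normalization exists so that reflection decisions are made upstream,
  deterministically, and only once.

# Superimposition

`gpa()` performs partial generalized Procrustes analysis: configurations
are centred, scaled to unit centroid size, and iteratively rotated (proper
rotations only; reflections are a biological statement, handled by
orientation normalization, not an optimizer's degree of freedom) to an
evolving consensus until the Procrustes sum of squares Q changes by less
than `tol` (default 1e-10, `max_iter` 100 — chosen to exceed typical
convergence by a wide margin and exposed as arguments). Q is defined as
the summed squared distances of aligned specimens to the consensus and is
non-increasing across iterations; the full `q_history` is returned.

Because GPA only fixes shapes relative to each other, the rotational gauge
is then removed: the consensus is rotated onto its principal axes with a
third-moment sign rule. This makes aligned coordinates — and every
downstream table — invariant (to 1e-8) under a global similarity
transform of the raw input, which is also a tested property.

**Sliding semilandmarks.** `slide_semilandmarks()` alternates GPA with a
bending-energy step: for each specimen, every semilandmark may move along
its local tangent (the chord between its curve neighbours — the standard
estimator; the tangent choice is not prescribed by the field's
descriptions), and all slide amounts are solved jointly as the linear
system minimizing the thin-plate-spline bending energy of the
specimen-to-consensus deformation. Slides are clamped to twice the local
inter-point spacing to prevent curve fold-over, with an exact line search
along the clamped direction so the quadratic objective can never increase
(a tested invariant). Five outer GPA–slide cycles are the default; the
consensus typically stabilizes in two or three.

A consequence worth knowing: sliding deliberately discards the tangential
component of digitization noise. Estimates of *designed* landmark-noise
variance (as in the synthetic 2:1 disparity scenario) are therefore made
after plain GPA; sliding is for real curves whose point spacing is
arbitrary.

# Ordination and shape reconstruction

`shape_pca()` ordinates tangent-space coordinates (orthogonal projection
at the consensus; raw Procrustes coordinates are available by flag — at
the shape variances involved the two differ by well under 1e-6 in
inter-specimen distances). The covariance uses 1/(N−1); the disparity
estimator below deliberately uses 1/N — both conventions are documented
and tested, and the partial-disparity decomposition uses 1/(N−1) where
additivity requires it. Eigenvectors are oriented so each PC's
largest-magnitude loading is positive, making score signs reproducible
across runs.

Shapes are reconstructed anywhere in morphospace as
mean + Σ score_j · eigenvector_j (`backtransform()`). The **modal shape**
on an axis is the reconstruction at the mode of the score distribution,
estimated as the argmax of a Gaussian kernel density (Silverman
bandwidth, 512-point grid spanning the scores ±5% margin) — a
deterministic, standard estimator consistent with overlaying a "modal
value" on box plots. `tps_warp()` fits the interpolating thin-plate
spline between two configurations; `deformation_heatmap()` reports
log |det J| of that map on a grid (0 for the identity, log 4 for uniform
2× scaling). The heat-map scalar is this package's concrete
interpretation of "deformation isolines": the cited visualization
literature gives no formula, so the log-Jacobian — exact, analytic, and
testable against finite differences — stands in, and is flagged as such.

# Disparity

Disparity is Procrustes variance: each specimen's summed squared
deviation from its group mean shape (SSW), averaged with denominator
N_t — exactly the printed estimator, reproduced to 1e-12 by brute-force
summation in the tests.

**Partial disparity.** Two conventions exist and genuinely conflict. The
group-mean form (deviations from each subgroup's own mean, weighted
n_i/(N−1)) is what a literal reading of the published equations gives,
but it cannot be additive: it omits the between-group spread. The
additive decomposition — the stated purpose of the calculation — requires
deviations from the *bin grand mean* (Foote-style), whose per-group sums
equal the 1/(N−1) total exactly. `partial_disparity()` defaults to
`grand_mean`, keeps the literal `group_mean` behind a flag, and reports
the additivity gap so the discrepancy is itself an output rather than a
silent choice.

**Inference.** `pv_permutation_test()` permutes specimens' grand-mean
residual vectors across group labels (the residual-randomization scheme),
recomputes pairwise |PV| differences, and reports add-one-corrected
p-values with Benjamini–Hochberg adjustment across pairs; p-values can
never be exactly zero. Bootstrap CIs resample specimens with replacement
(1,000 by default); rarefaction subsamples without replacement (999
iterations by default) to a common size and reports percentile 95%
prediction intervals — at the full sample size the rarefied distribution
is degenerate at the observed PV, exactly. Add-one correction and
percentile intervals are this package's choices where the source
descriptions are silent.

# Shape statistics

`procrustes_lm()` fits OLS linear models to the multivariate shape data
with Type I (sequential) sums of squares; each term's F is tested by
randomizing the residuals of the reduced model preceding it (RRPP), and
the effect size Z standardizes the observed log-F against the permutation
distribution of log-F — log-transformation is standard RRPP practice; the
field's tables only say Z is "based on the F distribution". Single-level
factors yield 0-df, SS = 0 rows rather than errors, so formulas like
`shape ~ tooth_position + bin` stay valid in one-bin subsets.

Distribution diagnostics report skewness g1 (third standardized moment,
no small-sample correction) and *raw* Pearson kurtosis (normal = 3, so
"platykurtic" means < 3 — matching how the numbers are phrased in the
literature this package serves), IQR, and two tests implemented from
their published definitions because no implementation exists in this
environment:

- **Hartigan dip**: computed by iteratively narrowing a candidate modal
  interval between the greatest convex minorant of the lower step corners
  and least concave majorant of the upper step corners of the empirical
  cdf, accumulating flank deviations; the dip is half the final maximal
  gap. The implementation reproduces closed-form cases derived
  independently (two points → 1/4; n equally spaced points → 1/(2n); two
  tight pairs → 1/4), and its p-value is Monte-Carlo under the uniform
  null (10,000 draws by default, seeded).
- **Henze–Zirkler**: the standard statistic on scaled Mahalanobis
  distances with the lognormal null approximation; validated to nine
  digits against an independent reference implementation on a frozen
  input. Shape data are rank-deficient, so the test is applied to
  PC-score subsets.

`two_block_pls()` takes the SVD of the cross-block covariance; r-PLS is
the correlation of the first singular-score pair, with a row-shuffling
permutation p and standardized effect size. `measurement_error()`
partitions replicate-digitization variance by one-way ANOVA over
specimens; the reported percentage is 100·s²_within/(s²_within+s²_among).
A published "intraclass correlation of 2% (or 1 in 50)" reads as an
*error proportion*, not a repeatability of 0.02, so both the error
percentage and its complement (repeatability) are emitted.

# The synthetic world

`make_tooth()` draws a crown outline between junctions at (±0.5, 0) and
an apex at (recurvature/2, crown height): cubic splines through five
control points per edge with a small fixed outward bulge, sinusoidal
cusplets, an optional Gaussian heel notch on the distal edge, a
self-intersection check, curve resampling to the standard partition, and
isotropic Gaussian landmark noise. The parameters were chosen to span the
principal contrasts real tooth morphospaces show — tall/narrow versus
broad/low crowns on PC1, recurvature/heel versus upright-with-cusplets
beyond it.

Scenario defaults state the simulated world once: bins of n = 60 (100 in
the disparity-ratio design), crown height 1.5 ± 0.2, recurvature
0.2 ± 0.1, heel 0.05, landmark noise sd 0.02 on a unit base width —
within-bin shape variance and sample sizes of the order real stage-level
assemblages provide. The `disparity_shift` preset fixes all parameter sds
to zero and sets the landmark-noise ratio to sqrt(2), a designed 2:1 PV
contrast; `selective_loss` removes the broad-low ("blade-like") region of
morphospace after the boundary; `heterodonty_gradient` imposes a
recurvature gradient of 0/0.4/0.8 across tooth positions with nuisance
variation kept below the gradient, so the positional term is the dominant
signal as the scenario's contract requires.

What the generator does **not** emulate: taphonomic loss correlated with
shape, serrations (never digitized in the source data either), phylogenetic
autocorrelation between specimens, digitizer-specific bias, and
non-isotropic landmark error. A green calibration test therefore
establishes that the estimators are correct and calibrated under an
idealized sampling model — not that any particular fossil inference is
right.

# Numerical choices and degenerate inputs

- GPA: tol 1e-10 on ΔQ, max 100 iterations, non-convergence flagged, not
  thrown. Degenerate (zero-size) configurations error at entry.
- Sliding: singular slide systems fall back to unslid GPA with a warning;
  coincident reference points in the TPS kernel error with jitter
  guidance.
- PCA: components below 1e-10 of the leading singular value are treated
  as null; rank-0 input errors.
- Mode estimation requires ≥ 10 scores; moments ≥ 4; dip ≥ 8; smaller
  groups yield flagged NAs, not errors, in summary tables.
- All stochastic routines take explicit seeds; the pipeline derives
  per-stage child seeds from one global seed so stage-wise reruns equal
  the monolithic run byte for byte.

# Known limitations

- 2D outlines only; no 3D crown geometry.
- Procrustes variance is the only disparity metric (by design — it is the
  one the downstream comparisons are defined on); sums of ranges or hull
  volumes are out of scope.
- The dip test's null is the uniform distribution (the least favourable
  unimodal case), which is conservative for peaked unimodal alternatives.
- Reproducing the source study's printed values requires its deposited
  landmark data, which cannot ship with the package; the acceptance tests
  encode those checks and run whenever the files are supplied.
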