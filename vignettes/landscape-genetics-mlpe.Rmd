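---
title: "Landscape genetics with MLPE models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape genetics with MLPE models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmlpe)
```

This vignette is the package's own account of the statistical machinery
it implements: the models, the conventions that had to be fixed where
the field's common practice is ambiguous, and what the validation
experiments do and do not demonstrate.

## 1. The MLPE mixed model

Pairwise distance data violate the independence assumptions of ordinary
regression: every individual appears in many pairs. The
maximum-likelihood population effects (MLPE) model handles this with
one random effect per individual,

$$y_{ij} = \beta_0 + \beta_{GD}\,GD_{ij} + \sum_c \beta_c x_{c,ij}
  + u_i + u_j + \varepsilon_{ij},
  \qquad u_k \sim N(0,\sigma_u^2),\;
  \varepsilon_{ij} \sim N(0,\sigma_e^2),$$

so two pairs sharing exactly one individual have correlation
$\rho = \sigma_u^2 / (2\sigma_u^2 + \sigma_e^2)$, which is bounded
above by 0.5. `mlpe()` maximises the *full ML* likelihood (not REML):
the AICc comparisons at the heart of the workflow span models with
different fixed effects, and REML likelihoods are not comparable across
fixed-effect structures.

**Estimation.** Writing $\theta = \sigma_u^2/\sigma_e^2$, the marginal
covariance is $\sigma_e^2 (I + \theta Z Z^\top)$ with $Z$ the
pairs-by-individuals incidence matrix (entries of 1 for both members of
a pair; $\rho$ is derived, not parameterised directly). For fixed
$\theta$, $\hat\beta$ (GLS) and $\hat\sigma_e^2$ have closed forms, so
the profile likelihood is one-dimensional in $\theta$ and is maximised
with `optimize()` on $[0, \theta_{\max}]$ (default $10^3$; a boundary
estimate triggers a warning) with an explicit comparison against
$\theta = 0$. The $n \times n$ covariance is never formed: the Woodbury
identity reduces every evaluation to an $m \times m$ Cholesky
factorisation ($m$ = individuals), with
$\log|I + \theta ZZ^\top| = \log|I_m + \theta Z^\top Z|$. At $\theta =
0$ the profile likelihood equals the OLS Gaussian likelihood exactly,
which the tests assert.

**Parameter count.** AICc $= -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ =
fixed effects (including intercept) + 2 variance parameters and $n$ =
included pairs. Conventions for $k$ differ across software; since only
AICc *differences within a fixed dataset* drive every decision in the
pipeline, the choice is inert as long as it is consistent, and it is
recorded in every fit object.

**Standardization.** Predictors are z-scored inside `mlpe()` by default
so that coefficient magnitudes are comparable across predictors —
required for the rank-of-importance criterion. `standardize = FALSE`
restores raw-scale coefficients.

## 2. Resistance surfaces

`pland_moving_window()` scores each cell with the percentage of the
surrounding square window occupied by a class. Windows are specified by
edge length in meters and converted to the nearest odd cell count;
windows truncated at the raster edge are renormalised by the in-bounds
cell count rather than padded, which avoids border bias at the cost of
a smaller effective sample near edges.

`transform_surface()` maps percentages $p \in [0,100]$, $x = p/100$,
through

* linear: $g(x) = x$;
* monomolecular: $g(x) = (1 - e^{-sx})/(1 - e^{-s})$ (saturating);
* Ricker: $g(x) = x e^{-sx}$, rescaled by its maximum on $[0,1]$
  (unimodal, peak at $x = \min(1, 1/s)$);

with the `reverse` modifier replacing $x$ by $1-x$, the `inverse`
modifier replacing $g$ by $1-g$, and finally $R = 1 + (M-1)g$. Defaults
$s = 2$, $M = 100$. The sources that popularised these families do not
publish closed forms in this normalised parameterisation; the equations
above are this package's fixed convention, chosen so that every family
maps $[0,1]$ onto $[0,1]$ before rescaling (asserted numerically in the
tests) and so that the qualitative shapes match the field's usage. A
useful consequence tested exactly: for $M = 100$, an `inverse` family
equals $101$ minus its plain counterpart pointwise.

Five windows (100–1000 m) × nine families give the 45 candidates per
class produced by `candidate_surfaces()`.

## 3. Commute distances on the lattice graph

`build_graph()` connects 8-neighbours (4 optional) with conductance
$((1/R_a + 1/R_b)/2)/w$, $w = \sqrt 2$ for diagonals — the mean of the
cell conductances with a geometric correction, mirroring the defaults
of the raster-distance tools practitioners use. `commute_distance()`
solves the grounded graph Laplacian by sparse Cholesky (one
factorisation shared by all point pairs) and returns
$C(i,j) = \mathrm{vol}(G)\, R_{\mathrm{eff}}(i,j)$, restricted to the
connected component containing the points; points in different
components are an explicit error (the MLPE response cannot absorb
infinities, and synthetic configurations should avoid them) rather
than an infinite distance. Points snap to the centre of their
containing cell; co-located individuals share a node and are 0 apart.

A caution on scaling, verified numerically in the tests: multiplying
all resistances by $k$ scales conductances and hence the volume by
$1/k$ and effective resistance by $k$, so the *commute time is
invariant* (the random walk's transition probabilities do not change)
while the circuit-theoretic resistance distance $C/\mathrm{vol}$ scales
by $k$. This is precisely why random-walk and circuit distances "differ
only in scaling" on any given surface.

`residualize()` regresses each candidate's commute column on the
homogeneous-landscape commute column (all-ones raster, same geometry)
with intercept, and model fitting uses the residuals: the part of the
resistance signal not explained by straight-line distance.
`collinearity_screen()` then drops the lower-priority member of any
class pair with $|r| > 0.5$, scanning a user-set priority order
(habitat relevance, e.g. wetland over water).

## 4. Genetic distance

`encode_and_pca()` uses the standard individual-PCA encoding: one
column per observed allele per locus, value (copies)/2 ∈ {0, 0.5, 1}.
The upstream literature does not state its encoding, imputation, or
scaling choices, so the package fixes defaults and exposes the
alternatives: missing locus-calls (which must be missing at *both*
allele slots — enforced at parse time) are imputed with the column
mean, which provably leaves complete columns untouched; columns are
mean-centred but not variance-scaled by default (`scale. = TRUE`
switches). The default 64 retained axes follow common practice for
microsatellite panels, capped at the matrix rank so low-rank synthetic
data do not error. `pca_distance()` is the Euclidean distance on the
retained axes; with all axes retained and centring only, it equals the
Euclidean distance on the encoded matrix (orthogonal invariance —
tested against a brute-force eigendecomposition).

## 5. Spatial structure

`mantel_correlogram()` uses equal-width distance classes over
$(0, \max(geo)]$ (default 30). The per-class statistic is *minus* the
Pearson correlation between genetic distances and the 0/1 within-class
indicator, so positive $r$ means positive spatial autocorrelation —
matching the field's reading of "positively correlated" correlograms.
Significance comes from permuting individual labels (default 999),
one-sided on $|r|$; Holm-adjusted p-values are reported alongside raw
ones. `neighborhood_size()` — the largest class with positive,
significant $r$ — uses raw p-values by default (the published
neighborhood estimates appear to be based on unadjusted tests) with
`use_adjusted = TRUE` available. A configuration check warns when the
class width exceeds the minimum site spacing.

`semivariogram()` bins pairs into fixed 1.5 km lags (52 bins by
default, covering 78 km) and reports
$\gamma(h) = \sum_{\text{pairs}} g^2 / (2 n_h)$; empty bins are kept
with $n_h = 0$ and `NA` semivariance.

## 6. Synthetic generators: what they emulate and what they do not

The generators are *stylized stand-ins*, not biological simulators; the
empirical study they mirror has no generative model, so every choice
here is the package's own and is labelled as such.

* `generate_landscape()`: per class, seeded white noise smoothed with an
  isotropic Gaussian kernel; each cell takes the argmax class. This
  reproduces the patch-mosaic structure of a classified satellite map
  with tunable patch size (patch density falls as smoothing rises —
  tested), but has no anisotropy, no linear features (roads, streams),
  and no class-adjacency structure.
* `place_sampling_design()`: uniform rejection sampling under a minimum
  spacing, with a fixed 10,000-draw budget; infeasible packings fail
  deterministically with a message naming the constraint, rather than
  silently violating spacing.
* `simulate_genotypes()`: location-level allele frequencies are
  logistic-normal deviations around shared baselines, spatially
  correlated as $\exp(-D/\bar D)$ in commute distance $D$, scaled by
  `drift_scale`; individuals are Hardy–Weinberg draws. This produces
  resistance-driven isolation-by-distance in the PCA distance (the
  correlogram detects it — tested) but has no mutation model, no
  drift through time, and no linkage.
* `simulate_pairwise_distances()`: the exact generative mirror of the
  MLPE likelihood, used for oracle and recovery tests.

Because the genotype channel with 8 loci is information-poor (as real
microsatellite panels are), the headline recovery experiments inject
effects through the MLPE mirror, where the planted truth is
unambiguous. Passing tests therefore demonstrate that the *pipeline*
(surfaces → commute → residualize → MLPE → AICc) recovers a known
signal; they do not certify power for any particular empirical panel.

## 7. Validation experiments and problem sizes

The experiment drivers fix their study conditions once:

* `surface_recovery_experiment()`: 60 × 60 cells of 100 m, 5 classes,
  smoothing 4; 12 locations ≥ 900 m apart, 3 individuals each (630
  pairs, between-location pairs used for fitting); truth = class 1,
  500 m window, monomolecular, $\beta = 1.5$ per SD against
  $\sigma_u = 0.15$, $\sigma_e = 0.3$, plus a $\beta_{GD} = 0.5$
  isolation-by-distance component. Strong-but-noisy: the 45 candidates
  are heavily intercorrelated, so exact (window, transformation)
  selection is a demanding target; 20 replicates.
* `full_model_experiment()`: same landscape/design; all five classes
  active ($|\beta| \in [0.8, 1.2]$) at a common scale/transformation;
  the ten-model AICc ranking should put the full model first.
* `mantel_null_calibration()`: 100 replicates of 30 individuals with
  genetic distance independent of geography; the share of significant
  classes at $\alpha = 0.05$ (199 permutations; p-values are exact
  multiples of 1/200, so the nominal level is attainable) should be
  close to 0.05.
* `scheme_congruence_experiment()`: a 9 × 9 km landscape with a nested
  4 × 4 km small area, 10 sparse + dense-infill locations, thresholds
  scaled down in proportion to the design spacing (Sparse-Small keeps
  pairs > 2.5 km); a scheme-independent effect should code "A" for the
  sign criterion.

These sizes keep the full test suite under a minute while leaving the
commute solves (the dominant cost, one sparse factorisation per
candidate surface) non-trivial.

## 8. Degenerate inputs, ties, and other numerical choices

* `optimize_surface()` ties on AICc break toward the smaller window,
  then the fixed family order of `transform_families()`, and are
  flagged; failed candidate fits are recorded and skipped with a
  warning.
* `effect_signs()` ranks by $|\hat\beta|$ descending, breaks exact ties
  by class name (flagged), and ranks exactly-zero coefficients last
  with sign `"0"`.
* The congruence classifier treats similarity as exact categorical
  equality (same rank position, sign, window, transformation label);
  the published comparisons are exact-match too. For the binary sign
  criterion the all-distinct outcome E is impossible by construction.
* Scheme labels: outcome B = the two *sparse* datasets agree (density
  drives outcomes), C = the two *small-area* datasets agree (area size
  drives outcomes). Published summaries of these labels are internally
  inconsistent in one footnote; the package follows the usage in the
  results they accompany.
* Commute solves use a sparse Cholesky with no iterative refinement;
  against a dense pseudo-inverse oracle the error is ~1e-12 at the
  tested sizes, comfortably inside the 1e-6 contract.
* `place_subregion()` scans all stride-offset windows with summed-area
  tables; the acceptance tolerance for composition mismatch defaults to
  6.3 % (the placement criterion used in the empirical study this
  mirrors).

## 9. Known limitations

* Raster I/O is ESRI ASCII only — a plain-text format every GIS reads
  and writes; GeoTIFF is out of scope.
* No least-cost paths, current maps, or anisotropic movement; no
  model-based variogram fitting (sill/range estimation); no HWE,
  null-allele, or linkage testing (descriptive genotype summaries
  only).
* The MLPE profile is assumed unimodal in $\theta$ (true for this
  covariance family in practice); pathological tiny datasets can push
  $\hat\theta$ to the search boundary, which is warned about rather
  than silently truncated.
* A Dense-Large scheme is intentionally absent from the nested
  comparison: the empirical design it mirrors could not field one.
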