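# landmlpe

Individual-based landscape genetics in R: from a categorical land-use
raster and multilocus genotypes to optimized resistance surfaces,
maximum-likelihood population effects (MLPE) model rankings, and a
classification of how sampling design changes the inferences.

## The problem

Landscape genetics asks which land-cover features restrict or
facilitate gene flow. For continuously distributed, dispersal-limited
animals (e.g. terrestrial salamanders) the standard workflow is:

1. summarise each land-use class at several spatial scales with
   moving-window class percentages (PLAND),
2. map percentages to candidate **resistance surfaces** through a family
   of curves (linear, monomolecular, Ricker, and their input-reversed /
   output-inverted variants) with shape *s* = 2 and maximum resistance
   *M* = 100, giving 5 window sizes × 9 curves = **45 candidates per
   class**,
3. compute **commute-time (random-walk) distances** between sampled
   individuals on each surface — `C(i,j) = vol(G) · R_eff(i,j)` on the
   lattice conductance graph, proportional to circuit-theory resistance
   distance,
4. residualize each candidate against the commute distance on a
   homogeneous (all-ones) landscape to strip the straight-line
   isolation-by-distance component,
5. fit an **MLPE mixed model** per candidate and pick the lowest AICc:
   for pairwise genetic distances `y_ij`,

   ```
   y_ij = β₀ + β_GD GD_ij + β x_ij + u_i + u_j + ε_ij,
   u_k ~ N(0, σ_u²),  ε_ij ~ N(0, σ_e²),
   ```

   so pairs sharing an individual are correlated with
   `ρ = σ_u² / (2σ_u² + σ_e²) ≤ 0.5`,
6. rank a fixed ten-model set (full, isolation-by-distance, three
   ecological combinations, five univariate; all including the
   homogeneous distance GD) by AICc, and read each class's **sign of
   effect** (positive = gene-flow restriction, negative =
   facilitation) and rank of importance,
7. repeat on three nested datasets — Sparse-Large, Dense-Small,
   Sparse-Small — and code each class × criterion (rank, sign, scale,
   transformation) with a congruence outcome **A–E** (insensitive /
   density-driven / area-size-driven / effort-driven / combined).

`landmlpe` implements the whole chain, with the MLPE fit as a classic R
modelling function (`mlpe()` returning an S3 object with `print`,
`summary`, `coef`, `logLik`, `AICc`, `predict`, `residuals`,
`simulate`, `vcov`, `plot` methods). Genetic distance is the Euclidean
distance between individuals on the leading axes (default 64) of a PCA
of allele-dosage encodings; spatial genetic structure is summarised by
a permutation-tested Mantel correlogram and a semivariogram. Seeded
synthetic generators (patchy landscapes, spaced sampling designs,
genotypes with resistance-driven spatial correlation, MLPE-distributed
pairwise distances) make every stage testable with known ground truth.

## Worked example

Simulate a five-class landscape with 12 sampling locations (3
individuals each), plant a strong effect of class 1 at a 500 m window
with a monomolecular transformation, and ask the pipeline to find it:

```r
library(landmlpe)

st <- simulate_study(seed = 11)                 # landscape + design
preds <- class_predictors(st$raster, st$design, class_id = 1,
                          pairs = st$pairs_all) # 45 residualized candidates

x_true <- as.numeric(scale(preds$residuals[["w500_monomolecular"]]))
y_mat <- simulate_pairwise_distances(
  st$design, x_true,
  truth = list(beta = 1.5, sigma_u = 0.15, sigma_e = 0.3), seed = 12)

pm  <- st$pairs_model                           # between-location pairs
sel <- match(paste(pm$i, pm$j), paste(st$pairs_all$i, st$pairs_all$j))
opt <- optimize_surface(y_mat[cbind(pm$i, pm$j)],
                        preds$residuals[sel, ], preds$GD[sel],
                        cbind(pm$id_i, pm$id_j))
opt
#> optimized surface: w500_monomolecular (window 500 m, monomolecular )
#> AICc = 311.79 over 45 candidates
summary(opt$fit)
#> Fixed effects:
#>              Estimate Std. Error z value Pr(>|z|)
#> (Intercept) -0.038106   0.044890 -0.8489   0.3959
#> GD           0.014567   0.017179  0.8480   0.3964
#> x            1.551218   0.030365 51.0849   <2e-16 ***
#> Random effects: individual sigma_u^2 = 0.01683 ; residual sigma_e^2 = 0.08619
#> Correlation of pairs sharing an individual: rho = 0.1404
#> logLik = -150.84 ; AICc = 311.79 (k = 5 , n = 594 pairs)
```

The optimizer selects the true window and transformation out of the 45
candidates, and the standardized effect estimate (1.55) recovers the
planted β = 1.5. `rank_model_set()` then compares the ten-model set,
`effect_signs()` extracts signs and ranks, and `comparison_report()` /
`classify_congruence()` code the agreement of three nested schemes
(built by `nested_design()` + `build_scheme_datasets()`) into outcomes
A–E.

For genotype-level work: `simulate_genotypes()` /
`read_genotypes()` → `encode_and_pca()` → `pca_distance()` →
`mantel_correlogram()` / `semivariogram()` / `neighborhood_size()`.

## Vignette

`vignettes/landscape-genetics-mlpe.Rmd` documents the model, the
transformation conventions, the commute-distance contract, the
synthetic generators and what they do and do not emulate, and all
numerical choices.
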