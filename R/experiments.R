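#' Simulate a complete synthetic study
#'
#' Generates a patchy categorical landscape and a spatially constrained
#' sampling design over its extent: the shared starting point of the
#' validation experiments below. Defaults give a 6 x 6 km landscape of
#' five classes with 12 locations of 3 individuals each.
#'
#' @param seed integer seed.
#' @param n_rows,n_cols,cell_size,n_classes,smoothing landscape
#'   parameters, see [generate_landscape()].
#' @param n_locations,min_spacing,n_per_location design parameters, see
#'   [place_sampling_design()].
#' @return List with `raster`, `design`, `pairs_all` (all unordered
#'   pairs) and `pairs_model` (between-location pairs only).
#' @export
simulate_study <- function(seed, n_rows = 60, n_cols = 60,
                           cell_size = 100, n_classes = 5, smoothing = 4,
                           n_locations = 12, min_spacing = 900,
                           n_per_location = 3) {
  r <- generate_landscape(seed, n_rows, n_cols, cell_size, n_classes,
                          smoothing)
  extent <- c(xmin = 0, xmax = n_cols * cell_size,
              ymin = 0, ymax = n_rows * cell_size)
  design <- place_sampling_design(extent, n_locations, min_spacing,
                                  n_per_location, seed = seed + 1L)
  list(raster = r, design = design,
       pairs_all = enumerate_pairs(design, exclude_within_location = FALSE),
       pairs_model = enumerate_pairs(design))
}

# Expand a location-level distance matrix to individuals (individuals
# inherit their location's coordinates; same-location distance is 0).
expand_to_individuals <- function(D_loc, design) {
  idx <- match(design$individuals$location_id, design$locations$id)
  D <- D_loc[idx, idx]
  diag(D) <- 0
  dimnames(D) <- list(design$individuals$id, design$individuals$id)
  D
}

#' Residualized candidate predictors for one class
#'
#' Computes the 45 candidate resistance surfaces for `class_id`, their
#' commute distances between the design's locations, expands to
#' individual pairs, and residualizes each against the homogeneous
#' commute distance. Commute systems are solved at the location level
#' (co-located individuals share a raster cell).
#'
#' @param raster categorical [land_raster].
#' @param design `sampling_design`.
#' @param class_id focal land-use class.
#' @param pairs pair index rows to extract (default: all pairs).
#' @param window_sides,families passed to [candidate_surfaces()].
#' @return List with `GD` (homogeneous commute per pair), `residuals`
#'   (data.frame of residualized candidate columns), `commute`
#'   (data.frame of raw commute columns).
#' @export
class_predictors <- function(raster, design, class_id,
                             pairs = enumerate_pairs(design, FALSE),
                             window_sides = c(100, 250, 500, 750, 1000),
                             families = transform_families()) {
  pts <- design$locations[, c("x", "y")]
  hom_loc <- homogeneous_distance(pts, raster)
  GD <- expand_to_individuals(hom_loc, design)[cbind(pairs$i, pairs$j)]
  cands <- candidate_surfaces(raster, class_id, window_sides, families)
  commute <- list(); resid <- list()
  for (lab in names(cands)) {
    D <- commute_distance(build_graph(cands[[lab]]), pts)
    cc <- expand_to_individuals(D, design)[cbind(pairs$i, pairs$j)]
    commute[[lab]] <- cc
    resid[[lab]] <- residualize(cc, GD)
  }
  list(GD = GD, residuals = as.data.frame(resid),
       commute = as.data.frame(commute))
}

#' Scale-and-transformation recovery experiment
#'
#' The headline pipeline validation: for each replicate, simulate a
#' landscape and design, pick the candidate surface named by `truth` as
#' the generative predictor, draw pairwise distances from the MLPE
#' generative model with a strong effect, and check whether
#' [optimize_surface()] selects the true (window, transformation) pair
#' and recovers the sign of the effect.
#'
#' @param n_rep number of replicates.
#' @param seed integer seed (per-replicate seeds are derived from it).
#' @param truth list with `class_id`, `window`, `transform`, `beta`,
#'   `gd_beta`, `sigma_u`, `sigma_e`.
#' @param ... study-condition overrides passed to [simulate_study()].
#' @return data.frame with one row per replicate: selected `window`,
#'   `transform`, logical `exact` (both correct), `sign_ok`, estimated
#'   `beta`.
#' @export
surface_recovery_experiment <- function(n_rep = 20, seed = 1,
                                        truth = list(class_id = 1,
                                                     window = 500,
                                                     transform = "monomolecular",
                                                     beta = 1.5,
                                                     gd_beta = 0.5,
                                                     sigma_u = 0.15,
                                                     sigma_e = 0.3),
                                        ...) {
  true_lab <- paste0("w", truth$window, "_", truth$transform)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    s <- as.integer(seed) * 1000L + r
    st <- simulate_study(s, ...)
    preds <- class_predictors(st$raster, st$design, truth$class_id,
                              pairs = st$pairs_all)
    x_true <- as.numeric(scale(preds$residuals[[true_lab]]))
    gd_std <- as.numeric(scale(preds$GD))
    y_mat <- simulate_pairwise_distances(
      st$design, x_true,
      truth = list(beta0 = 0, beta = truth$beta, sigma_u = truth$sigma_u,
                   sigma_e = truth$sigma_e),
      seed = s + 1L
    )
    # add the isolation-by-distance component
    pa <- st$pairs_all
    y_mat[cbind(pa$i, pa$j)] <- y_mat[cbind(pa$i, pa$j)] +
      truth$gd_beta * gd_std
    y_mat[cbind(pa$j, pa$i)] <- y_mat[cbind(pa$i, pa$j)]
    pm <- st$pairs_model
    rowsel <- match(paste(pm$i, pm$j), paste(pa$i, pa$j))
    y <- y_mat[cbind(pm$i, pm$j)]
    opt <- optimize_surface(
      y, preds$residuals[rowsel, , drop = FALSE],
      gd = preds$GD[rowsel], pairs = cbind(pm$id_i, pm$id_j)
    )
    beta_hat <- unname(opt$fit$coefficients["x"])
    rows[[r]] <- data.frame(
      replicate = r, window = opt$window, transform = opt$transform,
      exact = opt$window == truth$window &&
        opt$transform == truth$transform,
      sign_ok = sign(beta_hat) == sign(truth$beta),
      beta = beta_hat
    )
  }
  do.call(rbind, rows)
}

#' Full-model ranking experiment
#'
#' Simulates pairwise distances in which every land-use class has an
#' active (strong) effect at a known scale and transformation, fits the
#' ten-model comparison set, and records which model ranks first by
#' AICc. With all effects active the full model should win.
#'
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @param betas named numeric vector of class effects (canonical order
#'   agriculture, hardwoods, pine, manmade, wetlands).
#' @param gd_beta,sigma_u,sigma_e remaining generative parameters.
#' @param window,transform scale and transformation used for every
#'   class's generative surface.
#' @param ... study-condition overrides passed to [simulate_study()].
#' @return data.frame with one row per replicate: `best` model name and
#'   logical `full_first`.
#' @export
full_model_experiment <- function(n_rep = 20, seed = 1,
                                  betas = c(agriculture = 1,
                                            hardwoods = 0.8,
                                            pine = -0.8,
                                            manmade = -1,
                                            wetlands = 1.2),
                                  gd_beta = 0.5, sigma_u = 0.15,
                                  sigma_e = 0.3,
                                  window = 500,
                                  transform = "monomolecular", ...) {
  classes <- names(betas)
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    s <- as.integer(seed) * 1000L + r
    st <- simulate_study(s, ...)
    pts <- st$design$locations[, c("x", "y")]
    hom_loc <- homogeneous_distance(pts, st$raster)
    pa <- st$pairs_all
    GD <- expand_to_individuals(hom_loc, st$design)[cbind(pa$i, pa$j)]
    resid <- list()
    for (ci in seq_along(classes)) {
      p <- pland_moving_window(st$raster, ci - 1L, window)
      surf <- transform_surface(p, transform_spec(transform))
      D <- commute_distance(build_graph(surf), pts)
      cc <- expand_to_individuals(D, st$design)[cbind(pa$i, pa$j)]
      resid[[classes[ci]]] <- residualize(cc, GD)
    }
    xs <- vapply(resid, function(v) as.numeric(scale(v)),
                 numeric(nrow(pa)))
    mu <- as.numeric(xs %*% betas) + gd_beta * as.numeric(scale(GD))
    y_mat <- simulate_pairwise_distances(
      st$design, mu / 1,                       # mean passed through beta=1
      truth = list(beta0 = 0, beta = 1, sigma_u = sigma_u,
                   sigma_e = sigma_e),
      seed = s + 1L
    )
    pm <- st$pairs_model
    rowsel <- match(paste(pm$i, pm$j), paste(pa$i, pa$j))
    y <- y_mat[cbind(pm$i, pm$j)]
    rk <- rank_model_set(
      y, as.data.frame(resid)[rowsel, , drop = FALSE],
      gd = GD[rowsel], pairs = cbind(pm$id_i, pm$id_j)
    )
    rows[[r]] <- data.frame(replicate = r, best = rk$best,
                            full_first = rk$best == "Full model",
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Type-I error calibration of the Mantel correlogram
#'
#' Under the null (genetic distances independent of geography), the
#' fraction of correlogram classes declared significant at level
#' `alpha` should be close to `alpha`. Genetic distances are drawn as
#' iid symmetric noise; locations are uniform.
#'
#' @param n_rep number of replicates.
#' @param n_ind individuals per replicate.
#' @param n_classes,n_perm,alpha correlogram settings.
#' @param seed integer seed.
#' @return List with `rate` (significant fraction over all replicate
#'   classes), `n_tests`.
#' @export
mantel_null_calibration <- function(n_rep = 100, n_ind = 30,
                                    n_classes = 30, n_perm = 199,
                                    alpha = 0.05, seed = 1) {
  rng <- local_rng(seed)
  sig <- 0L; total <- 0L
  for (r in seq_len(n_rep)) {
    xy <- cbind(rng$runif(n_ind, 0, 1e4), rng$runif(n_ind, 0, 1e4))
    geo <- as.matrix(stats::dist(xy))
    g <- matrix(0, n_ind, n_ind)
    g[lower.tri(g)] <- rng$runif(n_ind * (n_ind - 1) / 2)
    g <- g + t(g)
    cl <- mantel_correlogram(g, geo, n_classes = n_classes,
                             n_perm = n_perm,
                             seed = as.integer(seed) * 1000L + r,
                             alpha = alpha)
    ok <- !is.na(cl$p_raw)
    # two-sided type-I accounting: count small p regardless of r sign
    sig <- sig + sum(cl$p_raw[ok] <= alpha)
    total <- total + sum(ok)
  }
  list(rate = sig / total, n_tests = total)
}

#' Scheme-congruence experiment for the sign criterion
#'
#' Simulates a nested sampling design on one landscape with a single,
#' scheme-independent strong effect of the focal class, fits the
#' focal-class model separately on the Sparse-Large, Dense-Small and
#' Sparse-Small datasets, and classifies the congruence of the sign of
#' effect. With a scheme-independent truth the expected outcome is A.
#'
#' @param n_rep replicates.
#' @param seed integer seed.
#' @param truth as in [surface_recovery_experiment()].
#' @return data.frame per replicate: the three signs and the outcome
#'   `code`.
#' @export
scheme_congruence_experiment <- function(n_rep = 10, seed = 1,
                                         truth = list(class_id = 1,
                                                      window = 500,
                                                      transform = "monomolecular",
                                                      beta = 1.5,
                                                      gd_beta = 0.5,
                                                      sigma_u = 0.15,
                                                      sigma_e = 0.3)) {
  rows <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    s <- as.integer(seed) * 1000L + r
    rast <- generate_landscape(s, 90, 90, cell_size = 100, n_classes = 5,
                               smoothing = 4)
    extent <- c(xmin = 0, xmax = 9000, ymin = 0, ymax = 9000)
    small <- c(xmin = 2500, xmax = 6500, ymin = 2500, ymax = 6500)
    des <- nested_design(extent, small,
                         n_sparse = 10, sparse_spacing = 2200,
                         n_dense = 9, dense_spacing = 1100,
                         n_per_location = 3, seed = s)
    pa <- enumerate_pairs(des, exclude_within_location = FALSE)
    pts <- des$locations[, c("x", "y")]
    hom_loc <- homogeneous_distance(pts, rast)
    GD <- expand_to_individuals(hom_loc, des)[cbind(pa$i, pa$j)]
    p <- pland_moving_window(rast, truth$class_id, truth$window)
    surf <- transform_surface(p, transform_spec(truth$transform))
    D <- commute_distance(build_graph(surf), pts)
    cc <- expand_to_individuals(D, des)[cbind(pa$i, pa$j)]
    x <- as.numeric(scale(residualize(cc, GD)))
    y_mat <- simulate_pairwise_distances(
      des, x, truth = list(beta0 = 0, beta = truth$beta,
                           sigma_u = truth$sigma_u,
                           sigma_e = truth$sigma_e),
      seed = s + 1L
    )
    pa_key <- paste(pa$i, pa$j)
    add_gd <- truth$gd_beta * as.numeric(scale(GD))
    schemes <- build_scheme_datasets(des, small, sparse_threshold = 2500)
    signs <- vapply(schemes, function(sc) {
      pm <- sc$pairs
      # scheme pairs index into the full individual table
      key <- paste(match(pm$id_i, des$individuals$id),
                   match(pm$id_j, des$individuals$id))
      rowsel <- match(key, pa_key)
      y <- y_mat[cbind(match(pm$id_i, des$individuals$id),
                       match(pm$id_j, des$individuals$id))] + add_gd[rowsel]
      xr <- residualize(cc[rowsel], GD[rowsel])
      d <- data.frame(y = y, GD = GD[rowsel], x = xr)
      fit <- mlpe(y ~ GD + x, d, cbind(pm$id_i, pm$id_j))
      unname(ifelse(fit$coefficients["x"] > 0, "+", "-"))
    }, character(1))
    rows[[r]] <- data.frame(
      replicate = r, sign_sl = signs[["sparse_large"]],
      sign_ds = signs[["dense_small"]], sign_ss = signs[["sparse_small"]],
      code = classify_congruence(signs[["sparse_large"]],
                                 signs[["dense_small"]],
                                 signs[["sparse_small"]]),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
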