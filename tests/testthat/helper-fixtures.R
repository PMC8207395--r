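# Shared small fixtures, built in code.

tiny_extent <- c(xmin = 0, xmax = 6000, ymin = 0, ymax = 6000)

tiny_design <- function(seed = 2, n_locations = 10, min_spacing = 900,
                        n_per_location = 3) {
  place_sampling_design(tiny_extent, n_locations, min_spacing,
                        n_per_location, seed = seed)
}

tiny_raster <- function(seed = 1, n = 60, n_classes = 5, smoothing = 3) {
  generate_landscape(seed, n, n, cell_size = 100, n_classes = n_classes,
                     smoothing = smoothing)
}

# genotype table with known allele structure, 3 individuals, 2 loci
hand_genotypes <- function() {
  ind <- data.frame(id = c("a", "b", "c"),
                    location_id = c("L1", "L1", "L2"),
                    x = c(0, 0, 1000), y = c(0, 0, 0),
                    stringsAsFactors = FALSE)
  am <- rbind(c(100L, 100L, 200L, 202L),
              c(100L, 102L, 200L, 200L),
              c(102L, 104L, NA, NA))
  genotype_table(ind, am, loci = c("A", "B"))
}

# dense multivariate-normal log-likelihood for the MLPE model
dense_mlpe_loglik <- function(y, X, beta, sigma_u2, sigma_e2, pairs) {
  ids <- sort(unique(c(pairs[, 1], pairs[, 2])))
  n <- length(y)
  Z <- matrix(0, n, length(ids))
  Z[cbind(seq_len(n), match(pairs[, 1], ids))] <- 1
  Z[cbind(seq_len(n), match(pairs[, 2], ids))] <- 1
  V <- sigma_u2 * tcrossprod(Z) + sigma_e2 * diag(n)
  r <- y - X %*% beta
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus +
            t(r) %*% solve(V, r))[1]
}

# profile the dense likelihood at a given theta (ML in beta, sigma_e2)
dense_profile_loglik <- function(y, X, theta, pairs) {
  ids <- sort(unique(c(pairs[, 1], pairs[, 2])))
  n <- length(y)
  Z <- matrix(0, n, length(ids))
  Z[cbind(seq_len(n), match(pairs[, 1], ids))] <- 1
  Z[cbind(seq_len(n), match(pairs[, 2], ids))] <- 1
  W <- theta * tcrossprod(Z) + diag(n)
  Wi <- solve(W)
  beta <- solve(t(X) %*% Wi %*% X, t(X) %*% Wi %*% y)
  r <- y - X %*% beta
  se2 <- as.numeric(t(r) %*% Wi %*% r) / n
  -n / 2 * (log(2 * pi) + log(se2) + 1) -
    0.5 * determinant(W, logarithm = TRUE)$modulus[1]
}

# a small simulated MLPE dataset over a design
simulated_pairs <- function(design, beta = 2, sigma_u = 0.3,
                            sigma_e = 0.5, seed = 9) {
  pa <- enumerate_pairs(design, exclude_within_location = FALSE)
  withr::with_seed(seed, {
    x <- stats::rnorm(nrow(pa))
  })
  y_mat <- simulate_pairwise_distances(
    design, x, list(beta = beta, sigma_u = sigma_u, sigma_e = sigma_e),
    seed = seed + 1
  )
  pm <- enumerate_pairs(design)
  rowsel <- match(paste(pm$i, pm$j), paste(pa$i, pa$j))
  list(data = data.frame(y = y_mat[cbind(pm$i, pm$j)], x = x[rowsel]),
       pairs = cbind(pm$id_i, pm$id_j), pm = pm, pa = pa, x_all = x,
       y_mat = y_mat)
}
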