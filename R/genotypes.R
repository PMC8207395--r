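#' Genotype table constructor
#'
#' Individuals-by-loci diploid allele calls with site coordinates.
#' Alleles are integers (e.g. fragment lengths); a missing call must be
#' missing at both slots of a locus.
#'
#' @param ind data.frame with columns `id`, `location_id`, `x`, `y`.
#' @param alleles integer matrix, one row per individual and two columns
#'   per locus (`<locus>_1`, `<locus>_2`); `NA` for missing calls.
#' @param loci character vector of locus names.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ind, alleles, loci) {
  if (anyDuplicated(ind$id)) stop("duplicate individual id")
  if (ncol(alleles) != 2L * length(loci))
    stop("allele matrix must have two columns per locus")
  if (any(!is.finite(ind$x)) || any(!is.finite(ind$y)))
    stop("coordinates must be finite")
  for (k in seq_along(loci)) {
    a1 <- alleles[, 2L * k - 1L]; a2 <- alleles[, 2L * k]
    bad <- xor(is.na(a1), is.na(a2))
    if (any(bad))
      stop("locus ", loci[k], ": individual(s) ",
           paste(ind$id[bad], collapse = ", "),
           " have exactly one missing allele; calls must be missing pairwise")
  }
  colnames(alleles) <- paste0(rep(loci, each = 2L), "_", 1:2)
  structure(list(individuals = ind, alleles = alleles, loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$individuals), "individuals,",
      length(x$loci), "loci\n")
  miss <- mean(is.na(x$alleles[, seq(1, ncol(x$alleles), by = 2)])) * 100
  cat("missing locus-calls:", round(miss, 2), "%\n")
  invisible(x)
}

#' Write a genotype table as tabular text
#'
#' One row per individual: id, location, x, y, then two integer allele
#' columns per locus. Missing alleles are written as `NA`.
#'
#' @param g a [genotype_table].
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  df <- cbind(g$individuals[, c("id", "location_id", "x", "y")], g$alleles)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype table from tabular text
#'
#' Inverse of [write_genotypes()]: a write/read round trip returns an
#' identical table. Parse errors name the offending row and locus.
#'
#' @param path tab-separated file as written by [write_genotypes()].
#' @return A [genotype_table].
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no individuals in genotype file: ", path)
  fixed <- c("id", "location_id", "x", "y")
  if (!all(fixed %in% names(df)))
    stop("genotype file must have columns ", paste(fixed, collapse = ", "))
  acols <- setdiff(names(df), fixed)
  if (length(acols) %% 2L != 0L)
    stop("odd number of allele columns (", length(acols),
         "); need two per locus")
  loci <- unique(sub("_[12]$", "", acols))
  if (length(loci) * 2L != length(acols))
    stop("allele columns must come in <locus>_1/<locus>_2 pairs")
  am <- as.matrix(df[, paste0(rep(loci, each = 2L), "_", 1:2)])
  if (!is.numeric(am) || any(am != round(am), na.rm = TRUE))
    stop("non-integer allele call in genotype file")
  storage.mode(am) <- "integer"
  genotype_table(df[, fixed], am, loci)
}

#' Per-locus allele summaries
#'
#' Allele counts per locus (ignoring missing calls), mean number of
#' alleles per locus, and the percentage of missing locus-calls.
#'
#' @param g a [genotype_table].
#' @return List with `per_locus` (data.frame locus, n_alleles, n_missing),
#'   `mean_alleles_per_locus`, `percent_missing`.
#' @export
summarize_genotypes <- function(g) {
  if (nrow(g$individuals) < 1L) stop("no individuals")
  per <- lapply(seq_along(g$loci), function(k) {
    a <- c(g$alleles[, 2L * k - 1L], g$alleles[, 2L * k])
    n_miss <- sum(is.na(g$alleles[, 2L * k - 1L]))
    data.frame(locus = g$loci[k],
               n_alleles = length(unique(a[!is.na(a)])),
               n_missing = n_miss, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  total_calls <- nrow(g$individuals) * length(g$loci)
  list(
    per_locus = per,
    mean_alleles_per_locus = mean(per$n_alleles),
    percent_missing = 100 * sum(per$n_missing) / total_calls
  )
}

#' Simulate genotypes with resistance-driven spatial structure
#'
#' A stylized generative model (not a forward-time or coalescent
#' simulation): location-level allele frequencies are logistic-normal
#' deviations around shared baseline log-frequencies, spatially
#' correlated with correlation decaying exponentially in the commute
#' distance between locations on the supplied resistance surface;
#' `drift_scale` sets the deviation magnitude. Individuals are drawn as
#' Hardy-Weinberg samples from their location's frequencies.
#'
#' @param design a `sampling_design`.
#' @param surface a `resistance_surface` (or any [land_raster] with
#'   values >= 1) governing between-location genetic correlation.
#' @param n_loci number of loci.
#' @param alleles_per_locus alleles segregating per locus (>= 2).
#' @param drift_scale standard deviation of the location-level
#'   log-frequency deviations; 0 gives identical frequencies everywhere.
#' @param seed integer seed.
#' @param missing_rate probability a locus-call is missing.
#' @return A [genotype_table]; the per-location allele frequencies are
#'   attached as attribute `freqs` (list over loci of locations x alleles
#'   matrices, rows summing to 1).
#' @export
simulate_genotypes <- function(design, surface, n_loci = 8,
                               alleles_per_locus = 10, drift_scale = 1,
                               seed = 1, missing_rate = 0) {
  if (alleles_per_locus < 2) stop("alleles_per_locus must be at least 2")
  loc <- design$locations
  nl <- nrow(loc)
  g <- build_graph(surface)
  D <- commute_distance(g, loc[, c("x", "y")])
  if (nl > 1) {
    d0 <- mean(D[upper.tri(D)])
    C <- exp(-D / d0)
    L <- t(chol(C + diag(1e-8, nl)))
  } else {
    L <- matrix(1, 1, 1)
  }
  rng <- local_rng(seed)
  freqs <- vector("list", n_loci)
  A <- alleles_per_locus
  for (k in seq_len(n_loci)) {
    base <- rng$rnorm(A, 0, 1)                    # uneven baseline freqs
    dev <- L %*% matrix(rng$rnorm(nl * A), nl, A) * drift_scale
    eta <- sweep(dev, 2L, base, "+")
    f <- exp(eta)
    freqs[[k]] <- f / rowSums(f)
  }
  ind <- design$individuals
  n <- nrow(ind)
  loc_idx <- match(ind$location_id, loc$id)
  am <- matrix(NA_integer_, n, 2L * n_loci)
  allele_labels <- function(A) 100L + 2L * seq_len(A)  # microsat-like sizes
  for (k in seq_len(n_loci)) {
    f <- freqs[[k]]
    labs <- allele_labels(A)
    for (i in seq_len(n)) {
      draw <- rng$sample(A, 2L, replace = TRUE, prob = f[loc_idx[i], ])
      am[i, 2L * k - 1L] <- labs[draw[1L]]
      am[i, 2L * k] <- labs[draw[2L]]
    }
    if (missing_rate > 0) {
      miss <- rng$runif(n) < missing_rate
      am[miss, c(2L * k - 1L, 2L * k)] <- NA_integer_
    }
  }
  gt <- genotype_table(ind[, c("id", "location_id", "x", "y")], am,
                       loci = sprintf("loc%02d", seq_len(n_loci)))
  attr(gt, "freqs") <- freqs
  gt
}

#' Encode genotypes and compute PCA scores
#'
#' Builds the standard individual-based PCA encoding: one column per
#' observed allele per locus, with value (copies carried)/2 in
#' \{0, 0.5, 1\}; missing locus-calls are imputed with the column mean;
#' columns are mean-centred (optionally variance-scaled). Scores are the
#' projections onto the leading `min(n_axes, rank)` principal axes.
#'
#' @param g a [genotype_table].
#' @param n_axes number of ordination axes to retain (default 64, capped
#'   at the matrix rank).
#' @param scale. also scale columns to unit variance (default `FALSE`:
#'   centring only).
#' @return List of class `pca_scores`: `ids`, `scores` (individuals x
#'   axes), `eigenvalues` (variance per retained axis), `n_axes`.
#' @export
encode_and_pca <- function(g, n_axes = 64, scale. = FALSE) {
  if (n_axes < 1) stop("n_axes must be at least 1")
  if (nrow(g$individuals) < 2L) stop("need at least 2 individuals")
  X <- encode_dosage(g)
  if (all(is.na(X))) stop("all genotype calls missing")
  # mean imputation leaves complete columns untouched
  for (jj in which(colSums(is.na(X)) > 0L)) {
    m <- mean(X[, jj], na.rm = TRUE)
    X[is.na(X[, jj]), jj] <- if (is.nan(m)) 0 else m
  }
  if (scale.) {
    sds <- apply(X, 2L, stats::sd)
    keep <- sds > 0
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  rank <- sum(pc$sdev > pc$sdev[1L] * 1e-9)
  k <- min(n_axes, rank)
  structure(
    list(ids = g$individuals$id,
         scores = pc$x[, seq_len(k), drop = FALSE],
         eigenvalues = ev[seq_len(k)], n_axes = k),
    class = "pca_scores"
  )
}

# Dosage encoding: columns are (locus, allele) pairs; value = copies/2.
encode_dosage <- function(g) {
  n <- nrow(g$individuals)
  cols <- list()
  for (k in seq_along(g$loci)) {
    a1 <- g$alleles[, 2L * k - 1L]; a2 <- g$alleles[, 2L * k]
    alleles <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
    for (al in alleles) {
      v <- ((a1 == al) + (a2 == al)) / 2
      cols[[paste0(g$loci[k], ".", al)]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- g$individuals$id
  X
}

#' Euclidean genetic distance in PCA space
#'
#' Pairwise Euclidean distance between individuals over the retained
#' ordination axes: symmetric, zero-diagonal, non-negative, and (being
#' Euclidean) a metric.
#'
#' @param scores a `pca_scores` object from [encode_and_pca()].
#' @return A symmetric distance matrix with individual ids as dimnames.
#' @export
pca_distance <- function(scores) {
  if (any(!is.finite(scores$scores))) stop("non-finite PCA scores")
  d <- as.matrix(stats::dist(scores$scores))
  dimnames(d) <- list(scores$ids, scores$ids)
  d
}

#' Write / read a square distance matrix as tabular text
#'
#' @param d symmetric matrix with id dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(cbind(id = rownames(d), as.data.frame(d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  m
}
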