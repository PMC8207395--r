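#' Mantel correlogram of genetic against geographic distance
#'
#' Splits the off-diagonal pairs into `n_classes` equal-width geographic
#' distance classes over `(0, max(geo)]`. For class k the statistic is
#' minus the Pearson correlation between the genetic distances and the
#' 0/1 within-class indicator, so that positive r means individuals
#' within the class are more similar than average (positive spatial
#' autocorrelation). Significance comes from permuting individual labels
#' of the genetic matrix; the default test is one-sided on |r|. Holm
#' adjustment across classes is reported alongside raw p-values.
#'
#' @param gd symmetric genetic-distance matrix.
#' @param geo symmetric geographic-distance matrix (same individuals).
#' @param n_classes number of distance classes (default 30).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param alpha significance level recorded in the output.
#' @param min_spacing optional smallest between-location distance; a
#'   warning is issued if the class width exceeds it.
#' @return data.frame of class `mantel_correlogram`: one row per class
#'   with `class`, `lower`, `upper`, `midpoint`, `n_pairs`, `mantel_r`,
#'   `p_raw`, `p_adjusted`, `significant`.
#' @export
mantel_correlogram <- function(gd, geo, n_classes = 30, n_perm = 999,
                               seed = 1, alpha = 0.05,
                               min_spacing = NULL) {
  check_dist_pair(gd, geo)
  if (n_classes < 2) stop("need at least 2 distance classes")
  n <- nrow(gd)
  lt <- lower.tri(gd)
  gvec <- gd[lt]
  dvec <- geo[lt]
  width <- max(dvec) / n_classes
  if (!is.null(min_spacing) && width > min_spacing)
    warning("class width (", round(width), " m) exceeds the minimum ",
            "site spacing (", min_spacing, " m)")
  cls <- pmin(pmax(ceiling(dvec / width), 1L), n_classes)
  if (length(unique(cls)) < 2L) stop("all pairs fall in one distance class")
  N <- length(gvec)
  n_k <- tabulate(cls, n_classes)
  mx <- mean(gvec); sx <- stats::sd(gvec)
  sd_ind <- sqrt(n_k / (N - 1) * (1 - n_k / N))        # sd of 0/1 indicator
  r_from_sums <- function(S) {
    # cor(x, I_k) from per-class sums of x; sign flipped
    r <- (S - n_k * mx) / ((N - 1) * sx * sd_ind)
    -r
  }
  class_sums <- function(x) {
    S <- numeric(n_classes)
    agg <- rowsum(x, cls)
    S[as.integer(rownames(agg))] <- agg
    S
  }
  r_obs <- r_from_sums(class_sums(gvec))
  rng <- local_rng(seed)
  exceed <- integer(n_classes)
  for (b in seq_len(n_perm)) {
    p <- rng$sample(n)
    r_p <- r_from_sums(class_sums(gd[p, p][lt]))
    exceed <- exceed + (abs(r_p) >= abs(r_obs) - 1e-12)
  }
  p_raw <- (exceed + 1) / (n_perm + 1)
  defined <- n_k > 0 & n_k < N
  p_raw[!defined] <- NA
  r_obs[!defined] <- NA
  p_adj <- rep(NA_real_, n_classes)
  p_adj[defined] <- stats::p.adjust(p_raw[defined], method = "holm")
  out <- data.frame(
    class = seq_len(n_classes),
    lower = (seq_len(n_classes) - 1) * width,
    upper = seq_len(n_classes) * width,
    midpoint = (seq_len(n_classes) - 0.5) * width,
    n_pairs = n_k,
    mantel_r = r_obs,
    p_raw = p_raw,
    p_adjusted = p_adj,
    significant = !is.na(p_raw) & p_raw <= alpha & r_obs > 0
  )
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}

check_dist_pair <- function(gd, geo) {
  if (!isTRUE(all.equal(dim(gd), dim(geo))))
    stop("distance matrices must have identical dimensions")
  if (nrow(gd) != ncol(gd)) stop("distance matrices must be square")
  if (max(abs(gd - t(gd))) > 1e-8 || max(abs(geo - t(geo))) > 1e-8)
    stop("distance matrices must be symmetric")
}

#' Semivariogram of genetic distance
#'
#' Bins pairs into contiguous fixed-interval geographic lag classes and
#' reports the empirical semivariance
#' `gamma(h) = sum(gd^2) / (2 * n_pairs)` per bin. Pairs beyond
#' `n_bins * interval` are dropped; empty bins are reported with
#' `n_pairs = 0` and `gamma = NA`.
#'
#' @param gd,geo symmetric distance matrices over the same individuals.
#' @param interval lag width in meters (default 1500).
#' @param n_bins number of lag bins (default 52).
#' @return data.frame with `bin`, `lower`, `upper`, `midpoint`,
#'   `n_pairs`, `gamma`.
#' @export
semivariogram <- function(gd, geo, interval = 1500, n_bins = 52) {
  check_dist_pair(gd, geo)
  if (interval <= 0) stop("interval must be positive")
  lt <- lower.tri(gd)
  gvec <- gd[lt]; dvec <- geo[lt]
  bin <- ceiling(dvec / interval)
  bin[dvec == 0] <- 1L
  keep <- bin <= n_bins
  bin <- bin[keep]; gvec <- gvec[keep]
  n_k <- tabulate(bin, n_bins)
  ss <- numeric(n_bins)
  if (length(bin)) {
    agg <- rowsum(gvec^2, bin)
    ss[as.integer(rownames(agg))] <- agg
  }
  out <- data.frame(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) * interval,
    upper = seq_len(n_bins) * interval,
    midpoint = (seq_len(n_bins) - 0.5) * interval,
    n_pairs = n_k,
    gamma = ifelse(n_k > 0, ss / (2 * n_k), NA_real_)
  )
  class(out) <- c("semivariogram", "data.frame")
  out
}

#' @export
plot.mantel_correlogram <- function(x, ...) {
  graphics::plot(x$midpoint / 1000, x$mantel_r, type = "b", pch = 21,
                 bg = ifelse(x$significant, "black", "white"),
                 xlab = "distance class midpoint (km)",
                 ylab = "Mantel r", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
plot.semivariogram <- function(x, ...) {
  ok <- x$n_pairs > 0
  graphics::plot(x$midpoint[ok] / 1000, x$gamma[ok], type = "b", pch = 19,
                 xlab = "lag midpoint (km)", ylab = "semivariance", ...)
  invisible(x)
}

#' Genetic neighborhood size from a Mantel correlogram
#'
#' The largest distance class with positive and significant Mantel r;
#' its upper bound is the neighborhood-size estimate (the midpoint is
#' also reported). Returns `NULL` when no class qualifies.
#'
#' @param classes a `mantel_correlogram` data.frame.
#' @param alpha significance level (default 0.05).
#' @param use_adjusted test on Holm-adjusted p-values instead of raw
#'   (default `FALSE`).
#' @return List with `upper`, `midpoint`, `class`, or `NULL`.
#' @export
neighborhood_size <- function(classes, alpha = 0.05,
                              use_adjusted = FALSE) {
  if (nrow(classes) == 0L) stop("empty correlogram")
  p <- if (use_adjusted) classes$p_adjusted else classes$p_raw
  ok <- which(!is.na(p) & p <= alpha & classes$mantel_r > 0)
  if (length(ok) == 0L) return(NULL)
  k <- max(ok)
  list(upper = classes$upper[k], midpoint = classes$midpoint[k], class = k)
}
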