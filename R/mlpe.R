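#' Fit a maximum-likelihood population effects (MLPE) model
#'
#' Fits the linear mixed model for pairwise distance data
#' `y_ij = x_ij' beta + u_i + u_j + e_ij`, with one random effect per
#' individual appearing in a pair (`u ~ N(0, sigma_u^2)`) and independent
#' pair-level noise (`e ~ N(0, sigma_e^2)`). Pairs sharing one individual
#' are correlated with `rho = sigma_u^2 / (2 sigma_u^2 + sigma_e^2)`
#' (bounded above by 0.5). Estimation maximises the full ML Gaussian
#' likelihood (not REML, so AICc comparisons across fixed-effect sets are
#' valid) by profiling `beta` and `sigma_e^2` out in closed form and
#' optimising the single ratio `theta = sigma_u^2 / sigma_e^2`
#' numerically; the n-by-n covariance is never formed thanks to the
#' Woodbury identity on `I + theta Z Z'`.
#'
#' @param formula model formula; the response is the pairwise (genetic)
#'   distance, predictors are pair-level columns such as the homogeneous
#'   commute distance and residualized resistance predictors.
#' @param data data.frame of pair rows.
#' @param pairs two-column matrix or data.frame giving the two individual
#'   ids of each pair (same row order as `data`).
#' @param standardize z-score the non-intercept predictor columns before
#'   fitting (default `TRUE`), making coefficients comparable in
#'   magnitude across predictors.
#' @param theta_max upper bound for the variance-ratio search.
#' @return An object of class `mlpe` with components `coefficients`,
#'   `sigma_u2`, `sigma_e2`, `rho`, `theta`, `logLik`, `k` (parameter
#'   count: fixed effects + 2 variances), `n`, `aicc`, `fitted.values`,
#'   `residuals`, plus bookkeeping for the methods.
#' @seealso [AICc()], [optimize_surface()], [rank_model_set()],
#'   [simulate_pairwise_distances()]
#' @examples
#' d <- data.frame(y = rnorm(6), x = rnorm(6))
#' p <- t(combn(4, 2))
#' fit <- mlpe(y ~ x, d, p)
#' coef(fit); AICc(fit)
#' @export
mlpe <- function(formula, data, pairs, standardize = TRUE,
                 theta_max = 1e3) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) != n) stop("`pairs` must have one row per data row")
  if (n <= ncol(X) + 1L)
    stop("need more pairs (", n, ") than parameters (", ncol(X) + 1L, ")")
  scale_info <- NULL
  if (standardize && ncol(X) > 1L) {
    keep <- colnames(X) != "(Intercept)"
    ctr <- colMeans(X[, keep, drop = FALSE])
    scl <- apply(X[, keep, drop = FALSE], 2L, stats::sd)
    if (any(scl == 0)) stop("constant predictor column: ",
                            paste(colnames(X)[keep][scl == 0], collapse = ", "))
    X[, keep] <- scale(X[, keep, drop = FALSE], center = ctr, scale = scl)
    scale_info <- list(center = ctr, scale = scl)
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed-effect matrix")
  ids <- sort(unique(c(as.character(pairs[, 1L]), as.character(pairs[, 2L]))))
  m <- length(ids)
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 2L),
    j = c(match(as.character(pairs[, 1L]), ids),
          match(as.character(pairs[, 2L]), ids)),
    x = 1, dims = c(n, m)
  )
  ZtZ <- as.matrix(Matrix::crossprod(Z))
  ZtX <- as.matrix(Matrix::crossprod(Z, X))
  Zty <- as.numeric(Matrix::crossprod(Z, y))
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y * y)
  p <- ncol(X)

  # Profile negative log-likelihood in theta via Woodbury:
  # W = I + theta ZZ', W^-1 = I - theta Z A^-1 Z', A = I_m + theta Z'Z,
  # log|W| = log|A|.
  profile_fit <- function(theta) {
    if (theta == 0) {
      XtWiX <- XtX; XtWiy <- Xty; yWiy <- yty; ldet <- 0
    } else {
      A <- diag(m) + theta * ZtZ
      cA <- chol(A)
      ldet <- 2 * sum(log(diag(cA)))
      AiZtX <- backsolve(cA, forwardsolve(t(cA), ZtX))
      AiZty <- backsolve(cA, forwardsolve(t(cA), Zty))
      XtWiX <- XtX - theta * crossprod(ZtX, AiZtX)
      XtWiy <- Xty - theta * crossprod(ZtX, AiZty)
      yWiy <- yty - theta * sum(Zty * AiZty)
    }
    beta <- solve(XtWiX, XtWiy)
    rss <- as.numeric(yWiy - crossprod(XtWiy, beta))
    sigma_e2 <- max(rss / n, 1e-300)
    ll <- -n / 2 * (log(2 * pi) + log(sigma_e2) + 1) - ldet / 2
    list(beta = as.numeric(beta), sigma_e2 = sigma_e2, logLik = ll,
         XtWiX = XtWiX)
  }
  nll <- function(theta) -profile_fit(theta)$logLik
  opt <- stats::optimize(nll, interval = c(0, theta_max), tol = 1e-9)
  theta <- opt$minimum
  if (nll(0) <= opt$objective) theta <- 0
  if (theta > 0.99 * theta_max)
    warning("variance ratio estimate at the search boundary (",
            signif(theta, 3), "); increase theta_max")
  fit <- profile_fit(theta)
  beta <- fit$beta
  names(beta) <- colnames(X)
  sigma_e2 <- fit$sigma_e2
  sigma_u2 <- theta * sigma_e2
  k <- p + 2L
  fitted <- as.numeric(X %*% beta)
  out <- list(
    coefficients = beta,
    sigma_u2 = sigma_u2,
    sigma_e2 = sigma_e2,
    rho = sigma_u2 / (2 * sigma_u2 + sigma_e2),
    theta = theta,
    logLik = fit$logLik,
    k = k, n = n, n_individuals = m,
    aicc = aicc(fit$logLik, k, n),
    fitted.values = fitted,
    residuals = y - fitted,
    XtWiX = fit$XtWiX,
    standardize = standardize,
    scale_info = scale_info,
    terms = attr(mf, "terms"),
    pair_ids = ids,
    pairs = pairs,
    call = cl
  )
  class(out) <- "mlpe"
  out
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; requires `n > k + 1`.
#'
#' @param log_likelihood maximised log-likelihood (or an `mlpe` fit for
#'   the generic).
#' @param k number of estimated parameters.
#' @param n sample size (pairs).
#' @return AICc value.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) stop("AICc undefined: n (", n, ") must exceed k + 1 (",
                       k + 1, ")")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @param object a fitted `mlpe` model.
#' @param ... unused.
#' @export
AICc <- function(object, ...) UseMethod("AICc")

#' @export
AICc.mlpe <- function(object, ...) object$aicc

#' @export
print.mlpe <- function(x, ...) {
  cat("MLPE model (", x$n, " pairs, ", x$n_individuals, " individuals)\n",
      sep = "")
  cat("Coefficients",
      if (x$standardize) " (standardized predictors)" else "", ":\n",
      sep = "")
  print(round(x$coefficients, 4))
  cat("sigma_u^2 =", signif(x$sigma_u2, 4),
      " sigma_e^2 =", signif(x$sigma_e2, 4),
      " rho =", round(x$rho, 4), "\n")
  cat("logLik =", round(x$logLik, 2), " AICc =", round(x$aicc, 2),
      " (k =", x$k, ")\n")
  invisible(x)
}

#' @export
summary.mlpe <- function(object, ...) {
  se <- sqrt(diag(vcov(object)))
  z <- object$coefficients / se
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 `z value` = z,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = coefs, sigma_u2 = object$sigma_u2,
              sigma_e2 = object$sigma_e2, rho = object$rho,
              logLik = object$logLik, aicc = object$aicc,
              k = object$k, n = object$n,
              n_individuals = object$n_individuals, call = object$call)
  class(out) <- "summary.mlpe"
  out
}

#' @export
print.summary.mlpe <- function(x, ...) {
  cat("MLPE model fit by profiled maximum likelihood\n")
  cat("Call: "); print(x$call)
  cat("\nFixed effects:\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nRandom effects: individual sigma_u^2 =", signif(x$sigma_u2, 4),
      "; residual sigma_e^2 =", signif(x$sigma_e2, 4), "\n")
  cat("Correlation of pairs sharing an individual: rho =",
      round(x$rho, 4), "\n")
  cat("logLik =", round(x$logLik, 2), "; AICc =", round(x$aicc, 2),
      "(k =", x$k, ", n =", x$n, "pairs)\n")
  invisible(x)
}

#' @export
coef.mlpe <- function(object, ...) object$coefficients

#' @export
logLik.mlpe <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.mlpe <- function(object, ...) object$n

#' @export
vcov.mlpe <- function(object, ...) {
  V <- object$sigma_e2 * solve(object$XtWiX)
  dimnames(V) <- list(names(object$coefficients),
                      names(object$coefficients))
  V
}

#' @export
fitted.mlpe <- function(object, ...) object$fitted.values

#' @export
residuals.mlpe <- function(object, ...) object$residuals

#' @export
predict.mlpe <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  if (!is.null(object$scale_info)) {
    keep <- colnames(X) != "(Intercept)"
    X[, keep] <- scale(X[, keep, drop = FALSE],
                       center = object$scale_info$center,
                       scale = object$scale_info$scale)
  }
  as.numeric(X %*% object$coefficients)
}

#' @export
plot.mlpe <- function(x, ...) {
  graphics::plot(x$fitted.values, x$residuals,
                 xlab = "fitted pairwise distance",
                 ylab = "marginal residual", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' @export
simulate.mlpe <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ids <- object$pair_ids
  i1 <- match(as.character(object$pairs[, 1L]), ids)
  i2 <- match(as.character(object$pairs[, 2L]), ids)
  out <- as.data.frame(replicate(nsim, {
    u <- stats::rnorm(length(ids), 0, sqrt(object$sigma_u2))
    object$fitted.values + u[i1] + u[i2] +
      stats::rnorm(object$n, 0, sqrt(object$sigma_e2))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Simulate pairwise distances under the MLPE generative model
#'
#' Generates `y_ij = beta0 + beta * x_ij + u_i + u_j + e_ij` over all
#' unordered pairs of individuals in a design, with per-individual
#' random effects `u ~ N(0, sigma_u^2)` and pair noise
#' `e ~ N(0, sigma_e^2)`. The generative mirror of the model [mlpe()]
#' fits.
#'
#' @param design a `sampling_design`.
#' @param x numeric vector of predictor values, one per unordered pair in
#'   the order of [enumerate_pairs()]`(design, exclude_within_location
#'   = FALSE)` (typically standardized).
#' @param truth list with `beta0` (default 0), `beta`, `sigma_u`,
#'   `sigma_e`.
#' @param seed integer seed.
#' @return Symmetric matrix of simulated distances over individuals
#'   (zero diagonal), dimnames = individual ids.
#' @export
simulate_pairwise_distances <- function(design, x, truth, seed = 1) {
  stopifnot(is.list(truth), !is.null(truth$beta),
            !is.null(truth$sigma_u), !is.null(truth$sigma_e))
  if (truth$sigma_u < 0 || truth$sigma_e <= 0)
    stop("sigma_u must be >= 0 and sigma_e > 0")
  beta0 <- if (is.null(truth$beta0)) 0 else truth$beta0
  pairs <- enumerate_pairs(design, exclude_within_location = FALSE)
  if (length(x) != nrow(pairs))
    stop("predictor length (", length(x), ") does not match pair count (",
         nrow(pairs), ")")
  ind <- design$individuals
  rng <- local_rng(seed)
  u <- rng$rnorm(nrow(ind), 0, truth$sigma_u)
  e <- rng$rnorm(nrow(pairs), 0, truth$sigma_e)
  yv <- beta0 + truth$beta * x + u[pairs$i] + u[pairs$j] + e
  n <- nrow(ind)
  y <- matrix(0, n, n, dimnames = list(ind$id, ind$id))
  y[cbind(pairs$i, pairs$j)] <- yv
  y[cbind(pairs$j, pairs$i)] <- yv
  y
}
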