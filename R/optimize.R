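#' Optimize the scale and transformation of one land-use class
#'
#' Fits one single-predictor MLPE model (homogeneous distance `GD` plus
#' one candidate residualized predictor) per candidate surface and
#' returns the candidate with the lowest AICc as the optimized (window
#' side, transformation) for the class. Ties are broken by smaller
#' window then the fixed family order of [transform_families()], and
#' flagged.
#'
#' @param y response vector (genetic distance per pair).
#' @param candidates named list or data.frame of residualized candidate
#'   predictor columns; names like `w250_inverse_ricker` (as produced by
#'   [candidate_surfaces()] labels).
#' @param gd homogeneous-landscape commute distance per pair.
#' @param pairs two-column matrix of individual ids per pair.
#' @return List of class `surface_optimization`: `window`, `transform`,
#'   `label`, `fit` (the winning `mlpe`), `leaderboard` (data.frame with
#'   one row per candidate: label, window, transform, logLik, aicc,
#'   beta), `tie` flag, `failures`.
#' @export
optimize_surface <- function(y, candidates, gd, pairs) {
  candidates <- as.data.frame(candidates, optional = TRUE)
  labs <- names(candidates)
  rows <- vector("list", length(labs))
  fits <- vector("list", length(labs))
  failures <- character(0)
  for (ii in seq_along(labs)) {
    d <- data.frame(y = y, GD = gd, x = candidates[[ii]])
    fit <- tryCatch(mlpe(y ~ GD + x, d, pairs),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("candidate ", labs[ii], " failed: ", conditionMessage(fit))
      failures <- c(failures, labs[ii])
      next
    }
    fits[[ii]] <- fit
    rows[[ii]] <- data.frame(
      label = labs[ii],
      window = parse_label(labs[ii])$window,
      transform = parse_label(labs[ii])$family,
      logLik = fit$logLik, aicc = fit$aicc,
      beta = unname(fit$coefficients["x"]),
      stringsAsFactors = FALSE
    )
  }
  lb <- do.call(rbind, rows)
  if (is.null(lb) || nrow(lb) == 0L) stop("all candidate fits failed")
  fam_order <- match(lb$transform, transform_families())
  o <- order(lb$aicc, lb$window, fam_order)
  lb <- lb[o, ]
  rownames(lb) <- NULL
  tie <- nrow(lb) > 1L && isTRUE(abs(lb$aicc[2L] - lb$aicc[1L]) < 1e-8)
  win_idx <- which(labs == lb$label[1L])
  structure(
    list(window = lb$window[1L], transform = lb$transform[1L],
         label = lb$label[1L], fit = fits[[win_idx]],
         leaderboard = lb, tie = tie, failures = failures),
    class = "surface_optimization"
  )
}

#' @export
print.surface_optimization <- function(x, ...) {
  cat("optimized surface:", x$label, "(window", x$window, "m,",
      x$transform, ")\n")
  cat("AICc =", round(x$leaderboard$aicc[1L], 2), "over",
      nrow(x$leaderboard), "candidates",
      if (x$tie) "[tie flagged]" else "", "\n")
  invisible(x)
}

parse_label <- function(label) {
  m <- regmatches(label, regexec("^w([0-9]+)_(.+)$", label))[[1L]]
  if (length(m) == 3L) list(window = as.numeric(m[2L]), family = m[3L])
  else list(window = NA_real_, family = label)
}

#' Default ten-model comparison set
#'
#' The standard comparison set for five land-use predictors given in
#' canonical order (agriculture, hardwoods, pine, manmade structures,
#' wetlands): the full model, isolation by distance (homogeneous
#' distance only), three ecological combinations (moderate habitat =
#' agriculture + pine; modified habitat = agriculture + manmade; forest
#' cover = pine + hardwoods + wetlands), and the five univariate models.
#' Every model also includes the homogeneous distance `GD`.
#'
#' @param classes character vector of five class names, canonical order.
#' @return Named list of character vectors (predictor subsets).
#' @export
default_model_set <- function(classes) {
  if (length(classes) != 5L)
    stop("the default model set needs exactly 5 classes in canonical ",
         "order (agriculture, hardwoods, pine, manmade, wetlands); ",
         "supply `specs` for other layouts")
  sets <- list(
    "Full model" = classes,
    "Isolation by distance" = character(0),
    "Moderate habitat" = classes[c(1L, 3L)],
    "Modified habitat" = classes[c(1L, 4L)],
    "Forest cover" = classes[c(3L, 2L, 5L)]
  )
  uni <- stats::setNames(as.list(classes), paste(classes, "only"))
  c(sets, uni)
}

#' Fit and rank the ten-model MLPE comparison set
#'
#' Fits each model (always including the homogeneous distance `GD`) to
#' the pairwise response and ranks by AICc ascending.
#'
#' @param y response vector per pair.
#' @param predictors named data.frame/list of optimized residualized
#'   predictor columns, one per retained class.
#' @param gd homogeneous commute distance per pair.
#' @param pairs two-column matrix of individual ids per pair.
#' @param specs named list of predictor subsets; defaults to
#'   [default_model_set()] over `names(predictors)`.
#' @return List of class `model_ranking`: `leaderboard` (model, k,
#'   logLik, aicc, delta_aicc, rank), `fits` (named list of `mlpe`
#'   objects), `best` (name of the top model).
#' @export
rank_model_set <- function(y, predictors, gd, pairs, specs = NULL) {
  predictors <- as.data.frame(predictors, optional = TRUE)
  if (is.null(specs)) specs <- default_model_set(names(predictors))
  missing <- setdiff(unique(unlist(specs)), names(predictors))
  if (length(missing))
    stop("model set needs optimized predictor(s) not supplied: ",
         paste(missing, collapse = ", "))
  fits <- list()
  rows <- list()
  for (nm in names(specs)) {
    vars <- specs[[nm]]
    d <- data.frame(y = y, GD = gd)
    for (v in vars) d[[v]] <- predictors[[v]]
    fml <- stats::reformulate(c("GD", vars), response = "y")
    fit <- mlpe(fml, d, pairs)
    fits[[nm]] <- fit
    rows[[nm]] <- data.frame(model = nm, k = fit$k, logLik = fit$logLik,
                             aicc = fit$aicc, stringsAsFactors = FALSE)
  }
  lb <- do.call(rbind, rows)
  lb <- lb[order(lb$aicc), ]
  lb$delta_aicc <- lb$aicc - lb$aicc[1L]
  lb$rank <- seq_len(nrow(lb))
  rownames(lb) <- NULL
  structure(list(leaderboard = lb, fits = fits, best = lb$model[1L]),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("MLPE model ranking (", nrow(x$leaderboard), " models)\n", sep = "")
  print(transform(x$leaderboard, logLik = round(logLik, 2),
                  aicc = round(aicc, 2),
                  delta_aicc = round(delta_aicc, 2)), row.names = FALSE)
  invisible(x)
}

#' Sign, label and rank of each land-use effect
#'
#' From a fitted model, reports for each land-use predictor (the
#' intercept and `GD` are excluded) the sign of its standardized
#' coefficient, the corresponding gene-flow label (positive =
#' restriction, negative = facilitation), and its rank by absolute
#' coefficient, largest first. Exact ties are broken by class name and
#' flagged; an exactly-zero coefficient gets sign `"0"` and ranks last.
#'
#' @param fit an `mlpe` fit.
#' @return data.frame with `class`, `coefficient`, `sign`, `label`,
#'   `rank`; attribute `ties`.
#' @export
effect_signs <- function(fit) {
  co <- fit$coefficients
  co <- co[!(names(co) %in% c("(Intercept)", "GD"))]
  if (length(co) == 0L) stop("model has no land-use predictors")
  sgn <- ifelse(co > 0, "+", ifelse(co < 0, "-", "0"))
  lab <- ifelse(co > 0, "restriction", ifelse(co < 0, "facilitation", "none"))
  key <- abs(co)
  key[co == 0] <- -Inf                          # exact zeros rank last
  o <- order(-key, names(co))
  ties <- anyDuplicated(key[key > -Inf]) > 0L
  out <- data.frame(class = names(co)[o], coefficient = unname(co)[o],
                    sign = unname(sgn)[o], label = unname(lab)[o],
                    rank = seq_along(co), stringsAsFactors = FALSE)
  attr(out, "ties") <- ties
  out
}
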