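#' Classify congruence of a criterion across the three nested schemes
#'
#' Given the value of one categorical criterion (rank position, sign,
#' optimized window, or transformation label) observed under the
#' Sparse-Large (SL), Dense-Small (DS) and Sparse-Small (SS) schemes,
#' returns the outcome code:
#' \describe{
#'   \item{A}{all three equal — inferences insensitive to sampling
#'     density and study area size;}
#'   \item{B}{SL = SS but DS differs — sampling density drives outcomes
#'     (the two sparse datasets agree);}
#'   \item{C}{DS = SS but SL differs — study area size drives outcomes
#'     (the two small-area datasets agree);}
#'   \item{D}{SL = DS but SS differs — total sampling effort (pair
#'     count) drives outcomes, possibly a threshold effect;}
#'   \item{E}{all three differ — combined effects.}
#' }
#' Similarity is exact categorical equality.
#'
#' @param sl,ds,ss the criterion value under each scheme (length-1
#'   atomic values of a shared domain).
#' @return A single character, one of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @export
classify_congruence <- function(sl, ds, ss) {
  vals <- c(sl, ds, ss)
  if (length(vals) != 3L || anyNA(vals))
    stop("need exactly three non-missing values")
  if (sl == ds && ds == ss) return("A")
  if (sl == ss && sl != ds) return("B")
  if (ds == ss && sl != ds) return("C")
  if (sl == ds && ds != ss) return("D")
  "E"
}

#' Congruence report across the three nested schemes
#'
#' Crosses the best-fit model summaries of the three schemes and codes
#' every land-use class by every criterion (rank, sign, scale,
#' transformation) with [classify_congruence()]. Sign is a binary trait,
#' so outcome E (all three distinct) is impossible for it; the `E`
#' column of the sign criterion is reported as `NA` by construction.
#'
#' @param sl,ds,ss per-scheme summaries: each a data.frame with columns
#'   `class`, `rank`, `sign`, `scale`, `transform` (one row per land-use
#'   class). `rank`/`sign` typically come from [effect_signs()] on the
#'   best-fit model, `scale`/`transform` from [optimize_surface()].
#' @return data.frame of class `congruence_report`: one row per class
#'   with the three observed values and the outcome code per criterion
#'   (`rank_code`, `sign_code`, `scale_code`, `transform_code`).
#' @export
comparison_report <- function(sl, ds, ss) {
  need <- c("class", "rank", "sign", "scale", "transform")
  for (d in list(sl, ds, ss))
    if (!all(need %in% names(d)))
      stop("each scheme summary needs columns ",
           paste(need, collapse = ", "))
  classes <- sort(unique(sl$class))
  for (d in list(ds, ss))
    if (!setequal(d$class, classes))
      stop("schemes disagree on the set of land-use classes")
  rows <- lapply(classes, function(cl) {
    v <- lapply(list(sl, ds, ss), function(d) d[d$class == cl, ])
    codes <- vapply(c("rank", "sign", "scale", "transform"), function(cr)
      classify_congruence(v[[1L]][[cr]], v[[2L]][[cr]], v[[3L]][[cr]]),
      character(1))
    data.frame(
      class = cl,
      rank_sl = v[[1]]$rank, rank_ds = v[[2]]$rank, rank_ss = v[[3]]$rank,
      rank_code = codes[["rank"]],
      sign_sl = v[[1]]$sign, sign_ds = v[[2]]$sign, sign_ss = v[[3]]$sign,
      sign_code = codes[["sign"]],
      scale_sl = v[[1]]$scale, scale_ds = v[[2]]$scale,
      scale_ss = v[[3]]$scale, scale_code = codes[["scale"]],
      transform_sl = v[[1]]$transform, transform_ds = v[[2]]$transform,
      transform_ss = v[[3]]$transform, transform_code = codes[["transform"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("congruence_report", "data.frame")
  out
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("Congruence of best-fit models across nested schemes\n")
  m <- as.matrix(x[, c("rank_code", "sign_code", "scale_code",
                       "transform_code")])
  dimnames(m) <- list(x$class, c("rank", "sign", "scale", "transform"))
  print(m, quote = FALSE)
  cat("codes: A insensitive; B density-driven; C area-size-driven;\n",
      "       D effort/threshold-driven; E combined effects\n", sep = "")
  invisible(x)
}

#' Summarize one scheme's fits for the congruence report
#'
#' Combines [effect_signs()] output from the scheme's best-fit model
#' with the optimized scale and transformation of each class.
#'
#' @param signs data.frame from [effect_signs()].
#' @param optimized named list of `surface_optimization` objects, one per
#'   class (names matching `signs$class`).
#' @return data.frame with `class`, `rank`, `sign`, `scale`, `transform`.
#' @export
scheme_summary <- function(signs, optimized) {
  if (!all(signs$class %in% names(optimized)))
    stop("missing optimized surface for class(es): ",
         paste(setdiff(signs$class, names(optimized)), collapse = ", "))
  data.frame(
    class = signs$class,
    rank = signs$rank,
    sign = signs$sign,
    scale = vapply(optimized[signs$class], `[[`, numeric(1), "window"),
    transform = vapply(optimized[signs$class], `[[`, character(1),
                       "transform"),
    stringsAsFactors = FALSE
  )
}
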