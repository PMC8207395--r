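#' Place a spatially constrained sampling design
#'
#' Rejection-samples point locations uniformly inside a rectangular
#' extent, keeping a candidate only if it lies at least `min_spacing`
#' from every accepted location. Each location receives
#' `n_per_location` individuals, all sharing the location's coordinates.
#' If the budget of candidate draws is exhausted before `n_locations`
#' points are accepted the packing is declared infeasible.
#'
#' @param extent named numeric vector `xmin`, `xmax`, `ymin`, `ymax`
#'   (meters).
#' @param n_locations number of sampling locations.
#' @param min_spacing minimum pairwise distance between locations, meters.
#' @param n_per_location individuals sampled per location.
#' @param seed integer seed; the design is a pure function of the
#'   arguments.
#' @param max_attempts rejection-sampling budget (candidate draws).
#' @return An object of class `sampling_design`: list with `locations`
#'   (data.frame id, x, y), `individuals` (data.frame id, location_id,
#'   x, y), `extent`, `min_spacing`.
#' @export
place_sampling_design <- function(extent, n_locations, min_spacing,
                                  n_per_location, seed,
                                  max_attempts = 10000L) {
  stopifnot(all(c("xmin", "xmax", "ymin", "ymax") %in% names(extent)))
  rng <- local_rng(seed)
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n_locations && attempts < max_attempts) {
    attempts <- attempts + 1L
    x <- rng$runif(1, extent[["xmin"]], extent[["xmax"]])
    y <- rng$runif(1, extent[["ymin"]], extent[["ymax"]])
    if (length(xs) == 0L ||
        min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_spacing) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < n_locations)
    stop("packing infeasible: placed ", length(xs), " of ", n_locations,
         " locations at min spacing ", min_spacing, " m within ",
         max_attempts, " draws")
  loc <- data.frame(
    id = sprintf("L%02d", seq_len(n_locations)),
    x = xs, y = ys, stringsAsFactors = FALSE
  )
  ind <- data.frame(
    id = sprintf("%s_%d", rep(loc$id, each = n_per_location),
                 rep(seq_len(n_per_location), n_locations)),
    location_id = rep(loc$id, each = n_per_location),
    x = rep(loc$x, each = n_per_location),
    y = rep(loc$y, each = n_per_location),
    stringsAsFactors = FALSE
  )
  structure(
    list(locations = loc, individuals = ind, extent = extent,
         min_spacing = min_spacing),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("sampling_design:", nrow(x$locations), "locations,",
      nrow(x$individuals), "individuals\n")
  cat("extent: x [", x$extent[["xmin"]], ",", x$extent[["xmax"]],
      "] y [", x$extent[["ymin"]], ",", x$extent[["ymax"]], "] m;",
      "min spacing", x$min_spacing, "m\n")
  invisible(x)
}

# Combine two designs' location sets into one design (shared individuals
# keep their ids); used to build nested large + dense layouts.
merge_designs <- function(a, b) {
  loc <- rbind(a$locations, b$locations)
  ind <- rbind(a$individuals, b$individuals)
  structure(
    list(locations = loc, individuals = ind, extent = a$extent,
         min_spacing = min(a$min_spacing, b$min_spacing)),
    class = "sampling_design"
  )
}

#' Nested sampling design: sparse large-area plus dense small-area
#'
#' Builds a sparse design over the full extent, then adds a denser design
#' inside `small_bounds`. Sparse locations that fall inside the small
#' bounds are shared between the two tiers. Location ids are prefixed
#' `S` (sparse tier) and `D` (dense additions).
#'
#' @param extent full-region bounds, as in [place_sampling_design()].
#' @param small_bounds bounds of the nested small study area.
#' @param n_sparse,sparse_spacing sparse-tier location count and minimum
#'   spacing (meters).
#' @param n_dense,dense_spacing dense-tier totals inside the small area.
#' @param n_per_location individuals per location.
#' @param seed integer seed.
#' @return A `sampling_design` whose `locations` carry logical columns
#'   `in_large` (sparse tier) and `in_small` (inside the small bounds).
#' @export
nested_design <- function(extent, small_bounds,
                          n_sparse, sparse_spacing,
                          n_dense, dense_spacing,
                          n_per_location, seed) {
  sparse <- place_sampling_design(extent, n_sparse, sparse_spacing,
                                  n_per_location, seed)
  sparse$locations$id <- sub("^L", "S", sparse$locations$id)
  sparse$individuals$id <- sub("^L", "S", sparse$individuals$id)
  sparse$individuals$location_id <- sub("^L", "S",
                                        sparse$individuals$location_id)
  inside <- function(x, y, b)
    x >= b[["xmin"]] & x <= b[["xmax"]] & y >= b[["ymin"]] & y <= b[["ymax"]]
  shared <- sparse$locations[inside(sparse$locations$x, sparse$locations$y,
                                    small_bounds), , drop = FALSE]
  n_extra <- n_dense - nrow(shared)
  if (n_extra < 0) stop("small area already holds more than n_dense sparse locations")
  # place extra dense locations keeping spacing to the shared ones
  rng_seed <- as.integer(seed) + 1L
  extra <- NULL
  if (n_extra > 0) {
    rng <- local_rng(rng_seed)
    xs <- shared$x; ys <- shared$y
    ex <- numeric(0); ey <- numeric(0)
    attempts <- 0L
    while (length(ex) < n_extra && attempts < 10000L) {
      attempts <- attempts + 1L
      x <- rng$runif(1, small_bounds[["xmin"]], small_bounds[["xmax"]])
      y <- rng$runif(1, small_bounds[["ymin"]], small_bounds[["ymax"]])
      if (min(sqrt((c(xs, ex) - x)^2 + (c(ys, ey) - y)^2),
              Inf) >= dense_spacing) {
        ex <- c(ex, x); ey <- c(ey, y)
      }
    }
    if (length(ex) < n_extra)
      stop("packing infeasible: dense tier placed ", length(ex), " of ",
           n_extra, " extra locations at spacing ", dense_spacing, " m")
    extra <- data.frame(id = sprintf("D%02d", seq_len(n_extra)),
                        x = ex, y = ey, stringsAsFactors = FALSE)
  }
  loc <- rbind(sparse$locations, extra)
  loc$in_large <- grepl("^S", loc$id)
  loc$in_small <- inside(loc$x, loc$y, small_bounds)
  n_per <- n_per_location
  new_ind <- if (is.null(extra)) NULL else data.frame(
    id = sprintf("%s_%d", rep(extra$id, each = n_per),
                 rep(seq_len(n_per), nrow(extra))),
    location_id = rep(extra$id, each = n_per),
    x = rep(extra$x, each = n_per),
    y = rep(extra$y, each = n_per),
    stringsAsFactors = FALSE
  )
  structure(
    list(locations = loc, individuals = rbind(sparse$individuals, new_ind),
         extent = extent, small_bounds = small_bounds,
         min_spacing = dense_spacing),
    class = "sampling_design"
  )
}

#' Enumerate unordered individual pairs
#'
#' All `C(n, 2)` unordered pairs of individuals in a design, with
#' geographic (straight-line) distance and a same-location flag. Pairs of
#' individuals from the same sampling location can be excluded from model
#' rows; both counts are always reported.
#'
#' @param design a `sampling_design`, or a data.frame with columns `id`,
#'   `location_id`, `x`, `y`.
#' @param exclude_within_location drop same-location pairs from the
#'   returned table (default `TRUE`).
#' @return data.frame with columns `i`, `j` (indices into the individual
#'   table, `i < j`), `id_i`, `id_j`, `location_i`, `location_j`,
#'   `same_location`, `geo_dist`; attributes `n_pairs_total` and
#'   `n_pairs_within`.
#' @export
enumerate_pairs <- function(design, exclude_within_location = TRUE) {
  ind <- if (inherits(design, "sampling_design")) design$individuals else design
  n <- nrow(ind)
  if (n < 2L) stop("need at least 2 individuals")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  same <- ind$location_id[i] == ind$location_id[j]
  pairs <- data.frame(
    i = i, j = j,
    id_i = ind$id[i], id_j = ind$id[j],
    location_i = ind$location_id[i], location_j = ind$location_id[j],
    same_location = same,
    geo_dist = sqrt((ind$x[i] - ind$x[j])^2 + (ind$y[i] - ind$y[j])^2),
    stringsAsFactors = FALSE
  )
  n_total <- nrow(pairs)
  n_within <- sum(same)
  if (exclude_within_location) pairs <- pairs[!pairs$same_location, ]
  rownames(pairs) <- NULL
  attr(pairs, "n_pairs_total") <- n_total
  attr(pairs, "n_pairs_within") <- n_within
  pairs
}

#' Build the three nested scheme datasets
#'
#' From one nested design, constructs the Sparse-Large (sparse-tier
#' individuals, all between-location pairs), Dense-Small (all individuals
#' inside the small bounds, between-location pairs) and Sparse-Small
#' (Dense-Small pairs separated by more than `sparse_threshold`)
#' datasets. Within-location pairs are excluded throughout.
#'
#' @param design a nested `sampling_design` (see [nested_design()]).
#' @param small_bounds bounds of the small study area; defaults to
#'   `design$small_bounds`.
#' @param sparse_threshold distance (meters) above which Dense-Small
#'   pairs are retained in Sparse-Small; default 7000.
#' @return Named list of three scheme datasets, each a list with `name`,
#'   `individuals` (data.frame) and `pairs` (as [enumerate_pairs()]).
#' @export
build_scheme_datasets <- function(design, small_bounds = design$small_bounds,
                                  sparse_threshold = 7000) {
  if (is.null(small_bounds)) stop("design has no small-area bounds")
  loc <- design$locations
  if (is.null(loc$in_large) || is.null(loc$in_small))
    stop("design locations need `in_large`/`in_small` flags; see nested_design()")
  ind <- design$individuals
  sl_ind <- ind[ind$location_id %in% loc$id[loc$in_large], , drop = FALSE]
  ds_ind <- ind[ind$location_id %in% loc$id[loc$in_small], , drop = FALSE]
  sl_pairs <- enumerate_pairs(sl_ind)
  ds_pairs <- enumerate_pairs(ds_ind)
  ss_pairs <- ds_pairs[ds_pairs$geo_dist > sparse_threshold, , drop = FALSE]
  if (nrow(ss_pairs) == 0L)
    stop("Sparse-Small is empty: no pairs farther apart than ",
         sparse_threshold, " m")
  rownames(ss_pairs) <- NULL
  list(
    sparse_large = list(name = "Sparse-Large", individuals = sl_ind,
                        pairs = sl_pairs),
    dense_small = list(name = "Dense-Small", individuals = ds_ind,
                       pairs = ds_pairs),
    sparse_small = list(name = "Sparse-Small", individuals = ds_ind,
                        pairs = ss_pairs)
  )
}
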