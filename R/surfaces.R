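#' @title Moving-window class percentage (PLAND) surface
#'
#' @description For every cell, the percentage of cells in the centred
#' square window that belong to `class_id`. Windows truncated at raster
#' edges are normalised by the number of in-bounds cells, so values stay
#' in \[0, 100\] everywhere.
#'
#' @param r a categorical [land_raster].
#' @param class_id class label to score.
#' @param window_side window edge length in meters; converted to the
#'   nearest odd cell count (minimum 1 cell).
#' @return A [land_raster] of percentages with attributes `class_id` and
#'   `window_side`.
#' @export
pland_moving_window <- function(r, class_id, window_side) {
  v <- r$values
  if (window_side < r$cell_size)
    stop("window side must be at least one cell (", r$cell_size, " m)")
  if (!any(v == class_id, na.rm = TRUE))
    warning("class ", class_id, " absent from raster; surface is all zero")
  ncells <- max(1L, round(window_side / r$cell_size))
  half <- ncells %/% 2L
  mask <- (v == class_id) & !is.na(v)
  valid <- !is.na(v)
  cnt_class <- box_sum(mask * 1, half)
  cnt_valid <- box_sum(valid * 1, half)
  p <- ifelse(cnt_valid > 0, 100 * cnt_class / cnt_valid, NA_real_)
  p[!valid] <- NA_real_
  out <- land_raster(p, cell_size = r$cell_size, xll = r$xll, yll = r$yll)
  attr(out, "class_id") <- class_id
  attr(out, "window_side") <- window_side
  out
}

# Sum over centred (2*half+1)^2 windows, truncated at edges, via a
# summed-area table.
box_sum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  sat <- matrix(0, nr + 1L, nc + 1L)
  sat[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  # out[i,j] = sat[r2+1, c2+1] - sat[r1, c2+1] - sat[r2+1, c1] + sat[r1, c1]
  out <- sat[cbind(rep(r2 + 1L, nc), rep(c2 + 1L, each = nr))] -
    sat[cbind(rep(r1, nc), rep(c2 + 1L, each = nr))] -
    sat[cbind(rep(r2 + 1L, nc), rep(c1, each = nr))] +
    sat[cbind(rep(r1, nc), rep(c1, each = nr))]
  matrix(out, nrow = nr, ncol = nc)
}

#' Area covered by a square moving window
#'
#' @param window_side window edge length in meters.
#' @return Window area in square kilometers (a 250 m window covers
#'   0.0625 km^2).
#' @export
window_area_km2 <- function(window_side) (window_side / 1000)^2

#' The nine resistance transformation families
#'
#' Names of the supported percentage-to-resistance curve families:
#' `linear` plus the monomolecular (saturating) and Ricker (unimodal)
#' curves with their `reverse` (input-flipped) and `inverse`
#' (output-flipped) modifiers.
#'
#' @return Character vector of nine family labels.
#' @export
transform_families <- function() {
  c("linear",
    "monomolecular", "reverse_monomolecular",
    "inverse_monomolecular", "inverse_reverse_monomolecular",
    "ricker", "reverse_ricker",
    "inverse_ricker", "inverse_reverse_ricker")
}

#' Transformation specification
#'
#' @param family one of [transform_families()].
#' @param shape curve shape parameter `s` (> 0); default 2.
#' @param rmax maximum resistance `M` (> 1); default 100.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(family, shape = 2, rmax = 100) {
  family <- match.arg(family, transform_families())
  if (shape <= 0) stop("shape must be positive")
  if (rmax <= 1) stop("rmax must exceed 1")
  structure(list(family = family, shape = shape, rmax = rmax),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("transform_spec:", x$family, " (shape ", x$shape, ", rmax ", x$rmax,
      ")\n", sep = "")
  invisible(x)
}

# g: [0,1] -> [0,1] base curve for a family (before rescaling to [1, M]).
transform_g <- function(x, family, s) {
  rev_in <- grepl("reverse", family)
  inv_out <- grepl("inverse", family)
  if (rev_in) x <- 1 - x
  g <- if (grepl("monomolecular", family)) {
    (1 - exp(-s * x)) / (1 - exp(-s))
  } else if (grepl("ricker", family)) {
    xpk <- min(1, 1 / s)
    (x * exp(-s * x)) / (xpk * exp(-s * xpk))
  } else {
    x
  }
  if (inv_out) g <- 1 - g
  g
}

#' Transform a percentage surface into a resistance surface
#'
#' Maps class-percentage values `p` in \[0, 100\] through a curve family
#' onto resistance values in \[1, M\]. With `x = p/100`:
#' monomolecular `g(x) = (1 - e^(-s x)) / (1 - e^(-s))`, Ricker
#' `g(x) = x e^(-s x)` rescaled by its maximum on \[0, 1\], linear
#' `g(x) = x`; the `reverse` modifier replaces `x` by `1 - x`, the
#' `inverse` modifier replaces `g` by `1 - g`; finally
#' `R = 1 + (M - 1) g`.
#'
#' @param p a percentage surface from [pland_moving_window()].
#' @param t a [transform_spec].
#' @return A [land_raster] of resistances (class `resistance_surface`)
#'   with attributes `class_id`, `window_side`, `transform`.
#' @export
transform_surface <- function(p, t) {
  stopifnot(inherits(t, "transform_spec"))
  v <- p$values
  rng <- range(v, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 100)
    stop("percentage surface values must lie in [0, 100]")
  g <- transform_g(v / 100, t$family, t$shape)
  R <- 1 + (t$rmax - 1) * g
  out <- land_raster(R, cell_size = p$cell_size, xll = p$xll, yll = p$yll)
  class(out) <- c("resistance_surface", class(out))
  attr(out, "class_id") <- attr(p, "class_id")
  attr(out, "window_side") <- attr(p, "window_side")
  attr(out, "transform") <- t
  out
}

#' All candidate resistance surfaces for one land-use class
#'
#' The Cartesian product of the five moving-window sides and the nine
#' transformation families (linear plus eight nonlinear curves): 45
#' uniquely labelled surfaces per class, each with values in \[1, rmax\].
#'
#' @param r a categorical [land_raster].
#' @param class_id class label.
#' @param window_sides window edges in meters.
#' @param families transformation family labels.
#' @param shape,rmax passed to [transform_spec()].
#' @return Named list of `resistance_surface` objects; names are
#'   `w<side>_<family>`.
#' @export
candidate_surfaces <- function(r, class_id,
                               window_sides = c(100, 250, 500, 750, 1000),
                               families = transform_families(),
                               shape = 2, rmax = 100) {
  out <- list()
  for (w in window_sides) {
    p <- pland_moving_window(r, class_id, w)
    for (f in families) {
      s <- transform_surface(p, transform_spec(f, shape, rmax))
      out[[paste0("w", w, "_", f)]] <- s
    }
  }
  out
}

#' Patch configuration metrics for one land-use class
#'
#' Patches are connected components of the class mask under the chosen
#' neighbour rule. Reported metrics: patch density (patches per 100 ha),
#' patch cohesion (percent), and correlation length (the area-weighted
#' mean radius of gyration across patches, meters).
#'
#' @param r a categorical [land_raster].
#' @param class_id class label.
#' @param connectivity `"queen"` (8-neighbour, default) or `"rook"`
#'   (4-neighbour).
#' @return List with `n_patches`, `patch_density`, `cohesion`,
#'   `correlation_length`.
#' @export
patch_metrics <- function(r, class_id, connectivity = c("queen", "rook")) {
  connectivity <- match.arg(connectivity)
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  mask <- which((v == class_id) & !is.na(v))
  total_cells <- sum(!is.na(v))
  area_ha <- total_cells * r$cell_size^2 / 1e4
  if (length(mask) == 0L) {
    return(list(n_patches = 0L, patch_density = 0, cohesion = 0,
                correlation_length = 0))
  }
  comp <- label_components(v == class_id & !is.na(v), connectivity)
  lab <- comp[mask]
  n_patches <- max(lab)
  rows <- ((mask - 1L) %% nr) + 1L
  cols <- ((mask - 1L) %/% nr) + 1L
  areas <- tabulate(lab, n_patches)                 # cells per patch
  # perimeter: class-mask cell edges bordering non-class or raster border
  perim <- patch_perimeters(v == class_id & !is.na(v), lab, mask, n_patches)
  cohesion <- 100 * (1 - sum(perim) / sum(perim * sqrt(areas))) /
    (1 - 1 / sqrt(total_cells))
  # radius of gyration per patch: mean cell-centre distance to centroid
  cx <- tapply(cols, lab, mean); cy <- tapply(rows, lab, mean)
  d <- sqrt((cols - cx[lab])^2 + (rows - cy[lab])^2) * r$cell_size
  gyr <- tapply(d, lab, mean)
  wts <- areas / sum(areas)
  list(
    n_patches = n_patches,
    patch_density = n_patches / area_ha * 100,
    cohesion = as.numeric(cohesion),
    correlation_length = as.numeric(sum(wts * gyr))
  )
}

# Connected-component labels over a logical mask; 0 outside the mask.
label_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- integer(nr * nc)
  if (length(idx) == 0L) return(lab)
  pos <- match(seq_len(nr * nc), idx)               # cell -> node id
  offs <- if (connectivity == "queen") {
    rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
          c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  } else {
    rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  }
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    r2 <- rows + offs[k, 1L]; c2 <- cols + offs[k, 2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- mask[j]
    edges <- rbind(edges, cbind(pos[idx[ok][keep]], pos[j[keep]]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(0), 0, 2) else edges,
    directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  lab[idx] <- igraph::components(g)$membership
  lab
}

# Cell-edge perimeter per patch, counting raster-border edges.
patch_perimeters <- function(mask, lab, idx, n_patches) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  per <- numeric(n_patches)
  for (k in 1:4) {
    dr <- c(-1L, 1L, 0L, 0L)[k]; dc <- c(0L, 0L, -1L, 1L)[k]
    r2 <- rows + dr; c2 <- cols + dc
    outside <- r2 < 1L | r2 > nr | c2 < 1L | c2 > nc
    j <- (pmax(pmin(c2, nc), 1L) - 1L) * nr + pmax(pmin(r2, nr), 1L)
    exposed <- outside | !mask[j]
    per <- per + tabulate(lab[exposed], n_patches)
  }
  per
}

#' Place a representative square subregion
#'
#' Scans square windows across the raster and returns the placement whose
#' per-class composition is closest to the full raster's: the objective is
#' the maximum over classes of the absolute difference in class
#' percentages. Mirrors the placement of a small study area chosen to
#' match the land-use composition of the full region.
#'
#' @param r a categorical [land_raster].
#' @param side subregion edge length, meters.
#' @param stride scan step in cells.
#' @param tolerance acceptable maximum composition difference, percent
#'   (default 6.3).
#' @return List with `row`, `col` (upper-left cell of the best window),
#'   `bounds` (xmin/xmax/ymin/ymax in meters), `objective` (max class
#'   delta, percent), `deltas` (per-class percent differences), and
#'   `within_tolerance`.
#' @export
place_subregion <- function(r, side, stride = 1L, tolerance = 6.3) {
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  w <- max(1L, round(side / r$cell_size))
  if (w > nr || w > nc) stop("subregion side exceeds raster extent")
  classes <- sort(unique(c(v[!is.na(v)])))
  full_pct <- 100 * vapply(classes, function(cl)
    mean(v == cl, na.rm = TRUE), numeric(1))
  sats <- lapply(classes, function(cl) {
    m <- (v == cl) & !is.na(v)
    sat <- matrix(0, nr + 1L, nc + 1L)
    sat[-1L, -1L] <- t(apply(apply(m * 1, 2L, cumsum), 1L, cumsum))
    sat
  })
  rs <- seq(1L, nr - w + 1L, by = stride)
  cs <- seq(1L, nc - w + 1L, by = stride)
  best <- list(obj = Inf)
  for (i in rs) {
    for (j in cs) {
      cnts <- vapply(sats, function(s)
        s[i + w, j + w] - s[i, j + w] - s[i + w, j] + s[i, j], numeric(1))
      pct <- 100 * cnts / (w * w)
      deltas <- pct - full_pct
      obj <- max(abs(deltas))
      if (obj < best$obj) best <- list(obj = obj, row = i, col = j,
                                       deltas = deltas)
    }
  }
  names(best$deltas) <- as.character(classes)
  xmin <- r$xll + (best$col - 1L) * r$cell_size
  ymax <- r$yll + (nr - best$row + 1L) * r$cell_size
  list(
    row = best$row, col = best$col,
    bounds = c(xmin = xmin, xmax = xmin + w * r$cell_size,
               ymin = ymax - w * r$cell_size, ymax = ymax),
    objective = best$obj,
    deltas = best$deltas,
    within_tolerance = best$obj <= tolerance
  )
}

#' Crop a raster to rectangular bounds
#'
#' @param r a [land_raster].
#' @param bounds named numeric vector `xmin`, `xmax`, `ymin`, `ymax`.
#' @return The cropped [land_raster].
#' @export
crop_raster <- function(r, bounds) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  c1 <- max(1L, floor((bounds[["xmin"]] - r$xll) / r$cell_size) + 1L)
  c2 <- min(nc, ceiling((bounds[["xmax"]] - r$xll) / r$cell_size))
  r2 <- max(1L, nr - ceiling((bounds[["ymax"]] - r$yll) / r$cell_size) + 1L)
  r1 <- min(nr, nr - floor((bounds[["ymin"]] - r$yll) / r$cell_size))
  land_raster(r$values[r2:r1, c1:c2, drop = FALSE], r$cell_size,
              xll = r$xll + (c1 - 1L) * r$cell_size,
              yll = r$yll + (nr - r1) * r$cell_size)
}
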