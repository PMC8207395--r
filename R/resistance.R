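#' Build a lattice conductance graph from a resistance surface
#'
#' One node per non-nodata cell; edges join 4- or 8-neighbours with
#' conductance `((1/R_a + 1/R_b)/2) / w`, where `w = 1` for orthogonal
#' and `sqrt(2)` for diagonal neighbours (cell units). The graph volume
#' (sum of node degrees in conductance units) scales the effective
#' resistance into commute time.
#'
#' @param surface a `resistance_surface` or any [land_raster] with values
#'   >= 1 (or `NA` for blocked cells).
#' @param neighborhood 8 (default) or 4.
#' @return An object of class `lattice_graph`: edge list (`from`, `to`,
#'   `conductance`), node-to-cell index map, `volume`, component labels,
#'   and the source raster geometry.
#' @export
build_graph <- function(surface, neighborhood = 8) {
  if (!neighborhood %in% c(4, 8)) stop("neighborhood must be 4 or 8")
  v <- surface$values
  if (any(v < 1, na.rm = TRUE)) stop("resistance values must be >= 1")
  nr <- nrow(v); nc <- ncol(v)
  valid <- which(!is.na(v))
  if (length(valid) == 0L) stop("all cells are nodata")
  node <- integer(nr * nc)
  node[valid] <- seq_along(valid)
  cond_cell <- 1 / v
  offs <- list(c(0L, 1L), c(1L, 0L))                 # right, down
  wts <- c(1, 1)
  if (neighborhood == 8) {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))     # down-right, down-left
    wts <- c(wts, sqrt(2), sqrt(2))
  }
  rows <- ((valid - 1L) %% nr) + 1L
  cols <- ((valid - 1L) %/% nr) + 1L
  from <- to <- integer(0); cond <- numeric(0)
  for (k in seq_along(offs)) {
    r2 <- rows + offs[[k]][1L]; c2 <- cols + offs[[k]][2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- !is.na(v[j])
    a <- valid[ok][keep]; b <- j[keep]
    from <- c(from, node[a]); to <- c(to, node[b])
    cond <- c(cond, ((cond_cell[a] + cond_cell[b]) / 2) / wts[k])
  }
  comp <- rep(1L, length(valid))
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(valid) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  structure(
    list(from = from, to = to, conductance = cond,
         cells = valid, n_nodes = length(valid),
         component = comp,
         volume = 2 * sum(cond),
         nrow = nr, ncol = nc, cell_size = surface$cell_size,
         xll = surface$xll, yll = surface$yll),
    class = "lattice_graph"
  )
}

#' @export
print.lattice_graph <- function(x, ...) {
  cat("lattice_graph:", x$n_nodes, "nodes,", length(x$from), "edges,",
      max(x$component), "component(s); volume", format(x$volume), "\n")
  invisible(x)
}

graph_node_at <- function(g, x, y) {
  col <- pmin(pmax(floor((x - g$xll) / g$cell_size) + 1L, 1L), g$ncol)
  row <- pmin(pmax(g$nrow - floor((y - g$yll) / g$cell_size), 1L), g$nrow)
  cell <- (col - 1L) * g$nrow + row
  node <- match(cell, g$cells)
  if (anyNA(node)) stop("point falls on a nodata cell")
  node
}

#' Commute-time distances between points on a lattice graph
#'
#' The commute time `C(i,j) = vol(G) * R_eff(i,j)`, with the effective
#' resistance obtained by solving the grounded graph Laplacian (sparse
#' Cholesky, one factorisation shared across all point pairs). Points are
#' snapped to the centre of their containing cell; co-located points
#' share a node and get distance 0. The volume is that of the connected
#' component containing the points.
#'
#' @param g a `lattice_graph`.
#' @param points data.frame or matrix with columns `x`, `y` (meters).
#' @return Symmetric matrix of commute distances, zero diagonal.
#' @export
commute_distance <- function(g, points) {
  points <- as.data.frame(points)
  nodes <- graph_node_at(g, points[[1L]], points[[2L]])
  comps <- unique(g$component[nodes])
  if (length(comps) > 1L)
    stop("points fall in ", length(comps),
         " disconnected components (labels ",
         paste(comps, collapse = ", "),
         "); commute distance is undefined across components")
  comp <- comps[1L]
  in_comp <- which(g$component == comp)
  relab <- integer(g$n_nodes)
  relab[in_comp] <- seq_along(in_comp)
  keep <- g$component[g$from] == comp
  ef <- relab[g$from[keep]]; et <- relab[g$to[keep]]
  ec <- g$conductance[keep]
  m <- length(in_comp)
  vol <- 2 * sum(ec)
  L <- Matrix::sparseMatrix(
    i = c(ef, et, ef, et),
    j = c(et, ef, ef, et),
    x = c(-ec, -ec, ec, ec),
    dims = c(m, m)
  )
  snodes <- relab[nodes]
  uniq <- sort(unique(snodes))
  ground <- uniq[1L]
  kept <- setdiff(seq_len(m), ground)
  Lg <- L[kept, kept, drop = FALSE]
  others <- setdiff(uniq, ground)
  n_pt <- nrow(points)
  if (length(others)) {
    rhs <- Matrix::sparseMatrix(
      i = match(others, kept), j = seq_along(others),
      x = 1, dims = c(m - 1L, length(others))
    )
    sol <- Matrix::solve(Matrix::Cholesky(Lg, LDL = FALSE), rhs)
    G <- as.matrix(sol[match(others, kept), , drop = FALSE])
  } else {
    G <- matrix(0, 0, 0)
  }
  # Gfull over uniq nodes with ground row/col zero
  gi <- match(snodes, others)            # NA for ground
  C <- matrix(0, n_pt, n_pt)
  for (a in seq_len(n_pt)) {
    for (b in seq_len(n_pt)) {
      if (a >= b) next
      ia <- gi[a]; ib <- gi[b]
      gaa <- if (is.na(ia)) 0 else G[ia, ia]
      gbb <- if (is.na(ib)) 0 else G[ib, ib]
      gab <- if (is.na(ia) || is.na(ib)) 0 else G[ia, ib]
      C[a, b] <- C[b, a] <- vol * (gaa + gbb - 2 * gab)
    }
  }
  if (!is.null(rownames(points))) dimnames(C) <- list(rownames(points),
                                                      rownames(points))
  C
}

#' Commute distance on a homogeneous landscape
#'
#' Commute-time distance computed on an all-ones resistance surface with
#' the same geometry as `r`; used as the straight-line geographic
#' distance surrogate ("GD") in the pairwise models.
#'
#' @param points data.frame/matrix with columns `x`, `y`.
#' @param r a [land_raster] providing the grid geometry.
#' @param neighborhood passed to [build_graph()].
#' @return Symmetric commute-distance matrix.
#' @export
homogeneous_distance <- function(points, r, neighborhood = 8) {
  ones <- land_raster(matrix(1, nrow(r$values), ncol(r$values)),
                      cell_size = r$cell_size, xll = r$xll, yll = r$yll)
  commute_distance(build_graph(ones, neighborhood), points)
}

#' Residualize a commute predictor against the homogeneous distance
#'
#' Ordinary least squares of the predictor pair-column on the
#' homogeneous-landscape pair-column (with intercept); the residuals —
#' the part of the resistance signal not explained by straight-line
#' distance — are used as model predictors.
#'
#' @param predictor numeric vector of commute distances per pair.
#' @param homogeneous numeric vector of homogeneous commute distances,
#'   same pairs.
#' @return Numeric vector of residuals (mean 0, orthogonal to
#'   `homogeneous`).
#' @export
residualize <- function(predictor, homogeneous) {
  if (length(predictor) != length(homogeneous))
    stop("predictor and homogeneous columns differ in length")
  if (stats::sd(homogeneous) == 0)
    stop("homogeneous distance column is constant")
  stats::lm.fit(cbind(1, homogeneous), predictor)$residuals
}

#' Greedy collinearity screen over predictor classes
#'
#' Scans classes in priority order; a class is retained only if its
#' Pearson correlation with every higher-priority retained class is at
#' most `threshold`. The full correlation matrix is attached to the
#' result.
#'
#' @param predictors named list or data.frame of per-pair predictor
#'   columns (one per land-use class).
#' @param threshold correlation above which one of a pair is dropped
#'   (default 0.5).
#' @param priority character vector of class names, highest priority
#'   first; defaults to the order of `predictors`.
#' @return Character vector of retained class names; attributes
#'   `correlations` (matrix) and `dropped`.
#' @export
collinearity_screen <- function(predictors, threshold = 0.5,
                                priority = names(predictors)) {
  predictors <- as.data.frame(predictors)
  if (ncol(predictors) < 2L) stop("need at least 2 predictors")
  if (!setequal(priority, names(predictors)))
    stop("priority must name exactly the predictor classes")
  cm <- stats::cor(predictors)
  retained <- character(0)
  for (cl in priority) {
    if (all(abs(cm[cl, retained]) <= threshold))
      retained <- c(retained, cl)
  }
  dropped <- setdiff(priority, retained)
  structure(retained[order(match(retained, names(predictors)))],
            correlations = cm, dropped = dropped)
}

#' Assemble a pair table of distances and residual predictors
#'
#' Convenience wrapper joining a pair index with the genetic distance,
#' homogeneous commute distance, per-class commute distances, and their
#' residualized versions.
#'
#' @param pairs pair index from [enumerate_pairs()].
#' @param gd genetic-distance matrix over the same individuals.
#' @param homogeneous homogeneous commute matrix over individuals.
#' @param predictors named list of commute matrices, one per class.
#' @return data.frame: the pair index plus `gd`, `GD` (homogeneous) and,
#'   per class, `<class>_commute` and `<class>` (residual).
#' @export
pair_table <- function(pairs, gd, homogeneous, predictors = list()) {
  ij <- cbind(pairs$i, pairs$j)
  out <- pairs
  out$gd <- gd[ij]
  out$GD <- homogeneous[ij]
  for (cl in names(predictors)) {
    cc <- predictors[[cl]][ij]
    out[[paste0(cl, "_commute")]] <- cc
    out[[cl]] <- residualize(cc, out$GD)
  }
  out
}
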