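#' Categorical land-use raster
#'
#' A minimal in-memory raster: an integer matrix of class ids plus cell
#' geometry. Row 1 is the northern edge; cell centres are at
#' `x = xll + (col - 0.5) * cell_size`, `y = yll + (nrow - row + 0.5) * cell_size`.
#'
#' @param values integer matrix of class ids (0-based class labels) or,
#'   for continuous surfaces, numeric values. `NA` marks nodata.
#' @param cell_size cell edge length in meters.
#' @param xll,yll coordinates of the lower-left corner of the grid, meters.
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(values, cell_size, xll = 0, yll = 0) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  structure(
    list(values = values, cell_size = cell_size, xll = xll, yll = yll),
    class = "land_raster"
  )
}

#' @export
print.land_raster <- function(x, ...) {
  v <- x$values
  cat("land_raster:", nrow(v), "x", ncol(v), "cells,",
      x$cell_size, "m cells\n")
  cat("extent: x [", x$xll, ",", x$xll + ncol(v) * x$cell_size, "] y [",
      x$yll, ",", x$yll + nrow(v) * x$cell_size, "] m\n")
  if (all(v == round(v), na.rm = TRUE) && !anyNA(v) && length(unique(c(v))) <= 32) {
    tab <- table(factor(c(v)))
    cat("classes:", paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
  } else {
    cat("values: [", format(min(v, na.rm = TRUE)), ",",
        format(max(v, na.rm = TRUE)), "]\n")
  }
  invisible(x)
}

#' @export
dim.land_raster <- function(x) dim(x$values)

#' Cell-centre coordinates of every cell, by row-major cell index
#' @noRd
cell_centers <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(
    row = row, col = col,
    x = r$xll + (col - 0.5) * r$cell_size,
    y = r$yll + (nr - row + 0.5) * r$cell_size
  )
}

#' Map point coordinates to (row, col) of the containing cell
#' @noRd
snap_to_cell <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- pmin(pmax(floor((x - r$xll) / r$cell_size) + 1L, 1L), nc)
  row <- pmin(pmax(nr - floor((y - r$yll) / r$cell_size), 1L), nr)
  cbind(row = row, col = col)
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text `.asc` raster format (6 header lines followed by
#' whitespace-separated cell values, first data row = north).
#'
#' @param path file path.
#' @return A [land_raster].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ESRI ASCII header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cell values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    hdr$yllcenter - hdr$cellsize / 2
  land_raster(m, cell_size = hdr$cellsize, xll = xll, yll = yll)
}

#' Write an ESRI ASCII grid
#'
#' @param r a [land_raster].
#' @param path output file path.
#' @param nodata numeric code written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(r$xll, scientific = FALSE)),
    paste("yllcorner", format(r$yll, scientific = FALSE)),
    paste("cellsize", format(r$cell_size, scientific = FALSE)),
    paste("NODATA_value", nodata)
  )
  rows <- apply(v, 1L, function(z) paste(format(z, trim = TRUE), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# 1-D convolution of each column of `m` with symmetric kernel `k`,
# zero-padded; paired with an identical convolution of a ones matrix the
# caller can renormalise truncated edges.
conv_cols <- function(m, k) {
  h <- (length(k) - 1L) %/% 2L
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  for (o in -h:h) {
    w <- k[o + h + 1L]
    src <- seq_len(nr) + o
    keep <- src >= 1L & src <= nr
    out[keep, ] <- out[keep, ] + w * m[src[keep], , drop = FALSE]
  }
  out
}

gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  sm <- t(conv_cols(t(conv_cols(m, k)), k))
  ones <- matrix(1, nrow(m), ncol(m))
  wt <- t(conv_cols(t(conv_cols(ones, k)), k))
  sm / wt
}

#' Generate a patchy categorical landscape
#'
#' Draws one field of white noise per class, smooths each with an isotropic
#' Gaussian kernel, and labels every cell with the class whose smoothed
#' field is largest. Larger `smoothing` produces larger, smoother patches.
#' The output is a deterministic function of the arguments.
#'
#' This is a stylized stand-in for a classified satellite land-use map: it
#' reproduces the patch mosaic structure such maps have, not any real
#' geography.
#'
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param n_rows,n_cols raster dimensions in cells.
#' @param cell_size cell edge, meters.
#' @param n_classes number of land-use classes (labels `0:(n_classes-1)`).
#' @param smoothing kernel length-scale in cells; 0 gives iid labels.
#' @param xll,yll lower-left corner, meters.
#' @return A [land_raster] of integer class labels.
#' @examples
#' r <- generate_landscape(1, 60, 60, cell_size = 100, n_classes = 5,
#'                         smoothing = 3)
#' table(r$values)
#' @export
generate_landscape <- function(seed, n_rows, n_cols, cell_size = 30,
                               n_classes = 6, smoothing = 3,
                               xll = 0, yll = 0) {
  if (n_rows < 1 || n_cols < 1) stop("raster dimensions must be positive")
  if (n_classes < 2) stop("need at least 2 classes")
  if (n_classes > 255) stop("n_classes must be at most 255")
  if (smoothing < 0) stop("smoothing must be non-negative")
  rng <- local_rng(seed)
  fields <- lapply(seq_len(n_classes), function(cl) {
    noise <- matrix(rng$rnorm(n_rows * n_cols), n_rows, n_cols)
    gaussian_smooth(noise, smoothing)
  })
  arr <- array(unlist(fields), dim = c(n_rows, n_cols, n_classes))
  lab <- apply(arr, c(1, 2), which.max) - 1L
  land_raster(lab, cell_size = cell_size, xll = xll, yll = yll)
}

# Private RNG stream: seeded draws that do not disturb the global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  with_state <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
          assign(".Random.seed", old, globalenv())
      })
      fn(...)
    }
  }
  list(
    rnorm = with_state(stats::rnorm),
    runif = with_state(stats::runif),
    sample = with_state(base::sample),
    rbinom = with_state(stats::rbinom)
  )
}
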