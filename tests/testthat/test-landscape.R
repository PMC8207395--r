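test_that("generated landscapes are seeded, complete and patchier when smoothed", {
  r <- generate_landscape(1, 100, 100, cell_size = 30, n_classes = 5,
                          smoothing = 3)
  expect_setequal(unique(c(r$values)), 0:4)
  r2 <- generate_landscape(1, 100, 100, cell_size = 30, n_classes = 5,
                           smoothing = 3)
  expect_identical(r$values, r2$values)

  rough <- generate_landscape(3, 80, 80, cell_size = 30, n_classes = 3,
                              smoothing = 1)
  smooth <- generate_landscape(3, 80, 80, cell_size = 30, n_classes = 3,
                               smoothing = 6)
  pd_rough <- patch_metrics(rough, 0)$patch_density
  pd_smooth <- patch_metrics(smooth, 0)$patch_density
  expect_lt(pd_smooth, pd_rough)
})

test_that("landscape generator validates its arguments", {
  expect_error(generate_landscape(1, 0, 10, 30, 5, 1), "positive")
  expect_error(generate_landscape(1, 10, 10, 30, 1, 1), "2 classes")
  expect_error(generate_landscape(1, 10, 10, 30, 300, 1), "255")
  expect_error(generate_landscape(1, 10, 10, 30, 5, -1), "non-negative")
})

test_that("ESRI ASCII grids round-trip through write/read", {
  r <- tiny_raster(seed = 4, n = 12)
  r$values[3, 5] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_equal(r2$values, r$values)
  expect_equal(r2$cell_size, r$cell_size)
  expect_equal(r2$xll, r$xll)
  expect_equal(r2$yll, r$yll)
})

test_that("pland surfaces hit the closed-form cases", {
  const <- land_raster(matrix(2L, 20, 20), cell_size = 30)
  p <- pland_moving_window(const, 2, 150)
  expect_true(all(p$values == 100))

  checker <- land_raster(outer(1:40, 1:40, function(i, j) (i + j) %% 2L),
                         cell_size = 30)
  p2 <- pland_moving_window(checker, 1, 900)   # 31-cell window >> cell
  interior <- p2$values[16:25, 16:25]
  expect_true(all(abs(interior - 50) < 2))

  expect_warning(pland_moving_window(const, 9, 150), "absent")
  expect_equal(window_area_km2(250), 0.0625)
})

test_that("pland is translation-equivariant away from edges", {
  r <- tiny_raster(seed = 6, n = 40)
  shifted <- land_raster(r$values[, c(5:40, 1:4)], cell_size = r$cell_size)
  p <- pland_moving_window(r, 1, 300)
  ps <- pland_moving_window(shifted, 1, 300)
  # columns 5..36 of the original appear at 1..32 of the shifted raster
  expect_equal(ps$values[10:30, 2:30], p$values[10:30, 6:34])
})

test_that("transformation families obey their algebra", {
  x <- seq(0, 1, by = 0.01)
  for (fam in transform_families()) {
    g <- landmlpe:::transform_g(x, fam, 2)
    expect_true(all(g >= -1e-12 & g <= 1 + 1e-12), info = fam)
  }
  # non-inverse families map 0 -> R = 1; linear maps 1 -> 100
  p0 <- land_raster(matrix(0, 2, 2), cell_size = 30)
  for (fam in c("linear", "monomolecular", "ricker")) {
    s <- transform_surface(p0, transform_spec(fam))
    expect_equal(unname(s$values[1, 1]), 1, info = fam)
  }
  p100 <- land_raster(matrix(100, 2, 2), cell_size = 30)
  expect_equal(transform_surface(p100, transform_spec("linear"))$values[1, 1],
               100)
  # inverse family equals 101 - non-inverse value pointwise (M = 100)
  pr <- land_raster(matrix(runif(64, 0, 100), 8, 8), cell_size = 30)
  for (fam in c("monomolecular", "ricker", "reverse_monomolecular",
                "reverse_ricker")) {
    plain <- transform_surface(pr, transform_spec(fam))$values
    inv <- transform_surface(pr, transform_spec(paste0("inverse_", fam)))$values
    expect_equal(inv, 101 - plain, tolerance = 1e-12, info = fam)
  }
  # monomolecular variants monotone, Ricker unimodal for s = 2
  gm <- landmlpe:::transform_g(x, "monomolecular", 2)
  expect_true(all(diff(gm) > 0))
  gr <- landmlpe:::transform_g(x, "ricker", 2)
  peak <- which.max(gr)
  expect_true(all(diff(gr[seq_len(peak)]) >= 0))
  expect_true(all(diff(gr[peak:length(gr)]) <= 0))
  expect_equal(max(gr), 1)
})

test_that("candidate enumeration yields 45 uniquely labelled surfaces in range", {
  r <- tiny_raster(seed = 2, n = 30)
  cands <- candidate_surfaces(r, 1)
  expect_length(cands, 45)
  expect_false(anyDuplicated(names(cands)) > 0)
  rng <- sapply(cands, function(s) range(s$values))
  expect_true(all(rng[1, ] >= 1))
  expect_true(all(rng[2, ] <= 100))
})

test_that("patch metrics match hand-computable cases", {
  # one single-cell patch: zero correlation length
  m <- matrix(0L, 10, 10); m[5, 5] <- 1L
  r <- land_raster(m, cell_size = 100)
  pm <- patch_metrics(r, 1)
  expect_equal(pm$n_patches, 1)
  expect_equal(pm$correlation_length, 0)

  # 100-ha raster (10x10 cells of 100 m) with one patch: density 1 per 100 ha
  expect_equal(pm$patch_density, 1)

  # diagonal adjacency: one patch under queen, two under rook
  m2 <- matrix(0L, 6, 6); m2[2, 2] <- 1L; m2[3, 3] <- 1L
  r2 <- land_raster(m2, cell_size = 100)
  expect_equal(patch_metrics(r2, 1, "queen")$n_patches, 1)
  expect_equal(patch_metrics(r2, 1, "rook")$n_patches, 2)

  # absent class: zeroed metrics
  pm0 <- patch_metrics(r, 7)
  expect_equal(pm0$n_patches, 0)
  expect_equal(pm0$patch_density, 0)
})

test_that("subregion placement minimises composition mismatch", {
  hom <- land_raster(matrix(1L, 30, 30), cell_size = 100)
  res <- place_subregion(hom, 1000)
  expect_equal(res$objective, 0)
  expect_true(res$within_tolerance)

  r <- tiny_raster(seed = 5, n = 40)
  fine <- place_subregion(r, 2000, stride = 1)
  coarse <- place_subregion(r, 2000, stride = 4)
  expect_lte(fine$objective, coarse$objective)
  expect_error(place_subregion(r, 1e6), "exceeds")
  # default tolerance mirrors the published placement criterion
  expect_equal(formals(place_subregion)$tolerance, 6.3)
})
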