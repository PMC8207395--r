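test_that("genotype tables round-trip through tabular text", {
  g <- hand_genotypes()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path)
  expect_equal(g2$alleles, g$alleles)
  expect_equal(g2$individuals$id, g$individuals$id)
  expect_equal(g2$loci, g$loci)
})

test_that("genotype parsing enforces diploid semantics", {
  g <- hand_genotypes()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  # corrupt: drop one allele of a pair
  lines <- readLines(path)
  lines[4] <- sub("102\t104\tNA\tNA", "102\tNA\tNA\tNA", lines[4])
  writeLines(lines, path)
  expect_error(read_genotypes(path), "locus A.*c", ignore.case = TRUE)

  writeLines(lines[1], path)
  expect_error(read_genotypes(path), "no individuals")

  ind <- data.frame(id = c("a", "a"), location_id = "L", x = 0, y = 0)
  expect_error(genotype_table(ind, matrix(1L, 2, 2), "A"), "duplicate")
})

test_that("genotype summaries count alleles by hand-checkable rules", {
  g <- hand_genotypes()
  s <- summarize_genotypes(g)
  # locus A alleles {100/100, 100/102, 102/104}: 3 distinct alleles
  expect_equal(s$per_locus$n_alleles[s$per_locus$locus == "A"], 3)
  expect_equal(s$per_locus$n_alleles[s$per_locus$locus == "B"], 2)
  expect_equal(s$mean_alleles_per_locus, 2.5)
  # 1 missing call of 6 locus-calls
  expect_equal(s$percent_missing, 100 / 6)

  # no missing data -> 0 percent
  g$alleles[3, 3:4] <- c(200L, 200L)
  expect_equal(summarize_genotypes(g)$percent_missing, 0)
})

test_that("PCA scores match a brute-force eigendecomposition", {
  d <- tiny_design(seed = 3, n_locations = 6)
  r <- tiny_raster(seed = 2, n = 30)
  surf <- transform_surface(pland_moving_window(r, 1, 300),
                            transform_spec("monomolecular"))
  g <- simulate_genotypes(d, surf, n_loci = 5, alleles_per_locus = 6,
                          drift_scale = 1, seed = 4, missing_rate = 0.05)
  sc <- encode_and_pca(g, n_axes = 1e6)   # capped at rank, no error
  X <- landmlpe:::encode_dosage(g)
  for (jj in which(colSums(is.na(X)) > 0)) {
    X[is.na(X[, jj]), jj] <- mean(X[, jj], na.rm = TRUE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(Xc) - 1), symmetric = TRUE)$values
  # sum of retained score variances equals sum of retained eigenvalues
  expect_equal(sum(apply(sc$scores, 2, var)),
               sum(ev[seq_len(sc$n_axes)]), tolerance = 1e-8)
  expect_equal(sum(sc$eigenvalues), sum(ev[seq_len(sc$n_axes)]),
               tolerance = 1e-8)
  # eigenvalues non-increasing
  expect_true(all(diff(sc$eigenvalues) <= 1e-12))
})

test_that("imputation leaves complete columns untouched and twins coincide", {
  g <- hand_genotypes()
  # duplicate individual a as d: identical score rows
  ind <- rbind(g$individuals,
               data.frame(id = "d", location_id = "L2", x = 1000, y = 0))
  am <- rbind(g$alleles, g$alleles[1, ])
  g2 <- genotype_table(ind, am, g$loci)
  sc <- encode_and_pca(g2, 3)
  expect_equal(sc$scores[1, ], sc$scores[4, ], ignore_attr = TRUE)
  d <- pca_distance(sc)
  expect_equal(d["a", "d"], 0)
})

test_that("PCA distance equals Euclidean distance on the encoded matrix", {
  d <- tiny_design(seed = 7, n_locations = 5)
  r <- tiny_raster(seed = 2, n = 30)
  surf <- transform_surface(pland_moving_window(r, 1, 300),
                            transform_spec("linear"))
  g <- simulate_genotypes(d, surf, n_loci = 4, alleles_per_locus = 5,
                          drift_scale = 1, seed = 6)
  sc <- encode_and_pca(g, n_axes = 1e6)
  gd <- pca_distance(sc)
  X <- landmlpe:::encode_dosage(g)
  direct <- as.matrix(dist(scale(X, center = TRUE, scale = FALSE)))
  expect_equal(unname(gd), unname(direct), tolerance = 1e-8)
  # symmetric, zero diagonal, triangle inequality on a sample of triples
  expect_equal(gd, t(gd))
  expect_true(all(diag(gd) == 0))
  n <- nrow(gd)
  for (t in seq_len(50)) {
    ijk <- sample(n, 3)
    expect_lte(gd[ijk[1], ijk[3]],
               gd[ijk[1], ijk[2]] + gd[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("simulated genotype frequencies live on the simplex", {
  d <- tiny_design(seed = 2, n_locations = 6)
  r <- tiny_raster(seed = 2, n = 30)
  surf <- transform_surface(pland_moving_window(r, 1, 300),
                            transform_spec("monomolecular"))
  g <- simulate_genotypes(d, surf, n_loci = 3, alleles_per_locus = 7,
                          drift_scale = 2, seed = 5)
  for (f in attr(g, "freqs")) {
    expect_equal(unname(rowSums(f)), rep(1, nrow(f)))
    expect_true(all(f >= 0))
  }
  # determinism
  g2 <- simulate_genotypes(d, surf, n_loci = 3, alleles_per_locus = 7,
                           drift_scale = 2, seed = 5)
  expect_identical(g$alleles, g2$alleles)
  expect_error(simulate_genotypes(d, surf, alleles_per_locus = 1),
               "at least 2")
})

test_that("distance matrices round-trip through tabular text", {
  d <- as.matrix(dist(matrix(rnorm(10), ncol = 2)))
  dimnames(d) <- list(letters[1:5], letters[1:5])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, path)
  d2 <- read_distance_matrix(path)
  expect_equal(d2, d, tolerance = 1e-12)
})
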