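test_that("edge conductances follow the mean-conductance rule", {
  # uniform R = 1: orthogonal conductance 1, diagonal 1/sqrt(2)
  r <- land_raster(matrix(1, 3, 3), cell_size = 100)
  g <- build_graph(r, neighborhood = 8)
  expect_true(all(abs(g$conductance - 1) < 1e-12 |
                    abs(g$conductance - 1 / sqrt(2)) < 1e-12))
  g4 <- build_graph(r, neighborhood = 4)
  expect_true(all(abs(g4$conductance - 1) < 1e-12))
  expect_equal(length(g4$from), 12)   # 3x3 rook lattice has 12 edges

  # R = 1 and R = 3 neighbours: conductance (1 + 1/3)/2 = 2/3
  r2 <- land_raster(matrix(c(1, 3), 1, 2), cell_size = 100)
  g2 <- build_graph(r2)
  expect_equal(g2$conductance, 2 / 3)

  expect_error(build_graph(land_raster(matrix(0.5, 2, 2), 100)), ">= 1")
  expect_error(build_graph(land_raster(matrix(NA_real_, 2, 2), 100)),
               "nodata")
})

test_that("commute distance matches analytic and dense pseudo-inverse oracles", {
  # single edge of conductance 1: commute time = vol * R_eff = 2 * 1
  r <- land_raster(matrix(1, 1, 2), cell_size = 100)
  g <- build_graph(r)
  pts <- data.frame(x = c(50, 150), y = c(50, 50))
  C <- commute_distance(g, pts)
  expect_equal(C[1, 2], 2)

  # path of 3 nodes with unit conductances: C(end,end) = vol 4 * R_eff 2
  r3 <- land_raster(matrix(1, 1, 3), cell_size = 100)
  C3 <- commute_distance(build_graph(r3),
                         data.frame(x = c(50, 250), y = 50))
  expect_equal(C3[1, 2], 8)

  # random 5x5 surfaces vs dense Moore-Penrose pseudo-inverse
  for (seed in 1:3) {
    set.seed(seed)
    vals <- matrix(runif(25, 1, 50), 5, 5)
    rr <- land_raster(vals, cell_size = 100)
    gg <- build_graph(rr)
    n <- gg$n_nodes
    L <- matrix(0, n, n)
    for (e in seq_along(gg$from)) {
      a <- gg$from[e]; b <- gg$to[e]; c_ <- gg$conductance[e]
      L[a, b] <- L[a, b] - c_; L[b, a] <- L[b, a] - c_
      L[a, a] <- L[a, a] + c_; L[b, b] <- L[b, b] + c_
    }
    Lp <- MASS::ginv(L)
    pts <- expand.grid(x = c(50, 250, 450), y = c(50, 450))
    C <- commute_distance(gg, pts)
    nodes <- landmlpe:::graph_node_at(gg, pts$x, pts$y)
    for (a in 1:5) for (b in (a + 1):6) {
      reff <- Lp[nodes[a], nodes[a]] + Lp[nodes[b], nodes[b]] -
        2 * Lp[nodes[a], nodes[b]]
      expect_equal(C[a, b], gg$volume * reff, tolerance = 1e-6)
    }
  }
})

test_that("commute distance is a metric and scales linearly with resistance", {
  set.seed(4)
  vals <- matrix(runif(36, 1, 20), 6, 6)
  r <- land_raster(vals, cell_size = 100)
  pts <- data.frame(x = c(50, 250, 550, 350), y = c(50, 350, 550, 150))
  C <- commute_distance(build_graph(r), pts)
  expect_equal(C, t(C))
  expect_true(all(diag(C) == 0))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(C[i, k], C[i, j] + C[j, k] + 1e-9)
  # scaling all resistances by k: effective resistance scales by k while
  # the walk itself (and hence commute time = volume * R_eff) is
  # invariant, because the volume scales by 1/k
  gk <- build_graph(land_raster(3 * vals, 100))
  Ck <- commute_distance(gk, pts)
  expect_equal(Ck, C, tolerance = 1e-8)
  g1 <- build_graph(land_raster(vals, 100))
  expect_equal(gk$volume, g1$volume / 3, tolerance = 1e-12)
  expect_equal(Ck / gk$volume, 3 * (C / g1$volume), tolerance = 1e-8)
})

test_that("disconnected components raise an explicit error", {
  vals <- matrix(1, 5, 5)
  vals[, 3] <- NA                     # vertical barrier
  r <- land_raster(vals, cell_size = 100)
  g <- build_graph(r)
  expect_gt(max(g$component), 1)
  expect_error(
    commute_distance(g, data.frame(x = c(50, 450), y = c(250, 250))),
    "disconnected"
  )
  # both points on one side: fine
  C <- commute_distance(g, data.frame(x = c(50, 150), y = c(250, 250)))
  expect_gt(C[1, 2], 0)
})

test_that("homogeneous distance equals commute on an all-ones surface and grows with separation", {
  r <- tiny_raster(seed = 3, n = 20)
  pts <- data.frame(x = c(150, 750, 1450), y = c(1050, 1050, 1050))
  hom <- homogeneous_distance(pts, r)
  ones <- land_raster(matrix(1, 20, 20), cell_size = 100)
  expect_equal(hom, commute_distance(build_graph(ones), pts))
  # strictly increasing with Euclidean separation for collinear points
  expect_lt(hom[1, 2], hom[1, 3])
})

test_that("residualization removes the straight-line component exactly", {
  set.seed(6)
  hom <- runif(200, 1, 100)
  pred <- 2 * hom + 5
  expect_equal(residualize(pred, hom), rep(0, 200), tolerance = 1e-9)
  pred2 <- 2 * hom + rnorm(200)
  res <- residualize(pred2, hom)
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(abs(sum(res * hom)) / sqrt(sum(res^2) * sum(hom^2)), 1e-6)
  # matches the normal-equations solution
  A <- cbind(1, hom)
  beta <- solve(t(A) %*% A, t(A) %*% pred2)
  expect_equal(res, as.numeric(pred2 - A %*% beta), tolerance = 1e-8)
  expect_error(residualize(pred, rep(1, 200)), "constant")
})

test_that("collinearity screen drops the lower-priority member of correlated pairs", {
  set.seed(9)
  base <- rnorm(100)
  preds <- list(
    wetland = base,
    water = base + rnorm(100, 0, 0.1),     # r > 0.9 with wetland
    pine = rnorm(100),
    agri = rnorm(100)
  )
  kept <- collinearity_screen(preds, threshold = 0.5,
                              priority = c("wetland", "water", "pine",
                                           "agri"))
  expect_true("wetland" %in% kept)
  expect_false("water" %in% kept)
  expect_setequal(attr(kept, "dropped"), "water")
  expect_gt(attr(kept, "correlations")["wetland", "water"], 0.9)

  # duplicated predictor: exactly one retained
  kept2 <- collinearity_screen(list(a = base, b = base))
  expect_equal(unclass(kept2)[seq_along(kept2)], "a", ignore_attr = TRUE)

  # all pairwise r below threshold: all retained
  ortho <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_length(collinearity_screen(ortho, threshold = 0.99), 3)
})

test_that("pair tables join distances with residualized predictors", {
  d <- tiny_design(seed = 21, n_locations = 5, n_per_location = 2)
  pm <- enumerate_pairs(d)
  n <- nrow(d$individuals)
  set.seed(2)
  gd <- as.matrix(dist(matrix(rnorm(2 * n), ncol = 2)))
  hom <- as.matrix(dist(d$individuals[, c("x", "y")]))
  predm <- hom * 2 + 5
  pt <- pair_table(pm, gd, hom, list(agri = predm))
  expect_equal(pt$gd, gd[cbind(pm$i, pm$j)])
  expect_equal(pt$GD, hom[cbind(pm$i, pm$j)])
  # predictor exactly linear in GD: residuals vanish
  expect_equal(pt$agri, rep(0, nrow(pt)), tolerance = 1e-9)
  expect_equal(pt$agri_commute, predm[cbind(pm$i, pm$j)])
})
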