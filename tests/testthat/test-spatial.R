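test_that("lattice contiguity weights have the expected neighbour counts", {
  w <- weights_grid(2, 2, "rook")
  expect_equal(unname(rowSums(w$W)), rep(2, 4))
  expect_true(isSymmetric(w$W))
  wq <- weights_grid(3, 3, "queen")
  expect_equal(sort(unique(rowSums(wq$W))), c(3, 5, 8))
})

test_that("row standardization makes nonzero rows sum to one", {
  w <- row_standardize(weights_grid(4, 4, "rook"))
  expect_equal(unname(rowSums(w$W)), rep(1, 16), tolerance = 1e-12)
  expect_equal(w$style, "row-standardized")
})

test_that("edge lists symmetrize and reject unknown entities", {
  e <- tibble::tibble(src = "A", dst = "B")
  w <- weights_from_edges(e, entities = c("A", "B", "C"))
  expect_equal(w$W["A", "B"], 1)
  expect_equal(w$W["B", "A"], 1)
  expect_equal(sum(w$W), 2)
  expect_equal(sum(rowSums(w$W) == 0), 1)  # C is an island
  expect_error(weights_from_edges(e, entities = c("A")), "unknown")
})

test_that("k-nearest weights link each entity to exactly k neighbours", {
  set.seed(31)
  coords <- tibble::tibble(entity = sprintf("E%d", 1:10),
                           x = runif(10), y = runif(10))
  w <- weights_knn(coords, k = 3, style = "binary")
  expect_equal(unname(rowSums(w$W)), rep(3, 10))
  expect_error(weights_knn(coords, k = 10), "smaller than")
})

test_that("the checkerboard on a rook lattice attains I = -1 exactly", {
  w <- weights_grid(4, 4, "rook")
  y <- checkerboard_y()
  expect_equal(moran_i(y, w)$I, -1, tolerance = 1e-14)
})

test_that("moran_i equals the double-loop evaluation on random small instances", {
  set.seed(32)
  for (n in 4:6) {
    coords <- tibble::tibble(entity = sprintf("E%d", 1:n),
                             x = runif(n), y = runif(n))
    for (w in list(weights_knn(coords, k = 2, style = "binary"),
                   weights_idw(coords),
                   row_standardize(weights_knn(coords, k = 2, style = "binary")))) {
      y <- rnorm(n)
      expect_equal(moran_i(y, w)$I, oracle_moran(y, w$W), tolerance = 1e-12)
    }
  }
})

test_that("moran_i is exactly invariant to affine transforms of y", {
  set.seed(33)
  w <- weights_grid(3, 3, "queen")
  y <- rnorm(9)
  expect_equal(moran_i(2.5 * y - 7, w)$I, moran_i(y, w)$I, tolerance = 1e-12)
})

test_that("the exhaustive relabelling mean of I equals -1/(n-1)", {
  # cycle graphs, n = 4..6: enumerate every permutation of y
  for (n in 4:6) {
    e <- tibble::tibble(src = sprintf("E%d", seq_len(n)),
                        dst = sprintf("E%d", c(seq_len(n)[-1], 1)))
    w <- weights_from_edges(e, entities = sprintf("E%d", seq_len(n)))
    y <- c(seq_len(n - 1), n + 2)  # arbitrary distinct values
    Is <- vapply(all_perms(n), function(p) moran_i(y[p], w)$I, numeric(1))
    expect_equal(mean(Is), -1 / (n - 1), tolerance = 1e-10)
  }
})

test_that("islands are excluded and counted; degenerate inputs error", {
  e <- tibble::tibble(src = c("A", "B"), dst = c("B", "C"))
  w <- weights_from_edges(e, entities = c("A", "B", "C", "D"))
  y <- c(A = 1, B = 2, C = 5, D = NA)  # island D may be missing
  r <- moran_i(y, w)
  expect_equal(r$n, 3)
  expect_equal(r$n_islands, 1)
  expect_error(moran_i(c(A = 1, B = 1, C = 1, D = 1), w), "constant")
  expect_error(moran_i(c(A = 1, B = 2, C = NA, D = 1), w), "missing")
})

test_that("permutation test flags designed clustering and obeys the add-one rule", {
  set.seed(34)
  # two tight blocks far apart, within-block edges via knn
  coords <- tibble::tibble(
    entity = sprintf("E%d", 1:20),
    x = c(rnorm(10), rnorm(10) + 50), y = rnorm(20))
  w <- weights_knn(coords, k = 4)
  y <- stats::setNames(c(rnorm(10, 0), rnorm(10, 10)), coords$entity)
  r <- moran_test(y, w, n_perm = 999, seed = 99)
  expect_lte(r$p_perm, 0.01)
  expect_equal(r$p_perm, (1 + sum(r$perm_I >= r$I)) / 1000)
  expect_gte(r$p_perm, 1 / 1000)
})

test_that("permutation p-values are reproducible under a seed and warn when unstable", {
  set.seed(35)
  w <- weights_grid(4, 4, "rook")
  y <- rnorm(16)
  r1 <- moran_test(y, w, n_perm = 199, seed = 7)
  r2 <- moran_test(y, w, n_perm = 199, seed = 7)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_warning(moran_test(y, w, n_perm = 49, seed = 1), "unstable")
})

test_that("tidy and autoplot work on moran results", {
  w <- weights_grid(4, 4, "rook")
  set.seed(36)
  r <- moran_test(rnorm(16), w, n_perm = 199, seed = 1)
  td <- tidy(r)
  expect_equal(td$statistic, r$I)
  expect_equal(td$p.value, r$p_perm)
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("geojson representative points feed the weight builders", {
  gj <- '{"type":"FeatureCollection","features":[
    {"type":"Feature","properties":{"id":"A"},
     "geometry":{"type":"Point","coordinates":[0,0]}},
    {"type":"Feature","properties":{"id":"B"},
     "geometry":{"type":"Polygon","coordinates":[[[1,1],[3,1],[3,3],[1,3]]]}},
    {"type":"Feature","properties":{"id":"C"},
     "geometry":{"type":"Point","coordinates":[10,10]}}]}'
  path <- tempfile(fileext = ".geojson")
  writeLines(gj, path)
  pts <- read_geojson_points(path)
  expect_equal(pts$entity, c("A", "B", "C"))
  expect_equal(pts$x[2], 2)  # vertex average of the square
  w <- weights_knn(pts, k = 1, style = "binary")
  expect_equal(w$W["A", "B"], 1)  # B's centroid is A's nearest neighbour
  unlink(path)
})
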