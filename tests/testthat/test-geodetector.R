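test_that("q hits its definitional anchors: complete dependence and independence", {
  # distinct constant value within each stratum -> q = 1
  y1 <- c(2, 2, 5, 5, 9, 9)
  s1 <- c("a", "a", "b", "b", "c", "c")
  r1 <- q_statistic(y1, s1)
  expect_equal(r1$q, 1)
  expect_true(r1$saturated)
  expect_true(is.infinite(r1$F))
  expect_gt(r1$p, 0)

  # identical copy of the response in each stratum -> q = 0
  y0 <- c(1, 2, 3, 1, 2, 3)
  s0 <- rep(c("A", "B"), each = 3)
  expect_equal(q_statistic(y0, s0)$q, 0)
})

test_that("the two-strata worked example evaluates exactly", {
  # sigma2 = 35/12, each stratum variance 2/3: q = 1 - 4/17.5
  r <- q_statistic(1:6, rep(c("a", "b"), each = 3))
  expect_equal(r$q, 1 - 4 / 17.5, tolerance = 1e-14)
  expect_equal(r$sigma2, 35 / 12, tolerance = 1e-14)
  expect_equal(r$strata$sigma2i, c(2 / 3, 2 / 3), tolerance = 1e-14)
  expect_equal(r$F, ((6 - 2) / (2 - 1)) * r$q / (1 - r$q), tolerance = 1e-12)
})

test_that("q equals the brute-force variance decomposition on random instances", {
  set.seed(41)
  for (n in c(5, 8, 12)) {
    for (m in 2:3) {
      y <- rnorm(n)
      s <- sample(letters[1:m], n, replace = TRUE)
      if (length(unique(s)) < 2) s[1:2] <- c("a", "b")
      expect_equal(q_statistic(y, s)$q, oracle_q(y, s), tolerance = 1e-12)
    }
  }
})

test_that("q is invariant to affine transforms and recomputable from its parts", {
  set.seed(42)
  y <- rnorm(10)
  s <- rep(c("u", "v"), 5)
  r <- q_statistic(y, s)
  expect_equal(q_statistic(3 * y - 2, s)$q, r$q, tolerance = 1e-12)
  expect_equal(r$q, 1 - sum(r$strata$Ni * r$strata$sigma2i) / (r$N * r$sigma2),
               tolerance = 1e-14)
})

test_that("singleton strata contribute zero variance; degenerate inputs error", {
  y <- c(1, 5, 6, 7)
  r <- q_statistic(y, c("a", "b", "b", "b"))
  expect_equal(r$strata$sigma2i[r$strata$stratum == "a"], 0)
  expect_error(q_statistic(rep(1, 5), rep(c("a", "b"), c(2, 3))), "constant")
  expect_error(q_statistic(1:5, rep("a", 5)), "2")
})

test_that("noncentral-F and permutation routes broadly agree on signal strength", {
  set.seed(43)
  y <- c(rnorm(15, 0), rnorm(15, 4))
  s <- rep(c("lo", "hi"), each = 15)
  p_ncf <- q_statistic(y, s, method = "ncF")$p
  p_perm <- q_statistic(y, s, method = "permutation", seed = 9)$p
  expect_true(p_ncf >= 0 && p_ncf <= 1)
  expect_lt(p_perm, 0.05)
  # and both see no signal in noise
  yn <- rnorm(30)
  expect_gt(q_statistic(yn, s, method = "permutation", seed = 9)$p, 0.05)
})

test_that("permutation significance holds its size under the null", {
  set.seed(44)
  n <- 24
  rej <- vapply(1:500, function(i) {
    y <- rnorm(n)
    s <- sample(rep(letters[1:3], each = n / 3))
    q_statistic(y, s, method = "permutation", n_perm = 99, seed = i)$p <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("overlay interactions behave on identical, refined, and XOR designs", {
  set.seed(45)
  y <- rnorm(12)
  s1 <- rep(c("a", "b"), each = 6)
  # identical partitions: q12 = q1 = q2
  r_id <- interaction_q(y, s1, s1)
  expect_equal(r_id$q12, r_id$q1, tolerance = 1e-12)

  # refinement never lowers q
  s2 <- rep(c("a1", "a2", "b1", "b2"), each = 3)
  r_ref <- interaction_q(y, s1, s2)
  expect_gte(r_ref$q12 + 1e-12, r_ref$q1)

  # XOR: marginals see nothing, the overlay sees everything
  yx <- c(0, 0, 1, 1, 1, 1, 0, 0)
  f1 <- rep(c("L", "R"), each = 4)
  f2 <- rep(c("T", "B"), each = 2, times = 2)
  rx <- interaction_q(yx, f1, f2)
  expect_equal(rx$q1, 0, tolerance = 1e-12)
  expect_equal(rx$q2, 0, tolerance = 1e-12)
  expect_equal(rx$q12, 1, tolerance = 1e-12)
  expect_equal(rx$category, "nonlinear-enhance")

  # single-stratum overlay errors
  expect_error(interaction_q(y, rep("a", 12), rep("z", 12)), "single stratum")
})

test_that("interaction classification matches the five printed comparisons", {
  expect_equal(as.character(classify_interaction(0.3, 0.4, 0.9)), "nonlinear-enhance")
  expect_equal(as.character(classify_interaction(0.3, 0.4, 0.65)), "bivariate-enhance")
  expect_equal(as.character(classify_interaction(0.3, 0.4, 0.2)), "nonlinear-weaken")
  expect_equal(as.character(classify_interaction(0.3, 0.4, 0.35)), "uniform-weaken")
  expect_equal(as.character(classify_interaction(0.3, 0.4, 0.7)), "independent")
})

test_that("an exhaustive sweep reaches exactly the five categories", {
  grid <- seq(0, 1, by = 0.05)
  cats <- character(0)
  for (q1 in grid) for (q2 in grid) for (q12 in grid) {
    cats <- c(cats, as.character(classify_interaction(q1, q2, q12)))
  }
  expect_setequal(unique(cats),
                  c("independent", "nonlinear-enhance", "bivariate-enhance",
                    "uniform-weaken", "nonlinear-weaken"))
})

test_that("boundary q12 values are deterministically assigned and flagged", {
  b1 <- classify_interaction(0.3, 0.6, 0.6)   # q12 == max < sum
  expect_equal(as.character(b1), "bivariate-enhance")
  expect_true(isTRUE(attr(b1, "boundary")))
  b2 <- classify_interaction(0.3, 0.6, 0.3)   # q12 == min
  expect_equal(as.character(b2), "nonlinear-weaken")
  expect_true(isTRUE(attr(b2, "boundary")))
})

test_that("discretize produces the documented stratifications", {
  x <- c(1, 2, 3, 11, 12, 13)
  expect_equal(discretize(x, "jenks", 2), rep(c("s1", "s2"), each = 3))
  # equal-interval k=2 splits at the midpoint of the range
  xm <- c(0, 1, 4, 10)
  expect_equal(discretize(xm, "equal", 2), c("s1", "s1", "s1", "s2"))
  # quantile k=4 on 8 distinct values: strata of size 2
  xq <- 1:8
  expect_equal(as.integer(table(discretize(xq, "quantile", 4))), rep(2L, 4))
  expect_warning(discretize(c(1, 1, 2, 2), k = 3), "distinct")
})

test_that("the geodetector wrapper ranks a constructed dominant driver first", {
  set.seed(46)
  n <- 40
  eco <- rnorm(n)
  soc <- rnorm(n)
  resp <- eco + 0.1 * rnorm(n)
  d <- tibble::tibble(CSDI = resp, economic = eco, social = soc)
  g <- geodetector(d, y = "CSDI", x = c("economic", "social"), k = 4)
  q <- stats::setNames(g$factors$q, g$factors$driver)
  expect_gt(q[["economic"]], q[["social"]])
  expect_equal(nrow(g$interactions), 1)
  expect_s3_class(plot_interaction_matrix(g), "ggplot")
})
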