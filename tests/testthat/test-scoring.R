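h4 <- tiny_hierarchy()

test_that("min-max normalization hits its endpoints and honours direction", {
  p <- panel_from_cols(list(n1 = c(10, 20, 30), e1 = c(10, 20, 30),
                            s1 = c(1, 2, 3), s2 = c(10, 20, 30)))
  np <- normalize_panel(p, h4)
  get <- function(id) np$value[np$indicator == id]
  expect_equal(get("n1"), c(0, 0.5, 1))
  expect_equal(get("s2"), c(1, 0.5, 0))  # negative direction reverses
})

test_that("constant columns map to the 0.5 midpoint with a warning", {
  p <- panel_from_cols(list(n1 = c(7, 7, 7), e1 = c(1, 2, 3),
                            s1 = c(1, 2, 3), s2 = c(1, 2, 3)))
  expect_warning(np <- normalize_panel(p, h4), "constant")
  expect_equal(np$value[np$indicator == "n1"], c(0.5, 0.5, 0.5))
})

test_that("an all-missing indicator is an error naming it", {
  p <- panel_from_cols(list(n1 = c(NA_real_, NA, NA), e1 = c(1, 2, 3),
                            s1 = c(1, 2, 3), s2 = c(1, 2, 3)))
  expect_error(normalize_panel(p, h4), "n1")
})

test_that("pooled scope rescales across periods jointly, per-period separately", {
  p <- dplyr::bind_rows(
    panel_from_cols(list(n1 = c(0, 1), e1 = c(0, 1), s1 = c(0, 1), s2 = c(0, 1)),
                    period = "2010"),
    panel_from_cols(list(n1 = c(0, 3), e1 = c(0, 1), s1 = c(0, 1), s2 = c(0, 1)),
                    period = "2015")
  )
  pooled <- normalize_panel(p, h4, scope = "pooled")
  per <- normalize_panel(p, h4, scope = "per-period")
  n1_2010 <- function(np) np$value[np$indicator == "n1" & np$period == "2010"]
  expect_equal(max(n1_2010(pooled)), 1 / 3)  # 1 relative to pooled max 3
  expect_equal(max(n1_2010(per)), 1)         # 1 relative to 2010's own max
})

test_that("aggregation is the weighted mean up the tree on a 0-100 scale", {
  # two equal-weight indicators at 0.2 and 0.6 -> sub-theme 40
  p <- panel_from_cols(list(n1 = c(0.5, 0.6, 0.4), e1 = c(0.5, 0.1, 0.9),
                            s1 = c(0.2, 0.5, 0.5), s2 = c(0.6, 0.5, 0.5)))
  sc <- aggregate_scores(p, h4)
  expect_equal(sc$society[sc$entity == "E1"], 40)
  # CSDI is the equal-weight mean of the three theme scores
  expect_equal(sc$CSDI, (sc$natural + sc$economic + sc$social) / 3,
               tolerance = 1e-12)
})

test_that("a perfect panel scores exactly 100 at every level", {
  p <- panel_from_cols(list(n1 = c(1, 1, 1), e1 = c(1, 1, 1),
                            s1 = c(1, 1, 1), s2 = c(1, 1, 1)))
  sc <- aggregate_scores(p, h4)
  expect_equal(sc$CSDI, rep(100, 3))
  expect_equal(sc$natural, rep(100, 3))
  expect_equal(sc$society, rep(100, 3))
  expect_equal(sc$C, rep(1, 3))
  expect_equal(sc$D, rep(100, 3))
})

test_that("theme means reproduce the composite as their weighted mean", {
  # themes at 0.475 / 0.190 / 0.348 -> CSDI = mean = 33.7666...
  p <- panel_from_cols(list(n1 = c(0.475, 0, 1), e1 = c(0.190, 0, 1),
                            s1 = c(0.348, 0, 1), s2 = c(0.348, 0, 1)))
  sc <- aggregate_scores(p, h4)
  expect_equal(sc$CSDI[sc$entity == "E1"], mean(c(47.5, 19.0, 34.8)),
               tolerance = 1e-9)
})

test_that("weights renormalize over present indicators; whole-theme gaps stay missing", {
  p <- panel_from_cols(list(n1 = c(0.5, 0.4, NA), e1 = c(0.5, 0.1, 0.9),
                            s1 = c(NA, 0.5, 0.5), s2 = c(0.6, 0.5, 0.5)))
  sc <- aggregate_scores(p, h4)
  # s1 missing for E1: society falls back to s2 alone
  expect_equal(sc$society[sc$entity == "E1"], 60)
  # n1 missing for E3: the whole natural theme is missing -> CSDI missing
  expect_true(is.na(sc$natural[sc$entity == "E3"]))
  expect_true(is.na(sc$CSDI[sc$entity == "E3"]))
  expect_false(anyNA(sc$CSDI[sc$entity != "E3"]))
})

test_that("raising a positive indicator never lowers any score above it", {
  set.seed(11)
  for (rep in 1:5) {
    vals <- list(n1 = runif(4), e1 = runif(4), s1 = runif(4), s2 = runif(4))
    p <- panel_from_cols(vals)
    sc0 <- aggregate_scores(p, h4)
    vals2 <- vals
    vals2$s1[2] <- min(1, vals2$s1[2] + 0.3)
    sc1 <- aggregate_scores(panel_from_cols(vals2), h4)
    expect_gte(sc1$society[2] - sc0$society[2], -1e-12)
    expect_gte(sc1$social[2] - sc0$social[2], -1e-12)
    expect_gte(sc1$CSDI[2] - sc0$CSDI[2], -1e-12)
    expect_equal(sc1$CSDI[-2], sc0$CSDI[-2])
  }
})

test_that("normalize-then-aggregate is invariant to affine rescaling of raw columns", {
  set.seed(12)
  vals <- list(n1 = rnorm(5), e1 = rnorm(5), s1 = rnorm(5), s2 = rnorm(5))
  p <- panel_from_cols(vals)
  sc0 <- aggregate_scores(normalize_panel(p, h4), h4)
  vals2 <- vals
  vals2$n1 <- 3.7 * vals2$n1 - 11       # positive-direction: positive slope
  vals2$s2 <- 0.2 * vals2$s2 + 5        # negative-direction column too
  sc1 <- aggregate_scores(normalize_panel(panel_from_cols(vals2), h4), h4)
  expect_equal(sc1$CSDI, sc0$CSDI, tolerance = 1e-10)
})

test_that("entropy weights match the hand-computed oracle and its limits", {
  # frozen oracle: shares/entropy evaluated independently before build
  X <- cbind(a = c(0.1, 0.9, 0.2, 0.8), b = c(0.4, 0.6, 0.5, 0.5))
  w <- entropy_weights(X)
  expect_equal(unname(w), c(0.96534004, 0.03465996), tolerance = 1e-7)

  # two identical columns split the weight evenly
  X2 <- cbind(a = c(0.1, 0.5, 0.9), b = c(0.1, 0.5, 0.9))
  expect_equal(unname(entropy_weights(X2)), c(0.5, 0.5))

  # a constant column is uninformative: all weight on the varying one
  X3 <- cbind(a = c(0.3, 0.3, 0.3), b = c(0.1, 0.5, 0.9))
  expect_equal(unname(entropy_weights(X3)), c(0, 1))

  # all constant: equal weights with a warning
  X4 <- cbind(a = c(1, 1, 1), b = c(2, 2, 2))
  expect_warning(w4 <- entropy_weights(X4), "uninformative|constant")
  expect_equal(unname(w4), c(0.5, 0.5))
})

test_that("entropy weight mode runs end to end and weights stay normalized", {
  sim <- simulate_panel(sim_config(n_entities = 10, seed = 5, missing_rate = 0))
  np <- normalize_panel(sim$panel, sim$hierarchy)
  sc <- aggregate_scores(np, sim$hierarchy, weight_mode = "entropy")
  expect_true(all(sc$CSDI >= 0 & sc$CSDI <= 100))
  expect_error(
    aggregate_scores(np[np$entity %in% c("C01", "C02"), ], sim$hierarchy,
                     weight_mode = "entropy"),
    "3 entities")
})

test_that("panels reject duplicates and unknown indicators", {
  p <- panel_from_cols(list(n1 = c(1, 2), e1 = c(1, 2),
                            s1 = c(1, 2), s2 = c(1, 2)))
  expect_error(as_panel(dplyr::bind_rows(p, p[1, ])), "duplicate")
  p2 <- p
  p2$indicator[1] <- "mystery"
  expect_error(as_panel(p2, h4), "mystery")
})
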