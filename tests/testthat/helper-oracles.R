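# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's implementations: plain double loops and exhaustive
# enumeration, kept simple enough to verify by eye.

# Moran's I by literal double-loop evaluation of the defining formula,
# population variance.
oracle_moran <- function(y, W) {
  n <- length(y)
  yb <- mean(y)
  num <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * (y[i] - yb) * (y[j] - yb)
    }
  }
  s2 <- sum((y - yb)^2) / n
  num / (s2 * sum(W))
}

# Geodetector q by explicit within/total variance decomposition with
# population (divisor-N) variances.
oracle_q <- function(y, strata) {
  N <- length(y)
  sigma2 <- mean((y - mean(y))^2)
  ssw <- 0
  for (g in unique(strata)) {
    v <- y[strata == g]
    ssw <- ssw + length(v) * mean((v - mean(v))^2)
  }
  1 - ssw / (N * sigma2)
}

# Minimal within-class SSD over all contiguous k-partitions of sorted x,
# by exhaustive enumeration of split points.
oracle_jenks_ssw <- function(x, k) {
  v <- sort(x)
  n <- length(v)
  ssd <- function(seg) sum((seg - mean(seg))^2)
  if (k == 1) return(ssd(v))
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  for (s in splits) {
    bounds <- c(0, s, n)
    tot <- 0
    for (c in seq_len(k)) {
      tot <- tot + ssd(v[(bounds[c] + 1):bounds[c + 1]])
    }
    best <- min(best, tot)
  }
  best
}

# all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# 4x4 checkerboard fixture: alternating +1/-1 on a rook lattice
checkerboard_y <- function(nr = 4, nc = 4) {
  idx <- expand.grid(c = seq_len(nc), r = seq_len(nr))
  (-1)^(idx$r + idx$c)
}

# tiny two-indicator hierarchy used by scoring unit tests
tiny_hierarchy <- function() {
  nes_hierarchy(
    indicators = tibble::tibble(
      id = c("n1", "e1", "s1", "s2"),
      name = c("n1", "e1", "s1", "s2"),
      subtheme = c("nature", "economy", "society", "society"),
      theme = c("natural", "economic", "social", "social"),
      direction = c("positive", "positive", "positive", "negative"),
      weight = c(1, 1, 0.5, 0.5)
    ),
    subthemes = tibble::tibble(
      subtheme = c("nature", "economy", "society"),
      theme = c("natural", "economic", "social"),
      weight = c(1, 1, 1)
    ),
    themes = tibble::tibble(theme = c("natural", "economic", "social"),
                            weight = rep(1 / 3, 3))
  )
}

# long panel from a named list of indicator columns (one period)
panel_from_cols <- function(cols, period = "2010") {
  n <- length(cols[[1]])
  dplyr::bind_rows(lapply(names(cols), function(id) {
    tibble::tibble(entity = sprintf("E%d", seq_len(n)), indicator = id,
                   period = period, value = cols[[id]])
  }))
}
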