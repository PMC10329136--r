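#' Exact Jenks (Fisher) natural-breaks classification
#'
#' Finds the contiguous partition of the sorted values into `k` classes
#' that minimizes the within-class sum of squared deviations, by exact
#' dynamic programming (Fisher's optimal univariate partition). Ties in
#' the objective are broken deterministically toward the lowest
#' breakpoints. Classes form half-open intervals \[lower, upper) with the
#' final class closed above.
#'
#' @param x Numeric values (at least `k` distinct values).
#' @param k Number of classes, `k >= 1`.
#' @param breakpoint_style `"class-max"` (default, the classic convention:
#'   each breakpoint is the maximum value of the lower class) or
#'   `"midpoint"` (halfway between adjacent classes).
#' @return A `jenks_breaks` object: `k`, `breakpoints` (length k-1,
#'   strictly ascending), `classes` (class index 1..k per input value, in
#'   input order), `intervals` (tibble with class, lower, upper, n),
#'   `gvf` (goodness of variance fit, 1 - SSW/SST), `ssw`.
#' @export
#' @examples
#' jb <- jenks_breaks(c(1, 2, 3, 11, 12, 13), k = 2)
#' jb$classes    # 1 1 1 2 2 2
#' jb$breakpoints
jenks_breaks <- function(x, k, breakpoint_style = c("class-max", "midpoint")) {
  breakpoint_style <- match.arg(breakpoint_style)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (anyNA(x)) stop("jenks_breaks does not accept missing values", call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  ndist <- length(unique(x))
  if (k > ndist) {
    stop(sprintf("k = %d exceeds the number of distinct values (%d)", k, ndist),
         call. = FALSE)
  }
  ord <- order(x)
  v <- x[ord]
  n <- length(v)

  # prefix sums for O(1) within-segment SSD
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  seg_ssd <- function(i, j) { # SSD of v[i..j], 1-based inclusive
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }

  # D[c, j]: minimal SSW splitting v[1..j] into c classes; B[c, j]: start of last class
  D <- matrix(Inf, k, n)
  B <- matrix(NA_integer_, k, n)
  for (j in 1:n) { D[1, j] <- seg_ssd(1, j); B[1, j] <- 1L }
  if (k > 1) {
    for (c in 2:k) {
      for (j in c:n) {
        best <- Inf; bi <- NA_integer_
        for (i in c:j) {
          cand <- D[c - 1, i - 1] + seg_ssd(i, j)
          if (cand < best) { best <- cand; bi <- i }
        }
        D[c, j] <- best; B[c, j] <- bi
      }
    }
  }

  # backtrack class boundaries (indices into sorted v)
  starts <- integer(k)
  j <- n
  for (c in k:1) { starts[c] <- B[c, j]; j <- starts[c] - 1L }
  ends <- c(starts[-1] - 1L, n)

  cls_sorted <- rep(seq_len(k), times = ends - starts + 1L)
  classes <- integer(n)
  classes[ord] <- cls_sorted

  breakpoints <- if (k > 1) {
    if (breakpoint_style == "class-max") v[ends[-k]]
    else (v[ends[-k]] + v[starts[-1]]) / 2
  } else numeric(0)

  # recompute objective from the partition with the stable two-pass formula
  # (the prefix-sum shortcut can lose a few ulps)
  ssw <- sum(vapply(seq_len(k), function(c) {
    seg <- v[starts[c]:ends[c]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
  sst <- sum((v - mean(v))^2)
  gvf <- if (sst > 0) 1 - ssw / sst else 0
  if (k == 1) gvf <- 0

  intervals <- tibble::tibble(
    class = seq_len(k),
    lower = v[starts], upper = v[ends],
    n = ends - starts + 1L
  )
  structure(list(k = k, breakpoints = breakpoints, classes = classes,
                 intervals = intervals, gvf = gvf, ssw = ssw,
                 breakpoint_style = breakpoint_style),
            class = "jenks_breaks")
}

#' @export
print.jenks_breaks <- function(x, ...) {
  cat(sprintf("Jenks natural breaks: k = %d, GVF = %.4f\n", x$k, x$gvf))
  lab <- sprintf("%s[%.4g-%.4g] (n=%d)",
                 utils::as.roman(x$intervals$class), x$intervals$lower,
                 x$intervals$upper, x$intervals$n)
  cat(" ", paste(lab, collapse = "  "), "\n")
  invisible(x)
}

#' Classify entity scores into Jenks interval classes
#'
#' Applies [jenks_breaks()] to one column of a score table and appends the
#' class index and a Roman-numeral label (I = lowest interval), the
#' convention used for mapping composite sustainability scores into
#' levels.
#'
#' @param data A data frame of scores.
#' @param by Column to classify (default `"CSDI"`).
#' @param k Number of classes (default 4).
#' @return The input with added integer `class` and character
#'   `class_label` columns; the `jenks_breaks` fit is attached as the
#'   `"breaks"` attribute.
#' @export
classify_scores <- function(data, by = "CSDI", k = 4) {
  stopifnot(by %in% names(data))
  ok <- !is.na(data[[by]])
  jb <- jenks_breaks(data[[by]][ok], k)
  data$class <- NA_integer_
  data$class[ok] <- jb$classes
  data$class_label <- ifelse(is.na(data$class), NA_character_,
                             as.character(utils::as.roman(data$class)))
  attr(data, "breaks") <- jb
  data
}
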