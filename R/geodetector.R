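#' Geographical detector q-statistic
#'
#' The factor detector measures how much of a response's variance a
#' categorical stratification explains:
#' \deqn{q = 1 - \frac{\sum_{h=1}^{m} N_h \sigma_h^2}{N \sigma^2}}
#' with population (divisor-N) variances, so \eqn{q \in [0, 1]}: 0 means
#' the strata carry no information about the response and 1 means the
#' response is completely determined by the strata. Significance follows
#' the noncentral-F reference of the geographical-detector methodology:
#' \eqn{F = \frac{N - m}{m - 1}\,\frac{q}{1 - q}} compared against a
#' noncentral F with \eqn{(m-1, N-m)} degrees of freedom and noncentrality
#' \deqn{\lambda = \frac{1}{\sigma^2}\left[\sum_h \bar Y_h^2 N_h -
#'   \frac{1}{N}\left(\sum_h \sqrt{N_h}\,\bar Y_h\right)^2\right].}
#' A model-free permutation p-value (random reassignment of stratum
#' labels) is available as an independent route.
#'
#' @param y Numeric response, one value per entity, no missing values.
#' @param strata Stratum labels, same length as `y`; at least 2 nonempty
#'   strata. Singleton strata are allowed and contribute zero within-stratum
#'   variance.
#' @param method `"ncF"` (noncentral-F significance, default) or
#'   `"permutation"`.
#' @param n_perm Permutations for `method = "permutation"` (default 999).
#' @param seed Seed for the permutation route.
#' @return A `q_result`: `q`, `N`, `sigma2`, per-stratum tibble `strata`
#'   (`stratum`, `Ni`, `sigma2i`, `mean`), `F`, `p`, `method`, and
#'   `saturated` (TRUE when q = 1 so F is infinite and `p` is reported as
#'   the smallest representable positive value).
#' @export
#' @examples
#' y <- c(1, 2, 3, 4, 5, 6)
#' q_statistic(y, rep(c("a", "b"), each = 3))$q  # 1 - 4/17.5
q_statistic <- function(y, strata, method = c("ncF", "permutation"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  if (length(y) != length(strata)) {
    stop("y and strata must have the same length", call. = FALSE)
  }
  if (anyNA(y) || anyNA(strata)) {
    stop("q_statistic does not accept missing values", call. = FALSE)
  }
  N <- length(y)
  if (N < 3) stop("q_statistic needs N >= 3", call. = FALSE)
  strata <- as.character(strata)
  m <- length(unique(strata))
  if (m < 2) stop("q_statistic needs at least 2 nonempty strata", call. = FALSE)

  pop_var <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2) / length(v)
  sigma2 <- pop_var(y)
  if (sigma2 == 0) stop("constant response: q undefined", call. = FALSE)

  per <- tibble::tibble(stratum = strata, y = y) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(Ni = dplyr::n(),
                     sigma2i = pop_var(.data$y),
                     mean = mean(.data$y), .groups = "drop")

  q <- 1 - sum(per$Ni * per$sigma2i) / (N * sigma2)
  q <- min(max(q, 0), 1)
  saturated <- (1 - q) < 1e-14

  if (saturated) {
    Fstat <- Inf
    p <- .Machine$double.xmin
  } else {
    Fstat <- ((N - m) / (m - 1)) * q / (1 - q)
    if (method == "ncF") {
      lambda <- (sum(per$mean^2 * per$Ni) -
                   sum(sqrt(per$Ni) * per$mean)^2 / N) / sigma2
      p <- stats::pf(Fstat, m - 1, N - m, ncp = max(lambda, 0), lower.tail = FALSE)
    } else {
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
        set.seed(seed)
      }
      qs <- replicate(n_perm, q_value_only(y, sample(strata)))
      p <- (1 + sum(qs >= q)) / (n_perm + 1)
    }
  }
  structure(list(q = q, N = N, sigma2 = sigma2, strata = per,
                 F = Fstat, p = p, method = method, m = m,
                 saturated = saturated),
            class = "q_result")
}

# bare q computation used by the permutation null
q_value_only <- function(y, strata) {
  N <- length(y)
  ssw <- sum(vapply(split(y, strata), function(v) {
    if (length(v) < 2) 0 else sum((v - mean(v))^2)
  }, numeric(1)))
  sst <- sum((y - mean(y))^2)
  1 - ssw / sst
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Geodetector q = %.4f (N = %d, m = %d strata), F = %.4g, p = %.4g [%s]\n",
              x$q, x$N, x$m, x$F, x$p, x$method))
  invisible(x)
}

#' Classify the interaction between two drivers
#'
#' Compares the q of the overlay of two stratifications with the marginal
#' q values, yielding the five canonical interaction categories:
#' independent (\eqn{q_{12} = q_1 + q_2}), nonlinear-enhance
#' (\eqn{q_{12} > q_1 + q_2}), bivariate-enhance
#' (\eqn{\max(q_1,q_2) < q_{12} < q_1 + q_2}), uniform-weaken
#' (\eqn{\min(q_1,q_2) < q_{12} < \max(q_1,q_2)}), and nonlinear-weaken
#' (\eqn{q_{12} < \min(q_1,q_2)}). Equality with the sum is judged within
#' `tolerance`; a `q12` landing exactly on the max (or min) boundary is
#' assigned deterministically to the adjacent bivariate-enhance
#' (nonlinear-weaken) class and flagged via the `boundary` attribute.
#'
#' @param q1,q2 Marginal q values in \[0, 1\].
#' @param q12 Overlay q value in \[0, 1\].
#' @param tolerance Comparison epsilon for the equality cases (default 1e-9).
#' @return A length-1 character: one of `"independent"`,
#'   `"nonlinear-enhance"`, `"bivariate-enhance"`, `"uniform-weaken"`,
#'   `"nonlinear-weaken"`, with attribute `boundary = TRUE` when q12 sat on
#'   a min/max boundary.
#' @export
#' @examples
#' classify_interaction(0.3, 0.4, 0.9)   # nonlinear-enhance
#' classify_interaction(0.3, 0.4, 0.65)  # bivariate-enhance
classify_interaction <- function(q1, q2, q12, tolerance = 1e-9) {
  stopifnot(all(is.finite(c(q1, q2, q12))),
            all(c(q1, q2, q12) >= -tolerance), all(c(q1, q2, q12) <= 1 + tolerance))
  hi <- max(q1, q2); lo <- min(q1, q2); s <- q1 + q2
  boundary <- FALSE
  cat <- if (abs(q12 - s) <= tolerance) {
    "independent"
  } else if (q12 > s) {
    "nonlinear-enhance"
  } else if (abs(q12 - hi) <= tolerance) {
    boundary <- TRUE
    "bivariate-enhance"
  } else if (q12 > hi) {
    "bivariate-enhance"
  } else if (abs(q12 - lo) <= tolerance) {
    boundary <- TRUE
    "nonlinear-weaken"
  } else if (q12 < lo) {
    "nonlinear-weaken"
  } else {
    "uniform-weaken"
  }
  if (boundary) attr(cat, "boundary") <- TRUE
  cat
}

#' Interaction detector for two stratifications
#'
#' Overlays two stratifications (the pairwise intersection of their
#' labels), computes q on the overlay and on each marginal, and classifies
#' the interaction.
#'
#' @inheritParams q_statistic
#' @param strata1,strata2 Two stratum label vectors aligned with `y`.
#' @param tolerance Epsilon for [classify_interaction()].
#' @return An `interaction_result`: `q1`, `q2`, `q12`, `category`,
#'   `tolerance`.
#' @export
interaction_q <- function(y, strata1, strata2, tolerance = 1e-9) {
  s1 <- as.character(strata1); s2 <- as.character(strata2)
  overlay <- paste(s1, s2, sep = "∩")
  if (length(unique(overlay)) < 2) {
    stop("overlay of the two stratifications yields a single stratum", call. = FALSE)
  }
  q1 <- q_statistic(y, s1)$q
  q2 <- q_statistic(y, s2)$q
  q12 <- q_statistic(y, overlay)$q
  category <- classify_interaction(q1, q2, q12, tolerance)
  structure(list(q1 = q1, q2 = q2, q12 = q12,
                 category = as.character(category),
                 boundary = isTRUE(attr(category, "boundary")),
                 tolerance = tolerance),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("q1 = %.4f, q2 = %.4f, q(X1∩X2) = %.4f -> %s\n",
              x$q1, x$q2, x$q12, x$category))
  invisible(x)
}

#' Discretize a continuous driver into strata
#'
#' Continuous drivers must be stratified before entering the factor
#' detector. Three standard schemes are offered; when the data hold fewer
#' distinct values than `k`, `k` is reduced with a warning.
#'
#' @param x Numeric vector.
#' @param method `"jenks"` (natural breaks, default), `"quantile"`, or
#'   `"equal"` (equal-width intervals).
#' @param k Number of classes, at least 2.
#' @return A character vector of stratum labels `"s1"..."sk"`.
#' @export
discretize <- function(x, method = c("jenks", "quantile", "equal"), k = 5) {
  method <- match.arg(method)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (anyNA(x)) stop("discretize does not accept missing values", call. = FALSE)
  ndist <- length(unique(x))
  if (ndist < k) {
    warning(sprintf("only %d distinct values; reducing k from %d", ndist, k),
            call. = FALSE)
    k <- ndist
    if (k < 2) stop("cannot stratify a constant vector", call. = FALSE)
  }
  cls <- switch(method,
    jenks = jenks_breaks(x, k)$classes,
    quantile = {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1)))
      findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
    },
    equal = {
      br <- seq(min(x), max(x), length.out = k + 1)
      findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
    })
  sprintf("s%d", cls)
}

#' Factor and interaction detectors over a score table
#'
#' Convenience wrapper reproducing the driver analysis: each candidate
#' driver column is discretized (jenks, k = 5 by default), its factor-
#' detector q and p against the response are computed, and every driver
#' pair is run through the interaction detector.
#'
#' @param data A data frame (e.g. a `csd_scores` table).
#' @param y Name of the response column (e.g. `"CSDI"`).
#' @param x Character vector of driver column names.
#' @param method Significance route passed to [q_statistic()].
#' @param discretize_method,k Stratification scheme for continuous drivers.
#' @param seed Seed for the permutation route.
#' @return A `geodetector_result` with tibbles `factors` (driver, q, F, p)
#'   and `interactions` (x1, x2, q1, q2, q12, category).
#' @export
#' @examples
#' h <- default_nes_hierarchy()
#' sim <- simulate_panel(sim_config(n_entities = 25, seed = 3))
#' scores <- normalize_panel(sim$panel, h) |> aggregate_scores(h)
#' geodetector(scores, y = "CSDI", x = c("economic", "social", "water"))
geodetector <- function(data, y, x, method = c("ncF", "permutation"),
                        discretize_method = "jenks", k = 5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(y %in% names(data), all(x %in% names(data)))
  keep <- stats::complete.cases(data[c(y, x)])
  data <- data[keep, ]
  yy <- data[[y]]
  strata <- lapply(data[x], discretize, method = discretize_method, k = k)
  factors <- dplyr::bind_rows(lapply(x, function(v) {
    r <- q_statistic(yy, strata[[v]], method = method, seed = seed)
    tibble::tibble(driver = v, q = r$q, F = r$F, p = r$p, m = r$m)
  }))
  pairs <- if (length(x) >= 2) utils::combn(x, 2, simplify = FALSE) else list()
  interactions <- dplyr::bind_rows(lapply(pairs, function(pr) {
    r <- interaction_q(yy, strata[[pr[1]]], strata[[pr[2]]])
    tibble::tibble(x1 = pr[1], x2 = pr[2], q1 = r$q1, q2 = r$q2,
                   q12 = r$q12, category = r$category)
  }))
  structure(list(factors = factors, interactions = interactions,
                 response = y, n = nrow(data), method = method),
            class = "geodetector_result")
}

#' @export
print.geodetector_result <- function(x, ...) {
  cat(sprintf("Geographical detector on '%s' (n = %d, %s significance)\n",
              x$response, x$n, x$method))
  print(x$factors)
  if (nrow(x$interactions) > 0) {
    cat("Interactions:\n")
    print(x$interactions)
  }
  invisible(x)
}
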