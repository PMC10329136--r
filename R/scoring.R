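#' Validate and coerce a long indicator panel
#'
#' A panel is a long tibble with one row per (entity, indicator, period)
#' cell: columns `entity`, `indicator`, `period`, `value`. Missing values
#' are allowed; duplicate cells are not.
#'
#' @param panel A data frame in long format.
#' @param hierarchy Optional `nes_hierarchy`; when given, every indicator in
#'   the panel must be declared in it.
#' @return The panel as a tibble with columns in canonical order.
#' @export
as_panel <- function(panel, hierarchy = NULL) {
  need <- c("entity", "indicator", "period", "value")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  panel <- tibble::as_tibble(panel)[need]
  panel$entity <- as.character(panel$entity)
  panel$indicator <- as.character(panel$indicator)
  panel$period <- as.character(panel$period)
  if (!is.numeric(panel$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(panel$value))) & !is.na(panel$value))
    if (length(bad) > 0) {
      stop("non-numeric value in panel row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    panel$value <- as.numeric(panel$value)
  }
  key <- paste(panel$entity, panel$indicator, panel$period, sep = "\r")
  if (anyDuplicated(key)) {
    d <- panel[duplicated(key), ][1, ]
    stop(sprintf("duplicate panel cell: entity=%s indicator=%s period=%s",
                 d$entity, d$indicator, d$period), call. = FALSE)
  }
  if (length(unique(panel$entity)) < 2) {
    stop("panel needs at least 2 entities", call. = FALSE)
  }
  if (!is.null(hierarchy)) {
    unknown <- setdiff(unique(panel$indicator), hierarchy$indicators$id)
    if (length(unknown) > 0) {
      stop("panel contains indicator(s) not in the hierarchy: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  panel
}

#' Min-max normalize a raw indicator panel
#'
#' Rescales each indicator to \[0, 1\] within the chosen scope, honouring
#' the indicator's direction: for positive indicators
#' \eqn{(x - \min)/(\max - \min)}, for negative indicators
#' \eqn{(\max - x)/(\max - \min)}, so 1 always means "most sustainable".
#' Missing cells stay missing. A degenerate column (all present values
#' equal, so max = min) is mapped to the uninformative midpoint 0.5 with a
#' warning rather than aborting the run.
#'
#' @param panel A long panel (see [as_panel()]).
#' @param hierarchy A `nes_hierarchy` supplying indicator directions.
#' @param scope `"pooled"` (default) rescales each indicator over all
#'   periods jointly, keeping scores comparable across time; `"per-period"`
#'   rescales within each period separately.
#' @return A tibble like `panel` with `value` in \[0, 1\].
#' @export
#' @examples
#' h <- default_nes_hierarchy()
#' p <- simulate_panel(sim_config(n_entities = 5, seed = 1))$panel
#' np <- normalize_panel(p, h)
#' range(np$value, na.rm = TRUE)
normalize_panel <- function(panel, hierarchy, scope = c("pooled", "per-period")) {
  scope <- match.arg(scope)
  panel <- as_panel(panel, hierarchy)
  dir <- stats::setNames(hierarchy$indicators$direction, hierarchy$indicators$id)

  out <- panel |>
    dplyr::group_by(.data$indicator,
                    .group_period = if (scope == "per-period") .data$period else "") |>
    dplyr::group_modify(function(df, key) {
      v <- df$value
      if (all(is.na(v))) {
        stop(sprintf("indicator '%s' has no observed values in scope", key$indicator),
             call. = FALSE)
      }
      lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
      if (hi == lo) {
        warning(sprintf("indicator '%s' is constant in scope; mapped to 0.5",
                        key$indicator), call. = FALSE)
        df$value <- ifelse(is.na(v), NA_real_, 0.5)
      } else if (dir[[key$indicator]] == "negative") {
        df$value <- (hi - v) / (hi - lo)
      } else {
        df$value <- (v - lo) / (hi - lo)
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select(!".group_period") |>
    dplyr::select("entity", "indicator", "period", "value")
  out
}

#' Entropy-method weights for a group of indicator columns
#'
#' Classic entropy weighting: with observations \eqn{i = 1..n} and columns
#' \eqn{j}, shares \eqn{p_{ij} = x_{ij} / \sum_i x_{ij}}, entropy
#' \eqn{e_j = -(1/\ln n) \sum_i p_{ij} \ln p_{ij}} (with \eqn{0 \ln 0 := 0}),
#' and weight \eqn{w_j = (1 - e_j) / \sum_k (1 - e_k)}. A constant column has
#' maximal entropy and receives zero weight; if every column is constant the
#' weights fall back to equal shares with a warning.
#'
#' @param x A numeric matrix or data frame of nonnegative values
#'   (observations in rows, sibling indicators in columns). Rows with
#'   missing entries are dropped column-wise.
#' @return A named weight vector summing to 1.
#' @export
entropy_weights <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("entropy weights need at least 3 observations", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) stop("entropy weights require nonnegative values", call. = FALSE)
  ent <- apply(x, 2, function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    if (n < 2 || sum(col) == 0) return(1)
    p <- col / sum(col)
    p <- p[p > 0]
    -sum(p * log(p)) / log(n)
  })
  d <- pmax(0, 1 - ent)
  if (sum(d) <= .Machine$double.eps * ncol(x)) {
    warning("all columns are uninformative (constant); using equal entropy weights",
            call. = FALSE)
    d <- rep(1, ncol(x))
  }
  w <- d / sum(d)
  stats::setNames(w, colnames(x))
}

#' Aggregate a normalized panel into sub-theme, theme, and composite scores
#'
#' Rolls normalized indicator values up the hierarchy on a 0-100 scale:
#' sub-theme score = 100 x weighted mean of its present indicators (weights
#' renormalized over the present subset, no imputation); theme score =
#' weighted mean of its present sub-theme scores; the composite CSDI =
#' weighted mean of the theme scores. The coupling degree C, coordination
#' index T, and coupling-coordination degree D of the three theme scores
#' (see [coupling_coordination()]) are reported alongside. An entity-period
#' whose entire theme is missing gets a missing CSDI rather than an imputed
#' one.
#'
#' @param norm A normalized panel from [normalize_panel()].
#' @param hierarchy A `nes_hierarchy`.
#' @param weight_mode `"config"` uses the hierarchy's weights; `"entropy"`
#'   replaces indicator-level weights with entropy-method weights estimated
#'   from the normalized values (sub-theme and theme weights stay as
#'   configured). Entropy mode needs at least 3 entities.
#' @param alpha Coordination weights for the three themes in the
#'   coupling-coordination model; defaults to the hierarchy's theme weights.
#' @return A `csd_scores` tibble with one row per entity-period: a column
#'   per sub-theme and theme, `C`, `T`, `D`, and `CSDI`.
#' @export
#' @examples
#' h <- default_nes_hierarchy()
#' sim <- simulate_panel(sim_config(n_entities = 8, seed = 1))
#' scores <- normalize_panel(sim$panel, h) |> aggregate_scores(h)
#' dplyr::glimpse(scores)
aggregate_scores <- function(norm, hierarchy,
                             weight_mode = c("config", "entropy"),
                             alpha = NULL) {
  weight_mode <- match.arg(weight_mode)
  norm <- as_panel(norm, hierarchy)
  v <- norm$value[!is.na(norm$value)]
  if (length(v) > 0 && (min(v) < -1e-12 || max(v) > 1 + 1e-12)) {
    stop("aggregate_scores expects normalized values in [0, 1]; run normalize_panel first",
         call. = FALSE)
  }
  ind <- hierarchy$indicators
  if (weight_mode == "entropy") {
    if (length(unique(norm$entity)) < 3) {
      stop("entropy weighting needs at least 3 entities", call. = FALSE)
    }
    wide <- tidyr::pivot_wider(norm, names_from = "indicator", values_from = "value")
    for (st in unique(ind$subtheme)) {
      ids <- ind$id[ind$subtheme == st]
      ids <- intersect(ids, names(wide))
      if (length(ids) < 2) next
      w <- entropy_weights(wide[ids])
      ind$weight[match(ids, ind$id)] <- w
    }
  }

  joined <- dplyr::left_join(norm, ind[c("id", "subtheme", "theme", "weight")],
                             by = c(indicator = "id"))

  sub_scores <- joined |>
    dplyr::group_by(.data$entity, .data$period, .data$subtheme, .data$theme) |>
    dplyr::summarise(
      score = if (all(is.na(.data$value))) NA_real_ else {
        ok <- !is.na(.data$value)
        100 * sum(.data$weight[ok] * .data$value[ok]) / sum(.data$weight[ok])
      },
      .groups = "drop"
    )

  sub_w <- stats::setNames(hierarchy$subthemes$weight, hierarchy$subthemes$subtheme)
  theme_scores <- sub_scores |>
    dplyr::group_by(.data$entity, .data$period, .data$theme) |>
    dplyr::summarise(
      score = {
        w <- sub_w[.data$subtheme]
        ok <- !is.na(.data$score)
        if (!any(ok)) NA_real_ else sum(w[ok] * .data$score[ok]) / sum(w[ok])
      },
      .groups = "drop"
    )

  thm_w <- stats::setNames(hierarchy$themes$weight, hierarchy$themes$theme)
  csdi <- theme_scores |>
    dplyr::group_by(.data$entity, .data$period) |>
    dplyr::summarise(
      CSDI = {
        w <- thm_w[.data$theme]
        if (any(is.na(.data$score))) NA_real_
        else sum(w * .data$score) / sum(w)
      },
      .groups = "drop"
    )

  sub_wide <- tidyr::pivot_wider(sub_scores[c("entity", "period", "subtheme", "score")],
                                 names_from = "subtheme", values_from = "score")
  thm_wide <- tidyr::pivot_wider(theme_scores, names_from = "theme", values_from = "score")

  out <- sub_wide |>
    dplyr::left_join(thm_wide, by = c("entity", "period")) |>
    dplyr::left_join(csdi, by = c("entity", "period"))

  theme_order <- hierarchy$themes$theme
  if (is.null(alpha)) alpha <- hierarchy$themes$weight
  U <- as.matrix(out[theme_order]) / 100
  cc <- coupling_coordination(U[, 1], U[, 2], U[, 3], alpha = alpha)
  out$C <- cc$C
  out$T <- cc$T
  out$D <- cc$D
  out <- out[c("entity", "period", hierarchy$subthemes$subtheme, theme_order,
               "C", "T", "D", "CSDI")]
  out <- out[order(out$entity, out$period), ]
  structure(out, class = c("csd_scores", class(out)),
            hierarchy = hierarchy, weight_mode = weight_mode)
}
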