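#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Moran test
#'
#' @param x A `moran_test` or `moran_result`.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, its null expectation, and
#'   (for tests) the permutation p-value.
#' @method tidy moran_result
#' @export
tidy.moran_result <- function(x, ...) {
  out <- tibble::tibble(statistic = x$I, expected = x$expected_I,
                        n = x$n, n_islands = x$n_islands)
  if (!is.null(x$p_perm)) {
    out$p.value <- x$p_perm
    out$n_perm <- x$n_perm
    out$tail <- x$tail
  }
  out
}

#' @rdname tidy.moran_result
#' @method glance moran_result
#' @export
glance.moran_result <- function(x, ...) tidy.moran_result(x, ...)

#' Tidy a geodetector q result
#'
#' @param x A `q_result`.
#' @param ... Unused.
#' @return A one-row tibble with `q`, `statistic` (F), `p.value`, `N`, `m`.
#' @method tidy q_result
#' @export
tidy.q_result <- function(x, ...) {
  tibble::tibble(q = x$q, statistic = x$F, p.value = x$p,
                 N = x$N, m = x$m, method = x$method)
}

#' @rdname tidy.q_result
#' @method glance q_result
#' @export
glance.q_result <- function(x, ...) tidy.q_result(x, ...)

#' Tidy an interaction-detector result
#'
#' @param x An `interaction_result`.
#' @param ... Unused.
#' @return A one-row tibble with the marginal and overlay q values and the
#'   interaction category.
#' @method tidy interaction_result
#' @export
tidy.interaction_result <- function(x, ...) {
  tibble::tibble(q1 = x$q1, q2 = x$q2, q12 = x$q12,
                 category = x$category, boundary = x$boundary)
}

#' Tidy Jenks breaks
#'
#' @param x A `jenks_breaks`.
#' @param ... Unused.
#' @return The class-interval tibble (`class`, `lower`, `upper`, `n`).
#' @method tidy jenks_breaks
#' @export
tidy.jenks_breaks <- function(x, ...) x$intervals

#' @rdname tidy.jenks_breaks
#' @method glance jenks_breaks
#' @export
glance.jenks_breaks <- function(x, ...) {
  tibble::tibble(k = x$k, gvf = x$gvf, ssw = x$ssw)
}
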