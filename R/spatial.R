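#' Spatial weight matrices
#'
#' A `spatial_weights` object wraps an n x n nonnegative matrix `W` with a
#' zero diagonal, the ordered entity keys, the construction scheme, and the
#' style (`"binary"` or `"row-standardized"`). Entities with an all-zero
#' row are "islands": they are permitted, counted, and excluded from
#' autocorrelation statistics.
#'
#' @param W A square numeric matrix, zero diagonal, nonnegative entries.
#' @param entities Character keys, one per row of `W`. Defaults to the
#'   rownames of `W`.
#' @param style `"binary"` or `"row-standardized"`.
#' @param scheme A label recording how the matrix was built.
#' @return A `spatial_weights` object.
#' @export
spatial_weights <- function(W, entities = rownames(W),
                            style = c("binary", "row-standardized"),
                            scheme = "explicit") {
  style <- match.arg(style)
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square", call. = FALSE)
  if (is.null(entities)) entities <- as.character(seq_len(nrow(W)))
  if (length(entities) != nrow(W)) {
    stop("entities must match the dimension of W", call. = FALSE)
  }
  if (any(W < 0)) stop("spatial weights must be nonnegative", call. = FALSE)
  diag(W) <- 0
  dimnames(W) <- list(entities, entities)
  structure(list(entities = as.character(entities), W = W,
                 style = style, scheme = scheme),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  rs <- rowSums(x$W)
  cat(sprintf("<spatial_weights> n=%d scheme=%s style=%s islands=%d\n",
              length(x$entities), x$scheme, x$style, sum(rs == 0)))
  invisible(x)
}

#' Row-standardize a weight matrix
#'
#' Divides every nonzero row by its sum, so rows sum to one; zero rows
#' (islands) are left untouched.
#'
#' @param w A `spatial_weights` object.
#' @return A `spatial_weights` with style `"row-standardized"`.
#' @export
row_standardize <- function(w) {
  stopifnot(inherits(w, "spatial_weights"))
  rs <- rowSums(w$W)
  W <- w$W
  nz <- rs > 0
  W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  spatial_weights(W, w$entities, style = "row-standardized", scheme = w$scheme)
}

#' Weights from an explicit edge list
#'
#' @param edges A data frame with columns `src`, `dst` and optionally `w`
#'   (default weight 1).
#' @param entities Entity universe; defaults to the keys appearing in the
#'   edge list. Unknown keys in `edges` are an error when `entities` is
#'   given.
#' @param symmetrize Mirror each edge so `W[i,j] == W[j,i]` (default).
#' @param style Output style; row-standardization is applied after
#'   symmetrization.
#' @return A `spatial_weights`.
#' @export
weights_from_edges <- function(edges, entities = NULL, symmetrize = TRUE,
                               style = c("binary", "row-standardized")) {
  style <- match.arg(style)
  if (!all(c("src", "dst") %in% names(edges))) {
    stop("edge list needs columns 'src' and 'dst'", call. = FALSE)
  }
  if (!"w" %in% names(edges)) edges$w <- 1
  keys <- unique(c(edges$src, edges$dst))
  if (is.null(entities)) {
    entities <- sort(keys)
  } else {
    unknown <- setdiff(keys, entities)
    if (length(unknown) > 0) {
      stop("edge list references unknown entities: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  n <- length(entities)
  W <- matrix(0, n, n, dimnames = list(entities, entities))
  for (i in seq_len(nrow(edges))) {
    W[edges$src[i], edges$dst[i]] <- edges$w[i]
    if (symmetrize) W[edges$dst[i], edges$src[i]] <- edges$w[i]
  }
  out <- spatial_weights(W, entities, style = "binary", scheme = "explicit")
  if (style == "row-standardized") out <- row_standardize(out)
  out
}

#' Contiguity weights on a regular lattice
#'
#' Rook contiguity links edge-sharing cells; queen contiguity additionally
#' links diagonal neighbors. Entities are labelled `"r-c"` in row-major
#' order.
#'
#' @param nrow,ncol Lattice dimensions.
#' @param scheme `"rook"` or `"queen"`.
#' @param style Output style.
#' @return A `spatial_weights`.
#' @export
#' @examples
#' w <- weights_grid(2, 2, "rook")
#' rowSums(w$W)  # every cell of a 2x2 lattice has exactly 2 rook neighbors
weights_grid <- function(nrow, ncol, scheme = c("rook", "queen"),
                         style = c("binary", "row-standardized")) {
  scheme <- match.arg(scheme)
  style <- match.arg(style)
  idx <- expand.grid(c = seq_len(ncol), r = seq_len(nrow))[, c("r", "c")]
  ent <- sprintf("%d-%d", idx$r, idx$c)
  n <- nrow * ncol
  W <- matrix(0, n, n, dimnames = list(ent, ent))
  for (i in seq_len(n)) {
    dr <- abs(idx$r - idx$r[i]); dc <- abs(idx$c - idx$c[i])
    nb <- if (scheme == "rook") (dr + dc) == 1 else (pmax(dr, dc) == 1)
    W[i, nb] <- 1
  }
  out <- spatial_weights(W, ent, style = "binary",
                         scheme = paste0(scheme, "-contiguity"))
  if (style == "row-standardized") out <- row_standardize(out)
  out
}

#' k-nearest-neighbour weights from point coordinates
#'
#' The default scheme for country-level work: each entity is linked to its
#' `k` nearest representative points (Euclidean distance), then the matrix
#' is row-standardized. Note k-nearest graphs are directed; they are not
#' symmetrized.
#'
#' @param coords A data frame with columns `entity`, `x`, `y`.
#' @param k Number of neighbours, `1 <= k < n`.
#' @param style Output style; default row-standardized.
#' @return A `spatial_weights`.
#' @export
weights_knn <- function(coords, k = 4,
                        style = c("row-standardized", "binary")) {
  style <- match.arg(style)
  stopifnot(all(c("entity", "x", "y") %in% names(coords)))
  n <- nrow(coords)
  if (k >= n) stop(sprintf("k = %d must be smaller than n = %d", k, n), call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  D <- as.matrix(stats::dist(coords[c("x", "y")]))
  diag(D) <- Inf
  W <- matrix(0, n, n, dimnames = list(coords$entity, coords$entity))
  for (i in seq_len(n)) {
    W[i, order(D[i, ])[seq_len(k)]] <- 1
  }
  out <- spatial_weights(W, coords$entity, style = "binary", scheme = "k-nearest")
  if (style == "row-standardized") out <- row_standardize(out)
  out
}

#' Inverse-distance weights from point coordinates
#'
#' @param coords A data frame with columns `entity`, `x`, `y`.
#' @param power Distance decay exponent (default 1).
#' @param style Output style.
#' @return A `spatial_weights`.
#' @export
weights_idw <- function(coords, power = 1,
                        style = c("row-standardized", "binary")) {
  style <- match.arg(style)
  stopifnot(all(c("entity", "x", "y") %in% names(coords)))
  D <- as.matrix(stats::dist(coords[c("x", "y")]))
  if (any(D[upper.tri(D)] == 0)) {
    stop("coincident points give infinite inverse-distance weights", call. = FALSE)
  }
  W <- 1 / D^power
  diag(W) <- 0
  out <- spatial_weights(W, coords$entity, style = "binary",
                         scheme = "inverse-distance")
  if (style == "row-standardized") out <- row_standardize(out)
  out
}

#' Representative points from a GeoJSON file
#'
#' Reads a GeoJSON FeatureCollection (WGS84 lon/lat) and returns one
#' representative point per feature: Point coordinates directly, and the
#' vertex average of the outer ring for Polygon/MultiPolygon features. The
#' entity key is taken from the feature property named by `key`.
#'
#' @param path Path to a `.geojson`/`.json` file.
#' @param key Property holding the entity key (default `"id"`, falling back
#'   to `"name"`).
#' @return A tibble with columns `entity`, `x`, `y` suitable for
#'   [weights_knn()] / [weights_idw()].
#' @export
read_geojson_points <- function(path, key = "id") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats)) stop("not a GeoJSON FeatureCollection", call. = FALSE)
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    props <- f$properties
    ent <- props[[key]]
    if (is.null(ent)) ent <- props[["name"]]
    if (is.null(ent)) ent <- as.character(i)
    g <- f$geometry
    xy <- switch(g$type,
      Point = unlist(g$coordinates)[1:2],
      Polygon = {
        ring <- do.call(rbind, lapply(g$coordinates[[1]], function(p) unlist(p)[1:2]))
        colMeans(ring)
      },
      MultiPolygon = {
        ring <- do.call(rbind, lapply(g$coordinates[[1]][[1]], function(p) unlist(p)[1:2]))
        colMeans(ring)
      },
      stop(sprintf("unsupported geometry type '%s'", g$type), call. = FALSE)
    )
    tibble::tibble(entity = as.character(ent), x = xy[1], y = xy[2])
  })
  dplyr::bind_rows(rows)
}

# Align y (named or positional) with the weights, dropping islands.
align_y_weights <- function(y, w) {
  stopifnot(inherits(w, "spatial_weights"))
  if (!is.null(names(y))) {
    miss <- setdiff(w$entities, names(y))
    if (length(miss) > 0) {
      stop("y is missing values for entities: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    }
    y <- y[w$entities]
  } else if (length(y) != length(w$entities)) {
    stop("length(y) must match the number of entities in the weights", call. = FALSE)
  }
  rs <- rowSums(w$W)
  islands <- which(rs == 0)
  keep <- setdiff(seq_along(y), islands)
  if (any(is.na(y[keep]))) {
    stop("y has missing values among weighted entities", call. = FALSE)
  }
  list(y = as.numeric(y[keep]),
       W = w$W[keep, keep, drop = FALSE],
       n_islands = length(islands))
}

#' Global Moran's I
#'
#' Computes the global spatial autocorrelation statistic
#' \deqn{I = \frac{\sum_i \sum_j W_{ij}(Y_i - \bar Y)(Y_j - \bar Y)}
#'                {S^2 \sum_i \sum_j W_{ij}}}
#' with \eqn{S^2 = \sum_i (Y_i - \bar Y)^2 / n} by default (population
#' variance), under which the statistic is the standard global Moran's I
#' with range \[-1, 1\] on binary contiguity structures. Positive I means
#' similar values cluster in space; the expected value under the random
#' labelling null is \eqn{-1/(n-1)}. Islands (zero weight rows) are
#' excluded from the computation and counted.
#'
#' @param y Numeric vector of attribute values, optionally named by entity.
#' @param w A `spatial_weights`.
#' @param variance `"population"` (divisor n, default) or `"sample"`
#'   (divisor n-1).
#' @return A `moran_result` list with elements `I`, `n`, `n_islands`,
#'   `expected_I`.
#' @export
#' @examples
#' w <- weights_grid(4, 4, "rook")
#' idx <- expand.grid(c = 1:4, r = 1:4)
#' y <- (-1)^(idx$r + idx$c)  # checkerboard
#' moran_i(y, w)$I            # exactly -1
moran_i <- function(y, w, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  al <- align_y_weights(y, w)
  y <- al$y; W <- al$W
  n <- length(y)
  if (n < 3) stop("Moran's I needs at least 3 weighted entities", call. = FALSE)
  s0 <- sum(W)
  if (s0 == 0) stop("all spatial weights are zero", call. = FALSE)
  z <- y - mean(y)
  ss <- sum(z^2)
  if (ss == 0) stop("constant attribute: Moran's I undefined", call. = FALSE)
  s2 <- ss / if (variance == "population") n else (n - 1)
  I <- sum(z * (W %*% z)) / (s2 * s0)
  structure(list(I = I, n = n, n_islands = al$n_islands,
                 expected_I = -1 / (n - 1), variance = variance),
            class = "moran_result")
}

#' Permutation test for global Moran's I
#'
#' Randomizes the attribute values over the spatial units `n_perm` times
#' and compares the observed statistic with the permutation distribution.
#' The p-value uses the add-one rule
#' \eqn{p = (1 + \#\{I^* \ \mathrm{at\ least\ as\ extreme}\})/(n_{perm} + 1)},
#' so with 999 permutations the denominator is 1000. The default
#' alternative is `"greater"` (spatial clustering).
#'
#' @inheritParams moran_i
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for reproducible permutations.
#' @param tail `"greater"`, `"less"`, or `"two-sided"` (extremity measured
#'   as distance from the permutation-null mean).
#' @return A `moran_test` object: the `moran_result` fields plus `p_perm`,
#'   `n_perm`, `seed`, `tail`, and the permuted statistics `perm_I`.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_entities = 20, rho = 0.9, seed = 7))
#' w <- weights_knn(sim$coords, k = 4)
#' y <- stats::setNames(sim$truth$entity_latent, sim$coords$entity)
#' moran_test(y, w, n_perm = 199, seed = 1)
moran_test <- function(y, w, n_perm = 999, seed = NULL,
                       tail = c("greater", "less", "two-sided"),
                       variance = c("population", "sample")) {
  tail <- match.arg(tail)
  variance <- match.arg(variance)
  if (n_perm < 99) {
    warning("n_perm < 99 gives unstable permutation p-values", call. = FALSE)
  }
  obs <- moran_i(y, w, variance = variance)
  al <- align_y_weights(y, w)
  yy <- al$y; W <- al$W
  n <- length(yy)
  s0 <- sum(W)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  Z <- vapply(seq_len(n_perm), function(i) sample(yy), numeric(n))
  Z <- sweep(Z, 2, colMeans(Z))
  denom <- colSums(Z^2) / if (variance == "population") n else (n - 1)
  perm_I <- colSums(Z * (W %*% Z)) / (denom * s0)
  extreme <- switch(tail,
    greater = sum(perm_I >= obs$I),
    less = sum(perm_I <= obs$I),
    `two-sided` = {
      ctr <- mean(perm_I)
      sum(abs(perm_I - ctr) >= abs(obs$I - ctr))
    })
  p <- (1 + extreme) / (n_perm + 1)
  structure(c(unclass(obs),
              list(p_perm = p, n_perm = n_perm, seed = seed, tail = tail,
                   perm_I = perm_I)),
            class = c("moran_test", "moran_result"))
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (n = %d, E[I] = %.4f, islands = %d)\n",
              x$I, x$n, x$expected_I, x$n_islands))
  if (!is.null(x$p_perm)) {
    cat(sprintf("Permutation test: p = %.4g (%d permutations, tail = %s)\n",
                x$p_perm, x$n_perm, x$tail))
  }
  invisible(x)
}
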