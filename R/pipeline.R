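#' Read an indicator panel from CSV
#'
#' Long format has columns `entity`, `indicator`, `period`, `value`; wide
#' format has `entity`, `period` plus one column per indicator. The format
#' is auto-detected from the header.
#'
#' @param path CSV file path.
#' @param format `"auto"` (default), `"long"`, or `"wide"`.
#' @return A long panel tibble (see [as_panel()]).
#' @export
read_panel <- function(path, format = c("auto", "long", "wide")) {
  format <- match.arg(format)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (format == "auto") {
    format <- if (all(c("entity", "indicator", "period", "value") %in% names(df)))
      "long" else "wide"
  }
  if (format == "long") {
    miss <- setdiff(c("entity", "indicator", "period", "value"), names(df))
    if (length(miss) > 0) {
      stop("long panel CSV is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  } else {
    miss <- setdiff(c("entity", "period"), names(df))
    if (length(miss) > 0) {
      stop("wide panel CSV is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    df <- tidyr::pivot_longer(df, cols = !c("entity", "period"),
                              names_to = "indicator", values_to = "value")
  }
  as_panel(df)
}

#' Write an indicator panel to CSV
#'
#' @param panel A long panel tibble.
#' @param path Output path.
#' @param format `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("long", "wide")) {
  format <- match.arg(format)
  panel <- as_panel(panel)
  if (format == "wide") {
    panel <- tidyr::pivot_wider(panel, names_from = "indicator",
                                values_from = "value")
  }
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

# manifest of a pipeline run: parameters + content hashes
build_manifest <- function(panel, hierarchy, params) {
  list(
    tool = "nescoast",
    version = as.character(utils::packageVersion("nescoast")),
    panel_hash = rlang::hash(panel),
    hierarchy_hash = rlang::hash(hierarchy),
    params = params
  )
}

#' Run the full assessment pipeline
#'
#' Executes every stage in order: min-max normalization, hierarchical
#' aggregation with coupling-coordination, Jenks classification of the
#' entity-mean composite score, global Moran's I with permutation
#' inference per period, and the geographical detector (factor +
#' interaction) of theme and natural sub-theme drivers against the
#' composite score. A run manifest (input hashes and every parameter) is
#' returned and, when `out_dir` is given, all outputs are written
#' atomically (staging directory, then rename).
#'
#' @param panel A long indicator panel.
#' @param hierarchy A `nes_hierarchy`.
#' @param spatial Spatial structure: a `spatial_weights`, a coordinates
#'   data frame (`entity`, `x`, `y`) for the default k-nearest scheme, or
#'   an edge-list data frame (`src`, `dst`).
#' @param scope Normalization scope (see [normalize_panel()]).
#' @param weight_mode Aggregation weighting (see [aggregate_scores()]).
#' @param k_neighbors Neighbours for the k-nearest weights when `spatial`
#'   is coordinates. Default 4.
#' @param n_perm Permutations for the Moran test. Default 999.
#' @param k_classes Jenks classes for the composite map. Default 4.
#' @param detector_k Strata per driver in the geodetector. Default 5.
#' @param seed Seed governing permutation inference.
#' @param out_dir Optional output directory; receives `scores.csv`,
#'   `moran.csv`, `geodetector_factors.csv`, `geodetector_interactions.csv`,
#'   `classes.csv`, `manifest.json`.
#' @param quiet Suppress stage messages.
#' @return A `csd_pipeline` list: `scores`, `moran` (tibble, one row per
#'   period), `detector` (a `geodetector_result`), `classes`, `manifest`.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_entities = 15, seed = 9))
#' res <- run_csd_pipeline(sim$panel, sim$hierarchy, sim$coords,
#'                         n_perm = 199, seed = 1, quiet = TRUE)
#' res$moran
run_csd_pipeline <- function(panel, hierarchy, spatial,
                             scope = "pooled",
                             weight_mode = "config",
                             k_neighbors = 4, n_perm = 999,
                             k_classes = 4, detector_k = 5,
                             seed = 1L, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  panel <- as_panel(panel, hierarchy)
  say("normalize: %d entities x %d indicators x %d periods",
      length(unique(panel$entity)), length(unique(panel$indicator)),
      length(unique(panel$period)))
  norm <- normalize_panel(panel, hierarchy, scope = scope)

  say("aggregate: weight mode '%s'", weight_mode)
  scores <- aggregate_scores(norm, hierarchy, weight_mode = weight_mode)

  w <- if (inherits(spatial, "spatial_weights")) {
    spatial
  } else if (all(c("entity", "x", "y") %in% names(spatial))) {
    weights_knn(spatial, k = k_neighbors)
  } else if (all(c("src", "dst") %in% names(spatial))) {
    weights_from_edges(spatial, entities = sort(unique(panel$entity)),
                       style = "row-standardized")
  } else {
    stop("spatial must be spatial_weights, coordinates, or an edge list",
         call. = FALSE)
  }

  say("moran: scheme %s, %d permutations", w$scheme, n_perm)
  periods <- sort(unique(scores$period))
  moran <- dplyr::bind_rows(lapply(seq_along(periods), function(i) {
    p <- periods[i]
    sp <- scores[scores$period == p & !is.na(scores$CSDI), ]
    y <- stats::setNames(sp$CSDI, sp$entity)
    sub_w <- subset_weights(w, names(y))
    mt <- moran_test(y, sub_w, n_perm = n_perm, seed = seed + i)
    tibble::tibble(period = p, I = mt$I, expected_I = mt$expected_I,
                   p_perm = mt$p_perm, n = mt$n, n_islands = mt$n_islands)
  }))

  say("geodetector: themes + natural sub-themes vs CSDI")
  natural_subs <- hierarchy$subthemes$subtheme[hierarchy$subthemes$theme == "natural"]
  drivers <- intersect(c(hierarchy$themes$theme, natural_subs), names(scores))
  drivers <- setdiff(drivers, "CSDI")
  det <- geodetector(scores, y = "CSDI", x = drivers, k = detector_k, seed = seed)

  say("classify: jenks k = %d on entity-mean CSDI", k_classes)
  mean_scores <- scores |>
    dplyr::group_by(.data$entity) |>
    dplyr::summarise(CSDI = mean(.data$CSDI, na.rm = TRUE), .groups = "drop")
  classes <- classify_scores(mean_scores, by = "CSDI", k = k_classes)

  manifest <- build_manifest(panel, hierarchy, params = list(
    scope = scope, weight_mode = weight_mode, k_neighbors = k_neighbors,
    weights_scheme = w$scheme, weights_style = w$style,
    n_perm = n_perm, k_classes = k_classes, detector_k = detector_k,
    seed = seed
  ))

  out <- structure(list(scores = scores, moran = moran, detector = det,
                        classes = classes, manifest = manifest),
                   class = "csd_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  say("done in %.2fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out
}

# restrict a weight matrix to a subset of entities (order given)
subset_weights <- function(w, entities) {
  miss <- setdiff(entities, w$entities)
  if (length(miss) > 0) {
    stop("weights lack entities: ", paste(utils::head(miss, 5), collapse = ", "),
         call. = FALSE)
  }
  spatial_weights(w$W[entities, entities, drop = FALSE], entities,
                  style = w$style, scheme = w$scheme)
}

# atomic write: everything into a staging dir, then rename into place
write_pipeline_outputs <- function(res, out_dir) {
  staging <- paste0(out_dir, ".staging")
  if (dir.exists(staging)) unlink(staging, recursive = TRUE)
  dir.create(staging, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(staging, recursive = TRUE), add = TRUE)
  readr::write_csv(tibble::as_tibble(res$scores), file.path(staging, "scores.csv"),
                   progress = FALSE)
  readr::write_csv(res$moran, file.path(staging, "moran.csv"), progress = FALSE)
  readr::write_csv(res$detector$factors,
                   file.path(staging, "geodetector_factors.csv"), progress = FALSE)
  readr::write_csv(res$detector$interactions,
                   file.path(staging, "geodetector_interactions.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(res$classes), file.path(staging, "classes.csv"),
                   progress = FALSE)
  jsonlite::write_json(res$manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  file.rename(staging, out_dir)
  ok <- TRUE
  invisible(out_dir)
}

#' @export
print.csd_pipeline <- function(x, ...) {
  cat("Coastal sustainability assessment pipeline\n")
  cat(sprintf("  scores: %d entity-periods\n", nrow(x$scores)))
  cat("  Moran's I per period:\n")
  print(x$moran)
  cat(sprintf("  top factor q: %s\n",
              paste(sprintf("%s=%.3f", x$detector$factors$driver,
                            x$detector$factors$q), collapse = ", ")))
  invisible(x)
}
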