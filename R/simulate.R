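#' Configuration for the synthetic indicator-panel generator
#'
#' Bundles and validates the generator's parameters. The defaults emulate
#' the study conditions of a 41-country, three-period coastal assessment:
#' the default 3/7/29 hierarchy, five regional clusters (the five world
#' regions the assessment spans), moderate spatial clustering, and
#' socioeconomically dominated composite variation.
#'
#' @param n_entities Number of entities (countries). Default 41.
#' @param n_periods Number of assessment periods. Default 3 (labelled
#'   2010, 2015, 2020 when 3).
#' @param hierarchy A `nes_hierarchy`; default [default_nes_hierarchy()].
#' @param n_regions Number of spatial clusters. Default 5.
#' @param rho Regional-clustering strength in \[0, 1): the latent entity
#'   score is `rho * regional mean + (1 - rho) * idiosyncratic`. Default
#'   0.6.
#' @param theme_effects Named or ordered triple of per-theme variance
#'   shares driving the latent score (natural, economic, social); must sum
#'   to at most 1. Default `c(0.20, 0.45, 0.35)`.
#' @param noise_sd Indicator-level noise scale (also scales the theme
#'   factors' idiosyncratic part, so `noise_sd = 0` makes every indicator
#'   a deterministic monotone function of the latent score). Default 0.3.
#' @param direction_mix Fraction of indicators generated with negative
#'   direction semantics (raw values anti-correlated with sustainability).
#'   Default 0.3.
#' @param missing_rate Completely-at-random missingness rate in \[0, 0.2\].
#'   Default 0.02.
#' @param seed Integer RNG seed; every random draw in the generator flows
#'   from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_entities = 41, n_periods = 3,
                       hierarchy = default_nes_hierarchy(),
                       n_regions = 5, rho = 0.6,
                       theme_effects = c(natural = 0.20, economic = 0.45, social = 0.35),
                       noise_sd = 0.3, direction_mix = 0.3,
                       missing_rate = 0.02, seed = 1L) {
  stopifnot(inherits(hierarchy, "nes_hierarchy"))
  if (n_entities < 2) stop("n_entities must be at least 2", call. = FALSE)
  if (n_periods < 1) stop("n_periods must be at least 1", call. = FALSE)
  if (n_regions < 1 || n_regions > n_entities) {
    stop("n_regions must be between 1 and n_entities", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (length(theme_effects) != 3 || any(theme_effects < 0) || sum(theme_effects) > 1 + 1e-9) {
    stop("theme_effects must be three nonnegative shares summing to at most 1",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (direction_mix < 0 || direction_mix > 1) {
    stop("direction_mix must lie in [0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 0.2) {
    stop("missing_rate must lie in [0, 0.2]", call. = FALSE)
  }
  structure(list(n_entities = as.integer(n_entities),
                 n_periods = as.integer(n_periods),
                 hierarchy = hierarchy, n_regions = as.integer(n_regions),
                 rho = rho,
                 theme_effects = stats::setNames(as.numeric(theme_effects),
                                                 hierarchy$themes$theme),
                 noise_sd = noise_sd, direction_mix = direction_mix,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic indicator panel with known structure
#'
#' Builds a country-style panel whose statistical structure matches what
#' the downstream analysis assumes, with full ground truth attached:
#'
#' 1. Entities are placed in `n_regions` spatial point clusters on a
#'    plane (cluster centres on a circle, Gaussian jitter).
#' 2. Each region draws a latent effect; the per-entity latent
#'    sustainability score mixes it with an idiosyncratic draw as
#'    `rho * regional + (1 - rho) * idiosyncratic`, plus a small period
#'    drift.
#' 3. Each theme factor loads on the latent score with loading
#'    `sqrt(theme_effects[theme])`, plus `noise_sd`-scaled theme noise.
#' 4. Every indicator is its theme factor plus `noise_sd`-scaled noise;
#'    a `direction_mix` fraction of indicators is flipped in sign and
#'    marked `direction = "negative"` in the returned hierarchy.
#' 5. Cells are deleted completely at random at `missing_rate`.
#'
#' All randomness derives from `config$seed`; identical configurations
#' reproduce the panel bit for bit.
#'
#' @param config A [sim_config()].
#' @return A `csd_sim` list: `panel` (long tibble), `coords`
#'   (entity, x, y, region), `hierarchy` (with simulated directions),
#'   `truth` (regional effects, entity latent scores, per-period latent
#'   matrix, theme factors, true driver shares), and `config`.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_entities = 10, seed = 42))
#' dplyr::glimpse(sim$panel)
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  n <- config$n_entities
  h <- config$hierarchy
  periods <- if (config$n_periods == 3) c("2010", "2015", "2020")
             else as.character(seq(2010, by = 5, length.out = config$n_periods))
  entities <- sprintf("C%02d", seq_len(n))

  # spatial clusters: centres on a circle of radius 10, sd-1 jitter
  region <- rep_len(seq_len(config$n_regions), n)
  theta <- 2 * pi * (seq_len(config$n_regions) - 1) / config$n_regions
  centres <- cbind(10 * cos(theta), 10 * sin(theta))
  coords <- tibble::tibble(
    entity = entities,
    x = centres[region, 1] + stats::rnorm(n),
    y = centres[region, 2] + stats::rnorm(n),
    region = sprintf("R%d", region)
  )

  regional_effect <- stats::rnorm(config$n_regions)
  idio <- stats::rnorm(n)
  entity_latent <- config$rho * regional_effect[region] + (1 - config$rho) * idio
  drift <- stats::rnorm(config$n_periods, sd = 0.1)
  latent <- outer(entity_latent, rep(1, config$n_periods)) +
    outer(rep(1, n), drift)
  dimnames(latent) <- list(entities, periods)

  themes <- h$themes$theme
  shares <- config$theme_effects
  theme_factors <- array(0, dim = c(n, config$n_periods, 3),
                         dimnames = list(entities, periods, themes))
  for (t in seq_along(themes)) {
    load <- sqrt(shares[[t]])
    resid <- sqrt(max(0, 1 - shares[[t]]))
    theme_factors[, , t] <- load * latent +
      resid * config$noise_sd * matrix(stats::rnorm(n * config$n_periods),
                                       n, config$n_periods)
  }

  ind <- h$indicators
  n_neg <- round(config$direction_mix * nrow(ind))
  neg_ids <- if (n_neg > 0) sample(ind$id, n_neg) else character(0)
  ind$direction <- ifelse(ind$id %in% neg_ids, "negative", "positive")
  hierarchy_sim <- nes_hierarchy(ind, h$subthemes, h$themes)

  cells <- tidyr::expand_grid(entity = entities, indicator = ind$id,
                              period = periods)
  theme_of <- stats::setNames(ind$theme, ind$id)
  tf <- theme_factors[cbind(match(cells$entity, entities),
                            match(cells$period, periods),
                            match(theme_of[cells$indicator], themes))]
  value <- tf + config$noise_sd * stats::rnorm(nrow(cells))
  flip <- cells$indicator %in% neg_ids
  value[flip] <- -value[flip]
  if (config$missing_rate > 0) {
    value[stats::runif(length(value)) < config$missing_rate] <- NA_real_
  }
  cells$value <- value
  panel <- cells

  structure(list(
    panel = panel,
    coords = coords,
    hierarchy = hierarchy_sim,
    truth = list(regional_effect = stats::setNames(regional_effect,
                                                   sprintf("R%d", seq_len(config$n_regions))),
                 entity_latent = stats::setNames(entity_latent, entities),
                 latent = latent,
                 theme_factors = theme_factors,
                 driver_shares = shares),
    config = config
  ), class = "csd_sim")
}

#' Compare computed scores with the generator's ground truth
#'
#' Reports how well the pipeline recovers the simulated structure: the
#' Spearman rank correlation between the latent entity-period scores and
#' the computed composite (CSDI), and, when driver q values are supplied,
#' the rank agreement between the true theme variance shares and the
#' estimated q values.
#'
#' @param scores A `csd_scores` table computed from the simulated panel.
#' @param sim The `csd_sim` object the panel came from.
#' @param q Optional named vector of estimated q values per theme (names
#'   matching the hierarchy's themes).
#' @return A tibble with columns `metric` and `value`: rank correlation of
#'   CSDI vs latent truth, and (if `q` given) the Spearman correlation
#'   between true shares and estimated q.
#' @export
truth_recovery <- function(scores, sim, q = NULL) {
  stopifnot(inherits(sim, "csd_sim"))
  truth_long <- tibble::as_tibble(as.data.frame.table(sim$truth$latent,
                                                      responseName = "latent"))
  names(truth_long)[1:2] <- c("entity", "period")
  truth_long$entity <- as.character(truth_long$entity)
  truth_long$period <- as.character(truth_long$period)
  merged <- dplyr::inner_join(tibble::as_tibble(scores)[c("entity", "period", "CSDI")],
                              truth_long, by = c("entity", "period"))
  if (nrow(merged) == 0) stop("scores and simulation share no entity-periods", call. = FALSE)
  out <- tibble::tibble(
    metric = "spearman_csdi_latent",
    value = stats::cor(merged$CSDI, merged$latent, method = "spearman",
                       use = "complete.obs")
  )
  if (!is.null(q)) {
    shares <- sim$truth$driver_shares[names(q)]
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = "spearman_q_shares",
      value = stats::cor(as.numeric(q), as.numeric(shares), method = "spearman")
    ))
  }
  out
}
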