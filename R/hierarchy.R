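#' Evaluation hierarchies
#'
#' A `nes_hierarchy` describes the three-tier evaluation tree used for
#' composite coastal-sustainability scoring: themes (natural, economic,
#' social) split into sub-themes, which hold the measured indicators.
#' Each indicator carries a direction (`"positive"` if larger raw values
#' mean more sustainable, `"negative"` otherwise) and a nonnegative weight;
#' within every sibling group (indicators under a sub-theme, sub-themes
#' under a theme, themes under the root) weights sum to one.
#'
#' @param indicators A data frame with columns `id`, `name`, `subtheme`,
#'   `theme`, `direction`, `weight`.
#' @param subthemes A data frame with columns `subtheme`, `theme`, `weight`.
#' @param themes A data frame with columns `theme`, `weight`.
#' @param strict Require exactly three themes (the natural-economic-social
#'   framing)? Default `TRUE`.
#' @return A validated object of class `nes_hierarchy`.
#' @export
nes_hierarchy <- function(indicators, subthemes, themes, strict = TRUE) {
  h <- structure(
    list(
      indicators = tibble::as_tibble(indicators),
      subthemes  = tibble::as_tibble(subthemes),
      themes     = tibble::as_tibble(themes)
    ),
    class = "nes_hierarchy"
  )
  validate_hierarchy(h, strict = strict)
}

#' @rdname nes_hierarchy
#' @param x A `nes_hierarchy`.
#' @export
validate_hierarchy <- function(x, strict = TRUE) {
  stopifnot(inherits(x, "nes_hierarchy"))
  ind <- x$indicators
  sub <- x$subthemes
  thm <- x$themes

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(sprintf("hierarchy %s table is missing column(s): %s",
                   what, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(ind, c("id", "subtheme", "theme", "direction", "weight"), "indicator")
  need(sub, c("subtheme", "theme", "weight"), "sub-theme")
  need(thm, c("theme", "weight"), "theme")

  if (strict && nrow(thm) != 3L) {
    stop(sprintf("strict mode requires exactly 3 themes, found %d", nrow(thm)),
         call. = FALSE)
  }
  if (anyDuplicated(ind$id)) {
    stop("duplicate indicator id(s): ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_dir <- setdiff(unique(ind$direction), c("positive", "negative"))
  if (length(bad_dir) > 0) {
    stop("indicator direction must be 'positive' or 'negative', found: ",
         paste(bad_dir, collapse = ", "), call. = FALSE)
  }
  for (df in list(ind, sub, thm)) {
    if (any(!is.finite(df$weight)) || any(df$weight < 0)) {
      stop("hierarchy weights must be finite and nonnegative", call. = FALSE)
    }
  }
  orphan_ind <- setdiff(ind$subtheme, sub$subtheme)
  if (length(orphan_ind) > 0) {
    stop("indicator(s) reference unknown sub-theme(s): ",
         paste(orphan_ind, collapse = ", "), call. = FALSE)
  }
  orphan_sub <- setdiff(sub$theme, thm$theme)
  if (length(orphan_sub) > 0) {
    stop("sub-theme(s) reference unknown theme(s): ",
         paste(orphan_sub, collapse = ", "), call. = FALSE)
  }
  mismatch <- dplyr::anti_join(
    dplyr::distinct(ind, .data$subtheme, .data$theme),
    sub, by = c("subtheme", "theme")
  )
  if (nrow(mismatch) > 0) {
    stop("indicator theme does not match its sub-theme's theme for: ",
         paste(mismatch$subtheme, collapse = ", "), call. = FALSE)
  }

  check_sum1 <- function(groups, label) {
    bad <- names(groups)[vapply(groups, function(w) abs(sum(w) - 1) > 1e-9, logical(1))]
    if (length(bad) > 0) {
      stop(sprintf("%s weights do not sum to 1 in group(s): %s",
                   label, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check_sum1(split(ind$weight, ind$subtheme), "indicator")
  check_sum1(split(sub$weight, sub$theme), "sub-theme")
  check_sum1(list(root = thm$weight), "theme")
  x
}

# Fill absent weights with equal shares within each sibling group;
# renormalize explicit non-unit sums with a warning. Order-preserving.
fill_weights_ordered <- function(w, group, label) {
  out <- w
  for (g in unique(group)) {
    idx <- which(group == g)
    wi <- w[idx]
    if (all(is.na(wi))) {
      wi <- rep(1 / length(wi), length(wi))
    } else {
      wi[is.na(wi)] <- 0
      if (any(wi < 0)) {
        stop(sprintf("negative %s weight in group '%s'", label, g), call. = FALSE)
      }
      s <- sum(wi)
      if (s <= 0) {
        stop(sprintf("%s weights in group '%s' sum to zero", label, g), call. = FALSE)
      }
      if (abs(s - 1) > 1e-9) {
        warning(sprintf("%s weights in group '%s' sum to %.6g; renormalizing to 1",
                        label, g, s), call. = FALSE)
        wi <- wi / s
      }
    }
    out[idx] <- wi
  }
  out
}

#' Load an evaluation hierarchy from a YAML or JSON document
#'
#' The configuration declares themes, their sub-themes, and the indicators
#' under each sub-theme. Weights are optional at every level: absent weights
#' are filled with equal shares within the sibling group, and explicit
#' weights that do not sum to one are renormalized with a warning.
#'
#' The schema is
#' ```yaml
#' themes:
#'   - key: natural
#'     weight: 0.333        # optional
#'     subthemes:
#'       - key: water
#'         weight: 0.2      # optional
#'         indicators:
#'           - id: nat.water.01
#'             name: Clean seawater    # optional
#'             direction: positive     # or negative
#'             weight: 0.5             # optional
#' ```
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a literal
#'   document string. The dialect is auto-detected.
#' @param strict Require exactly three themes. Default `TRUE`.
#' @return A `nes_hierarchy`.
#' @export
load_hierarchy <- function(path, strict = TRUE) {
  txt <- if (length(path) == 1 && !grepl("[\n:{]", path) && file.exists(path)) {
    paste(readLines(path, warn = FALSE), collapse = "\n")
  } else {
    paste(path, collapse = "\n")
  }
  doc <- tryCatch({
    if (grepl("^\\s*\\{", txt)) {
      jsonlite::fromJSON(txt, simplifyVector = FALSE)
    } else {
      yaml::yaml.load(txt)
    }
  }, error = function(e) {
    stop("failed to parse hierarchy config: ", conditionMessage(e), call. = FALSE)
  })
  if (is.null(doc$themes)) {
    stop("hierarchy config must declare a top-level 'themes' list", call. = FALSE)
  }

  opt <- function(x, default = NA) if (is.null(x)) default else x
  thm_rows <- list(); sub_rows <- list(); ind_rows <- list()
  for (th in doc$themes) {
    if (is.null(th$key)) stop("every theme needs a 'key'", call. = FALSE)
    thm_rows[[length(thm_rows) + 1L]] <-
      tibble::tibble(theme = th$key, weight = as.numeric(opt(th$weight)))
    for (st in th$subthemes) {
      if (is.null(st$key)) stop("every sub-theme needs a 'key'", call. = FALSE)
      sub_rows[[length(sub_rows) + 1L]] <-
        tibble::tibble(subtheme = st$key, theme = th$key,
                       weight = as.numeric(opt(st$weight)))
      for (ind in st$indicators) {
        if (is.null(ind$id)) stop("every indicator needs an 'id'", call. = FALSE)
        ind_rows[[length(ind_rows) + 1L]] <- tibble::tibble(
          id = ind$id,
          name = as.character(opt(ind$name, ind$id)),
          subtheme = st$key,
          theme = th$key,
          direction = as.character(opt(ind$direction, "positive")),
          weight = as.numeric(opt(ind$weight))
        )
      }
    }
  }
  thm <- dplyr::bind_rows(thm_rows)
  sub <- dplyr::bind_rows(sub_rows)
  ind <- dplyr::bind_rows(ind_rows)
  if (nrow(ind) == 0) stop("hierarchy config declares no indicators", call. = FALSE)
  if (any(!is.na(ind$weight) & ind$weight < 0) ||
      any(!is.na(sub$weight) & sub$weight < 0) ||
      any(!is.na(thm$weight) & thm$weight < 0)) {
    stop("hierarchy weights must be nonnegative", call. = FALSE)
  }

  ind$weight <- fill_weights_ordered(ind$weight, ind$subtheme, "indicator")
  sub$weight <- fill_weights_ordered(sub$weight, sub$theme, "sub-theme")
  thm$weight <- fill_weights_ordered(thm$weight, rep("root", nrow(thm)), "theme")
  nes_hierarchy(ind, sub, thm, strict = strict)
}

#' Serialize a hierarchy back to YAML or JSON
#'
#' @param hierarchy A `nes_hierarchy`.
#' @param path Output file; dialect chosen from the extension (`.json` for
#'   JSON, anything else YAML). If `NULL`, the document text is returned.
#' @param format `"auto"`, `"yaml"` or `"json"`.
#' @return The path (invisibly), or the document string when `path` is `NULL`.
#' @export
write_hierarchy <- function(hierarchy, path = NULL, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(hierarchy, "nes_hierarchy"))
  if (format == "auto") {
    format <- if (!is.null(path) && grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  doc <- list(themes = lapply(seq_len(nrow(hierarchy$themes)), function(i) {
    th <- hierarchy$themes[i, ]
    subs <- hierarchy$subthemes[hierarchy$subthemes$theme == th$theme, ]
    list(
      key = th$theme, weight = th$weight,
      subthemes = lapply(seq_len(nrow(subs)), function(j) {
        st <- subs[j, ]
        inds <- hierarchy$indicators[hierarchy$indicators$subtheme == st$subtheme, ]
        list(
          key = st$subtheme, weight = st$weight,
          indicators = lapply(seq_len(nrow(inds)), function(k) {
            r <- inds[k, ]
            list(id = r$id, name = r$name, direction = r$direction, weight = r$weight)
          })
        )
      })
    )
  }))
  txt <- if (format == "json") {
    jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::as.yaml(doc, precision = 15)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' The bundled default natural-economic-social hierarchy
#'
#' Returns the canonical 3-theme / 7-sub-theme / 29-indicator structure:
#' the natural theme holds five sub-themes (atmosphere, coast, land, water,
#' biodiversity), while the economic and social themes each form a single
#' sub-theme. Indicator ids are structural placeholders (`nat.water.01`,
#' `eco.economy.02`, ...); real deployments replace them via
#' [load_hierarchy()] with their own indicator definitions. All sibling
#' weights are equal.
#'
#' @return A `nes_hierarchy`.
#' @export
#' @examples
#' h <- default_nes_hierarchy()
#' nrow(h$indicators)  # 29
default_nes_hierarchy <- function() {
  layout <- list(
    natural  = c(atmosphere = 4, coast = 4, land = 4, water = 4, biodiversity = 4),
    economic = c(economy = 5),
    social   = c(society = 4)
  )
  prefix <- c(natural = "nat", economic = "eco", social = "soc")
  ind <- dplyr::bind_rows(lapply(names(layout), function(th) {
    dplyr::bind_rows(lapply(names(layout[[th]]), function(st) {
      n <- layout[[th]][[st]]
      tibble::tibble(
        id = sprintf("%s.%s.%02d", prefix[[th]], st, seq_len(n)),
        name = sprintf("%s indicator %d", st, seq_len(n)),
        subtheme = st, theme = th,
        direction = "positive",
        weight = 1 / n
      )
    }))
  }))
  sub <- dplyr::bind_rows(lapply(names(layout), function(th) {
    tibble::tibble(subtheme = names(layout[[th]]), theme = th,
                   weight = 1 / length(layout[[th]]))
  }))
  thm <- tibble::tibble(theme = names(layout), weight = 1 / 3)
  nes_hierarchy(ind, sub, thm)
}

#' @export
print.nes_hierarchy <- function(x, ...) {
  cat(sprintf("<nes_hierarchy> %d themes / %d sub-themes / %d indicators\n",
              nrow(x$themes), nrow(x$subthemes), nrow(x$indicators)))
  for (i in seq_len(nrow(x$themes))) {
    th <- x$themes$theme[i]
    subs <- x$subthemes$subtheme[x$subthemes$theme == th]
    cnt <- vapply(subs, function(s) sum(x$indicators$subtheme == s), integer(1))
    cat(sprintf("  %s (w=%.3g): %s\n", th, x$themes$weight[i],
                paste(sprintf("%s[%d]", subs, cnt), collapse = ", ")))
  }
  invisible(x)
}

#' @method as_tibble nes_hierarchy
#' @export
as_tibble.nes_hierarchy <- function(x, ...) x$indicators
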