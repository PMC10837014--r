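#' Enumerate simulated environments over sites, years and planting dates
#'
#' Expands each (site, year, planting-window) row into one simulated
#' environment per daily planting date, endpoints inclusive, in
#' deterministic (site, year, date) order. A "site" may be a site-season
#' set: a location planted in two seasons contributes two sites (for
#' example a summer and a winter set at the same coordinates).
#'
#' @param site_windows Tibble with columns `site`, `year`, `window_start`,
#'   `window_end` (Dates or coercible; the window may cross a year
#'   boundary, e.g. 1 December to 20 January of the following year).
#' @return Tibble with `site`, `year`, `planting_date`, one row per
#'   simulated environment.
#' @export
#' @examples
#' build_env_grid(tibble::tibble(
#'   site = "A", year = 2020,
#'   window_start = "2020-05-01", window_end = "2020-05-03"
#' ))
build_env_grid <- function(site_windows) {
  need <- c("site", "year", "window_start", "window_end")
  missing_cols <- setdiff(need, names(site_windows))
  if (length(missing_cols) > 0) {
    abort(paste0("`site_windows` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ws <- as.Date(site_windows$window_start)
  we <- as.Date(site_windows$window_end)
  if (any(we < ws)) abort("A planting window ends before it starts.")
  out <- purrr::pmap(
    list(site_windows$site, site_windows$year, as.character(ws), as.character(we)),
    function(site, year, s, e) {
      tibble(site = as.character(site), year = as.integer(year),
             planting_date = seq(as.Date(s), as.Date(e), by = "day"))
    }
  ) %>% purrr::list_rbind() %>%
    dplyr::arrange(.data$site, .data$year, .data$planting_date)
  dup <- duplicated(out[, c("site", "year", "planting_date")])
  if (any(dup)) abort("Duplicate (site, year, planting_date) cells in the grid.")
  out
}

#' Sorghum-style simulated trial design
#'
#' Three summer site-sets (Iowa, Kansas, Puerto Rico summer) planted
#' 21 May to 10 July and a Puerto Rico winter set planted 1 December to
#' 20 January, each over seven years: 4 sets x 7 years x 51 daily dates =
#' 1428 environments.
#'
#' @param years Integer vector of years (default 2010:2016).
#' @return A `site_windows` tibble for [build_env_grid()].
#' @export
sorghum_design <- function(years = 2010:2016) {
  summer <- tidyr::expand_grid(site = c("IA", "KS", "PRS"), year = years) %>%
    dplyr::mutate(window_start = as.Date(paste0(.data$year, "-05-21")),
                  window_end = as.Date(paste0(.data$year, "-07-10")))
  winter <- tibble(site = "PRW", year = years) %>%
    dplyr::mutate(window_start = as.Date(paste0(.data$year, "-12-01")),
                  window_end = as.Date(paste0(.data$year + 1, "-01-20")))
  dplyr::bind_rows(summer, winter)
}

#' Rice-style simulated trial design
#'
#' Six sites planted daily 30 March to 30 June over three years:
#' 6 x 3 x 93 = 1674 environments.
#'
#' @param years Integer vector of years (default 2007:2009).
#' @param sites Site ids (default the six rice sites).
#' @return A `site_windows` tibble for [build_env_grid()].
#' @export
rice_design <- function(years = 2007:2009,
                        sites = c("TS", "FU", "ISI", "ISA", "HA", "TH")) {
  tidyr::expand_grid(site = sites, year = years) %>%
    dplyr::mutate(window_start = as.Date(paste0(.data$year, "-03-30")),
                  window_end = as.Date(paste0(.data$year, "-06-30")))
}

#' Sequential variance partitioning of environmental-index values
#'
#' Decomposes the total (centered) sum of squares of index values into
#' contributions of categorical factors entered sequentially in the given
#' order (Type-I ANOVA), expressed as percentages; the remainder is the
#' residual. With a balanced factorial grid the sequential percentages are
#' order-invariant. Percentages are invariant to affine transforms of the
#' values.
#'
#' @param values Numeric vector of index values, one per environment.
#' @param factors Data frame of factor labels (one column per factor, one
#'   row per environment).
#' @param order Factor entry order (default: column order of `factors`).
#' @return Tibble with `term` (factors then `"residual"`) and `percent`,
#'   summing to 100 (all zero when the total SS is 0).
#' @export
#' @examples
#' partition_variance(c(0, 0, 1, 1),
#'                    data.frame(A = c("a", "a", "b", "b"),
#'                               B = c("x", "y", "x", "y")))
partition_variance <- function(values, factors, order = names(factors)) {
  if (length(values) < 2) abort("Need >= 2 environments.")
  factors <- as.data.frame(factors)
  if (nrow(factors) != length(values)) {
    abort("`factors` must have one row per value.")
  }
  bad <- setdiff(order, names(factors))
  if (length(bad) > 0) abort(paste0("Unknown factor(s): ", paste(bad, collapse = ", ")))
  if (anyNA(factors[order]) || anyNA(values)) abort("Values and factor labels must be complete.")

  single <- order[vapply(factors[order], function(f) length(unique(f)) < 2, logical(1))]
  if (length(single) > 0) {
    warn(paste0("Factor(s) with a single level contribute 0%: ",
                paste(single, collapse = ", ")))
  }
  tss <- sum((values - mean(values))^2)
  if (tss == 0) {
    return(tibble(term = c(order, "residual"), percent = 0))
  }
  used <- setdiff(order, single)
  if (length(used) == 0) {
    return(tibble(term = c(order, "residual"),
                  percent = c(rep(0, length(order)), 100)))
  }
  df <- data.frame(.y = values, lapply(factors[used], factor),
                   check.names = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", used), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  terms <- rownames(an)
  pct <- 100 * ss / tss
  # anova rows follow the model's term order; last row is residuals
  out <- tibble(term = c(gsub("`", "", utils::head(terms, -1)), "residual"),
                percent = c(utils::head(pct, -1), utils::tail(pct, 1)))
  # factors with a single level are dropped by lm; restore them at 0%
  missing_terms <- setdiff(order, out$term)
  if (length(missing_terms) > 0) {
    out <- dplyr::bind_rows(
      tibble(term = missing_terms, percent = 0), out
    )
    out <- out[match(c(order, "residual"), out$term), ]
  }
  out
}

#' Per-site distributions of environmental-index values
#'
#' Summary statistics and kernel-density estimates of the simulated index
#' values by site, on a common grid so densities are directly comparable
#' across sites — the basis for judging which testing sites offer large
#' environmental variability. Site groups that overlap geographically can
#' be merged before summarizing.
#'
#' @param envs Tibble with `site` and `value` columns (for example the
#'   output of [env_index_table()] on a [build_env_grid()] table).
#' @param merge Optional named list merging sites, e.g.
#'   `list("TS+FU" = c("TS", "FU"))`.
#' @param n_grid Number of points of the common density grid.
#' @return List with `summary` (tibble: `site`, `n`, `min`, `max`, `mean`,
#'   `sd`, `degenerate`) and `density` (tibble: `site`, `x`, `density`;
#'   zero-variance sites are flagged degenerate and excluded from the
#'   density table).
#' @export
site_distributions <- function(envs, merge = NULL, n_grid = 256) {
  df <- tibble(site = as.character(envs$site), value = envs$value) %>%
    dplyr::filter(is.finite(.data$value))
  if (!is.null(merge)) {
    for (nm in names(merge)) {
      df$site[df$site %in% merge[[nm]]] <- nm
    }
  }
  summary <- df %>%
    dplyr::group_by(.data$site) %>%
    dplyr::summarise(n = dplyr::n(), min = min(.data$value), max = max(.data$value),
                     mean = mean(.data$value),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), NA_real_),
                     .groups = "drop") %>%
    dplyr::mutate(degenerate = !is.na(.data$sd) & .data$sd == 0)
  xr <- range(df$value)
  pad <- 0.05 * max(diff(xr), .Machine$double.eps)
  grid <- seq(xr[1] - pad, xr[2] + pad, length.out = n_grid)
  dens <- df %>%
    dplyr::group_by(.data$site) %>%
    dplyr::filter(dplyr::n() >= 2, stats::sd(.data$value) > 0) %>%
    dplyr::group_modify(function(d, key) {
      kd <- stats::density(d$value, from = min(grid), to = max(grid), n = n_grid)
      tibble(x = kd$x, density = kd$y)
    }) %>%
    dplyr::ungroup()
  list(summary = summary, density = dens)
}

#' Plot per-site environmental-index densities
#' @param envs Tibble with `site` and `value` (see [site_distributions()]).
#' @param merge Optional site-merging list.
#' @return A ggplot.
#' @export
plot_site_distributions <- function(envs, merge = NULL) {
  sd_ <- site_distributions(envs, merge = merge)
  ggplot2::ggplot(sd_$density,
                  ggplot2::aes(.data$x, .data$density, colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Environmental index", y = "Density",
                  title = "Environmental-index distributions by testing site") +
    ggplot2::theme_minimal()
}
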