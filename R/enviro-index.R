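#' Daily growing degree days with base and ceiling temperatures
#'
#' Daily maximum and minimum temperatures are each clamped into
#' `[base, ceiling]` before averaging (the standard capped-GDD convention),
#' then the base is subtracted:
#' \deqn{GDD = (\min(\max(T_{max}, base), ceil) +
#'             \min(\max(T_{min}, base), ceil))/2 - base.}
#' Defaults are the sorghum flowering-time convention: base 10 degC,
#' ceiling 37.8 degC. The result is bounded in `[0, ceiling - base]` and is
#' non-decreasing in both temperatures.
#'
#' @param tmax,tmin Daily maximum/minimum temperature (degC); vectorized.
#' @param base,ceiling Base and ceiling temperatures (degC).
#' @return Numeric vector of daily GDD (degC day).
#' @export
#' @examples
#' daily_gdd(40, 20) # (37.8 + 20)/2 - 10 = 18.9
daily_gdd <- function(tmax, tmin, base = 10, ceiling = 37.8) {
  if (any(tmax < tmin, na.rm = TRUE)) abort("`tmax` must be >= `tmin`.")
  cl <- function(t) pmin(pmax(t, base), ceiling)
  (cl(tmax) + cl(tmin)) / 2 - base
}

#' Astronomical day length from latitude and date
#'
#' Sunrise-to-sunset duration computed from solar declination (fractional
#' year Fourier series) with sunrise/sunset defined at solar zenith
#' 90.833 degrees (accounting for refraction and the solar disc). Beyond
#' the polar circles the value is clamped into `[0, 24]`.
#'
#' @param latitude Decimal degrees, in `[-90, 90]`.
#' @param date `Date` vector (or coercible).
#' @return Day length in hours, in `[0, 24]`.
#' @export
#' @examples
#' day_length(42, as.Date("2014-06-21"))
day_length <- function(latitude, date) {
  if (any(abs(latitude) > 90)) abort("Latitude must lie in [-90, 90].")
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  gamma <- 2 * pi / 365 * (doy - 1 + 0.5)
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  lat <- latitude * pi / 180
  zen <- 90.833 * pi / 180
  cos_ha <- (cos(zen) - sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  cos_ha <- pmin(pmax(cos_ha, -1), 1)
  2 * acos(cos_ha) * 180 / pi / 15
}

#' Environmental index over a growth window after planting
#'
#' Accumulates the daily thermal value over a fixed window of days after
#' planting: family `"GDD"` uses [daily_gdd()]; family `"PTT"`
#' (photothermal time) multiplies each day's GDD by its day length. The
#' planting day is day 0, so a window of 18 to 43 days after planting spans
#' the 26 calendar days from `planting_date + 18` through
#' `planting_date + 43`. Daily values are combined by their arithmetic mean
#' by default (keeping windows of different lengths comparable in a search);
#' set `aggregate = "sum"` for accumulated totals.
#'
#' @param weather Daily weather tibble for one site: `date`, `tmax`,
#'   `tmin`, optional `day_length` (hours; computed from `latitude` when
#'   absent).
#' @param planting_date `Date` (or coercible).
#' @param start_day,end_day Window bounds in days after planting,
#'   inclusive, `0 <= start_day <= end_day`.
#' @param family `"GDD"` or `"PTT"`.
#' @param latitude Site latitude; required for `"PTT"` unless `weather`
#'   carries a `day_length` column.
#' @param aggregate `"mean"` or `"sum"` of daily values.
#' @param base,ceiling GDD temperatures (degC).
#' @return A single index value (degC day for GDD, degC day h for PTT).
#' @export
window_index <- function(weather, planting_date, start_day, end_day,
                         family = c("GDD", "PTT"), latitude = NULL,
                         aggregate = c("mean", "sum"),
                         base = 10, ceiling = 37.8) {
  family <- match.arg(family)
  aggregate <- match.arg(aggregate)
  if (start_day < 0 || end_day < start_day) {
    abort("Require 0 <= start_day <= end_day.")
  }
  planting_date <- as.Date(planting_date)
  days <- planting_date + seq(start_day, end_day)
  idx <- match(days, as.Date(weather$date))
  if (anyNA(idx)) {
    abort(paste0("Weather does not cover the window; missing date(s) starting ",
                 format(days[which(is.na(idx))[1]]), "."))
  }
  w <- weather[idx, ]
  vals <- daily_gdd(w$tmax, w$tmin, base = base, ceiling = ceiling)
  if (family == "PTT") {
    dl <- if ("day_length" %in% names(w) && !anyNA(w$day_length)) {
      w$day_length
    } else {
      if (is.null(latitude)) abort("PTT needs `latitude` or a `day_length` column.")
      day_length(latitude, w$date)
    }
    vals <- vals * dl
  }
  if (aggregate == "mean") mean(vals) else sum(vals)
}

#' Environmental-index values for a table of environments
#'
#' @param env_table Tibble with one row per environment: `environment`,
#'   `site`, `planting_date`.
#' @param weather Daily weather tibble covering all sites (`site`, `date`,
#'   `tmax`, `tmin`, optional `day_length`).
#' @param sites Site metadata tibble (`site`, `latitude`); optional for GDD.
#' @inheritParams window_index
#' @return `env_table` with added columns `family`, `start_day`, `end_day`,
#'   `value`.
#' @export
env_index_table <- function(env_table, weather, sites = NULL,
                            start_day, end_day, family = c("GDD", "PTT"),
                            aggregate = c("mean", "sum"),
                            base = 10, ceiling = 37.8) {
  family <- match.arg(family)
  aggregate <- match.arg(aggregate)
  vals <- purrr::pmap_dbl(
    list(env_table$site, env_table$planting_date),
    function(st, pd) {
      lat <- if (!is.null(sites)) sites$latitude[match(st, sites$site)] else NULL
      window_index(dplyr::filter(weather, .data$site == st),
                   pd, start_day, end_day, family = family,
                   latitude = lat, aggregate = aggregate,
                   base = base, ceiling = ceiling)
    }
  )
  dplyr::mutate(env_table, family = family, start_day = start_day,
                end_day = end_day, value = vals)
}

#' Search growth windows for the best environmental index
#'
#' For every candidate window `(start, end)` on the supplied grids, computes
#' the index for each environment and its Pearson correlation across
#' environments with the observed environmental means (from the trial
#' phenotypes), returning the full correlation surface and the window
#' maximizing `|r|`. This is how a weather-based surrogate for the
#' environmental mean — such as the photothermal-time window 18-43 days
#' after planting for sorghum flowering, or the growing-degree-day window
#' 9-50 days for rice — is identified so that environments can be indexed
#' before any trait is expressed. Ties are broken toward the earliest start
#' and then the shortest window.
#'
#' @param env_table Tibble: `environment`, `site`, `planting_date`,
#'   `observed_mean` (>= 3 environments).
#' @param weather,sites As in [env_index_table()].
#' @param family `"GDD"` or `"PTT"`.
#' @param start_grid,end_grid Integer grids of window bounds (days after
#'   planting); only pairs with `start <= end` are evaluated.
#' @inheritParams window_index
#' @return List with `surface` (tibble `start_day`, `end_day`, `r`) and
#'   `best` (one-row tibble, highest `|r|`).
#' @export
window_search <- function(env_table, weather, sites = NULL,
                          family = c("GDD", "PTT"),
                          start_grid, end_grid,
                          aggregate = c("mean", "sum"),
                          base = 10, ceiling = 37.8) {
  family <- match.arg(family)
  aggregate <- match.arg(aggregate)
  if (nrow(env_table) < 3) abort("Window search needs >= 3 environments.")
  if (length(start_grid) == 0 || length(end_grid) == 0) {
    abort("Window grids must be non-empty.")
  }
  lo <- min(start_grid); hi <- max(end_grid)

  # per-environment daily values on the full offset range, then cumulative
  # sums so each window is an O(1) lookup
  daily <- purrr::map(seq_len(nrow(env_table)), function(i) {
    st <- env_table$site[i]
    pd <- as.Date(env_table$planting_date[i])
    w <- dplyr::filter(weather, .data$site == st)
    days <- pd + seq(lo, hi)
    idx <- match(days, as.Date(w$date))
    if (anyNA(idx)) {
      abort(paste0("Weather for site ", st, " does not cover offsets ",
                   lo, "..", hi, " from planting ", format(pd), "."))
    }
    w <- w[idx, ]
    v <- daily_gdd(w$tmax, w$tmin, base = base, ceiling = ceiling)
    if (family == "PTT") {
      dl <- if ("day_length" %in% names(w) && !anyNA(w$day_length)) {
        w$day_length
      } else {
        lat <- if (!is.null(sites)) sites$latitude[match(st, sites$site)] else NULL
        if (is.null(lat)) abort("PTT needs `sites` latitudes or a day_length column.")
        day_length(lat, w$date)
      }
      v <- v * dl
    }
    cumsum(v)
  })
  csum <- do.call(rbind, daily) # env x offsets, cumulative

  grid <- tidyr::expand_grid(start_day = sort(unique(start_grid)),
                             end_day = sort(unique(end_grid))) %>%
    dplyr::filter(.data$start_day <= .data$end_day)
  obs <- env_table$observed_mean
  r <- purrr::map2_dbl(grid$start_day, grid$end_day, function(s, e) {
    i0 <- s - lo; i1 <- e - lo + 1
    tot <- csum[, i1] - (if (i0 > 0) csum[, i0] else 0)
    vals <- if (aggregate == "mean") tot / (e - s + 1) else tot
    if (stats::sd(vals) == 0) return(NA_real_)
    stats::cor(vals, obs)
  })
  surface <- dplyr::mutate(grid, r = r)
  ranked <- surface %>%
    dplyr::filter(is.finite(.data$r)) %>%
    dplyr::arrange(dplyr::desc(abs(.data$r)), .data$start_day,
                   .data$end_day - .data$start_day)
  list(surface = surface, best = ranked[1, ])
}
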