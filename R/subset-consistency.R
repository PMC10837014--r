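#' Enumerate environment subsets
#'
#' All size-`k` combinations of the environment set for `k` from `k_min` to
#' `k_max`, in deterministic lexicographic order. With nine environments and
#' `k` from 2 to 8 this yields the 501 subsets
#' (36, 84, 126, 126, 84, 36, 9 by size).
#'
#' @param environments Character vector of environment ids, or a single
#'   integer `n` (ids become `E1..En`).
#' @param k_min,k_max Inclusive subset-size bounds; `k_min >= 2`.
#' @return Tibble with columns `k`, `members` (list-column of id vectors)
#'   and `subset_id` (semicolon-joined members).
#' @export
#' @examples
#' enumerate_env_subsets(4, 2, 3)
enumerate_env_subsets <- function(environments, k_min = 2, k_max = NULL) {
  if (is.numeric(environments) && length(environments) == 1) {
    environments <- paste0("E", seq_len(environments))
  }
  environments <- as.character(environments)
  n <- length(environments)
  if (is.null(k_max)) k_max <- n - 1
  if (k_min < 2) abort("`k_min` must be >= 2 (a single environment has no range).")
  if (k_min > k_max || k_max > n) abort("Require 2 <= k_min <= k_max <= n_env.")
  members <- purrr::map(k_min:k_max, function(k) {
    utils::combn(environments, k, simplify = FALSE)
  }) %>% purrr::flatten()
  tibble(
    k = lengths(members),
    members = members,
    subset_id = purrr::map_chr(members, paste, collapse = ";")
  )
}

#' Consistency of reaction-norm parameters across environment subsets
#'
#' Re-estimates reaction norms within every environment subset (joint
#' regression for three or more environments, the two-environment rule for
#' pairs) and correlates the subset estimates with the whole-set estimates,
#' giving one consistency score per subset and parameter. The
#' environmental-mean range of a subset is measured on the whole-set index
#' scale so that ranges are comparable across subsets; `range_fraction`
#' rescales it by the whole-set range.
#'
#' Subsets whose estimation fails (for example a pair with identical
#' environmental means) are kept in the output with `NA` correlations and
#' the error message in `note` rather than aborting the scan.
#'
#' @param pheno Long phenotype tibble.
#' @param k_min,k_max Subset sizes to scan (defaults 2 to `n_env - 1`).
#' @return Tibble with one row per subset: `k`, `subset_id`, `members`,
#'   `env_mean_range`, `range_fraction`, `corr_slope`, `corr_intercept`,
#'   `n_genotypes`, `note`.
#' @export
consistency_scan <- function(pheno, k_min = 2, k_max = NULL) {
  pheno <- check_phenotypes(pheno)
  whole <- reaction_norms(pheno)
  wp <- tidy(whole)
  wI <- stats::setNames(whole$env_means$index, whole$env_means$environment)
  whole_range <- max(wI) - min(wI)
  subsets <- enumerate_env_subsets(whole$env_means$environment, k_min, k_max)

  res <- purrr::map(subsets$members, function(envs) {
    rng <- max(wI[envs]) - min(wI[envs])
    est <- tryCatch(
      suppressWarnings(reaction_norms(pheno, envs)),
      error = function(e) e
    )
    if (inherits(est, "error")) {
      return(tibble(env_mean_range = rng, range_fraction = rng / whole_range,
                    corr_slope = NA_real_, corr_intercept = NA_real_,
                    n_genotypes = 0L, note = conditionMessage(est)))
    }
    sp <- tidy(est)
    j <- dplyr::inner_join(wp, sp, by = "genotype", suffix = c("_whole", "_sub"))
    tibble(
      env_mean_range = rng,
      range_fraction = rng / whole_range,
      corr_slope = stats::cor(j$slope_whole, j$slope_sub),
      corr_intercept = stats::cor(j$intercept_whole, j$intercept_sub),
      n_genotypes = nrow(j),
      note = NA_character_
    )
  }) %>% purrr::list_rbind()

  dplyr::bind_cols(subsets, res)
}

#' Cube-root power-curve fit of consistency against range
#'
#' Fits \eqn{y = a + b x^{-1/3} + e} by ordinary least squares, the summary
#' curve used to visualize how quickly consistency rises with the
#' environmental-mean range.
#'
#' @param x Positive predictor values (environmental-mean range).
#' @param y Response (correlation or accuracy).
#' @return Object of class `"cube_root_fit"` with `tidy()`, `glance()`,
#'   `predict()` and `autoplot()` methods.
#' @export
fit_cube_root <- function(x, y) {
  if (any(!is.finite(x)) || any(x <= 0)) abort("All `x` must be positive and finite.")
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2) abort("Need >= 2 distinct x values.")
  fit <- stats::lm(y ~ I(x^(-1/3)))
  structure(
    list(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]),
         fitted = unname(stats::fitted(fit)), rss = sum(stats::resid(fit)^2),
         x = x, y = y, lm = fit),
    class = "cube_root_fit"
  )
}

#' @export
print.cube_root_fit <- function(x, ...) {
  cat("Cube-root curve  y = a + b * x^(-1/3)\n")
  cat("  a =", format(x$a, digits = 6), "  b =", format(x$b, digits = 6),
      "  RSS =", format(x$rss, digits = 6), "\n")
  invisible(x)
}

#' @rdname fit_cube_root
#' @param object,newdata,... `predict`: a fit and a data frame (or vector)
#'   of new `x` values.
#' @export
predict.cube_root_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$a + object$b * x^(-1/3)
}

#' @exportS3Method generics::tidy
tidy.cube_root_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @exportS3Method generics::glance
glance.cube_root_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, rss = x$rss, n = length(x$x))
}

#' @exportS3Method ggplot2::autoplot
autoplot.cube_root_fit <- function(object, ...) {
  grid <- tibble(x = seq(min(object$x), max(object$x), length.out = 200))
  grid$y <- predict(object, grid)
  ggplot2::ggplot(tibble(x = object$x, y = object$y),
                  ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "black", linewidth = 0.8) +
    ggplot2::labs(x = "Environmental mean range", y = "Correlation",
                  title = "Cube-root consistency curve") +
    ggplot2::theme_minimal()
}

#' Smoothing-spline summary curves per environment sample size
#'
#' Fits one smoothing spline (smoothing parameter by generalized
#' cross-validation) of consistency or accuracy against environmental-mean
#' range for each subset-size group, the standard way to compare how the
#' range-consistency relationship changes with the number of environments.
#' Groups with fewer than 4 points fall back to a straight least-squares
#' line (noted in the output); groups with fewer than 2 points are skipped
#' with a warning.
#'
#' @param data Tibble containing the predictor, response and group columns
#'   (for example the output of [consistency_scan()]).
#' @param x,y,group Column names (strings) for predictor, response and
#'   sample-size group. Defaults fit `corr_slope` against `env_mean_range`
#'   grouped by `k`.
#' @param n_grid Number of points of the common evaluation grid.
#' @return Tibble with one row per group: `group`, `model` ("spline" or
#'   "linear"), `spar` (spline smoothing parameter, `NA` for linear),
#'   `n`, and a list-column `curve` of tibbles (`x`, `fitted`).
#' @export
fit_range_splines <- function(data, x = "env_mean_range", y = "corr_slope",
                              group = "k", n_grid = 100) {
  df <- tibble(x = data[[x]], y = data[[y]], group = data[[group]]) %>%
    dplyr::filter(is.finite(.data$x), is.finite(.data$y))
  purrr::map(split(df, df$group), function(d) {
    g <- d$group[1]
    if (nrow(d) < 2) {
      warn(paste0("Group ", g, " has < 2 points; skipped."))
      return(NULL)
    }
    grid <- seq(min(d$x), max(d$x), length.out = n_grid)
    if (nrow(d) >= 4 && length(unique(d$x)) >= 4) {
      sp <- stats::smooth.spline(d$x, d$y, cv = FALSE) # GCV
      tibble(group = g, model = "spline", spar = sp$spar, n = nrow(d),
             curve = list(tibble(x = grid,
                                 fitted = stats::predict(sp, grid)$y)))
    } else {
      inform(paste0("Group ", g, ": < 4 points, using a linear fit."))
      lf <- stats::lm(y ~ x, data = d)
      tibble(group = g, model = "linear", spar = NA_real_, n = nrow(d),
             curve = list(tibble(x = grid,
                                 fitted = unname(stats::predict(lf, tibble(x = grid))))))
    }
  }) %>% purrr::list_rbind()
}

#' Write a consistency scan as a tidy CSV
#' @param scan Output of [consistency_scan()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_consistency <- function(scan, path) {
  out <- dplyr::select(scan, -"members")
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Plot a consistency scan against environmental-mean range
#'
#' @param scan Output of [consistency_scan()].
#' @param parameter `"slope"` or `"intercept"`.
#' @param cube_root Overlay the cube-root summary curve.
#' @return A ggplot.
#' @export
plot_consistency <- function(scan, parameter = c("slope", "intercept"),
                             cube_root = TRUE) {
  parameter <- match.arg(parameter)
  ycol <- paste0("corr_", parameter)
  df <- tibble(x = scan$env_mean_range, y = scan[[ycol]],
               k = factor(scan$k)) %>%
    dplyr::filter(is.finite(.data$y))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$k)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Environmental mean range",
                  y = paste("Correlation of", parameter, "with whole set"),
                  colour = "n environments") +
    ggplot2::theme_minimal()
  if (cube_root && sum(df$x > 0) >= 2) {
    cr <- fit_cube_root(df$x[df$x > 0], df$y[df$x > 0])
    grid <- tibble(x = seq(min(df$x[df$x > 0]), max(df$x), length.out = 200))
    grid$y <- predict(cr, grid)
    p <- p + ggplot2::geom_line(data = grid, ggplot2::aes(.data$x, .data$y),
                                inherit.aes = FALSE, colour = "black")
  }
  p
}
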