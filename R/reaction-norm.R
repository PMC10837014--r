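#' Environmental means and the centered environmental index
#'
#' The environmental mean of environment \eqn{j} is the average line mean of
#' all genotypes observed there. Centering by the grand mean (the unweighted
#' mean of the environmental means) gives the environmental index \eqn{I_j}
#' used as the regressor in joint regression, so that the fitted intercept is
#' the genotypic value at the average environment.
#'
#' @param pheno Long phenotype tibble (`genotype`, `environment`, `value`).
#' @param environments Optional character vector restricting the computation
#'   to a subset of environments (the subset defines its own grand mean).
#' @return A tibble with columns `environment`, `mean` (trait units) and
#'   `index` (centered mean, trait units); the grand mean is attached as
#'   attribute `"grand_mean"`.
#' @export
#' @examples
#' ph <- tidyr::expand_grid(genotype = c("g1", "g2"), environment = c("A", "B", "C"))
#' ph$value <- c(1, 2, 3, 3, 4, 5)
#' environment_means(ph)
environment_means <- function(pheno, environments = NULL) {
  pheno <- check_phenotypes(pheno)
  if (!is.null(environments)) {
    if (length(environments) == 0) abort("`environments` must be non-empty.")
    bad <- setdiff(environments, unique(pheno$environment))
    if (length(bad) > 0) {
      abort(paste0("Unknown environment(s): ", paste(bad, collapse = ", ")))
    }
    pheno <- dplyr::filter(pheno, .data$environment %in% environments)
  } else {
    environments <- sort(unique(pheno$environment))
  }
  em <- pheno %>%
    dplyr::group_by(.data$environment) %>%
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     n_obs = sum(!is.na(.data$value)), .groups = "drop")
  empty <- em$environment[em$n_obs == 0]
  if (length(empty) > 0) {
    abort(paste0("Environment(s) with no observed genotypes: ",
                 paste(empty, collapse = ", ")))
  }
  em <- em[match(environments, em$environment), ]
  grand <- mean(em$mean)
  out <- tibble(environment = em$environment, mean = em$mean,
                index = em$mean - grand)
  attr(out, "grand_mean") <- grand
  out
}

#' Reaction-norm estimation by joint regression
#'
#' Fits, for every genotype, the Finlay-Wilkinson model
#' \deqn{Y_{ij} = \mu_i + \beta_i I_j + \delta_{ij}}
#' by per-genotype ordinary least squares of the line means on the centered
#' environmental index \eqn{I_j}. The intercept \eqn{\mu_i} is the genotypic
#' value at the average environment and the slope \eqn{\beta_i} is the
#' plasticity: the expected change in performance per unit change in
#' environmental mean (population average slope is 1 by construction).
#'
#' Genotypes are fitted on their non-missing environments only; genotypes
#' observed in fewer than 3 of the requested environments are dropped with a
#' warning. For exactly two environments use [two_env_parameters()].
#'
#' @param pheno Long phenotype tibble.
#' @param environments Optional subset of environment ids (>= 3). The
#'   environmental index is recomputed (re-centered) within the subset.
#' @return An object of class `"reaction_norm_fit"`: see [tidy()][generics::tidy]
#'   for the per-genotype parameter tibble, [glance()][generics::glance] for
#'   the one-row summary, `residuals()` for the per-cell deviations, and
#'   [ggplot2::autoplot()] for a reaction-norm plot.
#' @export
fit_joint_regression <- function(pheno, environments = NULL) {
  em <- environment_means(pheno, environments)
  if (nrow(em) < 3) {
    abort("Joint regression needs >= 3 environments; use two_env_parameters() for a pair.")
  }
  if (max(em$index) - min(em$index) < .Machine$double.eps^0.5 * (1 + abs(attr(em, "grand_mean")))) {
    abort("All environmental means are identical: the joint-regression design is singular.")
  }
  Y <- pheno_matrix(pheno, em$environment)
  I <- em$index

  n_obs <- rowSums(!is.na(Y))
  keep <- n_obs >= 3
  if (!all(keep)) {
    warn(paste0(sum(!keep), " genotype(s) with < 3 observed environments dropped: ",
                paste(utils::head(rownames(Y)[!keep], 5), collapse = ", ")))
    Y <- Y[keep, , drop = FALSE]
  }
  if (nrow(Y) < 1) abort("No genotype has >= 3 observed environments.")

  g <- nrow(Y)
  slope <- numeric(g); intercept <- numeric(g)
  complete <- rowSums(is.na(Y)) == 0
  if (any(complete)) {
    Yc <- Y[complete, , drop = FALSE]
    ssI <- sum(I^2) # I is centered within the environment set
    slope[complete] <- as.vector(Yc %*% I) / ssI
    intercept[complete] <- rowMeans(Yc)
  }
  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    x <- I[ok]; y <- Y[i, ok]
    xc <- x - mean(x)
    b <- sum(xc * y) / sum(xc^2)
    slope[i] <- b
    intercept[i] <- mean(y) - b * mean(x)
  }
  fitted <- intercept %o% rep(1, length(I)) + slope %o% I
  resid <- Y - fitted

  params <- tibble(
    genotype = rownames(Y),
    intercept = intercept,
    slope = slope,
    n_env = rowSums(!is.na(Y)),
    method = "ols"
  )
  residuals <- tibble(
    genotype = rep(rownames(Y), times = ncol(Y)),
    environment = rep(colnames(Y), each = nrow(Y)),
    residual = as.vector(resid)
  ) %>% dplyr::filter(!is.na(.data$residual))

  new_reaction_norm_fit(params, em, residuals, method = "ols")
}

#' Reaction-norm parameters from exactly two environments
#'
#' With only two environments a regression is saturated, so the parameters
#' are taken directly: the intercept is the average of the two line means
#' and the slope is their difference standardized by the difference in
#' environmental index, with the pair ordered so the higher-mean environment
#' comes second. The standardization puts the two-environment slopes on the
#' same scale as ordinary joint-regression slopes; Pearson correlations
#' against whole-set slopes are identical to those of the raw differences.
#'
#' @param pheno Long phenotype tibble.
#' @param env_pair Character vector of exactly two environment ids.
#' @return A `"reaction_norm_fit"` (method `"two_env"`). Genotypes missing
#'   either value are excluded; their ids are in attribute `"dropped"`.
#' @export
two_env_parameters <- function(pheno, env_pair) {
  if (length(env_pair) != 2 || anyDuplicated(env_pair)) {
    abort("`env_pair` must name exactly 2 distinct environments.")
  }
  em <- environment_means(pheno, env_pair)
  if (abs(diff(em$index)) < .Machine$double.eps^0.5 * (1 + abs(attr(em, "grand_mean")))) {
    abort("The two environmental means are equal: slope is undefined for this pair.")
  }
  # order ascending by environmental mean so I_2 > I_1
  ord <- order(em$index)
  em <- em[ord, ]
  attr(em, "grand_mean") <- mean(em$mean)
  Y <- pheno_matrix(pheno, em$environment)
  ok <- rowSums(is.na(Y)) == 0
  dropped <- rownames(Y)[!ok]
  if (length(dropped) > 0) {
    warn(paste0(length(dropped), " genotype(s) missing a value in the pair were excluded."))
  }
  Y <- Y[ok, , drop = FALSE]
  if (nrow(Y) < 1) abort("No genotype observed in both environments.")
  dI <- em$index[2] - em$index[1]
  params <- tibble(
    genotype = rownames(Y),
    intercept = unname((Y[, 1] + Y[, 2]) / 2),
    slope = unname((Y[, 2] - Y[, 1]) / dI),
    n_env = 2L,
    method = "two_env"
  )
  residuals <- tibble(genotype = character(), environment = character(),
                      residual = double())
  out <- new_reaction_norm_fit(params, em, residuals, method = "two_env")
  attr(out, "dropped") <- dropped
  out
}

#' Estimate reaction norms for any environment set
#'
#' Dispatches to [fit_joint_regression()] when three or more environments are
#' requested and to [two_env_parameters()] for a pair.
#'
#' @inheritParams fit_joint_regression
#' @return A `"reaction_norm_fit"`.
#' @export
reaction_norms <- function(pheno, environments = NULL) {
  if (is.null(environments)) {
    environments <- sort(unique(check_phenotypes(pheno)$environment))
  }
  if (length(environments) == 2) {
    two_env_parameters(pheno, environments)
  } else {
    fit_joint_regression(pheno, environments)
  }
}

new_reaction_norm_fit <- function(params, env_means, residuals, method) {
  structure(
    list(params = params, env_means = env_means, residuals = residuals,
         grand_mean = attr(env_means, "grand_mean"), method = method),
    class = "reaction_norm_fit"
  )
}

#' @export
print.reaction_norm_fit <- function(x, ...) {
  cat("Reaction-norm fit (", x$method, "): ",
      nrow(x$params), " genotypes x ", nrow(x$env_means), " environments\n", sep = "")
  cat("Grand mean:", format(x$grand_mean, digits = 6),
      " | environmental-mean range:",
      format(max(x$env_means$index) - min(x$env_means$index), digits = 6), "\n")
  print(utils::head(x$params, 5))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-genotype reaction-norm parameters
#' @param x A `"reaction_norm_fit"`.
#' @param ... Unused.
#' @return Tibble with `genotype`, `intercept`, `slope`, `n_env`, `method`.
#' @exportS3Method generics::tidy
tidy.reaction_norm_fit <- function(x, ...) x$params

#' One-row summary of a reaction-norm fit
#' @param x A `"reaction_norm_fit"`.
#' @param ... Unused.
#' @return Tibble with genotype/environment counts, grand mean, mean and sd
#'   of intercepts and slopes, and the environmental-mean range.
#' @exportS3Method generics::glance
glance.reaction_norm_fit <- function(x, ...) {
  tibble(
    n_genotypes = nrow(x$params),
    n_env = nrow(x$env_means),
    grand_mean = x$grand_mean,
    mean_intercept = mean(x$params$intercept),
    mean_slope = mean(x$params$slope),
    sd_intercept = stats::sd(x$params$intercept),
    sd_slope = stats::sd(x$params$slope),
    env_mean_range = max(x$env_means$index) - min(x$env_means$index)
  )
}

#' @export
residuals.reaction_norm_fit <- function(object, ...) object$residuals

#' Plot fitted reaction norms across the environmental gradient
#'
#' One line per genotype over the observed index range, with the
#' environmental means marked on the 1:1 population line.
#'
#' @param object A `"reaction_norm_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.reaction_norm_fit <- function(object, ...) {
  rng <- range(object$env_means$index)
  lines <- tidyr::expand_grid(tidy(object), index = rng) %>%
    dplyr::mutate(value = .data$intercept + .data$slope * .data$index)
  ggplot2::ggplot(lines, ggplot2::aes(.data$index, .data$value, group = .data$genotype)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::geom_point(
      data = object$env_means,
      ggplot2::aes(.data$index, .data$index + object$grand_mean),
      inherit.aes = FALSE, colour = "red", size = 2
    ) +
    ggplot2::labs(x = "Environmental index (centered environmental mean)",
                  y = "Trait value",
                  title = "Reaction norms by joint regression") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
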