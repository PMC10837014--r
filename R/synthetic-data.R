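#' Simulate a biparental inbred mapping population
#'
#' Generates marker genotypes with realistic linkage structure. Markers are
#' evenly spaced along each chromosome; along a chromosome genotypes follow
#' a Markov chain whose switch probability at inter-marker distance `d` cM
#' comes from Haldane's map function, \eqn{r = (1 - e^{-2d/100})/2}, with
#' the standard RIL adjustment \eqn{R = 2r/(1+2r)} that accounts for the
#' extra effective recombination accumulated over selfing generations.
#'
#' Recombinant inbred lines (`"RIL"`) are fully homozygous: codes are
#' `-1`/`+1` with expected allele frequency 1/2. Backcross inbred lines
#' (`"BIL"`) are skewed 75/25 toward the recurrent parent (coded `-1`) and
#' may retain residual heterozygosity (code `0`): at each marker the chain
#' either copies the previous genotype or, with the distance-driven switch
#' probability, redraws from the stationary distribution (70% recurrent
#' homozygote, 10% heterozygote, 20% donor homozygote).
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param n_markers Total marker count, spread across chromosomes.
#' @param n_chromosomes Number of chromosomes (default 10).
#' @param population_type `"RIL"` or `"BIL"`.
#' @param chrom_length Genetic length of each chromosome in centimorgans.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Coded marker matrix (lines in rows, markers `M1..` in columns).
#' @export
simulate_biparental_genotypes <- function(n_lines = 64, n_markers = 200,
                                          n_chromosomes = 10,
                                          population_type = c("RIL", "BIL"),
                                          chrom_length = 100, seed = 1) {
  population_type <- match.arg(population_type)
  if (n_lines < 2) abort("`n_lines` must be >= 2.")
  if (n_markers < n_chromosomes) abort("Need at least one marker per chromosome.")
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  per_chr <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1

  chain_chr <- function(m) {
    d <- if (m > 1) chrom_length / (m - 1) else 0
    r <- 0.5 * (1 - exp(-2 * d / 100))
    R <- 2 * r / (1 + 2 * r)
    if (population_type == "RIL") {
      g <- matrix(0, n_lines, m)
      g[, 1] <- sample(c(-1, 1), n_lines, replace = TRUE)
      if (m > 1) {
        for (j in 2:m) {
          flip <- stats::runif(n_lines) < R
          g[, j] <- ifelse(flip, -g[, j - 1], g[, j - 1])
        }
      }
      g
    } else {
      states <- c(-1, 0, 1)
      pi0 <- c(0.70, 0.10, 0.20) # recurrent hom, het, donor hom
      g <- matrix(0, n_lines, m)
      g[, 1] <- sample(states, n_lines, replace = TRUE, prob = pi0)
      if (m > 1) {
        for (j in 2:m) {
          redraw <- stats::runif(n_lines) < R
          g[, j] <- g[, j - 1]
          if (any(redraw)) {
            g[redraw, j] <- sample(states, sum(redraw), replace = TRUE, prob = pi0)
          }
        }
      }
      g
    }
  }
  G <- do.call(cbind, lapply(per_chr, chain_chr))
  dimnames(G) <- list(paste0("L", seq_len(n_lines)),
                      paste0("M", seq_len(n_markers)))
  G
}

#' Simulate a multi-environment reaction-norm study
#'
#' Builds phenotypes from the linear reaction-norm model
#' \eqn{Y_{ij} = \mu_i + \beta_i I_j + \delta_{ij}} used generatively:
#' per-genotype intercepts and slopes are parameter baselines plus sparse
#' additive marker effects (disjoint QTL sets for the two parameters by
#' default, so their prediction accuracies are separately meaningful),
#' environment index values are evenly spaced across `index_range`
#' (optionally jittered) and centered, and the deviations
#' \eqn{\delta_{ij}} are iid Gaussian noise.
#'
#' Defaults mirror a sorghum flowering-time study measured in growing
#' degree days: baseline 2000 GDD, environment means spanning about
#' 950 GDD, residual noise 60 GDD, population-average slope 1.
#'
#' @param markers Coded marker matrix (see
#'   [simulate_biparental_genotypes()]).
#' @param n_env Number of environments.
#' @param index_range Span of the true environment index (trait units).
#' @param n_qtl Number of causal markers per parameter.
#' @param mu_baseline,slope_baseline Population baselines for intercept and
#'   slope.
#' @param mu_effect_sd,slope_effect_sd Per-QTL additive effect standard
#'   deviations (trait units; slope effects are per unit of index).
#' @param noise_sd Standard deviation of \eqn{\delta_{ij}} (trait units).
#' @param index_jitter_sd Jitter added to the evenly spaced index values.
#' @param overlap_qtl Allow the two QTL sets to overlap (default disjoint).
#' @param seed Integer seed.
#' @return List with `pheno` (long phenotype tibble), and `truth`: a list
#'   carrying `params` (tibble `genotype`, `mu`, `beta`), `index` (tibble
#'   `environment`, `index`), effect vectors, QTL indices, `noise_sd` and
#'   the seed.
#' @export
simulate_study <- function(markers, n_env = 9, index_range = 950,
                           n_qtl = 10, mu_baseline = 2000,
                           slope_baseline = 1, mu_effect_sd = 40,
                           slope_effect_sd = 0.07, noise_sd = 60,
                           index_jitter_sd = 0, overlap_qtl = FALSE,
                           seed = 1) {
  Z <- impute_markers(marker_matrix(markers))
  p <- ncol(Z)
  if (n_env < 2) abort("`n_env` must be >= 2.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_qtl > p || (!overlap_qtl && 2 * n_qtl > p)) {
    abort("Too many QTL for the number of markers.")
  }
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  qtl_mu <- sort(sample.int(p, n_qtl))
  pool <- if (overlap_qtl) seq_len(p) else setdiff(seq_len(p), qtl_mu)
  qtl_beta <- sort(sample(pool, n_qtl))
  eff_mu <- numeric(p); eff_mu[qtl_mu] <- stats::rnorm(n_qtl, 0, mu_effect_sd)
  eff_beta <- numeric(p); eff_beta[qtl_beta] <- stats::rnorm(n_qtl, 0, slope_effect_sd)

  mu <- mu_baseline + as.vector(Z %*% eff_mu)
  beta <- slope_baseline + as.vector(Z %*% eff_beta)

  I <- seq(-index_range / 2, index_range / 2, length.out = n_env)
  if (index_jitter_sd > 0) I <- I + stats::rnorm(n_env, 0, index_jitter_sd)
  I <- I - mean(I)
  env_ids <- sprintf("env%02d", seq_len(n_env))

  Y <- outer(mu, rep(1, n_env)) + outer(beta, I) +
    matrix(stats::rnorm(length(mu) * n_env, 0, noise_sd), nrow = length(mu))
  pheno <- tibble(
    genotype = rep(rownames(Z), times = n_env),
    environment = rep(env_ids, each = nrow(Z)),
    value = as.vector(Y)
  )
  truth <- list(
    params = tibble(genotype = rownames(Z), mu = mu, beta = beta),
    index = tibble(environment = env_ids, index = I),
    effects_mu = eff_mu, effects_beta = eff_beta,
    qtl_mu = qtl_mu, qtl_beta = qtl_beta,
    noise_sd = noise_sd, seed = seed
  )
  list(pheno = pheno, truth = truth)
}

#' One-call synthetic study at a named scale
#'
#' Convenience wrapper generating a RIL population and phenotypes with the
#' package defaults. `"ci"` is the fast test scale (64 lines, 200 markers,
#' 9 environments); `"full"` matches the sorghum study shape (237 lines,
#' 1462 markers, 9 environments).
#'
#' @param scale `"ci"` or `"full"`.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_study()] (e.g. `noise_sd`).
#' @return List with `markers`, `pheno`, `truth`.
#' @export
synthetic_study <- function(scale = c("ci", "full"), seed = 1, ...) {
  scale <- match.arg(scale)
  dims <- switch(scale,
    ci = list(n_lines = 64, n_markers = 200),
    full = list(n_lines = 237, n_markers = 1462)
  )
  G <- simulate_biparental_genotypes(dims$n_lines, dims$n_markers, seed = seed)
  st <- simulate_study(G, seed = seed + 1, ...)
  list(markers = G, pheno = st$pheno, truth = st$truth)
}

#' Simulate daily weather with sinusoidal seasonality
#'
#' Generates per-site daily temperature series: the daily mean is a site
#' baseline (declining with latitude) plus a seasonal sinusoid whose
#' amplitude increases with absolute latitude (flipping phase in the
#' southern hemisphere), a site-year effect, and iid daily noise; maxima
#' and minima are the mean plus/minus a fixed diurnal half-range. This
#' reproduces the pattern that high-latitude sites sweep a much wider
#' thermal range across planting dates and years than tropical sites.
#'
#' @param sites Tibble with `site` and `latitude` columns.
#' @param years Integer vector of calendar years to cover (full years are
#'   generated).
#' @param seed Integer seed.
#' @param mean_base Sea-level equatorial annual-mean temperature (degC).
#' @param mean_lat_slope Decline of annual mean per degree of |latitude|.
#' @param amplitude_per_deg Seasonal amplitude gained per degree of
#'   |latitude| (degC).
#' @param year_effect_sd SD of the site-year temperature shift (degC).
#' @param daily_noise_sd SD of day-to-day noise (degC).
#' @param diurnal_half_range Half of the daily max-min spread (degC).
#' @return Daily weather tibble: `site`, `date`, `tmax`, `tmin`.
#' @export
simulate_weather <- function(sites, years, seed = 1,
                             mean_base = 27, mean_lat_slope = 0.43,
                             amplitude_per_deg = 0.35,
                             year_effect_sd = 0.8, daily_noise_sd = 2,
                             diurnal_half_range = 5) {
  if (amplitude_per_deg < 0 || year_effect_sd < 0 || daily_noise_sd < 0) {
    abort("Amplitude and noise parameters must be >= 0.")
  }
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  purrr::pmap(list(as.character(sites$site), sites$latitude), function(st, lat) {
    base_mean <- mean_base - mean_lat_slope * abs(lat)
    amp <- amplitude_per_deg * abs(lat)
    hemi <- ifelse(lat >= 0, 1, -1)
    purrr::map(years, function(yr) {
      dates <- seq(as.Date(paste0(yr, "-01-01")), as.Date(paste0(yr, "-12-31")),
                   by = "day")
      doy <- as.integer(strftime(dates, "%j"))
      seasonal <- -amp * hemi * cos(2 * pi * (doy - 15) / 365.25)
      yr_eff <- stats::rnorm(1, 0, year_effect_sd)
      tmean <- base_mean + seasonal + yr_eff +
        stats::rnorm(length(dates), 0, daily_noise_sd)
      tibble(site = st, date = dates,
             tmax = tmean + diurnal_half_range,
             tmin = tmean - diurnal_half_range)
    }) %>% purrr::list_rbind()
  }) %>% purrr::list_rbind()
}
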