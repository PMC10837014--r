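#' Cross-validated genomic prediction of reaction-norm parameters
#'
#' Evaluates how well intercepts and slopes of untested genotypes can be
#' predicted from markers under two scenarios. In scenario `"within"`, both
#' the training values and the held-out reference values are the parameters
#' estimated from the given subset of environments. In scenario `"whole"`,
#' models are still trained on subset-estimated parameters, but held-out
#' predictions are scored against the parameters estimated from the whole
#' set of environments — measuring whether a cheap subset of environments
#' can stand in for the full trial series.
#'
#' Genotypes are partitioned into folds by a seeded uniform shuffle followed
#' by contiguous blocks; accuracy is the average over folds of the Pearson
#' correlation between a fold's held-out predictions and its reference
#' values. Averaging within folds keeps a no-signal model at zero expected
#' accuracy; a single correlation pooled across all folds is contaminated
#' by the anti-correlation between a fold's training mean and its held-out
#' mean and is biased negative when marker effects are heavily shrunk.
#'
#' @param markers Coded marker matrix or tibble (see [fit_ridge_blup()]).
#' @param pheno Long phenotype tibble.
#' @param environments Environment subset used for training estimates
#'   (default: all environments).
#' @param scenario `"within"` or `"whole"`.
#' @param parameter Parameters to evaluate (default both).
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @return Tibble with one row per parameter: `scenario`, `parameter`,
#'   `subset_id`, `k`, `n_folds`, `seed`, `n_genotypes`, `accuracy`.
#' @export
cv_genomic_prediction <- function(markers, pheno,
                                  environments = NULL,
                                  scenario = c("within", "whole"),
                                  parameter = c("intercept", "slope"),
                                  n_folds = 10, seed = 1) {
  scenario <- match.arg(scenario)
  parameter <- match.arg(parameter, several.ok = TRUE)
  Z <- impute_markers(marker_matrix(markers))
  pheno <- check_phenotypes(pheno)
  if (is.null(environments)) environments <- sort(unique(pheno$environment))

  sub_fit <- suppressWarnings(reaction_norms(pheno, environments))
  sub_par <- tidy(sub_fit)
  ref_par <- if (scenario == "whole") {
    tidy(suppressWarnings(reaction_norms(pheno)))
  } else {
    sub_par
  }

  ids <- Reduce(intersect, list(rownames(Z), sub_par$genotype, ref_par$genotype))
  n <- length(ids)
  if (n < n_folds) abort("Fewer genotypes than folds.")
  if (n_folds < 2) abort("`n_folds` must be >= 2.")
  Z <- Z[ids, , drop = FALSE]
  sub_par <- sub_par[match(ids, sub_par$genotype), ]
  ref_par <- ref_par[match(ids, ref_par$genotype), ]

  folds <- make_folds(n, n_folds, seed)
  if (min(table(folds)) < 2) abort("A fold has < 2 genotypes; reduce `n_folds`.")

  purrr::map(parameter, function(par) {
    y_train <- stats::setNames(sub_par[[par]], ids)
    y_ref <- stats::setNames(ref_par[[par]], ids)
    fold_r <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      test <- folds == f
      fit <- fit_ridge_blup(Z[!test, , drop = FALSE], y_train[!test])
      pred_f <- predict(fit, Z[test, , drop = FALSE])
      if (stats::sd(pred_f) > 0 && stats::sd(y_ref[test]) > 0) {
        fold_r[f] <- stats::cor(pred_f, y_ref[test])
      }
    }
    tibble(
      scenario = scenario, parameter = par,
      subset_id = paste(environments, collapse = ";"),
      k = length(environments), n_folds = as.integer(n_folds),
      seed = as.integer(seed), n_genotypes = n,
      accuracy = mean(fold_r, na.rm = TRUE)
    )
  }) %>% purrr::list_rbind()
}

# Seeded shuffle, then contiguous blocks as balanced as possible.
make_folds <- function(n, n_folds, seed) {
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ord <- sample.int(n)
  sizes <- rep(n %/% n_folds, n_folds) + (seq_len(n_folds) <= n %% n_folds)
  folds <- integer(n)
  folds[ord] <- rep(seq_len(n_folds), times = sizes)
  folds
}

# Local seed handling so callers' RNG state is untouched.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Cross-validation accuracy over many environment subsets
#'
#' Runs [cv_genomic_prediction()] for each subset in a scan table (for
#' example a sample of [enumerate_env_subsets()] output joined with range
#' information), collecting accuracies for plotting against
#' environmental-mean range.
#'
#' @param markers Coded marker matrix or tibble.
#' @param pheno Long phenotype tibble.
#' @param subsets Tibble with a `members` list-column (see
#'   [enumerate_env_subsets()]).
#' @param scenario `"within"` or `"whole"`.
#' @param n_folds,seed Passed to [cv_genomic_prediction()].
#' @return Tibble of CV results with `env_mean_range` and `range_fraction`
#'   columns (measured on the whole-set index scale).
#' @export
cv_subset_scan <- function(markers, pheno, subsets,
                           scenario = c("within", "whole"),
                           n_folds = 10, seed = 1) {
  scenario <- match.arg(scenario)
  whole <- suppressWarnings(reaction_norms(pheno))
  wI <- stats::setNames(whole$env_means$index, whole$env_means$environment)
  whole_range <- max(wI) - min(wI)
  purrr::imap(subsets$members, function(envs, idx) {
    rng <- max(wI[envs]) - min(wI[envs])
    res <- tryCatch(
      suppressWarnings(
        cv_genomic_prediction(markers, pheno, envs, scenario = scenario,
                              n_folds = n_folds, seed = seed + idx)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    res$env_mean_range <- rng
    res$range_fraction <- rng / whole_range
    res
  }) %>% purrr::list_rbind()
}
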