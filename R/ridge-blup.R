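#' Ridge-regression BLUP of marker effects with REML
#'
#' Fits the whole-genome shrinkage model
#' \deqn{y = 1 m + Z u + e,\qquad u \sim N(0, \sigma^2_u I_p),\quad
#'       e \sim N(0, \sigma^2_e I_n)}
#' where `Z` is the genotype-by-marker code matrix. The variance ratio
#' \eqn{\lambda = \sigma^2_e / \sigma^2_u} is estimated by restricted
#' maximum likelihood: the restricted log-likelihood is profiled on a
#' one-time eigendecomposition of the marker kernel projected off the mean,
#' scanned on a 25-point grid over \eqn{\log_{10}\lambda \in [-6, 6]} and
#' refined by golden-section search (ties broken toward larger
#' \eqn{\lambda}, i.e. more shrinkage). Marker effects are the ridge (BLUP)
#' solution at the optimum; the overall mean is its generalized
#' least-squares estimate.
#'
#' Missing marker codes are imputed by the marker's mean code before
#' fitting.
#'
#' @param markers Coded marker matrix (genotype rownames, codes in
#'   `{-1, 0, 1}`, `NA` allowed) or a tibble whose first column is the
#'   genotype id.
#' @param y Named numeric vector of per-genotype values (names matched to
#'   marker rows) or an unnamed vector in marker row order.
#' @return Object of class `"ridge_blup"` with components `mean`,
#'   `effects`, `lambda`, `sigma2_u`, `sigma2_e`, `loglik` (restricted
#'   log-likelihood at the optimum) and the marker ids; supports
#'   `predict()`, `tidy()` and `glance()`.
#' @export
fit_ridge_blup <- function(markers, y) {
  Z <- impute_markers(marker_matrix(markers))
  if (!is.null(names(y))) {
    common <- intersect(rownames(Z), names(y))
    if (length(common) < 3) abort("Need >= 3 genotypes present in both markers and y.")
    Z <- Z[common, , drop = FALSE]
    y <- y[common]
  }
  y <- as.numeric(y)
  if (length(y) != nrow(Z)) abort("`y` length must match the number of genotypes.")
  if (any(!is.finite(y))) abort("`y` must be finite.")
  n <- nrow(Z)
  if (n < 3) abort("Need >= 3 genotypes.")
  col_var <- apply(Z, 2, stats::var)
  if (all(col_var == 0)) {
    abort("All marker rows are identical: the design carries no genetic signal.")
  }

  prof <- reml_profile(Z, y)
  opt <- reml_optimize(prof)
  lambda <- opt$lambda
  sol <- blup_solve(Z, y, lambda)

  structure(
    list(mean = sol$mean, effects = sol$effects, lambda = lambda,
         sigma2_u = opt$sigma2_u, sigma2_e = lambda * opt$sigma2_u,
         loglik = opt$loglik, marker_ids = colnames(Z), n = n),
    class = "ridge_blup"
  )
}

# Eigendecomposition-based restricted-likelihood profile for y = 1m + Zu + e.
# Returns a closure environment with theta (eigenvalues of the projected
# kernel), eta2 (squared rotated data) and m = n - 1 residual df.
reml_profile <- function(Z, y) {
  n <- nrow(Z)
  # orthonormal basis of the complement of the intercept column
  T_ <- qr.Q(qr(cbind(rep(1, n), diag(n))))[, 2:n, drop = FALSE]
  K <- tcrossprod(Z)
  M <- crossprod(T_, K %*% T_)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  theta <- pmax(ev$values, 0)
  eta <- as.vector(crossprod(ev$vectors, crossprod(T_, y)))
  list(theta = theta, eta2 = eta^2, m = n - 1)
}

# Restricted log-likelihood at a given lambda (profiled over sigma2_u).
reml_loglik <- function(prof, lambda) {
  d <- prof$theta + lambda
  s2 <- sum(prof$eta2 / d) / prof$m
  if (s2 <= 0) return(-Inf)
  -0.5 * (prof$m * log(2 * pi) + prof$m * log(s2) + sum(log(d)) + prof$m)
}

# 25-point coarse grid on log10 lambda in [-6, 6], golden-section refinement,
# ties toward larger lambda.
reml_optimize <- function(prof, log10_bounds = c(-6, 6), n_grid = 25) {
  grid <- seq(log10_bounds[1], log10_bounds[2], length.out = n_grid)
  ll <- vapply(grid, function(g) reml_loglik(prof, 10^g), numeric(1))
  best <- max(which(ll >= max(ll) - 0))  # ties toward larger lambda
  lo <- grid[max(best - 1, 1)]
  hi <- grid[min(best + 1, n_grid)]
  gs <- golden_section(function(g) reml_loglik(prof, 10^g), lo, hi)
  cand_g <- c(grid[best], gs$x)
  cand_ll <- c(ll[best], gs$value)
  pick <- which(cand_ll >= max(cand_ll) - 1e-12)
  g_opt <- max(cand_g[pick])
  lambda <- 10^g_opt
  d <- prof$theta + lambda
  list(lambda = lambda,
       sigma2_u = sum(prof$eta2 / d) / prof$m,
       loglik = reml_loglik(prof, lambda))
}

# Golden-section maximization on [lo, hi].
golden_section <- function(f, lo, hi, tol = 1e-6, max_iter = 200) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(max_iter)) {
    if (b - a < tol) break
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
  }
  x <- if (f1 < f2) x2 else x1
  list(x = x, value = max(f1, f2))
}

# Mixed-model solution at fixed lambda: GLS mean and BLUP effects.
blup_solve <- function(Z, y, lambda) {
  n <- nrow(Z)
  H <- tcrossprod(Z) + lambda * diag(n)
  Hi1 <- solve(H, rep(1, n))
  m <- sum(Hi1 * y) / sum(Hi1)
  r <- y - m
  u <- as.vector(crossprod(Z, solve(H, r)))
  list(mean = m, effects = stats::setNames(u, colnames(Z)))
}

#' @export
print.ridge_blup <- function(x, ...) {
  cat("Ridge-regression BLUP: ", x$n, " genotypes, ",
      length(x$effects), " markers\n", sep = "")
  cat("  lambda =", format(x$lambda, digits = 5),
      " sigma2_u =", format(x$sigma2_u, digits = 5),
      " sigma2_e =", format(x$sigma2_e, digits = 5), "\n")
  invisible(x)
}

#' Predict genotypic values from a fitted ridge-BLUP model
#'
#' @param object A `"ridge_blup"` fit.
#' @param markers Marker matrix or tibble for new genotypes; marker ids
#'   must match the training set.
#' @param ... Unused.
#' @return Named numeric vector: overall mean plus marker codes times
#'   estimated effects.
#' @export
predict.ridge_blup <- function(object, markers, ...) {
  Z <- impute_markers(marker_matrix(markers))
  miss <- setdiff(object$marker_ids, colnames(Z))
  if (length(miss) > 0) {
    abort(paste0("New data is missing ", length(miss), " training marker(s): ",
                 paste(utils::head(miss, 5), collapse = ", ")))
  }
  Z <- Z[, object$marker_ids, drop = FALSE]
  stats::setNames(object$mean + as.vector(Z %*% object$effects), rownames(Z))
}

#' Per-marker effect estimates
#' @param x A `"ridge_blup"` fit.
#' @param ... Unused.
#' @return Tibble with `marker` and `effect`.
#' @exportS3Method generics::tidy
tidy.ridge_blup <- function(x, ...) {
  tibble(marker = x$marker_ids, effect = unname(x$effects))
}

#' One-row model summary
#' @param x A `"ridge_blup"` fit.
#' @param ... Unused.
#' @return Tibble with the mean, variance components, lambda and REML
#'   log-likelihood.
#' @exportS3Method generics::glance
glance.ridge_blup <- function(x, ...) {
  tibble(mean = x$mean, lambda = x$lambda, sigma2_u = x$sigma2_u,
         sigma2_e = x$sigma2_e, loglik = x$loglik,
         n_genotypes = x$n, n_markers = length(x$effects))
}
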