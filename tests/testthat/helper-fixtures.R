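# Build a long phenotype tibble from a genotype x environment matrix.
toy_pheno <- function(values, genotypes = NULL, environments = NULL) {
  g <- nrow(values); e <- ncol(values)
  if (is.null(genotypes)) genotypes <- paste0("g", seq_len(g))
  if (is.null(environments)) environments <- paste0("E", seq_len(e))
  tibble::tibble(
    genotype = rep(genotypes, times = e),
    environment = rep(environments, each = g),
    value = as.vector(values)
  )
}

# Independent per-genotype OLS via explicit normal equations (oracle).
oracle_ols <- function(y, x) {
  X <- cbind(1, x)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# Naive REML evaluation by direct determinants and inversion (oracle for the
# eigendecomposition-based profile): profiled restricted log-likelihood of
# y = 1 m + Z u + e at variance ratio lambda.
oracle_reml <- function(Z, y, lambda) {
  n <- nrow(Z)
  X <- matrix(1, n, 1)
  H <- tcrossprod(Z) + lambda * diag(n)
  Hi <- solve(H)
  XtHiX <- t(X) %*% Hi %*% X
  b <- solve(XtHiX, t(X) %*% Hi %*% y)
  r <- y - X %*% b
  m <- n - 1
  s2 <- as.numeric(t(r) %*% Hi %*% r) / m
  as.numeric(-0.5 * (m * log(2 * pi) + m * log(s2) +
                       determinant(H)$modulus + determinant(XtHiX)$modulus -
                       log(n) + m))
}

# Independent day-length oracle: CBM model of Forsythe et al. (1995),
# a different derivation from the package's fractional-year series.
oracle_day_length <- function(latitude, date) {
  J <- as.integer(strftime(as.Date(date), "%j"))
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (J - 186)))
  phi <- asin(0.39795 * cos(theta))
  p <- 0.8333
  L <- latitude * pi / 180
  a <- (sin(p * pi / 180) + sin(L) * sin(phi)) / (cos(L) * cos(phi))
  a <- pmin(pmax(a, -1), 1)
  24 - (24 / pi) * acos(a)
}

# Constant-temperature weather covering the given date span for one site.
constant_weather <- function(site = "S", from, to, tmax, tmin) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  tibble::tibble(site = site, date = dates, tmax = tmax, tmin = tmin)
}
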