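test_that("environment means center correctly", {
  # constant data: centered index all zero, grand mean = the constant
  ph <- toy_pheno(matrix(7, nrow = 3, ncol = 4))
  em <- environment_means(ph)
  expect_equal(em$index, rep(0, 4))
  expect_equal(attr(em, "grand_mean"), 7)

  # hand arithmetic: 2 genotypes x 3 environments
  ph2 <- toy_pheno(matrix(c(1, 3, 2, 4, 3, 5), nrow = 2))
  em2 <- environment_means(ph2)
  expect_equal(em2$mean, c(2, 3, 4))
  expect_equal(attr(em2, "grand_mean"), 3)
  expect_equal(em2$index, c(-1, 0, 1))

  expect_error(environment_means(ph2, character(0)), "non-empty")
  expect_error(environment_means(ph2, c("E1", "nope")), "nope")
})

test_that("joint regression matches hand OLS and recovers noiseless truth", {
  # designed so environment means are (2,3,4): index (-1,0,1);
  # genotype A = (10,12,17) has OLS slope 3.5, intercept 13
  A <- c(10, 12, 17); B <- c(-6, -6, -9)
  ph <- toy_pheno(rbind(A, B), genotypes = c("A", "B"))
  fit <- fit_joint_regression(ph)
  pa <- tidy(fit)
  expect_equal(pa$slope[pa$genotype == "A"], 3.5)
  expect_equal(pa$intercept[pa$genotype == "A"], 13)

  # noise-free linear model is recovered to machine precision
  set.seed(42)
  g <- 20; e <- 6
  mu <- rnorm(g, 100, 10); beta <- rnorm(g, 1, 0.2)
  I <- seq(-5, 5, length.out = e)
  Y <- outer(mu, rep(1, e)) + outer(beta, I)
  fit2 <- fit_joint_regression(toy_pheno(Y))
  pa2 <- tidy(fit2)
  # the estimated index is an affine transform of the true gradient, so the
  # noiseless fit reproduces mu exactly and beta up to the (unit) scale
  expect_equal(pa2$intercept, mu, tolerance = 1e-10)
  expect_equal(stats::cor(pa2$slope, beta), 1, tolerance = 1e-12)
})

test_that("population mean slope is 1 and mean intercept is the grand mean", {
  set.seed(7)
  for (rep in 1:3) {
    Y <- matrix(rnorm(30 * 5, 50, 8), nrow = 30)
    fit <- fit_joint_regression(toy_pheno(Y))
    gl <- glance(fit)
    expect_equal(gl$mean_slope, 1, tolerance = 1e-8)
    expect_equal(gl$mean_intercept, gl$grand_mean, tolerance = 1e-8)
  }
})

test_that("joint regression agrees with a brute-force normal-equations oracle", {
  set.seed(11)
  for (rep in 1:5) {
    Y <- matrix(rnorm(25, 10, 3), nrow = 5)
    ph <- toy_pheno(Y)
    em <- environment_means(ph)
    fit <- tidy(fit_joint_regression(ph))
    for (i in 1:5) {
      cf <- oracle_ols(Y[i, ], em$index)
      expect_equal(fit$intercept[i], cf[1], tolerance = 1e-10)
      expect_equal(fit$slope[i], cf[2], tolerance = 1e-10)
    }
  }
})

test_that("residuals are orthogonal to the index and sum to zero per genotype", {
  set.seed(3)
  Y <- matrix(rnorm(8 * 6, 20, 4), nrow = 8)
  fit <- fit_joint_regression(toy_pheno(Y))
  res <- residuals(fit)
  I <- stats::setNames(fit$env_means$index, fit$env_means$environment)
  by_g <- split(res, res$genotype)
  for (d in by_g) {
    expect_equal(sum(d$residual), 0, tolerance = 1e-9)
    expect_equal(sum(d$residual * I[d$environment]), 0, tolerance = 1e-8)
  }
})

test_that("location and scale transforms act on intercepts only as expected", {
  set.seed(5)
  Y <- matrix(rnorm(12 * 4, 30, 5), nrow = 12)
  base <- tidy(fit_joint_regression(toy_pheno(Y)))
  shifted <- tidy(fit_joint_regression(toy_pheno(Y + 11)))
  expect_equal(shifted$intercept, base$intercept + 11, tolerance = 1e-9)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-9)
  scaled <- tidy(fit_joint_regression(toy_pheno(Y * 2.5)))
  expect_equal(scaled$intercept, base$intercept * 2.5, tolerance = 1e-9)
  expect_equal(scaled$slope, base$slope, tolerance = 1e-9)
})

test_that("two-environment rule gives averages and index-standardized differences", {
  # env means (-2, 2) by construction; g1 = (10, 14) -> intercept 12, slope 1
  ph <- toy_pheno(rbind(c(10, 14), c(-14, -10)), genotypes = c("g1", "g2"))
  fit <- two_env_parameters(ph, c("E1", "E2"))
  pa <- tidy(fit)
  expect_equal(pa$intercept[pa$genotype == "g1"], 12)
  expect_equal(pa$slope[pa$genotype == "g1"], 1)

  # flat genotype among varying ones: intercept = level, slope = 0
  ph2 <- toy_pheno(rbind(c(5, 5), c(0, 10)), genotypes = c("flat", "steep"))
  pa2 <- tidy(two_env_parameters(ph2, c("E1", "E2")))
  expect_equal(pa2$intercept[pa2$genotype == "flat"], 5)
  expect_equal(pa2$slope[pa2$genotype == "flat"], 0)

  # slopes are a positive rescaling of raw differences: correlation exactly 1
  set.seed(9)
  Y <- matrix(rnorm(40, 50, 6), nrow = 20)
  Y[, 2] <- Y[, 2] + 5 # separate the environment means
  ph3 <- toy_pheno(Y)
  pa3 <- tidy(two_env_parameters(ph3, c("E1", "E2")))
  em3 <- environment_means(ph3)
  ord <- order(em3$index)
  diffs <- Y[, ord[2]] - Y[, ord[1]]
  expect_equal(stats::cor(pa3$slope, diffs), 1, tolerance = 1e-12)

  # equal environment means make the pair singular
  ph4 <- toy_pheno(rbind(c(1, 2), c(2, 1)))
  expect_error(two_env_parameters(ph4, c("E1", "E2")), "undefined|equal")
})

test_that("estimation handles missing cells and enforces minimum coverage", {
  set.seed(13)
  Y <- matrix(rnorm(6 * 5, 10, 2), nrow = 6)
  Y[1, c(1, 2, 3)] <- NA # only 2 environments left for g1
  expect_warning(fit <- fit_joint_regression(toy_pheno(Y)), "dropped")
  expect_false("g1" %in% tidy(fit)$genotype)
  expect_equal(nrow(tidy(fit)), 5)

  expect_error(fit_joint_regression(toy_pheno(Y[, 1:2])), "two_env_parameters")
})
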