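test_that("environment grids enumerate sites x years x daily dates", {
  # singleton
  g1 <- build_env_grid(tibble::tibble(site = "A", year = 2020,
                                      window_start = "2020-05-01",
                                      window_end = "2020-05-01"))
  expect_equal(nrow(g1), 1)

  # counts equal the product formula, cross-checked by brute force
  sw <- tibble::tibble(site = rep(c("A", "B"), each = 2),
                       year = c(2019, 2020, 2019, 2020),
                       window_start = paste0(c(2019, 2020, 2019, 2020), "-04-01"),
                       window_end = paste0(c(2019, 2020, 2019, 2020), "-04-10"))
  g <- build_env_grid(sw)
  expect_equal(nrow(g), 2 * 2 * 10)
  brute <- sum(vapply(seq_len(nrow(sw)), function(i) {
    length(seq(as.Date(sw$window_start[i]), as.Date(sw$window_end[i]), by = "day"))
  }, numeric(1)))
  expect_equal(nrow(g), brute)

  expect_error(build_env_grid(tibble::tibble(
    site = "A", year = 2020,
    window_start = "2020-05-10", window_end = "2020-05-01")), "ends before")
})

test_that("the sorghum-style and rice-style designs give 1428 and 1674 cells", {
  gs <- build_env_grid(sorghum_design())
  expect_equal(nrow(gs), 1428)
  expect_equal(length(unique(gs$site)), 4)
  # each site-set contributes 7 years x 51 daily dates
  expect_equal(as.vector(table(gs$site)), rep(7L * 51L, 4))
  # the winter window crosses the year boundary
  prw <- gs[gs$site == "PRW" & gs$year == 2010, ]
  expect_equal(range(prw$planting_date),
               as.Date(c("2010-12-01", "2011-01-20")))

  gr <- build_env_grid(rice_design())
  expect_equal(nrow(gr), 1674)
  expect_equal(as.vector(table(gr$site)), rep(3L * 93L, 6))
})

test_that("variance partitioning resolves pure-factor and toy designs", {
  # value depends only on site
  f <- data.frame(site = rep(c("a", "b", "c"), each = 4),
                  year = rep(2001:2004, 3))
  v <- rep(c(0, 5, 9), each = 4)
  p <- partition_variance(v, f, order = c("site", "year"))
  expect_equal(p$percent[p$term == "site"], 100)
  expect_equal(p$percent[p$term == "year"], 0)
  expect_equal(p$percent[p$term == "residual"], 0)

  # 2x2 balanced toy split by A
  p2 <- partition_variance(c(0, 0, 1, 1),
                           data.frame(A = c("a", "a", "b", "b"),
                                      B = c("x", "y", "x", "y")))
  expect_equal(p2$percent[p2$term == "A"], 100)
  expect_equal(p2$percent[p2$term == "B"], 0)
  expect_equal(sum(p2$percent), 100)
})

test_that("iid values attribute almost everything to the residual", {
  set.seed(71)
  n <- 1000
  f <- data.frame(site = sample(letters[1:4], n, TRUE),
                  year = sample(2001:2007, n, TRUE),
                  date = sample(1:50, n, TRUE))
  p <- partition_variance(rnorm(n), f)
  expect_true(all(p$percent[p$term != "residual"] < 5))
  expect_gt(p$percent[p$term == "residual"], 85)
  expect_equal(sum(p$percent), 100, tolerance = 1e-6)
})

test_that("partition percentages are affine-invariant and order-invariant when balanced", {
  set.seed(72)
  grid <- expand.grid(site = c("a", "b", "c"), year = 2001:2004, date = 1:5)
  v <- rnorm(nrow(grid)) + as.numeric(factor(grid$site)) * 2 +
    as.numeric(grid$year %% 3)
  p1 <- partition_variance(v, grid, order = c("site", "year", "date"))
  p2 <- partition_variance(3 * v - 40, grid, order = c("site", "year", "date"))
  expect_equal(p1$percent, p2$percent, tolerance = 1e-9)

  p3 <- partition_variance(v, grid, order = c("date", "year", "site"))
  for (tm in c("site", "year", "date")) {
    expect_equal(p1$percent[p1$term == tm], p3$percent[p3$term == tm],
                 tolerance = 1e-9)
  }

  # single-level factor contributes zero with a warning
  grid$const <- "only"
  expect_warning(
    p4 <- partition_variance(v, grid, order = c("const", "site")),
    "single level"
  )
  expect_equal(p4$percent[p4$term == "const"], 0)

  # constant values: all-zero partition
  p5 <- partition_variance(rep(2, 10),
                           data.frame(site = rep(c("a", "b"), 5)))
  expect_true(all(p5$percent == 0))
})

test_that("site distributions summarize and merge correctly", {
  envs <- tibble::tibble(site = rep(c("A", "B", "C"), each = 4),
                         value = c(1, 2, 3, 4, 1, 2, 3, 4, 5, 5, 5, 5))
  sd_ <- site_distributions(envs)
  a <- sd_$summary[sd_$summary$site == "A", ]
  b <- sd_$summary[sd_$summary$site == "B", ]
  expect_equal(a[, c("min", "max", "mean", "sd")], b[, c("min", "max", "mean", "sd")])
  expect_true(sd_$summary$degenerate[sd_$summary$site == "C"])
  expect_false("C" %in% sd_$density$site)

  merged <- site_distributions(envs, merge = list("A+B" = c("A", "B")))
  expect_equal(merged$summary$n[merged$summary$site == "A+B"], 8)
})

test_that("high-latitude sites show wider index spread than equatorial ones", {
  sites <- tibble::tibble(site = c("high", "low"), latitude = c(45, 5))
  sds <- vapply(1:5, function(s) {
    w <- simulate_weather(sites, 2014, seed = s)
    env <- tibble::tibble(environment = paste0("e", 1:20),
                          site = rep(c("high", "low"), each = 10),
                          planting_date = rep(as.Date("2014-04-15") + seq(0, 90, by = 10), 2))
    idx <- env_index_table(env, w, sites, 18, 43, family = "PTT")
    c(stats::sd(idx$value[idx$site == "high"]),
      stats::sd(idx$value[idx$site == "low"]))
  }, numeric(2))
  expect_gt(stats::median(sds[1, ]), stats::median(sds[2, ]))
})
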