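test_that("euclidean d follows the textbook geometry", {
  expect_equal(euclidean_d(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_d(c(1, 2, 2), c(0, 0, 0)), 3)
  expect_equal(euclidean_d(c(1, 1), c(1, 1)), 0)
  expect_error(euclidean_d(1:2, 1:3), "equal length")
  expect_error(euclidean_d(c(1, NA), c(1, 2)), "missing")
})

test_that("mean vectors are trait-wise and missingness-aware", {
  df <- data.frame(group = "K01",
                   stl = c(40, 50, NA),
                   mds = c(2L, 2L, 2L))
  df$`lps.sc` <- c(NA, NA, NA)
  tab <- build_table(df)
  m <- mean_vector(tab, "K01", traits = c("stl", "mds"))
  expect_equal(unname(m), c(45, 2), ignore_attr = TRUE)
  expect_equal(unname(attr(m, "n")), c(2L, 3L))
  expect_error(mean_vector(tab, "K01", traits = c("stl", "lps.sc")),
               "entirely missing in group K01")
  expect_error(mean_vector(tab, "K99", traits = "stl"), "not present")
})

test_that("bootstrap d is reproducible, positive, and covers the estimate", {
  set.seed(12)
  df <- data.frame(group = rep(c("K01", "K02"), each = 30L),
                   stl = c(rnorm(30, 52, 3), rnorm(30, 41, 3)))
  tab <- build_table(df)
  b1 <- bootstrap_d(tab, "K01", "K02", traits = "stl", seed = 4L)
  b2 <- bootstrap_d(tab, "K01", "K02", traits = "stl", seed = 4L)
  expect_identical(b1$values, b2$values)
  expect_length(b1$values, 99L)
  expect_gt(b1$sd, 0)
  d_obs <- euclidean_d(mean_vector(tab, "K01", "stl"),
                       mean_vector(tab, "K02", "stl"))
  expect_lt(abs(d_obs - b1$mean), 3 * b1$sd)

  # same specimens on both sides: d stays non-negative, near zero
  df2 <- df
  df2$group <- rep(c("K01", "K02"), 30L)
  df2$stl <- rep(rnorm(30, 45, 3), each = 2L)
  tabs <- build_table(df2)
  b0 <- bootstrap_d(tabs, "K01", "K02", traits = "stl", seed = 4L)
  expect_true(all(b0$values >= 0))
})

test_that("bootstrap replicates with an all-missing trait are redrawn", {
  df <- data.frame(group = rep(c("K01", "K02"), each = 4L),
                   stl = c(50, 51, 52, 53, 40, 41, 42, 43))
  df$`lps.sc` <- c(8, NA, NA, NA, 2, 2.5, 2.2, 2.1)
  tab <- build_table(df)
  msgs <- capture_messages(
    b <- bootstrap_d(tab, "K01", "K02", traits = c("stl", "lps.sc"),
                     B = 99L, seed = 2L))
  expect_gt(b$redraws, 0L)
  expect_match(paste(msgs, collapse = " "), "redrawn")
  expect_length(b$values, 99L)
})

test_that("permutation p hits the add-one floor for separated groups", {
  set.seed(13)
  df <- data.frame(group = rep(c("K01", "K02"), each = 25L),
                   stl = c(rnorm(25, 55, 2), rnorm(25, 40, 2)))
  tab <- build_table(df)
  pr <- permutation_d(tab, "K01", "K02", traits = "stl", seed = 6L)
  expect_equal(pr$p, 0.01)
  expect_identical(permutation_d(tab, "K01", "K02", traits = "stl",
                                 seed = 6L)$p, pr$p)
})

test_that("welch comparison matches the hand formulae", {
  x <- c(19.2, 20.1, 19.8)
  y <- c(26.5, 27.2, 26.9)
  res <- compare_divergence(x, y)
  oracle <- welch_oracle(x, y)
  expect_equal(res$t, oracle$t, tolerance = 1e-12)
  expect_equal(res$df, oracle$df, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)

  set.seed(14)
  a <- rnorm(99)
  b <- rnorm(99)
  res2 <- compare_divergence(a, b)
  expect_lte(res2$df, 196)
  expect_lt(abs(res2$t), 4)

  far <- compare_divergence(rnorm(99, 0, 1), rnorm(99, 50, 1))
  expect_lt(far$p, 1e-4)
})

test_that("the divergence fit bundles its pieces coherently", {
  set.seed(15)
  df <- data.frame(group = rep(c("K01", "K02"), each = 20L),
                   stl = c(rnorm(20, 52, 2), rnorm(20, 42, 2)),
                   mds = c(rbinom(20, 3, .9), rbinom(20, 3, .2)))
  tab <- build_table(df)
  fit <- divergence(tab, "K01", "K02", traits = c("stl", "mds"), seed = 8L)
  expect_s3_class(fit, "divergence")
  expect_equal(fit$d,
               euclidean_d(fit$mean_first, fit$mean_last))
  expect_equal(fit$alpha_family, 0.05 / 2)
  expect_equal(names(coef(fit)), c("stl", "mds"))
  expect_equal(attr(coef(fit), "d"), fit$d)

  drop <- divergence(tab, "K01", "K02", traits = c("stl", "mds"),
                     drop_traits = "stl", seed = 8L)
  expect_equal(drop$traits, "mds")
  expect_lt(drop$d, fit$d)

  expect_output(print(fit), "Multivariate divergence")
  expect_output(print(summary(fit)), "effect_size")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("trajectories enumerate every later sample against the first", {
  sim <- simulate_fossil_series(
    fossil_series_params(n_range = c(12L, 20L), miss_rate = 0), seed = 31L)
  traj <- divergence_trajectory(sim$table, B = 19L, seed = 5L)
  expect_equal(nrow(traj), 17L)
  expect_true(all(diff(traj$age_years) > 0))
  expect_equal(traj$generations, traj$age_years / 2)
  expect_equal(traj$group[1L], "K02")
})

test_that("monotone series yield rising divergence in expectation", {
  mean_d <- matrix(NA_real_, 20L, 5L)
  for (s in 1:20) {
    sim <- simulate_fossil_series(
      fossil_series_params(n_samples = 6L, n_range = c(20L, 30L),
                           miss_rate = 0), seed = 100L + s)
    tab <- sim$table
    mean_d[s, ] <- vapply(2:6, function(k)
      euclidean_d(mean_vector(tab, "K01"),
                  mean_vector(tab, sprintf("K%02d", k))), numeric(1L))
  }
  avg <- colMeans(mean_d)
  expect_true(all(diff(avg) > 0))
})

test_that("stationary series show no divergence trend", {
  tr <- default_fossil_trajectories()
  tr$end <- tr$start
  tr$shape <- "linear"
  params <- fossil_series_params(n_samples = 8L, n_range = c(25L, 35L),
                                 trajectories = tr, miss_rate = 0)
  sim <- simulate_fossil_series(params, seed = 41L)
  d_1k <- vapply(2:8, function(k)
    euclidean_d(mean_vector(sim$table, "K01"),
                mean_vector(sim$table, sprintf("K%02d", k))), numeric(1L))
  ages <- seq_len(7L)
  ci <- confint(lm(d_1k ~ ages))["ages", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_lt(max(d_1k), 3)
})

test_that("first overlap finds the earliest intersecting sample", {
  traj <- structure(
    data.frame(group = sprintf("K%02d", 2:6),
               age_years = c(1000, 2000, 3000, 4000, 5000),
               generations = c(500, 1000, 1500, 2000, 2500),
               d = c(2, 4, 7, 9, 10),
               boot_mean = c(2, 4, 7, 9, 10),
               boot_sd = c(.5, .5, .5, .5, .5)),
    first_group = "K01", traits = "stl",
    class = c("divergence_trajectory", "data.frame"))
  ref <- list(boot_mean = 8, boot_sd = 0.6)
  hit <- first_overlap_time(traj, ref)
  expect_equal(hit$age_years, 3000)
  expect_equal(hit$generations, 1500)
  expect_equal(hit$group, "K04")

  none <- first_overlap_time(traj, list(boot_mean = 50, boot_sd = 1))
  expect_true(is.na(none$age_years))

  # sd = 0 reference reduces to an interval-contains-point test
  point <- first_overlap_time(traj, list(boot_mean = 9.4, boot_sd = 0))
  expect_equal(point$age_years, 4000)

  # range criterion uses the point estimate against the reference range
  rng <- first_overlap_time(traj, list(boot_mean = 8, boot_sd = 1,
                                       values = c(6.8, 8, 9.5)),
                            criterion = "range")
  expect_equal(rng$age_years, 3000)
})

test_that("trait-mean correlations recover exact linear relations", {
  df <- data.frame(group = rep(sprintf("K%02d", 1:5), each = 3L))
  t_idx <- rep(1:5, each = 3L)
  df$stl <- 50 - 2 * t_idx            # decreasing
  df$mds <- rep(3:-1, each = 3L) + 4  # decreasing -> r = 1 with stl
  df$`lps.sc` <- 1 + 0.5 * t_idx      # increasing -> r = -1 with stl
  tab <- build_table(df)
  tc <- trait_mean_correlations(tab, traits = c("stl", "mds", "lps.sc"))
  expect_equal(unname(tc$r["stl", "mds"]), 1, tolerance = 1e-12)
  expect_equal(unname(tc$r["stl", "lps.sc"]), -1, tolerance = 1e-12)
  expect_equal(diag(tc$r), c(stl = 1, mds = 1, "lps.sc" = 1))
  expect_error(trait_mean_correlations(tab, ordered_groups = c("K01", "K02")),
               ">= 3")
})

test_that("the default series reduces traits in concert", {
  sim <- simulate_fossil_series(seed = 51L)
  tc <- trait_mean_correlations(sim$table)
  expect_equal(tc$n_pairs, 120L)
  expect_equal(dim(tc$r), c(16L, 16L))
  expect_true(isSymmetric(tc$r))
  expect_gt(tc$mean, 0)
})
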