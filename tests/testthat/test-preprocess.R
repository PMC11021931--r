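test_that("pooled z-scores match hand computation and spare mild extremes", {
  # mean 20.8, sd 44.27 -> z of 100 is 1.79, below the 3.5 threshold
  tab <- build_table(data.frame(group = "K01", stl = c(1, 1, 1, 1, 100)))
  rep_ <- suppressWarnings(detect_outliers(tab))
  expect_equal(nrow(rep_$flagged), 0L)
  z <- (100 - 20.8) / sd(c(1, 1, 1, 1, 100))
  expect_equal(z, 1.789, tolerance = 1e-3)
})

test_that("a gross injected value is flagged and masked", {
  set.seed(8)
  vals <- c(rnorm(200, mean = 10, sd = 1), 50)
  tab <- build_table(data.frame(group = "K01", stl = vals))
  rep_ <- suppressWarnings(detect_outliers(tab))
  expect_equal(rep_$flagged$code, "stl")
  expect_equal(rep_$flagged$value, 50)
  expect_gt(abs(rep_$flagged$z), 3.5)

  masked <- suppressMessages(apply_outlier_mask(tab, rep_))
  expect_equal(sum(is.na(masked$stl)), 1L)
  expect_true(is.na(masked$stl[201]))
  # all other cells untouched
  expect_identical(masked$stl[-201], tab$stl[-201])
  # idempotent under the same report
  again <- suppressMessages(apply_outlier_mask(masked, rep_))
  expect_identical(as.data.frame(again), as.data.frame(masked))
})

test_that("constant trait columns warn and yield no flags", {
  tab <- build_table(data.frame(group = "K01", stl = rep(5, 4)))
  w <- capture_warnings(rep_ <- detect_outliers(tab))
  expect_true(all(grepl("constant", w)))
  expect_true(any(grepl("stl", w)))
  expect_equal(nrow(rep_$flagged), 0L)
})

test_that("an empty report leaves the table untouched", {
  tab <- build_table(data.frame(group = "K01", stl = c(4, 5, 6)))
  rep_ <- suppressWarnings(detect_outliers(tab))
  expect_identical(as.data.frame(apply_outlier_mask(tab, rep_)),
                   as.data.frame(tab))
})

test_that("size-correction recovers an exact linear allometry", {
  set.seed(2)
  n <- 30L
  df <- data.frame(group = rep(c("K01", "K02"), each = n),
                   stl = runif(2 * n, 35, 60))
  offset <- ifelse(df$group == "K01", 2, 5)
  df$`lps.sc` <- 0.5 * df$stl + offset
  tab <- build_table(df)
  model <- suppressWarnings(suppressMessages(fit_size_correction(tab)))
  expect_equal(unname(coef(model)["lps.sc"]), 0.5, tolerance = 1e-8)

  corr <- size_correct(tab, model)
  # a trait that is exactly 0.5*stl + group offset corrects to offset + 0.5*Lbar
  expect_equal(corr$`lps.sc`,
               offset + 0.5 * model$stl_bar, tolerance = 1e-6)
  # residuals of the fitted model are zero for an exact fit
  expect_lt(max(abs(residuals(model, tab)[, "lps.sc"])), 1e-6)
})

test_that("size-correction slope is near zero when traits ignore size", {
  set.seed(4)
  n <- 250L
  df <- data.frame(group = rep(c("K01", "K02", "K03"), each = n),
                   stl = runif(3 * n, 35, 60))
  df$`lps.sc` <- rnorm(3 * n, mean = 6, sd = 1) +
    rep(c(0, 1, 2), each = n)
  tab <- build_table(df)
  model <- suppressMessages(fit_size_correction(tab))
  se_approx <- 1 / (sd(df$stl) * sqrt(3 * n))
  expect_lt(abs(unname(coef(model)["lps.sc"])), 3 * se_approx)
})

test_that("size-correction preconditions are enforced", {
  tab <- build_table(data.frame(group = "K01", stl = c(40, 45, 50)))
  expect_error(fit_size_correction(tab), "grouping required")
  tab2 <- build_table(data.frame(group = rep(c("K01", "K02"), each = 3L),
                                 stl = rep(40, 6)))
  expect_error(fit_size_correction(tab2), "singular")
  mixed <- rbind(as.data.frame(build_table(
    data.frame(group = "K01", stl = c(40, 45)))), local({
      d <- as.data.frame(build_table(
        data.frame(group = "enos.benthic", stl = c(40, 45)), "extant"))
      d$specimen_id <- paste0("E", d$specimen_id)
      d
    }))
  expect_error(fit_size_correction(specimen_table(mixed)), "separately")
})

test_that("correction arithmetic follows observed - b*(stl - Lbar)", {
  model <- structure(list(
    slopes = c("lps.sc" = 0.3), intercepts = list("lps.sc" = c(K01 = 0)),
    stl_bar = 45, grouping = "group", dataset = "fossil",
    traits = "lps.sc", method = c("lps.sc" = "ols"),
    n_used = c("lps.sc" = 2L)), class = "size_correction")
  tab <- build_table(data.frame(group = "K01", stl = c(40, 50, NA),
                                `lps.sc` = c(6, 6, 6), check.names = FALSE))
  corr <- size_correct(tab, model)
  # equal traits, stl 10 apart, b = 0.3: corrected values differ by -3
  expect_equal(corr$`lps.sc`[2] - corr$`lps.sc`[1], -3)
  # missing stl propagates to the corrected value
  expect_true(is.na(corr$`lps.sc`[3]))

  # b = 0 is the identity wherever standard length is observed
  model$slopes[["lps.sc"]] <- 0
  corr0 <- size_correct(tab, model)
  expect_identical(corr0$`lps.sc`[1:2], tab$`lps.sc`[1:2])
  expect_true(is.na(corr0$`lps.sc`[3]))
})

test_that("group means are preserved when a group sits at mean size", {
  set.seed(6)
  stl1 <- c(40, 45, 50)            # mean 45
  stl2 <- c(38, 45, 52)            # mean 45 -> grand mean 45
  df <- data.frame(group = rep(c("K01", "K02"), each = 3L),
                   stl = c(stl1, stl2))
  df$`lps.sc` <- 0.4 * df$stl + rep(c(1, 3), each = 3L) + rnorm(6, 0, .1)
  tab <- build_table(df)
  model <- suppressWarnings(suppressMessages(fit_size_correction(tab)))
  corr <- size_correct(tab, model)
  for (g in c("K01", "K02"))
    expect_equal(mean(corr$`lps.sc`[corr$group == g]),
                 mean(tab$`lps.sc`[tab$group == g]), tolerance = 1e-10)
})
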