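test_that("fossil series generator honours the sampling design", {
  sim <- simulate_fossil_series(seed = 11L)
  tab <- sim$table
  sizes <- table(tab$group)
  expect_equal(length(sizes), 18L)
  expect_true(all(sizes >= 12L & sizes <= 67L))
  ages <- unique(as.data.frame(tab)[, c("sample_order", "age_years")])
  ages <- ages[order(ages$sample_order), ]
  expect_equal(ages$age_years[1], 0)
  expect_equal(max(ages$age_years), 16363)
  expect_true(all(diff(ages$age_years) > 0))
  expect_equal(dim(sim$truth$true_means), c(18L, 16L))
  expect_gt(sim$truth$true_d, 0)

  again <- simulate_fossil_series(seed = 11L)
  expect_identical(as.data.frame(again$table), as.data.frame(tab))
  expect_identical(again$truth$true_d, sim$truth$true_d)
})

test_that("noise-free generation reproduces the true trajectory means", {
  sim <- simulate_fossil_series(noise_free_params(), seed = 5L)
  tab <- sim$table
  reg <- default_registry()
  cont <- reg$code[reg$kind == "continuous"]
  cnt <- reg$code[reg$kind == "count"]
  for (g in rownames(sim$truth$true_means)) {
    m <- mean_vector(tab, g)
    # continuous values are emitted at 6-decimal measurement precision
    expect_lt(max(abs(m[cont] - sim$truth$true_means[g, cont])), 5e-7)
    expect_equal(unname(m[cnt]),
                 unname(round(sim$truth$true_means[g, cnt])),
                 tolerance = 1e-12)
  }
})

test_that("plateau trajectories reject inverted endpoints", {
  tr <- default_fossil_trajectories()
  tr$end[tr$code == "mds"] <- 5  # above start and above the trait ceiling
  expect_error(fossil_series_params(trajectories = tr),
               "inadmissible trajectory")
})

test_that("species-pair generator honours its design and null case", {
  sim <- simulate_species_pairs(seed = 21L)
  tab <- sim$table
  sizes <- table(tab$group)
  expect_equal(length(sizes), 10L)
  expect_true(all(sizes >= 22L & sizes <= 69L))
  expect_setequal(unique(sub("\\..*$", "", tab$group)),
                  c("little_quarry", "enos", "paxton", "priest", "emily"))
  expect_true(all(sim$truth$true_d > 7 & sim$truth$true_d < 28))

  null_sim <- simulate_species_pairs(pair_lakes_params(offset_scale = 0),
                                     seed = 21L)
  expect_true(all(null_sim$truth$true_d == 0))
})

test_that("realized pair divergence grows with the offset scale", {
  mean_d <- function(scale) {
    vals <- vapply(1:20, function(s) {
      sim <- simulate_species_pairs(
        pair_lakes_params(offset_scale = scale, miss_rate = 0), seed = s)
      euclidean_d(mean_vector(sim$table, "enos.benthic"),
                  mean_vector(sim$table, "enos.limnetic"))
    }, numeric(1L))
    mean(vals)
  }
  d_low <- mean_d(0.25)
  d_mid <- mean_d(0.75)
  d_high <- mean_d(1.25)
  expect_lt(d_low, d_mid)
  expect_lt(d_mid, d_high)
})

test_that("armour scenario is perfectly associated at rate 0", {
  tab <- simulate_armour_sample(armour_scenario_params(63L, 7L, 0), seed = 3L)
  ct <- dichotomize_armour(tab)
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(7L, 0L, 0L, 63L))
  again <- simulate_armour_sample(armour_scenario_params(63L, 7L, 0),
                                  seed = 3L)
  expect_identical(as.data.frame(again), as.data.frame(tab))
})

test_that("full hybridization yields a calibrated association screen", {
  # with pelvis and spines decoupled, a large balanced sample should reject
  # at close to the nominal rate (exact-test discreteness keeps it at or
  # slightly below 0.05)
  rejections <- vapply(1:1000, function(s) {
    tab <- simulate_armour_sample(armour_scenario_params(100L, 100L, 1),
                                  seed = s)
    suppressWarnings(
      fisher_exact_2x2(dichotomize_armour(tab))$p_two_sided) <= 0.05
  }, logical(1L))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("degenerate armour scenarios stay usable downstream", {
  tab <- simulate_armour_sample(armour_scenario_params(10L, 0L, 0), seed = 1L)
  ct <- dichotomize_armour(tab)
  expect_equal(ct$a + ct$b, 0L)
  expect_warning(res <- fisher_exact_2x2(ct), "margin")
  expect_equal(res$p_two_sided, 1)
  expect_error(armour_scenario_params(2L, 1L), ">= 4")
})
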