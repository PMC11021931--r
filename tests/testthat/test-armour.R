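test_that("armour dichotomy splits on pelvic score exactly 3 and 3 spines", {
  # 7 fully armoured, one reduced-pelvis fish carrying 3 spines (score 2.6),
  # 62 typical low-armour fish, plus one unscored specimen
  tab <- armour_specimens(
    pelvic = c(rep(3, 7), 2.6, rep(c(0, 0.5, 1), length.out = 62), NA),
    spines = c(rep(3L, 7), 3L, rep(c(0L, 1L), length.out = 62), 2L))
  expect_message(ct <- dichotomize_armour(tab), "1 specimen")
  expect_equal(ct$a, 7L)
  expect_equal(ct$b, 0L)
  expect_equal(ct$c, 1L)   # pelvic 2.6 is a reduced pelvis
  expect_equal(ct$d, 62L)
  expect_equal(ct$n, 70L)
})

test_that("the published perfectly associated tables give vanishing p", {
  res_d4 <- fisher_exact_2x2(armour_table(7, 0, 0, 63))
  expect_equal(res_d4$p_two_sided, 1 / choose(70, 7), tolerance = 1e-12)
  expect_lt(res_d4$p_two_sided, 1e-4)
  expect_identical(res_d4$odds_ratio, Inf)

  res_l <- fisher_exact_2x2(armour_table(26, 0, 0, 40))
  expect_equal(res_l$p_two_sided, 1 / choose(66, 26), tolerance = 1e-12)
  expect_lt(res_l$p_two_sided, 1e-17)
})

test_that("a balanced table carries no evidence of association", {
  expect_equal(fisher_exact_2x2(armour_table(5, 5, 5, 5))$p_two_sided, 1)
})

test_that("fisher p agrees with hypergeometric enumeration on random tables", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:40, 1L)
    cells <- as.vector(stats::rmultinom(1L, n, prob = runif(4, .1, 1)))
    if (any(rowSums(matrix(cells, 2, byrow = TRUE)) == 0) ||
        any(colSums(matrix(cells, 2, byrow = TRUE)) == 0)) next
    res <- fisher_exact_2x2(armour_table(cells[1], cells[2],
                                         cells[3], cells[4]))
    expect_equal(res$p_two_sided,
                 fisher_enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("fisher p is invariant to row and column swaps", {
  p0 <- fisher_exact_2x2(armour_table(9, 2, 3, 14))$p_two_sided
  expect_equal(fisher_exact_2x2(armour_table(3, 14, 9, 2))$p_two_sided, p0)
  expect_equal(fisher_exact_2x2(armour_table(2, 9, 14, 3))$p_two_sided, p0)
})

test_that("weakening a perfect association increases p", {
  p_perfect <- fisher_exact_2x2(armour_table(7, 0, 0, 63))$p_two_sided
  p_weaker <- fisher_exact_2x2(armour_table(6, 1, 1, 62))$p_two_sided
  expect_gt(p_weaker, p_perfect)
})

test_that("mixed-phenotype frequencies reproduce simple proportions", {
  # 441 scored specimens: 14 full-pelvis/low-spine, 2 high-spine/reduced
  tab <- armour_specimens(
    pelvic = c(rep(3, 14), rep(1, 2), rep(0, 425)),
    spines = c(rep(1L, 14), rep(3L, 2), rep(0L, 425)))
  fr <- mixed_armour_frequencies(tab)
  expect_equal(fr$n, 441L)
  expect_equal(fr$prop_full_pelvis_reduced_spines, 14 / 441)
  expect_equal(round(100 * fr$prop_full_pelvis_reduced_spines, 1), 3.2)
  expect_equal(fr$prop_three_spines_reduced_pelvis, 2 / 441)
  expect_lt(100 * fr$prop_three_spines_reduced_pelvis, 1)

  none <- armour_specimens(pelvic = c(3, 3, 0, 0),
                           spines = c(3L, 3L, 0L, 0L))
  expect_equal(mixed_armour_frequencies(none)$prop_full_pelvis_reduced_spines,
               0)
})
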