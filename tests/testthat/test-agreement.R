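test_that("crosstab counts pairs with rows = bruise b, columns = bruise a", {
  tab <- crosstab(c("x", "y", "x", "x"), c("y", "y", "x", "x"), c("x", "y"))
  expect_equal(unname(tab), matrix(c(2L, 1L, 0L, 1L), nrow = 2))
  expect_equal(sum(tab), 4)
  expect_error(crosstab("z", "x", c("x", "y")), "unknown category.*z")
  expect_error(crosstab(character(0), character(0), "x"), "n = 0")
})

test_that("percent agreement is the diagonal proportion", {
  expect_equal(percent_agreement(diag(4) * 3), 1)
  expect_equal(percent_agreement(matrix(c(0, 2, 2, 0), 2)), 0)
  expect_equal(percent_agreement(published_age_crosstab()), 39 / 81)
  expect_error(percent_agreement(matrix(0, 2, 2)), "n = 0")
})

test_that("kappa matches hand-computed and degenerate/perfect edge cases", {
  # hand-computed 2x2: p_o = 0.7, p_e = 0.5, kappa = 0.4
  k <- cohen_kappa(matrix(c(20, 10, 5, 15), 2))
  expect_equal(k$p_observed, 0.7)
  expect_equal(k$p_expected, 0.5)
  expect_equal(k$kappa, 0.4)
  # perfect agreement over >= 2 occupied categories
  expect_equal(cohen_kappa(diag(3) * 7)$kappa, 1)
  # constant variable: all mass in one cell -> degenerate, not an exception
  d <- cohen_kappa(matrix(c(50, 0, 0, 0), 2))
  expect_true(d$degenerate)
  expect_equal(d$kappa, 0)
  expect_equal(d$label, "degenerate")
  expect_true(is.na(d$p_value))
})

test_that("kappa invariants: label permutation, zero at independence, CI width", {
  set.seed(402)
  for (rep in 1:20) {
    r <- sample(2:5, 1)
    tab <- random_table(r, sample(30:200, 1))
    if (sum(diag(tab)) == sum(tab) || cohen_kappa(tab)$degenerate) next
    k1 <- cohen_kappa(tab)$kappa
    perm <- sample(r)
    expect_equal(cohen_kappa(tab[perm, perm])$kappa, k1, tolerance = 1e-12)
    expect_equal(k1, brute_force_kappa(tab), tolerance = 1e-12)
  }
  # p_o == p_e gives kappa 0 (independence-proportional table)
  tab0 <- outer(c(20, 20), c(10, 30)) / 40
  expect_equal(cohen_kappa(tab0)$kappa, 0, tolerance = 1e-12)
  # CI narrows as n grows at fixed proportions
  base <- matrix(c(20, 10, 5, 15), 2)
  widths <- sapply(c(1, 4, 16), function(f) {
    k <- cohen_kappa(base * f); k$ci_upper - k$ci_lower
  })
  expect_true(all(diff(widths) < 0))
})

test_that("interpretation labels follow significance gate then Landis-Koch bands", {
  mk <- function(kappa, ci, p) {
    structure(list(kappa = kappa, ci_lower = ci[1], ci_upper = ci[2],
                   p_value = p, degenerate = FALSE), class = "kappa_result")
  }
  expect_equal(interpret(mk(0.24, c(0.08, 0.40), 0.0008)), "fair")
  expect_equal(interpret(mk(0.52, c(0.23, 0.80), 0.0034)), "moderate")
  expect_equal(interpret(mk(0.58, c(0.29, 0.88), 0.0037)), "moderate")
  expect_equal(interpret(mk(0.29, c(-0.18, 0.76), 0.1508)), "not_significant")
  expect_equal(interpret(mk(0.34, c(0.13, 0.54), 0.0012)), "fair")
  expect_equal(interpret(mk(0.15, c(0.02, 0.28), 0.01)), "slight")
  expect_equal(interpret(mk(0.9, c(0.7, 1.0), 1e-6)), "almost_perfect")
  expect_equal(interpret(mk(0.7, c(0.5, 0.9), 1e-4)), "substantial")
  # significant p but CI through zero is still not significant
  expect_equal(interpret(mk(0.49, c(-0.21, 1.19), 0.001)), "not_significant")
})

test_that("cohort-level agreement report has all rows and honest exclusions", {
  sim <- generate_cohort(simulation_config(n_pigs = 40, seed = 9,
                                           emission_noise = 0.4))
  cohort <- sim$cohort
  # drop bruise b of one pig: it must be excluded and named, not silently lost
  cohort <- cohort[!(cohort$pig_id == "P003" & cohort$bruise_label == "b"), ]
  fit <- bruise_agreement(cohort)
  expect_s3_class(fit, "bruise_agreement")
  expect_equal(fit$n_pigs, 39L)
  expect_equal(fit$excluded, "P003")
  expect_equal(nrow(fit$variables), 15L) # 14 histology rows + age category
  expect_true(all(c("age_category", "muscle_leukocytes_interstitial",
                    "muscle_leukocytes_intramuscular") %in%
                    fit$variables$variable))
  # marginals are the crosstab sums, always
  expect_equal(unname(colSums(fit$age_crosstab)), fit$age_marginals$count_a)
  expect_equal(unname(rowSums(fit$age_crosstab)), fit$age_marginals$count_b)
})

test_that("identical paired lesions give kappa 1 everywhere it is defined", {
  sim <- generate_cohort(simulation_config(n_pigs = 30, seed = 21,
                                           emission_noise = 0.5))
  a <- sim$cohort[sim$cohort$bruise_label == "a", ]
  b <- a; b$bruise_label <- "b"
  fit <- bruise_agreement(validate_bruise_table(rbind(a, b)))
  expect_equal(fit$percent_agreement, 1)
  for (kr in fit$results)
    if (!kr$degenerate) expect_equal(kr$kappa, 1)
})

test_that("independently drawn lesion pairs give kappa near zero at large n", {
  set.seed(77)
  sim <- generate_cohort(simulation_config(n_pigs = 2000, seed = 55,
                                           emission_noise = 0.6))
  a <- sim$cohort[sim$cohort$bruise_label == "a", ]
  b <- sim$cohort[sim$cohort$bruise_label == "b", ]
  # break the within-pig time link by permuting b across pigs
  b <- b[sample(nrow(b)), ]
  est_a <- estimate_age(a)$age_category
  est_b <- estimate_age(b)$age_category
  k <- cohen_kappa(crosstab(est_a, est_b, age_categories()))
  expect_lt(abs(k$kappa), 3 * k$se_estimate + 0.02)
})
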