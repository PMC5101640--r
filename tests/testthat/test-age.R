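test_that("score-to-interval lookup matches the calibration", {
  expect_equal(score_to_interval("neutrophil_subcutis", 1), c(1, 3))
  expect_equal(score_to_interval("neutrophil_subcutis", 2), c(1, 8))
  expect_equal(score_to_interval("neutrophil_subcutis", 3), c(4, 10))
  expect_equal(score_to_interval("macrophage_muscle", 1), c(2, 9))
  expect_equal(score_to_interval("macrophage_muscle", 2), c(2, 10))
  expect_equal(score_to_interval("macrophage_muscle", 3), c(4, 10))
  expect_null(score_to_interval("neutrophil_subcutis", 0))
  expect_null(score_to_interval("macrophage_muscle", 0))
  expect_error(score_to_interval("neutrophil_subcutis", 4), "0, 1, 2, 3")
  expect_error(score_to_interval("eosinophil", 1))
})

test_that("combination rules follow the evidence-combination scheme", {
  r <- combine_intervals(0, 0)
  expect_null(r$interval); expect_equal(r$category, "inconclusive")
  r <- combine_intervals(1, 3) # disjoint [1,3] vs [4,10]: higher score wins
  expect_equal(r$interval, c(4, 10))
  expect_equal(r$rule, "dominant_score")
  expect_equal(r$category, "over_4h")
  r <- combine_intervals(1, 1) # overlap -> narrowest consistent interval
  expect_equal(r$interval, c(2, 3))
  expect_equal(r$rule, "intersection")
  expect_equal(r$category, "under_4h")
  r <- combine_intervals(3, 0) # one zero: the other cell type alone
  expect_equal(r$interval, c(4, 10))
  expect_equal(r$rule, "single_cell_type")
})

test_that("every score pair matches the grid-membership oracle", {
  tab <- full_combination_table()
  expect_equal(nrow(tab), 16L)
  for (i in seq_len(16)) {
    o <- grid_combine(tab$n_score[i], tab$m_score[i])
    lab <- sprintf("(n=%d, m=%d)", tab$n_score[i], tab$m_score[i])
    if (is.null(o$interval)) {
      expect_true(is.na(tab$interval_lower_h[i]), info = lab)
    } else {
      expect_equal(c(tab$interval_lower_h[i], tab$interval_upper_h[i]),
                   o$interval, info = lab)
    }
    expect_equal(tab$age_category[i], o$category, info = lab)
    expect_equal(tab$combination_rule[i], o$rule, info = lab)
  }
})

test_that("structural properties hold over the full enumeration", {
  tab <- full_combination_table()
  expect_equal(sum(tab$age_category == "inconclusive"), 1L)
  # dominant_score fires only for the single disjoint pair (n=1, m=3)
  dom <- tab[tab$combination_rule == "dominant_score", ]
  expect_equal(nrow(dom), 1L)
  expect_equal(c(dom$n_score, dom$m_score), c(1L, 3L))
  # narrowing and containment when both pieces of evidence exist
  for (i in which(tab$combination_rule == "intersection")) {
    ni <- score_to_interval("neutrophil_subcutis", tab$n_score[i])
    mi <- score_to_interval("macrophage_muscle", tab$m_score[i])
    w <- tab$interval_upper_h[i] - tab$interval_lower_h[i]
    expect_lte(w, min(diff(ni), diff(mi)))
    inside <- function(iv) tab$interval_lower_h[i] >= iv[1] &&
      tab$interval_upper_h[i] <= iv[2]
    expect_true(inside(ni) || inside(mi))
  }
  # raising a score from 0 never flips over_4h to under_4h
  catm <- matrix(tab$age_category, nrow = 4) # n varies fastest
  for (n in 1:4) for (m in 1:4) {
    if (n > 1 && catm[1, m] == "over_4h") expect_false(catm[n, m] == "under_4h")
    if (m > 1 && catm[n, 1] == "over_4h") expect_false(catm[n, m] == "under_4h")
  }
})

test_that("equal nonzero scores with disjoint intervals are a contract error", {
  # every reachable tie is an overlap under the shipped calibration...
  ties <- subset(full_combination_table(), n_score == m_score & n_score > 0)
  expect_true(all(ties$combination_rule == "intersection"))
  # ...and a hypothetical disjoint tie refuses to guess
  local_mocked_bindings(
    score_to_interval = function(cell_type, score)
      if (startsWith(cell_type, "neutrophil")) c(1, 2) else c(5, 6),
    .package = "bruiseAge")
  expect_error(combine_intervals(2, 2), "disjoint")
})

test_that("categorize splits at the 4-hour boundary as documented", {
  expect_equal(categorize(NULL), "inconclusive")
  expect_equal(categorize(c(2, 3)), "under_4h")
  expect_equal(categorize(c(4, 10)), "over_4h")
  expect_equal(categorize(c(1, 8)), "overlapping_4h")
  expect_equal(categorize(c(2, 10)), "overlapping_4h")
})

test_that("estimate_age appends age columns driven only by the two key scores", {
  df <- rbind(
    make_bruise_row(bruise_label = "a", subcutis_neutrophils = 2L,
                    muscle_macrophages = 2L),
    make_bruise_row(bruise_label = "b", subcutis_neutrophils = 3L,
                    muscle_macrophages = 0L),
    make_bruise_row(bruise_label = "c", subcutis_neutrophils = 0L,
                    muscle_macrophages = 0L,
                    muscle_neutrophils = 0L,
                    muscle_leukocyte_localization = "not_applicable"))
  est <- estimate_age(df)
  expect_equal(est$interval_lower_h, c(2, 4, NA))
  expect_equal(est$interval_upper_h, c(8, 10, NA))
  expect_equal(est$age_category, c("overlapping_4h", "over_4h", "inconclusive"))
  expect_equal(est$combination_rule,
               c("intersection", "single_cell_type", "inconclusive"))
  # descriptive variables do not move the age call
  df2 <- df
  df2$dermis_hemorrhage <- "absent"
  df2$muscle_necrosis <- 3L
  expect_equal(estimate_age(df2)$age_category, est$age_category)
})
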