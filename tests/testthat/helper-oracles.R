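# Independent oracles used across the suite. These deliberately recompute
# quantities by a different route than the package (loops over defining sums,
# grid-based interval algebra, numerical integration) so agreement is
# evidence, not tautology.

# Cohen's kappa straight from the defining sums, cell by cell.
brute_force_kappa <- function(tab) {
  r <- nrow(tab)
  n <- 0
  for (i in 1:r) for (j in 1:r) n <- n + tab[i, j]
  po <- 0
  for (i in 1:r) po <- po + tab[i, i] / n
  pe <- 0
  for (i in 1:r) {
    row_i <- 0; col_i <- 0
    for (j in 1:r) { row_i <- row_i + tab[i, j]; col_i <- col_i + tab[j, i] }
    pe <- pe + (row_i / n) * (col_i / n)
  }
  (po - pe) / (1 - pe)
}

# Interval combination via membership on a half-hour grid instead of bound
# arithmetic. Returns list(interval or NULL, category, rule).
grid_combine <- function(n_score, m_score) {
  niv <- list(NULL, c(1, 3), c(1, 8), c(4, 10))[[n_score + 1]]
  miv <- list(NULL, c(2, 9), c(2, 10), c(4, 10))[[m_score + 1]]
  grid <- seq(0, 12, by = 0.5)
  memb <- function(iv) if (is.null(iv)) rep(FALSE, length(grid)) else
    grid >= iv[1] & grid <= iv[2]
  if (is.null(niv) && is.null(miv))
    return(list(interval = NULL, category = "inconclusive", rule = "inconclusive"))
  if (is.null(niv) || is.null(miv)) {
    pts <- grid[memb(if (is.null(niv)) miv else niv)]
    rule <- "single_cell_type"
  } else {
    both <- memb(niv) & memb(miv)
    if (any(both)) {
      pts <- grid[both]; rule <- "intersection"
    } else {
      pts <- grid[memb(if (n_score > m_score) niv else miv)]
      rule <- "dominant_score"
    }
  }
  iv <- c(min(pts), max(pts))
  cat <- if (max(pts) < 4) "under_4h" else if (min(pts) >= 4) "over_4h" else "overlapping_4h"
  list(interval = iv, category = cat, rule = rule)
}

# Random square contingency table, r categories, total about n.
random_table <- function(r, n) {
  p <- stats::runif(r * r)
  matrix(stats::rmultinom(1, n, p / sum(p)), nrow = r)
}

# One fully valid bruise row as a data.frame; fields overridable.
make_bruise_row <- function(pig_id = "P1", bruise_label = "a", ...) {
  row <- list(
    pig_id = pig_id, bruise_label = bruise_label,
    dermis_hemorrhage = "present", dermis_hyperleukocytosis = "absent",
    dermis_leukocytes = "present",
    subcutis_hemorrhage = "present", subcutis_hyperleukocytosis = "absent",
    subcutis_neutrophils = 1L, subcutis_macrophages = 0L,
    muscle_hemorrhage = "present", muscle_hyperleukocytosis = "absent",
    muscle_necrosis = 1L, muscle_neutrophils = 1L, muscle_macrophages = 1L,
    muscle_leukocyte_localization = "interstitial", gross_pattern = ""
  )
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

# Analytic marginal over age categories: numerically integrate the emission
# model over the transport + lairage time distribution (density of the sum by
# discrete convolution of the two truncated-normal densities).
analytic_age_marginal <- function(noise, tm = list(transport_mean = 2.13,
                                                   transport_sd = 3.33,
                                                   lairage_mean = 3.03,
                                                   lairage_sd = 3.44)) {
  h <- 0.01
  grid <- seq(0, 40, by = h)
  dtn <- function(t, m, s) stats::dnorm(t, m, s) / stats::pnorm(m / s)
  f1 <- dtn(grid, tm$transport_mean, tm$transport_sd)
  f2 <- dtn(grid, tm$lairage_mean, tm$lairage_sd)
  fs <- stats::convolve(f1, rev(f2), type = "open") * h
  tgrid <- seq(0, by = h, length.out = length(fs))
  fs <- fs / (sum(fs) * h)
  lookup <- matrix(full_combination_table()$age_category, nrow = 4)
  out <- setNames(numeric(4), age_categories())
  for (i in seq_along(tgrid)) {
    em <- default_emission(tgrid[i], noise)
    pj <- outer(em$neutrophil, em$macrophage) # 4x4 over (n, m)
    for (cat in age_categories())
      out[cat] <- out[cat] + fs[i] * h * sum(pj[lookup == cat])
  }
  out / sum(out)
}
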