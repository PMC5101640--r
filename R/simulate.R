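#' Configuration for a synthetic bruise cohort
#'
#' Bundles the parameters of the cohort generator. Every bruise on a pig
#' shares one latent infliction-to-slaughter time t (bruises are inflicted
#' near-simultaneously); t is drawn as the sum of a transport and a lairage
#' component, each normal truncated at 0, with the defaults taken from the
#' herd-level logistics of Danish slaughter pigs (transport 2.13 +/- 3.33 h,
#' lairage 3.03 +/- 3.44 h). Scores are then emitted per bruise from
#' [default_emission()] at the configured noise.
#'
#' @param n_pigs number of pigs (default 81).
#' @param bruises_per_pig bruises sampled per pig (default 2, labelled
#'   "a", "b", ...).
#' @param emission_noise leak parameter in [0, 1): 0 gives deterministic
#'   scores, values near 1 approach a uniform score distribution. Default
#'   0.35, a regime with visible between-lesion disagreement.
#' @param time_model list with \code{transport_mean}, \code{transport_sd},
#'   \code{lairage_mean}, \code{lairage_sd} (hours).
#' @param seed integer seed; identical config and seed give an identical
#'   cohort.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_pigs = 81, bruises_per_pig = 2,
                              emission_noise = 0.35,
                              time_model = list(transport_mean = 2.13,
                                                transport_sd = 3.33,
                                                lairage_mean = 3.03,
                                                lairage_sd = 3.44),
                              seed = NULL) {
  stopifnot(n_pigs >= 1, bruises_per_pig >= 1,
            emission_noise >= 0, emission_noise < 1,
            all(c("transport_mean", "transport_sd",
                  "lairage_mean", "lairage_sd") %in% names(time_model)))
  structure(list(n_pigs = as.integer(n_pigs),
                 bruises_per_pig = as.integer(bruises_per_pig),
                 emission_noise = emission_noise,
                 time_model = time_model,
                 seed = seed),
            class = "simulation_config")
}

## normal truncated at 0, sampled by rejection (acceptance prob is ~0.7-0.8
## for the default parameters, so a few rounds suffice)
.rtnorm0 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

.draw_times <- function(n, tm) {
  .rtnorm0(n, tm$transport_mean, tm$transport_sd) +
    .rtnorm0(n, tm$lairage_mean, tm$lairage_sd)
}

## Modal (noiseless) score at time t: the lowest score whose calibrated age
## interval contains t; 0 before the first interval opens; 3 past 10 h.
.base_score <- function(t, cell_type) {
  tab <- if (cell_type == "neutrophil") .neutrophil_intervals else .macrophage_intervals
  lo <- vapply(tab[2:4], `[`, numeric(1), 1)
  hi <- vapply(tab[2:4], `[`, numeric(1), 2)
  vapply(t, function(ti) {
    hits <- which(lo <= ti & ti <= hi)
    if (length(hits)) hits[1]
    else if (ti > 10) 3L
    else 0L
  }, integer(1))
}

## Geometric leak around a base score: P(k) proportional to noise^|k - s|.
.leak_probs <- function(s, noise) {
  w <- noise^abs(0:3 - s)
  w / sum(w)
}

#' Score-emission distribution at a given lesion age
#'
#' The per-cell-type probability vector over scores 0--3 for a bruise of true
#' age \code{t} hours. At noise 0 all mass sits on the score whose calibrated
#' age interval contains t (ties broken toward the lower score); before any
#' interval opens the score is 0, and past 10 h it is 3. As \code{noise}
#' grows, mass leaks geometrically to neighbouring scores
#' (P(k) proportional to noise^|k - s|), reaching the uniform distribution in
#' the limit noise -> 1. This emission model is a documented stand-in: the
#' underlying study reports substantial between-lesion variation but no
#' distributional form.
#'
#' @param t true lesion age in hours (scalar, >= 0).
#' @param noise leak parameter in [0, 1).
#' @return List with components \code{neutrophil} and \code{macrophage}, each
#'   a probability vector of length 4 (scores 0--3) summing to 1.
#' @export
#' @examples
#' default_emission(2, noise = 0)    # both concentrate on score 1
#' default_emission(6, noise = 0.3)  # mass leaks to adjacent scores
default_emission <- function(t, noise = 0) {
  if (!(is.numeric(t) && length(t) == 1L && t >= 0))
    stop("t must be a single non-negative number of hours", call. = FALSE)
  stopifnot(noise >= 0, noise < 1)
  list(neutrophil = .leak_probs(.base_score(t, "neutrophil"), noise),
       macrophage = .leak_probs(.base_score(t, "macrophage"), noise))
}

## Vectorized sampler: one score per element of `base`, leak `noise`.
.emit_scores <- function(base, noise) {
  if (noise == 0) return(as.integer(base))
  u <- stats::runif(length(base))
  out <- integer(length(base))
  for (s in unique(base)) {
    idx <- base == s
    cp <- cumsum(.leak_probs(s, noise))
    out[idx] <- pmin(findInterval(u[idx], cp), 3L) # 0..3
  }
  out
}

## 4x4 lookup: category index by (n_score, m_score), from the combination
## rules themselves so the simulator can never drift from the estimator.
.category_lookup <- function() {
  tab <- full_combination_table()
  matrix(tab$age_category, nrow = 4, byrow = FALSE) # n_score varies fastest
}

#' Generate a synthetic bruise cohort with ground truth
#'
#' Draws one latent infliction time per pig, emits per-bruise scores for the
#' two age-determining cell types (subcutis neutrophils, muscle macrophages)
#' and the remaining histological variables from simple documented
#' conditionals on t, and returns a table that passes
#' [validate_bruise_table()]. Ancillary variables (hemorrhage,
#' hyper-leukocytosis, necrosis, localization, the non-age cell scores) exist
#' so agreement reports have every row; they never enter the age call.
#'
#' Ancillary model, given true age t: hemorrhage present with probability
#' 0.95/0.90/0.80 in dermis/subcutis/muscle; hyper-leukocytosis present with
#' probability plogis(t - 2) in each layer; dermis leukocyte infiltration
#' present with probability plogis(t - 3); necrosis score emitted around a
#' base of 0 (t < 1), 1 (t < 4), 2 (t < 8) or 3 with the same geometric leak;
#' localization is \code{not_applicable} when both muscle cell scores are 0,
#' otherwise interstitial with probability 0.7.
#'
#' @param config a [simulation_config()].
#' @return List with \code{cohort} (validated \code{bruise_cohort} data
#'   frame, \code{n_pigs * bruises_per_pig} rows) and \code{ground_truth}
#'   (data frame: pig_id, true_time_h, true_category — the noiseless category
#'   at that time).
#' @export
#' @examples
#' sim <- generate_cohort(simulation_config(n_pigs = 5, seed = 42))
#' table(sim$ground_truth$true_category)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_pigs; k <- config$bruises_per_pig
  noise <- config$emission_noise
  t_pig <- .draw_times(n, config$time_model)
  t_row <- rep(t_pig, each = k)
  pig_id <- sprintf("P%03d", rep(seq_len(n), each = k))
  bruise_label <- rep(letters[seq_len(k)], times = n)
  if (k > 26) bruise_label <- rep(sprintf("b%02d", seq_len(k)), times = n)

  nb <- .base_score(t_row, "neutrophil")
  mb <- .base_score(t_row, "macrophage")
  subcutis_neutrophils <- .emit_scores(nb, noise)
  muscle_macrophages <- .emit_scores(mb, noise)
  muscle_neutrophils <- .emit_scores(nb, noise)
  subcutis_macrophages <- .emit_scores(mb, noise)

  nr <- length(t_row)
  p_hl <- stats::plogis(t_row - 2)
  necrosis_base <- ifelse(t_row < 1, 0L, ifelse(t_row < 4, 1L, ifelse(t_row < 8, 2L, 3L)))
  muscle_necrosis <- .emit_scores(necrosis_base, noise)
  pres <- function(p) ifelse(stats::runif(nr) < p, "present", "absent")
  loc <- ifelse(muscle_neutrophils == 0 & muscle_macrophages == 0,
                "not_applicable",
                ifelse(stats::runif(nr) < 0.7, "interstitial", "intramuscular"))

  cohort <- data.frame(
    pig_id = pig_id,
    bruise_label = bruise_label,
    dermis_hemorrhage = pres(0.95),
    dermis_hyperleukocytosis = pres(p_hl),
    dermis_leukocytes = pres(stats::plogis(t_row - 3)),
    subcutis_hemorrhage = pres(0.90),
    subcutis_hyperleukocytosis = pres(p_hl),
    subcutis_neutrophils = subcutis_neutrophils,
    subcutis_macrophages = subcutis_macrophages,
    muscle_hemorrhage = pres(0.80),
    muscle_hyperleukocytosis = pres(p_hl),
    muscle_necrosis = muscle_necrosis,
    muscle_neutrophils = muscle_neutrophils,
    muscle_macrophages = muscle_macrophages,
    muscle_leukocyte_localization = loc,
    gross_pattern = "",
    stringsAsFactors = FALSE
  )
  lookup <- .category_lookup()
  truth <- data.frame(
    pig_id = sprintf("P%03d", seq_len(n)),
    true_time_h = t_pig,
    true_category = lookup[cbind(.base_score(t_pig, "neutrophil") + 1L,
                                 .base_score(t_pig, "macrophage") + 1L)],
    stringsAsFactors = FALSE
  )
  list(cohort = validate_bruise_table(cohort), ground_truth = truth)
}

## Fast path used by the Monte-Carlo routines: age categories only, one
## matrix of n_pigs x k category calls, no data-frame construction.
.sim_categories <- function(n_pigs, k, noise, time_model) {
  t_pig <- .draw_times(n_pigs, time_model)
  t_row <- rep(t_pig, each = k)
  ns <- .emit_scores(.base_score(t_row, "neutrophil"), noise)
  ms <- .emit_scores(.base_score(t_row, "macrophage"), noise)
  lookup <- .category_lookup()
  matrix(lookup[cbind(ns + 1L, ms + 1L)], nrow = n_pigs, ncol = k, byrow = TRUE)
}

## Mean age-category kappa over `reps` simulated 2-bruise cohorts.
## Degenerate cohorts (one occupied category) are dropped from the mean.
.mean_sim_kappa <- function(config, noise, reps) {
  ks <- vapply(seq_len(reps), function(i) {
    cats <- .sim_categories(config$n_pigs, 2L, noise, config$time_model)
    kr <- cohen_kappa(crosstab(cats[, 1], cats[, 2], .age_categories))
    if (kr$degenerate) NA_real_ else kr$kappa
  }, numeric(1))
  mean(ks, na.rm = TRUE)
}

#' Probability that k bruises from one pig agree on the age category
#'
#' Monte-Carlo estimate of the chance that all \code{k} sampled bruises of a
#' single pig fall in the same age category, under the configured time and
#' emission model. This is the quantity behind the sampling-design question
#' of how many lesions must be examined: with any emission noise it is
#' non-increasing in k.
#'
#' @param config a [simulation_config()] (its \code{bruises_per_pig} is
#'   ignored in favour of \code{k}; its \code{seed}, if set, seeds the
#'   simulation).
#' @param k number of bruises sampled per pig (>= 1).
#' @param reps Monte-Carlo replicates (>= 100).
#' @return List with \code{estimate}, \code{se} (binomial Monte-Carlo
#'   standard error), \code{k}, \code{reps}.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, emission_noise = 0.3)
#' consensus_probability(cfg, k = 2, reps = 1000)
consensus_probability <- function(config, k, reps = 10000) {
  stopifnot(inherits(config, "simulation_config"), k >= 1, reps >= 100)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (k == 1 || config$emission_noise == 0) {
    ## all bruises share t; noiseless emission is deterministic given t
    return(list(estimate = 1.0, se = 0.0, k = as.integer(k),
                reps = as.integer(reps)))
  }
  cats <- .sim_categories(as.integer(reps), as.integer(k),
                          config$emission_noise, config$time_model)
  agree <- rowSums(cats == cats[, 1]) == k
  p <- mean(agree)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), k = as.integer(k),
       reps = as.integer(reps))
}

#' Calibrate emission noise to a target between-lesion kappa
#'
#' Finds the emission-noise value at which simulated two-bruise cohorts of
#' \code{config$n_pigs} pigs have a mean age-category kappa equal to
#' \code{target_kappa}, by bisection on the noise -> kappa curve. The curve's
#' monotone decrease over the searched bracket is verified from the endpoint
#' and midpoint estimates before bisection starts, not assumed; a target
#' outside the achieved range raises an error reporting that range.
#'
#' @param config a [simulation_config()]; \code{seed}, if set, seeds the
#'   search.
#' @param target_kappa target in (0, 1).
#' @param reps simulated cohorts per noise evaluation (default 40).
#' @param bracket noise interval to search (default c(0.02, 0.9)).
#' @param tol bisection width at which to stop (default 0.005).
#' @return The calibrated noise (scalar), with attribute
#'   \code{achieved_kappa}.
#' @export
calibrate_noise_to_kappa <- function(config, target_kappa, reps = 40,
                                     bracket = c(0.02, 0.9), tol = 0.005) {
  stopifnot(inherits(config, "simulation_config"),
            target_kappa > 0, target_kappa < 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  lo <- bracket[1]; hi <- bracket[2]
  k_lo <- .mean_sim_kappa(config, lo, reps)
  k_hi <- .mean_sim_kappa(config, hi, reps)
  k_mid <- .mean_sim_kappa(config, (lo + hi) / 2, reps)
  mc_slack <- 0.08  # sampling spread of a mean kappa at modest reps
  if (!(k_lo >= k_mid - mc_slack && k_mid >= k_hi - mc_slack))
    stop("noise -> kappa curve is not monotone decreasing over the bracket (",
         sprintf("kappa at %.2f/%.2f/%.2f: %.3f/%.3f/%.3f",
                 lo, (lo + hi) / 2, hi, k_lo, k_mid, k_hi), ")", call. = FALSE)
  if (target_kappa > k_lo || target_kappa < k_hi)
    stop(sprintf(
      "target kappa %.3f outside achievable range [%.3f, %.3f] for noise in [%.2f, %.2f]",
      target_kappa, k_hi, k_lo, lo, hi), call. = FALSE)
  achieved <- NA_real_
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    achieved <- .mean_sim_kappa(config, mid, reps)
    if (achieved > target_kappa) lo <- mid else hi <- mid
  }
  out <- (lo + hi) / 2
  attr(out, "achieved_kappa") <- achieved
  out
}
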