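## Calibration of score -> age interval (hours post-infliction), from
## experimental porcine bruises: neutrophils scored in subcutis, macrophages
## in muscle. Score 0 carries no interval (inconclusive evidence).
.neutrophil_intervals <- list(NULL, c(1, 3), c(1, 8), c(4, 10))
.macrophage_intervals <- list(NULL, c(2, 9), c(2, 10), c(4, 10))

.age_categories <- c("inconclusive", "under_4h", "over_4h", "overlapping_4h")

#' Age categories for bruises
#'
#' The four mutually exclusive, exhaustive categories a bruise age call can
#' take: \code{inconclusive} (neither cell type infiltrating), \code{under_4h}
#' (interval entirely below 4 h), \code{over_4h} (lower bound at or above
#' 4 h), \code{overlapping_4h} (interval straddles 4 h, e.g. 1--8 h).
#'
#' @return Character vector of the four category names, in display order.
#' @export
age_categories <- function() .age_categories

#' Map a cell score to its age interval
#'
#' Looks up the calibrated age interval, in hours post-infliction, for a
#' semi-quantitative infiltration score. Neutrophils (subcutis): 1 maps to
#' 1--3 h, 2 to 1--8 h, 3 to 4--10 h. Macrophages (muscle): 1 maps to 2--9 h,
#' 2 to 2--10 h, 3 to 4--10 h. A score of 0 is inconclusive and yields no
#' interval.
#'
#' @param cell_type \code{"neutrophil_subcutis"} or \code{"macrophage_muscle"}.
#' @param score integer score in 0--3.
#' @return Numeric \code{c(lower, upper)} in hours, or \code{NULL} for score 0.
#' @export
#' @examples
#' score_to_interval("neutrophil_subcutis", 1)  # 1 3
#' score_to_interval("macrophage_muscle", 2)    # 2 10
#' score_to_interval("neutrophil_subcutis", 0)  # NULL
score_to_interval <- function(cell_type, score) {
  if (!(length(score) == 1L && .is_score(score)))
    stop("score must be a single integer in {0, 1, 2, 3}", call. = FALSE)
  score <- as.integer(score)
  tab <- switch(match.arg(cell_type, c("neutrophil_subcutis", "macrophage_muscle")),
                neutrophil_subcutis = .neutrophil_intervals,
                macrophage_muscle = .macrophage_intervals)
  if (score == 0L) NULL else tab[[score + 1L]]
}

#' Combine neutrophil and macrophage age evidence for one bruise
#'
#' Applies the combination rules to a subcutis neutrophil score and a muscle
#' macrophage score: if both are 0 the bruise is inconclusive; if exactly one
#' is 0 the other cell type's interval is used alone; if both intervals exist
#' and overlap, their intersection (the narrowest interval consistent with
#' both) is used; if they are disjoint, the interval of the strictly higher
#' score wins. A score tie with disjoint intervals is unreachable under the
#' shipped calibration and raises an error rather than guessing.
#'
#' @param n_score subcutis neutrophil score, 0--3.
#' @param m_score muscle macrophage score, 0--3.
#' @return An object of class \code{age_result}: a list with \code{interval}
#'   (numeric \code{c(lower, upper)} hours, or \code{NULL}), \code{category}
#'   (one of [age_categories()]), \code{rule} (one of \code{"inconclusive"},
#'   \code{"single_cell_type"}, \code{"intersection"},
#'   \code{"dominant_score"}) and the two scores with their intervals.
#' @export
#' @examples
#' combine_intervals(1, 3)  # disjoint -> macrophage interval 4-10 h
#' combine_intervals(1, 1)  # intersection -> 2-3 h
combine_intervals <- function(n_score, m_score) {
  ni <- score_to_interval("neutrophil_subcutis", n_score)
  mi <- score_to_interval("macrophage_muscle", m_score)
  n_score <- as.integer(n_score); m_score <- as.integer(m_score)
  if (is.null(ni) && is.null(mi)) {
    interval <- NULL; rule <- "inconclusive"
  } else if (is.null(ni) || is.null(mi)) {
    interval <- if (is.null(ni)) mi else ni
    rule <- "single_cell_type"
  } else {
    lo <- max(ni[1], mi[1]); hi <- min(ni[2], mi[2])
    if (lo <= hi) {
      interval <- c(lo, hi); rule <- "intersection"
    } else if (n_score == m_score) {
      stop("equal scores with disjoint age intervals: no combination rule is ",
           "defined (unreachable under the shipped calibration)", call. = FALSE)
    } else {
      interval <- if (n_score > m_score) ni else mi
      rule <- "dominant_score"
    }
  }
  structure(list(
    interval = interval,
    category = categorize(interval),
    rule = rule,
    n_score = n_score, n_interval = ni,
    m_score = m_score, m_interval = mi
  ), class = "age_result")
}

#' Assign an age interval to one of the four categories
#'
#' \code{NULL} is inconclusive; an interval with upper bound below 4 h is
#' \code{under_4h}; one with lower bound at or above 4 h is \code{over_4h};
#' anything else straddles 4 h and is \code{overlapping_4h}.
#'
#' @param interval numeric \code{c(lower, upper)} in hours, or \code{NULL}.
#' @return A single category name.
#' @export
#' @examples
#' categorize(c(1, 8))   # overlapping_4h
#' categorize(c(4, 10))  # over_4h
categorize <- function(interval) {
  if (is.null(interval)) return("inconclusive")
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  if (interval[2] < 4) "under_4h"
  else if (interval[1] >= 4) "over_4h"
  else "overlapping_4h"
}

#' Estimate the age of each bruise in a cohort
#'
#' Runs the combination rules over every row of a validated bruise table.
#' Only the subcutis neutrophil and muscle macrophage scores enter the age
#' call; all other histological variables are descriptive and feed the
#' agreement analysis only.
#'
#' @param x a \code{bruise_cohort} data frame (or anything
#'   [validate_bruise_table()] accepts), or a single-row data frame.
#' @return The input with four appended columns: \code{interval_lower_h},
#'   \code{interval_upper_h} (NA when inconclusive), \code{age_category},
#'   \code{combination_rule}.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_pigs = 3, seed = 1))$cohort
#' estimate_age(cohort)[, c("pig_id", "age_category")]
estimate_age <- function(x) {
  x <- validate_bruise_table(x)
  res <- lapply(seq_len(nrow(x)), function(i)
    combine_intervals(x$subcutis_neutrophils[i], x$muscle_macrophages[i]))
  x$interval_lower_h <- vapply(res, function(r)
    if (is.null(r$interval)) NA_real_ else r$interval[1], numeric(1))
  x$interval_upper_h <- vapply(res, function(r)
    if (is.null(r$interval)) NA_real_ else r$interval[2], numeric(1))
  x$age_category <- vapply(res, function(r) r$category, character(1))
  x$combination_rule <- vapply(res, function(r) r$rule, character(1))
  x
}

#' Exhaustive combination table over all score pairs
#'
#' Enumerates all 16 (neutrophil, macrophage) score pairs and the resulting
#' combined interval, category and rule. Serves as the authoritative oracle
#' surface for the combination logic: exactly one row is inconclusive and,
#' under the shipped calibration, the dominant-score rule fires only for the
#' single disjoint pair (neutrophil 1, macrophage 3).
#'
#' @return Data frame with 16 rows and columns \code{n_score}, \code{m_score},
#'   \code{interval_lower_h}, \code{interval_upper_h}, \code{age_category},
#'   \code{combination_rule}.
#' @export
full_combination_table <- function() {
  grid <- expand.grid(n_score = 0:3, m_score = 0:3)
  res <- Map(combine_intervals, grid$n_score, grid$m_score)
  data.frame(
    n_score = grid$n_score,
    m_score = grid$m_score,
    interval_lower_h = vapply(res, function(r)
      if (is.null(r$interval)) NA_real_ else r$interval[1], numeric(1)),
    interval_upper_h = vapply(res, function(r)
      if (is.null(r$interval)) NA_real_ else r$interval[2], numeric(1)),
    age_category = vapply(res, function(r) r$category, character(1)),
    combination_rule = vapply(res, function(r) r$rule, character(1))
  )
}

#' @export
print.age_result <- function(x, ...) {
  iv <- if (is.null(x$interval)) "none"
        else sprintf("[%g, %g] h", x$interval[1], x$interval[2])
  cat(sprintf("Bruise age: %s (%s; rule: %s)\n", iv, x$category, x$rule))
  cat(sprintf("  neutrophils (subcutis) score %d, macrophages (muscle) score %d\n",
              x$n_score, x$m_score))
  invisible(x)
}
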