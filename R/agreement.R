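#' Cross-tabulate paired categorical calls
#'
#' Builds the square contingency table of one call per pig on each of two
#' bruises. Rows index the second bruise (b), columns the first (a), both over
#' the same ordered category list, so the diagonal holds the agreeing pigs.
#'
#' @param call_a,call_b character vectors of equal length, one element per pig.
#' @param categories ordered character vector of permitted labels.
#' @return Integer matrix with \code{categories} as both dimnames
#'   (rows = bruise b, columns = bruise a).
#' @export
#' @examples
#' crosstab(c("x", "y", "x"), c("x", "y", "y"), c("x", "y"))
crosstab <- function(call_a, call_b, categories) {
  stopifnot(length(call_a) == length(call_b))
  if (length(call_a) == 0L) stop("no pairs to tabulate (n = 0)", call. = FALSE)
  unknown <- setdiff(unique(c(call_a, call_b)), categories)
  if (length(unknown))
    stop("unknown category label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  m <- table(factor(call_b, levels = categories),
             factor(call_a, levels = categories))
  m <- matrix(as.integer(m), nrow = length(categories),
              dimnames = list(b = categories, a = categories))
  m
}

#' Proportion of exact agreement in a contingency table
#'
#' @param tab square count matrix (rows = bruise b, columns = bruise a).
#' @return Proportion in [0, 1]: trace divided by total count.
#' @export
#' @examples
#' percent_agreement(diag(3) * 5)  # 1
percent_agreement <- function(tab) {
  tab <- .check_table(tab)
  sum(diag(tab)) / sum(tab)
}

.check_table <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("contingency table must be square", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency table must hold non-negative integer counts", call. = FALSE)
  if (sum(tab) == 0) stop("contingency table is empty (n = 0)", call. = FALSE)
  tab
}

#' Cohen's kappa with asymptotic confidence interval and one-sided test
#'
#' Unweighted chance-corrected agreement for a square contingency table of
#' paired calls, computed from the defining formulas. With observed agreement
#' p_o (the diagonal proportion) and chance agreement p_e (the product of the
#' marginal proportions, summed), kappa = (p_o - p_e) / (1 - p_e). The
#' confidence interval uses the large-sample standard error
#' sqrt(p_o (1 - p_o) / (n (1 - p_e)^2)) with a normal quantile; the test of
#' kappa = 0 uses the null-variance standard error and reports the one-sided
#' upper-tail p-value. Ordinal scores are treated as unweighted nominal
#' categories.
#'
#' Degenerate tables -- all mass in a single category on both margins, so
#' chance agreement is 1 and kappa is undefined -- are flagged with label
#' \code{"degenerate"} (kappa reported as 0, CI and p set to NA) instead of
#' raising, so that cohort-wide reports still render when a variable is
#' constant.
#'
#' @param tab square count matrix (rows = bruise b, columns = bruise a), e.g.
#'   from [crosstab()].
#' @param conf.level confidence level for the interval (default 0.95).
#' @param alpha significance level used by the interpretation label.
#' @return An object of class \code{kappa_result}: list with components
#'   \code{kappa}, \code{p_observed}, \code{p_expected}, \code{se_estimate},
#'   \code{se_null}, \code{ci_lower}, \code{ci_upper}, \code{z},
#'   \code{p_value}, \code{n}, \code{conf.level}, \code{degenerate},
#'   \code{label}. Methods: \code{print}, \code{summary}, \code{confint}.
#' @references Cohen J (1960) A coefficient of agreement for nominal scales.
#'   Educ Psychol Meas 20:37-46. Fleiss JL, Levin B, Paik MC (2003)
#'   Statistical Methods for Rates and Proportions, 3rd ed. Landis JR,
#'   Koch GG (1977) The measurement of observer agreement for categorical
#'   data. Biometrics 33:159-174.
#' @export
#' @examples
#' tab <- matrix(c(20, 10, 5, 15), 2)  # kappa = 0.4
#' cohen_kappa(tab)
cohen_kappa <- function(tab, conf.level = 0.95, alpha = 0.05) {
  tab <- .check_table(tab)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  r <- rowSums(tab) / n
  cc <- colSums(tab) / n
  pe <- sum(r * cc)
  degenerate <- (1 - pe) < sqrt(.Machine$double.eps)
  if (degenerate) {
    out <- list(kappa = 0, p_observed = po, p_expected = pe,
                se_estimate = NA_real_, se_null = NA_real_,
                ci_lower = NA_real_, ci_upper = NA_real_,
                z = NA_real_, p_value = NA_real_,
                n = n, conf.level = conf.level, degenerate = TRUE)
  } else {
    kappa <- (po - pe) / (1 - pe)
    se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
    zq <- stats::qnorm(1 - (1 - conf.level) / 2)
    se0 <- sqrt(pe + pe^2 - sum(r * cc * (r + cc))) / ((1 - pe) * sqrt(n))
    z <- kappa / se0
    out <- list(kappa = kappa, p_observed = po, p_expected = pe,
                se_estimate = se, se_null = se0,
                ci_lower = kappa - zq * se, ci_upper = kappa + zq * se,
                z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
                n = n, conf.level = conf.level, degenerate = FALSE)
  }
  out <- structure(out, class = "kappa_result")
  out$label <- interpret(out, alpha = alpha)
  out
}

#' Interpretation label for a kappa result
#'
#' Degenerate tables are labelled \code{"degenerate"}. A result whose
#' one-sided p-value is at or above \code{alpha}, or whose confidence interval
#' contains 0, is \code{"not_significant"}. Otherwise the point estimate is
#' banded on the Landis-Koch scale: (0, 0.20] slight, (0.20, 0.40] fair,
#' (0.40, 0.60] moderate, (0.60, 0.80] substantial, (0.80, 1] almost perfect.
#'
#' @param x a \code{kappa_result} from [cohen_kappa()].
#' @param alpha significance level (default 0.05).
#' @return A single label string.
#' @export
interpret <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "kappa_result"))
  if (isTRUE(x$degenerate)) return("degenerate")
  if (is.na(x$p_value) || x$p_value >= alpha) return("not_significant")
  if (!is.na(x$ci_lower) && x$ci_lower <= 0 && x$ci_upper >= 0)
    return("not_significant")
  k <- x$kappa
  if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost_perfect"
}

#' @export
print.kappa_result <- function(x, digits = 2, ...) {
  cat("Cohen's kappa (unweighted)\n")
  if (x$degenerate) {
    cat(sprintf("  degenerate table (chance agreement = 1), n = %d\n", x$n))
    return(invisible(x))
  }
  cat(sprintf("  kappa = %.*f, %d%% CI [%.*f, %.*f], n = %d\n",
              digits, x$kappa, round(100 * x$conf.level),
              digits, x$ci_lower, digits, x$ci_upper, x$n))
  cat(sprintf("  one-sided test of kappa = 0: z = %.3f, p = %.4f (%s)\n",
              x$z, x$p_value, gsub("_", " ", x$label)))
  invisible(x)
}

#' @export
summary.kappa_result <- function(object, ...) {
  cat(sprintf(
    "Observed agreement %.4f, chance agreement %.4f (n = %d)\n",
    object$p_observed, object$p_expected, object$n))
  print(object, digits = 4)
  invisible(object)
}

#' @export
confint.kappa_result <- function(object, parm, level, ...) {
  ci <- matrix(c(object$ci_lower, object$ci_upper), nrow = 1,
               dimnames = list("kappa",
                               sprintf("%g %%", 100 * c((1 - object$conf.level) / 2,
                                                        1 - (1 - object$conf.level) / 2))))
  ci
}

## Variables entering the per-variable agreement report, in display order.
## Localization is expanded into two binary indicators mirroring the two
## report rows; not_applicable counts as "no" for both.
.agreement_variables <- function() {
  list(
    list(name = "dermis_hyperleukocytosis", tissue = "dermis",
         extract = function(df) df$dermis_hyperleukocytosis,
         levels = c("present", "absent")),
    list(name = "dermis_leukocytes", tissue = "dermis",
         extract = function(df) df$dermis_leukocytes,
         levels = c("present", "absent")),
    list(name = "dermis_hemorrhage", tissue = "dermis",
         extract = function(df) df$dermis_hemorrhage,
         levels = c("present", "absent")),
    list(name = "subcutis_neutrophils", tissue = "subcutis",
         extract = function(df) as.character(df$subcutis_neutrophils),
         levels = as.character(0:3)),
    list(name = "subcutis_hyperleukocytosis", tissue = "subcutis",
         extract = function(df) df$subcutis_hyperleukocytosis,
         levels = c("present", "absent")),
    list(name = "subcutis_macrophages", tissue = "subcutis",
         extract = function(df) as.character(df$subcutis_macrophages),
         levels = as.character(0:3)),
    list(name = "subcutis_hemorrhage", tissue = "subcutis",
         extract = function(df) df$subcutis_hemorrhage,
         levels = c("present", "absent")),
    list(name = "muscle_necrosis", tissue = "muscle",
         extract = function(df) as.character(df$muscle_necrosis),
         levels = as.character(0:3)),
    list(name = "muscle_neutrophils", tissue = "muscle",
         extract = function(df) as.character(df$muscle_neutrophils),
         levels = as.character(0:3)),
    list(name = "muscle_macrophages", tissue = "muscle",
         extract = function(df) as.character(df$muscle_macrophages),
         levels = as.character(0:3)),
    list(name = "muscle_leukocytes_interstitial", tissue = "muscle",
         extract = function(df)
           ifelse(df$muscle_leukocyte_localization == "interstitial", "yes", "no"),
         levels = c("yes", "no")),
    list(name = "muscle_leukocytes_intramuscular", tissue = "muscle",
         extract = function(df)
           ifelse(df$muscle_leukocyte_localization == "intramuscular", "yes", "no"),
         levels = c("yes", "no")),
    list(name = "muscle_hyperleukocytosis", tissue = "muscle",
         extract = function(df) df$muscle_hyperleukocytosis,
         levels = c("present", "absent")),
    list(name = "muscle_hemorrhage", tissue = "muscle",
         extract = function(df) df$muscle_hemorrhage,
         levels = c("present", "absent")),
    list(name = "age_category", tissue = "age",
         extract = function(df) df$age_category,
         levels = .age_categories)
  )
}

#' Between-lesion agreement analysis for a bruise cohort
#'
#' The package's main analysis: for each histological variable and for the
#' four-way age category, cross-tabulates the calls on two named bruises from
#' every pig and computes unweighted Cohen's kappa with its confidence
#' interval, one-sided test and interpretation label. Pigs missing either of
#' the two named bruises are excluded and listed, never silently dropped.
#'
#' @param x a \code{bruise_cohort} data frame (age columns are added with
#'   [estimate_age()] if absent).
#' @param pair_labels length-2 character vector naming the two bruises to
#'   compare (default \code{c("a", "b")}).
#' @param conf.level,alpha passed to [cohen_kappa()].
#' @return An object of class \code{bruise_agreement}: list with
#'   \code{variables} (data frame: tissue, variable, kappa, ci_lower,
#'   ci_upper, label, p_value, n), \code{results} (named list of
#'   \code{kappa_result}s), \code{age_crosstab} (4x4 matrix, rows = bruise b),
#'   \code{age_marginals} (counts and percentages per category and bruise),
#'   \code{percent_agreement}, \code{n_pigs}, \code{excluded} (pig ids).
#'   Methods: \code{print}, \code{summary}, \code{plot}.
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_pigs = 40, seed = 7,
#'                                             emission_noise = 0.3))$cohort
#' fit <- bruise_agreement(cohort)
#' fit
bruise_agreement <- function(x, pair_labels = c("a", "b"),
                             conf.level = 0.95, alpha = 0.05) {
  stopifnot(length(pair_labels) == 2L)
  x <- validate_bruise_table(as.data.frame(x)[bruise_schema_columns()])
  x <- estimate_age(x)
  has_a <- x$bruise_label == pair_labels[1]
  has_b <- x$bruise_label == pair_labels[2]
  pigs <- unique(x$pig_id)
  ok <- pigs[pigs %in% x$pig_id[has_a] & pigs %in% x$pig_id[has_b]]
  excluded <- setdiff(pigs, ok)
  if (!length(ok))
    stop("no pig carries both bruise labels '", pair_labels[1], "' and '",
         pair_labels[2], "'", call. = FALSE)
  a <- x[has_a & x$pig_id %in% ok, ]
  b <- x[has_b & x$pig_id %in% ok, ]
  a <- a[match(ok, a$pig_id), ]
  b <- b[match(ok, b$pig_id), ]

  vars <- .agreement_variables()
  results <- list()
  rows <- vector("list", length(vars))
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    tab <- crosstab(v$extract(a), v$extract(b), v$levels)
    kr <- cohen_kappa(tab, conf.level = conf.level, alpha = alpha)
    results[[v$name]] <- kr
    rows[[i]] <- data.frame(
      tissue = v$tissue, variable = v$name,
      kappa = kr$kappa, ci_lower = kr$ci_lower, ci_upper = kr$ci_upper,
      label = kr$label, p_value = kr$p_value, n = kr$n
    )
  }
  age_tab <- crosstab(a$age_category, b$age_category, .age_categories)
  marg <- data.frame(
    age_category = .age_categories,
    count_a = colSums(age_tab), count_b = rowSums(age_tab),
    row.names = NULL
  )
  marg$percent_a <- .round_half_up(100 * marg$count_a / length(ok))
  marg$percent_b <- .round_half_up(100 * marg$count_b / length(ok))

  structure(list(
    variables = do.call(rbind, rows),
    results = results,
    age_crosstab = age_tab,
    age_marginals = marg,
    percent_agreement = percent_agreement(age_tab),
    n_pigs = length(ok),
    excluded = excluded,
    pair_labels = pair_labels,
    conf.level = conf.level, alpha = alpha
  ), class = "bruise_agreement")
}

## round half away from zero, matching "30 (37 %)"-style display
.round_half_up <- function(x) trunc(x + sign(x) * 0.5)

#' @export
print.bruise_agreement <- function(x, digits = 2, ...) {
  cat(sprintf("Between-lesion agreement, bruises '%s' vs '%s': %d pigs",
              x$pair_labels[1], x$pair_labels[2], x$n_pigs))
  if (length(x$excluded))
    cat(sprintf(" (%d excluded: %s)", length(x$excluded),
                paste(x$excluded, collapse = ", ")))
  cat("\n\n")
  v <- x$variables
  v$kappa <- sprintf("%.*f", digits, v$kappa)
  v$ci_lower <- sprintf("%.*f", digits, v$ci_lower)
  v$ci_upper <- sprintf("%.*f", digits, v$ci_upper)
  v$p_value <- sprintf("%.4f", v$p_value)
  v$label <- gsub("_", " ", v$label)
  print(v, row.names = FALSE)
  cat(sprintf("\nSame age category in %d%% of pigs (age kappa %.2f)\n",
              .round_half_up(100 * x$percent_agreement),
              x$results$age_category$kappa))
  invisible(x)
}

#' @export
summary.bruise_agreement <- function(object, ...) {
  print(object, ...)
  cat("\nAge-category cross-tabulation (rows = bruise ",
      object$pair_labels[2], ", columns = bruise ",
      object$pair_labels[1], "):\n", sep = "")
  print(object$age_crosstab)
  cat("\nMarginal age distribution:\n")
  print(object$age_marginals, row.names = FALSE)
  invisible(object)
}

#' Dot-and-whisker plot of per-variable kappas
#'
#' @param x a \code{bruise_agreement} object.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, \code{x}.
#' @export
plot.bruise_agreement <- function(x, ...) {
  v <- x$variables[!is.na(x$variables$kappa) & !is.na(x$variables$ci_lower), ]
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  idx <- rev(seq_len(nrow(v)))
  graphics::plot(v$kappa, idx, xlim = range(c(-0.2, 1, v$ci_lower, v$ci_upper)),
                 yaxt = "n", ylab = "", xlab = "Cohen's kappa", pch = 19, ...)
  graphics::segments(v$ci_lower, idx, v$ci_upper, idx)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = idx, labels = v$variable, las = 1, cex.axis = 0.8)
  invisible(x)
}
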