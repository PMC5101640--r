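#' Published age-category cross-tabulation for 81 slaughter pigs
#'
#' The 4x4 cross-tabulation of the estimated age category of two bruises
#' (a and b) sampled from each of 81 Danish slaughter pigs with multiple
#' human-inflicted bruises, as reported in the forensic cohort study this
#' package implements. Rows index bruise b, columns bruise a; the diagonal
#' holds the 39 pigs whose two bruises were called to the same category.
#'
#' @return Integer 4x4 matrix with dimnames over [age_categories()]
#'   (rows = bruise b, columns = bruise a), total count 81.
#' @export
#' @examples
#' tab <- published_age_crosstab()
#' percent_agreement(tab)      # 0.481...
#' cohen_kappa(tab)            # kappa 0.24, 95% CI [0.08, 0.40]
published_age_crosstab <- function() {
  path <- system.file("extdata", "age_crosstab_81pigs.csv",
                      package = "bruiseAge", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(b = df[[1]], a = colnames(df)[-1])
  stopifnot(identical(rownames(m), .age_categories),
            identical(colnames(m), .age_categories))
  m
}
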