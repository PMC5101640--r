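#' @keywords internal
"_PACKAGE"

## Column schema for the bruise histology table. Order is the canonical CSV
## column order; types drive validation in read_bruise_table().
.bruise_schema <- data.frame(
  column = c(
    "pig_id", "bruise_label",
    "dermis_hemorrhage", "dermis_hyperleukocytosis", "dermis_leukocytes",
    "subcutis_hemorrhage", "subcutis_hyperleukocytosis",
    "subcutis_neutrophils", "subcutis_macrophages",
    "muscle_hemorrhage", "muscle_hyperleukocytosis",
    "muscle_necrosis", "muscle_neutrophils", "muscle_macrophages",
    "muscle_leukocyte_localization", "gross_pattern"
  ),
  type = c(
    "id", "id",
    "presence", "presence", "presence",
    "presence", "presence",
    "score", "score",
    "presence", "presence",
    "score", "score", "score",
    "localization", "freetext"
  ),
  stringsAsFactors = FALSE
)

.presence_levels <- c("present", "absent")
.localization_levels <- c("interstitial", "intramuscular", "not_applicable")

#' Column names of the bruise histology CSV schema
#'
#' The canonical column set (and order) used by [read_bruise_table()] and
#' [write_bruise_table()]. Presence/absence variables are serialized as the
#' strings \code{"present"}/\code{"absent"}; semi-quantitative cell and
#' necrosis scores as the integers 0--3; leukocyte localization in muscle as
#' one of \code{"interstitial"}, \code{"intramuscular"},
#' \code{"not_applicable"}.
#'
#' @return Character vector of column names.
#' @export
#' @examples
#' bruise_schema_columns()
bruise_schema_columns <- function() .bruise_schema$column

.is_score <- function(x) {
  suppressWarnings(v <- as.integer(x))
  !is.na(v) & as.character(v) == trimws(as.character(x)) & v %in% 0:3
}

#' Validate a bruise histology table
#'
#' Checks a data frame against the scoring-scheme contract: all schema columns
#' present, presence variables in \{present, absent\}, cell and necrosis
#' scores integers in 0--3, leukocyte localization one of its three levels and
#' \code{not_applicable} only when both muscle cell scores are 0, and
#' (pig_id, bruise_label) unique. Every cell is checked; nothing is coerced
#' silently.
#'
#' @param df data frame to validate.
#' @return The validated data frame, columns in schema order, with class
#'   \code{"bruise_cohort"} prepended; scores as integers.
#' @export
validate_bruise_table <- function(df) {
  stopifnot(is.data.frame(df))
  sch <- .bruise_schema
  missing_cols <- setdiff(sch$column, names(df))
  if (length(missing_cols)) {
    stop("schema error: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, sch$column, drop = FALSE]
  errs <- character(0)
  add_err <- function(rows, col, vals, what) {
    sprintf("row %d, column '%s': invalid value '%s' (%s)", rows, col, vals, what)
  }
  for (i in seq_len(nrow(sch))) {
    col <- sch$column[i]
    x <- df[[col]]
    bad <- switch(sch$type[i],
      id = is.na(x) | trimws(as.character(x)) == "",
      presence = !(as.character(x) %in% .presence_levels),
      score = !.is_score(x),
      localization = !(as.character(x) %in% .localization_levels),
      freetext = rep(FALSE, length(x))
    )
    if (sch$type[i] == "freetext") {
      df[[col]] <- ifelse(is.na(x), "", as.character(x))
      next
    }
    if (any(bad)) {
      what <- switch(sch$type[i],
        id = "must be a non-empty identifier",
        presence = "must be 'present' or 'absent'",
        score = "must be an integer in {0, 1, 2, 3}",
        localization = paste0("must be one of ",
                              paste(.localization_levels, collapse = ", "))
      )
      errs <- c(errs, add_err(which(bad), col, as.character(x)[bad], what))
    } else {
      df[[col]] <- switch(sch$type[i],
        score = as.integer(as.character(x)),
        as.character(x)
      )
    }
  }
  if (!length(errs)) {
    na_loc <- df$muscle_leukocyte_localization == "not_applicable"
    cells <- df$muscle_neutrophils > 0 | df$muscle_macrophages > 0
    bad <- which(na_loc & cells)
    if (length(bad)) {
      errs <- c(errs, sprintf(
        "row %d, column 'muscle_leukocyte_localization': 'not_applicable' requires both muscle cell scores to be 0",
        bad))
    }
    key <- paste(df$pig_id, df$bruise_label, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup)) {
      errs <- c(errs, sprintf(
        "row %d: duplicate (pig_id, bruise_label) pair ('%s', '%s')",
        dup, df$pig_id[dup], df$bruise_label[dup]))
    }
  }
  if (length(errs)) {
    stop("validation error:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("bruise_cohort", "data.frame")
  df
}

#' Read a bruise histology table from CSV
#'
#' Reads a comma-separated, UTF-8 file with the exact header given by
#' [bruise_schema_columns()] (one row per bruise) and validates every field.
#' Malformed headers, out-of-range scores and duplicate (pig_id, bruise_label)
#' pairs raise structured errors naming the offending row and column.
#'
#' @param file path or connection to a CSV file.
#' @return A validated \code{bruise_cohort} data frame, rows in input order.
#' @seealso [write_bruise_table()], [pig_records()]
#' @export
read_bruise_table <- function(file) {
  df <- utils::read.csv(file, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  validate_bruise_table(df)
}

#' Write a bruise histology table to CSV
#'
#' Inverse of [read_bruise_table()]: writes the schema columns in canonical
#' order so that a read-back reproduces the table field for field. Presence
#' variables are written as \code{"present"}/\code{"absent"} (never 0/1, to
#' avoid confusion with ordinal scores) and a missing gross pattern as the
#' empty string.
#'
#' @param df a validated \code{bruise_cohort} data frame (or a data frame that
#'   passes [validate_bruise_table()]).
#' @param file path or connection to write to.
#' @return Invisibly, the number of data rows written.
#' @export
write_bruise_table <- function(df, file) {
  df <- validate_bruise_table(df)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(nrow(df))
}

#' Split a cohort into per-pig records
#'
#' Groups a validated bruise table by \code{pig_id}, preserving first-seen pig
#' order and within-pig row order. Age estimation works on any number of
#' bruises per pig; the paired agreement analysis needs at least two.
#'
#' @param df a validated \code{bruise_cohort} data frame.
#' @return Named list of data frames, one per pig.
#' @export
pig_records <- function(df) {
  df <- validate_bruise_table(df)
  split(as.data.frame(df), factor(df$pig_id, levels = unique(df$pig_id)))
}

#' @export
print.bruise_cohort <- function(x, ...) {
  cat(sprintf("Bruise histology cohort: %d bruises from %d pigs\n",
              nrow(x), length(unique(x$pig_id))))
  NextMethod()
}
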