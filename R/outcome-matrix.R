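#' Binary outcome matrix
#'
#' The unit of analysis: a subjects-by-outcomes table of dichotomous (0/1)
#' variables with optional missing values and an optional binary
#' stratification variable. All analysis functions in the package operate
#' on objects of this class.
#'
#' @param values matrix or data.frame of outcome values; entries must be
#'   0, 1 or `NA`. Columns are outcomes, rows are subjects.
#' @param subject_ids character vector of unique subject identifiers;
#'   defaults to rownames of `values` or `"S1"`, `"S2"`, ...
#' @param outcome_names character vector of unique, non-empty outcome
#'   labels; defaults to `colnames(values)`.
#' @param strata optional vector of 0/1/`NA` stratum indicators, one per
#'   subject.
#' @param strata_name label for the stratification variable (required when
#'   `strata` is given).
#'
#' @return An object of class `outcome_matrix`: a list with elements
#'   `subject_ids`, `outcome_names`, `values` (integer matrix), and
#'   optionally `strata_name`, `strata`.
#' @export
outcome_matrix <- function(values, subject_ids = NULL, outcome_names = NULL,
                           strata = NULL, strata_name = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("`values` must be a matrix or data.frame")
  storage.mode(values) <- "integer"
  if (is.null(outcome_names)) outcome_names <- colnames(values)
  if (is.null(outcome_names)) stop("outcome names are required")
  outcome_names <- as.character(outcome_names)
  if (length(outcome_names) != ncol(values))
    stop("length of `outcome_names` does not match number of columns")
  if (anyDuplicated(outcome_names) || any(!nzchar(outcome_names)))
    stop("outcome names must be unique and non-empty")
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values))
    stop("length of `subject_ids` does not match number of rows")
  if (anyDuplicated(subject_ids))
    stop("duplicate subject id: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  bad <- which(!is.na(values) & values != 0L & values != 1L)
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("value %s in row '%s', column '%s' is not 0, 1 or missing",
                 values[bad[1]], subject_ids[i], outcome_names[j]))
  }
  dimnames(values) <- list(subject_ids, outcome_names)
  m <- list(subject_ids = subject_ids, outcome_names = outcome_names,
            values = values)
  if (!is.null(strata)) {
    if (is.null(strata_name)) stop("`strata_name` is required with `strata`")
    strata <- as.integer(strata)
    if (length(strata) != nrow(values))
      stop("length of `strata` does not match number of rows")
    if (any(!is.na(strata) & strata != 0L & strata != 1L))
      stop("stratum values must be 0, 1 or missing")
    m$strata_name <- as.character(strata_name)
    m$strata <- strata
  }
  class(m) <- "outcome_matrix"
  m
}

#' @export
print.outcome_matrix <- function(x, ...) {
  cat(sprintf("<outcome_matrix> %d subjects x %d outcomes\n",
              nrow(x$values), ncol(x$values)))
  cat("  outcomes:", paste(x$outcome_names, collapse = ", "), "\n")
  if (!is.null(x$strata))
    cat("  stratum: ", x$strata_name, "\n", sep = "")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat("  missing outcome values:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.outcome_matrix <- function(x) dim(x$values)

# Row subset preserving strata and attributes.
subset_rows <- function(m, keep) {
  outcome_matrix(m$values[keep, , drop = FALSE],
                 subject_ids = m$subject_ids[keep],
                 outcome_names = m$outcome_names,
                 strata = if (!is.null(m$strata)) m$strata[keep],
                 strata_name = m$strata_name)
}

#' Read a binary outcome table from CSV
#'
#' Reads a delimited text file (first row header) and validates it into an
#' [outcome_matrix()]. Cells are parsed with configurable truthy/falsy and
#' missing-value tokens, so the CSV dialects of typical clinical exports
#' ("yes"/"no", empty cells, "NA", ".") can be mapped without preprocessing.
#'
#' @param path file path.
#' @param id_column name of the subject-identifier column.
#' @param outcome_columns character vector of outcome column names.
#' @param strata_column optional name of a binary stratification column.
#' @param missing_tokens strings treated as missing values.
#' @param true_tokens,false_tokens strings parsed as 1 and 0 (in addition
#'   to `"1"` and `"0"`, always accepted).
#' @param delim field delimiter, default comma.
#'
#' @return An [outcome_matrix()].
#' @export
read_outcomes <- function(path, id_column, outcome_columns,
                          strata_column = NULL,
                          missing_tokens = c("", "NA", "NaN", "."),
                          true_tokens = "1", false_tokens = "0",
                          delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#", quote = "\"",
                          na.strings = character(0),  # token mapping is ours
                          fileEncoding = "UTF-8")
  need <- c(id_column, outcome_columns, strata_column)
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop("column(s) not present in header: ", paste(absent, collapse = ", "))
  true_tokens <- union(true_tokens, "1")
  false_tokens <- union(false_tokens, "0")
  parse_col <- function(x, col) {
    x <- trimws(x)
    out <- rep(NA_integer_, length(x))
    out[x %in% true_tokens] <- 1L
    out[x %in% false_tokens] <- 0L
    bad <- !(x %in% c(true_tokens, false_tokens, missing_tokens))
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("unparseable cell in row %d, column '%s': token '%s'",
                   i, col, x[i]))
    }
    out
  }
  vals <- vapply(outcome_columns, function(cn) parse_col(df[[cn]], cn),
                 integer(nrow(df)))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, outcome_columns))
  strata <- if (!is.null(strata_column)) parse_col(df[[strata_column]], strata_column)
  outcome_matrix(vals, subject_ids = df[[id_column]],
                 outcome_names = outcome_columns,
                 strata = strata, strata_name = strata_column)
}

#' Restrict to subjects with complete outcome data
#'
#' Keeps exactly the rows with no missing value on any outcome column,
#' the inclusion rule used for the analysis sample. Missingness on the
#' stratification variable does not drop a row here; stratified analyses
#' apply their own restriction. Row and column order are preserved and the
#' operation is idempotent.
#'
#' @param m an [outcome_matrix()].
#' @param quiet suppress the informational message.
#'
#' @return The filtered [outcome_matrix()], with a `filter_report`
#'   attribute: a list with `n_before`, `n_after`, `n_dropped`
#'   (see [filter_report()]).
#' @export
complete_case_filter <- function(m, quiet = FALSE) {
  stopifnot(inherits(m, "outcome_matrix"))
  keep <- stats::complete.cases(m$values)
  if (!any(keep)) stop("no complete cases")
  out <- subset_rows(m, keep)
  rep <- list(n_before = nrow(m$values), n_after = sum(keep),
              n_dropped = sum(!keep))
  attr(out, "filter_report") <- rep
  if (!quiet)
    message(sprintf("complete-case filter: %d of %d subjects retained (%d dropped)",
                    rep$n_after, rep$n_before, rep$n_dropped))
  out
}

#' @rdname complete_case_filter
#' @export
filter_report <- function(m) attr(m, "filter_report")

#' Write an outcome matrix to CSV
#'
#' Writes the same dialect [read_outcomes()] reads (header row, comma
#' delimiter, missing values as `NA`), so generated cohorts round-trip.
#'
#' @param m an [outcome_matrix()].
#' @param path output file path.
#' @param id_column header label for the identifier column.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(m, path, id_column = "id") {
  stopifnot(inherits(m, "outcome_matrix"))
  df <- data.frame(m$subject_ids, as.data.frame(m$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, m$outcome_names)
  if (!is.null(m$strata)) df[[m$strata_name]] <- m$strata
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}
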