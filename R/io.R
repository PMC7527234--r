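#' Read an embryo table from a delimited-text file
#'
#' The interchange format is a flat comma-separated UTF-8 table with a
#' header row and one embryo per row: \code{cohort_id, embryo_id, p1..p5}
#' plus the optional \code{true_class}, \code{implantation},
#' \code{euploid}, \code{transferred} columns (see
#' \code{\link{embryo_table}}).  Rows are grouped by \code{cohort_id}
#' preserving file order.  Validation failures report the offending data
#' line number(s).
#'
#' @param path file to read.
#' @param eligibility enforce cohort eligibility (2-12 embryos, at least
#'   one blastocyst-class embryo per cohort).
#' @return an \code{\link{embryo_table}}.
#' @export
read_embryo_table <- function(path, eligibility = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cohort_id", "embryo_id", prob_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pm <- as.matrix(df[prob_cols])
  storage.mode(pm) <- "double"
  bad <- which(apply(pm, 1L, function(r) any(!is.finite(r)) || any(r < 0)) |
                 rowSums(pm) < 0.99 | rowSums(pm) > 1.01)
  if (length(bad)) {
    stop(path, ": invalid probability row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (values must be non-negative and sum to within [0.99, 1.01])",
         call. = FALSE)
  }
  dup <- which(duplicated(df[c("cohort_id", "embryo_id")]))
  if (length(dup)) {
    stop(path, ": duplicate embryo_id within a cohort at line(s) ",
         paste(dup + 1L, collapse = ", "), call. = FALSE)
  }
  embryo_table(df, eligibility = eligibility)
}

#' Write an embryo table to a delimited-text file
#'
#' Inverse of \code{\link{read_embryo_table}}: the written file reads back
#' to an identical table.
#'
#' @param tab an \code{\link{embryo_table}}.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_embryo_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a selection table
#'
#' @param selections results from \code{\link{rank_cohorts}} (or an
#'   already-flattened \code{\link{selection_table}} data frame).
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_selection_table <- function(selections, path) {
  df <- if (is.data.frame(selections)) selections else
    selection_table(selections)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an evaluation report as a structured-text document
#'
#' Serializes any list of evaluation results (accuracy results, ROC
#' results, rater comparisons, score-bin tables, ...) to pretty-printed
#' JSON, stripping S3 classes.
#'
#' @param report a named list.
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (is.data.frame(x)) {
      ms <- attr(x, "miscalled")
      x <- as.data.frame(x)
      attr(x, "miscalled") <- NULL
      if (!is.null(ms)) return(list(table = x, miscalled = ms))
      return(x)
    }
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
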