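#' Morphology class codes and the hierarchical two-level categorization
#'
#' Day-5 (113 hours post-insemination) embryos are graded into five ordinal
#' morphology classes.  Classes 1-2 are degenerate/arrested or morula-stage
#' embryos ("non-blastocysts"); classes 3-5 are blastocysts.  Class 5 alone
#' meets the clinic's cryopreservation criterion (better than a "3CC"
#' Gardner grade) and is therefore the "highest-quality blastocyst" (HQB)
#' class.
#'
#' @param class integer vector of morphology class codes in \code{1:5}.
#' @return \code{inference_class()} returns a character vector with values
#'   \code{"blastocyst"} or \code{"non-blastocyst"};
#'   \code{is_high_quality()} returns a logical vector, \code{TRUE} only for
#'   class 5.
#' @examples
#' inference_class(1:5)
#' is_high_quality(c(4, 5))
#' @export
inference_class <- function(class) {
  class <- check_class_code(class)
  ifelse(class <= 2L, "non-blastocyst", "blastocyst")
}

#' @rdname inference_class
#' @export
is_high_quality <- function(class) {
  class <- check_class_code(class)
  class == 5L
}

check_class_code <- function(class, allow_na = FALSE) {
  cls <- suppressWarnings(as.integer(class))
  bad <- (!allow_na & is.na(cls)) | (!is.na(cls) & (cls < 1L | cls > 5L))
  if (any(bad)) {
    stop("invalid morphology class code(s): ",
         paste(unique(class[bad]), collapse = ", "),
         "; codes must be integers in 1..5", call. = FALSE)
  }
  cls
}

#' Validate and normalize a five-class probability vector
#'
#' Classifier outputs are softmax probabilities over the five morphology
#' classes.  Vectors whose components are non-negative and sum to within
#' \code{[0.99, 1.01]} (rounded inputs) are renormalized to sum exactly to
#' one; anything else is rejected as corrupt.
#'
#' @param p numeric vector of length 5, or a numeric matrix with 5 columns
#'   (one row per embryo).
#' @return the normalized vector or matrix.
#' @examples
#' class_probs(c(0.1, 0.1, 0.2, 0.3, 0.3))
#' @export
class_probs <- function(p) {
  if (is.null(dim(p))) {
    m <- matrix(as.numeric(p), nrow = 1)
    drop_out <- TRUE
  } else {
    m <- as.matrix(p)
    storage.mode(m) <- "double"
    drop_out <- FALSE
  }
  if (ncol(m) != 5L) {
    stop("class probabilities must have 5 components", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("class probabilities must be finite and non-negative", call. = FALSE)
  }
  s <- rowSums(m)
  bad <- s < 0.99 | s > 1.01
  if (any(bad)) {
    stop("probability row(s) ", paste(which(bad), collapse = ", "),
         " sum outside [0.99, 1.01]; refusing to renormalize corrupt input",
         call. = FALSE)
  }
  out <- m / s
  if (drop_out) drop(out) else out
}

prob_cols <- paste0("p", 1:5)

#' Construct a validated embryo table
#'
#' The package's central container is a flat data frame with one row per
#' embryo, grouped into patient cohorts by \code{cohort_id}.  Columns:
#' \describe{
#'   \item{cohort_id, embryo_id}{non-empty identifier strings;
#'     \code{embryo_id} must be unique within its cohort.}
#'   \item{p1..p5}{the classifier's five-class probabilities; validated and
#'     renormalized by \code{\link{class_probs}}.}
#'   \item{true_class}{optional morphology class in 1..5 (\code{NA} =
#'     unknown).}
#'   \item{implantation}{\code{"positive"}, \code{"negative"} or
#'     \code{"unknown"}.}
#'   \item{euploid}{\code{"yes"}, \code{"no"} or \code{"untested"}.}
#'   \item{transferred}{logical; a known implantation outcome implies
#'     \code{transferred = TRUE}.}
#' }
#' Missing optional columns are filled with their unknown values.
#'
#' @param df a data frame with at least \code{cohort_id}, \code{embryo_id}
#'   and \code{p1..p5}.
#' @param eligibility if \code{TRUE}, enforce the cohort eligibility rules
#'   used when assembling selection test sets: 2 to 12 embryos per cohort
#'   and at least one embryo of blastocyst class (true class >= 3).
#' @return the validated data frame with class \code{"embryo_table"}.
#' @examples
#' df <- data.frame(cohort_id = "C1", embryo_id = c("E1", "E2"),
#'                  p1 = c(1, 0), p2 = 0, p3 = 0, p4 = 0, p5 = c(0, 1),
#'                  true_class = c(1, 5))
#' tab <- embryo_table(df)
#' @export
embryo_table <- function(df, eligibility = FALSE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("cohort_id", "embryo_id", prob_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("embryo table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$cohort_id <- as.character(df$cohort_id)
  df$embryo_id <- as.character(df$embryo_id)
  if (any(!nzchar(df$cohort_id)) || any(!nzchar(df$embryo_id))) {
    stop("cohort_id and embryo_id must be non-empty", call. = FALSE)
  }
  dup <- duplicated(df[c("cohort_id", "embryo_id")])
  if (any(dup)) {
    stop("duplicate embryo_id within a cohort: ",
         paste(df$embryo_id[dup], collapse = ", "), call. = FALSE)
  }
  df[prob_cols] <- class_probs(as.matrix(df[prob_cols]))
  if (is.null(df$true_class)) df$true_class <- NA_integer_
  df$true_class <- check_class_code(df$true_class, allow_na = TRUE)
  if (is.null(df$implantation)) df$implantation <- "unknown"
  df$implantation <- match_levels(df$implantation,
                                  c("positive", "negative", "unknown"),
                                  "implantation")
  if (is.null(df$euploid)) df$euploid <- "untested"
  df$euploid <- match_levels(df$euploid, c("yes", "no", "untested"),
                             "euploid")
  if (is.null(df$transferred)) df$transferred <- FALSE
  df$transferred <- as.logical(df$transferred)
  known <- df$implantation != "unknown"
  if (any(known & !df$transferred)) {
    stop("embryos with a known implantation outcome must be transferred",
         call. = FALSE)
  }
  if (eligibility) {
    sz <- table(factor(df$cohort_id, levels = unique(df$cohort_id)))
    if (any(sz < 2L | sz > 12L)) {
      stop("eligible cohorts must contain 2-12 embryos", call. = FALSE)
    }
    has_blast <- tapply(df$true_class, df$cohort_id,
                        function(tc) any(!is.na(tc) & tc >= 3L))
    if (any(!has_blast)) {
      stop("eligible cohorts must contain at least one blastocyst-class ",
           "embryo (true class >= 3)", call. = FALSE)
    }
  }
  class(df) <- c("embryo_table", "data.frame")
  df
}

match_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !(x %in% levels)
  if (any(bad)) {
    stop(what, " must be one of ", paste(levels, collapse = "/"),
         "; got: ", paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Split an embryo table into per-cohort tables
#'
#' @param tab an \code{\link{embryo_table}}.
#' @return a named list of embryo tables, one per cohort, in file order.
#' @export
split_cohorts <- function(tab) {
  split(as.data.frame(tab),
        factor(tab$cohort_id, levels = unique(tab$cohort_id)))
}

#' Highest morphology class present in a cohort
#'
#' The genetic algorithm's fitness rewards picking an embryo of the highest
#' class available in its cohort, so every embryo needs a known true class.
#'
#' @param x an embryo table (or one cohort of it), or an integer vector of
#'   class codes.
#' @return the maximum class code present (integer scalar).
#' @export
top_available_class <- function(x) {
  tc <- if (is.data.frame(x)) x$true_class else x
  if (length(tc) == 0L) stop("empty cohort", call. = FALSE)
  tc <- check_class_code(tc, allow_na = TRUE)
  if (any(is.na(tc))) {
    stop("all embryos must have a known true_class", call. = FALSE)
  }
  max(tc)
}
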