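#' Transfer score of one or more probability vectors
#'
#' The transfer score is the dot product of the five scoring weights with
#' the classifier's five-class probability vector.  Because probabilities
#' sum to one, adding a constant to every weight shifts all scores equally
#' and never changes within-cohort rank order.
#'
#' @param w 5-element weight vector (e.g. \code{\link{published_weights}}).
#' @param p a probability 5-vector, or a matrix with 5 columns (one row per
#'   embryo).  Validated by \code{\link{class_probs}} unless \code{raw}.
#' @param raw skip probability validation/renormalization (scores arbitrary
#'   numeric vectors, e.g. all-zero edge cases).
#' @return numeric score(s).
#' @examples
#' transfer_score(published_weights(), c(0, 0, 0, 0, 1))  # 2.8715555
#' @export
transfer_score <- function(w, p, raw = FALSE) {
  w <- check_weights(w)
  if (is.null(dim(p))) p <- matrix(as.numeric(p), nrow = 1)
  if (!raw) p <- class_probs(p)
  drop(as.matrix(p) %*% w)
}

#' Rank one cohort and pick transfer candidates
#'
#' Embryos are ranked by transfer score, highest first, score ties broken
#' by lowest embryo index (input order).  The single-embryo-transfer (SET)
#' pick is the top-ranked embryo; the double-embryo-transfer (DET) picks
#' are the top two (absent for single-embryo cohorts).
#'
#' @param w 5-element weight vector.
#' @param cohort an \code{\link{embryo_table}} (or one element of
#'   \code{\link{split_cohorts}}) holding a single cohort.
#' @return a \code{"selection_result"} list: \code{cohort_id},
#'   \code{ranked_ids}, \code{scores} (non-increasing, parallel to
#'   \code{ranked_ids}), \code{set_pick}, \code{det_picks}.
#' @export
rank_cohort <- function(w, cohort) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  if (length(unique(cohort$cohort_id)) != 1L) {
    stop("rank_cohort() expects a single cohort; see rank_cohorts()",
         call. = FALSE)
  }
  s <- transfer_score(w, as.matrix(cohort[prob_cols]), raw = TRUE)
  ord <- order(-s)   # stable: ties keep input (lowest-index) order
  structure(list(cohort_id = cohort$cohort_id[1L],
                 ranked_ids = cohort$embryo_id[ord],
                 scores = s[ord],
                 set_pick = cohort$embryo_id[ord[1L]],
                 det_picks = if (nrow(cohort) >= 2L)
                   cohort$embryo_id[ord[1:2]] else NULL),
            class = "selection_result")
}

#' Rank every cohort of an embryo table
#'
#' @param w 5-element weight vector.
#' @param tab an \code{\link{embryo_table}}.
#' @return a named list of \code{\link{rank_cohort}} results, one per
#'   cohort in input order.
#' @export
rank_cohorts <- function(w, tab) {
  lapply(split_cohorts(tab), function(co) rank_cohort(w, co))
}

#' Flatten selection results to a delimited-text-ready table
#'
#' @param selections a list of selection results from
#'   \code{\link{rank_cohorts}}.
#' @return a data frame with columns \code{cohort_id, rank, embryo_id,
#'   score, set_flag, det_flag}.
#' @export
selection_table <- function(selections) {
  if (inherits(selections, "selection_result")) selections <- list(selections)
  do.call(rbind, lapply(selections, function(sel) {
    n <- length(sel$ranked_ids)
    data.frame(cohort_id = sel$cohort_id,
               rank = seq_len(n),
               embryo_id = sel$ranked_ids,
               score = sel$scores,
               set_flag = sel$ranked_ids == sel$set_pick,
               det_flag = sel$ranked_ids %in% sel$det_picks,
               stringsAsFactors = FALSE)
  }))
}

#' Dichotomize implantation potentials into calls
#'
#' The implantation-potential classifier emits a probability in [0, 1];
#' a potential at or above the call threshold is called positive.  The
#' default threshold 0.5 is the point of lowest confidence; an alternative
#' pilot operating point of 0.47 is also meaningful and the threshold is a
#' parameter, never hard-coded.
#'
#' @param potential numeric vector of probabilities in [0, 1].
#' @param threshold call threshold in [0, 1].
#' @param embryo_id optional ids carried through to the output.
#' @return a data frame with class \code{"implantation_calls"}: columns
#'   \code{embryo_id}, \code{potential}, \code{call_threshold}, \code{call}
#'   (\code{"positive"}/\code{"negative"}).
#' @examples
#' implantation_call(c(0.47, 0.2), threshold = 0.47)
#' @export
implantation_call <- function(potential, threshold = 0.5, embryo_id = NULL) {
  potential <- as.numeric(potential)
  if (any(!is.finite(potential) | potential < 0 | potential > 1)) {
    stop("implantation potentials must lie in [0, 1]", call. = FALSE)
  }
  if (length(threshold) != 1L || threshold < 0 || threshold > 1) {
    stop("threshold must be a single probability", call. = FALSE)
  }
  if (is.null(embryo_id)) {
    embryo_id <- paste0("E", seq_along(potential))
  }
  out <- data.frame(embryo_id = as.character(embryo_id),
                    potential = potential,
                    call_threshold = threshold,
                    call = ifelse(potential >= threshold,
                                  "positive", "negative"),
                    stringsAsFactors = FALSE)
  class(out) <- c("implantation_calls", "data.frame")
  out
}
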