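#' Clopper-Pearson exact binomial confidence interval
#'
#' Equal-tailed exact interval for a binomial proportion via the standard
#' incomplete-beta inversion: the lower limit is the \code{alpha/2} beta
#' quantile with shapes \code{(x, n - x + 1)} (0 when \code{x = 0}) and the
#' upper limit the \code{1 - alpha/2} quantile with shapes
#' \code{(x + 1, n - x)} (1 when \code{x = n}).
#'
#' @param successes,trials non-negative counts, \code{successes <= trials},
#'   \code{trials >= 1}.
#' @param confidence coverage, default 0.95.
#' @return named numeric vector \code{c(low =, high =)} of proportions.
#' @examples
#' clopper_pearson(24, 29)   # c(0.6423, 0.9415) to 4 decimals
#' @export
clopper_pearson <- function(successes, trials, confidence = 0.95) {
  x <- as.integer(successes); n <- as.integer(trials)
  if (is.na(x) || is.na(n) || n < 1L || x < 0L || x > n) {
    stop("need 0 <= successes <= trials and trials >= 1", call. = FALSE)
  }
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  alpha <- 1 - confidence
  low <- if (x == 0L) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Accuracy with its exact binomial interval
#'
#' @param correct,total counts.
#' @param confidence interval coverage.
#' @return an \code{"accuracy_result"} list: \code{correct}, \code{total},
#'   \code{accuracy}, \code{ci_low}, \code{ci_high}, \code{confidence}.
#' @export
accuracy_result <- function(correct, total, confidence = 0.95) {
  correct <- unname(correct); total <- unname(total)
  ci <- clopper_pearson(correct, total, confidence)
  structure(list(correct = as.integer(correct), total = as.integer(total),
                 accuracy = correct / total,
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 confidence = confidence),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("accuracy %d/%d = %.2f%% (exact %g%% CI: %.2f%% to %.2f%%)\n",
              x$correct, x$total, 100 * x$accuracy, 100 * x$confidence,
              100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

outcome01 <- function(outcomes) {
  if (is.logical(outcomes)) return(as.integer(outcomes))
  if (is.numeric(outcomes)) {
    if (any(!outcomes %in% c(0, 1))) {
      stop("numeric outcomes must be 0/1", call. = FALSE)
    }
    return(as.integer(outcomes))
  }
  out <- match_levels(as.character(outcomes),
                      c("positive", "negative", "unknown"), "outcome")
  ifelse(out == "positive", 1L, ifelse(out == "negative", 0L, NA_integer_))
}

criterion_fun <- function(criterion) {
  switch(criterion,
         "blastocyst" = function(tc, top) tc >= 3L,
         "highest-available-class" = function(tc, top) tc == top,
         "high-quality" = function(tc, top) tc == 5L,
         stop("unknown criterion: ", criterion, call. = FALSE))
}

#' SET/DET selection accuracy against a morphology criterion
#'
#' Judges ranked selections cohort by cohort.  Under SET the single top
#' pick must satisfy the criterion; under DET (default rule \code{"any"})
#' at least one of the two picks must — the stricter \code{"both"} rule is
#' also available.  Criteria: \code{"blastocyst"} (picked class >= 3),
#' \code{"high-quality"} (picked class 5, the freezing criterion), or
#' \code{"highest-available-class"} (picked class equals the cohort
#' maximum, the genetic algorithm's own training target).  Cohorts in
#' which no embryo can satisfy the criterion (e.g. no class-5 embryo under
#' \code{"high-quality"}) are judged against the highest-available-class
#' fallback and reported as a separate stratum.
#'
#' @param tab the labelled \code{\link{embryo_table}} that was ranked.
#' @param selections results from \code{\link{rank_cohorts}} on \code{tab}.
#' @param criterion one of \code{"blastocyst"},
#'   \code{"highest-available-class"}, \code{"high-quality"}.
#' @param mode \code{"SET"} (top-1) or \code{"DET"} (top-2).
#' @param det_rule \code{"any"} (at least one pick satisfies) or
#'   \code{"both"}.
#' @param confidence CI coverage.
#' @return a \code{"selection_accuracy"} list: \code{primary} and (if any
#'   cohorts fell back) \code{fallback} \code{\link{accuracy_result}}s,
#'   plus the settings used.
#' @export
selection_accuracy <- function(tab, selections,
                               criterion = c("blastocyst",
                                             "highest-available-class",
                                             "high-quality"),
                               mode = c("SET", "DET"),
                               det_rule = c("any", "both"),
                               confidence = 0.95) {
  criterion <- match.arg(criterion)
  mode <- match.arg(mode)
  det_rule <- match.arg(det_rule)
  cohorts <- split_cohorts(tab)
  if (!setequal(names(cohorts), vapply(selections, `[[`, "", "cohort_id"))) {
    stop("selections do not match the cohorts in the table", call. = FALSE)
  }
  sel_by_id <- stats::setNames(selections,
                               vapply(selections, `[[`, "", "cohort_id"))
  crit <- criterion_fun(criterion)
  fallback_crit <- criterion_fun("highest-available-class")
  primary <- c(correct = 0L, total = 0L)
  fallback <- c(correct = 0L, total = 0L)
  for (id in names(cohorts)) {
    co <- cohorts[[id]]
    top <- top_available_class(co)
    sel <- sel_by_id[[id]]
    picks <- if (mode == "SET") sel$set_pick else {
      if (is.null(sel$det_picks)) {
        stop("DET evaluation needs cohorts of size >= 2 (cohort ", id, ")",
             call. = FALSE)
      }
      sel$det_picks
    }
    tc <- co$true_class[match(picks, co$embryo_id)]
    satisfiable <- any(crit(co$true_class, top))
    f <- if (satisfiable) crit else fallback_crit
    ok <- f(tc, top)
    correct <- if (mode == "DET" && det_rule == "both") all(ok) else any(ok)
    if (satisfiable) {
      primary <- primary + c(correct, 1L)
    } else {
      fallback <- fallback + c(correct, 1L)
    }
  }
  structure(list(primary = if (primary["total"] > 0)
                   accuracy_result(primary["correct"], primary["total"],
                                   confidence),
                 fallback = if (fallback["total"] > 0)
                   accuracy_result(fallback["correct"], fallback["total"],
                                   confidence),
                 criterion = criterion, mode = mode, det_rule = det_rule),
            class = "selection_accuracy")
}

#' @export
print.selection_accuracy <- function(x, ...) {
  cat(sprintf("%s selection, criterion = %s%s\n", x$mode, x$criterion,
              if (x$mode == "DET") paste0(" (rule: ", x$det_rule, ")") else ""))
  if (!is.null(x$primary)) { cat("  primary stratum:  "); print(x$primary) }
  if (!is.null(x$fallback)) {
    cat("  fallback stratum (criterion unsatisfiable; judged by ",
        "highest-available-class):\n    ", sep = "")
    print(x$fallback)
  }
  invisible(x)
}

#' Implantation-call accuracy against known outcomes
#'
#' Embryos with unknown outcomes are excluded from the denominator; their
#' count is reported in the result.
#'
#' @param calls an \code{\link{implantation_call}} data frame, or a
#'   character/logical vector of calls.
#' @param outcomes outcomes parallel to \code{calls}
#'   (\code{"positive"}/\code{"negative"}/\code{"unknown"}, or 0/1/NA).
#' @param confidence CI coverage.
#' @return an \code{\link{accuracy_result}} with an extra
#'   \code{n_excluded} field.
#' @export
implantation_accuracy <- function(calls, outcomes, confidence = 0.95) {
  call01 <- if (is.data.frame(calls)) {
    ifelse(calls$call == "positive", 1L, 0L)
  } else {
    out <- outcome01(calls)
    if (any(is.na(out))) stop("calls must be positive/negative", call. = FALSE)
    out
  }
  y <- outcome01(outcomes)
  if (length(call01) != length(y)) {
    stop("calls and outcomes differ in length", call. = FALSE)
  }
  known <- !is.na(y)
  if (!any(known)) stop("no embryos with known outcomes", call. = FALSE)
  res <- accuracy_result(sum(call01[known] == y[known]), sum(known),
                         confidence)
  res$n_excluded <- sum(!known)
  res
}

#' Empirical ROC curve and AUC for implantation potentials
#'
#' The ROC curve is swept over every distinct score threshold; the AUC is
#' the tie-corrected pairwise concordance probability (the Mann-Whitney
#' statistic): the probability that a random positive outscores a random
#' negative, counting ties as 1/2.  The confidence interval is a seeded
#' stratified bootstrap (resampling positives and negatives separately) by
#' default; an asymptotic normal interval (Hanley-McNeil standard error)
#' is available as an alternative.
#'
#' @param potentials numeric scores.
#' @param outcomes binary outcomes (both classes must be present).
#' @param confidence CI coverage.
#' @param n_boot bootstrap resamples.
#' @param seed optional seed for the bootstrap.
#' @param ci_method \code{"bootstrap"} or \code{"normal"}.
#' @return a \code{"roc_result"} list: \code{points} (data frame of
#'   \code{fpr}, \code{tpr} from (0,0) to (1,1)), \code{auc},
#'   \code{auc_ci_low}, \code{auc_ci_high}, \code{n_pos}, \code{n_neg}.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), seed = 1)$auc  # 0.75
#' @export
roc_auc <- function(potentials, outcomes, confidence = 0.95,
                    n_boot = 2000L, seed = NULL,
                    ci_method = c("bootstrap", "normal")) {
  ci_method <- match.arg(ci_method)
  s <- as.numeric(potentials)
  y <- outcome01(outcomes)
  keep <- !is.na(y) & is.finite(s)
  s <- s[keep]; y <- y[keep]
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  auc <- auc_rank(s, y, n_pos, n_neg)
  thr <- sort(unique(s), decreasing = TRUE)
  pts <- rbind(data.frame(fpr = 0, tpr = 0),
               do.call(rbind, lapply(thr, function(t) {
                 data.frame(fpr = sum(s >= t & y == 0L) / n_neg,
                            tpr = sum(s >= t & y == 1L) / n_pos)
               })))
  alpha <- 1 - confidence
  if (ci_method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    ip <- which(y == 1L); ineg <- which(y == 0L)
    boots <- vapply(seq_len(n_boot), function(b) {
      sp <- s[sample(ip, n_pos, replace = TRUE)]
      sn <- s[sample(ineg, n_neg, replace = TRUE)]
      auc_rank(c(sp, sn), rep(c(1L, 0L), c(n_pos, n_neg)), n_pos, n_neg)
    }, numeric(1))
    ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    # percentile intervals can exclude a degenerate point estimate; clip
    ci <- c(min(ci[1], auc), max(ci[2], auc))
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                  (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
    z <- stats::qnorm(1 - alpha / 2)
    ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  }
  structure(list(points = pts, auc = auc,
                 auc_ci_low = ci[1], auc_ci_high = ci[2],
                 n_pos = n_pos, n_neg = n_neg,
                 ci_method = ci_method, confidence = confidence),
            class = "roc_result")
}

auc_rank <- function(s, y, n_pos, n_neg) {
  r <- rank(s)   # midranks: ties contribute 1/2
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%g%% CI: %.3f to %.3f; %s), %d positives / %d negatives\n",
              x$auc, 100 * x$confidence, x$auc_ci_low, x$auc_ci_high,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare human rater accuracies against a reference accuracy
#'
#' Two-sided one-sample t-test of the rater accuracies against the
#' reference (e.g. the automated system's accuracy), with the t-based
#' confidence interval of the rater mean.  A zero-variance rater set is
#' degenerate but reachable on synthetic data; it is reported with
#' \code{p_value = 1} and \code{degenerate_variance = TRUE} rather than
#' failing.
#'
#' @param rater_accuracies proportions, one per rater (at least two).
#' @param reference the reference accuracy to test against.
#' @param confidence CI coverage.
#' @return a \code{"rater_comparison"} list: \code{rater_accuracies},
#'   \code{mean}, \code{ci_low}, \code{ci_high}, \code{reference_accuracy},
#'   \code{t_statistic}, \code{p_value}, \code{degenerate_variance}.
#' @export
rater_comparison <- function(rater_accuracies, reference,
                             confidence = 0.95) {
  x <- as.numeric(rater_accuracies)
  if (length(x) < 2L) {
    stop("need at least two raters (variance undefined otherwise)",
         call. = FALSE)
  }
  n <- length(x)
  m <- mean(x)
  if (stats::sd(x) == 0) {
    res <- list(t_statistic = if (m == reference) 0 else
                  sign(m - reference) * Inf,
                p_value = 1, ci_low = m, ci_high = m,
                degenerate_variance = TRUE)
  } else {
    tt <- stats::t.test(x, mu = reference, conf.level = confidence)
    res <- list(t_statistic = unname(tt$statistic),
                p_value = tt$p.value,
                ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                degenerate_variance = FALSE)
  }
  structure(list(rater_accuracies = x, mean = m,
                 ci_low = res$ci_low, ci_high = res$ci_high,
                 reference_accuracy = reference,
                 t_statistic = res$t_statistic, p_value = res$p_value,
                 degenerate_variance = res$degenerate_variance,
                 confidence = confidence),
            class = "rater_comparison")
}

#' @export
print.rater_comparison <- function(x, ...) {
  cat(sprintf("%d raters, mean accuracy %.2f%% (%g%% CI: %.2f%% to %.2f%%)\n",
              length(x$rater_accuracies), 100 * x$mean, 100 * x$confidence,
              100 * x$ci_low, 100 * x$ci_high))
  cat(sprintf("one-sample t vs reference %.2f%%: t = %.3f, p = %.4g%s\n",
              100 * x$reference_accuracy, x$t_statistic, x$p_value,
              if (x$degenerate_variance) " (degenerate variance)" else ""))
  invisible(x)
}

#' Implantation-score bins
#'
#' Tabulates the implanted fraction within the reporting bands used for
#' implantation potentials: below 0.33, 0.33 to 0.66, above 0.66, and --
#' overlapping the last band, flagged so it is never double-counted in
#' totals -- at or above 0.80.  A summary of the low-confidence band is
#' attached: among miscalled embryos (call vs outcome at
#' \code{threshold}), the fraction whose score lies in 0.51-0.63 and the
#' mean miscalled score.
#'
#' @param calls an \code{\link{implantation_call}} data frame or a numeric
#'   vector of potentials.
#' @param outcomes outcomes parallel to the calls.
#' @param threshold call threshold used for the miscall summary when
#'   \code{calls} is a bare numeric vector.
#' @return a \code{"score_bin_table"} data frame with columns \code{band},
#'   \code{lo}, \code{hi}, \code{count}, \code{implanted},
#'   \code{implanted_frac} (NA when the band is empty) and
#'   \code{overlapping}; the miscall summary is attached as attribute
#'   \code{"miscalled"}.
#' @export
score_bins <- function(calls, outcomes, threshold = 0.5) {
  if (is.data.frame(calls)) {
    pot <- calls$potential
    call01 <- ifelse(calls$call == "positive", 1L, 0L)
  } else {
    pot <- as.numeric(calls)
    call01 <- as.integer(pot >= threshold)
  }
  y <- outcome01(outcomes)
  keep <- !is.na(y)
  pot <- pot[keep]; y <- y[keep]; call01 <- call01[keep]
  if (!length(pot)) stop("no scored embryos with known outcomes",
                         call. = FALSE)
  bands <- data.frame(
    band = c("<0.33", "0.33-0.66", ">0.66", ">=0.80"),
    lo = c(-Inf, 0.33, 0.66, 0.80),
    hi = c(0.33, 0.66, Inf, Inf),
    overlapping = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  in_band <- function(lo, hi, closed_lo) {
    if (closed_lo) pot >= lo & pot <= hi else pot > lo & pot <= hi
  }
  rows <- lapply(seq_len(nrow(bands)), function(i) {
    sel <- switch(bands$band[i],
                  "<0.33" = pot < 0.33,
                  "0.33-0.66" = pot >= 0.33 & pot <= 0.66,
                  ">0.66" = pot > 0.66,
                  ">=0.80" = pot >= 0.80)
    data.frame(count = sum(sel), implanted = sum(y[sel]),
               implanted_frac = if (any(sel)) mean(y[sel]) else NA_real_)
  })
  out <- cbind(bands, do.call(rbind, rows))
  mis <- call01 != y
  attr(out, "miscalled") <- list(
    n = sum(mis),
    mean_score = if (any(mis)) mean(pot[mis]) else NA_real_,
    frac_in_0.51_0.63 = if (any(mis))
      mean(pot[mis] >= 0.51 & pot[mis] <= 0.63) else NA_real_)
  class(out) <- c("score_bin_table", "data.frame")
  out
}
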