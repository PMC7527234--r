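#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a clinical embryo
#' selection study: patient cohorts of 2-12 embryos each containing at
#' least one blastocyst-class embryo; a five-class morphology classifier
#' whose argmax agrees with the true class about 91\% of the time; an
#' implantation rate near 44.1\% among transferred blastocysts; and a
#' panel of 15 human raters with per-rater implantation-call accuracies in
#' the mid-to-high 60s.  Every output is a pure function of
#' \code{(config, seed)}.
#'
#' @param n_cohorts number of patient cohorts.
#' @param cohort_size_range integer pair, cohort sizes drawn uniformly.
#' @param class_mix length-5 proportions of true morphology classes.  The
#'   default keeps every class above 10\% mass and puts about half of all
#'   embryos in the non-blastocyst classes, a realistic day-5 blastulation
#'   rate.
#' @param eligibility if \code{TRUE} (the clinical evaluation-set rule),
#'   cohorts are rejection-sampled until each contains at least one
#'   blastocyst-class embryo.  Set \code{FALSE} to generate unfiltered
#'   cohorts, the recommended protocol for GA \emph{training} sets:
#'   cohorts whose best embryo is a non-blastocyst are what make the
#'   ordering of the class-1 and class-2 weights identifiable.
#' @param classifier_concentration Dirichlet concentration placed on the
#'   true class; \code{NULL} (default) calibrates it to
#'   \code{target_argmax_accuracy} via \code{\link{calibrate_concentration}}.
#' @param classifier_confusion_decay factor by which the Dirichlet
#'   concentration of a wrong class shrinks per unit of ordinal distance
#'   from the true class.  Values below 1 concentrate classifier errors on
#'   adjacent classes, as an ordinal grading classifier's confusion matrix
#'   does; embryos of higher true class then carry stochastically higher
#'   class-probability mass, which is what makes a monotone weight vector
#'   optimal.  1 gives exchangeable (unstructured) confusion.
#' @param target_argmax_accuracy desired probability that the classifier's
#'   argmax equals the true class (marginally over \code{class_mix}).
#' @param blastocyst_implantation_rate target marginal implantation rate
#'   among transferred blastocyst-class embryos.
#' @param class_logit_slope log-odds increase in implantation per
#'   morphology class (monotone outcome model).
#' @param transfer_prob probability that a blastocyst-class embryo is
#'   transferred (and thus has a known outcome); non-blastocysts are never
#'   transferred by the generator, reproducing partial-outcome data.
#' @param rater_accuracy_range per-rater accuracy drawn uniformly here.
#' @param n_raters number of simulated raters.
#' @param potential_pos_shape,potential_neg_shape Beta shape pairs for
#'   implantation potentials of implanted / non-implanted embryos.
#' @param seed integer seed; every generator entry point re-seeds from it.
#' @return a list with class \code{"synth_config"}.
#' @export
synth_config <- function(n_cohorts = 97L,
                         cohort_size_range = c(2L, 12L),
                         class_mix = c(0.25, 0.25, 0.20, 0.15, 0.15),
                         eligibility = TRUE,
                         classifier_concentration = NULL,
                         classifier_confusion_decay = 0.5,
                         target_argmax_accuracy = 0.91,
                         blastocyst_implantation_rate = 0.441,
                         class_logit_slope = 0.5,
                         transfer_prob = 0.6,
                         rater_accuracy_range = c(0.64, 0.70),
                         n_raters = 15L,
                         potential_pos_shape = c(4, 2),
                         potential_neg_shape = c(2, 4),
                         seed = NULL) {
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              cohort_size_range = as.integer(cohort_size_range),
              class_mix = as.numeric(class_mix),
              eligibility = isTRUE(eligibility),
              classifier_concentration = classifier_concentration,
              classifier_confusion_decay = classifier_confusion_decay,
              target_argmax_accuracy = target_argmax_accuracy,
              blastocyst_implantation_rate = blastocyst_implantation_rate,
              class_logit_slope = class_logit_slope,
              transfer_prob = transfer_prob,
              rater_accuracy_range = as.numeric(rater_accuracy_range),
              n_raters = as.integer(n_raters),
              potential_pos_shape = as.numeric(potential_pos_shape),
              potential_neg_shape = as.numeric(potential_neg_shape),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (length(cfg$class_mix) != 5L || any(cfg$class_mix < 0) ||
      abs(sum(cfg$class_mix) - 1) > 1e-6) {
    stop("class_mix must be 5 non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (length(cfg$cohort_size_range) != 2L ||
      cfg$cohort_size_range[1] > cfg$cohort_size_range[2] ||
      cfg$cohort_size_range[1] < 1L || cfg$cohort_size_range[2] > 50L) {
    stop("cohort_size_range must be an increasing pair within [1, 50]",
         call. = FALSE)
  }
  props <- c(cfg$target_argmax_accuracy, cfg$blastocyst_implantation_rate,
             cfg$transfer_prob, cfg$rater_accuracy_range)
  if (any(props < 0 | props > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

maybe_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  invisible(NULL)
}

#' Calibrate the classifier concentration to a target argmax accuracy
#'
#' The synthetic classifier draws each probability vector from a Dirichlet
#' distribution whose concentration is \code{concentration} on the true
#' class and \code{classifier_confusion_decay^distance} on a wrong class
#' at that ordinal distance.  This routine bisects on the true-class
#' concentration until the Monte-Carlo argmax accuracy, marginal over the
#' configured class mix (a deterministic function of the candidate, via a
#' fixed internal seed), is within \code{tol} of
#' \code{target_argmax_accuracy}.
#'
#' @param config a \code{\link{synth_config}} supplying the target, the
#'   confusion decay and the class mix.
#' @param n_draws Monte-Carlo draws per candidate evaluation.
#' @param tol acceptable deviation from the target.
#' @return the calibrated concentration (positive scalar).
#' @export
calibrate_concentration <- function(config = synth_config(),
                                    n_draws = 10000L, tol = 0.005) {
  target <- config$target_argmax_accuracy
  if (target <= 0.2 || target >= 1) {
    stop("target accuracy must exceed the 0.2 chance level and be < 1",
         call. = FALSE)
  }
  acc_at <- function(conc) {
    # fixed internal seed: deterministic, monotone-in-conc up to MC noise
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(20260901L)
    tc <- sample.int(5L, n_draws, replace = TRUE, prob = config$class_mix)
    p <- gen_probs_impl(tc, conc, config$classifier_confusion_decay)
    mean(max.col(p, ties.method = "first") == tc)
  }
  lo <- 0.5; hi <- 4
  while (acc_at(hi) < target) {
    lo <- hi; hi <- hi * 2
    if (hi > 1e6) stop("calibration failed to bracket the target",
                       call. = FALSE)
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    a <- acc_at(mid)
    if (abs(a - target) <= tol) return(mid)
    if (a < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

resolved_concentration <- function(config) {
  if (!is.null(config$classifier_concentration))
    return(config$classifier_concentration)
  calibrate_concentration(config)
}

gen_cohorts_impl <- function(config) {
  if (config$eligibility && sum(config$class_mix[3:5]) <= 0) {
    stop("class_mix puts no mass on blastocyst classes: cohort ",
         "eligibility (>= 1 embryo of class >= 3) is unsatisfiable",
         call. = FALSE)
  }
  lo <- config$cohort_size_range[1]; hi <- config$cohort_size_range[2]
  sizes <- lo + sample.int(hi - lo + 1L, config$n_cohorts,
                           replace = TRUE) - 1L
  rows <- lapply(seq_len(config$n_cohorts), function(i) {
    repeat {
      tc <- sample.int(5L, sizes[i], replace = TRUE,
                       prob = config$class_mix)
      if (!config$eligibility || any(tc >= 3L)) break
    }
    cid <- sprintf("C%04d", i)
    data.frame(cohort_id = cid,
               embryo_id = sprintf("%s_E%02d", cid, seq_len(sizes[i])),
               true_class = tc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate patient cohorts with true morphology classes
#'
#' Cohort sizes are uniform over \code{cohort_size_range}; true classes are
#' drawn from \code{class_mix}; cohorts are rejection-sampled until each
#' contains at least one blastocyst-class embryo (class >= 3), the
#' eligibility rule for selection test sets.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a data frame with \code{cohort_id}, \code{embryo_id},
#'   \code{true_class} (no probabilities yet).
#' @export
gen_cohorts <- function(config = synth_config()) {
  maybe_seed(config)
  gen_cohorts_impl(config)
}

gen_probs_impl <- function(true_class, concentration, decay = 0.5) {
  n <- length(true_class)
  dist <- abs(matrix(1:5, n, 5L, byrow = TRUE) - true_class)
  alpha <- decay^dist
  alpha[cbind(seq_len(n), true_class)] <- concentration
  g <- matrix(stats::rgamma(n * 5L, shape = alpha), n, 5L)
  g / rowSums(g)
}

#' Synthetic classifier probabilities for given true classes
#'
#' Draws each embryo's five-class probability vector from a Dirichlet
#' distribution concentrated on the true class; the concentration is taken
#' from the config or calibrated so the argmax accuracy matches
#' \code{target_argmax_accuracy}.
#'
#' @param true_class integer vector of true classes.
#' @param config a \code{\link{synth_config}}.
#' @return a matrix with one probability row per embryo (rows sum to 1).
#' @export
gen_probs <- function(true_class, config = synth_config()) {
  true_class <- check_class_code(true_class)
  conc <- resolved_concentration(config)
  maybe_seed(config)
  gen_probs_impl(true_class, conc, config$classifier_confusion_decay)
}

# Per-class implantation probabilities: logistic in class with the
# intercept solved so the class-mix-weighted rate over classes 3-5 hits
# the configured blastocyst implantation rate.
implant_prob_by_class <- function(config) {
  target <- config$blastocyst_implantation_rate
  slope <- config$class_logit_slope
  if (target <= 0) return(rep(0, 5L))
  if (target >= 1) return(rep(1, 5L))
  mix <- config$class_mix[3:5]
  mix <- mix / sum(mix)
  f <- function(b0) sum(mix * stats::plogis(b0 + slope * (0:2))) - target
  b0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  stats::plogis(b0 + slope * ((1:5) - 3L))
}

gen_outcomes_impl <- function(tab, config) {
  p_class <- implant_prob_by_class(config)
  tc <- tab$true_class
  n <- nrow(tab)
  transferred <- tab$transferred |
    (tc >= 3L & stats::runif(n) < config$transfer_prob)
  implanted <- stats::runif(n) < p_class[tc]
  tab$transferred <- transferred
  tab$implantation <- ifelse(!transferred, "unknown",
                             ifelse(implanted, "positive", "negative"))
  tab
}

#' Attach simulated implantation outcomes
#'
#' Outcomes follow a logistic model monotone increasing in morphology
#' class, with the intercept solved numerically so the marginal rate among
#' transferred blastocyst-class embryos matches
#' \code{blastocyst_implantation_rate}.  Non-blastocysts are left
#' untransferred with unknown outcomes (unless already flagged
#' transferred), reproducing the partial-outcome structure of clinical
#' cohorts.
#'
#' @param tab a data frame with \code{true_class} (and optionally a
#'   \code{transferred} flag to force outcome ascertainment).
#' @param config a \code{\link{synth_config}}.
#' @return \code{tab} with \code{transferred} and \code{implantation}
#'   filled in.
#' @export
gen_outcomes <- function(tab, config = synth_config()) {
  if (any(is.na(tab$true_class))) {
    stop("true classes must be assigned before outcomes", call. = FALSE)
  }
  if (is.null(tab$transferred)) tab$transferred <- FALSE
  maybe_seed(config)
  gen_outcomes_impl(tab, config)
}

#' Simulate a panel of human raters calling implantation outcomes
#'
#' Each rater's accuracy is drawn uniformly from
#' \code{rater_accuracy_range}; the rater's call equals the true outcome
#' with that probability, independently per embryo.  Only embryos with
#' known outcomes are rated.
#'
#' @param tab an embryo table with implantation outcomes.
#' @param config a \code{\link{synth_config}}.
#' @return a \code{"rater_calls"} list: \code{accuracies} (assigned, one
#'   per rater), \code{calls} (0/1 matrix, raters x embryos),
#'   \code{outcomes} (0/1), \code{embryo_id}, and
#'   \code{empirical_accuracies}.
#' @export
gen_raters <- function(tab, config = synth_config()) {
  y <- outcome01(tab$implantation)
  keep <- !is.na(y)
  if (!any(keep)) stop("no embryos with known outcomes to rate",
                       call. = FALSE)
  y <- y[keep]
  maybe_seed(config)
  acc <- stats::runif(config$n_raters, config$rater_accuracy_range[1],
                      config$rater_accuracy_range[2])
  n <- length(y)
  correct <- matrix(stats::runif(config$n_raters * n), config$n_raters, n) <
    acc
  calls <- ifelse(correct, rep(y, each = config$n_raters),
                  1L - rep(y, each = config$n_raters))
  structure(list(accuracies = acc, calls = calls, outcomes = y,
                 embryo_id = tab$embryo_id[keep],
                 empirical_accuracies =
                   rowMeans(calls == matrix(y, config$n_raters, n,
                                            byrow = TRUE))),
            class = "rater_calls")
}

#' Simulate implantation potentials given outcomes
#'
#' Implanted embryos draw their potential from
#' \code{Beta(potential_pos_shape)}, non-implanted from
#' \code{Beta(potential_neg_shape)}; with the defaults the two
#' distributions mirror each other around 0.5 so scores near 0.5 carry the
#' least information.
#'
#' @param outcomes outcome vector (\code{"positive"}/\code{"negative"} or
#'   0/1); unknowns get \code{NA} potentials.
#' @param config a \code{\link{synth_config}}.
#' @return numeric vector of potentials in [0, 1].
#' @export
gen_potentials <- function(outcomes, config = synth_config()) {
  y <- outcome01(outcomes)
  maybe_seed(config)
  gen_potentials_impl(y, config)
}

#' Generate a complete synthetic embryo table
#'
#' Runs the whole generator pipeline under a single seeding: cohorts and
#' true classes, classifier probabilities, transfer flags and implantation
#' outcomes.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a validated \code{\link{embryo_table}}.
#' @examples
#' tab <- synth_cohorts(synth_config(n_cohorts = 5, seed = 42))
#' @export
synth_cohorts <- function(config = synth_config()) {
  conc <- resolved_concentration(config)
  maybe_seed(config)
  tab <- gen_cohorts_impl(config)
  probs <- gen_probs_impl(tab$true_class, conc,
                          config$classifier_confusion_decay)
  colnames(probs) <- prob_cols
  tab <- cbind(tab, as.data.frame(probs))
  tab$transferred <- FALSE
  tab <- gen_outcomes_impl(tab, config)
  tab$euploid <- "untested"
  embryo_table(tab, eligibility = config$eligibility)
}

#' Generate a synthetic euploid test set
#'
#' Emulates a genetically screened single-transfer evaluation set: all
#' embryos are euploid, of high baseline morphological quality (classes 4
#' and 5 only), all transferred, with implantation outcomes balanced
#' 50/50 by default, and an implantation potential attached per embryo.
#'
#' @param n_embryos number of embryos (one per patient).
#' @param config a \code{\link{synth_config}}.
#' @param implantation_rate outcome prevalence of the euploid set.
#' @return an \code{\link{embryo_table}} with an extra \code{potential}
#'   column.
#' @export
synth_euploid <- function(n_embryos = 97L, config = synth_config(),
                          implantation_rate = 0.5) {
  conc <- resolved_concentration(config)
  maybe_seed(config)
  tc <- sample(4:5, n_embryos, replace = TRUE)
  probs <- gen_probs_impl(tc, conc, config$classifier_confusion_decay)
  colnames(probs) <- prob_cols
  y <- stats::runif(n_embryos) < implantation_rate
  ids <- sprintf("P%04d", seq_len(n_embryos))
  tab <- data.frame(cohort_id = ids,
                    embryo_id = paste0(ids, "_E01"),
                    true_class = tc, stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(probs))
  tab$implantation <- ifelse(y, "positive", "negative")
  tab$euploid <- "yes"
  tab$transferred <- TRUE
  tab$potential <- gen_potentials_impl(as.integer(y), config)
  embryo_table(tab)
}

gen_potentials_impl <- function(y, config) {
  pot <- rep(NA_real_, length(y))
  pos <- which(y == 1L); neg <- which(y == 0L)
  pot[pos] <- stats::rbeta(length(pos), config$potential_pos_shape[1],
                           config$potential_pos_shape[2])
  pot[neg] <- stats::rbeta(length(neg), config$potential_neg_shape[1],
                           config$potential_neg_shape[2])
  pot
}
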