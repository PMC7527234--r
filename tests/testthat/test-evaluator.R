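test_that("Clopper-Pearson intervals match the exact closed forms", {
  ci <- clopper_pearson(24, 29)
  expect_equal(round(unname(ci), 4), c(0.6423, 0.9415))
  expect_equal(unname(clopper_pearson(0, 10)["low"]), 0)
  all29 <- clopper_pearson(29, 29)
  expect_equal(unname(all29["low"]), 0.025^(1 / 29), tolerance = 1e-10)
  expect_equal(unname(all29["high"]), 1)
  expect_error(clopper_pearson(5, 4), "successes")
  expect_error(clopper_pearson(1, 0), "trials")
})

test_that("Clopper-Pearson agrees with binom.test and widens with confidence", {
  for (case in list(c(3, 17), c(24, 29), c(50, 120))) {
    ours <- clopper_pearson(case[1], case[2])
    ref <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-10)
    wide <- clopper_pearson(case[1], case[2], confidence = 0.99)
    expect_lte(wide["low"], ours["low"])
    expect_gte(wide["high"], ours["high"])
    expect_gte(case[1] / case[2], ours["low"])
    expect_lte(case[1] / case[2], ours["high"])
  }
})

test_that("SET selection against the blastocyst criterion judges the top pick", {
  tab <- onehot_table(list(c(1, 5)))
  sel <- rank_cohorts(published_weights(), tab)
  res <- selection_accuracy(tab, sel, criterion = "blastocyst",
                            mode = "SET")
  expect_equal(res$primary$accuracy, 1)
  # single-class cohort is always correct under highest-available-class
  tab2 <- onehot_table(list(c(2, 2)))
  sel2 <- rank_cohorts(published_weights(), tab2)
  res2 <- selection_accuracy(tab2, sel2,
                             criterion = "highest-available-class",
                             mode = "SET")
  expect_equal(res2$primary$accuracy, 1)
})

test_that("DET correctness defaults to the at-least-one rule", {
  # ranked order under increasing weights: class 3 then class 1 in top two
  df <- onehot_table(list(c(3, 1)))
  sel <- rank_cohorts(c(1, 2, 3, 4, 5), df)
  expect_equal(sort(sel[[1]]$det_picks), c("C01_E01", "C01_E02"))
  any_rule <- selection_accuracy(df, sel, criterion = "blastocyst",
                                 mode = "DET", det_rule = "any")
  expect_equal(any_rule$primary$accuracy, 1)
  both_rule <- selection_accuracy(df, sel, criterion = "blastocyst",
                                  mode = "DET", det_rule = "both")
  expect_equal(both_rule$primary$accuracy, 0)
})

test_that("cohorts that cannot satisfy the criterion form a fallback stratum", {
  # second cohort has no class-5 embryo: judged by highest-available-class
  tab <- onehot_table(list(c(1, 5), c(3, 4)))
  sel <- rank_cohorts(published_weights(), tab)
  res <- selection_accuracy(tab, sel, criterion = "high-quality",
                            mode = "SET")
  expect_equal(res$primary$total, 1L)
  expect_equal(res$primary$accuracy, 1)
  expect_equal(res$fallback$total, 1L)
  expect_equal(res$fallback$accuracy, 1)   # class 4 picked, top available
})

test_that("highest-available-class SET accuracy equals GA fitness over cohorts", {
  tab <- synth_cohorts(fast_synth_config(n_cohorts = 40, seed = 51))
  w <- stats::rnorm(5)
  sel <- rank_cohorts(w, tab)
  res <- selection_accuracy(tab, sel,
                            criterion = "highest-available-class",
                            mode = "SET")
  expect_equal(res$primary$correct, ga_fitness(w, tab))
  expect_equal(res$primary$total, length(unique(tab$cohort_id)))
})

test_that("implantation accuracy excludes unknown outcomes and matches counts", {
  calls <- implantation_call(c(0.9, 0.8, 0.2, 0.7))
  all_right <- implantation_accuracy(calls, c("positive", "positive",
                                              "negative", "positive"))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$ci_high, 1)
  half <- implantation_accuracy(calls, c("positive", "negative",
                                         "positive", "positive"))
  expect_equal(half$accuracy, 0.5)
  with_unknown <- implantation_accuracy(calls,
                                        c("positive", "unknown",
                                          "negative", "unknown"))
  expect_equal(with_unknown$total, 2L)
  expect_equal(with_unknown$n_excluded, 2L)
  expect_error(implantation_accuracy(calls, rep("unknown", 4)),
               "known outcomes")
})

test_that("a 24-of-29 result reproduces the exact printed interval", {
  calls <- implantation_call(c(rep(0.9, 24), rep(0.9, 5)))
  outcomes <- c(rep("positive", 24), rep("negative", 5))
  res <- implantation_accuracy(calls, outcomes)
  expect_equal(round(res$accuracy, 4), 0.8276)
  expect_equal(round(res$ci_low, 4), 0.6423)
  expect_equal(round(res$ci_high, 4), 0.9415)
})

test_that("AUC equals the tie-corrected pairwise concordance", {
  res <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), seed = 1)
  expect_equal(res$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1), seed = 1)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1), seed = 1)$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both outcome classes")
})

test_that("AUC matches the exhaustive pairwise oracle on small instances", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(stats::runif(n), 1)   # rounding forces occasional ties
    res <- roc_auc(s, y, n_boot = 50, seed = i)
    expect_equal(res$auc, pairwise_auc(s, y))
    expect_gte(res$auc, res$auc_ci_low)
    expect_lte(res$auc, res$auc_ci_high)
  }
})

test_that("AUC and ROC curve agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  s <- stats::runif(40)
  y <- stats::rbinom(40, 1, 0.5 + 0.3 * (s > 0.5))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  ours <- roc_auc(s, y, n_boot = 50, seed = 3)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(sort(ours$points$fpr), sort(1 - ref$specificities),
               tolerance = 1e-10)
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  set.seed(63)
  s <- stats::runif(30); y <- stats::rbinom(30, 1, 0.5)
  y[1:2] <- 0:1
  pts <- roc_auc(s, y, n_boot = 50, seed = 4)$points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("rater comparison reproduces the one-sample t closed form", {
  x <- c(0.64, 0.66, 0.68, 0.70, 0.72)
  ref <- 0.75
  res <- rater_comparison(x, ref)
  t_hand <- (mean(x) - ref) / (stats::sd(x) / sqrt(length(x)))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = length(x) - 1)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_equal(res$mean, mean(x))

  sym <- rater_comparison(c(0.6, 0.8), 0.7)
  expect_equal(sym$t_statistic, 0)
  expect_equal(sym$p_value, 1)
})

test_that("zero-variance rater sets are flagged, not fatal", {
  res <- rater_comparison(c(0.6, 0.6, 0.6), 0.6)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate_variance)
  expect_error(rater_comparison(0.6, 0.6), "at least two")
})

test_that("score bins partition scores with the 0.80 band flagged as overlapping", {
  high <- score_bins(implantation_call(rep(0.9, 8)), rep("positive", 8))
  expect_equal(high[high$band == ">=0.80", "implanted_frac"], 1)
  expect_equal(high[high$band == "<0.33", "count"], 0L)
  expect_true(is.na(high[high$band == "<0.33", "implanted_frac"]))
  expect_equal(high$overlapping, c(FALSE, FALSE, FALSE, TRUE))
  # non-overlapping bands partition the scored embryos
  set.seed(71)
  pot <- stats::runif(200)
  y <- stats::rbinom(200, 1, pot)
  tab <- score_bins(pot, y)
  expect_equal(sum(tab$count[!tab$overlapping]), 200L)
})

test_that("band fractions match the generator's analytic expectations", {
  cfg <- synth_config(seed = 101)
  n <- 20000
  y <- rep(0:1, each = n / 2)
  pot <- gen_potentials(y, cfg)
  tab <- score_bins(pot, y)
  band_frac <- function(lo, hi) {
    ppos <- stats::pbeta(hi, 4, 2) - stats::pbeta(lo, 4, 2)
    pneg <- stats::pbeta(hi, 2, 4) - stats::pbeta(lo, 2, 4)
    ppos / (ppos + pneg)   # 50/50 prevalence
  }
  expected <- c(band_frac(0, 0.33), band_frac(0.33, 0.66),
                band_frac(0.66, 1), band_frac(0.80, 1))
  expect_true(all(abs(tab$implanted_frac - expected) < 0.05))
})
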