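# Build an embryo table of one-hot probability vectors from true classes.
# `classes` is a list: one integer vector per cohort.
onehot_table <- function(classes) {
  rows <- lapply(seq_along(classes), function(i) {
    tc <- classes[[i]]
    p <- diag(5)[tc, , drop = FALSE]
    colnames(p) <- paste0("p", 1:5)
    cid <- sprintf("C%02d", i)
    cbind(data.frame(cohort_id = cid,
                     embryo_id = sprintf("%s_E%02d", cid, seq_along(tc)),
                     true_class = tc, stringsAsFactors = FALSE),
          as.data.frame(p))
  })
  embryo_table(do.call(rbind, rows))
}

# Brute-force maximal fitness over all orderings of the five weight
# components; for one-hot probability vectors the fitness depends only on
# that ordering, so the 120 permutations of 1:5 cover the search space
# exhaustively.
brute_force_max_fitness <- function(tab) {
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 5L), ]
  max(apply(perms, 1, function(w) ga_fitness(w, tab)))
}

# Exhaustive tie-corrected pairwise concordance (AUC oracle).
pairwise_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# A synth_config with the concentration pre-resolved once per test run,
# so repeated generator calls skip recalibration.
cached_concentration <- local({
  conc <- NULL
  function() {
    if (is.null(conc)) conc <<- calibrate_concentration(synth_config())
    conc
  }
})

fast_synth_config <- function(...) {
  synth_config(classifier_concentration = cached_concentration(), ...)
}
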