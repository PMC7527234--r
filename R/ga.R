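#' Genetic-algorithm configuration
#'
#' The scoring weights are learned by a plain generational genetic algorithm
#' with elitist truncation selection, uniform (mask) crossover, and additive
#' uniform mutation.  Defaults follow the study protocol: a population of
#' 100 weight vectors, the best 20 retained each cycle, crossover and
#' per-component mutation probabilities of 20\%, and five mutants per elite.
#'
#' @param population_size number of weight vectors per generation.
#' @param elite_count number of top-fitness specimens retained each cycle.
#' @param crossover_prob probability that a sampled elite pair is crossed.
#' @param mutation_prob per-component probability of perturbation.
#' @param mutants_per_specimen mutants generated from each elite.
#' @param init_low,init_high uniform initialization range for weights.
#' @param mutation_low,mutation_high uniform range of mutation perturbations.
#' @param max_generations cap on evaluation cycles if the population never
#'   converges to a single fitness value.
#' @param mask_prob probability that a crossover mask bit is 1.
#' @param keep_overflow if \code{TRUE}, keep elites plus all mutants without
#'   truncating back to \code{population_size}.
#' @param seed optional integer seed fixing the whole run.
#' @return a list with class \code{"ga_config"}.
#' @export
ga_config <- function(population_size = 100L, elite_count = 20L,
                      crossover_prob = 0.20, mutation_prob = 0.20,
                      mutants_per_specimen = 5L,
                      init_low = -10, init_high = 10,
                      mutation_low = -1, mutation_high = 1,
                      max_generations = 1000L, mask_prob = 0.5,
                      keep_overflow = FALSE, seed = NULL) {
  cfg <- list(population_size = as.integer(population_size),
              elite_count = as.integer(elite_count),
              crossover_prob = crossover_prob,
              mutation_prob = mutation_prob,
              mutants_per_specimen = as.integer(mutants_per_specimen),
              init_low = init_low, init_high = init_high,
              mutation_low = mutation_low, mutation_high = mutation_high,
              max_generations = as.integer(max_generations),
              mask_prob = mask_prob,
              keep_overflow = isTRUE(keep_overflow),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$population_size < 1L || cfg$elite_count < 1L ||
      cfg$elite_count > cfg$population_size) {
    stop("need 0 < elite_count <= population_size", call. = FALSE)
  }
  probs <- c(cfg$crossover_prob, cfg$mutation_prob, cfg$mask_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!(cfg$init_low < cfg$init_high)) {
    stop("init_low must be < init_high", call. = FALSE)
  }
  if (cfg$mutation_low > cfg$mutation_high) {
    stop("mutation_low must be <= mutation_high", call. = FALSE)
  }
  class(cfg) <- "ga_config"
  cfg
}

#' Random initial population of weight vectors
#'
#' Each of \code{population_size} specimens has its five components drawn
#' independently and uniformly from \code{[init_low, init_high]}.  Consumes
#' the current RNG stream; seed via \code{set.seed()} or let
#' \code{\link{ga_evolve}} handle seeding.
#'
#' @param config a \code{\link{ga_config}}.
#' @return a numeric matrix, one row per specimen, five columns.
#' @export
ga_initialize <- function(config = ga_config()) {
  matrix(stats::runif(config$population_size * 5L,
                      config$init_low, config$init_high),
         nrow = config$population_size, ncol = 5L)
}

# Precompute per-cohort structure once per training run.
ga_prepare <- function(tab) {
  if (!nrow(tab)) stop("no training cohorts supplied", call. = FALSE)
  if (any(is.na(tab$true_class))) {
    stop("fitness is undefined without labels: every training embryo ",
         "needs a known true_class", call. = FALSE)
  }
  cid <- factor(tab$cohort_id, levels = unique(tab$cohort_id))
  idx <- split(seq_len(nrow(tab)), cid)
  list(P = as.matrix(tab[prob_cols]),
       idx = idx,
       true_class = tab$true_class,
       top = vapply(idx, function(i) max(tab$true_class[i]), integer(1)))
}

# Fitness of every row of W (m x 5) against prepared cohorts: the number of
# cohorts whose top-scored embryo (ties -> lowest index) has the highest
# class available in that cohort.
ga_fitness_all <- function(W, prep) {
  S <- prep$P %*% t(W)                       # embryos x specimens
  fit <- integer(nrow(W))
  for (j in seq_along(prep$idx)) {
    rows <- prep$idx[[j]]
    pick <- max.col(t(S[rows, , drop = FALSE]), ties.method = "first")
    fit <- fit + as.integer(prep$true_class[rows][pick] == prep$top[j])
  }
  fit
}

#' Fitness of a weight vector on labelled training cohorts
#'
#' For each cohort the embryo with the highest transfer score
#' \code{sum(w * p)} is picked (score ties broken by lowest embryo index);
#' the fitness is the number of cohorts whose pick belongs to the highest
#' morphology class available in that cohort.
#'
#' @param w a 5-element weight vector.
#' @param tab an \code{\link{embryo_table}} with known \code{true_class} for
#'   every embryo.
#' @return integer fitness in \code{0..n_cohorts}.
#' @export
ga_fitness <- function(w, tab) {
  ga_fitness_all(matrix(check_weights(w), nrow = 1), ga_prepare(tab))
}

#' Elitist truncation selection
#'
#' @param pop specimen matrix (rows are weight vectors).
#' @param fitness integer fitness per row.
#' @param elite_count how many to keep.
#' @return the \code{elite_count} rows with highest fitness, in descending
#'   fitness order; fitness ties are broken by earlier row index.
#' @export
ga_select_elite <- function(pop, fitness, elite_count) {
  if (is.null(fitness) || length(fitness) != nrow(pop)) {
    stop("fitness must be computed for every specimen", call. = FALSE)
  }
  keep <- order(-fitness)[seq_len(elite_count)]   # order() is stable on ties
  pop[keep, , drop = FALSE]
}

#' Uniform-mask crossover of two weight vectors
#'
#' With probability \code{prob} a random binary 5-mask is drawn (each bit 1
#' with probability \code{mask_prob}) and the masked components are swapped
#' between the parents; otherwise both are returned unchanged.
#'
#' @param a,b parent weight vectors.
#' @param prob probability that the crossover is applied at all.
#' @param mask_prob per-bit probability used to draw the swap mask.
#' @param mask optional explicit logical/0-1 mask of length 5, bypassing the
#'   random draw (the crossover is then always applied).
#' @return \code{list(a =, b =, applied =)}.
#' @export
ga_crossover <- function(a, b, prob = 0.20, mask_prob = 0.5, mask = NULL) {
  a <- check_weights(a); b <- check_weights(b)
  if (is.null(mask)) {
    if (stats::runif(1) >= prob) {
      return(list(a = a, b = b, applied = FALSE))
    }
    mask <- stats::runif(5) < mask_prob
  } else {
    mask <- as.logical(mask)
    stopifnot(length(mask) == 5L)
  }
  tmp <- a[mask]
  a[mask] <- b[mask]
  b[mask] <- tmp
  list(a = a, b = b, applied = TRUE)
}

#' Mutate one specimen into a batch of mutants
#'
#' Each mutant is the parent plus a perturbation vector whose components are
#' independently non-zero with probability \code{mutation_prob} and, when
#' non-zero, uniform on \code{[mutation_low, mutation_high]}.
#'
#' @param w parent weight vector.
#' @param config a \code{\link{ga_config}} (uses the mutation fields).
#' @return a matrix of \code{mutants_per_specimen} rows.
#' @export
ga_mutate <- function(w, config = ga_config()) {
  w <- check_weights(w)
  m <- config$mutants_per_specimen
  hit <- matrix(stats::runif(m * 5L) < config$mutation_prob, m, 5L)
  delta <- matrix(stats::runif(m * 5L, config$mutation_low,
                               config$mutation_high), m, 5L)
  matrix(w, m, 5L, byrow = TRUE) + hit * delta
}

# One breeding pass over the elite pool: pair elites by uniform random
# sampling without replacement; each pair crosses with crossover_prob;
# offspring replace their parents in the pool.
ga_breed <- function(elite, config) {
  n <- nrow(elite)
  perm <- sample.int(n)
  for (k in seq_len(n %/% 2L)) {
    i <- perm[2L * k - 1L]; j <- perm[2L * k]
    out <- ga_crossover(elite[i, ], elite[j, ],
                        prob = config$crossover_prob,
                        mask_prob = config$mask_prob)
    elite[i, ] <- out$a
    elite[j, ] <- out$b
  }
  elite
}

#' Learn scoring weights by genetic algorithm
#'
#' Runs the evaluate / select-elite / crossover / mutate cycle on labelled
#' training cohorts until every specimen in the population attains the same
#' fitness (convergence) or \code{max_generations} is hit.  Each new
#' generation consists of the (post-crossover) elites plus their mutants;
#' when that pool exceeds \code{population_size} the surplus is removed
#' uniformly at random from the mutants, so elites always survive.  The
#' returned weight vector is drawn uniformly at random from the final
#' population, as all its members are equivalent at convergence.
#'
#' @param tab an \code{\link{embryo_table}} with known true classes.
#' @param config a \code{\link{ga_config}}; \code{config$seed} (if set)
#'   makes the whole run reproducible.
#' @return an object of class \code{"ga_fit"}: a list with
#'   \code{weights} (numeric 5-vector), \code{generations},
#'   \code{converged}, \code{history} (best fitness per generation),
#'   \code{fitness} (of the returned weights), \code{n_cohorts} and
#'   \code{config}.
#' @examples
#' tab <- synth_cohorts(synth_config(n_cohorts = 20, seed = 1))
#' fit <- ga_evolve(tab, ga_config(max_generations = 50, seed = 1))
#' fit$weights
#' @export
ga_evolve <- function(tab, config = ga_config()) {
  prep <- ga_prepare(tab)
  if (!is.null(config$seed)) set.seed(config$seed)
  pop <- ga_initialize(config)
  history <- integer(0)
  converged <- FALSE
  gen <- 0L
  repeat {
    gen <- gen + 1L
    fit <- ga_fitness_all(pop, prep)
    history[gen] <- max(fit)
    if (all(fit == fit[1L])) {
      converged <- TRUE
      break
    }
    if (gen >= config$max_generations) break
    elite <- ga_select_elite(pop, fit, config$elite_count)
    elite <- ga_breed(elite, config)
    mutants <- do.call(rbind, lapply(seq_len(nrow(elite)), function(i) {
      ga_mutate(elite[i, ], config)
    }))
    pop <- rbind(elite, mutants)
    excess <- nrow(pop) - config$population_size
    if (excess > 0L && !config$keep_overflow) {
      drop_i <- nrow(elite) + sample.int(nrow(mutants), excess)
      pop <- pop[-drop_i, , drop = FALSE]
    }
  }
  pick <- sample.int(nrow(pop), 1L)
  w <- as.numeric(pop[pick, ])
  names(w) <- paste0("w", 1:5)
  structure(list(weights = w,
                 generations = gen,
                 converged = converged,
                 history = history,
                 fitness = ga_fitness_all(matrix(w, nrow = 1), prep),
                 n_cohorts = length(prep$idx),
                 config = config),
            class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat("Genetic-algorithm scoring weights\n")
  cat(sprintf("  weights:     %s\n",
              paste(formatC(x$weights, digits = 6, format = "g"),
                    collapse = ", ")))
  cat(sprintf("  fitness:     %d / %d training cohorts topped\n",
              x$fitness, x$n_cohorts))
  cat(sprintf("  generations: %d (%s)\n", x$generations,
              if (x$converged) "population converged" else
                "stopped at max_generations"))
  invisible(x)
}
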