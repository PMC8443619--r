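# Joint evolutionary learning of the rule set and the conceptual-label
# numeric ranges.  A genome ("phenotype") concatenates, for each of Q
# candidate patterns, Amax channel genes (0 = don't care), Amax label genes
# and one consequent gene, followed by 16 real-valued breakpoint genes per
# channel.  The fitness is 1 - mean k-fold validation MCC; the k-fold split
# is fixed before the run and no information flows between training folds.

#' Genetic algorithm configuration
#'
#' Defaults follow the reference settings where stated (population 200,
#' tolerance 1e-5, at most 20 patterns of up to 3 antecedents, 5 folds,
#' tournament selection); operator rates and the generation cap are this
#' implementation's defaults.
#'
#' @param population_size Number of individuals per generation.
#' @param tolerance Absolute cost threshold stopping the run early.
#' @param max_generations Generation cap (the tolerance alone may never
#'   trigger).
#' @param tournament_size Individuals drawn per tournament.
#' @param crossover_rate Probability a child is produced by uniform per-gene
#'   crossover rather than cloning.
#' @param mutation_rate Per-gene mutation probability; default `1/length`.
#' @param Q Maximum number of patterns.
#' @param Amax Maximum antecedents per pattern.
#' @param k_folds Cross-validation folds used inside the cost.
#' @param rng_seed Integer seed making the whole run reproducible.
#' @param elitism Number of best individuals copied unchanged.
#' @param delta_sd_frac Gaussian mutation s.d. for breakpoint genes, as a
#'   fraction of the channel's data range.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 200L, tolerance = 1e-5,
                      max_generations = 500L, tournament_size = 3L,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      Q = 20L, Amax = 3L, k_folds = 5L, rng_seed = 1L,
                      elitism = 1L, delta_sd_frac = 0.1) {
  cfg <- list(population_size = as.integer(population_size),
              tolerance = tolerance,
              max_generations = as.integer(max_generations),
              tournament_size = as.integer(tournament_size),
              crossover_rate = crossover_rate,
              mutation_rate = mutation_rate,
              Q = as.integer(Q), Amax = as.integer(Amax),
              k_folds = as.integer(k_folds),
              rng_seed = as.integer(rng_seed),
              elitism = as.integer(elitism),
              delta_sd_frac = delta_sd_frac)
  with(cfg, {
    if (population_size < 2L || Q < 1L || Amax < 1L || k_folds < 2L ||
        tournament_size < 1L || max_generations < 0L || elitism < 0L)
      stop("ga_config: sizes must be positive", call. = FALSE)
    if (tolerance <= 0) stop("ga_config: tolerance must be > 0", call. = FALSE)
  })
  structure(cfg, class = "ga_config")
}

#' Genome length of the joint encoding
#'
#' `Q * (2 * Amax + 1)` pattern genes plus `16 * n_channels` conceptual-label
#' breakpoint genes.  With the defaults (Q = 20, Amax = 3) and 10 channels
#' this is 140 + 160 = 300.
#'
#' @param Q Maximum number of patterns.
#' @param Amax Maximum antecedents per pattern.
#' @param n_channels Number of channels.
#' @return Integer genome length.
#' @export
phenotype_length <- function(Q, Amax, n_channels) {
  if (any(c(Q, Amax, n_channels) < 1))
    stop("all arguments must be positive integers", call. = FALSE)
  as.integer(Q * (2 * Amax + 1) + 16 * n_channels)
}

.pattern_block_len <- function(cfg) cfg$Q * (2L * cfg$Amax + 1L)

#' Decode a genome into a rule base skeleton and concept bank
#'
#' Channel genes equal to 0 are "don't care" slots; duplicate channels within
#' a pattern keep their first occurrence; patterns with no remaining
#' antecedents are dropped.  The concept block is repaired channel by
#' channel, so any finite real genome decodes to a valid model.
#'
#' @param ph Numeric genome of length `phenotype_length(Q, Amax, n)`.
#' @param cfg A [ga_config()].
#' @param classes The two stimulus classes (consequent gene 1 maps to the
#'   first).
#' @param channel_ids Channel identifiers, length n.
#' @return List with `patterns` (unfitted [xmvpa_pattern()]s) and `bank`.
#' @export
decode_phenotype <- function(ph, cfg, classes, channel_ids) {
  n <- length(channel_ids)
  want <- phenotype_length(cfg$Q, cfg$Amax, n)
  if (length(ph) != want)
    stop("genome length ", length(ph), " != expected ", want, call. = FALSE)
  pb <- .pattern_block_len(cfg)
  lev <- col_levels()
  patterns <- list()
  for (q in seq_len(cfg$Q)) {
    off <- (q - 1L) * (2L * cfg$Amax + 1L)
    phi <- as.integer(round(ph[off + seq_len(cfg$Amax)]))
    lam <- as.integer(round(ph[off + cfg$Amax + seq_len(cfg$Amax)]))
    gam <- as.integer(round(ph[off + 2L * cfg$Amax + 1L]))
    keep <- phi >= 1L & phi <= n
    phi <- phi[keep]; lam <- lam[keep]
    dup <- duplicated(phi)
    phi <- phi[!dup]; lam <- lam[!dup]
    if (!length(phi)) next
    lam <- pmin(pmax(lam, 1L), 3L)
    gam <- pmin(pmax(gam, 1L), 2L)
    patterns[[length(patterns) + 1L]] <-
      xmvpa_pattern(channel_ids[phi], lev[lam], classes[gam])
  }
  bank <- vector_to_bank(ph[(pb + 1L):length(ph)], channel_ids)
  list(patterns = patterns, bank = bank)
}

#' Encode a rule base skeleton and bank into a canonical genome
#'
#' Inverse of [decode_phenotype()] up to canonical form: antecedents occupy
#' the leading slots, unused slots carry the don't-care channel 0 with label
#' gene 1, unused pattern blocks are all-zero.
#'
#' @param patterns List of [xmvpa_pattern()] objects (at most `cfg$Q`).
#' @param bank A [concept_bank()].
#' @param cfg A [ga_config()].
#' @param classes The two stimulus classes.
#' @return Numeric genome.
#' @export
encode_phenotype <- function(patterns, bank, cfg, classes) {
  n <- bank$n_channels
  ph <- numeric(phenotype_length(cfg$Q, cfg$Amax, n))
  if (length(patterns) > cfg$Q) stop("more patterns than Q", call. = FALSE)
  for (q in seq_along(patterns)) {
    p <- patterns[[q]]
    off <- (q - 1L) * (2L * cfg$Amax + 1L)
    phi <- match(p$channels, bank$channel_ids)
    lam <- match(p$cols, col_levels())
    slots <- seq_along(phi)
    ph[off + slots] <- phi
    ph[off + cfg$Amax + seq_len(cfg$Amax)] <- 1
    ph[off + cfg$Amax + slots] <- lam
    ph[off + 2L * cfg$Amax + 1L] <- match(p$consequent, classes)
  }
  ph[(.pattern_block_len(cfg) + 1L):length(ph)] <- bank_to_vector(bank)
  ph
}

#' Draw a random genome
#'
#' Pattern genes are drawn uniformly (channel slots are don't-care with
#' probability `p_dontcare`); concept genes are drawn around
#' `delta_center` (e.g. the [default_bank()] vector) with Gaussian jitter.
#'
#' @param cfg A [ga_config()].
#' @param n_channels Number of channels.
#' @param delta_center Numeric vector of length `16 * n_channels`; default 0.
#' @param delta_jitter Per-gene jitter s.d. (scalar or vector); default 1.
#' @param p_dontcare Probability a channel slot is empty.
#' @return Numeric genome (uses the ambient RNG stream).
#' @export
random_phenotype <- function(cfg, n_channels, delta_center = NULL,
                             delta_jitter = 1, p_dontcare = 0.25) {
  pb <- .pattern_block_len(cfg)
  nd <- 16L * n_channels
  if (is.null(delta_center)) delta_center <- numeric(nd)
  ph <- numeric(pb + nd)
  for (q in seq_len(cfg$Q)) {
    off <- (q - 1L) * (2L * cfg$Amax + 1L)
    empty <- stats::runif(cfg$Amax) < p_dontcare
    ph[off + seq_len(cfg$Amax)] <-
      ifelse(empty, 0L, sample.int(n_channels, cfg$Amax, replace = TRUE))
    ph[off + cfg$Amax + seq_len(cfg$Amax)] <- sample.int(3L, cfg$Amax,
                                                         replace = TRUE)
    ph[off + 2L * cfg$Amax + 1L] <- sample.int(2L, 1L)
  }
  ph[(pb + 1L):(pb + nd)] <- delta_center +
    stats::rnorm(nd, 0, delta_jitter)
  ph
}

#' Cost of a genome: one minus the mean k-fold validation MCC
#'
#' For each fold the dominance scores are fitted on the training fold and
#' the held-out fold is classified; the Matthews correlation coefficient of
#' each held-out fold is averaged.  Unclassified trials are scored as the
#' wrong class.  A genome decoding to an empty rule base leaves every trial
#' unclassified and therefore gets the worst cost.
#'
#' @param ph Numeric genome.
#' @param matrix An [mv_matrix()] with two classes.
#' @param cfg A [ga_config()].
#' @param folds Optional precomputed fold vector (from [make_folds()]);
#'   default derives it from `cfg$rng_seed` so repeated calls agree.
#' @return Numeric cost in `[0, 2]`.
#' @export
ga_cost <- function(ph, matrix, cfg, folds = NULL) {
  stopifnot(inherits(matrix, "mv_matrix"), inherits(cfg, "ga_config"))
  if (is.null(folds)) folds <- make_folds(matrix$labels, cfg$k_folds,
                                          cfg$rng_seed)
  dec <- decode_phenotype(ph, cfg, matrix$classes, matrix$channel_ids)
  .cost_decoded(dec, matrix, folds)
}

.cost_decoded <- function(dec, matrix, folds) {
  k <- max(folds)
  if (!length(dec$patterns)) return(2)        # nothing ever classified
  fz <- .fuzzify_values(dec$bank, matrix$values)
  w <- .strength_matrices(dec$patterns, dec$bank, fz)
  consequents <- vapply(dec$patterns, `[[`, character(1), "consequent")
  labels <- matrix$labels
  positive <- matrix$classes[1]
  mccs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(labels[!tr])) < 2L || length(unique(labels[tr])) < 2L) {
      warning("fold ", f, " has a single class; its MCC is set to 0",
              call. = FALSE)
      mccs[f] <- 0
      next
    }
    tab <- .fit_ds_table(list(lower = w$lower[tr, , drop = FALSE],
                              upper = w$upper[tr, , drop = FALSE]),
                         labels[tr], consequents)
    cls <- .classify_engine(list(lower = w$lower[!tr, , drop = FALSE],
                                 upper = w$upper[!tr, , drop = FALSE]),
                            tab$ds_lower, tab$ds_upper)
    pred <- ifelse(is.na(cls$winner), unclassified_label(),
                   consequents[cls$winner])
    mccs[f] <- mcc(confusion(labels[!tr], pred, positive))
  }
  1 - mean(mccs)
}

#' Fit the explainable classifier by evolutionary search
#'
#' Runs the genetic algorithm: tournament selection, uniform per-gene
#' crossover, random-reset mutation for the integer pattern genes and
#' Gaussian perturbation for the concept breakpoint genes (repaired at
#' decode).  The best individual is kept unchanged each generation, so the
#' best cost is non-increasing.  The run stops when the best cost drops
#' below `cfg$tolerance` or at the generation cap, and is fully reproducible
#' from `cfg$rng_seed`.
#'
#' @param matrix An [mv_matrix()] with two classes and at least
#'   `2 * k_folds` trials.
#' @param cfg A [ga_config()].
#' @param verbose Print per-generation progress.
#' @return An object of class `xmvpa`: list with the fitted `rule_base`
#'   (dominance scores refitted on all trials), `bank`, `history` data frame
#'   (`generation`, `best_cost`, `mean_cost`), `best_cost`, `cv_mcc`
#'   (`1 - best_cost`), `folds`, `phenotype` and `config`.
#' @export
xmvpa_fit <- function(matrix, cfg = ga_config(), verbose = FALSE) {
  stopifnot(inherits(matrix, "mv_matrix"), inherits(cfg, "ga_config"))
  if (length(matrix$classes) != 2L)
    stop("fitting needs exactly two classes", call. = FALSE)
  if (nrow(matrix$values) < 2L * cfg$k_folds)
    stop("need at least 2 * k_folds trials", call. = FALSE)
  folds <- make_folds(matrix$labels, cfg$k_folds, cfg$rng_seed)
  n <- ncol(matrix$values)
  pb <- .pattern_block_len(cfg)
  len <- phenotype_length(cfg$Q, cfg$Amax, n)
  mu <- cfg$mutation_rate %||% (1 / len)

  delta_center <- bank_to_vector(default_bank(matrix))
  ranges <- apply(matrix$values, 2L, function(v) diff(range(v)))
  delta_sd <- rep(ranges * cfg$delta_sd_frac, each = 16L)
  classes <- matrix$classes

  eval_cost <- function(ph)
    .cost_decoded(decode_phenotype(ph, cfg, classes, matrix$channel_ids),
                  matrix, folds)

  .with_seed(cfg$rng_seed, {
    pop <- lapply(seq_len(cfg$population_size), function(i)
      random_phenotype(cfg, n, delta_center, delta_jitter = delta_sd * 2))
    costs <- vapply(pop, eval_cost, numeric(1))
    hist_best <- numeric(0); hist_mean <- numeric(0)
    gen <- 0L
    repeat {
      hist_best <- c(hist_best, min(costs))
      hist_mean <- c(hist_mean, mean(costs))
      if (verbose)
        message(sprintf("generation %d: best %.4f mean %.4f", gen,
                        min(costs), mean(costs)))
      if (min(costs) < cfg$tolerance || gen >= cfg$max_generations) break
      elite <- order(costs)[seq_len(min(cfg$elitism, length(pop)))]
      newpop <- pop[elite]
      newcosts <- costs[elite]
      while (length(newpop) < cfg$population_size) {
        p1 <- pop[[.tournament(costs, cfg$tournament_size)]]
        child <- if (stats::runif(1) < cfg$crossover_rate) {
          p2 <- pop[[.tournament(costs, cfg$tournament_size)]]
          mask <- stats::runif(len) < 0.5
          ifelse(mask, p1, p2)
        } else p1
        child <- .mutate(child, cfg, n, mu, pb, delta_sd)
        newpop[[length(newpop) + 1L]] <- child
        newcosts <- c(newcosts, NA_real_)
      }
      todo <- which(is.na(newcosts))
      newcosts[todo] <- vapply(newpop[todo], eval_cost, numeric(1))
      pop <- newpop
      costs <- newcosts
      gen <- gen + 1L
    }
    best <- which.min(costs)
    dec <- decode_phenotype(pop[[best]], cfg, classes, matrix$channel_ids)
    rb <- rule_base(dec$patterns, dec$bank, classes)
    rb <- fit_dominance(rb, matrix)
    structure(list(rule_base = rb, bank = dec$bank,
                   history = data.frame(generation = seq_along(hist_best) - 1L,
                                        best_cost = hist_best,
                                        mean_cost = hist_mean),
                   best_cost = costs[best], cv_mcc = 1 - costs[best],
                   folds = folds, phenotype = pop[[best]], config = cfg),
              class = "xmvpa")
  })
}

.tournament <- function(costs, size) {
  cand <- sample.int(length(costs), min(size, length(costs)))
  cand[which.min(costs[cand])]
}

.mutate <- function(ph, cfg, n, mu, pb, delta_sd) {
  hit <- which(stats::runif(length(ph)) < mu)
  if (!length(hit)) return(ph)
  blk <- 2L * cfg$Amax + 1L
  for (g in hit) {
    if (g > pb) {
      ph[g] <- ph[g] + stats::rnorm(1, 0, delta_sd[g - pb])
    } else {
      pos <- (g - 1L) %% blk + 1L
      ph[g] <- if (pos <= cfg$Amax) sample(0:n, 1L)            # channel
               else if (pos <= 2L * cfg$Amax) sample.int(3L, 1L)  # label
               else sample.int(2L, 1L)                            # consequent
    }
  }
  ph
}

#' @export
print.xmvpa <- function(x, ...) {
  cat("<xmvpa> cross-validated MCC ", round(x$cv_mcc, 4), " after ",
      max(x$history$generation), " generation(s)\n", sep = "")
  print(x$rule_base)
  invisible(x)
}

#' @export
predict.xmvpa <- function(object, newdata, ...) {
  predict(object$rule_base, newdata)
}
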