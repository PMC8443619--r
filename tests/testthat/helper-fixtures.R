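# Shared fixtures: all built in code, no files.

# a crisp two-channel bank: labels tile [0, 3) with boundaries at 0.5/1.5
crisp_bank <- function(n_channels = 2L) {
  sets <- lapply(seq_len(n_channels), function(j)
    channel_concept_set(
      j,
      inactive    = repair_mf("left_shoulder", c(0.5, 0.5), c(0.5, 0.5)),
      active      = repair_mf("trapezium", c(0.5, 0.5, 1.5, 1.5),
                              c(0.5, 0.5, 1.5, 1.5)),
      very_active = repair_mf("right_shoulder", c(1.5, 1.5), c(1.5, 1.5))))
  concept_bank(sets)
}

# random raw 16-parameter channel block on an interesting scale
random_params16 <- function() stats::rnorm(16, 0, 2)

# random repaired IT2 membership function of a random shape
random_mf <- function() {
  shape <- sample(c("left_shoulder", "trapezium", "right_shoulder"), 1)
  np <- if (shape == "trapezium") 4L else 2L
  repair_mf(shape, stats::rnorm(np, 0, 2), stats::rnorm(np, 0, 2))
}

# small labelled feature matrix with an obvious class split on channel 1
toy_matrix <- function(n = 8L) {
  lab <- rep(c("A", "B"), length.out = n)
  v1 <- ifelse(lab == "A", 1, 2)          # A sits in "active", B "very active"
  v2 <- rep(1, n)
  mv_matrix(cbind(v1, v2), lab, channel_ids = 1:2)
}

# random fitted rule base over a random repaired bank (for oracle tests)
random_fitted_rule_base <- function(n_channels = 4L, n_patterns = 5L,
                                    n_train = 30L) {
  bank <- vector_to_bank(stats::rnorm(16L * n_channels, 0, 2),
                         seq_len(n_channels))
  classes <- c("A", "B")
  patterns <- lapply(seq_len(n_patterns), function(q) {
    na <- sample.int(3L, 1L)
    xmvpa_pattern(sample.int(n_channels, na),
                  sample(col_levels(), na, replace = TRUE),
                  sample(classes, 1L))
  })
  train <- mv_matrix(matrix(stats::rnorm(n_train * n_channels, 0, 2),
                            n_train),
                     rep_len(classes, n_train),
                     channel_ids = seq_len(n_channels))
  fit_dominance(rule_base(patterns, bank, classes), train)
}

# independent slow classifier: per-instance loop over patterns using the
# scalar public operations, with the documented tie-break
brute_force_classify <- function(rb, m) {
  vals <- m$values
  vapply(seq_len(nrow(vals)), function(i) {
    x <- stats::setNames(vals[i, ], rb$bank$channel_ids)
    h <- vapply(rb$patterns, association_degree, numeric(1),
                bank = rb$bank, x = x)
    if (all(h == 0)) return(unclassified_label())
    ds <- vapply(rb$patterns, `[[`, numeric(1), "ds_point")
    best <- which(h == max(h))
    best <- best[order(-ds[best], best)][1]
    rb$patterns[[best]]$consequent
  }, character(1))
}

# dense-grid check that mu_lower <= mu_upper everywhere for a repaired mf
nesting_holds <- function(mf, from = -8, to = 8, n = 400L) {
  g <- seq(from, to, length.out = n)
  g <- sort(c(g, mf$upper, mf$lower))     # include breakpoints
  mu <- membership_interval(mf, g)
  all(mu$lower <= mu$upper + 1e-12) && all(mu$lower >= 0) &&
    all(mu$upper <= 1)
}
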