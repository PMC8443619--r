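# Synthetic fNIRS-like data with planted, recoverable rule structure.  The
# defaults mirror the reference study's dimensions: 19 subjects, 524 trials,
# 10 channels, two stimulus classes.  Channel features are class-conditional
# Gaussians centred on the target activity level of each planted antecedent
# (inactive / active / very active), plus subject random intercepts to
# emulate inter-subject variability.

#' Default planted rules
#'
#' Two rules, one per class, in the spirit of the occipital/temporal
#' visual-auditory dissociation: the first class activates channels 1, 2 and
#' 4; the second class deactivates channel 1 and activates channel 9.
#' With fewer channels the antecedents are clipped into `1..n_channels`.
#'
#' @param classes The two class labels.
#' @param n_channels Number of channels available.
#' @return List of planted rules (`channels`, `cols`, `class`).
#' @export
default_planted_rules <- function(classes = c("Visual", "Auditory"),
                                  n_channels = 10L) {
  ch_vis <- unique(pmin(c(1, 2, 4), n_channels))
  ch_aud <- unique(c(1, min(9, n_channels)))
  list(list(channels = ch_vis,
            cols = rep("active", length(ch_vis)),
            class = classes[1]),
       list(channels = ch_aud,
            cols = c("inactive", "active")[seq_along(ch_aud)],
            class = classes[2]))
}

#' Specify a synthetic dataset
#'
#' @param n_subjects Number of subjects (default 19).
#' @param n_trials Total number of trials (default 524).
#' @param n_channels Number of channels (default 10).
#' @param classes The two stimulus class labels.
#' @param planted_rules List of planted rules as in
#'   [default_planted_rules()]; `NULL` or `list()` plants no signal
#'   (label-independent channels).
#' @param noise_sd Trial-level Gaussian noise s.d. around each channel's
#'   target level (default 0.3; with unit level spacing the adjacent levels
#'   are separated by more than 3 s.d.).
#' @param subject_sd S.d. of the per-subject random intercept (default 0.1).
#' @param level_spacing Distance between adjacent activity-level centres
#'   (inactive 0, active 1, very active 2, times this spacing; arbitrary
#'   HbO2 concentration-change units).
#' @param sample_rate Sampling rate in Hz for time-series mode (default 10).
#' @param epoch_span Epoch extent in seconds relative to stimulus onset
#'   (default -2..12, covering the 4-7 s analysis window).
#' @param epoch_noise_sd White-noise s.d. added to each time sample.
#' @param window Analysis window the epochs must cover.
#' @param rng_seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 19L, n_trials = 524L,
                           n_channels = 10L,
                           classes = c("Visual", "Auditory"),
                           planted_rules = default_planted_rules(classes,
                                                                 n_channels),
                           noise_sd = 0.3, subject_sd = 0.1,
                           level_spacing = 1,
                           sample_rate = 10, epoch_span = c(-2, 12),
                           epoch_noise_sd = 0.05, window = c(4, 7),
                           rng_seed = 1L) {
  if (length(classes) != 2L) stop("exactly two classes", call. = FALSE)
  if (n_subjects < 1L || n_trials < n_subjects || n_channels < 1L)
    stop("need n_subjects >= 1 and at least one trial per subject",
         call. = FALSE)
  planted_rules <- planted_rules %||% list()
  maps <- list()
  for (r in planted_rules) {
    if (!all(r$channels >= 1 & r$channels <= n_channels))
      stop("planted rule references channel outside 1..", n_channels,
           call. = FALSE)
    if (!all(r$cols %in% col_levels()))
      stop("planted rule uses unknown conceptual label", call. = FALSE)
    if (!r$class %in% classes)
      stop("planted rule consequent is not a known class", call. = FALSE)
    m <- maps[[r$class]] %||% character(0)
    for (a in seq_along(r$channels)) {
      key <- as.character(r$channels[a])
      if (!is.null(m[key]) && !is.na(m[key]) && m[key] != r$cols[a])
        stop("contradictory planted rules: channel ", key, " assigned both ",
             m[key], " and ", r$cols[a], " for class ", r$class,
             call. = FALSE)
      m[key] <- r$cols[a]
    }
    maps[[r$class]] <- m
  }
  if (length(planted_rules) &&
      length(maps) == 2L && identical(maps[[classes[1]]], maps[[classes[2]]]))
    stop("contradictory planted rules: both classes imply the same ",
         "channel-level assignments (no discriminating channel)",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 classes = classes, planted_rules = planted_rules,
                 class_maps = maps,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 level_spacing = level_spacing,
                 sample_rate = sample_rate, epoch_span = epoch_span,
                 epoch_noise_sd = epoch_noise_sd, window = window,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

.level_centers <- function(spec)
  stats::setNames(c(0, 1, 2) * spec$level_spacing, col_levels())

# crisp ground-truth concept bank: upper = lower, boundaries midway between
# adjacent level centres
.truth_bank <- function(spec) {
  s <- spec$level_spacing
  sets <- lapply(seq_len(spec$n_channels), function(j)
    channel_concept_set(
      j,
      inactive    = repair_mf("left_shoulder", c(0.4, 0.6) * s,
                              c(0.4, 0.6) * s),
      active      = repair_mf("trapezium", c(0.4, 0.6, 1.4, 1.6) * s,
                              c(0.4, 0.6, 1.4, 1.6) * s),
      very_active = repair_mf("right_shoulder", c(1.4, 1.6) * s,
                              c(1.4, 1.6) * s)))
  concept_bank(sets)
}

#' Generate a synthetic multivariate matrix with planted rules
#'
#' Classes alternate in balanced proportion.  Channels named by a planted
#' rule of the trial's class are drawn from a Gaussian centred on the target
#' level; unnamed channels draw their level uniformly at random
#' (class-independent, so they carry no signal).  A per-subject random
#' intercept is added to every channel.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (an [mv_matrix()]) and `truth` (a fitted
#'   [rule_base()] holding the planted patterns over a crisp ground-truth
#'   concept bank, for recovery scoring).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$rng_seed, .generate_matrix_impl(spec))
}

.generate_matrix_impl <- function(spec) {
  centers <- .level_centers(spec)
  n <- spec$n_trials
  labels <- sample(rep_len(spec$classes, n))
  subject <- sort(rep_len(seq_len(spec$n_subjects), n))
  intercept <- stats::rnorm(spec$n_subjects, 0, spec$subject_sd)
  vals <- base::matrix(0, n, spec$n_channels,
                       dimnames = list(NULL, seq_len(spec$n_channels)))
  for (i in seq_len(n)) {
    m <- spec$class_maps[[labels[i]]]
    lvl <- col_levels()[sample.int(3L, spec$n_channels, replace = TRUE)]
    if (!is.null(m)) lvl[as.integer(names(m))] <- m
    vals[i, ] <- centers[lvl] + intercept[subject[i]] +
      stats::rnorm(spec$n_channels, 0, spec$noise_sd)
  }
  mat <- mv_matrix(vals, labels, channel_ids = seq_len(spec$n_channels),
                   subject_id = subject, window = spec$window,
                   classes = spec$classes)
  truth <- NULL
  if (length(spec$planted_rules)) {
    patterns <- lapply(spec$planted_rules, function(r)
      xmvpa_pattern(r$channels, r$cols, r$class))
    truth <- fit_dominance(rule_base(patterns, .truth_bank(spec),
                                     spec$classes), mat)
  }
  list(matrix = mat, truth = truth)
}

# gamma-shaped haemodynamic kernel, zero before onset, peaking inside the
# analysis window; normalised so its discrete mean over the window is 1
.hrf_kernel <- function(times, window) {
  k <- stats::dgamma(pmax(times, 0), shape = 7, rate = 1.25)
  win <- times >= window[1] - 1e-9 & times <= window[2] + 1e-9
  k / mean(k[win])
}

#' Generate synthetic epoched time series
#'
#' Each trial's channel trace is a canonical haemodynamic-shaped bump scaled
#' by the trial's planted feature amplitude plus white noise.  The kernel's
#' discrete mean over the analysis window is normalised to 1, so
#' [window_mean_matrix()] recovers the planted amplitudes exactly at zero
#' noise and within noise tolerance otherwise.
#'
#' @param spec A [synthetic_spec()] whose `epoch_span` covers `window`.
#' @return List with `epochs` (an [epoch_set()]), `matrix` (the planted
#'   amplitude [mv_matrix()]) and `truth` (as in [generate_matrix()]).
#' @export
generate_epochs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$epoch_span[1] > spec$window[1] ||
      spec$epoch_span[2] < spec$window[2])
    stop("epoch span must cover the analysis window", call. = FALSE)
  .with_seed(spec$rng_seed, {
    gm <- .generate_matrix_impl(spec)
    times <- seq(spec$epoch_span[1], spec$epoch_span[2],
                 by = 1 / spec$sample_rate)
    kern <- .hrf_kernel(times, spec$window)
    nt <- length(times)
    m <- gm$matrix
    n <- nrow(m$values)
    nch <- spec$n_channels
    rows <- n * nch * nt
    amp <- m$values[rep(seq_len(n), each = nch * nt) +
                    (rep(rep(seq_len(nch), each = nt), n) - 1L) * n]
    value <- amp * rep.int(kern, n * nch) +
      stats::rnorm(rows, 0, spec$epoch_noise_sd)
    d <- data.frame(
      trial_id = rep(m$trial_id, each = nch * nt),
      subject_id = rep(m$subject_id, each = nch * nt),
      label = rep(m$labels, each = nch * nt),
      channel = rep(rep(m$channel_ids, each = nt), n),
      time_s = rep.int(times, n * nch),
      value = value)
    list(epochs = epoch_set(d, sample_rate = spec$sample_rate),
         matrix = m, truth = gm$truth)
  })
}
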