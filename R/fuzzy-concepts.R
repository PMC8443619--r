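# Interval type-2 (IT2) conceptual labels: each channel's activity level is
# described by three fuzzy sets -- "inactive" (left shoulder), "active"
# (trapezium), "very active" (right shoulder) -- whose membership at any point
# is an interval [mu_lower, mu_upper].  The numeric breakpoints of these sets
# are free parameters (16 per channel) learned by the genetic algorithm.

#' Conceptual label names
#'
#' The three linguistic activity levels used throughout the package, in their
#' fixed order: `inactive`, `active`, `very_active`.
#'
#' @return Character vector of length 3.
#' @export
col_levels <- function() c("inactive", "active", "very_active")

# shape assigned to each conceptual label (fixed by the method)
.col_shapes <- c(inactive = "left_shoulder",
                 active = "trapezium",
                 very_active = "right_shoulder")

# number of breakpoints per bound for each shape
.shape_np <- c(left_shoulder = 2L, trapezium = 4L, right_shoulder = 2L)

#' Construct an interval type-2 membership function
#'
#' An IT2 set is realised as a nested pair of piecewise-linear type-1
#' membership functions: an upper and a lower bound.  Shoulders carry 2
#' breakpoints per bound (the sloped edge), trapezia carry 4 (so a full
#' conceptual-label triple costs 4 + 8 + 4 = 16 scalars per channel).
#'
#' Breakpoints must already be "repaired": non-decreasing within each bound
#' and with the lower function nested inside the upper so that
#' `mu_lower(x) <= mu_upper(x)` for every `x`.  Use [repair_mf()] to coerce
#' arbitrary real vectors into this form.
#'
#' @param shape One of `"left_shoulder"`, `"trapezium"`, `"right_shoulder"`.
#' @param upper Numeric breakpoints of the upper membership function.
#' @param lower Numeric breakpoints of the lower membership function.
#' @return An object of class `it2_mf`.
#' @seealso [membership_interval()], [repair_mf()]
#' @export
it2_mf <- function(shape, upper, lower) {
  np <- .shape_np[[shape]]
  if (is.null(np))
    stop("unknown shape '", shape, "'", call. = FALSE)
  upper <- as.numeric(upper)
  lower <- as.numeric(lower)
  if (length(upper) != np || length(lower) != np)
    stop("'", shape, "' requires ", np, " breakpoints per bound, got ",
         length(upper), "/", length(lower), call. = FALSE)
  if (!all(is.finite(upper)) || !all(is.finite(lower)))
    stop("membership breakpoints must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (is.unsorted(upper) || is.unsorted(lower))
    stop("membership breakpoints must be non-decreasing; call repair_mf()",
         call. = FALSE)
  ok <- switch(shape,
    left_shoulder  = all(lower <= upper),
    right_shoulder = all(lower >= upper),
    trapezium      = lower[1] >= upper[1] && lower[2] >= upper[2] &&
                     lower[2] <= upper[3] &&
                     lower[3] <= upper[3] && lower[4] <= upper[4])
  if (!ok)
    stop("lower membership function is not nested inside the upper; ",
         "call repair_mf()", call. = FALSE)
  structure(list(shape = shape, upper = upper, lower = lower),
            class = "it2_mf")
}

#' @export
print.it2_mf <- function(x, ...) {
  cat("<it2_mf ", x$shape, ">\n  upper: ",
      paste(signif(x$upper, 4), collapse = ", "),
      "\n  lower: ", paste(signif(x$lower, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# piecewise-linear primitives; degenerate zero-width edges become steps
.eval_shoulder_down <- function(x, a, b) {
  y <- numeric(length(x))
  y[x <= a] <- 1
  mid <- x > a & x < b
  if (any(mid)) y[mid] <- (b - x[mid]) / (b - a)
  y
}

.eval_shoulder_up <- function(x, a, b) {
  y <- numeric(length(x))
  y[x >= b] <- 1
  mid <- x > a & x < b
  if (any(mid)) y[mid] <- (x[mid] - a) / (b - a)
  y
}

.eval_trapezium <- function(x, p) {
  y <- numeric(length(x))
  y[x >= p[2] & x <= p[3]] <- 1
  ris <- x > p[1] & x < p[2]
  if (any(ris)) y[ris] <- (x[ris] - p[1]) / (p[2] - p[1])
  fal <- x > p[3] & x < p[4]
  if (any(fal)) y[fal] <- (p[4] - x[fal]) / (p[4] - p[3])
  y
}

.eval_bound <- function(shape, p, x) {
  switch(shape,
    left_shoulder  = .eval_shoulder_down(x, p[1], p[2]),
    right_shoulder = .eval_shoulder_up(x, p[1], p[2]),
    trapezium      = .eval_trapezium(x, p))
}

#' Evaluate an IT2 membership interval
#'
#' Evaluates both bounds of an interval type-2 membership function at the
#' given points.  Left of a left shoulder (and right of a right shoulder)
#' membership is 1; outside the support it is 0.
#'
#' @param mf An [it2_mf()] object (repaired).
#' @param x Numeric vector of feature values.
#' @return A list with numeric components `lower` and `upper`, each the same
#'   length as `x`, satisfying `0 <= lower <= upper <= 1` elementwise.
#' @examples
#' mf <- it2_mf("left_shoulder", upper = c(0, 1), lower = c(0, 0.5))
#' membership_interval(mf, c(-1, 0.25, 2))
#' @export
membership_interval <- function(mf, x) {
  if (!inherits(mf, "it2_mf")) stop("'mf' must be an it2_mf object")
  x <- as.numeric(x)
  if (anyNA(x)) stop("'x' contains NA/NaN")
  list(lower = .eval_bound(mf$shape, mf$lower, x),
       upper = .eval_bound(mf$shape, mf$upper, x))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Repair raw breakpoints into a valid IT2 membership function
#'
#' The genetic algorithm proposes unordered real vectors; this deterministic
#' repair sorts each bound's breakpoints and clips the lower function into the
#' upper one so the nesting invariant `mu_lower <= mu_upper` holds everywhere.
#' The map is idempotent: repairing a repaired set is a no-op.
#'
#' @param shape Shape name as in [it2_mf()].
#' @param upper,lower Raw numeric breakpoints (finite, any order).
#' @return A valid [it2_mf()] object.
#' @export
repair_mf <- function(shape, upper, lower) {
  if (is.null(.shape_np[[shape]]))
    stop("unknown shape '", shape, "'", call. = FALSE)
  u <- sort(as.numeric(upper))
  l <- sort(as.numeric(lower))
  if (!all(is.finite(u)) || !all(is.finite(l)))
    stop("membership breakpoints must be finite", call. = FALSE)
  if (shape == "left_shoulder") {
    l <- pmin(l, u)                      # lower edge falls no later than upper
  } else if (shape == "right_shoulder") {
    l <- pmax(l, u)                      # lower edge rises no earlier
  } else {
    l[1] <- .clamp(l[1], u[1], u[3])
    l[2] <- .clamp(max(l[2], l[1]), u[2], u[3])
    l[3] <- .clamp(l[3], l[2], u[3])
    l[4] <- .clamp(l[4], l[3], u[4])
  }
  it2_mf(shape, u, l)
}

#' Build one channel's conceptual-label set
#'
#' Bundles the three conceptual labels of a channel.  The order and shapes are
#' fixed: *inactive* (left shoulder, 4 scalars), *active* (trapezium, 8),
#' *very active* (right shoulder, 4) -- 16 scalars in total.
#'
#' @param channel_id Channel identifier (kept as given; typically 1..n).
#' @param inactive,active,very_active [it2_mf()] objects of the right shapes.
#' @return An object of class `channel_concept_set`.
#' @export
channel_concept_set <- function(channel_id, inactive, active, very_active) {
  mfs <- list(inactive = inactive, active = active, very_active = very_active)
  for (nm in names(mfs)) {
    mf <- mfs[[nm]]
    if (!inherits(mf, "it2_mf") || mf$shape != .col_shapes[[nm]])
      stop("'", nm, "' must be an it2_mf of shape ", .col_shapes[[nm]],
           call. = FALSE)
  }
  structure(c(list(channel_id = channel_id), mfs),
            class = "channel_concept_set")
}

#' Repair a flat 16-vector into a channel concept set
#'
#' Parameter layout (fixed, used by the genome and by serialisation):
#' positions 1:2 inactive upper, 3:4 inactive lower, 5:8 active upper,
#' 9:12 active lower, 13:14 very-active upper, 15:16 very-active lower.
#'
#' @param params Numeric vector of exactly 16 finite reals.
#' @param channel_id Channel identifier attached to the result.
#' @return A `channel_concept_set`.
#' @export
repair_concepts <- function(params, channel_id = 1L) {
  params <- as.numeric(params)
  if (length(params) != 16L)
    stop("expected 16 parameters per channel, got ", length(params),
         call. = FALSE)
  if (!all(is.finite(params)))
    stop("channel parameters must be finite", call. = FALSE)
  channel_concept_set(
    channel_id,
    inactive    = repair_mf("left_shoulder",  params[1:2],   params[3:4]),
    active      = repair_mf("trapezium",      params[5:8],   params[9:12]),
    very_active = repair_mf("right_shoulder", params[13:14], params[15:16]))
}

#' Flatten a channel concept set to its 16-parameter vector
#'
#' Inverse of [repair_concepts()] for already-repaired sets.
#'
#' @param set A `channel_concept_set`.
#' @return Numeric vector of length 16 in the canonical layout.
#' @export
concepts_to_vector <- function(set) {
  stopifnot(inherits(set, "channel_concept_set"))
  c(set$inactive$upper, set$inactive$lower,
    set$active$upper, set$active$lower,
    set$very_active$upper, set$very_active$lower)
}

#' Construct a concept bank
#'
#' A concept bank holds one conceptual-label set per channel
#' (16 x n_channels scalar parameters).
#'
#' @param sets List of `channel_concept_set` objects with unique channel ids.
#' @return An object of class `concept_bank`.
#' @export
concept_bank <- function(sets) {
  if (!length(sets) || !all(vapply(sets, inherits, TRUE, "channel_concept_set")))
    stop("'sets' must be a non-empty list of channel_concept_set objects")
  ids <- vapply(sets, function(s) as.character(s$channel_id), character(1))
  if (anyDuplicated(ids)) stop("duplicate channel ids in concept bank")
  structure(list(sets = sets, n_channels = length(sets), channel_ids = ids),
            class = "concept_bank")
}

#' @export
print.concept_bank <- function(x, ...) {
  cat("<concept_bank> ", x$n_channels, " channels, ",
      16L * x$n_channels, " parameters\n", sep = "")
  invisible(x)
}

#' Flatten a concept bank to one parameter vector
#'
#' @param bank A [concept_bank()].
#' @return Numeric vector of length `16 * n_channels` (channels in order, 16
#'   parameters each in the [repair_concepts()] layout).
#' @export
bank_to_vector <- function(bank) {
  stopifnot(inherits(bank, "concept_bank"))
  unlist(lapply(bank$sets, concepts_to_vector), use.names = FALSE)
}

#' Rebuild a concept bank from a flat parameter vector
#'
#' Each channel's 16-block is repaired independently, so arbitrary finite
#' reals (e.g. a genome's concept block) are accepted.
#'
#' @param params Numeric vector of length `16 * n_channels`.
#' @param channel_ids Channel identifiers; default `1:n`.
#' @return A [concept_bank()].
#' @export
vector_to_bank <- function(params, channel_ids = NULL) {
  params <- as.numeric(params)
  if (length(params) %% 16L != 0L)
    stop("parameter vector length must be a multiple of 16")
  n <- length(params) %/% 16L
  if (is.null(channel_ids)) channel_ids <- seq_len(n)
  if (length(channel_ids) != n) stop("need one channel id per 16-block")
  sets <- lapply(seq_len(n), function(j)
    repair_concepts(params[(16L * (j - 1L) + 1L):(16L * j)], channel_ids[[j]]))
  concept_bank(sets)
}

#' Quantile-seeded default concept bank
#'
#' Places each channel's conceptual-label breakpoints at data quantiles so
#' that the three labels tile the observed feature range: *inactive* covers
#' the low end, *active* the middle, *very active* the high end.  Used to
#' seed the genetic algorithm's initial population.
#'
#' @param matrix An [mv_matrix()] (or plain numeric matrix of trial x channel
#'   features).
#' @return A [concept_bank()] with one set per column.
#' @export
default_bank <- function(matrix) {
  vals <- if (inherits(matrix, "mv_matrix")) matrix$values else as.matrix(matrix)
  ids <- if (inherits(matrix, "mv_matrix")) matrix$channel_ids else
    colnames(vals) %||% seq_len(ncol(vals))
  if (nrow(vals) < 2L) stop("need at least 2 trials to place quantiles")
  sets <- lapply(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    if (diff(range(v)) <= 0)
      stop("channel ", ids[[j]], " is constant: cannot place a degenerate ",
           "concept range", call. = FALSE)
    q <- stats::quantile(v, probs = c(.10, .20, .30, .40, .45, .55,
                                      .60, .70, .80, .90), names = FALSE)
    channel_concept_set(
      ids[[j]],
      inactive    = repair_mf("left_shoulder", c(q[2], q[4]), c(q[1], q[3])),
      active      = repair_mf("trapezium", c(q[2], q[4], q[7], q[9]),
                              c(q[3], q[5], q[6], q[8])),
      very_active = repair_mf("right_shoulder", c(q[7], q[9]), c(q[8], q[10])))
  })
  concept_bank(sets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fast path: fuzzify a plain values matrix into a 4-d array
# [trial, channel, label, bound(lower, upper)].
.fuzzify_values <- function(bank, vals) {
  n <- nrow(vals)
  nch <- ncol(vals)
  fz <- array(0, dim = c(n, nch, 3L, 2L),
              dimnames = list(NULL, bank$channel_ids, col_levels(),
                              c("lower", "upper")))
  for (j in seq_len(nch)) {
    set <- bank$sets[[j]]
    x <- vals[, j]
    for (k in seq_len(3L)) {
      mf <- set[[col_levels()[k]]]
      fz[, j, k, 1L] <- .eval_bound(mf$shape, mf$lower, x)
      fz[, j, k, 2L] <- .eval_bound(mf$shape, mf$upper, x)
    }
  }
  fz
}

#' Fuzzify a multivariate matrix
#'
#' Converts the numeric trial x channel feature matrix into its conceptual
#' form: for every trial, channel and conceptual label, the membership
#' interval of the feature value.
#'
#' @param bank A [concept_bank()] whose channel count matches the matrix.
#' @param matrix An [mv_matrix()] or numeric matrix.
#' @return A 4-d array `[trial, channel, label, bound]` with values in
#'   `[0, 1]`; `bound` dimension is `c("lower", "upper")`.
#' @export
fuzzify <- function(bank, matrix) {
  stopifnot(inherits(bank, "concept_bank"))
  vals <- if (inherits(matrix, "mv_matrix")) matrix$values else as.matrix(matrix)
  if (ncol(vals) != bank$n_channels)
    stop("matrix has ", ncol(vals), " channels but bank has ",
         bank$n_channels, call. = FALSE)
  .fuzzify_values(bank, vals)
}

#' Write a concept bank to JSON
#'
#' The document has one entry per channel with the upper/lower breakpoints of
#' each conceptual label; doubles are written in full precision so the
#' round-trip through [read_concept_bank()] is bit-stable.
#'
#' @param bank A [concept_bank()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_concept_bank <- function(bank, path) {
  stopifnot(inherits(bank, "concept_bank"))
  doc <- list(n_channels = bank$n_channels,
              channels = lapply(bank$sets, function(s) {
                list(id = s$channel_id,
                     inactive = list(upper = s$inactive$upper,
                                     lower = s$inactive$lower),
                     active = list(upper = s$active$upper,
                                   lower = s$active$lower),
                     very_active = list(upper = s$very_active$upper,
                                        lower = s$very_active$lower))
              }))
  # digits = I(17): 17 significant digits, enough for exact double round-trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       always_decimal = TRUE)
  invisible(path)
}

.bank_from_doc <- function(doc) {
  sets <- lapply(doc$channels, function(ch) {
    channel_concept_set(
      ch$id,
      inactive = it2_mf("left_shoulder", unlist(ch$inactive$upper),
                        unlist(ch$inactive$lower)),
      active = it2_mf("trapezium", unlist(ch$active$upper),
                      unlist(ch$active$lower)),
      very_active = it2_mf("right_shoulder", unlist(ch$very_active$upper),
                           unlist(ch$very_active$lower)))
  })
  concept_bank(sets)
}

#' Read a concept bank from JSON
#'
#' @param path File written by [write_concept_bank()].
#' @return A [concept_bank()].
#' @export
read_concept_bank <- function(path) {
  doc <- jsonlite::read_json(path)
  .bank_from_doc(doc)
}
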