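# Explainable patterns: IF (channel is <conceptual label>) AND ... THEN
# stimulus.  A pattern's weight on the training data is its dominance score
# DS = confidence x support, carried as an interval (lower, upper) because
# memberships are interval-valued.  Prediction picks the consequent of the
# pattern with the highest association degree h = mean of the bound-wise
# products of activation strength and dominance score.

.MAX_ANTECEDENTS <- 3L
.MAX_PATTERNS <- 20L

#' Construct an explainable pattern
#'
#' @param channels Antecedent channel ids (1 to 3, distinct).
#' @param cols Conceptual label per antecedent, from [col_levels()].
#' @param consequent Stimulus class predicted by the pattern.
#' @param ds_lower,ds_upper Optional fitted dominance-score bounds.
#' @return An object of class `xmvpa_pattern`.
#' @export
xmvpa_pattern <- function(channels, cols, consequent,
                          ds_lower = NA_real_, ds_upper = NA_real_) {
  channels <- as.character(channels)
  cols <- as.character(cols)
  if (length(channels) < 1L || length(channels) > .MAX_ANTECEDENTS)
    stop("a pattern carries 1 to ", .MAX_ANTECEDENTS, " antecedents",
         call. = FALSE)
  if (anyDuplicated(channels))
    stop("antecedent channels must be distinct", call. = FALSE)
  if (length(cols) != length(channels) || !all(cols %in% col_levels()))
    stop("'cols' must pair each channel with one of: ",
         paste(col_levels(), collapse = ", "), call. = FALSE)
  if (!is.na(ds_lower) && !is.na(ds_upper)) {
    if (ds_lower < 0 || ds_upper > 1 || ds_lower > ds_upper)
      stop("dominance bounds must satisfy 0 <= lower <= upper <= 1",
           call. = FALSE)
  }
  structure(list(channels = channels, cols = cols,
                 consequent = as.character(consequent),
                 ds_lower = ds_lower, ds_upper = ds_upper,
                 ds_point = (ds_lower + ds_upper) / 2),
            class = "xmvpa_pattern")
}

.pattern_fitted <- function(p) !is.na(p$ds_lower) && !is.na(p$ds_upper)

#' Construct a rule base
#'
#' @param patterns List of [xmvpa_pattern()] objects (at most 20).
#' @param bank A [concept_bank()] covering every antecedent channel.
#' @param classes The two stimulus classes, positive class first.
#' @return An object of class `rule_base`.
#' @export
rule_base <- function(patterns, bank, classes) {
  if (!all(vapply(patterns, inherits, TRUE, "xmvpa_pattern")))
    stop("'patterns' must be xmvpa_pattern objects", call. = FALSE)
  if (length(patterns) > .MAX_PATTERNS)
    stop("a rule base carries at most ", .MAX_PATTERNS, " patterns",
         call. = FALSE)
  stopifnot(inherits(bank, "concept_bank"))
  classes <- as.character(classes)
  if (length(classes) != 2L) stop("exactly two stimulus classes are required")
  for (p in patterns) {
    if (!all(p$channels %in% bank$channel_ids))
      stop("pattern references channel(s) absent from the concept bank: ",
           paste(setdiff(p$channels, bank$channel_ids), collapse = ", "),
           call. = FALSE)
    if (!p$consequent %in% classes)
      stop("pattern consequent '", p$consequent, "' is not a known class",
           call. = FALSE)
  }
  structure(list(patterns = patterns, bank = bank, classes = classes),
            class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat("<rule_base> ", length(x$patterns), " pattern(s), classes: ",
      paste(x$classes, collapse = " / "), "\n", sep = "")
  if (length(x$patterns) && all(vapply(x$patterns, .pattern_fitted, TRUE)))
    cat(render_rules(x), sep = "\n")
  invisible(x)
}

# -- internal fast engine ----------------------------------------------------
# Activation strengths of every pattern on every trial, from a fuzzified
# array: product t-norm over antecedents, bound-wise.
.strength_matrices <- function(patterns, bank, fz) {
  n <- dim(fz)[1]
  Q <- length(patterns)
  wl <- matrix(1, n, Q)
  wu <- matrix(1, n, Q)
  lev <- col_levels()
  for (q in seq_len(Q)) {
    p <- patterns[[q]]
    js <- match(p$channels, bank$channel_ids)
    ks <- match(p$cols, lev)
    for (a in seq_along(js)) {
      wl[, q] <- wl[, q] * fz[, js[a], ks[a], 1L]
      wu[, q] <- wu[, q] * fz[, js[a], ks[a], 2L]
    }
  }
  list(lower = wl, upper = wu)
}

# Confidence, support and dominance bounds for every pattern from strength
# matrices restricted to training rows.  Returns a data frame, one row per
# pattern.  A pattern never activated has confidence defined as 0.
.fit_ds_table <- function(w, labels, consequents) {
  n <- length(labels)
  Q <- length(consequents)
  out <- matrix(0, Q, 6,
                dimnames = list(NULL, c("c_lower", "c_upper", "s_lower",
                                        "s_upper", "ds_lower", "ds_upper")))
  for (q in seq_len(Q)) {
    own <- labels == consequents[q]
    tl <- sum(w$lower[, q]); tu <- sum(w$upper[, q])
    pl <- sum(w$lower[own, q]); pu <- sum(w$upper[own, q])
    cl <- if (tl > 0) pl / tl else 0
    cu <- if (tu > 0) pu / tu else 0
    # interval-weighted ratios need not come out ordered; report as interval
    cb <- sort(c(cl, cu))
    sl <- pl / n; su <- pu / n
    out[q, ] <- c(cb[1], cb[2], sl, su, cb[1] * sl, cb[2] * su)
  }
  as.data.frame(out)
}

# association-degree matrix (trials x patterns) and winner per trial;
# tie-break: larger ds_point, then lower pattern index; all-zero -> NA winner
.classify_engine <- function(w, ds_lower, ds_upper) {
  h <- 0.5 * (sweep(w$lower, 2L, ds_lower, "*") +
              sweep(w$upper, 2L, ds_upper, "*"))
  ds_point <- (ds_lower + ds_upper) / 2
  ord <- order(-ds_point, seq_along(ds_point))
  win <- ord[max.col(h[, ord, drop = FALSE], ties.method = "first")]
  h_best <- h[cbind(seq_len(nrow(h)), win)]
  win[h_best == 0] <- NA_integer_
  list(h = h, winner = win, h_best = h_best)
}

# ---------------------------------------------------------------------------

#' Activation strengths of a pattern on one instance
#'
#' Conjunction over the antecedents with the product t-norm, applied
#' bound-wise to the membership intervals.
#'
#' @param p An [xmvpa_pattern()].
#' @param bank A [concept_bank()].
#' @param x Named numeric vector of channel features (names = channel ids),
#'   or an unnamed vector aligned with the bank's channels.
#' @return Numeric `c(lower, upper)` with `0 <= lower <= upper <= 1`.
#' @export
activation_strengths <- function(p, bank, x) {
  stopifnot(inherits(p, "xmvpa_pattern"), inherits(bank, "concept_bank"))
  x <- .align_instance(x, bank)
  wl <- 1; wu <- 1
  for (a in seq_along(p$channels)) {
    j <- match(p$channels[a], bank$channel_ids)
    if (is.na(j)) stop("instance lacks channel ", p$channels[a], call. = FALSE)
    mu <- membership_interval(bank$sets[[j]][[p$cols[a]]], x[j])
    wl <- wl * mu$lower
    wu <- wu * mu$upper
  }
  c(lower = wl, upper = wu)
}

.align_instance <- function(x, bank) {
  x <- unlist(x)
  if (!is.null(names(x))) {
    j <- match(bank$channel_ids, names(x))
    if (anyNA(j)) stop("instance lacks channel(s): ",
                       paste(bank$channel_ids[is.na(j)], collapse = ", "),
                       call. = FALSE)
    x <- x[j]
  } else if (length(x) != bank$n_channels) {
    stop("instance length does not match the concept bank", call. = FALSE)
  }
  as.numeric(x)
}

#' Confidence and support of a pattern on training data
#'
#' For each bound b, confidence is the activation-weighted fraction of
#' matching trials that carry the pattern's consequent class,
#' `sum_i[y_i = Y_q] w_b(x_i) / sum_i w_b(x_i)` (0 if the pattern never
#' activates), and support is the coverage of the training set,
#' `sum_i[y_i = Y_q] w_b(x_i) / N`.  Because the confidence ratio mixes the
#' two bounds in numerator and denominator it need not come out ordered; the
#' pair is reported as a sorted interval.
#'
#' @param p An [xmvpa_pattern()].
#' @param bank A [concept_bank()].
#' @param train An [mv_matrix()] of training trials.
#' @return Named numeric `c(c_lower, c_upper, s_lower, s_upper)`, all in
#'   `[0, 1]` with lower <= upper.
#' @export
confidence_support <- function(p, bank, train) {
  stopifnot(inherits(train, "mv_matrix"))
  if (nrow(train$values) == 0L) stop("training matrix is empty")
  fz <- fuzzify(bank, train)
  w <- .strength_matrices(list(p), bank, fz)
  tab <- .fit_ds_table(w, train$labels, p$consequent)
  c(c_lower = tab$c_lower, c_upper = tab$c_upper,
    s_lower = tab$s_lower, s_upper = tab$s_upper)
}

#' Fit a pattern's dominance-score bounds
#'
#' The dominance score is the product of confidence and support, bound-wise:
#' `ds_lower = c_lower * s_lower`, `ds_upper = c_upper * s_upper`.  The
#' reported point value is the interval midpoint.
#'
#' @inheritParams confidence_support
#' @return The pattern with `ds_lower`, `ds_upper`, `ds_point` filled in.
#' @export
dominance_scores <- function(p, bank, train) {
  cs <- confidence_support(p, bank, train)
  xmvpa_pattern(p$channels, p$cols, p$consequent,
                ds_lower = unname(cs["c_lower"] * cs["s_lower"]),
                ds_upper = unname(cs["c_upper"] * cs["s_upper"]))
}

#' Fit dominance scores for every pattern in a rule base
#'
#' @param rb A [rule_base()].
#' @param train An [mv_matrix()] of training trials.
#' @return The rule base with all patterns fitted.
#' @export
fit_dominance <- function(rb, train) {
  stopifnot(inherits(rb, "rule_base"), inherits(train, "mv_matrix"))
  if (nrow(train$values) == 0L) stop("training matrix is empty")
  fz <- fuzzify(rb$bank, train)
  w <- .strength_matrices(rb$patterns, rb$bank, fz)
  consequents <- vapply(rb$patterns, `[[`, character(1), "consequent")
  tab <- .fit_ds_table(w, train$labels, consequents)
  rb$patterns <- lapply(seq_along(rb$patterns), function(q) {
    p <- rb$patterns[[q]]
    xmvpa_pattern(p$channels, p$cols, p$consequent,
                  ds_lower = tab$ds_lower[q], ds_upper = tab$ds_upper[q])
  })
  rb
}

#' Association degree of a fitted pattern with an instance
#'
#' `h = (w_upper * ds_upper + w_lower * ds_lower) / 2`: the midpoint of the
#' bound-wise products of activation strength and dominance score.
#'
#' @inheritParams activation_strengths
#' @return A single numeric in `[0, 1]`.
#' @export
association_degree <- function(p, bank, x) {
  if (!.pattern_fitted(p))
    stop("pattern has no fitted dominance score; call dominance_scores()",
         call. = FALSE)
  w <- activation_strengths(p, bank, x)
  unname((w["upper"] * p$ds_upper + w["lower"] * p$ds_lower) / 2)
}

#' Classify instances with a fitted rule base
#'
#' Each trial is assigned the consequent of the pattern with the highest
#' association degree.  Ties are broken by larger dominance-score midpoint,
#' then by lower pattern index.  A trial with zero association to every
#' pattern is labelled `"unclassified"` (scored as an error downstream).
#'
#' @param rb A fitted [rule_base()].
#' @param newdata An [mv_matrix()] (labels optional) or a numeric matrix with
#'   channel columns.
#' @return A data frame with columns `predicted`, `winning_pattern` (index,
#'   `NA` when unclassified) and `h_best`; the full trials x patterns
#'   association matrix is attached as attribute `"h"`.
#' @export
classify <- function(rb, newdata) {
  stopifnot(inherits(rb, "rule_base"))
  if (!length(rb$patterns)) stop("rule base has no patterns", call. = FALSE)
  if (!all(vapply(rb$patterns, .pattern_fitted, TRUE)))
    stop("rule base is not fitted; call fit_dominance()", call. = FALSE)
  fz <- fuzzify(rb$bank, newdata)
  w <- .strength_matrices(rb$patterns, rb$bank, fz)
  dsl <- vapply(rb$patterns, `[[`, numeric(1), "ds_lower")
  dsu <- vapply(rb$patterns, `[[`, numeric(1), "ds_upper")
  cls <- .classify_engine(w, dsl, dsu)
  consequents <- vapply(rb$patterns, `[[`, character(1), "consequent")
  predicted <- ifelse(is.na(cls$winner), "unclassified",
                      consequents[cls$winner])
  out <- data.frame(predicted = predicted,
                    winning_pattern = cls$winner,
                    h_best = cls$h_best,
                    stringsAsFactors = FALSE)
  attr(out, "h") <- cls$h
  out
}

#' @export
predict.rule_base <- function(object, newdata, ...) {
  classify(object, newdata)$predicted
}

.col_display <- c(inactive = "Inactive", active = "Active",
                  very_active = "Very Active")

.ch_display <- function(id) {
  if (grepl("^[0-9]+$", id)) paste0("Ch", id) else id
}

#' Render a fitted rule base as text
#'
#' One line per pattern in the field's conventional form, e.g.
#' `"Pattern P1: IF Ch1 is Active AND Ch2 is Active THEN stimulus is Visual
#' with dominance score 0.581"`.  Patterns are ordered by class (first class
#' first) and, within a class, by descending dominance-score midpoint.
#'
#' @param rb A fitted [rule_base()].
#' @return Character vector, one element per pattern.
#' @export
render_rules <- function(rb) {
  stopifnot(inherits(rb, "rule_base"))
  if (!all(vapply(rb$patterns, .pattern_fitted, TRUE)))
    stop("rule base is not fitted", call. = FALSE)
  consequents <- vapply(rb$patterns, `[[`, character(1), "consequent")
  ds <- vapply(rb$patterns, `[[`, numeric(1), "ds_point")
  ord <- order(match(consequents, rb$classes), -ds)
  lines <- character(length(ord))
  for (i in seq_along(ord)) {
    p <- rb$patterns[[ord[i]]]
    ante <- paste(vapply(seq_along(p$channels), function(a)
      paste(.ch_display(p$channels[a]), "is", .col_display[[p$cols[a]]]),
      character(1)), collapse = " AND ")
    lines[i] <- sprintf(
      "Pattern P%d: IF %s THEN stimulus is %s with dominance score %.3f",
      i, ante, p$consequent, p$ds_point)
  }
  lines
}

#' Parse a rendered rule report back into pattern skeletons
#'
#' Inverse of [render_rules()] up to the 3-decimal rounding of the dominance
#' score: recovers antecedents, consequents and the printed score.
#'
#' @param lines Character vector as produced by [render_rules()].
#' @return List of lists with `channels`, `cols`, `consequent`, `ds_point`.
#' @export
parse_rules <- function(lines) {
  lapply(lines, function(ln) {
    m <- regmatches(ln, regexec(
      "^Pattern P[0-9]+: IF (.+) THEN stimulus is (.+) with dominance score ([0-9.]+)$",
      ln))[[1]]
    if (length(m) != 4L) stop("unparseable rule line: ", ln, call. = FALSE)
    parts <- strsplit(m[2], " AND ", fixed = TRUE)[[1]]
    chs <- character(0); cols <- character(0)
    for (p in parts) {
      pm <- regmatches(p, regexec("^(\\S+) is (.+)$", p))[[1]]
      ch <- sub("^Ch", "", pm[2])
      col <- names(.col_display)[match(pm[3], .col_display)]
      if (is.na(col)) stop("unknown conceptual label: ", pm[3], call. = FALSE)
      chs <- c(chs, ch); cols <- c(cols, col)
    }
    list(channels = chs, cols = cols, consequent = m[3],
         ds_point = as.numeric(m[4]))
  })
}

#' Write / read a rule base as JSON
#'
#' The document embeds the concept bank and optional fit metadata (analysis
#' window, seed, fold count) for provenance; doubles round-trip exactly.
#'
#' @param rb A [rule_base()].
#' @param path Output file path.
#' @param meta Optional named list of fit metadata.
#' @return `write_rule_base()` returns `path` invisibly; `read_rule_base()`
#'   returns the [rule_base()] (metadata in attribute `"meta"`).
#' @export
write_rule_base <- function(rb, path, meta = NULL) {
  stopifnot(inherits(rb, "rule_base"))
  doc <- list(
    classes = rb$classes,
    patterns = lapply(rb$patterns, function(p)
      list(channels = p$channels, cols = p$cols, consequent = p$consequent,
           ds_lower = p$ds_lower, ds_upper = p$ds_upper)),
    bank = jsonlite::fromJSON(.bank_json(rb$bank), simplifyVector = FALSE),
    meta = meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       always_decimal = TRUE, null = "null")
  invisible(path)
}

.bank_json <- function(bank) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_concept_bank(bank, tmp)
  paste(readLines(tmp, warn = FALSE), collapse = "\n")
}

#' @rdname write_rule_base
#' @export
read_rule_base <- function(path) {
  doc <- jsonlite::read_json(path)
  bank <- .bank_from_doc(doc$bank)
  patterns <- lapply(doc$patterns, function(p)
    xmvpa_pattern(unlist(p$channels), unlist(p$cols), p$consequent,
                  ds_lower = p$ds_lower %||% NA_real_,
                  ds_upper = p$ds_upper %||% NA_real_))
  rb <- rule_base(patterns, bank, unlist(doc$classes))
  attr(rb, "meta") <- doc$meta
  rb
}
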