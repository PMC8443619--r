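# Trial containers and window-mean feature extraction.  An epoch set holds
# per-trial channel time series relative to stimulus onset; the multivariate
# matrix holds one window-mean haemodynamic feature per trial and channel
# (mean HbO2 concentration change, arbitrary units) plus the stimulus label.

#' Construct an epoch set
#'
#' @param data A data frame in long format with columns `trial_id`,
#'   `subject_id`, `label`, `channel`, `time_s`, `value`; `time_s` is in
#'   seconds relative to stimulus onset.
#' @param sample_rate Sampling rate in Hz (metadata only).
#' @return An object of class `epoch_set` wrapping the data frame.
#' @export
epoch_set <- function(data, sample_rate = NULL) {
  need <- c("trial_id", "subject_id", "label", "channel", "time_s", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("epoch data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)[need]
  if (anyNA(data$value) || anyNA(data$time_s))
    stop("epoch samples contain NA", call. = FALSE)
  labs <- unique(as.character(data$label))
  if (length(labs) != 2L)
    stop("epoch labels must come from exactly two classes, found ",
         length(labs), call. = FALSE)
  # channel count must be constant across trials
  nch <- tapply(data$channel, data$trial_id,
                function(ch) length(unique(ch)))
  if (length(unique(nch)) != 1L)
    stop("channel count differs across trials", call. = FALSE)
  structure(list(data = data, sample_rate = sample_rate,
                 channels = sort(unique(as.character(data$channel))),
                 classes = labs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> ", length(unique(x$data$trial_id)), " trials, ",
      length(x$channels), " channels, classes: ",
      paste(x$classes, collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Construct a multivariate pattern matrix
#'
#' @param values Numeric matrix, trials in rows and channels in columns; no
#'   missing values.
#' @param labels Per-trial stimulus class (character), length `nrow(values)`.
#' @param channel_ids Channel identifiers (default: column names or `1:n`).
#' @param trial_id,subject_id Optional per-trial identifiers.
#' @param window Optional `(start_s, end_s)` provenance of the features.
#' @param classes Optional class order (first class plays the positive
#'   role); default: order of first appearance in `labels`.
#' @return An object of class `mv_matrix`.
#' @export
mv_matrix <- function(values, labels, channel_ids = NULL, trial_id = NULL,
                      subject_id = NULL, window = NULL, classes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("feature matrix contains NA/NaN", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("need one label per trial row", call. = FALSE)
  if (is.null(channel_ids)) channel_ids <- colnames(values) %||% seq_len(ncol(values))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != ncol(values))
    stop("need one channel id per column", call. = FALSE)
  colnames(values) <- channel_ids
  if (is.null(trial_id)) trial_id <- seq_len(nrow(values))
  classes <- classes %||% unique(labels)
  if (!all(labels %in% classes))
    stop("labels outside the declared class set", call. = FALSE)
  structure(list(values = values, labels = labels, channel_ids = channel_ids,
                 trial_id = trial_id, subject_id = subject_id,
                 window = window, classes = classes),
            class = "mv_matrix")
}

#' @export
print.mv_matrix <- function(x, ...) {
  cat("<mv_matrix> ", nrow(x$values), " trials x ", ncol(x$values),
      " channels; classes: ", paste(x$classes, collapse = " / "), sep = "")
  if (!is.null(x$window))
    cat("; window ", x$window[1], "-", x$window[2], " s", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.mv_matrix <- function(x) dim(x$values)

# row subset preserving all per-trial metadata
.mv_subset <- function(m, idx) {
  mv_matrix(m$values[idx, , drop = FALSE], m$labels[idx], m$channel_ids,
            trial_id = m$trial_id[idx],
            subject_id = if (!is.null(m$subject_id)) m$subject_id[idx],
            window = m$window, classes = m$classes)
}

#' Window-mean multivariate matrix from epochs
#'
#' Entry (i, j) is the arithmetic mean of channel j's samples with
#' `start_s <= t <= end_s` (closed interval, with a tiny floating-point
#' tolerance on the endpoints) in trial i.  The reference analysis uses the
#' 4-7 s post-stimulus window, where the haemodynamic response peaks.
#'
#' @param epochs An [epoch_set()].
#' @param window Numeric `(start_s, end_s)`, `start < end`.
#' @return An [mv_matrix()] with the window recorded.
#' @export
window_mean_matrix <- function(epochs, window = c(4, 7)) {
  stopifnot(inherits(epochs, "epoch_set"))
  window <- as.numeric(window)
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop("'window' must be (start_s, end_s) with start < end", call. = FALSE)
  d <- epochs$data
  eps <- 1e-9 * max(1, abs(window))
  tsup <- tapply(d$time_s, d$trial_id, range)
  bad <- names(tsup)[vapply(tsup, function(r)
    r[1] > window[1] + eps || r[2] < window[2] - eps, TRUE)]
  if (length(bad))
    stop("window [", window[1], ", ", window[2], "] s not covered by trial(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  sel <- d$time_s >= window[1] - eps & d$time_s <= window[2] + eps
  if (!any(sel)) stop("no samples fall inside the window", call. = FALSE)
  sub <- d[sel, ]
  tr <- factor(sub$trial_id, levels = unique(d$trial_id))
  ch <- factor(as.character(sub$channel), levels = epochs$channels)
  vals <- tapply(sub$value, list(tr, ch), mean)
  if (anyNA(vals))
    stop("some trial/channel combinations have no samples in the window",
         call. = FALSE)
  first <- !duplicated(d$trial_id)
  mv_matrix(unclass(vals),
            labels = as.character(d$label[first]),
            channel_ids = epochs$channels,
            trial_id = d$trial_id[first],
            subject_id = d$subject_id[first],
            window = window)
}

#' Grid search over candidate analysis windows
#'
#' Scores each candidate window by an externally supplied cross-validated fit
#' procedure (conventionally the mean cross-validated Matthews correlation
#' coefficient) and returns the best one.  Ties are broken deterministically:
#' earliest start, then shortest duration.  Candidates that fail feature
#' extraction are skipped with a warning.
#'
#' @param epochs An [epoch_set()].
#' @param candidates List of `(start_s, end_s)` windows.
#' @param eval_fun Function taking an [mv_matrix()] and returning a single
#'   numeric score (larger is better).
#' @return List with `best_window` and a data frame `scores`
#'   (`start`, `end`, `score`; skipped candidates carry `NA`).
#' @export
grid_search_window <- function(epochs, candidates, eval_fun) {
  if (!length(candidates)) stop("need at least one candidate window")
  scores <- vapply(candidates, function(w) {
    tryCatch(eval_fun(window_mean_matrix(epochs, w)),
             error = function(e) {
               warning("skipping window [", w[1], ", ", w[2], "]: ",
                       conditionMessage(e), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  if (all(is.na(scores)))
    stop("all candidate windows failed feature extraction", call. = FALSE)
  starts <- vapply(candidates, `[`, numeric(1), 1L)
  durs <- vapply(candidates, function(w) w[2] - w[1], numeric(1))
  best <- order(-scores, starts, durs, na.last = TRUE)[1L]
  list(best_window = as.numeric(candidates[[best]]),
       scores = data.frame(start = starts, end = starts + durs,
                           score = scores))
}

#' Read / write epoch CSV (long format)
#'
#' Columns `trial_id, subject_id, label, channel, time_s, value`, header row,
#' UTF-8, '.' decimal.
#'
#' @param path CSV file path.
#' @param sample_rate Optional sampling rate metadata for the reader.
#' @return `read_epochs()` returns an [epoch_set()]; `write_epochs()` returns
#'   `path` invisibly.
#' @export
read_epochs <- function(path, sample_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  epoch_set(d, sample_rate = sample_rate)
}

#' @rdname read_epochs
#' @param epochs An [epoch_set()] to serialise.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  utils::write.csv(epochs$data, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a multivariate matrix CSV (wide format)
#'
#' Columns `trial_id, subject_id, label, <channel columns>`; one row per
#' trial.
#'
#' @param path CSV file path.
#' @return `read_mv_matrix()` returns an [mv_matrix()]; `write_mv_matrix()`
#'   returns `path` invisibly.
#' @export
read_mv_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- intersect(c("trial_id", "subject_id", "label"), names(d))
  if (!("label" %in% meta)) stop("matrix CSV lacks a 'label' column")
  chcols <- setdiff(names(d), meta)
  if (!length(chcols)) stop("matrix CSV has no channel columns")
  mv_matrix(as.matrix(d[chcols]), labels = d$label, channel_ids = chcols,
            trial_id = if ("trial_id" %in% meta) d$trial_id,
            subject_id = if ("subject_id" %in% meta) d$subject_id)
}

#' @rdname read_mv_matrix
#' @param matrix An [mv_matrix()] to serialise.
#' @export
write_mv_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "mv_matrix"))
  d <- data.frame(trial_id = matrix$trial_id %||% seq_len(nrow(matrix$values)),
                  stringsAsFactors = FALSE)
  if (!is.null(matrix$subject_id)) d$subject_id <- matrix$subject_id
  d$label <- matrix$labels
  d <- cbind(d, as.data.frame(matrix$values, check.names = FALSE))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
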