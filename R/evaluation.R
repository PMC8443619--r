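# Confusion-matrix metrics, the Matthews correlation coefficient, stratified
# k-fold cross-validation, and the permutation baseline.  By convention the
# first class plays the "positive" role (the visual stimulus in the reference
# design) and the second the "negative" role.

#' Sentinel label for trials no pattern matches
#'
#' @return The string `"unclassified"`.
#' @export
unclassified_label <- function() "unclassified"

#' Tally a binary confusion matrix
#'
#' The abstention sentinel [unclassified_label()] is scored as the wrong
#' class: it increments FN when the truth is positive and FP when the truth
#' is negative, so abstaining can never improve any metric.
#'
#' @param truth Character vector of true labels (two classes).
#' @param predicted Character vector of predictions (may contain the
#'   sentinel).
#' @param positive The class playing the positive role.
#' @return An object of class `confusion`: list with integer fields `tp`,
#'   `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, predicted, positive) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  classes <- unique(truth)
  if (!positive %in% classes && length(classes) <= 2L)
    classes <- unique(c(positive, classes))
  if (length(classes) > 2L)
    stop("more than two classes in 'truth'", call. = FALSE)
  bad <- setdiff(unique(predicted), c(classes, unclassified_label()))
  if (length(bad))
    stop("prediction label(s) outside the class set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  pos <- truth == positive
  hit <- predicted == truth
  # sentinel rows have hit = FALSE and are charged to FN/FP via truth
  structure(list(tp = sum(pos & hit), fp = sum(!pos & !hit),
                 tn = sum(!pos & hit), fn = sum(pos & !hit)),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat("<confusion> TP=", x$tp, " FP=", x$fp, " TN=", x$tn, " FN=", x$fn,
      "\n", sep = "")
  invisible(x)
}

.guard_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (0/0); reporting 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Confusion-matrix performance measures
#'
#' Accuracy, positive/negative predictive value, F-score, false positive and
#' false negative rates.  Undefined 0/0 ratios are reported as 0 with a
#' warning.
#'
#' @param cm A [confusion()] object.
#' @return Named numeric vector `accuracy, ppv, npv, fscore, fpr, fnr`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  c(accuracy = (cm$tp + cm$tn) / n,
    ppv = .guard_ratio(cm$tp, cm$tp + cm$fp, "PPV"),
    npv = .guard_ratio(cm$tn, cm$tn + cm$fn, "NPV"),
    fscore = .guard_ratio(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn, "Fscore"),
    fpr = .guard_ratio(cm$fp, cm$fp + cm$tn, "FPR"),
    fnr = .guard_ratio(cm$fn, cm$fn + cm$tp, "FNR"))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' conventional guard: if any factor of the denominator is zero the
#' coefficient is reported as 0.
#'
#' @param cm A [confusion()] object.
#' @return A numeric in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `k` folds so that every fold keeps
#' (approximately) the class proportions; the assignment is a deterministic
#' function of the seed.
#'
#' @param labels Per-trial class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per trial.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  if (k > min(table(labels)))
    stop("'k' exceeds the size of the smallest class", call. = FALSE)
  fold <- integer(length(labels))
  rng <- .with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
  rng
}

# run expr with a local RNG state restored afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Cross-validate a fit procedure
#'
#' Fits on each training fold and scores the held-out fold; folds are
#' disjoint, exhaustive and stratified.  The pooled confusion matrix is the
#' sum of the per-fold matrices.
#'
#' @param matrix An [mv_matrix()] with two classes.
#' @param fit_fun Function taking a training [mv_matrix()] and returning any
#'   object for which `predict(object, newdata)` yields labels.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param positive Positive class (default: first class of the matrix).
#' @return List with `metrics` (pooled, including `mcc`), `per_fold` data
#'   frame, `pooled` [confusion()], `folds`, and per-trial `predictions`.
#' @export
cross_validate <- function(matrix, fit_fun, k = 5L, seed = 1L,
                           positive = NULL) {
  stopifnot(inherits(matrix, "mv_matrix"))
  if (length(matrix$classes) != 2L)
    stop("cross-validation needs exactly two classes", call. = FALSE)
  positive <- positive %||% matrix$classes[1]
  fold <- make_folds(matrix$labels, k, seed)
  preds <- character(length(matrix$labels))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- fit_fun(.mv_subset(matrix, tr))
    p <- predict(model, .mv_subset(matrix, !tr))
    preds[!tr] <- p
    cmf <- confusion(matrix$labels[!tr], p, positive)
    per_fold[[f]] <- data.frame(fold = f, n = sum(!tr),
                                mcc = mcc(cmf),
                                t(classification_metrics(cmf)))
  }
  pooled <- confusion(matrix$labels, preds, positive)
  list(metrics = c(classification_metrics(pooled), mcc = mcc(pooled),
                   mean_fold_mcc = mean(vapply(per_fold, `[[`, numeric(1),
                                               "mcc"))),
       per_fold = do.call(rbind, per_fold),
       pooled = pooled, folds = fold, predictions = preds)
}

#' Permutation-baseline significance test
#'
#' Builds the null distribution of decoding metrics by re-running the full
#' evaluation under randomly permuted stimulus labels (the reference design
#' uses 5000 permutations; desk-scale runs pass a smaller `n_perm`).
#' P-values use the add-one estimator `p = (1 + #{null >= observed}) /
#' (1 + n_perm)`, with the comparison reversed for error rates (`fpr`,
#' `fnr`), which is valid (conservative) under the null for any `n_perm`.
#'
#' @param matrix An [mv_matrix()].
#' @param eval_fun Function taking an [mv_matrix()] and returning a named
#'   numeric vector of metrics (e.g. wrapping [cross_validate()] around a
#'   reduced-budget [xmvpa_fit()]).  It is applied identically to the
#'   observed and every permuted dataset; give it a fixed internal seed so
#'   the statistic is a deterministic function of the data.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed for drawing the permutations.
#' @param observed Optional precomputed observed metrics (skips one
#'   evaluation).
#' @param lower_is_better Metric names for which smaller observed values
#'   count as more extreme.
#' @return List with `p_values`, `observed`, and the `null` matrix
#'   (one row per permutation).
#' @export
permutation_test <- function(matrix, eval_fun, n_perm = 5000L, seed = 1L,
                             observed = NULL,
                             lower_is_better = c("fpr", "fnr")) {
  stopifnot(inherits(matrix, "mv_matrix"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("'n_perm' must be at least 1", call. = FALSE)
  if (is.null(observed)) observed <- eval_fun(matrix)
  observed <- unlist(observed)
  n <- length(matrix$labels)
  perms <- .with_seed(seed,
    lapply(seq_len(n_perm), function(i) sample.int(n)))
  null <- base::matrix(NA_real_, n_perm, length(observed),
                       dimnames = list(NULL, names(observed)))
  worst <- ifelse(names(observed) %in% lower_is_better, Inf, -Inf)
  for (i in seq_len(n_perm)) {
    pm <- matrix
    pm$labels <- matrix$labels[perms[[i]]]
    res <- tryCatch(unlist(eval_fun(pm)), error = function(e) {
      warning("permutation ", i, " failed (", conditionMessage(e),
              "); recording worst-case metrics", call. = FALSE)
      stats::setNames(worst, names(observed))
    })
    null[i, ] <- res[names(observed)]
  }
  p <- vapply(seq_along(observed), function(m) {
    ge <- if (names(observed)[m] %in% lower_is_better)
      sum(null[, m] <= observed[m]) else sum(null[, m] >= observed[m])
    (1 + ge) / (1 + n_perm)
  }, numeric(1))
  names(p) <- names(observed)
  list(p_values = p, observed = observed, null = null)
}
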