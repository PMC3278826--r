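# Evaluation machinery: confusion counts, the five performance metrics
# (precision, sensitivity, specificity, accuracy, MCC), stratified k-fold
# cross-validation, the window-length sweep and the feature-combination
# comparison.

#' Confusion counts for binary site prediction
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(stats::setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_counts")
}

# Tally predictions against truth labels into confusion counts.
tally_confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_counts(tp = sum(truth == "positive" & predicted == "positive"),
                   fp = sum(truth == "negative" & predicted == "positive"),
                   tn = sum(truth == "negative" & predicted == "negative"),
                   fn = sum(truth == "positive" & predicted == "negative"))
}

#' Compute the five performance metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/total` and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric with a zero denominator is defined as 0.  Full precision is
#' retained; textual output truncates to three decimals (see
#' [format.metric_report()]).
#'
#' @param counts A [confusion_counts()] object.
#' @return A `metric_report` with elements `precision`, `sensitivity`,
#'   `specificity`, `accuracy`, `mcc` and the `counts`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0L) stop("confusion counts are all zero")
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  structure(list(
    precision = safe_div(tp, tp + fp),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = (tp + tn) / total,
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    counts = counts), class = "metric_report")
}

# Truncate (not round) towards zero at three decimals, as in printed tables.
truncate3 <- function(x) trunc(x * 1000 + sign(x) * 1e-9) / 1000

#' @export
format.metric_report <- function(x, ...) {
  vals <- truncate3(unlist(x[c("precision", "sensitivity", "specificity",
                               "accuracy", "mcc")]))
  paste0(c("Pre", "Sn", "Sp", "Acc", "MCC"), "=",
         formatC(vals, digits = 3, format = "f"), collapse = "  ")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Flatten a metric report to a named numeric vector
#'
#' @param report A `metric_report`.
#' @param truncated Truncate to three decimals as in textual output.
#' @return Named numeric vector `precision`, `sensitivity`, `specificity`,
#'   `accuracy`, `mcc`.
#' @export
metric_vector <- function(report, truncated = FALSE) {
  v <- unlist(report[c("precision", "sensitivity", "specificity",
                       "accuracy", "mcc")])
  if (truncated) v <- truncate3(v)
  v
}

#' Stratified k-fold assignment
#'
#' Samples of each class are shuffled (seeded) and dealt round-robin, so
#' per-class fold sizes differ by at most one and each sample lands in
#' exactly one fold.
#'
#' @param labels Class labels, one per sample.
#' @param k Number of folds, `2 <= k <= length(labels)`.
#' @param seed RNG seed; the assignment is deterministic given it.
#' @return Integer vector of fold ids in `1..k`.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > length(labels)) stop("k (", k, ") exceeds sample count (",
                               length(labels), ")")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' k-fold cross-validation of the site predictor
#'
#' For each fold, the PWM is rebuilt from the positive fragments of the
#' training split only, features are encoded, an RBF-SVM is trained and the
#' held-out fold is predicted.  Per-fold predictions are pooled into a
#' single set of confusion counts and one metric report.
#'
#' @param fragments Fragment data frame (after homology reduction).
#' @param profiles Named profile list; required when `ASA` or `SS` is
#'   selected.
#' @param selection Feature selection, default the best-performing
#'   combination `AA_PWM + AAC + ASA`.
#' @param cfg An [svm_config()].
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `counts`, `metrics`, and `predictions` (per-fragment
#'   fold id, truth, predicted label and decision value).
#' @export
cross_validate <- function(fragments, profiles = NULL,
                           selection = c("AA_PWM", "AAC", "ASA"),
                           cfg = svm_config(), k = 5L, seed = 1L) {
  selection <- check_selection(selection)
  folds <- kfold_split(fragments$label, k = k, seed = seed)
  predicted <- character(nrow(fragments))
  decision <- numeric(nrow(fragments))
  for (f in seq_len(k)) {
    tr <- folds != f
    train_frags <- fragments[tr, , drop = FALSE]
    pwm <- NULL
    if ("AA_PWM" %in% selection) {
      pwm <- build_pwm(train_frags[train_frags$label == "positive", ])
    }
    x_train <- encode_fragments(train_frags, selection, pwm, profiles)
    x_test <- encode_fragments(fragments[!tr, , drop = FALSE], selection,
                               pwm, profiles)
    model <- train_model(x_train, train_frags$label, cfg)
    pred <- predict(model, x_test)
    predicted[!tr] <- pred$label
    decision[!tr] <- pred$decision
  }
  counts <- tally_confusion(fragments$label, predicted)
  list(counts = counts,
       metrics = compute_metrics(counts),
       predictions = data.frame(protein_id = fragments$protein_id,
                                center = fragments$center,
                                fold = folds,
                                truth = fragments$label,
                                label = predicted,
                                decision = decision,
                                stringsAsFactors = FALSE))
}

#' Sweep the window half-width and cross-validate each length
#'
#' Re-runs the full pipeline (fragment extraction, homology reduction,
#' cross-validation) for each half-width in `n_values`.  Amino-acid
#' composition is the default training feature, as in the window-length
#' analysis that selects the 15-mer.
#'
#' @param records Named record list with annotated sites.
#' @param profiles Named profile list (only needed if `selection` uses
#'   structure features).
#' @param n_values Integer half-widths to evaluate, default `4:10`.
#' @param selection Feature selection, default `AAC`.
#' @param cfg An [svm_config()].
#' @param k,seed Cross-validation folds and seed.
#' @param homologous_pairs Optional precomputed [find_homologous_pairs()]
#'   result; computed once from `records` when `NULL`.
#' @return Data frame with one row per `n`: window length, class sizes after
#'   reduction and the five metrics.
#' @export
window_sweep <- function(records, profiles = NULL, n_values = 4:10,
                         selection = "AAC", cfg = svm_config(), k = 5L,
                         seed = 1L, homologous_pairs = NULL) {
  if (is.null(homologous_pairs)) {
    homologous_pairs <- find_homologous_pairs(records)
  }
  rows <- lapply(as.integer(n_values), function(n) {
    frags <- extract_fragments(records, window_config(n))
    frags <- reduce_fragments(frags, homologous_pairs)
    cv <- cross_validate(frags, profiles, selection, cfg, k = k, seed = seed)
    data.frame(n = n, window_length = 2L * n + 1L,
               n_positive = sum(frags$label == "positive"),
               n_negative = sum(frags$label == "negative"),
               t(metric_vector(cv$metrics)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The ten canonical feature combinations
#'
#' Single features and the hybrid combinations compared by cross-validation:
#' `AA_PWM`, `AAC`, `ASA`, `SS`, `AA_PWM+AAC`, `AA_PWM+ASA`, `AA_PWM+SS`,
#' `AA_PWM+AAC+ASA`, `AA_PWM+AAC+SS` and all four.
#'
#' @return List of character vectors.
#' @export
default_feature_combinations <- function() {
  list(c("AA_PWM"), c("AAC"), c("ASA"), c("SS"),
       c("AA_PWM", "AAC"), c("AA_PWM", "ASA"), c("AA_PWM", "SS"),
       c("AA_PWM", "AAC", "ASA"), c("AA_PWM", "AAC", "SS"),
       c("AA_PWM", "AAC", "ASA", "SS"))
}

#' Cross-validate a list of feature combinations
#'
#' @param fragments Fragment data frame (after homology reduction).
#' @param profiles Named profile list.
#' @param combinations List of feature selections, default
#'   [default_feature_combinations()].
#' @param cfg,k,seed Passed to [cross_validate()].
#' @return Data frame with one row per combination and the five metrics.
#' @export
feature_combination_eval <- function(fragments, profiles = NULL,
                                     combinations = default_feature_combinations(),
                                     cfg = svm_config(), k = 5L, seed = 1L) {
  rows <- lapply(combinations, function(sel) {
    cv <- cross_validate(fragments, profiles, sel, cfg, k = k, seed = seed)
    data.frame(features = paste(check_selection(sel), collapse = "+"),
               t(metric_vector(cv$metrics)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a fitted model on an independent test set
#'
#' The test proteins must be disjoint from the training proteins; the
#' fragments are encoded with the training PWM, predicted in a single pass
#' and summarized as confusion counts plus the five metrics.
#'
#' @param model A fitted [fit_gla_model()] object.
#' @param fragments Held-out fragment data frame with both classes present.
#' @param profiles Named profile list covering the test proteins (required
#'   when the model uses structure features).
#' @return List with `counts`, `metrics` and per-fragment `predictions`.
#' @export
independent_test <- function(model, fragments, profiles = NULL) {
  stopifnot(inherits(model, "gla_model"))
  overlap <- intersect(unique(fragments$protein_id), model$train_protein_ids)
  if (length(overlap) > 0L) {
    stop("test proteins overlap the training set: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  }
  if (!any(fragments$label == "positive")) {
    stop("independent test set has no positive fragments")
  }
  if (!any(fragments$label == "negative")) {
    stop("independent test set has no negative fragments")
  }
  pred <- predict(model, fragments, profiles)
  counts <- tally_confusion(fragments$label, pred$label)
  list(counts = counts, metrics = compute_metrics(counts),
       predictions = cbind(fragments[c("protein_id", "center")], pred))
}
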