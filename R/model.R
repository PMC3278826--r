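# RBF-kernel support vector machine (libsvm via e1071): training,
# prediction with a fixed decision threshold of 0, and grid search over
# (cost, gamma) by k-fold cross-validation accuracy.

#' SVM hyper-parameter configuration
#'
#' @param cost Positive soft-margin cost.
#' @param gamma Positive RBF width, or `NULL` for the libsvm default
#'   `1 / n_features`.
#' @param class_weights Optional named weights for `positive` / `negative`
#'   (off by default; the classifier is trained unweighted despite the class
#'   imbalance).
#' @return An `svm_config` object.
#' @export
svm_config <- function(cost = 1, gamma = NULL, class_weights = NULL) {
  stopifnot(is.numeric(cost), length(cost) == 1L, cost > 0)
  if (!is.null(gamma)) stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  structure(list(cost = cost, gamma = gamma, kernel = "radial",
                 class_weights = class_weights),
            class = "svm_config")
}

#' Train a binary RBF-SVM on encoded features
#'
#' @param features Numeric matrix, one row per sample (values expected in
#'   `[0, 1]`; no further rescaling is applied).
#' @param labels Character/factor vector of `"positive"` / `"negative"`,
#'   both classes present.
#' @param cfg An [svm_config()].
#' @return An `svm_site_model`: the fitted libsvm model plus the feature
#'   schema, configuration and a training-set fingerprint.  Decision values
#'   are oriented so positive values mean the positive class.
#' @export
train_model <- function(features, labels, cfg = svm_config()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  if (!all(labels %in% c("positive", "negative"))) {
    stop("labels must be 'positive' or 'negative'")
  }
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  gamma <- if (is.null(cfg$gamma)) 1 / ncol(features) else cfg$gamma
  y <- factor(labels, levels = c("positive", "negative"))
  wts <- cfg$class_weights
  fit <- e1071::svm(x = features, y = y, type = "C-classification",
                    kernel = "radial", cost = cfg$cost, gamma = gamma,
                    scale = FALSE, class.weights = wts)
  dv <- attr(stats::predict(fit, features[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- !startsWith(colnames(dv)[1], "positive")
  structure(list(fit = fit, flip = flip,
                 config = svm_config(cfg$cost, gamma, wts),
                 schema = attr(features, "schema"),
                 n_features = ncol(features),
                 fingerprint = list(n = nrow(features), p = ncol(features),
                                    n_positive = sum(labels == "positive"),
                                    checksum = sum(features))),
            class = "svm_site_model")
}

#' Predict labels and decision values
#'
#' A sample is called `"positive"` exactly when its (oriented) decision
#' value exceeds 0.
#'
#' @param object An `svm_site_model`.
#' @param features Feature matrix matching the training schema.
#' @param ... Unused.
#' @return Data frame with columns `label` and `decision`.
#' @export
predict.svm_site_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (nrow(features) == 0L) {
    return(data.frame(label = character(0), decision = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (ncol(features) != object$n_features) {
    stop("feature matrix has ", ncol(features), " columns; model expects ",
         object$n_features)
  }
  pr <- stats::predict(object$fit, features, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  if (object$flip) dv <- -dv
  data.frame(label = ifelse(dv > 0, "positive", "negative"),
             decision = dv, stringsAsFactors = FALSE)
}

#' Tune (cost, gamma) by k-fold cross-validation accuracy
#'
#' Every pair from `costs` x `gammas` is evaluated with the same stratified
#' fold assignment; the pair with the highest pooled accuracy wins, ties
#' broken by smaller cost then smaller gamma, so the result does not depend
#' on the grid ordering.
#'
#' @param features Feature matrix.
#' @param labels `"positive"` / `"negative"` labels.
#' @param costs,gammas Non-empty candidate vectors.  The defaults follow the
#'   usual libsvm coarse grid: cost `2^(-5), 2^(-3), ..., 2^15` and gamma
#'   `2^(-15), 2^(-13), ..., 2^3`.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @return List with `best` (an [svm_config()]) and `table` (accuracy per
#'   evaluated pair).
#' @export
grid_search <- function(features, labels,
                        costs = 2^seq(-5, 15, by = 2),
                        gammas = 2^seq(-15, 3, by = 2),
                        k = 5L, seed = 1L) {
  stopifnot(length(costs) > 0L, length(gammas) > 0L)
  features <- as.matrix(features)
  labels <- as.character(labels)
  grid <- unique(expand.grid(cost = as.numeric(costs),
                             gamma = as.numeric(gammas)))
  folds <- kfold_split(labels, k = k, seed = seed)
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- svm_config(grid$cost[i], grid$gamma[i])
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- folds != f
      model <- train_model(features[tr, , drop = FALSE], labels[tr], cfg)
      pred <- predict(model, features[!tr, , drop = FALSE])
      correct <- correct + sum(pred$label == labels[!tr])
    }
    correct / length(labels)
  }, numeric(1))
  tab <- cbind(grid, accuracy = acc)
  best <- tab[order(-tab$accuracy, tab$cost, tab$gamma), ][1, ]
  list(best = svm_config(best$cost, best$gamma),
       table = tab[order(tab$cost, tab$gamma), , drop = FALSE])
}
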