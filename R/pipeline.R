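# High-level model fitting and whole-protein site scanning.

#' Fit the carboxylation-site predictor on a training fragment set
#'
#' Builds the PWM from the positive training fragments (when selected),
#' encodes the chosen features and trains the RBF-SVM.
#'
#' @param fragments Training fragment data frame (after homology reduction).
#' @param profiles Named profile list, required for `ASA`/`SS` features.
#' @param selection Feature selection, default `AA_PWM + AAC + ASA`.
#' @param cfg An [svm_config()].
#' @return A `gla_model` holding the SVM, the PWM, the selection, and the
#'   training protein ids.
#' @export
fit_gla_model <- function(fragments, profiles = NULL,
                          selection = c("AA_PWM", "AAC", "ASA"),
                          cfg = svm_config()) {
  selection <- check_selection(selection)
  pwm <- NULL
  if ("AA_PWM" %in% selection) {
    pwm <- build_pwm(fragments[fragments$label == "positive", ])
  }
  features <- encode_fragments(fragments, selection, pwm, profiles)
  svm <- train_model(features, fragments$label, cfg)
  structure(list(svm = svm, pwm = pwm, selection = selection,
                 cfg = svm$config,
                 n = fragment_half_width(fragments$window),
                 train_protein_ids = unique(fragments$protein_id)),
            class = "gla_model")
}

#' Predict labels for a set of fragments
#'
#' @param object A `gla_model`.
#' @param fragments Fragment data frame.
#' @param profiles Named profile list (required for structure features).
#' @param ... Unused.
#' @return Data frame with `label` and `decision`, one row per fragment.
#' @export
predict.gla_model <- function(object, fragments, profiles = NULL, ...) {
  if (nrow(fragments) == 0L) {
    return(data.frame(label = character(0), decision = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (fragment_half_width(fragments$window) != object$n) {
    stop("fragment window length does not match the model (n = ",
         object$n, ")")
  }
  features <- encode_fragments(fragments, object$selection, object$pwm,
                               profiles)
  predict(object$svm, features)
}

#' Scan proteins for candidate carboxylation sites
#'
#' Extracts a window around every glutamate of every record and predicts
#' each one.  Proteins without glutamate yield no rows.
#'
#' @param model A fitted `gla_model`.
#' @param records Named record list.
#' @param profiles Named profile list (required for structure features).
#' @return Data frame with `protein_id`, `position`, `label`, `decision`.
#' @export
predict_sites <- function(model, records, profiles = NULL) {
  frags <- extract_fragments(records, window_config(model$n))
  if (nrow(frags) == 0L) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      label = character(0), decision = numeric(0),
                      stringsAsFactors = FALSE))
  }
  pred <- predict(model, frags, profiles)
  data.frame(protein_id = frags$protein_id, position = frags$center,
             label = pred$label, decision = pred$decision,
             stringsAsFactors = FALSE)
}
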