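# Feature encodings: positional weighted matrix (PWM), amino-acid
# composition (AAC), solvent accessibility (ASA) and secondary structure
# (SS), concatenated in that fixed order.

#' Build a positional weighted matrix from positive fragments
#'
#' The PWM holds, for each window position `-n..+n`, the occurrence
#' frequency of the 21 symbols (20 residues plus the `'-'` terminal signal)
#' among the supplied positive fragments.  No pseudocounts are added;
#' `'X'` residues are not counted (their column does not exist), so rows of
#' X-free input sum to exactly 1.
#'
#' @param positive_fragments Fragment data frame or character vector of
#'   windows, all of length `2n + 1`.
#' @param cfg Optional [window_config()]; inferred from the windows when
#'   omitted.
#' @return A `(2n + 1) x 21` matrix of class `pwm`, rows named by offset.
#' @export
build_pwm <- function(positive_fragments, cfg = NULL) {
  windows <- as_windows(positive_fragments)
  if (length(windows) == 0L) stop("cannot build a PWM from zero fragments")
  n <- fragment_half_width(windows)
  if (!is.null(cfg) && cfg$n != n) {
    stop("fragments have half-width ", n, " but cfg$n is ", cfg$n)
  }
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  freq <- t(apply(mat, 2L, function(col) {
    tabulate(factor(col, levels = ALPHABET21), nbins = 21L)
  })) / length(windows)
  dimnames(freq) <- list(as.character(seq.int(-n, n)), ALPHABET21)
  structure(freq, class = c("pwm", "matrix"), n = n)
}

#' Encode a fragment against a positional weighted matrix
#'
#' Each window position maps to the PWM frequency of the symbol observed
#' there, yielding a `(2n + 1)`-element vector.  Symbols unseen in training
#' (and `'X'`) encode to 0.  Set `flatten = TRUE` for the alternative
#' `(2n + 1) x 21` one-hot reading, in which each position contributes a
#' 21-element block that is all zero except the observed symbol's PWM
#' frequency.
#'
#' @param fragment A window string or one-row fragment data frame.
#' @param pwm A [build_pwm()] matrix.
#' @param flatten Use the flattened one-hot-weighted encoding (default off).
#' @return Numeric feature vector of length `2n + 1` (or `(2n + 1) * 21`).
#' @export
encode_pwm <- function(fragment, pwm, flatten = FALSE) {
  window <- as_windows(fragment)
  stopifnot(length(window) == 1L)
  cc <- chars(window)
  if (length(cc) != nrow(pwm)) {
    stop("fragment length ", length(cc), " does not match PWM rows ", nrow(pwm))
  }
  bad <- setdiff(cc, FRAGMENT_SYMBOLS)
  if (length(bad) > 0L) {
    stop("fragment contains symbols outside the alphabet: ",
         paste(bad, collapse = ", "))
  }
  col <- match(cc, colnames(pwm))
  if (!flatten) {
    vals <- numeric(length(cc))
    seen <- !is.na(col)
    vals[seen] <- pwm[cbind(which(seen), col[seen])]
    return(vals)
  }
  out <- matrix(0, nrow = nrow(pwm), ncol = ncol(pwm))
  seen <- !is.na(col)
  out[cbind(which(seen), col[seen])] <- pwm[cbind(which(seen), col[seen])]
  as.numeric(t(out))
}

#' Amino-acid composition of a fragment
#'
#' Relative frequency of the 20 residues within the window; terminal padding
#' and `'X'` are excluded from both numerator and denominator.
#'
#' @param fragment A window string or one-row fragment data frame.
#' @return Named numeric vector of length 20 summing to 1 (or at most 1 in
#'   degenerate cases).
#' @export
encode_aac <- function(fragment) {
  window <- as_windows(fragment)
  stopifnot(length(window) == 1L)
  cc <- chars(window)
  cc <- cc[cc %in% AA20]
  if (length(cc) == 0L) stop("fragment has no standard residues")
  counts <- tabulate(factor(cc, levels = AA20), nbins = 20L)
  stats::setNames(counts / length(cc), AA20)
}

#' One-hot encode a secondary-structure window
#'
#' Each position becomes a 3-bit block in the order `(H, E, C)`:
#' helix `100`, sheet `010`, coil `001`, padding `000`.
#'
#' @param ss_window Character vector over `H`, `E`, `C`, `pad`.
#' @return Numeric vector of length `3 * length(ss_window)`.
#' @export
encode_ss <- function(ss_window) {
  bad <- setdiff(unique(ss_window), c(SS_STATES, "pad"))
  if (length(bad) > 0L) {
    stop("unknown secondary-structure state(s): ", paste(bad, collapse = ", "))
  }
  blocks <- vapply(ss_window, function(s) {
    as.numeric(SS_STATES == s)
  }, numeric(3))
  as.numeric(blocks)
}

#' Validate and pass through a normalized ASA window
#'
#' @param asa_window Numeric vector in `[0, 1]`.
#' @return The same vector.
#' @export
encode_asa <- function(asa_window) {
  if (anyNA(asa_window) || any(asa_window < 0 | asa_window > 1)) {
    stop("normalized ASA values must lie in [0, 1]")
  }
  as.numeric(asa_window)
}

#' Length of an encoded feature vector
#'
#' @param selection Character subset of `AA_PWM`, `AAC`, `ASA`, `SS`.
#' @param n Window half-width.
#' @return Integer vector length.
#' @export
feature_length <- function(selection, n) {
  selection <- check_selection(selection)
  w <- 2L * n + 1L
  sum(c(AA_PWM = w, AAC = 20L, ASA = w, SS = 3L * w)[selection])
}

check_selection <- function(selection) {
  selection <- unique(as.character(selection))
  if (length(selection) == 0L) stop("feature selection must be non-empty")
  bad <- setdiff(selection, FEATURE_NAMES)
  if (length(bad) > 0L) {
    stop("unknown feature(s): ", paste(bad, collapse = ", "))
  }
  FEATURE_NAMES[FEATURE_NAMES %in% selection]
}

#' Concatenate selected feature encodings for one fragment
#'
#' Features are concatenated in the fixed order `AA_PWM`, `AAC`, `ASA`,
#' `SS`; a `"schema"` attribute records each span.
#'
#' @param fragment A window string or one-row fragment data frame.
#' @param selection Non-empty subset of `AA_PWM`, `AAC`, `ASA`, `SS`.
#' @param pwm PWM, required when `AA_PWM` is selected.
#' @param asa_window Normalized ASA window, required when `ASA` is selected.
#' @param ss_window State window, required when `SS` is selected.
#' @return Numeric feature vector with a `schema` attribute.
#' @export
concat_features <- function(fragment, selection, pwm = NULL,
                            asa_window = NULL, ss_window = NULL) {
  selection <- check_selection(selection)
  parts <- list()
  if ("AA_PWM" %in% selection) {
    if (is.null(pwm)) stop("AA_PWM selected but no PWM supplied")
    parts$AA_PWM <- encode_pwm(fragment, pwm)
  }
  if ("AAC" %in% selection) parts$AAC <- as.numeric(encode_aac(fragment))
  if ("ASA" %in% selection) {
    if (is.null(asa_window)) stop("ASA selected but no structure profile supplied")
    parts$ASA <- encode_asa(asa_window)
  }
  if ("SS" %in% selection) {
    if (is.null(ss_window)) stop("SS selected but no structure profile supplied")
    parts$SS <- encode_ss(ss_window)
  }
  out <- unlist(parts, use.names = FALSE)
  attr(out, "schema") <- data.frame(
    feature = names(parts),
    length = vapply(parts, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Encode a set of fragments as a feature matrix
#'
#' @param fragments Fragment data frame.
#' @param selection Feature selection (see [concat_features()]).
#' @param pwm PWM built from positive training fragments, required for
#'   `AA_PWM`.
#' @param profiles Named list of [residue_profile()] objects, required for
#'   `ASA` or `SS`.
#' @return Numeric matrix, one row per fragment, with a `schema` attribute.
#' @export
encode_fragments <- function(fragments, selection, pwm = NULL,
                             profiles = NULL) {
  selection <- check_selection(selection)
  needs_profile <- any(c("ASA", "SS") %in% selection)
  n <- fragment_half_width(fragments$window)
  cfg <- window_config(n)
  rows <- vector("list", nrow(fragments))
  for (i in seq_len(nrow(fragments))) {
    asa_w <- NULL
    ss_w <- NULL
    if (needs_profile) {
      pid <- fragments$protein_id[i]
      if (is.null(profiles) || is.null(profiles[[pid]])) {
        stop("structure profile required but missing for protein ", pid)
      }
      pw <- profile_window(profiles[[pid]], fragments$center[i], cfg)
      asa_w <- pw$asa
      ss_w <- pw$ss
    }
    rows[[i]] <- concat_features(fragments$window[i], selection, pwm = pwm,
                                 asa_window = asa_w, ss_window = ss_w)
  }
  schema <- if (nrow(fragments) > 0L) attr(rows[[1]], "schema") else NULL
  mat <- do.call(rbind, rows)
  if (is.null(mat)) mat <- matrix(numeric(0), nrow = 0L,
                                  ncol = feature_length(selection, n))
  attr(mat, "schema") <- schema
  mat
}

#' Write a PWM to TSV
#'
#' @param pwm A [build_pwm()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwm, path) {
  df <- data.frame(position = rownames(pwm), unclass(pwm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PWM from TSV
#'
#' @param path Path written by [write_pwm()].
#' @return A `pwm` matrix.
#' @export
read_pwm <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  if (!identical(colnames(mat), ALPHABET21)) {
    stop("PWM file columns do not match the 21-symbol alphabet: ", path)
  }
  n <- (nrow(mat) - 1L) / 2L
  structure(mat, class = c("pwm", "matrix"), n = as.integer(n))
}
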