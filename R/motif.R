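# Position-specific composition analyses: per-position residue frequencies,
# two-sample enrichment/depletion statistics, mean-ASA curves and
# secondary-structure fractions at the central glutamate.

#' Per-position residue frequency matrix
#'
#' Relative frequency of the 20 residues at each window offset; padding and
#' `'X'` are excluded, with per-position renormalization over the residues
#' actually observed.
#'
#' @param fragments Fragment data frame or character vector of windows.
#' @return `(2n + 1) x 20` matrix, rows named by offset `-n..+n`, each row
#'   summing to 1 (or `NA` if a position is entirely padding).
#' @export
frequency_matrix <- function(fragments) {
  windows <- as_windows(fragments)
  if (length(windows) == 0L) stop("no fragments supplied")
  n <- fragment_half_width(windows)
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  freq <- t(apply(mat, 2L, function(col) {
    counts <- tabulate(factor(col, levels = AA20), nbins = 20L)
    if (sum(counts) == 0L) rep(NA_real_, 20L) else counts / sum(counts)
  }))
  dimnames(freq) <- list(as.character(seq.int(-n, n)), AA20)
  freq
}

#' Position-specific composition differences between two fragment sets
#'
#' For every (offset, residue) cell, a two-proportion z-test (pooled
#' variance, two-sided) compares the occurrence frequency between the two
#' sets; cells with `p < alpha` are reported as enriched (more frequent in
#' the first set) or depleted.  Padding and `'X'` are excluded from the
#' per-position denominators; cells whose pooled frequency is 0 or 1 carry
#' no information and are skipped.
#'
#' @param pos_fragments,neg_fragments The two fragment sets (data frames or
#'   window vectors) with equal window lengths.
#' @param alpha Significance level, default 0.05 (no multiple-testing
#'   correction, matching the usual two-sample logo convention).
#' @param p_adjust_method Optional [stats::p.adjust()] method applied across
#'   all tested cells before thresholding (default `"none"`).
#' @return Data frame with `position`, `residue`, `direction`, `p_value`,
#'   `freq_pos`, `freq_neg`, sorted by position then residue.
#' @export
two_sample_diff <- function(pos_fragments, neg_fragments, alpha = 0.05,
                            p_adjust_method = "none") {
  pos <- as_windows(pos_fragments)
  neg <- as_windows(neg_fragments)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both fragment sets must be non-empty")
  }
  n <- fragment_half_width(c(pos, neg))
  count_at <- function(windows) {
    mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
    counts <- apply(mat, 2L, function(col) {
      tabulate(factor(col, levels = AA20), nbins = 20L)
    })
    rownames(counts) <- AA20
    counts  # 20 x (2n+1)
  }
  c1 <- count_at(pos)
  c2 <- count_at(neg)
  n1 <- matrix(rep(colSums(c1), each = 20L), nrow = 20L)
  n2 <- matrix(rep(colSums(c2), each = 20L), nrow = 20L)
  p1 <- c1 / n1
  p2 <- c2 / n2
  pp <- (c1 + c2) / (n1 + n2)
  testable <- n1 > 0 & n2 > 0 & pp > 0 & pp < 1
  z <- matrix(NA_real_, 20L, 2L * n + 1L)
  z[testable] <- (p1[testable] - p2[testable]) /
    sqrt(pp[testable] * (1 - pp[testable]) *
           (1 / n1[testable] + 1 / n2[testable]))
  pval <- 2 * stats::pnorm(-abs(z))
  pval[testable] <- stats::p.adjust(pval[testable], method = p_adjust_method)
  offsets <- seq.int(-n, n)
  hit <- which(testable & pval < alpha, arr.ind = TRUE)
  out <- data.frame(
    position = offsets[hit[, 2L]],
    residue = AA20[hit[, 1L]],
    direction = ifelse(p1[hit] > p2[hit], "enriched", "depleted"),
    p_value = pval[hit],
    freq_pos = p1[hit],
    freq_neg = p2[hit],
    stringsAsFactors = FALSE)
  out[order(out$position, out$residue), , drop = FALSE]
}

#' Mean ASA percentage per window offset
#'
#' Arithmetic mean of the per-residue ASA percentage at each offset across a
#' fragment set; positions beyond the protein termini are excluded from the
#' mean (not counted as zero).
#'
#' @param fragments Fragment data frame.
#' @param profiles Named profile list covering every fragment's protein.
#' @return Data frame with `offset`, `mean_asa_percent`, `n_residues`.
#' @export
mean_asa_curve <- function(fragments, profiles) {
  n <- fragment_half_width(fragments$window)
  offsets <- seq.int(-n, n)
  vals <- matrix(NA_real_, nrow = nrow(fragments), ncol = length(offsets))
  for (i in seq_len(nrow(fragments))) {
    prof <- profiles[[fragments$protein_id[i]]]
    if (is.null(prof)) {
      stop("missing structure profile for protein ", fragments$protein_id[i])
    }
    idx <- fragments$center[i] + offsets
    inside <- idx >= 1L & idx <= length(prof$asa)
    vals[i, inside] <- prof$asa[idx[inside]]
  }
  data.frame(offset = offsets,
             mean_asa_percent = colMeans(vals, na.rm = TRUE),
             n_residues = colSums(!is.na(vals)))
}

#' Secondary-structure fractions at the central position
#'
#' @param fragments Fragment data frame.
#' @param profiles Named profile list covering every fragment's protein.
#' @return Named numeric vector of the helix/sheet/coil fractions at the
#'   window centre, summing to 1.
#' @export
ss_fractions <- function(fragments, profiles) {
  states <- vapply(seq_len(nrow(fragments)), function(i) {
    prof <- profiles[[fragments$protein_id[i]]]
    if (is.null(prof)) {
      stop("missing structure profile for protein ", fragments$protein_id[i])
    }
    prof$ss[fragments$center[i]]
  }, character(1))
  counts <- tabulate(factor(states, levels = SS_STATES), nbins = 3L)
  stats::setNames(counts / sum(counts), SS_STATES)
}
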