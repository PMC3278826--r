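# Two-stage homology reduction: proteins above 30% pairwise similarity are
# homologous; among fragments from homologous proteins, pairs above 50%
# similarity are collapsed to the first-seen fragment.

# BLOSUM62 scoring matrix, loaded once from Biostrings.
.blosum_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.blosum_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$m <- e$BLOSUM62
  }
  .blosum_cache$m
}

#' Pairwise local-alignment similarity of two residue strings
#'
#' Computes the best Smith-Waterman local alignment under BLOSUM62 with
#' affine gap costs 11 (open) / 1 (extend) and returns the number of
#' identical aligned residue pairs divided by the length of the shorter
#' sequence.  Padding symbols (`'-'`) are stripped before alignment.  When no
#' positive-scoring alignment exists the similarity is 0.
#'
#' @param seq_a,seq_b Residue strings (padding allowed, stripped first).
#' @return Similarity in `[0, 1]`; symmetric, and 1 for identical sequences.
#' @export
pairwise_similarity <- function(seq_a, seq_b) {
  a <- gsub(PAD_SYMBOL, "", seq_a, fixed = TRUE)
  b <- gsub(PAD_SYMBOL, "", seq_b, fixed = TRUE)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("cannot align an empty sequence")
  }
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1)
  if (Biostrings::score(aln) <= 0) return(0)
  ident <- Biostrings::nmatch(aln)
  min(1, ident / min(nchar(a), nchar(b)))
}

#' Find homologous protein pairs
#'
#' All unordered pairs of records whose full-length pairwise similarity
#' exceeds `threshold` (strictly) are reported as homologous.
#'
#' @param records Named list of protein records.
#' @param threshold Similarity threshold, default 0.30.
#' @return Data frame with columns `a_id`, `b_id`, `similarity`.
#' @export
find_homologous_pairs <- function(records, threshold = 0.30) {
  if (length(records) < 2L) {
    return(data.frame(a_id = character(0), b_id = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE))
  }
  ids <- vapply(records, `[[`, character(1), "id")
  combos <- utils::combn(length(records), 2L)
  sims <- apply(combos, 2L, function(ij) {
    pairwise_similarity(records[[ij[1]]]$sequence, records[[ij[2]]]$sequence)
  })
  keep <- sims > threshold
  data.frame(a_id = ids[combos[1L, keep]],
             b_id = ids[combos[2L, keep]],
             similarity = sims[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove redundant fragments from homologous proteins
#'
#' Greedy left-to-right scan: each fragment is compared (padding stripped)
#' against the already-kept fragments of the same label whose parent protein
#' forms a homologous pair with its own; if any such pair exceeds
#' `frag_threshold` similarity the incoming fragment is dropped.  Positive
#' and negative fragments are reduced independently, the input order is
#' preserved, and the result is idempotent.
#'
#' @param fragments Fragment data frame (all windows the same length).
#' @param homologous_pairs Data frame of homologous protein id pairs as
#'   returned by [find_homologous_pairs()].
#' @param frag_threshold Fragment-level similarity threshold, default 0.50.
#' @return The retained fragments, with a `"report"` attribute listing
#'   `(kept_protein, kept_center, removed_protein, removed_center,
#'   similarity)` for every removal.
#' @export
reduce_fragments <- function(fragments, homologous_pairs,
                             frag_threshold = 0.50) {
  fragment_half_width(fragments$window)  # errors on mixed lengths
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  hom <- character(0)
  if (nrow(homologous_pairs) > 0L) {
    hom <- pair_key(homologous_pairs$a_id, homologous_pairs$b_id)
  }
  keep <- logical(nrow(fragments))
  report <- list()
  kept_idx <- integer(0)
  for (i in seq_len(nrow(fragments))) {
    drop_against <- NA_integer_
    sim_hit <- NA_real_
    for (j in kept_idx) {
      if (fragments$label[j] != fragments$label[i]) next
      pid_i <- fragments$protein_id[i]
      pid_j <- fragments$protein_id[j]
      if (pid_i == pid_j) next
      if (!(pair_key(pid_i, pid_j) %in% hom)) next
      sim <- pairwise_similarity(fragments$window[i], fragments$window[j])
      if (sim > frag_threshold) {
        drop_against <- j
        sim_hit <- sim
        break
      }
    }
    if (is.na(drop_against)) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    } else {
      report[[length(report) + 1L]] <- data.frame(
        kept_protein = fragments$protein_id[drop_against],
        kept_center = fragments$center[drop_against],
        removed_protein = fragments$protein_id[i],
        removed_center = fragments$center[i],
        similarity = sim_hit,
        stringsAsFactors = FALSE)
    }
  }
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- if (length(report) > 0L) {
    do.call(rbind, report)
  } else {
    data.frame(kept_protein = character(0), kept_center = integer(0),
               removed_protein = character(0), removed_center = integer(0),
               similarity = numeric(0), stringsAsFactors = FALSE)
  }
  out
}
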