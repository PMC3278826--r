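# Independent oracles used to cross-check the implementation.

# Smith-Waterman local alignment with affine gaps (Gotoh), scored like the
# implementation (BLOSUM62; gap of length L costs open + L * ext) but coded
# independently as a plain dynamic program with traceback.
sw_oracle <- function(a, b, open = 11, ext = 1) {
  sub <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  H <- matrix(0, na + 1, nb + 1)
  E <- matrix(-Inf, na + 1, nb + 1)  # gap in a (consumes b)
  F <- matrix(-Inf, na + 1, nb + 1)  # gap in b (consumes a)
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      diag <- H[i - 1, j - 1] + sub[av[i - 1], bv[j - 1]]
      H[i, j] <- max(0, diag, E[i, j], F[i, j])
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)[1, ]
  score <- max(H)
  # traceback for identities / alignment length
  i <- best[1]; j <- best[2]; state <- "H"
  ident <- 0L; alen <- 0L
  while (TRUE) {
    if (state == "H") {
      if (H[i, j] == 0) break
      diag <- H[i - 1, j - 1] + sub[av[i - 1], bv[j - 1]]
      if (H[i, j] == diag) {
        alen <- alen + 1L
        if (av[i - 1] == bv[j - 1]) ident <- ident + 1L
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      alen <- alen + 1L
      from_h <- H[i, j - 1] - open - ext
      if (E[i, j] == from_h) { j <- j - 1L; state <- "H" }
      else { E_prev <- E[i, j - 1] - ext; stopifnot(E[i, j] == E_prev); j <- j - 1L }
    } else {
      alen <- alen + 1L
      from_h <- H[i - 1, j] - open - ext
      if (F[i, j] == from_h) { i <- i - 1L; state <- "H" }
      else { F_prev <- F[i - 1, j] - ext; stopifnot(F[i, j] == F_prev); i <- i - 1L }
    }
  }
  list(score = score, identities = ident, alen = alen,
       similarity = if (score <= 0) 0 else min(1, ident / min(na, nb)))
}

# Brute-force metric recount: recompute the five metrics directly from
# per-sample truth/prediction vectors with the plain formulas.
recount_metrics <- function(truth, predicted) {
  tp <- sum(truth == "positive" & predicted == "positive")
  fp <- sum(truth == "negative" & predicted == "positive")
  tn <- sum(truth == "negative" & predicted == "negative")
  fn <- sum(truth == "positive" & predicted == "negative")
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
    specificity = if (tn + fp == 0) 0 else tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# Greedy left-to-right reduction oracle: scan fragments in order, keep a
# fragment unless some already-kept fragment of the same label from a
# homologous parent exceeds the similarity threshold.
reduce_oracle <- function(fragments, hom_pairs, threshold = 0.5) {
  keyify <- function(a, b) paste(pmin(a, b), pmax(a, b))
  hom <- if (nrow(hom_pairs)) keyify(hom_pairs$a_id, hom_pairs$b_id) else character(0)
  kept <- integer(0)
  for (i in seq_len(nrow(fragments))) {
    dup <- FALSE
    for (j in kept) {
      if (fragments$label[i] != fragments$label[j]) next
      if (fragments$protein_id[i] == fragments$protein_id[j]) next
      if (!(keyify(fragments$protein_id[i], fragments$protein_id[j]) %in% hom)) next
      if (pairwise_similarity(fragments$window[i], fragments$window[j]) > threshold) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  fragments[kept, , drop = FALSE]
}

random_protein <- function(len, seed) {
  aa <- c("A","C","D","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
  withr::with_seed(seed, paste(sample(aa, len, replace = TRUE), collapse = ""))
}
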