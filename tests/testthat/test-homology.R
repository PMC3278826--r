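test_that("pairwise similarity matches the self/dissimilar/derived cases", {
  expect_equal(pairwise_similarity("MEAE", "MEAE"), 1)
  expect_equal(pairwise_similarity("AAAA", "CCCC"), 0)
  expect_equal(pairwise_similarity("MEAEKLV", "MEAEKIV"),
               sw_oracle("MEAEKLV", "MEAEKIV")$similarity)
  # padding is stripped before alignment
  expect_equal(pairwise_similarity("--MEAE-", "MEAE"), 1)
  expect_error(pairwise_similarity("----", "MEAE"), "empty")
})

test_that("alignment scores agree with an independent dynamic program", {
  set.seed(7)
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "")
  for (rep in 1:15) {
    a <- paste(sample(aa, sample(6:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(6:12, 1), replace = TRUE), collapse = "")
    oracle <- sw_oracle(a, b)
    aln <- Biostrings::pairwiseAlignment(
      a, b, type = "local",
      substitutionMatrix = glapred:::blosum62(),
      gapOpening = 11, gapExtension = 1)
    expect_equal(Biostrings::score(aln), oracle$score,
                 info = paste(a, b))
  }
})

test_that("similarity is symmetric", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:10) {
    a <- paste(sample(aa, 20, replace = TRUE), collapse = "")
    b <- paste(sample(aa, 25, replace = TRUE), collapse = "")
    expect_equal(pairwise_similarity(a, b), pairwise_similarity(b, a))
  }
})

test_that("homologous pairs form the expected graph", {
  s <- random_protein(80, seed = 21)
  recs <- list(A = protein_record("A", s),
               B = protein_record("B", s),
               C = protein_record("C", s))
  pairs <- find_homologous_pairs(recs)
  expect_equal(nrow(pairs), 3L)  # complete graph on 3 identical proteins
  expect_true(all(pairs$similarity == 1))

  recs2 <- list(A = protein_record("A", strrep("A", 60)),
                B = protein_record("B", strrep("C", 60)))
  expect_equal(nrow(find_homologous_pairs(recs2)), 0L)
  expect_equal(nrow(find_homologous_pairs(recs2[1])), 0L)
})

test_that("fragment reduction keeps the first of similar fragments and is gated by protein homology", {
  w <- "ACDEFGHELMNPQRS"  # 15-mer, centre E
  frags <- data.frame(protein_id = c("A", "B"), center = c(8L, 8L),
                      window = c(w, w), label = "positive",
                      stringsAsFactors = FALSE)
  hom <- data.frame(a_id = "A", b_id = "B", similarity = 1,
                    stringsAsFactors = FALSE)
  no_hom <- hom[0, ]
  red <- reduce_fragments(frags, hom)
  expect_equal(nrow(red), 1L)
  expect_equal(red$protein_id, "A")  # stable keep-first
  expect_equal(nrow(attr(red, "report")), 1L)
  # identical fragments from non-homologous proteins are both kept
  expect_equal(nrow(reduce_fragments(frags, no_hom)), 2L)

  # three mutually similar fragments from mutually homologous proteins
  frags3 <- data.frame(protein_id = c("A", "B", "C"), center = 8L,
                       window = w, label = "positive",
                       stringsAsFactors = FALSE)
  hom3 <- data.frame(a_id = c("A", "A", "B"), b_id = c("B", "C", "C"),
                     similarity = 1, stringsAsFactors = FALSE)
  red3 <- reduce_fragments(frags3, hom3)
  expect_equal(nrow(red3), 1L)
  expect_equal(red3, reduce_oracle(frags3, hom3), ignore_attr = TRUE)

  expect_error(reduce_fragments(
    data.frame(protein_id = c("A", "B"), center = 8L,
               window = c(w, substr(w, 1, 9)), label = "positive"),
    hom), "mixed window lengths")
})

test_that("reduction is idempotent, label-separated and leaves no similar retained pair", {
  # duplicated proteins give genuinely homologous parents
  d <- generate_gla_dataset(gla_generator_spec(n_proteins = 6L,
                                               duplicate_proteins = 4L,
                                               seed = 33L))
  frags <- extract_fragments(d$records, window_config(7))
  hom <- find_homologous_pairs(d$records)
  expect_gte(nrow(hom), 4L)
  red <- reduce_fragments(frags, hom)
  expect_lt(nrow(red), nrow(frags))
  # positives and negatives are reduced independently of one another
  expect_equal(sum(red$label == "positive") + sum(red$label == "negative"),
               nrow(red))
  # idempotence
  strip <- function(df) {
    attr(df, "report") <- NULL
    rownames(df) <- NULL
    df
  }
  red2 <- reduce_fragments(red, hom)
  expect_equal(strip(red2), strip(red))
  # matches the independent greedy-scan oracle
  expect_equal(strip(red), strip(reduce_oracle(frags, hom)))
  # post-condition: no retained same-label pair from homologous parents
  # exceeds the threshold
  keyify <- function(a, b) paste(pmin(a, b), pmax(a, b))
  homkeys <- keyify(hom$a_id, hom$b_id)
  for (i in seq_len(nrow(red) - 1)) {
    for (j in seq(i + 1, nrow(red))) {
      if (red$label[i] != red$label[j]) next
      if (red$protein_id[i] == red$protein_id[j]) next
      if (!(keyify(red$protein_id[i], red$protein_id[j]) %in% homkeys)) next
      expect_lte(pairwise_similarity(red$window[i], red$window[j]), 0.5)
    }
  }
  # a singleton set is unchanged
  single <- frags[1, , drop = FALSE]
  expect_equal(strip(reduce_fragments(single, hom)), strip(single))
})
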