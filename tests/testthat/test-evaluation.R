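test_that("metrics reproduce hand-computable confusion tables", {
  perfect <- compute_metrics(confusion_counts(5, 0, 5, 0))
  expect_equal(metric_vector(perfect),
               c(precision = 1, sensitivity = 1, specificity = 1,
                 accuracy = 1, mcc = 1))
  random <- compute_metrics(confusion_counts(1, 1, 1, 1))
  expect_equal(random$mcc, 0)
  expect_equal(random$accuracy, 0.5)
  # zero-denominator factors define MCC as 0
  degenerate <- compute_metrics(confusion_counts(0, 0, 4, 2))
  expect_equal(degenerate$mcc, 0)
  expect_equal(degenerate$precision, 0)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "all zero")
  expect_error(confusion_counts(-1, 0, 1, 0), "non-negative")
})

test_that("textual metric output truncates to three decimals", {
  m <- compute_metrics(confusion_counts(260, 51, 516, 42))
  # 0.86092... and 0.89298... truncate (not round) to 0.860 and 0.892
  v <- metric_vector(m, truncated = TRUE)
  expect_equal(unname(v["sensitivity"]), 0.860)
  expect_equal(unname(v["accuracy"]), 0.892)
  expect_match(format(m), "Sn=0.860")
})

test_that("stratified k-fold assignments satisfy the partition laws", {
  labels <- rep(c("positive", "negative"), c(5, 5))
  folds <- kfold_split(labels, k = 5, seed = 3)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(as.vector(table(folds)), rep(2L, 5))
  expect_identical(folds, kfold_split(labels, k = 5, seed = 3))
  expect_false(identical(folds, kfold_split(labels, k = 5, seed = 4)))
  expect_error(kfold_split(labels, k = 11), "exceeds sample count")
  expect_error(kfold_split(labels, k = 1), "at least 2")

  # per-class fold sizes differ by at most one on imbalanced data
  labels2 <- rep(c("positive", "negative"), c(23, 48))
  folds2 <- kfold_split(labels2, k = 5, seed = 1)
  for (cls in c("positive", "negative")) {
    sizes <- table(factor(folds2[labels2 == cls], levels = 1:5))
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("cross-validation pools per-fold predictions conservatively", {
  frags <- small_fragments()
  d <- small_dataset()
  cv <- cross_validate(frags, d$profiles, c("AA_PWM", "AAC", "ASA"),
                       tuned_cfg(), k = 5, seed = 3)
  counts <- cv$counts
  expect_equal(counts$TP + counts$FP + counts$TN + counts$FN, nrow(frags))
  expect_equal(counts$TP + counts$FN, sum(frags$label == "positive"))
  expect_equal(counts$TN + counts$FP, sum(frags$label == "negative"))
  # the pooled metrics agree with a direct recount of per-sample outcomes
  expect_equal(metric_vector(cv$metrics),
               recount_metrics(cv$predictions$truth, cv$predictions$label))
  # every fragment is predicted exactly once, in its own fold
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)

  # the combined sequence+ASA features beat secondary structure alone
  cv_ss <- cross_validate(frags, d$profiles, "SS", tuned_cfg(),
                          k = 5, seed = 3)
  expect_gt(cv$metrics$accuracy, cv_ss$metrics$accuracy)
})

test_that("window sweep re-runs the pipeline per half-width", {
  d <- small_dataset()
  sub <- d$records[1:12]
  tab <- window_sweep(sub, d$profiles, n_values = 7, selection = "AAC",
                      cfg = tuned_cfg(), seed = 2,
                      homologous_pairs = find_homologous_pairs(sub))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$window_length, 15L)
  tab2 <- window_sweep(sub, d$profiles, n_values = c(4, 6, 8),
                       selection = "AAC", cfg = tuned_cfg(), seed = 2,
                       homologous_pairs = find_homologous_pairs(sub))
  expect_equal(tab2$n, c(4L, 6L, 8L))
  expect_true(all(tab2$accuracy >= 0 & tab2$accuracy <= 1))
})

test_that("accuracy plateaus once the window covers the planted signal", {
  # signal confined to offsets within +/-4
  spec <- gla_generator_spec(
    n_proteins = 25L,
    glu_enriched_offsets = c(-4, -3, -1, 1, 3, 4),
    arg_enriched_offsets = c(-4, -1, 3),
    seed = 77L)
  d <- generate_gla_dataset(spec)
  tab <- window_sweep(d$records, d$profiles, n_values = c(4, 7, 10),
                      selection = c("AA_PWM", "AAC", "ASA"),
                      cfg = tuned_cfg(), seed = 5,
                      homologous_pairs = find_homologous_pairs(d$records))
  expect_lt(max(tab$accuracy) - min(tab$accuracy), 0.06)
})

test_that("feature-combination evaluation mirrors the canonical table layout", {
  expect_length(default_feature_combinations(), 10L)
  frags <- small_fragments()[1:150, ]
  d <- small_dataset()
  tab <- feature_combination_eval(frags, d$profiles,
                                  combinations = list("AAC", c("AAC", "ASA")),
                                  cfg = tuned_cfg(), k = 3, seed = 2)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$features, c("AAC", "AAC+ASA"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_true(all(tab$mcc >= -1 & tab$mcc <= 1))
})

test_that("independent testing guards against protein overlap and degenerate sets", {
  d <- small_dataset()
  ids <- names(d$records)
  train_frags <- extract_fragments(d$records[ids[1:24]], window_config(7))
  test_frags <- extract_fragments(d$records[ids[25:30]], window_config(7))
  model <- fit_gla_model(train_frags, d$profiles,
                         c("AA_PWM", "AAC", "ASA"), tuned_cfg())
  expect_error(independent_test(model, train_frags, d$profiles), "overlap")
  neg_only <- test_frags[test_frags$label == "negative", ]
  expect_error(independent_test(model, neg_only, d$profiles), "no positive")

  res <- independent_test(model, test_frags, d$profiles)
  expect_equal(res$counts$TP + res$counts$FN,
               sum(test_frags$label == "positive"))
  # held-out performance tracks cross-validation on the same generator
  cv <- cross_validate(train_frags, d$profiles, c("AA_PWM", "AAC", "ASA"),
                       tuned_cfg(), k = 5, seed = 3)
  expect_lt(abs(res$metrics$accuracy - cv$metrics$accuracy), 0.1)
})
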