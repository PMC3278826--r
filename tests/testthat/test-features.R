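test_that("the PWM records per-position symbol frequencies", {
  pwm <- build_pwm(c("AEC"))
  expect_equal(pwm["-1", "A"], 1)
  expect_equal(pwm["0", "E"], 1)
  expect_equal(pwm["1", "C"], 1)
  pwm2 <- build_pwm(c("AEC", "CEA"))
  expect_equal(pwm2["-1", "A"], 0.5)
  expect_equal(pwm2["-1", "C"], 0.5)
  expect_equal(unname(rowSums(pwm2)), rep(1, 3))
  # the centre row of any valid fragment set is a point mass on E
  pwm3 <- build_pwm(small_fragments()[small_fragments()$label == "positive", ])
  expect_equal(pwm3["0", "E"], 1)
  expect_equal(unname(rowSums(pwm3)), rep(1, 15), tolerance = 1e-9)
  # padding counts in the '-' column
  pwm4 <- build_pwm(c("-EA", "AEC"))
  expect_equal(pwm4["-1", "-"], 0.5)
  expect_error(build_pwm(character(0)), "zero fragments")
})

test_that("PWM encoding looks up positional frequencies", {
  pwm <- build_pwm(c("AEC"))
  expect_equal(encode_pwm("AEC", pwm), c(1, 1, 1))
  expect_equal(encode_pwm("CEA", pwm), c(0, 1, 0))
  expect_equal(encode_pwm("XEX", pwm), c(0, 1, 0))  # unknown residue -> 0
  expect_error(encode_pwm("AE", pwm), "does not match")
  expect_error(encode_pwm("AE?", pwm), "outside the alphabet")
  # values are bounded by the maximum row frequency
  pwm2 <- build_pwm(c("AEC", "CEA", "AEA"))
  for (w in c("AEA", "CEC", "WEW")) {
    expect_true(all(encode_pwm(w, pwm2) <= apply(pwm2, 1, max)))
  }
  # flattened reading expands to (2n+1) x 21 with one block per position
  flat <- encode_pwm("AEC", pwm, flatten = TRUE)
  expect_length(flat, 3 * 21)
  expect_equal(sum(flat != 0), 3)
})

test_that("amino-acid composition excludes padding and unknowns", {
  aac <- encode_aac("EEEEEEE")
  expect_equal(unname(aac["E"]), 1)
  expect_equal(sum(aac), 1)
  aac2 <- encode_aac("AAEEEEG")
  expect_equal(unname(aac2[c("A", "E", "G")]), c(2, 4, 1) / 7)
  expect_equal(unname(encode_aac("-EE")["E"]), 1)  # denominator 2
  expect_equal(unname(encode_aac("XEE-")["E"]), 1)
  expect_error(encode_aac("---"), "no standard residues")
})

test_that("secondary structure one-hot encodes H/E/C with zero padding", {
  expect_equal(encode_ss(c("H", "E", "C")),
               c(1, 0, 0, 0, 1, 0, 0, 0, 1))
  expect_equal(encode_ss(c("pad", "H")), c(0, 0, 0, 1, 0, 0))
  expect_equal(encode_ss(rep("C", 15)), rep(c(0, 0, 1), 15))
  expect_error(encode_ss(c("H", "Q")), "unknown")
})

test_that("ASA encoding is a checked identity", {
  expect_equal(encode_asa(c(0.378, 0.5, 0)), c(0.378, 0.5, 0))
  expect_equal(encode_asa(rep(0, 9)), rep(0, 9))
  expect_error(encode_asa(c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("feature vector lengths are pure functions of selection and n", {
  expect_equal(feature_length("AAC", 7), 20L)
  expect_equal(feature_length(c("AA_PWM", "AAC", "ASA"), 7), 50L)
  expect_equal(feature_length(c("AA_PWM", "AAC", "ASA", "SS"), 7), 95L)
  selections <- list("AA_PWM", "AAC", "ASA", "SS",
                     c("AA_PWM", "AAC"), c("AA_PWM", "ASA"),
                     c("AA_PWM", "AAC", "ASA"),
                     c("AA_PWM", "AAC", "ASA", "SS"))
  for (n in 4:10) {
    w <- 2 * n + 1
    pwm <- build_pwm(strrep("E", w))
    asa_w <- rep(0.5, w)
    ss_w <- rep("C", w)
    for (sel in selections) {
      fv <- concat_features(strrep("E", w), sel, pwm = pwm,
                            asa_window = asa_w, ss_window = ss_w)
      expect_length(fv, feature_length(sel, n))
      expect_equal(sum(attr(fv, "schema")$length), length(fv))
    }
  }
})

test_that("concatenation order is fixed and missing inputs are errors", {
  pwm <- build_pwm("AEC")
  fv <- concat_features("AEC", c("SS", "AAC", "AA_PWM"), pwm = pwm,
                        ss_window = c("H", "E", "C"))
  expect_equal(attr(fv, "schema")$feature, c("AA_PWM", "AAC", "SS"))
  expect_error(concat_features("AEC", character(0)), "non-empty")
  expect_error(concat_features("AEC", "ASA"), "no structure profile")
  expect_error(concat_features("AEC", "AA_PWM"), "no PWM")
  expect_error(concat_features("AEC", "BAD"), "unknown feature")
})

test_that("PWM round-trips through its TSV export", {
  pwm <- build_pwm(small_fragments()[small_fragments()$label == "positive", ])
  path <- tempfile(fileext = ".tsv")
  write_pwm(pwm, path)
  back <- read_pwm(path)
  expect_equal(unclass(back), unclass(pwm), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("encoding a fragment set yields a consistent matrix", {
  frags <- small_fragments()[1:40, ]
  d <- small_dataset()
  pwm <- build_pwm(small_fragments()[small_fragments()$label == "positive", ])
  X <- encode_fragments(frags, c("AA_PWM", "AAC", "ASA", "SS"), pwm,
                        d$profiles)
  expect_equal(dim(X), c(40L, 95L))
  expect_true(all(X >= 0 & X <= 1))
  expect_error(encode_fragments(frags, "ASA", profiles = NULL),
               "structure profile required")
})
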