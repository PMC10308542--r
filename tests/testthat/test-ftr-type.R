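test_that("negation detection sees tokens, contractions and is scope-free", {
  expect_equal(detect_negation("Rain tomorrow is not possible"), 1L)
  expect_equal(detect_negation("It will rain tomorrow"), 0L)
  expect_equal(detect_negation("I won't go"), 1L)          # will + not
  expect_equal(detect_negation("I can't and never will"), 1L)
  expect_equal(detect_negation("The knot was tight"), 0L)  # token boundary
})

test_that("mixed-modal detection needs one high- and one low-certainty key", {
  expect_equal(detect_mixed_modal("There is definitely a possibility of rain tomorrow"), 1L)
  expect_equal(detect_mixed_modal("It will definitely rain"), 0L)
  expect_equal(detect_mixed_modal("It could certainly rain"), 1L)
  expect_equal(detect_mixed_modal("It could probably rain"), 0L)  # both low
})

test_that("modal categories dominate tense and all matched modal flags set", {
  r <- classify_ftr_type(c("It will possibly rain tomorrow",
                           "Tomorrow it could rain",
                           "I wish it would rain tomorrow"))
  expect_equal(r$other_low_certainty[1], 1L)
  expect_equal(r$future_tense[1], 0L)
  expect_equal(r$present_tense[1], 0L)
  expect_equal(r$verbal_low_certainty[2], 1L)
  expect_equal(r$present_tense[2], 0L)
  # flag sets: bouletic wish + irrealis would both fire
  expect_equal(r$bouletic[3], 1L)
  expect_equal(r$irrealis[3], 1L)
})

test_that("exclusion precedence: negation before mixed-modal, flags zeroed", {
  r <- classify_ftr_type("It is definitely not possible it rains tomorrow")
  expect_equal(r$excluded, 1L)
  expect_equal(r$exclusion_reason, "negation")
  expect_true(all(r[1, ftrclassify:::.type_flags] == 0))
})

test_that("every non-excluded sentence gets at least one flag; present tense is the residual", {
  corp <- generate_labeled_sentences(8, seed = 21)
  ftr <- corp[corp$time_ref == "FTR", ]
  got <- classify_ftr_type(ftr$text)
  flags <- as.matrix(got[, ftrclassify:::.type_flags])
  nonexcl <- got$excluded == 0
  expect_true(all(rowSums(flags[nonexcl, , drop = FALSE]) >= 1))
  expect_true(all(flags[got$excluded == 1, ] == 0))
  # present_tense fires exactly when nothing else does
  pt <- flags[, "present_tense"] == 1
  expect_true(all(rowSums(flags[pt, , drop = FALSE]) == 1))
})

test_that("classifier closure: planted template flags are reproduced exactly", {
  corp <- generate_labeled_sentences(10, seed = 7)
  ftr <- corp[corp$time_ref == "FTR", ]
  got <- classify_ftr_type(ftr$text)
  for (fl in ftrclassify:::.type_flags) {
    expect_equal(got[[fl]], ftr[[fl]], info = fl)
  }
  expect_equal(got$excluded, ftr$excluded)
  expect_equal(got$exclusion_reason, ftr$exclusion_reason)
})

test_that("concord is the only multi-flag combination across the low-certainty split", {
  corp <- generate_labeled_sentences(10, seed = 13)
  ftr <- corp[corp$time_ref == "FTR", ]
  got <- classify_ftr_type(ftr$text)
  keep <- got$excluded == 0
  flags <- as.matrix(got[keep, ftrclassify:::.type_flags])
  multi <- rowSums(flags) > 1
  if (any(multi)) {
    combos <- unique(apply(flags[multi, , drop = FALSE], 1, function(x)
      paste(names(x)[x == 1], collapse = "+")))
    expect_setequal(combos, "verbal_low_certainty+other_low_certainty")
  }
  # determinism / idempotence
  expect_identical(got, classify_ftr_type(ftr$text))
})

test_that("periphrastic future and semi-modal inflections are matched", {
  r <- classify_ftr_type(c("The band is going to play tomorrow",
                           "She has to leave tomorrow",
                           "He needs to finish it tomorrow"))
  expect_equal(r$future_tense[1], 1L)
  expect_equal(r$deontic[2], 1L)
  expect_equal(r$deontic[3], 1L)
})

test_that("verbal_high_certainty never fires by default but can be configured", {
  r <- classify_ftr_type("It will definitely rain tomorrow")
  expect_equal(r$verbal_high_certainty, 0L)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(verbal_high_certainty = list("darn", "tootin")),
                       f)
  lex <- read_lexicon(f)
  r2 <- classify_ftr_type("It darn will rain tomorrow", lex)
  expect_equal(r2$verbal_high_certainty, 1L)
  expect_equal(r2$future_tense, 0L)  # dominance still applies

  # a keyword in two categories is rejected
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(verbal_high_certainty = list("will")), f2)
  expect_error(read_lexicon(f2), "more than one category")
})

test_that("proportions normalise to one and match hand arithmetic", {
  all_future <- data.frame(matrix(0L, 4, length(ftrclassify:::.type_flags),
                                  dimnames = list(NULL, ftrclassify:::.type_flags)))
  all_future$future_tense <- 1L
  p <- proportions_by_type(all_future)
  expect_equal(unname(p["future_tense"]), 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # two types with equal raw means -> 0.5 each
  sym <- all_future
  sym$future_tense <- c(1L, 1L, 0L, 0L)
  sym$bouletic <- c(0L, 0L, 1L, 1L)
  p2 <- proportions_by_type(sym)
  expect_equal(unname(p2[c("future_tense", "bouletic")]), c(0.5, 0.5))

  # mixed set against a direct arithmetic oracle
  set.seed(8)
  mix <- as.data.frame(matrix(rbinom(9 * 40, 1, 0.3), nrow = 40,
                              dimnames = list(NULL, ftrclassify:::.type_flags)))
  p3 <- proportions_by_type(mix)
  oracle <- colMeans(mix) / sum(colMeans(mix))
  expect_equal(p3, oracle)
  expect_equal(sum(p3), 1, tolerance = 1e-12)

  expect_error(proportions_by_type(mix[0, ]), "empty")
})
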