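anchor_june10 <- as.Date("2020-06-10")

test_that("keyword deictics resolve relative to the anchor", {
  e <- extract_temporal_expressions("I leave tomorrow", anchor_june10)
  expect_equal(e$resolved, as.Date("2020-06-11"))
  e2 <- extract_temporal_expressions("today is the day", anchor_june10)
  expect_equal(e2$resolved, anchor_june10)
  e3 <- extract_temporal_expressions("it rained yesterday", anchor_june10)
  expect_equal(e3$resolved, as.Date("2020-06-09"))
})

test_that("absolute dates resolve regardless of anchor", {
  for (a in list(anchor_june10, as.Date("1999-01-01"))) {
    e <- extract_temporal_expressions("It was November 7, 2012 then", a)
    expect_equal(e$resolved, as.Date("2012-11-07"))
  }
  e <- extract_temporal_expressions("due 10-06-2020 sharp", anchor_june10)
  expect_equal(e$resolved, as.Date("2020-06-10"))  # day-first default
  e2 <- extract_temporal_expressions("due 10-06-2020 sharp", anchor_june10,
                                     dayfirst = FALSE)
  expect_equal(e2$resolved, as.Date("2020-10-06"))
})

test_that("offset words, weekdays and unit shifts resolve deterministically", {
  e <- extract_temporal_expressions("in three weeks we go", anchor_june10)
  expect_equal(e$resolved, anchor_june10 + 21)
  e2 <- extract_temporal_expressions("we met 2 days ago", anchor_june10)
  expect_equal(e2$resolved, anchor_june10 - 2)
  # 2020-06-10 is a Wednesday
  e3 <- extract_temporal_expressions("see you this Friday", anchor_june10)
  expect_equal(e3$resolved, as.Date("2020-06-12"))
  e4 <- extract_temporal_expressions("we met last Friday", anchor_june10)
  expect_equal(e4$resolved, as.Date("2020-06-05"))
  e5 <- extract_temporal_expressions("maybe next year", anchor_june10)
  expect_equal(e5$resolved, as.Date("2021-06-10"))
  # determinism across calls
  expect_identical(e3, extract_temporal_expressions("see you this Friday",
                                                    anchor_june10))
})

test_that("expression spans are unique and an anchor is mandatory", {
  e <- extract_temporal_expressions("tomorrow at 3pm, then in 2 days",
                                    anchor_june10)
  expect_equal(nrow(e), 2)
  expect_false(any(duplicated(e[, c("start", "end")])))
  expect_equal(e$kind[1], "combined")
  expect_error(extract_temporal_expressions("tomorrow", NULL), "anchor")
})

test_that("H(s) is the mean day delta with the documented sign convention", {
  mk <- function(dates) data.frame(surface = "x", start = 1, end = 1,
                                   kind = "relative", resolved = dates,
                                   sub_day = FALSE)
  r1 <- sentence_horizon(mk(anchor_june10 + 1), anchor_june10)
  expect_equal(r1$H_days, 1)
  expect_equal(r1$t_ref, 0L)
  r2 <- sentence_horizon(mk(anchor_june10 + c(2, 4)), anchor_june10)
  expect_equal(r2$H_days, 3)
  r3 <- sentence_horizon(mk(anchor_june10 - 10), anchor_june10)
  expect_equal(r3$H_days, -10)
  expect_equal(r3$t_ref, 1L)
  # empty expression set -> no_expression record
  r4 <- sentence_horizon(NULL, anchor_june10)
  expect_equal(r4$retained, 0L)
  expect_equal(r4$drop_reason, "no_expression")
})

test_that("horizon antisymmetry and the mean-aggregation oracle hold", {
  set.seed(31)
  for (trial in 1:50) {
    k <- sample(1:400, 1)
    fwd <- sentence_horizon(
      extract_temporal_expressions(sprintf("in %d days", k), anchor_june10),
      anchor_june10)
    bwd <- sentence_horizon(
      extract_temporal_expressions(sprintf("%d days ago", k), anchor_june10),
      anchor_june10)
    expect_equal(fwd$H_days, -bwd$H_days)
    expect_equal(fwd$abs_H, bwd$abs_H)
  }
  for (trial in 1:25) {
    offs <- sample(-50:50, sample(1:5, 1), replace = TRUE)
    dates <- anchor_june10 + offs
    rec <- sentence_horizon(
      data.frame(surface = "x", start = seq_along(offs), end = seq_along(offs),
                 kind = "relative", resolved = dates, sub_day = FALSE),
      anchor_june10)
    expect_equal(rec$H_days, sum(offs) / length(offs))  # brute-force mean
  }
})

test_that("planted offsets are recovered exactly through the full pipeline", {
  for (offs in list(1L, c(2L, 4L), -30L, c(-3L, 7L, 14L))) {
    posts <- generate_timed_posts(5, offs, seed = 17)
    sents <- segment_corpus(posts)
    recs <- compute_horizons(sents)
    expect_equal(recs$H_days, rep(mean(offs), nrow(recs)))
    expect_equal(recs$n_refs, rep(length(offs), nrow(recs)))
  }
})

test_that("same-day past false positives are dropped, real references kept", {
  posted <- as.POSIXct("2020-08-03 16:00:00", tz = "UTC")
  e <- extract_temporal_expressions("I'm seeing her tonight", posted)
  rec <- sentence_horizon(e, posted, "s1")
  expect_equal(rec$H_days, 0)
  expect_lt(rec$raw_delta_days, 0)  # the -16 h construction
  kept <- suppressMessages(filter_horizons(rec))
  expect_equal(nrow(kept), 0)
  flagged <- suppressMessages(filter_horizons(rec, keep_all = TRUE))
  expect_equal(flagged$drop_reason, "same_day_past")

  ok <- sentence_horizon(
    extract_temporal_expressions("see you tomorrow", posted), posted, "s2")
  expect_equal(suppressMessages(filter_horizons(ok))$retained, 1L)
  noexpr <- sentence_horizon(
    extract_temporal_expressions("nothing temporal here", posted), posted)
  expect_equal(nrow(suppressMessages(filter_horizons(noexpr))), 0)
})

test_that("log transform of |H| matches closed forms and guards zero", {
  mk <- function(H) data.frame(sentence_ref = "s", n_refs = 1L, H_days = H,
                               abs_H = abs(H), log_abs_H = NA_real_,
                               t_ref = 0L, raw_delta_days = H, retained = 1L,
                               drop_reason = "none")
  expect_equal(log_abs_horizon(mk(1))$log_abs_H, 0)
  expect_equal(log_abs_horizon(mk(exp(1)))$log_abs_H, 1)
  expect_equal(log_abs_horizon(mk(30))$log_abs_H, 3.401197, tolerance = 1e-6)
  expect_equal(log_abs_horizon(mk(-30))$log_abs_H, log(30))
  expect_error(log_abs_horizon(mk(0)), "abs_H = 0")
  expect_message(z <- log_abs_horizon(mk(0), on_zero = "drop"), "dropped")
  expect_equal(nrow(z), 0)
})

test_that("missing timestamps are an explicit error at horizon time", {
  posts <- generate_timed_posts(2, 1L, seed = 1)
  sents <- segment_corpus(posts)
  sents$posted_at[1] <- NA
  expect_error(compute_horizons(sents), "posted_at")
})
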