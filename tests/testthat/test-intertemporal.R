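test_that("the battery fully crosses 10 amounts with 11 delays", {
  bat <- generate_battery()
  expect_equal(nrow(bat), 110)
  expect_equal(sort(unique(bat$ssr)), seq(50, 95, by = 5))
  expect_equal(length(unique(bat$delay_label)), 11)
  expect_true(all(bat$llr == 100))
  expect_true(all(bat$ssr < bat$llr))
  # presentation order is a separate seeded permutation of the same items
  shuf <- generate_battery(shuffle_seed = 4)
  expect_setequal(shuf$item_id, bat$item_id)
  expect_false(identical(shuf$item_id, bat$item_id))
})

test_that("hyperbolic value matches closed forms and monotonicity", {
  expect_equal(hyperbolic_value(100, 0.07, 0), 100)
  expect_equal(hyperbolic_value(100, 1 / 30, 30), 50)
  expect_equal(hyperbolic_value(100, 0.01, 365), 100 / 4.65)
  expect_equal(hyperbolic_value(100, 0.01, 365), 21.505376, tolerance = 1e-6)
  ks <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(hyperbolic_value(100, ks, 30)) < 0))
  Ds <- 0:100
  expect_true(all(diff(hyperbolic_value(100, 0.02, Ds)) < 0))
  expect_error(hyperbolic_value(100, -0.1, 3), "non-negative")
})

test_that("the candidate grid holds all indifference points, zero-delay excluded", {
  bat <- generate_battery()
  grid <- candidate_k_grid(bat)
  expect_true((1 / 30) %in% grid)                     # SSR 50, D 30
  expect_equal(min(grid), (100 / 95 - 1) / 3650)       # ~1.442e-5
  expect_equal((100 / 95 - 1) / 3650, 1.441961e-5, tolerance = 1e-6)
  expect_lte(length(grid), 100)                        # 10 x 10 minus collisions
  expect_true(all(diff(grid) > 0))
  # enumeration oracle
  oracle <- sort(unique(as.vector(outer(100 / seq(50, 95, 5) - 1,
                                        c(1, 7, 30, 61, 91, 182, 365, 730,
                                          1825, 3650), "/"))))
  expect_equal(grid, oracle)
})

test_that("noiseless grid choosers are recovered with full match", {
  bat <- generate_battery()
  grid <- candidate_k_grid(bat)
  set.seed(5)
  for (k_true in sample(grid, 12)) {
    ch <- simulate_choices(k_true, epsilon = 0, seed = 1)
    est <- estimate_k(ch, grid)
    expect_equal(est$match_prop, 1)
    expect_equal(est$stochasticity, 0)
  }
})

test_that("ties resolve to the geometric mean of the full tied set", {
  # one positive-delay item both candidates predict identically -> tie
  resp <- data.frame(ssr = 50, llr = 100, delay_days = 10, choice = 1)
  est <- estimate_k(resp, grid = c(0.01, 0.04))
  expect_equal(est$k, sqrt(0.01 * 0.04))
  expect_equal(est$k, 0.02)
  expect_equal(est$n_tied, 2)
  expect_equal(est$log_k, log(0.02))
})

test_that("an always-later chooser lands on the grid minimum via brute force", {
  bat <- generate_battery()
  grid <- candidate_k_grid(bat)
  resp <- bat
  resp$choice <- 1L
  est <- estimate_k(resp, grid)
  # brute-force oracle over the grid
  matches <- sapply(grid, function(k)
    sum((bat$llr / (1 + k * bat$delay_days) > bat$ssr) == (resp$choice == 1)))
  tied <- grid[matches == max(matches)]
  expect_equal(est$k, exp(mean(log(tied))))
  expect_equal(est$match_prop, max(matches) / 110)
})

test_that("choice structure is monotone in delay under any fixed k", {
  bat <- generate_battery()
  set.seed(6)
  for (k in exp(runif(10, log(1e-4), log(0.3)))) {
    ch <- simulate_choices(k, epsilon = 0, seed = 1)
    for (ssr in unique(ch$ssr)) {
      sub <- ch[ch$ssr == ssr, ]
      sub <- sub[order(sub$delay_days), ]
      expect_true(all(diff(sub$choice) <= 0))  # once SSR wins, it keeps winning
    }
  }
})

test_that("off-grid rates are recovered within the local grid spacing", {
  bat <- generate_battery()
  grid <- candidate_k_grid(bat)
  set.seed(7)
  errs <- numeric(200)
  spac <- numeric(200)
  lg <- log(grid)
  for (i in 1:200) {
    k_true <- exp(runif(1, log(1e-4), log(0.25)))
    ch <- simulate_choices(k_true, epsilon = 0, seed = i)
    est <- estimate_k(ch, grid)
    errs[i] <- abs(est$log_k - log(k_true))
    lo <- max(c(lg[lg <= log(k_true)], min(lg)))
    hi <- min(c(lg[lg >= log(k_true)], max(lg)))
    spac[i] <- max(hi - lo, max(diff(lg)) / 2)
  }
  expect_lte(median(errs - spac), 0)
  expect_lte(median(errs), median(spac) + 1e-9)
})

test_that("flip noise appears as stochasticity of about the flip rate", {
  grid <- candidate_k_grid(generate_battery())
  set.seed(8)
  st <- vapply(1:100, function(i) {
    k_true <- exp(runif(1, log(1e-4), log(0.25)))
    ch <- simulate_choices(k_true, epsilon = 0.1, seed = 1000 + i)
    est <- estimate_k(ch, grid)
    expect_equal(est$stochasticity, 1 - est$match_prop)
    est$stochasticity
  }, numeric(1))
  expect_gt(mean(st), 0.07)
  expect_lt(mean(st), 0.13)
})

test_that("multi-participant fits keep ids and accept delay labels", {
  ch1 <- simulate_choices(0.01, seed = 1, participant_id = "alice")
  ch2 <- simulate_choices(0.1, seed = 2, participant_id = "bob")
  resp <- rbind(ch1, ch2)[, c("participant_id", "ssr", "delay_label", "choice")]
  fit <- fit_discount(resp)
  expect_s3_class(fit, "discount_fit")
  expect_setequal(fit$participant_id, c("alice", "bob"))
  expect_gt(fit$k[fit$participant_id == "bob"],
            fit$k[fit$participant_id == "alice"])
  expect_equal(unname(coef(fit)), fit$log_k)
  expect_error(fit_discount(resp[0, ]))
})

test_that("attention checks fail on any smaller-reward choice", {
  checks <- data.frame(is_check = c(TRUE, TRUE), choice = c(1, 0))
  expect_equal(attention_check(checks), "fail")
  expect_equal(attention_check(data.frame(is_check = c(TRUE, TRUE),
                                          choice = c(1, 1))), "pass")
  expect_warning(res <- attention_check(data.frame(is_check = TRUE,
                                                   choice = 1)), "1 attention")
  expect_equal(res, "pass")
  expect_warning(res2 <- attention_check(data.frame(is_check = logical(0),
                                                    choice = numeric(0))),
                 "no attention")
  expect_equal(res2, "pass")
})
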