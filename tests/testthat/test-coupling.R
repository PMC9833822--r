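test_that("windowed lag-1 autocorrelation matches direct Pearson on lag pairs", {
  expect_equal(lag1_autocorr(1:10), 1)
  expect_equal(lag1_autocorr(rep(c(1, 2), 5)), -1)  # 9 alternating pairs
  # too few valid pairs -> undefined, not zero and not an error
  x <- rnorm(10); m <- rep(FALSE, 10); m[c(1, 2, 5, 6)] <- TRUE
  expect_true(is.na(lag1_autocorr(x, m, min_valid = 5)))
  # oracle: direct Pearson over the lag pairs
  withr::with_seed(31, {
    for (rep in 1:50) {
      v <- rnorm(sample(8:30, 1))
      expect_equal(lag1_autocorr(v, min_valid = 2),
                   cor(v[-length(v)], v[-1]), tolerance = 1e-12)
    }
  })
})

test_that("zero-lag coupling detrends each side then rank-correlates", {
  w <- c(0, 1, 0, 2, 0, 3, 0, 4, 0, 5)
  expect_equal(zero_lag_coupling(w, w), 1)
  # a negated residual pattern gives -1 (detrend removes only the line)
  x <- seq(0, 9) + c(0.5, -0.5, 0.4, -0.4, 0.3, -0.3, 0.2, -0.2, 0.1, -0.1)
  resid <- x - fitted(lm(x ~ seq_along(x)))
  y <- fitted(lm(x ~ seq_along(x))) - resid
  expect_equal(zero_lag_coupling(x, y), -1)
  # both sides exactly linear: residuals vanish -> undefined
  expect_true(is.na(zero_lag_coupling(1:10, seq(2, 20, by = 2))))
  # mask shorter than min_valid -> undefined
  m <- c(rep(TRUE, 4), rep(FALSE, 6))
  expect_true(is.na(zero_lag_coupling(w, w, m, m, min_valid = 5)))
  # agrees with the direct recipe on noisy windows
  withr::with_seed(77, {
    for (rep in 1:20) {
      a <- rnorm(10); b <- rnorm(10)
      ra <- residuals(lm(a ~ seq_along(a)))
      rb <- residuals(lm(b ~ seq_along(b)))
      expect_equal(zero_lag_coupling(a, b),
                   cor(ra, rb, method = "spearman"), tolerance = 1e-12)
    }
  })
})

test_that("windowed series places windows every S epochs with floor centers", {
  d <- toy_dyad(rnorm(20), rnorm(20))
  ws <- windowed_series(d, "stability", W = 10, S = 5)
  expect_equal(ws$start, c(0, 5, 10))
  expect_equal(ws$center, c(5, 10, 15))
  expect_warning(ws9 <- windowed_series(toy_dyad(rnorm(9), rnorm(9)), "stability"),
                 "shorter")
  expect_equal(nrow(ws9), 0L)
  # a window with 7 of 10 epochs invalid is undefined at min_valid = 5
  valid <- rep(TRUE, 20); valid[11:17] <- FALSE
  dm <- toy_dyad(rnorm(20), rnorm(20), valid = valid)
  wm <- windowed_series(dm, "stability", W = 10, S = 5)
  expect_true(is.na(wm$value[wm$start == 10]))
  # all values in [-1, 1] where defined
  expect_true(all(abs(wm$value) <= 1, na.rm = TRUE))
})

test_that("event-locked windowed statistics average nearest-center windows", {
  d <- toy_dyad(rnorm(40), rnorm(40), inf_events = 20)
  ws <- windowed_series(d, "stability")
  ws$value[] <- 0.3
  tr <- event_locked_stat(ws, d$events, lags = -3:3)
  expect_true(all(tr$mean_stat == 0.3))

  # spike at the window whose center is nearest the event epoch
  ws2 <- windowed_series(d, "stability")
  ws2$value[] <- 0
  nearest <- which.min(abs(ws2$center - 20))
  ws2$value[nearest] <- 0.9
  tr2 <- event_locked_stat(ws2, d$events, lags = 0)
  expect_equal(tr2$mean_stat, 0.9)

  # two events mapping to stats 0.2 and 0.4 average to 0.3
  d2 <- toy_dyad(rnorm(40), rnorm(40), inf_events = c(5, 25))
  ws3 <- windowed_series(d2, "stability")
  ws3$value[] <- NA_real_
  ws3$value[which.min(abs(ws3$center - 5))] <- 0.2
  ws3$value[which.min(abs(ws3$center - 25))] <- 0.4
  tr3 <- event_locked_stat(ws3, d2$events, lags = 0)
  expect_equal(tr3$mean_stat, 0.3)
  # undefined values propagate as missing, not zero
  tr4 <- event_locked_stat(ws3, d2$events, lags = 10)
  expect_true(is.na(tr4$mean_stat) || tr4$n_events < 2)
})

test_that("windowed stability increases with the AR coefficient", {
  mean_stab <- function(phi, seed0) {
    mean(vapply(1:40, function(i) {
      p <- scenario_params("null", seed = seed0 + i,
                           phi_infant = phi, phi_caregiver = phi)
      mean(windowed_series(simulate_dyad(p), "stability")$value, na.rm = TRUE)
    }, 0))
  }
  s2 <- mean_stab(0.2, 400); s5 <- mean_stab(0.5, 500); s8 <- mean_stab(0.8, 600)
  expect_lt(s2, s5)
  expect_lt(s5, s8)
})

test_that("cross-coupled dyads show elevated windowed coupling", {
  mean_coup <- function(kappa, seed0, n = 25) {
    vapply(1:n, function(i) {
      p <- scenario_params("null", seed = seed0 + i,
                           phi_infant = 0.4, phi_caregiver = 0.4,
                           kappa_i2c = kappa, kappa_c2i = kappa)
      mean(windowed_series(simulate_dyad(p), "coupling")$value, na.rm = TRUE)
    }, 0)
  }
  c5 <- mean_coup(0.5, 700); c0 <- mean_coup(0, 800)
  expect_gt(mean(c5), mean(c0))
  expect_lt(mw_hl(c5, c0)$p, 0.01)
})
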