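test_that("bin grid is symmetric with a 1-3 min bin and covers the span", {
  b <- bin_grid()
  expect_true(any(b$lo == 1 & b$hi == 3))
  expect_true(any(b$lo == -1 & b$hi == 1))
  expect_equal(b$lo, -rev(b$hi))        # symmetric about 0
  expect_true(all(b$hi[-nrow(b)] == b$lo[-1]))   # contiguous
  expect_lte(min(b$lo), -20); expect_gte(max(b$hi), 20)
})

test_that("likelihood profile scores per-event window indicators", {
  g <- epoch_grid(60)
  b <- bin_grid(span = 4)
  prof <- function(ref, target) {
    likelihood_profile(
      event_series(ref, rep("infant", length(ref)), "cry", g),
      event_series(target, rep("infant", length(target)), "cry", g), b)
  }
  p1 <- prof(10, 12)
  expect_equal(p1$likelihood[p1$lo == 1], 1)     # epoch 12 in [11, 13)
  p2 <- prof(10, 14)
  expect_equal(p2$likelihood[p2$lo == 1], 0)
  p3 <- prof(c(10, 20), c(11, 23))
  expect_equal(p3$likelihood[p3$lo == 1], 0.5)   # indicators (1, 0)
  expect_error(prof(integer(), 5), "empty reference")
})

test_that("likelihood profile excludes unobservable windows", {
  g <- epoch_grid(30)
  ref <- event_series(1, "infant", "cry", g)      # epoch 1: [-5,-3) fully off-grid
  target <- event_series(25, "infant", "cry", g)
  b <- bin_grid(span = 4)
  p <- likelihood_profile(ref, target, b)
  expect_true(is.na(p$likelihood[p$lo == -5]))
  expect_equal(p$n_events[p$lo == -5], 0L)
  # an invalid mask over a whole window does the same
  mask <- rep(TRUE, 30); mask[12:16] <- FALSE
  ref2 <- event_series(12, "infant", "cry", g)
  p2 <- likelihood_profile(ref2, target, b, mask = mask)
  expect_true(is.na(p2$likelihood[p2$lo == 1]))   # epochs 13-14 masked out
})

test_that("event-locked arousal averages series values at each lag", {
  d <- toy_dyad(rep(0, 60), inf_events = 30)
  tr0 <- event_locked_arousal(
    arousal_series(rep(0, 60), rescale = FALSE, role = "infant"),
    d$events, lags = -3:3)
  expect_true(all(tr0$mean_arousal == 0))

  g <- epoch_grid(60)
  spike <- arousal_series(c(rep(0, 30), 1, rep(0, 29)), rescale = FALSE)
  ev <- event_series(30, "infant", "cry", g)
  tr <- event_locked_arousal(spike, ev, lags = -2:2)
  expect_equal(tr$mean_arousal, c(0, 0, 1, 0, 0))

  vals <- rep(0, 60); vals[11] <- 0.2; vals[41] <- 0.6
  two <- event_locked_arousal(arousal_series(vals, rescale = FALSE),
                              event_series(c(10, 40), rep("infant", 2), "cry", g),
                              lags = 0)
  expect_equal(two$mean_arousal, 0.4)
  expect_equal(two$n_events, 2L)
  expect_error(event_locked_arousal(spike, event_series(grid = g), lags = 0),
               "no events")
})

test_that("lags outside the session are undefined, not zero", {
  g <- epoch_grid(30)
  s <- arousal_series(rnorm(30))
  ev <- event_series(1, "infant", "cry", g)
  tr <- event_locked_arousal(s, ev, lags = -5:0)
  expect_true(all(is.na(tr$mean_arousal[tr$lag < -1])))
  expect_equal(tr$n_events[tr$lag == -5], 0L)
})

test_that("peak detection uses a strict percentile threshold", {
  s <- arousal_series(1:100, rescale = FALSE, valid = rep(TRUE, 100))
  pk <- detect_peaks(s, pct = 10)
  expect_equal(pk$events$epoch, 90:99)           # values 91..100
  # ties exactly at the threshold are excluded by strictness
  v <- c(1:90, rep(90.1, 10))
  st <- arousal_series(v, rescale = FALSE)
  thr <- quantile(v, 0.9, names = FALSE)
  pk2 <- detect_peaks(st, pct = 10)
  expect_true(all(v[pk2$events$epoch + 1] > thr))
  # constant series: nothing strictly exceeds the threshold
  cst <- arousal_series(rep(2, 50), rescale = FALSE)
  expect_equal(nrow(detect_peaks(cst, 10)$events), 0L)
  expect_error(detect_peaks(s, pct = 0), "pct")
  expect_error(detect_peaks(s, pct = 60), "pct")
})

test_that("peak count respects the percentile convention for distinct values", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      n <- sample(25:200, 1)
      pct <- sample(c(5, 10, 20), 1)
      s <- arousal_series(sample(seq_len(10 * n), n))  # all distinct
      k <- nrow(detect_peaks(s, pct)$events)
      expect_true(k %in% c(floor(n * pct / 100), ceiling(n * pct / 100)),
                  label = sprintf("n=%d pct=%d k=%d", n, pct, k))
    }
  })
})

test_that("quartile split orders events into four equal groups", {
  s <- arousal_series(c(1:8, rep(0, 32)), rescale = FALSE)
  ev <- event_series(0:7, rep("infant", 8), "speech_like", epoch_grid(40))
  q <- quartile_split_events(s, ev)
  expect_equal(q$quartile, rep(1:4, each = 2))
  expect_error(quartile_split_events(s, filter_events(ev, "caregiver")),
               "need >= 8")
})

test_that("partner quartile profiles produce per-bin F tests on participant means", {
  withr::with_seed(55, {
    dyads <- lapply(1:10, function(i) {
      toy_dyad(rnorm(200), rnorm(200), inf_events = sort(sample(0:199, 20)),
               id = sprintf("d%02d", i))
    })
    qp <- partner_quartile_profiles(dyads, "infant", "all", bins = bin_grid(span = 6))
    expect_equal(qp$n_dyads, 10L)
    expect_true(all(is.na(qp$tests$F) | qp$tests$F >= 0))
    expect_equal(sort(unique(qp$traj$quartile)), 1:4)
  })
})
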