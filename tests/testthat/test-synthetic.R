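test_that("parameter validation enforces stationarity and bounds", {
  expect_error(sim_params(phi_infant = 1), "AR coefficients")
  expect_error(sim_params(phi_infant = 0.7, phi_caregiver = 0.7,
                          kappa_i2c = 0.5, kappa_c2i = 0.5), "non-stationary")
  expect_error(sim_params(n_epochs = 39), "n_epochs")
  expect_error(sim_params(noise_sd = 0), "noise_sd")
  expect_error(sim_params(snapshot_s = 61), "snapshot_s")
  expect_error(sim_params(mask_valid_frac = 0), "mask_valid_frac")
  expect_s3_class(sim_params(), "sim_params")
})

test_that("a fixed seed reproduces the dyad bit-for-bit", {
  p <- scenario_params("paper_like", seed = 99)
  a <- simulate_dyad(p, "x")
  b <- simulate_dyad(p, "x")
  expect_identical(a, b)
  # and different seeds differ
  p2 <- scenario_params("paper_like", seed = 100)
  expect_false(identical(simulate_dyad(p2, "x"), a))
})

test_that("simulated dyads satisfy the structural invariants", {
  p <- scenario_params("paper_like", seed = 5)
  d <- simulate_dyad(p)
  for (s in list(d$infant, d$caregiver)) {
    expect_equal(mean(s$values[s$valid]), 0, tolerance = 1e-9)
    expect_equal(sd(s$values[s$valid]), 1, tolerance = 1e-9)
    expect_true(all(is.na(s$values[!s$valid])))
  }
  # events only on valid epochs
  expect_true(all(d$infant$valid[d$events$events$epoch + 1]))
  # at most one event per (epoch, speaker)
  key <- paste(d$events$events$epoch, d$events$events$speaker)
  expect_false(anyDuplicated(key) > 0)
  # mask fraction near the requested value, in contiguous blocks
  expect_equal(mean(d$infant$valid), p$mask_valid_frac, tolerance = 0.02)
  runs <- rle(d$infant$valid)
  expect_lt(sum(!runs$values), 6)       # few invalid blocks, not scattered epochs
})

test_that("under the independence null arousal does not predict events", {
  # per-dyad AUC has no information; a modest batch keeps this fast, the
  # full 200-dyad calibration lives in the acceptance suite
  aucs <- vapply(1:60, function(i) {
    p <- scenario_params("null", seed = 3000 + i, mask_valid_frac = 1)
    d <- simulate_dyad(p)
    roc_auc(d$infant, filter_events(d$events, "infant", "all"))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("own-arousal dependence produces elevated event-locked arousal at lag 0", {
  bs <- matrix(0, 2, 3, dimnames = list(c("infant", "caregiver"),
                                        c("cry", "speech_like", "other")))
  bs["infant", "speech_like"] <- 1.5
  at0 <- at20 <- numeric(100)
  for (i in 1:100) {
    p <- scenario_params("null", seed = 4000 + i, beta_self = bs)
    d <- simulate_dyad(p)
    ev <- filter_events(d$events, "infant", "speech_like")
    if (nrow(ev$events) == 0) next
    tr <- event_locked_arousal(d$infant, ev, lags = c(-20, 0, 20))
    at0[i] <- tr$mean_arousal[2]
    at20[i] <- mean(tr$mean_arousal[c(1, 3)], na.rm = TRUE)
  }
  expect_gt(mean(at0), 0)
  expect_lt(mw_hl(at0, at20)$p, 0.01)
  expect_gt(median(at0 - at20), 0)
})

test_that("self-excitation induces temporal clustering of events", {
  rate_gap1 <- function(gamma, seed) {
    p <- scenario_params("null", seed = seed, gamma_cluster = gamma)
    d <- simulate_dyad(p)
    ep <- filter_events(d$events, "infant", "all")$events$epoch
    if (length(ep) < 5) return(NA_real_)
    mean(diff(ep) <= 3)
  }
  g0 <- mean(vapply(1:30, function(i) rate_gap1(0, 5000 + i), 0), na.rm = TRUE)
  g1 <- mean(vapply(1:30, function(i) rate_gap1(1.5, 6000 + i), 0), na.rm = TRUE)
  expect_gt(g1, g0)
})

test_that("post-event impulses shape infant arousal after cries vs speech", {
  p <- scenario_params("cry_vs_speech", seed = 17)
  post_minus_pre <- function(category) {
    diffs <- c()
    for (i in 1:60) {
      pp <- p; pp$seed <- 7000 + i
      d <- simulate_dyad(pp)
      ev <- filter_events(d$events, "infant", category)
      if (nrow(ev$events) < 3) next
      tr <- event_locked_arousal(d$infant, ev, lags = -8:8)
      diffs <- c(diffs, mean(tr$mean_arousal[tr$lag > 0], na.rm = TRUE) -
                        mean(tr$mean_arousal[tr$lag < 0], na.rm = TRUE))
    }
    diffs
  }
  dc <- post_minus_pre("cry")
  ds <- post_minus_pre("speech_like")
  expect_lt(mean(dc), mean(ds))         # cries drop, speech sustains
  expect_lt(mean(dc), 0)
})

test_that("duty-cycled sampling detects intervals overlapping the snapshot", {
  # a full-minute vocalisation is always caught
  iv <- data.frame(onset = 120, offset = 180, speaker = "infant", category = "cry")
  es <- sparse_sample_events(iv, 5, 60, n_epochs = 5)
  expect_equal(es$events$epoch, 2L)
  # an interval missing the 5-s snapshot is not
  iv2 <- data.frame(onset = 10, offset = 20, speaker = "infant", category = "cry")
  expect_equal(nrow(sparse_sample_events(iv2, 5, 60, n_epochs = 1)$events), 0L)
  # label comes from the earliest-starting overlapping interval
  iv3 <- data.frame(onset = c(2, 1), offset = c(4, 3), speaker = "infant",
                    category = c("cry", "speech_like"))
  expect_equal(sparse_sample_events(iv3, 5, 60, n_epochs = 1)$events$category,
               "speech_like")
  expect_error(sparse_sample_events(iv, 61, 60), "snapshot_s")
  expect_error(sparse_sample_events(data.frame(onset = -1, offset = 3,
                                               speaker = "infant", category = "cry"),
                                    5, 60), "non-negative")
})

test_that("Poisson vocalising is detected at the closed-form rate", {
  lambda <- 0.05; snap <- 5
  n_ep <- 10000
  withr::with_seed(123, {
    gaps <- rexp(2 * lambda * n_ep * 60, lambda)
    times <- cumsum(gaps)
    times <- times[times < n_ep * 60]
  })
  iv <- data.frame(onset = times, offset = times + 0.001,
                   speaker = "infant", category = "cry")
  es <- sparse_sample_events(iv, snap, 60, n_epochs = n_ep)
  frac <- nrow(es$events) / n_ep
  expect_equal(frac, 1 - exp(-lambda * snap), tolerance = 0.03)
})

test_that("the audio duty cycle covers 8 percent of each minute", {
  p <- sim_params()
  expect_equal(round(100 * p$snapshot_s / p$period_s), 8)
})

test_that("sparse detection preserves the shape of likelihood profiles", {
  # group profiles of all vocalisations about themselves, duty-cycled vs
  # fully observed; the acceptance suite runs the full 50-dyad version
  bins <- bin_grid()
  pl <- scenario_params("paper_like", seed = 3)
  hs <- hf <- ns <- nf <- matrix(0, 25, nrow(bins))
  for (i in 1:25) {
    pp <- pl; pp$seed <- dyadarousal:::derive_seed(3, 200 + i)
    d <- simulate_dyad(pp)
    iv <- events_to_intervals(d$events, seed = pp$seed)
    full <- sparse_sample_events(iv, 60, 60, n_epochs = d$grid$n_epochs)
    sparse <- sparse_sample_events(iv, 5, 60, n_epochs = d$grid$n_epochs)
    if (nrow(sparse$events) < 2) next
    ls <- likelihood_profile(sparse, sparse, bins)
    lf <- likelihood_profile(full, full, bins)
    hs[i, ] <- ifelse(is.na(ls$likelihood), 0, ls$likelihood * ls$n_events)
    ns[i, ] <- ls$n_events
    hf[i, ] <- ifelse(is.na(lf$likelihood), 0, lf$likelihood * lf$n_events)
    nf[i, ] <- lf$n_events
  }
  rho <- cor(colSums(hs) / colSums(ns), colSums(hf) / colSums(nf),
             method = "spearman")
  expect_gt(rho, 0.7)
})
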