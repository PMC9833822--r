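#' Simulation parameters for a synthetic dyad
#'
#' Defines the forward model used to generate dyads with the statistical
#' structure the analyses assume: a bivariate AR(1) latent arousal process
#' with cross-coupling, a per-epoch logistic link from (z-scaled) arousal to
#' vocal-event probability with additive self-excitation (temporal
#' clustering), fixed-length additive arousal impulses after infant events
#' (cries pull infant arousal down, speech-like vocalisations sustain it),
#' a contiguous-block validity mask emulating nap/outdoor exclusions, and
#' 5-s-per-60-s duty-cycled audio sampling.
#'
#' `beta0`, `beta_self` and `beta_partner` are speaker-by-category matrices
#' (rows `infant`, `caregiver`; columns `cry`, `speech_like`, `other`);
#' scalars are recycled. Arousal enters the logistic link standardised to
#' unit stationary variance, so the slopes are per z-unit of arousal.
#'
#' @param n_epochs number of 60-s epochs (>= 40; default 240, ~4 h awake at
#'   home).
#' @param phi_infant,phi_caregiver AR(1) coefficients in `[0, 1)`.
#' @param kappa_i2c,kappa_c2i cross-coupling: weight of the partner's arousal
#'   in one's own update (infant-to-caregiver and vice versa). Coupling acts
#'   within the epoch (bidirectional mixing), emulating co-regulation faster
#'   than the 60-s sampling; it induces lagged cross-influence and positive
#'   zero-lag synchrony.
#' @param noise_sd innovation SD of the latent process.
#' @param beta0 baseline log-odds of an event per epoch.
#' @param beta_self,beta_partner slopes of own / partner z-scaled arousal on
#'   event log-odds.
#' @param gamma_cluster increment to log-odds when the same speaker produced
#'   any event in the previous `k_excite` epochs.
#' @param k_excite self-excitation memory in epochs.
#' @param post_cry_drop,post_speech_sustain additive impulse to the infant
#'   latent arousal input for `post_len_cry` / `post_len_speech` epochs after
#'   an infant cry / speech-like vocalisation.
#' @param post_len_cry,post_len_speech impulse lengths in epochs.
#' @param mask_valid_frac fraction of epochs marked valid (home + awake).
#' @param snapshot_s,period_s audio duty cycle: snapshot length and period in
#'   seconds (defaults 5 and 60).
#' @param seed master RNG seed; all sub-streams derive from it.
#' @return validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_epochs = 240L,
                       phi_infant = 0.7, phi_caregiver = 0.7,
                       kappa_i2c = 0, kappa_c2i = 0,
                       noise_sd = 1,
                       beta0 = -Inf, beta_self = 0, beta_partner = 0,
                       gamma_cluster = 0, k_excite = 3L,
                       post_cry_drop = 0, post_speech_sustain = 0,
                       post_len_cry = 5L, post_len_speech = 10L,
                       mask_valid_frac = 1,
                       snapshot_s = 5, period_s = 60,
                       seed = 1L) {
  as_sc_mat <- function(x) {
    if (is.matrix(x)) {
      m <- x[SPEAKERS, CATEGORIES, drop = FALSE]
    } else {
      m <- matrix(x, 2, 3, dimnames = list(SPEAKERS, CATEGORIES))
    }
    storage.mode(m) <- "double"
    m
  }
  p <- structure(list(
    n_epochs = as.integer(n_epochs),
    phi_infant = phi_infant, phi_caregiver = phi_caregiver,
    kappa_i2c = kappa_i2c, kappa_c2i = kappa_c2i,
    noise_sd = noise_sd,
    beta0 = as_sc_mat(beta0), beta_self = as_sc_mat(beta_self),
    beta_partner = as_sc_mat(beta_partner),
    gamma_cluster = gamma_cluster, k_excite = as.integer(k_excite),
    post_cry_drop = post_cry_drop, post_speech_sustain = post_speech_sustain,
    post_len_cry = as.integer(post_len_cry),
    post_len_speech = as.integer(post_len_speech),
    mask_valid_frac = mask_valid_frac,
    snapshot_s = snapshot_s, period_s = period_s,
    seed = as.integer(seed)), class = "sim_params")
  validate_sim_params(p)
  p
}

# within-epoch bidirectional mixing: each partner's arousal receives
# kappa times the other's arousal of the same epoch (coupling faster than
# the 60-s sampling), which induces both lagged cross-influence and
# correlated innovations
mix_matrix <- function(p) {
  K <- matrix(c(0, p$kappa_c2i, p$kappa_i2c, 0), 2, 2, byrow = TRUE)
  if (abs(p$kappa_i2c * p$kappa_c2i) >= 1) {
    stop("parameter-validation error: |kappa_i2c * kappa_c2i| must be < 1")
  }
  solve(diag(2) - K)
}

# effective 2x2 lag matrix; its spectral radius must stay below 1
lag_matrix <- function(p) {
  mix_matrix(p) %*% diag(c(p$phi_infant, p$phi_caregiver))
}

validate_sim_params <- function(p) {
  if (p$n_epochs < 40L) stop("parameter-validation error: n_epochs must be >= 40")
  if (p$phi_infant < 0 || p$phi_infant >= 1 ||
      p$phi_caregiver < 0 || p$phi_caregiver >= 1) {
    stop("parameter-validation error: AR coefficients must lie in [0, 1)")
  }
  rho <- max(Mod(eigen(lag_matrix(p), only.values = TRUE)$values))
  if (rho >= 1) {
    stop(sprintf("parameter-validation error: non-stationary system (spectral radius %.3f >= 1)", rho))
  }
  if (p$noise_sd <= 0) stop("parameter-validation error: noise_sd must be > 0")
  if (p$mask_valid_frac <= 0 || p$mask_valid_frac > 1) {
    stop("parameter-validation error: mask_valid_frac must be in (0, 1]")
  }
  if (p$snapshot_s > p$period_s) stop("parameter-validation error: snapshot_s > period_s")
  if (p$k_excite < 0L) stop("parameter-validation error: k_excite must be >= 0")
  invisible(p)
}

# stationary covariance of the bivariate VAR(1): solves S = A S A' + Q
stationary_cov <- function(A, Q) {
  v <- solve(diag(4) - kronecker(A, A), as.vector(Q))
  matrix(v, 2, 2)
}

# deterministic sub-seed derivation from the master seed (kept < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647) * 31 + 7 * k) %% 2147483629L + 1L
}

# contiguous-block validity mask: invalid time is split into a few blocks
# inserted at random positions among the valid epochs (nap/outdoor pattern)
simulate_mask <- function(n, valid_frac) {
  n_invalid <- round(n * (1 - valid_frac))
  if (n_invalid == 0) return(rep(TRUE, n))
  n_blocks <- max(1L, round(n_invalid / 20))
  cuts <- sort(sample.int(n_invalid - 1L, min(n_blocks - 1L, n_invalid - 1L)))
  sizes <- diff(c(0L, cuts, n_invalid))
  n_valid <- n - n_invalid
  at <- sort(sample.int(n_valid + 1L, length(sizes)) - 1L)  # gap index 0..n_valid
  mask <- rep(TRUE, n_valid)
  out <- logical(0)
  prev <- 0L
  for (b in seq_along(sizes)) {
    out <- c(out, mask[seq_len(at[b] - prev) + prev], rep(FALSE, sizes[b]))
    prev <- at[b]
  }
  c(out, mask[seq_len(n_valid - prev) + prev])
}

#' Simulate one caregiver-infant dyad
#'
#' Runs the forward model of [sim_params()]: latent arousal evolves as a
#' bivariate AR(1); each epoch, each speaker may emit at most one vocal event
#' whose log-odds depend on own and partner z-scaled arousal and on recent
#' own events; infant cries / speech-like events feed impulses back into the
#' infant arousal input. Events are only emitted on valid epochs, and both
#' arousal series are z-scored over valid epochs on output. The same
#' parameters and seed reproduce the dyad bit-for-bit.
#'
#' @param params a [sim_params()].
#' @param id dyad identifier.
#' @return a [dyad()].
#' @export
simulate_dyad <- function(params, id = "sim") {
  validate_sim_params(params)
  n <- params$n_epochs
  M <- mix_matrix(params)
  A <- lag_matrix(params)
  Q <- M %*% (diag(2) * params$noise_sd^2) %*% t(M)
  zsd <- sqrt(diag(stationary_cov(A, Q)))
  grid <- epoch_grid(n, params$period_s)

  mask <- withr::with_seed(derive_seed(params$seed, 1L),
                           simulate_mask(n, params$mask_valid_frac))

  withr::with_seed(derive_seed(params$seed, 2L), {
    eps <- matrix(stats::rnorm(2L * n, 0, params$noise_sd), nrow = 2L)
    u <- array(stats::runif(2L * 3L * n), dim = c(2L, 3L, n))
    a <- matrix(0, 2L, n)                       # rows: infant, caregiver
    imp <- numeric(n + max(params$post_len_cry, params$post_len_speech, 1L))
    last_event <- c(-Inf, -Inf)                 # most recent event epoch per speaker
    ev_epoch <- integer(0); ev_speaker <- character(0); ev_cat <- character(0)
    state <- c(0, 0)
    for (t in seq_len(n)) {
      state <- as.numeric(M %*% (c(params$phi_infant, params$phi_caregiver) * state +
                                   c(imp[t], 0) + eps[, t]))
      a[, t] <- state
      z <- state / zsd
      if (mask[t]) {
        for (s in 1:2) {
          excited <- (t - 1L - last_event[s]) <= params$k_excite &&
                     (t - 1L - last_event[s]) >= 1L
          lo <- params$beta0[s, ] + params$beta_self[s, ] * z[s] +
                params$beta_partner[s, ] * z[3L - s] +
                if (excited) params$gamma_cluster else 0
          hit <- which(u[s, , t] < stats::plogis(lo))
          if (length(hit)) {
            cat <- CATEGORIES[min(hit)]         # cry > speech_like > other
            ev_epoch <- c(ev_epoch, t - 1L)
            ev_speaker <- c(ev_speaker, SPEAKERS[s])
            ev_cat <- c(ev_cat, cat)
            last_event[s] <- t - 1L
            if (s == 1L) {
              if (cat == "cry" && params$post_len_cry > 0L) {
                idx <- t + seq_len(params$post_len_cry)
                imp[idx] <- imp[idx] + params$post_cry_drop
              } else if (cat == "speech_like" && params$post_len_speech > 0L) {
                idx <- t + seq_len(params$post_len_speech)
                imp[idx] <- imp[idx] + params$post_speech_sustain
              }
            }
          }
        }
      }
    }
    inf <- arousal_series(ifelse(mask, a[1, ], NA_real_), valid = mask,
                          grid = grid, role = "infant", dyad_id = id)
    care <- arousal_series(ifelse(mask, a[2, ], NA_real_), valid = mask,
                           grid = grid, role = "caregiver", dyad_id = id)
    ev <- event_series(epoch = ev_epoch, speaker = ev_speaker,
                       category = ev_cat, grid = grid)
    dyad(infant = inf, caregiver = care, events = ev, id = id)
  })
}

#' Simulate a cohort of dyads
#'
#' @param params a [sim_params()]; each dyad gets a sub-seed derived from
#'   `params$seed` and its index.
#' @param n_dyads number of dyads.
#' @return list of [dyad()] objects named `dyad01`, `dyad02`, ...
#' @export
simulate_cohort <- function(params, n_dyads) {
  lapply(stats::setNames(seq_len(n_dyads),
                         sprintf("dyad%02d", seq_len(n_dyads))),
         function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, 100L + i)
    simulate_dyad(p, id = sprintf("dyad%02d", i))
  })
}

#' Duty-cycled detection of vocal intervals
#'
#' Emulates a duty-cycled wearable microphone that records a `snapshot_s`-second
#' audio snapshot at the start of every `period_s`-second epoch (5 s per
#' 60 s, i.e. 8% of each minute). An event is emitted for epoch `e` iff a
#' true vocal interval overlaps the snapshot window
#' `[e * period_s, e * period_s + snapshot_s)`; when several intervals
#' overlap one snapshot, the earliest-starting interval provides the label.
#' Setting `snapshot_s = period_s` gives fully observed (continuous)
#' detection.
#'
#' @param intervals data.frame with columns `onset`, `offset` (seconds,
#'   `onset < offset`, non-negative), `speaker`, `category`.
#' @param snapshot_s,period_s duty cycle (snapshot must not exceed period).
#' @param n_epochs session length in epochs; defaults to covering the last
#'   interval.
#' @return an [event_series()].
#' @export
sparse_sample_events <- function(intervals, snapshot_s = 5, period_s = 60,
                                 n_epochs = NULL) {
  if (snapshot_s > period_s) stop("snapshot_s must be <= period_s")
  if (snapshot_s <= 0 || period_s <= 0) stop("snapshot_s and period_s must be > 0")
  if (nrow(intervals) && any(intervals$onset < 0 | intervals$offset <= intervals$onset)) {
    stop("intervals must be non-negative with onset < offset")
  }
  if (is.null(n_epochs)) {
    n_epochs <- max(1, ceiling(max(c(intervals$offset, period_s)) / period_s))
  }
  grid <- epoch_grid(n_epochs, period_s)
  if (nrow(intervals) && any(intervals$offset > n_epochs * period_s)) {
    stop("interval extends past the session")
  }
  hits <- list()
  if (nrow(intervals)) {
    o <- order(intervals$onset)
    intervals <- intervals[o, , drop = FALSE]
    for (e in seq_len(n_epochs) - 1L) {
      w0 <- e * period_s
      w1 <- w0 + snapshot_s
      ov <- which(intervals$onset < w1 & intervals$offset > w0)
      if (length(ov)) {
        for (sp in unique(intervals$speaker[ov])) {
          first <- ov[intervals$speaker[ov] == sp][1L]   # earliest-starting
          hits[[length(hits) + 1L]] <- data.frame(
            epoch = e, speaker = sp,
            category = intervals$category[first],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  h <- if (length(hits)) do.call(rbind, hits) else
    data.frame(epoch = integer(), speaker = character(), category = character())
  event_series(epoch = h$epoch, speaker = h$speaker, category = h$category,
               grid = grid)
}

#' Expand epoch-level vocal events to continuous-time intervals
#'
#' Gives each vocal epoch a true underlying interval: an onset uniform
#' within its minute and a category-specific duration (cry bouts run tens of
#' seconds; protophones are short utterances). Used to examine what the
#' duty-cycled microphone would and would not have detected.
#'
#' @param events an [event_series()] whose epochs mark true "vocal minutes".
#' @param dur_range named list of duration ranges in seconds per category.
#' @param seed RNG seed.
#' @param period_s epoch duration in seconds.
#' @return data.frame with `onset`, `offset`, `speaker`, `category`.
#' @export
events_to_intervals <- function(events,
                                dur_range = list(cry = c(5, 30),
                                                 speech_like = c(1, 5),
                                                 other = c(1, 8)),
                                seed = 1L, period_s = 60) {
  ev <- events$events
  withr::with_seed(as.integer(seed), {
    dur <- vapply(ev$category, function(cat) {
      r <- dur_range[[cat]]
      stats::runif(1, r[1], r[2])
    }, 0, USE.NAMES = FALSE)
    onset <- ev$epoch * period_s + stats::runif(nrow(ev), 0, period_s)
    offset <- pmin(onset + dur, events$grid$n_epochs * period_s)
    data.frame(onset = onset, offset = offset,
               speaker = ev$speaker, category = ev$category,
               stringsAsFactors = FALSE)
  })
}

#' Named parameter scenarios
#'
#' Three presets exercised throughout the analyses:
#' \describe{
#'   \item{null}{events occur at realistic base rates but independently of
#'     arousal and of each other; no cross-coupling. Every detector should
#'     reject at its nominal rate here.}
#'   \item{paper_like}{autocorrelated coupled arousal, arousal-contingent
#'     vocalising (stronger in the infant than the caregiver, whose events
#'     track the infant's arousal instead), temporal clustering, and
#'     category-specific after-effects. Baseline rates are calibrated to the
#'     typical infant category proportions (roughly 3 cries to 6-7
#'     speech-like to a handful of rare others), not to absolute rates,
#'     which day-long recordings of this kind do not pin down.}
#'   \item{cry_vs_speech}{as `paper_like` with the post-event contrast
#'     emphasised: cries pull infant arousal down afterwards, speech-like
#'     vocalisations sustain it.}
#' }
#'
#' @param scenario one of `"null"`, `"paper_like"`, `"cry_vs_speech"`.
#' @param seed master seed.
#' @param ... overrides passed to [sim_params()].
#' @return a [sim_params()].
#' @export
scenario_params <- function(scenario = c("null", "paper_like", "cry_vs_speech"),
                            seed = 1L, ...) {
  scenario <- match.arg(scenario)
  b0 <- matrix(c(stats::qlogis(0.011), stats::qlogis(0.075), stats::qlogis(0.005),
                 -Inf, -Inf, stats::qlogis(0.10)),
               2, 3, byrow = TRUE, dimnames = list(SPEAKERS, CATEGORIES))
  base <- switch(scenario,
    null = list(phi_infant = 0.7, phi_caregiver = 0.7,
                kappa_i2c = 0, kappa_c2i = 0,
                beta0 = b0, beta_self = 0, beta_partner = 0,
                gamma_cluster = 0, mask_valid_frac = 0.92),
    paper_like = ,
    cry_vs_speech = {
      bs <- matrix(0, 2, 3, dimnames = list(SPEAKERS, CATEGORIES))
      bs["infant", "cry"] <- 1.2
      bs["infant", "speech_like"] <- 0.8
      bp <- matrix(0, 2, 3, dimnames = list(SPEAKERS, CATEGORIES))
      bp["caregiver", "other"] <- 0.6
      drop <- if (scenario == "cry_vs_speech") -0.8 else -0.5
      sustain <- if (scenario == "cry_vs_speech") 0.4 else 0.3
      list(phi_infant = 0.75, phi_caregiver = 0.75,
           kappa_i2c = 0.08, kappa_c2i = 0.08,
           beta0 = b0, beta_self = bs, beta_partner = bp,
           gamma_cluster = 0.8, k_excite = 3L,
           post_cry_drop = drop, post_speech_sustain = sustain,
           mask_valid_frac = 0.92)
    })
  do.call(sim_params, utils::modifyList(c(base, seed = as.integer(seed)),
                                        list(...)))
}
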