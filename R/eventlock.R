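#' Likelihood profile of target events around reference events
#'
#' For each reference event at epoch `t` and each relative-time bin
#' `[a, b)` minutes, scores an indicator that at least one target event lies
#' in epochs `[t + a, t + b)`, and averages the indicators over reference
#' events: the participant's likelihood of a target vocalisation in that
#' window. A bin contributes for a given event only if at least one of its
#' epochs is observable (inside the session and, when a mask is supplied,
#' valid); otherwise the event is excluded from that bin's average.
#'
#' @param ref an [event_series()] of reference events (errors if empty).
#' @param target an [event_series()] of target events.
#' @param bins a [bin_grid()] (minutes; epochs are minutes on the default
#'   grid).
#' @param mask optional logical validity vector over epochs.
#' @return data.frame: `lo`, `hi`, `likelihood`, `n_events` per bin.
#' @export
likelihood_profile <- function(ref, target, bins = bin_grid(), mask = NULL) {
  t_ref <- ref$events$epoch
  if (length(t_ref) == 0L) stop("empty reference series")
  n <- ref$grid$n_epochs
  if (is.null(mask)) mask <- rep(TRUE, n)
  hit <- rep(FALSE, n)
  hit[target$events$epoch + 1L] <- TRUE
  out <- bins
  out$likelihood <- NA_real_
  out$n_events <- 0L
  for (b in seq_len(nrow(bins))) {
    # epoch offsets covered by [lo, hi) minutes; epoch == minute index here
    offs <- seq.int(ceiling(bins$lo[b]), ceiling(bins$hi[b]) - 1L)
    ind <- vapply(t_ref, function(t) {
      ep <- t + offs
      ep <- ep[ep >= 0L & ep < n]
      ep <- ep[mask[ep + 1L]]
      if (length(ep) == 0L) return(NA)            # bin unobservable for this event
      any(hit[ep + 1L])
    }, NA)
    use <- !is.na(ind)
    out$n_events[b] <- sum(use)
    if (any(use)) out$likelihood[b] <- mean(ind[use])
  }
  out
}

#' Event-locked arousal trajectory
#'
#' Mean arousal at each relative lag (default -20 to +20 min in 1-min steps)
#' over a participant's events: for lag `l`, the mean of the series value at
#' epoch `t + l` over events `t` where that epoch is valid. Lags with no
#' contributing observation are `NA`, never 0. Because the series is z-scored
#' within person, the chance level of the trajectory is 0 (that participant's
#' average arousal over the analysed day).
#'
#' @param series an [arousal_series()].
#' @param events an [event_series()] on the same grid (errors if empty).
#' @param lags integer vector of relative lags in epochs.
#' @return data.frame: `lag`, `mean_arousal`, `n_events`.
#' @export
event_locked_arousal <- function(series, events, lags = -20:20) {
  if (!same_grid(series$grid, events$grid)) stop("series and events on different grids")
  t_ev <- events$events$epoch
  if (length(t_ev) == 0L) stop("no events to lock to")
  n <- series$grid$n_epochs
  vals <- series$values
  out <- data.frame(lag = lags, mean_arousal = NA_real_, n_events = 0L)
  for (i in seq_along(lags)) {
    ep <- t_ev + lags[i]
    ok <- ep >= 0L & ep < n
    v <- vals[ep[ok] + 1L]
    v <- v[!is.na(v)]
    out$n_events[i] <- length(v)
    if (length(v)) out$mean_arousal[i] <- mean(v)
  }
  out
}

#' Detect arousal peaks
#'
#' Flags the valid epochs whose arousal strictly exceeds the participant's
#' `100 - pct` percentile that day (linear-interpolation percentile; strict
#' exceedance, so with the default `pct = 10` an epoch is a peak when it
#' exceeds the top-10% threshold). The usual threshold levels
#' are 10% (main) and 5% / 20% (robustness checks).
#'
#' @param series an [arousal_series()] with >= 20 valid epochs.
#' @param pct percentile band in `(0, 50]`.
#' @return an [event_series()] of peak epochs (speaker = series role,
#'   category `other`).
#' @export
detect_peaks <- function(series, pct = 10) {
  if (pct <= 0 || pct > 50) stop("pct must lie in (0, 50]")
  v <- series$values[series$valid]
  if (length(v) < 20L) stop("need >= 20 valid epochs for peak detection")
  thr <- stats::quantile(v, 1 - pct / 100, names = FALSE)  # type 7: linear interpolation
  ep <- which(series$valid & !is.na(series$values) & series$values > thr) - 1L
  event_series(epoch = ep, speaker = rep(series$role, length(ep)),
               category = rep("other", length(ep)), grid = series$grid)
}

#' Quartile split of events by the vocaliser's arousal
#'
#' Assigns each event to an arousal quartile by the vocaliser-side arousal
#' at the event epoch, quartiles taken over that participant's own events.
#' Ties are broken by rank with stable ordering on epoch index, so group
#' sizes are as equal as `n` allows (e.g. 8 events of increasing arousal
#' give groups \{1,2\}, \{3,4\}, \{5,6\}, \{7,8\}).
#'
#' @param own_series the vocaliser's [arousal_series()].
#' @param events the vocaliser's [event_series()].
#' @param min_events minimum usable events (default 8); fewer is an error so
#'   callers can exclude the participant with a warning.
#' @return data.frame: `epoch`, `arousal`, `quartile` (1 = lowest) for events
#'   with defined arousal at lag 0.
#' @export
quartile_split_events <- function(own_series, events, min_events = 8L) {
  ep <- events$events$epoch
  ar <- own_series$values[ep + 1L]
  keep <- !is.na(ar)
  ep <- ep[keep]; ar <- ar[keep]
  if (length(ep) < min_events) {
    stop(sprintf("only %d events with defined arousal (need >= %d)", length(ep), min_events))
  }
  o <- order(ar, ep)                      # stable: ties resolved by epoch
  rk <- integer(length(ar)); rk[o] <- seq_along(ar)
  q <- ceiling(4 * rk / length(rk))
  data.frame(epoch = ep, arousal = ar, quartile = q)
}

#' Partner arousal around events, split by vocaliser arousal quartile
#'
#' For each participant, subdivides the vocaliser's events into quartiles of
#' the vocaliser's arousal at the event epoch and computes the partner's
#' event-locked arousal trajectory per quartile, averaged within relative
#' time bins. Across participants, each bin is then tested with a one-way
#' ANOVA on the participant-level quartile means (cluster correction over
#' bins is applied downstream with [permutation_cluster()]'s machinery or
#' reported per bin).
#'
#' @param dyads list of [dyad()] objects.
#' @param vocaliser role whose events and arousal define the quartiles.
#' @param category event category (`"all"` for every category).
#' @param bins a [bin_grid()].
#' @param min_events per-participant minimum (participants below it are
#'   dropped with a warning).
#' @return list: `traj` (data.frame dyad x quartile x bin mean partner
#'   arousal), `tests` (per-bin `F` and `p` from [oneway_f()]), `n_dyads`.
#' @export
partner_quartile_profiles <- function(dyads, vocaliser = "infant",
                                      category = "all", bins = bin_grid(),
                                      min_events = 8L) {
  partner <- setdiff(SPEAKERS, vocaliser)
  rows <- list()
  for (d in dyads) {
    own <- d[[vocaliser]]; ps <- d[[partner]]
    if (is.null(own) || is.null(ps)) next
    ev <- filter_events(d$events, vocaliser, category)
    qs <- tryCatch(quartile_split_events(own, ev, min_events),
                   error = function(e) {
                     warning("dyad ", d$id, " excluded: ", conditionMessage(e))
                     NULL
                   })
    if (is.null(qs)) next
    for (q in 1:4) {
      eq <- event_series(epoch = qs$epoch[qs$quartile == q],
                         speaker = rep(vocaliser, sum(qs$quartile == q)),
                         category = "other", grid = d$grid)
      if (nrow(eq$events) == 0L) next
      tr <- event_locked_arousal(ps, eq, lags = seq(floor(min(bins$lo)), ceiling(max(bins$hi))))
      bm <- bin_means(tr, bins)
      rows[[length(rows) + 1L]] <- data.frame(dyad = d$id, quartile = q,
                                              bin = seq_len(nrow(bins)),
                                              lo = bins$lo, hi = bins$hi,
                                              mean_arousal = bm)
    }
  }
  traj <- do.call(rbind, rows)
  if (is.null(traj)) stop("no usable participants for the quartile analysis")
  tests <- data.frame(bin = seq_len(nrow(bins)), lo = bins$lo, hi = bins$hi,
                      F = NA_real_, p = NA_real_)
  for (b in seq_len(nrow(bins))) {
    sub <- traj[traj$bin == b & !is.na(traj$mean_arousal), ]
    groups <- split(sub$mean_arousal, sub$quartile)
    groups <- groups[vapply(groups, length, 1L) >= 2L]
    if (length(groups) >= 2L) {
      ft <- oneway_f(groups)
      tests$F[b] <- ft$F
      tests$p[b] <- ft$p
    }
  }
  list(traj = traj, tests = tests, n_dyads = length(unique(traj$dyad)))
}

# average a lag-resolved trajectory within relative-time bins
bin_means <- function(traj, bins) {
  vapply(seq_len(nrow(bins)), function(b) {
    sel <- traj$lag >= bins$lo[b] & traj$lag < bins$hi[b] & !is.na(traj$mean_arousal)
    if (!any(sel)) return(NA_real_)
    mean(traj$mean_arousal[sel])
  }, 0)
}
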