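#' Lag-1 autocorrelation within a window (arousal stability)
#'
#' Pearson correlation between `x[t]` and `x[t+1]` over pairs of consecutive
#' valid epochs in the window. Higher values mean smoother, more persistent
#' arousal. Returns `NA` (not an error, and never 0) when fewer than
#' `min_valid` pairs are available or a side of the pairing is constant.
#'
#' @param x numeric window values.
#' @param mask logical validity per value (default: non-missing).
#' @param min_valid minimum number of valid consecutive pairs (default 5).
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
lag1_autocorr <- function(x, mask = NULL, min_valid = 5L) {
  if (is.null(mask)) mask <- !is.na(x)
  n <- length(x)
  if (n < 2L) return(NA_real_)
  pair <- which(mask[-n] & mask[-1])
  if (length(pair) < min_valid) return(NA_real_)
  x0 <- x[pair]; x1 <- x[pair + 1L]
  if (stats::sd(x0) == 0 || stats::sd(x1) == 0) return(NA_real_)
  stats::cor(x0, x1)
}

#' Zero-lag rank cross-correlation within a window (arousal coupling)
#'
#' Each partner's window is independently detrended by an ordinary
#' least-squares line fitted over its own valid epochs; the Spearman
#' correlation (average ranks for ties) of the residuals is then taken over
#' jointly valid epochs. Returns `NA` when fewer than `min_valid` jointly
#' valid epochs remain or either residual is constant.
#'
#' @param x,y infant and caregiver window values.
#' @param mask_x,mask_y validity per value (default: non-missing).
#' @param min_valid minimum jointly valid epochs (default 5).
#' @return Spearman rho in `[-1, 1]`, or `NA`.
#' @export
zero_lag_coupling <- function(x, y, mask_x = NULL, mask_y = NULL, min_valid = 5L) {
  if (is.null(mask_x)) mask_x <- !is.na(x)
  if (is.null(mask_y)) mask_y <- !is.na(y)
  if (length(x) != length(y)) stop("windows must be the same length")
  detrend <- function(v, m) {
    idx <- which(m)
    if (length(idx) < 2L) return(rep(NA_real_, length(v)))
    fit <- stats::lm.fit(cbind(1, idx), v[idx])
    r <- rep(NA_real_, length(v))
    r[idx] <- fit$residuals
    r
  }
  rx <- detrend(x, mask_x)
  ry <- detrend(y, mask_y)
  both <- mask_x & mask_y & !is.na(rx) & !is.na(ry)
  if (sum(both) < min_valid) return(NA_real_)
  # exactly linear windows leave residuals at rounding-error level
  tol <- 1e-10 * max(1, abs(x[mask_x]), abs(y[mask_y]))
  if (stats::sd(rx[both]) <= tol || stats::sd(ry[both]) <= tol) return(NA_real_)
  stats::cor(rx[both], ry[both], method = "spearman")
}

#' Moving-window stability or coupling series
#'
#' Slides a window of `W` epochs in steps of `S` over the dyad's grid
#' (the standard moving-window design: 10-epoch windows shifting by 5)
#' and computes arousal stability ([lag1_autocorr()], per role) or arousal
#' coupling ([zero_lag_coupling()], needs both partners) in each window.
#' Window `[i, i + W)` is assigned the centre epoch `i + floor(W / 2)`.
#'
#' @param d a [dyad()].
#' @param stat `"stability"` or `"coupling"`.
#' @param role which partner's stability (ignored for coupling).
#' @param W window size in epochs (default 10).
#' @param S shift between windows in epochs (default 5).
#' @param min_valid per-window validity floor passed to the stat.
#' @return object of class `"windowed_stat"`: data.frame `start`, `center`,
#'   `value`, with attributes `stat`, `W`, `S`; zero rows (with a warning)
#'   when the grid is shorter than `W`.
#' @export
windowed_series <- function(d, stat = c("stability", "coupling"),
                            role = "infant", W = 10L, S = 5L, min_valid = 5L) {
  stat <- match.arg(stat)
  n <- d$grid$n_epochs
  starts <- if (n < W) {
    warning("grid shorter than window: empty windowed series")
    integer(0)
  } else seq.int(0L, n - W, by = S)
  vals <- vapply(starts, function(i) {
    idx <- i + seq_len(W)
    if (stat == "stability") {
      s <- dyad_series(d, role)
      lag1_autocorr(s$values[idx], s$valid[idx], min_valid)
    } else {
      inf <- dyad_series(d, "infant"); care <- dyad_series(d, "caregiver")
      zero_lag_coupling(inf$values[idx], care$values[idx],
                        inf$valid[idx], care$valid[idx], min_valid)
    }
  }, 0)
  out <- data.frame(start = starts, center = starts + W %/% 2L, value = vals)
  structure(out, stat = stat, W = W, S = S, class = c("windowed_stat", "data.frame"))
}

#' Excerpt a windowed statistic around events
#'
#' For each event and relative lag, takes the value of the window whose
#' centre is nearest the lagged epoch (ties go to the earlier window) and
#' averages over events per lag. Undefined window values propagate as
#' missing rather than zero; a lag with no defined value is `NA`.
#'
#' @param windowed a [windowed_series()] result.
#' @param events an [event_series()] (errors if empty).
#' @param lags relative lags in epochs.
#' @return data.frame: `lag`, `mean_stat`, `n_events`.
#' @export
event_locked_stat <- function(windowed, events, lags = -20:20) {
  if (nrow(windowed) == 0L) stop("empty windowed series")
  t_ev <- events$events$epoch
  if (length(t_ev) == 0L) stop("no events to lock to")
  centers <- windowed$center
  # nearest centre via midpoint boundaries; a lagged epoch exactly between
  # two centres goes to the earlier window (left-open intervals)
  mids <- (centers[-length(centers)] + centers[-1]) / 2
  out <- data.frame(lag = lags, mean_stat = NA_real_, n_events = 0L)
  for (i in seq_along(lags)) {
    idx <- findInterval(t_ev + lags[i], mids, left.open = TRUE) + 1L
    v <- windowed$value[idx]
    v <- v[!is.na(v)]
    out$n_events[i] <- length(v)
    if (length(v)) out$mean_stat[i] <- mean(v)
  }
  out
}
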