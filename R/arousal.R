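#' Per-participant arousal series
#'
#' A z-scored composite arousal value per 60-s epoch with a validity mask.
#' Values are `NA` exactly where the mask is `FALSE`; over valid epochs the
#' series has mean 0 and sample SD 1 immediately after z-scoring.
#'
#' @param values numeric vector, one value per epoch (`NA` allowed).
#' @param valid logical mask, same length; defaults to `!is.na(values)`.
#' @param grid an [epoch_grid()]; defaults to one epoch per value.
#' @param role `"infant"` or `"caregiver"`.
#' @param dyad_id identifier carried through outputs.
#' @param rescale z-score over valid epochs on construction (default TRUE).
#' @return object of class `"arousal_series"`.
#' @export
arousal_series <- function(values, valid = NULL, grid = NULL,
                           role = c("infant", "caregiver"),
                           dyad_id = "dyad", rescale = TRUE) {
  role <- match.arg(role)
  values <- as.numeric(values)
  if (is.null(valid)) valid <- !is.na(values)
  valid <- as.logical(valid) & !is.na(values)
  if (length(valid) != length(values)) stop("valid mask length mismatch")
  if (is.null(grid)) grid <- epoch_grid(length(values))
  if (grid$n_epochs != length(values)) stop("values do not match grid length")
  values[!valid] <- NA_real_
  x <- structure(list(values = values, valid = valid, grid = grid,
                      role = role, dyad_id = dyad_id),
                 class = "arousal_series")
  if (rescale) x <- zscore_series(x) else x
}

#' @export
print.arousal_series <- function(x, ...) {
  cat(sprintf("<arousal_series> %s/%s: %d epochs, %d valid\n",
              x$dyad_id, x$role, x$grid$n_epochs, sum(x$valid)))
  invisible(x)
}

# z-score over valid epochs (sample SD); errors on degenerate input
zscore_series <- function(series) {
  v <- series$values[series$valid]
  if (length(v) == 0L) stop("empty-data error: no valid epochs to z-score")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("zero-variance error: arousal series is constant over valid epochs")
  series$values <- (series$values - mean(v)) / s
  series
}

#' Build a composite arousal series from raw channels
#'
#' Collapses per-epoch autonomic channels (heart rate, heart-rate variability,
#' movement) into one within-person arousal index: each channel is
#' sign-oriented so that higher always means more aroused, z-scored over its
#' own valid epochs, the oriented z-scores are averaged across the channels
#' available at each epoch, and the average is re-z-scored over valid epochs.
#' An epoch is valid if at least one channel is observed there.
#'
#' Default orientations: heart rate +1 (faster = more aroused), HRV -1
#' (lower variability = more aroused), movement +1.
#'
#' @param channels data.frame or named list of numeric per-epoch channel
#'   vectors (`NA` = missing); all the same length.
#' @param orientation named numeric vector of +1/-1 per channel; channels not
#'   named fall back to the defaults above, then to +1.
#' @param valid optional logical epoch mask applied on top of per-channel
#'   missingness.
#' @param grid,role,dyad_id passed to [arousal_series()].
#' @param min_epochs minimum valid epochs required per channel (default 10).
#' @return an [arousal_series()].
#' @export
composite_arousal <- function(channels, orientation = NULL, valid = NULL,
                              grid = NULL, role = "infant", dyad_id = "dyad",
                              min_epochs = 10L) {
  channels <- as.list(channels)
  if (length(channels) == 0L) stop("at least one channel required")
  n <- unique(vapply(channels, length, 1L))
  if (length(n) != 1L) stop("channels must share the epoch grid")
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n) stop("valid mask length mismatch")
  defaults <- c(heart_rate = 1, hrv = -1, movement = 1)
  zs <- matrix(NA_real_, nrow = n, ncol = length(channels))
  for (j in seq_along(channels)) {
    nm <- names(channels)[j]
    sgn <- if (!is.null(orientation) && !is.null(nm) && nm %in% names(orientation)) {
      orientation[[nm]]
    } else if (!is.null(nm) && nm %in% names(defaults)) defaults[[nm]] else 1
    x <- as.numeric(channels[[j]])
    ok <- valid & !is.na(x)
    if (sum(ok) < min_epochs) {
      stop(sprintf("insufficient valid epochs in channel '%s' (need >= %d)", nm, min_epochs))
    }
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) stop(sprintf("zero-variance error in channel '%s'", nm))
    zs[ok, j] <- sgn * (x[ok] - mean(x[ok])) / s
  }
  comp <- rowMeans(zs, na.rm = TRUE)
  any_obs <- rowSums(!is.na(zs)) > 0L
  comp[!any_obs] <- NA_real_
  arousal_series(comp, valid = any_obs & valid, grid = grid,
                 role = role, dyad_id = dyad_id)
}

#' Remove first-order autocorrelation from an arousal series
#'
#' Fits a single AR(1) regression `x[t] ~ x[t-1]` by ordinary least squares
#' over all pairs of consecutive valid epochs, replaces the series with the
#' regression residuals (defined at epochs whose predecessor is also valid),
#' and re-z-scores over the surviving epochs. Gaps in the validity mask break
#' pair formation; the first epoch of each valid run becomes invalid in the
#' output because it has no predecessor.
#'
#' @param series an [arousal_series()].
#' @param min_pairs minimum number of consecutive valid pairs (default 20).
#' @return an [arousal_series()] of residuals with near-zero lag-1
#'   autocorrelation.
#' @export
remove_autocorrelation <- function(series, min_pairs = 20L) {
  v <- series$valid
  n <- length(v)
  pair <- which(v[-n] & v[-1])      # x[pair] -> x[pair+1]
  if (length(pair) < min_pairs) {
    stop(sprintf("insufficient valid consecutive pairs for AR(1) fit (%d < %d)",
                 length(pair), min_pairs))
  }
  x0 <- series$values[pair]
  x1 <- series$values[pair + 1L]
  fit <- stats::lm.fit(cbind(1, x0), x1)
  res <- rep(NA_real_, n)
  res[pair + 1L] <- fit$residuals
  arousal_series(res, valid = !is.na(res), grid = series$grid,
                 role = series$role, dyad_id = series$dyad_id)
}

#' Restrict an arousal series to a home/awake mask
#'
#' Epochs outside the mask become invalid and the z-scoring baseline is
#' recomputed over the surviving epochs, so "0" afterwards means that
#' participant's average arousal over the analysed (home and awake) part of
#' the day.
#'
#' @param series an [arousal_series()].
#' @param home_awake_mask logical vector on the same grid.
#' @return re-z-scored [arousal_series()].
#' @export
apply_mask <- function(series, home_awake_mask) {
  if (length(home_awake_mask) != series$grid$n_epochs) {
    stop("mask length mismatch: expected ", series$grid$n_epochs,
         " epochs, got ", length(home_awake_mask))
  }
  keep <- series$valid & as.logical(home_awake_mask)
  vals <- series$values
  vals[!keep] <- NA_real_
  arousal_series(vals, valid = keep, grid = series$grid,
                 role = series$role, dyad_id = series$dyad_id)
}
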