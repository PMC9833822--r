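#' Epoch grid
#'
#' The shared time base of a recording day: `n_epochs` contiguous epochs of
#' `epoch_s` seconds, starting `t0` seconds into the session. Epochs are
#' indexed 0-based and treated as half-open intervals
#' `[t0 + e * epoch_s, t0 + (e + 1) * epoch_s)`.
#'
#' @param n_epochs number of epochs (>= 1).
#' @param epoch_s epoch duration in seconds (default 60).
#' @param t0 session start offset in seconds.
#' @return an object of class `"epoch_grid"`.
#' @export
epoch_grid <- function(n_epochs, epoch_s = 60, t0 = 0) {
  n_epochs <- as.integer(n_epochs)
  if (is.na(n_epochs) || n_epochs < 1L) stop("n_epochs must be >= 1")
  if (!is.numeric(epoch_s) || epoch_s <= 0) stop("epoch_s must be > 0")
  structure(list(n_epochs = n_epochs, epoch_s = epoch_s, t0 = t0),
            class = "epoch_grid")
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf("<epoch_grid> %d epochs x %gs (t0 = %gs)\n",
              x$n_epochs, x$epoch_s, x$t0))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n_epochs == b$n_epochs && a$epoch_s == b$epoch_s && a$t0 == b$t0
}

#' Relative-time bin grid
#'
#' Contiguous half-open bins `[lo, hi)` in minutes relative to an event,
#' spanning `-span` to `+span` symmetrically about 0. With the default
#' 2-min width and a 20-min span the bins have edges at odd minutes
#' (..., [-3,-1), [-1,1), [1,3), ...), so that "1-3 min after" is one bin.
#'
#' @param span half-range in minutes (default 20).
#' @param width bin width in minutes (default 2).
#' @return data.frame with columns `lo`, `hi` (minutes), class `"bin_grid"`.
#' @export
bin_grid <- function(span = 20, width = 2) {
  if (span <= 0 || width <= 0) stop("span and width must be > 0")
  # edges symmetric about 0 with the central bin [-width/2, width/2), so the
  # grid contains a "1-3 min after" bin at the default width; the outermost
  # bins are the first to fully cover +/- span
  half <- width / 2
  k <- ceiling((span - half) / width)
  edges <- seq(-(k * width + half), k * width + half, by = width)
  b <- data.frame(lo = edges[-length(edges)], hi = edges[-1])
  class(b) <- c("bin_grid", "data.frame")
  b
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d bins, [%g, %g) min\n", nrow(x), min(x$lo), max(x$hi)))
  invisible(x)
}
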