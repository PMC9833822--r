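#' A caregiver-infant dyad
#'
#' Pairs the two partners' arousal series with the day's vocal events on a
#' shared epoch grid. Either arousal series may be `NULL` (dyads with only
#' one partner's usable autonomic data); paired analyses require both.
#'
#' @param infant,caregiver [arousal_series()] objects or `NULL`.
#' @param events an [event_series()].
#' @param id dyad identifier.
#' @return object of class `"dyad"`.
#' @export
dyad <- function(infant = NULL, caregiver = NULL, events, id = "dyad") {
  if (is.null(infant) && is.null(caregiver)) stop("at least one arousal series required")
  for (s in list(infant, caregiver)) {
    if (!is.null(s) && !same_grid(s$grid, events$grid)) stop("series and events on different grids")
  }
  structure(list(infant = infant, caregiver = caregiver,
                 events = events, id = id,
                 grid = events$grid),
            class = "dyad")
}

#' @export
print.dyad <- function(x, ...) {
  cat(sprintf("<dyad> %s: %d epochs, %d events, partners: %s\n",
              x$id, x$grid$n_epochs, nrow(x$events$events),
              paste(c("infant", "caregiver")[!vapply(list(x$infant, x$caregiver), is.null, TRUE)],
                    collapse = "+")))
  invisible(x)
}

# shared validity: epochs valid for every partner that is present
dyad_valid <- function(d) {
  m <- rep(TRUE, d$grid$n_epochs)
  if (!is.null(d$infant)) m <- m & d$infant$valid
  if (!is.null(d$caregiver)) m <- m & d$caregiver$valid
  m
}

# fetch one partner's series, erroring if absent
dyad_series <- function(d, role = c("infant", "caregiver")) {
  role <- match.arg(role)
  s <- d[[role]]
  if (is.null(s)) stop("dyad ", d$id, " has no ", role, " arousal series")
  s
}
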