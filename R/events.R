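SPEAKERS <- c("infant", "caregiver")
CATEGORIES <- c("cry", "speech_like", "other")

# morphological infant codes collapsed for analysis; laughs/squeals/growls are
# kept as "other" and excluded from the cry/speech-like contrasts
SPEECH_LIKE_CODES <- c("quasi-resonant vowel", "fully-resonant vowel",
                       "marginal syllable", "canonical syllable")
OTHER_CODES <- c("laugh", "squeal", "growl")

#' Collapse raw vocal codes to analysis categories
#'
#' Maps the morphological infant vocalisation codes to the three analysis
#' categories: `cry` stays `cry`; the four protophone codes (quasi-resonant
#' vowel, fully-resonant vowel, marginal syllable, canonical syllable) become
#' `speech_like`; laugh/squeal/growl become `other` (excluded from
#' cry-vs-speech contrasts because of their rarity). Already-collapsed labels
#' pass through unchanged.
#'
#' @param codes character vector of raw or collapsed labels.
#' @return character vector over `cry`, `speech_like`, `other`.
#' @export
collapse_vocal_codes <- function(codes) {
  codes <- tolower(trimws(as.character(codes)))
  out <- ifelse(codes %in% c("cry", CATEGORIES), codes,
         ifelse(codes %in% SPEECH_LIKE_CODES, "speech_like",
         ifelse(codes %in% OTHER_CODES, "other", NA_character_)))
  bad <- unique(codes[is.na(out)])
  if (length(bad)) stop("unknown vocal code(s): ", paste(bad, collapse = ", "))
  out
}

#' Vocal event series
#'
#' Point events on the epoch grid: one row per (epoch, speaker) after
#' collapsing (the 5-s duty-cycled snapshot cannot resolve several
#' vocalisations by the same speaker within one epoch). When duplicates are
#' merged the earliest row wins, with `cry` taking priority over
#' `speech_like` over `other` so cries are never silently discarded.
#'
#' @param epoch integer 0-based epoch indices.
#' @param speaker `"infant"` / `"caregiver"` per event.
#' @param category `cry` / `speech_like` / `other`, or raw morphological codes
#'   (collapsed via [collapse_vocal_codes()]).
#' @param grid an [epoch_grid()].
#' @param affect,intensity optional per-event labels.
#' @return object of class `"event_series"`: a list with `events` (data.frame
#'   sorted by epoch) and `grid`.
#' @export
event_series <- function(epoch = integer(), speaker = character(),
                         category = character(), grid,
                         affect = NULL, intensity = NULL) {
  epoch <- as.integer(epoch)
  n <- length(epoch)
  speaker <- rep_len(as.character(speaker), n)
  category <- if (n == 0L) character() else collapse_vocal_codes(rep_len(category, n))
  if (!all(speaker %in% SPEAKERS)) stop("speaker must be 'infant' or 'caregiver'")
  if (any(epoch < 0L | epoch >= grid$n_epochs)) stop("event epoch outside grid")
  ev <- data.frame(epoch = epoch, speaker = speaker, category = category,
                   affect = rep_len(if (is.null(affect)) NA_character_ else as.character(affect), n),
                   intensity = rep_len(if (is.null(intensity)) NA_character_ else as.character(intensity), n),
                   stringsAsFactors = FALSE)
  # collapse to one event per (epoch, speaker): cry > speech_like > other
  if (nrow(ev)) {
    prio <- match(ev$category, CATEGORIES)
    ev <- ev[order(ev$epoch, ev$speaker, prio), , drop = FALSE]
    ev <- ev[!duplicated(ev[c("epoch", "speaker")]), , drop = FALSE]
    ev <- ev[order(ev$epoch, ev$speaker), , drop = FALSE]
    rownames(ev) <- NULL
  }
  structure(list(events = ev, grid = grid), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  tab <- table(x$events$speaker, x$events$category)
  cat(sprintf("<event_series> %d events on %d epochs\n", nrow(x$events), x$grid$n_epochs))
  if (nrow(x$events)) print(tab)
  invisible(x)
}

#' Filter events by speaker and category
#'
#' @param series an [event_series()].
#' @param speaker `"infant"`, `"caregiver"` or `"all"`.
#' @param category one of `cry`, `speech_like`, `other`, or `"all"` (keeps
#'   every category including `other`).
#' @return an [event_series()] preserving event order.
#' @export
filter_events <- function(series, speaker = "all", category = "all") {
  if (!speaker %in% c(SPEAKERS, "all")) stop("unknown speaker: ", speaker)
  if (!category %in% c(CATEGORIES, "all")) stop("unknown category: ", category)
  ev <- series$events
  if (speaker != "all") ev <- ev[ev$speaker == speaker, , drop = FALSE]
  if (category != "all") ev <- ev[ev$category == category, , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, grid = series$grid), class = "event_series")
}

#' Epochs carrying at least one event
#' @param series an [event_series()].
#' @return sorted integer vector of 0-based epoch indices.
#' @export
event_epochs <- function(series) sort(unique(series$events$epoch))

#' Draw matched control "non-vocalisation" event sets
#'
#' For a set of reference events, draws `n_reps` pseudo-event sets of the
#' same size, uniformly without replacement from the eligible epochs: epochs
#' that are valid for the dyad (home and awake for all present partners) and
#' carry no vocalisation from either partner. Averaging a statistic over the
#' control sets gives its resampling null.
#'
#' @param dyad a [dyad()].
#' @param ref an [event_series()] of reference events whose count each control
#'   set matches (defaults to all of the dyad's vocal events).
#' @param n_reps number of control sets (default 1000).
#' @param seed integer seed; fixed seed gives identical draws.
#' @param exclude_epochs extra epochs to exclude from eligibility (e.g.
#'   arousal-peak epochs when the reference events are peaks).
#' @return list of `n_reps` [event_series()] objects; the pseudo-events are
#'   placeholders (category `other`) carrying only their epochs.
#' @export
sample_control_events <- function(dyad, ref = NULL, n_reps = 1000L, seed = 1L,
                                  exclude_epochs = integer()) {
  if (is.null(ref)) ref <- dyad$events
  n_ev <- nrow(ref$events)
  mask <- dyad_valid(dyad)
  eligible <- setdiff(which(mask) - 1L,
                      c(event_epochs(dyad$events), as.integer(exclude_epochs)))
  if (length(eligible) < n_ev) {
    stop(sprintf("too few eligible non-vocalisation epochs: %d available, %d needed",
                 length(eligible), n_ev))
  }
  if (n_ev == 0L) stop("empty reference series: no events to match")
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_reps), function(i) {
      ep <- sort(eligible[sample.int(length(eligible), n_ev)])
      event_series(epoch = ep,
                   speaker = rep("infant", n_ev),
                   category = rep("other", n_ev),
                   grid = ref$grid)
    })
  })
}
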