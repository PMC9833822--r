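# independent oracles used across the suite

# exact two-sided Mann-Whitney p by full enumeration of all C(m+n, m)
# assignments of the pooled ranks (no ties assumed)
mw_exact_enum <- function(real, control) {
  m <- length(real); n <- length(control)
  r <- rank(c(real, control))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  u_null <- apply(sets, 2, function(idx) sum(seq_len(m + n)[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
}

# rank-sum (probability of correct ordering) AUC with ties counted 0.5
auc_ranksum <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  m <- sum(labels)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * sum(!labels))
}

# minimal hand-built dyad: explicit arousal values and event epochs
toy_dyad <- function(inf_values, care_values = NULL, inf_events = integer(),
                     care_events = integer(), inf_cat = "speech_like",
                     care_cat = "other", valid = NULL, id = "toy") {
  n <- length(inf_values)
  grid <- epoch_grid(n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  inf <- arousal_series(inf_values, valid = valid, grid = grid,
                        role = "infant", dyad_id = id, rescale = FALSE)
  care <- if (is.null(care_values)) NULL else
    arousal_series(care_values, valid = valid, grid = grid,
                   role = "caregiver", dyad_id = id, rescale = FALSE)
  ev <- event_series(
    epoch = c(inf_events, care_events),
    speaker = c(rep("infant", length(inf_events)),
                rep("caregiver", length(care_events))),
    category = c(rep(inf_cat, length(inf_events)),
                 rep(care_cat, length(care_events))),
    grid = grid)
  dyad(infant = inf, caregiver = care, events = ev, id = id)
}

# AR(1) series with burn-in, for preprocessing tests
sim_ar1 <- function(n, phi, seed, sd = 1) {
  withr::with_seed(seed, {
    x <- numeric(n + 100)
    e <- rnorm(n + 100, 0, sd)
    for (t in 2:(n + 100)) x[t] <- phi * x[t - 1] + e[t]
    x[-seq_len(100)]
  })
}
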