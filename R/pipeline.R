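read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a per-dyad arousal table
#'
#' Canonical schema (TSV or CSV, sniffed from the header line): columns
#' `dyad_id`, `role`, `epoch` (0-based, consecutive within dyad and role),
#' `valid` (0/1 or logical), and either a `composite` column (already
#' collapsed arousal, z-scored on read) or raw channel columns among
#' `heart_rate`, `hrv`, `movement` (collapsed via [composite_arousal()]).
#' Schema violations are reported with the offending row numbers.
#'
#' @param path delimited text file.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(dyad_id = "id")`.
#' @return nested list: `result[[dyad_id]][[role]]` is an
#'   [arousal_series()].
#' @export
read_arousal_table <- function(path, column_map = NULL) {
  df <- read_delim_auto(path)
  for (nm in names(column_map)) {
    names(df)[names(df) == column_map[[nm]]] <- nm
  }
  need <- c("dyad_id", "role", "epoch", "valid")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  channels <- intersect(c("heart_rate", "hrv", "movement"), names(df))
  if (!"composite" %in% names(df) && length(channels) == 0L) {
    stop("need a 'composite' column or raw channel columns (heart_rate/hrv/movement)")
  }
  if (!all(df$role %in% SPEAKERS)) {
    bad <- which(!df$role %in% SPEAKERS)
    stop("unknown role at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  key <- paste(df$dyad_id, df$role, df$epoch)
  if (anyDuplicated(key)) {
    stop("duplicate (dyad, role, epoch) at row ", which(duplicated(key))[1L])
  }
  out <- list()
  for (id in unique(df$dyad_id)) {
    out[[as.character(id)]] <- list()
    for (role in unique(df$role[df$dyad_id == id])) {
      sub <- df[df$dyad_id == id & df$role == role, , drop = FALSE]
      sub <- sub[order(sub$epoch), , drop = FALSE]
      if (!identical(as.integer(sub$epoch), seq_len(nrow(sub)) - 1L)) {
        stop(sprintf("non-consecutive epochs for dyad %s role %s", id, role))
      }
      grid <- epoch_grid(nrow(sub))
      valid <- as.logical(sub$valid)
      series <- if ("composite" %in% names(df)) {
        arousal_series(ifelse(valid, sub$composite, NA_real_), valid = valid,
                       grid = grid, role = role, dyad_id = as.character(id))
      } else {
        composite_arousal(sub[channels], valid = valid, grid = grid,
                          role = role, dyad_id = as.character(id))
      }
      out[[as.character(id)]][[role]] <- series
    }
  }
  out
}

#' Read a per-dyad vocal event table
#'
#' Canonical schema: columns `dyad_id`, `epoch`, `speaker`, `category`;
#' the category vocabulary is the collapsed set (`cry`, `speech_like`,
#' `other`) or the raw morphological codes, which are collapsed on read
#' (see [collapse_vocal_codes()]); unknown codes are an error. Optional
#' `affect` and `intensity` columns are carried through.
#'
#' @param path delimited text file.
#' @param n_epochs named integer vector (or single value) giving each dyad's
#'   grid length; defaults to covering the last event.
#' @param column_map as in [read_arousal_table()].
#' @return list: `result[[dyad_id]]` is an [event_series()].
#' @export
read_event_table <- function(path, n_epochs = NULL, column_map = NULL) {
  df <- read_delim_auto(path)
  for (nm in names(column_map)) {
    names(df)[names(df) == column_map[[nm]]] <- nm
  }
  need <- c("dyad_id", "epoch", "speaker", "category")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (id in unique(df$dyad_id)) {
    sub <- df[df$dyad_id == id, , drop = FALSE]
    n <- if (is.null(n_epochs)) max(sub$epoch) + 1L
         else if (length(n_epochs) == 1L && is.null(names(n_epochs))) n_epochs
         else n_epochs[[as.character(id)]]
    out[[as.character(id)]] <- event_series(
      epoch = sub$epoch, speaker = sub$speaker, category = sub$category,
      grid = epoch_grid(n),
      affect = if ("affect" %in% names(sub)) sub$affect else NULL,
      intensity = if ("intensity" %in% names(sub)) sub$intensity else NULL)
  }
  out
}

#' Assemble dyads from arousal and event tables
#'
#' @param arousal_path,events_path canonical tables (see
#'   [read_arousal_table()] and [read_event_table()]).
#' @return list of [dyad()] objects (dyads present in both tables).
#' @export
read_dyads <- function(arousal_path, events_path) {
  ar <- read_arousal_table(arousal_path)
  n_ep <- vapply(ar, function(d) d[[1]]$grid$n_epochs, 1L)
  ev <- read_event_table(events_path, n_epochs = n_ep)
  ids <- intersect(names(ar), names(ev))
  lapply(stats::setNames(ids, ids), function(id) {
    dyad(infant = ar[[id]]$infant, caregiver = ar[[id]]$caregiver,
         events = ev[[id]], id = id)
  })
}

#' Write dyads to the canonical delimited tables
#'
#' @param dyads list of [dyad()] objects.
#' @param dir output directory (created if needed); writes `arousal.tsv`
#'   and `events.tsv`.
#' @return invisibly, the two file paths.
#' @export
write_dyad_tables <- function(dyads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ar <- do.call(rbind, unlist(lapply(dyads, function(d) {
    lapply(Filter(Negate(is.null), list(d$infant, d$caregiver)), function(s) {
      data.frame(dyad_id = d$id, role = s$role,
                 epoch = seq_len(s$grid$n_epochs) - 1L,
                 valid = as.integer(s$valid),
                 composite = ifelse(s$valid, round(s$values, 6), NA))
    })
  }), recursive = FALSE))
  ev <- do.call(rbind, lapply(dyads, function(d) {
    e <- d$events$events
    if (nrow(e) == 0L) return(NULL)
    data.frame(dyad_id = d$id, epoch = e$epoch, speaker = e$speaker,
               category = e$category)
  }))
  fa <- file.path(dir, "arousal.tsv"); fe <- file.path(dir, "events.tsv")
  utils::write.table(ar, fa, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ev, fe, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(fa, fe))
}

# per-dyad mean control profile over n_reps resampled non-vocalisation sets
control_profile <- function(d, ref, target, bins, n_reps, seed,
                            exclude_epochs = integer(), mask = NULL) {
  sets <- sample_control_events(d, ref = ref, n_reps = n_reps, seed = seed,
                                exclude_epochs = exclude_epochs)
  mats <- vapply(sets, function(cs) {
    likelihood_profile(cs, target, bins, mask)$likelihood
  }, numeric(nrow(bins)))
  rowMeans(matrix(mats, nrow = nrow(bins)), na.rm = TRUE)
}

#' Temporal-clustering analysis over a cohort
#'
#' The real-vs-control vocalisation clustering contrast: per dyad, the
#' likelihood profile of target events around reference events, against the
#' mean profile around matched random non-vocalisation moments; across
#' dyads, per-bin Mann-Whitney tests with Hodges-Lehmann effect sizes and a
#' label-swap permutation cluster correction.
#'
#' @param dyads list of [dyad()] objects.
#' @param ref_speaker,ref_category reference event selection.
#' @param target_speaker,target_category target event selection.
#' @param bins a [bin_grid()].
#' @param n_control_reps control sets per dyad (default 1000).
#' @param n_perm,cluster_alpha,seed cluster-test settings.
#' @return list: `bin_stats` (per-bin real/control means, HL, p),
#'   `clusters` ([permutation_cluster()] result), `real`, `control`
#'   matrices, `n_dyads`.
#' @export
cohort_likelihood_analysis <- function(dyads, ref_speaker = "infant",
                                       ref_category = "all",
                                       target_speaker = "infant",
                                       target_category = "all",
                                       bins = bin_grid(),
                                       n_control_reps = 1000L,
                                       n_perm = 1000L, cluster_alpha = 0.05,
                                       seed = 1L) {
  real <- list(); ctrl <- list()
  for (j in seq_along(dyads)) {
    d <- dyads[[j]]
    ref <- filter_events(d$events, ref_speaker, ref_category)
    target <- filter_events(d$events, target_speaker, target_category)
    if (nrow(ref$events) == 0L || nrow(target$events) == 0L) next
    mask <- dyad_valid(d)
    r <- likelihood_profile(ref, target, bins, mask)$likelihood
    cc <- tryCatch(
      control_profile(d, ref, target, bins, n_control_reps,
                      derive_seed(seed, j), mask = mask),
      error = function(e) NULL)
    if (is.null(cc)) next
    real[[d$id]] <- r; ctrl[[d$id]] <- cc
  }
  finish_contrast(real, ctrl, bins, n_perm, cluster_alpha, seed)
}

#' Vocalisation likelihood around arousal peaks over a cohort
#'
#' As [cohort_likelihood_analysis()], with arousal-peak epochs (see
#' [detect_peaks()]) as the reference events and matched non-peak,
#' non-vocalisation moments as controls.
#'
#' @inheritParams cohort_likelihood_analysis
#' @param peak_role whose arousal peaks.
#' @param pct peak percentile band (10 main; 5 and 20 as robustness).
#' @return as [cohort_likelihood_analysis()].
#' @export
cohort_peak_analysis <- function(dyads, peak_role = "infant",
                                 target_speaker = "infant",
                                 target_category = "all",
                                 pct = 10, bins = bin_grid(),
                                 n_control_reps = 1000L,
                                 n_perm = 1000L, cluster_alpha = 0.05,
                                 seed = 1L) {
  real <- list(); ctrl <- list()
  for (j in seq_along(dyads)) {
    d <- dyads[[j]]
    s <- d[[peak_role]]
    if (is.null(s)) next
    peaks <- tryCatch(detect_peaks(s, pct), error = function(e) NULL)
    if (is.null(peaks) || nrow(peaks$events) == 0L) next
    target <- filter_events(d$events, target_speaker, target_category)
    if (nrow(target$events) == 0L) next
    mask <- dyad_valid(d)
    r <- likelihood_profile(peaks, target, bins, mask)$likelihood
    cc <- tryCatch(
      control_profile(d, peaks, target, bins, n_control_reps,
                      derive_seed(seed, j),
                      exclude_epochs = event_epochs(peaks), mask = mask),
      error = function(e) NULL)
    if (is.null(cc)) next
    real[[d$id]] <- r; ctrl[[d$id]] <- cc
  }
  finish_contrast(real, ctrl, bins, n_perm, cluster_alpha, seed)
}

finish_contrast <- function(real, ctrl, bins, n_perm, cluster_alpha, seed) {
  if (length(real) < 8L) stop("fewer than 8 usable dyads for this contrast")
  R <- do.call(rbind, real); C <- do.call(rbind, ctrl)
  keep <- stats::complete.cases(R) & stats::complete.cases(C)
  R <- R[keep, , drop = FALSE]; C <- C[keep, , drop = FALSE]
  if (nrow(R) < 8L) stop("fewer than 8 complete dyads for this contrast")
  bin_stats <- bins
  bin_stats$real_mean <- colMeans(R)
  bin_stats$control_mean <- colMeans(C)
  tests <- lapply(seq_len(ncol(R)), function(b) mw_hl(R[, b], C[, b]))
  bin_stats$HL <- vapply(tests, `[[`, 0, "HL")
  bin_stats$p_uncorrected <- vapply(tests, `[[`, 0, "p")
  cl <- permutation_cluster(R, C, n_perm = n_perm,
                            cluster_alpha = cluster_alpha, seed = seed,
                            null = "label_swap")
  list(bin_stats = bin_stats, clusters = cl, real = R, control = C,
       n_dyads = nrow(R))
}

#' Event-locked arousal trajectories over a cohort
#'
#' Per dyad, the event-locked mean arousal trajectory (after autocorrelation
#' removal when `prewhiten = TRUE`, the default); across dyads, a
#' sign-flip permutation cluster test of the trajectory against 0, the
#' participant's day-average arousal.
#'
#' @param dyads list of [dyad()] objects.
#' @param series_role whose arousal.
#' @param event_speaker,event_category which events to lock to.
#' @param lags relative lags in epochs (minutes).
#' @param prewhiten remove lag-1 autocorrelation first (default TRUE).
#' @param n_perm,cluster_alpha,seed cluster-test settings.
#' @return list: `lag_stats` (per-lag group mean, SE, n), `clusters`,
#'   `real` matrix, `n_dyads`.
#' @export
cohort_trajectory_analysis <- function(dyads, series_role = "infant",
                                       event_speaker = "infant",
                                       event_category = "all",
                                       lags = -20:20, prewhiten = TRUE,
                                       n_perm = 1000L, cluster_alpha = 0.05,
                                       seed = 1L) {
  rows <- list()
  for (d in dyads) {
    s <- d[[series_role]]
    if (is.null(s)) next
    if (prewhiten) {
      s <- tryCatch(remove_autocorrelation(s), error = function(e) NULL)
      if (is.null(s)) next
    }
    ev <- filter_events(d$events, event_speaker, event_category)
    if (nrow(ev$events) == 0L) next
    rows[[d$id]] <- event_locked_arousal(s, ev, lags)$mean_arousal
  }
  if (length(rows) < 8L) stop("fewer than 8 usable dyads for this contrast")
  R <- do.call(rbind, rows)
  keep <- stats::complete.cases(R)
  R <- R[keep, , drop = FALSE]
  if (nrow(R) < 8L) stop("fewer than 8 complete dyads for this contrast")
  lag_stats <- data.frame(lag = lags, mean = colMeans(R),
                          se = apply(R, 2, stats::sd) / sqrt(nrow(R)),
                          n = nrow(R))
  cl <- permutation_cluster(R, n_perm = n_perm, cluster_alpha = cluster_alpha,
                            seed = seed, null = "sign_flip")
  list(lag_stats = lag_stats, clusters = cl, real = R, n_dyads = nrow(R))
}

#' Per-dyad ROC AUCs and group test against chance
#'
#' @param dyads list of [dyad()] objects.
#' @param series_role arousal side of the prediction.
#' @param event_speaker,event_category events being predicted.
#' @return list: `auc` (named per-dyad vector), `mean_auc`, `p` (two-sided
#'   Mann-Whitney of the AUCs against the chance value 0.5), `n_dyads`.
#' @export
cohort_roc_analysis <- function(dyads, series_role = "infant",
                                event_speaker = "infant",
                                event_category = "all") {
  aucs <- c()
  for (d in dyads) {
    s <- d[[series_role]]
    if (is.null(s)) next
    ev <- filter_events(d$events, event_speaker, event_category)
    a <- tryCatch(roc_auc(s, ev), error = function(e) NA_real_)
    if (!is.na(a)) aucs[d$id] <- a
  }
  if (length(aucs) == 0L) stop("no usable dyads for the ROC analysis")
  list(auc = aucs, mean_auc = mean(aucs),
       p = mw_hl(aucs, rep(0.5, length(aucs)))$p,
       n_dyads = length(aucs))
}

#' Event-locked arousal stability or coupling over a cohort
#'
#' Per dyad, the moving-window statistic series is excerpted around the
#' selected events and around matched control non-vocalisation moments;
#' across dyads, a label-swap permutation cluster test compares the two.
#' Coupling runs only on dyads with both partners' arousal.
#'
#' @param dyads list of [dyad()] objects.
#' @param stat `"stability"` or `"coupling"`.
#' @param role partner for stability (ignored for coupling).
#' @param event_speaker,event_category events to lock to.
#' @param lags relative lags in epochs.
#' @param W,S,min_valid moving-window settings (defaults 10, 5).
#' @param n_control_reps,n_perm,cluster_alpha,seed as elsewhere.
#' @return list: `lag_stats`, `clusters`, `real`, `control`, `n_dyads`.
#' @export
cohort_windowed_analysis <- function(dyads, stat = c("stability", "coupling"),
                                     role = "infant",
                                     event_speaker = "infant",
                                     event_category = "all",
                                     lags = -20:20, W = 10L, S = 5L,
                                     min_valid = 5L,
                                     n_control_reps = 1000L,
                                     n_perm = 1000L, cluster_alpha = 0.05,
                                     seed = 1L) {
  stat <- match.arg(stat)
  real <- list(); ctrl <- list()
  for (j in seq_along(dyads)) {
    d <- dyads[[j]]
    if (stat == "coupling" && (is.null(d$infant) || is.null(d$caregiver))) next
    if (stat == "stability" && is.null(d[[role]])) next
    ws <- windowed_series(d, stat, role = role, W = W, S = S, min_valid = min_valid)
    if (nrow(ws) == 0L) next
    ev <- filter_events(d$events, event_speaker, event_category)
    if (nrow(ev$events) == 0L) next
    r <- event_locked_stat(ws, ev, lags)$mean_stat
    cc <- tryCatch({
      sets <- sample_control_events(d, ref = ev, n_reps = n_control_reps,
                                    seed = derive_seed(seed, j))
      mats <- vapply(sets, function(cs) event_locked_stat(ws, cs, lags)$mean_stat,
                     numeric(length(lags)))
      rowMeans(matrix(mats, nrow = length(lags)), na.rm = TRUE)
    }, error = function(e) NULL)
    if (is.null(cc)) next
    real[[d$id]] <- r; ctrl[[d$id]] <- cc
  }
  if (length(real) < 8L) stop("fewer than 8 usable dyads for this contrast")
  R <- do.call(rbind, real); C <- do.call(rbind, ctrl)
  keep <- stats::complete.cases(R) & stats::complete.cases(C)
  R <- R[keep, , drop = FALSE]; C <- C[keep, , drop = FALSE]
  if (nrow(R) < 8L) stop("fewer than 8 complete dyads for this contrast")
  lag_stats <- data.frame(lag = lags, real_mean = colMeans(R),
                          control_mean = colMeans(C), n = nrow(R))
  cl <- permutation_cluster(R, C, n_perm = n_perm,
                            cluster_alpha = cluster_alpha, seed = seed,
                            null = "label_swap")
  list(lag_stats = lag_stats, clusters = cl, real = R, control = C,
       n_dyads = nrow(R))
}

#' Pipeline run configuration
#'
#' @param preset synthetic scenario name (see [scenario_params()]), or `NULL`
#'   when reading from files.
#' @param n_dyads dyads to simulate (with `preset`).
#' @param arousal_path,events_path input tables (without `preset`).
#' @param out_dir output directory.
#' @param bins a [bin_grid()].
#' @param lags trajectory lags in epochs.
#' @param W,S,min_valid moving-window settings.
#' @param peak_pct peak threshold percentile.
#' @param n_control_reps control sets per dyad (default 1000).
#' @param n_perm permutations (default 1000).
#' @param cluster_alpha cluster-forming threshold.
#' @param seed master seed.
#' @param analyses character subset of `clustering`, `trajectory`, `peaks`,
#'   `roc`, `quartiles`, `stability`, `coupling`.
#' @param categories infant event splits to run (`all`, `cry`,
#'   `speech_like`).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(preset = "paper_like", n_dyads = 20L,
                       arousal_path = NULL, events_path = NULL,
                       out_dir = tempfile("dyadarousal_run_"),
                       bins = bin_grid(), lags = -20:20,
                       W = 10L, S = 5L, min_valid = 5L, peak_pct = 10,
                       n_control_reps = 1000L, n_perm = 1000L,
                       cluster_alpha = 0.05, seed = 1L,
                       analyses = c("clustering", "trajectory", "peaks",
                                    "roc", "quartiles", "stability",
                                    "coupling"),
                       categories = c("all", "cry", "speech_like")) {
  stopifnot(n_control_reps > 0, n_perm > 0, n_dyads > 0,
            cluster_alpha > 0, cluster_alpha < 1)
  structure(as.list(environment()), class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

cluster_rows <- function(cl, label) {
  if (nrow(cl$clusters) == 0L) {
    return(data.frame(analysis = label, start = NA_integer_, end = NA_integer_,
                      sign = NA_real_, mass = NA_real_, p = NA_real_,
                      significant = FALSE))
  }
  cbind(analysis = label, cl$clusters,
        significant = cl$clusters$p <= 0.05)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the enabled analyses over a cohort of dyads (simulated from
#' a preset or read from the canonical tables), writes one TSV per analysis
#' plus a cluster summary, a machine-readable `summary.json`, an
#' effective-config snapshot, and a log of per-dyad exclusions. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param dyads optional pre-built list of [dyad()] objects (overrides
#'   `preset` / paths).
#' @return invisibly, a list with every analysis result plus `out_dir`.
#' @export
run_pipeline <- function(config, dyads = NULL) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("dyadarousal %s | seed %d",
                         as.character(utils::packageVersion("dyadarousal")),
                         cfg$seed))
  if (is.null(dyads)) {
    dyads <- if (!is.null(cfg$preset)) {
      simulate_cohort(scenario_params(cfg$preset, seed = cfg$seed), cfg$n_dyads)
    } else {
      read_dyads(cfg$arousal_path, cfg$events_path)
    }
  }
  if (length(dyads) < 8L) stop("need at least 8 dyads with usable data")
  log_lines <- c(log_lines, sprintf("%d dyads loaded", length(dyads)))

  res <- list(out_dir = cfg$out_dir)
  clusters <- list()
  log_note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  safely <- function(label, expr) {
    r <- tryCatch(expr, error = function(e) {
      log_note("SKIP %s: %s", label, conditionMessage(e))
      NULL
    })
    if (!is.null(r)) log_note("done %s (n=%s)", label,
                              if (!is.null(r$n_dyads)) r$n_dyads else "?")
    r
  }
  cats <- cfg$categories

  if ("clustering" %in% cfg$analyses) {
    combos <- expand.grid(ref = SPEAKERS, target = SPEAKERS,
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      for (cat in if (combos$ref[i] == "infant") cats else "all") {
        label <- sprintf("clustering_%s_%s_to_%s", combos$ref[i], cat, combos$target[i])
        r <- safely(label, cohort_likelihood_analysis(
          dyads, combos$ref[i], cat, combos$target[i], "all",
          bins = cfg$bins, n_control_reps = cfg$n_control_reps,
          n_perm = cfg$n_perm, cluster_alpha = cfg$cluster_alpha,
          seed = cfg$seed))
        if (!is.null(r)) {
          res[[label]] <- r
          write_tsv(cbind(analysis = label, r$bin_stats, n = r$n_dyads),
                    file.path(cfg$out_dir, paste0(label, ".tsv")))
          clusters[[label]] <- cluster_rows(r$clusters, label)
        }
      }
    }
  }
  if ("trajectory" %in% cfg$analyses) {
    combos <- expand.grid(series = SPEAKERS, speaker = SPEAKERS,
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      for (cat in if (combos$speaker[i] == "infant") cats else "all") {
        label <- sprintf("trajectory_%s_arousal_to_%s_%s",
                         combos$series[i], combos$speaker[i], cat)
        r <- safely(label, cohort_trajectory_analysis(
          dyads, combos$series[i], combos$speaker[i], cat,
          lags = cfg$lags, n_perm = cfg$n_perm,
          cluster_alpha = cfg$cluster_alpha, seed = cfg$seed))
        if (!is.null(r)) {
          res[[label]] <- r
          write_tsv(cbind(analysis = label, r$lag_stats),
                    file.path(cfg$out_dir, paste0(label, ".tsv")))
          clusters[[label]] <- cluster_rows(r$clusters, label)
        }
      }
    }
  }
  if ("peaks" %in% cfg$analyses) {
    for (target in SPEAKERS) {
      label <- sprintf("peaks_infant_to_%s", target)
      r <- safely(label, cohort_peak_analysis(
        dyads, "infant", target, "all", pct = cfg$peak_pct, bins = cfg$bins,
        n_control_reps = cfg$n_control_reps, n_perm = cfg$n_perm,
        cluster_alpha = cfg$cluster_alpha, seed = cfg$seed))
      if (!is.null(r)) {
        res[[label]] <- r
        write_tsv(cbind(analysis = label, r$bin_stats, n = r$n_dyads),
                  file.path(cfg$out_dir, paste0(label, ".tsv")))
        clusters[[label]] <- cluster_rows(r$clusters, label)
      }
    }
  }
  if ("roc" %in% cfg$analyses) {
    rows <- list()
    for (series in SPEAKERS) for (speaker in SPEAKERS) {
      for (cat in if (speaker == "infant") cats else "all") {
        label <- sprintf("roc_%s_arousal_to_%s_%s", series, speaker, cat)
        r <- safely(label, cohort_roc_analysis(dyads, series, speaker, cat))
        if (!is.null(r)) {
          res[[label]] <- r
          rows[[label]] <- data.frame(analysis = label, mean_auc = r$mean_auc,
                                      p = r$p, n = r$n_dyads)
        }
      }
    }
    if (length(rows)) write_tsv(do.call(rbind, rows),
                                file.path(cfg$out_dir, "roc_auc.tsv"))
  }
  if ("quartiles" %in% cfg$analyses) {
    for (voc in SPEAKERS) {
      label <- sprintf("quartiles_%s_vocalisations", voc)
      r <- safely(label, {
        qp <- partner_quartile_profiles(dyads, voc, "all", bins = cfg$bins)
        qp$clusters <- quartile_cluster(qp, n_perm = cfg$n_perm,
                                        cluster_alpha = cfg$cluster_alpha,
                                        seed = cfg$seed)
        qp
      })
      if (!is.null(r)) {
        res[[label]] <- r
        write_tsv(cbind(analysis = label, r$tests, n = r$n_dyads),
                  file.path(cfg$out_dir, paste0(label, ".tsv")))
        clusters[[label]] <- cluster_rows(r$clusters, label)
      }
    }
  }
  for (stat in intersect(c("stability", "coupling"), cfg$analyses)) {
    roles <- if (stat == "stability") SPEAKERS else "infant"
    for (role in roles) for (speaker in SPEAKERS) {
      for (cat in if (speaker == "infant") cats else "all") {
        label <- if (stat == "stability") {
          sprintf("stability_%s_to_%s_%s", role, speaker, cat)
        } else sprintf("coupling_to_%s_%s", speaker, cat)
        if (!is.null(res[[label]])) next
        r <- safely(label, cohort_windowed_analysis(
          dyads, stat, role = role, event_speaker = speaker,
          event_category = cat, lags = cfg$lags, W = cfg$W, S = cfg$S,
          min_valid = cfg$min_valid, n_control_reps = cfg$n_control_reps,
          n_perm = cfg$n_perm, cluster_alpha = cfg$cluster_alpha,
          seed = cfg$seed))
        if (!is.null(r)) {
          res[[label]] <- r
          write_tsv(cbind(analysis = label, r$lag_stats),
                    file.path(cfg$out_dir, paste0(label, ".tsv")))
          clusters[[label]] <- cluster_rows(r$clusters, label)
        }
      }
    }
  }

  if (length(clusters)) {
    write_tsv(do.call(rbind, clusters), file.path(cfg$out_dir, "clusters.tsv"))
  }
  summary <- list(
    n_dyads = length(dyads),
    seed = cfg$seed,
    analyses_run = setdiff(names(res), "out_dir"),
    significant_clusters = if (length(clusters)) {
      cc <- do.call(rbind, clusters)
      as.list(table(cc$analysis[which(cc$significant)]))
    } else list())
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  snap <- cfg
  snap$bins <- NULL
  jsonlite::write_json(snap[!vapply(snap, is.null, TRUE)],
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  invisible(res)
}
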