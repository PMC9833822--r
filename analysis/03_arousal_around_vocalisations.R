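#!/usr/bin/env Rscript
# How does arousal relate to vocalisation timing?
#  (1) event-locked arousal trajectories (after autocorrelation removal)
#      tested against 0 with the sign-flip cluster test, split by infant
#      vocal category;
#  (2) vocalisation likelihood around infant arousal peaks (top 10%);
#  (3) per-dyad ROC AUC of arousal predicting vocalisation presence;
#  (4) partner arousal split by vocaliser-arousal quartiles.
#
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(dyadarousal))

seed <- 2026L
dyads <- read_dyads("results/data/paper_like/arousal.tsv",
                    "results/data/paper_like/events.tsv")
dir.create("results/arousal", recursive = TRUE, showWarnings = FALSE)

# (1) event-locked trajectories
for (series in c("infant", "caregiver")) {
  for (cat_ in c("all", "cry", "speech_like")) {
    label <- sprintf("%s_arousal_infant_%s", series, cat_)
    r <- tryCatch(cohort_trajectory_analysis(dyads, series, "infant", cat_,
                                             n_perm = 500, seed = seed),
                  error = function(e) NULL)
    if (is.null(r)) { cat(label, ": skipped (too few dyads)\n"); next }
    write.table(cbind(analysis = label, r$lag_stats),
                file.path("results/arousal", paste0(label, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
    cl <- r$clusters$clusters; sig <- cl[cl$p <= 0.05, , drop = FALSE]
    lag0 <- r$lag_stats$mean[r$lag_stats$lag == 0]
    cat(sprintf("%-34s: arousal at lag 0 = %+.2f z, %d significant cluster(s)\n",
                label, lag0, nrow(sig)))
  }
}

# (2) vocalisation likelihood around infant arousal peaks
pk <- cohort_peak_analysis(dyads, "infant", "infant", "all", pct = 10,
                           n_control_reps = 100, n_perm = 500, seed = seed)
write.table(cbind(analysis = "peaks_infant", pk$bin_stats, n = pk$n_dyads),
            "results/arousal/peaks_infant.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("infant vocalisations around infant arousal peaks: %d significant cluster(s)\n",
            sum(pk$clusters$clusters$p <= 0.05)))

# (3) ROC AUCs
rows <- list()
for (series in c("infant", "caregiver")) for (speaker in c("infant", "caregiver")) {
  r <- cohort_roc_analysis(dyads, series, speaker, "all")
  rows[[paste(series, speaker)]] <-
    data.frame(arousal = series, events = speaker,
               mean_auc = r$mean_auc, p = r$p, n = r$n_dyads)
  cat(sprintf("AUC %s arousal -> %s vocalisations: %.3f (p = %.3g)\n",
              series, speaker, r$mean_auc, r$p))
}
write.table(do.call(rbind, rows), "results/arousal/roc_auc.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

# (4) partner arousal by vocaliser-arousal quartile
qp <- partner_quartile_profiles(dyads, "infant", "all")
qc <- quartile_cluster(qp, n_perm = 500, seed = seed)
write.table(cbind(analysis = "quartiles_infant", qp$tests, n = qp$n_dyads),
            "results/arousal/quartiles_infant.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(sprintf("caregiver arousal by infant-arousal quartile: %d significant cluster(s)\n",
            sum(qc$clusters$p <= 0.05)))
cat("wrote results/arousal/\n")
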