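#!/usr/bin/env Rscript
# Moving-window arousal stability (lag-1 autocorrelation) and dyadic
# coupling (detrended zero-lag Spearman), excerpted around vocalisations
# and compared with matched non-vocalisation controls. Windows of 10
# epochs shifting by 5, as in the moving-window design.
#
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(dyadarousal))

seed <- 2026L
dyads <- read_dyads("results/data/cry_vs_speech/arousal.tsv",
                    "results/data/cry_vs_speech/events.tsv")
dir.create("results/windows", recursive = TRUE, showWarnings = FALSE)

run <- function(stat, role, cat_) {
  label <- if (stat == "stability") sprintf("stability_%s_infant_%s", role, cat_)
           else sprintf("coupling_infant_%s", cat_)
  r <- tryCatch(
    cohort_windowed_analysis(dyads, stat, role = role,
                             event_speaker = "infant", event_category = cat_,
                             n_control_reps = 100, n_perm = 500, seed = seed),
    error = function(e) NULL)
  if (is.null(r)) { cat(label, ": skipped (too few dyads)\n"); return(invisible()) }
  write.table(cbind(analysis = label, r$lag_stats),
              file.path("results/windows", paste0(label, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cl <- r$clusters$clusters; sig <- cl[cl$p <= 0.05, , drop = FALSE]
  cat(sprintf("%-34s: mean real %.3f vs control %.3f | %d significant cluster(s)\n",
              label, mean(r$lag_stats$real_mean), mean(r$lag_stats$control_mean),
              nrow(sig)))
}

for (cat_ in c("all", "cry", "speech_like")) {
  run("stability", "infant", cat_)
  run("stability", "caregiver", cat_)
  run("coupling", "infant", cat_)
}
cat("wrote results/windows/\n")
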