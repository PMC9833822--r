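#!/usr/bin/env Rscript
# Do vocalisations cluster in time, within a speaker and across the dyad?
# For each contrast (e.g. infant vocalisations around caregiver
# vocalisations) we compare the likelihood profile around real events with
# the profile around matched random non-vocalisation moments, and correct
# across time bins with the permutation cluster test.
#
# Run analysis/01_simulate.R first.

suppressPackageStartupMessages(library(dyadarousal))

seed <- 2026L
dyads <- read_dyads("results/data/paper_like/arousal.tsv",
                    "results/data/paper_like/events.tsv")
dir.create("results/clustering", recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (ref in c("infant", "caregiver")) for (target in c("infant", "caregiver")) {
  label <- sprintf("%s_around_%s", target, ref)
  r <- cohort_likelihood_analysis(dyads, ref_speaker = ref,
                                  target_speaker = target,
                                  n_control_reps = 100, n_perm = 500,
                                  seed = seed)
  write.table(cbind(contrast = label, r$bin_stats, n = r$n_dyads),
              file.path("results/clustering", paste0(label, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cl <- r$clusters$clusters
  sig <- cl[cl$p <= 0.05, , drop = FALSE]
  cat(sprintf("%-28s: %d significant cluster(s)", label, nrow(sig)))
  if (nrow(sig)) {
    b <- r$bin_stats
    cat(sprintf(" [%g to %g min, p = %.3g]",
                b$lo[sig$start[1]], b$hi[sig$end[1]], sig$p[1]))
  }
  cat("\n")
  if (nrow(cl)) rows[[label]] <- cbind(contrast = label, cl)
}
write.table(do.call(rbind, rows), "results/clustering/clusters.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote results/clustering/\n")
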