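#' Mann-Whitney U test with Hodges-Lehmann effect size
#'
#' Two-sided Mann-Whitney U comparing a "real" and a "control" sample, with
#' the Hodges-Lehmann estimate (the median of all pairwise real - control
#' differences) as the effect size, as used for the real-vs-control
#' likelihood and trajectory contrasts. The p-value is exact (from the null
#' distribution of U) when the combined sample size is at most 20 and no
#' ties are present, and otherwise uses the normal approximation with tie
#' correction (no continuity correction).
#'
#' @param real,control numeric samples (both non-empty).
#' @return list: `U` (number of real > control pairs, ties 0.5), `p`
#'   two-sided, `HL` Hodges-Lehmann estimate, `direction` sign of `HL`.
#' @export
mw_hl <- function(real, control) {
  real <- as.numeric(real); control <- as.numeric(control)
  m <- length(real); n <- length(control)
  if (m == 0L || n == 0L) stop("empty sample")
  r <- rank(c(real, control))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(c(real, control)))
  if (!ties && m + n <= 20L) {
    p <- min(1, 2 * min(stats::pwilcox(U, m, n),
                        1 - stats::pwilcox(U - 1, m, n)))
  } else {
    N <- m + n
    tie_tab <- table(r)
    sig2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - m * n / 2) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  HL <- stats::median(outer(real, control, "-"))
  list(U = U, p = p, HL = HL, direction = sign(HL))
}

#' ROC AUC by exhaustive threshold sweep
#'
#' Thresholds the score at every observed value from its minimum to maximum;
#' at each threshold an observation is classified positive when its score is
#' at or above the threshold, giving one (false positive rate, true positive
#' rate) point per threshold; the area under the resulting curve is computed
#' by trapezoidal integration. This equals the rank-sum
#' (probability-of-correct-ordering) AUC with ties counted 0.5.
#'
#' @param scores numeric predictor values.
#' @param labels logical (or 0/1): event present.
#' @return AUC in `[0, 1]`.
#' @export
auc_sweep <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("need both event and non-event observations")
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  # sweep runs from the most lenient threshold (everything positive, point
  # (1,1)) up; close the curve at (0,0)
  fpr <- c(1, fpr, 0)
  tpr <- c(1, tpr, 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Per-dyad ROC AUC of arousal predicting vocal events
#'
#' Labels every valid epoch by whether the given events include it and asks
#' how well the arousal value alone separates event from non-event epochs
#' (AUC 0.5 = chance). Group-level inference compares the per-participant
#' AUCs with 0.5 via [mw_hl()].
#'
#' @param series an [arousal_series()].
#' @param events an [event_series()] on the same grid.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(series, events) {
  if (!same_grid(series$grid, events$grid)) stop("series and events on different grids")
  lab <- rep(FALSE, series$grid$n_epochs)
  lab[events$events$epoch + 1L] <- TRUE
  use <- series$valid & !is.na(series$values)
  auc_sweep(series$values[use], lab[use])
}

#' One-way ANOVA F
#'
#' Classical one-way fixed-effects F statistic with its p-value from the F
#' distribution, applied per time bin in the quartile analyses.
#'
#' @param groups list of >= 2 numeric samples, each with >= 2 values.
#' @return list: `F`, `p`, `df1`, `df2`.
#' @export
oneway_f <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- nlevels(g); N <- length(y)
  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssw == 0 && ssb == 0) stop("degenerate groups: no variance at all")
  Fst <- if (ssw == 0) Inf else (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(Fst)) 0 else stats::pf(Fst, df1, df2, lower.tail = FALSE)
  list(F = Fst, p = p, df1 = df1, df2 = df2)
}

# maximal runs of contiguous supra-threshold bins with a common sign
clusters_from_z <- function(z, zcrit) {
  lab <- ifelse(abs(z) > zcrit, sign(z), 0)
  out <- list()
  r <- rle(lab)
  stop_at <- cumsum(r$lengths)
  start_at <- stop_at - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] != 0) {
      idx <- start_at[i]:stop_at[i]
      out[[length(out) + 1L]] <- data.frame(
        start = start_at[i], end = stop_at[i],
        sign = r$values[i], mass = sum(abs(z[idx])))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), sign = numeric(), mass = numeric())
}

#' Permutation-based temporal cluster test
#'
#' Corrects the per-bin real-vs-control comparisons for multiple comparisons
#' across time, crediting temporally contiguous effects: (1) each bin gets a
#' standardised statistic z; (2) bins with two-sided p below `cluster_alpha`
#' form candidate clusters of contiguous, same-signed bins whose mass is the
#' sum of |z|; (3) the null distribution of the maximum cluster mass is
#' built by `n_perm` permutations that respect the participant structure;
#' (4) each observed cluster's p-value is
#' `(1 + #permutations with max mass >= observed) / (n_perm + 1)`.
#'
#' Two nulls are available. `"label_swap"` (real vs resampled-control
#' comparisons): per bin, z is the tie-corrected Mann-Whitney normal score
#' comparing the real and control values across participants, and each
#' permutation swaps the real/control labels within a random subset of
#' participants. `"sign_flip"` (trajectory-vs-zero comparisons, where 0 is
#' the participant's day-average arousal): per bin, z is the Wilcoxon
#' signed-rank normal score of the participant differences, and each
#' permutation flips the sign of whole participant rows.
#'
#' @param real participants x bins matrix.
#' @param control participants x bins matrix (defaults to zeros for
#'   `"sign_flip"`).
#' @param n_perm number of permutations (default 1000).
#' @param cluster_alpha two-sided cluster-forming threshold (default 0.05).
#' @param seed RNG seed for the permutation draws.
#' @param null `"label_swap"` or `"sign_flip"`.
#' @param min_participants minimum rows (default 8).
#' @return object of class `"cluster_result"`: list with `bin_z`,
#'   `threshold`, `clusters` (data.frame `start`, `end`, `sign`, `mass`,
#'   `p`), `n_perm`, `alpha`, `null`.
#' @export
permutation_cluster <- function(real, control = NULL, n_perm = 1000L,
                                cluster_alpha = 0.05, seed = 1L,
                                null = c("label_swap", "sign_flip"),
                                min_participants = 8L) {
  null <- match.arg(null)
  real <- as.matrix(real)
  if (is.null(control)) {
    if (null == "label_swap") stop("label_swap null requires a control matrix")
    control <- matrix(0, nrow(real), ncol(real))
  }
  control <- as.matrix(control)
  if (!all(dim(real) == dim(control))) stop("real and control must share participants and bins")
  n <- nrow(real); B <- ncol(real)
  if (n < min_participants) {
    stop(sprintf("too few participants: %d < %d", n, min_participants))
  }
  if (anyNA(real) || anyNA(control)) {
    stop("real/control matrices must be complete; drop or aggregate missing participants first")
  }
  zcrit <- stats::qnorm(1 - cluster_alpha / 2)

  if (null == "label_swap") {
    M <- rbind(real, control)
    R <- apply(M, 2, rank)
    sig <- vapply(seq_len(B), function(b) {
      tt <- table(R[, b])
      s2 <- n * n / 12 * ((2 * n + 1) - sum(tt^3 - tt) / (2 * n * (2 * n - 1)))
      if (s2 > 0) sqrt(s2) else NA_real_
    }, 0)
    zfun <- function(sel) {
      U <- colSums(R[sel, , drop = FALSE]) - n * (n + 1) / 2
      z <- (U - n * n / 2) / sig
      z[is.na(z)] <- 0
      z
    }
    obs_sel <- seq_len(n)
    z_obs <- zfun(obs_sel)
    perm_max <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(p) {
        sel <- seq_len(n) + n * stats::rbinom(n, 1L, 0.5)
        cl <- clusters_from_z(zfun(sel), zcrit)
        if (nrow(cl)) max(cl$mass) else 0
      }, 0)
    })
  } else {
    d <- real - control
    SG <- sign(d)
    RK <- apply(abs(d), 2, function(col) {
      rk <- numeric(length(col))
      nz <- col != 0
      rk[nz] <- rank(col[nz])
      rk
    })
    nz_n <- colSums(SG != 0)
    mu <- nz_n * (nz_n + 1) / 4
    sig <- vapply(seq_len(B), function(b) {
      rk <- RK[SG[, b] != 0, b]
      tt <- table(rk)
      s2 <- nz_n[b] * (nz_n[b] + 1) * (2 * nz_n[b] + 1) / 24 - sum(tt^3 - tt) / 48
      if (s2 > 0) sqrt(s2) else NA_real_
    }, 0)
    zfun <- function(s) {
      V <- colSums(RK * ((SG * s) > 0))
      z <- (V - mu) / sig
      z[is.na(z)] <- 0
      z
    }
    z_obs <- zfun(rep(1, n))
    perm_max <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(p) {
        s <- stats::rbinom(n, 1L, 0.5) * 2L - 1L
        cl <- clusters_from_z(zfun(s), zcrit)
        if (nrow(cl)) max(cl$mass) else 0
      }, 0)
    })
  }

  clusters <- clusters_from_z(z_obs, zcrit)
  clusters$p <- if (nrow(clusters)) {
    vapply(clusters$mass, function(m) (1 + sum(perm_max >= m)) / (n_perm + 1), 0)
  } else numeric(0)
  structure(list(bin_z = z_obs, threshold = zcrit, clusters = clusters,
                 n_perm = n_perm, alpha = cluster_alpha, null = null),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s null, %d bins, %d permutations, |z| > %.2f\n",
              x$null, length(x$bin_z), x$n_perm, x$threshold))
  if (nrow(x$clusters)) print(x$clusters) else cat("no clusters\n")
  invisible(x)
}

#' Cluster correction for the per-bin quartile ANOVA
#'
#' The quartile analysis tests, bin by bin, whether the partner's
#' event-locked arousal differs across vocaliser-arousal quartiles with a
#' one-way F on participant-level quartile means. This corrects those F
#' tests across bins: bins with one-sided p below `cluster_alpha` form
#' contiguous clusters whose mass is the summed normal-score of the F
#' p-values, and the maximum-mass null is built by permuting each
#' participant's quartile labels independently.
#'
#' @param qp result of [partner_quartile_profiles()].
#' @param n_perm,cluster_alpha,seed permutation settings.
#' @param min_participants minimum complete participants (default 8).
#' @return object of class `"cluster_result"` (positive sign only).
#' @export
quartile_cluster <- function(qp, n_perm = 1000L, cluster_alpha = 0.05,
                             seed = 1L, min_participants = 8L) {
  traj <- qp$traj
  B <- max(traj$bin)
  ids <- unique(traj$dyad)
  A <- array(NA_real_, c(length(ids), 4L, B))
  for (r in seq_len(nrow(traj))) {
    A[match(traj$dyad[r], ids), traj$quartile[r], traj$bin[r]] <- traj$mean_arousal[r]
  }
  complete <- apply(A, 1, function(m) !anyNA(m))
  A <- A[complete, , , drop = FALSE]
  n <- dim(A)[1]
  if (n < min_participants) {
    stop(sprintf("too few complete participants for the quartile cluster test: %d < %d",
                 n, min_participants))
  }
  zcrit <- stats::qnorm(1 - cluster_alpha)
  f_z <- function(Ax) {
    vapply(seq_len(B), function(b) {
      x <- Ax[, , b]
      gm <- colMeans(x)
      ssb <- n * sum((gm - mean(x))^2)
      ssw <- sum(sweep(x, 2, gm)^2)
      df1 <- 3L; df2 <- 4L * n - 4L
      if (ssw == 0) return(Inf)
      Fst <- (ssb / df1) / (ssw / df2)
      # one-sided: large F -> large z; log-scale for stability in the tails
      stats::qnorm(stats::pf(Fst, df1, df2, lower.tail = FALSE, log.p = TRUE),
                   lower.tail = FALSE, log.p = TRUE)
    }, 0)
  }
  z_obs <- f_z(A)
  cl_pos <- function(z) clusters_from_z(pmax(z, 0), zcrit)
  perm_max <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(p) {
      Ap <- A
      for (i in seq_len(n)) Ap[i, , ] <- A[i, sample.int(4L), ]
      cl <- cl_pos(f_z(Ap))
      if (nrow(cl)) max(cl$mass) else 0
    }, 0)
  })
  clusters <- cl_pos(z_obs)
  clusters$p <- if (nrow(clusters)) {
    vapply(clusters$mass, function(m) (1 + sum(perm_max >= m)) / (n_perm + 1), 0)
  } else numeric(0)
  structure(list(bin_z = z_obs, threshold = zcrit, clusters = clusters,
                 n_perm = n_perm, alpha = cluster_alpha, null = "quartile_relabel"),
            class = "cluster_result")
}
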