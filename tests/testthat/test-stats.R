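test_that("Mann-Whitney with Hodges-Lehmann matches hand-computed examples", {
  r <- mw_hl(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)               # 2 * 1/20 over all C(6,3) rank splits
  expect_equal(r$HL, -3)               # median of the 9 pairwise differences
  expect_equal(r$direction, -1)

  same <- mw_hl(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$HL, 0)
  expect_equal(same$p, 1)

  # shift equivariance of HL
  x <- rnorm(8)
  expect_equal(mw_hl(x + 1.7, x)$HL, 1.7)
})

test_that("exact Mann-Whitney p equals full enumeration for all n, m <= 6", {
  withr::with_seed(42, {
    for (m in 2:6) for (n in 2:6) {
      for (rep in 1:3) {
        real <- rnorm(m); control <- rnorm(n)   # continuous: no ties
        expect_equal(mw_hl(real, control)$p, mw_exact_enum(real, control),
                     tolerance = 1e-12,
                     label = sprintf("m=%d n=%d rep=%d", m, n, rep))
      }
    }
  })
})

test_that("HL estimate equals the median of enumerated pairwise differences", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
      expect_equal(mw_hl(a, b)$HL, median(as.vector(outer(a, b, "-"))))
    }
  })
})

test_that("large-sample Mann-Whitney agrees with wilcox.test's normal approximation", {
  withr::with_seed(13, {
    x <- rnorm(30); y <- rnorm(25, 0.4)
    ref <- suppressWarnings(wilcox.test(x, y, correct = FALSE, exact = FALSE))
    expect_equal(mw_hl(x, y)$p, ref$p.value, tolerance = 1e-10)
    # with ties
    xt <- round(rnorm(15), 1); yt <- round(rnorm(15), 1)
    reft <- suppressWarnings(wilcox.test(xt, yt, correct = FALSE, exact = FALSE))
    expect_equal(mw_hl(xt, yt)$p, reft$p.value, tolerance = 1e-10)
  })
})

test_that("AUC sweep matches hand-enumerated orderings", {
  expect_equal(auc_sweep(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_sweep(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  # events at 1 and 3 vs non-events at 2 and 4: one winning pair of four
  expect_equal(auc_sweep(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.25)
  expect_error(auc_sweep(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("AUC sweep equals the rank-sum formulation on random instances", {
  withr::with_seed(314, {
    for (rep in 1:200) {
      n <- sample(4:50, 1)
      scores <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)  # many ties
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(labels) || all(labels)) next
      expect_equal(auc_sweep(scores, labels), auc_ranksum(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("one-way F matches hand computation and the base-R reference", {
  f <- oneway_f(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(f$F, 1.5)               # MSB = 1.5, MSW = 1
  expect_equal(f$df1, 1L); expect_equal(f$df2, 4L)

  same <- oneway_f(list(c(1, 2), c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$F, 0)

  sep <- oneway_f(list(c(0, 0), c(10, 10)))
  expect_true(is.infinite(sep$F))
  expect_lt(sep$p, 0.001)

  withr::with_seed(5, {
    g <- list(rnorm(6), rnorm(7, 0.5), rnorm(5, 1))
    ref <- oneway.test(y ~ grp, data.frame(y = unlist(g),
                                           grp = rep(letters[1:3], lengths(g))),
                       var.equal = TRUE)
    mine <- oneway_f(g)
    expect_equal(mine$F, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  })
  expect_error(oneway_f(list(1:3)), ">= 2 groups")
  expect_error(oneway_f(list(1:3, 2)), ">= 2 values")
})

test_that("cluster test finds nothing without supra-threshold bins", {
  withr::with_seed(21, {
    R <- matrix(rnorm(200, 0, 0.01), 10)
    C <- R + matrix(rnorm(200, 0, 0.01), 10)   # no systematic difference
    res <- permutation_cluster(R, C, n_perm = 100, seed = 1)
    if (nrow(res$clusters)) expect_gt(min(res$clusters$p), 0.05)
    expect_length(res$bin_z, 20L)
  })
})

test_that("cluster test recovers a contiguous injected effect", {
  withr::with_seed(77, {
    hits <- 0
    for (s in 1:30) {
      R <- matrix(rnorm(20 * 15), 20)
      C <- matrix(rnorm(20 * 15), 20)
      R[, 5:9] <- R[, 5:9] + 1.2
      res <- permutation_cluster(R, C, n_perm = 200, seed = s)
      cl <- res$clusters
      ok <- nrow(cl) > 0 &&
        any(cl$p <= 0.05 & cl$start <= 9 & cl$end >= 5 & cl$sign > 0)
      hits <- hits + ok
    }
    expect_gte(hits / 30, 0.9)
  })
})

test_that("cluster results are reproducible under a fixed seed", {
  withr::with_seed(3, {
    R <- matrix(rnorm(160), 8); C <- matrix(rnorm(160), 8)
  })
  a <- permutation_cluster(R, C, n_perm = 150, seed = 42)
  b <- permutation_cluster(R, C, n_perm = 150, seed = 42)
  expect_identical(a, b)
  expect_error(permutation_cluster(R[1:5, ], C[1:5, ]), "too few participants")
})

test_that("sign-flip cluster test is calibrated and detects a one-sample shift", {
  withr::with_seed(2024, {
    # null: no lag should light up often
    fp <- 0
    for (s in 1:40) {
      R <- matrix(rnorm(15 * 20), 15)
      cl <- permutation_cluster(R, n_perm = 200, seed = s, null = "sign_flip")$clusters
      fp <- fp + (nrow(cl) > 0 && min(cl$p) <= 0.05)
    }
    expect_lte(fp / 40, 0.15)
    # shift on bins 8..12 across participants
    hits <- 0
    for (s in 1:20) {
      R <- matrix(rnorm(15 * 20), 15)
      R[, 8:12] <- R[, 8:12] + 1
      cl <- permutation_cluster(R, n_perm = 200, seed = s, null = "sign_flip")$clusters
      hits <- hits + (nrow(cl) > 0 && any(cl$p <= 0.05 & cl$start <= 12 & cl$end >= 8))
    }
    expect_gte(hits / 20, 0.9)
  })
})

test_that("quartile cluster test ignores exchangeable groups and finds injected offsets", {
  mk_traj <- function(seed, offset = 0, bins_hit = integer()) {
    withr::with_seed(seed, {
      rows <- expand.grid(dyad = sprintf("d%02d", 1:20), quartile = 1:4,
                          bin = 1:21, stringsAsFactors = FALSE)
      rows$mean_arousal <- rnorm(nrow(rows), 0, 0.3)
      sel <- rows$quartile == 4 & rows$bin %in% bins_hit
      rows$mean_arousal[sel] <- rows$mean_arousal[sel] + offset
      rows
    })
  }
  # exchangeable quartiles: family-wise false positives near the nominal rate
  fp <- 0
  for (s in 1:20) {
    cl0 <- quartile_cluster(list(traj = mk_traj(s)), n_perm = 200, seed = s)$clusters
    fp <- fp + (nrow(cl0) > 0 && min(cl0$p) <= 0.05)
  }
  expect_lte(fp / 20, 0.2)

  # +0.5 offset in the top quartile over the 2-6 min bins (bins 12-13 of the
  # default grid, i.e. [1,3) and [3,5) plus [5,7))
  hits <- 0
  for (s in 1:30) {
    qa <- list(traj = mk_traj(100 + s, offset = 0.5, bins_hit = 12:14))
    cl <- quartile_cluster(qa, n_perm = 200, seed = s)$clusters
    hits <- hits + (nrow(cl) > 0 && any(cl$p <= 0.05 & cl$start <= 14 & cl$end >= 12))
  }
  expect_gte(hits / 30, 0.9)
})

test_that("cluster decisions are stable in the number of permutations", {
  withr::with_seed(909, {
    strong_R <- matrix(rnorm(20 * 15), 20); strong_R[, 6:10] <- strong_R[, 6:10] + 1.5
    strong_C <- matrix(rnorm(20 * 15), 20)
    null_R <- matrix(rnorm(20 * 15), 20)
    null_C <- matrix(rnorm(20 * 15), 20)
  })
  decide <- function(R, C, n_perm) {
    cl <- permutation_cluster(R, C, n_perm = n_perm, seed = 31)$clusters
    nrow(cl) > 0 && min(cl$p) <= 0.05
  }
  expect_identical(decide(strong_R, strong_C, 200), decide(strong_R, strong_C, 2000))
  expect_identical(decide(null_R, null_C, 200), decide(null_R, null_C, 2000))
  expect_true(decide(strong_R, strong_C, 200))
  expect_false(decide(null_R, null_C, 200))
})
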