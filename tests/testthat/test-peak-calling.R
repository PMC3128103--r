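# Normalization, the window caller against the exhaustive oracle, the
# permutation FDR, and threshold calibration.

test_that("biweight centering is robust, shift-equivariant and degenerate-safe", {
  x <- make_probe_table("g1", seq(-200, 200, 100), rep(0.7, 5))
  expect_message(out <- normalize_biweight(x), "median")
  expect_equal(out$log2_ratio, rep(0, 5))

  y <- make_probe_table("g1", seq(-200, 200, 100),
                        c(0.1, -0.1, 0.0, 0.2, 10))
  loc <- y$log2_ratio - normalize_biweight(y)$log2_ratio
  expect_true(all(abs(loc - loc[1]) < 1e-12))
  # outlier downweighted: location stays in the bulk, unlike the mean (2.04)
  expect_gte(loc[1], -0.1)
  expect_lte(loc[1], 0.2)
  expect_equal(loc[1], oracle_biweight(y$log2_ratio), tolerance = 1e-12)

  # shift equivariance: x and x + delta normalize identically
  z <- y
  z$log2_ratio <- z$log2_ratio + 5
  expect_equal(normalize_biweight(z)$log2_ratio,
               normalize_biweight(y)$log2_ratio, tolerance = 1e-12)

  expect_error(normalize_biweight(y[0, ]), "empty")
})

test_that("caller handles flat signal, planted bumps and configuration errors", {
  flat <- make_grid_sample(3)
  expect_equal(nrow(call_peaks(flat, score_threshold = 0.5, min_probes = 3)),
               0)

  one <- make_grid_sample(1, sites = -1000, height = 2)
  pk <- call_peaks(one, score_threshold = 0.5, min_probes = 3)
  expect_equal(nrow(pk), 1)
  site_w <- -1000 - tiled_window()[1]
  expect_lt(pk$start, site_w)
  expect_gt(pk$end, site_w)

  two <- make_grid_sample(1, sites = -2000, height = 2)
  off <- seq(-3250, 750, 100)
  two$log2_ratio <- two$log2_ratio + 2 * pmax(0, 1 - abs(off - 0) / 500)
  pk2 <- call_peaks(two, score_threshold = 0.5, min_probes = 3)
  expect_equal(nrow(pk2), 2)

  expect_error(call_peaks(flat, window_bp = 50), "probe spacing")
})

test_that("caller agrees exactly with the exhaustive window-start oracle", {
  set.seed(42)
  for (case in 1:12) {
    window_bp <- sample(c(250, 400, 500, 800), 1)
    min_probes <- sample(2:5, 1)
    thresh <- runif(1, 0.3, 0.8)
    n_genes <- sample(3:6, 1)
    tabs <- lapply(seq_len(n_genes), function(i) {
      k <- sample(10:35, 1)
      offs <- -3250 + cumsum(sample(c(50, 100, 150, 200), k, replace = TRUE))
      offs <- offs[offs <= 750]
      v <- rnorm(length(offs), 0, 0.4)
      if (runif(1) < 0.7) {
        site <- sample(offs, 1)
        v <- v + runif(1, 1, 2.5) * pmax(0, 1 - abs(offs - site) / 500)
      }
      make_probe_table(sprintf("g%02d", i), offs, v)
    })
    sample_tab <- do.call(rbind, tabs)
    got <- call_peaks(sample_tab, window_bp, min_probes, thresh)
    for (i in seq_len(n_genes)) {
      tab <- tabs[[i]]
      want <- oracle_scan(tab$offset, tab$log2_ratio, window_bp, min_probes,
                          thresh)
      have <- got[got$gene_id == sprintf("g%02d", i), , drop = FALSE]
      expect_equal(nrow(have), nrow(want))
      if (nrow(want)) {
        expect_equal(have$start + tiled_window()[1], want$start)
        expect_equal(have$end + tiled_window()[1], want$end)
        expect_equal(have$score, want$score, tolerance = 1e-12)
        expect_equal(have$n_probes, want$n_probes)
      }
    }
  }
})

test_that("FDR estimates are monotone, tie-consistent and bounded", {
  set.seed(7)
  s <- make_grid_sample(30, sites = c(rep(-1000, 10), rep(NA, 20)),
                        height = 1.5, noise_sd = 0.3)
  s <- normalize_biweight(s)
  pk <- call_peaks(s, score_threshold = 0.4, min_probes = 4)
  pk <- estimate_fdr(pk, s, n_permutations = 50, seed = 11)
  expect_true(all(pk$fdr >= 0 & pk$fdr <= 1))
  ord <- order(pk$score, decreasing = TRUE)
  expect_true(all(diff(pk$fdr[ord]) >= -1e-12))
  # equal scores get equal fdr
  dup <- rbind(pk[1, ], pk[1, ])
  dup2 <- estimate_fdr(dup, s, n_permutations = 20, seed = 3,
                       window_bp = 500, min_probes = 4,
                       score_threshold = 0.4)
  expect_equal(dup2$fdr[1], dup2$fdr[2])
  expect_error(estimate_fdr(pk, s, n_permutations = 0), ">= 1")
})

test_that("a peak above every null score reports fdr below 1/n_permutations", {
  set.seed(5)
  s <- make_grid_sample(20, sites = c(-500, rep(NA, 19)), height = 5,
                        noise_sd = 0.2)
  s <- normalize_biweight(s)
  pk <- call_peaks(s, score_threshold = 0.5, min_probes = 4)
  pk <- estimate_fdr(pk, s, n_permutations = 40, seed = 8)
  top <- pk[which.max(pk$score), ]
  expect_lt(top$fdr, 1 / 40)
})

test_that("signal-free data rarely yields discoveries at FDR 0.1", {
  # a cheap version of the null-calibration check (the full one is in the
  # acceptance suite): 20 seeds of pure-noise samples
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    s <- make_grid_sample(50, noise_sd = 0.3)
    s <- normalize_biweight(s)
    pk <- call_peaks(s)
    if (nrow(pk)) {
      pk <- estimate_fdr(pk, s, n_permutations = 50, seed = seed + 1000)
      hits <- hits + (sum(pk$fdr <= 0.1) > 0)
    }
  }
  expect_lte(hits, 2)
})

test_that("threshold calibration follows the recovery rule", {
  sets <- list("0.05" = c("a"), "0.1" = c("a", "b", "known1"),
               "0.2" = c("a", "b", "known1", "known2"))
  known <- c("known1", "known2")
  cal <- calibrate_fdr_threshold(sets, known)
  expect_equal(cal$chosen, 0.2)
  expect_equal(cal$report$n_known_recovered, c(0L, 1L, 2L))
  expect_true(all(diff(cal$report$n_targets) >= 0))

  # recovery goal below 1 picks the earliest adequate threshold
  sets2 <- list("0.05" = "k1", "0.1" = c("k1", "k2", "k3", "k4"),
                "0.2" = paste0("k", 1:5))
  cal2 <- calibrate_fdr_threshold(sets2, paste0("k", 1:5),
                                  recovery_goal = 0.8)
  expect_equal(cal2$chosen, 0.1)

  # fully recovered everywhere -> smallest threshold
  sets3 <- list("0.05" = known, "0.1" = known, "0.2" = known)
  expect_equal(calibrate_fdr_threshold(sets3, known)$chosen, 0.05)

  expect_error(calibrate_fdr_threshold(sets, character()), "empty")
  expect_warning(calibrate_fdr_threshold(list("0.1" = "x"), known),
                 "maximal recovery")
})

test_that("calibration on planted data recovers the strong-target list", {
  p <- sim_params(n_genes = 150)
  u <- simulate_universe(p, 1)
  tr <- simulate_truth(p, u, 2)
  s <- split_by_sample(simulate_chip_signals(tr, p, 3))[["Sirt6|WT|15"]]
  s <- normalize_biweight(s)
  pk <- estimate_fdr(call_peaks(s), s, n_permutations = 60, seed = 4)
  thresholds <- c(0.05, 0.1, 0.2)
  sets <- lapply(thresholds, function(th)
    peaks_to_genes(pk, u, th, factor = "Sirt6", genotype = "WT",
                   timepoint = 15))
  names(sets) <- thresholds
  known <- tr$gene_id[tr$sirt6_wt[, "t15"] == 1]
  cal <- calibrate_fdr_threshold(sets, known)
  chosen_set <- sets[[as.character(cal$chosen)]]
  expect_equal(length(intersect(chosen_set$genes, known)), length(known))
})
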