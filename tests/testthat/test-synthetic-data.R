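# The synthetic-data generator: determinism, planted-parameter recovery,
# boundary behaviour, and the signal model contracts.

test_that("parameter validation catches impossible settings", {
  expect_error(sim_params(frac_shared = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(noise_sd = 0), "noise_sd")
  expect_error(sim_params(class_proportions = c(AllUp = 1, TNFUp = 0.5,
                                                ZeroUp = 0, Inverse = 0,
                                                RelABlockedSirt6 = 0,
                                                Neutral = 0)), "sum to 1")
  # shared set cannot exceed the Sirt6 target budget
  expect_error(sim_params(frac_shared = 1, frac_rela_targets = 0.5,
                          frac_sirt6_targets = 0.2), "inconsistent")
})

test_that("universe simulation is deterministic with non-overlapping windows", {
  p <- sim_params(n_genes = 10)
  u1 <- simulate_universe(p, 1)
  u2 <- simulate_universe(p, 1)
  expect_identical(u1, u2)
  expect_equal(nrow(u1), 10)
  expect_false(anyDuplicated(u1$gene_id) > 0)
  expect_true(all(diff(u1$tss) > 2 * 4000 + diff(tiled_window())))
  expect_equal(nrow(simulate_universe(sim_params(n_genes = 0), 1)), 0)
})

test_that("simulation is bitwise deterministic given (params, seed)", {
  p <- sim_params(n_genes = 40)
  u <- simulate_universe(p, 1)
  t1 <- simulate_truth(p, u, 9); t2 <- simulate_truth(p, u, 9)
  expect_identical(t1, t2)
  expect_identical(simulate_chip_signals(t1, p, 5),
                   simulate_chip_signals(t2, p, 5))
  expect_identical(simulate_expression(t1, p, 6),
                   simulate_expression(t2, p, 6))
})

test_that("planted fractions are realized within binomial sampling error", {
  p <- sim_params(n_genes = 5000)
  u <- simulate_universe(p, 1)
  se <- function(f, n) sqrt(f * (1 - f) / n)
  for (seed in 1:20) {
    tr <- simulate_truth(p, u, seed)
    n_rela <- sum(tr$rela_target)
    f_shared <- sum(tr$shared) / n_rela
    expect_lt(abs(f_shared - p$frac_shared), 3 * se(p$frac_shared, n_rela))
    f_dep <- mean(tr$dependence[tr$shared] == "abrogated")
    expect_lt(abs(f_dep - p$frac_rela_dependent),
              3 * se(p$frac_rela_dependent, sum(tr$shared)) + 1e-9)
    f_500 <- mean(tr$pair_distance[tr$shared] < 500)
    expect_lt(abs(f_500 - p$frac_within_500bp),
              3 * se(p$frac_within_500bp, sum(tr$shared)) + 1e-9)
    base <- rowSums(tr$sirt6_wt[tr$sirt6_target, , drop = FALSE][, 1,
                                                                 drop = FALSE])
    f_base <- mean(base == 1)
    expect_lt(abs(f_base - p$frac_sirt6_baseline),
              3 * se(p$frac_sirt6_baseline, sum(tr$sirt6_target)) + 1e-9)
  }
})

test_that("dependence boundaries behave as planted", {
  p1 <- sim_params(n_genes = 500, frac_rela_dependent = 1)
  u <- simulate_universe(p1, 1)
  tr <- simulate_truth(p1, u, 3)
  expect_true(all(rowSums(tr$sirt6_relako[tr$shared, , drop = FALSE]) == 0))

  p2 <- sim_params(n_genes = 500, frac_vacated = 0)
  tr2 <- simulate_truth(p2, u, 3)
  base <- tr2$sirt6_wt[, 1] == 1
  expect_true(all(rowSums(tr2$sirt6_wt[base, 2:4, drop = FALSE]) >= 1))

  # the reduced class is bound at strictly fewer timepoints, never zero
  p3 <- sim_params(n_genes = 2000)
  tr3 <- simulate_truth(p3, u <- simulate_universe(p3, 1), 4)
  red <- which(tr3$dependence == "reduced")
  expect_true(all(rowSums(tr3$sirt6_relako[red, , drop = FALSE]) >= 1))
  expect_true(all(rowSums(tr3$sirt6_relako[red, , drop = FALSE]) <
                    rowSums(tr3$sirt6_wt[red, , drop = FALSE])))
})

test_that("chip signal carries the planted kernel and clean controls", {
  p <- sim_params(n_genes = 60, noise_sd = 1e-9)
  u <- simulate_universe(p, 1)
  tr <- simulate_truth(p, u, 2)
  probes <- simulate_chip_signals(tr, p, 3)
  s <- split_by_sample(probes)[["Sirt6|WT|15"]]
  bound <- which(tr$sirt6_wt[, "t15"] == 1)
  g <- tr$gene_id[bound[1]]
  site <- tr$sirt6_site[bound[1]]
  apex <- s$log2_ratio[s$gene_id == g & s$offset == site]
  expect_equal(apex, p$peak_height, tolerance = 1e-6)

  # unbound gene: pure noise
  ub <- tr$gene_id[which(tr$sirt6_wt[, "t15"] == 0)[1]]
  expect_lt(max(abs(s$log2_ratio[s$gene_id == ub])), 1e-6)

  # knockout-control sample indistinguishable from the noise distribution
  p2 <- sim_params(n_genes = 200)
  tr2 <- simulate_truth(p2, simulate_universe(p2, 1), 2)
  ctrl <- split_by_sample(simulate_chip_signals(tr2, p2, 7))[["Sirt6|Sirt6KO|15"]]
  ks <- suppressWarnings(stats::ks.test(ctrl$log2_ratio, "pnorm", 0,
                                        p2$noise_sd))
  expect_gt(ks$p.value, 0.01)
})

test_that("bound windows carry more signal than unbound windows", {
  p <- sim_params(n_genes = 300)
  tr <- simulate_truth(p, simulate_universe(p, 1), 2)
  s <- split_by_sample(simulate_chip_signals(tr, p, 3))[["Sirt6|WT|15"]]
  bound_genes <- tr$gene_id[tr$sirt6_wt[, "t15"] == 1]
  m <- tapply(s$log2_ratio, s$gene_id, mean)
  tt <- stats::t.test(m[names(m) %in% bound_genes],
                      m[!(names(m) %in% bound_genes)],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("expression templates are exact in the noise-free limit", {
  p <- sim_params(n_genes = 400, expr_noise_sdlog = 1e-12,
                  frac_expressed = 1)
  tr <- simulate_truth(p, simulate_universe(p, 1), 2)
  expr <- simulate_expression(tr, p, 3)
  fold <- normalize_to_reference(expr)
  g_all <- tr$gene_id[which(tr$epistasis_class == "AllUp")[1]]
  f <- fold[fold$gene_id == g_all, ]
  get <- function(gt, tp) f$foldchange[f$genotype == gt & f$timepoint == tp]
  expect_equal(get("WT", 0), 1)
  expect_equal(get("Sirt6KO", 0), p$effect_size, tolerance = 1e-6)
  expect_equal(get("Sirt6KO", 90), p$effect_size * get("WT", 90),
               tolerance = 1e-6)
  expect_equal(get("DKO", 0), 1, tolerance = 1e-6)
  expect_equal(get("DKO", 90), get("WT", 90), tolerance = 1e-6)
})

test_that("planted sub-floor fraction matches the detection filter", {
  p <- sim_params(n_genes = 4000, frac_expressed = 0.75)
  tr <- simulate_truth(p, simulate_universe(p, 1), 2)
  expr <- simulate_expression(tr, p, 3)
  kept <- filter_expressed(expr, p$detection_floor)
  frac <- length(unique(kept$gene_id)) / length(unique(expr$gene_id))
  n <- length(unique(expr$gene_id))
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / n) + 1e-9)
})
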