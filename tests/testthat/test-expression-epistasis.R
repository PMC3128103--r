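# Detection filtering, fold-change normalization, the epistasis rules and
# descriptive clustering.

expr_row <- function(gene, gt, tp, det)
  data.frame(gene_id = gene, genotype = gt, timepoint = tp, detection = det)

test_that("detection filter keeps genes reaching the floor in any sample", {
  tab <- rbind(expr_row("low", "WT", c(0, 90), c(50, 50)),
               expr_row("edge", "WT", c(0, 90), c(40, 100)),
               expr_row("high", "WT", c(0, 90), c(500, 900)))
  kept <- unique(filter_expressed(tab, 100)$gene_id)
  expect_setequal(kept, c("edge", "high"))   # >= is inclusive
})

test_that("reference normalization is exact, scale-free and guarded", {
  tab <- rbind(expr_row("g", "WT", c(0, 90), c(200, 200)),
               expr_row("g", "Sirt6KO", c(0, 90), c(400, 200)),
               expr_row("g", "DKO", c(0, 90), c(200, 200)))
  f <- normalize_to_reference(tab)
  expect_equal(f$foldchange[f$genotype == "WT" & f$timepoint == 0], 1)
  expect_equal(f$foldchange[f$genotype == "Sirt6KO" & f$timepoint == 0], 2)
  # constant gene -> all ones
  expect_true(all(f$foldchange[f$genotype != "Sirt6KO"] == 1))
  # doubling every detection changes nothing
  tab2 <- transform(tab, detection = detection * 2)
  expect_equal(normalize_to_reference(tab2)$foldchange, f$foldchange)
  # non-positive reference drops the gene with a message
  bad <- transform(tab, gene_id = "g2",
                   detection = ifelse(genotype == "WT" & timepoint == 0,
                                      0, detection))
  expect_message(out <- normalize_to_reference(rbind(tab, bad)), "dropped")
  expect_false("g2" %in% out$gene_id)
})

test_that("epistasis rules reproduce the worked class examples", {
  rules <- epistasis_rules(1.5)
  expect_equal(classify_epistasis(fold_matrix(c(1, 1), c(2, 2), c(1, 1)),
                                  rules)$label, "AllUp")
  expect_equal(classify_epistasis(fold_matrix(c(1, 3), c(1, 6), c(1, 3)),
                                  rules)$label, "TNFUp")
  expect_equal(classify_epistasis(fold_matrix(c(1, 1), c(2, 1), c(1, 1)),
                                  rules)$label, "ZeroUp")
  inv <- classify_epistasis(fold_matrix(c(1, 0.6), c(0.4, 0.1),
                                        c(0.4, 1.5)), rules)
  expect_equal(inv$label, "Inverse")
  expect_false(inv$antagonistic)
  blocked <- classify_epistasis(fold_matrix(c(1, 1), c(2, 1), c(2, 1)),
                                rules)
  expect_equal(blocked$label, "RelABlockedSirt6")
  neutral <- classify_epistasis(fold_matrix(c(1, 2), c(1, 2), c(1, 2)),
                                rules)
  expect_equal(neutral$label, "Unclassified")
  expect_true(classify_epistasis(fold_matrix(c(1, 1), c(2, 2), c(1, 1)),
                                 rules)$antagonistic)

  expect_error(classify_epistasis(fold_matrix(c(1, 1), c(2, 2),
                                              c(1, 1))[1:2, ]), "DKO")
  m <- fold_matrix(c(1, 1), c(2, 2), c(1, 1), tps = c(15, 90))
  expect_error(classify_epistasis(m), "including 0")
  expect_error(epistasis_rules(0.9), "up_fold")
})

test_that("classification is total, exclusive and scale invariant", {
  set.seed(11)
  labs <- c("AllUp", "TNFUp", "ZeroUp", "Inverse", "RelABlockedSirt6",
            "Unclassified")
  for (i in 1:300) {
    n_tp <- sample(2:4, 1)
    tps <- c(0, sort(sample(c(15, 30, 60, 90), n_tp - 1)))
    m <- matrix(exp(rnorm(3 * n_tp, 0, 1)), 3,
                dimnames = list(c("WT", "Sirt6KO", "DKO"), tps))
    cl <- classify_epistasis(m)
    expect_true(cl$label %in% labs)
    expect_identical(cl$antagonistic,
                     cl$label %in% c("AllUp", "TNFUp", "ZeroUp"))
    # multiplying all of a gene's values by a constant changes nothing
    cl2 <- classify_epistasis(m * runif(1, 0.1, 10))
    expect_identical(cl2$label, cl$label)
  }
})

test_that("noise-free planted classes are recovered perfectly", {
  p <- sim_params(n_genes = 600, expr_noise_sdlog = 1e-12,
                  frac_expressed = 1)
  tr <- simulate_truth(p, simulate_universe(p, 1), 2)
  fold <- normalize_to_reference(
    filter_expressed(simulate_expression(tr, p, 3), p$detection_floor))
  calls <- classify_epistasis_table(fold)
  planted <- tr$epistasis_class[match(calls$gene_id, tr$gene_id)]
  planted[planted == "Neutral"] <- "Unclassified"
  expect_equal(mean(calls$label == planted), 1)
})

test_that("class counting is exhaustive and flags antagonistic totals", {
  empty <- count_classes(data.frame(gene_id = character(),
                                    label = character()))
  expect_true(all(empty$counts == 0))
  expect_equal(empty$antagonistic, 0)
  calls <- data.frame(gene_id = paste0("g", 1:5),
                      label = c("AllUp", "AllUp", "AllUp", "Inverse",
                                "Inverse"))
  cc <- count_classes(calls)
  expect_equal(cc$antagonistic, 3)
  expect_equal(sum(cc$counts), 5)
})

test_that("hierarchical clustering is deterministic and separates groups", {
  base1 <- c(1, 2, 3, 4, 5, 6)
  base2 <- c(6, 5, 4, 3, 2, 1)
  m <- rbind(a = base1 + 0.01, b = base1, c = base2, d = base2 + 0.02)
  hc <- hierarchical_cluster(m)
  grp <- stats::cutree(hc$hclust, 2)
  expect_equal(grp[["a"]], grp[["b"]])
  expect_equal(grp[["c"]], grp[["d"]])
  expect_false(grp[["a"]] == grp[["c"]])

  # identical rows merge first at height 0
  m2 <- rbind(x = base1, y = base1, z = base2)
  hc2 <- hierarchical_cluster(m2)
  expect_equal(hc2$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(abs(hc2$hclust$merge[1, ]), c(1, 2))

  # permuting rows leaves the merge heights unchanged
  perm <- c(3, 1, 4, 2)
  hc3 <- hierarchical_cluster(m[perm, ])
  expect_equal(sort(hc3$hclust$height), sort(hc$hclust$height),
               tolerance = 1e-12)

  # constant rows get unit distance, with a message
  m4 <- rbind(u = rep(1, 6), v = base1, w = base2)
  expect_message(hc4 <- hierarchical_cluster(m4), "constant")
  expect_true(all(is.finite(hc4$hclust$height)))

  expect_error(hierarchical_cluster(m[1, , drop = FALSE]), ">= 2 rows")
})
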