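# End-to-end pipeline on simulated data, plus recovery metrics against the
# planted ground truth. This is the harness used for benchmarking and
# acceptance checks; each stage is also usable on its own with real
# probe-level tables.

#' Run the full analysis pipeline on a simulated dataset
#'
#' Simulates a promoter universe, ground truth, probe-level ChIP signal and
#' expression, then runs every analysis stage: biweight normalization, peak
#' calling, permutation FDR, gene-level target mapping with knockout-control
#' subtraction, per-factor unions, occupancy matrix, dynamics labels,
#' co-occupancy overlap, site distances, RelA-dependence classification,
#' expression filtering/normalization/epistasis classification, and gene-set
#' enrichment against a small simulated motif-module collection (one module
#' is the planted RelA target set; the rest are random).
#'
#' @param params [sim_params()] list.
#' @param config configuration list from [default_config()]/[load_config()].
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @return list with the simulated inputs, every intermediate stage, and a
#'   \code{metrics} list of recovery statistics (see
#'   [evaluate_recovery()]).
#' @export
run_pipeline <- function(params = sim_params(), config = default_config(),
                         seed = 1) {
  universe <- simulate_universe(params, seed)
  truth <- simulate_truth(params, universe, seed + 1L)
  probes <- simulate_chip_signals(truth, params, seed + 2L)
  expr <- simulate_expression(truth, params, seed + 3L)

  samples <- split_by_sample(probes)
  peaks <- vector("list", length(samples))
  names(peaks) <- names(samples)
  for (i in seq_along(samples)) {
    s <- normalize_biweight(samples[[i]])
    pk <- call_peaks(s, window_bp = config$window_bp,
                     min_probes = config$min_probes,
                     score_threshold = config$score_threshold,
                     window = params$window)
    peaks[[i]] <- estimate_fdr(pk, s, n_permutations = config$n_permutations,
                               seed = seed + 100L + i)
  }

  fdr_for <- function(fac) {
    if (fac == "Sirt6") config$fdr_threshold_sirt6 else config$fdr_threshold_rela
  }
  tset <- function(fac, gt, tp) {
    key <- paste(fac, gt, tp, sep = "|")
    peaks_to_genes(peaks[[key]], universe, fdr_for(fac),
                   flank_bp = config$flank_bp, factor = fac, genotype = gt,
                   timepoint = tp, window = params$window)
  }

  sirt6_tp <- .chip_timepoints$Sirt6
  rela_tp <- .chip_timepoints$RelA
  sets <- list()
  for (tp in sirt6_tp) {
    ko <- tset("Sirt6", "Sirt6KO", tp)
    sets[[paste("Sirt6", "WT", tp, sep = "|")]] <-
      subtract_knockout_control(tset("Sirt6", "WT", tp), ko)
    sets[[paste("Sirt6", "RelAKO", tp, sep = "|")]] <-
      subtract_knockout_control(tset("Sirt6", "RelAKO", tp), ko)
  }
  for (tp in rela_tp) {
    sets[[paste("RelA", "WT", tp, sep = "|")]] <-
      subtract_knockout_control(tset("RelA", "WT", tp),
                                tset("RelA", "RelAKO", tp))
  }

  sirt6_union <- union_over_timepoints(
    sets[paste("Sirt6", "WT", sirt6_tp, sep = "|")])
  sirt6_relako_union <- union_over_timepoints(
    sets[paste("Sirt6", "RelAKO", sirt6_tp, sep = "|")])
  rela_union <- union_over_timepoints(
    sets[paste("RelA", "WT", rela_tp, sep = "|")])

  occ <- build_occupancy_matrix(sets, universe)
  occ_s6_wt <- occ[, paste("Sirt6", "WT", sirt6_tp, sep = "|"), drop = FALSE]
  occ_s6_ko <- occ[, paste("Sirt6", "RelAKO", sirt6_tp, sep = "|"),
                   drop = FALSE]
  dyn <- dynamics_labels(occ_s6_wt)

  shared_genes <- intersect(sirt6_union$genes, rela_union$genes)
  overlap <- overlap_hypergeometric(sirt6_union$genes, rela_union$genes,
                                    universe)

  pass <- function(fac, keys) {
    do.call(rbind, lapply(keys, function(k) {
      p <- peaks[[k]]
      p[p$fdr <= fdr_for(fac), , drop = FALSE]
    }))
  }
  s6_peaks <- pass("Sirt6", paste("Sirt6", "WT", sirt6_tp, sep = "|"))
  ra_peaks <- pass("RelA", paste("RelA", "WT", rela_tp, sep = "|"))
  dist_sum <- site_distance_summary(s6_peaks, ra_peaks, shared_genes,
                                    threshold = 500)

  dep_genes <- shared_genes[rowSums(occ_s6_wt[shared_genes, , drop = FALSE]) > 0]
  dep <- rela_dependence_table(occ_s6_wt[dep_genes, , drop = FALSE],
                               occ_s6_ko[dep_genes, , drop = FALSE])

  expressed <- filter_expressed(expr, config$detection_floor)
  fold <- normalize_to_reference(expressed)
  rules <- epistasis_rules(config$up_fold, config$down_fold)
  calls <- if (nrow(fold)) classify_epistasis_table(fold, rules) else NULL
  class_counts <- if (!is.null(calls)) count_classes(calls) else NULL

  collection <- .simulated_module_collection(truth, seed + 4L)
  enr <- set_enrichment(sirt6_union$genes, collection, universe,
                        q_threshold = config$enrichment_q)

  res <- list(params = params, config = config, seed = seed,
              universe = universe, truth = truth,
              peaks = peaks, target_sets = sets,
              sirt6_union = sirt6_union, rela_union = rela_union,
              sirt6_relako_union = sirt6_relako_union,
              occupancy = occ, dynamics = dyn,
              shared_genes = shared_genes, overlap = overlap,
              distance = dist_sum, dependence = dep,
              expression = expr, foldchange = fold,
              epistasis_calls = calls, class_counts = class_counts,
              enrichment = enr)
  res$metrics <- evaluate_recovery(res)
  res
}

# A small motif-module-like collection: the planted RelA target set plus
# random modules drawn from the universe.
.simulated_module_collection <- function(truth, seed, n_random = 19) {
  .seed_if(seed)
  uni <- truth$gene_id
  sets <- list(NFKB_module = uni[truth$rela_target])
  for (i in seq_len(n_random)) {
    sets[[sprintf("random_module_%02d", i)]] <-
      sample(uni, min(length(uni), sample(50:200, 1)))
  }
  sets
}

#' Recovery metrics against the planted ground truth
#'
#' Measures how well the pipeline recovered what the generator planted:
#' \describe{
#'   \item{peak_sensitivity}{fraction of planted bound (gene, sample) sites
#'     with a passing peak (FDR <= 0.1) within one fragment width, over all
#'     non-control samples}
#'   \item{peak_fdp}{fraction of passing peaks not matching a planted site}
#'   \item{frac_shared}{recovered |Sirt6 n RelA| / |RelA| union overlap}
#'   \item{frac_abrogated}{fraction of recovered shared, WT-bound genes
#'     classified abrogated in RelA-null cells}
#'   \item{frac_within_500}{fraction of measurable shared genes with site
#'     distance < 500 bp}
#'   \item{epistasis_recovery}{fraction of classified genes whose label
#'     matches the planted class (planted Neutral counts as Unclassified)}
#' }
#'
#' @param res result list from [run_pipeline()].
#' @return named list of metrics.
#' @export
evaluate_recovery <- function(res) {
  truth <- res$truth
  params <- res$params
  fw <- params$fragment_width

  # --- peak sensitivity / false discovery proportion at FDR <= 0.1
  hits <- 0L; planted <- 0L; false_peaks <- 0L; called <- 0L
  keys <- c(paste("Sirt6", "WT", .chip_timepoints$Sirt6, sep = "|"),
            paste("RelA", "WT", .chip_timepoints$RelA, sep = "|"))
  for (key in keys) {
    f <- strsplit(key, "|", fixed = TRUE)[[1]]
    bound <- .bound_bits(truth, f[1], f[2], as.numeric(f[3]))
    site <- if (f[1] == "Sirt6") truth$sirt6_site else truth$rela_site
    site_w <- site - params$window[1]          # window coordinates
    pk <- res$peaks[[key]]
    pk <- pk[pk$fdr <= 0.1, , drop = FALSE]
    idx <- match(pk$gene_id, truth$gene_id)
    ok <- bound[idx] == 1L & !is.na(site_w[idx]) &
      pk$start < site_w[idx] + fw & pk$end > site_w[idx] - fw
    called <- called + nrow(pk)
    false_peaks <- false_peaks + sum(!ok)
    b <- which(bound == 1L & !is.na(site_w))
    planted <- planted + length(b)
    rec <- unique(pk$gene_id[ok])
    hits <- hits + length(intersect(truth$gene_id[b], rec))
  }

  # --- co-occupancy / dependence / distance recovery
  frac_shared <- if (length(res$rela_union$genes))
    length(res$shared_genes) / length(res$rela_union$genes) else NA_real_
  frac_abro <- if (nrow(res$dependence))
    mean(res$dependence$label == "abrogated") else NA_real_

  # --- epistasis class recovery (planted Neutral <-> called Unclassified)
  epi_rec <- NA_real_
  if (!is.null(res$epistasis_calls) && nrow(res$epistasis_calls)) {
    planted_cls <- truth$epistasis_class[
      match(res$epistasis_calls$gene_id, truth$gene_id)]
    planted_cls[planted_cls == "Neutral"] <- "Unclassified"
    epi_rec <- mean(res$epistasis_calls$label == planted_cls)
  }

  list(peak_sensitivity = if (planted) hits / planted else NA_real_,
       peak_fdp = if (called) false_peaks / called else 0,
       frac_shared = frac_shared,
       frac_abrogated = frac_abro,
       frac_within_500 = res$distance$frac_within,
       epistasis_recovery = epi_rec)
}
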