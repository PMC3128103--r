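# Synthetic-data generator: plants promoter binding sites, oscillatory
# occupancy, partial co-occupancy with a RelA-dependent fraction, and
# knockout epistasis classes, so that every downstream stage can be tested
# against known ground truth.

#' Simulation parameters
#'
#' Defaults reproduce the genome-wide proportions of the study system this
#' generator emulates: a Sirt6/RelA promoter time course in TNF-stimulated
#' fibroblasts. Fractions are of the stated base set (see argument docs).
#'
#' @param n_genes number of promoters in the universe.
#' @param probe_spacing probe pitch in bp (the tiling density of the array).
#' @param window tiled window offsets relative to the TSS.
#' @param frac_sirt6_targets fraction of the universe ever Sirt6-bound
#'   (union over the time course); default 5050/21249.
#' @param frac_sirt6_baseline fraction of Sirt6 targets bound before TNF;
#'   default 1899/5050.
#' @param frac_vacated fraction of baseline-bound Sirt6 targets with no
#'   post-TNF binding; default 684/1899.
#' @param frac_rela_targets fraction of the universe ever RelA-bound;
#'   default 2738/21249.
#' @param frac_rela_t0 fraction of RelA targets bound in unstimulated cells.
#' @param frac_rela_tnf fraction of RelA targets bound under TNF.
#' @param frac_shared fraction of RelA targets co-occupied by Sirt6.
#' @param frac_rela_dependent fraction of shared targets whose Sirt6 binding
#'   is completely abrogated in RelA-null cells.
#' @param frac_rela_reduced fraction of the remaining (non-abrogated) shared
#'   targets with reduced (strictly fewer bound timepoints) Sirt6 binding in
#'   RelA-null cells.
#' @param frac_within_500bp fraction of shared targets whose two binding
#'   sites lie < 500 bp apart.
#' @param peak_height enrichment bump apex, log2 units.
#' @param fragment_width chromatin fragment size in bp; the bump half-width.
#' @param noise_sd probe noise SD, log2 units (additive).
#' @param effect_size knockout expression effect, fold.
#' @param expr_noise_sdlog multiplicative (lognormal) expression noise, SD of
#'   the natural log.
#' @param detection_floor absolute detection value below which a gene counts
#'   as not expressed.
#' @param frac_expressed fraction of shared targets expressed above the
#'   detection floor.
#' @param class_proportions named proportions over epistasis classes
#'   (AllUp, TNFUp, ZeroUp, Inverse, RelABlockedSirt6, Neutral); must sum
#'   to 1.
#' @return validated parameter list of class \code{"sim_params"}.
#' @export
sim_params <- function(n_genes = 2000,
                       probe_spacing = 100,
                       window = tiled_window(),
                       frac_sirt6_targets = 5050 / 21249,
                       frac_sirt6_baseline = 1899 / 5050,
                       frac_vacated = 684 / 1899,
                       frac_rela_targets = 2738 / 21249,
                       frac_rela_t0 = 0.13,
                       frac_rela_tnf = 0.91,
                       frac_shared = 0.54,
                       frac_rela_dependent = 0.49,
                       frac_rela_reduced = 0.20,
                       frac_within_500bp = 0.65,
                       peak_height = 1.5,
                       fragment_width = 500,
                       noise_sd = 0.3,
                       effect_size = 2.0,
                       expr_noise_sdlog = 0.1,
                       detection_floor = 100,
                       frac_expressed = 0.75,
                       class_proportions = c(AllUp = 0.25, TNFUp = 0.27,
                                             ZeroUp = 0.11, Inverse = 0.10,
                                             RelABlockedSirt6 = 0.10,
                                             Neutral = 0.17)) {
  p <- as.list(environment())
  fracs <- p[grep("^frac_", names(p))]
  bad <- names(fracs)[vapply(fracs, function(x) x < 0 || x > 1, TRUE)]
  if (length(bad))
    stop("fraction parameter(s) outside [0, 1]: ", paste(bad, collapse = ", "))
  if (p$peak_height <= 0) stop("peak_height must be > 0")
  if (p$noise_sd <= 0) stop("noise_sd must be > 0")
  if (p$probe_spacing <= 0) stop("probe_spacing must be > 0")
  if (p$fragment_width <= 0) stop("fragment_width must be > 0")
  if (p$n_genes < 0) stop("n_genes must be >= 0")
  if (abs(sum(p$class_proportions) - 1) > 1e-8)
    stop("class_proportions must sum to 1")
  need <- c("AllUp", "TNFUp", "ZeroUp", "Inverse", "RelABlockedSirt6",
            "Neutral")
  if (!setequal(names(p$class_proportions), need))
    stop("class_proportions must be named over: ",
         paste(need, collapse = ", "))
  # the shared set lives inside both factors' target sets
  if (p$frac_shared * p$frac_rela_targets > p$frac_sirt6_targets + 1e-12)
    stop("inconsistent fractions: frac_shared * frac_rela_targets exceeds ",
         "frac_sirt6_targets")
  structure(p, class = "sim_params")
}

.seed_if <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Simulate the promoter universe
#'
#' TSS positions are spaced widely enough that tiled windows (and +/-4 kb
#' promoter flanks) never overlap; strands alternate.
#'
#' @param params [sim_params()] list.
#' @param seed integer seed (the layout is deterministic; accepted for
#'   interface uniformity).
#' @return promoter annotation data.frame.
#' @export
simulate_universe <- function(params, seed = NULL) {
  .seed_if(seed)
  n <- params$n_genes
  if (n == 0)
    return(promoter_annotation(character(), character(), integer(),
                               character()))
  promoter_annotation(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = "chr1",
    tss = 10000L + (seq_len(n) - 1L) * 20000L,
    strand = rep_len(c("+", "-"), n))
}

# draw k indices from pool (without replacement); k clamped to pool size
.draw <- function(pool, k) {
  k <- min(length(pool), max(0L, as.integer(round(k))))
  if (k == 0) return(integer(0))
  pool[sample.int(length(pool), k)]
}

#' Simulate ground-truth occupancy, sites and epistasis classes
#'
#' Plants, per gene: Sirt6/RelA occupancy bits per timepoint in WT, Sirt6
#' occupancy in RelA-null cells (abrogated / reduced / independent), binding
#' site offsets (with the planted within-500 bp co-occupancy fraction), and
#' an epistasis class for each shared target. The temporal template is the
#' oscillation observed under TNF: on at 15 min, mostly off at 30, rebound
#' at 60; a planted subset of baseline-bound genes vacates entirely.
#'
#' @param params [sim_params()] list.
#' @param universe promoter annotation from [simulate_universe()].
#' @param seed integer seed.
#' @return list of class \code{"promodyn_truth"}; see Details.
#' @details Fields: logical vectors \code{sirt6_target, rela_target, shared,
#'   expressed}; occupancy bit matrices \code{sirt6_wt} (4 timepoints),
#'   \code{sirt6_relako}, \code{rela_wt} (3 timepoints); integer site offsets
#'   \code{sirt6_site, rela_site} (TSS-relative, NA when unbound);
#'   \code{dependence} in \{abrogated, reduced, independent, NA\};
#'   \code{pair_distance} (bp, shared genes); \code{epistasis_class}.
#' @export
simulate_truth <- function(params, universe, seed = NULL) {
  .seed_if(seed)
  p <- params
  n <- nrow(universe)
  ids <- universe$gene_id

  n_rela <- round(p$frac_rela_targets * n)
  rela_idx <- .draw(seq_len(n), n_rela)
  shared_idx <- .draw(rela_idx, p$frac_shared * length(rela_idx))
  n_sirt6 <- round(p$frac_sirt6_targets * n)
  extra_idx <- .draw(setdiff(seq_len(n), rela_idx),
                     n_sirt6 - length(shared_idx))
  sirt6_idx <- c(shared_idx, extra_idx)

  sirt6_target <- rela_target <- shared <- logical(n)
  sirt6_target[sirt6_idx] <- TRUE
  rela_target[rela_idx] <- TRUE
  shared[shared_idx] <- TRUE

  # --- Sirt6 occupancy in WT: baseline / vacated / oscillating / induced
  tp_s <- .chip_timepoints$Sirt6
  sirt6_wt <- matrix(0L, n, 4, dimnames = list(ids, paste0("t", tp_s)))
  base_idx <- .draw(sirt6_idx, p$frac_sirt6_baseline * length(sirt6_idx))
  vac_idx <- .draw(base_idx, p$frac_vacated * length(base_idx))
  osc_idx <- setdiff(base_idx, vac_idx)
  ind_idx <- setdiff(sirt6_idx, base_idx)
  sirt6_wt[vac_idx, ] <- rep(c(1L, 0L, 0L, 0L), each = length(vac_idx))
  sirt6_wt[osc_idx, ] <- rep(c(1L, 1L, 0L, 1L), each = length(osc_idx))
  if (length(ind_idx)) {
    pat <- sample(3, length(ind_idx), replace = TRUE,
                  prob = c(0.70, 0.15, 0.15))
    pats <- rbind(c(0L, 1L, 0L, 1L),   # periodic: on at 15, off at 30, on at 60
                  c(0L, 0L, 0L, 1L),   # late recruit
                  c(0L, 1L, 1L, 1L))   # sustained
    sirt6_wt[ind_idx, ] <- pats[pat, , drop = FALSE]
  }

  # --- RelA occupancy in WT (timepoints 0, 15, 30)
  rela_wt <- matrix(0L, n, 3, dimnames = list(ids, paste0("t", .chip_timepoints$RelA)))
  t0only_idx <- .draw(rela_idx, (1 - p$frac_rela_tnf) * length(rela_idx))
  tnf_idx <- setdiff(rela_idx, t0only_idx)
  rela_wt[t0only_idx, 1] <- 1L
  if (length(tnf_idx)) {
    p0 <- max(0, (p$frac_rela_t0 - (1 - p$frac_rela_tnf)) / p$frac_rela_tnf)
    rela_wt[tnf_idx, 1] <- rbinom(length(tnf_idx), 1, p0)
    pat <- sample(3, length(tnf_idx), replace = TRUE,
                  prob = c(0.75, 0.15, 0.10))
    pats <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 1L))
    rela_wt[tnf_idx, 2:3] <- pats[pat, , drop = FALSE]
  }

  # --- RelA dependence of Sirt6 binding (shared targets)
  dependence <- rep(NA_character_, n)
  abro_idx <- .draw(shared_idx, p$frac_rela_dependent * length(shared_idx))
  rest <- setdiff(shared_idx, abro_idx)
  multi <- rest[rowSums(sirt6_wt[rest, , drop = FALSE]) >= 2]
  red_idx <- .draw(multi, p$frac_rela_reduced * length(rest))
  dependence[abro_idx] <- "abrogated"
  dependence[red_idx] <- "reduced"
  dependence[setdiff(rest, red_idx)] <- "independent"

  sirt6_relako <- sirt6_wt
  sirt6_relako[abro_idx, ] <- 0L
  for (i in red_idx) {
    bound <- which(sirt6_relako[i, ] == 1L)
    drop <- if (length(bound) > 1) sample(bound, 1) else bound
    sirt6_relako[i, drop] <- 0L
  }

  # --- binding sites; shared pairs get a planted distance dichotomy.
  # Sites sit on the probe grid, >= one fragment width inside the window so
  # the bump is fully tiled; paired distances avoid the 500 bp boundary by
  # one probe spacing on either side (the array cannot resolve 400 vs 500).
  grid <- seq(p$window[1], p$window[2], by = p$probe_spacing)
  safe <- grid[grid >= p$window[1] + p$fragment_width &
                 grid <= p$window[2] - p$fragment_width]
  sirt6_site <- rela_site <- rep(NA_integer_, n)
  sirt6_site[sirt6_idx] <- as.integer(sample(safe, length(sirt6_idx),
                                             replace = TRUE))
  solo_rela <- setdiff(rela_idx, shared_idx)
  rela_site[solo_rela] <- as.integer(sample(safe, length(solo_rela),
                                            replace = TRUE))
  pair_distance <- rep(NA_integer_, n)
  if (length(shared_idx)) {
    near_idx <- .draw(shared_idx, p$frac_within_500bp * length(shared_idx))
    far_idx <- setdiff(shared_idx, near_idx)
    d <- integer(n)
    d[near_idx] <- sample(seq(0, 400 - p$probe_spacing, p$probe_spacing),
                          length(near_idx), replace = TRUE)
    d[far_idx] <- sample(seq(500 + p$probe_spacing, 1500, p$probe_spacing),
                         length(far_idx), replace = TRUE)
    sgn <- sample(c(-1L, 1L), n, replace = TRUE)
    for (i in shared_idx) {
      cand <- sirt6_site[i] + sgn[i] * d[i]
      if (cand < min(safe) || cand > max(safe))
        cand <- sirt6_site[i] - sgn[i] * d[i]
      rela_site[i] <- as.integer(cand)
      pair_distance[i] <- abs(rela_site[i] - sirt6_site[i])
    }
  }

  # --- epistasis classes and expression detectability (shared targets)
  epi <- rep(NA_character_, n)
  if (length(shared_idx)) {
    cls <- sample(names(p$class_proportions), length(shared_idx),
                  replace = TRUE, prob = p$class_proportions)
    epi[shared_idx] <- cls
  }
  expressed <- rep(NA, n)
  expr_idx <- .draw(shared_idx, p$frac_expressed * length(shared_idx))
  expressed[shared_idx] <- FALSE
  expressed[expr_idx] <- TRUE

  structure(list(gene_id = ids, sirt6_target = sirt6_target,
                 rela_target = rela_target, shared = shared,
                 sirt6_wt = sirt6_wt, sirt6_relako = sirt6_relako,
                 rela_wt = rela_wt,
                 sirt6_site = sirt6_site, rela_site = rela_site,
                 dependence = dependence, pair_distance = pair_distance,
                 epistasis_class = epi, expressed = expressed,
                 params = p),
            class = "promodyn_truth")
}

# Triangular enrichment kernel: apex 1 at the site, zero beyond one
# fragment width.
.kernel <- function(dist_bp, fragment_width) {
  pmax(0, 1 - abs(dist_bp) / fragment_width)
}

#' Simulate probe-level ChIP signal for the full sample design
#'
#' Generates one probe table covering: Sirt6 antibody in WT (4 timepoints),
#' in Sirt6-null cells (antibody-specificity control; no planted signal) and
#' in RelA-null cells; RelA antibody in WT and RelA-null cells (3
#' timepoints). Probe values are Gaussian noise plus, for bound
#' (gene, sample) pairs, a triangular enrichment bump of the planted height
#' centered on the planted site.
#'
#' @param truth ground truth from [simulate_truth()].
#' @param params [sim_params()] list.
#' @param seed integer seed.
#' @return multi-sample probe table (data.frame).
#' @export
simulate_chip_signals <- function(truth, params, seed = NULL) {
  .seed_if(seed)
  p <- params
  grid <- seq(p$window[1], p$window[2], by = p$probe_spacing)
  n <- length(truth$gene_id)

  design <- rbind(
    expand.grid(factor = "Sirt6", genotype = c("WT", "Sirt6KO", "RelAKO"),
                timepoint = .chip_timepoints$Sirt6,
                stringsAsFactors = FALSE),
    expand.grid(factor = "RelA", genotype = c("WT", "RelAKO"),
                timepoint = .chip_timepoints$RelA,
                stringsAsFactors = FALSE))
  design <- design[order(design$factor, design$genotype, design$timepoint), ]

  gene_col <- rep(truth$gene_id, each = length(grid))
  offset_col <- rep(grid, n)
  probe_col <- paste0(gene_col, ":", offset_col)

  one_sample <- function(fac, gt, tp) {
    vals <- matrix(rnorm(n * length(grid), 0, p$noise_sd), n, length(grid))
    bound <- .bound_bits(truth, fac, gt, tp)
    site <- if (fac == "Sirt6") truth$sirt6_site else truth$rela_site
    idx <- which(bound == 1L & !is.na(site))
    if (length(idx)) {
      K <- .kernel(outer(site[idx], grid, "-"), p$fragment_width)
      vals[idx, ] <- vals[idx, ] + p$peak_height * K
    }
    data.frame(factor = fac, genotype = gt, timepoint = tp,
               probe_id = probe_col, gene_id = gene_col,
               offset = offset_col,
               log2_ratio = as.vector(t(vals)),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    one_sample(design$factor[i], design$genotype[i], design$timepoint[i])
  }))
  rownames(out) <- NULL
  out
}

# Planted occupancy bit for (factor, genotype, timepoint). Knockout-control
# samples (antibody against the deleted protein) carry no signal.
.bound_bits <- function(truth, fac, gt, tp) {
  if (fac == "Sirt6") {
    if (gt == "Sirt6KO") return(integer(length(truth$gene_id)))
    m <- if (gt == "RelAKO") truth$sirt6_relako else truth$sirt6_wt
    m[, paste0("t", tp)]
  } else {
    if (gt == "RelAKO") return(integer(length(truth$gene_id)))
    truth$rela_wt[, paste0("t", tp)]
  }
}

# Noise-free fold-change templates per epistasis class; rows WT/Sirt6KO/DKO,
# columns t0/t90. `e` is the knockout effect size, `w` the WT TNF response.
.class_template <- function(class, e, w) {
  wt <- c(1, w)
  s6 <- switch(class,
               AllUp = c(e, e * w),
               TNFUp = c(1, e * w),
               ZeroUp = c(e, w),
               Inverse = c(1 / e, w / e),
               RelABlockedSirt6 = c(e, w),
               Neutral = c(1, w))
  dk <- switch(class,
               Inverse = c(e, e * w),
               RelABlockedSirt6 = c(e, w),
               c(1, w))
  rbind(WT = wt, Sirt6KO = s6, DKO = dk)
}

#' Simulate genotype-by-time expression detection values
#'
#' Generates detection values for every shared (co-bound) target over
#' genotypes \{WT, Sirt6KO, DKO\} and timepoints \{0, 90\} minutes. Each
#' gene follows its planted epistasis-class template scaled by a per-gene
#' base detection level and WT TNF-response fold, with multiplicative
#' lognormal noise; a planted fraction of genes stays below the detection
#' floor (flat low signal).
#'
#' @param truth ground truth from [simulate_truth()].
#' @param params [sim_params()] list.
#' @param seed integer seed.
#' @return long data.frame \code{gene_id, genotype, timepoint, detection}.
#' @export
simulate_expression <- function(truth, params, seed = NULL) {
  .seed_if(seed)
  p <- params
  idx <- which(truth$shared)
  if (!length(idx))
    return(data.frame(gene_id = character(), genotype = character(),
                      timepoint = numeric(), detection = numeric()))
  rows <- lapply(idx, function(i) {
    if (isTRUE(truth$expressed[i])) {
      b <- p$detection_floor * runif(1, 2, 50)
      w <- rlnorm(1, log(2), 0.4)
      tmpl <- .class_template(truth$epistasis_class[i], p$effect_size, w)
    } else {
      b <- p$detection_floor * runif(1, 0.05, 0.5)
      tmpl <- matrix(1, 3, 2, dimnames = list(.expr_genotypes, NULL))
    }
    noise <- matrix(rlnorm(6, 0, p$expr_noise_sdlog), 3, 2)
    det <- b * tmpl * noise
    data.frame(gene_id = truth$gene_id[i],
               genotype = rep(rownames(tmpl), 2),
               timepoint = rep(.expr_timepoints, each = 3),
               detection = as.vector(det),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
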