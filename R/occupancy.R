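# Occupancy analysis: the genes x samples binary occupancy matrix, temporal
# dynamics classes, co-occupancy statistics (hypergeometric overlap in log
# space, binding-site distances) and the RelA-dependence classification of
# Sirt6 binding.

#' Build a binary occupancy matrix
#'
#' @param target_sets list of [target_set()] objects over one universe; the
#'   sample key of each must be unique.
#' @param universe promoter annotation table (row order of the matrix).
#' @return integer 0/1 matrix, rows = genes, columns = sample keys
#'   (\code{"factor|genotype|timepoint"}).
#' @export
build_occupancy_matrix <- function(target_sets, universe) {
  validate_annotation(universe)
  keys <- vapply(target_sets, function(s)
    paste(s$factor, s$genotype, s$timepoint, sep = "|"), "")
  if (anyDuplicated(keys))
    stop("duplicate sample key: ", keys[which(duplicated(keys))[1]])
  occ <- matrix(0L, nrow(universe), length(target_sets),
                dimnames = list(universe$gene_id, keys))
  for (j in seq_along(target_sets)) {
    g <- target_sets[[j]]$genes
    unknown <- setdiff(g, universe$gene_id)
    if (length(unknown))
      stop("target set ", keys[j], " contains genes outside the universe: ",
           unknown[1])
    occ[g, j] <- 1L
  }
  occ
}

#' Classify the temporal occupancy pattern of one gene
#'
#' Labels a 4-bit occupancy vector over timepoints (0, 15, 30, 60 min):
#' \describe{
#'   \item{unbound}{never bound}
#'   \item{constitutive}{bound at all four timepoints}
#'   \item{periodic}{on at 15, off at 30, back on at 60 (the oscillation),
#'     regardless of the baseline bit}
#'   \item{baseline_vacated}{bound only before stimulation}
#'   \item{induced}{unbound at baseline, bound at >= 1 later timepoint}
#'   \item{other}{any remaining pattern}
#' }
#' Precedence: unbound > constitutive > periodic > baseline_vacated >
#' induced > other; every 4-bit pattern maps to exactly one label.
#'
#' @param bits integer/logical vector of exactly 4 occupancy bits
#'   (t = 0, 15, 30, 60).
#' @return single character label.
#' @export
classify_dynamics <- function(bits) {
  if (length(bits) != 4) stop("expected exactly 4 occupancy bits")
  b <- as.integer(bits)
  if (!all(b %in% c(0L, 1L))) stop("occupancy bits must be 0/1")
  if (all(b == 0L)) return("unbound")
  if (all(b == 1L)) return("constitutive")
  if (b[2] == 1L && b[3] == 0L && b[4] == 1L) return("periodic")
  if (b[1] == 1L && all(b[2:4] == 0L)) return("baseline_vacated")
  if (b[1] == 0L && any(b[2:4] == 1L)) return("induced")
  "other"
}

#' @rdname classify_dynamics
#' @param occ occupancy matrix (genes x 4 timepoints).
#' @return `dynamics_labels`: named character vector, one label per row.
#' @export
dynamics_labels <- function(occ) {
  stopifnot(ncol(occ) == 4)
  setNames(apply(occ, 1, classify_dynamics), rownames(occ))
}

#' Upper-tail hypergeometric overlap test
#'
#' Tests whether two target sets share more genes than expected from random
#' draws out of the promoter universe: with \code{N} universe genes,
#' \code{K = |A|}, \code{n = |B|} and overlap \code{k}, computes
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)} in log space, so
#' overlaps far below double precision (p < 1e-300) stay representable.
#'
#' @param set_a,set_b character vectors of gene ids (subsets of the
#'   universe).
#' @param universe promoter annotation table or character vector of gene
#'   ids.
#' @return list with counts \code{universe_n, set_a_n, set_b_n, overlap_k},
#'   \code{log10_p}, and overlap fractions \code{frac_of_a},
#'   \code{frac_of_b}.
#' @export
overlap_hypergeometric <- function(set_a, set_b, universe) {
  uni <- if (is.data.frame(universe)) universe$gene_id else universe
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, uni)) || length(setdiff(set_b, uni)))
    stop("both sets must be subsets of the universe")
  N <- length(uni); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  log10_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                    log.p = TRUE) / log(10)
  list(universe_n = N, set_a_n = K, set_b_n = n, overlap_k = k,
       log10_p = log10_p,
       frac_of_a = if (K > 0) k / K else NA_real_,
       frac_of_b = if (n > 0) k / n else NA_real_)
}

#' Overlap percentage with the reporting rounding rule
#'
#' \code{100 * k / n}, rounded to the nearest integer when >= 20 percent
#' and to one decimal below 20 percent.
#'
#' @param overlap_k overlap count.
#' @param set_n set size (> 0, >= overlap_k).
#' @return rounded percentage.
#' @export
overlap_fraction <- function(overlap_k, set_n) {
  if (set_n <= 0) stop("set_n must be positive")
  if (overlap_k > set_n) stop("overlap_k cannot exceed set_n")
  pct <- 100 * overlap_k / set_n
  if (pct >= 20) round(pct) else round(pct, 1)
}

#' Distance between two factors' binding sites at one gene
#'
#' Minimum over peak pairs of the absolute difference of peak centers
#' (\code{floor((start + end) / 2)}); both peak tables must be in the same
#' (window) coordinate system.
#'
#' @param gene gene id.
#' @param peaks_a,peaks_b peak tables (already filtered to passing peaks)
#'   for the two factors.
#' @return distance in bp, or \code{NA} if either factor lacks a peak at
#'   the gene.
#' @export
site_distance <- function(gene, peaks_a, peaks_b) {
  ca <- .peak_centers(peaks_a, gene)
  cb <- .peak_centers(peaks_b, gene)
  if (!length(ca) || !length(cb)) return(NA_integer_)
  min(abs(outer(ca, cb, "-")))
}

.peak_centers <- function(peaks, gene) {
  p <- peaks[peaks$gene_id == gene, , drop = FALSE]
  if (nrow(p) == 0) return(integer(0))
  as.integer(floor((p$start + p$end) / 2))
}

#' Site-distance summary over shared targets
#'
#' Computes [site_distance()] for every gene in \code{genes} and the
#' fraction of measurable genes with distance strictly below
#' \code{threshold} (the fragment-size resolution limit). Genes missing a
#' peak for either factor are skipped and counted.
#'
#' @param peaks_a,peaks_b passing peak tables for the two factors.
#' @param genes shared target gene ids.
#' @param threshold distance cutoff in bp.
#' @return list with \code{distances} (named vector), \code{frac_within},
#'   \code{n_skipped}.
#' @export
site_distance_summary <- function(peaks_a, peaks_b, genes,
                                  threshold = 500) {
  d <- vapply(genes, site_distance, NA_integer_,
              peaks_a = peaks_a, peaks_b = peaks_b)
  n_skip <- sum(is.na(d))
  if (n_skip)
    message(n_skip, " gene(s) lacked peaks for one factor and were skipped")
  meas <- d[!is.na(d)]
  list(distances = meas,
       frac_within = if (length(meas)) mean(meas < threshold) else NA_real_,
       n_skipped = n_skip)
}

#' Classify RelA dependence of Sirt6 binding at one gene
#'
#' Compares Sirt6 occupancy bits over the time course in wild-type versus
#' RelA-null cells. Occupancy is binary (score magnitudes are not compared
#' across genotypes), so dependence is defined by bound-timepoint counts:
#' \describe{
#'   \item{abrogated}{no binding at any timepoint in the knockout}
#'   \item{reduced}{bound, but at strictly fewer timepoints than wild-type}
#'   \item{independent}{bound at as many or more timepoints}
#' }
#'
#' @param wt_bits,ko_bits occupancy bits over the same timepoints; the gene
#'   must be bound somewhere in wild-type.
#' @return label in \code{c("abrogated", "reduced", "independent")}.
#' @export
classify_rela_dependence <- function(wt_bits, ko_bits) {
  if (length(wt_bits) != length(ko_bits))
    stop("wild-type and knockout bit vectors differ in length")
  nw <- sum(as.integer(wt_bits)); nk <- sum(as.integer(ko_bits))
  if (nw == 0)
    stop("gene is unbound in wild-type; dependence is undefined")
  if (nk == 0) return("abrogated")
  if (nk < nw) return("reduced")
  "independent"
}

#' @rdname classify_rela_dependence
#' @param occ_wt,occ_ko occupancy matrices (genes x timepoints) for
#'   wild-type and knockout; rows with no wild-type binding are dropped.
#' @return `rela_dependence_table`: data.frame \code{gene_id, label}.
#' @export
rela_dependence_table <- function(occ_wt, occ_ko) {
  stopifnot(identical(dim(occ_wt), dim(occ_ko)),
            identical(rownames(occ_wt), rownames(occ_ko)))
  bound <- rowSums(occ_wt) > 0
  genes <- rownames(occ_wt)[bound]
  lab <- vapply(genes, function(g)
    classify_rela_dependence(occ_wt[g, ], occ_ko[g, ]), "")
  data.frame(gene_id = genes, label = lab, row.names = NULL,
             stringsAsFactors = FALSE)
}
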