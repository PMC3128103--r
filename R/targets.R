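# Gene-level target mapping: significant peaks are intersected with
# promoter flanks, knockout-control targets are subtracted (antibody
# specificity), and per-timepoint sets are unioned into per-factor target
# universes.

#' Map significant peaks to gene-level targets
#'
#' A gene is a target iff at least one of its peaks has
#' \code{fdr <= fdr_threshold} (inclusive) and the peak's genomic span
#' intersects the promoter flank \code{[tss - flank_bp, tss + flank_bp)}
#' (half-open; a 1-bp overlap suffices).
#'
#' @param peaks peak table with \code{fdr} filled.
#' @param annotations promoter annotation table.
#' @param fdr_threshold inclusive FDR cutoff.
#' @param flank_bp promoter half-width in bp.
#' @param factor,genotype,timepoint sample key recorded on the returned set.
#' @param window tiled window offsets used when the peaks were called.
#' @return a [target_set()].
#' @export
peaks_to_genes <- function(peaks, annotations, fdr_threshold,
                           flank_bp = 4000, factor, genotype, timepoint,
                           window = tiled_window()) {
  validate_annotation(annotations)
  if (nrow(peaks) == 0)
    return(target_set(character(), factor, genotype, timepoint))
  if (anyNA(peaks$fdr))
    stop("peaks must carry fdr; run estimate_fdr() first")
  idx <- match(peaks$gene_id, annotations$gene_id)
  if (anyNA(idx))
    stop("peak references unknown gene_id: ",
         peaks$gene_id[which(is.na(idx))[1]])
  ann <- annotations[idx, ]
  span <- peak_genomic_span(peaks$start, peaks$end, ann$tss, ann$strand,
                            window)
  hit <- peaks$fdr <= fdr_threshold &
    span$start < ann$tss + flank_bp &
    span$end > ann$tss - flank_bp
  target_set(unique(peaks$gene_id[hit]), factor, genotype, timepoint)
}

#' Subtract knockout-control targets
#'
#' Removes genes also called in cells lacking the immunoprecipitated
#' protein (nonspecific antibody signal). Both sets must come from the same
#' factor and timepoint.
#'
#' @param wt wild-type [target_set()].
#' @param ko knockout-control [target_set()] (same factor and timepoint).
#' @return [target_set()] with \code{wt} genes not in \code{ko}.
#' @export
subtract_knockout_control <- function(wt, ko) {
  if (!identical(wt$factor, ko$factor))
    stop("control subtraction requires matching factors (",
         wt$factor, " vs ", ko$factor, ")")
  if (!identical(wt$timepoint, ko$timepoint))
    stop("control subtraction requires matching timepoints (",
         wt$timepoint, " vs ", ko$timepoint, ")")
  target_set(setdiff(wt$genes, ko$genes), wt$factor, wt$genotype,
             wt$timepoint)
}

#' Union target sets across the time course
#'
#' The per-factor target universe: genes bound at one or more timepoints.
#'
#' @param sets non-empty list of [target_set()] objects sharing factor and
#'   genotype.
#' @return [target_set()] with \code{timepoint = "any"}.
#' @export
union_over_timepoints <- function(sets) {
  if (length(sets) == 0) stop("union over an empty set collection")
  fac <- unique(vapply(sets, `[[`, "", "factor"))
  gt <- unique(vapply(sets, `[[`, "", "genotype"))
  if (length(fac) != 1 || length(gt) != 1)
    stop("all sets must share factor and genotype")
  target_set(unique(unlist(lapply(sets, `[[`, "genes"))),
             fac, gt, "any")
}
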