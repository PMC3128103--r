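# Shared domain types and validators.
#
# Tables are plain data.frames throughout; target sets are a light S3 class
# carrying the sample key (assayed factor, genotype, timepoint) alongside the
# gene-id set.

# Allowed sample-design vocabulary. ChIP time courses run 0-60 min after
# TNF-alpha; the 60-min point exists only for the Sirt6 antibody (the RelA
# signal desynchronizes by then). Expression is assayed at 0 and 90 min.
.chip_factors <- c("Sirt6", "RelA")
.genotypes <- c("WT", "Sirt6KO", "RelAKO", "DKO")
.chip_timepoints <- list(Sirt6 = c(0, 15, 30, 60), RelA = c(0, 15, 30))
.expr_timepoints <- c(0, 90)
.expr_genotypes <- c("WT", "Sirt6KO", "DKO")

#' Tiled promoter window
#'
#' The array design tiles a fixed window around every TSS; offsets are
#' strand-oriented base pairs relative to the TSS (negative = upstream).
#'
#' @return integer vector \code{c(lo, hi)}, default \code{c(-3250, 750)}.
#' @export
tiled_window <- function() c(-3250L, 750L)

#' Construct/validate a promoter annotation table
#'
#' One promoter per gene: this table defines the gene universe used by all
#' set statistics downstream.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param chrom chromosome names.
#' @param tss transcription start sites (0-based, non-negative integers).
#' @param strand \code{"+"} or \code{"-"} per gene.
#' @return data.frame with columns \code{gene_id, chrom, tss, strand}.
#' @export
promoter_annotation <- function(gene_id, chrom, tss, strand) {
  ann <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    tss = as.integer(tss),
                    strand = as.character(strand),
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' @rdname promoter_annotation
#' @param ann a candidate annotation data.frame.
#' @export
validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("annotation gene_id values must be unique")
  if (any(ann$tss < 0)) stop("tss must be non-negative")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(ann)
}

#' Sample key helpers
#'
#' A ChIP sample is identified by (factor, genotype, timepoint); the key is
#' serialized as \code{"factor|genotype|timepoint"} in tables and matrix
#' column names.
#'
#' @param factor assayed factor, \code{"Sirt6"} or \code{"RelA"}.
#' @param genotype one of \code{"WT", "Sirt6KO", "RelAKO", "DKO"}.
#' @param timepoint minutes after TNF-alpha addition.
#' @return single character key.
#' @export
sample_key <- function(factor, genotype, timepoint) {
  validate_sample_key(factor, genotype, timepoint)
  paste(factor, genotype, timepoint, sep = "|")
}

#' @rdname sample_key
#' @export
validate_sample_key <- function(factor, genotype, timepoint) {
  if (!all(factor %in% .chip_factors))
    stop("unknown factor: ", paste(setdiff(factor, .chip_factors), collapse = ", "))
  if (!all(genotype %in% .genotypes))
    stop("unknown genotype: ", paste(setdiff(genotype, .genotypes), collapse = ", "))
  ok <- mapply(function(f, t) t %in% .chip_timepoints[[f]], factor, timepoint)
  if (!all(ok))
    stop("timepoint not in the allowed set for factor ",
         paste(unique(factor[!ok]), collapse = ", "))
  invisible(TRUE)
}

#' Construct a gene-level target set
#'
#' @param genes character vector of gene ids (de-duplicated).
#' @param factor,genotype assayed factor and cell genotype.
#' @param timepoint minutes, or \code{"any"} for a union over the time course.
#' @return object of class \code{"target_set"}.
#' @export
target_set <- function(genes, factor, genotype, timepoint) {
  if (!identical(timepoint, "any"))
    validate_sample_key(factor, genotype, as.numeric(timepoint))
  structure(list(genes = unique(as.character(genes)),
                 factor = factor, genotype = genotype,
                 timepoint = timepoint),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %s ChIP in %s, t=%s: %d genes\n",
              x$factor, x$genotype, as.character(x$timepoint),
              length(x$genes)))
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$genes)

#' Validate a probe-level measurement table
#'
#' Expected columns: \code{factor, genotype, timepoint, probe_id, gene_id,
#' offset, log2_ratio}. Offsets must lie inside the tiled window and ratios
#' must be finite.
#'
#' @param probes data.frame of probe measurements (one or more samples).
#' @param window tiled window, \code{c(lo, hi)}.
#' @return the table, invisibly, after validation.
#' @export
validate_probe_table <- function(probes, window = tiled_window()) {
  need <- c("factor", "genotype", "timepoint", "probe_id", "gene_id",
            "offset", "log2_ratio")
  miss <- setdiff(need, names(probes))
  if (length(miss))
    stop("probe table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(probes$offset < window[1] | probes$offset > window[2])
  if (length(bad))
    stop("offset outside tiled window [", window[1], ", ", window[2],
         "] at row ", bad[1], " (offset ", probes$offset[bad[1]], ")")
  if (any(!is.finite(probes$log2_ratio)))
    stop("non-finite log2_ratio at row ",
         which(!is.finite(probes$log2_ratio))[1])
  combos <- unique(probes[c("factor", "genotype", "timepoint")])
  validate_sample_key(combos$factor, combos$genotype, combos$timepoint)
  invisible(probes)
}

# Split a multi-sample probe table into per-sample tables keyed by sample_key.
#' Split a probe table by sample
#' @param probes validated multi-sample probe table.
#' @return named list of single-sample probe tables.
#' @export
split_by_sample <- function(probes) {
  n <- nrow(probes)
  if (n == 0) return(list())
  # samples are usually stored as contiguous row blocks; find block
  # boundaries cheaply, then group blocks sharing a key
  chg <- which(probes$factor[-1] != probes$factor[-n] |
                 probes$genotype[-1] != probes$genotype[-n] |
                 probes$timepoint[-1] != probes$timepoint[-n])
  starts <- c(1L, chg + 1L)
  ends <- c(chg, n)
  keys <- paste(probes$factor[starts], probes$genotype[starts],
                probes$timepoint[starts], sep = "|")
  out <- lapply(split(seq_along(starts), factor(keys, levels = unique(keys))),
                function(bl) {
                  idx <- unlist(lapply(bl, function(b) starts[b]:ends[b]))
                  probes[idx, , drop = FALSE]
                })
  out
}
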