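# Strand-aware conversion between tiled-window coordinates and genomic
# coordinates.
#
# Window coordinates are 0-based positions within the tiled promoter window,
# increasing 5'->3' of the gene; position 0 sits at tss + window_lo on the
# + strand and at tss - window_lo on the - strand (window_lo is negative).
# Genomic intervals follow the BED convention (0-based, half-open).

#' Convert window coordinates to genomic positions
#'
#' @param x 0-based positions within the tiled window.
#' @param tss transcription start site (0-based genomic).
#' @param strand \code{"+"} or \code{"-"}.
#' @param window tiled window as \code{c(lo, hi)} offsets relative to the TSS.
#' @return genomic positions (same length as \code{x}).
#' @export
window_to_genomic <- function(x, tss, strand, window = tiled_window()) {
  n <- max(length(x), length(tss), length(strand))
  x <- rep_len(x, n); tss <- rep_len(tss, n)
  plus <- rep_len(strand == "+", n)
  out <- numeric(n)
  out[plus] <- tss[plus] + window[1] + x[plus]
  out[!plus] <- tss[!plus] - window[1] - x[!plus]
  out
}

#' @rdname window_to_genomic
#' @param pos genomic positions to convert back to window coordinates.
#' @export
genomic_to_window <- function(pos, tss, strand, window = tiled_window()) {
  n <- max(length(pos), length(tss), length(strand))
  pos <- rep_len(pos, n); tss <- rep_len(tss, n)
  plus <- rep_len(strand == "+", n)
  out <- numeric(n)
  out[plus] <- pos[plus] - tss[plus] - window[1]
  out[!plus] <- tss[!plus] - window[1] - pos[!plus]
  out
}

# Genomic half-open span of a window-coordinate interval [start, end).
# On the - strand the interval mirrors across the TSS: increasing window
# coordinate runs toward decreasing genomic coordinate.
peak_genomic_span <- function(start, end, tss, strand,
                              window = tiled_window()) {
  gs <- window_to_genomic(start, tss, strand, window)
  ge <- window_to_genomic(end - 1L, tss, strand, window)
  data.frame(start = pmin(gs, ge), end = pmax(gs, ge) + 1L)
}
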