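# Per-sample normalization: subtract the Tukey biweight mean of the
# log2 ratios, so samples are centered robustly against outlying probes.

#' One-step Tukey biweight location
#'
#' Robust location estimate: median/MAD start, bisquare weights with tuning
#' constant \code{c}, one weighted-mean step (the microarray convention).
#' When the MAD is zero the median is returned.
#'
#' @param x numeric vector (finite values).
#' @param c tuning constant; points beyond \code{c} MADs get zero weight.
#' @param epsilon small stabilizer added to the scale.
#' @return scalar location estimate.
#' @export
tukey_biweight <- function(x, c = 9, epsilon = 1e-4) {
  m <- median(x)
  s <- median(abs(x - m))
  if (s == 0) return(m)
  u <- (x - m) / (c * s + epsilon)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Center one sample's probe signal by its biweight mean
#'
#' Subtracts the Tukey biweight location of the sample's log2 ratios from
#' every probe. If the MAD is zero (degenerate signal) the median is
#' subtracted instead, with a message; an empty sample is an error.
#'
#' @param probes single-sample probe table.
#' @param c,epsilon passed to [tukey_biweight()].
#' @return the probe table with centered \code{log2_ratio}.
#' @export
normalize_biweight <- function(probes, c = 9, epsilon = 1e-4) {
  x <- probes$log2_ratio
  if (length(x) == 0) stop("cannot normalize an empty sample")
  if (any(!is.finite(x))) stop("log2_ratio must be finite")
  if (median(abs(x - median(x))) == 0) {
    message("biweight scale is zero; falling back to median subtraction")
    loc <- median(x)
  } else {
    loc <- tukey_biweight(x, c = c, epsilon = epsilon)
  }
  probes$log2_ratio <- x - loc
  probes
}
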