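# Gene-set enrichment: upper-tail hypergeometric test of a target set
# against each set of a user-supplied collection (motif modules, functional
# sets), with Benjamini-Hochberg correction across the collection.

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each set in the collection, tests whether the target set overlaps it
#' more than random draws from the universe would
#' (\code{P(X >= k)}, upper-tail hypergeometric), then adjusts across the
#' collection by Benjamini-Hochberg. Genes in a set but absent from the
#' universe are dropped before testing, with a message.
#'
#' @param targets character vector of target gene ids (subset of the
#'   universe).
#' @param collection non-empty named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param universe promoter annotation table or gene-id vector.
#' @param q_threshold significance cutoff on the adjusted p-value.
#' @return data.frame \code{set, set_size, overlap_k, p, q, log10_p,
#'   significant}, ordered as the collection.
#' @export
set_enrichment <- function(targets, collection, universe,
                           q_threshold = 0.05) {
  if (length(collection) == 0) stop("empty gene-set collection")
  if (is.null(names(collection)) || any(!nzchar(names(collection))))
    stop("collection must be a named list")
  uni <- if (is.data.frame(universe)) universe$gene_id else universe
  targets <- unique(targets)
  if (length(setdiff(targets, uni)))
    stop("targets must be a subset of the universe")
  trimmed <- lapply(collection, function(s) intersect(unique(s), uni))
  n_drop <- sum(vapply(collection, function(s) length(unique(s)), 1L)) -
    sum(vapply(trimmed, length, 1L))
  if (n_drop)
    message(n_drop, " set gene(s) absent from the universe were dropped")
  N <- length(uni); n <- length(targets)
  K <- vapply(trimmed, length, 1L)
  k <- vapply(trimmed, function(s) length(intersect(s, targets)), 1L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  log10_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                    log.p = TRUE) / log(10)
  q <- bh_adjust(p)
  data.frame(set = names(collection), set_size = K, overlap_k = k,
             p = p, q = q, log10_p = log10_p,
             significant = q < q_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (classical FDR control across a family of
#' hypergeometric tests).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
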