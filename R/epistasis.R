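# Expression epistasis: detection filtering, normalization to the untreated
# wild-type reference, rule-based classification of genotype-by-time
# fold-change profiles into epistasis classes, and descriptive hierarchical
# clustering.

#' Epistasis rule parameters
#'
#' The class definitions state directions (elevated / repressed / reverted)
#' but no fold cutoffs; this record is the explicit home of those cutoffs.
#' Defaults use the conventional 1.5-fold array threshold.
#'
#' @param up_fold minimum knockout/wild-type ratio to count as elevated.
#' @param down_fold maximum ratio to count as repressed (default
#'   \code{1/up_fold}).
#' @return list of class \code{"epistasis_rules"}.
#' @export
epistasis_rules <- function(up_fold = 1.5, down_fold = 1 / up_fold) {
  if (!(up_fold > 1 && down_fold < 1 && down_fold > 0))
    stop("need up_fold > 1 > down_fold > 0")
  structure(list(up_fold = up_fold, down_fold = down_fold),
            class = "epistasis_rules")
}

#' Filter genes by absolute detection
#'
#' A gene is retained iff its maximum detection value over all samples is
#' at least \code{detection_floor} (inclusive).
#'
#' @param profiles long expression table (\code{gene_id, genotype,
#'   timepoint, detection}).
#' @param detection_floor detection cutoff.
#' @return the table restricted to retained genes.
#' @export
filter_expressed <- function(profiles, detection_floor = 100) {
  mx <- tapply(profiles$detection, profiles$gene_id, max)
  keep <- names(mx)[mx >= detection_floor]
  profiles[profiles$gene_id %in% keep, , drop = FALSE]
}

#' Normalize detections to the untreated wild-type sample
#'
#' Divides every detection value of a gene by that gene's (WT, t = 0)
#' detection, so the reference cell becomes exactly 1. Genes whose
#' reference is missing or non-positive are dropped with a message.
#'
#' @param profiles long expression table.
#' @return the table with a \code{foldchange} column added.
#' @export
normalize_to_reference <- function(profiles) {
  ref <- profiles[profiles$genotype == "WT" & profiles$timepoint == 0, ]
  refv <- setNames(ref$detection, ref$gene_id)
  genes <- unique(profiles$gene_id)
  ok <- genes[genes %in% names(refv) & refv[genes] > 0]
  dropped <- length(genes) - length(ok)
  if (dropped)
    message(dropped,
            " gene(s) dropped: missing or non-positive (WT, t=0) reference")
  out <- profiles[profiles$gene_id %in% ok, , drop = FALSE]
  out$foldchange <- out$detection / refv[out$gene_id]
  out
}

#' Classify one gene's epistasis pattern
#'
#' Given fold-changes for genotypes WT, Sirt6KO and DKO (double knockout)
#' over shared timepoints (t = 0 plus >= 1 stimulated timepoint), evaluates
#' per timepoint \code{t}:
#' \itemize{
#'   \item up(t): Sirt6KO(t)/WT(t) >= up_fold
#'   \item down(t): Sirt6KO(t)/WT(t) <= down_fold
#'   \item reverted(t): DKO(t)/WT(t) < up_fold
#'   \item over(t): DKO(t)/WT(t) >= up_fold
#' }
#' and assigns, with precedence AllUp > TNFUp > ZeroUp > Inverse >
#' RelABlockedSirt6 > Unclassified:
#' \describe{
#'   \item{AllUp}{up at t=0 and every stimulated timepoint, reverted at all}
#'   \item{TNFUp}{up at >= 1 stimulated timepoint but not at t=0, reverted
#'     at the elevated timepoints}
#'   \item{ZeroUp}{up at t=0 only, reverted at t=0}
#'   \item{Inverse}{down at >= 1 timepoint and over at >= 1 timepoint}
#'   \item{RelABlockedSirt6}{up somewhere and not reverted there}
#' }
#' The first three are the antagonistic classes (Sirt6 represses, RelA
#' activates); the last two are the reversed-hierarchy patterns.
#'
#' @param fold numeric matrix, rows \code{WT, Sirt6KO, DKO}, columns
#'   timepoints (numeric names, including 0).
#' @param rules an [epistasis_rules()] record.
#' @return list \code{label}, \code{antagonistic}.
#' @export
classify_epistasis <- function(fold, rules = epistasis_rules()) {
  need <- c("WT", "Sirt6KO", "DKO")
  if (!all(need %in% rownames(fold)))
    stop("fold matrix must have rows WT, Sirt6KO, DKO; missing: ",
         paste(setdiff(need, rownames(fold)), collapse = ", "))
  tp <- as.numeric(colnames(fold))
  if (anyNA(tp) || !(0 %in% tp) || length(tp) < 2)
    stop("fold matrix needs numeric timepoint columns including 0 and >= 1 ",
         "stimulated timepoint")
  if (any(!is.finite(fold)) || any(fold <= 0))
    stop("fold-changes must be finite and positive")
  i0 <- which(tp == 0)
  it <- which(tp != 0)
  r_ko <- fold["Sirt6KO", ] / fold["WT", ]
  r_dk <- fold["DKO", ] / fold["WT", ]
  up <- r_ko >= rules$up_fold
  down <- r_ko <= rules$down_fold
  rev <- r_dk < rules$up_fold
  over <- r_dk >= rules$up_fold

  label <- if (up[i0] && all(up[it]) && all(rev)) {
    "AllUp"
  } else if (any(up[it]) && !up[i0] && all(rev[it][up[it]])) {
    "TNFUp"
  } else if (up[i0] && !any(up[it]) && rev[i0]) {
    "ZeroUp"
  } else if (any(down) && any(over)) {
    "Inverse"
  } else if (any(up & !rev)) {
    "RelABlockedSirt6"
  } else {
    "Unclassified"
  }
  list(label = label,
       antagonistic = label %in% c("AllUp", "TNFUp", "ZeroUp"))
}

#' @rdname classify_epistasis
#' @param profiles long table with \code{foldchange} from
#'   [normalize_to_reference()].
#' @return `classify_epistasis_table`: data.frame \code{gene_id, label,
#'   antagonistic}.
#' @export
classify_epistasis_table <- function(profiles, rules = epistasis_rules()) {
  stopifnot("foldchange" %in% names(profiles))
  genes <- unique(profiles$gene_id)
  rows <- lapply(genes, function(g) {
    p <- profiles[profiles$gene_id == g, ]
    tps <- sort(unique(p$timepoint))
    fold <- matrix(NA_real_, 3, length(tps),
                   dimnames = list(c("WT", "Sirt6KO", "DKO"), tps))
    for (r in seq_len(nrow(p)))
      fold[p$genotype[r], as.character(p$timepoint[r])] <- p$foldchange[r]
    if (anyNA(fold))
      stop("gene ", g, " is missing genotype/timepoint combinations")
    cl <- classify_epistasis(fold, rules)
    data.frame(gene_id = g, label = cl$label,
               antagonistic = cl$antagonistic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count epistasis classes
#'
#' @param calls data.frame from [classify_epistasis_table()].
#' @return list \code{counts} (named integer vector over all labels) and
#'   \code{antagonistic} (total in the three antagonistic classes).
#' @export
count_classes <- function(calls) {
  labs <- c("AllUp", "TNFUp", "ZeroUp", "Inverse", "RelABlockedSirt6",
            "Unclassified")
  counts <- table(factor(calls$label, levels = labs))
  list(counts = setNames(as.integer(counts), labs),
       antagonistic = sum(counts[c("AllUp", "TNFUp", "ZeroUp")]))
}

#' Average-linkage hierarchical clustering with correlation distance
#'
#' Descriptive ordering of fold-change profiles: distance is 1 - Pearson
#' correlation between rows (constant rows get distance 1 to everything,
#' with a message), linkage is average, and the leaf order follows a
#' deterministic convention: at every merge the subtree containing the
#' smaller minimum original row index comes first.
#'
#' @param mat numeric matrix (genes x samples), >= 2 rows, no missing
#'   values.
#' @return list with \code{order} (row indices), \code{labels} (rownames in
#'   leaf order) and \code{hclust} (the merge tree).
#' @export
hierarchical_cluster <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2)
    stop("need a matrix with >= 2 rows")
  if (anyNA(mat)) stop("missing values are not allowed")
  v <- apply(mat, 1, stats::var)
  if (any(v == 0))
    message(sum(v == 0),
            " constant row(s): correlation undefined, distance set to 1")
  cc <- suppressWarnings(cor(t(mat)))
  cc[is.na(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  ord <- .canonical_leaf_order(hc$merge)
  list(order = ord,
       labels = if (!is.null(rownames(mat))) rownames(mat)[ord] else NULL,
       hclust = hc)
}

# Leaf order with the smaller-minimum-original-index subtree first at every
# merge; independent of input row order up to relabeling.
.canonical_leaf_order <- function(merge) {
  n_nodes <- nrow(merge)
  leaves <- function(node) {
    if (node < 0) return(-node)
    l <- leaves(merge[node, 1]); r <- leaves(merge[node, 2])
    if (min(l) <= min(r)) c(l, r) else c(r, l)
  }
  leaves(n_nodes)
}
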