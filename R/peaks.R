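# Sliding-window peak calling with a within-promoter permutation null.
# The proprietary caller the source data came from is unspecified; this is
# the package's defined stand-in: windows of the fragment size are slid
# across each promoter's probes, windows with enough probes and a high
# enough mean log2 ratio are merged into peaks, and the FDR attached to each
# peak comes from re-running the identical caller on within-promoter
# permutations of the probe values.

# Order a single-sample probe table by (gene, offset) and build the gene
# pointer vector the C++ scan expects.
.probe_layout <- function(probes) {
  ord <- order(probes$gene_id, probes$offset)
  probes <- probes[ord, ]
  genes <- unique(probes$gene_id)
  cnt <- table(factor(probes$gene_id, levels = genes))
  list(probes = probes, genes = genes,
       ptr = as.integer(c(0, cumsum(cnt))))
}

#' Call enriched peaks on promoter windows
#'
#' Slides a window of \code{window_bp} across each promoter's probe offsets;
#' a window is a candidate if it holds at least \code{min_probes} probes with
#' mean log2 ratio at least \code{score_threshold}. Overlapping or touching
#' candidate windows merge into one peak whose score is the mean over member
#' probes and whose span runs from the first to one past the last member
#' probe. Every distinct window position is considered (the scan enumerates
#' all realizable probe contents, equivalent to every integer start).
#'
#' @param probes single-sample probe table (normalized).
#' @param window_bp scan window width in bp (default: fragment size).
#' @param min_probes minimum probes per candidate window.
#' @param score_threshold minimum candidate mean log2 ratio.
#' @param window tiled window offsets; peak \code{start}/\code{end} are
#'   reported 0-based half-open relative to the window origin
#'   (\code{offset - window[1]}).
#' @return data.frame \code{gene_id, start, end, score, n_probes, fdr}
#'   (\code{fdr} is \code{NA} until [estimate_fdr()]).
#' @export
call_peaks <- function(probes, window_bp = 500, min_probes = 4,
                       score_threshold = 0.75, window = tiled_window()) {
  lay <- .probe_layout(probes)
  same <- lay$probes$gene_id[-1] == lay$probes$gene_id[-nrow(lay$probes)]
  gaps <- diff(lay$probes$offset)[same]
  if (length(gaps) && window_bp < min(gaps))
    stop("window_bp (", window_bp, ") is smaller than the probe spacing (",
         min(gaps), ")")
  res <- scan_peaks_cpp(lay$ptr, as.integer(lay$probes$offset),
                        as.numeric(lay$probes$log2_ratio),
                        as.integer(window_bp), as.integer(min_probes),
                        score_threshold)
  if (nrow(res) == 0) {
    out <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), score = numeric(),
                      n_probes = integer(), fdr = numeric())
  } else {
    g0 <- lay$ptr[res$gene + 1L]              # 0-based gene block start
    off_lo <- lay$probes$offset[g0 + res$i0 + 1L]
    off_hi <- lay$probes$offset[g0 + res$i1 + 1L]
    out <- data.frame(gene_id = lay$genes[res$gene + 1L],
                      start = off_lo - window[1],
                      end = off_hi + 1L - window[1],
                      score = res$score,
                      n_probes = res$i1 - res$i0 + 1L,
                      fdr = NA_real_,
                      stringsAsFactors = FALSE)
  }
  attr(out, "window") <- window
  attr(out, "params") <- list(window_bp = window_bp, min_probes = min_probes,
                              score_threshold = score_threshold)
  out
}

#' Attach permutation-based FDR estimates to called peaks
#'
#' Builds a null by permuting probe log2 ratios \code{n_permutations} times
#' and re-running the caller with identical parameters. For a peak of score
#' \code{s}, the raw FDR is the expected number of null peaks scoring at
#' least \code{s} (per permutation) divided by the number of observed peaks
#' scoring at least \code{s}, capped at 1; a step-down pass then takes, for
#' each peak, the minimum raw FDR over all cutoffs at or below its score,
#' making FDR monotone non-increasing in score. Equal scores receive equal
#' FDR.
#'
#' By default values are shuffled sample-wide across all promoters (probe
#' positions fixed, so per-promoter probe counts are preserved): the null
#' hypothesis is "no enrichment anywhere". \code{permute = "promoter"}
#' instead shuffles within each promoter window, which preserves each
#' promoter's own value distribution but retains real enrichment mass inside
#' bound promoters and is therefore conservative when fragment-size peaks
#' cover an appreciable share of the tiled window.
#'
#' @param peaks output of [call_peaks()] on these probes with these
#'   parameters.
#' @param probes the same single-sample probe table.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @param permute \code{"sample"} (default) or \code{"promoter"}.
#' @param window_bp,min_probes,score_threshold caller parameters; default to
#'   those recorded on \code{peaks}.
#' @return \code{peaks} with the \code{fdr} column filled.
#' @export
estimate_fdr <- function(peaks, probes, n_permutations = 100, seed = NULL,
                         permute = c("sample", "promoter"),
                         window_bp = NULL, min_probes = NULL,
                         score_threshold = NULL) {
  permute <- match.arg(permute)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  par <- attr(peaks, "params")
  if (is.null(window_bp)) window_bp <- par$window_bp
  if (is.null(min_probes)) min_probes <- par$min_probes
  if (is.null(score_threshold)) score_threshold <- par$score_threshold
  if (is.null(window_bp) || is.null(min_probes) || is.null(score_threshold))
    stop("caller parameters not found on `peaks`; pass them explicitly")
  if (nrow(peaks) == 0) return(peaks)
  .seed_if(seed)
  lay <- .probe_layout(probes)
  null_scores <- scan_null_scores_cpp(
    lay$ptr, as.integer(lay$probes$offset),
    as.numeric(lay$probes$log2_ratio), as.integer(window_bp),
    as.integer(min_probes), score_threshold, as.integer(n_permutations),
    within_promoter = (permute == "promoter"))

  obs <- peaks$score
  cuts <- sort(unique(obs))                     # ascending cutoffs
  null_sorted <- sort(null_scores)
  n_null_ge <- length(null_sorted) -
    findInterval(cuts - 1e-12, null_sorted)     # nulls scoring >= cutoff
  obs_sorted <- sort(obs)
  n_obs_ge <- length(obs_sorted) -
    findInterval(cuts - 1e-12, obs_sorted)
  raw <- pmin(1, (n_null_ge / n_permutations) / n_obs_ge)
  q <- cummin(raw)                              # step-down over cutoffs
  peaks$fdr <- q[match(obs, cuts)]
  peaks
}

#' Calibrate the FDR threshold against a known-target list
#'
#' Given gene-level target sets obtained at several candidate FDR
#' thresholds, reports how many known targets each threshold recovers and
#' picks the smallest threshold whose recovery reaches
#' \code{recovery_goal} (a fraction of the known set; default complete
#' recovery). If no threshold reaches the goal, the threshold with maximal
#' recovery is chosen with a warning.
#'
#' @param peak_sets named list of [target_set()] objects (or plain gene-id
#'   vectors); names are the candidate thresholds.
#' @param known_targets non-empty character vector of known target genes.
#' @param recovery_goal required recovered fraction in \[0, 1\].
#' @return list with \code{report} (data.frame: threshold, n_targets,
#'   n_known_recovered, n_known_total) and \code{chosen} (numeric
#'   threshold).
#' @export
calibrate_fdr_threshold <- function(peak_sets, known_targets,
                                    recovery_goal = 1.0) {
  if (length(known_targets) == 0)
    stop("known_targets is empty: calibration is undefined")
  thr <- as.numeric(names(peak_sets))
  if (anyNA(thr)) stop("peak_sets must be named by numeric thresholds")
  ord <- order(thr)
  thr <- thr[ord]
  peak_sets <- peak_sets[ord]
  genes <- lapply(peak_sets, function(s)
    if (inherits(s, "target_set")) s$genes else as.character(s))
  report <- data.frame(
    threshold = thr,
    n_targets = vapply(genes, length, 1L),
    n_known_recovered = vapply(genes, function(g)
      length(intersect(g, known_targets)), 1L),
    n_known_total = length(known_targets))
  frac <- report$n_known_recovered / report$n_known_total
  ok <- which(frac >= recovery_goal)
  if (length(ok)) {
    chosen <- thr[ok[1]]
  } else {
    warning("no threshold reaches the recovery goal; choosing the one with ",
            "maximal recovery")
    chosen <- thr[which.max(frac)]
  }
  list(report = report, chosen = chosen)
}
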