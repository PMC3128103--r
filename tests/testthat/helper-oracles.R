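# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-implementations kept separate from the package code
# paths they check.

# Brute-force window scan: enumerate EVERY integer window start, apply the
# candidate rule, merge overlapping/touching windows, emit merged spans
# (offset space, [first member probe, last member probe + 1)) and scores.
oracle_scan <- function(offsets, values, window_bp, min_probes, thresh) {
  stopifnot(!is.unsorted(offsets))
  starts <- (min(offsets) - window_bp):max(offsets)
  lo <- NA; hi <- NA
  ivs <- list()
  for (s in starts) {
    in_w <- which(offsets >= s & offsets < s + window_bp)
    cand <- length(in_w) >= min_probes && mean(values[in_w]) >= thresh
    if (cand) {
      if (is.na(lo)) { lo <- s; hi <- s + window_bp }
      else if (s <= hi) hi <- s + window_bp   # overlap or touch
      else { ivs[[length(ivs) + 1]] <- c(lo, hi); lo <- s; hi <- s + window_bp }
    }
  }
  if (!is.na(lo)) ivs[[length(ivs) + 1]] <- c(lo, hi)
  if (!length(ivs))
    return(data.frame(start = integer(), end = integer(), score = numeric(),
                      n_probes = integer()))
  rows <- lapply(ivs, function(iv) {
    memb <- which(offsets >= iv[1] & offsets < iv[2])
    data.frame(start = offsets[min(memb)], end = offsets[max(memb)] + 1L,
               score = mean(values[memb]), n_probes = length(memb))
  })
  do.call(rbind, rows)
}

# Exhaustive hypergeometric upper tail by enumerating every n-subset of an
# N-element universe whose first K elements are "successes".
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Independent one-step Tukey biweight (median/MAD start, bisquare weights).
oracle_biweight <- function(x, cc = 9, eps = 1e-4) {
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  u <- (x - m) / (cc * s + eps)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  sum(w * x) / sum(w)
}

# Single-sample probe table on an arbitrary offset layout.
make_probe_table <- function(gene_id, offsets, values, factor = "Sirt6",
                             genotype = "WT", timepoint = 15) {
  data.frame(factor = factor, genotype = genotype, timepoint = timepoint,
             probe_id = paste0(gene_id, ":", offsets),
             gene_id = gene_id, offset = offsets, log2_ratio = values,
             stringsAsFactors = FALSE)
}

# Regular-grid probe table with optional triangular bumps.
make_grid_sample <- function(n_genes, sites = rep(NA, n_genes), height = 2,
                             width = 500, noise_sd = 0, spacing = 100,
                             window = c(-3250, 750)) {
  off <- seq(window[1], window[2], by = spacing)
  rows <- lapply(seq_len(n_genes), function(i) {
    v <- rnorm(length(off), 0, max(noise_sd, 1e-12))
    if (!is.na(sites[i]))
      v <- v + height * pmax(0, 1 - abs(off - sites[i]) / width)
    make_probe_table(sprintf("g%03d", i), off, v)
  })
  do.call(rbind, rows)
}

# Small fold-change table for one gene over WT/Sirt6KO/DKO x {0, 90}.
fold_matrix <- function(wt, s6, dk, tps = c(0, 90)) {
  m <- rbind(WT = wt, Sirt6KO = s6, DKO = dk)
  colnames(m) <- tps
  m
}
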