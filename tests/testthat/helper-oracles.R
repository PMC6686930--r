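# Independent brute-force oracles used by the property tests. These
# deliberately share no code with the package implementation.

# Enumerate, for one read, every terminal-anchored tail at the given end and
# return the longest one satisfying the gap predicate (no internal non-base
# run longer than endgap), before any length/purity thresholds.
# end = "suffix" scans 3' A tails, "prefix" scans 5' T tails.
bf_terminal_tail <- function(read, base, end = c("suffix", "prefix"),
                             endgap = 2L) {
  end <- match.arg(end)
  ch <- strsplit(read, "", fixed = TRUE)[[1]]
  if (end == "prefix") ch <- rev(ch)
  n <- length(ch)
  best <- 0L
  for (s in seq_len(n)) {
    seg <- ch[s:n]
    if (seg[1] != base || seg[length(seg)] != base) next
    runs <- rle(seg != base)
    if (any(runs$lengths[runs$values] > endgap)) next
    best <- n - s + 1L
    break  # first (smallest) s is the longest suffix
  }
  if (best == 0L) return(list(len = 0L, nona = 0L))
  seg <- ch[(n - best + 1L):n]
  list(len = best, nona = sum(seg != base))
}

# Full brute-force scan of one read mirroring the stated selection rule
# (thresholds, protocol, longer-accepted-tail-wins, tie -> 3' A).
bf_scan <- function(read, min_tail = 8L, endgap = 2L, max_nona = 0.10,
                    protocol = "unstranded", mate = 1L) {
  t3 <- bf_terminal_tail(read, "A", "suffix", endgap)
  t5 <- bf_terminal_tail(read, "T", "prefix", endgap)
  ok3 <- t3$len >= min_tail && t3$nona <= max_nona * t3$len
  ok5 <- t5$len >= min_tail && t5$nona <= max_nona * t5$len
  if (protocol == "stranded") {
    if (mate == 1L) ok3 <- FALSE else ok5 <- FALSE
  }
  if (ok3 && (!ok5 || t3$len >= t5$len)) {
    list(end = "three_prime_A", len = t3$len, nona = t3$nona)
  } else if (ok5) {
    list(end = "five_prime_T", len = t5$len, nona = t5$nona)
  } else {
    list(end = "none", len = 0L, nona = 0L)
  }
}

# Vectorised brute-force tail lengths for many same-alphabet reads: for each
# read, the longest suffix anchored at the 3' terminus that starts/ends with
# `base` and has no internal non-base run longer than `endgap`, found by
# explicit enumeration over all suffix start positions.
bf_tail_matrix <- function(reads, base = "A", endgap = 2L) {
  out_len <- integer(length(reads))
  out_nona <- integer(length(reads))
  for (L in sort(unique(nchar(reads)))) {
    idx <- which(nchar(reads) == L)
    mat <- matrix(unlist(strsplit(reads[idx], "", fixed = TRUE)),
                  nrow = length(idx), byrow = TRUE)
    isB <- mat == base
    g1 <- endgap + 1L
    # badg[, j]: a non-base run of length endgap+1 starts at column j
    if (L >= g1) {
      badg <- matrix(TRUE, nrow = length(idx), ncol = L - g1 + 1L)
      for (o in 0:(g1 - 1L)) badg <- badg & !isB[, (1L + o):(L - g1 + 1L + o),
                                                 drop = FALSE]
      badsuf <- badg
      if (ncol(badsuf) > 1L) for (j in (ncol(badsuf) - 1L):1L)
        badsuf[, j] <- badsuf[, j] | badsuf[, j + 1L]
    } else {
      badsuf <- NULL
    }
    nonb_from <- if (L == 1L) matrix(as.integer(!isB), ncol = 1L) else
      t(apply(!isB[, L:1, drop = FALSE], 1L, cumsum))[, L:1, drop = FALSE]
    len <- integer(length(idx)); nona <- integer(length(idx))
    endB <- isB[, L]
    for (s in seq_len(L)) {
      cand <- endB & isB[, s] & len == 0L
      if (!is.null(badsuf) && s <= ncol(badsuf)) {
        cand <- cand & !badsuf[, s]
      }
      len[cand] <- L - s + 1L
      nona[cand] <- nonb_from[cand, s]
    }
    out_len[idx] <- len
    out_nona[idx] <- nona
  }
  list(len = out_len, nona = out_nona)
}

# Independent implementation of the support-ranked greedy clustering rule:
# repeatedly pick the unassigned site with the highest count (tie: smallest
# position) and absorb all unassigned sites within +/- window.
bf_cluster <- function(sites, window = 24L, min_reads = 3L) {
  sites <- sites[sites$read_count >= min_reads, , drop = FALSE]
  res <- list()
  for (key in unique(paste(sites$chrom, sites$strand))) {
    g <- sites[paste(sites$chrom, sites$strand) == key, , drop = FALSE]
    pos <- g$position; cnt <- g$read_count
    unassigned <- rep(TRUE, length(pos))
    while (any(unassigned)) {
      cand <- which(unassigned)
      rep_i <- cand[order(-cnt[cand], pos[cand])[1L]]
      memb <- cand[abs(pos[cand] - pos[rep_i]) <= window]
      unassigned[memb] <- FALSE
      res[[length(res) + 1L]] <- data.frame(
        chrom = g$chrom[1L], strand = g$strand[1L],
        span_start = min(pos[memb]), span_end = max(pos[memb]),
        representative_position = pos[rep_i],
        representative_count = cnt[rep_i],
        n_sites = length(memb), total_support = sum(cnt[memb]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  out[order(out$chrom, out$strand, out$span_start), , drop = FALSE]
}

# Random cleavage-site table for clustering property tests.
random_sites <- function(n_max = 50L, count_max = 30L) {
  n <- sample.int(n_max, 1L)
  data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             position = sample.int(500L, n),
             read_count = sample.int(count_max, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# De-duplicate positions within chrom+strand (aggregate counts) so the site
# table satisfies the aggregate_sites contract.
dedup_sites <- function(s) {
  agg <- stats::aggregate(read_count ~ chrom + strand + position, data = s,
                          FUN = sum)
  agg[order(agg$chrom, agg$strand, agg$position), , drop = FALSE]
}

# Small fast simulation config for integration tests.
small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, n_genes = 30L, chromosome_length = 120000L,
                   n_reads = 20000L, frac_polya_reads = 0.1,
                   n_decoy_regions = 6L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
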