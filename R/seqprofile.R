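#' Extract strand-aware windows around PAC representative sites
#'
#' Returns the genomic `[-up, +down]` window around each representative
#' cleavage site in mRNA sense (reverse complement for minus-strand PACs),
#' with window position 0 at the representative (last templated) base.
#' Windows that would cross a contig boundary are skipped and counted.
#'
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param pacs PAC data frame.
#' @param up,down nt upstream / downstream of the site (defaults 300 / 100).
#' @return `DNAStringSet` named by `pac_id`, with attributes `up`, `down`
#'   and `n_skipped`.
#' @export
extract_windows <- function(genome, pacs, up = 300L, down = 100L) {
  genome <- as_genome_chr(genome)
  clen <- nchar(genome)[pacs$chrom]
  pos <- pacs$representative_position
  plus <- pacs$strand == "+"
  lo <- ifelse(plus, pos - up, pos - down)       # 0-based window start
  hi <- ifelse(plus, pos + down, pos + up)
  ok <- lo >= 0L & hi <= clen - 1L
  seqs <- substring(genome[pacs$chrom[ok]], lo[ok] + 1L, hi[ok] + 1L)
  minus <- !plus[ok]
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- pacs$pac_id[ok]
  attr(out, "up") <- as.integer(up)
  attr(out, "down") <- as.integer(down)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Per-position nucleotide composition of aligned windows
#'
#' Counts A/C/G/U at every window position (genomic T is reported as U, the
#' presentation convention for RNA motifs) and the per-position frequencies
#' over non-N bases.
#'
#' @param windows equal-width `DNAStringSet`, e.g. from [extract_windows()]
#'   (its `up` attribute, when present, anchors position 0).
#' @param up nt upstream of the site; overrides the attribute.
#' @return list of class `position_profile`: `n_sequences`, `positions`,
#'   `counts` (4 x width matrix, rows A/C/G/U), `freq` (columns sum to 1
#'   wherever any non-N base exists).
#' @export
position_composition <- function(windows, up = NULL) {
  w <- unique(Biostrings::width(windows))
  if (length(w) != 1L) stop("windows must all have the same length")
  if (is.null(up)) up <- attr(windows, "up")
  if (is.null(up)) up <- w - 1L
  cm <- Biostrings::consensusMatrix(windows, baseOnly = TRUE)
  counts <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  rownames(counts) <- c("A", "C", "G", "U")
  tot <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(tot, 1L), "/")
  positions <- seq.int(-up, w - 1L - up)
  colnames(counts) <- colnames(freq) <- positions
  structure(list(n_sequences = length(windows), positions = positions,
                 counts = counts, freq = freq), class = "position_profile")
}

#' Per-position chi-squared deviation between two composition profiles
#'
#' At every window position the observed base counts are compared against
#' expected counts formed from the reference profile's base frequencies
#' scaled to the observed sequence count (a 4-category goodness-of-fit
#' statistic, 3 df). When a base has zero reference frequency but a nonzero
#' observed count, add-one smoothing is applied to the reference counts at
#' that position (and noted in the `smoothed` attribute).
#'
#' @param observed,reference `position_profile` objects over identical
#'   window coordinates (the reference is conventionally the 3'-UTR PAC
#'   profile).
#' @return numeric vector of chi-squared values named by position.
#' @export
chi2_compare <- function(observed, reference) {
  if (!identical(observed$positions, reference$positions))
    stop("profiles must cover identical window positions")
  n <- observed$n_sequences
  W <- length(observed$positions)
  chi2 <- numeric(W)
  smoothed <- logical(W)
  for (j in seq_len(W)) {
    O <- observed$counts[, j]
    p <- reference$freq[, j]
    if (any(p == 0 & O > 0)) {
      rc <- reference$counts[, j] + 1
      p <- rc / sum(rc)
      smoothed[j] <- TRUE
    }
    E <- p * sum(O)
    use <- E > 0
    chi2[j] <- sum((O[use] - E[use])^2 / E[use])
  }
  names(chi2) <- observed$positions
  attr(chi2, "smoothed") <- smoothed
  chi2
}

#' Enumerate hexamers in the NUE search region upstream of PACs
#'
#' Scans the `[region[1], region[2]]` sub-window (default -40..-10, the
#' near-upstream-element region) of every window. With `once = TRUE` each
#' distinct hexamer is counted at most once per window. Windows containing
#' an N inside the scanned sub-region are excluded (counted in the
#' `n_excluded` attribute). Motifs are reported in the RNA alphabet.
#'
#' @param windows `DNAStringSet` from [extract_windows()].
#' @param region integer c(from, to) in window coordinates (site = 0).
#' @param up upstream window extent; defaults to the `up` attribute.
#' @param once logical; count each motif at most once per window.
#' @return data frame sorted by descending count: `motif`, `observed`,
#'   `frequency_pct` (percent of scanned windows containing the motif).
#'   Attributes: `n_windows`, `n_excluded`, `n_placements` (hexamer start
#'   positions per window), `base_freqs` (A/C/G/T composition of the
#'   scanned sub-windows, the 0-order background).
#' @export
hexamer_scan <- function(windows, region = c(-40L, -10L), up = NULL,
                         once = TRUE) {
  k <- 6L
  if (is.null(up)) up <- attr(windows, "up")
  if (is.null(up)) stop("supply `up` to anchor window coordinates")
  w <- unique(Biostrings::width(windows))
  if (length(w) != 1L) stop("windows must all have the same length")
  i1 <- region[1] + up + 1L
  i2 <- region[2] + up + 1L
  if (i1 < 1L || i2 > w || i2 - i1 + 1L < k)
    stop("windows do not cover the requested hexamer region")
  sub <- substr(as.character(windows), i1, i2)
  keep <- !grepl("N", sub, fixed = TRUE)
  n_excluded <- sum(!keep)
  sub <- sub[keep]
  L <- i2 - i1 + 1L
  m <- L - k + 1L
  n_win <- length(sub)

  counts <- integer(0)
  if (n_win > 0L) {
    hex <- unlist(lapply(seq_len(m), function(o) substr(sub, o, o + k - 1L)),
                  use.names = FALSE)
    win <- rep(seq_len(n_win), times = m)
    if (once) {
      dup <- duplicated(paste0(win, "_", hex))
      hex <- hex[!dup]
    }
    counts <- sort(table(hex), decreasing = TRUE)
  }
  bases <- c(A = 0, C = 0, G = 0, T = 0)
  if (n_win > 0L) {
    for (b in names(bases)) bases[b] <- sum(char_count(sub, b))
    bases <- bases / sum(bases)
  }
  motifs <- if (length(counts)) chartr("T", "U", names(counts)) else character(0)
  out <- data.frame(motif = motifs,
                    observed = as.integer(counts),
                    frequency_pct = 100 * as.integer(counts) / max(n_win, 1L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_windows") <- n_win
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_placements") <- m
  attr(out, "base_freqs") <- bases
  out
}

#' Enrichment Z-scores for scanned hexamers
#'
#' Under a 0-order Bernoulli background with base frequencies `base_freqs`
#' (by default estimated from the scanned sub-windows themselves), the
#' probability that a given hexamer occurs at one placement is the product
#' of its letter frequencies, the per-window occurrence probability over
#' `n_placements` start positions is `q = 1 - (1 - p)^m`, and the observed
#' window count is compared against Binomial(n_windows, q):
#' `z = (observed - n q) / sqrt(n q (1 - q))`.
#'
#' @param stats data frame from [hexamer_scan()] (or any data frame with
#'   `motif` and `observed`).
#' @param base_freqs named A/C/G/T frequency vector; defaults to the
#'   `base_freqs` attribute of `stats`.
#' @param n_windows,n_placements background model sizes; default to the
#'   attributes of `stats`.
#' @return `stats` with `expected` and `zscore` columns added (`zscore` is
#'   `NA` when the binomial variance is 0).
#' @export
motif_zscore <- function(stats, base_freqs = NULL, n_windows = NULL,
                         n_placements = NULL) {
  if (is.null(base_freqs)) base_freqs <- attr(stats, "base_freqs")
  if (is.null(n_windows)) n_windows <- attr(stats, "n_windows")
  if (is.null(n_placements)) n_placements <- attr(stats, "n_placements")
  if (is.null(base_freqs) || is.null(n_windows) || is.null(n_placements))
    stop("supply base_freqs, n_windows and n_placements (or use hexamer_scan output)")
  dna <- chartr("U", "T", stats$motif)
  p_word <- vapply(strsplit(dna, ""), function(ch)
    prod(base_freqs[ch]), numeric(1))
  q <- 1 - (1 - p_word)^n_placements
  E <- n_windows * q
  V <- n_windows * q * (1 - q)
  stats$expected <- E
  stats$zscore <- ifelse(V > 0, (stats$observed - E) / sqrt(V), NA_real_)
  stats
}
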