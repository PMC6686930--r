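#' Parameters for terminal poly(A)/poly(T) tail scanning
#'
#' Controls how candidate polyadenylated reads are recognised. A tail is the
#' longest terminal homopolymer-like stretch: perfect A (or T) runs merged
#' across internal non-A (non-T) gaps of at most `endgap` bases. The merged
#' tail is accepted only if it is at least `min_tail` long and its non-A
#' (non-T) fraction does not exceed `max_nona_frac`.
#'
#' @param min_tail minimum accepted tail length in nt (default 8).
#' @param endgap maximum internal non-A/non-T run length merged into a tail
#'   (default 2).
#' @param max_nona_frac maximum fraction of non-A (non-T) bases within the
#'   merged tail (default 0.10).
#' @param min_trimmed_len minimum insert length after tail removal; shorter
#'   trimmed reads are discarded (default 20).
#' @param protocol `"unstranded"` (both read ends are tested, the longer
#'   accepted tail wins, ties go to the 3' A tail) or `"stranded"` (only the
#'   strand-appropriate end of the appropriate mate is tested: mate 1 for 5' T
#'   tails, mate 2 for 3' A tails).
#' @param seed integer seed used only for the random replacement of N bases;
#'   `NULL` leaves the RNG state untouched.
#' @return a list of class `tail_params`.
#' @export
tail_params <- function(min_tail = 8L, endgap = 2L, max_nona_frac = 0.10,
                        min_trimmed_len = 20L,
                        protocol = c("unstranded", "stranded"),
                        seed = NULL) {
  protocol <- match.arg(protocol)
  min_tail <- as.integer(min_tail)
  endgap <- as.integer(endgap)
  if (min_tail < 1L) stop("min_tail must be >= 1")
  if (endgap < 0L) stop("endgap must be >= 0")
  if (max_nona_frac < 0 || max_nona_frac >= 1)
    stop("max_nona_frac must be in [0, 1)")
  structure(list(min_tail = min_tail, endgap = endgap,
                 max_nona_frac = max_nona_frac,
                 min_trimmed_len = as.integer(min_trimmed_len),
                 protocol = protocol, seed = seed),
            class = "tail_params")
}

# Length of the longest prefix of each string that starts and ends with
# `base` and contains no internal non-`base` run longer than `endgap`.
# 0 when the first character is not `base`. Implemented as a single greedy
# regular expression; each internal gap run must be consumed whole, so the
# match is exactly the maximal valid prefix.
.terminal_run_len <- function(x, base, endgap) {
  if (endgap > 0L) {
    pat <- sprintf("^%s+(?:[^%s]{1,%d}%s+)*", base, base, endgap, base)
  } else {
    pat <- sprintf("^%s+", base)
  }
  m <- regexpr(pat, x, perl = TRUE)
  len <- attr(m, "match.length")
  len[m == -1L] <- 0L
  as.integer(len)
}

# Replace every N base with a random draw from {A,C,G,T}, seeded.
.replace_n <- function(reads, seed) {
  has_n <- grepl("N", reads, fixed = TRUE)
  if (!any(has_n)) return(reads)
  with_seed(seed, {
    idx <- which(has_n)
    for (i in idx) {
      chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      nn <- chars == "N"
      chars[nn] <- sample(c("A", "C", "G", "T"), sum(nn), replace = TRUE)
      reads[i] <- paste(chars, collapse = "")
    }
    reads
  })
}

#' Scan reads for terminal poly(A)/poly(T) tails
#'
#' Vectorised tail scan over a character vector of reads. For a 3' A tail the
#' tail is the longest suffix that ends in A at the read terminus, begins with
#' A, and contains no internal non-A run longer than `endgap`; the symmetric
#' prefix rule detects 5' T tails. N bases are first replaced uniformly at
#' random (seeded) and count toward the non-A/non-T tally if the replacement
#' is not A (T). A candidate tail is accepted only if its length is at least
#' `min_tail` and its non-A (non-T) fraction is at most `max_nona_frac`.
#'
#' Under the unstranded protocol both ends are tested and the longer accepted
#' tail wins (tie: 3' A). Under the stranded protocol only the 5' end of mate
#' 1 (T tail) or the 3' end of mate 2 (A tail) is tested.
#'
#' @param reads character vector of read sequences over \{A,C,G,T,N\}.
#' @param params a [tail_params()] object.
#' @param mate 1 or 2; used only under the stranded protocol.
#' @param read_ids optional read identifiers (defaults to names or index).
#' @return data frame with one row per read: `read_id`, `tail_end`
#'   (`"three_prime_A"`, `"five_prime_T"` or `"none"`), `tail_length`,
#'   `nona_count`, `trimmed` (read minus the tail), `mrna_sense` (trimmed read
#'   oriented so its 3' end abuts the tail; reverse complement for 5' T
#'   tails), and `ambiguous` (both ends qualified under unstranded scanning).
#' @export
scan_tails <- function(reads, params = tail_params(), mate = 1L,
                       read_ids = NULL) {
  if (is.null(read_ids)) {
    read_ids <- if (!is.null(names(reads))) names(reads) else
      paste0("read", seq_along(reads))
  }
  if (length(reads) == 0L) {
    return(data.frame(read_id = character(0), tail_end = character(0),
                      tail_length = integer(0), nona_count = integer(0),
                      trimmed = character(0), mrna_sense = character(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(reads))) {
    stop("empty read sequence: ", read_ids[which(!nzchar(reads))[1]])
  }
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    stop("read contains characters outside {A,C,G,T,N}: ",
         read_ids[which(bad)[1]])
  }
  reads <- .replace_n(reads, params$seed)

  n <- length(reads)
  len3 <- len5 <- integer(n)
  scan3 <- params$protocol == "unstranded" || mate == 2L
  scan5 <- params$protocol == "unstranded" || mate == 1L
  if (scan3) len3 <- .terminal_run_len(str_reverse(reads), "A", params$endgap)
  if (scan5) len5 <- .terminal_run_len(reads, "T", params$endgap)

  nc <- nchar(reads)
  nona3 <- nona5 <- integer(n)
  ok3 <- len3 >= params$min_tail
  if (any(ok3)) {
    tail3 <- substr(reads[ok3], nc[ok3] - len3[ok3] + 1L, nc[ok3])
    nona3[ok3] <- len3[ok3] - char_count(tail3, "A")
    ok3[ok3] <- nona3[ok3] <= params$max_nona_frac * len3[ok3]
  }
  ok5 <- len5 >= params$min_tail
  if (any(ok5)) {
    tail5 <- substr(reads[ok5], 1L, len5[ok5])
    nona5[ok5] <- len5[ok5] - char_count(tail5, "T")
    ok5[ok5] <- nona5[ok5] <= params$max_nona_frac * len5[ok5]
  }

  # choose the winning end: longer accepted tail, tie -> 3' A
  use3 <- ok3 & (!ok5 | len3 >= len5)
  use5 <- ok5 & !use3

  tail_end <- rep("none", n)
  tail_end[use3] <- "three_prime_A"
  tail_end[use5] <- "five_prime_T"
  tail_length <- integer(n)
  tail_length[use3] <- len3[use3]
  tail_length[use5] <- len5[use5]
  nona <- integer(n)
  nona[use3] <- nona3[use3]
  nona[use5] <- nona5[use5]

  trimmed <- reads
  trimmed[use3] <- substr(reads[use3], 1L, nc[use3] - len3[use3])
  trimmed[use5] <- substr(reads[use5], len5[use5] + 1L, nc[use5])
  trimmed[tail_end == "none"] <- NA_character_

  mrna <- trimmed
  if (any(use5)) {
    nonempty <- use5 & nzchar(trimmed) & !is.na(trimmed)
    mrna[nonempty] <- revcomp(trimmed[nonempty])
  }

  data.frame(read_id = read_ids, tail_end = tail_end,
             tail_length = tail_length, nona_count = nona,
             trimmed = trimmed, mrna_sense = mrna,
             ambiguous = ok3 & ok5, stringsAsFactors = FALSE)
}

#' Scan a single read for a terminal tail
#'
#' Convenience wrapper around [scan_tails()] for one sequence.
#'
#' @inheritParams scan_tails
#' @param read_sequence a single read sequence.
#' @return a one-row data frame, see [scan_tails()].
#' @export
scan_tail <- function(read_sequence, params = tail_params(), mate = 1L) {
  scan_tails(read_sequence, params, mate = mate, read_ids = "read1")
}

#' Trim detected tails and apply the minimum-insert filter
#'
#' Keeps only scans with a detected tail whose trimmed insert is at least
#' `min_trimmed_len` nt; 5' T-tail reads are reverse complemented so every
#' output sequence is in mRNA sense with its 3' end abutting the tail.
#'
#' @param scans data frame from [scan_tails()].
#' @param params a [tail_params()] object.
#' @return the subset of rows that pass, with a `mrna_sense` column holding
#'   the trimmed, mRNA-sense insert.
#' @export
trim_and_filter <- function(scans, params = tail_params()) {
  keep <- scans$tail_end != "none" &
    !is.na(scans$trimmed) &
    nchar(scans$trimmed) >= params$min_trimmed_len
  scans[keep, , drop = FALSE]
}
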