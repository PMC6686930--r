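#' Parameters of the internal-priming filter
#'
#' A called cleavage event is treated as an internal-priming artifact (the
#' oligo-dT having primed on a genomically encoded A stretch rather than a
#' real tail) when the genomic window immediately downstream of the site in
#' mRNA sense is A-rich: at least `max_a` A bases in `window` nt, or an A run
#' of at least `max_run` nt.
#'
#' @param window downstream window length in nt (default 10).
#' @param max_a A count at or above which the event is dropped (default 7).
#' @param max_run A-run length at or above which the event is dropped
#'   (default 6).
#' @return list of class `ip_filter_params`.
#' @export
ip_filter_params <- function(window = 10L, max_a = 7L, max_run = 6L) {
  window <- as.integer(window); max_a <- as.integer(max_a)
  max_run <- as.integer(max_run)
  if (max_a > window || max_run > window)
    stop("max_a and max_run must not exceed window")
  structure(list(window = window, max_a = max_a, max_run = max_run),
            class = "ip_filter_params")
}

# Coerce a genome (named character vector, DNAStringSet, or FASTA path)
# to a named character vector of chromosome sequences.
as_genome_chr <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    g <- as.character(genome)
    names(g) <- sub("\\s.*$", "", names(genome))
    return(g)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("genome must be a named character vector, DNAStringSet, or FASTA path")
}

#' Exact-match alignment of reads against a small genome
#'
#' A deliberately simple end-to-end aligner for testing and simulated data:
#' each read is located by exact substring search on both strands. A read
#' with exactly one occurrence is reported as uniquely aligned; zero
#' occurrences is `unmapped`; two or more is `multi`. Occurrences are found
#' with a fixed-width anchor ([Biostrings::matchPDict()] on the first 20 nt)
#' followed by full-length verification, so every exact occurrence is
#' enumerated.
#'
#' @param reads character vector of read sequences (length >= 20 nt each).
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param read_ids optional identifiers (default: names or index).
#' @return data frame with columns `read_id`, `status`
#'   (`unique`/`multi`/`unmapped`), `chrom`, `strand`, `start`, `end`
#'   (0-based, both inclusive; `NA` unless unique). Strand `-` means the
#'   read sequence matches the reverse complement of the forward genome.
#' @export
naive_align <- function(reads, genome, read_ids = NULL) {
  genome <- as_genome_chr(genome)
  if (is.null(read_ids)) {
    read_ids <- if (!is.null(names(reads))) names(reads) else
      paste0("read", seq_along(reads))
  }
  n <- length(reads)
  out <- data.frame(read_id = read_ids,
                    status = rep("unmapped", n),
                    chrom = rep(NA_character_, n),
                    strand = rep(NA_character_, n),
                    start = rep(NA_integer_, n), end = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  if (any(nchar(reads) < 20L)) stop("naive_align requires reads >= 20 nt")

  hits_n <- integer(length(reads))
  hit_chrom <- rep(NA_character_, length(reads))
  hit_strand <- rep(NA_character_, length(reads))
  hit_start <- rep(NA_integer_, length(reads))

  for (strand in c("+", "-")) {
    query <- if (strand == "+") reads else revcomp(reads)
    anchors <- Biostrings::DNAStringSet(substr(query, 1L, 20L))
    pd <- Biostrings::PDict(anchors)
    qlen <- nchar(query)
    for (chrom in names(genome)) {
      subject <- Biostrings::DNAString(genome[[chrom]])
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      idx <- which(lengths(starts) > 0L)
      if (!length(idx)) next
      cand_read <- rep(idx, lengths(starts)[idx])
      cand_start <- unlist(starts[idx], use.names = FALSE)
      # verify the full read matches at the anchored position
      full <- substring(genome[[chrom]], cand_start,
                        cand_start + qlen[cand_read] - 1L)
      ok <- full == query[cand_read]
      cand_read <- cand_read[ok]; cand_start <- cand_start[ok]
      if (!length(cand_read)) next
      tab <- tabulate(cand_read, nbins = length(reads))
      hits_n <- hits_n + tab
      first <- !duplicated(cand_read)
      fr <- cand_read[first]; fs <- cand_start[first]
      new <- is.na(hit_start[fr])
      hit_chrom[fr[new]] <- chrom
      hit_strand[fr[new]] <- strand
      hit_start[fr[new]] <- fs[new] - 1L  # to 0-based
    }
  }
  uniq <- hits_n == 1L
  out$status[hits_n >= 2L] <- "multi"
  out$status[uniq] <- "unique"
  out$chrom[uniq] <- hit_chrom[uniq]
  out$strand[uniq] <- hit_strand[uniq]
  out$start[uniq] <- hit_start[uniq]
  out$end[uniq] <- hit_start[uniq] + nchar(reads)[uniq] - 1L
  out
}

#' Keep only candidates whose untrimmed read failed to align
#'
#' A genuine poly(A) tail is added post-transcriptionally and must not be
#' encoded in the genome, so a candidate read that aligns end-to-end
#' \emph{before} tail trimming carries a templated "tail" and is discarded.
#'
#' @param candidate_ids character vector of candidate read ids.
#' @param untrimmed_alignments alignment data frame (as from [naive_align()])
#'   of the \emph{untrimmed} candidate reads; may be empty.
#' @return the surviving read ids.
#' @export
pretail_genomic_filter <- function(candidate_ids, untrimmed_alignments) {
  if (is.null(untrimmed_alignments) || nrow(untrimmed_alignments) == 0L) {
    warning("no untrimmed alignments supplied; keeping all candidates")
    return(candidate_ids)
  }
  unknown <- setdiff(untrimmed_alignments$read_id, candidate_ids)
  if (length(unknown)) {
    warning(sprintf("%d alignment record(s) reference unknown read ids; ignored",
                    length(unknown)))
  }
  aligned <- untrimmed_alignments$read_id[
    untrimmed_alignments$status != "unmapped"]
  setdiff(candidate_ids, aligned)
}

#' Call cleavage-site coordinates from trimmed-read alignments
#'
#' Multi-mapping and unmapped records are dropped; for a read uniquely
#' aligned to the + strand the cleavage position is the rightmost aligned
#' reference base, for the - strand the leftmost (the reads are already in
#' mRNA sense, so the alignment strand is the transcript strand).
#'
#' @param alignments alignment data frame of trimmed mRNA-sense reads.
#' @param genome genome (used for bounds checking of contig names).
#' @return data frame of cleavage events: `chrom`, `strand`, `position`
#'   (0-based last templated base), `read_id`.
#' @export
call_cleavage_events <- function(alignments, genome = NULL) {
  al <- alignments[alignments$status == "unique", , drop = FALSE]
  if (!is.null(genome)) {
    genome <- as_genome_chr(genome)
    bad <- !(al$chrom %in% names(genome))
    if (any(bad)) {
      stop("alignment references unknown contig: ", unique(al$chrom[bad])[1])
    }
  }
  data.frame(chrom = al$chrom, strand = al$strand,
             position = ifelse(al$strand == "+", al$end, al$start),
             read_id = al$read_id, stringsAsFactors = FALSE)
}

#' Remove internally primed cleavage events
#'
#' Examines the `window` genomic bases immediately downstream of each event
#' in mRNA sense (+ strand: positions pos+1..pos+window; - strand: reverse
#' complement of pos-window..pos-1) and drops the event when the A content
#' reaches `max_a` or the longest A run reaches `max_run`. Windows truncated
#' by a contig end scale both thresholds proportionally (rounding up); an
#' event with no downstream base at all is kept.
#'
#' @param events cleavage event data frame.
#' @param genome genome sequences.
#' @param params an [ip_filter_params()] object.
#' @return list with `kept` and `dropped` event data frames.
#' @export
internal_priming_filter <- function(events, genome,
                                    params = ip_filter_params()) {
  genome <- as_genome_chr(genome)
  if (nrow(events) == 0L) return(list(kept = events, dropped = events))
  clen <- nchar(genome)[events$chrom]
  plus <- events$strand == "+"
  ds_start <- ifelse(plus, events$position + 1L,
                     pmax(0L, events$position - params$window))
  ds_end <- ifelse(plus, pmin(clen - 1L, events$position + params$window),
                   events$position - 1L)
  w <- pmax(0L, ds_end - ds_start + 1L)
  win <- substring(genome[events$chrom], ds_start + 1L, ds_end + 1L)
  # on the - strand the mRNA-sense downstream A content equals the T content
  # of the forward-strand slice (run lengths are reversal-invariant)
  base <- ifelse(plus, "A", "T")
  a_count <- integer(nrow(events))
  a_run <- integer(nrow(events))
  nz <- w > 0L
  a_count[nz] <- ifelse(base[nz] == "A", char_count(win[nz], "A"),
                        char_count(win[nz], "T"))
  if (any(nz & !plus)) {
    a_run[nz & !plus] <- max_char_run(win[nz & !plus], "T")
  }
  if (any(nz & plus)) {
    a_run[nz & plus] <- max_char_run(win[nz & plus], "A")
  }
  thr_a <- ceiling(params$max_a * w / params$window)
  thr_run <- ceiling(params$max_run * w / params$window)
  drop <- nz & (a_count >= thr_a | a_run >= thr_run)
  list(kept = events[!drop, , drop = FALSE],
       dropped = events[drop, , drop = FALSE])
}

#' Read alignments from a SAM/BAM file into the internal alignment table
#'
#' Thin ingestion layer for alignments produced by an external end-to-end
#' aligner. Uniqueness is taken from the aligner's own reporting: records
#' flagged secondary, or primary records whose `XS` score tag indicates an
#' equally good secondary hit, are treated as multi-mapping. Requires the
#' Rsamtools package.
#'
#' @param path SAM or BAM file path (SAM is converted on the fly).
#' @return alignment data frame as produced by [naive_align()].
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("read_alignments() requires the Rsamtools package")
  }
  if (grepl("\\.sam$", path)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "mapq"),
    tag = c("AS", "XS"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  unmapped <- bitwAnd(b$flag, 4L) > 0L
  secondary <- bitwAnd(b$flag, 256L) > 0L
  multi <- rep(FALSE, length(b$qname))
  if (!is.null(b$tag$AS) && !is.null(b$tag$XS)) {
    multi <- !is.na(b$tag$XS) & !is.na(b$tag$AS) & b$tag$XS >= b$tag$AS
  }
  multi <- multi | b$qname %in% b$qname[secondary]
  status <- ifelse(unmapped, "unmapped", ifelse(multi, "multi", "unique"))
  keep <- !secondary
  data.frame(read_id = b$qname[keep], status = status[keep],
             chrom = as.character(b$rname)[keep],
             strand = as.character(b$strand)[keep],
             start = b$pos[keep] - 1L,
             end = b$pos[keep] - 1L + b$qwidth[keep] - 1L,
             stringsAsFactors = FALSE)
}
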