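#' Load gene models from GFF3 for PAC annotation
#'
#' Imports gene/mRNA/exon/CDS/UTR features, keeps the longest transcript per
#' gene (span length; ties broken by lexicographically smallest transcript
#' id), derives introns from exon gaps, and derives UTRs from exon-minus-CDS
#' when explicit UTR features are absent. GFF3 1-based inclusive coordinates
#' are converted to 0-based half-open internally.
#'
#' @param gff a GFF3 file path or a `GRanges` with `type`, `ID`, `Parent`
#'   metadata columns.
#' @return list of class `genome_annotation`: `genes` (gene_id, chrom,
#'   strand, start, end, longest_transcript, has_utr3), `features`
#'   (gene_id, transcript_id, chrom, strand, type in UTR5/CDS/intron/UTR3,
#'   start, end; longest transcripts only), `utr3_lengths` (named numeric,
#'   total 3'-UTR length per transcript over \emph{all} transcripts that
#'   have one), `n_transcripts`.
#' @export
load_annotation <- function(gff) {
  gr <- if (methods::is(gff, "GRanges")) gff else
    rtracklayer::import(gff, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- as.character(mc$ID)
  parent <- vapply(as.list(mc$Parent), function(p) {
    if (length(p) == 0L || !nzchar(p[1])) NA_character_ else p[1]
  }, character(1))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,   # 0-based half-open
                   end = GenomicRanges::end(gr),
                   type = type, ID = id, parent = parent,
                   stringsAsFactors = FALSE)

  genes <- df[df$type == "gene", , drop = FALSE]
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(genes) == 0L || nrow(tx) == 0L)
    stop("GFF3 contains no gene/mRNA features")
  tx$span <- tx$end - tx$start
  tx <- tx[order(tx$parent, -tx$span, tx$ID), , drop = FALSE]
  longest <- tx[!duplicated(tx$parent), , drop = FALSE]

  kids <- df[df$type %in% c("exon", "CDS", "five_prime_UTR",
                            "three_prime_UTR"), , drop = FALSE]
  # reject transcripts whose exons sit on mixed strands
  ex_strand <- tapply(kids$strand[kids$type == "exon"],
                      kids$parent[kids$type == "exon"],
                      function(s) length(unique(s)))
  mixed <- names(ex_strand)[ex_strand > 1L]
  if (length(mixed))
    stop("transcript with exons on mixed strands: ", mixed[1])

  # 3'-UTR length per transcript, over ALL transcripts (explicit features,
  # else derived from exon minus CDS on the 3' side)
  tx_feats <- function(tid, tstrand) {
    k <- kids[kids$parent == tid, , drop = FALSE]
    ex <- k[k$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- k[k$type == "CDS", , drop = FALSE]
    u5 <- k[k$type == "five_prime_UTR", c("start", "end"), drop = FALSE]
    u3 <- k[k$type == "three_prime_UTR", c("start", "end"), drop = FALSE]
    if (nrow(u5) == 0L && nrow(u3) == 0L && nrow(cds) > 0L) {
      # derive UTR intervals: exonic bases outside [cds_start, cds_end)
      cs <- min(cds$start); ce <- max(cds$end)
      left <- ex[ex$start < cs, , drop = FALSE]
      if (nrow(left)) left$end <- pmin(left$end, cs)
      right <- ex[ex$end > ce, , drop = FALSE]
      if (nrow(right)) right$start <- pmax(right$start, ce)
      if (tstrand == "+") {
        u5 <- left[, c("start", "end"), drop = FALSE]
        u3 <- right[, c("start", "end"), drop = FALSE]
      } else {
        u5 <- right[, c("start", "end"), drop = FALSE]
        u3 <- left[, c("start", "end"), drop = FALSE]
      }
    }
    introns <- NULL
    if (nrow(ex) > 1L) {
      introns <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
      introns <- introns[introns$end > introns$start, , drop = FALSE]
    }
    list(u5 = u5, u3 = u3, cds = cds[, c("start", "end"), drop = FALSE],
         introns = introns)
  }

  utr3_lengths <- numeric(0)
  for (i in seq_len(nrow(tx))) {
    f <- tx_feats(tx$ID[i], tx$strand[i])
    len <- if (nrow(f$u3)) sum(f$u3$end - f$u3$start) else 0
    if (len > 0) utr3_lengths[tx$ID[i]] <- len
  }

  feat_rows <- list()
  has_utr3 <- logical(nrow(longest))
  for (i in seq_len(nrow(longest))) {
    tid <- longest$ID[i]
    f <- tx_feats(tid, longest$strand[i])
    add <- function(tab, lab) {
      if (is.null(tab) || nrow(tab) == 0L) return(NULL)
      data.frame(gene_id = longest$parent[i], transcript_id = tid,
                 chrom = longest$chrom[i], strand = longest$strand[i],
                 type = lab, start = tab$start, end = tab$end,
                 stringsAsFactors = FALSE)
    }
    feat_rows[[i]] <- rbind(add(f$u5, "UTR5"), add(f$cds, "CDS"),
                            add(f$introns, "intron"), add(f$u3, "UTR3"))
    has_utr3[i] <- !is.null(f$u3) && nrow(f$u3) > 0L &&
      sum(f$u3$end - f$u3$start) > 0
  }
  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL

  genes_out <- data.frame(
    gene_id = genes$ID, chrom = genes$chrom, strand = genes$strand,
    start = genes$start, end = genes$end, stringsAsFactors = FALSE)
  m <- match(genes_out$gene_id, longest$parent)
  genes_out$longest_transcript <- longest$ID[m]
  genes_out$has_utr3 <- has_utr3[m]
  genes_out <- genes_out[!is.na(genes_out$longest_transcript), , drop = FALSE]
  rownames(genes_out) <- NULL

  structure(list(genes = genes_out, features = features,
                 utr3_lengths = utr3_lengths, n_transcripts = nrow(tx)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d genes (%d with 3'-UTR), %d transcripts\n",
    nrow(x$genes), sum(x$genes$has_utr3), x$n_transcripts))
  invisible(x)
}

#' 3'-UTR extension parameters
#'
#' @param ext extension in nt applied downstream of genes with an annotated
#'   3'-UTR (the median of the intergenic PAC distance distribution).
#' @param utr3_median median annotated 3'-UTR length across all transcripts.
#' @param max_assign_distance window over which the intergenic median is
#'   computed.
#' @return list of class `ext_params` with `no_utr3_ext = utr3_median + ext`,
#'   the extension applied to genes lacking an annotated 3'-UTR.
#' @export
ext_params <- function(ext = 150L, utr3_median = 310L,
                       max_assign_distance = 1000L) {
  structure(list(ext = as.integer(ext),
                 utr3_median = as.integer(utr3_median),
                 no_utr3_ext = as.integer(utr3_median + ext),
                 max_assign_distance = as.integer(max_assign_distance)),
            class = "ext_params")
}

# distance (in mRNA sense) from each position to the 3' end of the nearest
# upstream gene on the same chrom+strand, plus that gene's id and the
# room available before the next same-strand gene begins.
.upstream_gene_distance <- function(chrom, strand, position, genes) {
  n <- length(position)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_integer_, n),
                    room = rep(NA_integer_, n), stringsAsFactors = FALSE)
  for (key in unique(paste(chrom, strand))) {
    sel <- paste(chrom, strand) == key
    g <- genes[paste(genes$chrom, genes$strand) == key, , drop = FALSE]
    if (nrow(g) == 0L) next
    pos <- position[sel]
    if (g$strand[1] == "+") {
      ends <- sort(g$end - 1L)               # 0-based last gene base
      g <- g[order(g$end), , drop = FALSE]
      idx <- findInterval(pos - 1L, ends)    # nearest gene ending before pos
      ok <- idx >= 1L
      d <- ifelse(ok, pos - ends[pmax(idx, 1L)], NA_integer_)
      nxt_start <- c(g$start[-1L], Inf)
      room <- ifelse(ok, nxt_start[pmax(idx, 1L)] - 1L - ends[pmax(idx, 1L)],
                     NA_integer_)
      out$gene_id[sel] <- ifelse(ok, g$gene_id[pmax(idx, 1L)], NA)
    } else {
      starts <- sort(g$start)                # 0-based first base = 3' end
      g <- g[order(g$start), , drop = FALSE]
      idx <- findInterval(pos, starts) + 1L  # nearest gene starting after pos
      ok <- idx <= nrow(g)
      idx2 <- pmin(idx, nrow(g))
      d <- ifelse(ok, starts[idx2] - pos, NA_integer_)
      prev_end <- c(-Inf, g$end[-nrow(g)])
      room <- ifelse(ok, starts[idx2] - prev_end[idx2], NA_integer_)
      out$gene_id[sel] <- ifelse(ok, g$gene_id[idx2], NA)
    }
    out$distance[sel] <- as.integer(d)
    out$room[sel] <- as.integer(pmin(room, .Machine$integer.max))
  }
  out
}

#' Assign each PAC a genomic region
#'
#' The representative site of each PAC is tested against the features of the
#' longest transcript of every gene on the same chromosome and strand. PACs
#' inside annotated features are labelled by priority UTR3 > CDS > UTR5 >
#' intron (ties across genes: the gene with the nearest 3' end). Otherwise,
#' when `ext` parameters are supplied, a PAC within the data-driven extension
#' window downstream of a gene in mRNA sense (`ext` nt for genes with an
#' annotated 3'-UTR, `utr3_median + ext` nt for genes without one; never
#' crossing into the next same-strand gene) is labelled `extended_UTR3`.
#' Everything else is `intergenic`.
#'
#' @param pacs PAC data frame (from `cluster_sites()$pacs`).
#' @param annotation a `genome_annotation`.
#' @param ext an [ext_params()] object, or `NULL` for the first pass
#'   (no extension).
#' @return data frame: `pac_id`, `region`, `gene_id`, `distance` (nt
#'   downstream of the assigned/nearest gene 3' end; `NA` for genic PACs),
#'   `ambiguous` (overlapping features of several genes).
#' @export
assign_region <- function(pacs, annotation, ext = NULL) {
  stopifnot(inherits(annotation, "genome_annotation"))
  feats <- annotation$features
  priority <- c(UTR3 = 1L, CDS = 2L, UTR5 = 3L, intron = 4L)
  fgr <- GenomicRanges::GRanges(
    feats$chrom,
    IRanges::IRanges(feats$start + 1L, feats$end), strand = feats$strand)
  pgr <- GenomicRanges::GRanges(
    pacs$chrom,
    IRanges::IRanges(pacs$representative_position + 1L,
                     pacs$representative_position + 1L),
    strand = pacs$strand)
  hits <- GenomicRanges::findOverlaps(pgr, fgr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  n <- nrow(pacs)
  region <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)
  if (length(qh)) {
    genes <- annotation$genes
    g3end <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
    names(g3end) <- genes$gene_id
    ord <- order(qh, priority[feats$type[sh]],
                 abs(pacs$representative_position[qh] -
                       g3end[feats$gene_id[sh]]))
    qh <- qh[ord]; sh <- sh[ord]
    n_genes_hit <- tapply(feats$gene_id[sh], qh,
                          function(x) length(unique(x)))
    first <- !duplicated(qh)
    region[qh[first]] <- feats$type[sh[first]]
    gene_id[qh[first]] <- feats$gene_id[sh[first]]
    ambiguous[as.integer(names(n_genes_hit))] <- n_genes_hit > 1L
  }

  up <- .upstream_gene_distance(pacs$chrom, pacs$strand,
                                pacs$representative_position,
                                annotation$genes)
  distance <- ifelse(region == "intergenic", up$distance, NA_integer_)
  if (!is.null(ext)) {
    stopifnot(inherits(ext, "ext_params"))
    gmap <- annotation$genes
    hu <- stats::setNames(gmap$has_utr3, gmap$gene_id)
    e_gene <- ifelse(hu[up$gene_id], ext$ext, ext$no_utr3_ext)
    within <- region == "intergenic" & !is.na(up$distance) &
      up$distance > 0L & up$distance <= pmin(e_gene, up$room, na.rm = FALSE)
    within[is.na(within)] <- FALSE
    region[within] <- "extended_UTR3"
    gene_id[within] <- up$gene_id[within]
  }
  data.frame(pac_id = pacs$pac_id, region = region, gene_id = gene_id,
             distance = distance, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' Derive data-driven 3'-UTR extension parameters from intergenic PACs
#'
#' Runs a first-pass region assignment without extensions, measures for each
#' intergenic PAC the distance from its representative site to the 3' end of
#' the nearest upstream gene on the same strand, and sets the extension to
#' the rounded median of the distances within `(0, max_assign_distance]`.
#' The extension for genes lacking an annotated 3'-UTR additionally adds the
#' median 3'-UTR length over all annotated transcripts.
#'
#' @inheritParams assign_region
#' @param max_assign_distance distance window for the median (default 1000).
#' @param default_ext fallback extension when no intergenic PAC qualifies
#'   (a warning is emitted).
#' @return an [ext_params()] object.
#' @export
compute_extensions <- function(pacs, annotation,
                               max_assign_distance = 1000L,
                               default_ext = 150L) {
  pass1 <- assign_region(pacs, annotation, ext = NULL)
  d <- pass1$distance[pass1$region == "intergenic"]
  d <- d[!is.na(d) & d > 0L & d <= max_assign_distance]
  if (length(d) == 0L) {
    warning("no intergenic PAC within the assignment window; ",
            "using default extension of ", default_ext, " nt")
    ext <- as.integer(default_ext)
  } else {
    ext <- as.integer(round(stats::median(d)))
  }
  u3m <- as.integer(round(stats::median(annotation$utr3_lengths)))
  ext_params(ext = ext, utr3_median = u3m,
             max_assign_distance = max_assign_distance)
}

#' Compare PACs with known transcript termini
#'
#' Termini are first clustered with the same iterative 24-nt rule (unit
#' weights, leftmost site as representative); a clustered terminus is
#' supported when its distance to the nearest PAC interval on the same
#' chromosome and strand is at most `window` nt (0 when inside the span).
#'
#' @param pacs PAC data frame.
#' @param termini data frame with `chrom`, `strand`, `position` (0-based).
#' @param window agreement window in nt (default 24).
#' @return list: `termini` (clustered, with `nearest_distance` and
#'   `supported`), `supported_fraction`.
#' @export
compare_termini <- function(pacs, termini, window = 24L) {
  stop_if_not_df_cols(termini, c("chrom", "strand", "position"), "termini")
  sites <- termini
  sites$read_count <- 1L
  cl <- cluster_sites(aggregate_sites(
    data.frame(chrom = sites$chrom, strand = sites$strand,
               position = sites$position)), window = window, min_reads = 1L)
  reps <- cl$pacs[, c("chrom", "strand", "representative_position")]
  names(reps)[3] <- "position"
  dist <- rep(NA_integer_, nrow(reps))
  for (key in unique(paste(reps$chrom, reps$strand))) {
    sel <- which(paste(reps$chrom, reps$strand) == key)
    p <- pacs[paste(pacs$chrom, pacs$strand) == key, , drop = FALSE]
    if (nrow(p) == 0L) next
    dmat <- vapply(sel, function(i) {
      pos <- reps$position[i]
      min(pmax(0L, pmax(p$span_start - pos, pos - p$span_end)))
    }, numeric(1))
    dist[sel] <- as.integer(dmat)
  }
  reps$nearest_distance <- dist
  reps$supported <- !is.na(dist) & dist <= window
  list(termini = reps,
       supported_fraction = mean(reps$supported))
}

#' Validate intergenic PACs against externally assembled novel genes
#'
#' @param pacs PAC data frame.
#' @param assignments region assignments (from [assign_region()]).
#' @param novel_genes data frame of stranded intervals: `chrom`, `strand`,
#'   `start`, `end` (0-based, both ends inclusive).
#' @return data frame of intergenic PACs with a `validated` flag (the
#'   representative lies within a same-strand novel-gene interval).
#' @export
validate_intergenic <- function(pacs, assignments, novel_genes) {
  stop_if_not_df_cols(novel_genes, c("chrom", "strand", "start", "end"),
                      "novel_genes")
  inter <- pacs[assignments$region[match(pacs$pac_id, assignments$pac_id)] ==
                  "intergenic", , drop = FALSE]
  validated <- vapply(seq_len(nrow(inter)), function(i) {
    pos <- inter$representative_position[i]
    any(novel_genes$chrom == inter$chrom[i] &
          novel_genes$strand == inter$strand[i] &
          novel_genes$start <= pos & pos <= novel_genes$end)
  }, logical(1))
  inter$validated <- validated
  inter
}
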