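#' Configuration of the synthetic poly(A) truth set
#'
#' Bundles every tunable of the synthetic genome / annotation / read
#' generator. The defaults describe the study conditions the test-bed
#' emulates: a compact two-chromosome genome of high-entropy random sequence
#' carrying ~200 non-overlapping genes, a minority of which lack an annotated
#' 3'-UTR; per-gene poly(A) site counts drawn from a distribution averaging
#' ~1.75 sites per gene; a majority of multi-site genes dominated by one site
#' (usage > 0.7); cleavage micro-heterogeneity of a few nt around each true
#' site; planted genomic A-runs acting as internal-priming decoys; and
#' standard RNA-seq read mixtures in which only a few percent of reads carry
#' a non-templated poly(A) tail.
#'
#' @param seed integer seed; identical configurations reproduce identical
#'   outputs byte for byte.
#' @param n_chromosomes,chromosome_length genome shape (nt).
#' @param n_genes number of genes to place (error if they do not fit without
#'   overlap).
#' @param frac_genes_without_utr3 fraction of genes whose transcript lacks a
#'   three_prime_UTR feature; their true poly(A) sites lie downstream of the
#'   annotated gene end.
#' @param pacs_per_gene_weights probability vector over 1..4 true poly(A)
#'   sites per gene (must sum to 1).
#' @param dominant_gene_fraction fraction of multi-site genes whose top site
#'   usage exceeds 0.7.
#' @param heterogeneity_sd standard deviation (nt) of the rounded Normal
#'   spread of individual cleavage positions around each true site.
#' @param tail_length_range inclusive `[min, max]` of appended tail lengths.
#' @param read_length read length in nt; must exceed
#'   `max(tail_length_range) + 20` so every trimmed insert can pass the
#'   20-nt length filter.
#' @param n_reads total reads to simulate.
#' @param frac_polya_reads fraction of reads carrying a true poly(A) tail.
#' @param frac_decoy_reads fraction of reads ending in a planted genomic
#'   A-run (internal-priming decoys).
#' @param n_decoy_regions number of planted A-runs (>= 12 nt) outside gene
#'   neighbourhoods.
#' @param protocol `"unstranded_single"` or `"stranded_paired"`.
#' @param sequencing_error_rate per-base substitution probability.
#' @param nue_frac fraction of true sites with the near-upstream-element
#'   motif written into the genome 20-30 nt upstream in mRNA sense.
#' @param nue_motif the planted motif (DNA alphabet).
#' @param intron_site_prob probability that a multi-site gene places one
#'   non-dominant site in its intron instead of the 3'-UTR.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 300000L,
                       n_genes = 200L,
                       frac_genes_without_utr3 = 0.2,
                       pacs_per_gene_weights = c(0.50, 0.30, 0.15, 0.05),
                       dominant_gene_fraction = 0.55,
                       heterogeneity_sd = 2,
                       tail_length_range = c(10L, 25L),
                       read_length = 100L,
                       n_reads = 500000L,
                       frac_polya_reads = 0.05,
                       frac_decoy_reads = 0.01,
                       n_decoy_regions = 20L,
                       protocol = c("unstranded_single", "stranded_paired"),
                       sequencing_error_rate = 0.001,
                       nue_frac = 0.6,
                       nue_motif = "AATAAA",
                       intron_site_prob = 0.15) {
  protocol <- match.arg(protocol)
  fracs <- c(frac_genes_without_utr3, dominant_gene_fraction,
             frac_polya_reads, frac_decoy_reads, sequencing_error_rate,
             nue_frac, intron_site_prob)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (abs(sum(pacs_per_gene_weights) - 1) > 1e-8)
    stop("pacs_per_gene_weights must sum to 1")
  if (length(pacs_per_gene_weights) != 4L)
    stop("pacs_per_gene_weights must have length 4 (sites per gene 1..4)")
  if (frac_polya_reads + frac_decoy_reads > 1)
    stop("frac_polya_reads + frac_decoy_reads must not exceed 1")
  if (tail_length_range[1] > tail_length_range[2] || tail_length_range[1] < 1)
    stop("invalid tail_length_range")
  if (read_length <= tail_length_range[2] + 20L)
    stop("read_length must exceed max tail length + 20 nt, otherwise ",
         "trimmed inserts could fail the 20-nt length filter")
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_genes = as.integer(n_genes),
    frac_genes_without_utr3 = frac_genes_without_utr3,
    pacs_per_gene_weights = pacs_per_gene_weights,
    dominant_gene_fraction = dominant_gene_fraction,
    heterogeneity_sd = heterogeneity_sd,
    tail_length_range = as.integer(tail_length_range),
    read_length = as.integer(read_length),
    n_reads = as.integer(n_reads),
    frac_polya_reads = frac_polya_reads,
    frac_decoy_reads = frac_decoy_reads,
    n_decoy_regions = as.integer(n_decoy_regions),
    protocol = protocol,
    sequencing_error_rate = sequencing_error_rate,
    nue_frac = nue_frac, nue_motif = toupper(nue_motif),
    intron_site_prob = intron_site_prob), class = "sim_config")
}

# Draw per-gene usage fractions. Dominant genes get one site > 0.7 with
# margin; non-dominant genes keep every usage comfortably below 0.7 so the
# strong/medium distinction is identifiable at moderate read depth.
.draw_usages <- function(k, dominant) {
  if (k == 1L) return(1)
  if (dominant) {
    top <- stats::runif(1, 0.76, 0.90)
    w <- stats::runif(k - 1L, 0.8, 1.2)
    u <- c(top, (1 - top) * w / sum(w))
  } else if (k == 2L) {
    top <- stats::runif(1, 0.52, 0.62)
    u <- c(top, 1 - top)
  } else {
    w <- stats::runif(k, 0.8, 1.2)
    u <- sort(w / sum(w), decreasing = TRUE)
  }
  u
}

# Place k mRNA-sense offsets with pairwise spacing >= 60 inside [lo, hi].
.spaced_offsets <- function(k, lo, hi, spacing = 60L) {
  avail <- (hi - lo) - (k - 1L) * spacing
  if (avail < 0) stop("region too short to place ", k, " spaced sites")
  extra <- sort(stats::runif(k, 0, avail))
  as.integer(round(lo + extra + (seq_len(k) - 1L) * spacing))
}

#' Simulate a genome, annotation and poly(A)-site truth table
#'
#' Builds `n_chromosomes` of uniform random sequence, places non-overlapping
#' genes (5'-UTR, two CDS exons, one intron, optional 3'-UTR), draws 1-4 true
#' poly(A) sites per gene with usage fractions, writes the NUE motif into a
#' fraction of site upstream regions, and plants A-run decoy regions in
#' intergenic space away from genes and true sites.
#'
#' Genes lacking a 3'-UTR place their sites 40-260 nt downstream of the
#' annotated gene end (truth label `downstream`); all other sites sit inside
#' the 3'-UTR except for occasional intronic sites.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `truth_sites.tsv` and `decoy_regions.tsv`.
#' @return list of class `pac_sim`: `genome` (named character), `gff`
#'   (GRanges of gene/mRNA/exon/CDS/UTR features), `genes`, `truth` (one row
#'   per true site: `gene_id`, `chrom`, `strand`, `true_site_position`
#'   0-based, `usage_fraction`, `region_label`), `decoys`, `config`.
#' @export
simulate_genome <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  genome <- vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chromosome_length,
                 replace = TRUE), collapse = "")
  }, character(1))

  # --- gene placement -------------------------------------------------
  n_no_utr3 <- round(cfg$frac_genes_without_utr3 * cfg$n_genes)
  no_utr3 <- rep(FALSE, cfg$n_genes)
  if (n_no_utr3 > 0) no_utr3[sample.int(cfg$n_genes, n_no_utr3)] <- TRUE

  genes <- vector("list", cfg$n_genes)
  cursors <- stats::setNames(rep(600L, cfg$n_chromosomes), chroms)
  chrom_of <- chroms[(seq_len(cfg$n_genes) - 1L) %% cfg$n_chromosomes + 1L]
  for (i in seq_len(cfg$n_genes)) {
    u5 <- sample(80:150, 1); c1 <- sample(200:400, 1)
    intr <- sample(150:300, 1); c2 <- sample(200:400, 1)
    u3 <- if (no_utr3[i]) 0L else sample(250:400, 1)
    glen <- u5 + c1 + intr + c2 + u3
    gap <- sample(800:1500, 1)
    ch <- chrom_of[i]
    s <- cursors[[ch]]
    if (s + glen + 600L > cfg$chromosome_length) {
      stop(sprintf(
        "cannot place gene %d on %s without overlap: increase chromosome_length or reduce n_genes",
        i, ch))
    }
    cursors[[ch]] <- s + glen + gap
    genes[[i]] <- data.frame(
      gene_id = sprintf("G%04d", i), chrom = ch,
      strand = sample(c("+", "-"), 1),
      start = s, end = s + glen,                 # 0-based half-open
      u5 = u5, cds1 = c1, intron = intr, cds2 = c2, u3 = u3,
      has_utr3 = !no_utr3[i], stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)

  # mRNA-sense feature intervals (0-based half-open) for one gene
  gene_features <- function(g) {
    segs <- c(UTR5 = g$u5, CDS1 = g$cds1, intron = g$intron,
              CDS2 = g$cds2, UTR3 = g$u3)
    if (g$strand == "+") {
      e <- g$start + cumsum(segs); s <- c(g$start, utils::head(e, -1))
    } else {
      s <- g$end - cumsum(segs)
      e <- g$end - c(0, utils::head(cumsum(segs), -1))
    }
    data.frame(type = names(segs), start = as.integer(s),
               end = as.integer(e), stringsAsFactors = FALSE)
  }

  # --- true sites ------------------------------------------------------
  k_per_gene <- sample(1:4, cfg$n_genes, replace = TRUE,
                       prob = cfg$pacs_per_gene_weights)
  truth <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    g <- genes[i, ]
    k <- k_per_gene[i]
    dominant <- k > 1L && stats::runif(1) < cfg$dominant_gene_fraction
    usage <- .draw_usages(k, dominant)
    feats <- gene_features(g)
    if (g$has_utr3) {
      u3row <- feats[feats$type == "UTR3", ]
      offs <- .spaced_offsets(k, 40L, g$u3 - 15L)
      region <- rep("UTR3", k)
      # optionally move one non-dominant site into the intron
      if (k >= 2L && stats::runif(1) < cfg$intron_site_prob &&
          g$intron >= 150L) {
        region[k] <- "intron"
      }
      pos <- integer(k)
      for (j in seq_len(k)) {
        frow <- feats[feats$type == ifelse(region[j] == "intron",
                                           "intron", "UTR3"), ]
        off <- if (region[j] == "intron") sample(40:(g$intron - 15L), 1)
               else offs[j]
        pos[j] <- if (g$strand == "+") frow$start + off
                  else frow$end - 1L - off
      }
    } else {
      d <- .spaced_offsets(k, 40L, 260L)
      pos <- if (g$strand == "+") (g$end - 1L) + d else g$start - d
      region <- rep("downstream", k)
    }
    truth[[i]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      true_site_position = pos, usage_fraction = usage,
      region_label = region, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # --- plant the NUE motif upstream of a fraction of sites -------------
  motif <- cfg$nue_motif
  mlen <- nchar(motif)
  plant <- stats::runif(nrow(truth)) < cfg$nue_frac
  truth$nue_planted <- plant
  for (j in which(plant)) {
    p <- -sample(21:30, 1)   # motif start, mRNA-sense offset from site
    ch <- truth$chrom[j]; pos <- truth$true_site_position[j]
    if (truth$strand[j] == "+") {
      a <- pos + p                       # 0-based motif start
      substr(genome[[ch]], a + 1L, a + mlen) <- motif
    } else {
      a <- pos - p - (mlen - 1L)
      substr(genome[[ch]], a + 1L, a + mlen) <- revcomp(motif)
    }
  }

  # --- decoy A-runs ----------------------------------------------------
  forbidden <- rbind(
    data.frame(chrom = genes$chrom, start = genes$start - 300L,
               end = genes$end + 600L),
    data.frame(chrom = truth$chrom,
               start = truth$true_site_position - 400L,
               end = truth$true_site_position + 400L))
  decoys <- NULL
  if (cfg$n_decoy_regions > 0) {
    placed <- 0L; tries <- 0L
    rows <- vector("list", cfg$n_decoy_regions)
    while (placed < cfg$n_decoy_regions) {
      tries <- tries + 1L
      if (tries > 1000L * cfg$n_decoy_regions)
        stop("could not place decoy regions away from genes and sites")
      ch <- sample(chroms, 1)
      run <- sample(12:18, 1)
      s <- sample.int(cfg$chromosome_length - 2L * cfg$read_length, 1) +
        cfg$read_length
      e <- s + run                       # 0-based half-open
      f <- forbidden[forbidden$chrom == ch, , drop = FALSE]
      if (any(s < f$end & e > f$start)) next
      if (placed > 0L) {
        prev <- do.call(rbind, rows[seq_len(placed)])
        if (any(prev$chrom == ch & s < prev$end + 200L &
                e > prev$start - 200L)) next
      }
      strand <- sample(c("+", "-"), 1)
      base <- if (strand == "+") "A" else "T"
      substr(genome[[ch]], s + 1L, e) <- strrep(base, run)
      placed <- placed + 1L
      rows[[placed]] <- data.frame(chrom = ch, strand = strand,
                                   start = s, end = e, run_length = run,
                                   stringsAsFactors = FALSE)
    }
    decoys <- do.call(rbind, rows)
    decoys$decoy_id <- sprintf("D%03d", seq_len(nrow(decoys)))
  } else {
    decoys <- data.frame(chrom = character(0), strand = character(0),
                         start = integer(0), end = integer(0),
                         run_length = integer(0), decoy_id = character(0),
                         stringsAsFactors = FALSE)
  }

  gff <- .build_gff(genes, gene_features)
  sim <- structure(list(genome = genome, gff = gff, genes = genes,
                        truth = truth, decoys = decoys, config = cfg),
                   class = "pac_sim")
  if (!is.null(outdir)) write_sim(sim, outdir)
  sim
}

# Assemble the GRanges mirror of the annotation: gene/mRNA/exon/CDS/UTR
# features with ID/Parent attributes, ready for GFF3 export. A tenth of the
# genes get a second, shorter transcript (first exon only) so that
# longest-transcript selection is exercised downstream.
.build_gff <- function(genes, gene_features) {
  recs <- list()
  add <- function(chrom, strand, start, end, type, id = NA, parent = NA) {
    recs[[length(recs) + 1L]] <<- data.frame(
      chrom = chrom, strand = strand, start = start, end = end,
      type = type, ID = id, Parent = parent, phase = NA_integer_,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- g$gene_id; tid <- paste0(gid, ".t1")
    add(g$chrom, g$strand, g$start, g$end, "gene", gid)
    add(g$chrom, g$strand, g$start, g$end, "mRNA", tid, gid)
    f <- gene_features(g)
    f <- f[f$end > f$start, , drop = FALSE]
    # exon1 = UTR5 + CDS1, exon2 = CDS2 + UTR3 (mRNA order)
    rng <- function(types) {
      sub <- f[f$type %in% types, , drop = FALSE]
      c(min(sub$start), max(sub$end))
    }
    ex1 <- rng(c("UTR5", "CDS1")); ex2 <- rng(c("CDS2", "UTR3"))
    add(g$chrom, g$strand, ex1[1], ex1[2], "exon", parent = tid)
    add(g$chrom, g$strand, ex2[1], ex2[2], "exon", parent = tid)
    c1len <- with(f[f$type == "CDS1", ], end - start)
    for (tt in c("CDS1", "CDS2")) {
      r <- f[f$type == tt, ]
      add(g$chrom, g$strand, r$start, r$end, "CDS", parent = tid)
      recs[[length(recs)]]$phase <-
        if (tt == "CDS1") 0L else (3L - c1len %% 3L) %% 3L
    }
    r <- f[f$type == "UTR5", ]
    add(g$chrom, g$strand, r$start, r$end, "five_prime_UTR", parent = tid)
    if (any(f$type == "UTR3")) {
      r <- f[f$type == "UTR3", ]
      add(g$chrom, g$strand, r$start, r$end, "three_prime_UTR", parent = tid)
    }
    if (i %% 10L == 0L) {  # a deterministic minority of two-transcript genes
      tid2 <- paste0(gid, ".t2")
      add(g$chrom, g$strand, ex1[1], ex1[2], "mRNA", tid2, gid)
      add(g$chrom, g$strand, ex1[1], ex1[2], "exon", parent = tid2)
    }
  }
  df <- do.call(rbind, recs)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$source <- "pacscan_sim"
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  gr
}

#' Write a simulated truth set to disk
#'
#' @param sim a `pac_sim` object.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(g, file.path(outdir, "genome.fa"))
  rtracklayer::export(sim$gff, file.path(outdir, "annotation.gff3"),
                      format = "gff3")
  write_tsv_table(sim$truth, file.path(outdir, "truth_sites.tsv"))
  write_tsv_table(sim$decoys, file.path(outdir, "decoy_regions.tsv"))
  invisible(outdir)
}

# Introduce substitution errors at the configured per-base rate.
.apply_errors <- function(reads, rate) {
  if (rate <= 0) return(list(reads = reads, n_errors = integer(length(reads))))
  nc <- nchar(reads)
  n_err <- stats::rbinom(length(reads), nc, rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    at <- sample.int(nc[i], n_err[i])
    for (p in at) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  list(reads = reads, n_errors = n_err)
}

#' Simulate RNA-seq reads from a synthetic truth set
#'
#' Draws signal reads whose template ends at a cleavage site (the true site
#' plus rounded Normal micro-heterogeneity) followed by a non-templated A-run
#' of uniform random length, background fragments from anywhere in the
#' genome, and decoy reads whose template runs into a planted genomic A-run
#' (so the "tail" is templated). Reads are oriented per protocol and subject
#' to per-base substitution errors.
#'
#' @param sim `pac_sim` object from [simulate_genome()].
#' @param config optional override of `sim$config`.
#' @param outdir optional directory for FASTQ output (`reads.fastq`, or
#'   `reads_1.fastq`/`reads_2.fastq` for the paired protocol) and the
#'   read-level truth TSV.
#' @return list of class `pac_reads`: `reads` (named character vector; mate 1
#'   under the paired protocol), `reads2` (mate 2 or `NULL`), `truth` (one
#'   row per fragment: `read_id`, `label` in \{signal, background, decoy\},
#'   origin gene, true site, actual cleavage position, tail length, error
#'   count), `config`.
#' @export
simulate_reads <- function(sim, config = sim$config, outdir = NULL) {
  stopifnot(inherits(sim, "pac_sim"), inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  genome <- sim$genome
  clen <- nchar(genome)
  n <- cfg$n_reads
  lab <- sample(c("signal", "decoy", "background"), n, replace = TRUE,
                prob = c(cfg$frac_polya_reads, cfg$frac_decoy_reads,
                         1 - cfg$frac_polya_reads - cfg$frac_decoy_reads))
  if (cfg$frac_polya_reads == 0) lab[lab == "signal"] <- "background"

  truth <- data.frame(read_id = sprintf("r%07d", seq_len(n)), label = lab,
                      gene_id = NA_character_, chrom = NA_character_,
                      strand = NA_character_, true_site = NA_integer_,
                      cleavage_pos = NA_integer_, tail_length = NA_integer_,
                      stringsAsFactors = FALSE)
  reads <- character(n)

  # --- signal ----------------------------------------------------------
  is_sig <- which(lab == "signal")
  if (length(is_sig)) {
    st <- sim$truth
    site_idx <- sample(seq_len(nrow(st)), length(is_sig), replace = TRUE,
                       prob = st$usage_fraction / sum(st$usage_fraction))
    jit <- as.integer(round(stats::rnorm(length(is_sig), 0,
                                         cfg$heterogeneity_sd)))
    tl <- sample(cfg$tail_length_range[1]:cfg$tail_length_range[2],
                 length(is_sig), replace = TRUE)
    ins <- cfg$read_length - tl
    ch <- st$chrom[site_idx]; str <- st$strand[site_idx]
    pos <- st$true_site_position[site_idx] +
      ifelse(str == "+", jit, -jit)       # move along mRNA sense
    pos <- pmax(pmin(pos, clen[ch] - cfg$read_length - 1L), cfg$read_length)
    plus <- str == "+"
    s1 <- ifelse(plus, pos - ins + 1L, pos) + 1L       # 1-based
    e1 <- s1 + ins - 1L
    tmpl <- substring(genome[ch], s1, e1)
    if (any(!plus)) tmpl[!plus] <- revcomp(tmpl[!plus])
    reads[is_sig] <- paste0(tmpl, strrep("A", tl))
    truth$gene_id[is_sig] <- st$gene_id[site_idx]
    truth$chrom[is_sig] <- ch
    truth$strand[is_sig] <- str
    truth$true_site[is_sig] <- st$true_site_position[site_idx]
    truth$cleavage_pos[is_sig] <- pos
    truth$tail_length[is_sig] <- tl
  }

  # --- decoys ----------------------------------------------------------
  is_dec <- which(lab == "decoy")
  if (length(is_dec) && nrow(sim$decoys)) {
    di <- sample(seq_len(nrow(sim$decoys)), length(is_dec), replace = TRUE)
    d <- sim$decoys[di, ]
    # template ends inside the A-run leaving >= 12 terminal templated A
    slack <- pmax(d$run_length - 12L, 0L)
    off <- as.integer(floor(stats::runif(length(is_dec)) * (slack + 1L)))
    plus <- d$strand == "+"
    endp <- ifelse(plus, d$end - 1L - off, d$start + off)  # 0-based last base
    s1 <- ifelse(plus, endp - cfg$read_length + 1L, endp) + 1L
    e1 <- s1 + cfg$read_length - 1L
    tmpl <- substring(genome[d$chrom], s1, e1)
    if (any(!plus)) tmpl[!plus] <- revcomp(tmpl[!plus])
    reads[is_dec] <- tmpl
    truth$chrom[is_dec] <- d$chrom
    truth$strand[is_dec] <- d$strand
    truth$cleavage_pos[is_dec] <- endp
  } else if (length(is_dec)) {
    lab[is_dec] <- "background"
    truth$label[is_dec] <- "background"
  }

  # --- background ------------------------------------------------------
  is_bg <- which(truth$label == "background")
  if (length(is_bg)) {
    ch <- sample(names(genome), length(is_bg), replace = TRUE)
    str <- sample(c("+", "-"), length(is_bg), replace = TRUE)
    s1 <- as.integer(floor(stats::runif(length(is_bg)) *
                             (clen[ch] - cfg$read_length))) + 1L
    tmpl <- substring(genome[ch], s1, s1 + cfg$read_length - 1L)
    minus <- str == "-"
    if (any(minus)) tmpl[minus] <- revcomp(tmpl[minus])
    reads[is_bg] <- tmpl
    truth$chrom[is_bg] <- ch
    truth$strand[is_bg] <- str
  }

  err <- .apply_errors(reads, cfg$sequencing_error_rate)
  reads <- err$reads
  truth$n_errors <- err$n_errors

  if (cfg$protocol == "unstranded_single") {
    flip <- stats::runif(n) < 0.5
    reads[flip] <- revcomp(reads[flip])
    truth$emitted_orientation <- ifelse(flip, "antisense", "sense")
    names(reads) <- truth$read_id
    out <- structure(list(reads = reads, reads2 = NULL, truth = truth,
                          config = cfg), class = "pac_reads")
  } else {
    r2 <- reads                      # mate 2: mRNA sense, 3' A tail
    r1 <- revcomp(reads)             # mate 1: antisense, 5' T tail
    names(r1) <- names(r2) <- truth$read_id
    truth$emitted_orientation <- "paired"
    out <- structure(list(reads = r1, reads2 = r2, truth = truth,
                          config = cfg), class = "pac_reads")
  }
  if (!is.null(outdir)) write_reads(out, outdir)
  out
}

#' Write simulated reads as FASTQ plus the read-level truth table
#'
#' @param rd a `pac_reads` object.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_reads <- function(rd, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, path) {
    ss <- Biostrings::DNAStringSet(x)
    q <- Biostrings::BStringSet(strrep("I", Biostrings::width(ss)))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q)
  }
  if (is.null(rd$reads2)) {
    wr(rd$reads, file.path(outdir, "reads.fastq"))
  } else {
    wr(rd$reads, file.path(outdir, "reads_1.fastq"))
    wr(rd$reads2, file.path(outdir, "reads_2.fastq"))
  }
  write_tsv_table(rd$truth, file.path(outdir, "read_truth.tsv"))
  invisible(outdir)
}
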