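#' Run the full poly(A)-site discovery pipeline on simulated data
#'
#' Orchestrates tail scanning, the post-transcriptional (pre-tail) genomic
#' filter, trimmed-read alignment with the built-in exact aligner, cleavage
#' event calling, internal-priming filtering, site aggregation and 24-nt
#' clustering, two-pass region annotation with data-driven 3'-UTR extension,
#' APA classification, micro-heterogeneity statistics and sequence profiles
#' around the discovered PACs.
#'
#' @param sim `pac_sim` from [simulate_genome()] (provides genome and
#'   annotation).
#' @param reads `pac_reads` from [simulate_reads()].
#' @param tails a [tail_params()] object; its protocol should match the
#'   read protocol.
#' @param ip an [ip_filter_params()] object.
#' @param window clustering window in nt (default 24).
#' @param min_reads minimum reads per cleavage site (default 3).
#' @param threshold RE threshold for strong PACs (default 0.7).
#' @param nue_region hexamer search region in window coordinates
#'   (default -40..-10).
#' @param up,down profile window extent around sites (defaults 300/100).
#' @param termini optional known transcript termini
#'   (`chrom`/`strand`/`position`) for the agreement analysis.
#' @param novel_genes optional novel-gene intervals for intergenic PAC
#'   validation.
#' @param outdir optional directory for TSV/BED outputs.
#' @return list of class `pacscan_run`; see the elements written by the
#'   function (notably `pac_set`, `assignments`, `ext`, `profiles`,
#'   `classes`, `rank_fractions`, `heterogeneity`, `composition`, `chi2`,
#'   `nue`, `manifest`).
#' @export
run_pipeline <- function(sim, reads, tails = NULL, ip = ip_filter_params(),
                         window = 24L, min_reads = 3L, threshold = 0.7,
                         nue_region = c(-40L, -10L), up = 300L, down = 100L,
                         termini = NULL, novel_genes = NULL, outdir = NULL) {
  stopifnot(inherits(sim, "pac_sim"), inherits(reads, "pac_reads"))
  paired <- !is.null(reads$reads2)
  if (is.null(tails)) {
    tails <- tail_params(protocol = if (paired) "stranded" else "unstranded",
                         seed = reads$config$seed)
  }
  genome <- sim$genome

  # 1. terminal-tail scan ------------------------------------------------
  if (!paired) {
    scans <- scan_tails(reads$reads, tails)
    untrimmed <- reads$reads
  } else {
    s1 <- scan_tails(reads$reads, tails, mate = 1L,
                     read_ids = paste0(names(reads$reads), "/1"))
    s2 <- scan_tails(reads$reads2, tails, mate = 2L,
                     read_ids = paste0(names(reads$reads2), "/2"))
    scans <- rbind(s1, s2)
    untrimmed <- c(stats::setNames(reads$reads,
                                   paste0(names(reads$reads), "/1")),
                   stats::setNames(reads$reads2,
                                   paste0(names(reads$reads2), "/2")))
  }
  cand <- scans[scans$tail_end != "none", , drop = FALSE]

  # 2. post-transcriptional check: untrimmed candidates must not align ----
  un_al <- naive_align(untrimmed[cand$read_id], genome,
                       read_ids = cand$read_id)
  survivors <- pretail_genomic_filter(cand$read_id, un_al)
  cand <- cand[cand$read_id %in% survivors, , drop = FALSE]

  # 3. trim, filter, align in mRNA sense, call events ---------------------
  trimmed <- trim_and_filter(cand, tails)
  al <- naive_align(trimmed$mrna_sense, genome, read_ids = trimmed$read_id)
  events_raw <- call_cleavage_events(al, genome)
  ipres <- internal_priming_filter(events_raw, genome, ip)
  events <- ipres$kept

  # 4. sites, clustering, heterogeneity ----------------------------------
  sites <- aggregate_sites(events)
  pac_set <- cluster_sites(sites, window = window, min_reads = min_reads)
  het <- heterogeneity_stats(sites, pac_set, window = window,
                             min_reads = min_reads)

  # 5. two-pass annotation -----------------------------------------------
  ann <- load_annotation(sim$gff)
  extp <- compute_extensions(pac_set$pacs, ann)
  assignments <- assign_region(pac_set$pacs, ann, extp)

  # 6. APA quantification ------------------------------------------------
  profiles <- gene_profiles(pac_set$pacs, assignments)
  classes <- classify_pacs(profiles, threshold = threshold)
  rank_fracs <- rank_read_fractions(profiles)

  # 7. sequence context --------------------------------------------------
  composition <- list(); chi2 <- list(); nue <- list()
  regions <- split(pac_set$pacs,
                   assignments$region[match(pac_set$pacs$pac_id,
                                            assignments$pac_id)])
  for (rg in names(regions)) {
    if (nrow(regions[[rg]]) < 5L) next
    ws <- extract_windows(genome, regions[[rg]], up = up, down = down)
    if (length(ws) < 5L) next
    composition[[rg]] <- position_composition(ws)
    sc <- hexamer_scan(ws, region = nue_region, up = up, once = TRUE)
    nue[[rg]] <- motif_zscore(sc)
  }
  if (!is.null(composition$UTR3)) {
    for (rg in setdiff(names(composition), "UTR3")) {
      chi2[[rg]] <- chi2_compare(composition[[rg]], composition$UTR3)
    }
  }

  term_cmp <- if (!is.null(termini))
    compare_termini(pac_set$pacs, termini, window = window) else NULL
  novel_val <- if (!is.null(novel_genes))
    validate_intergenic(pac_set$pacs, assignments, novel_genes) else NULL

  manifest <- list(
    protocol = reads$config$protocol,
    n_reads = length(reads$reads) * (1L + paired),
    n_candidates = nrow(scans[scans$tail_end != "none", ]),
    n_posttranscriptional = length(survivors),
    n_trimmed_kept = nrow(trimmed),
    n_unique_alignments = sum(al$status == "unique"),
    n_events = nrow(events),
    n_ip_dropped = nrow(ipres$dropped),
    n_sites = nrow(sites),
    n_sites_filtered = sum(sites$read_count >= min_reads),
    n_pacs = nrow(pac_set$pacs),
    region_counts = table(assignments$region),
    label_counts = table(classes$pac_labels$label),
    params = list(window = window, min_reads = min_reads,
                  threshold = threshold, ip = unclass(ip),
                  tails = unclass(tails), ext = unclass(extp)))

  run <- structure(list(
    events = events, sites = sites, pac_set = pac_set,
    heterogeneity = het, annotation = ann, ext = extp,
    assignments = assignments, profiles = profiles, classes = classes,
    rank_fractions = rank_fracs, composition = composition, chi2 = chi2,
    nue = nue, termini = term_cmp, novel_validation = novel_val,
    manifest = manifest), class = "pacscan_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.pacscan_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0(
    "pacscan_run: %d reads -> %d tail candidates -> %d post-transcriptional\n",
    "  -> %d events (%d IP-dropped) -> %d sites -> %d PACs\n"),
    m$n_reads, m$n_candidates, m$n_posttranscriptional, m$n_events,
    m$n_ip_dropped, m$n_sites, m$n_pacs))
  invisible(x)
}

#' Write the tabular outputs of a pipeline run
#'
#' Emits events, sites, the PAC table (TSV and BED6 with the span as the
#' interval and total support as the score), member sites, region
#' assignments, APA profiles and labels, rank fractions, heterogeneity
#' summary and the NUE motif tables.
#'
#' @param run a `pacscan_run`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(run$events, file.path(outdir, "cleavage_events.tsv"))
  write_tsv_table(run$sites, file.path(outdir, "cleavage_sites.tsv"))
  write_tsv_table(run$pac_set$pacs, file.path(outdir, "pacs.tsv"))
  write_tsv_table(run$pac_set$members, file.path(outdir, "pac_members.tsv"))
  p <- run$pac_set$pacs
  bed <- data.frame(p$chrom, p$span_start, p$span_end + 1L, p$pac_id,
                    p$total_support, p$strand)
  utils::write.table(bed, file.path(outdir, "pacs.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv_table(run$assignments, file.path(outdir, "assignments.tsv"))
  write_tsv_table(run$profiles, file.path(outdir, "apa_profiles.tsv"))
  write_tsv_table(run$classes$pac_labels, file.path(outdir, "pac_labels.tsv"))
  write_tsv_table(run$classes$gene_classes,
                  file.path(outdir, "gene_classes.tsv"))
  write_tsv_table(run$rank_fractions, file.path(outdir, "rank_fractions.tsv"))
  het <- run$heterogeneity
  write_tsv_table(
    data.frame(stat = c("frac_multisite_pacs", "mean_sites_per_pac",
                        "sd_sites_per_pac", "frac_span_le_window",
                        "frac_adjacent_le_window", "pearson_r_lnln"),
               value = c(het$frac_multisite_pacs, het$mean_sites_per_pac,
                         het$sd_sites_per_pac, het$frac_span_le_window,
                         het$frac_adjacent_le_window, het$pearson_r_lnln)),
    file.path(outdir, "heterogeneity.tsv"))
  if (length(het$adjacent_distances)) {
    h <- table(het$adjacent_distances)
    write_tsv_table(data.frame(distance = as.integer(names(h)),
                               count = as.integer(h)),
                    file.path(outdir, "adjacent_distance_hist.tsv"))
  }
  for (rg in names(run$nue)) {
    write_tsv_table(run$nue[[rg]],
                    file.path(outdir, paste0("nue_", rg, ".tsv")))
  }
  invisible(outdir)
}

#' Summary tables mirroring the standard figures of a PAC survey
#'
#' @param run a `pacscan_run`.
#' @return list of data frames: `region_distribution` (region, n, pct),
#'   `pac_categories` (label, n_pacs, pct_pacs, n_genes, pct_genes),
#'   `rank_fractions`, `adjacent_distance_hist`, `nue_top` (top five motifs
#'   per region category).
#' @export
summarize_run <- function(run) {
  stopifnot(inherits(run, "pacscan_run"))
  rc <- table(run$assignments$region)
  region_distribution <- data.frame(
    region = names(rc), n = as.integer(rc),
    pct = 100 * as.integer(rc) / sum(rc), stringsAsFactors = FALSE)

  pl <- run$classes$pac_labels
  gc <- run$classes$gene_classes
  labs <- c("unique", "strong", "weak", "medium")
  n_pacs <- vapply(labs, function(l) sum(pl$label == l), integer(1))
  n_genes <- vapply(labs, function(l) {
    if (l == "weak") sum(gc$class == "strong")
    else sum(gc$class == l)
  }, integer(1))
  pac_categories <- data.frame(
    label = labs, n_pacs = n_pacs,
    pct_pacs = 100 * n_pacs / max(sum(n_pacs), 1L),
    n_genes = n_genes,
    pct_genes = 100 * n_genes / max(nrow(gc), 1L),
    stringsAsFactors = FALSE)

  h <- table(run$heterogeneity$adjacent_distances)
  adjacent_distance_hist <- data.frame(distance = as.integer(names(h)),
                                       count = as.integer(h))
  nue_top <- do.call(rbind, lapply(names(run$nue), function(rg) {
    top <- utils::head(run$nue[[rg]], 5L)
    if (nrow(top)) cbind(region = rg, top) else NULL
  }))
  list(region_distribution = region_distribution,
       pac_categories = pac_categories,
       rank_fractions = run$rank_fractions,
       adjacent_distance_hist = adjacent_distance_hist,
       nue_top = nue_top)
}
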