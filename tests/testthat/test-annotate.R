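# Hand-built GRanges annotation (coordinates 1-based inclusive, as in GFF3).
mk_gr <- function(rows) {
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$ID <- rows$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(rows$Parent, function(p) if (is.na(p)) character(0) else p))
  gr
}

row <- function(type, start, end, ID = NA, Parent = NA, strand = "+",
                chrom = "c1") {
  data.frame(chrom = chrom, strand = strand, start = start, end = end,
             type = type, ID = ID, Parent = Parent, stringsAsFactors = FALSE)
}

test_that("longest transcript selection, intron derivation and UTR derivation", {
  rows <- rbind(
    row("gene", 101, 1300, ID = "g1"),
    row("mRNA", 101, 1000, ID = "g1.a", Parent = "g1"),   # span 900
    row("mRNA", 101, 1300, ID = "g1.b", Parent = "g1"),   # span 1200 (longest)
    row("exon", 101, 200, Parent = "g1.b"),
    row("exon", 301, 400, Parent = "g1.b"),
    row("exon", 301, 400, Parent = "g1.a"),
    row("CDS", 151, 350, Parent = "g1.b"),
    row("CDS", 301, 400, Parent = "g1.a"))
  ann <- load_annotation(mk_gr(rows))
  expect_equal(ann$genes$longest_transcript, "g1.b")
  f <- ann$features
  # intron between the exons: 0-based half-open [200, 300)
  expect_equal(f[f$type == "intron", c("start", "end")],
               data.frame(start = 200L, end = 300L),
               ignore_attr = TRUE)
  # UTRs derived from exon minus CDS
  expect_equal(f[f$type == "UTR5", c("start", "end")],
               data.frame(start = 100L, end = 150L), ignore_attr = TRUE)
  expect_equal(f[f$type == "UTR3", c("start", "end")],
               data.frame(start = 350L, end = 400L), ignore_attr = TRUE)
  expect_true(ann$genes$has_utr3)
  # g1.a: CDS runs to its transcript end -> no derived 3'-UTR
  expect_false("g1.a" %in% names(ann$utr3_lengths))

  # transcript-span tie breaks to the lexicographically smaller id
  rows2 <- rbind(
    row("gene", 1, 500, ID = "g2"),
    row("mRNA", 1, 500, ID = "g2.zz", Parent = "g2"),
    row("mRNA", 1, 500, ID = "g2.aa", Parent = "g2"),
    row("exon", 1, 500, Parent = "g2.zz"),
    row("exon", 1, 500, Parent = "g2.aa"))
  expect_equal(load_annotation(mk_gr(rows2))$genes$longest_transcript, "g2.aa")
})

test_that("mixed-strand exons within one transcript are rejected", {
  rows <- rbind(
    row("gene", 1, 500, ID = "g1"),
    row("mRNA", 1, 500, ID = "g1.t", Parent = "g1"),
    row("exon", 1, 100, Parent = "g1.t", strand = "+"),
    row("exon", 200, 300, Parent = "g1.t", strand = "-"))
  expect_error(load_annotation(mk_gr(rows)), "mixed strands")
})

# annotation with a + strand gene at 0-based [1000, 3001): UTR3 at
# [2800, 3001) so the gene's last base is 3000, and a second downstream gene
mk_two_gene_ann <- function(second_start = 8001) {
  rows <- rbind(
    row("gene", 1001, 3001, ID = "gA"),
    row("mRNA", 1001, 3001, ID = "gA.t", Parent = "gA"),
    row("exon", 1001, 3001, Parent = "gA.t"),
    row("CDS", 1101, 2800, Parent = "gA.t"),
    row("five_prime_UTR", 1001, 1100, Parent = "gA.t"),
    row("three_prime_UTR", 2801, 3001, Parent = "gA.t"),
    row("gene", second_start, second_start + 999, ID = "gB"),
    row("mRNA", second_start, second_start + 999, ID = "gB.t", Parent = "gB"),
    row("exon", second_start, second_start + 999, Parent = "gB.t"),
    row("CDS", second_start, second_start + 999, Parent = "gB.t"))
  load_annotation(mk_gr(rows))
}

pac_at <- function(pos, strand = "+", chrom = "c1", id = "P1") {
  data.frame(pac_id = id, chrom = chrom, strand = strand,
             span_start = pos, span_end = pos,
             representative_position = pos, representative_count = 10L,
             n_sites = 1L, total_support = 10L, stringsAsFactors = FALSE)
}

test_that("region assignment: genic, extended and intergenic cases", {
  ann <- mk_two_gene_ann()
  ep <- ext_params(ext = 150, utr3_median = 310)
  expect_equal(ep$no_utr3_ext, 460L)

  expect_equal(assign_region(pac_at(2900), ann, ep)$region, "UTR3")
  a <- assign_region(pac_at(3100), ann, ep)
  expect_equal(a$region, "extended_UTR3")   # 3000 < 3100 <= 3150
  expect_equal(a$distance, 100L)
  expect_equal(a$gene_id, "gA")
  expect_equal(assign_region(pac_at(3200), ann, ep)$region, "intergenic")
  expect_equal(assign_region(pac_at(4000), ann, ep)$region, "intergenic")
  expect_equal(assign_region(pac_at(1150), ann, ep)$region, "CDS")
  expect_equal(assign_region(pac_at(1050), ann, ep)$region, "UTR5")
  # wrong strand: no genic feature, no upstream gene -> intergenic
  expect_equal(assign_region(pac_at(2900, strand = "-"), ann, ep)$region,
               "intergenic")
})

test_that("extensions never cross into the next same-strand gene", {
  ann <- mk_two_gene_ann(second_start = 3051)   # gB begins at 0-based 3050
  ep <- ext_params(ext = 150, utr3_median = 310)
  # 3100 is inside gB's CDS -> genic wins
  expect_equal(assign_region(pac_at(3100), ann, ep)$region, "CDS")
  # 3040 is 40 nt past gA within the truncated window -> extended
  expect_equal(assign_region(pac_at(3040), ann, ep)$region, "extended_UTR3")
})

test_that("extension parameters derive from the intergenic distance median", {
  ann <- mk_two_gene_ann()
  # distances from gA end (3000): 50, 150, 300 -> median 150
  pacs <- rbind(pac_at(3050, id = "P1"), pac_at(3150, id = "P2"),
                pac_at(3300, id = "P3"))
  ep <- compute_extensions(pacs, ann)
  expect_equal(ep$ext, 150L)
  # utr3_median over all transcripts' 3'-UTR lengths
  expect_equal(ep$utr3_median,
               as.integer(round(median(ann$utr3_lengths))))
  expect_equal(ep$no_utr3_ext, ep$ext + ep$utr3_median)

  # all qualifying distances beyond the window -> default with warning
  far <- rbind(pac_at(4200, id = "P1"), pac_at(4500, id = "P2"))
  expect_warning(ep2 <- compute_extensions(far, ann), "default extension")
  expect_equal(ep2$ext, 150L)
})

test_that("toy extension arithmetic: median UTR3 310 + 150 gives 460", {
  # the stated reference values: UTR3 length median over {100, 310, 500}
  expect_equal(median(c(100, 310, 500)), 310)
  expect_equal(ext_params(ext = median(c(50, 150, 300)),
                          utr3_median = 310)$no_utr3_ext, 460L)
})

test_that("two-pass consistency: extended PACs were intergenic in pass 1", {
  cfg <- small_sim_config(seed = 31)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  run <- run_pipeline(sim, rd)
  ann <- run$annotation
  pass1 <- assign_region(run$pac_set$pacs, ann, ext = NULL)
  ext_ids <- run$assignments$pac_id[run$assignments$region == "extended_UTR3"]
  expect_true(all(pass1$region[pass1$pac_id %in% ext_ids] == "intergenic"))
  # partition: every PAC gets exactly one label
  expect_equal(sort(run$assignments$pac_id), sort(run$pac_set$pacs$pac_id))
  expect_false(any(is.na(run$assignments$region)))
})

test_that("genes without 3'-UTRs attract the intergenic first-pass PACs", {
  cfg <- small_sim_config(seed = 32, frac_genes_without_utr3 = 0.3)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  run <- run_pipeline(sim, rd)
  pass1 <- assign_region(run$pac_set$pacs, run$annotation, ext = NULL)
  near <- pass1[pass1$region == "intergenic" & !is.na(pass1$distance) &
                  pass1$distance <= 1000, ]
  ann <- run$annotation
  hu <- setNames(ann$genes$has_utr3, ann$genes$gene_id)
  up <- pacscan:::.upstream_gene_distance(
    run$pac_set$pacs$chrom, run$pac_set$pacs$strand,
    run$pac_set$pacs$representative_position, ann$genes)
  near_gene <- up$gene_id[match(near$pac_id, run$pac_set$pacs$pac_id)]
  frac_no_utr3_with_pac <- mean(!hu[unique(near_gene)])
  frac_no_utr3_overall <- mean(!ann$genes$has_utr3)
  expect_gt(frac_no_utr3_with_pac, frac_no_utr3_overall)
})

test_that("termini agreement uses clustered termini and interval distance", {
  pacs <- pac_at(3090); pacs$span_start <- 3080L; pacs$span_end <- 3100L
  # 3105: 5 nt past the span end; 3200: 100 nt away; 3000: 80 nt before
  term <- data.frame(chrom = "c1", strand = "+",
                     position = c(3105L, 3000L, 3200L))
  cmp <- compare_termini(pacs, term, window = 24)
  t <- cmp$termini[order(cmp$termini$position), ]
  expect_equal(t$nearest_distance, c(80L, 5L, 100L))
  expect_equal(t$supported, c(FALSE, TRUE, FALSE))
  expect_equal(cmp$supported_fraction, 1 / 3)
  # a terminus inside the span has distance 0
  inside <- compare_termini(pacs, data.frame(chrom = "c1", strand = "+",
                                             position = 3090L))
  expect_equal(inside$termini$nearest_distance, 0L)
  expect_true(inside$termini$supported)
  # termini within 24 nt of each other collapse into one cluster first
  term2 <- data.frame(chrom = "c1", strand = "+",
                      position = c(3105L, 3110L, 3120L))
  cmp2 <- compare_termini(pacs, term2, window = 24)
  expect_equal(nrow(cmp2$termini), 1L)
  expect_equal(cmp2$termini$position, 3105L)   # leftmost representative
})

test_that("intergenic validation is strand-aware and end-inclusive", {
  pacs <- rbind(pac_at(5000, id = "P1"), pac_at(6000, strand = "-", id = "P2"),
                pac_at(4500, id = "P3"))
  asg <- data.frame(pac_id = c("P1", "P2", "P3"), region = "intergenic",
                    gene_id = NA, distance = NA, stringsAsFactors = FALSE)
  novel <- data.frame(chrom = "c1", strand = "+", start = 4500L, end = 6000L)
  v <- validate_intergenic(pacs, asg, novel)
  expect_equal(v$validated[v$pac_id == "P1"], TRUE)
  expect_equal(v$validated[v$pac_id == "P2"], FALSE)  # opposite strand
  expect_equal(v$validated[v$pac_id == "P3"], TRUE)   # boundary inclusive
})
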