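test_that("identical configurations reproduce identical outputs", {
  cfg <- sim_config(seed = 5, n_genes = 12, chromosome_length = 80000,
                    n_reads = 2000)
  a <- simulate_genome(cfg); b <- simulate_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  expect_identical(a$decoys, b$decoys)
  ra <- simulate_reads(a); rb <- simulate_reads(b)
  expect_identical(ra$reads, rb$reads)
  expect_identical(ra$truth, rb$truth)
})

test_that("configuration validation catches inconsistent settings", {
  expect_error(sim_config(pacs_per_gene_weights = c(0.5, 0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(sim_config(frac_polya_reads = 1.2), "fractions")
  expect_error(sim_config(read_length = 40, tail_length_range = c(10, 25)),
               "20-nt length filter")
  expect_error(sim_config(n_genes = 500, chromosome_length = 50000,
                          n_chromosomes = 1) |> simulate_genome(),
               "without overlap")
})

test_that("every transcript gets a 3'-UTR when frac_genes_without_utr3 = 0", {
  cfg <- sim_config(seed = 2, n_genes = 15, chromosome_length = 80000,
                    n_reads = 1000, frac_genes_without_utr3 = 0)
  sim <- simulate_genome(cfg)
  expect_true(all(sim$genes$has_utr3))
  gff <- sim$gff
  mrna1 <- S4Vectors::mcols(gff)$ID[S4Vectors::mcols(gff)$type == "mRNA"]
  mrna1 <- mrna1[grepl("\\.t1$", mrna1)]
  u3_parents <- unlist(S4Vectors::mcols(gff)$Parent[
    S4Vectors::mcols(gff)$type == "three_prime_UTR"])
  expect_setequal(mrna1, unique(u3_parents))
})

test_that("planted decoy regions are disjoint genomic A/T runs of >= 12 nt", {
  cfg <- sim_config(seed = 9, n_genes = 10, chromosome_length = 80000,
                    n_reads = 1000, n_decoy_regions = 5)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$decoys), 5L)
  # one-line independent scan: each recorded interval is one homopolymer run
  for (i in seq_len(5)) {
    d <- sim$decoys[i, ]
    base <- if (d$strand == "+") "A" else "T"
    run <- substring(sim$genome[[d$chrom]], d$start + 1L, d$end)
    expect_gte(nchar(run), 12L)
    expect_equal(run, strrep(base, nchar(run)))
  }
  # pairwise disjoint
  for (i in 1:4) for (j in (i + 1):5) {
    a <- sim$decoys[i, ]; b <- sim$decoys[j, ]
    expect_true(a$chrom != b$chrom || a$end <= b$start || b$end <= a$start)
  }
})

test_that("per-gene usage fractions sum to 1 and sites sit in their declared regions", {
  cfg <- sim_config(seed = 4, n_genes = 40, chromosome_length = 150000,
                    n_reads = 1000)
  sim <- simulate_genome(cfg)
  sums <- tapply(sim$truth$usage_fraction, sim$truth$gene_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  g <- sim$genes[match(sim$truth$gene_id, sim$genes$gene_id), ]
  inside <- sim$truth$true_site_position >= g$start &
    sim$truth$true_site_position < g$end
  down <- sim$truth$region_label == "downstream"
  expect_true(all(inside[!down]))
  d <- ifelse(g$strand == "+",
              sim$truth$true_site_position - (g$end - 1L),
              g$start - sim$truth$true_site_position)
  expect_true(all(d[down] > 0 & d[down] <= 460))
})

test_that("signal read counts follow the configured poly(A) fraction", {
  cfg <- sim_config(seed = 8, n_genes = 10, chromosome_length = 80000,
                    n_reads = 10000, frac_polya_reads = 0.05)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  n_sig <- sum(rd$truth$label == "signal")
  bound <- 3 * sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(n_sig - 500), bound)

  cfg0 <- sim_config(seed = 8, n_genes = 10, chromosome_length = 80000,
                     n_reads = 2000, frac_polya_reads = 0)
  rd0 <- simulate_reads(simulate_genome(cfg0))
  expect_equal(sum(rd0$truth$label == "signal"), 0L)
})

test_that("error-free signal reads end in the appended tail and map back to their origin", {
  cfg <- sim_config(seed = 6, n_genes = 10, chromosome_length = 80000,
                    n_reads = 3000, frac_polya_reads = 0.2,
                    sequencing_error_rate = 0, n_decoy_regions = 0)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  sig <- which(rd$truth$label == "signal")[1:50]
  for (i in sig) {
    r <- rd$reads[[i]]
    mrna <- if (rd$truth$emitted_orientation[i] == "antisense")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    else r
    tl <- rd$truth$tail_length[i]
    expect_equal(substr(mrna, nchar(mrna) - tl + 1L, nchar(mrna)),
                 strrep("A", tl))
    insert <- substr(mrna, 1L, nchar(mrna) - tl)
    al <- naive_align(insert, sim$genome)
    expect_equal(al$status, "unique")
    expect_equal(al$strand, rd$truth$strand[i])
    pos <- if (al$strand == "+") al$end else al$start
    expect_equal(pos, rd$truth$cleavage_pos[i])
  }
})

test_that("decoy reads carry a templated terminal A-run from a planted region", {
  cfg <- sim_config(seed = 13, n_genes = 10, chromosome_length = 80000,
                    n_reads = 3000, frac_decoy_reads = 0.05,
                    sequencing_error_rate = 0)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  dec <- which(rd$truth$label == "decoy")
  expect_gt(length(dec), 0L)
  for (i in dec[1:min(30, length(dec))]) {
    r <- rd$reads[[i]]
    mrna <- if (rd$truth$emitted_orientation[i] == "antisense")
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    else r
    expect_equal(substr(mrna, nchar(mrna) - 11L, nchar(mrna)), strrep("A", 12))
    # untrimmed decoy read is fully templated
    expect_equal(naive_align(mrna, sim$genome)$status, "unique")
  }
})

test_that("stranded-paired protocol puts T tails on mate 1 and A tails on mate 2", {
  cfg <- sim_config(seed = 17, n_genes = 10, chromosome_length = 80000,
                    n_reads = 2000, frac_polya_reads = 0.2,
                    sequencing_error_rate = 0,
                    protocol = "stranded_paired")
  rd <- simulate_reads(simulate_genome(cfg))
  expect_false(is.null(rd$reads2))
  sig <- which(rd$truth$label == "signal")[1:20]
  tl <- rd$truth$tail_length[sig]
  expect_true(all(substr(rd$reads[sig], 1L, 8L) == strrep("T", 8)))
  expect_true(all(mapply(function(r, t)
    substr(r, nchar(r) - t + 1L, nchar(r)) == strrep("A", t),
    rd$reads2[sig], tl)))
})

test_that("written outputs round-trip through standard formats", {
  cfg <- sim_config(seed = 3, n_genes = 8, chromosome_length = 60000,
                    n_reads = 500)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim)
  out <- tempfile("simout")
  write_sim(sim, out)
  write_reads(rd, out)
  fa <- Biostrings::readDNAStringSet(file.path(out, "genome.fa"))
  expect_equal(as.character(fa[["chr1"]]), sim$genome[["chr1"]])
  ann <- load_annotation(file.path(out, "annotation.gff3"))
  expect_equal(sort(ann$genes$gene_id), sort(sim$genes$gene_id))
  fq <- Biostrings::readDNAStringSet(file.path(out, "reads.fastq"),
                                     format = "fastq")
  expect_equal(length(fq), length(rd$reads))
  expect_equal(unname(as.character(fq[1])), unname(rd$reads[1]))
  unlink(out, recursive = TRUE)
})
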