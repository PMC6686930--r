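mk_pac_row <- function(pos, strand = "+", chrom = "g", id = "P1") {
  data.frame(pac_id = id, chrom = chrom, strand = strand, span_start = pos,
             span_end = pos, representative_position = pos,
             representative_count = 5L, n_sites = 1L, total_support = 5L,
             stringsAsFactors = FALSE)
}

# synthetic windows: fixed width with a given up extent
mk_windows <- function(seqs, up) {
  ws <- Biostrings::DNAStringSet(seqs)
  attr(ws, "up") <- as.integer(up)
  ws
}

test_that("window extraction is strand-aware and boundary-checked", {
  set.seed(1)
  g <- c(g = paste(sample(c("A", "C", "G", "T"), 401, replace = TRUE),
                   collapse = ""))
  # + strand site at 0-based 300 on a 401-nt contig: exactly fits
  ws <- extract_windows(g, mk_pac_row(300L), up = 300, down = 100)
  expect_equal(length(ws), 1L)
  expect_equal(Biostrings::width(ws), 401L)
  expect_equal(attr(ws, "n_skipped"), 0L)
  # position 0 of the window is the representative base
  expect_equal(substr(as.character(ws[[1]]), 301, 301),
               substr(g[["g"]], 301, 301))

  # too close to the contig start: skipped and counted
  ws2 <- extract_windows(g, mk_pac_row(100L), up = 300, down = 100)
  expect_equal(length(ws2), 0L)
  expect_equal(attr(ws2, "n_skipped"), 1L)

  # minus strand window is the reverse complement of the mirrored slice
  ws3 <- extract_windows(g, mk_pac_row(100L, strand = "-"),
                         up = 300, down = 100)
  slice <- substr(g[["g"]], 1, 401)
  expect_equal(as.character(ws3[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(slice))))
})

test_that("per-position composition counts bases and normalises over non-N", {
  ws <- mk_windows(c("ACGT", "ACGT", "ACGT"), up = 2)
  pp <- position_composition(ws)
  expect_equal(pp$positions, -2:1)
  expect_equal(unname(pp$freq["A", 1]), 1)
  expect_equal(unname(pp$freq["C", 2]), 1)
  expect_equal(unname(pp$freq["U", 4]), 1)   # T reported as U
  expect_true(all(abs(colSums(pp$freq) - 1) < 1e-12))

  mixed <- position_composition(mk_windows(c("AC", "GC"), up = 1))
  expect_equal(unname(mixed$freq["A", 1]), 0.5)
  expect_equal(unname(mixed$freq["G", 1]), 0.5)
  expect_equal(unname(mixed$freq["C", 2]), 1.0)

  expect_error(position_composition(mk_windows(c("AC", "ACG"), up = 1)),
               "same length")
})

test_that("chi-squared series: zero for identical profiles, hand value for divergence", {
  set.seed(2)
  seqs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  pp <- position_composition(mk_windows(seqs, up = 10))
  expect_lt(max(abs(chi2_compare(pp, pp))), 1e-12)

  # 10 observed all-A windows against a uniform reference:
  # (10-2.5)^2/2.5 + 3*(0-2.5)^2/2.5 = 30
  obs <- position_composition(mk_windows(rep("A", 10), up = 0))
  ref <- position_composition(mk_windows(c("A", "C", "G", "T"), up = 0))
  expect_equal(as.numeric(chi2_compare(obs, ref)), 30)

  # non-negativity on random pairs
  pp2 <- position_composition(mk_windows(sample(seqs), up = 10))
  expect_true(all(chi2_compare(pp2, pp) >= 0))
})

test_that("hexamer scan respects the region bounds and once-per-window counting", {
  up <- 50L
  bg <- strrep("C", 101)  # width 101, up = 50 -> positions -50..50
  put <- function(x, p, motif = "AATAAA") {
    # place motif start at window position p (site at 0)
    i <- p + up + 1L
    substr(x, i, i + nchar(motif) - 1L) <- motif
    x
  }
  w10 <- vapply(1:10, function(i) put(bg, -30L), character(1))
  sc <- hexamer_scan(mk_windows(w10, up), region = c(-40L, -10L))
  expect_equal(sc$observed[sc$motif == "AAUAAA"], 10L)
  expect_equal(sc$frequency_pct[sc$motif == "AAUAAA"], 100)

  # a double occurrence still contributes 1 with once = TRUE
  w2 <- put(put(bg, -35L), -25L)
  sc2 <- hexamer_scan(mk_windows(c(w2, w10), up), region = c(-40L, -10L))
  expect_equal(sc2$observed[sc2$motif == "AAUAAA"], 11L)
  sc2n <- hexamer_scan(mk_windows(c(w2, w10), up), region = c(-40L, -10L),
                       once = FALSE)
  expect_equal(sc2n$observed[sc2n$motif == "AAUAAA"], 12L)

  # a hexamer starting at -14 overlaps position -9 (outside the region)
  w_out <- put(bg, -14L)
  sc3 <- hexamer_scan(mk_windows(w_out, up), region = c(-40L, -10L))
  expect_false("AAUAAA" %in% sc3$motif)
  # ... but starting at -15 it ends exactly at -10 and is counted
  w_in <- put(bg, -15L)
  sc4 <- hexamer_scan(mk_windows(w_in, up), region = c(-40L, -10L))
  expect_equal(sc4$observed[sc4$motif == "AAUAAA"], 1L)

  # windows with N in the scanned region are excluded and counted
  wN <- put(bg, -30L, "AANTAA")
  sc5 <- hexamer_scan(mk_windows(c(wN, w10), up), region = c(-40L, -10L))
  expect_equal(attr(sc5, "n_excluded"), 1L)
  expect_equal(attr(sc5, "n_windows"), 10L)
})

test_that("motif Z-scores follow the 0-order binomial occurrence model", {
  stats <- data.frame(motif = "AAUAAA", observed = 50L,
                      stringsAsFactors = FALSE)
  pi4 <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  z <- motif_zscore(stats, base_freqs = pi4, n_windows = 1000L,
                    n_placements = 26L)
  # closed form evaluated independently
  p <- 0.25^6
  q <- 1 - (1 - p)^26
  expect_equal(z$expected, 1000 * q)
  expect_equal(z$zscore, (50 - 1000 * q) / sqrt(1000 * q * (1 - q)))

  z0 <- motif_zscore(data.frame(motif = "AAUAAA", observed = 1000 * q),
                     base_freqs = pi4, n_windows = 1000L, n_placements = 26L)
  expect_equal(z0$zscore, 0)
  zneg <- motif_zscore(data.frame(motif = "AAUAAA", observed = 0L),
                       base_freqs = pi4, n_windows = 1000L,
                       n_placements = 26L)
  expect_lt(zneg$zscore, 0)
})

test_that("a planted NUE motif is recovered as the top-ranked hexamer", {
  set.seed(31)
  up <- 50L
  n <- 500L
  seqs <- vapply(seq_len(n), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), 101, replace = TRUE),
               collapse = "")
    if (i <= 0.6 * n) {
      p <- sample(-30:-20, 1)          # motif start within [-30, -20]
      i0 <- p + up + 1L
      substr(s, i0, i0 + 5L) <- "AATAAA"
    }
    s
  }, character(1))
  sc <- motif_zscore(hexamer_scan(mk_windows(seqs, up),
                                  region = c(-40L, -10L)))
  expect_equal(sc$motif[1], "AAUAAA")
  expect_gt(sc$zscore[1], 5)
})

test_that("planted U/A-rich composition appears at the expected offsets", {
  set.seed(32)
  up <- 50L
  seqs <- vapply(1:400, function(i) {
    ch <- sample(c("A", "C", "G", "T"), 101, replace = TRUE)
    # A-rich NUE band and U-rich cleavage band upstream of the site
    nue <- (-28:-13) + up + 1L
    ch[nue[runif(16) < 0.5]] <- "A"
    ce <- (-10:-1) + up + 1L
    ch[ce[runif(10) < 0.5]] <- "T"
    paste(ch, collapse = "")
  }, character(1))
  pp <- position_composition(mk_windows(seqs, up))
  posn <- as.integer(colnames(pp$freq))
  u_in <- mean(pp$freq["U", posn >= -10 & posn <= -1])
  u_out <- mean(pp$freq["U", posn >= 10 & posn <= 40])
  a_in <- mean(pp$freq["A", posn >= -28 & posn <= -13])
  a_out <- mean(pp$freq["A", posn >= 10 & posn <= 40])
  expect_gt(u_in, u_out + 0.1)
  expect_gt(a_in, a_out + 0.1)
})
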