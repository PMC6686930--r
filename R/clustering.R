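#' Pool cleavage events into unique cleavage sites
#'
#' Events sharing chromosome, strand and position are pooled into one
#' cleavage site whose read count is the number of supporting events.
#'
#' @param events data frame with columns `chrom`, `strand`, `position`
#'   (0-based coordinate of the last templated base), one row per supporting
#'   read.
#' @return data frame of sites (`chrom`, `strand`, `position`, `read_count`)
#'   sorted by chromosome, strand, position.
#' @export
aggregate_sites <- function(events) {
  if (nrow(events) == 0L) {
    return(data.frame(chrom = character(0), strand = character(0),
                      position = integer(0), read_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  stop_if_not_df_cols(events, c("chrom", "strand", "position"), "events")
  key <- paste(events$chrom, events$strand, events$position, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    strand = vapply(parts, `[`, "", 2L),
                    position = as.integer(vapply(parts, `[`, "", 3L)),
                    read_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$strand, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster cleavage sites into poly(A) site clusters (PACs)
#'
#' Sites supported by fewer than `min_reads` reads are discarded, then sites
#' on the same chromosome and strand are clustered iteratively: the unassigned
#' site with the highest read count (tie: smaller coordinate) seeds a cluster
#' and absorbs every unassigned site within `window` nt; the process repeats
#' until all sites are assigned. The seed is the cluster's representative
#' site and the cluster support is the sum of member read counts.
#'
#' A single-linkage alternative (`linkage = "chain"`), in which consecutive
#' sites at most `window` nt apart are chained into one cluster and the
#' highest-count member becomes the representative, is available for
#' comparison; it allows unbounded cluster spans.
#'
#' @param sites data frame from [aggregate_sites()].
#' @param window clustering window in nt (default 24; "within `window`" means
#'   a distance of at most `window`).
#' @param min_reads minimum reads per site before clustering (default 3).
#' @param linkage `"greedy"` (default, support-ranked seeding) or `"chain"`.
#' @return a list of class `pac_set` with elements `pacs` (one row per PAC:
#'   `pac_id`, `chrom`, `strand`, `span_start`, `span_end`,
#'   `representative_position`, `representative_count`, `n_sites`,
#'   `total_support`) and `members` (`pac_id`, `position`, `read_count`).
#' @export
cluster_sites <- function(sites, window = 24L, min_reads = 3L,
                          linkage = c("greedy", "chain")) {
  linkage <- match.arg(linkage)
  window <- as.integer(window)
  min_reads <- as.integer(min_reads)
  if (window < 0L) stop("window must be >= 0")
  if (min_reads < 1L) stop("min_reads must be >= 1")
  stop_if_not_df_cols(sites, c("chrom", "strand", "position", "read_count"),
                      "sites")
  sites <- sites[sites$read_count >= min_reads, , drop = FALSE]

  empty_pacs <- data.frame(pac_id = character(0), chrom = character(0),
                           strand = character(0), span_start = integer(0),
                           span_end = integer(0),
                           representative_position = integer(0),
                           representative_count = integer(0),
                           n_sites = integer(0), total_support = integer(0),
                           stringsAsFactors = FALSE)
  empty_members <- data.frame(pac_id = character(0), position = integer(0),
                              read_count = integer(0),
                              stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) {
    return(structure(list(pacs = empty_pacs, members = empty_members),
                     class = "pac_set"))
  }

  pac_list <- list()
  mem_list <- list()
  grp <- split(seq_len(nrow(sites)), paste(sites$chrom, sites$strand))
  for (g in grp) {
    pos <- sites$position[g]
    cnt <- sites$read_count[g]
    o <- order(pos)
    pos <- pos[o]; cnt <- cnt[o]
    n <- length(pos)
    cluster_of <- integer(n)  # 0 = unassigned
    if (linkage == "greedy") {
      # visit sites in decreasing support (tie: leftmost); each unassigned
      # visit seeds a cluster absorbing unassigned sites within +/- window
      rank_order <- order(-cnt, pos)
      k <- 0L
      reps <- integer(0)
      for (i in rank_order) {
        if (cluster_of[i] != 0L) next
        k <- k + 1L
        reps[k] <- i
        lo <- findInterval(pos[i] - window, pos, left.open = TRUE) + 1L
        hi <- findInterval(pos[i] + window, pos)
        memb <- lo:hi
        memb <- memb[cluster_of[memb] == 0L]
        cluster_of[memb] <- k
      }
    } else {
      k <- 1L
      cluster_of[1L] <- 1L
      if (n > 1L) for (i in 2:n) {
        if (pos[i] - pos[i - 1L] > window) k <- k + 1L
        cluster_of[i] <- k
      }
      # representative: highest count, tie -> leftmost
      reps <- vapply(seq_len(k), function(cl) {
        idx <- which(cluster_of == cl)
        idx[order(-cnt[idx], pos[idx])[1L]]
      }, integer(1))
    }
    chrom <- sites$chrom[g[1L]]
    strand <- sites$strand[g[1L]]
    for (cl in seq_along(reps)) {
      idx <- which(cluster_of == cl)
      pac_list[[length(pac_list) + 1L]] <- data.frame(
        chrom = chrom, strand = strand,
        span_start = min(pos[idx]), span_end = max(pos[idx]),
        representative_position = pos[reps[cl]],
        representative_count = cnt[reps[cl]],
        n_sites = length(idx), total_support = sum(cnt[idx]),
        stringsAsFactors = FALSE)
      mem_list[[length(mem_list) + 1L]] <- data.frame(
        position = pos[idx], read_count = cnt[idx],
        stringsAsFactors = FALSE)
    }
  }
  pacs <- do.call(rbind, pac_list)
  o <- order(pacs$chrom, pacs$strand, pacs$span_start)
  pacs <- pacs[o, , drop = FALSE]
  mem_list <- mem_list[o]
  pacs$pac_id <- sprintf("PAC%05d", seq_len(nrow(pacs)))
  pacs <- pacs[, c("pac_id", "chrom", "strand", "span_start", "span_end",
                   "representative_position", "representative_count",
                   "n_sites", "total_support")]
  rownames(pacs) <- NULL
  members <- do.call(rbind, Map(function(id, m) {
    data.frame(pac_id = id, m, stringsAsFactors = FALSE)
  }, pacs$pac_id, mem_list))
  rownames(members) <- NULL
  structure(list(pacs = pacs, members = members), class = "pac_set")
}

#' @export
print.pac_set <- function(x, ...) {
  cat(sprintf("pac_set: %d PACs from %d cleavage sites (%d multi-site)\n",
              nrow(x$pacs), nrow(x$members), sum(x$pacs$n_sites > 1L)))
  invisible(x)
}

#' Micro-heterogeneity statistics of cleavage sites and PACs
#'
#' Summarises the spread of cleavage positions: distribution of distances
#' between adjacent filtered sites (same chromosome and strand), the fraction
#' of multi-site PACs, sites-per-PAC moments, the fraction of PAC spans within
#' the clustering window, and the Pearson correlation between the natural
#' logs of sites-per-PAC and representative-site read count.
#'
#' @param sites site data frame (pre-clustering); the `min_reads` filter is
#'   applied here so the distance distribution matches the clustered input.
#' @param pac_set a `pac_set` from [cluster_sites()].
#' @param window the clustering window used (default 24).
#' @param min_reads minimum reads per site (default 3), matching the
#'   clustering run.
#' @return a list of class `heterogeneity_stats`: `adjacent_distances`
#'   (integer vector), `frac_adjacent_le_window`, `frac_multisite_pacs`,
#'   `mean_sites_per_pac`, `sd_sites_per_pac`, `frac_span_le_window`, and
#'   `pearson_r_lnln` (`NA` when fewer than 2 PACs or either log vector has
#'   zero variance).
#' @export
heterogeneity_stats <- function(sites, pac_set, window = 24L, min_reads = 3L) {
  sites <- sites[sites$read_count >= min_reads, , drop = FALSE]
  dists <- integer(0)
  if (nrow(sites) > 1L) {
    grp <- split(sites$position, paste(sites$chrom, sites$strand))
    dists <- unlist(lapply(grp, function(p) diff(sort(p))), use.names = FALSE)
  }
  pacs <- pac_set$pacs
  span <- pacs$span_end - pacs$span_start
  r <- NA_real_
  if (nrow(pacs) >= 2L) {
    ls <- log(pacs$n_sites)
    lc <- log(pacs$representative_count)
    if (stats::sd(ls) > 0 && stats::sd(lc) > 0) r <- stats::cor(ls, lc)
  }
  structure(list(
    adjacent_distances = dists,
    frac_adjacent_le_window =
      if (length(dists)) mean(dists <= window) else NA_real_,
    frac_multisite_pacs = mean(pacs$n_sites > 1L),
    mean_sites_per_pac = mean(pacs$n_sites),
    sd_sites_per_pac = stats::sd(pacs$n_sites),
    frac_span_le_window = mean(span <= window),
    pearson_r_lnln = r), class = "heterogeneity_stats")
}

#' PAC discovery saturation under event down-sampling
#'
#' Randomly down-samples cleavage events without replacement and re-runs
#' site aggregation, support filtering and clustering at each sampling
#' fraction, recording the resulting PAC count.
#'
#' @param events cleavage event data frame (one row per read).
#' @param fractions numeric vector of sampling fractions in (0, 1].
#' @param min_reads,window clustering parameters, see [cluster_sites()].
#' @param seed integer seed for the down-sampling.
#' @return data frame with columns `fraction`, `n_events`, `n_pacs`.
#' @export
saturation_curve <- function(events, fractions, min_reads = 3L, window = 24L,
                             seed = NULL) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  n <- nrow(events)
  with_seed(seed, {
    res <- lapply(fractions, function(f) {
      m <- if (f == 1) n else floor(f * n)
      ev <- if (m == n) events else events[sample.int(n, m), , drop = FALSE]
      pacs <- cluster_sites(aggregate_sites(ev), window = window,
                            min_reads = min_reads)
      data.frame(fraction = f, n_events = m, n_pacs = nrow(pacs$pacs))
    })
    do.call(rbind, res)
  })
}
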