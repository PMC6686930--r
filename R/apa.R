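#' Per-gene PAC usage profiles
#'
#' Groups genic PACs (3'-UTR, extended 3'-UTR, CDS, intron, 5'-UTR) by gene
#' and computes each PAC's relative expression (RE): its cluster support
#' divided by the summed support of all PACs of the gene. PACs are ranked
#' per gene by descending RE (ties: higher support, then smaller
#' representative coordinate).
#'
#' @param pacs PAC data frame (from `cluster_sites()$pacs`).
#' @param assignments region assignments (from [assign_region()]).
#' @return data frame: `gene_id`, `pac_id`, `region`, `support`, `RE`,
#'   `rank`, `n_pacs` (PACs of the gene).
#' @export
gene_profiles <- function(pacs, assignments) {
  genic <- c("UTR3", "extended_UTR3", "CDS", "intron", "UTR5")
  a <- assignments[assignments$region %in% genic & !is.na(assignments$gene_id),
                   c("pac_id", "region", "gene_id"), drop = FALSE]
  df <- merge(a, pacs[, c("pac_id", "total_support",
                          "representative_position")], by = "pac_id")
  tot <- tapply(df$total_support, df$gene_id, sum)
  zero <- names(tot)[tot <= 0]
  if (length(zero)) {
    warning(length(zero), " gene(s) with zero total support excluded")
    df <- df[!(df$gene_id %in% zero), , drop = FALSE]
    tot <- tot[!(names(tot) %in% zero)]
  }
  df$RE <- df$total_support / as.numeric(tot[df$gene_id])
  df <- df[order(df$gene_id, -df$RE, -df$total_support,
                 df$representative_position), , drop = FALSE]
  df$rank <- stats::ave(df$RE, df$gene_id, FUN = seq_along)
  df$n_pacs <- stats::ave(df$RE, df$gene_id, FUN = length)
  out <- data.frame(gene_id = df$gene_id, pac_id = df$pac_id,
                    region = df$region, support = df$total_support,
                    RE = df$RE, rank = as.integer(df$rank),
                    n_pacs = as.integer(df$n_pacs),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify PACs and genes by relative expression
#'
#' A PAC in a multi-PAC gene with RE strictly greater than `threshold` is
#' `strong` and its co-resident PACs are `weak`; multi-PAC genes without a
#' strong PAC have all-`medium` PACs; single-PAC genes are `unique`. Genes
#' are classed `strong` / `medium` / `unique` accordingly.
#'
#' @param profiles data frame from [gene_profiles()].
#' @param threshold RE cutoff, strict inequality (default 0.7). Must lie in
#'   (0.5, 1): at or below 0.5 a gene could hold two "strong" PACs.
#' @return list: `pac_labels` (`pac_id`, `gene_id`, `label`), `gene_classes`
#'   (`gene_id`, `class`).
#' @export
classify_pacs <- function(profiles, threshold = 0.7) {
  if (threshold <= 0.5 || threshold >= 1)
    stop("threshold must lie in (0.5, 1)")
  has_strong <- tapply(profiles$RE > threshold, profiles$gene_id, any)
  gene_class <- ifelse(
    tapply(profiles$n_pacs, profiles$gene_id, `[`, 1L) == 1L, "unique",
    ifelse(has_strong, "strong", "medium"))
  gcl <- gene_class[profiles$gene_id]
  label <- ifelse(gcl == "unique", "unique",
           ifelse(gcl == "medium", "medium",
           ifelse(profiles$RE > threshold, "strong", "weak")))
  list(pac_labels = data.frame(pac_id = profiles$pac_id,
                               gene_id = profiles$gene_id,
                               label = unname(label),
                               stringsAsFactors = FALSE),
       gene_classes = data.frame(gene_id = names(gene_class),
                                 class = unname(gene_class),
                                 stringsAsFactors = FALSE))
}

#' Fraction of poly(A) reads mapped to each PAC rank in APA genes
#'
#' Over genes with two or more PACs, sums the support of the rank-r PAC of
#' every gene and divides by the total support of all APA genes; the
#' fractions over all ranks sum to 1.
#'
#' @param profiles data frame from [gene_profiles()].
#' @return data frame: `rank`, `support`, `fraction`.
#' @export
rank_read_fractions <- function(profiles) {
  apa <- profiles[profiles$n_pacs >= 2L, , drop = FALSE]
  if (nrow(apa) == 0L) {
    return(data.frame(rank = integer(0), support = numeric(0),
                      fraction = numeric(0)))
  }
  sup <- tapply(apa$support, apa$rank, sum)
  data.frame(rank = as.integer(names(sup)), support = as.numeric(sup),
             fraction = as.numeric(sup) / sum(apa$support),
             row.names = NULL)
}

#' Compare feature lengths of PAC-bearing vs PAC-free features
#'
#' Draws `n_controls` disjoint control groups of size `length(with_pac)`
#' from the pool of PAC-free feature lengths (without replacement; when the
#' pool is too small the groups are made as large as an even split allows,
#' with a warning) and tests, one-sided, whether PAC-bearing features are
#' longer than the pooled controls (Wilcoxon rank-sum).
#'
#' @param with_pac numeric lengths of features carrying a PAC.
#' @param pool_without numeric lengths of features without a PAC.
#' @param n_controls number of disjoint control groups (default 3).
#' @param seed integer seed for the control draws.
#' @return list of class `feature_length_test`: `group_stats` (mean/median
#'   per group), `p_value`, `statistic`, `controls` (list of the drawn
#'   groups).
#' @export
feature_length_test <- function(with_pac, pool_without, n_controls = 3L,
                                seed = NULL) {
  if (length(with_pac) == 0L || length(pool_without) == 0L)
    stop("both length vectors must be non-empty")
  m <- length(with_pac)
  if (length(pool_without) < n_controls * m) {
    warning("control pool smaller than ", n_controls, " x ", m,
            "; drawing smaller disjoint groups")
    m <- length(pool_without) %/% n_controls
    if (m == 0L) stop("control pool too small for any control group")
  }
  controls <- with_seed(seed, {
    perm <- sample(pool_without)
    lapply(seq_len(n_controls), function(i) perm[((i - 1L) * m + 1L):(i * m)])
  })
  pooled <- unlist(controls)
  wt <- stats::wilcox.test(with_pac, pooled, alternative = "greater")
  gs <- rbind(
    data.frame(group = "with_pac", n = length(with_pac),
               mean = mean(with_pac), median = stats::median(with_pac)),
    do.call(rbind, lapply(seq_along(controls), function(i) {
      data.frame(group = paste0("control_", i), n = length(controls[[i]]),
                 mean = mean(controls[[i]]),
                 median = stats::median(controls[[i]]))
    })))
  structure(list(group_stats = gs, p_value = wt$p.value,
                 statistic = unname(wt$statistic), controls = controls),
            class = "feature_length_test")
}

#' @export
print.feature_length_test <- function(x, ...) {
  print(x$group_stats, row.names = FALSE)
  cat(sprintf("one-sided (greater) rank-sum p = %.4g\n", x$p_value))
  invisible(x)
}
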