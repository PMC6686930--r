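# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Vectorised reverse complement on plain character vectors.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Vectorised string reversal (Biostrings handles the heavy lifting).
str_reverse <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

# Count occurrences of a single character in each string.
char_count <- function(x, ch) {
  nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE))
}

# Longest run of character `ch` in each string (0 if absent).
max_char_run <- function(x, ch) {
  pat <- paste0(ch, "+")
  vapply(gregexpr(pat, x), function(m) {
    if (m[1] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1))
}

#' Write a data frame as tab-separated values
#'
#' Plain TSV with a header row, no quoting, no row names; the on-disk format
#' used for every tabular output of the pipeline.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stop_if_not_df_cols <- function(x, cols, what) {
  if (!is.data.frame(x) || !all(cols %in% names(x))) {
    stop(sprintf("%s must be a data frame with columns: %s",
                 what, paste(cols, collapse = ", ")), call. = FALSE)
  }
}
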