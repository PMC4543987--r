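#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Normalize chromosome labels to "chrN" strings ("1" -> "chr1", "chrX" kept).
normalize_chrom <- function(x) {
  x <- as.character(x)
  x <- sub("^(?i)chr", "", x, perl = TRUE)
  paste0("chr", x)
}

# Natural chromosome order: chr1..chr22, chrX, chrY, chrM, then others
# alphabetically. Returns an integer rank usable as a sort key.
chrom_rank <- function(chrom) {
  body <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(body))
  rank <- ifelse(!is.na(num), num,
    ifelse(body == "X", 23L,
      ifelse(body == "Y", 24L,
        ifelse(body %in% c("M", "MT"), 25L, NA_integer_))))
  ifelse(is.na(rank), 1000L + as.integer(factor(body)), rank)
}

# Sort a data frame carrying a `chrom` column by genome order then `...` keys.
arrange_genome <- function(df, ...) {
  dplyr::arrange(df, chrom_rank(.data$chrom), .data$chrom, ...)
}

# CNV type from copy number: deletion iff cn < 2, duplication iff cn > 2.
cn_to_type <- function(cn) {
  ifelse(cn < 2, "deletion", ifelse(cn > 2, "duplication", NA_character_))
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
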