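#' Read a probe map (array design) file
#'
#' Reads the ordered set of array probes with genomic positions, the
#' coordinate backbone of the per-probe association scan. Two dialects are
#' supported: `"pfb"` (PennCNV population-frequency-of-B-allele files with
#' columns `Name`, `Chr`, `Position`, `PFB`) and `"tsv"` (columns
#' `probe_id`, `chrom`, `pos`, optional `pfb` and `gc`).
#'
#' All positions are 1-based. The returned map is sorted by genome order
#' (chrom, pos); unsorted input is accepted and sorted with a message.
#' Duplicate probe ids are an error.
#'
#' @param path Path to the probe map file (tab-separated, with header).
#' @param dialect `"tsv"` or `"pfb"`.
#' @return A tibble with columns `probe_id`, `chrom` (normalized to
#'   `"chrN"`), `pos` (integer bp, 1-based), `pfb` and `gc` (fractions,
#'   `NA` when absent).
#' @export
read_probe_map <- function(path, dialect = c("tsv", "pfb")) {
  dialect <- match.arg(dialect)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (dialect == "pfb") {
    stopifnot_cols(df, c("Name", "Chr", "Position"), "PFB probe map")
    df <- tibble(
      probe_id = as.character(df$Name),
      chrom = as.character(df$Chr),
      pos = df$Position,
      pfb = if ("PFB" %in% names(df)) df$PFB else NA_real_,
      gc = NA_real_
    )
  } else {
    stopifnot_cols(df, c("probe_id", "chrom", "pos"), "probe map")
    df <- tibble(
      probe_id = as.character(df$probe_id),
      chrom = as.character(df$chrom),
      pos = df$pos,
      pfb = if ("pfb" %in% names(df)) df$pfb else NA_real_,
      gc = if ("gc" %in% names(df)) df$gc else NA_real_
    )
  }
  validate_probe_map(df, source = path)
}

validate_probe_map <- function(df, source = "probe map") {
  bad <- which(is.na(df$pos) | df$pos < 1)
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid position at line %d (pos must be >= 1)",
                  source, bad[1] + 1L))
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0) {
    abort(sprintf("%s: duplicate probe_id(s): %s",
                  source, paste(unique(dup), collapse = ", ")))
  }
  ok <- !is.na(df$pfb) & (df$pfb < 0 | df$pfb > 1)
  if (any(ok)) abort(sprintf("%s: PFB outside [0,1]", source))
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  sorted <- arrange_genome(df, .data$pos)
  if (!identical(sorted$probe_id, df$probe_id)) {
    inform(sprintf("%s: probes were not in genome order; sorted.", source))
  }
  sorted
}

#' Write a probe map in PFB dialect
#'
#' @param map A probe map tibble (see [read_probe_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_map <- function(map, path) {
  out <- tibble(Name = map$probe_id, Chr = sub("^chr", "", map$chrom),
                Position = map$pos,
                PFB = ifelse(is.na(map$pfb), 0.5, map$pfb))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read CNV calls (PennCNV rawcnv or TSV dialect)
#'
#' Parses per-sample CNV calls. The rawcnv dialect is PennCNV's text output,
#' one call per line:
#'
#' ```
#' chr1:109367944-109371874  numsnp=12  length=3,931  state2,cn=1  S001  startsnp=rs1 endsnp=rs2
#' ```
#'
#' The TSV dialect has a header with columns `sample_id`, `chrom`, `start`,
#' `end`, `cn`, `n_probes` and optional `conf`. The dialect is detected from
#' the first non-empty line unless given.
#'
#' Calls are by definition non-diploid: a record with `cn = 2` is rejected,
#' as is `start > end`. Coordinates are 1-based inclusive.
#'
#' @param path Path to the call file.
#' @param dialect `"auto"`, `"rawcnv"` or `"tsv"`.
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`,
#'   `cn`, `n_probes`, `conf` (`NA` when absent) and derived `cnv_type`
#'   (`"deletion"`/`"duplication"`).
#' @export
read_cnv_calls <- function(path, dialect = c("auto", "rawcnv", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_calls())
  if (dialect == "auto") {
    dialect <- if (grepl("^chr[0-9XYM]+:[0-9]+-[0-9]+\\s", lines[1])) "rawcnv" else "tsv"
  }
  if (dialect == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot_cols(df, c("sample_id", "chrom", "start", "end", "cn", "n_probes"),
                   "CNV call table")
    calls <- tibble(
      sample_id = as.character(df$sample_id),
      chrom = normalize_chrom(df$chrom),
      start = as.integer(df$start), end = as.integer(df$end),
      cn = as.integer(df$cn), n_probes = as.integer(df$n_probes),
      conf = if ("conf" %in% names(df)) as.numeric(df$conf) else NA_real_
    )
  } else {
    calls <- purrr::map_dfr(seq_along(lines), function(i) {
      parse_rawcnv_line(lines[i], i, path)
    })
  }
  validate_calls(calls, source = path)
}

parse_rawcnv_line <- function(line, lineno, source) {
  fields <- strsplit(trimws(line), "\\s+")[[1]]
  region <- regmatches(fields[1],
    regexec("^(chr[0-9XYM]+):([0-9]+)-([0-9]+)$", fields[1]))[[1]]
  if (length(region) != 4) {
    abort(sprintf("%s: line %d: cannot parse region '%s'", source, lineno, fields[1]))
  }
  grab <- function(key) {
    hit <- grep(paste0("^", key, "="), fields, value = TRUE)
    if (length(hit) == 0) NA_character_ else sub(paste0("^", key, "="), "", hit[1])
  }
  state <- grep("^state[0-9]+,cn=[0-9]+$", fields, value = TRUE)
  if (length(state) == 0) {
    abort(sprintf("%s: line %d: missing state/cn field", source, lineno))
  }
  cn <- as.integer(sub("^state[0-9]+,cn=", "", state[1]))
  nsnp <- grab("numsnp")
  # the sample field is the first token that is neither the region, a
  # key=value pair, nor the state field (PennCNV puts the input file there)
  kv <- grepl("=", fields) | seq_along(fields) == 1
  sample_id <- fields[!kv][1]
  if (is.na(sample_id)) {
    abort(sprintf("%s: line %d: missing sample field", source, lineno))
  }
  conf <- grab("conf")
  tibble(
    sample_id = sample_id,
    chrom = region[2],
    start = as.integer(region[3]), end = as.integer(region[4]),
    cn = cn,
    n_probes = as.integer(gsub(",", "", nsnp %||% NA_character_)),
    conf = as.numeric(conf)
  )
}

empty_calls <- function() {
  tibble(sample_id = character(), chrom = character(),
         start = integer(), end = integer(), cn = integer(),
         n_probes = integer(), conf = numeric(), cnv_type = character())
}

validate_calls <- function(calls, source = "CNV calls") {
  if (nrow(calls) == 0) return(empty_calls())
  if (any(calls$cn == 2, na.rm = TRUE)) {
    abort(sprintf("%s: call with cn=2 (diploid records are not CNV calls)", source))
  }
  if (any(!calls$cn %in% c(0L, 1L, 3L, 4L))) {
    abort(sprintf("%s: copy number outside {0,1,3,4}", source))
  }
  if (any(calls$start > calls$end)) {
    abort(sprintf("%s: call with start > end", source))
  }
  calls$cnv_type <- cn_to_type(calls$cn)
  arrange_genome(calls, .data$start, .data$end, .data$sample_id)
}

#' Write CNV calls in PennCNV rawcnv dialect
#'
#' The emitted text is accepted back by [read_cnv_calls()] (round-trip safe)
#' and by PennCNV-consuming tools.
#'
#' @param calls A CNV call tibble (see [read_cnv_calls()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path) {
  state <- c(`0` = 1L, `1` = 2L, `3` = 5L, `4` = 6L)[as.character(calls$cn)]
  lines <- sprintf("%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s",
                   calls$chrom, calls$start, calls$end,
                   ifelse(is.na(calls$n_probes), 0L, calls$n_probes),
                   calls$end - calls$start + 1L,
                   state, calls$cn, calls$sample_id)
  conf <- !is.na(calls$conf)
  lines[conf] <- paste0(lines[conf], sprintf(" conf=%g", calls$conf[conf]))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read intervals from a BED file into 1-based inclusive coordinates
#'
#' BED is 0-based half-open; internally all coordinates are 1-based
#' inclusive, so start gains 1 and end is kept. The BED name column (gene or
#' cytoband label) is carried through as `name`.
#'
#' @param path Path to a BED file (no header; columns chrom, start, end,
#'   name).
#' @param merge_by_name If `TRUE`, overlapping or book-ended intervals
#'   sharing a name (e.g. exons of one gene) are unioned per name.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, sorted by
#'   genome order.
#' @export
read_exon_intervals <- function(path, merge_by_name = FALSE) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t")
  n <- lengths(parts)
  if (any(n < 3)) {
    abort(sprintf("%s: BED line %d has fewer than 3 fields",
                  path, which(n < 3)[1]))
  }
  df <- tibble(
    chrom = normalize_chrom(vapply(parts, `[`, "", 1)),
    start0 = as.integer(vapply(parts, `[`, "", 2)),
    end0 = as.integer(vapply(parts, `[`, "", 3)),
    name = vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_, "")
  )
  if (any(is.na(df$start0) | is.na(df$end0)) || any(df$start0 < 0)) {
    abort(sprintf("%s: negative or non-numeric BED coordinates", path))
  }
  out <- tibble(chrom = df$chrom, start = df$start0 + 1L, end = df$end0,
                name = df$name)
  if (merge_by_name) out <- merge_intervals_by_name(out)
  arrange_genome(out, .data$start, .data$end)
}

merge_intervals_by_name <- function(iv) {
  iv |>
    group_by(.data$chrom, .data$name) |>
    group_modify(function(g, key) {
      r <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) |>
    ungroup()
}

#' Read a sample phenotype table
#'
#' @param path TSV with header columns `sample_id`, `phenotype`
#'   (`case`/`control`), optional `sex` (`male`/`female`/`unknown`) and
#'   `group` (e.g. ethnicity label).
#' @return A tibble with those columns plus `included = TRUE` (updated by
#'   [apply_sample_qc()]).
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("sample_id", "phenotype"), "phenotype table")
  if (anyDuplicated(df$sample_id)) abort("phenotype table: duplicate sample_id")
  bad <- setdiff(unique(df$phenotype), c("case", "control"))
  if (length(bad) > 0) {
    abort(sprintf("phenotype table: phenotype must be case/control (saw %s)",
                  paste(bad, collapse = ", ")))
  }
  tibble(
    sample_id = as.character(df$sample_id),
    phenotype = df$phenotype,
    sex = if ("sex" %in% names(df)) df$sex else "unknown",
    group = if ("group" %in% names(df)) df$group else NA_character_,
    included = TRUE
  )
}

#' Write a CNVR association table
#'
#' Emits one row per region with the standard reporting columns
#' (`CNVR(hg19)`, `P`, `Cases CNV`, `Controls CNV`, `Gene`, `CNV Type`,
#' `Cytoband`), sorted by ascending p-value, p printed to 3 significant
#' figures.
#'
#' @param regions A region tibble (from [cnv_associate()] /
#'   [annotate_regions()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  cols <- c("CNVR(hg19)", "P", "Cases CNV", "Controls CNV",
            "Gene", "CNV Type", "Cytoband")
  if (nrow(regions) == 0) {
    readr::write_lines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  regions <- arrange(regions, .data$p)
  out <- tibble(
    `CNVR(hg19)` = sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end),
    P = vapply(signif(regions$p, 3), format, "", scientific = FALSE,
               trim = TRUE),
    `Cases CNV` = regions$case_carriers,
    `Controls CNV` = regions$control_carriers,
    Gene = if ("genes" %in% names(regions)) {
      vapply(regions$genes, function(g) paste(sort(unique(g)), collapse = ","), "")
    } else "",
    `CNV Type` = ifelse(regions$cnv_type == "deletion", "Del", "Dup"),
    Cytoband = if ("cytoband" %in% names(regions)) regions$cytoband else NA_character_
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a CNVR association table written by [write_region_table()]
#'
#' @param path Path to the table.
#' @return A region tibble with columns `chrom`, `start`, `end`, `p`,
#'   `case_carriers`, `control_carriers`, `genes`, `cnv_type`, `cytoband`.
#' @export
read_region_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  p = numeric(), case_carriers = integer(),
                  control_carriers = integer(), genes = list(),
                  cnv_type = character(), cytoband = character()))
  }
  m <- regmatches(df$`CNVR(hg19)`,
                  regexec("^(chr[0-9XYM]+):([0-9]+)-([0-9]+)$", df$`CNVR(hg19)`))
  tibble(
    chrom = vapply(m, `[`, "", 2),
    start = as.integer(vapply(m, `[`, "", 3)),
    end = as.integer(vapply(m, `[`, "", 4)),
    p = df$P,
    case_carriers = as.integer(df$`Cases CNV`),
    control_carriers = as.integer(df$`Controls CNV`),
    genes = lapply(strsplit(as.character(df$Gene), ","), function(g) g[nzchar(g) & !is.na(g)]),
    cnv_type = ifelse(df$`CNV Type` == "Del", "deletion", "duplication"),
    cytoband = as.character(df$Cytoband)
  )
}

#' Read a genotype matrix from TSV
#'
#' @param path TSV with first column `sample_id` and one column per probe;
#'   entries are B-allele dosages 0/1/2 with `NA` for missing.
#' @return A numeric matrix, samples in rows (rownames = sample ids),
#'   probes in columns.
#' @export
read_genotype_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, "sample_id", "genotype matrix")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df$sample_id)
  bad <- m[!is.na(m) & !(m %in% c(0, 1, 2))]
  if (length(bad) > 0) abort("genotype matrix: codes must be 0/1/2 or NA")
  m
}

#' Write a genotype matrix to TSV
#' @param geno Numeric matrix, samples in rows (rownames = sample ids).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(geno, path) {
  df <- as_tibble(geno)
  df <- dplyr::bind_cols(tibble(sample_id = rownames(geno)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read one sample's LRR/BAF intensity track
#'
#' @param path TSV with header columns `probe_id`, `lrr`, `baf`.
#' @param map Optional probe map; when given, the track is checked and
#'   reordered to match the map exactly.
#' @return A tibble with columns `probe_id`, `lrr`, `baf` (baf clipped to
#'   \[0,1\]).
#' @export
read_intensity_track <- function(path, map = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(df, c("probe_id", "lrr", "baf"), "intensity track")
  df <- tibble(probe_id = as.character(df$probe_id),
               lrr = as.numeric(df$lrr),
               baf = pmin(pmax(as.numeric(df$baf), 0), 1))
  if (!is.null(map)) {
    if (!setequal(df$probe_id, map$probe_id) || nrow(df) != nrow(map)) {
      abort("intensity track does not match the probe map")
    }
    df <- df[match(map$probe_id, df$probe_id), ]
  }
  df
}
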