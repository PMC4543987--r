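#' Annotate CNV regions with genes, exon overlap and cytoband
#'
#' Intersects each region (closed 1-based intervals on both sides) with
#' gene spans, exon intervals and cytobands: `genes` collects every gene
#' span the region touches (alphabetical), `exonic` is `TRUE` iff at least
#' one exon interval intersects, and `cytoband` is the band containing the
#' region start (regions extending past that band keep the start band and
#' are flagged `multi_band`). A chromosome missing from an annotation set
#' yields an empty annotation with a warning.
#'
#' @param regions Region tibble (from [cnv_associate()] or
#'   [collapse_to_regions()]).
#' @param exons Exon interval tibble (`chrom`, `start`, `end`, `name`);
#'   see [read_exon_intervals()].
#' @param genes Optional gene-span tibble (same shape); defaults to the
#'   union of exon intervals per gene name.
#' @param cytobands Optional cytoband tibble (`chrom`, `start`, `end`,
#'   `name`).
#' @return `regions` with `genes` (list column), `exonic`, `cytoband`,
#'   `multi_band` columns.
#' @export
annotate_regions <- function(regions, exons, genes = NULL, cytobands = NULL) {
  if (is.null(genes) && nrow(exons) > 0) {
    genes <- exons |>
      group_by(.data$chrom, name = .data$name) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
  }
  warned <- character()
  hit_names <- function(chrom, start, end, iv) {
    if (is.null(iv) || nrow(iv) == 0) return(character())
    sub <- iv[iv$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0) {
      if (!chrom %in% warned) {
        warn(sprintf("chromosome %s absent from annotation", chrom))
        warned <<- c(warned, chrom)
      }
      return(character())
    }
    hits <- IRanges::findOverlaps(IRanges::IRanges(start, end),
                                  IRanges::IRanges(sub$start, sub$end))
    sub$name[S4Vectors::subjectHits(hits)]
  }
  n <- nrow(regions)
  gene_list <- vector("list", n)
  exonic <- logical(n)
  band <- rep(NA_character_, n)
  multi <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ch <- regions$chrom[i]; s <- regions$start[i]; e <- regions$end[i]
    gene_list[[i]] <- sort(unique(hit_names(ch, s, e, genes)))
    exonic[i] <- length(hit_names(ch, s, e, exons)) > 0
    if (!is.null(cytobands)) {
      b_start <- hit_names(ch, s, s, cytobands)
      b_end <- hit_names(ch, e, e, cytobands)
      band[i] <- if (length(b_start) > 0) b_start[1] else NA_character_
      multi[i] <- !identical(b_start[1], b_end[1])
    }
  }
  regions$genes <- gene_list
  regions$exonic <- exonic
  regions$cytoband <- band
  regions$multi_band <- multi
  regions
}

#' Cohort CNV burden profile with case/control comparison
#'
#' Summarises per-subject CNV burden by group: totals and per-subject
#' means of all CNVs, deletions and duplications, with a two-sample
#' t-test (Welch by default) comparing cases to controls on the
#' per-subject counts. Samples without calls count as zero; only
#' QC-included samples enter.
#'
#' @param calls CNV call tibble.
#' @param samples Phenotype tibble.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return A `cohort_profile` object: list with `table` (tibble `metric`,
#'   `cases`, `controls`, `p`) and `per_subject` (tibble of per-subject
#'   counts).
#' @export
cohort_profile <- function(calls, samples, var_equal = FALSE) {
  if ("included" %in% names(samples)) samples <- filter(samples, .data$included)
  counts <- samples |>
    select("sample_id", "phenotype") |>
    left_join(
      calls |>
        group_by(.data$sample_id) |>
        summarise(total = dplyr::n(),
                  deletions = sum(.data$cnv_type == "deletion"),
                  duplications = sum(.data$cnv_type == "duplication"),
                  .groups = "drop"),
      by = "sample_id") |>
    mutate(across(c("total", "deletions", "duplications"),
                  ~ tidyr::replace_na(.x, 0L)))
  grp <- function(ph) counts[counts$phenotype == ph, , drop = FALSE]
  cases <- grp("case"); controls <- grp("control")
  cmp <- function(col) {
    x <- cases[[col]]; y <- controls[[col]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (stats::var(x) == 0 && stats::var(y) == 0) return(1)
    stats::t.test(x, y, var.equal = var_equal)$p.value
  }
  table <- tibble(
    metric = c("n_samples", "total_cnvs", "total_deletions",
               "total_duplications", "mean_cnvs_per_subject",
               "mean_dels_per_subject", "mean_dups_per_subject"),
    cases = c(nrow(cases), sum(cases$total), sum(cases$deletions),
              sum(cases$duplications), mean(cases$total),
              mean(cases$deletions), mean(cases$duplications)),
    controls = c(nrow(controls), sum(controls$total), sum(controls$deletions),
                 sum(controls$duplications), mean(controls$total),
                 mean(controls$deletions), mean(controls$duplications)),
    p = c(NA, NA, NA, NA, cmp("total"), cmp("deletions"), cmp("duplications"))
  )
  structure(list(table = table, per_subject = counts),
            class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  t <- x$table
  get <- function(m, col) t[[col]][t$metric == m]
  cat(sprintf(
    "Cohort profile: %d cases / %d controls\nmean CNVs per subject %.1f vs %.1f (t-test p = %.2g)\n",
    get("n_samples", "cases"), get("n_samples", "controls"),
    get("mean_cnvs_per_subject", "cases"),
    get("mean_cnvs_per_subject", "controls"),
    get("mean_cnvs_per_subject", "p")))
  invisible(x)
}

#' Write the report tables for an association run
#'
#' Emits three TSVs into `out_dir`: the cohort burden profile
#' (`cohort_profile.tsv`, means to one decimal), the CNVR association
#' table (`cnvr_table.tsv`, standard reporting columns sorted by p) and a
#' run log (`run_log.tsv`) recording the number of CNVR tests and the
#' experiment-wide threshold.
#'
#' @param profile A [cohort_profile()] object.
#' @param fit A `cnv_assoc` object (annotated regions preferred).
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
render_tables <- function(profile, fit, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(profile = file.path(out_dir, "cohort_profile.tsv"),
             regions = file.path(out_dir, "cnvr_table.tsv"),
             log = file.path(out_dir, "run_log.tsv"))
  tab <- profile$table |>
    mutate(cases = ifelse(grepl("^mean", .data$metric),
                          round(.data$cases, 1), .data$cases),
           controls = ifelse(grepl("^mean", .data$metric),
                             round(.data$controls, 1), .data$controls),
           p = signif(.data$p, 2))
  readr::write_tsv(tab, paths["profile"], progress = FALSE)
  write_region_table(fit$regions, paths["regions"])
  readr::write_tsv(tibble(n_tests = fit$n_tests,
                          threshold = signif(fit$threshold, 3),
                          fwer = fit$fwer,
                          n_significant = sum(fit$regions$significant)),
                   paths["log"], progress = FALSE)
  invisible(paths)
}
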