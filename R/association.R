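#' Build the per-probe CNV carrier matrix
#'
#' For one CNV type (deletion or duplication), marks each (sample, probe)
#' pair as carrier if the sample has at least one call of that type whose
#' 1-based inclusive span covers the probe position. Overlapping calls in
#' one sample still count once (boolean carrier status).
#'
#' @param calls CNV call tibble.
#' @param map Probe map tibble.
#' @param samples Phenotype tibble; if it has an `included` column only
#'   included samples enter the matrix.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @return A `carrier_matrix` object: list with `cnv_type`, `probes`
#'   (tibble `probe_id`, `chrom`, `pos`), `samples` (tibble `sample_id`,
#'   `phenotype`), and `carrier` (logical matrix, samples x probes).
#' @export
build_carrier_matrix <- function(calls, map, samples,
                                 cnv_type = c("deletion", "duplication")) {
  cnv_type <- match.arg(cnv_type)
  if ("included" %in% names(samples)) samples <- filter(samples, .data$included)
  ids <- samples$sample_id
  calls <- filter(calls, .data$cnv_type == !!cnv_type,
                  .data$sample_id %in% ids)
  off_map <- setdiff(unique(calls$chrom), unique(map$chrom))
  if (length(off_map) > 0) {
    warn(sprintf("calls on chromosome(s) absent from probe map skipped: %s",
                 paste(off_map, collapse = ", ")))
    calls <- filter(calls, !.data$chrom %in% off_map)
  }
  carrier <- matrix(FALSE, nrow = length(ids), ncol = nrow(map),
                    dimnames = list(ids, map$probe_id))
  for (chr in unique(calls$chrom)) {
    probe_idx <- which(map$chrom == chr)
    cc <- filter(calls, .data$chrom == chr)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(map$pos[probe_idx], map$pos[probe_idx]),
      IRanges::IRanges(cc$start, cc$end))
    pi <- probe_idx[S4Vectors::queryHits(hits)]
    si <- match(cc$sample_id[S4Vectors::subjectHits(hits)], ids)
    carrier[cbind(si, pi)] <- TRUE
  }
  structure(
    list(cnv_type = cnv_type,
         probes = map[, c("probe_id", "chrom", "pos")],
         samples = samples[, c("sample_id", "phenotype")],
         carrier = carrier),
    class = "carrier_matrix"
  )
}

#' @export
print.carrier_matrix <- function(x, ...) {
  cat(sprintf("Carrier matrix (%s): %d samples x %d probes, %d carrier cells\n",
              x$cnv_type, nrow(x$carrier), ncol(x$carrier), sum(x$carrier)))
  invisible(x)
}

#' Fisher exact test for CNV carrier enrichment in cases
#'
#' Exact p-value for the 2x2 table (case carriers `a` of `n1` cases,
#' control carriers `c` of `n2` controls). `"one_greater"` (default) is the
#' upper hypergeometric tail — the probability of `a` or more case carriers
#' given the margins — testing enrichment in cases; `"two"` is the
#' two-sided test by the point-probability rule (all tables no more likely
#' than the observed one). Vectorized over `a` and `c`.
#'
#' @param a Case carrier count(s), `0 <= a <= n1`.
#' @param n1 Number of cases (> 0).
#' @param c Control carrier count(s), `0 <= c <= n2`.
#' @param n2 Number of controls (> 0).
#' @param sided `"one_greater"` or `"two"`.
#' @return p-value(s) in (0, 1].
#' @export
fisher_case_enrichment <- function(a, n1, c, n2,
                                   sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  if (n1 < 1 || n2 < 1) abort("both groups must be non-empty")
  if (any(a < 0 | a > n1) || any(c < 0 | c > n2)) {
    abort("carrier counts outside [0, group size]")
  }
  m <- a + c
  if (sided == "one_greater") {
    p <- stats::phyper(a - 1, m, n1 + n2 - m, n1, lower.tail = FALSE)
  } else {
    p <- mapply(function(ai, mi) {
      lo <- max(0, mi - n2); hi <- min(n1, mi)
      d <- stats::dhyper(lo:hi, mi, n1 + n2 - mi, n1)
      sum(d[d <= d[ai - lo + 1] * (1 + 1e-7)])
    }, a, m)
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Per-probe Fisher scan over a carrier matrix
#'
#' Tests, at every probe, whether carriers of the matrix's CNV type are
#' enriched in cases versus controls.
#'
#' @param carriers A [build_carrier_matrix()] result.
#' @param sided Passed to [fisher_case_enrichment()].
#' @return A tibble with one row per probe: `probe_id`, `chrom`, `pos`,
#'   `cnv_type`, `a` (case carriers), `n1`, `c` (control carriers), `n2`,
#'   `p`.
#' @export
fisher_scan <- function(carriers, sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  is_case <- carriers$samples$phenotype == "case"
  n1 <- sum(is_case); n2 <- sum(!is_case)
  a <- unname(colSums(carriers$carrier[is_case, , drop = FALSE]))
  c_ <- unname(colSums(carriers$carrier[!is_case, , drop = FALSE]))
  p <- fisher_case_enrichment(a, n1, c_, n2, sided)
  tibble(
    probe_id = carriers$probes$probe_id,
    chrom = carriers$probes$chrom,
    pos = carriers$probes$pos,
    cnv_type = carriers$cnv_type,
    a = as.integer(a), n1 = n1,
    c = as.integer(c_), n2 = n2,
    p = p
  )
}

#' Prefilter probes by minimum case carrier count
#'
#' Keeps probes carried by at least `min_case_carriers` cases — the
#' upfront frequency filter analogous to a minor-allele-frequency cutoff
#' in SNP GWAS. The implied minimum case frequency
#' (`min_case_carriers / n1`) is attached as attribute
#' `min_case_frequency`.
#'
#' @param tests Probe-test tibble from [fisher_scan()].
#' @param min_case_carriers Minimum case carriers (default 3; 0 keeps all).
#' @return The filtered tibble.
#' @export
prefilter_probes <- function(tests, min_case_carriers = 3) {
  out <- filter(tests, .data$a >= min_case_carriers)
  attr(out, "min_case_frequency") <-
    if (nrow(tests) > 0) min_case_carriers / tests$n1[1] else NA_real_
  out
}

#' Smallest case carrier count reaching nominal significance
#'
#' Ascending search for the smallest number of case carriers `a` such that
#' `fisher_case_enrichment(a, n1, 0, n2) < alpha` — i.e. the minimal case
#' frequency that could yield nominal significance against carrier-free
#' controls. Returns `n1 + 1` (with attribute `attainable = FALSE`) if no
#' count suffices.
#'
#' @param n1,n2 Group sizes (>= 1).
#' @param alpha Nominal level (default 0.05).
#' @param sided Passed to [fisher_case_enrichment()].
#' @return Integer count, with attributes `min_case_frequency` and
#'   `attainable`.
#' @export
min_nominal_case_count <- function(n1, n2, alpha = 0.05,
                                   sided = c("one_greater", "two")) {
  sided <- match.arg(sided)
  for (a in 0:n1) {
    if (fisher_case_enrichment(a, n1, 0, n2, sided) < alpha) {
      return(structure(a, min_case_frequency = a / n1, attainable = TRUE))
    }
  }
  structure(n1 + 1L, min_case_frequency = NA_real_, attainable = FALSE)
}

#' Collapse probe tests into CNV regions (CNVRs)
#'
#' Left-to-right sweep over position-sorted probe tests of one CNV type:
#' consecutive probes stay in the same region while they share a
#' chromosome, are closer than `max_gap` bp, and have comparable
#' significance — within `log_band` units of log10 p of the previous
#' retained probe (`band_mode = "chained"`, default) or of the running
#' region minimum (`"region_min"`). Probes with no carriers in either
#' group are dropped first (their undefined-as-1 p-values would otherwise
#' bridge unrelated regions).
#'
#' Each region is represented by its anchor probe — the leftmost member
#' with the minimal p — whose p-value and carrier counts become the
#' region's.
#'
#' @param tests Filtered probe-test tibble (one `cnv_type`).
#' @param max_gap Maximum intra-region inter-probe gap in bp, exclusive
#'   (default 1 Mb: a gap >= 1 Mb splits).
#' @param log_band Maximum |log10 p| difference (default 1.0).
#' @param band_mode `"chained"` or `"region_min"`.
#' @return A region tibble: `chrom`, `start`, `end`, `cnv_type`,
#'   `n_probes`, `anchor_probe`, `p`, `case_carriers`, `control_carriers`,
#'   `member_probes` (list column), sorted by genome order.
#' @export
collapse_to_regions <- function(tests, max_gap = 1e6, log_band = 1.0,
                                band_mode = c("chained", "region_min")) {
  band_mode <- match.arg(band_mode)
  if (length(unique(tests$cnv_type)) > 1) {
    abort("collapse one cnv_type at a time")
  }
  tests <- tests |>
    filter(.data$a + .data$c > 0) |>
    arrange_genome(.data$pos)
  if (nrow(tests) == 0) return(empty_regions())
  lp <- log10(tests$p)
  region_id <- integer(nrow(tests))
  cur <- 1L
  region_id[1] <- cur
  ref_lp <- lp[1]
  for (i in seq_len(nrow(tests))[-1]) {
    new_chrom <- tests$chrom[i] != tests$chrom[i - 1]
    big_gap <- !new_chrom && (tests$pos[i] - tests$pos[i - 1]) >= max_gap
    far_p <- abs(lp[i] - ref_lp) > log_band
    if (new_chrom || big_gap || far_p) {
      cur <- cur + 1L
      ref_lp <- lp[i]
    } else {
      ref_lp <- if (band_mode == "chained") lp[i] else min(ref_lp, lp[i])
    }
    region_id[i] <- cur
  }
  tests$`..region` <- region_id
  regions <- tests |>
    group_by(.data$`..region`) |>
    group_modify(function(g, key) {
      anchor <- which(g$p == min(g$p))[1]  # leftmost minimal p
      tibble(chrom = g$chrom[1], start = min(g$pos), end = max(g$pos),
             cnv_type = g$cnv_type[1], n_probes = nrow(g),
             anchor_probe = g$probe_id[anchor], p = g$p[anchor],
             case_carriers = g$a[anchor], control_carriers = g$c[anchor],
             member_probes = list(g$probe_id))
    }) |>
    ungroup() |>
    select(-"..region")
  arrange_genome(regions, .data$start)
}

empty_regions <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         cnv_type = character(), n_probes = integer(),
         anchor_probe = character(), p = numeric(),
         case_carriers = integer(), control_carriers = integer(),
         member_probes = list())
}

#' Experiment-wide Bonferroni significance threshold
#'
#' The number of CNVR tests is the total count of deletion plus duplication
#' regions; the experiment-wide threshold is the family-wise error rate
#' divided by that count.
#'
#' @param n_del_regions,n_dup_regions Region counts (>= 0, not both 0).
#' @param fwer Family-wise error rate (default 0.05).
#' @return A list with `n_tests` and `threshold`.
#' @export
experimentwide_threshold <- function(n_del_regions, n_dup_regions,
                                     fwer = 0.05) {
  n <- n_del_regions + n_dup_regions
  if (n <= 0) abort("no CNV regions: experiment-wide threshold undefined")
  list(n_tests = as.integer(n), threshold = fwer / n)
}

#' Run the full segment-based CNV case/control association scan
#'
#' Composes the whole pipeline for both CNV types independently: carrier
#' matrix, per-probe Fisher scan, case-carrier prefilter, collapse into
#' CNVRs, and the experiment-wide Bonferroni threshold over the combined
#' region count. Deletion and duplication regions are then concatenated and
#' flagged against the derived threshold. Region carrier counts are those
#' of the anchor probe; union counts over the whole region span are
#' emitted alongside (`case_carriers_union`, `control_carriers_union`).
#'
#' @param calls CNV call tibble (QC-passed samples).
#' @param map Probe map tibble.
#' @param samples Phenotype tibble (rows with `included = FALSE` are
#'   dropped).
#' @param min_case_carriers,max_gap,log_band,sided,fwer,band_mode Scan
#'   parameters; see the stage functions.
#' @return A `cnv_assoc` object: list with `regions` (tibble incl.
#'   `significant` flag), `probe_tests`, `n_tests`, `threshold`, `fwer`,
#'   `n_cases`, `n_controls`, `params`.
#' @export
cnv_associate <- function(calls, map, samples, min_case_carriers = 3,
                          max_gap = 1e6, log_band = 1.0,
                          sided = c("one_greater", "two"), fwer = 0.05,
                          band_mode = c("chained", "region_min")) {
  sided <- match.arg(sided)
  band_mode <- match.arg(band_mode)
  per_type <- lapply(c("deletion", "duplication"), function(ty) {
    cm <- build_carrier_matrix(calls, map, samples, ty)
    tests <- fisher_scan(cm, sided)
    kept <- prefilter_probes(tests, min_case_carriers)
    regions <- collapse_to_regions(kept, max_gap, log_band, band_mode)
    if (nrow(regions) > 0) {
      uni <- region_union_counts(regions, cm)
      regions$case_carriers_union <- uni$case
      regions$control_carriers_union <- uni$control
    } else {
      regions$case_carriers_union <- integer()
      regions$control_carriers_union <- integer()
    }
    list(tests = tests, regions = regions, cm = cm)
  })
  regions <- dplyr::bind_rows(per_type[[1]]$regions, per_type[[2]]$regions)
  mt <- experimentwide_threshold(nrow(per_type[[1]]$regions),
                                 nrow(per_type[[2]]$regions), fwer)
  regions$significant <- regions$p < mt$threshold
  n_case <- sum(per_type[[1]]$cm$samples$phenotype == "case")
  n_ctrl <- sum(per_type[[1]]$cm$samples$phenotype == "control")
  structure(
    list(
      regions = arrange(regions, .data$p),
      probe_tests = dplyr::bind_rows(per_type[[1]]$tests, per_type[[2]]$tests),
      n_tests = mt$n_tests, threshold = mt$threshold, fwer = fwer,
      n_cases = n_case, n_controls = n_ctrl,
      params = list(min_case_carriers = min_case_carriers, max_gap = max_gap,
                    log_band = log_band, sided = sided, band_mode = band_mode)
    ),
    class = "cnv_assoc"
  )
}

# carriers of >= 1 spanning call anywhere in the region (union over members)
region_union_counts <- function(regions, cm) {
  is_case <- cm$samples$phenotype == "case"
  case <- integer(nrow(regions)); control <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    cols <- match(regions$member_probes[[i]], cm$probes$probe_id)
    any_carrier <- rowSums(cm$carrier[, cols, drop = FALSE]) > 0
    case[i] <- sum(any_carrier & is_case)
    control[i] <- sum(any_carrier & !is_case)
  }
  list(case = case, control = control)
}

#' @export
print.cnv_assoc <- function(x, ...) {
  cat(sprintf(
    "CNV association scan: %d cases / %d controls\n%d CNVR tests, experiment-wide threshold %.3g\n%d region(s) significant\n",
    x$n_cases, x$n_controls, x$n_tests, x$threshold,
    sum(x$regions$significant)))
  invisible(x)
}
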