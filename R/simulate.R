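# Named substream seeding: every stochastic stage draws from its own
# deterministic substream of the master seed, so stages can be regenerated
# independently and the whole cohort is byte-reproducible.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483562) + 1L
}

with_substream <- function(seed, name, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, name))
  force(code)
}

#' Describe a synthetic case/control CNV cohort
#'
#' Full generative description of a simulated two-group SNP-array cohort:
#' group sizes, probe grid, low-frequency causal CNV regions (spiked
#' deletion/duplication carrier frequencies per group), background CNVs at
#' realistic per-subject rates, boundary jitter and call error rates. The
#' defaults emulate the study conditions the pipeline targets: 63 cases and
#' 145 controls, ~75 and ~64 background CNVs per subject respectively, a
#' desk-scale probe grid of 2 chromosomes x 25 Mb at 4 kb spacing.
#'
#' @param n_cases,n_controls Group sizes (defaults 63 / 145).
#' @param probe_spacing Probe spacing in bp (default 4000).
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param causal_regions Tibble with columns `chrom`, `start`, `end`,
#'   `cnv_type`, `case_freq`, `control_freq` and optional exact-count
#'   columns `case_carriers`, `control_carriers` (integer counts override
#'   the Bernoulli frequencies).
#' @param background_rate_case,background_rate_control Mean background
#'   CNVs per subject (Poisson; defaults 75.2 / 64.1).
#' @param bg_len_meanlog,bg_len_sdlog Log-normal background CNV length
#'   (default median 50 kb, sigma_log 1).
#' @param del_fraction Fraction of background CNVs that are deletions
#'   (default 0.27, ~1:2.7 deletion:duplication).
#' @param boundary_jitter_sd SD of call-boundary jitter in probes
#'   (default 1).
#' @param call_fp_rate,call_fn_rate Per-sample probability of a spurious
#'   causal-locus call in a non-carrier / of dropping a true carrier call
#'   (defaults 0.01 / 0.05).
#' @param seed Master seed (mandatory; every draw is a named substream of
#'   it).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 63, n_controls = 145,
                        probe_spacing = 4000,
                        chromosomes = c(chr1 = 25e6, chr2 = 25e6),
                        causal_regions = NULL,
                        background_rate_case = 75.2,
                        background_rate_control = 64.1,
                        bg_len_meanlog = log(5e4), bg_len_sdlog = 1.0,
                        del_fraction = 0.27,
                        boundary_jitter_sd = 1,
                        call_fp_rate = 0.01, call_fn_rate = 0.05,
                        seed) {
  if (missing(seed)) abort("cohort_spec requires an explicit seed")
  if (is.null(causal_regions)) {
    causal_regions <- tibble(chrom = character(), start = integer(),
                             end = integer(), cnv_type = character(),
                             case_freq = numeric(), control_freq = numeric())
  }
  causal_regions <- as_tibble(causal_regions)
  if (nrow(causal_regions) > 0) {
    if (any(!causal_regions$chrom %in% names(chromosomes)) ||
        any(causal_regions$end > chromosomes[causal_regions$chrom]) ||
        any(causal_regions$start < 1)) {
      abort("causal region outside its chromosome")
    }
    in01 <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
    if (!in01(causal_regions$case_freq) || !in01(causal_regions$control_freq)) {
      abort("causal carrier frequencies must be in [0,1]")
    }
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls,
    probe_spacing = probe_spacing, chromosomes = chromosomes,
    causal_regions = causal_regions,
    background_rate_case = background_rate_case,
    background_rate_control = background_rate_control,
    bg_len_meanlog = bg_len_meanlog, bg_len_sdlog = bg_len_sdlog,
    del_fraction = del_fraction,
    boundary_jitter_sd = boundary_jitter_sd,
    call_fp_rate = call_fp_rate, call_fn_rate = call_fn_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Simulate a synthetic CNV cohort
#'
#' Generates, fully reproducibly from the spec's master seed: the probe
#' map (with PFB and a smooth GC track), the phenotype table, causal-region
#' carrier assignments (Bernoulli per group frequency, or forced exact
#' counts), background CNV calls (Poisson per subject, log-normal lengths,
#' uniform placement), boundary jitter in whole probes, and false
#' negative/positive call noise at the causal loci. The truth table records
#' carrier ground truth before any noise.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `map` (probe map tibble), `samples` (phenotype
#'   tibble), `calls` (CNV call tibble) and `truth` (tibble `region_id`,
#'   `chrom`, `start`, `end`, `cnv_type`, `sample_id`, `carrier`).
#' @export
simulate_cohort <- function(spec) {
  map <- with_substream(spec$seed, "map", sim_probe_map(spec))
  samples <- with_substream(spec$seed, "samples", sim_samples(spec))
  truth <- with_substream(spec$seed, "carriers", sim_carriers(spec, samples))
  causal <- with_substream(spec$seed, "causal_calls",
                           sim_causal_calls(spec, map, truth))
  background <- with_substream(spec$seed, "background",
                               sim_background_calls(spec, map, samples))
  calls <- dplyr::bind_rows(causal, background)
  calls <- with_substream(spec$seed, "jitter", sim_jitter(spec, map, calls))
  calls <- validate_calls(calls, source = "simulate_cohort")
  list(map = map, samples = samples, calls = calls, truth = truth)
}

sim_probe_map <- function(spec) {
  maps <- purrr::imap(as.list(spec$chromosomes), function(len, chr) {
    pos <- seq(spec$probe_spacing %/% 2, len, by = spec$probe_spacing)
    # GC varies smoothly at the ~Mb scale around 0.45
    win_gc <- stats::runif(ceiling(len / 1e6), 0.35, 0.55)
    tibble(
      probe_id = sprintf("%s_p%06d", chr, seq_along(pos)),
      chrom = chr, pos = as.integer(pos),
      pfb = round(stats::runif(length(pos), 0.05, 0.95), 4),
      gc = round(win_gc[pos %/% 1e6 + 1], 4)
    )
  })
  validate_probe_map(dplyr::bind_rows(maps), source = "simulated map")
}

sim_samples <- function(spec) {
  ids <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
           sprintf("ctrl_%03d", seq_len(spec$n_controls)))
  tibble(
    sample_id = ids,
    phenotype = rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
    sex = sample(c("male", "female"), length(ids), replace = TRUE),
    group = sample(c("popA", "popB"), length(ids), replace = TRUE),
    included = TRUE
  )
}

sim_carriers <- function(spec, samples) {
  cr <- spec$causal_regions
  if (nrow(cr) == 0) {
    return(tibble(region_id = integer(), chrom = character(),
                  start = integer(), end = integer(), cnv_type = character(),
                  sample_id = character(), carrier = logical()))
  }
  purrr::map_dfr(seq_len(nrow(cr)), function(i) {
    carrier <- logical(nrow(samples))
    for (ph in c("case", "control")) {
      idx <- which(samples$phenotype == ph)
      exact_col <- if (ph == "case") "case_carriers" else "control_carriers"
      exact <- if (exact_col %in% names(cr)) cr[[exact_col]][i] else NA
      if (!is.na(exact)) {
        carrier[sample(idx, exact)] <- TRUE
      } else {
        f <- if (ph == "case") cr$case_freq[i] else cr$control_freq[i]
        carrier[idx] <- stats::runif(length(idx)) < f
      }
    }
    tibble(region_id = i, chrom = cr$chrom[i], start = cr$start[i],
           end = cr$end[i], cnv_type = cr$cnv_type[i],
           sample_id = samples$sample_id, carrier = carrier)
  })
}

sim_causal_calls <- function(spec, map, truth) {
  carriers <- filter(truth, .data$carrier)
  if (nrow(carriers) == 0) return(empty_calls()[, 1:7])
  calls <- purrr::map_dfr(seq_len(nrow(carriers)), function(i) {
    row <- carriers[i, ]
    inside <- map$chrom == row$chrom & map$pos >= row$start & map$pos <= row$end
    if (!any(inside)) abort("causal region covers no probes")
    tibble(sample_id = row$sample_id, chrom = row$chrom,
           start = min(map$pos[inside]), end = max(map$pos[inside]),
           cn = if (row$cnv_type == "deletion") 1L else 3L,
           n_probes = sum(inside), conf = NA_real_)
  })
  # false negatives: drop carrier calls; false positives: spurious calls in
  # non-carriers at the same loci
  keep <- stats::runif(nrow(calls)) >= spec$call_fn_rate
  calls <- calls[keep, , drop = FALSE]
  fp <- filter(truth, !.data$carrier)
  if (nrow(fp) > 0 && spec$call_fp_rate > 0) {
    hit <- stats::runif(nrow(fp)) < spec$call_fp_rate
    fp <- fp[hit, , drop = FALSE]
    if (nrow(fp) > 0) {
      extra <- purrr::map_dfr(seq_len(nrow(fp)), function(i) {
        row <- fp[i, ]
        inside <- map$chrom == row$chrom & map$pos >= row$start &
          map$pos <= row$end
        tibble(sample_id = row$sample_id, chrom = row$chrom,
               start = min(map$pos[inside]), end = max(map$pos[inside]),
               cn = if (row$cnv_type == "deletion") 1L else 3L,
               n_probes = sum(inside), conf = NA_real_)
      })
      calls <- dplyr::bind_rows(calls, extra)
    }
  }
  calls
}

sim_background_calls <- function(spec, map, samples) {
  rates <- ifelse(samples$phenotype == "case",
                  spec$background_rate_case, spec$background_rate_control)
  n_per_sample <- stats::rpois(nrow(samples), rates)
  total <- sum(n_per_sample)
  if (total == 0) return(empty_calls()[, 1:7])
  chrom <- sample(names(spec$chromosomes), total, replace = TRUE,
                  prob = spec$chromosomes / sum(spec$chromosomes))
  len <- pmax(spec$probe_spacing,
              round(stats::rlnorm(total, spec$bg_len_meanlog, spec$bg_len_sdlog)))
  chr_len <- spec$chromosomes[chrom]
  start <- floor(stats::runif(total) * pmax(1, chr_len - len)) + 1
  is_del <- stats::runif(total) < spec$del_fraction
  cn <- ifelse(is_del,
               ifelse(stats::runif(total) < 0.1, 0L, 1L),
               ifelse(stats::runif(total) < 0.1, 4L, 3L))
  calls <- tibble(
    sample_id = rep(samples$sample_id, n_per_sample),
    chrom = chrom, start = as.integer(start),
    end = as.integer(pmin(start + len - 1, chr_len)),
    cn = as.integer(cn), conf = NA_real_
  )
  snap_calls_to_probes(calls, map)
}

# snap call boundaries to the covered probe span; drop calls covering no probe
snap_calls_to_probes <- function(calls, map) {
  out <- purrr::map_dfr(split(calls, calls$chrom), function(cc) {
    pos <- map$pos[map$chrom == cc$chrom[1]]
    i1 <- findInterval(cc$start - 1L, pos) + 1L   # first probe >= start
    i2 <- findInterval(cc$end, pos)               # last probe <= end
    ok <- i1 <= i2 & i1 <= length(pos)
    cc <- cc[ok, , drop = FALSE]
    cc$start <- as.integer(pos[i1[ok]])
    cc$end <- as.integer(pos[i2[ok]])
    cc$n_probes <- as.integer(i2[ok] - i1[ok] + 1L)
    cc
  })
  out
}

sim_jitter <- function(spec, map, calls) {
  if (spec$boundary_jitter_sd <= 0 || nrow(calls) == 0) return(calls)
  out <- purrr::map_dfr(split(calls, calls$chrom), function(cc) {
    pos <- map$pos[map$chrom == cc$chrom[1]]
    i1 <- match(cc$start, pos); i2 <- match(cc$end, pos)
    j1 <- i1 + round(stats::rnorm(nrow(cc), 0, spec$boundary_jitter_sd))
    j2 <- i2 + round(stats::rnorm(nrow(cc), 0, spec$boundary_jitter_sd))
    j1 <- pmin(pmax(j1, 1), length(pos))
    j2 <- pmin(pmax(j2, j1), length(pos))
    cc$start <- as.integer(pos[j1]); cc$end <- as.integer(pos[j2])
    cc$n_probes <- as.integer(j2 - j1 + 1L)
    cc
  })
  out
}

#' Simulate LRR/BAF intensity tracks from true copy-number paths
#'
#' The generative inverse of [viterbi_call()]: for each sample, the true
#' copy-number path (diploid except under that sample's calls) drives LRR
#' draws from the state's Gaussian and BAF draws from the state's
#' PFB-weighted genotype-band mixture (uniform for copy number 0, and a
#' uniform outlier component at the emission model's outlier weight).
#'
#' @param calls CNV call tibble giving each sample's true non-diploid
#'   segments.
#' @param map Probe map (PFB defaults to 0.5 where missing).
#' @param params An [hmm_params()] emission model.
#' @param sample_ids Samples to simulate (default: those present in
#'   `calls`).
#' @param seed Master seed.
#' @return Named list of intensity tibbles (`probe_id`, `lrr`, `baf`).
#' @export
simulate_intensities <- function(calls, map, params = hmm_params(),
                                 sample_ids = unique(calls$sample_id),
                                 seed) {
  if (missing(seed)) abort("simulate_intensities requires a seed")
  pfb <- ifelse(is.na(map$pfb), 0.5, map$pfb)
  out <- lapply(sample_ids, function(id) {
    with_substream(seed, paste0("intensity_", id), {
      cn <- rep(2L, nrow(map))
      cc <- filter(calls, .data$sample_id == id)
      for (i in seq_len(nrow(cc))) {
        hit <- map$chrom == cc$chrom[i] & map$pos >= cc$start[i] &
          map$pos <= cc$end[i]
        cn[hit] <- cc$cn[i]
      }
      lrr <- stats::rnorm(nrow(map), params$lrr_mean[cn + 1],
                          params$lrr_sd[cn + 1])
      baf <- numeric(nrow(map))
      for (s in unique(cn)) {
        idx <- which(cn == s)
        if (s == 0) {
          baf[idx] <- stats::runif(length(idx))
        } else {
          k <- stats::rbinom(length(idx), s, pfb[idx])
          baf[idx] <- stats::rnorm(length(idx), k / s, params$baf_sd)
        }
      }
      outlier <- stats::runif(nrow(map)) < params$baf_outlier
      baf[outlier] <- stats::runif(sum(outlier))
      tibble(probe_id = map$probe_id, lrr = lrr,
             baf = pmin(pmax(baf, 0), 1))
    })
  })
  stats::setNames(out, sample_ids)
}

#' Simulate a genotype matrix with optional relatedness and substructure
#'
#' Hardy-Weinberg draws per probe from per-probe allele frequencies.
#' Related pairs are constructed by allele copying (duplicates share the
#' full genotype; a parent transmits one allele per locus to its
#' offspring). In two-subpopulation mode, each subpopulation draws its own
#' allele frequencies around the ancestral ones (Balding-Nichols Beta
#' model at divergence `fst`), which gives PCA-separable structure.
#'
#' @param samples Phenotype tibble (only `sample_id`, and `group` in
#'   subpopulation mode, are used).
#' @param n_probes Number of probes (default 1000).
#' @param freq_range Ancestral allele-frequency range (uniform draw;
#'   default 0.05–0.95).
#' @param related_pairs Optional tibble (`sample_1`, `sample_2`,
#'   `relationship` in `"duplicate"`/`"parent_offspring"`); `sample_2` is
#'   rebuilt from `sample_1`.
#' @param subpop Divergent-frequency mode: `NULL` (off) or the name of the
#'   sample column holding the subpopulation label.
#' @param fst Subpopulation divergence (default 0.1).
#' @param missing_rate Fraction of genotypes set missing (default 0).
#' @param seed Master seed.
#' @return Numeric matrix (samples x probes, B-allele dosage 0/1/2) with
#'   attribute `allele_freqs`.
#' @export
simulate_genotypes <- function(samples, n_probes = 1000,
                               freq_range = c(0.05, 0.95),
                               related_pairs = NULL, subpop = NULL,
                               fst = 0.1, missing_rate = 0, seed) {
  if (missing(seed)) abort("simulate_genotypes requires a seed")
  n <- nrow(samples)
  with_substream(seed, "genotypes", {
    p <- stats::runif(n_probes, freq_range[1], freq_range[2])
    if (!is.null(subpop)) {
      labels <- samples[[subpop]]
      shape <- (1 - fst) / fst
      pk <- lapply(unique(labels), function(l) {
        stats::rbeta(n_probes, p * shape, (1 - p) * shape)
      })
      names(pk) <- unique(labels)
      G <- t(vapply(seq_len(n), function(i) {
        stats::rbinom(n_probes, 2, pk[[labels[i]]])
      }, numeric(n_probes)))
    } else {
      G <- t(vapply(seq_len(n), function(i) stats::rbinom(n_probes, 2, p),
                    numeric(n_probes)))
    }
    rownames(G) <- samples$sample_id
    colnames(G) <- sprintf("snp%05d", seq_len(n_probes))
    if (!is.null(related_pairs)) {
      for (i in seq_len(nrow(related_pairs))) {
        a <- related_pairs$sample_1[i]; b <- related_pairs$sample_2[i]
        if (related_pairs$relationship[i] == "duplicate") {
          G[b, ] <- G[a, ]
        } else {
          transmitted <- stats::rbinom(n_probes, 1, G[a, ] / 2)
          G[b, ] <- transmitted + stats::rbinom(n_probes, 1, p)
        }
      }
    }
    if (missing_rate > 0) {
      G[stats::runif(length(G)) < missing_rate] <- NA
    }
    attr(G, "allele_freqs") <- p
    G
  })
}

#' Write all cohort artefacts to a directory
#'
#' Emits every simulator output in the plain-text formats the readers
#' accept: probe map (PFB dialect), phenotype TSV, rawcnv call text and
#' the carrier truth table.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Named vector of paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(map = file.path(dir, "probes.pfb"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             calls = file.path(dir, "calls.rawcnv"),
             truth = file.path(dir, "truth.tsv"))
  write_probe_map(cohort$map, paths["map"])
  readr::write_tsv(cohort$samples[, c("sample_id", "phenotype", "sex", "group")],
                   paths["phenotypes"], progress = FALSE)
  write_cnv_calls(cohort$calls, paths["calls"])
  readr::write_tsv(cohort$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
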