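#' Compute per-sample CNV quality-control metrics
#'
#' For each sample the four standard array-CNV quality measures are
#' computed: genotyping call rate, the standard deviation of the autosomal
#' Log R Ratio (LRR SD, intensity noise), the GC wave factor (GCWF,
#' intensity waviness along the genome), and the number of CNV calls.
#'
#' GCWF is computed as the regression slope of window-median LRR on window
#' GC fraction over 1-Mb windows, multiplied by the standard deviation of
#' window GC — i.e. the LRR shift per one-SD change in local GC. A
#' perfectly flat sample gives exactly 0. When a probe map has no `gc`
#' column (or no intensity track is available) the corresponding metric may
#' be supplied precomputed via `lrr_sd`/`gcwf`.
#'
#' @param samples Phenotype tibble (see [read_phenotypes()]).
#' @param genotypes Genotype matrix, samples in rows (see
#'   [read_genotype_matrix()]).
#' @param calls CNV call tibble; `cnv_count` is the number of calls per
#'   sample (0 for samples with none).
#' @param intensities Optional named list of intensity tracks (one per
#'   sample, see [read_intensity_track()]).
#' @param map Optional probe map; used to restrict LRR SD to autosomes and
#'   to provide per-probe GC for GCWF.
#' @param lrr_sd,gcwf Optional named numeric vectors of precomputed metrics
#'   (used for samples without an intensity track).
#' @param window_bp GCWF window size in bp (default 1 Mb).
#' @return A tibble with columns `sample_id`, `call_rate`, `lrr_sd`,
#'   `gcwf`, `cnv_count`.
#' @export
compute_qc_metrics <- function(samples, genotypes, calls,
                               intensities = NULL, map = NULL,
                               lrr_sd = NULL, gcwf = NULL,
                               window_bp = 1e6) {
  ids <- samples$sample_id
  missing_ids <- setdiff(ids, rownames(genotypes))
  if (length(missing_ids) > 0) {
    abort(sprintf("samples absent from genotype matrix: %s",
                  paste(missing_ids, collapse = ", ")))
  }
  call_rate <- 1 - rowMeans(is.na(genotypes[ids, , drop = FALSE]))
  n_calls <- calls |> count(.data$sample_id)
  cnv_count <- stats::setNames(rep(0L, length(ids)), ids)
  cnv_count[n_calls$sample_id[n_calls$sample_id %in% ids]] <-
    n_calls$n[n_calls$sample_id %in% ids]

  get_metric <- function(id, which) {
    pre <- switch(which, lrr_sd = lrr_sd, gcwf = gcwf)
    if (!is.null(intensities) && id %in% names(intensities)) {
      tr <- intensities[[id]]
      if (!is.null(map) && nrow(tr) != nrow(map)) {
        abort(sprintf("intensity track for %s does not match the probe map", id))
      }
      if (which == "lrr_sd") lrr_sd_autosomal(tr, map)
      else gc_wave_factor(tr, map, window_bp)
    } else if (!is.null(pre) && id %in% names(pre)) {
      unname(pre[id])
    } else NA_real_
  }
  tibble(
    sample_id = ids,
    call_rate = unname(call_rate),
    lrr_sd = vapply(ids, get_metric, 0, which = "lrr_sd", USE.NAMES = FALSE),
    gcwf = vapply(ids, get_metric, 0, which = "gcwf", USE.NAMES = FALSE),
    cnv_count = as.integer(unname(cnv_count[ids]))
  )
}

lrr_sd_autosomal <- function(track, map = NULL) {
  lrr <- track$lrr
  if (!is.null(map)) lrr <- lrr[!map$chrom %in% c("chrX", "chrY")]
  stats::sd(lrr)
}

gc_wave_factor <- function(track, map, window_bp = 1e6) {
  if (is.null(map) || all(is.na(map$gc))) return(NA_real_)
  df <- tibble(chrom = map$chrom, pos = map$pos, gc = map$gc, lrr = track$lrr) |>
    filter(!.data$chrom %in% c("chrX", "chrY"), !is.na(.data$gc)) |>
    mutate(win = paste(.data$chrom, .data$pos %/% window_bp)) |>
    group_by(.data$win) |>
    summarise(gc = mean(.data$gc), lrr = stats::median(.data$lrr), .groups = "drop")
  if (nrow(df) < 3 || stats::sd(df$gc) == 0 || stats::sd(df$lrr) == 0) return(0)
  slope <- stats::coef(stats::lm(lrr ~ gc, data = df))[["gc"]]
  slope * stats::sd(df$gc)
}

#' Apply sample-level QC inclusion filters
#'
#' Partitions samples into included and excluded using the standard
#' array-CNV thresholds: genotyping call rate > 98%, LRR SD < 0.3,
#' |GCWF| < 0.02 and CNV count < 100. By default the LRR SD and GCWF
#' conditions are both required (`lrr_gcwf_logic = "and"`);
#' `lrr_gcwf_logic = "or"` accepts a sample passing either one.
#'
#' Each excluded sample is labelled with the first failing criterion, in
#' the order call rate, LRR SD, GCWF, CNV count.
#'
#' @param samples Phenotype tibble.
#' @param qc QC metrics tibble from [compute_qc_metrics()]; every sample
#'   must be present with finite metrics.
#' @param call_rate_min,lrr_sd_max,gcwf_max,cnv_count_max Thresholds
#'   (defaults 0.98, 0.3, 0.02, 100; all strict inequalities).
#' @param lrr_gcwf_logic `"and"` (default) or `"or"`.
#' @return The `samples` tibble with `included` (logical) and
#'   `exclude_reason` (`NA` for included samples) columns, plus the QC
#'   metric columns joined in.
#' @export
apply_sample_qc <- function(samples, qc,
                            call_rate_min = 0.98, lrr_sd_max = 0.3,
                            gcwf_max = 0.02, cnv_count_max = 100,
                            lrr_gcwf_logic = c("and", "or")) {
  lrr_gcwf_logic <- match.arg(lrr_gcwf_logic)
  df <- left_join(samples[setdiff(names(samples),
                                  c("included", "exclude_reason",
                                    names(qc)[-1]))],
                  qc, by = "sample_id")
  bad <- df$sample_id[is.na(df$call_rate) | is.na(df$lrr_sd) |
                        is.na(df$gcwf) | is.na(df$cnv_count)]
  if (length(bad) > 0) {
    abort(sprintf("missing QC metrics for sample(s): %s",
                  paste(bad, collapse = ", ")))
  }
  ok_cr <- df$call_rate > call_rate_min
  ok_sd <- df$lrr_sd < lrr_sd_max
  ok_gc <- abs(df$gcwf) < gcwf_max
  ok_noise <- if (lrr_gcwf_logic == "and") ok_sd & ok_gc else ok_sd | ok_gc
  ok_cnt <- df$cnv_count < cnv_count_max
  df$included <- ok_cr & ok_noise & ok_cnt
  # label each exclusion with the first failing criterion
  first_fail <- function(cr, sdn, gc, noise, cnt) {
    if (!cr) return("call_rate")
    if (lrr_gcwf_logic == "and") {
      if (!sdn) return("lrr_sd")
      if (!gc) return("gcwf")
    } else if (!noise) return("lrr_sd_and_gcwf")
    if (!cnt) return("cnv_count")
    NA_character_
  }
  df$exclude_reason <- mapply(first_fail, ok_cr, ok_sd, ok_gc, ok_noise, ok_cnt)
  df
}

#' Estimate pairwise identity-by-descent (IBD) sharing
#'
#' Method-of-moments estimator of the IBD coefficients Z0/Z1/Z2 and
#' PI_HAT = Z2 + Z1/2 from identity-by-state (IBS) sharing, given per-probe
#' allele frequencies: the expected per-locus IBS 0/1/2 probabilities under
#' IBD 0/1/2 are solved against the observed IBS counts, then Z components
#' are clipped to \[0,1\] and renormalized. This is the classic
#' allele-frequency-based relatedness estimator used for cryptic-relatedness
#' screening (no small-sample bias correction).
#'
#' @param genotypes Genotype matrix (B-allele dosage 0/1/2, `NA` missing),
#'   samples in rows.
#' @param allele_freqs Optional per-probe B-allele frequencies in (0,1);
#'   estimated from the matrix when `NULL`. Monomorphic probes are dropped;
#'   an entirely monomorphic probe set is an error.
#' @param pairs Optional two-column matrix/data frame of sample id pairs;
#'   defaults to all unordered pairs.
#' @return A tibble with columns `sample_1`, `sample_2`, `z0`, `z1`, `z2`,
#'   `pi_hat`.
#' @export
estimate_ibd <- function(genotypes, allele_freqs = NULL, pairs = NULL) {
  G <- genotypes
  if (is.null(allele_freqs)) allele_freqs <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(allele_freqs) & allele_freqs > 0 & allele_freqs < 1
  if (!any(poly)) abort("IBD estimator undefined: all probes monomorphic")
  G <- G[, poly, drop = FALSE]
  p <- allele_freqs[poly]
  q <- 1 - p
  L <- ncol(G)

  # expected per-locus IBS probabilities given IBD state, summed over loci
  e0_ibd0 <- sum(2 * p^2 * q^2)
  e1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_ibd0 <- L - e0_ibd0 - e1_ibd0
  e1_ibd1 <- sum(2 * p * q)            # 2p^2q + 2pq^2
  e2_ibd1 <- L - e1_ibd1               # p^2 + q^2 per locus

  V <- !is.na(G)
  A0 <- (G == 0) & V; A1 <- (G == 1) & V; A2 <- (G == 2) & V
  storage.mode(A0) <- storage.mode(A1) <- storage.mode(A2) <- "double"
  storage.mode(V) <- "double"
  N2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  N0 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  Lp <- tcrossprod(V)
  N1 <- Lp - N0 - N2

  ids <- rownames(G)
  if (is.null(pairs)) {
    idx <- which(upper.tri(Lp), arr.ind = TRUE)
  } else {
    pairs <- as.matrix(pairs)
    idx <- cbind(match(pairs[, 1], ids), match(pairs[, 2], ids))
    if (anyNA(idx)) abort("pair refers to unknown sample id")
  }
  scale <- Lp[idx] / L   # pro-rate locus-sum expectations to non-missing loci
  z0 <- N0[idx] / (e0_ibd0 * scale)
  z1 <- (N1[idx] - z0 * e1_ibd0 * scale) / (e1_ibd1 * scale)
  z2 <- (N2[idx] - z0 * e2_ibd0 * scale - z1 * e2_ibd1 * scale) / Lp[idx]
  z0 <- pmin(pmax(z0, 0), 1); z1 <- pmin(pmax(z1, 0), 1); z2 <- pmin(pmax(z2, 0), 1)
  tot <- z0 + z1 + z2
  z0 <- z0 / tot; z1 <- z1 / tot; z2 <- z2 / tot
  tibble(
    sample_1 = ids[idx[, 1]], sample_2 = ids[idx[, 2]],
    z0 = z0, z1 = z1, z2 = z2,
    pi_hat = pmin(pmax(z2 + z1 / 2, 0), 1)
  )
}

#' Flag cryptically related samples for removal
#'
#' Given pairwise IBD estimates, returns the minimal-style greedy set of
#' samples to drop so that no retained pair has PI_HAT above the cutoff:
#' one member per flagged pair is removed, preferring the sample involved
#' in most flagged pairs, then the one with the lower call rate, then the
#' lexicographically later id.
#'
#' @param estimates IBD tibble from [estimate_ibd()].
#' @param cutoff PI_HAT cutoff (default 0.30, strict).
#' @param call_rate Optional named vector of call rates used to pick which
#'   member of a pair is dropped.
#' @return Character vector of sample ids to drop (possibly empty).
#' @export
flag_related <- function(estimates, cutoff = 0.30, call_rate = NULL) {
  flagged <- estimates[estimates$pi_hat > cutoff, , drop = FALSE]
  drop <- character()
  while (nrow(flagged) > 0) {
    members <- c(flagged$sample_1, flagged$sample_2)
    deg <- table(members)
    top <- names(deg)[deg == max(deg)]
    if (length(top) > 1 && !is.null(call_rate) &&
        all(top %in% names(call_rate))) {
      # lower call rate dropped first
      top <- top[call_rate[top] == min(call_rate[top])]
    }
    victim <- sort(top, decreasing = TRUE)[1]  # ties: lexicographically later
    drop <- c(drop, victim)
    flagged <- flagged[flagged$sample_1 != victim & flagged$sample_2 != victim, ,
                       drop = FALSE]
  }
  drop
}

#' Prune probes by pairwise linkage-disequilibrium r-squared
#'
#' Sliding-window LD pruning on genotype correlation: within each window of
#' `window` probes (advanced by `step`), any retained pair with squared
#' Pearson correlation above `r2_max` loses its later probe. Scan order is
#' deterministic (earlier probe kept). Zero-variance probes are removed
#' before correlation.
#'
#' @param genotypes Genotype matrix, samples in rows.
#' @param window Window size in probes (>= 2; default 50).
#' @param step Window step in probes (default 5).
#' @param r2_max Maximum allowed pairwise r-squared (default 0.2).
#' @return Character vector of retained probe ids (column names).
#' @export
ld_prune <- function(genotypes, window = 50, step = 5, r2_max = 0.2) {
  if (window < 2) abort("window must be >= 2 probes")
  v <- apply(genotypes, 2, stats::var, na.rm = TRUE)
  keepable <- which(!is.na(v) & v > 0)
  G <- genotypes[, keepable, drop = FALSE]
  m <- ncol(G)
  keep <- rep(TRUE, m)
  starts <- seq(1, max(1, m), by = step)
  for (s in starts) {
    e <- min(s + window - 1, m)
    if (e <= s) next
    idx <- s:e
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(stats::cor(G[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    for (i in seq_along(idx)[-length(idx)]) {
      if (!keep[idx[i]]) next
      for (j in seq(i + 1, length(idx))) {
        if (keep[idx[j]] && !is.na(r2[i, j]) && r2[i, j] > r2_max) {
          keep[idx[j]] <- FALSE
        }
      }
    }
    if (e == m) break
  }
  colnames(G)[keep]
}

#' Principal component analysis of standardized genotypes
#'
#' Computes sample coordinates on the top principal components of the
#' genotype matrix standardized per probe by subtracting the mean and
#' dividing by `sqrt(p(1-p))` (p = allele frequency), the convention of
#' genotype-based population-structure analysis. Monomorphic probes are
#' dropped; missing genotypes are mean-imputed (zero after centring).
#'
#' @param genotypes Genotype matrix, samples in rows.
#' @param probes Optional probe-id subset (e.g. from [ld_prune()]).
#' @param k Number of components (default 2); must satisfy
#'   `k < min(n_samples, n_probes)`.
#' @return A `cnv_pca` object: list with `coordinates` (tibble `sample_id`,
#'   `PC1`..`PCk`), `eigenvalues` (nonincreasing), `n_probes`.
#' @export
pca_genotypes <- function(genotypes, probes = NULL, k = 2) {
  G <- genotypes
  if (!is.null(probes)) G <- G[, probes, drop = FALSE]
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  if (k >= min(nrow(G), ncol(G))) {
    abort("k must be smaller than both the number of samples and of probes")
  }
  Z <- sweep(G, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  sv <- svd(Z, nu = k, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(
    list(
      coordinates = dplyr::bind_cols(tibble(sample_id = rownames(G)),
                                     as_tibble(coords)),
      eigenvalues = sv$d^2 / max(1, nrow(G) - 1),
      n_probes = ncol(G)
    ),
    class = "cnv_pca"
  )
}

#' @export
print.cnv_pca <- function(x, ...) {
  cat(sprintf("Genotype PCA: %d samples x %d probes, top eigenvalues: %s\n",
              nrow(x$coordinates), x$n_probes,
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}
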