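#' Parameters of the LRR/BAF copy-number hidden Markov model
#'
#' A simplified five-state (copy numbers 0–4) HMM over array probes, in the
#' spirit of trained SNP-array CNV callers: Gaussian Log R Ratio (LRR)
#' emissions per state, B Allele Frequency (BAF) emissions as a mixture of
#' genotype bands weighted by the population B-allele frequency (PFB), and
#' distance-dependent transitions whose off-diagonal mass grows with the
#' genomic gap between adjacent probes.
#'
#' @param lrr_mean Per-state LRR means, strictly increasing in copy number
#'   (defaults -3.5, -0.66, 0, 0.40, 0.68).
#' @param lrr_sd Per-state LRR standard deviations (cn=0 is wide: the
#'   signal there is noise-dominated).
#' @param baf_sd Standard deviation of each BAF genotype band (default
#'   0.03).
#' @param baf_outlier Weight of the uniform BAF outlier component (default
#'   0.01).
#' @param transit_base Base probability of leaving the current state at
#'   infinite gap, from the diploid state; `transit_exit` is the base
#'   probability of returning to diploid from a CNV state.
#' @param d0 Distance-decay constant in bp (default 100 kb): the
#'   off-diagonal transition mass at gap g is scaled by `1 - exp(-g/d0)`.
#' @param min_probes Minimum run length (probes) for an emitted call
#'   (default 3).
#' @return An `hmm_params` list.
#' @export
hmm_params <- function(lrr_mean = c(-3.5, -0.66, 0, 0.40, 0.68),
                       lrr_sd = c(1.0, 0.25, 0.18, 0.20, 0.22),
                       baf_sd = 0.03, baf_outlier = 0.01,
                       transit_base = 1e-5, transit_exit = 0.05,
                       d0 = 1e5, min_probes = 3) {
  stopifnot(length(lrr_mean) == 5, length(lrr_sd) == 5,
            all(diff(lrr_mean) > 0), all(lrr_sd > 0), min_probes >= 1)
  structure(list(states = 0:4, lrr_mean = lrr_mean, lrr_sd = lrr_sd,
                 baf_sd = baf_sd, baf_outlier = baf_outlier,
                 transit_base = transit_base, transit_exit = transit_exit,
                 d0 = d0, min_probes = as.integer(min_probes)),
            class = "hmm_params")
}

# BAF band positions and PFB-weighted genotype weights for copy number cn.
# cn=0 has no genotype: BAF is uniform noise.
baf_bands <- function(cn, pfb) {
  if (cn == 0) return(NULL)
  k <- 0:cn
  list(mean = k / cn, weight = stats::dbinom(k, cn, pfb))
}

#' Per-state emission log-likelihoods for LRR/BAF probes
#'
#' Evaluates, for each probe, the log-density of its (LRR, BAF) observation
#' under each of the five copy-number states. LRR and BAF contributions are
#' summed in log space; the BAF density is a genotype-band normal mixture
#' weighted by the probe's PFB, plus a uniform outlier component (and pure
#' uniform for copy number 0, which carries no genotype).
#'
#' @param lrr,baf,pfb Numeric vectors of equal length (BAF and PFB in
#'   \[0,1\]; BAF is clipped).
#' @param params An [hmm_params()] object.
#' @return A numeric matrix, probes in rows, the five states (cn 0..4) in
#'   columns; all entries finite.
#' @export
emission_loglik <- function(lrr, baf, pfb, params = hmm_params()) {
  n <- length(lrr)
  baf <- pmin(pmax(baf, 0), 1)
  pfb <- pmin(pmax(pfb, 0), 1)
  out <- matrix(NA_real_, n, 5, dimnames = list(NULL, paste0("cn", 0:4)))
  for (s in 0:4) {
    ll_lrr <- stats::dnorm(lrr, params$lrr_mean[s + 1], params$lrr_sd[s + 1],
                           log = TRUE)
    if (s == 0) {
      dens <- rep(1, n)  # uniform on [0,1]
    } else {
      dens <- rep(0, n)
      for (k in 0:s) {
        w <- stats::dbinom(k, s, pfb)
        dens <- dens + w * stats::dnorm(baf, k / s, params$baf_sd)
      }
      dens <- params$baf_outlier + (1 - params$baf_outlier) * dens
    }
    out[, s + 1] <- ll_lrr + log(dens)
  }
  out[!is.finite(out)] <- -745  # floor at ~log(.Machine$double.xmin)
  out
}

# 5x5 log transition matrix for a given inter-probe gap (bp).
transition_logmat <- function(gap, params) {
  f <- 1 - exp(-max(gap, 1) / params$d0)
  Tb <- matrix(0, 5, 5)
  for (i in 1:5) {
    cn <- i - 1
    off <- if (cn == 2) rep(params$transit_base, 5) else {
      o <- rep(params$transit_base, 5)
      o[3] <- params$transit_exit
      o
    }
    off[i] <- 0
    Tb[i, ] <- off
    Tb[i, i] <- 1 - sum(off)
  }
  Tm <- diag(5) + f * (Tb - diag(5))
  log(Tm)
}

#' Call CNVs from an intensity track by Viterbi decoding
#'
#' Decodes the maximum a-posteriori copy-number state path per chromosome
#' and emits maximal runs of non-diploid states of at least `min_probes`
#' probes as CNV calls spanning the first to last probe of the run.
#'
#' @param track Intensity tibble (`probe_id`, `lrr`, `baf`) aligned to
#'   `map` (see [read_intensity_track()]).
#' @param map Probe map; PFB defaults to 0.5 where missing.
#' @param params An [hmm_params()] object.
#' @param sample_id Sample identifier stamped on the calls.
#' @param autosome_only Drop chrX/chrY before calling (default `TRUE`).
#' @return A CNV call tibble (same shape as [read_cnv_calls()]).
#' @export
viterbi_call <- function(track, map, params = hmm_params(),
                         sample_id = "sample", autosome_only = TRUE) {
  if (nrow(track) != nrow(map)) abort("track and probe map lengths differ")
  df <- tibble(chrom = map$chrom, pos = map$pos,
               pfb = ifelse(is.na(map$pfb), 0.5, map$pfb),
               lrr = track$lrr, baf = track$baf)
  if (autosome_only) df <- filter(df, !.data$chrom %in% c("chrX", "chrY"))
  calls <- df |>
    group_by(.data$chrom) |>
    group_modify(function(g, key) {
      if (nrow(g) < params$min_probes) {
        inform(sprintf("chromosome %s has fewer than %d probes; skipped",
                       key$chrom, params$min_probes))
        return(tibble(start = integer(), end = integer(), cn = integer(),
                      n_probes = integer()))
      }
      path <- viterbi_path(g, params)
      runs_to_calls(path, g$pos, params$min_probes)
    }) |>
    ungroup()
  if (nrow(calls) == 0) return(empty_calls())
  calls <- mutate(calls, sample_id = sample_id, conf = NA_real_,
                  cnv_type = cn_to_type(.data$cn))
  validate_calls(calls[, c("sample_id", "chrom", "start", "end", "cn",
                           "n_probes", "conf")],
                 source = sample_id)
}

# Viterbi decode one chromosome; returns the integer copy-number path.
viterbi_path <- function(g, params) {
  em <- emission_loglik(g$lrr, g$baf, g$pfb, params)
  n <- nrow(em)
  # initial distribution: overwhelmingly diploid
  init <- log(c(2.5e-4, 2.5e-4, 0.999, 2.5e-4, 2.5e-4))
  delta <- init + em[1, ]
  back <- matrix(0L, n, 5)
  if (n > 1) {
    gaps <- diff(g$pos)
    ug <- unique(gaps)
    Tcache <- lapply(ug, transition_logmat, params = params)
    gi <- match(gaps, ug)
    for (t in 2:n) {
      Tl <- Tcache[[gi[t - 1]]]
      cand <- delta + Tl            # column j: delta_i + T[i, j]
      back[t, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(back[t, ], 1:5)] + em[t, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (t in seq(n - 1, 1)) path[t] <- back[t + 1, path[t + 1]]
  path - 1L
}

# log-probability of a given state path (for optimality checks)
path_loglik <- function(g, path, params) {
  em <- emission_loglik(g$lrr, g$baf, g$pfb, params)
  init <- log(c(2.5e-4, 2.5e-4, 0.999, 2.5e-4, 2.5e-4))
  ll <- init[path[1] + 1] + em[1, path[1] + 1]
  if (length(path) > 1) {
    gaps <- diff(g$pos)
    for (t in 2:length(path)) {
      Tl <- transition_logmat(gaps[t - 1], params)
      ll <- ll + Tl[path[t - 1] + 1, path[t] + 1] + em[t, path[t] + 1]
    }
  }
  unname(ll)
}

runs_to_calls <- function(path, pos, min_probes) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 2 & r$lengths >= min_probes
  tibble(start = pos[starts[keep]], end = pos[ends[keep]],
         cn = as.integer(r$values[keep]),
         n_probes = as.integer(r$lengths[keep]))
}
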