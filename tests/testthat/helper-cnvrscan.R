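# shared fixture builders and independent oracles

make_map <- function(n = 100, chrom = "chr1", spacing = 4000, pfb = 0.5) {
  tibble::tibble(
    probe_id = sprintf("%s_t%04d", chrom, seq_len(n)),
    chrom = chrom,
    pos = as.integer(seq(spacing, by = spacing, length.out = n)),
    pfb = pfb, gc = 0.45
  )
}

make_samples <- function(n_cases = 63, n_controls = 145) {
  tibble::tibble(
    sample_id = c(sprintf("case_%03d", seq_len(n_cases)),
                  sprintf("ctrl_%03d", seq_len(n_controls))),
    phenotype = rep(c("case", "control"), c(n_cases, n_controls)),
    sex = "unknown", group = "pop", included = TRUE
  )
}

# one call per listed carrier spanning [start, end]
make_calls <- function(carrier_ids, chrom, start, end, cn = 1L, n_probes = 10L) {
  tibble::tibble(
    sample_id = carrier_ids, chrom = chrom,
    start = as.integer(start), end = as.integer(end),
    cn = cn, n_probes = n_probes, conf = NA_real_,
    cnv_type = ifelse(cn < 2, "deletion", "duplication")
  )
}

# independent Fisher oracle: enumerate all tables with the observed margins
# from log-factorials, never calling phyper/dhyper/fisher.test
fisher_oracle <- function(a, n1, c, n2, sided = "one_greater") {
  m <- a + c
  lo <- max(0, m - n2); hi <- min(n1, m)
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  logp <- vapply(lo:hi, function(k) {
    lchoose2(n1, k) + lchoose2(n2, m - k) - lchoose2(n1 + n2, m)
  }, 0)
  prob <- exp(logp)
  if (sided == "one_greater") {
    sum(prob[(lo:hi) >= a])
  } else {
    sum(prob[prob <= prob[a - lo + 1] * (1 + 1e-7)])
  }
}

# brute-force interval overlap (closed 1-based intervals)
overlaps_oracle <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1
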