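test_that("Fisher enrichment matches printed CNVR p-values and edge cases", {
  checks <- list(
    list(a = 8, c = 1, p = 0.000347, digits = 3),
    list(a = 10, c = 3, p = 0.000471, digits = 3),
    list(a = 6, c = 0, p = 0.00065, digits = 2),
    list(a = 3, c = 0, p = 0.0269, digits = 3),
    list(a = 4, c = 0, p = 0.00786, digits = 3),
    list(a = 5, c = 1, p = 0.0104, digits = 3),
    list(a = 4, c = 1, p = 0.0302, digits = 3)
  )
  for (ch in checks) {
    expect_equal(signif(fisher_case_enrichment(ch$a, 63, ch$c, 145), ch$digits),
                 ch$p)
  }
  expect_equal(fisher_case_enrichment(0, 63, 0, 145), 1)
  expect_error(fisher_case_enrichment(1, 0, 0, 10), "non-empty")
  expect_error(fisher_case_enrichment(70, 63, 0, 145), "outside")
})

test_that("Fisher p equals brute-force hypergeometric enumeration on the grid", {
  for (a in 0:15) for (c in 0:15) {
    expect_equal(fisher_case_enrichment(a, 63, c, 145),
                 fisher_oracle(a, 63, c, 145), tolerance = 1e-12)
    expect_equal(fisher_case_enrichment(a, 63, c, 145, sided = "two"),
                 fisher_oracle(a, 63, c, 145, sided = "two"),
                 tolerance = 1e-12)
  }
  # one-sided p nonincreasing in a at fixed c
  for (c in c(0, 3, 10)) {
    p <- fisher_case_enrichment(0:15, 63, c, 145)
    expect_true(all(diff(p) <= 1e-15))
  }
  # cross-check against the reference exact test on a sample of tables
  for (tab in list(c(8, 1), c(6, 0), c(12, 9))) {
    m <- matrix(c(tab[1], 63 - tab[1], tab[2], 145 - tab[2]), 2)
    expect_equal(fisher_case_enrichment(tab[1], 63, tab[2], 145),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_case_enrichment(tab[1], 63, tab[2], 145, sided = "two"),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("carrier matrices mark inclusive spans without double counting", {
  map <- tibble::tibble(probe_id = sprintf("p%d", 1:4), chrom = "chr1",
                        pos = c(100L, 200L, 300L, 400L),
                        pfb = 0.5, gc = NA_real_)
  samples <- make_samples(1, 1)
  calls <- make_calls("case_001", "chr1", 100, 300)
  cm <- build_carrier_matrix(calls, map, samples, "deletion")
  expect_equal(unname(cm$carrier["case_001", ]), c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(cm$carrier["ctrl_001", ]))

  # two overlapping deletions stay boolean
  two <- dplyr::bind_rows(calls, make_calls("case_001", "chr1", 200, 400))
  cm2 <- build_carrier_matrix(two, map, samples, "deletion")
  expect_equal(unname(cm2$carrier["case_001", ]), c(TRUE, TRUE, TRUE, TRUE))

  expect_warning(
    build_carrier_matrix(make_calls("case_001", "chr7", 100, 300), map,
                         samples, "deletion"),
    "chr7")
})

test_that("carrier matrix agrees with brute-force membership on random calls", {
  set.seed(23)
  map <- make_map(200)
  samples <- make_samples(10, 10)
  n <- 80
  start <- map$pos[sample.int(190, n, replace = TRUE)]
  calls <- make_calls(sample(samples$sample_id, n, replace = TRUE),
                      "chr1", start, start + sample.int(5e4, n), cn = 1L)
  cm <- build_carrier_matrix(calls, map, samples, "deletion")
  brute <- matrix(FALSE, nrow(samples), nrow(map),
                  dimnames = list(samples$sample_id, map$probe_id))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(map))) {
      if (calls$start[i] <= map$pos[j] && map$pos[j] <= calls$end[i]) {
        brute[calls$sample_id[i], j] <- TRUE
      }
    }
  }
  expect_equal(cm$carrier, brute)
})

test_that("the case-carrier prefilter implements the >=3-carrier rule", {
  tests <- tibble::tibble(
    probe_id = sprintf("p%d", 1:4), chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L), cnv_type = "deletion",
    a = c(2L, 3L, 5L, 0L), n1 = 63L, c = c(0L, 1L, 2L, 0L), n2 = 145L,
    p = fisher_case_enrichment(c(2, 3, 5, 0), 63, c(0, 1, 2, 0), 145)
  )
  kept <- prefilter_probes(tests, 3)
  expect_equal(kept$probe_id, c("p2", "p3"))
  expect_equal(signif(attr(kept, "min_case_frequency"), 3), 0.0476)
  expect_equal(prefilter_probes(tests, 0)$probe_id, tests$probe_id)
})

test_that("minimal nominally significant case count is found by exact search", {
  m <- min_nominal_case_count(63, 145, 0.05)
  expect_equal(as.integer(m), 3L)
  expect_true(attr(m, "attainable"))
  # consistency: 2 vs 0 not significant, 3 vs 0 significant
  expect_gt(fisher_case_enrichment(2, 63, 0, 145), 0.05)
  expect_lt(fisher_case_enrichment(3, 63, 0, 145), 0.05)

  u <- min_nominal_case_count(1, 1, 0.05)
  expect_equal(as.integer(u), 2L)
  expect_false(attr(u, "attainable"))

  # monotone nonincreasing in the control group size
  counts <- vapply(c(20, 50, 100, 200, 500),
                   function(n2) as.integer(min_nominal_case_count(63, n2, 0.05)),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("region collapsing follows the gap and log-p band rules", {
  mk_tests <- function(pos, p, a = 5L, c = 0L) {
    tibble::tibble(probe_id = sprintf("p%d", seq_along(pos)), chrom = "chr1",
                   pos = as.integer(pos), cnv_type = "deletion",
                   a = a, n1 = 63L, c = c, n2 = 145L, p = p)
  }
  one <- collapse_to_regions(mk_tests(100, 0.01))
  expect_equal(nrow(one), 1)
  expect_equal(one$p, 0.01)
  expect_equal(one$n_probes, 1L)

  two_far <- collapse_to_regions(mk_tests(c(1e6, 3e6), c(0.01, 0.01)))
  expect_equal(nrow(two_far), 2)

  # hand-enumerated sweep: 100 kb spacing, p = 1e-3, 2e-3, 3e-3, 1e-1
  # |log10(3e-3) - log10(1e-1)| = 1.52 > 1 splits before the last probe
  swept <- collapse_to_regions(mk_tests(seq(1e5, 4e5, 1e5),
                                        c(1e-3, 2e-3, 3e-3, 1e-1)))
  expect_equal(nrow(swept), 2)
  expect_equal(swept$n_probes, c(3L, 1L))
  expect_equal(swept$p, c(1e-3, 1e-1))
  expect_equal(swept$anchor_probe[1], "p1")

  # gap of exactly 1 Mb splits; anything less chains
  at_gap <- collapse_to_regions(mk_tests(c(1e6, 2e6), c(0.01, 0.01)))
  expect_equal(nrow(at_gap), 2)
  under_gap <- collapse_to_regions(mk_tests(c(1e6, 2e6 - 1), c(0.01, 0.01)))
  expect_equal(nrow(under_gap), 1)

  # region-min band mode splits a probe that drifts away from the region
  # minimum even though each neighbour step stays inside the band
  drift <- mk_tests(seq(1e5, 3e5, 1e5), 10^c(-5, -4.4, -3.8))
  expect_equal(nrow(collapse_to_regions(drift, band_mode = "chained")), 1)
  expect_equal(nrow(collapse_to_regions(drift, band_mode = "region_min")), 2)

  # zero-carrier probes are dropped, never bridge
  bridged <- mk_tests(c(1e5, 2e5, 3e5), c(0.01, 1, 0.01), a = c(5L, 0L, 5L),
                      c = c(0L, 0L, 0L))
  expect_equal(nrow(collapse_to_regions(bridged)), 1)
  expect_equal(collapse_to_regions(bridged)$n_probes, 2L)

  expect_equal(nrow(collapse_to_regions(mk_tests(integer(), numeric()))), 0)
})

test_that("collapsing partitions the retained probe set", {
  set.seed(99)
  pos <- sort(sample.int(3e7, 300))
  p <- 10^stats::runif(300, -6, 0)
  tests <- tibble::tibble(probe_id = sprintf("p%03d", 1:300), chrom = "chr1",
                          pos = as.integer(pos), cnv_type = "duplication",
                          a = 4L, n1 = 63L, c = 1L, n2 = 145L, p = p)
  regions <- collapse_to_regions(tests)
  members <- unlist(regions$member_probes)
  expect_setequal(members, tests$probe_id)
  expect_equal(anyDuplicated(members), 0)
  expect_equal(sum(regions$n_probes), 300L)
  # region p is the member minimum
  for (i in seq_len(nrow(regions))) {
    expect_equal(regions$p[i],
                 min(tests$p[tests$probe_id %in% regions$member_probes[[i]]]))
  }
})

test_that("experiment-wide threshold is Bonferroni over both type scans", {
  mt <- experimentwide_threshold(20, 69, 0.05)
  expect_equal(mt$n_tests, 89L)
  expect_equal(signif(mt$threshold, 3), 5.62e-4)
  expect_equal(mt$threshold * mt$n_tests, 0.05)
  expect_equal(experimentwide_threshold(1, 0, 0.05)$threshold, 0.05)
  expect_error(experimentwide_threshold(0, 0), "no CNV regions")
})

test_that("the end-to-end scan reproduces the spiked deletion association", {
  causal <- tibble::tibble(chrom = "chr1", start = 5e6, end = 5.04e6,
                           cnv_type = "deletion",
                           case_freq = NA_real_, control_freq = NA_real_,
                           case_carriers = 8L, control_carriers = 1L)
  spec <- cohort_spec(causal_regions = causal, boundary_jitter_sd = 0,
                      call_fp_rate = 0, call_fn_rate = 0,
                      background_rate_case = 0, background_rate_control = 0,
                      seed = 404)
  coh <- simulate_cohort(spec)
  fit <- cnv_associate(coh$calls, coh$map, coh$samples)
  flagged <- fit$regions[fit$regions$significant, ]
  expect_equal(nrow(flagged), 1)
  expect_equal(flagged$cnv_type, "deletion")
  expect_equal(signif(flagged$p, 3), 3.47e-4)
  expect_equal(flagged$case_carriers, 8L)
  expect_equal(flagged$control_carriers, 1L)
  expect_true(flagged$start >= 5e6 && flagged$end <= 5.04e6)

  # no calls at all: the threshold stage errors out
  expect_error(cnv_associate(coh$calls[0, ], coh$map, coh$samples),
               "no CNV regions")

  # permuting the sample table leaves the fit invariant
  perm <- coh$samples[sample(nrow(coh$samples)), ]
  fit2 <- cnv_associate(coh$calls, coh$map, perm)
  expect_equal(fit2$regions$p, fit$regions$p)
  expect_equal(fit2$n_tests, fit$n_tests)
})

test_that("tidiers and autoplot expose the fit", {
  causal <- tibble::tibble(chrom = "chr1", start = 5e6, end = 5.04e6,
                           cnv_type = "deletion",
                           case_freq = 0.1, control_freq = 0.01)
  spec <- cohort_spec(causal_regions = causal, background_rate_case = 3,
                      background_rate_control = 3, seed = 7)
  coh <- simulate_cohort(spec)
  fit <- cnv_associate(coh$calls, coh$map, coh$samples)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("region", "p", "significant") %in% names(td)))
  expect_false(is.unsorted(td$p))
  gl <- glance(fit)
  expect_equal(gl$n_regions, nrow(fit$regions))
  expect_equal(gl$threshold, 0.05 / gl$n_tests)
  expect_s3_class(autoplot(fit), "ggplot")
})
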