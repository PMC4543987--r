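test_that("QC metrics match their definitions", {
  samples <- make_samples(2, 1)[, ]
  G <- matrix(1, nrow = 3, ncol = 1000,
              dimnames = list(samples$sample_id, sprintf("p%04d", 1:1000)))
  G[2, 1:100] <- NA
  map <- make_map(1000)
  tracks <- list(
    case_001 = tibble::tibble(probe_id = map$probe_id, lrr = 0, baf = 0.5),
    case_002 = tibble::tibble(probe_id = map$probe_id,
                              lrr = stats::rnorm(1000), baf = 0.5)
  )
  calls <- make_calls(c("case_001", "case_001", "ctrl_001"),
                      "chr1", 4000, 40000)
  qc <- compute_qc_metrics(samples, G, calls, intensities = tracks, map = map)
  expect_equal(qc$call_rate, c(1, 0.9, 1))
  # constant LRR: no noise and no waviness
  expect_equal(qc$lrr_sd[1], 0)
  expect_equal(qc$gcwf[1], 0)
  expect_equal(qc$cnv_count, c(2L, 0L, 1L))
  expect_error(compute_qc_metrics(make_samples(1, 0) |>
                                    dplyr::mutate(sample_id = "ghost"),
                                  G, calls), "ghost")
})

test_that("LRR SD estimate is within the sampling-error band", {
  # N(0, 0.2) over 10,000 probes: chi-square bounds put sd in [0.19, 0.21]
  set.seed(1)
  map <- make_map(10000)
  tr <- tibble::tibble(probe_id = map$probe_id,
                       lrr = stats::rnorm(10000, 0, 0.2), baf = 0.5)
  samples <- make_samples(1, 0)
  G <- matrix(0, 1, 10, dimnames = list(samples$sample_id, NULL))
  qc <- compute_qc_metrics(samples, G, make_calls(character(), "chr1", 1, 1),
                           intensities = list(case_001 = tr), map = map)
  expect_gt(qc$lrr_sd, 0.19)
  expect_lt(qc$lrr_sd, 0.21)
})

test_that("sample inclusion follows the QC thresholds with labelled reasons", {
  samples <- make_samples(4, 0)
  qc <- tibble::tibble(
    sample_id = samples$sample_id,
    call_rate = c(0.99, 0.97, 0.99, 0.99),
    lrr_sd = c(0.1, 0.1, 0.1, 0.35),
    gcwf = c(0.0, 0.0, 0.0, 0.0),
    cnv_count = c(50L, 50L, 150L, 50L)
  )
  res <- apply_sample_qc(samples, qc)
  expect_equal(res$included, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$exclude_reason,
               c(NA, "call_rate", "cnv_count", "lrr_sd"))

  # literal OR variant: high LRR SD passes while |GCWF| is small
  res_or <- apply_sample_qc(samples, qc, lrr_gcwf_logic = "or")
  expect_true(res_or$included[4])

  # idempotent and order-independent
  res2 <- apply_sample_qc(res, qc)
  expect_equal(res2$included, res$included)
  perm <- sample(nrow(samples))
  res3 <- apply_sample_qc(samples[perm, ], qc)
  expect_equal(res3$included[order(perm)], res$included)

  expect_error(apply_sample_qc(samples, qc[-1, ]), "case_001")
})

test_that("IBD estimates recover duplicates, parent-offspring and unrelateds", {
  samples <- make_samples(10, 0)
  rel <- tibble::tibble(sample_1 = c("case_001", "case_003"),
                        sample_2 = c("case_002", "case_004"),
                        relationship = c("duplicate", "parent_offspring"))
  G <- simulate_genotypes(samples, n_probes = 10000, related_pairs = rel,
                          seed = 99)
  ibd <- estimate_ibd(G)
  key <- paste(ibd$sample_1, ibd$sample_2)
  expect_gte(ibd$pi_hat[key == "case_001 case_002"], 0.95)
  po <- ibd$pi_hat[key == "case_003 case_004"]
  expect_gte(po, 0.4); expect_lte(po, 0.6)
  unrel <- ibd$pi_hat[!grepl("case_00[1-4]", ibd$sample_1) &
                        !grepl("case_00[1-4]", ibd$sample_2)]
  expect_equal(length(unrel), choose(6, 2))
  expect_true(all(unrel >= 0 & unrel <= 0.1))
  # near-unbiasedness at 10,000 informative probes, averaged over pairs
  expect_lt(abs(mean(unrel)), 0.02)
  # internal consistency of the decomposition
  expect_equal(ibd$pi_hat, ibd$z2 + ibd$z1 / 2, tolerance = 1e-8)

  mono <- matrix(2, 4, 50, dimnames = list(samples$sample_id[1:4], NULL))
  expect_error(estimate_ibd(mono), "monomorphic")
})

test_that("relatedness pruning drops one member per pair, minimally on chains", {
  none <- tibble::tibble(sample_1 = "A", sample_2 = "B",
                         z0 = 1, z1 = 0, z2 = 0, pi_hat = 0.1)
  expect_equal(flag_related(none), character())

  pair <- tibble::tibble(sample_1 = "A", sample_2 = "B",
                         z0 = 0, z1 = 1, z2 = 0, pi_hat = 0.5)
  dropped <- flag_related(pair)
  expect_equal(length(dropped), 1)
  expect_true(dropped %in% c("A", "B"))
  # lower call rate loses
  expect_equal(flag_related(pair, call_rate = c(A = 0.99, B = 0.95)), "B")

  chain <- tibble::tibble(sample_1 = c("A", "B"), sample_2 = c("B", "C"),
                          z0 = 0, z1 = 1, z2 = 0, pi_hat = c(0.5, 0.5))
  got <- flag_related(chain)
  expect_equal(got, "B")
  # brute force: the unique minimal vertex cover of A-B, B-C is {B}
  covers <- Filter(function(s) any(c("A", "B") %in% s) && any(c("B", "C") %in% s),
                   lapply(1:7, function(i) c("A", "B", "C")[as.logical(bitwAnd(i, c(1, 2, 4)))]))
  minimal <- covers[lengths(covers) == min(lengths(covers))]
  expect_equal(sort(got), sort(minimal[[1]]))
})

test_that("LD pruning removes correlated probes deterministically", {
  set.seed(3)
  base <- matrix(stats::rbinom(50 * 30, 2, 0.4), nrow = 50)
  colnames(base) <- sprintf("s%03d", 1:30)
  rownames(base) <- sprintf("id%02d", 1:50)
  # duplicate probe pair: second of the two removed
  G <- cbind(base, dup1 = base[, 1])
  kept <- ld_prune(G, window = 40, step = 5, r2_max = 0.2)
  expect_false("dup1" %in% kept)
  expect_true("s001" %in% kept)

  # independent probes all retained
  kept2 <- ld_prune(base, window = 10, step = 5, r2_max = 0.8)
  expect_equal(sort(kept2), sort(colnames(base)))

  # triples of identical probes: exactly one survivor each
  trip <- base[, rep(1:3, each = 3)]
  colnames(trip) <- sprintf("t%d_%d", rep(1:3, each = 3), 1:3)
  kept3 <- ld_prune(trip, window = 9, step = 3, r2_max = 0.2)
  expect_equal(kept3, c("t1_1", "t2_1", "t3_1"))

  # invariant to appending zero-variance probes
  Gz <- cbind(base, flat = 1)
  expect_equal(ld_prune(Gz, 10, 5, 0.2), ld_prune(base, 10, 5, 0.2))
})

test_that("genotype PCA separates divergent subpopulations on PC1", {
  samples <- make_samples(20, 20)
  samples$group <- rep(c("popA", "popB"), each = 20)
  G <- simulate_genotypes(samples, n_probes = 2000, subpop = "group",
                          fst = 0.15, seed = 21)
  pca <- pca_genotypes(G, k = 2)
  co <- tidy(pca)
  co$grp <- samples$group[match(co$sample_id, samples$sample_id)]
  a <- co$PC1[co$grp == "popA"]; b <- co$PC1[co$grp == "popB"]
  expect_true(max(a) < min(b) || max(b) < min(a))
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))

  # identical rows: no variance on any component
  flat <- matrix(rep(c(0, 1, 2, 1), each = 10), nrow = 10)
  flat <- flat[, c(1:4, 1:4)]
  rownames(flat) <- sprintf("S%02d", 1:10)
  p2 <- pca_genotypes(flat, k = 2)
  expect_lt(max(p2$eigenvalues), 1e-20)

  expect_error(pca_genotypes(G, k = 40), "k must be smaller")
})
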