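# Consensus caller: genotyping thresholds, callable sites, the
# unique-heterozygote rule against exhaustive oracles, and curation filters.

test_that("genotype_from_evidence follows the thresholding contract", {
  th <- genotype_thresholds()
  # depth 30, alt 15 -> het
  expect_identical(as.character(
    genotype_from_evidence(c(15, 0, 15, 0), "A", th)), "het")
  # depth 3 below min_depth 10 -> no_call
  expect_identical(as.character(
    genotype_from_evidence(c(3, 0, 0, 0), "A", th)), "no_call")
  # clean hom-ref
  expect_identical(as.character(
    genotype_from_evidence(c(30, 0, 0, 0), "A", th)), "hom_ref")
  # hom-alt
  expect_identical(as.character(
    genotype_from_evidence(c(1, 0, 29, 0), "A", th)), "hom_alt")
  expect_error(genotype_from_evidence(c(10, 0, 0, 0), "N", th),
               class = "mutaccum_base_error")
})

test_that("genotype sweep matches the brute-force threshold oracle", {
  th <- genotype_thresholds()
  for (depth in c(9, 10, 20, 37)) {
    for (k in 0:depth) {
      ad <- c(depth - k, 0, k, 0)  # ref A, alt G
      got <- as.character(genotype_from_evidence(ad, "A", th))
      expect_identical(got, oracle_genotype(ad, 1L, th),
                       info = sprintf("depth=%d k=%d", depth, k))
    }
  }
  # and with reads on two alternate bases
  ad <- c(10, 6, 8, 0)
  expect_identical(as.character(genotype_from_evidence(ad, "A", th)),
                   oracle_genotype(ad, 1L, th))
})

test_that("callable_sites counts fully genotyped sites", {
  n <- 500L
  gt <- matrix(0L, n, 6)
  gm <- make_gm(gt)
  expect_identical(callable_sites(gm), n)
  gt[100, 3] <- NA
  expect_identical(callable_sites(make_gm(gt)), n - 1L)
  # random missingness vs brute-force intersection
  set.seed(14)
  for (i in 1:5) {
    gt <- matrix(sample(c(0L, 1L, NA), n * 6, TRUE, c(0.8, 0.1, 0.1)),
                 n, 6)
    oracle <- sum(vapply(seq_len(n), function(s) !anyNA(gt[s, ]),
                         logical(1)))
    expect_identical(callable_sites(make_gm(gt)), oracle)
  }
  expect_error(callable_sites(genotype_matrix(character(), integer(),
                                              character(), character(),
                                              matrix(integer(), 0, 0))),
               class = "mutaccum_call_error")
})

test_that("unique-heterozygote rule matches an exhaustive oracle", {
  # hand cases
  gt <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L),  # candidate in line 1
              c(1L, 1L, 0L, 0L, 0L, 0L),  # shared het: not de novo
              c(1L, 0L, 0L, 0L, 0L, NA),  # missing other line: excluded
              c(1L, 2L, 0L, 0L, 0L, 0L),  # hom-alt elsewhere: excluded
              c(0L, 0L, 0L, 0L, 0L, 0L))  # no variant
  cand <- consensus_candidates(make_gm(gt))
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$line, "L1")
  expect_identical(cand$pos, 1L)

  # random matrices against the per-site scan oracle
  set.seed(33)
  for (i in 1:5) {
    n <- 2000
    gt <- matrix(sample(c(0L, 1L, 2L, NA), n * 6, TRUE,
                        c(0.85, 0.08, 0.02, 0.05)), n, 6)
    gm <- make_gm(gt)
    got <- consensus_candidates(gm)
    oracle <- oracle_consensus(gt)
    expect_identical(nrow(got), nrow(oracle))
    expect_setequal(paste(got$pos, match(got$line, gm$samples)),
                    paste(oracle$site, oracle$line))
  }
})

test_that("no candidate is called at an uncallable site", {
  gt <- matrix(0L, 10, 6)
  gt[c(2, 7), 1] <- 1L
  mask <- IRanges::IRanges(1, 5)  # only sites 1..5 callable
  cand <- consensus_candidates(make_gm(gt), mask)
  expect_identical(cand$pos, 2L)
})

test_that("curation filters tag candidates with one primary reason", {
  lines <- paste0("R_L", 1:6)
  depth <- matrix(50L, 300, 6)
  depth[40, 2:6] <- 3L           # thin non-focal lines at site 40
  depth[50, 1] <- 400L           # excess depth at site 50
  depth[60, 1] <- 5L             # low focal depth at site 60
  alt <- data.table::data.table(
    pos = c(10L, 20L, 20L, 30L, 40L, 50L, 60L, 100L, 103L),
    line = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L),
    base = c(3L, 3L, 2L, 3L, 3L, 3L, 3L, 3L, 3L),
    count = c(2L, 25L, 5L, 25L, 25L, 200L, 2L, 25L, 25L))
  data.table::setkeyv(alt, c("pos", "line"))
  ev <- list(depth = depth, alt = alt, lines = lines)
  cand <- mutaccum:::new_candidates(
    regime = rep("R", 8), line = lines[c(1, 1, 1, 1, 1, 1, 2, 2)],
    chrom = rep("chr1", 8), pos = c(10, 20, 30, 40, 50, 60, 100, 103),
    ref = rep("A", 8), alt = rep("G", 8), caller = rep("consensus", 8))
  out <- apply_filters(cand, ev, filter_config())
  res <- setNames(out$reason, out$pos)
  expect_identical(unname(res["10"]), "allele_balance")   # 2/50 = 0.04
  expect_identical(unname(res["20"]), "multiallelic")     # second allele 5
  expect_true(is.na(res["30"]))                           # clean: accepted
  expect_identical(unname(res["40"]), "other_line_depth")
  expect_identical(unname(res["50"]), "high_depth")
  expect_identical(unname(res["60"]), "low_depth")
  expect_identical(unname(res["100"]), "cluster")         # 3 bp apart
  expect_identical(unname(res["103"]), "cluster")
  expect_identical(out$status[out$pos == 30], "accepted")
  expect_identical(sum(out$status == "accepted"), 1L)
})

test_that("error-free deep data gives perfect recall and precision", {
  cfg <- sim_config(genome_length = 3e4, mu_per_regime = 3e-5,
                    seq_error = 0, mean_depth_per_regime = 80,
                    depth_dispersion = 50, seed = 77)
  ex <- simulate_experiment(cfg)
  expect_gt(nrow(ex$truth), 5)
  for (r in cfg$regime_names) {
    gm <- genotype_matrix_from_evidence(ex, r)
    cand <- consensus_candidates(gm, ex$masks[[r]], regime = r)
    acc <- apply_filters(cand, ex$evidence[[r]])
    acc <- acc[acc$status == "accepted", ]
    tr <- ex$truth[ex$truth$regime == r, ]
    expect_setequal(paste(acc$line, acc$pos, acc$alt),
                    paste(tr$line, tr$pos, tr$alt))
  }
})

test_that("acceptance rates by regime are tabulated and tested", {
  cfg <- small_config(55, genome = 5e4, mu = 1e-4)
  ex <- simulate_experiment(cfg)
  all_cand <- data.table::rbindlist(lapply(cfg$regime_names, function(r) {
    gm <- genotype_matrix_from_evidence(ex, r)
    apply_filters(consensus_candidates(gm, ex$masks[[r]], regime = r),
                  ex$evidence[[r]])
  }))
  res <- acceptance_by_regime(all_cand, B = 500, seed = 2)
  expect_true(all(c("n_candidates", "n_accepted", "acceptance_rate")
                  %in% names(res$table)))
  expect_true(all(res$table$acceptance_rate >= 0 &
                    res$table$acceptance_rate <= 1))
})
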