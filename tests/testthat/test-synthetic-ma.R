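# Simulator: config validation, truth calibration, spectrum self-checks,
# survivorship, conservation and reproducibility.

test_that("out-of-range configs are rejected with a named error", {
  expect_error(sim_config(seed = 1, gc_content = 1.5),
               class = "mutaccum_config_error")
  expect_error(sim_config(seed = 1, genome_length = 100),
               class = "mutaccum_config_error")
  expect_error(sim_config(seed = 1, mu_per_regime = -1e-8),
               class = "mutaccum_config_error")
  expect_error(sim_config(seed = 1, seq_error = 0.7),
               class = "mutaccum_config_error")
  expect_error(sim_config(seed = 1, extinction_prob_per_regime = 2),
               class = "mutaccum_config_error")
  expect_error(sim_config(genome_length = 1e5),
               class = "mutaccum_config_error")  # missing seed
  expect_error(sim_config(seed = 1, mu_per_regime = c(1e-8, 1e-8)),
               class = "mutaccum_config_error")  # wrong length
})

test_that("mu = 0 yields no truth records; extinction 0 yields full survival", {
  ex <- simulate_experiment(sim_config(genome_length = 2e4, seed = 3,
                                       mu_per_regime = 0,
                                       extinction_prob_per_regime = 0),
                            evidence = FALSE)
  expect_identical(nrow(ex$truth), 0L)
  expect_true(all(ex$survival$frac_alive == 1))
})

test_that("truth counts are Poisson-calibrated at mu*n*T over replicates", {
  # stated example: mu 1e-8, genome 1e7, T = 3 -> 0.3 per line
  # (callable_fraction 1 so every site is mutable)
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i) {
    ex <- simulate_experiment(
      sim_config(genome_length = 1e7, n_regimes = 1, mu_per_regime = 1e-8,
                 callable_fraction_target = 1, seed = 1000 + i),
      evidence = FALSE)
    nrow(ex$truth)
  }, numeric(1))
  expected_per_line <- 1e-8 * 1e7 * 3
  mean_per_line <- sum(counts) / (n_rep * 6)
  se <- sqrt(expected_per_line / (n_rep * 6))
  expect_lt(abs(mean_per_line - expected_per_line), 3 * se)
  # totals across 6 lines Poisson with mean 1.8
  expect_lt(abs(mean(counts) - 1.8), 3 * sqrt(1.8 / n_rep))
})

test_that("transition fraction of the truth converges to ts_fraction", {
  ex <- simulate_experiment(
    sim_config(genome_length = 1e5, mu_per_regime = 1.9e-3,
               callable_fraction_target = 1, ts_fraction = 0.5, seed = 11),
    evidence = FALSE)
  sp <- spectrum_of_truth(ex)
  pooled <- sp[sp$group == "all", ]
  expect_gt(pooled$total, 5000)
  se <- sqrt(0.25 / pooled$total)
  expect_lt(abs(pooled$ts / pooled$total - 0.5), 3 * se)

  ex1 <- simulate_experiment(
    sim_config(genome_length = 5e4, mu_per_regime = 1e-4, ts_fraction = 1,
               seed = 12), evidence = FALSE)
  sp1 <- spectrum_of_truth(ex1)
  expect_identical(sp1[sp1$group == "all", ]$tv, 0L)

  # empty truth -> all-zero counts
  sp0 <- spectrum_of_truth(data.table::data.table(
    regime = character(), ref = character(), alt = character()))
  expect_true(all(sp0$total == 0))
})

test_that("identical seeds give identical experiments", {
  cfg <- small_config(99, genome = 2e4)
  ex1 <- simulate_experiment(cfg)
  ex2 <- simulate_experiment(cfg)
  expect_identical(ex1, ex2)
  # and the seed does not leak into the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulate_experiment(cfg, evidence = FALSE))
  expect_identical(runif(1), before)
})

test_that("truth mutations are carried by exactly one line (conservation)", {
  cfg <- small_config(21, genome = 2e4, mu = 1e-4, seq_error = 0)
  ex <- simulate_experiment(cfg)
  expect_gt(nrow(ex$truth), 0)
  for (r in unique(ex$truth$regime)) {
    ev <- ex$evidence[[r]]
    tr <- ex$truth[ex$truth$regime == r, ]
    # with seq_error 0 every non-ref read is mutational: non-ref evidence
    # exists only at truth cells
    expect_setequal(paste(ev$alt$pos, ev$alt$line),
                    paste(tr$pos, match(tr$line, ev$lines)))
    # and the alt base matches the truth allele
    m <- merge(ev$alt[, c("pos", "base")], tr[, c("pos", "alt")],
               by = "pos")
    expect_true(all(mutaccum:::BASES[m$base] == m$alt))
  }
  # (line, position) unique within a regime
  expect_false(anyDuplicated(ex$truth[, c("regime", "pos")]) > 0)
})

test_that("mutations land only in the callable mask unless allowed", {
  cfg <- small_config(31, genome = 5e4, mu = 1e-4,
                      callable_fraction_target = 0.5)
  ex <- simulate_experiment(cfg, evidence = FALSE)
  for (r in unique(ex$truth$regime)) {
    pos <- ex$truth$pos[ex$truth$regime == r]
    hit <- IRanges::overlapsAny(IRanges::IRanges(pos, pos), ex$masks[[r]])
    expect_true(all(hit))
  }
  # realized callable fraction near target
  frac <- ex$n_callable / cfg$genome_length
  expect_true(all(abs(frac - 0.5) < 0.05))

  ex2 <- simulate_experiment(sim_config(genome_length = 5e4, seed = 31,
                                        mu_per_regime = 2e-4,
                                        callable_fraction_target = 0.3),
                             evidence = FALSE, allow_uncallable = TRUE)
  out <- vapply(unique(ex2$truth$regime), function(r) {
    pos <- ex2$truth$pos[ex2$truth$regime == r]
    sum(!IRanges::overlapsAny(IRanges::IRanges(pos, pos), ex2$masks[[r]]))
  }, numeric(1))
  expect_gt(sum(out), 0)  # some mutations outside the 30% mask
})

test_that("survivorship is non-increasing and respects extinction probs", {
  for (seed in c(1, 2, 3)) {
    ex <- simulate_experiment(sim_config(genome_length = 1e4, seed = seed,
                                         generations = 5),
                              evidence = FALSE)
    for (r in unique(ex$survival$regime)) {
      s <- ex$survival$frac_alive[ex$survival$regime == r]
      expect_true(all(diff(s) <= 0))
      expect_identical(s[1], 1)
    }
  }
  # generation-of-origin favours late generations (transmission survival)
  ex <- simulate_experiment(sim_config(genome_length = 1e5, seed = 8,
                                       mu_per_regime = 1e-3,
                                       callable_fraction_target = 1),
                            evidence = FALSE)
  tab <- table(ex$truth$gen_origin)
  expect_true(tab[["3"]] > tab[["1"]])  # weights 1 vs 1/4
})

test_that("config files round-trip", {
  cfg <- small_config(17)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2, cfg)
  expect_error(read_sim_config(withr::local_tempfile()),
               class = "mutaccum_io_error")
})
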