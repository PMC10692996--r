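# Simulation configuration: the stated world of the synthetic MA experiment.

#' Simulation configuration for a synthetic MA experiment
#'
#' Describes a mutation-accumulation (MA) experiment: a diploid founder
#' genome, `n_regimes` age-at-reproduction regimes, `lines_per_regime`
#' sequenced lines per regime, `generations` single-pair transmissions, and
#' per-regime mutation rate, sequencing depth, callable fraction and line
#' extinction probability. Defaults are the conditions of a three-regime
#' nematode MA experiment: 6 sequenced lines per regime, T = 3 generations,
#' regime mutation rates 0.74/0.30/1.20e-8 per site per generation, mean
#' depths 68.5/76.6/52.9x, callable fractions 72.8/75.4/74.5%, and a
#' transition fraction of 36/37.
#'
#' `mu_per_regime` is the per-*mutable*-site per-generation rate of
#' heterozygous mutations observed in the sequenced generation-T individual;
#' mutable sites are the callable sites unless uncallable placement is
#' enabled in [simulate_experiment()].
#'
#' @param genome_length Genome size in bp (>= 1e4).
#' @param gc_content GC fraction of the founder genome in `[0, 1]`.
#' @param n_regimes Number of age-at-reproduction regimes.
#' @param lines_per_regime Number of sequenced MA lines per regime.
#' @param generations Number of generations of accumulation, T.
#' @param mu_per_regime Per-site per-generation diploid heterozygous mutation
#'   rate, one value per regime (recycled).
#' @param ts_fraction Probability a mutation is a transition.
#' @param mean_depth_per_regime Mean sequencing depth per regime.
#' @param depth_dispersion Negative-binomial `size` of per-site depth
#'   (smaller = more overdispersed).
#' @param seq_error Per-base sequencing error probability in `[0, 0.5)`.
#' @param callable_fraction_target Fraction of the genome covered by each
#'   regime's callable mask (recycled per regime).
#' @param extinction_prob_per_regime Per-generation probability that a
#'   founded line goes extinct, per regime.
#' @param founded_per_regime Number of lines founded per regime (the
#'   denominator of the survivorship table).
#' @param seed Integer seed; mandatory.
#' @param regime_names Optional regime labels; defaults to
#'   `YoungT1/PeakT2/OldT5` for three regimes.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_experiment()]
#' @examples
#' cfg <- sim_config(genome_length = 5e4, seed = 1)
#' cfg$mu_per_regime
#' @export
sim_config <- function(genome_length = 1e6,
                       gc_content = 0.36,
                       n_regimes = 3,
                       lines_per_regime = 6,
                       generations = 3,
                       mu_per_regime = c(0.74e-8, 0.30e-8, 1.20e-8),
                       ts_fraction = 36 / 37,
                       mean_depth_per_regime = c(68.50, 76.59, 52.92),
                       depth_dispersion = 5,
                       seq_error = 1e-3,
                       callable_fraction_target = c(0.7275, 0.7536, 0.7450),
                       extinction_prob_per_regime = c(0.05, 0.10, 0.50),
                       founded_per_regime = c(120, 60, 149),
                       seed,
                       regime_names = NULL) {
  if (missing(seed)) {
    ma_error("'seed' is mandatory in sim_config()", "mutaccum_config_error")
  }
  check_scalar(seed, "seed", -2^31, 2^31)
  check_scalar(genome_length, "genome_length", 1e4, Inf)
  check_scalar(gc_content, "gc_content", 0, 1)
  check_scalar(n_regimes, "n_regimes", 1, Inf)
  check_scalar(lines_per_regime, "lines_per_regime", 1, Inf)
  check_scalar(generations, "generations", 1, Inf)
  check_scalar(ts_fraction, "ts_fraction", 0, 1)
  check_scalar(depth_dispersion, "depth_dispersion", 1e-6, Inf)
  check_scalar(seq_error, "seq_error", 0, 0.5 - 1e-12)

  n_regimes <- as.integer(n_regimes)
  # the shipped defaults describe a three-regime experiment; for other
  # regime counts fall back to experiment-wide averages unless overridden
  if (n_regimes != 3L) {
    if (missing(mu_per_regime)) mu_per_regime <- 0.74e-8
    if (missing(mean_depth_per_regime)) mean_depth_per_regime <- 66
    if (missing(callable_fraction_target)) callable_fraction_target <- 0.742
    if (missing(extinction_prob_per_regime)) {
      extinction_prob_per_regime <- 0.1
    }
    if (missing(founded_per_regime)) founded_per_regime <- 100
  }
  cfg <- list(
    genome_length = as.integer(genome_length),
    gc_content = gc_content,
    n_regimes = n_regimes,
    lines_per_regime = as.integer(lines_per_regime),
    generations = as.integer(generations),
    mu_per_regime = per_regime(mu_per_regime, n_regimes, "mu_per_regime",
                               0, 1),
    ts_fraction = ts_fraction,
    mean_depth_per_regime = per_regime(mean_depth_per_regime, n_regimes,
                                       "mean_depth_per_regime", 0, Inf),
    depth_dispersion = depth_dispersion,
    seq_error = seq_error,
    callable_fraction_target = per_regime(callable_fraction_target, n_regimes,
                                          "callable_fraction_target", 0, 1),
    extinction_prob_per_regime = per_regime(extinction_prob_per_regime,
                                            n_regimes,
                                            "extinction_prob_per_regime",
                                            0, 1),
    founded_per_regime = as.integer(per_regime(founded_per_regime, n_regimes,
                                               "founded_per_regime", 1, Inf)),
    seed = as.integer(seed)
  )
  if (is.null(regime_names)) {
    regime_names <- if (n_regimes == 3) {
      c("YoungT1", "PeakT2", "OldT5")
    } else {
      paste0("R", seq_len(n_regimes))
    }
  }
  if (length(regime_names) != n_regimes || anyDuplicated(regime_names)) {
    ma_error("'regime_names' must be unique and match n_regimes",
             "mutaccum_config_error")
  }
  cfg$regime_names <- as.character(regime_names)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MA simulation config:", x$n_regimes, "regimes x", x$lines_per_regime,
      "lines x", x$generations, "generations;",
      format(x$genome_length, big.mark = ","), "bp genome\n")
  cat("  mu:", paste(format(x$mu_per_regime, digits = 3), collapse = ", "),
      " depth:", paste(format(x$mean_depth_per_regime, digits = 4),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Read a simulation config from a key = value text file
#'
#' Lines of the form `key = value`; `#` starts a comment. Vector-valued
#' fields are comma-separated. Unknown keys are an error; `seed` is
#' mandatory.
#'
#' @param path Path to the config file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    ma_error(paste("config file not found:", path), "mutaccum_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    ma_error(paste("malformed config line:", lines[bad][1]),
             "mutaccum_config_error")
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  known <- setdiff(names(formals(sim_config)), "regime_names")
  if (any(!keys %in% c(known, "regime_names"))) {
    ma_error(paste("unknown config key:",
                   paste(setdiff(keys, c(known, "regime_names")),
                         collapse = ", ")),
             "mutaccum_config_error")
  }
  args <- lapply(seq_along(keys), function(i) {
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    if (keys[i] == "regime_names") v else as.numeric(v)
  })
  names(args) <- keys
  do.call(sim_config, args)
}

#' Write a simulation config as a key = value text file
#'
#' @param config A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  keys <- setdiff(names(config), NULL)
  out <- vapply(keys, function(k) {
    paste0(k, " = ", paste(format(config[[k]], digits = 15, scientific = NA),
                           collapse = ","))
  }, "")
  writeLines(out, path)
  invisible(path)
}
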