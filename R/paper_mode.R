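# "Paper mode": run the whole statistics layer from count tables alone
# (regime-level mutation counts, callable sites, Ts/Tv pools and effect
# category counts), with no sequence-level data. This validates the
# numerics independently of the callers.

#' Statistics layer from count tables (paper mode)
#'
#' Recomputes the downstream statistic set of an MA study from two small
#' input tables: a per-regime summary (lines, total and mean/SE mutation
#' counts, callable sites, generations, transitions, transversions) and a
#' consequence-by-regime effect count table. Shipped defaults hold the
#' counts of a three-regime nematode MA experiment.
#'
#' Computed per regime: mean mutation rate and SE on the 1e-8 scale;
#' transition/transversion equal-proportion goodness-of-fit chi-square with
#' Monte-Carlo p. Pooled: Ts/Tv counts and ratio. Across regimes: binomial
#' and Poisson-offset GLM likelihood-ratio statistics on the regime totals.
#' Effects: the impact table aggregated from consequences under the fixed
#' severity mapping, and equal-proportion GoF chi-squares per category.
#'
#' @param regime_file TSV with columns regime, lines, mutations,
#'   mutations_mean, mutations_se, callable_sites, generations,
#'   transitions, transversions.
#' @param effect_file TSV with column `consequence` then one count column
#'   per regime.
#' @param B Monte-Carlo replicates for simulated p values.
#' @param seed Seed for the simulated p values.
#' @return A nested list: `rates`, `glm`, `spectrum`, `effects`.
#' @export
paper_check <- function(regime_file = system.file("extdata",
                          "regime_counts.tsv", package = "mutaccum"),
                        effect_file = system.file("extdata",
                          "effect_counts.tsv", package = "mutaccum"),
                        B = 10000, seed = 1) {
  reg <- read_tsv(regime_file)
  eff <- read_tsv(effect_file)
  stopifnot(all(c("regime", "lines", "mutations", "callable_sites",
                  "generations", "transitions", "transversions")
                %in% names(reg)))

  rates <- lapply(seq_len(nrow(reg)), function(i) {
    est <- mutation_rate(reg$mutations[i], reg$lines[i],
                         reg$callable_sites[i], reg$generations[i])
    se <- if ("mutations_se" %in% names(reg)) {
      reg$mutations_se[i] / (reg$callable_sites[i] * reg$generations[i])
    } else {
      NA_real_
    }
    list(regime = reg$regime[i], m = est$m, L = est$L, n = est$n,
         T = est$T, mu = est$mu, mu_1e8 = est$mu * 1e8,
         mu_se = se, mu_se_1e8 = se * 1e8)
  })
  names(rates) <- reg$regime

  glm_bin <- compare_regimes_binomial(
    reg$mutations, reg$lines * reg$callable_sites, reg$regime)
  glm_poi <- compare_regimes_poisson(
    reg$mutations, reg$lines * reg$callable_sites, reg$generations[1],
    reg$regime)

  sp <- lapply(seq_len(nrow(reg)), function(i) {
    g <- chisq_gof(c(reg$transitions[i], reg$transversions[i]),
                   B = B, seed = seed)
    list(regime = reg$regime[i], ts = reg$transitions[i],
         tv = reg$transversions[i], statistic = g$statistic,
         p_simulated = g$p_simulated)
  })
  names(sp) <- reg$regime
  ts_all <- sum(reg$transitions)
  tv_all <- sum(reg$transversions)
  spectrum <- list(
    per_regime = sp,
    pooled = list(ts = ts_all, tv = tv_all,
                  ts_tv_ratio = if (tv_all > 0) ts_all / tv_all else
                    NA_real_))

  regimes <- setdiff(names(eff), "consequence")
  cons_mat <- as.matrix(eff[, regimes, with = FALSE])
  rownames(cons_mat) <- eff$consequence
  imp_names <- impact_of(rownames(cons_mat))
  imp_mat <- rowsum(cons_mat, imp_names)
  tab <- structure(list(consequence = cons_mat, impact = imp_mat),
                   class = "effect_table")
  cats <- c(rownames(cons_mat)[rowSums(cons_mat) > 0],
            rownames(imp_mat)[rowSums(imp_mat) > 0])
  eff_tests <- lapply(cats, function(cc) {
    g <- compare_effect_counts(tab, cc, B = B, seed = seed)
    list(category = cc, N = sum(g$observed), statistic = g$statistic,
         p_simulated = g$p_simulated)
  })
  names(eff_tests) <- cats

  list(rates = rates,
       glm = list(binomial = list(statistic = glm_bin$statistic,
                                  df = glm_bin$df, p = glm_bin$p),
                  poisson = list(statistic = glm_poi$statistic,
                                 df = glm_poi$df, p = glm_poi$p)),
       spectrum = spectrum,
       effects = list(table = tab, tests = eff_tests),
       B = B, seed = seed)
}
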