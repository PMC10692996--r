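# Mutation-rate estimation (mu = m / (L * n * T)) and regime-comparison
# generalized linear models.

#' Per-site per-generation mutation rate
#'
#' `mu = m / (L * n * T)`: `m` mutations over `L` lines, `n` callable
#' sites, `T` generations. `L = 1` gives a line-level estimate.
#'
#' @param m Mutation count (>= 0).
#' @param L Number of lines (>= 1).
#' @param n Callable sites (>= 1).
#' @param T_gen Generations of accumulation (>= 1).
#' @return A `mutation_rate_estimate` list: `m`, `L`, `n`, `T`, `mu`.
#' @examples
#' mutation_rate(12, 6, 90566554, 3)$mu * 1e8  # 0.74
#' @export
mutation_rate <- function(m, L, n, T_gen) {
  stopifnot(m >= 0, L >= 1, n >= 1, T_gen >= 1)
  denom <- as.double(L) * as.double(n) * as.double(T_gen)
  if (denom == 0) {
    ma_error("zero denominator in mutation rate", "mutaccum_rate_error")
  }
  structure(list(m = m, L = L, n = n, T = T_gen, mu = m / denom),
            class = "mutation_rate_estimate")
}

#' @export
print.mutation_rate_estimate <- function(x, ...) {
  cat(sprintf("mu = %.3g per site per generation (m=%g, L=%g, n=%g, T=%g)\n",
              x$mu, x$m, x$L, x$n, x$T))
  invisible(x)
}

#' Regime-level mean mutation rate with standard error
#'
#' The regime mean is the mean of the per-line rates `m_i / (n * T)`; its
#' standard error is the sample SD of the per-line rates divided by
#' `sqrt(L)`. With a common `n` this equals the pooled
#' `sum(m) / (L * n * T)`.
#'
#' @param counts Per-line mutation counts (length >= 2).
#' @param n Callable sites of the regime.
#' @param T_gen Generations.
#' @return List with `mu_mean`, `mu_se`, `mu_per_line`, `m`, `L`, `n`, `T`.
#' @export
regime_mean_rate <- function(counts, n, T_gen) {
  L <- length(counts)
  if (L < 2L) {
    ma_error("need >= 2 lines for a regime mean", "mutaccum_rate_error")
  }
  per_line <- counts / (as.double(n) * T_gen)
  list(mu_mean = mean(per_line),
       mu_se = stats::sd(per_line) / sqrt(L),
       mu_per_line = per_line,
       m = sum(counts), L = L, n = n, T = T_gen)
}

#' glm wrapper muffling the benign rare-event boundary warnings
#' @noRd
quiet_glm <- function(...) {
  withCallingHandlers(stats::glm(...), warning = function(w) {
    if (grepl("fitted (probabilities|rates) numerically 0",
              conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' @noRd
lr_comparison <- function(fit1, fit0, model, n_regimes, boot_stat = NULL) {
  stat <- as.numeric(fit0$deviance - fit1$deviance)
  stat <- max(stat, 0)
  df <- n_regimes - 1L
  structure(list(model = model, statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 p_boot = boot_stat),
            class = "regime_comparison")
}

#' @export
print.regime_comparison <- function(x, ...) {
  cat(sprintf("%s GLM regime comparison: X2 = %.4g, df = %d, p = %.3g\n",
              x$model, x$statistic, x$df, x$p))
  if (!is.null(x$p_boot)) cat(sprintf("  parametric bootstrap p = %.3g\n",
                                      x$p_boot))
  invisible(x)
}

#' Binomial GLM comparison of mutation rates between regimes
#'
#' Fits mutated vs non-mutated callable sites (`cbind(m, n - m)`) against
#' the regime factor and reports the likelihood-ratio chi-square against
#' the intercept-only model. Optionally adds a seeded parametric-bootstrap
#' p value (simulate counts under the pooled-rate null, `B` replicates) for
#' small-count safety.
#'
#' @param m Per-unit mutation counts (per line, or per regime totals).
#' @param n Callable-site denominators, recycled against `m`.
#' @param regime Regime factor, one element per entry of `m`.
#' @param B Bootstrap replicates (0 = asymptotic p only).
#' @param seed Bootstrap seed.
#' @return A `regime_comparison`.
#' @export
compare_regimes_binomial <- function(m, n, regime, B = 0, seed = 1) {
  regime <- factor(regime)
  if (nlevels(regime) < 2L) {
    ma_error("need >= 2 regimes", "mutaccum_rate_error")
  }
  n <- rep_len(n, length(m))
  fit1 <- quiet_glm(cbind(m, n - m) ~ regime, family = stats::binomial())
  fit0 <- quiet_glm(cbind(m, n - m) ~ 1, family = stats::binomial())
  p_boot <- NULL
  if (B > 0) {
    obs <- fit0$deviance - fit1$deviance
    phat <- sum(m) / sum(n)
    p_boot <- with_seed(seed, {
      sims <- vapply(seq_len(B), function(b) {
        mb <- stats::rbinom(length(n), n, phat)
        f1 <- quiet_glm(cbind(mb, n - mb) ~ regime,
                        family = stats::binomial())
        f0 <- quiet_glm(cbind(mb, n - mb) ~ 1, family = stats::binomial())
        f0$deviance - f1$deviance
      }, numeric(1))
      mean(sims >= obs - 1e-12)
    })
  }
  lr_comparison(fit1, fit0, "binomial", nlevels(regime), p_boot)
}

#' Poisson GLM comparison of mutation rates between regimes
#'
#' Poisson regression of mutation counts with a `log(n * T)` exposure
#' offset; likelihood-ratio chi-square of the regime factor against the
#' intercept-only model. (The offset parameterization is the standard rate
#' model; prior-weight parameterizations of the same contrast produce
#' degenerate statistics and are not used here.)
#'
#' @param m Per-unit mutation counts.
#' @param n Callable-site denominators, recycled.
#' @param T_gen Generations (scalar exposure multiplier).
#' @param regime Regime factor.
#' @param B,seed Optional parametric bootstrap as in
#'   [compare_regimes_binomial()].
#' @return A `regime_comparison`.
#' @export
compare_regimes_poisson <- function(m, n, T_gen, regime, B = 0, seed = 1) {
  regime <- factor(regime)
  if (nlevels(regime) < 2L) {
    ma_error("need >= 2 regimes", "mutaccum_rate_error")
  }
  n <- rep_len(n, length(m))
  expo <- log(n * T_gen)
  fit1 <- quiet_glm(m ~ regime + offset(expo), family = stats::poisson())
  fit0 <- quiet_glm(m ~ 1 + offset(expo), family = stats::poisson())
  p_boot <- NULL
  if (B > 0) {
    obs <- fit0$deviance - fit1$deviance
    lam <- sum(m) / sum(n * T_gen)
    p_boot <- with_seed(seed, {
      sims <- vapply(seq_len(B), function(b) {
        mb <- stats::rpois(length(n), lam * n * T_gen)
        f1 <- quiet_glm(mb ~ regime + offset(expo),
                        family = stats::poisson())
        f0 <- quiet_glm(mb ~ 1 + offset(expo), family = stats::poisson())
        f0$deviance - f1$deviance
      }, numeric(1))
      mean(sims >= obs - 1e-12)
    })
  }
  lr_comparison(fit1, fit0, "poisson", nlevels(regime), p_boot)
}
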