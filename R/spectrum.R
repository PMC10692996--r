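# Mutation spectrum: six strand-collapsed substitution classes, Ts/Tv
# pooling, and chi-squared tests with Monte-Carlo simulated p values.

#' The six strand-collapsed substitution classes, in canonical order
#' @export
SPECTRUM_CLASSES <- c("A:T>G:C", "G:C>A:T", "A:T>C:G",
                      "G:C>T:A", "A:T>T:A", "G:C>C:G")

#' Classify a substitution into one of six strand-collapsed classes
#'
#' A mutation and its reverse complement map to the same class
#' (e.g. both A>G and T>C are `A:T>G:C`). The first two classes are the
#' transitions.
#'
#' @param ref,alt Reference and alternate bases (vectors of A/C/G/T;
#'   `ref != alt` elementwise).
#' @return A data.table with columns `type` (factor over the six classes)
#'   and `is_transition`.
#' @examples
#' classify_substitution(c("A", "T", "C"), c("G", "C", "A"))
#' @export
classify_substitution <- function(ref, alt) {
  r <- base_to_code(ref)
  a <- base_to_code(alt)
  if (any(r == a)) {
    ma_error("ref and alt must differ", "mutaccum_spectrum_error")
  }
  # collapse strands: represent each pair with the purine A or G on the
  # Watson strand (complement both alleles when ref is C or T)
  comp <- c(4L, 3L, 2L, 1L)
  flip <- r %in% c(2L, 4L)
  r2 <- ifelse(flip, comp[r], r)
  a2 <- ifelse(flip, comp[a], a)
  key <- paste(BASES[r2], BASES[a2], sep = ">")
  map <- c("A>G" = "A:T>G:C", "G>A" = "G:C>A:T", "A>C" = "A:T>C:G",
           "G>T" = "G:C>T:A", "A>T" = "A:T>T:A", "G>C" = "G:C>C:G")
  type <- unname(map[key])
  data.table::data.table(
    type = factor(type, levels = SPECTRUM_CLASSES),
    is_transition = type %in% SPECTRUM_CLASSES[1:2])
}

#' Tally substitutions into spectrum counts per group
#'
#' @param ref,alt Base vectors as in [classify_substitution()].
#' @param group Optional grouping vector (e.g. regime); a pooled `"all"`
#'   row is always appended.
#' @return A `spectrum_counts` data.table: one row per group with the six
#'   class counts, `ts`, `tv`, `total` and `ts_tv_ratio` (`NA` with
#'   `tv_zero = TRUE` when there are no transversions).
#' @export
spectrum_counts <- function(ref, alt, group = NULL) {
  n <- length(ref)
  if (is.null(group)) group <- rep("all", n)
  groups <- unique(as.character(group))
  cls <- if (n) classify_substitution(ref, alt)$type else
    factor(character(), levels = SPECTRUM_CLASSES)
  tab <- function(sel, label) {
    cnt <- as.integer(table(cls[sel]))
    ts <- sum(cnt[1:2])
    tv <- sum(cnt[3:6])
    out <- data.table::as.data.table(as.list(cnt))
    data.table::setnames(out, SPECTRUM_CLASSES)
    out[, `:=`(group = label, ts = ts, tv = tv, total = ts + tv,
               ts_tv_ratio = if (tv > 0) ts / tv else NA_real_,
               tv_zero = tv == 0L)]
    data.table::setcolorder(out, "group")
    out
  }
  res <- data.table::rbindlist(c(
    lapply(groups, function(g) tab(as.character(group) == g, g)),
    list(tab(rep(TRUE, n), "all"))))
  structure(res, class = c("spectrum_counts", class(res)))
}

#' Chi-squared goodness-of-fit test with Monte-Carlo p value
#'
#' Computes Pearson's \eqn{X^2 = \sum (O-E)^2/E} against expected
#' proportions and simulates the p value as the fraction of `B` multinomial
#' draws (same total, given proportions) whose statistic is at least the
#' observed one. The default is the plain Monte-Carlo fraction; set
#' `add_one = TRUE` for the (s+1)/(B+1) convention.
#'
#' @param observed Non-negative integer counts, not all zero.
#' @param p Expected proportions (default equal); must sum to 1.
#' @param B Number of Monte-Carlo replicates (default 10,000).
#' @param seed Seed for the simulated p value.
#' @param add_one Use the (s+1)/(B+1) convention?
#' @return List with `statistic`, `p_simulated`, `B`, `seed`, `observed`,
#'   `expected`.
#' @examples
#' chisq_gof(c(12, 0), seed = 1)$statistic  # 12
#' @export
chisq_gof <- function(observed, p = NULL, B = 10000, seed = 1,
                      add_one = FALSE) {
  if (any(observed < 0) || sum(observed) == 0) {
    ma_error("counts must be non-negative and not all zero",
             "mutaccum_stat_error")
  }
  k <- length(observed)
  if (is.null(p)) p <- rep(1 / k, k)
  if (length(p) != k || abs(sum(p) - 1) > 1e-8) {
    ma_error("proportions must match counts and sum to 1",
             "mutaccum_stat_error")
  }
  if (any(p <= 0)) {
    ma_error("zero expected cell", "mutaccum_stat_error")
  }
  N <- sum(observed)
  E <- N * p
  x2 <- sum((observed - E)^2 / E)
  p_sim <- with_seed(seed, {
    sim <- stats::rmultinom(B, N, p)
    sim_x2 <- colSums((sim - E)^2 / E)
    if (add_one) (sum(sim_x2 >= x2 - 1e-12) + 1) / (B + 1) else
      mean(sim_x2 >= x2 - 1e-12)
  })
  list(statistic = x2, p_simulated = p_sim, B = as.integer(B),
       seed = as.integer(seed), observed = observed, expected = E)
}

#' Chi-squared test of independence with Monte-Carlo p value
#'
#' Pearson's statistic on a two-way table against the independence
#' expectation; the p value is simulated from `B` multinomial draws over all
#' cells with independence probabilities (row margin x column margin / N^2),
#' holding the table total.
#'
#' @param tab Non-negative two-way matrix/table with positive margins.
#' @param B Monte-Carlo replicates.
#' @param seed Seed.
#' @param add_one Use the (s+1)/(B+1) convention?
#' @return List with `statistic`, `df`, `p_simulated`, `B`, `seed`.
#' @export
chisq_contingency <- function(tab, B = 10000, seed = 1, add_one = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    ma_error("table must be non-negative with positive margins",
             "mutaccum_stat_error")
  }
  N <- sum(tab)
  nr <- nrow(tab); nc <- ncol(tab)
  pearson <- function(m) {
    # Pearson X2 against the table's own independence expectation;
    # cells with zero margins contribute 0
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    d <- (m - E)^2
    sum(d[E > 0] / E[E > 0])
  }
  x2 <- pearson(tab)
  pr <- outer(rowSums(tab), colSums(tab)) / N^2
  p_sim <- with_seed(seed, {
    sim <- stats::rmultinom(B, N, as.vector(pr))
    sim_x2 <- apply(sim, 2L, function(v) {
      pearson(matrix(v, nr, nc))
    })
    if (add_one) (sum(sim_x2 >= x2 - 1e-12) + 1) / (B + 1) else
      mean(sim_x2 >= x2 - 1e-12)
  })
  list(statistic = x2, df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
       p_simulated = p_sim, B = as.integer(B), seed = as.integer(seed))
}
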