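# Probabilistic de novo calling: a simplified accuMUlate-style model.
# Per site, the posterior probability that exactly one line carries a
# heterozygous de novo mutation given all lines' read counts, under a
# biallelic binomial two-hypothesis model. This is a deliberate reduction
# of the published Dirichlet-multinomial/pedigree model to a desk-scale,
# testable core; see the methods vignette.

#' Parameters of the probabilistic single-mutant-line model
#'
#' @param theta Prior probability of a de novo event per site per line
#'   (`0 < theta << 1`).
#' @param seq_error Per-base sequencing error rate epsilon in `[0, 0.5)`.
#' @param posterior_cutoff Acceptance threshold on the per-line posterior.
#' @return A `prob_model_params` list.
#' @export
prob_model_params <- function(theta = 1e-7, seq_error = 1e-3,
                              posterior_cutoff = 0.9) {
  stopifnot(theta > 0, theta < 0.01, seq_error >= 0, seq_error < 0.5,
            posterior_cutoff > 0, posterior_cutoff < 1)
  structure(list(theta = theta, seq_error = seq_error,
                 posterior_cutoff = posterior_cutoff),
            class = "prob_model_params")
}

#' Binomial genotype likelihood of an observed alternate read count
#'
#' Under hom-ref, alternate reads arise with probability epsilon; under
#' het, 0.5; under hom-alt, `1 - epsilon`. Zero depth gives likelihood 1
#' for every genotype.
#'
#' @param depth Total reads at the site (vectorized).
#' @param alt_count Reads supporting the alternate allele.
#' @param genotype One of `"hom_ref"`, `"het"`, `"hom_alt"`.
#' @param epsilon Per-base error rate.
#' @param log Return log-likelihood?
#' @return Numeric (log-)likelihood.
#' @examples
#' genotype_likelihood(10, 5, "het", 1e-3)
#' @export
genotype_likelihood <- function(depth, alt_count, genotype, epsilon = 1e-3,
                                log = FALSE) {
  stopifnot(all(depth >= 0), all(alt_count >= 0), all(alt_count <= depth))
  p <- switch(genotype,
              hom_ref = epsilon,
              het = 0.5,
              hom_alt = 1 - epsilon,
              ma_error("unknown genotype", "mutaccum_call_error"))
  stats::dbinom(alt_count, depth, p, log = log)
}

#' Row sums of a matrix excluding one column per cell, -Inf-safe
#' @noRd
rowsum_excl <- function(mat) {
  rs <- rowSums(mat)
  out <- rs - mat
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    for (k in seq_len(nrow(bad))) {
      i <- bad[k, 1]
      out[i, bad[k, 2]] <- sum(mat[i, -bad[k, 2]])
    }
  }
  out
}

#' Posterior probability that exactly one line is a de novo heterozygote
#'
#' At one site, with per-line depths and alternate read counts, computes
#' for each line i the posterior of the hypothesis "line i het, all other
#' lines hom-ref", with prior weight `theta` per line, against the null
#' "all lines hom-ref" with prior weight `1 - n_lines * theta`. All
#' arithmetic is in log space (no underflow for depths up to 1e4).
#'
#' @param depth Integer vector of per-line depths (>= 2 lines).
#' @param alt_count Integer vector of per-line alternate read counts.
#' @param params A [prob_model_params()].
#' @return List with `posterior` (per line), `null`, and `unscorable`
#'   (TRUE when every hypothesis has zero likelihood).
#' @export
site_mutation_posterior <- function(depth, alt_count,
                                    params = prob_model_params()) {
  L <- length(depth)
  if (L < 2L) {
    ma_error("need >= 2 lines", "mutaccum_call_error")
  }
  eps <- params$seq_error
  ldhom <- stats::dbinom(alt_count, depth, eps, log = TRUE)
  ldhet <- stats::dbinom(alt_count, depth, 0.5, log = TRUE)
  s_excl <- rowsum_excl(matrix(ldhom, nrow = 1L))[1L, ]
  lw <- log(params$theta) + ldhet + s_excl
  lnull <- log1p(-L * params$theta) + sum(ldhom)
  all_lw <- c(lw, lnull)
  if (all(all_lw == -Inf)) {
    return(list(posterior = rep(NA_real_, L), null = NA_real_,
                unscorable = TRUE))
  }
  mx <- max(all_lw)
  w <- exp(all_lw - mx)
  w <- w / sum(w)
  list(posterior = w[seq_len(L)], null = w[L + 1L], unscorable = FALSE)
}

#' Probabilistic candidate calling over a simulated regime
#'
#' Scores every site carrying at least one non-reference read (other sites
#' have posterior ~ `n_lines * theta` and cannot reach any sensible
#' cutoff): per site the focal alternate allele is the non-reference base
#' with the highest pooled read count, and candidates are the (line, site)
#' pairs whose single-mutant-line posterior reaches
#' `params$posterior_cutoff` at callable-mask sites.
#'
#' @param experiment An `ma_experiment` with evidence.
#' @param regime Regime name.
#' @param params A [prob_model_params()].
#' @param use_mask Restrict to the regime's callable mask?
#' @return An `ma_candidates` table with the per-candidate `posterior`.
#' @export
call_probabilistic <- function(experiment, regime,
                               params = prob_model_params(),
                               use_mask = TRUE) {
  ev <- experiment$evidence[[regime]]
  if (is.null(ev)) {
    ma_error(paste("no evidence for regime", regime), "mutaccum_call_error")
  }
  sites <- sort(unique(ev$alt$pos))
  if (use_mask && length(sites)) {
    m <- experiment$masks[[regime]]
    keep <- IRanges::overlapsAny(IRanges::IRanges(sites, sites), m)
    sites <- sites[keep]
  }
  if (!length(sites)) {
    return(new_candidates(character(), character(), character(), integer(),
                          character(), character(), character()))
  }
  L <- length(ev$lines)
  n <- length(sites)
  depth <- ev$depth[sites, , drop = FALSE]

  sub <- ev$alt[pos %in% sites]
  pooled <- sub[, .(count = sum(count)), by = .(pos, base)]
  data.table::setorder(pooled, pos, -count, base)
  top <- pooled[!duplicated(pos)]
  site_alt <- top$base[match(sites, top$pos)]

  alt_count <- matrix(0L, n, L)
  foc <- sub[which(base == site_alt[match(pos, sites)])]
  if (nrow(foc)) {
    focal <- foc[, .(cnt = sum(count)), by = .(pos, line)]
    alt_count[cbind(match(focal$pos, sites), focal$line)] <- focal$cnt
  }

  eps <- params$seq_error
  ldhom <- stats::dbinom(alt_count, depth, eps, log = TRUE)
  ldhet <- stats::dbinom(alt_count, depth, 0.5, log = TRUE)
  s_excl <- rowsum_excl(ldhom)
  lw <- log(params$theta) + ldhet + s_excl
  lnull <- log1p(-L * params$theta) + rowSums(ldhom)
  # normalize per site in log space
  mx <- pmax(apply(lw, 1L, max), lnull)
  denom <- rowSums(exp(lw - mx)) + exp(lnull - mx)
  post <- exp(lw - mx) / denom

  hits <- which(post >= params$posterior_cutoff, arr.ind = TRUE)
  idx <- hits[, 1L]
  new_candidates(regime = rep(regime, length(idx)),
                 line = ev$lines[hits[, 2L]],
                 chrom = rep("chr1", length(idx)),
                 pos = sites[idx],
                 ref = BASES[experiment$ref_code[sites[idx]]],
                 alt = BASES[site_alt[idx]],
                 caller = rep("probabilistic", length(idx)),
                 posterior = post[hits])
}

#' Merge consensus and probabilistic candidate cohorts
#'
#' `shared` keeps the intersection on (line, position, alt);
#' `union` keeps every candidate, with `caller = "both"` on the overlap.
#' The default is `shared`.
#'
#' @param consensus,probabilistic `ma_candidates` tables for the same
#'   regime(s).
#' @param mode `"shared"` or `"union"`.
#' @return An `ma_candidates` table.
#' @export
merge_cohorts <- function(consensus, probabilistic,
                          mode = c("shared", "union")) {
  mode <- match.arg(mode)
  a <- data.table::as.data.table(consensus)
  b <- data.table::as.data.table(probabilistic)
  keycols <- c("regime", "line", "chrom", "pos", "alt")
  ka <- do.call(paste, a[, keycols, with = FALSE])
  kb <- do.call(paste, b[, keycols, with = FALSE])
  if (mode == "shared") {
    out <- a[ka %in% kb]
    out[, caller := "both"]
    out[, posterior := b$posterior[match(ka[ka %in% kb], kb)]]
  } else {
    both <- ka %in% kb
    a2 <- data.table::copy(a)
    a2[both, caller := "both"]
    a2[both, posterior := b$posterior[match(ka[both], kb)]]
    out <- data.table::rbindlist(list(a2, b[!kb %in% ka]))
    data.table::setorder(out, regime, pos, line)
  }
  structure(out, class = c("ma_candidates", class(data.table::data.table())))
}
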