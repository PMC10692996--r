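# Consensus (unique-heterozygote) de novo mutation calling and the
# automated curation filters that stand in for manual alignment inspection.

#' Genotyping thresholds
#'
#' @param min_depth Minimum read depth for any call (below: no-call).
#' @param het_lo,het_hi Alternate-allele fraction window for a heterozygous
#'   call (`0 < het_lo < 0.5 < het_hi < 1`).
#' @param hom_max Maximum non-reference fraction for a homozygous-reference
#'   call (and symmetric for hom-alt).
#' @return A `genotype_thresholds` list.
#' @export
genotype_thresholds <- function(min_depth = 10, het_lo = 0.3, het_hi = 0.7,
                                hom_max = 0.1) {
  stopifnot(het_lo > 0, het_lo < 0.5, het_hi > 0.5, het_hi < 1,
            hom_max >= 0, hom_max < het_lo, min_depth >= 1)
  structure(list(min_depth = min_depth, het_lo = het_lo, het_hi = het_hi,
                 hom_max = hom_max), class = "genotype_thresholds")
}

#' Genotype a single site of a single line from allele depths
#'
#' Hard-threshold genotyping: no-call below `min_depth`; homozygous
#' reference when the total non-reference fraction is at most `hom_max`;
#' heterozygous when the top non-reference allele's fraction lies in
#' `[het_lo, het_hi]`; homozygous alternate when it is at least
#' `1 - hom_max`; otherwise no-call.
#'
#' @param allele_depths Length-4 numeric vector of read counts per base in
#'   A, C, G, T order.
#' @param ref Reference base at the site.
#' @param thresholds A [genotype_thresholds()].
#' @return One of `"hom_ref"`, `"het"`, `"hom_alt"`, `"no_call"`, with the
#'   top alternate base as attribute `alt` (NA when there are no
#'   non-reference reads).
#' @examples
#' genotype_from_evidence(c(15, 0, 15, 0), "A", genotype_thresholds())
#' @export
genotype_from_evidence <- function(allele_depths, ref,
                                   thresholds = genotype_thresholds()) {
  stopifnot(length(allele_depths) == 4L, all(allele_depths >= 0))
  r <- base_to_code(ref)
  depth <- sum(allele_depths)
  nonref <- allele_depths[-r]
  alt_idx <- setdiff(1:4, r)[which.max(nonref)]
  alt <- if (sum(nonref) > 0) BASES[alt_idx] else NA_character_
  g <- if (depth < thresholds$min_depth) {
    "no_call"
  } else if (sum(nonref) / depth <= thresholds$hom_max) {
    "hom_ref"
  } else {
    af <- max(nonref) / depth
    if (af >= thresholds$het_lo && af <= thresholds$het_hi) "het"
    else if (af >= 1 - thresholds$hom_max) "hom_alt"
    else "no_call"
  }
  structure(g, alt = alt)
}

#' Genotype all lines of one regime at selected sites
#'
#' Vectorized equivalent of [genotype_from_evidence()] over a simulated
#' regime's evidence, restricted to `sites` (default: all sites carrying at
#' least one non-reference read, plus nothing else — sites without
#' non-reference reads can only be hom-ref or no-call and are handled by
#' depth alone where needed).
#'
#' @param experiment An `ma_experiment` with evidence.
#' @param regime Regime name.
#' @param thresholds A [genotype_thresholds()].
#' @param sites Optional integer vector of 1-based positions.
#' @return A [genotype_matrix()] with AD/DP filled in; the per-site `alt`
#'   is the non-reference allele with the highest total read count across
#'   lines (NA if none).
#' @export
genotype_matrix_from_evidence <- function(experiment, regime,
                                          thresholds = genotype_thresholds(),
                                          sites = NULL) {
  ev <- experiment$evidence[[regime]]
  if (is.null(ev)) {
    ma_error(paste("no evidence for regime", regime), "mutaccum_call_error")
  }
  alt_dt <- ev$alt
  if (is.null(sites)) sites <- sort(unique(alt_dt$pos))
  sites <- as.integer(sites)
  L <- length(ev$lines)
  n <- length(sites)
  depth <- ev$depth[sites, , drop = FALSE]
  ref_code <- experiment$ref_code[sites]

  # per-site focal alt allele: top pooled non-ref base
  sub <- alt_dt[pos %in% sites]
  site_alt <- rep(NA_integer_, n)
  if (nrow(sub)) {
    pooled <- sub[, .(count = sum(count)), by = .(pos, base)]
    data.table::setorder(pooled, pos, -count, base)
    top <- pooled[!duplicated(pos)]
    site_alt[match(top$pos, sites)] <- top$base
  }

  # per-cell totals: total non-ref, top non-ref, count of focal alt
  nonref_tot <- matrix(0L, n, L)
  nonref_top <- matrix(0L, n, L)
  alt_count <- matrix(0L, n, L)
  if (nrow(sub)) {
    cell <- sub[, .(tot = sum(count), top = max(count)), by = .(pos, line)]
    ij <- cbind(match(cell$pos, sites), cell$line)
    nonref_tot[ij] <- cell$tot
    nonref_top[ij] <- cell$top
    foc <- sub[which(base == site_alt[match(pos, sites)])]
    if (nrow(foc)) {
      focal <- foc[, .(cnt = sum(count)), by = .(pos, line)]
      alt_count[cbind(match(focal$pos, sites), focal$line)] <- focal$cnt
    }
  }

  gt <- matrix(NA_integer_, n, L)
  callable <- depth >= thresholds$min_depth
  homref <- callable & (nonref_tot <= thresholds$hom_max * depth)
  af <- ifelse(depth > 0, nonref_top / depth, 0)
  het <- callable & !homref & af >= thresholds$het_lo &
    af <= thresholds$het_hi
  homalt <- callable & !homref & !het & af >= 1 - thresholds$hom_max
  gt[homref] <- GT_HOMREF
  gt[het] <- GT_HET
  gt[homalt] <- GT_HOMALT

  genotype_matrix(chrom = rep("chr1", n), pos = sites,
                  ref = BASES[ref_code],
                  alt = ifelse(is.na(site_alt), NA_character_,
                               BASES[site_alt]),
                  gt = gt, ad_ref = depth - nonref_tot, ad_alt = alt_count,
                  dp = depth, samples = ev$lines)
}

#' Count callable sites of a genotype matrix
#'
#' A site is callable when every line has a non-missing genotype.
#'
#' @param gm A [genotype_matrix()].
#' @return Integer count.
#' @export
callable_sites <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$samples) == 0L) {
    ma_error("empty regime: no lines", "mutaccum_call_error")
  }
  sum(rowSums(is.na(gm$gt)) == 0L)
}

#' Callable-site denominator for one regime of a simulated experiment
#'
#' Counts genome positions inside the regime's callable mask at which every
#' line is genotyped (depth at least `min_depth` and an unambiguous call).
#'
#' @param experiment An `ma_experiment` with evidence.
#' @param regime Regime name.
#' @param thresholds A [genotype_thresholds()].
#' @param use_mask Intersect with the regime's callable mask?
#' @return Integer count of callable sites.
#' @export
regime_callable_sites <- function(experiment, regime,
                                  thresholds = genotype_thresholds(),
                                  use_mask = TRUE) {
  ev <- experiment$evidence[[regime]]
  if (is.null(ev)) {
    ma_error(paste("no evidence for regime", regime), "mutaccum_call_error")
  }
  ok <- rowSums(ev$depth >= thresholds$min_depth) == ncol(ev$depth)
  # ambiguous cells (no-call despite depth) only occur at sites with
  # non-ref reads; re-genotype those exactly
  var_sites <- sort(unique(ev$alt$pos))
  if (length(var_sites)) {
    gm <- genotype_matrix_from_evidence(experiment, regime, thresholds,
                                        sites = var_sites)
    ok[var_sites] <- ok[var_sites] & rowSums(is.na(gm$gt)) == 0L
  }
  if (use_mask) {
    inmask <- logical(length(ok))
    m <- experiment$masks[[regime]]
    for (i in seq_along(m)) {
      inmask[IRanges::start(m)[i]:IRanges::end(m)[i]] <- TRUE
    }
    ok <- ok & inmask
  }
  sum(ok)
}

#' Consensus candidate mutations: unique heterozygote rule
#'
#' A site yields a candidate for line i iff line i is heterozygous and every
#' other line of the regime is homozygous reference at the site, and the
#' site falls in the callable mask (when supplied). Sites where any other
#' line is het, hom-alt or no-call are excluded entirely (shared variation
#' or insufficient evidence, not de novo).
#'
#' @param gm A [genotype_matrix()] for the regime's lines.
#' @param mask Optional [callable_mask()] (or `IRanges`).
#' @param regime Regime label recorded on the candidates.
#' @return A `candidate` data.table: regime, line, chrom, pos, ref, alt,
#'   caller, status (`"candidate"`), reason (NA).
#' @export
consensus_candidates <- function(gm, mask = NULL, regime = "regime1") {
  stopifnot(inherits(gm, "genotype_matrix"))
  n_het <- rowSums(gm$gt == GT_HET, na.rm = TRUE)
  n_homref <- rowSums(gm$gt == GT_HOMREF, na.rm = TRUE)
  L <- length(gm$samples)
  is_cand <- n_het == 1L & n_homref == L - 1L
  if (!is.null(mask)) {
    if (inherits(mask, "IRanges")) mask <- callable_mask(mask)
    pos_ok <- IRanges::overlapsAny(
      IRanges::IRanges(gm$pos, gm$pos),
      IRanges::ranges(mask$ranges))
    is_cand <- is_cand & pos_ok
  }
  idx <- which(is_cand)
  line_idx <- if (length(idx)) {
    apply(gm$gt[idx, , drop = FALSE] == GT_HET, 1L, which.max)
  } else {
    integer()
  }
  new_candidates(regime = rep(regime, length(idx)),
                 line = gm$samples[line_idx],
                 chrom = gm$chrom[idx], pos = gm$pos[idx],
                 ref = gm$ref[idx], alt = gm$alt[idx],
                 caller = rep("consensus", length(idx)))
}

#' @noRd
new_candidates <- function(regime, line, chrom, pos, ref, alt, caller,
                           posterior = rep(NA_real_, length(pos))) {
  dt <- data.table::data.table(
    regime = as.character(regime), line = as.character(line),
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    caller = as.character(caller), posterior = as.numeric(posterior),
    status = rep("candidate", length(pos)),
    reason = rep(NA_character_, length(pos)))
  data.table::setorder(dt, regime, pos, line)
  structure(dt, class = c("ma_candidates", class(dt)))
}

# ---- curation filters -----------------------------------------------------

#' Curation filter configuration
#'
#' Automated stand-ins for manual alignment inspection of candidate de novo
#' SNPs. All thresholds are exposed; defaults follow common MA-line
#' curation practice.
#'
#' @param min_depth Minimum focal-line depth at the candidate site.
#' @param max_depth_fold Maximum focal-line depth as a multiple of that
#'   line's mean depth (collapsed repeats / CNV proxy).
#' @param allele_balance Heterozygous allele-balance acceptance window
#'   `c(lo, hi)` with `0 < lo < 0.5 < hi < 1`.
#' @param cluster_window Two candidates within this many bp in the same
#'   line are both rejected (clustered artifacts).
#' @param min_other_line_depth Minimum depth required in every non-focal
#'   line.
#' @param multiallelic_min_reads A second distinct non-reference allele with
#'   at least this many reads in the focal line rejects the site.
#' @param genotype A [genotype_thresholds()] (carried along for pipelines).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 10, max_depth_fold = 3,
                          allele_balance = c(0.3, 0.7),
                          cluster_window = 100,
                          min_other_line_depth = 5,
                          multiallelic_min_reads = 2,
                          genotype = genotype_thresholds()) {
  stopifnot(length(allele_balance) == 2L,
            allele_balance[1] > 0, allele_balance[1] < 0.5,
            allele_balance[2] > 0.5, allele_balance[2] < 1,
            cluster_window > 0)
  structure(list(min_depth = min_depth, max_depth_fold = max_depth_fold,
                 allele_balance = allele_balance,
                 cluster_window = cluster_window,
                 min_other_line_depth = min_other_line_depth,
                 multiallelic_min_reads = multiallelic_min_reads,
                 genotype = genotype),
            class = "filter_config")
}

#' Apply curation filters to candidate mutations
#'
#' Each candidate is labelled `accepted` or `rejected` with exactly one
#' primary reason, the first failing check in the order: `multiallelic`,
#' `low_depth`, `high_depth`, `allele_balance`, `other_line_depth`,
#' `cluster`. The cluster check runs last, among candidates that survived
#' the per-candidate checks, and rejects *both* members of any same-line
#' pair closer than `cluster_window` bp.
#'
#' @param candidates An `ma_candidates` table (one regime).
#' @param evidence The regime's evidence (element of
#'   `ma_experiment$evidence`): `depth` matrix, sparse `alt` table, `lines`.
#' @param config A [filter_config()].
#' @return The candidates with `status` and `reason` filled in.
#' @export
apply_filters <- function(candidates, evidence, config = filter_config()) {
  cand <- data.table::copy(candidates)
  if (nrow(cand) == 0L) return(cand)
  line_idx <- match(cand$line, evidence$lines)
  if (anyNA(line_idx)) {
    ma_error("candidate line not present in evidence", "mutaccum_call_error")
  }
  mean_depth <- colMeans(evidence$depth)
  depth <- evidence$depth[cbind(cand$pos, line_idx)]

  alt_dt <- evidence$alt
  cell <- alt_dt[paste(pos, line) %in% paste(cand$pos, line_idx)]
  key <- paste(cand$pos, line_idx)
  alt_code <- base_to_code(cand$alt)
  alt_reads <- integer(nrow(cand))
  second_reads <- integer(nrow(cand))
  if (nrow(cell)) {
    ck <- paste(cell$pos, cell$line)
    is_focal <- cell$base == alt_code[match(ck, key)]
    foc <- cell[which(is_focal)]
    if (nrow(foc)) {
      focal <- foc[, .(cnt = sum(count)), by = .(pos, line)]
      alt_reads[match(paste(focal$pos, focal$line), key)] <- focal$cnt
    }
    oth <- cell[which(!is_focal)]
    if (nrow(oth)) {
      other <- oth[, .(mx = max(count)), by = .(pos, line)]
      second_reads[match(paste(other$pos, other$line), key)] <- other$mx
    }
  }
  ab <- ifelse(depth > 0, alt_reads / depth, 0)
  min_other <- vapply(seq_len(nrow(cand)), function(i) {
    min(evidence$depth[cand$pos[i], -line_idx[i]])
  }, numeric(1))

  reason_vec <- rep(NA_character_, nrow(cand))
  fail <- function(sel, tag) {
    sel <- sel & is.na(reason_vec)
    reason_vec[sel] <<- tag
  }
  fail(second_reads >= config$multiallelic_min_reads, "multiallelic")
  fail(depth < config$min_depth, "low_depth")
  fail(depth > config$max_depth_fold * mean_depth[line_idx], "high_depth")
  fail(ab < config$allele_balance[1] | ab > config$allele_balance[2],
       "allele_balance")
  fail(min_other < config$min_other_line_depth, "other_line_depth")

  # cluster check among survivors
  ok <- which(is.na(reason_vec))
  if (length(ok) > 1L) {
    dt <- data.table::data.table(i = ok, line = cand$line[ok],
                                 pos = cand$pos[ok])
    data.table::setorder(dt, line, pos)
    near <- dt[, {
      d_prev <- c(Inf, diff(pos))
      d_next <- c(diff(pos), Inf)
      list(i = i, hit = d_prev <= config$cluster_window |
             d_next <= config$cluster_window)
    }, by = line]
    reason_vec[near$i[near$hit]] <- "cluster"
  }

  cand[, `:=`(status = ifelse(is.na(reason_vec), "accepted", "rejected"),
              reason = reason_vec)]
  cand
}

#' Acceptance-rate table by regime
#'
#' Counts candidates and accepted calls per regime and tests homogeneity of
#' acceptance rates across regimes with a chi-squared test
#' (accepted/rejected x regime), Monte-Carlo p value.
#'
#' @param candidates Filtered candidates (possibly several regimes).
#' @param B,seed Monte-Carlo settings for [chisq_contingency()].
#' @return List with `table` (per-regime counts and rates) and `test`.
#' @export
acceptance_by_regime <- function(candidates, B = 10000, seed = 1) {
  tab <- data.table::as.data.table(candidates)[, .(
    n_candidates = .N,
    n_accepted = sum(status == "accepted")), by = regime]
  tab[, acceptance_rate := n_accepted / n_candidates]
  test <- NULL
  m <- as.matrix(tab[, .(n_accepted, n_candidates - n_accepted)])
  if (nrow(tab) >= 2L && all(rowSums(m) > 0) && all(colSums(m) > 0)) {
    test <- chisq_contingency(m, B = B, seed = seed)
  }
  list(table = tab[], test = test)
}
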