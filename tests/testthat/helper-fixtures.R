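# Shared fixtures and independent oracles, built in code.

# small three-regime config with an elevated rate so events exist at toy
# genome sizes
small_config <- function(seed, genome = 5e4, mu = 2e-6, ...) {
  sim_config(genome_length = genome, mu_per_regime = mu, seed = seed, ...)
}

# hand-built genotype matrix (codes 0/1/2/NA)
make_gm <- function(gt, pos = seq_len(nrow(gt)), ref = NULL, alt = NULL,
                    ...) {
  gt <- as.matrix(gt)
  if (is.null(colnames(gt))) colnames(gt) <- paste0("L", seq_len(ncol(gt)))
  if (is.null(ref)) ref <- rep("A", nrow(gt))
  if (is.null(alt)) alt <- rep("G", nrow(gt))
  genotype_matrix(chrom = rep("chr1", nrow(gt)), pos = pos, ref = ref,
                  alt = alt, gt = gt, ...)
}

# brute-force genotype oracle: re-states the thresholding rule
# independently of the package's vectorized code path
oracle_genotype <- function(ad, ref_code, th) {
  depth <- sum(ad)
  if (depth < th$min_depth) return("no_call")
  nonref <- ad[-ref_code]
  if (sum(nonref) / depth <= th$hom_max) return("hom_ref")
  af <- max(nonref) / depth
  if (af >= th$het_lo && af <= th$het_hi) return("het")
  if (af >= 1 - th$hom_max) return("hom_alt")
  "no_call"
}

# brute-force per-site consensus scan
oracle_consensus <- function(gt, mask_pos = NULL, pos = seq_len(nrow(gt))) {
  hits <- list()
  for (s in seq_len(nrow(gt))) {
    if (!is.null(mask_pos) && !(pos[s] %in% mask_pos)) next
    g <- gt[s, ]
    if (any(is.na(g))) next
    if (sum(g == 1) == 1 && sum(g == 0) == length(g) - 1) {
      hits[[length(hits) + 1]] <- c(site = s, line = which(g == 1))
    }
  }
  if (!length(hits)) {
    return(data.frame(site = integer(), line = integer()))
  }
  as.data.frame(do.call(rbind, hits))
}

# closed-form binomial LR oracle on per-regime totals
oracle_binomial_lr <- function(m, n) {
  ll <- function(mm, nn, p) {
    out <- 0
    if (mm > 0) out <- out + mm * log(p)
    if (nn - mm > 0) out <- out + (nn - mm) * log(1 - p)
    out
  }
  p_pool <- sum(m) / sum(n)
  l1 <- sum(mapply(function(mi, ni) ll(mi, ni, mi / ni), m, n))
  l0 <- sum(mapply(function(mi, ni) ll(mi, ni, p_pool), m, n))
  2 * (l1 - l0)
}

# closed-form Poisson LR oracle on per-regime totals with exposures
oracle_poisson_lr <- function(m, expo) {
  lam_pool <- sum(m) / sum(expo)
  l1 <- sum(ifelse(m > 0, m * log(m / expo), 0) - m)
  l0 <- sum(ifelse(m > 0, m * log(lam_pool), 0) - lam_pool * expo)
  2 * (l1 - l0)
}

# independent effect oracle: classify one position by whole-CDS
# retranslation and plain interval logic
oracle_effect <- function(p, alt, ann, genome) {
  W <- ann$W
  tx <- ann$transcripts
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  translate_cds <- function(g, ex) {
    ex <- ex[order(ex$start), ]
    cds <- paste(mapply(function(s, e) substr(g, s, e), ex$start, ex$end),
                 collapse = "")
    if (ex$strand[1] == "-") {
      cds <- paste(rev(comp[strsplit(cds, "")[[1]]]), collapse = "")
    }
    n3 <- (nchar(cds) %/% 3) * 3
    paste(sapply(seq(1, n3, by = 3), function(i) {
      Biostrings::GENETIC_CODE[[substr(cds, i, i + 2)]]
    }), collapse = "")
  }
  terms <- character()
  mut <- genome
  substr(mut, p, p) <- alt
  for (j in seq_len(nrow(tx))) {
    t1 <- tx[j, ]
    ex <- as.data.frame(ann$exons[ann$exons$transcript_id ==
                                    t1$transcript_id, ])
    strand <- t1$strand
    in_exon <- any(p >= ex$start & p <= ex$end)
    if (in_exon) {
      p0 <- translate_cds(genome, ex)
      p1 <- translate_cds(mut, ex)
      stopifnot(nchar(p0) == nchar(p1))
      d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])
      terms <- c(terms,
                 if (!length(d)) "synonymous_variant"
                 else if (strsplit(p1, "")[[1]][d[1]] == "*") "stop_gained"
                 else "missense_variant")
    } else if (p >= t1$start && p <= t1$end) {
      last <- max(ex$exon_rank)
      donors <- unlist(lapply(which(ex$exon_rank < last), function(k) {
        if (strand == "+") ex$end[k] + 1:2 else ex$start[k] - 2:1
      }))
      terms <- c(terms, if (p %in% donors) "splice_donor_variant" else
        "intron_variant")
    } else {
      us <- if (strand == "+") (t1$start - W):(t1$start - 1) else
        (t1$end + 1):(t1$end + W)
      ds <- if (strand == "+") (t1$end + 1):(t1$end + W) else
        (t1$start - W):(t1$start - 1)
      if (p %in% us) terms <- c(terms, "upstream_gene_variant")
      else if (p %in% ds) terms <- c(terms, "downstream_gene_variant")
    }
  }
  if (!length(terms)) return("intergenic_variant")
  terms[which.min(match(terms, CONSEQUENCE_TERMS))]
}
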