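# Minimal variant-effect predictor over a toy annotation, plus the
# per-regime consequence / impact-class comparisons.

#' Consequence terms, most to least severe
#' @export
CONSEQUENCE_TERMS <- c("splice_donor_variant", "stop_gained",
                       "missense_variant", "synonymous_variant",
                       "intron_variant", "upstream_gene_variant",
                       "downstream_gene_variant", "intergenic_variant")

#' Impact class of a consequence term
#'
#' Fixed mapping: HIGH = stop_gained + splice_donor; MODERATE = missense;
#' LOW = synonymous; MODIFIER = upstream + downstream + intron +
#' intergenic.
#'
#' @param consequence Character vector of consequence terms.
#' @return Character vector of `HIGH`, `MODERATE`, `LOW`, `MODIFIER`.
#' @examples
#' impact_of("stop_gained")
#' @export
impact_of <- function(consequence) {
  map <- c(splice_donor_variant = "HIGH", stop_gained = "HIGH",
           missense_variant = "MODERATE", synonymous_variant = "LOW",
           intron_variant = "MODIFIER", upstream_gene_variant = "MODIFIER",
           downstream_gene_variant = "MODIFIER",
           intergenic_variant = "MODIFIER")
  out <- unname(map[consequence])
  if (anyNA(out)) {
    ma_error(paste("unknown consequence term:",
                   paste(consequence[is.na(out)], collapse = ", ")),
             "mutaccum_effect_error")
  }
  out
}

#' @noRd
complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Spliced CDS of one transcript in transcription order
#' @noRd
transcript_cds <- function(exons_tx, genome) {
  # splice in genomic order; reverse-complement the whole spliced sequence
  # for minus-strand transcripts (equivalent to per-exon revcomp in
  # transcription order)
  ord <- order(exons_tx$start)
  segs <- vapply(ord, function(i) {
    substr(genome, exons_tx$start[i], exons_tx$end[i])
  }, "")
  cds <- paste(segs, collapse = "")
  if (exons_tx$strand[1] == "-") {
    cds <- paste(rev(complement_base(strsplit(cds, "")[[1]])),
                 collapse = "")
  }
  cds
}

#' Consequence of a SNP relative to one transcript, or NA if unrelated
#' @noRd
effect_in_transcript <- function(pos, alt, tx, exons_tx, genome, W) {
  strand <- tx$strand
  if (pos >= tx$start && pos <= tx$end) {
    ex_hit <- which(pos >= exons_tx$start & pos <= exons_tx$end)
    if (length(ex_hit) == 1L) {
      # coding: locate the codon in the spliced CDS
      ord <- order(exons_tx$exon_rank)
      cum <- cumsum(c(0L, exons_tx$end[ord] - exons_tx$start[ord] + 1L))
      k <- match(ex_hit, ord)
      off <- if (strand == "+") pos - exons_tx$start[ex_hit] else
        exons_tx$end[ex_hit] - pos
      cds_pos <- cum[k] + off + 1L
      cds <- transcript_cds(exons_tx, genome)
      alt_t <- if (strand == "+") alt else unname(complement_base(alt))
      ci <- (cds_pos - 1L) %/% 3L
      wi <- (cds_pos - 1L) %% 3L
      codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
      if (nchar(codon) < 3L) return("synonymous_variant")  # trailing partial
      new_codon <- codon
      substr(new_codon, wi + 1L, wi + 1L) <- alt_t
      aa_old <- Biostrings::GENETIC_CODE[[codon]]
      aa_new <- Biostrings::GENETIC_CODE[[new_codon]]
      if (identical(aa_old, aa_new)) return("synonymous_variant")
      if (aa_new == "*") return("stop_gained")
      return("missense_variant")  # incl. stop/start loss, mapped to nearest
    }
    # intronic: splice donor = first 2 intronic bases past an exon in
    # transcription direction (not past the terminal exon)
    last_rank <- max(exons_tx$exon_rank)
    donor <- exons_tx$exon_rank < last_rank
    if (strand == "+") {
      hit <- any(donor & pos >= exons_tx$end + 1L & pos <= exons_tx$end + 2L)
    } else {
      hit <- any(donor & pos >= exons_tx$start - 2L &
                   pos <= exons_tx$start - 1L)
    }
    return(if (hit) "splice_donor_variant" else "intron_variant")
  }
  up <- if (strand == "+") {
    pos >= tx$start - W && pos < tx$start
  } else {
    pos > tx$end && pos <= tx$end + W
  }
  if (up) return("upstream_gene_variant")
  down <- if (strand == "+") {
    pos > tx$end && pos <= tx$end + W
  } else {
    pos >= tx$start - W && pos < tx$start
  }
  if (down) return("downstream_gene_variant")
  NA_character_
}

#' Predict the consequence of a biallelic SNP on a toy annotation
#'
#' One consequence per variant: when a site relates to several transcripts
#' or features, the most severe term wins, in the order splice_donor >
#' stop_gained > missense > synonymous > intron > upstream > downstream >
#' intergenic. Splice donors are the first 2 intronic bases after an exon
#' on the coding strand; coding consequences come from codon translation
#' under the standard genetic code; upstream/downstream extend `W` bp from
#' the transcript ends, respecting strand.
#'
#' @param pos 1-based position(s); vectorized.
#' @param ref,alt Reference and alternate bases.
#' @param annotation A `toy_annotation`.
#' @param genome Genome as a single character string (see
#'   [reference_string()]).
#' @param W Window for upstream/downstream; defaults to the annotation's.
#' @return Character vector of consequence terms.
#' @export
predict_effect <- function(pos, ref, alt, annotation, genome,
                           W = annotation$W) {
  stopifnot(inherits(annotation, "toy_annotation"))
  G <- nchar(genome)
  if (any(pos < 1L | pos > G)) {
    ma_error("SNP position outside the sequence", "mutaccum_effect_error")
  }
  ref_obs <- substring(genome, pos, pos)
  if (any(ref_obs != ref)) {
    ma_error("ref allele does not match the genome", "mutaccum_effect_error")
  }
  tx <- annotation$transcripts
  ex <- annotation$exons
  sev <- function(term) match(term, CONSEQUENCE_TERMS)
  vapply(seq_along(pos), function(i) {
    # transcripts whose influence zone covers the position
    near <- which(pos[i] >= tx$start - W & pos[i] <= tx$end + W)
    terms <- vapply(near, function(j) {
      effect_in_transcript(pos[i], alt[i], tx[j],
                           ex[ex$transcript_id == tx$transcript_id[j]],
                           genome, W)
    }, "")
    terms <- terms[!is.na(terms)]
    if (!length(terms)) "intergenic_variant" else
      terms[which.min(sev(terms))]
  }, "")
}

#' Per-regime consequence and impact-class count table
#'
#' @param consequence Character vector of consequence terms.
#' @param regime Parallel regime labels.
#' @param regimes Optional regime column order.
#' @return An `effect_table`: list with `consequence` and `impact` count
#'   matrices (rows = categories, columns = regimes).
#' @export
effect_table <- function(consequence, regime, regimes = unique(regime)) {
  cons <- table(factor(consequence, levels = sort(CONSEQUENCE_TERMS)),
                factor(regime, levels = regimes))
  imp <- table(factor(impact_of(consequence),
                      levels = c("HIGH", "LOW", "MODERATE", "MODIFIER")),
               factor(regime, levels = regimes))
  cons <- unclass(as.matrix(cons))
  imp <- unclass(as.matrix(imp))
  names(dimnames(cons)) <- names(dimnames(imp)) <- NULL
  structure(list(consequence = cons, impact = imp),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat("Consequence counts:\n")
  print(x$consequence)
  cat("Impact counts:\n")
  print(x$impact)
  invisible(x)
}

#' Compare one effect category's counts across regimes
#'
#' Equal-proportions goodness-of-fit chi-square across the regimes for one
#' consequence term or impact class, with Monte-Carlo p value
#' (see [chisq_gof()]).
#'
#' @param tab An [effect_table()].
#' @param category A consequence term or impact class present in `tab`.
#' @param B,seed Monte-Carlo settings.
#' @return As [chisq_gof()].
#' @examples
#' tab <- list(impact = rbind(MODIFIER = c(39, 8, 37)))
#' class(tab) <- "effect_table"
#' compare_effect_counts(tab, "MODIFIER", seed = 1)$statistic  # 21.5
#' @export
compare_effect_counts <- function(tab, category, B = 10000, seed = 1) {
  stopifnot(inherits(tab, "effect_table"))
  src <- if (!is.null(tab$consequence) &&
             category %in% rownames(tab$consequence)) {
    tab$consequence
  } else if (!is.null(tab$impact) && category %in% rownames(tab$impact)) {
    tab$impact
  } else {
    ma_error(paste("unknown effect category:", category),
             "mutaccum_effect_error")
  }
  counts <- src[category, ]
  if (sum(counts) < 1) {
    ma_error("category total must be >= 1", "mutaccum_effect_error")
  }
  chisq_gof(counts, B = B, seed = seed)
}
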