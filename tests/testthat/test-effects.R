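# Variant-effect prediction on the toy annotation and the per-regime
# effect-category comparisons.

# designed single-gene fixture: exon1 starts with codons TGG|CTC|ATG so
# specific substitutions produce known consequences
designed_fixture <- function(strand = "+") {
  ann <- toy_annotation(3000, spacing = 3000, W = 500)
  stopifnot(nrow(ann$transcripts) == 1L)
  if (strand == "-") {
    ann$transcripts$strand <- "-"
    ann$exons$strand <- "-"
    ann$exons$exon_rank <- rev(ann$exons$exon_rank)
  }
  set.seed(101)
  genome <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                  collapse = "")
  tx <- ann$transcripts
  if (strand == "+") {
    substr(genome, tx$start, tx$start + 8L) <- "TGGCTCATG"
  } else {
    # same codons in transcription order, laid on the minus strand: the
    # CDS begins at the genomic *end* of the transcription-first exon, so
    # write the reverse complement of TGGCTCATG there
    ex <- ann$exons[ann$exons$exon_rank == 1L, ]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- paste(comp[rev(strsplit("TGGCTCATG", "")[[1]])], collapse = "")
    substr(genome, ex$end - 8L, ex$end) <- rc
  }
  list(ann = ann, genome = genome)
}

# a non-reference transition allele for a given reference base
alt_of <- function(r) unname(c(A = "G", C = "T", G = "A", T = "C")[r])

test_that("codon-level consequences are classified on the plus strand", {
  fx <- designed_fixture("+")
  tx <- fx$ann$transcripts
  s <- tx$start
  # TGG -> TGA: stop gained at codon 1 position 3
  expect_identical(predict_effect(s + 2L, "G", "A", fx$ann, fx$genome),
                   "stop_gained")
  # CTC -> CTT: synonymous (Leu) at codon 2 position 3
  expect_identical(predict_effect(s + 5L, "C", "T", fx$ann, fx$genome),
                   "synonymous_variant")
  # ATG -> GTG: missense (Met -> Val) at codon 3 position 1
  expect_identical(predict_effect(s + 6L, "A", "G", fx$ann, fx$genome),
                   "missense_variant")
  check_at <- function(p, expected) {
    r <- substr(fx$genome, p, p)
    expect_identical(predict_effect(p, r, alt_of(r), fx$ann, fx$genome),
                     expected, info = paste("pos", p))
  }
  ex1_end <- min(fx$ann$exons$end)
  check_at(ex1_end + 1L, "splice_donor_variant")
  check_at(ex1_end + 2L, "splice_donor_variant")
  check_at(ex1_end + 3L, "intron_variant")
  check_at(s - 100L, "upstream_gene_variant")
  check_at(tx$end + 100L, "downstream_gene_variant")
  check_at(5L, "intergenic_variant")
  expect_error(predict_effect(99999L, "A", "G", fx$ann, fx$genome),
               class = "mutaccum_effect_error")
})

test_that("minus-strand genes classify through the reverse complement", {
  fx <- designed_fixture("-")
  ex3p <- fx$ann$exons[fx$ann$exons$exon_rank == 1L, ]  # 3'-most genomic
  # CDS codon 1 position 3 is genomic ex3p$end - 2 (complemented G>A is C>T)
  p <- ex3p$end - 2L
  expect_identical(predict_effect(p, substr(fx$genome, p, p), "T",
                                  fx$ann, fx$genome),
                   "stop_gained")
  # splice donor: two genomic bases *before* the transcription-first exon
  p2 <- ex3p$start - 1L
  r2 <- substr(fx$genome, p2, p2)
  expect_identical(predict_effect(p2, r2, alt_of(r2), fx$ann, fx$genome),
                   "splice_donor_variant")
  # upstream is genomically downstream of the transcript end
  tx <- fx$ann$transcripts
  p3 <- tx$end + 50L
  r3 <- substr(fx$genome, p3, p3)
  expect_identical(predict_effect(p3, r3, alt_of(r3), fx$ann, fx$genome),
                   "upstream_gene_variant")
})

test_that("exhaustive scan equals the whole-CDS retranslation oracle", {
  ann <- toy_annotation(12000)
  set.seed(202)
  genome <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE,
                         prob = c(0.32, 0.18, 0.18, 0.32)), collapse = "")
  # scan every 3rd position across the two genes and their flanks, plus
  # every position in a window straddling exon/intron boundaries
  focus <- c(seq(400, 7200, by = 3),
             (ann$transcripts$start[1] - 2):(ann$transcripts$start[1] + 130),
             (ann$exons$end[1] - 2):(ann$exons$end[1] + 4))
  focus <- unique(focus)
  comp_alt <- c(A = "G", C = "T", G = "A", T = "C")  # transition alt
  for (p in focus) {
    r <- substr(genome, p, p)
    a <- unname(comp_alt[r])
    expect_identical(predict_effect(p, r, a, ann, genome),
                     oracle_effect(p, a, ann, genome),
                     info = paste("pos", p))
  }
})

test_that("effect calls are invariant under reverse complementation", {
  ann <- toy_annotation(12000)
  set.seed(303)
  genome <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE),
                  collapse = "")
  G <- nchar(genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_genome <- paste(rev(comp[strsplit(genome, "")[[1]]]), collapse = "")
  rc_ann <- ann
  rc_ann$transcripts <- data.table::copy(ann$transcripts)
  rc_ann$exons <- data.table::copy(ann$exons)
  rc_ann$transcripts[, `:=`(start2 = G - end + 1L, end2 = G - start + 1L,
                            strand = ifelse(strand == "+", "-", "+"))]
  rc_ann$transcripts[, `:=`(start = start2, end = end2,
                            start2 = NULL, end2 = NULL)]
  rc_ann$exons[, `:=`(start2 = G - end + 1L, end2 = G - start + 1L,
                      strand = ifelse(strand == "+", "-", "+"))]
  rc_ann$exons[, `:=`(start = start2, end = end2,
                      start2 = NULL, end2 = NULL)]
  pos <- sample(500:11500, 150)
  comp_alt <- c(A = "G", C = "T", G = "A", T = "C")
  for (p in pos) {
    r <- substr(genome, p, p)
    a <- unname(comp_alt[r])
    orig <- predict_effect(p, r, a, ann, genome)
    p2 <- G - p + 1L
    mirrored <- predict_effect(p2, unname(comp[r]), unname(comp[a]),
                               rc_ann, rc_genome)
    expect_identical(mirrored, orig, info = paste("pos", p))
  }
})

test_that("impact mapping and aggregation identity hold", {
  expect_identical(impact_of("stop_gained"), "HIGH")
  expect_identical(impact_of("splice_donor_variant"), "HIGH")
  expect_identical(impact_of("synonymous_variant"), "LOW")
  expect_identical(impact_of("missense_variant"), "MODERATE")
  expect_identical(impact_of("intron_variant"), "MODIFIER")
  expect_error(impact_of("frameshift_variant"),
               class = "mutaccum_effect_error")
  # aggregation identity on random effect tables
  set.seed(6)
  for (i in 1:5) {
    cons <- sample(CONSEQUENCE_TERMS, 60, TRUE)
    reg <- sample(c("T1", "T2", "T5"), 60, TRUE)
    tab <- effect_table(cons, reg, regimes = c("T1", "T2", "T5"))
    agg <- rowsum(tab$consequence, impact_of(rownames(tab$consequence)))
    expect_equal(tab$impact[rownames(agg), ], agg[rownames(agg), ])
    expect_identical(colSums(tab$impact), colSums(tab$consequence))
  }
})

test_that("effect-category comparisons reproduce the printed statistics", {
  tab <- effect_table(character(), character(), regimes = c("T1", "T2", "T5"))
  tab$impact["MODIFIER", ] <- c(39, 8, 37)
  tab$consequence["upstream_gene_variant", ] <- c(19, 3, 16)
  expect_equal(compare_effect_counts(tab, "MODIFIER", B = 10,
                                     seed = 1)$statistic, 21.5)
  expect_equal(round(compare_effect_counts(tab, "upstream_gene_variant",
                                           B = 10, seed = 1)$statistic, 2),
               11.42)
  tab$impact["MODERATE", ] <- c(4, 4, 4)
  expect_identical(compare_effect_counts(tab, "MODERATE", B = 10,
                                         seed = 1)$statistic, 0)
  expect_error(compare_effect_counts(tab, "LOW"),
               class = "mutaccum_effect_error")
  expect_error(compare_effect_counts(tab, "nonsense"),
               class = "mutaccum_effect_error")
})
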