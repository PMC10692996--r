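# Standard-format IO: FASTA, multi-sample VCF (GT/AD/DP), BED callable
# masks, GFF3 toy annotation, TSV tables. Internal coordinates are 1-based
# inclusive everywhere; BED's 0-based half-open convention is converted at
# the file boundary (rtracklayer does this on import/export).

# ---- genotype matrix ------------------------------------------------------

GT_HOMREF <- 0L
GT_HET <- 1L
GT_HOMALT <- 2L

#' Construct a genotype matrix
#'
#' One row per biallelic SNP site, one column per sample. Genotypes are
#' coded 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = no-call.
#'
#' @param chrom,pos,ref,alt Per-site vectors (1-based positions).
#' @param gt Integer matrix (sites x samples) of genotype codes.
#' @param ad_ref,ad_alt,dp Optional matrices of ref/alt allele depths and
#'   total depth.
#' @param samples Sample names; defaults to `colnames(gt)`.
#' @param skipped Number of input records skipped (indels/multiallelics).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, gt, ad_ref = NULL,
                            ad_alt = NULL, dp = NULL, samples = colnames(gt),
                            skipped = 0L) {
  gt <- as.matrix(gt)
  if (is.null(samples)) {
    samples <- if (ncol(gt) > 0L) paste0("S", seq_len(ncol(gt))) else
      character()
  }
  stopifnot(length(pos) == nrow(gt), length(ref) == length(pos),
            length(alt) == length(pos))
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 gt = gt, ad_ref = ad_ref, ad_alt = ad_alt, dp = dp,
                 samples = as.character(samples),
                 skipped = as.integer(skipped)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$gt), "biallelic SNP sites x",
      length(x$samples), "samples;", x$skipped, "records skipped\n")
  invisible(x)
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Only biallelic SNP records are kept; indels and multiallelic records are
#' skipped and counted in `$skipped`. GT is required; AD and DP are used
#' when present.
#'
#' @param path Path to a VCF (optionally gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    ma_error(paste("VCF not found:", path), "mutaccum_io_error")
  }
  v <- VariantAnnotation::readVcf(path)
  if (ncol(v) == 0L) {
    ma_error("VCF has zero samples", "mutaccum_io_error")
  }
  keep <- VariantAnnotation::isSNV(v, singleAltOnly = TRUE)
  skipped <- sum(!keep)
  v <- v[keep, ]
  rr <- SummarizedExperiment::rowRanges(v)
  gt_chr <- VariantAnnotation::geno(v)$GT
  code <- matrix(NA_integer_, nrow = nrow(gt_chr), ncol = ncol(gt_chr))
  clean <- gsub("|", "/", gt_chr, fixed = TRUE)
  code[clean %in% c("0/0")] <- GT_HOMREF
  code[clean %in% c("0/1", "1/0")] <- GT_HET
  code[clean %in% c("1/1")] <- GT_HOMALT
  ad_ref <- ad_alt <- dp <- NULL
  g <- VariantAnnotation::geno(v)
  if ("AD" %in% names(g)) {
    ad <- g$AD
    ad_ref <- apply(ad, c(1, 2), function(x) {
      x <- x[[1]]
      if (length(x) >= 1) as.integer(x[1]) else NA_integer_
    })
    ad_alt <- apply(ad, c(1, 2), function(x) {
      x <- x[[1]]
      if (length(x) >= 2) as.integer(x[2]) else NA_integer_
    })
  }
  if ("DP" %in% names(g)) {
    dp <- matrix(as.integer(g$DP), nrow = nrow(g$DP))
  }
  alt_chr <- as.character(unlist(VariantAnnotation::alt(v)))
  genotype_matrix(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt_chr,
    gt = code, ad_ref = ad_ref, ad_alt = ad_alt, dp = dp,
    samples = colnames(gt_chr), skipped = skipped)
}

#' Write a genotype matrix as a multi-sample VCF
#'
#' Emits VCF 4.2 with FORMAT GT, and AD/DP when the matrix carries them.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  has_ad <- !is.null(gm$ad_ref) && !is.null(gm$ad_alt)
  has_dp <- !is.null(gm$dp)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mutaccum")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (has_ad) {
    hdr <- c(hdr, paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                         "Description=\"Allelic depths\">"))
  }
  if (has_dp) {
    hdr <- c(hdr, paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                         "Description=\"Read depth\">"))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples),
                      collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$gt + 1L], nrow = nrow(gm$gt))
  gt_str[is.na(gm$gt)] <- "./."
  fmt <- paste(c("GT", if (has_ad) "AD", if (has_dp) "DP"), collapse = ":")
  cells <- gt_str
  if (has_ad) {
    cells <- matrix(paste0(cells, ":", gm$ad_ref, ",", gm$ad_alt),
                    nrow = nrow(cells))
  }
  if (has_dp) {
    cells <- matrix(paste0(cells, ":", gm$dp), nrow = nrow(cells))
  }
  body <- if (nrow(gm$gt)) {
    paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", ".", ".", fmt,
          apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  } else {
    character()
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- callable masks -------------------------------------------------------

#' Construct a callable mask from intervals
#'
#' Intervals are stored 1-based inclusive; overlapping or touching input
#' intervals are merged (with a warning if any merging occurred).
#'
#' @param ranges An `IRanges` or `GRanges` of callable intervals.
#' @param seqname Sequence name used when `ranges` is an `IRanges`.
#' @return An object of class `callable_mask` with `$ranges` (reduced
#'   `GRanges`) and `$n_callable`.
#' @export
callable_mask <- function(ranges, seqname = "chr1") {
  if (inherits(ranges, "IRanges")) {
    ranges <- GenomicRanges::GRanges(seqname, ranges)
  }
  stopifnot(inherits(ranges, "GRanges"))
  red <- GenomicRanges::reduce(ranges)
  if (length(red) != length(ranges) ||
      sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(ranges))) {
    warning("overlapping/unsorted intervals merged in callable mask")
  }
  structure(list(ranges = red,
                 n_callable = sum(GenomicRanges::width(red))),
            class = "callable_mask")
}

#' @export
print.callable_mask <- function(x, ...) {
  cat("callable_mask:", length(x$ranges), "intervals,",
      format(x$n_callable, big.mark = ","), "callable sites\n")
  invisible(x)
}

#' Read a BED file into a callable mask
#'
#' BED is 0-based half-open on disk; the returned mask is 1-based inclusive.
#'
#' @param path Path to a BED file.
#' @return A [callable_mask()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    ma_error(paste("BED not found:", path), "mutaccum_io_error")
  }
  callable_mask(rtracklayer::import(path, format = "BED"))
}

#' Write a callable mask as BED (0-based half-open)
#'
#' @param mask A [callable_mask()] (or `IRanges`/`GRanges`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mask, path) {
  gr <- if (inherits(mask, "callable_mask")) mask$ranges else
    callable_mask(mask)$ranges
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Enumerate the 1-based callable positions of a mask (small masks only)
#' @param mask A [callable_mask()].
#' @return Integer vector of positions (single-sequence masks).
#' @export
mask_positions <- function(mask) {
  gr <- mask$ranges
  unlist(Map(seq.int, GenomicRanges::start(gr), GenomicRanges::end(gr)),
         use.names = FALSE)
}

# ---- FASTA ----------------------------------------------------------------

#' Write a reference sequence as FASTA
#' @param x Character string, `DNAStringSet`, or `ma_experiment`.
#' @param path Output path.
#' @param name Sequence name for bare strings.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, name = "chr1") {
  if (inherits(x, "ma_experiment")) x <- reference_string(x)
  if (is.character(x)) {
    x <- Biostrings::DNAStringSet(stats::setNames(x, name))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path Path to FASTA.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

# ---- GFF3 -----------------------------------------------------------------

#' Write a toy annotation as GFF3 (1-based, inclusive)
#' @param annotation A [toy_annotation()].
#' @param path Output path.
#' @param seqname Sequence name.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, seqname = "chr1") {
  tx <- annotation$transcripts
  ex <- annotation$exons
  gr_tx <- GenomicRanges::GRanges(seqname,
    IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
    type = "mRNA", ID = tx$transcript_id, Parent = tx$gene_id)
  gr_ex <- GenomicRanges::GRanges(seqname,
    IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
    type = "exon", ID = paste0(ex$transcript_id, ".e", ex$exon_rank),
    Parent = ex$transcript_id)
  rtracklayer::export(c(gr_tx, gr_ex), path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 toy annotation
#'
#' Expects mRNA/transcript features with exon children (as written by
#' [write_gff3()]); exons are re-ranked in transcription order.
#'
#' @param path Path to GFF3.
#' @param W Upstream/downstream window length (not stored in GFF3).
#' @return A `toy_annotation`.
#' @export
read_gff3 <- function(path, W = 500L) {
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  is_tx <- ty %in% c("mRNA", "transcript")
  is_ex <- ty == "exon"
  first_chr <- function(x) vapply(x, function(e) as.character(e)[1], "")
  tx <- data.table::data.table(
    gene_id = first_chr(gr$Parent[is_tx]),
    transcript_id = as.character(gr$ID[is_tx]),
    strand = as.character(GenomicRanges::strand(gr[is_tx])),
    start = GenomicRanges::start(gr[is_tx]),
    end = GenomicRanges::end(gr[is_tx]))
  ex <- data.table::data.table(
    transcript_id = first_chr(gr$Parent[is_ex]),
    start = GenomicRanges::start(gr[is_ex]),
    end = GenomicRanges::end(gr[is_ex]),
    strand = as.character(GenomicRanges::strand(gr[is_ex])))
  ex <- merge(ex, tx[, .(gene_id, transcript_id)], by = "transcript_id")
  data.table::setorder(ex, transcript_id, start)
  ex[, exon_rank := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N)),
     by = transcript_id]
  structure(list(transcripts = tx, exons = ex, W = as.integer(W)),
            class = "toy_annotation")
}

# ---- TSV ------------------------------------------------------------------

#' Write a table as TSV
#' @param x A data.frame/data.table.
#' @param path Output path (`.gz` transparently compressed).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' Read a TSV table
#' @param path Path (gzip transparent).
#' @return A data.table.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) {
    ma_error(paste("TSV not found:", path), "mutaccum_io_error")
  }
  data.table::fread(path, sep = "\t")
}
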