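# Forward simulation of a mutation-accumulation experiment with known truth.
#
# The simulator draws, per line, the heterozygous de novo mutations observed
# in the sequenced generation-T individual; read evidence is per-site allele
# depths (a stand-in for aligned pileups), not reads.

#' Simulate a founder reference sequence
#' @noRd
simulate_reference <- function(genome_length, gc_content) {
  p <- c((1 - gc_content) / 2, gc_content / 2,
         gc_content / 2, (1 - gc_content) / 2)
  sample.int(4L, genome_length, replace = TRUE, prob = p)
}

#' Draw a callable mask covering ~`fraction` of the genome
#'
#' The genome is tiled into windows and `round(fraction * n_windows)` windows
#' are kept, so the realized callable fraction equals the target up to
#' window-rounding. `fraction = 1` yields the whole genome.
#' @noRd
simulate_mask <- function(genome_length, fraction, window = 1000L) {
  window <- min(window, max(1L, genome_length %/% 20L))
  starts <- seq.int(1L, genome_length, by = window)
  n_win <- length(starts)
  keep <- sort(sample.int(n_win, round(fraction * n_win)))
  if (length(keep) == 0L) {
    return(IRanges::IRanges())
  }
  IRanges::reduce(IRanges::IRanges(
    start = starts[keep],
    end = pmin(starts[keep] + window - 1L, genome_length)
  ))
}

#' Sample `n` distinct positions uniformly from a mask
#' @noRd
sample_mask_positions <- function(mask, n) {
  total <- sum(IRanges::width(mask))
  if (n > total) {
    ma_error("more mutations requested than mutable sites",
             "mutaccum_sim_error")
  }
  offs <- sample.int(total, n)
  cw <- cumsum(IRanges::width(mask))
  iv <- findInterval(offs - 1L, c(0L, cw), rightmost.closed = FALSE)
  IRanges::start(mask)[iv] + (offs - 1L) - c(0L, cw)[iv]
}

#' Build a toy gene annotation
#'
#' Deterministically lays out protein-coding genes with three fully coding
#' exons (120, 90 and 99 bp, total divisible by 3) separated by 60 bp
#' introns, on alternating strands, spaced so that upstream/downstream
#' windows and intergenic space all occur. Used for variant-effect
#' prediction on synthetic data.
#'
#' @param genome_length Genome size in bp.
#' @param spacing Distance between consecutive gene starts (bp).
#' @param W Upstream/downstream window length in bp.
#' @return A `toy_annotation` object with `$transcripts` and `$exons`
#'   data.tables.
#' @export
toy_annotation <- function(genome_length, spacing = 5000L, W = 500L) {
  exon_len <- c(120L, 90L, 99L)
  intron_len <- 60L
  span <- sum(exon_len) + 2L * intron_len
  first <- 2L * W + 1L
  n_genes <- max(0L, (genome_length - first - span - 2L * W) %/% spacing + 1L)
  if (n_genes < 1L) {
    ma_error("genome too short for any toy gene", "mutaccum_annot_error")
  }
  tx <- data.table::data.table(
    gene_id = paste0("gene", seq_len(n_genes)),
    transcript_id = paste0("tx", seq_len(n_genes)),
    strand = rep_len(c("+", "-"), n_genes),
    start = first + (seq_len(n_genes) - 1L) * spacing
  )
  tx[, `:=`(end = start + span - 1L)]
  exons <- tx[, {
    s <- cumsum(c(0L, (exon_len + intron_len)[-3L]))
    list(exon_rank = 1:3,
         start = start + s,
         end = start + s + exon_len - 1L,
         strand = strand)
  }, by = .(gene_id, transcript_id)]
  # on '-' genes rank 1 is the 3'-most genomic exon; re-rank in
  # transcription order
  exons[strand == "-", exon_rank := rev(exon_rank), by = transcript_id]
  structure(list(transcripts = tx, exons = exons, W = as.integer(W)),
            class = "toy_annotation")
}

#' Draw per-line truth mutations for one regime
#' @noRd
draw_truth_regime <- function(config, regime_idx, mask, ref_code) {
  mu <- config$mu_per_regime[regime_idx]
  TT <- config$generations
  L <- config$lines_per_regime
  n_mutable <- sum(IRanges::width(mask))
  counts <- stats::rpois(L, mu * n_mutable * TT)
  total <- sum(counts)
  if (total == 0L) {
    return(data.table::data.table(
      regime = character(), line = character(), pos = integer(),
      ref = character(), alt = character(), gen_origin = integer()))
  }
  pos <- sample_mask_positions(mask, total)
  ref <- if (is.null(ref_code)) {
    # truth-level runs skip the full reference; ref bases are i.i.d. from
    # the founder base composition
    gc <- config$gc_content
    sample.int(4L, total, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  } else {
    ref_code[pos]
  }
  is_ts <- stats::runif(total) < config$ts_fraction
  alt <- integer(total)
  alt[is_ts] <- TRANSITION_OF[ref[is_ts]]
  if (any(!is_ts)) {
    pick <- stats::runif(sum(!is_ts)) < 0.5
    tv <- vapply(seq_along(which(!is_ts)), function(i) {
      TRANSVERSIONS_OF[[ref[!is_ts][i]]][if (pick[i]) 1L else 2L]
    }, integer(1))
    alt[!is_ts] <- tv
  }
  # Mendelian survival through single-pair bottlenecks: among observed
  # mutations the generation of origin g has weight 0.5^(T - g)
  w <- 0.5^(TT - seq_len(TT))
  gen <- sample.int(TT, total, replace = TRUE, prob = w / sum(w))
  data.table::data.table(
    regime = config$regime_names[regime_idx],
    line = rep(paste0(config$regime_names[regime_idx], "_L",
                      seq_len(L)), counts),
    pos = pos, ref = code_to_base(ref), alt = code_to_base(alt),
    gen_origin = gen)
}

#' Simulate read evidence (per-site allele depths) for one regime
#' @noRd
simulate_evidence_regime <- function(config, regime_idx, ref_code, truth) {
  G <- config$genome_length
  L <- config$lines_per_regime
  depth <- matrix(stats::rnbinom(G * L, size = config$depth_dispersion,
                                 mu = config$mean_depth_per_regime[regime_idx]),
                  nrow = G, ncol = L)
  lines <- paste0(config$regime_names[regime_idx], "_L", seq_len(L))
  colnames(depth) <- lines

  # sequencing errors: each read is miscalled with prob seq_error, uniformly
  # to one of the three other bases
  eps <- config$seq_error
  alt <- data.table::data.table(pos = integer(), line = integer(),
                                base = integer(), count = integer())
  if (eps > 0) {
    nerr <- stats::rbinom(G * L, as.vector(depth), eps)
    idx <- which(nerr > 0L)
    if (length(idx)) {
      k <- nerr[idx]
      c1 <- stats::rbinom(length(idx), k, 1 / 3)
      c2 <- stats::rbinom(length(idx), k - c1, 1 / 2)
      c3 <- k - c1 - c2
      cell_pos <- ((idx - 1L) %% G) + 1L
      cell_line <- ((idx - 1L) %/% G) + 1L
      r <- ref_code[cell_pos]
      others <- matrix(0L, nrow = length(idx), ncol = 3L)
      for (b in 1:4) {
        sel <- r == b
        if (any(sel)) {
          others[sel, ] <- matrix(setdiff(1:4, b), nrow = sum(sel),
                                  ncol = 3L, byrow = TRUE)
        }
      }
      alt <- data.table::data.table(
        pos = rep(cell_pos, 3L),
        line = rep(cell_line, 3L),
        base = c(others[, 1L], others[, 2L], others[, 3L]),
        count = c(c1, c2, c3))
      alt <- alt[count > 0L]
    }
  }

  # heterozygous mutant cells: reads from ref/alt chromosomes at 0.5 each,
  # then per-read error
  if (nrow(truth)) {
    line_idx <- match(truth$line, lines)
    refc <- base_to_code(truth$ref)
    altc <- base_to_code(truth$alt)
    cells <- cbind(truth$pos, line_idx)
    d <- depth[cells]
    new_rows <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      p <- rep(eps / 3, 4)
      p[refc[i]] <- p[altc[i]] <- 0.5 * (1 - eps) + eps / 3
      cnt <- as.integer(stats::rmultinom(1L, d[i], p))
      nz <- which(cnt > 0L & seq_len(4L) != refc[i])
      if (length(nz)) {
        new_rows[[i]] <- data.table::data.table(
          pos = truth$pos[i], line = line_idx[i], base = nz,
          count = cnt[nz])
      }
    }
    # drop pre-existing error rows at mutant cells, then add the resimulated
    # cell counts
    key <- paste(truth$pos, line_idx)
    alt <- alt[!paste(pos, line) %in% key]
    alt <- data.table::rbindlist(c(list(alt), new_rows))
  }
  data.table::setkeyv(alt, c("pos", "line"))
  list(depth = depth, alt = alt, lines = lines)
}

#' Simulate a full MA experiment with known ground truth
#'
#' Draws a founder genome, per-regime callable masks, per-line de novo
#' heterozygous truth mutations (Poisson with mean
#' `mu * n_mutable * generations` per line), per-site allele-depth read
#' evidence with sequencing error, a toy gene annotation, and a line
#' survivorship table under per-regime extinction probabilities.
#'
#' Every truth mutation is heterozygous in exactly one line; all other lines
#' carry the founder homozygous-reference genotype at that site. Mutations
#' are placed only at callable sites unless `allow_uncallable = TRUE`.
#' Identical configs (same seed) give identical results.
#'
#' @param config A [sim_config()].
#' @param evidence Generate read evidence? Set `FALSE` for cheap truth-level
#'   simulations (e.g. rate parameter recovery), which skips the per-site
#'   depth matrices entirely.
#' @param allow_uncallable If `TRUE`, mutations may land outside the callable
#'   mask (to probe denominator sensitivity).
#' @return An object of class `ma_experiment`: a list with elements
#'   `config`, `ref_code` (integer-coded founder sequence), `truth`
#'   (data.table: regime, line, pos, ref, alt, gen_origin), `evidence`
#'   (per-regime list of `depth` matrix and sparse non-reference allele
#'   depths, or `NULL`), `masks` (per-regime `IRanges`), `n_callable`,
#'   `annotation` and `survival`.
#' @examples
#' ex <- simulate_experiment(sim_config(genome_length = 2e4, seed = 7,
#'                                      mu_per_regime = 1e-5))
#' ex$truth
#' @export
simulate_experiment <- function(config, evidence = TRUE,
                                allow_uncallable = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    G <- config$genome_length
    ref_code <- if (evidence) simulate_reference(G, config$gc_content) else
      NULL

    masks <- lapply(seq_len(config$n_regimes), function(r) {
      simulate_mask(G, config$callable_fraction_target[r])
    })
    names(masks) <- config$regime_names
    n_callable <- vapply(masks, function(m) sum(IRanges::width(m)),
                         numeric(1))

    truth <- data.table::rbindlist(lapply(seq_len(config$n_regimes),
      function(r) {
        mutable <- if (allow_uncallable) IRanges::IRanges(1L, G) else
          masks[[r]]
        draw_truth_regime(config, r, mutable, ref_code)
      }))

    ev <- NULL
    if (evidence) {
      ev <- lapply(seq_len(config$n_regimes), function(r) {
        simulate_evidence_regime(config, r, ref_code,
                                 truth[regime == config$regime_names[r]])
      })
      names(ev) <- config$regime_names
    }

    annotation <- toy_annotation(G)

    survival <- data.table::rbindlist(lapply(seq_len(config$n_regimes),
      function(r) {
        n0 <- config$founded_per_regime[r]
        p_ext <- config$extinction_prob_per_regime[r]
        alive <- integer(config$generations + 1L)
        alive[1L] <- n0
        for (g in seq_len(config$generations)) {
          alive[g + 1L] <- stats::rbinom(1L, alive[g], 1 - p_ext)
        }
        data.table::data.table(regime = config$regime_names[r],
                               generation = 0:config$generations,
                               n_alive = alive,
                               frac_alive = alive / n0)
      }))

    structure(list(config = config, ref_code = ref_code, truth = truth,
                   evidence = ev, masks = masks, n_callable = n_callable,
                   annotation = annotation, survival = survival),
              class = "ma_experiment")
  })
}

#' @export
print.ma_experiment <- function(x, ...) {
  cat("MA experiment:", format(x$config$genome_length, big.mark = ","),
      "bp;", x$config$n_regimes, "regimes x", x$config$lines_per_regime,
      "lines;", nrow(x$truth), "truth mutations",
      if (is.null(x$evidence)) "(no read evidence)" else "", "\n")
  invisible(x)
}

#' Founder reference as a character string
#' @param experiment An `ma_experiment`.
#' @return Single character string of A/C/G/T.
#' @export
reference_string <- function(experiment) {
  if (is.null(experiment$ref_code)) {
    ma_error("experiment was simulated without evidence; no reference kept",
             "mutaccum_sim_error")
  }
  paste(BASES[experiment$ref_code], collapse = "")
}

#' Mutation spectrum of the simulated truth
#'
#' Tallies the truth records of an experiment (or a truth data.table) into
#' the six strand-collapsed substitution classes, per regime and pooled.
#' Used for simulator self-checks against `ts_fraction`.
#'
#' @param truth An `ma_experiment` or its `$truth` data.table.
#' @return A `spectrum_counts` table; see [spectrum_counts()].
#' @export
spectrum_of_truth <- function(truth) {
  if (inherits(truth, "ma_experiment")) truth <- truth$truth
  spectrum_counts(truth$ref, truth$alt, truth$regime)
}
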