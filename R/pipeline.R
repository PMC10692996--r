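# End-to-end pipeline: simulate -> call -> merge -> rates -> spectrum ->
# effects -> report, as one seeded, reproducible run.

#' Run the full MA analysis pipeline on a simulated experiment
#'
#' Simulates an experiment from `config`, writes all standard-format stage
#' outputs (FASTA reference, per-regime multi-sample VCF of variant sites,
#' BED callable masks, GFF3 toy annotation, truth/survival TSV), calls de
#' novo candidates by the consensus and/or probabilistic arm, applies the
#' curation filters to each arm, merges the cohorts, and computes rates,
#' spectrum statistics and effect tables. Everything stochastic is seeded
#' from `config$seed` and `stat_seed`; the same configuration produces
#' byte-identical summaries.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created; refuses to overwrite an
#'   existing non-empty directory unless `overwrite = TRUE`).
#' @param caller `"both"`, `"consensus"` or `"probabilistic"`.
#' @param merge `"shared"` or `"union"` (used when `caller = "both"`).
#' @param filters A [filter_config()].
#' @param prob_params A [prob_model_params()].
#' @param B Monte-Carlo replicates for simulated p values.
#' @param stat_seed Seed for the Monte-Carlo tests.
#' @param overwrite Allow writing into a non-empty directory?
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config, outdir,
                         caller = c("both", "consensus", "probabilistic"),
                         merge = c("shared", "union"),
                         filters = filter_config(),
                         prob_params = prob_model_params(),
                         B = 10000, stat_seed = 1, overwrite = FALSE) {
  caller <- match.arg(caller)
  merge <- match.arg(merge)
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite) {
    ma_error(paste("output directory not empty:", outdir),
             "mutaccum_pipeline_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  logf <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ma_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "mutaccum_pipeline_error")
    })
  }

  logf("mutaccum pipeline; seed=%d caller=%s merge=%s B=%d stat_seed=%d",
       config$seed, caller, merge, B, stat_seed)
  logf("filters: %s", paste(names(filters)[1:6], "=",
       vapply(filters[1:6], function(x) paste(x, collapse = ","), ""),
       collapse = "; "))

  ex <- stage("simulate", simulate_experiment(config))
  stage("write_inputs", {
    write_fasta(ex, file.path(outdir, "reference.fasta"))
    write_tsv(ex$truth, file.path(outdir, "truth.tsv"))
    write_tsv(ex$survival, file.path(outdir, "survival.tsv"))
    write_gff3(ex$annotation, file.path(outdir, "annotation.gff3"))
    for (r in config$regime_names) {
      write_bed(callable_mask(ex$masks[[r]]),
                file.path(outdir, paste0("callable_", r, ".bed")))
    }
  })

  genome <- reference_string(ex)
  all_cand <- list()
  final <- list()
  accept_tabs <- list()
  n_call <- numeric(config$n_regimes)
  names(n_call) <- config$regime_names

  for (r in config$regime_names) {
    gm <- stage("genotype",
                genotype_matrix_from_evidence(ex, r, filters$genotype))
    write_vcf(gm, file.path(outdir, paste0("variants_", r, ".vcf")),
              contig_lengths = c(chr1 = config$genome_length))
    n_call[r] <- stage("callable",
                       regime_callable_sites(ex, r, filters$genotype))
    cons <- prob <- NULL
    if (caller %in% c("both", "consensus")) {
      cons <- stage("consensus", {
        cand <- consensus_candidates(gm, ex$masks[[r]], regime = r)
        apply_filters(cand, ex$evidence[[r]], filters)
      })
    }
    if (caller %in% c("both", "probabilistic")) {
      prob <- stage("probabilistic", {
        cand <- call_probabilistic(ex, r, prob_params)
        apply_filters(cand, ex$evidence[[r]], filters)
      })
    }
    all_cand[[r]] <- data.table::rbindlist(list(cons, prob))
    final[[r]] <- if (caller == "both") {
      merge_cohorts(cons[status == "accepted"], prob[status == "accepted"],
                    mode = merge)
    } else if (caller == "consensus") {
      cons[status == "accepted"]
    } else {
      prob[status == "accepted"]
    }
    logf("regime %s: callable=%d candidates=%d final=%d", r, n_call[r],
         nrow(all_cand[[r]]), nrow(final[[r]]))
  }
  audit <- data.table::rbindlist(all_cand)
  cohort <- data.table::rbindlist(final)
  write_tsv(audit, file.path(outdir, "candidates_audit.tsv"))
  write_tsv(cohort, file.path(outdir, "cohort.tsv"))
  acc <- acceptance_by_regime(audit, B = B, seed = stat_seed)
  write_tsv(acc$table, file.path(outdir, "acceptance_by_regime.tsv"))

  # rates per line and regime
  TT <- config$generations
  lines_all <- unlist(lapply(config$regime_names, function(r) {
    paste0(r, "_L", seq_len(config$lines_per_regime))
  }))
  per_line <- data.table::data.table(
    line = lines_all,
    regime = rep(config$regime_names, each = config$lines_per_regime))
  cnt <- cohort[, .N, by = line]
  per_line[, m := ifelse(line %in% cnt$line, cnt$N[match(line, cnt$line)],
                         0L)]
  per_line[, `:=`(n = n_call[regime], T = TT)]
  per_line[, mu := m / (n * T)]
  regime_rates <- per_line[, {
    est <- regime_mean_rate(m, n[1], T[1])
    list(m = est$m, L = est$L, n = est$n, T = est$T,
         mu_mean = est$mu_mean, mu_se = est$mu_se)
  }, by = regime]
  write_tsv(per_line, file.path(outdir, "rates_per_line.tsv"))
  write_tsv(regime_rates, file.path(outdir, "rates_per_regime.tsv"))

  comp_bin <- stage("glm", compare_regimes_binomial(
    per_line$m, per_line$n, per_line$regime))
  comp_poi <- compare_regimes_poisson(per_line$m, per_line$n, TT,
                                      per_line$regime)
  comps <- data.table::data.table(
    model = c(comp_bin$model, comp_poi$model),
    statistic = c(comp_bin$statistic, comp_poi$statistic),
    df = c(comp_bin$df, comp_poi$df),
    p = c(comp_bin$p, comp_poi$p))
  write_tsv(comps, file.path(outdir, "regime_comparisons.tsv"))

  # spectrum
  spec <- spectrum_counts(cohort$ref, cohort$alt, cohort$regime)
  write_tsv(spec, file.path(outdir, "spectrum.tsv"))
  sp_tests <- list()
  for (r in config$regime_names) {
    row <- spec[group == r]
    if (nrow(row) && row$total > 0) {
      g <- chisq_gof(c(row$ts, row$tv), B = B, seed = stat_seed)
      sp_tests[[r]] <- data.table::data.table(
        test = paste0("ts_tv_gof_", r), statistic = g$statistic,
        B = B, p_simulated = g$p_simulated, seed = stat_seed)
    }
  }
  type_tab <- as.matrix(spec[group != "all",
                             SPECTRUM_CLASSES, with = FALSE])
  if (nrow(type_tab) >= 2 && sum(type_tab) > 0 &&
      all(rowSums(type_tab) > 0)) {
    keep <- colSums(type_tab) > 0
    if (sum(keep) >= 2) {
      ct <- chisq_contingency(type_tab[, keep, drop = FALSE], B = B,
                              seed = stat_seed)
      sp_tests[["contingency"]] <- data.table::data.table(
        test = "spectrum_by_regime", statistic = ct$statistic, B = B,
        p_simulated = ct$p_simulated, seed = stat_seed)
    }
  }
  sp_tests <- data.table::rbindlist(sp_tests)
  if (nrow(sp_tests)) {
    write_tsv(sp_tests, file.path(outdir, "spectrum_tests.tsv"))
  }

  # effects
  eff_tests <- data.table::data.table()
  eff <- NULL
  if (nrow(cohort)) {
    cohort[, consequence := predict_effect(pos, ref, alt, ex$annotation,
                                           genome)]
    cohort[, impact := impact_of(consequence)]
    write_tsv(cohort, file.path(outdir, "cohort_effects.tsv"))
    eff <- effect_table(cohort$consequence, cohort$regime,
                        regimes = config$regime_names)
    write_tsv(data.table::as.data.table(eff$consequence,
                                        keep.rownames = "consequence"),
              file.path(outdir, "effect_consequences.tsv"))
    write_tsv(data.table::as.data.table(eff$impact,
                                        keep.rownames = "impact"),
              file.path(outdir, "effect_impacts.tsv"))
    cats <- c(rownames(eff$consequence)[rowSums(eff$consequence) > 0],
              rownames(eff$impact)[rowSums(eff$impact) > 0])
    eff_tests <- data.table::rbindlist(lapply(cats, function(cc) {
      g <- compare_effect_counts(eff, cc, B = B, seed = stat_seed)
      data.table::data.table(test = paste0("gof_", cc),
                             statistic = g$statistic, B = B,
                             p_simulated = g$p_simulated, seed = stat_seed)
    }))
    if (nrow(eff_tests)) {
      write_tsv(eff_tests, file.path(outdir, "effect_tests.tsv"))
    }
  }

  summary <- list(
    seed = config$seed, caller = caller, merge = merge, B = B,
    stat_seed = stat_seed,
    regimes = lapply(config$regime_names, function(r) {
      rr <- regime_rates[regime == r]
      sp <- spec[group == r]
      list(regime = r, m = rr$m, n_callable = rr$n, L = rr$L, T = rr$T,
           mu_mean = rr$mu_mean, mu_se = rr$mu_se,
           ts = sp$ts, tv = sp$tv,
           ts_tv_ratio = if (isTRUE(sp$tv_zero)) "undefined" else
             sp$ts_tv_ratio)
    }),
    comparisons = comps,
    spectrum_tests = sp_tests,
    effect_impacts = if (!is.null(eff)) as.data.frame(eff$impact),
    effect_tests = eff_tests,
    acceptance = acc$table,
    truth_mutations = nrow(ex$truth))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  logf("done: %d final cohort mutations", nrow(cohort))
  invisible(summary)
}
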