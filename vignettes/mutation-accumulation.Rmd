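---
title: "Methods: mutation-accumulation line analysis with mutaccum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-accumulation line analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutaccum)
```

## The experimental design this package models

A mutation-accumulation (MA) experiment founds many replicate lines from a
single isogenic pair and propagates each line through a one-male,
one-female bottleneck every generation. Because the effective population
size is ~2, selection is nearly powerless and new germline mutations drift
to fixation or loss essentially neutrally; sequencing one individual per
line after *T* generations and counting the variants unique to that line
estimates the germline mutation rate. Running the design at several
parental ages (here three regimes: young, peak-reproduction, old) turns it
into an assay of age-specific germline mutation rates.

`mutaccum` implements the computational half of such a study: de novo
single-nucleotide mutation calling from multi-line evidence, callable-site
accounting, the rate estimator, spectrum and variant-effect statistics,
regime-comparison models, and a forward simulator that generates the whole
experiment with known ground truth so that every downstream stage is
testable without any external data.

## The rate estimator and its denominator

The per-site per-generation rate is μ = m/(L·n·T). Two conventions matter:

* **Callable sites n** are positions genotyped in *every* line of a
  regime. Using anything else makes regimes with different coverage
  incomparable. In the pipeline, n is the size of the intersection of the
  regime's callable mask with the set of positions at which all lines
  receive a genotype call (depth at least `min_depth` and an unambiguous
  allele fraction).
* **Regime means** are means of per-line rates, SE = SD/√L. With a shared
  denominator this equals the pooled Σm/(L·n·T); both identities are
  tested.

## Consensus calling and curation filters

Genotypes are hard-threshold calls from allele depths: no-call below
`min_depth` (10); hom-ref when the non-reference fraction is ≤ `hom_max`
(0.1); het when the top alternate fraction lies in [0.3, 0.7]; hom-alt
above 0.9. A candidate is a callable site where exactly one line is het
and all others hom-ref; any other configuration (shared het, hom-alt,
missing call) is treated as inherited variation or insufficient evidence
and excluded entirely.

Manual alignment inspection is replaced by automated filters, each
config-exposed (`filter_config()`), applied in a fixed precedence so every
rejection carries exactly one primary reason:

1. `multiallelic` — a second distinct non-reference allele with ≥ 2 reads
   in the focal line;
2. `low_depth` / `high_depth` — focal depth < 10 or > 3× the line's mean
   depth (collapsed-repeat proxy);
3. `allele_balance` — heterozygous balance outside [0.3, 0.7];
4. `other_line_depth` — any non-focal line with < 5 reads;
5. `cluster` — two surviving candidates within 100 bp in one line reject
   each other (clustered artifacts). The cluster check runs last among
   survivors; a candidate whose neighbour already failed another filter is
   not penalized.

The original study's exact curation criteria live in supplementary
material that is not machine-readable; these defaults are standard MA-line
curation proxies and are deliberately explicit rather than hidden.

## The probabilistic caller

The published probabilistic approach for MA data (accuMUlate) uses a
Dirichlet-multinomial model over four alleles with pedigree transitions.
We deliberately reduce it to a biallelic two-hypothesis model — this is a
simplification, stated prominently: per site, hypotheses "line *i* is a de
novo heterozygote, all others hom-ref" (prior θ each, default 10⁻⁷)
against "all hom-ref" (prior 1 − Lθ). Read-count likelihoods are binomial
with alternate-read probability ε (default 10⁻³) for homozygotes and ½ for
heterozygotes. All arithmetic is in log space; the contract (tested) is no
underflow to depth 10⁴. Candidates are cells with posterior ≥ 0.9, passed
through the same curation filters as the consensus arm.

On error-free, deep data the two arms provably coincide (tested). On
realistic data they differ in the tails, which is why the pipeline's
default cohort is their **intersection** (`shared`); `union` is available.
The study this design follows used the shared set of the two approaches
for its statistics while calling the combination a union cohort — the
terminology is ambiguous there, and we resolve it in favour of the
intersection as the conservative default.

## Monte-Carlo chi-squared tests

Goodness-of-fit tests use X² = Σ(O−E)²/E with E = N·p (p equal by default:
for Ts/Tv the implied 0.5/0.5 expectation reproduces the printed
statistics exactly, which fixes the convention). p values are simulated:
the fraction of B = 10,000 seeded multinomial draws whose statistic
reaches the observed one. The plain Monte-Carlo fraction is the default;
the (s+1)/(B+1) convention is a flag. Contingency tests hold the table
total and draw cells multinomially with independence probabilities,
recomputing each draw's statistic against *its own* margins.

With 0 transversions the Ts:Tv ratio is reported as undefined alongside
the raw counts, never as a number — two of the three default regimes have
exactly this configuration.

## Regime-comparison GLMs

Two models compare rates between regimes, both reported as
likelihood-ratio chi-squares against the intercept-only model (df =
regimes − 1):

* binomial: mutated vs non-mutated callable sites ~ regime;
* Poisson: counts ~ regime with a log(n·T) exposure offset.

In the rare-event limit the two agree to well under 1% (tested). A
deliberate deviation: fitting the Poisson model with the callable sites as
*prior weights* — as the source study describes — multiplies every
log-likelihood contribution by ~9×10⁷ and produces an astronomically
inflated statistic (the study prints X² = 759,046,551). The offset
parameterization is the defensible estimate of the same contrast, so that
is what this package computes; the printed weighted value is reproducible
only by repeating the misuse, which we do not do. Similarly, a direct LR
recomputation from the study's regime totals gives X² ≈ 9.8, not the
printed 8.16; the exact model variant behind 8.16 is not stated, so
neither GLM statistic is an acceptance target. A seeded
parametric-bootstrap p value (B configurable) is available for small
counts where the asymptotic chi-square is doubtful.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` draws, per line, the heterozygous mutations
*observed in the sequenced generation-T individual*:

* **Counts** are Poisson with mean μ·n_mutable·T per line, where mutable
  sites are the callable sites (flag `allow_uncallable` widens this to the
  genome — useful for probing denominator sensitivity). Defining μ per
  mutable site keeps the estimator unbiased: E[m]/(n·T) = μ exactly, which
  the calibration tests check. The per-line count distribution is not
  stated by any study at this scale; Poisson is the natural choice for
  rare independent events and is the assumption here.
* **Transmission**: a mutation arising in generation g survives the
  single-pair bottlenecks to the sequenced M_T individual with probability
  0.5^(T−g). We draw the surviving total directly and assign generations
  of origin with probabilities ∝ 0.5^(T−g) — the conditional distribution
  among survivors — so the stated count calibration holds exactly.
* **Evidence** is per-site allele depths (not reads): depth ~ negative
  binomial with per-regime means (defaults 68.5/76.6/52.9×, matching the
  study's regimes) and dispersion `size = 5` — strongly overdispersed, a
  nod to whole-genome-amplified single-worm libraries; heterozygous
  allele balance is symmetric binomial at ½; each read is miscalled with
  probability `seq_error` (default 10⁻³) uniformly to the other bases.
* **Masks** tile the genome in 1 kb windows and keep a random subset
  matching the per-regime callable fractions (defaults 72.8/75.4/74.5%).
* **Survivorship**: lines go extinct per generation with per-regime
  probabilities (defaults 0.05/0.10/0.50 over 120/60/149 founded lines —
  chosen to reproduce the qualitative pattern of high early extinction in
  the old-age regime; the study reports the old-regime lines collapsing by
  generation 3). The survival table is monotone by construction.
* **Defaults** elsewhere: regime rates 0.74/0.30/1.20 × 10⁻⁸ (the study's
  Table-1 values), transition fraction 36/37 (its pooled spectrum), GC
  content 0.36 (typical for *Caenorhabditis* genomes), T = 3, 6 sequenced
  lines per regime.

Not emulated: read-level artifacts (mapping error, duplicates,
amplification chimeras), indels, sex chromosomes, male/female germline
asymmetry, and linked selection. A green simulation test therefore
establishes the *computational* correctness of the callers and statistics
under the stated generative model — not robustness to alignment-level
pathologies, which the automated filters only proxy.

## Numerical and interface choices

* Coordinates are 1-based inclusive everywhere in memory (VCF/GFF3
  convention); BED's 0-based half-open convention is converted at the file
  boundary. Overlapping or touching mask intervals are merged with a
  warning.
* Only biallelic SNPs enter the pipeline; indel and multiallelic VCF
  records are skipped and counted.
* The focal alternate allele at a site is the non-reference base with the
  highest pooled count; a tie is broken toward the alphabetically first
  base (deterministic).
* Effect prediction assigns one consequence per variant — the most severe
  by the fixed order splice_donor > stop_gained > missense > synonymous >
  intron > upstream > downstream > intergenic — which makes the
  consequence table additive and the impact aggregation (HIGH = stop +
  splice donor, MODERATE = missense, LOW = synonymous, MODIFIER = the
  rest) an exact identity. Start/stop-loss codon changes map to missense,
  the nearest term in this reduced set. The upstream/downstream window W
  defaults to 500 bp (the reference tool's window is unstated; 500 bp on a
  toy annotation keeps all eight categories populated).
* Every stochastic entry point takes an explicit seed and restores the
  caller's RNG state; identical configs give byte-identical outputs.

## Scaling choices in the test suite

The acceptance tests state simulation scales in their comments: the caller
recall/precision criterion runs 30 seeded replicates (not 100) of a
one-regime, 1 Mb, 6-line experiment with an elevated rate (2 × 10⁻⁶) so
that a desk-scale genome carries events at all; thresholds (recall and
precision ≥ 0.9) are unchanged. Parameter recovery keeps 200 replicates at
genome 10⁷ by simulating at the truth level (no read evidence), which is
exact for the quantity under test. The type-I-error check keeps 1,000
replicates.

## Known limitations

* The probabilistic model is a two-hypothesis reduction; it does not score
  multi-line events, somatic mosaicism, or non-reference founders.
* Filters are proxies for visual curation; their defaults are sensible but
  not fitted to any particular sequencing platform.
* The effect predictor handles fully coding toy transcripts (no UTRs, no
  splice acceptors, no phase offsets); it is meant for pipeline
  validation, not annotation-grade VEP replacement.
* Real-data entry (VCF + BED + GFF3) supports the consensus arm and
  filters via per-site AD/DP; the probabilistic arm requires full per-base
  allele depths, which standard VCFs carry only for the called alleles.
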