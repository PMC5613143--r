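#' Configuration for the synthetic maternal-transcriptome generator
#'
#' Collects and validates every tunable of the synthetic data generator. The
#' defaults encode the degradation-wave structure of oocyte maturation: three
#' maturation classes (stabilized / destabilized / unchanged) whose
#' prevalences and mean linear-scale MII/GV retentions are calibrated so that
#' the expected total RNA retained across maturation is
#' `sum(class_fractions * class_retention_means) = 0.7996`, i.e. the
#' well-established ~20% loss of total maternal RNA from GV to MII. A
#' configurable fraction of the destabilized + unchanged genes are knockout
#' targets: in the maternal knockout their MII abundance is boosted
#' `ko_retention_boost`-fold (they fail to be degraded), while GV profiles
#' are untouched in both genotypes (the knockout GV transcriptome is near
#' normal). Target transcripts additionally carry planted motif instances
#' clustered around the stop codon; m6A peak intervals are likewise planted
#' near target stop codons.
#'
#' @param n_genes Number of genes (one transcript per gene). Default 6000.
#' @param flank_len Anchor-window flank length in nucleotides. Default 400.
#' @param motif_pattern Motif to plant/scan, bracket syntax over `ACGU`
#'   (`[UA]` = U or A). Default `"GAC[UA]"`, the YTHDF2 PAR-CLIP consensus.
#' @param class_fractions Named proportions of the `stabilized`,
#'   `destabilized` and `unchanged` classes; must sum to 1.
#' @param class_retention_means Named linear-scale mean MII/GV retention per
#'   class. Defaults 1.10 / 0.33 / 0.84, calibrated for ~20% total loss.
#' @param retention_sd_log2 Per-gene log2 spread of retention around the
#'   class mean (mean-corrected on the linear scale). Default 0.12.
#' @param ko_target_fraction Fraction of destabilized+unchanged genes that
#'   are knockout targets. Default 0.04.
#' @param ko_retention_boost Multiplicative MII retention gain of targets in
#'   the knockout. Default 2.
#' @param target_motif_rate,background_motif_rate Expected planted motif
#'   instances per target transcript (stop-codon proximal) and per
#'   non-target transcript (uniform over the transcript). Defaults 3 and 1.
#' @param motif_position_sd SD (nt) of planted positions around the stop
#'   codon for targets. Default 60.
#' @param n_replicates Replicates per stage x genotype. Default 3.
#' @param noise_sd_log2 Replicate noise SD on the log2 scale. Default 0.12.
#' @param gv_mean_log2,gv_sd_log2 Mean and SD of per-gene GV log2 abundance.
#'   Defaults 8 and 1.5.
#' @param utr5_mean,cds_mean,utr3_mean Mean lengths (nt) of the simulated
#'   5'UTR, coding region and 3'UTR. The 3'UTR distribution deliberately
#'   puts mass below `flank_len` so that window padding is exercised.
#' @param n_peak_samples Number of simulated m6A peak samples. Default 12.
#' @param peak_width_mean,peak_width_sd Peak width distribution (nt).
#' @param peak_pos_sd SD (nt) of target-peak centres around the stop codon.
#'   Default 50.
#' @param peak_background_rate Expected background peaks per contig per
#'   sample. Default 0.05.
#' @param seed Integer seed; every generator consumes seeds derived from it.
#' @return A validated list of class `"synthetic_config"`.
#' @examples
#' cfg <- synthetic_config(n_genes = 50, seed = 1)
#' cfg$class_fractions
#' @export
synthetic_config <- function(n_genes = 6000,
                             flank_len = 400,
                             motif_pattern = "GAC[UA]",
                             class_fractions = c(
                               stabilized = 0.08,
                               destabilized = 0.12,
                               unchanged = 0.80
                             ),
                             class_retention_means = c(
                               stabilized = 1.10,
                               destabilized = 0.33,
                               unchanged = 0.84
                             ),
                             retention_sd_log2 = 0.12,
                             ko_target_fraction = 0.04,
                             ko_retention_boost = 2,
                             target_motif_rate = 3,
                             background_motif_rate = 1,
                             motif_position_sd = 60,
                             n_replicates = 3,
                             noise_sd_log2 = 0.12,
                             gv_mean_log2 = 8,
                             gv_sd_log2 = 1.5,
                             utr5_mean = 150,
                             cds_mean = 900,
                             utr3_mean = 300,
                             n_peak_samples = 12,
                             peak_width_mean = 150,
                             peak_width_sd = 15,
                             peak_pos_sd = 50,
                             peak_background_rate = 0.05,
                             seed = 1) {
  check_number(n_genes, "n_genes", lower = 1)
  check_number(flank_len, "flank_len", lower = 1)
  parse_motif_pattern(motif_pattern) # validates

  classes <- c("stabilized", "destabilized", "unchanged")
  for (nm in c("class_fractions", "class_retention_means")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3 || is.null(names(v)) ||
        !setequal(names(v), classes)) {
      stop_bad_arg(sprintf(
        "`%s` must be a numeric vector named %s", nm,
        paste(classes, collapse = "/")
      ))
    }
  }
  class_fractions <- class_fractions[classes]
  class_retention_means <- class_retention_means[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop_bad_arg("`class_fractions` must sum to 1 (got ", sum(class_fractions), ")")
  }
  if (any(class_fractions < 0)) stop_bad_arg("`class_fractions` must be >= 0")
  if (any(class_retention_means <= 0)) {
    stop_bad_arg("`class_retention_means` must all be > 0")
  }
  check_number(retention_sd_log2, "retention_sd_log2", lower = 0)
  check_number(ko_target_fraction, "ko_target_fraction", lower = 0, upper = 1)
  check_number(ko_retention_boost, "ko_retention_boost", lower = 1e-12)
  check_number(target_motif_rate, "target_motif_rate", lower = 0)
  check_number(background_motif_rate, "background_motif_rate", lower = 0)
  check_number(motif_position_sd, "motif_position_sd", lower = 0)
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(noise_sd_log2, "noise_sd_log2", lower = 0)
  check_number(gv_sd_log2, "gv_sd_log2", lower = 0)
  check_number(n_peak_samples, "n_peak_samples", lower = 1)
  check_number(peak_width_mean, "peak_width_mean", lower = 10)
  check_number(peak_width_sd, "peak_width_sd", lower = 0)
  check_number(peak_pos_sd, "peak_pos_sd", lower = 0)
  check_number(peak_background_rate, "peak_background_rate", lower = 0)
  check_number(seed, "seed", lower = -2147483646, upper = 2147483646)

  cfg <- list(
    n_genes = as.integer(n_genes),
    flank_len = as.integer(flank_len),
    motif_pattern = motif_pattern,
    class_fractions = class_fractions,
    class_retention_means = class_retention_means,
    retention_sd_log2 = retention_sd_log2,
    ko_target_fraction = ko_target_fraction,
    ko_retention_boost = ko_retention_boost,
    target_motif_rate = target_motif_rate,
    background_motif_rate = background_motif_rate,
    motif_position_sd = motif_position_sd,
    n_replicates = as.integer(n_replicates),
    noise_sd_log2 = noise_sd_log2,
    gv_mean_log2 = gv_mean_log2,
    gv_sd_log2 = gv_sd_log2,
    utr5_mean = utr5_mean,
    cds_mean = cds_mean,
    utr3_mean = utr3_mean,
    n_peak_samples = as.integer(n_peak_samples),
    peak_width_mean = peak_width_mean,
    peak_width_sd = peak_width_sd,
    peak_pos_sd = peak_pos_sd,
    peak_background_rate = peak_background_rate,
    seed = as.integer(seed)
  )
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  genes: %d, replicates: %d per stage x genotype, seed: %d\n",
              x$n_genes, x$n_replicates, x$seed))
  cat(sprintf("  class fractions:  %s\n",
              paste(sprintf("%s=%.2f", names(x$class_fractions),
                            x$class_fractions), collapse = ", ")))
  cat(sprintf("  class retentions: %s  (expected total retention %.4f)\n",
              paste(sprintf("%s=%.2f", names(x$class_retention_means),
                            x$class_retention_means), collapse = ", "),
              sum(x$class_fractions * x$class_retention_means)))
  cat(sprintf("  knockout: %.0f%% of destab+unchanged are targets, boost x%.2f\n",
              100 * x$ko_target_fraction, x$ko_retention_boost))
  cat(sprintf("  motif: %s, target rate %.2f (sd %.0f nt at stop), background rate %.2f\n",
              x$motif_pattern, x$target_motif_rate, x$motif_position_sd,
              x$background_motif_rate))
  invisible(x)
}
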