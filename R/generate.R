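#' @title Synthetic maternal-transcriptome generator
#' @name generate
#' @description Seeded generators for transcripts, expression matrices and
#'   m6A peak intervals with ground-truth labels. See [synthetic_config()]
#'   for the model the generator encodes.
NULL

scan_starts <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

match_at <- function(chars, parsed, start1) {
  for (o in seq_len(parsed$length)) {
    if (!(chars[start1 + o - 1] %in% parsed$allowed[[o]])) return(FALSE)
  }
  TRUE
}

# Destroy every pattern match by point mutation, leaving `protected_pos`
# (1-based) and starts listed in `keep_starts` untouched. Re-scans until
# clean because a mutation can in principle create a new match.
scrub_chars <- function(chars, parsed, protected_pos, keep_starts = integer(0)) {
  L <- parsed$length
  for (iter in seq_len(50)) {
    starts <- scan_starts(paste(chars, collapse = ""), parsed$regex)
    starts <- setdiff(starts, keep_starts)
    if (length(starts) == 0) return(chars)
    for (st in starts) {
      if (!match_at(chars, parsed, st)) next # destroyed by an earlier edit
      mutable <- integer(0)
      for (o in seq_len(L)) {
        pos <- st + o - 1
        if (!(pos %in% protected_pos) && length(parsed$allowed[[o]]) < 4) {
          mutable <- c(mutable, o)
        }
      }
      if (length(mutable) == 0) next
      o <- mutable[1]
      pos <- st + o - 1
      repl <- setdiff(RNA_BASES, parsed$allowed[[o]])
      chars[pos] <- repl[sample.int(length(repl), 1)]
    }
  }
  stop("internal error: motif scrubbing did not converge")
}

# Clip, de-overlap and codon-protect candidate planting offsets (0-based).
filter_plant_positions <- function(pos0, len, L, cds_start, stop_start,
                                   lo = 0L, hi = NULL) {
  hi <- hi %||% (len - L)
  if (hi < lo || length(pos0) == 0) return(integer(0))
  pos0 <- pmin(pmax(as.integer(round(pos0)), lo), hi)
  in_codon <- (pos0 >= cds_start - L + 1 & pos0 <= cds_start + 2) |
    (pos0 >= stop_start - L + 1 & pos0 <= stop_start + 2)
  pos0 <- sort(unique(pos0[!in_codon]))
  keep <- integer(0)
  last <- -Inf
  for (p in pos0) {
    if (p - last >= L + 1) {
      keep <- c(keep, p)
      last <- p
    }
  }
  keep
}

#' Generate synthetic transcript records and gene models
#'
#' Draws one single-exon gene per transcript, each on its own contig, with a
#' canonical AUG start codon and UAA/UAG/UGA stop codon. Background sequence
#' is motif-free by construction (chance matches of `cfg$motif_pattern` are
#' scrubbed by point mutation), after which motif instances are planted:
#' knockout-target transcripts receive `Poisson(target_motif_rate)` instances
#' at positions `Normal(stop_start, motif_position_sd)` clipped to the
#' stop-codon window, non-targets receive
#' `Poisson(background_motif_rate)` instances placed uniformly along the
#' transcript. Planted instances never overlap the start/stop codons or each
#' other, so a motif scan recovers exactly the recorded planting offsets.
#' 3'UTR lengths are drawn with substantial mass below `flank_len`, so some
#' downstream stop-codon windows require `N` padding.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `"transcript_set"` with tibbles `transcripts`
#'   (`transcript_id`, `gene_id`, `sequence`, `cds_start`, `stop_start`,
#'   `length`; coordinates 0-based), `models` (single-exon gene models with
#'   genomic codon coordinates and strand), `genes` (truth labels: maturation
#'   `class` and `is_ko_target`), and `plantings` (recorded 0-based motif
#'   offsets with their origin).
#' @examples
#' ts <- generate_transcripts(synthetic_config(n_genes = 5, seed = 1))
#' ts$transcripts
#' @export
generate_transcripts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(child_seed(cfg$seed, 0))
  parsed <- parse_motif_pattern(cfg$motif_pattern)
  L <- parsed$length
  n <- cfg$n_genes

  gene_id <- sprintf("g%05d", seq_len(n))
  transcript_id <- sprintf("t%05d", seq_len(n))
  classes <- names(cfg$class_fractions)
  class <- sample(classes, n, replace = TRUE, prob = cfg$class_fractions)
  is_ko_target <- class != "stabilized" &
    stats::runif(n) < cfg$ko_target_fraction

  utr5 <- 10L + as.integer(round(stats::rgamma(n, shape = 4,
                                               scale = cfg$utr5_mean / 4)))
  n_sense <- 60L + as.integer(round(stats::rgamma(
    n, shape = 6, scale = max(cfg$cds_mean / 3 - 60, 10) / 6
  )))
  utr3 <- 5L + as.integer(round(stats::rgamma(
    n, shape = 1.6, scale = max(cfg$utr3_mean - 5, 10) / 1.6
  )))
  cds_start <- utr5
  stop_start <- cds_start + 3L * n_sense
  len <- stop_start + 3L + utr3
  strand <- sample(c("+", "-"), n, replace = TRUE)

  sequences <- character(n)
  plantings <- vector("list", n)
  for (i in seq_len(n)) {
    chars <- sample(RNA_BASES, len[i], replace = TRUE)
    cs <- cds_start[i]
    ss <- stop_start[i]
    chars[(cs + 1):(cs + 3)] <- c("A", "U", "G")
    chars[(ss + 1):(ss + 3)] <- strsplit(
      STOP_CODONS[sample.int(3, 1)], ""
    )[[1]]
    codon_pos <- c((cs + 1):(cs + 3), (ss + 1):(ss + 3))
    chars <- scrub_chars(chars, parsed, codon_pos)

    if (is_ko_target[i]) {
      k <- stats::rpois(1, cfg$target_motif_rate)
      raw <- stats::rnorm(k, mean = ss, sd = cfg$motif_position_sd)
      pos <- filter_plant_positions(
        raw, len[i], L, cs, ss,
        lo = max(0L, ss - cfg$flank_len),
        hi = min(len[i] - L, ss + cfg$flank_len - L)
      )
    } else {
      k <- stats::rpois(1, cfg$background_motif_rate)
      raw <- if (k > 0) sample.int(len[i] - L + 1, k, replace = TRUE) - 1L
             else integer(0)
      pos <- filter_plant_positions(raw, len[i], L, cs, ss)
    }
    if (length(pos)) {
      for (p in pos) {
        for (o in seq_len(L)) {
          a <- parsed$allowed[[o]]
          chars[p + o] <- a[sample.int(length(a), 1)]
        }
      }
      planted_intervals <- unlist(lapply(pos, function(p) (p + 1):(p + L)))
      chars <- scrub_chars(chars, parsed,
                           protected_pos = c(codon_pos, planted_intervals),
                           keep_starts = pos + 1L)
    }
    sequences[i] <- paste(chars, collapse = "")
    plantings[[i]] <- pos
  }

  transcripts <- tibble::tibble(
    transcript_id = transcript_id,
    gene_id = gene_id,
    sequence = sequences,
    cds_start = cds_start,
    stop_start = stop_start,
    length = len
  )
  models <- tibble::tibble(
    gene_id = gene_id,
    contig = paste0("ctg_", gene_id),
    strand = strand,
    exon_start = 0L,
    exon_end = len,
    start_codon_pos = ifelse(strand == "+", cds_start, len - 1L - cds_start),
    stop_codon_pos = ifelse(strand == "+", stop_start, len - 1L - stop_start)
  )
  genes <- tibble::tibble(
    gene_id = gene_id,
    transcript_id = transcript_id,
    class = factor(class, levels = classes),
    is_ko_target = is_ko_target
  )
  plantings <- tibble::tibble(
    transcript_id = rep(transcript_id, lengths(plantings)),
    offset = unlist(plantings, use.names = FALSE) %||% integer(0),
    origin = rep(ifelse(is_ko_target, "target", "background"),
                 lengths(plantings))
  )
  structure(
    list(transcripts = transcripts, models = models, genes = genes,
         plantings = plantings, motif_pattern = cfg$motif_pattern),
    class = "transcript_set"
  )
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf(
    "<transcript_set> %d transcripts (%d knockout targets), motif %s, %d planted instances\n",
    nrow(x$transcripts), sum(x$genes$is_ko_target), x$motif_pattern,
    nrow(x$plantings)
  ))
  invisible(x)
}

resolve_genes <- function(genes) {
  if (inherits(genes, "transcript_set")) genes <- genes$genes
  if (inherits(genes, "synthetic_study")) genes <- genes$genes
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "class", "is_ko_target") %in% names(genes)))
  genes
}

#' Generate a synthetic expression study
#'
#' Builds log2 expression matrices for a GV/MII x control/knockout design.
#' Per-gene GV log2 abundance is `Normal(gv_mean_log2, gv_sd_log2)`. The MII
#' control mean adds `log2(class retention x jitter)` where the per-gene
#' lognormal jitter is mean-corrected on the linear scale, so the expected
#' linear-scale total MII/GV mass ratio equals
#' `sum(class_fractions * class_retention_means)` (0.7996 under defaults,
#' the ~20% degradation wave). Knockout targets gain
#' `log2(ko_retention_boost)` at MII only; GV profiles are identical in
#' expectation across genotypes. Independent `Normal(0, noise_sd_log2)`
#' replicate noise is added to every cell.
#'
#' @param cfg A [synthetic_config()].
#' @param genes Truth labels: a `transcript_set`, or a tibble with
#'   `gene_id`, `class`, `is_ko_target`.
#' @return An object of class `"expression_study"`: a list with `genes`
#'   (truth labels plus the per-gene GV mean and realised log2 retention),
#'   `samples` (`sample_id`, `stage`, `genotype`, `replicate`) and `matrix`
#'   (genes x samples, log2 scale).
#' @examples
#' cfg <- synthetic_config(n_genes = 20, seed = 1)
#' study <- generate_expression(cfg, generate_transcripts(cfg))
#' sample_ids(study, stage = "MII", genotype = "CTL")
#' @export
generate_expression <- function(cfg, genes) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- resolve_genes(genes)
  set.seed(child_seed(cfg$seed, 1))
  n <- nrow(genes)
  s <- cfg$retention_sd_log2

  gv_mean <- stats::rnorm(n, cfg$gv_mean_log2, cfg$gv_sd_log2)
  retention_log2 <- log2(cfg$class_retention_means[as.character(genes$class)]) +
    stats::rnorm(n, 0, s) - s^2 * log(2) / 2
  mii_ctl_mean <- gv_mean + retention_log2
  mii_ko_mean <- mii_ctl_mean +
    log2(cfg$ko_retention_boost) * genes$is_ko_target

  samples <- tidyr::expand_grid(
    stage = c("GV", "MII"),
    genotype = c("CTL", "mCKO"),
    replicate = seq_len(cfg$n_replicates)
  )
  samples$sample_id <- sprintf("%s_%s_%d", samples$stage, samples$genotype,
                               samples$replicate)
  samples <- samples[, c("sample_id", "stage", "genotype", "replicate")]

  mean_for <- function(stage, genotype) {
    if (stage == "GV") gv_mean
    else if (genotype == "CTL") mii_ctl_mean
    else mii_ko_mean
  }
  mat <- vapply(seq_len(nrow(samples)), function(j) {
    mean_for(samples$stage[j], samples$genotype[j]) +
      stats::rnorm(n, 0, cfg$noise_sd_log2)
  }, numeric(n))
  if (n == 1) mat <- matrix(mat, nrow = 1)
  dimnames(mat) <- list(genes$gene_id, samples$sample_id)

  structure(
    list(
      genes = tibble::tibble(
        gene_id = genes$gene_id,
        class = genes$class,
        is_ko_target = genes$is_ko_target,
        gv_mean_log2 = gv_mean,
        retention_log2 = unname(retention_log2)
      ),
      samples = samples,
      matrix = mat
    ),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d genes x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(unique(paste(x$samples$stage, x$samples$genotype, sep = "_")),
                    collapse = ", ")))
  invisible(x)
}

#' @describeIn generate_expression Sample ids of an expression study,
#'   optionally filtered by stage and/or genotype.
#' @param study An `expression_study`.
#' @param stage,genotype Optional filters (`"GV"`/`"MII"`,
#'   `"CTL"`/`"mCKO"`).
#' @export
sample_ids <- function(study, stage = NULL, genotype = NULL) {
  stopifnot(inherits(study, "expression_study"))
  s <- study$samples
  if (!is.null(stage)) s <- s[s$stage %in% stage, ]
  if (!is.null(genotype)) s <- s[s$genotype %in% genotype, ]
  s$sample_id
}

#' @export
as_tibble.expression_study <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(gene_id = rownames(x$matrix) %||% character(0)),
    tibble::as_tibble(x$matrix)
  )
}

#' @export
tidy.expression_study <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble.expression_study(x),
                              cols = -"gene_id",
                              names_to = "sample_id", values_to = "log2_expr")
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Generate synthetic m6A peak intervals
#'
#' For each of `cfg$n_peak_samples` simulated samples, every knockout-target
#' gene receives one peak of width ~ `Normal(peak_width_mean, peak_width_sd)`
#' centred `Normal(stop_codon_pos, peak_pos_sd)` on its contig, with a
#' positive enrichment score; background peaks land uniformly on contigs at
#' rate `peak_background_rate` per contig per sample. Intervals are clipped
#' to contig bounds and emitted as 0-based half-open BED6-compatible records.
#'
#' @param cfg A [synthetic_config()].
#' @param models A `transcript_set` or its `models` tibble.
#' @param targets Character vector of target gene ids; defaults to the truth
#'   labels when `models` is a `transcript_set`.
#' @return A tibble with `contig`, `start`, `end`, `name`, `score`,
#'   `strand`, `sample_id` and truth flag `is_target_peak`.
#' @export
generate_peaks <- function(cfg, models, targets = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (inherits(models, "transcript_set")) {
    targets <- targets %||% models$genes$gene_id[models$genes$is_ko_target]
    models <- models$models
  }
  stopifnot(is.data.frame(models),
            all(c("gene_id", "contig", "exon_end", "stop_codon_pos") %in%
                  names(models)))
  targets <- targets %||% character(0)
  set.seed(child_seed(cfg$seed, 2))

  tgt <- models[models$gene_id %in% targets, ]
  out <- vector("list", cfg$n_peak_samples)
  for (s in seq_len(cfg$n_peak_samples)) {
    sid <- sprintf("s%02d", s)
    rows <- list()
    if (nrow(tgt) > 0) {
      width <- pmax(50L, as.integer(round(
        stats::rnorm(nrow(tgt), cfg$peak_width_mean, cfg$peak_width_sd)
      )))
      centre <- as.integer(round(
        stats::rnorm(nrow(tgt), tgt$stop_codon_pos, cfg$peak_pos_sd)
      ))
      start <- pmax(0L, centre - width %/% 2L)
      end <- pmin(tgt$exon_end, start + width)
      keep <- end > start
      rows$target <- tibble::tibble(
        contig = tgt$contig[keep], start = start[keep], end = end[keep],
        score = round(stats::rlnorm(sum(keep), log(8), 0.4), 3),
        sample_id = sid, is_target_peak = TRUE
      )
    }
    n_bg <- stats::rpois(nrow(models), cfg$peak_background_rate)
    if (sum(n_bg) > 0) {
      idx <- rep(seq_len(nrow(models)), n_bg)
      width <- pmax(50L, as.integer(round(
        stats::rnorm(length(idx), cfg$peak_width_mean, cfg$peak_width_sd)
      )))
      start <- as.integer(floor(stats::runif(length(idx), 0,
                                             pmax(1, models$exon_end[idx] - width))))
      end <- pmin(models$exon_end[idx], start + width)
      keep <- end > start
      rows$background <- tibble::tibble(
        contig = models$contig[idx][keep], start = start[keep],
        end = end[keep],
        score = round(stats::rlnorm(sum(keep), log(3), 0.4), 3),
        sample_id = sid, is_target_peak = FALSE
      )
    }
    out[[s]] <- dplyr::bind_rows(rows)
  }
  peaks <- dplyr::bind_rows(out)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(
      contig = character(0), start = integer(0), end = integer(0),
      name = character(0), score = numeric(0), strand = character(0),
      sample_id = character(0), is_target_peak = logical(0)
    ))
  }
  peaks$name <- sprintf("%s.p%05d", peaks$sample_id,
                        stats::ave(seq_len(nrow(peaks)), peaks$sample_id,
                                   FUN = seq_along))
  peaks$strand <- "."
  peaks[, c("contig", "start", "end", "name", "score", "strand",
            "sample_id", "is_target_peak")]
}

#' Run the full synthetic generator
#'
#' Convenience wrapper chaining [generate_transcripts()],
#' [generate_expression()] and [generate_peaks()] under one seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `"synthetic_study"` with elements `config`,
#'   `transcripts`, `models`, `genes`, `plantings`, `study` (the
#'   `expression_study`) and `peaks`.
#' @examples
#' sim <- simulate_study(synthetic_config(n_genes = 10, seed = 1))
#' names(sim)
#' @export
simulate_study <- function(cfg) {
  ts <- generate_transcripts(cfg)
  study <- generate_expression(cfg, ts)
  peaks <- generate_peaks(cfg, ts)
  structure(
    list(config = cfg, transcripts = ts$transcripts, models = ts$models,
         genes = ts$genes, plantings = ts$plantings, study = study,
         peaks = peaks),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d genes, %d samples, %d peaks (seed %d)\n",
    nrow(x$transcripts), ncol(x$study$matrix), nrow(x$peaks), x$config$seed
  ))
  invisible(x)
}
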