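peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$contig,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    score = peaks$score
  )
}

#' Condense peak samples into one occupancy track
#'
#' Merges peak intervals from one or more samples into a disjoint, sorted
#' occupancy track per contig: overlapping or adjacent-overlapping
#' intervals are unioned and the merged interval takes the maximum score of
#' its contributors (configurable to mean or count). An optional
#' minimum-score filter is applied before merging. The operation is
#' idempotent: condensing a condensed track returns it unchanged.
#'
#' @param peaks A peaks tibble (`contig`, `start`, `end`, `score`, ...),
#'   e.g. from [generate_peaks()] or [read_peaks_bed()], possibly holding
#'   many samples; or a list of such tibbles (one per sample).
#' @param min_score Drop peaks with score below this before merging.
#' @param score_rule How to combine scores of merged intervals: `"max"`
#'   (default), `"mean"`, or `"count"` (number of contributing peaks).
#' @return A tibble of class `"occupancy_track"` with `contig`, `start`,
#'   `end` (0-based half-open), `score`, sorted with disjoint intervals per
#'   contig.
#' @export
condense_samples <- function(peaks, min_score = NULL,
                             score_rule = c("max", "mean", "count")) {
  score_rule <- match.arg(score_rule)
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- dplyr::bind_rows(peaks)
  }
  stopifnot(is.data.frame(peaks),
            all(c("contig", "start", "end", "score") %in% names(peaks)))
  if (!is.null(min_score)) {
    check_number(min_score, "min_score")
    peaks <- peaks[peaks$score >= min_score, ]
  }
  if (nrow(peaks) == 0) {
    out <- tibble::tibble(contig = character(0), start = integer(0),
                          end = integer(0), score = numeric(0))
    class(out) <- c("occupancy_track", class(out))
    return(out)
  }
  gr <- peaks_to_granges(peaks)
  merged <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(merged)$revmap
  combine <- switch(score_rule,
    max = function(i) max(peaks$score[i]),
    mean = function(i) mean(peaks$score[i]),
    count = function(i) length(i)
  )
  out <- tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    score = vapply(revmap, combine, numeric(1))
  )
  out <- dplyr::arrange(out, .data$contig, .data$start)
  class(out) <- c("occupancy_track", class(out))
  out
}

# Transcript-oriented bin breakpoints for one gene: upstream flank bins,
# body bins (last absorbs the remainder), downstream flank bins; in
# transcript coordinates relative to the body start (0 = first nt of the
# start codon ... body_len = first nt just past the stop codon anchor).
gene_bin_breaks <- function(body_len, body_bins, flank_nt, flank_bin_nt) {
  n_flank <- flank_nt %/% flank_bin_nt
  up <- seq.int(-flank_nt, 0L, by = flank_bin_nt)
  w <- body_len %/% body_bins
  body <- c(seq.int(0L, by = w, length.out = body_bins), body_len)
  down <- seq.int(body_len, body_len + flank_nt, by = flank_bin_nt)
  starts <- c(up[-length(up)], body[-length(body)], down[-length(down)])
  ends <- c(up[-1], body[-1], down[-1])
  list(starts = starts, ends = ends,
       n_cols = 2L * n_flank + body_bins, n_flank = n_flank)
}

#' Scale-regions metagene matrix of peak occupancy over gene bodies
#'
#' For every gene, the body (start codon to stop codon) is divided into
#' `body_bins` equal-width bins (the last absorbs the remainder) and each
#' 400-nt flank into fixed `flank_bin_nt`-wide bins; the value of a bin is
#' the fraction of its bases covered by the occupancy track (`mode =
#' "binary"`, prevalence) or the coverage-weighted mean score density
#' (`mode = "score"`). Minus-strand genes are mirrored so columns always
#' run 5' to 3'. Genes whose body is shorter than `body_bins` are skipped
#' with a warning.
#'
#' @param models Gene models tibble (`gene_id`, `contig`, `strand`,
#'   `exon_start`, `exon_end`, `start_codon_pos`, `stop_codon_pos`;
#'   genomic coordinates of each codon's first nucleotide, 0-based), e.g.
#'   from [generate_transcripts()].
#' @param track A [condense_samples()] occupancy track (any data frame of
#'   disjoint `contig`/`start`/`end`/`score` intervals).
#' @param body_bins Number of gene-body bins. Default 100.
#' @param flank_nt Flank width in nt. Default 400.
#' @param flank_bin_nt Flank bin width in nt; must divide `flank_nt`.
#'   Default 10.
#' @param mode `"binary"` (covered fraction, default) or `"score"`.
#' @return An object of class `"metagene_matrix"`: list with `matrix`
#'   (genes x bins), `body_bins`, `flank_nt`, `flank_bin_nt`, `mode`,
#'   `n_flank_bins`, and the column blocks `upstream_cols`, `body_cols`,
#'   `downstream_cols` (the downstream block is the default stop-codon
#'   region of [stop_region_ttest()]).
#' @export
metagene_matrix <- function(models, track, body_bins = 100, flank_nt = 400,
                            flank_bin_nt = 10,
                            mode = c("binary", "score")) {
  mode <- match.arg(mode)
  check_number(body_bins, "body_bins", lower = 1)
  check_number(flank_nt, "flank_nt", lower = 1)
  check_number(flank_bin_nt, "flank_bin_nt", lower = 1)
  if (flank_nt %% flank_bin_nt != 0) {
    stop_bad_arg("`flank_bin_nt` must divide `flank_nt`")
  }
  need <- c("gene_id", "contig", "strand", "start_codon_pos",
            "stop_codon_pos")
  stopifnot(is.data.frame(models), all(need %in% names(models)),
            is.data.frame(track))
  body_bins <- as.integer(body_bins)
  flank_nt <- as.integer(flank_nt)
  flank_bin_nt <- as.integer(flank_bin_nt)

  # body in genomic coordinates: [start_codon, stop_codon) on +,
  # (stop_codon, start_codon] on - (first codon nucleotides are 5'-most).
  plus <- models$strand == "+"
  body_len <- ifelse(plus,
                     models$stop_codon_pos - models$start_codon_pos,
                     models$start_codon_pos - models$stop_codon_pos)
  short <- body_len < body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) with body shorter than ", body_bins,
            " nt skipped: ",
            paste(utils::head(models$gene_id[short], 5), collapse = ", "),
            call. = FALSE)
  }
  models <- models[!short, , drop = FALSE]
  body_len <- body_len[!short]
  plus <- plus[!short]
  n_flank <- flank_nt %/% flank_bin_nt
  n_cols <- 2L * n_flank + body_bins
  if (nrow(models) == 0) {
    stop_bad_arg("no gene model has a body of at least `body_bins` nt")
  }

  # per-gene transcript-oriented bins mapped to genomic intervals
  bins <- vector("list", nrow(models))
  for (g in seq_len(nrow(models))) {
    bb <- gene_bin_breaks(body_len[g], body_bins, flank_nt, flank_bin_nt)
    if (plus[g]) {
      B <- models$start_codon_pos[g]
      gs <- B + bb$starts
      ge <- B + bb$ends
    } else {
      Bend <- models$start_codon_pos[g] + 1L
      gs <- Bend - bb$ends
      ge <- Bend - bb$starts
    }
    bins[[g]] <- tibble::tibble(
      gene = g, col = seq_len(bb$n_cols),
      contig = models$contig[g], start = gs, end = ge
    )
  }
  bins <- dplyr::bind_rows(bins)
  bin_width <- bins$end - bins$start

  mat <- matrix(0, nrow = nrow(models), ncol = n_cols,
                dimnames = list(models$gene_id, NULL))
  if (nrow(track) > 0) {
    bin_gr <- GenomicRanges::GRanges(
      bins$contig, IRanges::IRanges(start = bins$start + 1L, end = bins$end)
    )
    track_gr <- peaks_to_granges(track)
    ov <- GenomicRanges::findOverlaps(bin_gr, track_gr)
    if (length(ov) > 0) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      inter_w <- pmin(bins$end[q], track$end[s]) -
        pmax(bins$start[q], track$start[s])
      val <- if (mode == "binary") inter_w else inter_w * track$score[s]
      agg <- rowsum(val, group = q)
      qi <- as.integer(rownames(agg))
      frac <- agg[, 1] / bin_width[qi]
      mat[cbind(bins$gene[qi], bins$col[qi])] <- frac
    }
  }

  structure(
    list(matrix = mat, body_bins = body_bins, flank_nt = flank_nt,
         flank_bin_nt = flank_bin_nt, mode = mode, n_flank_bins = n_flank,
         upstream_cols = seq_len(n_flank),
         body_cols = seq.int(n_flank + 1L, n_flank + body_bins),
         downstream_cols = seq.int(n_flank + body_bins + 1L, n_cols)),
    class = "metagene_matrix"
  )
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf(
    "<metagene_matrix> %d genes x %d bins (%d flank + %d body + %d flank), mode %s\n",
    nrow(x$matrix), ncol(x$matrix), x$n_flank_bins, x$body_bins,
    x$n_flank_bins, x$mode
  ))
  invisible(x)
}

#' @export
tidy.metagene_matrix <- function(x, ...) {
  tibble::tibble(
    gene_id = rep(rownames(x$matrix), times = ncol(x$matrix)),
    bin = rep(seq_len(ncol(x$matrix)), each = nrow(x$matrix)),
    value = as.vector(x$matrix)
  )
}

#' Per-set mean and SD metagene profiles
#'
#' @param mm A [metagene_matrix()].
#' @param gene_sets Named list of gene id vectors (e.g. upregulated /
#'   downregulated / unchanged). Every set must be non-empty and contained
#'   in the matrix rows.
#' @return A tibble of class `"metagene_profiles"` with `set_label`, `bin`,
#'   `region` (upstream/body/downstream), `mean`, `sd`, `n_genes`; bin
#'   geometry in attributes.
#' @export
group_profiles <- function(mm, gene_sets) {
  stopifnot(inherits(mm, "metagene_matrix"), is.list(gene_sets),
            length(gene_sets) > 0, !is.null(names(gene_sets)))
  region <- rep("body", ncol(mm$matrix))
  region[mm$upstream_cols] <- "upstream"
  region[mm$downstream_cols] <- "downstream"
  out <- purrr::imap(gene_sets, function(ids, label) {
    if (length(ids) == 0) stop_bad_arg("empty gene set: ", label)
    missing <- setdiff(ids, rownames(mm$matrix))
    if (length(missing) > 0) {
      stop_bad_arg("gene set ", label, " has genes absent from the matrix: ",
                   paste(utils::head(missing, 5), collapse = ", "))
    }
    sub <- mm$matrix[ids, , drop = FALSE]
    tibble::tibble(
      set_label = label,
      bin = seq_len(ncol(sub)),
      region = region,
      mean = colMeans(sub),
      sd = apply(sub, 2, stats::sd),
      n_genes = length(ids)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "body_bins") <- mm$body_bins
  attr(out, "n_flank_bins") <- mm$n_flank_bins
  attr(out, "mode") <- mm$mode
  class(out) <- c("metagene_profiles", class(out))
  out
}

#' Two-sample t-test of regional metagene occupancy
#'
#' Reduces each gene to its mean occupancy over a bin region (by default
#' the 400-nt downstream stop-codon flank block) and compares two gene sets
#' with a two-sided two-sample t-test (Welch by default; classic pooled via
#' `var_equal = TRUE`).
#'
#' @param mm A [metagene_matrix()].
#' @param set_a,set_b Gene id vectors (each of size >= 2, rows of the
#'   matrix).
#' @param region_bins Integer bin (column) indices; default
#'   `mm$downstream_cols`, the stop-codon flank block.
#' @param var_equal Pooled-variance t-test instead of Welch? Default
#'   `FALSE`.
#' @return An object of class `"region_ttest"`: list with `statistic`,
#'   `df`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`, `region_bins`,
#'   `var_equal`.
#' @export
stop_region_ttest <- function(mm, set_a, set_b, region_bins = NULL,
                              var_equal = FALSE) {
  stopifnot(inherits(mm, "metagene_matrix"))
  check_flag(var_equal, "var_equal")
  region_bins <- region_bins %||% mm$downstream_cols
  if (length(region_bins) == 0 ||
      !all(region_bins %in% seq_len(ncol(mm$matrix)))) {
    stop_bad_arg("`region_bins` must be valid bin indices")
  }
  for (nm in c("set_a", "set_b")) {
    ids <- get(nm)
    if (length(ids) < 2) stop_bad_arg("`", nm, "` has fewer than 2 genes")
    missing <- setdiff(ids, rownames(mm$matrix))
    if (length(missing) > 0) {
      stop_bad_arg("`", nm, "` has genes absent from the matrix: ",
                   paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  score_a <- rowMeans(mm$matrix[set_a, region_bins, drop = FALSE])
  score_b <- rowMeans(mm$matrix[set_b, region_bins, drop = FALSE])
  if (stats::sd(score_a) == 0 && stats::sd(score_b) == 0 &&
      mean(score_a) == mean(score_b)) {
    # degenerate but well-defined: identical constant groups
    tt <- list(statistic = c(t = 0), parameter = c(df = length(score_a) +
                                                     length(score_b) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(score_a, score_b, var.equal = var_equal)
  }
  structure(
    list(
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      mean_a = mean(score_a), mean_b = mean(score_b),
      n_a = length(score_a), n_b = length(score_b),
      region_bins = region_bins, var_equal = var_equal
    ),
    class = "region_ttest"
  )
}

#' @export
print.region_ttest <- function(x, ...) {
  cat(sprintf(
    "<region_ttest> t = %.3f, df = %.1f, p = %.4g (means %.4g vs %.4g; n = %d vs %d)\n",
    x$statistic, x$df, x$p_value, x$mean_a, x$mean_b, x$n_a, x$n_b
  ))
  invisible(x)
}

#' @export
tidy.region_ttest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    mean_a = x$mean_a, mean_b = x$mean_b, n_a = x$n_a, n_b = x$n_b,
    var_equal = x$var_equal
  )
}
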