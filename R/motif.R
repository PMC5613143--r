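#' Deduplicate isoforms and rank transcripts by fold change
#'
#' Applies the transcript-selection convention used for positional motif
#' analysis: where a gene has several transcripts, the one with the highest
#' absolute fold change is retained (ties broken by lexicographically
#' smallest `transcript_id`); after ranking by signed fold change
#' (descending), later entries whose sequence is identical to an
#' earlier-retained sequence are dropped, so retained sequences are unique.
#'
#' @param results Data frame with `gene_id` and `log2_fc`; a
#'   `transcript_id` column makes the fold changes transcript-level,
#'   otherwise every isoform of a gene inherits the gene's fold change.
#' @param transcripts Data frame with `transcript_id`, `gene_id`,
#'   `sequence`, and (carried through when present) `cds_start`,
#'   `stop_start`.
#' @return A tibble sorted by `log2_fc` descending, one row per retained
#'   transcript, with a `rank` column.
#' @export
dedupe_and_rank <- function(results, transcripts) {
  stopifnot(is.data.frame(results),
            all(c("gene_id", "log2_fc") %in% names(results)),
            is.data.frame(transcripts),
            all(c("transcript_id", "gene_id", "sequence") %in%
                  names(transcripts)))
  no_seq <- setdiff(unique(results$gene_id), transcripts$gene_id)
  if (length(no_seq) > 0) {
    stop_bad_arg("genes with no transcript sequence: ",
                 paste(utils::head(no_seq, 10), collapse = ", "),
                 if (length(no_seq) > 10) ", ..." else "")
  }

  if ("transcript_id" %in% names(results)) {
    merged <- dplyr::inner_join(
      results[, c("transcript_id", "gene_id", "log2_fc")],
      transcripts[, setdiff(names(transcripts), c("gene_id", "log2_fc"))],
      by = "transcript_id"
    )
  } else {
    merged <- dplyr::inner_join(
      results[, c("gene_id", "log2_fc")],
      transcripts,
      by = "gene_id",
      relationship = "one-to-many"
    )
  }

  per_gene <- merged |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(abs(.data$log2_fc)), .data$transcript_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  ranked <- per_gene |>
    dplyr::arrange(dplyr::desc(.data$log2_fc), .data$transcript_id)
  ranked <- ranked[!duplicated(ranked$sequence), ]
  ranked$rank <- seq_len(nrow(ranked))
  front <- c("rank", "transcript_id", "gene_id", "log2_fc")
  ranked[, c(front, setdiff(names(ranked), front))]
}

#' Select the top, bottom and centre transcript sets
#'
#' From a ranked list (fold change descending), takes the `set_size` most
#' upregulated, the `set_size` most downregulated (in increasing rank of
#' downregulation), and the `set_size` transcripts centred on list position
#' `floor(L/2)`. Requires `L >= 3 * set_size`, which also guarantees the
#' three sets are disjoint.
#'
#' @param ranked A [dedupe_and_rank()] tibble (any data frame ordered by
#'   fold change descending works).
#' @param set_size Transcripts per set. Default 1000.
#' @return A tibble with the selected rows, a `set_label` factor
#'   (`upregulated` / `downregulated` / `unchanged`) and a `rank_in_set`
#'   column (1 = most extreme for up/down, left edge for the centre set).
#' @export
select_sets <- function(ranked, set_size = 1000) {
  stopifnot(is.data.frame(ranked))
  check_number(set_size, "set_size", lower = 1)
  set_size <- as.integer(set_size)
  L <- nrow(ranked)
  if (L < 3 * set_size) {
    stop_bad_arg(sprintf(
      "ranked list has %d entries; need >= 3 * set_size = %d",
      L, 3 * set_size
    ))
  }
  centre_start <- floor(L / 2) - floor(set_size / 2) + 1L
  idx <- list(
    upregulated = seq_len(set_size),
    downregulated = rev(seq.int(L - set_size + 1L, L)),
    unchanged = seq.int(centre_start, centre_start + set_size - 1L)
  )
  out <- purrr::imap(idx, function(i, label) {
    block <- tibble::as_tibble(ranked[i, ])
    block$set_label <- label
    block$rank_in_set <- seq_along(i)
    block
  })
  out <- dplyr::bind_rows(out)
  out$set_label <- factor(out$set_label,
                          levels = c("upregulated", "downregulated",
                                     "unchanged"))
  out
}

anchor_window_string <- function(sequence, anchor_pos, flank_len) {
  len <- nchar(sequence)
  lo <- anchor_pos - flank_len # 0-based inclusive
  hi <- anchor_pos + flank_len # 0-based exclusive
  n_pad_left <- max(0L, -lo)
  n_pad_right <- max(0L, hi - len)
  core <- substr(sequence, max(0L, lo) + 1L, min(len, hi))
  list(
    window = paste0(strrep("N", n_pad_left), core, strrep("N", n_pad_right)),
    n_pad_left = n_pad_left,
    n_pad_right = n_pad_right
  )
}

#' Extract anchor-centred sequence windows
#'
#' Cuts, for each transcript, the window
#' `[anchor - flank_len, anchor + flank_len)` where the anchor is the
#' 0-based index of the first nucleotide of the start or stop codon (so the
#' downstream half includes the codon itself). Positions outside the
#' transcript are padded with `N`, giving every window length
#' `2 * flank_len`.
#'
#' @param transcripts Data frame with `transcript_id`, `sequence`, and
#'   `cds_start` / `stop_start` (0-based codon first-nucleotide indices).
#' @param anchor `"stop_codon"` (default) or `"start_codon"`.
#' @param flank_len Flank length in nt. Default 400.
#' @return A tibble with `transcript_id`, `window`, `n_pad_left`,
#'   `n_pad_right`.
#' @export
extract_anchor_window <- function(transcripts,
                                  anchor = c("stop_codon", "start_codon"),
                                  flank_len = 400) {
  anchor <- match.arg(anchor)
  check_number(flank_len, "flank_len", lower = 1)
  flank_len <- as.integer(flank_len)
  pos_col <- if (anchor == "stop_codon") "stop_start" else "cds_start"
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "sequence", pos_col) %in%
                  names(transcripts)))
  seqs <- normalize_rna(transcripts$sequence, what = "transcript sequence")
  res <- purrr::map2(seqs, transcripts[[pos_col]],
                     anchor_window_string, flank_len = flank_len)
  tibble::tibble(
    transcript_id = transcripts$transcript_id,
    window = purrr::map_chr(res, "window"),
    n_pad_left = purrr::map_int(res, ~ as.integer(.x$n_pad_left)),
    n_pad_right = purrr::map_int(res, ~ as.integer(.x$n_pad_right))
  )
}

#' Motif match start offsets within a window
#'
#' Scans every position of `window` for a match of `pattern` (bracket
#' syntax, e.g. `"GAC[UA]"`), allowing overlapping matches — the scanning
#' convention, not the consuming global-regex convention. `N` never
#' matches.
#'
#' @param window A sequence string over `A`, `C`, `G`, `U`/`T`, `N`.
#' @param pattern Motif pattern. Default `"GAC[UA]"`.
#' @return Sorted integer vector of 0-based match start offsets.
#' @examples
#' motif_match_positions("GACUGACA") # 0 and 4
#' @export
motif_match_positions <- function(window, pattern = "GAC[UA]") {
  stopifnot(is.character(window), length(window) == 1)
  parsed <- parse_motif_pattern(pattern)
  window <- normalize_rna(window, what = "window")
  scan_starts(window, parsed$regex) - 1L
}

#' Build a binary motif occurrence matrix over anchor windows
#'
#' For a set of transcripts, extracts anchor-centred windows (with `N`
#' padding) and marks every window offset at which a motif match starts.
#' With the canonical 1000-transcript sets and 400-nt flanks this is the
#' 1000 x 800 occurrence matrix.
#'
#' @inheritParams extract_anchor_window
#' @param pattern Motif pattern. Default `"GAC[UA]"`.
#' @param set_label Optional label (e.g. `"upregulated"`) carried in the
#'   result.
#' @return An object of class `"occurrence_matrix"`: list with `matrix`
#'   (binary, transcripts x `2*flank_len`, rownames = transcript ids,
#'   colnames = signed offsets relative to the anchor), `anchor`,
#'   `flank_len`, `pattern`, `set_label`.
#' @export
build_occurrence_matrix <- function(transcripts,
                                    anchor = c("stop_codon", "start_codon"),
                                    flank_len = 400,
                                    pattern = "GAC[UA]",
                                    set_label = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(is.data.frame(transcripts), nrow(transcripts) > 0)
  if (any(is.na(transcripts$sequence))) {
    stop_bad_arg("missing sequence for: ",
                 paste(utils::head(
                   transcripts$transcript_id[is.na(transcripts$sequence)], 5
                 ), collapse = ", "))
  }
  parsed <- parse_motif_pattern(pattern)
  flank_len <- as.integer(flank_len)
  windows <- extract_anchor_window(transcripts, anchor, flank_len)
  width <- 2L * flank_len
  mat <- matrix(0L, nrow = nrow(windows), ncol = width,
                dimnames = list(windows$transcript_id,
                                as.character(seq(-flank_len, flank_len - 1L))))
  for (i in seq_len(nrow(windows))) {
    starts <- scan_starts(windows$window[i], parsed$regex)
    if (length(starts) > 0) mat[i, starts] <- 1L
  }
  structure(
    list(matrix = mat, anchor = anchor, flank_len = flank_len,
         pattern = pattern, set_label = set_label),
    class = "occurrence_matrix"
  )
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf(
    "<occurrence_matrix> %d transcripts x %d positions, %s anchor, pattern %s%s: %d match sites\n",
    nrow(x$matrix), ncol(x$matrix), x$anchor, x$pattern,
    if (is.null(x$set_label)) "" else paste0(" [", x$set_label, "]"),
    sum(x$matrix)
  ))
  invisible(x)
}

#' @export
tidy.occurrence_matrix <- function(x, ...) {
  hits <- which(x$matrix == 1L, arr.ind = TRUE)
  tibble::tibble(
    transcript_id = rownames(x$matrix)[hits[, 1]],
    offset = as.integer(colnames(x$matrix)[hits[, 2]])
  ) |> dplyr::arrange(.data$transcript_id, .data$offset)
}

#' Column-summed positional motif profile with smoothing
#'
#' Sums an occurrence matrix over transcripts at each window position and
#' fits a smoother: by default a cubic smoothing spline
#' (`stats::smooth.spline`, smoothing parameter chosen by generalised
#' cross-validation), alternatively local regression (loess). Smoothed
#' values are clipped at zero for reporting; enrichment statistics never
#' depend on the smoother.
#'
#' @param om An [build_occurrence_matrix()] result.
#' @param smoother `"spline"` (default) or `"loess"`.
#' @param smooth_param Optional smoothing parameter: `spar` for the spline,
#'   `span` for loess. `NULL` lets the spline use GCV and loess its default
#'   span (0.25).
#' @return A tibble of class `"positional_profile"` with `offset`
#'   (nt relative to the anchor), `raw` and `smoothed`; smoother metadata in
#'   attributes.
#' @export
positional_profile <- function(om, smoother = c("spline", "loess"),
                               smooth_param = NULL) {
  smoother <- match.arg(smoother)
  stopifnot(inherits(om, "occurrence_matrix"))
  mat <- om$matrix
  if (ncol(mat) < 10) {
    stop_bad_arg("fewer than 10 window positions; smoothing is ill-posed")
  }
  raw <- colSums(mat)
  x <- as.integer(colnames(mat))
  if (smoother == "spline") {
    fit <- if (is.null(smooth_param)) {
      stats::smooth.spline(x, raw, cv = FALSE)
    } else {
      stats::smooth.spline(x, raw, spar = smooth_param)
    }
    smoothed <- stats::predict(fit, x)$y
  } else {
    span <- smooth_param %||% 0.25
    fit <- stats::loess(raw ~ x, span = span, degree = 2)
    smoothed <- stats::predict(fit, data.frame(x = x))
  }
  out <- tibble::tibble(
    offset = x,
    raw = unname(raw),
    smoothed = pmax(0, unname(smoothed))
  )
  attr(out, "anchor") <- om$anchor
  attr(out, "set_label") <- om$set_label
  attr(out, "smoother") <- list(kind = smoother, smooth_param = smooth_param)
  class(out) <- c("positional_profile", class(out))
  out
}

# Upper-tail hypergeometric probability P(X >= k), computed in log space.
hyper_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- seq.int(k, min(K, n))
  if (length(i) == 0 || k > min(K, n)) return(0)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, exp(logsumexp(log_terms)))
}

#' Hypergeometric enrichment of motif-bearing transcripts
#'
#' Tests whether the test set contains more motif-bearing transcripts than
#' expected by sampling from the combined universe. A transcript is a *hit*
#' if at least one match starts inside `region`; the universe is test set
#' plus reference set; the p-value is the upper tail
#' `P(X >= k)` of the hypergeometric distribution with `N` transcripts, `K`
#' total hits and `n` draws, evaluated in log space.
#'
#' @param test_om,reference_om [build_occurrence_matrix()] results with
#'   identical column layout (e.g. upregulated vs unchanged sets).
#' @param region Integer vector of window offsets (nt relative to the
#'   anchor) defining where matches count; default all offsets.
#' @return An object of class `"enrichment_result"`: list with `k`, `K`,
#'   `n`, `N`, `p_value`, `region_range`, `anchor` and the two set labels.
#' @export
enrichment_test <- function(test_om, reference_om, region = NULL) {
  stopifnot(inherits(test_om, "occurrence_matrix"),
            inherits(reference_om, "occurrence_matrix"))
  if (ncol(test_om$matrix) != ncol(reference_om$matrix)) {
    stop_bad_arg("occurrence matrices have different widths")
  }
  offsets <- as.integer(colnames(test_om$matrix))
  region <- region %||% offsets
  if (length(region) == 0) stop_bad_arg("`region` must be non-empty")
  cols <- which(offsets %in% as.integer(region))
  if (length(cols) == 0) {
    stop_bad_arg("`region` does not overlap the window offsets")
  }
  hits_test <- rowSums(test_om$matrix[, cols, drop = FALSE]) > 0
  hits_ref <- rowSums(reference_om$matrix[, cols, drop = FALSE]) > 0
  k <- sum(hits_test)
  K <- k + sum(hits_ref)
  n <- length(hits_test)
  N <- n + length(hits_ref)
  structure(
    list(
      k = k, K = K, n = n, N = N,
      p_value = hyper_upper_tail(k, K, n, N),
      region_range = range(offsets[cols]),
      anchor = test_om$anchor,
      test_label = test_om$set_label,
      reference_label = reference_om$set_label
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s%s: k = %d of n = %d vs K = %d of N = %d in [%d, %d]; p = %.4g\n",
    x$anchor,
    if (is.null(x$test_label)) "" else {
      sprintf(" (%s vs %s)", x$test_label, x$reference_label)
    },
    x$k, x$n, x$K, x$N, x$region_range[1], x$region_range[2], x$p_value
  ))
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble::tibble(
    anchor = x$anchor,
    test_label = x$test_label %||% NA_character_,
    reference_label = x$reference_label %||% NA_character_,
    k = x$k, K = x$K, n = x$n, N = x$N,
    p_value = x$p_value
  )
}
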