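#' Classify genes by behaviour across oocyte maturation
#'
#' Applies the fold-change/p gate to a GV-vs-MII control comparison:
#' `stabilized` when `log2_fc(MII - GV) >= log2(fc_min)` with the
#' p-criterion met, `destabilized` symmetrically, `unchanged` otherwise.
#' The default p-criterion is inclusive (`p <= p_max`), matching the
#' convention used for the maturation contrast, whereas the knockout
#' contrast of [call_deregulated()] defaults to strict.
#'
#' @param gv_vs_mii A [moderated_t()] result where group A are GV control
#'   samples and group B are MII control samples.
#' @inheritParams call_deregulated
#' @return A tibble with `gene_id`, `log2_fc`, `p_used` and `class`
#'   (factor stabilized/destabilized/unchanged).
#' @export
classify_maturation <- function(gv_vs_mii, fc_min = 2, p_max = 0.05,
                                use_adjusted = FALSE,
                                p_comparison = c("inclusive", "strict")) {
  p_comparison <- match.arg(p_comparison)
  calls <- call_deregulated(gv_vs_mii, fc_min = fc_min, p_max = p_max,
                            use_adjusted = use_adjusted,
                            p_comparison = p_comparison)
  tibble::tibble(
    gene_id = calls$gene_id,
    log2_fc = calls$log2_fc,
    p_used = calls$p_used,
    class = factor(
      dplyr::case_when(
        calls$call == "up" ~ "stabilized",
        calls$call == "down" ~ "destabilized",
        TRUE ~ "unchanged"
      ),
      levels = c("stabilized", "destabilized", "unchanged")
    )
  )
}

#' Cross-tabulate knockout dosage calls against maturation classes
#'
#' Builds the 3x3 gate table counting genes by knockout call (up / down /
#' unchanged) against maturation class (stabilized / destabilized /
#' unchanged), with margins and — for the upregulated row — the fractions of
#' up-called genes falling in each maturation class (the published gate
#' split reports, e.g., 168/201 unchanged and 33/201 destabilized).
#'
#' @param ko_calls A [call_deregulated()] table for the knockout contrast.
#' @param maturation_classes A [classify_maturation()] table over the same
#'   gene universe.
#' @return An object of class `"gate_table"`: a list with `counts` (3x3
#'   integer matrix, rows = knockout call), `n_genes`, `row_margins`,
#'   `col_margins` and `up_row_fractions`.
#' @export
gate_crosstab <- function(ko_calls, maturation_classes) {
  stopifnot(is.data.frame(ko_calls),
            all(c("gene_id", "call") %in% names(ko_calls)),
            is.data.frame(maturation_classes),
            all(c("gene_id", "class") %in% names(maturation_classes)))
  only_ko <- setdiff(ko_calls$gene_id, maturation_classes$gene_id)
  only_mat <- setdiff(maturation_classes$gene_id, ko_calls$gene_id)
  if (length(only_ko) > 0 || length(only_mat) > 0) {
    stop_bad_arg(
      "gene universes differ; only in ko_calls: {",
      paste(utils::head(only_ko, 5), collapse = ", "),
      if (length(only_ko) > 5) ", ..." else "",
      "}; only in maturation_classes: {",
      paste(utils::head(only_mat, 5), collapse = ", "),
      if (length(only_mat) > 5) ", ..." else "", "}"
    )
  }
  if (anyDuplicated(ko_calls$gene_id) || anyDuplicated(maturation_classes$gene_id)) {
    stop_bad_arg("gene ids must be unique in both inputs")
  }

  merged <- dplyr::inner_join(
    ko_calls[, c("gene_id", "call")],
    maturation_classes[, c("gene_id", "class")],
    by = "gene_id"
  )
  counts <- table(
    ko_call = factor(merged$call, levels = c("up", "down", "unchanged")),
    maturation = factor(merged$class,
                        levels = c("stabilized", "destabilized", "unchanged"))
  )
  counts <- unclass(counts)
  up <- counts["up", ]
  n_up <- sum(up)
  structure(
    list(
      counts = counts,
      n_genes = nrow(merged),
      row_margins = rowSums(counts),
      col_margins = colSums(counts),
      up_row_fractions = if (n_up > 0) up / n_up else up * NA_real_
    ),
    class = "gate_table"
  )
}

#' @export
print.gate_table <- function(x, ...) {
  cat(sprintf("<gate_table> %d genes\n", x$n_genes))
  print(x$counts)
  up <- x$counts["up", ]
  n_up <- sum(up)
  if (n_up > 0) {
    cat(sprintf(
      "up row: %d/%d unchanged, %d/%d destabilized, %d/%d stabilized\n",
      up[["unchanged"]], n_up, up[["destabilized"]], n_up,
      up[["stabilized"]], n_up
    ))
  }
  invisible(x)
}

#' @export
tidy.gate_table <- function(x, ...) {
  df <- as.data.frame.table(as.table(x$counts), responseName = "n")
  tibble::tibble(
    ko_call = factor(df$ko_call, levels = rownames(x$counts)),
    maturation = factor(df$maturation, levels = colnames(x$counts)),
    n = as.integer(df$n)
  )
}
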