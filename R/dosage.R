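#' Equalise linear-scale totals across samples
#'
#' Rescales every sample column of a log2 expression table so that all
#' columns have the same linear-scale total (the geometric mean of the
#' original totals). Because maturation removes an appreciable fraction of
#' total RNA, comparisons of *relative* transcript dosage — the quantity an
#' RMA-normalised array reports — are made on total-equalised values.
#'
#' @param data A data frame whose first column is `gene_id` and whose
#'   remaining numeric columns are log2 expression values.
#' @param gene_col Name of the gene id column. Default `"gene_id"`.
#' @return A tibble of the same shape with rescaled sample columns.
#' @export
normalize_total <- function(data, gene_col = "gene_id") {
  stopifnot(is.data.frame(data), gene_col %in% names(data))
  sample_cols <- setdiff(names(data), gene_col)
  mat <- as.matrix(data[, sample_cols])
  if (!is.numeric(mat) || !all(is.finite(mat))) {
    stop_bad_arg("expression values must be finite numerics")
  }
  totals <- colSums(2^mat)
  offset <- log2(totals) - mean(log2(totals))
  mat <- sweep(mat, 2, offset, `-`)
  out <- tibble::as_tibble(data)
  out[, sample_cols] <- tibble::as_tibble(mat)
  out
}

trigamma_inverse <- function(y) {
  # Monotone Newton iteration for trigamma^{-1}; trigamma is decreasing on
  # (0, Inf) with range (0, Inf).
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(100)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Gene-wise sample variances on the log2 scale are modelled as scaled
#' chi-square draws around a prior variance `s0_sq` with `d0` prior degrees
#' of freedom. Hyperparameters are estimated by moment matching on
#' `z = log(s2)`: `trigamma(d0/2) = var(z) - trigamma(d/2)` is solved for
#' `d0` by monotone root-finding, and
#' `s0_sq = exp(mean(z) - digamma(d/2) + log(d/2) + digamma(d0/2) -
#' log(d0/2))`. When the observed dispersion of `z` does not exceed the
#' chi-square expectation (`var(z) <= trigamma(d/2)`), the prior is
#' degenerate: `d0 = Inf` and all posterior variances collapse to `s0_sq`.
#'
#' @param s2 Vector of gene-wise sample variances (log2 scale). Genes with
#'   `s2 == 0` are ignored for estimation; at least two positive values are
#'   required.
#' @param d Residual degrees of freedom common to all genes
#'   (`n_A + n_B - 2`).
#' @return A list of class `"ebayes_prior"` with `d0`, `s0_sq`, `d` and
#'   `n_genes` (number of variances used).
#' @seealso [moderated_t()], which consumes the prior.
#' @examples
#' set.seed(1)
#' s2 <- 0.05 * 4 / rchisq(1000, df = 4)
#' estimate_ebayes_prior(s2, d = 4)
#' @export
estimate_ebayes_prior <- function(s2, d) {
  if (!is.numeric(s2) || length(s2) < 2 || any(is.na(s2)) || any(s2 < 0)) {
    stop_bad_arg("`s2` must be a numeric vector of >= 2 non-negative variances")
  }
  check_number(d, "d", lower = 1)
  if (all(s2 == 0)) stop_bad_arg("degenerate variance input: all s2 are zero")
  z <- log(s2[s2 > 0])
  if (length(z) < 2) {
    stop_bad_arg("degenerate variance input: fewer than 2 positive variances")
  }
  vz <- stats::var(z)
  mz <- mean(z)
  excess <- vz - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mz - digamma(d / 2) + log(d / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mz - digamma(d / 2) + log(d / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, d = d, n_genes = length(z)),
            class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf(
    "<ebayes_prior> d0 = %s, s0_sq = %.6g (from %d genes, d = %g)\n",
    format(x$d0, digits = 4), x$s0_sq, x$n_genes, x$d
  ))
  invisible(x)
}

#' @export
glance.ebayes_prior <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s0_sq = x$s0_sq, df_residual = x$d,
                 n_genes = x$n_genes)
}

#' Empirical-Bayes moderated t-statistics between two sample groups
#'
#' For each gene, computes the log2 fold change `mean(B) - mean(A)`, the
#' pooled sample variance, and the moderated t-statistic in which the
#' gene-wise variance is shrunk toward the empirical-Bayes prior:
#' `s2_tilde = (d0 * s0_sq + d * s2) / (d0 + d)` (or `s0_sq` when
#' `d0 = Inf`). The statistic `t = log2FC / sqrt(s2_tilde * (1/nA + 1/nB))`
#' is referred two-sided to a t distribution with `d0 + d` degrees of
#' freedom (standard normal when `d0 = Inf`). Benjamini-Hochberg adjusted
#' p-values are appended.
#'
#' @param data Data frame with a `gene_id` column (see `gene_col`) and one
#'   numeric column per sample, log2 scale.
#' @param a,b Character vectors of sample column names for groups A and B;
#'   the reported fold change is B relative to A. Each group needs >= 2
#'   samples.
#' @param prior An [estimate_ebayes_prior()] result, or `NULL` (default) to
#'   estimate it from the pooled variances of `data` itself.
#' @param gene_col Name of the gene id column.
#' @return A tibble of class `"group_comparison"` with columns `gene_id`,
#'   `mean_a`, `mean_b`, `log2_fc`, `s2`, `df_residual`, `t_mod`,
#'   `df_total`, `p_value`, `q_value`. The prior is attached as attribute
#'   `"prior"`.
#' @examples
#' cfg <- synthetic_config(n_genes = 100, seed = 1)
#' study <- generate_expression(cfg, generate_transcripts(cfg))
#' cmp <- moderated_t(as_tibble(study),
#'                    a = sample_ids(study, "MII", "CTL"),
#'                    b = sample_ids(study, "MII", "mCKO"))
#' head(cmp)
#' @export
moderated_t <- function(data, a, b, prior = NULL, gene_col = "gene_id") {
  stopifnot(is.data.frame(data), gene_col %in% names(data))
  for (grp in list(A = a, B = b)) {
    missing <- setdiff(grp, names(data))
    if (length(missing) > 0) {
      stop_bad_arg("sample columns not found: ",
                   paste(missing, collapse = ", "))
    }
  }
  if (length(a) < 2) stop_bad_arg("group A has fewer than 2 replicates")
  if (length(b) < 2) stop_bad_arg("group B has fewer than 2 replicates")
  if (length(intersect(a, b)) > 0) {
    stop_bad_arg("groups A and B share samples: ",
                 paste(intersect(a, b), collapse = ", "))
  }

  ma <- as.matrix(data[, a])
  mb <- as.matrix(data[, b])
  if (!all(is.finite(ma)) || !all(is.finite(mb))) {
    stop_bad_arg("expression values must be finite")
  }
  na <- length(a)
  nb <- length(b)
  d <- na + nb - 2
  mean_a <- rowMeans(ma)
  mean_b <- rowMeans(mb)
  log2_fc <- mean_b - mean_a
  var_a <- apply(ma, 1, stats::var)
  var_b <- apply(mb, 1, stats::var)
  s2 <- ((na - 1) * var_a + (nb - 1) * var_b) / d

  if (is.null(prior)) prior <- estimate_ebayes_prior(s2, d)
  stopifnot(inherits(prior, "ebayes_prior"))
  d0 <- prior$d0
  s0 <- prior$s0_sq
  s2_tilde <- if (is.finite(d0)) (d0 * s0 + d * s2) / (d0 + d) else rep(s0, length(s2))

  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, log2_fc / se, ifelse(log2_fc == 0, 0, Inf * sign(log2_fc)))
  df_total <- d0 + d
  p <- if (is.finite(d0)) {
    2 * stats::pt(-abs(t_mod), df = df_total)
  } else {
    2 * stats::pnorm(-abs(t_mod))
  }
  p[!is.finite(t_mod)] <- 0
  p[t_mod == 0] <- 1

  out <- tibble::tibble(
    gene_id = data[[gene_col]],
    mean_a = mean_a,
    mean_b = mean_b,
    log2_fc = log2_fc,
    s2 = s2,
    df_residual = d,
    t_mod = t_mod,
    df_total = df_total,
    p_value = p,
    q_value = adjust_bh(p)
  )
  attr(out, "prior") <- prior
  class(out) <- c("group_comparison", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} (m * p_(j) / j)` capped at 1, returned in the
#' original order. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    stop_bad_arg("`p` must be numeric p-values in [0, 1]")
  }
  if (length(p) == 0) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Call deregulated genes by fold-change and p-value cut-offs
#'
#' Tri-state call per gene: `up` when `log2_fc >= log2(fc_min)` and the
#' p-criterion holds, `down` symmetrically, `unchanged` otherwise. The
#' canonical cut-off is a fold change of at least two with p < 0.05.
#'
#' @param comparison A [moderated_t()] result (or any data frame with
#'   `gene_id`, `log2_fc`, `p_value`, `q_value`).
#' @param fc_min Minimum linear-scale fold change (>= 1). Default 2.
#' @param p_max Significance cut-off. Default 0.05.
#' @param use_adjusted Use BH-adjusted `q_value` instead of raw `p_value`?
#'   Default `FALSE`.
#' @param p_comparison `"strict"` (`p < p_max`, default) or `"inclusive"`
#'   (`p <= p_max`).
#' @return A tibble of class `"deregulation_calls"` with `gene_id`,
#'   `log2_fc`, `p_used` and `call` (factor up/down/unchanged); the count
#'   triple is attached as attribute `"counts"` and available via
#'   [deregulation_counts()].
#' @examples
#' cmp <- tibble::tibble(gene_id = c("a", "b"), log2_fc = c(1.5, 0.2),
#'                       p_value = c(0.01, 0.5), q_value = c(0.02, 0.5))
#' call_deregulated(cmp)
#' @export
call_deregulated <- function(comparison, fc_min = 2, p_max = 0.05,
                             use_adjusted = FALSE,
                             p_comparison = c("strict", "inclusive")) {
  p_comparison <- match.arg(p_comparison)
  check_number(p_max, "p_max", lower = 0, upper = 1)
  check_flag(use_adjusted, "use_adjusted")
  if (!is.numeric(fc_min) || length(fc_min) != 1 || is.na(fc_min) ||
      fc_min < 1) {
    stop_bad_arg("`fc_min` must be a single number >= 1")
  }
  need <- c("gene_id", "log2_fc", if (use_adjusted) "q_value" else "p_value")
  stopifnot(is.data.frame(comparison), all(need %in% names(comparison)))

  p_used <- if (use_adjusted) comparison$q_value else comparison$p_value
  p_ok <- if (p_comparison == "strict") p_used < p_max else p_used <= p_max
  thr <- log2(fc_min)
  call <- dplyr::case_when(
    comparison$log2_fc >= thr & p_ok ~ "up",
    comparison$log2_fc <= -thr & p_ok ~ "down",
    TRUE ~ "unchanged"
  )
  out <- tibble::tibble(
    gene_id = comparison$gene_id,
    log2_fc = comparison$log2_fc,
    p_used = p_used,
    call = factor(call, levels = c("up", "down", "unchanged"))
  )
  counts <- as.list(table(out$call))
  attr(out, "counts") <- list(n_up = counts$up, n_down = counts$down,
                              n_unchanged = counts$unchanged)
  attr(out, "thresholds") <- list(fc_min = fc_min, p_max = p_max,
                                  use_adjusted = use_adjusted,
                                  p_comparison = p_comparison)
  class(out) <- c("deregulation_calls", class(out))
  out
}

#' @describeIn call_deregulated Extract the `(n_up, n_down, n_unchanged)`
#'   counts of a call table.
#' @param calls A `deregulation_calls` tibble.
#' @export
deregulation_counts <- function(calls) {
  counts <- attr(calls, "counts")
  if (is.null(counts)) {
    tab <- table(factor(calls$call, levels = c("up", "down", "unchanged")))
    counts <- list(n_up = unname(tab[["up"]]), n_down = unname(tab[["down"]]),
                   n_unchanged = unname(tab[["unchanged"]]))
  }
  counts
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Computes, for each sample, `dCt = Ct(target) - mean(Ct(reference
#' genes))`, then `ddCt = dCt - mean(dCt over reference-condition samples)`
#' and the fold change `2^-ddCt`.
#'
#' @param data Long-format tibble with columns `sample_id`, `condition`,
#'   `gene`, `ct` (one row per well mean).
#' @param target_gene Name of the gene of interest.
#' @param reference_condition Condition the fold changes are relative to.
#' @param reference_genes Internal-control genes; default: every gene other
#'   than `target_gene`.
#' @return A tibble with `sample_id`, `condition`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`.
#' @examples
#' qpcr <- tibble::tibble(
#'   sample_id = rep(c("c1", "k1"), each = 2),
#'   condition = rep(c("control", "knockout"), each = 2),
#'   gene = rep(c("Target", "Gapdh"), 2),
#'   ct = c(24, 20, 23, 20)
#' )
#' ddct_fold_change(qpcr, "Target", "control")
#' @export
ddct_fold_change <- function(data, target_gene, reference_condition,
                             reference_genes = NULL) {
  need <- c("sample_id", "condition", "gene", "ct")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  if (!all(is.finite(data$ct)) || any(data$ct <= 0)) {
    stop_bad_arg("all Ct values must be finite and > 0")
  }
  if (!target_gene %in% data$gene) {
    stop_bad_arg("target gene not present: ", target_gene)
  }
  reference_genes <- reference_genes %||% setdiff(unique(data$gene),
                                                  target_gene)
  if (length(reference_genes) < 1) {
    stop_bad_arg("at least one reference gene is required")
  }
  if (!reference_condition %in% data$condition) {
    stop_bad_arg("reference condition not present: ", reference_condition)
  }

  per_sample <- lapply(split(data, data$sample_id), function(df) {
    sid <- df$sample_id[1]
    ct_target <- df$ct[df$gene == target_gene]
    if (length(ct_target) != 1) {
      stop_bad_arg("sample ", sid, ": expected exactly one Ct for ",
                   target_gene, ", got ", length(ct_target))
    }
    refs <- df$ct[df$gene %in% reference_genes]
    missing <- setdiff(reference_genes, df$gene)
    if (length(missing) > 0) {
      stop_bad_arg("sample ", sid, ": missing reference gene Ct for ",
                   paste(missing, collapse = ", "))
    }
    tibble::tibble(sample_id = sid, condition = df$condition[1],
                   delta_ct = ct_target - mean(refs))
  })
  out <- dplyr::bind_rows(per_sample)
  ref_mean <- mean(out$delta_ct[out$condition == reference_condition])
  out$delta_delta_ct <- out$delta_ct - ref_mean
  out$fold_change <- 2^(-out$delta_delta_ct)
  out
}
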