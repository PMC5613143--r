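# Shared fixtures, built once per test run and cached in-process.

.fixture_cache <- new.env(parent = emptyenv())

cached_sim <- function(n_genes = 1500, seed = 7, ...) {
  key <- paste("sim", n_genes, seed, paste(c(...), collapse = "_"), sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_study(
      synthetic_config(n_genes = n_genes, seed = seed, ...)
    )
  }
  .fixture_cache[[key]]
}

# Truth-label gene table without the (expensive) sequence generation, for
# expression-only tests.
synth_genes <- function(n, seed, cfg = synthetic_config(n_genes = n)) {
  set.seed(seed)
  classes <- names(cfg$class_fractions)
  class <- sample(classes, n, replace = TRUE, prob = cfg$class_fractions)
  tibble::tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    class = factor(class, levels = classes),
    is_ko_target = class != "stabilized" & stats::runif(n) < cfg$ko_target_fraction
  )
}

# A degenerate-noise-safe prior for zero-noise fixtures.
flat_prior <- function(s0_sq = 1e-6) {
  structure(list(d0 = Inf, s0_sq = s0_sq, d = 4, n_genes = NA_integer_),
            class = "ebayes_prior")
}

# Hand-rolled occurrence_matrix construction for profile/enrichment tests.
manual_om <- function(mat, flank_len = ncol(mat) / 2, anchor = "stop_codon",
                      set_label = NULL) {
  colnames(mat) <- as.character(seq(-flank_len, flank_len - 1))
  rownames(mat) <- rownames(mat) %||% sprintf("t%04d", seq_len(nrow(mat)))
  structure(list(matrix = mat, anchor = anchor, flank_len = flank_len,
                 pattern = "GAC[UA]", set_label = set_label),
            class = "occurrence_matrix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
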