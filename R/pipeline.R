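pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    force = FALSE,
    simulate = list(),
    inputs = NULL,
    dosage = list(fc_min = 2, p_max = 0.05, use_adjusted = FALSE,
                  p_comparison = "strict"),
    maturation = list(fc_min = 2, p_max = 0.05, use_adjusted = FALSE,
                      p_comparison = "inclusive", normalize = TRUE),
    motif = list(set_size = 1000, flank_len = 400, pattern = NULL,
                 smoother = "spline"),
    metagene = list(body_bins = 100, flank_nt = 400, flank_bin_nt = 10,
                    mode = "binary")
  )
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_bad_arg("`config` must be a list or a YAML path")
  merge_config(pipeline_defaults(), config)
}

#' Validate a pipeline configuration
#'
#' Checks a configuration (R list or YAML file path) against every
#' constraint [run_pipeline()] relies on and returns the problems found —
#' an empty result means the configuration is runnable. The configuration
#' either carries a `simulate` block (parameters forwarded to
#' [synthetic_config()]; a `seed` is then required) or an `inputs` block
#' with paths `fasta`, `expression`, `annotation`, `peaks`.
#'
#' @param config A named list or path to a YAML file.
#' @return A tibble with columns `field` and `problem`; zero rows iff the
#'   configuration is runnable.
#' @export
validate_config <- function(config) {
  problems <- list()
  note <- function(field, problem) {
    problems[[length(problems) + 1]] <<- tibble::tibble(field = field,
                                                        problem = problem)
  }
  cfg <- tryCatch(load_config(config), error = function(e) {
    note("config", conditionMessage(e))
    NULL
  })
  if (is.null(cfg)) return(dplyr::bind_rows(problems))

  simulate_mode <- is.null(cfg$inputs)
  if (simulate_mode) {
    if (is.null(cfg$seed) && is.null(cfg$simulate$seed)) {
      note("seed", "a seed is required when simulating")
    }
    sim_check <- tryCatch({
      do.call(synthetic_config, c(cfg$simulate,
                                  if (is.null(cfg$simulate$seed))
                                    list(seed = cfg$seed %||% 1L)))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(sim_check)) note("simulate", sim_check)
    cf <- cfg$simulate$class_fractions
    if (!is.null(cf) && abs(sum(unlist(cf)) - 1) > 1e-9) {
      note("simulate$class_fractions",
           sprintf("must sum to 1 (got %g)", sum(unlist(cf))))
    }
    n_genes <- cfg$simulate$n_genes %||% 6000
    if (n_genes < 3 * cfg$motif$set_size) {
      note("motif$set_size",
           sprintf("n_genes = %d cannot supply 3 disjoint sets of %d",
                   as.integer(n_genes), as.integer(cfg$motif$set_size)))
    }
  } else {
    for (nm in c("fasta", "expression", "annotation", "peaks")) {
      path <- cfg$inputs[[nm]]
      if (is.null(path)) {
        note(paste0("inputs$", nm), "path is required in non-simulate mode")
      } else if (!file.exists(path)) {
        note(paste0("inputs$", nm), paste0("file does not exist: ", path))
      }
    }
  }
  for (block in c("dosage", "maturation")) {
    fc <- cfg[[block]]$fc_min
    if (!is.numeric(fc) || fc < 1) {
      note(paste0(block, "$fc_min"), "must be a number >= 1")
    }
    pm <- cfg[[block]]$p_max
    if (!is.numeric(pm) || pm <= 0 || pm > 1) {
      note(paste0(block, "$p_max"), "must be in (0, 1]")
    }
    if (!cfg[[block]]$p_comparison %in% c("strict", "inclusive")) {
      note(paste0(block, "$p_comparison"),
           "must be 'strict' or 'inclusive'")
    }
  }
  if (cfg$motif$set_size < 1) note("motif$set_size", "must be >= 1")
  pat <- tryCatch({
    parse_motif_pattern(cfg$motif$pattern %||% "GAC[UA]")
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(pat)) note("motif$pattern", pat)
  if (cfg$metagene$flank_nt %% cfg$metagene$flank_bin_nt != 0) {
    note("metagene$flank_bin_nt", "must divide metagene$flank_nt")
  }
  if (length(problems) == 0) {
    tibble::tibble(field = character(0), problem = character(0))
  } else {
    dplyr::bind_rows(problems)
  }
}

fmt_num <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)

#' Run the full maternal-dosage pipeline
#'
#' Orchestrates one reproducible run: simulate (or load) the study, call
#' knockout dosage changes at MII, classify maturation behaviour
#' (GV vs MII in controls, on total-equalised values by default),
#' cross-tabulate the gates, profile motif occurrences around stop and
#' start codons with hypergeometric enrichment of the upregulated and
#' downregulated sets against the unchanged set, and run the scale-regions
#' m6A metagene analysis with stop-region t-tests. Every stage writes its
#' artifact under `out_dir`; `report.json` (machine-readable) and
#' `report.md` (human-readable) contain identical numbers, and rerunning
#' with the same configuration reproduces `report.json` byte for byte.
#' Timing and artifact checksums go to `run.log`.
#'
#' @param config A named list or YAML path; see [validate_config()].
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return (Invisibly) the report as a list of class `"run_report"`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- load_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop_bad_arg("an output directory is required")
  problems <- validate_config(cfg)
  if (nrow(problems) > 0) {
    stop_bad_arg("invalid configuration:\n",
                 paste(sprintf("  - %s: %s", problems$field,
                               problems$problem), collapse = "\n"))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    result <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_msg("stage %-10s done in %.1fs", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    result
  }

  # --- data -----------------------------------------------------------
  data <- run_stage("data", {
    if (is.null(cfg$inputs)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      scfg <- do.call(synthetic_config, sim_args)
      sim <- simulate_study(scfg)
      # the fixture dir belongs to this run; reruns overwrite it
      write_fixture(sim, file.path(cfg$out_dir, "fixture"), force = TRUE)
      list(study = sim$study, transcripts = sim$transcripts,
           models = sim$models, peaks = sim$peaks, config = scfg)
    } else {
      ann <- read_transcript_annotation(cfg$inputs$annotation)
      fasta <- read_transcripts_fasta(cfg$inputs$fasta)
      transcripts <- dplyr::inner_join(ann, fasta, by = "transcript_id")
      if (!all(c("contig", "strand") %in% names(transcripts))) {
        transcripts$contig <- paste0("ctg_", transcripts$gene_id)
        transcripts$strand <- "+"
      }
      models <- tibble::tibble(
        gene_id = transcripts$gene_id,
        contig = transcripts$contig,
        strand = transcripts$strand,
        exon_start = 0L,
        exon_end = transcripts$length %||% nchar(transcripts$sequence),
        start_codon_pos = ifelse(transcripts$strand == "+",
                                 transcripts$cds_start,
                                 transcripts$length - 1L - transcripts$cds_start),
        stop_codon_pos = ifelse(transcripts$strand == "+",
                                transcripts$stop_start,
                                transcripts$length - 1L - transcripts$stop_start)
      )
      list(study = read_expression_study(cfg$inputs$expression),
           transcripts = transcripts, models = models,
           peaks = read_peaks_bed(cfg$inputs$peaks), config = NULL)
    }
  })
  study <- data$study
  expr <- as_tibble.expression_study(study)

  # --- knockout dosage at MII ----------------------------------------
  dosage <- run_stage("dosage", {
    cmp <- moderated_t(expr,
                       a = sample_ids(study, "MII", "CTL"),
                       b = sample_ids(study, "MII", "mCKO"))
    calls <- call_deregulated(cmp, fc_min = cfg$dosage$fc_min,
                              p_max = cfg$dosage$p_max,
                              use_adjusted = cfg$dosage$use_adjusted,
                              p_comparison = cfg$dosage$p_comparison)
    readr::write_tsv(
      dplyr::left_join(tibble::as_tibble(cmp),
                       calls[, c("gene_id", "call")], by = "gene_id"),
      file.path(cfg$out_dir, "dosage_mii_ko_vs_ctl.tsv")
    )
    list(comparison = cmp, calls = calls)
  })

  # --- maturation classes (GV vs MII, controls) ----------------------
  maturation <- run_stage("maturation", {
    mat_expr <- if (isTRUE(cfg$maturation$normalize)) {
      normalize_total(expr)
    } else {
      expr
    }
    cmp <- moderated_t(mat_expr,
                       a = sample_ids(study, "GV", "CTL"),
                       b = sample_ids(study, "MII", "CTL"))
    classes <- classify_maturation(cmp, fc_min = cfg$maturation$fc_min,
                                   p_max = cfg$maturation$p_max,
                                   use_adjusted = cfg$maturation$use_adjusted,
                                   p_comparison = cfg$maturation$p_comparison)
    readr::write_tsv(classes,
                     file.path(cfg$out_dir, "maturation_classes.tsv"))
    list(comparison = cmp, classes = classes)
  })

  # --- gates ----------------------------------------------------------
  gates <- run_stage("gates", {
    gt <- gate_crosstab(dosage$calls, maturation$classes)
    readr::write_tsv(tidy(gt), file.path(cfg$out_dir, "gate_table.tsv"))
    gt
  })

  # --- motif profiling ------------------------------------------------
  motif <- run_stage("motif", {
    pattern <- cfg$motif$pattern %||%
      (data$config$motif_pattern %||% "GAC[UA]")
    ranked <- dedupe_and_rank(dosage$comparison, data$transcripts)
    sets <- select_sets(ranked, set_size = cfg$motif$set_size)
    anchors <- c("stop_codon", "start_codon")
    out <- list(sets = sets, matrices = list(), profiles = list(),
                enrichment = list())
    for (anchor in anchors) {
      for (lab in levels(sets$set_label)) {
        block <- sets[sets$set_label == lab, ]
        om <- build_occurrence_matrix(block, anchor = anchor,
                                      flank_len = cfg$motif$flank_len,
                                      pattern = pattern, set_label = lab)
        out$matrices[[anchor]][[lab]] <- om
        out$profiles[[anchor]][[lab]] <-
          positional_profile(om, smoother = cfg$motif$smoother)
      }
      for (lab in c("upregulated", "downregulated")) {
        out$enrichment[[anchor]][[paste0(lab, "_vs_unchanged")]] <-
          enrichment_test(out$matrices[[anchor]][[lab]],
                          out$matrices[[anchor]][["unchanged"]])
      }
    }
    prof_tbl <- dplyr::bind_rows(lapply(anchors, function(anchor) {
      dplyr::bind_rows(lapply(levels(sets$set_label), function(lab) {
        p <- out$profiles[[anchor]][[lab]]
        tibble::tibble(anchor = anchor, set_label = lab,
                       offset = p$offset, raw = p$raw, smoothed = p$smoothed)
      }))
    }))
    readr::write_tsv(prof_tbl, file.path(cfg$out_dir, "motif_profiles.tsv"))
    out
  })

  # --- metagene -------------------------------------------------------
  metagene <- run_stage("metagene", {
    track <- condense_samples(data$peaks)
    mm <- metagene_matrix(data$models, track,
                          body_bins = cfg$metagene$body_bins,
                          flank_nt = cfg$metagene$flank_nt,
                          flank_bin_nt = cfg$metagene$flank_bin_nt,
                          mode = cfg$metagene$mode)
    sets <- motif$sets
    gene_sets <- lapply(split(sets$gene_id, sets$set_label), function(ids) {
      intersect(ids, rownames(mm$matrix))
    })
    gp <- group_profiles(mm, gene_sets)
    readr::write_tsv(tibble::as_tibble(gp),
                     file.path(cfg$out_dir, "metagene_profiles.tsv"))
    tests <- list(
      upregulated_vs_unchanged = stop_region_ttest(
        mm, gene_sets$upregulated, gene_sets$unchanged
      ),
      downregulated_vs_unchanged = stop_region_ttest(
        mm, gene_sets$downregulated, gene_sets$unchanged
      )
    )
    list(matrix = mm, profiles = gp, tests = tests)
  })

  # --- report ---------------------------------------------------------
  report <- run_stage("report", {
    counts <- deregulation_counts(dosage$calls)
    class_counts <- as.list(table(maturation$classes$class))
    enr <- lapply(motif$enrichment, function(by_anchor) {
      lapply(by_anchor, function(e) {
        list(k = e$k, K = e$K, n = e$n, N = e$N, p_value = e$p_value)
      })
    })
    mg <- lapply(metagene$tests, function(t) {
      list(statistic = t$statistic, df = t$df, p_value = t$p_value,
           mean_a = t$mean_a, mean_b = t$mean_b)
    })
    rep <- list(
      package = "matdosage",
      version = as.character(utils::packageVersion("matdosage")),
      seed = cfg$seed %||% cfg$simulate$seed,
      parameters = list(
        n_genes = if (!is.null(data$config)) data$config$n_genes else
          nrow(study$matrix),
        dosage = cfg$dosage,
        maturation = cfg$maturation,
        motif = list(set_size = cfg$motif$set_size,
                     flank_len = cfg$motif$flank_len,
                     pattern = cfg$motif$pattern %||%
                       (data$config$motif_pattern %||% "GAC[UA]"),
                     smoother = cfg$motif$smoother),
        metagene = cfg$metagene
      ),
      dosage = counts,
      maturation = class_counts,
      gates = list(
        counts = apply(gates$counts, 1, as.list, simplify = FALSE),
        up_row_fractions = as.list(gates$up_row_fractions)
      ),
      motif_enrichment = enr,
      metagene_tests = mg
    )
    json_path <- file.path(cfg$out_dir, "report.json")
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    md <- c(
      "# Maternal transcript dosage run report",
      "",
      sprintf("- package: %s %s", rep$package, rep$version),
      sprintf("- seed: %s", fmt_num(rep$seed)),
      sprintf("- genes: %s", fmt_num(rep$parameters$n_genes)),
      "",
      "## Knockout dosage calls (MII)",
      sprintf("- up: %s, down: %s, unchanged: %s",
              fmt_num(counts$n_up), fmt_num(counts$n_down),
              fmt_num(counts$n_unchanged)),
      "",
      "## Maturation classes (GV vs MII, controls)",
      sprintf("- stabilized: %s, destabilized: %s, unchanged: %s",
              fmt_num(class_counts$stabilized),
              fmt_num(class_counts$destabilized),
              fmt_num(class_counts$unchanged)),
      "",
      "## Gate table (knockout call x maturation class)",
      sprintf("- %s: stabilized %s, destabilized %s, unchanged %s",
              rownames(gates$counts),
              vapply(rownames(gates$counts), function(r)
                fmt_num(gates$counts[r, "stabilized"]), ""),
              vapply(rownames(gates$counts), function(r)
                fmt_num(gates$counts[r, "destabilized"]), ""),
              vapply(rownames(gates$counts), function(r)
                fmt_num(gates$counts[r, "unchanged"]), "")),
      "",
      "## Motif enrichment (hypergeometric, vs unchanged set)",
      unlist(lapply(names(enr), function(anchor) {
        vapply(names(enr[[anchor]]), function(nm) {
          e <- enr[[anchor]][[nm]]
          sprintf("- %s, %s: k = %s of n = %s (K = %s of N = %s), p = %s",
                  anchor, nm, fmt_num(e$k), fmt_num(e$n), fmt_num(e$K),
                  fmt_num(e$N), fmt_num(e$p_value))
        }, "")
      })),
      "",
      "## Metagene stop-region t-tests",
      vapply(names(mg), function(nm) {
        t <- mg[[nm]]
        sprintf("- %s: t = %s, df = %s, p = %s", nm,
                fmt_num(t$statistic), fmt_num(t$df), fmt_num(t$p_value))
      }, "")
    )
    writeLines(md, file.path(cfg$out_dir, "report.md"))
    rep
  })

  artifacts <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  artifacts <- setdiff(artifacts, log_path)
  hashes <- tools::md5sum(artifacts)
  log_lines <- c(log_lines,
                 sprintf("artifact %s md5 %s",
                         substring(artifacts, nchar(cfg$out_dir) + 2),
                         unname(hashes)))
  writeLines(log_lines, log_path)
  invisible(structure(report, class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s %s (seed %s)\n", x$package, x$version,
              x$seed))
  cat(sprintf("  dosage: %d up / %d down / %d unchanged\n",
              x$dosage$n_up, x$dosage$n_down, x$dosage$n_unchanged))
  for (anchor in names(x$motif_enrichment)) {
    for (nm in names(x$motif_enrichment[[anchor]])) {
      cat(sprintf("  motif %s %s: p = %.4g\n", anchor, nm,
                  x$motif_enrichment[[anchor]][[nm]]$p_value))
    }
  }
  for (nm in names(x$metagene_tests)) {
    cat(sprintf("  metagene %s: p = %.4g\n", nm,
                x$metagene_tests[[nm]]$p_value))
  }
  invisible(x)
}
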