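#' Write a synthetic study to disk as plain-text fixtures
#'
#' Writes four files to `out_dir`: `transcripts.fasta` (RNA sequences),
#' `expression.tsv` (log2 matrix, first column `gene_id`, sample columns
#' named `stage_genotype_rep`, trailing truth columns `maturation_class` and
#' `is_ko_target`), `annotation.tsv` (0-based transcript coordinates plus
#' contig/strand so gene models round-trip), and `peaks.bed` (BED6, 0-based
#' half-open, score in column 5, sample id encoded in the name as
#' `sample.pNNNNN`). All files round-trip losslessly through the package
#' readers ([read_expression_study()], [read_transcript_annotation()],
#' [read_transcripts_fasta()], [read_peaks_bed()]).
#'
#' @param sim A `synthetic_study` from [simulate_study()], or a list with
#'   elements `study`, `transcripts`, `models`, `peaks`.
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite existing files? Default `FALSE`: refuses if any
#'   output file already exists.
#' @return (Invisibly) a tibble manifest with `file`, `path` and `n_records`.
#' @export
write_fixture <- function(sim, out_dir, force = FALSE) {
  check_flag(force, "force")
  stopifnot(all(c("study", "transcripts", "models", "peaks") %in% names(sim)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- file.path(out_dir, c("transcripts.fasta", "expression.tsv",
                                "annotation.tsv", "peaks.bed"))
  names(paths) <- c("transcripts.fasta", "expression.tsv", "annotation.tsv",
                    "peaks.bed")
  existing <- paths[file.exists(paths)]
  if (length(existing) > 0 && !force) {
    stop_bad_arg(
      "refusing to overwrite existing files (use `force = TRUE`): ",
      paste(basename(existing), collapse = ", ")
    )
  }

  tr <- sim$transcripts
  seqs <- Biostrings::RNAStringSet(stats::setNames(tr$sequence,
                                                   tr$transcript_id))
  Biostrings::writeXStringSet(seqs, paths[["transcripts.fasta"]], width = 80)

  study <- sim$study
  expr <- as_tibble.expression_study(study)
  expr$maturation_class <- as.character(study$genes$class)
  expr$is_ko_target <- study$genes$is_ko_target
  readr::write_tsv(expr, paths[["expression.tsv"]])

  ann <- dplyr::left_join(
    tr[, c("transcript_id", "gene_id", "cds_start", "stop_start", "length")],
    sim$models[, c("gene_id", "contig", "strand")],
    by = "gene_id"
  )
  readr::write_tsv(ann, paths[["annotation.tsv"]])

  pk <- sim$peaks
  readr::write_tsv(
    pk[, c("contig", "start", "end", "name", "score", "strand")],
    paths[["peaks.bed"]], col_names = FALSE
  )

  manifest <- tibble::tibble(
    file = names(paths),
    path = unname(paths),
    n_records = c(nrow(tr), nrow(expr), nrow(ann), nrow(pk))
  )
  invisible(manifest)
}

#' Read an expression study fixture
#'
#' Reads an expression TSV whose first column is `gene_id` and whose sample
#' columns are named `stage_genotype_rep` (e.g. `MII_CTL_1`); optional
#' trailing `maturation_class` / `is_ko_target` columns are parsed as truth
#' labels.
#'
#' @param path Path to the TSV.
#' @return An `expression_study`.
#' @export
read_expression_study <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(df)) {
    stop_bad_arg("expression TSV must have a `gene_id` column: ", path)
  }
  sample_cols <- grep("^(GV|MII)_(CTL|mCKO)_\\d+$", names(df), value = TRUE)
  if (length(sample_cols) == 0) {
    stop_bad_arg("no sample columns named stage_genotype_rep found in ", path)
  }
  mat <- as.matrix(df[, sample_cols])
  rownames(mat) <- df$gene_id
  if (!all(is.finite(mat))) {
    stop_bad_arg("expression matrix contains non-finite values: ", path)
  }
  parts <- stringr::str_match(sample_cols, "^(GV|MII)_(CTL|mCKO)_(\\d+)$")
  samples <- tibble::tibble(
    sample_id = sample_cols,
    stage = parts[, 2],
    genotype = parts[, 3],
    replicate = as.integer(parts[, 4])
  )
  genes <- tibble::tibble(gene_id = df$gene_id)
  if ("maturation_class" %in% names(df)) {
    genes$class <- factor(df$maturation_class,
                          levels = c("stabilized", "destabilized", "unchanged"))
  }
  if ("is_ko_target" %in% names(df)) genes$is_ko_target <- df$is_ko_target
  structure(list(genes = genes, samples = samples, matrix = mat),
            class = "expression_study")
}

#' Read a transcript annotation TSV
#'
#' Expects at least `transcript_id`, `gene_id`, `cds_start`, `stop_start`
#' (0-based codon first-nucleotide indices); `length`, `contig` and `strand`
#' are carried through when present.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_transcript_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("transcript_id", "gene_id", "cds_start", "stop_start")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0) {
    stop_bad_arg("annotation TSV missing columns: ",
                 paste(missing, collapse = ", "))
  }
  bad <- ann$cds_start < 0 | ann$cds_start >= ann$stop_start
  if (any(bad)) {
    stop_bad_arg("invalid codon coordinates for: ",
                 paste(utils::head(ann$transcript_id[bad], 5), collapse = ", "))
  }
  for (col in intersect(c("cds_start", "stop_start", "length"), names(ann))) {
    ann[[col]] <- as.integer(ann[[col]])
  }
  ann
}

#' Read transcript sequences from FASTA
#'
#' Sequences are converted to the RNA alphabet (`T` becomes `U`), the
#' package-internal canonical form.
#'
#' @param path Path to a FASTA file (DNA or RNA alphabet).
#' @return A tibble with `transcript_id` and `sequence`.
#' @export
read_transcripts_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  tibble::tibble(
    transcript_id = names(seqs),
    sequence = unname(normalize_rna(as.character(seqs), what = path))
  )
}

#' Read peak intervals from BED
#'
#' Parses a BED file with at least five columns (contig, start, end, name,
#' score; 0-based half-open) into peak records. Malformed lines are reported
#' with their line numbers. When the peak name follows the
#' `sample.pNNNNN` convention used by [write_fixture()], the sample id is
#' recovered into a `sample_id` column (otherwise the name itself is used).
#'
#' @param path Path to the BED file.
#' @return A tibble with `contig`, `start`, `end`, `name`, `score`,
#'   `strand`, `sample_id`.
#' @export
read_peaks_bed <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  empty_tbl <- tibble::tibble(
    contig = character(0), start = integer(0), end = integer(0),
    name = character(0), score = numeric(0), strand = character(0),
    sample_id = character(0)
  )
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warning("empty BED file: ", path, call. = FALSE)
    return(empty_tbl)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5)) {
    stop_bad_arg("BED lines with fewer than 5 columns at line(s): ",
                 paste(utils::head(lineno[nf < 5], 5), collapse = ", "))
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3)))
  score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5)))
  bad <- is.na(start) | is.na(end) | is.na(score)
  if (any(bad)) {
    stop_bad_arg("unparseable BED coordinates/score at line(s): ",
                 paste(utils::head(lineno[bad], 5), collapse = ", "))
  }
  bad <- start >= end
  if (any(bad)) {
    stop_bad_arg("BED intervals with start >= end at line(s): ",
                 paste(utils::head(lineno[bad], 5), collapse = ", "))
  }
  name <- vapply(fields, `[`, "", 4)
  strand <- vapply(seq_along(fields), function(i) {
    if (nf[i] >= 6) fields[[i]][6] else "."
  }, "")
  tibble::tibble(
    contig = vapply(fields, `[`, "", 1),
    start = start,
    end = end,
    name = name,
    score = score,
    strand = strand,
    sample_id = ifelse(grepl("^.+\\.p\\d+$", name),
                       sub("\\.p\\d+$", "", name), name)
  )
}
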