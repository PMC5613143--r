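test_that("BED parsing handles clean, empty and malformed inputs", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t250\tpeak1\t7.5", path)
  pk <- read_peaks_bed(path)
  expect_equal(pk$contig, "chr1")
  expect_equal(pk$start, 100L)
  expect_equal(pk$end, 250L)
  expect_equal(pk$score, 7.5)
  expect_equal(pk$strand, ".")

  writeLines(character(0), path)
  expect_warning(pk0 <- read_peaks_bed(path), "empty")
  expect_equal(nrow(pk0), 0)

  writeLines(c("chr1\t100\t250\tp1\t1.0", "chr1\t300\t200\tp2\t1.0"), path)
  expect_error(read_peaks_bed(path), "start >= end at line\\(s\\): 2")

  writeLines(c("chr1\t100\t250\tp1\t1.0", "chr1\t1"), path)
  expect_error(read_peaks_bed(path), "fewer than 5 columns at line\\(s\\): 2")

  # round trip through a generated fixture of ~1000 peaks
  cfg <- synthetic_config(n_genes = 80, seed = 3, n_peak_samples = 12,
                          peak_background_rate = 1)
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_peaks_bed(file.path(dir, "peaks.bed"))
  expect_gt(nrow(back), 500)
  expect_identical(back$start, sim$peaks$start)
  expect_identical(back$end, sim$peaks$end)
  expect_identical(back$contig, sim$peaks$contig)
})

test_that("sample condensation merges overlaps with max-score union", {
  peaks <- tibble::tibble(
    contig = c("c1", "c1"), start = c(100L, 150L), end = c(200L, 300L),
    score = c(2, 5)
  )
  track <- condense_samples(peaks)
  expect_equal(track$start, 100L)
  expect_equal(track$end, 300L)
  expect_equal(track$score, 5)

  # disjoint input is untouched; condensation is idempotent
  disjoint <- tibble::tibble(
    contig = c("c1", "c1", "c2"), start = c(10L, 50L, 5L),
    end = c(20L, 80L, 9L), score = c(1, 2, 3)
  )
  track1 <- condense_samples(disjoint)
  expect_equal(track1$start, disjoint$start)
  expect_equal(track1$score, disjoint$score)
  track2 <- condense_samples(track1)
  expect_equal(tibble::as_tibble(track2), tibble::as_tibble(track1))

  # score rules
  expect_equal(condense_samples(peaks, score_rule = "mean")$score, 3.5)
  expect_equal(condense_samples(peaks, score_rule = "count")$score, 2)
  # min-score filter applies before merging
  expect_equal(condense_samples(peaks, min_score = 3)$start, 150L)
})

test_that("condensation matches a per-base boolean oracle on 10-kb contigs", {
  set.seed(111)
  contig_len <- 10000L
  for (rep_i in 1:5) {
    n <- 60
    start <- sample.int(contig_len - 400L, n)
    width <- sample(20:400, n, replace = TRUE)
    peaks <- tibble::tibble(
      contig = sample(c("cA", "cB"), n, TRUE),
      start = start, end = pmin(start + width, contig_len),
      score = runif(n, 1, 10)
    )
    track <- condense_samples(peaks)
    for (ctg in unique(peaks$contig)) {
      p <- peaks[peaks$contig == ctg, ]
      t <- track[track$contig == ctg, ]
      cov <- oracle_coverage(p$start, p$end, contig_len)
      # merged intervals are disjoint and sorted
      expect_true(all(t$start < t$end))
      if (nrow(t) > 1) expect_true(all(t$start[-1] >= t$end[-nrow(t)]))
      # union of bases is preserved exactly
      cov_track <- oracle_coverage(t$start, t$end, contig_len)
      expect_identical(cov_track, cov)
      # each merged score is the max of its contributors
      for (j in seq_len(nrow(t))) {
        contrib <- p$score[p$start < t$end[j] & p$end > t$start[j]]
        expect_equal(t$score[j], max(contrib))
      }
    }
  }
})

make_model <- function(gene_id = "g1", strand = "+", len = 1200L,
                       start_codon = 400L, stop_codon = 600L) {
  tibble::tibble(
    gene_id = gene_id, contig = paste0("ctg_", gene_id), strand = strand,
    exon_start = 0L, exon_end = len,
    start_codon_pos = start_codon, stop_codon_pos = stop_codon
  )
}

test_that("metagene binning: full coverage, flank halves, remainders", {
  model <- make_model()
  full <- tibble::tibble(contig = "ctg_g1", start = 0L, end = 1200L,
                         score = 2)
  mm <- metagene_matrix(model, full)
  expect_equal(dim(mm$matrix), c(1, 180))
  expect_equal(unname(mm$matrix[1, ]), rep(1, 180))

  # peak covering exactly the downstream half of the upstream flank:
  # upstream bins 21..40 are fully covered, everything else empty
  half <- tibble::tibble(contig = "ctg_g1", start = 200L, end = 400L,
                         score = 1)
  mm2 <- metagene_matrix(model, half)
  expect_equal(unname(mm2$matrix[1, 1:20]), rep(0, 20))
  expect_equal(unname(mm2$matrix[1, 21:40]), rep(1, 20))
  expect_equal(unname(mm2$matrix[1, 41:180]), rep(0, 140))

  # body remainder: body of 205 nt -> bins of 2 nt, last bin 7 nt
  model3 <- make_model(len = 1500L, start_codon = 500L, stop_codon = 705L)
  tail_peak <- tibble::tibble(contig = "ctg_g1", start = 698L, end = 705L,
                              score = 1)
  mm3 <- metagene_matrix(model3, tail_peak)
  body <- mm3$body_cols
  expect_equal(unname(mm3$matrix[1, body[100]]), 1) # last bin fully covered
  expect_equal(sum(mm3$matrix[1, body[1:99]]), 0)

  # score mode weights by score density
  mm4 <- metagene_matrix(model, full, mode = "score")
  expect_equal(unname(mm4$matrix[1, ]), rep(2, 180))

  # short bodies are skipped with a warning
  model5 <- dplyr::bind_rows(model, make_model("g2", stop_codon = 450L))
  expect_warning(mm5 <- metagene_matrix(model5, full), "skipped")
  expect_equal(rownames(mm5$matrix), "g1")

  expect_error(metagene_matrix(model, full, flank_bin_nt = 7), "divide")
})

test_that("metagene bin values match a per-base oracle and conserve coverage", {
  set.seed(121)
  for (rep_i in 1:4) {
    len <- 10000L
    start_codon <- sample(500:2000, 1)
    stop_codon <- start_codon + sample(150:6000, 1)
    model <- make_model(len = len, start_codon = start_codon,
                        stop_codon = stop_codon)
    n <- 40
    ps <- sample.int(len - 300L, n)
    peaks <- tibble::tibble(contig = "ctg_g1", start = ps,
                            end = pmin(ps + sample(30:300, n, TRUE), len),
                            score = 1)
    track <- condense_samples(peaks)
    mm <- metagene_matrix(model, track)
    cov <- oracle_coverage(track$start, track$end, len)

    expect_true(all(mm$matrix >= 0 & mm$matrix <= 1))

    # upstream flank bins, one by one
    for (b in 1:40) {
      lo <- start_codon - 400L + (b - 1L) * 10L
      expect_equal(unname(mm$matrix[1, b]),
                   oracle_covered_bases(cov, lo, lo + 10L) / 10,
                   label = sprintf("flank bin %d", b))
    }
    # whole-body conservation: sum(value * width) == covered bases in body
    body_len <- stop_codon - start_codon
    w <- body_len %/% 100L
    widths <- c(rep(w, 99), body_len - 99L * w)
    got <- sum(mm$matrix[1, mm$body_cols] * widths)
    expect_equal(got, oracle_covered_bases(cov, start_codon, stop_codon))
  }
})

test_that("minus-strand genes mirror their plus-strand twins", {
  len <- 2000L
  start_codon <- 600L
  stop_codon <- 1100L
  plus <- make_model("gp", "+", len, start_codon, stop_codon)
  # mirrored coordinates: genomic g on + maps to len - 1 - g on -
  minus <- make_model("gm", "-", len,
                      start_codon = len - 1L - start_codon,
                      stop_codon = len - 1L - stop_codon)
  set.seed(131)
  n <- 25
  ps <- sample.int(len - 200L, n)
  peaks_plus <- tibble::tibble(contig = "ctg_gp", start = ps,
                               end = ps + sample(20:150, n, TRUE),
                               score = 1)
  peaks_minus <- tibble::tibble(contig = "ctg_gm",
                                start = len - peaks_plus$end,
                                end = len - peaks_plus$start,
                                score = 1)
  track <- condense_samples(dplyr::bind_rows(peaks_plus, peaks_minus))
  mm <- metagene_matrix(dplyr::bind_rows(plus, minus), track)
  expect_equal(unname(mm$matrix["gp", ]), unname(mm$matrix["gm", ]))
})

test_that("group profiles are column means with exact bookkeeping", {
  model <- dplyr::bind_rows(lapply(1:6, function(i) {
    make_model(sprintf("g%d", i))
  }))
  set.seed(141)
  peaks <- tibble::tibble(
    contig = sample(model$contig, 30, TRUE),
    start = sample.int(1000L, 30), score = 1
  )
  peaks$end <- pmin(peaks$start + 120L, 1200L)
  mm <- metagene_matrix(model, condense_samples(peaks))

  gp1 <- group_profiles(mm, list(solo = "g1"))
  expect_equal(gp1$mean, unname(mm$matrix["g1", ]))
  expect_equal(unique(gp1$n_genes), 1)

  # identical rows give zero sd; means equal brute-force column averages
  gp2 <- group_profiles(mm, list(pair = c("g2", "g2")))
  expect_true(all(gp2$sd == 0))
  ids <- c("g1", "g3", "g5")
  gp3 <- group_profiles(mm, list(trio = ids))
  manual <- vapply(seq_len(ncol(mm$matrix)), function(j) {
    mean(mm$matrix[ids, j])
  }, numeric(1))
  expect_equal(gp3$mean, manual)
  expect_equal(unique(gp3$region[gp3$bin %in% mm$downstream_cols]),
               "downstream")

  expect_error(group_profiles(mm, list(bad = character(0))), "empty gene set")
  expect_error(group_profiles(mm, list(bad = "nope")), "absent")
})

test_that("stop-region t-test behaves at the null and under large effects", {
  # identical sets: t = 0, p = 1
  model <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_model(sprintf("g%d", i))
  }))
  set.seed(151)
  peaks <- tibble::tibble(contig = sample(model$contig, 40, TRUE),
                          start = sample.int(1000L, 40), score = 1)
  peaks$end <- peaks$start + 150L
  mm <- metagene_matrix(model, condense_samples(peaks))
  ids <- sprintf("g%d", 1:10)
  same <- stop_region_ttest(mm, ids, ids)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(stop_region_ttest(mm, "g1", ids), "fewer than 2")
  expect_error(stop_region_ttest(mm, ids, ids, region_bins = 999L),
               "valid bin indices")

  # constructed large effect: p < 1e-10
  set.seed(152)
  big <- matrix(0, nrow = 400, ncol = 180,
                dimnames = list(sprintf("h%03d", 1:400), NULL))
  big[1:200, 141:180] <- pmin(1, pmax(0, rnorm(200 * 40, 0.5, 0.1)))
  big[201:400, 141:180] <- pmin(1, pmax(0, rnorm(200 * 40, 0.1, 0.1)))
  mm_big <- mm
  mm_big$matrix <- big
  tt <- stop_region_ttest(mm_big, rownames(big)[1:200], rownames(big)[201:400])
  expect_lt(tt$p_value, 1e-10)
  expect_equal(tt$region_bins, 141:180)

  # pooled variant runs and agrees with stats::t.test
  tt_pooled <- stop_region_ttest(mm_big, rownames(big)[1:200],
                                 rownames(big)[201:400], var_equal = TRUE)
  ref <- stats::t.test(rowMeans(big[1:200, 141:180]),
                       rowMeans(big[201:400, 141:180]), var.equal = TRUE)
  expect_equal(tt_pooled$statistic, unname(ref$statistic))
})

test_that("planted m6A peaks localise at the stop codon in the metagene", {
  sim <- cached_sim(n_genes = 1500, seed = 7)
  track <- condense_samples(sim$peaks)
  mm <- metagene_matrix(sim$models, track)
  targets <- sim$genes$gene_id[sim$genes$is_ko_target]
  gp <- group_profiles(mm, list(target = targets))
  # maximal plateau centred at the body/downstream boundary (bin 140.5)
  mx <- max(gp$mean)
  plateau <- gp$bin[gp$mean > mx - 1e-9]
  expect_lte(abs(mean(range(plateau)) - 140.5), 5)

  # up-set enrichment is significant, down-set is not
  study <- sim$study
  cmp <- moderated_t(as_tibble(study),
                     a = sample_ids(study, "MII", "CTL"),
                     b = sample_ids(study, "MII", "mCKO"))
  sets <- select_sets(dedupe_and_rank(cmp, sim$transcripts), 500)
  gs <- lapply(split(sets$gene_id, sets$set_label), intersect,
               y = rownames(mm$matrix))
  expect_lt(stop_region_ttest(mm, gs$upregulated, gs$unchanged)$p_value,
            0.05)
  expect_gte(stop_region_ttest(mm, gs$downregulated, gs$unchanged)$p_value,
             0.05)
})
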