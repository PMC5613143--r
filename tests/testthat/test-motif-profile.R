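test_that("isoform deduplication keeps the highest |fold change| and unique sequences", {
  results <- tibble::tibble(
    transcript_id = c("t1a", "t1b", "t2a"),
    gene_id = c("g1", "g1", "g2"),
    log2_fc = c(1.2, 0.3, -0.5)
  )
  transcripts <- tibble::tibble(
    transcript_id = c("t1a", "t1b", "t2a"),
    gene_id = c("g1", "g1", "g2"),
    sequence = c("AAAA", "CCCC", "GGGG")
  )
  ranked <- dedupe_and_rank(results, transcripts)
  expect_equal(ranked$transcript_id, c("t1a", "t2a"))
  expect_equal(ranked$rank, 1:2)

  # identical sequences across genes: only the first-ranked survives
  transcripts2 <- transcripts
  transcripts2$sequence <- c("AAAA", "CCCC", "AAAA")
  ranked2 <- dedupe_and_rank(results, transcripts2)
  expect_equal(ranked2$transcript_id, "t1a")

  # missing sequences are an error naming the gene
  expect_error(
    dedupe_and_rank(tibble::tibble(gene_id = c("g1", "gX"),
                                   log2_fc = c(1, 2)),
                    transcripts),
    "gX"
  )
})

test_that("deduplication matches a brute-force two-pass oracle", {
  set.seed(61)
  n_genes <- 200
  gene_id <- sprintf("g%03d", sample(n_genes, 320, replace = TRUE))
  transcript_id <- sprintf("t%03d", seq_along(gene_id))
  # a limited sequence pool forces cross-gene duplicates
  seq_pool <- vapply(1:150, function(i) {
    paste(sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")
  }, "")
  transcripts <- tibble::tibble(
    transcript_id = transcript_id,
    gene_id = gene_id,
    sequence = sample(seq_pool, length(gene_id), replace = TRUE)
  )
  results <- tibble::tibble(
    transcript_id = transcript_id,
    gene_id = gene_id,
    log2_fc = round(rnorm(length(gene_id)), 2)
  )
  ranked <- dedupe_and_rank(results, transcripts)
  ref <- oracle_dedupe_rank(as.data.frame(results),
                            as.data.frame(transcripts))
  expect_equal(ranked$transcript_id, ref$transcript_id)
  expect_equal(ranked$log2_fc, ref$log2_fc)
  expect_false(any(duplicated(ranked$gene_id)))
  expect_false(any(duplicated(ranked$sequence)))
})

test_that("set selection tiles the ranked list with a centred middle block", {
  ranked <- tibble::tibble(gene_id = sprintf("g%04d", 1:3000),
                           transcript_id = sprintf("t%04d", 1:3000),
                           log2_fc = seq(3, -3, length.out = 3000))
  sets <- select_sets(ranked, 1000)
  up <- sets[sets$set_label == "upregulated", ]
  down <- sets[sets$set_label == "downregulated", ]
  centre <- sets[sets$set_label == "unchanged", ]
  expect_equal(up$gene_id, ranked$gene_id[1:1000])
  expect_equal(down$gene_id[1], ranked$gene_id[3000]) # most downregulated first
  expect_equal(centre$gene_id, ranked$gene_id[1001:2000])
  expect_equal(length(intersect(up$gene_id, centre$gene_id)), 0)

  # odd-length list: floor convention
  ranked2 <- ranked[1:3000, ]
  ranked2 <- dplyr::bind_rows(ranked2,
                              tibble::tibble(gene_id = "gx",
                                             transcript_id = "tx",
                                             log2_fc = -4))
  centre2 <- select_sets(ranked2, 1000)
  centre2 <- centre2[centre2$set_label == "unchanged", ]
  expect_equal(centre2$gene_id, ranked2$gene_id[1001:2000])

  sets3 <- select_sets(ranked[1:3, ], 1)
  expect_equal(sets3$gene_id[sets3$set_label == "upregulated"],
               ranked$gene_id[1])
  expect_equal(sets3$gene_id[sets3$set_label == "unchanged"],
               ranked$gene_id[2])
  expect_equal(sets3$gene_id[sets3$set_label == "downregulated"],
               ranked$gene_id[3])

  expect_error(select_sets(ranked[1:2999, ], 1000), "3 \\* set_size")
})

test_that("anchor windows slice and N-pad to exactly 2 * flank_len", {
  seq1000 <- paste(rep(c("A", "C", "G", "U"), 250), collapse = "")
  tr <- tibble::tibble(transcript_id = "t1", sequence = seq1000,
                       cds_start = 10, stop_start = 500)
  win <- extract_anchor_window(tr, "stop_codon", 400)
  expect_equal(nchar(win$window), 800)
  expect_equal(win$n_pad_left, 0L)
  expect_equal(win$n_pad_right, 0L)
  expect_equal(win$window, substr(seq1000, 101, 900))

  tr$stop_start <- 100
  win <- extract_anchor_window(tr, "stop_codon", 400)
  expect_equal(win$n_pad_left, 300L)
  expect_equal(substr(win$window, 1, 300), strrep("N", 300))

  tr$stop_start <- 997 # length - 3
  win <- extract_anchor_window(tr, "stop_codon", 400)
  expect_equal(win$n_pad_right, 397L)
  expect_equal(win$window, oracle_anchor_window(seq1000, 997, 400))

  # random transcripts against the naive slice-and-pad oracle
  set.seed(71)
  for (i in 1:25) {
    len <- sample(50:900, 1)
    s <- paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = "")
    anchor <- sample(0:(len - 3), 1)
    tr_i <- tibble::tibble(transcript_id = "t", sequence = s,
                           stop_start = anchor, cds_start = 0)
    win_i <- extract_anchor_window(tr_i, "stop_codon", 400)
    expect_equal(win_i$window, oracle_anchor_window(s, anchor, 400))
    expect_equal(nchar(win_i$window), 800)
  }
})

test_that("motif matching is an overlapping scan where N matches nothing", {
  expect_equal(motif_match_positions("GACU"), 0L)
  expect_equal(motif_match_positions("GACA"), 0L)
  expect_length(motif_match_positions("GACG"), 0)
  expect_equal(motif_match_positions("GACUGACA"), c(0L, 4L))
  expect_equal(motif_match_positions("GACACU"), 0L)
  expect_length(motif_match_positions("GACNGACN"), 0)
  expect_length(motif_match_positions("NNNNNNNN"), 0)
  # T input is converted to the RNA alphabet
  expect_equal(motif_match_positions("GACT"), 0L)
  # overlapping matches of a self-overlapping pattern
  expect_equal(motif_match_positions("AAAA", "AA"), c(0L, 1L, 2L))

  expect_error(motif_match_positions("GACU", "GA-U"), "malformed")
  expect_error(motif_match_positions("GACU", "GAC[UA"), "malformed")
  expect_error(motif_match_positions("GACU", ""), "malformed")
  expect_error(motif_match_positions("GACX"), "outside")

  set.seed(73)
  for (i in 1:50) {
    w <- paste(sample(c("A", "C", "G", "U", "N"), 200, TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    expect_identical(motif_match_positions(w),
                     oracle_match_positions(w, "GAC[UA]"))
    expect_identical(motif_match_positions(w, "GCA[UA]"),
                     oracle_match_positions(w, "GCA[UA]"))
  }
})

test_that("occurrence matrices have set-by-window geometry and exact row sums", {
  set.seed(79)
  n <- 40
  tr <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:n),
    sequence = vapply(1:n, function(i) {
      paste(sample(c("A", "C", "G", "U"), 600, TRUE), collapse = "")
    }, ""),
    cds_start = 30L,
    stop_start = 450L
  )
  om <- build_occurrence_matrix(tr, "stop_codon", flank_len = 100)
  expect_equal(dim(om$matrix), c(40, 200))
  expect_equal(colnames(om$matrix)[1], "-100")
  win <- extract_anchor_window(tr, "stop_codon", 100)
  for (i in seq_len(n)) {
    expect_equal(unname(rowSums(om$matrix)[i]),
                 length(motif_match_positions(win$window[i])))
  }
  # positions line up: a 1 at column j means a match starts at offset j
  hits <- tidy(om)
  for (r in sample(nrow(hits), min(20, nrow(hits)))) {
    i <- match(hits$transcript_id[r], tr$transcript_id)
    expect_true((hits$offset[r] + 100) %in%
                  (oracle_match_positions(win$window[i], "GAC[UA]")))
  }

  # permutation equivariance
  perm <- sample(n)
  om_p <- build_occurrence_matrix(tr[perm, ], "stop_codon", flank_len = 100)
  expect_identical(om_p$matrix, om$matrix[perm, ])

  # absent pattern: all-zero matrix
  om0 <- build_occurrence_matrix(tr, "stop_codon", flank_len = 100,
                                 pattern = "UUUUUUUUUU")
  expect_equal(sum(om0$matrix), 0)
})

test_that("positional profiles smooth the column sums sensibly", {
  # constant raw vector is reproduced by the spline
  mat <- matrix(0L, nrow = 10, ncol = 400)
  mat[1:5, ] <- 1L
  om <- manual_om(mat)
  prof <- positional_profile(om)
  expect_equal(prof$raw, rep(5, 400))
  expect_lt(max(abs(prof$smoothed - 5)), 1e-6 * 5)

  # a planted Gaussian bump at the anchor is localised by the smoother
  set.seed(83)
  offsets <- seq(-400, 399)
  bump <- 50 * exp(-offsets^2 / (2 * 30^2))
  raw <- rpois(800, bump + 1)
  mat_b <- do.call(rbind, lapply(1:60, function(i) {
    as.integer(rmultinom(1, size = round(sum(raw) / 60), prob = raw + 0.01)) > 0
  }))
  storage.mode(mat_b) <- "integer"
  om_b <- manual_om(mat_b)
  prof_b <- positional_profile(om_b)
  expect_lt(abs(prof_b$offset[which.max(prof_b$smoothed)]), 25)
  prof_l <- positional_profile(om_b, smoother = "loess")
  expect_lt(abs(prof_l$offset[which.max(prof_l$smoothed)]), 25)

  # very strong smoothing tends to the least-squares line
  set.seed(89)
  mat_r <- matrix(rbinom(20 * 400, 1, 0.3), nrow = 20)
  om_r <- manual_om(mat_r)
  prof_r <- positional_profile(om_r, smooth_param = 2)
  line <- unname(stats::lm(raw ~ offset, data = prof_r)$fitted.values)
  expect_lt(max(abs(prof_r$smoothed - pmax(0, line))), 0.05 * diff(range(prof_r$raw)))

  expect_error(positional_profile(manual_om(matrix(0L, 5, 8), flank_len = 4)),
               "fewer than 10")
})

test_that("hypergeometric enrichment equals exact combinatorial enumeration", {
  z20 <- manual_om(matrix(0L, 10, 20), flank_len = 10)

  # k = 0 -> P(X >= 0) = 1
  e0 <- enrichment_test(z20, z20)
  expect_equal(e0$p_value, 1)

  # N = 20, n = 10, K = 10, k = 9 against factorial enumeration
  m_test <- matrix(0L, 10, 20)
  m_test[1:9, 1] <- 1L
  m_ref <- matrix(0L, 10, 20)
  m_ref[1, 1] <- 1L
  e <- enrichment_test(manual_om(m_test, 10), manual_om(m_ref, 10))
  expect_equal(e$k, 9)
  expect_equal(e$K, 10)
  expect_equal(e$p_value, oracle_hyper_upper(9, 10, 10, 20),
               tolerance = 1e-12)

  # grid over N <= 60: enumeration oracle and phyper agree to 1e-12 relative
  set.seed(97)
  for (i in 1:150) {
    N <- sample(2:60, 1)
    n <- sample(1:(N - 1), 1)
    K <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    p_pkg <- matdosage:::hyper_upper_tail(k, K, n, N)
    p_oracle <- oracle_hyper_upper(k, K, n, N)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12,
                 label = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
    expect_equal(p_pkg, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # monotone nonincreasing in k at fixed (N, n, K)
  p_seq <- vapply(0:10, matdosage:::hyper_upper_tail, numeric(1),
                  K = 10, n = 10, N = 20)
  expect_true(all(diff(p_seq) <= 1e-15))

  # region restriction: matches outside the region do not count
  m2 <- matrix(0L, 10, 20)
  m2[, 1] <- 1L # offset -10 only
  e_regional <- enrichment_test(manual_om(m2, 10), z20, region = 0:9)
  expect_equal(e_regional$k, 0)
  expect_equal(e_regional$p_value, 1)
  expect_error(enrichment_test(manual_om(m2, 10), z20, region = integer(0)),
               "non-empty")
})

test_that("planted stop-codon motif enrichment is detected end to end", {
  sim <- cached_sim(n_genes = 1500, seed = 7)
  study <- sim$study
  cmp <- moderated_t(as_tibble(study),
                     a = sample_ids(study, "MII", "CTL"),
                     b = sample_ids(study, "MII", "mCKO"))
  ranked <- dedupe_and_rank(cmp, sim$transcripts)
  sets <- select_sets(ranked, set_size = 500)
  oms <- lapply(split(sets, sets$set_label), build_occurrence_matrix)
  expect_lt(enrichment_test(oms$upregulated, oms$unchanged)$p_value, 0.05)

  oms_start <- lapply(split(sets, sets$set_label), build_occurrence_matrix,
                      anchor = "start_codon")
  expect_gte(enrichment_test(oms_start$upregulated,
                             oms_start$unchanged)$p_value, 0.05)

  # smoothed profile of the up set dominates near the stop codon only
  prof_up <- positional_profile(oms$upregulated)
  prof_un <- positional_profile(oms$unchanged)
  band <- abs(prof_up$offset) <= 100
  expect_gt(mean(prof_up$smoothed[band]), mean(prof_un$smoothed[band]))
  prof_up_s <- positional_profile(oms_start$upregulated)
  prof_un_s <- positional_profile(oms_start$unchanged)
  expect_lte(mean(prof_up_s$smoothed[band]), mean(prof_un_s$smoothed[band]))
})
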