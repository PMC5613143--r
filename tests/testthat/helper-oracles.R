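# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately share no code with the package.

# --- motif matching ---------------------------------------------------

# Parse a bracket pattern into per-position allowed-base sets, by hand.
oracle_parse_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  allowed <- list()
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1
      grp <- character(0)
      while (chars[j] != "]") {
        grp <- c(grp, chars[j])
        j <- j + 1
      }
      allowed[[length(allowed) + 1]] <- grp
      i <- j + 1
    } else {
      allowed[[length(allowed) + 1]] <- chars[i]
      i <- i + 1
    }
  }
  allowed
}

# Character-by-character overlapping scan; returns 0-based start offsets.
oracle_match_positions <- function(window, pattern) {
  allowed <- oracle_parse_pattern(pattern)
  L <- length(allowed)
  chars <- strsplit(window, "")[[1]]
  W <- length(chars)
  if (W < L) return(integer(0))
  ok <- rep(TRUE, W - L + 1)
  for (o in seq_len(L)) {
    ok <- ok & chars[seq.int(o, W - L + o)] %in% allowed[[o]]
  }
  which(ok) - 1L
}

# Naive slice-and-pad window extraction (0-based anchor).
oracle_anchor_window <- function(sequence, anchor_pos, flank_len) {
  chars <- strsplit(sequence, "")[[1]]
  idx <- seq.int(anchor_pos - flank_len, anchor_pos + flank_len - 1) + 1
  out <- vapply(idx, function(i) {
    if (i >= 1 && i <= length(chars)) chars[i] else "N"
  }, "")
  paste(out, collapse = "")
}

# --- multiple testing -------------------------------------------------

# Literal step-up definition: q_(i) = min over j with p_(j) >= p_(i) of
# m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * p_sorted[i:m] / seq.int(i, m)))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# --- hypergeometric ---------------------------------------------------

# P(X >= k) by direct term enumeration with choose().
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- seq.int(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- eBayes prior -----------------------------------------------------

# Bisection on the moment equation trigamma(d0/2) = excess.
oracle_prior <- function(s2, d) {
  z <- log(s2[s2 > 0])
  excess <- stats::var(z) - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  } else {
    f <- function(half_d0) trigamma(half_d0) - excess
    lo <- 1e-8
    hi <- 1e8
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    d0 <- 2 * (lo + hi) / 2
    s0 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0)
}

# --- intervals --------------------------------------------------------

# Per-base boolean union of intervals on one contig of known length.
oracle_coverage <- function(starts, ends, contig_len) {
  cov <- logical(contig_len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) {
      cov[seq.int(starts[i] + 1, min(ends[i], contig_len))] <- TRUE
    }
  }
  cov
}

# Covered-base count of [start, end) under a boolean coverage vector.
oracle_covered_bases <- function(cov, start, end) {
  start <- max(0L, start)
  end <- min(length(cov), end)
  if (end <= start) return(0L)
  sum(cov[seq.int(start + 1, end)])
}

# --- transcript selection --------------------------------------------

# Two-pass filter: per gene keep max |fc| (tie: smallest transcript id),
# rank by signed fc descending, then first-seen unique sequences.
oracle_dedupe_rank <- function(results, transcripts) {
  merged <- merge(results, transcripts, by = c("transcript_id", "gene_id"))
  kept <- do.call(rbind, lapply(split(merged, merged$gene_id), function(df) {
    df <- df[order(-abs(df$log2_fc), df$transcript_id), ]
    df[1, ]
  }))
  kept <- kept[order(-kept$log2_fc, kept$transcript_id), ]
  seen <- character(0)
  keep <- logical(nrow(kept))
  for (i in seq_len(nrow(kept))) {
    if (!(kept$sequence[i] %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, kept$sequence[i])
    }
  }
  kept[keep, ]
}
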