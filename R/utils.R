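RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
      (!allow_inf && !is.finite(x)) || x < lower || x > upper) {
    stop_bad_arg(sprintf(
      "`%s` must be a single number in [%s, %s]", name,
      format(lower), format(upper)
    ))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    stop_bad_arg(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

# Normalise an RNA/DNA sequence string: uppercase, T -> U, validate alphabet.
normalize_rna <- function(x, what = "sequence", allow_n = TRUE) {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  alphabet <- if (allow_n) "ACGUN" else "ACGU"
  bad <- !grepl(sprintf("^[%s]*$", alphabet), x)
  if (any(bad)) {
    stop_bad_arg(sprintf(
      "%s contains characters outside {%s}",
      what, paste(strsplit(alphabet, "")[[1]], collapse = ",")
    ))
  }
  x
}

#' Parse an IUPAC-like bracket motif pattern
#'
#' Patterns are strings over `A`, `C`, `G`, `U` (or `T`, converted to `U`)
#' where a bracketed group such as `[UA]` matches any one of the enclosed
#' bases, e.g. the YTHDF2 consensus `"GAC[UA]"`. The parsed form records, for
#' each pattern position, the set of bases it accepts.
#'
#' @param pattern A single pattern string, e.g. `"GAC[UA]"`.
#' @return A list with elements `regex` (the normalised pattern, directly
#'   usable as a regular expression), `length` (number of positions) and
#'   `allowed` (list of allowed-base character vectors per position).
#' @keywords internal
parse_motif_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1 || is.na(pattern) ||
      !nzchar(pattern)) {
    stop_bad_arg("malformed motif pattern: must be a non-empty string")
  }
  norm <- gsub("T", "U", toupper(pattern), fixed = TRUE)
  if (!grepl("^([ACGU]|\\[[ACGU]+\\])+$", norm)) {
    stop_bad_arg("malformed motif pattern: ", pattern)
  }
  tokens <- regmatches(norm, gregexpr("\\[[ACGU]+\\]|[ACGU]", norm))[[1]]
  allowed <- lapply(tokens, function(tk) {
    unique(strsplit(gsub("\\[|\\]", "", tk), "")[[1]])
  })
  list(regex = norm, length = length(allowed), allowed = allowed)
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483646) + 1L
}
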