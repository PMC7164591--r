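# Independent brute-force oracles used to validate the package's kernels.
# These deliberately share no code with the implementation: plain string
# splitting, dictionary counting and textbook formulas.

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Dictionary k-mer count over every window, skipping windows containing
# characters outside ACGT.
oracle_kmer_count <- function(seq, k) {
  n <- nchar(seq)
  out <- setNames(rep(0L, 4^k), kmer_names(k))
  if (n < k) return(out)
  wins <- substring(seq, 1:(n - k + 1), k:n)
  wins <- wins[!grepl("[^ACGT]", wins)]
  tb <- table(wins)
  out[names(tb)] <- as.integer(tb)
  out
}

# All Hamming-distance hits of a spacer on both strands of a virus sequence,
# sliding one position at a time; windows containing non-ACGT text skipped.
oracle_spacer_hits <- function(virus, spacer, max_mm) {
  vc <- strsplit(virus, "", fixed = TRUE)[[1L]]
  scan_one <- function(pattern, strand) {
    pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
    m <- length(pc)
    n <- length(vc)
    if (m > n) {
      return(data.frame(start = integer(), strand = character(),
                        mismatches = integer()))
    }
    starts <- 1:(n - m + 1)
    mm <- integer(length(starts))
    has_n <- logical(length(starts))
    for (j in seq_len(m)) {
      ch <- vc[starts + j - 1L]
      mm <- mm + (ch != pc[[j]])
      has_n <- has_n | !(ch %in% c("A", "C", "G", "T"))
    }
    keep <- !has_n & mm <= max_mm
    data.frame(start = starts[keep], strand = rep(strand, sum(keep)),
               mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  rc <- paste(rev(chartr("ACGT", "TGCA",
                         strsplit(spacer, "", fixed = TRUE)[[1L]])),
              collapse = "")
  out <- rbind(scan_one(spacer, "+"), scan_one(rc, "-"))
  out[order(out$start, out$strand), , drop = FALSE]
}

# Textbook Pearson correlation from sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Phi coefficient from the 2x2 contingency table of two binary vectors.
oracle_phi <- function(x, y) {
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  c <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  (a * d - b * c) /
    sqrt((a + b) * (c + d) * (a + c) * (b + d))
}

# Brute-force largest terminal repeat: test every L from floor(n/2) down.
oracle_dtr <- function(seq, min_len = 1) {
  n <- nchar(seq)
  if (floor(n / 2) < min_len) return(0L)
  for (L in seq(floor(n / 2), min_len)) {
    if (substr(seq, 1, L) == substr(seq, n - L + 1, n)) return(L)
  }
  0L
}

seq_tbl <- function(seq, id = "s") tibble::tibble(id = id, seq = seq)
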