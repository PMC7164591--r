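# Structural characterisation of candidate viral contigs: direct terminal
# repeat (DTR) detection and base composition. A DTR — the same sequence
# duplicated exactly at both contig ends — is the standard assembler signature
# of a circular (or circularly permuted) genome.

#' Detect direct terminal repeats
#'
#' For each contig, finds the largest `L` with `min_len <= L <= floor(len/2)`
#' such that the length-`L` prefix equals the length-`L` suffix exactly
#' (character-exact match, no mismatches). `repeat_length` is 0 when no such
#' `L` exists. The cap at half the contig length prevents a homopolymer from
#' reporting itself as its own repeat. Because the assembler's duplicated end
#' inflates the apparent genome size, both the raw contig length and the
#' repeat-trimmed length are reported.
#'
#' @param seqs Sequence tibble (columns `id`, `seq`); every contig must be at
#'   least `2 * min_len` long.
#' @param min_len Minimum repeat length to accept (default 20; shorter
#'   end-matches are likely by chance).
#' @return A tibble with one row per contig: `id`, `length`, `repeat_length`,
#'   `suffix_start` (1-based start of the terminal copy, `NA` if none),
#'   `trimmed_length` (`length - repeat_length`), `gc_percent`, and
#'   `is_circular_candidate`.
#' @export
#' @examples
#' detect_terminal_repeat(
#'   tibble::tibble(id = "c1", seq = "ATGCCGTTATGCCG"), min_len = 4
#' )
detect_terminal_repeat <- function(seqs, min_len = 20) {
  seqs <- check_seq_tbl(seqs)
  if (min_len < 1) abort("min_len must be >= 1")
  n <- nchar(seqs$seq)
  short <- which(n < 2 * min_len)
  if (length(short) > 0L) {
    abort(sprintf("contig '%s' is shorter than 2 * min_len (%d < %d)",
                  seqs$id[[short[[1L]]]], n[[short[[1L]]]], 2L * as.integer(min_len)))
  }
  raw <- vapply(seqs$seq, cpp_detect_dtr, integer(1), USE.NAMES = FALSE)
  rep_len <- ifelse(raw >= min_len, raw, 0L)
  gc <- gc_content(seqs)$gc
  tibble(
    id = seqs$id,
    length = n,
    repeat_length = as.integer(rep_len),
    suffix_start = ifelse(rep_len > 0, n - rep_len + 1L, NA_integer_),
    trimmed_length = as.integer(n - rep_len),
    gc_percent = round(100 * gc, 1),
    is_circular_candidate = rep_len >= min_len
  )
}

#' G+C content of sequences
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` residues are excluded from both
#' numerator and denominator. An all-`N` sequence is an error.
#'
#' @param seqs Sequence tibble (columns `id`, `seq`).
#' @return A tibble with columns `id` and `gc` (fraction in `[0, 1]`).
#' @export
#' @examples
#' gc_content(tibble::tibble(id = "x", seq = "ACGTN"))
gc_content <- function(seqs) {
  seqs <- check_seq_tbl(seqs)
  gc <- stringr::str_count(seqs$seq, "[GC]")
  acgt <- stringr::str_count(seqs$seq, "[ACGT]")
  bad <- which(acgt == 0L)
  if (length(bad) > 0L) {
    abort(sprintf("sequence '%s' has no A/C/G/T residues", seqs$id[[bad[[1L]]]]))
  }
  tibble(id = seqs$id, gc = gc / acgt)
}
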