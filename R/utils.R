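# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over `x`; `N` complements to `N`.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement("AACGT")
reverse_complement <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgtn", "TGCAtgcaN", x))
}

# Construct/validate the canonical sequence tibble: one row per sequence with
# columns id, desc, seq (upper-case residues).
new_seq_tbl <- function(id, seq, desc = "") {
  tibble(id = as.character(id), desc = as.character(desc),
         seq = toupper(as.character(seq)))
}

check_seq_tbl <- function(x, arg = "seqs") {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg))
  }
  x <- as_tibble(x)
  if (!"desc" %in% names(x)) x$desc <- ""
  x$seq <- toupper(x$seq)
  x
}

check_one_seq <- function(x, arg = "reference") {
  x <- check_seq_tbl(x, arg)
  if (nrow(x) != 1) {
    abort(sprintf("`%s` must contain exactly one sequence (got %d)", arg, nrow(x)))
  }
  x
}

# Error (naming record and 1-based position) if a sequence contains residues
# outside {A,C,G,T,N}; input must already be upper-case.
check_residues <- function(seq, id, allow_n = TRUE) {
  pattern <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- regexpr(pattern, seq)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[[1L]]
    p <- bad[[i]]
    abort(sprintf("invalid residue '%s' in record '%s' at position %d",
                  substr(seq[[i]], p, p), id[[i]], p))
  }
  invisible(TRUE)
}

# Derive a stream of reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
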