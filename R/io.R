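# Readers/writers for FASTA, paired FASTQ, the sample manifest and spacer
# tables. Parsing of the standard formats is delegated to Biostrings; this
# layer enforces the pipeline's contracts (alphabet, pairing, uniqueness).

#' Read a FASTA file into a sequence tibble
#'
#' Residues are upper-cased and must be in `{A,C,G,T,N}` (after case
#' normalisation). `U` and IUPAC ambiguity codes other than `N` are rejected
#' with an error naming the offending record and position.
#'
#' @param path Path to a FASTA file (may be gzip-compressed).
#' @return A tibble with columns `id` (first header token), `desc` (remainder
#'   of the header) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) abort(sprintf("no FASTA records in %s", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  check_residues(seqs, id)
  new_seq_tbl(id, seqs, desc)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Sequence tibble (columns `id`, optional `desc`, `seq`).
#' @param path Output path.
#' @param width Line-wrap width in characters (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  seqs <- check_seq_tbl(seqs)
  set <- Biostrings::BStringSet(seqs$seq)
  names(set) <- ifelse(nzchar(seqs$desc), paste(seqs$id, seqs$desc), seqs$id)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a pair of FASTQ files as read pairs
#'
#' Mate files must contain the same number of records in the same order; read
#' ids (first header token, with any `/1` or `/2` suffix stripped) must agree
#' record by record. Gzip input is accepted by suffix.
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A tibble with columns `read_id`, `mate1`, `mate2`, `qual1`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  for (p in c(path1, path2)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  s1 <- Biostrings::readBStringSet(path1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readBStringSet(path2, format = "fastq", with.qualities = TRUE)
  if (length(s1) != length(s2)) {
    abort(sprintf("mate files differ in record count: %d vs %d",
                  length(s1), length(s2)))
  }
  strip <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  id1 <- strip(names(s1))
  id2 <- strip(names(s2))
  bad <- which(id1 != id2)
  if (length(bad) > 0L) {
    abort(sprintf("read id mismatch at record %d: '%s' vs '%s'",
                  bad[[1L]], id1[[bad[[1L]]]], id2[[bad[[1L]]]]))
  }
  tibble(read_id = unname(id1),
         mate1 = unname(toupper(as.character(s1))),
         mate2 = unname(toupper(as.character(s2))),
         qual1 = unname(as.character(S4Vectors::mcols(s1)$qualities)),
         qual2 = unname(as.character(S4Vectors::mcols(s2)$qualities)))
}

#' Write read pairs to a pair of FASTQ files
#'
#' Records are written unwrapped, ids suffixed `/1` and `/2`.
#'
#' @param pairs Read-pair tibble as returned by [read_fastq_pairs()].
#' @param path1,path2 Output paths for the two mate files.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_one <- function(seqs, quals, ids, suffix, path) {
    set <- Biostrings::BStringSet(seqs)
    names(set) <- paste0(ids, suffix)
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(pairs$mate1, pairs$qual1, pairs$read_id, "/1", path1)
  write_one(pairs$mate2, pairs$qual2, pairs$read_id, "/2", path2)
  invisible(c(path1, path2))
}

#' Read the sample manifest
#'
#' A TSV with header columns `sample_id`, `fastq1`, `fastq2`, `tph_ppm`,
#' `replicate_group`. `replicate_group` is the soil-sample id shared by the
#' replicate DNA isolations of one soil sample. An empty `tph_ppm` field means
#' below the quantification floor of the TPH analyzer and is kept as `NA`,
#' distinct from zero.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with one row per sequencing library, in file order.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    fastq1 = readr::col_character(),
    fastq2 = readr::col_character(),
    tph_ppm = readr::col_double(),
    replicate_group = readr::col_character()
  ))
  required <- c("sample_id", "fastq1", "fastq2", "tph_ppm", "replicate_group")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    abort(sprintf("manifest is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dup <- m$sample_id[duplicated(m$sample_id)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate sample_id in manifest: %s", dup[[1L]]))
  }
  neg <- which(!is.na(m$tph_ppm) & m$tph_ppm < 0)
  if (length(neg) > 0L) {
    abort(sprintf("negative tph_ppm for sample '%s'", m$sample_id[[neg[[1L]]]]))
  }
  m[required]
}

#' Read a CRISPR spacer table
#'
#' Accepts either a 3-column TSV (`spacer_id`, `taxon`, `seq`) or a FASTA file
#' whose headers are `spacer_id|taxon`. Spacers containing `N` are dropped
#' with a warning giving the rejected count.
#'
#' @param path Path to the spacer TSV or FASTA.
#' @return A tibble with columns `spacer_id`, `taxon`, `seq`.
#' @export
read_spacers <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    fa <- read_fasta(path)
    parts <- stringr::str_split_fixed(fa$id, stringr::fixed("|"), 2)
    out <- tibble(spacer_id = parts[, 1],
                  taxon = ifelse(nzchar(parts[, 2]), parts[, 2], fa$desc),
                  seq = fa$seq)
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(
      spacer_id = readr::col_character(),
      taxon = readr::col_character(),
      seq = readr::col_character()
    ))
    out$seq <- toupper(out$seq)
    check_residues(out$seq, out$spacer_id, allow_n = TRUE)
  }
  has_n <- grepl("N", out$seq, fixed = TRUE) | !nzchar(out$seq)
  if (any(has_n)) {
    warn(sprintf("dropped %d spacer(s) containing N or empty", sum(has_n)))
    out <- out[!has_n, ]
  }
  out
}
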