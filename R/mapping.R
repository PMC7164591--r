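# Per-sample viral and host abundance. Reads are placed by a defined
# seed-and-extend mapper: a mate maps when it shares at least one exact
# `seed_len`-mer with the reference (either strand) and its best ungapped
# end-to-end placement anchored at such a seed reaches `min_identity`. PCR
# duplicates are removed at the pair level, and abundance is the
# deduplicated mapped-read count divided by the library size (total reads in
# the sample), expressed as a percentage; breadth is the fraction of
# reference positions covered at depth >= 1.

#' Map read pairs to a single reference
#'
#' Both mates of each pair are mapped independently; each mate's best
#' placement (highest identity, ties broken by leftmost start, then `+`
#' strand) is reported when identity is at least `min_identity`. Alignment is
#' ungapped and end-to-end; `N` never matches.
#'
#' @param pairs Read-pair tibble (columns `read_id`, `mate1`, `mate2`), e.g.
#'   from [read_fastq_pairs()].
#' @param reference Sequence tibble with exactly one sequence, at least
#'   `seed_len` long.
#' @param seed_len Exact-seed length for the reference index (default 31).
#' @param min_identity Minimum fraction of matching bases over the full read
#'   (default 0.95).
#' @return An alignment tibble: `read_id`, `mate` (1 or 2), `ref_id`,
#'   `ref_start` (1-based), `strand`, `aligned_length`, `identity`,
#'   `mismatches`.
#' @export
map_reads <- function(pairs, reference, seed_len = 31, min_identity = 0.95) {
  reference <- check_one_seq(reference)
  if (nchar(reference$seq) < seed_len) abort("reference shorter than seed_len")
  n <- nrow(pairs)
  reads <- c(pairs$mate1, pairs$mate2)
  hits <- cpp_map_reads(toupper(reads), reference$seq,
                        as.integer(seed_len), min_identity)
  idx <- hits$read
  tibble(
    read_id = pairs$read_id[ifelse(idx > n, idx - n, idx)],
    mate = ifelse(idx > n, 2L, 1L),
    ref_id = reference$id,
    ref_start = hits$start + 1L,
    strand = hits$strand,
    aligned_length = hits$aligned_length,
    identity = hits$identity,
    mismatches = hits$mismatches
  )
}

#' Remove duplicate read pairs from alignments
#'
#' A pair is a duplicate when both of its mates share identical
#' `(ref_start, strand)` signatures with a previously seen pair; the first
#' occurrence in input order is kept. Orphan mates (only one mate mapped)
#' are deduplicated on their own `(mate, ref_start, strand)` signature.
#' Counts are invariant to which duplicate is kept.
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @return The alignment tibble with duplicate pairs removed.
#' @export
deduplicate_alignments <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  sig <- alignments |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      signature = paste(.data$mate, .data$ref_start, .data$strand,
                        collapse = ";"),
      orphan = dplyr::n() < 2L,
      .groups = "drop"
    )
  # preserve first-occurrence order of read ids
  sig <- sig[match(unique(alignments$read_id), sig$read_id), ]
  sig$signature <- paste0(ifelse(sig$orphan, "orphan:", "pair:"), sig$signature)
  keep <- sig$read_id[!duplicated(sig$signature)]
  alignments[alignments$read_id %in% keep, ]
}

#' Per-sample abundance of one reference
#'
#' Deduplicates the alignments, then computes the mapped-read percentage of
#' the library and depth/breadth over the reference. Each aligned base of
#' each surviving mate contributes depth once; overlapping mates of a pair
#' double-count (a documented simplification).
#'
#' @param alignments Alignment tibble from [map_reads()] (pre-deduplication).
#' @param library_size Total number of reads in the sample (2 per pair); must
#'   be at least the number of mapped reads and positive.
#' @param reference The reference sequence tibble (one sequence).
#' @param sample_id Optional sample label carried into the output.
#' @return A one-row tibble: `sample_id`, `ref_id`, `mapped_reads_raw`,
#'   `mapped_reads_dedup`, `library_size`, `percent_mapped`, `breadth`,
#'   `mean_depth`.
#' @export
compute_abundance <- function(alignments, library_size, reference,
                              sample_id = NA_character_) {
  reference <- check_one_seq(reference)
  if (library_size <= 0) abort("library_size must be positive")
  raw <- nrow(alignments)
  if (raw > library_size) abort("library_size smaller than mapped read count")
  dedup <- deduplicate_alignments(alignments)
  L <- nchar(reference$seq)
  if (nrow(dedup) > 0L) {
    starts <- dedup$ref_start
    ends <- pmin(dedup$ref_start + dedup$aligned_length - 1L, L)
    inc <- tabulate(starts, nbins = L)
    dec <- tabulate(ends + 1L, nbins = L + 1L)
    depth <- cumsum(inc - dec[seq_len(L)])
    breadth <- mean(depth > 0)
    mean_depth <- sum(dedup$aligned_length) / L
  } else {
    breadth <- 0
    mean_depth <- 0
  }
  tibble(
    sample_id = sample_id,
    ref_id = reference$id,
    mapped_reads_raw = raw,
    mapped_reads_dedup = nrow(dedup),
    library_size = as.integer(library_size),
    percent_mapped = 100 * nrow(dedup) / library_size,
    breadth = breadth,
    mean_depth = mean_depth
  )
}

#' Best-hit taxon abundance of a read set
#'
#' Each read (mate) is assigned to the candidate reference genome on which it
#' attains the highest placement identity (subject to the mapper's seed and
#' identity rules); reads tied between two references are left unassigned.
#'
#' @param pairs Read-pair tibble.
#' @param references Sequence tibble of candidate genomes with a `taxon`
#'   column (defaults to `id` when absent); at least one row.
#' @param seed_len,min_identity Mapper parameters, see [map_reads()].
#' @return A tibble `(taxon, raw_reads, percent_of_library)`; the library
#'   size is the total number of reads in `pairs`.
#' @export
taxon_abundance <- function(pairs, references, seed_len = 31,
                            min_identity = 0.95) {
  references <- check_seq_tbl(references, "references")
  if (nrow(references) == 0L) abort("at least one reference is required")
  if (!"taxon" %in% names(references)) references$taxon <- references$id
  reads <- toupper(c(pairs$mate1, pairs$mate2))
  library_size <- length(reads)
  ident <- matrix(NA_real_, nrow = library_size, ncol = nrow(references))
  for (j in seq_len(nrow(references))) {
    h <- cpp_map_reads(reads, references$seq[[j]], as.integer(seed_len),
                       min_identity)
    ident[h$read, j] <- h$identity
  }
  m <- ident
  m[is.na(m)] <- -1
  rmax <- do.call(pmax, as.data.frame(m))
  n_tied <- rowSums(m == rmax)
  best <- max.col(m, ties.method = "first")
  best[rmax < 0 | n_tied > 1L] <- NA_integer_
  counts <- tabulate(best, nbins = nrow(references))
  agg <- rowsum(counts, references$taxon)
  tibble(
    taxon = rownames(agg),
    raw_reads = as.integer(agg[, 1]),
    percent_of_library = 100 * agg[, 1] / library_size
  )
}

#' Map every manifest sample against a reference
#'
#' Runs [map_reads()], [deduplicate_alignments()] and [compute_abundance()]
#' for each library in the manifest.
#'
#' @param manifest Manifest tibble from [read_manifest()].
#' @param reference Sequence tibble with one sequence.
#' @param seed_len,min_identity Mapper parameters.
#' @return A tibble with one [compute_abundance()] row per library.
#' @export
sample_abundance <- function(manifest, reference, seed_len = 31,
                             min_identity = 0.95) {
  purrr::pmap_dfr(
    manifest[c("sample_id", "fastq1", "fastq2")],
    function(sample_id, fastq1, fastq2) {
      pairs <- read_fastq_pairs(fastq1, fastq2)
      aln <- map_reads(pairs, reference, seed_len, min_identity)
      compute_abundance(aln, 2L * nrow(pairs), reference, sample_id)
    })
}

#' Per-sample taxon abundance across a manifest
#'
#' @inheritParams sample_abundance
#' @param references Candidate host genomes with a `taxon` column.
#' @return A tibble `(sample_id, taxon, raw_reads, percent_of_library)`.
#' @export
sample_taxon_abundance <- function(manifest, references, seed_len = 31,
                                   min_identity = 0.95) {
  purrr::pmap_dfr(
    manifest[c("sample_id", "fastq1", "fastq2")],
    function(sample_id, fastq1, fastq2) {
      pairs <- read_fastq_pairs(fastq1, fastq2)
      dplyr::mutate(
        taxon_abundance(pairs, references, seed_len, min_identity),
        sample_id = sample_id, .before = 1
      )
    })
}

#' Write accepted alignments as minimal SAM
#'
#' A small interoperability dump: header (`@HD`, `@SQ`) plus the 11 mandatory
#' columns, one line per aligned mate (flag 0/16 for strand only, MAPQ 255,
#' full-length match CIGAR).
#'
#' @param alignments Alignment tibble from [map_reads()].
#' @param reference The reference sequence tibble (one sequence).
#' @param path Output path.
#' @param pairs Optional read-pair tibble supplying SEQ fields.
#' @return `path`, invisibly.
#' @export
write_sam_minimal <- function(alignments, reference, path, pairs = NULL) {
  reference <- check_one_seq(reference)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", reference$id, nchar(reference$seq)))
  seqf <- rep("*", nrow(alignments))
  if (!is.null(pairs)) {
    key <- match(alignments$read_id, pairs$read_id)
    seqf <- ifelse(alignments$mate == 1L, pairs$mate1[key], pairs$mate2[key])
    minus <- alignments$strand == "-"
    seqf[minus] <- reverse_complement(seqf[minus])
  }
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                  paste0(alignments$read_id, "/", alignments$mate),
                  ifelse(alignments$strand == "-", 16L, 0L),
                  alignments$ref_id, alignments$ref_start,
                  alignments$aligned_length, seqf)
  writeLines(c(header, body), path)
  invisible(path)
}
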