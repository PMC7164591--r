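# CRISPR spacer (protospacer) matching against the viral genome. A spacer is
# a short virus-derived segment archived in a prokaryote's CRISPR array; an
# exact or near-exact match of a taxon's spacer inside a viral genome records
# a past infection and is the most direct in-silico host signal.

#' Match CRISPR spacers against a viral genome
#'
#' Ungapped sliding-window (Hamming distance) scan of every spacer against
#' both strands of the virus. All windows with at most `max_mismatches`
#' mismatches are reported — overlapping hits of the same spacer are not
#' masked. A minus-strand hit (the reverse complement of the spacer matching
#' the forward virus strand) reports the forward-strand coordinate of the
#' matched window. Windows containing `N` in the virus are skipped. No
#' wrap-around matching is attempted across the ends of the contig, even for
#' circular candidates (a direct terminal repeat already duplicates the
#' junction).
#'
#' @param spacers Spacer tibble (columns `spacer_id`, `taxon`, `seq`), e.g.
#'   from [read_spacers()]. Spacers longer than the virus are skipped with a
#'   warning.
#' @param virus Sequence tibble with exactly one sequence.
#' @param max_mismatches Hamming mismatch budget (default 3).
#' @return A tibble of hits sorted by `(spacer_id, start)`: `spacer_id`,
#'   `taxon`, `start` (1-based on the forward strand), `strand` (`+`/`-`),
#'   `mismatches`.
#' @export
match_spacers <- function(spacers, virus, max_mismatches = 3) {
  if (!is.data.frame(spacers) ||
      !all(c("spacer_id", "taxon", "seq") %in% names(spacers))) {
    abort("`spacers` must have columns spacer_id, taxon, seq")
  }
  virus <- check_one_seq(virus, "virus")
  vseq <- virus$seq
  vlen <- nchar(vseq)
  spacers <- as_tibble(spacers)
  spacers$seq <- toupper(spacers$seq)
  too_long <- nchar(spacers$seq) > vlen
  if (any(too_long)) {
    warn(sprintf("skipped %d spacer(s) longer than the virus genome",
                 sum(too_long)))
    spacers <- spacers[!too_long, ]
  }
  hits <- purrr::pmap_dfr(
    list(spacers$spacer_id, spacers$taxon, spacers$seq),
    function(sid, taxon, s) {
      fwd <- cpp_hamming_scan(vseq, s, as.integer(max_mismatches))
      rev <- cpp_hamming_scan(vseq, reverse_complement(s), as.integer(max_mismatches))
      tibble(
        spacer_id = sid, taxon = taxon,
        start = c(fwd$pos, rev$pos) + 1L,
        strand = c(rep("+", length(fwd$pos)), rep("-", length(rev$pos))),
        mismatches = c(fwd$mm, rev$mm)
      )
    })
  if (nrow(hits) == 0L) {
    return(tibble(spacer_id = character(), taxon = character(),
                  start = integer(), strand = character(),
                  mismatches = integer()))
  }
  dplyr::arrange(hits, .data$spacer_id, .data$start)
}

#' Summarise spacer hits per candidate host taxon
#'
#' @param hits Hit tibble from [match_spacers()].
#' @return One row per taxon with `n_hits`, `n_distinct_spacers` and
#'   `best_mismatches`, sorted by `(n_hits desc, best_mismatches asc,
#'   taxon asc)`. Empty input gives an empty table.
#' @export
summarize_candidate_hosts <- function(hits) {
  if (nrow(hits) == 0L) {
    return(tibble(taxon = character(), n_hits = integer(),
                  n_distinct_spacers = integer(), best_mismatches = integer()))
  }
  hits |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n_hits = dplyr::n(),
      n_distinct_spacers = dplyr::n_distinct(.data$spacer_id),
      best_mismatches = min(.data$mismatches),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_hits), .data$best_mismatches, .data$taxon)
}
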