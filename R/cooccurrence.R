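# Presence calling, binarisation, replicate averaging and the correlation
# analyses: the binary virus/pollution co-occurrence (phi coefficient) and
# the per-taxon abundance-profile correlations. Threshold conventions are
# inclusive throughout (>= 0.01 % of library, >= 75 % breadth, >= 125 ppm
# TPH) and are recorded in every report.

#' Average replicate libraries within soil samples
#'
#' Replicate DNA isolations of the same soil sample are averaged on the
#' normalised scale: the arithmetic mean of `percent_mapped` (and of
#' `breadth`, `mapped_reads_raw`, `mapped_reads_dedup`) is taken within each
#' `replicate_group`.
#'
#' @param abundance Per-library abundance tibble from [sample_abundance()].
#' @param manifest Manifest tibble mapping `sample_id` to `replicate_group`
#'   and `tph_ppm`.
#' @return A tibble with one row per replicate group: `group_id`,
#'   `n_replicates`, averaged abundance columns and `tph_ppm` (first value in
#'   the group).
#' @export
average_replicates <- function(abundance, manifest) {
  joined <- dplyr::left_join(abundance,
                             manifest[c("sample_id", "replicate_group", "tph_ppm")],
                             by = "sample_id")
  if (any(is.na(joined$replicate_group))) {
    bad <- joined$sample_id[is.na(joined$replicate_group)][[1L]]
    abort(sprintf("sample '%s' has no replicate_group in the manifest", bad))
  }
  joined |>
    dplyr::group_by(group_id = .data$replicate_group) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mapped_reads_raw = mean(.data$mapped_reads_raw),
      mapped_reads_dedup = mean(.data$mapped_reads_dedup),
      percent_mapped = mean(.data$percent_mapped),
      breadth = mean(.data$breadth),
      tph_ppm = .data$tph_ppm[[1L]],
      .groups = "drop"
    )
}

#' Call viral presence from abundance
#'
#' Presence is 1 when `percent_mapped >= pct_threshold` and — only when
#' `use_breadth` is `TRUE` (survey mode, screening external metagenomes) —
#' `breadth >= breadth_threshold`. Thresholds are inclusive. Vectorised.
#'
#' @param percent_mapped Percentage of library reads mapped to the virus.
#' @param breadth Fraction of the genome covered at depth >= 1.
#' @param pct_threshold Presence threshold on the percentage (default 0.01).
#' @param breadth_threshold Breadth cut-off (default 0.75).
#' @param use_breadth Apply the breadth rule (default `FALSE`).
#' @return Integer vector of 0/1 flags.
#' @export
call_presence <- function(percent_mapped, breadth = NULL, pct_threshold = 0.01,
                          breadth_threshold = 0.75, use_breadth = FALSE) {
  flag <- percent_mapped >= pct_threshold
  if (use_breadth) {
    if (is.null(breadth)) abort("breadth required when use_breadth = TRUE")
    flag <- flag & (breadth >= breadth_threshold)
  }
  as.integer(flag)
}

#' Binarise TPH pollution
#'
#' 1 when the TPH concentration is present and at least `threshold` ppm
#' (inclusive); a missing concentration means below the analyzer's
#' quantification floor and yields 0.
#'
#' @param tph_ppm Numeric vector of TPH concentrations (ppm), `NA` allowed.
#' @param threshold Pollution threshold in ppm (default 125, the calibration
#'   floor).
#' @return Integer vector of 0/1 flags.
#' @export
binarize_tph <- function(tph_ppm, threshold = 125) {
  as.integer(!is.na(tph_ppm) & tph_ppm >= threshold)
}

#' Binary co-occurrence (phi coefficient)
#'
#' Pearson correlation of two 0/1 vectors, algebraically identical to the phi
#' coefficient of their 2x2 contingency table. If either vector is constant
#' the statistic is undefined: `NA` is returned with a warning.
#'
#' @param presence,pollution Equal-length 0/1 vectors (length >= 2).
#' @return A correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
binary_cooccurrence <- function(presence, pollution) {
  if (length(presence) != length(pollution)) {
    abort("presence and pollution must have equal length")
  }
  if (length(presence) < 2L) abort("need at least two samples")
  if (!all(presence %in% c(0, 1)) || !all(pollution %in% c(0, 1))) {
    abort("inputs must be 0/1 vectors")
  }
  if (length(unique(presence)) < 2L || length(unique(pollution)) < 2L) {
    warn("degenerate co-occurrence: a vector is constant, phi undefined")
    return(NA_real_)
  }
  cor(presence, pollution)
}

#' Abundance-profile correlation between virus and a candidate host
#'
#' Pearson correlation of the per-sample abundances; `mode = "raw"` is meant
#' for read counts, `mode = "normalized"` for percent-of-library values.
#'
#' @param virus,host Equal-length numeric vectors (length >= 3).
#' @param mode Label recorded for the analysis (`"normalized"` or `"raw"`).
#' @return A correlation, or `NA` with a warning for constant input.
#' @export
abundance_correlation <- function(virus, host, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  if (length(virus) != length(host)) abort("vectors must have equal length")
  if (length(virus) < 3L) abort("need at least three samples")
  if (stats::sd(virus) == 0 || stats::sd(host) == 0) {
    warn(sprintf("degenerate %s abundance correlation: constant vector", mode))
    return(NA_real_)
  }
  cor(virus, host)
}

#' Build the per-soil-sample study table
#'
#' Joins replicate-averaged viral abundance with the pollution measurements
#' and derives the binary flags. This is the in-memory form of the occurrence
#' table the co-occurrence analysis runs on.
#'
#' @param averaged Replicate-averaged tibble from [average_replicates()].
#' @param pct_threshold,breadth_threshold,use_breadth Presence rule, see
#'   [call_presence()].
#' @param tph_threshold Pollution threshold in ppm, see [binarize_tph()].
#' @return A `vm_study` tibble: `group_id`, abundance columns, `tph_ppm`,
#'   `presence_flag`, `tph_flag`, plus a `tph_note` marking concentrations
#'   below quantification. Thresholds are stored as attributes and shown by
#'   [glance()].
#' @export
build_study_table <- function(averaged, pct_threshold = 0.01,
                              breadth_threshold = 0.75, use_breadth = FALSE,
                              tph_threshold = 125) {
  out <- averaged |>
    dplyr::mutate(
      presence_flag = call_presence(.data$percent_mapped, .data$breadth,
                                    pct_threshold, breadth_threshold,
                                    use_breadth),
      tph_flag = binarize_tph(.data$tph_ppm, tph_threshold),
      tph_note = ifelse(is.na(.data$tph_ppm), "below quantification", "")
    )
  structure(out,
            class = c("vm_study", class(out)),
            thresholds = list(pct = pct_threshold, breadth = breadth_threshold,
                              use_breadth = use_breadth, tph = tph_threshold,
                              convention = "inclusive (>=)"))
}

#' @rdname build_study_table
#' @param x A `vm_study` table.
#' @param ... Unused.
#' @export
glance.vm_study <- function(x, ...) {
  th <- attr(x, "thresholds")
  phi <- withCallingHandlers(
    binary_cooccurrence(x$presence_flag, x$tph_flag),
    warning = function(w) invokeRestart("muffleWarning")
  )
  tibble(
    phi = phi,
    n_groups = nrow(x),
    n_present = sum(x$presence_flag),
    n_polluted = sum(x$tph_flag),
    degenerate = is.na(phi),
    pct_threshold = th$pct,
    tph_threshold = th$tph,
    breadth_threshold = th$breadth,
    use_breadth = th$use_breadth
  )
}

#' @rdname build_study_table
#' @param object A `vm_study` table.
#' @export
autoplot.vm_study <- function(object, ...) {
  th <- attr(object, "thresholds")
  df <- dplyr::mutate(as_tibble(object),
                      pollution = factor(.data$tph_flag, levels = c(0, 1),
                                         labels = c("unpolluted", "polluted")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group_id,
                                   y = .data$percent_mapped,
                                   fill = .data$pollution)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = th$pct, linetype = 2, colour = "grey40") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = NULL, y = "% of library mapped to virus",
                  fill = "TPH status",
                  title = "Marker-virus occurrence by soil sample") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Merge the three host-prediction signals into one report
#'
#' One row per candidate taxon with the spacer, abundance-correlation and
#' k-mer columns; signals not computed for a taxon are `NA` (rendered `n.d.`
#' when written). No automatic winner is declared unless **all** available
#' signals (at least two) rank the same taxon first; that taxon is then
#' flagged `consistent`.
#'
#' @param spacer_summary Taxon summary from [summarize_candidate_hosts()], or
#'   `NULL`.
#' @param abundance_correlations Tibble `(taxon, r_raw, r_normalized)`, or
#'   `NULL`.
#' @param kmer_results Tibble `(taxon, r_real, null_mean)` (e.g. bound
#'   [glance()] rows of [kmer_null_comparison()] with a `taxon` column), or
#'   `NULL`.
#' @return A tibble with columns `taxon`, `spacer_hits`, `spacer_best_mm`,
#'   `r_raw`, `r_normalized`, `kmer_r`, `kmer_null_mean`, `consistent`.
#' @export
host_prediction_report <- function(spacer_summary = NULL,
                                   abundance_correlations = NULL,
                                   kmer_results = NULL) {
  pieces <- list()
  rankings <- list()
  if (!is.null(spacer_summary) && nrow(spacer_summary) > 0L) {
    pieces$spacer <- tibble(taxon = spacer_summary$taxon,
                            spacer_hits = spacer_summary$n_hits,
                            spacer_best_mm = spacer_summary$best_mismatches)
    ord <- order(-spacer_summary$n_hits, spacer_summary$best_mismatches,
                 spacer_summary$taxon)
    rankings$spacer <- spacer_summary$taxon[ord][[1L]]
  }
  if (!is.null(abundance_correlations) && nrow(abundance_correlations) > 0L) {
    pieces$abund <- as_tibble(abundance_correlations)
    ok <- !is.na(abundance_correlations$r_normalized)
    if (any(ok)) {
      a <- abundance_correlations[ok, ]
      rankings$abund <- a$taxon[order(-a$r_normalized, a$taxon)][[1L]]
    }
  }
  if (!is.null(kmer_results) && nrow(kmer_results) > 0L) {
    pieces$kmer <- tibble(taxon = kmer_results$taxon,
                          kmer_r = kmer_results$r_real,
                          kmer_null_mean = kmer_results$null_mean)
    ok <- !is.na(kmer_results$r_real)
    if (any(ok)) {
      kk <- kmer_results[ok, ]
      rankings$kmer <- kk$taxon[order(-kk$r_real, kk$taxon)][[1L]]
    }
  }
  if (length(pieces) == 0L) abort("at least one signal is required")
  report <- purrr::reduce(pieces, dplyr::full_join, by = "taxon")
  for (col in c("spacer_hits", "spacer_best_mm", "r_raw", "r_normalized",
                "kmer_r", "kmer_null_mean")) {
    if (!col %in% names(report)) report[[col]] <- NA_real_
  }
  tops <- unlist(rankings)
  winner <- if (length(tops) >= 2L && length(unique(tops)) == 1L) tops[[1L]] else NA_character_
  report$consistent <- !is.na(winner) & report$taxon == winner
  report <- dplyr::arrange(report, dplyr::desc(.data$consistent), .data$taxon)
  report[c("taxon", "spacer_hits", "spacer_best_mm", "r_raw", "r_normalized",
           "kmer_r", "kmer_null_mean", "consistent")]
}

#' Write a host-prediction report as TSV with `n.d.` for missing signals
#'
#' @param report Report tibble from [host_prediction_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_host_report <- function(report, path) {
  out <- dplyr::mutate(report, dplyr::across(
    dplyr::where(is.numeric),
    ~ ifelse(is.na(.x), "n.d.", format(.x, digits = 4, trim = TRUE))
  ))
  readr::write_tsv(out, path)
  invisible(path)
}
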