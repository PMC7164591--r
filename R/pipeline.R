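# End-to-end orchestration: DTR characterisation -> per-library abundance
# (virus and candidate hosts) -> replicate averaging -> presence calling and
# binary co-occurrence -> spacer matching -> k-mer null comparison -> merged
# host-prediction report. Every stage's table is written to the run
# directory together with a config echo, and a rerun with the same config is
# bit-identical.

#' Assemble a pipeline configuration
#'
#' Defaults are the study's standard operating values: presence at 0.01 % of
#' library reads, pollution at 125 ppm TPH, 75 % breadth (survey mode only),
#' 31-mer seeds with 95 % identity, tetramers with 3 shuffled controls.
#'
#' @param manifest,virus_fasta Paths to the sample manifest and the viral
#'   contig FASTA (required).
#' @param hosts_fasta Path to candidate host genomes FASTA (headers
#'   `id taxon`), or `NA` to skip abundance/k-mer host signals.
#' @param spacers Path to the spacer table (TSV or FASTA), or `NA` to skip
#'   the CRISPR signal.
#' @param pct_threshold,breadth_threshold,use_breadth,tph_threshold
#'   Presence/pollution rules, see [call_presence()] and [binarize_tph()].
#' @param seed_len,min_identity Mapper parameters, see [map_reads()].
#' @param k,n_shuffles k-mer signal parameters, see [kmer_null_comparison()].
#' @param max_mismatches Spacer Hamming budget, see [match_spacers()].
#' @param min_dtr Minimum terminal-repeat length, see
#'   [detect_terminal_repeat()].
#' @param seed Integer seed (shuffled-null construction).
#' @return A named list of class `vm_config`.
#' @export
pipeline_config <- function(manifest, virus_fasta, hosts_fasta = NA,
                            spacers = NA, pct_threshold = 0.01,
                            breadth_threshold = 0.75, use_breadth = FALSE,
                            tph_threshold = 125, seed_len = 31,
                            min_identity = 0.95, k = 4, n_shuffles = 3,
                            max_mismatches = 3, min_dtr = 20, seed = 1) {
  structure(list(
    manifest = manifest, virus_fasta = virus_fasta,
    hosts_fasta = hosts_fasta, spacers = spacers,
    pct_threshold = pct_threshold, breadth_threshold = breadth_threshold,
    use_breadth = use_breadth, tph_threshold = tph_threshold,
    seed_len = seed_len, min_identity = min_identity, k = k,
    n_shuffles = n_shuffles, max_mismatches = max_mismatches,
    min_dtr = min_dtr, seed = seed
  ), class = "vm_config")
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Lines of the form `key = value` (or `key value`); unknown keys are an
#' error. Values are coerced to the type of the corresponding
#' [pipeline_config()] default.
#'
#' @param path Path to the config file.
#' @return A `vm_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- stringr::str_match(lines, "^(\\S+)\\s*[=:]?\\s*(.*)$")
  keys <- kv[, 2]
  vals <- trimws(kv[, 3])
  known <- names(formals(pipeline_config))
  bad <- setdiff(keys, known)
  if (length(bad) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  args <- as.list(vals)
  names(args) <- keys
  numeric_keys <- c("pct_threshold", "breadth_threshold", "tph_threshold",
                    "seed_len", "min_identity", "k", "n_shuffles",
                    "max_mismatches", "min_dtr", "seed")
  for (key in intersect(names(args), numeric_keys)) {
    args[[key]] <- as.numeric(args[[key]])
  }
  if ("use_breadth" %in% names(args)) {
    args$use_breadth <- toupper(args$use_breadth) %in% c("TRUE", "1", "YES")
  }
  do.call(pipeline_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", name, conditionMessage(e)))
  })
}

path_or_null <- function(p) {
  if (is.null(p) || length(p) == 0L || is.na(p) || !nzchar(p)) NULL else p
}

#' Run the full marker-virus pipeline
#'
#' Executes every stage on the inputs named in `config`, writes each stage's
#' TSV/JSON output plus a config echo (`run_manifest.json`) to `out_dir`, and
#' returns all results. Reruns with the same config are bit-identical. Any
#' stage failure aborts with the stage name and the offending input.
#'
#' @param config A `vm_config` from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage progress messages (default `TRUE`).
#' @return An object of class `vm_run`: a list with `dtr`, `abundance`,
#'   `taxon_abundance`, `study` (a `vm_study` table), `cooccurrence`
#'   ([glance()] of the study), `spacer_hits`, `spacer_summary`,
#'   `abundance_correlations`, `kmer`, `report` (the merged host-prediction
#'   table) and `config`.
#' @export
run_study_pipeline <- function(config, out_dir, quiet = TRUE) {
  if (!inherits(config, "vm_config")) {
    abort("`config` must be created by pipeline_config() or read_pipeline_config()")
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  for (key in c("manifest", "virus_fasta")) {
    if (is.na(config[[key]]) || !file.exists(config[[key]])) {
      abort(sprintf("[input] %s file not found: %s", key, config[[key]]))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[io] reading inputs")
  manifest <- stage("io", read_manifest(config$manifest))
  virus <- stage("io", read_fasta(config$virus_fasta))
  if (nrow(virus) != 1) abort("[io] virus FASTA must contain one contig")
  hosts_path <- path_or_null(config$hosts_fasta)
  hosts <- NULL
  if (!is.null(hosts_path)) {
    if (!file.exists(hosts_path)) {
      abort(sprintf("[input] hosts_fasta file not found: %s", hosts_path))
    }
    hosts <- stage("io", read_fasta(hosts_path))
    hosts$taxon <- ifelse(nzchar(hosts$desc), hosts$desc, hosts$id)
  }
  spacers_path <- path_or_null(config$spacers)
  spacers <- NULL
  if (!is.null(spacers_path)) {
    if (!file.exists(spacers_path)) {
      abort(sprintf("[input] spacers file not found: %s", spacers_path))
    }
    spacers <- stage("io", read_spacers(spacers_path))
  }

  say("[dtr] terminal repeat scan")
  dtr <- stage("dtr", detect_terminal_repeat(virus, config$min_dtr))

  say("[abundance] mapping %d libraries", nrow(manifest))
  abundance <- NULL
  taxa <- NULL
  abundance <- stage("abundance", {
    purrr::pmap_dfr(
      manifest[c("sample_id", "fastq1", "fastq2")],
      function(sample_id, fastq1, fastq2) {
        pairs <- read_fastq_pairs(fastq1, fastq2)
        aln <- map_reads(pairs, virus, config$seed_len, config$min_identity)
        vir <- compute_abundance(aln, 2L * nrow(pairs), virus, sample_id)
        if (!is.null(hosts)) {
          ta <- taxon_abundance(pairs, hosts, config$seed_len,
                                config$min_identity)
          taxa <<- dplyr::bind_rows(taxa,
                                    dplyr::mutate(ta, sample_id = sample_id,
                                                  .before = 1))
        }
        vir
      })
  })

  say("[cooccur] replicate averaging and presence calls")
  averaged <- stage("cooccur", average_replicates(abundance, manifest))
  study <- stage("cooccur", build_study_table(
    averaged, config$pct_threshold, config$breadth_threshold,
    config$use_breadth, config$tph_threshold))
  cooc <- glance(study)

  spacer_hits <- NULL
  spacer_summary <- NULL
  if (!is.null(spacers)) {
    say("[spacers] matching %d spacers", nrow(spacers))
    spacer_hits <- stage("spacers",
                         match_spacers(spacers, virus, config$max_mismatches))
    spacer_summary <- summarize_candidate_hosts(spacer_hits)
  }

  abund_cor <- NULL
  kmer_tbl <- NULL
  if (!is.null(hosts)) {
    say("[host-signals] abundance correlations and k-mer profiles")
    taxa_avg <- stage("cooccur", {
      taxa |>
        dplyr::left_join(manifest[c("sample_id", "replicate_group")],
                         by = "sample_id") |>
        dplyr::group_by(group_id = .data$replicate_group, .data$taxon) |>
        dplyr::summarise(raw_reads = mean(.data$raw_reads),
                         percent_of_library = mean(.data$percent_of_library),
                         .groups = "drop")
    })
    abund_cor <- stage("cooccur", {
      taxa_avg |>
        dplyr::left_join(averaged[c("group_id", "mapped_reads_dedup",
                                    "percent_mapped")], by = "group_id") |>
        dplyr::group_by(.data$taxon) |>
        dplyr::summarise(
          r_raw = suppressWarnings(
            abundance_correlation(.data$mapped_reads_dedup, .data$raw_reads,
                                  "raw")),
          r_normalized = suppressWarnings(
            abundance_correlation(.data$percent_mapped,
                                  .data$percent_of_library, "normalized")),
          .groups = "drop")
    })
    kmer_tbl <- stage("kmer", {
      purrr::map_dfr(seq_len(nrow(hosts)), function(j) {
        res <- kmer_null_comparison(virus, hosts[j, ], k = config$k,
                                    n_shuffles = config$n_shuffles,
                                    seed = config$seed + j)
        dplyr::mutate(glance(res), taxon = hosts$taxon[[j]], .before = 1)
      })
    })
  }

  say("[report] merging host-prediction signals")
  report <- NULL
  if (!is.null(spacer_summary) || !is.null(abund_cor) || !is.null(kmer_tbl)) {
    kmer_in <- if (is.null(kmer_tbl)) NULL else
      dplyr::select(kmer_tbl, "taxon", "r_real", "null_mean")
    report <- stage("report", host_prediction_report(
      spacer_summary, abund_cor, kmer_in))
  }

  # --- write outputs -------------------------------------------------------
  readr::write_tsv(dtr, file.path(out_dir, "dtr.tsv"))
  readr::write_tsv(abundance, file.path(out_dir, "abundance.tsv"))
  if (!is.null(taxa)) {
    readr::write_tsv(taxa, file.path(out_dir, "taxon_abundance.tsv"))
  }
  readr::write_tsv(as_tibble(study), file.path(out_dir, "study_table.tsv"),
                   na = "")
  jsonlite::write_json(
    c(as.list(cooc), list(threshold_convention = "inclusive (>=)")),
    file.path(out_dir, "cooccurrence.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(spacer_hits)) {
    readr::write_tsv(spacer_hits, file.path(out_dir, "spacer_hits.tsv"))
    readr::write_tsv(spacer_summary, file.path(out_dir, "spacer_summary.tsv"))
  }
  if (!is.null(kmer_tbl)) {
    readr::write_tsv(kmer_tbl, file.path(out_dir, "kmer_host.tsv"))
  }
  if (!is.null(report)) {
    write_host_report(report, file.path(out_dir, "host_prediction.tsv"))
  }
  jsonlite::write_json(
    list(package = "viromarker",
         version = as.character(utils::packageVersion("viromarker")),
         config = unclass(config)),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  structure(list(
    dtr = dtr, abundance = abundance, taxon_abundance = taxa,
    study = study, cooccurrence = cooc, spacer_hits = spacer_hits,
    spacer_summary = spacer_summary, abundance_correlations = abund_cor,
    kmer = kmer_tbl, report = report, config = config, out_dir = out_dir
  ), class = "vm_run")
}

#' @export
print.vm_run <- function(x, ...) {
  cat("viromarker pipeline run\n")
  cat(sprintf("  libraries: %d  soil samples: %d\n",
              nrow(x$abundance), nrow(x$study)))
  cat(sprintf("  presence flags: %d of %d; phi vs pollution = %s\n",
              sum(x$study$presence_flag), nrow(x$study),
              ifelse(is.na(x$cooccurrence$phi), "undefined (degenerate)",
                     sprintf("%.3f", x$cooccurrence$phi))))
  if (!is.null(x$report)) {
    win <- x$report$taxon[x$report$consistent]
    cat(sprintf("  host prediction: %s\n",
                if (length(win) == 1L) sprintf("'%s' (consistent across signals)", win)
                else "no consistent candidate"))
  }
  invisible(x)
}

#' @rdname run_study_pipeline
#' @param x,object A `vm_run` object.
#' @param ... Unused.
#' @export
glance.vm_run <- function(x, ...) {
  dplyr::mutate(x$cooccurrence,
                consistent_host = {
                  win <- x$report$taxon[x$report$consistent %||% FALSE]
                  if (length(win) == 1L) win else NA_character_
                },
                dtr_length = x$dtr$repeat_length[[1L]])
}
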