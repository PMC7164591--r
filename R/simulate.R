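# Synthetic study generator. Produces every input the analysis consumes —
# genomes with controllable k-mer composition, a viral genome with a planted
# direct terminal repeat, a host genome carrying a CRISPR array of
# virus-derived spacers, and multi-sample paired-end libraries whose viral
# fraction tracks a binary pollution label — together with ground-truth
# records, so the whole inference chain can be validated against known
# parameters. All generators are deterministic per (parameters, seed).

#' Markov composition model for genome generation
#'
#' Transition probabilities over `{A,C,G,T}` conditioned on the previous
#' `order` bases. Rows are drawn from a symmetric Dirichlet; small `alpha`
#' gives strongly skewed (signature-rich) compositions.
#'
#' @param order Markov order (0--8; default 3, so tetramer structure is the
#'   model's natural signature).
#' @param alpha Dirichlet concentration per row (default 0.5).
#' @param seed Integer seed.
#' @return A `vm_composition` list with elements `order` and `probs`
#'   (`4^order` x 4 row-stochastic matrix).
#' @export
composition_model <- function(order = 3, alpha = 0.5, seed = 1) {
  if (order < 0 || order > 8) abort("order must be between 0 and 8")
  if (alpha <= 0) abort("alpha must be positive")
  nrow <- 4L^order
  withr::with_seed(as.integer(seed), {
    g <- matrix(rgamma(nrow * 4L, shape = alpha), nrow = nrow, ncol = 4L)
  })
  probs <- g / rowSums(g)
  structure(list(order = as.integer(order), probs = probs),
            class = "vm_composition")
}

#' @rdname composition_model
#' @param order Markov order (uniform over `{A,C,G,T}` at every position).
#' @export
uniform_composition_model <- function(order = 0) {
  structure(list(order = as.integer(order),
                 probs = matrix(0.25, nrow = 4L^order, ncol = 4L)),
            class = "vm_composition")
}

check_model <- function(model) {
  if (!inherits(model, "vm_composition")) {
    abort("`model` must be a composition_model()")
  }
  if (any(model$probs < 0) ||
      any(abs(rowSums(model$probs) - 1) > 1e-9)) {
    abort("invalid composition model: rows must be non-negative and sum to 1")
  }
  model
}

#' Generate a genome from a composition model
#'
#' @param length Genome length in bases (>= 1).
#' @param model A [composition_model()].
#' @param seed Integer seed.
#' @param id Sequence id for the output tibble.
#' @return A one-row sequence tibble.
#' @export
generate_genome <- function(length, model, seed = 1, id = "genome") {
  check_model(model)
  if (length < 1) abort("length must be >= 1")
  withr::with_seed(as.integer(seed), {
    s <- cpp_sample_markov(as.integer(length), model$order, model$probs)
  })
  new_seq_tbl(id, s)
}

#' Generate a viral genome with a direct terminal repeat
#'
#' Samples a core of `length - dtr_len` bases and copies its first `dtr_len`
#' bases to the end, so the first and last `dtr_len` bases of the result are
#' identical — the assembler signature of a circular genome. Defaults emulate
#' the scale of the MetMV contig (67,826 bp with an 8,697 bp repeat).
#'
#' @param length Total genome length including the duplicated end.
#' @param model A [composition_model()].
#' @param dtr_len Direct-terminal-repeat length; must be at most `length / 2`.
#' @param seed Integer seed.
#' @param id Sequence id.
#' @return A one-row sequence tibble.
#' @export
generate_virus <- function(length = 67826, model = composition_model(),
                           dtr_len = 8697, seed = 1, id = "virus_contig") {
  if (dtr_len < 0) abort("dtr_len must be >= 0")
  if (dtr_len > length / 2) abort("dtr_len must be at most length / 2")
  core <- generate_genome(length - dtr_len, model, seed, id)$seq
  new_seq_tbl(id, paste0(core, substr(core, 1, dtr_len)))
}

#' Plant a CRISPR array of virus-derived spacers into a host genome
#'
#' Samples `n_spacers` non-overlapping-start windows of the virus without
#' replacement, interleaves them with `repeat_unit` (repeat, spacer, repeat,
#' ..., repeat) and inserts the array at a random position of the host
#' genome.
#'
#' @param host,virus One-row sequence tibbles.
#' @param n_spacers Number of spacers (>= 1; default 5).
#' @param spacer_len Spacer length in bases (default 32).
#' @param repeat_unit CRISPR repeat sequence between spacers.
#' @param seed Integer seed.
#' @param taxon Taxon label recorded for the spacers (defaults to the host
#'   id).
#' @return A list with `host` (modified sequence tibble) and `spacers`
#'   (tibble `spacer_id`, `taxon`, `seq`, `virus_start`, 1-based) plus the
#'   array insertion point `array_start`.
#' @export
plant_crispr_array <- function(host, virus, n_spacers = 5, spacer_len = 32,
                               repeat_unit = "GTTTCAATCCACGCACCCATCAGGGC",
                               seed = 1, taxon = NULL) {
  host <- check_one_seq(host, "host")
  virus <- check_one_seq(virus, "virus")
  if (n_spacers < 1) abort("n_spacers must be >= 1")
  vlen <- nchar(virus$seq)
  if (vlen < spacer_len) abort("virus shorter than spacer_len")
  n_starts <- vlen - spacer_len + 1L
  if (n_spacers > n_starts) abort("too many spacers for the virus length")
  taxon <- taxon %||% host$id
  withr::with_seed(as.integer(seed), {
    starts <- sort(sample.int(n_starts, n_spacers))
    insert_at <- sample.int(nchar(host$seq) + 1L, 1L)
  })
  spacer_seqs <- stringr::str_sub(virus$seq, starts, starts + spacer_len - 1L)
  array <- paste0(repeat_unit,
                  paste0(spacer_seqs, repeat_unit, collapse = ""))
  new_host_seq <- paste0(stringr::str_sub(host$seq, 1, insert_at - 1L), array,
                         stringr::str_sub(host$seq, insert_at, nchar(host$seq)))
  list(
    host = new_seq_tbl(host$id, new_host_seq, host$desc),
    spacers = tibble(
      spacer_id = sprintf("%s_sp%02d", taxon, seq_len(n_spacers)),
      taxon = taxon,
      seq = spacer_seqs,
      virus_start = as.integer(starts)
    ),
    array_start = as.integer(insert_at)
  )
}

#' Simulate one paired-end shotgun library
#'
#' Fragments are sampled uniformly from each reference in the given
#' proportions (multinomial allocation of `n_pairs`); mates are read from
#' opposite ends of the fragment on opposite strands; per-base substitution
#' errors are applied at `error_rate` (no indels, matching the ungapped
#' mapper); a `duplicate_rate` fraction of pairs is emitted twice.
#' Fractions summing to less than 1 leave the remainder to a background
#' genome (supplied or generated uniformly at random).
#'
#' @param refs Sequence tibble with a `fraction` column summing to at most 1.
#' @param n_pairs Number of unique read pairs.
#' @param read_len Read length in bases (default 150).
#' @param insert_mean,insert_sd Fragment-size distribution (default 300/30);
#'   inserts are clamped to `[read_len, reference length]`.
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param duplicate_rate Probability that a pair is emitted twice (default 0).
#' @param seed Integer seed.
#' @param dir Output directory for the FASTQ pair.
#' @param sample_id Label used for file names and read ids.
#' @param background Optional one-row sequence tibble for the unexplained
#'   fraction.
#' @return A list with `fastq1`, `fastq2` (paths), `truth` (tibble `ref_id`,
#'   `n_pairs_unique`, `n_pairs_emitted`) and `n_reads` (total reads written).
#' @export
simulate_sample <- function(refs, n_pairs, read_len = 150, insert_mean = 300,
                            insert_sd = 30, error_rate = 0.005,
                            duplicate_rate = 0, seed = 1,
                            dir = tempdir(), sample_id = "sample",
                            background = NULL) {
  refs <- check_seq_tbl(refs, "refs")
  if (!"fraction" %in% names(refs)) abort("`refs` needs a `fraction` column")
  if (any(refs$fraction < 0) || sum(refs$fraction) > 1 + 1e-9) {
    abort("fractions must be non-negative and sum to at most 1")
  }
  if (error_rate < 0 || error_rate > 1) abort("error_rate must be in [0, 1]")
  if (duplicate_rate < 0 || duplicate_rate > 1) {
    abort("duplicate_rate must be in [0, 1]")
  }
  if (insert_mean < read_len) abort("insert_mean must be >= read_len")
  seeds <- derive_seeds(seed, 2)
  rest <- 1 - sum(refs$fraction)
  if (rest > 1e-9) {
    if (is.null(background)) {
      background <- generate_genome(50000, uniform_composition_model(),
                                    seeds[[1L]], id = "background")
    }
    background <- check_one_seq(background, "background")
    refs <- dplyr::bind_rows(refs,
                             dplyr::mutate(background, fraction = rest))
  }
  withr::with_seed(seeds[[2L]], {
    counts <- as.integer(rmultinom(1, n_pairs, refs$fraction))
    rows <- purrr::map_dfr(which(counts > 0L), function(j) {
      n <- counts[[j]]
      s <- refs$seq[[j]]
      L <- nchar(s)
      if (L < read_len) abort(sprintf("reference '%s' shorter than read_len",
                                      refs$id[[j]]))
      insert <- pmin(pmax(round(rnorm(n, insert_mean, insert_sd)), read_len), L)
      start <- floor(runif(n) * (L - insert + 1)) + 1L
      fwd_first <- stringr::str_sub(s, start, start + read_len - 1L)
      fwd_last <- stringr::str_sub(s, start + insert - read_len,
                                   start + insert - 1L)
      flip <- runif(n) < 0.5
      tibble(
        source = refs$id[[j]],
        mate1 = ifelse(flip, reverse_complement(fwd_last), fwd_first),
        mate2 = ifelse(flip, fwd_first, reverse_complement(fwd_last))
      )
    })
    rows <- rows[sample.int(nrow(rows)), ]
    rows$read_id <- sprintf("%s_%06d", sample_id, seq_len(nrow(rows)))
    unique_counts <- table(factor(rows$source, levels = refs$id))
    dup <- rows[runif(nrow(rows)) < duplicate_rate, ]
    if (nrow(dup) > 0L) {
      dup$read_id <- paste0(dup$read_id, "_dup")
      rows <- dplyr::bind_rows(rows, dup)
    }
    rows$mate1 <- cpp_add_errors(rows$mate1, error_rate)
    rows$mate2 <- cpp_add_errors(rows$mate2, error_rate)
  })
  emitted_counts <- table(factor(rows$source, levels = refs$id))
  qual <- strrep("I", read_len)
  pairs <- tibble(read_id = rows$read_id, mate1 = rows$mate1,
                  mate2 = rows$mate2, qual1 = qual, qual2 = qual)
  fastq1 <- file.path(dir, paste0(sample_id, "_R1.fastq"))
  fastq2 <- file.path(dir, paste0(sample_id, "_R2.fastq"))
  write_fastq_pairs(pairs, fastq1, fastq2)
  list(
    fastq1 = fastq1, fastq2 = fastq2,
    truth = tibble(ref_id = refs$id,
                   fraction = refs$fraction,
                   n_pairs_unique = as.integer(unique_counts),
                   n_pairs_emitted = as.integer(emitted_counts)),
    n_reads = 2L * nrow(pairs)
  )
}

#' Generate a complete synthetic occurrence study
#'
#' Builds the full input set for the pipeline: a virus genome with a planted
#' direct terminal repeat, a planted host genome sharing the virus's
#' composition model and carrying a CRISPR array of virus-derived spacers, a
#' compositionally distinct decoy host (with decoy spacers never planted in
#' the virus), a background genome, and one paired-end library per replicate
#' of each soil sample. Soil samples form locations x depths; the deep
#' samples of all locations but the third are polluted. In `"coupled"` mode
#' the viral fraction is above the presence threshold exactly in polluted
#' samples (log-uniform on `[0.005, 0.084]`) and zero elsewhere, and the
#' planted host's fraction is an affine function of the viral fraction plus
#' noise; `"independent"` mode draws presence i.i.d. Bernoulli(0.25) per soil
#' sample, breaking the coupling.
#'
#' @param dir Output directory (created if needed).
#' @param n_samples Number of soil samples (>= 4; default 12).
#' @param n_replicates Replicate DNA isolations per soil sample (default 3).
#' @param n_pairs Read pairs per replicate library (default 2000).
#' @param coupling `"coupled"` or `"independent"`.
#' @param seed Integer master seed.
#' @param read_len,error_rate,duplicate_rate Library parameters, see
#'   [simulate_sample()].
#' @param host_length Candidate host genome length (default 60000).
#' @param virus_length,dtr_length Virus genome geometry, see
#'   [generate_virus()].
#' @param n_spacers,spacer_len CRISPR array parameters, see
#'   [plant_crispr_array()].
#' @param order,alpha Composition-model parameters, see
#'   [composition_model()].
#' @return A list with input paths (`manifest`, `virus_fasta`, `hosts_fasta`,
#'   `spacers`, `ground_truth`), the genome tibbles, and `truth` (per-sample
#'   fractions, labels and planted features).
#' @export
generate_study <- function(dir, n_samples = 12, n_replicates = 3,
                           n_pairs = 2000, coupling = c("coupled", "independent"),
                           seed = 1, read_len = 150, error_rate = 0.005,
                           duplicate_rate = 0, host_length = 60000,
                           virus_length = 67826, dtr_length = 8697,
                           n_spacers = 5, spacer_len = 32,
                           order = 3, alpha = 0.5) {
  coupling <- match.arg(coupling)
  if (n_samples < 4) abort("n_samples must be >= 4")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- derive_seeds(seed, 12 + n_samples * n_replicates)

  model_host <- composition_model(order, alpha, s[[1L]])
  model_decoy <- composition_model(order, alpha, s[[2L]])
  virus <- generate_virus(virus_length, model_host, dtr_length, s[[3L]])
  taxon_true <- "Methanosarcina_like"
  taxon_decoy <- "Methanocaldococcus_like"
  host_true <- generate_genome(host_length, model_host, s[[4L]],
                               id = "host_alpha")
  host_decoy <- generate_genome(host_length, model_decoy, s[[5L]],
                                id = "host_beta")
  planted <- plant_crispr_array(host_true, virus, n_spacers, spacer_len,
                                seed = s[[6L]], taxon = taxon_true)
  host_true <- planted$host
  withr::with_seed(s[[7L]], {
    decoy_starts <- sample.int(host_length - spacer_len, 3L)
  })
  decoy_spacers <- tibble(
    spacer_id = sprintf("%s_sp%02d", taxon_decoy, 1:3),
    taxon = taxon_decoy,
    seq = stringr::str_sub(host_decoy$seq, decoy_starts,
                           decoy_starts + spacer_len - 1L),
    virus_start = NA_integer_
  )
  spacers <- dplyr::bind_rows(planted$spacers, decoy_spacers)
  background <- generate_genome(50000, uniform_composition_model(), s[[8L]],
                                id = "background")

  loc <- rep(seq_len(ceiling(n_samples / 3)), each = 3L)[seq_len(n_samples)]
  depth <- rep(c("1.0m", "5.5m", "7.5m"), length.out = n_samples)
  group_id <- sprintf("B%d_%s", loc, depth)
  idx <- seq_len(n_samples)
  polluted <- (idx %% 3L == 0L) & (loc != 3L)

  withr::with_seed(s[[9L]], {
    tph <- ifelse(polluted, round(runif(n_samples, 300, 2000)), NA_real_)
    present <- if (coupling == "coupled") polluted else rbinom(n_samples, 1, 0.25) == 1
    vfrac <- ifelse(present, 10^runif(n_samples, log10(0.005), log10(0.084)), 0)
    host_frac <- pmax(0.001, 0.02 + 2.5 * vfrac + rnorm(n_samples, 0, 0.002))
    decoy_frac <- runif(n_samples, 0.02, 0.06)
  })

  lib_seeds <- matrix(s[12L + seq_len(n_samples * n_replicates)],
                      nrow = n_samples)
  manifest <- NULL
  for (i in idx) {
    refs <- dplyr::bind_rows(
      dplyr::mutate(virus, fraction = vfrac[[i]]),
      dplyr::mutate(host_true, fraction = host_frac[[i]]),
      dplyr::mutate(host_decoy, fraction = decoy_frac[[i]])
    )
    for (j in seq_len(n_replicates)) {
      sid <- sprintf("%s_rep%d", group_id[[i]], j)
      sim <- simulate_sample(refs, n_pairs, read_len = read_len,
                             error_rate = error_rate,
                             duplicate_rate = duplicate_rate,
                             seed = lib_seeds[i, j], dir = dir,
                             sample_id = sid, background = background)
      manifest <- dplyr::bind_rows(manifest, tibble(
        sample_id = sid, fastq1 = sim$fastq1, fastq2 = sim$fastq2,
        tph_ppm = tph[[i]], replicate_group = group_id[[i]]
      ))
    }
  }

  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, na = "")
  virus_path <- file.path(dir, "virus.fasta")
  write_fasta(virus, virus_path)
  hosts_path <- file.path(dir, "hosts.fasta")
  write_fasta(dplyr::bind_rows(
    dplyr::mutate(host_true, desc = taxon_true),
    dplyr::mutate(host_decoy, desc = taxon_decoy)
  ), hosts_path)
  spacers_path <- file.path(dir, "spacers.tsv")
  readr::write_tsv(spacers, spacers_path, na = "")

  truth <- list(
    seed = as.integer(seed),
    coupling = coupling,
    samples = tibble(group_id = group_id, polluted = polluted,
                     tph_ppm = tph, viral_fraction = vfrac,
                     host_fraction = host_frac, decoy_fraction = decoy_frac),
    planted_host_taxon = taxon_true,
    decoy_taxon = taxon_decoy,
    dtr_length = as.integer(dtr_length),
    spacer_virus_starts = planted$spacers$virus_start
  )
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  list(dir = dir, manifest = manifest_path, virus_fasta = virus_path,
       hosts_fasta = hosts_path, spacers = spacers_path,
       ground_truth = truth_path, virus = virus, hosts = dplyr::bind_rows(
         dplyr::mutate(host_true, taxon = taxon_true),
         dplyr::mutate(host_decoy, taxon = taxon_decoy)
       ), spacer_table = spacers, truth = truth)
}
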