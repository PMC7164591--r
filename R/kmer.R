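# Tetranucleotide (general k) frequency profiling, the shuffled-sequence null,
# and profile correlation — the compositional host-prediction signal. A virus
# and its host tend to share oligonucleotide usage through co-residence and
# co-evolution; shuffling the host genome preserves length and mononucleotide
# content while destroying higher-order composition, giving a negative control
# for the observed correlation.

#' All k-mers in lexicographic order
#'
#' @param k Word length (1--10).
#' @return Character vector of the `4^k` k-mers with `A < C < G < T`.
#' @export
kmer_names <- function(k) {
  if (k < 1 || k > 10) abort("k must be between 1 and 10")
  g <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  do.call(paste0, rev(as.list(g)))
}

#' Count k-mers of each sequence
#'
#' Sliding window of step 1 over the given strand only (non-canonical
#' counting); windows containing `N` are skipped, so the total is
#' `length - k + 1` minus the skipped windows.
#'
#' @param seqs Sequence tibble (columns `id`, `seq`), every sequence at least
#'   `k` long.
#' @param k Word length (default 4, tetramers).
#' @return A long tibble with columns `id`, `kmer`, `count`, `freq`
#'   (`count / total` within each sequence); `4^k` rows per sequence in
#'   lexicographic k-mer order.
#' @export
#' @examples
#' dplyr::filter(count_kmers(tibble::tibble(id = "s", seq = "ACGTACGT")),
#'               count > 0)
count_kmers <- function(seqs, k = 4) {
  seqs <- check_seq_tbl(seqs)
  short <- which(nchar(seqs$seq) < k)
  if (length(short) > 0L) {
    abort(sprintf("sequence '%s' is shorter than k = %d",
                  seqs$id[[short[[1L]]]], as.integer(k)))
  }
  nm <- kmer_names(k)
  purrr::map2_dfr(seqs$id, seqs$seq, function(id, s) {
    counts <- cpp_count_kmers(s, as.integer(k))
    total <- sum(counts)
    tibble(id = id, kmer = nm, count = counts,
           freq = if (total > 0) counts / total else NA_real_)
  })
}

# Pull one profile's count vector (lexicographic order) out of a count_kmers
# tibble, checking it describes a single sequence.
profile_vector <- function(p, arg = "p") {
  if (!is.data.frame(p) || !all(c("kmer", "count") %in% names(p))) {
    abort(sprintf("`%s` must be a count_kmers() tibble", arg))
  }
  if ("id" %in% names(p) && length(unique(p$id)) > 1) {
    abort(sprintf("`%s` contains profiles for more than one sequence", arg))
  }
  k <- unique(nchar(p$kmer))
  if (length(k) != 1) abort(sprintf("`%s` mixes k-mer lengths", arg))
  counts <- p$count[order(p$kmer, method = "radix")]
  list(k = k, counts = counts)
}

#' Pearson correlation of two k-mer profiles
#'
#' Computed on the relative-frequency vectors (`count / total`) over all
#' `4^k` coordinates, so sequences of very different lengths are comparable.
#' Identical to the correlation of raw counts up to the totals' scale, hence
#' scale-invariant.
#'
#' @param p,q Profiles from [count_kmers()], one sequence each, same `k`.
#' @return A single correlation in `[-1, 1]`.
#' @export
profile_correlation <- function(p, q) {
  pv <- profile_vector(p, "p")
  qv <- profile_vector(q, "q")
  if (pv$k != qv$k) {
    abort(sprintf("profiles have different k (%d vs %d)", pv$k, qv$k))
  }
  tp <- sum(pv$counts)
  tq <- sum(qv$counts)
  if (tp == 0 || tq == 0) abort("profile with zero total")
  fp <- pv$counts / tp
  fq <- qv$counts / tq
  if (stats::sd(fp) == 0 || stats::sd(fq) == 0) {
    abort("degenerate profile: all k-mer frequencies equal")
  }
  cor(fp, fq)
}

#' Shuffle sequences preserving composition
#'
#' A uniform random permutation of each sequence's residues: length and
#' mononucleotide content are preserved exactly while all higher-order
#' structure is destroyed.
#'
#' @param seqs Sequence tibble; non-empty sequences.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A sequence tibble of the same shape with ids suffixed
#'   `_shuffled`.
#' @export
shuffle_sequence <- function(seqs, seed) {
  seqs <- check_seq_tbl(seqs)
  if (any(!nzchar(seqs$seq))) abort("cannot shuffle an empty sequence")
  withr::with_seed(as.integer(seed), {
    shuffled <- vapply(seqs$seq, function(s) {
      paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  new_seq_tbl(paste0(seqs$id, "_shuffled"), shuffled, seqs$desc)
}

#' Virus-host k-mer correlation against a shuffled-sequence null
#'
#' Computes the Pearson correlation between the k-mer frequency profiles of
#' the virus and the candidate host, then re-computes it against `n_shuffles`
#' composition-preserving shuffles of the *host* genome (the virus profile is
#' held fixed). The mean of the null correlations is the negative control the
#' real correlation is judged against.
#'
#' @param virus,host Sequence tibbles with exactly one sequence each.
#' @param k Word length (default 4).
#' @param n_shuffles Number of shuffled controls (default 3).
#' @param seed Integer seed governing the shuffles.
#' @return An object of class `vm_kmer_null`: a list with elements `r_real`,
#'   `null` (tibble of per-shuffle correlations), `null_mean`, `k`,
#'   `n_shuffles`, `seed`, `virus_id`, `host_id`, and the two frequency
#'   profiles. Has [tidy()], [glance()], [autoplot()] and `print` methods.
#' @export
kmer_null_comparison <- function(virus, host, k = 4, n_shuffles = 3, seed = 1) {
  virus <- check_one_seq(virus, "virus")
  host <- check_one_seq(host, "host")
  if (n_shuffles < 1) abort("n_shuffles must be >= 1")
  pv <- count_kmers(virus, k)
  ph <- count_kmers(host, k)
  r_real <- profile_correlation(pv, ph)
  seeds <- derive_seeds(seed, n_shuffles)
  r_null <- vapply(seq_len(n_shuffles), function(i) {
    sh <- shuffle_sequence(host, seeds[[i]])
    profile_correlation(pv, count_kmers(sh, k))
  }, numeric(1))
  structure(list(
    r_real = r_real,
    null = tibble(shuffle = seq_len(n_shuffles), r = r_null),
    null_mean = mean(r_null),
    k = as.integer(k),
    n_shuffles = as.integer(n_shuffles),
    seed = as.integer(seed),
    strand = "single",
    virus_id = virus$id, host_id = host$id,
    virus_profile = pv, host_profile = ph
  ), class = "vm_kmer_null")
}

#' @export
print.vm_kmer_null <- function(x, ...) {
  cat(sprintf("k-mer host signal (k = %d, single strand)\n", x$k))
  cat(sprintf("  virus: %s  vs  host: %s\n", x$virus_id, x$host_id))
  cat(sprintf("  r_real    = %.3f\n", x$r_real))
  cat(sprintf("  null mean = %.3f over %d shuffles (%s)\n",
              x$null_mean, x$n_shuffles,
              paste(sprintf("%.3f", x$null$r), collapse = ", ")))
  invisible(x)
}

#' @rdname kmer_null_comparison
#' @param x A `vm_kmer_null` object.
#' @param ... Unused.
#' @export
tidy.vm_kmer_null <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "observed", shuffle = NA_integer_, r = x$r_real),
    dplyr::mutate(x$null, term = "null", .before = 1)
  )
}

#' @rdname kmer_null_comparison
#' @export
glance.vm_kmer_null <- function(x, ...) {
  tibble(r_real = x$r_real, null_mean = x$null_mean, k = x$k,
         n_shuffles = x$n_shuffles, seed = x$seed,
         virus_id = x$virus_id, host_id = x$host_id)
}

#' @rdname kmer_null_comparison
#' @param object A `vm_kmer_null` object.
#' @export
autoplot.vm_kmer_null <- function(object, ...) {
  df <- tibble(
    kmer = object$virus_profile$kmer,
    virus = object$virus_profile$freq,
    host = object$host_profile$freq
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$host, y = .data$virus)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = sprintf("host %d-mer frequency", object$k),
      y = sprintf("virus %d-mer frequency", object$k),
      title = sprintf("r = %.2f (shuffled-host null mean %.2f)",
                      object$r_real, object$null_mean)
    ) +
    ggplot2::theme_minimal()
}
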