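survey_path <- system.file("extdata", "metmv_occurrence.tsv",
                           package = "viromarker")

test_that("replicate averaging is the arithmetic mean on the normalised scale", {
  ab <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    ref_id = "v",
    mapped_reads_raw = c(60, 90, 102, 0),
    mapped_reads_dedup = c(60, 90, 102, 0),
    library_size = 1000L,
    percent_mapped = c(6.0, 9.0, 10.2, 0),
    breadth = c(0.9, 0.8, 1.0, 0),
    mean_depth = 1
  )
  mf <- tibble::tibble(sample_id = paste0("s", 1:4),
                       fastq1 = "x", fastq2 = "y",
                       tph_ppm = c(500, 500, 500, NA),
                       replicate_group = c("g1", "g1", "g1", "g2"))
  avg <- average_replicates(ab, mf)
  g1 <- dplyr::filter(avg, group_id == "g1")
  expect_equal(g1$percent_mapped, 8.4)
  expect_equal(g1$n_replicates, 3)
  g2 <- dplyr::filter(avg, group_id == "g2")
  expect_equal(g2$percent_mapped, 0)   # singleton passes through
  expect_true(is.na(g2$tph_ppm))

  expect_error(average_replicates(ab, dplyr::mutate(mf, replicate_group = NA)),
               "no replicate_group")
})

test_that("presence and pollution thresholds are inclusive", {
  expect_equal(call_presence(c(8.4, 0.0, 0.01, 0.0099)), c(1L, 0L, 1L, 0L))
  # breadth rule only fires in survey mode
  expect_equal(call_presence(0.5, breadth = 0.5, use_breadth = FALSE), 1L)
  expect_equal(call_presence(0.5, breadth = 0.5, use_breadth = TRUE), 0L)
  expect_equal(call_presence(0.5, breadth = 0.75, use_breadth = TRUE), 1L)

  expect_equal(binarize_tph(c(2000, NA, 125, 124.9, 0)), c(1L, 0L, 1L, 0L, 0L))
})

test_that("presence calling is monotone in percent and breadth", {
  pcts <- sort(runif(20, 0, 0.05))
  flags <- call_presence(pcts)
  expect_true(all(diff(flags) >= 0))
  brs <- sort(runif(20))
  flags_b <- call_presence(rep(1, 20), breadth = brs, use_breadth = TRUE)
  expect_true(all(diff(flags_b) >= 0))
})

test_that("binary co-occurrence equals the phi coefficient", {
  # the shipped occurrence survey: presence and pollution flags agree exactly
  survey <- readr::read_tsv(survey_path, show_col_types = FALSE)
  expect_equal(binary_cooccurrence(survey$presence_flag, survey$tph_flag), 1.0)

  x <- c(1, 1, 0, 0, 1, 0)
  expect_equal(binary_cooccurrence(x, 1 - x), -1.0)

  # (a,b,c,d) = (3,1,1,3) gives phi = 0.5 by the contingency formula
  p <- c(1, 1, 1, 1, 0, 0, 0, 0)
  q <- c(1, 1, 1, 0, 1, 0, 0, 0)
  expect_equal(binary_cooccurrence(p, q), 0.5)
  expect_equal(binary_cooccurrence(p, q), oracle_phi(p, q))

  set.seed(51)
  for (i in 1:20) {
    a <- rbinom(12, 1, 0.4)
    b <- rbinom(12, 1, 0.4)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(binary_cooccurrence(a, b), oracle_phi(a, b))
  }

  expect_warning(r <- binary_cooccurrence(rep(1, 5), c(0, 1, 1, 0, 1)),
                 "degenerate")
  expect_true(is.na(r))
  expect_error(binary_cooccurrence(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(binary_cooccurrence(c(1, 2), c(0, 1)), "0/1")
})

test_that("abundance correlation matches the textbook formula", {
  expect_equal(abundance_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(abundance_correlation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  x <- c(1, 2, 3, 4)
  y <- c(4, 1, 3, 2)
  expect_equal(abundance_correlation(x, y, "raw"), oracle_pearson(x, y))
  expect_warning(r <- abundance_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "degenerate")
  expect_true(is.na(r))
})

test_that("study table derives flags and glance reports phi with thresholds", {
  avg <- tibble::tibble(
    group_id = paste0("g", 1:4), n_replicates = 3,
    mapped_reads_raw = c(84, 8, 0, 1), mapped_reads_dedup = c(84, 8, 0, 1),
    percent_mapped = c(8.4, 0.8, 0, 0.005), breadth = c(1, 0.9, 0, 0.1),
    tph_ppm = c(1500, 300, NA, NA)
  )
  st <- build_study_table(avg)
  expect_equal(st$presence_flag, c(1L, 1L, 0L, 0L))
  expect_equal(st$tph_flag, c(1L, 1L, 0L, 0L))
  expect_equal(st$tph_note[[3]], "below quantification")
  gl <- glance(st)
  expect_equal(gl$phi, 1.0)
  expect_equal(gl$pct_threshold, 0.01)
  expect_equal(gl$tph_threshold, 125)

  # degenerate study (virus nowhere) yields NA phi, flagged
  st0 <- build_study_table(dplyr::mutate(avg, percent_mapped = 0))
  gl0 <- glance(st0)
  expect_true(is.na(gl0$phi))
  expect_true(gl0$degenerate)

  p <- autoplot(st)
  expect_s3_class(p, "ggplot")
})

test_that("host report flags a taxon only when all signals agree", {
  spac <- tibble::tibble(taxon = c("A", "B"), n_hits = c(5L, 1L),
                         n_distinct_spacers = c(4L, 1L),
                         best_mismatches = c(0L, 2L))
  abc <- tibble::tibble(taxon = c("A", "B"), r_raw = c(0.97, 0.1),
                        r_normalized = c(0.98, 0.05))
  kmr <- tibble::tibble(taxon = c("A", "B"), r_real = c(0.66, 0.2),
                        null_mean = c(0.5, 0.48))
  rep1 <- host_prediction_report(spac, abc, kmr)
  expect_true(rep1$consistent[rep1$taxon == "A"])
  expect_false(any(rep1$consistent[rep1$taxon != "A"]))

  # single signal: no winner declared
  rep2 <- host_prediction_report(spacer_summary = spac)
  expect_false(any(rep2$consistent))
  expect_true(all(is.na(rep2$kmer_r)))

  # conflicting rankings: no flag
  kmr_conflict <- dplyr::mutate(kmr, r_real = rev(r_real))
  rep3 <- host_prediction_report(spac, abc, kmr_conflict)
  expect_false(any(rep3$consistent))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_host_report(rep2, f)
  txt <- readLines(f)
  expect_true(any(grepl("n\\.d\\.", txt)))
})
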