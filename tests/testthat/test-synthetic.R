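test_that("composition models are valid and genome generation is seeded", {
  m <- composition_model(3, 0.5, seed = 1)
  expect_equal(dim(m$probs), c(64, 4))
  expect_true(all(abs(rowSums(m$probs) - 1) < 1e-9))

  g1 <- generate_genome(5000, m, seed = 9)
  g2 <- generate_genome(5000, m, seed = 9)
  g3 <- generate_genome(5000, m, seed = 10)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, g3$seq))

  # uniform model: GC within 4 binomial SE of 0.5
  u <- generate_genome(1000, uniform_composition_model(), seed = 2)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(gc_content(u)$gc - 0.5), 4 * se)

  # skewed order-0 model: P(G) = P(C) = 0.4 -> GC near 0.8
  sk <- uniform_composition_model(0)
  sk$probs <- matrix(c(0.1, 0.4, 0.4, 0.1), nrow = 1)
  gsk <- generate_genome(1000, sk, seed = 3)
  expect_lt(abs(gc_content(gsk)$gc - 0.8), 4 * sqrt(0.8 * 0.2 / 1000))
})

test_that("generated viruses carry the planted terminal repeat", {
  m <- composition_model(3, 0.5, seed = 4)
  v <- generate_virus(20000, m, dtr_len = 500, seed = 5)
  expect_equal(nchar(v$seq), 20000)
  expect_equal(detect_terminal_repeat(v)$repeat_length, 500L)

  v0 <- generate_virus(20000, m, dtr_len = 0, seed = 6)
  expect_equal(detect_terminal_repeat(v0)$repeat_length, 0L)

  expect_error(generate_virus(1000, m, dtr_len = 600, seed = 1),
               "at most length / 2")
})

test_that("planted CRISPR arrays are recovered by the spacer scan", {
  m <- composition_model(3, 0.5, seed = 7)
  virus <- generate_virus(20000, m, dtr_len = 0, seed = 8)
  host <- generate_genome(30000, m, seed = 9, id = "host")
  planted <- plant_crispr_array(host, virus, n_spacers = 5, spacer_len = 32,
                                seed = 10, taxon = "planted_taxon")
  expect_equal(nrow(planted$spacers), 5)
  expect_gt(nchar(planted$host$seq), nchar(host$seq))

  hits <- match_spacers(planted$spacers, virus, max_mismatches = 0)
  expect_gte(nrow(hits), 5)
  expect_true(all(planted$spacers$virus_start %in% hits$start))
  expect_true(all(hits$mismatches == 0))

  # spacers listed under a decoy taxon but never planted match nowhere
  decoy <- tibble::tibble(spacer_id = "d1", taxon = "decoy",
                          seq = random_seq(32))
  expect_equal(nrow(match_spacers(decoy, virus, 0)), 0)

  planted2 <- plant_crispr_array(host, virus, n_spacers = 5, spacer_len = 32,
                                 seed = 10, taxon = "planted_taxon")
  expect_identical(planted$host$seq, planted2$host$seq)
})

test_that("library simulation conserves truth counts and recovers fractions", {
  m <- composition_model(3, 0.5, seed = 11)
  virus <- generate_virus(30000, m, dtr_len = 1000, seed = 12)
  d <- withr::local_tempdir()
  sim <- simulate_sample(dplyr::mutate(virus, fraction = 0.08),
                         n_pairs = 5000, seed = 13, dir = d,
                         sample_id = "lib1")
  pairs <- read_fastq_pairs(sim$fastq1, sim$fastq2)
  expect_equal(nrow(pairs), sum(sim$truth$n_pairs_emitted))

  aln <- map_reads(pairs, virus)
  ab <- compute_abundance(aln, 2 * nrow(pairs), virus)
  truth_frac <- sim$truth$n_pairs_emitted[[1]] / sum(sim$truth$n_pairs_emitted)
  se <- sqrt(0.08 * 0.92 / (2 * nrow(pairs)))
  expect_lt(abs(ab$percent_mapped / 100 - truth_frac), 3 * se)

  # zero viral fraction with no shared seeds: no mapped reads at all
  sim0 <- simulate_sample(dplyr::mutate(virus, fraction = 0),
                          n_pairs = 2000, error_rate = 0, seed = 14,
                          dir = d, sample_id = "lib0")
  pairs0 <- read_fastq_pairs(sim0$fastq1, sim0$fastq2)
  expect_equal(nrow(map_reads(pairs0, virus)), 0)

  # determinism per seed
  simA <- simulate_sample(dplyr::mutate(virus, fraction = 0.05),
                          n_pairs = 500, seed = 15, dir = d, sample_id = "A")
  simB <- simulate_sample(dplyr::mutate(virus, fraction = 0.05),
                          n_pairs = 500, seed = 15, dir = d, sample_id = "A")
  expect_identical(readLines(simA$fastq1), readLines(simB$fastq1))
})

test_that("generate_study lays out samples, replicates and coupled labels", {
  d <- withr::local_tempdir()
  st <- generate_study(d, n_samples = 12, n_replicates = 2, n_pairs = 60,
                       virus_length = 4000, dtr_length = 400,
                       host_length = 5000, seed = 16)
  mf <- read_manifest(st$manifest)
  expect_equal(nrow(mf), 24)
  expect_equal(dplyr::n_distinct(mf$replicate_group), 12)
  expect_true(all(file.exists(mf$fastq1, mf$fastq2)))

  truth <- st$truth$samples
  expect_equal(sum(truth$polluted), 3)
  # coupled mode: viral fraction positive exactly in polluted samples
  expect_true(all((truth$viral_fraction > 0) == truth$polluted))
  expect_true(all(is.na(truth$tph_ppm[!truth$polluted])))
  expect_true(all(truth$tph_ppm[truth$polluted] >= 125))

  # ground truth is written and readable
  gt <- jsonlite::read_json(st$ground_truth)
  expect_equal(gt$coupling, "coupled")
  expect_equal(gt$dtr_length, 400)

  # independent mode decouples presence from pollution labels
  st2 <- generate_study(file.path(d, "ind"), n_samples = 12,
                        n_replicates = 1, n_pairs = 60,
                        virus_length = 4000, dtr_length = 400,
                        host_length = 5000, coupling = "independent",
                        seed = 17)
  expect_equal(st2$truth$coupling, "independent")
})
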