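make_pairs <- function(mate1, mate2 = reverse_complement(mate1),
                       ids = paste0("r", seq_along(mate1))) {
  tibble::tibble(read_id = ids, mate1 = mate1, mate2 = mate2)
}

test_that("error-free reads map at their origin with identity 1", {
  set.seed(31)
  ref <- seq_tbl(random_seq(4000), id = "ref")
  read <- substr(ref$seq, 201, 350)
  aln <- map_reads(make_pairs(read), ref)
  m1 <- dplyr::filter(aln, mate == 1)
  expect_equal(m1$ref_start, 201L)
  expect_equal(m1$identity, 1.0)
  expect_equal(m1$strand, "+")
  # the reverse-complement mate maps to the same window on the minus strand
  m2 <- dplyr::filter(aln, mate == 2)
  expect_equal(m2$ref_start, 201L)
  expect_equal(m2$strand, "-")
})

test_that("identity thresholding accepts 3 and rejects 10 substitutions", {
  set.seed(32)
  ref <- seq_tbl(random_seq(4000), id = "ref")
  read <- substr(ref$seq, 1001, 1150)  # 150 bp
  mutate_at <- function(s, pos) {
    for (p in pos) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  r3 <- mutate_at(read, c(40, 80, 120))     # identity 147/150 = 0.98
  r10 <- mutate_at(read, seq(5, 145, length.out = 10))  # 140/150 = 0.933
  aln <- map_reads(make_pairs(c(r3, r10), c(r3, r10)), ref,
                   min_identity = 0.95)
  expect_true(all(aln$read_id == "r1"))
  expect_equal(unique(aln$mismatches), 3L)
  expect_equal(unique(aln$identity), 0.98)
})

test_that("reads sharing no seed with the reference stay unmapped", {
  set.seed(33)
  ref <- seq_tbl(random_seq(5000), id = "ref")
  alien <- random_seq(150)
  # verify the premise with an oracle 31-mer intersection
  km <- function(s) substring(s, 1:(nchar(s) - 30), 31:nchar(s))
  expect_length(intersect(c(km(alien), km(reverse_complement(alien))),
                          km(ref$seq)), 0)
  aln <- map_reads(make_pairs(alien, alien), ref)
  expect_equal(nrow(aln), 0)
})

test_that("every error-free read sampled from the reference maps", {
  set.seed(34)
  ref <- seq_tbl(random_seq(6000), id = "ref")
  starts <- sample(nchar(ref$seq) - 100, 50)
  reads <- substring(ref$seq, starts, starts + 99)
  aln <- map_reads(make_pairs(reads), ref)
  m1 <- dplyr::filter(aln, mate == 1)
  expect_equal(nrow(m1), 50)
  expect_true(all(m1$identity == 1))
  expect_equal(m1$ref_start, starts[match(m1$read_id, paste0("r", 1:50))])
})

test_that("pair deduplication keeps one copy per coordinate signature", {
  aln <- tibble::tibble(
    read_id = rep(c("p1", "p2", "p3"), each = 2),
    mate = rep(1:2, 3),
    ref_id = "ref",
    ref_start = c(100L, 300L, 100L, 300L, 100L, 350L),
    strand = rep(c("+", "-"), 3),
    aligned_length = 100L, identity = 1, mismatches = 0L
  )
  kept <- deduplicate_alignments(aln)
  # p2 duplicates p1 exactly; p3 differs in mate-2 start
  expect_setequal(unique(kept$read_id), c("p1", "p3"))
})

test_that("simulated PCR duplicates are removed to the unique-fragment count", {
  m <- composition_model(2, 1, seed = 5)
  g <- generate_genome(20000, m, seed = 6, id = "g")
  d <- withr::local_tempdir()
  sim <- simulate_sample(dplyr::mutate(g, fraction = 1), n_pairs = 1500,
                         duplicate_rate = 0.2, error_rate = 0, seed = 77,
                         dir = d, sample_id = "dup")
  pairs <- read_fastq_pairs(sim$fastq1, sim$fastq2)
  expect_equal(nrow(pairs), sim$truth$n_pairs_emitted[[1]])
  aln <- map_reads(pairs, g)
  ab <- compute_abundance(aln, 2 * nrow(pairs), g, "dup")
  # dedup recovers the unique fragment count up to coordinate coincidences
  expect_lt(abs(ab$mapped_reads_dedup - 2 * sim$truth$n_pairs_unique[[1]]), 40)
  expect_gt(ab$mapped_reads_raw, ab$mapped_reads_dedup)
})

test_that("abundance arithmetic, breadth and edge cases", {
  ref <- seq_tbl(strrep("ACGT", 250), id = "ref")  # 1000 bp
  # 84 mapped reads of a 1000-read library -> 8.4 %
  aln <- tibble::tibble(
    read_id = paste0("p", rep(1:42, each = 2)), mate = rep(1:2, 42),
    ref_id = "ref", ref_start = rep(seq(1, 988, length.out = 42), each = 2),
    strand = rep(c("+", "-"), 42), aligned_length = 10L,
    identity = 1, mismatches = 0L
  )
  aln$ref_start <- as.integer(aln$ref_start)
  ab <- compute_abundance(aln, 1000, ref)
  expect_equal(ab$percent_mapped, 8.4)
  expect_equal(ab$mapped_reads_dedup, 84)

  # breadth from a hand-built depth profile: cover 3 of 4 positions
  tiny <- seq_tbl("ACGT", id = "t")
  a2 <- tibble::tibble(read_id = c("a", "b", "c"), mate = 1L, ref_id = "t",
                       ref_start = c(1L, 3L, 3L), strand = "+",
                       aligned_length = c(1L, 2L, 2L),
                       identity = 1, mismatches = 0L)
  ab2 <- compute_abundance(a2, 10, tiny)
  expect_equal(ab2$breadth, 0.75)

  # zero alignments
  ab0 <- compute_abundance(aln[0, ], 100, ref)
  expect_equal(ab0$percent_mapped, 0)
  expect_equal(ab0$breadth, 0)

  expect_error(compute_abundance(aln, 0, ref), "positive")
  expect_error(compute_abundance(aln, 10, ref), "library_size smaller")
})

test_that("a library tiling the reference reaches breadth 1", {
  set.seed(36)
  ref <- seq_tbl(random_seq(2000), id = "ref")
  starts <- seq(1, 1901, by = 50)
  reads <- substring(ref$seq, starts, starts + 99)
  aln <- map_reads(make_pairs(reads), ref)
  ab <- compute_abundance(aln, 2 * length(reads), ref)
  expect_equal(ab$breadth, 1.0)
})

test_that("mapped percentages are invariant under read order permutation", {
  set.seed(37)
  ref <- seq_tbl(random_seq(3000), id = "ref")
  starts <- sample(2900, 30)
  pairs <- make_pairs(substring(ref$seq, starts, starts + 79))
  perm <- pairs[sample(nrow(pairs)), ]
  a1 <- compute_abundance(map_reads(pairs, ref), 60, ref)
  a2 <- compute_abundance(map_reads(perm, ref), 60, ref)
  expect_equal(a1$percent_mapped, a2$percent_mapped)
  expect_equal(a1$mapped_reads_dedup, a2$mapped_reads_dedup)
})

test_that("best-hit taxon assignment recovers planted proportions and ties", {
  m1 <- composition_model(2, 1, seed = 41)
  m2 <- composition_model(2, 1, seed = 42)
  hostA <- dplyr::mutate(generate_genome(30000, m1, seed = 43, id = "A"),
                         taxon = "A", fraction = 0.9)
  hostB <- dplyr::mutate(generate_genome(30000, m2, seed = 44, id = "B"),
                         taxon = "B", fraction = 0.1)
  d <- withr::local_tempdir()
  sim <- simulate_sample(dplyr::bind_rows(hostA, hostB), n_pairs = 2500,
                         error_rate = 0, seed = 45, dir = d, sample_id = "tx")
  pairs <- read_fastq_pairs(sim$fastq1, sim$fastq2)
  ta <- taxon_abundance(pairs, dplyr::bind_rows(hostA, hostB))
  pa <- ta$percent_of_library[ta$taxon == "A"]
  pb <- ta$percent_of_library[ta$taxon == "B"]
  expect_lt(abs(pa - 90), 2)
  expect_lt(abs(pb - 10), 2)

  # a read present verbatim in both references is left unassigned
  shared <- substr(hostA$seq, 1000, 1149)
  hostB2 <- hostB
  hostB2$seq <- paste0(shared, hostB$seq)
  both <- dplyr::bind_rows(hostA, hostB2)
  ta2 <- taxon_abundance(make_pairs(shared, shared), both)
  expect_equal(sum(ta2$raw_reads), 0)

  expect_error(taxon_abundance(make_pairs("ACGT"), hostA[0, ]),
               "at least one reference")
})

test_that("minimal SAM output has a header and 11 mandatory columns", {
  set.seed(38)
  ref <- seq_tbl(random_seq(500), id = "ref")
  pairs <- make_pairs(substr(ref$seq, 11, 110))
  aln <- map_reads(pairs, ref)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam_minimal(aln, ref, f, pairs)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "@HD"))
  expect_true(any(startsWith(lines, "@SQ\tSN:ref\tLN:500")))
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), nrow(aln))
  expect_true(all(lengths(strsplit(body, "\t")) == 11))
})
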