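# viromarker

Detection of a marker virus across shotgun metagenome samples and in-silico
prediction of its prokaryotic host, for microbial ecologists working on
viruses that cannot be cultivated — in the motivating case, a ~68 kb circular
archaeal virus (MetMV) found in hydrocarbon-polluted soil and linked to the
methanogen genus *Methanosarcina*.

The package implements the complete inference chain as tested, reusable R
functions:

* **Genome structure** — direct terminal repeat (DTR) detection: the largest
  `L ≤ len/2` with an exact prefix/suffix match, the assembler signature of
  a circular genome; plus G+C content.
* **Occurrence** — a defined seed-and-extend read mapper (exact 31-mer seed,
  ungapped extension, ≥ 95 % identity), pair-level duplicate removal, and
  per-sample abundance as `100 · mapped_dedup / library_size` with breadth of
  coverage; presence is called at ≥ 0.01 % of the library (plus ≥ 75 %
  breadth in survey mode).
* **Host prediction** from three independent signals:
  1. CRISPR spacers of known taxa matched against the virus by an ungapped
     Hamming scan on both strands (protospacers record past infections);
  2. Pearson correlation of per-sample virus and candidate-taxon abundance
     profiles (raw counts and library-normalised percentages);
  3. Pearson correlation of tetranucleotide frequency signatures
     `r(f_virus, f_host)` over all 256 tetramers, judged against the mean of
     three composition-preserving shuffles of the host genome.
* **Co-occurrence** — presence flags vs. a binary pollution label
  (TPH ≥ 125 ppm) via the phi coefficient
  `φ = (ad − bc) / √((a+b)(c+d)(a+c)(b+d))`, identical to the Pearson
  correlation of the 0/1 vectors.
* **Synthetic studies** — a generator that plants all of the above (DTR,
  CRISPR array, coupled virus/host fractions, pollution labels) in
  multi-sample paired-end libraries with recorded ground truth, so the whole
  chain is validated by parameter recovery.

Everything is tidyverse-native: data frames in, tibbles out, with
`tidy()`/`glance()` and `autoplot()` methods on result objects, and a thin
CLI at `inst/scripts/viromarker`.

## Worked example

Generate a coupled synthetic study (12 soil samples, virus present exactly
in the three polluted ones, planted host coupled to the virus) and run the
full pipeline:

```r
library(viromarker)

study <- generate_study("study", n_replicates = 1, n_pairs = 1200, seed = 1)
cfg <- pipeline_config(study$manifest, study$virus_fasta,
                       study$hosts_fasta, study$spacers, seed = 1)
run <- run_study_pipeline(cfg, "study/out")
run
#> viromarker pipeline run
#>   libraries: 12  soil samples: 12
#>   presence flags: 3 of 12; phi vs pollution = 1.000
#>   host prediction: 'Methanosarcina_like' (consistent across signals)

run$dtr
#>             id length repeat_length suffix_start trimmed_length gc_percent is_circular_candidate
#> 1 virus_contig  67826          8697        59130          59129       49.4                  TRUE

run$report
#>                     taxon spacer_hits spacer_best_mm  r_raw r_normalized kmer_r kmer_null_mean consistent
#> 1     Methanosarcina_like           7              0  0.979        0.979  0.998          0.207       TRUE
#> 2 Methanocaldococcus_like          NA             NA -0.364       -0.364  0.008         -0.053      FALSE
```

Reading the output: the planted 8,697 bp terminal repeat is recovered
exactly on the 67,826 bp contig (so the genome is flagged as a circular
candidate, with the repeat-trimmed length also reported); presence flags
coincide with the pollution labels, giving phi = 1.0; and the planted host
ranks first on all three signals — seven protospacer hits at zero
mismatches (five planted spacers, two hit twice through the duplicated
terminal repeat), abundance correlation 0.979, and tetramer correlation
0.998 against a shuffled-host null mean of 0.207 — so it is flagged
`consistent`. The decoy taxon shows no spacer hits (`n.d.` in the written
report) and correlations near zero.

The same stages are available individually (`detect_terminal_repeat()`,
`sample_abundance()`, `match_spacers()`, `kmer_null_comparison()`,
`build_study_table()`, `host_prediction_report()`); see the vignette in
`vignettes/marker-virus-host-prediction.Rmd` for the models, parameter
meanings and design decisions.

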