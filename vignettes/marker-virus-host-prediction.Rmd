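---
title: "Detecting a marker virus and predicting its archaeal host"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a marker virus and predicting its archaeal host}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromarker)
```

## The problem

A large share of any shotgun metagenome aligns to no known organism — the
"viral dark matter". When an unknown viral contig assembles out of such data,
two questions follow immediately: *is this genome really a complete virus*,
and *which organism does it infect*? Neither can be answered by cultivation
when the candidate host is an anaerobic archaeon, so the answers have to come
from the sequence data itself. viromarker implements a complete in-silico
chain for both questions, built around the case of a ~68 kb circular virus
(MetMV) recovered from hydrocarbon-polluted soil metagenomes and predicted to
infect a *Methanosarcina*-group methanogen:

1. **Genome structure.** A direct terminal repeat (DTR) — the same sequence
   duplicated exactly at both contig ends — is the standard assembler
   signature of a circular genome.
2. **Occurrence.** The virus is called present in a sample when the fraction
   of the library's reads that map to its genome reaches a threshold
   (0.01 %), optionally combined with a breadth-of-coverage rule (75 % of
   genome positions covered) when screening external metagenomes.
3. **Host prediction** from three independent signals: CRISPR spacers of
   known taxa matching the viral genome (protospacers, a record of past
   infection); correlation of the virus's abundance profile with each
   candidate taxon's abundance across samples; and correlation of
   tetranucleotide frequency signatures, judged against a shuffled-sequence
   null.
4. **Co-occurrence.** Presence flags are correlated with a binary pollution
   label (total petroleum hydrocarbons, TPH, at the analyzer's 125 ppm
   calibration floor) via the phi coefficient — the Pearson correlation of
   two 0/1 vectors.

## Stage models and their assumptions

### Direct terminal repeats

`detect_terminal_repeat()` returns the largest `L` with
`min_len <= L <= floor(len/2)` such that the length-`L` prefix equals the
length-`L` suffix *exactly*. Exact matching is deliberate: assemblers emit
exact duplicated ends for circular genomes, and a mismatch tolerance would
only admit chance matches. The cap at half the length prevents a homopolymer
from being its own repeat. `min_len` defaults to 20 because shorter
end-matches arise by chance (a random end-match of length `L` has
probability about `4^-L`). Because a duplicated end inflates the apparent
genome size, the result reports both the raw and the repeat-trimmed length
and does not decide which one "is" the genome size.

### Read mapping and abundance

The mapper is a defined seed-and-extend procedure rather than a wrapper
around an external aligner, so its behaviour is part of the package's
contract and is validated by property tests: a mate maps when it shares at
least one exact 31-mer with the reference (either strand) and its best
ungapped end-to-end placement anchored at a shared seed reaches 95 %
identity. Ties go to the leftmost placement, then the plus strand. Seeds
occurring more than 16 times in the reference are skipped when collecting
candidate placements (standard repetitive-seed limiting); if that removes
every candidate, the least-frequent shared seed's positions are used
instead, so an error-free read always retains its true placement.

Consequences to be aware of:

* **No indels.** Alignment is ungapped. For presence/abundance estimation on
  substitution-dominated data this is adequate; reads from indel-rich
  regions would be lost.
* **Duplicates** are removed per read pair on the joint
  `(ref_start, strand)` signature of both mates, the usual duplicate-marking
  semantics; orphan mates use their own signature. Counts are invariant to
  which duplicate copy is kept.
* **Library size** is the total number of reads supplied (two per pair),
  with no internal quality trimming: the denominator is whatever read set
  the caller provides, which resolves the ambiguity between raw and trimmed
  library sizes by contract.
* **Depth** counts each aligned base of each surviving mate once, so
  overlapping mates of one pair double-count. Breadth (fraction of positions
  with depth ≥ 1) is unaffected by this simplification.

`taxon_abundance()` assigns each read to the candidate genome with the
highest placement identity and leaves ties unassigned — a deliberately
conservative stand-in for taxonomic classification that is only meaningful
against the supplied candidate genomes.

### k-mer host signal

`count_kmers()` counts on the given strand only (non-canonical), windows
containing `N` are skipped, and `profile_correlation()` is the Pearson
correlation of the two *relative frequency* vectors over all `4^k`
coordinates. Frequencies, not counts, so a 68 kb virus is comparable with a
multi-Mb host genome; Pearson, not Spearman, so one estimator is used for
every correlation in the package. The null model
(`kmer_null_comparison()`) shuffles the *host* genome — preserving length
and mononucleotide content exactly while destroying higher-order
composition — three times by default and reports the mean null correlation
alongside the observed one. The single-strand convention is recorded in the
output metadata.

### CRISPR spacer signal

`match_spacers()` is an exhaustive ungapped Hamming scan of every spacer
against both strands, reporting *all* windows within the mismatch budget
(default 3) — overlapping hits are not masked, and minus-strand hits report
the forward-strand coordinate of the window. An ungapped budget replaces a
gapped aligner's model: spacers are 20–60 bases long, and at that length a
small Hamming budget captures the biologically plausible hit set while
staying exactly testable against a brute-force oracle. There is no
wrap-around matching across the ends of a circular contig; a DTR already
duplicates the junction sequence, so junction-spanning protospacers are
still found in practice. All coordinates in this package are 1-based.

### Presence, binarisation, co-occurrence

All thresholds are **inclusive** (`>= 0.01 %`, `>= 75 %` breadth,
`>= 125 ppm`), and the convention is recorded in every report. A missing TPH
concentration means *below the analyzer's quantification floor* and maps to
"non-polluted" — it is kept distinct from an explicit zero throughout.
Replicate DNA isolations of one soil sample are averaged on the normalised
scale (mean of percentages), i.e. normalised-then-averaged; averaging raw
counts first would weight replicates by their library sizes and give
different numbers. The breadth rule is off for manifest samples and intended
for survey mode (screening external metagenomes), where mapped-read
percentages alone are unreliable.

`binary_cooccurrence()` refuses to emit a number for a constant vector
(returns `NA` with a warning) rather than silently reporting a degenerate
correlation. The same policy applies to constant abundance vectors and to
flat k-mer profiles.

The merged `host_prediction_report()` declares no winner unless **all**
available signals (at least two) rank the same taxon first; that taxon is
then flagged `consistent`. Signals not computed for a taxon are rendered
`n.d.` in the written report.

## The synthetic study generator

`generate_study()` produces the full input set with the statistical
structure the analysis assumes, plus ground truth:

* Virus and planted host genomes are sampled from the **same** order-3
  Markov composition model (rows Dirichlet-distributed, concentration 0.5),
  a decoy host from an independent model — this is exactly the structure the
  tetramer signal assumes (shared composition through co-residence).
* The virus carries a planted DTR (defaults 67,826 bp with an 8,697 bp
  repeat, the scale of the motivating contig).
* The planted host carries a CRISPR array of five 32-base virus windows;
  the decoy taxon gets spacers drawn from its own genome, which therefore
  match nowhere in the virus.
* Twelve soil samples in a locations-by-depths layout, the deep samples of
  three of the four locations polluted (TPH uniform on 300–2000 ppm,
  missing below the floor elsewhere), three replicate libraries per soil
  sample, 2,000 read pairs of 150 bases per library by default.
* In **coupled** mode the viral fraction is log-uniform on [0.005, 0.084]
  (the upper end matching the largest observed occurrence, 8.4 %) in
  polluted samples and zero elsewhere, and the planted host's fraction is
  affine in the viral fraction (`0.02 + 2.5 v`) plus Gaussian noise
  (sd 0.002), so the abundance correlation is recoverable near 1 by
  construction. **Independent** mode draws presence i.i.d. Bernoulli(0.25)
  per soil sample, breaking the coupling while keeping everything else
  identical.
* Reads carry substitution errors only (default 0.005 per base, matching
  the ungapped mapper); optional PCR duplicates are re-emissions of whole
  pairs. The unexplained majority of each library comes from a uniform
  random background genome — emulating the fact that most metagenome reads
  match nothing, without modelling real dark-matter composition.

What the generator does **not** emulate: real genome repeat structure and
mobile elements, GC-dependent coverage bias, quality-score profiles, indels
and chimeras, multi-Mb host genome sizes (candidate hosts default to 60 kb
to keep studies desk-sized — the compositional signal at 60 kb is already
stable), or real taxonomic breadth (two candidate hosts instead of a
database). Passing the recovery tests therefore demonstrates that the
*inference chain* is correct under its own assumptions, not that those
assumptions hold for any particular real dataset.

## Numerical and testing choices

* Every generator is deterministic per (parameters, seed); sub-seeds are
  derived from the master seed by one `sample.int()` draw, so no stage's
  randomness can silently interact with another's.
* `N` never matches anything: k-mer windows and spacer-scan windows
  containing `N` are skipped, and `N` counts as a mismatch during placement
  extension. GC content excludes `N` from numerator and denominator.
* Degenerate inputs (constant binary vectors, flat profiles, all-`N`
  sequences, empty groups) raise errors or flagged `NA`s; they never produce
  silent numbers.
* Test problem sizes are chosen for a desk-scale run: oracle-equivalence
  sweeps use 50–100 random instances; abundance recovery uses 50,000 read
  pairs per condition (fractions from 10⁻⁴ to 0.084 re-estimated within
  three binomial standard errors); the end-to-end recovery properties use
  100 seeded 12-sample studies at 800 pairs per library. At those depths a
  polluted sample at the very bottom of the fraction range occasionally
  yields zero viral pairs (about 1–2 % of runs), which is why the
  end-to-end acceptance rates are specified as ≥ 95/100 and ≥ 90/100 rather
  than all-or-nothing; at the generator's default depth (2,000 pairs,
  three replicates) the event is negligible.
* For twelve samples, two genuinely independent 0/1 vectors still reach
  `|phi| >= 0.5` in roughly 9 % of draws (exact enumeration over the
  Bernoulli presence model); the independent-study criterion of ≥ 90 quiet
  runs out of 100 sits deliberately at that boundary — it tests that the
  pipeline adds no *systematic* association on top of chance.

## Worked example

```{r example, eval = FALSE}
library(viromarker)

study <- generate_study("study", n_replicates = 1, n_pairs = 1200, seed = 1)
cfg <- pipeline_config(study$manifest, study$virus_fasta,
                       study$hosts_fasta, study$spacers, seed = 1)
run <- run_study_pipeline(cfg, "study/out")
run
glance(run$study)   # phi, flag counts, thresholds
run$report          # per-taxon host-prediction table
autoplot(run$study) # occurrence bar chart by soil sample
```

## Known limitations

* Ungapped mapping and matching throughout; indel-divergent viruses or
  spacers are invisible.
* `taxon_abundance()` is best-hit against supplied genomes only — it is not
  a taxonomic classifier and inherits the candidate list's biases.
* No significance testing is attached to any correlation; with a dozen
  samples the binary phi in particular should be read as descriptive.
* Survey mode's breadth rule needs reasonably even coverage; a virus with a
  large deletion polymorphism could fail 75 % breadth while genuinely
  present.
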