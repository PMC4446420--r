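---
title: "Stage-resolved detection of tRNA wobble inosine: models and methods"
author: "inosine34"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved detection of tRNA wobble inosine: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inosine34)
```

## The measurement model

Inosine is a guanosine analogue: reverse transcriptases and sequencers read
it as `G`. For the eight human tRNA types whose genomically encoded
anticodon begins with adenosine (ANN tRNAs: Ala-AGC, Arg-ACG, Ile-AAT,
Leu-AAG, Pro-AGG, Ser-AGA, Thr-AGT, Val-AAC), an A-to-G mismatch at the
first anticodon residue (position 34) in a small RNA-seq read is therefore
a direct readout of A-to-I editing by the heterodimeric tRNA deaminase
(ADAT2/ADAT3). The package estimates, per tRNA type, the A/G mismatch
proportion

$$\hat\pi = \frac{n_G}{n_A + n_G}$$

at residue 34, separately for two maturation stages, and tests differences
in this proportion between stages and between conditions with two-sided
Fisher exact tests, Benjamini–Hochberg-adjusted across the family of types
tested together.

Three features of tRNA biology shape the pipeline:

* **Multi-copy gene families.** A tRNA type is encoded by several genomic
  copies with identical (or near-identical) mature sequence, so most tRNA
  reads multi-map. A read is kept only if every gene it aligns to belongs
  to one type ("unequivocal" assignment); reads touching two or more types
  are discarded entirely. Within a type, a multi-mapping read is counted
  once, at its primary alignment — counting it at every copy would inflate
  depth by copy number without changing type-level composition, since
  copies are identical. A flag-free design decision: the package consumes a
  SAM that reports all hits per read and performs the set logic itself,
  which reproduces the two-pass alignment bookkeeping with a single input
  contract.
* **Maturation stages.** Primary transcripts carry 5′-leader and
  3′-trailer sequences that are removed during maturation. A read whose
  aligned span (soft clips excluded) lies entirely within the mature gene
  span is `processed`; a read with at least one aligned nucleotide outside
  it is `precursor`. A read overlapping only flank sequence is classified
  precursor — it consists of leader/trailer sequence by definition.
  Fragments internal to the mature span are processed reads; they cannot
  be distinguished from full-length molecules at this read length and are
  not separated.
* **Sparse, biased coverage.** tRNA reads are rare and unevenly
  distributed, so gene copies with anticodon depth below `min_depth`
  (default 10) are removed before aggregation, and the package deliberately
  does not rank editing levels across tRNA types: library and mapping
  biases differ per type, so only within-type contrasts (stage or
  condition) are emitted by default.

## Coordinates and pileups

All genomic coordinates are 0-based half-open internally, matching SAM/BED
arithmetic. Window positions are indexed relative to residue 34 in tRNA
sense orientation: 0 is residue 34, +1 is 35, +3 is 37; minus-strand genes
contribute complemented bases at mirrored offsets. The anticodon offset
within the mature sequence is explicit input rather than inferred from
secondary structure (offsets vary with D-loop length);
`infer_anticodon_offset()` derives it by substring search and errs on
ambiguity. Pileups are built per gene copy over a ±`window` nt window
(default 50, mirroring the base-calling window around the anticodon used
with the real libraries), coverage-filtered per copy, then summed to type
level; the sum is associative, so copies and replicates can be pooled in
either order. Base-quality weighting is not applied (the reference analysis
used raw base calls); intron-carrying genes are loaded but excluded from
assignment by default, since their genomic anticodon coordinates only apply
to unspliced precursors.

## Statistics

`fisher_exact_2x2()` computes the two-sided Fisher exact p-value (summing
hypergeometric probabilities no larger than the observed table's, with the
common 1e-7 relative tie tolerance); `bh_adjust()` applies the
Benjamini–Hochberg step-up over the non-missing p-values. Both delegate to
R's reference implementations (`fisher.test`, `p.adjust`); the test suite
verifies them against an independent log-binomial enumeration and a direct
transcription of the step-up formula. Two-sided testing is the default
because both increases (maturation) and decreases (knockdown) are real
hypotheses; the BH family is the set of types in one comparison (the eight
ANN types), mirroring per-figure adjustment, not all window positions.
Replicates are pooled before testing (aggregated counts), with per-copy
tables available upstream. Stars annotate adjusted values at
0.05/0.01/0.001. `wilson_interval()` is provided as a convenience and is
not part of the testing procedure.

## The synthetic-data generator

`build_genome()` and `simulate_reads()` exist so every downstream stage is
testable against exact per-read truth without an aligner or external data.
The generator emulates: identical multi-copy genes per type (one chromosome
per type, three copies by default, copy 2 minus-strand so the
complementation paths are exercised); an optional cross-type pair of genes
sharing one mature sequence (their mature-contained reads genuinely
multi-map across types and must be discarded); reads with and without
leader/trailer overlap; Bernoulli editing at residue 34 with
stage-dependent probability; the stepwise position-37 modification of
Ala-AGC (read G when carrying inosine 37, T when 1-methylinosine 37);
uniform per-base substitution error; fragment-length variation; and a
knockdown condition that multiplies all editing probabilities by a factor
κ.

Default study conditions, chosen once: editing probability 0.2 in precursor
and 0.8 in processed reads (a low-but-detectable early level rising towards
the near-complete modification of mature ANN tRNAs), per-base error 0.005
(Illumina-like), κ = 0.5 (a partial knockdown, as expected from shRNA),
an even precursor/processed split, 85% of read spans covering the
anticodon, mature length 76 nt (canonical), and a position-37 model of
G = 0.3/T = 0 in precursors vs G = 0.3/T = 0.4 in processed reads (the
methylated readout appears only downstream in maturation). Residue 37 of
every synthetic mature sequence is reference A so the position-37 readout
and the background profile have a defined substrate in every type.

The error model substitutes each base independently with probability ε,
uniformly over the three other bases. Its implied rates, used by the
negative-control tests: non-reference fraction ε at any unmodified
position; background A-to-G proportion (ε/3)/(1 − 2ε/3).

What the generator does **not** emulate — and hence what passing tests do
not show about real libraries: ligation and RT biases against structured
or modified tRNAs, adapter artefacts, quality-score structure, per-molecule
correlation of modification states, size selection, and near-identical (as
opposed to identical) gene copies. Truth-equality tests demonstrate the
bookkeeping is exact; they cannot certify unbiasedness on real data, which
is precisely why cross-type level comparisons are suppressed by default.

The truth SAM contains one alignment per true origin plus, for
ambiguous-pair reads contained in the shared mature sequence, a secondary
record on the partner gene; precursor reads of the pair carry copy-specific
flank sequence and genuinely map uniquely. Emitting truth alignments
removes the aligner from the test loop while the FASTQ output keeps real
alignment possible.

## Numerical and degenerate-input choices

* Editing fraction uses G/(A+G); C/T calls are reported but excluded, so
  the statistic is insensitive to symmetric error at the other bases.
* Zero depth yields missing values, never zeros: a type/stage without
  coverage is absent from proportions, and a position without coverage has
  `NA` fractions.
* Degenerate Fisher tables: a zero margin gives p = 1, the all-zero table
  gives `NA`.
* Coverage filtering is per copy at the raw depth (all four bases) of the
  residue-34 position, applied before aggregation; the boundary is
  inclusive (depth exactly `min_depth` is retained).
* Determinism: all simulation randomness flows from one seed; identical
  configuration and seed give byte-identical FASTQ/SAM/TSV outputs, and
  every simulated dataset directory carries its resolved configuration and
  an md5 manifest.

## In-vitro readouts

`sanger_readout()` predicts the chromatogram-level consequence of full
deamination (every inosine position reads G, all else unchanged).
`endov_cleave()` predicts Endonuclease V fragmentation: EndoV cleaves the
second phosphodiester bond 3′ of an inosine, so the 5′ product retains one
nucleotide past the inosine. For the canonical pre-tRNA construct — 6-nt
leader, 76-nt mature with inosine at residue 34, 13-nt trailer — this gives
a 41-nt 5′ arm and a 54-nt 3′ arm from the 95-nt construct. The leader and
trailer lengths of `example_val_construct()` are back-derived from that
length arithmetic; the sequence content is synthetic (the construct's exact
sequence is not machine-readable from the original figure), which is why
the function and its documentation label it a synthetic stand-in. The
cleavage offset is a parameter (`nt_after_inosine`) should a different
enzyme convention be needed.

## Problem sizes used by the test suite

The suite runs entirely on generated data at desk scale: the stage-contrast
dataset uses 8 types × 3 copies × 1700 expected reads per copy (≈41k reads;
≈2200 anticodon-covering reads per type and stage), the exact-recovery
dataset 500 reads per copy with ε = 0, the knockdown contrast 800 reads per
copy per condition, and the null-calibration check 200 simulated
eight-type families at the count level. These sizes give the binomial
standard errors the assertions are written against (3·SE windows), chosen
so that each check is decisive at desk scale.

## Known limitations

* Alignment is out of scope: the package consumes SAM and trusts the
  aligner's mismatch handling; soft clips are excluded but no realignment
  is attempted.
* Spliced (intron-gapped) alignments are not handled; intron-carrying
  genes are excluded from assignment by default.
* The precursor class conflates 5′-leader-only, 3′-trailer-only and
  both-ended intermediates; callers can split on the assigned span if
  needed.
* Editing calls other than the A→G (inosine) and →T (1-methylinosine)
  readouts are out of scope.
```{r example, eval = FALSE}
cfg <- sim_config(depth_per_copy = 300, seed = 1)
sim_dir <- tempfile()
run_simulate(cfg, sim_dir)
analysis <- run_analyze(file.path(sim_dir, "genes.tsv"),
                        file.path(sim_dir, "genome.fa"),
                        file.path(sim_dir, "truth.sam"),
                        condition = "control")
editing_fraction(analysis$pileups)
run_compare(analysis, mode = "stage")
```
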