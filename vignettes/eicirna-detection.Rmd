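---
title: "Detecting exon-intron circular RNAs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting exon-intron circular RNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eicir)
library(dplyr)
```

## The problem

Circular RNAs arise when a downstream splice donor joins an upstream splice
acceptor (back-splicing), producing a covalently closed circle whose
diagnostic signature in RNA-seq is the back-splice junction (BSJ) read.
Most circRNAs contain only exonic sequence (EcircRNAs), but a subclass —
exon-intron circRNAs (EIciRNAs) — retains one or more introns between the
circularised exons. Standard circRNA callers report BSJs but say nothing
about whether the internal introns are retained, so EIciRNAs are invisible
to them. `eicir` closes that gap: starting from BSJ calls (CIRI2-format
table), a genome, an annotation and the read data, it decides which calls
are EIciRNAs and which internal intron is retained.

Detection runs in three steps:

1. **Host assignment.** Each `exon`-type BSJ call is scored against every
   overlapping transcript: 2 when both call boundaries coincide exactly
   with annotated exon boundaries (start with an exon start, end with an
   exon end), 1 when exactly one matches, 0 otherwise. All transcripts at
   the maximal score become hosts, and their introns falling inside the
   call span are the candidate retained introns.
2. **Intronic evidence from BSJ pairs.** The read pairs that support a BSJ
   are re-placed on a circular pseudo-reference: the genomic span of the
   circle plus its first `readlen - 1` bases appended again (the rotation
   pad), so any read from the circle — including one crossing the BSJ —
   aligns contiguously. Each placed mate is projected back to genomic
   coordinates; a call becomes a candidate EIciRNA if at least one pair
   has a mate mapping entirely within a candidate intron, or crossing an
   exon/intron boundary with at least 5 aligned bases on both sides.
3. **Retention validation.** From the genome alignments of *all* reads,
   five per-intron metrics are computed: `#EE` (spliced reads whose gap
   matches the intron exactly), `#EI` and `#IE` (unspliced reads crossing
   the 5' and 3' intron boundaries), `#I` (reads inside the middle 200 nt
   of the intron, or the whole intron when shorter) and `#IC` (fraction of
   intron positions covered). All junction-type counts require a 5 nt
   overhang. An intron validates when `#EE >= 1`, `#EI >= 1`, `#IE >= 1`,
   `#I >= 1` and `#IC >= 0.9`; a call with a validated candidate intron is
   reported as an EIciRNA, quantified by its count of step-2-qualifying
   BSJ pairs and normalised as BRPM (back-spliced reads per million mapped
   reads).

Note the consequence of requiring `#EE >= 1`: a retained intron can only be
validated at a locus that also produces spliced (linear) reads across the
same intron. This is deliberate — the metrics use all primary alignments,
not just circle-derived ones, so a locus transcribed exclusively into the
retained form is not callable under these rules.

## Percent intron retention and intron classes

The fraction of splicing events that retain an intron is summarised as

$$\mathrm{PIR} = \frac{(\#EI + \#IE)/2}{(\#EI + \#IE)/2 + \#EE},$$

defined as 0 when no junction read of either kind is observed. This is the
standard junction-read-based retention ratio of the intron-retention
literature; the same ratio computed on a poly(A)-plus (linear) library is
used as the linear retention ratio (IRratio). Introns are then classed as:

* **CIR** — retained in a circRNA: validated with circ-context
  `PIR >= 0.1`;
* **NCI** — internal to an EcircRNA but spliced out of it:
  `PIR <= 0.02`;
* **LIR** — retained in a linear transcript: linear `IRratio >= 0.1`.

An intron meeting several definitions receives all matching labels, so the
overlap between classes is visible rather than silently resolved.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `overhang` | 5 | nt | minimum aligned bases flanking any junction; shorter overhangs make junction assignment unreliable |
| `min_support` | 1 | pairs | step 2 is deliberately permissive; validation happens in step 3 |
| `IC` cutoff | 0.9 | fraction | near-complete intron coverage distinguishes retention from spurious intronic fragments |
| `EE`, `EI`, `IE`, `I` minima | 1 | reads | presence thresholds of the validation rule |
| `min_mapq` | 1 | — | excludes typical multi-mappers from the metrics; intronic sequence attracts repeats |
| `max_mismatch_rate` | 0.05 | fraction | pseudo-reference placement tolerance per mate |
| `k` (seed length) | 20 | nt | exact seed for the built-in placement |
| CIR / NCI / LIR cutoffs | 0.1 / 0.02 / 0.1 | PIR | class definitions above |

PIR cutoffs and validation thresholds are exposed in `RunConfig`-style
config lists and as function arguments; the tie rule for equally scored
host transcripts (union vs intersection of their introns) is switchable in
`assign_hosts()` (`tie_rule`), with union as the default since a
single-winner rule would silently drop candidate introns.

## The built-in placement and its limits

Production pipelines typically delegate read placement to an external
aligner. `eicir` instead ships a small exact-k-mer-seeded, ungapped placer
(`place_pair()`): non-overlapping 20-mers of each mate are looked up in the
pseudo-reference, candidate offsets are scored by full-length Hamming
distance, and a mate places when its best offset is unique with at most 5%
mismatches; mates of a pair must land on opposite strands. This keeps the
whole pipeline hermetic and testable. The cost is that indel-containing or
spliced reads do not place — in particular, a read spanning a *spliced*
junction of the circle (whose intron is present in the pseudo-reference)
is rejected rather than split-aligned. Such reads can only generate
spurious boundary evidence when a mate overhangs an exon edge by a few
error-tolerated bases; step-3 validation removes these, which our
planted-truth tests confirm (zero false EIciRNA calls). Externally aligned
SAM against the pseudo-references can replace the built-in placer where
gapped alignment matters.

## What the simulator emulates — and what it does not

`make_toy_genome()` plants non-overlapping plus-strand genes (default 3
genes x 5 exons of 150 nt, 400 nt introns) in uniform-random sequence with
canonical boundaries (`GT..AG`, a `GTAAGT` donor and a pyrimidine tract
before the acceptor) so that splice-site PWMs are trainable from the toy
annotation. `simulate_reads()` draws Gaussian fragment lengths (default
300 +/- 30 nt, truncated at the read length; the defaults respect the
recommendation of >250 bp fragments and 150 bp reads for EIciRNA
detection) from spliced mRNA, circularised spliced exons (EcircRNA) or
circularised exons plus one retained intron (EIciRNA), applies uniform
substitution errors (default 0.005/base) and emits FASTQ, a per-pair truth
table, a CIRI2-schema truth BSJ table and genome SAM records equivalent to
a splice-aware aligner's output (computable exactly because true origins
are known; BSJ-crossing mates are soft-clipped at the junction, as a local
aligner would).

The default study design places the EIciRNA and a linear transcript on
gene 1, an EcircRNA on gene 2 and a linear transcript on gene 3 — the
linear gene-1 transcript is required by the validation rule itself (it
supplies the `#EE` reads, see above). The simulator does *not* model
quality-score variation, indels, PCR duplicates, rolling-circle reads,
coverage biases or minus-strand templates; a pass on simulated data
therefore demonstrates the correctness of the counting and decision rules,
not robustness to real-library artefacts.

## The intron-class neural network

The three-class intron analysis (NCI / CIR / LIR) is implemented on the
sequence-computable feature subset: log10 intron length, intron GC,
relative transcript position (ordinal / intron count), donor and acceptor
PWM log-odds scores (PWMs trained on the catalog's annotated introns with
pseudocount 1; windows of 3 exonic + 6 intronic nt and 20 intronic + 3
exonic nt), and flanking-exon lengths and GC. Conservation, secondary
structure, motif-database and nucleosome features require external
resources and are out of scope, but the feature matrix accepts extra
user-supplied numeric columns.

"Three-layer" is read as three hidden layers; sizes default to 64/32/16
with rectified-linear activations and a softmax output — none of these are
dictated by the analysis being reproduced, so all are configurable.
Training uses mini-batch Adam (learning rate 1e-3, batch 64, L2 1e-4, 150
epochs) on a class-weighted cross-entropy (inverse class frequency),
with a stratified 70/15/15 train/validation/test split; standardisation
parameters come from the training split only, and a fixed seed makes the
fit bit-identical. Evaluation is pairwise one-vs-one AUROC/AUPRC on the
held-out test split (a held-out split, not cross-validation, is used and
reported as such), with permutation importance as the mean AUROC drop over
20 shuffles per feature, signed by the point-biserial correlation.

`make_feature_dataset()` draws class-conditional Gaussians whose mean
shifts follow the observed effect directions (CIR and LIR vs NCI: shorter,
higher GC, weaker splice sites; CIR vs LIR: longer, lower GC, closer to
the 5' end), with the shift magnitude in within-class standard deviations
as the `effect_size` knob.

## Quantification choices

* **BRPM denominator**: total primary mapped reads of the library, the
  standard per-million-mapped reading; this depth-normalises across
  libraries.
* **tau**: replicate samples are averaged (arithmetic mean) per tissue
  before the index; values are `log2(x + 1)`-transformed by default
  (common practice for expression-based tau), switchable and recorded in
  the output header. `tau = sum(1 - x_i / max(x)) / (n - 1)`; undefined
  (flagged, not 0) for all-zero vectors.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; GTF, CIRI2 and SAM are
  converted at the I/O boundary.
* The `#I` window is centred with a `floor((len - 200)/2)` offset.
* `#EE` requires the spliced gap to match the intron exactly on both
  boundaries; near-miss gaps indicate different splice events, not
  evidence about this intron.
* A read contributing an exact-gap `#EE` event at an intron is excluded
  from `#EI`/`#IE` there; a single unspliced read may count once per
  boundary (`#EI` at the 5' and `#IE` at the 3' boundary).
* Strand `.` is treated as `+` for sequence extraction (with a warning);
  retention metrics are strand-symmetric, only intron ordinals depend on
  strand.
* Abutting exons (zero-length gaps) produce no intron, with a warning.
* Ambiguous placements (tied best offsets) are reported as `ambiguous`
  and never classified; duplicate reads are not removed.
* Circles shorter than 20 nt are refused as un-placeable.

## Problem sizes

The bundled checks run at deliberately small scale so the whole suite
completes in minutes on one CPU: the planted-truth recovery uses the
default 3-gene toy genome at 50x depth over 20 seeds; oracle-equivalence
checks use 50 random fixtures of at most 200 reads and 100 random
catalogs; the classifier demonstration uses 600 introns per class with
2-sd effects. These sizes are choices of the test design, not limits of
the implementation.

## Known limitations

* Only single-intron EIciRNA records are produced per candidate intron;
  multi-intron EIciRNAs are reported as separate records only when each
  intron validates independently — intron combinations within one circle
  are not modelled.
* The detector consumes BSJ calls; it does not discover BSJs from
  chimeric reads itself.
* The built-in placer is ungapped (see above); GFF3 annotations and
  minus-strand simulation templates are unsupported.
* Whether the linear-library IRratio and the circ-context PIR are
  numerically identical metrics is left open in the source analysis; one
  junction-based ratio is used for both contexts here, with the library
  type recorded alongside.
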