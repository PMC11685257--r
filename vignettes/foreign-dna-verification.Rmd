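---
title: "Verifying transgene-free genome-edited strains from k-mer evidence"
author: "transclean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying transgene-free genome-edited strains from k-mer evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transclean)
```

## The question the pipeline answers

A strain edited with a CRISPR/Cas9 transformation plasmid is only usable as
a non-GMO product if none of that plasmid's DNA remains in its genome.
Southern blots and targeted PCR can miss short integrated fragments, so the
decisive evidence comes from whole-genome resequencing: if any piece of the
vector 20 bp or longer is present in the edited genome, reads covering it
will contain 20-mers unique to the vector.  Published detection-limit work
underpins the parameters: DNA fragments of 20 bp and longer are effectively
unique in these genomes, and at sequencing depths of 30-fold and above a
20-mer scan detects such inserts with a very low false-positive rate.
`transclean` implements this evidence chain end to end, together with the
companion amplicon-level analyses used to characterise the edits
themselves.

## Model and procedure

**k-mer count tracks.**  For every position $p$ of the vector sequence
(positions are 20-mer window starts, 1-based), we count the number of reads
$n_p$ that contain the canonical form of the vector's 20-mer at $p$.  The
canonical form of a k-mer is the lexicographic minimum of the k-mer and its
reverse complement, which matches both strands symmetrically without
scanning reads twice.  A read increments a position at most once, so $n_p$
is "the number of reads supporting this 20-mer" and is bounded by the local
sequencing depth.  Both mates of a pair are independent reads.  The track
also records the total number of reads scanned, $N$.

**Per-position G-test.**  At each position the edited sample
(count $a$ of $A$ reads) is compared to a wild-type control
(count $b$ of $B$ reads) with a G-test of independence on the 2x2 table
with both margins observed:

$$G = 2 \sum_{ij} O_{ij} \ln\left(\frac{O_{ij}}{E_{ij}}\right),\qquad
O = \begin{pmatrix} a & A-a\\ b & B-b \end{pmatrix},\quad
E_{ij} = \frac{r_i c_j}{N},$$

with zero cells contributing nothing.  $G$ is asymptotically
$\chi^2_1$; a position is significant when $G$ exceeds the critical value
$6.634$, the $0.99$ quantile of $\chi^2_1$ truncated to three decimals,
i.e. the 1% level.  The statistic equals twice the log-likelihood ratio of
two free binomials against a pooled binomial, which is how the test suite
cross-checks it.

**Peaks and classification.**  Maximal runs of significant positions with
one enrichment direction form peaks (`peakGap` non-significant positions
may be bridged; the default is 0, and adjacent positions with opposite
directions never merge).  Classification is biological:

* *sample-enriched* peak -> **foreign candidate**: the edited strain
  supports vector sequence its control does not — the signature of
  integrated plasmid DNA;
* *control-enriched* peak overlapping the gRNA spacer window ->
  **target-mutation signature**: the wild type still carries the intact
  20-bp target that the edited strain destroyed by its indel;
* other control-enriched peaks -> unclassified;
* non-significant regions supported by both tracks are reported as shared
  endogenous sequence.

The strain is declared **foreign-free** iff no foreign candidate remains.
A target-mutation signature is expected in a successful clean edit and
does not negate the verdict.

**Amplicon-level evidence.**  The remaining links of the chain are:
global affine-gap alignment of amplicons to a reference
(`globalAlign()`), an indel call in the protospacer+PAM window with size
and offset from the cut site (`callTargetMutation()`; the blunt cut falls
between protospacer positions 17 and 18, 3 bp from the PAM), SNV-based
assignment of an amplicon to the donor or recipient nucleus
(`assignNucleusOrigin()`), and exact-match in-silico PCR
(`insilicoPcr()`) reproducing presence/absence genotyping.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 20 bp | word size of the scan; 20 bp is the uniqueness threshold for foreign DNA |
| `gCritical` | 6.634 | 1% critical value of $\chi^2_1$, truncated to 3 decimals |
| `peakGap` | 0 | non-significant positions bridged inside a peak |
| `multipleTesting` | none | every position is tested at the fixed threshold; Bonferroni available |
| `williams` | FALSE | Williams' continuity correction on G |
| `coverage` | 30x | simulated depth; the regime in which 20-bp detection is reliable |
| `readLength` | 150 bp | paired-end read length |
| `errorRate` | 0.001 | per-base substitution error |
| `insertMean`, `insertSd` | 400, 50 bp | fragment-length model, truncated at the read length |

The default of **no multiple-testing adjustment** replicates the published
practice of using 6.634 as a fixed per-position threshold.  This is
defensible here because positions with zero counts in both tracks give
$G = 0$ exactly: the number of live tests is the handful of positions with
any read support, not the vector length.  When Bonferroni is requested,
$\alpha$ is divided by exactly that number of live positions.

## What the synthetic generator emulates

`simulateExperiment()` builds a complete study from one seed: a random
donor genome; a recipient strain derived from it by i.i.d. SNVs (the
protospacer+PAM window is protected so both strains stay editable); a
transformation vector whose nine features mirror a fungal Cas9 plasmid
layout (origin, bacterial marker, terminator, NLS, Cas9, promoters, the
20-bp spacer, a fungal resistance marker; 9,167 bp in total) and which by
construction shares **only** the 20-bp spacer with the host; an edited
recipient carrying a cut-site indel; optionally an integrated vector
fragment; and 150-bp paired-end reads at 30x for both the edited sample
and the unedited control.

The generator reproduces the statistical structure the analysis relies on
— depth, read length, error rate, shared-spacer uniqueness — but not
everything about real data: no indel sequencing errors, no PCR duplicates,
no GC-coverage bias, no repetitive host sequence beyond chance 20-mer
collisions, and a single-contig genome far smaller than a real fungal
assembly.  Passing tests therefore demonstrate that the *method* behaves
as designed under its stated assumptions; they do not certify performance
on any particular real library preparation.

## Numerical and design choices

* **Cut-site convention**: blunt cut between protospacer positions 17/18
  (3 bp 5' of the PAM), the standard SpCas9 geometry.
* **Fragment lengths**: normal(`insertMean`, `insertSd`) truncated below
  at the read length; base qualities are written as a constant Phred 40
  because the analysis never reads them.
* **Circular plasmids are treated as linear**: k-mers do not wrap the
  origin, matching the linear position axis on which results are
  reported.  A fragment spanning the junction would still be detected by
  its non-junction windows.
* **Per-read counting** (not per-occurrence): counts are interpretable as
  read support and bounded by depth.  Whether the original analyses
  counted per read or per occurrence is not documented; this choice is
  recorded here as this package's convention.
* **Alignment scoring**: match +2, mismatch −3, gap open −6 (first gapped
  base), gap extend −1; ties prefer a mismatch over a gap and a deletion
  over an insertion, so alignments are fully deterministic.  Indels are
  then left-aligned within repeats, mirroring variant-normalization
  practice.  A full-matrix dynamic-programming reference implementation
  in the test suite checks the production aligner on short sequences.
* **In-silico PCR requires exact primer matches**: the published readout
  is binary presence/absence on a gel; a thermodynamic mismatch model
  would add parameters without adding evidence.
* **Protospacers are exactly 20 bp**.  Printed target coordinates in the
  motivating experiments are occasionally 21-nt spans; coordinates are
  treated as possibly off-by-one and validated against the 20-bp
  invariant.
* **N handling**: any window containing a non-ACGT base is skipped on
  both the vector and the read side.
* **Degenerate inputs**: an empty read set is a valid all-zero track;
  tracks with zero total reads are rejected by the test stage; a vector
  shorter than k is an error.

## Problem sizes used in the validation suites

The package's own validation runs use a 50-kb genome for the single-peak
clean-run emulation and 20-kb genomes for the 20-seed detection-power and
specificity loops, both at 30x coverage — large enough that every
statistical regime of the method (tens of supporting reads per position,
~10,000-read totals) is exercised, small enough that the whole suite runs
in minutes on one CPU.  Detection power is driven by depth, not genome
size: a 20-bp insert contributes one exactly-matching window covered by
roughly `coverage * (readLength - k + 1) / readLength` ≈ 26 reads at 30x,
giving $G \approx 36$ against a zero-count control — comfortably above
6.634 — while a clean run leaves the sample track empty away from the
spacer.

## Known limitations

* Approximate matching is out of scope: a foreign fragment diverged from
  the vector reference (or heavily mutated on integration) is only
  detected through its remaining exact 20-mers.
* The verdict is relative to the supplied vector sequence; foreign DNA
  from any other source is invisible.
* Very short inserts (< 20 bp) are below the designed detection limit and
  are deliberately not reported.
* The amplicon caller assumes a haploid (monokaryon) template; mixed
  traces from heterokaryons are not deconvolved.
* Real-data peak counts depend on repeat content between host and vector
  (shared promoters, markers); the generator's uniqueness guarantee makes
  synthetic runs cleaner than some real ones, where shared endogenous
  peaks appear in both tracks and are classified as such.
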