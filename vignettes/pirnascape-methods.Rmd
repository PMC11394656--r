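---
title: "Methods: simulating and profiling testis piRNA repertoires"
author: "pirnascape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and profiling testis piRNA repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnascape)
```

## The problem

PIWI-interacting RNAs (piRNAs) are 24-33 nt germline small RNAs that
silence transposons and tune germ-cell mRNA programs. In seasonally
breeding mammals, testis piRNA repertoires differ sharply between the
breeding and non-breeding state. A standard analysis of such a
two-condition small-RNA experiment has five stages, each implemented here
as an exported function family:

1. **Class profiling** — annotate reads against ncRNA references
   (rRNA, tRNA, snRNA, snoRNA, miRNA), call the remainder as candidate
   piRNAs by the *1U/10A rule*, and summarize lengths and class shares.
2. **Biogenesis signatures** — positional base biases (U at position 1
   marks primary biogenesis, A at position 10 marks ping-pong
   secondaries) and the 10-nt 5'-overlap ping-pong statistic.
3. **Genomic context** — assign mapped piRNAs to repeat / gene / other
   origin categories.
4. **Differential expression** — TPM normalization and a
   fold-change + p-value screen.
5. **Target network** — antisense duplex scoring against mRNAs and a
   bipartite piRNA-mRNA regulatory network.

Because real deposited libraries and curated annotation databases are not
reproducible at desk scale, the package ships a fully parameterised
synthetic-data generator whose defaults encode the statistical structure
such experiments report. Every analysis stage is validated by *parameter
recovery*: simulate with known truth, analyse, and check the estimates.

## Candidate piRNA calling

A read is a candidate piRNA if its length falls in a window and its first
base is U **or** its tenth base is A. The default window is 27-32 nt
(`pirna_windows()$canonical`), matching the unimodal testis length profile
with a 30-nt peak that the generator emulates; a broader 24-33 nt preset
(`broad`) is shipped for repertoires described with the wider range, but it
is never silently substituted. U and T are treated as equivalent
throughout, so FASTA/FASTQ in either alphabet behave identically.

Class annotation precedes the rule: reads matching a reference class
(exact sequence or exact substring, priority rRNA → tRNA → snRNA →
snoRNA → miRNA) are never called piRNA. Exact-substring matching was
chosen over alignment for determinism and testability; the priority order
puts the abundant structural RNAs first so that a fragment of an rRNA that
happens to start with U is not miscalled. The rule is applied *after*
class exclusion.

## The synthetic-data generator

`generator_config()` holds every tunable. The defaults are the study
conditions; they were chosen once, from the emulated experiment's reported
ranges, and are not adjusted per analysis:

* **Class mixtures** — piRNA 0.678 in the breeding condition (BSB;
  midpoint of the reported 65.11-70.46% range) and 0.237 in the
  non-breeding condition (NBS; midpoint of 22.13-25.24%), the remainder
  dominated by miRNA.
* **piRNA lengths** — probabilities {27: .05, 28: .10, 29: .20, 30: .35,
  31: .20, 32: .10}; only the range and the 30-nt peak are reported, so a
  symmetric-ish unimodal profile around 30 was fixed.
* **Base biases** — `q1U = q10A = 0.85`: strong but imperfect, so
  signatures are detectable yet non-degenerate.
* **Origins** — repeat 0.15, gene 0.01, other 0.84, from the reported
  10-20% repeat and ~1% gene shares.
* **Counts** — negative binomial with mean 500 and dispersion 0.05,
  per-piRNA baselines log-normal (sdlog 0.5, mean-preserving); 3
  replicates per condition; 20% of piRNAs truly DE with |log2FC| = 2, of
  which 88.6% are up in BSB (86,433 of 97,580 in the emulated study).
* **Library size** — 200,000 reads. No library sizes are reported for the
  emulated experiment; this is a desk-scale choice that keeps multinomial
  noise on class shares near ±0.1 percentage points.

### How base biases are realised

Genome-derived reads must equal the genome substring at their alignment
coordinates (the package treats this as an invariant, so that alignment
coordinates, sequences and signatures can never disagree). Biases are
therefore imposed by *rejection sampling of loci*: for each read the
desired outcome at the 5' base (U with probability `q1U`) and at position
10 (A with probability `q10A`) is drawn first, and loci are re-drawn until
the genome exhibits that outcome. The genome itself is never edited.

Both biases apply to **every** piRNA read, not only one per pathway. This
is deliberate: real testis piRNA populations show the 1U preference across
the whole population, and the 10th position prefers A (and U) overall, not
only among ping-pong products. It is also what makes the candidate rule
consistent with the class mixture — with independent 0.85/0.85 biases only
`0.15 × 0.15 ≈ 2%` of true piRNAs fail both prongs of the rule, so the
called piRNA share lands near the intended class fraction. If the 1U bias
were restricted to primaries and the 10A bias to secondaries, ~11% of true
piRNAs would fail the rule and the simulated class composition could never
reach the values the generator is supposed to emulate.

### Ping-pong pairs and uni-strand clusters

A `pingpong_fraction` of piRNA reads are emitted as secondary partners:
the antisense read whose 5' end overlaps its primary's 5' end by exactly
10 nt. Secondaries are emitted in couples with their primary, so the
realised secondary share is capped at 0.5 (at `pingpong_fraction = 1` the
library is entirely pairs). Because both reads cover one duplex, the
partner's bases are tied by complementarity: the primary's 1U *is* the
secondary's 10A and vice versa — the generator does not need to (and must
not) place bases independently on the two strands.

Origin intervals behave as **uni-strand clusters**: all primary reads of
one interval share a strand, mirroring the predominantly single-stranded
transcription of piRNA clusters. Antisense reads therefore only arise
through ping-pong pairing. This matters for calibration: if strands were
assigned per read, the plus-strand position-10-A sites and minus-strand
position-1-U sites would be the *same genomic bases*, and their
co-location would manufacture a 10-nt overlap excess — a spurious
ping-pong signal — even with no pairs at all. With uni-strand clusters the
no-ping-pong null is clean (the overlap profile is empty and the statistic
is 0 by its zero-variance rule).

### What the generator does not emulate

No sequencing error, no adapter contamination, no quality-score realism,
no multi-mapping ambiguity (one alignment per read), no repeat-family
substructure, no expression-coupled locus usage. "Other" reads are random
sequences with lengths outside the piRNA window, so class-composition
recovery measures the classifier against reference-derived and
genome-derived reads, not against adversarial near-piRNA decoys. Passing
recovery tests on this generator shows the analysis code is correct and
calibrated under the stated statistical structure; it does not certify
performance on the messier failure modes of real libraries.

## The ping-pong statistic

For plus-strand 5' end $a$ and minus-strand 5' end $b$ on one chromosome,
the 5'-5' overlap is $o = b - a + 1$; pairs with $1 \le o \le 20$ are
tallied with weight equal to the product of the two copy numbers. The
enrichment statistic standardizes the 10-nt bin against the others:

$$z_{10} = \frac{c_{10} - \operatorname{mean}(c_{o \ne 10})}
                {\operatorname{sd}(c_{o \ne 10})},$$

with sample sd and $z_{10} = 0$ when the sd is 0. The package
operationalizes "signature detected" as $z_{10} > 1.96$; this is a
conventional z-threshold, not a calibrated test (bins are correlated
through shared reads), and the null behaviour is therefore verified by
simulation in the test suite rather than assumed. A binomial alternative
(10-bin count against the pooled others) was considered and rejected as
default because it is more sensitive to the arbitrary 1..20 range.
Coordinates are 0-based half-open; a minus-strand read's 5' end is
`end - 1`. Pair enumeration aggregates copy weights per distinct 5'
position and sweeps 20 offsets per chromosome; its contract is exact
equality with the naive all-pairs enumeration, which the tests enforce.

## Genomic category assignment

A read is assigned to the first category in the priority order (default
`repeat` before `gene`) covering at least half of its bases
(`min_overlap_fraction = 0.5`; the emulated study states no overlap rule).
Intervals of one category are merged before overlap is measured, so a
split annotation behaves like its union. Overlap is strand-agnostic —
piRNAs engage transposons from either strand. Everything else is "other",
defined as the annotation complement. Repeat outranks gene to reflect the
transposon-silencing reading of repeat-derived piRNAs; both the order and
the threshold are arguments.

## Differential expression

TPM here is reads-per-million without length normalization (the small-RNA
convention): `tpm = count / column_total * 1e6`, so columns sum to 1e6
exactly. The screen uses

* `log2fc = log2((mean BSB TPM + 1) / (mean NBS TPM + 1))`, positive =
  higher in BSB;
* a two-sided Welch t-test on `log2(TPM + 1)` per piRNA (vectorised;
  verified against `stats::t.test` row by row);
* status `up` / `down` by strict thresholds |log2FC| > 1 and p < 0.05, no
  multiple-testing correction by default (BH available via
  `adjust = "BH"`).

The emulated study names thresholds but no test; Welch on logs was chosen
as a transparent, dependency-light default that is adequate at 3 vs 3 and
slightly conservative on NB data (simulated type-I error ≈ 0.03-0.05 at
the default dispersion; asserted at 0.05 ± 0.02 in the tests). Degenerate
rows with zero variance in both groups get p = 1 when the means are equal,
else p floored at 1e-12. A pseudo-count of 1 TPM stabilizes logs at low
abundance. Note the compositional effect of strongly asymmetric DE: when
most effects are up in BSB, TPM renormalization shifts null piRNAs'
apparent fold change toward NBS; the recovery tests measure sensitivity
and direction shares under exactly this regime.

## Duplex scoring and the network

The target scorer is a deliberately simple antisense complementarity
score: the reversed piRNA slides along the mRNA; each position contributes
+1 for a Watson-Crick pair, +0.5 for a G:U wobble, -1 otherwise; the best
site is reported (ties to the smallest mRNA offset) with its count of
Watson-Crick matches at piRNA positions 2-11 (the seed, by analogy with
miRanda's seed emphasis; default filter ≥ 9 of 10). There is no
thermodynamic ΔG, gap or bulge model — production predictions from
dedicated tools can be supplied as an external edge table and fed straight
into `build_network()`.

Network edges are restricted to DE piRNAs × DE mRNAs, carry both
statuses, collapse duplicates, and export as TSV (loss-less round trip),
SIF (`piRNA regulates mRNA`) or GraphML with bipartite and status
attributes. The per-mRNA regulator degree counts distinct piRNA neighbors.

## Numerical and testing choices

* Ties: length-histogram modes and enrichment argmaxes break to the
  smallest length/position; duplex sites to the smallest offset.
* Determinism: every simulator takes an explicit seed and is byte-stable;
  classification is order-independent.
* Problem sizes in the shipped tests — 200k-read libraries for
  composition/length recovery, 100k for category recovery, 50k for
  position-10 enrichment, 20k × 100 seeds for the ping-pong null, 5,000
  piRNAs for DE recovery and 2,000 for the null — were fixed once as the
  package's validation scale: large enough that recovery bands reflect
  bias rather than noise, small enough to run in seconds.
* Oracle tests pin the optimized implementations (overlap sweep, interval
  assignment, sliding duplex score) to brute-force re-implementations on
  randomized instances.

## Known limitations

The classifier's exact-substring matching will not tolerate sequencing
errors or ncRNA variants absent from the references; the packaged
reference set is synthetic and minimal, intended for simulation and
testing, and should be replaced by curated databases for real data. The
ping-pong threshold 1.96 is conventional rather than calibrated. The DE
test does not share dispersion information across piRNAs, so at very low
counts a count-based framework will be more powerful. The duplex scorer
ranks complementarity only and must not be interpreted energetically.
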