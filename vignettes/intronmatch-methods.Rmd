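---
title: "Methods: optimal matched segments between introns and their mRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal matched segments between introns and their mRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A post-spliced intron can in principle hybridize with its own mature
mRNA wherever the two molecules carry complementary stretches. The
package screens for such stretches at the sequence level only: the
intron is complemented, the mRNA is locally aligned against it, and the
single highest-scoring local alignment — the optimal matched segment
(OMS) — is taken as the candidate interaction site for that (mRNA,
intron) pair. This is a deliberately minimal model. It assumes that
hybridization propensity is captured by base-pairing alone; base
stacking, loop entropies and secondary structure of either molecule are
ignored, and exactly one segment per pair is scored even when co-optimal
alternatives exist.

Two substitution schemes are built in. `SW` is the standard EDNAFULL
(NUC4.4) matrix (+5 match, −4 mismatch, published integer values for
IUPAC ambiguity codes) and serves as the match-counting control. `BFE`
weights a correct pair by its pairing energy: A:T scores +5 and G:C
scores +6, reflecting the roughly 2:3 ratio of the two pairing energies
(two versus three hydrogen bonds), with −4 for any wrong pairing.
Because alignment runs against the *complemented* intron, these appear
as identity scores. Any column containing an ambiguity symbol scores −4
under `BFE`, since pairing energies are defined only for canonical
bases; under `SW` the EDNAFULL ambiguity entries apply.

Both schemes use affine gap penalties of 50 (open) and 5 (per
additional column), i.e. a gap of length $g$ costs $50 + 5(g-1)$. With
a maximal pair score of 6, a gap is worth opening only when it bridges
at least nine further scoring columns, so matched segments are
effectively contiguous — consistent with reading them as hybridization
stretches.

## Profile statistics

For a tested mRNA of length $L$, base $j$ maps to the relative site
$k = 100j/L$ when that is an integer and $\lfloor 100j/L\rfloor + 1$
otherwise; integer arithmetic makes the mapping exact, and the last
base always lands on site 100. Each pair contributes an indicator
vector equal to 1 on the sites its OMS covers; the matched frequency
$F(k)$ is the mean over pairs (pairs whose best alignment is empty
contribute zeros but still count), and the relative matched frequency
is $RF(k) = F(k)/\langle F\rangle$.

$\langle F\rangle$ is the average covered fraction per pair. On the
normalized coordinate every tested sequence has length 100, so the
package computes $\langle F\rangle = \tfrac1N\sum_i (k_e^i - k_s^i +
1)/100$. This choice makes the mean of RF over the 100 bins exactly 1,
which is what "RF = 1 is the average" requires; computing the fraction
on the un-normalized mRNA instead biases mean RF upward by roughly one
bin width per segment (a segment of $l$ bases straddles up to
$\lceil 100l/L\rceil + 1$ bins), an effect of 10–30% at typical segment
lengths.

Functional-site profiles are un-normalized: coverage is tallied at
offsets −60..+60 around the first base of the start codon, the first
base of the stop codon, or an exon–exon junction (origin = last base of
the upstream exon). Transcripts must contain the full window, and for
the codon-anchored windows the 5′UTR ≥ 50 bp / 3′UTR ≥ 80 bp filter
avoids boundary effects. Junctions are grouped into first / middle /
last; a two-exon transcript's single junction counts as both first and
last, and "middle" requires at least four exons. Because these windows
are not length-normalized, their RF denominator is the average covered
fraction computed with true lengths $l_i/L_i$ over the pairs
contributing to the window, so RF = 1 keeps its average-coverage
meaning. Every (mRNA,
intron) pair contributes one unit per eligible anchor; a transcript
with five introns contributes five units per anchor.

Region contrasts (e.g. 3′ end vs CDS bins) use a two-sided Welch
t-test on per-bin RF values. These tests are descriptive; no
multiple-testing correction is applied, and the reports say so.

## Sequence statistics

Match rate is the percent of identical columns among all alignment
columns. G+C content excludes ambiguity symbols from numerator and
denominator. The second-order informational redundancy is the mutual
information between adjacent bases,
$D_2 = \sum_{ij} p_{ij}\log_2[p_{ij}/(p_i p_j)]$, with $0\log 0 = 0$,
single-base marginals taken from the analyzed sequence(s), and
dinucleotides counted within — never across — sequences. For $N$ bases
of an independent-base sequence, $N\,D_2$ fluctuates on the scale of
the 0.99 quantile of $\chi^2_9/(2\ln 2) \approx 15.65$, hence the 99%
fluctuation bound $15.65/N$; the test suite re-derives this constant by
Monte Carlo. The exact entropy form is the primary definition; the
quadratic ($\chi^2$-style) approximation is emitted alongside as a
labeled secondary value. Class tables (CDS, 5′UTR, 3′UTR, OMS) default
to pooled counts — one number per class — with the per-sequence mean
also reported; the OMS class uses the matched segments on the intron
side. Tiny negative rounding of $D_2$ is clipped at zero.

## Null model

The composition-constrained (CC) null independently permutes the
letters of every mRNA and every intron (exact base multiset preserved),
re-runs the whole alignment + profile pipeline, and averages over
replicates (default 10; the replicate count is a user choice, as no
canonical value exists). Each replicate draws from its own RNG stream
derived from (seed, replicate), so results are reproducible and
independent of execution order.

One structural caveat: even under shuffling, the RF profile is not
perfectly flat at the terminal bins. A segment of length $l$ can cover
position $p < l$ only if it starts at or before $p$, so coverage ramps
up over the first and last $\sim l$ bases of every mRNA. On the 100-bin
coordinate this depresses the outermost bins (and, since mean RF is
exactly 1, slightly elevates the interior). This is a property of any
correct local aligner, not positional preference; null-based inference
should compare like with like (real vs shuffled profiles, as the test
suite does) rather than test terminal bins against RF = 1.

## Synthetic data

The generator builds single-isoform protein-coding gene models on a
single contig with alternating strands: uniform exon counts (2–5),
CDS of 80–200 internal codons flanked by ATG/TAA, 5′UTRs of 50–150 bp
and 3′UTRs of 80–250 bp (so site windows are eligible by
construction), and introns drawn from an even mixture of short
(40–80 bp) and long (81–400 bp) classes around the 80 bp boundary,
respecting the 40 bp minimum. Background bases are i.i.d. with G+C
0.36, a round figure in the range typical of A/T-rich nematode
genomes. Optional plants copy the complement (or reverse complement —
whichever convention is in force, so the aligner can rediscover it) of
a chosen mRNA region into an intron, with a controllable identity
fraction and, optionally, a distinct G+C for the planted segment
written into both molecules.

What the generator does *not* emulate: splice-site motifs, codon
usage, repeat content, isoform structure, or realistic length
distributions — lengths are uniform within their ranges and mRNAs are
shorter than genomic averages to keep test runtimes in seconds. Tests
passing on these data therefore demonstrate correctness of the
machinery (coordinates, scoring, normalization, recovery of planted
signal) rather than any biological claim about real genomes.

## Numerical and design choices

* **Orientation.** Whether the intron should be plain-complemented
  (parallel reading) or reverse-complemented (antiparallel duplex) is
  genuinely open; the package defaults to the plain complement and
  carries `orientation` as a first-class, recorded option. Downstream
  statistics never mix orientations.
* **Determinism.** All scheme scores are integers, so alignment scores
  are bit-reproducible. Among equal-scoring cells the aligner picks the
  smallest tested end coordinate, then the smallest aligned end
  coordinate; the traceback prefers stopping at score zero, then a
  paired column, then a gap in the aligned sequence, then a gap in the
  tested sequence. Re-runs are byte-identical.
* **Degenerate inputs.** If no alignment column can score positively,
  the pair gets the empty sentinel (score 0, zero length, NA
  coordinates); it stays in the pair count N but contributes zero
  coverage. A dataset whose pairs are all empty has
  $\langle F\rangle = 0$ and RF is refused rather than returned as
  NaN. Zero-variance region contrasts return p = 1 with a warning.
* **Coordinates.** 1-based inclusive everywhere in emitted results, on
  both the mRNA and the original intron (the aligned-side interval is
  mapped back through the complementation, undoing any reversal).
* **Boundaries.** All printed thresholds are inclusive as worded:
  introns of exactly 40 bp pass the length filter, an 80 bp intron is
  short, UTRs of exactly 50/80 bp pass the site filter.
* **Parsing.** GFF3 is the only annotation dialect; models with CDS
  outside exons or CDS length not divisible by 3 are rejected
  individually with a reason, while a non-ATG start codon only warns
  (the anchor is always the annotated boundary). Genes containing
  ncRNAs or repeats are excluded via a user-supplied ID list, not
  detected.
* **Problem sizes.** The test suite and the acceptance script run on
  simulated sets of 25–200 genes (up to ~500 intron–mRNA pairs), 5,000
  Monte-Carlo replicates for the $D_2$ calibration and a $10^6$-base
  sequence for its large-N limit — sizes chosen so the whole suite
  completes in about a minute while keeping Monte-Carlo error well
  inside the asserted tolerances.

## Known limitations

Thermodynamics beyond pair counting (stacking, structure) is out of
scope, as are co-optimal alignment enumeration, dinucleotide-preserving
shuffles, alternative splicing and GTF input. The terminal-bin coverage
artifact described above applies to all profile statistics at the very
ends of the coordinate. Reported p-values are descriptive only.
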