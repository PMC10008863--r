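# intronmatch

Sequence-level screening for association between post-spliced introns and
their own mature mRNAs. After splicing, the excised intron is a free RNA
species; if it base-pairs with its mRNA, the two sequences must contain
complementary stretches. `intronmatch` finds, for every (mRNA, intron)
pair of a gene set, the single best such stretch — the **optimal matched
segment (OMS)** — and summarises where these segments fall on the mRNA
and what they look like. It is aimed at genome-scale analyses of
protein-coding gene sets (the approach was developed on *C. elegans*) and
at method studies comparing match-count scoring with binding-energy
weighted scoring.

## Method

Each intron is complemented (optionally reverse-complemented) and locally
aligned against its mRNA (three-state Gotoh recurrence, affine gaps, gap
open 50 / extend 5, so short matched segments are effectively gapless)
under one of two substitution schemes:

* **SW** — the classic EDNAFULL (NUC4.4) matrix: +5 match / −4 mismatch;
* **BFE** — binding-free-energy weighting: an A:T pair scores +5, the
  more stable G:C pair +6 (the ≈2:3 pairing-energy ratio), mismatches −4.

For a tested mRNA of length *L*, base *j* maps to a relative site
*k* = 100·*j*/*L* (rounded up to the next integer when fractional), so
every mRNA is normalized to 100 sites. Each pair contributes an indicator
vector *f(k)* = 1 on the sites its OMS covers; the **matched frequency**
*F(k)* is the mean over the *N* pairs, the average ⟨F⟩ = (1/N)·Σᵢ lᵢ/Lᵢ
(on the normalized coordinate, Lᵢ = 100), and the **relative matched
frequency** is RF(k) = F(k)/⟨F⟩. Sites with RF > 1 are preferred
interaction positions; maximal runs of them are **optimal matched regions
(OMR)**. Un-normalized ±60 bp profiles are computed around the start
codon, stop codon and exon–exon junctions, separately for long (>80 bp)
and short (≤80 bp) introns. Sequence structure of the matched segments is
summarised by match rate, length, G+C and the second-order informational
redundancy D₂ = Σᵢⱼ pᵢⱼ·log₂[pᵢⱼ/(pᵢpⱼ)] with its 99% fluctuation bound
15.65/N. A composition-constrained shuffle of every sequence (exact base
multiset preserved) provides the null profile.

## Worked example

Everything is testable without downloads: the built-in generator writes
genome + GFF3 + ground truth with planted complementary segments.

```r
library(intronmatch)

spec <- sim_spec(n_genes = 40, seed = 8, plant_rate = 1,
                 plant_region = "3UTR", plant_identity = 1,
                 plant_len_range = c(25L, 25L))
models <- sim_models(spec)              # simulate, then parse GFF3+FASTA
oms    <- oms_table(models, bfe_scheme())
head(oms[, c("mrna_id", "intron_id", "mrna_start", "mrna_end",
             "score", "match_rate", "intron_class")], 3)
#>   mrna_id     intron_id mrna_start mrna_end score match_rate intron_class
#> 1   t0001 t0001_intron1        652      676   135  100.00000        short
#> 2   t0001 t0001_intron2        604      646   143   79.06977         long
#> 3   t0001 t0001_intron3        564      589   137  100.00000         long

rf_profile(oms)
#> <rf_profile BFE/complement> N = 103 pairs, <F> = 0.0546,
#>   mean RF = 1.0000, max RF = 6.94 (bin 92)
detect_omr(rf_profile(oms))
#>   start_bin end_bin  peak_rf
#> 1        77     100 6.939502

site_profile(models, oms, "UAA", intron_class = "long")
#> <site_profile UAA/long> 47 units (47 pairs), <F> = 0.0491,
#>   peak RF = 6.50 at +54 bp
```

A perfect 25 bp segment scores 135 (`5·n_AT + 6·n_GC`); mismatched
plants show up as match rates below 100%. The planted 3′UTR signal
surfaces exactly where it was placed: the OMR spans bins 77–100 and the
stop-codon window peaks downstream of the UAA site. On real data the
same calls (`parse_gene_models()`, `filter_dataset()`, `oms_table()`,
`rf_profile()`, `site_profile()`, `class_statistics()`,
`null_rf_profile()`) run from a genome FASTA + GFF3; `run_pipeline()`
wires them end to end and writes TSV reports, and `exec/intronmatch`
exposes `simulate` and `all` subcommands for shell use.

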