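---
title: "Models and methods behind emsbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emsbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emsbias)
```

`emsbias` analyses the genome-wide bias of EMS (ethyl methanesulfonate)
mutagenesis from multi-bulk bulked-segregant resequencing. This vignette
explains the statistical models, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical and design decisions that were genuinely open.

## The screen model

Each mutant bulk pools 30 phenotype-selected F2 individuals from a
backcross, resequenced to ~39x. Unlinked EMS mutations are heterozygous in
every pooled individual, so the expected alt-read fraction (the SNP index,
SI) is 0.5; the causal site is homozygous in all selected individuals, so
its expected SI is 1. The generator implements exactly this two-level
frequency model: read depth is Poisson(`depth`), alt reads are
Binomial(depth, SI-expectation). It deliberately does not resample the 30
individuals per site: unlinked sites segregate independently and the
pooled frequency concentrates tightly around 0.5, so the binomial around
0.5 (exactly 1.0 at the causal site) captures the read-level statistics
the caller actually sees. Linkage and recombination structure around the
causal site are out of scope; only the causal-site SI contrast is
modelled.

## Calling EMS-induced SNPs

A candidate site is accepted iff

1. exactly one bulk has at least `min_alt_mq20 = 3` alt reads at mapping
   quality >= 20 (a tie between two passing bulks is rejected as shared,
   never assigned to the stronger bulk);
2. the mean alt-read count over all other bulks is <= 1 (absent records
   count as zero; the divisor is the number of other bulks, not the number
   of other records);
3. no other bulk shows an alt fraction above `error_tolerance = 0.20`.

Rules 2 and 3 are deliberately composed rather than alternated: rule 3
interprets sub-20% alt evidence in another bulk as tolerated sequencing
error (so it does not break uniqueness), while rule 2 bounds the absolute
amount of such evidence. This is the only composition that uses both
stated thresholds.

Residual heterozygous fragments — chromosome segments dense in
parent-derived SNPs retained from breeding — would otherwise pass the
uniqueness filter (they are unique to one bulk). Any window of
`fragment_mask_window = 100` kb containing `fragment_mask_min_snps = 20`
or more accepted candidates of one bulk is masked and its SNPs excluded
with reason `residual_fragment`. The window threshold is a package
default: the count cutoff is not dictated by the screen design, and 20
SNPs/100 kb is ~40x the genome-wide mean density, far beyond what the EMS
rate can produce while well below the density of a true residual fragment
(hundreds of natural heterozygous differences per 100 kb between *indica*
parents). Both values are configurable.

ED^6 is computed per accepted SNP between the test bulk's
allele-frequency 4-vector and the mean of the other bulks' vectors
(absent evidence contributing the reference-only vector); with only the
reference and one alt allele segregating this reduces to
`(sqrt(2) * |SI_test - mean(SI_other)|)^6`. The exact bulk set entering
the "other" mean is a documented choice: all bulks except the test bulk.

## Density scan and class boundaries

Windows of 100 kb are placed at every 50-kb step start before the
chromosome end and clipped at the end, so every interior position is
covered by exactly window/step = 2 bins; trailing partial windows are
emitted, never discarded, because chromosome ends must remain scannable.
The chi-square cuts solve `(n - mu)^2 / mu = qchisq(1 - alpha, 1)` in
closed form. The four density classes resolve the boundary ambiguity of
"0–5 / 5–10 / >= 10" as coldspot = {0}, low = [1, 5), mid = [5, 10),
hotspot = [10, Inf): the only resolution in which the four groups are
mutually exclusive and sum to the bin total. The hotspot call itself is
the integer rule `count >= 10`; the chi-square cut is reported alongside
as its justification. The mean `mu` includes clipped bins by default
(`include_clipped = FALSE` to exclude).

## Sequence context

Flanking GC excludes the SNP base itself ("on both sides"); the site
composition is reported separately as the G/C-site fraction of the
spectrum. The +/-1 "G/C adjacent" statistic counts a SNP when *at least
one* immediate neighbour is G or C (the stricter both-neighbours variant
is derivable from the dinucleotide tables). k-mer context tables are
extracted from the reference plus strand at five position sets (-1/0,
0/+1, -2/-1/0, -1/0/+1, 0/+1/+2); enrichment uses 2x2 chi-square tests
with 1 df and no continuity correction (a `correct` flag exposes Yates).
Raw p < 0.05 is the default decision rule; Benjamini–Hochberg adjusted
values are reported alongside. Random-site baselines draw uniform
positions without replacement within each replicate (default ~10,000
sites, 10 replicates), excluding N bases, and report mean ± SD across
replicates. Codon usage selects the longest transcript per gene and uses
the standard genetic code, strand-aware; stop codons are tracked in the
genome codon table via their amino-acid label.

## CpG islands

Islands are called by sliding a 100-bp window by 1 bp; windows with GC >=
50% and observed/expected CpG >= 0.6 are marked, overlapping marked
windows are merged, and merged spans of >= 200 bp are reported. This
honours the four stated parameters exactly but is simpler than the EMBOSS
`newcpgreport` internals, which average over 10 windows before calling;
the acceptance criterion here is per-window with merged spans, and the
whole-span GC and obs/exp are reported descriptively, not re-thresholded.
N bases count toward window length but not toward C/G counts, so they
fail both criteria. Island-to-bin assignment is by midpoint (so an island
is counted in every overlapping bin containing its midpoint); the same
midpoint rule is used for DH sites and genes.

## Chromatin overlay

DH sites within 36 bp (the source assay's read length) are merged
transitively. Per-SNP epigenetic values take the maximum over a
modification's experiments at the SNP base, falling back to the maximum
within +/-10 bp when uncovered, then `missing`; a flat maximum over all
experiments is used (a per-tissue-first maximum is a plausible alternative
the upstream description leaves open). Modifications covering fewer than
half of the SNPs are dropped — this reproduces generically the exclusion
of low-coverage histone-methylation tracks. For class averaging, a SNP
lying in two overlapping bins inherits the class of the bin with the
higher SNP count (ties: the earlier bin) — the overlap makes some
assignment rule necessary, and the denser bin is the one that defines the
hot/cold contrast being tested. FPKM means are unweighted over datasets;
genes absent from the matrix are excluded rather than zero-filled, since
absence indicates no measurement, not silence.

## Genic annotation

Precedence is gene body (exon > intron) > upstream (3 kb, strand-aware) >
downstream > intergenic; a SNP upstream of one gene and downstream of
another is upstream. Exonic CDS SNPs are split into non-synonymous /
synonymous by translation; exonic non-CDS positions are reported as a
separate `exon_noncoding` subcategory folded into exon totals. The
upstream fraction is reported both against all SNPs and against non-genic
SNPs, because the latter is the natural base for "of the intergenic SNPs,
x% were within 3 kb upstream".

## What the generator emulates — and what it does not

The generator reproduces, with a fixed seed and byte-identical reruns:

* context-biased mutation hazards — per-site hazard = `base_rate` x
  `gc_multiplier` (G/C sites) x trinucleotide multipliers (-2/-1/0 frame)
  x `heterochromatin_multiplier`;
* mutation-type draws dominated by G>A / C>T at G/C sites (85%
  transitions by default, configurable); A/T sites split evenly between
  transitions and transversions;
* shared homozygous natural variants present in every bulk, unique
  sequencing-error sites with alt fraction below `seq_error_rate`, and
  residual heterozygous fragments (one per bulk with probability 0.2,
  150 kb, ~0.8 SNPs/kb);
* a centromeric heterochromatin block (40% of each chromosome) with
  elevated GC, denser CpG islands, most TE genes, higher
  methylation/MNase signal, fewer DH sites and lower expression;
  euchromatic arms with the reverse pattern;
* a natural-variation panel with Hardy–Weinberg genotypes, skewed MAF and
  missingness distributions, and a 20% overlap with implanted sites.

Mutation placement uses independent per-site Bernoulli(hazard) draws —
with hazards around 1e-6 this is the same point process as
Poisson-count-then-weighted-placement to second order, and it vectorises
over megabase chromosomes.

CpG structure is modelled as discrete islands on a depleted background:
background CpGs decay to CpA/CpT with probability 0.7 (plant genomes are
methylation-depleted in CpG outside islands) and explicit island segments
(300–800 bp, GC 0.65, obs/exp ~1) are planted at 1/2.5 kb in
heterochromatin vs 1/6 kb in euchromatin. Base frequencies are
compensated so realized domain GC still hits its target (0.40
euchromatin, 0.55 heterochromatin). Without this, an i.i.d. GC-rich
domain makes nearly every window pass the island criteria and whole
domains merge into single "islands", voiding per-bin island counts.

The generator does **not** emulate: read-level errors and mapping (FASTQ,
alignment); linkage blocks around causal sites; indels and structural
variants; isoform diversity (one transcript per gene, exons = CDS);
realistic k-mer composition beyond the configured multipliers; or
inter-experiment correlation structure in the signal tracks. Passing
tests therefore demonstrate that the *pipeline* recovers the biases it is
pointed at, under idealised read statistics — not that any particular
real genome shows them.

## Study conditions and default parameters

| parameter | default | why |
|---|---|---|
| `n_bulks` | 52 | the emulated screen's bulk count |
| `pool_size` | 30 | F2 individuals pooled per bulk |
| `depth` | 39 | mean resequencing depth |
| `base_rate` | 1e-6 /bp/bulk | empirical genome-wide EMS rate scale (~17.4k SNPs / 52 bulks / 373 Mb) |
| `gc_multiplier` | 4 | strong G/C preference of EMS |
| `kmer_multipliers` | AAG = 3 | favourable AAG (-2/-1/0) context |
| `heterochromatin_multiplier` | 3 | heterochromatin enrichment |
| `seq_error_rate` | 0.02 | Illumina-scale error allele fractions |
| `n_expr_datasets` | 284 | expression-panel width emulated |
| `n_varieties` | 40 | panel width (>= 30 needed by the panel filter) |

The recovery analyses (tests and `scripts/acceptance.R`) run the
generator on one 5-Mb chromosome with 10 bulks — chosen so that the mean
window density (~4.7 SNPs per 100-kb bin) matches the genome-scale
screen's ~4.65 while every density class stays populated and the full
pipeline remains a minutes-scale computation on one CPU. At that size the
caller's precision and recall against the implanted truth both exceed
0.95, the G/C and AAG enrichments are recovered at p < 0.01, and the
methylation/DH class contrasts reproduce the expected directions.

## Numerical choices and degenerate inputs

* Interval columns are 1-based inclusive throughout (the GRanges/GFF
  convention); BED/BedGraph conversion happens in the I/O layer.
* `snp_index` refuses zero depth; `euclidean_distance6` validates that
  frequency vectors sum to 1 within 1e-6.
* `obs_exp_cpg` returns 0 when a window has no C or no G; zero-margin
  2x2 tables return statistic 0, p = 1, with a degenerate flag.
* Empty SNP sets give zero counts with NA fractions (flagged), empty bins
  give ED^6 = 0, classes with no covered SNPs give NA means.
* All sub-generators derive their seeds deterministically from the single
  configuration seed; identical configurations give byte-identical output
  trees (asserted by checksum in the tests).

## Known limitations

The caller's uniqueness filter is evaluated per position, not per allele,
so two different alt alleles at one position in different bulks are
treated as shared evidence (conservative). Strict monotonicity of the
accepted set in `min_alt_mq20` can fail on adversarial tables through the
tie rule (raising the threshold can demote a second passing bulk whose
evidence then falls inside the error tolerance); on bulk-sequencing-like
data, where other-bulk evidence is either error-scale or shared-variant
scale, the subset property holds. CpG island calls differ from EMBOSS
`newcpgreport` in boundary detail (no 10-window averaging). The
annotation assigns one gene per SNP deterministically (lexicographic tie
break), which matters only for overlapping gene models. Finally, true EMS
mutations that land inside (or within one mask window of) a residual
heterozygous fragment are excluded together with the fragment — they are
indistinguishable from fragment variants by design — and
`caller_performance()` deliberately counts them against recall rather
than excusing them, so reported recall is a conservative bound.
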