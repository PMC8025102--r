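# emsbias

Genome-wide analysis of EMS mutagenesis bias from multi-bulk
bulked-segregant resequencing.

Ethyl methanesulfonate (EMS) alkylates O6-guanine and is the workhorse
mutagen of plant forward genetics, classically assumed to mutate the genome
uniformly. Resequencing many phenotype-selected F2 bulks from a single
mutant library makes it possible to test that assumption: SNPs unique to
one bulk are EMS-induced, and their genomic distribution can be compared
with sequence context, CpG islands, transposable-element (TE) annotation,
gene expression, DNase I hypersensitive (DH) sites, and epigenetic signal
tracks. `emsbias` implements that full analysis for researchers studying
mutagenesis spectra or mapping mutations by bulked-segregant sequencing,
together with a synthetic-data generator that emulates the statistical
structure of such a screen so every step is testable against a known truth.

## The statistics at the core

For a candidate site in a test bulk with `alt` mutant reads out of `n`
total, the **SNP index** is `SI = alt / n`; pools of heterozygous F2
mutants give `SI ~ 0.5` at unlinked sites and `SI ~ 1` at the causal
mutation. Linkage to the phenotype is scored by the Euclidean distance
between the test bulk's allele-frequency 4-vector `f_t` and the mean
vector of the other bulks `f_o`, sharpened to

    ED^6 = ( sqrt( sum_b (f_t,b - f_o,b)^2 ) )^6 .

A site is accepted as EMS-induced only if it has at least 3 mutant reads
with mapping quality >= 20 in exactly one bulk, mean mutant reads <= 1
across all other bulks, and alt fraction <= 20% (the tolerated sequencing
error) in every other bulk; dense SNP runs (residual heterozygous
fragments from breeding) are masked. Density is scanned in 100-kb windows
stepped by 50 kb; with mean count mu per window, counts `n` with
`(n - mu)^2 / mu >= chisq_1(0.95) = 3.84` are significantly non-uniform,
giving cuts `mu ± sqrt(3.84 mu)` (for mu = 4.65: <= 0.42 and >= 8.8).
Windows with >= 10 SNPs are hotspots, windows with none are coldspots.
CpG islands are called with the Gardiner-Garden-style criteria (100-bp
windows, GC >= 50%, observed/expected CpG = `N_CpG * L / (N_C * N_G)`
>= 0.6, merged spans >= 200 bp). Context preferences are tested per
di-/trinucleotide with 2x2 chi-square tests against genome-wide or
random-site baselines.

## Worked example

```r
library(emsbias)

cfg  <- sim_config(seed = 1, n_chrom = 1, chrom_len = 1e6, n_bulks = 6)
sim  <- simulate_ems_study(cfg)
snps <- call_ems_snps(sim$bulk_variants, n_bulks = 6)
caller_performance(snps, sim$truth$ems)
#>   n_called n_truth n_matched precision recall
#> 1       25      25        25         1      1

sp <- mutation_spectrum(snps, sim$genome)
head(dplyr::arrange(tibble::as_tibble(sp), dplyr::desc(n)), 4)
#>   type  ref   alt       n fraction
#> 1 G>A   G     A        11     0.44
#> 2 C>T   C     T         9     0.36
#> 3 A>G   A     G         2     0.08
#> 4 G>C   G     C         2     0.08
attr(sp, "gc_site_fraction")
#> [1] 0.92

scan <- bin_scan(snps, chrom_lengths(sim$genome))
scan
#> EMS SNP density scan: 20 bins of 1e+05 bp (step 50000 bp)
#> mean 2.400 SNPs/bin; chi-square cuts (alpha=0.05): <=0.00 / >=5.44
#> coldspot      low      mid  hotspot
#>        4       13        3        0
```

All 25 implanted mutations are recovered with no false positives; the
spectrum is dominated by the two EMS transitions (G>A + C>T = 80% here)
and 92% of sites are at G/C, reflecting the generator's G/C hazard
multiplier. `glance(scan)` / `tidy(scan)` return the scan as tibbles,
`ggplot2::autoplot(scan)` plots density along the genome, and
`run_ems_pipeline(cfg, outdir = "report")` runs every stage (spectrum,
context enrichment, CpG, DH, TE, expression, signal and annotation
overlays) and writes the report tables.

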