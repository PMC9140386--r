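# mutmapr

Bulked-segregant SNP-index mapping of recessive EMS-induced mutations, for
geneticists who map a mutant phenotype from whole-genome sequencing of two
phenotype-selected F2 bulks (the MutMap / QTL-seq design) — plus the
supporting analyses that usually accompany such a study: codon-level
variant-effect triage, a 3:1 segregation test, and fold-change /
rank-sum screens for metabolite and expression differences.

Because real mutant-bulk resequencing data is large and rarely released,
the package ships a first-class simulator: it generates complete in-silico
mapping experiments (EMS-style background SNPs, Haldane meiosis, recessive
phenotyping, 20/20 bulks, Poisson-depth read counts) with known ground
truth, so every stage of the pipeline is testable end to end on a desktop.

## The statistic

At each biallelic SNP, a bulk's **SNP index** is the fraction of reads
carrying the mutant allele, alt/(ref+alt). The mapping signal is

```
Δ(SNP index) = SNP index(mutant bulk) − SNP index(wild bulk)
```

For a recessive mutation, the mutant bulk is fixed at the causal site
(index 1) and the phenotype-selected wild bulk has expected index 1/3, so
E[Δ] = 2/3 at the causal locus, decaying to 0 with genetic distance.
Sites are filtered (index < 0.3 in both bulks, alt support < 7 reads in
both bulks, or zero coverage in either), Δ is averaged in sliding windows
(2 Mb / 50 kb by default), and windows are compared against a simulated
null: 1000 replicates of phenotype-blind bulk resampling at the observed
depths, whose 2.5%/97.5% window-mean quantiles form a 95% confidence band.
Runs of windows above the upper bound become candidate intervals.

## Worked example

```r
library(mutmapr)
ds <- simulate_mapping_experiment(seed = 1)   # default desk-scale fixture
ds$phenotype_counts
#> mutant   wild
#>     41    159                               # ~3:1 recessive segregation
report <- map_dataset(ds$counts, seed = 2)
report$candidates
#>   chrom start   end peak_delta peak_pos n_windows
#> 1  chr2     1 3e+07  0.6930651 14250000       597
ds$truth$pos
#> [1] 14682808
```

One candidate interval is called, on the correct chromosome, with its peak
window centred ~0.4 Mb from the true causal position (the interval spans
the chromosome because a 100 cM chromosome is fully linked to a selected
locus at this resolution; the peak localizes the candidate). At the causal
site itself:

```r
subset(report$snps, pos == ds$truth$pos)[, c("index_mut", "index_wt", "delta")]
#>     index_mut  index_wt     delta
#> 443         1 0.3333333 0.6666667
```

the mutant bulk is fixed (index 1) and the wild bulk sits at the expected
1/3. The segregation test and the downstream screens:

```r
segregation_chisq(159, 41)
#> Segregation test: 159 wild : 41 mutant (expected 150.0 : 50.0)
#> chi2 = 2.16 (df = 1), critical = 3.84 -> consistent
```

`run_all(run_config(seed = 3), out_dir)` chains simulate → map → annotate
and reports whether the truth locus fell in the top interval and its
consequence class (the default fixture plants the causal G→A on the third
base of a TGG codon, so the expected call is a Trp→stop `stop_gain`).
`metabolite_screen()` and `expression_log2_ratio()` cover the fold-change
(≥2 / ≤0.5) + Wilcoxon screen and log2(FPKM ratio) ranking.

See `vignettes/snp-index-mapping.Rmd` for the model, defaults, and the
design decisions behind them.

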