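---
title: "Mapping recessive EMS mutations from phenotype-selected F2 bulks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive EMS mutations from phenotype-selected F2 bulks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmapr)
```

## The mapping model

`mutmapr` implements bulked-segregant mapping of a single recessive,
EMS-induced mutation from whole-genome sequencing of two phenotype-selected
F2 bulks — the MutMap design. A mutant line is crossed back to its
(non-mutagenized) parent, the F1 is selfed, and two bulks of F2 plants are
pooled by phenotype and sequenced: one bulk of plants showing the mutant
phenotype, one of phenotypically wild plants.

At every biallelic SNP distinguishing the mutant line from the reference
parent, the **SNP index** of a bulk is the fraction of reads carrying the
mutant allele, $\mathrm{alt}/(\mathrm{ref}+\mathrm{alt})$. For a recessive
mutation, every plant in the mutant bulk is homozygous for the causal
allele, so the mutant-bulk SNP index at the causal site is 1 (absent
sequencing error). The wild bulk is a phenotype-selected draw from the
non-mutant genotype classes, AA : Aa = 1 : 2, so its expected causal-site
index is 1/3 — *not* 0, although informal descriptions of the method often
say "close to 0". The package follows the genetics: the expected

$$\Delta(\text{SNP index}) = \text{index}_{\text{mutant bulk}} -
\text{index}_{\text{wild bulk}}$$

peaks at $1 - 1/3 = 2/3$ at the causal locus and decays towards 0 with
genetic distance, because recombination progressively decouples linked
markers from the selected genotype. Unlinked markers have expectation 1/2
in both bulks and delta 0.

## Filters

Before windowing, sites are removed when (a) one bulk has no coverage at
all, (b) the SNP index is below 0.3 in *both* bulks, or (c) fewer than 7
reads support the alt allele in *both* bulks. These are the standard
MutMap read-quality filters against alignment and sequencing artifacts;
requiring failure in both bulks keeps true causal-region sites, where the
wild bulk is legitimately low. "Support" is interpreted as alt-supporting
read count; total depth would be an alternative reading, and the cutoff is
configurable through `filter_config()`.

## Windows and the simulated null band

Per-SNP deltas are noisy at practical depths, so the decision statistic is
the arithmetic mean of delta in sliding windows (defaults: 2 Mb windows
every 50 kb, at least 3 SNPs per window; windows below the SNP minimum are
treated as missing and never called). The defaults give the desk-scale
fixture several hundred windows per chromosome, enough to see the peak
decay; real genomes with denser SNP sets tolerate larger minima.

Significance comes from a simulated null rather than an analytic one.
Under the null of no linkage to the phenotype, each bulk is just a random
draw of $n$ F2 plants, so at every site the bulk allele frequency is
$\mathrm{Binomial}(2n, 1/2)/2n$ (genotype sampling) and the read counts are
binomial at the *observed* depth on top of that. `simulate_null_thresholds()`
replays this process (default 1000 replicates), re-windows each replicate,
and takes the 2.5% and 97.5% quantiles of the replicate window means as a
two-sided 95% band. Re-drawing the bulk composition in every replicate puts
bulk-size sampling variance — the dominant noise source at realistic depths
— inside the null. Candidate intervals are maximal runs of consecutive
windows whose mean delta exceeds the *upper* bound (the signal at a
recessive causal locus is positive by construction); the interval's peak
window and its midpoint are reported.

Two properties of this band are worth stating precisely:

* It is **marginal**, per window. On data generated from the null process
  itself, ~5% of windows fall outside the band; the calibration test
  measures this on non-overlapping windows (window = step) over several
  independent null datasets, because overlapping windows share most of
  their SNPs and would make the measured fraction extremely noisy.
* On *linked* genomes the within-chromosome correlation of bulk
  composition makes neighbouring window means strongly dependent, so the
  number of windows outside the band is not binomial and the band is not a
  family-wise error control. This matches how such thresholds are used in
  practice: as a per-window screening line, with the candidate defined by
  the peak region.

## The simulator

The synthetic-data generator produces complete experiments with known
ground truth; its defaults are the package's study conditions and are not
tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes x 30 Mb, 100 cM each | minutes-scale runs that still show peak decay |
| causal locus | chr2:14,682,808, G>A | a classic EMS transition coordinate |
| background SNPs | 10 per Mb | EMS library scale after filtering |
| transition fraction | 0.9 | EMS is dominated by G:C-to-A:T changes |
| F2 population | 200 plants | ~50 mutant-phenotype plants for a 20-plant bulk |
| bulks | 20 mutant / 20 wild | the standard bulk size of the design |
| depth | Poisson, mean 30 per bulk | routine resequencing coverage |
| base error | 0.005 | typical post-filter short-read error |
| phenotyping error | 0 | error-free by default; a misclassification rate exists because bulking errors are a known BSA failure mode |

Meiosis uses the Haldane model: crossovers are Poisson with no
interference, so genotypes along a chromosome form a Markov chain in which
the allele switches between adjacent loci with probability
$r = (1 - e^{-2d/100})/2$ for map distance $d$ cM. The package simulates
that chain directly — it is distributionally identical to drawing Poisson
crossover counts and uniform crossover positions, and it vectorizes over
gametes. Physical and genetic maps are related linearly (uniform cM/Mb)
because no finer map is assumed.

What the generator deliberately does **not** emulate: read-level errors
correlated along reads, alignment artifacts, structural variants,
segregation distortion, EMS dosage or chimerism effects, multi-locus or
quantitative traits. Passing tests therefore demonstrate the statistical
machinery under clean Mendelian conditions, not robustness to every
artifact of real resequencing data — the filters exist for those, but
their real-data behaviour is not certified by simulation.

## Variant effect annotation

Candidate SNPs are classified at codon level against single-transcript
gene models: the affected codon is rebuilt on the coding strand, both
alleles are translated with the standard genetic code, and the change is
labelled `stop_gain`, `stop_loss`, `nonsynonymous`, `synonymous`,
`splice_site` (the 2 intronic bases flanking each exon — the ANNOVAR
convention), `intronic` or `intergenic`. Ranking for candidate triage puts
stop changes first, then nonsynonymous, then splice site, with positional
tie-breaks; the sort is stable. `translate_cds()` keeps the initiator
methionine and drops the terminal stop, so a complete CDS of $3k$ nt
encodes $k-1$ residues (2433 nt gives 810), and an internal stop raises an
error naming the codon — the stop-gain signature. Only the nuclear standard
code is supported, and isoforms are out of scope.

`causal_gene_fixture()` embeds a synthetic 2433-nt single-exon gene in the
simulated genome so that the default causal G-to-A change falls on the
third base of a TGG (Trp) codon, producing a TGA stop — letting the whole
simulate-map-annotate loop run with a known expected consequence.

## Supporting screens

* `segregation_chisq()` tests phenotype counts against 3:1 (one df,
  default critical value 3.84 = `chisq_critical(0.05, 1)`).
* `metabolite_screen()` computes mutant/wild fold change from group means
  and a two-sided Wilcoxon rank-sum p-value. The classification gates on
  fold change alone (>= 2 up, <= 0.5 down) by default, with the p-value
  reported; an optional `p_gate` combines both. Rationale: with 3-replicate
  designs the exact two-sided Wilcoxon p cannot go below 0.1, so a p gate
  would empty the screen; fold change is the operative rule. A zero
  wild-type mean with positive mutant signal is classified "up" with a
  missing fold change — the direction is unambiguous even though the ratio
  is not finite.
* The Wilcoxon p is exact (tie-free rank-sum distribution, or full label
  enumeration under ties) up to group size 10 and a tie-corrected normal
  approximation without continuity correction above — at meaningful
  metabolomics scales the exact branch always applies.
* `expression_log2_ratio()` reports `log2((mutant FPKM + c)/(wild FPKM + c))`
  with a shared pseudocount `c = 0.01` so silent genes stay finite; results
  sort ascending so the strongest down-regulation (e.g. a silenced laccase)
  tops the list. No multiple-testing correction is applied in either
  screen; they are candidate-generating filters, not inference.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_mapping_experiment(seed = 1)
report <- map_dataset(ds$counts, seed = 2)
report$candidates[1, ]          # top interval; contains ds$truth$pos
res <- run_all(run_config(seed = 3), tempdir())
res$report$causal_effect        # "stop_gain"
```

## Numerical and design notes

* All coordinates are 1-based inclusive; every random step takes an
  explicit integer seed, and a whole-pipeline run is a pure function of its
  `run_config()`.
* Quantiles use R's default type-7 interpolation; null thresholds with the
  same seed are bit-identical.
* Missing window means (too few SNPs, or zero-depth bulks upstream) are
  excluded from calling, never imputed.
* Test problem sizes are chosen for tight feedback: the recovery suite
  runs 20 seeds of the default fixture with 1000-replicate nulls in about
  a minute; calibration uses 10 independent null datasets of 300 sites.

## Limitations

Single recessive causal locus only — no dominance, no multi-QTL, no
G-statistic or Euclidean-distance BSA variants. The simulator emits bulk
data only (no parental tracks). Indels, MNVs and regulatory annotation are
out of scope, as are DE calling from counts and enrichment analyses.
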