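# xyseg

Sex-linked gene inference and Y-chromosome degeneration analysis from
RNA-seq family crosses.

## The problem

In dioecious plants with young or intermediate-age sex chromosomes, there is
usually no reference genome with assembled X and Y. Sex-linked genes can
nevertheless be identified from RNA-seq of a single controlled cross — two
parents plus sexed F1 offspring — because transmission patterns differ by
genomic location. At a bi-allelic SNP:

* **autosomal** — both parental alleles segregate Mendelian in sons and
  daughters alike;
* **X/Y** — the father carries one X and one Y allele; the Y allele passes
  exclusively from father to sons, while the X alleles reach all offspring;
* **X-hemizygous** — the Y copy is lost or silent; sons carry (and express)
  a single maternal X, observed as homozygous.

`xyseg` implements this segregation analysis as a mixture model over the
three types, fitted by EM with an explicit per-genotype error rate
`epsilon`: the likelihood of a SNP under a type sums, over all parental
haplotype configurations of that type, the product over family members of
`P(observed | true)`, with `P = 1 - epsilon` for a correct call and
`epsilon/(G-1)` for each wrong one. Contig-level posteriors combine all
SNPs of a contig; contigs are called sex-linked when their sex-linked
posterior exceeds the autosomal one *and* at least one sex-linked SNP is
explainable with zero invoked errors, and called X-hemizygous when no male
Y-allele expression is observed.

On top of the inferred gene set the package quantifies Y degeneration and
dosage compensation:

* **allelic expression** — X- and Y-allele read depths at diagnostic X/Y
  SNPs, normalized per individual as `depth / (library_size * n_snps) * 1e6`,
  with a male/female correction anchored on autosomal medians;
* **ratios** — the per-contig Y/X expression ratio (per male, then averaged)
  and `log2(Xmale / 2Xfemale)`, which sits at −1 without dosage compensation
  (one male X vs two female X) and at 0 under full compensation;
* **degeneration** — corrected gene-loss rate
  (`100 * n_hemizygous / n_XY_with_X_polymorphism`), premature stop-codon
  contingency (two-tailed Fisher), pairwise synonymous divergence dS by
  Nei–Gojobori (1986) counting with Jukes–Cantor correction, and
  molecular-clock dating `age = dS_max / rate` (per-year clocks) or
  `age = dS_max / (2 mu) * generation_time` (per-generation clocks);
* **dosage** — extreme-ratio exclusion (Xmale/2Xfemale above 8 or under
  0.125), compensation classification (`0 ± 0.2` compensated, `−1 ± 0.2`
  non-compensated), Y/X binning and bootstrap CIs of category medians;
* **sex bias** — CPM filtering, differential expression by edgeR,
  limma-voom and an internal exact permutation test, consensus calls
  (significant in ≥ 2 methods at FDR < 1e-4) and chromosome-class
  enrichment tests.

Because the original sequencing reads are not needed to exercise any of
this logic, the package ships a synthetic cross simulator
(`simulate_family()`) that generates genotypes, allele depths, counts and
X/Y haplotype pairs with known truth labels, so every stage is verifiable
at desk scale.

## Worked example

```r
library(xyseg)

cfg <- pipeline_config(seed = 1, sim = sim_config(n_contigs = 500, seed = 1))
res <- run_pipeline(cfg)
res
#> xyseg pipeline result
#>   contigs simulated: 500 (with SNPs: 487)
#>   epsilon-hat: 0.0202
#>   assigned: autosomal=374, XY=110, X_hemizygous=2, unassigned=1
#>   corrected gene loss: 8.70%
```

The summary holds the headline statistics. The genotyping-error rate is
recovered at 0.0202 against a simulated truth of 0.02, and the mixture
proportions at (0.756, 0.240, 0.004); the simulated Y expression decay
shows up as a mean Y/X ratio of 0.57 across X/Y contigs:

```r
unlist(res$summary$pi_hat)
#>    autosomal           XY X_hemizygous
#>    0.7558106    0.2400826  0.004106776
round(res$summary$yx_ratio_mean, 3)
#> [1] 0.567
round(res$summary$correction_coefficient, 3)
#> [1] 0.816
```

The correction coefficient below 1 reflects the simulated male "organ hub"
genes: a handful of extremely male-expressed genes inflate male library
sizes, making ordinary genes look under-expressed in males until the
autosomal-median correction is applied. Downstream, the maximum X–Y
synonymous divergence and the per-year clock date the recombination arrest,
and the sex-bias consensus shows the expected enrichment on sex-linked
contigs:

```r
res$summary$degeneration$ds_max_all
#> [1] 0.168055
res$summary$degeneration$ages_myr[[1]]$age_all   # 1.5e-8 / year clock
#> [1] 11.2
res$summary$sexbias$class_percentages
#>          class n_biased n_total percent
#> 1   sex_linked       31     112   27.68
#> 2           XY       30     110   27.27
#> 3 X_hemizygous        1       2   50.00
#> 4    autosomal       22     374    5.88
```

Sex-linked contigs are strongly enriched for sex-biased expression relative
to autosomal ones (Fisher p = 3.1e-09 here), mirroring the biology the
simulator encodes: degenerate, non-compensated sex-linked genes are
genuinely expressed differently in males and females.

Individual stages are plain functions and can be used on their own — e.g.
`em_fit()` / `assign_contigs()` on a dataset read with
`read_genotype_table()` (VCF 4.2 with GT+AD, or the flat TSV dialect),
`ng86_ds()` on haplotype pairs from `read_haplotypes_fasta()`, or
`consensus_vote()` on externally computed DE results imported with
`import_method_results()`.

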