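---
title: "Inferring sex-linked genes and Y degeneration from a family cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex-linked genes and Y degeneration from a family cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xyseg)
```

## The model

`xyseg` analyses an RNA-seq family cross — a mother, a father and sexed F1
offspring — to classify expressed contigs into three segregation types:
autosomal, X/Y (both gametologs expressed) and X-hemizygous (Y copy lost or
silent). The signal is transmission: at a bi-allelic SNP, an allele carried
by the father and passed to every son but to no daughter, and absent from
the mother, is a Y allele; a locus where sons only ever show a single
maternal allele while daughters combine a maternal and the paternal allele
behaves X-hemizygously; everything else segregates Mendelian.

Genotype calls from RNA-seq are noisy, so the package models observation
error explicitly. For a SNP with two alleles there are three observable
genotypes; the observed genotype equals the true one with probability
$1-\varepsilon$ and each of the other two with probability $\varepsilon/2$.
The likelihood of a SNP under segregation type $t$ is

$$P(\mathbf{g} \mid t, \varepsilon) \;=\; \frac{1}{|C_t|}
\sum_{c \in C_t} \prod_{i} \Big[(1-\varepsilon)\,p_i(c) +
\tfrac{\varepsilon}{2}\,(1-p_i(c))\Big],$$

where $C_t$ is the set of parental haplotype configurations of type $t$
(9 autosomal, 12 X/Y, 6 X-hemizygous for a bi-allelic SNP), and $p_i(c)$ is
the probability that individual $i$'s true genotype equals the observed one
under configuration $c$ — an indicator for the parents, a Mendelian mixture
for offspring. Missing genotypes contribute a factor of 1. Configurations
carry a uniform prior within their type: the allele-frequency weighting
used by the original model-based method is not recoverable from published
material, so the package defines this simpler, symmetric observation model
and uses the *same* error process in its simulator, which keeps parameter
recovery well-posed.

Contigs combine their SNPs multiplicatively (SNPs treated as independent
given the configuration — the same simplification the per-SNP analysis
makes), and a three-component mixture with proportions $\pi$ is fitted by
EM: the E-step computes per-contig type posteriors, the M-step sets $\pi$
to the mean posterior and maximizes the expected complete-data
log-likelihood over $\varepsilon$ by 1-D numerical search. Plain
(deterministic) EM is the default rather than the stochastic EM of the
original tool: it is reproducible and shares its stationary points in
expectation; `em_fit(stochastic = TRUE)` samples hard assignments in the
E-step for users who want the stochastic variant. The observed-data
log-likelihood trace is stored and is non-decreasing by construction
(both M-step components are exact maximizations); the test suite asserts
this on every fitted dataset.

### Assignment rules

SNPs whose posterior of being autosomal *or* sex-linked exceeds 0.8 count
as informative. A contig is called sex-linked when its sex-linked posterior
exceeds the autosomal one **and** at least one retained sex-linked SNP is
"error-free": its maximum-posterior sex-linked configuration explains every
observed genotype with zero invoked errors. Sex-linked contigs whose summed
male Y-allele depth over the retained sex-linked diagnostic SNPs is exactly
zero are X-hemizygous; the rest are X/Y. Contigs with no informative SNP
are unassigned; ties between sex-linked and autosomal probabilities go to
autosomal (the conservative choice). "No Y expression" is a strict zero —
no published threshold exists, and the simulator's negative-binomial depths
make an exact zero the natural operationalization.

An identifiability limit motivates the gene-loss correction below: an
X-hemizygous contig whose mother is homozygous (and whose paternal X
carries the same allele) is monomorphic in the family and indistinguishable
from autosomal homozygosity. The simulator therefore only emits SNPs for
X-hemizygous contigs with maternal X polymorphism; the test suite asserts
that hemizygous contigs without it are never assigned X-hemizygous.

## Allelic expression and the autosomal correction

X- and Y-allele expression is measured from reads spanning diagnostic X/Y
SNPs only (SNPs where the Y allele is distinct from the X alleles in play,
so male reads separate cleanly), summed per contig and individual and
normalized as $d/(L \cdot n_{\text{SNP}}) \times 10^6$, with $L$ the
individual's library size. The $10^6$ scale is cosmetic — every downstream
statistic is a ratio.

A small set of genes can be extremely highly expressed in developing male
flowers; after library-size normalization this deflates every other male
value. The correction divides male values by the ratio of median male to
median female autosomal expression, which makes the autosomal medians equal
by construction and is idempotent. Two per-contig statistics follow:

* the **Y/X ratio**, computed per male (skipping males with zero X
  expression) and then averaged — not the ratio of sums — with
  X-hemizygous contigs fixed at 0;
* $\log_2(\text{Xmale}/2\text{Xfemale})$, the dosage statistic: one male X
  against two female X copies gives $-1$ without compensation and $0$ with
  full compensation.

## Degeneration statistics

**Gene loss.** X-hemizygous contigs are only detectable where the X is
polymorphic, whereas X/Y contigs are detected from fixed X–Y differences;
the raw hemizygous count therefore underestimates loss. The corrected rate
is $100 \cdot n_{\text{hemi}} / n_{\text{X/Y with X polymorphism}}$ — both
detection probabilities scale with the same X-polymorphism rate, which
cancels. The alternative denominator including the hemizygous contigs
themselves ($168/592 = 28.4\%$ on the published counts) answers a subtly
different question (loss among detected sex-linked genes); the package
follows the published estimator ($168/424 = 39.62\%$).

**Premature stops.** TAA/TAG/TGA before the final codon (standard code
only). Frequencies in X versus Y alleles are compared with a two-tailed
Fisher exact test; the implementation delegates to `stats::fisher.test`,
and the suite checks it against an exhaustive margin-fixed enumeration.

**Synonymous divergence.** X–Y divergence is estimated by Nei–Gojobori
(1986) counting with the Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ instead of a codon-model ML fit:
for divergences in the range seen between plant gametologs
($d_S \lesssim 0.2$) the two differ negligibly, and the counting method is
exactly testable by hand. Conventions: changes producing a stop codon count
as non-synonymous in site counting; codons containing N, or a stop in
either sequence, are skipped; multi-hit codons average over minimal
pathways excluding those through stops (falling back to all pathways when
every one is blocked, which is rare). The estimator is symmetric and
returns exactly 0 on identical sequences; it raises an error when
$p_S \ge 3/4$, where the correction is undefined.

**Dating.** With a per-year clock, $\text{age} = d_{S,\max}/\text{rate}$;
with a per-generation mutation rate $\mu$,
$\text{age} = d_{S,\max}/(2\mu) \times$ generation time (divergence
accumulates on both lineages). Three Brassicaceae-derived clocks ship as
defaults ($1.5\times10^{-8}$/site/year, $7.1\times10^{-9}$/site/generation,
$4\times10^{-9}$/site/year). Only the first clock's published ages are
arithmetically reproducible from the printed $d_{S,\max}$ values (0.17 →
11.3 Myr, 0.13 → 8.7 Myr); the published entries for the other two clocks
are inconsistent with their stated rates (e.g. $0.17/4\times10^{-9} =
42.5$ Myr, not 34.7), so the package reports the formula's value and the
tests assert proportionality in generation time rather than those printed
numbers.

## Dosage compensation

Contigs with Xmale/2Xfemale above 8 or under 0.125 are excluded ("above"
and "under" read strictly, so the boundary values are retained — the
published wording does not address equality). Retained contigs are
classified on closed bands: $|x| \le 0.2$ compensated, $|x+1| \le 0.2$
non-compensated, else unclassified; the band half-width is a parameter
(0.5 is a common robustness choice). Y/X categories use half-open
intervals $(a,b]$ with 0 as its own category, in a coarse 4-category and a
fine 6-bin scheme; fine-scheme ratios above 1.25 are excluded (whether such
contigs should instead be truncated into the top bin is unstated in the
source material; exclusion is logged). Category medians are normalized by
the category's female XX median and bootstrapped (percentile CIs, 2000
resamples by default, seed-controlled; the original analysis does not state
its CI method). Two reference lines accompany the male X median: full
compensation ($\text{Xmale} = \text{XXfemale} - \text{Ymale}$) and none
($\text{Xmale} = 0.5\,\text{XXfemale}$).

## Sex-biased expression

Genes with mean CPM below 0.5 are removed. Differential expression between
the sexes is computed by edgeR (tagwise-dispersion GLM LRT) and limma-voom
— the standard tools for this design — plus an internal exact permutation
test on the difference of mean $\log_2(\text{CPM}+0.5)$, provided so the
pipeline is self-contained and exactly verifiable. With 5 vs 5 samples the
permutation test's smallest achievable p is $1/252$, far above the
consensus FDR cutoff of $10^{-4}$; it is a labelled stand-in and the
consensus in practice rests on the two model-based methods agreeing. A gene
is sex-biased when significant in at least two methods at within-method
BH-FDR $< 10^{-4}$ (per-method adjustment, as the cited tools do); its
direction is the sign of the agreeing fold changes, and direction conflicts
drop the gene with a logged reason. Class enrichment (sex-linked vs
autosomal, X-hemizygous vs autosomal) uses two-tailed Fisher tests,
BH-adjusted across the comparisons performed.

## The simulator: what it emulates, and what it does not

`simulate_family()` generates the full study design: 5 sons + 5 daughters
plus parents; segregation types in proportions (0.73, 0.24, 0.03);
per-genotype error $\varepsilon = 0.02$; 2–10 SNPs per contig; an
X-polymorphism rate of 0.35 (matching the observed 424/1196 X/Y contigs
with X polymorphism); per-contig Y/X decay from Beta(2, 1.2) (mean 0.625,
matching the reported average Y/X expression ratio of ~0.63); a 40%
compensated fraction (close to the observed 23/54 bimodal split of
X-hemizygous contigs); log-normal per-contig expression and library sizes
around $10^7$ reads; and negative-binomial depths (size 8 — moderate
RNA-seq overdispersion; the source material is silent on count noise, so
the dispersion and library spread are exposed in the configuration).
Dosage compensation raises the male X copy weight to $2 - y$ (X/Y contigs
with Y factor $y$) or 2 (X-hemizygous), so the male total matches the
female total exactly on the full-compensation line.

Sex-biased genes come in two kinds: ordinary biased genes (fold change 4,
5% male / 1.5% female) and a 1% set of autosomal "organ hub" genes with a
30-fold male excess. The hub genes genuinely inflate male library sizes,
reproducing mechanistically the normalization artifact (males apparently
globally under-expressed) that the autosomal correction removes — library
sizes are always the realized column sums of the simulated counts, never
faked. The count matrix itself is the per-contig sum of SNP-spanning
allele depths (plus an equivalent draw for contigs without SNPs), so
conservation (library size = summed reads) holds exactly and differential
expression runs on the same noise process as the allelic tables.

Deliberate simplifications, which bound what green tests prove about real
data: SNPs are bi-allelic with per-SNP independent maternal transmission
(no within-contig haplotype structure); there is no mapping bias, no
paralogy, no isoform structure, and no assembly error; genotype calls and
read depths are conditionally independent given the truth, whereas real
genotypes are *called from* the depths; and X-hemizygous contigs without
maternal X polymorphism emit no SNPs at all, a structural encoding of the
detection limit rather than an emergent property of a read-level model.
Recovery rates measured here (≥ 95% assignment accuracy,
$\varepsilon$ within ±0.01) are therefore upper bounds on what identical
settings would achieve on real reads.

## Numerical choices and problem sizes

EM initializes at $\pi = (0.8, 0.15, 0.05)$, $\varepsilon = 0.05$,
converges on $|\Delta \log L| < 10^{-6}$ with at most 200 iterations, and
bounds $\varepsilon \in [10^{-8}, 0.4]$ in the M-step search. Per-SNP
likelihoods are computed by tabulating, once per dataset, how many
individuals fall at each distinct match probability per configuration, so
each $\varepsilon$ evaluation is a small matrix product; a 2000-contig,
~12,000-SNP dataset fits in a few seconds. The test suite uses 2000
contigs for the recovery benchmark, ~400-contig strata for the
dosage-compensation checks and 5000 genes for the null false-positive
check — sizes chosen so each property is measured with comfortable
statistical margin while the whole suite stays quick to run.

## Known limitations

The model is single-family, diploid and bi-allelic; paralog filtering,
multi-family designs and polyploidy are out of scope. The exact update
order, allele-level error model and configuration priors of the original
stochastic-EM tool are not published in a reimplementable form, so this
package defines a compatible but simplified model — results on real data
will differ in detail. The NG86 estimator assumes positionally aligned,
indel-free gametolog ORFs. Externally computed dS values (e.g. from a
codon-model ML fit) and externally computed DE tables can be supplied
through `import_method_results()` and the haplotype FASTA interface when
those trade-offs matter.
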