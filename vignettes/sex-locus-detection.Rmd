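---
title: "Detecting and dating a sex locus from a family cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating a sex locus from a family cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylink)
```

# The problem

In a male-heterogametic (XY) species, SNPs inside the non-recombining sex
locus segregate with sex: the father carries one X and one Y haplotype,
sons inherit the Y, and daughters do not. Given whole-genome genotypes of
a family cross — two parents and sexed offspring — such sites can be
recognised from their transmission pattern alone. `xylink` implements two
complementary detectors (a probabilistic mixture model and a strict
empirical filter), validates candidates in an independent panel of sexed
individuals, delimits the locus, and dates the X/Y split from synonymous
divergence of coding pseudosequences.

# Segregation model

Each biallelic SNP is assigned one of three latent segregation types:

* **autosomal** — both parents diploid, each transmits one random allele;
* **xy** (fully sex-linked) — the Y allele is private to the Y haplotype.
  The father is X/Y heterozygous, the mother is homozygous for the X
  allele; daughters receive the paternal X, sons the paternal Y. Only the
  two allele orientations of this pattern exist as parental
  configurations. This is deliberately narrower than "father heterozygous
  with any mother": at a site whose polymorphism is the X-vs-Y difference,
  every X copy in the cross carries the X allele. Allowing the mother to
  carry the Y-type allele would duplicate autosomal transmission patterns
  and let chance sex-correlated Mendelian segregation (with only five
  offspring per sex, an appreciable fraction of autosomal sites) leak into
  the sex-linked class.
* **x_hemizygous** — present on the X, absent from the Y. The mother may
  have any genotype and the father is hemizygous for his X allele; sons
  carry a single maternal allele.

Genotyping error is per-allele: each of the two allele reads of a diploid
call flips independently with probability ε. A true heterozygote is
observed as a homozygote with probability ε(1−ε) per direction, a true
homozygote as a heterozygote with probability 2ε(1−ε). A hemizygote is
observed as two reads drawn from its single allele, each flipped with ε —
numerically identical to the corresponding homozygote row, so hemizygotes
are coded as homozygotes throughout. Missing genotypes contribute a
likelihood factor of 1.

The site likelihood marginalises the type's parental configurations
(uniform prior within type) and, per offspring, the true genotype given
Mendelian transmission. Sites are a mixture over types with genome-wide
weights π. `fit_em()` fits (ε, π) by EM:

* E-step: per-site type responsibilities, and the posterior expectation of
  the number of allele flips per observation. All (true, observed) pairs
  imply a deterministic flip count except het→het, whose expectation is
  2ε²/((1−ε)²+ε²).
* M-step: π is the mean responsibility; ε is expected flips divided by
  allele reads (two per non-missing call). This is an exact EM, so the
  observed-data log-likelihood is non-decreasing; the fitter asserts this
  at every iteration.

Convergence is a relative log-likelihood change below 1e-8 (at most 500
iterations); initialisation is ε₀ = 0.02 and uniform π — deterministic, no
random restarts. ε is floored at 1e-12 so the log-domain E-step stays
finite if a site is inconsistent with every type at ε = 0. Sites with
posterior P(xy) strictly above 0.6 are called sex-linked; the X/Y allele
orientation comes from the maximising parental configuration, and a site
whose two orientations tie is dropped from allele-specific downstream
analyses.

A single ε is shared by all individuals and sites. Per-individual error
rates would add eleven parameters for little benefit at these sample
sizes and are not identifiable at sites where an individual is rarely
informative.

# Variant filters

`filter_variants()` applies, in order: (1) heterozygote calls whose
alternate-read fraction falls outside [0.25, 0.75] are set to missing;
(2) calls with total depth above twice the per-sample coverage mode are
set to missing; (3) sites with minor allele frequency ≤ 0.05 are removed
(alleles counted over called genotypes — missing calls excluded);
(4) sites with more than 20% missing calls are removed. Masking before
the missing-rate rule matters: a site whose heterozygotes are mostly
artefactual is removed by rule 4 even though no rule targets it directly.
The coverage mode is the argmax of the per-sample histogram of non-zero
total depths after a centred moving-average smoothing (window 5);
smoothed ties break by raw count, then toward the smaller depth, so the
statistic is deterministic without any distribution fitting. A
heterozygote call with zero total depth cannot be assessed by rule 1 and
is left unchanged.

# Empirical detection, validation, boundaries

The empirical filter retains sites where every called female of the cross
(mother and daughters) is homozygous for the same allele, every called
male (father and sons) is heterozygous, and at most `max_missing_calls`
(default 2) genotype calls are missing; the Y allele is the allele absent
from females. The default reads "allowing two missing alleles" as two
missing diploid genotype calls; the literal one-genotype reading is
available as `max_missing_calls = 1`. An optional region restriction is
applied first — linkage makes sites near the locus segregate with sex in
a single cross, so the empirical scan is meant for the region the
probabilistic caller indicates.

Validation marks a candidate when, among called panel genotypes, every
male is heterozygous and every female is homozygous for the same allele.
Missing panel calls are ignored, but at least one called individual of
each sex is required; requiring zero missingness would discard sites that
are unambiguous in every called individual.

`locus_boundaries()` returns the min–max position interval per chromosome
(1-based inclusive; span in bp and nearest-integer kb). XX/XY/YY tracks
(`classify_sex_genotypes()`) and `recombinant_blocks()` summarise panel
haplotypes: maximal runs of equal class, with missing sites absorbed when
both non-missing flanks agree, and a sample is recombinant when it shows
two blocks of different classes.

# Divergence and dating

`build_pseudosequences()` substitutes the X or Y allele at each in-CDS SNP
of a gene (alleles are given on the forward strand and complemented for
minus-strand genes), concatenates the CDS segments in coding orientation
and trims any trailing partial codon (with a warning). Sequences are
coordinate-built, never realigned.

`ng86_divergence()` implements Nei–Gojobori (1986) counting: per-codon
synonymous site fractions by enumerating the nine single-base mutations
(mutations creating a stop codon count as nonsynonymous); between-codon
differences averaged over mutational pathways, excluding pathways that
pass through a stop codon (if every pathway is blocked, all are used, so
the codon still contributes); Jukes–Cantor correction
d = −(3/4)·ln(1 − 4p/3) with delta-method variance
9p(1−p)/((3−4p)²·n). Proportions at or above 3/4 are flagged saturated
and the distance is undefined. Codons containing ambiguity codes, or that
are stop codons in either sequence, are skipped and counted. Only the
standard genetic code table is built in, but the counting is generic in
the code table.

The published analysis used PAML's yn00; this package uses NG86 with
equal codon weighting instead — at divergences of a few percent the two
agree to well within the standard errors, and NG86 admits an exact
brute-force oracle, which the test suite exercises on hundreds of random
codon pairs.

Dating: divergence accrues on both lineages, so
`T = dS / (2µ) · g` years, with µ = 7 × 10⁻⁹ substitutions per site per
generation (a plant nuclear clock) and generation time g in years;
`clock_generation_time()` is the exact inverse. Outlier genes are
excluded from dS summaries only by an explicit list — no automatic rule.

# Expression summaries

RPKM is `count · 10⁹ / (library_total · length_bp)`. Allele-specific
expression sums per-site X- and Y-oriented allele depths by gene
(summation is the default; per-gene averaging is available) and
normalises by the library's total variant-file reads and transcript
length, with the same 10⁹ scaling — the absolute scale cancels in X vs Y
comparisons. Restriction to a site list (e.g. variants shared by Y and
Yh when analysing hermaphrodites) is a set intersection on (chrom, pos).
Tau is Σ(1 − x̂ᵢ)/(N−1) on transformed profiles; the default transform is
log2(x+1), which is zero-safe and standard for RPKM-scale specificity
indices (the transform and base are configurable).

# The simulator

`simulate_cross()` emulates the target study design: two parents plus
five offspring per sex; 4500 autosomal SNPs (on a separate chromosome, so
boundary checks are unambiguous), a contiguous sex-linked region of 400
XY SNPs spaced 278 bp from position 4,810,929 on "chr2" (a ~111 kb
locus), and 100 X-hemizygous SNPs interleaved inside it; per-allele error
2%; 5% missing calls. Parental genotypes at autosomal and X-hemizygous
sites are drawn from a per-site allele frequency (uniform on
[0.1, 0.9] by default); XY sites take the canonical configuration with
the orientation drawn from the same frequency. Read depths are negative
binomial (mean 20, size 10) per call — a realistic per-sample
resequencing depth that exercises the coverage filters — with binomial
allele splitting for heterozygotes. All randomness flows from one
mandatory seed; the simulated VCF records it and is byte-identical across
reruns.

What it does **not** emulate: linkage disequilibrium beyond complete
linkage inside the sex-linked region, read-level artefacts (mapping bias,
allele-specific dropout), depth-genotype error correlation, indels or
multiallelic sites, and population structure in the validation panel.
Passing recovery tests therefore demonstrates correctness of the
inference given the model's assumptions, not robustness to every
real-data pathology.

Test problem sizes: the parameter-recovery and detection checks run on
5,000–5,500-site crosses (seconds per EM fit); likelihood values are
verified against an exhaustive allele-level enumeration oracle on
families of up to four offspring, where the enumeration is exact and
cheap; NG86 counts are verified against a pathway-enumeration oracle on
random 10–50-codon pairs.

# Known limitations

* Female-heterogametic (ZW) systems are out of scope, as is the
  contig-level inference from RNA-seq of the original segregation-based
  detectors.
* The mixture weights are genome-wide; clustering of sex-linked sites
  along the chromosome is not modelled, so borderline posteriors near the
  locus edge do not borrow strength from neighbours.
* With five offspring per sex, an autosomal site can mimic the sex-linked
  pattern by chance (roughly one in a thousand informative sites even
  error-free); panel validation exists precisely to remove such sites.
* NG86 underestimates divergence when transition/transversion bias is
  strong; at the few-percent dS range targeted here the effect is
  negligible relative to the standard errors.
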