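---
title: "haploscan: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haploscan: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`haploscan` is a pipeline for population-genomic analysis of haploid
resequencing panels — collections of a few dozen clonal, haploid strains
(wild yeasts are the motivating case) genotyped against a single reference.
This vignette is the package's own account of the statistics it computes,
the conventions it fixes where the field leaves choices open, and what its
synthetic-data generator does and does not emulate.

## Coordinates and containers

All internal coordinates are 0-based half-open. VCF and GFF3 are 1-based;
the conversion happens in `read_variants()` and `read_annotation()` and
nowhere else, which removes the usual source of off-by-one drift. Genotypes
are integer allele indices (0 = reference) in an `n × S` matrix; multiallelic
sites are retained with indices `0..k` and every statistic uses the general
k-allele form rather than dropping such sites. The central container, the
`analysis_matrix`, couples the polymorphic-site matrix with a *callable
track*: per-chromosome intervals of sites called in **every** sample. The
track supplies the monomorphic-site denominators that per-site diversity
needs; it can come from an all-sites VCF or from a BED callable track next
to a SNP-only VCF.

## Call filtering and masking

A call is masked when the site quality is below 30, its depth below 10 or
above a per-sample cap, or when the genotype was heterozygous — impossible
in a haploid, so treated as an error. The depth cap phrase "below 3 times
the standard deviation of the average depth" admits two readings; the
default `mean_plus_3sd` uses mean + 3·SD per sample (the standard outlier
rule), and `literal_3sd` (3·SD as an absolute cap) is kept as an option.

Sequence masks cover maximal homopolymer runs longer than 9 bases and
maximal di-/trinucleotide tandem repeats of more than 5 complete units, each
with 10 bp flanks; ±10 bp around indel anchors; and annotated transposable
elements, centromeres and telomeres. Repeat detection scans for maximal
period-p regions; a region satisfying several definitions is simply masked
under each reason — masks have union semantics, so double-masking is
harmless and `mask_union()` is idempotent.

Read-level filtering (`filter_reads`) implements the documented cascade:
end-trimming to the first/last run of ≥10 bases at phred ≥ 30, removal of
3′ regions from position 150 (then 200) onward when ≥10% of their bases are
below phred 20, whole-read removal at the same fraction, adapter trimming
(exact match, cut to read end), a 45 bp length floor, and removal of
single-base reads, reads with ≥3 consecutive Ns, reverse-complement pairs,
and widowed mates. Where the source leaves open whether the 150 bp and
200 bp checks are alternatives, both are applied in sequence (150 first);
after a truncation at 149 the 200 bp check is vacuous, which makes the
choice conservative and deterministic.

## Site classes and Nei–Gojobori counting

Classes are painted per position with precedence CDS > UTR > intron >
ncRNA > intergenic. tRNA/rRNA/snoRNA genes, pseudogenes, repeats and masked
feature footprints are excluded outright; annotated elements with less than
50 bp of called sequence or at least one third missing are excluded as a
whole. Intron sites are restricted to positions 8 (1-based from the 5′
splice site) through the base before the CTAAC branchpoint motif; the
leftmost exact match at or after position 8 wins, a single-mismatch match is
accepted only when no exact match exists, and motif-less introns are
dropped. Stop codons and incompletely-called codons inside a CDS are
excluded rather than inheriting a lower-precedence label.

Synonymous/nonsynonymous site counts follow the classical counting method:
at each codon position the synonymous fraction is the share of the three
single-base changes preserving the amino acid, with changes to stop codons
counted as nonsynonymous — so each codon contributes exactly 3 sites.
Between two codons differing at d positions, difference counts are averaged
over all d! single-step pathways, excluding pathways through stop codons and
re-weighting the rest; in the (biologically irrelevant but reproducibility
relevant) case where every pathway is blocked, the d differences are split
equally. Per-gene π~S~ is the pathway-averaged synonymous difference count
per pair, averaged over pairs, divided by the mean synonymous site count
over samples; genes are flagged eligible for ratio reporting when more than
200 synonymous sites could be analyzed. A per-site class label for SNP
tables calls a CDS SNP synonymous/nonsynonymous when all observed
non-reference bases are synonymous/nonsynonymous changes of the reference
codon and `CDS_mixed` otherwise.

## Diversity statistics

π is the mean over called sites of the pairwise difference proportion
(1 − Σ~a~ C(c~a~,2)/C(n,2) per site); monomorphic called sites contribute 0
to the numerator and enter the denominator. Tajima's D uses the standard
constants for sample size n and is undefined (NA) when no site segregates —
and also at n = 3, where the variance constants vanish identically. Window
scans anchor full windows at position 0 of each chromosome (20 kb windows,
4 kb steps by default; 10 kb/2 kb and 200 bp/40 bp are the finer scan
scales) and append one final partial window with its true extent when the
full windows stop short of the chromosome end; a 100 kb chromosome at
20 kb/4 kb therefore yields exactly 21 windows. D~xy~ is the mean cross-group
difference proportion per called site, windowed the same way, with
within-group π of the larger group reported as a control.

## Structure

*p*-distances are mismatch proportions over all called sites (the constant
invariant-site denominator only rescales the matrix). Neighbor joining
delegates to the standard Saitou–Nei implementation in \pkg{ape}; branch
lengths are reported as computed, including the negative lengths NJ can
produce. SNP thinning follows the documented rule exactly: per chromosome,
one uniform draw among SNPs within 50 kb of the 5′-most SNP, then repeatedly
the closest SNP at least 50 kb downstream. PCA encodes haplotypes 0/1 as
major/non-major per SNP, centers columns without variance scaling (a
MAF-scaling flag exists), and fixes component signs by making the
largest-magnitude loading positive.

## LD decay and the recombination rate

r² is computed for within-chromosome pairs with both minor-allele
frequencies ≥ 10% and separation up to 500 kb, as the squared correlation of
0/1 (major/non-major) indicators — identical to D²/(p~A~q~A~p~B~q~B~).
Multiallelic sites are reduced to major-vs-rest for LD only and flagged.
Pair distances are binned in non-overlapping 1 kb bins, and ρ = 4Nr per bp
is fit by least squares of the per-bin mean r² against the drift expectation
σ²~d~(C) = (10 + C)/(22 + 13C + C²), C = ρ·distance, over bins with
midpoints between 1 and 100 kb — beyond that range population structure
dominates the signal. Bins are weighted by pair count (an unweighted flag
exists) and the 1-D minimization runs on a log₁₀ ρ scale over
[10⁻¹², 1], so a noise-free curve is inverted to ~10⁻⁹ relative error. A
finite-sample 1/n adjustment to σ²~d~ is implemented but off by default.

## The PHS test

For allele A carried by n~A~ samples at position x,

$$\mathrm{PHS}_A(x) = \binom{n_A}{2}^{-1}\!\!\sum_{\substack{i<j \\ i,j\,\in\,\text{carriers}}}\!\! Z_{ijx} \;-\; \binom{n}{2}^{-1}\sum_{i<j} Z_{ijx}, \qquad Z_{ijx} = \frac{d_{ijx}-\bar d_{ij}}{\sigma_{ij}},$$

where d~ijx~ is the genetic length of the identity tract of pair (i,j)
spanning x, and d̄~ij~, σ~ij~ are the mean and population standard deviation
of that pair's tract lengths genome-wide. Conventions the source text leaves
open are fixed as follows:

* **Genetic map.** A degree-4 polynomial of cM against bp per chromosome,
  fit on unit-scaled coordinates (raw bp powers are numerically
  rank-deficient at megabase scale). Evaluation clamps outside the marker
  range; a fit that decreases anywhere on a 1 kb grid is repaired to its
  running maximum and flagged, with evaluation then interpolating the
  repaired grid.
* **Tract boundaries** are the flanking discordant positions themselves
  (exclusive) or the chromosome ends; the tract spanning a site where the
  pair is discordant has genetic length 0.
* **Missing clusters.** Any stretch of ≥ 30 kb (physical bp) without a
  called site terminates tracts at its edges; no tract exists inside the
  gap.
* **Moments** are taken over *all* maximal tracts of the pair genome-wide,
  not only tracts spanning SNPs. Pairs with fewer than two tracts or zero
  tract-length variance (clones) are flagged and contribute Z = 0.
* **Candidates.** PHS is computed for every allele with ≥ 2 carriers at
  every SNP; the top 0.1% (ceiling-rounded) are flagged *within
  carrier-count classes*, because allele frequency strongly shapes the null
  distribution of PHS. A global ranking mode exists. Because carrier-pair
  tracts span the entire shared haplotype of a sweep, PHS is nearly constant
  across a swept block and the flagged record is best read as marking the
  block, not a base-resolution peak.

PHS depends only on differences of genetic positions after per-pair
standardization, so it is invariant to adding a constant to all cM values —
a property the test suite checks.

## The synthetic-data generator

The generator's defaults state the conditions the pipeline is validated
under: n = 32 haploid samples, per-site θ = 0.003 (echoing a genome-wide
diversity of ≈ 0.3%), ρ = θ/100 (an effective recombination rate about 1/100
of the mutation scale), megabase-scale chromosomes, a 5-sample clade forced
monophyletic below a deep split (clade split depth 4 coalescent time units,
roughly twice the expected neutral TMRCA — deep enough to echo a clearly
differentiated subgroup without overwhelming genome-wide diversity), an
8-of-32-carrier partial sweep over 50 kb, and a 5%-divergent 1 kb segment.

Chromosomes are partitioned into linkage blocks by a Poisson process and
each block carries one independent coalescent genealogy; mutations fall on
branches at rate θ/2 per site per unit time, so E(π) = θ and
E(S) = θ·a₁·L exactly. The block-boundary rate is ρ/2: a block boundary
decorrelates genealogies *completely*, while a single ancestral
recombination event does so only partially, so the turnover rate matching
the exponential block-survival decay of r² to σ²~d~(ρd) over the 1–100 kb
fit range is about half the nominal ρ. With this constant the fitted ρ
recovers the simulated value with a geometric-mean ratio near 1 over
replicates, though individual 2 Mb replicates — holding only ~30 independent
blocks — spread by roughly a factor of 3 either way; the recovery check is
therefore asserted on the geometric mean of 20 replicates.

Fixture annotations are written *into* the reference sequence so their
contracts hold by construction: CDSs begin with ATG, end with a stop, avoid
internal stops and are codon-aligned across their intron; introns carry a
CTAAC motif at position ≥ 12; repeat tracts matching the masking rules,
ncRNAs, pseudogenes, transposable elements, centromeres and telomeres are
placed per chromosome. Marker tables derive from a smooth monotone quartic
truth map (≈ 100 cM per chromosome) with 0.5 cM Gaussian marker noise.

**What the generator does not emulate** — and hence what green tests do and
do not show about real data: there is no selection, so synonymous,
nonsynonymous and intergenic diversity are equal by construction and the
contrast between them (the hallmark of purifying selection in real panels)
is *not* reproduced; no sequencing-error or mapping-error process, so the
call filters are exercised on dedicated toy reads rather than end to end; no
demography beyond the single forced clade; block-wise rather than gradual
genealogy turnover, so fine-scale LD structure within blocks is too clean;
and the genetic map is smooth by construction. Passing tests demonstrate
correctness of the statistics and the pipeline plumbing under known truth,
not the rediscovery of biological signal.

## Numerical choices and degenerate inputs

* Tajima's D returns NA for S = 0 and for n = 3 (vanishing variance
  constants).
* Codon columns containing a stop or ambiguous codon in any sample are
  excluded from both site and difference counts, matching the complete-sites
  philosophy.
* ρ fitting requires ≥ 3 bins in range; a flat decay at 10/22 fits ρ ≈ 0.
* PCA drops constant SNP columns with a warning and returns an all-zero
  spectrum when every column is constant.
* `estimate_rho` is invariant to rescaling all bin weights by a constant.
* All generators and the pipeline are deterministic given their seeds;
  fixtures regenerate byte-identically, and `run_pipeline` reruns
  byte-identically from the same config (the manifest records parameters,
  input checksums and the package version).

## Problem sizes used by the test suite and acceptance script

Unit tests run on toy matrices and 20–60 kb simulations. The acceptance
suite uses: 200 neutral replicates of 100 kb for calibration; 20 replicates
of 4 × 500 kb for ρ recovery; 20 replicates of 500 kb with a 50 kb sweep
for PHS detection; 20 replicates of 100 kb for the divergence scan and NJ
clan recovery. `scripts/acceptance.R` runs a 3 × 200 kb full-scenario
pipeline plus reduced replicate counts of the same experiments. These sizes
keep a complete run in the minutes range on a single core while leaving
Monte-Carlo error well inside the asserted bands.

## Known limitations

Identity tracts and PHS are quadratic in sample count (all C(n,2) pairs) and
linear in SNPs; panels far beyond ~100 haploids would want a compiled
backend. The LD estimator assumes biallelic (major-vs-rest) encoding.
`filter_reads` trims exact-match adapters only — discovery belongs to
external QC tools. The NJ implementation is borrowed from \pkg{ape}, so
tie-breaking among exactly equal Q-criterion pairs follows that
implementation. dN/dS against an outgroup is out of scope (no usable
outgroup at the motivating divergence scales), as are coalescent p-values
for D and composite-likelihood recombination maps.
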