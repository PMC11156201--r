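---
title: "Methods: measuring purging of recessive deleterious variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring purging of recessive deleterious variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package addresses

Small, fragmented plant populations — alpine shrubs are the motivating case
— experience strong drift and often elevated inbreeding through selfing or
biparental inbreeding. The classical expectation is that small effective
size weakens purifying selection and lets deleterious mutations accumulate.
The opposite can happen for *recessive* deleterious alleles: inbreeding
exposes them as homozygotes, selection sees them, and the population purges
them. The observable signature, per individual, is a *lower* ratio of
derived deleterious alleles to derived neutral alleles in the bottlenecked,
inbred populations, together with reduced neutral diversity, long runs of
homozygosity (ROH), and a deleterious site-frequency spectrum (SFS) shifted
toward rare variants.

`purgescan` implements the full measurement chain for this signature on
biallelic SNP data, and a forward simulator that generates data with the
relevant statistical structure so every stage can be validated end to end.

# The genetic load proxy

For sample $j$, with $D_j$ the summed dosage of derived deleterious
nonsynonymous alleles (dnSNPs) over called genotypes and $S_j$ the summed
dosage of derived alleles at four-fold degenerate sites,

$$ \widehat{L}_j \;=\; D_j / S_j . $$

The four-fold denominator controls for how much derived variation a sample
carries overall (mapping distance to the reference, missingness, ancestral
misidentification), so the ratio tracks the *deleterious fraction* of
derived variation rather than raw diversity. "Allele counts" are read
literally as diploid dosages (heterozygote = 1, derived homozygote = 2); a
carrier-based variant (any dosage $\ge 1$ counts 1) is available behind the
`carriers` flag of `loadTable()`. Missing calls drop out of both numerator
and denominator for that sample. A zero denominator flags the sample as
undefined rather than dividing.

Sites where the two outgroups agree on a third allele have *both* focal
alleles derived. They would add a constant dosage of 2 to every sample —
informative for absolute load, constant for comparisons — and are excluded
by default (`includeExternal = FALSE`), with counts reported.

# Ancestral state inference

Polarization uses two single-genome outgroups. The rules, in order: if both
outgroups carry the same allele and it is one of the two focal alleles,
that allele is ancestral (`resolved`); if they agree on an allele carried
by neither focal allele, both focal alleles are treated as derived
(`resolved_external`; used for load, excluded from the SFS whose frequency
axis needs a single derived allele); if the outgroups disagree or either is
missing, the site is `unresolved` and carries no derived-allele counts
anywhere. The rule is symmetric in the outgroups. Outgroup-discordant sites
are excluded rather than resolved by majority because a single outgroup
provides no parsimony signal at a biallelic site; their counts are
reported.

# Functional annotation

Site and variant classes are recomputed from the reference FASTA and GFF3
CDS models rather than ingested: region classes (CDS, intron, upstream,
downstream, intergenic), per-site codon degeneracy, and per-variant effects
(synonymous, nonsynonymous, stopgain, stoploss). Minus-strand codons are
read on the reverse complement; the GFF3 phase column is honored, and a
transcript whose CDS length is not a multiple of three after phase trimming
is excluded from codon classes with a warning. Across overlapping
transcripts a variant takes the most severe effect
(stopgain > stoploss > nonsynonymous > synonymous), while four-fold status
requires unanimity — a site that is four-fold in one reading frame only is
not a valid neutrality proxy, and conservatism here protects $\pi_s$.
The upstream/downstream window is 1 kb, the conventional default of this
tool family; it is configurable (`flankBp`) because annotations differ in
what they call "regulatory neighborhood".

Deleteriousness itself is *not* predicted: dnSNP labels are ingested from
an external list (in practice a SIFT-style "score < 0.05" set, or the
simulator's truth labels). Conservation-based scoring is out of scope.

# Population statistics

Per-site diversity is the mean pairwise difference
$\pi = 2c(n-c)/(n(n-1))$ on called haplotypes. Window values divide the
summed site $\pi$ by the *full* window length in bp, monomorphic positions
included — the convention behind per-bp figures like $10^{-3}$ and the
behavior of the standard windowed tools (50 kb windows, 10 kb steps for
scans; nonoverlapping 10 kb windows restricted to the four-fold site list
for $\pi_s$). Windows are half-open `[start, end)` internally; coordinates
are 1-based only at the VCF boundary.

$F_{ST}$ uses the Weir–Cockerham (1984) two-population variance components
on allele counts, with heterozygosity entering at its random-mating
expectation ($2pq \cdot 2n/(2n-1)$) since the estimator is fed allele
counts, not genotypes — the "no inbreeding correction" variant. Windows use
the ratio-of-sums (weighted) estimator $\sum a / \sum(a+b+c)$; negative
values are retained, and windows with fewer than 10 informative SNPs
(configurable) are missing.

The unfolded SFS is computed on a fixed number of haplotypes via
hypergeometric projection: site $j$ with $K_j$ derived among $N_j$ called
haplotypes contributes $P(i \mid K_j, N_j, n)$ to bin $i$. Projection
handles missing genotypes without discarding sites; mass projected to the
fixed classes $0$ and $n$ is excluded. The rare-variant fraction uses a
default DAF threshold of 0.1 (strict inequality), configurable — binned
spectra in the literature motivate a threshold near the lowest bins but fix
none.

# Runs of homozygosity

ROH detection reimplements the PLINK-style scanning-window caller with the
standard resequencing parameterization (window of 40 SNPs tolerating 2
heterozygous and 10 missing calls; SNP qualification at a minimum 5%
homozygous-window fraction; final segments of at least 40 SNPs and 30 kb,
inter-SNP gaps at most 1000 kb, at least one SNP per 50 kb — the gap and
density units are kilobases, a common misreading hazard). The exact rule
set is frozen in code and by a brute-force window-enumeration oracle in the
test suite: windows truncated at chromosome ends still count toward hit
fractions; qualifying runs are split at over-gap jumps, trimmed of
heterozygous/missing boundary SNPs, then filtered on SNP count, length and
density. The tool-family threshold semantics are "minimum fraction of
homozygous windows", and that is what the caller implements.

# The forward simulator

`simulatePopulations()` is a diploid Wright–Fisher simulator with viability
selection (multiplicative fitness $1$, $1-hs$, $1-s$ per site), partial
selfing (an offspring selfs with probability $F$, with the *whole
individual* selfed, which preserves the genome-wide identity
disequilibrium that makes ROH and purging work), demographic epochs and
population splits, and two linkage modes:

* `independent` (default): free recombination; every site segregates
  independently given the pedigree. Closed-form single-locus checks are
  exact in this mode.
* `block`: one non-recombining segment, transmitting whole haplotypes.

Mutations arise only at pre-enumerated candidate sites of a toy annotated
genome built alongside the simulation: four-fold degenerate positions
(neutral class), missense-capable positions (deleterious class, default
$s = 0.1$), and stop-capable positions (stopgain class, default $s = 0.9$,
$h = 0.02$, a nearly recessive, strongly deleterious "loss-of-function
equivalent"). Because the candidate alleles are chosen from the codon
table, the simulated class labels are *literally true* under annotation of
the emitted FASTA + GFF3 — a cross-module consistency the tests exploit.
Genes are two-exon (non-zero GFF3 phases are exercised) on alternating
strands.

A mutation hitting an already-segregating site adds a copy of the *same*
derived allele. Strict infinite-sites suppression would cut the mutational
influx at segregating sites and push the recessive mutation–selection
balance below its closed form $\sqrt{u/s}$; same-allele recurrence keeps
sites biallelic (the point of the infinite-sites approximation here) while
matching the equilibrium. Outgroup alleles are generated by mutating the
true ancestral allele once per lineage with probability $1 - e^{-d}$;
outgroups are never polymorphic, matching single-genome outgroups.

Random streams are keyed per population, generation and stage from the
master seed, so identical configurations reproduce bit-identical bundles.
Extinction (total fitness zero) is an explicit error naming the population
and generation.

## The highland/lowland scenario

`highlandLowlandScenario()` encodes the study conditions: one large
outcrossing lowland population and four highland populations that split
simultaneously, bottleneck to graded sizes and reproduce with selfing rate
$F = 0.8$. The graded sizes (25–90 diploids at desk scale against a
lowland 120) create the across-clade gradient in long-term $N_e$ that the
$\pi_s$–load correlation measures. The selfing rate is a free parameter of
the scenario, not an empirical estimate — the motivating system lacks a
published selfing rate — and 0.8 puts the scenario firmly in the
strong-inbreeding regime where purging theory predicts a clear signal.
Desk-scale mutation rates are inflated (neutral $1.4 \times 10^{-5}$ per
candidate site per generation) so that a 200 kb toy genome over 700
generations segregates a few thousand SNPs; the real per-site rate
($7 \times 10^{-9}$, generation time 3 years in the motivating system)
would need genome sizes and times far beyond a test suite, and only the
*ratios* of drift, selection and mutation matter for the directional
claims.

The purging experiment runs the scenario twice per replicate — deleterious
mutations fully recessive ($h = 0$) versus additive ($h = 0.5$) — through
the full pipeline, and tabulates per-clade medians plus directional
indicators. Under recessivity the highland clades show lower load, more
ROH, lower $\pi_s$ and an excess of rare deleterious variants; under
additivity the load ordering is deliberately not enforced, because without
homozygote exposure inbreeding gains selection nothing — that contrast is
the recessivity dependence at the heart of the purging interpretation.
The experiment filters with MAF 0 (the pipeline default keeps the
conventional 0.05): at desk-scale sample sizes a 5% MAF cut deletes the
rare-variant tail that load and SFS comparisons measure. Rare-variant
fractions are compared between pooled altitude groups, mirroring group-level
comparisons; within a single bottlenecked clade the neutral SFS also loses
rare variants, so the group contrast is where the deleterious excess is
legible.

## What the generator does and does not emulate

It emulates: bottlenecks and splits, selfing with genome-wide identity
disequilibrium, recessive and additive deleterious variation, stopgain-like
variants, outgroup divergence with ancestral-state noise, and a consistent
reference + annotation. It does not emulate: linkage and local LD structure
(so ROH in the independent mode reflect genome-wide autozygosity of inbred
individuals rather than IBD tracts; the block mode is the opposite
extreme), sequencing depth and call error (depth filters are exercised on
hand-built fixtures instead), gene conversion, recombination maps, or
demographic inference. Passing tests therefore validate the estimators and
the directional biology, not read-level realism.

# Numerical and degenerate-input choices

* Quantile outliers use order statistics: cutoff at the
  $\lceil qm \rceil$-th largest value, ties included (a constant track
  returns everything, with a warning).
* The SFS projection refuses `projectionN` larger than the called
  haplotypes at more than half the sites, advising a smaller projection.
* Windows larger than the chromosome collapse to one truncated, flagged
  window.
* Duplicate windows in an external score track, duplicate outgroup rows,
  unsorted ROH positions, and REF mismatches against the reference are
  errors, not warnings.
* Sample-order invariance and ref/alt-swap invariance of the window tracks
  are asserted in the tests.
* Wilcoxon rank-sum tests between clades use the normal approximation
  (`exact = FALSE`) since load ties are common; pairwise p-values are
  Benjamini–Hochberg adjusted; singleton clades keep their medians but are
  excluded from tests.

# Problem sizes

The test-suite simulations use desk-scale sizes chosen to keep each
statistical check well-powered while the whole suite stays interactive:
closed-form neutral checks at $N = 100$ over 50 replicates of a 30 kb
neutral genome; mutation–selection balance at $N = 60000$ over a small
single-gene mutational target — the deterministic $\sqrt{u/s}$ requires
$4Nu$ comfortably above 1, below which Wright's stationary density pulls
the mean frequency down; the purging experiment at 30 replicates of the small
scenario (200 kb genome, 700 generations, 72 sampled diploids); sweep
recovery over 20 replicates of a 600 kb two-population scenario. The
acceptance script reruns the same computations at slightly reduced
replicate counts and reports the resulting quantities as JSON.

# Known limitations

* The load proxy is a *relative* measure; it does not decompose realized
  versus masked load and encodes no fitness scale.
* Free recombination removes hitchhiking, so the planted-sweep check
  validates the outlier/intersection machinery on a single-site signal,
  not the spatial footprint of a real sweep.
* The Weir–Cockerham estimator here assumes random mating within
  populations; in strongly selfing populations site-level $F_{ST}$ against
  an outcrossing population absorbs some within-population structure.
* Polarization accuracy is bounded by double-hit convergence in the
  outgroups ($\sim d^2/3$ per site), which the monotonicity test
  quantifies on simulated truth.
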