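---
title: "Methods: simulation-validated comparative population genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-validated comparative population genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guenomix)
```

# Scope

`guenomix` implements the statistical chain used in comparative genomic
studies of closely related primate lineages: genotype-level quality
filters, heterozygosity and runs of homozygosity (ROH), derived-allele
mutation load, ABBA-BABA D-statistics, windowed f_dM introgression
landscapes, convergent amino-acid detection, and gene-set overlap
tests. Because the interesting claims of such studies depend on dozens
of genomes and external annotation pipelines, the package pairs every
analysis with a truth-known synthetic-data generator, so that each
stage can be validated end to end against planted signal: a known
admixture fraction, known autozygous tracts, known impact labels, known
convergent columns.

This vignette records the models, the tunable parameters and their
defaults, the numerical decisions, and the limits of what the
simulation-based validation shows.

# Data model and genotype filters

Genotypes are diploid dosages of the alternate allele (0/1/2, `NA` for
missing) at biallelic SNPs, held in a sites-by-samples matrix with
1-based VCF positions. All interval work (windows, ROH segments, gene
bodies) is 0-based half-open; the converters live in the readers, so no
analysis code ever translates coordinates. Indels and multiallelic
records are excluded at parse time: every downstream statistic is
defined on the biallelic pattern algebra, and phase is never used.

Two per-genotype filters mirror standard resequencing practice:

* **Depth mask** — a genotype is set to missing when its site depth is
  below half or above twice the sample's mean depth (the mean is
  supplied per sample; use the X-chromosomal mean for X data). Both
  bounds are strict; boundary depths survive.
* **Allele-balance mask** — a heterozygous call whose minor allele is
  supported by `< 0.25` of its reads is set to missing. Homozygous
  calls are never touched; het calls with zero reported allele depth
  are masked and tallied in a warning.

Both masks only ever replace values with `NA` (never alter a surviving
genotype) and are idempotent; both properties are unit-tested.

# The synthetic-data generator

## Multi-population SNP data

Genealogies are simulated with a structured coalescent over a
demography of population splits and mass-migration pulses: backward in
time, each lineage in the pulse's recipient moves to the donor
independently with probability *f*. Mutations fall on branches as a
Poisson process under an infinite-sites model; the outgroup is a
sampled population, and reference/alternate labels are randomised so
that analyses must polarize against the outgroup exactly as on real
data.

The genome is modelled as independent, non-recombining loci (default
10 kb) with free recombination between loci. This is the standard
desk-scale approximation: linkage within a window is total and linkage
between windows absent, which preserves everything the window- and
block-based statistics consume (per-window genealogical correlation,
between-block independence for the jackknife) while keeping 5 Mb
genomes at well under a second of compute. Within-locus recombination,
recombination-map structure and selection are deliberately not
modelled.

Default four-taxon design (`sim_config()`): populations P1, P2
(sisters), P3 (donor), OUT (outgroup); two diploid samples per
population; diploid *N*~e~ = 10,000 on every branch; split times
10,000 / 40,000 / 100,000 generations; mutation rate 1e-8 per bp per
generation; optional pulse from P3 into P2 at 5,000 generations. These
are fixture choices giving realistic primate-scale heterozygosity
(~1e-3 per categorized site at the simulated density) and clear but not
trivial introgression signal at 5 Mb.

The two-recipient design (`sim_config_two_recipients()`) adds a second
recipient: topology (((P1,(P2a,P2b)),P3),OUT), splits at 2,000 /
25,000 / 40,000 / 100,000 generations. A `shared` pulse lands in the
recipients' common ancestor (default 20,000 generations); `independent`
pulses land separately in each recipient (default 1,000 generations).
The recipient-ancestor branch has its own *N*~e~ (default 5,000, a mild
bottleneck): lineages from the two recipients then usually coalesce
before the shared pulse, so introgressed ancestry — and hence the
windowed f_dM landscape — is inherited jointly, the signature used to
place gene flow on an ancestral branch. The mutation rate of this
design is raised to 4e-8 so that 10-kb windows carry on the order of
100+ usable SNPs, matching the SNP density at which real landscapes
are retained after the 100-SNP window filter; it compresses a
multi-gigabase analysis into 5 Mb rather than emulating a primate
mutation rate.

## Fixture generators

* `simulate_roh_genome()` scatters SNPs at a chosen density (default
  1/500 bp), makes them heterozygous with probability `het_rate`
  (default 0.3) outside planted tracts and homozygous inside, with an
  optional residual error-het rate inside tracts.
* `simulate_impact_table()` labels alternate alleles
  synonymous/moderate/high at chosen rates and records per-sample
  derived-allele truth counts (outgroup-polarized when a population
  map is supplied).
* `simulate_codon_alignments()` builds in-frame codon alignments where
  every focal sequence carries the planted amino acid at planted
  columns; optional noise columns, internal stop codons and missing
  stretches exercise the translation filters.

All four generators are byte-deterministic under a fixed seed.

# Introgression statistics

A site is usable when the outgroup role is monomorphic (its allele is
taken as ancestral — polymorphic or heterozygous outgroups are
skipped, tallied) and every role has at least one called genotype.
With derived-allele frequencies p1, p2, p3, p4 the site weights are
ABBA = (1−p1)·p2·p3·(1−p4) and BABA = p1·(1−p2)·p3·(1−p4): population
frequencies, not pseudohaploid draws, matching the behaviour of the
standard multi-sample tooling. D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA).

Standard errors come from a weighted delete-one-block jackknife
(Busing's delete-m~j~ formulae) over contiguous blocks, weighted by
per-block usable-site counts; Z = D/SE. The default block is 1 Mb; the
desk-scale analyses use 250 kb so that a 5 Mb genome yields 20 blocks,
the conventional minimum for stable jackknife variance. Identical
blocks give SE = 0 exactly, and the estimator refuses (<2 non-empty
blocks) or warns (<20) on degenerate partitions.

Windowed f_dM uses non-overlapping 10-kb windows (windows with fewer
than 100 usable SNPs excluded). The numerator is the windowed
ABBA−BABA sum; the denominator substitutes the *dynamic donor*
pD = max(p2, p3) where p2 ≥ p1, and pD = max(p1, p3) with a negative
sign where p1 > p2 — the symmetric windowed estimator associated with
the sliding-window ABBA-BABA tooling. The statistic is bounded in
[−1, 1] and sign-matches D on any single-site window; both are
property-tested. Retained windows with a zero denominator (possible
only in degenerate frequency configurations) are dropped and tallied.

Outlier windows use the linear-interpolation empirical quantile
(R type 7) with a `>=` comparison, so ties at the threshold are all
included. Landscape comparison pairs windows by exact coordinates and
reports Pearson's r over windows retained in both landscapes.

# Runs of homozygosity

The caller reproduces the plink `--homozyg` parameterization quoted in
primate resequencing work: runs of ≥100 kb and ≥100 SNPs, ≤1
heterozygous call per 50-SNP scanning window, ≥1 SNP per 50 kb on
average, and no internal gap >1 Mb. Missing genotypes are removed
before scanning so they can neither break nor extend a run. A SNP is
run-compatible when at least 5% of the scanning windows containing it
pass the het limit; maximal stretches of compatible SNPs are split at
oversized gaps and then tested against all thresholds. Segment
endpoints are the first/last SNP of the run (SNP-delimited, reported
half-open); plink's own edge trimming is under-documented, so this
SNP-delimited variant is declared the reference behaviour here and
pinned by fixtures that violate each threshold in isolation.

The *accessible genome* denominator converts every heterozygous call
to homozygous and reruns the identical caller: SNP deserts and
low-density regions where no ROH could ever have been called drop out
of the denominator. A fully homozygous genome therefore has ROH
fraction exactly 1 — a fixed point asserted in the tests. Short ROH
are 100 kb–1 Mb (inclusive bounds), long ROH strictly >1 Mb.

# Heterozygosity and mutation load

Heterozygosity is the fraction of called genotypes that are
heterozygous, over whatever site set is supplied; absolute values
therefore depend on the callable-site set, and only relative and
property-level behaviour is claimed. Load counts derived *alleles*
(dosage sums — a homozygous-derived genotype contributes 2) per impact
category and reports moderate/synonymous and high/synonymous ratios;
the ratio form cancels per-genome callability provided callability is
category-independent. Impact categories are assumed pre-resolved to
one category per alt allele (canonical-transcript resolution is
upstream of this package).

# Convergent amino-acid substitutions

Sequences are translated with the standard genetic code; a terminal
stop is permitted (recoded as missing), any internal stop excludes the
sequence, as does >50% missing amino acids (strictly more than half).
A gene is rejected when more than half of either focal group was
excluded. A column is convergent when all non-missing residues of both
focal groups equal one state that is absent from every non-missing
background residue. Two decisions are worth making explicit: fixation
is evaluated over non-missing residues only (requiring unanimity over
missing data would discard sequences the filters deliberately kept),
and the background is only required to *lack* the shared state, not to
be monomorphic — that is what "private" means. Adding background
samples can therefore only remove calls, never add them
(anti-monotonicity, property-tested).

# Gene-set statistics

Genes are matched to windows when the gene body or its strand-aware
upstream interval (exactly `upstream_bp` = 10 kb, half-open, clipped
at zero) overlaps a window by ≥1 bp. Overlap significance uses the
two-sided Fisher's exact test with the classical minimum-likelihood
summation convention (alternatives such as doubling change p, so the
convention is pinned and checked against full hypergeometric
enumeration). The universe must be stated explicitly; the worked
examples use the 12,569 genes testable on the focal ancestral branch
as the default universe, with set memberships intersected into the
universe first. The sample odds ratio is reported, with zero cells
flagged as degenerate.

# Validation design and problem sizes

The test suite and the acceptance script validate each stage at fixed
desk-scale sizes, chosen so the whole suite runs in about a minute:

* D-statistic calibration: 20 replicates of 5 Mb, four taxa, 250-kb
  jackknife blocks; the null (f = 0) must keep |Z| < 3 in at least
  19/20 replicates and a 10% pulse must give Z > 3 in at least 18/20.
* Landscape comparison: 5 Mb two-recipient genomes; a shared ancestral
  pulse must give r > 0.8 between the recipients' 10-kb landscapes,
  and independent pulses a significantly lower r (Fisher-z test). Some
  residual correlation remains under independent pulses because both
  landscapes share P1, P3 and the outgroup — this mirrors real
  paired-landscape comparisons, which share the same reference panel.
* ROH: planted tracts of 0.3–3 Mb with het rate 0.3 outside must be
  recovered with base-pair precision and recall ≥ 0.95; each plink
  threshold is additionally pinned by a fixture violating it alone.
* Load and convergence: generator truth must be recovered exactly.
* Fisher/Pearson: equality with brute-force oracles to 1e-9 on 100
  random instances.

What passing these tests shows — and does not show. The generator
produces clean biallelic genotypes with no genotyping error, no
missingness (unless planted), no repeat or mappability structure, and
free recombination between loci. Passing therefore demonstrates that
the estimators are implemented correctly and behave as the theory
predicts under their own assumptions; it does not certify behaviour
under real-data artefacts (reference bias, paralogy, callability
heterogeneity), which the depth and allele-balance masks only partly
emulate. Absolute heterozygosity and load levels in the simulations
are fixture properties, not predictions for any real taxon.

# Known limitations

* No within-locus recombination: haplotype-length statistics (e.g.
  dating introgression from tract lengths) are out of scope.
* The outgroup-monomorphism polarization silently mis-polarizes sites
  where the outgroup is fixed derived; this is a property of the
  method itself, shared with the real analyses it reproduces.
* The ROH caller is a scanning-window heuristic by design (matching
  plink), not a likelihood/HMM caller.
* `fisher_overlap` tests one pair of sets; multiple-testing control
  across many gene-set tests is the caller's responsibility.
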