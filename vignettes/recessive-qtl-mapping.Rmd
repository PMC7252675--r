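---
title: "Mapping recessive semen-quality loci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive semen-quality loci: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recessivescan)
```

`recessivescan` implements the analysis chain that maps a recessive locus
for semen quality and male fertility from routine artificial-insemination
data: phenotype construction from repeated ejaculate records, pedigree
variance components, a sliding-window haplotype scan under three
inheritance models, shared-autozygosity fine-mapping, recessive-compatible
variant filtration, and cryptic splice-donor analysis. This vignette is the
package's account of the underlying science: the models and their
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## Phenotypes from repeated ejaculate records

Semen quality is measured on every ejaculate, not once per animal, so the
phenotype pipeline starts from record-level data. `filter_ejaculates()`
applies a fixed-order cascade of laboratory plausibility rules (interval to
the preceding collection known; collection age 400–1000 days; volume and
motility recorded; no rejection cause; motility ≥ 70%; volume > 1 ml;
concentration > 0.3 × 10⁹/ml; not pooled; first ejaculate per day;
collector known; anomaly scores in 0–3; 15–25 million sperm per straw; at
least 8 retained ejaculates per bull). The order matters — each rule is
applied to the survivors of the previous one, and the attrition log records
records and bulls remaining after each step — so the order is fixed and
only the thresholds are configurable. The volume and concentration minima
are part of the AI minimum requirements rather than separate bookkeeping
rows in the source data; they are applied as explicit steps directly after
the motility rule so that the attrition log accounts for every removal.

The default association phenotype is the per-bull arithmetic mean of the
filtered records (`aggregate_traits()`). `adjust_traits()` offers the
alternative: per-trait least-squares adjustment for age, collection
interval, collector and season (calendar quarter of the collection date),
averaging residuals per bull. On data with realistic effect sizes the two
are nearly collinear (r > 0.9), which is why the raw averages are the
default — effect estimates stay on the original trait scale.

Bull fertility is estimated from insemination outcomes (success = no
re-insemination within 56 days) with a linear probability model containing
month, parity, straw-price class, breed combination, technician, herd and
bull (`estimate_fertility()`). Whether herd should be random or fixed is
not determinable from the data description we target; at the scale this
package addresses a fixed-effect herd is an adequate approximation and
keeps the model a single sparse least-squares solve. Bull effects are
standardized to mean 100, SD 12 over the estimation cohort (exactly, before
outlier handling), and bulls more than 3 SD below the mean are dropped as
likely carriers of rare defects that would otherwise generate spurious
association signals.

## Variance components: the repeated-records animal model

`reml_fit()` fits

$$y = Xb + Z_u u + Z_p p + e, \qquad
u \sim N(0, A\sigma_g^2),\;
p \sim N(0, I\sigma_{pe}^2),\;
e \sim N(0, I\sigma_e^2),$$

where the fixed effects are age, collection interval, collector and season,
$A$ is the pedigree numerator relationship matrix (tabular method in
`build_A()`, Henderson's-rules sparse inverse with inbreeding in
`build_Ainv()`), $u$ are additive genetic effects and $p$ permanent
environmental effects of the bulls. Heritability is
$\sigma_g^2 / (\sigma_g^2 + \sigma_{pe}^2 + \sigma_e^2)$ and repeatability
$(\sigma_g^2 + \sigma_{pe}^2) / (\sigma_g^2 + \sigma_{pe}^2 + \sigma_e^2)$;
repeatability ≥ heritability by construction, and the gap measures
permanent environmental variance — large for semen traits, where
between-collection conditions persist per bull.

The maximizer is EM-REML on the mixed-model equations: monotone in the
restricted likelihood, robust near the boundary, but linearly convergent.
By default a short EM burn-in (3 rounds) is followed by average-information
(AI) updates, which typically converge in about ten iterations at tolerance
1e-8 on the relative parameter change; any AI step that would leave the
parameter space or decrease the restricted likelihood falls back to an EM
step, so the likelihood trajectory remains monotone for the accepted
sequence. Pure EM (`method = "em"`) is kept for the monotonicity guarantee
and for boundary cases. Variance components are floored at 1e-12 times the
phenotypic variance and reported as zero at the boundary. The restricted
likelihood is evaluated through the mixed-model-equation identity
$\log|V| + \log|X'V^{-1}X| = (n - n_f - q - q_p)\log\sigma_e^2 + \log|A| +
q\log\sigma_g^2 + q_p\log\sigma_{pe}^2 + \log|C|$; the tests confirm it
against a direct dense-$V$ computation (`reml_loglik_direct()`), which also
powers a 21³ grid-search oracle on a five-animal toy.

Standard errors are not computed by default; parameter-recovery accuracy is
instead demonstrated by simulation (below). This keeps the fit to one
Cholesky factorization per iteration.

## The haplotype scan

Phased genotypes are analysed in windows of 50 contiguous SNPs advanced in
steps of 15 SNPs per chromosome; trailing markers that do not fill a window
are untested, and windows never span chromosomes. A haplotype is an exact
50-allele string; a bull carries 0, 1 or 2 copies by exact string match on
each phased chromosome. Haplotypes with frequency above 1% are tested by
ordinary least squares of the phenotype on an intercept, the top ten
principal components of the VanRaden genomic relationship matrix
(`grm_pcs()`: centered, variance-standardized genotypes; eigenvectors
scaled by the root eigenvalue), and the haplotype predictor — copy count
(additive), carrier indicator (dominant) or homozygosity indicator
(recessive). Recessive tests require homozygotes in at least
`ceiling(0.01 N)` bulls, since the homozygote-indicator contrast is
meaningless below that. Within a scan the base design is fixed, so each
test residualizes the phenotype and the predictor on the base design once
(Frisch–Waugh); this is algebraically the full OLS fit and is verified
against `lm()` to 1e-10 in the tests.

Two genome-wide summaries are reported. The Bonferroni threshold divides
0.05 by the number of haplotype tests actually performed — not the number
of windows — because each haplotype within a window is a separate test;
with the 112,667 tests of a dense-panel fertility scan this gives the
familiar 4.4 × 10⁻⁷. The genomic inflation factor is
`median(qchisq(1 - p, 1)) / qchisq(0.5, 1)` over all P values of the scan
and should sit near 1 under proper stratification control.

`conditional_scan()` adds the top haplotype's coding (homozygosity
indicator for recessive scans, copy count for additive) as a covariate to
every regression. If that haplotype fully tags the causal variant, no
window overlapping the locus stays significant — the package's criterion
for "the haplotype accounts for the QTL". A window elsewhere on the same
chromosome can still clear the genome-wide threshold by chance; the
conditional check therefore evaluates windows overlapping the associated
segment, not the whole chromosome.

Principal components are computed once from the full panel and reused
across scans and conditional re-scans; recomputing them per scan would
change nothing materially and would blur comparisons between scans.

## Shared autozygosity and variant filtration

Homozygous carriers of a recessive haplotype descend from a common founder
segment, so around the associated window they are homozygous for identical
alleles over a much longer stretch than the window itself.
`shared_segment()` extends from the seed window marker by marker in both
directions while every carrier is homozygous and all carriers agree,
reporting the outermost conforming markers (the bounds could also be taken
halfway to the first violating marker; outermost-conforming is the
conservative, reproducible choice). Missing genotypes conform by default
(imputed panels are complete; sequence-derived panels may not be), with a
`"break"` option. The segment is maximal by construction and can only
shrink as carriers are added.

Candidate causal variants inside the associated region are filtered by
group-wise alternate-allele frequency: ≥ 0.8 in homozygous carriers,
within [0.4, 0.6] in heterozygous carriers, ≤ 0.05 in non-carriers, all
bounds inclusive (the natural reading of "between"; uniform inclusivity
keeps the rule monotone in its thresholds). Frequencies pool alleles
across each group rather than averaging per-sample frequencies — with a
handful of sequenced homozygotes, one under-called heterozygous genotype
would otherwise veto a true variant; pooling tolerates occasional
sequencing errors, genotype under-calling at low coverage, and misassigned
haplotype statuses. A group with no called alleles fails the rule closed.
Multi-allelic records are tested per alternate allele; symbolic
structural-variant records pass through the same rule. Consequence strings
(synonymous/missense/…) are read from existing `ANN`/`CSQ` annotation when
present, never computed.

## Cryptic splice-donor analysis

A synonymous exonic variant can still damage a protein by creating a
splice donor inside the exon. `find_donor_gain()` enumerates every exonic
GT dinucleotide whose −3..+6 context contains the variant, scores the
9-mer context under the reference and alternate alleles with a packaged
vertebrate donor position-weight matrix (log2 odds against a uniform
background; the matrix consensus is CAG|GTAAGT), and reports sites where
the alternate allele reaches the score threshold (default 0 bits) and
strictly exceeds the reference score — a gain, not a pre-existing site.
The score is a detection device, not a calibrated splicing-efficiency
prediction; the default threshold deliberately errs permissive because the
gain condition (alt > ref at the variant) is the discriminating part.
Using a cryptic donor at position $g$ truncates the exon at $g - 1$;
truncation length modulo 3 decides in-frame versus frameshift, and for
in-frame truncations `protein_deletion()` translates the full and
truncated coding sequences and reports the residues after the longest
common prefix, whose count is exactly truncation/3. Minus-strand genes are
reverse-complemented at ingest and positions mapped back to the genome.

`tally_junctions()` counts junction support in spliced alignments: a read
supports a junction when consecutive aligned reference blocks (CIGAR split
on N) end exactly at the donor and start exactly at the acceptor with at
least 6 aligned bases on each side. Exact block-edge matching with a
6-base overhang is strict, but junction-spanning evidence with smaller
overhangs is unreliable in practice and fuzzier matching would need an
error model the data cannot support. Reads spanning the wild-type junction
that support neither isoform are counted as unassigned, so wt + mt +
unassigned equals the junction-overlapping read count.

## The synthetic cohort: what it emulates, and what it does not

All inputs can be generated under a single seeded configuration
(`sim_config()`), whose defaults are the study conditions the package is
designed around:

* **Cohort and panel**: 800 bulls; three chromosomes of 900/450/450 SNPs
  at ~4 kb mean spacing (the QTL chromosome is long enough to carry the
  autozygosity span). Haplotypes are mosaics over a pool of 4 founder
  haplotypes with a per-marker switch probability of 0.01; founder alleles
  are drawn per SNP at frequencies uniform on (0.05, 0.95). The pool size
  and switch rate jointly set the local linkage disequilibrium and the
  number of recessive-eligible haplotype tests per scan (~450 at the
  defaults); real LD decay is not matched to any particular population —
  the copying model is a stand-in that provides multi-SNP sharing, which
  is all the scan requires.
* **The QTL**: carrier haplotypes (binomially sampled at frequency 0.24)
  carry founder 1's alleles across a 595-marker span (~2.4 Mb) with a
  unique 50-SNP core string in the designated window. The unique core
  makes the window the single strongest recessive signal — at off-core
  span windows, background haplotypes that match founder 1 contribute
  extra, unaffected homozygotes that dilute the contrast — while all
  homozygous carriers still share the full span as a run of identical
  homozygosity. One mechanism thus reproduces both the mapping signal and
  the fine-mapping segment.
* **Records**: per-record trait values follow the same animal model the
  REML module fits: status mean + pedigree-transmitted genetic effect +
  permanent environment + collector + season + age + residual, with
  h² = 0.25 and repeatability 0.43 by default and trait SDs specified at
  the level of per-bull averages (the scale on which cohort tables are
  reported); the generator back-computes the record-level variance from
  the expected records per bull. Homozygote means are shifted —
  motility 86.37 → 82.77 (−1.6 SD), anomaly scores +2 to +2.1 SD, sperm
  per straw +1.5 SD — and heterozygotes equal non-carriers, which is what
  "recessive" means here. Clean records are generated clear of every QC
  boundary (motility at least 70, volume above 1.05 ml, straw counts
  clipped into 15–25) so that the attrition log equals the deliberately
  injected violations exactly; the cost is mild truncation of the trait
  distributions, irrelevant at the effect sizes involved. Real data
  violate QC rules for many correlated reasons the generator does not
  model.
* **Inseminations, candidate region, junction reads**: Bernoulli non-return
  outcomes with month/parity/price/breed/technician/herd effects and a
  configurable per-bull fertility shift; a candidate-region VCF with an
  exact, INFO-annotated number of rule-compatible variants; spliced SAM
  reads with exact junction counts. `simulate_splice_gene()` constructs a
  three-exon gene whose middle exon reproduces the cryptic-donor geometry:
  a C>T eight bases from the natural donor creates a GT nine bases
  upstream of the exon end, the upstream coding sequence spans exactly 413
  codons, so the in-frame truncation deletes residues 414–416.

Passing tests on this cohort demonstrate that the estimators recover known
truth under the model they assume — unbiased variance components, correct
mapping and conditioning behaviour, exact filtration and splice geometry.
They do not demonstrate robustness to features the generator omits:
genotyping and phasing error, population admixture beyond what PCs absorb,
non-normal trait distributions, ascertainment of the recorded ejaculates,
or LD structure of any real breed.

## Problem sizes and reproducibility

The simulation-based checks run at fixed, deliberately modest sizes: null
calibration on a 6 × 900-SNP panel of 800 bulls (~1,400 recessive tests);
mapping power over 20 independent cohorts at the default design;
REML recovery at 800 bulls × 20 records per seed (10 seeds in the test
suite, 5 in the acceptance script), where the mean estimate is required to
sit within two empirical standard errors of the simulated truth. Every
generator call takes an explicit seed and identical configurations yield
byte-identical outputs; the analysis stages draw no random numbers at all,
so pipeline reports replay exactly.

## Known limitations

* Single-trait REML only; no multi-trait or genomic-relationship variance
  components, and no analytical standard errors.
* The scan is fixed-effects OLS with PC adjustment, not a mixed-model
  association; with strong cryptic relatedness lambda will exceed 1 and
  the Bonferroni control is approximate.
* Haplotype identity is exact string match: genotyping errors fragment
  haplotypes, which real-data applications must address upstream
  (imputation/phasing quality).
* The donor-site matrix is a generic vertebrate model; organism-specific
  splice-site usage, branch points and exonic splicing enhancers are out
  of scope.
* `estimate_fertility()` is a desk-scale linear probability model, not a
  national multi-trait genetic evaluation; its indices are comparable
  within the cohort analysed only.
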