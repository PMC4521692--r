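---
title: "Screening for differentially methylated CpG sites between maternal blood and chorionic villus DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for differentially methylated CpG sites between maternal blood and chorionic villus DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcscreen)
```

## The screening problem

Cell-free fetal DNA (cffDNA) circulates in maternal plasma against a large
background of maternal DNA. CpG sites that are consistently methylated in
one compartment and unmethylated in the other can serve as fetal-specific
markers: if the maternal fraction is unmethylated at a site that overlaps
the recognition sequence of a methylation-sensitive restriction enzyme
(MSRE), digestion removes the maternal signal while the methylated fetal
copies survive and can be quantified by PCR. Counting such markers on a
chromosome of interest against markers on a reference chromosome gives a
route to non-invasive aneuploidy testing.

`dmcscreen` implements the genome-wide discovery side of this idea as a
five-stage screen over a 450K-style beta-value matrix comparing maternal
blood cell DNA (MBC, n = 10) with chorionic villus samples (CVS, n = 12,
a proxy for the fetal/placental compartment):

1. **Complete cases** — probes missing a beta-value for any primary sample
   are removed.
2. **DMC stage** — per CpG, a two-sided Wilcoxon rank-sum test between the
   groups; Benjamini–Hochberg adjustment across all complete probes; keep
   probes with FDR < 0.05 **and** |Δβ| > 0.2, where Δβ is the absolute
   difference of group means.
3. **Strict stage** — keep probes whose group means are extreme: MBC mean
   β < 0.25 and CVS mean β > 0.75, or vice versa; this fixes the marker's
   direction.
4. **MSRE stage** — keep probes whose interrogated CpG is *spanned* by a
   recognition-site occurrence of at least one configured MSRE.
5. **Consistency stage** — keep probes where at least 10 MBC samples and
   at least 10 CVS samples individually clear the same strict cut-offs.

All comparisons are strict inequalities, matching the published operators
(`FDR < 0.05`, `Δβ > 0.2`, `β < 0.25`, `β > 0.75`); boundary values fail.

## Statistical choices

**Rank-sum, not signed-rank.** The groups are unpaired and of unequal size
(10 vs 12), so the implemented test is the Wilcoxon–Mann–Whitney rank-sum
test. Ties are handled by midranks. Two p-value modes are provided:
an exact mode that enumerates all assignments of the observed midranks to
the groups (valid with ties, used automatically for total n ≤ 12) and a
normal approximation with tie-corrected variance. No continuity
correction is applied by default (`correct = TRUE` enables it); at
n = 10 vs 12 the uncorrected approximation is almost exactly calibrated
(null rejection rate 0.0503 at α = 0.05), whereas the continuity-corrected
version is conservative (0.043).

**FDR across all probes jointly.** BH adjustment is computed once over
every complete probe, before any other filter, so the testing stage sees
the full multiplicity burden.

**Δβ as an absolute difference.** The screen treats hyper- and
hypomethylated markers symmetrically; direction is recorded separately at
the strict stage. Δβ, p-values and the final probe set are invariant
under relabelling MBC ↔ CVS (directions flip).

## MSRE overlap semantics

A recognition-site occurrence counts only if its span covers *both* bases
of the interrogated CpG: methylation of that cytosine must be able to
block the enzyme for the assay logic to work, which a site touching only
one base would not guarantee. Matching is IUPAC-aware and scans both
strands (the reverse complement of the pattern is searched in forward
coordinates; palindromic sites are reported once, on `+`). When several
occurrences of one enzyme overlap the CpG they are numbered left to right
and labelled `Enzyme.1`, `Enzyme.2`, … in reports; a single occurrence
keeps the bare name. We read the `.1`/`.2` suffixes that appear in
published candidate tables as exactly such occurrence indices; this is a
documented assumption, as is the 61 nt flank length (the screen scans
whatever flank the manifest provides, centred on the CpG).

The default enzyme table holds the nine CpG-cutting MSREs that appear in
the bundled candidate set (AciI CCGC, HhaI GCGC, HpyCH4IV ACGT, HpaII
CCGG, AatII GACGTC, BstUI CGCG, ClaI ATCGAT, EagI CGGCCG, AgeI ACCGGT).
The table is configuration, not code: a larger screening panel (e.g. a
16-enzyme set) is supplied as a two-column TSV via `read_enzymes()`.

## Coordinate and format conventions

* Probe positions are 1-based coordinates of the CpG's C on the forward
  strand (array-manifest convention).
* Genomic regions are 0-based half-open `[start, end)` BED intervals
  (the bundled micro-deletion syndrome table starts several regions at 0).
  A probe at 1-based position *p* falls in `[s, e)` iff `s ≤ p − 1 < e`.
* In manifest files the CpG is addressed by a 0-based `cpg_offset` into
  the flank; in memory the package uses the 1-based `cpg_site`.
* Missing beta cells read as `NA`, `NaN` or empty; written as `NA`.
* Two result tables are written: a report rounded to 2 decimals in the
  publication column order (`probe_id, chromosome, gene, cvs_mean,
  mbc_mean, delta, refseq, msre`) and a full-precision table. The
  rounding is lossy by design; printed deltas can differ by 0.01 from
  the difference of the printed means, so checks against printed values
  target rows where the rounding is self-consistent.

## The synthetic data generator

Real screening data cannot ship with the package, so `simulate_dataset()`
generates datasets with the statistical structure the analysis assumes.
Its defaults *are* the study conditions: 10 MBC vs 12 CVS primary
samples, 5,000 probes of which 50 are planted fully-differential markers,
65 SNP control probes, 4 technical replicate pairs, and a per-probe
missingness rate of 0.0285 (the incomplete-probe rate implied by a
485,777 → 471,956 complete-case filter).

* **Background probes** draw every sample from Beta(5, 5): intermediate,
  non-differential methylation.
* **Planted markers** draw the hypomethylated group from Beta(1, 30)
  (mean 0.032) and the hypermethylated group from Beta(30, 1), with the
  direction split evenly by default. These shapes were chosen so that a
  planted n = 10/12 probe clears the *per-sample* strict thresholds
  (all 10 MBC below 0.25, ≥ 10 of 12 CVS above 0.75) with probability
  ≈ 0.998: under the softer Beta(1, 15) the chance that a single sample
  exceeds 0.25 is 1 − 0.75¹⁵ ≈ 0.013, so all ten MBC samples pass only
  87% of the time — too leaky for a "fully differential" planted truth.
* **Missingness** is per probe: with probability 0.0285 a probe has one
  (occasionally more) primary-sample cell blanked uniformly at random,
  mirroring a filter that drops probes "incomplete in one or more
  samples". Replicate columns are kept complete; they are QC-only and
  excluded from the completeness check.
* **SNP control probes** get a per-individual genotype at {0, 0.5, 1}
  (probabilities ¼, ½, ¼) plus N(0, 0.05) measurement noise, clamped to
  [0, 1]. Replicate columns reuse the genotype of their source
  individual.
* **Technical replicates**: each pair consists of two fresh columns equal
  to the source column plus N(0, 0.01) noise, clamped. The two noise
  scales were calibrated (analytically, then by simulation) so that the
  Spearman correlation of SNP probes between duplicate columns falls in
  the 0.96–0.98 regime reported for well-behaved replicate arrays; the
  dominant term is the ratio of duplicate noise to per-probe measurement
  noise within genotype clusters.
* **Flanks** are uniform random A/C/G/T with the CG dinucleotide forced
  at the centre (length 61 by default). Planted probes flagged as MSRE
  carriers get a concrete realisation of a randomly chosen enzyme pattern
  written over the centre so that one of its CpGs coincides with the
  target CpG; planted probes without a site are regenerated by rejection
  until no configured enzyme matches anywhere on either strand.
* **Genomic placement** spreads probes uniformly over approximate
  autosome lengths, so chromosome counting and region assignment are
  exercised with realistic label diversity.

What the generator does **not** model: cellular heterogeneity of
chorionic villi (the CVS signal is drawn as a single methylation state,
not a trophoblast/mesenchyme mixture), Infinium type I/II probe chemistry
bias, spatial autocorrelation along the genome, batch effects, and raw
two-colour intensities (the pipeline starts from beta-values). Passing
recovery tests on synthetic data therefore demonstrates correctness of
the screening logic under its own assumptions, not performance on real
arrays.

**Recovery semantics.** Sensitivity in the recovery checks is computed
over *assessable* planted markers — those that survive the complete-case
filter. A planted probe with a blanked cell is removed by stage 1 by
design; counting it as a miss would measure the missingness rate, not
the funnel.

## Numerical and degenerate-input choices

* Exact rank-sum enumeration uses `combn` over midranks; the two-sided p
  is twice the smaller tail (including the observed statistic), capped at
  1. When all values in both groups are identical, p = 1.
* Midrank comparisons in the enumeration use a 1e-9 tolerance so floating
  midranks compare robustly.
* `heatmap_order()` is plain `hclust(dist(x), "complete")` on rows and
  columns independently — deterministic for a given input, ties broken by
  `hclust`'s lowest-index convention; no optimal leaf ordering
  (reproducibility over aesthetics). Matrices with fewer than 2 rows or
  columns return the identity order.
* `spearman_rho()` errors on constant input rather than returning `NA`.
* Empty inputs propagate: an empty configuration yields empty outputs,
  an empty region file an empty region set, an empty track a header-only
  file.
* Seeds: `simulate_dataset()` is fully determined by `config$seed`;
  identical seeds give bit-identical datasets.

## Problem sizes used by the tests

The test-suite and the acceptance script run at desk scale, chosen to
finish in minutes while keeping every statistical check well-powered:
recovery uses five runs of the default 5,000-probe study (50 planted
markers each), type-I calibration uses 2,000 null probes, the
MSRE-vs-oracle comparison uses 1,000 random 61-mers against the full
default enzyme panel, and the exhaustive rank-sum check covers every
group-size split with total n ≤ 10. The published full-array survivor
counts (471,956 → 144,273 → 5,956 → 2,184 → 958) require the original
array data and manifest, which are not redistributable here; the
structural content of that funnel — stage order, strict operators,
nesting and monotone counts — is what the tests pin down.

## Known limitations

* The screen operates on beta-values as given; no normalisation, batch
  correction, or probe-type adjustment is performed or planned.
* Region acceptance is structural (interval arithmetic), not numeric:
  published per-region DMC counts depend on the array manifest.
* The MSRE stage is a pure sequence overlap test; partial methylation
  sensitivity, star activity and isoschizomer equivalence are out of
  scope.
* Exact rank-sum enumeration is limited to small groups (total n ≤ 20);
  larger designs use the tie-corrected normal approximation.
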