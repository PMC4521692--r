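# dmcscreen

Genome-wide screening of differentially methylated CpG sites (DMCs)
between maternal blood cell DNA (MBC) and chorionic villus sample DNA
(CVS), aimed at discovering fetal-specific epigenetic markers for
non-invasive prenatal testing. Cell-free fetal DNA in maternal plasma can
be distinguished from the maternal background at CpG sites where the two
compartments are methylated in opposite states; if such a site overlaps a
methylation-sensitive restriction enzyme (MSRE) recognition sequence, the
unmethylated fraction can be digested away and the surviving fraction
quantified by PCR. `dmcscreen` is for epigenomics researchers who want a
tested, reusable implementation of this marker-discovery funnel, complete
with a synthetic 450K-style data generator so every stage can be
exercised and validated without downloading array data.

## The method

Given a probes × samples matrix of beta-values $\beta \in [0,1]$
(fraction methylated), with $n_\mathrm{MBC} = 10$ and
$n_\mathrm{CVS} = 12$ primary samples, candidates pass five nested
stages:

1. **Complete cases** — drop probes with a missing $\beta$ in any
   primary sample.
2. **DMC test** — per CpG, two-sided Wilcoxon rank-sum test between the
   groups (midranks for ties; exact enumeration for small n, otherwise a
   tie-corrected normal approximation); Benjamini–Hochberg FDR over all
   complete probes; keep `FDR < 0.05` and
   $\Delta\beta = |\bar\beta_\mathrm{MBC} - \bar\beta_\mathrm{CVS}| > 0.2$.
3. **Strict thresholds** — keep probes with
   $\bar\beta_\mathrm{MBC} < 0.25$ and $\bar\beta_\mathrm{CVS} > 0.75$,
   or vice versa (this assigns the marker's direction).
4. **MSRE overlap** — keep probes whose interrogated CpG dinucleotide is
   fully spanned by a recognition-site occurrence of at least one
   configured MSRE (IUPAC-aware, both strands).
5. **Consistency** — keep probes where at least 10 MBC and at least 10
   CVS samples individually clear the same strict cut-offs.

All inequalities are strict. Survivor counts are recorded after each
stage; per-probe records carry nested stage flags, direction, and MSRE
hit labels (`BstUI.1`, `BstUI.2`, … when several occurrences of one
enzyme overlap the CpG). Final candidates can be counted per chromosome,
mapped to micro-deletion syndrome regions (0-based half-open intervals),
and exported as an ideogram data track coloured by direction. Replicate
quality control uses the Spearman correlation of SNP control probes
between technical-replicate arrays; heatmap layouts use complete-linkage
clustering on Euclidean distances.

## Worked example

```r
library(dmcscreen)

# a synthetic study under the default conditions: 5,000 probes,
# 50 planted fully differential markers, 10 MBC vs 12 CVS samples
sim <- simulate_dataset(simulation_config(seed = 1))
res <- run_funnel(sim$beta, sim$manifest)
res
#> Five-stage DMC screening funnel
#>   probes analysed            5000
#>   complete cases             4849
#>   DMCs (FDR & delta)           47
#>   strict hypo/hyper            47
#>   MSRE site over CpG           47
#>   per-sample consistent        47

planted_recovery(res, sim$truth)[c("sensitivity", "fdp")]
#> $sensitivity
#> [1] 1
#> $fdp
#> [1] 0

replicate_concordance(sim$beta, sim$manifest$probe_id[sim$manifest$is_snp])
#>   sample_a sample_b   rho
#> 1 MBC01.r1 MBC01.r2 0.978
#> 2 CVS01.r1 CVS01.r2 0.986
#> 3 MBC02.r1 MBC02.r2 0.990
#> 4 CVS02.r1 CVS02.r2 0.979
```

The funnel finds 47 of the 50 planted markers — the other 3 were removed
by the complete-case stage (the generator blanks cells at the study's
2.85% per-probe missingness rate), and every assessable marker is
recovered with no false positives. Replicate correlations sit in the
0.96–0.99 band expected of well-behaved arrays.

The package also ships a 44-marker candidate set on the trisomy
chromosomes, useful as a worked fixture:

```r
count_by_chromosome(candidate_markers())
#> 13 18 21
#> 26  6 12
```

A command-line wrapper (installed under `exec/dmcscreen`) exposes the
same pipeline as subcommands `simulate`, `run`, `msre-annotate`,
`regions`, `qc`, `report`; thresholds and simulation settings can be
given as YAML (`--thresholds`, `--config`), and every `run` writes
`funnel_counts.tsv`, full-precision and rounded candidate tables, and a
`run_manifest.json` with input digests and parameters.

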