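# phosflow

Differential phospho-signaling analysis for multiplexed (isobaric-label)
phosphoproteomics of a three-condition design: unstimulated **control**,
**acute** receptor stimulation (minutes of exogenous ligand) and **chronic**
stimulation (days of sustained, autocrine ligand exposure). The package is
aimed at proteomics and systems-biology analysts who have peptide-level
signal-to-noise tables in hand and want a reproducible route from reporter
intensities to kinase-substrate networks and group-level significance
calls — plus a synthetic-data generator with planted effects so that every
stage can be validated without access to raw MS data.

## What it computes

For each analyte (protein or phosphopeptide isoform) with per-sample
signal-to-noise values *v₁…vₖ*, the **relative abundance** is
*rᵢ = 100·vᵢ/Σⱼvⱼ*. Phosphosites are kept when their localization score
(AScore) exceeds 13 (P < 0.05 for correct site assignment, strict
inequality). Phosphopeptide relative abundances are divided sample-wise by
the parent protein's relative abundance, replicate channels are collapsed
by the mean, and two contrasts are formed per analyte:

    log2FC_acute   = log2(acute / control)
    log2FC_chronic = log2(chronic / control)
    differential   = log2FC_chronic − log2FC_acute  = log2(chronic / acute)

Sites are merged with a phosphorylation-site reference database
(PhosphoSitePlus column dialect) by a three-tier, first-hit-wins policy —
(1) accession+residue+position, same organism; (2) case-folded gene
symbol+residue+position, same organism; (3) exact ±7 flanking window, any
organism — and annotated with kinases from a kinase-substrate table.
Functional and kinase-substrate groups are then scanned with two-sample
Kolmogorov–Smirnov tests (group vs complement,
D = supₜ|ECDF_group(t) − ECDF_rest(t)|, asymptotic Kolmogorov p at
effective size n₁n₂/(n₁+n₂) or permutation p), Benjamini–Hochberg adjusted.
Outlier events (|differential| > 1) feed an upper-tail hypergeometric
over-representation test of their proteins. CellDesigner-flavored SBML
signaling maps can be parsed, inventoried and audited for concordance with
the reference, and the kinase→substrate-site network is exported for
Cytoscape (SIF, GraphML, attribute tables).

## Worked example

Simulate a small study in which the "RNA binding and translation" group is
repressed by 1.5 log2 units under chronic relative to acute stimulation,
then run the full pipeline:

```r
library(phosflow)

cfg <- simulation_config(seed = 42, n_proteins = 400, n_phospho_proteins = 180,
                         noise_sd_log2 = 0.3, n_kinases = 8,
                         frac_matched_with_kinase = 0.5,
                         group_effects = c("RNA binding and translation" = -1.5))
dir <- tempfile("study_")
sim <- simulate_dataset(cfg, dir)
res <- run_pipeline(analysis_config(
  protein_quant    = sim$paths[["proteins"]],
  phospho_quant    = sim$paths[["phospho"]],
  phospho_sites    = sim$paths[["sites"]],
  reference_sites  = sim$paths[["reference_sites"]],
  kinase_substrate = sim$paths[["kinase_substrate"]],
  groups           = sim$paths[["groups"]],
  out_dir = file.path(dir, "out"), seed = 42))

print(res$match_report)
#> match report: 451/500 site(s) matched (90.2%), 49 unmatched
#>   by tier: accession=438, gene=0, window=13

head(res$group_scan, 3)
#>                          group n_in n_out         D      p_value      q_value
#> 1  RNA binding and translation   18   482 1.0000000 1.695408e-15 1.525867e-14
#> 2       small GTPase signaling   14   486 0.3350970 9.413345e-02 4.236005e-01
#> 3 transcription and cell cycle    8   492 0.3567073 2.691252e-01 6.635810e-01

round(res$outliers$inside_fraction, 3)
#> [1] 0.966

head(res$enrichment[, c("term", "k", "K", "p_value", "q_value")], 2)
#>                          term k K      p_value      q_value
#> 1 RNA binding and translation 7 7 1.451759e-12 1.451759e-11
#> 2           calcium signaling 0 7 1.000000e+00 1.000000e+00

print(res$network)
#> kinase-substrate network: 217 node(s) (8 kinase, 209 site), 260 edge(s)
```

Reading the output: 90.2% of localized sites were found in the reference
(438 by exact accession key, 13 rescued by flanking-window matching across
accession drift); the KS scan ranks the planted "RNA binding and
translation" group first with D = 1 (its 18 site differentials sit entirely
below everything else) at q ≈ 10⁻¹⁴; 96.6% of phosphopeptides stay within
±1 log2 unit between chronic and acute stimulation, and the outlier
proteins are over-represented in the planted term (7 of 7 outlier-bearing
proteins, hypergeometric q ≈ 10⁻¹¹). All stage outputs — site
differentials, match report, scan tables, SIF/GraphML network exports and a
JSON manifest with input checksums and per-stage counts — are written under
`out_dir`.

The methods vignette
(`vignettes/differential-phospho-signaling.Rmd`) documents the model, the
matching policy, the generator's assumptions and the package's numerical
choices.

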