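---
title: "Differential phospho-signaling analysis with phosflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential phospho-signaling analysis with phosflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosflow)
```

## The analysis problem

Receptor tyrosine kinases are usually studied under acute stimulation — a
bolus of ligand for minutes — although disease-relevant signaling is mostly
chronic: sustained, autocrine ligand exposure over days. Multiplexed
(isobaric-label) phosphoproteomics can quantify thousands of phosphopeptide
isoforms across an unstimulated control, an acutely stimulated and a
chronically stimulated condition in a single experiment, but turning
reporter-ion signal-to-noise values into biological statements requires a
chain of normalization, annotation and testing steps. phosflow implements
that chain as a reusable, fully testable pipeline:

1. **Relative abundance.** Each analyte's per-sample signal-to-noise value
   is divided by the analyte's row total and scaled to 100
   (`relative_abundance()`). Rows summing to zero carry no information and
   are dropped with a logged count.
2. **Localization gate.** Phosphosites whose localization confidence
   (AScore) is at or below 13 — the score corresponding to P = 0.05 for a
   correct site assignment — are removed (`localization_filter()`). The
   inequality is strict: a score of exactly 13 is filtered.
3. **Protein normalization.** Phosphopeptide relative abundances are
   divided, sample by sample, by the relative abundance of the parent
   protein (`normalize_to_protein()`), so protein-level expression changes
   do not masquerade as phosphorylation changes. Peptides whose protein was
   not quantified are carried forward unnormalized and flagged.
4. **Contrasts.** Replicate channels are collapsed by the arithmetic mean
   (`condition_collapse()`), and per-analyte log2 fold changes are computed
   against control for both stimulation regimes
   (`compute_differentials()`). The central quantity is the
   *chronic-vs-acute differential*,
   `log2(chronic/acute) = log2FC_chronic − log2FC_acute`. No pseudocounts
   are used: any missing or non-positive condition value yields missing
   contrasts with a logged reason, because a fabricated fold change is
   worse than an absent one.
5. **Database merge.** Measured sites are matched against a
   phosphorylation-site reference in the PhosphoSitePlus column dialect
   with a three-tier, first-hit-wins policy (`match_sites()`), then
   annotated with kinases from a kinase–substrate table
   (`annotate_kinases()`).
6. **Group statistics.** Functional groups (from a curated signaling map or
   any assignment table) and kinase–substrate groups are scanned with
   two-sample Kolmogorov–Smirnov tests of the group's differentials against
   the complement (`group_ks_scan()`, `kinase_ks_scan()`), with
   Benjamini–Hochberg correction within each scan. Outlier phospho-events
   (|differential| strictly greater than 1 log2 unit) feed a hypergeometric
   over-representation test of their proteins against the quantified
   background (`select_outliers()`, `hypergeometric_enrichment()`).
7. **Map audit and network export.** CellDesigner-flavored SBML signaling
   maps are parsed and inventoried (`parse_celldesigner_sbml()`,
   `map_summary()`), their annotated phosphosites audited for concordance
   with the reference database (`map_concordance()`), and the
   kinase→substrate-site network is exported for Cytoscape as SIF, GraphML
   and attribute tables (`build_network()`, `export_sif()`,
   `export_graphml()`).

`run_pipeline()` sequences stages 1–7 from tab-separated inputs and records
a JSON manifest with input checksums, per-stage counts and the seed. The
package's interface is deliberately function-first: a declarative
`analysis_config()` plus `run_pipeline()` replaces a subcommand shell tool,
which keeps every stage individually scriptable and testable from R.

## The tiered matching policy

Reference databases and search engines drift apart in accession versions,
isoform suffixes and organism coverage, so an exact primary-key join
undercounts true overlap. `match_sites()` therefore tries, per measured
site and in order, taking the first hit:

| tier | key | organism |
|------|-----------------------------------------------|-----------|
| 1    | accession + residue + position                | same      |
| 2    | case-folded gene symbol + residue + position  | same      |
| 3    | exact 15-mer flanking window                  | any       |

Accessions are normalized before tier 1 (version suffixes such as `.1` and
isoform suffixes such as `-2` are stripped, with a logged count). Tier 3 is
the only cross-species tier by design: sequence windows are the only key
that is meaningful across orthologs, and restricting gene-symbol matches to
the same organism keeps the use of human/rat curation conservative.
Duplicate reference keys within a tier resolve to the first occurrence and
are logged. Every match records its winning tier, so alternative policies
can be compared by disabling tiers (`match_policy()`); the suite verifies
that the tiered matcher is identical to a brute-force all-pairs matcher and
that disabling tiers never increases the match count.

## The Kolmogorov–Smirnov scan

For samples x and y the statistic is
D = sup over the pooled points of |ECDF_x − ECDF_y|, with right-continuous
ECDFs evaluated at the pooled sorted unique values — this removes any
ambiguity for tied values. The asymptotic p-value uses the Kolmogorov
distribution at `sqrt(ne) * D` with effective size ne = |x||y|/(|x|+|y|);
a permutation mode with p = (1 + #{D_perm ≥ D_obs})/(1 + n_perm) is
available for small groups and is validated against exhaustive enumeration
of all splits for pooled sizes up to 10.

"Significance among groups" is deliberately implemented as a
group-vs-complement scan: each functional group's differentials are tested
against all other sites' differentials, and p-values are BH-adjusted across
the scan, which yields exactly the kind of per-group ranking ("group X shows
the most significantly different distribution") that the analysis is meant
to produce. An all-pairs mode (`comparison = "pairwise"`) is available
behind a flag for users who want group-against-group contrasts. Groups
below `min_n` (default 5) sites are skipped and logged; the `unclassified`
pool is never tested as a foreground group but always contributes to
complements.

The over-representation stage is a generic annotation-table-driven
hypergeometric test (upper tail, BH-adjusted), so no external enrichment
service or ontology release is required; any GMT file — including real GO
annotations — can serve as the term table. Note that hypergeometric
p-values are discrete and therefore *super-uniform* under the null
(P(p ≤ α) ≤ α): rejection rates are controlled at every level, but the
p-value histogram is not exactly flat.

## What the synthetic generator emulates

Because raw data of this kind are typically available on request only, the
package ships a first-class generator (`simulation_config()`,
`simulate_dataset()`) whose defaults emulate a deep three-condition TMT
study, and whose ground-truth record makes every downstream stage testable:

* ~7,500 quantified proteins with log-normal baselines
  (`baseline_log_abundance_sd = 2` in log2 units) and per-condition protein
  effects (SD 0.2 log2 units) that the protein-normalization stage must
  remove;
* ~2,045 phosphoproteins carrying 1–10 sites each; the default
  site-count distribution places 73.6% of proteins at 1–3 sites with mean
  ~3.1, and site positions are laid out sequentially within proteins whose
  length grows with their site count;
* phosphoacceptor composition of 80.0% Ser, 16.6% Thr, 3.4% Tyr;
* a minority (10%) of sites quantified on shared multi-site peptide
  isoforms (at most 3 sites per isoform), exercising
  `explode_multisite()`;
* localization scores drawn so 10% fall at or below the AScore gate, so
  the localized analysis set numbers ~5,770 sites;
* per-isoform acute effects (SD 0.5 log2 units, symmetric, so ~50% of
  phospho-events rise acutely) and planted group-level chronic-vs-acute
  shifts `group_effects` (all zero by default — the null study);
* channel noise `noise_sd_log2 = 0.57`, chosen once so that under the null
  ~96.5% of phosphopeptide differentials fall within ±1 log2 unit after
  replicate collapse — the regime in which a ±1 outlier cutoff separates a
  few-percent tail;
* a reference database containing 90.3% of the measured sites (a 2%
  sub-fraction reachable only through window matching, mimicking
  cross-species curation, and 5% of covered accessions carrying version
  suffixes), plus 5,000 decoy sites; kinase annotations on 346/5209 of the
  covered sites drawn from 150 kinase labels.

The three-condition, three-replicate channel layout is an assumption — the
generator simulates replicate channels per condition and collapses them by
the mean, which exercises the collapse stage and provides within-condition
variance; the run manifest flags this assumption. What the generator does
**not** model: MS2/MS3 interference, isotopic impurity, missing-value
mechanisms of data-dependent acquisition, peptide-to-protein inference
ambiguity, and real flanking sequence composition (windows are random
15-mers with the phosphoacceptor centered, lowercase). Passing tests
therefore demonstrate the correctness of the pipeline's arithmetic,
matching, calibration and bookkeeping — not robustness to every artifact of
real spectra.

## Numerical and design choices

* **Strict thresholds.** Both the localization gate (score > 13) and the
  outlier cutoff (|differential| > 1) are strict inequalities; boundary
  values are excluded.
* **Zeros.** No pseudocounts anywhere. Zero-sum analytes are dropped at
  relative-abundance time; zero protein abundance in a sample makes that
  normalized cell missing; non-positive collapsed condition values make all
  of an analyte's contrasts missing. Each path is logged with counts.
* **Differential on normalized values.** The chronic-vs-acute differential
  is computed on protein-normalized values, in the same stream as the
  vs-control contrasts, and equals their difference exactly (an algebraic
  identity the tests assert).
* **Multi-site isoforms.** Quantitation belongs to the peptide isoform;
  after explosion each constituent site inherits the isoform's values,
  matching the MS reality that the isoform, not the site, is quantified.
* **Map parsing.** Only reaction-level PMIDs count toward the publication
  tally (species notes may cite background literature); species are
  deduplicated across maps by (name, compartment); positionless
  phosphorylated residues are inventoried but excluded from concordance
  denominators and reported separately. Map concordance matches by
  case-folded protein label because curated maps name proteins by label,
  not accession; an optional alias table enables accession-level matching.
* **Canonical exports.** Network exports sort nodes and edges, so identical
  networks give byte-identical files; missing edge attributes are empty
  fields in TSV and omitted keys in GraphML.
* **Determinism.** Every generator consumes an explicit seed and each
  generator stage derives its stream from it, so identical configurations
  reproduce all outputs byte for byte.

## Problem sizes used in validation

The shipped suite validates oracle equivalence on 50 random matching
instances (n·m ≤ 10,000), permutation KS tests against exhaustive
enumeration at pooled sizes ≤ 10, null calibration of the group scan on 100
simulations with groups of 40 against a nominal 5% level, and recovery of a
planted −1.5 log2 group shift (≈50 sites per group, channel noise 0.3) in
at least 90% of 50 seeds. Printed-scale checks run the summary operations
on a 5,767-site study and a 648-species/481-reaction map fixture carrying
189 annotated phosphosites (149 Ser/Thr, 40 Tyr) on 56 proteins.

## Known limitations

* The matching policy is a declared reconstruction of common practice;
  sequence-alignment-based site remapping between isoforms is out of scope.
* The KS scan tests distribution equality, not effect size or direction;
  a group can be significant through variance changes alone.
* The hypergeometric stage performs no ontology graph propagation.
* The SBML reader targets Level 2 documents with the CellDesigner
  extension namespace; other levels are parsed best-effort with a warning.
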