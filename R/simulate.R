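## Synthetic-data generator: emulates a three-condition (control / acute /
## chronic) isobaric-label phosphoproteomics study with planted group-level
## chronic-vs-acute shifts, a reference site database overlapping the measured
## sites at a controlled fraction, kinase annotations on a controlled subset,
## and a ground-truth record for every emitted site.

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

default_group_labels <- function() {
  c("RNA binding and translation", "MAPK cascade", "mTOR signaling",
    "PI3K-AKT signaling", "cytoskeleton dynamics",
    "transcription and cell cycle", "endocytosis and trafficking",
    "calcium signaling", "small GTPase signaling")
}

default_kinase_names <- function(n) {
  named <- c("MTOR", "RPS6KA1", "RPS6KA3", "RPS6KB1", "MAPK1", "MAPK3",
             "MAPK8", "MAPK9", "MAPK10", "MAPK14", "AKT1", "AKT2", "PRKCA",
             "PRKCB", "CSNK2A1", "CDK1", "CDK2", "GSK3B", "SRC", "FYN")
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("KIN%03d", seq.int(length(named) + 1L, n)))
}

#' Configuration for the synthetic phosphoproteomics study
#'
#' Defaults emulate the scale and structure of a deep TMT phosphoproteomics
#' experiment on receptor-stimulated cells: ~7,500 quantified proteins, a
#' phosphoproteome of ~5,800 localized sites on ~1,850 proteins (most carrying
#' 1-3 sites each), three conditions (unstimulated control, acute stimulation,
#' chronic stimulation) with three replicate channels each, a reference site
#' database covering 90.3% of measured sites, and kinase annotations on a
#' small fraction of matched sites.
#'
#' @param seed integer RNG seed; identical config + seed reproduce all
#'   outputs byte-identically.
#' @param n_proteins number of quantified proteins.
#' @param n_phospho_proteins number of proteins carrying phosphosites
#'   (must not exceed `n_proteins`).
#' @param sites_per_protein_probs probabilities for 1..10 sites per protein.
#'   The default places 73.6% of proteins at 1-3 sites with mean ~3.1,
#'   so ~2,045 phosphoproteins yield ~6,400 sites of which ~5,770 pass the
#'   localization gate at the default `frac_below_localization_threshold`.
#' @param n_replicates_per_condition replicate channels per condition.
#' @param conditions ordered condition labels; the contrasts assume
#'   `control`, `acute` and `chronic` are all present.
#' @param baseline_log_abundance_sd log2 SD of protein baseline abundance.
#' @param noise_sd_log2 log2 SD of per-channel multiplicative measurement
#'   noise (applied independently to protein and phosphopeptide channels).
#'   The default 0.57 calibrates the null chronic-vs-acute differential so
#'   ~96.5% of phosphopeptides fall within one log2 unit.
#' @param protein_effect_sd_log2 log2 SD of per-protein condition effects
#'   (protein abundance changes that phosphosite-to-protein normalization
#'   must remove).
#' @param acute_effect_sd_log2 log2 SD of per-peptide acute stimulation
#'   effects (symmetric, so ~50% of phospho-events increase acutely).
#' @param frac_multisite probability that a site is quantified on the same
#'   peptide isoform as the preceding site of its protein (multi-site
#'   isoforms carry at most 3 sites).
#' @param frac_below_localization_threshold fraction of sites whose
#'   localization score falls at or below the AScore gate of 13.
#' @param frac_sites_in_reference fraction of measured sites present in the
#'   reference phosphorylation-site database (default 0.903).
#' @param frac_window_only among reference-covered sites, fraction whose
#'   reference record carries a foreign accession and organism so that only
#'   flank-window matching can recover it.
#' @param frac_matched_with_kinase fraction of reference-covered sites that
#'   carry at least one kinase annotation (default 346/5209).
#' @param n_kinases number of distinct kinase labels.
#' @param n_decoy_reference_sites reference sites absent from the measured
#'   data.
#' @param group_labels functional-group names.
#' @param group_probs named probabilities over `c(group_labels,
#'   "unclassified")` for protein group membership; defaults to 70%
#'   unclassified with the rest spread evenly.
#' @param group_effects named log2 chronic-vs-acute shifts planted per group
#'   (defaults to all zero, the null study).
#' @param residue_probs probabilities of S/T/Y phosphoacceptors.
#' @param organism organism label attached to measured sites.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 7528L,
                              n_phospho_proteins = 2045L,
                              sites_per_protein_probs =
                                c(0.300, 0.250, 0.186, 0.040, 0.040,
                                  0.040, 0.040, 0.038, 0.033, 0.033),
                              n_replicates_per_condition = 3L,
                              conditions = c("control", "acute", "chronic"),
                              baseline_log_abundance_sd = 2,
                              noise_sd_log2 = 0.57,
                              protein_effect_sd_log2 = 0.2,
                              acute_effect_sd_log2 = 0.5,
                              frac_multisite = 0.10,
                              frac_below_localization_threshold = 0.10,
                              frac_sites_in_reference = 0.903,
                              frac_window_only = 0.02,
                              frac_matched_with_kinase = 346 / 5209,
                              n_kinases = 150L,
                              n_decoy_reference_sites = 5000L,
                              group_labels = default_group_labels(),
                              group_probs = NULL,
                              group_effects = NULL,
                              residue_probs = c(S = 0.800, T = 0.166, Y = 0.034),
                              organism = "mouse") {
  cfg <- list(
    seed = check_count(seed, "seed", minimum = 0L),
    n_proteins = check_count(n_proteins, "n_proteins"),
    n_phospho_proteins = check_count(n_phospho_proteins, "n_phospho_proteins"),
    sites_per_protein_probs = sites_per_protein_probs,
    n_replicates_per_condition =
      check_count(n_replicates_per_condition, "n_replicates_per_condition"),
    conditions = conditions,
    baseline_log_abundance_sd =
      check_positive(baseline_log_abundance_sd, "baseline_log_abundance_sd"),
    noise_sd_log2 = check_positive(noise_sd_log2, "noise_sd_log2"),
    protein_effect_sd_log2 =
      check_positive(protein_effect_sd_log2, "protein_effect_sd_log2"),
    acute_effect_sd_log2 =
      check_positive(acute_effect_sd_log2, "acute_effect_sd_log2"),
    frac_multisite = check_fraction(frac_multisite, "frac_multisite"),
    frac_below_localization_threshold =
      check_fraction(frac_below_localization_threshold,
                     "frac_below_localization_threshold"),
    frac_sites_in_reference =
      check_fraction(frac_sites_in_reference, "frac_sites_in_reference"),
    frac_window_only = check_fraction(frac_window_only, "frac_window_only"),
    frac_matched_with_kinase =
      check_fraction(frac_matched_with_kinase, "frac_matched_with_kinase"),
    n_kinases = check_count(n_kinases, "n_kinases"),
    n_decoy_reference_sites =
      check_count(n_decoy_reference_sites, "n_decoy_reference_sites",
                  minimum = 0L),
    group_labels = group_labels,
    residue_probs = residue_probs,
    organism = organism
  )
  if (!is.character(conditions) || length(conditions) < 2L ||
      anyDuplicated(conditions)) {
    stop_config("conditions", "must be >= 2 distinct labels")
  }
  if (!is.numeric(sites_per_protein_probs) ||
      length(sites_per_protein_probs) != 10L ||
      any(sites_per_protein_probs < 0) || sum(sites_per_protein_probs) <= 0) {
    stop_config("sites_per_protein_probs",
                "must be 10 non-negative weights for 1..10 sites")
  }
  cfg$sites_per_protein_probs <-
    sites_per_protein_probs / sum(sites_per_protein_probs)
  if (cfg$n_phospho_proteins > cfg$n_proteins) {
    stop_config("n_phospho_proteins", "must not exceed 'n_proteins'")
  }
  if (!is.numeric(residue_probs) || length(residue_probs) != 3L ||
      !identical(names(residue_probs), c("S", "T", "Y")) ||
      any(residue_probs < 0)) {
    stop_config("residue_probs", "must be named weights for S, T, Y")
  }
  cfg$residue_probs <- residue_probs / sum(residue_probs)
  if (is.null(group_probs)) {
    group_probs <- c(
      setNames(rep(0.30 / length(group_labels), length(group_labels)),
               group_labels),
      unclassified = 0.70)
  }
  if (is.null(names(group_probs)) || any(group_probs < 0) ||
      !all(group_labels %in% names(group_probs))) {
    stop_config("group_probs",
                "must be named non-negative weights covering 'group_labels'")
  }
  cfg$group_probs <- group_probs / sum(group_probs)
  if (is.null(group_effects)) {
    group_effects <- setNames(rep(0, length(group_labels)), group_labels)
  }
  if (is.null(names(group_effects)) ||
      !all(names(group_effects) %in% c(group_labels, "unclassified"))) {
    stop_config("group_effects", "must be named after entries of 'group_labels'")
  }
  cfg$group_effects <- group_effects
  class(cfg) <- "simulation_config"
  cfg
}

sample_labels <- function(config) {
  as.vector(vapply(
    config$conditions,
    function(cond) paste(cond, seq_len(config$n_replicates_per_condition),
                         sep = "_"),
    character(config$n_replicates_per_condition)))
}

#' Map sample labels to conditions
#'
#' Sample columns are named `<condition>_<replicate>`; this strips the
#' replicate suffix.
#'
#' @param labels character vector of sample labels.
#' @return character vector of condition names.
#' @export
condition_of <- function(labels) sub("_[0-9]+$", "", labels)

random_windows <- function(n) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(AMINO_ACIDS, 15L * n, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

center_window <- function(windows, residues) {
  paste0(substr(windows, 1L, 7L), tolower(residues), substr(windows, 9L, 15L))
}

#' Simulate the protein-level quantification table
#'
#' One row per protein, one column per sample (`<condition>_<replicate>`).
#' Values are signal-to-noise draws: a log-normal protein baseline times a
#' per-condition protein effect times multiplicative channel noise.
#'
#' @param config a [simulation_config()].
#' @return data frame with `analyte_id` and one numeric column per sample;
#'   the accession-to-gene map is attached as attribute `gene_map`.
#' @export
generate_protein_quant <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  labels <- sample_labels(config)
  conds <- condition_of(labels)
  accession <- sprintf("P%05d", seq_len(n))
  gene <- sprintf("GENE%04d", seq_len(n))
  baseline <- 2^rnorm(n, mean = 7, sd = config$baseline_log_abundance_sd)
  effect <- matrix(0, nrow = n, ncol = length(config$conditions),
                   dimnames = list(NULL, config$conditions))
  for (cond in setdiff(config$conditions, "control")) {
    effect[, cond] <- rnorm(n, 0, config$protein_effect_sd_log2)
  }
  noise <- matrix(rnorm(n * length(labels), 0, config$noise_sd_log2),
                  nrow = n)
  values <- baseline * 2^(effect[, conds, drop = FALSE]) * 2^noise
  out <- data.frame(analyte_id = accession, values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("analyte_id", labels)
  attr(out, "gene_map") <- setNames(gene, accession)
  out
}

#' Simulate phosphopeptide quantification with ground truth
#'
#' Sites are placed on a random subset of the proteins (counts drawn from the
#' sites-per-protein distribution, positions sequential within a protein whose
#' length grows with its site count).  Sites are grouped into peptide isoforms
#' (a configured minority carry 2-3 sites); each isoform's signal-to-noise is
#' its parent protein's measured signal times a condition multiplier (acute
#' effect, plus the planted group shift on chronic channels) times channel
#' noise.  Localization scores are drawn so that a configured fraction falls
#' at or below the AScore gate of 13.
#'
#' @param config a [simulation_config()].
#' @param proteins protein table from [generate_protein_quant()] (same
#'   config).
#' @return list with `quant` (peptide-level quant table), `sites`
#'   (peptide-to-site records; multi-site isoforms carry `/`-separated
#'   residue, position, ascore and flank fields, ready for
#'   [explode_multisite()]), and `truth` (one row per individual site:
#'   group, true acute effect, true chronic-vs-acute differential,
#'   localization).
#' @export
generate_phospho_quant <- function(config, proteins) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  if (!"analyte_id" %in% names(proteins)) {
    stop("generation error: protein table lacks an 'analyte_id' column")
  }
  if (config$n_phospho_proteins > nrow(proteins)) {
    stop("generation error: fewer proteins than 'n_phospho_proteins'")
  }
  gene_map <- attr(proteins, "gene_map")
  labels <- sample_labels(config)
  conds <- condition_of(labels)
  prot_values <- as.matrix(proteins[, labels, drop = FALSE])

  rows <- sort(sample.int(nrow(proteins), config$n_phospho_proteins))
  acc <- proteins$analyte_id[rows]
  gene <- if (is.null(gene_map)) acc else unname(gene_map[acc])
  gene[is.na(gene)] <- acc[is.na(gene)]
  n_sites_per_protein <- sample.int(10L, config$n_phospho_proteins,
                                    replace = TRUE,
                                    prob = config$sites_per_protein_probs)
  n_sites <- sum(n_sites_per_protein)

  ## per-protein site layout: longer proteins carry more sites
  protein_len <- pmin(2000L,
                      100L + n_sites_per_protein * 150L +
                        sample.int(400L, config$n_phospho_proteins,
                                   replace = TRUE))
  position <- unlist(lapply(seq_len(config$n_phospho_proteins), function(i) {
    sort(sample(seq.int(8L, protein_len[i] - 7L), n_sites_per_protein[i]))
  }))
  protein_of_site <- rep.int(seq_len(config$n_phospho_proteins),
                             n_sites_per_protein)
  residue <- sample(names(config$residue_probs), n_sites, replace = TRUE,
                    prob = config$residue_probs)
  group_of_protein <- sample(names(config$group_probs),
                             config$n_phospho_proteins, replace = TRUE,
                             prob = config$group_probs)
  group <- group_of_protein[protein_of_site]

  ## group consecutive sites of a protein into peptide isoforms (max 3 sites)
  join_prev <- runif(n_sites) < config$frac_multisite
  peptide_of_site <- integer(n_sites)
  pep <- 0L
  size <- 0L
  for (s in seq_len(n_sites)) {
    first_of_protein <- s == 1L ||
      protein_of_site[s] != protein_of_site[s - 1L]
    if (first_of_protein || !join_prev[s] || size >= 3L) {
      pep <- pep + 1L
      size <- 1L
    } else {
      size <- size + 1L
    }
    peptide_of_site[s] <- pep
  }
  n_pep <- pep
  peptide_id <- sprintf("pep%05d", seq_len(n_pep))
  pep_protein <- protein_of_site[!duplicated(peptide_of_site)]

  ## condition effects live at the isoform level; the planted differential is
  ## the group effect of the (single) parent protein
  acute <- rnorm(n_pep, 0, config$acute_effect_sd_log2)
  effects <- config$group_effects
  pep_group <- group_of_protein[pep_protein]
  delta <- ifelse(pep_group %in% names(effects), effects[pep_group], 0)
  delta[is.na(delta)] <- 0

  effect_by_cond <- matrix(0, nrow = n_pep, ncol = length(config$conditions),
                           dimnames = list(NULL, config$conditions))
  if ("acute" %in% config$conditions) effect_by_cond[, "acute"] <- acute
  if ("chronic" %in% config$conditions) {
    effect_by_cond[, "chronic"] <- acute + delta
  }
  noise <- matrix(rnorm(n_pep * length(labels), 0, config$noise_sd_log2),
                  nrow = n_pep)
  values <- prot_values[rows[pep_protein], , drop = FALSE] *
    2^(effect_by_cond[, conds, drop = FALSE]) * 2^noise
  quant <- data.frame(analyte_id = peptide_id, values,
                      check.names = FALSE, stringsAsFactors = FALSE)
  names(quant) <- c("analyte_id", labels)
  rownames(quant) <- NULL

  below <- runif(n_sites) < config$frac_below_localization_threshold
  ascore <- ifelse(below, runif(n_sites, 0, 13), 13 + rexp(n_sites, 1 / 12))
  flank <- center_window(random_windows(n_sites), residue)

  per_site <- data.frame(
    peptide_id = peptide_id[peptide_of_site],
    accession = acc[protein_of_site],
    gene = gene[protein_of_site],
    organism = config$organism,
    residue = residue,
    position = position,
    ascore = ascore,
    flank = flank,
    stringsAsFactors = FALSE)

  collapse <- function(x, fmt = identity) {
    unname(tapply(fmt(x), peptide_of_site, paste, collapse = "/"))
  }
  sites <- data.frame(
    peptide_id = peptide_id,
    accession = acc[pep_protein],
    gene = gene[pep_protein],
    organism = config$organism,
    residue = collapse(per_site$residue),
    position = collapse(per_site$position, as.character),
    ascore = collapse(per_site$ascore, function(x) sprintf("%.4f", x)),
    flank = collapse(per_site$flank),
    n_sites = as.integer(table(peptide_of_site)),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    site_key = site_key(per_site$accession, per_site$residue,
                        per_site$position),
    peptide_id = per_site$peptide_id,
    accession = per_site$accession,
    gene = per_site$gene,
    group = group,
    acute_effect = acute[peptide_of_site],
    differential = delta[peptide_of_site],
    ascore = ascore,
    localized = ascore > 13,
    stringsAsFactors = FALSE)

  list(quant = quant, sites = sites, truth = truth)
}

#' Simulate the reference phosphorylation-site and kinase-substrate datasets
#'
#' A configured fraction of the measured sites is present in the reference
#' (a small sub-fraction only recoverable through flank-window matching,
#' mimicking cross-species curation), plus decoy reference sites absent from
#' the measured data.  Kinase annotations cover a configured fraction of the
#' reference-covered sites.
#'
#' @param config a [simulation_config()].
#' @param sites site records from [generate_phospho_quant()] (either the
#'   peptide-collapsed table or an already exploded per-site table).
#' @return list with `reference_sites`, `kinase_substrate` (both in the
#'   column layout written by [write_psp_site_dataset()] /
#'   [write_kinase_substrate_dataset()]) and `membership` (per measured
#'   site: reference membership, window-only flag, assigned kinases).
#' @export
generate_reference_db <- function(config, sites) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  per_site <- if (any(grepl("/", sites$position, fixed = TRUE))) {
    explode_multisite(sites)
  } else {
    sites
  }
  key <- site_key(per_site$accession, per_site$residue, per_site$position)
  keep <- !duplicated(key)
  per_site <- per_site[keep, , drop = FALSE]
  key <- key[keep]
  n <- nrow(per_site)

  in_ref <- runif(n) < config$frac_sites_in_reference
  window_only <- in_ref & runif(n) < config$frac_window_only

  acc_id <- per_site$accession
  organism <- rep(config$organism, n)
  versioned <- in_ref & !window_only & runif(n) < 0.05
  acc_id[versioned] <- paste0(acc_id[versioned], ".1")
  acc_id[window_only] <- sub("^P", "H", per_site$accession[window_only])
  organism[window_only] <- "human"

  mod_rsd <- sprintf("%s%d-p", per_site$residue, per_site$position)
  ref_ms <- data.frame(
    GENE = per_site$gene,
    PROTEIN = per_site$gene,
    ACC_ID = acc_id,
    ORGANISM = organism,
    MOD_RSD = mod_rsd,
    `SITE_+/-7_AA` = per_site$flank,
    check.names = FALSE, stringsAsFactors = FALSE)[in_ref, , drop = FALSE]
  rownames(ref_ms) <- NULL

  n_decoy <- config$n_decoy_reference_sites
  decoy_res <- sample(names(config$residue_probs), n_decoy, replace = TRUE,
                      prob = config$residue_probs)
  ref_decoy <- data.frame(
    GENE = sprintf("DGENE%04d", seq_len(n_decoy)),
    PROTEIN = sprintf("DGENE%04d", seq_len(n_decoy)),
    ACC_ID = sprintf("D%05d", seq_len(n_decoy)),
    ORGANISM = sample(c(config$organism, "human", "rat"), n_decoy,
                      replace = TRUE, prob = c(0.5, 0.35, 0.15)),
    MOD_RSD = paste0(decoy_res, sample.int(1500L, n_decoy, replace = TRUE),
                     "-p"),
    `SITE_+/-7_AA` = center_window(random_windows(n_decoy), decoy_res),
    check.names = FALSE, stringsAsFactors = FALSE)
  reference_sites <- rbind(ref_ms, ref_decoy)

  kinases <- default_kinase_names(config$n_kinases)
  annotated <- in_ref & runif(n) < config$frac_matched_with_kinase
  idx <- which(annotated)
  n_k <- sample(1:3, length(idx), replace = TRUE, prob = c(0.75, 0.20, 0.05))
  ks_site <- rep.int(idx, n_k)
  ks_kinase <- unlist(lapply(n_k, function(k) sample(kinases, k)))
  kin_of_site <- vapply(seq_len(n), function(i) "", "")
  if (length(idx)) {
    kin_of_site[idx] <- unname(tapply(ks_kinase, ks_site, paste,
                                      collapse = ";")[as.character(idx)])
  }

  ## decoy kinase rows on reference-only sites, as in real curated datasets;
  ## substrate accessions follow the reference record (so curation drift on
  ## window-only sites is reflected on the kinase side too)
  decoy_idx <- which(runif(n_decoy) < 0.10)
  kinase_substrate <- data.frame(
    KINASE = c(ks_kinase, sample(kinases, length(decoy_idx), replace = TRUE)),
    KIN_ORGANISM = config$organism,
    SUBSTRATE = c(per_site$gene[ks_site], ref_decoy$GENE[decoy_idx]),
    SUB_ACC_ID = c(acc_id[ks_site], ref_decoy$ACC_ID[decoy_idx]),
    SUB_GENE = c(per_site$gene[ks_site], ref_decoy$GENE[decoy_idx]),
    SUB_ORGANISM = c(organism[ks_site], ref_decoy$ORGANISM[decoy_idx]),
    SUB_MOD_RSD = c(mod_rsd[ks_site], ref_decoy$MOD_RSD[decoy_idx]),
    `SITE_+/-7_AA` = c(per_site$flank[ks_site],
                       ref_decoy$`SITE_+/-7_AA`[decoy_idx]),
    check.names = FALSE, stringsAsFactors = FALSE)

  membership <- data.frame(
    site_key = key,
    in_reference = in_ref,
    window_only = window_only,
    kinases = kin_of_site,
    stringsAsFactors = FALSE)

  list(reference_sites = reference_sites,
       kinase_substrate = kinase_substrate,
       membership = membership)
}

#' Configuration for a synthetic CellDesigner-flavored SBML map
#'
#' @param n_species number of species; the first `n_proteins_with_sites`
#'   carry phosphorylated modification residues.
#' @param n_reactions number of reactions (each connects declared species and
#'   may carry PMID references in its notes).
#' @param n_ser_thr,n_tyr counts of serine/threonine and tyrosine
#'   phosphosites to annotate.
#' @param n_proteins_with_sites number of species carrying at least one site.
#' @param n_pmids number of distinct PubMed identifiers distributed over the
#'   reaction notes (requires `n_reactions >= 1` when positive).
#' @param n_positionless number of phosphorylated residues annotated without
#'   a sequence position.
#' @param seed integer RNG seed.
#' @return a validated `map_fixture_config` list.
#' @export
map_fixture_config <- function(n_species = 10L, n_reactions = 6L,
                               n_ser_thr = 3L, n_tyr = 1L,
                               n_proteins_with_sites = 3L,
                               n_pmids = 3L, n_positionless = 0L,
                               seed = 1L) {
  cfg <- list(
    n_species = check_count(n_species, "n_species", minimum = 0L),
    n_reactions = check_count(n_reactions, "n_reactions", minimum = 0L),
    n_ser_thr = check_count(n_ser_thr, "n_ser_thr", minimum = 0L),
    n_tyr = check_count(n_tyr, "n_tyr", minimum = 0L),
    n_proteins_with_sites =
      check_count(n_proteins_with_sites, "n_proteins_with_sites", minimum = 0L),
    n_pmids = check_count(n_pmids, "n_pmids", minimum = 0L),
    n_positionless = check_count(n_positionless, "n_positionless",
                                 minimum = 0L),
    seed = check_count(seed, "seed", minimum = 0L))
  n_sites <- cfg$n_ser_thr + cfg$n_tyr + cfg$n_positionless
  if (n_sites > 0L && cfg$n_proteins_with_sites < 1L) {
    stop_config("n_proteins_with_sites", "must be >= 1 when sites are requested")
  }
  if (cfg$n_proteins_with_sites > cfg$n_species) {
    stop_config("n_proteins_with_sites", "must not exceed 'n_species'")
  }
  if (n_sites > 0L && cfg$n_proteins_with_sites > n_sites) {
    stop_config("n_proteins_with_sites", "must not exceed the site count")
  }
  if (cfg$n_pmids > 0L && cfg$n_reactions < 1L) {
    stop_config("n_pmids", "requires at least one reaction")
  }
  if (cfg$n_reactions > 0L && cfg$n_species < 2L) {
    stop_config("n_species", "must be >= 2 when reactions are requested")
  }
  class(cfg) <- "map_fixture_config"
  cfg
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a synthetic CellDesigner-flavored SBML map
#'
#' Produces a valid SBML Level 2 document carrying the CellDesigner extension
#' namespace, with species (some bearing phosphorylated modification
#' residues), reactions over declared species, and reaction notes containing
#' PMID strings.  Round-trips exactly through [parse_celldesigner_sbml()]
#' and [map_summary()].
#'
#' @param config a [map_fixture_config()].
#' @param path destination file.
#' @return invisibly, a list with the species table, the phosphosite table
#'   and the PMID pool that were written.
#' @export
generate_map_fixture <- function(config, path) {
  stopifnot(inherits(config, "map_fixture_config"))
  set.seed(config$seed)
  n_sp <- config$n_species
  species <- data.frame(
    id = sprintf("sp%04d", seq_len(n_sp)),
    name = sprintf("MAPPROT%04d", seq_len(n_sp)),
    compartment = "cytosol",
    stringsAsFactors = FALSE)

  n_sites <- config$n_ser_thr + config$n_tyr + config$n_positionless
  sites <- NULL
  if (n_sites > 0L) {
    residue <- c(sample(c("S", "T"), config$n_ser_thr, replace = TRUE),
                 rep("Y", config$n_tyr),
                 sample(c("S", "T", "Y"), config$n_positionless,
                        replace = TRUE, prob = c(0.6, 0.2, 0.2)))
    residue <- sample(residue)
    ## every site-bearing species gets >= 1 site
    owner <- c(seq_len(config$n_proteins_with_sites),
               sample.int(config$n_proteins_with_sites,
                          n_sites - config$n_proteins_with_sites,
                          replace = TRUE))
    owner <- sort(owner)
    position <- integer(n_sites)
    for (i in seq_len(config$n_proteins_with_sites)) {
      mine <- which(owner == i)
      position[mine] <- sort(sample.int(2000L, length(mine)))
    }
    positionless <- rep(FALSE, n_sites)
    if (config$n_positionless > 0L) {
      positionless[sample.int(n_sites, config$n_positionless)] <- TRUE
    }
    sites <- data.frame(
      species_id = species$id[owner],
      protein = species$name[owner],
      residue = residue,
      position = ifelse(positionless, NA_integer_, position),
      stringsAsFactors = FALSE)
  }

  pmids <- if (config$n_pmids > 0L) {
    sort(sample.int(25000000L, config$n_pmids) + 9999999L)
  } else {
    integer(0)
  }

  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level2/version4" ',
           'xmlns:celldesigner="http://www.sbml.org/2001/ns/celldesigner" ',
           'level="2" version="4">'),
    '  <model id="synthetic_map" name="synthetic signaling map">',
    '    <listOfCompartments>',
    '      <compartment id="cytosol" name="cytosol"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (i in seq_len(n_sp)) {
    sp_sites <- if (is.null(sites)) NULL else
      sites[sites$species_id == species$id[i], , drop = FALSE]
    open <- sprintf('      <species id="%s" name="%s" compartment="%s"',
                    species$id[i], xml_escape(species$name[i]),
                    species$compartment[i])
    if (is.null(sp_sites) || nrow(sp_sites) == 0L) {
      lines <- c(lines, paste0(open, "/>"))
    } else {
      mods <- sprintf(
        '              <celldesigner:modification residue="%s%s" state="phosphorylated"/>',
        sp_sites$residue,
        ifelse(is.na(sp_sites$position), "", sp_sites$position))
      lines <- c(lines, paste0(open, ">"),
                 "        <annotation>",
                 "          <celldesigner:extension>",
                 "            <celldesigner:speciesIdentity>",
                 '            <celldesigner:class>PROTEIN</celldesigner:class>',
                 "            <celldesigner:state>",
                 "            <celldesigner:listOfModifications>",
                 mods,
                 "            </celldesigner:listOfModifications>",
                 "            </celldesigner:state>",
                 "            </celldesigner:speciesIdentity>",
                 "          </celldesigner:extension>",
                 "        </annotation>",
                 "      </species>")
    }
  }
  lines <- c(lines, "    </listOfSpecies>")
  if (config$n_reactions > 0L) {
    lines <- c(lines, "    <listOfReactions>")
    pmid_owner <- if (length(pmids)) {
      ((seq_along(pmids) - 1L) %% config$n_reactions) + 1L
    } else {
      integer(0)
    }
    for (j in seq_len(config$n_reactions)) {
      pair <- sample.int(n_sp, 2L)
      note <- if (any(pmid_owner == j)) {
        paste(sprintf("PMID: %d", pmids[pmid_owner == j]), collapse = "; ")
      } else {
        "curated reaction"
      }
      lines <- c(
        lines,
        sprintf('      <reaction id="re%04d" reversible="false">', j),
        "        <notes>",
        '          <body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf("            <p>%s</p>", note),
        "          </body>",
        "        </notes>",
        "        <listOfReactants>",
        sprintf('          <speciesReference species="%s"/>',
                species$id[pair[1L]]),
        "        </listOfReactants>",
        "        <listOfProducts>",
        sprintf('          <speciesReference species="%s"/>',
                species$id[pair[2L]]),
        "        </listOfProducts>",
        "      </reaction>")
    }
    lines <- c(lines, "    </listOfReactions>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("I/O error writing map fixture: ",
                                    conditionMessage(e), call. = FALSE))
  invisible(list(species = species, sites = sites, pmids = pmids))
}
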