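## End-to-end orchestration: write a complete synthetic study to disk,
## run the analysis pipeline over tab-separated inputs, and record a
## reproducibility manifest.

GROUP_PALETTE <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
                   "#A65628", "#F781BF", "#1B9E77", "#66A61E", "#7570B3",
                   "#D95F02", "#999999")

#' Write a complete synthetic study to disk
#'
#' Generates protein quant, phosphopeptide quant with site records, the
#' reference site and kinase-substrate datasets, a protein-level functional
#' group table, the ground-truth record, and (optionally) a signaling-map
#' fixture, writing each as the tab-separated format the pipeline reads.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param map optional [map_fixture_config()]; when supplied a
#'   CellDesigner-flavored SBML fixture is written as `map.xml`.
#' @return invisibly, a list with the generated objects and the written
#'   `paths`.
#' @export
simulate_dataset <- function(config, dir, map = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  proteins <- generate_protein_quant(config)
  phospho <- generate_phospho_quant(config, proteins)
  refdb <- generate_reference_db(config, phospho$sites)

  truth <- phospho$truth
  truth$in_reference <- refdb$membership$in_reference[
    match(truth$site_key, refdb$membership$site_key)]
  truth$kinases <- refdb$membership$kinases[
    match(truth$site_key, refdb$membership$site_key)]

  phospho_groups <- unique(truth[, c("accession", "group")])
  labels <- sort(unique(phospho_groups$group))
  palette <- setNames(rep(GROUP_PALETTE, length.out = length(labels)),
                      labels)
  palette["unclassified"] <- "#CCCCCC"
  groups <- data.frame(key = phospho_groups$accession,
                       level = "protein",
                       group = phospho_groups$group,
                       color = unname(palette[phospho_groups$group]),
                       stringsAsFactors = FALSE)
  groups <- groups[order(groups$key), , drop = FALSE]

  paths <- c(
    proteins = file.path(dir, "protein_quant.tsv"),
    phospho = file.path(dir, "phospho_quant.tsv"),
    sites = file.path(dir, "phospho_sites.tsv"),
    reference_sites = file.path(dir, "reference_sites.tsv"),
    kinase_substrate = file.path(dir, "kinase_substrate.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth_sites.tsv"))
  write_quant_tsv(proteins, paths[["proteins"]])
  write_quant_tsv(phospho$quant, paths[["phospho"]])
  write_tsv(phospho$sites, paths[["sites"]])
  write_psp_site_dataset(refdb$reference_sites, paths[["reference_sites"]])
  write_kinase_substrate_dataset(refdb$kinase_substrate,
                                 paths[["kinase_substrate"]])
  write_tsv(groups, paths[["groups"]])
  write_tsv(truth, paths[["truth"]])
  map_fixture <- NULL
  if (!is.null(map)) {
    paths <- c(paths, map = file.path(dir, "map.xml"))
    map_fixture <- generate_map_fixture(map, paths[["map"]])
  }
  invisible(list(config = config, proteins = proteins, phospho = phospho,
                 refdb = refdb, truth = truth, groups = groups,
                 map_fixture = map_fixture, paths = paths))
}

#' Analysis configuration
#'
#' Collects input paths and the thresholds the pipeline applies: the
#' localization gate (AScore > 13), the outlier cutoff (|log2FC| > 1 on the
#' chronic-vs-acute differential), the Kolmogorov-Smirnov mode, the minimum
#' group size and the Benjamini-Hochberg significance level.
#'
#' @param protein_quant,phospho_quant,phospho_sites,reference_sites,kinase_substrate
#'   input file paths (see [simulate_dataset()] for the formats).
#' @param groups optional group-assignment table path.
#' @param terms optional GMT file path for the over-representation stage;
#'   when absent, protein-level terms are derived from the group table.
#' @param map optional SBML map path (audited, not required).
#' @param out_dir output directory.
#' @param conditions named character vector naming the control, acute and
#'   chronic conditions.
#' @param localization_threshold AScore gate (default 13).
#' @param outlier_cutoff log2 outlier cutoff (default 1).
#' @param outlier_field contrast used for outliers (default
#'   `"differential"`).
#' @param ks_mode `"asymptotic"` or `"permutation"`.
#' @param n_perm permutations in permutation mode.
#' @param min_group_size minimum in-group site count for the scans.
#' @param alpha Benjamini-Hochberg significance level (recorded in the
#'   manifest; results carry q-values).
#' @param seed integer seed used for any randomized stage.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(protein_quant, phospho_quant, phospho_sites,
                            reference_sites, kinase_substrate,
                            groups = NULL, terms = NULL, map = NULL,
                            out_dir = tempfile("phosflow_run_"),
                            conditions = c(control = "control",
                                           acute = "acute",
                                           chronic = "chronic"),
                            localization_threshold = 13,
                            outlier_cutoff = 1.0,
                            outlier_field = "differential",
                            ks_mode = c("asymptotic", "permutation"),
                            n_perm = 1000L,
                            min_group_size = 5L,
                            alpha = 0.05,
                            seed = 1L) {
  cfg <- list(
    protein_quant = protein_quant, phospho_quant = phospho_quant,
    phospho_sites = phospho_sites, reference_sites = reference_sites,
    kinase_substrate = kinase_substrate, groups = groups, terms = terms,
    map = map, out_dir = out_dir, conditions = conditions,
    localization_threshold = check_positive(localization_threshold,
                                            "localization_threshold"),
    outlier_cutoff = check_positive(outlier_cutoff, "outlier_cutoff"),
    outlier_field = outlier_field,
    ks_mode = match.arg(ks_mode),
    n_perm = check_count(n_perm, "n_perm"),
    min_group_size = check_count(min_group_size, "min_group_size"),
    alpha = check_positive(alpha, "alpha"),
    seed = check_count(seed, "seed", minimum = 0L))
  if (!all(c("control", "acute", "chronic") %in% names(cfg$conditions))) {
    stop_config("conditions", "must name control, acute and chronic")
  }
  required <- c("protein_quant", "phospho_quant", "phospho_sites",
                "reference_sites", "kinase_substrate")
  for (field in required) {
    if (!is.character(cfg[[field]]) || length(cfg[[field]]) != 1L) {
      stop_config(field, "must be a single file path")
    }
  }
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the analysis pipeline end-to-end
#'
#' Stages, in order: relative-abundance normalization of the protein and
#' phosphopeptide tables; multi-site isoform explosion and localization
#' filtering; phosphosite-to-protein normalization; condition collapse and
#' log2 fold-change contrasts; reference-site matching and kinase
#' annotation; group assignment, outlier selection, Kolmogorov-Smirnov
#' scans and hypergeometric over-representation; kinase-substrate network
#' export.  A failure in any stage aborts with the stage name.  All stage
#' outputs are written under `config$out_dir` together with a JSON manifest
#' (config snapshot, input checksums, per-stage counts, package version,
#' seed, timestamps).
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list with the manifest and the in-memory stage
#'   outputs (`differentials`, `site_differentials`, `match_report`,
#'   `annotation`, `group_scan`, `kinase_scan`, `outliers`, `enrichment`,
#'   `network`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  inputs <- c(protein_quant = config$protein_quant,
              phospho_quant = config$phospho_quant,
              phospho_sites = config$phospho_sites,
              reference_sites = config$reference_sites,
              kinase_substrate = config$kinase_substrate,
              groups = config$groups, terms = config$terms,
              map = config$map)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0L) {
    stop("configuration error: missing input file(s): ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "),
         call. = FALSE)
  }
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                              recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## quant ------------------------------------------------------------
  proteins <- stage("read", read_quant_tsv(config$protein_quant))
  phospho <- stage("read", read_quant_tsv(config$phospho_quant))
  sites_raw <- stage("read", read.delim(config$phospho_sites,
                                        check.names = FALSE,
                                        stringsAsFactors = FALSE))
  prot_ra <- stage("quant", relative_abundance(proteins))
  phos_ra <- stage("quant", relative_abundance(phospho))
  counts$quant <- list(n_proteins = nrow(prot_ra),
                       n_phosphopeptides = nrow(phos_ra),
                       n_zero_sum_dropped =
                         length(attr(prot_ra, "dropped")) +
                         length(attr(phos_ra, "dropped")))

  exploded <- stage("explode", explode_multisite(sites_raw))
  loc <- stage("localization",
               localization_filter(exploded, config$localization_threshold))
  counts$localization <- list(sites_in = nrow(exploded),
                              sites_kept = nrow(loc$kept),
                              sites_filtered = nrow(loc$discarded))

  pep_map <- unique(exploded[, c("peptide_id", "accession")])
  names(pep_map) <- c("analyte_id", "accession")
  norm <- stage("normalize",
                normalize_to_protein(phos_ra, prot_ra, pep_map))
  collapsed <- stage("collapse", condition_collapse(norm$values))
  differentials <- stage("contrasts",
                         compute_differentials(collapsed,
                                               config$conditions))
  counts$contrasts <- list(
    n_peptides = nrow(differentials),
    n_with_contrasts = sum(!is.na(differentials$differential)),
    n_missing_contrasts = sum(is.na(differentials$differential)),
    n_unnormalized = sum(!norm$flags$normalized))

  ## site-level differentials: sites inherit their isoform's contrasts
  site_diff <- loc$kept
  site_diff$site_key <- site_key(site_diff$accession, site_diff$residue,
                                 site_diff$position)
  hit <- match(site_diff$peptide_id, differentials$site_key)
  site_diff$log2fc_acute <- differentials$log2fc_acute[hit]
  site_diff$log2fc_chronic <- differentials$log2fc_chronic[hit]
  site_diff$differential <- differentials$differential[hit]
  site_differentials <- site_diff[!duplicated(site_diff$site_key),
                                  c("site_key", "accession", "gene",
                                    "log2fc_acute", "log2fc_chronic",
                                    "differential")]

  ## match ------------------------------------------------------------
  ref <- stage("match", read_psp_site_dataset(config$reference_sites))
  ks_db <- stage("match",
                 read_kinase_substrate_dataset(config$kinase_substrate))
  report <- stage("match", match_sites(loc$kept, ref))
  annotation <- stage("match", annotate_kinases(report, ks_db))
  spp <- sites_per_protein_summary(loc$kept)
  counts$match <- list(
    sites_in = report$n_total,
    sites_matched = report$n_matched,
    sites_unmatched = report$n_unmatched,
    tier_counts = as.list(report$tier_counts),
    n_kinases = annotation$summary$n_kinases,
    n_annotated_sites = annotation$summary$n_annotated_sites,
    n_annotated_proteins = annotation$summary$n_annotated_proteins,
    n_phosphoproteins = spp$n_proteins,
    fraction_1to3 = spp$fraction_1to3)

  ## group_stats -------------------------------------------------------
  group_table <- if (!is.null(config$groups)) {
    stage("groups", read_group_table(config$groups))
  } else {
    NULL
  }
  grouped <- stage("groups", assign_groups(loc$kept, group_table))
  grouped$site_key <- site_key(grouped$accession, grouped$residue,
                               grouped$position)
  grouped <- grouped[!duplicated(grouped$site_key), , drop = FALSE]
  outliers <- stage("outliers",
                    select_outliers(site_differentials,
                                    config$outlier_cutoff,
                                    config$outlier_field))
  group_scan <- stage("ks_scan",
                      group_ks_scan(site_differentials, grouped,
                                    mode = config$ks_mode,
                                    min_n = config$min_group_size,
                                    n_perm = config$n_perm,
                                    seed = config$seed))
  kinase_scan <- stage("ks_scan",
                       kinase_ks_scan(site_differentials,
                                      annotation$pairs,
                                      mode = config$ks_mode,
                                      min_n = config$min_group_size,
                                      n_perm = config$n_perm,
                                      seed = config$seed + 10000L))
  counts$group_stats <- list(
    n_groups_tested = nrow(group_scan),
    n_kinases_tested = nrow(kinase_scan),
    n_outliers = nrow(outliers$outliers),
    inside_fraction = outliers$inside_fraction)

  terms <- if (!is.null(config$terms)) {
    stage("enrichment", read_gmt(config$terms))
  } else if (!is.null(group_table)) {
    prot_level <- group_table[group_table$level == "protein", , drop = FALSE]
    split(prot_level$key, prot_level$group)
  } else {
    NULL
  }
  enrichment <- NULL
  if (!is.null(terms)) {
    background <- unique(site_differentials$accession[
      !is.na(site_differentials$differential)])
    foreground <- unique(site_differentials$accession[
      site_differentials$site_key %in% outliers$outliers$site_key])
    enrichment <- stage("enrichment",
                        hypergeometric_enrichment(foreground, background,
                                                  terms))
    counts$enrichment <- list(n_terms_tested = nrow(enrichment),
                              n_foreground = length(foreground),
                              n_background = length(background))
  }

  ## network_export ----------------------------------------------------
  network <- stage("network",
                   build_network(annotation$pairs, site_differentials,
                                 grouped))
  counts$network <- list(n_nodes = nrow(network$nodes),
                         n_edges = nrow(network$edges))

  ## map audit (optional) ----------------------------------------------
  map_audit <- NULL
  if (!is.null(config$map)) {
    parsed_map <- stage("map", parse_celldesigner_sbml(config$map))
    map_audit <- list(summary = map_summary(parsed_map),
                      concordance = stage("map",
                                          map_concordance(parsed_map, ref)))
    counts$map <- c(map_audit$summary,
                    list(concordance = map_audit$concordance$concordance))
  }

  ## outputs and manifest ------------------------------------------------
  out <- function(name) file.path(config$out_dir, name)
  write_tsv(site_differentials, out("site_differentials.tsv"))
  write_tsv(report$matches, out("match_report.tsv"))
  write_tsv(report$unmatched, out("unmatched_sites.tsv"))
  write_tsv(annotation$pairs[, c("kinase", "ms_key", "gene", "residue",
                                 "position")], out("kinase_annotations.tsv"))
  write_tsv(group_scan, out("group_ks.tsv"))
  write_tsv(kinase_scan, out("kinase_ks.tsv"))
  write_tsv(outliers$outliers, out("outlier_sites.tsv"))
  if (!is.null(enrichment)) write_tsv(enrichment, out("enrichment.tsv"))
  export_sif(network, out("network.sif"))
  export_graphml(network, out("network.graphml"))
  export_attribute_tables(network, config$out_dir)
  jsonlite::write_json(
    list(n_total = report$n_total, n_matched = report$n_matched,
         n_unmatched = report$n_unmatched,
         tier_counts = as.list(report$tier_counts)),
    out("match_summary.json"), auto_unbox = TRUE)

  manifest <- list(
    package = "phosflow",
    version = as.character(packageVersion("phosflow")),
    seed = config$seed,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "out_dir")],
    input_checksums = as.list(setNames(unname(md5sum(unname(inputs))),
                                       names(inputs))),
    counts = counts,
    notes = paste("simulated three-condition design: the channel-to-condition",
                  "layout is an assumption of the synthetic generator"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(list(manifest = manifest,
                 differentials = differentials,
                 site_differentials = site_differentials,
                 match_report = report,
                 annotation = annotation,
                 grouped = grouped,
                 group_scan = group_scan,
                 kinase_scan = kinase_scan,
                 outliers = outliers,
                 enrichment = enrichment,
                 network = network,
                 map_audit = map_audit))
}
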