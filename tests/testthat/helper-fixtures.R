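# Shared fixtures and independent oracles used across the suite.

small_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_proteins = 80L, n_phospho_proteins = 40L,
                   n_decoy_reference_sites = 60L, n_kinases = 12L,
                   frac_matched_with_kinase = 0.3)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# run the quant stages on a simulated study and join site-level contrasts
# with the generator's ground truth
mini_differentials <- function(cfg) {
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  prot_ra <- relative_abundance(prot)
  phos_ra <- relative_abundance(ph$quant)
  ex <- explode_multisite(ph$sites)
  pep_map <- unique(ex[, c("peptide_id", "accession")])
  names(pep_map) <- c("analyte_id", "accession")
  norm <- suppressMessages(normalize_to_protein(phos_ra, prot_ra, pep_map))
  d <- suppressMessages(
    compute_differentials(condition_collapse(norm$values)))
  hit <- match(ex$peptide_id, d$site_key)
  out <- data.frame(site_key = site_key(ex$accession, ex$residue,
                                        ex$position),
                    log2fc_acute = d$log2fc_acute[hit],
                    log2fc_chronic = d$log2fc_chronic[hit],
                    differential = d$differential[hit],
                    stringsAsFactors = FALSE)
  truth <- ph$truth
  names(truth)[names(truth) == "differential"] <- "true_differential"
  names(truth)[names(truth) == "acute_effect"] <- "true_acute"
  merge(out, truth, by = "site_key")
}

# all-pairs brute-force site matcher applying the tier rules literally;
# independent of the tiered implementation
oracle_match <- function(ms, ref, tiers = c("accession", "gene", "window")) {
  norm_acc <- function(a) sub("-[0-9]+$", "", sub("\\.[0-9]+$", "", a))
  n <- nrow(ms)
  hits <- rep(NA_integer_, n)
  tier_of <- rep(NA_character_, n)
  ms_flank <- if ("flank" %in% names(ms)) ms$flank else rep(NA_character_, n)
  for (i in seq_len(n)) {
    for (tier in tiers) {
      found <- NA_integer_
      for (j in seq_len(nrow(ref))) {
        ok <- switch(
          tier,
          accession =
            norm_acc(ms$accession[i]) == norm_acc(ref$acc_id[j]) &&
            identical(ms$organism[i], ref$organism[j]) &&
            toupper(ms$residue[i]) == toupper(ref$residue[j]) &&
            ms$position[i] == ref$position[j],
          gene =
            tolower(ms$gene[i]) == tolower(ref$gene[j]) &&
            identical(ms$organism[i], ref$organism[j]) &&
            toupper(ms$residue[i]) == toupper(ref$residue[j]) &&
            ms$position[i] == ref$position[j],
          window =
            !is.na(ms_flank[i]) && !is.na(ref$flank[j]) &&
            nzchar(ms_flank[i]) && nzchar(ref$flank[j]) &&
            toupper(ms_flank[i]) == toupper(ref$flank[j]))
        if (isTRUE(ok)) {
          found <- j
          break
        }
      }
      if (!is.na(found)) {
        hits[i] <- found
        tier_of[i] <- tier
        break
      }
    }
  }
  list(hits = hits, tiers = tier_of)
}

# random matching instance with deliberate key collisions, accession-suffix
# drift, cross-organism rows and shared flank windows
random_match_instance <- function(seed) {
  set.seed(seed)
  n <- sample(10:40, 1)
  m <- sample(20:80, 1)
  accs <- sprintf("P%03d", 1:12)
  genes <- setNames(sprintf("g%03d", 1:12), accs)
  window_pool <- replicate(12, paste(sample(LETTERS[1:5], 15, replace = TRUE),
                                     collapse = ""))
  ms_acc <- sample(accs, n, replace = TRUE)
  ms <- data.frame(
    peptide_id = sprintf("pep%03d", seq_len(n)),
    accession = paste0(ms_acc, sample(c("", "-2", ".1"), n, replace = TRUE,
                                      prob = c(0.8, 0.1, 0.1))),
    gene = unname(genes[ms_acc]),
    organism = sample(c("mouse", "human"), n, replace = TRUE,
                      prob = c(0.8, 0.2)),
    residue = sample(c("S", "T", "Y"), n, replace = TRUE),
    position = sample(1:25, n, replace = TRUE),
    flank = sample(c(window_pool, NA_character_), n, replace = TRUE),
    stringsAsFactors = FALSE)
  ref_acc <- sample(accs, m, replace = TRUE)
  ref <- data.frame(
    acc_id = paste0(ref_acc, sample(c("", "-3", ".2"), m, replace = TRUE,
                                    prob = c(0.7, 0.15, 0.15))),
    gene = ifelse(runif(m) < 0.85, unname(genes[ref_acc]),
                  sample(genes, m, replace = TRUE)),
    organism = sample(c("mouse", "human", "rat"), m, replace = TRUE),
    residue = sample(c("S", "T", "Y"), m, replace = TRUE),
    position = sample(1:25, m, replace = TRUE),
    flank = sample(c(window_pool, NA_character_), m, replace = TRUE),
    stringsAsFactors = FALSE)
  list(ms = ms, ref = ref)
}

# exact permutation p-value by exhaustive enumeration of all splits
exhaustive_ks_p <- function(x, y) {
  pooled <- c(x, y)
  n_x <- length(x)
  d_obs <- ks_two_sample(x, y)$D
  splits <- utils::combn(length(pooled), n_x)
  d_all <- apply(splits, 2, function(idx) {
    ks_two_sample(pooled[idx], pooled[-idx])$D
  })
  mean(d_all >= d_obs - 1e-12)
}

# reference table built directly from a parsed map's phosphosite inventory
reference_from_map_sites <- function(sites) {
  data.frame(
    GENE = sites$protein,
    PROTEIN = sites$protein,
    ACC_ID = sprintf("MAP%04d", seq_len(nrow(sites))),
    ORGANISM = "mouse",
    MOD_RSD = paste0(sites$residue, sites$position, "-p"),
    `SITE_+/-7_AA` = NA_character_,
    check.names = FALSE, stringsAsFactors = FALSE)
}

expect_same_match <- function(report, oracle, instance) {
  matched_impl <- which(report$ms$matched)
  matched_orac <- which(!is.na(oracle$hits))
  expect_identical(matched_impl, matched_orac)
  tier_names <- c(accession = "accession", gene = "gene", window = "window")
  expect_identical(report$ms$match_tier[matched_impl],
                   unname(tier_names[oracle$tiers[matched_orac]]))
}
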