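test_that("configuration is validated field by field", {
  expect_error(simulation_config(frac_sites_in_reference = 1.2),
               "frac_sites_in_reference")
  expect_error(simulation_config(n_proteins = 0), "n_proteins")
  expect_error(simulation_config(n_phospho_proteins = 50, n_proteins = 10),
               "n_phospho_proteins")
  expect_error(simulation_config(noise_sd_log2 = -1), "noise_sd_log2")
  expect_error(simulation_config(conditions = c("a", "a")), "conditions")
})

test_that("protein quant shape follows the configuration", {
  cfg <- simulation_config(seed = 7, n_proteins = 50, n_phospho_proteins = 20)
  m <- generate_protein_quant(cfg)
  expect_equal(nrow(m), 50)
  expect_equal(ncol(m), 1 + 9)
  expect_true(all(as.matrix(m[, -1]) > 0))
  expect_equal(condition_of(names(m)[-1]),
               rep(c("control", "acute", "chronic"), each = 3))
})

test_that("identical config and seed reproduce identical outputs", {
  cfg <- small_config(seed = 11)
  a <- generate_protein_quant(cfg)
  b <- generate_protein_quant(cfg)
  expect_identical(a, b)
  pa <- generate_phospho_quant(cfg, a)
  pb <- generate_phospho_quant(cfg, b)
  expect_identical(pa, pb)
  ra <- generate_reference_db(cfg, pa$sites)
  rb <- generate_reference_db(cfg, pb$sites)
  expect_identical(ra, rb)
})

test_that("zero noise and zero effects give constant protein rows", {
  cfg <- small_config(seed = 2, noise_sd_log2 = 0, protein_effect_sd_log2 = 0)
  m <- generate_protein_quant(cfg)
  spread <- apply(as.matrix(m[, -1]), 1, function(r) diff(range(r)))
  expect_true(all(spread < 1e-12))
})

test_that("null effects and zero noise give exactly zero differentials", {
  cfg <- small_config(seed = 5, noise_sd_log2 = 0)
  d <- mini_differentials(cfg)
  expect_true(all(abs(d$differential) < 1e-9))
  # acute contrast equals the planted acute effect exactly
  expect_equal(d$log2fc_acute, d$true_acute, tolerance = 1e-9)
})

test_that("planted group shifts are recovered exactly without noise", {
  for (delta in c(-1.5, -1, 1, 1.5)) {
    cfg <- small_config(
      seed = 30 + round(10 * delta), noise_sd_log2 = 0,
      group_labels = "RNA binding and translation",
      group_probs = c("RNA binding and translation" = 0.3,
                      unclassified = 0.7),
      group_effects = c("RNA binding and translation" = delta))
    d <- mini_differentials(cfg)
    planted <- d$group == "RNA binding and translation"
    expect_gt(sum(planted), 0)
    expect_true(all(abs(d$differential[planted] - delta) < 1e-9))
    expect_true(all(abs(d$differential[!planted]) < 1e-9))
  }
})

test_that("a planted shift of -1.5 is recovered within 0.2 at noise 0.3", {
  stats <- vapply(1:20, function(s) {
    cfg <- simulation_config(
      seed = 100 + s, n_proteins = 200, n_phospho_proteins = 90,
      noise_sd_log2 = 0.3, n_decoy_reference_sites = 10,
      group_probs = c("RNA binding and translation" = 0.25,
                      unclassified = 0.75),
      group_labels = "RNA binding and translation",
      group_effects = c("RNA binding and translation" = -1.5))
    d <- mini_differentials(cfg)
    planted <- d$group == "RNA binding and translation"
    c(mean(d$differential[planted], na.rm = TRUE), sum(planted))
  }, numeric(2))
  expect_gte(mean(stats[2, ]), 50)
  expect_lt(abs(mean(stats[1, ]) - (-1.5)), 0.2)
})

test_that("localization scores fall below the gate at the configured rate", {
  cfg <- simulation_config(seed = 9, n_proteins = 700,
                           n_phospho_proteins = 320,
                           frac_below_localization_threshold = 0.1,
                           n_decoy_reference_sites = 10)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  ex <- explode_multisite(ph$sites)
  loc <- localization_filter(ex)
  n <- nrow(ex)
  # kept set equals the truth record exactly
  expect_equal(nrow(loc$kept), sum(ph$truth$localized))
  # filtered count is binomially consistent with the configured fraction
  bounds <- qbinom(c(0.0005, 0.9995), n, 0.1)
  expect_gte(nrow(loc$discarded), bounds[1])
  expect_lte(nrow(loc$discarded), bounds[2])
})

test_that("reference overlap is binomially consistent with the configuration", {
  cfg <- simulation_config(seed = 13, n_proteins = 1500,
                           n_phospho_proteins = 640,
                           frac_below_localization_threshold = 0,
                           n_decoy_reference_sites = 500)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  refdb <- generate_reference_db(cfg, ph$sites)
  ex <- explode_multisite(ph$sites)
  report <- suppressMessages(match_sites(ex, refdb$reference_sites))
  n <- report$n_total
  p_hat <- report$n_matched / n
  expect_lt(abs(p_hat - 0.903), 4 * sqrt(0.903 * 0.097 / n))
  # matching recovers the membership record exactly (no decoy collisions)
  expect_equal(report$n_matched, sum(refdb$membership$in_reference))
})

test_that("saturating the kinase fraction annotates every matched site", {
  cfg <- small_config(seed = 21, frac_matched_with_kinase = 1)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  refdb <- generate_reference_db(cfg, ph$sites)
  ex <- explode_multisite(ph$sites)
  report <- suppressMessages(match_sites(ex, refdb$reference_sites))
  ann <- annotate_kinases(report, refdb$kinase_substrate)
  expect_equal(ann$summary$n_annotated_sites, report$n_matched)
  expect_true(all(ann$sites$kinases != ""))
})

test_that("an empty reference fraction yields zero matches", {
  cfg <- small_config(seed = 22, frac_sites_in_reference = 0,
                      n_decoy_reference_sites = 40)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  refdb <- generate_reference_db(cfg, ph$sites)
  ex <- explode_multisite(ph$sites)
  report <- match_sites(ex, refdb$reference_sites)
  expect_equal(report$n_matched, 0)
  expect_equal(report$n_unmatched, report$n_total)
})

test_that("every emitted phosphosite has exactly one truth row", {
  cfg <- small_config(seed = 23)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  ex <- explode_multisite(ph$sites)
  keys <- site_key(ex$accession, ex$residue, ex$position)
  expect_equal(sort(keys), sort(ph$truth$site_key))
  expect_equal(anyDuplicated(ph$truth$site_key), 0)
})

test_that("sites-per-protein distribution matches its configuration", {
  cfg <- simulation_config(seed = 31, n_proteins = 4000,
                           n_phospho_proteins = 1800,
                           n_decoy_reference_sites = 10)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  ex <- explode_multisite(ph$sites)
  spp <- sites_per_protein_summary(ex)
  expect_equal(spp$n_proteins, 1800)
  # configured mass on 1-3 sites is 0.736
  expect_lt(abs(spp$fraction_1to3 - 0.736),
            4 * sqrt(0.736 * 0.264 / 1800))
})
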