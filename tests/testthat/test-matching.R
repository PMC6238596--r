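test_that("multi-site isoforms explode into per-site records", {
  rec <- data.frame(peptide_id = c("p1", "p2"),
                    accession = c("P1", "P2"),
                    gene = c("g1", "g2"),
                    organism = "mouse",
                    residue = c("S/S", "T"),
                    position = c("235/236", "99"),
                    ascore = c("20/30", "15"),
                    flank = c("AAAAAAAsAAAAAAA/BBBBBBBsBBBBBBB", "CCCCCCCtCCCCCCC"),
                    stringsAsFactors = FALSE)
  out <- explode_multisite(rec)
  expect_equal(nrow(out), 3)
  expect_equal(out$peptide_id, c("p1", "p1", "p2"))
  expect_equal(out$position, c(235L, 236L, 99L))
  expect_equal(out$ascore, c(20, 30, 15))
  expect_equal(out$is_multisite, c(TRUE, TRUE, FALSE))
  # all-singleton input passes through with the same content
  single <- rec[2, ]
  out2 <- explode_multisite(single)
  expect_equal(out2$position, 99L)
  expect_equal(nrow(out2), 1)
  expect_error(explode_multisite(transform(rec, position = c("x/y", "99"))),
               "malformed position")
})

test_that("exploded record count equals the sum of sites per isoform", {
  cfg <- small_config(seed = 41, frac_multisite = 0.35)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  out <- explode_multisite(ph$sites)
  expect_equal(nrow(out), sum(ph$sites$n_sites))
  expect_equal(as.integer(table(out$peptide_id)[ph$sites$peptide_id]),
               ph$sites$n_sites)
})

test_that("matching against an empty reference leaves everything unmatched", {
  inst <- random_match_instance(1)
  empty <- inst$ref[0, ]
  report <- match_sites(inst$ms, empty)
  expect_equal(report$n_matched, 0)
  expect_equal(report$n_unmatched, nrow(inst$ms))
})

test_that("tiered matcher equals the all-pairs brute-force oracle", {
  for (seed in 1:50) {
    inst <- random_match_instance(seed)
    report <- suppressMessages(match_sites(inst$ms, inst$ref))
    oracle <- oracle_match(inst$ms, inst$ref)
    expect_same_match(report, oracle, inst)
    # partition exactness
    expect_equal(report$n_matched + report$n_unmatched, report$n_total)
    expect_equal(nrow(report$matches) + nrow(report$unmatched),
                 nrow(inst$ms))
  }
})

test_that("disabling the window tier never increases the match count", {
  for (seed in c(3, 17, 29)) {
    inst <- random_match_instance(seed)
    full <- suppressMessages(match_sites(inst$ms, inst$ref))
    no_window <- suppressMessages(
      match_sites(inst$ms, inst$ref,
                  match_policy(tiers = c("accession", "gene"))))
    acc_only <- suppressMessages(
      match_sites(inst$ms, inst$ref, match_policy(tiers = "accession")))
    expect_lte(no_window$n_matched, full$n_matched)
    expect_lte(acc_only$n_matched, no_window$n_matched)
  }
})

test_that("re-matching the matched subset reproduces the same pairs", {
  inst <- random_match_instance(8)
  report <- suppressMessages(match_sites(inst$ms, inst$ref))
  matched_ms <- inst$ms[report$ms$matched, , drop = FALSE]
  again <- suppressMessages(match_sites(matched_ms, inst$ref))
  expect_equal(again$n_matched, nrow(matched_ms))
  expect_equal(again$matches[order(again$matches$ms_key), ],
               report$matches[order(report$matches$ms_key), ],
               ignore_attr = TRUE)
})

test_that("accession normalization bridges version and isoform suffixes", {
  ms <- data.frame(peptide_id = "p1", accession = "P0001-2", gene = "g1",
                   organism = "mouse", residue = "S", position = 10L,
                   flank = NA_character_, stringsAsFactors = FALSE)
  ref <- data.frame(acc_id = "P0001.1", gene = "other", organism = "mouse",
                    residue = "S", position = 10L, flank = NA_character_,
                    stringsAsFactors = FALSE)
  expect_message(report <- match_sites(ms, ref), "normalized 2 accession")
  expect_equal(report$n_matched, 1)
  expect_equal(report$matches$tier, "accession")
})

test_that("kinase annotation joins on the reference key and summarizes", {
  cfg <- small_config(seed = 44)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  refdb <- generate_reference_db(cfg, ph$sites)
  ex <- explode_multisite(ph$sites)
  report <- suppressMessages(match_sites(ex, refdb$reference_sites))
  ann <- annotate_kinases(report, refdb$kinase_substrate)
  truth <- merge(ph$truth, refdb$membership[, c("site_key", "kinases")],
                 by = "site_key")
  truth_annotated <- truth[truth$kinases != "", ]
  expect_equal(ann$summary$n_annotated_sites, nrow(truth_annotated))
  expect_equal(ann$summary$n_annotated_proteins,
               length(unique(truth_annotated$accession)))
  expect_equal(ann$summary$n_kinases,
               length(unique(unlist(strsplit(truth_annotated$kinases, ";")))))
  # per-site kinase sets agree with the truth record
  m <- merge(ann$sites[, c("ms_key", "kinases")], truth,
             by.x = "ms_key", by.y = "site_key")
  split_sort <- function(x) lapply(strsplit(x, ";"), sort)
  expect_equal(split_sort(m$kinases.x), split_sort(m$kinases.y))
  # empty kinase dataset leaves every set empty
  ann0 <- annotate_kinases(report, refdb$kinase_substrate[0, ])
  expect_equal(ann0$summary$n_annotated_sites, 0)
  expect_true(all(ann0$sites$kinases == ""))
})

test_that("sites-per-protein histogram counts by hand", {
  sites <- data.frame(
    peptide_id = sprintf("p%d", 1:6),
    accession = c("A", "B", "C", "C", "C", "C"),
    residue = "S", position = c(1, 1, 1, 2, 3, 4),
    stringsAsFactors = FALSE)
  spp <- sites_per_protein_summary(sites)
  expect_equal(as.integer(spp$histogram[c("1", "4")]), c(2L, 1L))
  expect_equal(spp$fraction_1to3, 2 / 3)
  expect_equal(spp$n_proteins, 3)
  empty <- sites_per_protein_summary(sites[0, ])
  expect_equal(empty$n_proteins, 0)
})

test_that("reference TSV dialect round-trips through its parser", {
  cfg <- small_config(seed = 51)
  prot <- generate_protein_quant(cfg)
  ph <- generate_phospho_quant(cfg, prot)
  refdb <- generate_reference_db(cfg, ph$sites)
  ref_path <- tempfile(fileext = ".tsv")
  ks_path <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(ref_path, ks_path)), add = TRUE)
  write_psp_site_dataset(refdb$reference_sites, ref_path)
  write_kinase_substrate_dataset(refdb$kinase_substrate, ks_path)
  ref <- read_psp_site_dataset(ref_path)
  expect_equal(nrow(ref), nrow(refdb$reference_sites))
  expect_equal(ref$acc_id, refdb$reference_sites$ACC_ID)
  parsed <- parse_mod_rsd(refdb$reference_sites$MOD_RSD)
  expect_equal(ref$residue, parsed$residue)
  expect_equal(ref$position, parsed$position)
  ks <- read_kinase_substrate_dataset(ks_path)
  expect_equal(nrow(ks), nrow(refdb$kinase_substrate))
  # malformed MOD_RSD rows are dropped with a message
  broken <- refdb$reference_sites
  broken$MOD_RSD[1] <- "K27-ac"
  write_psp_site_dataset(broken, ref_path)
  expect_message(ref2 <- read_psp_site_dataset(ref_path), "dropped 1 row")
  expect_equal(nrow(ref2), nrow(broken) - 1)
})
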