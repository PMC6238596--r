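test_that("map fixtures round-trip through the parser for random configs", {
  set.seed(77)
  for (i in 1:20) {
    n_species <- sample(2:25, 1)
    n_proteins <- sample(0:min(4, n_species), 1)
    n_sites <- if (n_proteins == 0) 0 else n_proteins + sample(0:6, 1)
    n_tyr <- if (n_sites == 0) 0 else sample(0:n_sites, 1)
    n_reactions <- sample(0:8, 1)
    n_pmids <- if (n_reactions == 0) 0 else sample(0:10, 1)
    cfg <- map_fixture_config(
      n_species = n_species, n_reactions = n_reactions,
      n_ser_thr = n_sites - n_tyr, n_tyr = n_tyr,
      n_proteins_with_sites = n_proteins, n_pmids = n_pmids,
      seed = 1000 + i)
    path <- tempfile(fileext = ".xml")
    generate_map_fixture(cfg, path)
    m <- if (n_sites == 0) {
      suppressWarnings(parse_celldesigner_sbml(path))
    } else {
      parse_celldesigner_sbml(path)
    }
    s <- map_summary(m)
    expect_equal(s$n_species, n_species)
    expect_equal(s$n_reactions, n_reactions)
    expect_equal(s$n_publications, n_pmids)
    expect_equal(s$n_phosphosites, n_sites)
    expect_equal(s$n_ser_thr, n_sites - n_tyr)
    expect_equal(s$n_tyr, n_tyr)
    expect_equal(s$n_proteins_with_sites, n_proteins)
    expect_equal(s$n_phosphosites, s$n_ser_thr + s$n_tyr)
    unlink(path)
  }
})

test_that("residue classes tally as expected in a tiny fixture", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  generate_map_fixture(map_fixture_config(n_species = 5, n_reactions = 3,
                                          n_ser_thr = 3, n_tyr = 1,
                                          n_proteins_with_sites = 2,
                                          n_pmids = 2, seed = 4), path)
  s <- map_summary(parse_celldesigner_sbml(path))
  expect_equal(c(s$n_ser_thr, s$n_tyr), c(3, 1))
})

test_that("positionless residues are inventoried but reported separately", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  generate_map_fixture(map_fixture_config(n_species = 6, n_reactions = 2,
                                          n_ser_thr = 4, n_tyr = 1,
                                          n_proteins_with_sites = 5,
                                          n_positionless = 1,
                                          n_pmids = 2, seed = 8), path)
  m <- parse_celldesigner_sbml(path)
  s <- map_summary(m)
  expect_equal(s$n_phosphosites, 6)
  expect_equal(s$n_positionless, 1)
  expect_message(conc <- map_concordance(m, reference_from_map_sites(
    m$phosphosites[!is.na(m$phosphosites$position), ])), "positionless")
  expect_equal(conc$n_positionless, 1)
  expect_equal(conc$n_map_sites, 5)
})

test_that("a map without the CellDesigner namespace degrades gracefully", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="m"><listOfSpecies>',
    '    <species id="s1" name="A" compartment="c"/>',
    '    <species id="s2" name="B" compartment="c"/>',
    '  </listOfSpecies>',
    '  <listOfReactions><reaction id="r1">',
    '    <listOfReactants><speciesReference species="s1"/></listOfReactants>',
    '    <listOfProducts><speciesReference species="s2"/></listOfProducts>',
    '  </reaction></listOfReactions>',
    '  </model></sbml>'), path)
  expect_warning(m <- parse_celldesigner_sbml(path), "CellDesigner")
  expect_equal(nrow(m$species), 2)
  expect_equal(nrow(m$reactions), 1)
  expect_equal(nrow(m$phosphosites), 0)
})

test_that("dangling reaction participants are reported", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="m"><listOfSpecies>',
    '    <species id="s1" name="A" compartment="c"/>',
    '  </listOfSpecies>',
    '  <listOfReactions><reaction id="r1">',
    '    <listOfReactants><speciesReference species="s1"/></listOfReactants>',
    '    <listOfProducts><speciesReference species="ghost"/></listOfProducts>',
    '  </reaction></listOfReactions>',
    '  </model></sbml>'), path)
  expect_warning(expect_warning(parse_celldesigner_sbml(path), "ghost"),
                 "CellDesigner")
})

test_that("union summaries deduplicate shared species", {
  p1 <- tempfile(fileext = ".xml")
  p2 <- tempfile(fileext = ".xml")
  on.exit(unlink(c(p1, p2)))
  generate_map_fixture(map_fixture_config(n_species = 5, n_reactions = 2,
                                          n_ser_thr = 2, n_tyr = 0,
                                          n_proteins_with_sites = 1,
                                          n_pmids = 2, seed = 3), p1)
  generate_map_fixture(map_fixture_config(n_species = 8, n_reactions = 3,
                                          n_ser_thr = 0, n_tyr = 0,
                                          n_proteins_with_sites = 0,
                                          n_pmids = 3, seed = 3), p2)
  m1 <- parse_celldesigner_sbml(p1)
  m2 <- suppressWarnings(parse_celldesigner_sbml(p2))
  u <- map_summary(list(m1, m2))
  # species names are deterministic, so the 5 names of map 1 all recur in map 2
  expect_equal(u$n_species, 8)
  s1 <- map_summary(m1)
  s2 <- map_summary(m2)
  expect_lte(u$n_species, s1$n_species + s2$n_species)
  expect_lte(u$n_publications, s1$n_publications + s2$n_publications)
})

test_that("concordance is 1 for covering references and 0 for disjoint ones", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  generate_map_fixture(map_fixture_config(n_species = 10, n_reactions = 4,
                                          n_ser_thr = 6, n_tyr = 2,
                                          n_proteins_with_sites = 4,
                                          n_pmids = 3, seed = 12), path)
  m <- parse_celldesigner_sbml(path)
  ref <- reference_from_map_sites(m$phosphosites)
  full <- map_concordance(m, ref)
  expect_equal(full$concordance, 1)
  expect_equal(full$n_missing, 0)
  disjoint <- ref
  disjoint$GENE <- paste0("x_", disjoint$GENE)
  disjoint$PROTEIN <- disjoint$GENE
  none <- map_concordance(m, disjoint)
  expect_equal(none$concordance, 0)
  expect_equal(none$n_missing, none$n_map_sites)
})

test_that("withholding 9 of 189 sites mirrors the 95% concordance audit", {
  path <- tempfile(fileext = ".xml")
  on.exit(unlink(path))
  generate_map_fixture(map_fixture_config(n_species = 80, n_reactions = 20,
                                          n_ser_thr = 149, n_tyr = 40,
                                          n_proteins_with_sites = 56,
                                          n_pmids = 30, seed = 6), path)
  m <- parse_celldesigner_sbml(path)
  expect_equal(nrow(m$phosphosites), 189)
  ref <- reference_from_map_sites(m$phosphosites)
  set.seed(1)
  withheld <- sample(nrow(ref), 9)
  conc <- map_concordance(m, ref[-withheld, ])
  expect_equal(conc$n_map_sites, 189)
  expect_equal(conc$n_found, 180)
  expect_equal(conc$n_missing, 9)
  expect_equal(round(100 * conc$concordance), 95)
})
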