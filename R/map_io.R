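## CellDesigner-flavored SBML signaling maps: parsing, summary statistics
## and concordance auditing against a reference site database.

CELLDESIGNER_NS <- "http://www.sbml.org/2001/ns/celldesigner"

#' Parse a CellDesigner-flavored SBML map
#'
#' Species and reactions are read from the standard SBML elements;
#' phosphorylation residues from the CellDesigner extension (modification
#' residues with state `"phosphorylated"`, residue strings like `"S235"` or
#' a bare `"S"` for positionless annotations); PMIDs from reaction notes and
#' annotations via the pattern `PMID[: ]<digits>`.  Reaction participants
#' that do not resolve to a declared species are reported with a warning.
#'
#' @param path SBML file.
#' @return a `signaling_map` list: `species` (id, name, compartment),
#'   `reactions` (id + list-columns `reactants`, `products`, `modifiers`,
#'   `pmids`), `phosphosites` (protein, residue, position), `source`.
#' @export
parse_celldesigner_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- tryCatch(xml2::xml_ns(doc), error = function(e) character(0))
  has_cd <- any(vapply(ns, identical, logical(1L), CELLDESIGNER_NS))
  level <- xml2::xml_attr(doc, "level")
  if (!is.na(level) && level != "2") {
    warning(sprintf("SBML level %s: attempting a best-effort parse", level),
            call. = FALSE)
  }
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)
  species$name[is.na(species$name)] <- species$id[is.na(species$name)]

  re_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  participants <- function(node, xpath) {
    xml2::xml_attr(xml2::xml_find_all(node, xpath), "species")
  }
  reactions <- data.frame(id = xml2::xml_attr(re_nodes, "id"),
                          stringsAsFactors = FALSE)
  reactions$reactants <- lapply(re_nodes, participants,
                                "./listOfReactants/speciesReference")
  reactions$products <- lapply(re_nodes, participants,
                               "./listOfProducts/speciesReference")
  reactions$modifiers <- lapply(re_nodes, participants,
                                "./listOfModifiers/modifierSpeciesReference")
  reactions$pmids <- lapply(re_nodes, function(node) {
    text <- paste(
      vapply(xml2::xml_find_all(node, "./notes | ./annotation"),
             xml2::xml_text, character(1L)),
      collapse = " ")
    m <- regmatches(text, gregexpr("PMID[:[:space:]]*([0-9]+)", text))[[1L]]
    unique(as.integer(sub("PMID[:[:space:]]*", "", m)))
  })

  dangling <- setdiff(
    unlist(c(reactions$reactants, reactions$products, reactions$modifiers)),
    species$id)
  if (length(dangling) > 0L) {
    warning("reaction participant(s) not declared as species: ",
            paste(dangling, collapse = ", "), call. = FALSE)
  }

  if (has_cd) {
    mod_nodes <- xml2::xml_find_all(
      doc,
      ".//species//*[local-name()='modification'][@state='phosphorylated']")
    protein <- vapply(mod_nodes, function(node) {
      sp <- xml2::xml_find_first(node, "./ancestor::species")
      nm <- xml2::xml_attr(sp, "name")
      if (is.na(nm)) xml2::xml_attr(sp, "id") else nm
    }, character(1L))
    res_str <- xml2::xml_attr(mod_nodes, "residue")
    m <- regmatches(res_str, regexec("^([STY])([0-9]*)$", res_str))
    residue <- vapply(m, function(g) {
      if (length(g) == 0L) NA_character_ else g[2L]
    }, character(1L))
    position <- vapply(m, function(g) {
      if (length(g) == 0L || g[3L] == "") NA_integer_ else as.integer(g[3L])
    }, integer(1L))
    unparsed <- sum(is.na(residue))
    if (unparsed > 0L) {
      message(sprintf(
        "parse_celldesigner_sbml: ignored %d unrecognized modification residue(s)",
        unparsed))
    }
    phosphosites <- data.frame(protein = protein[!is.na(residue)],
                               residue = residue[!is.na(residue)],
                               position = position[!is.na(residue)],
                               stringsAsFactors = FALSE)
  } else {
    warning("no CellDesigner extension namespace: phosphosite inventory is empty",
            call. = FALSE)
    phosphosites <- data.frame(protein = character(0),
                               residue = character(0),
                               position = integer(0),
                               stringsAsFactors = FALSE)
  }

  structure(list(species = species, reactions = reactions,
                 phosphosites = phosphosites, source = path),
            class = "signaling_map")
}

#' Summarize one signaling map, or the union of several
#'
#' Counts species, reactions, distinct reaction-level PMIDs and annotated
#' phosphosites (split into Ser/Thr and Tyr).  When given a list of maps,
#' the union summary deduplicates species by (name, compartment), reactions
#' by id, phosphosites by (protein, residue, position) and PMIDs by value.
#'
#' @param m a `signaling_map` or a list of them.
#' @return named list: `n_species`, `n_reactions`, `n_publications`,
#'   `n_phosphosites`, `n_ser_thr`, `n_tyr`, `n_proteins_with_sites`,
#'   `n_positionless` (positionless residues are counted in the inventory
#'   but reported separately as well).
#' @export
map_summary <- function(m) {
  maps <- if (inherits(m, "signaling_map")) list(m) else m
  stopifnot(all(vapply(maps, inherits, logical(1L), "signaling_map")))
  species <- do.call(rbind, lapply(maps, `[[`, "species"))
  species <- species[!duplicated(paste(species$name, species$compartment)), ,
                     drop = FALSE]
  reaction_ids <- unique(unlist(lapply(maps, function(x) x$reactions$id)))
  pmids <- unique(unlist(lapply(maps, function(x) x$reactions$pmids)))
  sites <- do.call(rbind, lapply(maps, `[[`, "phosphosites"))
  sites <- sites[!duplicated(paste(sites$protein, sites$residue,
                                   sites$position)), , drop = FALSE]
  list(
    n_species = nrow(species),
    n_reactions = length(reaction_ids),
    n_publications = length(pmids),
    n_phosphosites = nrow(sites),
    n_ser_thr = sum(sites$residue %in% c("S", "T")),
    n_tyr = sum(sites$residue == "Y"),
    n_proteins_with_sites = length(unique(sites$protein)),
    n_positionless = sum(is.na(sites$position)))
}

#' Concordance of map phosphosites with a reference site database
#'
#' A positioned map site is "found" when some reference record matches it by
#' case-folded protein name (against the reference gene or protein symbol),
#' residue and position, or - when the map site carries one - by exact flank
#' window.  Positionless map sites are excluded from the denominator and
#' reported separately.
#'
#' @param m a `signaling_map`.
#' @param ref reference site records (generator layout or
#'   [read_psp_site_dataset()] output).
#' @param alias optional named character vector mapping map protein labels
#'   to reference accessions; aliased sites also match by accession.
#' @return list: `n_map_sites` (positioned), `n_found`, `n_missing`,
#'   `missing` (data frame), `n_positionless`, `concordance`.
#' @export
map_concordance <- function(m, ref, alias = NULL) {
  stopifnot(inherits(m, "signaling_map"))
  ref <- standardize_reference(ref)
  sites <- m$phosphosites
  positionless <- is.na(sites$position)
  if (any(positionless)) {
    message(sprintf(
      "map_concordance: %d positionless site(s) excluded from the denominator",
      sum(positionless)))
  }
  sites <- sites[!positionless, , drop = FALSE]
  key_gene <- paste(tolower(ref$gene), ref$residue, ref$position, sep = "|")
  ref_protein <- if ("protein" %in% names(ref)) ref$protein else ref$gene
  key_prot <- paste(tolower(ref_protein), ref$residue, ref$position,
                    sep = "|")
  site_keys <- paste(tolower(sites$protein), toupper(sites$residue),
                     sites$position, sep = "|")
  found <- site_keys %in% key_gene | site_keys %in% key_prot
  if (!is.null(alias)) {
    acc <- unname(alias[sites$protein])
    acc_keys <- site_key(as.character(normalize_accession(acc)),
                         sites$residue, sites$position)
    ref_acc_keys <- site_key(as.character(normalize_accession(ref$acc_id)),
                             ref$residue, ref$position)
    found <- found | (!is.na(acc) & acc_keys %in% ref_acc_keys)
  }
  if ("flank" %in% names(sites)) {
    w <- sites$flank
    found <- found | (!is.na(w) & toupper(w) %in% toupper(ref$flank))
  }
  list(
    n_map_sites = nrow(sites),
    n_found = sum(found),
    n_missing = sum(!found),
    missing = sites[!found, , drop = FALSE],
    n_positionless = sum(positionless),
    concordance = if (nrow(sites) > 0) sum(found) / nrow(sites) else
      NA_real_)
}
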