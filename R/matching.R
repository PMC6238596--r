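## Database merging: explode multi-site phosphopeptide isoforms, match
## measured phosphosites against a reference phosphorylation-site dataset
## with a tiered key policy, and annotate matched sites with kinases from a
## kinase-substrate dataset.

#' One record per individual phosphosite
#'
#' Phosphopeptide isoforms are quantified as a unit but may carry several
#' sites (`residue = "S/S"`, `position = "235/236"`).  This expands each
#' isoform into per-site records that inherit the isoform's quant linkage
#' (`peptide_id`); singleton records pass through unchanged.
#'
#' @param records site records with columns `peptide_id`, `accession`,
#'   `gene`, `organism`, `residue`, `position` and optionally `ascore` and
#'   `flank` (`/`-separated in multi-site records).
#' @return data frame with one row per site: integer `position`, numeric
#'   `ascore`, and an `is_multisite` flag.
#' @export
explode_multisite <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("peptide_id", "accession", "residue", "position") %in%
                  names(records)))
  split_field <- function(x) strsplit(as.character(x), "/", fixed = TRUE)
  pos_list <- split_field(records$position)
  res_list <- split_field(records$residue)
  n_sites <- lengths(pos_list)
  bad <- n_sites == 0L | vapply(pos_list, function(p) {
    anyNA(suppressWarnings(as.integer(p))) ||
      any(suppressWarnings(as.integer(p)) < 1L)
  }, logical(1L))
  if (any(bad)) {
    stop("malformed position list for peptide(s): ",
         paste(utils::head(records$peptide_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  ## a single residue letter is recycled across the isoform's positions
  res_list <- mapply(function(r, k) {
    if (length(r) == 1L) rep(r, k) else r
  }, res_list, n_sites, SIMPLIFY = FALSE)
  if (any(lengths(res_list) != n_sites)) {
    stop("malformed position list: residue/position cardinality mismatch",
         call. = FALSE)
  }
  residue <- toupper(unlist(res_list))
  if (!all(residue %in% c("S", "T", "Y"))) {
    stop("malformed position list: residues must be S, T or Y",
         call. = FALSE)
  }
  expand_opt <- function(column, convert = identity) {
    if (!column %in% names(records)) return(NULL)
    parts <- split_field(records[[column]])
    parts <- mapply(function(p, k) if (length(p) == 1L) rep(p, k) else p,
                    parts, n_sites, SIMPLIFY = FALSE)
    if (any(lengths(parts) != n_sites)) {
      stop(sprintf("malformed '%s' list: cardinality mismatch", column),
           call. = FALSE)
    }
    convert(unlist(parts))
  }
  idx <- rep.int(seq_len(nrow(records)), n_sites)
  out <- data.frame(
    peptide_id = records$peptide_id[idx],
    accession = records$accession[idx],
    gene = if ("gene" %in% names(records)) records$gene[idx] else
      records$accession[idx],
    organism = if ("organism" %in% names(records)) records$organism[idx] else
      NA_character_,
    residue = residue,
    position = as.integer(unlist(pos_list)),
    stringsAsFactors = FALSE)
  ascore <- expand_opt("ascore", function(x) suppressWarnings(as.numeric(x)))
  if (!is.null(ascore)) out$ascore <- ascore
  flank <- expand_opt("flank")
  if (!is.null(flank)) out$flank <- flank
  out$is_multisite <- (n_sites > 1L)[idx]
  rownames(out) <- NULL
  out
}

#' Matching policy for [match_sites()]
#'
#' The default three-tier, first-hit-wins policy: tier 1 matches on
#' (accession, residue, position) within the same organism; tier 2 on
#' (case-folded gene symbol, residue, position) within the same organism;
#' tier 3 on the exact 15-mer flanking window, any organism (absorbing
#' cross-species curation).  Accessions are normalized (isoform/version
#' suffixes stripped) before tier 1 unless disabled.
#'
#' @param tiers subset of `c("accession", "gene", "window")`, in the order
#'   they are attempted.
#' @param normalize_accessions strip isoform/version suffixes before tier-1
#'   comparison.
#' @return a `match_policy` list.
#' @export
match_policy <- function(tiers = c("accession", "gene", "window"),
                         normalize_accessions = TRUE) {
  tiers <- match.arg(tiers, c("accession", "gene", "window"),
                     several.ok = TRUE)
  structure(list(tiers = tiers,
                 normalize_accessions = isTRUE(normalize_accessions)),
            class = "match_policy")
}

tier_keys <- function(tier, acc, gene, organism, residue, position, flank) {
  switch(tier,
    accession = paste(organism, acc, toupper(residue), position, sep = "|"),
    gene = paste(organism, tolower(gene), toupper(residue), position,
                 sep = "|"),
    window = ifelse(is.na(flank) | flank == "", NA_character_,
                    toupper(flank)))
}

#' Match measured phosphosites against a reference site dataset
#'
#' Tiered, first-hit-wins matching per measured site (see [match_policy()]).
#' Duplicate reference keys within a tier use the first occurrence; the
#' duplicate count is reported.  The matched/unmatched partition is
#' exhaustive and disjoint.
#'
#' @param ms exploded per-site records ([explode_multisite()]), with
#'   `accession`, `gene`, `organism`, `residue`, `position` and optionally
#'   `flank`.
#' @param ref reference site records ([read_psp_site_dataset()] or
#'   [generate_reference_db()]): columns `ACC_ID`/`acc_id`, `GENE`/`gene`,
#'   `ORGANISM`/`organism`, residue+position (`MOD_RSD` or parsed), flank
#'   window.
#' @param policy a [match_policy()].
#' @return a `match_report` list: `n_total`, `n_matched`, `n_unmatched`,
#'   `matches` (ms_key, ref_key, tier), `unmatched` (ms_key), `tier_counts`,
#'   and `ms` (the input records with match columns appended).
#' @export
match_sites <- function(ms, ref, policy = match_policy()) {
  stopifnot(inherits(policy, "match_policy"))
  ref <- standardize_reference(ref)
  n <- nrow(ms)
  ms_acc <- ms$accession
  ref_acc <- ref$acc_id
  if (policy$normalize_accessions) {
    ms_acc_n <- normalize_accession(ms_acc)
    ref_acc_n <- normalize_accession(ref_acc)
    n_changed <- attr(ms_acc_n, "n_changed") + attr(ref_acc_n, "n_changed")
    if (n_changed > 0L) {
      message(sprintf("match_sites: normalized %d accession(s)", n_changed))
    }
    ms_acc <- as.character(ms_acc_n)
    ref_acc <- as.character(ref_acc_n)
  }
  ms_flank <- if ("flank" %in% names(ms)) ms$flank else rep(NA_character_, n)
  ref_key_canonical <- site_key(ref_acc, ref$residue, ref$position)

  hit <- rep(NA_integer_, n)
  tier_of <- rep(NA_character_, n)
  n_dup <- 0L
  for (tier in policy$tiers) {
    open <- is.na(hit)
    if (!any(open)) break
    ref_keys <- tier_keys(tier, ref_acc, ref$gene, ref$organism,
                          ref$residue, ref$position, ref$flank)
    n_dup <- n_dup + sum(duplicated(ref_keys[!is.na(ref_keys)]))
    ms_keys <- tier_keys(tier, ms_acc[open], ms$gene[open], ms$organism[open],
                         ms$residue[open], ms$position[open], ms_flank[open])
    found <- match(ms_keys, ref_keys, incomparables = NA)
    hit[open] <- found
    tier_of[open][!is.na(found)] <- tier
  }
  if (n_dup > 0L) {
    message(sprintf(
      "match_sites: %d duplicate reference key(s); first occurrence used",
      n_dup))
  }
  ms_key <- site_key(ms$accession, ms$residue, ms$position)
  matched <- !is.na(hit)
  out <- ms
  out$ms_key <- ms_key
  out$matched <- matched
  out$match_tier <- tier_of
  out$ref_key <- ifelse(matched, ref_key_canonical[hit], NA_character_)
  report <- list(
    n_total = n,
    n_matched = sum(matched),
    n_unmatched = sum(!matched),
    matches = data.frame(ms_key = ms_key[matched],
                         ref_key = ref_key_canonical[hit[matched]],
                         tier = tier_of[matched],
                         stringsAsFactors = FALSE),
    unmatched = data.frame(ms_key = ms_key[!matched],
                           stringsAsFactors = FALSE),
    tier_counts = table(factor(tier_of[matched],
                               levels = policy$tiers)),
    ms = out)
  class(report) <- "match_report"
  report
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match report: %d/%d site(s) matched (%.1f%%), %d unmatched\n",
              x$n_matched, x$n_total,
              if (x$n_total > 0) 100 * x$n_matched / x$n_total else 0,
              x$n_unmatched))
  if (x$n_matched > 0) {
    tc <- x$tier_counts
    cat("  by tier:",
        paste(sprintf("%s=%d", names(tc), as.integer(tc)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

## accept either the generator's upper-case column layout or a pre-parsed one
standardize_reference <- function(ref) {
  stopifnot(is.data.frame(ref))
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(ref)) return(ref[[nm]])
    NULL
  }
  acc <- pick("acc_id", "ACC_ID")
  if (is.null(acc)) stop("reference lacks an accession column", call. = FALSE)
  residue <- pick("residue")
  position <- pick("position")
  if (is.null(residue) || is.null(position)) {
    mod <- pick("MOD_RSD", "mod_rsd", "SUB_MOD_RSD")
    if (is.null(mod)) {
      stop("reference lacks residue/position information", call. = FALSE)
    }
    parsed <- parse_mod_rsd(mod)
    residue <- parsed$residue
    position <- parsed$position
  }
  data.frame(
    acc_id = acc,
    gene = pick("gene", "GENE", "SUB_GENE") %||% acc,
    organism = pick("organism", "ORGANISM", "SUB_ORGANISM") %||%
      NA_character_,
    residue = toupper(residue),
    position = as.integer(position),
    flank = pick("flank", "SITE_+/-7_AA") %||% NA_character_,
    stringsAsFactors = FALSE)
}

#' Annotate matched sites with kinases
#'
#' Attaches to each matched site the (possibly empty) set of kinases whose
#' substrate key (accession, residue, position) equals the site's reference
#' key, and summarizes the annotation: distinct kinase count, annotated-site
#' count, annotated-protein count.
#'
#' @param report a [match_sites()] report.
#' @param ks kinase-substrate records ([read_kinase_substrate_dataset()] or
#'   [generate_reference_db()]).
#' @return list with `pairs` (one row per kinase-site pair), `sites` (one
#'   row per matched site, kinases `;`-collapsed) and `summary`.
#' @export
annotate_kinases <- function(report, ks) {
  stopifnot(inherits(report, "match_report"))
  matched <- report$ms[report$ms$matched, , drop = FALSE]
  kin_col <- if ("KINASE" %in% names(ks)) "KINASE" else "kinase"
  sub_acc <- if ("SUB_ACC_ID" %in% names(ks)) ks$SUB_ACC_ID else ks$sub_acc_id
  mod <- if ("SUB_MOD_RSD" %in% names(ks)) ks$SUB_MOD_RSD else ks$sub_mod_rsd
  parsed <- parse_mod_rsd(mod)
  ks_key <- site_key(as.character(normalize_accession(sub_acc)),
                     parsed$residue, parsed$position)
  idx <- which(ks_key %in% matched$ref_key)
  pairs <- data.frame(
    kinase = ks[[kin_col]][idx],
    ref_key = ks_key[idx],
    stringsAsFactors = FALSE)
  pairs <- merge(pairs,
                 matched[, c("ms_key", "ref_key", "accession", "gene",
                             "residue", "position", "peptide_id")],
                 by = "ref_key")
  pairs <- pairs[!duplicated(pairs[, c("kinase", "ms_key")]), , drop = FALSE]
  pairs <- pairs[order(pairs$kinase, pairs$ms_key), , drop = FALSE]
  rownames(pairs) <- NULL

  kin_per_site <- if (nrow(pairs) > 0L) {
    tapply(pairs$kinase, pairs$ms_key,
           function(k) paste(sort(unique(k)), collapse = ";"))
  } else {
    character(0)
  }
  sites <- matched
  sites$kinases <- ""
  hit <- match(sites$ms_key, names(kin_per_site))
  sites$kinases[!is.na(hit)] <- unname(kin_per_site[hit[!is.na(hit)]])
  annotated <- sites[sites$kinases != "", , drop = FALSE]
  list(
    pairs = pairs,
    sites = sites,
    summary = list(
      n_kinases = length(unique(pairs$kinase)),
      n_annotated_sites = nrow(annotated),
      n_annotated_proteins = length(unique(annotated$accession))))
}

#' Sites-per-protein distribution
#'
#' @param sites exploded per-site records (deduplicated by site key before
#'   counting).
#' @return list with `per_protein` (accession, n_sites), `histogram`
#'   (site-count bins 1..max), `fraction_1to3` (fraction of proteins with
#'   1-3 sites), `n_proteins`, `n_sites`.
#' @export
sites_per_protein_summary <- function(sites) {
  if (nrow(sites) == 0L) {
    return(list(per_protein = data.frame(accession = character(0),
                                         n_sites = integer(0)),
                histogram = table(factor(integer(0), levels = integer(0))),
                fraction_1to3 = NA_real_,
                n_proteins = 0L, n_sites = 0L))
  }
  key <- site_key(sites$accession, sites$residue, sites$position)
  uniq <- sites[!duplicated(key), , drop = FALSE]
  counts <- table(uniq$accession)
  per_protein <- data.frame(accession = names(counts),
                            n_sites = as.integer(counts),
                            stringsAsFactors = FALSE)
  histogram <- table(factor(per_protein$n_sites,
                            levels = seq_len(max(per_protein$n_sites))))
  list(per_protein = per_protein,
       histogram = histogram,
       fraction_1to3 = mean(per_protein$n_sites <= 3L),
       n_proteins = nrow(per_protein),
       n_sites = nrow(uniq))
}
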