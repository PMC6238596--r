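## Quantification: signal-to-noise -> relative abundance, localization
## filtering, phosphosite-to-protein normalization, condition collapse and
## log2 fold-change contrasts.

quant_matrix_check <- function(m, what = "quant table") {
  if (!is.data.frame(m) || !"analyte_id" %in% names(m)) {
    stop(sprintf("%s must be a data frame with an 'analyte_id' column", what),
         call. = FALSE)
  }
  samples <- setdiff(names(m), "analyte_id")
  if (length(samples) < 1L) {
    stop(sprintf("%s must have at least one sample column", what),
         call. = FALSE)
  }
  samples
}

#' Per-analyte relative abundance
#'
#' Each sample's signal-to-noise value is divided by the analyte's row sum
#' and scaled so every row totals 100.  Rows whose sum is zero carry no
#' quantitative information and are dropped (their count is reported via a
#' message and the `dropped` attribute).
#'
#' @param m quant table: data frame with `analyte_id` plus one non-negative
#'   numeric column per sample.
#' @return data frame of the same layout whose rows each sum to 100;
#'   attribute `dropped` holds the analyte ids of removed zero-sum rows.
#' @export
relative_abundance <- function(m) {
  samples <- quant_matrix_check(m)
  values <- as.matrix(m[, samples, drop = FALSE])
  if (anyNA(values)) values[is.na(values)] <- 0
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop(sprintf(
      "negative signal-to-noise value for analyte '%s' in sample '%s'",
      m$analyte_id[neg[1L, 1L]], samples[neg[1L, 2L]]), call. = FALSE)
  }
  sums <- rowSums(values)
  zero <- sums == 0
  if (any(zero)) {
    message(sprintf("relative_abundance: dropped %d zero-sum row(s)",
                    sum(zero)))
  }
  out <- m[!zero, , drop = FALSE]
  out[, samples] <- 100 * values[!zero, , drop = FALSE] / sums[!zero]
  rownames(out) <- NULL
  attr(out, "dropped") <- m$analyte_id[zero]
  out
}

#' Localization-confidence filter
#'
#' Keeps phosphosite records whose localization score is strictly greater
#' than the threshold (AScore > 13 corresponds to P < 0.05 that the site
#' assignment is correct).  Records with a missing score are routed to the
#' discarded set with a reason code; the partition is exhaustive and
#' disjoint.
#'
#' @param sites per-site records with a numeric `ascore` column (e.g. the
#'   output of [explode_multisite()]).
#' @param threshold localization score cutoff (default 13).
#' @return list with `kept` and `discarded` data frames; `discarded` gains a
#'   `reason` column (`"at_or_below_threshold"` or `"missing_score"`).
#' @export
localization_filter <- function(sites, threshold = 13) {
  stopifnot(is.data.frame(sites), "ascore" %in% names(sites))
  score <- suppressWarnings(as.numeric(sites$ascore))
  keep <- !is.na(score) & score > threshold
  discarded <- sites[!keep, , drop = FALSE]
  discarded$reason <- ifelse(is.na(score[!keep]), "missing_score",
                             "at_or_below_threshold")
  kept <- sites[keep, , drop = FALSE]
  rownames(kept) <- rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Normalize phosphopeptide abundance to protein abundance
#'
#' Divides each phosphopeptide's per-sample relative abundance by the
#' relative abundance of its parent protein, removing protein-level
#' abundance changes from the phosphorylation signal.  Peptides whose
#' protein lacks quantitation are flagged `normalized = FALSE` and carried
#' forward with their raw values; sample cells where the protein relative
#' abundance is zero become missing.
#'
#' @param phospho phosphopeptide relative-abundance table
#'   (from [relative_abundance()]).
#' @param protein protein relative-abundance table with identical sample
#'   columns.
#' @param site_to_protein data frame mapping `analyte_id` to `accession`
#'   (at most one protein per peptide), or a named character vector.
#' @return list with `values` (normalized table) and `flags` (per analyte:
#'   `normalized` logical); a message reports unnormalized peptides and
#'   zeroed cells.
#' @export
normalize_to_protein <- function(phospho, protein, site_to_protein) {
  p_samples <- quant_matrix_check(phospho, "phospho table")
  q_samples <- quant_matrix_check(protein, "protein table")
  if (!identical(sort(p_samples), sort(q_samples))) {
    stop("phospho and protein tables must share the same sample columns",
         call. = FALSE)
  }
  if (is.data.frame(site_to_protein)) {
    stopifnot(all(c("analyte_id", "accession") %in% names(site_to_protein)))
    map <- setNames(site_to_protein$accession, site_to_protein$analyte_id)
  } else {
    map <- site_to_protein
  }
  if (anyDuplicated(names(map))) {
    dup <- names(map)[duplicated(names(map))]
    if (any(tapply(map, names(map), function(x) length(unique(x))) > 1L)) {
      stop("peptide mapped to more than one protein: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
    map <- map[!duplicated(names(map))]
  }
  acc <- unname(map[phospho$analyte_id])
  prot_row <- match(acc, protein$analyte_id)
  normalized <- !is.na(prot_row)
  if (any(!normalized)) {
    message(sprintf(
      "normalize_to_protein: %d peptide(s) without protein quantitation kept unnormalized",
      sum(!normalized)))
  }
  values <- as.matrix(phospho[, p_samples, drop = FALSE])
  denom <- as.matrix(protein[prot_row, p_samples, drop = FALSE])
  zero_cells <- normalized & (denom == 0)
  zero_cells[is.na(zero_cells)] <- FALSE
  if (any(zero_cells)) {
    message(sprintf(
      "normalize_to_protein: %d cell(s) with zero protein abundance set to missing",
      sum(zero_cells)))
  }
  ratio <- values / denom
  ratio[zero_cells] <- NA_real_
  values[normalized, ] <- ratio[normalized, , drop = FALSE]
  out <- phospho
  out[, p_samples] <- values
  list(values = out,
       flags = data.frame(analyte_id = phospho$analyte_id,
                          normalized = normalized,
                          stringsAsFactors = FALSE))
}

#' Collapse replicate samples to per-condition values
#'
#' The per-condition value is the arithmetic mean of that condition's
#' replicate channels; missing samples are excluded from the mean.  A
#' condition with no non-missing replicate yields a missing value.
#'
#' @param m quant-like table (`analyte_id` + sample columns).
#' @param design sample-to-condition assignment: named character vector; by
#'   default derived from the `<condition>_<replicate>` column names.
#' @return data frame with `analyte_id` and one column per condition (in
#'   first-appearance order of the design).
#' @export
condition_collapse <- function(m, design = NULL) {
  samples <- quant_matrix_check(m)
  if (is.null(design)) {
    design <- setNames(condition_of(samples), samples)
  }
  if (!all(samples %in% names(design))) {
    stop("configuration error: design does not cover samples: ",
         paste(setdiff(samples, names(design)), collapse = ", "),
         call. = FALSE)
  }
  conditions <- unique(unname(design[samples]))
  values <- as.matrix(m[, samples, drop = FALSE])
  out <- data.frame(analyte_id = m$analyte_id, stringsAsFactors = FALSE)
  for (cond in conditions) {
    cols <- samples[design[samples] == cond]
    out[[cond]] <- rowMeans(values[, cols, drop = FALSE], na.rm = TRUE)
    out[[cond]][is.nan(out[[cond]])] <- NA_real_
  }
  out
}

#' Log2 fold-change contrasts and the chronic-vs-acute differential
#'
#' Computes `log2fc_acute = log2(acute/control)`, `log2fc_chronic =
#' log2(chronic/control)` and their difference, the chronic-vs-acute
#' differential (algebraically `log2(chronic/acute)`).  Analytes with any
#' missing or non-positive condition value yield missing contrasts (no
#' pseudocounts are introduced); their count is reported via a message.
#'
#' @param collapsed per-condition table from [condition_collapse()].
#' @param conditions named character vector giving the column names of the
#'   `control`, `acute` and `chronic` conditions.
#' @return data frame: `site_key` (the analyte id), `log2fc_acute`,
#'   `log2fc_chronic`, `differential`.
#' @export
compute_differentials <- function(collapsed,
                                  conditions = c(control = "control",
                                                 acute = "acute",
                                                 chronic = "chronic")) {
  needed <- c("control", "acute", "chronic")
  if (!all(needed %in% names(conditions))) {
    stop("configuration error: 'conditions' must name control, acute and chronic",
         call. = FALSE)
  }
  missing_cols <- setdiff(unname(conditions[needed]), names(collapsed))
  if (length(missing_cols) > 0L) {
    stop("configuration error: unknown condition label(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ctrl <- collapsed[[conditions[["control"]]]]
  acute <- collapsed[[conditions[["acute"]]]]
  chronic <- collapsed[[conditions[["chronic"]]]]
  ok <- !is.na(ctrl) & !is.na(acute) & !is.na(chronic) &
    ctrl > 0 & acute > 0 & chronic > 0
  if (any(!ok)) {
    message(sprintf(
      "compute_differentials: %d analyte(s) with missing or non-positive condition values",
      sum(!ok)))
  }
  out <- data.frame(
    site_key = collapsed$analyte_id,
    log2fc_acute = ifelse(ok, log2(acute / ctrl), NA_real_),
    log2fc_chronic = ifelse(ok, log2(chronic / ctrl), NA_real_),
    stringsAsFactors = FALSE)
  out$differential <- out$log2fc_chronic - out$log2fc_acute
  out
}
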