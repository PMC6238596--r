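## Readers and writers for the pipeline's tab-separated formats: quant
## tables, reference-site and kinase-substrate datasets (PhosphoSitePlus
## dialect, incl. a tolerated 3-line preamble), group-assignment tables and
## GMT term annotations.

#' Parse modified-residue strings
#'
#' Parses `MOD_RSD`-style strings (`"S235-p"`, `"Y742"`) into residue and
#' 1-based position.  Entries not matching `[STY]<digits>(-p)?` yield `NA`.
#'
#' @param x character vector.
#' @return data frame with `residue` and `position` columns.
#' @export
parse_mod_rsd <- function(x) {
  m <- regmatches(x, regexec("^([STYsty])([0-9]+)(-p)?$", as.character(x)))
  residue <- vapply(m, function(g) {
    if (length(g) == 0L) NA_character_ else toupper(g[2L])
  }, character(1L))
  position <- vapply(m, function(g) {
    if (length(g) == 0L) NA_integer_ else as.integer(g[3L])
  }, integer(1L))
  data.frame(residue = residue, position = position, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  tryCatch(
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ""),
    error = function(e) stop("I/O error writing '", path, "': ",
                             conditionMessage(e), call. = FALSE))
}

#' Read a quant table
#'
#' Tab-separated, header row, `analyte_id` first column, one numeric column
#' per sample named `<condition>_<replicate>`; empty fields are missing
#' values.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_quant_tsv <- function(path) {
  m <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = "")
  quant_matrix_check(m, path)
  m
}

#' Write a quant table
#'
#' @param m quant table.
#' @param path destination.
#' @export
write_quant_tsv <- function(m, path) {
  quant_matrix_check(m)
  write_tsv(m, path)
}

psp_preamble <- function(title) {
  c(title,
    "synthetic dataset generated by the phosflow package",
    "")
}

read_psp_table <- function(path, required) {
  head_lines <- readLines(path, n = 10L, warn = FALSE)
  header_at <- which(vapply(head_lines, function(l) {
    all(vapply(required, grepl, logical(1L), x = l, fixed = TRUE))
  }, logical(1L)))[1L]
  if (is.na(header_at)) {
    stop(sprintf("malformed reference file '%s': no header with columns %s %s",
                 path, paste(required, collapse = ", "),
                 "found in the first 10 lines"), call. = FALSE)
  }
  read.delim(path, skip = header_at - 1L, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = "")
}

#' Read a phosphorylation-site dataset (PhosphoSitePlus dialect)
#'
#' Expects tab-separated columns `GENE`, `PROTEIN`, `ACC_ID`, `ORGANISM`,
#' `MOD_RSD` (`"S235-p"`), `SITE_+/-7_AA`; a preamble of up to a few lines
#' before the header is tolerated, and optional columns may be absent.
#' Rows whose `MOD_RSD` does not parse as `[STY]<digits>(-p)?` are dropped
#' with a message.
#'
#' @param path file path.
#' @return data frame with lower-case parsed columns `gene`, `protein`,
#'   `acc_id`, `organism`, `residue`, `position`, `flank`.
#' @export
read_psp_site_dataset <- function(path) {
  raw <- read_psp_table(path, c("ACC_ID", "MOD_RSD"))
  parsed <- parse_mod_rsd(raw$MOD_RSD)
  bad <- is.na(parsed$residue)
  if (any(bad)) {
    message(sprintf("read_psp_site_dataset: dropped %d row(s) with unparseable MOD_RSD",
                    sum(bad)))
  }
  out <- data.frame(
    gene = (raw$GENE %||% raw$ACC_ID)[!bad],
    protein = (raw$PROTEIN %||% raw$GENE %||% raw$ACC_ID)[!bad],
    acc_id = raw$ACC_ID[!bad],
    organism = (raw$ORGANISM %||% rep(NA_character_, nrow(raw)))[!bad],
    residue = parsed$residue[!bad],
    position = parsed$position[!bad],
    flank = (raw$`SITE_+/-7_AA` %||% rep(NA_character_, nrow(raw)))[!bad],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a phosphorylation-site dataset (PhosphoSitePlus dialect)
#'
#' @param ref reference table from [generate_reference_db()] (columns
#'   `GENE`, `PROTEIN`, `ACC_ID`, `ORGANISM`, `MOD_RSD`, `SITE_+/-7_AA`).
#' @param path destination.
#' @export
write_psp_site_dataset <- function(ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(psp_preamble("Phosphorylation site dataset"), con)
  write.table(ref, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' Read a kinase-substrate dataset (PhosphoSitePlus dialect)
#'
#' Columns `KINASE`, `KIN_ORGANISM`, `SUBSTRATE`, `SUB_ACC_ID`, `SUB_GENE`,
#' `SUB_ORGANISM`, `SUB_MOD_RSD`, `SITE_+/-7_AA`; preamble tolerated.
#'
#' @param path file path.
#' @return data frame (original upper-case columns plus parsed `residue` and
#'   `position`).
#' @export
read_kinase_substrate_dataset <- function(path) {
  raw <- read_psp_table(path, c("KINASE", "SUB_ACC_ID", "SUB_MOD_RSD"))
  parsed <- parse_mod_rsd(raw$SUB_MOD_RSD)
  bad <- is.na(parsed$residue)
  if (any(bad)) {
    message(sprintf(
      "read_kinase_substrate_dataset: dropped %d row(s) with unparseable SUB_MOD_RSD",
      sum(bad)))
  }
  out <- raw[!bad, , drop = FALSE]
  out$residue <- parsed$residue[!bad]
  out$position <- parsed$position[!bad]
  rownames(out) <- NULL
  out
}

#' Write a kinase-substrate dataset (PhosphoSitePlus dialect)
#'
#' @param ks kinase-substrate table from [generate_reference_db()].
#' @param path destination.
#' @export
write_kinase_substrate_dataset <- function(ks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(psp_preamble("Kinase substrate dataset"), con)
  write.table(ks, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

#' Read a group-assignment table
#'
#' Tab-separated columns `key`, `level` (`protein` or `site`), `group`,
#' `color` (hex).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_group_table <- function(path) {
  g <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = "")
  needed <- c("key", "level", "group")
  if (!all(needed %in% names(g))) {
    stop(sprintf("group table '%s' must have columns %s", path,
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (!"color" %in% names(g)) g$color <- NA_character_
  g
}

#' Read a GMT term-annotation file
#'
#' One term per line: term, description, then member identifiers,
#' tab-separated.
#'
#' @param path file path.
#' @return named list of character member vectors; descriptions in
#'   attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop(sprintf("malformed GMT file '%s' at line %d", path, which(bad)[1L]),
         call. = FALSE)
  }
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, "", 1L)
  attr(terms, "description") <- vapply(parts, `[[`, "", 2L)
  terms
}

#' Write a GMT term-annotation file
#'
#' @param terms named list of member vectors.
#' @param path destination.
#' @param description optional per-term descriptions.
#' @export
write_gmt <- function(terms, path, description = NULL) {
  description <- description %||% rep("na", length(terms))
  lines <- vapply(seq_along(terms), function(i) {
    paste(c(names(terms)[i], description[i], terms[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
}
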