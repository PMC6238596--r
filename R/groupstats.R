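## Group-level statistics: functional-group assignment, outlier selection,
## two-sample Kolmogorov-Smirnov scans over functional and kinase-substrate
## groups (Benjamini-Hochberg corrected), and hypergeometric
## over-representation of outlier proteins.

#' Assign functional groups to sites
#'
#' Site-level assignments (key = `accession|residue|position`) win over
#' protein-level assignments (key = accession); keys without any assignment
#' resolve to `"unclassified"`.
#'
#' @param sites per-site records with `accession`, `residue`, `position`.
#' @param table assignment table with columns `key`, `level`
#'   (`"protein"`/`"site"`), `group` and optional `color`
#'   ([read_group_table()]); may be empty.
#' @return `sites` with `group` and `color` columns appended.
#' @export
assign_groups <- function(sites, table = NULL) {
  out <- sites
  out$group <- "unclassified"
  out$color <- NA_character_
  if (is.null(table) || nrow(table) == 0L) return(out)
  stopifnot(all(c("key", "level", "group") %in% names(table)))
  if (!"color" %in% names(table)) table$color <- NA_character_
  conflicts <- tapply(table$group, paste(table$level, table$key),
                      function(g) length(unique(g)) > 1L)
  if (any(conflicts)) {
    stop("conflicting group assignments for key(s): ",
         paste(names(conflicts)[conflicts], collapse = ", "), call. = FALSE)
  }
  table <- table[!duplicated(paste(table$level, table$key)), , drop = FALSE]
  prot <- table[table$level == "protein", , drop = FALSE]
  site <- table[table$level == "site", , drop = FALSE]
  hit_p <- match(out$accession, prot$key)
  ok <- !is.na(hit_p)
  out$group[ok] <- prot$group[hit_p[ok]]
  out$color[ok] <- prot$color[hit_p[ok]]
  skey <- site_key(out$accession, out$residue, out$position)
  hit_s <- match(skey, site$key)
  ok <- !is.na(hit_s)
  out$group[ok] <- site$group[hit_s[ok]]
  out$color[ok] <- site$color[hit_s[ok]]
  out
}

#' Select outlier phospho-events
#'
#' Members strictly exceed the cutoff in absolute value on the chosen
#' contrast (default: the chronic-vs-acute differential, cutoff 1 log2
#' unit); the fraction of sites inside `[-cutoff, +cutoff]` is reported.
#'
#' @param differentials data frame from [compute_differentials()] (or any
#'   table with `site_key` and the chosen contrast column).
#' @param cutoff positive log2 cutoff (default 1).
#' @param field contrast column to threshold (default `"differential"`).
#' @return list with `outliers` (site_key, value, direction),
#'   `inside_fraction` (of sites with a non-missing value), `n_values`,
#'   `cutoff`, `field`.
#' @export
select_outliers <- function(differentials, cutoff = 1.0,
                            field = "differential") {
  if (!field %in% names(differentials)) {
    stop("configuration error: unknown contrast field '", field, "'",
         call. = FALSE)
  }
  cutoff <- check_positive(cutoff, "cutoff")
  value <- differentials[[field]]
  ok <- !is.na(value)
  out <- abs(value) > cutoff & ok
  outliers <- data.frame(
    site_key = differentials$site_key[out],
    value = value[out],
    direction = ifelse(value[out] > 0, "up", "down"),
    stringsAsFactors = FALSE)
  list(outliers = outliers,
       inside_fraction = if (any(ok)) sum(abs(value[ok]) <= cutoff) / sum(ok)
                         else NA_real_,
       n_values = sum(ok),
       cutoff = cutoff,
       field = field)
}

ks_statistic <- function(x, y) {
  ## sup over the pooled points of |ECDF_x - ECDF_y|, right-continuous ECDFs
  pts <- sort(unique(c(x, y)))
  fx <- findInterval(pts, sort(x)) / length(x)
  fy <- findInterval(pts, sort(y)) / length(y)
  max(abs(fx - fy))
}

## upper tail of the Kolmogorov distribution, Q(t) = 2 sum (-1)^{k-1} e^{-2k^2 t^2}
kolmogorov_upper <- function(t) {
  if (t < 0.05) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic D is the supremum over the pooled sample points of the
#' absolute difference between the two right-continuous empirical CDFs.
#' The asymptotic p-value uses the Kolmogorov distribution with effective
#' size `ne = |x||y| / (|x|+|y|)`; the permutation p-value is
#' `(1 + #{permuted D >= observed D}) / (1 + n_perm)`.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode `"asymptotic"` or `"permutation"`.
#' @param n_perm number of permutations (permutation mode; fewer than 100
#'   triggers a warning).
#' @param seed optional RNG seed for the permutation draw.
#' @return list with `D`, `p_value`, `mode`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y, mode = c("asymptotic", "permutation"),
                          n_perm = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) {
    stop("ks_two_sample: both samples must be non-empty", call. = FALSE)
  }
  d <- ks_statistic(x, y)
  if (mode == "asymptotic") {
    ne <- length(x) * length(y) / (length(x) + length(y))
    p <- kolmogorov_upper(sqrt(ne) * d)
  } else {
    if (n_perm < 100L) warning("ks_two_sample: n_perm < 100", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    pooled <- c(x, y)
    n_x <- length(x)
    count <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pooled), n_x)
      if (ks_statistic(pooled[idx], pooled[-idx]) >= d - 1e-12) {
        count <- count + 1L
      }
    }
    p <- (1 + count) / (1 + n_perm)
  }
  list(D = d, p_value = p, mode = mode, n_x = length(x), n_y = length(y))
}

ks_scan_core <- function(values, membership, min_n, mode, n_perm, seed,
                         label_col) {
  labels <- names(membership)
  rows <- lapply(seq_along(membership), function(i) {
    inside <- membership[[i]]
    x <- values[inside]
    y <- values[!inside]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < min_n || length(y) < 1L) return(NULL)
    ks <- ks_two_sample(x, y, mode = mode, n_perm = n_perm,
                        seed = if (is.null(seed)) NULL else seed + i)
    data.frame(label = labels[i], n_in = length(x), n_out = length(y),
               D = ks$D, p_value = ks$p_value, stringsAsFactors = FALSE)
  })
  skipped <- labels[vapply(rows, is.null, logical(1L))]
  if (length(skipped) > 0L) {
    message(sprintf("ks scan: skipped %d group(s) below the minimum size: %s",
                    length(skipped),
                    paste(utils::head(skipped, 8L), collapse = ", ")))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(label = character(0), n_in = integer(0),
                      n_out = integer(0), D = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
    names(out)[1L] <- label_col
    return(out)
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$label), , drop = FALSE]
  names(out)[1L] <- label_col
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov scan over functional groups
#'
#' For every functional group with at least `min_n` sites, tests the group's
#' values (default: chronic-vs-acute differentials) against the complement
#' of all other sites; p-values are Benjamini-Hochberg adjusted across the
#' scan and results are sorted by p.  With `comparison = "pairwise"`, every
#' ordered pair of groups is tested instead.
#'
#' @param differentials data frame with `site_key` and the value column.
#' @param grouped per-site group assignment ([assign_groups()]): `site_key`
#'   or (`accession`,`residue`,`position`) plus `group`.
#' @param mode,n_perm,seed passed to [ks_two_sample()].
#' @param min_n minimum in-group site count (default 5).
#' @param field value column (default `"differential"`).
#' @param exclude group labels never tested as a foreground group (their
#'   sites still count in complements); default `"unclassified"`.
#' @param comparison `"complement"` (each group vs all other sites) or
#'   `"pairwise"` (each pair of groups).
#' @return data frame: `group` (or `group_a`/`group_b`), `n_in`, `n_out`,
#'   `D`, `p_value`, `q_value`.
#' @export
group_ks_scan <- function(differentials, grouped,
                          mode = c("asymptotic", "permutation"),
                          min_n = 5L, n_perm = 1000L, seed = NULL,
                          field = "differential",
                          exclude = "unclassified",
                          comparison = c("complement", "pairwise")) {
  mode <- match.arg(mode)
  comparison <- match.arg(comparison)
  if (!"site_key" %in% names(grouped)) {
    grouped$site_key <- site_key(grouped$accession, grouped$residue,
                                 grouped$position)
  }
  value <- differentials[[field]][match(grouped$site_key,
                                        differentials$site_key)]
  groups <- grouped$group
  testable <- setdiff(unique(groups), exclude)
  if (length(testable) < 2L && comparison == "pairwise") {
    stop("group_ks_scan: fewer than 2 testable groups", call. = FALSE)
  }
  if (length(testable) < 1L) {
    stop("group_ks_scan: no testable groups", call. = FALSE)
  }
  if (comparison == "complement") {
    membership <- lapply(testable, function(g) groups == g)
    names(membership) <- testable
    return(ks_scan_core(value, membership, min_n, mode, n_perm, seed,
                        "group"))
  }
  pairs <- utils::combn(sort(testable), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    x <- value[groups == a & !is.na(value)]
    y <- value[groups == b & !is.na(value)]
    if (length(x) < min_n || length(y) < min_n) return(NULL)
    ks <- ks_two_sample(x, y, mode = mode, n_perm = n_perm,
                        seed = if (is.null(seed)) NULL else seed + j)
    data.frame(group_a = a, group_b = b, n_in = length(x), n_out = length(y),
               D = ks$D, p_value = ks$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    return(data.frame(group_a = character(0), group_b = character(0),
                      n_in = integer(0), n_out = integer(0), D = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov scan over kinase-substrate groups
#'
#' For each kinase with at least `min_n` annotated substrate sites, tests
#' the differentials of its substrate sites against all other sites' values;
#' same minimum-size and Benjamini-Hochberg rules as [group_ks_scan()].
#'
#' @param differentials data frame with `site_key` and the value column.
#' @param pairs kinase-site pairs from [annotate_kinases()] (`kinase`,
#'   `ms_key`).
#' @param background optional site keys (with values in `differentials`)
#'   forming the scan universe; defaults to all sites in `differentials`.
#' @param mode,n_perm,seed passed to [ks_two_sample()].
#' @param min_n minimum substrate-site count (default 5).
#' @param field value column (default `"differential"`).
#' @return data frame: `kinase`, `n_in`, `n_out`, `D`, `p_value`, `q_value`.
#' @export
kinase_ks_scan <- function(differentials, pairs,
                           mode = c("asymptotic", "permutation"),
                           min_n = 5L, n_perm = 1000L, seed = NULL,
                           field = "differential", background = NULL) {
  mode <- match.arg(mode)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("kinase_ks_scan: no kinase annotations", call. = FALSE)
    return(data.frame(kinase = character(0), n_in = integer(0),
                      n_out = integer(0), D = numeric(0),
                      p_value = numeric(0), q_value = numeric(0)))
  }
  keys <- background %||% differentials$site_key
  value <- differentials[[field]][match(keys, differentials$site_key)]
  kinases <- sort(unique(pairs$kinase))
  membership <- lapply(kinases, function(k) {
    keys %in% pairs$ms_key[pairs$kinase == k]
  })
  names(membership) <- kinases
  ks_scan_core(value, membership, min_n, mode, n_perm, seed, "kinase")
}

#' Hypergeometric over-representation
#'
#' For each term, the probability of observing at least `k` foreground hits
#' among `n` foreground proteins drawn from a background of `N` proteins of
#' which `K` carry the term (upper-tail hypergeometric); Benjamini-Hochberg
#' adjusted across tested terms.  Terms with no background member are
#' skipped.
#'
#' @param foreground character vector of foreground identifiers (must be a
#'   subset of `background`).
#' @param background character vector of background identifiers.
#' @param terms named list of member vectors ([read_gmt()]).
#' @return data frame: `term`, `k`, `K`, `n`, `N`, `p_value`, `q_value`,
#'   sorted by p.
#' @export
hypergeometric_enrichment <- function(foreground, background, terms) {
  foreground <- unique(foreground)
  background <- unique(background)
  stray <- setdiff(foreground, background)
  if (length(stray) > 0L) {
    stop("foreground not contained in background: ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  }
  n_bg <- length(background)
  n_fg <- length(foreground)
  rows <- lapply(names(terms), function(term) {
    members <- intersect(terms[[term]], background)
    big_k <- length(members)
    if (big_k == 0L) return(NULL)
    k <- length(intersect(members, foreground))
    p <- phyper(k - 1L, big_k, n_bg - big_k, n_fg, lower.tail = FALSE)
    data.frame(term = term, k = k, K = big_k, n = n_fg, N = n_bg,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
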