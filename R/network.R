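## Kinase-substrate network: build from kinase-annotated sites with
## fold-change and functional-group attributes, export in
## Cytoscape-compatible formats (SIF, GraphML, attribute tables).

#' Build the kinase-substrate network
#'
#' One site node per kinase-annotated matched site (label `GENE_S123`), one
#' kinase node per distinct kinase, one deduplicated edge per (kinase, site)
#' pair carrying the acute log2 fold change and the chronic-vs-acute
#' differential.  Functional-group labels and colors are copied from the
#' group assignment when provided.
#'
#' @param pairs kinase-site pairs from [annotate_kinases()] (`kinase`,
#'   `ms_key`, `gene`, `residue`, `position`).
#' @param differentials site-level contrasts (`site_key`, `log2fc_acute`,
#'   `differential`); sites without a differential produce edges with
#'   missing attributes (reported via a message).
#' @param groups optional per-site assignment ([assign_groups()]) with
#'   `site_key` (or accession/residue/position) plus `group`, `color`.
#' @param collapse_proteins collapse site nodes to one node per protein
#'   (labelled by gene symbol); edges deduplicate accordingly.
#' @return a `ks_network` list with `nodes` (id, kind, label, group, color)
#'   and `edges` (kinase, site, log2fc_acute, differential), both in
#'   canonical sorted order.
#' @export
build_network <- function(pairs, differentials = NULL, groups = NULL,
                          collapse_proteins = FALSE) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(structure(list(
      nodes = data.frame(id = character(0), kind = character(0),
                         label = character(0), group = character(0),
                         color = character(0), stringsAsFactors = FALSE),
      edges = data.frame(kinase = character(0), site = character(0),
                         log2fc_acute = numeric(0),
                         differential = numeric(0),
                         stringsAsFactors = FALSE)),
      class = "ks_network"))
  }
  site_id <- if (collapse_proteins) {
    pairs$gene
  } else {
    paste0(pairs$gene, "_", pairs$residue, pairs$position)
  }
  edges <- data.frame(kinase = pairs$kinase, site = site_id,
                      ms_key = pairs$ms_key, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("kinase", "site")]), , drop = FALSE]
  if (!is.null(differentials)) {
    hit <- match(edges$ms_key, differentials$site_key)
    edges$log2fc_acute <- differentials$log2fc_acute[hit]
    edges$differential <- differentials$differential[hit]
    n_missing <- sum(is.na(edges$log2fc_acute) & is.na(edges$differential))
    if (n_missing > 0L) {
      message(sprintf(
        "build_network: %d edge(s) without fold-change attributes",
        n_missing))
    }
  } else {
    edges$log2fc_acute <- NA_real_
    edges$differential <- NA_real_
  }

  site_nodes <- data.frame(id = edges$site, kind = "site",
                           label = edges$site, ms_key = edges$ms_key,
                           stringsAsFactors = FALSE)
  site_nodes <- site_nodes[!duplicated(site_nodes$id), , drop = FALSE]
  site_nodes$group <- NA_character_
  site_nodes$color <- NA_character_
  if (!is.null(groups)) {
    if (!"site_key" %in% names(groups)) {
      groups$site_key <- site_key(groups$accession, groups$residue,
                                  groups$position)
    }
    hit <- match(site_nodes$ms_key, groups$site_key)
    site_nodes$group <- groups$group[hit]
    if ("color" %in% names(groups)) site_nodes$color <- groups$color[hit]
  }
  kinase_nodes <- data.frame(
    id = sort(unique(edges$kinase)), kind = "kinase",
    label = sort(unique(edges$kinase)),
    group = NA_character_, color = NA_character_,
    stringsAsFactors = FALSE)
  nodes <- rbind(kinase_nodes,
                 site_nodes[, c("id", "kind", "label", "group", "color")])
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  edges <- edges[order(edges$kinase, edges$site),
                 c("kinase", "site", "log2fc_acute", "differential")]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ks_network")
}

#' @export
print.ks_network <- function(x, ...) {
  cat(sprintf("kinase-substrate network: %d node(s) (%d kinase, %d site), %d edge(s)\n",
              nrow(x$nodes), sum(x$nodes$kind == "kinase"),
              sum(x$nodes$kind == "site"), nrow(x$edges)))
  invisible(x)
}

#' Export a network in SIF format
#'
#' One line per edge: `KINASE<TAB>phosphorylates<TAB>SITE`, in canonical
#' (kinase, site) order, so identical networks produce byte-identical files.
#'
#' @param net a `ks_network`.
#' @param path destination.
#' @export
export_sif <- function(net, path) {
  stopifnot(inherits(net, "ks_network"))
  lines <- sprintf("%s\tphosphorylates\t%s", net$edges$kinase,
                   net$edges$site)
  tryCatch(writeLines(lines, path),
           error = function(e) stop("I/O error writing '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Export node and edge attribute tables
#'
#' Writes `node_attributes.tsv` (id, kind, label, group, color) and
#' `edge_attributes.tsv` (kinase, site, log2fc_acute, differential) in
#' canonical order; missing values are empty fields.
#'
#' @param net a `ks_network`.
#' @param dir destination directory (created if needed).
#' @return paths of the two files, invisibly.
#' @export
export_attribute_tables <- function(net, dir) {
  stopifnot(inherits(net, "ks_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  node_path <- file.path(dir, "node_attributes.tsv")
  edge_path <- file.path(dir, "edge_attributes.tsv")
  write_tsv(net$nodes, node_path)
  write_tsv(net$edges, edge_path)
  invisible(c(nodes = node_path, edges = edge_path))
}

graphml_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 15, scientific = FALSE)
  }, character(1L))
}

#' Export a network in GraphML 1.0
#'
#' Node attributes `kind`, `group`, `color` (strings) and edge attributes
#' `log2fc_acute`, `differential` (doubles) are embedded as typed keys;
#' missing attributes omit the data element.  Output is byte-stable for
#' identical networks.
#'
#' @param net a `ks_network`.
#' @param path destination.
#' @export
export_graphml <- function(net, path) {
  stopifnot(inherits(net, "ks_network"))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="kind" for="node" attr.name="kind" attr.type="string"/>',
    '  <key id="group" for="node" attr.name="group" attr.type="string"/>',
    '  <key id="color" for="node" attr.name="color" attr.type="string"/>',
    '  <key id="log2fc_acute" for="edge" attr.name="log2fc_acute" attr.type="double"/>',
    '  <key id="differential" for="edge" attr.name="differential" attr.type="double"/>',
    '  <graph id="kinase_substrate" edgedefault="directed">')
  for (i in seq_len(nrow(net$nodes))) {
    node <- net$nodes[i, ]
    data <- sprintf('      <data key="kind">%s</data>',
                    xml_escape(node$kind))
    if (!is.na(node$group)) {
      data <- c(data, sprintf('      <data key="group">%s</data>',
                              xml_escape(node$group)))
    }
    if (!is.na(node$color)) {
      data <- c(data, sprintf('      <data key="color">%s</data>',
                              xml_escape(node$color)))
    }
    lines <- c(lines,
               sprintf('    <node id="%s">', xml_escape(node$id)),
               data, "    </node>")
  }
  for (i in seq_len(nrow(net$edges))) {
    edge <- net$edges[i, ]
    data <- character(0)
    if (!is.na(edge$log2fc_acute)) {
      data <- c(data, sprintf('      <data key="log2fc_acute">%s</data>',
                              graphml_number(edge$log2fc_acute)))
    }
    if (!is.na(edge$differential)) {
      data <- c(data, sprintf('      <data key="differential">%s</data>',
                              graphml_number(edge$differential)))
    }
    lines <- c(lines,
               sprintf('    <edge source="%s" target="%s">',
                       xml_escape(edge$kinase), xml_escape(edge$site)),
               data, "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("I/O error writing '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a GraphML network export back
#'
#' Inverse of [export_graphml()]; used for round-trip validation.
#'
#' @param path GraphML file.
#' @return a `ks_network`.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  node_nodes <- xml2::xml_find_all(doc, ".//graph/node")
  get_data <- function(node, key) {
    v <- xml2::xml_text(
      xml2::xml_find_first(node, sprintf("./data[@key='%s']", key)))
    if (length(v) == 0L) NA_character_ else v
  }
  nodes <- data.frame(
    id = xml2::xml_attr(node_nodes, "id"),
    kind = vapply(node_nodes, get_data, "", "kind"),
    stringsAsFactors = FALSE)
  nodes$label <- nodes$id
  nodes$group <- vapply(node_nodes, get_data, "", "group")
  nodes$color <- vapply(node_nodes, get_data, "", "color")
  edge_nodes <- xml2::xml_find_all(doc, ".//graph/edge")
  edges <- data.frame(
    kinase = xml2::xml_attr(edge_nodes, "source"),
    site = xml2::xml_attr(edge_nodes, "target"),
    log2fc_acute = as.numeric(vapply(edge_nodes, get_data, "",
                                     "log2fc_acute")),
    differential = as.numeric(vapply(edge_nodes, get_data, "",
                                     "differential")),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$kind, nodes$id), , drop = FALSE]
  edges <- edges[order(edges$kinase, edges$site), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "ks_network")
}
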