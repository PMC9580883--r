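# Graph serialization: GraphML (typed attribute keys), a Cytoscape-style
# JSON dialect, and plain node/edge CSV. All attributes and coordinates are
# preserved; re-reading a GraphML file reproduces the attribute tables.

.graphml_type <- function(col) {
  if (is.logical(col)) "boolean"
  else if (is.integer(col)) "int"
  else if (is.numeric(col)) "double"
  else "string"
}

.merge_coords <- function(network, coordinates) {
  n <- network$nodes
  if (!is.null(coordinates)) {
    m <- match(n$node_id, coordinates$node_id)
    n$x <- coordinates$x[m]
    n$y <- coordinates$y[m]
  }
  n
}

#' Write a styled network to GraphML
#'
#' Produces namespaced GraphML with one typed `<key>` per node/edge
#' attribute column. NA values are omitted (and read back as NA).
#'
#' @param network a `pcpi_network` (styled and annotated as desired).
#' @param file output path.
#' @param coordinates optional layout data.frame ([layout_compartments()]).
#' @return the file path, invisibly.
#' @export
write_graphml <- function(network, file, coordinates = NULL) {
  nodes <- .merge_coords(network, coordinates)
  edges <- network$edges
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  node_attrs <- setdiff(names(nodes), "node_id")
  edge_attrs <- setdiff(names(edges), c("source", "target"))
  for (a in node_attrs) {
    xml2::xml_add_child(doc, "key", id = paste0("n_", a), `for` = "node",
                        attr.name = a, attr.type = .graphml_type(nodes[[a]]))
  }
  for (a in edge_attrs) {
    xml2::xml_add_child(doc, "key", id = paste0("e_", a), `for` = "edge",
                        attr.name = a, attr.type = .graphml_type(edges[[a]]))
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "pcpinet",
                               edgedefault = "directed")
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v) && !is.integer(v)) sprintf("%.17g", v)
    else as.character(v)
  }
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = nodes$node_id[i])
    for (a in node_attrs) {
      v <- nodes[[a]][i]
      if (!is.na(v)) {
        xml2::xml_add_child(nd, "data", fmt(v), key = paste0("n_", a))
      }
    }
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(graph, "edge", source = edges$source[i],
                              target = edges$target[i])
    for (a in edge_attrs) {
      v <- edges[[a]][i]
      if (!is.na(v)) {
        xml2::xml_add_child(ed, "data", fmt(v), key = paste0("e_", a))
      }
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param file GraphML path.
#' @return list with `nodes` and `edges` data.frames (attribute types
#'   restored from the key declarations).
#' @export
read_graphml <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  keytab <- data.frame(
    id = xml2::xml_attr(keys, "id"),
    domain = xml2::xml_attr(keys, "for"),
    name = xml2::xml_attr(keys, "attr.name"),
    type = xml2::xml_attr(keys, "attr.type"),
    stringsAsFactors = FALSE
  )
  cast <- function(v, type) {
    switch(type,
           boolean = as.logical(toupper(v)),
           int = as.integer(v),
           double = as.numeric(v),
           v)
  }
  parse_elems <- function(xpath, domain, id_attrs) {
    elems <- xml2::xml_find_all(doc, xpath, ns)
    kt <- keytab[keytab$domain == domain, , drop = FALSE]
    rows <- lapply(elems, function(el) {
      base <- lapply(id_attrs, function(a) xml2::xml_attr(el, a))
      names(base) <- names(id_attrs)
      data <- xml2::xml_find_all(el, "./g:data", ns)
      vals <- stats::setNames(xml2::xml_text(data),
                              xml2::xml_attr(data, "key"))
      for (j in seq_len(nrow(kt))) {
        raw <- if (kt$id[j] %in% names(vals)) vals[[kt$id[j]]] else NA
        base[[kt$name[j]]] <- cast(raw, kt$type[j])
      }
      as.data.frame(base, stringsAsFactors = FALSE)
    })
    if (length(rows) == 0) return(data.frame())
    do.call(rbind, rows)
  }
  nodes <- parse_elems(".//g:node", "node", c(node_id = "id"))
  edges <- parse_elems(".//g:edge", "edge",
                       c(source = "source", target = "target"))
  list(nodes = nodes, edges = edges)
}

#' Write a styled network as viewer-loadable JSON
#'
#' Elements-format JSON (nodes with a `data` block and a `position`, edges
#' with a `data` block) loadable by common web graph viewers.
#'
#' @inheritParams write_graphml
#' @export
write_cytoscape_json <- function(network, file, coordinates = NULL) {
  nodes <- .merge_coords(network, coordinates)
  edges <- network$edges
  node_list <- lapply(seq_len(nrow(nodes)), function(i) {
    dat <- as.list(nodes[i, setdiff(names(nodes), c("x", "y")), drop = FALSE])
    names(dat)[names(dat) == "node_id"] <- "id"
    dat <- dat[!vapply(dat, function(v) length(v) == 1 && is.na(v),
                       logical(1))]
    el <- list(data = dat)
    if (!is.null(nodes$x) && !is.na(nodes$x[i])) {
      el$position <- list(x = nodes$x[i], y = nodes$y[i])
    }
    el
  })
  edge_list <- lapply(seq_len(nrow(edges)), function(i) {
    dat <- as.list(edges[i, , drop = FALSE])
    dat <- dat[!vapply(dat, function(v) length(v) == 1 && is.na(v),
                       logical(1))]
    dat$id <- sprintf("e%d", i)
    list(data = dat)
  })
  jsonlite::write_json(list(elements = list(nodes = node_list,
                                            edges = edge_list)),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Write the network style legend
#'
#' Human-readable description of every visual channel in the export.
#'
#' @param style a `style_map`.
#' @param file output path.
#' @export
write_style_legend <- function(style, file) {
  lines <- c(
    "pcpinet network style legend",
    "",
    sprintf("Edge width: prediction probability mapped linearly onto [%g, %g] (thicker = more probable)",
            style$edge_width_range[1], style$edge_width_range[2]),
    "Edge colour by interaction type:",
    sprintf("  %-20s %s", names(style$edge_colors), style$edge_colors),
    "Edge line style: glycoside-aglycone dashed, all others solid",
    "",
    "Node shape: ligand = circle, protein = square",
    sprintf("Node opacity: log P mapped linearly onto [%g, %g] (more lipophilic = more opaque)",
            style$node_opacity_range[1], style$node_opacity_range[2]),
    sprintf("Node size: GI absorption high = %g, low = %g; proteins = %g",
            style$node_size_map[["high"]], style$node_size_map[["low"]],
            style$protein_node_size),
    sprintf("Node border colour: Abbott bioavailability score bins low < %g <= medium < %g <= high",
            style$bioavailability_bins[1], style$bioavailability_bins[2]),
    sprintf("  %-8s %s", names(style$border_colors), style$border_colors),
    sprintf("Node fill: ligand class palette (alphabetical); proteins %s",
            style$protein_fill),
    "Label colour by protein function:",
    sprintf("  %-18s %s", names(style$label_colors), style$label_colors)
  )
  writeLines(lines, file)
  invisible(file)
}

#' One-call styled export in every supported format
#'
#' @param network an annotated `pcpi_network`.
#' @param dir output directory (created if needed).
#' @param style a `style_map`.
#' @param geometry optional compartment geometry.
#' @param seed layout seed.
#' @param basename file stem for the exports.
#' @return named character vector of written files, invisibly.
#' @export
export_network <- function(network, dir, style = default_style_map(),
                           geometry = NULL, seed = 1,
                           basename = "network") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  styled <- compute_style(network, style)
  coords <- layout_compartments(styled, geometry = geometry, seed = seed)
  files <- c(
    graphml = file.path(dir, paste0(basename, ".graphml")),
    json = file.path(dir, paste0(basename, ".json")),
    nodes = file.path(dir, paste0(basename, "_nodes.csv")),
    edges = file.path(dir, paste0(basename, "_edges.csv")),
    legend = file.path(dir, paste0(basename, "_legend.txt"))
  )
  write_graphml(styled, files[["graphml"]], coords)
  write_cytoscape_json(styled, files[["json"]], coords)
  with_xy <- styled
  with_xy$nodes <- .merge_coords(styled, coords)
  write_network(with_xy, files[["nodes"]], files[["edges"]])
  write_style_legend(style, files[["legend"]])
  invisible(files)
}
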