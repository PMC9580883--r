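# Typed, directed disease network: ligand and protein nodes; PCPI/DPI,
# signed PPI, and glycoside-aglycone edges.
#
# A pcpi_network is a list(nodes, edges):
#   nodes: node_id, node_kind (ligand/protein), name, ligand_class, role,
#          plus annotation columns added later (compartment, PK, function)
#   edges: source, target, edge_type, probability, provenance

.new_network <- function(nodes, edges) {
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "pcpi_network")
}

.edge_types_ligand <- c("PCPI", "DPI", "glycoside-aglycone")
.edge_types_ppi <- c("PPI-up", "PPI-down", "PPI-other")

#' Assemble the disease interaction network
#'
#' Creates a ligand node for every ligand with at least one disease PCPI and
#' a protein node for every disease target; ligand-to-protein edges are typed
#' `DPI` for control molecules and `PCPI` otherwise. PPI edges are retained
#' only when both endpoints are disease-network proteins (the disease targets
#' act as the join clause on both sides). Glycoside-aglycone edges (directed
#' parent to child) are retained only when both ligands are in the network.
#'
#' @param disease_pcpis data.frame of disease-filtered PCPI records.
#' @param ppis data.frame of causal PPI records ([read_ppi_table()]).
#' @param relations data.frame (`parent_id`, `child_id`) of
#'   glycoside-aglycone pairs.
#' @param registry a `ligand_registry`.
#' @param control_ids ligand ids to type as `DPI`; defaults to registry
#'   records whose role contains "control".
#' @return an (uncleaned) `pcpi_network`.
#' @export
assemble_network <- function(disease_pcpis, ppis = NULL, relations = NULL,
                             registry = NULL, control_ids = NULL) {
  if (nrow(disease_pcpis) == 0) stop_assembly("no disease PCPIs to assemble")
  reg <- if (!is.null(registry)) registry$registry else NULL
  if (!is.null(reg)) {
    unknown <- setdiff(unique(disease_pcpis$ligand_id), reg$ligand_id)
    if (length(unknown)) {
      stop_assembly("PCPI references unknown ligand id(s): %s",
                    paste(unknown, collapse = ", "))
    }
    if (is.null(control_ids)) {
      control_ids <- reg$ligand_id[grepl("control", reg$role)]
    }
  }
  control_ids <- control_ids %||% character(0)

  lig_ids <- unique(disease_pcpis$ligand_id)
  prot_ids <- unique(toupper(disease_pcpis$protein))

  lig_nodes <- data.frame(node_id = lig_ids, node_kind = "ligand",
                          stringsAsFactors = FALSE)
  if (!is.null(reg)) {
    m <- match(lig_ids, reg$ligand_id)
    lig_nodes$name <- reg$name[m]
    lig_nodes$ligand_class <- reg$ligand_class[m]
    lig_nodes$role <- reg$role[m]
  } else {
    lig_nodes$name <- lig_ids
    lig_nodes$ligand_class <- NA_character_
    lig_nodes$role <- NA_character_
  }
  prot_nodes <- data.frame(node_id = prot_ids, node_kind = "protein",
                           name = prot_ids, ligand_class = NA_character_,
                           role = NA_character_, stringsAsFactors = FALSE)
  nodes <- rbind(lig_nodes, prot_nodes)

  pcpi_edges <- data.frame(
    source = disease_pcpis$ligand_id,
    target = toupper(disease_pcpis$protein),
    edge_type = ifelse(disease_pcpis$ligand_id %in% control_ids,
                       "DPI", "PCPI"),
    probability = disease_pcpis$probability,
    provenance = "reverse-screening", stringsAsFactors = FALSE)

  edges <- pcpi_edges
  if (!is.null(ppis) && nrow(ppis) > 0) {
    keep <- toupper(ppis$source) %in% prot_ids &
      toupper(ppis$target) %in% prot_ids
    if (any(!keep)) {
      log_info("assembly: dropped %d PPI row(s) with an endpoint outside the disease targets",
               sum(!keep))
    }
    if (any(keep)) {
      pe <- ppis[keep, , drop = FALSE]
      edges <- rbind(edges, data.frame(
        source = toupper(pe$source), target = toupper(pe$target),
        edge_type = paste0("PPI-", sub("-regulates", "", pe$effect,
                                       fixed = TRUE)),
        probability = NA_real_, provenance = pe$provenance,
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(relations) && nrow(relations) > 0) {
    keep <- relations$parent_id %in% lig_ids & relations$child_id %in% lig_ids
    if (any(!keep)) {
      log_info("assembly: dropped %d glycoside-aglycone relation(s) with a ligand outside the network",
               sum(!keep))
    }
    if (any(keep)) {
      re <- relations[keep, , drop = FALSE]
      edges <- rbind(edges, data.frame(
        source = re$parent_id, target = re$child_id,
        edge_type = "glycoside-aglycone", probability = NA_real_,
        provenance = "hydrolysis", stringsAsFactors = FALSE))
    }
  }
  net <- .new_network(nodes, edges)
  .assert_edge_constraints(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structural edge-type constraints: PCPI/DPI ligand->protein, PPI
# protein->protein, glycoside-aglycone ligand->ligand.
.assert_edge_constraints <- function(net) {
  kind <- stats::setNames(net$nodes$node_kind, net$nodes$node_id)
  e <- net$edges
  sk <- kind[e$source]; tk <- kind[e$target]
  bad <- (e$edge_type %in% c("PCPI", "DPI") &
            !(sk == "ligand" & tk == "protein")) |
    (e$edge_type %in% .edge_types_ppi & !(sk == "protein" & tk == "protein")) |
    (e$edge_type == "glycoside-aglycone" & !(sk == "ligand" & tk == "ligand"))
  if (any(bad, na.rm = TRUE) || anyNA(sk) || anyNA(tk)) {
    stop_assembly("edge-type constraint violated (first offending edge: %s -> %s [%s])",
                  e$source[which(bad | is.na(sk) | is.na(tk))[1]],
                  e$target[which(bad | is.na(sk) | is.na(tk))[1]],
                  e$edge_type[which(bad | is.na(sk) | is.na(tk))[1]])
  }
  invisible(net)
}

#' Clean a network: remove self-loops and duplicate edges
#'
#' Among edges sharing (source, target, edge_type) the edge with the highest
#' probability is kept (ties: first encountered; edges without probability
#' keep the first). Self-loops are removed. Removal counts are logged.
#' Idempotent.
#'
#' @param network a `pcpi_network`.
#' @return the cleaned `pcpi_network`.
#' @export
clean_network <- function(network) {
  e <- network$edges
  n0 <- nrow(e)
  loops <- e$source == e$target
  if (any(loops)) log_info("clean: removed %d self-loop(s)", sum(loops))
  e <- e[!loops, , drop = FALSE]
  # stable keep-max-probability within duplicate groups
  prob <- ifelse(is.na(e$probability), -Inf, e$probability)
  ord <- order(-prob, seq_len(nrow(e)))
  key <- paste(e$source, e$target, e$edge_type, sep = "\r")
  dup <- duplicated(key[ord])
  if (any(dup)) log_info("clean: removed %d duplicate edge(s)", sum(dup))
  e <- e[sort(ord[!dup]), , drop = FALSE]  # keep winners, original order
  net <- network
  net$edges <- e
  rownames(net$edges) <- NULL
  net
}

#' Summarize a network's composition
#'
#' @param network a (cleaned) `pcpi_network`.
#' @return list with `n_nodes`, `n_edges`, `nodes_by_kind`,
#'   `ligands_by_class`, `edges_by_type` (data.frames of counts that
#'   partition the totals exactly).
#' @export
network_summary <- function(network) {
  n <- network$nodes
  e <- network$edges
  tab <- function(x) {
    t <- table(x, useNA = "no")
    data.frame(value = names(t), count = as.integer(t),
               stringsAsFactors = FALSE)
  }
  out <- list(
    n_nodes = nrow(n), n_edges = nrow(e),
    nodes_by_kind = tab(n$node_kind),
    ligands_by_class = tab(n$ligand_class[n$node_kind == "ligand"]),
    edges_by_type = tab(e$edge_type)
  )
  class(out) <- "pcpi_network_summary"
  out
}

#' @export
print.pcpi_network_summary <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d interactions\n", x$n_nodes, x$n_edges))
  cat(" nodes by kind: ",
      paste(sprintf("%s=%d", x$nodes_by_kind$value, x$nodes_by_kind$count),
            collapse = ", "), "\n")
  cat(" edges by type: ",
      paste(sprintf("%s=%d", x$edges_by_type$value, x$edges_by_type$count),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pcpi_network <- function(x, ...) {
  print(network_summary(x))
  invisible(x)
}

#' @export
summary.pcpi_network <- function(object, ...) network_summary(object)

#' Network CSV interchange
#'
#' Lossless node/edge table export and import (all annotation and style
#' attributes included).
#'
#' @param network a `pcpi_network`.
#' @param nodes_file,edges_file CSV paths.
#' @name network_io
#' @export
write_network <- function(network, nodes_file, edges_file) {
  .write_csv_precise(network$nodes, nodes_file)
  .write_csv_precise(network$edges, edges_file)
  invisible(c(nodes_file, edges_file))
}

#' @rdname network_io
#' @export
read_network <- function(nodes_file, edges_file) {
  nodes <- utils::read.csv(nodes_file, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edges_file, stringsAsFactors = FALSE)
  if (!is.null(edges$probability)) {
    edges$probability <- as.numeric(edges$probability)
  }
  .new_network(nodes, edges)
}
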