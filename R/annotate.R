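# Node annotation: subcellular compartments, pharmacokinetics, protein
# function classes.

# Controlled compartment vocabulary with a synonym map harmonizing
# fractionation-map and curated-annotation terms.
.compartment_synonyms <- c(
  "cytosol" = "cytoplasm", "cytoplasmic" = "cytoplasm",
  "nuclear" = "nucleus", "nucleoplasm" = "nucleus",
  "mitochondria" = "mitochondrion", "mitochondrial" = "mitochondrion",
  "pm" = "plasma membrane", "cell membrane" = "plasma membrane",
  "membrane" = "plasma membrane",
  "secreted" = "extracellular", "extracellular space" = "extracellular",
  "extracellular region" = "extracellular",
  "er" = "endoplasmic reticulum"
)

#' Normalize a compartment name to the controlled vocabulary
#' @param x character vector of compartment names.
#' @return normalized lower-case compartment names.
#' @export
normalize_compartment <- function(x) {
  low <- tolower(trimws(x))
  hit <- match(low, names(.compartment_synonyms))
  out <- ifelse(is.na(hit), low, .compartment_synonyms[hit])
  unname(out)
}

# Ligand placement priority: first matching tier wins.
.ligand_priority <- c("nucleus", "mitochondrion", "plasma membrane",
                      "cytoplasm")

#' Assign subcellular compartments to protein nodes
#'
#' Each protein takes its compartment from the primary (fractionation-style)
#' map when present, else from the fallback (curated-annotation) map, else
#' `"other"` with a logged warning. Provenance is recorded per node.
#'
#' @param network a `pcpi_network`.
#' @param primary_map,fallback_map named character vectors keyed by gene
#'   symbol ([read_protein_map()]).
#' @return the network with `compartment` and `compartment_provenance`
#'   columns filled for protein nodes.
#' @export
assign_protein_locations <- function(network, primary_map,
                                     fallback_map = NULL) {
  nodes <- network$nodes
  if (is.null(nodes$compartment)) {
    nodes$compartment <- NA_character_
    nodes$compartment_provenance <- NA_character_
  }
  is_prot <- nodes$node_kind == "protein"
  pm <- stats::setNames(normalize_compartment(primary_map),
                        toupper(names(primary_map)))
  fm <- if (!is.null(fallback_map)) {
    stats::setNames(normalize_compartment(fallback_map),
                    toupper(names(fallback_map)))
  } else character(0)
  unknown <- character(0)
  for (i in which(is_prot)) {
    p <- toupper(nodes$node_id[i])
    if (p %in% names(pm)) {
      nodes$compartment[i] <- pm[[p]]
      nodes$compartment_provenance[i] <- "primary-table"
    } else if (p %in% names(fm)) {
      nodes$compartment[i] <- fm[[p]]
      nodes$compartment_provenance[i] <- "fallback-table"
    } else {
      nodes$compartment[i] <- "other"
      nodes$compartment_provenance[i] <- "unmapped"
      unknown <- c(unknown, p)
    }
  }
  if (length(unknown)) {
    log_warn("no compartment for %d protein(s), assigned 'other': %s",
             length(unknown), paste(unknown, collapse = ", "))
  }
  network$nodes <- nodes
  network
}

#' Place one ligand from its targets' compartments
#'
#' The four-tier priority rule: a ligand with any target in the nucleus goes
#' to the nucleus; else mitochondrion; else plasma membrane; else cytoplasm.
#' When no tier matches, the plurality compartment among the targets is used
#' (ties broken alphabetically) with provenance `"plurality-fallback"`.
#'
#' @param target_compartments character vector (multiset) of the compartments
#'   of the ligand's own targets.
#' @return list with `compartment` and `provenance`.
#' @export
assign_ligand_location <- function(target_compartments) {
  if (length(target_compartments) == 0) {
    stop_annotation("ligand has no targets to derive a location from")
  }
  comps <- normalize_compartment(target_compartments)
  for (tier in .ligand_priority) {
    if (tier %in% comps) {
      return(list(compartment = tier, provenance = "ligand-priority-rule"))
    }
  }
  tab <- table(comps)
  best <- sort(names(tab)[tab == max(tab)])[1]
  list(compartment = best, provenance = "plurality-fallback")
}

#' Assign compartments to all ligand nodes
#'
#' Applies [assign_ligand_location()] to every ligand node using the
#' compartments of its PCPI/DPI targets in the network. Protein nodes must
#' already carry compartments.
#'
#' @param network a `pcpi_network` with protein compartments assigned.
#' @return the network with ligand compartments filled.
#' @export
assign_ligand_locations <- function(network) {
  nodes <- network$nodes
  e <- network$edges
  comp <- stats::setNames(nodes$compartment, nodes$node_id)
  for (i in which(nodes$node_kind == "ligand")) {
    lid <- nodes$node_id[i]
    tgt <- e$target[e$source == lid & e$edge_type %in% c("PCPI", "DPI")]
    if (length(tgt) == 0) {
      stop_annotation("ligand '%s' has no protein targets in the network", lid)
    }
    a <- assign_ligand_location(comp[tgt])
    nodes$compartment[i] <- a$compartment
    nodes$compartment_provenance[i] <- a$provenance
  }
  network$nodes <- nodes
  network
}

#' Attach pharmacokinetic attributes to ligand nodes
#'
#' Adds `bioavailability`, `gi_absorption` and `logp` columns to ligand
#' nodes. Ligands without a matching record get NA attributes and a warning;
#' protein nodes are untouched.
#'
#' @param network a `pcpi_network`.
#' @param pk data.frame from [read_adme_table()] (must carry `ligand_id`).
#' @return the annotated network.
#' @export
annotate_pharmacokinetics <- function(network, pk) {
  nodes <- network$nodes
  nodes$bioavailability <- NA_real_
  nodes$gi_absorption <- NA_character_
  nodes$logp <- NA_real_
  is_lig <- nodes$node_kind == "ligand"
  m <- match(nodes$node_id, pk$ligand_id)
  sel <- is_lig & !is.na(m)
  nodes$bioavailability[sel] <- pk$bioavailability[m[sel]]
  nodes$gi_absorption[sel] <- pk$gi_absorption[m[sel]]
  nodes$logp[sel] <- pk$logp[m[sel]]
  missing <- nodes$node_id[is_lig & is.na(m)]
  if (length(missing)) {
    log_warn("no pharmacokinetic data for %d ligand(s): %s",
             length(missing), paste(missing, collapse = ", "))
  }
  network$nodes <- nodes
  network
}

#' Attach protein function classes
#'
#' Maps proteins to `oncogene`, `tumor suppressor` or `other` (the default
#' for unmapped proteins). Drives label colouring in the visual export.
#'
#' @param network a `pcpi_network`.
#' @param function_map named character vector keyed by gene symbol.
#' @return the annotated network.
#' @export
annotate_protein_function <- function(network, function_map = character(0)) {
  nodes <- network$nodes
  nodes$protein_function <- NA_character_
  is_prot <- nodes$node_kind == "protein"
  fm <- stats::setNames(tolower(trimws(function_map)),
                        toupper(names(function_map)))
  vals <- unname(fm[toupper(nodes$node_id[is_prot])])
  vals[is.na(vals) | !vals %in% c("oncogene", "tumor suppressor")] <- "other"
  nodes$protein_function[is_prot] <- vals
  network$nodes <- nodes
  network
}
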