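# Simulated metabolism: hydrolysis of O-glycosidic bonds.
#
# A saccharide ring is a 5- or 6-membered ring with exactly one ring oxygen,
# all other ring atoms carbon, and at least two ring carbons bearing hydroxyl
# or hydroxymethyl substituents. The anomeric carbon is a ring carbon adjacent
# to the ring oxygen. An O-glycosidic bond is the bond between an anomeric
# carbon and an exocyclic oxygen whose other neighbour is a carbon outside
# that ring. Cleavage removes the anomeric C-O bond and caps the anomeric
# carbon with a new hydroxyl oxygen (net addition of one water per bond); the
# bridging oxygen stays with the partner fragment. C- and N-glycosides are
# deliberately not cleaved.

# Bond order between atoms a and b (0 when not bonded).
.bond_order <- function(g, a, b) {
  hit <- (g$bonds$from == a & g$bonds$to == b) |
    (g$bonds$from == b & g$bonds$to == a)
  if (any(hit)) g$bonds$order[hit][1] else 0L
}

# All bonds of an atom are single (excludes aromatic/carbonyl carbons).
.is_saturated <- function(g, a) {
  ords <- g$bonds$order[g$bonds$from == a | g$bonds$to == a]
  length(ords) == 0 || all(ords == 1L)
}

# Perceive saccharide rings. Returns list of list(ring, ring_o, anomeric).
# A true hydroxyl is a degree-1 oxygen attached by a single bond (a carbonyl
# oxygen is degree 1 but double-bonded, and must not count); anomeric
# candidates are restricted to saturated ring carbons so that aromatic
# oxygen heterocycles (chromones, furans) are never mistaken for sugars.
.saccharide_rings <- function(g) {
  adj <- .adjacency(g)
  deg <- .heavy_degree(g)
  is_hydroxyl <- function(at, o) {
    g$elements[o] == "O" && deg[o] == 1L && .bond_order(g, at, o) == 1L
  }
  out <- list()
  for (ring in .oxygen_rings(g)) {
    els <- g$elements[ring]
    if (sum(els == "O") != 1L || !all(els %in% c("C", "O"))) next
    ring_o <- ring[els == "O"]
    ring_c <- ring[els == "C"]
    # count ring carbons with hydroxyl (-OH) or hydroxymethyl (-CH2OH)
    n_hydroxy <- 0L
    for (c_at in ring_c) {
      exo <- setdiff(adj[[c_at]], ring)
      has <- any(vapply(exo, function(o) is_hydroxyl(c_at, o), logical(1)))
      if (!has) {
        for (e in exo[g$elements[exo] == "C"]) {
          if (any(vapply(adj[[e]], function(o) is_hydroxyl(e, o),
                         logical(1)))) {
            has <- TRUE
            break
          }
        }
      }
      if (has) n_hydroxy <- n_hydroxy + 1L
    }
    if (n_hydroxy < 2L) next
    anomeric <- intersect(adj[[ring_o]], ring_c)
    anomeric <- anomeric[vapply(anomeric, function(a) .is_saturated(g, a),
                                logical(1))]
    if (length(anomeric) == 0) next
    out[[length(out) + 1L]] <- list(ring = ring, ring_o = ring_o,
                                    anomeric = anomeric)
  }
  out
}

# Find glycosidic bonds. Returns data.frame(anomeric, oxygen) of atom indices.
.glycosidic_bonds <- function(g) {
  adj <- .adjacency(g)
  res <- data.frame(anomeric = integer(), oxygen = integer())
  for (sac in .saccharide_rings(g)) {
    for (a in sac$anomeric) {
      for (o in setdiff(adj[[a]], sac$ring)) {
        if (g$elements[o] != "O" || .bond_order(g, a, o) != 1L) next
        partner <- setdiff(adj[[o]], a)
        ok <- vapply(partner, function(p) {
          g$elements[p] == "C" && !(p %in% sac$ring) &&
            .bond_order(g, o, p) == 1L
        }, logical(1))
        if (any(ok)) res <- rbind(res, data.frame(anomeric = a, oxygen = o))
      }
    }
  }
  unique(res)
}

# Cleave one glycosidic bond in place: drop bond (a, o), attach a new
# hydroxyl oxygen to the anomeric carbon.
.cleave_bond <- function(g, a, o) {
  keep <- !((g$bonds$from == a & g$bonds$to == o) |
              (g$bonds$from == o & g$bonds$to == a))
  g$bonds <- g$bonds[keep, , drop = FALSE]
  g$elements <- c(g$elements, "O")
  g$coords <- rbind(g$coords, g$coords[a, ] + c(0.35, 0.35, 0))
  g$charges <- c(g$charges, 0L)
  g$bonds <- rbind(g$bonds, data.frame(from = a, to = length(g$elements),
                                       order = 1L, stereo = 0L))
  g
}

# Is a fragment (mol_graph) sugar-only? True when it contains at least one
# ring, and every ring atom lies in a saccharide ring.
.is_sugar_fragment <- function(g) {
  in_ring <- .ring_atoms(g)
  if (length(in_ring) == 0) return(FALSE)
  sac_atoms <- unique(unlist(lapply(.saccharide_rings(g), `[[`, "ring")))
  all(in_ring %in% sac_atoms)
}

.subgraph <- function(g, atoms) {
  idx <- match(seq_along(g$elements), atoms)
  b <- g$bonds[g$bonds$from %in% atoms & g$bonds$to %in% atoms, , drop = FALSE]
  list(elements = g$elements[atoms],
       coords = g$coords[atoms, , drop = FALSE],
       bonds = data.frame(from = idx[b$from], to = idx[b$to],
                          order = b$order, stereo = b$stereo),
       charges = g$charges[atoms])
}

#' Simulate hydrolysis of O-glycosidic bonds
#'
#' Cleaves every O-glycosidic bond in a molecule, capping each cleavage site
#' with a hydroxyl (one water added per bond). With `exhaustive = TRUE`
#' (default) cleavage repeats until no glycosidic bond remains, emulating
#' complete metabolic deglycosylation. Products are canonicalized; identical
#' products are collapsed with a multiplicity count.
#'
#' @param smiles a single SMILES string (the glycoside, or any molecule).
#' @param exhaustive logical; repeat cleavage to completion.
#' @return list with elements `parent` (canonical SMILES), `bonds_cleaved`
#'   (integer), and `products`, a data.frame with columns `smiles`, `kind`
#'   ("aglycone" or "sugar") and `count` (multiplicity). `products` has zero
#'   rows when no glycosidic bond is present.
#' @examples
#' \dontrun{
#' hydrolyze_glycosides("OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O")  # salicin
#' }
#' @export
hydrolyze_glycosides <- function(smiles, exhaustive = TRUE) {
  if (length(smiles) != 1L) stop_input("hydrolyze_glycosides takes one SMILES")
  g <- mol_graph(smiles)
  parent_can <- g$smiles
  total <- 0L
  repeat {
    gb <- .glycosidic_bonds(g)
    if (nrow(gb) == 0) break
    # one cleavage per bridging oxygen per pass (a trehalose-type oxygen
    # linking two anomeric carbons is cleaved on one side only; the second
    # side no longer matches once the first is capped)
    gb <- gb[!duplicated(gb$oxygen), , drop = FALSE]
    for (i in seq_len(nrow(gb))) {
      g <- .cleave_bond(g, gb$anomeric[i], gb$oxygen[i])
      total <- total + 1L
    }
    if (!exhaustive) break
  }
  if (total == 0L) {
    return(list(parent = parent_can, bonds_cleaved = 0L,
                products = data.frame(smiles = character(),
                                      kind = character(),
                                      count = integer())))
  }
  frags <- lapply(.components(g), function(atoms) {
    fg <- .subgraph(g, atoms)
    data.frame(smiles = .graph_to_smiles(fg),
               kind = if (.is_sugar_fragment(fg)) "sugar" else "aglycone",
               stringsAsFactors = FALSE)
  })
  prod <- do.call(rbind, frags)
  agg <- stats::aggregate(list(count = rep(1L, nrow(prod))),
                          by = prod[c("smiles", "kind")], FUN = sum)
  agg <- agg[order(agg$kind, agg$smiles), c("smiles", "kind", "count")]
  rownames(agg) <- NULL
  list(parent = parent_can, bonds_cleaved = total, products = agg)
}
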