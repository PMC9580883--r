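#' Canonicalize a SMILES string
#'
#' Converts any valid SMILES encoding of a molecule to a single canonical
#' form, so that two encodings of the same molecular graph compare equal as
#' strings. Canonicalization is delegated to OpenBabel (via ChemmineOB); the
#' output is idempotent (canonical input maps to itself).
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_structure("C1=CC=CC=C1") == canonicalize_structure("c1ccccc1")
#' }
#' @export
canonicalize_structure <- function(smiles) {
  if (!is.character(smiles)) stop_parse("smiles must be a character vector")
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      stop_parse("cannot canonicalize empty/NA SMILES")
    }
    out <- .ob_convert("SMI", "CAN", s)
    if (!nzchar(out)) stop_parse("unparseable SMILES: '%s'", s)
    out
  }, character(1), USE.NAMES = FALSE)
}

# OpenBabel conversion with title/whitespace stripped. Returns "" on failure
# (OpenBabel reports the reason on stderr).
.ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, text),
                  error = function(e) "")
  out <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  if (is.na(out)) return("")
  # SMILES output is "smiles<TAB>title"
  trimws(strsplit(out, "\t", fixed = TRUE)[[1]][1])
}

#' @rdname canonicalize_structure
#' @export
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(FALSE)
    nzchar(.ob_convert("SMI", "CAN", s))
  }, logical(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Molecular graph representation used by the hydrolysis engine.
#
# A mol_graph is a plain list:
#   elements : character, element symbol per atom (no explicit hydrogens)
#   coords   : numeric matrix n x 3
#   bonds    : data.frame(from, to, order, stereo) with 1-based atom indices
# Built from the OpenBabel SDF rendering of a SMILES; written back to a V2000
# molfile when fragments are re-exported to SMILES.

mol_graph <- function(smiles) {
  can <- canonicalize_structure(smiles)
  sdf_text <- .ob_convert_full("SMI", "SDF", smiles)
  if (!nzchar(sdf_text)) stop_parse("unparseable SMILES: '%s'", smiles)
  .parse_molfile(sdf_text, can)
}

.ob_convert_full <- function(from, to, text) {
  tryCatch(ChemmineOB::convertFormat(from, to, text), error = function(e) "")
}

.parse_molfile <- function(text, smiles = NA_character_) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop_parse("truncated molfile")
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || is.na(nbonds)) stop_parse("bad molfile counts line")
  atom_lines <- lines[seq_len(natoms) + 4L]
  elements <- trimws(substr(atom_lines, 32, 34))
  coords <- cbind(
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30))
  )
  if (nbonds > 0) {
    bond_lines <- lines[seq_len(nbonds) + 4L + natoms]
    bonds <- data.frame(
      from = as.integer(substr(bond_lines, 1, 3)),
      to = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9)),
      stereo = as.integer(substr(bond_lines, 10, 12))
    )
    bonds$stereo[is.na(bonds$stereo)] <- 0L
  } else {
    bonds <- data.frame(from = integer(), to = integer(),
                        order = integer(), stereo = integer())
  }
  # formal charges from M  CHG property lines
  charges <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)),
                                "\\s+")[[1]])
    if (length(flds) >= 2) {
      idx <- flds[seq(1, length(flds), by = 2)]
      chg <- flds[seq(2, length(flds), by = 2)]
      charges[idx] <- chg
    }
  }
  list(elements = elements, coords = coords, bonds = bonds,
       charges = charges, smiles = smiles)
}

# Serialize a mol_graph back to a V2000 molfile (for fragment -> SMILES).
.write_molfile <- function(g) {
  n <- length(g$elements)
  b <- g$bonds
  header <- c("", " pcpinet", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   g$coords[, 1], g$coords[, 2], g$coords[, 3], g$elements)
  bonds <- if (nrow(b)) {
    sprintf("%3d%3d%3d%3d  0  0  0", b$from, b$to, b$order, b$stereo)
  } else character(0)
  chg <- which(g$charges != 0)
  chg_lines <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, g$charges[chg]), collapse = ""))
  } else character(0)
  paste(c(header, atoms, bonds, chg_lines, "M  END", "$$$$"), collapse = "\n")
}

# Canonical SMILES of a mol_graph (via molfile round trip).
.graph_to_smiles <- function(g) {
  out <- .ob_convert("SDF", "CAN", .write_molfile(g))
  if (!nzchar(out)) stop_parse("internal: fragment failed to re-parse")
  out
}

#' Count heavy (non-hydrogen) atoms in a molecule
#'
#' @param smiles character vector of SMILES strings.
#' @return integer vector of heavy-atom counts.
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    g <- mol_graph(s)
    sum(g$elements != "H")
  }, integer(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# Graph helpers

.adjacency <- function(g) {
  n <- length(g$elements)
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$from[i]; b <- g$bonds$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.heavy_degree <- function(g) {
  n <- length(g$elements)
  deg <- integer(n)
  tab <- table(c(g$bonds$from, g$bonds$to))
  deg[as.integer(names(tab))] <- as.integer(tab)
  deg
}

# Connected components as a list of atom index vectors.
.components <- function(g) {
  n <- length(g$elements)
  if (n == 0) return(list())
  gi <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(g$bonds)) {
    gi <- igraph::add_edges(gi, rbind(g$bonds$from, g$bonds$to))
  }
  comp <- igraph::components(gi)
  split(seq_len(n), comp$membership)
}

# Atoms belonging to any cycle (the 2-core of the heavy-atom graph).
.ring_atoms <- function(g) {
  n <- length(g$elements)
  if (n == 0 || nrow(g$bonds) == 0) return(integer(0))
  gi <- igraph::make_empty_graph(n, directed = FALSE)
  gi <- igraph::add_edges(gi, rbind(g$bonds$from, g$bonds$to))
  which(igraph::coreness(gi) >= 2)
}

# Enumerate simple rings of size 5 or 6 that contain at least one oxygen.
# Saccharide rings always contain a ring oxygen, so anchoring the search at
# O atoms is sufficient for glycoside perception. Returns a list of integer
# vectors (ring atom sets, in cycle order starting at the anchor oxygen).
.oxygen_rings <- function(g, sizes = c(5L, 6L)) {
  adj <- .adjacency(g)
  ox <- which(g$elements == "O")
  found <- list()
  seen <- character(0)
  maxlen <- max(sizes)
  for (o in ox) {
    # DFS over simple paths from o of length <= maxlen
    stack <- list(o)
    while (length(stack)) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      for (nb in adj[[last]]) {
        if (nb == o && length(path) %in% sizes) {
          key <- paste(sort(path), collapse = ",")
          if (!(key %in% seen)) {
            seen <- c(seen, key)
            found[[length(found) + 1L]] <- path
          }
        } else if (!(nb %in% path) && length(path) < maxlen && nb > 0) {
          stack[[length(stack) + 1L]] <- c(path, nb)
        }
      }
    }
  }
  found
}
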