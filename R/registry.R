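# Ligand registry: compile, canonicalize, deduplicate, simulate metabolism.

.slugify <- function(x) {
  s <- tolower(trimws(x))
  s <- gsub("[^a-z0-9]+", "-", s)
  s <- gsub("^-+|-+$", "", s)
  ifelse(nzchar(s), s, "ligand")
}

.unique_id <- function(base, taken) {
  if (!(base %in% taken)) return(base)
  i <- 2L
  while (sprintf("%s-%d", base, i) %in% taken) i <- i + 1L
  sprintf("%s-%d", base, i)
}

# Derive a class label for a metabolite record from its parent's class.
.aglycone_class <- function(parent_class) {
  if (is.na(parent_class) || !nzchar(parent_class)) return("aglycone")
  if (grepl("glycoside", parent_class, ignore.case = TRUE)) {
    sub("glycosides?", "aglycone", parent_class, ignore.case = TRUE)
  } else {
    paste(parent_class, "aglycone")
  }
}

#' Build a ligand registry from a raw ligand table
#'
#' Canonicalizes every structure, merges rows encoding the same molecule
#' (first-seen name becomes primary, later names become synonyms), simulates
#' glycoside hydrolysis on every entry, registers novel non-sugar products as
#' aglycone records with `parent_id` set, and records one glycoside-aglycone
#' relation per aglycone. Sugar fragments are never registered.
#'
#' @param raw_ligands data.frame with columns `name`, `smiles`, `class`,
#'   `role` (role one of phytochemical, positive-control, negative-control),
#'   or the path of a CSV file with those headers.
#' @param exhaustive logical; hydrolyze glycosidic bonds to completion
#'   (default) rather than a single pass.
#' @return an object of class `ligand_registry`: a list with `registry`
#'   (data.frame: ligand_id, name, smiles, ligand_class, role, parent_id,
#'   synonyms) and `relations` (data.frame: parent_id, child_id).
#' @export
build_registry <- function(raw_ligands, exhaustive = TRUE) {
  if (is.character(raw_ligands) && length(raw_ligands) == 1L) {
    raw_ligands <- read_ligand_table(raw_ligands)
  }
  req <- c("name", "smiles", "class", "role")
  if (!all(req %in% names(raw_ligands))) {
    stop_input("ligand table must have columns %s", paste(req, collapse = ", "))
  }
  n <- nrow(raw_ligands)
  if (n == 0) stop_input("ligand table is empty")

  can <- character(n)
  for (i in seq_len(n)) {
    can[i] <- tryCatch(canonicalize_structure(raw_ligands$smiles[i]),
                       error = function(e) {
                         stop_parse("row %d ('%s'): %s", i,
                                    raw_ligands$name[i], conditionMessage(e))
                       })
  }

  # merge duplicates by canonical structure
  reg <- data.frame(ligand_id = character(), name = character(),
                    smiles = character(), ligand_class = character(),
                    role = character(), parent_id = character(),
                    synonyms = character(), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    j <- match(can[i], reg$smiles)
    if (is.na(j)) {
      id <- .unique_id(.slugify(raw_ligands$name[i]), reg$ligand_id)
      reg <- rbind(reg, data.frame(
        ligand_id = id, name = trimws(raw_ligands$name[i]), smiles = can[i],
        ligand_class = raw_ligands$class[i], role = raw_ligands$role[i],
        parent_id = NA_character_, synonyms = "", stringsAsFactors = FALSE))
    } else {
      nm <- trimws(raw_ligands$name[i])
      if (!identical(nm, reg$name[j]) &&
          !nm %in% strsplit(reg$synonyms[j], ";", fixed = TRUE)[[1]]) {
        reg$synonyms[j] <- if (nzchar(reg$synonyms[j])) {
          paste(reg$synonyms[j], nm, sep = ";")
        } else nm
      }
      pcpi_log("debug", "merged duplicate structure '%s' into '%s'",
               nm, reg$name[j])
    }
  }
  n_merged <- n - nrow(reg)
  if (n_merged > 0) log_info("merged %d duplicate structure(s)", n_merged)

  # simulate metabolism; queue includes newly added records
  relations <- data.frame(parent_id = character(), child_id = character(),
                          stringsAsFactors = FALSE)
  i <- 1L
  while (i <= nrow(reg)) {
    hy <- hydrolyze_glycosides(reg$smiles[i], exhaustive = exhaustive)
    if (hy$bonds_cleaved > 0) {
      agl <- hy$products[hy$products$kind == "aglycone", , drop = FALSE]
      for (k in seq_len(nrow(agl))) {
        j <- match(agl$smiles[k], reg$smiles)
        if (is.na(j)) {
          id <- .unique_id(.slugify(paste(reg$name[i], "aglycone")),
                           reg$ligand_id)
          reg <- rbind(reg, data.frame(
            ligand_id = id, name = paste(reg$name[i], "aglycone"),
            smiles = agl$smiles[k],
            ligand_class = .aglycone_class(reg$ligand_class[i]),
            role = reg$role[i], parent_id = reg$ligand_id[i],
            synonyms = "", stringsAsFactors = FALSE))
          j <- nrow(reg)
        } else if (is.na(reg$parent_id[j])) {
          reg$parent_id[j] <- reg$ligand_id[i]
        }
        pair <- data.frame(parent_id = reg$ligand_id[i],
                           child_id = reg$ligand_id[j],
                           stringsAsFactors = FALSE)
        if (!any(relations$parent_id == pair$parent_id &
                   relations$child_id == pair$child_id)) {
          relations <- rbind(relations, pair)
        }
      }
      log_info("hydrolyzed '%s': %d bond(s), %d aglycone product(s)",
               reg$name[i], hy$bonds_cleaved, nrow(agl))
    }
    i <- i + 1L
  }
  if (anyDuplicated(reg$ligand_id)) {
    stop_registry("duplicate ligand_id in registry")
  }
  rownames(reg) <- NULL
  structure(list(registry = reg, relations = relations),
            class = "ligand_registry")
}

#' @export
print.ligand_registry <- function(x, ...) {
  r <- x$registry
  cat(sprintf("Ligand registry: %d records (%d with a glycoside parent), %d glycoside-aglycone relation(s)\n",
              nrow(r), sum(!is.na(r$parent_id)), nrow(x$relations)))
  cls <- table(r$ligand_class)
  for (k in names(cls)) cat(sprintf("  %-28s %d\n", k, cls[[k]]))
  invisible(x)
}

#' Resolve ligand names to registry ids
#'
#' Exact case-insensitive match on primary name, then on synonyms. No fuzzy
#' matching. Unresolved names return `NA`.
#'
#' @param names character vector of ligand names.
#' @param registry a `ligand_registry`.
#' @return character vector of ligand ids (NA where unresolved).
#' @export
resolve_ligand_ids <- function(names, registry) {
  reg <- registry$registry
  low <- tolower(trimws(names))
  prim <- match(low, tolower(reg$name))
  syn_map <- lapply(strsplit(reg$synonyms, ";", fixed = TRUE), tolower)
  vapply(seq_along(low), function(i) {
    if (!is.na(prim[i])) return(reg$ligand_id[prim[i]])
    hit <- which(vapply(syn_map, function(s) low[i] %in% s, logical(1)))
    if (length(hit)) reg$ligand_id[hit[1]] else NA_character_
  }, character(1))
}

#' Read and write ligand/registry tables
#'
#' `read_ligand_table` reads the raw input CSV (`name,smiles,class,role`);
#' `write_registry` / `read_registry` round-trip the compiled registry and
#' its glycoside-aglycone relation list.
#'
#' @param file path of a CSV file.
#' @name registry_io
#' @export
read_ligand_table <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  req <- c("name", "smiles", "class", "role")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop_dialect("ligand CSV %s lacks column(s): %s", file,
                 paste(miss, collapse = ", "))
  }
  df[req]
}

#' @rdname registry_io
#' @param registry a `ligand_registry`.
#' @param registry_file,relations_file output CSV paths.
#' @export
write_registry <- function(registry, registry_file, relations_file) {
  .write_csv_precise(registry$registry, registry_file)
  .write_csv_precise(registry$relations, relations_file)
  invisible(c(registry_file, relations_file))
}

#' @rdname registry_io
#' @export
read_registry <- function(registry_file, relations_file) {
  reg <- utils::read.csv(registry_file, stringsAsFactors = FALSE,
                         colClasses = "character")
  rel <- utils::read.csv(relations_file, stringsAsFactors = FALSE,
                         colClasses = "character")
  reg$parent_id[reg$parent_id == ""] <- NA_character_
  if (is.null(reg$synonyms)) reg$synonyms <- ""
  reg$synonyms[is.na(reg$synonyms)] <- ""
  structure(list(registry = reg, relations = rel), class = "ligand_registry")
}
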