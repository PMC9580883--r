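# Table dialect readers/writers for the external tools the pipeline consumes
# and the pipeline's own interchange CSVs. All files are UTF-8 with "." as
# the decimal separator. Numeric columns are written with %.17g so that a
# read -> write -> read round trip reproduces values bit-exactly.

.write_csv_precise <- function(df, file) {
  out <- df
  for (k in names(out)) {
    if (is.numeric(out[[k]]) && !is.integer(out[[k]])) {
      v <- sprintf("%.17g", out[[k]])
      v[is.na(out[[k]])] <- NA
      out[[k]] <- v
    }
  }
  utils::write.csv(out, file, row.names = FALSE, na = "")
  invisible(file)
}

# Resolve one logical column against a header-alias table.
# Exact match after whitespace strip, case-insensitive.
.resolve_col <- function(headers, aliases, what, file, required = TRUE) {
  idx <- match(tolower(trimws(aliases)), tolower(trimws(headers)))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    if (!required) return(NA_integer_)
    stop_dialect("%s: no '%s' column (expected one of: %s); found: %s",
                 file, what, paste(aliases, collapse = ", "),
                 paste(headers, collapse = ", "))
  }
  idx[1]
}

#' Read a reverse-screening target-prediction table
#'
#' Parses the per-ligand CSV dialect of reverse-screening tools (one file per
#' query molecule, with target name, optional UniProt accession, and a
#' prediction probability column). Rows with probability zero are dropped
#' (and counted in the log); rows with probability in (0, 1] become records.
#'
#' @param file CSV path.
#' @param ligand_id registry id of the query molecule the file belongs to.
#' @return data.frame with columns `ligand_id`, `protein` (gene symbol,
#'   upper-cased), `uniprot_id`, `probability`.
#' @export
read_target_predictions <- function(file, ligand_id) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  h <- names(df)
  i_tgt <- .resolve_col(h, c("Common name", "common_name", "Target", "protein",
                             "Gene name"), "target name", file)
  i_prb <- .resolve_col(h, c("Probability*", "Probability", "probability"),
                        "probability", file)
  i_uni <- .resolve_col(h, c("Uniprot ID", "UniProt", "uniprot_id", "uniprot"),
                        "uniprot", file, required = FALSE)
  if (nrow(df) == 0) {
    log_warn("%s: header-only prediction file (no rows)", file)
    return(data.frame(ligand_id = character(), protein = character(),
                      uniprot_id = character(), probability = numeric()))
  }
  prob <- suppressWarnings(as.numeric(df[[i_prb]]))
  bad <- which(is.na(prob) | prob < 0 | prob > 1)
  if (length(bad)) {
    stop_value("%s: probability outside [0,1] (or non-numeric) at row %d",
               file, bad[1])
  }
  dropped <- sum(prob == 0)
  if (dropped > 0) {
    log_info("%s: dropped %d zero-probability row(s)", file, dropped)
  }
  keep <- prob > 0
  res <- data.frame(
    ligand_id = ligand_id,
    protein = toupper(trimws(as.character(df[[i_tgt]][keep]))),
    uniprot_id = if (!is.na(i_uni)) trimws(as.character(df[[i_uni]][keep]))
                 else NA_character_,
    probability = prob[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(res) == 0) log_warn("%s: no nonzero-probability predictions", file)
  res
}

#' Read a causal protein-protein interaction table
#'
#' Parses the tab-separated causal-PPI dialect (entity A/B names and types
#' plus a free-text effect). Only rows where both entities are proteins are
#' retained; effect strings containing "up-regulates" / "down-regulates" map
#' to the signed categories, anything else to "other".
#'
#' @param file TSV path.
#' @return data.frame with columns `source`, `target` (gene symbols,
#'   upper-cased), `effect` (up-regulates/down-regulates/other),
#'   `provenance`.
#' @export
read_ppi_table <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  h <- names(df)
  i_a <- .resolve_col(h, c("ENTITYA", "Entity A", "entity_a", "source"),
                      "entity A", file)
  i_b <- .resolve_col(h, c("ENTITYB", "Entity B", "entity_b", "target"),
                      "entity B", file)
  i_ta <- .resolve_col(h, c("TYPEA", "Type A", "type_a"), "type A", file)
  i_tb <- .resolve_col(h, c("TYPEB", "Type B", "type_b"), "type B", file)
  i_ef <- .resolve_col(h, c("EFFECT", "Effect", "effect"), "effect", file)
  i_mc <- .resolve_col(h, c("MECHANISM", "Mechanism"), "mechanism", file,
                       required = FALSE)
  i_pm <- .resolve_col(h, c("PMID", "pmid"), "pmid", file, required = FALSE)
  i_pv <- .resolve_col(h, c("PROVENANCE", "provenance"), "provenance", file,
                       required = FALSE)
  if (nrow(df) == 0) {
    return(data.frame(source = character(), target = character(),
                      effect = character(), provenance = character()))
  }
  is_prot <- tolower(trimws(df[[i_ta]])) == "protein" &
    tolower(trimws(df[[i_tb]])) == "protein"
  if (any(!is_prot)) {
    log_info("%s: dropped %d non protein-protein row(s)", file, sum(!is_prot))
  }
  df <- df[is_prot, , drop = FALSE]
  eff <- tolower(df[[i_ef]])
  effect <- ifelse(grepl("down-regulates", eff), "down-regulates",
                   ifelse(grepl("up-regulates", eff), "up-regulates", "other"))
  if (!is.na(i_pv)) {
    prov <- df[[i_pv]]
  } else {
    prov <- df[[i_ef]]
    if (!is.na(i_mc)) prov <- paste0(prov, "|", df[[i_mc]])
    if (!is.na(i_pm)) prov <- paste0(prov, "|", df[[i_pm]])
  }
  data.frame(source = toupper(trimws(df[[i_a]])),
             target = toupper(trimws(df[[i_b]])),
             effect = effect, provenance = prov, stringsAsFactors = FALSE)
}

#' Read an ADME property table
#'
#' Parses the pharmacokinetics CSV dialect (molecule name, Abbott
#' bioavailability score in \[0,1\], categorical GI absorption, log P).
#' Molecule names are matched to registry ids case-insensitively (primary
#' name, then synonyms); unmatched names are kept with `ligand_id = NA` and
#' a warning.
#'
#' @param file CSV path.
#' @param registry optional `ligand_registry` used to resolve names.
#' @return data.frame with columns `ligand_id`, `name`, `bioavailability`,
#'   `gi_absorption` ("high"/"low"), `logp`.
#' @export
read_adme_table <- function(file, registry = NULL) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  h <- names(df)
  i_nm <- .resolve_col(h, c("Molecule", "Name", "Compound", "molecule"),
                       "molecule name", file)
  i_ba <- .resolve_col(h, c("Bioavailability Score", "Bioavailability",
                            "Abbott Bioavailability Score"),
                       "bioavailability", file)
  i_gi <- .resolve_col(h, c("GI absorption", "GI Absorption",
                            "Gastrointestinal absorption", "gi_absorption"),
                       "GI absorption", file)
  i_lp <- .resolve_col(h, c("Consensus Log P", "log P", "logP", "logp",
                            "XLOGP3", "iLOGP"), "log P", file)
  df <- unique(df)
  gi <- tolower(trimws(df[[i_gi]]))
  bad <- which(!gi %in% c("high", "low"))
  if (length(bad)) {
    stop_value("%s: GI absorption must be High or Low, got '%s' at row %d",
               file, df[[i_gi]][bad[1]], bad[1])
  }
  ba <- suppressWarnings(as.numeric(df[[i_ba]]))
  badba <- which(is.na(ba) | ba < 0 | ba > 1)
  if (length(badba)) {
    stop_value("%s: bioavailability score outside [0,1] at row %d",
               file, badba[1])
  }
  nm <- trimws(as.character(df[[i_nm]]))
  lid <- if (!is.null(registry)) resolve_ligand_ids(nm, registry)
         else NA_character_
  if (!is.null(registry) && anyNA(lid)) {
    log_warn("%s: %d molecule name(s) not resolvable to a ligand id (%s)",
             file, sum(is.na(lid)),
             paste(utils::head(nm[is.na(lid)], 5), collapse = ", "))
  }
  out <- data.frame(ligand_id = lid, name = nm, bioavailability = ba,
                    gi_absorption = gi,
                    logp = suppressWarnings(as.numeric(df[[i_lp]])),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Read a docking-result table
#'
#' @param file CSV with columns `ligand_id`, `protein`, `energy` (kcal/mol,
#'   more negative = stronger), `probability` (the matching prediction
#'   probability in (0, 1\]).
#' @return data.frame of docking records.
#' @export
read_docking_table <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  h <- names(df)
  i_l <- .resolve_col(h, c("ligand_id", "ligand"), "ligand id", file)
  i_p <- .resolve_col(h, c("protein", "target"), "protein", file)
  i_e <- .resolve_col(h, c("energy", "docking energy", "E"), "energy", file)
  i_q <- .resolve_col(h, c("probability", "P"), "probability", file)
  e <- suppressWarnings(as.numeric(df[[i_e]]))
  p <- suppressWarnings(as.numeric(df[[i_q]]))
  if (any(!is.finite(e))) {
    stop_value("%s: non-finite docking energy at row %d", file,
               which(!is.finite(e))[1])
  }
  if (any(is.na(p) | p <= 0 | p > 1)) {
    stop_value("%s: probability outside (0,1] at row %d", file,
               which(is.na(p) | p <= 0 | p > 1)[1])
  }
  data.frame(ligand_id = trimws(df[[i_l]]),
             protein = toupper(trimws(df[[i_p]])),
             energy = e, probability = p, stringsAsFactors = FALSE)
}

#' Read/write GMT pathway gene sets
#'
#' GMT: one gene set per line, tab-separated: id, description, then member
#' gene symbols (upper-cased on read).
#'
#' @param file GMT path.
#' @return list of gene sets, each `list(pathway_id, description, genes)`.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop_dialect("%s: GMT line with fewer than 3 fields", file)
    genes <- unique(toupper(trimws(f[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop_dialect("%s: empty gene set '%s'", file, f[1])
    list(pathway_id = f[1], description = f[2], genes = genes)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "pathway_id")
  sets
}

#' @rdname read_gmt
#' @param sets a list of gene sets as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, file) {
  lines <- vapply(sets, function(s) {
    paste(c(s$pathway_id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read a simple protein lookup table
#'
#' Used for protein-to-compartment (`protein,compartment`) and
#' protein-to-function (`protein,function`) maps. Returns a named character
#' vector keyed by upper-cased gene symbol. When a value lists several
#' entries separated by ";" the first is taken (and logged).
#'
#' @param file CSV path with two columns.
#' @param value_col name of the value column.
#' @return named character vector.
#' @export
read_protein_map <- function(file, value_col = "compartment") {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  h <- tolower(trimws(names(df)))
  i_p <- .resolve_col(names(df), c("protein", "gene", "symbol"), "protein", file)
  i_v <- .resolve_col(names(df), c(value_col, "value", "function"),
                      value_col, file)
  val <- trimws(as.character(df[[i_v]]))
  multi <- grepl(";", val, fixed = TRUE)
  if (any(multi)) {
    log_info("%s: %d multi-valued entr(ies); taking the first value",
             file, sum(multi))
    val[multi] <- trimws(vapply(strsplit(val[multi], ";", fixed = TRUE),
                                `[[`, character(1), 1))
  }
  stats::setNames(val, toupper(trimws(df[[i_p]])))
}

#' Write pipeline interchange tables
#'
#' Writers for the pipeline's own record lists; the matching readers accept
#' the written dialect, so write -> read round-trips are identity.
#'
#' @param df a record data.frame.
#' @param file output path.
#' @name table_writers
#' @export
write_pcpi_table <- function(df, file) .write_csv_precise(df, file)

#' @rdname table_writers
#' @export
write_ppi_table <- function(df, file) {
  out <- data.frame(ENTITYA = df$source, TYPEA = "protein",
                    ENTITYB = df$target, TYPEB = "protein",
                    EFFECT = df$effect, PROVENANCE = df$provenance,
                    stringsAsFactors = FALSE)
  utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname table_writers
#' @export
write_adme_table <- function(df, file) {
  out <- data.frame(
    "Molecule" = df$name,
    "Bioavailability Score" = df$bioavailability,
    "GI absorption" = df$gi_absorption,
    "Consensus Log P" = df$logp,
    check.names = FALSE, stringsAsFactors = FALSE)
  .write_csv_precise(out, file)
}

#' @rdname table_writers
#' @export
write_docking_table <- function(df, file) .write_csv_precise(df, file)

#' Read back a pipeline PCPI table written by [write_pcpi_table()]
#' @param file CSV path.
#' @return data.frame of PCPI records.
#' @export
read_pcpi_table <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  df$probability <- as.numeric(df$probability)
  df
}
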