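# Over-representation analysis of predicted targets against pathway gene
# sets, and restriction of PCPIs to a chosen disease pathway.

#' Hypergeometric over-representation test across pathway gene sets
#'
#' For each gene set the one-sided upper-tail hypergeometric probability of
#' drawing at least the observed overlap is computed (drawing `|targets|`
#' genes from the background without replacement), then adjusted across all
#' tested sets with the Benjamini-Hochberg step-up. Gene sets are intersected
#' with the background before testing; gene symbols are upper-cased.
#'
#' @param targets character vector of predicted target gene symbols.
#' @param gene_sets list of gene sets as returned by [read_gmt()].
#' @param background character vector of background gene symbols; defaults to
#'   the union of all genes in `gene_sets`.
#' @param alpha significance threshold on the adjusted p-value (default 0.05).
#' @param keep_all return all tested sets rather than only significant ones.
#' @return data.frame sorted by adjusted p: `pathway_id`, `description`,
#'   `n_overlap`, `p_value`, `adjusted_p`, `overlap` (semicolon-joined gene
#'   symbols).
#' @export
overrepresentation_test <- function(targets, gene_sets, background = NULL,
                                    alpha = 0.05, keep_all = FALSE) {
  if (length(gene_sets) == 0) stop_input("no gene sets supplied")
  if (is.null(background)) {
    background <- unique(unlist(lapply(gene_sets, `[[`, "genes")))
  }
  background <- unique(toupper(trimws(background)))
  targets <- unique(toupper(trimws(targets)))
  if (length(background) == 0) stop_input("empty background")
  if (length(targets) == 0) stop_input("empty target list")
  outside <- setdiff(targets, background)
  if (length(outside)) {
    log_warn("%d target(s) outside the background were dropped: %s",
             length(outside), paste(utils::head(outside, 5), collapse = ", "))
    targets <- intersect(targets, background)
    if (length(targets) == 0) stop_input("no targets inside the background")
  }
  N <- length(background)
  n <- length(targets)
  rows <- lapply(gene_sets, function(s) {
    genes <- intersect(toupper(s$genes), background)
    ov <- sort(intersect(targets, genes))
    k <- length(ov)
    K <- length(genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = s$pathway_id, description = s$description,
               n_overlap = k, p_value = p,
               overlap = paste(ov, collapse = ";"), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$adjusted_p, res$p_value, res$pathway_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res <- res[c("pathway_id", "description", "n_overlap", "p_value",
               "adjusted_p", "overlap")]
  if (!keep_all) res <- res[res$adjusted_p <= alpha, , drop = FALSE]
  res
}

#' Restrict PCPIs to a disease pathway's intersected proteins
#'
#' Keeps exactly those PCPI records whose protein is in the overlap set
#' (the pathway genes intersected with the predicted targets). Ligands with
#' no surviving record simply disappear from downstream stages.
#'
#' @param pcpis data.frame of PCPI records (`ligand_id`, `protein`,
#'   `probability`, ...).
#' @param pathway a single gene set (`list(pathway_id, description, genes)`).
#' @param overlap character vector of gene symbols; must be a subset of the
#'   pathway's genes.
#' @return the filtered PCPI data.frame.
#' @export
filter_to_pathway <- function(pcpis, pathway, overlap) {
  overlap <- unique(toupper(trimws(overlap)))
  if (!all(overlap %in% toupper(pathway$genes))) {
    stop_input("overlap contains genes outside pathway '%s'",
               pathway$pathway_id)
  }
  out <- pcpis[toupper(pcpis$protein) %in% overlap, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    log_warn("no PCPIs left after filtering to pathway '%s'",
             pathway$pathway_id)
  } else {
    log_info("pathway filter '%s': kept %d of %d PCPI(s)",
             pathway$pathway_id, nrow(out), nrow(pcpis))
  }
  out
}

#' Write enrichment results to CSV
#' @param results data.frame from [overrepresentation_test()].
#' @param file output path.
#' @export
write_enrichment <- function(results, file) .write_csv_precise(results, file)
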