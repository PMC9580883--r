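# Docking-based confidence calibration.
#
# Calibration logic: among interactions whose prediction probability equals
# 1 (structures already recorded in the bioactivity database underlying the
# reverse screen), the most negative docking energy defines the soft cutoff,
# and the upper bound of the mean +/- k_hard * SD band (99.7% for k = 3)
# defines the hard cutoff. Docking confidence classes: high (E below soft),
# medium (between), low (E at/above hard). Probability confidence regions are
# then derived from the docking classes: the upper bound of the low-class
# mean probability (mean + k_prob * SD, 68% for k = 1) is the high-confidence
# probability threshold, and the lower bound of the medium-class mean is the
# low-confidence threshold.

.sd_fun <- function(x, sd_type) {
  if (length(x) <= 1) return(0)
  if (sd_type == "sample") stats::sd(x)
  else sqrt(mean((x - mean(x))^2))
}

#' Calibrate docking-energy cutoffs
#'
#' @param dockings data.frame of docking records (`energy`, `probability`).
#' @param k_hard CI width multiplier for the hard cutoff (3 corresponds to a
#'   99.7% band under normality).
#' @param sd_type "population" (divide by n, the default) or "sample"
#'   (divide by n - 1).
#' @return list with `soft_cutoff` (most negative probability-1 energy) and
#'   `hard_cutoff` (probability-1 mean energy + `k_hard` * SD), kcal/mol.
#' @export
compute_docking_cutoffs <- function(dockings, k_hard = 3,
                                    sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  e1 <- dockings$energy[dockings$probability == 1]
  if (length(e1) == 0) {
    stop_calibration(paste0(
      "no probability-1 docking records to calibrate on; ",
      "supply explicit cutoffs via the `cutoffs` argument/config"))
  }
  soft <- min(e1)
  hard <- mean(e1) + k_hard * .sd_fun(e1, sd_type)
  list(soft_cutoff = soft, hard_cutoff = hard)
}

#' Classify docking confidence
#'
#' High: E strictly below the soft cutoff; medium: soft <= E < hard;
#' low: E at or above the hard cutoff. Boundary energies fall in the weaker
#' class (conservative triage).
#'
#' @param energy numeric vector, kcal/mol.
#' @param model a `confidence_model`, or a list with `soft_cutoff` and
#'   `hard_cutoff`.
#' @return character vector in {"high","medium","low"}.
#' @export
classify_docking_confidence <- function(energy, model) {
  soft <- model$soft_cutoff
  hard <- model$hard_cutoff
  ifelse(energy < soft, "high", ifelse(energy < hard, "medium", "low"))
}

#' Calibrate probability-confidence region thresholds
#'
#' @param classified data.frame with `probability` and `docking_confidence`.
#' @param k_prob CI width multiplier (1 corresponds to a 68% band).
#' @param sd_type see [compute_docking_cutoffs()].
#' @return list with `prob_high_threshold` (low-class mean probability +
#'   `k_prob` * SD) and `prob_low_threshold` (medium-class mean - `k_prob` *
#'   SD).
#' @export
compute_probability_regions <- function(classified, k_prob = 1,
                                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  p_low <- classified$probability[classified$docking_confidence == "low"]
  p_med <- classified$probability[classified$docking_confidence == "medium"]
  if (length(p_low) == 0 || length(p_med) == 0) {
    stop_calibration(paste0(
      "need non-empty low and medium docking-confidence groups; ",
      "supply explicit thresholds via `prob_thresholds`"))
  }
  list(
    prob_high_threshold = mean(p_low) + k_prob * .sd_fun(p_low, sd_type),
    prob_low_threshold = mean(p_med) - k_prob * .sd_fun(p_med, sd_type)
  )
}

#' Classify probability confidence
#'
#' High: P strictly above the high threshold; low: P at or below the low
#' threshold; uncertain otherwise. Boundary probabilities fall in the lower
#' region.
#'
#' @param probability numeric vector in (0, 1].
#' @param model a `confidence_model`, or a list with `prob_high_threshold`
#'   and `prob_low_threshold`.
#' @return character vector in {"high","uncertain","low"}.
#' @export
classify_probability_confidence <- function(probability, model) {
  hi <- model$prob_high_threshold
  lo <- model$prob_low_threshold
  ifelse(probability > hi, "high",
         ifelse(probability <= lo, "low", "uncertain"))
}

#' Fit a docking-confidence calibration model
#'
#' Computes the soft/hard docking-energy cutoffs from the probability-1
#' docking records, classifies every docking record, and derives the
#' probability-confidence region thresholds from the medium and low docking
#' classes. Either calibration step can be bypassed with explicit values
#' (needed when reproducing published thresholds without the underlying
#' docking table).
#'
#' @param dockings data.frame of docking records ([read_docking_table()]).
#' @param k_hard,k_prob CI width multipliers (defaults 3 and 1).
#' @param sd_type "population" (default) or "sample" SD.
#' @param cutoffs optional list/vector with `soft_cutoff`, `hard_cutoff` to
#'   bypass docking calibration.
#' @param prob_thresholds optional list/vector with `prob_high_threshold`,
#'   `prob_low_threshold` to bypass region calibration.
#' @return object of class `confidence_model` with the thresholds, the
#'   classified records (`$classified`), and the fitting parameters.
#' @seealso [predict.confidence_model()], [extract_high_confidence_subnetwork()]
#' @export
confidence_model <- function(dockings = NULL, k_hard = 3, k_prob = 1,
                             sd_type = c("population", "sample"),
                             cutoffs = NULL, prob_thresholds = NULL) {
  sd_type <- match.arg(sd_type)
  if (is.null(cutoffs)) {
    if (is.null(dockings)) {
      stop_calibration("either dockings or explicit cutoffs are required")
    }
    cutoffs <- compute_docking_cutoffs(dockings, k_hard, sd_type)
  } else {
    cutoffs <- as.list(cutoffs)
  }
  if (cutoffs$soft_cutoff > cutoffs$hard_cutoff) {
    stop_calibration("soft cutoff (%g) must not exceed hard cutoff (%g)",
                     cutoffs$soft_cutoff, cutoffs$hard_cutoff)
  }
  classified <- NULL
  if (!is.null(dockings) && nrow(dockings) > 0) {
    classified <- dockings
    classified$docking_confidence <-
      classify_docking_confidence(dockings$energy, cutoffs)
  }
  if (is.null(prob_thresholds)) {
    if (is.null(classified)) {
      stop_calibration("either dockings or explicit prob_thresholds are required")
    }
    prob_thresholds <- compute_probability_regions(classified, k_prob, sd_type)
  } else {
    prob_thresholds <- as.list(prob_thresholds)
  }
  if (prob_thresholds$prob_high_threshold <=
        prob_thresholds$prob_low_threshold) {
    stop_calibration("prob_high_threshold must exceed prob_low_threshold")
  }
  model <- structure(list(
    soft_cutoff = cutoffs$soft_cutoff,
    hard_cutoff = cutoffs$hard_cutoff,
    prob_high_threshold = prob_thresholds$prob_high_threshold,
    prob_low_threshold = prob_thresholds$prob_low_threshold,
    k_hard = k_hard, k_prob = k_prob, sd_type = sd_type,
    n = if (is.null(dockings)) 0L else nrow(dockings),
    classified = NULL, call = match.call()
  ), class = "confidence_model")
  if (!is.null(classified)) {
    classified$probability_confidence <-
      classify_probability_confidence(classified$probability, model)
    model$classified <- classified
  }
  model
}

#' @export
print.confidence_model <- function(x, digits = 4, ...) {
  cat("Docking-confidence calibration model\n")
  cat(sprintf("  soft cutoff: %s kcal/mol (high docking confidence below)\n",
              format(x$soft_cutoff, digits = digits)))
  cat(sprintf("  hard cutoff: %s kcal/mol (low docking confidence at/above)\n",
              format(x$hard_cutoff, digits = digits)))
  cat(sprintf("  probability thresholds: high > %s, low <= %s\n",
              format(x$prob_high_threshold, digits = digits),
              format(x$prob_low_threshold, digits = digits)))
  cat(sprintf("  fitted on %d docking record(s); k_hard = %g, k_prob = %g, %s SD\n",
              x$n, x$k_hard, x$k_prob, x$sd_type))
  invisible(x)
}

#' @export
coef.confidence_model <- function(object, ...) {
  c(soft_cutoff = object$soft_cutoff, hard_cutoff = object$hard_cutoff,
    prob_high_threshold = object$prob_high_threshold,
    prob_low_threshold = object$prob_low_threshold)
}

#' @export
summary.confidence_model <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$classified)) {
    cl <- object$classified
    grp <- split(cl, cl$docking_confidence)
    out$groups <- do.call(rbind, lapply(names(grp), function(g) {
      data.frame(docking_confidence = g, n = nrow(grp[[g]]),
                 mean_energy = mean(grp[[g]]$energy),
                 mean_probability = mean(grp[[g]]$probability),
                 sd_probability = .sd_fun(grp[[g]]$probability,
                                          object$sd_type),
                 stringsAsFactors = FALSE)
    }))
    out$probability_regions <- table(cl$probability_confidence)
  }
  class(out) <- "summary.confidence_model"
  out
}

#' @export
print.summary.confidence_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$groups)) {
    cat("\nDocking-confidence groups:\n")
    print(x$groups, row.names = FALSE)
  }
  invisible(x)
}

#' Classify new interactions with a fitted calibration model
#'
#' @param object a `confidence_model`.
#' @param newdata data.frame with `energy` and/or `probability` columns.
#' @param type "both" (default), "docking", or "probability".
#' @param ... unused.
#' @return `newdata` with `docking_confidence` and/or
#'   `probability_confidence` columns appended.
#' @export
predict.confidence_model <- function(object, newdata,
                                     type = c("both", "docking",
                                              "probability"), ...) {
  type <- match.arg(type)
  out <- newdata
  if (type %in% c("both", "docking")) {
    if (is.null(newdata$energy)) stop_input("newdata lacks an energy column")
    out$docking_confidence <-
      classify_docking_confidence(newdata$energy, object)
  }
  if (type %in% c("both", "probability")) {
    if (is.null(newdata$probability)) {
      stop_input("newdata lacks a probability column")
    }
    out$probability_confidence <-
      classify_probability_confidence(newdata$probability, object)
  }
  out
}

#' Extract the high-confidence subnetwork
#'
#' Keeps ligand-protein edges that dock with high confidence or carry
#' prediction probability 1; keeps the nodes incident to the surviving
#' ligand-protein edges, the PPI edges among surviving proteins, and
#' glycoside-aglycone edges among surviving ligands. The result is always a
#' node- and edge-subset of the input.
#'
#' @param network a cleaned, annotated `pcpi_network`.
#' @param classified data.frame with `ligand_id`, `protein`,
#'   `docking_confidence` (e.g. `model$classified`).
#' @param model the fitted `confidence_model` (used when `classified` is
#'   omitted).
#' @return the simplified `pcpi_network`.
#' @export
extract_high_confidence_subnetwork <- function(network, classified = NULL,
                                               model = NULL) {
  if (is.null(classified)) {
    if (is.null(model) || is.null(model$classified)) {
      stop_input("supply classified interactions or a fitted model")
    }
    classified <- model$classified
  }
  e <- network$edges
  is_lp <- e$edge_type %in% c("PCPI", "DPI")
  key <- paste(e$source, e$target, sep = "\r")
  ckey <- paste(classified$ligand_id, toupper(classified$protein), sep = "\r")
  dock <- classified$docking_confidence[match(key, ckey)]
  keep_lp <- is_lp & ((!is.na(dock) & dock == "high") |
                        (!is.na(e$probability) & e$probability == 1))
  keep_nodes <- unique(c(e$source[keep_lp], e$target[keep_lp]))
  kind <- stats::setNames(network$nodes$node_kind, network$nodes$node_id)
  keep_prot <- keep_nodes[kind[keep_nodes] == "protein"]
  keep_lig <- keep_nodes[kind[keep_nodes] == "ligand"]
  keep_ppi <- e$edge_type %in% .edge_types_ppi &
    e$source %in% keep_prot & e$target %in% keep_prot
  keep_rel <- e$edge_type == "glycoside-aglycone" &
    e$source %in% keep_lig & e$target %in% keep_lig
  out <- network
  out$edges <- e[keep_lp | keep_ppi | keep_rel, , drop = FALSE]
  out$nodes <- network$nodes[network$nodes$node_id %in% keep_nodes, ,
                             drop = FALSE]
  rownames(out$edges) <- NULL
  rownames(out$nodes) <- NULL
  log_info("high-confidence subnetwork: %d of %d nodes, %d of %d edges",
           nrow(out$nodes), nrow(network$nodes),
           nrow(out$edges), nrow(network$edges))
  out
}

#' Write classified interactions and the model config block
#'
#' @param model a fitted `confidence_model`.
#' @param file CSV path for the classified interactions.
#' @export
write_classified_interactions <- function(model, file) {
  if (is.null(model$classified)) stop_input("model carries no classified records")
  .write_csv_precise(model$classified, file)
  invisible(file)
}

#' @rdname write_classified_interactions
#' @export
write_confidence_config <- function(model, file) {
  lines <- c(
    "# docking-confidence calibration",
    sprintf("soft_cutoff: %.17g", model$soft_cutoff),
    sprintf("hard_cutoff: %.17g", model$hard_cutoff),
    sprintf("prob_high_threshold: %.17g", model$prob_high_threshold),
    sprintf("prob_low_threshold: %.17g", model$prob_low_threshold),
    sprintf("k_hard: %g", model$k_hard),
    sprintf("k_prob: %g", model$k_prob),
    sprintf("sd_type: %s", model$sd_type)
  )
  writeLines(lines, file)
  invisible(file)
}
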