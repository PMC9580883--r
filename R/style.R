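# Visual-channel mapping. Channel assignments follow the published legend:
# edge width from prediction probability (thicker = more probable); edge
# colour from interaction type (PCPI/DPI blue, PPI up green, PPI down red,
# glycoside-aglycone dark green dashed, other PPI neutral grey); ligands are
# circles coloured by class, proteins pink squares; node opacity from log P
# (more lipophilic = more opaque), node size from GI absorption, border
# colour from bioavailability bins, label colour from protein function.
# Concrete numbers and the class palette are package defaults, fully
# overridable through the style map.

#' Default style map
#'
#' @param edge_width_range numeric length 2; widths mapped linearly from
#'   probability 0..1.
#' @param node_opacity_range numeric length 2 in \[0,1\]; mapped linearly
#'   from the observed log P range.
#' @param node_size_map named numeric, sizes for high/low GI absorption.
#' @param bioavailability_bins numeric length 2, upper edges of the low and
#'   medium Abbott-score bins.
#' @return a `style_map` list; see the source for all channels.
#' @export
default_style_map <- function(edge_width_range = c(1, 8),
                              node_opacity_range = c(0.3, 1),
                              node_size_map = c(high = 40, low = 20),
                              bioavailability_bins = c(0.35, 0.7)) {
  structure(list(
    edge_width_range = edge_width_range,
    ppi_edge_width = edge_width_range[1],
    edge_colors = c("PCPI" = "#1f78b4", "DPI" = "#1f78b4",
                    "PPI-up" = "#33a02c", "PPI-down" = "#e31a1c",
                    "PPI-other" = "#888888",
                    "glycoside-aglycone" = "#006400"),
    edge_line_style = c("PCPI" = "solid", "DPI" = "solid",
                        "PPI-up" = "solid", "PPI-down" = "solid",
                        "PPI-other" = "solid",
                        "glycoside-aglycone" = "dashed"),
    node_shape = c(ligand = "circle", protein = "square"),
    node_opacity_range = node_opacity_range,
    node_size_map = node_size_map,
    protein_node_size = 30,
    bioavailability_bins = bioavailability_bins,
    border_colors = c(low = "#d73027", medium = "#fc8d59", high = "#1a9850"),
    protein_fill = "#f4a6c6",
    ligand_class_palette = c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3",
                             "#a6d854", "#ffd92f", "#e5c494", "#b3b3b3",
                             "#1b9e77", "#d95f02"),
    label_colors = c("oncogene" = "#ff0000", "tumor suppressor" = "#008000",
                     "other" = "#000000")
  ), class = "style_map")
}

#' Attach visual attributes to an annotated network
#'
#' Adds `vis_*` columns to nodes and edges. Probability maps linearly onto
#' the width range; log P maps linearly from the observed ligand range onto
#' the opacity range; missing PK attributes map to the channel minimum and
#' are flagged in `vis_pk_missing`.
#'
#' @param network an annotated `pcpi_network`.
#' @param style a `style_map` ([default_style_map()]).
#' @return the styled network.
#' @export
compute_style <- function(network, style = default_style_map()) {
  e <- network$edges
  n <- network$nodes
  unknown <- setdiff(unique(e$edge_type), names(style$edge_colors))
  if (length(unknown)) {
    stop_style("no style defined for edge type(s): %s",
               paste(unknown, collapse = ", "))
  }
  wr <- style$edge_width_range
  e$vis_width <- ifelse(
    e$edge_type %in% c("PCPI", "DPI") & !is.na(e$probability),
    wr[1] + e$probability * (wr[2] - wr[1]),
    style$ppi_edge_width)
  e$vis_color <- unname(style$edge_colors[e$edge_type])
  e$vis_line_style <- unname(style$edge_line_style[e$edge_type])

  n$vis_shape <- unname(style$node_shape[n$node_kind])
  is_lig <- n$node_kind == "ligand"

  # fill: ligand class palette (alphabetical class order), protein pink
  classes <- sort(unique(n$ligand_class[is_lig & !is.na(n$ligand_class)]))
  pal <- rep(style$ligand_class_palette, length.out = max(1, length(classes)))
  fill <- stats::setNames(pal[seq_along(classes)], classes)
  n$vis_fill <- ifelse(is_lig, unname(fill[n$ligand_class]),
                       style$protein_fill)
  n$vis_fill[is_lig & is.na(n$vis_fill)] <- "#cccccc"

  # opacity from log P over the observed ligand range
  orng <- style$node_opacity_range
  lp <- n$logp[is_lig]
  n$vis_opacity <- 1
  if (any(!is.na(lp))) {
    lo <- min(lp, na.rm = TRUE); hi <- max(lp, na.rm = TRUE)
    scale01 <- if (hi > lo) (n$logp - lo) / (hi - lo) else rep(1, nrow(n))
    n$vis_opacity[is_lig] <- (orng[1] + scale01 * (orng[2] - orng[1]))[is_lig]
  }
  n$vis_opacity[is_lig & is.na(n$logp)] <- orng[1]

  # size from GI absorption
  n$vis_size <- style$protein_node_size
  n$vis_size[is_lig] <- unname(style$node_size_map[n$gi_absorption[is_lig]])
  n$vis_size[is_lig & is.na(n$vis_size)] <- min(style$node_size_map)

  # border colour from bioavailability bins
  bins <- style$bioavailability_bins
  bin_of <- function(x) ifelse(x < bins[1], "low",
                               ifelse(x < bins[2], "medium", "high"))
  n$vis_border_color <- NA_character_
  n$vis_border_color[is_lig] <-
    unname(style$border_colors[bin_of(n$bioavailability[is_lig])])
  n$vis_border_color[is_lig & is.na(n$bioavailability)] <-
    unname(style$border_colors["low"])

  n$vis_pk_missing <- is_lig & (is.na(n$logp) | is.na(n$gi_absorption) |
                                  is.na(n$bioavailability))

  # label colour from protein function
  n$vis_label_color <- "#000000"
  if (!is.null(n$protein_function)) {
    pf <- n$node_kind == "protein" & !is.na(n$protein_function)
    n$vis_label_color[pf] <- unname(style$label_colors[n$protein_function[pf]])
  }
  out <- network
  out$nodes <- n
  out$edges <- e
  out
}

#' Default compartment-box geometry
#'
#' A simple cell template in abstract canvas units (1000 x ~900): an
#' extracellular band on top, the plasma membrane band under it, then
#' cytoplasm, nucleus and mitochondrion boxes, and an "other" band at the
#' bottom. Compartments used by a network but absent from the base template
#' get extra bands appended below.
#'
#' @param extra_compartments character vector of additional compartment
#'   names to allocate boxes for.
#' @return data.frame with columns `compartment`, `x`, `y`, `width`,
#'   `height`.
#' @export
default_compartment_geometry <- function(extra_compartments = character(0)) {
  geo <- data.frame(
    compartment = c("extracellular", "plasma membrane", "cytoplasm",
                    "nucleus", "mitochondrion", "other"),
    x = c(0, 0, 0, 640, 640, 0),
    y = c(0, 130, 240, 240, 460, 680),
    width = c(1000, 1000, 620, 340, 340, 1000),
    height = c(120, 100, 430, 200, 200, 100),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(unique(normalize_compartment(extra_compartments)),
                   geo$compartment)
  for (i in seq_along(extra)) {
    geo <- rbind(geo, data.frame(compartment = extra[i], x = 0,
                                 y = 790 + (i - 1) * 90, width = 1000,
                                 height = 80, stringsAsFactors = FALSE))
  }
  geo
}

#' Lay nodes out inside their compartment boxes
#'
#' Nodes are placed on a jittered grid strictly inside their compartment's
#' rectangle; deterministic for a given seed; pairwise separation within a
#' compartment is kept at or above `min_sep` (jitter is shrunk, and an error
#' raised, when a box is too crowded for that).
#'
#' @param network a `pcpi_network` whose nodes carry `compartment`.
#' @param geometry data.frame from [default_compartment_geometry()]; by
#'   default the base template extended with the network's extra
#'   compartments.
#' @param seed integer RNG seed for the jitter.
#' @param min_sep minimum pairwise distance between nodes of a compartment.
#' @param margin inner margin between box border and node centres.
#' @return data.frame with `node_id`, `compartment`, `x`, `y`.
#' @export
layout_compartments <- function(network, geometry = NULL, seed = 1,
                                min_sep = 8, margin = 12) {
  nodes <- network$nodes
  if (is.null(nodes$compartment) || anyNA(nodes$compartment)) {
    stop_layout("every node needs a compartment before layout")
  }
  if (is.null(geometry)) {
    geometry <- default_compartment_geometry(unique(nodes$compartment))
  }
  missing_geo <- setdiff(unique(nodes$compartment), geometry$compartment)
  if (length(missing_geo)) {
    stop_layout("no rectangle for compartment(s): %s",
                paste(missing_geo, collapse = ", "))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  out <- data.frame(node_id = character(), compartment = character(),
                    x = numeric(), y = numeric(), stringsAsFactors = FALSE)
  for (comp in sort(unique(nodes$compartment))) {
    ids <- sort(nodes$node_id[nodes$compartment == comp])
    k <- length(ids)
    gr <- geometry[geometry$compartment == comp, ]
    w <- gr$width - 2 * margin
    h <- gr$height - 2 * margin
    if (w <= 0 || h <= 0) stop_layout("compartment '%s' box too small", comp)
    if (k == 1) {
      out <- rbind(out, data.frame(node_id = ids, compartment = comp,
                                   x = gr$x + gr$width / 2,
                                   y = gr$y + gr$height / 2,
                                   stringsAsFactors = FALSE))
      next
    }
    ncol <- max(1L, ceiling(sqrt(k * w / h)))
    nrow_ <- ceiling(k / ncol)
    cw <- w / ncol
    ch <- h / nrow_
    jitter_frac <- 0.2
    # shrink jitter if needed to respect min_sep; error if impossible
    if (min(cw, ch) * (1 - 2 * jitter_frac) < min_sep) {
      jitter_frac <- max(0, (1 - min_sep / min(cw, ch)) / 2)
      if (min(cw, ch) < min_sep) {
        stop_layout("compartment '%s' too crowded for min_sep = %g (%d nodes)",
                    comp, min_sep, k)
      }
    }
    idx <- seq_len(k) - 1L
    cx <- gr$x + margin + (idx %% ncol + 0.5) * cw
    cy <- gr$y + margin + (idx %/% ncol + 0.5) * ch
    jx <- stats::runif(k, -jitter_frac * cw, jitter_frac * cw)
    jy <- stats::runif(k, -jitter_frac * ch, jitter_frac * ch)
    out <- rbind(out, data.frame(node_id = ids, compartment = comp,
                                 x = cx + jx, y = cy + jy,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
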