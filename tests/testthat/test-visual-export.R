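# Visual-channel mapping, compartment layout, and graph serialization.

styled_toy <- function() {
  inp <- toy_assembly_inputs()
  net <- suppressMessages(clean_network(
    assemble_network(inp$pcpis, inp$ppis, inp$relations, inp$registry)))
  net <- suppressMessages(assign_protein_locations(
    net, c(PA = "nucleus", PB = "cytoplasm", PC = "plasma membrane",
           PD = "mitochondrion")))
  net <- assign_ligand_locations(net)
  pk <- data.frame(ligand_id = paste0("l", 1:5),
                   bioavailability = c(0.11, 0.55, 0.85, 0.56, 0.17),
                   gi_absorption = c("low", "high", "high", "low", "high"),
                   logp = c(-0.5, 1.2, 3.4, 2.0, 5.1),
                   stringsAsFactors = FALSE)
  net <- annotate_pharmacokinetics(net, pk)
  net <- annotate_protein_function(net, c(PA = "oncogene",
                                          PB = "tumor suppressor"))
  compute_style(net)
}

test_that("edge width maps probability linearly and monotonically", {
  net <- styled_toy()
  e <- net$edges[net$edges$edge_type %in% c("PCPI", "DPI"), ]
  style <- default_style_map()
  expect_equal(e$vis_width,
               style$edge_width_range[1] +
                 e$probability * diff(style$edge_width_range))
  expect_equal(max(e$vis_width[e$probability == 1]),
               style$edge_width_range[2])
  ord <- order(e$probability)
  expect_true(all(diff(e$vis_width[ord]) >= 0))
})

test_that("edge colours and line styles follow the interaction type", {
  net <- styled_toy()
  e <- net$edges
  expect_identical(unique(e$vis_color[e$edge_type == "PPI-up"]), "#33a02c")
  expect_identical(unique(e$vis_color[e$edge_type == "PPI-down"]), "#e31a1c")
  expect_identical(unique(e$vis_color[e$edge_type == "PCPI"]), "#1f78b4")
  expect_identical(
    unique(e$vis_line_style[e$edge_type == "glycoside-aglycone"]), "dashed")
  expect_true(all(e$vis_line_style[e$edge_type != "glycoside-aglycone"] ==
                    "solid"))
})

test_that("node opacity follows log P monotonically; lowest log P is most transparent", {
  net <- styled_toy()
  n <- net$nodes[net$nodes$node_kind == "ligand", ]
  style <- default_style_map()
  ord <- order(n$logp)
  expect_true(all(diff(n$vis_opacity[ord]) >= 0))
  expect_equal(n$vis_opacity[which.min(n$logp)],
               style$node_opacity_range[1])
  expect_equal(n$vis_opacity[which.max(n$logp)],
               style$node_opacity_range[2])
})

test_that("node size, border, shape and label colours follow their channels", {
  net <- styled_toy()
  n <- net$nodes
  style <- default_style_map()
  lig <- n$node_kind == "ligand"
  expect_true(all(n$vis_shape[lig] == "circle"))
  expect_true(all(n$vis_shape[!lig] == "square"))
  expect_identical(unname(n$vis_size[lig & n$gi_absorption == "high"][1]),
                   style$node_size_map[["high"]])
  expect_identical(unname(n$vis_size[lig & n$gi_absorption == "low"][1]),
                   style$node_size_map[["low"]])
  expect_identical(n$vis_border_color[n$bioavailability == 0.11][1],
                   unname(style$border_colors[["low"]]))
  expect_identical(n$vis_border_color[n$bioavailability == 0.85][1],
                   unname(style$border_colors[["high"]]))
  expect_identical(n$vis_label_color[n$node_id == "PA"], "#ff0000")
  expect_identical(n$vis_label_color[n$node_id == "PB"], "#008000")
  expect_identical(n$vis_label_color[n$node_id == "PC"], "#000000")
  expect_true(all(n$vis_fill[!lig] == style$protein_fill))
})

test_that("missing PK attributes map to the channel minimum with a marker", {
  inp <- toy_assembly_inputs()
  net <- suppressMessages(clean_network(
    assemble_network(inp$pcpis, inp$ppis, inp$relations, inp$registry)))
  pk <- data.frame(ligand_id = "l1", bioavailability = 0.85,
                   gi_absorption = "high", logp = 2,
                   stringsAsFactors = FALSE)
  net <- suppressMessages(annotate_pharmacokinetics(net, pk))
  styled <- compute_style(net)
  style <- default_style_map()
  n <- styled$nodes
  l2 <- n$node_id == "l2"
  expect_true(n$vis_pk_missing[l2])
  expect_equal(n$vis_opacity[l2], style$node_opacity_range[1])
  expect_identical(unname(n$vis_size[l2]), min(style$node_size_map))
  expect_false(n$vis_pk_missing[n$node_id == "l1"])
})

test_that("unknown edge types are a style error", {
  net <- styled_toy()
  net$edges$edge_type[1] <- "mystery"
  expect_error(compute_style(net), "mystery", class = "pcpinet_style_error")
})

test_that("layout places nodes strictly inside their compartment rectangles", {
  net <- styled_toy()
  geo <- default_compartment_geometry(unique(net$nodes$compartment))
  coords <- layout_compartments(net, geo, seed = 5)
  expect_identical(sort(coords$node_id), sort(net$nodes$node_id))
  for (i in seq_len(nrow(coords))) {
    g <- geo[geo$compartment == coords$compartment[i], ]
    expect_gt(coords$x[i], g$x)
    expect_lt(coords$x[i], g$x + g$width)
    expect_gt(coords$y[i], g$y)
    expect_lt(coords$y[i], g$y + g$height)
  }
})

test_that("layout is deterministic given a seed and separates crowded nodes", {
  # 50 nodes forced into one compartment
  nodes <- data.frame(node_id = sprintf("n%02d", 1:50),
                      node_kind = "protein", compartment = "cytoplasm",
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes,
                        edges = data.frame(source = character(),
                                           target = character(),
                                           edge_type = character())),
                   class = "pcpi_network")
  c1 <- layout_compartments(net, seed = 9, min_sep = 8)
  c2 <- layout_compartments(net, seed = 9, min_sep = 8)
  expect_identical(c1, c2)
  c3 <- layout_compartments(net, seed = 10, min_sep = 8)
  expect_false(identical(c1$x, c3$x))
  dmat <- as.matrix(stats::dist(c1[c("x", "y")]))
  diag(dmat) <- Inf
  expect_gte(min(dmat), 8)
})

test_that("a single node is centred in its compartment", {
  nodes <- data.frame(node_id = "solo", node_kind = "protein",
                      compartment = "nucleus", stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = data.frame()),
                   class = "pcpi_network")
  geo <- default_compartment_geometry()
  coords <- layout_compartments(net, geo, seed = 1)
  g <- geo[geo$compartment == "nucleus", ]
  expect_equal(coords$x, g$x + g$width / 2)
  expect_equal(coords$y, g$y + g$height / 2)
})

test_that("compartments without a rectangle are a layout error", {
  nodes <- data.frame(node_id = "n1", node_kind = "protein",
                      compartment = "peroxisome", stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = data.frame()),
                   class = "pcpi_network")
  geo <- default_compartment_geometry()  # no peroxisome box
  expect_error(layout_compartments(net, geo), "peroxisome",
               class = "pcpinet_layout_error")
})

test_that("GraphML round-trips all node and edge attributes", {
  net <- styled_toy()
  coords <- layout_compartments(net, seed = 2)
  f <- tempfile(fileext = ".graphml")
  write_graphml(net, f, coords)
  doc <- xml2::read_xml(f)
  expect_identical(xml2::xml_name(doc), "graphml")
  expect_match(xml2::xml_ns(doc)[[1]], "graphml.graphdrawing.org")
  back <- read_graphml(f)
  expect_identical(nrow(back$nodes), nrow(net$nodes))
  expect_identical(nrow(back$edges), nrow(net$edges))
  m <- match(net$nodes$node_id, back$nodes$node_id)
  for (col in c("node_kind", "compartment", "vis_fill", "gi_absorption")) {
    expect_identical(back$nodes[[col]][m], net$nodes[[col]], info = col)
  }
  expect_equal(back$nodes$logp[m], net$nodes$logp)
  expect_equal(back$nodes$vis_opacity[m], net$nodes$vis_opacity)
  ek <- function(df) sort(paste(df$source, df$target, df$edge_type,
                                df$vis_color))
  expect_identical(ek(back$edges), ek(net$edges))
  expect_equal(sort(back$edges$probability), sort(net$edges$probability))
})

test_that("an empty network writes a valid GraphML file", {
  net <- structure(list(
    nodes = data.frame(node_id = character(), node_kind = character(),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = character(), target = character(),
                       edge_type = character(), stringsAsFactors = FALSE)),
    class = "pcpi_network")
  f <- tempfile(fileext = ".graphml")
  write_graphml(net, f)
  back <- read_graphml(f)
  expect_identical(nrow(back$nodes), 0L)
})

test_that("exports agree with the network summary on edge counts", {
  net <- styled_toy()
  dir <- tempfile()
  files <- export_network(net, dir, seed = 3)
  s <- network_summary(net)
  gm <- read_graphml(files[["graphml"]])
  expect_identical(nrow(gm$edges), s$n_edges)
  js <- jsonlite::fromJSON(files[["json"]], simplifyVector = FALSE)
  expect_length(js$elements$edges, s$n_edges)
  expect_length(js$elements$nodes, s$n_nodes)
  expect_true(file.exists(files[["legend"]]))
})
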