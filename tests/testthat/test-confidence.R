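# Docking-confidence calibration: closed forms, boundary conventions,
# partition/monotonicity properties, subnetwork extraction.

toy_dockings <- function() {
  data.frame(
    ligand_id = sprintf("l%d", 1:9),
    protein = sprintf("P%d", 1:9),
    energy = c(-7.8, -7.4, -7.0,  -6.9, -6.8, -6.6,  -5.5, -5.0, -4.5),
    probability = c(1, 1, 1,  0.09, 0.08, 0.07,  0.12, 0.10, 0.14),
    stringsAsFactors = FALSE)
}

test_that("docking cutoffs match the hand-computed closed form", {
  d <- toy_dockings()
  cut <- compute_docking_cutoffs(d, k_hard = 3)
  # probability-1 energies {-7.8, -7.4, -7.0}: soft = min
  expect_equal(cut$soft_cutoff, -7.8)
  # hard = mean + 3 * population SD = -7.4 + 3 * sqrt(0.32/3)
  expect_equal(cut$hard_cutoff, -7.4 + 3 * sqrt(0.32 / 3), tolerance = 1e-12)
  # sample-SD variant
  cut_s <- compute_docking_cutoffs(d, k_hard = 3, sd_type = "sample")
  expect_equal(cut_s$hard_cutoff, -7.4 + 3 * sqrt(0.32 / 2), tolerance = 1e-12)
})

test_that("a single probability-1 record collapses soft = hard", {
  d <- data.frame(ligand_id = "a", protein = "P", energy = -8,
                  probability = 1)
  cut <- compute_docking_cutoffs(d)
  expect_equal(cut$soft_cutoff, -8)
  expect_equal(cut$hard_cutoff, -8)
})

test_that("calibration without probability-1 records instructs an override", {
  d <- data.frame(ligand_id = "a", protein = "P", energy = -8,
                  probability = 0.5)
  expect_error(compute_docking_cutoffs(d), "explicit cutoff",
               class = "pcpinet_calibration_error")
})

test_that("probability regions match the hand-computed closed form", {
  cl <- data.frame(
    probability = c(0.05, 0.15, 0.08, 0.10),
    docking_confidence = c("low", "low", "medium", "medium"))
  th <- compute_probability_regions(cl, k_prob = 1)
  expect_equal(th$prob_high_threshold, 0.10 + 0.05, tolerance = 1e-12)
  expect_equal(th$prob_low_threshold, 0.09 - 0.01, tolerance = 1e-12)
  # degenerate SD = 0 collapses threshold to the group mean
  cl0 <- data.frame(probability = c(0.1, 0.1, 0.1, 0.08),
                    docking_confidence = c("low", "low", "low", "medium"))
  th0 <- compute_probability_regions(cl0)
  expect_equal(th0$prob_high_threshold, 0.1)
  expect_equal(th0$prob_low_threshold, 0.08)
  # empty group -> calibration error
  cl_bad <- data.frame(probability = 0.5, docking_confidence = "high")
  expect_error(compute_probability_regions(cl_bad),
               class = "pcpinet_calibration_error")
})

paper_model <- function() {
  confidence_model(
    cutoffs = list(soft_cutoff = -7.8, hard_cutoff = -6.4),
    prob_thresholds = list(prob_high_threshold = 0.1263,
                           prob_low_threshold = 0.0774))
}

test_that("published thresholds reproduce the printed class definitions on probes", {
  m <- paper_model()
  eps <- 1e-9
  expect_identical(classify_docking_confidence(-8.0, m), "high")
  expect_identical(classify_docking_confidence(-7.0, m), "medium")
  expect_identical(classify_docking_confidence(-6.0, m), "low")
  # boundary probes +/- epsilon; exact boundaries fall in the weaker class
  expect_identical(classify_docking_confidence(-7.8 - eps, m), "high")
  expect_identical(classify_docking_confidence(-7.8, m), "medium")
  expect_identical(classify_docking_confidence(-7.8 + eps, m), "medium")
  expect_identical(classify_docking_confidence(-6.4 - eps, m), "medium")
  expect_identical(classify_docking_confidence(-6.4, m), "low")
  expect_identical(classify_docking_confidence(-6.4 + eps, m), "low")
  expect_identical(classify_probability_confidence(1.0, m), "high")
  expect_identical(classify_probability_confidence(0.10, m), "uncertain")
  expect_identical(classify_probability_confidence(0.05, m), "low")
  expect_identical(classify_probability_confidence(0.1263 + eps, m), "high")
  expect_identical(classify_probability_confidence(0.1263, m), "uncertain")
  expect_identical(classify_probability_confidence(0.0774 + eps, m),
                   "uncertain")
  expect_identical(classify_probability_confidence(0.0774, m), "low")
})

test_that("every (E, P) pair maps to exactly one class of each kind", {
  m <- paper_model()
  E <- seq(-10, -4, by = 0.1)
  P <- seq(0.01, 1, by = 0.03)
  dc <- classify_docking_confidence(E, m)
  pc <- classify_probability_confidence(P, m)
  expect_true(all(dc %in% c("high", "medium", "low")))
  expect_true(all(pc %in% c("high", "uncertain", "low")))
  # monotonicity: decreasing E never lowers docking confidence
  rank_d <- c(low = 1, medium = 2, high = 3)
  expect_true(all(diff(rank_d[dc]) <= 0))
  rank_p <- c(low = 1, uncertain = 2, high = 3)
  expect_true(all(diff(rank_p[pc]) >= 0))
})

test_that("parameter recovery: cutoffs match closed forms on synthetic groups", {
  set.seed(17)
  for (i in 1:5) {
    mu <- runif(1, -9.5, -7.5)
    sd <- runif(1, 0, 0.8)
    n <- sample(4:40, 1)
    e <- rnorm(n, mu, sd)
    d <- data.frame(ligand_id = "x", protein = "P", energy = e,
                    probability = 1)
    cut <- compute_docking_cutoffs(d, k_hard = 3)
    expect_equal(cut$soft_cutoff, min(e), tolerance = 1e-9)
    expect_equal(cut$hard_cutoff,
                 mean(e) + 3 * sqrt(mean((e - mean(e))^2)),
                 tolerance = 1e-9)
  }
})

test_that("the fitted model classifies, summarizes and predicts coherently", {
  d <- toy_dockings()
  m <- confidence_model(d)
  expect_s3_class(m, "confidence_model")
  expect_named(coef(m), c("soft_cutoff", "hard_cutoff",
                          "prob_high_threshold", "prob_low_threshold"))
  expect_identical(nrow(m$classified), nrow(d))
  expect_true(all(c("docking_confidence", "probability_confidence") %in%
                    names(m$classified)))
  s <- summary(m)
  expect_identical(sum(s$groups$n), nrow(d))
  pr <- predict(m, data.frame(energy = c(-9, -6), probability = c(1, 0.01)))
  expect_identical(pr$docking_confidence[1], "high")
  expect_identical(pr$probability_confidence[2], "low")
  expect_output(print(m), "soft cutoff")
})

test_that("high-confidence subnetwork keeps the stated edges and is a subgraph", {
  nodes <- data.frame(
    node_id = c("l1", "l2", "l3", "A", "B", "C"),
    node_kind = c("ligand", "ligand", "ligand", "protein", "protein",
                  "protein"), stringsAsFactors = FALSE)
  edges <- data.frame(
    source = c("l1", "l2", "l3", "A", "B", "l1"),
    target = c("A", "B", "C", "B", "C", "l2"),
    edge_type = c("PCPI", "PCPI", "PCPI", "PPI-up", "PPI-down",
                  "glycoside-aglycone"),
    probability = c(1, 0.3, 0.3, NA, NA, NA),
    provenance = "t", stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "pcpi_network")
  classified <- data.frame(
    ligand_id = c("l1", "l2", "l3"), protein = c("A", "B", "C"),
    energy = c(-5, -8.5, -7.0), probability = c(1, 0.3, 0.3),
    docking_confidence = c("low", "high", "medium"),
    stringsAsFactors = FALSE)
  sub <- suppressMessages(
    extract_high_confidence_subnetwork(net, classified))
  # l1->A kept (P = 1), l2->B kept (high docking), l3->C dropped
  keys <- paste(sub$edges$source, sub$edges$target)
  expect_true(all(c("l1 A", "l2 B") %in% keys))
  expect_false("l3 C" %in% keys)
  # PPI A->B kept (both proteins survive); B->C dropped (C gone)
  expect_true("A B" %in% keys)
  expect_false("B C" %in% keys)
  # glycoside edge among surviving ligands kept
  expect_true("l1 l2" %in% keys)
  expect_false("l3" %in% sub$nodes$node_id)
  # structural subset assertions
  expect_true(all(sub$nodes$node_id %in% net$nodes$node_id))
  expect_true(all(paste(sub$edges$source, sub$edges$target,
                        sub$edges$edge_type) %in%
                    paste(net$edges$source, net$edges$target,
                          net$edges$edge_type)))
})

test_that("explicit threshold overrides bypass calibration errors", {
  d <- data.frame(ligand_id = "a", protein = "P", energy = -8,
                  probability = 0.5)
  m <- confidence_model(d, cutoffs = list(soft_cutoff = -7.8,
                                          hard_cutoff = -6.4),
                        prob_thresholds = list(prob_high_threshold = 0.1263,
                                               prob_low_threshold = 0.0774))
  expect_identical(m$classified$docking_confidence, "high")
  # inconsistent overrides are rejected
  expect_error(confidence_model(cutoffs = list(soft_cutoff = -6,
                                               hard_cutoff = -7),
                                prob_thresholds = list(
                                  prob_high_threshold = 0.2,
                                  prob_low_threshold = 0.1)),
               class = "pcpinet_calibration_error")
})
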