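toy_net <- function() {
  interaction_network(tibble::tibble(
    source = c("Nanog", "Sox2", "Esrrb", "Klf4", "Tcf7l1"),
    target = c("Esrrb", "Nanog", "Klf4", "Nanog", "Esrrb"),
    sign = c("activation", "activation", "activation", "activation",
             "inhibition")))
}

test_that("network container validates and deduplicates edges", {
  net <- toy_net()
  expect_setequal(net$nodes, c("Nanog", "Sox2", "Esrrb", "Klf4", "Tcf7l1"))
  dup <- interaction_network(tibble::tibble(
    source = c("a", "a"), target = c("b", "b"),
    sign = c("activation", "activation")))
  expect_equal(nrow(dup$edges), 1)
  expect_error(interaction_network(
    tibble::tibble(source = "a", target = "b", sign = "binds")), "sign")
})

test_that("reduction keeps the induced subgraph on dynamic genes plus anchors", {
  net <- toy_net()
  # all nodes dynamic: identity (anchors restricted to present regulators)
  red_all <- reduce_network(net, net$nodes, anchors = c("Nanog", "Sox2"))
  expect_setequal(red_all$nodes, net$nodes)
  expect_equal(nrow(red_all$edges), nrow(net$edges))
  # disjoint dynamic set: anchors plus anchor-anchor edges survive
  expect_warning(red_anchor <- reduce_network(net, c("Gata6"),
                                              anchors = c("Nanog", "Sox2",
                                                          "Pou5f1")),
                 "Pou5f1")
  expect_setequal(red_anchor$nodes, c("Nanog", "Sox2"))
  expect_equal(nrow(red_anchor$edges), 1)   # Sox2 -> Nanog
  # planted count arithmetic on a synthetic fixture
  sim <- simulate_counts(recovery_sim(8, n_genes = 400))
  net2 <- simulate_network(sim, n_nodes = 16, edge_density = 0.4)
  dyn8 <- net2$nodes[1:8]
  red <- reduce_network(net2, dyn8, anchors = character(0),
                        keep_isolated = TRUE)
  expect_equal(length(red$nodes), 8)
  # matching is case-insensitive
  red_ci <- reduce_network(net, toupper(net$nodes),
                           anchors = c("Nanog", "Sox2"))
  expect_setequal(red_ci$nodes, net$nodes)
})

test_that("activity follows strict positivity of relative expression", {
  net <- toy_net()
  rel <- matrix(
    c( 0.5, -0.5,
       0.0,  0.0,
      -0.2,  0.2,
       1.0, -1.0),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("Nanog", "Sox2", "Esrrb", "Klf4"), c("pre", "post")))
  expect_warning(act <- node_activity(rel, "pre", net), "Tcf7l1")
  expect_setequal(act, c("Nanog", "Klf4"))          # +0.5 and +1.0
  expect_false("Sox2" %in% act)                     # exactly 0 -> inactive
  expect_error(suppressWarnings(node_activity(rel, "nope", net)), "stage")

  # edge rule: both endpoints must be active
  ed <- active_edges(net, c("Nanog", "Klf4"))
  expect_equal(nrow(ed), 1)                         # Klf4 -> Nanog only
  expect_equal(ed$source, "Klf4")
  expect_equal(nrow(active_edges(net, character(0))), 0)
  # monotonicity: enlarging the active set never removes edges
  ed_big <- active_edges(net, c("Nanog", "Klf4", "Esrrb"))
  expect_true(all(paste(ed$source, ed$target) %in%
                    paste(ed_big$source, ed_big$target)))
})

test_that("edge-activity closure holds on random networks and expressions", {
  set.seed(9)
  for (rep in 1:20) {
    nodes <- paste0("n", 1:12)
    edges <- tibble::tibble(
      source = sample(nodes, 30, TRUE), target = sample(nodes, 30, TRUE),
      sign = sample(c("activation", "inhibition"), 30, TRUE))
    edges <- edges[edges$source != edges$target, ]
    net <- interaction_network(edges, nodes = nodes)
    rel <- matrix(rnorm(length(net$nodes) * 3), nrow = length(net$nodes),
                  dimnames = list(net$nodes, c("a", "b", "c")))
    rel <- rel - rowMeans(rel)
    for (st in colnames(rel)) {
      act <- node_activity(rel, st, net)
      ed <- active_edges(net, act)
      manual <- net$edges[net$edges$source %in% act &
                            net$edges$target %in% act, ]
      expect_identical(ed, manual)
      # centered rows: any varying gene is active somewhere, inactive somewhere
    }
    varying <- rownames(rel)[apply(rel, 1, function(r) diff(range(r)) > 0)]
    pos_counts <- rowSums(rel[varying, , drop = FALSE] > 0)
    expect_true(all(pos_counts >= 1 & pos_counts < ncol(rel)))
  }
})

test_that("connectivity profile finds the planted peak stage", {
  sim <- simulate_counts(recovery_sim(10, n_genes = 400))
  net <- simulate_network(sim, n_nodes = 20, edge_density = 0.3,
                          peak_stage = "E4.5")
  rel <- scale_to_stage_mean(fpkm(sim), sim$samples$stage)
  prof <- connectivity_profile(net, rel)
  expect_equal(attr(prof, "peak_stage"), "E4.5")
  expect_equal(nrow(prof), 4)
  # flat expression: zero active nodes everywhere
  flat <- matrix(0, length(net$nodes), 4,
                 dimnames = list(net$nodes, colnames(rel)))
  prof0 <- connectivity_profile(net, flat)
  expect_true(all(prof0$n_active_nodes == 0))
  expect_true(all(prof0$n_active_edges == 0))
  # all nodes positive at one stage: all edges active there
  allpos <- flat; allpos[, "E3.5"] <- 1
  prof1 <- connectivity_profile(net, allpos)
  expect_equal(prof1$n_active_edges[prof1$stage == "E3.5"],
               nrow(net$edges))
})

test_that("core coexpression returns the exact stage set", {
  expr <- matrix(
    c(20, 5, 30, 1,
      15, 12, 40, 2,
      11, 3, 25, 1),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("Pou5f1", "Nanog", "Esrrb"),
                    c("icm", "morula", "epi", "post")))
  expect_equal(core_coexpression_stages(expr, rownames(expr), floor = 10),
               c("icm", "epi"))
  expect_equal(core_coexpression_stages(expr, rownames(expr), floor = 1e6),
               character(0))
  expect_equal(core_coexpression_stages(expr, rownames(expr), floor = 0),
               colnames(expr))
  expect_error(core_coexpression_stages(expr, c("Nanog", "Zfp42")), "Zfp42")
  expect_error(core_coexpression_stages(expr, character(0)), "non-empty")
})

test_that("SIF round-trips preserve networks", {
  net <- toy_net()
  tmp <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, tmp)
  back <- read_sif(tmp)
  expect_setequal(back$nodes, net$nodes)
  expect_equal(dplyr::arrange(back$edges, source, target),
               dplyr::arrange(net$edges, source, target))
})
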