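test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_dynamic = 1.5), "frac_dynamic")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(n_genes = 50, frac_dynamic = 0.1, n_modules = 10),
               "at least")
  expect_error(
    sim_config(stages = c("a", "b"), n_modules = 1,
               module_profiles = list(c(1, -2))),
    "positive")
  expect_error(
    sim_config(stages = c("a", "b"), n_modules = 2,
               module_profiles = list(c(1, 2))),
    "one profile per module")
})

test_that("simulation is deterministic and respects flat profiles", {
  cf <- sim_config(n_genes = 120, stages = c("s1", "s2", "s3"),
                   replicates_per_stage = 3, frac_dynamic = 0, seed = 11)
  s1 <- simulate_counts(cf)
  s2 <- simulate_counts(cf)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$genes, s2$genes)
  # frac_dynamic = 0: every gene's true stage means are equal across stages
  expect_true(all(apply(s1$truth$stage_means, 1,
                        function(r) length(unique(r)) == 1)))
  # ground truth closure
  expect_true(all(is.na(s1$genes$module)))
  expect_equal(exp(mean(log(s1$truth$lib_factors))), 1, tolerance = 1e-12)
})

test_that("module labels exist exactly for dynamic genes and pseudotime is nondecreasing in stage order", {
  sim <- simulate_counts(recovery_sim(3, n_genes = 500))
  expect_true(all(!is.na(sim$genes$module[sim$genes$dynamic])))
  expect_true(all(is.na(sim$genes$module[!sim$genes$dynamic])))
  ord <- order(as.integer(sim$samples$stage))
  expect_true(all(diff(sim$samples$pseudotime[ord]) >= 0))
})

test_that("dispersion 0 gives Poisson counts (variance/mean near 1) and NB moments match", {
  cf <- sim_config(n_genes = 4, stages = "s1", replicates_per_stage = 10000,
                   frac_dynamic = 0, n_modules = 1,
                   module_profiles = list(1), baseline_mean = 40,
                   dispersion = 0, libsize_log_sd = 0, frac_detectable = 1,
                   baseline_log_sd = 0.3, seed = 21)
  sim <- simulate_counts(cf)
  vm <- apply(sim$counts, 1, var) / rowMeans(sim$counts)
  expect_true(all(abs(vm - 1) < 0.05))

  cfnb <- sim_config(n_genes = 4, stages = "s1",
                     replicates_per_stage = 20000, frac_dynamic = 0,
                     n_modules = 1, module_profiles = list(1),
                     baseline_mean = 50, dispersion = 0.1,
                     libsize_log_sd = 0, frac_detectable = 1,
                     baseline_log_sd = 0, seed = 22)
  simnb <- simulate_counts(cfnb)
  mu <- simnb$truth$stage_means[, 1]
  emp_mean <- rowMeans(simnb$counts)
  emp_var <- apply(simnb$counts, 1, var)
  expect_true(all(abs(emp_mean / mu - 1) < 0.02))
  expect_true(all(abs(emp_var / (mu + 0.1 * mu^2) - 1) < 0.05))
})

test_that("simulated networks are complete at density 1 and live on dynamic genes peaking at the planted stage", {
  sim <- simulate_counts(recovery_sim(5, n_genes = 400))
  net <- simulate_network(sim, n_nodes = 4, edge_density = 1)
  expect_equal(nrow(net$edges), 12)          # complete digraph, no self-loops
  expect_false(any(net$edges$source == net$edges$target))
  dyn <- sim$genes$gene_id[sim$genes$dynamic]
  expect_true(all(net$nodes %in% dyn))
  # planted profiles peak at the recorded stage: all nodes active there
  ps <- attr(net, "peak_stage")
  fk <- fpkm(sim)
  rel <- scale_to_stage_mean(fk, sim$samples$stage)
  act <- node_activity(rel, ps, net)
  expect_setequal(act, net$nodes)
  expect_error(simulate_network(sim, 4, 0), "edge_density")
  expect_error(simulate_network(sim, 4, 1.2), "edge_density")
})

test_that("IF cell simulation is deterministic, validates channels, and plants effects", {
  c1 <- simulate_if_cells(n_embryos_per_treatment = 2, cells_per_embryo = 20,
                          seed = 3)
  c2 <- simulate_if_cells(n_embryos_per_treatment = 2, cells_per_embryo = 20,
                          seed = 3)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_error(
    simulate_if_cells(effects = list(DMSO = list(mean_mult = c(FOO = 2)))),
    "Unknown channel")

  # null effects: planted class proportions equal across arms in expectation
  null_cells <- simulate_if_cells(
    n_embryos_per_treatment = 25, cells_per_embryo = 100,
    treatments = c("t1", "t2"), effects = list(t1 = list(), t2 = list()),
    seed = 8)
  frac <- tapply(null_cells$true_class == "nanog_only",
                 null_cells$treatment, mean)
  expect_lt(abs(frac["t1"] - frac["t2"]), 0.03)

  # channel-mean effect: NANOG x2 doubles the arm's mean intensity
  eff <- simulate_if_cells(
    n_embryos_per_treatment = 40, cells_per_embryo = 125,
    treatments = c("ctrl", "boost"),
    effects = list(ctrl = list(), boost = list(mean_mult = c(NANOG = 2))),
    seed = 9)
  mns <- tapply(eff$nanog, eff$treatment, mean)
  expect_equal(unname(mns["boost"] / mns["ctrl"]), 2, tolerance = 0.1)
})

test_that("wave profiles are smooth positive bumps sweeping the stage axis", {
  pr <- wave_module_profiles(6, 5, fold = 4)
  expect_length(pr, 6)
  expect_true(all(vapply(pr, function(p) all(p > 0), logical(1))))
  peaks <- vapply(pr, which.max, integer(1))
  expect_true(all(diff(peaks) >= 0))
  expect_equal(peaks[1], 1L)
  expect_equal(peaks[6], 5L)
})
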