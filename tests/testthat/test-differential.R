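test_that("dispersion estimation recovers known values and handles degenerate genes", {
  mk <- function(alpha, seed) {
    cf <- sim_config(n_genes = 600, stages = c("A", "B"),
                     replicates_per_stage = 8, frac_dynamic = 0,
                     baseline_mean = 100, dispersion = alpha,
                     frac_detectable = 1, libsize_log_sd = 0.1, seed = seed)
    simulate_counts(cf)
  }
  sim0 <- mk(0, 31)
  d0 <- estimate_dispersion(sim0$counts, size_factors(sim0$counts),
                            sim0$samples$stage)
  expect_lt(median(d0$dispersion_gene), 0.01)

  sim2 <- mk(0.2, 32)
  d2 <- estimate_dispersion(sim2$counts, size_factors(sim2$counts),
                            sim2$samples$stage)
  expect_gt(median(d2$dispersion), 0.1)
  expect_lt(median(d2$dispersion), 0.4)

  # constant gene: floored, finite
  m <- matrix(7L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  dc <- estimate_dispersion(m, rep(1, 4), c("A", "A", "B", "B"))
  expect_true(all(is.finite(dc$dispersion)))
  expect_true(all(dc$dispersion >= 1e-8))

  expect_error(
    estimate_dispersion(m, rep(1, 4), c("A", "B", "C", "D")),
    "alpha")
})

test_that("NB exact test matches brute-force enumeration for all totals up to 40", {
  sa <- c(1, 1, 1); sb <- c(1, 1, 1)
  worst <- 0
  for (alpha in c(0.01, 0.1, 0.5)) {
    for (total in 1:40) {
      for (ka in 0:total) {
        p_pkg <- lineagemap:::nb_exact_pval(ka, total - ka, sum(sa), sum(sb),
                                            sum(sa^2), sum(sb^2), alpha)
        p_ora <- nb_brute_pval(ka, total - ka, sa, sb, alpha)
        worst <- max(worst, abs(p_pkg - p_ora))
      }
    }
  }
  expect_lt(worst, 1e-10)
  # unbalanced factors too
  sa <- c(0.7, 1.4); sb <- c(1.1, 0.9, 1.3)
  worst <- 0
  for (total in c(5, 17, 33)) {
    for (ka in 0:total) {
      p_pkg <- lineagemap:::nb_exact_pval(ka, total - ka, sum(sa), sum(sb),
                                          sum(sa^2), sum(sb^2), 0.2)
      p_ora <- nb_brute_pval(ka, total - ka, sa, sb, 0.2)
      worst <- max(worst, abs(p_pkg - p_ora))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("NB test boundary cases and invariances hold", {
  m <- matrix(c(5L, 5L, 5L, 5L,   0L, 0L, 50L, 50L,   0L, 0L, 0L, 0L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("same", "strong", "zero"), paste0("s", 1:4)))
  grp <- c("A", "A", "B", "B")
  res <- nb_exact_test(m, rep(1, 4), 0.01, grp, c("A", "B"))
  expect_equal(res$pval[res$gene_id == "same"], 1)     # identical groups
  expect_equal(res$pval[res$gene_id == "zero"], 1)     # no information
  expect_equal(res$log2fc[res$gene_id == "zero"], 0)
  expect_lt(res$pval[res$gene_id == "strong"], 0.01)   # 0,0 vs 50,50
  expect_true(all(res$padj >= res$pval))

  # permuting sample order never changes any p-value
  perm <- c(3, 1, 4, 2)
  res_p <- nb_exact_test(m[, perm], rep(1, 4), 0.01, grp[perm], c("A", "B"))
  expect_equal(res_p$pval[match(res$gene_id, res_p$gene_id)], res$pval)

  expect_error(nb_exact_test(m, rep(1, 4), 0.01, grp, c("A", "Z")),
               "Unknown condition")
})

test_that("NB test is calibrated on null data and power rises with fold change", {
  cf <- sim_config(n_genes = 2000, stages = c("A", "B"),
                   replicates_per_stage = 4, frac_dynamic = 0,
                   dispersion = 0.1, frac_detectable = 1, seed = 99)
  sim <- simulate_counts(cf)
  de <- nb_exact_test(sim$counts, size_factors(sim$counts), 0.1,
                      sim$samples$stage, c("A", "B"))
  frac <- mean(de$pval < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)

  # power nondecreasing in fold change at fixed n and alpha; most genes stay
  # flat so size factors remain estimable
  rej <- vapply(c(1, 2, 4), function(fc) {
    cfp <- sim_config(n_genes = 1000, stages = c("A", "B"),
                      replicates_per_stage = 4, frac_dynamic = 0.2,
                      n_modules = 1,
                      module_profiles = list(c(1, max(fc, 1 + 1e-9))),
                      dispersion = 0.1, frac_detectable = 1, seed = 77)
    simp <- simulate_counts(cfp)
    dep <- nb_exact_test(simp$counts, size_factors(simp$counts), 0.1,
                         simp$samples$stage, c("A", "B"))
    mean(dep$pval[simp$genes$dynamic] < 0.05)
  }, numeric(1))
  expect_true(all(diff(rej) >= 0))
  expect_gt(rej[3], 0.9)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)                    # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  # general case against a hand evaluation of the step-up rule
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  m <- length(p)
  stepup <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(bh_adjust(p), pmin(stepup, 1))
})

test_that("all-pairs DE covers every contrast with within-contrast adjustment", {
  sim <- simulate_counts(recovery_sim(13, n_genes = 150))
  de <- de_all_pairs(sim$counts, size_factors(sim$counts), 0.1,
                     sim$samples$stage)
  expect_equal(nrow(de), 150 * 6)
  pairs <- unique(paste(de$contrast_a, de$contrast_b))
  expect_length(pairs, 6)
  one <- de[de$contrast_a == "E2.5" & de$contrast_b == "E3.5", ]
  expect_equal(one$padj, bh_adjust(one$pval))
})
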