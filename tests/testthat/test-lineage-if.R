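mini_cells <- function() {
  tibble::tibble(
    cell_id = paste0("c", 1:4), embryo_id = "e1", treatment = "DMSO",
    nanog = c(200, 50, 300, 10), gata6 = c(20, 400, 350, 15),
    cdx2 = rep(10, 4), dapi = c(100, 100, 100, 0))
}

test_that("DAPI normalization is a per-cell ratio and drops bad cells", {
  expect_message(norm <- normalize_cells(mini_cells()), "Dropped 1")
  expect_equal(nrow(norm), 3)
  expect_equal(attr(norm, "n_dropped"), 1)
  expect_equal(norm$nanog_norm[1], 2)
  # scaling every channel of a cell leaves normalized values unchanged
  cells <- mini_cells()[1:3, ]
  scaled <- cells
  scaled[2, c("nanog", "gata6", "cdx2", "dapi")] <-
    scaled[2, c("nanog", "gata6", "cdx2", "dapi")] * 7
  expect_equal(normalize_cells(scaled)$nanog_norm,
               normalize_cells(cells)$nanog_norm)
})

test_that("positivity rules: Otsu separates planted modes, fixed rule is a strict cut", {
  set.seed(21)
  n <- 2000
  truth <- rep(c(TRUE, FALSE), times = n / 2)  # both modes in every embryo
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:n),
    embryo_id = rep(paste0("e", 1:4), each = n / 4),
    treatment = "t",
    nanog = exp(ifelse(truth, log(900), log(40)) + rnorm(n, 0, 0.3)),
    gata6 = 50, cdx2 = 50, dapi = 1000)
  cells <- normalize_cells(cells)
  called <- call_positive(cells, "nanog")
  # the geometric midpoint of the two planted modes is the ideal separator
  expect_gte(
    mean(called$nanog_pos == (cells$nanog > sqrt(900 * 40))), 0.99)

  # all-equal intensities: everyone negative under strict >
  flat <- cells; flat$nanog <- 7; flat$nanog_norm <- 7 / flat$dapi
  called_flat <- call_positive(flat, "nanog")
  expect_false(any(called_flat$nanog_pos))

  # fixed rule boundary
  two <- cells[1:2, ]
  two$nanog_norm <- c(0.5 + 1e-9, 0.5 - 1e-9)
  fx <- call_positive(two, "nanog", method = "fixed", threshold = 0.5)
  expect_equal(fx$nanog_pos, c(TRUE, FALSE))

  # tiny embryo falls back to the global threshold with a warning
  small <- cells[1:20, ]
  small$embryo_id[1:2] <- "tiny"
  expect_warning(call_positive(small, "nanog"), "global")
})

test_that("lineage classes partition cells and NANOG-high is inclusive at 1.5x", {
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:4), embryo_id = "e1", treatment = "x",
    nanog_norm = c(3, 0.1, 2, 0.2),
    nanog_pos = c(TRUE, FALSE, TRUE, FALSE),
    gata6_pos = c(FALSE, TRUE, TRUE, FALSE))
  calls <- classify_lineage(cells)
  expect_equal(as.character(calls$class),
               c("NANOG-only", "GATA6-only", "coexpressing",
                 "double-negative"))
  expect_false(anyNA(calls$class))
  # exact 1.5x the embryo mean counts as high (and requires positivity):
  # set cell 1 so that v = 1.5 * (v + s) / 4, s = sum of the other cells
  s <- sum(cells$nanog_norm[-1])
  v <- 1.5 * s / (4 - 1.5)
  cells$nanog_norm[1] <- v
  calls <- classify_lineage(cells)
  expect_true(calls$nanog_high[1])            # exactly 1.5x mean: inclusive
  expect_true(calls$nanog_high[3])            # 2 > 1.5x mean and positive
  expect_false(any(calls$nanog_high[c(2, 4)]))
  # NANOG-high implies NANOG-positive even at high intensity
  expect_true(all(!calls$nanog_high | calls$nanog_pos))
})

test_that("embryo proportions partition exactly and respond to planted effects", {
  cells <- simulate_if_cells(n_embryos_per_treatment = 3,
                             cells_per_embryo = 10, seed = 2)
  cells <- normalize_cells(cells)
  cells <- call_positive(cells, "nanog")
  cells <- call_positive(cells, "gata6")
  props <- embryo_proportions(classify_lineage(cells))
  expect_equal(props$frac_nanog_only + props$frac_gata6_only +
                 props$frac_coexpressing + props$frac_double_negative,
               rep(1, nrow(props)), tolerance = 1e-12)
  expect_true(all(props$n_cells == 10))

  # a doubled planted NANOG-only probability shows up in the estimate
  big <- simulate_if_cells(
    n_embryos_per_treatment = 5, cells_per_embryo = 1000,
    treatments = c("ctrl", "dbl"),
    effects = list(ctrl = list(),
                   dbl = list(props = c(nanog_only = 0.3, gata6_only = 0.25,
                                        coexpressing = 0.05,
                                        double_negative = 0.4))),
    base_props = c(nanog_only = 0.15, gata6_only = 0.32, coexpressing = 0.05,
                   double_negative = 0.48),
    seed = 14)
  frac <- tapply(big$true_class == "nanog_only", big$treatment, mean)
  expect_equal(unname(frac["dbl"] / frac["ctrl"]), 2, tolerance = 0.15)
})

test_that("one-way ANOVA with Tukey HSD handles boundaries and matches oracles", {
  # all groups identical
  d0 <- data.frame(g = rep(c("a", "b", "c"), each = 3), y = 5)
  a0 <- anova_tukey(d0, y, g)
  expect_equal(a0$f_statistic, 0)
  expect_equal(a0$p_overall, 1)
  expect_true(all(tidy(a0)$p_adj == 1))

  # zero within-group variance with unequal means: floored p
  d1 <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2), each = 3))
  a1 <- anova_tukey(d1, y, g)
  expect_lte(a1$p_overall, 1e-15)

  # two groups: Tukey p equals the pooled two-sided t-test via q = |t|*sqrt(2)
  set.seed(31)
  d2 <- data.frame(g = rep(c("a", "b"), each = 6), y = rnorm(12, rep(c(0, 1), each = 6)))
  a2 <- anova_tukey(d2, y, g)
  tt <- t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(tidy(a2)$p_adj, tt$p.value, tolerance = 1e-10)
  expect_equal(glance(a2)$p_value, tt$p.value, tolerance = 1e-10)

  # three groups with planted shift: p matches the studentized-range
  # quadrature oracle
  set.seed(32)
  d3 <- data.frame(g = rep(c("a", "b", "c"), each = 4),
                   y = rnorm(12, rep(c(0, 0.8, 1.6), each = 4)))
  a3 <- anova_tukey(d3, y, g)
  mse <- sum(tapply(d3$y, d3$g, function(v) sum((v - mean(v))^2))) / 9
  means <- tapply(d3$y, d3$g, mean)
  td <- tidy(a3)
  for (i in seq_len(nrow(td))) {
    q_obs <- abs(means[td$group_b[i]] - means[td$group_a[i]]) /
      sqrt(mse / 4)
    p_oracle <- 1 - srange_cdf(q_obs, k = 3, df = 9)
    expect_lt(abs(td$p_adj[i] - p_oracle), 1e-4)
  }

  expect_error(anova_tukey(data.frame(g = c("a", "a", "b"), y = 1:3), y, g),
               "2 observations")
})

test_that("ANOVA/Tukey is calibrated under the null", {
  set.seed(33)
  res <- replicate(1000, {
    d <- data.frame(g = rep(c("a", "b", "c"), each = 6), y = rnorm(18))
    at <- anova_tukey(d, y, g)
    c(overall = at$p_overall < 0.05, fw = any(at$comparisons$p_adj < 0.05))
  })
  expect_gte(mean(res["overall", ]), 0.035)
  expect_lte(mean(res["overall", ]), 0.065)
  expect_lte(mean(res["fw", ]), 0.07)
})

test_that("calls are invariant to embryo-wise intensity scaling", {
  cells <- simulate_if_cells(n_embryos_per_treatment = 2,
                             cells_per_embryo = 40, seed = 6)
  run <- function(x) {
    x <- normalize_cells(x)
    x <- call_positive(x, "nanog")
    x <- call_positive(x, "gata6")
    classify_lineage(x)
  }
  base <- run(cells)
  scaled <- cells
  e1 <- scaled$embryo_id == scaled$embryo_id[1]
  scaled[e1, c("nanog", "gata6", "cdx2", "dapi")] <-
    scaled[e1, c("nanog", "gata6", "cdx2", "dapi")] * 3.7
  expect_equal(as.character(run(scaled)$class), as.character(base$class))
  expect_equal(run(scaled)$nanog_high, base$nanog_high)
})
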