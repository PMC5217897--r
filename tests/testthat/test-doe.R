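test_that("constant data decomposes into a bare grand mean", {
  d <- factorial_dataset(rep(c("fine", "coarse"), each = 4),
                         rep(c("dry", "humid"), times = 4),
                         rep(7.5, 8))
  dec <- decompose_factorial(d)
  expect_equal(dec$grand_mean, 7.5)
  expect_equal(unname(dec$effect_a), c(0, 0))
  expect_equal(unname(dec$effect_b), c(0, 0))
  expect_equal(unname(as.vector(dec$interaction)), rep(0, 4))
  expect_equal(dec$residuals, rep(0, 8))
  an <- factorial_anova(dec)
  expect_equal(an$sumsq, rep(0, 4))
  gm <- grouped_means(d)
  expect_true(all(abs(gm$cell_means$mean - 7.5) < 1e-12))
})

test_that("additive noise-free data has zero interaction and parallel profiles", {
  d <- simulate_factorial(grand_mean = 1, effect_a = 0.2, effect_b = 0.4,
                          interaction = 0, r = 4, sd = 0, seed = 1)
  dec <- decompose_factorial(d)
  expect_true(all(abs(dec$interaction) < 1e-12))
  expect_equal(sort(abs(unname(dec$effect_a))), c(0.2, 0.2))
  gm <- grouped_means(d)
  cell <- matrix(gm$cell_means$mean, 2, byrow = TRUE)
  # parallel level profiles: equal differences across factor B
  expect_equal(cell[1, 1] - cell[1, 2], cell[2, 1] - cell[2, 2],
               tolerance = 1e-12)
})

test_that("decomposition reconstructs every observation exactly", {
  set.seed(23)
  for (i in 1:20) {
    d <- factorial_dataset(rep(c("a1", "a2"), each = 8),
                           rep(c("b1", "b2"), times = 8),
                           rnorm(16, 5, 2))
    dec <- decompose_factorial(d)
    recon <- dec$grand_mean + dec$effect_a[d$a] + dec$effect_b[d$b] +
      dec$interaction[cbind(d$a, d$b)] + dec$residuals
    expect_equal(unname(recon), d$response, tolerance = 1e-12)
    # zero-sum constraints
    expect_equal(sum(dec$effect_a), 0, tolerance = 1e-12)
    expect_equal(sum(dec$effect_b), 0, tolerance = 1e-12)
    expect_true(all(abs(rowSums(dec$interaction)) < 1e-12))
    expect_true(all(abs(colSums(dec$interaction)) < 1e-12))
    res_by_cell <- tapply(dec$residuals, list(d$a, d$b), sum)
    expect_true(all(abs(res_by_cell) < 1e-12))
    # cell means agree with the reconstruction identity
    gm <- grouped_means(d)
    expect_equal(gm$cell_means$mean,
                 dec$grand_mean + dec$effect_a[gm$cell_means$a] +
                   dec$effect_b[gm$cell_means$b] +
                   dec$interaction[cbind(gm$cell_means$a, gm$cell_means$b)],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("the ANOVA table matches stats::aov and partitions the total SS", {
  set.seed(29)
  for (i in 1:10) {
    d <- simulate_factorial(1, 0.1, 0.3, 0.05, r = 4, sd = 0.2)
    dec <- decompose_factorial(d)
    an <- factorial_anova(dec)
    # SS partition against a direct total-SS computation
    ss_tot <- sum((d$response - mean(d$response))^2)
    expect_equal(sum(an$sumsq), ss_tot, tolerance = 1e-9)
    # independent route: stats::aov on the same data
    fit <- summary(stats::aov(response ~ a * b, data = d))[[1]]
    expect_equal(an$sumsq, unname(fit[["Sum Sq"]]), tolerance = 1e-9)
    expect_equal(an$statistic[1:3], unname(fit[["F value"]][1:3]),
                 tolerance = 1e-9)
    expect_equal(an$p.value[1:3], unname(fit[["Pr(>F)"]][1:3]),
                 tolerance = 1e-9)
    expect_equal(an$df, c(1, 1, 1, 12))
  }
})

test_that("a strong B effect is detected while an absent A effect is not", {
  set.seed(37)
  hits_b <- 0; miss_a <- 0
  n_sim <- 200
  for (i in 1:n_sim) {
    d <- simulate_factorial(1, effect_a = 0, effect_b = 0.5,
                            interaction = 0, r = 4, sd = 0.1)
    an <- factorial_anova(decompose_factorial(d))
    if (an$p.value[2] < 0.001) hits_b <- hits_b + 1
    if (an$p.value[1] > 0.05) miss_a <- miss_a + 1
  }
  expect_gte(hits_b / n_sim, 0.95)
  expect_gte(miss_a / n_sim, 0.90)
})

test_that("ANOVA is shift invariant and SS scale quadratically", {
  d <- simulate_factorial(1, 0.2, 0.1, 0.05, r = 4, sd = 0.2, seed = 5)
  an <- factorial_anova(decompose_factorial(d))
  d_shift <- factorial_dataset(d$a, d$b, d$response + 100)
  an_shift <- factorial_anova(decompose_factorial(d_shift))
  expect_equal(an$sumsq, an_shift$sumsq, tolerance = 1e-9)
  expect_equal(an$p.value, an_shift$p.value, tolerance = 1e-9)
  d_scale <- factorial_dataset(d$a, d$b, 3 * d$response)
  an_scale <- factorial_anova(decompose_factorial(d_scale))
  expect_equal(an_scale$sumsq, 9 * an$sumsq, tolerance = 1e-9)
  expect_equal(an_scale$statistic[1:3], an$statistic[1:3], tolerance = 1e-9)
})

test_that("degenerate and unbalanced designs are rejected or flagged", {
  expect_error(factorial_dataset(c("a1", "a1", "a2", "a2", "a2"),
                                 c("b1", "b2", "b1", "b2", "b2"),
                                 1:5), "unbalanced")
  expect_error(factorial_dataset(rep("a1", 4),
                                 rep(c("b1", "b2"), 2), 1:4),
               "two levels")
  expect_error(factorial_dataset(c("a1", "a1", "a2", "a2"),
                                 c("b1", "b2", "b1", "b2"), 1:4),
               "two replicates")
  # zero residual variation: infinite F, p = 0
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(c("b1", "b2"), times = 4)
  d <- factorial_dataset(a, b, ifelse(a == "a1", 0, 10) +
                           ifelse(b == "b1", 0, 1))
  an <- factorial_anova(decompose_factorial(d))
  expect_true(all(is.infinite(an$statistic[1:2])))
  expect_equal(an$p.value[1:2], c(0, 0))
})
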