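test_that("variance components hit the boundary and the balanced ANOVA solution", {
  # identical group means, unit within-group variance
  set.seed(3)
  y <- c(scale(rnorm(60)), scale(rnorm(60)))   # both groups mean 0, var 1
  g <- rep(c("a", "b"), each = 60)
  vc <- variance_components(y, g)
  expect_equal(vc$sigma2_GB, 0)
  expect_true(vc$boundary)
  expect_equal(vc$sigma2_GW, 1, tolerance = 0.05)
  # balanced 2 x 50, values = group mean +-1 alternating, means 0 and 10
  y2 <- c(rep(c(-1, 1), 25), rep(c(9, 11), 25))
  g2 <- rep(c("a", "b"), each = 50)
  msw <- 50 / 49                    # pooled sample variance of +-1
  msb <- sum(50 * (c(0, 10) - 5)^2) # df1 = 1
  gb_hand <- (msb - msw) / 50
  for (m in c("reml", "moments")) {
    vc2 <- variance_components(y2, g2, method = m)
    expect_equal(vc2$sigma2_GB, gb_hand, tolerance = 1e-6)
    expect_equal(vc2$sigma2_GW, msw, tolerance = 1e-6)
  }
  # degenerate groups
  expect_warning(variance_components(c(1, 2, 3, 4, 5, 6),
                                     c("a", "a", "a", "b", "b", "c")),
                 "excluding")
  expect_error(suppressWarnings(variance_components(c(1, 2, 3), c("a", "a", "b"))),
               "at least 2 groups")
})

test_that("components of a fixed-means generator are recovered", {
  # three populations with configured means (-2, 0, 2): among-group variance
  # var(c(-2,0,2)) = 4; within-group sd 1 -> sigma2_GW = 1
  hit_gb <- hit_gw <- 0
  for (s in 1:100) {
    set.seed(s)
    y <- c(rnorm(200, -2), rnorm(200, 0), rnorm(200, 2))
    g <- rep(c("a", "b", "c"), each = 200)
    vc <- variance_components(y, g, method = "moments")
    if (abs(vc$sigma2_GB - 4) / 4 < 0.25) hit_gb <- hit_gb + 1
    if (abs(vc$sigma2_GW - 1) < 0.25) hit_gw <- hit_gw + 1
  }
  expect_gte(hit_gb, 90)
  expect_gte(hit_gw, 90)
})

test_that("pst arithmetic, scale invariance and monotonicity hold", {
  expect_equal(pst(list(sigma2_GB = 0, sigma2_GW = 1)), 0)
  expect_equal(pst(list(sigma2_GB = 5, sigma2_GW = 0)), 1)
  expect_equal(pst(list(sigma2_GB = 2, sigma2_GW = 1)), 0.5)
  expect_error(pst(list(sigma2_GB = 0, sigma2_GW = 0)), "undefined")
  # scale invariance: both components scale by the square of the constant
  set.seed(1)
  y <- c(rnorm(40, 0), rnorm(40, 3)); g <- rep(c("a", "b"), each = 40)
  p1 <- pst(variance_components(y, g))
  p2 <- pst(variance_components(y * 7.5, g))
  expect_equal(p1, p2, tolerance = 1e-6)
  # monotone in sigma2_GB at fixed sigma2_GW
  gws <- pst(list(sigma2_GB = 1, sigma2_GW = 1))
  expect_true(pst(list(sigma2_GB = 2, sigma2_GW = 1)) > gws)
  expect_true(pst(list(sigma2_GB = 4, sigma2_GW = 1)) >
                pst(list(sigma2_GB = 2, sigma2_GW = 1)))
})

test_that("pairwise P_ST behaves at the null and under strong divergence", {
  set.seed(21)
  ph <- data.frame(id = sprintf("i%03d", 1:150),
                   mean_plates = c(rnorm(50, 10, 2), rnorm(50, 10, 2),
                                   rnorm(50, 10, 2)))
  grp <- stats::setNames(rep(c("a", "b", "c"), each = 50), ph$id)
  pp <- pairwise_pst(ph, grp, n_boot = 300, seed = 2)
  expect_lt(max(pp$point, na.rm = TRUE), 0.15)          # null: near 0
  expect_lt(min(pp$ci_low, na.rm = TRUE), 0.05)
  # strong divergence: means 5 vs 31, sd 1
  ph2 <- data.frame(id = sprintf("j%03d", 1:100),
                    mean_plates = c(rnorm(50, 5, 1), rnorm(50, 31, 1)))
  g2 <- stats::setNames(rep(c("lo", "hi"), each = 50), ph2$id)
  pp2 <- pairwise_pst(ph2, g2, n_boot = 300, seed = 3)
  expect_gt(pp2$point["lo", "hi"], 0.95)
  # seeded determinism of CI bounds
  pp3 <- pairwise_pst(ph2, g2, n_boot = 300, seed = 3)
  expect_identical(pp2$ci_low, pp3$ci_low)
})

test_that("correlation t statistic matches closed forms and guards", {
  expect_equal(cor_t_stat(0.83, 4)$t, 0.83 * 2 / sqrt(1 - 0.83^2), tolerance = 1e-12)
  z <- cor_t_stat(0, 10)
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  expect_equal(cor_t_stat(0.5, 4)$t, 0.5 * 2 / sqrt(0.75), tolerance = 1e-12)
  expect_warning(w <- cor_t_stat(1, 4), "infinite")
  expect_identical(w$t, Inf)
})

test_that("pst_fst_correlation aligns pairs and refuses degenerate input", {
  pv <- stats::setNames(c(0.2, 0.5, 0.8, 0.9, 0.3, 0.6),
                        c("a:b", "a:c", "a:d", "b:c", "b:d", "c:d"))
  fv <- pv * 0.5 + 0.01                    # perfectly linear -> r = 1 warned
  expect_warning(cc <- pst_fst_correlation(pv, fv), "infinite")
  expect_equal(cc$r, 1)
  set.seed(4)
  fv2 <- pv + rnorm(6, 0, 0.1)
  cc2 <- pst_fst_correlation(pv, fv2)
  expect_equal(cc2$df, 4)
  expect_equal(cc2$t, cor_t_stat(cc2$r, 4)$t)
  expect_error(pst_fst_correlation(pv[1:3], fv2[1:3]), "4")
  expect_error(pst_fst_correlation(pv, stats::setNames(rep(0.3, 6), names(pv))),
               "constant")
})

test_that("the combined report has one row per pair, statistic and panel", {
  set.seed(31)
  ds <- simulate_three_ecotype_scenario(scenario_config(n_per_pop = 30, seed = 31))
  # a 4th group: duplicate resident1 with jitter so pairs = 6
  gt <- ds$genotypes
  extra <- subset_individuals(gt, gt$groups == "resident1")
  extra <- genotype_table(paste0("x", extra$ids), extra$markers, extra$a1,
                          extra$a2, rep("resident3", n_ind(extra)))
  gt4 <- bind_genotypes(gt, extra)
  ph <- ds$phenotypes
  ph4 <- rbind(ph, transform(ph[ph$id %in% ds$genotypes$ids[ds$groups == "resident1"], ],
                             id = paste0("x", id)))
  grp4 <- gt4$groups
  psts <- pairwise_pst(ph4, grp4, n_boot = 100, seed = 1)
  fsts <- list(
    all = pairwise_matrix(gt4, panel = "all", n_boot = 100, seed = 1),
    neutral = pairwise_matrix(gt4, panel = "neutral", n_boot = 100, seed = 1),
    qtl = pairwise_matrix(gt4, panel = "qtl", n_boot = 100, seed = 1))
  rep <- pst_fst_report(psts, fsts)
  expect_equal(nrow(rep$estimates), 6 * 4)     # 6 pairs x (P_ST + 3 panels)
  expect_equal(nrow(rep$comparisons), 3)
  # strong trait divergence, weak neutral divergence: P_ST tops theta
  est <- rep$estimates
  for (pr in unique(est$pair)) {
    p_pst <- est$point[est$pair == pr & est$statistic == "P_ST"]
    p_th <- est$point[est$pair == pr & est$panel == "neutral"]
    expect_gte(p_pst, p_th - 0.05)
  }
})
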