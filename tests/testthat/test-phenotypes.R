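test_that("size correction recovers the pooled slope and leaves b=0 traits alone", {
  set.seed(41)
  g <- rep(c("a", "b"), each = 30)
  size <- c(rnorm(30, 40, 3), rnorm(30, 60, 3))
  # trait independent of size
  y0 <- rnorm(60, 10, 1)
  sc0 <- size_correct(data.frame(t = y0), size, g)
  expect_equal(sc0$model$slope, 0, tolerance = 0.12)
  # exact b = 0 construction: within-group-constant trait
  yc <- ifelse(g == "a", 3, 8)
  scc <- size_correct(data.frame(t = yc), size, g)
  expect_equal(scc$model$slope, 0, tolerance = 1e-12)
  expect_equal(scc$adjusted$t, yc, tolerance = 1e-12)
  # group mean differences of a size-independent trait unchanged
  expect_equal(diff(tapply(scc$adjusted$t, g, mean)),
               diff(tapply(yc, g, mean)), tolerance = 1e-12)
  # trait = 2 * size within groups -> adjusted constant within groups
  y2 <- 2 * size + ifelse(g == "a", 0, 5)
  sc2 <- size_correct(data.frame(t = y2), size, g)
  expect_equal(sc2$model$slope, 2, tolerance = 1e-9)
  expect_lt(max(tapply(sc2$adjusted$t, g, stats::sd)), 1e-9)
  # known slope 1.5 with noise-free construction and hand formula
  y3 <- 1.5 * size + ifelse(g == "a", 1, 4)
  sc3 <- size_correct(data.frame(t = y3), size, g)
  expect_equal(sc3$model$slope, 1.5, tolerance = 1e-9)
  expect_equal(sc3$adjusted$t, y3 - 1.5 * (size - mean(size)), tolerance = 1e-9)
  # zero within-group size variance is an error
  expect_error(size_correct(data.frame(t = y0), rep(c(40, 60), each = 30), g),
               "size variance")
})

test_that("plate morph classes partition [0, 40] with the stated boundaries", {
  expect_equal(as.character(classify_plate_morph(c(5, 10.5, 31))),
               c("low", "partial", "complete"))
  expect_equal(as.character(classify_plate_morph(9)), "low")       # boundary
  expect_equal(as.character(classify_plate_morph(28.5)), "partial")
  expect_equal(as.character(classify_plate_morph(29)), "complete")
  expect_error(classify_plate_morph(-1), ">= 0")
  # total deterministic partition
  x <- seq(0, 40, by = 0.25)
  m <- classify_plate_morph(x)
  expect_false(anyNA(m))
  expect_identical(m, classify_plate_morph(x))
  expect_true(is.na(classify_plate_morph(NA)[1]))
})

test_that("spine PCA concentrates variance as the correlation structure dictates", {
  # perfectly correlated traits: one axis, 100% variance
  set.seed(42)
  z <- rnorm(50)
  perf <- data.frame(DS1 = z, DS2 = 2 * z + 1, PS = 0.5 * z - 3)
  sp <- spine_pca(perf)
  expect_equal(sp$var_explained[1], 1, tolerance = 1e-9)
  expect_equal(sum(sp$loadings[, 1]^2), 1, tolerance = 1e-9)   # unit norm
  # independent equal-variance traits: each axis near 1/3
  iso <- data.frame(DS1 = rnorm(1e4), DS2 = rnorm(1e4), PS = rnorm(1e4))
  si <- spine_pca(iso)
  expect_equal(unname(si$var_explained), rep(1 / 3, 3), tolerance = 0.03)
  # r = 0.95 construction: all axis-1 loadings positive
  rho <- 0.95
  zc <- rnorm(500)
  cor95 <- data.frame(DS1 = rho * zc + sqrt(1 - rho^2) * rnorm(500),
                      DS2 = rho * zc + sqrt(1 - rho^2) * rnorm(500),
                      PS = rho * zc + sqrt(1 - rho^2) * rnorm(500))
  s95 <- spine_pca(cor95)
  expect_true(all(s95$loadings[, 1] > 0))
  expect_gt(s95$var_explained[1], 0.9)
  # scores align with rows, NA for incomplete cases
  cor95$DS1[3] <- NA
  s2 <- spine_pca(cor95)
  expect_true(is.na(s2$scores[3]))
  expect_equal(length(s2$scores), 500)
  expect_error(spine_pca(data.frame(DS1 = c(1, 1, 1), DS2 = c(1, 1, 1),
                                    PS = c(1, 1, 1))), "constant")
})

test_that("trait ANOVA reproduces closed-form identities", {
  # class fully determines the trait
  r <- suppressWarnings(
    trait_anova(rep(c(1, 5, 9), each = 10), rep(c("a", "b", "c"), each = 10)))
  expect_equal(r$R2, 1)
  # F equals the squared two-sample t for 2 balanced classes
  set.seed(43)
  y <- c(rnorm(20, 0), rnorm(20, 1)); g <- rep(c("a", "b"), each = 20)
  r2 <- trait_anova(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-9)
  # E[R2] approx (k-1)/(n-1) under random labels
  set.seed(44)
  r2s <- replicate(200, trait_anova(rnorm(300), sample(rep(c("a", "b", "c"), 100)))$R2)
  expect_lt(abs(mean(r2s) - 2 / 299), 0.002)
  # affine invariance of R2
  r3 <- trait_anova(3 * y - 7, g)
  expect_equal(r3$R2, r2$R2, tolerance = 1e-12)
  expect_error(trait_anova(y, rep("a", 40)), "2 classes")
  # post-hoc output present on request
  r4 <- trait_anova(rep(c(1, 5, 9), each = 10) + rnorm(30, 0, 0.1),
                    rep(c("a", "b", "c"), each = 10), posthoc = TRUE)
  expect_s3_class(r4$tukey, "TukeyHSD")
})

test_that("HWE-expected phenotype fractions follow the penetrance map", {
  expect_equal(expected_complete_fraction(p = 0.283), 0.283^2)
  expect_equal(round(expected_complete_fraction(p = 0.283), 3), 0.08)
  expect_equal(expected_complete_fraction(p = 0), 0)
  expect_equal(expected_complete_fraction(p = 1), 1)
  # dominant penetrance
  expect_equal(expected_complete_fraction(p = 0.3, penetrance = c(CC = 1, CL = 1, LL = 0)),
               0.3^2 + 2 * 0.3 * 0.7)
  # inference from an observed fraction
  expect_equal(expected_complete_fraction(observed_fraction = 0.08, model = "recessive"),
               0.08, tolerance = 1e-12)
  expect_error(expected_complete_fraction(p = 0.5, penetrance = c(CC = 2, CL = 0, LL = 0)),
               "penetrance")
  expect_error(expected_complete_fraction(p = 1.2), "\\[0, 1\\]")
})
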