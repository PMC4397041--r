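test_that("class likelihoods favour the true class at diagnostic loci", {
  bl <- diagnostic_baselines(L = 6, n = 25)
  bf <- baseline_frequencies(bl$A, bl$B)
  het <- rep(1L, 6); het2 <- rep(2L, 6)        # all-heterozygous {1,2}
  lls <- vapply(genotype_classes()$label,
                function(cl) class_likelihood(het, het2, bf, cl), numeric(1))
  expect_equal(names(which.max(lls)), "F1")
  expect_gt(lls["F1"] - max(lls[names(lls) != "F1"]), 0)
  # post-smoothing impossibility: F1 vs parental likelihood ratio > 1e6
  expect_gt(lls["F1"] - lls["PA"], log(1e6))
  expect_gt(lls["F1"] - lls["PB"], log(1e6))
  # all-homozygous-A individual -> PA maximal
  hom <- rep(1L, 6)
  lls2 <- vapply(genotype_classes()$label,
                 function(cl) class_likelihood(hom, hom, bf, cl), numeric(1))
  expect_equal(names(which.max(lls2)), "PA")
  expect_error(class_likelihood(rep(NA_integer_, 6), rep(NA_integer_, 6), bf, "F1"),
               "zero usable loci")
})

test_that("likelihoods equal the brute-force enumeration oracle", {
  set.seed(14)
  # polymorphic two-allele baselines, one to three loci
  for (rep in 1:10) {
    L <- sample(1:3, 1)
    fa <- fb <- list()
    for (l in seq_len(L)) {
      p <- runif(1, 0.1, 0.9); q <- runif(1, 0.1, 0.9)
      fa[[paste0("L", l)]] <- c(`1` = p, `2` = 1 - p)
      fb[[paste0("L", l)]] <- c(`1` = q, `2` = 1 - q)
    }
    gA <- simulate_genotypes(list(A = fa), 6)
    gB <- simulate_genotypes(list(B = fb), 6)
    bf <- baseline_frequencies(gA, gB)
    a1 <- sample(1:2, L, TRUE); a2 <- pmax(a1, sample(1:2, L, TRUE))
    for (cl in genotype_classes()$label)
      expect_equal(class_likelihood(a1, a2, bf, cl),
                   class_likelihood_enum(a1, a2, bf, cl), tolerance = 1e-12)
  }
})

test_that("classification posteriors normalise and nail diagnostic cohorts", {
  bl <- diagnostic_baselines(L = 6, n = 25)
  bf <- baseline_frequencies(bl$A, bl$B)
  set.seed(15)
  f1 <- simulate_class("F1", bf$rawA, bf$rawB, 40, markers = bl$A$markers)
  cp <- classify(f1, bf)
  post <- as.matrix(cp[, paste0("post_", genotype_classes()$label)])
  expect_equal(unname(rowSums(post)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(cp$assigned == "F1"))
  # permutation invariance across loci
  perm <- sample(6)
  f1p <- genotype_table(f1$ids, f1$markers[perm, ], f1$a1[, perm],
                        f1$a2[, perm], f1$groups)
  bfp <- bf
  bfp$p <- bf$p[perm]; bfp$q <- bf$q[perm]
  bfp$loci <- bf$loci[perm]; bfp$markers <- bf$markers[perm, ]
  cpp <- classify(f1p, bfp)
  expect_equal(cp$loglik_F1, cpp$loglik_F1, tolerance = 1e-12)
})

test_that("admixture q hits boundaries, the grid oracle and antisymmetry", {
  bl <- diagnostic_baselines(L = 6, n = 25)
  bf <- baseline_frequencies(bl$A, bl$B)
  # pure A individual -> exactly 1 (boundary optimum)
  qa <- admixture_q(rep(1L, 6), rep(1L, 6), bf)
  expect_identical(qa$q, 1)
  expect_true(qa$pure_flag)
  # all-heterozygous -> 0.5 (likelihood prop. to (q(1-q))^L)
  qh <- admixture_q(rep(1L, 6), rep(2L, 6), bf)
  expect_equal(qh$q, 0.5, tolerance = 1e-4)
  expect_false(qh$pure_flag)
  # one-locus cases agree with the 1e-4 grid oracle
  set.seed(16)
  for (rep in 1:8) {
    p <- runif(1, 0.1, 0.9); q <- runif(1, 0.1, 0.9)
    gA <- simulate_genotypes(list(A = list(L1 = c(`1` = p, `2` = 1 - p))), 10)
    gB <- simulate_genotypes(list(B = list(L1 = c(`1` = q, `2` = 1 - q))), 10)
    bf1 <- baseline_frequencies(gA, gB)
    a1 <- sample(1:2, 1); a2 <- max(a1, sample(1:2, 1))
    got <- admixture_q(a1, a2, bf1)$q
    expect_equal(got, admixture_grid_oracle(a1, a2, bf1), tolerance = 1e-3)
  }
  # antisymmetry under baseline swap
  swapped <- bf
  swapped$p <- bf$q; swapped$q <- bf$p
  swapped$rawA <- bf$rawB; swapped$rawB <- bf$rawA
  set.seed(17)
  bx <- simulate_class("BXA", bf$rawA, bf$rawB, 5, markers = bl$A$markers)
  for (i in 1:5) {
    q1 <- admixture_q(bx$a1[i, ], bx$a2[i, ], bf)$q
    q2 <- admixture_q(bx$a1[i, ], bx$a2[i, ], swapped)$q
    expect_equal(q1, 1 - q2, tolerance = 1e-5)
  }
})

test_that("the purity filter keeps pure fish and drops salted F1s", {
  bl <- diagnostic_baselines(L = 14, n = 30)
  pooled <- bind_genotypes(bl$A, bl$B)
  pf <- purity_filter(pooled, "A", "B")
  expect_equal(n_ind(pf$baselineA), 30)           # all retained
  expect_equal(n_ind(pf$baselineB), 30)
  expect_length(pf$excluded, 0)
  # salt baseline A with 10% F1s mislabelled as A
  bf <- baseline_frequencies(bl$A, bl$B)
  set.seed(18)
  f1 <- simulate_class("F1", bf$rawA, bf$rawB, 3, markers = bl$A$markers)
  f1$groups[] <- "A"
  salted <- bind_genotypes(bl$A, f1, bl$B)
  pf2 <- purity_filter(salted, "A", "B", threshold = 0.9)
  expect_setequal(pf2$excluded, f1$ids)
  expect_equal(n_ind(pf2$baselineA), 30)
  # threshold 0 is the identity filter
  pf3 <- purity_filter(salted, "A", "B", threshold = 0)
  expect_length(pf3$excluded, 0)
  # over-aggressive threshold errors with advice
  tiny <- bind_genotypes(subset_individuals(bl$A, 1:2), subset_individuals(bl$B, 1:2))
  set.seed(19)
  noisy <- make_gt(list(A = matrix(sample(1:2, 40, TRUE), 2),
                        B = matrix(sample(1:2, 40, TRUE), 2)),
                   loci = sprintf("D%d", 1:10))
  expect_error(purity_filter(noisy, "A", "B", threshold = 0.999), "relax")
})

test_that("power is non-decreasing along a diagnostic-locus ladder", {
  accs <- vapply(c(2, 6, 14), function(L) {
    bl <- diagnostic_baselines(L = L, n = 25)
    pr <- power_analysis(bl$A, bl$B, cross_spec(n_per_class = 15, n_reps = 2, seed = 55))
    mean(pr$per_class[c("F1", "F2", "BXA", "BXB")])
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-9))
  expect_gt(accs[3], accs[1])
})

test_that("power reports are deterministic and structurally sound", {
  bl <- make_power_baselines(f = 0.5, n_loci = 8, n_per_pop = 30, seed = 21)
  spec <- cross_spec(n_per_class = 10, n_reps = 2, seed = 22)
  p1 <- power_analysis(bl$A, bl$B, spec)
  p2 <- power_analysis(bl$A, bl$B, spec)
  expect_identical(p1$per_rep, p2$per_rep)
  expect_identical(p1$confusion, p2$confusion)
  # confusion rows sum to n_per_class * n_reps for simulated classes
  expect_equal(unname(rowSums(p1$confusion)[c("F1", "F2", "BXA", "BXB")]),
               rep(10 * 2, 4))
  expect_true(all(p1$per_class >= 0 & p1$per_class <= 1))
})
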