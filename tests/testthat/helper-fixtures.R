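# Small builders used across the suite.

# Build a genotype table from a list of per-group call matrices:
# make_gt(list(g1 = rbind(c(1,1), c(1,2))), loci = "L1") -> 2 individuals,
# 1 locus. Each group entry is an n x (2*L) matrix of allele pairs
# (a1, a2 per locus, columns interleaved).
make_gt <- function(groups, loci = NULL, panel = NULL) {
  L <- ncol(groups[[1]]) / 2
  if (is.null(loci)) loci <- sprintf("L%d", seq_len(L))
  if (is.null(panel)) panel <- rep("neutral", L)
  ids <- character(0); grp <- character(0)
  a1 <- a2 <- NULL
  for (g in names(groups)) {
    m <- groups[[g]]
    ids <- c(ids, sprintf("%s_%d", g, seq_len(nrow(m))))
    grp <- c(grp, rep(g, nrow(m)))
    a1 <- rbind(a1, m[, seq(1, 2 * L, 2), drop = FALSE])
    a2 <- rbind(a2, m[, seq(2, 2 * L, 2), drop = FALSE])
  }
  genotype_table(ids, data.frame(name = loci, panel = panel), a1, a2, grp)
}

# Two baselines fixed for disjoint alleles (1 vs 2) at `L` diagnostic loci.
diagnostic_baselines <- function(L = 6, n = 20) {
  m1 <- matrix(1L, n, 2 * L); m2 <- matrix(2L, n, 2 * L)
  list(A = make_gt(list(A = m1), loci = sprintf("D%d", 1:L)),
       B = make_gt(list(B = m2), loci = sprintf("D%d", 1:L)))
}

# Random small genotype table for property tests (<= 4 groups, <= 6
# alleles, n = 3..10 per group, occasional missingness).
random_gt <- function(seed) {
  set.seed(seed)
  r <- sample(2:4, 1)
  L <- sample(1:3, 1)
  groups <- list()
  for (g in seq_len(r)) {
    n <- sample(3:10, 1)
    m <- matrix(NA_integer_, n, 2 * L)
    for (l in seq_len(L)) {
      k <- sample(2:6, 1)
      f <- stats::runif(k); f <- f / sum(f)
      m[, 2 * l - 1] <- sample(seq_len(k), n, TRUE, prob = f)
      m[, 2 * l] <- sample(seq_len(k), n, TRUE, prob = f)
    }
    if (stats::runif(1) < 0.3) {
      drop <- stats::runif(n * L) < 0.05
      for (l in seq_len(L)) {
        d <- drop[(l - 1) * n + seq_len(n)]
        m[d, 2 * l - 1] <- NA_integer_; m[d, 2 * l] <- NA_integer_
      }
    }
    groups[[paste0("g", g)]] <- m
  }
  make_gt(groups)
}
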