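# Independent oracles, kept deliberately separate from the package's own
# computation paths.

# Weir-Cockerham theta via the nested-ANOVA mean-squares route (sums of
# squares over allele indicators at the population / individual / gene-copy
# levels), algebraically equivalent to the direct variance-component
# formulas the package uses but organised differently.
theta_anova_oracle <- function(gt, grouping = NULL) {
  grp <- if (is.null(grouping)) gt$groups else grouping
  grp <- unname(grp[gt$ids])
  num <- den <- 0
  for (l in seq_len(nrow(gt$markers))) {
    a1 <- gt$a1[, l]; a2 <- gt$a2[, l]
    typed <- !is.na(a1)
    a1 <- a1[typed]; a2 <- a2[typed]; g <- grp[typed]
    pops <- unique(g); r <- length(pops)
    if (r < 2) next
    n_i <- vapply(pops, function(p) sum(g == p), numeric(1))
    S1 <- sum(n_i)
    if (S1 / r <= 1) next
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2) next
    nc <- (S1 - sum(n_i^2) / S1) / (r - 1)
    for (u in alleles) {
      p_i <- vapply(pops, function(p) {
        s <- g == p; (sum(a1[s] == u) + sum(a2[s] == u)) / (2 * sum(s))
      }, numeric(1))
      h_i <- vapply(pops, function(p) {
        s <- g == p; mean((a1[s] == u) != (a2[s] == u))
      }, numeric(1))
      pbar <- sum(n_i * p_i) / S1
      MSP <- sum(2 * n_i * (p_i - pbar)^2) / (r - 1)
      MSI <- sum(2 * n_i * p_i * (1 - p_i) - n_i * h_i / 2) / (S1 - r)
      MSG <- sum(n_i * h_i) / (2 * S1)
      a <- (MSP - MSI) / (2 * nc)
      b <- (MSI - MSG) / 2
      num <- num + a
      den <- den + a + b + MSG
    }
  }
  num / den
}

# Brute-force genotype-class likelihood: enumerate the ancestry-pair
# outcome of the locus and, within it, every ordered pair of allele draws.
class_likelihood_enum <- function(a1, a2, baseline, class) {
  phi <- genotype_classes()
  phi <- phi[phi$label == class, ]
  ll <- 0
  for (l in seq_along(baseline$loci)) {
    if (is.na(a1[l])) next
    p <- baseline$p[[l]]; q <- baseline$q[[l]]
    al <- as.integer(names(p))
    target <- sort(c(a1[l], a2[l]))
    prob <- 0
    for (z in c("AA", "AB", "BB")) {
      w <- switch(z, AA = phi$phi_AA, AB = phi$phi_AB, BB = phi$phi_BB)
      if (w == 0) next
      f1 <- if (z == "BB") q else p
      f2 <- if (z == "AA") p else q
      for (x in al) for (y in al)
        if (identical(sort(c(x, y)), target))
          prob <- prob + w * f1[as.character(x)] * f2[as.character(y)]
    }
    ll <- ll + log(prob)
  }
  unname(ll)
}

# Grid-search admixture proportion at 1e-4 resolution.
admixture_grid_oracle <- function(a1, a2, baseline) {
  qs <- seq(0, 1, by = 1e-4)
  ll <- vapply(qs, function(qv) {
    s <- 0
    for (l in seq_along(baseline$loci)) {
      if (is.na(a1[l])) next
      x <- qv * baseline$p[[l]] + (1 - qv) * baseline$q[[l]]
      i <- as.character(a1[l]); j <- as.character(a2[l])
      s <- s + if (i == j) 2 * log(x[i]) else log(2 * x[i] * x[j])
    }
    s
  }, numeric(1))
  qs[which.max(ll)]
}
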