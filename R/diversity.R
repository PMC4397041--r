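#' Observed and unbiased expected heterozygosity
#'
#' Per group x locus, `H_O` is the fraction of typed individuals that are
#' heterozygous and `H_E` is the small-sample-corrected expected
#' heterozygosity `(2n/(2n-1)) * (1 - sum(p_a^2))` with `n` the number of
#' typed diploid individuals. Group x locus cells with no typed individual
#' are reported as missing.
#'
#' @param gt a [genotype_table()].
#' @param grouping optional named grouping vector (defaults to `gt$groups`).
#' @return A list of class `diversity_result` with `per_locus` (data.frame:
#'   group, locus, panel, n_typed, H_O, H_E) and `group_means` (data.frame:
#'   group, panel, mean_HO, mean_HE averaged across the panel's loci).
#' @export
heterozygosity <- function(gt, grouping = NULL) {
  af <- allele_frequencies(gt, grouping)
  grouping <- if (is.null(grouping)) gt$groups else grouping
  if (is.null(names(grouping))) grouping <- stats::setNames(as.character(grouping), gt$ids)
  rows <- list()
  for (g in af$groups) {
    gi <- which(grouping[gt$ids] == g)
    for (l in seq_along(af$loci)) {
      n <- af$n_typed[g, l]
      if (n == 0L) { ho <- he <- NA_real_ } else {
        a1 <- gt$a1[gi, l]; a2 <- gt$a2[gi, l]
        typed <- !is.na(a1)
        ho <- mean(a1[typed] != a2[typed])
        p <- af$freqs[[g]][[l]]
        he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
        if (n == 1L) he <- 2 * (1 - sum(p^2))  # 2n/(2n-1) = 2 at n = 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, locus = af$loci[l], panel = gt$markers$panel[l],
        n_typed = n, H_O = ho, H_E = he)
    }
  }
  per_locus <- do.call(rbind, rows)
  gm <- do.call(rbind, lapply(split(per_locus, per_locus[c("group", "panel")]), function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(group = d$group[1], panel = d$panel[1],
               mean_HO = mean(d$H_O, na.rm = TRUE),
               mean_HE = mean(d$H_E, na.rm = TRUE))
  }))
  rownames(gm) <- NULL
  structure(list(per_locus = per_locus, group_means = gm), class = "diversity_result")
}

# chi-square goodness-of-fit statistic of genotype counts against HWE
# expectations. `pairs` is a 2-column matrix of canonicalised allele codes;
# `classes` / `expected` come from .hwe_classes() so that rare expected
# classes are pooled consistently between the observed table and permuted
# tables.
.hwe_stat <- function(pairs, classes, expected) {
  key <- paste(pairs[, 1], pairs[, 2])
  obs <- vapply(classes, function(cl) sum(key %in% cl), numeric(1))
  sum((obs - expected)^2 / expected)
}

# Genotype classes under HWE from allele frequencies; classes with expected
# count < 1 are pooled into one "other" class.
.hwe_classes <- function(p, n) {
  al <- names(p)
  k <- length(al)
  cls <- list(); exp_ct <- numeric(0)
  for (i in seq_len(k)) for (j in i:k) {
    e <- if (i == j) n * p[i]^2 else 2 * n * p[i] * p[j]
    cls[[length(cls) + 1L]] <- paste(al[i], al[j])
    exp_ct <- c(exp_ct, e)
  }
  small <- exp_ct < 1
  if (any(small) && sum(small) > 1) {
    pooled <- unlist(cls[small])
    cls <- c(cls[!small], list(pooled))
    exp_ct <- c(exp_ct[!small], sum(exp_ct[small]))
  }
  list(classes = cls, expected = exp_ct, n_alleles = k)
}

#' Hardy-Weinberg equilibrium tests per group and locus
#'
#' Two methods: `"chi2"` is a goodness-of-fit test of observed genotype
#' counts against HWE expectations computed from the observed allele
#' frequencies (genotype classes with expected count < 1 pooled into one
#' class; df = number of classes minus number of alleles, at least 1);
#' `"exact_mc"` is a Monte Carlo exact test that permutes the `2n` allele
#' copies into random diploid pairings and reports
#' `p = (1 + #\{permuted chi-square >= observed\}) / (1 + n_perm)`.
#'
#' Monomorphic group x locus cells return `p = 1` by convention; cells with
#' fewer than 2 typed individuals are missing. The Bonferroni flag treats
#' all tests computed in the one call as a single family.
#'
#' @param gt a [genotype_table()].
#' @param grouping optional named grouping vector.
#' @param method `"exact_mc"` (default) or `"chi2"`.
#' @param n_perm Monte Carlo permutations for `"exact_mc"`.
#' @param alpha family-wise significance level for the Bonferroni flag.
#' @param seed optional integer seed for the Monte Carlo permutations.
#' @return A data.frame of class `hwe_result`: group, locus, n_typed,
#'   statistic, p_value, method, n_perm, significant_after_bonferroni.
#' @export
hwe_test <- function(gt, grouping = NULL, method = c("exact_mc", "chi2"),
                     n_perm = 10000, alpha = 0.05, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  af <- allele_frequencies(gt, grouping)
  grouping <- if (is.null(grouping)) gt$groups else grouping
  if (is.null(names(grouping))) grouping <- stats::setNames(as.character(grouping), gt$ids)
  rows <- list()
  for (g in af$groups) {
    gi <- which(grouping[gt$ids] == g)
    for (l in seq_along(af$loci)) {
      n <- af$n_typed[g, l]
      stat <- p <- NA_real_
      if (n >= 2L) {
        a1 <- gt$a1[gi, l]; a2 <- gt$a2[gi, l]
        typed <- !is.na(a1)
        pairs <- cbind(a1[typed], a2[typed])
        pfreq <- af$freqs[[g]][[l]]
        if (length(pfreq) < 2L) { stat <- 0; p <- 1 } else {
          hc <- .hwe_classes(pfreq, n)
          stat <- .hwe_stat(pairs, hc$classes, hc$expected)
          if (method == "chi2") {
            df <- max(1L, length(hc$classes) - hc$n_alleles)
            p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
          } else {
            copies <- c(pairs[, 1], pairs[, 2])
            ge <- 0L
            for (b in seq_len(n_perm)) {
              perm <- sample(copies)
              pp <- cbind(pmin(perm[seq_len(n)], perm[n + seq_len(n)]),
                          pmax(perm[seq_len(n)], perm[n + seq_len(n)]))
              if (.hwe_stat(pp, hc$classes, hc$expected) >= stat - 1e-12) ge <- ge + 1L
            }
            p <- (1 + ge) / (1 + n_perm)
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, locus = af$loci[l], n_typed = n, statistic = stat,
        p_value = p, method = method,
        n_perm = if (method == "exact_mc") n_perm else NA_integer_)
    }
  }
  res <- do.call(rbind, rows)
  res$significant_after_bonferroni <- bonferroni(res$p_value, alpha = alpha)
  class(res) <- c("hwe_result", "data.frame")
  res
}

#' Bonferroni correction flags
#'
#' Flags `p_i < alpha / m` where `m` is the family size, i.e. the number of
#' non-missing p-values supplied in the one call.
#'
#' @param p_values numeric vector of p-values (NA allowed, stays NA).
#' @param alpha family-wise significance level.
#' @return Logical vector of the same length.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(logical(0))
  m <- sum(!is.na(p_values))
  if (m == 0L) return(rep(NA, length(p_values)))
  p_values < alpha / m
}
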