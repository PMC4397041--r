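#' One-way variance components for a quantitative trait
#'
#' Decomposes trait variance into the among-population component
#' `sigma2_GB` and the average within-population component `sigma2_GW`,
#' with population as a random intercept. `method = "reml"` (default) fits
#' the random-intercept model by REML via lme4; boundary estimates are
#' reported as 0 and flagged. `method = "moments"` is the one-way ANOVA
#' method-of-moments solution (`sigma2_GB = max(0, (MS_between -
#' MS_within)/n0)` with `n0` the effective per-group size), which equals
#' the REML solution for balanced designs and is used inside bootstraps
#' where thousands of fits are needed.
#'
#' Groups with fewer than 2 non-missing values are excluded with a warning;
#' fewer than 2 usable groups is an error.
#'
#' @param values numeric trait values, one per individual (NA allowed).
#' @param grouping group label per value.
#' @param method `"reml"` or `"moments"`.
#' @return A list of class `variance_components`: `sigma2_GB`, `sigma2_GW`,
#'   `n_groups`, `n_total`, `method`, `boundary` (TRUE when the
#'   among-group component was truncated at 0).
#' @export
variance_components <- function(values, grouping, method = c("reml", "moments")) {
  method <- match.arg(method)
  keep <- !is.na(values) & !is.na(grouping)
  values <- values[keep]; grouping <- as.character(grouping[keep])
  sizes <- table(grouping)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 values: ", paste(small, collapse = ", "))
    keep <- !grouping %in% small
    values <- values[keep]; grouping <- grouping[keep]
    sizes <- table(grouping)
  }
  r <- length(sizes)
  if (r < 2L) stop("need at least 2 groups with >= 2 values each")
  N <- length(values)
  if (method == "reml") {
    fit <- lme4::lmer(values ~ 1 + (1 | grouping),
                      data = data.frame(values = values, grouping = grouping),
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    gb <- vc$vcov[vc$grp == "grouping"]
    gw <- vc$vcov[vc$grp == "Residual"]
    boundary <- gb < 1e-10
    gb <- max(0, gb)
  } else {
    n_i <- as.numeric(sizes)
    mu_i <- tapply(values, grouping, mean)
    gm <- sum(n_i * mu_i) / N
    ssw <- sum((values - mu_i[grouping])^2)
    msw <- ssw / (N - r)
    msb <- sum(n_i * (mu_i - gm)^2) / (r - 1)
    n0 <- (N - sum(n_i^2) / N) / (r - 1)
    gb <- (msb - msw) / n0
    boundary <- gb < 0
    gb <- max(0, gb)
    gw <- msw
  }
  structure(list(sigma2_GB = gb, sigma2_GW = gw, n_groups = r, n_total = N,
                 method = method, boundary = boundary),
            class = "variance_components")
}

#' P_ST from variance components
#'
#' `P_ST = c/h2 * sigma2_GB / (c/h2 * sigma2_GB + 2 * sigma2_GW)`. The
#' default `scalar = 1` (the ratio of the proportion of phenotypic variance
#' that is additive between versus within populations, c/h^2) gives the
#' plain form `sigma2_GB / (sigma2_GB + 2*sigma2_GW)`; other values support
#' sensitivity analyses.
#'
#' @param vc a [variance_components()] result (or a list with `sigma2_GB`
#'   and `sigma2_GW`).
#' @param scalar the c/h^2 multiplier on the among-population component.
#' @return The P_ST value in `[0, 1]`.
#' @export
pst <- function(vc, scalar = 1) {
  gb <- vc$sigma2_GB; gw <- vc$sigma2_GW
  if (gb == 0 && gw == 0) stop("both variance components are zero: P_ST undefined")
  scalar * gb / (scalar * gb + 2 * gw)
}

# Vectorised moments bootstrap of pairwise P_ST: resample individuals with
# replacement within each of two groups; degenerate replicates (no variance
# anywhere) are recorded as 0 per the estimator's convention.
.boot_pst_pair <- function(v1, v2, n_boot, scalar) {
  n1 <- length(v1); n2 <- length(v2); N <- n1 + n2
  m1 <- matrix(sample(v1, n1 * n_boot, replace = TRUE), n1)
  m2 <- matrix(sample(v2, n2 * n_boot, replace = TRUE), n2)
  mu1 <- colMeans(m1); mu2 <- colMeans(m2)
  ss1 <- colSums(m1^2) - n1 * mu1^2
  ss2 <- colSums(m2^2) - n2 * mu2^2
  msw <- (ss1 + ss2) / (N - 2)
  gm <- (n1 * mu1 + n2 * mu2) / N
  msb <- n1 * (mu1 - gm)^2 + n2 * (mu2 - gm)^2
  n0 <- (N - (n1^2 + n2^2) / N)
  gb <- pmax(0, (msb - msw) / n0)
  den <- scalar * gb + 2 * msw
  ifelse(den == 0, 0, scalar * gb / den)
}

#' Pairwise P_ST with bootstrap confidence intervals
#'
#' For each unordered group pair, variance components are fitted on that
#' pair only (REML point estimate) and P_ST computed; the 95% CI is the
#' percentile interval over `n_boot` resamples of individuals with
#' replacement within each group (method-of-moments components per
#' replicate; replicates with zero variance everywhere are recorded as 0).
#'
#' @param phenotypes data.frame with an `id` column and the trait column,
#'   as from [read_phenotypes()].
#' @param grouping named character vector keyed by individual id.
#' @param trait trait column name (default `"mean_plates"`).
#' @param n_boot bootstrap replicates.
#' @param seed optional integer seed.
#' @param scalar c/h^2 multiplier, see [pst()].
#' @param conf confidence level.
#' @return A list of class `pairwise_pst`: `point`, `ci_low`, `ci_high`
#'   (group x group matrices), `per_pair` data.frame, `trait`, `n_boot`.
#' @export
pairwise_pst <- function(phenotypes, grouping, trait = "mean_plates",
                         n_boot = 1000, seed = NULL, scalar = 1, conf = 0.95) {
  if (!trait %in% names(phenotypes)) stop("trait '", trait, "' not in phenotype table")
  if (!is.null(seed)) set.seed(seed)
  val <- stats::setNames(phenotypes[[trait]], phenotypes$id)
  grouping <- grouping[names(val)]
  keep <- !is.na(val) & !is.na(grouping)
  val <- val[keep]; grouping <- grouping[keep]
  groups <- unique(unname(grouping))
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  point <- lo <- hi <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v1 <- val[grouping == groups[i]]; v2 <- val[grouping == groups[j]]
    vc <- variance_components(c(v1, v2), rep(c(groups[i], groups[j]),
                                             c(length(v1), length(v2))))
    p0 <- pst(vc, scalar)
    reps <- .boot_pst_pair(v1, v2, n_boot, scalar)
    ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    point[i, j] <- point[j, i] <- p0
    lo[i, j] <- lo[j, i] <- ci[1]; hi[i, j] <- hi[j, i] <- ci[2]
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste(groups[i], groups[j], sep = ":"),
      group1 = groups[i], group2 = groups[j], statistic = "P_ST",
      panel = "phenotype", point = p0, ci_low = ci[1], ci_high = ci[2])
  }
  structure(list(point = point, ci_low = lo, ci_high = hi,
                 per_pair = do.call(rbind, rows), trait = trait,
                 n_boot = n_boot, scalar = scalar),
            class = "pairwise_pst")
}

#' t statistic for a Pearson correlation
#'
#' `t = r * sqrt(df) / sqrt(1 - r^2)` with the two-sided p-value from the
#' central t distribution on `df` degrees of freedom.
#'
#' @param r Pearson correlation coefficient.
#' @param df degrees of freedom (number of pairs minus 2).
#' @return list with `r`, `t`, `df`, `p`.
#' @export
cor_t_stat <- function(r, df) {
  if (abs(r) >= 1 - 1e-12) {
    warning("|r| = 1: t statistic is infinite")
    t <- sign(r) * Inf
  } else t <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' P_ST-F_ST correlation across group pairs
#'
#' Vectorises the two pairwise matrices in matching pair order and tests
#' the Pearson correlation, treating the pairwise values as independent
#' observations (df = number of pairs - 2).
#'
#' @param pst_matrix a [pairwise_pst()] result (or a named numeric vector
#'   of pairwise P_ST values keyed `"g1:g2"`).
#' @param fst_matrix a [pairwise_matrix()] result (or a matching named
#'   numeric vector).
#' @return A list of class `pst_fst_comparison`: `pairs`, `pst_values`,
#'   `fst_values`, `r`, `t`, `df`, `p`.
#' @export
pst_fst_correlation <- function(pst_matrix, fst_matrix) {
  pv <- if (inherits(pst_matrix, "pairwise_pst"))
    stats::setNames(pst_matrix$per_pair$point, pst_matrix$per_pair$pair)
  else pst_matrix
  fv <- if (inherits(fst_matrix, "pairwise_diff")) {
    lng <- pairwise_long(fst_matrix)
    stats::setNames(lng$point, lng$pair)
  } else fst_matrix
  pairs <- intersect(names(pv), names(fv))
  if (length(pairs) < 4L) stop("need >= 4 shared group pairs (df >= 2)")
  x <- unname(pv[pairs]); y <- unname(fv[pairs])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant pairwise values: correlation undefined")
  r <- stats::cor(x, y)
  ts <- cor_t_stat(r, length(pairs) - 2L)
  structure(list(pairs = pairs, pst_values = x, fst_values = y,
                 r = r, t = ts$t, df = ts$df, p = ts$p),
            class = "pst_fst_comparison")
}

#' @export
print.pst_fst_comparison <- function(x, ...) {
  cat(sprintf("P_ST-F_ST correlation over %d pairs: r = %.2f, t = %.2f, df = %d, P = %.2g\n",
              length(x$pairs), x$r, x$t, x$df, x$p))
  invisible(x)
}

#' Combined P_ST / F_ST report table
#'
#' Long-format table of every pairwise estimate (P_ST plus each marker
#' panel's differentiation statistic) with confidence intervals, suitable
#' for a grouped barplot, plus one P_ST-F_ST correlation row per panel.
#'
#' @param pst_matrix a [pairwise_pst()] result.
#' @param fst_matrices named list of [pairwise_matrix()] results, one per
#'   marker panel.
#' @return list of class `pst_fst_report`: `estimates` (long data.frame:
#'   pair, statistic, panel, point, ci_low, ci_high) and `comparisons`
#'   (data.frame: panel, r, t, df, p).
#' @export
pst_fst_report <- function(pst_matrix, fst_matrices) {
  est <- pst_matrix$per_pair[c("pair", "statistic", "panel", "point", "ci_low", "ci_high")]
  cmp <- list()
  for (nm in names(fst_matrices)) {
    lng <- pairwise_long(fst_matrices[[nm]])
    lng$panel <- nm
    est <- rbind(est, lng[c("pair", "statistic", "panel", "point", "ci_low", "ci_high")])
    cc <- pst_fst_correlation(pst_matrix, fst_matrices[[nm]])
    cmp[[nm]] <- data.frame(panel = nm, r = cc$r, t = cc$t, df = cc$df, p = cc$p)
  }
  structure(list(estimates = est, comparisons = do.call(rbind, cmp)),
            class = "pst_fst_report")
}
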