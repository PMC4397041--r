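# Per-locus Weir-Cockerham variance components, summed over alleles.
# Returns list(num = sum of among-population components a, den = sum of
# a + b + c) or NULL when the locus is unusable (fewer than 2 groups typed,
# or mean sample size <= 1); monomorphic loci come back with den = 0 and
# are excluded upstream.
.theta_locus <- function(a1, a2, grp) {
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]; grp <- grp[typed]
  groups <- unique(grp)
  r <- length(groups)
  if (r < 2L) return(NULL)
  n_i <- vapply(groups, function(g) sum(grp == g), numeric(1))
  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(list(num = 0, den = 0))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  num <- den <- 0
  for (u in alleles) {
    p_i <- h_i <- numeric(r)
    for (k in seq_len(r)) {
      s <- grp == groups[k]
      p_i[k] <- (sum(a1[s] == u) + sum(a2[s] == u)) / (2 * n_i[k])
      h_i[k] <- mean((a1[s] == u) != (a2[s] == u))
    }
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  list(num = num, den = den)
}

# Per-locus Jost's D components. Sample-size-corrected within-group
# heterozygosity Hs uses 2*nh/(2*nh - 1) with nh the harmonic mean group
# size; the total heterozygosity Ht (from unweighted mean allele
# frequencies) carries the matching Hs/(2*nh*r) correction (Nei-Chesser).
.jost_locus <- function(a1, a2, grp) {
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]; grp <- grp[typed]
  groups <- unique(grp)
  r <- length(groups)
  if (r < 2L) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(list(mono = TRUE))
  n_i <- vapply(groups, function(g) sum(grp == g), numeric(1))
  nh <- r / sum(1 / n_i)
  p <- matrix(0, length(alleles), r)
  for (k in seq_len(r)) {
    s <- grp == groups[k]
    p[, k] <- vapply(alleles, function(u) (sum(a1[s] == u) + sum(a2[s] == u)) / (2 * n_i[k]),
                     numeric(1))
  }
  hs <- mean(1 - colSums(p^2))
  Hs <- (2 * nh / (2 * nh - 1)) * hs
  pbar <- rowMeans(p)
  Ht <- (1 - sum(pbar^2)) + Hs / (2 * nh * r)
  if (Hs >= 1) return(list(mono = FALSE, undefined = TRUE))
  list(mono = FALSE, undefined = FALSE, Hs = Hs, Ht = Ht, r = r,
       D = (Ht - Hs) / (1 - Hs) * r / (r - 1))
}

.new_diff_estimate <- function(statistic, per_locus, value, panel, groups,
                               excluded, ci = c(NA_real_, NA_real_), extra = list()) {
  structure(c(list(statistic = statistic, per_locus = per_locus, value = value,
                   ci_low = ci[1], ci_high = ci[2], panel = panel,
                   groups = groups, excluded = excluded), extra),
            class = "diff_estimate")
}

#' @export
print.diff_estimate <- function(x, ...) {
  cat(sprintf("%s [%s panel, groups: %s]\n  multi-locus = %.4f", x$statistic,
              x$panel, paste(x$groups, collapse = ", "), x$value))
  if (!is.na(x$ci_low)) cat(sprintf("  (95%% CI %.4f, %.4f)", x$ci_low, x$ci_high))
  cat("\n ", sum(!is.na(x$per_locus)), "loci used;",
      length(x$excluded), "excluded\n")
  invisible(x)
}

#' Weir-Cockerham theta (F_ST estimator)
#'
#' Moment estimator of F_ST from the 1984 variance components: per allele
#' at each locus the among-population (`a`), among-individual-within-
#' population (`b`) and within-individual (`c`) components are computed
#' from group sizes, allele frequencies and observed heterozygote
#' proportions; the locus estimate is `sum(a)/sum(a+b+c)` over alleles and
#' the multi-locus estimate is the ratio of sums over all loci and alleles
#' (not a mean of per-locus ratios). Negative estimates are reported, not
#' clamped. Loci monomorphic across all groups (zero denominator) or typed
#' in fewer than two groups are excluded with a message.
#'
#' @param gt a [genotype_table()].
#' @param grouping optional named grouping vector (defaults to `gt$groups`).
#' @param panel `"all"`, `"neutral"` or `"qtl"`.
#' @return A `diff_estimate`: per-locus values, multi-locus `value`, the
#'   per-locus component sums (`loc_num`, `loc_den`, reused by the locus
#'   bootstrap), panel and groups.
#' @export
wc_theta <- function(gt, grouping = NULL, panel = "all") {
  gt <- subset_panel(gt, panel)
  grp <- if (is.null(grouping)) gt$groups else {
    if (is.null(names(grouping))) stats::setNames(as.character(grouping), gt$ids)
    else grouping[gt$ids]
  }
  loci <- gt$markers$name
  num <- den <- stats::setNames(rep(NA_real_, length(loci)), loci)
  for (l in seq_along(loci)) {
    comp <- .theta_locus(gt$a1[, l], gt$a2[, l], unname(grp))
    if (!is.null(comp)) { num[l] <- comp$num; den[l] <- comp$den }
  }
  usable <- !is.na(den) & den != 0
  excluded <- loci[!usable]
  if (!any(usable)) stop("no usable polymorphic loci for theta")
  if (length(excluded))
    message("wc_theta: excluded ", length(excluded), " locus/loci (monomorphic or untyped): ",
            paste(excluded, collapse = ", "))
  per_locus <- ifelse(usable, num / den, NA_real_)
  names(per_locus) <- loci
  .new_diff_estimate("theta_WC", per_locus, sum(num[usable]) / sum(den[usable]),
                     panel, unique(unname(grp)), excluded,
                     extra = list(loc_num = num[usable], loc_den = den[usable]))
}

#' Jost's D differentiation estimator
#'
#' Per locus, `D = [(H_T - H_S)/(1 - H_S)] * n/(n-1)` with `n` groups,
#' where `H_S` is the mean within-group expected heterozygosity corrected
#' by `2*nh/(2*nh - 1)` (`nh` = harmonic mean group size) and `H_T` is the
#' total expected heterozygosity from the unweighted mean allele
#' frequencies plus its matching correction `H_S/(2*nh*n)`. The multi-locus
#' value combines across-locus arithmetic means of the `H_S` and `H_T`
#' components before taking the ratio (`d_combine = "components"`), or
#' averages the per-locus D values (`"mean_of_loci"`). Shared-monomorphic
#' loci and loci with `H_S = 1` are excluded with a message.
#'
#' @inheritParams wc_theta
#' @param d_combine multi-locus combination rule, `"components"` (default)
#'   or `"mean_of_loci"`.
#' @return A `diff_estimate` with per-locus `H_S`/`H_T` components in
#'   `loc_hs`/`loc_ht`.
#' @export
jost_d <- function(gt, grouping = NULL, panel = "all",
                   d_combine = c("components", "mean_of_loci")) {
  d_combine <- match.arg(d_combine)
  gt <- subset_panel(gt, panel)
  grp <- if (is.null(grouping)) gt$groups else {
    if (is.null(names(grouping))) stats::setNames(as.character(grouping), gt$ids)
    else grouping[gt$ids]
  }
  loci <- gt$markers$name
  D <- hs <- ht <- stats::setNames(rep(NA_real_, length(loci)), loci)
  r_used <- NA_integer_
  for (l in seq_along(loci)) {
    comp <- .jost_locus(gt$a1[, l], gt$a2[, l], unname(grp))
    if (is.null(comp) || isTRUE(comp$mono) || isTRUE(comp$undefined)) next
    D[l] <- comp$D; hs[l] <- comp$Hs; ht[l] <- comp$Ht; r_used <- comp$r
  }
  usable <- !is.na(D)
  excluded <- loci[!usable]
  if (!any(usable)) stop("no usable polymorphic loci for Jost's D")
  if (length(excluded))
    message("jost_d: excluded ", length(excluded), " locus/loci: ",
            paste(excluded, collapse = ", "))
  value <- if (d_combine == "components") {
    mhs <- mean(hs[usable]); mht <- mean(ht[usable])
    (mht - mhs) / (1 - mhs) * r_used / (r_used - 1)
  } else mean(D[usable])
  .new_diff_estimate("D_Jost", D, value, panel, unique(unname(grp)), excluded,
                     extra = list(loc_hs = hs[usable], loc_ht = ht[usable],
                                  n_groups = r_used, d_combine = d_combine))
}

# Locus bootstrap of a diff_estimate: resample used loci with replacement
# and recombine with the estimator's own multi-locus rule.
.boot_loci <- function(est, n_boot, conf) {
  reps <- numeric(n_boot)
  if (est$statistic == "theta_WC") {
    num <- est$loc_num; den <- est$loc_den; L <- length(num)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(L, L, replace = TRUE)
      reps[b] <- sum(num[idx]) / sum(den[idx])
    }
  } else {
    hs <- est$loc_hs; ht <- est$loc_ht; L <- length(hs); r <- est$n_groups
    per_d <- (ht - hs) / (1 - hs) * r / (r - 1)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(L, L, replace = TRUE)
      reps[b] <- if (est$d_combine == "components") {
        mhs <- mean(hs[idx]); mht <- mean(ht[idx])
        (mht - mhs) / (1 - mhs) * r / (r - 1)
      } else mean(per_d[idx])
    }
  }
  stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE, na.rm = TRUE)
}

#' Pairwise differentiation matrix with bootstrap confidence intervals
#'
#' Computes the chosen differentiation statistic for every unordered group
#' pair on the requested marker panel, with 95% percentile-bootstrap
#' confidence intervals. The default bootstrap unit is loci (resampled with
#' replacement, the standard for multi-locus differentiation); resampling
#' individuals within groups is available via `boot_unit = "individuals"`.
#'
#' @inheritParams wc_theta
#' @param statistic `"theta_WC"` or `"D_Jost"`.
#' @param n_boot number of bootstrap replicates.
#' @param seed optional integer seed (identical seed, identical CIs).
#' @param boot_unit `"loci"` (default) or `"individuals"`.
#' @param conf confidence level.
#' @param d_combine passed to [jost_d()].
#' @return A list of class `pairwise_diff`: `point`, `ci_low`, `ci_high`
#'   (group x group matrices, lower triangle filled symmetrically),
#'   `mean_pairwise` (mean of the pairwise multi-locus values), `per_pair`
#'   (named list of `diff_estimate`), plus `statistic` and `panel`.
#' @export
pairwise_matrix <- function(gt, grouping = NULL, statistic = c("theta_WC", "D_Jost"),
                            panel = "all", n_boot = 1000, seed = NULL,
                            boot_unit = c("loci", "individuals"), conf = 0.95,
                            d_combine = "components") {
  statistic <- match.arg(statistic)
  boot_unit <- match.arg(boot_unit)
  if (!is.null(seed)) set.seed(seed)
  grp <- if (is.null(grouping)) gt$groups else {
    if (is.null(names(grouping))) stats::setNames(as.character(grouping), gt$ids)
    else grouping[gt$ids]
  }
  groups <- unique(unname(grp))
  if (length(groups) < 2L) stop("need at least two groups")
  k <- length(groups)
  point <- lo <- hi <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  per_pair <- list()
  fit <- function(sub) {
    if (statistic == "theta_WC") wc_theta(sub, panel = panel)
    else jost_d(sub, panel = panel, d_combine = d_combine)
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sub <- subset_individuals(gt, grp %in% groups[c(i, j)])
    est <- suppressMessages(fit(sub))
    ci <- if (boot_unit == "loci") .boot_loci(est, n_boot, conf) else {
      reps <- numeric(n_boot)
      by_grp <- split(sub$ids, sub$groups[sub$ids])
      for (b in seq_len(n_boot)) {
        take <- unlist(lapply(by_grp, function(v) sample(v, length(v), replace = TRUE)))
        rs <- sub
        ii <- match(take, sub$ids)
        rs$ids <- paste0("b", seq_along(take))
        rs$a1 <- sub$a1[ii, , drop = FALSE]; rs$a2 <- sub$a2[ii, , drop = FALSE]
        rownames(rs$a1) <- rownames(rs$a2) <- rs$ids
        rs$groups <- stats::setNames(unname(sub$groups[take]), rs$ids)
        reps[b] <- tryCatch(suppressMessages(fit(rs))$value, error = function(e) NA_real_)
      }
      stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE, na.rm = TRUE)
    }
    if (ci[1] == ci[2])
      message("pairwise_matrix: degenerate CI for pair ", groups[i], "-", groups[j])
    est$ci_low <- ci[1]; est$ci_high <- ci[2]
    point[i, j] <- point[j, i] <- est$value
    lo[i, j] <- lo[j, i] <- ci[1]
    hi[i, j] <- hi[j, i] <- ci[2]
    per_pair[[paste(groups[i], groups[j], sep = ":")]] <- est
  }
  structure(list(statistic = statistic, panel = panel, groups = groups,
                 point = point, ci_low = lo, ci_high = hi,
                 mean_pairwise = mean(point[upper.tri(point)]),
                 per_pair = per_pair, n_boot = n_boot, boot_unit = boot_unit),
            class = "pairwise_diff")
}

#' @export
print.pairwise_diff <- function(x, ...) {
  cat(sprintf("pairwise %s (%s panel), mean = %.4f\n", x$statistic, x$panel,
              x$mean_pairwise))
  print(round(x$point, 4))
  invisible(x)
}

#' Flatten a pairwise_diff object to a long data.frame
#'
#' @param x a `pairwise_diff` from [pairwise_matrix()].
#' @return data.frame: pair, group1, group2, statistic, panel, point,
#'   ci_low, ci_high.
#' @export
pairwise_long <- function(x) {
  do.call(rbind, lapply(names(x$per_pair), function(nm) {
    e <- x$per_pair[[nm]]
    gg <- strsplit(nm, ":")[[1]]
    data.frame(pair = nm, group1 = gg[1], group2 = gg[2],
               statistic = x$statistic, panel = x$panel,
               point = e$value, ci_low = e$ci_low, ci_high = e$ci_high)
  }))
}
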