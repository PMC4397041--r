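#' Smoothed plug-in baseline allele frequencies
#'
#' Builds strictly positive allele frequency maps for two baseline
#' populations by adding a pseudo-count (default 0.5) per allele of the
#' observed universe (the union of alleles seen in either baseline at a
#' locus) to the allele counts, then renormalising. This is the plug-in
#' simplification of the full Bayesian treatment of allele-frequency
#' uncertainty used by MCMC assignment samplers.
#'
#' @param baselineA,baselineB [genotype_table()]s, each pooled as one
#'   baseline population.
#' @param pseudo pseudo-count added per universe allele.
#' @return list of class `baseline_freqs`: `p` and `q` (named lists, locus
#'   -> named frequency vector over the shared universe), `loci`,
#'   `markers`, and the raw (unsmoothed) frequency lists `rawA`, `rawB`.
#' @export
baseline_frequencies <- function(baselineA, baselineB, pseudo = 0.5) {
  if (!identical(baselineA$markers$name, baselineB$markers$name))
    stop("baselines must share identical loci")
  afA <- allele_frequencies(baselineA, rep("A", n_ind(baselineA)))
  afB <- allele_frequencies(baselineB, rep("B", n_ind(baselineB)))
  loci <- baselineA$markers$name
  p <- q <- stats::setNames(vector("list", length(loci)), loci)
  for (l in seq_along(loci)) {
    fA <- afA$freqs[["A"]][[l]]; fB <- afB$freqs[["B"]][[l]]
    nA <- afA$n_typed["A", l]; nB <- afB$n_typed["B", l]
    universe <- sort(unique(as.integer(c(names(fA), names(fB)))))
    if (!length(universe)) stop("locus ", loci[l], " untyped in both baselines")
    k <- length(universe)
    cntA <- cntB <- stats::setNames(rep(0, k), universe)
    cntA[names(fA)] <- fA * 2 * nA
    cntB[names(fB)] <- fB * 2 * nB
    p[[l]] <- (cntA + pseudo) / (2 * nA + pseudo * k)
    q[[l]] <- (cntB + pseudo) / (2 * nB + pseudo * k)
  }
  structure(list(p = p, q = q, loci = loci, markers = baselineA$markers,
                 rawA = afA$freqs[["A"]], rawB = afB$freqs[["B"]], pseudo = pseudo),
            class = "baseline_freqs")
}

# Per-locus genotype log-probability lookup used by both the class
# classifier and the admixture estimator. Returns NA for missing calls and
# skips alleles absent from the baseline universe (treated as missing).
.locus_probs <- function(i, j, f) {
  ci <- as.character(i); cj <- as.character(j)
  if (!(ci %in% names(f)) || !(cj %in% names(f))) return(NA_real_)
  if (i == j) f[ci]^2 else 2 * f[ci] * f[cj]
}

#' Log-likelihood of a genotype under one hybrid genotype class
#'
#' Per locus, with smoothed baseline frequencies `p` (population A) and `q`
#' (population B) and the class's ancestry-pair frequencies
#' `(phi_AA, phi_AB, phi_BB)`, the probability of observing genotype
#' `{i, j}` is `phi_AA*P_AA + phi_AB*P_AB + phi_BB*P_BB`, where
#' `P_AA = p_i^2` (i = j) or `2*p_i*p_j`, `P_BB` analogously with `q`, and
#' `P_AB = p_i*q_i` (i = j) or `p_i*q_j + p_j*q_i`. The total is the sum of
#' per-locus logs over non-missing loci; loci are assumed unlinked.
#'
#' @param a1,a2 integer allele vectors over loci (NA = missing call).
#' @param baseline a [baseline_frequencies()] object.
#' @param class one of the six labels of [genotype_classes()].
#' @return The log-likelihood (a single number).
#' @export
class_likelihood <- function(a1, a2, baseline, class) {
  phi <- genotype_classes()
  phi <- phi[phi$label == class, ]
  if (!nrow(phi)) stop("unknown class '", class, "'")
  ll <- 0; used <- 0L
  for (l in seq_along(baseline$loci)) {
    i <- a1[l]; j <- a2[l]
    if (is.na(i)) next
    p <- baseline$p[[l]]; q <- baseline$q[[l]]
    ci <- as.character(i); cj <- as.character(j)
    if (!(ci %in% names(p)) || !(cj %in% names(p))) next
    paa <- if (i == j) p[ci]^2 else 2 * p[ci] * p[cj]
    pbb <- if (i == j) q[ci]^2 else 2 * q[ci] * q[cj]
    pab <- if (i == j) p[ci] * q[ci] else p[ci] * q[cj] + p[cj] * q[ci]
    ll <- ll + log(phi$phi_AA * paa + phi$phi_AB * pab + phi$phi_BB * pbb)
    used <- used + 1L
  }
  if (used == 0L) stop("individual has zero usable loci")
  unname(ll)
}

#' Assign individuals to the six genotype classes
#'
#' Computes every individual's log-likelihood under each of the six classes
#' and the posterior under a uniform class prior (numerically stabilised by
#' max-subtraction). Posterior ties are broken by the fixed class order
#' PA, PB, F1, F2, BXA, BXB and reported via a message.
#'
#' @param gt a [genotype_table()] of individuals to classify.
#' @param baseline a [baseline_frequencies()] object on the same loci.
#' @param prior optional non-uniform prior over the six classes (named
#'   numeric, normalised internally).
#' @return A data.frame of class `class_posterior`: `id`, `loglik_<class>`
#'   and `post_<class>` columns, and `assigned`.
#' @export
classify <- function(gt, baseline, prior = NULL) {
  if (!identical(gt$markers$name, baseline$markers$name))
    stop("cohort and baseline loci differ")
  classes <- genotype_classes()$label
  if (is.null(prior)) prior <- stats::setNames(rep(1 / 6, 6), classes)
  prior <- prior[classes] / sum(prior)
  n <- n_ind(gt)
  ll <- matrix(NA_real_, n, 6, dimnames = list(gt$ids, classes))
  for (i in seq_len(n)) for (k in seq_along(classes))
    ll[i, k] <- class_likelihood(gt$a1[i, ], gt$a2[i, ], baseline, classes[k])
  lp <- sweep(ll, 2, log(prior), `+`)
  mx <- apply(lp, 1, max)
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  assigned <- classes[apply(post, 1, which.max)]
  ties <- apply(post, 1, function(z) sum(abs(z - max(z)) < 1e-12) > 1)
  if (any(ties)) message("classify: ", sum(ties),
                         " posterior tie(s) broken by fixed class order")
  out <- data.frame(id = gt$ids, ll, post, assigned, check.names = FALSE)
  names(out) <- c("id", paste0("loglik_", classes), paste0("post_", classes), "assigned")
  class(out) <- c("class_posterior", "data.frame")
  out
}

#' Supervised admixture proportion of one individual
#'
#' Maximises over `q` in `[0, 1]` the likelihood of the individual's
#' genotype under the per-copy mixture frequency
#' `x_a = q*p_a + (1 - q)*q_a` (HWE within the mixture), i.e. the
#' supervised two-population analogue of a clustering q-value. The profile
#' is optimised by golden-section search (tolerance 1e-6) with explicit
#' endpoint checks so pure individuals return exactly 0 or 1.
#'
#' @inheritParams class_likelihood
#' @param threshold purity threshold on q for `pure_flag`.
#' @param tol search tolerance.
#' @return list of class `admixture_estimate`: `q` (ancestry proportion
#'   from baseline A), `loglik`, `pure_flag`
#'   (`q >= threshold || q <= 1 - threshold`).
#' @export
admixture_q <- function(a1, a2, baseline, threshold = 0.9, tol = 1e-6) {
  loci <- seq_along(baseline$loci)
  ok <- logical(length(loci))
  for (l in loci) {
    if (is.na(a1[l])) next
    p <- baseline$p[[l]]
    ok[l] <- all(c(as.character(a1[l]), as.character(a2[l])) %in% names(p))
  }
  if (!any(ok)) stop("zero informative loci: q undefined")
  f <- function(qv) {
    ll <- 0
    for (l in loci[ok]) {
      x <- qv * baseline$p[[l]] + (1 - qv) * baseline$q[[l]]
      i <- as.character(a1[l]); j <- as.character(a2[l])
      ll <- ll + if (i == j) 2 * log(x[i]) else log(2 * x[i] * x[j])
    }
    unname(ll)
  }
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- 1
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    if (fc > fd) { b <- d1; d1 <- c1; fd <- fc; c1 <- b - gr * (b - a); fc <- f(c1) }
    else { a <- c1; c1 <- d1; fc <- fd; d1 <- a + gr * (b - a); fd <- f(d1) }
  }
  cand <- c(0, (a + b) / 2, 1)
  vals <- c(f(0), f((a + b) / 2), f(1))
  q <- cand[which.max(vals)]
  structure(list(q = q, loglik = max(vals),
                 pure_flag = q >= threshold || q <= 1 - threshold),
            class = "admixture_estimate")
}

#' Purity-filter two candidate baselines
#'
#' Each individual is pre-labelled to a candidate baseline by its group;
#' its supervised admixture proportion `q` (toward baseline A) is computed
#' against the smoothed frequencies of the labelled groups, and only
#' individuals with `q >= threshold` toward their own baseline are kept
#' (`q >= threshold` for A-labelled, `1 - q >= threshold` for B-labelled).
#' Baseline frequencies are then recomputed from the kept individuals.
#'
#' @param gt a [genotype_table()] containing both candidate baselines.
#' @param label_a,label_b the group labels of the two candidate baselines.
#' @param threshold purity threshold (default 0.9; 0 keeps everyone).
#' @param pseudo pseudo-count for [baseline_frequencies()].
#' @return list of class `purity_filter`: `baselineA`, `baselineB`
#'   (purified `genotype_table`s), `freqs` (recomputed
#'   [baseline_frequencies()]), `q` (named vector over all candidates),
#'   `excluded` (ids).
#' @export
purity_filter <- function(gt, label_a, label_b, threshold = 0.9, pseudo = 0.5) {
  ia <- gt$groups == label_a; ib <- gt$groups == label_b
  if (!any(ia) || !any(ib)) stop("labels not found in table")
  gtA <- subset_individuals(gt, ia); gtB <- subset_individuals(gt, ib)
  bf <- baseline_frequencies(gtA, gtB, pseudo)
  qv <- stats::setNames(numeric(sum(ia) + sum(ib)), c(gtA$ids, gtB$ids))
  for (id in names(qv)) {
    i <- match(id, gt$ids)
    qv[id] <- admixture_q(gt$a1[i, ], gt$a2[i, ], bf, threshold = threshold)$q
  }
  keepA <- gtA$ids[qv[gtA$ids] >= threshold]
  keepB <- gtB$ids[1 - qv[gtB$ids] >= threshold]
  if (threshold == 0) { keepA <- gtA$ids; keepB <- gtB$ids }
  if (length(keepA) < 2L || length(keepB) < 2L)
    stop("purity filter left a baseline with < 2 individuals; relax the threshold")
  pureA <- subset_individuals(gtA, keepA)
  pureB <- subset_individuals(gtB, keepB)
  structure(list(baselineA = pureA, baselineB = pureB,
                 freqs = baseline_frequencies(pureA, pureB, pseudo),
                 q = qv, threshold = threshold,
                 excluded = setdiff(names(qv), c(keepA, keepB))),
            class = "purity_filter")
}

#' Hybrid-detection power analysis
#'
#' Full pipeline estimating how reliably the genotype-class classifier
#' recovers simulated hybrids between two baselines: purify the baselines
#' with the q >= `threshold` rule, recompute their allele frequencies,
#' simulate the crosses of `spec` (plus the purified parental individuals
#' relabelled PA/PB), classify every individual, and summarise per-class
#' correct-assignment proportions averaged across repeats, the summed
#' confusion matrix, and the coarse parent-vs-hybrid dichotomy accuracy.
#' Baseline divergence is reported as the multi-locus Weir-Cockerham theta
#' between the purified baselines.
#'
#' @param baselineA,baselineB candidate baseline [genotype_table()]s
#'   sharing loci.
#' @param spec a [cross_spec()].
#' @param panel marker panel to use (`"all"`, `"neutral"`, `"qtl"`).
#' @param threshold purity threshold.
#' @param pseudo classifier pseudo-count.
#' @param include_parents append the purified parental individuals to every
#'   simulated cohort (as the study design does).
#' @return list of class `power_report`: `per_class` (mean accuracy per
#'   class), `per_rep` (repeat x class matrix), `confusion` (true x
#'   assigned counts summed over repeats), `dichotomy_accuracy`,
#'   `baseline_theta`, `panel`, `spec`, `n_kept` per baseline.
#' @export
power_analysis <- function(baselineA, baselineB, spec, panel = "all",
                           threshold = 0.9, pseudo = 0.5, include_parents = TRUE) {
  baselineA <- subset_panel(baselineA, panel)
  baselineB <- subset_panel(baselineB, panel)
  bA <- baselineA; bA$groups[] <- "A"
  bB <- baselineB; bB$groups[] <- "B"
  pooled <- bind_genotypes(bA, bB)
  pf <- purity_filter(pooled, "A", "B", threshold = threshold, pseudo = pseudo)
  bf <- pf$freqs
  theta <- suppressMessages(
    wc_theta(bind_genotypes(pf$baselineA, pf$baselineB),
             grouping = c(stats::setNames(rep("A", n_ind(pf$baselineA)), pf$baselineA$ids),
                          stats::setNames(rep("B", n_ind(pf$baselineB)), pf$baselineB$ids))))$value
  cohorts <- simulate_cross(spec, bf$rawA, bf$rawB,
                            parentA = if (include_parents) pf$baselineA,
                            parentB = if (include_parents) pf$baselineB,
                            markers = baselineA$markers)
  classes <- genotype_classes()$label
  per_rep <- matrix(NA_real_, spec$n_reps, 6,
                    dimnames = list(paste0("rep", seq_len(spec$n_reps)), classes))
  confusion <- matrix(0L, 6, 6, dimnames = list(true = classes, assigned = classes))
  dich <- numeric(spec$n_reps)
  parent_cl <- c("PA", "PB")
  for (r in seq_along(cohorts)) {
    cp <- classify(cohorts[[r]], bf)
    truth <- unname(cohorts[[r]]$groups)
    for (cl in unique(truth)) {
      s <- truth == cl
      per_rep[r, cl] <- mean(cp$assigned[s] == cl)
    }
    confusion <- confusion + table(factor(truth, classes),
                                   factor(cp$assigned, classes))
    dich[r] <- mean((truth %in% parent_cl) == (cp$assigned %in% parent_cl))
  }
  structure(list(per_class = colMeans(per_rep, na.rm = TRUE),
                 per_rep = per_rep, confusion = confusion,
                 dichotomy_accuracy = mean(dich), baseline_theta = theta,
                 panel = panel, spec = spec,
                 n_kept = c(A = n_ind(pf$baselineA), B = n_ind(pf$baselineB))),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("hybrid-detection power (%s panel, baseline theta = %.3f)\n",
              x$panel, x$baseline_theta))
  cat("mean correct-assignment proportion per class:\n")
  print(round(x$per_class, 3))
  cat(sprintf("parent-vs-hybrid dichotomy accuracy: %.3f\n", x$dichotomy_accuracy))
  invisible(x)
}
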