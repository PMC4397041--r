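#' ANCOVA-style size correction of linear traits
#'
#' Removes allometric size dependence by fitting, per trait, a single
#' pooled-within-group slope `b` of the trait on the size covariate (the
#' ANCOVA common slope, estimated from within-group covariances only so
#' that group mean differences do not inflate it) and adjusting every value
#' to the grand mean size: `adjusted = observed - b*(size - mean(size))`.
#'
#' @param traits data.frame (or matrix) of trait columns, one row per
#'   individual; NA allowed.
#' @param size positive numeric size covariate (e.g. centroid size), one
#'   per individual.
#' @param grouping group label per individual.
#' @return list of class `size_correction`: `adjusted` (data.frame, same
#'   shape as `traits`), `model` (data.frame: trait, slope, r2 of the
#'   covariate within groups), `grand_mean_size`.
#' @export
size_correct <- function(traits, size, grouping) {
  traits <- as.data.frame(traits)
  grouping <- as.character(grouping)
  if (any(size <= 0, na.rm = TRUE)) stop("size covariate must be positive")
  sizes <- table(grouping[!is.na(size)])
  if (sum(sizes >= 3) < 2) stop("need >= 2 groups with >= 3 individuals")
  grand <- mean(size, na.rm = TRUE)
  adj <- traits
  model <- data.frame(trait = names(traits), slope = NA_real_, r2 = NA_real_)
  for (k in seq_along(traits)) {
    y <- traits[[k]]
    ok <- !is.na(y) & !is.na(size) & !is.na(grouping)
    xs <- size[ok]; ys <- y[ok]; gs <- grouping[ok]
    xc <- xs - stats::ave(xs, gs)   # within-group centred covariate
    yc <- ys - stats::ave(ys, gs)
    sxx <- sum(xc^2)
    if (sxx == 0) stop("zero within-group size variance for trait '", names(traits)[k], "'")
    b <- sum(xc * yc) / sxx
    model$slope[k] <- b
    syy <- sum(yc^2)
    model$r2[k] <- if (syy > 0) sum(xc * yc)^2 / (sxx * syy) else 0
    adj[[k]] <- y - b * (size - grand)
  }
  structure(list(adjusted = adj, model = model, grand_mean_size = grand),
            class = "size_correction")
}

#' Classify lateral-plate morphs from mean plate number
#'
#' Morph classes from the mean of the left and right lateral plate counts:
#' low (0-9), partial (above 9 and below 29) and complete (29 and up). The
#' printed class ranges overlap at their boundaries; this implementation
#' resolves exactly 9 plates to `low` and 29 or more to `complete`, which
#' preserves the canonical exemplars (partials around 10.5, completes at
#' 29-32).
#'
#' @param mean_plates numeric vector of mean plate counts (>= 0).
#' @return factor with levels `low`, `partial`, `complete` (NA propagated).
#' @export
classify_plate_morph <- function(mean_plates) {
  if (any(mean_plates < 0, na.rm = TRUE)) stop("mean_plates must be >= 0")
  out <- ifelse(is.na(mean_plates), NA_character_,
                ifelse(mean_plates <= 9, "low",
                       ifelse(mean_plates < 29, "partial", "complete")))
  factor(out, levels = c("low", "partial", "complete"))
}

#' PCA summary of the three defensive-spine traits
#'
#' Principal components of the covariance matrix (by default; set
#' `use_correlation = TRUE` to standardise first) of the first dorsal,
#' second dorsal and pelvic spine lengths, computed on complete cases. The
#' first axis (`PC_AP`) summarises overall spine investment; its sign is
#' fixed so the spine loadings are non-negative whenever the axis allows it
#' (the axis is flipped when the loading sum is negative).
#'
#' @param spines data.frame/matrix with columns `DS1`, `DS2`, `PS`
#'   (size-corrected upstream).
#' @param use_correlation PCA on the correlation rather than covariance
#'   matrix.
#' @return list of class `spine_pca`: `loadings` (3 x 3, unit-norm
#'   columns), `var_explained` (fractions summing to 1), `scores`
#'   (per-individual PC_AP = axis-1 scores, NA for incomplete rows),
#'   `n_used`.
#' @export
spine_pca <- function(spines, use_correlation = FALSE) {
  spines <- as.data.frame(spines)[c("DS1", "DS2", "PS")]
  cc <- stats::complete.cases(spines)
  if (sum(cc) < 3) stop("need >= 3 complete cases")
  x <- as.matrix(spines[cc, ])
  if (all(apply(x, 2, stats::sd) == 0)) stop("all traits constant: PCA undefined")
  pc <- stats::prcomp(x, center = TRUE, scale. = use_correlation)
  if (sum(pc$rotation[, 1]) < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
  }
  scores <- rep(NA_real_, nrow(spines))
  scores[cc] <- pc$x[, 1]
  structure(list(loadings = pc$rotation,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 scores = scores, n_used = sum(cc)),
            class = "spine_pca")
}

#' One-way ANOVA association between a trait and genotype classes
#'
#' Fixed-effects one-way ANOVA of the trait on the class labels, reporting
#' the F statistic, `R^2 = SS_between/SS_total`, the p-value, degrees of
#' freedom and per-class trait means; optional Tukey HSD post-hoc pairwise
#' comparisons.
#'
#' @param values numeric trait values (NA dropped).
#' @param labels class labels (e.g. genotypes at a locus), one per value.
#' @param posthoc also run Tukey HSD pairwise comparisons.
#' @return list of class `association_result`: `F`, `R2`, `p`, `df`
#'   (c(between, within)), `group_means`, `n`, and `tukey` when requested.
#' @export
trait_anova <- function(values, labels, posthoc = FALSE) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]; labels <- factor(as.character(labels[ok]))
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  fit <- stats::aov(values ~ labels)
  an <- stats::anova(fit)
  ssb <- an$`Sum Sq`[1]; ssw <- an$`Sum Sq`[2]
  out <- list(F = an$`F value`[1], R2 = ssb / (ssb + ssw), p = an$`Pr(>F)`[1],
              df = c(between = an$Df[1], within = an$Df[2]),
              group_means = tapply(values, labels, mean), n = length(values))
  if (posthoc) out$tukey <- stats::TukeyHSD(fit)
  structure(out, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: R2 = %.2f, F(%d, %d) = %.2f, P = %.3g\n",
              x$R2, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' HWE-expected frequency of a phenotype class at a diallelic locus
#'
#' Given the frequency `p` of the "complete" allele C at a diallelic major
#' locus and a penetrance map giving the probability that each genotype
#' (`CC`, `CL`, `LL`) expresses the phenotype, returns the Hardy-Weinberg
#' expected phenotype frequency `p^2*pen_CC + 2p(1-p)*pen_CL +
#' (1-p)^2*pen_LL`. When `p` is not supplied it is inferred from an
#' observed phenotype fraction under a stated deterministic dominance
#' model: `"recessive"` (phenotype iff CC, `p = sqrt(f)`) or `"dominant"`
#' (phenotype iff CC or CL, `p = 1 - sqrt(1 - f)`).
#'
#' @param p frequency of the C allele in `[0, 1]`.
#' @param penetrance named numeric `c(CC=, CL=, LL=)`, each in `[0, 1]`.
#' @param observed_fraction observed phenotype frequency, used with `model`
#'   when `p` is missing.
#' @param model dominance model for the inference, `"recessive"` or
#'   `"dominant"`.
#' @return Expected phenotype fraction.
#' @export
expected_complete_fraction <- function(p = NULL,
                                       penetrance = c(CC = 1, CL = 0, LL = 0),
                                       observed_fraction = NULL,
                                       model = c("recessive", "dominant")) {
  if (!all(c("CC", "CL", "LL") %in% names(penetrance)) ||
      any(penetrance < 0 | penetrance > 1))
    stop("inconsistent penetrance map: needs CC, CL, LL each in [0, 1]")
  if (is.null(p)) {
    if (is.null(observed_fraction)) stop("supply either p or observed_fraction")
    model <- match.arg(model)
    p <- if (model == "recessive") sqrt(observed_fraction)
         else 1 - sqrt(1 - observed_fraction)
  }
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  unname(p^2 * penetrance["CC"] + 2 * p * (1 - p) * penetrance["CL"] +
           (1 - p)^2 * penetrance["LL"])
}
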