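#' Balding-Nichols subpopulation allele frequencies
#'
#' Draws each population's allele frequency vector independently from a
#' Dirichlet distribution with parameters `ancestral * (1 - F)/F`, the
#' F-model under which the expected among-population differentiation is
#' approximately `F`. `F = 0` is handled as an exact copy of the ancestral
#' frequencies.
#'
#' @param ancestral named numeric vector of ancestral allele frequencies
#'   (must sum to 1).
#' @param F differentiation parameter in `[0, 1)`.
#' @param n_pops number of populations.
#' @return list of `n_pops` named frequency vectors (uses the current RNG
#'   state).
#' @export
balding_nichols_freqs <- function(ancestral, F, n_pops) {
  if (abs(sum(ancestral) - 1) > 1e-9) stop("ancestral frequencies must sum to 1")
  if (F < 0 || F >= 1) stop("F must be in [0, 1)")
  if (F == 0) return(replicate(n_pops, ancestral, simplify = FALSE))
  shape <- ancestral * (1 - F) / F
  lapply(seq_len(n_pops), function(i) {
    x <- stats::rgamma(length(shape), shape = shape)
    if (sum(x) == 0) x[which.max(shape)] <- 1  # degenerate draw guard
    stats::setNames(x / sum(x), names(ancestral))
  })
}

#' Simulate diploid genotypes from per-population allele frequencies
#'
#' Two independent allele draws per individual per locus (Hardy-Weinberg
#' proportions within populations), with optional uniform missingness.
#'
#' @param pop_freqs named list: population -> (named list: locus -> named
#'   allele frequency vector).
#' @param n_per_pop individuals per population (scalar or one per
#'   population).
#' @param markers optional marker data.frame (`name`, `panel`); defaults to
#'   all-neutral markers named after the first population's loci.
#' @param missing_rate probability that a call is set missing.
#' @return A [genotype_table()] grouped by population.
#' @export
simulate_genotypes <- function(pop_freqs, n_per_pop, markers = NULL,
                               missing_rate = 0) {
  pops <- names(pop_freqs)
  loci <- names(pop_freqs[[1]])
  if (length(n_per_pop) == 1L) n_per_pop <- rep(n_per_pop, length(pops))
  ntot <- sum(n_per_pop)
  a1 <- a2 <- matrix(NA_integer_, ntot, length(loci))
  ids <- character(ntot); grp <- character(ntot)
  row <- 0L
  for (k in seq_along(pops)) {
    n <- n_per_pop[k]
    rows <- row + seq_len(n)
    ids[rows] <- sprintf("%s_%03d", pops[k], seq_len(n))
    grp[rows] <- pops[k]
    for (l in seq_along(loci)) {
      f <- pop_freqs[[k]][[loci[l]]]
      a1[rows, l] <- sample_gamete(f, n)
      a2[rows, l] <- sample_gamete(f, n)
    }
    row <- row + n
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(ntot * length(loci)) < missing_rate,
                   ntot, length(loci))
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  if (is.null(markers)) markers <- data.frame(name = loci, panel = "neutral")
  genotype_table(ids, markers, a1, a2, grp)
}

#' Configuration of the three-ecotype synthetic scenario
#'
#' Defaults describe a contact zone with two freshwater-resident
#' populations and one anadromous population: 9 neutral microsatellite loci
#' (6 alleles each) at Balding-Nichols `F = 0.12`, 4 QTL-linked loci (2-4
#' alleles, `F = 0.3`, QTL markers being less variable than neutral ones)
#' plus a diallelic major-effect plate locus (allele codes 240 = C,
#' 172 = L) fixed for C in the anadromous population and for L in both
#' residents. Mean lateral plate number follows the major-locus genotype
#' (CC 31 +- 1, i.e. complete; LL 5 +- 2 in resident1, a 50:50 mixture of
#' 7 +- 2 and 13 +- 3 in resident2, emulating coexisting low and partial
#' residents; CL 20 +- 3 if heterozygotes arise) with an optional polygenic
#' modifier SD added on top. Linear traits get population means/SDs
#' (anadromous standard length 59 +- 2 mm versus resident 39 +- 5 mm,
#' spines sharing a strong common factor, gill-raker length longest in the
#' anadromous fish) and an allometric slope on size.
#'
#' @param n_per_pop individuals per population.
#' @param n_neutral_loci,n_qtl_loci marker counts (QTL count excludes the
#'   major locus).
#' @param alleles_neutral,alleles_qtl alleles per locus (qtl recycled over
#'   loci).
#' @param F_neutral,F_qtl Balding-Nichols F per panel.
#' @param major_freqs frequency of the C allele per population.
#' @param plate_model list of per-genotype `mean`/`sd` and `mixture` for
#'   the LL class of resident2, plus `modifier_sd`.
#' @param trait_model list: per-trait named vectors `mean` (per population)
#'   and `sd`, `allometry` slope per trait, `spine_cor` common-factor
#'   correlation between spines.
#' @param missing_rate genotype missingness.
#' @param seed integer seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_per_pop = 50, n_neutral_loci = 9, n_qtl_loci = 4,
                            alleles_neutral = 6, alleles_qtl = c(2, 3, 4, 2),
                            F_neutral = 0.12, F_qtl = 0.3,
                            major_freqs = c(resident1 = 0, resident2 = 0, anadromous = 1),
                            plate_model = list(
                              CC = list(mean = 31, sd = 1),
                              CL = list(mean = 20, sd = 3),
                              LL_resident1 = list(mean = 5, sd = 2),
                              LL_resident2 = list(weights = c(0.5, 0.5),
                                                  means = c(7, 13), sds = c(2, 3)),
                              modifier_sd = 0),
                            trait_model = list(
                              SL  = list(mean = c(resident1 = 39, resident2 = 39, anadromous = 59),
                                         sd = 5, allometry = NA),
                              BD  = list(mean = c(resident1 = 8, resident2 = 9, anadromous = 13),
                                         sd = 0.8, allometry = 0.15),
                              DS1 = list(mean = c(resident1 = 3.2, resident2 = 3.6, anadromous = 6.0),
                                         sd = 0.35, allometry = 0.06),
                              DS2 = list(mean = c(resident1 = 3.6, resident2 = 4.0, anadromous = 6.6),
                                         sd = 0.35, allometry = 0.06),
                              PS  = list(mean = c(resident1 = 4.4, resident2 = 4.9, anadromous = 7.8),
                                         sd = 0.4, allometry = 0.07),
                              GRL = list(mean = c(resident1 = 0.86, resident2 = 0.95, anadromous = 1.26),
                                         sd = 0.15, allometry = 0.005),
                              GRN = list(mean = c(resident1 = 18, resident2 = 19, anadromous = 21),
                                         sd = 1.5, allometry = 0),
                              spine_cor = 0.95),
                            missing_rate = 0, seed = 1) {
  if (!is.null(plate_model$LL_resident2$weights) &&
      abs(sum(plate_model$LL_resident2$weights) - 1) > 1e-9)
    stop("invalid mixture weights: must sum to 1")
  stopifnot(F_neutral > 0, F_neutral < 1, F_qtl > 0, F_qtl < 1,
            all(major_freqs >= 0 & major_freqs <= 1))
  structure(as.list(environment()), class = "scenario_config")
}

# SDs recycled per locus
.qtl_allele_counts <- function(cfg) {
  rep_len(cfg$alleles_qtl, cfg$n_qtl_loci)
}

#' Simulate the full three-ecotype dataset
#'
#' Generates genotypes (neutral + QTL panels via Balding-Nichols draws, the
#' diallelic major plate locus per `major_freqs`) and phenotypes (plates
#' from the major-locus genotype model, linear traits per population with
#' allometric size dependence and strongly correlated spines) for the
#' scenario in [scenario_config()].
#'
#' @param config a [scenario_config()].
#' @return list of class `simulated_dataset`: `genotypes`
#'   ([genotype_table()]), `phenotypes` (data.frame), `groups` (named
#'   vector), `config` (the input, echoed).
#' @export
simulate_three_ecotype_scenario <- function(config = scenario_config()) {
  cfg <- config
  set.seed(cfg$seed)
  pops <- names(cfg$major_freqs)
  loci_neutral <- sprintf("NEU%02d", seq_len(cfg$n_neutral_loci))
  loci_qtl <- sprintf("QTL%02d", seq_len(cfg$n_qtl_loci))
  qtl_k <- .qtl_allele_counts(cfg)

  pop_freqs <- stats::setNames(lapply(pops, function(p) list()), pops)
  for (l in seq_along(loci_neutral)) {
    anc <- rep(1 / cfg$alleles_neutral, cfg$alleles_neutral)
    names(anc) <- 100 + seq_len(cfg$alleles_neutral)
    bn <- balding_nichols_freqs(anc, cfg$F_neutral, length(pops))
    for (k in seq_along(pops)) pop_freqs[[k]][[loci_neutral[l]]] <- bn[[k]]
  }
  for (l in seq_along(loci_qtl)) {
    anc <- rep(1 / qtl_k[l], qtl_k[l])
    names(anc) <- 200 + seq_len(qtl_k[l])
    bn <- balding_nichols_freqs(anc, cfg$F_qtl, length(pops))
    for (k in seq_along(pops)) pop_freqs[[k]][[loci_qtl[l]]] <- bn[[k]]
  }
  for (k in seq_along(pops)) {
    pC <- cfg$major_freqs[[pops[k]]]
    f <- c(`240` = pC, `172` = 1 - pC)
    pop_freqs[[k]][["EDA"]] <- f[f > 0]
  }
  markers <- data.frame(name = c(loci_neutral, loci_qtl, "EDA"),
                        panel = c(rep("neutral", cfg$n_neutral_loci),
                                  rep("qtl", cfg$n_qtl_loci + 1L)))
  gt <- simulate_genotypes(pop_freqs, cfg$n_per_pop, markers = markers,
                           missing_rate = cfg$missing_rate)

  n <- n_ind(gt)
  pop <- unname(gt$groups)
  eda1 <- gt$a1[, "EDA"]; eda2 <- gt$a2[, "EDA"]
  geno <- ifelse(eda1 == 240 & eda2 == 240, "CC",
                 ifelse(eda1 == 172 & eda2 == 172, "LL", "CL"))
  geno[is.na(eda1)] <- sample(c("CC", "LL"), sum(is.na(eda1)), replace = TRUE)

  pm <- cfg$plate_model
  plates <- numeric(n)
  for (i in seq_len(n)) {
    plates[i] <- if (geno[i] == "CC") stats::rnorm(1, pm$CC$mean, pm$CC$sd)
    else if (geno[i] == "CL") stats::rnorm(1, pm$CL$mean, pm$CL$sd)
    else if (pop[i] == "resident2") {
      comp <- sample(seq_along(pm$LL_resident2$weights), 1,
                     prob = pm$LL_resident2$weights)
      stats::rnorm(1, pm$LL_resident2$means[comp], pm$LL_resident2$sds[comp])
    } else stats::rnorm(1, pm$LL_resident1$mean, pm$LL_resident1$sd)
  }
  if (pm$modifier_sd > 0) plates <- plates + stats::rnorm(n, 0, pm$modifier_sd)
  plates <- pmin(pmax(plates, 0), 32)
  plates_left <- pmin(pmax(round(plates + stats::rnorm(n, 0, 0.5)), 0), 32)
  plates_right <- pmin(pmax(round(plates + stats::rnorm(n, 0, 0.5)), 0), 32)

  tm <- cfg$trait_model
  SL <- tm$SL$mean[pop] + stats::rnorm(n, 0, tm$SL$sd)
  size_dev <- SL - tm$SL$mean[pop]
  z_common <- stats::rnorm(n)
  rho <- tm$spine_cor
  lin <- function(spec, shared = NULL) {
    noise <- if (is.null(shared)) stats::rnorm(n) else
      rho * shared + sqrt(1 - rho^2) * stats::rnorm(n)
    spec$mean[pop] + spec$allometry * size_dev + spec$sd * noise
  }
  pheno <- data.frame(
    id = gt$ids,
    SL = SL,
    BD = lin(tm$BD),
    DS1 = lin(tm$DS1, z_common),
    DS2 = lin(tm$DS2, z_common),
    PS = lin(tm$PS, z_common),
    plates_left = plates_left,
    plates_right = plates_right,
    mean_plates = (plates_left + plates_right) / 2,
    GRN = round(lin(tm$GRN)),
    GRL = lin(tm$GRL),
    centroid_size = 2.2 * SL + stats::rnorm(n, 0, 1),
    row.names = NULL)

  structure(list(genotypes = gt, phenotypes = pheno, groups = gt$groups,
                 config = cfg),
            class = "simulated_dataset")
}

#' Two synthetic baselines for the hybrid-detection power analysis
#'
#' Generates two populations at a configurable divergence (Balding-Nichols
#' `F`, with expected multi-locus theta near `F`) over `n_loci` equally
#' polymorphic microsatellite loci, ready for [simulate_cross()] /
#' [power_analysis()]. The default 14 loci match the full marker panel
#' size.
#'
#' @param f Balding-Nichols differentiation parameter.
#' @param n_loci number of loci.
#' @param n_per_pop individuals per baseline.
#' @param alleles_per_locus alleles per locus.
#' @param seed integer seed.
#' @return list: `A` and `B`, each a [genotype_table()] (groups `"A"` /
#'   `"B"`).
#' @export
make_power_baselines <- function(f = 0.5, n_loci = 14, n_per_pop = 50,
                                 alleles_per_locus = 6, seed = 1) {
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(n_loci))
  pop_freqs <- list(A = list(), B = list())
  for (l in seq_len(n_loci)) {
    anc <- rep(1 / alleles_per_locus, alleles_per_locus)
    names(anc) <- 100 + seq_len(alleles_per_locus)
    bn <- balding_nichols_freqs(anc, f, 2)
    pop_freqs$A[[loci[l]]] <- bn[[1]]
    pop_freqs$B[[loci[l]]] <- bn[[2]]
  }
  gt <- simulate_genotypes(pop_freqs, n_per_pop)
  list(A = subset_individuals(gt, gt$groups == "A"),
       B = subset_individuals(gt, gt$groups == "B"))
}
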