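#' The six genotype classes of a two-generation hybrid model
#'
#' After two generations of admixture between parental populations A and B
#' an individual belongs to one of six categories: parent A (`PA`), parent
#' B (`PB`), first-generation hybrid (`F1`), second-generation hybrid
#' (`F2`), backcross to A (`BXA`) and backcross to B (`BXB`). Each class is
#' characterised by the expected frequencies of the three per-locus
#' ancestry pairs (both gene copies of A origin, one of each, both of B
#' origin).
#'
#' @return data.frame with columns `label`, `phi_AA`, `phi_AB`, `phi_BB`.
#' @export
genotype_classes <- function() {
  data.frame(label = c("PA", "PB", "F1", "F2", "BXA", "BXB"),
             phi_AA = c(1, 0, 0, 0.25, 0.5, 0),
             phi_AB = c(0, 0, 1, 0.50, 0.5, 0.5),
             phi_BB = c(0, 1, 0, 0.25, 0,   0.5))
}

#' Draw gametes from an allele frequency map
#'
#' @param freqs named numeric vector mapping allele code to relative
#'   frequency (must sum to 1 within 1e-6).
#' @param n number of gametes to draw.
#' @return Integer vector of allele codes (uses the current RNG state).
#' @export
sample_gamete <- function(freqs, n = 1) {
  if (!length(freqs)) stop("empty allele frequency map")
  if (abs(sum(freqs) - 1) > 1e-6) stop("allele frequencies do not sum to 1")
  al <- as.integer(names(freqs))
  if (length(al) == 1L) return(rep(al, n))
  sample(al, n, replace = TRUE, prob = freqs)
}

# Draw a cohort of F1 individuals as allele-pair matrices (one gamete from
# each baseline per locus); used both directly and as parents of F2/BX.
.draw_f1 <- function(freqsA, freqsB, n, loci) {
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (l in seq_along(loci)) {
    a1[, l] <- sample_gamete(freqsA[[loci[l]]], n)
    a2[, l] <- sample_gamete(freqsB[[loci[l]]], n)
  }
  list(a1 = a1, a2 = a2)
}

# One transmitted allele per locus from each parent, chosen uniformly and
# independently across loci (free recombination between unlinked markers).
.transmit <- function(parent) {
  n <- nrow(parent$a1); L <- ncol(parent$a1)
  pick <- matrix(stats::runif(n * L) < 0.5, n, L)
  ifelse(pick, parent$a1, parent$a2)
}

#' Simulate one genotype-class cohort by explicit Mendelian mating
#'
#' Parental classes draw both gene copies from their baseline frequencies
#' (HWE within the baseline). `F1` takes one gamete from each baseline.
#' `F2` individuals are formed by mating two independently simulated F1
#' parents, each transmitting one of its two alleles chosen uniformly at
#' every locus independently; backcrosses mate one simulated F1 parent with
#' a parental-baseline gamete. Loci are unlinked.
#'
#' @param class one of `"PA"`, `"PB"`, `"F1"`, `"F2"`, `"BXA"`, `"BXB"`.
#' @param freqsA,freqsB named lists mapping locus name to an allele
#'   frequency map (as in `allele_frequencies(gt)$freqs[[group]]`); both
#'   must cover the same loci with non-empty maps.
#' @param n cohort size.
#' @param markers optional marker data.frame (`name`, `panel`) to carry
#'   panel tags; defaults to all-neutral markers named after `freqsA`.
#' @param id_prefix prefix for generated individual IDs.
#' @return A [genotype_table()] whose group label is the true class.
#' @export
simulate_class <- function(class, freqsA, freqsB, n,
                           markers = NULL, id_prefix = class) {
  stopifnot(class %in% genotype_classes()$label)
  loci <- names(freqsA)
  if (!identical(sort(loci), sort(names(freqsB))))
    stop("freqsA and freqsB must be defined on the same loci")
  empty <- !vapply(freqsA[loci], length, integer(1)) |
           !vapply(freqsB[loci], length, integer(1))
  if (any(empty)) stop("empty frequency map at locus: ",
                       paste(loci[empty], collapse = ", "))
  draw_parental <- function(freqs) {
    a1 <- a2 <- matrix(NA_integer_, n, length(loci))
    for (l in seq_along(loci)) {
      a1[, l] <- sample_gamete(freqs[[loci[l]]], n)
      a2[, l] <- sample_gamete(freqs[[loci[l]]], n)
    }
    list(a1 = a1, a2 = a2)
  }
  g <- switch(class,
    PA = draw_parental(freqsA),
    PB = draw_parental(freqsB),
    F1 = .draw_f1(freqsA, freqsB, n, loci),
    F2 = {
      p1 <- .draw_f1(freqsA, freqsB, n, loci)
      p2 <- .draw_f1(freqsA, freqsB, n, loci)
      list(a1 = .transmit(p1), a2 = .transmit(p2))
    },
    BXA = {
      p1 <- .draw_f1(freqsA, freqsB, n, loci)
      a2 <- matrix(NA_integer_, n, length(loci))
      for (l in seq_along(loci)) a2[, l] <- sample_gamete(freqsA[[loci[l]]], n)
      list(a1 = .transmit(p1), a2 = a2)
    },
    BXB = {
      p1 <- .draw_f1(freqsA, freqsB, n, loci)
      a2 <- matrix(NA_integer_, n, length(loci))
      for (l in seq_along(loci)) a2[, l] <- sample_gamete(freqsB[[loci[l]]], n)
      list(a1 = .transmit(p1), a2 = a2)
    })
  if (is.null(markers)) markers <- data.frame(name = loci, panel = "neutral")
  genotype_table(sprintf("%s_%03d", id_prefix, seq_len(n)), markers,
                 g$a1, g$a2, rep(class, n))
}

#' Specification of a simulated-cross design
#'
#' @param n_per_class individuals simulated per genotype class (default 30).
#' @param classes genotype classes to simulate (default the four hybrid
#'   classes `F1`, `F2`, `BXA`, `BXB`).
#' @param n_reps number of independent repeats of the whole cross
#'   (default 5).
#' @param seed master seed; per-repeat sub-seeds are derived from it
#'   deterministically.
#' @return list of class `cross_spec`.
#' @export
cross_spec <- function(n_per_class = 30, classes = c("F1", "F2", "BXA", "BXB"),
                       n_reps = 5, seed = 1) {
  stopifnot(n_per_class > 0, n_reps > 0,
            all(classes %in% genotype_classes()$label))
  structure(list(n_per_class = n_per_class, classes = classes,
                 n_reps = n_reps, seed = seed), class = "cross_spec")
}

#' Simulate a repeated cross between two baselines
#'
#' Runs [simulate_class()] for every class in the spec, `n_reps` times,
#' each repeat under its own sub-seed drawn deterministically from the
#' master seed. When parental tables are supplied their individuals are
#' concatenated to each repeat's cohort (group labels `PA` / `PB`).
#'
#' @param spec a [cross_spec()].
#' @param freqsA,freqsB baseline allele frequency lists (see
#'   [simulate_class()]).
#' @param parentA,parentB optional [genotype_table()]s of baseline
#'   individuals to append to every repeat, relabelled `PA` / `PB`.
#' @param markers optional marker data.frame carried into the cohorts.
#' @return list of `genotype_table`s, one per repeat; each has attributes
#'   `rep_seed` and `true_class` (named vector, identical to its groups).
#' @export
simulate_cross <- function(spec, freqsA, freqsB, parentA = NULL, parentB = NULL,
                           markers = NULL) {
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, spec$n_reps)
  out <- vector("list", spec$n_reps)
  for (r in seq_len(spec$n_reps)) {
    set.seed(rep_seeds[r])
    cohorts <- lapply(spec$classes, function(cl)
      simulate_class(cl, freqsA, freqsB, spec$n_per_class, markers = markers,
                     id_prefix = sprintf("rep%d_%s", r, cl)))
    relabel <- function(gt, lab, pref) {
      gt$groups[] <- lab
      genotype_table(paste0(pref, gt$ids), gt$markers, gt$a1, gt$a2,
                     stats::setNames(unname(gt$groups), paste0(pref, gt$ids)))
    }
    if (!is.null(parentA)) cohorts <- c(cohorts, list(relabel(parentA, "PA", sprintf("rep%d_", r))))
    if (!is.null(parentB)) cohorts <- c(cohorts, list(relabel(parentB, "PB", sprintf("rep%d_", r))))
    gt <- do.call(bind_genotypes, cohorts)
    attr(gt, "rep_seed") <- rep_seeds[r]
    attr(gt, "true_class") <- gt$groups
    out[[r]] <- gt
  }
  out
}
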