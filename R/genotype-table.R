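#' Construct a diploid codominant genotype table
#'
#' The central container for microsatellite data: an individuals x loci
#' matrix of unordered diploid allele pairs (alleles coded as positive
#' integers, typically fragment sizes), a marker panel assignment
#' (`neutral` or `qtl`) per locus, and one group label per individual.
#'
#' Allele pairs are stored canonicalised smaller-first. Missingness is
#' whole-genotype: if either allele of a call is `NA` the call is demoted
#' to fully missing (with a warning when only one side was missing).
#'
#' @param ids character vector of unique individual identifiers.
#' @param markers data.frame with columns `name` (unique locus names) and
#'   `panel` (each `"neutral"` or `"qtl"`); a character vector of names is
#'   accepted and assigned to the `"neutral"` panel.
#' @param a1,a2 integer matrices (individuals x loci) holding the two
#'   alleles of each call; `NA` marks missing data.
#' @param groups group label per individual: either a character vector in
#'   `ids` order or a named vector keyed by individual id.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, markers, a1, a2, groups) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate individual IDs: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.character(markers)) markers <- data.frame(name = markers, panel = "neutral")
  if (!all(c("name", "panel") %in% names(markers)))
    stop("'markers' needs columns 'name' and 'panel'")
  markers$name <- as.character(markers$name)
  markers$panel <- as.character(markers$panel)
  if (!all(markers$panel %in% c("neutral", "qtl")))
    stop("marker panel must be 'neutral' or 'qtl'")
  if (anyDuplicated(markers$name)) stop("duplicate marker names")
  n <- length(ids); L <- nrow(markers)
  a1 <- matrix(as.integer(a1), n, L); a2 <- matrix(as.integer(a2), n, L)
  if (any(c(a1, a2) <= 0L, na.rm = TRUE)) stop("allele codes must be positive integers")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    warning(sum(half), " half-missing genotype(s) demoted to fully missing")
    a1[half] <- NA_integer_; a2[half] <- NA_integer_
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(ids, markers$name)
  if (is.null(names(groups))) {
    if (length(groups) != n) stop("'groups' must have one label per individual")
    groups <- stats::setNames(as.character(groups), ids)
  } else {
    if (!all(ids %in% names(groups))) stop("'groups' is missing labels for some individuals")
    groups <- stats::setNames(as.character(groups[ids]), ids)
  }
  if (anyNA(groups)) stop("every individual needs exactly one group label")
  structure(list(ids = ids, markers = markers, a1 = a1, a2 = a2, groups = groups),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals x", nrow(x$markers), "loci\n")
  cat("  panels:", sum(x$markers$panel == "neutral"), "neutral,",
      sum(x$markers$panel == "qtl"), "qtl\n")
  cat("  groups:", paste(sprintf("%s (%d)", names(table(x$groups)), table(x$groups)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Number of individuals / loci in a genotype table
#'
#' @param gt a [genotype_table()].
#' @return An integer count.
#' @export
n_ind <- function(gt) length(gt$ids)

#' @rdname n_ind
#' @export
n_loci <- function(gt) nrow(gt$markers)

#' Restrict a genotype table to a marker panel
#'
#' @param gt a [genotype_table()].
#' @param panel `"all"`, `"neutral"` or `"qtl"`.
#' @return A `genotype_table` with only the requested loci.
#' @export
subset_panel <- function(gt, panel = c("all", "neutral", "qtl")) {
  panel <- match.arg(panel)
  if (panel == "all") return(gt)
  keep <- gt$markers$panel == panel
  if (!any(keep)) stop("no loci in panel '", panel, "'")
  genotype_table(gt$ids, gt$markers[keep, , drop = FALSE],
                 gt$a1[, keep, drop = FALSE], gt$a2[, keep, drop = FALSE], gt$groups)
}

#' Restrict a genotype table to a subset of individuals
#'
#' @param gt a [genotype_table()].
#' @param ids individual identifiers (or logical/integer index) to keep.
#' @return A `genotype_table`.
#' @export
subset_individuals <- function(gt, ids) {
  if (is.logical(ids) || is.numeric(ids)) ids <- gt$ids[ids]
  ids <- as.character(ids)
  if (!all(ids %in% gt$ids)) stop("unknown individual IDs")
  i <- match(ids, gt$ids)
  genotype_table(ids, gt$markers, gt$a1[i, , drop = FALSE],
                 gt$a2[i, , drop = FALSE], gt$groups[i])
}

#' Concatenate genotype tables over the same loci
#'
#' @param ... `genotype_table` objects sharing identical marker definitions.
#' @return A single `genotype_table`.
#' @export
bind_genotypes <- function(...) {
  gts <- list(...)
  ref <- gts[[1]]$markers
  for (g in gts[-1])
    if (!identical(g$markers$name, ref$name)) stop("loci differ between tables")
  genotype_table(unlist(lapply(gts, `[[`, "ids")), ref,
                 do.call(rbind, lapply(gts, `[[`, "a1")),
                 do.call(rbind, lapply(gts, `[[`, "a2")),
                 unlist(lapply(gts, `[[`, "groups")))
}

#' Per-group, per-locus allele frequencies
#'
#' Frequencies are computed from non-missing calls only; `n_typed` records
#' the number of diploid individuals with a call per group x locus. A group
#' entirely missing at a locus yields an empty frequency map (not an error).
#'
#' @param gt a [genotype_table()].
#' @param grouping optional replacement grouping: named character vector
#'   keyed by individual id (defaults to `gt$groups`).
#' @return An object of class `allele_freq_table`: list with `freqs`
#'   (`freqs[[group]][[locus]]` a named numeric vector summing to 1),
#'   `n_typed` (group x locus integer matrix), `groups` and `loci`.
#' @export
allele_frequencies <- function(gt, grouping = NULL) {
  if (is.null(grouping)) grouping <- gt$groups
  if (is.null(names(grouping))) grouping <- stats::setNames(as.character(grouping), gt$ids)
  grouping <- grouping[gt$ids]
  if (anyNA(grouping)) stop("grouping must assign every individual to exactly one group")
  groups <- unique(unname(grouping))
  loci <- gt$markers$name
  n_typed <- matrix(0L, length(groups), length(loci), dimnames = list(groups, loci))
  freqs <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    rows <- which(grouping == g)
    fl <- stats::setNames(vector("list", length(loci)), loci)
    for (l in seq_along(loci)) {
      x <- c(gt$a1[rows, l], gt$a2[rows, l])
      x <- x[!is.na(x)]
      n_typed[g, l] <- length(x) %/% 2L
      if (length(x)) {
        tab <- table(x)
        fl[[l]] <- stats::setNames(as.numeric(tab) / length(x), names(tab))
      } else fl[[l]] <- stats::setNames(numeric(0), character(0))
    }
    freqs[[g]] <- fl
  }
  structure(list(freqs = freqs, n_typed = n_typed, groups = groups, loci = loci),
            class = "allele_freq_table")
}
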