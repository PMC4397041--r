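#' Read a GenePop-format genotype file
#'
#' Accepts the common GenePop 4 layout: a title line, locus names (one per
#' line and/or comma-separated), `POP` block separators, and per-individual
#' lines `id , a1a2 a1a2 ...` where each token is either the 2-digit
#' (4 characters) or 3-digit (6 characters) diploid dialect; `0000` /
#' `000000` encodes a missing genotype. Allele codes are kept as integers.
#'
#' Group labels come, in order of preference, from the `groups` sidecar
#' (the primary mechanism: study groupings typically cross files), from the
#' shared non-numeric prefix of the IDs in each POP block, or from the
#' block index (`pop1`, `pop2`, ...).
#'
#' @param path path to the GenePop text file.
#' @param qtl_loci character vector of locus names to tag as the `qtl`
#'   panel; all other loci are tagged `neutral`.
#' @param groups optional grouping sidecar: a named character vector keyed
#'   by individual id, or the path to a two-column TSV
#'   (`individual_id`, `group`) as written by [write_groups()].
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path, qtl_loci = character(), groups = NULL) {
  raw <- readLines(path, warn = FALSE)
  lines <- trimws(raw)
  if (length(lines) < 3) stop("not a GenePop file: fewer than 3 lines")
  is_pop <- toupper(lines) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found")
  loci <- unlist(strsplit(lines[2:(first_pop - 1)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop("no locus names between title and first POP")
  L <- length(loci)

  ids <- character(0); grp_idx <- integer(0)
  a1 <- a2 <- NULL
  block <- 0L; block_sizes <- integer(0)
  rows1 <- list(); rows2 <- list()
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (toupper(ln) == "POP") {
      if (block > 0L && block_sizes[block] == 0L)
        stop("empty POP block (block ", block, ")")
      block <- block + 1L; block_sizes[block] <- 0L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2) stop("line ", i, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop("line ", i, ": ", length(toks), " genotype(s) for ", L, " loci")
    v1 <- v2 <- integer(L)
    for (l in seq_len(L)) {
      tk <- toks[l]
      w <- nchar(tk)
      if (!grepl("^[0-9]+$", tk) || !(w %in% c(4L, 6L)))
        stop("line ", i, ": malformed genotype token '", tk, "'")
      h <- w %/% 2L
      x1 <- as.integer(substr(tk, 1L, h)); x2 <- as.integer(substr(tk, h + 1L, w))
      if (x1 == 0L || x2 == 0L) { v1[l] <- NA_integer_; v2[l] <- NA_integer_ }
      else { v1[l] <- x1; v2[l] <- x2 }
    }
    if (id %in% ids) stop("line ", i, ": duplicate individual ID '", id, "'")
    ids <- c(ids, id); grp_idx <- c(grp_idx, block)
    block_sizes[block] <- block_sizes[block] + 1L
    rows1[[length(rows1) + 1L]] <- v1; rows2[[length(rows2) + 1L]] <- v2
  }
  if (block == 0L || !length(ids)) stop("no individuals found after POP")
  if (block_sizes[block] == 0L) stop("empty POP block (block ", block, ")")
  a1 <- do.call(rbind, rows1); a2 <- do.call(rbind, rows2)

  lab <- character(length(ids))
  if (!is.null(groups)) {
    if (is.character(groups) && length(groups) == 1L && is.null(names(groups)))
      groups <- read_groups(groups)
    if (!all(ids %in% names(groups)))
      stop("grouping sidecar is missing IDs: ",
           paste(utils::head(setdiff(ids, names(groups)), 5), collapse = ", "))
    lab <- unname(groups[ids])
  } else {
    for (b in seq_len(block)) {
      bi <- grp_idx == b
      pre <- sub("[0-9_.-]+$", "", ids[bi][1])
      lab[bi] <- if (nzchar(pre)) pre else paste0("pop", b)
    }
    # distinct blocks must keep distinct labels
    for (b in seq_len(block)) {
      bi <- grp_idx == b
      if (any(lab[!bi & grp_idx < b] == lab[bi][1]))
        lab[bi] <- paste0(lab[bi], ".", b)
    }
  }
  markers <- data.frame(name = loci,
                        panel = ifelse(loci %in% qtl_loci, "qtl", "neutral"))
  genotype_table(ids, markers, a1, a2, lab)
}

#' Write a genotype table as 3-digit GenePop
#'
#' Emits the 3-digit dialect (missing = `000000`), one locus name per line,
#' one POP block per group in order of first appearance. Output is
#' deterministic for a given table.
#'
#' @param gt a [genotype_table()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @return Invisibly, `path`.
#' @export
write_genepop <- function(gt, path, title = "contactzone export") {
  if (n_loci(gt) == 0L) stop("cannot write a table with no loci")
  mx <- suppressWarnings(max(c(gt$a1, gt$a2), na.rm = TRUE))
  if (is.finite(mx) && mx > 999L) stop("allele code > 999 cannot be written in the 3-digit dialect")
  out <- c(title, gt$markers$name)
  for (g in unique(unname(gt$groups))) {
    out <- c(out, "POP")
    for (i in which(gt$groups == g)) {
      toks <- sprintf("%03d%03d",
                      ifelse(is.na(gt$a1[i, ]), 0L, gt$a1[i, ]),
                      ifelse(is.na(gt$a2[i, ]), 0L, gt$a2[i, ]))
      out <- c(out, paste0(gt$ids[i], " , ", paste(toks, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write the grouping sidecar
#'
#' A two-column delimited text file (`individual_id`, `group`) mapping each
#' individual to exactly one analysis group.
#'
#' @param path file path.
#' @return `read_groups`: a named character vector keyed by individual id.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("grouping sidecar needs columns individual_id, group")
  if (anyDuplicated(df[[1]])) stop("duplicate individual IDs in grouping sidecar")
  stats::setNames(df[[2]], df[[1]])
}

#' @rdname read_groups
#' @param groups named character vector (names = individual ids).
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(individual_id = names(groups), group = unname(groups)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.pheno_traits <- c("SL", "BD", "DS1", "DS2", "PS", "plates_left", "plates_right",
                   "mean_plates", "GRN", "GRL", "centroid_size")

#' Read a per-individual phenotype table
#'
#' Delimited text (comma or tab, sniffed from the header) with one row per
#' individual. An `id` column is required (case-insensitive). Recognised
#' trait columns: `SL`, `BD`, `DS1`, `DS2`, `PS` (lengths, mm),
#' `plates_left`, `plates_right`, `mean_plates` (lateral plate counts),
#' `GRN`, `GRL` (gill rakers), `centroid_size`. Unknown columns are kept
#' as-is. Non-numeric trait cells are recorded as missing with a warning;
#' `mean_plates` is computed as `(plates_left + plates_right)/2` where
#' absent and both sides are present. Out-of-range values (non-positive
#' lengths, plate counts outside `[0, 40]`) are demoted to missing with a
#' warning.
#'
#' @param path file path.
#' @return A data.frame with an `id` column and one column per trait.
#' @export
read_phenotypes <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  idc <- which(tolower(names(df)) == "id")
  if (!length(idc)) stop("phenotype file has no 'id' column")
  names(df)[idc[1]] <- "id"
  for (tr in intersect(names(df), .pheno_traits)) {
    raw <- trimws(df[[tr]])
    raw[!nzchar(raw)] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad))
      warning(sum(bad), " non-numeric value(s) in '", tr, "' recorded as missing")
    if (tr %in% c("SL", "BD", "DS1", "DS2", "PS", "GRL", "centroid_size")) {
      neg <- !is.na(num) & num <= 0
      if (any(neg)) { warning(sum(neg), " non-positive length(s) in '", tr,
                              "' recorded as missing"); num[neg] <- NA_real_ }
    }
    if (tr %in% c("plates_left", "plates_right", "mean_plates")) {
      oob <- !is.na(num) & (num < 0 | num > 40)
      if (any(oob)) { warning(sum(oob), " plate count(s) outside [0, 40] in '", tr,
                              "' recorded as missing"); num[oob] <- NA_real_ }
    }
    df[[tr]] <- num
  }
  if (!"mean_plates" %in% names(df) &&
      all(c("plates_left", "plates_right") %in% names(df))) {
    df$mean_plates <- (df$plates_left + df$plates_right) / 2
  } else if (all(c("mean_plates", "plates_left", "plates_right") %in% names(df))) {
    fill <- is.na(df$mean_plates) & !is.na(df$plates_left) & !is.na(df$plates_right)
    df$mean_plates[fill] <- (df$plates_left[fill] + df$plates_right[fill]) / 2
  }
  df
}

#' @rdname read_phenotypes
#' @param phenotypes data.frame as returned by [read_phenotypes()].
#' @param sep field separator (`","` or `"\t"`).
#' @export
write_phenotypes <- function(phenotypes, path, sep = ",") {
  utils::write.table(phenotypes, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
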