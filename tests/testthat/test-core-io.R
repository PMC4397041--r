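test_that("genotype_table canonicalises calls and enforces its invariants", {
  gt <- genotype_table(c("i1", "i2"), c("L1", "L2"),
                       a1 = rbind(c(5L, 2L), c(3L, NA)),
                       a2 = rbind(c(1L, 2L), c(3L, NA)),
                       groups = c("g", "g"))
  expect_true(all(gt$a1 <= gt$a2, na.rm = TRUE))      # smaller-first storage
  expect_identical(gt$a1["i1", "L1"], 1L)
  expect_error(genotype_table(c("a", "a"), "L1", cbind(1L, 1L)[1, , drop = FALSE],
                              cbind(1L, 1L)[1, , drop = FALSE], "g"),
               "duplicate")
  expect_warning(
    genotype_table("i1", "L1", matrix(1L), matrix(NA_integer_), "g"),
    "half-missing")
})

test_that("GenePop reader handles both digit dialects, panels and errors", {
  f <- withr::local_tempfile(fileext = ".gen")
  loci9 <- c("GAC5196", "GAC4170", "GAC1125", "GAC1097", "GAC7033",
             "STN18", "STN32", "STN75", "STN84")
  writeLines(c("nine neutral loci", paste(loci9, collapse = ", "),
               "POP",
               paste("FL_1 ,", paste(rep("101103", 9), collapse = " ")),
               paste("FL_2 ,", paste(rep("000000", 9), collapse = " "))), f)
  gt <- read_genepop(f)
  expect_equal(nrow(gt$markers), 9)
  expect_identical(gt$markers$name, loci9)
  expect_true(all(is.na(gt$a1["FL_2", ])))

  # minimal single individual, 3-digit token 001002 -> call {1, 2}
  f2 <- withr::local_tempfile()
  writeLines(c("t", "L1", "POP", "ind1 , 001002"), f2)
  g2 <- read_genepop(f2)
  expect_equal(n_ind(g2), 1)
  expect_identical(unname(c(g2$a1[1, 1], g2$a2[1, 1])), c(1L, 2L))

  # 2-digit dialect
  f3 <- withr::local_tempfile()
  writeLines(c("t", "L1,L2", "POP", "x1 , 0102 0304"), f3)
  g3 <- read_genepop(f3)
  expect_identical(unname(g3$a1[1, ]), c(1L, 3L))

  # malformed locus count names the line
  f4 <- withr::local_tempfile()
  writeLines(c("t", "L1,L2", "POP", "x1 , 001002"), f4)
  expect_error(read_genepop(f4), "line 4")
  # empty POP block
  f5 <- withr::local_tempfile()
  writeLines(c("t", "L1", "POP", "POP", "x1 , 001001"), f5)
  expect_error(read_genepop(f5), "empty POP")
  # duplicate individual
  f6 <- withr::local_tempfile()
  writeLines(c("t", "L1", "POP", "x1 , 001001", "x1 , 001002"), f6)
  expect_error(read_genepop(f6), "duplicate")
})

test_that("GenePop writer emits 3-digit dialect and round-trips", {
  gt <- make_gt(list(fee = rbind(c(1L, 2L, 101L, 101L), c(3L, 3L, NA, NA)),
                     fur = rbind(c(2L, 2L, 104L, 110L))),
                loci = c("L1", "L2"), panel = c("neutral", "qtl"))
  f <- withr::local_tempfile()
  write_genepop(gt, f)
  txt <- readLines(f)
  expect_true(any(grepl("000000", txt)))  # missing encoding
  gs <- withr::local_tempfile()
  write_groups(gt$groups, gs)
  back <- read_genepop(f, qtl_loci = "L2", groups = gs)
  expect_identical(back, gt)
  # identical output bytes on a rewrite
  f2 <- withr::local_tempfile()
  write_genepop(gt, f2)
  expect_identical(readLines(f), readLines(f2))
  # allele code > 999 refused
  bad <- make_gt(list(g = rbind(c(1000L, 1000L))))
  expect_error(write_genepop(bad, f), "999")
  empty <- gt; empty$markers <- gt$markers[0, ]; empty$a1 <- gt$a1[, 0]; empty$a2 <- gt$a2[, 0]
  expect_error(write_genepop(empty, f), "no loci")
})

test_that("phenotype reader computes mean plates and flags bad cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,SL,BD,DS1,DS2,PS,plates_left,plates_right,note",
               "a1,41.2,8.3,3.1,3.5,4.2,10,11,ok",
               "a2,39.0,oops,3.0,3.3,4.0,7,,fine"), f)
  expect_warning(ph <- read_phenotypes(f), "non-numeric")
  expect_equal(ph$mean_plates, c(10.5, NA))
  expect_true(all(c("SL", "BD", "DS1", "DS2", "PS") %in% names(ph)))
  expect_true(is.na(ph$BD[2]))
  expect_identical(ph$note, c("ok", "fine"))   # unknown columns preserved
  f2 <- withr::local_tempfile()
  writeLines(c("name,SL", "a,40"), f2)
  expect_error(read_phenotypes(f2), "id")
})

test_that("allele frequencies count correctly and pool consistently", {
  gt <- make_gt(list(g = rbind(c(1L, 1L), c(1L, 2L))))
  af <- allele_frequencies(gt)
  expect_equal(unname(af$freqs$g$L1), c(0.75, 0.25))
  expect_equal(af$n_typed["g", "L1"], 2)
  # monomorphic
  mono <- allele_frequencies(make_gt(list(g = rbind(c(7L, 7L)))))
  expect_equal(unname(mono$freqs$g$L1), 1)
  # all-missing marker -> empty map, n_typed 0
  mis <- make_gt(list(g = rbind(c(NA, NA), c(NA, NA))))
  afm <- allele_frequencies(mis)
  expect_length(afm$freqs$g$L1, 0)
  expect_equal(afm$n_typed["g", "L1"], 0)
})

test_that("frequencies sum to 1 and pooling equals typed-count-weighted mix", {
  for (s in 1:20) {
    gt <- random_gt(s)
    af <- allele_frequencies(gt)
    for (g in af$groups) for (l in af$loci)
      if (af$n_typed[g, l] > 0) expect_equal(sum(af$freqs[[g]][[l]]), 1, tolerance = 1e-9)
    # pool the first two groups and compare to weighted combination
    gs <- unique(unname(gt$groups))
    pooledlab <- ifelse(gt$groups %in% gs[1:2], "pool", gt$groups)
    afp <- allele_frequencies(gt, stats::setNames(pooledlab, gt$ids))
    for (l in af$loci) {
      n1 <- af$n_typed[gs[1], l]; n2 <- af$n_typed[gs[2], l]
      if (n1 + n2 == 0) next
      u <- union(names(af$freqs[[gs[1]]][[l]]), names(af$freqs[[gs[2]]][[l]]))
      f1 <- f2 <- stats::setNames(rep(0, length(u)), u)
      f1[names(af$freqs[[gs[1]]][[l]])] <- af$freqs[[gs[1]]][[l]]
      f2[names(af$freqs[[gs[2]]][[l]])] <- af$freqs[[gs[2]]][[l]]
      expected <- (n1 * f1 + n2 * f2) / (n1 + n2)
      got <- afp$freqs[["pool"]][[l]][u]
      expect_equal(unname(got), unname(expected), tolerance = 1e-12)
    }
  }
})
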