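# Tree and character-matrix I/O: parsing, ambiguity codes, polytomies,
# round trips, and tip/matrix mismatch errors.

test_that("newick parsing preserves topology and polytomies", {
  tr <- readTreeFile("(A,(B,C));")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  poly <- readTreeFile("(A,B,C);")
  expect_equal(poly$Nnode, 1)
  expect_equal(sum(poly$edge[, 1] == 4), 3)  # root polytomy of degree 3
  expect_true(all(poly$edge.length == 1))    # uniform default lengths
})

test_that("CSV matrices parse singletons, ambiguity sets and missing", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("taxon,state", "A,0", "B,01", "C,{02}", "D,?", "E,1/2"), f)
  cm <- readCharMatrix(f)
  expect_identical(cm$A, 0L)
  expect_identical(cm$B, 0:1)
  expect_identical(cm$C, c(0L, 2L))
  expect_identical(cm$D, 0:2)
  expect_identical(cm$E, 1:2)
})

test_that("NEXUS matrices parse with {} groups and charIndex selection", {
  f <- tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN CHARACTERS;",
               "DIMENSIONS NCHAR=3;", "MATRIX",
               "TaxonA 01{01}", "TaxonB 2?0", "'Taxon C' {12}21",
               ";", "END;"), f)
  cm1 <- readCharMatrix(f, charIndex = 1)
  expect_identical(cm1$TaxonA, 0L)
  expect_identical(cm1[["Taxon C"]], 1:2)
  cm3 <- readCharMatrix(f, charIndex = 3)
  expect_identical(cm3$TaxonA, 0:1)
  expect_identical(cm3$TaxonB, 0L)
})

test_that("matrix round-trips through CSV", {
  cm <- list(A = 0L, B = 0:1, C = 0:2)
  f <- tempfile(fileext = ".csv")
  writeCharMatrix(cm, f)
  expect_identical(readCharMatrix(f), cm)
})

test_that("tree round-trips through newick write/read", {
  tr <- randomTree(9, seed = 4)
  f <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  tr2 <- readTreeFile(f)
  expect_identical(sort(tr$tip.label), sort(tr2$tip.label))
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = FALSE))
  expect_equal(sort(tr$edge.length), sort(tr2$edge.length))
})

test_that("tip/matrix label mismatch raises an error naming offenders", {
  tr <- readTreeFile("(A,(B,C));")
  expect_error(sankoffParsimony(tr, list(A = 0L, B = 1L)), "C")
})

test_that("packaged synthetic example runs end to end", {
  tr <- readTreeFile(system.file("extdata",
                                 "synthetic-ichthyosauriform-tree.nwk",
                                 package = "SeqIsoTrim"))
  cm <- readCharMatrix(system.file("extdata",
                                   "synthetic-crownshape-chars.csv",
                                   package = "SeqIsoTrim"))
  p <- sankoffParsimony(tr, cm)
  expect_gte(minCost(p), 0)
  expect_true(p@originRange[1] >= 1)       # molariform states are present
  m <- fitRate(tr, cm)
  expect_true(is.finite(m@logLik))
  tab <- asrTable(m, tr)
  expect_equal(nrow(tab), length(tr$tip.label) + tr$Nnode)
  f <- tempfile(fileext = ".json")
  asrToJson(p, tr, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "")))
})
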