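writeToyTable <- function(lines, ann_lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  writeLines(ann_lines, paste0(path, ".annotation.tsv"))
  path
}

test_that("readExpressionTable parses a well-formed table with annotation", {
  path <- writeToyTable(
    c("gene\ts1\ts2\ts3\ts4",
      "g1\t1.0\t2.0\t3.0\t4.0",
      "g2\t0.5\tbad\t1.5\t2.5",
      "g3\t-1\t0\t1\t2"),
    c("sample\tcondition", "s1\tA", "s2\tA", "s3\tB", "s4\tB"))
  ds <- readExpressionTable(path)
  expect_s4_class(ds, "ExpressionDataset")
  expect_equal(dim(ds), c(3L, 4L))
  expect_true(is.na(exprsMatrix(ds)["g2", "s2"]))  # unparseable -> missing
  expect_equal(exprsMatrix(ds)["g1", "s4"], 4.0)
  expect_equal(unname(sampleConditions(ds)), c("A", "A", "B", "B"))
})

test_that("readExpressionTable rejects duplicate genes and unannotated samples", {
  dup <- writeToyTable(
    c("gene\ts1\ts2", "GAPDH\t1\t2", "GAPDH\t3\t4"),
    c("sample\tcondition", "s1\tA", "s2\tB"))
  expect_error(readExpressionTable(dup), "GAPDH")
  noann <- writeToyTable(
    c("gene\ts1\ts2", "g1\t1\t2"),
    c("sample\tcondition", "s1\tA"))
  expect_error(readExpressionTable(noann), "s2")
})

test_that("expression tables round-trip through write/read", {
  m <- toyMatrix(round(rnorm(12), 6), paste0("g", 1:3), paste0("s", 1:4))
  ds <- ExpressionDataset(m, condition = c("A", "A", "B", "B"),
                          pairing = c("p1", "p2", "p1", "p2"))
  path <- tempfile(fileext = ".tsv")
  writeExpressionTable(ds, path)
  back <- readExpressionTable(path)
  expect_equal(exprsMatrix(back), exprsMatrix(ds), tolerance = 1e-9)
  expect_equal(samplePairing(back), samplePairing(ds))
})

test_that("medianNormalize centers every sample at median zero and is idempotent", {
  m <- toyMatrix(c(1, 5, 9,
                   2, 2, 2,
                   0, NA, 4), paste0("g", 1:3), paste0("s", 1:3))
  # column s1 = (1,2,0); after normalization median 0
  ds <- ExpressionDataset(m, condition = c("A", "A", "B"))
  nm <- medianNormalize(ds)
  expect_equal(unname(apply(exprsMatrix(nm), 2, median, na.rm = TRUE)),
               c(0, 0, 0))
  # a specific column: (5, 2, NA) has median over observed 3.5
  expect_equal(unname(exprsMatrix(nm)[, "s2"]), c(5, 2, NA) - 3.5)
  again <- medianNormalize(nm)
  expect_equal(exprsMatrix(again), exprsMatrix(nm))
  m[, 1] <- NA
  ds_bad <- ExpressionDataset(m, condition = c("A", "A", "B"))
  expect_error(medianNormalize(ds_bad), "missing")
})

test_that("filterGenePresence applies the across-array fraction and is monotone", {
  # g1 present 8/10 arrays, g2 present 6/10, g3 always
  m1 <- toyMatrix(c(1, NA, 1, 1, 1,
                    1, NA, NA, 1, 1,
                    1, 1, 1, 1, 1), paste0("g", 1:3), paste0("s", 1:5))
  m2 <- toyMatrix(c(1, 1, 1, NA, 1,
                    NA, 1, 1, NA, 1,
                    1, 1, 1, 1, 1), paste0("g", 1:3), paste0("t", 1:5))
  d1 <- ExpressionDataset(m1, condition = c("A", "A", "A", "B", "B"))
  d2 <- ExpressionDataset(m2, condition = c("A", "A", "A", "B", "B"))
  expect_setequal(filterGenePresence(list(d1, d2), 0.7), c("g1", "g3"))
  expect_setequal(filterGenePresence(list(d1, d2), 1.0), "g3")
  expect_error(filterGenePresence(list()), "empty")
  for (f in seq(0.1, 1, by = 0.1)) {
    lo <- filterGenePresence(list(d1, d2), f)
    hi <- filterGenePresence(list(d1, d2), min(f + 0.1, 1))
    expect_true(all(hi %in% lo))  # raising the threshold never adds genes
  }
})

test_that("Cytoscape tables round-trip and enforce node annotation", {
  net <- netFromEdges(list(c("a", "b"), c("b", "c")))
  ann <- data.frame(gene = c("a", "b", "c"), is_deg = TRUE,
                    is_dc = c(TRUE, FALSE, FALSE), is_causal = FALSE)
  ep <- tempfile(); np <- tempfile()
  writeCytoscapeTables(net, ann, ep, np)
  edges <- read.table(ep, header = TRUE, sep = "\t")
  expect_equal(nrow(edges), 2L)
  nodes <- read.table(np, header = TRUE, sep = "\t")
  expect_equal(nodes$degree[nodes$gene == "b"], 2L)
  back <- readCytoscapeEdges(ep, np)
  expect_equal(networkEdges(back)[, c("gene_i", "gene_j")],
               networkEdges(net)[, c("gene_i", "gene_j")])
  expect_error(writeCytoscapeTables(net, ann[-1, ], ep, np), "a")
  # empty network -> header-only files
  empty <- CoexpressionNetwork("A", character())
  writeCytoscapeTables(empty, ann[0, ], ep, np)
  expect_equal(nrow(read.table(ep, header = TRUE, sep = "\t")), 0L)
})
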