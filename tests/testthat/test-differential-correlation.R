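test_that("fisherZ is the atanh transform with its symmetries", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.8), 0.5 * log(9))  # = atanh(0.8) ~ 1.0986
  expect_equal(fisherZ(-0.3), -fisherZ(0.3))
  expect_error(fisherZ(1))
  expect_error(fisherZ(-1.2))
})

test_that("diffCorrTest matches the normal-tail oracle and its symmetries", {
  eq <- diffCorrTest(0.5, 20, 0.5, 30)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  ex <- diffCorrTest(0.8, 12, 0, 12)
  expect_equal(ex$z, 2.3305086, tolerance = 1e-6)
  expect_equal(ex$p, 0.0197793, tolerance = 1e-5)
  sw <- diffCorrTest(0, 12, 0.8, 12)
  expect_equal(sw$p, ex$p)
  expect_equal(sw$z, -ex$z)
  expect_true(is.na(diffCorrTest(0.5, 3, 0.2, 12)$p))  # n too small
})

simPair <- function(seed, n = 12, r_A = 0, r_B = 0.8, shared = FALSE) {
  # two datasets; pair (G01,G02) with per-condition correlation r_A / r_B;
  # shared = TRUE plants the same correlation in both conditions
  set.seed(seed)
  SA <- diag(6); SA[1, 2] <- SA[2, 1] <- r_A
  SB <- diag(6); SB[1, 2] <- SB[2, 1] <- if (shared) r_A else r_B
  list(corrDataset(SA, SB, n, id = "d1"), corrDataset(SA, SB, n, id = "d2"))
}

test_that("uncorrelated pairs never become DCP candidates", {
  dss <- simPair(71, r_A = 0, r_B = 0)
  degs <- degStub(sprintf("G%02d", 1:6))
  nA <- buildCoexpressionNetwork(dss, degs, "A", dcConfig())
  nB <- buildCoexpressionNetwork(dss, degs, "B", dcConfig())
  dcps <- callDCPs(dss, nA, nB, dcConfig())
  cand <- attr(dcps, "candidates")
  # a pair with r = 0 everywhere fails the initial correlation screen
  expect_false(cand$candidate[cand$gene_i == "G01" & cand$gene_j == "G02"])
})

test_that("pairs that are edges in both networks are excluded from DCPs", {
  dss <- simPair(72, r_A = 0.9, shared = TRUE, n = 30)
  degs <- degStub(sprintf("G%02d", 1:6))
  nA <- buildCoexpressionNetwork(dss, degs, "A", dcConfig())
  nB <- buildCoexpressionNetwork(dss, degs, "B", dcConfig())
  ek <- function(n) paste(networkEdges(n)$gene_i, networkEdges(n)$gene_j)
  expect_true("G01 G02" %in% ek(nA) && "G01 G02" %in% ek(nB))
  dcps <- callDCPs(dss, nA, nB, dcConfig())
  expect_false("G01 G02" %in% paste(dcps$gene_i, dcps$gene_j))
})

test_that("a strong planted gain is detected and classified as a gain", {
  found <- 0
  for (s in 1:10) {
    dss <- simPair(720 + s, r_A = 0, r_B = 0.95, n = 14)
    degs <- degStub(sprintf("G%02d", 1:6))
    nA <- buildCoexpressionNetwork(dss, degs, "A", dcConfig())
    nB <- buildCoexpressionNetwork(dss, degs, "B", dcConfig())
    dcps <- callDCPs(dss, nA, nB, dcConfig())
    hit <- dcps$gene_i == "G01" & dcps$gene_j == "G02"
    if (any(hit)) {
      expect_equal(dcps$change_direction[hit], "gain")
      expect_equal(dcps$host_network[hit], "B")
      found <- found + 1
    }
  }
  expect_gte(found, 7)
})

test_that("exchanging condition labels maps gains to losses with identical p", {
  dss <- simPair(73, r_A = 0, r_B = 0.95, n = 14)
  degs <- degStub(sprintf("G%02d", 1:6))
  flip <- lapply(dss, function(ds) {
    cond <- sampleConditions(ds)
    ExpressionDataset(exprsMatrix(ds),
                      condition = ifelse(cond == "A", "B", "A"),
                      datasetId = datasetId(ds))
  })
  run <- function(d) {
    nA <- buildCoexpressionNetwork(d, degs, "A", dcConfig())
    nB <- buildCoexpressionNetwork(d, degs, "B", dcConfig())
    callDCPs(d, nA, nB, dcConfig())
  }
  fwd <- run(dss); rev <- run(flip)
  key <- function(d) paste(d$gene_i, d$gene_j)
  expect_setequal(key(fwd), key(rev))
  common <- intersect(key(fwd), key(rev))
  for (k in common) {
    i <- match(k, key(fwd)); j <- match(k, key(rev))
    expect_equal(fwd$combined_p[i], rev$combined_p[j])
    expect_true(fwd$change_direction[i] != rev$change_direction[j])
  }
})

test_that("every called DCP is an edge of exactly one network (structural)", {
  tr <- generateTruth(truthConfig(), seed = 74)
  dss <- sampleDatasets(tr, seed = 75)
  res <- runPipeline(datasets = dss, config = dcConfig(), seed = 74,
                     n_perm = 10)
  ek <- function(n) paste(networkEdges(n)$gene_i, networkEdges(n)$gene_j)
  inA <- paste(res$dcps$gene_i, res$dcps$gene_j) %in% ek(res$network_A)
  inB <- paste(res$dcps$gene_i, res$dcps$gene_j) %in% ek(res$network_B)
  expect_true(all(xor(inA, inB)))
  expect_equal(res$dcps$change_direction, ifelse(inB, "gain", "loss"))
})
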