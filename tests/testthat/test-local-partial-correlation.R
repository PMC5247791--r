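test_that("pairNeighborhood keeps first-order neighbors of the pair only", {
  # pair (X2,X5); X3,X6,X8,X9 adjacent to a pair member; X1,X4,X7 are
  # second-order (adjacent only to the neighbors) and must be excluded
  net <- netFromEdges(list(c("X2", "X5"), c("X2", "X3"), c("X2", "X6"),
                           c("X5", "X8"), c("X5", "X9"), c("X3", "X1"),
                           c("X6", "X4"), c("X8", "X7")))
  expect_equal(pairNeighborhood(net, c("X2", "X5")),
               c("X3", "X6", "X8", "X9"))
  iso <- netFromEdges(list(c("a", "b"), c("c", "d")))
  expect_equal(pairNeighborhood(iso, c("a", "b")), character())
  star <- netFromEdges(list(c("h", "l1"), c("h", "l2"), c("h", "l3"),
                            c("h", "x")))
  expect_equal(pairNeighborhood(star, c("h", "x")), c("l1", "l2", "l3"))
})

test_that("capNeighborhood truncates to floor(n/2) by strongest pair correlation", {
  nb <- paste0("n", 1:5)
  cp <- cbind(r_i = c(.9, .1, .5, .3, .2), r_j = c(.1, .8, .2, .7, .1))
  rownames(cp) <- nb
  expect_equal(capNeighborhood(nb, cp, n = 12), nb)  # below the cap
  nb8 <- paste0("n", 1:8)
  cp8 <- cbind(r_i = c(.9, .8, .7, .6, .5, .4, .3, .2),
               r_j = rep(0, 8))
  rownames(cp8) <- nb8
  expect_equal(capNeighborhood(nb8, cp8, n = 6), c("n1", "n2", "n3"))
  # ties at the cut break lexicographically
  cp8[, 1] <- 0.5
  expect_equal(capNeighborhood(nb8, cp8, n = 6), c("n1", "n2", "n3"))
})

test_that("localPartialCorr reduces to Pearson at k = 0 and to the first-order formula at k = 1", {
  S2 <- matrix(c(1, 0.63, 0.63, 1), 2)
  res <- localPartialCorr(S2, c(1, 2), n = 20)
  expect_equal(res$partial_r, 0.63, tolerance = 1e-12)
  expect_equal(res$k, 0L)
  # k = 0 p-value formula is the Pearson formula with df = n - 2
  expect_equal(res$p, 2 * pt(-abs(0.63 * sqrt(18 / (1 - 0.63^2))), 18))
  # chain A - B - C: conditioning on B annihilates the A-C correlation
  S3 <- matrix(c(1, .6, .36,
                 .6, 1, .6,
                 .36, .6, 1), 3)
  chain <- localPartialCorr(S3[c(1, 3, 2), c(1, 3, 2)], c(1, 2), n = 30)
  expect_equal(chain$partial_r, 0, tolerance = 1e-12)
  expect_equal(chain$partial_r,
               partialCorrOracle(0.36, 0.6, 0.6), tolerance = 1e-12)
  # symmetry in the pair
  set.seed(81)
  S <- randomCorr(5)
  a <- localPartialCorr(S, c(1, 2), n = 30)
  b <- localPartialCorr(S[c(2, 1, 3:5), c(2, 1, 3:5)], c(1, 2), n = 30)
  expect_equal(a$partial_r, b$partial_r, tolerance = 1e-12)
})

test_that("a saturated conditioning set equals the global precision-matrix value", {
  set.seed(82)
  for (i in 1:20) {
    k <- sample(3:10, 1)
    S <- randomCorr(k)
    om <- solve(S)
    global <- -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
    loc <- localPartialCorr(S, c(1, 2), n = 50)
    expect_equal(loc$partial_r, global, tolerance = 1e-10)
  }
})

test_that("with two variables the LPC network equals the thresholded Pearson network", {
  set.seed(83)
  S <- matrix(c(1, .8, .8, 1), 2)
  ds <- corrDataset(S, S, n = 30)
  degs <- degStub(c("G01", "G02"))
  cfg <- dcConfig("cervical", k_required = 1L)
  lpc <- buildLPCNetwork(list(ds), degs, "A", cfg)
  pea <- buildCoexpressionNetwork(list(ds), degs, "A",
                                  dcConfig(k_required = 1L, p_corr = cfg$p_lpc_screen,
                                           q_corr = cfg$q_lpc))
  expect_equal(networkEdges(lpc)[, c("gene_i", "gene_j", "sign")],
               networkEdges(pea)[, c("gene_i", "gene_j", "sign")])
  expect_equal(networkEdges(lpc)$combined_p, networkEdges(pea)$combined_p,
               tolerance = 1e-12)
})

test_that("LPC removes the indirect edge of a Gaussian chain", {
  # A - B - C with r = 0.7: the marginal A-C correlation (0.49) is
  # significant at n = 100, but vanishes after conditioning on B
  degs <- degStub(c("A", "B", "C"))
  S <- matrix(c(1, .7, .49, .7, 1, .7, .49, .7, 1), 3)
  set.seed(84)
  marg_ac <- lpc_ac <- logical(10)
  for (i in 1:10) {
    ds <- corrDataset(S, diag(3), n = 100, genes = c("A", "B", "C"))
    cfg1 <- dcConfig(k_required = 1L)
    marg <- buildCoexpressionNetwork(list(ds), degs, "A", cfg1)
    lpc <- buildLPCNetwork(list(ds), degs, "A", dcConfig("cervical", k_required = 1L))
    ek <- function(n) paste(networkEdges(n)$gene_i, networkEdges(n)$gene_j)
    marg_ac[i] <- "A C" %in% ek(marg)
    lpc_ac[i] <- "A C" %in% ek(lpc)
    expect_true(all(c("A B", "B C") %in% ek(lpc)))  # direct edges survive
  }
  expect_gte(mean(marg_ac), 0.9)
  expect_lte(mean(lpc_ac), 0.1)
})

test_that("datasets below six samples per condition are skipped with a warning", {
  set.seed(85)
  ds <- corrDataset(diag(3), diag(3), n = 5)
  expect_warning(
    net <- buildLPCNetwork(list(ds), degStub(sprintf("G%02d", 1:3)), "A",
                           dcConfig("cervical", k_required = 1L)),
    "fewer than 6")
  expect_equal(nrow(networkEdges(net)), 0L)
})
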