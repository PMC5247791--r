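#' Default configuration for the synthetic truth generator
#'
#' The defaults emulate a two-dataset, two-condition knockout-style design:
#' 300 genes of which 60 are differentially expressed at 1.5 SD; 5 causal
#' hub genes, each gaining correlations (r 0 -> 0.8) with 4 partner genes
#' in condition B (20 primary gain pairs; the one-factor hub blocks induce
#' weaker secondary gains among partners); 10 pairs losing an r = 0.8
#' correlation; 5 pairs correlated identically in both conditions (edges
#' of both networks, hence never DCPs); and a per-pair random effect with
#' intraclass correlation 0.15 for paired designs.
#'
#' @param n_genes,n_causal,n_deg,n_gain,n_loss,n_shared,r_planted,effect_size,pairICC
#'   see Details in [generateTruth()].
#' @return a named list.
#' @export
truthConfig <- function(n_genes = 300, n_causal = 5, n_deg = 60,
                        n_gain = 20, n_loss = 10, n_shared = 5,
                        r_planted = 0.8, effect_size = 1.5,
                        pairICC = 0.15) {
  list(n_genes = n_genes, n_causal = n_causal, n_deg = n_deg,
       n_gain = n_gain, n_loss = n_loss, n_shared = n_shared,
       r_planted = r_planted, effect_size = effect_size, pairICC = pairICC)
}

#' Generate a planted ground truth for a two-condition study
#'
#' Builds block correlation structures on the observed (within-condition)
#' scale: condition A is the baseline; condition B equals A with the gain
#' pairs set to \code{r_planted} (previously 0) and the loss pairs set to
#' 0 (previously \code{r_planted}). Causal genes are hubs of one-factor
#' gain blocks (each hub drives \code{n_gain / n_causal} partner genes),
#' so hub-partner pairs gain \code{r_planted} and partner-partner pairs
#' carry an induced secondary gain; both are recorded in the truth, the
#' former flagged \code{primary}. Differential expression effects (B minus
#' A, in units of total per-sample SD) apply to condition B means only.
#' For paired sampling a fraction \code{pairICC} of each gene's variance
#' is a per-pair random effect shared across conditions, which bounds the
#' representable planted correlation by \code{1 - pairICC}; infeasible
#' configurations are an error. Matrices are repaired to the nearest
#' positive semi-definite matrix by eigenvalue clipping when needed, and
#' planted entries are asserted to stay within 0.02 of target. Fully
#' reproducible from \code{seed}.
#'
#' @param config list from [truthConfig()].
#' @param seed integer seed.
#' @return a [SyntheticTruth-class] object.
#' @export
generateTruth <- function(config = truthConfig(), seed = 1L) {
  cf <- config
  icc <- cf$pairICC
  if (cf$r_planted <= 0 || cf$r_planted >= 1) stop("r_planted must be in (0,1)")
  re <- cf$r_planted / (1 - icc)  # residual-scale correlation
  if (re >= 0.999)
    stop("infeasible configuration: r_planted/(1 - pairICC) must be < 1")
  if (cf$n_gain > 0 && cf$n_causal == 0)
    stop("gain pairs require at least one causal hub")
  if (cf$n_causal > 0 && cf$n_gain %% cf$n_causal != 0)
    stop("n_gain must be a multiple of n_causal (partners per hub)")
  if (cf$n_causal > 0 && cf$n_gain < cf$n_causal)
    stop("each causal hub needs at least one gain pair")
  pph <- if (cf$n_causal > 0) cf$n_gain / cf$n_causal else 0
  n_planted <- cf$n_causal * (1 + pph) + 2 * cf$n_loss + 2 * cf$n_shared
  if (n_planted > cf$n_deg)
    stop("n_deg too small for the planted pair structure")
  if (cf$n_deg > cf$n_genes) stop("n_deg exceeds n_genes")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(cf$n_genes))
  slots_ <- sample(genes)  # random placement of planted genes

  take <- function(k) {
    out <- slots_[seq_len(k)]
    slots_ <<- slots_[-seq_len(k)]
    out
  }
  blocks <- list()
  dirs <- character(0)
  dcp <- list()
  causal <- character(0)
  blkdir <- function(i) if (i %% 2L == 1L) "UP" else "DN"

  for (h in seq_len(cf$n_causal)) {
    gs <- sort(take(1 + pph))
    hub <- gs[1L]
    causal <- c(causal, hub)
    # one-factor residual block in B: hub-partner re, partner-partner re^2
    k <- length(gs)
    Cb <- matrix(re^2, k, k)
    Cb[1L, ] <- Cb[, 1L] <- re
    diag(Cb) <- 1
    blocks[[length(blocks) + 1L]] <-
      list(genes = gs, corrA = diag(k), corrB = Cb, kind = "gain")
    dirs <- c(dirs, stats::setNames(rep(blkdir(h), k), gs))
    for (p in gs[-1L])
      dcp[[length(dcp) + 1L]] <- data.frame(
        gene_i = min(hub, p), gene_j = max(hub, p), class = "gain",
        r_A = 0, r_B = cf$r_planted, primary = TRUE,
        stringsAsFactors = FALSE)
    if (k > 2L) {
      prt <- gs[-1L]
      cmb <- utils::combn(prt, 2L)
      for (cc in seq_len(ncol(cmb)))
        dcp[[length(dcp) + 1L]] <- data.frame(
          gene_i = cmb[1L, cc], gene_j = cmb[2L, cc], class = "gain",
          r_A = 0, r_B = re^2 * (1 - icc), primary = FALSE,
          stringsAsFactors = FALSE)
    }
  }
  for (l in seq_len(cf$n_loss)) {
    gs <- sort(take(2L))
    Ca <- matrix(c(1, re, re, 1), 2L)
    blocks[[length(blocks) + 1L]] <-
      list(genes = gs, corrA = Ca, corrB = diag(2L), kind = "loss")
    dirs <- c(dirs, stats::setNames(rep(blkdir(cf$n_causal + l), 2L), gs))
    dcp[[length(dcp) + 1L]] <- data.frame(
      gene_i = gs[1L], gene_j = gs[2L], class = "loss",
      r_A = cf$r_planted, r_B = 0, primary = TRUE, stringsAsFactors = FALSE)
  }
  for (sh in seq_len(cf$n_shared)) {
    gs <- sort(take(2L))
    Cs <- matrix(c(1, re, re, 1), 2L)
    blocks[[length(blocks) + 1L]] <-
      list(genes = gs, corrA = Cs, corrB = Cs, kind = "shared")
    dirs <- c(dirs, stats::setNames(rep(blkdir(cf$n_causal + cf$n_loss + sh), 2L), gs))
  }
  n_extra <- cf$n_deg - n_planted
  if (n_extra > 0) {
    gs <- take(n_extra)
    dirs <- c(dirs, stats::setNames(
      ifelse(seq_len(n_extra) %% 2L == 1L, "UP", "DN"), gs))
  }

  degTruth <- data.frame(gene = genes,
                         direction = "null", effect = 0,
                         stringsAsFactors = FALSE)
  idx <- match(names(dirs), genes)
  degTruth$direction[idx] <- unname(dirs)
  degTruth$effect[idx] <- ifelse(dirs == "UP", cf$effect_size,
                                 -cf$effect_size)

  mkFull <- function(which) {
    M <- diag(cf$n_genes)
    dimnames(M) <- list(genes, genes)
    for (b in blocks) {
      gi <- match(b$genes, genes)
      M[gi, gi] <- b[[which]] * (1 - icc)
      diag(M)[gi] <- 1
    }
    M
  }
  corrA <- mkFull("corrA"); corrB <- mkFull("corrB")
  corrA <- .psdRepair(corrA); corrB <- .psdRepair(corrB)

  dcpTruth <- if (length(dcp)) do.call(rbind, dcp)
    else data.frame(gene_i = character(), gene_j = character(),
                    class = character(), r_A = numeric(), r_B = numeric(),
                    primary = logical(), stringsAsFactors = FALSE)
  dcpTruth <- dcpTruth[order(dcpTruth$gene_i, dcpTruth$gene_j), ]
  rownames(dcpTruth) <- NULL

  new("SyntheticTruth", genes = genes, degTruth = degTruth,
      corrA = corrA, corrB = corrB, dcpTruth = dcpTruth,
      causalGenes = sort(causal), blocks = blocks, pairICC = icc,
      seed = as.integer(seed))
}

# Nearest-PSD repair by eigenvalue clipping with re-normalised unit
# diagonal; identity when already PSD.
.psdRepair <- function(M, eps = 1e-8) {
  ev <- eigen(M, symmetric = TRUE)
  if (min(ev$values) >= -eps) return(M)
  v <- pmax(ev$values, eps)
  R <- ev$vectors %*% (v * t(ev$vectors))
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  dimnames(R) <- dimnames(M)
  (R + t(R)) / 2
}

#' Sample expression datasets from a planted truth
#'
#' Draws \code{m_datasets} parallel datasets. Within each dataset and
#' condition, samples follow a multivariate normal with the condition's
#' planted correlation structure (realised blockwise) plus the planted
#' mean shifts in condition B, on a log-expression scale with baseline 8.
#' Paired designs share, per pair and gene, a random intercept carrying a
#' fraction \code{pairICC} of the unit total variance (the within-pair
#' sharing that motivates a paired test); the planted matrices are
#' realised on the observed within-condition scale either way.
#' Heterogeneity \code{h} emulates multi-causal tumors: each condition-B
#' sample activates each causal hub block independently with probability
#' \code{1 - h}, an inactive block reverting to the condition-A structure
#' for that sample.
#'
#' @param truth a [SyntheticTruth-class].
#' @param m_datasets number of parallel datasets.
#' @param n_per_condition samples per condition per dataset (>= 4).
#' @param paired logical; share a per-pair random intercept and emit
#'   pair identifiers.
#' @param heterogeneity h in [0, 1].
#' @param seed integer seed.
#' @return list of [ExpressionDataset-class] objects.
#' @export
sampleDatasets <- function(truth, m_datasets = 2L, n_per_condition = 12L,
                           paired = TRUE, heterogeneity = 0, seed = 1L) {
  stopifnot(n_per_condition >= 4L,
            heterogeneity >= 0, heterogeneity <= 1)
  icc <- truth@pairICC
  genes <- truth@genes
  G <- length(genes)
  n <- n_per_condition
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- stats::setNames(rep(8, G), genes)
  shift <- stats::setNames(truth@degTruth$effect, truth@degTruth$gene)[genes]
  chols <- lapply(truth@blocks, function(b)
    list(genes = b$genes, kind = b$kind,
         A = chol(b$corrA), B = chol(b$corrB)))
  out <- vector("list", m_datasets)
  for (d in seq_len(m_datasets)) {
    epsA <- matrix(stats::rnorm(G * n), G, n, dimnames = list(genes, NULL))
    epsB <- matrix(stats::rnorm(G * n), G, n, dimnames = list(genes, NULL))
    for (bc in chols) {
      gi <- bc$genes
      k <- length(gi)
      epsA[gi, ] <- crossprod(bc$A, matrix(stats::rnorm(k * n), k, n))
      zB <- crossprod(bc$B, matrix(stats::rnorm(k * n), k, n))
      if (heterogeneity > 0 && bc$kind == "gain") {
        inactive <- stats::runif(n) < heterogeneity
        if (any(inactive))
          zB[, inactive] <- crossprod(bc$A,
            matrix(stats::rnorm(k * sum(inactive)), k, sum(inactive)))
      }
      epsB[gi, ] <- zB
    }
    bA <- matrix(stats::rnorm(G * n), G, n)
    bB <- if (paired) bA else matrix(stats::rnorm(G * n), G, n)
    XA <- mu + sqrt(icc) * bA + sqrt(1 - icc) * epsA
    XB <- mu + shift + sqrt(icc) * bB + sqrt(1 - icc) * epsB
    X <- cbind(XA, XB)
    colnames(X) <- c(sprintf("d%dA%02d", d, seq_len(n)),
                     sprintf("d%dB%02d", d, seq_len(n)))
    pairing <- if (paired) rep(sprintf("p%02d", seq_len(n)), 2L) else NULL
    out[[d]] <- ExpressionDataset(
      X, condition = rep(c("A", "B"), each = n), pairing = pairing,
      datasetId = sprintf("sim%d", d))
  }
  out
}
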