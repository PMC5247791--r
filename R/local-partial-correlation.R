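#' Conditioning neighborhood of a significantly correlated pair
#'
#' The genes adjacent (significantly correlated) to either member of the
#' pair in the given network, excluding the pair itself. Genes correlated
#' only with the neighbors but not with the pair are excluded: the inverse
#' is applied to the sub-matrix of the pair plus this first-order
#' neighborhood only.
#'
#' @param network a [CoexpressionNetwork-class] (typically the per-dataset
#'   screened correlation graph).
#' @param pair character vector of the two gene identifiers.
#' @return character vector of neighborhood gene identifiers (possibly
#'   empty), sorted.
#' @export
pairNeighborhood <- function(network, pair) {
  e <- networkEdges(network)
  hit <- e$gene_i %in% pair | e$gene_j %in% pair
  nb <- unique(c(e$gene_i[hit], e$gene_j[hit]))
  sort(setdiff(nb, pair))
}

#' Cap a conditioning neighborhood at n/2 genes
#'
#' When the neighborhood outgrows the sample count \code{n}, only the
#' \eqn{\lfloor n/2 \rfloor} neighbors with the largest absolute
#' correlation to either member of the pair are retained (ranking key
#' \code{max(|r to gene_i|, |r to gene_j|)} by default, switchable to the
#' mean). Ties at the cut are broken by lexicographic gene identifier.
#'
#' @param neighbors character vector of neighborhood genes.
#' @param corr_to_pair numeric matrix (or 2-column data.frame) with one row
#'   per neighbor (rownames = neighbor ids) holding the correlations to
#'   \code{gene_i} and \code{gene_j}.
#' @param n per-condition sample count of the dataset.
#' @param rank aggregator over the two correlations, \code{"max"} or
#'   \code{"mean"}.
#' @return the (possibly truncated) neighbor set.
#' @export
capNeighborhood <- function(neighbors, corr_to_pair, n, rank = c("max", "mean")) {
  rank <- match.arg(rank)
  if (length(neighbors) <= n) return(neighbors)
  cp <- abs(as.matrix(corr_to_pair))[neighbors, , drop = FALSE]
  key <- if (rank == "max") pmax(cp[, 1L], cp[, 2L], na.rm = TRUE)
         else rowMeans(cp, na.rm = TRUE)
  ord <- order(-key, neighbors)
  neighbors[ord][seq_len(floor(n / 2))]
}

#' Local partial correlation from a correlation sub-matrix
#'
#' Inverts the correlation sub-matrix over the pair plus its conditioning
#' set and returns the pair's partial correlation
#' \eqn{-\Omega_{ij} / \sqrt{\Omega_{ii}\Omega_{jj}}} with a two-sided
#' p-value from \eqn{t = \rho\sqrt{(n-k-2)/(1-\rho^2)}} on \eqn{n - k - 2}
#' degrees of freedom, where \eqn{k} is the conditioning-set size. A
#' singular sub-matrix falls back to a small diagonal ridge (1e-8) with a
#' warning, keeping the computation deterministic.
#'
#' @param corr_submatrix symmetric correlation matrix over
#'   \{pair\} \eqn{\cup} \{conditioning set\}.
#' @param pair_idx indices (or names) of the pair within the sub-matrix.
#' @param n number of samples behind the correlations.
#' @return list with \code{partial_r}, \code{p}, \code{k} (conditioning-set
#'   size) and \code{df}; \code{p = NA} when \eqn{n - k - 2 < 1}.
#' @export
localPartialCorr <- function(corr_submatrix, pair_idx = c(1L, 2L), n) {
  S <- as.matrix(corr_submatrix)
  if (is.character(pair_idx)) pair_idx <- match(pair_idx, rownames(S))
  k <- nrow(S) - 2L
  om <- tryCatch(solve(S), error = function(e) {
    warning("singular correlation sub-matrix; applying diagonal ridge")
    solve(S + diag(1e-8, nrow(S)))
  })
  i <- pair_idx[1L]; j <- pair_idx[2L]
  pr <- -om[i, j] / sqrt(om[i, i] * om[j, j])
  pr <- min(max(pr, -1), 1)
  df <- n - k - 2
  p <- if (df >= 1) {
    if (abs(pr) >= 1) 0
    else 2 * stats::pt(-abs(pr * sqrt(df / (1 - pr^2))), df = df)
  } else NA_real_
  list(partial_r = pr, p = p, k = k, df = df)
}

#' Build a local partial correlation (LPC) network
#'
#' Designed for settings where variables outnumber samples, so the global
#' precision matrix cannot be estimated. Per dataset, pairs of DEG nodes
#' are screened by their Pearson correlation p-value (\code{p_lpc_screen});
#' for each screened pair the correlation sub-matrix over the pair plus its
#' screened-graph neighborhood — capped at \eqn{\lfloor n/2\rfloor}
#' neighbors when the neighborhood outgrows the sample count — is inverted
#' to give that dataset's partial correlation and p-value. The
#' cross-dataset funnel then applies the direction filter on the partial
#' correlation signs, Fisher combination over agreeing datasets,
#' Benjamini-Hochberg adjustment at \code{q_lpc}, and the PUC concordance
#' filter.
#'
#' @param datasets list of [ExpressionDataset-class] objects.
#' @param degs DEG table as for [buildCoexpressionNetwork()].
#' @param condition \code{"A"} or \code{"B"}.
#' @param config analysis configuration from [dcConfig()]; uses
#'   \code{p_lpc_screen}, \code{q_lpc}, \code{k_required},
#'   \code{neighbor_rank}, \code{puc}.
#' @return a [CoexpressionNetwork-class] with a \code{"pair_stats"}
#'   attribute analogous to [buildCoexpressionNetwork()] (correlations
#'   replaced by partial correlations).
#' @export
buildLPCNetwork <- function(datasets, degs, condition, config = dcConfig("cervical")) {
  nodes <- sort(degs$gene[degs$is_deg])
  dirs <- stats::setNames(degs$direction, degs$gene)
  pairs <- .genePairs(nodes)
  if (!nrow(pairs)) {
    warning("no testable pairs; returning empty network")
    return(CoexpressionNetwork(condition, nodes))
  }
  m <- length(datasets)
  prmat <- matrix(NA_real_, nrow(pairs), m)
  ppmat <- prmat; nmat <- prmat
  idx <- cbind(match(pairs$gene_i, nodes), match(pairs$gene_j, nodes))
  for (d in seq_len(m)) {
    ds <- datasets[[d]]
    keep <- sampleConditions(ds) == condition
    n <- sum(keep)
    if (n < 6L) {
      warning("dataset '", datasetId(ds), "' has fewer than 6 samples in ",
              "condition ", condition, "; skipped for LPC")
      next
    }
    X <- exprsMatrix(ds)[nodes, keep, drop = FALSE]
    st <- .pairCorrStats(X, idx)
    R <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
    screened <- which(!is.na(st$p) & st$p < config$p_lpc_screen)
    if (!length(screened)) next
    # adjacency of the screened correlation graph
    adj <- vector("list", length(nodes))
    for (kk in screened) {
      i <- idx[kk, 1L]; j <- idx[kk, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    for (kk in screened) {
      i <- idx[kk, 1L]; j <- idx[kk, 2L]
      nb <- setdiff(unique(c(adj[[i]], adj[[j]])), c(i, j))
      if (length(nb) > n) {
        key <- pmax(abs(R[nb, i]), abs(R[nb, j]))
        if (config$neighbor_rank == "mean")
          key <- (abs(R[nb, i]) + abs(R[nb, j])) / 2
        ord <- order(-key, nodes[nb])
        nb <- nb[ord][seq_len(floor(n / 2))]
      }
      sub <- R[c(i, j, nb), c(i, j, nb), drop = FALSE]
      res <- suppressWarnings(localPartialCorr(sub, c(1L, 2L), n))
      prmat[kk, d] <- res$partial_r
      ppmat[kk, d] <- res$p
      nmat[kk, d] <- n
    }
  }
  smat <- sign(prmat)
  smat[is.na(ppmat)] <- NA_real_
  fun <- .metaFunnel(ppmat, smat, config$k_required, p_within = 1)
  q <- rep(NA_real_, nrow(pairs))
  q[fun$pass] <- bhFdr(fun$combined_p[fun$pass])
  puc_ok <- if (isTRUE(config$puc))
    pucFilter(fun$consensus, dirs[pairs$gene_i], dirs[pairs$gene_j])
  else rep(TRUE, nrow(pairs))
  is_edge <- fun$pass & !is.na(q) & q < config$q_lpc & puc_ok
  edges <- data.frame(gene_i = pairs$gene_i[is_edge],
                      gene_j = pairs$gene_j[is_edge],
                      sign = fun$consensus[is_edge],
                      combined_p = fun$combined_p[is_edge],
                      q = q[is_edge], stringsAsFactors = FALSE)
  net <- CoexpressionNetwork(condition, nodes, edges)
  stats_df <- cbind(pairs,
                    data.frame(consensus = fun$consensus,
                               n_support = fun$n_support,
                               combined_p = fun$combined_p, q = q,
                               puc_pass = puc_ok, is_edge = is_edge))
  attr(stats_df, "r") <- prmat
  attr(stats_df, "p") <- ppmat
  attr(stats_df, "n") <- nmat
  attr(net, "pair_stats") <- stats_df
  net
}
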