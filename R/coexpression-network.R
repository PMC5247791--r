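#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson correlation on complete cases with the classical test
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} against a t distribution with
#' \eqn{n - 2} degrees of freedom (two-sided). Perfect correlation
#' (\eqn{|r| = 1}) returns \eqn{p = 0}. A constant vector (or fewer than 4
#' complete cases) is untestable and returns \code{NA}s rather than an
#' error.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with \code{r}, \code{p} and \code{n} (complete cases).
#' @export
pearsonWithP <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 4L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x[ok], y[ok])
  p <- .pearsonP(r, n)
  list(r = r, p = p, n = n)
}

# Two-sided p for Pearson r at complete-case count n (vectorised).
.pearsonP <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n >= 4
  exact <- ok & abs(r) >= 1
  p[exact] <- 0
  mid <- ok & !exact
  t <- r[mid] * sqrt((n[mid] - 2) / (1 - r[mid]^2))
  p[mid] <- 2 * stats::pt(-abs(t), df = n[mid] - 2)
  p
}

# Correlation, p and complete-case n for the pairs indexed by `pairs`
# (2-column integer matrix into rows of X). Pairwise complete cases.
.pairCorrStats <- function(X, pairs) {
  R <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
  obs <- !is.na(X)
  N <- tcrossprod(obs + 0)
  r <- R[pairs]
  n <- N[pairs]
  r[n < 4] <- NA_real_
  list(r = r, p = .pearsonP(r, n), n = n)
}

# All unordered pairs (i < j by lexicographic gene id) over a gene vector.
.genePairs <- function(genes) {
  genes <- sort(genes)
  if (length(genes) < 2L)
    return(data.frame(gene_i = character(), gene_j = character(),
                      stringsAsFactors = FALSE))
  idx <- utils::combn(length(genes), 2L)
  data.frame(gene_i = genes[idx[1L, ]], gene_j = genes[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' PUC sign-concordance edge filter
#'
#' Discards "unexpected" correlations: an edge passes only when the sign of
#' the correlation matches the product of the two genes' differential
#' expression directions — positive for same-direction pairs (UP/UP or
#' DN/DN), negative for opposite-direction pairs.
#'
#' @param sign_r correlation sign, \code{-1} or \code{+1} (vectorised).
#' @param dir_i,dir_j per-gene regulation, \code{"UP"} or \code{"DN"}.
#' @return logical, \code{TRUE} when the edge is concordant.
#' @export
pucFilter <- function(sign_r, dir_i, dir_j) {
  expected <- ifelse(dir_i == dir_j, 1L, -1L)
  sign_r == expected
}

#' Build one condition's co-expression network
#'
#' For every unordered pair of DEG nodes, per-dataset Pearson correlations
#' are computed from that condition's samples only; the funnel then
#' requires sign agreement in at least \code{k_required} datasets, combines
#' the agreeing datasets' correlation p-values with Fisher's method,
#' adjusts by Benjamini-Hochberg over the pairs passing the direction
#' filter, and keeps as edges the pairs with at least \code{k_required}
#' agreeing datasets individually significant at \code{p_corr}, adjusted
#' combined p below \code{q_corr}, and a PUC-concordant sign.
#'
#' @param datasets list of [ExpressionDataset-class] objects.
#' @param degs data.frame from [callDEGs()] (or any data.frame with
#'   \code{gene}, \code{direction} and \code{is_deg} columns); the network
#'   nodes are the genes with \code{is_deg = TRUE}.
#' @param condition \code{"A"} or \code{"B"}.
#' @param config analysis configuration from [dcConfig()]; uses
#'   \code{p_corr}, \code{q_corr}, \code{k_required}, \code{veto},
#'   \code{puc}.
#' @return a [CoexpressionNetwork-class]. The edge table of screened pairs
#'   (before the edge decision) is attached as attribute
#'   \code{"pair_stats"} for downstream differential-correlation analysis.
#' @export
buildCoexpressionNetwork <- function(datasets, degs, condition,
                                     config = dcConfig()) {
  nodes <- sort(degs$gene[degs$is_deg])
  dirs <- stats::setNames(degs$direction, degs$gene)
  pairs <- .genePairs(nodes)
  if (!nrow(pairs)) {
    warning("no testable pairs; returning empty network")
    return(CoexpressionNetwork(condition, nodes))
  }
  m <- length(datasets)
  rmat <- matrix(NA_real_, nrow(pairs), m)
  pmat <- rmat; nmat <- rmat
  for (d in seq_len(m)) {
    ds <- datasets[[d]]
    keep <- sampleConditions(ds) == condition
    X <- exprsMatrix(ds)[nodes, keep, drop = FALSE]
    idx <- cbind(match(pairs$gene_i, nodes), match(pairs$gene_j, nodes))
    st <- .pairCorrStats(X, idx)
    rmat[, d] <- st$r; pmat[, d] <- st$p; nmat[, d] <- st$n
  }
  smat <- sign(rmat)
  smat[is.na(pmat)] <- NA_real_
  fun <- .metaFunnel(pmat, smat, config$k_required, config$p_corr,
                     veto = config$veto, p_veto = config$p_corr)
  # sequential funnel: BH over the pairs surviving the per-dataset screen
  # and the direction filter, not over all possible pairs
  pool <- fun$pass & fun$n_support >= config$k_required
  q <- rep(NA_real_, nrow(pairs))
  q[pool] <- bhFdr(fun$combined_p[pool])
  puc_ok <- if (isTRUE(config$puc))
    pucFilter(fun$consensus, dirs[pairs$gene_i], dirs[pairs$gene_j])
  else rep(TRUE, nrow(pairs))
  is_edge <- pool & !is.na(q) & q < config$q_corr & puc_ok
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
  attr(stats_df, "r") <- rmat
  attr(stats_df, "p") <- pmat
  attr(stats_df, "n") <- nmat
  attr(net, "pair_stats") <- stats_df
  net
}
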