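#' Fisher z transform of a correlation coefficient
#'
#' \eqn{z = \mathrm{atanh}(r) = \tfrac{1}{2}\log((1+r)/(1-r))}, the
#' variance-stabilizing transform for correlation difference tests.
#'
#' @param r correlation(s) with \eqn{|r| < 1}.
#' @return the transformed value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1")
  atanh(r)
}

#' Two-sample test for a difference between correlations
#'
#' Fisher z test: \eqn{Z = (z(r_1) - z(r_2)) / \sqrt{1/(n_1-3) + 1/(n_2-3)}}
#' referred to a standard normal, two-sided.
#'
#' @param r1,r2 sample correlations with \eqn{|r| < 1}.
#' @param n1,n2 sample sizes (at least 4).
#' @return list with \code{z} (the standardised statistic, sign of
#'   \eqn{z(r_1) - z(r_2)}) and \code{p} (two-sided); \code{NA}s flag an
#'   untestable input.
#' @export
diffCorrTest <- function(r1, n1, r2, n2) {
  bad <- is.na(r1) | is.na(r2) | abs(r1) >= 1 | abs(r2) >= 1 | n1 < 4 | n2 < 4
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(-abs(z))
  z[bad] <- NA_real_
  p[bad] <- NA_real_
  list(z = z, p = p)
}

#' Detect differentially correlated pairs (DCPs) between conditions
#'
#' Candidate pairs are those whose per-dataset correlation is nominally
#' significant (\code{p_screen}) in at least \code{k_required} datasets in
#' at least one condition. For each candidate and dataset the Fisher z
#' difference test compares the condition-B against the condition-A
#' correlation; the funnel then requires sign agreement of the difference
#' in \code{k_required} datasets with per-dataset difference p below
#' \code{p_diff}, combines agreeing datasets' two-sided p-values by
#' Fisher's method, and adjusts by Benjamini-Hochberg over the candidates
#' passing the direction filter. A DCP must additionally be an edge of
#' exactly one of the two condition networks: a \emph{gain} when the edge
#' lives in the B network, a \emph{loss} when it lives in the A network;
#' pairs that are edges in both or neither network are excluded.
#'
#' @param datasets list of [ExpressionDataset-class] objects.
#' @param network_A,network_B condition networks from
#'   [buildCoexpressionNetwork()] (or [buildLPCNetwork()]), built on the
#'   same DEG universe, with their \code{"pair_stats"} attribute intact.
#' @param config analysis configuration from [dcConfig()]; uses
#'   \code{p_screen}, \code{p_diff}, \code{q_diff}, \code{k_required}.
#' @return data.frame with one row per DCP: \code{gene_i}, \code{gene_j},
#'   mean per-condition correlations \code{r_A}, \code{r_B}, the consensus
#'   difference sign, \code{combined_p}, \code{q},
#'   \code{change_direction} (\code{"gain"}/\code{"loss"}) and
#'   \code{host_network}. The full candidate table is attached as
#'   attribute \code{"candidates"}.
#' @export
callDCPs <- function(datasets, network_A, network_B, config = dcConfig()) {
  stA <- attr(network_A, "pair_stats")
  stB <- attr(network_B, "pair_stats")
  if (is.null(stA) || is.null(stB))
    stop("networks must carry their 'pair_stats' attribute")
  if (!identical(stA$gene_i, stB$gene_i) ||
      !identical(stA$gene_j, stB$gene_j))
    stop("networks must be built on the same DEG universe")
  pA <- attr(stA, "p"); pB <- attr(stB, "p")
  rA <- attr(stA, "r"); rB <- attr(stB, "r")
  nA <- attr(stA, "n"); nB <- attr(stB, "n")
  m <- ncol(pA)
  k <- config$k_required
  cand <- rowSums(!is.na(pA) & pA < config$p_screen) >= k |
    rowSums(!is.na(pB) & pB < config$p_screen) >= k
  rAc <- pmin(pmax(rA, -1 + 1e-12), 1 - 1e-12)
  rBc <- pmin(pmax(rB, -1 + 1e-12), 1 - 1e-12)
  dt <- diffCorrTest(rBc, nB, rAc, nA)
  pd <- dt$p; sd_ <- sign(dt$z)
  pd[!cand, ] <- NA_real_
  fun <- .metaFunnel(pd, sd_, k, config$p_diff)
  # BH over candidates surviving the per-dataset difference screen and
  # the direction filter (sequential funnel)
  pool <- cand & fun$pass & fun$n_support >= k
  q <- rep(NA_real_, length(cand))
  q[pool] <- bhFdr(fun$combined_p[pool])
  ekey <- function(net) paste(networkEdges(net)$gene_i,
                              networkEdges(net)$gene_j)
  key <- paste(stA$gene_i, stA$gene_j)
  inA <- key %in% ekey(network_A)
  inB <- key %in% ekey(network_B)
  is_dcp <- pool & !is.na(q) & q < config$q_diff & xor(inA, inB)
  out <- data.frame(gene_i = stA$gene_i[is_dcp],
                    gene_j = stA$gene_j[is_dcp],
                    r_A = rowMeans(rA, na.rm = TRUE)[is_dcp],
                    r_B = rowMeans(rB, na.rm = TRUE)[is_dcp],
                    diff_sign = fun$consensus[is_dcp],
                    combined_p = fun$combined_p[is_dcp],
                    q = q[is_dcp],
                    change_direction = ifelse(inB[is_dcp], "gain", "loss"),
                    host_network = ifelse(inB[is_dcp], "B", "A"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  cand_df <- data.frame(gene_i = stA$gene_i, gene_j = stA$gene_j,
                        candidate = cand, dir_pass = fun$pass,
                        n_support = fun$n_support,
                        combined_p = fun$combined_p, q = q,
                        edge_A = inA, edge_B = inB, is_dcp = is_dcp,
                        stringsAsFactors = FALSE)
  attr(out, "candidates") <- cand_df
  out
}

#' Genes participating in at least one DCP
#'
#' @param dcps data.frame from [callDCPs()].
#' @param direction optionally restrict to \code{"gain"} or \code{"loss"}
#'   pairs.
#' @return character vector of DC gene identifiers.
#' @export
dcGenes <- function(dcps, direction = NULL) {
  if (!is.null(direction))
    dcps <- dcps[dcps$change_direction == direction, , drop = FALSE]
  sort(unique(c(dcps$gene_i, dcps$gene_j)))
}
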