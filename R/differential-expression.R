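# Vectorised one-sample t on the rows of a matrix of paired differences.
# Zero-variance rows are degenerate: p = 0 when the mean difference is
# nonzero (the evidence is unbounded), p = 1 at mean 0.
.rowPairedT <- function(d) {
  n <- rowSums(!is.na(d))
  mu <- rowMeans(d, na.rm = TRUE)
  v <- rowSums((d - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
  t <- mu / sqrt(v / n)
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  zerovar <- v == 0 & n >= 2
  p[zerovar & mu != 0] <- 0
  t[zerovar & mu != 0] <- Inf * sign(mu[zerovar & mu != 0])
  p[zerovar & mu == 0] <- 1
  t[zerovar & mu == 0] <- 0
  p[n < 2] <- NA_real_
  t[n < 2] <- NA_real_
  list(t = t, p = p, sign = sign(mu), n = n)
}

# Vectorised Welch two-sample t (B - A) on rows of two matrices.
.rowWelchT <- function(a, b) {
  na <- rowSums(!is.na(a)); nb <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  va <- rowSums((a - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((b - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * stats::pt(-abs(t), df = df)
  zerovar <- se2 == 0 & na >= 2 & nb >= 2
  p[zerovar & mb != ma] <- 0
  t[zerovar & mb != ma] <- Inf * sign(mb[zerovar & mb != ma] - ma[zerovar & mb != ma])
  p[zerovar & mb == ma] <- 1
  t[zerovar & mb == ma] <- 0
  bad <- na < 2 | nb < 2
  p[bad] <- NA_real_; t[bad] <- NA_real_
  list(t = t, p = p, sign = sign(mb - ma), n = na + nb)
}

# Per-dataset differential expression for all genes; paired t when a
# pairing is present, Welch t otherwise.
.deTestDataset <- function(ds) {
  m <- exprsMatrix(ds)
  cond <- sampleConditions(ds)
  pr <- samplePairing(ds)
  if (!is.null(pr) && any(!is.na(pr))) {
    pa <- pr[cond == "A"]; pb <- pr[cond == "B"]
    common <- intersect(pa[!is.na(pa)], pb[!is.na(pb)])
    sa <- names(pa)[match(common, pa)]
    sb <- names(pb)[match(common, pb)]
    .rowPairedT(m[, sb, drop = FALSE] - m[, sa, drop = FALSE])
  } else {
    .rowWelchT(m[, cond == "A", drop = FALSE], m[, cond == "B", drop = FALSE])
  }
}

#' Paired t-test for a single gene
#'
#' Classical paired t-test on per-pair differences (condition B minus
#' condition A). Zero-variance differences are degenerate and return
#' \eqn{p = 0} when the mean difference is nonzero.
#'
#' @param ds an [ExpressionDataset-class] with a pairing.
#' @param gene gene identifier.
#' @return list with \code{t}, \code{p} (two-sided), \code{sign} (sign of
#'   the mean paired difference) and \code{n} (complete pairs);
#'   \code{p = NA} flags an untestable gene (fewer than 2 complete pairs).
#' @export
pairedT <- function(ds, gene) {
  pr <- samplePairing(ds)
  if (is.null(pr) || all(is.na(pr))) stop("dataset has no pairing")
  cond <- sampleConditions(ds)
  pa <- pr[cond == "A"]; pb <- pr[cond == "B"]
  common <- intersect(pa[!is.na(pa)], pb[!is.na(pb)])
  sa <- names(pa)[match(common, pa)]
  sb <- names(pb)[match(common, pb)]
  m <- exprsMatrix(ds)
  d <- m[gene, sb] - m[gene, sa]
  res <- .rowPairedT(matrix(d, nrow = 1L))
  lapply(res, function(v) unname(v[1L]))
}

#' Welch two-sample t-test for a single gene
#'
#' @param ds an [ExpressionDataset-class].
#' @param gene gene identifier.
#' @return list with \code{t}, \code{p} (two-sided), \code{sign} (sign of
#'   mean(B) - mean(A)) and \code{n}; \code{p = NA} flags an untestable
#'   gene (a condition with fewer than 2 complete samples).
#' @export
unpairedT <- function(ds, gene) {
  cond <- sampleConditions(ds)
  m <- exprsMatrix(ds)
  res <- .rowWelchT(m[gene, cond == "A", drop = FALSE],
                    m[gene, cond == "B", drop = FALSE])
  lapply(res, function(v) unname(v[1L]))
}

#' Call differentially expressed genes by meta-analysis
#'
#' Per gene and dataset, a paired t-test (when the dataset carries a
#' pairing) or Welch t-test compares condition B against condition A. The
#' cross-dataset funnel then requires direction consistency in at least
#' \code{k_required} datasets, combines the agreeing datasets' two-sided
#' p-values with Fisher's method, and adjusts the combined p-values by
#' Benjamini-Hochberg over all genes passing the direction filter. A gene
#' is a DEG when at least \code{k_required} agreeing datasets are
#' individually significant at \code{p_deg} and the adjusted combined
#' p-value is below \code{q_deg}.
#'
#' @param datasets list of [ExpressionDataset-class] objects sharing a gene
#'   universe.
#' @param config analysis configuration from [dcConfig()]; uses
#'   \code{p_deg}, \code{q_deg}, \code{k_required}, \code{veto}.
#' @return data.frame with one row per gene: per-dataset p-values and signs
#'   (columns \code{p.<id>}, \code{sign.<id>}), \code{n_agree},
#'   \code{n_support}, \code{combined_p}, \code{q}, \code{direction}
#'   (\code{"UP"}/\code{"DN"}/\code{NA}) and \code{is_deg}. Genes
#'   untestable in too many datasets to satisfy \code{k_required} are
#'   excluded (attribute \code{"excluded"} lists them).
#' @export
callDEGs <- function(datasets, config = dcConfig()) {
  stopifnot(length(datasets) >= 1L)
  genes <- rownames(exprsMatrix(datasets[[1L]]))
  m <- length(datasets)
  p <- matrix(NA_real_, length(genes), m, dimnames = list(genes, NULL))
  s <- p
  ids <- vapply(datasets, datasetId, character(1L))
  for (d in seq_len(m)) {
    if (!identical(rownames(exprsMatrix(datasets[[d]])), genes))
      stop("datasets must share a common gene universe")
    res <- .deTestDataset(datasets[[d]])
    p[, d] <- res$p
    s[, d] <- res$sign
    s[is.na(res$p), d] <- NA_real_
  }
  testable <- rowSums(!is.na(p)) >= config$k_required
  fun <- .metaFunnel(p[testable, , drop = FALSE], s[testable, , drop = FALSE],
                     config$k_required, config$p_deg,
                     veto = config$veto, p_veto = config$p_deg)
  # BH over the genes surviving the per-dataset screen and direction filter
  pool <- fun$pass & fun$n_support >= config$k_required
  q <- rep(NA_real_, sum(testable))
  q[pool] <- bhFdr(fun$combined_p[pool])
  out <- data.frame(gene = genes[testable], stringsAsFactors = FALSE)
  for (d in seq_len(m)) {
    out[[paste0("p.", ids[d])]] <- p[testable, d]
    out[[paste0("sign.", ids[d])]] <- s[testable, d]
  }
  out$n_agree <- fun$n_agree
  out$n_support <- fun$n_support
  out$combined_p <- fun$combined_p
  out$q <- q
  out$direction <- ifelse(fun$consensus > 0, "UP",
                          ifelse(fun$consensus < 0, "DN", NA))
  out$is_deg <- pool & !is.na(q) & q < config$q_deg
  rownames(out) <- NULL
  attr(out, "excluded") <- genes[!testable]
  out
}
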