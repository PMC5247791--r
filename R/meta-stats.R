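#' Fisher combined probability test
#'
#' Combines independent p-values with Fisher's method: the statistic
#' \eqn{X = -2 \sum_i \log p_i} is referred to a chi-square distribution with
#' \eqn{2m} degrees of freedom and the upper-tail probability is returned.
#' With a single p-value the combination is the identity.
#'
#' @param pvalues numeric vector of p-values, each in (0, 1].
#' @return the combined p-value in (0, 1].
#' @examples
#' fisherCombine(0.2)            # 0.2
#' fisherCombine(c(0.05, 0.05))  # ~0.0175
#' @export
fisherCombine <- function(pvalues) {
  if (length(pvalues) == 0L) stop("need at least one p-value")
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  x <- -2 * sum(log(pvalues))
  stats::pchisq(x, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment
#' (\eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j}, capped at 1),
#' order-preserving with the input.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return numeric vector of adjusted values (q-values) in input order.
#' @export
bhFdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Cross-dataset direction-consistency filter
#'
#' A gene (or gene pair) passes when some direction \eqn{s \in \{-1, +1\}}
#' is observed in at least \code{k_required} datasets. Datasets with sign 0
#' count toward neither direction. If both directions reach
#' \code{k_required} with equal support the unit fails (no consensus);
#' with unequal support the better-supported direction wins. Optionally, a
#' dataset carrying the opposite sign vetoes the unit when its own
#' per-dataset p-value is nominally significant (off by default: the
#' funnel's published form requires only k-of-m agreement).
#'
#' @param signs integer vector of per-dataset signs in \{-1, 0, +1\}.
#' @param k_required minimum number of datasets that must agree.
#' @param veto logical; enable the opposite-sign significance veto.
#' @param pvalues per-dataset p-values (needed when \code{veto = TRUE}).
#' @param p_veto significance threshold for the veto.
#' @return list with elements \code{pass} (logical) and \code{consensus}
#'   (the consensus sign, 0 when the filter fails).
#' @export
directionFilter <- function(signs, k_required, veto = FALSE,
                            pvalues = NULL, p_veto = 0.05) {
  m <- length(signs)
  if (k_required < 1L || k_required > m)
    stop("k_required must be between 1 and the number of datasets")
  n_pos <- sum(signs > 0, na.rm = TRUE)
  n_neg <- sum(signs < 0, na.rm = TRUE)
  cons <- 0L
  if (n_pos >= k_required && n_pos > n_neg) cons <- 1L
  if (n_neg >= k_required && n_neg > n_pos) cons <- -1L
  if (cons != 0L && veto) {
    if (is.null(pvalues)) stop("veto requires per-dataset p-values")
    opp <- !is.na(signs) & signs == -cons & !is.na(pvalues) & pvalues < p_veto
    if (any(opp)) cons <- 0L
  }
  list(pass = cons != 0L, consensus = cons)
}

# Vectorised meta-analysis funnel used by the DEG, network and DCP stages.
# p, s: units x datasets matrices of per-dataset p-values and signs (NA =
# untestable in that dataset). Returns, per unit: the direction-filter
# verdict, the consensus sign, the number of datasets supporting the
# consensus at the nominal per-dataset threshold, and the Fisher combined
# p over the agreeing datasets.
.metaFunnel <- function(p, s, k_required, p_within,
                        veto = FALSE, p_veto = p_within) {
  stopifnot(identical(dim(p), dim(s)))
  n <- nrow(p)
  n_pos <- rowSums(s > 0, na.rm = TRUE)
  n_neg <- rowSums(s < 0, na.rm = TRUE)
  cons <- integer(n)
  cons[n_pos >= k_required & n_pos > n_neg] <- 1L
  cons[n_neg >= k_required & n_neg > n_pos] <- -1L
  if (veto) {
    oppsig <- (s == -cons) & !is.na(s) & (p < p_veto) & !is.na(p)
    cons[cons != 0L & rowSums(oppsig, na.rm = TRUE) > 0] <- 0L
  }
  agree <- (s == cons) & (cons != 0L) & !is.na(s)
  support <- rowSums(agree & !is.na(p) & p < p_within)
  lp <- log(p)
  lp[!agree | is.na(p)] <- 0
  x <- -2 * rowSums(lp)
  df <- 2 * rowSums(agree)
  combined <- rep(NA_real_, n)
  ok <- cons != 0L & df > 0
  combined[ok] <- stats::pchisq(x[ok], df = df[ok], lower.tail = FALSE)
  list(pass = cons != 0L, consensus = cons, n_agree = rowSums(agree),
       n_support = support, combined_p = combined)
}
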