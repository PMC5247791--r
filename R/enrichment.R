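#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric tail for the one-sided alternatives; for the
#' two-sided alternative, the sum of all tables with probability no larger
#' than the observed one. A table with a zero margin is uninformative and
#' returns \eqn{p = 1}.
#'
#' @param a,b,c,d nonnegative integer cell counts: \code{a} = causal in
#'   group, \code{b} = non-causal in group, \code{c} = causal in
#'   background, \code{d} = non-causal in background.
#' @param alternative \code{"greater"}, \code{"less"} or
#'   \code{"two.sided"}.
#' @return the exact p-value.
#' @examples
#' fisherExact2x2(15, 48, 11, 404, "greater")  # < 0.001
#' @export
fisherExact2x2 <- function(a, b, c, d,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(1)
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2L),
                     alternative = alternative)$p.value
}

#' Enrichment of a causal gene set within a gene group
#'
#' Builds the 2x2 table crossing membership in \code{group} versus the
#' rest of the background with membership in \code{causal}, and tests
#' over-representation of causal genes in the group (one-sided Fisher
#' exact by default). The odds ratio uses the Haldane 0.5 correction when
#' a zero cell occurs.
#'
#' @param group gene set of interest (e.g. DC genes of one change
#'   direction).
#' @param causal causal / key-driver gene set.
#' @param background reference gene universe (e.g. all DEGs); group
#'   members are removed from the background side of the table.
#' @param alternative passed to [fisherExact2x2()].
#' @return list with \code{table} (named counts \code{a}, \code{b},
#'   \code{c}, \code{d}), \code{odds_ratio} and \code{p}.
#' @export
enrichmentOfSet <- function(group, causal, background,
                            alternative = "greater") {
  group <- unique(group)
  rest <- setdiff(unique(background), group)
  a <- sum(group %in% causal)
  b <- length(group) - a
  c <- sum(rest %in% causal)
  d <- length(rest) - c
  if (length(group) == 0L)
    return(list(table = c(a = 0L, b = 0L, c = c, d = d),
                odds_ratio = NA_real_, p = 1))
  or <- if (any(c(a, b, c, d) == 0))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  else (a * d) / (b * c)
  list(table = c(a = a, b = b, c = c, d = d), odds_ratio = or,
       p = fisherExact2x2(a, b, c, d, alternative))
}

#' After/before treatment normalized cell index (A/B index)
#'
#' Normalizes a growth cell index to initial cell-number differences:
#' cell index after treatment divided by cell index before treatment.
#'
#' @param cell_index_before positive cell index at the pre-treatment
#'   reading.
#' @param cell_index_after cell index at the post-treatment reading.
#' @return the A/B index.
#' @export
abIndex <- function(cell_index_before, cell_index_after) {
  if (any(cell_index_before <= 0)) stop("cell index before must be > 0")
  cell_index_after / cell_index_before
}

#' Inhibition index of a knockdown treatment
#'
#' \eqn{(control - treatment) / control} on the A/B indices: positive
#' values indicate a decrease in proliferation after the knockdown, 0 no
#' difference from the non-targeting control, negative values a growth
#' increase.
#'
#' @param control_ab positive control A/B index.
#' @param treatment_ab treatment A/B index.
#' @return the inhibition index.
#' @export
inhibitionIndex <- function(control_ab, treatment_ab) {
  if (any(control_ab <= 0)) stop("control A/B index must be > 0")
  (control_ab - treatment_ab) / control_ab
}

#' One-sided one-sample t-test against zero
#'
#' Used on replicate-level inhibition indices: \code{"mean_gt_0"} tests
#' for growth inhibition (expected for an oncogene knockdown),
#' \code{"mean_lt_0"} for growth increase (expected for a tumor-suppressor
#' knockdown). Zero variance is degenerate: \eqn{p = 0} when the mean lies
#' strictly on the alternative side, otherwise \eqn{p = 1}.
#'
#' @param values numeric replicate values (length at least 2).
#' @param alternative \code{"mean_gt_0"} or \code{"mean_lt_0"}.
#' @return the one-sided p-value.
#' @export
oneSidedT <- function(values, alternative = c("mean_gt_0", "mean_lt_0")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) >= 2)
  side <- if (alternative == "mean_gt_0") "greater" else "less"
  if (stats::sd(values) == 0) {
    mu <- mean(values)
    onside <- (side == "greater" && mu > 0) || (side == "less" && mu < 0)
    return(if (onside) 0 else 1)
  }
  stats::t.test(values, mu = 0, alternative = side)$p.value
}

#' Knockdown growth analysis from replicate cell-index readings
#'
#' Computes per-replicate A/B indices, normalizes each treatment replicate
#' to its experiment's non-targeting control, and applies the one-sided t
#' test in the direction implied by the gene's expected role.
#'
#' @param readings data.frame with columns \code{experiment},
#'   \code{treatment} (\code{"control"} or a target name), \code{before}
#'   and \code{after} (cell indices).
#' @param target the treatment to evaluate.
#' @param direction \code{"oncogene_expected"} (knockdown should inhibit
#'   growth, tests mean inhibition > 0) or \code{"suppressor_expected"}
#'   (tests mean inhibition < 0).
#' @return list with \code{inhibition_index} (per replicate/experiment)
#'   and \code{p}.
#' @export
knockdownTest <- function(readings, target,
                          direction = c("oncogene_expected",
                                        "suppressor_expected")) {
  direction <- match.arg(direction)
  stopifnot(all(c("experiment", "treatment", "before", "after") %in%
                colnames(readings)))
  ii <- numeric()
  for (ex in unique(readings$experiment)) {
    sub <- readings[readings$experiment == ex, , drop = FALSE]
    ctrl <- sub[sub$treatment == "control", , drop = FALSE]
    trt <- sub[sub$treatment == target, , drop = FALSE]
    if (!nrow(ctrl) || !nrow(trt)) next
    ctrl_ab <- mean(abIndex(ctrl$before, ctrl$after))
    ii <- c(ii, inhibitionIndex(ctrl_ab, abIndex(trt$before, trt$after)))
  }
  if (length(ii) < 2) stop("need at least 2 replicates with a control")
  alt <- if (direction == "oncogene_expected") "mean_gt_0" else "mean_lt_0"
  list(inhibition_index = ii, p = oneSidedT(ii, alt))
}
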