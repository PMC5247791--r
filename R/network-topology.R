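#' Minimum shortest path from a gene to a set of key drivers
#'
#' Unweighted shortest-path distance from the gene to each key driver,
#' minimised over the reachable drivers; 0 when the gene is itself a
#' driver, \code{NA} when no driver is reachable.
#'
#' @param network a [CoexpressionNetwork-class] or \pkg{igraph} graph.
#' @param gene gene identifier (vectorised).
#' @param drivers nonempty character vector of key-driver genes present in
#'   the network.
#' @return integer distance(s), \code{NA} when unreachable.
#' @export
minShortestPathToSet <- function(network, gene, drivers) {
  g <- if (inherits(network, "CoexpressionNetwork")) asIgraph(network)
       else network
  drivers <- intersect(drivers, igraph::V(g)$name)
  if (!length(drivers)) stop("no driver is present in the network")
  if (!all(gene %in% igraph::V(g)$name))
    stop("gene not in network: ", paste(setdiff(gene, igraph::V(g)$name),
                                        collapse = ", "))
  d <- igraph::distances(g, v = gene, to = drivers)
  out <- apply(d, 1L, min)
  out[!is.finite(out)] <- NA_real_
  as.integer(out)
}

# Breadth-first search with shortest-path counting from one root.
# Returns integer distances (NA if unreachable) and path counts sigma.
.bfsSigma <- function(adj, root, nv) {
  dist <- rep(NA_integer_, nv)
  sigma <- numeric(nv)
  dist[root] <- 0L
  sigma[root] <- 1
  frontier <- root
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1L)
          sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

#' Bipartite betweenness centrality
#'
#' Shortest-path betweenness restricted to ordered source-target pairs
#' \eqn{(s, t)} with \eqn{s} in \code{sources}, \eqn{t} in \code{targets},
#' \eqn{s \ne t}: every interior vertex \eqn{v} of the \eqn{s}-\eqn{t}
#' shortest paths accumulates \eqn{\sigma_{st}(v)/\sigma_{st}} (the
#' fraction of shortest paths through it); endpoints receive no credit and
#' unreachable pairs contribute 0. In the intended use the sources are the
#' key drivers and the targets the peripheral genes (degree-1 nodes), so a
#' high value marks a bottleneck through which the drivers' signal must
#' flow. \code{mode = "count"} accumulates raw shortest-path counts
#' \eqn{\sigma_{st}(v)} instead of fractions (the two coincide when
#' shortest paths are unique).
#'
#' @param network a [CoexpressionNetwork-class] or \pkg{igraph} graph.
#' @param sources,targets character vectors of gene identifiers; genes
#'   absent from the network are ignored.
#' @param mode \code{"fractional"} (default) or \code{"count"}.
#' @return named numeric vector over all network genes.
#' @export
bipartiteBetweenness <- function(network, sources, targets,
                                 mode = c("fractional", "count")) {
  mode <- match.arg(mode)
  g <- if (inherits(network, "CoexpressionNetwork")) asIgraph(network)
       else network
  nms <- igraph::V(g)$name
  nv <- length(nms)
  bbc <- stats::setNames(numeric(nv), nms)
  src <- match(intersect(sources, nms), nms)
  tgt <- match(intersect(targets, nms), nms)
  if (!length(src) || !length(tgt)) {
    warning("empty source or target set; returning zeros")
    return(bbc)
  }
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  bs <- lapply(unique(c(src, tgt)), .bfsSigma, adj = adj, nv = nv)
  names(bs) <- as.character(unique(c(src, tgt)))
  for (s in src) {
    fs <- bs[[as.character(s)]]
    for (t in tgt) {
      if (t == s || is.na(fs$dist[t])) next
      ft <- bs[[as.character(t)]]
      dst <- fs$dist[t]
      interior <- which(!is.na(fs$dist) & !is.na(ft$dist) &
                        fs$dist + ft$dist == dst)
      interior <- setdiff(interior, c(s, t))
      if (!length(interior)) next
      through <- fs$sigma[interior] * ft$sigma[interior]
      contrib <- if (mode == "fractional") through / fs$sigma[t] else through
      bbc[interior] <- bbc[interior] + contrib
    }
  }
  bbc
}

#' Degree-1 (peripheral) genes of a network
#'
#' @param network a [CoexpressionNetwork-class].
#' @return character vector of genes with network degree exactly 1.
#' @export
peripheralGenes <- function(network) {
  e <- networkEdges(network)
  if (!nrow(e)) return(character())
  tab <- table(c(e$gene_i, e$gene_j))
  sort(names(tab)[tab == 1L])
}

#' Mann-Whitney rank-sum test
#'
#' Mann-Whitney U with the normal approximation and tie correction; when
#' every value is tied across both groups the test is degenerate and
#' returns \eqn{p = 1}.
#'
#' @param x,y numeric vectors (both nonempty).
#' @return list with \code{U} and the two-sided \code{p}.
#' @export
rankSumTest <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  list(U = unname(wt$statistic), p = p)
}

#' Permutation test for a difference of group means
#'
#' Observed statistic: \code{mean(values[dc]) - mean(values[other])}. The
#' group labels are shuffled uniformly \code{n_perm} times and the
#' two-sided p-value is \eqn{(1 + \#\{|stat^\pi| \ge |stat|\}) /
#' (n_{perm} + 1)}. Seeded and reproducible.
#'
#' @param values named numeric vector (one value per gene).
#' @param group_labels character vector (same length/names) with labels
#'   \code{"dc"} and \code{"other"}.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return the permutation p-value.
#' @export
permutationTestMeanDiff <- function(values, group_labels, n_perm = 10000,
                                    seed = 1L) {
  stopifnot(length(values) == length(group_labels), n_perm >= 1)
  is_dc <- group_labels == "dc"
  if (!any(is_dc) || all(is_dc)) stop("both groups must be nonempty")
  obs <- mean(values[is_dc]) - mean(values[!is_dc])
  n1 <- sum(is_dc)
  hits <- 0L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(values), n1)
    stat <- mean(values[idx]) - mean(values[-idx])
    if (abs(stat) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Topology annotation of a network relative to key drivers
#'
#' Computes, for every network gene, the minimum shortest path to the key
#' drivers and the bipartite betweenness centrality between key drivers
#' and peripheral genes, plus the group-comparison statistics between DC
#' genes and the remaining eligible genes (non-driver, non-peripheral):
#' rank-sum tests on both measures and a permutation test on the mean
#' bipartite betweenness difference.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param drivers key-driver gene identifiers.
#' @param dc_genes DC gene identifiers (from [dcGenes()]).
#' @param n_perm permutations for the permutation test.
#' @param seed seed for the permutation test.
#' @param bbc_mode passed to [bipartiteBetweenness()].
#' @return list with \code{table} (per-gene data.frame: \code{gene},
#'   \code{is_key_driver}, \code{is_peripheral}, \code{is_dc}, \code{msp},
#'   \code{bbc}) and \code{stats} (data.frame of test results; genes with
#'   undefined msp are dropped from the msp comparison, with counts
#'   recorded).
#' @export
topologyAnnotation <- function(network, drivers, dc_genes, n_perm = 10000,
                               seed = 1L, bbc_mode = "fractional") {
  nodes <- networkNodes(network)
  periph <- peripheralGenes(network)
  msp <- minShortestPathToSet(network, nodes, drivers)
  bbc <- bipartiteBetweenness(network, sources = drivers, targets = periph,
                              mode = bbc_mode)
  tab <- data.frame(gene = nodes,
                    is_key_driver = nodes %in% drivers,
                    is_peripheral = nodes %in% periph,
                    is_dc = nodes %in% dc_genes,
                    msp = msp, bbc = unname(bbc[nodes]),
                    stringsAsFactors = FALSE)
  eligible <- !tab$is_key_driver & !tab$is_peripheral
  dc <- eligible & tab$is_dc
  other <- eligible & !tab$is_dc
  stats <- data.frame(measure = character(), test = character(),
                      statistic = numeric(), p = numeric(),
                      n_dc = integer(), n_other = integer(),
                      stringsAsFactors = FALSE)
  msp_ok <- !is.na(tab$msp)
  if (any(dc & msp_ok) && any(other & msp_ok)) {
    rs <- rankSumTest(tab$msp[dc & msp_ok], tab$msp[other & msp_ok])
    stats <- rbind(stats, data.frame(measure = "msp", test = "rank_sum",
                                     statistic = rs$U, p = rs$p,
                                     n_dc = sum(dc & msp_ok),
                                     n_other = sum(other & msp_ok)))
  }
  if (any(dc) && any(other)) {
    rs <- rankSumTest(tab$bbc[dc], tab$bbc[other])
    stats <- rbind(stats, data.frame(measure = "bbc", test = "rank_sum",
                                     statistic = rs$U, p = rs$p,
                                     n_dc = sum(dc), n_other = sum(other)))
    vals <- tab$bbc[eligible]
    names(vals) <- tab$gene[eligible]
    labs <- ifelse(tab$is_dc[eligible], "dc", "other")
    pp <- permutationTestMeanDiff(vals, labs, n_perm = n_perm, seed = seed)
    stats <- rbind(stats, data.frame(measure = "bbc", test = "permutation",
                                     statistic = NA_real_, p = pp,
                                     n_dc = sum(dc), n_other = sum(other)))
  }
  list(table = tab, stats = stats,
       n_msp_undefined = sum(!msp_ok))
}
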