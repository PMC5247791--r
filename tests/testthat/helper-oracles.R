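# Independent oracles used to cross-check the package's statistics.

# Upper tail of a chi-square with 2m df (Erlang closed form):
# S(x) = exp(-x/2) * sum_{k=0}^{m-1} (x/2)^k / k!
chisqUpperOracle <- function(x, m) {
  h <- x / 2
  exp(-h) * sum(h^seq(0, m - 1) / factorial(seq(0, m - 1)))
}

# Brute-force Benjamini-Hochberg step-up from the definition.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n))
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# Textbook Welch two-sample t coded independently of the package internals.
welchOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# First-order partial correlation, closed form.
partialCorrOracle <- function(r_ij, r_ik, r_jk) {
  (r_ij - r_ik * r_jk) / sqrt((1 - r_ik^2) * (1 - r_jk^2))
}

# --- exhaustive shortest-path machinery on an edge list -------------------

# adjacency list (by integer vertex) from a 2-column edge matrix over 1..nv
adjFromEdges <- function(edges, nv) {
  adj <- vector("list", nv)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

bfsDistOracle <- function(adj, root) {
  nv <- length(adj)
  d <- rep(NA_integer_, nv)
  d[root] <- 0L
  q <- root
  while (length(q)) {
    v <- q[1L]; q <- q[-1L]
    for (w in adj[[v]]) if (is.na(d[w])) {
      d[w] <- d[v] + 1L
      q <- c(q, w)
    }
  }
  d
}

# Enumerate every shortest s-t path by recursive backtracking on BFS levels.
enumShortestPaths <- function(adj, s, t) {
  d <- bfsDistOracle(adj, s)
  if (is.na(d[t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (w in adj[[v]])
      if (!is.na(d[w]) && d[w] == d[v] + 1L && d[w] <= d[t])
        walk(w, c(acc, w))
  }
  walk(s, s)
  Filter(function(p) p[length(p)] == t && length(p) == d[t] + 1L, paths)
}

# Bipartite betweenness by full path enumeration (fractional counting,
# endpoints excluded), ordered (s, t) pairs.
bbcOracle <- function(edges, nv, sources, targets) {
  adj <- adjFromEdges(edges, nv)
  bbc <- numeric(nv)
  for (s in sources) for (t in targets) {
    if (s == t) next
    paths <- enumShortestPaths(adj, s, t)
    if (!length(paths)) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      bbc[interior] <- bbc[interior] + 1 / length(paths)
    }
  }
  bbc
}

# random connected graph on nv vertices (spanning tree + extra edges)
randomConnectedGraph <- function(nv, p_extra = 0.3) {
  edges <- cbind(2:nv, vapply(2:nv, function(i) sample.int(i - 1L, 1L), 1L))
  extra <- t(combn(nv, 2L))
  extra <- extra[runif(nrow(extra)) < p_extra, , drop = FALSE]
  unique(rbind(edges[, c(2, 1), drop = FALSE],
               extra[extra[, 1] < extra[, 2], , drop = FALSE]))
}

# random symmetric positive-definite correlation matrix
randomCorr <- function(k) {
  A <- matrix(rnorm(k * (k + 2)), k)
  S <- tcrossprod(A) / (k + 2)
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}
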