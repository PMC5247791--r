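# Small in-code fixtures shared across test files.

# gene x sample matrix with named dims
toyMatrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# unpaired two-condition dataset from a correlation matrix (one condition
# may reuse a different matrix); genes are the rownames of corrA
corrDataset <- function(corrA, corrB, n, id = "d1", genes = NULL) {
  k <- nrow(corrA)
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(k))
  XA <- t(chol(corrA)) %*% matrix(rnorm(k * n), k, n)
  XB <- t(chol(corrB)) %*% matrix(rnorm(k * n), k, n)
  X <- cbind(XA, XB)
  dimnames(X) <- list(genes, sprintf("s%03d", seq_len(2 * n)))
  ExpressionDataset(X, condition = rep(c("A", "B"), each = n),
                    datasetId = id)
}

# DEG table stub for network construction over a fixed gene set
degStub <- function(genes, direction = "UP") {
  data.frame(gene = genes,
             direction = rep(direction, length.out = length(genes)),
             is_deg = TRUE, stringsAsFactors = FALSE)
}

# network from an explicit edge list (sign +1, nominal p/q)
netFromEdges <- function(edges_chr, nodes = NULL, condition = "A") {
  e <- do.call(rbind, lapply(edges_chr, function(x)
    data.frame(gene_i = x[1], gene_j = x[2], sign = 1L,
               combined_p = 0.001, q = 0.001, stringsAsFactors = FALSE)))
  if (is.null(nodes)) nodes <- sort(unique(c(e$gene_i, e$gene_j)))
  CoexpressionNetwork(condition, nodes, e)
}
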