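#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' ExpressionDataset: one dataset's gene-by-sample log-expression matrix
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a single
#' two-condition expression dataset. The assay \code{"exprs"} contains
#' log-scale expression values (missing values allowed); \code{colData}
#' carries a \code{condition} column with levels \code{"A"} and \code{"B"}
#' and an optional \code{pair_id} column encoding a one-to-one pairing
#' between a subset of A-samples and B-samples (e.g. littermate pairs or
#' matched normal/tumor samples).
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [ExpressionDataset()] for the constructor,
#'   [sampleConditions()], [samplePairing()], [datasetId()].
#' @export
setClass("ExpressionDataset", contains = "SummarizedExperiment")

.validExpressionDataset <- function(object) {
  msg <- character()
  cd <- colData(object)
  if (!"condition" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'condition' column")
  else {
    cond <- as.character(cd$condition)
    if (anyNA(cond) || !all(cond %in% c("A", "B")))
      msg <- c(msg, "every sample must have condition 'A' or 'B'")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate gene identifier: %s",
                          rownames(object)[duplicated(rownames(object))][1L]))
  if ("pair_id" %in% colnames(cd) && "condition" %in% colnames(cd)) {
    pid <- cd$pair_id
    cond <- as.character(cd$condition)
    used <- !is.na(pid)
    if (any(used)) {
      pa <- pid[used & cond == "A"]
      pb <- pid[used & cond == "B"]
      if (anyDuplicated(pa) || anyDuplicated(pb) ||
          !setequal(pa, pb))
        msg <- c(msg, "pair_id must define a one-to-one A<->B pairing")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ExpressionDataset", .validExpressionDataset)

#' Construct an ExpressionDataset
#'
#' @param values numeric gene-by-sample matrix of log-scale expression with
#'   gene identifiers as rownames and sample identifiers as colnames.
#'   Missing values are allowed and are propagated (pairwise statistics use
#'   complete cases for each pair).
#' @param condition character (or factor) vector of length \code{ncol(values)}
#'   with entries \code{"A"} or \code{"B"}, named by sample or in column
#'   order.
#' @param pairing optional vector of pair identifiers (length
#'   \code{ncol(values)}, \code{NA} for unpaired samples); each pair id must
#'   occur exactly once in condition A and once in condition B.
#' @param datasetId character scalar identifying the dataset.
#' @return an [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- ExpressionDataset(m, condition = c("A", "A", "B", "B"))
#' @export
ExpressionDataset <- function(values, condition, pairing = NULL,
                              datasetId = "dataset1") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (!is.null(names(condition)))
    condition <- condition[colnames(values)]
  if (length(condition) != ncol(values))
    stop("'condition' must cover every sample")
  cd <- DataFrame(condition = as.character(condition),
                  row.names = colnames(values))
  if (!is.null(pairing)) {
    if (!is.null(names(pairing))) pairing <- pairing[colnames(values)]
    cd$pair_id <- pairing
  }
  se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
  metadata(se)$datasetId <- datasetId
  new("ExpressionDataset", se)
}

#' Accessors for ExpressionDataset
#'
#' \code{exprsMatrix} returns the log-expression matrix, \code{sampleConditions}
#' the named condition vector, \code{samplePairing} the named pair-id vector
#' (or \code{NULL} for unpaired designs), and \code{datasetId} the dataset
#' identifier.
#'
#' @param x an [ExpressionDataset-class].
#' @return see description.
#' @rdname ExpressionDataset-accessors
#' @export
exprsMatrix <- function(x) assay(x, "exprs")

#' @rdname ExpressionDataset-accessors
#' @export
sampleConditions <- function(x) {
  stats::setNames(as.character(colData(x)$condition), colnames(x))
}

#' @rdname ExpressionDataset-accessors
#' @export
samplePairing <- function(x) {
  cd <- colData(x)
  if (!"pair_id" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$pair_id, colnames(x))
}

#' @rdname ExpressionDataset-accessors
#' @export
datasetId <- function(x) metadata(x)$datasetId

setMethod("show", "ExpressionDataset", function(object) {
  cond <- table(sampleConditions(object))
  cat("ExpressionDataset '", datasetId(object), "': ",
      nrow(object), " genes x ", ncol(object), " samples (A: ",
      cond[["A"]], ", B: ", cond[["B"]], ")",
      if (!is.null(samplePairing(object))) ", paired" else "",
      "\n", sep = "")
})

#' CoexpressionNetwork: an undirected co-expression network for one condition
#'
#' Simple undirected graph over differentially expressed genes for a single
#' condition. Edges carry the consensus correlation sign, the Fisher
#' combined p-value, and the BH-adjusted q-value.
#'
#' @slot condition character, \code{"A"} or \code{"B"}.
#' @slot nodes character vector of gene identifiers (the DEG node set; may
#'   include isolated nodes).
#' @slot edges data.frame with columns \code{gene_i}, \code{gene_j}
#'   (with \code{gene_i < gene_j} lexicographically), \code{sign}
#'   (\code{-1} or \code{+1}), \code{combined_p}, \code{q}.
#' @seealso [CoexpressionNetwork()], [networkNodes()], [networkEdges()],
#'   [asIgraph()].
#' @export
setClass("CoexpressionNetwork",
         representation(condition = "character",
                        nodes = "character",
                        edges = "data.frame"))

.validCoexpressionNetwork <- function(object) {
  msg <- character()
  if (length(object@condition) != 1L ||
      !object@condition %in% c("A", "B"))
    msg <- c(msg, "condition must be 'A' or 'B'")
  e <- object@edges
  need <- c("gene_i", "gene_j", "sign", "combined_p", "q")
  if (!all(need %in% colnames(e)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  else if (nrow(e)) {
    if (!all(c(e$gene_i, e$gene_j) %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a node")
    if (any(e$gene_i >= e$gene_j))
      msg <- c(msg, "edges must satisfy gene_i < gene_j (no self pairs)")
    if (anyDuplicated(paste(e$gene_i, e$gene_j)))
      msg <- c(msg, "multi-edges are not allowed")
    if (!all(e$sign %in% c(-1, 1)))
      msg <- c(msg, "edge sign must be -1 or +1")
  }
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "duplicate node identifiers")
  if (length(msg)) msg else TRUE
}
setValidity("CoexpressionNetwork", .validCoexpressionNetwork)

#' Construct a CoexpressionNetwork
#'
#' @param condition \code{"A"} or \code{"B"}.
#' @param nodes character vector of gene identifiers.
#' @param edges data.frame with columns \code{gene_i}, \code{gene_j},
#'   \code{sign}, \code{combined_p}, \code{q}; pairs are canonicalised so
#'   that \code{gene_i < gene_j}.
#' @return a [CoexpressionNetwork-class] object.
#' @export
CoexpressionNetwork <- function(condition, nodes, edges = NULL) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(gene_i = character(), gene_j = character(),
                        sign = integer(), combined_p = numeric(),
                        q = numeric(), stringsAsFactors = FALSE)
  } else {
    swap <- edges$gene_i > edges$gene_j
    if (any(swap)) {
      tmp <- edges$gene_i[swap]
      edges$gene_i[swap] <- edges$gene_j[swap]
      edges$gene_j[swap] <- tmp
    }
    edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("CoexpressionNetwork", condition = condition,
      nodes = as.character(nodes), edges = edges)
}

#' Accessors for CoexpressionNetwork
#'
#' @param x a [CoexpressionNetwork-class].
#' @return \code{networkCondition}: the condition label;
#'   \code{networkNodes}: the node identifiers; \code{networkEdges}: the
#'   edge data.frame; \code{asIgraph}: the network as an undirected
#'   \pkg{igraph} graph (isolated nodes retained).
#' @rdname CoexpressionNetwork-accessors
#' @export
networkCondition <- function(x) x@condition

#' @rdname CoexpressionNetwork-accessors
#' @export
networkNodes <- function(x) x@nodes

#' @rdname CoexpressionNetwork-accessors
#' @export
networkEdges <- function(x) x@edges

#' @rdname CoexpressionNetwork-accessors
#' @export
asIgraph <- function(x) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x@nodes), name = x@nodes)
  if (nrow(x@edges))
    g <- igraph::add_edges(g, rbind(x@edges$gene_i, x@edges$gene_j),
                           sign = x@edges$sign)
  g
}

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork (condition ", object@condition, "): ",
      length(object@nodes), " nodes, ", nrow(object@edges), " edges\n",
      sep = "")
})

#' SyntheticTruth: planted ground truth for a simulated two-condition study
#'
#' Records everything planted by [generateTruth()]: the per-gene differential
#' expression truth, per-condition target correlation matrices, the set of
#' differentially correlated pairs with their planted correlations, and the
#' causal hub genes whose correlations are gained in condition B.
#'
#' @slot genes gene identifiers.
#' @slot degTruth data.frame with columns \code{gene}, \code{direction}
#'   (\code{"UP"}, \code{"DN"} or \code{"null"}) and \code{effect}
#'   (mean shift of condition B in units of total per-sample SD).
#' @slot corrA,corrB symmetric unit-diagonal positive semi-definite target
#'   correlation matrices (observed, within-condition scale).
#' @slot dcpTruth data.frame with columns \code{gene_i}, \code{gene_j},
#'   \code{class} (\code{"gain"}/\code{"loss"}), \code{r_A}, \code{r_B} and
#'   \code{primary} (TRUE for directly planted hub-partner or loss pairs,
#'   FALSE for correlations induced by the one-factor hub blocks).
#' @slot causalGenes hub genes of the gain blocks.
#' @slot blocks internal block structure used for sampling.
#' @slot pairICC intraclass correlation of the per-pair random effect.
#' @slot seed integer seed the truth was generated from.
#' @export
setClass("SyntheticTruth",
         representation(genes = "character",
                        degTruth = "data.frame",
                        corrA = "matrix",
                        corrB = "matrix",
                        dcpTruth = "data.frame",
                        causalGenes = "character",
                        blocks = "list",
                        pairICC = "numeric",
                        seed = "integer"))

.validSyntheticTruth <- function(object) {
  msg <- character()
  for (nm in c("corrA", "corrB")) {
    m <- slot(object, nm)
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
      msg <- c(msg, paste(nm, "must be symmetric"))
    if (max(abs(diag(m) - 1)) > 1e-8)
      msg <- c(msg, paste(nm, "must have unit diagonal"))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      msg <- c(msg, paste(nm, "must be positive semi-definite"))
  }
  if (nrow(object@dcpTruth)) {
    idx <- cbind(match(object@dcpTruth$gene_i, object@genes),
                 match(object@dcpTruth$gene_j, object@genes))
    if (max(abs(object@corrA[idx] - object@dcpTruth$r_A)) > 0.02 ||
        max(abs(object@corrB[idx] - object@dcpTruth$r_B)) > 0.02)
      msg <- c(msg, "dcpTruth correlations must match the matrices")
  }
  if (length(object@causalGenes) &&
      !all(object@causalGenes %in%
           c(object@dcpTruth$gene_i[object@dcpTruth$class == "gain"],
             object@dcpTruth$gene_j[object@dcpTruth$class == "gain"])))
    msg <- c(msg, "every causal gene must participate in a planted gain pair")
  if (length(msg)) msg else TRUE
}
setValidity("SyntheticTruth", .validSyntheticTruth)

setMethod("show", "SyntheticTruth", function(object) {
  dt <- object@dcpTruth
  cat("SyntheticTruth: ", length(object@genes), " genes, ",
      sum(object@degTruth$direction != "null"), " DEGs, ",
      sum(dt$class == "gain"), " gain pairs, ",
      sum(dt$class == "loss"), " loss pairs, ",
      length(object@causalGenes), " causal hubs (seed ", object@seed, ")\n",
      sep = "")
})
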