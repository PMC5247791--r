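#' Read a tab-delimited expression matrix with sample annotation
#'
#' Expression tables are tab-delimited text with one header row of sample
#' identifiers and gene identifiers in the first column, values on a log
#' scale. A side annotation file (columns \code{sample}, \code{condition},
#' optional \code{pair_id}) assigns every sample to condition \code{"A"} or
#' \code{"B"} and, for paired designs, to a pair. Cells that fail to parse
#' as numbers become missing values; duplicate gene identifiers are a hard
#' error; a sample without a condition is a hard error.
#'
#' @param path path to the expression table.
#' @param annotation_path path to the sample annotation table; defaults to
#'   \code{<path>.annotation.tsv}.
#' @param datasetId dataset identifier; defaults to the file name.
#' @param sep field separator (tab).
#' @return an [ExpressionDataset-class].
#' @export
readExpressionTable <- function(path,
                                annotation_path = paste0(path, ".annotation.tsv"),
                                datasetId = basename(path), sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier: ", genes[duplicated(genes)][1L])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage <- suppressWarnings(apply(vals, 2L, as.numeric))
  storage <- matrix(storage, nrow = length(genes),
                    dimnames = list(genes, colnames(vals)))
  ann <- utils::read.table(annotation_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (!all(c("sample", "condition") %in% colnames(ann)))
    stop("annotation must have 'sample' and 'condition' columns")
  miss <- setdiff(colnames(storage), ann$sample)
  if (length(miss))
    stop("missing condition for sample(s): ", paste(miss, collapse = ", "))
  idx <- match(colnames(storage), ann$sample)
  pairing <- if ("pair_id" %in% colnames(ann)) ann$pair_id[idx] else NULL
  ExpressionDataset(storage, condition = ann$condition[idx],
                    pairing = pairing, datasetId = datasetId)
}

#' Write an ExpressionDataset as a tab-delimited table plus annotation
#'
#' Inverse of [readExpressionTable()]; round-trips values to printed
#' precision.
#'
#' @param ds an [ExpressionDataset-class].
#' @param path output path for the expression table.
#' @param annotation_path output path for the sample annotation.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTable <- function(ds, path,
                                 annotation_path = paste0(path, ".annotation.tsv")) {
  m <- exprsMatrix(ds)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample = colnames(m),
                    condition = unname(sampleConditions(ds)),
                    stringsAsFactors = FALSE)
  pr <- samplePairing(ds)
  if (!is.null(pr)) ann$pair_id <- unname(pr)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-sample median normalization
#'
#' Subtracts from each sample (array) its median over non-missing genes, so
#' every sample's post-normalization median is 0. Idempotent. Applied on
#' the log scale.
#'
#' @param ds an [ExpressionDataset-class].
#' @return a median-normalized [ExpressionDataset-class].
#' @export
medianNormalize <- function(ds) {
  m <- exprsMatrix(ds)
  med <- apply(m, 2L, stats::median, na.rm = TRUE)
  if (anyNA(med))
    stop("sample(s) with all values missing: ",
         paste(colnames(m)[is.na(med)], collapse = ", "))
  ExpressionDataset(sweep(m, 2L, med), condition = sampleConditions(ds),
                    pairing = samplePairing(ds), datasetId = datasetId(ds))
}

#' Presence filter across datasets
#'
#' Keeps the genes observed (non-missing) in at least \code{min_fraction}
#' of all arrays, pooling the samples of every dataset. The default 0.70
#' is the conventional 70\%-of-arrays presence requirement.
#'
#' @param datasets list of [ExpressionDataset-class] objects.
#' @param min_fraction required non-missing fraction, in (0, 1].
#' @return character vector of retained gene identifiers.
#' @export
filterGenePresence <- function(datasets, min_fraction = 0.70) {
  if (!length(datasets)) stop("empty dataset list")
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  genes <- rownames(exprsMatrix(datasets[[1L]]))
  present <- stats::setNames(numeric(length(genes)), genes)
  total <- 0L
  for (ds in datasets) {
    m <- exprsMatrix(ds)
    if (!identical(rownames(m), genes))
      stop("datasets must share a common gene universe")
    present <- present + rowSums(!is.na(m))
    total <- total + ncol(m)
  }
  names(present)[present / total >= min_fraction]
}

#' Write Cytoscape-importable edge and node tables
#'
#' Writes two tab-delimited tables: edges (\code{source}, \code{target},
#' \code{sign}, \code{combined_p}, \code{q}) and nodes (\code{gene},
#' \code{is_deg}, \code{is_dc}, \code{is_causal}, \code{degree}). The edge
#' table round-trips through [readCytoscapeEdges()].
#'
#' @param network a [CoexpressionNetwork-class].
#' @param annotations data.frame with columns \code{gene}, \code{is_deg},
#'   \code{is_dc}, \code{is_causal} covering every node.
#' @param edge_path,node_path output paths.
#' @return invisibly \code{NULL}.
#' @export
writeCytoscapeTables <- function(network, annotations, edge_path, node_path) {
  nodes <- networkNodes(network)
  if (!all(nodes %in% annotations$gene))
    stop("annotation missing for node(s): ",
         paste(setdiff(nodes, annotations$gene), collapse = ", "))
  e <- networkEdges(network)
  edges <- data.frame(source = e$gene_i, target = e$gene_j, sign = e$sign,
                      combined_p = e$combined_p, q = e$q,
                      stringsAsFactors = FALSE)
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  deg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(e)) {
    tab <- table(c(e$gene_i, e$gene_j))
    deg[names(tab)] <- as.integer(tab)
  }
  idx <- match(nodes, annotations$gene)
  nodetab <- data.frame(gene = nodes,
                        is_deg = annotations$is_deg[idx],
                        is_dc = annotations$is_dc[idx],
                        is_causal = annotations$is_causal[idx],
                        degree = unname(deg),
                        stringsAsFactors = FALSE)
  utils::write.table(nodetab, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a Cytoscape edge table back into a CoexpressionNetwork
#'
#' @param edge_path path written by [writeCytoscapeTables()].
#' @param node_path optional node table path; when given, its genes become
#'   the node set (retaining isolated nodes).
#' @param condition condition label for the reconstructed network.
#' @return a [CoexpressionNetwork-class].
#' @export
readCytoscapeEdges <- function(edge_path, node_path = NULL, condition = "A") {
  e <- utils::read.table(edge_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  edges <- if (nrow(e))
    data.frame(gene_i = e$source, gene_j = e$target, sign = e$sign,
               combined_p = e$combined_p, q = e$q, stringsAsFactors = FALSE)
  else NULL
  nodes <- if (!is.null(node_path))
    utils::read.table(node_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "")$gene
  else unique(c(e$source, e$target))
  CoexpressionNetwork(condition, nodes, edges)
}
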