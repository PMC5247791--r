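#' Analysis configuration with named presets
#'
#' Two presets encode the threshold sets of the two study designs the
#' package emulates. \code{"bcko"} (two paired datasets, Pearson
#' networks): DEG p < 0.05 and fdr < 0.10, correlation p < 0.20 and
#' fdr < 0.025, correlation-difference p < 0.10 and fdr < 0.02, direction
#' consistency in 2 of 2 datasets. \code{"cervical"} (five datasets, LPC
#' networks): correlation p < 0.10 and fdr < 1e-8, difference p < 0.10 and
#' fdr < 0.0025, LPC screen p < 0.40 and fdr < 0.05, direction consistency
#' in 3 of 5 datasets. Any key can be overridden through \code{...}.
#'
#' @param preset \code{"bcko"} or \code{"cervical"}.
#' @param ... overrides for individual keys.
#' @return a named list of class \code{"dc_config"}.
#' @export
dcConfig <- function(preset = c("bcko", "cervical"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    mode = "pearson",      # or "lpc"
    k_required = 2L,
    p_deg = 0.05, q_deg = 0.10,
    p_corr = 0.20, q_corr = 0.025,
    p_screen = 0.20, p_diff = 0.10, q_diff = 0.02,
    p_lpc_screen = 0.40, q_lpc = 0.05,
    veto = FALSE, puc = TRUE,
    neighbor_rank = "max", bbc_mode = "fractional")
  if (preset == "cervical") {
    base$mode <- "lpc"
    base$k_required <- 3L
    base$p_corr <- 0.10; base$q_corr <- 1e-8
    base$p_screen <- 0.10
    base$q_diff <- 0.0025
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  thr <- c("p_deg", "q_deg", "p_corr", "q_corr", "p_screen", "p_diff",
           "q_diff", "p_lpc_screen", "q_lpc")
  for (nm in thr)
    if (base[[nm]] <= 0 || base[[nm]] > 1)
      stop("threshold '", nm, "' must lie in (0, 1]")
  structure(base, class = "dc_config")
}

#' Run the full differential co-expression pipeline
#'
#' Executes, in order: DEG calling by meta-analysis; per-condition network
#' construction (Pearson or local-partial-correlation mode); differential
#' correlation (DCP) calling; topology annotation relative to the key
#' drivers (when given); and causal-gene enrichment among the gain and
#' loss DC genes (when drivers are given). A funnel log records each
#' filter's input and output counts. When \code{output_dir} is given,
#' DEG/DCP/topology tables, Cytoscape edge and node tables for both
#' networks, and a run manifest (configuration, seed, package version)
#' are written atomically (complete file or no file).
#'
#' @param datasets list of [ExpressionDataset-class] objects, or
#'   \code{NULL} to simulate.
#' @param config a [dcConfig()] configuration.
#' @param drivers optional key-driver / causal gene identifiers.
#' @param degs optional externally supplied DEG table (data.frame with
#'   \code{gene}, \code{direction}, \code{is_deg}); when given, the DEG
#'   stage is skipped (the design used for the cancer system, whose DEGs
#'   come from a prior study).
#' @param simulate optional list with elements \code{truth_config} (from
#'   [truthConfig()]), \code{m_datasets}, \code{n_per_condition},
#'   \code{paired}, \code{heterogeneity}; used when \code{datasets} is
#'   \code{NULL}. Requires \code{seed}.
#' @param seed integer seed (mandatory for simulation; also seeds the
#'   permutation test).
#' @param output_dir optional output directory.
#' @param n_perm permutations for the topology permutation test.
#' @return list with elements \code{degs}, \code{network_A},
#'   \code{network_B}, \code{dcps}, \code{topology}, \code{enrichment},
#'   \code{log}, \code{truth} (simulation only) and \code{config}.
#' @export
runPipeline <- function(datasets = NULL, config = dcConfig(),
                        drivers = NULL, degs = NULL, simulate = NULL,
                        seed = NULL, output_dir = NULL, n_perm = 10000) {
  log <- list()
  truth <- NULL
  if (is.null(datasets)) {
    if (is.null(simulate)) stop("either datasets or a simulate block is required")
    if (is.null(seed)) stop("seed is mandatory in simulate mode")
    sim <- utils::modifyList(
      list(truth_config = truthConfig(), m_datasets = 2L,
           n_per_condition = 12L, paired = TRUE, heterogeneity = 0),
      simulate)
    truth <- generateTruth(sim$truth_config, seed = seed)
    datasets <- sampleDatasets(truth, m_datasets = sim$m_datasets,
                               n_per_condition = sim$n_per_condition,
                               paired = sim$paired,
                               heterogeneity = sim$heterogeneity,
                               seed = seed + 1L)
    if (is.null(drivers)) drivers <- truth@causalGenes
  }
  if (is.null(degs)) {
    degs <- tryCatch(callDEGs(datasets, config),
                     error = function(e) stop("stage DEG failed: ",
                                              conditionMessage(e)))
  }
  log$genes_tested <- nrow(degs)
  log$degs <- sum(degs$is_deg)
  build <- function(cond) {
    fn <- if (config$mode == "lpc") buildLPCNetwork
          else buildCoexpressionNetwork
    tryCatch(fn(datasets, degs, cond, config),
             error = function(e) stop("stage network-", cond, " failed: ",
                                      conditionMessage(e)))
  }
  netA <- build("A"); netB <- build("B")
  for (cond in c("A", "B")) {
    st <- attr(if (cond == "A") netA else netB, "pair_stats")
    if (!is.null(st)) {
      log[[paste0("pairs_", cond)]] <- nrow(st)
      log[[paste0("pairs_dir_", cond)]] <- sum(!is.na(st$q))
      log[[paste0("pairs_fdr_", cond)]] <-
        sum(!is.na(st$q) & st$q < (if (config$mode == "lpc") config$q_lpc
                                   else config$q_corr) &
            st$n_support >= (if (config$mode == "lpc") 0 else config$k_required))
      log[[paste0("edges_", cond)]] <- sum(st$is_edge)
    }
  }
  dcps <- tryCatch(callDCPs(datasets, netA, netB, config),
                   error = function(e) stop("stage DCP failed: ",
                                            conditionMessage(e)))
  cand <- attr(dcps, "candidates")
  log$dcp_candidates <- sum(cand$candidate)
  log$dcp_dir <- sum(cand$candidate & cand$dir_pass)
  log$dcp_fdr <- sum(cand$is_dcp | (cand$candidate & cand$dir_pass &
                                    !is.na(cand$q) & cand$q < config$q_diff))
  log$dcps <- nrow(dcps)
  log$gains <- sum(dcps$change_direction == "gain")
  log$losses <- sum(dcps$change_direction == "loss")

  topo <- NULL; enrich <- NULL
  dcg <- dcGenes(dcps)
  if (!is.null(drivers) && length(intersect(drivers, networkNodes(netB)))) {
    topo <- topologyAnnotation(netB, drivers, dcg, n_perm = n_perm,
                               seed = if (is.null(seed)) 1L else seed,
                               bbc_mode = config$bbc_mode)
    background <- setdiff(degs$gene[degs$is_deg], dcg)
    enrich <- list(
      gain = enrichmentOfSet(dcGenes(dcps, "gain"), drivers, background),
      loss = enrichmentOfSet(dcGenes(dcps, "loss"), drivers, background))
  }
  res <- list(degs = degs, network_A = netA, network_B = netB, dcps = dcps,
              topology = topo, enrichment = enrich, log = log,
              truth = truth, config = config)
  if (!is.null(output_dir)) .writeResults(res, output_dir, seed)
  res
}

# Atomic write: serialize to a temp file in the target directory, then
# rename into place; partial outputs are removed on failure.
.atomicWrite <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  file.rename(tmp, path)
  ok <- TRUE
  invisible(path)
}

.writeResults <- function(res, output_dir, seed) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    .atomicWrite(function(p) utils::write.table(
      df, p, sep = "\t", quote = FALSE, row.names = FALSE),
      file.path(output_dir, name))
  tsv(res$degs, "degs.tsv")
  tsv(res$dcps, "dcps.tsv")
  dcg <- dcGenes(res$dcps)
  for (cond in c("A", "B")) {
    net <- if (cond == "A") res$network_A else res$network_B
    ann <- data.frame(gene = networkNodes(net),
                      is_deg = TRUE,
                      is_dc = networkNodes(net) %in% dcg,
                      is_causal = if (!is.null(res$truth))
                        networkNodes(net) %in% res$truth@causalGenes
                      else FALSE,
                      stringsAsFactors = FALSE)
    writeCytoscapeTables(net, ann,
                         file.path(output_dir, paste0("edges_", cond, ".tsv")),
                         file.path(output_dir, paste0("nodes_", cond, ".tsv")))
  }
  if (!is.null(res$topology)) {
    tsv(res$topology$table, "topology.tsv")
    tsv(res$topology$stats, "topology_stats.tsv")
  }
  manifest <- list(
    config = unclass(res$config),
    seed = seed,
    package_version = as.character(utils::packageVersion("diffcoexpr")),
    log = res$log)
  .atomicWrite(function(p) jsonlite::write_json(
    manifest, p, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    file.path(output_dir, "manifest.json"))
  invisible(NULL)
}

#' Recovery metrics of pipeline results against a planted truth
#'
#' Standard confusion-matrix metrics per stage. Sensitivity is the
#' fraction of planted positives recovered; FDR is the fraction of
#' discoveries that are not planted (0 when there are no discoveries).
#' DCP metrics are reported over all planted differential pairs and,
#' separately, over the primary pairs planted at the full
#' \code{r_planted} (hub-partner gains and losses); the gain/loss
#' confusion matrix counts planted pairs by called change direction.
#'
#' @param results list from [runPipeline()].
#' @param truth a [SyntheticTruth-class] covering the result genes.
#' @return list with \code{deg_sensitivity}, \code{deg_fdr},
#'   \code{dcp_sensitivity}, \code{dcp_gain_sensitivity_primary},
#'   \code{dcp_loss_sensitivity_primary}, \code{dcp_fdr} and
#'   \code{gain_loss_confusion} (2x2 matrix truth x called).
#' @export
recoveryReport <- function(results, truth) {
  degs <- results$degs
  if (!all(degs$gene %in% truth@genes))
    stop("gene universe mismatch between results and truth")
  true_deg <- truth@degTruth$gene[truth@degTruth$direction != "null"]
  called_deg <- degs$gene[degs$is_deg]
  deg_sens <- if (length(true_deg)) mean(true_deg %in% called_deg) else NA_real_
  deg_fdr <- if (length(called_deg)) mean(!called_deg %in% true_deg) else 0

  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  tt <- truth@dcpTruth
  tkey <- key(tt$gene_i, tt$gene_j)
  dcps <- results$dcps
  ckey <- if (nrow(dcps)) key(dcps$gene_i, dcps$gene_j) else character()
  dcp_sens <- if (nrow(tt)) mean(tkey %in% ckey) else NA_real_
  dcp_fdr <- if (length(ckey)) mean(!ckey %in% tkey) else 0
  prim <- function(cls) {
    pk <- tkey[tt$primary & tt$class == cls]
    if (!length(pk)) return(NA_real_)
    hit <- ckey[match(pk, ckey)]
    mean(pk %in% ckey[dcps$change_direction == cls])
  }
  conf <- matrix(0L, 2L, 2L,
                 dimnames = list(truth = c("gain", "loss"),
                                 called = c("gain", "loss")))
  if (nrow(dcps)) {
    hit <- match(ckey, tkey)
    ok <- !is.na(hit)
    for (tc in c("gain", "loss")) for (cc in c("gain", "loss"))
      conf[tc, cc] <- sum(ok & tt$class[hit] == tc &
                          dcps$change_direction == cc)
  }
  list(deg_sensitivity = deg_sens, deg_fdr = deg_fdr,
       dcp_sensitivity = dcp_sens,
       dcp_gain_sensitivity_primary = prim("gain"),
       dcp_loss_sensitivity_primary = prim("loss"),
       dcp_fdr = dcp_fdr,
       gain_loss_confusion = conf)
}
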