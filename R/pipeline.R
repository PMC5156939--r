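#' Analysis configuration
#'
#' Collects every tunable of the pipeline: the screening thresholds, PLS-DA
#' settings, network settings, the seed, and input/output paths. Serializable
#' to and from YAML; unknown keys are rejected.
#'
#' @param thresholds an \code{\link{md_thresholds}} (or list of overrides).
#' @param plsda list: \code{n_components} (default 3), \code{B} (default
#'   2000).
#' @param network list: \code{lambda_method} (\code{"bic"}/\code{"cv"}),
#'   \code{symmetrize} (\code{"or"}/\code{"and"}).
#' @param feature_subset features used for PLS-DA: \code{"volcano"}
#'   (volcano-selected annotated metabolites, the default),
#'   \code{"annotated"}, or \code{"all"}.
#' @param normalization \code{"none"} or \code{"total"}.
#' @param outlier list: \code{n_components} (2), \code{alpha} (0.025).
#' @param module_seeds character vector of seed metabolites for module
#'   extraction.
#' @param gmt_path optional metabolite-set library for enrichment.
#' @param seed integer seed.
#' @param input_path,metadata_path,output_dir file locations (may be NULL
#'   when the pipeline is run on an in-memory matrix).
#' @return A list of class \code{analysis_config}.
#' @export
analysis_config <- function(thresholds = md_thresholds(),
                            plsda = list(n_components = 3, B = 2000),
                            network = list(lambda_method = "bic",
                                           symmetrize = "or"),
                            feature_subset = c("volcano", "annotated", "all"),
                            normalization = c("none", "total"),
                            outlier = list(n_components = 2, alpha = 0.025),
                            module_seeds = character(),
                            gmt_path = NULL,
                            seed = 1L,
                            input_path = NULL, metadata_path = NULL,
                            output_dir = NULL) {
  feature_subset <- match.arg(feature_subset)
  normalization <- match.arg(normalization)
  if (!inherits(thresholds, "md_thresholds"))
    thresholds <- do.call(md_thresholds, as.list(thresholds))
  plsda <- utils::modifyList(list(n_components = 3, B = 2000), plsda)
  network <- utils::modifyList(list(lambda_method = "bic", symmetrize = "or"),
                               network)
  outlier <- utils::modifyList(list(n_components = 2, alpha = 0.025), outlier)
  structure(list(thresholds = thresholds, plsda = plsda, network = network,
                 feature_subset = feature_subset,
                 normalization = normalization, outlier = outlier,
                 module_seeds = module_seeds, gmt_path = gmt_path,
                 seed = as.integer(seed), input_path = input_path,
                 metadata_path = metadata_path, output_dir = output_dir),
            class = "analysis_config")
}

config_keys <- c("thresholds", "plsda", "network", "feature_subset",
                 "normalization", "outlier", "module_seeds", "gmt_path",
                 "seed", "input_path", "metadata_path", "output_dir")

#' Read an analysis configuration from YAML
#'
#' @param path YAML file; unknown top-level keys are rejected.
#' @return An \code{\link{analysis_config}}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  if (!is.null(raw$thresholds)) {
    raw$thresholds[vapply(raw$thresholds, is.null, logical(1))] <- NULL
    raw$thresholds <- do.call(md_thresholds, raw$thresholds)
  }
  if (!is.null(raw$module_seeds)) raw$module_seeds <- as.character(raw$module_seeds)
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to YAML
#'
#' @param config an \code{\link{analysis_config}}.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  out <- unclass(config)
  out$thresholds <- unclass(out$thresholds)
  out <- lapply(out, function(x) if (is.null(x)) NULL else x)
  yaml::write_yaml(out, path)
  invisible(path)
}

# append a timestamped stage record to the in-memory run log
log_stage <- function(log, stage, ...) {
  rec <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 stage, paste(sprintf("%s=%s", names(list(...)),
                                      unlist(list(...))), collapse = " "))
  c(log, rec)
}

#' Clustered z-score matrix for heatmap display
#'
#' Autoscales the selected features and orders samples and features by
#' hierarchical clustering (Euclidean distance, average linkage). Returned
#' as data, not an image, so downstream plotting is up to the user and the
#' output is exactly testable.
#'
#' @param M log2-scale \code{\link{abundance_matrix}}.
#' @param feature_ids features to include.
#' @return A list with the reordered z-score \code{matrix}, \code{row_order}
#'   and \code{col_order} (names in display order), and the group label per
#'   displayed sample.
#' @export
heatmap_matrix <- function(M, feature_ids) {
  stopifnot(inherits(M, "abundance_matrix"))
  sel <- subset_abundance(M, features = match(feature_ids, M$feature_ids))
  Z <- suppressWarnings(autoscale(sel))
  ro <- stats::hclust(stats::dist(Z$values), method = "average")$order
  co <- if (ncol(Z$values) > 1)
    stats::hclust(stats::dist(t(Z$values)), method = "average")$order
  else 1L
  list(matrix = Z$values[ro, co, drop = FALSE],
       row_order = Z$sample_ids[ro], col_order = Z$feature_ids[co],
       y = Z$y[ro])
}

#' Run the full differential-network analysis pipeline
#'
#' Executes the stage sequence: per-sample normalization, log2 transform,
#' PCA outlier exclusion, univariate screening (fold change on linear data,
#' Student's t on log2, BH FDR, volcano selection), autoscaling, PLS-DA with
#' leave-one-out cross-validation and permutation significance on the
#' configured feature subset, common/differential network construction on
#' annotated features, seed-module extraction, optional over-representation
#' analysis, and the clustered z-score heatmap matrix. When
#' \code{config$output_dir} is set, every artifact is also written as TSV /
#' SIF, together with a timestamped run log.
#'
#' @param M a linear-scale \code{\link{abundance_matrix}}; alternatively
#'   \code{NULL} to read from \code{config$input_path}/\code{metadata_path}.
#' @param config an \code{\link{analysis_config}}.
#' @return A list with elements \code{outliers}, \code{univariate},
#'   \code{plsda}, \code{loo}, \code{permutation}, \code{network},
#'   \code{modules}, \code{enrichment}, \code{heatmap}, \code{log}, and
#'   \code{files} (paths written, if any).
#' @export
run_pipeline <- function(M = NULL, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(M)) {
    if (is.null(config$input_path)) stop("no data: supply M or input_path")
    M <- read_abundance(config$input_path, config$metadata_path)
  }
  log <- character()
  log <- log_stage(log, "input", samples = nrow(M$values),
                   features = ncol(M$values), seed = config$seed)

  factors <- if (config$normalization == "total") "total" else NULL
  Mn <- normalize_per_sample(M, factors)
  log <- log_stage(log, "normalize", policy = config$normalization)

  Ml <- log2_transform(Mn)
  ex <- pca_outlier_exclude(Ml, n_components = config$outlier$n_components,
                            alpha = config$outlier$alpha)
  keep <- match(ex$data$sample_ids, Mn$sample_ids)
  Mn <- subset_abundance(Mn, samples = keep)
  Ml <- ex$data
  log <- log_stage(log, "pca_outlier_exclude",
                   excluded = length(ex$report$excluded_sample_ids),
                   remaining = nrow(Ml$values))

  thr <- config$thresholds
  if (is.null(thr$m_total)) thr$m_total <- ncol(Mn$values)
  uni <- univariate_screen(Mn, thr)
  log <- log_stage(log, "univariate", tested = nrow(uni),
                   selected = sum(uni$selected),
                   selected_annotated = sum(uni$selected &
                                              uni$annotation == "known"))

  subset_ids <- switch(config$feature_subset,
    volcano = uni$feature_id[uni$selected & uni$annotation == "known"],
    annotated = uni$feature_id[uni$annotation == "known"],
    all = uni$feature_id)
  if (length(subset_ids) < 2) {
    # degenerate screen (e.g. a null cohort): fall back to all annotated
    subset_ids <- uni$feature_id[uni$annotation == "known"]
    log <- log_stage(log, "feature_subset_fallback", used = "annotated")
  }
  Msub <- subset_abundance(Ml, features = match(subset_ids, Ml$feature_ids))
  A <- suppressWarnings(autoscale(Msub))
  ncomp <- min(config$plsda$n_components, nrow(A$values) - 1L, ncol(A$values))
  fit <- fit_plsda(A, n_components = ncomp)
  loo <- loo_cv(Msub, n_components = ncomp)
  perm <- permutation_test(A, n_components = ncomp, B = config$plsda$B,
                           seed = config$seed)
  log <- log_stage(log, "plsda", features = ncol(A$values),
                   n_components = ncomp, loo_accuracy = loo$accuracy,
                   permutation_p = perm$p_value)

  Mann <- subset_abundance(Ml, features = which(Ml$annotation == "known"))
  Aann <- suppressWarnings(autoscale(Mann))
  net <- build_networks(Aann$values, Aann$y,
                        symmetrize = config$network$symmetrize,
                        method = config$network$lambda_method)
  log <- log_stage(log, "network", nodes = length(net$nodes),
                   common_edges = nrow(net$common_edges),
                   diff_edges = nrow(net$diff_edges))

  modules <- lapply(intersect(config$module_seeds, net$nodes), function(s)
    extract_module(net, s, mode = "component", univariate = uni))
  names(modules) <- intersect(config$module_seeds, net$nodes)

  enr <- NULL
  if (!is.null(config$gmt_path)) {
    lib <- read_gmt(config$gmt_path)
    universe <- uni$feature_id[uni$annotation == "known"]
    query <- intersect(subset_ids, universe)
    if (length(query) > 0) enr <- ora(query, universe, lib)
    log <- log_stage(log, "enrichment",
                     sets = if (is.null(enr)) 0L else nrow(enr))
  }

  hm_ids <- uni$feature_id[uni$selected]
  hm <- if (length(hm_ids) >= 2) heatmap_matrix(Ml, hm_ids) else NULL
  log <- log_stage(log, "heatmap",
                   features = if (is.null(hm)) 0L else length(hm$col_order))

  files <- character()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    write_univariate(uni, out("univariate.tsv"))
    write_outlier_report(ex$report, out("outliers.tsv"))
    sc <- data.frame(sample_id = A$sample_ids, group = A$y, fit$x_scores)
    names(sc)[-(1:2)] <- paste0("comp", seq_len(ncomp))
    utils::write.table(sc, out("plsda_scores.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    ld <- data.frame(feature_id = A$feature_ids, fit$x_loadings)
    names(ld)[-1] <- paste0("comp", seq_len(ncomp))
    utils::write.table(ld, out("plsda_loadings.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(permuted_stat = perm$permuted_stats), out("permutation.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    write_network_tsv(net, out("network_edges.tsv"))
    export_network(net, out("network.sif"), format = "sif")
    if (!is.null(hm)) {
      hmdf <- data.frame(sample_id = hm$row_order, group = hm$y, hm$matrix,
                         check.names = FALSE)
      utils::write.table(hmdf, out("heatmap_matrix.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    if (!is.null(enr))
      utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    writeLines(log, out("run_log.txt"))
    files <- list.files(config$output_dir, full.names = TRUE)
  }

  list(outliers = ex$report, univariate = uni, plsda = fit, loo = loo,
       permutation = perm, network = net, modules = modules,
       enrichment = enr, heatmap = hm, log = log, files = files)
}
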