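#' Per-sample normalization
#'
#' Divides each sample row by a positive factor. This is the in-silico
#' analogue of wet-lab creatinine volume adjustment: either pass explicit
#' per-sample factors, or use the \code{"total"} policy, which rescales every
#' sample so its total intensity equals the cohort median of the input
#' per-sample totals. Factors of 1 (the default) leave the data untouched.
#'
#' @param M linear-scale \code{\link{abundance_matrix}}.
#' @param factors numeric vector of positive per-sample factors, the string
#'   \code{"total"}, or \code{NULL} for pass-through.
#' @return A normalized \code{abundance_matrix}; the input is not modified.
#' @export
normalize_per_sample <- function(M, factors = NULL) {
  stopifnot(inherits(M, "abundance_matrix"))
  if (M$scale != "linear") stop("normalization applies to linear-scale data")
  n <- nrow(M$values)
  if (is.null(factors)) factors <- rep(1, n)
  if (identical(factors, "total")) {
    sums <- rowSums(M$values)
    factors <- sums / stats::median(sums)
  }
  if (!is.numeric(factors) || length(factors) != n)
    stop("'factors' must be one positive value per sample or \"total\"")
  if (any(factors <= 0)) stop("normalization factors must be positive")
  out <- M
  out$values <- M$values / factors
  out
}

#' Log2 transformation
#'
#' Elementwise log2 of a strictly positive linear-scale matrix. No pseudocount
#' is added; a non-positive cell is an error naming the offending sample and
#' feature.
#'
#' @param M linear-scale \code{\link{abundance_matrix}}.
#' @return An \code{abundance_matrix} on the log2 scale.
#' @export
log2_transform <- function(M) {
  stopifnot(inherits(M, "abundance_matrix"))
  if (M$scale != "linear") stop("input is already transformed")
  if (any(M$values <= 0)) {
    bad <- which(M$values <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive value at sample '%s', feature '%s'",
                 M$sample_ids[bad[1L]], M$feature_ids[bad[2L]]))
  }
  out <- M
  out$values <- log2(M$values)
  out$scale <- "log2"
  out
}

#' Autoscaling (mean-centering and unit-variance scaling)
#'
#' Centers each feature to mean 0 and scales it to sample standard deviation 1
#' (n - 1 denominator), the standard pretreatment before PCA/PLS-DA on
#' metabolomics data. Zero-variance features cannot be scaled and are dropped
#' with a warning rather than raising an error.
#'
#' @param M an \code{\link{abundance_matrix}} (any scale).
#' @return An autoscaled \code{abundance_matrix}; attributes
#'   \code{feature_means} and \code{feature_sds} store the statistics used.
#' @export
autoscale <- function(M) {
  stopifnot(inherits(M, "abundance_matrix"))
  if (nrow(M$values) < 2) stop("autoscaling needs at least 2 samples")
  mu <- colMeans(M$values)
  sdv <- apply(M$values, 2L, stats::sd)
  keep <- sdv > 0
  if (!all(keep))
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(!keep), paste(M$feature_ids[!keep], collapse = ", ")))
  out <- subset_abundance(M, features = which(keep))
  out$values <- sweep(sweep(out$values, 2L, mu[keep]), 2L, sdv[keep], "/")
  out$scale <- "autoscaled"
  attr(out, "feature_means") <- mu[keep]
  attr(out, "feature_sds") <- sdv[keep]
  out
}

#' PCA-based outlier exclusion
#'
#' Computes principal-component scores on autoscaled data and flags samples
#' whose squared score distance (sum over the retained components of
#' score^2 / component variance, a Hotelling-type statistic) exceeds the
#' chi-square quantile with \code{n_components} degrees of freedom at
#' \code{1 - alpha}. A single pass: flagged samples are removed once, with no
#' iteration.
#'
#' @param M an \code{\link{abundance_matrix}} (log2 scale recommended).
#' @param n_components number of principal components retained (default 2).
#' @param alpha tail probability of the chi-square rule, in (0, 0.5);
#'   default 0.025.
#' @return A list with \code{data} (the filtered \code{abundance_matrix}, on
#'   the input scale) and \code{report} (class \code{outlier_report}:
#'   excluded ids, per-sample score distances, threshold, n_components).
#' @export
pca_outlier_exclude <- function(M, n_components = 2, alpha = 0.025) {
  stopifnot(inherits(M, "abundance_matrix"))
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)")
  n <- nrow(M$values)
  if (n <= n_components + 1) stop("too few samples for the requested components")
  A <- suppressWarnings(autoscale(M))
  pc <- stats::prcomp(A$values, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  vars <- pc$sdev[seq_len(k)]^2
  d2 <- rowSums(sweep(scores^2, 2L, vars, "/"))
  threshold <- stats::qchisq(1 - alpha, df = k)
  flagged <- which(d2 > threshold)
  report <- structure(list(excluded_sample_ids = M$sample_ids[flagged],
                           score_distances = stats::setNames(d2, M$sample_ids),
                           threshold = threshold,
                           n_components = k, alpha = alpha),
                      class = "outlier_report")
  keep <- setdiff(seq_len(n), flagged)
  list(data = subset_abundance(M, samples = keep), report = report)
}

#' Write an outlier report as TSV
#'
#' @param report an \code{outlier_report} from
#'   \code{\link{pca_outlier_exclude}}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_outlier_report <- function(report, path) {
  df <- data.frame(sample_id = names(report$score_distances),
                   score_distance = unname(report$score_distances),
                   excluded = names(report$score_distances) %in%
                     report$excluded_sample_ids,
                   threshold = report$threshold,
                   n_components = report$n_components)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
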