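#' Default thresholds for differential screening
#'
#' The volcano rule keeps features with fold change above \code{fc_high} or
#' below \code{fc_low} and raw p below \code{p_volcano}; \code{p_raw} is the
#' uncorrected significance level and \code{fdr_level} the FDR level used for
#' reporting; \code{m_total} is the total number of tests for the
#' Benjamini-Hochberg adjustment (the full number of detected features, which
#' may exceed the number of p-values actually in hand).
#'
#' @param fc_high,fc_low fold-change thresholds (strict inequalities).
#' @param p_volcano raw p threshold of the volcano rule (strict).
#' @param p_raw uncorrected significance level.
#' @param fdr_level FDR reporting level.
#' @param m_total total number of tests; \code{NULL} means "as many as the
#'   p-values supplied".
#' @return A list of class \code{md_thresholds}.
#' @export
md_thresholds <- function(fc_high = 1.20, fc_low = 0.83, p_volcano = 0.1,
                          p_raw = 0.05, fdr_level = 0.05, m_total = NULL) {
  if (!(0 < fc_low && fc_low < 1 && 1 < fc_high))
    stop("need 0 < fc_low < 1 < fc_high")
  for (p in c(p_volcano, p_raw, fdr_level))
    if (p <= 0 || p >= 1) stop("probability thresholds must lie in (0, 1)")
  structure(list(fc_high = fc_high, fc_low = fc_low, p_volcano = p_volcano,
                 p_raw = p_raw, fdr_level = fdr_level, m_total = m_total),
            class = "md_thresholds")
}

#' Per-feature linear fold change
#'
#' Arithmetic mean over case samples divided by arithmetic mean over control
#' samples, per feature, on normalized linear-scale intensities (the
#' MetaboAnalyst-style convention, distinct from the log2-scale t-test).
#'
#' @param M linear-scale \code{\link{abundance_matrix}} with both groups
#'   non-empty.
#' @return Named numeric vector of case/control mean ratios.
#' @export
fold_change <- function(M) {
  stopifnot(inherits(M, "abundance_matrix"))
  if (M$scale != "linear") stop("fold change is defined on linear-scale data")
  if (!any(M$y == 1L) || !any(M$y == 0L)) stop("both groups must be non-empty")
  m1 <- colMeans(M$values[M$y == 1L, , drop = FALSE])
  m0 <- colMeans(M$values[M$y == 0L, , drop = FALSE])
  if (any(m0 == 0)) stop("zero control mean")
  stats::setNames(m1 / m0, M$feature_ids)
}

#' Per-feature Student's t-test on log2 intensities
#'
#' Two-sided pooled-variance (equal-variance Student) t-test per feature,
#' case versus control, with n1 + n2 - 2 degrees of freedom.
#'
#' @param M log2-scale \code{\link{abundance_matrix}}; each group needs at
#'   least 2 samples.
#' @return Data frame with columns \code{feature_id}, \code{t_stat},
#'   \code{p_value}.
#' @export
feature_t_test <- function(M) {
  stopifnot(inherits(M, "abundance_matrix"))
  if (M$scale != "log2") stop("the t-test is applied to log2-scale data")
  if (sum(M$y == 1L) < 2 || sum(M$y == 0L) < 2)
    stop("each group needs at least 2 samples")
  case <- M$values[M$y == 1L, , drop = FALSE]
  ctrl <- M$values[M$y == 0L, , drop = FALSE]
  res <- vapply(seq_len(ncol(M$values)), function(j) {
    ht <- stats::t.test(case[, j], ctrl[, j], var.equal = TRUE)
    c(ht$statistic, ht$p.value)
  }, numeric(2))
  data.frame(feature_id = M$feature_ids, t_stat = res[1L, ],
             p_value = res[2L, ], row.names = NULL)
}

#' Benjamini-Hochberg adjustment with an external total-test count
#'
#' Step-up FDR adjustment treating the supplied p-values as the smallest
#' among \code{m_total} tests; the absent tests are imputed at p = 1 in the
#' highest ranks, so they can never lower the step-up minimum. With
#' \code{m_total = length(p_values)} this is the ordinary BH adjustment.
#'
#' @param p_values numeric vector in [0, 1].
#' @param m_total total number of tests, at least \code{length(p_values)}.
#' @return Adjusted p-values in the input order, capped at 1.
#' @export
bh_adjust <- function(p_values, m_total = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (m_total < length(p_values))
    stop("m_total must be at least the number of p-values supplied")
  stats::p.adjust(p_values, method = "BH", n = m_total)
}

#' Volcano selection rule
#'
#' Selects features with fold change strictly above \code{fc_high} or
#' strictly below \code{fc_low} and raw p strictly below \code{p_volcano}.
#'
#' @param results data frame with columns \code{fold_change} and
#'   \code{p_value} (e.g. from \code{\link{univariate_screen}}).
#' @param thresholds an \code{\link{md_thresholds}}.
#' @return Logical vector, one per row of \code{results}.
#' @export
volcano_select <- function(results, thresholds = md_thresholds()) {
  if (nrow(results) == 0) stop("'results' is empty")
  (results$fold_change > thresholds$fc_high |
     results$fold_change < thresholds$fc_low) &
    results$p_value < thresholds$p_volcano
}

#' Restrict results to annotated metabolites
#'
#' Keeps rows whose annotation is \code{"known"}; when no annotation column
#' is present, rows whose name does not start with \code{"Unknown"} are kept
#' (the naming convention for unidentified signals).
#'
#' @param results data frame with an \code{annotation} column or a
#'   \code{name}/\code{feature_id} column.
#' @return The filtered data frame.
#' @export
annotated_subset <- function(results) {
  if (nrow(results) == 0) return(results)
  if (!is.null(results$annotation)) {
    results[results$annotation == "known", , drop = FALSE]
  } else {
    nm <- if (!is.null(results$name)) results$name else results$feature_id
    results[!startsWith(nm, "Unknown"), , drop = FALSE]
  }
}

#' Univariate differential screen
#'
#' Runs the full per-metabolite screen: linear fold change on the normalized
#' matrix, Student's t-test on its log2 transform, Benjamini-Hochberg FDR at
#' \code{m_total} total tests, and the volcano selection flag.
#'
#' @param M normalized linear-scale \code{\link{abundance_matrix}}.
#' @param thresholds an \code{\link{md_thresholds}}; its \code{m_total}
#'   defaults to the number of features in \code{M}.
#' @return Data frame with columns \code{feature_id}, \code{annotation},
#'   \code{fold_change}, \code{log2fc}, \code{t_stat}, \code{p_value},
#'   \code{p_adjusted}, \code{selected}.
#' @export
univariate_screen <- function(M, thresholds = md_thresholds()) {
  stopifnot(inherits(M, "abundance_matrix"))
  fc <- fold_change(M)
  tt <- feature_t_test(log2_transform(M))
  m_total <- if (is.null(thresholds$m_total)) length(fc) else thresholds$m_total
  res <- data.frame(feature_id = M$feature_ids,
                    annotation = M$annotation,
                    fold_change = unname(fc),
                    log2fc = log2(unname(fc)),
                    t_stat = tt$t_stat,
                    p_value = tt$p_value,
                    p_adjusted = bh_adjust(tt$p_value, m_total),
                    row.names = NULL)
  res$selected <- volcano_select(res, thresholds)
  res
}

#' Write univariate results as TSV
#'
#' Columns mirror the reference-table layout (Num, Name, Fold-change,
#' p-value, FDR) plus \code{t_stat}, \code{log2fc}, \code{selected}.
#'
#' @param results output of \code{\link{univariate_screen}}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_univariate <- function(results, path) {
  ord <- order(results$p_value)
  out <- data.frame(num = seq_len(nrow(results)),
                    name = results$feature_id[ord],
                    fold_change = results$fold_change[ord],
                    p_value = results$p_value[ord],
                    fdr = results$p_adjusted[ord],
                    t_stat = results$t_stat[ord],
                    log2fc = results$log2fc[ord],
                    selected = results$selected[ord])
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
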