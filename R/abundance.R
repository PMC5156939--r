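#' Construct an abundance matrix
#'
#' The central container of the package: a samples x features table of
#' metabolite intensities together with per-sample binary group labels
#' (1 = case, e.g. interstitial cystitis; 0 = control) and a per-feature
#' annotation status (\code{"known"} for library-matched metabolites,
#' \code{"unknown"} for unidentified signals).
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   Linear-scale intensities must be strictly positive; a matrix that has
#'   already been log2-transformed or autoscaled is tracked via \code{scale}.
#' @param y integer vector of 0/1 group labels, one per sample.
#' @param annotation character vector per feature, \code{"known"} or
#'   \code{"unknown"}. Defaults to \code{"known"} for every feature.
#' @param sample_ids,feature_ids optional identifier vectors; default to the
#'   dimnames of \code{values} or generated names.
#' @param scale one of \code{"linear"}, \code{"log2"}, \code{"autoscaled"};
#'   records which stage of the pipeline the values are on.
#' @return An object of class \code{abundance_matrix}.
#' @export
abundance_matrix <- function(values, y, annotation = NULL,
                             sample_ids = NULL, feature_ids = NULL,
                             scale = c("linear", "log2", "autoscaled")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  n <- nrow(values); p <- ncol(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- sprintf("sample_%03d", seq_len(n))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- sprintf("feature_%04d", seq_len(p))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  if (length(sample_ids) != n) stop("length(sample_ids) != nrow(values)")
  if (length(feature_ids) != p) stop("length(feature_ids) != ncol(values)")
  y <- as.integer(y)
  if (length(y) != n) stop("length(y) != number of samples")
  if (!all(y %in% c(0L, 1L))) stop("group labels y must be 0/1")
  if (is.null(annotation)) annotation <- rep("known", p)
  annotation <- match.arg(annotation, c("known", "unknown"), several.ok = TRUE)
  if (length(annotation) == 1L) annotation <- rep(annotation, p)
  if (length(annotation) != p) stop("length(annotation) != number of features")
  if (scale == "linear" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("linear-scale intensities must be strictly positive; value at sample '%s', feature '%s' is not",
                 sample_ids[bad[1L]], feature_ids[bad[2L]]))
  }
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values, y = y, annotation = annotation,
                 sample_ids = sample_ids, feature_ids = feature_ids,
                 scale = scale),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d features (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  groups: %d case / %d control; features: %d known / %d unknown\n",
              sum(x$y == 1L), sum(x$y == 0L),
              sum(x$annotation == "known"), sum(x$annotation == "unknown")))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

# internal: subset samples and/or features, keeping metadata aligned
subset_abundance <- function(M, samples = NULL, features = NULL) {
  si <- if (is.null(samples)) seq_along(M$sample_ids) else samples
  fi <- if (is.null(features)) seq_along(M$feature_ids) else features
  abundance_matrix(M$values[si, fi, drop = FALSE],
                   y = M$y[si],
                   annotation = M$annotation[fi],
                   sample_ids = M$sample_ids[si],
                   feature_ids = M$feature_ids[fi],
                   scale = M$scale)
}

#' Read an abundance matrix and its sample metadata
#'
#' Expects a delimited table (comma- or tab-separated, inferred from the file
#' extension) whose first column holds sample identifiers and whose header row
#' holds feature identifiers, plus a two-column metadata table mapping sample
#' id to group (\code{IC}/\code{control} or \code{1}/\code{0}).
#'
#' @param path matrix file.
#' @param metadata_path metadata file with columns \code{sample_id},
#'   \code{group}.
#' @param annotation optional per-feature annotation; by default features whose
#'   name starts with \code{"Unknown"} are flagged unknown.
#' @return An \code{\link{abundance_matrix}} (linear scale).
#' @export
read_abundance <- function(path, metadata_path, annotation = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"")
  sample_ids <- raw[[1L]]
  if (anyDuplicated(sample_ids))
    stop(sprintf("duplicate sample ids in '%s': %s", path,
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at sample '%s', feature '%s'",
                 sample_ids[bad[1L]], colnames(vals)[bad[2L]]))
  }
  colnames(num) <- colnames(vals)
  msep <- if (grepl("\\.csv$", metadata_path, ignore.case = TRUE)) "," else "\t"
  meta <- utils::read.table(metadata_path, header = TRUE, sep = msep,
                            check.names = FALSE, colClasses = "character")
  missing <- setdiff(sample_ids, meta[[1L]])
  if (length(missing))
    stop(sprintf("sample(s) missing from metadata: %s",
                 paste(missing, collapse = ", ")))
  grp <- meta[[2L]][match(sample_ids, meta[[1L]])]
  y <- ifelse(grp %in% c("IC", "1", "case"), 1L,
              ifelse(grp %in% c("control", "0"), 0L, NA_integer_))
  if (anyNA(y)) stop("group values must be IC/control or 1/0")
  if (is.null(annotation))
    annotation <- ifelse(startsWith(colnames(num), "Unknown"), "unknown", "known")
  abundance_matrix(num, y = y, annotation = annotation,
                   sample_ids = sample_ids, scale = "linear")
}

#' Write an abundance matrix and its metadata to delimited files
#'
#' @param M an \code{\link{abundance_matrix}}.
#' @param path output matrix file (\code{.csv} or \code{.tsv}).
#' @param metadata_path output metadata file; defaults to
#'   \code{<path>_metadata.tsv}.
#' @return Invisibly, the paths written.
#' @export
write_abundance <- function(M, path, metadata_path = NULL) {
  stopifnot(inherits(M, "abundance_matrix"))
  if (is.null(metadata_path))
    metadata_path <- sub("(\\.[ct]sv)?$", "_metadata.tsv", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = M$sample_ids, M$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  meta <- data.frame(sample_id = M$sample_ids,
                     group = ifelse(M$y == 1L, "IC", "control"))
  utils::write.table(meta, metadata_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(path, metadata_path))
}
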