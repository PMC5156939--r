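#' Specify a synthetic two-group metabolomics cohort
#'
#' Defines the generative conditions for a case/control urine-metabolomics
#' style dataset: cohort sizes, numbers of annotated and unknown features,
#' planted log2 fold changes, and a pair of sparse precision matrices that
#' share common edges and differ on planted differential edges.
#'
#' Defaults mirror the motivating study design: 42 cases and 21 controls,
#' 200 annotated plus 290 unknown features. No effects or edges are planted
#' by default (a null cohort); recovery studies plant them explicitly.
#'
#' @param n_case,n_control group sizes (each >= 2).
#' @param p_known,p_unknown numbers of annotated and unannotated features.
#' @param effects named list or two-column matrix of planted effects:
#'   feature index and log2 fold change (case minus control on the log2
#'   scale). \code{NULL} for none.
#' @param n_common_edges,n_diff_edges numbers of planted partial-correlation
#'   edges shared between groups, and present in the case group only.
#' @param edge_strength absolute partial-correlation magnitude in (0, 1)
#'   targeted for planted edges (attenuated where diagonal loading is needed).
#' @param base_intensity linear-scale location: output intensity is
#'   \code{base_intensity * 2^z} for log2-scale draw \code{z}.
#' @param mult_noise_sd optional extra multiplicative log-normal technical
#'   noise, given as a standard deviation on the log2 scale (0 = off).
#' @param seed integer seed making every draw reproducible.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_case = 42, n_control = 21,
                           p_known = 200, p_unknown = 290,
                           effects = NULL,
                           n_common_edges = 0, n_diff_edges = 0,
                           edge_strength = 0.4,
                           base_intensity = 1000,
                           mult_noise_sd = 0,
                           seed = 1L) {
  p <- p_known + p_unknown
  if (n_case < 2 || n_control < 2) stop("both groups need at least 2 samples")
  if (p < 2 && (n_common_edges + n_diff_edges) > 0)
    stop("edges require at least 2 features")
  if (p < 1) stop("need at least one feature")
  if (edge_strength <= 0 || edge_strength >= 1)
    stop("edge_strength must lie in (0, 1)")
  if (base_intensity <= 0) stop("base_intensity must be positive")
  max_pairs <- p * (p - 1) / 2
  if (n_common_edges + n_diff_edges > max_pairs)
    stop(sprintf("requested %d edges exceed the %d available feature pairs",
                 n_common_edges + n_diff_edges, max_pairs))
  eff <- normalize_effects(effects, p)
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 p_known = as.integer(p_known), p_unknown = as.integer(p_unknown),
                 effects = eff,
                 n_common_edges = as.integer(n_common_edges),
                 n_diff_edges = as.integer(n_diff_edges),
                 edge_strength = edge_strength,
                 base_intensity = base_intensity,
                 mult_noise_sd = mult_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

normalize_effects <- function(effects, p) {
  if (is.null(effects) || length(effects) == 0L)
    return(data.frame(feature = integer(), log2fc = numeric()))
  if (is.list(effects) && !is.data.frame(effects))
    effects <- do.call(rbind, lapply(effects, function(e) data.frame(feature = e[[1L]], log2fc = e[[2L]])))
  effects <- as.data.frame(effects)
  names(effects) <- c("feature", "log2fc")
  effects$feature <- as.integer(effects$feature)
  if (anyDuplicated(effects$feature)) stop("effect feature indices must be unique")
  if (any(effects$feature < 1L | effects$feature > p))
    stop("effect feature index out of range")
  effects
}

#' Build a pair of sparse precision matrices with common and differential edges
#'
#' Plants \code{n_common_edges} off-diagonal supports shared by both groups
#' and \code{n_diff_edges} supports present only in the case-group precision.
#' Planted entries have magnitude \code{edge_strength} with random sign;
#' positive definiteness is enforced by diagonal loading: each diagonal entry
#' is raised to its absolute off-diagonal row sum plus a margin of 0.1
#' whenever that exceeds the unit baseline, giving strict diagonal dominance.
#' The loaded diagonal is computed on the union (case) support and shared by
#' both matrices, so the two precisions differ \emph{only} on the planted
#' differential off-diagonal entries and the ground truth is unambiguous.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A list with symmetric positive-definite matrices
#'   \code{precision_control}, \code{precision_case}, and data frames
#'   \code{common_edges}, \code{diff_edges} (columns \code{i}, \code{j},
#'   \code{value}) recording the planted supports.
#' @export
make_precision_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  draw_precision_pair(spec)
}

# internal worker: assumes the RNG stream is already positioned
draw_precision_pair <- function(spec) {
  p <- spec$p_known + spec$p_unknown
  n_edges <- spec$n_common_edges + spec$n_diff_edges
  pairs <- if (n_edges > 0) sample_pairs(p, n_edges) else
    data.frame(i = integer(), j = integer())
  signs <- if (n_edges > 0) sample(c(-1, 1), n_edges, replace = TRUE) else numeric()
  vals <- signs * spec$edge_strength
  common_idx <- seq_len(spec$n_common_edges)
  diff_idx <- setdiff(seq_len(n_edges), common_idx)
  omega0 <- diag(p)
  for (k in common_idx) {
    omega0[pairs$i[k], pairs$j[k]] <- vals[k]
    omega0[pairs$j[k], pairs$i[k]] <- vals[k]
  }
  omega1 <- omega0
  for (k in diff_idx) {
    omega1[pairs$i[k], pairs$j[k]] <- vals[k]
    omega1[pairs$j[k], pairs$i[k]] <- vals[k]
  }
  # shared loading computed on the union (case) support: both groups get the
  # same diagonal so they differ only on the planted differential entries
  d <- loaded_diagonal(omega1)
  diag(omega0) <- d
  diag(omega1) <- d
  list(precision_control = omega0,
       precision_case = omega1,
       common_edges = data.frame(i = pairs$i[common_idx], j = pairs$j[common_idx],
                                 value = vals[common_idx]),
       diff_edges = data.frame(i = pairs$i[diff_idx], j = pairs$j[diff_idx],
                               value = vals[diff_idx]))
}

# diagonal loading to strict diagonal dominance (margin 0.1)
loaded_diagonal <- function(omega, margin = 0.1) {
  rowsum_abs <- rowSums(abs(omega)) - abs(diag(omega))
  pmax(diag(omega), rowsum_abs + margin)
}

# sample n distinct unordered pairs from p features
sample_pairs <- function(p, n) {
  max_pairs <- p * (p - 1) / 2
  idx <- sample.int(max_pairs, n)
  # map linear index to (i, j) with i < j, column-major over the upper triangle
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  data.frame(i = as.integer(i), j = as.integer(j))
}

#' Generate a synthetic case/control abundance matrix with known truth
#'
#' Draws log2-scale data group-wise from multivariate normal distributions
#' with the group's precision matrix (case means shifted by the planted log2
#' fold changes) and returns a strictly positive linear-scale matrix,
#' \code{base_intensity * 2^z}. Feature names are \code{met_0001...} for
#' annotated features and \code{Unknown BB_...} for unknown ones. Fully
#' reproducible from \code{spec$seed}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return A list with \code{data} (an \code{\link{abundance_matrix}}) and
#'   \code{truth} (class \code{ground_truth}: \code{true_log2fc},
#'   \code{common_edges}, \code{diff_edges}, \code{precision_control},
#'   \code{precision_case}).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  p <- spec$p_known + spec$p_unknown
  pair <- draw_precision_pair(spec)
  sigma0 <- solve(pair$precision_control)
  sigma1 <- if (spec$n_diff_edges > 0) solve(pair$precision_case) else sigma0
  true_log2fc <- numeric(p)
  true_log2fc[spec$effects$feature] <- spec$effects$log2fc
  n0 <- spec$n_control; n1 <- spec$n_case
  z0 <- MASS::mvrnorm(n0, mu = rep(0, p), Sigma = sigma0)
  z1 <- MASS::mvrnorm(n1, mu = true_log2fc, Sigma = sigma1)
  z <- rbind(z1, z0)              # cases first, then controls
  if (spec$mult_noise_sd > 0)
    z <- z + matrix(stats::rnorm(length(z), sd = spec$mult_noise_sd), nrow(z))
  values <- spec$base_intensity * 2^z
  feature_ids <- c(sprintf("met_%04d", seq_len(spec$p_known)),
                   sprintf("Unknown BB_%05d", seq_len(spec$p_unknown)))
  annotation <- rep(c("known", "unknown"), c(spec$p_known, spec$p_unknown))
  y <- rep(c(1L, 0L), c(n1, n0))
  sample_ids <- sprintf("%s_%03d", ifelse(y == 1L, "case", "ctrl"),
                        c(seq_len(n1), seq_len(n0)))
  M <- abundance_matrix(values, y = y, annotation = annotation,
                        sample_ids = sample_ids, feature_ids = feature_ids,
                        scale = "linear")
  truth <- structure(list(true_log2fc = true_log2fc,
                          common_edges = pair$common_edges,
                          diff_edges = pair$diff_edges,
                          precision_control = pair$precision_control,
                          precision_case = pair$precision_case),
                     class = "ground_truth")
  list(data = M, truth = truth)
}

#' Write ground truth to plain-text files
#'
#' Serializes the planted effects and edge lists of a \code{ground_truth}
#' object as tab-separated tables.
#'
#' @param truth a \code{ground_truth} from \code{\link{generate_dataset}}.
#' @param effects_path,edges_path output TSV paths.
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, effects_path, edges_path) {
  eff <- data.frame(feature = seq_along(truth$true_log2fc),
                    log2fc = truth$true_log2fc)
  utils::write.table(eff, effects_path, sep = "\t", row.names = FALSE, quote = FALSE)
  edges <- rbind(
    if (nrow(truth$common_edges)) cbind(truth$common_edges, layer = "common"),
    if (nrow(truth$diff_edges)) cbind(truth$diff_edges, layer = "diff"))
  if (is.null(edges)) edges <- data.frame(i = integer(), j = integer(),
                                          value = numeric(), layer = character())
  utils::write.table(edges, edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(effects_path, edges_path))
}

#' Reference table of differential urinary metabolites in interstitial cystitis
#'
#' Returns the packaged 30-row reference table of metabolites differentially
#' expressed in interstitial cystitis urine versus controls (raw Student-t
#' p < 0.05): metabolite name, linear fold change (case/control), raw p-value
#' and Benjamini-Hochberg FDR computed over all 490 detected features.
#' Twelve rows are annotated metabolites; the rest are unidentified
#' \code{Unknown BB_*} signals.
#'
#' @return A data frame with columns \code{num}, \code{name},
#'   \code{fold_change}, \code{p_value}, \code{fdr}.
#' @export
ic_diff_table <- function() {
  path <- system.file("extdata", "ic_urine_diff_metabolites.tsv",
                      package = "metdiffnet", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  names(tab) <- c("num", "name", "fold_change", "p_value", "fdr")
  tab
}
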