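#' @useDynLib metdiffnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Build the node-wise design for the sparse local graphical model:
#   x_i ~ [ X_{-i} | y | y * X_{-i} ]
# The alpha block holds the group-shared partial associations, the
# unpenalized y column the group mean shift, and the beta block the
# y-dependent (differential) associations. Interaction columns are
# standardized after forming the product; all columns and the response are
# centered so the intercept drops out of the penalized solve.
node_design <- function(i, X, y) {
  p <- ncol(X)
  Xm <- X[, -i, drop = FALSE]
  inter <- Xm * y
  isd <- apply(inter, 2L, stats::sd)
  isd[isd == 0] <- 1                     # constant interaction: leave unscaled
  inter <- sweep(sweep(inter, 2L, colMeans(inter)), 2L, isd, "/")
  Z <- cbind(Xm, y, inter)
  mu <- colMeans(Z)
  Zc <- sweep(Z, 2L, mu)
  xc <- X[, i] - mean(X[, i])
  list(Z = Zc, x = xc, col_means = mu, x_mean = mean(X[, i]),
       alpha_idx = seq_len(p - 1L), y_idx = p,
       beta_idx = p + seq_len(p - 1L), inter_sd = isd)
}

resolve_design_input <- function(X, y) {
  if (inherits(X, "abundance_matrix")) {
    if (missing(y) || is.null(y)) y <- X$y
    X <- X$values
  }
  list(X = as.matrix(X), y = as.numeric(y))
}

#' Single-node L1-penalized regression of the local graphical model
#'
#' Treats metabolite \code{i} as the response and regresses it on the
#' remaining metabolites, the group label, and the group-by-metabolite
#' interactions, with an L1 penalty of \code{lambda_alpha} on the shared
#' (alpha) block and \code{lambda_beta} on the differential (beta) block.
#' The intercept and the y main effect are unpenalized, so group mean shifts
#' are not absorbed into beta edges. Solved by covariance-update coordinate
#' descent to a coefficient-change tolerance of 1e-7.
#'
#' @param i response feature index.
#' @param X autoscaled log2 matrix (samples x features), or an autoscaled
#'   \code{\link{abundance_matrix}}.
#' @param y binary 0/1 labels.
#' @param lambda_alpha,lambda_beta non-negative penalty levels.
#' @return An object of class \code{node_regression}: \code{alpha} and
#'   \code{beta} coefficient vectors of length p - 1 (indexed by the
#'   remaining features), \code{alpha_0} (intercept), \code{beta_0} (y main
#'   effect), the penalties, and \code{residual_variance}.
#' @export
node_lasso <- function(i, X, y, lambda_alpha, lambda_beta = lambda_alpha) {
  inp <- resolve_design_input(X, y)
  X <- inp$X; y <- inp$y
  if (!all(y %in% c(0, 1)) || length(unique(y)) != 2)
    stop("y must be binary 0/1 with both groups present")
  if (ncol(X) < 2) stop("need at least 2 features")
  if (lambda_alpha < 0 || lambda_beta < 0) stop("penalties must be >= 0")
  d <- node_design(i, X, y)
  n <- nrow(X)
  G <- crossprod(d$Z) / n
  g <- drop(crossprod(d$Z, d$x)) / n
  pen <- numeric(ncol(d$Z))
  pen[d$alpha_idx] <- lambda_alpha
  pen[d$beta_idx] <- lambda_beta
  b <- drop(cd_lasso_path(G, g, lambdas = 1, penalty = pen,
                          tol = 1e-7, max_iter = 5000L))
  r <- d$x - drop(d$Z %*% b)
  structure(list(i = i,
                 alpha = stats::setNames(b[d$alpha_idx],
                                         colnames(X)[-i]),
                 beta = stats::setNames(b[d$beta_idx], colnames(X)[-i]),
                 alpha_0 = d$x_mean - sum(b * d$col_means),
                 beta_0 = b[d$y_idx],
                 lambda_alpha = lambda_alpha, lambda_beta = lambda_beta,
                 residual_variance = sum(r^2) / n),
            class = "node_regression")
}

#' Select the penalty level for one node regression
#'
#' A single scalar penalty is shared between the alpha and beta blocks
#' (scaled by \code{beta_ratio} on the beta block) and chosen on a 50-point
#' log-spaced grid from the smallest all-zero penalty down by three decades.
#' \code{"bic"} scores each distinct support along the path by an extended
#' BIC on the least-squares refit: n log(RSS/n) + k (log n +
#' 2 gamma log p_design), with k the number of nonzero coefficients, p_design
#' the number of candidate columns and \code{gamma = 0.5} (the standard
#' extended-BIC default for sparse graphical model selection; plain BIC is
#' \code{gamma = 0}). Refitting removes the shrinkage bias from the
#' model-size score; the rule is deterministic and ties go to the sparser
#' fit. \code{"cv"} is 5-fold cross-validation with a fixed fold seed and
#' the one-standard-error rule.
#'
#' @param i response feature index.
#' @param X autoscaled matrix or \code{\link{abundance_matrix}}.
#' @param y 0/1 labels.
#' @param method \code{"bic"} or \code{"cv"}.
#' @param beta_ratio multiplier applied to the beta-block penalty
#'   (default 1: shared scalar).
#' @param n_lambda grid size (default 50).
#' @param gamma extended-BIC weight (default 0.5; 0 recovers plain BIC).
#' @param fold_seed seed for the CV fold assignment.
#' @return A list with \code{lambda_alpha}, \code{lambda_beta}, the
#'   \code{grid}, the per-grid-point \code{score} (BIC or CV error), and the
#'   coefficient path matrix \code{path}.
#' @export
select_lambda <- function(i, X, y, method = c("bic", "cv"), beta_ratio = 1,
                          n_lambda = 50, gamma = 0.5, fold_seed = 1L) {
  method <- match.arg(method)
  inp <- resolve_design_input(X, y)
  X <- inp$X; y <- inp$y
  d <- node_design(i, X, y)
  n <- nrow(X)
  G <- crossprod(d$Z) / n
  g <- drop(crossprod(d$Z, d$x)) / n
  pf <- numeric(ncol(d$Z))
  pf[d$alpha_idx] <- 1
  pf[d$beta_idx] <- beta_ratio
  # lambda_max: smallest penalty with every penalized coefficient zero,
  # computed from the residual of the unpenalized base fit x ~ y
  yc <- d$Z[, d$y_idx]
  by <- sum(yc * d$x) / sum(yc^2)
  r0 <- d$x - by * yc
  grad <- abs(drop(crossprod(d$Z, r0))) / n
  lam_max <- max(grad[pf > 0] / pf[pf > 0])
  if (lam_max <= 0) lam_max <- 1e-3
  # path floor: three decades below lambda_max in the tall regime, one
  # hundredth in a wide (p >= n) design where the unpenalized limit is
  # degenerate and coordinate descent has no unique target
  ratio <- if (ncol(d$Z) >= n) 1e-2 else 1e-3
  grid <- exp(seq(log(lam_max), log(lam_max * ratio), length.out = n_lambda))
  path <- cd_lasso_path(G, g, lambdas = grid, penalty = pf,
                        tol = 1e-7, max_iter = 5000L,
                        max_nnz = max(1L, n - 2L))
  if (method == "bic") {
    # score each distinct path support by extended BIC on its OLS refit
    Gn <- G * n; gn <- g * n; sxx <- sum(d$x^2)
    pz <- ncol(d$Z)
    score <- rep(Inf, n_lambda)
    seen <- list()
    for (l in seq_len(n_lambda)) {
      supp <- sort(unique(c(which(path[, l] != 0), d$y_idx)))
      key <- paste(supp, collapse = ",")
      if (!is.null(seen[[key]])) { score[l] <- seen[[key]]; next }
      if (length(supp) >= n - 1L) { seen[[key]] <- Inf; next }
      bs <- try(solve(Gn[supp, supp, drop = FALSE], gn[supp]), silent = TRUE)
      if (inherits(bs, "try-error")) { seen[[key]] <- Inf; next }
      rss <- sxx - sum(bs * gn[supp])
      if (rss <= 0) { seen[[key]] <- Inf; next }
      k <- length(supp)
      score[l] <- n * log(rss / n) + k * (log(n) + 2 * gamma * log(pz))
      seen[[key]] <- score[l]
    }
    best <- which(score <= min(score) + 1e-12)[1L]  # ties -> larger penalty
  } else {
    set.seed(fold_seed)
    folds <- sample(rep_len(seq_len(5L), n))
    cv_err <- matrix(NA_real_, 5L, n_lambda)
    for (f in seq_len(5L)) {
      tr <- folds != f
      Zt <- d$Z[tr, , drop = FALSE]; xt <- d$x[tr]
      Gt <- crossprod(Zt) / sum(tr)
      gt <- drop(crossprod(Zt, xt)) / sum(tr)
      pt <- cd_lasso_path(Gt, gt, lambdas = grid, penalty = pf,
                          tol = 1e-7, max_iter = 5000L,
                          max_nnz = max(1L, sum(tr) - 2L))
      resid <- d$x[!tr] - d$Z[!tr, , drop = FALSE] %*% pt
      cv_err[f, ] <- colMeans(resid^2)
    }
    m <- colMeans(cv_err)
    se <- apply(cv_err, 2L, stats::sd) / sqrt(5)
    best_min <- which.min(m)
    best <- which(m <= m[best_min] + se[best_min])[1L]  # 1-SE: sparser end
    score <- m
  }
  list(lambda_alpha = grid[best], lambda_beta = grid[best] * beta_ratio,
       grid = grid, score = score, best = best, path = path,
       alpha_idx = d$alpha_idx, beta_idx = d$beta_idx, y_idx = d$y_idx)
}

#' Build common and differential metabolite networks
#'
#' Runs the penalized node regression for every feature (each metabolite in
#' turn as the response, the remaining features as predictors) at its
#' selected penalty, then assembles the common network from the alpha
#' coefficients and the differential network from the beta coefficients.
#' Under \code{symmetrize = "or"} an edge (i, j) is present when either
#' direction's coefficient is nonzero (weight: mean of the nonzero
#' estimates); \code{"and"} requires both.
#'
#' @param X autoscaled log2 matrix of annotated features, or an autoscaled
#'   \code{\link{abundance_matrix}} (restricted to annotated features via
#'   \code{annotated_only}).
#' @param y 0/1 labels.
#' @param symmetrize \code{"or"} (union, the neighborhood-selection default)
#'   or \code{"and"} (intersection).
#' @param method penalty selection, \code{"bic"} or \code{"cv"}.
#' @param beta_ratio beta-block penalty multiplier (default 1, shared
#'   scalar).
#' @param annotated_only when \code{X} is an abundance matrix, restrict to
#'   annotated features (default TRUE).
#' @return An object of class \code{network_pair}: \code{nodes},
#'   \code{common_edges} and \code{diff_edges} data frames (\code{node_a},
#'   \code{node_b}, \code{weight}), and the coefficient matrices
#'   \code{alpha}, \code{beta} (row = response node).
#' @export
build_networks <- function(X, y, symmetrize = c("or", "and"),
                           method = c("bic", "cv"), beta_ratio = 1,
                           annotated_only = TRUE) {
  symmetrize <- match.arg(symmetrize)
  method <- match.arg(method)
  if (inherits(X, "abundance_matrix")) {
    if (missing(y) || is.null(y)) y <- X$y
    if (annotated_only) X <- subset_abundance(X, features = which(X$annotation == "known"))
    X <- X$values
  }
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  if (nrow(X) < 10) stop("network building needs at least 10 samples")
  nodes <- colnames(X)
  if (is.null(nodes)) nodes <- sprintf("feature_%04d", seq_len(p))
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(p)) {
    sel <- select_lambda(i, X, y, method = method, beta_ratio = beta_ratio)
    b <- sel$path[, sel$best]
    A[i, -i] <- b[sel$alpha_idx]
    B[i, -i] <- b[sel$beta_idx]
  }
  structure(list(nodes = nodes,
                 common_edges = symmetrize_edges(A, symmetrize),
                 diff_edges = symmetrize_edges(B, symmetrize),
                 alpha = A, beta = B, symmetrize = symmetrize),
            class = "network_pair")
}

symmetrize_edges <- function(M, rule) {
  nodes <- rownames(M)
  p <- ncol(M)
  out <- list()
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    a <- M[i, j]; b <- M[j, i]
    keep <- if (rule == "or") (a != 0 || b != 0) else (a != 0 && b != 0)
    if (keep) {
      nz <- c(a, b)[c(a, b) != 0]
      out[[length(out) + 1L]] <- data.frame(node_a = nodes[i], node_b = nodes[j],
                                            weight = mean(nz))
    }
  }
  if (length(out) == 0)
    return(data.frame(node_a = character(), node_b = character(),
                      weight = numeric()))
  do.call(rbind, out)
}

#' @export
print.network_pair <- function(x, ...) {
  cat(sprintf("network_pair: %d nodes, %d common edges, %d differential edges\n",
              length(x$nodes), nrow(x$common_edges), nrow(x$diff_edges)))
  invisible(x)
}

network_igraph <- function(edges, nodes) {
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Extract a seed-node module from the differential network
#'
#' Returns either the connected component of the differential network
#' containing the seed metabolite (\code{mode = "component"}) or the seed
#' plus its direct neighbors (\code{mode = "radius1"}). When univariate
#' screening results are supplied, each node carries an upregulated flag
#' (volcano-selected with fold change above 1).
#'
#' @param net a \code{network_pair}.
#' @param seed_node node name, must be present in the network.
#' @param mode \code{"component"} or \code{"radius1"}.
#' @param univariate optional output of \code{\link{univariate_screen}}.
#' @return An object of class \code{subnetwork}: \code{seed_node},
#'   \code{nodes}, \code{edges}, \code{upregulated} (named logical, NA when
#'   no univariate results are given).
#' @export
extract_module <- function(net, seed_node, mode = c("component", "radius1"),
                           univariate = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "network_pair"))
  if (!seed_node %in% net$nodes)
    stop(sprintf("seed node '%s' is not in the network", seed_node))
  g <- network_igraph(net$diff_edges, net$nodes)
  if (mode == "component") {
    comp <- igraph::components(g)
    members <- names(comp$membership)[comp$membership ==
                                        comp$membership[[seed_node]]]
  } else {
    members <- c(seed_node,
                 names(igraph::neighbors(g, seed_node)))
  }
  members <- unique(members)
  edges <- net$diff_edges[net$diff_edges$node_a %in% members &
                            net$diff_edges$node_b %in% members, , drop = FALSE]
  up <- stats::setNames(rep(NA, length(members)), members)
  if (!is.null(univariate)) {
    m <- match(members, univariate$feature_id)
    up <- stats::setNames(univariate$selected[m] & univariate$fold_change[m] > 1,
                          members)
  }
  structure(list(seed_node = seed_node, nodes = members, edges = edges,
                 upregulated = up, mode = mode),
            class = "subnetwork")
}

#' Export a network to SIF or GraphML
#'
#' SIF (Cytoscape simple interaction format): one line per edge,
#' \code{nodeA <layer> nodeB} with layer tag \code{common} or \code{diff};
#' isolated nodes are written alone on their own line. GraphML carries edge
#' \code{weight}/\code{layer} attributes and, when available, the node
#' \code{upregulated} attribute.
#'
#' @param x a \code{network_pair} or \code{subnetwork}.
#' @param path output file.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return Invisibly, the path.
#' @export
export_network <- function(x, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (inherits(x, "network_pair")) {
    edges <- rbind(
      if (nrow(x$common_edges)) cbind(x$common_edges, layer = "common"),
      if (nrow(x$diff_edges)) cbind(x$diff_edges, layer = "diff"))
    nodes <- x$nodes
    up <- NULL
  } else if (inherits(x, "subnetwork")) {
    edges <- if (nrow(x$edges)) cbind(x$edges, layer = "diff") else NULL
    nodes <- x$nodes
    up <- x$upregulated
  } else stop("unsupported object")
  if (is.null(edges))
    edges <- data.frame(node_a = character(), node_b = character(),
                        weight = numeric(), layer = character())
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$node_a, edges$layer, edges$node_b)
    isolated <- setdiff(nodes, unique(c(edges$node_a, edges$node_b)))
    writeLines(c(lines, isolated), path)
  } else {
    g <- network_igraph(edges[, c("node_a", "node_b", "weight", "layer")], nodes)
    if (!is.null(up)) igraph::V(g)$upregulated <- as.logical(up[nodes])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge list back from SIF or GraphML
#'
#' @param path file written by \code{\link{export_network}}.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return A list with \code{nodes} and \code{edges} (\code{node_a},
#'   \code{node_b}, \code{layer}, and \code{weight} for GraphML).
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    is_edge <- lengths(parts) == 3L
    edges <- if (any(is_edge)) {
      m <- do.call(rbind, parts[is_edge])
      data.frame(node_a = m[, 1L], node_b = m[, 3L], layer = m[, 2L])
    } else data.frame(node_a = character(), node_b = character(),
                      layer = character())
    singles <- unlist(parts[!is_edge])
    list(nodes = unique(c(edges$node_a, edges$node_b, singles)), edges = edges)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("node_a", "node_b")
    list(nodes = igraph::V(g)$name, edges = el)
  }
}

#' Write network edge lists as TSV
#'
#' Columns: \code{node_a}, \code{node_b}, \code{layer}, \code{weight}.
#'
#' @param net a \code{network_pair}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "network_pair"))
  edges <- rbind(
    if (nrow(net$common_edges)) cbind(net$common_edges, layer = "common"),
    if (nrow(net$diff_edges)) cbind(net$diff_edges, layer = "diff"))
  if (is.null(edges))
    edges <- data.frame(node_a = character(), node_b = character(),
                        weight = numeric(), layer = character())
  utils::write.table(edges[, c("node_a", "node_b", "layer", "weight")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
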