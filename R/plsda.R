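#' Fit a two-class PLS-DA model
#'
#' Iterative NIPALS-style partial least squares on an autoscaled predictor
#' matrix against the centered 0/1 class label. Per component, the weight
#' vector maximizes covariance between the X-score and the (deflated)
#' centered response; X is then deflated by its score-loading outer product.
#' For a univariate response each component has a closed-form weight
#' \eqn{w \propto X'y}, so no inner iteration is required.
#'
#' @param X autoscaled numeric matrix (samples x features), or an autoscaled
#'   \code{\link{abundance_matrix}}.
#' @param y binary 0/1 labels, both classes present.
#' @param n_components number of latent components (default 3); must not
#'   exceed the effective rank of X.
#' @return An object of class \code{plsda_model} with \code{x_scores},
#'   \code{x_loadings}, \code{x_weights}, \code{y_loadings}, the coefficient
#'   vector \code{coef} for predicting centered y, \code{y_mean}, and the
#'   centering/scaling statistics carried from the input.
#' @export
fit_plsda <- function(X, y, n_components = 3) {
  sc <- NULL
  if (inherits(X, "abundance_matrix")) {
    sc <- list(means = attr(X, "feature_means"), sds = attr(X, "feature_sds"))
    if (missing(y)) y <- X$y
    X <- X$values
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) != 2 || !all(y %in% c(0, 1)))
    stop("y must contain both classes, coded 0/1")
  n <- nrow(X); p <- ncol(X)
  if (n_components > min(n - 1, p)) stop("n_components exceeds the data rank")
  y_mean <- mean(y)
  u <- y - y_mean
  Xd <- X
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(Xd, u))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("n_components exceeds the data rank (degenerate component)")
    w <- w / nw
    tt <- drop(Xd %*% w)
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) stop("n_components exceeds the data rank (zero score)")
    pk <- drop(crossprod(Xd, tt)) / tt2
    qk <- sum(u * tt) / tt2
    Xd <- Xd - tcrossprod(tt, pk)
    u <- u - qk * tt
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tt; q[k] <- qk
  }
  # rotation mapping scaled X to scores: R = W (P'W)^{-1}
  R <- W %*% solve(crossprod(P, W))
  structure(list(n_components = n_components,
                 x_scores = Tm, x_loadings = P, x_weights = W,
                 y_loadings = q, rotation = R,
                 coef = drop(R %*% q), y_mean = y_mean,
                 feature_means = sc$means, feature_sds = sc$sds,
                 n_features = p),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d components over %d features\n",
              x$n_components, x$n_features))
  invisible(x)
}

#' Predict class labels from a fitted PLS-DA model
#'
#' Projects new samples (scaled with the model's stored feature means and
#' standard deviations when available) onto the latent components and
#' regresses the centered response on the scores. The predicted label is 1
#' when the centered prediction exceeds 0, the centered midpoint; an exact 0
#' (e.g. a degenerate all-zero scaled sample) falls to class 0.
#'
#' @param object a \code{plsda_model}.
#' @param newdata matrix of raw features (scaled internally when the model
#'   stores scaling statistics) or already-scaled features.
#' @param ... unused.
#' @return A list with \code{score} (predicted centered response) and
#'   \code{label} (0/1).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("newdata has %d features; the model was fitted with %d",
                 ncol(newdata), object$n_features))
  if (!is.null(object$feature_means))
    newdata <- sweep(sweep(newdata, 2L, object$feature_means), 2L,
                     object$feature_sds, "/")
  score <- drop(newdata %*% object$coef)
  list(score = score, label = as.integer(score > 0))
}

#' Separation distance of PLS-DA scores
#'
#' The permutation-test statistic: ratio of the between-group to the
#' within-group sum of squares of the score matrix, summed over components.
#' Zero within-group scatter yields \code{Inf}.
#'
#' @param x_scores samples x components score matrix.
#' @param y 0/1 labels.
#' @return The B/W ratio (non-negative, possibly \code{Inf}).
#' @export
separation_distance <- function(x_scores, y) {
  x_scores <- as.matrix(x_scores)
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  grand <- colMeans(x_scores)
  B <- 0; W <- 0
  for (g in c(0, 1)) {
    xg <- x_scores[y == g, , drop = FALSE]
    mg <- colMeans(xg)
    B <- B + nrow(xg) * sum((mg - grand)^2)
    W <- W + sum(sweep(xg, 2L, mg)^2)
  }
  if (W == 0) return(Inf)
  B / W
}

#' Leave-one-out cross-validation of PLS-DA
#'
#' For each sample, refits both the autoscaling and the PLS-DA model on the
#' remaining n - 1 samples (no information leakage) and predicts the held-out
#' sample.
#'
#' @param X raw (unscaled) numeric matrix or log2-scale
#'   \code{\link{abundance_matrix}}.
#' @param y 0/1 labels (taken from \code{X} when it is an abundance matrix).
#' @param n_components number of latent components.
#' @return A list with \code{predictions} (held-out 0/1 labels per sample)
#'   and \code{accuracy}.
#' @export
loo_cv <- function(X, y, n_components = 3) {
  if (inherits(X, "abundance_matrix")) {
    if (missing(y)) y <- X$y
    X <- X$values
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs at least 3 samples")
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("each class needs at least 2 members so no fold empties a class")
  preds <- integer(n)
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    mu <- colMeans(Xt)
    sdv <- apply(Xt, 2L, stats::sd)
    keep <- sdv > 0
    Xs <- sweep(sweep(Xt[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], "/")
    k <- min(n_components, nrow(Xs) - 1L, ncol(Xs))
    fit <- fit_plsda(Xs, y[-i], n_components = k)
    xnew <- (X[i, keep] - mu[keep]) / sdv[keep]
    preds[i] <- predict(fit, matrix(xnew, nrow = 1L))$label
  }
  list(predictions = preds, accuracy = mean(preds == y))
}

#' Permutation test of PLS-DA class separation
#'
#' Refits the model under B random relabelings and compares the observed
#' separation distance with the permuted null. The p-value uses the
#' add-one estimator p = (1 + #\{permuted >= observed\}) / (B + 1), which is
#' valid for any B; ties count as extreme.
#'
#' @param X autoscaled matrix or autoscaled \code{\link{abundance_matrix}}.
#' @param y 0/1 labels.
#' @param n_components latent components (default 3).
#' @param B number of permutations (default 2000).
#' @param seed integer seed for the permutation stream.
#' @return An object of class \code{permutation_result}: \code{observed_stat},
#'   \code{permuted_stats}, \code{p_value}, \code{B}, \code{seed}.
#' @export
permutation_test <- function(X, y, n_components = 3, B = 2000, seed = 1L) {
  if (inherits(X, "abundance_matrix")) {
    if (missing(y)) y <- X$y
    X <- X$values
  }
  X <- as.matrix(X); y <- as.numeric(y)
  if (B < 1) stop("B must be at least 1")
  fit_stat <- function(yy) {
    fit <- try(fit_plsda(X, yy, n_components = n_components), silent = TRUE)
    if (inherits(fit, "try-error")) return(0)
    separation_distance(fit$x_scores, yy)
  }
  observed <- fit_stat(y)
  set.seed(seed)
  permuted <- vapply(seq_len(B), function(b) fit_stat(sample(y)), numeric(1))
  p <- (1 + sum(permuted >= observed)) / (B + 1)
  structure(list(observed_stat = observed, permuted_stats = permuted,
                 p_value = p, B = B, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed separation %.4g, B = %d, p = %.4g\n",
              x$observed_stat, x$B, x$p_value))
  invisible(x)
}
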