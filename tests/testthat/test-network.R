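autoscaled_xy <- function(n = 120, p = 6, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = rep_len(c(0, 1), n))
}

test_that("node_lasso at zero penalty matches the normal equations", {
  d <- autoscaled_xy(n = 200, p = 6, seed = 1)
  fit <- node_lasso(1, d$X, d$y, lambda_alpha = 0, lambda_beta = 0)
  des <- metdiffnet:::node_design(1, d$X, d$y)
  ols <- drop(solve(crossprod(des$Z), crossprod(des$Z, des$x)))
  got <- c(fit$alpha, fit$beta_0, fit$beta)
  expect_equal(unname(got), unname(ols), tolerance = 1e-6)
})

test_that("a penalty at the gradient bound zeroes every alpha and beta", {
  d <- autoscaled_xy(n = 80, p = 5, seed = 2)
  fit <- node_lasso(2, d$X, d$y, lambda_alpha = 10, lambda_beta = 10)
  expect_true(all(fit$alpha == 0))
  expect_true(all(fit$beta == 0))
  # the unpenalized y main effect is still fitted
  sel <- select_lambda(2, d$X, d$y)
  top <- node_lasso(2, d$X, d$y, max(sel$grid) * 1.0001)
  expect_true(all(top$alpha == 0) && all(top$beta == 0))
})

test_that("node_lasso agrees with glmnet on the same design", {
  skip_if_not_installed("glmnet")
  d <- autoscaled_xy(n = 150, p = 5, seed = 3)
  des <- metdiffnet:::node_design(1, d$X, d$y)
  lam <- 0.08
  pf <- c(rep(1, 4), 0, rep(1, 4))
  gfit <- glmnet::glmnet(des$Z, des$x, lambda = lam, standardize = FALSE,
                         penalty.factor = pf, thresh = 1e-12, intercept = TRUE)
  # glmnet rescales penalty factors to sum to nvars; undo for comparison
  lam_eff <- lam * length(pf) / sum(pf)
  mine <- node_lasso(1, d$X, d$y, lambda_alpha = lam_eff,
                     lambda_beta = lam_eff)
  expect_equal(unname(c(mine$alpha, mine$beta_0, mine$beta)),
               unname(as.numeric(gfit$beta)), tolerance = 1e-4)
})

test_that("edge sets shrink monotonically along the penalty path", {
  d <- autoscaled_xy(n = 60, p = 8, seed = 4)
  sel <- select_lambda(3, d$X, d$y)
  nnz <- colSums(sel$path != 0)
  supports <- apply(sel$path != 0, 2, which, simplify = FALSE)
  # grid descends from lambda_max: supports grow (nested up to CD tolerance)
  for (l in seq_len(length(supports) - 1)) {
    expect_lte(nnz[l], nnz[l + 1] + 1e-9)
  }
})

test_that("penalty selection is deterministic and finds planted predictors", {
  d <- autoscaled_xy(n = 100, p = 5, seed = 5)
  s1 <- select_lambda(1, d$X, d$y, method = "bic")
  s2 <- select_lambda(1, d$X, d$y, method = "bic")
  expect_identical(s1$lambda_alpha, s2$lambda_alpha)
  c1 <- select_lambda(1, d$X, d$y, method = "cv", fold_seed = 7)
  c2 <- select_lambda(1, d$X, d$y, method = "cv", fold_seed = 7)
  expect_identical(c1$lambda_alpha, c2$lambda_alpha)

  # a strong single predictor survives selection in every seed
  hits <- sapply(1:20, function(seed) {
    set.seed(seed)
    n <- 100
    X <- matrix(rnorm(n * 5), n)
    X[, 1] <- 5 * X[, 2] + rnorm(n, sd = 0.1)
    X <- scale(X); colnames(X) <- paste0("f", 1:5)
    y <- rep_len(c(0, 1), n)
    sel <- select_lambda(1, X, y)
    b <- sel$path[, sel$best]
    b[sel$alpha_idx][1] != 0   # predictor f2 is the first alpha column
  })
  expect_equal(sum(hits), 20L)

  # pure-noise response: selection stays essentially empty
  nnz <- sapply(1:20, function(seed) {
    d <- autoscaled_xy(n = 100, p = 5, seed = 100 + seed)
    sel <- select_lambda(1, d$X, d$y)
    b <- sel$path[, sel$best]
    sum(b[c(sel$alpha_idx, sel$beta_idx)] != 0)
  })
  expect_lte(mean(nnz), 1)
})

test_that("no group effect in truth yields an empty differential block", {
  empties <- sapply(1:20, function(seed) {
    spec <- synthetic_spec(n_case = 250, n_control = 250, p_known = 10,
                           p_unknown = 0, n_common_edges = 5,
                           n_diff_edges = 0, seed = 200 + seed)
    ds <- generate_dataset(spec)
    A <- autoscale(log2_transform(ds$data))
    sel <- select_lambda(1, A$values, A$y)
    b <- sel$path[, sel$best]
    all(b[sel$beta_idx] == 0)
  })
  expect_gte(sum(empties), 18L)
})

test_that("built networks recover planted structure and respect symmetrization", {
  spec <- synthetic_spec(n_case = 400, n_control = 400, p_known = 12,
                         p_unknown = 0, n_common_edges = 6, n_diff_edges = 3,
                         edge_strength = 0.4, seed = 33)
  ds <- generate_dataset(spec)
  A <- autoscale(log2_transform(ds$data))
  net_or <- build_networks(A$values, A$y, symmetrize = "or")
  net_and <- build_networks(A$values, A$y, symmetrize = "and")
  # planted common edges are mostly found
  tkey <- edge_key(ds$truth$common_edges$i, ds$truth$common_edges$j)
  okey <- net_edge_key(net_or$common_edges, A$feature_ids)
  expect_gte(mean(tkey %in% okey), 0.8)
  # "and" edges are a subset of "or" edges on identical fits
  expect_true(all(net_edge_key(net_and$common_edges, A$feature_ids) %in% okey))
  expect_true(all(net_edge_key(net_and$diff_edges, A$feature_ids) %in%
                    net_edge_key(net_or$diff_edges, A$feature_ids)))
})

test_that("permuting feature order permutes edge endpoints consistently", {
  spec <- synthetic_spec(n_case = 200, n_control = 200, p_known = 8,
                         p_unknown = 0, n_common_edges = 4, n_diff_edges = 2,
                         seed = 12)
  ds <- generate_dataset(spec)
  A <- autoscale(log2_transform(ds$data))
  net <- build_networks(A$values, A$y)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  net_p <- build_networks(A$values[, perm], A$y)
  key <- function(net) {
    e <- net$common_edges
    sort(edge_key(e$node_a, e$node_b))
  }
  expect_identical(key(net_p), key(net))
  expect_identical(sort(edge_key(net_p$diff_edges$node_a, net_p$diff_edges$node_b)),
                   sort(edge_key(net$diff_edges$node_a, net$diff_edges$node_b)))
})

test_that("module extraction walks components and radius-1 neighborhoods", {
  # hand-built 3-node chain a-b-c plus isolated d in the differential layer
  net <- structure(list(
    nodes = c("a", "b", "c", "d"),
    common_edges = data.frame(node_a = character(), node_b = character(),
                              weight = numeric()),
    diff_edges = data.frame(node_a = c("a", "b"), node_b = c("b", "c"),
                            weight = c(0.5, -0.3)),
    alpha = NULL, beta = NULL, symmetrize = "or"), class = "network_pair")
  comp <- extract_module(net, "a", mode = "component")
  expect_setequal(comp$nodes, c("a", "b", "c"))
  r1 <- extract_module(net, "a", mode = "radius1")
  expect_setequal(r1$nodes, c("a", "b"))
  solo <- extract_module(net, "d", mode = "component")
  expect_equal(solo$nodes, "d")
  expect_equal(nrow(solo$edges), 0L)
  expect_error(extract_module(net, "zzz"), "not in the network")

  uni <- data.frame(feature_id = c("a", "b", "c", "d"),
                    fold_change = c(2, 0.5, 1.5, 1),
                    selected = c(TRUE, TRUE, FALSE, FALSE))
  comp2 <- extract_module(net, "a", univariate = uni)
  expect_true(comp2$upregulated[["a"]])
  expect_false(comp2$upregulated[["b"]])   # selected but downregulated
  expect_false(comp2$upregulated[["c"]])
})

test_that("networks round-trip through SIF and GraphML", {
  net <- structure(list(
    nodes = c("a", "b", "c", "lonely"),
    common_edges = data.frame(node_a = "a", node_b = "b", weight = 0.4),
    diff_edges = data.frame(node_a = "b", node_b = "c", weight = -0.2),
    alpha = NULL, beta = NULL, symmetrize = "or"), class = "network_pair")
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, format = "sif")
  lines <- readLines(sif)
  expect_length(grep("\t", lines), 2L)       # exactly 2 edge lines
  expect_true("lonely" %in% lines)           # singleton convention
  back <- read_network(sif, format = "sif")
  expect_setequal(back$nodes, net$nodes)
  expect_setequal(paste(back$edges$node_a, back$edges$layer, back$edges$node_b),
                  c("a common b", "b diff c"))

  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, format = "graphml")
  back2 <- read_network(gml, format = "graphml")
  expect_setequal(back2$nodes, net$nodes)
  expect_setequal(edge_key(back2$edges$node_a, back2$edges$node_b),
                  c(edge_key("a", "b"), edge_key("b", "c")))
  expect_setequal(back2$edges$layer, c("common", "diff"))
  expect_setequal(back2$edges$weight, c(0.4, -0.2))

  expect_error(export_network(net, tempfile(), format = "dot"), "arg")
})
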