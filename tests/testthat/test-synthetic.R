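test_that("precision pairs are symmetric positive-definite with planted supports", {
  for (seed in c(1, 7, 42)) {
    spec <- synthetic_spec(p_known = 15, p_unknown = 5, n_common_edges = 8,
                           n_diff_edges = 4, seed = seed)
    pp <- make_precision_pair(spec)
    expect_equal(pp$precision_control, t(pp$precision_control))
    expect_equal(pp$precision_case, t(pp$precision_case))
    # independent eigendecomposition oracle for positive definiteness
    expect_gt(min(eigen(pp$precision_control, symmetric = TRUE)$values), 0)
    expect_gt(min(eigen(pp$precision_case, symmetric = TRUE)$values), 0)
    # off-diagonal differences are exactly the planted differential pairs
    diff_mask <- (pp$precision_case != pp$precision_control)
    diag(diff_mask) <- FALSE
    got <- which(diff_mask & upper.tri(diff_mask), arr.ind = TRUE)
    expect_setequal(edge_key(got[, 1], got[, 2]),
                    edge_key(pp$diff_edges$i, pp$diff_edges$j))
    expect_equal(nrow(pp$common_edges), 8)
    expect_equal(nrow(pp$diff_edges), 4)
  }
})

test_that("degenerate precision specs behave as documented", {
  spec0 <- synthetic_spec(p_known = 10, p_unknown = 0, n_common_edges = 5,
                          n_diff_edges = 0, seed = 3)
  pp0 <- make_precision_pair(spec0)
  expect_identical(pp0$precision_case, pp0$precision_control)

  spec1 <- synthetic_spec(p_known = 1, p_unknown = 0, seed = 3)
  pp1 <- make_precision_pair(spec1)
  expect_equal(dim(pp1$precision_case), c(1L, 1L))
  expect_gt(pp1$precision_case[1, 1], 0)

  expect_error(synthetic_spec(p_known = 3, p_unknown = 0, n_common_edges = 4),
               "exceed")
  expect_error(synthetic_spec(edge_strength = 1.2), "edge_strength")
  expect_error(synthetic_spec(n_case = 1), "at least 2")
})

test_that("generated datasets have the documented cohort geometry", {
  ds <- generate_dataset(synthetic_spec(seed = 5))
  expect_equal(dim(ds$data$values), c(63L, 490L))
  expect_equal(sum(ds$data$y == 1L), 42L)
  expect_equal(sum(ds$data$y == 0L), 21L)
  expect_equal(sum(ds$data$annotation == "known"), 200L)
  expect_equal(sum(startsWith(ds$data$feature_ids, "Unknown BB_")), 290L)
  expect_true(all(ds$data$values > 0))
})

test_that("identical spec and seed reproduce the dataset bitwise", {
  spec <- synthetic_spec(p_known = 20, p_unknown = 10, n_common_edges = 5,
                         n_diff_edges = 3, effects = list(c(2, 0.8)), seed = 11)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$truth, b$truth)
})

test_that("planted effects surface at the planted fold change", {
  spec <- synthetic_spec(n_case = 500, n_control = 500, p_known = 10,
                         p_unknown = 0, effects = list(c(5, 1)), seed = 21)
  ds <- generate_dataset(spec)
  fc <- fold_change(ds$data)
  expect_gt(fc[5], 1.8)
  expect_lt(fc[5], 2.2)
})

test_that("a null spec produces no systematic group differences", {
  spec <- synthetic_spec(n_case = 500, n_control = 500, p_known = 50,
                         p_unknown = 0, seed = 31)
  ds <- generate_dataset(spec)
  z <- log2(ds$data$values / spec$base_intensity)
  case <- z[ds$data$y == 1, ]; ctrl <- z[ds$data$y == 0, ]
  se <- sqrt(apply(case, 2, var) / nrow(case) + apply(ctrl, 2, var) / nrow(ctrl))
  frac_ok <- mean(abs(colMeans(case) - colMeans(ctrl)) <= 3 * se)
  expect_gte(frac_ok, 0.99)
})

test_that("sample covariance of log2 data converges to the inverse precision", {
  frob <- sapply(c(100, 1000), function(n) {
    spec <- synthetic_spec(n_case = n, n_control = 2, p_known = 10,
                           p_unknown = 0, n_common_edges = 6, seed = 13)
    ds <- generate_dataset(spec)
    z <- log2(ds$data$values[ds$data$y == 1, ] / spec$base_intensity)
    sigma <- solve(ds$truth$precision_case)
    sqrt(sum((cov(z) - sigma)^2))
  })
  expect_lt(frob[2], frob[1])
})

test_that("the packaged differential-metabolite table is intact", {
  tab <- ic_diff_table()
  expect_equal(nrow(tab), 30L)
  expect_true(all(diff(tab$p_value) > 0))
  expect_equal(sum(!startsWith(tab$name, "Unknown")), 12L)
  expect_equal(tab$name[1], "Unknown BB_31554")
  expect_equal(tab$fold_change[1], 2.56)
  expect_equal(tab$p_value[1], 0.000132)
  expect_equal(tab$fdr[1], 0.064576)
  expect_equal(tab$name[25], "histidine")
  expect_equal(tab$fold_change[25], 1.79)
  expect_equal(tab$p_value[25], 0.040576)
})

test_that("ground truth serializes to readable plain text", {
  spec <- synthetic_spec(p_known = 8, p_unknown = 0, n_common_edges = 3,
                         n_diff_edges = 2, effects = list(c(1, 0.5)), seed = 2)
  ds <- generate_dataset(spec)
  ef <- tempfile(fileext = ".tsv"); ed <- tempfile(fileext = ".tsv")
  write_ground_truth(ds$truth, ef, ed)
  eff <- read.delim(ef)
  edges <- read.delim(ed)
  expect_equal(eff$log2fc[1], 0.5)
  expect_equal(sum(edges$layer == "common"), 3L)
  expect_equal(sum(edges$layer == "diff"), 2L)
})
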