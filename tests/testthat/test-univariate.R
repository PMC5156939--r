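test_that("fold change is the ratio of linear group means", {
  vals <- rbind(matrix(4, 3, 2), matrix(2, 3, 2))
  M <- abundance_matrix(vals, y = rep(c(1, 0), each = 3))
  expect_equal(unname(fold_change(M)), c(2, 2))
  M2 <- abundance_matrix(rbind(matrix(5, 3, 2), matrix(5, 3, 2)),
                         y = rep(c(1, 0), each = 3))
  expect_equal(unname(fold_change(M2)), c(1, 1))
})

test_that("a planted log2 effect of 1.17 yields a fold change near 2.25", {
  spec <- synthetic_spec(n_case = 1000, n_control = 1000, p_known = 5,
                         p_unknown = 0, effects = list(c(2, 1.17)), seed = 8)
  ds <- generate_dataset(spec)
  fc <- fold_change(ds$data)
  expect_gt(fc[2], 2.1)
  expect_lt(fc[2], 2.4)
})

test_that("the pooled t-test matches its closed form and stats::t.test", {
  # groups (1,2,3) vs (4,5,6): pooled sd = 1, se = sqrt(2/3), 4 df
  vals <- matrix(2^c(1, 2, 3, 4, 5, 6), ncol = 1)
  M <- abundance_matrix(vals, y = c(1, 1, 1, 0, 0, 0))
  tt <- feature_t_test(log2_transform(M))
  t_hand <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(tt$t_stat, t_hand)
  expect_equal(tt$p_value, 2 * pt(t_hand, df = 4))

  same <- abundance_matrix(matrix(2^c(1, 2, 3, 1, 2, 3), ncol = 1),
                           y = c(1, 1, 1, 0, 0, 0))
  tts <- feature_t_test(log2_transform(same))
  expect_equal(tts$t_stat, 0)
  expect_equal(tts$p_value, 1)

  expect_error(feature_t_test(log2_transform(
    abundance_matrix(matrix(c(1, 2, 3), ncol = 1), y = c(1, 0, 0)))),
    "at least 2")
})

test_that("bh_adjust matches a brute-force step-up oracle", {
  set.seed(6)
  for (rep in 1:10) {
    k <- sample(3:40, 1)
    p <- runif(k)
    expect_equal(bh_adjust(p), bh_brute(p, k), tolerance = 1e-12)
    m <- k + sample(0:50, 1)
    expect_equal(bh_adjust(p, m), bh_brute(p, m), tolerance = 1e-12)
  }
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(runif(10), 5), "m_total")
  expect_error(bh_adjust(c(0.5, 1.2)), "p-values")
})

test_that("BH adjusted values are monotone in the ordered p-values", {
  set.seed(7)
  p <- runif(25)
  adj <- bh_adjust(p, 100)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("volcano selection uses strict fold-change and p thresholds", {
  res <- data.frame(fold_change = c(2.25, 1.0, 1.20, 0.83, 1.21, 0.82, 1.5),
                    p_value = c(0.018393, 1e-9, 0.01, 0.01, 0.09, 0.1, 0.1))
  expect_equal(volcano_select(res),
               c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  tab <- ic_diff_table()
  expect_true(all(volcano_select(tab)))   # every reported row passes the rule
})

test_that("annotated_subset retains only named metabolites", {
  tab <- ic_diff_table()
  expect_equal(nrow(annotated_subset(tab)), 12L)
  expect_equal(nrow(annotated_subset(tab[0, ])), 0L)
  allunk <- tab[startsWith(tab$name, "Unknown"), ]
  expect_equal(nrow(annotated_subset(allunk)), 0L)
  flagged <- data.frame(feature_id = c("a", "b"),
                        annotation = c("known", "unknown"))
  expect_equal(annotated_subset(flagged)$feature_id, "a")
})

test_that("null p-values are uniform and the screen has power at the study size", {
  # uniformity under the null generator
  rejects <- sum(sapply(1:20, function(seed) {
    ds <- generate_dataset(synthetic_spec(p_known = 100, p_unknown = 0,
                                          seed = seed))
    tt <- feature_t_test(log2_transform(ds$data))
    ks.test(tt$p_value, "punif")$p.value < 0.01
  }))
  expect_lte(rejects, 2L)

  # power: planted log2fc = 1 at 42/21 detected in most replicates
  hits <- sum(sapply(1:100, function(seed) {
    ds <- generate_dataset(synthetic_spec(p_known = 5, p_unknown = 0,
                                          effects = list(c(1, 1)),
                                          seed = 1000 + seed))
    feature_t_test(log2_transform(ds$data))$p_value[1] < 0.05
  }))
  expect_gte(hits, 80L)
})

test_that("univariate_screen assembles consistent per-feature results", {
  spec <- synthetic_spec(n_case = 30, n_control = 30, p_known = 8,
                         p_unknown = 4, effects = list(c(3, 2)), seed = 17)
  ds <- generate_dataset(spec)
  res <- univariate_screen(ds$data, md_thresholds(m_total = 50))
  expect_equal(nrow(res), 12L)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_equal(res$log2fc, log2(res$fold_change))
  expect_true(res$selected[3])   # a 4-fold effect at n=60 is unmissable
  f <- tempfile(fileext = ".tsv")
  write_univariate(res, f)
  back <- read.delim(f)
  expect_equal(back$p_value, sort(res$p_value))
})
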