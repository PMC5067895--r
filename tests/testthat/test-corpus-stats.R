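test_that("the exact signed-rank tail matches closed forms and wilcox.test", {
  # 14 equal positive differences: W+ is maximal, one-sided p = 1 / 2^14
  tst <- signed_rank_test(rep(0.1, 14))
  expect_equal(tst$statistic, 14 * 15 / 2)
  expect_equal(tst$p_value, 2^-14)
  expect_true(tst$exact)

  # no ties, mixed signs: must agree with the reference exact implementation
  set.seed(2)
  for (i in 1:8) {
    x <- round(stats::rnorm(sample(5:15, 1)), 3)
    x <- x[x != 0]
    if (anyDuplicated(abs(x))) next
    ref <- suppressWarnings(stats::wilcox.test(x, mu = 0,
                                               alternative = "greater",
                                               exact = TRUE))
    expect_equal(signed_rank_test(x)$p_value, unname(ref$p.value),
                 tolerance = 1e-12)
  }
  # zeros are dropped; an all-zero sample is degenerate
  expect_equal(signed_rank_test(c(0, 0, 0.5))$n, 1L)
  expect_true(is.na(signed_rank_test(rep(0, 5))$p_value))
})

test_that("wilcoxon ranking orders pairs by the median absolute difference", {
  mk <- function(version, values) {
    tibble::tibble(version = version, metric = oq_metric_ids(), value = values)
  }
  base <- seq(1, 2.3, length.out = 14)
  metrics <- dplyr::bind_rows(
    mk("v1", base),
    mk("v2", base + 0.01),            # pair A: small uniform |diff|
    mk("v3", base + 0.01 + 0.6),      # pair B: large uniform |diff|
    mk("v4", base + 0.01 + 0.6)       # pair C: identical -> degenerate
  )
  metrics$version <- factor(metrics$version, levels = paste0("v", 1:4))
  res <- wilcoxon_consecutive(metrics)
  expect_equal(nrow(res), 3)
  expect_true(res$degenerate[res$version == "v4"])
  ranked <- res$version[!res$degenerate]
  expect_equal(ranked, c("v2", "v3"))  # smaller estimate first
  expect_equal(res$estimate[res$version == "v2"], 0.01)
  expect_equal(res$estimate[res$version == "v3"], 0.6)
  expect_equal(res$p_value[res$version == "v3"], 2^-14)
})

test_that("perfectly correlated variables collapse onto one component", {
  set.seed(5)
  x <- stats::rnorm(10)
  cs <- tibble::tibble(version = paste0("v", 1:10), backward_size = x,
                       forward_size = x, mean_change = x)
  act <- tibble::tibble(version = paste0("v", 1:10), n_new = x,
                        n_deleted = x, n_changed = x)
  p <- pca_activity(cs, act)
  expect_equal(p$explained[[1]], 1, tolerance = 1e-9)
  expect_equal(unname(abs(p$loadings[, 1])), rep(1, 6), tolerance = 1e-6)
})

test_that("PCA recovers a planted two-factor structure up to sign", {
  set.seed(8)
  n <- 400
  f1 <- stats::rnorm(n)
  f2 <- stats::rnorm(n)
  # the two blocks get different noise levels so the eigenvalues separate and
  # the components are identifiable (not an arbitrary rotation)
  noise <- function(sd) stats::rnorm(n, sd = sd)
  cs <- tibble::tibble(version = paste0("v", seq_len(n)),
                       backward_size = f2 + noise(0.5),
                       forward_size = f2 + noise(0.5),
                       mean_change = f2 + noise(0.5))
  act <- tibble::tibble(version = paste0("v", seq_len(n)),
                        n_new = f1 + noise(0.1),
                        n_deleted = f1 + noise(0.1),
                        n_changed = f1 + noise(0.1))
  p <- pca_activity(cs, act)
  L <- abs(p$loadings)
  act_vars <- c("n_new", "n_deleted", "n_changed")
  qual_vars <- c("backward_size", "forward_size", "mean_change")
  # each block loads on its own factor (order/sign of factors is arbitrary)
  block1 <- which.max(colSums(L[act_vars, ]))
  block2 <- setdiff(1:2, block1)
  expect_true(all(L[act_vars, block1] > 0.9))
  expect_true(all(L[qual_vars, block2] > 0.75))
  expect_true(all(L[act_vars, block2] < 0.3))
  expect_true(all(L[qual_vars, block1] < 0.3))
  expect_true(all(diff(p$explained) <= 1e-9))
  expect_equal(sum(p$explained), 1)
  td <- tidy(p)
  expect_setequal(names(td), c("variable", "component", "loading"))
  expect_equal(nrow(td), 12)
})

test_that("independent variables spread variance around 1/6", {
  set.seed(13)
  n <- 5000
  cs <- tibble::tibble(version = paste0("v", seq_len(n)),
                       backward_size = stats::rnorm(n),
                       forward_size = stats::rnorm(n),
                       mean_change = stats::rnorm(n))
  act <- tibble::tibble(version = paste0("v", seq_len(n)),
                        n_new = stats::rnorm(n),
                        n_deleted = stats::rnorm(n),
                        n_changed = stats::rnorm(n))
  p <- pca_activity(cs, act)
  expect_equal(p$explained[[1]], 1 / 6, tolerance = 0.05)
})

test_that("constant variables are excluded from the PCA with a warning", {
  set.seed(3)
  x <- stats::rnorm(8)
  cs <- tibble::tibble(version = paste0("v", 1:8), backward_size = x,
                       forward_size = rev(x), mean_change = 1)
  act <- tibble::tibble(version = paste0("v", 1:8), n_new = x^2,
                        n_deleted = abs(x), n_changed = x + rev(x) * 0.5)
  expect_warning(p <- pca_activity(cs, act), "mean_change")
  expect_false("mean_change" %in% rownames(p$loadings))
})

test_that("pearson_pairs covers all pairs with exact limiting cases", {
  x <- c(1, 2, 3, 4, 5)
  df <- tibble::tibble(a = x, b = x, c = -x, d = c(2, 1, 4, 3, 5))
  pp <- pearson_pairs(df)
  expect_equal(nrow(pp), choose(4, 2))
  expect_equal(pp$estimate[pp$var1 == "a" & pp$var2 == "b"], 1)
  expect_equal(pp$estimate[pp$var1 == "a" & pp$var2 == "c"], -1)
  set.seed(10)
  n <- 1000
  z <- stats::rnorm(n)
  sim <- tibble::tibble(u = z, v = 0.8 * z + sqrt(1 - 0.64) * stats::rnorm(n),
                        w = stats::rnorm(n))
  pp2 <- pearson_pairs(sim)
  expect_equal(pp2$estimate[pp2$var1 == "u" & pp2$var2 == "v"], 0.8,
               tolerance = 0.05)
  expect_error(pearson_pairs(tibble::tibble(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant")
})
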