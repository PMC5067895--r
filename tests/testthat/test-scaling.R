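test_that("static scale reproduces the published anchor scores", {
  expect_equal(static_score("TMOnto", 1.28), 5L)
  expect_equal(static_score("RROnto", 0.74), 4L)   # 74 % -> (60, 80]
  expect_equal(static_score("DITOnto", 11), 1L)    # > 8
  # printed boundary: LCOMOnto "<=2" is score 5, "(2, 4]" is 4
  expect_equal(static_score("LCOMOnto", c(2, 2.0001)), c(5L, 4L))
  # percent metrics clamp above 100 %
  expect_equal(static_score("ANOnto", 1.5), 5L)
  # TMOnto below the lowest printed bin clamps to the best score
  expect_equal(static_score("TMOnto", 0.1), 5L)
  expect_error(static_score("NotAMetric", 1), "unknown metric")
  expect_error(static_score("TMOnto", -1), "non-negative")
})

test_that("scores are always integers in 1..5 and direction-monotone", {
  set.seed(99)
  for (metric in oq_metric_ids()) {
    raw <- sort(c(0, runif(40, 0, 20), 1:15))
    sc <- static_score(metric, raw)
    expect_true(all(sc %in% 1:5))
    d <- diff(sc)
    if (oq_metric_direction(metric) == "lower_better") {
      expect_true(all(d <= 0), label = paste("static monotone", metric))
    } else {
      expect_true(all(d >= 0), label = paste("static monotone", metric))
    }
    # dynamic scale fitted on the same values must be monotone too
    dyn <- fit_dynamic_scale(tibble::tibble(metric = metric, value = raw))
    ds <- dynamic_score(dyn, metric, raw)
    expect_true(all(ds %in% 1:5))
    d2 <- diff(ds)
    if (oq_metric_direction(metric) == "lower_better") {
      expect_true(all(d2 <= 0), label = paste("dynamic monotone", metric))
    } else {
      expect_true(all(d2 >= 0), label = paste("dynamic monotone", metric))
    }
    # the best observed raw value always scores 5
    best <- if (oq_metric_direction(metric) == "lower_better") min(raw) else max(raw)
    expect_equal(dynamic_score(dyn, metric, best), 5L)
  }
})

test_that("dynamic scale reproduces the published depth-metric intervals", {
  dit <- c(11, 11, 11, 11, 13, 13, 14, 13, 13, 13, 13, 12, 12, 12)
  sc <- fit_dynamic_scale(tibble::tibble(metric = "DITOnto", value = dit))
  expect_equal(sc$score, c(5L, 4L, 3L, 2L))  # score 1 category left empty
  expect_equal(sc$lo, c(11, 12, 13, 14))
  expect_equal(sc$hi, c(11, 12, 13, 14))
  traj <- dynamic_score(sc, "DITOnto", dit)
  expect_equal(traj[[1]], 5L)
  expect_equal(traj[[7]], 2L)
  expect_equal(traj[[length(traj)]], 4L)
})

test_that("a constant sequence maps everything to score 5", {
  sc <- fit_dynamic_scale(tibble::tibble(metric = "WMCOnto", value = rep(3.3, 6)))
  expect_equal(sc$score, 5L)
  expect_equal(dynamic_score(sc, "WMCOnto", c(3.3, 0, 100)), rep(5L, 3))
})

test_that("two well-separated groups split exactly as brute-force 2-means", {
  values <- c(0.1, 0.12, 0.11, 0.13, 0.1, 5.0, 5.2, 5.1, 5.3, 5.05)
  oracle <- brute_kmeans_cost(values, 2)
  sc <- fit_dynamic_scale(tibble::tibble(metric = "RROnto", value = values), k = 2)
  expect_equal(nrow(sc), 2)
  expect_equal(dynamic_scale_cost(sc, "RROnto", values), oracle$cost,
               tolerance = 1e-10)
  expect_equal(sc$hi[sc$score == min(sc$score)], max(values[values < 1]))
})

test_that("exact k-means equals exhaustive variance minimisation (<= 12 distinct)", {
  set.seed(7)
  for (rep in 1:12) {
    nd <- sample(2:12, 1)
    k <- sample(seq_len(min(5, nd)), 1)
    values <- sample(round(runif(nd, 0, 10), 2))
    values <- c(values, sample(values, sample(0:5, 1), replace = TRUE))  # ties
    oracle <- brute_kmeans_cost(values, k)
    sc <- fit_dynamic_scale(tibble::tibble(metric = "NOMOnto", value = values),
                            k = k)
    expect_equal(dynamic_scale_cost(sc, "NOMOnto", values), oracle$cost,
                 tolerance = 1e-9,
                 label = sprintf("k-means optimality rep %d (n=%d, k=%d)",
                                 rep, nd, k))
  }
})

test_that("score_vector propagates undefined metrics and records the scale", {
  m <- tibble::tibble(metric = c("TMOnto", "CBOnto"), value = c(1.28, NA))
  sv <- score_vector(m, "static")
  expect_equal(sv$score, c(5L, NA))
  expect_equal(attr(sv, "scale_type"), "static")
})

test_that("a fitted dynamic scale survives a JSON round-trip", {
  raw <- tibble::tibble(
    metric = rep(c("DITOnto", "RROnto"), each = 6),
    value = c(11, 11, 12, 13, 14, 12, 0.1, 0.15, 0.4, 0.41, 0.74, 0.75)
  )
  sc <- fit_dynamic_scale(raw)
  f <- withr::local_tempfile(fileext = ".json")
  write_dynamic_scale(sc, f)
  sc2 <- read_dynamic_scale(f)
  expect_equal(
    dplyr::arrange(as.data.frame(sc), metric, score),
    dplyr::arrange(as.data.frame(sc2), metric, score),
    ignore_attr = TRUE
  )
  expect_equal(dynamic_score(sc2, "RROnto", 0.74), dynamic_score(sc, "RROnto", 0.74))
})
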