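test_that("change vectors reproduce the four-metric running example", {
  s <- example_scores()
  expect_equal(unname(change_in_scale(s[1, ], s[2, ])), c(0, 0, 0, 0))
  expect_equal(unname(change_in_scale(s[2, ], s[3, ])), c(-1, -1, 0, 0))
  expect_equal(unname(change_in_scale(s[3, ], s[4, ])), c(-1, 1, 3, 0))
  expect_equal(unname(change_in_scale(s[5, ], s[6, ])), c(4, -4, -1, 1))
  expect_equal(unname(change_in_scale(s[4, ], s[4, ])), c(0, 0, 0, 0))
  expect_error(change_in_scale(c(1L, 2L), c(1L, 2L, 3L)), "length")
})

test_that("score tables from different scales refuse to be differenced", {
  m <- tibble::tibble(metric = c("TMOnto", "RROnto"), value = c(1.5, 0.7))
  a <- score_vector(m, "static")
  dyn <- fit_dynamic_scale(tibble::tibble(metric = c("TMOnto", "RROnto"),
                                          value = c(1.5, 0.7)))
  b <- score_vector(m, dyn)
  expect_error(change_in_scale(a, b), "different scales")
  expect_equal(unname(change_in_scale(a, a)), c(0L, 0L))
})

test_that("frequency distributions conserve the component count", {
  s <- example_scores()
  f2 <- frequency_distribution(change_in_scale(s[1, ], s[2, ]))
  expect_equal(unname(freq_counts(f2)["0"]), 4L)
  expect_equal(sum(f2$count), 4)
  f6 <- frequency_distribution(change_in_scale(s[5, ], s[6, ]))
  expect_equal(unname(freq_counts(f6)), c(1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L))
  # conservation on random change vectors
  set.seed(4)
  for (i in 1:20) {
    r <- sample(1:14, 1)
    l <- sample(-4:4, r, replace = TRUE)
    expect_equal(sum(frequency_distribution(l)$count), r)
  }
  expect_error(frequency_distribution(c(5L)), "-4..4")
})

test_that("change statistics reproduce the worked values", {
  s <- example_scores()
  st3 <- change_statistics(change_in_scale(s[2, ], s[3, ]))
  expect_true(is.na(st3$forward_mean))
  expect_equal(st3$backward_mean, -1)
  expect_equal(st3$mean_change, -0.5)
  expect_equal(st3$forward_size, 0)
  expect_equal(st3$backward_size, 2)
  expect_equal(st3$magnitude, 50)

  st4 <- change_statistics(change_in_scale(s[3, ], s[4, ]))
  expect_equal(st4$mean_change, 0.75)

  st6 <- change_statistics(change_in_scale(s[5, ], s[6, ]))
  expect_equal(st6$magnitude, 100)
  expect_equal(st6$mean_change, 0)
  expect_error(change_statistics(tibble::tibble(level = -4:4, count = 0L)),
               "empty")
})

test_that("mean change is (forward size - backward size) / r on random vectors", {
  set.seed(12)
  for (i in 1:25) {
    r <- sample(2:14, 1)
    l <- sample(-4:4, r, replace = TRUE)
    st <- change_statistics(frequency_distribution(l))
    expect_equal(st$mean_change, (st$forward_size - st$backward_size) / r)
    # magnitude 0 iff no component changed iff both directional means undefined
    expect_equal(st$magnitude == 0, all(l == 0))
    if (st$magnitude == 0) {
      expect_true(is.na(st$forward_mean) && is.na(st$backward_mean))
      expect_equal(st$mean_change, 0)
    }
  }
})

test_that("accumulative profiles sum mean changes and flag undefined entries", {
  p <- accumulative_profile(c(-0.5, 0.75))
  expect_equal(p$cumulative, c(-0.5, 0.25))
  p0 <- accumulative_profile(rep(0, 4))
  expect_equal(p0$cumulative, rep(0, 4))
  pna <- accumulative_profile(c(0.5, NA, -0.25))
  expect_equal(pna$cumulative, c(0.5, 0.5, 0.25))
  expect_equal(pna$imputed, c(FALSE, TRUE, FALSE))
})

test_that("corpus change statistics walk consecutive processed versions", {
  s <- example_scores()
  scores <- tibble::tibble(
    version = factor(rep(paste0("v", 1:6), each = 4),
                     levels = paste0("v", 1:6)),
    metric = rep(c("TMOnto", "RROnto", "LCOMOnto", "WMCOnto"), 6),
    score = as.integer(t(s))
  )
  cs <- corpus_change_statistics(scores)
  expect_equal(nrow(cs), 5)
  expect_equal(cs$version, paste0("v", 2:6))
  expect_equal(cs$previous, paste0("v", 1:5))
  expect_equal(cs$mean_change, c(0, -0.5, 0.75, 0, 0))
  expect_equal(cs$magnitude, c(0, 50, 75, 75, 100))
  # dropping v3 (as if unparseable): v4 is compared against v2
  cs2 <- corpus_change_statistics(scores[scores$version != "v3", ])
  expect_equal(cs2$previous[[2]], "v2")
  expect_equal(cs2$version[[2]], "v4")
  l42 <- change_in_scale(s[2, ], s[4, ])
  expect_equal(cs2$mean_change[[2]],
               change_statistics(frequency_distribution(l42))$mean_change)
})

test_that("the change-statistics CSV prints undefined values as '-'", {
  s <- example_scores()
  scores <- tibble::tibble(
    version = factor(rep(paste0("v", 1:3), each = 4),
                     levels = paste0("v", 1:3)),
    metric = rep(c("TMOnto", "RROnto", "LCOMOnto", "WMCOnto"), 3),
    score = as.integer(t(s[1:3, ]))
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_change_csv(corpus_change_statistics(scores), f)
  out <- utils::read.csv(f, check.names = FALSE)
  expect_equal(out$Change, c("Magnitude", "Mean. For", "Mean. Back", "Mean"))
  expect_equal(out[["v2"]][[2]], "-")   # no forward change v1 -> v2
  expect_equal(out[["v3"]][[3]], "1.00")
})
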