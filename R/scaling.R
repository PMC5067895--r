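# Discretisation of raw metric values to quality scores 1 (worst) .. 5 (best).
#
# Two scales are provided. The static scale is the fixed threshold table of
# the OQuaRE framework: metrics adapted from object-oriented practice are
# lower-is-better with absolute-value bins; ratio metrics are
# higher-is-better and read as percentages (raw ratio x 100). The dynamic
# scale is fitted to the raw values observed across a versioned corpus by
# exact one-dimensional k-means (k = 5, or the number of distinct values if
# fewer), anchored so the best observed value always scores 5; when fewer
# than five clusters exist the LOW scores are left empty.

# Upper break points for lower-is-better metrics: score = 5 - #breaks
# exceeded. Values at or below the first break score 5; above the last, 1.
STATIC_BREAKS <- list(
  LCOMOnto = c(2, 4, 6, 8),
  WMCOnto  = c(5, 8, 11, 15),
  DITOnto  = c(2, 4, 6, 8),
  NACOnto  = c(2, 4, 6, 8),
  NOCOnto  = c(3, 6, 8, 12),
  CBOnto   = c(2, 4, 6, 8),
  RFCOnto  = c(3, 6, 8, 12),
  NOMOnto  = c(2, 4, 6, 8),
  TMOnto   = c(2, 4, 6, 8)
)
# Percentage break points for higher-is-better metrics: score = 1 + #breaks
# exceeded, after multiplying the raw ratio by 100.
STATIC_PERCENT_BREAKS <- c(20, 40, 60, 80)

#' The OQuaRE static scale
#'
#' @return A tibble describing the fixed scale: one row per metric with its
#'   direction, unit and bin boundaries.
#' @export
oq_static_scale <- function() {
  lower <- tibble::tibble(
    metric = names(STATIC_BREAKS),
    direction = "lower_better",
    unit = "absolute",
    breaks = unname(STATIC_BREAKS)
  )
  higher <- tibble::tibble(
    metric = HIGHER_BETTER,
    direction = "higher_better",
    unit = "percent",
    breaks = rep(list(STATIC_PERCENT_BREAKS), length(HIGHER_BETTER))
  )
  out <- dplyr::bind_rows(lower, higher)
  out <- out[match(oq_metric_ids(), out$metric), ]
  structure(out, class = c("oquare_static_scale", class(out)))
}

#' Score a raw metric value on the static scale
#'
#' Percentage-unit metrics are multiplied by 100 before binning. Values
#' beyond the best bin clamp to 5 and beyond the worst bin to 1, so every
#' finite non-negative raw value receives a score; `NA` raw values propagate.
#'
#' @param metric Metric identifier.
#' @param raw Raw metric value(s), finite and non-negative.
#' @return Integer score(s) in 1..5.
#' @export
static_score <- function(metric, raw) {
  if (!metric %in% oq_metric_ids()) abort(paste0("unknown metric: ", metric))
  out <- rep(NA_integer_, length(raw))
  ok <- !is.na(raw)
  if (any(raw[ok] < 0 | !is.finite(raw[ok]))) {
    abort("raw metric values must be finite and non-negative")
  }
  if (metric %in% names(STATIC_BREAKS)) {
    br <- STATIC_BREAKS[[metric]]
    out[ok] <- 5L - vapply(raw[ok], function(x) sum(x > br), integer(1))
  } else {
    pct <- raw[ok] * 100
    out[ok] <- 1L + vapply(pct, function(x) sum(x > STATIC_PERCENT_BREAKS), integer(1))
  }
  out
}

# ---- dynamic scale ----------------------------------------------------------

#' Fit a corpus-specific dynamic scale
#'
#' For each metric, the raw values observed across all versions of the corpus
#' are partitioned into `k = min(5, number of distinct values)` groups by
#' exact one-dimensional k-means: the partition into contiguous intervals
#' that globally minimises the within-cluster sum of squares, found by
#' dynamic programming over the sorted distinct values (weighted by
#' multiplicity). The procedure is fully deterministic and seed-free. Groups
#' are mapped to scores by the metric's direction so that the best observed
#' value always scores 5; when fewer than five groups exist the lowest scores
#' are left empty.
#'
#' @param corpus_raw Long tibble with columns `metric` and `value` (one row
#'   per version and metric), e.g. from [metric_table()]. `NA` values are
#'   ignored with a warning.
#' @param k Maximum number of score categories (default 5).
#' @return An `oquare_dynamic_scale`: a tibble with columns `metric`,
#'   `score`, `lo`, `hi` (closed raw-value intervals; absent scores are
#'   empty categories).
#' @export
fit_dynamic_scale <- function(corpus_raw, k = 5) {
  stopifnot(is.data.frame(corpus_raw), all(c("metric", "value") %in% names(corpus_raw)))
  bad <- setdiff(unique(corpus_raw$metric), oq_metric_ids())
  if (length(bad) > 0) abort(paste0("unknown metric: ", paste(bad, collapse = ", ")))
  if (anyNA(corpus_raw$value)) {
    warn("NA raw values ignored when fitting the dynamic scale")
    corpus_raw <- corpus_raw[!is.na(corpus_raw$value), ]
  }
  if (nrow(corpus_raw) == 0) abort("no raw values to fit")
  out <- corpus_raw |>
    dplyr::group_by(.data$metric) |>
    dplyr::reframe(dynamic_intervals(.data$value, .data$metric[[1]], k = k))
  structure(tibble::as_tibble(out), class = c("oquare_dynamic_scale", class(out)))
}

dynamic_intervals <- function(values, metric, k = 5) {
  x <- sort(unique(values))
  w <- as.numeric(table(factor(values, levels = x)))
  kk <- min(k, length(x))
  groups <- kmeans_1d_exact(x, w, kk)
  # groups: integer cluster index (1 = smallest values) per distinct value
  lo <- tapply(x, groups, min)
  hi <- tapply(x, groups, max)
  if (oq_metric_direction(metric) == "lower_better") {
    score <- 5L - (seq_len(kk) - 1L)        # smallest cluster -> 5
  } else {
    score <- (5L - kk + 1L) + (seq_len(kk) - 1L)  # largest cluster -> 5
  }
  tibble::tibble(score = score, lo = as.numeric(lo), hi = as.numeric(hi))
}

# Exact weighted 1-D k-means: optimal contiguous partition of sorted distinct
# values x (weights w) into k clusters minimising the weighted within-cluster
# sum of squares. Ties between equal-cost partitions break toward the lowest
# split indices. Returns a cluster index per element of x, 1-based ascending.
kmeans_1d_exact <- function(x, w, k) {
  n <- length(x)
  stopifnot(k >= 1, k <= n)
  cw <- cumsum(c(0, w))
  cwx <- cumsum(c(0, w * x))
  cwx2 <- cumsum(c(0, w * x^2))
  # weighted SSE of x[a..b] around its weighted mean
  sse <- function(a, b) {
    W <- cw[b + 1] - cw[a]
    S <- cwx[b + 1] - cwx[a]
    Q <- cwx2[b + 1] - cwx2[a]
    Q - S^2 / W
  }
  cost <- matrix(Inf, k, n)
  split_at <- matrix(0L, k, n)
  for (i in seq_len(n)) cost[1, i] <- sse(1, i)
  if (k > 1) {
    for (j in 2:k) {
      for (i in j:n) {
        for (m in (j - 1):(i - 1)) {
          cand <- cost[j - 1, m] + sse(m + 1, i)
          if (cand < cost[j, i] - 1e-12) {
            cost[j, i] <- cand
            split_at[j, i] <- m
          }
        }
      }
    }
  }
  groups <- integer(n)
  i <- n
  for (j in k:1) {
    m <- if (j == 1) 0L else split_at[j, i]
    groups[(m + 1):i] <- j
    i <- m
  }
  groups
}

#' Score a raw value on a fitted dynamic scale
#'
#' Values inside a fitted interval receive that interval's score; values
#' outside every interval (out-of-hull or in a gap) clamp to the nearest
#' interval, ties resolving to the better score. `NA` raw values propagate.
#'
#' @param scale An `oquare_dynamic_scale` from [fit_dynamic_scale()].
#' @param metric Metric identifier present in the scale.
#' @param raw Raw value(s).
#' @return Integer score(s) in 1..5.
#' @export
dynamic_score <- function(scale, metric, raw) {
  stopifnot(inherits(scale, "oquare_dynamic_scale"))
  iv <- scale[scale$metric == metric, ]
  if (nrow(iv) == 0) abort(paste0("metric not in dynamic scale: ", metric))
  vapply(raw, function(x) {
    if (is.na(x)) return(NA_integer_)
    inside <- x >= iv$lo & x <= iv$hi
    if (any(inside)) return(as.integer(iv$score[inside][[1]]))
    d <- pmax(iv$lo - x, x - iv$hi)
    best <- which(d == min(d))
    as.integer(max(iv$score[best]))
  }, integer(1))
}

#' Discretise a metric vector under a chosen scale
#'
#' Applies [static_score()] or [dynamic_score()] componentwise. Undefined raw
#' metrics (`NA`) yield undefined score components.
#'
#' @param m Tibble with columns `metric`, `value` (e.g. [compute_metrics()]).
#' @param scale `"static"` (default), an `oquare_static_scale`, or a fitted
#'   `oquare_dynamic_scale`.
#' @return Tibble with columns `metric`, `raw`, `score` and the scale type
#'   in attribute `"scale_type"`.
#' @export
score_vector <- function(m, scale = "static") {
  stopifnot(is.data.frame(m), all(c("metric", "value") %in% names(m)))
  if (identical(scale, "static") || inherits(scale, "oquare_static_scale")) {
    sc <- purrr::map2_int(m$metric, m$value,
                          function(id, v) static_score(id, v)[[1]])
    type <- "static"
  } else if (inherits(scale, "oquare_dynamic_scale")) {
    sc <- purrr::map2_int(m$metric, m$value,
                          function(id, v) dynamic_score(scale, id, v)[[1]])
    type <- "dynamic"
  } else {
    abort("scale must be \"static\" or a fitted dynamic scale")
  }
  out <- tibble::tibble(metric = m$metric, raw = m$value, score = sc)
  attr(out, "scale_type") <- type
  out
}

#' Score every version of a corpus under a chosen scale
#'
#' @param metrics Long tibble `version`, `metric`, `value` from
#'   [metric_table()].
#' @param scale As in [score_vector()]; `"dynamic"` fits
#'   [fit_dynamic_scale()] on `metrics` first.
#' @return Long tibble `version`, `metric`, `raw`, `score`, with the scale
#'   type in attribute `"scale_type"`.
#' @export
score_table <- function(metrics, scale = "static") {
  if (identical(scale, "dynamic")) scale <- fit_dynamic_scale(metrics)
  out <- metrics |>
    dplyr::group_by(.data$version) |>
    dplyr::reframe(score_vector(dplyr::pick("metric", "value"), scale))
  attr(out, "scale_type") <- if (inherits(scale, "oquare_dynamic_scale")) "dynamic" else "static"
  tibble::as_tibble(out)
}

# ---- (de)serialisation ------------------------------------------------------

#' Save / load a fitted dynamic scale as JSON
#'
#' @param scale An `oquare_dynamic_scale`.
#' @param path JSON file path.
#' @return `path` invisibly, or the restored scale.
#' @export
write_dynamic_scale <- function(scale, path) {
  stopifnot(inherits(scale, "oquare_dynamic_scale"))
  lst <- split(scale[c("score", "lo", "hi")], scale$metric)
  jsonlite::write_json(lst, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_dynamic_scale
#' @export
read_dynamic_scale <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- purrr::imap(lst, function(df, m) {
    tibble::tibble(metric = m, score = as.integer(df$score),
                   lo = as.numeric(df$lo), hi = as.numeric(df$hi))
  }) |> purrr::list_rbind()
  structure(out, class = c("oquare_dynamic_scale", class(out)))
}
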