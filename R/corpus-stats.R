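# Ranking of consecutive version pairs by the significance of their raw
# metric differences, and the relation between quality change and class-level
# editing activity (PCA + Pearson correlations).

#' Exact one-sided Wilcoxon signed-rank test against zero
#'
#' Tests the alternative that the median of `x` is greater than zero. Zero
#' values are dropped; ties receive mid-ranks; the null distribution of the
#' positive-rank sum is computed exactly by convolution over the (doubled)
#' rank magnitudes for n <= `exact_max`, beyond which a normal approximation
#' with continuity and tie correction is used.
#'
#' @param x Numeric vector of differences.
#' @param exact_max Largest n for which the exact null distribution is used.
#' @return A list with `statistic` (positive-rank sum W+), `p_value`, `n`
#'   (nonzero values used) and `exact`.
#' @export
signed_rank_test <- function(x, exact_max = 20) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L, exact = NA))
  }
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  if (n <= exact_max) {
    # distribution of sum over subsets of doubled ranks (integers)
    d2 <- as.integer(round(2 * r))
    counts <- 1
    for (v in d2) {
      shifted <- c(rep(0, v), counts)
      counts <- c(counts, rep(0, v)) + shifted
    }
    tot <- 2^n
    p <- sum(counts[seq.int(round(2 * w) + 1L, length(counts))]) / tot
    return(list(statistic = w, p_value = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu - 0.5) / sqrt(sigma2)
  list(statistic = w, p_value = stats::pnorm(z, lower.tail = FALSE), n = n,
       exact = FALSE)
}

#' Wilcoxon ranking of consecutive version pairs
#'
#' For every consecutive pair of processed versions, takes the absolute
#' differences of the 14 raw metric values and tests, with the one-sided
#' signed-rank test, the alternative that their median exceeds zero. The
#' reported estimate ("critical value") is the sample median of the absolute
#' differences. Identical versions (all differences zero) are flagged
#' degenerate: no valid test exists.
#'
#' @param metrics Long raw-metric table (`version`, `metric`, `value`) from
#'   [metric_table()]. `NA` metric values are dropped pairwise.
#' @return Tibble sorted by increasing (estimate, p): `version`, `previous`,
#'   `estimate`, `p_value`, `n`, `degenerate`.
#' @export
wilcoxon_consecutive <- function(metrics) {
  versions <- if (is.factor(metrics$version)) {
    levels(droplevels(metrics$version))
  } else {
    unique(metrics$version)
  }
  if (length(versions) < 2) abort("need at least 2 versions")
  out <- purrr::map(seq_along(versions)[-1], function(i) {
    a <- metrics[metrics$version == versions[[i - 1]], ]
    b <- metrics[metrics$version == versions[[i]], ]
    d <- abs(b$value[match(a$metric, b$metric)] - a$value)
    d <- d[!is.na(d)]
    tst <- signed_rank_test(d)
    tibble::tibble(
      version = versions[[i]], previous = versions[[i - 1]],
      estimate = stats::median(d),
      p_value = tst$p_value, n = tst$n,
      degenerate = tst$n == 0
    )
  }) |> purrr::list_rbind()
  dplyr::arrange(out, .data$estimate, .data$p_value)
}

#' PCA of quality change against editing activity
#'
#' Principal component analysis relating the three dynamic-scale change
#' statistics of each version pair (backward size, forward size, mean change)
#' to the three class-activity counts (new, deleted, changed classes). All
#' variables are standardised (PCA on the correlation matrix); constant
#' variables are excluded with a warning. Loadings are reported as
#' variable-component correlations, so each column of `loadings` scales with
#' the component's standard deviation.
#'
#' @param change_stats Tibble with columns `version`, `backward_size`,
#'   `forward_size`, `mean_change` (dynamic scale), e.g. from
#'   [corpus_change_statistics()].
#' @param activity Tibble with columns `version`, `n_new`, `n_deleted`,
#'   `n_changed` (see [diff_versions()]).
#' @param n_components Components to retain (default 2).
#' @return An `oquare_pca` list: `loadings` (variables x components),
#'   `explained` (variance fractions, all components), `scores` (per-version
#'   coordinates), `dropped` (excluded constant variables).
#' @export
pca_activity <- function(change_stats, activity, n_components = 2) {
  df <- dplyr::inner_join(
    dplyr::select(change_stats, "version", "backward_size", "forward_size",
                  "mean_change"),
    dplyr::select(activity, "version", "n_new", "n_deleted", "n_changed"),
    by = "version"
  )
  if (nrow(df) < 3) abort("PCA needs at least 3 version pairs")
  mat <- as.matrix(df[-1])
  if (anyNA(mat)) abort("PCA input contains undefined values")
  const <- apply(mat, 2, function(v) sd(v) == 0)
  if (any(const)) {
    warn(paste0("constant variable(s) excluded from PCA: ",
                paste(colnames(mat)[const], collapse = ", ")))
    mat <- mat[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$rotation))
  loadings <- pc$rotation[, seq_len(k), drop = FALSE] %*%
    diag(pc$sdev[seq_len(k)], k, k)
  colnames(loadings) <- paste0("factor", seq_len(k))
  structure(
    list(
      loadings = loadings,
      explained = pc$sdev^2 / sum(pc$sdev^2),
      scores = tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE]) |>
        dplyr::mutate(version = df$version, .before = 1),
      dropped = colnames(df[-1])[const]
    ),
    class = "oquare_pca"
  )
}

#' @export
print.oquare_pca <- function(x, ...) {
  cat("<oquare_pca> ", ncol(x$loadings), " factors, explaining ",
      sprintf("%.1f%%", 100 * sum(x$explained[seq_len(ncol(x$loadings))])),
      " of the variance\n", sep = "")
  print(round(x$loadings, 4))
  invisible(x)
}

#' @export
tidy.oquare_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.oquare_pca <- function(x, ...) {
  tibble::tibble(
    n_factors = ncol(x$loadings),
    explained_1 = x$explained[[1]],
    explained_2 = if (length(x$explained) >= 2) x$explained[[2]] else NA_real_,
    explained_retained = sum(x$explained[seq_len(ncol(x$loadings))])
  )
}

#' Pairwise Pearson correlations
#'
#' Correlation and two-sided p-value for every pair of columns.
#'
#' @param variables Data frame of numeric columns (>= 3 rows). A `version`
#'   column, if present, is ignored.
#' @return Tibble `var1`, `var2`, `estimate`, `p_value` over all pairs.
#' @export
pearson_pairs <- function(variables) {
  df <- variables[setdiff(names(variables), "version")]
  if (nrow(df) < 3) abort("need at least 3 observations")
  const <- vapply(df, function(v) sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(const)) abort(paste0("constant column(s): ",
                               paste(names(df)[const], collapse = ", ")))
  pairs <- utils::combn(names(df), 2)
  purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    ct <- stats::cor.test(df[[a]], df[[b]], method = "pearson")
    tibble::tibble(var1 = a, var2 = b, estimate = unname(ct$estimate),
                   p_value = ct$p.value)
  }) |> purrr::list_rbind()
}
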