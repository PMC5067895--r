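# Change-in-scale statistics over a versioned corpus: componentwise score
# differences between consecutive versions, their frequency distribution over
# the nine change levels -4..4, and the derived statistics (forward /
# backward mean change, mean change, change sizes, magnitude of change).
# Directional means over an empty side are undefined and reported as NA, a
# distinct value that reports print as "-"; they are never coerced to zero.

#' Change in scale between two score vectors
#'
#' Componentwise integer difference `next_ - prev` of two quality-score
#' vectors over the same metrics and scale.
#'
#' @param prev,next_ Either integer vectors of equal length (optionally
#'   named) or score tibbles with columns `metric`, `score` (see
#'   [score_vector()]); tibbles are aligned by metric.
#' @return Integer vector of change levels in -4..4 (named when the inputs
#'   carry metric names).
#' @export
change_in_scale <- function(prev, next_) {
  if (is.data.frame(prev) != is.data.frame(next_)) {
    abort("prev and next_ must both be vectors or both score tables")
  }
  if (is.data.frame(prev)) {
    tp <- attr(prev, "scale_type")
    tn <- attr(next_, "scale_type")
    if (!is.null(tp) && !is.null(tn) && !identical(tp, tn)) {
      abort("score vectors come from different scales")
    }
    if (!setequal(prev$metric, next_$metric) || nrow(prev) != nrow(next_)) {
      abort("score vectors cover different metrics")
    }
    i <- match(prev$metric, next_$metric)
    out <- as.integer(next_$score[i] - prev$score)
    names(out) <- prev$metric
    return(out)
  }
  if (length(prev) != length(next_)) abort("score vectors differ in length (r)")
  out <- as.integer(next_) - as.integer(prev)
  names(out) <- names(prev) %||% names(next_)
  out
}

#' Frequency distribution of change levels
#'
#' Counts of each change level l in -4..4. The counts always sum to the
#' number of (defined) components r.
#'
#' @param l Integer change vector from [change_in_scale()]; `NA` components
#'   (undefined scores) are dropped.
#' @return Tibble with columns `level` (-4..4) and `count`.
#' @export
frequency_distribution <- function(l) {
  l <- l[!is.na(l)]
  if (any(l < -4 | l > 4)) abort("change levels must lie in -4..4")
  tibble::tibble(
    level = -4:4,
    count = as.integer(table(factor(l, levels = -4:4)))
  )
}

#' Statistics of change for one frequency distribution
#'
#' From a frequency distribution F over the levels -4..4 with counts f_l:
#' * forward mean — weighted mean of the positive levels,
#'   `sum(l * f_l, l >= 1) / sum(f_l, l >= 1)`; `NA` when no positive change;
#' * backward mean — weighted mean of the negative levels (a negative
#'   number); `NA` when no negative change;
#' * forward / backward size — the corresponding numerators, the backward one
#'   in absolute value;
#' * mean change — `sum(l * f_l) / r`;
#' * magnitude — percentage of components with a nonzero change level.
#'
#' @param f Frequency distribution tibble from [frequency_distribution()], or
#'   an integer change vector (converted internally).
#' @return One-row tibble with columns `r`, `magnitude`, `forward_mean`,
#'   `backward_mean`, `mean_change`, `forward_size`, `backward_size`.
#' @export
change_statistics <- function(f) {
  if (!is.data.frame(f)) f <- frequency_distribution(f)
  stopifnot(all(c("level", "count") %in% names(f)))
  lev <- f$level
  cnt <- f$count
  r <- sum(cnt)
  if (r == 0) abort("empty frequency distribution")
  pos <- lev >= 1
  neg <- lev <= -1
  fwd_n <- sum(cnt[pos])
  bwd_n <- sum(cnt[neg])
  tibble::tibble(
    r = r,
    magnitude = 100 * sum(cnt[lev != 0]) / r,
    forward_mean = if (fwd_n > 0) sum(lev[pos] * cnt[pos]) / fwd_n else NA_real_,
    backward_mean = if (bwd_n > 0) sum(lev[neg] * cnt[neg]) / bwd_n else NA_real_,
    mean_change = sum(lev * cnt) / r,
    forward_size = sum(lev[pos] * cnt[pos]),
    backward_size = sum(abs(lev[neg]) * cnt[neg])
  )
}

#' Accumulative profile of mean change
#'
#' Running sum of the per-version mean changes over the life-cycle. An
#' undefined mean change contributes zero and is flagged.
#'
#' @param mean_changes Numeric vector of per-version mean changes in
#'   chronological order (may contain `NA`).
#' @return Tibble with columns `step`, `mean_change`, `imputed` (`TRUE` where
#'   an undefined value contributed 0) and `cumulative`.
#' @export
accumulative_profile <- function(mean_changes) {
  imputed <- is.na(mean_changes)
  contrib <- ifelse(imputed, 0, mean_changes)
  tibble::tibble(
    step = seq_along(mean_changes),
    mean_change = mean_changes,
    imputed = imputed,
    cumulative = cumsum(contrib)
  )
}

#' Per-version change statistics for a scored corpus
#'
#' Computes [change_statistics()] for every consecutive pair of versions in a
#' score table. Versions are compared against the previous *processed*
#' version, so a corpus with skipped (unparseable) versions yields statistics
#' against the latest available predecessor.
#'
#' @param scores Long score table (`version`, `metric`, `score`) from
#'   [score_table()].
#' @return Tibble with one row per version from the second onwards: `version`,
#'   `previous`, plus the [change_statistics()] columns.
#' @export
corpus_change_statistics <- function(scores) {
  versions <- if (is.factor(scores$version)) {
    levels(droplevels(scores$version))
  } else {
    unique(scores$version)
  }
  if (length(versions) < 2) abort("change statistics need at least 2 versions")
  split_scores <- lapply(versions, function(v) scores[scores$version == v, ])
  purrr::map(seq_along(versions)[-1], function(i) {
    l <- change_in_scale(
      setNames(split_scores[[i - 1]]$score, split_scores[[i - 1]]$metric),
      setNames(split_scores[[i]]$score[match(split_scores[[i - 1]]$metric,
                                             split_scores[[i]]$metric)],
               split_scores[[i - 1]]$metric)
    )
    dplyr::mutate(change_statistics(frequency_distribution(l)),
                  version = versions[[i]], previous = versions[[i - 1]],
                  .before = 1)
  }) |> purrr::list_rbind()
}

#' Export change statistics in report layout
#'
#' Writes the change-statistics table with one column per version and the
#' rows magnitude (percent), forward mean, backward mean and mean change;
#' undefined values print as `-`.
#'
#' @param stats Tibble from [corpus_change_statistics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_change_csv <- function(stats, path) {
  fmt <- function(x, digits = 2) ifelse(is.na(x), "-", formatC(x, digits = digits,
                                                               format = "f"))
  wide <- rbind(
    c("Magnitude", paste0(fmt(stats$magnitude, 0), " %")),
    c("Mean. For", fmt(stats$forward_mean)),
    c("Mean. Back", fmt(abs(stats$backward_mean))),
    c("Mean", fmt(stats$mean_change))
  )
  colnames(wide) <- c("Change", as.character(stats$version))
  utils::write.csv(as.data.frame(wide), path, row.names = FALSE)
  invisible(path)
}
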