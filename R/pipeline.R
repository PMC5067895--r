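# End-to-end pipelines: single-version evaluation and full corpus evolution
# analysis, plus the command-line entry point used by inst/exec/oquare.

#' Evaluate one ontology version
#'
#' Reads an ontology, optionally removes deprecated classes, computes the 14
#' raw metrics, scores them on the static scale and aggregates them into a
#' quality report.
#'
#' @param path Ontology file.
#' @param normalise Remove deprecated classes first (default `TRUE`).
#' @param model Quality model (default [oq_quality_model()]).
#' @param out_dir If given, writes `metrics.csv` (raw values and scores) and
#'   `report.json` there.
#' @param dialect Passed to [read_ontology()].
#' @return A list with `graph`, `metrics` (raw), `scores` (static) and
#'   `report` (an `oquare_quality_report`).
#' @export
oq_evaluate <- function(path, normalise = TRUE, model = oq_quality_model(),
                        out_dir = NULL, dialect = "auto") {
  g <- read_ontology(path, dialect = dialect)
  g <- normalise_graph(g, remove_deprecated = normalise)
  m <- if (length(g$classes) == 0) {
    # empty ontology: every metric is undefined, reported as markers
    tibble::tibble(metric = oq_metric_ids(), value = NA_real_)
  } else {
    compute_metrics(g)
  }
  s <- score_vector(m, "static")
  rep <- quality_report(s, model)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(s, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(subcharacteristics = rep$subcharacteristics,
           characteristics = rep$characteristics, overall = rep$overall),
      file.path(out_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(graph = g, metrics = m, scores = s, report = rep)
}

#' Evaluate a versioned ontology corpus
#'
#' Runs the full evolution pipeline over a directory of chronologically
#' ordered ontology files (ordered by filename): read (unreadable versions
#' are skipped with a warning), normalise, raw metrics, static and/or dynamic
#' scores, per-pair change statistics and accumulative profile, Wilcoxon
#' ranking of consecutive pairs, per-pair activity deltas, and — when at
#' least three pairs exist under the dynamic scale — PCA of quality change
#' against activity with the pairwise Pearson correlations.
#'
#' @param source Directory containing the version files, or a character
#'   vector of file paths in chronological order.
#' @param scale `"both"` (default), `"static"` or `"dynamic"`.
#' @param normalise Remove deprecated classes per version.
#' @param model Quality model for per-version reports.
#' @param out_dir If given, CSV/JSON outputs are written there.
#' @param dialect Passed to [read_ontology()].
#' @return An `oquare_corpus_report` list: `versions`, `skipped`, `metrics`,
#'   `scores` (named list per scale), `change_stats` (per scale), `profiles`
#'   (per scale), `wilcoxon`, `activity`, `pca`, `pearson`, `quality`
#'   (per-version characteristic scores), `dynamic_scale`.
#' @export
oq_evaluate_corpus <- function(source, scale = c("both", "static", "dynamic"),
                               normalise = TRUE, model = oq_quality_model(),
                               out_dir = NULL, dialect = "auto") {
  scale <- match.arg(scale)
  paths <- if (length(source) == 1 && dir.exists(source)) {
    sort(list.files(source, pattern = "\\.(owl|rdf|xml|ttl|turtle)$",
                    full.names = TRUE))
  } else {
    source
  }
  graphs <- list()
  skipped <- character()
  for (p in paths) {
    v <- sub("\\.[^.]*$", "", basename(p))
    g <- tryCatch(read_ontology(p, dialect = dialect), error = function(e) {
      warn(paste0("skipping unreadable version ", basename(p), ": ",
                  conditionMessage(e)))
      NULL
    })
    if (is.null(g)) skipped <- c(skipped, v) else graphs[[v]] <- g
  }
  if (length(graphs) < 2) abort("need at least 2 processable versions")
  if (normalise) graphs <- lapply(graphs, normalise_graph)

  metrics <- metric_table(graphs)
  scales <- switch(scale, both = c("static", "dynamic"),
                   static = "static", dynamic = "dynamic")
  dyn_scale <- if ("dynamic" %in% scales) fit_dynamic_scale(metrics) else NULL
  scores <- lapply(setNames(scales, scales), function(sc) {
    score_table(metrics, if (sc == "dynamic") dyn_scale else "static")
  })
  change_stats <- lapply(scores, corpus_change_statistics)
  profiles <- lapply(change_stats, function(cs) {
    dplyr::mutate(accumulative_profile(cs$mean_change), version = cs$version)
  })
  vs <- names(graphs)
  activity <- purrr::map(seq_along(vs)[-1], function(i) {
    dplyr::mutate(diff_versions(graphs[[i - 1]], graphs[[i]]),
                  version = vs[[i]], .before = 1)
  }) |> purrr::list_rbind()
  wil <- wilcoxon_consecutive(metrics)

  pca <- NULL
  pearson <- NULL
  if ("dynamic" %in% scales && nrow(change_stats$dynamic) >= 3) {
    joined <- dplyr::inner_join(
      dplyr::select(change_stats$dynamic, "version", "backward_size",
                    "forward_size", "mean_change"),
      activity, by = "version")
    pca <- tryCatch(pca_activity(change_stats$dynamic, activity),
                    error = function(e) {
                      warn(paste0("PCA skipped: ", conditionMessage(e)))
                      NULL
                    })
    pearson <- tryCatch(pearson_pairs(joined),
                        error = function(e) NULL)
  }
  quality <- metrics |>
    dplyr::group_by(.data$version) |>
    dplyr::reframe({
      s <- score_vector(dplyr::pick("metric", "value"), "static")
      rep <- quality_report(s, model)
      dplyr::bind_rows(rep$characteristics,
                       tibble::tibble(characteristic = "Overall mean",
                                      score = rep$overall))
    })

  out <- structure(
    list(versions = vs, skipped = skipped, metrics = metrics, scores = scores,
         change_stats = change_stats, profiles = profiles, wilcoxon = wil,
         activity = activity, pca = pca, pearson = pearson, quality = quality,
         dynamic_scale = dyn_scale),
    class = "oquare_corpus_report"
  )
  if (!is.null(out_dir)) write_corpus_report(out, out_dir)
  out
}

#' @export
print.oquare_corpus_report <- function(x, ...) {
  cat("<oquare_corpus_report> ", length(x$versions), " versions",
      if (length(x$skipped) > 0) paste0(" (", length(x$skipped), " skipped)"),
      "\n", sep = "")
  for (sc in names(x$change_stats)) {
    cs <- x$change_stats[[sc]]
    cat(sprintf("  %s scale: mean |magnitude| %.1f%%, final accumulative mean change %.2f\n",
                sc, mean(cs$magnitude),
                x$profiles[[sc]]$cumulative[nrow(x$profiles[[sc]])]))
  }
  invisible(x)
}

#' Write all corpus-report tables to a directory
#'
#' @param report An `oquare_corpus_report`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_corpus_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_metric_csv(report$metrics, file.path(out_dir, "metrics_raw.csv"))
  for (sc in names(report$scores)) {
    utils::write.csv(
      tidyr::pivot_wider(report$scores[[sc]][c("version", "metric", "score")],
                         names_from = "metric", values_from = "score"),
      file.path(out_dir, paste0("scores_", sc, ".csv")), row.names = FALSE)
    write_change_csv(report$change_stats[[sc]],
                     file.path(out_dir, paste0("change_", sc, ".csv")))
    utils::write.csv(report$profiles[[sc]],
                     file.path(out_dir, paste0("profile_", sc, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$wilcoxon, file.path(out_dir, "wilcoxon.csv"),
                   row.names = FALSE)
  utils::write.csv(report$activity, file.path(out_dir, "activity.csv"),
                   row.names = FALSE)
  utils::write.csv(report$quality, file.path(out_dir, "quality.csv"),
                   row.names = FALSE)
  if (!is.null(report$pca)) {
    utils::write.csv(tibble::as_tibble(report$pca$loadings, rownames = "variable"),
                     file.path(out_dir, "pca_loadings.csv"), row.names = FALSE)
    utils::write.csv(report$pca$scores, file.path(out_dir, "pca_scores.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$pearson)) {
    utils::write.csv(report$pearson, file.path(out_dir, "pearson.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$dynamic_scale)) {
    write_dynamic_scale(report$dynamic_scale,
                        file.path(out_dir, "dynamic_scale.json"))
  }
  invisible(out_dir)
}

# ---- command-line entry point -----------------------------------------------

#' Command-line entry point
#'
#' Backs the `oquare` executable script (`inst/exec/oquare`). Usage:
#'
#' ```
#' oquare evaluate <ontology> [--out DIR] [--no-normalise] [--model-config YAML]
#' oquare corpus <directory> [--scale static|dynamic|both] [--out DIR]
#'        [--no-normalise] [--model-config YAML] [--seed N] [--log-level quiet|info]
#' ```
#'
#' Exit codes: 0 success; 2 bad arguments or unreadable input path; 1 any
#' other failure.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
oquare_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: oquare evaluate <ontology> [options]\n",
        "       oquare corpus <directory> [options]\n",
        "options: --scale static|dynamic|both  --out DIR  --no-normalise\n",
        "         --model-config YAML  --seed N  --log-level quiet|info\n",
        sep = "")
  }
  opts <- list(scale = "both", out = NULL, normalise = TRUE,
               model_config = NULL, seed = 1L, log_level = "info")
  pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    take_value <- function() {
      if (i + 1L > length(args)) abort(paste0("missing value for ", a))
      i <<- i + 1L
      args[[i]]
    }
    if (a == "--scale") opts$scale <- take_value()
    else if (a == "--out") opts$out <- take_value()
    else if (a == "--no-normalise") opts$normalise <- FALSE
    else if (a == "--normalise") opts$normalise <- TRUE
    else if (a == "--model-config") opts$model_config <- take_value()
    else if (a == "--seed") opts$seed <- as.integer(take_value())
    else if (a == "--log-level") opts$log_level <- take_value()
    else if (a %in% c("-h", "--help")) { usage(); return(invisible(0L)) }
    else if (startsWith(a, "--")) { usage(); return(invisible(2L)) }
    else pos <- c(pos, a)
    i <- i + 1L
  }
  if (length(pos) != 2 || !(pos[[1]] %in% c("evaluate", "corpus")) ||
      !(opts$scale %in% c("static", "dynamic", "both"))) {
    usage()
    return(invisible(2L))
  }
  target <- pos[[2]]
  exists_ok <- if (pos[[1]] == "corpus") dir.exists(target) else file.exists(target)
  if (!exists_ok) {
    message("input path not found: ", target)
    return(invisible(2L))
  }
  set.seed(opts$seed)
  model <- if (is.null(opts$model_config)) oq_quality_model() else
    read_quality_model(opts$model_config)
  status <- tryCatch({
    if (pos[[1]] == "evaluate") {
      res <- oq_evaluate(target, normalise = opts$normalise, model = model,
                         out_dir = opts$out)
      if (opts$log_level != "quiet") print(res$report)
    } else {
      res <- oq_evaluate_corpus(target, scale = opts$scale,
                                normalise = opts$normalise, model = model,
                                out_dir = opts$out)
      if (opts$log_level != "quiet") print(res)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
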