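# The fourteen structural quality metrics.
#
# Conventions (shared by all path metrics): path lengths are counted in
# edges; the implicit root owl:Thing is a path endpoint but never a class, so
# a parentless class sits at depth 1. "Direct children of the root" are the
# classes with no named parent. A class with no named parent contributes one
# superclass link (to the root) wherever total superclass links are counted.

#' Compute the fourteen OQuaRE metrics for one ontology
#'
#' Returns the raw (undiscretised) metric values. With `n` classes, `e`
#' subclass edges between named classes, `o` classes with no named parent
#' (direct root children), `u` property usages (restriction expressions plus
#' individual property assertions) and `s = e + o` total superclass links:
#'
#' * `ANOnto` — annotation assertions / n
#' * `AROnto` — restriction expressions / n
#' * `CBOnto` — s / (n - o)
#' * `CROnto` — asserted individuals / n
#' * `DITOnto` — length (in edges) of the longest root-to-leaf path
#' * `INROnto` — e / n
#' * `NACOnto` — mean number of direct parents over leaf classes (a
#'   parentless leaf has the root as its single parent)
#' * `NOCOnto` — e / (n - o)
#' * `NOMOnto` — u / n
#' * `LCOMOnto` — mean edge-length over all distinct leaf-to-root paths
#'   (every multi-parent class contributes one path per parent choice)
#' * `RFCOnto` — (u + s) / (n - o)
#' * `RROnto` — u / (e + number of object and data properties)
#' * `TMOnto` — fraction of classes with more than one direct named parent
#' * `WMCOnto` — (u + s) / n
#'
#' A metric whose denominator is zero (for example `CBOnto` when every class
#' is a direct root child) is reported as `NA`, the explicit undefined
#' marker; it is never infinite. Scoring and aggregation propagate the
#' marker.
#'
#' @param graph An acyclic [ontology_graph()] with at least one class.
#' @param max_paths Cap on the number of distinct leaf-to-root paths
#'   enumerated for `LCOMOnto`; an error is raised beyond it.
#' @return A tibble with columns `metric` and `value` (14 rows, canonical
#'   metric order).
#' @export
compute_metrics <- function(graph, max_paths = 1e6) {
  stopifnot(inherits(graph, "ontology_graph"))
  n <- length(graph$classes)
  if (n < 1) abort("compute_metrics needs at least one class")
  e <- nrow(graph$subclass_edges)
  orphans <- root_children(graph)
  o <- length(orphans)
  s <- e + o
  u <- total_usages(graph)
  leaves <- leaf_classes(graph)
  n_props <- length(graph$object_properties) + length(graph$data_properties)

  paths <- root_path_stats(graph, max_paths = max_paths)
  leaf_paths <- paths[leaves, , drop = FALSE]
  ratio <- function(num, den) if (den > 0) num / den else NA_real_

  parent_counts <- table(factor(graph$subclass_edges$child, levels = graph$classes))
  leaf_parents <- pmax(as.integer(parent_counts[leaves]), 1L)

  vals <- c(
    ANOnto = ratio(nrow(graph$annotations), n),
    AROnto = ratio(nrow(graph$restrictions), n),
    CBOnto = ratio(s, n - o),
    CROnto = ratio(nrow(graph$individuals), n),
    DITOnto = max(paths$depth),
    INROnto = ratio(e, n),
    NACOnto = mean(leaf_parents),
    NOCOnto = ratio(e, n - o),
    NOMOnto = ratio(u, n),
    LCOMOnto = sum(leaf_paths$sum_len) / sum(leaf_paths$n_paths),
    RFCOnto = ratio(u + s, n - o),
    RROnto = ratio(u, e + n_props),
    TMOnto = sum(parent_counts > 1) / n,
    WMCOnto = ratio(u + s, n)
  )
  tibble::tibble(metric = oq_metric_ids(), value = unname(vals[oq_metric_ids()]))
}

# Per class: number of distinct paths to the root, their total edge length,
# and the longest path length. Memoised DAG traversal in topological order;
# a parentless class has exactly one path, of length 1 (the edge to Thing).
root_path_stats <- function(graph, max_paths = 1e6) {
  cl <- graph$classes
  e <- graph$subclass_edges
  n_paths <- setNames(rep(NA_real_, length(cl)), cl)
  sum_len <- setNames(rep(NA_real_, length(cl)), cl)
  depth <- setNames(rep(NA_real_, length(cl)), cl)
  parents <- split(e$parent, factor(e$child, levels = cl))
  todo <- cl
  while (length(todo) > 0) {
    ready <- todo[vapply(todo, function(x) {
      p <- parents[[x]]
      length(p) == 0 || !anyNA(n_paths[p])
    }, logical(1))]
    if (length(ready) == 0) abort("subclass relation is cyclic")  # unreachable after validation
    for (x in ready) {
      p <- parents[[x]]
      if (length(p) == 0) {
        n_paths[[x]] <- 1
        sum_len[[x]] <- 1
        depth[[x]] <- 1
      } else {
        n_paths[[x]] <- sum(n_paths[p])
        sum_len[[x]] <- sum(sum_len[p]) + n_paths[[x]]
        depth[[x]] <- max(depth[p]) + 1
      }
      if (n_paths[[x]] > max_paths) {
        abort(paste0("leaf-to-root path count exceeds max_paths = ", max_paths))
      }
    }
    todo <- setdiff(todo, ready)
  }
  out <- data.frame(n_paths = n_paths, sum_len = sum_len, depth = depth)
  rownames(out) <- cl
  out
}

#' Raw metric table for a list of ontology versions
#'
#' @param graphs Named list of [ontology_graph()] objects, in chronological
#'   order; names are the version ids.
#' @param ... Passed on to [compute_metrics()].
#' @return A tibble with columns `version`, `metric`, `value` (long form),
#'   ordered as given.
#' @export
metric_table <- function(graphs, ...) {
  if (is.null(names(graphs))) {
    names(graphs) <- sprintf("v%d", seq_along(graphs))
  }
  purrr::imap(graphs, function(g, v) {
    dplyr::mutate(compute_metrics(g, ...), version = v, .before = 1)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(version = factor(.data$version, levels = names(graphs)))
}

#' Write a raw-metric table as CSV (one row per version, one column per metric)
#'
#' @param metrics Long metric table from [metric_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(metrics, path) {
  wide <- tidyr::pivot_wider(metrics, names_from = "metric", values_from = "value")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
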