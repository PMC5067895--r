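# Fixtures built in code and independent oracles used across the suite.

ns <- "http://example.org/onto#"
iri <- function(x) paste0(ns, x)

# root -> A -> B chain (plus optional extras), no properties
chain_graph <- function(n = 2) {
  cls <- iri(LETTERS[seq_len(n)])
  edges <- if (n > 1) {
    tibble::tibble(child = cls[-1], parent = cls[-n])
  } else NULL
  ontology_graph(classes = cls, subclass_edges = edges)
}

# 7-class DAG with one diamond:
#   A (root child) -> B, C; B, C -> D (diamond); D -> E; A -> F; G root child.
# Leaves: E, F, G. Leaf-to-root path edge lengths: E twice 4, F 2, G 1.
diamond_graph <- function() {
  ontology_graph(
    classes = iri(c("A", "B", "C", "D", "E", "F", "G")),
    subclass_edges = tibble::tibble(
      child = iri(c("B", "C", "D", "D", "E", "F")),
      parent = iri(c("A", "A", "B", "C", "D", "A"))
    )
  )
}

metric_value <- function(m, id) m$value[m$metric == id]

# Exhaustive leaf-to-root path enumeration, independent of the package's
# memoised traversal. Returns the edge length of every distinct path.
enum_path_lengths <- function(g) {
  parents <- split(g$subclass_edges$parent,
                   factor(g$subclass_edges$child, levels = g$classes))
  walk <- function(cl) {
    p <- parents[[cl]]
    if (length(p) == 0) return(1L)  # edge to the implicit root
    unlist(lapply(p, function(x) walk(x) + 1L))
  }
  leaves <- setdiff(g$classes, unique(g$subclass_edges$parent))
  unlist(lapply(leaves, walk))
}

# Brute-force weighted within-cluster sum of squares minimisation over all
# contiguous partitions of sorted distinct values into k groups.
brute_kmeans_cost <- function(values, k) {
  x <- sort(unique(values))
  w <- as.numeric(table(factor(values, levels = x)))
  n <- length(x)
  stopifnot(k <= n)
  sse <- function(idx) {
    mu <- sum(w[idx] * x[idx]) / sum(w[idx])
    sum(w[idx] * (x[idx] - mu)^2)
  }
  if (k == 1) return(list(cost = sse(seq_len(n)), groups = rep(1L, n)))
  best <- Inf
  best_groups <- NULL
  for (splits in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bounds <- c(0, splits, n)
    groups <- rep(seq_len(k), diff(bounds))
    cost <- sum(vapply(seq_len(k), function(j) sse(which(groups == j)),
                       numeric(1)))
    if (cost < best - 1e-12) {
      best <- cost
      best_groups <- groups
    }
  }
  list(cost = best, groups = best_groups)
}

dynamic_scale_cost <- function(scale, metric, values) {
  groups <- dynamic_score(scale, metric, values)
  sum(vapply(unique(groups), function(gr) {
    v <- values[groups == gr]
    sum((v - mean(v))^2)
  }, numeric(1)))
}

# Printed score matrix of the four-metric running example (rows s_1..s_6).
example_scores <- function() {
  rbind(
    c(5, 4, 2, 1),
    c(5, 4, 2, 1),
    c(4, 3, 2, 1),
    c(3, 4, 5, 1),
    c(1, 5, 5, 2),
    c(5, 1, 4, 3)
  )
}

freq_counts <- function(f) setNames(f$count, f$level)
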