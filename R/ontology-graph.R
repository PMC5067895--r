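#' Construct a structural ontology graph
#'
#' An `ontology_graph` is the uniform structural view of one OWL ontology
#' version that all metric and evolution computations consume. It records the
#' named-class is-a DAG together with the countable structural features:
#' property declarations, property usages inside restriction axioms and
#' individual assertions, annotation assertions, asserted individuals and
#' deprecation flags. The hierarchy root `owl:Thing` is implicit: it is never
#' a member of `classes`, and a class with no recorded parent is a direct
#' child of the root. Subclass edges whose parent is `owl:Thing` are therefore
#' dropped on construction.
#'
#' @param classes Character vector of named-class IRIs.
#' @param subclass_edges Data frame with columns `child`, `parent` (IRIs);
#'   both endpoints must be declared classes (edges to `owl:Thing` are
#'   normalised away). The relation must be acyclic.
#' @param object_properties,data_properties Character vectors of property IRIs.
#' @param restrictions Data frame with columns `class`, `property`, `kind`
#'   (one of `"some"`, `"all"`, `"value"`, `"min"`, `"max"`, `"exact"`) and
#'   `filler` (class IRI, individual IRI or literal, as character). Each row
#'   is one restriction expression in a class axiom and one usage of its
#'   property.
#' @param annotations Data frame with columns `class`, `property`, `value`:
#'   one annotation assertion per row.
#' @param individuals Data frame with columns `individual`, `class`.
#' @param assertions Data frame with columns `individual`, `property`,
#'   `value`: property assertions on individuals; each row is one usage of
#'   its property.
#' @param deprecated Character vector of class IRIs flagged obsolete.
#' @param base_iri Namespace used when serialising.
#'
#' @return An object of class `ontology_graph`.
#' @seealso [read_ontology()], [write_ontology()], [compute_metrics()],
#'   [normalise_graph()]
#' @export
ontology_graph <- function(classes = character(),
                           subclass_edges = NULL,
                           object_properties = character(),
                           data_properties = character(),
                           restrictions = NULL,
                           annotations = NULL,
                           individuals = NULL,
                           assertions = NULL,
                           deprecated = character(),
                           base_iri = "http://example.org/onto#") {
  subclass_edges <- as_tbl(subclass_edges, c(child = "character", parent = "character"))
  restrictions <- as_tbl(restrictions, c(class = "character", property = "character",
                                         kind = "character", filler = "character"))
  annotations <- as_tbl(annotations, c(class = "character", property = "character",
                                       value = "character"))
  individuals <- as_tbl(individuals, c(individual = "character", class = "character"))
  assertions <- as_tbl(assertions, c(individual = "character", property = "character",
                                     value = "character"))

  subclass_edges <- dplyr::filter(subclass_edges, .data$parent != OWL_THING)

  g <- structure(
    list(
      classes = unique(as.character(classes)),
      subclass_edges = dplyr::distinct(subclass_edges),
      object_properties = unique(as.character(object_properties)),
      data_properties = unique(as.character(data_properties)),
      restrictions = restrictions,
      annotations = annotations,
      individuals = individuals,
      assertions = assertions,
      deprecated = unique(as.character(deprecated)),
      base_iri = base_iri
    ),
    class = "ontology_graph"
  )
  validate_ontology_graph(g)
}

as_tbl <- function(x, spec) {
  if (is.null(x)) {
    cols <- lapply(spec, function(t) vector(t, 0L))
    return(tibble::as_tibble(cols))
  }
  x <- tibble::as_tibble(x)
  missing <- setdiff(names(spec), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  x[names(spec)]
}

validate_ontology_graph <- function(g) {
  cl <- g$classes
  e <- g$subclass_edges
  bad <- setdiff(unique(c(e$child, e$parent)), cl)
  if (length(bad) > 0) {
    abort(paste0("subclass edge endpoint(s) not declared as classes: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  cyc <- find_cycle(cl, e)
  if (!is.null(cyc)) {
    abort(paste0("subclass relation is cyclic: ",
                 paste(cyc, collapse = " -> ")),
          class = "oquare_cycle_error")
  }
  known_props <- c(g$object_properties, g$data_properties)
  if (nrow(g$restrictions) > 0 && !all(g$restrictions$property %in% known_props)) {
    abort("restriction uses an undeclared property")
  }
  if (nrow(g$restrictions) > 0 &&
      !all(g$restrictions$kind %in% c("some", "all", "value", "min", "max", "exact"))) {
    abort("unknown restriction kind")
  }
  if (!all(g$restrictions$class %in% cl)) abort("restriction on an undeclared class")
  if (!all(g$annotations$class %in% cl)) abort("annotation on an undeclared class")
  if (!all(g$individuals$class %in% cl)) abort("individual asserted to an undeclared class")
  if (nrow(g$assertions) > 0 && !all(g$assertions$individual %in% g$individuals$individual)) {
    abort("assertion on an undeclared individual")
  }
  if (!all(g$deprecated %in% cl)) abort("deprecated flag on an undeclared class")
  g
}

# Kahn topological sort; returns NULL if acyclic, else one cycle as a
# character vector of IRIs (closed: first element repeated at the end).
find_cycle <- function(classes, edges) {
  if (nrow(edges) == 0) return(NULL)
  indeg <- setNames(integer(length(classes)), classes)
  tab <- table(edges$child)  # edges point child -> parent; count per child
  indeg[names(tab)] <- as.integer(tab)
  # Peel nodes with no outstanding child->parent obligations: treat edge as
  # child depends-on parent; peel parents with no unpeeled children.
  remaining <- edges
  queue <- setdiff(classes, remaining$child)
  peeled <- character()
  while (length(queue) > 0) {
    n <- queue[[1]]
    queue <- queue[-1]
    peeled <- c(peeled, n)
    hit <- remaining$parent == n
    if (any(hit)) {
      kids <- remaining$child[hit]
      remaining <- remaining[!hit, , drop = FALSE]
      freed <- kids[!(kids %in% remaining$child)]
      queue <- c(queue, freed)
    }
  }
  if (nrow(remaining) == 0) return(NULL)
  # Walk the residual edges to exhibit a concrete cycle.
  start <- remaining$child[[1]]
  path <- start
  cur <- start
  repeat {
    nxt <- remaining$parent[remaining$child == cur][[1]]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", length(x$classes), " classes, ",
      nrow(x$subclass_edges), " subclass edges, ",
      length(x$object_properties), "+", length(x$data_properties),
      " properties, ", nrow(x$restrictions), " restrictions, ",
      nrow(x$annotations), " annotations, ", nrow(x$individuals),
      " individuals, ", length(x$deprecated), " deprecated\n", sep = "")
  invisible(x)
}

#' @export
format.ontology_graph <- function(x, ...) {
  paste0("<ontology_graph: ", length(x$classes), " classes>")
}

# ---- structural accessors ---------------------------------------------------

# Classes with no named parent: direct children of the implicit root.
root_children <- function(g) {
  setdiff(g$classes, unique(g$subclass_edges$child))
}

# Classes with no named child.
leaf_classes <- function(g) {
  setdiff(g$classes, unique(g$subclass_edges$parent))
}

# Usage count per property IRI: restriction occurrences plus individual
# property assertions. Declarations and domain/range axioms do not count.
property_usages <- function(g) {
  props <- c(g$object_properties, g$data_properties)
  n <- setNames(integer(length(props)), props)
  for (p in c(g$restrictions$property, g$assertions$property)) {
    n[[p]] <- n[[p]] + 1L
  }
  n
}

total_usages <- function(g) nrow(g$restrictions) + nrow(g$assertions)

# Per-class fingerprint of local axioms and annotations: direct parents,
# restriction expressions, annotation assertions, deprecation flag, asserted
# individuals and their property assertions. Two versions of a class compare
# equal iff these strings are equal.
class_fingerprints <- function(g) {
  fp <- setNames(vector("list", length(g$classes)), g$classes)
  add <- function(cls, txt) {
    for (i in seq_along(cls)) fp[[cls[[i]]]] <<- c(fp[[cls[[i]]]], txt[[i]])
  }
  e <- g$subclass_edges
  if (nrow(e) > 0) add(e$child, paste0("parent:", e$parent))
  r <- g$restrictions
  if (nrow(r) > 0) add(r$class, paste0("restr:", r$property, "|", r$kind, "|", r$filler))
  a <- g$annotations
  if (nrow(a) > 0) add(a$class, paste0("ann:", a$property, "|", a$value))
  if (length(g$deprecated) > 0) add(g$deprecated, rep("deprecated", length(g$deprecated)))
  ind <- g$individuals
  if (nrow(ind) > 0) add(ind$class, paste0("ind:", ind$individual))
  s <- g$assertions
  if (nrow(s) > 0) {
    owner <- ind$class[match(s$individual, ind$individual)]
    add(owner, paste0("assert:", s$individual, "|", s$property, "|", s$value))
  }
  vapply(fp, function(v) paste(sort(v), collapse = "\n"), character(1))
}

# ---- normalisation ----------------------------------------------------------

#' Remove deprecated classes from an ontology graph
#'
#' Normalisation drops every class flagged obsolete together with its incident
#' subclass edges, annotations, individuals (and their assertions), its own
#' restriction expressions and any restriction elsewhere whose filler names a
#' removed class. Children whose only parents were removed become direct
#' children of the implicit root (no re-wiring is needed: parentless classes
#' are root children by convention). The operation is idempotent.
#'
#' @param graph An [ontology_graph()].
#' @param remove_deprecated If `FALSE` the graph is returned unchanged.
#' @return A valid `ontology_graph` without deprecated classes.
#' @export
normalise_graph <- function(graph, remove_deprecated = TRUE) {
  stopifnot(inherits(graph, "ontology_graph"))
  if (!remove_deprecated || length(graph$deprecated) == 0) return(graph)
  drop <- graph$deprecated
  keep_ind <- graph$individuals[!(graph$individuals$class %in% drop), , drop = FALSE]
  ontology_graph(
    classes = setdiff(graph$classes, drop),
    subclass_edges = dplyr::filter(graph$subclass_edges,
                                   !(.data$child %in% drop), !(.data$parent %in% drop)),
    object_properties = graph$object_properties,
    data_properties = graph$data_properties,
    restrictions = dplyr::filter(graph$restrictions,
                                 !(.data$class %in% drop), !(.data$filler %in% drop)),
    annotations = dplyr::filter(graph$annotations, !(.data$class %in% drop)),
    individuals = keep_ind,
    assertions = dplyr::filter(graph$assertions,
                               .data$individual %in% keep_ind$individual),
    deprecated = character(),
    base_iri = graph$base_iri
  )
}

# ---- version diffing --------------------------------------------------------

#' Activity between two ontology versions
#'
#' Counts the classes added, deleted and modified between two versions — the
#' class-level editing-activity variables popularised by the Bubastis diff
#' tool. A shared class counts as changed when its local fingerprint (direct
#' parents, restrictions, annotations, deprecation flag, individuals and
#' their assertions) differs between the versions.
#'
#' @param prev,next_ Ontology graphs for the earlier and later version.
#' @return A one-row tibble with columns `n_new`, `n_deleted`, `n_changed`.
#' @export
diff_versions <- function(prev, next_) {
  stopifnot(inherits(prev, "ontology_graph"), inherits(next_, "ontology_graph"))
  shared <- intersect(prev$classes, next_$classes)
  fp_prev <- class_fingerprints(prev)
  fp_next <- class_fingerprints(next_)
  tibble::tibble(
    n_new = length(setdiff(next_$classes, prev$classes)),
    n_deleted = length(setdiff(prev$classes, next_$classes)),
    n_changed = sum(fp_prev[shared] != fp_next[shared])
  )
}
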