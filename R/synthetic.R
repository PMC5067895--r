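# Seeded generator of biomedical-style is-a hierarchies and mutated version
# corpora, with recorded ground truth so metric, diff and pipeline code can
# be tested without external downloads. IRIs are minted deterministically
# (namespace + zero-padded counters) so fingerprints and diffs are stable;
# the same seed yields a byte-identical corpus.

#' Generate a synthetic ontology
#'
#' Builds a named-class DAG level by level down to `depth` (the first `depth`
#' classes form a spine, one per level, so the construction depth is always
#' attained; remaining classes are assigned uniformly to levels). A class at
#' level 1 is a direct child of the implicit root; deeper classes draw their
#' parent from the level above. A fraction `multi_parent_fraction` of classes
#' receives a second parent drawn from a strictly shallower level than its
#' own, so the graph stays acyclic. Properties, restriction expressions,
#' annotation assertions, individuals, extra property-usage assertions and
#' deprecation flags are sprinkled at the given per-class rates.
#'
#' @param n_classes Number of named classes (>= 1).
#' @param depth Target depth in edges from the root (`1 <= depth <=
#'   n_classes`).
#' @param multi_parent_fraction Fraction of classes given a second direct
#'   parent (tangledness); only classes at level >= 2 are eligible, and the
#'   request errors if infeasible.
#' @param n_object_properties,n_data_properties Property counts.
#' @param restriction_rate Restriction expressions per class (each is one
#'   property usage).
#' @param usage_density Total property usages per class; usages beyond the
#'   restrictions are realised as property assertions on individuals (errors
#'   if there are no individuals to carry them).
#' @param annotation_rate Annotation assertions per class.
#' @param individual_rate Asserted individuals per class.
#' @param deprecation_rate Fraction of classes flagged obsolete.
#' @param seed Integer seed fixing all randomness.
#' @param base_iri Namespace for minted IRIs.
#' @return A list with elements `graph` (the [ontology_graph()]) and `truth`,
#'   a list of exact expected values recorded during construction:
#'   `depth`, `tm_fraction`, `n_multi_parent`, `anonto`, `aronto`, `cronto`,
#'   `inronto`, `nomonto`, plus the raw counts they derive from.
#' @export
generate_ontology <- function(n_classes,
                              depth = max(1L, min(n_classes, 3L)),
                              multi_parent_fraction = 0,
                              n_object_properties = 2,
                              n_data_properties = 1,
                              restriction_rate = 0.2,
                              usage_density = 0.5,
                              annotation_rate = 1,
                              individual_rate = 0.1,
                              deprecation_rate = 0,
                              seed = 1L,
                              base_iri = "http://example.org/onto#") {
  if (n_classes < 1) abort("n_classes must be >= 1")
  if (depth < 1 || depth > n_classes) abort("need 1 <= depth <= n_classes")
  withr_seed(seed)

  cls <- paste0(base_iri, sprintf("C%04d", seq_len(n_classes)))
  level <- integer(n_classes)
  level[seq_len(depth)] <- seq_len(depth)
  if (n_classes > depth) {
    level[(depth + 1):n_classes] <- sample(depth, n_classes - depth, replace = TRUE)
  }

  child <- character()
  parent <- character()
  for (i in seq_len(n_classes)) {
    if (level[[i]] == 1) next
    cand <- which(level == level[[i]] - 1 & seq_len(n_classes) != i)
    p <- if (length(cand) == 1) cand else sample(cand, 1)
    child <- c(child, cls[[i]])
    parent <- c(parent, cls[[p]])
  }

  n_multi <- round(multi_parent_fraction * n_classes)
  eligible <- which(level >= 2)
  # a second parent must come from a strictly shallower level and differ from
  # the first parent
  can_take <- vapply(eligible, function(i) {
    sum(level < level[[i]]) >= 2 || {
      first <- parent[match(cls[[i]], child)]
      any(level < level[[i]] & cls != first)
    }
  }, logical(1))
  eligible <- eligible[can_take]
  if (n_multi > length(eligible)) {
    abort(paste0("multi_parent_fraction infeasible: need ", n_multi,
                 " multi-parent classes but only ", length(eligible),
                 " are eligible"))
  }
  multi <- if (n_multi > 0) sort(sample_n_of(eligible, n_multi)) else integer()
  for (i in multi) {
    first <- parent[match(cls[[i]], child)]
    cand <- which(level < level[[i]] & cls != first)
    p <- if (length(cand) == 1) cand else sample(cand, 1)
    child <- c(child, cls[[i]])
    parent <- c(parent, cls[[p]])
  }
  edges <- tibble::tibble(child = child, parent = parent)

  obj_props <- if (n_object_properties > 0) {
    paste0(base_iri, sprintf("P%03d", seq_len(n_object_properties)))
  } else character()
  data_props <- if (n_data_properties > 0) {
    paste0(base_iri, sprintf("D%03d", seq_len(n_data_properties)))
  } else character()
  props <- c(obj_props, data_props)

  n_restr <- round(restriction_rate * n_classes)
  if (n_restr > 0 && length(obj_props) == 0) {
    abort("restriction_rate > 0 needs at least one object property")
  }
  restrictions <- if (n_restr > 0) {
    tibble::tibble(
      class = cls[sample.int(n_classes, n_restr, replace = TRUE)],
      property = obj_props[sample.int(length(obj_props), n_restr, replace = TRUE)],
      kind = sample(c("some", "all", "min"), n_restr, replace = TRUE),
      filler = cls[sample.int(n_classes, n_restr, replace = TRUE)]
    )
  } else NULL
  if (!is.null(restrictions)) {
    card <- restrictions$kind == "min"
    restrictions$filler[card] <- as.character(sample.int(3, sum(card), replace = TRUE))
  }

  n_ann <- round(annotation_rate * n_classes)
  ann_props <- paste0(NS_RDFS, c("label", "comment"))
  annotations <- if (n_ann > 0) {
    tibble::tibble(
      class = cls[sample.int(n_classes, n_ann, replace = TRUE)],
      property = ann_props[sample.int(2, n_ann, replace = TRUE)],
      value = paste0("term ", sample.int(10000, n_ann, replace = TRUE))
    )
  } else NULL

  n_ind <- round(individual_rate * n_classes)
  individuals <- if (n_ind > 0) {
    tibble::tibble(
      individual = paste0(base_iri, sprintf("I%04d", seq_len(n_ind))),
      class = cls[sample.int(n_classes, n_ind, replace = TRUE)]
    )
  } else NULL

  n_usage_extra <- max(0, round(usage_density * n_classes) - n_restr)
  if (n_usage_extra > 0 && n_ind == 0) {
    abort("usage_density exceeds restriction_rate but individual_rate is 0: no individuals to carry property assertions")
  }
  assertions <- if (n_usage_extra > 0) {
    prop <- props[sample.int(length(props), n_usage_extra, replace = TRUE)]
    tibble::tibble(
      individual = individuals$individual[sample.int(n_ind, n_usage_extra,
                                                     replace = TRUE)],
      property = prop,
      value = ifelse(prop %in% obj_props,
                     individuals$individual[sample.int(n_ind, n_usage_extra,
                                                       replace = TRUE)],
                     as.character(sample.int(100, n_usage_extra, replace = TRUE)))
    )
  } else NULL

  n_dep <- round(deprecation_rate * n_classes)
  deprecated <- if (n_dep > 0) cls[sample_n_of(seq_len(n_classes), n_dep)] else character()

  graph <- ontology_graph(
    classes = cls, subclass_edges = edges,
    object_properties = obj_props, data_properties = data_props,
    restrictions = restrictions, annotations = annotations,
    individuals = individuals, assertions = assertions,
    deprecated = deprecated, base_iri = base_iri
  )
  truth <- list(
    depth = depth,
    n_multi_parent = n_multi,
    tm_fraction = n_multi / n_classes,
    n_edges = nrow(edges),
    n_usages = n_restr + n_usage_extra,
    anonto = n_ann / n_classes,
    aronto = n_restr / n_classes,
    cronto = n_ind / n_classes,
    inronto = nrow(edges) / n_classes,
    nomonto = (n_restr + n_usage_extra) / n_classes
  )
  list(graph = graph, truth = truth)
}

# sample() without the length-1 surprise
sample_n_of <- function(x, n) x[sample.int(length(x), n)]

withr_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' Mutation plan for a successor version
#'
#' An ordered recipe of edit operations applied by [mutate_version()]:
#' `add_class` new leaf classes, `delete_class` leaf deletions,
#' `deprecate_class` obsolescence flags, `add_restriction` new restriction
#' expressions, `edit_annotation` annotation value edits (or additions),
#' `add_usage` new property assertions on individuals, `remove_annotation` /
#' `remove_individual` removals, `add_parent` second parents for single-parent
#' classes and `add_property` new (unused) object properties.
#'
#' @param add_class,delete_class,deprecate_class,add_restriction Counts.
#' @param edit_annotation,add_usage,remove_annotation,remove_individual Counts.
#' @param add_parent,add_property Counts.
#' @param seed Integer seed fixing the choice of targets.
#' @return A `mutation_plan` list.
#' @export
mutation_plan <- function(add_class = 0, delete_class = 0, deprecate_class = 0,
                          add_restriction = 0, edit_annotation = 0,
                          add_usage = 0, remove_annotation = 0,
                          remove_individual = 0, add_parent = 0,
                          add_property = 0, seed = 1L) {
  ops <- list(add_class = add_class, delete_class = delete_class,
              deprecate_class = deprecate_class, add_restriction = add_restriction,
              edit_annotation = edit_annotation, add_usage = add_usage,
              remove_annotation = remove_annotation,
              remove_individual = remove_individual, add_parent = add_parent,
              add_property = add_property)
  stopifnot(all(vapply(ops, function(x) x >= 0, logical(1))))
  structure(c(ops, list(seed = seed)), class = "mutation_plan")
}

#' Apply a mutation plan to an ontology version
#'
#' Produces the successor graph and the exact class-activity delta the plan
#' induces (which [diff_versions()] must reproduce). New classes attach to an
#' existing class (or the root) as leaves; deletions pick leaf classes;
#' second parents are drawn from strictly shallower levels, so no mutation
#' can create a cycle. Edit operations pick distinct surviving classes where
#' possible, and the returned `delta` counts the exact set of touched
#' survivors.
#'
#' @param graph An [ontology_graph()].
#' @param plan A [mutation_plan()].
#' @return A list with `graph` (the successor) and `delta`, a one-row tibble
#'   (`n_new`, `n_deleted`, `n_changed`).
#' @export
mutate_version <- function(graph, plan) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(plan, "mutation_plan"))
  withr_seed(plan$seed)
  g <- graph
  touched <- character()
  base <- g$base_iri

  pick <- function(pool, n, avoid = character()) {
    pool <- setdiff(pool, avoid)
    if (length(pool) < n) abort("mutation plan not applicable: not enough targets")
    sample_n_of(pool, n)
  }

  # deletions first (leaves only), so later ops target survivors
  if (plan$delete_class > 0) {
    victims <- pick(leaf_classes(g), plan$delete_class)
    mentioned <- unique(g$restrictions$class[g$restrictions$filler %in% victims])
    touched <- c(touched, setdiff(mentioned, victims))
    keep_ind <- g$individuals[!(g$individuals$class %in% victims), ]
    g <- ontology_graph(
      classes = setdiff(g$classes, victims),
      subclass_edges = dplyr::filter(g$subclass_edges, !(.data$child %in% victims),
                                     !(.data$parent %in% victims)),
      object_properties = g$object_properties, data_properties = g$data_properties,
      restrictions = dplyr::filter(g$restrictions, !(.data$class %in% victims),
                                   !(.data$filler %in% victims)),
      annotations = dplyr::filter(g$annotations, !(.data$class %in% victims)),
      individuals = keep_ind,
      assertions = dplyr::filter(g$assertions, .data$individual %in% keep_ind$individual),
      deprecated = setdiff(g$deprecated, victims), base_iri = base
    )
    deleted <- victims
  } else {
    deleted <- character()
  }

  added <- character()
  if (plan$add_class > 0) {
    idx <- max(c(0L, as.integer(sub(".*C(\\d+)$", "\\1",
                                    grep("C\\d+$", g$classes, value = TRUE)))))
    added <- paste0(base, sprintf("C%04d", idx + seq_len(plan$add_class)))
    parents <- if (length(g$classes) > 0) {
      sample(g$classes, plan$add_class, replace = TRUE)
    } else character()
    g$classes <- c(g$classes, added)
    if (length(parents) > 0) {
      g$subclass_edges <- dplyr::bind_rows(
        g$subclass_edges, tibble::tibble(child = added, parent = parents))
    }
  }

  if (plan$add_property > 0) {
    idx <- max(c(0L, as.integer(sub(".*P(\\d+)$", "\\1",
                                    grep("P\\d+$", g$object_properties, value = TRUE)))))
    g$object_properties <- c(g$object_properties,
                             paste0(base, sprintf("P%03d", idx + seq_len(plan$add_property))))
  }

  if (plan$add_parent > 0) {
    depth_of <- root_path_stats(g)
    single <- g$classes[!(g$classes %in% added)]
    single <- single[vapply(single, function(cl) {
      sum(g$subclass_edges$child == cl) == 1
    }, logical(1))]
    ok <- vapply(single, function(cl) {
      first <- g$subclass_edges$parent[g$subclass_edges$child == cl]
      any(depth_of[g$classes, "depth"] < depth_of[cl, "depth"] &
            g$classes != first)
    }, logical(1))
    targets <- pick(single[ok], plan$add_parent)
    for (cl in targets) {
      first <- g$subclass_edges$parent[g$subclass_edges$child == cl]
      cand <- g$classes[depth_of[g$classes, "depth"] < depth_of[cl, "depth"] &
                          g$classes != first]
      p <- if (length(cand) == 1) cand else sample(cand, 1)
      g$subclass_edges <- dplyr::bind_rows(g$subclass_edges,
                                           tibble::tibble(child = cl, parent = p))
    }
    touched <- c(touched, targets)
  }

  survivors <- setdiff(graph$classes, deleted)

  if (plan$deprecate_class > 0) {
    targets <- pick(setdiff(survivors, g$deprecated), plan$deprecate_class)
    g$deprecated <- c(g$deprecated, targets)
    touched <- c(touched, targets)
  }

  if (plan$add_restriction > 0) {
    if (length(g$object_properties) == 0) abort("add_restriction needs an object property")
    targets <- pick(survivors, plan$add_restriction)
    g$restrictions <- dplyr::bind_rows(g$restrictions, tibble::tibble(
      class = targets,
      property = sample(g$object_properties, plan$add_restriction, replace = TRUE),
      kind = "some",
      filler = sample(g$classes, plan$add_restriction, replace = TRUE)
    ))
    touched <- c(touched, targets)
  }

  if (plan$edit_annotation > 0) {
    targets <- pick(survivors, plan$edit_annotation)
    for (cl in targets) {
      hit <- which(g$annotations$class == cl)
      if (length(hit) > 0) {
        g$annotations$value[[hit[[1]]]] <- paste0(g$annotations$value[[hit[[1]]]], " (rev)")
      } else {
        g$annotations <- dplyr::bind_rows(
          g$annotations,
          tibble::tibble(class = cl, property = paste0(NS_RDFS, "comment"),
                         value = "added note"))
      }
    }
    touched <- c(touched, targets)
  }

  if (plan$remove_annotation > 0) {
    pool <- intersect(unique(g$annotations$class), survivors)
    targets <- pick(pool, plan$remove_annotation)
    for (cl in targets) {
      hit <- which(g$annotations$class == cl)
      g$annotations <- g$annotations[-hit[[1]], ]
    }
    touched <- c(touched, targets)
  }

  if (plan$remove_individual > 0) {
    pool <- intersect(unique(g$individuals$class), survivors)
    targets <- pick(pool, plan$remove_individual)
    for (cl in targets) {
      hit <- which(g$individuals$class == cl)
      iv <- g$individuals$individual[[hit[[1]]]]
      g$individuals <- g$individuals[-hit[[1]], ]
      if (!(iv %in% g$individuals$individual)) {
        g$assertions <- g$assertions[g$assertions$individual != iv, ]
      }
    }
    touched <- c(touched, targets)
  }

  if (plan$add_usage > 0) {
    if (nrow(g$individuals) == 0) abort("add_usage needs at least one individual")
    pool <- g$individuals[g$individuals$class %in% survivors, ]
    rows <- pool[sample.int(nrow(pool), plan$add_usage, replace = TRUE), ]
    props <- c(g$object_properties, g$data_properties)
    g$assertions <- dplyr::bind_rows(g$assertions, tibble::tibble(
      individual = rows$individual,
      property = sample(props, plan$add_usage, replace = TRUE),
      value = as.character(sample.int(1000, plan$add_usage, replace = TRUE))
    ))
    touched <- c(touched, rows$class)
  }

  g <- validate_ontology_graph(g)
  delta <- tibble::tibble(
    n_new = length(added),
    n_deleted = length(deleted),
    n_changed = length(unique(setdiff(touched, deleted)))
  )
  list(graph = g, delta = delta)
}

#' Generate a versioned corpus on disk
#'
#' Writes `v001.owl ... vNNN.owl` (or `.ttl`) into a directory together with
#' a `manifest.json` recording the version order, generator ground truth and
#' the exact per-pair activity deltas.
#'
#' @param dir Output directory (created if missing).
#' @param n_versions Number of versions (>= 1).
#' @param params Arguments for [generate_ontology()] as a list.
#' @param plans List of `n_versions - 1` [mutation_plan()]s, or a single plan
#'   recycled (its seed is offset per version so versions differ).
#' @param dialect `"rdfxml"` or `"turtle"`.
#' @param seed Master seed; per-version seeds derive from it.
#' @return Invisibly, a list with `paths`, `graphs`, `deltas` (tibble) and
#'   `manifest` path.
#' @export
generate_corpus <- function(dir, n_versions, params = list(n_classes = 30),
                            plans = NULL, dialect = c("rdfxml", "turtle"),
                            seed = 1L) {
  dialect <- match.arg(dialect)
  stopifnot(n_versions >= 1)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  params$seed <- params$seed %||% seed
  first <- do.call(generate_ontology, params)
  if (is.null(plans)) {
    plans <- lapply(seq_len(max(0, n_versions - 1)), function(i) {
      mutation_plan(add_class = 2, edit_annotation = 1, add_restriction = 1,
                    seed = seed + i)
    })
  } else if (inherits(plans, "mutation_plan")) {
    base_plan <- plans
    plans <- lapply(seq_len(max(0, n_versions - 1)), function(i) {
      p <- base_plan
      p$seed <- base_plan$seed + i
      p
    })
  }
  stopifnot(length(plans) == n_versions - 1)
  graphs <- vector("list", n_versions)
  graphs[[1]] <- first$graph
  deltas <- vector("list", max(0, n_versions - 1))
  for (i in seq_len(max(0, n_versions - 1))) {
    step <- mutate_version(graphs[[i]], plans[[i]])
    graphs[[i + 1]] <- step$graph
    deltas[[i]] <- dplyr::mutate(step$delta, version = sprintf("v%03d", i + 1),
                                 .before = 1)
  }
  ext <- if (dialect == "turtle") ".ttl" else ".owl"
  paths <- file.path(dir, sprintf("v%03d%s", seq_len(n_versions), ext))
  for (i in seq_len(n_versions)) write_ontology(graphs[[i]], paths[[i]], dialect)
  deltas <- if (n_versions > 1) purrr::list_rbind(deltas) else NULL
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(versions = basename(paths), truth = first$truth,
         deltas = deltas),
    manifest, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  names(graphs) <- sprintf("v%03d", seq_len(n_versions))
  invisible(list(paths = paths, graphs = graphs, deltas = deltas,
                 manifest = manifest))
}
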