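# OWL serialisation. Both dialects are reduced to a triple table
# (subject, predicate, object, object-is-IRI) and assembled by
# graph_from_triples(), so the two readers share all interpretation logic.
#
# Supported subset (documented in the package vignette): named classes with
# rdfs:subClassOf assertions, restriction expressions (some/all/hasValue and
# the three cardinality forms) nested under rdfs:subClassOf or
# owl:equivalentClass, object/datatype property declarations, named
# individuals with type and property assertions, literal- or resource-valued
# annotation assertions on classes, and owl:deprecated flags. Imports closure
# resolution and OBO flat files are out of scope.

#' Read an OWL ontology into a structural graph
#'
#' Parses an OWL file (RDF/XML or Turtle) into an [ontology_graph()].
#' Anonymous class expressions are never added to the class set, but each
#' restriction expression in a class axiom contributes to the restriction
#' count and to the usage count of its property. Classes are flagged
#' deprecated when they carry `owl:deprecated "true"`, an annotation whose
#' property local name contains "deprecated" or "obsolete" with a true-ish
#' value, or a label starting with `OBSOLETE` (a common convention in
#' OBO-style biomedical ontologies); pass a
#' custom `deprecation` predicate to override.
#'
#' @param source Path to the ontology file.
#' @param dialect `"auto"` (default; sniffs the file), `"rdfxml"` or
#'   `"turtle"`.
#' @param deprecation Either `"default"` or a function
#'   `f(class_iri, annotations)` returning `TRUE` for obsolete classes, where
#'   `annotations` is the class's annotation tibble.
#' @return An [ontology_graph()].
#' @export
read_ontology <- function(source, dialect = c("auto", "rdfxml", "turtle"),
                          deprecation = "default") {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) {
    abort(paste0("ontology file not found: ", source), class = "oquare_io_error")
  }
  if (dialect == "auto") dialect <- sniff_dialect(source)
  triples <- switch(dialect,
    rdfxml = rdfxml_triples(source),
    turtle = turtle_triples(source)
  )
  graph_from_triples(triples, deprecation = deprecation)
}

sniff_dialect <- function(path) {
  if (grepl("\\.(ttl|turtle)$", path, ignore.case = TRUE)) return("turtle")
  if (grepl("\\.(owl|rdf|xml)$", path, ignore.case = TRUE)) return("rdfxml")
  txt <- readChar(path, min(file.size(path), 2048L), useBytes = TRUE)
  if (grepl("@prefix", txt, fixed = TRUE)) return("turtle")
  "rdfxml"
}

# ---- triple assembly --------------------------------------------------------

triple_tbl <- function(s = character(), p = character(), o = character(),
                       o_iri = logical()) {
  tibble::tibble(s = s, p = p, o = o, o_iri = o_iri)
}

is_blank <- function(x) startsWith(x, "_:")

graph_from_triples <- function(tr, deprecation = "default") {
  typed <- function(type_iri) {
    unique(tr$s[tr$p == paste0(NS_RDF, "type") & tr$o == type_iri & !is_blank(tr$s)])
  }
  classes <- typed(paste0(NS_OWL, "Class"))
  obj_props <- typed(paste0(NS_OWL, "ObjectProperty"))
  data_props <- typed(paste0(NS_OWL, "DatatypeProperty"))
  ann_prop_decl <- typed(paste0(NS_OWL, "AnnotationProperty"))
  named_ind <- typed(paste0(NS_OWL, "NamedIndividual"))

  sub_p <- paste0(NS_RDFS, "subClassOf")
  eq_p <- paste0(NS_OWL, "equivalentClass")
  type_p <- paste0(NS_RDF, "type")
  dep_p <- paste0(NS_OWL, "deprecated")

  edges <- tr[tr$p == sub_p & tr$o_iri & !is_blank(tr$s) & !is_blank(tr$o), ]
  edges <- edges[edges$s %in% classes & (edges$o %in% classes | edges$o == OWL_THING), ]
  subclass_edges <- tibble::tibble(child = edges$s, parent = edges$o)

  # restriction blank nodes linked from a named class
  links <- tr[tr$p %in% c(sub_p, eq_p) & tr$o_iri & is_blank(tr$o) & tr$s %in% classes, ]
  restr_kind <- c(some = paste0(NS_OWL, "someValuesFrom"),
                  all = paste0(NS_OWL, "allValuesFrom"),
                  value = paste0(NS_OWL, "hasValue"),
                  min = paste0(NS_OWL, "minCardinality"),
                  max = paste0(NS_OWL, "maxCardinality"),
                  exact = paste0(NS_OWL, "cardinality"))
  on_prop <- paste0(NS_OWL, "onProperty")
  restr_type <- paste0(NS_OWL, "Restriction")
  restrictions <- purrr::map2(links$s, links$o, function(cls, b) {
    bt <- tr[tr$s == b, ]
    if (!any(bt$p == type_p & bt$o == restr_type)) return(NULL)
    prop <- bt$o[bt$p == on_prop]
    if (length(prop) != 1) return(NULL)
    for (k in names(restr_kind)) {
      hit <- bt$p == restr_kind[[k]]
      if (any(hit)) {
        return(tibble::tibble(class = cls, property = prop,
                              kind = k, filler = bt$o[hit][[1]]))
      }
    }
    NULL
  }) |> purrr::list_rbind()
  if (nrow(restrictions) == 0) {
    restrictions <- tibble::tibble(class = character(), property = character(),
                                   kind = character(), filler = character())
  }

  # individuals: class membership = any asserted type that is a named class
  ind_types <- tr[tr$p == type_p & tr$s %in% named_ind & tr$o %in% classes, ]
  individuals <- dplyr::distinct(tibble::tibble(individual = ind_types$s,
                                                class = ind_types$o))
  props <- c(obj_props, data_props)
  asrt <- tr[tr$s %in% individuals$individual & tr$p %in% props, ]
  assertions <- tibble::tibble(individual = asrt$s, property = asrt$p,
                               value = asrt$o)

  # annotations: every other statement about a named class with a literal or
  # plain-IRI object (deprecation flags are kept apart from annotations)
  core <- c(sub_p, eq_p, type_p, dep_p)
  ann <- tr[tr$s %in% classes & !(tr$p %in% core) & !is_blank(tr$o), ]
  annotations <- tibble::tibble(class = ann$s, property = ann$p, value = ann$o)

  dep_flag <- unique(tr$s[tr$p == dep_p & tolower(tr$o) %in% c("true", "1") &
                            tr$s %in% classes])
  if (is.function(deprecation)) {
    extra <- purrr::keep(classes, function(cl) {
      isTRUE(deprecation(cl, annotations[annotations$class == cl, ]))
    })
    deprecated <- union(dep_flag, extra)
  } else {
    deprecated <- union(dep_flag, default_deprecated(classes, annotations))
  }

  ontology_graph(
    classes = classes,
    subclass_edges = subclass_edges,
    object_properties = obj_props,
    data_properties = data_props,
    restrictions = restrictions,
    annotations = annotations,
    individuals = individuals,
    assertions = assertions,
    deprecated = deprecated
  )
}

default_deprecated <- function(classes, annotations) {
  if (nrow(annotations) == 0) return(character())
  local <- sub(".*[#/]", "", annotations$property)
  obo <- grepl("deprecated|obsolete", local, ignore.case = TRUE) &
    tolower(annotations$value) %in% c("true", "1")
  lab <- grepl("label$", local) & startsWith(annotations$value, "OBSOLETE")
  unique(annotations$class[obo | lab])
}

# ---- RDF/XML reader ---------------------------------------------------------

rdfxml_triples <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("cannot parse '", path,
                                                   "' as RDF/XML: ", conditionMessage(e)),
                                            class = "oquare_parse_error"))
  ns <- tryCatch(xml2::xml_ns(doc), error = function(e) character())
  root_name <- resolve_qname(xml2::xml_name(doc, ns), ns)
  if (!identical(root_name, paste0(NS_RDF, "RDF"))) {
    abort(paste0("cannot parse '", path, "' as RDF/XML: root element is not rdf:RDF"),
          class = "oquare_parse_error")
  }
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$bn <- 0L
  for (node in xml2::xml_children(doc)) rdfxml_node(node, ns, env)
  if (length(env$rows) == 0) return(triple_tbl())
  purrr::list_rbind(env$rows)
}

resolve_qname <- function(qname, ns) {
  parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1) return(parts[[1]])
  uri <- unname(ns[parts[[1]]])
  if (is.na(uri) || is.null(uri)) return(qname)
  paste0(uri, paste(parts[-1], collapse = ":"))
}

rdf_attr <- function(node, local) {
  at <- xml2::xml_attrs(node)
  hit <- names(at) %in% c(local, paste0("rdf:", local)) |
    endsWith(names(at), paste0(":", local))
  if (any(hit)) unname(at[hit][[1]]) else NA_character_
}

# Emits triples for one node element; returns its subject id.
rdfxml_node <- function(node, ns, env) {
  emit <- function(s, p, o, o_iri) {
    env$rows[[length(env$rows) + 1L]] <- triple_tbl(s, p, o, o_iri)
  }
  about <- rdf_attr(node, "about")
  if (is.na(about)) {
    env$bn <- env$bn + 1L
    subj <- paste0("_:b", env$bn)
  } else {
    subj <- about
  }
  type_iri <- resolve_qname(xml2::xml_name(node, ns), ns)
  if (!identical(type_iri, paste0(NS_RDF, "Description"))) {
    emit(subj, paste0(NS_RDF, "type"), type_iri, TRUE)
  }
  for (child in xml2::xml_children(node)) {
    pred <- resolve_qname(xml2::xml_name(child, ns), ns)
    res <- rdf_attr(child, "resource")
    kids <- xml2::xml_children(child)
    if (!is.na(res)) {
      emit(subj, pred, res, TRUE)
    } else if (length(kids) > 0) {
      obj <- rdfxml_node(kids[[1]], ns, env)
      emit(subj, pred, obj, TRUE)
    } else {
      emit(subj, pred, xml2::xml_text(child), FALSE)
    }
  }
  subj
}

# ---- Turtle reader ----------------------------------------------------------

turtle_triples <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  toks <- tryCatch(turtle_tokens(txt),
                   error = function(e) abort(paste0("cannot parse '", path,
                                                    "' as Turtle: ", conditionMessage(e)),
                                             class = "oquare_parse_error"))
  tryCatch(turtle_parse(toks),
           error = function(e) abort(paste0("cannot parse '", path, "' as Turtle: ",
                                            conditionMessage(e)),
                                     class = "oquare_parse_error"))
}

turtle_tokens <- function(txt) {
  pats <- c(
    ws = "^[\\s]+",
    comment = "^#[^\\n]*",
    iri = "^<[^>]*>",
    string = '^"(\\\\.|[^"\\\\])*"(\\^\\^(<[^>]*>|[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_-]*))?',
    prefix_kw = "^@prefix\\b",
    pname = "^[A-Za-z][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*|^:[A-Za-z0-9_.-]*",
    a_kw = "^a\\b",
    number = "^[+-]?[0-9]+(\\.[0-9]+)?",
    punct = "^[\\[\\];,.]"
  )
  out <- list()
  pos <- 1L
  n <- nchar(txt)
  while (pos <= n) {
    rest <- substr(txt, pos, n)
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(pats[[ty]], rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        val <- substr(rest, 1L, len)
        if (!(ty %in% c("ws", "comment"))) {
          out[[length(out) + 1L]] <- list(type = ty, value = val)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop("unexpected character at position ", pos, ": '",
           substr(txt, pos, pos + 20), "'")
    }
  }
  out
}

turtle_parse <- function(toks) {
  prefixes <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, xsd = NS_XSD)
  rows <- list()
  bn <- 0L
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  take <- function(type = NULL) {
    tk <- peek()
    if (is.null(tk)) stop("unexpected end of input")
    if (!is.null(type) && tk$type != type) {
      stop("expected ", type, ", got ", tk$type, " '", tk$value, "'")
    }
    i <<- i + 1L
    tk
  }
  emit <- function(s, p, o, o_iri) {
    rows[[length(rows) + 1L]] <<- triple_tbl(s, p, o, o_iri)
  }
  expand <- function(tk) {
    if (tk$type == "iri") return(substr(tk$value, 2L, nchar(tk$value) - 1L))
    if (tk$type == "a_kw") return(paste0(NS_RDF, "type"))
    if (tk$type == "pname") {
      parts <- strsplit(tk$value, ":", fixed = TRUE)[[1]]
      pre <- if (parts[[1]] == "") "" else parts[[1]]
      uri <- prefixes[pre]
      if (is.na(uri)) stop("undeclared prefix '", pre, ":'")
      return(paste0(unname(uri), if (length(parts) > 1) parts[[2]] else ""))
    }
    stop("expected IRI term, got ", tk$type)
  }
  parse_object <- function() {
    tk <- peek()
    if (tk$type == "string") {
      take()
      lit <- sub('\\^\\^\\S+$', "", tk$value)
      lit <- substr(lit, 2L, nchar(lit) - 1L)
      lit <- gsub('\\\\(["\\\\])', "\\1", lit)
      return(list(value = lit, iri = FALSE))
    }
    if (tk$type == "number") {
      take()
      return(list(value = tk$value, iri = FALSE))
    }
    if (tk$type == "punct" && tk$value == "[") {
      take()
      bn <<- bn + 1L
      id <- paste0("_:b", bn)
      parse_pol(id)
      close_tk <- take("punct")
      if (close_tk$value != "]") stop("expected ']'")
      return(list(value = id, iri = TRUE))
    }
    list(value = expand(take()), iri = TRUE)
  }
  parse_pol <- function(subj) {
    repeat {
      pred <- expand(take())
      repeat {
        obj <- parse_object()
        emit(subj, pred, obj$value, obj$iri)
        tk <- peek()
        if (!is.null(tk) && tk$type == "punct" && tk$value == ",") take() else break
      }
      tk <- peek()
      if (!is.null(tk) && tk$type == "punct" && tk$value == ";") {
        take()
        tk2 <- peek()
        # allow trailing ';' before '.' or ']'
        if (!is.null(tk2) && tk2$type == "punct" && tk2$value %in% c(".", "]")) break
      } else break
    }
  }
  while (!is.null(peek())) {
    tk <- peek()
    if (tk$type == "prefix_kw") {
      take()
      pn <- take("pname")$value
      pre <- sub(":$", "", pn)
      uri <- expand(take("iri"))
      dot <- take("punct")
      if (dot$value != ".") stop("expected '.' after @prefix")
      prefixes[pre] <- uri
      next
    }
    subj <- expand(take())
    parse_pol(subj)
    dot <- take("punct")
    if (dot$value != ".") stop("expected '.' at end of statement")
  }
  if (length(rows) == 0) return(triple_tbl())
  purrr::list_rbind(rows)
}

# ---- writers ----------------------------------------------------------------

#' Write an ontology graph as OWL
#'
#' Serialises an [ontology_graph()] to RDF/XML or Turtle such that
#' `read_ontology(write_ontology(g, f), f)` reproduces `g` (up to row order).
#' Output is deterministic: entities are written in sorted IRI order.
#'
#' @param graph An [ontology_graph()].
#' @param path Output file path.
#' @param dialect `"rdfxml"` (default) or `"turtle"`.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(graph, path, dialect = c("rdfxml", "turtle")) {
  stopifnot(inherits(graph, "ontology_graph"))
  dialect <- match.arg(dialect)
  txt <- switch(dialect,
    rdfxml = owl_rdfxml_text(graph),
    turtle = owl_turtle_text(graph)
  )
  ok <- tryCatch({
    writeLines(txt, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot write to '", path, "'"), class = "oquare_io_error")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

split_iri <- function(iri) {
  m <- regexpr("[#/](?=[^#/]*$)", iri, perl = TRUE)
  if (m < 0) abort(paste0("cannot derive a QName from IRI: ", iri))
  list(ns = substr(iri, 1, m), local = substr(iri, m + 1L, nchar(iri)))
}

restriction_elem <- c(some = "owl:someValuesFrom", all = "owl:allValuesFrom",
                      value = "owl:hasValue", min = "owl:minCardinality",
                      max = "owl:maxCardinality", exact = "owl:cardinality")

owl_rdfxml_text <- function(g) {
  # prefix map for annotation / assertion properties
  extra_iri <- unique(c(g$annotations$property, g$assertions$property))
  extra_ns <- unique(vapply(extra_iri, function(i) split_iri(i)$ns, character(1)))
  std <- c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, xsd = NS_XSD)
  extra_ns <- setdiff(extra_ns, std)
  pref <- std
  if (length(extra_ns) > 0) {
    pref <- c(std, setNames(extra_ns, paste0("ns", seq_along(extra_ns))))
  }
  qname <- function(iri) {
    sp <- split_iri(iri)
    p <- names(pref)[match(sp$ns, pref)]
    paste0(p, ":", sp$local)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0("<rdf:RDF",
           paste0(sprintf('\n    xmlns:%s="%s"', names(pref), pref), collapse = ""),
           ">"),
    sprintf('  <owl:Ontology rdf:about="%s"/>', xml_escape(sub("#$", "", g$base_iri)))
  )
  for (p in sort(g$object_properties)) {
    out <- c(out, sprintf('  <owl:ObjectProperty rdf:about="%s"/>', xml_escape(p)))
  }
  for (p in sort(g$data_properties)) {
    out <- c(out, sprintf('  <owl:DatatypeProperty rdf:about="%s"/>', xml_escape(p)))
  }
  for (cl in sort(g$classes)) {
    body <- character()
    par <- sort(g$subclass_edges$parent[g$subclass_edges$child == cl])
    body <- c(body, sprintf('    <rdfs:subClassOf rdf:resource="%s"/>', xml_escape(par)))
    r <- g$restrictions[g$restrictions$class == cl, ]
    if (nrow(r) > 0) {
      r <- dplyr::arrange(r, .data$property, .data$kind, .data$filler)
      for (j in seq_len(nrow(r))) {
        elem <- restriction_elem[[r$kind[[j]]]]
        filler <- if (r$kind[[j]] %in% c("min", "max", "exact")) {
          sprintf('<%s rdf:datatype="%snonNegativeInteger">%s</%s>',
                  elem, NS_XSD, xml_escape(r$filler[[j]]), elem)
        } else {
          sprintf('<%s rdf:resource="%s"/>', elem, xml_escape(r$filler[[j]]))
        }
        body <- c(body, paste0(
          "    <rdfs:subClassOf><owl:Restriction>",
          sprintf('<owl:onProperty rdf:resource="%s"/>', xml_escape(r$property[[j]])),
          filler, "</owl:Restriction></rdfs:subClassOf>"))
      }
    }
    if (cl %in% g$deprecated) {
      body <- c(body, sprintf(
        '    <owl:deprecated rdf:datatype="%sboolean">true</owl:deprecated>', NS_XSD))
    }
    a <- g$annotations[g$annotations$class == cl, ]
    if (nrow(a) > 0) {
      a <- dplyr::arrange(a, .data$property, .data$value)
      body <- c(body, sprintf("    <%s>%s</%s>", vapply(a$property, qname, character(1)),
                              xml_escape(a$value), vapply(a$property, qname, character(1))))
    }
    out <- c(out, sprintf('  <owl:Class rdf:about="%s">', xml_escape(cl)), body,
             "  </owl:Class>")
  }
  ind <- g$individuals
  if (nrow(ind) > 0) {
    for (iv in sort(unique(ind$individual))) {
      body <- sprintf('    <rdf:type rdf:resource="%s"/>',
                      xml_escape(sort(ind$class[ind$individual == iv])))
      s <- g$assertions[g$assertions$individual == iv, ]
      if (nrow(s) > 0) {
        s <- dplyr::arrange(s, .data$property, .data$value)
        is_obj <- s$property %in% g$object_properties
        body <- c(body, ifelse(is_obj,
          sprintf('    <%s rdf:resource="%s"/>',
                  vapply(s$property, qname, character(1)), xml_escape(s$value)),
          sprintf("    <%s>%s</%s>", vapply(s$property, qname, character(1)),
                  xml_escape(s$value), vapply(s$property, qname, character(1)))))
      }
      out <- c(out, sprintf('  <owl:NamedIndividual rdf:about="%s">', xml_escape(iv)),
               body, "  </owl:NamedIndividual>")
    }
  }
  c(out, "</rdf:RDF>")
}

ttl_lit <- function(x) paste0('"', gsub('(["\\\\])', "\\\\\\1", x), '"')

owl_turtle_text <- function(g) {
  out <- c(
    sprintf("@prefix rdf: <%s> .", NS_RDF),
    sprintf("@prefix rdfs: <%s> .", NS_RDFS),
    sprintf("@prefix owl: <%s> .", NS_OWL),
    sprintf("@prefix xsd: <%s> .", NS_XSD),
    ""
  )
  for (p in sort(g$object_properties)) {
    out <- c(out, sprintf("<%s> a owl:ObjectProperty .", p))
  }
  for (p in sort(g$data_properties)) {
    out <- c(out, sprintf("<%s> a owl:DatatypeProperty .", p))
  }
  for (cl in sort(g$classes)) {
    lines <- sprintf("<%s> a owl:Class", cl)
    par <- sort(g$subclass_edges$parent[g$subclass_edges$child == cl])
    lines <- c(lines, sprintf("    rdfs:subClassOf <%s>", par))
    r <- g$restrictions[g$restrictions$class == cl, ]
    if (nrow(r) > 0) {
      r <- dplyr::arrange(r, .data$property, .data$kind, .data$filler)
      for (j in seq_len(nrow(r))) {
        elem <- sub(":", ":", restriction_elem[[r$kind[[j]]]])
        filler <- if (r$kind[[j]] %in% c("min", "max", "exact")) {
          paste0(ttl_lit(r$filler[[j]]), "^^xsd:nonNegativeInteger")
        } else {
          paste0("<", r$filler[[j]], ">")
        }
        lines <- c(lines, sprintf(
          "    rdfs:subClassOf [ a owl:Restriction ; owl:onProperty <%s> ; %s %s ]",
          r$property[[j]], elem, filler))
      }
    }
    if (cl %in% g$deprecated) {
      lines <- c(lines, '    owl:deprecated "true"^^xsd:boolean')
    }
    a <- g$annotations[g$annotations$class == cl, ]
    if (nrow(a) > 0) {
      a <- dplyr::arrange(a, .data$property, .data$value)
      lines <- c(lines, sprintf("    <%s> %s", a$property, ttl_lit(a$value)))
    }
    out <- c(out, paste0(paste(lines, collapse = " ;\n"), " ."))
  }
  ind <- g$individuals
  if (nrow(ind) > 0) {
    for (iv in sort(unique(ind$individual))) {
      lines <- sprintf("<%s> a owl:NamedIndividual", iv)
      lines <- c(lines, sprintf("    rdf:type <%s>",
                                sort(ind$class[ind$individual == iv])))
      s <- g$assertions[g$assertions$individual == iv, ]
      if (nrow(s) > 0) {
        s <- dplyr::arrange(s, .data$property, .data$value)
        is_obj <- s$property %in% g$object_properties
        lines <- c(lines, ifelse(is_obj,
          sprintf("    <%s> <%s>", s$property, s$value),
          sprintf("    <%s> %s", s$property, ttl_lit(s$value))))
      }
      out <- c(out, paste0(paste(lines, collapse = " ;\n"), " ."))
    }
  }
  out
}

#' Test two ontology graphs for structural equality
#'
#' Compares all components up to row and element order.
#'
#' @param a,b Ontology graphs.
#' @return `TRUE` or `FALSE`.
#' @export
graph_equal <- function(a, b) {
  sort_tbl <- function(x) x[do.call(order, as.list(x)), , drop = FALSE]
  eq_tbl <- function(x, y) isTRUE(all.equal(as.data.frame(sort_tbl(x)),
                                            as.data.frame(sort_tbl(y)),
                                            check.attributes = FALSE))
  setequal(a$classes, b$classes) &&
    setequal(a$object_properties, b$object_properties) &&
    setequal(a$data_properties, b$data_properties) &&
    setequal(a$deprecated, b$deprecated) &&
    eq_tbl(a$subclass_edges, b$subclass_edges) &&
    eq_tbl(a$restrictions, b$restrictions) &&
    eq_tbl(a$annotations, b$annotations) &&
    eq_tbl(a$individuals, b$individuals) &&
    eq_tbl(a$assertions, b$assertions)
}
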