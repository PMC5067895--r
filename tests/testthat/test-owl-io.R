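test_that("an empty ontology file parses to an empty graph", {
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines(c('<?xml version="1.0"?>',
               '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
               '         xmlns:owl="http://www.w3.org/2002/07/owl#">',
               '</rdf:RDF>'), f)
  g <- read_ontology(f)
  expect_length(g$classes, 0)
  expect_equal(nrow(g$subclass_edges), 0)

  ft <- withr::local_tempfile(fileext = ".ttl")
  writeLines("@prefix owl: <http://www.w3.org/2002/07/owl#> .", ft)
  gt <- read_ontology(ft)
  expect_length(gt$classes, 0)
})

test_that("unparseable files raise a parse error naming the dialect", {
  f <- withr::local_tempfile(fileext = ".owl")
  writeLines("this is not XML at all <<<", f)
  expect_error(read_ontology(f, dialect = "rdfxml"),
               regexp = "RDF/XML", class = "oquare_parse_error")
  ft <- withr::local_tempfile(fileext = ".ttl")
  writeLines('<http://x#A> a owl:Class', ft)  # missing final '.'
  expect_error(read_ontology(ft, dialect = "turtle"),
               regexp = "Turtle", class = "oquare_parse_error")
  expect_error(read_ontology(file.path(tempdir(), "nope.owl")),
               class = "oquare_io_error")
})

test_that("a subclass cycle among named classes is a structural load error", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "<http://x#A> a owl:Class ; rdfs:subClassOf <http://x#B> .",
    "<http://x#B> a owl:Class ; rdfs:subClassOf <http://x#A> ."
  ), f)
  expect_error(read_ontology(f), class = "oquare_cycle_error")
})

test_that("write/read round-trips generator graphs in both dialects", {
  for (seed in 1:6) {
    gen <- generate_ontology(
      n_classes = sample(3:25, 1), depth = 2,
      multi_parent_fraction = sample(c(0, 0.2), 1),
      restriction_rate = 0.4, usage_density = 0.8,
      annotation_rate = 1.2, individual_rate = 0.3,
      deprecation_rate = 0.1, seed = seed
    )
    for (dialect in c("rdfxml", "turtle")) {
      f <- withr::local_tempfile(fileext = if (dialect == "turtle") ".ttl" else ".owl")
      write_ontology(gen$graph, f, dialect)
      back <- read_ontology(f)
      expect_true(graph_equal(gen$graph, back),
                  label = sprintf("round-trip seed %d dialect %s", seed, dialect))
    }
  }
  # a 5-class tree round-trips to the generator's exact ground truth
  gen5 <- generate_ontology(5, depth = 2, restriction_rate = 0,
                            usage_density = 0, seed = 42)
  f <- withr::local_tempfile(fileext = ".owl")
  write_ontology(gen5$graph, f)
  expect_true(graph_equal(gen5$graph, read_ontology(f)))
})

test_that("anonymous restriction classes count usages but never classes", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "<http://x#p> a owl:ObjectProperty .",
    "<http://x#A> a owl:Class .",
    "<http://x#B> a owl:Class ;",
    "    rdfs:subClassOf <http://x#A> ;",
    "    rdfs:subClassOf [ a owl:Restriction ; owl:onProperty <http://x#p> ; owl:someValuesFrom <http://x#A> ] ."
  ), f)
  g <- read_ontology(f)
  expect_setequal(g$classes, c("http://x#A", "http://x#B"))
  expect_equal(nrow(g$restrictions), 1)
  expect_equal(unname(property_usages(g)["http://x#p"]), 1L)
  expect_equal(nrow(g$subclass_edges), 1)
})

test_that("the three deprecation conventions are all detected", {
  f <- withr::local_tempfile(fileext = ".ttl")
  writeLines(c(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    '<http://x#A> a owl:Class ; owl:deprecated "true"^^<http://www.w3.org/2001/XMLSchema#boolean> .',
    '<http://x#B> a owl:Class ; <http://purl.obolibrary.org/oboInOwl#is_obsolete> "true" .',
    '<http://x#C> a owl:Class ; rdfs:label "OBSOLETE old term" .',
    '<http://x#D> a owl:Class ; rdfs:label "healthy term" .'
  ), f)
  g <- read_ontology(f)
  expect_setequal(g$deprecated, paste0("http://x#", c("A", "B", "C")))
  # custom predicate overrides the default convention
  g2 <- read_ontology(f, deprecation = function(cl, ann) endsWith(cl, "#D"))
  expect_true("http://x#D" %in% g2$deprecated)
})
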