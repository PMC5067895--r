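test_that("generator ground truth matches the computed metrics", {
  # pure tree: no tangledness, cohesion equals the mean leaf depth
  gen <- generate_ontology(25, depth = 4, multi_parent_fraction = 0,
                           seed = 17)
  m <- compute_metrics(gen$graph)
  expect_equal(metric_value(m, "TMOnto"), 0)
  expect_equal(metric_value(m, "DITOnto"), gen$truth$depth)
  lens <- enum_path_lengths(gen$graph)
  expect_equal(metric_value(m, "LCOMOnto"), mean(lens))

  # multi-parent fraction recovered exactly
  gen2 <- generate_ontology(40, depth = 4, multi_parent_fraction = 0.25,
                            seed = 23)
  m2 <- compute_metrics(gen2$graph)
  expect_equal(metric_value(m2, "TMOnto"), 0.25)
  expect_equal(gen2$truth$tm_fraction, 0.25)

  # count-based ground truth
  gen3 <- generate_ontology(30, depth = 3, restriction_rate = 0.4,
                            usage_density = 0.9, annotation_rate = 1.5,
                            individual_rate = 0.3, seed = 29)
  m3 <- compute_metrics(gen3$graph)
  for (pair in list(c("ANOnto", "anonto"), c("AROnto", "aronto"),
                    c("CROnto", "cronto"), c("INROnto", "inronto"),
                    c("NOMOnto", "nomonto"))) {
    expect_equal(metric_value(m3, pair[[1]]), gen3$truth[[pair[[2]]]],
                 label = pair[[1]])
  }
})

test_that("infeasible generator parameters error", {
  expect_error(generate_ontology(3, depth = 5), "depth")
  expect_error(generate_ontology(0), "n_classes")
  expect_error(generate_ontology(4, depth = 2, multi_parent_fraction = 1,
                                 seed = 1), "infeasible")
})

test_that("the same seed reproduces a byte-identical corpus", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- generate_corpus(d1, 3, params = list(n_classes = 15, seed = 9), seed = 9)
  c2 <- generate_corpus(d2, 3, params = list(n_classes = 15, seed = 9), seed = 9)
  for (i in seq_along(c1$paths)) {
    expect_identical(readLines(c1$paths[[i]]), readLines(c2$paths[[i]]))
  }
})

test_that("mutations report the exact activity delta diff_versions sees", {
  g <- generate_ontology(20, depth = 3, annotation_rate = 1,
                         individual_rate = 0.3, usage_density = 0.5,
                         restriction_rate = 0.2, seed = 3)$graph

  # empty plan: identical graph, (0, 0, 0)
  id <- mutate_version(g, mutation_plan(seed = 1))
  expect_true(graph_equal(id$graph, g))
  expect_equal(unlist(id$delta), c(n_new = 0L, n_deleted = 0L, n_changed = 0L))

  # mixed plan: (3 added, 2 deleted, 2 annotation edits)
  step <- mutate_version(g, mutation_plan(add_class = 3, delete_class = 2,
                                          edit_annotation = 2, seed = 5))
  expect_equal(step$delta$n_new, 3)
  expect_equal(step$delta$n_deleted, 2)
  expect_equal(diff_versions(g, step$graph), step$delta, ignore_attr = TRUE)

  # every operation type is visible to diff_versions
  plans <- list(
    mutation_plan(deprecate_class = 1, seed = 2),
    mutation_plan(add_restriction = 2, seed = 2),
    mutation_plan(add_usage = 2, seed = 2),
    mutation_plan(remove_annotation = 1, seed = 2),
    mutation_plan(remove_individual = 1, seed = 2),
    mutation_plan(add_parent = 1, seed = 2)
  )
  for (p in plans) {
    st <- mutate_version(g, p)
    expect_equal(diff_versions(g, st$graph), st$delta, ignore_attr = TRUE)
  }

  # deprecate then normalise drops the class
  dep <- mutate_version(g, mutation_plan(deprecate_class = 1, seed = 4))
  expect_equal(length(normalise_graph(dep$graph)$classes),
               length(g$classes) - 1)

  expect_error(mutate_version(g, mutation_plan(delete_class = 1000, seed = 1)),
               "not applicable")
})

test_that("corpus generation records deltas and round-trips through files", {
  d <- withr::local_tempdir()
  corp <- generate_corpus(d, 4, params = list(n_classes = 18, seed = 6),
                          plans = mutation_plan(add_class = 2, delete_class = 1,
                                                edit_annotation = 1, seed = 60),
                          seed = 6)
  expect_length(corp$paths, 4)
  expect_true(file.exists(corp$manifest))
  expect_equal(nrow(corp$deltas), 3)
  graphs <- lapply(corp$paths, read_ontology)
  for (i in 2:4) {
    expect_equal(diff_versions(graphs[[i - 1]], graphs[[i]]),
                 corp$deltas[i - 1, c("n_new", "n_deleted", "n_changed")],
                 ignore_attr = TRUE)
  }
})

test_that("a quality-degrading corpus never gains dynamic mean change", {
  # strip annotations and individuals each version: annotation and class
  # richness fall monotonically while every other raw metric stays constant,
  # so dynamic scores can only move down
  g0 <- generate_ontology(20, depth = 3, annotation_rate = 2,
                          individual_rate = 1, usage_density = 0.2,
                          restriction_rate = 0.2, seed = 19)$graph
  graphs <- list(v1 = g0)
  for (i in 2:5) {
    st <- mutate_version(graphs[[i - 1]],
                         mutation_plan(remove_annotation = 4,
                                       remove_individual = 2, seed = 100 + i))
    graphs[[paste0("v", i)]] <- st$graph
  }
  metrics <- metric_table(graphs)
  scores <- score_table(metrics, "dynamic")
  cs <- corpus_change_statistics(scores)
  expect_true(all(cs$mean_change <= 0))
  expect_true(any(cs$mean_change < 0))
})
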