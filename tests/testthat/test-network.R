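test_that("edges link overlapping consecutive cohorts with the printed probability", {
  cs <- make_cohort_sets(list(A = c("1", "2", "3")),
                         list(B = c("1", "2"), C = "3"))
  net <- build_network(cs)
  expect_equal(nrow(net$edges), 2L)
  ab <- net$edges[net$edges$target == "w2:c01", ]
  ac <- net$edges[net$edges$target == "w2:c02", ]
  expect_equal(ab$cardinality, 2L); expect_equal(ab$probability, 2 / 3)
  expect_equal(ac$cardinality, 1L); expect_equal(ac$probability, 1 / 3)
  expect_equal(net$edge_members[[ab$id]], c("1", "2"))

  disjoint <- make_cohort_sets(list(A = "1"), list(B = "2"))
  expect_equal(nrow(build_network(disjoint)$edges), 0L)
  single <- make_cohort_sets(list(A = c("1", "2")))
  expect_equal(nrow(build_network(single)$edges), 0L)
})

test_that("outcome entropy has its closed-form values in both modes", {
  expect_equal(outcome_entropy(1), 0)
  expect_equal(outcome_entropy(c(0.5, 0.5)), log(2))
  expect_equal(outcome_entropy(c(0.25, 0.25, 0.25, 0.25)), log(4))
  expect_equal(outcome_entropy(1, mode = "as-printed"), -1)
  expect_equal(outcome_entropy(c(0.5, 0.5), mode = "as-printed"), -0.5)
})

test_that("Shannon entropy is bounded and maximal exactly at uniform", {
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    p <- stats::runif(k); p <- p / sum(p)
    h <- outcome_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
    expect_lte(h, outcome_entropy(rep(1 / k, k)) + 1e-12)
  }
  expect_equal(outcome_entropy(rep(1 / 5, 5)), log(5))
})

test_that("entropy is attached to source nodes and attrition is tracked", {
  cs <- make_cohort_sets(list(A = c("1", "2", "3", "4"), D = c("5", "6")),
                         list(B = c("1", "2", "5", "6"), C = "3"))
  net <- build_network(cs)   # patient 4 leaves the observation range
  nA <- net$nodes[net$nodes$id == "w1:c01", ]
  nD <- net$nodes[net$nodes$id == "w1:c02", ]
  expect_equal(nA$prob_sum, 3 / 4)               # attrition flagged via prob_sum
  expect_equal(nD$prob_sum, 1)
  expect_equal(nD$entropy, 0)                    # single outcome
  expect_equal(nA$entropy,
               outcome_entropy(c(2 / 4, 1 / 4)))
  expect_true(is.na(net$nodes$entropy[net$nodes$window == 2][1]))
})

test_that("threshold-0 filtering keeps exactly single-target sources", {
  cs <- make_cohort_sets(
    list(A = c("1", "2", "3"), D = c("4", "5")),
    list(B = c("1", "2", "4", "5"), C = "3"))
  net <- build_network(cs)
  f0 <- filter_edges(net, 0)
  expect_equal(f0$edges$source, "w1:c02")        # D flows wholly into B
  expect_equal(nrow(f0$nodes), nrow(net$nodes))  # nodes never deleted
  # brute-force per-node scan
  for (id in net$nodes$id[net$nodes$n_out > 0]) {
    single <- sum(net$edges$source == id) == 1L &&
      abs(net$edges$probability[net$edges$source == id] - 1) < 1e-12
    expect_identical(id %in% f0$edges$source, single)
  }
  expect_equal(nrow(filter_edges(net, Inf)$edges), nrow(net$edges))
  expect_error(filter_edges(net, -1), "non-negative")
})

test_that("edge filtering is monotone in the threshold", {
  res <- synth_generate(synth_config(n_patients = 200, seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(res$events, f, row.names = FALSE, quote = FALSE)
  wp <- partition(build_trajectories(read_events(f), res$fm), res$windows)
  net <- build_network(lapply(1:3, function(l) frequency_cluster(wp, l, 5)))
  kept <- vapply(c(0, 0.2, 0.5, 1, 2, Inf), function(t)
    nrow(filter_edges(net, t)$edges), 0)
  expect_false(is.unsorted(kept))
  prev <- character()
  for (t in c(0, 0.2, 0.5, 1, 2, Inf)) {
    ids <- filter_edges(net, t)$edges$id
    expect_true(all(prev %in% ids))              # supersets as t grows
    expect_true(all(ids %in% net$edges$id))
    prev <- ids
  }
})

test_that("flow conservation holds when every member stays observed", {
  res <- synth_generate(synth_config(n_patients = 300, seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(res$events, f, row.names = FALSE, quote = FALSE)
  wp <- partition(build_trajectories(read_events(f), res$fm), res$windows)
  net <- build_network(lapply(1:3, function(l) frequency_cluster(wp, l, 10)))
  # every patient occupies some cohort in every window ((none) is explicit),
  # so outgoing cardinalities sum to the node size and probabilities to 1
  for (i in which(net$nodes$window < 3)) {
    id <- net$nodes$id[i]
    out <- net$edges[net$edges$source == id, ]
    expect_equal(sum(out$cardinality), net$nodes$size[i])
    expect_equal(sum(out$probability), 1, tolerance = 1e-12)
  }
})

test_that("highlighting counts selection overlap per node and edge", {
  cs <- make_cohort_sets(list(A = c("1", "2", "3")),
                         list(B = c("1", "2"), C = "3"))
  net <- build_network(cs)
  hl <- highlight_selection(net, node = "w2:c01")
  expect_setequal(hl$patients, c("1", "2"))
  expect_equal(hl$nodes$highlighted[hl$nodes$id == "w1:c01"], 2L)
  ec <- net$edges$id[net$edges$target == "w2:c02"]
  expect_equal(hl$edges$highlighted[hl$edges$id == ec], 0L)

  eid <- net$edges$id[net$edges$target == "w2:c01"]
  hl2 <- highlight_selection(net, edge = eid)
  expect_equal(hl2$nodes$highlighted[hl2$nodes$id == "w1:c01"], 2L)

  wp <- make_wp(list(`1` = c("CKD", "SLE"), `2` = "CKD", `3` = "CKD"))
  hl3 <- highlight_selection(net, factor = "SLE", wp = wp)
  expect_equal(hl3$patients, "1")
  hl4 <- highlight_selection(net, factor = "GN", wp = wp)
  expect_true(all(hl4$nodes$highlighted == 0L))
  expect_error(highlight_selection(net, node = "nope"), "unknown")
  expect_error(highlight_selection(net), "exactly one")
})

test_that("selection summaries report sex, age and factor prevalence", {
  wp <- make_wp(list(p1 = c("CKD", "HTN"), p2 = "CKD", p3 = c("CKD", "DM"),
                     p4 = "CKD"))
  md <- data.frame(patient_id = c("p1", "p2", "p3", "p4"),
                   sex = c("F", "F", "M", "F"),
                   birth_year = c(1950, 1960, 1940, 1955))
  s <- summarize_selection(c("p1", "p2", "p3"), wp, metadata = md)
  expect_equal(s$n, 3L)
  expect_equal(as.integer(s$sex[c("F", "M")]), c(2L, 1L))
  expect_equal(unname(s$factor_prevalence["CKD"]), 1)
  expect_equal(unname(s$factor_prevalence["HTN"]), 1 / 3)
  empty <- summarize_selection(character(), wp)
  expect_equal(empty$n, 0L)
})

test_that("a network round-trips through JSON, with and without member ids", {
  cs <- make_cohort_sets(list(A = c("1", "2", "3"), D = "4"),
                         list(B = c("1", "2", "4"), C = "3"))
  net <- build_network(cs)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f)
  net2 <- read_network(f)
  expect_equal(net2$edges[, c("source", "target", "cardinality", "probability")],
               net$edges[, c("source", "target", "cardinality", "probability")])
  expect_equal(net2$nodes$entropy, net$nodes$entropy)
  expect_equal(net2$node_members, net$node_members)
  write_network(net, f, members = FALSE)
  net3 <- read_network(f)
  expect_true(all(lengths(net3$node_members) == 0L))
})
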