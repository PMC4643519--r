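test_that("ochiai matches hand-computed values and conventions", {
  expect_equal(ochiai("f1", c("f1", "f2")), 1 / sqrt(2))
  expect_equal(ochiai(c("a", "b"), c("a", "b")), 1)
  expect_equal(ochiai("f1", "f2"), 0)
  expect_equal(ochiai(character(), character()), 1)
  expect_equal(ochiai(character(), "f1"), 0)
})

test_that("ochiai agrees with a brute-force oracle on all subset pairs", {
  subsets <- all_subsets(c("a", "b", "c", "d", "e"))
  oracle <- function(s1, s2) {
    # indicator-vector cosine similarity, computed independently
    u <- c("a", "b", "c", "d", "e")
    v1 <- as.numeric(u %in% s1); v2 <- as.numeric(u %in% s2)
    if (sum(v1) == 0 && sum(v2) == 0) return(1)
    if (sum(v1) == 0 || sum(v2) == 0) return(0)
    sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  }
  for (i in seq_along(subsets)) for (j in seq.int(i, length(subsets))) {
    s1 <- subsets[[i]]; s2 <- subsets[[j]]
    got <- ochiai(s1, s2)
    expect_equal(got, oracle(s1, s2), tolerance = 1e-12)
    expect_equal(got, ochiai(s2, s1))          # symmetry
    expect_gte(got, 0); expect_lte(got, 1)
    if (setequal(s1, s2)) expect_equal(got, 1)
    else if (length(s1) && length(s2)) expect_lt(got, 1)
  }
})

test_that("frequency clustering keeps large groups and splits small ones by index", {
  sets <- c(rep(list(c("CKD", "HTN")), 300),
            rep(list(c("CKD", "DM")), 100),
            rep(list("HTN"), 50))
  wp <- make_wp(stats::setNames(sets, sprintf("p%03d", seq_along(sets))))
  cs <- frequency_cluster(wp, 1, threshold = 250)
  sizes <- vapply(cs$cohorts, `[[`, 0L, "size")
  labels <- vapply(cs$cohorts, `[[`, "", "label")
  expect_equal(sort(sizes), c(50L, 100L, 300L))
  expect_equal(labels[sizes == 300], "CKD|HTN")
  others <- cs$cohorts[vapply(cs$cohorts, `[[`, "", "label") == "others"]
  expect_length(others, 2L)
  oi <- vapply(others, `[[`, NA, "contains_index")
  expect_setequal(oi, c(TRUE, FALSE))
  expect_equal(others[[which(oi)]]$size, 100L)
  expect_equal(others[[which(!oi)]]$size, 50L)
})

test_that("threshold 0 merges nothing; total membership always conserved", {
  set.seed(23)
  fs <- c("CKD", "HTN", "DM", "HD")
  sets <- lapply(1:60, function(i) sort(sample(fs, sample.int(3, 1))))
  wp <- make_wp(stats::setNames(sets, sprintf("p%02d", 1:60)))
  cs0 <- frequency_cluster(wp, 1, threshold = 0)
  expect_equal(length(cs0$cohorts), length(unique(window_keys(wp, 1))))
  for (x in c(0, 3, 10, 1e6)) {
    cs <- frequency_cluster(wp, 1, threshold = x)
    members <- unlist(lapply(cs$cohorts, `[[`, "members"))
    expect_setequal(members, wp$patient_id)
    expect_equal(length(members), 60L)          # disjoint cover
    kept <- Filter(function(c) is.null(c$custom_label), cs$cohorts)
    for (c in kept) expect_gte(c$size, x)
  }
})

test_that("hierarchical clustering honours similarity structure and k extremes", {
  wp <- make_wp(list(p1 = "HTN", p2 = c("DM", "HTN"), p3 = "SLE"))
  cs <- hierarchical_cluster(wp, 1, k = 2)
  grouped <- lapply(cs$cohorts, `[[`, "members")
  # {HTN} joins {DM,HTN} (similarity 1/sqrt(2)); {SLE} is disjoint from both
  expect_true(any(vapply(grouped, function(g) setequal(g, c("p1", "p2")), NA)))
  expect_true(any(vapply(grouped, function(g) identical(g, "p3"), NA)))

  cs1 <- hierarchical_cluster(wp, 1, k = 1)
  expect_length(cs1$cohorts, 1L)
  expect_setequal(cs1$cohorts[[1]]$members, c("p1", "p2", "p3"))
  cs3 <- hierarchical_cluster(wp, 1, k = 3)
  expect_length(cs3$cohorts, 3L)
  expect_error(hierarchical_cluster(wp, 1, k = 4), "out of range")
  expect_error(hierarchical_cluster(wp, 1, k = 0), "out of range")
})

test_that("hierarchical clustering is deterministic and nested in k", {
  set.seed(29)
  fs <- c("CKD", "HTN", "DM", "HD", "SLE", "CVD")
  sets <- lapply(1:30, function(i) sort(sample(fs, sample.int(4, 1))))
  wp <- make_wp(stats::setNames(sets, sprintf("p%02d", 1:30)))
  n <- length(unique(window_keys(wp, 1)))
  assignment <- function(cs) {
    a <- character()
    for (h in seq_along(cs$cohorts)) a[cs$cohorts[[h]]$members] <- h
    a[sort(names(a))]
  }
  for (k in seq_len(n)) {
    a1 <- assignment(hierarchical_cluster(wp, 1, k))
    a2 <- assignment(hierarchical_cluster(wp, 1, k))
    expect_identical(a1, a2)                     # deterministic
    if (k > 1) {
      coarse <- assignment(hierarchical_cluster(wp, 1, k - 1))
      # refinement: patients together at k stay together at k-1
      for (cl in unique(a1)) {
        ids <- names(a1)[a1 == cl]
        expect_length(unique(coarse[ids]), 1L)
      }
    }
  }
})

test_that("hierarchical clustering agrees with hclust/cutree on unique distances", {
  # fixture designed so all pairwise average-linkage distances are distinct
  sets <- list(A = c("a", "b", "c", "d"), B = c("a", "b", "c"),
               C = c("a", "e"), D = c("f", "g", "h"))
  wp <- make_wp(stats::setNames(unname(sets), c("p1", "p2", "p3", "p4")))
  keys <- vapply(sets, comorbidity_key, "")
  D <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) D[i, j] <- 1 - ochiai(sets[[i]], sets[[j]])
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  for (k in 1:4) {
    ref <- stats::cutree(hc, k)
    cs <- hierarchical_cluster(wp, 1, k)
    # same partition of the four unique sets
    canon <- function(groups) sort(unname(vapply(groups, function(g)
      paste(sort(g), collapse = ","), "")))
    got <- canon(lapply(cs$cohorts, `[[`, "members"))
    want <- canon(split(c("p1", "p2", "p3", "p4"), ref))
    expect_equal(got, want)
  }
})

test_that("cohort labels list shared factors with an asterisk for partial overlap", {
  wp <- make_wp(list(p1 = "HTN", p2 = "HTN"))
  cs <- frequency_cluster(wp, 1, threshold = 0)
  expect_equal(cs$cohorts[[1]]$label, "HTN")

  wp2 <- make_wp(list(p1 = "SLE", p2 = c("HTN", "SLE")))
  cs2 <- hierarchical_cluster(wp2, 1, k = 1)
  expect_equal(cs2$cohorts[[1]]$label, "SLE*")
  expect_true(cs2$cohorts[[1]]$partial)

  wp3 <- make_wp(list(p1 = "HTN", p2 = "DM"))
  cs3 <- hierarchical_cluster(wp3, 1, k = 1)
  expect_equal(cs3$cohorts[[1]]$label, "*")

  wp4 <- make_wp(list(p1 = character(), p2 = character()))
  cs4 <- frequency_cluster(wp4, 1, threshold = 0)
  expect_equal(cs4$cohorts[[1]]$label, "(none)")

  c5 <- cs3$cohorts[[1]]; c5$custom_label <- "mixed pre-index"
  expect_equal(label_cohort(c5), "mixed pre-index")
})

test_that("membership is conserved by both operators on a pipeline run", {
  res <- synth_generate(synth_config(n_patients = 150, seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(res$events, f, row.names = FALSE, quote = FALSE)
  pop <- build_trajectories(read_events(f), res$fm)
  wp <- partition(pop, res$windows)
  n <- length(wp$patient_id)
  for (l in seq_len(res$windows$n_windows)) {
    for (cs in list(frequency_cluster(wp, l, threshold = 10),
                    hierarchical_cluster(wp, l, k = min(
                      5L, length(unique(window_keys(wp, l))))))) {
      expect_equal(sum(vapply(cs$cohorts, `[[`, 0L, "size")), n)
      expect_false(anyDuplicated(unlist(lapply(cs$cohorts, `[[`, "members"))) > 0)
    }
  }
})
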