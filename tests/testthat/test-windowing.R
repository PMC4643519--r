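test_that("window factor sets are unions of in-window records", {
  ev <- day_events(list("p1", 0, "585"), list("p1", -100, "401"),
                   list("p1", -50, "250"))
  pop <- build_trajectories(ev, tiny_map())
  wp <- partition(pop, window_spec(c(-365, 0, 365)))
  expect_equal(wp$sets[[1]][[1]], c("DM", "HTN"))
  expect_equal(wp$sets[[1]][[2]], "CKD")
})

test_that("windows are half-open: a boundary record belongs to the opening window", {
  ev <- day_events(list("p1", 0, "585"), list("p1", 365, "58001C"),
                   list("p1", 364, "401"))
  pop <- build_trajectories(ev, tiny_map())
  wp <- partition(pop, window_spec(c(0, 365, 730)))
  expect_equal(wp$sets[[1]][[1]], c("CKD", "HTN"))  # day 364 in [0,365)
  expect_equal(wp$sets[[1]][[2]], "HD")             # day 365 opens window 2
})

test_that("out-of-range records are dropped, empty patients retained", {
  ev <- day_events(list("p1", 0, "585"), list("p1", 999, "401"),
                   list("p2", 0, "585"))
  pop <- build_trajectories(ev, tiny_map())
  wp <- partition(pop, window_spec(c(100, 200)))   # nothing in range
  expect_equal(length(wp$patient_id), 2L)
  expect_equal(wp$sets[[1]][[1]], character())
  expect_equal(window_keys(wp, 1), c("(none)", "(none)"))
})

test_that("watched-factor subsets intersect window sets", {
  ev <- day_events(list("p1", 0, "585"), list("p1", 10, "58001C"),
                   list("p1", 20, "401"),
                   list("p2", 0, "585"), list("p2", 5, "401"))
  pop <- build_trajectories(ev, tiny_map())
  wpp <- partition(pop, window_spec(c(0, 365), watch = list("HD")),
                   fm = tiny_map())
  expect_equal(wpp$sets[[1]][[1]], "HD")       # {CKD,HD,HTN} ∩ {HD}
  expect_equal(wpp$sets[[2]][[1]], character())
  expect_error(partition(pop, window_spec(c(0, 365), watch = list("XX")),
                         fm = tiny_map()), "XX")
})

test_that("one all-spanning window reproduces the union of all records", {
  set.seed(11)
  codes <- c("585", "401", "250", "4373", "7100")
  rows <- lapply(seq_len(200), function(i)
    list(sprintf("p%02d", sample.int(15, 1)), sample(-400:400, 1), sample(codes, 1)))
  pop <- build_trajectories(do.call(day_events, rows), tiny_map())
  wp <- partition(pop, window_spec(c(-1000, 1000)))
  for (i in seq_along(wp$patient_id)) {
    tr <- pop$trajectories[[wp$patient_id[i]]]
    expect_equal(wp$sets[[i]][[1]],
                 sort(unique(unlist(tr$factors))))
  }
})

test_that("each in-range record contributes to exactly one window", {
  set.seed(13)
  codes <- c("585", "401", "250", "4373")
  rows <- lapply(seq_len(250), function(i)
    list(sprintf("p%02d", sample.int(12, 1)), sample(-400:400, 1), sample(codes, 1)))
  pop <- build_trajectories(do.call(day_events, rows), tiny_map())
  b <- c(-300, -100, 0, 150, 400)
  wp <- partition(pop, window_spec(b))
  for (i in seq_along(wp$patient_id)) {
    tr <- pop$trajectories[[wp$patient_id[i]]]
    for (k in seq_along(tr$day)) {
      d <- tr$day[k]
      in_window <- vapply(seq_len(4), function(l) d >= b[l] && d < b[l + 1], NA)
      expect_equal(sum(in_window), as.integer(d >= b[1] && d < b[5]))
      if (any(in_window)) {
        l <- which(in_window)
        expect_true(all(tr$factors[[k]] %in% wp$sets[[i]][[l]]))
      }
    }
  }
})

test_that("partition is invariant to record order", {
  rows <- list(list("p1", -10, "401"), list("p1", 0, "585"),
               list("p1", 50, "250"), list("p1", 80, "4373"))
  pop1 <- build_trajectories(do.call(day_events, rows), tiny_map())
  pop2 <- build_trajectories(do.call(day_events, rev(rows)), tiny_map())
  s <- window_spec(c(-100, 0, 100))
  expect_equal(partition(pop1, s)$sets, partition(pop2, s)$sets)
})

test_that("comorbidity keys are canonical", {
  expect_equal(comorbidity_key(c("HD", "CKD")), "CKD|HD")
  expect_equal(comorbidity_key(character()), "(none)")
  expect_equal(comorbidity_key("CKD"), "CKD")
  expect_equal(comorbidity_key(c("CKD", "CKD", "HD")), "CKD|HD")
  # permutation invariance
  s <- c("HTN", "DM", "CKD", "SLE")
  for (i in 1:5) expect_equal(comorbidity_key(sample(s)), "CKD|DM|HTN|SLE")
})

test_that("distinct key counts match a set-of-sets oracle", {
  set.seed(17)
  fs <- c("CKD", "HTN", "DM", "HD", "SLE")
  sets <- lapply(1:40, function(i) sort(sample(fs, sample.int(4, 1))))
  wp <- make_wp(stats::setNames(sets, sprintf("p%02d", 1:40)))
  keys <- window_keys(wp, 1)
  oracle <- unique(lapply(sets, function(s) sort(unique(s))))
  expect_equal(length(unique(keys)), length(oracle))
})

test_that("carry-forward propagates earlier diagnoses but not procedures", {
  ev <- day_events(list("p1", -50, "401"), list("p1", 0, "585"),
                   list("p1", 100, "58001C"), list("p1", 500, "250"))
  pop <- build_trajectories(ev, tiny_map())
  s <- window_spec(c(-100, 0, 365, 730))
  raw <- partition(pop, s, fm = tiny_map())
  expect_equal(raw$sets[[1]][[3]], "DM")           # no persistence by default
  cf <- partition(pop, s, fm = tiny_map(), carry_forward = TRUE)
  expect_equal(cf$sets[[1]][[2]], c("CKD", "HD", "HTN"))
  # HD is a procedure: it does not carry into the last window
  expect_equal(cf$sets[[1]][[3]], c("CKD", "DM", "HTN"))
})

test_that("a windowed population survives serialization", {
  ev <- day_events(list("p1", 0, "585"), list("p1", -10, "401"),
                   list("p2", 0, "585"))
  pop <- build_trajectories(ev, tiny_map())
  wp <- partition(pop, window_spec(c(-100, 0, 100), watch = list(NULL, "CKD")),
                  fm = tiny_map())
  f <- withr::local_tempfile(fileext = ".json")
  write_windowed(wp, f)
  wp2 <- read_windowed(f)
  expect_equal(wp2$patient_id, wp$patient_id)
  expect_equal(wp2$sets, wp$sets)
  expect_equal(wp2$spec$boundaries, wp$spec$boundaries)
  expect_equal(wp2$index_factor, wp$index_factor)
})
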