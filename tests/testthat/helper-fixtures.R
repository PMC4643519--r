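# Small fixtures shared across the suite; everything is built in code.

tiny_map <- function() {
  parse_factor_map(list(
    index_factor = "CKD",
    factors = list(
      list(name = "Chronic Kidney Disease", abbreviation = "CKD", codes = "585, 586"),
      list(name = "Hypertension", abbreviation = "HTN", codes = "401"),
      list(name = "Diabetes mellitus", abbreviation = "DM", codes = "250"),
      list(name = "Cerebrovascular Disease", abbreviation = "CVD", codes = "430-438"),
      list(name = "Hemodialysis", abbreviation = "HD", codes = "58001C,58029C"),
      list(name = "Systemic Lupus Erythematosus", abbreviation = "SLE", codes = "7100"))))
}

# pre-aligned event table (integer day offsets)
day_events <- function(...) {
  rows <- list(...)
  df <- data.frame(
    patient_id = vapply(rows, `[[`, "", 1L),
    code = vapply(rows, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  df$time <- as.integer(vapply(rows, function(r) r[[2L]], 0))
  attr(df, "pre_aligned") <- TRUE
  df
}

# construct a windowed_population directly (bypassing trajectory building)
make_wp <- function(sets, boundaries = c(0, 1), index_factor = "CKD",
                    watch = NULL) {
  L <- length(boundaries) - 1L
  structure(list(
    patient_id = names(sets),
    sets = lapply(unname(sets), function(s) {
      if (is.list(s) && length(s) == L) lapply(s, as.character)
      else rep(list(as.character(s)), L)
    }),
    spec = window_spec(boundaries, watch = watch),
    index_factor = index_factor
  ), class = "windowed_population")
}

# two-window cohort sets from member-id lists, for network/layout tests
make_cohort_sets <- function(...) {
  windows <- list(...)
  lapply(seq_along(windows), function(l) {
    cohorts <- lapply(seq_along(windows[[l]]), function(h) {
      members <- windows[[l]][[h]]
      list(id = sprintf("w%d:c%02d", l, h), window = l,
           members = members, size = length(members),
           common_factors = character(), partial = FALSE,
           contains_index = FALSE,
           custom_label = names(windows[[l]])[h],
           label = names(windows[[l]])[h])
    })
    structure(list(window = l, cohorts = cohorts), class = "cohort_set")
  })
}

# independent brute-force weighted crossing counter (pair enumeration)
oracle_crossings <- function(net, order) {
  total <- 0
  e <- net$edges
  if (nrow(e) < 2) return(0)
  for (i in seq_len(nrow(e) - 1)) for (j in seq.int(i + 1, nrow(e))) {
    if (e$window[i] != e$window[j]) next
    s1 <- order[e$source[i]]; s2 <- order[e$source[j]]
    t1 <- order[e$target[i]]; t2 <- order[e$target[j]]
    if ((s1 < s2 && t1 > t2) || (s1 > s2 && t1 < t2)) {
      total <- total + e$cardinality[i] * e$cardinality[j]
    }
  }
  total
}

# all subsets of a universe, as a list of character vectors
all_subsets <- function(universe) {
  n <- length(universe)
  lapply(seq_len(2^n) - 1L, function(m) universe[bitwAnd(m, 2^(seq_len(n) - 1L)) > 0])
}
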