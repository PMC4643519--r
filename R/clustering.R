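#' Ochiai similarity between two factor sets
#'
#' The Ochiai coefficient \eqn{|s_1 \cap s_2| / \sqrt{|s_1||s_2|}}, i.e.
#' the cosine similarity between the sets' indicator vectors. Since the
#' formula divides by zero on empty sets, the conventions are: both empty
#' gives 1 (identical sets), exactly one empty gives 0.
#'
#' @param s1,s2 character vectors of factor names (sets).
#' @return similarity in `[0, 1]`.
#' @export
#' @examples
#' ochiai("f1", c("f1", "f2"))  # 1/sqrt(2)
ochiai <- function(s1, s2) {
  s1 <- unique(as.character(s1)); s2 <- unique(as.character(s2))
  n1 <- length(s1); n2 <- length(s2)
  if (n1 == 0L && n2 == 0L) return(1)
  if (n1 == 0L || n2 == 0L) return(0)
  length(intersect(s1, s2)) / sqrt(n1 * n2)
}

# group a window's patients by exact comorbidity key ->
# list(keys, members = list, sets = list of factor vectors)
.window_groups <- function(wp, window) {
  keys <- window_keys(wp, window)
  ukeys <- sort(unique(keys), method = "radix")
  members <- lapply(ukeys, function(k) wp$patient_id[keys == k])
  sets <- lapply(ukeys, function(k) {
    if (k == "(none)") character() else strsplit(k, "|", fixed = TRUE)[[1]]
  })
  list(keys = ukeys, members = members, sets = sets)
}

.new_cohort <- function(window, h, members, member_sets, index_factor,
                        custom_label = NULL) {
  common <- Reduce(intersect, member_sets)
  if (is.null(common)) common <- character()
  common <- sort(unique(common), method = "radix")
  partial <- any(vapply(member_sets, function(s) length(setdiff(s, common)) > 0L, NA))
  contains_index <- !is.null(index_factor) &&
    any(vapply(member_sets, function(s) index_factor %in% s, NA))
  c <- list(id = sprintf("w%d:c%02d", window, h), window = window,
            members = members, size = length(members),
            common_factors = common, partial = partial,
            contains_index = contains_index, custom_label = custom_label)
  c$label <- label_cohort(c)
  c
}

#' Label a cohort by its shared factors
#'
#' The label is the comorbidity key of the factors shared by *all* members,
#' with `"*"` appended when some member carries factors beyond the shared
#' ones. A mixed group sharing nothing is labelled exactly `"*"`; a group
#' whose members all have empty sets is `"(none)"`. A custom label, when
#' set on the cohort, overrides.
#'
#' @param c a cohort (as produced by the clustering operators).
#' @return a single string.
#' @export
label_cohort <- function(c) {
  if (!is.null(c$custom_label)) return(c$custom_label)
  if (length(c$common_factors) == 0L) {
    if (isTRUE(c$partial)) "*" else "(none)"
  } else {
    key <- comorbidity_key(c$common_factors)
    if (isTRUE(c$partial)) paste0(key, "*") else key
  }
}

.as_cohort_set <- function(window, cohorts) {
  structure(list(window = window, cohorts = cohorts), class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat(sprintf("<cohort_set> window %d: %d cohorts\n", x$window, length(x$cohorts)))
  for (c in x$cohorts) cat(sprintf("  %-10s %-24s n=%d\n", c$id, c$label, c$size))
  invisible(x)
}

#' Frequency-based cohort clustering
#'
#' Keeps every exact comorbidity group of size at least `threshold` as its
#' own cohort and merges the smaller groups into an "others" group. By
#' default the merged remainder is split in two by presence of the index
#' factor (others *with* and others *without* the index diagnosis), so
#' that the index-bearing minority remains visible; `split_others = FALSE`
#' collapses them into one.
#'
#' @param wp a `windowed_population`.
#' @param window window index.
#' @param threshold non-negative cardinality threshold `x`; groups with
#'   fewer members are merged. `0` performs no merging.
#' @param split_others split the merged group by index-factor presence.
#' @return a `cohort_set` whose cohorts partition the patients.
#' @export
frequency_cluster <- function(wp, window, threshold, split_others = TRUE) {
  stopifnot(inherits(wp, "windowed_population"), threshold >= 0)
  g <- .window_groups(wp, window)
  idx <- wp$index_factor
  keep <- vapply(g$members, length, 0L) >= threshold
  cohorts <- list()
  h <- 0L
  for (i in which(keep)) {
    h <- h + 1L
    cohorts[[h]] <- .new_cohort(window, h, g$members[[i]],
                                list(g$sets[[i]]), idx)
  }
  small <- which(!keep)
  if (length(small)) {
    has_idx <- vapply(small, function(i) !is.null(idx) && idx %in% g$sets[[i]], NA)
    buckets <- if (split_others) split(small, has_idx) else list(all = small)
    # deterministic order: others-with-index first
    for (nm in rev(sort(names(buckets)))) {
      ids <- buckets[[nm]]
      h <- h + 1L
      cohorts[[h]] <- .new_cohort(window, h,
                                  unlist(g$members[ids], use.names = FALSE),
                                  g$sets[ids], idx, custom_label = "others")
    }
  }
  .as_cohort_set(window, cohorts)
}

# Agglomerative average-linkage clustering over unique comorbidity sets
# under distance 1 - ochiai, via the Lance-Williams update for group
# averages (inter-cluster distance = weight-averaged item-pair distance;
# weights are 1 per unique set, or patient counts when `weighted`). Ties
# are broken by merging the pair whose (sorted) representative keys are
# lexicographically smallest, which makes the dendrogram, and hence every
# cut, fully deterministic. Cuts are nested by construction.
.agglomerate <- function(keys, sets, counts, weighted = FALSE) {
  n <- length(keys)
  D <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <- 1 - ochiai(sets[[i]], sets[[j]])
    }
  }
  diag(D) <- Inf
  members <- as.list(seq_len(n))         # clusters as index vectors
  reps <- keys                           # representative (smallest) key
  w <- if (weighted) as.numeric(counts) else rep(1, n)
  alive <- rep(TRUE, n)
  merges <- vector("list", max(0L, n - 1L))
  for (step in seq_len(max(0L, n - 1L))) {
    dmin <- min(D[alive, alive])
    cand <- which(D <= dmin + 1e-12 & upper.tri(D), arr.ind = TRUE)
    best <- NULL
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      pair_key <- sort(c(reps[i], reps[j]), method = "radix")
      if (is.null(best) || .key_lt(pair_key, best$key)) {
        best <- list(i = i, j = j, key = pair_key)
      }
    }
    i <- best$i; j <- best$j
    merges[[step]] <- list(members = sort(c(members[[i]], members[[j]])),
                           height = D[i, j])
    # group-average update: d(i∪j, k) = (w_i d_ik + w_j d_jk) / (w_i + w_j)
    upd <- (w[i] * D[i, ] + w[j] * D[j, ]) / (w[i] + w[j])
    D[i, ] <- upd; D[, i] <- upd
    D[i, i] <- Inf
    D[j, ] <- Inf; D[, j] <- Inf
    members[[i]] <- c(members[[i]], members[[j]])
    w[i] <- w[i] + w[j]
    reps[i] <- sort(c(reps[i], reps[j]), method = "radix")[1L]
    alive[j] <- FALSE
  }
  merges
}

# byte-order (locale-independent) string comparison
.str_lt <- function(a, b) a != b && sort(c(a, b), method = "radix")[1L] == a

# lexicographic comparison of two 2-element key pairs
.key_lt <- function(a, b) {
  if (a[1] != b[1]) return(.str_lt(a[1], b[1]))
  .str_lt(a[2], b[2])
}

# assignment of the n unique sets into k clusters, replaying merges
.cut_merges <- function(n, merges, k) {
  assign <- seq_len(n)
  n_clusters <- n
  for (m in merges) {
    if (n_clusters <= k) break
    target <- min(assign[m$members])
    assign[assign %in% assign[m$members]] <- target
    n_clusters <- length(unique(assign))
  }
  match(assign, sort(unique(assign)))
}

#' Hierarchical cohort clustering under Ochiai similarity
#'
#' Agglomerative (average linkage) clustering of the window's *unique*
#' comorbidity sets under distance `1 - ochiai`, cut at `k` clusters; each
#' patient joins the cluster of its comorbidity key. Operating on unique
#' sets rather than patients matches the similarity's definition between
#' unique comorbidities and makes cost depend on the number of distinct
#' combinations, not on the population size. Equal-distance merges are
#' resolved by the lexicographically smallest pair of cluster keys, so
#' results are deterministic and the `k`-cluster solution always refines
#' the `(k-1)`-cluster one.
#'
#' @param wp a `windowed_population`.
#' @param window window index.
#' @param k desired number of clusters, between 1 and the number of unique
#'   comorbidity keys in the window.
#' @param weighted if `TRUE`, linkage averages are weighted by each set's
#'   patient count (default unweighted, treating each unique combination
#'   equally).
#' @return a `cohort_set`.
#' @export
hierarchical_cluster <- function(wp, window, k, weighted = FALSE) {
  stopifnot(inherits(wp, "windowed_population"))
  g <- .window_groups(wp, window)
  n <- length(g$keys)
  if (k < 1L || k > n) {
    stop(sprintf("k = %d out of range: window %d has %d unique comorbidity keys",
                 k, window, n), call. = FALSE)
  }
  counts <- vapply(g$members, length, 0L)
  merges <- .agglomerate(g$keys, g$sets, counts, weighted = weighted)
  assign <- .cut_merges(n, merges, k)
  cohorts <- list()
  for (h in sort(unique(assign))) {
    ids <- which(assign == h)
    cohorts[[h]] <- .new_cohort(window, h,
                                unlist(g$members[ids], use.names = FALSE),
                                g$sets[ids], wp$index_factor)
  }
  .as_cohort_set(window, cohorts)
}

#' Cluster every window of a population
#'
#' Convenience wrapper applying one clustering operator per window.
#'
#' @param wp a `windowed_population`.
#' @param method `"frequency"` or `"hierarchical"`, recycled per window.
#' @param threshold frequency threshold(s), recycled.
#' @param k cluster count(s) for hierarchical windows, recycled; `NA`
#'   defaults to the number of unique keys capped at 10.
#' @param split_others,weighted passed through.
#' @return list of `cohort_set`, one per window.
#' @export
cluster_windows <- function(wp, method = "frequency", threshold = 0, k = NA,
                            split_others = TRUE, weighted = FALSE) {
  L <- wp$spec$n_windows
  method <- rep_len(method, L)
  threshold <- rep_len(threshold, L)
  k <- rep_len(k, L)
  lapply(seq_len(L), function(l) {
    if (method[l] == "hierarchical") {
      n <- length(unique(window_keys(wp, l)))
      kk <- if (is.na(k[l])) min(n, 10L) else k[l]
      hierarchical_cluster(wp, l, kk, weighted = weighted)
    } else {
      frequency_cluster(wp, l, threshold[l], split_others = split_others)
    }
  })
}
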