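#' Build the cohort-trajectory network
#'
#' Nodes are the cohorts of every window; a directed edge connects two
#' cohorts in consecutive windows whenever their member sets overlap, with
#' cardinality `|c_l,i ∩ c_l+1,j|` and conditional probability
#' `pb(c_l+1,j | c_l,i) = |c_l,i ∩ c_l+1,j| / |c_l,i|`. Each node with
#' outgoing edges carries its *outcome entropy* computed from those
#' probabilities (see [outcome_entropy()]); nodes of the last window, or
#' whose members all leave the observation range, have entropy `NA` and
#' are flagged. Because patients without in-window records stay in the
#' explicit "(none)" group, outgoing probabilities sum to 1 (to within
#' rounding) except at the trajectory's dropped out-of-range ends; the
#' per-node sum is recorded in `prob_sum`.
#'
#' @param cohort_sets list of `cohort_set`, one per window, in order.
#' @param entropy_mode `"shannon"` (default) or `"as-printed"`; see
#'   [outcome_entropy()].
#' @return an object of class `cohort_network` with `nodes` (data frame:
#'   `id`, `window`, `label`, `size`, `contains_index`, `entropy`,
#'   `prob_sum`, `n_out`), `node_members`/`node_factors` (named lists),
#'   `edges` (data frame: `id`, `source`, `target`, `window`,
#'   `cardinality`, `probability`), `edge_members` (named list) and
#'   `entropy_mode`.
#' @export
build_network <- function(cohort_sets, entropy_mode = c("shannon", "as-printed")) {
  entropy_mode <- match.arg(entropy_mode)
  stopifnot(length(cohort_sets) >= 1L)
  cohorts <- unlist(lapply(cohort_sets, `[[`, "cohorts"), recursive = FALSE)
  ids <- vapply(cohorts, `[[`, "", "id")
  nodes <- data.frame(
    id = ids,
    window = vapply(cohorts, `[[`, 0L, "window"),
    label = vapply(cohorts, `[[`, "", "label"),
    size = vapply(cohorts, `[[`, 0L, "size"),
    contains_index = vapply(cohorts, `[[`, NA, "contains_index"),
    stringsAsFactors = FALSE)
  node_members <- stats::setNames(lapply(cohorts, `[[`, "members"), ids)
  node_factors <- stats::setNames(lapply(cohorts, `[[`, "common_factors"), ids)

  edges <- list(); edge_members <- list()
  for (l in seq_len(length(cohort_sets) - 1L)) {
    for (src in cohort_sets[[l]]$cohorts) {
      for (tgt in cohort_sets[[l + 1L]]$cohorts) {
        ov <- intersect(src$members, tgt$members)
        if (length(ov) == 0L) next
        eid <- paste0(src$id, ">", tgt$id)
        edges[[eid]] <- data.frame(
          id = eid, source = src$id, target = tgt$id, window = l,
          cardinality = length(ov),
          probability = length(ov) / src$size,
          stringsAsFactors = FALSE)
        edge_members[[eid]] <- sort(ov, method = "radix")
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, unname(edges)) else
    data.frame(id = character(), source = character(), target = character(),
               window = integer(), cardinality = integer(),
               probability = numeric(), stringsAsFactors = FALSE)

  nodes$n_out <- vapply(nodes$id, function(i) sum(edges$source == i), 0L)
  nodes$prob_sum <- vapply(nodes$id, function(i)
    sum(edges$probability[edges$source == i]), 0)
  nodes$entropy <- vapply(seq_len(nrow(nodes)), function(i) {
    p <- edges$probability[edges$source == nodes$id[i]]
    if (length(p) == 0L) NA_real_ else outcome_entropy(p, entropy_mode)
  }, 0)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, node_members = node_members,
                 node_factors = node_factors, edges = edges,
                 edge_members = edge_members, entropy_mode = entropy_mode),
            class = "cohort_network")
}

#' @export
print.cohort_network <- function(x, ...) {
  cat(sprintf("<cohort_network> %d nodes over %d windows, %d edges (%s entropy)\n",
              nrow(x$nodes), length(unique(x$nodes$window)), nrow(x$edges),
              x$entropy_mode))
  invisible(x)
}

#' Outcome entropy of a cohort's transition probabilities
#'
#' Measures how dispersed a cohort's next-window outcomes are. The default
#' is the Shannon entropy with natural logarithm,
#' \eqn{-\sum_k p_k \ln p_k}: zero exactly when all members flow to a
#' single target ("fully overlapped cohorts") and maximal, \eqn{\ln K},
#' when the `K` outcomes are uniform. Mode `"as-printed"` instead returns
#' \eqn{-\sum_k p_k^2}, a negated Simpson-type concentration index that
#' ranges over `[-1, -1/K]` (it is `-1`, not 0, for a deterministic
#' outcome); it is provided for fidelity with tools that rank by that
#' quantity, and threshold semantics differ accordingly.
#'
#' @param p numeric vector of outgoing conditional probabilities
#'   (each in `(0, 1]`).
#' @param mode `"shannon"` or `"as-printed"`.
#' @return a single number.
#' @export
#' @examples
#' outcome_entropy(1)            # 0
#' outcome_entropy(c(.5, .5))    # log(2)
outcome_entropy <- function(p, mode = c("shannon", "as-printed")) {
  mode <- match.arg(mode)
  stopifnot(length(p) >= 1L, all(p > 0), all(p <= 1 + 1e-12))
  # + 0 normalizes IEEE negative zero (p = 1 gives -0 otherwise)
  if (mode == "shannon") -sum(p * log(p)) + 0 else -sum(p * p)
}

#' Filter network edges by source-cohort entropy
#'
#' Keeps exactly the edges whose *source* node's outcome entropy is at
#' most `threshold`; since entropy is a property of the source cohort, a
#' node's outgoing edges are removed all-or-none. Nodes are never removed.
#' At threshold 0 (Shannon mode) only edges leaving cohorts whose members
#' all flow to one target survive. Filtering is monotone: a larger
#' threshold never removes an edge a smaller one kept.
#'
#' @param net a `cohort_network`.
#' @param threshold entropy threshold; must be non-negative in Shannon
#'   mode (`Inf` keeps everything).
#' @return a `cohort_network` whose edges are the retained subset.
#' @export
filter_edges <- function(net, threshold) {
  stopifnot(inherits(net, "cohort_network"))
  if (net$entropy_mode == "shannon" && threshold < 0) {
    stop("threshold must be non-negative for Shannon entropy", call. = FALSE)
  }
  ent <- stats::setNames(net$nodes$entropy, net$nodes$id)
  keep <- !is.na(ent[net$edges$source]) & ent[net$edges$source] <= threshold
  keep[is.na(keep)] <- FALSE
  out <- net
  out$edges <- net$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out$edge_members <- net$edge_members[out$edges$id]
  out$filter_threshold <- threshold
  out
}

#' Resolve a selection to patients and highlight counts
#'
#' A selection is a node id, an edge id, an explicit vector of patient
#' ids, or a factor name (all patients whose factor set contains it in
#' *any* window). The result overlays, per node and per edge, how many of
#' its members are selected — the red-region counts of the interactive
#' display.
#'
#' @param net a `cohort_network`.
#' @param node,edge,factor,patients exactly one selector.
#' @param wp the `windowed_population` (required for `factor` selections).
#' @return an object of class `cohort_highlight`: `patients`, and data
#'   frames `nodes` (`id`, `highlighted`) and `edges` (`id`,
#'   `highlighted`).
#' @export
highlight_selection <- function(net, node = NULL, edge = NULL, factor = NULL,
                                patients = NULL, wp = NULL) {
  stopifnot(inherits(net, "cohort_network"))
  given <- !vapply(list(node, edge, factor, patients), is.null, NA)
  if (sum(given) != 1L) {
    stop("supply exactly one of node, edge, factor, patients", call. = FALSE)
  }
  sel <- if (!is.null(node)) {
    if (!node %in% names(net$node_members)) stop("unknown node id: ", node, call. = FALSE)
    net$node_members[[node]]
  } else if (!is.null(edge)) {
    if (!edge %in% names(net$edge_members)) stop("unknown edge id: ", edge, call. = FALSE)
    net$edge_members[[edge]]
  } else if (!is.null(factor)) {
    if (is.null(wp)) stop("factor selection requires the windowed population", call. = FALSE)
    has <- vapply(wp$sets, function(s) any(vapply(s, function(f) factor %in% f, NA)), NA)
    wp$patient_id[has]
  } else {
    as.character(patients)
  }
  sel <- unique(sel)
  nodes <- data.frame(
    id = net$nodes$id,
    highlighted = vapply(net$nodes$id, function(i)
      length(intersect(net$node_members[[i]], sel)), 0L),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    id = net$edges$id,
    highlighted = if (nrow(net$edges)) vapply(net$edges$id, function(i)
      length(intersect(net$edge_members[[i]], sel)), 0L) else integer(),
    stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(patients = sel, nodes = nodes, edges = edges),
            class = "cohort_highlight")
}

#' Summarize a selected patient group
#'
#' Demographic and factor summaries of a selection: counts by sex, the
#' distribution of age at the index date (needs `birth_year` metadata and
#' calendar-dated trajectories) and per-factor prevalence within the
#' selection (fraction of selected patients carrying the factor in any
#' window). Missing metadata degrades gracefully to the factor summary.
#'
#' @param patients character vector of selected patient ids.
#' @param wp a `windowed_population`.
#' @param metadata optional data frame with columns `patient_id` and any
#'   of `sex`, `birth_year`.
#' @param pop optional `population`, used to recover index dates for ages.
#' @return a list with `n`, `sex` (table or `NULL`), `age` (summary or
#'   `NULL`) and `factor_prevalence` (named numeric, fractions).
#' @export
summarize_selection <- function(patients, wp, metadata = NULL, pop = NULL) {
  stopifnot(inherits(wp, "windowed_population"))
  patients <- unique(as.character(patients))
  keep <- wp$patient_id %in% patients
  if (!any(keep)) {
    return(list(n = 0L, sex = NULL, age = NULL,
                factor_prevalence = stats::setNames(numeric(), character())))
  }
  facs <- sort(unique(unlist(wp$sets[keep], use.names = FALSE)), method = "radix")
  prev <- vapply(facs, function(f) {
    mean(vapply(wp$sets[keep], function(s)
      any(vapply(s, function(x) f %in% x, NA)), NA))
  }, 0)
  sex <- NULL; age <- NULL
  if (!is.null(metadata) && "patient_id" %in% names(metadata)) {
    md <- metadata[metadata$patient_id %in% patients, , drop = FALSE]
    if ("sex" %in% names(md)) sex <- table(md$sex)
    if ("birth_year" %in% names(md) && !is.null(pop)) {
      iy <- vapply(md$patient_id, function(pid) {
        tr <- pop$trajectories[[pid]]
        if (is.null(tr) || !inherits(tr$index_time, "Date")) NA_real_
        else as.numeric(format(tr$index_time, "%Y"))
      }, 0)
      ages <- iy - as.numeric(md$birth_year)
      if (any(!is.na(ages))) age <- summary(ages[!is.na(ages)])
    }
  }
  list(n = sum(keep), sex = sex, age = age, factor_prevalence = prev)
}

#' Serialize / restore a cohort network
#'
#' JSON form with nodes, edges and entropies; member ids are included
#' unless `members = FALSE` (privacy flag), in which case the restored
#' network supports layout and export but not highlighting.
#'
#' @param net a `cohort_network`.
#' @param path file path.
#' @param members include patient ids.
#' @return `path` (write) or a `cohort_network` (read).
#' @export
write_network <- function(net, path, members = TRUE) {
  stopifnot(inherits(net, "cohort_network"))
  doc <- list(
    entropy_mode = net$entropy_mode,
    filter_threshold = net$filter_threshold,
    nodes = lapply(seq_len(nrow(net$nodes)), function(i) {
      n <- as.list(net$nodes[i, ])
      n$entropy <- if (is.na(n$entropy)) NULL else n$entropy
      n$common_factors <- as.list(net$node_factors[[n$id]])
      if (members) n$members <- as.list(net$node_members[[n$id]])
      n
    }),
    edges = lapply(seq_len(nrow(net$edges)), function(i) {
      e <- as.list(net$edges[i, ])
      if (members) e$members <- as.list(net$edge_members[[e$id]])
      e
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA),
             path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  nodes <- do.call(rbind, lapply(doc$nodes, function(n) data.frame(
    id = n$id, window = as.integer(n$window), label = chr1(n$label),
    size = as.integer(n$size), contains_index = isTRUE(n$contains_index),
    n_out = as.integer(n$n_out), prob_sum = as.numeric(n$prob_sum),
    entropy = if (is.null(n$entropy)) NA_real_ else as.numeric(n$entropy),
    stringsAsFactors = FALSE)))
  node_members <- stats::setNames(lapply(doc$nodes, function(n)
    unname(vapply(n$members %||% list(), as.character, ""))), nodes$id)
  node_factors <- stats::setNames(lapply(doc$nodes, function(n)
    unname(vapply(n$common_factors %||% list(), as.character, ""))), nodes$id)
  edges <- if (length(doc$edges)) do.call(rbind, lapply(doc$edges, function(e)
    data.frame(id = e$id, source = e$source, target = e$target,
               window = as.integer(e$window),
               cardinality = as.integer(e$cardinality),
               probability = as.numeric(e$probability),
               stringsAsFactors = FALSE)))
  else data.frame(id = character(), source = character(), target = character(),
                  window = integer(), cardinality = integer(),
                  probability = numeric(), stringsAsFactors = FALSE)
  edge_members <- stats::setNames(lapply(doc$edges, function(e)
    unname(vapply(e$members %||% list(), as.character, ""))), edges$id)
  out <- structure(list(nodes = nodes, node_members = node_members,
                        node_factors = node_factors, edges = edges,
                        edge_members = edge_members,
                        entropy_mode = doc$entropy_mode),
                   class = "cohort_network")
  if (!is.null(doc$filter_threshold)) out$filter_threshold <- doc$filter_threshold
  out
}
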