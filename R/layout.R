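#' Weighted edge-crossing count of a node ordering
#'
#' Two edges between the same pair of consecutive windows cross when their
#' endpoints interleave; each crossing is weighted by the product of the
#' two edges' cardinalities (a crossing between two thick ribbons hurts
#' legibility more than one between hairlines).
#'
#' @param net a `cohort_network`.
#' @param order named integer vector: rank of each node within its window
#'   (names are node ids).
#' @return total weighted crossing count.
#' @export
count_crossings <- function(net, order) {
  stopifnot(inherits(net, "cohort_network"))
  e <- net$edges
  if (nrow(e) < 2L) return(0)
  total <- 0
  for (w in unique(e$window)) {
    ew <- e[e$window == w, , drop = FALSE]
    m <- nrow(ew)
    if (m < 2L) next
    so <- order[ew$source]; to <- order[ew$target]
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      if ((so[i] - so[j]) * (to[i] - to[j]) < 0) {
        total <- total + ew$cardinality[i] * ew$cardinality[j]
      }
    }
  }
  total
}

# stack a window's nodes (ids in rank order) into [top, top+height) bands
.stack_positions <- function(ids, sizes, gap) {
  tops <- cumsum(c(0, (sizes + gap)[-length(sizes)]))
  stats::setNames(tops, ids)
}

# centers of every node under a given per-window ordering
.centers <- function(net, orders, gap) {
  centers <- numeric(0)
  for (w in unique(net$nodes$window)) {
    ids <- names(sort(orders[names(orders) %in%
                               net$nodes$id[net$nodes$window == w]]))
    sizes <- net$nodes$size[match(ids, net$nodes$id)]
    tops <- .stack_positions(ids, sizes, gap)
    centers <- c(centers, tops + sizes / 2)
  }
  centers
}

# total weighted edge length under an ordering (secondary objective)
.edge_length <- function(net, orders, gap) {
  if (nrow(net$edges) == 0L) return(0)
  ctr <- .centers(net, orders, gap)
  sum(net$edges$cardinality * abs(ctr[net$edges$source] - ctr[net$edges$target]))
}

#' Optimize node order with barycenter sweeps and simulated annealing
#'
#' Starts from a readable initial order (descending cohort size, with the
#' "others" and "(none)" groups pinned to the bottom) and sweeps back and
#' forth across the windows. At each visited window every node's target
#' position is the cardinality-weighted mean (barycenter) of its
#' neighbours' centers in the adjacent windows; nodes are reordered by
#' target and restacked, which resolves overlaps by construction while
#' preserving the order. A proposed reordering is accepted when it does
#' not worsen the objective — weighted crossings first, total weighted
#' edge length as tie-breaker — or, with probability
#' `exp(-delta / temperature)`, even when it does; the temperature starts
#' at the mean node height and cools geometrically each sweep, so the run
#' ends in fixed time. The best state ever seen is returned, so the final
#' crossing count never exceeds the initial one.
#'
#' @param net a `cohort_network`.
#' @param seed integer; fixes all randomness (the global RNG state is
#'   left untouched).
#' @param sweeps number of back-and-forth passes.
#' @param cooling geometric cooling factor per sweep.
#' @param gap vertical gap between nodes, in cardinality units; default
#'   2\% of the largest window total.
#' @return an object of class `sankey_layout`: `nodes` (data frame `id`,
#'   `window`, `order`, `x`, `top`, `height`), `z` (edge ids in drawing
#'   order, see [z_order()]), `crossings` (`initial`, `final`) and the
#'   parameters used.
#' @export
optimize_order <- function(net, seed = 1L, sweeps = 32L, cooling = 0.98,
                           gap = NULL) {
  stopifnot(inherits(net, "cohort_network"), nrow(net$nodes) > 0L)
  windows <- sort(unique(net$nodes$window))
  if (is.null(gap)) {
    gap <- 0.02 * max(vapply(windows, function(w)
      sum(net$nodes$size[net$nodes$window == w]), 0))
    if (gap <= 0) gap <- 1
  }

  # initial order: size-descending, merged groups at the bottom, label ties
  orders <- integer(0)
  for (w in windows) {
    nw <- net$nodes[net$nodes$window == w, , drop = FALSE]
    bottom <- nw$label %in% c("others", "(none)")
    o <- order(bottom, -nw$size, nw$label)
    r <- integer(nrow(nw)); r[o] <- seq_len(nrow(nw))
    orders <- c(orders, stats::setNames(r, nw$id))
  }

  score <- function(ord) c(count_crossings(net, ord), .edge_length(net, ord, gap))
  cur <- orders; cur_s <- score(cur)
  best <- cur; best_s <- cur_s
  initial_crossings <- cur_s[1]
  temp <- mean(net$nodes$size)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  e <- net$edges
  for (pass in seq_len(sweeps)) {
    seq_w <- if (pass %% 2L == 1L) windows else rev(windows)
    for (w in seq_w) {
      ids <- net$nodes$id[net$nodes$window == w]
      if (length(ids) < 2L) next
      ctr <- .centers(net, cur, gap)
      target <- vapply(ids, function(id) {
        ein <- e[e$target == id, , drop = FALSE]
        eout <- e[e$source == id, , drop = FALSE]
        wgt <- c(ein$cardinality, eout$cardinality)
        nb <- c(ctr[ein$source], ctr[eout$target])
        if (length(nb) == 0L) ctr[id] else sum(wgt * nb) / sum(wgt)
      }, 0)
      prop <- cur
      o <- order(target, cur[ids])     # stable: ties keep current order
      prop[ids[o]] <- seq_along(ids)
      prop_s <- score(prop)
      delta <- (prop_s[1] - cur_s[1]) + 1e-6 * (prop_s[2] - cur_s[2])
      if (delta <= 0 || stats::runif(1) < exp(-delta / max(temp, 1e-9))) {
        cur <- prop; cur_s <- prop_s
      }
      if (cur_s[1] < best_s[1] ||
          (cur_s[1] == best_s[1] && cur_s[2] < best_s[2])) {
        best <- cur; best_s <- cur_s
      }
    }
    temp <- temp * cooling
  }

  nodes <- net$nodes[, c("id", "window", "size")]
  nodes$order <- best[nodes$id]
  nodes$x <- match(nodes$window, windows) - 1L
  nodes$top <- NA_real_
  for (w in windows) {
    sel <- nodes$window == w
    ids <- nodes$id[sel][order(nodes$order[sel])]
    tops <- .stack_positions(ids, nodes$size[match(ids, nodes$id)], gap)
    nodes$top[match(ids, nodes$id)] <- unname(tops)
  }
  names(nodes)[names(nodes) == "size"] <- "height"
  nodes <- nodes[, c("id", "window", "order", "x", "top", "height")]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, z = z_order(net),
                 crossings = c(initial = initial_crossings, final = best_s[1]),
                 params = list(seed = seed, sweeps = sweeps,
                               cooling = cooling, gap = gap)),
            class = "sankey_layout")
}

#' @export
print.sankey_layout <- function(x, ...) {
  cat(sprintf("<sankey_layout> %d nodes; weighted crossings %g -> %g (seed %d)\n",
              nrow(x$nodes), x$crossings[["initial"]], x$crossings[["final"]],
              x$params$seed))
  invisible(x)
}

#' Drawing order of the edges (z-order)
#'
#' Larger ribbons are drawn first (underneath) and smaller ones on top, so
#' minority flows — the outliers — stay visible. Ties are broken by source
#' then target label, then edge id.
#'
#' @param net a `cohort_network`.
#' @return character vector of edge ids, first element drawn first
#'   (bottom of the stack).
#' @export
z_order <- function(net) {
  stopifnot(inherits(net, "cohort_network"))
  e <- net$edges
  if (nrow(e) == 0L) return(character())
  lab <- stats::setNames(net$nodes$label, net$nodes$id)
  o <- order(-e$cardinality, lab[e$source], lab[e$target], e$id,
             method = "radix")
  e$id[o]
}
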