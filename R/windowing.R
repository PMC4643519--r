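#' Define time windows over index-aligned trajectories
#'
#' `L + 1` strictly increasing boundaries in days relative to the index
#' event define `L` half-open windows `[t_l, t_{l+1})`. A record whose day
#' equals a boundary belongs to the window opening at that boundary, never
#' the one closing there. Optionally each window carries a *watched* factor
#' subset: factor sets in that window are intersected with it (e.g. watch
#' only hemodialysis in the first post-index year).
#'
#' @param boundaries numeric vector of `L + 1` strictly increasing day
#'   values.
#' @param labels optional character vector of `L` display names.
#' @param watch optional list of length `L`; each element `NULL` (watch
#'   everything) or a character vector of factor names.
#' @return an object of class `window_spec`.
#' @export
#' @examples
#' window_spec(c(-3650, 0, 365, 1825),
#'             labels = c("pre", "first year", "post"),
#'             watch = list(NULL, "HD", c("Death", "PD", "RTPL")))
window_spec <- function(boundaries, labels = NULL, watch = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L || any(diff(boundaries) <= 0)) {
    stop("boundaries must be at least two strictly increasing day values",
         call. = FALSE)
  }
  L <- length(boundaries) - 1L
  if (is.null(labels)) {
    labels <- sprintf("[%g, %g)", boundaries[-length(boundaries)], boundaries[-1L])
  }
  stopifnot(length(labels) == L)
  if (!is.null(watch)) {
    stopifnot(is.list(watch), length(watch) == L)
  }
  structure(list(boundaries = boundaries, labels = labels,
                 watch = watch, n_windows = L),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d windows\n", x$n_windows))
  for (l in seq_len(x$n_windows)) {
    w <- if (is.null(x$watch) || is.null(x$watch[[l]])) "all factors"
         else paste("watch:", paste(x$watch[[l]], collapse = ", "))
    cat(sprintf("  %d. %-14s [%g, %g)  %s\n", l, x$labels[l],
                x$boundaries[l], x$boundaries[l + 1L], w))
  }
  invisible(x)
}

#' Partition trajectories into time windows
#'
#' For each patient and window `l`, the window's factor set is the union of
#' the factor sets of all records with `t_l <= day < t_{l+1}`; records
#' outside the overall span are dropped. Patients with no in-range records
#' are retained with all-empty window sets (they form the explicit
#' no-factor group downstream). When a window has a watched subset the
#' union is intersected with it.
#'
#' With `carry_forward = TRUE`, each window additionally inherits all
#' *diagnosis* factors (not procedures) seen in earlier in-range windows,
#' modelling chronic conditions that need not be re-coded; the default
#' keeps raw fidelity. Carried factors are subject to the same watch
#' intersection.
#'
#' @param pop a `population` from [build_trajectories()].
#' @param spec a `window_spec`.
#' @param fm the `factor_map` (required only for `carry_forward`, to tell
#'   diagnoses from procedures).
#' @param carry_forward logical; see Details.
#' @return an object of class `windowed_population`: `patient_id`
#'   (character vector), `sets` (list per patient of `L` sorted character
#'   vectors) and `spec`.
#' @export
partition <- function(pop, spec, fm = NULL, carry_forward = FALSE) {
  stopifnot(inherits(pop, "population"), inherits(spec, "window_spec"))
  if (length(pop$trajectories) == 0L) stop("population is empty", call. = FALSE)
  b <- spec$boundaries
  L <- spec$n_windows
  watch <- spec$watch
  if (!is.null(watch)) {
    known <- if (!is.null(fm)) factor_names(fm) else NULL
    if (!is.null(known)) {
      unknown <- setdiff(unlist(watch), known)
      if (length(unknown)) {
        stop(sprintf("watched factor(s) not in the factor map: %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
    }
  }
  diag_factors <- if (carry_forward) {
    if (is.null(fm)) stop("carry_forward requires the factor map", call. = FALSE)
    vapply(Filter(function(e) e$kind == "diagnosis", fm$entries), `[[`, "", "abbreviation")
  } else character()

  sets <- lapply(pop$trajectories, function(tr) {
    # window index per record; 0 or L+1 => out of range
    idx <- findInterval(tr$day, b, left.open = FALSE, rightmost.closed = FALSE)
    idx[tr$day >= b[length(b)]] <- 0L
    out <- vector("list", L)
    carried <- character()
    for (l in seq_len(L)) {
      s <- sort(unique(unlist(tr$factors[idx == l], use.names = FALSE)))
      if (carry_forward) {
        s_new <- s
        s <- sort(unique(c(s, carried)))
        carried <- unique(c(carried, intersect(s_new, diag_factors)))
      }
      if (!is.null(watch) && !is.null(watch[[l]])) s <- intersect(s, watch[[l]])
      out[[l]] <- if (length(s)) s else character()
    }
    out
  })
  structure(list(patient_id = names(pop$trajectories),
                 sets = unname(sets), spec = spec,
                 index_factor = pop$index_factor),
            class = "windowed_population")
}

#' @export
print.windowed_population <- function(x, ...) {
  cat(sprintf("<windowed_population> %d patients x %d windows\n",
              length(x$patient_id), x$spec$n_windows))
  invisible(x)
}

#' Canonical label for a comorbidity (a factor set)
#'
#' Factors sorted lexicographically (C collation, so labels are stable
#' across locales) and joined with `|`; the empty set is `"(none)"`. Two
#' windowsful of factors are the same *unique combination* exactly when
#' their keys are equal.
#'
#' @param s character vector of factor names.
#' @return a single string.
#' @export
#' @examples
#' comorbidity_key(c("HD", "CKD"))  # "CKD|HD"
comorbidity_key <- function(s) {
  s <- unique(as.character(s))
  if (length(s) == 0L) return("(none)")
  paste(sort(s, method = "radix"), collapse = "|")
}

#' Per-window comorbidity keys for every patient
#'
#' @param wp a `windowed_population`.
#' @param window window index in `1:L`.
#' @return character vector of keys, one per patient (same order as
#'   `wp$patient_id`).
#' @export
window_keys <- function(wp, window) {
  stopifnot(inherits(wp, "windowed_population"),
            window >= 1L, window <= wp$spec$n_windows)
  vapply(wp$sets, function(s) comorbidity_key(s[[window]]), "")
}

#' Serialize / restore a windowed population
#' @param wp a `windowed_population`.
#' @param path file path.
#' @return `path` (write) or a `windowed_population` (read).
#' @export
write_windowed <- function(wp, path) {
  stopifnot(inherits(wp, "windowed_population"))
  doc <- list(
    spec = list(boundaries = wp$spec$boundaries, labels = wp$spec$labels,
                watch = wp$spec$watch),
    index_factor = wp$index_factor,
    patient_id = wp$patient_id,
    sets = wp$sets
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_windowed
#' @export
read_windowed <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  watch <- doc$spec$watch
  if (!is.null(watch)) {
    watch <- lapply(watch, function(w) {
      if (is.null(w)) NULL else unname(vapply(w, as.character, ""))
    })
  }
  spec <- window_spec(unname(vapply(doc$spec$boundaries, as.numeric, 0)),
                      labels = unname(vapply(doc$spec$labels, as.character, "")),
                      watch = watch)
  sets <- lapply(doc$sets, function(p) {
    lapply(p, function(s) if (length(s)) unname(vapply(s, as.character, "")) else character())
  })
  structure(list(patient_id = unname(vapply(doc$patient_id, as.character, "")),
                 sets = sets, spec = spec,
                 index_factor = doc$index_factor),
            class = "windowed_population")
}
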