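#' Read a long-format event table
#'
#' Reads a claims/EMR extract in long format: one row per recorded code,
#' with a patient identifier, a time column and a code column. Time is
#' either a calendar date (ISO-8601, column `date`) or an integer day
#' offset (column `day`, for pre-aligned extracts). Column names are
#' configurable; duplicate rows are preserved, file order is kept.
#'
#' @param path CSV file path.
#' @param patient_col,code_col,date_col,day_col column names to use. If the
#'   date column is absent the day column is required (and vice versa).
#' @return a data frame with columns `patient_id` (character), `time`
#'   (Date, or integer days when pre-aligned) and `code` (character), with
#'   attribute `pre_aligned` set to `TRUE` when day offsets were read.
#' @export
read_events <- function(path, patient_col = "patient_id", code_col = "code",
                        date_col = "date", day_col = "day") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  for (col in c(patient_col, code_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("required column '%s' missing from %s", col, path), call. = FALSE)
    }
  }
  pre_aligned <- FALSE
  if (date_col %in% names(df)) {
    time <- as.Date(df[[date_col]], format = "%Y-%m-%d")
    if (anyNA(time)) {
      bad <- which(is.na(time))[1L]
      stop(sprintf("unparseable date '%s' at data row %d of %s",
                   df[[date_col]][bad], bad, path), call. = FALSE)
    }
  } else if (day_col %in% names(df)) {
    time <- suppressWarnings(as.integer(df[[day_col]]))
    if (anyNA(time)) {
      bad <- which(is.na(time))[1L]
      stop(sprintf("unparseable day offset '%s' at data row %d of %s",
                   df[[day_col]][bad], bad, path), call. = FALSE)
    }
    pre_aligned <- TRUE
  } else {
    stop(sprintf("neither a '%s' nor a '%s' column found in %s",
                 date_col, day_col, path), call. = FALSE)
  }
  out <- data.frame(patient_id = as.character(df[[patient_col]]),
                    code = as.character(df[[code_col]]),
                    stringsAsFactors = FALSE)
  out$time <- time
  attr(out, "pre_aligned") <- pre_aligned
  out
}

#' Build index-aligned patient trajectories
#'
#' Maps each event's code through the factor map, aligns every patient on
#' the first occurrence of the index factor (that date becomes day 0), and
#' merges same-day events into a single record whose factor set is the
#' union of the day's factors. Events whose codes match no factor are
#' dropped (counted); patients with no index-factor event are excluded
#' (counted, with their ids retained).
#'
#' @param events data frame from [read_events()] (or any data frame with
#'   columns `patient_id`, `time`, `code`; `time` may be `Date` or integer
#'   day offsets).
#' @param fm a `factor_map` with a non-`NULL` `index_factor`.
#' @return an object of class `population`: a list with elements
#'   `trajectories` (named list; each has `patient_id`, integer vector
#'   `day` sorted ascending, list `factors` of sorted character vectors,
#'   and `index_time` — the absolute time of the index event),
#'   `excluded` (`n`, `ids`, `reason`), `dropped_codes` (count of events
#'   matching no factor) and `index_factor`.
#' @export
build_trajectories <- function(events, fm) {
  stopifnot(inherits(fm, "factor_map"), nrow(events) > 0L)
  if (is.null(fm$index_factor)) {
    stop("factor map has no index factor; alignment is undefined", call. = FALSE)
  }
  pre_aligned <- isTRUE(attr(events, "pre_aligned")) || is.integer(events$time)

  codes <- unique(events$code)
  hits <- match_codes(codes, fm)                      # (code, factor) pairs
  mapped <- merge(events[, c("patient_id", "time", "code")], hits,
                  by = "code", all = FALSE)
  dropped <- sum(!events$code %in% hits$code)

  # distinct (patient, time, factor) triples
  mapped <- unique(mapped[, c("patient_id", "time", "factor")])

  all_ids <- unique(events$patient_id)
  trajectories <- list()
  excluded_ids <- character()

  if (nrow(mapped) > 0L) {
    by_patient <- split(mapped, mapped$patient_id)
    for (pid in names(by_patient)) {
      rec <- by_patient[[pid]]
      idx_times <- rec$time[rec$factor == fm$index_factor]
      if (length(idx_times) == 0L) {
        excluded_ids <- c(excluded_ids, pid)
        next
      }
      t0 <- min(idx_times)
      day <- as.integer(rec$time - t0)
      o <- order(day, rec$factor)
      day <- day[o]; fac <- rec$factor[o]
      udays <- unique(day)
      fsets <- lapply(udays, function(d) sort(unique(fac[day == d])))
      trajectories[[pid]] <- list(patient_id = pid, day = udays,
                                  factors = fsets, index_time = t0)
    }
  }
  excluded_ids <- sort(unique(c(excluded_ids,
                                setdiff(all_ids, c(names(trajectories), excluded_ids)))))
  structure(list(
    trajectories = trajectories[order(names(trajectories))],
    excluded = list(n = length(excluded_ids), ids = excluded_ids,
                    reason = "no index-factor event"),
    dropped_codes = dropped,
    index_factor = fm$index_factor,
    pre_aligned = pre_aligned
  ), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d trajectories (index factor %s); %d excluded; %d unmapped events\n",
              length(x$trajectories), x$index_factor, x$excluded$n, x$dropped_codes))
  invisible(x)
}

#' Serialize / restore a population
#'
#' JSON serialization used for caching between pipeline stages. Reading a
#' written population yields an identical structure.
#'
#' @param pop a `population`.
#' @param path file path.
#' @return `path` (write) or a `population` (read).
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "population"))
  doc <- list(
    index_factor = pop$index_factor,
    pre_aligned = pop$pre_aligned,
    dropped_codes = pop$dropped_codes,
    excluded = pop$excluded,
    trajectories = lapply(unname(pop$trajectories), function(tr) {
      list(patient_id = tr$patient_id, day = as.integer(tr$day),
           factors = tr$factors, index_time = as.character(tr$index_time))
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  trajectories <- lapply(doc$trajectories, function(tr) {
    it <- tr$index_time
    index_time <- if (grepl("^-?[0-9]+$", it)) as.integer(it) else as.Date(it)
    list(patient_id = tr$patient_id,
         day = unname(vapply(tr$day, as.integer, 0L)),
         factors = lapply(tr$factors, function(f) unname(vapply(f, as.character, ""))),
         index_time = index_time)
  })
  names(trajectories) <- vapply(trajectories, `[[`, "", "patient_id")
  structure(list(
    trajectories = trajectories,
    excluded = list(n = doc$excluded$n,
                    ids = unname(vapply(doc$excluded$ids, as.character, "")),
                    reason = doc$excluded$reason),
    dropped_codes = doc$dropped_codes,
    index_factor = doc$index_factor,
    pre_aligned = isTRUE(doc$pre_aligned)
  ), class = "population")
}
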