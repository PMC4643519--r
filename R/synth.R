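#' Configuration for the synthetic index-disease cohort generator
#'
#' Describes a claims-style cohort: every patient receives the index
#' diagnosis (CKD) at a randomized calendar date (day 0); comorbidity
#' codes accrue before the index as independent Poisson processes with
#' per-factor annual rates; the first post-index year may bring
#' hemodialysis; a later terminal-phase event (death, peritoneal dialysis
#' or renal transplantation) follows configured conditional
#' probabilities. A configurable fraction of patients forms a
#' *deterministic subcohort* whose pre-index set maps one-to-one to a
#' fixed outcome chain, giving the network zero-entropy transitions to
#' exercise confidence filtering.
#'
#' Defaults emulate the shipped CKD factor vocabulary on the 1998-2011
#' claims-era calendar: first-year hemodialysis probability 0.0954,
#' hemodialysis outcomes split none 0.702 / Death 0.149 / PD 0.099 /
#' RTPL 0.05, non-hemodialysis outcomes none 0.62 / Death 0.05 /
#' PD 0.28 / RTPL 0.05, and prevalence-ordered annual comorbidity rates
#' (hypertension highest, lupus lowest).
#'
#' @param n_patients number of patients.
#' @param seed integer seed; generation is fully reproducible from it.
#' @param span_before,span_after observation days before/after index.
#' @param pre_rates named annual incidence rates (events/patient-year)
#'   for pre-index comorbidity factors.
#' @param p_hd_year1 probability of hemodialysis in the first year.
#' @param outcome_hd,outcome_no_hd named probability vectors over
#'   `c("none", "Death", "PD", "RTPL")`, conditional on first-year
#'   hemodialysis status; each must sum to 1.
#' @param det_fraction fraction of patients in the deterministic
#'   subcohort (pre-index set exactly `{PKD}`, then hemodialysis, then
#'   peritoneal dialysis).
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 1000L, seed = 1L,
                         span_before = 2920L, span_after = 1825L,
                         pre_rates = c(HTN = 0.12, DM = 0.10,
                                       Hyperlipidemia = 0.08, CAD = 0.05,
                                       CVD = 0.04, CHF = 0.03,
                                       Proteinuria = 0.03, GN = 0.02,
                                       `Renal stone` = 0.02, PKD = 0.005,
                                       SLE = 0.005),
                         p_hd_year1 = 0.0954,
                         outcome_hd = c(none = 0.702, Death = 0.149,
                                        PD = 0.099, RTPL = 0.05),
                         outcome_no_hd = c(none = 0.62, Death = 0.05,
                                           PD = 0.28, RTPL = 0.05),
                         det_fraction = 0.1) {
  stopifnot(n_patients >= 1L, span_before > 365L, span_after > 366L,
            all(pre_rates >= 0), p_hd_year1 >= 0, p_hd_year1 <= 1,
            det_fraction >= 0, det_fraction <= 1)
  for (nm in c("outcome_hd", "outcome_no_hd")) {
    v <- get(nm)
    if (!setequal(names(v), c("none", "Death", "PD", "RTPL")) ||
        any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop(nm, " must be a probability vector over none/Death/PD/RTPL summing to 1",
           call. = FALSE)
    }
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 span_before = as.integer(span_before),
                 span_after = as.integer(span_after),
                 pre_rates = pre_rates, p_hd_year1 = p_hd_year1,
                 outcome_hd = outcome_hd, outcome_no_hd = outcome_no_hd,
                 det_fraction = det_fraction),
            class = "synth_config")
}

#' Factor map used with synthetic cohorts
#'
#' The default CKD map plus a `Death` factor bound to the sentinel event
#' code `DEATH` that the generator emits for mortality events (real
#' claims extracts encode death outside the diagnosis stream, so the
#' default map carries no death codes; the sentinel makes mortality an
#' ordinary factor here).
#'
#' @return a `factor_map` with 16 entries.
#' @export
synth_factor_map <- function() {
  fm <- default_ckd_map()
  doc <- list(index_factor = fm$index_factor,
              factors = c(lapply(fm$entries, function(e)
                list(name = e$name, abbreviation = e$abbreviation, codes = e$codes)),
                list(list(name = "Death", abbreviation = "Death", codes = "DEATH"))))
  parse_factor_map(doc)
}

# a concrete raw code exercising each pattern kind of a factor
.sample_code <- function(fm, factor) {
  e <- fm$entries[[match(factor, factor_names(fm))]]
  p <- e$patterns[[sample.int(length(e$patterns), 1L)]]
  switch(p$kind,
    "prefix" = p$value,
    "exact" = p$value,
    "numeric-range" = as.character(sample(seq.int(p$low, p$high), 1L)),
    "decimal-range" = sprintf("%.1f", stats::runif(1, p$low, p$high)))
}

#' Generate a synthetic index-disease cohort
#'
#' Draws a cohort per the configuration and returns (and optionally
#' writes) a long-format events table — columns `patient_id`, `date`,
#' `code`, with concrete codes sampled from the factor map's own pattern
#' lists so code matching is exercised end-to-end — together with a truth
#' table of each patient's per-window factor sets for the canonical
#' three-window design (pre-index, first year, later follow-up). The
#' truth table is derived deterministically from the emitted events, so
#' running the mapping and windowing stages over the CSV must recover it
#' exactly. Identical seeds produce byte-identical CSVs.
#'
#' @param cfg a `synth_config`.
#' @param events_path,truth_path optional output CSV paths.
#' @return invisibly, a list with `events` (data frame), `truth` (data
#'   frame `patient_id`, `window`, `key`), `windows` (the canonical
#'   `window_spec`) and `fm` (the map from [synth_factor_map()]).
#' @export
synth_generate <- function(cfg, events_path = NULL, truth_path = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  fm <- synth_factor_map()
  n <- cfg$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  # index dates inside 1998-2011 with room for both spans
  d0 <- as.Date("1998-01-01") + cfg$span_before
  d1 <- as.Date("2011-12-31") - cfg$span_after
  if (d1 < d0) {
    stop("observation spans exceed the 1998-2011 claims calendar", call. = FALSE)
  }
  index_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L

  det <- seq_len(n) <= round(cfg$det_fraction * n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    day <- integer(); code <- character()
    if (det[i]) {
      # deterministic subcohort: {PKD} -> HD -> PD
      day <- c(day, -sample.int(cfg$span_before - 1L, 1L))
      code <- c(code, .sample_code(fm, "PKD"))
      day <- c(day, sample.int(365L, 1L) - 1L)
      code <- c(code, .sample_code(fm, "HD"))
      day <- c(day, 365L + sample.int(cfg$span_after - 366L, 1L) - 1L)
      code <- c(code, .sample_code(fm, "PD"))
    } else {
      for (f in names(cfg$pre_rates)) {
        kf <- stats::rpois(1L, cfg$pre_rates[[f]] * cfg$span_before / 365)
        if (kf > 0L) {
          day <- c(day, -sample.int(cfg$span_before - 1L, kf, replace = TRUE))
          code <- c(code, vapply(seq_len(kf), function(z) .sample_code(fm, f), ""))
        }
      }
      hd <- stats::runif(1) < cfg$p_hd_year1
      if (hd) {
        day <- c(day, sample.int(365L, 1L) - 1L)
        code <- c(code, .sample_code(fm, "HD"))
      }
      probs <- if (hd) cfg$outcome_hd else cfg$outcome_no_hd
      out <- sample(names(probs), 1L, prob = probs)
      if (out != "none") {
        day <- c(day, 365L + sample.int(cfg$span_after - 366L, 1L) - 1L)
        code <- c(code, .sample_code(fm, out))
      }
    }
    # the index diagnosis itself, at day 0
    day <- c(day, 0L)
    code <- c(code, "585")
    rows[[i]] <- data.frame(patient_id = ids[i],
                            date = index_date[i] + day,
                            code = code, day = day,
                            stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, rows)
  events <- events[order(events$patient_id, events$day, events$code,
                         method = "radix"), ]
  rownames(events) <- NULL

  windows <- window_spec(c(-cfg$span_before, 0L, 365L, cfg$span_after),
                         labels = c("pre-index", "first year", "follow-up"))
  # truth: per-window factor keys derived from the emitted events
  fac <- match_codes(unique(events$code), fm)
  evf <- merge(events, fac, by = "code")
  b <- windows$boundaries
  truth <- do.call(rbind, lapply(ids, function(pid) {
    sub <- evf[evf$patient_id == pid, , drop = FALSE]
    key <- vapply(seq_len(windows$n_windows), function(l) {
      comorbidity_key(unique(sub$factor[sub$day >= b[l] & sub$day < b[l + 1L]]))
    }, "")
    data.frame(patient_id = pid, window = seq_len(windows$n_windows),
               key = key, stringsAsFactors = FALSE)
  }))
  events$day <- NULL
  events$date <- format(events$date, "%Y-%m-%d")

  if (!is.null(events_path)) {
    utils::write.csv(events, events_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(truth_path)) {
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = TRUE)
  }
  invisible(list(events = events, truth = truth, windows = windows, fm = fm))
}
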