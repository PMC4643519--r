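#' Assemble and validate an end-to-end run configuration
#'
#' The configuration drives the full stage sequence: map factors, align
#' trajectories, partition windows, cluster each window, build and filter
#' the network, lay it out and export. It can be given as a list or as a
#' path to a JSON file of the same shape.
#'
#' @param config list or JSON path with elements:
#'   \describe{
#'     \item{events}{path to the events CSV (required);}
#'     \item{factor_map}{path to a factor-map JSON, or `"default"` /
#'       `"synth"` for the shipped maps;}
#'     \item{out_dir}{output directory;}
#'     \item{windows}{list with `boundaries`, optional `labels`, `watch`;}
#'     \item{cluster}{`method` (`"frequency"`/`"hierarchical"`, per-window
#'       vector allowed), `threshold`, `k`, `split_others`, `weighted`;}
#'     \item{entropy}{`mode` (`"shannon"`/`"as-printed"`) and `threshold`
#'       (`NULL` keeps all edges);}
#'     \item{layout}{`seed`, `sweeps`, `cooling`, `gap`;}
#'     \item{carry_forward}{logical, default `FALSE`;}
#'     \item{highlight}{optional selection, e.g. `list(factor = "SLE")`.}
#'   }
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$events)) stop("run config needs an 'events' path", call. = FALSE)
  if (is.null(config$out_dir)) stop("run config needs an 'out_dir'", call. = FALSE)
  if (is.null(config$windows$boundaries)) {
    stop("run config needs windows$boundaries", call. = FALSE)
  }
  config$factor_map <- config$factor_map %||% "default"
  cl <- config$cluster %||% list()
  config$cluster <- list(method = cl$method %||% "frequency",
                         threshold = cl$threshold %||% 0,
                         k = cl$k %||% NA,
                         split_others = cl$split_others %||% TRUE,
                         weighted = cl$weighted %||% FALSE)
  en <- config$entropy %||% list()
  config$entropy <- list(mode = en$mode %||% "shannon",
                         threshold = en$threshold %||% NULL)
  la <- config$layout %||% list()
  config$layout <- list(seed = la$seed %||% 1L, sweeps = la$sweeps %||% 32L,
                        cooling = la$cooling %||% 0.98, gap = la$gap %||% NULL)
  config$carry_forward <- isTRUE(config$carry_forward)
  structure(config, class = "run_config")
}

# content hash of an R object (via its canonical JSON) or a file
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                           digits = NA, force = TRUE)), f)
  unname(tools::md5sum(f))
}

.hash_file <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline with stage caching
#'
#' Executes the stage sequence and writes every stage's serialized
#' artifact under `out_dir`: `population.json`, `windows.json`,
#' `network.json`, `network_filtered.json`, `sankey.json`, `sankey.html`
#' and `run.log`. Each stage's inputs (upstream artifacts, files and
#' parameters) are content-hashed into `.cache.json`; on re-runs a stage
#' whose hash is unchanged is reloaded from its artifact instead of
#' recomputed, and the log says so. The log also reports the counts a
#' study log needs: patients read and excluded, unmapped events, cohorts
#' per window, and edges before and after filtering.
#'
#' @param config a `run_config` (or anything [run_config()] accepts).
#' @param force recompute everything, ignoring the cache.
#' @param quiet suppress console messages (the log file is always
#'   written).
#' @return invisibly, a list with the pipeline objects (`pop`, `wp`,
#'   `cohorts`, `net`, `net_filtered`, `layout`, `doc`) and `out_dir`.
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  cache_path <- file.path(cfg$out_dir, ".cache.json")
  cache <- if (!force && file.exists(cache_path)) {
    jsonlite::fromJSON(cache_path, simplifyVector = TRUE)
  } else list()
  new_cache <- list()
  cached <- function(stage, hash, artifact) {
    !force && identical(unname(unlist(cache[[stage]])), unname(hash)) &&
      file.exists(file.path(cfg$out_dir, artifact))
  }

  # -- stage: factor map ----------------------------------------------------
  fm <- switch(cfg$factor_map,
               "default" = default_ckd_map(),
               "synth" = synth_factor_map(),
               parse_factor_map(cfg$factor_map))
  fm_hash <- .hash_obj(lapply(fm$entries, `[[`, "codes"))

  # -- stage: population ----------------------------------------------------
  pop_hash <- .hash_obj(list(events = .hash_file(cfg$events), fm = fm_hash))
  pop_file <- "population.json"
  if (cached("population", pop_hash, pop_file)) {
    pop <- read_population(file.path(cfg$out_dir, pop_file))
    say("stage population: cache hit (reused %s)", pop_file)
  } else {
    events <- read_events(cfg$events)
    pop <- build_trajectories(events, fm)
    write_population(pop, file.path(cfg$out_dir, pop_file))
    say("stage population: %d events read; %d patients retained, %d excluded (%s); %d unmapped events dropped",
        nrow(events), length(pop$trajectories), pop$excluded$n,
        pop$excluded$reason, pop$dropped_codes)
  }
  new_cache$population <- pop_hash

  # -- stage: windowing -----------------------------------------------------
  watch <- cfg$windows$watch
  if (!is.null(watch)) watch <- lapply(watch, function(w) if (length(w)) w else NULL)
  spec <- window_spec(cfg$windows$boundaries, labels = cfg$windows$labels,
                      watch = watch)
  win_hash <- .hash_obj(list(pop = pop_hash,
                             boundaries = spec$boundaries, watch = watch,
                             carry = cfg$carry_forward))
  win_file <- "windows.json"
  if (cached("windowing", win_hash, win_file)) {
    wp <- read_windowed(file.path(cfg$out_dir, win_file))
    say("stage windowing: cache hit (reused %s)", win_file)
  } else {
    wp <- partition(pop, spec, fm = fm, carry_forward = cfg$carry_forward)
    write_windowed(wp, file.path(cfg$out_dir, win_file))
    say("stage windowing: %d windows over %d patients",
        spec$n_windows, length(wp$patient_id))
  }
  new_cache$windowing <- win_hash

  # -- stage: clustering + network ------------------------------------------
  net_hash <- .hash_obj(list(win = win_hash, cluster = cfg$cluster,
                             mode = cfg$entropy$mode))
  net_file <- "network.json"
  if (cached("network", net_hash, net_file)) {
    net <- read_network(file.path(cfg$out_dir, net_file))
    say("stage network: cache hit (reused %s)", net_file)
    cohorts <- NULL
  } else {
    cohorts <- cluster_windows(wp, method = cfg$cluster$method,
                               threshold = cfg$cluster$threshold,
                               k = cfg$cluster$k,
                               split_others = isTRUE(cfg$cluster$split_others),
                               weighted = isTRUE(cfg$cluster$weighted))
    net <- build_network(cohorts, entropy_mode = cfg$entropy$mode)
    write_network(net, file.path(cfg$out_dir, net_file))
    say("stage network: cohorts per window [%s]; %d edges",
        paste(vapply(cohorts, function(cs) length(cs$cohorts), 0L), collapse = ", "),
        nrow(net$edges))
  }
  new_cache$network <- net_hash

  # -- stage: filtering -----------------------------------------------------
  thr <- cfg$entropy$threshold
  filt_hash <- .hash_obj(list(net = net_hash, thr = thr))
  filt_file <- "network_filtered.json"
  if (cached("filter", filt_hash, filt_file)) {
    net_f <- read_network(file.path(cfg$out_dir, filt_file))
    say("stage filter: cache hit (reused %s)", filt_file)
  } else {
    net_f <- if (is.null(thr)) net else filter_edges(net, thr)
    write_network(net_f, file.path(cfg$out_dir, filt_file))
    say("stage filter: threshold %s; %d of %d edges kept",
        if (is.null(thr)) "none" else format(thr), nrow(net_f$edges), nrow(net$edges))
  }
  new_cache$filter <- filt_hash

  # -- stage: layout + export -----------------------------------------------
  lay_hash <- .hash_obj(list(filt = filt_hash, layout = cfg$layout,
                             highlight = cfg$highlight))
  doc_file <- "sankey.json"
  if (cached("layout", lay_hash, doc_file)) {
    doc <- read_sankey(file.path(cfg$out_dir, doc_file))
    lay <- NULL
    say("stage layout: cache hit (reused %s)", doc_file)
  } else {
    lay <- optimize_order(net_f, seed = cfg$layout$seed,
                          sweeps = cfg$layout$sweeps,
                          cooling = cfg$layout$cooling, gap = cfg$layout$gap)
    hl <- if (!is.null(cfg$highlight)) {
      do.call(highlight_selection, c(list(net = net_f, wp = wp), cfg$highlight))
    }
    doc <- sankey_doc(net_f, lay, highlight = hl)
    export_json(doc, file.path(cfg$out_dir, doc_file))
    export_html(doc, file.path(cfg$out_dir, "sankey.html"))
    say("stage layout: weighted crossings %g -> %g; wrote %s and sankey.html",
        lay$crossings[["initial"]], lay$crossings[["final"]], doc_file)
  }
  new_cache$layout <- lay_hash

  writeLines(as.character(jsonlite::toJSON(new_cache, auto_unbox = TRUE)), cache_path)
  writeLines(log_lines, log_path)
  invisible(list(pop = pop, wp = wp, cohorts = cohorts, net = net,
                 net_filtered = net_f, layout = lay, doc = doc,
                 out_dir = cfg$out_dir))
}
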