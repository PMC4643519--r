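#' Factor maps: translating raw codes into a factor vocabulary
#'
#' A *factor* is a single binary criterion (a disease or a procedure) used to
#' characterise patients. A factor map holds, for each factor, the set of
#' code patterns that define it. Diagnosis codes are ICD-9-CM; procedure
#' codes (e.g. Taiwan NHI codes such as `58001C`) are terminal identifiers.
#'
#' Four pattern kinds are supported:
#' \describe{
#'   \item{prefix}{a normalized code matches if it starts with the pattern
#'     (so `250` covers `250`, `250.00`, ... — category codes include their
#'     children);}
#'   \item{numeric-range}{`430-438` matches any code whose leading digits,
#'     at the width of the endpoints, fall in the closed integer range;}
#'   \item{decimal-range}{`425.4-425.9` matches codes sharing the 3-digit
#'     category whose `category.decimal` value lies in the closed interval;}
#'   \item{exact}{string equality after normalization (used for
#'     alphanumeric procedure codes ending in a letter).}
#' }
#'
#' Normalization strips dots and whitespace and uppercases, so matching is
#' case- and dot-insensitive.
#'
#' @name factor_map
NULL

#' Normalize a raw diagnosis/procedure code
#'
#' Strips `.` and whitespace and converts to upper case. All matching is
#' performed on normalized codes, so `"425.4"` and `"4254"` are equivalent.
#'
#' @param code character vector of raw codes.
#' @return character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("425.4", " 58001c "))
normalize_code <- function(code) {
  toupper(gsub("[.[:space:]]", "", as.character(code)))
}

# en dash / em dash / hyphen all separate range endpoints in printed tables
.split_range <- function(token) {
  strsplit(token, "[-–—]")[[1]]
}

.parse_code_token <- function(token, row_label) {
  raw <- trimws(token)
  if (!nzchar(raw)) {
    stop(sprintf("empty code token in factor '%s'", row_label), call. = FALSE)
  }
  parts <- .split_range(raw)
  if (length(parts) == 2L) {
    a <- trimws(parts[[1]]); b <- trimws(parts[[2]])
    if (grepl("\\.", a) || grepl("\\.", b)) {
      # decimal range, e.g. 425.4-425.9: endpoints must share the category
      na <- normalize_code(a); nb <- normalize_code(b)
      if (!grepl("^[0-9]{4,}$", na) || !grepl("^[0-9]{4,}$", nb)) {
        stop(sprintf("malformed decimal range '%s' in factor '%s'", raw, row_label),
             call. = FALSE)
      }
      cat_a <- substr(na, 1L, 3L); cat_b <- substr(nb, 1L, 3L)
      if (cat_a != cat_b) {
        stop(sprintf(
          "decimal range '%s' in factor '%s' spans categories %s and %s",
          raw, row_label, cat_a, cat_b), call. = FALSE)
      }
      lo <- as.numeric(paste0(cat_a, ".", substring(na, 4L)))
      hi <- as.numeric(paste0(cat_b, ".", substring(nb, 4L)))
      if (lo > hi) {
        stop(sprintf("malformed range '%s' in factor '%s' (low > high)",
                     raw, row_label), call. = FALSE)
      }
      return(list(kind = "decimal-range", category = cat_a, low = lo, high = hi))
    }
    na <- normalize_code(a); nb <- normalize_code(b)
    if (!grepl("^[0-9]+$", na) || !grepl("^[0-9]+$", nb) || nchar(na) != nchar(nb)) {
      stop(sprintf("malformed numeric range '%s' in factor '%s'", raw, row_label),
           call. = FALSE)
    }
    lo <- as.integer(na); hi <- as.integer(nb)
    if (lo > hi) {
      stop(sprintf("malformed range '%s' in factor '%s' (low > high)",
                   raw, row_label), call. = FALSE)
    }
    return(list(kind = "numeric-range", width = nchar(na), low = lo, high = hi))
  }
  if (length(parts) != 1L) {
    stop(sprintf("malformed code token '%s' in factor '%s'", raw, row_label),
         call. = FALSE)
  }
  norm <- normalize_code(raw)
  if (grepl("[A-Z]$", norm)) {
    list(kind = "exact", value = norm)        # terminal procedure identifier
  } else {
    list(kind = "prefix", value = norm)
  }
}

#' Parse a factor-map configuration into a `factor_map`
#'
#' The configuration is either a path to a JSON file, a list already of that
#' shape, or a data frame. The JSON shape is
#' `{"index_factor": "CKD", "factors": [{"name": ..., "abbreviation": ...,
#' "codes": "585, 586"}, ...]}`; a data frame needs columns `name`,
#' `abbreviation` and `codes`. Each comma-separated token of `codes` becomes
#' one code pattern; hyphenated tokens become range patterns, tokens ending
#' in a letter become exact patterns, all others prefix patterns.
#'
#' Factors whose patterns are all exact are classed as procedures; all
#' others as diagnoses (used by the windowing carry-forward option).
#'
#' @param config path, list, or data frame (see Details).
#' @param index_factor abbreviation of the factor whose first occurrence
#'   defines day 0; overrides a value given in `config`.
#' @return an object of class `factor_map`.
#' @export
#' @examples
#' fm <- parse_factor_map(data.frame(
#'   name = c("Chronic Kidney Disease", "Hypertension"),
#'   abbreviation = c("CKD", "HTN"),
#'   codes = c("585, 586", "401")), index_factor = "CKD")
#' match_code("585.1", fm)
parse_factor_map <- function(config, index_factor = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  }
  if (is.data.frame(config)) {
    rows <- lapply(seq_len(nrow(config)), function(i) as.list(config[i, , drop = FALSE]))
    config <- list(factors = rows)
  }
  if (is.null(config$factors) || length(config$factors) == 0L) {
    stop("factor map configuration has no factors", call. = FALSE)
  }
  if (is.null(index_factor)) index_factor <- config$index_factor

  entries <- lapply(config$factors, function(row) {
    name <- as.character(row$name %||% row$abbreviation)
    abbr <- as.character(row$abbreviation %||% row$name)
    codes <- as.character(row$codes %||% "")
    if (!nzchar(trimws(codes))) {
      stop(sprintf("factor '%s' has an empty code specification", abbr), call. = FALSE)
    }
    tokens <- trimws(strsplit(codes, ",")[[1]])
    tokens <- tokens[nzchar(tokens)]
    patterns <- lapply(tokens, .parse_code_token, row_label = abbr)
    kind <- if (all(vapply(patterns, `[[`, "", "kind") == "exact")) "procedure" else "diagnosis"
    list(name = name, abbreviation = abbr, codes = codes,
         kind = kind, patterns = patterns)
  })
  abbrs <- vapply(entries, `[[`, "", "abbreviation")
  if (anyDuplicated(abbrs)) {
    stop(sprintf("duplicate factor name(s): %s",
                 paste(unique(abbrs[duplicated(abbrs)]), collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(index_factor) && !index_factor %in% abbrs) {
    stop(sprintf("index factor '%s' is not among the map's factors", index_factor),
         call. = FALSE)
  }
  structure(list(entries = entries, index_factor = index_factor),
            class = "factor_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.factor_map <- function(x, ...) {
  cat(sprintf("<factor_map> %d factors; index factor: %s\n",
              length(x$entries), x$index_factor %||% "<none>"))
  for (e in x$entries) {
    cat(sprintf("  %-16s %s  [%s]\n", e$abbreviation, e$codes, e$kind))
  }
  invisible(x)
}

#' Abbreviations of the factors in a map
#' @param fm a `factor_map`.
#' @return character vector of factor abbreviations, in map order.
#' @export
factor_names <- function(fm) {
  stopifnot(inherits(fm, "factor_map"))
  vapply(fm$entries, `[[`, "", "abbreviation")
}

.pattern_matches <- function(p, norm) {
  switch(p$kind,
    "prefix" = startsWith(norm, p$value),
    "exact"  = norm == p$value,
    "numeric-range" = {
      w <- p$width
      head <- substr(norm, 1L, w)
      nchar(norm) >= w & grepl("^[0-9]+$", head) &
        suppressWarnings(as.integer(head)) >= p$low &
        suppressWarnings(as.integer(head)) <= p$high
    },
    "decimal-range" = {
      ok <- startsWith(norm, p$category) & grepl("^[0-9]+$", norm)
      val <- rep(NA_real_, length(norm))
      rest <- substring(norm[ok], 4L)
      rest[!nzchar(rest)] <- "0"
      val[ok] <- suppressWarnings(as.numeric(paste0(p$category, ".", rest)))
      !is.na(val) & val >= p$low & val <= p$high
    },
    stop("unknown pattern kind: ", p$kind))
}

#' Map a raw code to the factors it belongs to
#'
#' A code may match several factors; a code matching none returns an empty
#' set. Matching is case- and dot-insensitive.
#'
#' @param code a single raw code string.
#' @param fm a `factor_map`.
#' @return character vector (possibly empty) of factor abbreviations.
#' @export
#' @examples
#' match_code("437.3", default_ckd_map())  # cerebrovascular disease
match_code <- function(code, fm) {
  stopifnot(inherits(fm, "factor_map"), length(code) == 1L, nzchar(code))
  norm <- normalize_code(code)
  hits <- vapply(fm$entries, function(e) {
    any(vapply(e$patterns, function(p) isTRUE(.pattern_matches(p, norm)), NA))
  }, NA)
  factor_names(fm)[hits]
}

# Vectorized matcher used by the pipeline: one row per (code, factor) hit.
# Unmatched codes yield no rows.
match_codes <- function(codes, fm) {
  stopifnot(inherits(fm, "factor_map"))
  norm <- normalize_code(codes)
  out <- lapply(fm$entries, function(e) {
    hit <- rep(FALSE, length(norm))
    for (p in e$patterns) hit <- hit | .pattern_matches(p, norm)
    if (any(hit)) data.frame(code = codes[hit],
                             factor = e$abbreviation,
                             stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(code = character(), factor = character(),
                               stringsAsFactors = FALSE)
  else out
}

#' The shipped chronic kidney disease factor map
#'
#' Returns the default CKD map: 15 diseases and procedures (cerebrovascular
#' disease, CKD itself, congestive heart failure, coronary artery disease,
#' diabetes, glomerulonephritis, hemodialysis, hyperlipidemia, hypertension,
#' peritoneal dialysis, polycystic kidney disease, proteinuria, renal stone,
#' renal transplantation, systemic lupus erythematosus) defined over
#' ICD-9-CM diagnosis ranges and Taiwan NHI procedure codes, with CKD as the
#' index factor. A death event has no standard claims code; callers who
#' track mortality add their own sentinel factor (see
#' [synth_factor_map()] for the convention used by the synthetic generator).
#'
#' @return a `factor_map` with 15 entries; `index_factor` is `"CKD"`.
#' @export
#' @examples
#' fm <- default_ckd_map()
#' factor_names(fm)
default_ckd_map <- function() {
  path <- system.file("extdata", "ckd_factors.json", package = "cohortflow",
                      mustWork = TRUE)
  parse_factor_map(path)
}

#' Serialize a factor map back to its JSON configuration
#'
#' Round-trips exactly: the original code specification strings are
#' preserved, so `parse_factor_map(write_factor_map(fm, f))` reproduces
#' `fm`.
#'
#' @param fm a `factor_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_factor_map <- function(fm, path) {
  stopifnot(inherits(fm, "factor_map"))
  doc <- list(
    index_factor = fm$index_factor,
    factors = lapply(fm$entries, function(e) {
      list(name = e$name, abbreviation = e$abbreviation, codes = e$codes)
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
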