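#' Deterministic colors for cohort labels
#'
#' Each unique comorbidity label is hashed onto a fixed 20-color
#' categorical palette, so a label keeps its color across regenerations
#' and across networks. Three colors are reserved: light orange for the
#' merged "others" group that carries the index factor, light green for
#' "others" without it, and neutral grey for the explicit no-factor group
#' "(none)". With more labels than palette entries collisions are
#' accepted.
#'
#' @param net a `cohort_network`.
#' @return data frame with columns `id`, `label`, `color` (hex strings).
#' @export
assign_colors <- function(net) {
  stopifnot(inherits(net, "cohort_network"))
  color <- character(nrow(net$nodes))
  for (i in seq_len(nrow(net$nodes))) {
    lab <- net$nodes$label[i]
    color[i] <- if (lab == "(none)") "#BDBDBD"
    else if (lab == "others") {
      if (net$nodes$contains_index[i]) "#FDBF6F" else "#B2DF8A"
    } else .palette20[(.label_hash(lab) %% 20L) + 1L]
  }
  data.frame(id = net$nodes$id, label = net$nodes$label, color = color,
             stringsAsFactors = FALSE)
}

# stable 31-polynomial string hash (platform- and locale-independent)
.label_hash <- function(label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 1000003
  as.integer(h)
}

.palette20 <- c(
  "#1F77B4", "#AEC7E8", "#FF7F0E", "#FFBB78", "#2CA02C",
  "#98DF8A", "#D62728", "#FF9896", "#9467BD", "#C5B0D5",
  "#8C564B", "#C49C94", "#E377C2", "#F7B6D2", "#7F7F7F",
  "#C7C7C7", "#BCBD22", "#DBDB8D", "#17BECF", "#9EDAE5")

#' Assemble a renderer-agnostic Sankey document
#'
#' Combines a network, its layout and an optional highlight overlay into
#' a plain-list document ready for [export_json()]: node positions and
#' heights (heights proportional to cardinality), per-label colors, link
#' sizes with the source cohort's entropy, gradient color pairs, z-order
#' indices and, when given, per-node/per-link highlighted sizes.
#'
#' @param net a `cohort_network`.
#' @param layout a `sankey_layout` computed for `net`.
#' @param highlight optional `cohort_highlight`.
#' @return a list of class `sankey_doc`.
#' @export
sankey_doc <- function(net, layout, highlight = NULL) {
  stopifnot(inherits(net, "cohort_network"), inherits(layout, "sankey_layout"))
  cols <- assign_colors(net)
  colmap <- stats::setNames(cols$color, cols$id)
  ent <- stats::setNames(net$nodes$entropy, net$nodes$id)
  zmap <- stats::setNames(seq_along(layout$z) - 1L, layout$z)
  ln <- layout$nodes
  nodes <- lapply(order(ln$window, ln$order), function(i) {
    id <- ln$id[i]
    list(id = id, window = ln$window[i],
         label = net$nodes$label[net$nodes$id == id],
         size = ln$height[i],
         x = ln$x[i], top = signif(ln$top[i], 6),
         color = unname(colmap[id]))
  })
  e <- net$edges
  links <- lapply(seq_len(nrow(e)), function(i) {
    list(id = e$id[i], source = e$source[i], target = e$target[i],
         size = e$cardinality[i],
         probability = signif(e$probability[i], 6),
         entropy = if (is.na(ent[e$source[i]])) NULL
                   else signif(unname(ent[e$source[i]]), 6),
         color = list(unname(colmap[e$source[i]]), unname(colmap[e$target[i]])),
         z = unname(zmap[e$id[i]]))
  })
  doc <- list(
    meta = list(generator = "cohortflow",
                entropy_mode = net$entropy_mode,
                filter_threshold = net$filter_threshold %||% NULL,
                crossings = as.list(layout$crossings)),
    nodes = nodes, links = links)
  if (!is.null(highlight)) {
    doc$highlight <- list(
      n_patients = length(highlight$patients),
      nodes = stats::setNames(as.list(highlight$nodes$highlighted),
                              highlight$nodes$id),
      links = stats::setNames(as.list(highlight$edges$highlighted),
                              highlight$edges$id))
  }
  structure(doc, class = "sankey_doc")
}

#' Validate a Sankey document's structural invariants
#'
#' Checks that link endpoints reference existing nodes, z-indices form a
#' permutation, inflow never exceeds node size, and highlight overlays
#' never exceed what they overlay. Used as an internal bug guard before
#' writing; a violation is an error.
#'
#' @param doc a `sankey_doc`.
#' @return `TRUE`, invisibly.
#' @export
validate_sankey <- function(doc) {
  ids <- vapply(doc$nodes, `[[`, "", "id")
  stopifnot(!anyDuplicated(ids))
  sizes <- stats::setNames(vapply(doc$nodes, function(n) as.numeric(n$size), 0), ids)
  for (l in doc$links) {
    if (!l$source %in% ids || !l$target %in% ids) {
      stop("sankey document link references a missing node: ", l$id, call. = FALSE)
    }
  }
  z <- vapply(doc$links, function(l) as.integer(l$z), 0L)
  if (length(z) && !identical(sort(z), seq_along(z) - 1L)) {
    stop("sankey document z-indices are not a permutation", call. = FALSE)
  }
  for (id in ids) {
    inflow <- sum(vapply(doc$links, function(l)
      if (l$target == id) as.numeric(l$size) else 0, 0))
    if (inflow > sizes[id] + 1e-9) {
      stop("inflow exceeds node size at ", id, call. = FALSE)
    }
  }
  if (!is.null(doc$highlight)) {
    for (id in names(doc$highlight$nodes)) {
      if (doc$highlight$nodes[[id]] > sizes[id] + 1e-9) {
        stop("highlight exceeds node size at ", id, call. = FALSE)
      }
    }
    lsizes <- stats::setNames(vapply(doc$links, function(l) as.numeric(l$size), 0),
                              vapply(doc$links, `[[`, "", "id"))
    for (id in names(doc$highlight$links)) {
      if (doc$highlight$links[[id]] > lsizes[id] + 1e-9) {
        stop("highlight exceeds link size at ", id, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Write a Sankey document as JSON
#'
#' Output is byte-stable: identical inputs produce identical files (fixed
#' key order, floats at 6 significant digits). The document is validated
#' before writing.
#'
#' @param doc a `sankey_doc` (or the `net`/`layout` pair via
#'   [sankey_doc()] first).
#' @param path output path (conventionally `*.sankey.json`).
#' @return `path`, invisibly.
#' @export
export_json <- function(doc, path) {
  stopifnot(inherits(doc, "sankey_doc"))
  validate_sankey(doc)
  json <- jsonlite::toJSON(unclass(doc), auto_unbox = TRUE, null = "null",
                           digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname export_json
#' @export
read_sankey <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  structure(doc, class = "sankey_doc")
}

#' Render a Sankey document to a standalone HTML file
#'
#' A single self-contained file: an SVG drawing computed from the
#' document (node bands, gradient ribbons in z-order, labels, hover
#' tooltips with label, size and source entropy) plus the document itself
#' embedded as JSON. Highlight overlays are drawn as red regions scaled to
#' the highlighted counts. No external resources are referenced, so the
#' file renders offline.
#'
#' @param doc a `sankey_doc`.
#' @param path output path.
#' @param width,height canvas size in pixels.
#' @return `path`, invisibly.
#' @export
export_html <- function(doc, path, width = 960, height = 600) {
  stopifnot(inherits(doc, "sankey_doc"))
  validate_sankey(doc)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  margin <- 40; node_w <- 18
  nx <- vapply(doc$nodes, function(n) as.numeric(n$x), 0)
  tops <- vapply(doc$nodes, function(n) as.numeric(n$top), 0)
  sz <- vapply(doc$nodes, function(n) as.numeric(n$size), 0)
  xmax <- max(nx); ymax <- max(tops + sz)
  sx <- (width - 2 * margin - node_w) / max(xmax, 1)
  sy <- (height - 2 * margin) / max(ymax, 1)
  px <- function(x) margin + x * sx
  py <- function(y) margin + y * sy

  ids <- vapply(doc$nodes, `[[`, "", "id")
  geom <- stats::setNames(lapply(doc$nodes, function(n) {
    list(x = px(as.numeric(n$x)), top = py(as.numeric(n$top)),
         h = as.numeric(n$size) * sy, color = n$color, label = n$label)
  }), ids)

  # per-node running offsets so ribbons tile each node face
  out_off <- stats::setNames(rep(0, length(ids)), ids)
  in_off <- stats::setNames(rep(0, length(ids)), ids)
  links <- doc$links[order(vapply(doc$links, function(l) as.integer(l$z), 0L))]
  defs <- character(); ribbons <- character()
  for (l in links) {
    s <- geom[[l$source]]; t <- geom[[l$target]]
    hs <- as.numeric(l$size) * sy
    y0 <- s$top + out_off[l$source]; y1 <- t$top + in_off[l$target]
    out_off[l$source] <- out_off[l$source] + hs
    in_off[l$target] <- in_off[l$target] + hs
    x0 <- s$x + node_w; x1 <- t$x
    xm <- (x0 + x1) / 2
    gid <- sprintf("g%04d", as.integer(l$z))
    defs <- c(defs, sprintf(
      paste0('<linearGradient id="%s" x1="0" x2="1" y1="0" y2="0">',
             '<stop offset="0" stop-color="%s"/>',
             '<stop offset="1" stop-color="%s"/></linearGradient>'),
      gid, l$color[[1]], l$color[[2]]))
    tip <- sprintf("%s -> %s | n=%s | p=%s%s",
                   geom[[l$source]]$label, geom[[l$target]]$label,
                   l$size, l$probability,
                   if (is.null(l$entropy)) "" else paste0(" | source entropy=", l$entropy))
    d <- sprintf(
      "M%.1f,%.1f C%.1f,%.1f %.1f,%.1f %.1f,%.1f L%.1f,%.1f C%.1f,%.1f %.1f,%.1f %.1f,%.1f Z",
      x0, y0, xm, y0, xm, y1, x1, y1,
      x1, y1 + hs, xm, y1 + hs, xm, y0 + hs, x0, y0 + hs)
    hl <- doc$highlight$links[[l$id]]
    ribbons <- c(ribbons, sprintf(
      '<path class="link" d="%s" fill="url(#%s)" fill-opacity="0.55"><title>%s</title></path>',
      d, gid, esc(tip)))
    if (!is.null(hl) && hl > 0) {
      hh <- as.numeric(hl) * sy
      dh <- sprintf(
        "M%.1f,%.1f C%.1f,%.1f %.1f,%.1f %.1f,%.1f L%.1f,%.1f C%.1f,%.1f %.1f,%.1f %.1f,%.1f Z",
        x0, y0, xm, y0, xm, y1, x1, y1,
        x1, y1 + hh, xm, y1 + hh, xm, y0 + hh, x0, y0 + hh)
      ribbons <- c(ribbons, sprintf(
        '<path class="highlight-link" d="%s" fill="#D62728" fill-opacity="0.8"/>', dh))
    }
  }

  rects <- character()
  for (id in ids) {
    g <- geom[[id]]
    n <- doc$nodes[[match(id, ids)]]
    tip <- sprintf("%s | n=%s", g$label, n$size)
    rects <- c(rects, sprintf(
      '<rect class="node" x="%.1f" y="%.1f" width="%d" height="%.2f" fill="%s" stroke="#333"><title>%s</title></rect>',
      g$x, g$top, node_w, max(g$h, 0.5), g$color, esc(tip)))
    hl <- doc$highlight$nodes[[id]]
    if (!is.null(hl) && hl > 0) {
      rects <- c(rects, sprintf(
        '<rect class="highlight-node" x="%.1f" y="%.1f" width="%d" height="%.2f" fill="#D62728"/>',
        g$x, g$top, node_w, as.numeric(hl) * sy))
    }
    rects <- c(rects, sprintf(
      '<text x="%.1f" y="%.1f" font-size="11" font-family="sans-serif">%s</text>',
      g$x + node_w + 4, g$top + max(g$h, 0.5) / 2 + 4, esc(g$label)))
  }

  json <- jsonlite::toJSON(unclass(doc), auto_unbox = TRUE, null = "null",
                           digits = NA)
  html <- c(
    "<!DOCTYPE html>",
    '<html><head><meta charset="utf-8"><title>Cohort trajectory Sankey</title>',
    "<style>body{font-family:sans-serif;margin:20px}.link:hover{fill-opacity:0.85}</style>",
    "</head><body>",
    "<h2>Cohort trajectory network</h2>",
    sprintf('<svg width="%d" height="%d"><defs>%s</defs>', width, height,
            paste(defs, collapse = "")),
    paste(ribbons, collapse = "\n"),
    paste(rects, collapse = "\n"),
    "</svg>",
    '<script type="application/json" id="sankey-doc">',
    json,
    "</script>",
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
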