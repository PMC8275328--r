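## Deterministic static rendering. Both views are first laid out as a
## scene graph (rect / bezier / band / circle / text primitives in canvas
## coordinates, y growing downward); the SVG backend serializes it with
## fixed number formatting, so identical inputs give byte-identical SVG.
## PNG/PDF re-draw the same scene on a grDevices device.

.QUAL_PALETTE <- c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3", "#a6d854",
                   "#ffd92f", "#e5c494", "#b3b3b3", "#1b9e77", "#d95f02",
                   "#7570b3", "#e7298a")
.RAMP_LOW <- "#deebf7"
.RAMP_HIGH <- "#3182bd"

#' Rendering parameters
#'
#' Time flows vertically top-to-bottom; patients are laid out
#' horizontally. All dimensions are pixels.
#'
#' @param cellWidth,cellHeight heatmap cell size.
#' @param cellGap horizontal gap between patient columns.
#' @param blockGap vertical space between blocks (where connections are
#'   drawn).
#' @param labelWidth left margin reserved for feature row labels.
#' @param margin outer canvas margin.
#' @param bandOpacity fill opacity of Sankey bands.
#' @param highlightColor stroke/fill for selected patients.
#' @param continuousGlyph `"boxplot"` or `"gradient"` nested summary for
#'   continuous features in grouped blocks.
#' @param pxPerDay vertical scale of the timeline view.
#' @return A named list of validated rendering parameters.
#' @export
renderSpec <- function(cellWidth = 14, cellHeight = 14, cellGap = 2,
                       blockGap = 40, labelWidth = 130, margin = 10,
                       bandOpacity = 0.6, highlightColor = "#e31a1c",
                       continuousGlyph = c("boxplot", "gradient"),
                       pxPerDay = 0.25) {
  continuousGlyph <- match.arg(continuousGlyph)
  dims <- c(cellWidth, cellHeight, blockGap, labelWidth, margin, pxPerDay)
  if (any(dims <= 0)) stop("all rendering dimensions must be positive")
  list(cellWidth = cellWidth, cellHeight = cellHeight, cellGap = cellGap,
       blockGap = blockGap, labelWidth = labelWidth, margin = margin,
       bandOpacity = bandOpacity, highlightColor = highlightColor,
       continuousGlyph = continuousGlyph, pxPerDay = pxPerDay)
}

## color per cell value; assignment order = domain order, reproducible
cellColors <- function(cellVector, values) {
  dt <- attr(cellVector, "datatype")
  dom <- attr(cellVector, "domain")
  if (identical(dt, "continuous")) {
    rng <- range(cellVector, na.rm = TRUE)
    span <- if (diff(rng) > 0) diff(rng) else 1
    ramp <- grDevices::colorRamp(c(.RAMP_LOW, .RAMP_HIGH))
    out <- rep("#bdbdbd", length(values))
    ok <- !is.na(values)
    if (any(ok)) {
      rgbm <- ramp((as.numeric(values[ok]) - rng[1]) / span)
      out[ok] <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3],
                                maxColorValue = 255)
    }
    out
  } else {
    pal <- stats::setNames(
      rep_len(.QUAL_PALETTE, length(dom)), as.character(dom))
    out <- unname(pal[as.character(values)])
    out[is.na(out)] <- "#bdbdbd"
    out
  }
}

groupColors <- function(cellVector) {
  dom <- as.character(attr(cellVector, "domain"))
  cols <- stats::setNames(rep_len(.QUAL_PALETTE, length(dom)), dom)
  c(cols, "(missing)" = "#bdbdbd")
}

el <- function(type, ...) c(list(type = type), list(...))
fmt <- function(x) sprintf("%.2f", x)

sceneToSVG <- function(scene, width, height) {
  body <- vapply(scene, function(e) {
    switch(e$type,
      rect = sprintf(
        '<rect class="%s" x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
        e$class, fmt(e$x), fmt(e$y), fmt(e$w), fmt(e$h), e$fill,
        if (!is.null(e$opacity)) sprintf(' fill-opacity="%s"',
                                         fmt(e$opacity)) else ""),
      bezier = sprintf(
        '<path class="%s" d="M %s %s C %s %s, %s %s, %s %s" stroke="%s" stroke-width="%s" fill="none"/>',
        e$class, fmt(e$x1), fmt(e$y1), fmt(e$x1), fmt((e$y1 + e$y2) / 2),
        fmt(e$x2), fmt((e$y1 + e$y2) / 2), fmt(e$x2), fmt(e$y2),
        e$stroke, fmt(e$width)),
      band = sprintf(
        paste0('<path class="%s" d="M %s %s C %s %s, %s %s, %s %s ',
               'L %s %s C %s %s, %s %s, %s %s Z" fill="%s" fill-opacity="%s"/>'),
        e$class,
        fmt(e$xl1), fmt(e$y1), fmt(e$xl1), fmt((e$y1 + e$y2) / 2),
        fmt(e$xl2), fmt((e$y1 + e$y2) / 2), fmt(e$xl2), fmt(e$y2),
        fmt(e$xr2), fmt(e$y2), fmt(e$xr2), fmt((e$y1 + e$y2) / 2),
        fmt(e$xr1), fmt((e$y1 + e$y2) / 2), fmt(e$xr1), fmt(e$y1),
        e$fill, fmt(e$opacity)),
      circle = sprintf(
        '<circle class="%s" cx="%s" cy="%s" r="%s" fill="%s"/>',
        e$class, fmt(e$cx), fmt(e$cy), fmt(e$r), e$fill),
      segment = sprintf(
        '<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
        e$class, fmt(e$x1), fmt(e$y1), fmt(e$x2), fmt(e$y2), e$stroke,
        fmt(e$width)),
      text = sprintf(
        '<text class="%s" x="%s" y="%s" font-size="%s" font-family="sans-serif"%s>%s</text>',
        e$class, fmt(e$x), fmt(e$y), fmt(e$size),
        if (!is.null(e$anchor)) sprintf(' text-anchor="%s"', e$anchor)
        else "", e$str),
      stop("unknown scene element: ", e$type))
  }, character(1))
  paste(c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                         'width="%s" height="%s" viewBox="0 0 %s %s">'),
                  fmt(width), fmt(height), fmt(width), fmt(height)),
          '<rect width="100%" height="100%" fill="white"/>',
          body, "</svg>"), collapse = "\n")
}

bezierPoints <- function(x1, y1, x2, y2, n = 24) {
  t <- seq(0, 1, length.out = n)
  cy <- (y1 + y2) / 2
  bx <- (1 - t)^3 * x1 + 3 * (1 - t)^2 * t * x1 +
    3 * (1 - t) * t^2 * x2 + t^3 * x2
  by <- (1 - t)^3 * y1 + 3 * (1 - t)^2 * t * cy +
    3 * (1 - t) * t^2 * cy + t^3 * y2
  list(x = bx, y = by)
}

drawSceneDevice <- function(scene, width, height) {
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, width), ylim = c(height, 0))
  graphics::rect(0, height, width, 0, col = "white", border = NA)
  for (e in scene) {
    switch(e$type,
      rect = graphics::rect(e$x, e$y + e$h, e$x + e$w, e$y,
        col = grDevices::adjustcolor(e$fill,
          alpha.f = if (!is.null(e$opacity)) e$opacity else 1),
        border = NA),
      bezier = {
        p <- bezierPoints(e$x1, e$y1, e$x2, e$y2)
        graphics::lines(p$x, p$y, col = e$stroke, lwd = e$width)
      },
      band = {
        l <- bezierPoints(e$xl1, e$y1, e$xl2, e$y2)
        r <- bezierPoints(e$xr1, e$y1, e$xr2, e$y2)
        graphics::polygon(c(l$x, rev(r$x)), c(l$y, rev(r$y)),
          col = grDevices::adjustcolor(e$fill, alpha.f = e$opacity),
          border = NA)
      },
      circle = graphics::symbols(e$cx, e$cy, circles = e$r, inches = FALSE,
                                 add = TRUE, fg = NA, bg = e$fill),
      segment = graphics::segments(e$x1, e$y1, e$x2, e$y2,
                                   col = e$stroke, lwd = e$width),
      text = graphics::text(e$x, e$y, e$str, cex = e$size / 12,
        adj = if (identical(e$anchor, "end")) 1 else 0))
  }
}

## ---- block view ----

columnX <- function(spec, i) spec$labelWidth + (i - 1) * (spec$cellWidth +
                                                            spec$cellGap)

## scene + per-block vertical extents for one grid
blockViewScene <- function(cohort, grid, spec, highlight = character(0)) {
  scene <- list()
  nP <- length(grid@patientIds)
  rowsOf <- function(b) b@rows
  drawn <- which(vapply(grid@blocks, function(b)
    length(b@rows) > 0 || b@kind == "timepoint", logical(1)))
  yTop <- numeric(length(grid@blocks))
  yBot <- numeric(length(grid@blocks))
  y <- spec$margin
  for (i in drawn) {
    b <- grid@blocks[[i]]
    h <- max(length(rowsOf(b)), 1) * spec$cellHeight
    yTop[i] <- y
    yBot[i] <- y + h
    y <- y + h + spec$blockGap
  }
  width <- spec$labelWidth +
    nP * (spec$cellWidth + spec$cellGap) - spec$cellGap + spec$margin
  height <- y - spec$blockGap + spec$margin

  ## connections first so blocks draw on top
  fsets <- flowSets(grid)
  if (length(highlight))
    fsets <- highlightSelection(grid, fsets, highlight)$flowsets
  for (fs in fsets)
    scene <- c(scene, flowScene(grid, fs, spec, yBot, yTop, highlight))

  for (i in drawn) {
    b <- grid@blocks[[i]]
    scene <- c(scene,
               if (b@grouped) groupedBlockScene(b, spec, yTop[i])
               else heatmapScene(b, spec, yTop[i], highlight))
  }
  list(scene = scene, width = width, height = height,
       yTop = yTop, yBot = yBot)
}

heatmapScene <- function(b, spec, y0, highlight) {
  out <- list()
  ord <- b@order
  for (r in seq_along(b@rows)) {
    fid <- b@rows[r]
    cv <- b@cells[[fid]]
    cols <- cellColors(cv, cv[ord])
    y <- y0 + (r - 1) * spec$cellHeight
    out[[length(out) + 1L]] <-
      el("text", class = "label", x = spec$labelWidth - 6,
         y = y + spec$cellHeight * 0.75, size = 10, anchor = "end",
         str = fid)
    for (i in seq_along(ord)) {
      p <- ord[i]
      x <- columnX(spec, i)
      if (b@gap[[p]]) {
        out[[length(out) + 1L]] <-
          el("rect", class = "gapcell", x = x, y = y,
             w = spec$cellWidth, h = spec$cellHeight - 1, fill = "#f5f5f5")
        out[[length(out) + 1L]] <-
          el("segment", class = "gaphatch", x1 = x, y1 = y +
               spec$cellHeight - 1, x2 = x + spec$cellWidth, y2 = y,
             stroke = "#d9d9d9", width = 1)
      } else {
        out[[length(out) + 1L]] <-
          el("rect", class = "cell", x = x, y = y,
             w = spec$cellWidth, h = spec$cellHeight - 1, fill = cols[i])
      }
    }
  }
  ## selection ticks above the block
  for (i in seq_along(ord))
    if (ord[i] %in% highlight)
      out[[length(out) + 1L]] <-
        el("rect", class = "selmark", x = columnX(spec, i), y = y0 - 4,
           w = spec$cellWidth, h = 3, fill = spec$highlightColor)
  out
}

## horizontal span of each group in a grouped block
groupSpans <- function(b, spec) {
  gs <- b@grouping@groups
  sizes <- vapply(gs, function(g) length(g$patients), integer(1))
  unit <- spec$cellWidth + spec$cellGap
  x <- spec$labelWidth
  spans <- list()
  for (i in seq_along(gs)) {
    w <- sizes[i] * unit - spec$cellGap
    spans[[gs[[i]]$value]] <- c(x, x + w)
    x <- x + sizes[i] * unit
  }
  spans
}

groupedBlockScene <- function(b, spec, y0) {
  out <- list()
  spans <- groupSpans(b, spec)
  cols <- groupColors(b@cells[[b@primaryFeature]])
  rows <- c(b@primaryFeature, setdiff(b@rows, b@primaryFeature))
  for (r in seq_along(rows)) {
    fid <- rows[r]
    y <- y0 + (r - 1) * spec$cellHeight
    out[[length(out) + 1L]] <-
      el("text", class = "label", x = spec$labelWidth - 6,
         y = y + spec$cellHeight * 0.75, size = 10, anchor = "end",
         str = fid)
    for (g in b@grouping@groups) {
      sp <- spans[[g$value]]
      if (fid == b@primaryFeature) {
        out[[length(out) + 1L]] <-
          el("rect", class = "grouprect", x = sp[1], y = y,
             w = sp[2] - sp[1], h = spec$cellHeight - 1,
             fill = unname(cols[g$value]))
        next
      }
      ns <- b@grouping@nestedSummaries[[g$value]][[fid]]
      if (ns$type == "categorical") {
        ncols <- groupColors(b@cells[[fid]])
        total <- sum(ns$counts) + ns$missing
        x <- sp[1]
        segs <- c(ns$counts, if (ns$missing) c("(missing)" = ns$missing))
        for (val in names(segs)) {
          w <- (sp[2] - sp[1]) * segs[[val]] / total
          out[[length(out) + 1L]] <-
            el("rect", class = "nestedseg", x = x, y = y, w = w,
               h = spec$cellHeight - 1,
               fill = unname(ncols[val]))
          x <- x + w
        }
      } else if (spec$continuousGlyph == "boxplot") {
        out <- c(out, boxplotGlyph(ns, b@cells[[fid]], sp, y, spec))
      } else {
        out <- c(out, gradientGlyph(ns, b@cells[[fid]], sp, y, spec))
      }
    }
  }
  out
}

boxplotGlyph <- function(ns, cellVector, sp, y, spec) {
  s <- ns$summary
  if (anyNA(s)) return(list())
  rng <- range(cellVector, na.rm = TRUE)
  span <- if (diff(rng) > 0) diff(rng) else 1
  px <- function(v) sp[1] + (v - rng[1]) / span * (sp[2] - sp[1])
  mid <- y + (spec$cellHeight - 1) / 2
  list(
    el("segment", class = "boxplot", x1 = px(s[["min"]]), y1 = mid,
       x2 = px(s[["max"]]), y2 = mid, stroke = "#636363", width = 1),
    el("rect", class = "boxplot", x = px(s[["q1"]]), y = y + 2,
       w = max(px(s[["q3"]]) - px(s[["q1"]]), 0.5),
       h = spec$cellHeight - 5, fill = "#9ecae1"),
    el("segment", class = "boxplot", x1 = px(s[["median"]]), y1 = y + 1,
       x2 = px(s[["median"]]), y2 = y + spec$cellHeight - 2,
       stroke = "#08519c", width = 1.5))
}

gradientGlyph <- function(ns, cellVector, sp, y, spec) {
  vals <- sort(ns$values[!is.na(ns$values)])
  if (!length(vals)) return(list())
  cols <- cellColors(cellVector, vals)
  w <- (sp[2] - sp[1]) / length(vals)
  lapply(seq_along(vals), function(i)
    el("rect", class = "gradientseg", x = sp[1] + (i - 1) * w, y = y,
       w = w, h = spec$cellHeight - 1, fill = cols[i]))
}

flowScene <- function(grid, fs, spec, yBot, yTop, highlight) {
  A <- grid@blocks[[fs@between[1]]]
  B <- grid@blocks[[fs@between[2]]]
  y1 <- yBot[fs@between[1]]
  y2 <- yTop[fs@between[2]]
  out <- list()
  colX <- function(b, p) {
    i <- match(p, b@order)
    columnX(spec, i) + spec$cellWidth / 2
  }
  if (fs@mode == "flows") {
    spansA <- groupSpans(A, spec)
    spansB <- groupSpans(B, spec)
    colsA <- groupColors(A@cells[[A@primaryFeature]])
    colsB <- groupColors(B@cells[[B@primaryFeature]])
    unitA <- function(g) diff(spansA[[g]]) /
      length(A@grouping@groups[[match(g, vapply(A@grouping@groups, `[[`,
        character(1), "value"))]]$patients)
    offA <- stats::setNames(vapply(names(spansA), function(g)
      spansA[[g]][1], numeric(1)), names(spansA))
    offB <- stats::setNames(vapply(names(spansB), function(g)
      spansB[[g]][1], numeric(1)), names(spansB))
    ## source-side spans in listed order (target-group-major per source);
    ## target-side allocation ordered by source group order
    srcSpan <- vector("list", length(fs@flows))
    for (k in seq_along(fs@flows)) {
      fl <- fs@flows[[k]]
      w <- length(fl$patients) * unitA(fl$source)
      srcSpan[[k]] <- c(offA[[fl$source]], offA[[fl$source]] + w)
      offA[[fl$source]] <- offA[[fl$source]] + w
    }
    tgtSpan <- vector("list", length(fs@flows))
    ordB <- vapply(B@grouping@groups, `[[`, character(1), "value")
    for (g in ordB) {
      unitB <- diff(spansB[[g]]) /
        length(B@grouping@groups[[match(g, ordB)]]$patients)
      for (k in seq_along(fs@flows)) {
        fl <- fs@flows[[k]]
        if (fl$target != g) next
        w <- length(fl$patients) * unitB
        tgtSpan[[k]] <- c(offB[[g]], offB[[g]] + w)
        offB[[g]] <- offB[[g]] + w
      }
    }
    for (k in seq_along(fs@flows)) {
      fl <- fs@flows[[k]]
      sel <- if (!is.null(fl$selectedCount)) fl$selectedCount else 0L
      out[[length(out) + 1L]] <-
        el("band", class = "band",
           xl1 = srcSpan[[k]][1], xr1 = srcSpan[[k]][2], y1 = y1 + 4,
           xl2 = tgtSpan[[k]][1], xr2 = tgtSpan[[k]][2], y2 = y2 - 4,
           fill = if (sel > 0) spec$highlightColor
                  else unname(colsA[fl$source]),
           opacity = spec$bandOpacity)
      ## primary-feature proxy colors repeated at both band ends
      out[[length(out) + 1L]] <-
        el("rect", class = "proxy", x = srcSpan[[k]][1], y = y1,
           w = srcSpan[[k]][2] - srcSpan[[k]][1], h = 4,
           fill = unname(colsA[fl$source]))
      out[[length(out) + 1L]] <-
        el("rect", class = "proxy", x = tgtSpan[[k]][1], y = y2 - 4,
           w = tgtSpan[[k]][2] - tgtSpan[[k]][1], h = 4,
           fill = unname(colsB[fl$target]))
    }
  } else if (fs@mode == "lines") {
    for (i in seq_len(nrow(fs@lines))) {
      p <- fs@lines$patient_id[i]
      selected <- p %in% highlight
      out[[length(out) + 1L]] <-
        el("bezier", class = "line", x1 = colX(A, p), y1 = y1,
           x2 = colX(B, p), y2 = y2,
           stroke = if (selected) spec$highlightColor else "#969696",
           width = if (selected) 2 else 1)
    }
  } else { # mixed: fan lines between a group segment and a column
    spans <- if (A@grouped) groupSpans(A, spec) else NULL
    spansB2 <- if (B@grouped) groupSpans(B, spec) else NULL
    for (i in seq_len(nrow(fs@lines))) {
      p <- fs@lines$patient_id[i]
      selected <- p %in% highlight
      xs <- if (A@grouped) mean(spans[[fs@lines$source[i]]])
            else colX(A, p)
      xt <- if (B@grouped) mean(spansB2[[fs@lines$target[i]]])
            else colX(B, p)
      out[[length(out) + 1L]] <-
        el("bezier", class = "line", x1 = xs, y1 = y1, x2 = xt, y2 = y2,
           stroke = if (selected) spec$highlightColor else "#969696",
           width = if (selected) 2 else 1)
    }
  }
  out
}

#' Render the block view
#'
#' Ungrouped blocks draw as heatmaps (one row per feature, one column
#' per patient in block order; gaps hatched, missing values grey),
#' grouped blocks as proportional bars with nested summaries, and
#' connections as curved per-patient lines or Sankey bands with the
#' primary feature's colors repeated as proxies at both band ends.
#' Output is byte-identical for identical inputs.
#'
#' @param cohort a [Cohort-class].
#' @param grid a [BlockGrid-class].
#' @param spec a [renderSpec()] list.
#' @param highlight selected patient ids to highlight.
#' @return `list(svg=, scene=, width=, height=)`.
#' @export
renderBlockView <- function(cohort, grid, spec = renderSpec(),
                            highlight = character(0)) {
  bv <- blockViewScene(cohort, grid, spec, highlight)
  list(svg = sceneToSVG(bv$scene, bv$width, bv$height),
       scene = bv$scene, width = bv$width, height = bv$height)
}

#' Render the timeline view
#'
#' One vertical track per patient: sample markers at date-proportional
#' positions colored by the display feature, event bars whose length
#' encodes duration (zero-duration/open-ended events draw as fixed-size
#' point markers), event types color-coded.
#'
#' @param cohort a [Cohort-class].
#' @param featureId sample-level feature coloring the sample markers.
#' @param spec a [renderSpec()] list.
#' @param highlight selected patient ids.
#' @return `list(svg=, scene=, width=, height=)`.
#' @export
renderTimelineView <- function(cohort, featureId, spec = renderSpec(),
                               highlight = character(0)) {
  series <- timelineSeries(cohort, featureId)
  f <- getFeature(cohort, featureId)
  trackW <- 3 * spec$cellWidth
  maxDate <- max(1, vapply(series, function(s)
    max(c(s$samples$date, s$events$stop, 0)), numeric(1)))
  width <- spec$margin + length(series) * trackW + spec$margin
  height <- spec$margin + 20 + maxDate * spec$pxPerDay + spec$margin
  evTypes <- sortStrings(unique(unlist(lapply(series, function(s)
    s$events$event_type))))
  evCols <- stats::setNames(rep_len(rev(.QUAL_PALETTE), length(evTypes)),
                            evTypes)
  cellsLike <- f@values  # for color mapping
  attr(cellsLike, "datatype") <- f@datatype
  attr(cellsLike, "domain") <- f@domain
  scene <- list()
  y0 <- spec$margin + 20
  for (i in seq_along(series)) {
    p <- names(series)[i]
    s <- series[[i]]
    x <- spec$margin + (i - 1) * trackW + trackW / 2
    selected <- p %in% highlight
    scene[[length(scene) + 1L]] <-
      el("segment", class = "track", x1 = x, y1 = y0,
         x2 = x, y2 = y0 + maxDate * spec$pxPerDay,
         stroke = if (selected) spec$highlightColor else "#d9d9d9",
         width = if (selected) 2 else 1)
    scene[[length(scene) + 1L]] <-
      el("text", class = "label", x = x, y = spec$margin + 10, size = 9,
         anchor = "end", str = p)
    if (nrow(s$events)) for (j in seq_len(nrow(s$events))) {
      ev <- s$events[j, ]
      if (ev$point) {
        scene[[length(scene) + 1L]] <-
          el("rect", class = "eventpoint", x = x + 4,
             y = y0 + ev$start * spec$pxPerDay - 2, w = 6, h = 4,
             fill = unname(evCols[ev$event_type]))
      } else {
        scene[[length(scene) + 1L]] <-
          el("rect", class = "eventbar", x = x + 4,
             y = y0 + ev$start * spec$pxPerDay, w = 6,
             h = ev$duration * spec$pxPerDay,
             fill = unname(evCols[ev$event_type]))
      }
    }
    cols <- cellColors(cellsLike, s$samples$value)
    for (j in seq_len(nrow(s$samples)))
      scene[[length(scene) + 1L]] <-
        el("circle", class = "samplemark", cx = x,
           cy = y0 + s$samples$date[j] * spec$pxPerDay,
           r = spec$cellWidth / 3, fill = cols[j])
  }
  list(svg = sceneToSVG(scene, width, height), scene = scene,
       width = width, height = height)
}

#' Export a rendered view
#'
#' Writes the figure in the requested format plus, when `cohort` and
#' `grid` are supplied, a JSON metadata sidecar (`<path>.meta.json`)
#' describing the displayed features, transform history and block
#' states.
#'
#' @param view result of [renderBlockView()] / [renderTimelineView()].
#' @param path output file path.
#' @param format `"svg"`, `"png"` or `"pdf"`.
#' @param cohort,grid optional, for the metadata sidecar.
#' @param scoreSettings optional score settings for the sidecar.
#' @return Written file paths, invisibly.
#' @export
exportFigure <- function(view, path, format = c("svg", "png", "pdf"),
                         cohort = NULL, grid = NULL,
                         scoreSettings = NULL) {
  if (!format[1] %in% c("svg", "png", "pdf"))
    stop("unsupported format: ", format[1])
  format <- match.arg(format)
  if (format == "svg") {
    writeLines(view$svg, path)
  } else if (format == "png") {
    grDevices::png(path, width = ceiling(view$width),
                   height = ceiling(view$height))
    drawSceneDevice(view$scene, view$width, view$height)
    grDevices::dev.off()
  } else {
    grDevices::pdf(path, width = view$width / 72, height = view$height / 72)
    drawSceneDevice(view$scene, view$width, view$height)
    grDevices::dev.off()
  }
  files <- path
  if (!is.null(cohort) && !is.null(grid)) {
    metaPath <- paste0(path, ".meta.json")
    exportViewMetadata(cohort, grid, metaPath, scoreSettings)
    files <- c(files, metaPath)
  }
  invisible(files)
}
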