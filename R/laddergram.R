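#' Build a Lewis ladder-diagram layout from an activation table
#'
#' Lanes are ordered top-to-bottom along the anterograde direction: the
#' upper row `SN` to `HB6`, with the slow-pathway lanes inset between the
#' `AM3` and `PB` levels and `AM*` drawn beside the atrial entrance.  Every
#' activation appears exactly once.  Conduction segments connect each
#' activation to the neighbouring-cell activation that caused it (the
#' closest preceding activation of a topologically adjacent cell within
#' `max_delay`); activations with no such cause are wave sources (stimuli or
#' pacemaker firings).  Fast-pathway segments are red, slow-pathway
#' segments blue, and segments in the `PB`/`HB` lanes take the colour of
#' the beat's leading pathway.  An annihilation marker is placed, at the
#' midpoint in time, on every junction where two opposing wavefronts met
#' (both cells activated closely in time, neither causing the other).
#'
#' @param tab an `activation_table`.
#' @param topo the `avn_topology` of the run.
#' @param schedule optional `avn_schedule`; adds stimulus arrow markers.
#' @param max_delay largest credible per-junction conduction delay, ms
#'   (default 60).
#' @param ann_window wavefront-meeting window for annihilation markers, ms
#'   (default 25).
#' @return an object of class `laddergram_layout`.
#' @export
build_laddergram <- function(tab, topo, schedule = NULL, max_delay = 60,
                             ann_window = 25) {
  labs <- avn_cell_labels()
  y_up <- stats::setNames(seq_along(labs$upper) - 1, labs$upper)
  y_am3 <- y_up[["AM3"]]; y_pb <- y_up[["PB"]]
  y_sp <- stats::setNames(y_am3 + (y_pb - y_am3) * (1:10) / 11,
                          paste0("SP", 1:10))
  lane_y <- c(y_up, y_sp, "AM*" = unname(y_up[["AM3"]]) - 0.45)
  lanes <- data.frame(cell = names(lane_y), y = unname(lane_y),
                      pacemaker = names(lane_y) %in%
                        topo$cells$label[topo$cells$a1 < 0],
                      stringsAsFactors = FALSE)

  acts <- as.data.frame(tab)
  lead <- assign_leading_pathway(tab)
  sp_cells <- paste0("SP", 1:10)
  fp_cells <- paste0("FP", 1:8)
  hb_cells <- c("PB", paste0("HB", 1:6))
  col_of <- function(cell, t) {
    if (cell %in% fp_cells) return("red")
    if (cell %in% sp_cells) return("blue")
    if (cell %in% hb_cells) {
      p <- pathway_at(lead, t)
      return(switch(p, FP = "red", SP = "blue", "black"))
    }
    "black"
  }

  jn <- topo$junctions[topo$junctions$d > 0, , drop = FALSE]
  nbrs <- split(c(jn$to, jn$from), c(jn$from, jn$to))

  n <- nrow(acts)
  cause <- rep(NA_integer_, n)
  if (n > 0) {
    for (q in seq_len(n)) {
      c_q <- acts$cell[q]; t_q <- acts$time[q]
      nb <- nbrs[[c_q]]
      if (is.null(nb)) next
      cand <- which(acts$cell %in% nb & acts$time < t_q &
                      acts$time >= t_q - max_delay)
      if (length(cand)) cause[q] <- cand[which.max(acts$time[cand])]
    }
  }
  segs <- NULL
  if (any(!is.na(cause))) {
    qi <- which(!is.na(cause))
    segs <- data.frame(
      t0 = acts$time[cause[qi]], y0 = lane_y[acts$cell[cause[qi]]],
      t1 = acts$time[qi], y1 = lane_y[acts$cell[qi]],
      color = vapply(qi, function(q) col_of(acts$cell[q], acts$time[q]),
                     character(1)),
      stringsAsFactors = FALSE)
    rownames(segs) <- NULL
  } else {
    segs <- data.frame(t0 = numeric(0), y0 = numeric(0), t1 = numeric(0),
                       y1 = numeric(0), color = character(0),
                       stringsAsFactors = FALSE)
  }

  # annihilations: adjacent cells activated closely, neither caused by the
  # other, both activations caused from their opposite sides
  ann <- list()
  for (r in seq_len(nrow(jn))) {
    a <- jn$from[r]; b <- jn$to[r]
    ia <- which(acts$cell == a)
    ib <- which(acts$cell == b)
    for (q in ia) {
      close_b <- ib[abs(acts$time[ib] - acts$time[q]) <= ann_window]
      for (p in close_b) {
        linked <- (!is.na(cause[p]) && cause[p] == q) ||
          (!is.na(cause[q]) && cause[q] == p)
        sourced <- !is.na(cause[p]) && !is.na(cause[q])
        if (!linked && sourced) {
          ann[[length(ann) + 1]] <-
            data.frame(t = (acts$time[q] + acts$time[p]) / 2,
                       y = (lane_y[[a]] + lane_y[[b]]) / 2)
        }
      }
    }
  }
  ann <- if (length(ann)) unique(do.call(rbind, ann))
         else data.frame(t = numeric(0), y = numeric(0))

  stim <- if (!is.null(schedule) && nrow(schedule$impulses) > 0) {
    data.frame(t = schedule$impulses$onset,
               y = lane_y[schedule$impulses$target],
               stringsAsFactors = FALSE)
  } else data.frame(t = numeric(0), y = numeric(0))

  points <- if (n > 0)
    data.frame(t = acts$time, y = lane_y[acts$cell],
               pacemaker = acts$cell %in% lanes$cell[lanes$pacemaker],
               stringsAsFactors = FALSE)
  else data.frame(t = numeric(0), y = numeric(0), pacemaker = logical(0))

  structure(list(lanes = lanes, points = points, segments = segs,
                 annihilations = ann, stimuli = stim,
                 t_range = if (n > 0) range(acts$time) else c(0, 1)),
            class = "laddergram_layout")
}

#' @export
print.laddergram_layout <- function(x, ...) {
  cat(sprintf(paste0("<laddergram_layout> %d activations, %d segments, ",
                     "%d annihilations, t = [%.1f, %.1f] ms\n"),
              nrow(x$points), nrow(x$segments), nrow(x$annihilations),
              x$t_range[1], x$t_range[2]))
  invisible(x)
}

svg_num <- function(x) formatC(x, format = "f", digits = 2)

#' Render a laddergram to SVG or PNG
#'
#' The SVG writer is deterministic: rendering the same layout twice
#' produces byte-identical files.
#'
#' @param layout a `laddergram_layout`.
#' @param path output file path.
#' @param format `"svg"` (default) or `"png"`.
#' @param px_per_ms horizontal scale (default 0.75).
#' @param px_per_lane vertical lane spacing (default 16).
#' @return `path`, invisibly.
#' @export
render_laddergram <- function(layout, path, format = c("svg", "png"),
                              px_per_ms = 0.75, px_per_lane = 16) {
  format <- match.arg(format)
  if (format == "png") {
    grDevices::png(path, width = 1200, height = 500)
    on.exit(grDevices::dev.off())
    plot(layout)
    return(invisible(path))
  }
  t0 <- layout$t_range[1]
  margin_l <- 46; margin_t <- 12
  tx <- function(t) margin_l + (t - t0) * px_per_ms
  ty <- function(y) margin_t + y * px_per_lane
  w <- tx(layout$t_range[2]) + 14
  h <- ty(max(layout$lanes$y)) + 22
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%s" height="%s" viewBox="0 0 %s %s">'),
                   svg_num(w), svg_num(h), svg_num(w), svg_num(h)),
           '<rect width="100%" height="100%" fill="white"/>')
  for (r in seq_len(nrow(layout$lanes))) {
    y <- ty(layout$lanes$y[r])
    out <- c(out,
             sprintf(paste0('<line x1="%s" y1="%s" x2="%s" y2="%s" ',
                            'stroke="#dddddd" stroke-width="0.6"/>'),
                     svg_num(margin_l), svg_num(y), svg_num(w - 6),
                     svg_num(y)),
             sprintf(paste0('<text x="2" y="%s" font-size="8" ',
                            'font-family="sans-serif">%s</text>'),
                     svg_num(y + 2.5), layout$lanes$cell[r]))
  }
  sg <- layout$segments
  for (r in seq_len(nrow(sg)))
    out <- c(out, sprintf(paste0('<line x1="%s" y1="%s" x2="%s" y2="%s" ',
                                 'stroke="%s" stroke-width="1.2"/>'),
                          svg_num(tx(sg$t0[r])), svg_num(ty(sg$y0[r])),
                          svg_num(tx(sg$t1[r])), svg_num(ty(sg$y1[r])),
                          sg$color[r]))
  pt <- layout$points
  for (r in seq_len(nrow(pt)))
    out <- c(out, sprintf(paste0('<circle cx="%s" cy="%s" r="%s" ',
                                 'fill="%s"/>'),
                          svg_num(tx(pt$t[r])), svg_num(ty(pt$y[r])),
                          if (pt$pacemaker[r]) "2.6" else "1.4",
                          if (pt$pacemaker[r]) "#555555" else "#222222"))
  an <- layout$annihilations
  for (r in seq_len(nrow(an))) {
    x <- tx(an$t[r]); y <- ty(an$y[r])
    out <- c(out,
             sprintf(paste0('<path d="M %s %s L %s %s M %s %s L %s %s" ',
                            'stroke="#777700" stroke-width="1.4"/>'),
                     svg_num(x - 3), svg_num(y - 3), svg_num(x + 3),
                     svg_num(y + 3), svg_num(x - 3), svg_num(y + 3),
                     svg_num(x + 3), svg_num(y - 3)))
  }
  st <- layout$stimuli
  for (r in seq_len(nrow(st))) {
    x <- tx(st$t[r]); y <- ty(st$y[r])
    out <- c(out,
             sprintf('<path d="M %s %s L %s %s L %s %s Z" fill="#006600"/>',
                     svg_num(x - 3), svg_num(y - 8), svg_num(x + 3),
                     svg_num(y - 8), svg_num(x), svg_num(y - 2)))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

#' @export
plot.laddergram_layout <- function(x, ...) {
  yr <- rev(range(x$lanes$y))
  graphics::plot(NA, xlim = x$t_range, ylim = yr + c(0.8, -0.8),
                 xlab = "time (ms)", ylab = "", yaxt = "n", bty = "n", ...)
  graphics::axis(2, at = x$lanes$y, labels = x$lanes$cell, las = 2,
                 cex.axis = 0.55, tick = FALSE)
  graphics::abline(h = x$lanes$y, col = "grey90", lwd = 0.6)
  sg <- x$segments
  if (nrow(sg))
    graphics::segments(sg$t0, sg$y0, sg$t1, sg$y1, col = sg$color,
                       lwd = 1.4)
  pt <- x$points
  if (nrow(pt))
    graphics::points(pt$t, pt$y, pch = 16,
                     cex = ifelse(pt$pacemaker, 0.8, 0.45),
                     col = "grey20")
  if (nrow(x$annihilations))
    graphics::points(x$annihilations$t, x$annihilations$y, pch = 4,
                     col = "darkgoldenrod3", cex = 1.1, lwd = 2)
  if (nrow(x$stimuli))
    graphics::points(x$stimuli$t, x$stimuli$y - 0.45, pch = 25,
                     bg = "darkgreen", col = "darkgreen", cex = 0.7)
  invisible(x)
}
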