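#' Cell labels of the two-row AV-node network
#'
#' The default network has 33 cells: an upper row of 22 cells (sinus node
#' `SN`, peripheral sinus node `PS1`-`PS3`, atrial muscle `AM1`-`AM3`, fast
#' pathway `FP1`-`FP8`, penetrating bundle `PB`, His bundle `HB1`-`HB6`) and
#' a lower row of 11 cells (slow pathway `SP1`-`SP10` plus the intermediate
#' atrial cell `AM*` used as the fibrillation/flutter pacing entry).
#'
#' @return named list with `upper`, `lower` and `all` character vectors.
#' @export
avn_cell_labels <- function() {
  upper <- c("SN", paste0("PS", 1:3), paste0("AM", 1:3), paste0("FP", 1:8),
             "PB", paste0("HB", 1:6))
  lower <- c(paste0("SP", 1:10), "AM*")
  list(upper = upper, lower = lower, all = c(upper, lower))
}

#' Subsidiary and primary pacemaker cells of the default network
#' @return character vector of cell labels.
#' @export
avn_pacemaker_labels <- function() {
  c("SN", "SP7", "SP8", "SP9", "SP10", "FP8", "PB")
}

#' Build a validated AV-node network topology
#'
#' Assembles the 33-cell two-row network from a configuration (per-cell
#' Aliev-Panfilov parameters plus a junction table with coupling coefficient
#' `d` and asymmetry `alpha`).  The upper row is a chain from `SN` to `HB6`
#' with open ends; the slow-pathway row attaches to the upper row through two
#' vertical junctions (`AM3`-`SP1` at the atrial end, `SP10`-`PB` at the
#' nodal end), and `AM*` attaches to `AM3`.
#'
#' Asymmetry convention: for every junction the `from` cell is the
#' anterograde-upstream side (closer to the atria) and `alpha` is applied to
#' the downstream cell, so `alpha < 1` accelerates anterograde and slows
#' retrograde conduction across that junction.
#'
#' @param config a configuration list as returned by [default_config()] or
#'   [read_avn_config()].
#' @return an object of class `avn_topology`.
#' @export
build_topology <- function(config = default_config()) {
  topo <- structure(list(cells = config$cells,
                         junctions = config$junctions,
                         ablation = "none",
                         entry = config$entry,
                         default_shape = TRUE),
                    class = "avn_topology")
  validate_topology(topo)
  topo
}

#' Assemble a free-form cell network
#'
#' Like [build_topology()] but without the 33-cell default-layout check;
#' useful for reduced test networks such as uniform cables.
#'
#' @param cells per-cell parameter data frame (columns `label`, `zone`,
#'   `k`, `a1`, `a2`, `mu1`, `mu2`, `eps0`, `ct`).
#' @param junctions junction data frame (columns `from`, `to`, `d`,
#'   `alpha`).
#' @param entry stimulus entry points (list with `antero`, `retro`, `af`).
#' @return an `avn_topology`.
#' @export
custom_topology <- function(cells, junctions,
                            entry = list(antero = cells$label[1],
                                         retro = cells$label[nrow(cells)],
                                         af = cells$label[1])) {
  rownames(cells) <- cells$label
  topo <- structure(list(cells = cells, junctions = junctions,
                         ablation = "none", entry = entry,
                         default_shape = FALSE),
                    class = "avn_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  cells <- topo$cells
  jn <- topo$junctions
  if (isTRUE(topo$default_shape)) {
    labs <- avn_cell_labels()
    missing <- setdiff(labs$all, cells$label)
    if (length(missing) > 0)
      stop("configuration is missing cell(s): ",
           paste(missing, collapse = ", "))
    extra <- setdiff(cells$label, labs$all)
    if (length(extra) > 0)
      stop("configuration has unknown cell(s): ",
           paste(extra, collapse = ", "))
  }
  if (anyDuplicated(cells$label))
    stop("duplicated cell label '", cells$label[duplicated(cells$label)][1],
         "'")
  num <- c("k", "a1", "a2", "mu1", "mu2", "eps0", "ct")
  for (col in num)
    if (any(!is.finite(cells[[col]])))
      stop("non-finite parameter '", col, "' for cell '",
           cells$label[which(!is.finite(cells[[col]]))[1]], "'")
  bad <- cells$label[cells$k <= 0 | cells$ct <= 0 | cells$eps0 <= 0 |
                       cells$mu1 < 0 | cells$mu2 <= 0]
  if (length(bad) > 0)
    stop("invalid cell parameters for '", bad[1], "'")
  if (!all(cells$zone %in% c("atrial", "his")))
    stop("unknown voltage-rescaling zone; use 'atrial' or 'his'")
  for (side in c("from", "to")) {
    unknown <- setdiff(jn[[side]], cells$label)
    if (length(unknown) > 0)
      stop("junction references unknown cell '", unknown[1], "'")
  }
  if (any(jn$d < 0))
    stop("negative coupling coefficient d on junction ",
         jn$from[which(jn$d < 0)[1]], "-", jn$to[which(jn$d < 0)[1]])
  if (any(jn$alpha <= 0))
    stop("non-positive asymmetry alpha on junction ",
         jn$from[which(jn$alpha <= 0)[1]], "-",
         jn$to[which(jn$alpha <= 0)[1]])
  pm <- sort(cells$label[cells$a1 < 0])
  expected <- sort(avn_pacemaker_labels())
  if (isTRUE(topo$default_shape) &&
      topo$ablation == "none" && !identical(pm, expected) &&
      !identical(sort(c(pm, "SN")), expected))
    warning("pacemaking cells are ", paste(pm, collapse = ", "),
            " (default network expects ", paste(expected, collapse = ", "),
            ")")
  invisible(topo)
}

#' @export
print.avn_topology <- function(x, ...) {
  cat(sprintf("<avn_topology> %d cells, %d junctions, ablation: %s\n",
              nrow(x$cells), nrow(x$junctions), x$ablation))
  pm <- x$cells$label[x$cells$a1 < 0]
  cat("  pacemaking:", paste(pm, collapse = ", "), "\n")
  invisible(x)
}

#' Coupling currents for a vector of cell potentials
#'
#' Evaluates the discrete diffusion current for every cell.  A junction
#' between upstream cell `i` and downstream cell `j` with coefficient `d`
#' and asymmetry `alpha` contributes `d * (-u_i + alpha * u_j)` to cell `i`
#' and `d * (u_i - alpha * u_j)` to cell `j`; the two contributions cancel
#' pairwise, so the total coupling current over the network is always zero.
#' With `alpha = 1` this is plain discrete diffusion.
#'
#' @param u numeric vector of potentials, in the order of `topo$cells`, or
#'   named by cell label.
#' @param topo an `avn_topology`.
#' @return numeric vector of per-cell coupling currents (1/s).
#' @export
coupling_currents <- function(u, topo) {
  cells <- topo$cells$label
  if (!is.null(names(u))) u <- u[cells]
  if (length(u) != length(cells)) stop("u must have one value per cell")
  names(u) <- cells
  if (any(!is.finite(u))) stop("non-finite potential")
  cur <- stats::setNames(numeric(length(cells)), cells)
  jn <- topo$junctions
  for (r in seq_len(nrow(jn))) {
    i <- jn$from[r]; j <- jn$to[r]
    t <- jn$d[r] * (u[[i]] - jn$alpha[r] * u[[j]])
    cur[[i]] <- cur[[i]] - t
    cur[[j]] <- cur[[j]] + t
  }
  cur
}

#' Sever one or both AV-node pathways
#'
#' Simulated catheter ablation: sets the coupling coefficient `d` to zero in
#' the middle of the named pathway(s) -- between `FP5` and `FP6` for the fast
#' pathway, between `SP6` and `SP7` for the slow pathway.  Cell states and
#' all other junctions are untouched.
#'
#' @param topo an `avn_topology`.
#' @param which `"FP"`, `"SP"` or `"both"`.
#' @return a modified copy of `topo`.
#' @export
apply_ablation <- function(topo, which = c("FP", "SP", "both")) {
  which <- match.arg(which)
  cut <- function(t, a, b) {
    r <- t$junctions$from == a & t$junctions$to == b
    if (!any(r)) stop("no junction ", a, "-", b, " in topology")
    t$junctions$d[r] <- 0
    t
  }
  if (which %in% c("FP", "both")) topo <- cut(topo, "FP5", "FP6")
  if (which %in% c("SP", "both")) topo <- cut(topo, "SP6", "SP7")
  topo$ablation <- if (topo$ablation == "none") which
                   else "both"
  topo
}

#' Render the sinus-node cell non-pacemaking
#'
#' Returns a copy of the topology in which the `SN` cell's thresholds are
#' set to a positive (quiescent excitable) value, leaving every junction and
#' all other cells unchanged.  Used to expose the subsidiary slow-pathway
#' pacemaker rhythm.
#'
#' @param topo an `avn_topology`.
#' @param a1 positive excitation threshold given to the silenced SN
#'   (default 0.15); `a2` is set to the same value.
#' @return a modified copy of `topo`.
#' @export
silence_sn <- function(topo, a1 = 0.15) {
  stopifnot(a1 > 0)
  r <- topo$cells$label == "SN"
  topo$cells$a1[r] <- a1
  topo$cells$a2[r] <- a1
  topo
}

#' Export the junction table
#'
#' @param topo an `avn_topology`.
#' @param path optional CSV path; when `NULL` the data frame is returned.
#' @return the junction table (columns `from`, `to`, `d`, `alpha`),
#'   invisibly when written to a file.
#' @export
junction_table <- function(topo, path = NULL) {
  jn <- topo$junctions[, c("from", "to", "d", "alpha")]
  if (!is.null(path)) {
    utils::write.csv(jn, path, row.names = FALSE, quote = FALSE)
    return(invisible(jn))
  }
  jn
}
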