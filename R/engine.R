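#' Solver options for the network integrator
#'
#' The engine is an adaptive explicit Runge-Kutta (2,3) pair (Bogacki-
#' Shampine) with proportional step control.  Integration is segmented at
#' every stimulus onset and offset so that no impulse can be skipped by the
#' adaptive stepping, and the solution is resampled onto a uniform output
#' grid by the method's cubic Hermite interpolant.
#'
#' @param rtol relative tolerance (default 1e-7).
#' @param atol absolute tolerance (default 1e-10).
#' @param dt_out output grid spacing in ms (default 0.1).
#' @param threshold upstroke activation threshold on `u` (default 0.25).
#' @param blanking per-cell refractory blanking window for activation
#'   detection, ms (default 20).
#' @return a `solver_options` list.
#' @export
solver_options <- function(rtol = 1e-7, atol = 1e-10, dt_out = 0.1,
                           threshold = 0.25, blanking = 20) {
  stopifnot(rtol > 0, atol > 0, dt_out > 0, blanking >= 0)
  structure(list(rtol = rtol, atol = atol, dt_out = dt_out,
                 threshold = threshold, blanking = blanking),
            class = "solver_options")
}

#' A single timed stimulus impulse
#'
#' @param target cell label receiving the current.
#' @param onset impulse start, ms.
#' @param duration impulse length, ms (default 1).
#' @param amplitude current amplitude in model units (default 280, about
#'   1.3x the excitation threshold of the default cells).
#' @return one-row data frame.
#' @export
stimulus_impulse <- function(target, onset, duration = 1, amplitude = 280) {
  stopifnot(onset >= 0, duration > 0, amplitude >= 0)
  data.frame(target = target, onset = onset, duration = duration,
             amplitude = amplitude, stringsAsFactors = FALSE)
}

#' A timed list of stimulus impulses
#'
#' @param impulses data frame with columns `target`, `onset`, `duration`,
#'   `amplitude` (rows may be built with [stimulus_impulse()] and `rbind`).
#'   An empty or `NULL` value gives a stimulus-free schedule.
#' @param horizon total simulated time, ms; must reach past the last
#'   impulse offset.
#' @return an object of class `avn_schedule`.
#' @export
stimulus_schedule <- function(impulses = NULL, horizon) {
  if (is.null(impulses) || nrow(impulses) == 0) {
    impulses <- data.frame(target = character(0), onset = numeric(0),
                           duration = numeric(0), amplitude = numeric(0),
                           stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("target", "onset", "duration", "amplitude") %in%
                    names(impulses)))
    if (any(impulses$onset < 0)) stop("impulse onsets must be >= 0")
    if (any(impulses$duration <= 0)) stop("impulse durations must be > 0")
    if (any(impulses$amplitude < 0)) stop("impulse amplitudes must be >= 0")
    impulses <- impulses[order(impulses$onset), , drop = FALSE]
    rownames(impulses) <- NULL
  }
  if (nrow(impulses) > 0 &&
      horizon < max(impulses$onset + impulses$duration))
    stop("horizon must extend past the last impulse offset")
  structure(list(impulses = impulses, horizon = horizon),
            class = "avn_schedule")
}

#' @export
print.avn_schedule <- function(x, ...) {
  cat(sprintf("<avn_schedule> %d impulse(s), horizon %.1f ms\n",
              nrow(x$impulses), x$horizon))
  if (nrow(x$impulses) > 0) {
    tg <- table(x$impulses$target)
    cat("  targets:", paste(sprintf("%s (%d)", names(tg), tg),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

# Pacemaking cells are seeded slightly depolarized because the exact origin
# is an equilibrium of the model; the sinus node is seeded closest to
# threshold so that settling starts with an orderly sinus beat rather than
# colliding wavefronts from several pacemakers.
rest_state <- function(topo, pacemaker_u0 = 0.003, sn_u0 = 0.01) {
  n <- nrow(topo$cells)
  u <- numeric(n)
  u[topo$cells$a1 < 0] <- pacemaker_u0
  u[topo$cells$label == "SN" & topo$cells$a1 < 0] <- sn_u0
  list(u = u, v = numeric(n))
}

engine_lists <- function(topo, schedule) {
  cells <- topo$cells
  idx <- stats::setNames(seq_len(nrow(cells)), cells$label)
  jn <- topo$junctions
  imp <- schedule$impulses
  bad <- setdiff(unique(imp$target), cells$label)
  if (length(bad) > 0)
    stop("schedule targets unknown cell '", bad[1], "'")
  list(
    cells = list(k = cells$k, a1 = cells$a1, a2 = cells$a2, mu1 = cells$mu1,
                 mu2 = cells$mu2, eps0 = cells$eps0, ct = cells$ct),
    junctions = list(from = unname(idx[jn$from]) - 1L,
                     to = unname(idx[jn$to]) - 1L,
                     d = jn$d, alpha = jn$alpha),
    stimuli = list(target = unname(idx[imp$target]) - 1L,
                   onset = imp$onset / 1000,
                   offset = (imp$onset + imp$duration) / 1000,
                   amplitude = imp$amplitude)
  )
}

#' Integrate the full network model
#'
#' Simulates the coupled reaction-diffusion system for all cells of the
#' topology under a stimulus schedule.  Simulation time starts at 0 ms; with
#' `init = "rest"` the model is first settled for `settle_ms` without
#' stimuli (the settling pre-roll is discarded) so that the pacemaker cells
#' are on their limit cycle when the protocol begins.  Excitable cells rest
#' at `(u, v) = (0, 0)`; pacemaking cells are seeded at `u = 0.01` because
#' the exact origin is an equilibrium of the model.
#'
#' @param topo an `avn_topology`.
#' @param schedule an `avn_schedule`, or `NULL` for a stimulus-free run.
#' @param horizon horizon in ms when `schedule` is `NULL`.
#' @param init `"rest"` or a list with numeric vectors `u` and `v` (one
#'   value per cell) taken as the exact initial state (no settling).
#' @param settle_ms settling pre-roll, ms (default 2000; ignored for
#'   explicit `init` states).
#' @param opts a [solver_options()] list.
#' @param record_trace keep the full `u`/`v` history on the output grid
#'   (default `TRUE`).  Long runs can set this to `FALSE` and still obtain
#'   activation times.
#' @return an object of class `avn_trace` with elements `time` (ms), `u`,
#'   `v` (matrices, one column per cell; only when recorded),
#'   `activations` (data frame `cell`, `time` in ms), `final_state`, and
#'   metadata (`topo`, `schedule`, `opts`, `nstep`).
#' @export
simulate_avn <- function(topo, schedule = NULL, horizon = NULL,
                         init = "rest", settle_ms = 2000,
                         opts = solver_options(), record_trace = TRUE) {
  validate_topology(topo)
  if (is.null(schedule)) {
    if (is.null(horizon)) stop("provide a schedule or a horizon")
    schedule <- stimulus_schedule(NULL, horizon)
  }
  el <- engine_lists(topo, schedule)

  if (identical(init, "rest")) {
    st <- rest_state(topo)
    if (settle_ms > 0) {
      pre <- .simulate_cpp(el$cells, el$junctions,
                           list(target = integer(0), onset = numeric(0),
                                offset = numeric(0), amplitude = numeric(0)),
                           st$u, st$v, 0, settle_ms / 1000,
                           opts$dt_out / 1000, opts$rtol, opts$atol,
                           FALSE, opts$threshold, opts$blanking / 1000)
      st <- list(u = pre$u_end, v = pre$v_end)
    }
  } else {
    st <- init
    if (length(st$u) != nrow(topo$cells) ||
        length(st$v) != nrow(topo$cells))
      stop("init state must have one u and one v value per cell")
  }

  res <- .simulate_cpp(el$cells, el$junctions, el$stimuli, st$u, st$v,
                       0, schedule$horizon / 1000, opts$dt_out / 1000,
                       opts$rtol, opts$atol, record_trace,
                       opts$threshold, opts$blanking / 1000)

  labs <- topo$cells$label
  acts <- data.frame(cell = labs[res$act_cell],
                     time = res$act_time * 1000,
                     stringsAsFactors = FALSE)
  acts <- acts[order(acts$time, acts$cell), , drop = FALSE]
  rownames(acts) <- NULL

  tr <- list(activations = acts,
             final_state = list(u = res$u_end, v = res$v_end),
             topo = topo, schedule = schedule, opts = opts,
             nstep = res$nstep)
  if (record_trace) {
    u <- res$u; v <- res$v
    colnames(u) <- labs
    colnames(v) <- labs
    tr$time <- res$time * 1000
    tr$u <- u
    tr$v <- v
  }
  structure(tr, class = "avn_trace")
}

#' @export
print.avn_trace <- function(x, ...) {
  cat(sprintf("<avn_trace> horizon %.1f ms, %d activations, %s trace\n",
              x$schedule$horizon, nrow(x$activations),
              if (is.null(x$u)) "no stored" else
                sprintf("%d x %d", nrow(x$u), ncol(x$u))))
  invisible(x)
}

#' Export a trace as a wide CSV
#'
#' One row per output-grid time (ms) and one column of `u` values per cell.
#'
#' @param trace an `avn_trace` with a recorded trace.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (is.null(trace$u)) stop("trace was simulated with record_trace = FALSE")
  df <- data.frame(time = trace$time, trace$u, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run metadata as JSON
#'
#' Writes the information needed to reproduce a run: package version,
#' solver options, ablation state, a hash of the full model configuration,
#' and any seed recorded on the schedule.
#'
#' @param trace an `avn_trace`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_trace_meta <- function(trace, path) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(trace$topo$cells, trace$topo$junctions), tf, version = 2)
  meta <- list(
    package = "avnsim",
    version = as.character(utils::packageVersion("avnsim")),
    config_md5 = unname(tools::md5sum(tf)),
    ablation = trace$topo$ablation,
    seed = attr(trace$schedule, "seed"),
    generator = attr(trace$schedule, "generator"),
    horizon_ms = trace$schedule$horizon,
    solver = unclass(trace$opts),
    nstep = trace$nstep
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
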