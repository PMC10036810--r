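#' Per-cell Aliev-Panfilov parameters
#'
#' Builds a validated parameter record for one model cell.  Each cell of the
#' network is a two-variable Aliev-Panfilov (A-P) excitable element; cells
#' with a negative excitation threshold `a1` are self-oscillating
#' (pacemaking), all others are quiescent excitable cells.
#'
#' The cell dynamics implemented throughout the package are
#' \deqn{du/dt = c_t [ k u (u - a_1) (1 - u) - v u ] + I_{coupl} + I_{stim}}
#' \deqn{dv/dt = c_t \epsilon(u, v) [ -v - k u (u - a_2 - 1) ]}
#' \deqn{\epsilon(u, v) = \epsilon_0 + \mu_1 v / (u + \mu_2)}
#' where `u` is the normalized transmembrane potential, `v` the slow
#' recovery variable, and the coupling and stimulus currents are supplied by
#' the network and protocol layers in units of 1/s.  The time-scaling
#' coefficient `ct` converts the dimensionless reaction rate into physical
#' time in seconds; coupling coefficients and stimulus amplitudes are already
#' expressed per second, so `ct` multiplies the reaction terms only.
#'
#' @param label cell name, e.g. `"FP3"`.
#' @param k transmembrane-current magnitude (> 0).
#' @param a1 excitation threshold; `a1 < 0` makes the cell pacemaking.
#' @param a2 recovery threshold; for quiescent excitable cells `a2 = a1 > 0`.
#' @param mu1,mu2 recovery-shape coefficients (`mu1 >= 0`, `mu2 > 0`).
#' @param eps0 base recovery rate (> 0).
#' @param ct time-scaling coefficient (> 0), dimensionless-to-seconds.
#' @param zone voltage-rescaling class, `"atrial"` or `"his"`.
#' @return an object of class `cell_params`.
#' @seealso [ap_rhs()], [intrinsic_period()], [rescale_to_mv()]
#' @export
cell_params <- function(label, k, a1, a2 = a1, mu1, mu2, eps0, ct,
                        zone = c("atrial", "his")) {
  zone <- match.arg(zone)
  vals <- c(k = k, a1 = a1, a2 = a2, mu1 = mu1, mu2 = mu2,
            eps0 = eps0, ct = ct)
  if (any(!is.finite(vals)))
    stop("non-finite parameter for cell '", label, "'")
  if (k <= 0) stop("k must be positive for cell '", label, "'")
  if (ct <= 0) stop("ct must be positive for cell '", label, "'")
  if (eps0 <= 0) stop("eps0 must be positive for cell '", label, "'")
  if (mu1 < 0) stop("mu1 must be non-negative for cell '", label, "'")
  if (mu2 <= 0) stop("mu2 must be positive for cell '", label, "'")
  structure(list(label = label, k = k, a1 = a1, a2 = a2, mu1 = mu1,
                 mu2 = mu2, eps0 = eps0, ct = ct, zone = zone,
                 pacemaking = a1 < 0),
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf("<cell_params> %s (%s)\n", x$label,
              if (x$pacemaking) "pacemaking" else "excitable"))
  cat(sprintf("  k=%g a1=%g a2=%g mu1=%g mu2=%g eps0=%g ct=%g zone=%s\n",
              x$k, x$a1, x$a2, x$mu1, x$mu2, x$eps0, x$ct, x$zone))
  invisible(x)
}

#' Instantaneous Aliev-Panfilov derivatives for one cell
#'
#' Evaluates the right-hand side of the two-variable cell model at a given
#' state.  `i_ext` is the total external current (coupling plus stimulus, in
#' 1/s) supplied by the caller; it enters the potential equation unscaled by
#' `ct`.
#'
#' @param state numeric vector `c(u, v)` or a list with elements `u`, `v`.
#' @param p a [cell_params()] object.
#' @param i_ext external current (default 0).
#' @return named numeric vector `c(du_dt, dv_dt)` in 1/s.
#' @export
ap_rhs <- function(state, p, i_ext = 0) {
  if (is.list(state)) state <- c(state$u, state$v)
  u <- state[[1]]; v <- state[[2]]
  if (!all(is.finite(c(u, v, i_ext)))) stop("non-finite cell state")
  du <- p$ct * (p$k * u * (u - p$a1) * (1 - u) - v * u) + i_ext
  eps <- p$eps0 + p$mu1 * v / (u + p$mu2)
  dv <- p$ct * eps * (-v - p$k * u * (u - p$a2 - 1))
  c(du_dt = du, dv_dt = dv)
}

#' Rescale the normalized potential to millivolts
#'
#' Affine map from the dimensionless potential `u` to a physiological
#' membrane voltage: atrial-like cells map as `120 u - 80` mV, His-like
#' cells as `100 u - 70` mV.
#'
#' @param u normalized potential (scalar or vector).
#' @param zone `"atrial"` or `"his"`.
#' @return voltage in mV.
#' @export
rescale_to_mv <- function(u, zone = c("atrial", "his")) {
  zone <- match.arg(zone)
  switch(zone, atrial = 120 * u - 80, his = 100 * u - 70)
}

#' Intrinsic oscillation period of an uncoupled cell
#'
#' Simulates a single uncoupled cell and measures its asymptotic
#' inter-activation interval (threshold-0.25 upstroke crossings).  Quiescent
#' excitable cells return `NA` (they do not self-oscillate).
#'
#' Pacemaking cells are started from a small positive potential because the
#' exact origin `(u, v) = (0, 0)` is an (unstable) equilibrium of the model;
#' the measurement discards a settling transient and averages the later
#' cycles.
#'
#' @param p a [cell_params()] object.
#' @param horizon_ms simulation horizon in ms (default 8000).
#' @param settle_cycles number of initial activations discarded (default 4).
#' @param opts solver options from [solver_options()].
#' @return period in ms, or `NA_real_` for a non-oscillating cell.
#' @export
intrinsic_period <- function(p, horizon_ms = 8000, settle_cycles = 4,
                             opts = solver_options()) {
  res <- simulate_single_cell(p, horizon_ms = horizon_ms, opts = opts)
  acts <- res$act_time * 1000
  if (!p$pacemaking && length(acts) == 0) return(NA_real_)
  if (length(acts) < settle_cycles + 3) {
    if (p$pacemaking)
      stop("horizon too short to observe the oscillation of '", p$label, "'")
    return(NA_real_)
  }
  iv <- diff(acts)
  mean(utils::tail(iv, length(iv) - settle_cycles + 1))
}

# uncoupled single-cell run, optionally with a stimulus schedule
simulate_single_cell <- function(p, horizon_ms, schedule = NULL,
                                 opts = solver_options()) {
  u0 <- if (p$pacemaking) 0.01 else 0
  cells <- list(k = p$k, a1 = p$a1, a2 = p$a2, mu1 = p$mu1, mu2 = p$mu2,
                eps0 = p$eps0, ct = p$ct)
  if (is.null(schedule)) {
    stim <- list(target = integer(0), onset = numeric(0),
                 offset = numeric(0), amplitude = numeric(0))
  } else {
    stim <- list(target = rep(0L, nrow(schedule$impulses)),
                 onset = schedule$impulses$onset / 1000,
                 offset = (schedule$impulses$onset +
                             schedule$impulses$duration) / 1000,
                 amplitude = schedule$impulses$amplitude)
  }
  .simulate_cpp(cells,
                list(from = integer(0), to = integer(0),
                     d = numeric(0), alpha = numeric(0)),
                stim, u0, 0, 0, horizon_ms / 1000, opts$dt_out / 1000,
                opts$rtol, opts$atol, FALSE, opts$threshold,
                opts$blanking / 1000)
}

#' Refractory period of an uncoupled excitable cell
#'
#' Single-cell analogue of the S1S2 protocol: a short train of suprathreshold
#' 1 ms impulses at the basic interval conditions the cell, then a premature
#' S2 impulse is moved in from the basic interval.  The refractory period is
#' the longest S1S2 interval that fails to elicit a second upstroke, resolved
#' to `step` ms by bisection over the scan grid (the response is monotone in
#' the coupling interval for an uncoupled cell).
#'
#' @param p a [cell_params()] object with `a1 > 0`.
#' @param s1_interval basic cycle length in ms (default 360).
#' @param step scan resolution in ms (default 1).
#' @param amplitude stimulus amplitude (default 280).
#' @param n_s1 number of conditioning impulses (default 3).
#' @param opts solver options.
#' @return refractory period in ms.
#' @export
refractory_period_uncoupled <- function(p, s1_interval = 360, step = 1,
                                        amplitude = 280, n_s1 = 3,
                                        opts = solver_options()) {
  if (p$pacemaking)
    stop("refractory_period_uncoupled() is defined for excitable cells")
  elicits <- function(s2) {
    onsets <- c((0:(n_s1 - 1)) * s1_interval,
                (n_s1 - 1) * s1_interval + s2)
    sch <- list(impulses = data.frame(onset = onsets, duration = 1,
                                      amplitude = amplitude))
    res <- simulate_single_cell(p, horizon_ms = max(onsets) + 300,
                                schedule = sch, opts = opts)
    s2_on <- onsets[length(onsets)]
    s1_on <- onsets[length(onsets) - 1]
    # the response must follow the S2 onset and not be the upstroke still
    # attributable to the preceding S1
    lo_t <- max(s2_on + 0.05, s1_on + 2)
    any(res$act_time * 1000 > lo_t & res$act_time * 1000 <= s2_on + 50)
  }
  if (!elicits(s1_interval))
    stop("cell '", p$label, "' is not excitable at this amplitude")
  lo <- step  # assumed refractory (not elicited)
  hi <- s1_interval  # elicited
  if (elicits(lo)) return(0)
  while (hi - lo > step) {
    mid <- lo + step * floor((hi - lo) / (2 * step))
    if (elicits(mid)) hi <- mid else lo <- mid
  }
  lo
}
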