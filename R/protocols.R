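#' S1S2 premature-stimulation specification
#'
#' Describes one S1S2 trial: a train of `n_s1` basic stimuli at
#' `s1_interval` followed by a single premature test stimulus `s2_interval`
#' after the last S1.  The anterograde site paces the atrial entry cell, the
#' retrograde site paces `HB1`.
#'
#' @param site `"antero"` or `"retro"`.
#' @param s2_interval S1S2 coupling interval, ms.
#' @param s1_interval basic cycle length, ms (default 360).
#' @param n_s1 number of basic stimuli (default 10).
#' @param amplitude stimulus amplitude (default 280).
#' @param duration stimulus duration, ms (default 1).
#' @return an object of class `s1s2_spec`.
#' @export
s1s2_spec <- function(site = c("antero", "retro"), s2_interval,
                      s1_interval = 360, n_s1 = 10, amplitude = 280,
                      duration = 1) {
  site <- match.arg(site)
  if (n_s1 < 1) stop("n_s1 must be at least 1")
  if (s2_interval > s1_interval)
    stop("s2_interval must not exceed s1_interval")
  structure(list(site = site, s2_interval = s2_interval,
                 s1_interval = s1_interval, n_s1 = n_s1,
                 amplitude = amplitude, duration = duration),
            class = "s1s2_spec")
}

#' Build the stimulus schedule of one S1S2 trial
#'
#' `n_s1` impulses at the basic interval starting at `t_start`, then one S2
#' at the coupling interval after the last S1.  The horizon extends
#' `tail_ms` past the S2 onset so conducted responses and any post-stimulus
#' reentry can be observed.
#'
#' @param spec an [s1s2_spec()].
#' @param topo topology providing the entry-point cell labels.
#' @param t_start onset of the first S1, ms (default 0).
#' @param tail_ms observation window after S2, ms (default 1500).
#' @return an `avn_schedule`.
#' @export
s1s2_schedule <- function(spec, topo, t_start = 0, tail_ms = 1500) {
  target <- switch(spec$site, antero = topo$entry$antero,
                   retro = topo$entry$retro)
  onsets <- t_start + (seq_len(spec$n_s1) - 1) * spec$s1_interval
  s2_on <- onsets[length(onsets)] + spec$s2_interval
  imp <- data.frame(target = target, onset = c(onsets, s2_on),
                    duration = spec$duration, amplitude = spec$amplitude,
                    stringsAsFactors = FALSE)
  sch <- stimulus_schedule(imp, horizon = s2_on + tail_ms)
  attr(sch, "s2_onset") <- s2_on
  attr(sch, "spec") <- spec
  sch
}

#' S1S2 sweep specification
#'
#' A descending scan of the S2 coupling interval, `start` down to `stop`
#' in steps of `step` ms, all other settings from the template spec.
#'
#' @param template an [s1s2_spec()] (its `s2_interval` is ignored).
#' @param start,stop sweep limits, ms (`start >= stop`); defaults 360 and
#'   90, covering the basic cycle length down past full nodal block.
#' @param step decrement, ms (default 1).
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(template, start = 360, stop = 90, step = 1) {
  if (start < stop) stop("sweep start must be >= stop")
  if (step <= 0) stop("sweep step must be positive")
  structure(list(template = template, start = start, stop = stop,
                 step = step), class = "sweep_spec")
}

#' S2 values covered by a sweep
#' @param sweep a [sweep_spec()].
#' @return numeric vector, descending from `start` to `stop` inclusive.
#' @export
sweep_intervals <- function(sweep) {
  v <- seq(sweep$start, sweep$stop, by = -sweep$step)
  if (utils::tail(v, 1) > sweep$stop) v <- c(v, sweep$stop)
  v
}

#' Random atrial-fibrillation pacing schedule
#'
#' Impulses delivered through the intermediate atrial cell (`AM*`) with
#' i.i.d. inter-impulse intervals uniform on `interval_range` ms,
#' reproducible from `seed` (R's Mersenne-Twister generator; the caller's
#' RNG state is left untouched).
#'
#' @param total total pacing duration, ms; a non-positive value gives an
#'   empty schedule.
#' @param interval_range `c(lo, hi)` in ms (default `c(75, 125)`).
#' @param seed integer seed.
#' @param topo topology providing the `AM*` entry label.
#' @param amplitude,duration impulse shape (defaults 280, 1 ms).
#' @param tail_ms horizon extension past the last impulse (default 500).
#' @return an `avn_schedule` with the seed and generator recorded as
#'   attributes.
#' @export
random_afb_schedule <- function(total, interval_range = c(75, 125), seed = 1,
                                topo = build_topology(), amplitude = 280,
                                duration = 1, tail_ms = 500) {
  lo <- interval_range[1]; hi <- interval_range[2]
  if (!(lo < hi)) stop("interval_range must satisfy lo < hi")
  if (total <= 0)
    return(stimulus_schedule(NULL, horizon = max(total, 1)))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  onsets <- numeric(0)
  t <- 0
  repeat {
    t <- t + stats::runif(1, lo, hi)
    if (t > total) break
    onsets <- c(onsets, t)
  }
  imp <- data.frame(target = topo$entry$af, onset = onsets,
                    duration = duration, amplitude = amplitude,
                    stringsAsFactors = FALSE)
  sch <- stimulus_schedule(imp, horizon = total + tail_ms)
  attr(sch, "seed") <- seed
  attr(sch, "generator") <- "Mersenne-Twister"
  sch
}

#' Regular atrial-flutter pacing schedule
#'
#' Impulses at exact multiples of `interval` targeting the `AM*` entry cell.
#'
#' @param interval pacing interval, ms (default 125.2, an atrial rate of
#'   about 480 bpm).
#' @param total total pacing duration, ms.
#' @param topo topology providing the `AM*` entry label.
#' @param amplitude,duration impulse shape (defaults 280, 1 ms).
#' @param tail_ms horizon extension past the last impulse (default 500).
#' @return an `avn_schedule`.
#' @export
regular_afl_schedule <- function(interval = 125.2, total,
                                 topo = build_topology(), amplitude = 280,
                                 duration = 1, tail_ms = 500) {
  if (interval <= 0) stop("pacing interval must be positive")
  n <- floor(total / interval)
  onsets <- (seq_len(n) - 1) * interval
  if (n == 0)
    return(stimulus_schedule(NULL, horizon = max(total, 1)))
  imp <- data.frame(target = topo$entry$af, onset = onsets,
                    duration = duration, amplitude = amplitude,
                    stringsAsFactors = FALSE)
  stimulus_schedule(imp, horizon = max(total, max(onsets) + duration) +
                      tail_ms)
}

#' Export a schedule as CSV
#' @param schedule an `avn_schedule`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule$impulses[, c("onset", "duration", "amplitude",
                                         "target")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
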