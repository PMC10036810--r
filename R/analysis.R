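#' Detect threshold-crossing activations in a trace
#'
#' An activation is an upward crossing of the detection threshold by the
#' normalized potential `u`, timed by linear interpolation between the two
#' bracketing output-grid samples.  Crossings closer than the blanking
#' window to the previous activation of the same cell are discarded.
#'
#' @param trace an `avn_trace`.
#' @param threshold upstroke threshold (default 0.25).
#' @param blanking per-cell blanking window, ms (default 20).
#' @return an `activation_table`: data frame with columns `cell`, `time`
#'   (ms), sorted by time, carrying the topology as an attribute.
#' @export
detect_activations <- function(trace, threshold = 0.25, blanking = 20) {
  if (is.null(trace$u)) {
    if (threshold != trace$opts$threshold ||
        blanking != trace$opts$blanking)
      stop("trace stores no u history; re-detection at other settings ",
           "needs record_trace = TRUE")
    return(activation_table(trace$activations, trace$topo))
  }
  tm <- trace$time
  dt <- tm[2] - tm[1]
  out <- vector("list", ncol(trace$u))
  for (ci in seq_len(ncol(trace$u))) {
    u <- trace$u[, ci]
    n <- length(u)
    below <- u[-n] < threshold
    above <- u[-1] >= threshold
    idx <- which(below & above & (u[-1] > u[-n]))
    if (length(idx) == 0) next
    tc <- tm[idx] + dt * (threshold - u[idx]) / (u[idx + 1] - u[idx])
    keep <- logical(length(tc))
    last <- -Inf
    for (q in seq_along(tc)) {
      if (tc[q] - last >= blanking) {
        keep[q] <- TRUE
        last <- tc[q]
      }
    }
    tc <- tc[keep]
    out[[ci]] <- data.frame(cell = colnames(trace$u)[ci], time = tc,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  if (is.null(tab))
    tab <- data.frame(cell = character(0), time = numeric(0),
                      stringsAsFactors = FALSE)
  tab <- tab[order(tab$time, tab$cell), , drop = FALSE]
  rownames(tab) <- NULL
  activation_table(tab, trace$topo)
}

activation_table <- function(df, topo) {
  structure(df, topo = topo, class = c("activation_table", "data.frame"))
}

#' Activation times of one cell
#' @param tab an `activation_table`.
#' @param cell cell label.
#' @return sorted numeric vector of activation times, ms.
#' @export
activations_of <- function(tab, cell) {
  sort(tab$time[tab$cell == cell])
}

#' Label the leading pathway of every penetrating-bundle beat
#'
#' For each `PB` activation, the arrival routes via `FP8` and `SP10` are
#' compared: among the upstream-neighbour activations inside the look-back
#' window before the PB beat, the earlier one delivered the excitation
#' first and defines the leading pathway.  Simultaneous arrivals resolve to
#' `FP` by convention; a PB beat with no upstream activation in the window
#' is labelled `none`.
#'
#' @param tab an `activation_table`.
#' @param window look-back window before each PB activation, ms
#'   (default 50).
#' @return data frame with columns `pb_time` and `pathway`
#'   (`"FP"`/`"SP"`/`"none"`).
#' @export
assign_leading_pathway <- function(tab, window = 50) {
  pb <- activations_of(tab, "PB")
  fp <- activations_of(tab, "FP8")
  sp <- activations_of(tab, "SP10")
  path <- character(length(pb))
  for (q in seq_along(pb)) {
    tf <- fp[fp < pb[q] & fp >= pb[q] - window]
    ts <- sp[sp < pb[q] & sp >= pb[q] - window]
    tf <- if (length(tf)) max(tf) else NA_real_
    ts <- if (length(ts)) max(ts) else NA_real_
    path[q] <- if (is.na(tf) && is.na(ts)) "none"
      else if (is.na(ts)) "FP"
      else if (is.na(tf)) "SP"
      else if (tf <= ts) "FP" else "SP"
  }
  data.frame(pb_time = pb, pathway = path, stringsAsFactors = FALSE)
}

# leading pathway of the beat containing a given His activation time
pathway_at <- function(lead, t_hb, window = 120) {
  ok <- lead$pb_time <= t_hb & lead$pb_time > t_hb - window
  if (!any(ok)) return("none")
  lead$pathway[max(which(ok))]
}

#' Reentry detection after an S1S2 trial
#'
#' Classifies perpetual AV-nodal reentrant tachycardia: at least
#' `min_cycles` His-bundle activations after the last stimulus offset, each
#' led by the slow pathway (anterograde SP leg with retrograde FP return),
#' with atrial re-activation between consecutive His beats.
#'
#' @param tab an `activation_table`.
#' @param schedule the `avn_schedule` that produced the run.
#' @param min_cycles minimum number of post-stimulus reentrant His beats
#'   (default 3).
#' @param max_cycle longest cycle length accepted as tachycardia, ms
#'   (default 350); distinguishes reentry from a slow junctional escape
#'   rhythm, which is also slow-pathway led.
#' @param measure named vector of measurement cells (`A`, `H`).
#' @return list with `reentrant` (logical), `n_cycles`, `cycle_length`
#'   (ms, mean; `NA` when not reentrant).
#' @export
detect_avnrt <- function(tab, schedule, min_cycles = 3, max_cycle = 350,
                         measure = c(A = "AM3", H = "HB6")) {
  imp <- schedule$impulses
  t_end <- if (nrow(imp) > 0) max(imp$onset + imp$duration) else 0
  hb <- activations_of(tab, measure[["H"]])
  am <- activations_of(tab, measure[["A"]])
  lead <- assign_leading_pathway(tab)
  hb <- hb[hb > t_end]
  if (length(hb) == 0)
    return(list(reentrant = FALSE, n_cycles = 0L, cycle_length = NA_real_))
  sp_led <- vapply(hb, function(t) pathway_at(lead, t) == "SP", logical(1))
  # longest run of consecutive SP-led His beats with interposed atrial beats
  best <- 0L
  run <- 0L
  times <- c()
  cur <- c()
  for (q in seq_along(hb)) {
    ok <- sp_led[q] &&
      (run == 0L || (hb[q] - hb[q - 1] <= max_cycle &&
                       any(am > hb[q - 1] & am < hb[q])))
    if (ok) {
      run <- run + 1L
      cur <- c(cur, hb[q])
    } else {
      run <- if (sp_led[q]) 1L else 0L
      cur <- if (sp_led[q]) hb[q] else c()
    }
    if (run > best) {
      best <- run
      times <- cur
    }
  }
  reent <- best >= min_cycles
  list(reentrant = reent, n_cycles = best,
       cycle_length = if (reent && length(times) > 1) mean(diff(times))
                      else NA_real_)
}

# measure the S2 beat of one trial; times relative to the trial run in
# which the last S1 fires at t = 0 and S2 at t = s2
measure_trial <- function(tab, s2, direction, response_window, measure,
                          schedule) {
  A <- measure[["A"]]; H <- measure[["H"]]
  am <- activations_of(tab, A)
  hb <- activations_of(tab, H)
  lead <- assign_leading_pathway(tab)
  eps <- 1e-9
  if (direction == "antero") {
    a1 <- am[am < s2]
    a1 <- if (length(a1)) max(a1) else NA_real_
    h1 <- hb[hb >= 0 & hb < s2 + response_window]
    h1 <- if (length(h1)) min(h1) else NA_real_
    a2 <- am[am >= s2 - eps]
    a2 <- if (length(a2)) min(a2) else NA_real_
    # the atrial response to S2 arrives within decremental atrial latency;
    # anything later is a spontaneous (escape) beat, not a response
    if (!is.na(a2) && a2 - s2 > 120) a2 <- NA_real_
    h2 <- NA_real_
    if (!is.na(a2)) {
      lo <- max(a2, if (is.na(h1)) -Inf else h1) + eps
      h2c <- hb[hb > lo & hb <= a2 + response_window]
      # the S2-driven His response must arrive before the next atrial
      # wave (e.g. a sinus escape beat) has re-engaged the node
      a_next <- am[am > a2 + 20]
      if (length(a_next)) h2c <- h2c[h2c < min(a_next) + 60]
      if (length(h2c)) h2 <- min(h2c)
    }
    conducted <- !is.na(h2)
    pathway <- if (conducted) pathway_at(lead, h2) else "none"
  } else {
    h1 <- hb[hb < s2]
    h1 <- if (length(h1)) max(h1) else NA_real_
    h2 <- hb[hb >= s2 - eps]
    h2 <- if (length(h2)) min(h2) else NA_real_
    a1 <- am[am >= 0 & am < s2]
    a1 <- if (length(a1)) min(a1) else NA_real_
    a2 <- NA_real_
    sn <- activations_of(tab, "SN")
    a2c <- am[am > max(s2, if (is.na(a1)) -Inf else a1 + eps) &
                am <= s2 + response_window]
    # a retro-conducted atrial response is not preceded by a sinus-node
    # upstroke (a sinus escape beat activates SN ~44 ms before AM3)
    if (length(a2c))
      a2c <- a2c[vapply(a2c, function(t)
        !any(sn > t - 55 & sn < t), logical(1))]
    if (length(a2c)) a2 <- min(a2c)
    conducted <- !is.na(a2)
    pathway <- "FP"  # retrograde route label resolved by curve context
  }
  reent <- detect_avnrt(tab, schedule, measure = measure)
  data.frame(s1s2 = s2, a1 = a1, h1 = h1, a2 = a2, h2 = h2,
             a1a2 = a2 - a1, h1h2 = h2 - h1, a2h2 = h2 - a2,
             h2a2 = a2 - h2, h1a2 = a2 - h1, a1h1 = h1 - a1,
             conducted = conducted, reentry = reent$reentrant,
             reentry_cl = reent$cycle_length,
             pathway = pathway, stringsAsFactors = FALSE)
}

#' Run a full S1S2 sweep and assemble the conduction curve
#'
#' One trial per S2 value, descending from `start` to `stop`.  All trials
#' share the deterministic settled S1-train prefix (settling pre-roll plus
#' the first `n_s1 - 1` basic stimuli), which is integrated once; each
#' trial then continues independently from that state with the last S1 at
#' trial time 0 and the premature S2 at its coupling interval.  This is
#' numerically equivalent to running every trial from settled rest and
#' keeps trials order-invariant.
#'
#' Conventions: the atrial measurement cell is `AM3` (last atrial cell) and
#' the His measurement cell `HB6` (model exit).  A trial is conducted when
#' the test response reaches the far measurement cell within
#' `response_window` after S2.  ERPN is the longest non-conducted S1S2
#' interval; FRPN the minimum H1H2 over conducted trials.
#'
#' @param topo an `avn_topology`.
#' @param sweep a [sweep_spec()].
#' @param opts solver options.
#' @param response_window conducted-response window after S2, ms
#'   (default 400).
#' @param tail_ms post-S2 observation horizon, ms (default 1500).
#' @param settle_ms settling pre-roll before the S1 train (default 2000).
#' @param s1_phase delay of the first S1 after the settled sinus upstroke,
#'   ms (default 200).  The basic cycle length (360 ms) is deliberately just
#'   below the spontaneous sinus cycle (361 ms), so the train only captures
#'   the atrium when the first S1 falls into diastole; locking the start to
#'   the SN phase makes capture (and the whole sweep) deterministic.
#' @param intervals optional explicit S2 values overriding the sweep grid.
#' @param measure named character vector with measurement cells `A` and `H`.
#' @return a `conduction_curve` data frame (one row per S2 value, columns
#'   `s1s2`, `a1a2`, `h1h2`, `a2h2`, `h2a2`, `h1a2`, `a1h1`, `conducted`,
#'   `reentry`, `pathway`, ...) with attributes `erpn`, `frpn`,
#'   `direction`.
#' @export
run_s1s2_sweep <- function(topo, sweep, opts = solver_options(),
                           response_window = 400, tail_ms = 1500,
                           settle_ms = 2000, s1_phase = NULL,
                           intervals = NULL,
                           measure = c(A = "AM3", H = "HB6")) {
  tpl <- sweep$template
  direction <- tpl$site
  # default first-S1 phase after the sinus upstroke: mid-diastole of the
  # paced chamber (the His side activates ~130 ms after the SN)
  if (is.null(s1_phase))
    s1_phase <- if (direction == "retro") 330 else 200
  target <- switch(direction, antero = topo$entry$antero,
                   retro = topo$entry$retro)
  # the His reference for retrograde trials is the paced His cell, so that
  # H1H2 is the pacing interval and H2A2 runs from the His activation
  if (direction == "retro" && identical(measure[["H"]], "HB6"))
    measure[["H"]] <- target
  state <- settled_phase_state(topo, settle_ms, s1_phase, opts)
  # shared prefix: S1 impulses 1 .. n_s1-1
  n_pre <- tpl$n_s1 - 1
  if (n_pre > 0) {
    pre_sched <- stimulus_schedule(
      data.frame(target = target,
                 onset = (seq_len(n_pre) - 1) * tpl$s1_interval,
                 duration = tpl$duration, amplitude = tpl$amplitude,
                 stringsAsFactors = FALSE),
      horizon = n_pre * tpl$s1_interval)
    pre <- simulate_avn(topo, pre_sched, init = state, opts = opts,
                        record_trace = FALSE)
    state <- pre$final_state
  }

  if (is.null(intervals)) intervals <- sweep_intervals(sweep)
  rows <- lapply(intervals, function(s2) {
    sch <- stimulus_schedule(
      data.frame(target = target, onset = c(0, s2),
                 duration = tpl$duration, amplitude = tpl$amplitude,
                 stringsAsFactors = FALSE),
      horizon = s2 + tail_ms)
    tr <- simulate_avn(topo, sch, init = state, opts = opts,
                       record_trace = FALSE)
    tab <- detect_activations(tr, threshold = opts$threshold,
                              blanking = opts$blanking)
    measure_trial(tab, s2, direction, response_window, measure, sch)
  })
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  # ERPN: top of the contiguous non-conducted band at the refractory
  # floor (spontaneous-beat collisions at long intervals do not count)
  ord <- order(curve$s1s2)
  cond_sorted <- curve$conducted[ord]
  s_sorted <- curve$s1s2[ord]
  erpn <- NA_real_
  if (!cond_sorted[1]) {
    run_end <- which(cond_sorted)[1]
    erpn <- if (is.na(run_end)) max(s_sorted)
            else s_sorted[run_end - 1]
  }
  cond <- curve[curve$conducted, , drop = FALSE]
  structure(curve,
            erpn = erpn,
            frpn = if (nrow(cond)) min(cond$h1h2) else NA_real_,
            direction = direction,
            class = c("conduction_curve", "data.frame"))
}

# settle the model, then advance to a fixed phase after the next sinus
# (or escape-pacemaker) upstroke so that pacing protocols start from a
# reproducible diastolic state
settled_phase_state <- function(topo, settle_ms, phase_ms,
                                opts = solver_options(),
                                lock_cell = "SN") {
  base <- simulate_avn(topo, horizon = max(settle_ms, 1), init = "rest",
                       settle_ms = 0, opts = opts, record_trace = FALSE)
  st <- base$final_state
  if (phase_ms <= 0) return(st)
  if (!(lock_cell %in% topo$cells$label) ||
      topo$cells[topo$cells$label == lock_cell, "a1"] >= 0)
    return(st)
  probe <- simulate_avn(topo, horizon = 1200, init = st, opts = opts,
                        record_trace = FALSE)
  tl <- probe$activations$time[probe$activations$cell == lock_cell]
  if (length(tl) == 0) return(st)
  lock <- simulate_avn(topo, horizon = min(tl) + phase_ms, init = st,
                       opts = opts, record_trace = FALSE)
  lock$final_state
}

#' Effective refractory period of a conduction curve
#' @param curve a `conduction_curve`.
#' @return ERPN in ms (longest non-conducted S1S2 interval).
#' @export
erpn <- function(curve) attr(curve, "erpn")

#' Functional refractory period of a conduction curve
#' @param curve a `conduction_curve`.
#' @return FRPN in ms (minimum H1H2 over conducted trials).
#' @export
frpn <- function(curve) attr(curve, "frpn")

#' Derived refractory and His-atrial curves
#'
#' From an anterograde sweep, extracts the refractory curve (H1H2 versus
#' A1A2) and the His-atrial curve (H1A2 versus A1A2) over the conducted
#' points.  By construction from one activation table per trial the
#' identities `H1H2 = A2H2 + H1A2` and `A1A2 = H1A2 + A1H1` hold exactly at
#' every conducted point.
#'
#' @param curve an anterograde `conduction_curve`.
#' @return list of two data frames, `refractory` (`a1a2`, `h1h2`) and
#'   `his_atrial` (`a1a2`, `h1a2`).
#' @export
refractory_and_his_atrial_curves <- function(curve) {
  cond <- curve[curve$conducted, , drop = FALSE]
  list(refractory = data.frame(a1a2 = cond$a1a2, h1h2 = cond$h1h2),
       his_atrial = data.frame(a1a2 = cond$a1a2, h1a2 = cond$h1a2))
}

#' Wenckebach analysis of a regular pacing run
#'
#' Identifies the repeating conduction block pattern during regular atrial
#' pacing.  Atrial beats are the activations of the atrial measurement cell;
#' each His-bundle activation is attributed to the most recent unconsumed
#' atrial beat.  After discarding `lead_in` atrial beats, the smallest
#' period of the conducted/blocked sequence gives the ratio
#' `n:m` (atrial beats per block : conducted beats per block).
#'
#' @param tab an `activation_table` from a regular pacing run.
#' @param pacing_interval the pacing interval, ms.
#' @param lead_in number of initial atrial beats discarded (default 10).
#' @param max_ah largest credible atrial-His delay, ms (default 350).
#' @param measure measurement cells (`A`, `H`).
#' @return list with `ratio` (integer vector `c(n, m)`), `ah` (data frame
#'   `a_time`, `ah`, `pathway` for conducted beats in the steady region),
#'   `hh` (numeric vector of His-His intervals), `conducted` (logical per
#'   analysed atrial beat).
#' @export
wenckebach_analysis <- function(tab, pacing_interval, lead_in = 10,
                                max_ah = 350,
                                measure = c(A = "AM3", H = "HB6")) {
  am <- activations_of(tab, measure[["A"]])
  hb <- activations_of(tab, measure[["H"]])
  lead <- assign_leading_pathway(tab)
  # attribute each His beat to the latest unconsumed atrial beat before it
  a_of_h <- integer(0)
  used <- logical(length(am))
  for (t in hb) {
    cand <- which(!used & am < t & am > t - max_ah)
    if (length(cand)) {
      used[max(cand)] <- TRUE
      a_of_h <- c(a_of_h, max(cand))
    } else a_of_h <- c(a_of_h, NA_integer_)
  }
  keep <- seq_along(am) > lead_in
  conducted <- used[keep]
  n_a <- length(conducted)
  if (n_a < 4) stop("not enough steady-state atrial beats for analysis")
  # smallest period of the conducted/blocked sequence
  ratio <- NULL
  for (p in 2:min(12, n_a - 1)) {
    reps <- conducted[seq_len(n_a - p)] == conducted[seq_len(n_a - p) + p]
    if (all(reps) && any(!conducted[seq_len(p)])) {
      ratio <- c(p, sum(conducted[seq_len(p)]))
      break
    }
  }
  if (is.null(ratio)) {
    if (all(conducted)) ratio <- c(1L, 1L)
    else stop("no repeating conduction pattern found; longest pattern: ",
              paste(as.integer(conducted), collapse = ""))
  }
  am_idx <- which(keep)
  cond_rows <- lapply(seq_along(hb), function(qi) {
    ai <- a_of_h[qi]
    if (is.na(ai) || !(ai %in% am_idx)) return(NULL)
    data.frame(a_time = am[ai], h_time = hb[qi], ah = hb[qi] - am[ai],
               pathway = pathway_at(lead, hb[qi]),
               stringsAsFactors = FALSE)
  })
  ah <- do.call(rbind, cond_rows)
  hh <- diff(hb[hb > am[am_idx[1]]])
  list(ratio = as.integer(ratio), ah = ah, hh = hh, conducted = conducted)
}

#' His-His interval statistics
#'
#' @param tab an `activation_table`.
#' @param from,to optional analysis window, ms.
#' @param measure His measurement cell (default `HB6`).
#' @return list with `mean_hh` (ms), `rate_bpm`, `intervals`.
#' @export
hh_statistics <- function(tab, from = -Inf, to = Inf,
                          measure = c(H = "HB6")) {
  hb <- activations_of(tab, measure[["H"]])
  hb <- hb[hb >= from & hb <= to]
  if (length(hb) < 2)
    stop("fewer than two His-bundle activations in the analysis window")
  iv <- diff(hb)
  list(mean_hh = mean(iv), rate_bpm = 60000 / mean(iv), intervals = iv)
}

#' Export an activation table or conduction curve as CSV
#' @param x an `activation_table` or `conduction_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
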