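test_that("an unstimulated excitable cable stays exactly at rest", {
  topo <- toy_chain(n = 6)
  tr <- simulate_avn(topo, horizon = 400, settle_ms = 0)
  expect_equal(nrow(tr$activations), 0)
  expect_lt(max(abs(tr$u)), 1e-12)
  expect_lt(max(abs(tr$v)), 1e-12)
})

test_that("simulation is deterministic", {
  topo <- toy_chain(n = 5)
  sch <- stimulus_schedule(stimulus_impulse("C1", 20), horizon = 300)
  t1 <- simulate_avn(topo, sch, settle_ms = 0)
  t2 <- simulate_avn(topo, sch, settle_ms = 0)
  expect_identical(t1$u, t2$u)
  expect_identical(t1$activations, t2$activations)
})

test_that("stimulus charge is delivered event-exactly", {
  # a nearly reaction-free cell integrates the pulse alone, so the
  # potential after the pulse equals amplitude x duration
  cells <- data.frame(label = "C1", zone = "atrial", k = 1e-9, a1 = 0.15,
                      a2 = 0.15, mu1 = 0.1, mu2 = 0.3, eps0 = 1e-9,
                      ct = 1e-9, stringsAsFactors = FALSE)
  topo <- custom_topology(cells, data.frame(from = character(0),
                                            to = character(0),
                                            d = numeric(0),
                                            alpha = numeric(0)))
  # onset/duration deliberately off the output grid and step boundaries
  sch <- stimulus_schedule(stimulus_impulse("C1", onset = 13.37,
                                            duration = 0.73,
                                            amplitude = 120),
                          horizon = 40)
  tr <- simulate_avn(topo, sch, settle_ms = 0)
  u_end <- unname(tr$u[nrow(tr$u), 1])
  expect_equal(u_end, 120 * 0.73 / 1000, tolerance = 1e-6)
  # nothing before onset
  expect_lt(max(abs(tr$u[tr$time < 13.3, 1])), 1e-12)
})

test_that("adaptive stepping never skips a short mid-interval impulse", {
  topo <- toy_chain(n = 3)
  sch <- stimulus_schedule(stimulus_impulse("C1", onset = 111.13,
                                            duration = 0.2,
                                            amplitude = 1500),
                          horizon = 400)
  tr <- simulate_avn(topo, sch, settle_ms = 0, record_trace = FALSE)
  a <- tr$activations
  expect_true(any(a$cell == "C1" & abs(a$time - 112) < 5))
  expect_true(any(a$cell == "C3"))
})

test_that("halving the tolerances moves activation times by < 0.05 ms", {
  topo <- build_topology()
  t1 <- simulate_avn(topo, horizon = 800, record_trace = FALSE)
  t2 <- simulate_avn(topo, horizon = 800, record_trace = FALSE,
                     opts = solver_options(rtol = 5e-8, atol = 5e-11))
  a1 <- t1$activations
  a2 <- t2$activations
  expect_equal(nrow(a1), nrow(a2))
  m <- merge(transform(a1, idx = ave(time, cell, FUN = seq_along)),
             transform(a2, idx = ave(time, cell, FUN = seq_along)),
             by = c("cell", "idx"))
  expect_lt(max(abs(m$time.x - m$time.y)), 0.05)
})

test_that("the integrator agrees with an independent reference solver", {
  skip_if_not_installed("deSolve")
  topo <- toy_chain(n = 4, d = 90)
  sch <- stimulus_schedule(stimulus_impulse("C1", 10), horizon = 250)
  tr <- simulate_avn(topo, sch, settle_ms = 0)

  cells <- topo$cells
  rhs <- function(t, y, parms) {
    n <- 4
    u <- y[1:n]; v <- y[(n + 1):(2 * n)]
    istim <- numeric(n)
    if (t >= 0.010 && t < 0.011) istim[1] <- 280
    icoup <- numeric(n)
    for (r in seq_len(nrow(topo$junctions))) {
      i <- match(topo$junctions$from[r], cells$label)
      j <- match(topo$junctions$to[r], cells$label)
      d <- topo$junctions$d[r]; al <- topo$junctions$alpha[r]
      tterm <- d * (u[i] - al * u[j])
      icoup[i] <- icoup[i] - tterm
      icoup[j] <- icoup[j] + tterm
    }
    du <- cells$ct * (cells$k * u * (u - cells$a1) * (1 - u) - v * u) +
      icoup + istim
    eps <- cells$eps0 + cells$mu1 * v / (u + cells$mu2)
    dv <- cells$ct * eps * (-v - cells$k * u * (u - cells$a2 - 1))
    list(c(du, dv))
  }
  times <- seq(0, 0.250, by = 1e-4)
  ref <- deSolve::ode(y = numeric(8), times = times, func = rhs,
                      parms = NULL, method = "ode45",
                      rtol = 1e-9, atol = 1e-12)
  for (ci in 1:4) {
    u_ref <- ref[, 1 + ci]
    cr <- which(u_ref[-1] >= 0.25 & u_ref[-length(u_ref)] < 0.25)[1]
    t_ref <- 1000 * (times[cr] +
      1e-4 * (0.25 - u_ref[cr]) / (u_ref[cr + 1] - u_ref[cr]))
    t_got <- tr$activations$time[tr$activations$cell == paste0("C", ci)][1]
    expect_equal(t_got, t_ref, tolerance = 0.05 / t_ref)
  }
})

test_that("fast pacing overdrive-suppresses the network pacemakers", {
  # atrial pacing at 300 ms is faster than both the sinus (361 ms) and the
  # subsidiary slow-pathway (600 ms) rhythms: during the train every His
  # beat is stimulus-driven and no pacemaker escapes break through
  topo <- build_topology()
  onsets <- seq(0, 2700, by = 300)
  sch <- stimulus_schedule(
    data.frame(target = "AM*", onset = onsets, duration = 1,
               amplitude = 280), horizon = 3000)
  tr <- simulate_avn(topo, sch, settle_ms = 2000, record_trace = FALSE)
  hb <- tr$activations$time[tr$activations$cell == "HB6"]
  hb <- hb[hb > 600]  # past the entrainment transient
  dist <- vapply(hb, function(t) min(t - onsets[onsets < t]), numeric(1))
  expect_true(all(dist < 220))
  # and the His rate follows the pacing rate 1:1
  expect_equal(mean(diff(hb)), 300, tolerance = 0.02)
})

test_that("trace export and metadata round-trip", {
  topo <- toy_chain(n = 3)
  sch <- stimulus_schedule(stimulus_impulse("C1", 10), horizon = 100)
  tr <- simulate_avn(topo, sch, settle_ms = 0)
  csv <- tempfile(fileext = ".csv")
  write_trace_csv(tr, csv)
  got <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(names(got), c("time", "C1", "C2", "C3"))
  expect_equal(nrow(got), length(tr$time))
  js <- tempfile(fileext = ".json")
  write_trace_meta(tr, js)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$package, "avnsim")
  expect_equal(meta$solver$rtol, 1e-7)
})
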