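test_that("activation detection interpolates threshold crossings", {
  # flat trace: no activations
  tm <- seq(0, 200, by = 0.1)
  flat <- synthetic_trace(tm, matrix(0, length(tm), 2))
  expect_equal(nrow(detect_activations(flat)), 0)

  # linear ramp crossing 0.25 exactly at t = 100.05 (between samples)
  u <- matrix(0, length(tm), 2)
  u[, 1] <- pmax(0, (tm - 80) / 40.1)  # 0.25 at t = 100.025
  tr <- synthetic_trace(tm, u)
  tab <- detect_activations(tr)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$time, 80 + 0.25 * 40.1, tolerance = 1e-6)

  # refractory blanking merges chattering crossings
  u2 <- matrix(0, length(tm), 2)
  u2[, 1] <- 0.3 + 0.1 * sin(tm * 2)  # crosses often, never drops below 0.2
  u2[tm < 50, 1] <- 0
  tr2 <- synthetic_trace(tm, u2)
  tab2 <- detect_activations(tr2, blanking = 1e6)
  expect_equal(nrow(tab2), 1)
})

test_that("leading-pathway assignment picks the first-arriving route", {
  topo <- default_topo_cached()
  tab <- synthetic_table(data.frame(
    cell = c("FP8", "SP10", "PB"), time = c(90, 91, 95),
    stringsAsFactors = FALSE), topo)
  expect_equal(assign_leading_pathway(tab)$pathway, "FP")
  tab2 <- synthetic_table(data.frame(
    cell = c("FP8", "SP10", "PB"), time = c(92, 90, 95),
    stringsAsFactors = FALSE), topo)
  expect_equal(assign_leading_pathway(tab2)$pathway, "SP")
  # documented tie-break: simultaneous arrival resolves to FP
  tab3 <- synthetic_table(data.frame(
    cell = c("FP8", "SP10", "PB"), time = c(90, 90, 95),
    stringsAsFactors = FALSE), topo)
  expect_equal(assign_leading_pathway(tab3)$pathway, "FP")
  # orphan PB beat
  tab4 <- synthetic_table(data.frame(cell = "PB", time = 95,
                                     stringsAsFactors = FALSE), topo)
  expect_equal(assign_leading_pathway(tab4)$pathway, "none")
})

test_that("conduction-curve identities hold exactly at conducted points", {
  topo <- default_topo_cached()
  sw <- sweep_spec(s1s2_spec("antero", s2_interval = 100))
  cv <- run_s1s2_sweep(topo, sw, intervals = c(320, 250, 190, 160))
  cond <- cv[cv$conducted, ]
  expect_gt(nrow(cond), 2)
  expect_equal(cond$h1h2, cond$a2h2 + cond$h1a2, tolerance = 1e-12)
  expect_equal(cond$a1a2, cond$h1a2 + cond$a1h1, tolerance = 1e-12)
  curves <- refractory_and_his_atrial_curves(cv)
  expect_equal(nrow(curves$refractory), nrow(cond))
  expect_equal(curves$refractory$h1h2 - curves$his_atrial$h1a2,
               cond$a2h2, tolerance = 1e-12)
})

test_that("recovery curve is decremental within the fast-pathway branch", {
  topo <- default_topo_cached()
  sw <- sweep_spec(s1s2_spec("antero", s2_interval = 100))
  cv <- run_s1s2_sweep(topo, sw, intervals = seq(340, 180, by = -20))
  fp <- cv[cv$conducted & cv$pathway == "FP", ]
  fp <- fp[order(fp$a1a2), ]
  expect_gt(nrow(fp), 3)
  # A2H2 non-increasing as the coupling interval grows
  expect_true(all(diff(fp$a2h2) <= 1e-9))
})

test_that("His-His statistics reduce to simple interval arithmetic", {
  topo <- default_topo_cached()
  tab <- synthetic_table(data.frame(cell = c("HB6", "HB6"),
                                    time = c(0, 200),
                                    stringsAsFactors = FALSE), topo)
  s <- hh_statistics(tab)
  expect_equal(s$mean_hh, 200)
  expect_equal(s$rate_bpm, 300)
  one <- synthetic_table(data.frame(cell = "HB6", time = 0,
                                    stringsAsFactors = FALSE), topo)
  expect_error(hh_statistics(one), "fewer than two")
})

test_that("Wenckebach analysis recovers a synthetic 5:4 block pattern", {
  topo <- default_topo_cached()
  # atrial beats every 125 ms; every 5th one blocked; AH grows within the
  # block, His beats follow the conducted atrial beats
  rows <- list()
  t <- 0
  for (cyc in 0:7) {
    for (b in 0:4) {
      at <- (cyc * 5 + b) * 125
      rows[[length(rows) + 1]] <- data.frame(cell = "AM3", time = at)
      if (b < 4) {
        ah <- 150 + 25 * b
        rows[[length(rows) + 1]] <- data.frame(cell = "HB6",
                                               time = at + ah)
      }
    }
  }
  tab <- synthetic_table(do.call(rbind, rows), topo)
  w <- wenckebach_analysis(tab, 125)
  expect_equal(w$ratio, c(5L, 4L))
  # AH increases within each block
  ah <- w$ah$ah
  blocks <- split(ah, cumsum(c(TRUE, diff(ah) < 0)))
  expect_true(all(vapply(blocks, function(x) all(diff(x) > 0) || length(x) == 1,
                         logical(1))))
})

test_that("reentry detection distinguishes tachycardia from escape rhythm", {
  topo <- default_topo_cached()
  sch <- stimulus_schedule(stimulus_impulse("AM1", 0), horizon = 2000)
  # four SP-led cycles at 220 ms with atrial re-activation in between
  mk_cycle <- function(t0) data.frame(
    cell = c("SP10", "PB", "HB6", "AM3"),
    time = t0 + c(-3, 0, 40, 60), stringsAsFactors = FALSE)
  tab <- synthetic_table(do.call(rbind, lapply(c(300, 520, 740, 960),
                                               mk_cycle)), topo)
  out <- detect_avnrt(tab, sch)
  expect_true(out$reentrant)
  expect_gte(out$n_cycles, 3)
  expect_equal(out$cycle_length, 220, tolerance = 1e-9)
  # FP-led (sinus-like) beats are not reentry
  mk_sinus <- function(t0) data.frame(
    cell = c("FP8", "PB", "HB6", "AM3"),
    time = t0 + c(-3, 0, 40, -40), stringsAsFactors = FALSE)
  tab2 <- synthetic_table(do.call(rbind, lapply(c(400, 760, 1120, 1480),
                                                mk_sinus)), topo)
  out2 <- detect_avnrt(tab2, sch)
  expect_false(out2$reentrant)
  # a slow SP-led escape rhythm (cycle > 350 ms) is not tachycardia
  tab3 <- synthetic_table(do.call(rbind, lapply(c(400, 1000, 1600),
                                                mk_cycle)), topo)
  expect_false(detect_avnrt(tab3, sch)$reentrant)
})
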