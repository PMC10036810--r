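test_that("default network has the documented 33-cell two-row layout", {
  topo <- default_topo_cached()
  labs <- avn_cell_labels()
  expect_equal(nrow(topo$cells), 33)
  expect_length(labs$upper, 22)
  expect_length(labs$lower, 11)
  expect_setequal(topo$cells$label, labs$all)
  # open chain along the upper row, two vertical junctions, one AM* link
  jn <- topo$junctions
  expect_equal(nrow(jn), 21 + 1 + 9 + 1 + 1)
  expect_true(all(c("AM3", "SP10", "AM*") %in% jn$from))
  # pacemaking cells are exactly the documented set
  expect_setequal(topo$cells$label[topo$cells$a1 < 0],
                  avn_pacemaker_labels())
})

test_that("configuration validation names the offending cell", {
  cfg <- default_config()
  cfg$cells <- cfg$cells[cfg$cells$label != "SP4", ]
  expect_error(build_topology(cfg), "SP4")
  cfg2 <- default_config()
  cfg2$junctions$d[3] <- -5
  expect_error(build_topology(cfg2), "negative coupling")
  cfg3 <- default_config()
  cfg3$junctions$alpha[5] <- 0
  expect_error(build_topology(cfg3), "alpha")
})

test_that("coupling currents follow the asymmetric discrete diffusion law", {
  pair <- toy_pair(d = 10, alpha = 1)
  expect_equal(unname(coupling_currents(c(1, 0), pair)), c(-10, 10))
  # uniform potential diffuses nothing for symmetric coupling
  expect_equal(unname(coupling_currents(c(0.4, 0.4), pair)), c(0, 0))
  # asymmetric pair: 10 * (-1 + 0.8 * 0.5) = -6 on the upstream cell
  pair2 <- toy_pair(d = 10, alpha = 0.8)
  expect_equal(unname(coupling_currents(c(1, 0.5), pair2)), c(-6, 6))
})

test_that("coupling currents conserve charge pairwise for any alpha", {
  topo <- default_topo_cached()
  set.seed(42)
  for (i in 1:20) {
    t2 <- topo
    t2$junctions$alpha <- runif(nrow(t2$junctions), 0.3, 1.5)
    u <- runif(nrow(t2$cells))
    expect_equal(sum(coupling_currents(u, t2)), 0, tolerance = 1e-12)
  }
})

test_that("asymmetric coupling with alpha = 1 reduces to plain diffusion", {
  topo <- default_topo_cached()
  t1 <- topo
  t1$junctions$alpha <- 1
  set.seed(7)
  u <- runif(33)
  got <- coupling_currents(u, t1)
  # independent evaluation of the symmetric law
  expected <- stats::setNames(numeric(33), t1$cells$label)
  for (r in seq_len(nrow(t1$junctions))) {
    i <- t1$junctions$from[r]; j <- t1$junctions$to[r]
    d <- t1$junctions$d[r]
    ui <- u[match(i, t1$cells$label)]
    uj <- u[match(j, t1$cells$label)]
    expected[[i]] <- expected[[i]] + d * (uj - ui)
    expected[[j]] <- expected[[j]] + d * (ui - uj)
  }
  expect_equal(got, expected)
})

test_that("ablation zeroes exactly the documented junction", {
  topo <- default_topo_cached()
  fp <- apply_ablation(topo, "FP")
  r <- fp$junctions$from == "FP5" & fp$junctions$to == "FP6"
  expect_equal(fp$junctions$d[r], 0)
  expect_equal(fp$junctions$d[!r], topo$junctions$d[!r])
  expect_identical(fp$cells, topo$cells)  # states/parameters untouched
  sp <- apply_ablation(topo, "SP")
  expect_equal(sp$junctions$d[sp$junctions$from == "SP6" &
                                sp$junctions$to == "SP7"], 0)
  both <- apply_ablation(topo, "both")
  expect_equal(sum(both$junctions$d == 0), 2)
  expect_error(apply_ablation(topo, "XX"))
})

test_that("silencing the sinus node flips only its thresholds", {
  topo <- default_topo_cached()
  s <- silence_sn(topo)
  expect_identical(s$junctions, topo$junctions)
  expect_gt(s$cells$a1[s$cells$label == "SN"], 0)
  other <- s$cells$label != "SN"
  expect_identical(s$cells[other, ], topo$cells[other, ])
  expect_identical(silence_sn(s), s)  # idempotent
})

test_that("junction table export has the documented columns", {
  topo <- default_topo_cached()
  path <- tempfile(fileext = ".csv")
  junction_table(topo, path)
  got <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(got), c("from", "to", "d", "alpha"))
  expect_equal(nrow(got), nrow(topo$junctions))
})
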