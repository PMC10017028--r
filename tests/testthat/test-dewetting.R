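make_series <- function(t50s, baselines, tdw_grid = seq(250, 400, 25),
                        n_frames = 40, width = 5, seed = 3) {
  n <- length(t50s)
  sys <- build_fame_topology(0, substr(strrep("GV", n), 1, n),
                             include_lipid = FALSE, seed = 1)
  hm <- hydration_model(baselines, t50s, width)
  list(sys = sys, hm = hm,
       series = simulate_annealing_series(sys, hm, tdw_grid, n_frames,
                                          seed = seed))
}

test_that("the printed annealing protocol is self-consistent", {
  expect_true(validate_schedule(annealing_schedule(250, 400, 1 / 20, 3000)))
  expect_false(suppressMessages(
    validate_schedule(annealing_schedule(250, 400, 1 / 20, 1000))))
  expect_error(annealing_schedule(250, 250, 1 / 20, 0), "exceed")
  expect_error(annealing_schedule(250, 400, 0, 3000), "positive")
})

test_that("temperature-independent occupancy normalizes to all ones", {
  fx <- make_series(t50s = rep(1e5, 6), baselines = rep(6, 6),
                    tdw_grid = c(250, 300, 350), n_frames = 80)
  om <- occupancy_matrix(fx$series)
  expect_true(all(abs(om$normalized - 1) < 0.25))
  expect_equal(unname(om$normalized[, 1]), rep(1, 6))
  # baseline column dehydrates nobody
  expect_equal(unname(percent_dehydrated_curve(om)[1]), 0)
})

test_that("dry-at-baseline residues are flagged and excluded", {
  fx <- make_series(t50s = rep(330, 5), baselines = c(6, 6, 0, 6, 6),
                    tdw_grid = c(250, 300, 350), n_frames = 40)
  om <- occupancy_matrix(fx$series)
  expect_true(om$baseline_flags[3])
  expect_error(residue_dewetting_temperature(om, om$residues[3]),
               "not hydrated")
  expect_true(all(is.na(om$normalized[3, ])))
})

test_that("dewetting temperature interpolates between bracketing grid points", {
  om <- structure(list(
    residues = 0L, tdw_grid = c(300, 320),
    raw = matrix(c(5, 2), 1), normalized = matrix(c(1.0, 0.4), 1),
    baseline_flags = FALSE, min_baseline = 1), class = "OccupancyMatrix")
  expect_equal(residue_dewetting_temperature(om, 0, theta = 0.5),
               300 + 20 * 0.5 / 0.6, tolerance = 1e-6)  # 316.667 K
  # interpolated value lies inside the bracketing interval
  tv <- residue_dewetting_temperature(om, 0, 0.5)
  expect_true(tv > 300 && tv < 320)
  # a row that never crosses theta returns the sentinel
  om$normalized <- matrix(c(1, 0.95), 1)
  expect_identical(residue_dewetting_temperature(om, 0, 0.5), Inf)
})

test_that("normalized occupancy decreases with T_dw on logistic fixtures", {
  fx <- make_series(t50s = rep(325, 6), baselines = rep(7, 6),
                    tdw_grid = seq(250, 400, 25), n_frames = 100)
  om <- occupancy_matrix(fx$series)
  for (r in seq_len(6)) {
    rho <- suppressWarnings(
      cor(om$tdw_grid, om$normalized[r, ], method = "spearman"))
    expect_lt(rho, 0)
  }
})

test_that("percent dehydrated splits planted T50 groups and is monotone in theta", {
  # 3 of 10 residues dewet early (T50 = 280), the rest late (T50 = 380)
  fx <- make_series(t50s = c(rep(280, 3), rep(380, 7)),
                    baselines = rep(6, 10),
                    tdw_grid = seq(250, 400, 10), n_frames = 60)
  om <- occupancy_matrix(fx$series)
  curve <- percent_dehydrated_curve(om, theta = 0.5)
  mid <- which.min(abs(om$tdw_grid - 330))  # between the two T50 groups
  expect_equal(unname(curve[mid]), 30)
  # non-increasing in theta at fixed T_dw
  for (tdw_col in c(3, 8, 12)) {
    vals <- vapply(c(0.8, 0.5, 0.2), function(th)
      unname(percent_dehydrated_curve(om, th)[tdw_col]), numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
  # roughly non-decreasing in T_dw
  expect_gte(unname(curve[length(curve)]), unname(curve[1]))
})

test_that("dewetting maps stack matching curves and reject mismatches", {
  c1 <- structure(setNames(c(0, 50, 100), c(250, 300, 350)),
                  tdw_grid = c(250, 300, 350))
  map1 <- assemble_dewetting_map(list(c1), tmd_grid = 250)
  expect_equal(dim(map1$percent), c(1, 3))
  expect_equal(unname(map1$percent[1, ]), unname(as.numeric(c1)))
  map2 <- assemble_dewetting_map(list(c1, c1), tmd_grid = c(250, 300))
  expect_equal(map2$percent[1, ], map2$percent[2, ])
  c2 <- structure(setNames(c(0, 100), c(250, 350)),
                  tdw_grid = c(250, 350))
  expect_error(assemble_dewetting_map(list(c1, c2), c(250, 300)),
               "share")
  tab <- dewetting_map_table(map2)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$percent_dehydrated >= 0 &
                    tab$percent_dehydrated <= 100))
})

test_that("hydropathy scores rescale dewetting temperatures onto [0, 1]", {
  tdw <- c(a = 250, b = 400, c = Inf, d = 325)
  sc <- hydropathy_scores(tdw)
  expect_equal(unname(sc), c(0, 1, 1, 0.5))
  expect_warning(hydropathy_scores(c(Inf, Inf)), "degenerate")
})

test_that("residues near the lipid score as the hydrophobic patch", {
  # planted low T50 (early dewetting) for the 5 residues nearest the lipid
  n <- 20
  t50 <- c(rep(275, 5), rep(370, n - 5))
  fx <- make_series(t50s = t50, baselines = rep(6, n),
                    tdw_grid = seq(250, 400, 10), n_frames = 60)
  om <- occupancy_matrix(fx$series)
  sc <- hydropathy_scores(dewetting_temperatures(om))
  expect_lt(mean(sc[1:5]), mean(sc[(n - 4):n]))
})

test_that("occupancy matrix rejects malformed series", {
  fx <- make_series(t50s = rep(325, 4), baselines = rep(5, 4),
                    tdw_grid = c(250, 300), n_frames = 5)
  expect_error(occupancy_matrix(fx$series[1]), "at least 2")
  rev_series <- fx$series[c(2, 1)]
  expect_error(occupancy_matrix(rev_series), "ascending|sorted")
  dup <- fx$series
  dup[[2]]$t_dw <- 250
  expect_error(occupancy_matrix(dup), "duplicate")
  empty <- simulate_annealing_series(fx$sys, fx$hm, c(250, 300),
                                     n_frames = 0, seed = 1)
  expect_error(occupancy_matrix(empty), "empty|undefined")
})
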