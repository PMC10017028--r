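test_that("construct topology has the expected residue architecture", {
  sys <- build_fame_topology(20, seed = 1)
  expect_equal(sys$peptide_length, 120)   # 12 LS + 8 His + 100 ELP
  expect_equal(sum(sys$residues$role == "lipid"), 1)
  myr <- sys$residues[sys$residues$role == "lipid", ]
  expect_equal(myr$last_atom - myr$first_atom + 1L, 14L)  # 14-bead myristoyl
  # degenerate single-residue construct without lipid
  tiny <- build_fame_topology(0, "G", include_lipid = FALSE, seed = 1)
  expect_equal(nrow(tiny$residues), 1)
  expect_false("lipid" %in% tiny$residues$role)
  expect_error(build_fame_topology(-1), ">= 0")
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- build_fame_topology(2, seed = 11)
  s2 <- build_fame_topology(2, seed = 11)
  expect_identical(s1$atoms, s2$atoms)
  hm <- hydration_model(rep(4, 30), rep(320, 30), 5)
  t1 <- simulate_hydration_frames(s1, hm, 300, 3, seed = 9)
  t2 <- simulate_hydration_frames(s2, hm, 300, 3, seed = 9)
  expect_identical(lapply(t1$frames, `[[`, "positions"),
                   lapply(t2$frames, `[[`, "positions"))
  a1 <- simulate_annealing_series(s1, hm, seq(250, 400, 50), n_frames = 2,
                                  seed = 4)
  a2 <- simulate_annealing_series(s1, hm, seq(250, 400, 50), n_frames = 2,
                                  seed = 4)
  expect_identical(lapply(a1, function(s) s$trajectory$frames[[1]]$positions),
                   lapply(a2, function(s) s$trajectory$frames[[1]]$positions))
  d1 <- simulate_dihedral_ensemble(rep("alpha_R", 5), 30, 2, seed = 6)
  d2 <- simulate_dihedral_ensemble(rep("alpha_R", 5), 30, 2, seed = 6)
  expect_identical(d1$frames[[2]]$positions, d2$frames[[2]]$positions)
})

test_that("zero expected occupancy yields zero counted waters", {
  sys <- build_fame_topology(1, "GV", include_lipid = FALSE, seed = 2)
  hm <- hydration_model(rep(0, 7), rep(320, 7), 5)
  traj <- simulate_hydration_frames(sys, hm, 300, 5, n_bulk = 10, seed = 3)
  for (f in traj$frames)
    expect_equal(count_chain_waters(f, traj$system), 0)
})

test_that("ground-truth metadata matches an independent recount exactly", {
  sys <- build_fame_topology(3, seed = 5)
  n <- sys$peptide_length
  set.seed(41)
  hm <- hydration_model(runif(n, 2, 7), runif(n, 280, 360), 5)
  traj <- simulate_hydration_frames(sys, hm, 320, 50, seed = 21)
  for (f in traj$frames) {
    expect_identical(unname(residue_water_counts(f, traj$system)),
                     unname(f$truth$per_residue))
    expect_identical(as.numeric(count_chain_waters(f, traj$system)),
                     as.numeric(f$truth$chain))
  }
})

test_that("mean recovered count at the logistic midpoint is half baseline", {
  sys <- build_fame_topology(1, "GVGVP", include_lipid = FALSE, seed = 2)
  hm <- hydration_model(rep(8, 10), rep(325, 10), 5)
  traj <- simulate_hydration_frames(sys, hm, temperature = 325,
                                    n_frames = 200, seed = 13)
  counts <- vapply(traj$frames, residue_water_counts,
                   numeric(10), traj$system)
  m <- mean(counts)           # per residue-frame; expected 4
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - 4), 3 * se)
})

test_that("annealing series dewets: low-T occupancy exceeds high-T", {
  sys <- build_fame_topology(1, "GVGVP", include_lipid = FALSE, seed = 2)
  hm <- hydration_model(rep(6, 10), rep(325, 10), 5)
  ser <- simulate_annealing_series(sys, hm, tdw_grid = c(250, 400),
                                   n_frames = 30, seed = 17)
  m <- vapply(ser, function(s)
    mean(vapply(s$trajectory$frames, count_chain_waters, integer(1),
                s$trajectory$system)), numeric(1))
  expect_gt(m[1], m[2])
  # solute coordinates identical across the series (restrained)
  sol <- which(ser[[1]]$trajectory$system$atoms$role != "water")
  expect_identical(ser[[1]]$trajectory$frames[[1]]$positions[sol, ],
                   ser[[2]]$trajectory$frames[[1]]$positions[sol, ])
  expect_error(simulate_annealing_series(sys, hm, c(300, 300), 2, seed = 1),
               "ascending")
})

test_that("noiseless scans reproduce the linear model exactly", {
  sys <- build_fame_topology(6, include_lipid = FALSE, seed = 2)
  sm <- scan_model(100, -0.2, -4, 0.05, noise_sd = 0)
  temps <- c(280, 300, 320)
  sc <- simulate_temperature_scan(sys, sm, temps, n_frames = 4, seed = 3)
  for (k in seq_along(temps)) {
    tr <- sc[[k]]$trajectory
    nw <- vapply(tr$frames, count_chain_waters, integer(1), tr$system)
    np <- vapply(tr$frames, count_intrachain_contacts, integer(1),
                 tr$system)
    expect_true(all(nw == round(100 - 0.2 * temps[k])))
    expect_true(all(np == round(-4 + 0.05 * temps[k])))
  }
})

test_that("scan ground truth equals recounts; infeasible models error", {
  sys <- build_fame_topology(6, include_lipid = FALSE, seed = 2)
  sm <- scan_model(120, -0.25, -3, 0.045, noise_sd = 2)
  sc <- simulate_temperature_scan(sys, sm, seq(280, 330, 10),
                                  n_frames = 10, seed = 31)
  for (s in sc) for (f in s$trajectory$frames) {
    expect_equal(count_chain_waters(f, s$trajectory$system), f$truth$nw)
    expect_equal(count_intrachain_contacts(f, s$trajectory$system),
                 f$truth$npp)
  }
  # negative expected water count over the range
  bad <- scan_model(50, -0.2, 0, 0.01)
  expect_error(simulate_temperature_scan(sys, bad, c(280, 300), 2,
                                         seed = 1), "negative")
})

test_that("dihedral ensembles rebuild to the drawn angles", {
  cls <- rep(c("alpha_R", "beta", "coil"), times = c(4, 4, 4))
  traj <- simulate_dihedral_ensemble(cls, kappa = 30, n_frames = 5,
                                     seed = 19)
  ds <- backbone_dihedrals(traj)
  for (fi in seq_len(5)) {
    tr <- traj$frames[[fi]]$truth
    expect_lt(max(abs(ds$phi[fi, -1] - tr$phi[-1])), 1e-3)
    expect_lt(max(abs(ds$psi[fi, -12] - tr$psi[-12])), 1e-3)
  }
  # coil angles lie in (-180, 180]
  one <- simulate_dihedral_ensemble(rep("coil", 6), 1, 1, seed = 2)
  ang <- c(one$frames[[1]]$truth$phi, one$frames[[1]]$truth$psi)
  ang <- ang[!is.na(ang)]
  expect_true(all(ang > -180 & ang <= 180))
  expect_error(simulate_dihedral_ensemble(c("alpha_R", "spiral", "coil"),
                                          10, 1, seed = 1), "spiral")
})

test_that("high concentration pins nearly all residue-frames in the box", {
  traj <- simulate_dihedral_ensemble(rep("alpha_R", 10), kappa = 400,
                                     n_frames = 40, seed = 23)
  ds <- backbone_dihedrals(traj)
  cls <- classify_conformation(as.vector(ds$phi), as.vector(ds$psi))
  cls <- cls[!is.na(cls)]
  expect_gte(mean(cls == "alpha_R"), 0.95)
})

test_that("expected occupancy is non-increasing in temperature", {
  set.seed(7)
  hm <- hydration_model(runif(20, 1, 9), runif(20, 260, 390), 5)
  temps <- seq(250, 400, 5)
  occ <- vapply(temps, function(tt) expected_occupancy(hm, tt),
                numeric(20))
  expect_true(all(apply(occ, 1, function(r) all(diff(r) <= 0))))
})
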