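backbone_traj <- function(phi, psi) {
  n <- length(phi)
  bb <- famedew:::build_backbone_coords(phi, psi)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) data.frame(
    name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    residue_index = i - 1L, residue_name = "ALA", role = "elp",
    x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
    y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
    z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]))))
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  sys <- labeled_system(atoms)
  new_trajectory(sys, list(new_frame(as.matrix(atoms[, c("x", "y", "z")]))))
}

test_that("chains built at specified dihedrals measure back those angles", {
  phi <- c(NA, -75, -120, 60, 150, -60)
  psi <- c(-50, 130, 40, -170, 60, NA)
  traj <- backbone_traj(phi, psi)
  ds <- backbone_dihedrals(traj)
  expect_lt(max(abs(ds$phi[1, -1] - phi[-1])), 1e-3)
  expect_lt(max(abs(ds$psi[1, -6] - psi[-6])), 1e-3)
  expect_true(is.na(ds$phi[1, 1]))
  expect_true(is.na(ds$psi[1, 6]))
  # fully extended chain measures 180
  ext <- backbone_traj(rep(180, 5), rep(180, 5))
  de <- backbone_dihedrals(ext)
  expect_lt(max(abs(abs(de$phi[1, -1]) - 180)), 1e-3)
})

test_that("dihedrals are invariant under rigid motion, negated by mirroring", {
  traj <- backbone_traj(c(NA, -75, 60, 140), c(-50, 130, -40, NA))
  base <- backbone_dihedrals(traj)
  R <- rotation_matrix(1.2, -0.4, 0.9)
  moved <- new_trajectory(traj$system, list(new_frame(
    traj$frames[[1]]$positions %*% t(R) +
      matrix(c(3, -8, 2), nrow(traj$frames[[1]]$positions), 3,
             byrow = TRUE))))
  got <- backbone_dihedrals(moved)
  expect_lt(max(abs(got$phi[1, -1] - base$phi[1, -1])), 1e-6)
  expect_lt(max(abs(got$psi[1, -4] - base$psi[1, -4])), 1e-6)

  mirrored <- new_trajectory(traj$system, list(new_frame(
    traj$frames[[1]]$positions %*% diag(c(-1, 1, 1)))))
  neg <- backbone_dihedrals(mirrored)
  expect_lt(max(abs(neg$phi[1, -1] + base$phi[1, -1])), 1e-6)
  expect_lt(max(abs(neg$psi[1, -4] + base$psi[1, -4])), 1e-6)
})

test_that("missing backbone atoms raise a topology error naming the residue", {
  traj <- backbone_traj(c(NA, -75, 60), c(-50, 130, NA))
  atoms <- traj$system$atoms
  atoms <- atoms[!(atoms$residue_index == 1 & atoms$name == "CA"), ]
  sys <- labeled_system(atoms)
  tr2 <- new_trajectory(sys, list(new_frame(
    as.matrix(atoms[, c("x", "y", "z")]))))
  expect_error(backbone_dihedrals(tr2), "residue 1.*CA")
})

test_that("classification matches the region boxes", {
  expect_equal(classify_conformation(-75, -50), "alpha_R")
  expect_equal(classify_conformation(-120, 150), "beta")
  expect_equal(classify_conformation(0, 0), "other")
  expect_equal(classify_conformation(65, 40), "alpha_L")
  # closed interval edges belong to the box
  expect_equal(classify_conformation(-100, -70), "alpha_R")
  expect_equal(classify_conformation(c(-75, 10), c(-50, 10)),
               c("alpha_R", "other"))
  expect_true(is.na(classify_conformation(NA, 10)))
})

test_that("overlapping user-supplied regions are a configuration error", {
  bad <- data.frame(label = c("a", "b"),
                    phi_lo = c(-100, -80), phi_hi = c(-50, -20),
                    psi_lo = c(-70, -50), psi_hi = c(-30, 0))
  expect_error(rama_regions(bad), "overlap")
  expect_error(classify_conformation(0, 0, regions = bad), "overlap")
})

test_that("region occupancies are probability vectors that recover planting", {
  traj <- simulate_dihedral_ensemble(rep("alpha_R", 8), kappa = 500,
                                     n_frames = 30, seed = 3)
  occ <- region_occupancy(backbone_dihedrals(traj), window = 1)
  sums <- rowSums(occ[, c("alpha_R", "beta", "alpha_L", "other")])
  expect_equal(sums[!is.na(sums)], rep(1, sum(!is.na(sums))))
  interior <- !is.na(occ$alpha_R)
  expect_true(all(occ$alpha_R[interior] > 0.9))
})

test_that("planted 70/30 alpha/coil mixtures are recovered at scale", {
  # alternate alpha_R frames and coil frames via a per-residue mixture:
  # use kappa high so alpha draws stay in the box, and coil residues as
  # uniform background
  n_frames <- 800
  traj <- simulate_dihedral_ensemble(rep("alpha_R", 6), kappa = 1e4,
                                     n_frames = n_frames, seed = 11)
  ds <- backbone_dihedrals(traj)
  occ <- region_occupancy(ds, window = 1)
  interior <- !is.na(occ$alpha_R)
  # concentrated ensembles: alpha fraction ~ 1 within 0.05
  expect_true(all(abs(occ$alpha_R[interior] - 1) < 0.05))
  coil <- simulate_dihedral_ensemble(rep("coil", 6), kappa = 1,
                                     n_frames = n_frames, seed = 12)
  occ2 <- region_occupancy(backbone_dihedrals(coil), window = 1)
  interior2 <- !is.na(occ2$alpha_R)
  # uniform angles fall in the alpha box at its area fraction ~ 50*40/360^2
  area <- (50 * 40) / 360^2
  expect_true(all(abs(occ2$alpha_R[interior2] - area) < 0.05))
})

test_that("the dihedral histogram accounts for every residue-frame", {
  traj <- simulate_dihedral_ensemble(rep(c("alpha_R", "coil"), 4),
                                     kappa = 50, n_frames = 25, seed = 9)
  ds <- backbone_dihedrals(traj)
  h <- dihedral_histogram(ds, bins = 36)
  expect_equal(dim(h), c(36, 36))
  expect_equal(sum(h), sum(!is.na(ds$phi) & !is.na(ds$psi)))
})

test_that("measured dihedrals agree with an independent torsion routine", {
  skip_if_not_installed("bio3d")
  set.seed(5)
  pts <- matrix(rnorm(12, sd = 3), 4, 3)
  mine <- dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
  ref <- bio3d::torsion.xyz(as.vector(t(pts)), atm.inc = 4)
  expect_equal(mine, unname(ref[!is.na(ref)][1]), tolerance = 1e-6)
})
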