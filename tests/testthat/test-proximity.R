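test_that("waters at and beyond the cutoff are excluded (strict <)", {
  ps <- point_system(matrix(c(0, 0, 0), 1, 3),
                     wat_pos = rbind(c(3.15, 0, 0),     # exactly at cutoff
                                     c(3.149, 0, 0),    # just inside
                                     c(10, 0, 0)))      # far
  expect_equal(count_chain_waters(ps$frame, ps$system), 1)
  # no waters at all
  ps0 <- point_system(matrix(0, 1, 3))
  expect_equal(count_chain_waters(ps0$frame, ps0$system), 0)
})

test_that("a shared water counts once per residue but once for the chain", {
  # water equidistant (3.0 A) from residues at x = -3 and x = +3
  ps <- point_system(rbind(c(-3, 0, 0), c(3, 0, 0)),
                     wat_pos = matrix(c(0, 0, 0), 1, 3))
  per <- residue_water_counts(ps$frame, ps$system)
  expect_equal(unname(per), c(1, 1))
  expect_equal(count_chain_waters(ps$frame, ps$system), 1)
  expect_gte(sum(per), count_chain_waters(ps$frame, ps$system))
})

test_that("cell-list counts match the brute-force oracle with and without a box", {
  for (seed in 1:25) {
    box <- if (seed %% 2 == 0) c(16, 18, 17) else NULL
    ps <- random_water_system(n_res = 25, n_wat = 60, box = box,
                              seed = seed)
    got <- residue_water_counts(ps$frame, ps$system)
    oracle <- oracle_water_counts(ps$frame, ps$system)
    expect_identical(unname(got), unname(oracle$per_residue))
    expect_identical(count_chain_waters(ps$frame, ps$system),
                     oracle$chain)
    expect_identical(count_intrachain_contacts(ps$frame, ps$system),
                     oracle_contacts(ps$frame, ps$system))
  }
})

test_that("an extended chain has no contacts at separation >= 3", {
  bb <- famedew:::build_backbone_coords(rep(180, 20), rep(180, 20))
  atoms <- do.call(rbind, lapply(1:20, function(i) data.frame(
    name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    residue_index = i - 1L, residue_name = "GLY", role = "elp",
    x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
    y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
    z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]))))
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  sys <- labeled_system(atoms)
  fr <- new_frame(as.matrix(atoms[, c("x", "y", "z")]))
  expect_equal(count_intrachain_contacts(fr, sys), 0)
})

test_that("sequence neighbors within range are filtered out", {
  # residues 0 and 1 are 4 A apart: separation 1 < 3, not a contact;
  # residues 0 and 3 are 5 A apart: counted
  ps <- point_system(rbind(c(0, 0, 0), c(4, 0, 0), c(40, 0, 0),
                           c(0, 5, 0)))
  expect_equal(count_intrachain_contacts(ps$frame, ps$system), 1)
  # relaxing the separation filter picks up the neighbor pair too
  loose <- shell_params(min_sequence_separation = 1)
  expect_equal(count_intrachain_contacts(ps$frame, ps$system, loose), 2)
})

test_that("counts are invariant under rigid motion, and PBC-translation", {
  ps <- random_water_system(n_res = 15, n_wat = 40, seed = 99)
  base_w <- count_chain_waters(ps$frame, ps$system)
  base_c <- count_intrachain_contacts(ps$frame, ps$system)
  R <- rotation_matrix(0.3, -1.1, 2.2)
  moved <- new_frame(ps$frame$positions %*% t(R) +
                       matrix(c(5, -3, 11), nrow(ps$frame$positions), 3,
                              byrow = TRUE))
  expect_equal(count_chain_waters(moved, ps$system), base_w)
  expect_equal(count_intrachain_contacts(moved, ps$system), base_c)

  box <- c(16, 18, 17)
  psb <- random_water_system(n_res = 15, n_wat = 40, box = box, seed = 7)
  bw <- count_chain_waters(psb$frame, psb$system)
  bc <- count_intrachain_contacts(psb$frame, psb$system)
  shifted <- new_frame(sweep(psb$frame$positions, 2, c(7.3, -4.1, 23.9),
                             "+"), box = box)
  expect_equal(count_chain_waters(shifted, psb$system), bw)
  expect_equal(count_intrachain_contacts(shifted, psb$system), bc)
})

test_that("counts are non-decreasing in the cutoff", {
  ps <- random_water_system(n_res = 20, n_wat = 50, seed = 4)
  cuts <- c(2.5, 3.15, 4, 5)
  w <- vapply(cuts, function(cc)
    count_chain_waters(ps$frame, ps$system,
                       shell_params(water_cutoff = cc)), integer(1))
  expect_true(all(diff(w) >= 0))
  ccuts <- c(4, 5, 6, 7.5)
  k <- vapply(ccuts, function(cc)
    count_intrachain_contacts(ps$frame, ps$system,
                              shell_params(contact_cutoff = cc)),
    integer(1))
  expect_true(all(diff(k) >= 0))
})

test_that("cutoff must stay below half the smallest box edge", {
  ps <- random_water_system(n_res = 5, n_wat = 5, box = c(6, 20, 20),
                            seed = 2)
  expect_error(count_chain_waters(ps$frame, ps$system), "half the smallest")
})

test_that("oxygen-free waters are a topology error under water_oxygen counting", {
  rows <- data.frame(serial = 1:2, name = c("CA", "HW"),
                     element = c("C", "H"), residue_index = c(0L, 1L),
                     residue_name = c("GLY", "HOH"),
                     role = c("elp", "water"), x = c(0, 2), y = 0, z = 0)
  sys <- labeled_system(rows)
  fr <- new_frame(as.matrix(rows[, c("x", "y", "z")]))
  expect_error(count_chain_waters(fr, sys), "oxygen")
  # any_water_atom mode accepts it
  expect_equal(count_chain_waters(fr, sys,
                                  shell_params(counting_atom = "any_water_atom")),
               1)
})

test_that("series statistics give mean, population sd and n", {
  ps <- point_system(matrix(0, 2, 3))
  frames <- lapply(1:10, function(i) new_frame(ps$frame$positions,
                                               time = i))
  traj <- new_trajectory(ps$system, frames)
  const <- series_statistics(traj, function(f, s) 7)
  expect_equal(const, list(mean = 7, sd = 0, n = 10))
  vals <- c(1, 2, 3)
  traj3 <- new_trajectory(ps$system,
                          lapply(1:3, function(i) new_frame(ps$frame$positions,
                                                            time = i)))
  st <- series_statistics(traj3, function(f, s) vals[round(f$time)])
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2 / 3))
  expect_error(series_statistics(new_trajectory(ps$system, list()),
                                 function(f, s) 1), "empty")
})

test_that("Poisson occupancy has sd near sqrt(mean) over many frames", {
  sys <- build_fame_topology(1, "GVGVP", include_lipid = FALSE, seed = 5)
  hm <- hydration_model(rep(3, 10), rep(380, 10), 5)
  traj <- simulate_hydration_frames(sys, hm, temperature = 250,
                                    n_frames = 400, n_bulk = 5, seed = 8)
  st <- series_statistics(traj, count_chain_waters)
  expect_lt(abs(st$sd - sqrt(st$mean)) / sqrt(st$mean), 0.2)
})
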