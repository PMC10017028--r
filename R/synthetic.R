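# Synthetic coordinate generators. These emulate the statistical structure
# the downstream analysis assumes -- logistic per-residue dewetting of shell
# occupancy, linear-in-temperature chain-level N_w / N_pp with Gaussian
# frame noise, and Ramachandran-concentrated dihedral ensembles -- without
# any force field or dynamics. Each generator records its drawn ground
# truth as frame metadata so the counting modules can be cross-checked
# against it exactly.

DEFAULT_LS_SEQUENCE <- "GLYASKLFSNLGHHHHHHHH"

#' Logistic per-residue hydration (dewetting) model
#'
#' Expected first-shell occupancy of residue r at dewetting temperature T is
#' `baseline_counts[r] / (1 + exp((T - midpoints[r]) / width))`: the full
#' baseline shell at low T, half lost at the residue's dewetting midpoint
#' T50, and an emptied shell well above it. Hydrophilic residues have high
#' T50 (they need more heat to dewet), hydrophobic ones low T50.
#'
#' @param baseline_counts non-negative expected shell water count per
#'   residue at the low-temperature plateau.
#' @param midpoints per-residue dewetting midpoint T50, K.
#' @param width logistic width w > 0, K (shared).
#' @return object of class `HydrationModel`
#' @export
hydration_model <- function(baseline_counts, midpoints, width) {
  stopifnot(length(baseline_counts) == length(midpoints),
            all(baseline_counts >= 0), width > 0)
  structure(list(baseline_counts = as.numeric(baseline_counts),
                 midpoints = as.numeric(midpoints),
                 width = as.numeric(width)),
            class = "HydrationModel")
}

#' Expected per-residue shell occupancy at a temperature
#' @param model [hydration_model()]
#' @param temperature K
#' @return numeric vector of expected counts
#' @export
expected_occupancy <- function(model, temperature) {
  stopifnot(inherits(model, "HydrationModel"))
  model$baseline_counts /
    (1 + exp((temperature - model$midpoints) / model$width))
}

#' Linear chain-level temperature-scan model
#'
#' Chain-level expected counts are linear in temperature:
#' `N_w(T) = nw_intercept + nw_slope * T` (slope typically negative, the
#' shell sheds water on heating) and
#' `N_pp(T) = npp_intercept + npp_slope * T` (slope typically positive, the
#' chain compacts). Per-frame realizations add Gaussian noise with
#' `noise_sd`, are rounded and clipped at zero.
#'
#' @param nw_intercept,nw_slope waters and waters/K.
#' @param npp_intercept,npp_slope contacts and contacts/K.
#' @param noise_sd standard deviation of the per-frame Gaussian noise.
#' @return object of class `ScanModel`
#' @export
scan_model <- function(nw_intercept, nw_slope, npp_intercept, npp_slope,
                       noise_sd = 0) {
  stopifnot(noise_sd >= 0)
  structure(list(nw_intercept = nw_intercept, nw_slope = nw_slope,
                 npp_intercept = npp_intercept, npp_slope = npp_slope,
                 noise_sd = noise_sd),
            class = "ScanModel")
}

#' Build a coarse FAME construct topology
#'
#' Assembles a lipidation site (default GLYASKLFSNLG followed by an
#' octahistidine tag) fused to `n_pentads` GVGVP elastin-like repeats, with
#' an optional 14-bead myristoyl chain attached at the first residue.
#' Backbone atoms (N, CA, C, O) are placed by ideal internal coordinates
#' with mildly jittered extended dihedrals; each non-glycine residue gets a
#' single pseudo heavy-atom side chain (CB).
#'
#' @param n_pentads number of GVGVP repeats (>= 0).
#' @param ls_sequence one-letter lipidation-site sequence; its length sets
#'   the lipidation-site / ELP boundary.
#' @param include_lipid attach the 14-carbon myristoyl bead chain
#'   (residue name `MYR`, role `lipid`).
#' @param seed RNG seed; coordinates are deterministic given the seed.
#' @return LabeledSystem with reference coordinates
#' @export
build_fame_topology <- function(n_pentads = 20L,
                                ls_sequence = DEFAULT_LS_SEQUENCE,
                                include_lipid = TRUE, seed = 1L) {
  if (n_pentads < 0) stop("n_pentads must be >= 0")
  seq1 <- paste0(ls_sequence, strrep("GVGVP", n_pentads))
  aa <- strsplit(seq1, "")[[1]]
  if (length(aa) == 0) stop("construct sequence is empty")
  bad <- setdiff(aa, names(AA3))
  if (length(bad) > 0)
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  n <- length(aa)

  with_seed(seed, {
    phi <- c(NA, -120 + rnorm(n - 1, 0, 12))
    psi <- c(130 + rnorm(n - 1, 0, 12), NA)
    bb <- build_backbone_coords(phi, psi)

    ridx0 <- if (include_lipid) 1L else 0L
    rows <- vector("list", n + include_lipid)
    if (include_lipid) {
      # myristoyl bead chain extending away from the N terminus
      d <- vunit(bb$N[1, ] - bb$CA[1, ])
      p <- vunit(vcross(d, c(0, 0, 1)))
      k <- seq_len(14)
      beads <- sweep(outer(1.0 + 1.30 * k, d), 2,
                     bb$N[1, ] + rep(0, 3), "+") +
        outer(0.5 * (k %% 2), p)
      rows[[1]] <- data.frame(
        name = paste0("C", k), element = "C", residue_index = 0L,
        residue_name = "MYR", role = "lipid",
        x = beads[, 1], y = beads[, 2], z = beads[, 3],
        stringsAsFactors = FALSE)
    }
    ls_len <- nchar(ls_sequence)
    for (i in seq_len(n)) {
      role <- if (i <= ls_len) "lipidation_site" else "elp"
      nm <- c("N", "CA", "C", "O")
      el <- c("N", "C", "C", "O")
      xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
      if (aa[i] != "G") {
        nm <- c(nm, "CB")
        el <- c(el, "C")
        xyz <- rbind(xyz, t(place_cb(bb$N[i, ], bb$CA[i, ], bb$C[i, ])))
      }
      rows[[i + include_lipid]] <- data.frame(
        name = nm, element = el, residue_index = ridx0 + i - 1L,
        residue_name = unname(AA3[aa[i]]), role = role,
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
    }
    atoms <- do.call(rbind, rows)
    atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
    labeled_system(atoms)
  })
}

# squared distances between rows of A (n x 3) and rows of B (m x 3)
cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

# Append n_wat single-oxygen water residues to a system; positions filled
# per frame.
extend_with_waters <- function(system, n_wat) {
  if (n_wat == 0) return(system)
  r0 <- max(system$atoms$residue_index) + 1L
  s0 <- max(system$atoms$serial)
  wat <- data.frame(
    serial = s0 + seq_len(n_wat), name = "OW", element = "O",
    residue_index = r0 + seq_len(n_wat) - 1L, residue_name = "HOH",
    role = "water", x = 0, y = 0, z = 0, is_heavy = TRUE,
    stringsAsFactors = FALSE)
  labeled_system(rbind(system$atoms, wat[names(system$atoms)]))
}

# Place `draws[r]` waters in the shell [r_in, cutoff) of residue r such that
# each water is within the cutoff of its own residue only (so per-residue
# ground truth equals an independent recount exactly). pep: peptide residue
# table; heavy_xyz/heavy_res: all solute heavy atoms and their residue
# index (-1 for non-peptide solute, used for sterics only).
place_exclusive_shell <- function(draws, pep, heavy_xyz, heavy_res,
                                  cutoff, r_in = 2.4, r_steric = 2.2,
                                  max_rounds = 60L) {
  total <- sum(draws)
  if (total == 0) return(matrix(numeric(0), 0, 3))
  target_res <- rep(pep$residue_index, draws)
  pos <- matrix(NA_real_, total, 3)
  todo <- seq_len(total)
  own_atoms <- split(seq_along(heavy_res), heavy_res)
  for (round in seq_len(max_rounds)) {
    # one candidate per unresolved water, anchored at a random heavy atom
    anchors <- vapply(target_res[todo], function(r) {
      idx <- own_atoms[[as.character(r)]]
      idx[sample.int(length(idx), 1)]
    }, integer(1))
    cand <- heavy_xyz[anchors, , drop = FALSE] +
      runif_shell(length(todo), r_in, cutoff)
    d2 <- cross_dist2(cand, heavy_xyz)
    ok <- logical(length(todo))
    for (k in seq_along(todo)) {
      other <- heavy_res != target_res[todo[k]]
      ok[k] <- all(d2[k, other] >= cutoff^2) && all(d2[k, ] >= r_steric^2)
    }
    pos[todo[ok], ] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
    if (length(todo) == 0) break
  }
  if (length(todo) > 0)
    stop("infeasible shell water placement after ", max_rounds,
         " retry rounds (", length(todo), " waters unplaced)")
  pos
}

# Bulk water positions strictly farther than cutoff + margin from every
# solute atom: a random far annulus around the solute centroid.
place_bulk <- function(n, solute_xyz, cutoff, margin = 1.0) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  ctr <- colMeans(solute_xyz)
  rmax <- sqrt(max(cross_dist2(matrix(ctr, 1), solute_xyz)))
  r0 <- rmax + cutoff + margin + 0.5
  dir <- runif_shell(n, r0, r0 + 15)
  sweep(dir, 2, ctr, "+")
}

#' Simulate first-hydration-shell frames at one temperature
#'
#' Per frame, per peptide residue, a shell water count is drawn from
#' `Poisson(expected occupancy at temperature)` and that many waters are
#' placed uniformly in the spherical shell r in [2.4, 3.15) Angstrom around
#' a randomly chosen heavy atom of the residue, rejected until they fall
#' outside every other residue's shell; bulk waters are placed beyond the
#' cutoff plus a margin from all solute atoms. Solute coordinates stay at
#' the system's reference positions (the restrained-solute setting of a
#' dewetting run). The drawn counts are stored as frame `truth`.
#'
#' @param system LabeledSystem (peptide roles assigned, no waters).
#' @param model [hydration_model()] with one entry per peptide residue.
#' @param temperature K.
#' @param n_frames number of frames (0 gives an empty trajectory).
#' @param box optional orthorhombic box edges, Angstrom; must be large
#'   enough to hold the solute plus the bulk shell.
#' @param n_bulk bulk (non-shell) waters per frame.
#' @param seed RNG seed.
#' @param params [shell_params()]; its `water_cutoff` is the shell radius.
#' @return Trajectory over `system` extended with single-oxygen waters
#' @export
simulate_hydration_frames <- function(system, model, temperature, n_frames,
                                      box = NULL, n_bulk = 30L, seed = 1L,
                                      params = shell_params()) {
  stopifnot(inherits(system, "LabeledSystem"),
            inherits(model, "HydrationModel"))
  pep <- peptide_residues(system)
  if (nrow(pep) != length(model$baseline_counts))
    stop("model has ", length(model$baseline_counts),
         " residues but system has ", nrow(pep), " peptide residues")
  if (any(system$atoms$role == "water"))
    stop("system already contains waters")
  cutoff <- params$water_cutoff

  at <- system$atoms
  heavy <- at$is_heavy
  heavy_xyz <- as.matrix(at[heavy, c("x", "y", "z")])
  heavy_res <- ifelse(at$role[heavy] %in% PEPTIDE_ROLES,
                      at$residue_index[heavy], -1L)

  btot <- sum(model$baseline_counts)
  cap <- ceiling(btot + 6 * sqrt(max(btot, 1)) + 5)
  n_wat <- cap + n_bulk
  ext <- extend_with_waters(system, n_wat)

  shift <- c(0, 0, 0)
  if (!is.null(box)) {
    ctr <- colMeans(heavy_xyz)
    rmax <- sqrt(max(cross_dist2(matrix(ctr, 1), heavy_xyz)))
    need <- 2 * (rmax + cutoff + 18)
    if (any(box < need))
      stop("box too small to hold system plus bulk waters (need >= ",
           round(need, 1), " Angstrom per edge)")
    shift <- box / 2 - ctr
  }

  sol_xyz <- as.matrix(at[, c("x", "y", "z")])
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(fi) {
      lam <- expected_occupancy(model, temperature)
      draws <- rpois(length(lam), lam)
      over <- sum(draws) - cap
      while (over > 0) {  # capacity cap; truth records what is placed
        j <- which.max(draws)
        draws[j] <- draws[j] - 1L
        over <- over - 1L
      }
      shell <- place_exclusive_shell(draws, pep, heavy_xyz, heavy_res,
                                     cutoff)
      bulk <- place_bulk(n_wat - nrow(shell), sol_xyz, cutoff)
      pos <- rbind(sol_xyz, shell, bulk)
      pos <- sweep(pos, 2, shift, "+")
      new_frame(pos, box = box, temperature = temperature, time = fi - 1,
                truth = list(
                  per_residue = setNames(as.numeric(draws),
                                         pep$residue_index),
                  chain = sum(draws)))
    })
  })
  new_trajectory(ext, frames)
}

#' Simulate a restrained-solute annealing series over a dewetting grid
#'
#' One hydration trajectory per dewetting temperature, all sharing the same
#' (restrained) solute coordinates; only the shell occupancy responds to
#' the grid temperature through the logistic model.
#'
#' @param system,model,n_frames,n_bulk,seed,params as in
#'   [simulate_hydration_frames()].
#' @param tdw_grid strictly ascending dewetting temperatures, K
#'   (default 250 to 400 K in 10 K steps).
#' @return list of elements `list(t_dw = <K>, trajectory = <Trajectory>)`
#' @export
simulate_annealing_series <- function(system, model,
                                      tdw_grid = seq(250, 400, by = 10),
                                      n_frames = 50L, n_bulk = 30L,
                                      seed = 1L, params = shell_params()) {
  if (length(tdw_grid) < 1 || any(diff(tdw_grid) <= 0))
    stop("tdw_grid must be strictly ascending")
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                    length(tdw_grid)))
  lapply(seq_along(tdw_grid), function(i) {
    list(t_dw = tdw_grid[i],
         trajectory = simulate_hydration_frames(
           system, model, temperature = tdw_grid[i], n_frames = n_frames,
           n_bulk = n_bulk, seed = sub[i], params = params))
  })
}

#' Simulate an equilibrium temperature scan of chain-level N_w and N_pp
#'
#' Per frame the chain-level water count is
#' `round(nw_intercept + nw_slope * T + N(0, noise_sd))` clipped at zero,
#' realized by placing that many waters in the first shell of random
#' peptide heavy atoms; the contact count is realized by pulling that many
#' disjoint residue pairs (sequence separation >= 3) within the contact
#' cutoff on a widely spaced residue lattice, so that an independent
#' recount reproduces the drawn ground truth exactly.
#'
#' @param system LabeledSystem (no waters).
#' @param model [scan_model()].
#' @param temps simulation temperatures, K.
#' @param n_frames frames per temperature.
#' @param n_bulk bulk waters per frame.
#' @param seed RNG seed.
#' @param params [shell_params()].
#' @return list of elements `list(temperature = <K>, trajectory = ...)`
#' @export
simulate_temperature_scan <- function(system, model, temps, n_frames = 50L,
                                      n_bulk = 20L, seed = 1L,
                                      params = shell_params()) {
  stopifnot(inherits(model, "ScanModel"))
  if (any(system$atoms$role == "water"))
    stop("system already contains waters")
  pep <- peptide_residues(system)
  npep <- nrow(pep)
  exp_nw <- model$nw_intercept + model$nw_slope * temps
  exp_npp <- model$npp_intercept + model$npp_slope * temps
  if (any(exp_nw < 0) || any(exp_npp < 0))
    stop("model slopes produce negative expected counts over temps")
  npp_max <- floor(npep / 2) - 2L
  if (any(exp_npp + 4 * model$noise_sd > npp_max))
    stop("expected contact counts exceed the ", npp_max,
         " disjoint pairs realizable with ", npep, " residues")

  spacing <- 20
  res_all <- system$residues
  at <- system$atoms
  # per-residue atom templates centered at CA (or centroid)
  templates <- lapply(seq_len(nrow(res_all)), function(i) {
    span <- res_all$first_atom[i]:res_all$last_atom[i]
    xyz <- as.matrix(at[span, c("x", "y", "z")])
    ca <- which(at$name[span] == "CA")
    ref <- if (length(ca) == 1) xyz[ca, ] else colMeans(xyz)
    sweep(xyz, 2, ref, "-")
  })
  pep_rows <- which(res_all$role %in% PEPTIDE_ROLES)
  heavy <- at$is_heavy & at$role %in% PEPTIDE_ROLES

  cap_nw <- max(0, ceiling(max(exp_nw) + 6 * model$noise_sd + 5))
  ext <- extend_with_waters(system, cap_nw + n_bulk)

  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1,
                                    length(temps)))
  lapply(seq_along(temps), function(ti) {
    tK <- temps[ti]
    frames <- with_seed(sub[ti], {
      lapply(seq_len(n_frames), function(fi) {
        nw <- max(0L, as.integer(round(model$nw_intercept +
                                         model$nw_slope * tK +
                                         rnorm(1, 0, model$noise_sd))))
        nw <- min(nw, cap_nw)
        npp <- max(0L, as.integer(round(model$npp_intercept +
                                          model$npp_slope * tK +
                                          rnorm(1, 0, model$noise_sd))))
        npp <- min(npp, npp_max)
        pairs <- draw_disjoint_pairs(npep, npp,
                                     params$min_sequence_separation)

        # residues on a line, pulled partners re-homed next to their mate
        slot <- seq_len(nrow(res_all)) - 1
        centers <- cbind(spacing * slot, 0, 0)
        if (npp > 0) {
          for (p in seq_len(nrow(pairs))) {
            i <- pairs[p, 1]; j <- pairs[p, 2]
            centers[pep_rows[j], ] <- centers[pep_rows[i], ] + c(0, 4, 0)
          }
        }
        sol <- do.call(rbind, lapply(seq_len(nrow(res_all)), function(i)
          sweep(templates[[i]], 2, centers[i, ], "+")))

        hx <- sol[which(heavy), , drop = FALSE]
        anchors <- if (nw > 0) sample.int(nrow(hx), nw, replace = TRUE)
          else integer(0)
        shell <- hx[anchors, , drop = FALSE] +
          runif_shell(nw, 2.4, params$water_cutoff)
        bulk <- place_bulk(cap_nw + n_bulk - nw, sol, params$water_cutoff)
        new_frame(rbind(sol, shell, bulk), temperature = tK, time = fi - 1,
                  truth = list(nw = nw, npp = npp, pairs = pairs))
      })
    })
    list(temperature = tK, trajectory = new_trajectory(ext, frames))
  })
}

# npp disjoint unordered residue pairs (1-based positional indices) with
# sequence separation >= min_sep; each residue is used at most once.
draw_disjoint_pairs <- function(n, npp, min_sep, max_tries = 200L) {
  if (npp == 0) return(matrix(integer(0), 0, 2))
  for (try in seq_len(max_tries)) {
    avail <- seq_len(n)
    out <- matrix(NA_integer_, npp, 2)
    ok <- TRUE
    for (p in seq_len(npp)) {
      i <- avail[sample.int(length(avail), 1)]
      cand <- avail[abs(avail - i) >= min_sep]
      if (length(cand) == 0) { ok <- FALSE; break }
      j <- cand[sample.int(length(cand), 1)]
      out[p, ] <- c(i, j)
      avail <- setdiff(avail, c(i, j))
    }
    if (ok) return(out)
  }
  stop("could not draw ", npp, " disjoint residue pairs from ", n,
       " residues")
}

RAMA_CENTERS <- list(alpha_R = c(-75, -50), beta = c(-120, 130),
                     alpha_L = c(65, 40))

#' Simulate a backbone dihedral ensemble with planted Ramachandran classes
#'
#' Per frame, each residue's (phi, psi) pair is drawn from a von Mises
#' circular distribution centered at its class center (`alpha_R` at
#' (-75, -50), `beta` at (-120, 130), `alpha_L` at (65, 40); `coil` is
#' uniform) and backbone coordinates are rebuilt by sequential
#' internal-coordinate construction, so [backbone_dihedrals()] recovers the
#' drawn angles. Drawn angles are stored as frame `truth`.
#'
#' @param class_map character vector of per-residue region labels.
#' @param kappa von Mises concentration (larger = tighter about the
#'   center).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return Trajectory over a backbone-only polyalanine-like chain
#' @export
simulate_dihedral_ensemble <- function(class_map, kappa = 20,
                                       n_frames = 10L, seed = 1L) {
  labs <- unique(class_map)
  bad <- setdiff(labs, c(names(RAMA_CENTERS), "coil"))
  if (length(bad) > 0)
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  n <- length(class_map)
  stopifnot(n >= 3)

  draw_one <- function(which_angle) {
    vapply(seq_len(n), function(i) {
      cl <- class_map[i]
      if (cl == "coil") return(runif(1, -180, 180))
      ctr <- RAMA_CENTERS[[cl]][if (which_angle == "phi") 1 else 2]
      rvonmises_deg(1, ctr, kappa)
    }, numeric(1))
  }

  with_seed(seed, {
    frames <- vector("list", n_frames)
    sys_atoms <- NULL
    for (fi in seq_len(n_frames)) {
      phi <- draw_one("phi"); phi[1] <- NA
      psi <- draw_one("psi"); psi[n] <- NA
      bb <- build_backbone_coords(phi, psi)
      xyz <- do.call(rbind, lapply(seq_len(n), function(i)
        rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])))
      if (is.null(sys_atoms)) {
        sys_atoms <- data.frame(
          serial = seq_len(4 * n),
          name = rep(c("N", "CA", "C", "O"), n),
          element = rep(c("N", "C", "C", "O"), n),
          residue_index = rep(seq_len(n) - 1L, each = 4),
          residue_name = "ALA", role = "elp",
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
          stringsAsFactors = FALSE)
      }
      frames[[fi]] <- new_frame(xyz, time = fi - 1,
                                truth = list(phi = phi, psi = psi))
    }
    new_trajectory(labeled_system(sys_atoms), frames)
  })
}
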