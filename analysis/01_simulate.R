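#!/usr/bin/env Rscript
# Build the synthetic study systems and write small demonstration
# trajectories with their ground-truth sidecars. The statistical analyses
# in 02-04 regenerate their inputs at full size from the same seeds; the
# files written here document the formats and let every reader inspect a
# concrete fixture.

suppressMessages(library(famedew))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
SEED <- 20260921L

# the 50-residue study construct: 12-residue recognition site + 8 His +
# 6 GVGVP pentads, with the 14-bead myristoyl chain
study <- build_fame_topology(n_pentads = 6, include_lipid = TRUE,
                             seed = SEED)
print(study)

# compact 30-residue sibling for the on-disk demonstration files
sys <- build_fame_topology(n_pentads = 2, include_lipid = TRUE, seed = SEED)

# a short hydration trajectory at 300 K under a logistic dewetting model
set.seed(SEED)
model <- hydration_model(baseline_counts = runif(sys$peptide_length, 4, 9),
                         midpoints = runif(sys$peptide_length, 265, 385),
                         width = 5)
traj <- simulate_hydration_frames(sys, model, temperature = 300,
                                  n_frames = 1, seed = SEED)
write_trajectory(traj, "results/sim/hydration_300K.pdb")
truth <- lapply(traj$frames, function(f)
  list(chain = f$truth$chain,
       per_residue = as.numeric(f$truth$per_residue)))
jsonlite::write_json(
  list(temperature = 300, width = model$width,
       baseline_counts = model$baseline_counts,
       midpoints = model$midpoints, frames = truth),
  "results/sim/hydration_300K_truth.json", auto_unbox = TRUE, digits = NA)

# one frame of a temperature-scan fixture, with its drawn N_w / N_pp
sm <- scan_model(230, -0.35, -2, 0.04, noise_sd = 2.5)
scan <- simulate_temperature_scan(study, sm, temps = c(280, 330),
                                  n_frames = 1, seed = SEED)
write_trajectory(scan[[1]]$trajectory, "results/sim/scan_280K.pdb")
cat("scan frame ground truth at 280 K: N_w =",
    scan[[1]]$trajectory$frames[[1]]$truth$nw, ", N_pp =",
    scan[[1]]$trajectory$frames[[1]]$truth$npp, "\n")

# a helix-biased dihedral ensemble over the lipidation-site length
rama <- simulate_dihedral_ensemble(rep("alpha_R", 20), kappa = 25,
                                   n_frames = 2, seed = SEED)
write_trajectory(rama, "results/sim/rama_alpha.pdb")

cat("wrote demonstration fixtures under results/sim/\n")
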