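#!/usr/bin/env Rscript
# The residue-level dewetting hydropathy scale: per-residue shell
# occupancy over a 250-400 K dewetting grid, dewetting temperatures by
# theta = 0.5 crossing, hydropathy scores, and the percent-dehydrated map
# over (T_MD, T_dw). Higher simulation temperature is emulated by shifting
# the planted dewetting midpoints downward (structures equilibrated hotter
# hold their shell more weakly).

suppressMessages(library(famedew))
dir.create("results", showWarnings = FALSE)
SEED <- 20260921L

sys <- build_fame_topology(n_pentads = 6, include_lipid = TRUE, seed = SEED)
n <- sys$peptide_length
set.seed(SEED)
baselines <- runif(n, 4, 9)
# hydrophobic patch near the lipid attachment: the 5 residues nearest the
# myristoyl dewet early
t50 <- runif(n, 330, 385)
t50[1:5] <- runif(5, 268, 285)
tdw_grid <- seq(250, 400, by = 10)

tmd_grid <- c(250, 280, 310)
curves <- list()
for (k in seq_along(tmd_grid)) {
  shift <- 15 * (k - 1)
  model <- hydration_model(baselines, pmax(260, t50 - shift), width = 5)
  series <- simulate_annealing_series(sys, model, tdw_grid,
                                      n_frames = 100, seed = SEED + k)
  om <- occupancy_matrix(series)
  curves[[k]] <- percent_dehydrated_curve(om, theta = 0.5)
  if (k == 1) {
    tdw <- dewetting_temperatures(om, theta = 0.5)
    scores <- hydropathy_scores(tdw)
    prof <- data.frame(residue_index = om$residues,
                       role = sys$residues$role[match(om$residues,
                                                      sys$residues$residue_index)],
                       planted_t50 = t50,
                       dewetting_temperature = unname(tdw),
                       hydropathy_score = unname(scores))
    write_profile_table(prof, "results/dewetting_profile.tsv")
    err <- abs(tdw - t50)
    cat(sprintf("T50 recovery at T_MD = 250 K: %.0f%% within 10 K (median |error| %.1f K)\n",
                100 * mean(err <= 10, na.rm = TRUE),
                median(err, na.rm = TRUE)))
    cat(sprintf("hydropathy near lipid (res 1-5): %.2f vs chain end: %.2f\n",
                mean(scores[1:5]), mean(scores[(n - 4):n])))
  }
}
map <- assemble_dewetting_map(curves, tmd_grid)
write_profile_table(dewetting_map_table(map), "results/dewetting_map.tsv")
cat("finding: the percent-dehydrated front moves to lower T_dw as T_MD",
    "rises, and the lipid-adjacent patch scores hydrophobic.\n")
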