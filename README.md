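# famedew

Single-chain analysis of **fatty-acid-modified elastin-like polypeptides
(FAMEs)** — recombinant GVGVP-repeat polypeptides carrying an N-terminal
myristoyl lipid via a GLYASKLFSNLG + octahistidine lipidation site. The
package quantifies how lipidation reshapes a chain's hydration and
conformation:

- **N_w** — the number of water molecules in the chain's (or each
  residue's) first hydration shell, waters whose oxygen lies strictly
  within 3.15 Å of a peptide heavy atom;
- **N_pp** — the number of intrachain residue contacts, unordered pairs
  (i, j) with |i − j| ≥ 3 having any heavy-atom pair within 6 Å;
- a **dewetting-temperature hydropathy scale**: the solute is restrained
  and heated over a dewetting-temperature grid T_dw = 250–400 K (1 K per
  20 ps, 3 ns); the temperature at which a residue's normalized shell
  occupancy crosses θ = 0.5 is its dewetting temperature, rescaled to a
  [0, 1] hydropathy score (higher = more hydrophilic, i.e. the residue
  holds its shell water to higher temperature);
- **Ramachandran classification** of backbone (Φ, Ψ) dihedrals, with the
  right-handed helical box Φ ∈ [−100, −50], Ψ ∈ [−70, −30];
- **length-normalized temperature trends** of N_w and N_pp with ordinary
  least-squares fits and 90% confidence intervals;
- the **hydrophilic mass fraction** f = m_peptide / (m_peptide +
  m_lipid) of each construct in the myr-V20 … myr-V60 library.

Because no trajectory data accompany the study, the package ships
first-class synthetic generators that emulate the statistical structure
the analysis assumes — logistic per-residue dewetting with planted
midpoints, linear-in-temperature chain counts with Gaussian frame noise,
and von Mises dihedral ensembles — each recording its drawn ground truth
as frame metadata so every counting stage can be verified against it
exactly.

## Worked example

```r
library(famedew)

# 50-residue myristoylated construct: 12-residue site + 8 His + 6 pentads
sys <- build_fame_topology(n_pentads = 6, include_lipid = TRUE, seed = 1)

# synthetic temperature scan, then N_w / N_pp trends
sm    <- scan_model(230, -0.35, -2, 0.04, noise_sd = 2.5)
temps <- seq(280, 330, by = 10)
scan  <- simulate_temperature_scan(sys, sm, temps, n_frames = 100, seed = 1)
nw <- sapply(scan, function(s)
  series_statistics(s$trajectory, count_chain_waters)$mean)
fit <- fit_linear_trend(temps, normalize_series(nw, sys$peptide_length))
fit
#> TrendFit: slope -0.00684914 [90% CI -0.00701582, -0.00668247], intercept 4.55686, R^2 0.9995, n = 6

hydrophilic_fraction(fame_preset("myr-V20"))
#> [1] 0.9804618
```

The fitted slope is the per-residue dehydration rate: about 0.007 shell
waters lost per residue per kelvin, recovering the planted −0.35/50 =
−0.007 and negative as heating weakens protein–water interactions. The
hydrophilic fraction rounds to f = 0.98: even the shortest construct is
almost entirely hydrophilic by mass, so its rodlike self-assembly must
come from lipid-induced local dehydration, not bulk composition.

The numbered scripts under `analysis/` run the full story — fixture
generation, hydration/contact trends, the dewetting map and hydropathy
profile, Ramachandran occupancy, and construct composition — writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # … Rscript analysis/05_composition.R
```

`run_pipeline(default_run_config(seed = 1), "out/")` performs the same
stages under one configuration and writes a manifest with MD5 checksums;
a fixed seed gives byte-identical outputs.

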