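---
title: "Hydration, dewetting and conformational analysis of lipidated ELPs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration, dewetting and conformational analysis of lipidated ELPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famedew)
```

## The system and the observables

Fatty-acid-modified elastin-like polypeptides (FAMEs) are intrinsically
disordered GVGVP-repeat polypeptides carrying a single N-terminal
myristoyl (C14:0) lipid, attached enzymatically through a recognition
peptide (GLYASKLFSNLG) followed by an octahistidine tag. The lipid is a
tiny fraction of the molecule's mass, yet it changes how the chain
hydrates, folds locally, and ultimately self-assembles. This package
quantifies that change on single chains through four observables.

**First-shell water count, N_w.** A water molecule belongs to the
chain's first hydration shell when its oxygen lies strictly within
`water_cutoff` (default 3.15 Å) of at least one peptide heavy atom. The
per-residue variant assigns a water to every residue whose shell it
occupies — per-residue shells overlap, so per-residue counts sum to at
least the chain count. Distances are measured to heavy atoms only: the
shell radius is an oxygen–heavy-atom convention, and including
hydrogens would change absolute counts without adding information.

**Intrachain contacts, N_pp.** Two peptide residues are in contact when
any pair of their heavy atoms is strictly within `contact_cutoff`
(default 6 Å) and their sequence separation is at least
`min_sequence_separation` (default 3). Counting residue *pairs* rather
than atom pairs keeps the observable insensitive to residue size, and
the separation filter removes bonded neighbors, which are always within
6 Å and carry no signal. Both choices are configurable; lipid atoms are
excluded from the peptide chain by default on both observables
(`include_lipid` re-admits them on the water side).

Both counts run through one compiled cell-list neighbor search with
minimum-image distances when an orthorhombic box is present. Minimum
image is only valid when the cutoff is below half the smallest box
edge; violating that is a hard error, not a warning. The cutoff
comparison is strict (`<`); this matters only on measure-zero inputs
but is stated so the boundary convention is testable.

**The dewetting hydropathy scale.** Traditional hydropathy scales give
each amino acid a fixed value; a disordered, thermoresponsive conjugate
needs a scale that sees local topography. The procedure here: take an
equilibrated structure at simulation temperature T_MD, restrain the
solute with its first shell, and heat over a grid of dewetting
temperatures T_dw = 250–400 K (the protocol arithmetic — 1 K per 20 ps
for 150 K, hence 3 ns — is validated by `validate_schedule()`). At each
grid point the per-residue shell count is averaged over the trailing
`window` fraction of frames and normalized to the residue's own count
at the lowest grid temperature. A residue *dewets* at the smallest grid
temperature where its normalized occupancy drops below `theta`, refined
by linear interpolation between the bracketing grid points; the
hydropathy score rescales this temperature over the annealing range to
[0, 1]. Stacking the percent-dehydrated curves of structures
equilibrated at several T_MD gives the (T_MD, T_dw) dewetting map.

**Ramachandran occupancy.** Backbone Φ(i) = C(i−1)–N(i)–CA(i)–C(i) and
Ψ(i) = N(i)–CA(i)–C(i)–N(i+1) follow the IUPAC sign convention (the
implementation is cross-checked in the tests against an independent
torsion routine). The right-handed helical box is Φ ∈ [−100, −50],
Ψ ∈ [−70, −30]; the β and left-handed boxes follow standard
conventions and are overridable. Boxes are closed at both ends,
pairwise disjointness is enforced at configuration time, and anything
outside every box is `other`, so per-residue region fractions always
form a probability vector.

**Composition.** The hydrophilic fraction is operationalized as a mass
fraction, f = m_peptide / (m_peptide + m_lipid), with the lipid
contribution C14H26O (myristic acid minus the water lost on amide
formation) and the N-terminal methionine excluded (it is removed when
the glycine is myristoylated). A volume-basis f would need a
partial-volume table; the mass basis is parameter-free and is the
interpretation we document. Residue masses are an internal table
(average and monoisotopic), cross-checked in the tests against an
independent summation.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `water_cutoff` | 3.15 | Å | first-shell oxygen–heavy-atom radius |
| `contact_cutoff` | 6.0 | Å | residue heavy-atom contact radius |
| `min_sequence_separation` | 3 | residues | removes bonded/near-bonded pairs |
| `theta` | 0.5 | — | "dewetted" = below half the baseline shell |
| `window` | 1 (annealing), 0.25 (equilibrium) | fraction | trailing-frame averaging |
| `min_baseline` | 1.0 | waters | a residue essentially dry at baseline cannot dewet |
| annealing range | 250–400 | K | dewetting grid endpoints |
| `ls_length` | 20 | residues | positional lipidation-site/ELP boundary (12 + 8 His) |

`theta = 0.5` deserves a note: "dehydrated" is not quantified anywhere
upstream of this package, so we define it as the midpoint of the
normalized occupancy decay — the same convention as the logistic
midpoint of the synthetic model — and expose it. Percent-dehydrated is
non-increasing in `theta` by construction. Normalization is
per-residue to its own baseline so that a tryptophan and a glycine are
comparable despite different shell sizes; an absolute-count reading is
available from the `raw` matrix. Residues that never cross `theta`
return the sentinel `Inf` and score 1.0 rather than `NA`, keeping
downstream tables dense; flagged (dry-at-baseline) residues are
excluded from percentages entirely.

## What the generators emulate — and what they do not

The synthetic generators are first-class, tested code that reproduce
the *statistical* structure the analysis assumes:

- `simulate_hydration_frames()` draws per-residue shell counts from a
  Poisson at the logistic expectation
  baseline / (1 + exp((T − T50)/w)) and places exactly that many waters
  in the shell annulus r ∈ [2.4, 3.15) Å of the residue — rejected
  until outside every *other* residue's shell — plus bulk waters beyond
  the cutoff. Poisson noise is our choice (counts are non-negative
  integers whose variance scales with the mean); the inner radius 2.4 Å
  merely prevents steric nonsense and any value below the cutoff would
  do. The water topology is fixed (shell capacity plus bulk) and
  waters are single-oxygen residues, equivalent under oxygen counting.
- `simulate_temperature_scan()` realizes chain-level
  round(intercept + slope·T + N(0, σ)) counts exactly: waters into the
  first shell of random peptide atoms, contacts by pulling disjoint
  residue pairs within the cutoff on a widely spaced residue lattice.
  Disjointness caps realizable contacts at ⌊n/2⌋; models exceeding that
  (or going negative over the range) are argument errors.
- `simulate_dihedral_ensemble()` draws (Φ, Ψ) from von Mises
  distributions about region centers (α_R at (−75, −50), β at
  (−120, 130); coil is uniform) and rebuilds coordinates by sequential
  internal-coordinate construction with ideal geometry (N–CA 1.458 Å,
  CA–C 1.525 Å, C–N 1.329 Å; angles 111°/117°/121°; ω = 180°), so the
  dihedral extractor must return the drawn angles.

Every generator records its draws as frame ground truth, giving exact
generator/counter cross-oracles, and is deterministic under a seed
(one RNG stream per call, caller state restored).

What they do **not** emulate: physical dynamics, force fields, water
hydrogen bonding, frame-to-frame correlation, equilibration transients
within an annealing window (each grid point is sampled stationary), or
multi-chain assembly. Passing tests therefore demonstrate that the
*analysis* is correct and well-calibrated on data with the assumed
structure — not that real trajectories have that structure.

## Numerical choices and degenerate inputs

Interpolated dewetting temperatures always lie inside the bracketing
grid interval; a first-column crossing (impossible when θ ≤ 1, since
normalization forces the baseline column to 1) returns the grid start.
Trend fits require at least three distinct temperatures; an exact line
yields a zero-width 90% interval. The slope interval uses the
t-distribution on n − 2 degrees of freedom; the optional weighted mode
uses 1/(sd²/n_frames) weights. Empty trajectories, unsorted or
duplicated grids, all-flagged occupancy matrices, oxygen-free waters
under oxygen counting, and missing backbone atoms are all hard errors
that name the offending residue, temperature or file line. Chains with
fewer residues than the separation filter allows return zero contacts
with a warning rather than erroring, since that is a meaningful count.

## Study sizes

The shipped configurations use a 50-residue construct (lipidation site
plus six pentads), a 16-point dewetting grid at 10 K spacing with
50–200 frames per point, six scan temperatures at 100 frames each, and
500 replicates for the confidence-interval coverage check. These sizes
give midpoint-recovery and coverage statistics whose Monte-Carlo error
is small against the tolerances tested while keeping a full run in the
minutes range on one core.

## Known limitations

- Only orthorhombic boxes; triclinic input is refused explicitly.
- The lipidation-site/ELP boundary is positional (first `ls_length`
  peptide residues): residue names cannot distinguish the two, and a
  misstated length silently mislabels roles.
- Whether the upstream analyses counted contacts as residue pairs or
  atom pairs, included lipid atoms in the chain shell, or averaged
  final snapshots versus windows is not documented; the defaults here
  (residue pairs, lipid excluded, windowed averages) are stated,
  configurable choices rather than reconstructions.
- The atom naming of the myristoyl group (`MYR`, beads C1–C14) is this
  package's convention.
- Hard Ramachandran boxes operationalize regions that are soft in
  reality; occupancies near box edges depend on that choice.
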