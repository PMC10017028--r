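#' Hydration-shell and contact counting parameters
#'
#' Defaults follow the single-chain analysis conventions: a water belongs to
#' the first hydration shell when its oxygen lies strictly within 3.15
#' Angstrom of a peptide heavy atom, and two peptide residues are in contact
#' when any pair of their heavy atoms lies strictly within 6 Angstrom, with
#' sequence neighbors closer than `min_sequence_separation` excluded
#' (bonded neighbors are always within 6 Angstrom and carry no signal).
#'
#' @param water_cutoff first-shell radius, Angstrom (default 3.15).
#' @param contact_cutoff residue contact radius, Angstrom (default 6).
#' @param min_sequence_separation smallest |i - j| counted as a contact
#'   (default 3).
#' @param counting_atom `"water_oxygen"` (default) counts a water by its
#'   oxygen; `"any_water_atom"` counts it by any of its atoms.
#' @param solute_atoms `"heavy"` (default) measures distances to peptide
#'   heavy atoms only; `"all"` includes hydrogens.
#' @param include_lipid include lipid heavy atoms on the solute side of the
#'   water count (default `FALSE`: the shell is the peptide chain's).
#' @return object of class `ShellParams`
#' @export
shell_params <- function(water_cutoff = 3.15, contact_cutoff = 6.0,
                         min_sequence_separation = 3L,
                         counting_atom = c("water_oxygen", "any_water_atom"),
                         solute_atoms = c("heavy", "all"),
                         include_lipid = FALSE) {
  stopifnot(water_cutoff > 0, contact_cutoff > 0,
            min_sequence_separation >= 1)
  structure(list(water_cutoff = water_cutoff,
                 contact_cutoff = contact_cutoff,
                 min_sequence_separation = as.integer(min_sequence_separation),
                 counting_atom = match.arg(counting_atom),
                 solute_atoms = match.arg(solute_atoms),
                 include_lipid = isTRUE(include_lipid)),
            class = "ShellParams")
}

check_box <- function(box, cutoff) {
  if (is.null(box)) return(numeric(0))
  if (cutoff >= min(box) / 2)
    stop("minimum-image distances need cutoff < half the smallest box edge (",
         "cutoff = ", cutoff, ", min edge = ", min(box), ")")
  as.numeric(box)
}

solute_selection <- function(system, params) {
  roles <- PEPTIDE_ROLES
  if (params$include_lipid) roles <- c(roles, "lipid")
  at <- system$atoms
  sel <- at$role %in% roles
  if (params$solute_atoms == "heavy") sel <- sel & at$is_heavy
  sel
}

water_selection <- function(system, params) {
  at <- system$atoms
  wat <- at$role == "water"
  if (!any(wat)) return(list(idx = integer(0), mol = integer(0)))
  if (params$counting_atom == "water_oxygen") {
    keep <- wat & toupper(at$element) == "O"
    wres <- system$residues$residue_index[system$residues$role == "water"]
    have <- unique(at$residue_index[keep])
    if (length(setdiff(wres, have)) > 0)
      stop("water residue(s) without an oxygen atom: cannot count by ",
           "water_oxygen (residues ",
           paste(utils::head(setdiff(wres, have), 5) + 1L, collapse = ", "),
           ")")
  } else keep <- wat
  idx <- which(keep)
  list(idx = idx,
       mol = as.integer(factor(at$residue_index[idx])) - 1L)
}

#' Count first-hydration-shell waters of the peptide chain (N_w)
#'
#' Number of distinct water molecules with at least one counting atom
#' strictly within `water_cutoff` of at least one peptide solute atom.
#' Uses a cell-list neighbor search with minimum-image distances when the
#' frame has a box.
#'
#' @param frame Frame
#' @param system LabeledSystem (roles assigned)
#' @param params [shell_params()]
#' @return integer count
#' @export
count_chain_waters <- function(frame, system, params = shell_params()) {
  counts <- residue_water_table(frame, system, params)
  counts$chain
}

#' Per-residue first-hydration-shell water counts
#'
#' A water within the cutoff of several residues is counted once for each
#' such residue (per-residue shells overlap), so the per-residue counts sum
#' to at least the chain-level `N_w`.
#'
#' @inheritParams count_chain_waters
#' @return named numeric vector over peptide residues (names are 0-based
#'   internal residue indices)
#' @export
residue_water_counts <- function(frame, system, params = shell_params()) {
  residue_water_table(frame, system, params)$per_residue
}

residue_water_table <- function(frame, system, params) {
  pep <- peptide_residues(system)
  if (nrow(pep) == 0) stop("system has no peptide residues")
  sel <- solute_selection(system, params)
  wsel <- water_selection(system, params)
  box <- check_box(frame$box, params$water_cutoff)

  pep_idx <- sort(pep$residue_index)
  empty <- setNames(numeric(length(pep_idx)), pep_idx)
  if (sum(sel) == 0 || length(wsel$idx) == 0)
    return(list(chain = 0L, per_residue = empty))

  # map solute atoms onto a dense 0-based residue slot
  slot <- match(system$atoms$residue_index[sel], pep_idx) - 1L
  sol_xyz <- frame$positions[which(sel), , drop = FALSE]
  res <- cpp_water_counts(sol_xyz,
                          ifelse(is.na(slot), -1L, slot),
                          frame$positions[wsel$idx, , drop = FALSE],
                          wsel$mol, params$water_cutoff, box,
                          length(pep_idx))
  per <- setNames(as.numeric(res$per_residue), pep_idx)
  list(chain = res$chain, per_residue = per)
}

#' Count intrachain residue contacts (N_pp)
#'
#' Number of unordered peptide residue pairs (i, j) with
#' `|i - j| >= min_sequence_separation` having at least one heavy-atom pair
#' strictly within `contact_cutoff`. Lipid atoms are excluded; pass a system
#' relabeled with [assign_roles()] to study lipid contacts separately.
#'
#' @inheritParams count_chain_waters
#' @return integer count (0 with a warning when too few residues exist to
#'   form any eligible pair)
#' @export
count_intrachain_contacts <- function(frame, system,
                                      params = shell_params()) {
  pep <- peptide_residues(system)
  if (nrow(pep) < 2) stop("need at least 2 peptide residues")
  if (nrow(pep) < params$min_sequence_separation + 1L) {
    warning("fewer than min_sequence_separation + 1 residues: no eligible ",
            "pairs")
    return(0L)
  }
  at <- system$atoms
  sel <- at$role %in% PEPTIDE_ROLES & at$is_heavy
  box <- check_box(frame$box, params$contact_cutoff)
  # positional residue rank, so separation is sequence separation
  rank <- match(at$residue_index[sel], sort(pep$residue_index)) - 1L
  cpp_contact_count(frame$positions[which(sel), , drop = FALSE],
                    rank, params$contact_cutoff,
                    params$min_sequence_separation, box)
}

#' Mean and standard deviation of a per-frame metric over a trajectory
#'
#' The spread is the population standard deviation of the per-frame values,
#' i.e. the time-average fluctuation quoted with equilibrium observables.
#'
#' @param trajectory Trajectory
#' @param metric function of (frame, system) returning one number
#' @param ... passed on to `metric`
#' @return list with `mean`, `sd` (population), `n`
#' @export
series_statistics <- function(trajectory, metric, ...) {
  stopifnot(inherits(trajectory, "Trajectory"))
  if (n_frames(trajectory) == 0) stop("empty trajectory")
  vals <- vapply(trajectory$frames, metric, numeric(1),
                 trajectory$system, ...)
  n <- length(vals)
  m <- mean(vals)
  list(mean = m, sd = sqrt(mean((vals - m)^2)), n = n)
}
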