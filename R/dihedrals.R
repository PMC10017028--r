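# Backbone dihedral extraction and Ramachandran-region classification.

#' Default Ramachandran region set
#'
#' The right-handed helical box follows the lipidation-site analysis
#' (phi in [-100, -50], psi in [-70, -30]); the beta and left-handed
#' helical boxes follow standard Ramachandran conventions. Boxes are
#' closed at both ends and must be pairwise disjoint; anything outside
#' every box classifies as `other`.
#'
#' @return data.frame with columns `label`, `phi_lo`, `phi_hi`, `psi_lo`,
#'   `psi_hi` (degrees)
#' @export
default_rama_regions <- function() {
  rama_regions(data.frame(
    label = c("alpha_R", "beta", "alpha_L"),
    phi_lo = c(-100, -180, 30), phi_hi = c(-50, -90, 100),
    psi_lo = c(-70, 90, 0), psi_hi = c(-30, 180, 80),
    stringsAsFactors = FALSE))
}

#' Validate a Ramachandran region table
#'
#' @param regions data.frame with `label`, `phi_lo`, `phi_hi`, `psi_lo`,
#'   `psi_hi` in degrees within (-180, 180]; boxes must be pairwise
#'   disjoint.
#' @return the validated table, class `RamachandranRegions`
#' @export
rama_regions <- function(regions) {
  need <- c("label", "phi_lo", "phi_hi", "psi_lo", "psi_hi")
  stopifnot(is.data.frame(regions), all(need %in% names(regions)))
  if (anyDuplicated(regions$label)) stop("duplicate region labels")
  with(regions, {
    if (any(phi_lo >= phi_hi) || any(psi_lo >= psi_hi))
      stop("region intervals must have lo < hi")
    if (any(phi_lo <= -180 - 1e-9) || any(phi_hi > 180) ||
        any(psi_lo <= -180 - 1e-9) || any(psi_hi > 180))
      stop("region intervals must lie within (-180, 180]")
  })
  n <- nrow(regions)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      overlap <- regions$phi_lo[i] <= regions$phi_hi[j] &&
        regions$phi_lo[j] <= regions$phi_hi[i] &&
        regions$psi_lo[i] <= regions$psi_hi[j] &&
        regions$psi_lo[j] <= regions$psi_hi[i]
      if (overlap)
        stop("regions '", regions$label[i], "' and '", regions$label[j],
             "' overlap")
    }
  }
  structure(regions, class = c("RamachandranRegions", "data.frame"))
}

# row-wise cross product of n x 3 matrices
cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

# vectorized torsion over rows of four n x 3 matrices, degrees in
# (-180, 180]
dihedral_rows <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1
  b2 <- P3 - P2
  b3 <- P4 - P3
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross_rows(n1, b2u)
  wrap_angle(rad2deg(atan2(-rowSums(m1 * n2), rowSums(n1 * n2))))
}

#' Backbone phi/psi dihedrals over a trajectory
#'
#' `phi(i)` is the C(i-1)-N(i)-CA(i)-C(i) torsion and `psi(i)` the
#' N(i)-CA(i)-C(i)-N(i+1) torsion, IUPAC sign convention; the first
#' peptide residue has no phi and the last no psi (`NA`).
#'
#' @param trajectory Trajectory
#' @param system LabeledSystem; defaults to the trajectory's own.
#' @return object of class `DihedralSeries`: list with `phi` and `psi`
#'   matrices (frames x residues, columns named by 0-based residue index)
#' @export
backbone_dihedrals <- function(trajectory, system = NULL) {
  stopifnot(inherits(trajectory, "Trajectory"))
  if (is.null(system)) system <- trajectory$system
  pep <- peptide_residues(system)
  pep <- pep[order(pep$residue_index), , drop = FALSE]
  n <- nrow(pep)
  if (n < 2) stop("need at least 2 peptide residues for dihedrals")

  atom_idx <- function(which_name) {
    vapply(seq_len(n), function(i) {
      span <- pep$first_atom[i]:pep$last_atom[i]
      hit <- span[system$atoms$name[span] == which_name]
      if (length(hit) != 1)
        stop("residue ", pep$residue_index[i], " (", pep$residue_name[i],
             ") lacks backbone atom ", which_name)
      hit
    }, integer(1))
  }
  iN <- atom_idx("N"); iCA <- atom_idx("CA"); iC <- atom_idx("C")

  nf <- n_frames(trajectory)
  phi <- psi <- matrix(NA_real_, nf, n,
                       dimnames = list(NULL, pep$residue_index))
  for (f in seq_len(nf)) {
    P <- trajectory$frames[[f]]$positions
    if (n >= 2) {
      phi[f, 2:n] <- dihedral_rows(P[iC[1:(n - 1)], , drop = FALSE],
                                   P[iN[2:n], , drop = FALSE],
                                   P[iCA[2:n], , drop = FALSE],
                                   P[iC[2:n], , drop = FALSE])
      psi[f, 1:(n - 1)] <- dihedral_rows(P[iN[1:(n - 1)], , drop = FALSE],
                                         P[iCA[1:(n - 1)], , drop = FALSE],
                                         P[iC[1:(n - 1)], , drop = FALSE],
                                         P[iN[2:n], , drop = FALSE])
    }
  }
  structure(list(phi = phi, psi = psi,
                 residues = pep$residue_index),
            class = "DihedralSeries")
}

#' Classify (phi, psi) pairs into Ramachandran regions
#'
#' Returns the label of the first region whose closed box contains the
#' pair, else `"other"`; `NA` angles give `NA`.
#'
#' @param phi,psi angles in degrees, recycled to a common length
#' @param regions [rama_regions()] table (default [default_rama_regions()])
#' @return character vector of labels
#' @export
classify_conformation <- function(phi, psi,
                                  regions = default_rama_regions()) {
  regions <- rama_regions(as.data.frame(regions))
  k <- max(length(phi), length(psi))
  phi <- rep_len(phi, k)
  psi <- rep_len(psi, k)
  out <- rep("other", k)
  out[is.na(phi) | is.na(psi)] <- NA_character_
  for (i in rev(seq_len(nrow(regions)))) {
    hit <- !is.na(phi) & !is.na(psi) &
      phi >= regions$phi_lo[i] & phi <= regions$phi_hi[i] &
      psi >= regions$psi_lo[i] & psi <= regions$psi_hi[i]
    out[hit] <- regions$label[i]
  }
  out
}

#' Per-residue Ramachandran region occupancy over a trailing window
#'
#' For each residue with both dihedrals defined, the fraction of windowed
#' frames falling in each region (plus `other`); fractions sum to 1. The
#' default `window = 0.25` mirrors analyzing the last quarter of an
#' equilibrium run.
#'
#' @param series [backbone_dihedrals()] result
#' @param window trailing fraction of frames, in (0, 1]
#' @param regions region table
#' @return data.frame: `residue_index` plus one fraction column per label
#' @export
region_occupancy <- function(series, window = 0.25,
                             regions = default_rama_regions()) {
  stopifnot(inherits(series, "DihedralSeries"), window > 0, window <= 1)
  nf <- nrow(series$phi)
  if (nf == 0) stop("empty dihedral series")
  idx <- seq.int(nf - ceiling(window * nf) + 1L, nf)
  labs <- c(regions$label, "other")
  n <- length(series$residues)
  frac <- matrix(NA_real_, n, length(labs),
                 dimnames = list(NULL, labs))
  for (r in seq_len(n)) {
    ph <- series$phi[idx, r]
    ps <- series$psi[idx, r]
    ok <- !is.na(ph) & !is.na(ps)
    if (!any(ok)) next
    cls <- classify_conformation(ph[ok], ps[ok], regions)
    frac[r, ] <- vapply(labs, function(l) mean(cls == l), numeric(1))
  }
  cbind(data.frame(residue_index = series$residues),
        as.data.frame(frac))
}

#' Binned (phi, psi) density over all residue-frames
#'
#' @param series [backbone_dihedrals()] result
#' @param bins number of bins per axis (default 36, i.e. 10 degree bins)
#' @return `bins x bins` count matrix; its sum equals the number of
#'   residue-frames with both angles defined
#' @export
dihedral_histogram <- function(series, bins = 36L) {
  stopifnot(inherits(series, "DihedralSeries"), bins >= 1)
  ph <- as.vector(series$phi)
  ps <- as.vector(series$psi)
  ok <- !is.na(ph) & !is.na(ps)
  brk <- seq(-180, 180, length.out = bins + 1)
  ip <- pmin(bins, pmax(1L, findInterval(ph[ok], brk, left.open = TRUE,
                                         rightmost.closed = TRUE)))
  is_ <- pmin(bins, pmax(1L, findInterval(ps[ok], brk, left.open = TRUE,
                                          rightmost.closed = TRUE)))
  h <- matrix(0L, bins, bins)
  for (k in seq_along(ip)) h[ip[k], is_[k]] <- h[ip[k], is_[k]] + 1L
  h
}
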