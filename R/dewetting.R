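# Residue-level dewetting analysis: occupancy over a dewetting-temperature
# grid, per-residue dewetting temperatures, percent-dehydrated curves and
# the (T_MD, T_dw) map, and the resulting hydropathy scores.

#' Restrained-solute annealing schedule
#'
#' The dewetting protocol heats the restrained solute plus its first shell
#' from `t_initial` to `t_final` at a fixed rate; the three quantities must
#' agree with the duration.
#'
#' @param t_initial starting dewetting temperature, K (default 250).
#' @param t_final final dewetting temperature, K (default 400).
#' @param rate heating rate, K/ps (default 1/20, i.e. 1 K per 20 ps).
#' @param duration total length, ps (default 3000).
#' @return object of class `AnnealingSchedule`
#' @export
annealing_schedule <- function(t_initial = 250, t_final = 400,
                               rate = 1 / 20, duration = 3000) {
  if (t_final <= t_initial) stop("t_final must exceed t_initial")
  if (rate <= 0) stop("heating rate must be positive")
  structure(list(t_initial = t_initial, t_final = t_final, rate = rate,
                 duration = duration), class = "AnnealingSchedule")
}

#' Check an annealing schedule for internal consistency
#'
#' `TRUE` iff `(t_final - t_initial) / rate` equals `duration` within 1e-9
#' relative tolerance; otherwise `FALSE` with a diagnostic message.
#'
#' @param schedule [annealing_schedule()]
#' @return logical
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "AnnealingSchedule"))
  implied <- (schedule$t_final - schedule$t_initial) / schedule$rate
  ok <- abs(implied - schedule$duration) <=
    1e-9 * max(abs(implied), abs(schedule$duration))
  if (!ok)
    message("schedule inconsistent: (t_final - t_initial)/rate = ",
            implied, " ps but duration = ", schedule$duration, " ps")
  ok
}

#' Per-residue occupancy matrix over a dewetting-temperature grid
#'
#' Averages per-residue first-shell water counts over the trailing
#' `window` fraction of each trajectory's frames, then normalizes each
#' residue row to its count at the lowest (baseline) grid temperature.
#' Residues whose baseline count falls below `min_baseline` are essentially
#' dry to begin with and cannot meaningfully dewet; they are flagged and
#' excluded from percentages.
#'
#' @param series list of `list(t_dw = <K>, trajectory = <Trajectory>)` as
#'   produced by [simulate_annealing_series()] or assembled from files.
#' @param params [shell_params()].
#' @param window trailing fraction of frames averaged, in (0, 1]
#'   (default 1: the whole restrained-annealing window).
#' @param min_baseline minimum baseline water count for a residue to be
#'   considered hydrated (default 1.0).
#' @return object of class `OccupancyMatrix` with `raw`, `normalized`
#'   (residue x T_dw), `tdw_grid`, `residues` and `baseline_flags`
#' @export
occupancy_matrix <- function(series, params = shell_params(), window = 1,
                             min_baseline = 1.0) {
  if (length(series) < 2) stop("need at least 2 dewetting grid points")
  tdw <- vapply(series, function(s) s$t_dw, numeric(1))
  if (anyDuplicated(tdw)) stop("duplicate T_dw grid points")
  if (any(diff(tdw) <= 0)) stop("T_dw grid must be sorted ascending")
  stopifnot(window > 0, window <= 1)

  cols <- lapply(series, function(s) {
    traj <- s$trajectory
    nf <- n_frames(traj)
    if (nf == 0)
      stop("empty trajectory at T_dw = ", s$t_dw,
           ": occupancy undefined")
    idx <- seq.int(nf - ceiling(window * nf) + 1L, nf)
    counts <- vapply(traj$frames[idx], residue_water_counts,
                     numeric(nrow(peptide_residues(traj$system))),
                     traj$system, params)
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
    rowMeans(counts)
  })
  raw <- do.call(cbind, cols)
  colnames(raw) <- tdw
  residues <- sort(peptide_residues(series[[1]]$trajectory$system)$residue_index)
  rownames(raw) <- residues

  flags <- raw[, 1] < min_baseline
  normalized <- raw / raw[, 1]
  normalized[flags, ] <- NA_real_
  structure(list(residues = residues, tdw_grid = tdw, raw = raw,
                 normalized = normalized, baseline_flags = flags,
                 min_baseline = min_baseline),
            class = "OccupancyMatrix")
}

#' Dewetting temperature of one residue
#'
#' The smallest grid temperature at which the residue's normalized
#' occupancy drops strictly below `theta`, refined by linear interpolation
#' between the bracketing grid points; `Inf` (the never-dewets sentinel)
#' when occupancy stays at or above `theta` across the whole grid.
#'
#' @param matrix [occupancy_matrix()]
#' @param residue internal (0-based) residue index present in the matrix
#' @param theta dewetting threshold on the normalized occupancy
#'   (default 0.5)
#' @return temperature in K, or `Inf`
#' @export
residue_dewetting_temperature <- function(matrix, residue, theta = 0.5) {
  stopifnot(inherits(matrix, "OccupancyMatrix"))
  k <- match(residue, matrix$residues)
  if (is.na(k)) stop("residue ", residue, " not in occupancy matrix")
  if (matrix$baseline_flags[k])
    stop("residue ", residue, " is not hydrated at baseline (flagged)")
  row <- matrix$normalized[k, ]
  tdw <- matrix$tdw_grid
  j <- which(row < theta)[1]
  if (is.na(j)) return(Inf)
  if (j == 1) return(tdw[1])
  tdw[j - 1] + (tdw[j] - tdw[j - 1]) *
    (row[j - 1] - theta) / (row[j - 1] - row[j])
}

#' Dewetting temperatures for all unflagged residues
#' @inheritParams residue_dewetting_temperature
#' @return named numeric vector over the matrix's residues; flagged
#'   residues are `NA`, never-dewetting residues are `Inf`
#' @export
dewetting_temperatures <- function(matrix, theta = 0.5) {
  out <- setNames(rep(NA_real_, length(matrix$residues)), matrix$residues)
  for (k in seq_along(matrix$residues)) {
    if (!matrix$baseline_flags[k])
      out[k] <- residue_dewetting_temperature(matrix, matrix$residues[k],
                                              theta)
  }
  out
}

#' Percent of residues dehydrated at each dewetting temperature
#'
#' At each grid temperature, 100 times the fraction of unflagged residues
#' whose normalized occupancy lies strictly below `theta`. The baseline
#' column is 0 by construction (normalization forces occupancy 1 there).
#'
#' @inheritParams residue_dewetting_temperature
#' @return numeric vector over the grid with attribute `tdw_grid`
#' @export
percent_dehydrated_curve <- function(matrix, theta = 0.5) {
  stopifnot(inherits(matrix, "OccupancyMatrix"))
  keep <- !matrix$baseline_flags
  if (!any(keep)) stop("all residues are flagged as non-hydrated")
  vals <- 100 * colMeans(matrix$normalized[keep, , drop = FALSE] < theta)
  structure(setNames(vals, matrix$tdw_grid), tdw_grid = matrix$tdw_grid)
}

#' Stack per-T_MD percent-dehydrated curves into a (T_MD, T_dw) map
#'
#' @param curves list of [percent_dehydrated_curve()] results sharing one
#'   dewetting grid
#' @param tmd_grid simulation temperatures, K, one per curve
#' @return object of class `DewettingMap` with a `percent` matrix
#'   (rows = T_MD, columns = T_dw)
#' @export
assemble_dewetting_map <- function(curves, tmd_grid) {
  stopifnot(length(curves) == length(tmd_grid), length(curves) >= 1)
  g1 <- attr(curves[[1]], "tdw_grid")
  for (cv in curves) {
    if (!isTRUE(all.equal(attr(cv, "tdw_grid"), g1)))
      stop("curves do not share one T_dw grid")
  }
  percent <- do.call(rbind, lapply(curves, as.numeric))
  rownames(percent) <- tmd_grid
  colnames(percent) <- g1
  if (any(percent < 0 | percent > 100)) stop("percent values out of [0,100]")
  structure(list(tmd_grid = as.numeric(tmd_grid), tdw_grid = g1,
                 percent = percent), class = "DewettingMap")
}

#' Long-format table of a dewetting map (for TSV export / contour plots)
#' @param map [assemble_dewetting_map()]
#' @return data.frame with `t_md`, `t_dw`, `percent_dehydrated`
#' @export
dewetting_map_table <- function(map) {
  stopifnot(inherits(map, "DewettingMap"))
  data.frame(t_md = rep(map$tmd_grid, times = length(map$tdw_grid)),
             t_dw = rep(map$tdw_grid, each = length(map$tmd_grid)),
             percent_dehydrated = as.vector(map$percent))
}

#' Functional hydropathy scores from dewetting temperatures
#'
#' A residue's score is its dewetting temperature rescaled over the
#' annealing range, `(T_dw - t_initial) / (t_final - t_initial)`, clipped
#' to [0, 1]; residues that never dewet score 1. Higher scores mean more
#' hydrophilic: the residue holds its shell water to higher temperature.
#'
#' @param tdw named vector from [dewetting_temperatures()] (`Inf` allowed,
#'   `NA` for flagged residues propagates).
#' @param t_initial,t_final annealing range, K (defaults 250 and 400).
#' @return named numeric scores in [0, 1]
#' @export
hydropathy_scores <- function(tdw, t_initial = 250, t_final = 400) {
  stopifnot(t_final > t_initial)
  fin <- tdw[!is.na(tdw)]
  if (length(fin) > 0 && all(!is.finite(fin)))
    warning("no residue dewets over the grid: all scores are 1 (degenerate)")
  s <- (tdw - t_initial) / (t_final - t_initial)
  s[is.infinite(tdw)] <- 1
  pmin(1, pmax(0, s))
}
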