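# Sequence-level mass and amphiphilicity metrics for lipidated constructs.

# residue (= amino acid minus water) masses, Da
RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
RESIDUE_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MASS <- c(average = 18.01528, monoisotopic = 18.010565)
ELEMENT_MASS_AVG <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                      S = 32.06)
ELEMENT_MASS_MONO <- c(C = 12, H = 1.00782503, N = 14.00307401,
                       O = 15.99491462, S = 31.97207069)

#' Peptide mass from a one-letter sequence
#'
#' Sum of residue masses plus one water (the free N and C termini).
#'
#' @param sequence one-letter amino acid string (20 canonical residues).
#' @param mass_mode `"average"` (default) or `"monoisotopic"`.
#' @return mass in Da
#' @export
peptide_mass <- function(sequence,
                         mass_mode = c("average", "monoisotopic")) {
  mass_mode <- match.arg(mass_mode)
  if (!is.character(sequence) || length(sequence) != 1 ||
      nchar(sequence) == 0)
    stop("sequence must be a non-empty one-letter string")
  aa <- strsplit(sequence, "")[[1]]
  tab <- if (mass_mode == "average") RESIDUE_MASS_AVG else RESIDUE_MASS_MONO
  bad <- which(!aa %in% names(tab))
  if (length(bad) > 0)
    stop("invalid residue character '", aa[bad[1]], "' at position ",
         bad[1])
  sum(tab[aa]) + WATER_MASS[[mass_mode]]
}

parse_formula <- function(formula) {
  if (!nzchar(formula)) return(setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  toks <- regmatches(formula, m)[[1]]
  if (sum(attr(m[[1]], "match.length")) != nchar(formula))
    stop("cannot parse molecular formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

#' Mass of a molecular formula
#' @param formula e.g. `"C14H26O"`; the empty string has mass 0.
#' @param mass_mode `"average"` or `"monoisotopic"`.
#' @return mass in Da
#' @export
formula_mass <- function(formula,
                         mass_mode = c("average", "monoisotopic")) {
  mass_mode <- match.arg(mass_mode)
  counts <- parse_formula(formula)
  if (length(counts) == 0) return(0)
  tab <- if (mass_mode == "average") ELEMENT_MASS_AVG else ELEMENT_MASS_MONO
  unknown <- setdiff(names(counts), names(tab))
  if (length(unknown) > 0)
    stop("no mass for element(s): ", paste(unknown, collapse = ", "))
  sum(tab[names(counts)] * counts)
}

#' Specification of a lipid-peptide conjugate
#'
#' The default lipid formula `C14H26O` is the myristoyl acyl contribution:
#' myristic acid (C14H28O2) minus the water lost on amide bond formation.
#' The peptide head includes the lipidation site and His tag; the
#' N-terminal Met is absent (removed upon myristoylation of the glycine).
#'
#' @param sequence one-letter peptide string.
#' @param lipid_formula molecular formula of the lipid contribution
#'   (default `"C14H26O"`; `""` for no lipid).
#' @param mass_mode `"average"` (default) or `"monoisotopic"`.
#' @return object of class `ConjugateSpec`
#' @export
conjugate_spec <- function(sequence, lipid_formula = "C14H26O",
                           mass_mode = c("average", "monoisotopic")) {
  mass_mode <- match.arg(mass_mode)
  # validate eagerly
  invisible(peptide_mass(sequence, mass_mode))
  invisible(formula_mass(lipid_formula, mass_mode))
  structure(list(sequence = sequence, lipid_formula = lipid_formula,
                 mass_mode = mass_mode), class = "ConjugateSpec")
}

#' Hydrophilic mass fraction f of a lipid-peptide amphiphile
#'
#' `f = peptide mass / (peptide mass + lipid mass)`: the fraction of the
#' conjugate's mass in the hydrophilic peptide head. Reported unrounded;
#' round only at presentation.
#'
#' @param spec [conjugate_spec()]
#' @return fraction in (0, 1]
#' @export
hydrophilic_fraction <- function(spec) {
  stopifnot(inherits(spec, "ConjugateSpec"))
  pm <- peptide_mass(spec$sequence, spec$mass_mode)
  lm_ <- formula_mass(spec$lipid_formula, spec$mass_mode)
  pm / (pm + lm_)
}

#' Preset myristoylated ELP constructs
#'
#' `myr-V20` through `myr-V60`: the GLYASKLFSNLG + octahistidine
#' lipidation site fused to 20-60 GVGVP repeats, myristoylated.
#'
#' @param name preset name, e.g. `"myr-V20"`.
#' @param mass_mode `"average"` or `"monoisotopic"`.
#' @return [conjugate_spec()]
#' @export
fame_preset <- function(name, mass_mode = c("average", "monoisotopic")) {
  m <- regmatches(name, regexec("^myr-V([0-9]+)$", name))[[1]]
  if (length(m) != 2)
    stop("unknown preset '", name, "' (expected myr-V<n>, e.g. myr-V20)")
  n <- as.integer(m[2])
  conjugate_spec(paste0(DEFAULT_LS_SEQUENCE, strrep("GVGVP", n)),
                 lipid_formula = "C14H26O", mass_mode = match.arg(mass_mode))
}
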