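#' @useDynLib famedew, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif setNames lm confint predict coef median
#' @importFrom utils write.table head tail
NULL

PEPTIDE_ROLES <- c("lipidation_site", "elp")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Construct a role-labeled molecular system
#'
#' A `LabeledSystem` holds an ordered atom table plus the residue table
#' derived from it. Atoms belonging to one residue must be contiguous.
#' Internal coordinates are always in Angstrom and internal residue indices
#' are 0-based; every emitted table prints residue indices 1-based.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `residue_index` (0-based), `residue_name`, `role` (one of `lipid`,
#'   `lipidation_site`, `elp`, `water`, `other`) and coordinates `x`, `y`,
#'   `z` in Angstrom. A logical `is_heavy` column is derived from `element`
#'   if absent.
#' @return object of class `LabeledSystem` with elements `atoms`,
#'   `residues` (one row per residue with its atom span) and
#'   `peptide_length` (number of residues with a peptide role).
#' @export
labeled_system <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("serial", "name", "element", "residue_index", "residue_name",
            "role", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique within a system")
  bad_role <- setdiff(unique(atoms$role),
                      c("lipid", PEPTIDE_ROLES, "water", "other"))
  if (length(bad_role) > 0)
    stop("unknown atom role(s): ", paste(bad_role, collapse = ", "))
  atoms$is_heavy <- toupper(atoms$element) != "H"

  # residue table from runs of residue_index; spans must be contiguous
  r <- rle(atoms$residue_index)
  if (anyDuplicated(r$values))
    stop("residue atom spans must be contiguous (residue index ",
         r$values[duplicated(r$values)][1], " appears in separate runs)")
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  residues <- data.frame(
    residue_index = r$values,
    residue_name = atoms$residue_name[first],
    role = atoms$role[first],
    first_atom = first,
    last_atom = last,
    stringsAsFactors = FALSE
  )
  # role and name must be constant within a residue
  for (k in seq_len(nrow(residues))) {
    span <- residues$first_atom[k]:residues$last_atom[k]
    if (length(unique(atoms$role[span])) != 1L)
      stop("residue ", residues$residue_index[k], " mixes roles")
  }
  nwat <- residues$last_atom[residues$role == "water"] -
    residues$first_atom[residues$role == "water"] + 1L
  if (length(nwat) > 0 && !all(nwat %in% c(1L, 3L)))
    stop("water residues must contain 3 atoms (O,H,H) or 1 atom (O only)")

  structure(
    list(atoms = atoms, residues = residues,
         peptide_length = sum(residues$role %in% PEPTIDE_ROLES)),
    class = "LabeledSystem"
  )
}

#' @export
print.LabeledSystem <- function(x, ...) {
  tab <- table(x$residues$role)
  cat("LabeledSystem:", nrow(x$atoms), "atoms,", nrow(x$residues),
      "residues (", paste(names(tab), tab, sep = "=", collapse = ", "),
      "), peptide_length =", x$peptide_length, "\n")
  invisible(x)
}

#' Residue table rows with a peptide role
#' @param system LabeledSystem
#' @return data.frame subset of `system$residues`
#' @export
peptide_residues <- function(system) {
  system$residues[system$residues$role %in% PEPTIDE_ROLES, , drop = FALSE]
}

#' Single coordinate frame
#'
#' @param positions N x 3 numeric matrix, Angstrom.
#' @param box optional length-3 vector of orthorhombic box edges, Angstrom.
#' @param temperature optional temperature label, K.
#' @param time optional time, ps.
#' @param truth optional list of generator ground-truth metadata.
#' @return object of class `Frame`
#' @export
new_frame <- function(positions, box = NULL, temperature = NA_real_,
                      time = NA_real_, truth = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop("box must be three strictly positive orthorhombic edge lengths")
  }
  structure(list(positions = positions, box = box,
                 temperature = as.numeric(temperature),
                 time = as.numeric(time), truth = truth),
            class = "Frame")
}

#' Ordered frames over one labeled system
#'
#' @param system LabeledSystem shared by all frames.
#' @param frames list of `Frame` objects; each must have as many position
#'   rows as the system has atoms, and frame times (when present) must be
#'   strictly increasing.
#' @return object of class `Trajectory`
#' @export
new_trajectory <- function(system, frames) {
  stopifnot(inherits(system, "LabeledSystem"), is.list(frames))
  n <- nrow(system$atoms)
  for (f in frames) {
    stopifnot(inherits(f, "Frame"))
    if (nrow(f$positions) != n)
      stop("frame has ", nrow(f$positions), " atoms but system has ", n)
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  tt <- times[!is.na(times)]
  if (length(tt) > 1 && any(diff(tt) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(system = system, frames = frames), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames over ")
  print(x$system)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory Trajectory
#' @return integer
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

infer_element <- function(name) {
  # element column fallback: first alphabetic character of the atom name
  vapply(name, function(nm) {
    ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (length(ch) == 0) "X" else toupper(ch)
  }, character(1), USE.NAMES = FALSE)
}

#' Default residue-name to role rules
#'
#' Water models (`HOH`, `SOL`, `TIP3`, `TIP3P`, `TIP4`, `WAT`, `SPC`) map to
#' `water`, the myristoyl residue `MYR` to `lipid`, and the 20 canonical
#' amino acids (plus histidine protonation variants) to `peptide`; the
#' peptide pool is later split positionally into lipidation site and ELP.
#'
#' @return named character vector, residue name to coarse role
#' @export
default_role_rules <- function() {
  c(setNames(rep("water", 7),
             c("HOH", "SOL", "TIP3", "TIP3P", "TIP4", "WAT", "SPC")),
    MYR = "lipid",
    setNames(rep("peptide", length(AA3) + 3),
             c(unname(AA3), "HSD", "HSE", "HSP")))
}

#' Assign lipid / lipidation-site / ELP / water roles by residue name
#'
#' Roles are assigned from a residue-name rule table; the peptide pool is
#' then split positionally, the first `ls_length` peptide residues becoming
#' the lipidation site and the remainder ELP (residue names cannot tell the
#' two apart). The default `ls_length = 20` matches the
#' GLYASKLFSNLG + octahistidine lipidation site.
#'
#' @param x Trajectory or LabeledSystem.
#' @param rules named character vector mapping residue names to one of
#'   `water`, `lipid`, `peptide`, `other`; defaults to
#'   [default_role_rules()].
#' @param default role used for residue names absent from `rules`; if
#'   `NULL` (default) unmapped names raise an error listing them.
#' @param ls_length number of leading peptide residues labeled
#'   `lipidation_site`; `0` labels every peptide residue `elp`.
#' @return LabeledSystem with roles assigned
#' @export
assign_roles <- function(x, rules = default_role_rules(), default = NULL,
                         ls_length = 20L) {
  system <- if (inherits(x, "Trajectory")) x$system else x
  stopifnot(inherits(system, "LabeledSystem"))
  atoms <- system$atoms
  res <- system$residues

  coarse <- unname(rules[res$residue_name])
  if (anyNA(coarse)) {
    unmapped <- unique(res$residue_name[is.na(coarse)])
    if (is.null(default))
      stop("no role rule for residue name(s): ",
           paste(unmapped, collapse = ", "),
           " (supply a rule or a default role)")
    coarse[is.na(coarse)] <- default
  }
  role <- coarse
  pep <- which(coarse == "peptide")
  if (length(pep) > 0) {
    k <- min(as.integer(ls_length), length(pep))
    role[pep] <- "elp"
    if (k > 0) role[pep[seq_len(k)]] <- "lipidation_site"
  }
  for (i in seq_len(nrow(res)))
    atoms$role[res$first_atom[i]:res$last_atom[i]] <- role[i]
  labeled_system(atoms)
}

# ---- structure file reading -------------------------------------------------

#' Read a coordinate file into a Trajectory
#'
#' Supported formats: multi-MODEL PDB (parsed with \pkg{bio3d}), GROMACS
#' `.gro` (single or concatenated frames, nm converted to Angstrom) and
#' extended XYZ whose comment line may carry `T=<K> t=<ps>`. Roles are
#' `other` until [assign_roles()] is applied. Only orthorhombic boxes are
#' supported; triclinic input raises an error.
#'
#' @param path file path
#' @param format one of `"pdb"`, `"gro"`, `"xyz"`; default guesses from the
#'   file extension.
#' @return Trajectory
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("pdb", "gro", "xyz"))
      stop("cannot guess format from extension '", ext, "'")
    format <- ext
  }
  switch(format,
         pdb = read_pdb_trajectory(path),
         gro = read_gro_trajectory(path),
         xyz = read_xyz_trajectory(path))
}

read_pdb_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse failure in ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stop("empty input: no atoms in ", path)

  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  elem[blank] <- infer_element(at$elety[blank])
  elem <- trimws(elem)

  # 0-based internal residue index from runs of chain/resno/insert
  key <- paste(at$chain, at$resno, at$insert)
  ridx <- as.integer(factor(key, levels = unique(key))) - 1L

  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    residue_index = ridx, residue_name = trimws(at$resid),
    role = "other",
    x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (nrow(xyz) == 0) stop("empty input: zero frames in ", path)

  box <- NULL
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) > 0) {
    v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                      substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                      substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
    if (any(abs(v[4:6] - 90) > 1e-6))
      stop("unsupported triclinic box in ", path,
           " (only orthorhombic boxes are handled)")
    if (all(v[1:3] > 0)) box <- v[1:3]
  }

  # per-model temperature/time from REMARK 250 lines written by
  # write_trajectory(); absent in foreign files
  rem <- grep("^REMARK 250 +T=", lines, value = TRUE)
  temps <- times <- rep(NA_real_, nrow(xyz))
  if (length(rem) == nrow(xyz)) {
    temps <- as.numeric(sub(".*T=\\s*([-0-9.eE+]+).*", "\\1", rem))
    times <- as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", rem))
  }

  a1 <- atoms
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    new_frame(m, box = box, temperature = temps[i], time = times[i])
  })
  a1$x <- frames[[1]]$positions[, 1]
  a1$y <- frames[[1]]$positions[, 2]
  a1$z <- frames[[1]]$positions[, 3]
  new_trajectory(labeled_system(a1), frames)
}

read_gro_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("empty input: ", path, " has no frames")
  frames <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat <= 0)
      stop("GRO format error at line ", i + 1L, ": expected atom count")
    if (i + 1L + nat + 1L > length(lines))
      stop("GRO format error: truncated frame starting at line ", i)
    rows <- lines[(i + 2L):(i + 1L + nat)]
    resno <- as.integer(substr(rows, 1, 5))
    resnm <- trimws(substr(rows, 6, 10))
    atnm <- trimws(substr(rows, 11, 15))
    atno <- as.integer(substr(rows, 16, 20))
    xyz <- cbind(as.numeric(substr(rows, 21, 28)),
                 as.numeric(substr(rows, 29, 36)),
                 as.numeric(substr(rows, 37, 44))) * 10  # nm -> Angstrom
    if (anyNA(xyz))
      stop("GRO format error: bad coordinate near line ",
           i + 1L + which(apply(is.na(xyz), 1, any))[1])
    bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + 2L + nat]),
                                               "\\s+")[[1]]))
    if (length(bv) > 3 && any(abs(bv[-(1:3)]) > 1e-9))
      stop("unsupported triclinic box in ", path)
    box <- if (length(bv) >= 3 && all(bv[1:3] > 0)) bv[1:3] * 10 else NULL
    tm <- if (grepl("t=", title))
      as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", title)) else NA_real_

    if (is.null(atoms)) {
      key <- cumsum(c(TRUE, resno[-1] != resno[-length(resno)] |
                        resnm[-1] != resnm[-length(resnm)]))
      atoms <- data.frame(
        serial = ifelse(is.na(atno), seq_len(nat), atno),
        name = atnm, element = infer_element(atnm),
        residue_index = key - 1L, residue_name = resnm, role = "other",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
      if (anyDuplicated(atoms$serial)) atoms$serial <- seq_len(nat)
    }
    frames[[length(frames) + 1L]] <- new_frame(xyz, box = box, time = tm)
    i <- i + nat + 3L
  }
  if (length(frames) == 0) stop("empty input: no frames in ", path)
  new_trajectory(labeled_system(atoms), frames)
}

read_xyz_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  atoms <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat <= 0)
      stop("XYZ format error at line ", i, ": expected atom count")
    comment <- lines[i + 1L]
    rows <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad) > 0)
      stop("XYZ format error at line ", i + 1L + bad[1])
    nm <- vapply(parts, `[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    tK <- if (grepl("T=", comment))
      as.numeric(sub(".*T=\\s*([-0-9.eE+]+).*", "\\1", comment)) else NA_real_
    tp <- if (grepl("t=", comment))
      as.numeric(sub(".*t=\\s*([-0-9.eE+]+).*", "\\1", comment)) else NA_real_
    if (is.null(atoms))
      atoms <- data.frame(
        serial = seq_len(nat), name = nm, element = infer_element(nm),
        residue_index = seq_len(nat) - 1L, residue_name = "UNK",
        role = "other", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <-
      new_frame(xyz, temperature = tK, time = tp)
    i <- i + nat + 2L
  }
  if (length(frames) == 0) stop("empty input: no frames in ", path)
  new_trajectory(labeled_system(atoms), frames)
}

# ---- structure file writing -------------------------------------------------

#' Write a Trajectory as a multi-MODEL PDB file
#'
#' Emits one MODEL per frame; a `REMARK 250 T=<K> t=<ps>` line precedes each
#' MODEL when the frame carries metadata, and a `CRYST1` record is written
#' when the first frame has a box. Residue numbers are emitted 1-based.
#'
#' @param trajectory Trajectory
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "Trajectory"))
  sys <- trajectory$system
  if (nrow(sys$residues) > 9999)
    stop("PDB residue numbers overflow beyond 9999 residues")
  at <- sys$atoms
  con <- file(path, "w")
  on.exit(close(con))

  b <- trajectory$frames[[1]]$box
  if (!is.null(b))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1], b[2], b[3], 90, 90, 90), con)
  name_fmt <- function(nm) {
    ifelse(nchar(nm) <= 3, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  }
  for (i in seq_along(trajectory$frames)) {
    fr <- trajectory$frames[[i]]
    if (!is.na(fr$temperature) || !is.na(fr$time))
      writeLines(sprintf("REMARK 250 T=%.4f t=%.4f",
                         fr$temperature, fr$time), con)
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial %% 100000L, name_fmt(at$name),
      substr(at$residue_name, 1, 3), at$residue_index + 1L,
      fr$positions[, 1], fr$positions[, 2], fr$positions[, 3],
      1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a keyed result table as TSV
#'
#' Tab-separated with a header row; any `residue_index` column is emitted
#' 1-based and floating-point values are printed at 6 significant digits.
#'
#' @param rows data.frame whose rows share one key set
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_profile_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  if ("residue_index" %in% names(out))
    out$residue_index <- out$residue_index + 1L
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
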