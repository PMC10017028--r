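# Independent brute-force oracles (plain R, all-pairs O(N*M) distances)
# used to verify the package's cell-list neighbor search, plus small
# fixture builders. These deliberately share no code with the package's
# counting path.

# squared distances from one point to the rows of a matrix, with optional
# minimum-image convention
oracle_d2 <- function(p, M, box = NULL) {
  D <- sweep(M, 2, p, "-")
  if (!is.null(box)) D <- D - sweep(round(sweep(D, 2, box, "/")), 2, box, "*")
  rowSums(D^2)
}

oracle_water_counts <- function(frame, system, params = shell_params()) {
  at <- system$atoms
  pep_roles <- c("lipidation_site", "elp")
  sol_sel <- at$role %in% pep_roles
  if (params$solute_atoms == "heavy") sol_sel <- sol_sel & at$is_heavy
  sol <- frame$positions[sol_sel, , drop = FALSE]
  sol_res <- at$residue_index[sol_sel]
  pep_idx <- sort(unique(at$residue_index[at$role %in% pep_roles]))

  wat_sel <- at$role == "water"
  if (params$counting_atom == "water_oxygen")
    wat_sel <- wat_sel & toupper(at$element) == "O"
  widx <- which(wat_sel)
  wmol <- at$residue_index[widx]

  per <- setNames(numeric(length(pep_idx)), pep_idx)
  chain <- 0L
  cut2 <- params$water_cutoff^2
  for (m in unique(wmol)) {
    rows <- widx[wmol == m]
    near <- character(0)
    for (r in rows) {
      d2 <- oracle_d2(frame$positions[r, ], sol, frame$box)
      near <- union(near, as.character(sol_res[d2 < cut2]))
    }
    if (length(near) > 0) {
      chain <- chain + 1L
      per[near] <- per[near] + 1
    }
  }
  list(chain = chain, per_residue = per)
}

oracle_contacts <- function(frame, system, params = shell_params()) {
  at <- system$atoms
  sel <- at$role %in% c("lipidation_site", "elp") & at$is_heavy
  xyz <- frame$positions[sel, , drop = FALSE]
  res <- at$residue_index[sel]
  rank <- match(res, sort(unique(res)))
  cut2 <- params$contact_cutoff^2
  pairs <- character(0)
  for (i in seq_len(nrow(xyz))) {
    d2 <- oracle_d2(xyz[i, ], xyz, frame$box)
    hit <- which(d2 < cut2)
    for (j in hit) {
      sep <- abs(rank[i] - rank[j])
      if (sep >= params$min_sequence_separation)
        pairs <- union(pairs, paste(min(rank[i], rank[j]),
                                    max(rank[i], rank[j])))
    }
  }
  length(pairs)
}

# random labeled system + frame: a compact peptide cluster with waters,
# optionally inside a periodic box
random_water_system <- function(n_res, n_wat, box = NULL, seed = 1) {
  set.seed(seed)
  span <- if (is.null(box)) 14 else min(box) * 0.9
  rows <- list()
  for (i in seq_len(n_res)) {
    natoms <- sample(1:3, 1)
    ctr <- runif(3, 0, span)
    rows[[i]] <- data.frame(
      name = paste0("C", seq_len(natoms)), element = "C",
      residue_index = i - 1L, residue_name = "GLY", role = "elp",
      x = ctr[1] + runif(natoms, -1, 1), y = ctr[2] + runif(natoms, -1, 1),
      z = ctr[3] + runif(natoms, -1, 1), stringsAsFactors = FALSE)
  }
  for (w in seq_len(n_wat)) {
    rows[[n_res + w]] <- data.frame(
      name = "OW", element = "O", residue_index = n_res + w - 1L,
      residue_name = "HOH", role = "water",
      x = runif(1, 0, span), y = runif(1, 0, span), z = runif(1, 0, span),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms)
  system <- labeled_system(atoms)
  frame <- new_frame(as.matrix(atoms[, c("x", "y", "z")]), box = box)
  list(system = system, frame = frame)
}

# minimal hand-placed system: peptide single-atom residues at given
# positions plus water oxygens at given positions
point_system <- function(res_pos, wat_pos = NULL, box = NULL) {
  n <- nrow(res_pos)
  rows <- data.frame(
    serial = seq_len(n), name = "CA", element = "C",
    residue_index = seq_len(n) - 1L, residue_name = "GLY", role = "elp",
    x = res_pos[, 1], y = res_pos[, 2], z = res_pos[, 3],
    stringsAsFactors = FALSE)
  if (!is.null(wat_pos)) {
    m <- nrow(wat_pos)
    rows <- rbind(rows, data.frame(
      serial = n + seq_len(m), name = "OW", element = "O",
      residue_index = n + seq_len(m) - 1L, residue_name = "HOH",
      role = "water", x = wat_pos[, 1], y = wat_pos[, 2], z = wat_pos[, 3],
      stringsAsFactors = FALSE))
  }
  system <- labeled_system(rows)
  frame <- new_frame(as.matrix(rows[, c("x", "y", "z")]), box = box)
  list(system = system, frame = frame)
}

rotation_matrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
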