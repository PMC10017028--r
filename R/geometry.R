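# Ideal backbone internal coordinates used by the chain builders.
# Bond lengths in Angstrom, angles in degrees; only dihedrals vary.
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
BOND_C_O <- 1.231
BOND_CA_CB <- 1.530
ANGLE_N_CA_C <- 111
ANGLE_CA_C_N <- 117
ANGLE_C_N_CA <- 121
ANGLE_CA_C_O <- 120.5
ANGLE_N_CA_CB <- 110.5

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the interval (-180, 180]
#' @param x angles in degrees
#' @return wrapped angles
#' @export
wrap_angle <- function(x) {
  r <- x %% 360
  ifelse(r > 180, r - 360, r)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every generator funnels its randomness through one such stream.
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vunit <- function(v) v / sqrt(sum(v * v))

#' Torsion angle defined by four points
#'
#' IUPAC sign convention: looking from `p2` to `p3`, a clockwise rotation of
#' the far bond relative to the near bond is positive. Result in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors
#' @return dihedral angle, degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  wrap_angle(rad2deg(atan2(-sum(m1 * n2), sum(n1 * n2))))
}

# Natural-extension (NeRF) placement: position a fourth atom at `bond` from
# `c`, bond angle `angle` at c (between b-c and c-new) and torsion
# `dihedral` over a-b-c-new, both in degrees.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle)
  chi <- deg2rad(dihedral)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi),
          bond * sin(th) * sin(chi))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + cbind(bc, m, n) %*% d2
}

# Build N/CA/C/O backbone coordinates for `n` residues from phi/psi vectors
# (degrees). phi[1] and psi[n] are ignored (undefined at chain termini);
# omega is held trans. Returns a list of n x 3 matrices.
build_backbone_coords <- function(phi, psi, omega = 180) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  phi[is.na(phi)] <- 180
  psi[is.na(psi)] <- 180
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- deg2rad(ANGLE_N_CA_C)
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(pi - th), sin(pi - th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            BOND_N_CA, ANGLE_C_N_CA, omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           BOND_CA_C, ANGLE_N_CA_C, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         BOND_C_O, ANGLE_CA_C_O, wrap_angle(psi[i] + 180))
  }
  list(N = N, CA = CA, C = C, O = O)
}

# One pseudo heavy atom side chain (CB) off each non-glycine CA.
place_cb <- function(N, CA, C) {
  place_atom(C, N, CA, BOND_CA_CB, ANGLE_N_CA_CB, -122)
}

# von Mises circular sampler (Best & Fisher 1979), mean mu and concentration
# kappa, both on the degree scale for mu; kappa -> 0 degrades to uniform.
rvonmises_deg <- function(n, mu, kappa) {
  if (kappa < 1e-6) return(wrap_angle(runif(n, -180, 180) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- runif(1)
      out[i] <- rad2deg(sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f))))
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

# Uniform point in a spherical shell r in [r_in, r_out).
runif_shell <- function(n, r_in, r_out) {
  u <- runif(n)
  r <- (r_in^3 + u * (r_out^3 - r_in^3))^(1 / 3)
  # avoid landing exactly on the outer radius
  r <- pmin(r, r_out * (1 - 1e-12))
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(r * s * cos(phi), r * s * sin(phi), r * z)
}
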