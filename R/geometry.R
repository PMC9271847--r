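# Internal 3D geometry: NeRF atom placement, torsion/angle measurement and
# ideal-geometry backbone construction.  All lengths in Angstrom, all
# angles/torsions in degrees at this level (SBM building converts to nm/rad).

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) a / vnorm(a)

# place atom d given positions a-b-c, |c-d| = bond, angle(b,c,d) and
# torsion(a,b,c,d); standard natural-extension-reference-frame construction
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- vunit(c - b)
  n  <- vunit(vcross(bc, b - a))
  m  <- vcross(n, bc)
  d  <- c(-bond * cos(ang),
          -bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# signed torsion a-b-c-d in degrees, IUPAC convention in (-180, 180]
measure_torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

measure_angle <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# ideal peptide geometry (Engh-Huber-like averages)
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

# canonical phi/psi per secondary-structure type
SS_TORSIONS <- list(
  helix  = c(phi = -57,  psi = -47),
  strand = c(phi = -139, psi = 135),
  loop   = c(phi = -70,  psi = 150)
)

# Build an N/CA/C backbone trace from per-residue (phi, psi) torsions.
# Returns a list of per-residue 3x3 matrices (rows N, CA, C).
build_backbone_from_torsions <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  g <- BB_GEOM
  res <- vector("list", n)
  # seed residue in a fixed frame
  N1  <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C1  <- CA1 + g$ca_c * c(-cos(ang), sin(ang), 0)
  res[[1]] <- rbind(N = N1, CA = CA1, C = C1)
  if (n == 1) return(res)
  for (i in 2:n) {
    Np  <- res[[i - 1]]["N", ]; CAp <- res[[i - 1]]["CA", ]; Cp <- res[[i - 1]]["C", ]
    Ni  <- place_atom(Np,  CAp, Cp,  g$c_n,  g$ang_ca_c_n, psi[i - 1])
    CAi <- place_atom(CAp, Cp,  Ni,  g$n_ca, g$ang_c_n_ca, g$omega)
    Ci  <- place_atom(Cp,  Ni,  CAi, g$ca_c, g$ang_n_ca_c, phi[i])
    res[[i]] <- rbind(N = Ni, CA = CAi, C = Ci)
  }
  res
}

# carbonyl O for residue i: anti to the next residue's N (psi - 180); the
# chain-terminal O uses the trailing psi value directly
place_carbonyl_oxygens <- function(bb, psi) {
  g <- BB_GEOM
  lapply(seq_along(bb), function(i) {
    tor <- psi[i] - 180
    place_atom(bb[[i]]["N", ], bb[[i]]["CA", ], bb[[i]]["C", ],
               g$c_o, g$ang_ca_c_o, tor)
  })
}

# rigid-body helpers ---------------------------------------------------------

rotation_matrix <- function(rx, ry, rz) {
  cx <- cos(rx * pi / 180); sx <- sin(rx * pi / 180)
  cy <- cos(ry * pi / 180); sy <- sin(ry * pi / 180)
  cz <- cos(rz * pi / 180); sz <- sin(rz * pi / 180)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# center a coordinate block and align its principal axis with +x (direction
# chosen so the chain runs N->C along +x); rows are atoms
canonical_frame <- function(xyz, ca_idx) {
  ctr <- colMeans(xyz[ca_idx, , drop = FALSE])
  x0  <- sweep(xyz, 2, ctr)
  sv  <- svd(x0[ca_idx, , drop = FALSE])
  ax  <- sv$v[, 1]
  span <- x0[ca_idx[length(ca_idx)], ] - x0[ca_idx[1], ]
  if (sum(ax * span) < 0) ax <- -ax
  # orthonormal frame with ax -> x
  ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  zax <- vunit(vcross(ax, ref))
  yax <- vcross(zax, ax)
  R <- rbind(ax, yax, zax)          # world -> canonical
  t(R %*% t(x0))
}

apply_rigid <- function(xyz, rotate = c(0, 0, 0), translate = c(0, 0, 0)) {
  R <- rotation_matrix(rotate[1], rotate[2], rotate[3])
  sweep(t(R %*% t(xyz)), 2, translate, `+`)
}
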