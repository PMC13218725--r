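# Backbone dihedral angles.

# Signed dihedral (degrees) defined by four points (rows of a matrix or
# separate vectors), standard atan2 formulation.
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi angles per residue
#'
#' Standard phi (`C[i-1]-N[i]-CA[i]-C[i]`) and psi (`N[i]-CA[i]-C[i]-N[i+1]`)
#' in degrees. Chain termini and residues with missing backbone atoms get
#' `NA` (with a warning for missing atoms, not a failure).
#'
#' @param atoms Atom table from [readStructure()].
#' @param chain Chain id.
#' @return data.frame with `chain`, `position`, `wt`, `phi`, `psi`.
#' @export
computeDihedrals <- function(atoms, chain = "A") {
  at <- atoms[atoms$chain == chain, , drop = FALSE]
  if (!nrow(at)) stop(sprintf("chain '%s' absent from structure", chain))
  resno <- sort(unique(at$resno))
  get <- function(pos, name) {
    row <- which(at$resno == pos & at$elety == name)
    if (length(row) != 1L) return(NULL)
    c(at$x[row], at$y[row], at$z[row])
  }
  n <- length(resno)
  phi <- psi <- rep(NA_real_, n)
  incomplete <- 0L
  for (k in seq_len(n)) {
    Ni <- get(resno[k], "N"); CAi <- get(resno[k], "CA"); Ci <- get(resno[k], "C")
    if (is.null(Ni) || is.null(CAi) || is.null(Ci)) {
      incomplete <- incomplete + 1L
      next
    }
    if (k > 1L && resno[k - 1L] == resno[k] - 1L) {
      Cprev <- get(resno[k - 1L], "C")
      if (!is.null(Cprev)) phi[k] <- dihedralAngle(Cprev, Ni, CAi, Ci)
    }
    if (k < n && resno[k + 1L] == resno[k] + 1L) {
      Nnext <- get(resno[k + 1L], "N")
      if (!is.null(Nnext)) psi[k] <- dihedralAngle(Ni, CAi, Ci, Nnext)
    }
  }
  if (incomplete)
    warning(sprintf("%d residue(s) lack complete N/CA/C backbone; dihedrals set to NA",
                    incomplete))
  aa <- at$aa[match(resno, at$resno)]
  data.frame(chain = chain, position = resno, wt = aa, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

# Build peptide backbone coordinates (N, CA, C) from phi/psi by internal
# coordinates (NeRF chain extension) with ideal bond geometry. Used to
# construct dihedral test fixtures with known angles; omega fixed at 180.
buildBackbone <- function(phi, psi) {
  stopifnot(length(phi) == length(psi))
  n <- length(phi)
  # bond lengths and angles (degrees): N-CA 1.458, CA-C 1.525, C-N 1.329
  place <- function(a, b, c, bond, angle, torsion) {
    ang <- angle * pi / 180; tor <- torsion * pi / 180
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
             ab[3] * bc[1] - ab[1] * bc[3],
             ab[1] * bc[2] - ab[2] * bc[1])
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- c(nrm[2] * bc[3] - nrm[3] * bc[2],
           nrm[3] * bc[1] - nrm[1] * bc[3],
           nrm[1] * bc[2] - nrm[2] * bc[1])
    d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
    c + d[1] * bc + d[2] * m + d[3] * nrm
  }
  coords <- matrix(NA_real_, 3L * n, 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  # seed first residue
  coords[1L, ] <- c(0, 0, 0)                               # N1
  coords[2L, ] <- c(1.458, 0, 0)                           # CA1
  th <- 111.2 * pi / 180
  coords[3L, ] <- coords[2L, ] + 1.525 * c(cos(pi - th), sin(pi - th), 0)  # C1
  for (k in 2L:n) {
    i <- 3L * (k - 1L)
    # N[k]: torsion psi[k-1] about CA-C
    coords[i + 1L, ] <- place(coords[i - 2L, ], coords[i - 1L, ], coords[i, ],
                              1.329, 116.2, psi[k - 1L])
    # CA[k]: omega = 180 about C-N
    coords[i + 2L, ] <- place(coords[i - 1L, ], coords[i, ], coords[i + 1L, ],
                              1.458, 121.7, 180)
    # C[k]: torsion phi[k] about N-CA
    coords[i + 3L, ] <- place(coords[i, ], coords[i + 1L, ], coords[i + 2L, ],
                              1.525, 111.2, phi[k])
  }
  data.frame(chain = "A", resno = rep(seq_len(n), each = 3L),
             resid = "ALA", aa = "A",
             elety = rep(c("N", "CA", "C"), n),
             elem = rep(c("N", "C", "C"), n),
             x = coords[, 1L], y = coords[, 2L], z = coords[, 3L], o = 1,
             stringsAsFactors = FALSE)
}
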