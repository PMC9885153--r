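#' Realize a conformation from backbone dihedral angles
#'
#' Builds Cartesian coordinates for every particle of a topology from one
#' (phi, psi) pair per residue, using fixed internal coordinates (bond
#' lengths/angles from the `geometry` section of the parameter file, omega
#' fixed at 180 degrees).  The side-chain bead is placed along the
#' CA -> pseudo-C-beta direction at the residue's `sc_distance`, with
#' L-amino-acid chirality.
#'
#' @param topo `PeptideTopology`.
#' @param dihedrals L x 2 matrix (or data.frame) of (phi, psi) in degrees.
#' @param ff `ForceFieldParams` supplying the internal coordinates.
#' @return an object of class `Conformation` with elements `coords`
#'   (n_particles x 3, Angstrom) and `dihedrals`.
#' @examples
#' topo <- parse_sequence("AAAAAAAAAAAAAAA")
#' helix <- build_conformation(topo, cbind(rep(-57, 15), rep(-47, 15)))
#' @export
build_conformation <- function(topo, dihedrals, ff = default_forcefield()) {
  stopifnot(inherits(topo, "PeptideTopology"))
  dihedrals <- as.matrix(dihedrals)
  if (nrow(dihedrals) != topo$L || ncol(dihedrals) != 2)
    stop("dihedrals must be an L x 2 matrix of (phi, psi); got ",
         nrow(dihedrals), " x ", ncol(dihedrals), " for L = ", topo$L)
  if (any(!is.finite(dihedrals)))
    stop("dihedrals must be finite")
  coords <- cpp_build_chain(
    dihedrals[, 1], dihedrals[, 2],
    topo$idx$N - 1L, topo$idx$H - 1L, topo$idx$CA - 1L,
    topo$idx$C - 1L, topo$idx$O - 1L,
    ifelse(is.na(topo$idx$SC), -1L, topo$idx$SC - 1L),
    topo$residues$sc_distance, ff$geometry, topo$n_particles
  )
  structure(list(coords = coords, dihedrals = dihedrals),
            class = "Conformation")
}

#' @export
print.Conformation <- function(x, ...) {
  cat("Conformation:", nrow(x$coords), "particles\n")
  invisible(x)
}

# torsion angle (degrees, IUPAC sign) for four points
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2u[3] - n1[3] * b2u[2],
          n1[3] * b2u[1] - n1[1] * b2u[3],
          n1[1] * b2u[2] - n1[2] * b2u[1])
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Measure backbone dihedrals from coordinates
#'
#' Standard definitions: phi(i) = C(i-1)-N(i)-CA(i)-C(i) and
#' psi(i) = N(i)-CA(i)-C(i)-N(i+1).  The first phi and the last psi are
#' undefined and reported as `NA`.
#'
#' @param conf `Conformation`.
#' @param topo matching `PeptideTopology`.
#' @return L x 2 matrix of (phi, psi) in degrees with `NA` at the termini.
#' @export
measure_dihedrals <- function(conf, topo) {
  stopifnot(inherits(topo, "PeptideTopology"))
  X <- conf$coords
  if (nrow(X) != topo$n_particles)
    stop("conformation has ", nrow(X), " particles but topology expects ",
         topo$n_particles)
  L <- topo$L
  idx <- topo$idx
  out <- matrix(NA_real_, L, 2, dimnames = list(NULL, c("phi", "psi")))
  for (i in seq_len(L)) {
    if (i > 1)
      out[i, 1] <- dihedral_angle(X[idx$C[i - 1], ], X[idx$N[i], ],
                                  X[idx$CA[i], ], X[idx$C[i], ])
    if (i < L)
      out[i, 2] <- dihedral_angle(X[idx$N[i], ], X[idx$CA[i], ],
                                  X[idx$C[i], ], X[idx$N[i + 1], ])
  }
  out
}
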