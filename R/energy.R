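#' Flat-bottomed dihedral well energy
#'
#' Zero inside the interval `[low, high]`; quadratic in the periodic
#' (shorter-arc) angular distance to the nearest bound outside it.  Applied
#' independently to phi and psi with residue-type-specific intervals.
#'
#' @param dihedral angle in degrees, interpreted on the circle.
#' @param low,high well bounds in degrees, `low < high`.
#' @param eps_phi stiffness in kcal/mol/deg^2.
#' @return energy in kcal/mol.
#' @examples
#' local_energy(-60, -90, -30, 0.005)   # inside the well: 0
#' local_energy(-20, -90, -30, 0.005)   # 0.005 * 10^2
#' @export
local_energy <- function(dihedral, low, high, eps_phi) {
  stopifnot(low < high)
  x <- wrap_angle(dihedral)
  inside <- x >= low & x <= high
  dlo <- abs(wrap_angle(x - low))
  dhi <- abs(wrap_angle(x - high))
  d <- pmin(dlo, dhi)
  ifelse(inside, 0, eps_phi * d^2)
}

wrap_angle <- function(x) {
  y <- (x + 180) %% 360
  y[y < 0] <- y[y < 0] + 360
  y - 180
}

#' Mie pair energy
#'
#' Generalized Lennard-Jones with exponents n > m: depth `-eps` at `r0`,
#' zero at `gR0 = (m/n)^(1/(n-m)) r0`.  With `repulsive_only`, only the
#' repulsive branch survives (the attractive tail is clamped to zero), which
#' is how charged side-chain pairs are treated.
#'
#' @param r distance in Angstrom (vectorized), must be positive.
#' @param p `MiePairParams` (see [mie_pair_params()]) or a list with fields
#'   `eps`, `r0`, `n`, `m` and optionally `repulsive_only`.
#' @return energy in kcal/mol.
#' @export
mie_energy <- function(r, p) {
  if (any(r <= 0)) stop("mie_energy requires r > 0")
  n <- p$n; m <- p$m
  rr <- p$r0 / r
  E <- p$eps * (m / (n - m) * rr^n - n / (n - m) * rr^m)
  if (isTRUE(p$repulsive_only)) E <- pmax(E, 0)
  E
}

#' Hydrogen-bond radial 12-10 term
#'
#' `depth * (5 (sigma/r)^12 - 6 (sigma/r)^10)`, minimum value `-depth`
#' attained exactly at `r = sigma` (1.8 Angstrom by default).
#'
#' @param r H...O distance in Angstrom (vectorized).
#' @param hb list with fields `sigma` and `depth` (the packaged defaults are
#'   in the `hbond` section of [default_forcefield()]).
#' @return energy in kcal/mol.
#' @export
hbond_radial <- function(r, hb) {
  if (any(r <= 0)) stop("hbond_radial requires r > 0")
  q <- hb$sigma / r
  hb$depth * (5 * q^12 - 6 * q^10)
}

#' Hydrogen-bond angular factor
#'
#' `cos^2(alpha)` for donor-H-acceptor angles alpha > 90 degrees, zero
#' otherwise: continuous at 90 degrees and equal to 1 for a collinear bond.
#'
#' @param alpha angle in degrees, in `[0, 180]` (vectorized).
#' @return dimensionless factor in `[0, 1]`.
#' @export
hbond_angular <- function(alpha) {
  stopifnot(all(alpha >= 0 & alpha <= 180))
  ca <- cos(alpha * pi / 180)
  ifelse(ca < 0, ca^2, 0)
}

# angle (degrees) at vertex b of triangle a-b-c
vertex_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cc <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cc))) * 180 / pi
}

#' Pairwise hydrogen-bond energy and recorded bond list
#'
#' Sums the radial x angular product over donor H(i) / acceptor O(j) pairs
#' with residue separation of at least `min_separation` (4).  Helical bonds
#' O(j)...H(j+4) (donor four residues after the acceptor) carry the
#' `eps_alpha_hb` weight; all other admissible pairs carry `eps_beta_hb`.
#' A bond is recorded when `mu * nu <= -record_threshold * depth`; the
#' recorded list feeds the cooperative term and the secondary-structure
#' assigner.  Proline is excluded as a donor.
#'
#' @param conf `Conformation`.
#' @param topo `PeptideTopology`.
#' @param ff `ForceFieldParams`.
#' @return list with `energy` (kcal/mol) and `hbonds`, a data.frame with
#'   columns donor, acceptor, r, alpha, mu_nu.
#' @export
hbond_pairwise <- function(conf, topo, ff = default_forcefield()) {
  hb <- ff$hbond
  X <- conf$coords
  idx <- topo$idx
  L <- topo$L
  energy <- 0
  rec <- list()
  for (i in seq_len(L)) {
    if (!topo$residues$hb_donor[i]) next
    for (j in seq_len(L)) {
      if (abs(i - j) < hb$min_separation) next
      Hp <- X[idx$H[i], ]; Op <- X[idx$O[j], ]; Np <- X[idx$N[i], ]
      r <- sqrt(sum((Hp - Op)^2))
      mu <- hbond_radial(r, hb)
      alpha <- vertex_angle(Np, Hp, Op)
      nu <- hbond_angular(alpha)
      w <- if (i - j == hb$min_separation) hb$eps_alpha_hb else hb$eps_beta_hb
      energy <- energy + w * mu * nu
      if (mu * nu <= -hb$record_threshold * hb$depth)
        rec[[length(rec) + 1]] <-
          data.frame(donor = i, acceptor = j, r = r, alpha = alpha,
                     mu_nu = mu * nu)
    }
  }
  hbonds <- if (length(rec) > 0) do.call(rbind, rec) else
    data.frame(donor = integer(), acceptor = integer(), r = numeric(),
               alpha = numeric(), mu_nu = numeric())
  list(energy = energy, hbonds = hbonds)
}

#' Cooperative four-body hydrogen-bond energy
#'
#' For ordered pairs of recorded H-bonds (i,j) then (k,l): a Gaussian factor
#' `C = exp(-(r_ij - sigma)^2 / 2) exp(-(r_kl - sigma)^2 / 2)` (r in
#' Angstrom) is added with weight `eps_alpha_coop` when (k,l) = (i+1, j+1)
#' (consecutive helical bonds) and `eps_beta_coop` when (k,l) = (i+2, j-2)
#' or (i+2, j+2) (antiparallel / parallel sheet ladders).
#'
#' @param hbonds recorded bond data.frame from [hbond_pairwise()].
#' @param ff `ForceFieldParams`.
#' @return energy in kcal/mol.
#' @export
hbond_cooperative <- function(hbonds, ff = default_forcefield()) {
  hb <- ff$hbond
  n <- nrow(hbonds)
  if (n < 2) return(0)
  ord <- order(hbonds$donor, hbonds$acceptor)
  hbonds <- hbonds[ord, ]
  energy <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      dd <- hbonds$donor[b] - hbonds$donor[a]
      da <- hbonds$acceptor[b] - hbonds$acceptor[a]
      w <- 0
      if (dd == 1 && da == 1) w <- hb$eps_alpha_coop
      else if (dd == 2 && (da == -2 || da == 2)) w <- hb$eps_beta_coop
      if (w != 0) {
        C <- exp(-0.5 * (hbonds$r[a] - hb$sigma)^2) *
          exp(-0.5 * (hbonds$r[b] - hb$sigma)^2)
        energy <- energy + w * C
      }
    }
  }
  energy
}

#' pH-independent coarse-grained energy of a conformation
#'
#' Reference implementation of the local + non-bonded + hydrogen-bond energy
#' (no electrostatics; see [total_energy()] for the pH-dependent sum).
#' Non-bonded interactions run over particle pairs separated by more than
#' two covalent bonds, with per-pair Mie parameters resolved by particle
#' type.  Charged side-chain pairs (passed via `charge_state`) keep only the
#' repulsive Mie branch.
#'
#' @param conf `Conformation`.
#' @param topo `PeptideTopology`.
#' @param ff `ForceFieldParams`.
#' @param charge_state optional `ChargeState`; used only to flag charged
#'   side-chain beads for the repulsive-only rule.
#' @return an `EnergyReport` list with components `e_local`, `e_nonbonded`,
#'   `e_hb_pairwise`, `e_hb_coop`, `e_dh` (0 here), `e_total` and the
#'   recorded `hbonds`.
#' @export
sopep_energy <- function(conf, topo, ff = default_forcefield(),
                         charge_state = NULL) {
  X <- conf$coords
  if (nrow(X) != topo$n_particles)
    stop("conformation/topology particle count mismatch")
  # local term from measured dihedrals (terminal phi/psi are undefined)
  dih <- measure_dihedrals(conf, topo)
  wells <- local_well_table(ff, topo$sequence)
  e_local <- 0
  for (i in seq_len(topo$L)) {
    if (!is.na(dih[i, 1]))
      e_local <- e_local +
        unname(local_energy(dih[i, 1], wells[i, 1], wells[i, 2],
                            ff$local$eps_phi))
    if (!is.na(dih[i, 2]))
      e_local <- e_local +
        unname(local_energy(dih[i, 2], wells[i, 3], wells[i, 4],
                            ff$local$eps_phi))
  }
  # Mie non-bonded
  tab <- build_mie_tables(ff)
  D <- as.matrix(dist(X))
  keep <- topo$exclusion & upper.tri(D)
  charged <- charged_sc_flags(topo, charge_state, ff)
  ij <- which(keep, arr.ind = TRUE)
  ti <- topo$particles$type[ij[, 1]]
  tj <- topo$particles$type[ij[, 2]]
  r <- D[keep]
  n <- tab$n[cbind(ti, tj)]; m <- tab$m[cbind(ti, tj)]
  rr <- tab$r0[cbind(ti, tj)] / r
  E <- tab$eps[cbind(ti, tj)] * (m / (n - m) * rr^n - n / (n - m) * rr^m)
  rep_only <- charged[ij[, 1]] & charged[ij[, 2]]
  E[rep_only] <- pmax(E[rep_only], 0)
  e_nonbonded <- sum(E)

  hbp <- hbond_pairwise(conf, topo, ff)
  e_coop <- hbond_cooperative(hbp$hbonds, ff)

  report <- list(
    e_local = e_local, e_nonbonded = e_nonbonded,
    e_hb_pairwise = hbp$energy, e_hb_coop = e_coop, e_dh = 0,
    e_total = e_local + e_nonbonded + hbp$energy + e_coop,
    hbonds = hbp$hbonds
  )
  class(report) <- "EnergyReport"
  report
}

# per-particle flag: side-chain bead carrying |q| >= charge_threshold
charged_sc_flags <- function(topo, charge_state, ff) {
  flags <- rep(FALSE, topo$n_particles)
  if (is.null(charge_state)) return(flags)
  sc <- topo$particles$kind == "SC"
  flags[sc] <- abs(charge_state$q[sc]) >= ff$dh$charge_threshold
  flags
}

#' @export
print.EnergyReport <- function(x, ...) {
  cat(sprintf("EnergyReport (kcal/mol)\n"))
  cat(sprintf("  local      %10.4f\n", x$e_local))
  cat(sprintf("  nonbonded  %10.4f\n", x$e_nonbonded))
  cat(sprintf("  hb pair    %10.4f\n", x$e_hb_pairwise))
  cat(sprintf("  hb coop    %10.4f\n", x$e_hb_coop))
  cat(sprintf("  DH         %10.4f\n", x$e_dh))
  cat(sprintf("  total      %10.4f\n", x$e_total))
  invisible(x)
}

#' Total energy including Debye-Hueckel electrostatics
#'
#' Adds the weighted, shifted, truncated Debye-Hueckel term for the given
#' charge state to the pH-independent energy.
#'
#' @param conf `Conformation`.
#' @param topo `PeptideTopology`.
#' @param ff `ForceFieldParams`.
#' @param charge_state `ChargeState` from [assign_charges()]; `NULL` gives
#'   the chargeless (DH-disabled) energy.
#' @return an `EnergyReport`.
#' @export
total_energy <- function(conf, topo, ff = default_forcefield(),
                         charge_state = NULL) {
  report <- sopep_energy(conf, topo, ff, charge_state)
  if (!is.null(charge_state)) {
    report$e_dh <- dh_total_energy(conf, topo, charge_state, ff)
    report$e_total <- report$e_total + report$e_dh
  }
  report
}
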