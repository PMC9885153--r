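#' Sigmoidal distance-dependent dielectric
#'
#' `eps(r) = Dw - (Dw - Dp) (s^2 r^2 / 2 + s r + 1) exp(-s r)`: equal to the
#' protein-interior value `Dp` at contact and rising monotonically to the
#' bulk-water value `Dw` at large separation.  Defaults Dw = 78, Dp = 2,
#' s = 0.6 per Angstrom.
#'
#' @param r distance in Angstrom (vectorized), non-negative.
#' @param d list with fields `dw`, `dp`, `s` (see the `dh` section of
#'   [default_forcefield()]).
#' @return dimensionless dielectric value in `[Dp, Dw]`.
#' @examples
#' sigmoidal_dielectric(0, list(dw = 78, dp = 2, s = 0.6))    # 2
#' sigmoidal_dielectric(1e6, list(dw = 78, dp = 2, s = 0.6))  # 78
#' @export
sigmoidal_dielectric <- function(r, d) {
  stopifnot(all(r >= 0))
  sr <- d$s * r
  d$dw - (d$dw - d$dp) * (sr^2 / 2 + sr + 1) * exp(-sr)
}

#' Debye screening length
#'
#' Standard aqueous electrolyte formula, `3.04 / sqrt(I)` Angstrom at 298 K
#' (scaled by `sqrt(T / 298)` at other temperatures).  Below an ionic
#' strength of 1e-7 mol/L the length is capped at 1e4 Angstrom, so the
#' no-salt limit behaves as an unscreened interaction at peptide scales.
#'
#' @param ionic_strength mol/L, non-negative.
#' @param temperature Kelvin.
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(ionic_strength, temperature = 298) {
  if (ionic_strength < 0) stop("ionic strength must be non-negative")
  if (ionic_strength < 1e-7) return(1e4)
  min(1e4, 3.04 * sqrt(temperature / 298) / sqrt(ionic_strength))
}

#' Assign pH-dependent fractional charges
#'
#' Henderson-Hasselbalch titration: acids (D, E side chains, C-terminal
#' carboxyl) get `q = -1 / (1 + 10^(pKa - pH))`, bases (H, K, R side chains,
#' N-terminal ammonium) get `q = +1 / (1 + 10^(pH - pKa))`.  Side-chain
#' charges sit on the SC bead; the N-terminal charge on the first backbone
#' N and the C-terminal charge on the last backbone C, unless the
#' corresponding blocking flag of the topology is set, in which case the
#' extremity carries no charge.  All other particles are neutral.
#'
#' @param topo `PeptideTopology`.
#' @param pH in `[0, 14]`.
#' @param ionic_strength mol/L (stored, used for the Debye length).
#' @param ff `ForceFieldParams` supplying the pKa table.
#' @return an object of class `ChargeState` with per-particle charges `q`,
#'   `pH`, `ionic_strength` and `debye_length`; the per-pair Debye-Hueckel
#'   calibration is attached lazily by [dh_calibrate()].
#' @examples
#' topo <- parse_sequence("KKKKKKKKKKKKKKK", n_blocked = TRUE, c_blocked = TRUE)
#' cs <- assign_charges(topo, pH = 10.5)
#' sum(abs(cs$q) > 0)  # 15 half-charged side chains, no terminal charges
#' @export
assign_charges <- function(topo, pH, ionic_strength = 0.15,
                           ff = default_forcefield()) {
  stopifnot(inherits(topo, "PeptideTopology"))
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]")
  acid_frac <- function(pka) -1 / (1 + 10^(pka - pH))
  base_frac <- function(pka) 1 / (1 + 10^(pH - pka))
  q <- numeric(topo$n_particles)
  for (i in seq_len(topo$L)) {
    if (!topo$residues$titratable[i]) next
    aa <- topo$sequence[i]
    pka <- ff$pka$side_chain[[aa]]
    q[topo$idx$SC[i]] <-
      if (aa %in% c("D", "E")) acid_frac(pka) else base_frac(pka)
  }
  if (!topo$n_blocked)
    q[topo$idx$N[1]] <- base_frac(ff$pka$n_terminus)
  if (!topo$c_blocked)
    q[topo$idx$C[topo$L]] <- acid_frac(ff$pka$c_terminus)
  structure(list(q = q, pH = pH, ionic_strength = ionic_strength,
                 debye_length = debye_length(ionic_strength),
                 pairs = NULL),
            class = "ChargeState")
}

#' @export
print.ChargeState <- function(x, ...) {
  cat(sprintf("ChargeState: pH %.2f, I %.3f mol/L, l_DH %.2f A\n",
              x$pH, x$ionic_strength, x$debye_length))
  cat(sprintf("  charged particles (|q| > 0.01): %d, net charge %+.3f e\n",
              sum(abs(x$q) > 0.01), sum(x$q)))
  invisible(x)
}

#' Calibrate the Debye-Hueckel shift against the Mie curve for one pair
#'
#' Reproduces the construction in which the shifted Debye-Hueckel curve is
#' made to cross the Mie curve of the particle pair at an energy `k`
#' (4 kcal/mol by default).  `crossing_r` is the distance on the repulsive
#' Mie branch where the pair energy equals `+k`; the shift then solves
#' `|E_DH|` evaluated at `crossing_r + shift` (with the dielectric taken at
#' the unshifted `crossing_r`) equal to `k`.  The magnitude `|q_i q_j|` is
#' used so that attractive pairs receive the same geometric shift.
#'
#' @param pair_mie `MiePairParams` for the particle pair.
#' @param q_prod product of the two charges (e^2), non-zero.
#' @param l_dh Debye length in Angstrom.
#' @param d dielectric parameter list (`dw`, `dp`, `s`) with Coulomb
#'   constant `coulomb` (332.06 kcal A / (mol e^2) by default).
#' @param k crossing energy in kcal/mol, positive.
#' @return list with `shift` and `crossing_r`, both in Angstrom.
#' @export
fit_shift <- function(pair_mie, q_prod, l_dh, d, k = 4) {
  if (q_prod == 0) stop("fit_shift requires a non-zero charge product")
  if (k <= 0) stop("crossing energy k must be positive")
  coul <- if (is.null(d$coulomb)) 332.06 else d$coulomb
  qq <- abs(q_prod)
  # crossing: Mie energy = +k on the repulsive branch (0, gR0)
  gR0 <- (pair_mie$m / pair_mie$n)^(1 / (pair_mie$n - pair_mie$m)) *
    pair_mie$r0
  f_mie <- function(r) mie_energy(r, pair_mie) - k
  lo <- 1e-3 * pair_mie$r0
  if (f_mie(lo) < 0 || f_mie(gR0) > 0)
    stop("no Mie crossing at +", k, " kcal/mol on (0, r0) for this pair")
  crossing_r <- bisect(f_mie, lo, gR0, tol = 1e-6)
  # shift: |E_DH(crossing_r + shift)| = k, dielectric frozen at crossing_r
  eps_r <- sigmoidal_dielectric(crossing_r, d)
  f_dh <- function(shift) {
    rs <- crossing_r + shift
    coul * qq * exp(-rs / l_dh) / (eps_r * rs) - k
  }
  lo_s <- (1e-9 - 1) * crossing_r    # rs -> 0+, where |E_DH| diverges
  hi_s <- 100
  if (f_dh(hi_s) > 0)
    stop("shift search not bracketed: |E_DH| > k even at shift = ", hi_s)
  shift <- bisect(f_dh, lo_s, hi_s, tol = 1e-6)
  list(shift = shift, crossing_r = crossing_r)
}

bisect <- function(f, lo, hi, tol = 1e-6, max_iter = 200) {
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("bisection bracket does not change sign on [", lo, ", ", hi, "]")
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (flo * fm < 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

#' Shifted, truncated Debye-Hueckel pair energy
#'
#' `E = C_elec q_i q_j exp(-(r + shift)/l_DH) / (eps(r) (r + shift))` with
#' the dielectric evaluated at the unshifted distance.  Below the calibrated
#' crossing distance the magnitude is truncated (clamped) at `k`, preserving
#' sign, so the electrostatic term never overwhelms the Mie core.
#'
#' @param r distance in Angstrom, positive.
#' @param q_i,q_j charges in units of e.
#' @param shift,crossing_r Angstrom, from [fit_shift()].
#' @param l_dh Debye length in Angstrom.
#' @param d dielectric parameter list (`dw`, `dp`, `s`, optional `coulomb`).
#' @param k truncation energy in kcal/mol.
#' @param truncation `"clamp"` (default) or `"none"`.
#' @return energy in kcal/mol.
#' @export
dh_pair_energy <- function(r, q_i, q_j, shift, crossing_r, l_dh, d, k = 4,
                           truncation = c("clamp", "none")) {
  if (any(r <= 0)) stop("dh_pair_energy requires r > 0")
  truncation <- match.arg(truncation)
  coul <- if (is.null(d$coulomb)) 332.06 else d$coulomb
  qq <- q_i * q_j
  if (qq == 0) return(rep(0, length(r)))
  rs <- r + shift
  E <- ifelse(rs <= 1e-6, sign(qq) * k,
              coul * qq * exp(-rs / l_dh) / (sigmoidal_dielectric(r, d) * rs))
  if (truncation == "clamp") {
    below <- r < crossing_r & abs(E) > k
    E[below] <- sign(E[below]) * k
  }
  E
}

# Attach the per-pair DH calibration (shift/crossing for every charged
# particle pair) to a charge state.  Shifts depend only on (pair type, pH,
# ionic strength), so they are computed once per unique (type_i, type_j,
# |q_i q_j|) and reused.
#' Attach Debye-Hueckel pair calibration to a charge state
#'
#' Computes [fit_shift()] results for every pair of charged particles of a
#' topology and caches them in the `ChargeState` (`pairs` element: indices
#' of charged particles plus shift and crossing matrices).  Called
#' automatically by the energy and sampling entry points.
#'
#' @param cs `ChargeState`.
#' @param topo matching `PeptideTopology`.
#' @param ff `ForceFieldParams`.
#' @return the charge state with the `pairs` element filled.
#' @export
dh_calibrate <- function(cs, topo, ff = default_forcefield()) {
  if (!is.null(cs$pairs)) return(cs)
  cidx <- which(abs(cs$q) > 1e-6)
  nc <- length(cidx)
  shift <- matrix(0, nc, nc)
  crossing <- matrix(0, nc, nc)
  d <- list(dw = ff$dh$dw, dp = ff$dh$dp, s = ff$dh$s,
            coulomb = ff$dh$coulomb)
  cache <- new.env(parent = emptyenv())
  types <- particle_types()
  if (nc >= 2) {
    for (a in seq_len(nc - 1)) {
      for (b in (a + 1):nc) {
        i <- cidx[a]; j <- cidx[b]
        ti <- topo$particles$type[i]; tj <- topo$particles$type[j]
        qq <- abs(cs$q[i] * cs$q[j])
        if (qq < 1e-8) next  # negligible pair: unshifted, untruncated
        key <- paste(min(ti, tj), max(ti, tj), signif(qq, 10), sep = "_")
        hit <- get0(key, envir = cache)
        if (is.null(hit)) {
          pm <- mie_pair_params(ff, types[ti], types[tj])
          hit <- fit_shift(pm, qq, cs$debye_length, d, ff$dh$k_cross)
          assign(key, hit, envir = cache)
        }
        shift[a, b] <- shift[b, a] <- hit$shift
        crossing[a, b] <- crossing[b, a] <- hit$crossing_r
      }
    }
  }
  cs$pairs <- list(cidx = cidx, shift = shift, crossing = crossing)
  cs
}

#' Total Debye-Hueckel energy of a conformation
#'
#' Sums the shifted, truncated pair energy over charged particle pairs with
#' particle index `j > i + 1` and residue separation of at least 1, each
#' term weighted by `w_near` (10) when the residue separation is below the
#' cutoff (7) and `w_far` (2) otherwise.
#'
#' @param conf `Conformation`.
#' @param topo `PeptideTopology`.
#' @param cs `ChargeState` (calibrated automatically if needed).
#' @param ff `ForceFieldParams`.
#' @return energy in kcal/mol.
#' @export
dh_total_energy <- function(conf, topo, cs, ff = default_forcefield()) {
  cs <- dh_calibrate(cs, topo, ff)
  p <- cs$pairs
  nc <- length(p$cidx)
  if (nc < 2) return(0)
  X <- conf$coords
  resid <- topo$particles$residue
  d <- list(dw = ff$dh$dw, dp = ff$dh$dp, s = ff$dh$s,
            coulomb = ff$dh$coulomb)
  trunc <- if (identical(ff$dh$truncation, "none")) "none" else "clamp"
  total <- 0
  for (a in seq_len(nc - 1)) {
    i <- p$cidx[a]
    for (b in (a + 1):nc) {
      j <- p$cidx[b]
      if (j <= i + 1) next
      rsep <- abs(resid[j] - resid[i])
      if (rsep < 1) next
      r <- sqrt(sum((X[i, ] - X[j, ])^2))
      E <- dh_pair_energy(r, cs$q[i], cs$q[j], p$shift[a, b],
                          p$crossing[a, b], cs$debye_length, d,
                          ff$dh$k_cross, trunc)
      w <- if (rsep < ff$dh$separation_cutoff) ff$dh$w_near else ff$dh$w_far
      total <- total + w * E
    }
  }
  total
}
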