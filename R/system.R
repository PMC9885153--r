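# Pack topology + parameters + charge state into the flat list consumed by
# the C++ kernel.  Index vectors are 0-based on the C++ side.
prepare_system <- function(topo, ff, charge_state = NULL, use_dh = NULL) {
  tab <- build_mie_tables(ff)
  wells <- local_well_table(ff, topo$sequence)
  if (is.null(use_dh)) use_dh <- !is.null(charge_state)
  charged <- charged_sc_flags(topo, charge_state, ff)
  if (use_dh) {
    if (is.null(charge_state))
      stop("use_dh = TRUE requires a charge state")
    charge_state <- dh_calibrate(charge_state, topo, ff)
    p <- charge_state$pairs
    dh <- list(use_dh = TRUE, cidx = p$cidx - 1L,
               cq = charge_state$q[p$cidx],
               shift = p$shift, crossing = p$crossing,
               l_dh = charge_state$debye_length)
  } else {
    dh <- list(use_dh = FALSE, cidx = integer(0), cq = numeric(0),
               shift = matrix(0, 0, 0), crossing = matrix(0, 0, 0),
               l_dh = 1)
  }
  dh <- c(dh, list(
    dw = ff$dh$dw, dp = ff$dh$dp, s = ff$dh$s, coulomb = ff$dh$coulomb,
    k_cross = ff$dh$k_cross, w_near = ff$dh$w_near, w_far = ff$dh$w_far,
    separation_cutoff = as.integer(ff$dh$separation_cutoff),
    trunc = if (identical(ff$dh$truncation, "none")) 1L else 0L
  ))
  list(
    L = topo$L, npart = topo$n_particles,
    idxN = topo$idx$N - 1L, idxH = topo$idx$H - 1L,
    idxCA = topo$idx$CA - 1L, idxC = topo$idx$C - 1L,
    idxO = topo$idx$O - 1L,
    idxSC = ifelse(is.na(topo$idx$SC), -1L, topo$idx$SC - 1L),
    sc_dist = topo$residues$sc_distance,
    geom = ff$geometry,
    type = topo$particles$type - 1L,
    EPS = tab$eps, R0 = tab$r0, NN = tab$n, MM = tab$m,
    keep = topo$exclusion,
    charged_sc = charged,
    resid = topo$particles$residue,
    phi_low = wells[, 1], phi_high = wells[, 2],
    psi_low = wells[, 3], psi_high = wells[, 4],
    eps_phi = ff$local$eps_phi,
    hb = c(ff$hbond, list(donor_ok = topo$residues$hb_donor)),
    dh = dh
  )
}

# Fast-path energy via the C++ kernel; same contract as total_energy().
cpp_total_energy <- function(conf, topo, ff, charge_state = NULL,
                             use_dh = NULL) {
  sys <- prepare_system(topo, ff, charge_state, use_dh)
  dih <- conf$dihedrals
  if (is.null(dih)) dih <- measure_dihedrals(conf, topo)
  dih2 <- dih
  dih2[is.na(dih2)] <- 0  # terminal angles carry no local energy
  en <- cpp_energy(conf$coords, dih2[, 1], dih2[, 2], sys)
  en
}
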