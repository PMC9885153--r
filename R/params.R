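#' Load force-field parameters from a structured text file
#'
#' All tunable constants of the model live in one YAML document: internal
#' geometry, dihedral wells, Mie pair parameters, hydrogen-bond weights,
#' Debye-Hueckel constants, pKa values and the per-residue side-chain bead
#' table.  See the file shipped at
#' `system.file("extdata", "forcefield_defaults.yaml", package = "phfold")`
#' for the documented schema.
#'
#' @param path path to a YAML parameter file.
#' @param overrides optional named list merged recursively over the file
#'   contents (e.g. `list(hbond = list(depth = 1.2))`).
#' @return an object of class `ForceFieldParams` (a validated nested list).
#' @export
load_forcefield <- function(path, overrides = NULL) {
  ff <- yaml::read_yaml(path)
  if (!is.null(overrides)) ff <- modifyList(ff, overrides)
  validate_forcefield(ff)
}

#' Default force-field parameters
#'
#' @return the packaged default `ForceFieldParams`.
#' @export
default_forcefield <- function() {
  path <- system.file("extdata", "forcefield_defaults.yaml", package = "phfold")
  load_forcefield(path)
}

validate_forcefield <- function(ff) {
  need <- c("geometry", "local", "mie", "hbond", "dh", "pka", "residues")
  miss <- setdiff(need, names(ff))
  if (length(miss) > 0)
    stop("force-field file is missing sections: ", paste(miss, collapse = ", "))
  stopifnot(
    is.numeric(ff$mie$n), is.numeric(ff$mie$m),
    is.numeric(ff$hbond$sigma), is.numeric(ff$local$eps_phi),
    ff$hbond$sigma > 0,
    ff$hbond$min_separation == 4,
    ff$mie$n > ff$mie$m, ff$mie$m > 0,
    ff$dh$dw > ff$dh$dp, ff$dh$dp > 0, ff$dh$s > 0,
    ff$dh$w_near > 0, ff$dh$w_far > 0,
    ff$local$eps_phi >= 0
  )
  pk <- ff$pka$side_chain
  if (!identical(sort(names(pk)), sort(c("D", "E", "H", "K", "R"))))
    stop("pKa table must contain exactly D, E, H, K, R side chains")
  if (any(unlist(ff$pka) <= 0) || any(unlist(ff$pka) >= 14))
    stop("pKa values must lie in (0, 14)")
  aa <- amino_acids()
  if (!all(aa %in% names(ff$residues)))
    stop("residue table incomplete")
  for (a in aa) {
    r <- ff$residues[[a]]
    lo <- ff$local[[a]]
    if (is.null(lo)) lo <- ff$local$default
    if (lo$phi_low >= lo$phi_high || lo$psi_low >= lo$psi_high)
      stop("dihedral well bounds must satisfy low < high for ", a)
    if (a != "G" && r$sc_distance <= 0)
      stop("sc_distance must be positive for ", a)
  }
  class(ff) <- "ForceFieldParams"
  ff
}

amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "V", "Y")
}

# Particle type names: 5 backbone kinds then one SC type per amino acid.
particle_types <- function() {
  c("N", "H", "CA", "C", "O", paste0("SC_", amino_acids()))
}

# Dense per-type Mie parameter matrices (eps, r0, n, m) from the combination
# rule eps_ij = sqrt(eps_i eps_j), r0_ij = r_i + r_j, with optional explicit
# per-pair overrides from the config.
build_mie_tables <- function(ff) {
  types <- particle_types()
  nt <- length(types)
  rad <- eps <- numeric(nt)
  for (k in 1:5) {
    bb <- ff$mie$backbone[[types[k]]]
    rad[k] <- bb$radius
    eps[k] <- bb$eps
  }
  aa <- amino_acids()
  for (i in seq_along(aa)) {
    rs <- ff$residues[[aa[i]]]
    rad[5 + i] <- rs$sc_radius
    eps[5 + i] <- rs$sc_eps
  }
  EPS <- sqrt(outer(eps, eps))
  R0 <- outer(rad, rad, "+")
  NN <- matrix(ff$mie$n, nt, nt)
  MM <- matrix(ff$mie$m, nt, nt)
  for (ov in ff$mie$pair_overrides) {
    i <- match(ov$type_i, types)
    j <- match(ov$type_j, types)
    if (is.na(i) || is.na(j))
      stop("unknown particle type in mie pair override: ",
           ov$type_i, "/", ov$type_j)
    if (!is.null(ov$eps)) EPS[i, j] <- EPS[j, i] <- ov$eps
    if (!is.null(ov$r0))  R0[i, j] <- R0[j, i] <- ov$r0
    if (!is.null(ov$n))   NN[i, j] <- NN[j, i] <- ov$n
    if (!is.null(ov$m))   MM[i, j] <- MM[j, i] <- ov$m
  }
  dimnames(EPS) <- dimnames(R0) <- dimnames(NN) <- dimnames(MM) <-
    list(types, types)
  # Glycine has no bead; its row is never used but must be positive to keep
  # gR0 well defined.
  R0[R0 <= 0] <- 1
  EPS[EPS <= 0] <- 1e-12
  list(eps = EPS, r0 = R0, n = NN, m = MM)
}

#' Mie pair parameters for a pair of particle types
#'
#' Resolves the well depth, minimum position and exponents for one particle
#' type pair, honouring the combination rule and any per-pair override in the
#' parameter file.
#'
#' @param ff `ForceFieldParams`.
#' @param type_i,type_j particle type names, e.g. `"CA"` or `"SC_K"` (see
#'   internal kinds N, H, CA, C, O and `SC_<aa>`).
#' @param repulsive_only logical; set for charged side-chain pairs.
#' @return a `MiePairParams` list with fields `eps`, `r0`, `n`, `m`,
#'   `repulsive_only` and the zero-crossing `gR0`.
#' @export
mie_pair_params <- function(ff, type_i, type_j, repulsive_only = FALSE) {
  tab <- build_mie_tables(ff)
  i <- match(type_i, particle_types())
  j <- match(type_j, particle_types())
  if (is.na(i) || is.na(j))
    stop("unknown particle type: ", type_i, "/", type_j)
  p <- list(eps = tab$eps[i, j], r0 = tab$r0[i, j],
            n = tab$n[i, j], m = tab$m[i, j],
            repulsive_only = isTRUE(repulsive_only))
  p$gR0 <- (p$m / p$n)^(1 / (p$n - p$m)) * p$r0
  class(p) <- "MiePairParams"
  p
}

# Per-residue dihedral well bounds as an L x 4 matrix.
local_well_table <- function(ff, sequence) {
  out <- matrix(NA_real_, length(sequence), 4,
                dimnames = list(NULL, c("phi_low", "phi_high",
                                        "psi_low", "psi_high")))
  for (i in seq_along(sequence)) {
    lo <- ff$local[[sequence[i]]]
    if (is.null(lo)) lo <- ff$local$default
    out[i, ] <- c(lo$phi_low, lo$phi_high, lo$psi_low, lo$psi_high)
  }
  out
}
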