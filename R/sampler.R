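#' Sampler configuration
#'
#' Defaults reproduce the prediction protocol: 200 independent
#' simulated-annealing runs of 5,000 Metropolis steps each over a geometric
#' ladder of 8 reduced temperatures from 2.0 down to 0.3, starting from the
#' extended chain.  Moves are 80% single-residue (phi, psi) Gaussian
#' perturbations (sd = `max_step_deg` / 2) and 20% pivots (uniform redraw of
#' one dihedral).  Energies are divided by the reduced temperature directly;
#' no physical kB mapping is claimed.
#'
#' @param n_models number of independent annealing runs (models).
#' @param n_steps_per_model Metropolis steps per model (split evenly across
#'   the temperature ladder).
#' @param temperatures decreasing vector of reduced temperatures.
#' @param max_step_deg local move scale in degrees, in (0, 180].
#' @param p_pivot probability of a pivot move.
#' @param seed integer seed for reproducibility; `NULL` leaves the RNG state
#'   untouched.
#' @param use_dh logical, include the Debye-Hueckel term.
#' @return a `SamplerConfig` list.
#' @export
sampler_config <- function(n_models = 200, n_steps_per_model = 5000,
                           temperatures = exp(seq(log(2.0), log(0.3),
                                                  length.out = 8)),
                           max_step_deg = 30, p_pivot = 0.2, seed = NULL,
                           use_dh = TRUE) {
  stopifnot(n_models >= 1, n_steps_per_model >= 0,
            all(temperatures > 0), max_step_deg > 0, max_step_deg <= 180,
            p_pivot >= 0, p_pivot <= 1)
  structure(list(n_models = as.integer(n_models),
                 n_steps_per_model = as.integer(n_steps_per_model),
                 temperatures = temperatures,
                 max_step_deg = max_step_deg, p_pivot = p_pivot,
                 seed = seed, use_dh = isTRUE(use_dh)),
            class = "SamplerConfig")
}

#' Metropolis acceptance rule
#'
#' Accept with probability `min(1, exp(-dE / T))`; consumes one uniform
#' deviate when the move is uphill.  This is the same rule the annealing
#' kernel applies internally.
#'
#' @param dE energy difference (proposed - current), kcal/mol.
#' @param temperature reduced temperature, positive.
#' @return logical.
#' @export
metropolis_accept <- function(dE, temperature) {
  stopifnot(temperature > 0)
  if (dE <= 0) return(TRUE)
  runif(1) < exp(-dE / temperature)
}

#' Generate a conformational ensemble by simulated-annealing Monte Carlo
#'
#' Runs `n_models` independent annealing trajectories over backbone
#' dihedrals, each starting from the fully extended chain (phi = psi = 180).
#' The energy is the coarse-grained potential plus, when a charge state is
#' supplied and `use_dh` is on, the weighted shifted Debye-Hueckel term.
#' Results are bit-reproducible for a fixed seed.
#'
#' @param topo `PeptideTopology`.
#' @param ff `ForceFieldParams`.
#' @param charge_state optional `ChargeState`; required when
#'   `cfg$use_dh` is `TRUE`.
#' @param cfg `SamplerConfig`.
#' @return a `ModelEnsemble`: conformations, per-model energy table,
#'   and the inputs needed for clustering and analysis.
#' @export
mc_run <- function(topo, ff = default_forcefield(), charge_state = NULL,
                   cfg = sampler_config()) {
  stopifnot(inherits(topo, "PeptideTopology"))
  use_dh <- cfg$use_dh && !is.null(charge_state)
  sys <- prepare_system(topo, ff, charge_state, use_dh)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  steps_per_temp <- max(0L, as.integer(floor(
    cfg$n_steps_per_model / length(cfg$temperatures))))
  start <- matrix(180, topo$L, 2)
  conformations <- vector("list", cfg$n_models)
  energies <- matrix(0, cfg$n_models, 6,
                     dimnames = list(NULL, c("e_local", "e_nonbonded",
                                             "e_hb_pairwise", "e_hb_coop",
                                             "e_dh", "e_total")))
  acc <- numeric(cfg$n_models)
  for (mdl in seq_len(cfg$n_models)) {
    out <- cpp_mc_anneal(start[, 1], start[, 2], sys, cfg$temperatures,
                         steps_per_temp, cfg$max_step_deg, cfg$p_pivot)
    dih <- cbind(phi = out$phi, psi = out$psi)
    conformations[[mdl]] <- structure(
      list(coords = out$coords, dihedrals = dih,
           hbonds = data.frame(donor = out$energy$hb_donor,
                               acceptor = out$energy$hb_acceptor,
                               r = out$energy$hb_r)),
      class = "Conformation")
    energies[mdl, ] <- c(out$energy$e_local, out$energy$e_nonbonded,
                         out$energy$e_hb_pairwise, out$energy$e_hb_coop,
                         out$energy$e_dh, out$energy$e_total)
    acc[mdl] <- out$acceptance
  }
  structure(list(conformations = conformations,
                 energies = as.data.frame(energies),
                 acceptance = acc,
                 topo = topo, charge_state = charge_state,
                 use_dh = use_dh, cfg = cfg,
                 cluster = NULL, representatives = NULL),
            class = "ModelEnsemble")
}

#' @export
print.ModelEnsemble <- function(x, ...) {
  cat("ModelEnsemble:", length(x$conformations), "models of",
      paste(x$topo$sequence, collapse = ""), "\n")
  cat(sprintf("  energy range [%.2f, %.2f] kcal/mol, DH %s\n",
              min(x$energies$e_total), max(x$energies$e_total),
              if (x$use_dh) "on" else "off"))
  if (!is.null(x$cluster))
    cat("  clusters:", length(unique(x$cluster)), "\n")
  invisible(x)
}

#' Greedy leader clustering by backbone RMSD
#'
#' Models are visited in ascending total-energy order; a model joins the
#' first existing cluster whose leader lies within `rmsd_cutoff` backbone
#' RMSD (N, CA, C, O after optimal superposition), otherwise it founds a new
#' cluster.  Leaders are therefore the lowest-energy member of their
#' cluster.
#'
#' @param ensemble `ModelEnsemble`.
#' @param rmsd_cutoff Angstrom, default 2.5.
#' @return the ensemble with a `cluster` label vector attached.
#' @export
cluster_models <- function(ensemble, rmsd_cutoff = 2.5) {
  stopifnot(inherits(ensemble, "ModelEnsemble"))
  n <- length(ensemble$conformations)
  ord <- order(ensemble$energies$e_total)
  labels <- integer(n)
  leaders <- integer(0)
  for (m in ord) {
    placed <- FALSE
    for (cl in seq_along(leaders)) {
      r <- backbone_rmsd(ensemble$conformations[[m]],
                         ensemble$conformations[[leaders[cl]]],
                         ensemble$topo)
      if (r <= rmsd_cutoff) {
        labels[m] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, m)
      labels[m] <- length(leaders)
    }
  }
  ensemble$cluster <- labels
  ensemble$leaders <- leaders
  ensemble
}

#' Select representative models
#'
#' The lowest-energy member (leader) of each of the `n` lowest-energy
#' clusters, in ascending energy order.  When fewer than `n` clusters
#' exist, the remaining slots are filled with the next-lowest-energy models
#' not already selected.
#'
#' @param ensemble clustered `ModelEnsemble` (see [cluster_models()]).
#' @param n number of representatives, default 5.
#' @return the ensemble with `representatives` (model indices) attached.
#' @export
select_representatives <- function(ensemble, n = 5) {
  stopifnot(inherits(ensemble, "ModelEnsemble"))
  if (length(ensemble$conformations) == 0) stop("empty ensemble")
  if (is.null(ensemble$cluster)) ensemble <- cluster_models(ensemble)
  e <- ensemble$energies$e_total
  reps <- ensemble$leaders[seq_len(min(n, length(ensemble$leaders)))]
  if (length(reps) < n) {
    pool <- setdiff(order(e), reps)
    reps <- c(reps, pool[seq_len(n - length(reps))])
  }
  reps <- reps[order(e[reps])]
  ensemble$representatives <- reps
  ensemble
}
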