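#' Predict a peptide conformational ensemble at given pH and ionic strength
#'
#' End-to-end protocol: build the coarse-grained topology, assign
#' Henderson-Hasselbalch charges and calibrate the Debye-Hueckel shifts,
#' generate models by simulated-annealing Monte Carlo, cluster them by
#' backbone RMSD, select the five lowest-energy cluster representatives,
#' and summarise their secondary-structure content.
#'
#' @param sequence amino-acid string (1-letter codes), or `NULL` with
#'   `topo` supplied.
#' @param ph solvent pH.
#' @param ionic_strength mol/L.
#' @param n_blocked,c_blocked terminal blocking (acetyl / N-methyl) flags.
#' @param use_dh include the Debye-Hueckel term (`FALSE` reproduces the
#'   pH-independent protocol).
#' @param n_models,n_steps,seed sampler settings (see [sampler_config()]).
#' @param n_representatives number of cluster representatives.
#' @param rmsd_cutoff clustering cutoff in Angstrom.
#' @param topo optional prebuilt `PeptideTopology` (overrides `sequence`).
#' @param ff `ForceFieldParams`.
#' @param charge_state optional prebuilt `ChargeState` (overrides the
#'   pH-derived one; used e.g. to force unit charges).
#' @return list with the clustered `ensemble`, `representatives` (model
#'   indices), `ss` (per-representative SS strings), and `content`
#'   (`SsContent` pooled over the representatives).
#' @examples
#' \donttest{
#' fit <- predict_ensemble("KKKKKKKKKKKKKKK", ph = 3.6, ionic_strength = 0,
#'                         n_blocked = TRUE, c_blocked = TRUE,
#'                         n_models = 10, n_steps = 1000, seed = 1)
#' fit$content
#' }
#' @export
predict_ensemble <- function(sequence = NULL, ph = 7.4, ionic_strength = 0.15,
                             n_blocked = FALSE, c_blocked = FALSE,
                             use_dh = TRUE, n_models = 200, n_steps = 5000,
                             seed = NULL, n_representatives = 5,
                             rmsd_cutoff = 2.5, topo = NULL,
                             ff = default_forcefield(),
                             charge_state = NULL) {
  if (is.null(topo)) {
    if (is.null(sequence)) stop("supply a sequence or a topology")
    topo <- parse_sequence(sequence, n_blocked, c_blocked, ff)
  }
  cs <- charge_state
  if (is.null(cs) && use_dh)
    cs <- assign_charges(topo, ph, ionic_strength, ff)
  cfg <- sampler_config(n_models = n_models, n_steps_per_model = n_steps,
                        seed = seed, use_dh = use_dh)
  ens <- mc_run(topo, ff, cs, cfg)
  ens <- cluster_models(ens, rmsd_cutoff)
  ens <- select_representatives(ens, n_representatives)
  reps <- ens$representatives
  ss <- lapply(ens$conformations[reps], function(cf)
    assign_ss(cf, topo, ff = ff))
  content <- ss_content(ss)
  list(ensemble = ens, representatives = reps,
       rep_energies = ens$energies$e_total[reps],
       ss = vapply(ss, paste, "", collapse = ""), content = content)
}
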