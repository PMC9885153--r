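#!/usr/bin/env Rscript
# Thin command-line wrapper over the phfold package.
#
#   phfold predict  --sequence KKKK... | --fasta seqs.fasta [--ph 7.4]
#                   [--ionic-strength 0.15] [--block-n] [--block-c]
#                   [--no-dh] [--n-models 200] [--n-steps 5000] [--seed 1]
#                   [--out-dir phfold_out]
#   phfold score    --pdb model.pdb [--ph 7.4] [--ionic-strength 0.15]
#                   [--block-n] [--block-c] [--no-dh]
#   phfold analyze  --pdb model.pdb [model2.pdb ...]
#   phfold fixtures [--name "(K)15"]

suppressPackageStartupMessages({
  library(optparse)
  library(phfold)
})

args <- commandArgs(trailingOnly = TRUE)
sub <- if (length(args) >= 1) args[[1]] else ""
rest <- args[-1]
usage <- function() {
  cat("usage: phfold <predict|score|analyze|fixtures> [options]\n")
  quit(status = 2)
}
if (!sub %in% c("predict", "score", "analyze", "fixtures")) usage()

common <- list(
  make_option("--ph", type = "double", default = 7.4),
  make_option("--ionic-strength", type = "double", default = 0.15,
              dest = "ionic_strength"),
  make_option("--block-n", action = "store_true", default = FALSE,
              dest = "block_n"),
  make_option("--block-c", action = "store_true", default = FALSE,
              dest = "block_c"),
  make_option("--no-dh", action = "store_true", default = FALSE,
              dest = "no_dh"),
  make_option("--ff-config", type = "character", default = NULL,
              dest = "ff_config", help = "force-field YAML override file")
)
get_ff <- function(o) {
  if (is.null(o$ff_config)) default_forcefield() else
    load_forcefield(o$ff_config)
}
fail <- function(...) { cat("error:", ..., "\n", file = stderr()); quit(status = 1) }

if (sub == "predict") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--sequence", type = "character", default = NULL),
    make_option("--fasta", type = "character", default = NULL),
    make_option("--n-models", type = "integer", default = 200,
                dest = "n_models"),
    make_option("--n-steps", type = "integer", default = 5000,
                dest = "n_steps"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out-dir", type = "character", default = "phfold_out",
                dest = "out_dir")))), args = rest)
  if (is.null(o$sequence) == is.null(o$fasta))
    fail("supply exactly one of --sequence / --fasta")
  seq <- if (!is.null(o$sequence)) o$sequence else read_fasta_sequence(o$fasta)
  ff <- get_ff(o)
  message(sprintf("predict: %s  pH %.2f  I %.3f M  seed %d  DH %s",
                  seq, o$ph, o$ionic_strength, o$seed, !o$no_dh))
  fit <- tryCatch(
    predict_ensemble(seq, ph = o$ph, ionic_strength = o$ionic_strength,
                     n_blocked = o$block_n, c_blocked = o$block_c,
                     use_dh = !o$no_dh, n_models = o$n_models,
                     n_steps = o$n_steps, seed = o$seed, ff = ff),
    error = function(e) fail(conditionMessage(e)))
  dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
  topo <- fit$ensemble$topo
  for (i in seq_along(fit$representatives)) {
    m <- fit$representatives[i]
    write_pdb(fit$ensemble$conformations[[m]], topo,
              file.path(o$out_dir, sprintf("model_%d.pdb", i)))
  }
  rep_tab <- data.frame(model = seq_along(fit$representatives),
                        energy_kcal_mol = round(fit$rep_energies, 4),
                        ss = fit$ss)
  write.table(rep_tab, file.path(o$out_dir, "models.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cont <- fit$content
  cat(sprintf("alpha %.1f%%  coil %.1f%%  turn %.1f%%  beta %.1f%%\n",
              cont$alpha_pct, cont$coil_pct, cont$turn_pct, cont$beta_pct))
  message("models written to ", o$out_dir)
} else if (sub == "score") {
  o <- parse_args(OptionParser(option_list = c(common, list(
    make_option("--pdb", type = "character", default = NULL)))), args = rest)
  if (is.null(o$pdb)) fail("--pdb required")
  ff <- get_ff(o)
  inp <- tryCatch(read_pdb(o$pdb, o$block_n, o$block_c, ff),
                  error = function(e) fail(conditionMessage(e)))
  cs <- if (o$no_dh) NULL else
    assign_charges(inp$topo, o$ph, o$ionic_strength, ff)
  print(total_energy(inp$conformation, inp$topo, ff, cs))
} else if (sub == "analyze") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--pdb", type = "character", default = NULL)),
    usage = "phfold analyze --pdb model.pdb [more.pdb ...]"),
    args = rest, positional_arguments = TRUE)
  paths <- c(o$options$pdb, o$args)
  if (length(paths) == 0) fail("at least one PDB path required")
  ff <- default_forcefield()
  strings <- lapply(paths, function(p) {
    inp <- tryCatch(read_pdb(p, ff = ff),
                    error = function(e) fail(p, ": ", conditionMessage(e)))
    ss <- assign_ss(inp$conformation, inp$topo, ff = ff)
    cat(p, "\t", paste(ss, collapse = ""), "\n")
    ss
  })
  cont <- ss_content(strings)
  cat(sprintf("alpha\t%.2f\ncoil\t%.2f\nturn\t%.2f\nbeta\t%.2f\n",
              cont$alpha_pct, cont$coil_pct, cont$turn_pct, cont$beta_pct))
} else if (sub == "fixtures") {
  o <- parse_args(OptionParser(option_list = list(
    make_option("--name", type = "character", default = NULL))), args = rest)
  if (is.null(o$name)) {
    nm <- c(names(phfold:::fixture_registry()),
            "ideal_helix_15", "ideal_extended_15", "hairpin_14")
    cat(nm, sep = "\n")
  } else {
    fx <- tryCatch(make_fixture(o$name),
                   error = function(e) fail(conditionMessage(e)))
    cat(sprintf("%s\t%s\tblocked N=%s C=%s\tpH %.1f\tI %.3f M\n",
                fx$name, fx$sequence, fx$n_blocked, fx$c_blocked,
                fx$ph, fx$ionic_strength))
  }
}
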