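three_letter <- function(aa) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
           Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
           L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
           S = "SER", T = "THR", W = "TRP", V = "VAL", Y = "TYR")
  unname(map[aa])
}

#' Write a coarse-grained conformation as PDB
#'
#' Fixed-column PDB records: backbone atoms named N, H, CA, C, O and the
#' side-chain bead as a pseudo-atom named SC, residue names in 3-letter
#' code, chain A, 1-based numbering.
#'
#' @param conf `Conformation`.
#' @param topo `PeptideTopology`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(conf, topo, path) {
  X <- conf$coords
  if (nrow(X) != topo$n_particles)
    stop("conformation/topology particle count mismatch")
  p <- topo$particles
  res3 <- three_letter(topo$sequence[p$residue])
  elem <- c(N = "N", H = "H", CA = "C", C = "C", O = "O", SC = "C")[p$kind]
  name4 <- ifelse(nchar(p$kind) == 1, paste0(" ", p$kind, "  "),
                  paste0(" ", p$kind, " "))
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(X)), name4, res3, p$residue,
    X[, 1], X[, 2], X[, 3], 1, 0, elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a coarse-grained PDB file
#'
#' Reconstructs the topology from residue names and the SC pseudo-atoms and
#' returns the coordinates with measured dihedrals.  Files must follow the
#' [write_pdb()] layout (full backbone N, H, CA, C, O per residue).
#'
#' @param path PDB file path.
#' @param n_blocked,c_blocked terminal blocking flags for the rebuilt
#'   topology (not stored in PDB).
#' @param ff `ForceFieldParams`.
#' @return list with elements `topo` and `conformation`.
#' @export
read_pdb <- function(path, n_blocked = FALSE, c_blocked = FALSE,
                     ff = default_forcefield()) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), ]
  if (nrow(at) == 0) stop("no atoms in ", path)
  resnos <- unique(at$resno)
  aa <- vapply(resnos, function(r) {
    bio3d::aa321(at$resid[at$resno == r][1])
  }, "")
  if (any(aa == "X"))
    stop("unknown residue name at residue ", resnos[which(aa == "X")[1]])
  topo <- parse_sequence(paste(aa, collapse = ""), n_blocked, c_blocked, ff)
  X <- matrix(NA_real_, topo$n_particles, 3)
  for (ri in seq_along(resnos)) {
    sub <- at[at$resno == resnos[ri], ]
    for (kind in c("N", "H", "CA", "C", "O", "SC")) {
      pi <- topo$idx[[kind]][ri]
      if (is.na(pi)) next
      row <- which(trimws(sub$elety) == kind)
      if (length(row) == 0) {
        if (kind == "SC")
          stop("missing SC bead for non-glycine residue ", resnos[ri])
        stop("missing backbone atom ", kind, " in residue ", resnos[ri])
      }
      X[pi, ] <- as.numeric(sub[row[1], c("x", "y", "z")])
    }
  }
  conf <- structure(list(coords = X, dihedrals = NULL),
                    class = "Conformation")
  conf$dihedrals <- measure_dihedrals(conf, topo)
  list(topo = topo, conformation = conf)
}

#' Read the first (or a named) sequence from a FASTA file
#'
#' @param path FASTA file.
#' @param id optional record identifier; default first record.
#' @return the sequence as a single upper-case string.
#' @export
read_fasta_sequence <- function(path, id = NULL) {
  fa <- bio3d::read.fasta(path)
  ids <- fa$id
  row <- if (is.null(id)) 1L else match(id, ids)
  if (is.na(row)) stop("no FASTA record with id '", id, "' in ", path)
  seq <- fa$ali[row, ]
  paste(toupper(seq[seq != "-"]), collapse = "")
}

fixture_registry <- function() {
  tab2 <- list(
    # PDB-derived benchmark peptides: sequence, blocking, pH, I (mol/L)
    "6mi9" = list(seq = "PMARNKILGKILRKIAAFK", n = FALSE, c = TRUE,
                  ph = 4.3, I = 0),
    "6j9p" = list(seq = "RRLIRLILRLLR", n = FALSE, c = FALSE, ph = 5, I = 0),
    "1fsd" = list(seq = "QQYTAKIKGRTFRNEKELRDFIEKFKGR", n = FALSE, c = FALSE,
                  ph = 5, I = 0),
    "1j4m" = list(seq = "RGKWTYNGITYEGR", n = FALSE, c = FALSE, ph = 5, I = 0),
    "1le1" = list(seq = "SWTWENGKWTWK", n = FALSE, c = TRUE, ph = 5.5, I = 0),
    "6nm3" = list(seq = "RKIWWWWL", n = FALSE, c = TRUE, ph = 5.8, I = 0),
    "6svc" = list(seq = "SKLPPGWEKRMSRNSGRVYYFNHITNASQFERPSG",
                  n = FALSE, c = FALSE, ph = 6, I = 0.150),
    "2evq" = list(seq = "KTWNPATGKWTE", n = FALSE, c = FALSE,
                  ph = 6, I = 0.020),
    "1egs" = list(seq = "TKSAGGIVL", n = TRUE, c = TRUE, ph = 6.5, I = 0),
    "6r2x" = list(seq = "FETLRGDERILSILRHQNLLKELQD", n = FALSE, c = FALSE,
                  ph = 6.5, I = 0.148),
    "7b2f" = list(seq = "MNNNELTSLPLAERKRLLELAKAAKLSRQHY",
                  n = FALSE, c = FALSE, ph = 6.5, I = 0.100),
    "6s0n" = list(seq = "QDVNTAVAW", n = FALSE, c = FALSE, ph = 6.8, I = 0.001),
    "7li2" = list(seq = "AGTMRVTYPDGQKPGQSDVEKD", n = FALSE, c = FALSE,
                  ph = 7, I = 0),
    "1wbr" = list(seq = "QAERMSQIKRLLSEKKT", n = TRUE, c = TRUE, ph = 7, I = 0),
    "1pgbF" = list(seq = "GEWTYDDATKTFTVTE", n = FALSE, c = FALSE,
                   ph = 7, I = 0),
    "pep17" = list(seq = "ETGTKAELLAKYEATHK", n = FALSE, c = FALSE,
                   ph = 2, I = 0),
    "pep38" = list(seq = "DWLKARVEQELQALEARGTDSNAELRAMEAKLKAEIQK",
                   n = FALSE, c = FALSE, ph = 3.6, I = 0.020),
    "pep10" = list(seq = "IYSNSDGWTWT", n = FALSE, c = FALSE, ph = 4.3, I = 0),
    "tau_fragment" = list(seq = "DNIKHVPGGGSVQIVYK", n = FALSE, c = FALSE,
                          ph = 7, I = 0)
  )
  poly <- list(
    # poly-charged peptides; (K)15 and (E)15 carry acetyl/N-methyl caps
    "(EK)15" = list(seq = strrep("EK", 15), n = FALSE, c = FALSE,
                    ph = 7.4, I = 0),
    "(EK)5" = list(seq = strrep("EK", 5), n = FALSE, c = FALSE,
                   ph = 7.4, I = 0),
    "(H)30" = list(seq = strrep("H", 30), n = FALSE, c = FALSE,
                   ph = 7.4, I = 0),
    "(E)15" = list(seq = strrep("E", 15), n = TRUE, c = TRUE,
                   ph = 7.4, I = 0),
    "(K)15" = list(seq = strrep("K", 15), n = TRUE, c = TRUE,
                   ph = 7.4, I = 0),
    "(R)25" = list(seq = strrep("R", 25), n = FALSE, c = FALSE,
                   ph = 7.4, I = 0)
  )
  c(poly, tab2)
}

#' Packaged sequence and geometry fixtures
#'
#' A registry of the poly-charged homopolymers ((K)15, (E)15, (R)25, (EK)5,
#' (EK)15, (H)30 with their experimental blocking flags), the benchmark
#' peptide sequences keyed by PDB id, and three built geometric fixtures
#' (`ideal_helix_15`, `ideal_extended_15`, `hairpin_14`).
#'
#' @param name registry key, e.g. `"(K)15"`, `"6j9p"`, `"ideal_helix_15"`.
#' @param ff `ForceFieldParams` used to build topologies/geometries.
#' @return list with `sequence`, blocking flags, reference `ph` and
#'   `ionic_strength`, the `topo`, and for geometric fixtures a
#'   `conformation`.
#' @examples
#' fx <- make_fixture("(K)15")
#' fx$sequence            # "KKKKKKKKKKKKKKK", both termini blocked
#' @export
make_fixture <- function(name, ff = default_forcefield()) {
  geo <- c("ideal_helix_15", "ideal_extended_15", "hairpin_14")
  reg <- fixture_registry()
  if (name %in% names(reg)) {
    fx <- reg[[name]]
    topo <- parse_sequence(fx$seq, fx$n, fx$c, ff)
    return(list(name = name, sequence = fx$seq, n_blocked = fx$n,
                c_blocked = fx$c, ph = fx$ph, ionic_strength = fx$I,
                topo = topo, conformation = NULL))
  }
  if (name == "ideal_helix_15") {
    topo <- parse_sequence(strrep("A", 15), ff = ff)
    dih <- cbind(rep(-57, 15), rep(-47, 15))
  } else if (name == "ideal_extended_15") {
    topo <- parse_sequence(strrep("A", 15), ff = ff)
    dih <- cbind(rep(-150, 15), rep(150, 15))
  } else if (name == "hairpin_14") {
    # two extended strands joined by a tight type-I' style reversal
    topo <- parse_sequence(strrep("A", 14), ff = ff)
    dih <- rbind(matrix(rep(c(-135, 150), 6), ncol = 2, byrow = TRUE),
                 c(55, -130), c(-95, 10),
                 matrix(rep(c(-135, 150), 6), ncol = 2, byrow = TRUE))
  } else {
    stop("unknown fixture '", name, "'; available: ",
         paste(c(names(reg), geo), collapse = ", "))
  }
  conf <- build_conformation(topo, dih, ff)
  list(name = name, sequence = paste(topo$sequence, collapse = ""),
       n_blocked = FALSE, c_blocked = FALSE, ph = 7.4, ionic_strength = 0.15,
       topo = topo, conformation = conf)
}
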