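#' Build the coarse-grained topology of a peptide from its sequence
#'
#' Each residue contributes the five backbone particles N, H, CA, C, O and,
#' for every amino acid except glycine, one side-chain bead (SC) placed at a
#' residue-specific distance from CA.  Blocking flags record acetyl /
#' N-methyl caps; they do not add particles, they only suppress the terminal
#' charges when charges are assigned.
#'
#' @param text amino-acid sequence using the 20 standard 1-letter codes.
#' @param n_blocked logical, acetylated N-terminus.
#' @param c_blocked logical, N-methylated C-terminus.
#' @param ff `ForceFieldParams` supplying the per-residue bead table.
#' @return an object of class `PeptideTopology`.
#' @examples
#' topo <- parse_sequence("RRLIRLILRLLR")
#' topo$n_particles  # 5 * 12 + 12 side-chain beads
#' @export
parse_sequence <- function(text, n_blocked = FALSE, c_blocked = FALSE,
                           ff = default_forcefield()) {
  stopifnot(is.character(text), length(text) == 1)
  seq <- strsplit(toupper(gsub("\\s", "", text)), "")[[1]]
  if (length(seq) < 2)
    stop("sequence must contain at least 2 residues")
  bad <- which(!(seq %in% amino_acids()))
  if (length(bad) > 0)
    stop("invalid amino-acid code '", seq[bad[1]], "' at position ", bad[1])
  L <- length(seq)

  res <- data.frame(
    aa = seq,
    sc_distance = vapply(seq, function(a) ff$residues[[a]]$sc_distance, 0),
    sc_radius   = vapply(seq, function(a) ff$residues[[a]]$sc_radius, 0),
    titratable  = seq %in% c("D", "E", "H", "K", "R"),
    side_chain_pKa = vapply(seq, function(a) {
      p <- ff$pka$side_chain[[a]]
      if (is.null(p)) NA_real_ else p
    }, 0),
    hb_donor = vapply(seq, function(a) isTRUE(ff$residues[[a]]$hb_donor), TRUE),
    row.names = NULL
  )

  kinds <- c("N", "H", "CA", "C", "O", "SC")
  plist <- lapply(seq_len(L), function(i) {
    k <- if (seq[i] == "G") kinds[1:5] else kinds
    data.frame(residue = i, kind = k)
  })
  particles <- do.call(rbind, plist)
  types <- particle_types()
  particles$type <- ifelse(
    particles$kind == "SC",
    match(paste0("SC_", seq[particles$residue]), types),
    match(particles$kind, types)
  )

  idx <- lapply(kinds, function(k) {
    out <- rep(NA_integer_, L)
    sel <- particles$kind == k
    out[particles$residue[sel]] <- which(sel)
    out
  })
  names(idx) <- kinds

  topo <- list(
    sequence = seq,
    residues = res,
    n_blocked = isTRUE(n_blocked),
    c_blocked = isTRUE(c_blocked),
    particles = particles,
    idx = idx,
    L = L,
    n_particles = nrow(particles)
  )
  topo$exclusion <- bond_exclusion_mask(topo)
  class(topo) <- "PeptideTopology"
  topo
}

#' @export
print.PeptideTopology <- function(x, ...) {
  cat("PeptideTopology:", paste(x$sequence, collapse = ""), "\n")
  cat("  residues:", x$L, " particles:", x$n_particles, "\n")
  cat("  titratable side chains:", count_titratable(x), "\n")
  cat("  blocked: N =", x$n_blocked, ", C =", x$c_blocked, "\n")
  invisible(x)
}

# Covalent bond list (2-column matrix of particle indices).
bond_list <- function(topo) {
  b <- list()
  idx <- topo$idx
  for (i in seq_len(topo$L)) {
    b[[length(b) + 1]] <- rbind(
      c(idx$N[i], idx$H[i]),
      c(idx$N[i], idx$CA[i]),
      c(idx$CA[i], idx$C[i]),
      c(idx$C[i], idx$O[i])
    )
    if (!is.na(idx$SC[i]))
      b[[length(b) + 1]] <- rbind(c(idx$CA[i], idx$SC[i]))
    if (i < topo$L)
      b[[length(b) + 1]] <- rbind(c(idx$C[i], idx$N[i + 1]))
  }
  do.call(rbind, b)
}

# TRUE where a particle pair is separated by more than 2 covalent bonds
# (1-2 and 1-3 excluded from the non-bonded sum, 1-4 kept at full weight).
bond_exclusion_mask <- function(topo) {
  n <- topo$n_particles
  bonds <- bond_list(topo)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  keep <- matrix(TRUE, n, n)
  diag(keep) <- FALSE
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    keep[i, one] <- FALSE
    keep[i, two] <- FALSE
    keep[i, i] <- FALSE
  }
  keep
}

#' Count titratable residues in a sequence
#'
#' Counts side chains in the set D, E, H, K, R; the backbone termini are not
#' included in this count even when charged.
#'
#' @param topo `PeptideTopology`.
#' @return integer count.
#' @examples
#' count_titratable(parse_sequence("RGKWTYNGITYEGR"))  # 4
#' @export
count_titratable <- function(topo) {
  stopifnot(inherits(topo, "PeptideTopology"))
  sum(topo$residues$titratable)
}
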