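#' Rule-based secondary-structure assignment
#'
#' Assigns one of H (helix), E (extended/sheet), T (turn) or C (coil) per
#' residue from backbone dihedrals and the recorded hydrogen-bond list:
#' \itemize{
#' \item H: (phi, psi) within 30 degrees of the canonical helix
#'   (-57, -47) and the residue lies in a run of at least 3 consecutive
#'   helical O(i)...H(i+4) bonds;
#' \item E: extended dihedrals (phi in \[-180, -90\], psi in \[90, 180\])
#'   and participation in a non-helical (cross-strand) recorded H-bond;
#' \item T: interior of a short chain reversal bridged by an (i, i+3) or
#'   (i, i+4) CA contact (< 7 Angstrom) whose interior lacks helix
#'   dihedrals;
#' \item C: everything else.
#' }
#'
#' @param conf `Conformation`.
#' @param topo `PeptideTopology`.
#' @param hbonds optional recorded H-bond data.frame (columns donor,
#'   acceptor, ...); computed via [hbond_pairwise()] when absent.
#' @param ff `ForceFieldParams`.
#' @return character vector of length L over the alphabet H, E, T, C.
#' @export
assign_ss <- function(conf, topo, hbonds = NULL,
                      ff = default_forcefield()) {
  L <- topo$L
  if (is.null(hbonds)) {
    hbonds <- if (!is.null(conf$hbonds)) conf$hbonds else
      hbond_pairwise(conf, topo, ff)$hbonds
  }
  dih <- if (!is.null(conf$dihedrals)) conf$dihedrals else
    measure_dihedrals(conf, topo)
  phi <- dih[, 1]; psi <- dih[, 2]
  helix_dih <- !is.na(phi) & !is.na(psi) &
    phi >= -87 & phi <= -27 & psi >= -77 & psi <= -17
  ext_dih <- !is.na(phi) & !is.na(psi) &
    phi >= -180 & phi <= -90 & psi >= 90 & psi <= 180

  # helical bond acceptors: O(a) ... H(a+4)
  helical <- hbonds$donor - hbonds$acceptor == 4
  acc <- sort(unique(hbonds$acceptor[helical]))
  in_helix_run <- rep(FALSE, L)
  if (length(acc) >= 3) {
    runs <- split(acc, cumsum(c(1, diff(acc) != 1)))
    for (rn in runs) {
      if (length(rn) >= 3)
        in_helix_run[min(rn):(max(rn) + 4)] <- TRUE
    }
  }
  ss <- rep("C", L)
  ss[helix_dih & in_helix_run] <- "H"

  cross <- unique(c(hbonds$donor[!helical], hbonds$acceptor[!helical]))
  isE <- ext_dih & seq_len(L) %in% cross & ss != "H"
  ss[isE] <- "E"

  # chain reversals: CA(i)-CA(j) contact with j - i of 3 or 4
  X <- conf$coords
  for (i in seq_len(L)) {
    for (j in intersect(c(i + 3, i + 4), seq_len(L))) {
      d <- sqrt(sum((X[topo$idx$CA[i], ] - X[topo$idx$CA[j], ])^2))
      interior <- (i + 1):(j - 1)
      if (d < 7 && !any(helix_dih[interior])) {
        lab <- interior[ss[interior] == "C"]
        ss[lab] <- "T"
      }
    }
  }
  ss
}

#' Secondary-structure content of a set of models
#'
#' Pools residues over all models (normally the 5 selected representatives)
#' and reports the percentage in each class.  The turn percentage maps the
#' T class and the beta percentage the E class.
#'
#' @param ss_strings list (or character vector) of per-model SS strings or
#'   per-residue character vectors, all of equal length.
#' @return an `SsContent` list with `alpha_pct`, `coil_pct`, `turn_pct`,
#'   `beta_pct` summing to 100.
#' @export
ss_content <- function(ss_strings) {
  if (is.character(ss_strings)) ss_strings <- as.list(ss_strings)
  chars <- unlist(lapply(ss_strings, function(s) {
    if (length(s) == 1) strsplit(s, "")[[1]] else s
  }))
  if (length(chars) == 0) stop("no residues to summarise")
  lens <- vapply(ss_strings, function(s) {
    if (length(s) == 1) nchar(s) else length(s)
  }, 0L)
  if (length(unique(lens)) != 1)
    stop("models have unequal lengths: ", paste(lens, collapse = ", "))
  bad <- setdiff(unique(chars), c("H", "E", "T", "C"))
  if (length(bad) > 0)
    stop("unknown SS characters: ", paste(bad, collapse = ", "))
  n <- length(chars)
  out <- list(alpha_pct = 100 * sum(chars == "H") / n,
              coil_pct = 100 * sum(chars == "C") / n,
              turn_pct = 100 * sum(chars == "T") / n,
              beta_pct = 100 * sum(chars == "E") / n)
  class(out) <- "SsContent"
  out
}

#' @export
print.SsContent <- function(x, ...) {
  cat(sprintf("SS content: alpha %.1f%%  coil %.1f%%  turn %.1f%%  beta %.1f%%\n",
              x$alpha_pct, x$coil_pct, x$turn_pct, x$beta_pct))
  invisible(x)
}

#' Optimal-superposition backbone RMSD
#'
#' Least-squares RMSD over the backbone particles (N, CA, C, O) after
#' optimal rigid superposition (Kabsch algorithm with reflection guard).
#'
#' @param a,b `Conformation`s of the same topology.
#' @param topo `PeptideTopology`.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b, topo) {
  sel <- topo$particles$kind %in% c("N", "CA", "C", "O")
  A <- a$coords[sel, , drop = FALSE]
  B <- b$coords[sel, , drop = FALSE]
  if (nrow(A) != nrow(B))
    stop("conformations have mismatched particle counts")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Bfit <- B %*% R
  sqrt(mean(rowSums((A - Bfit)^2)))
}
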