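# Shared test fixtures: one force field reused across tests, random
# sequence/conformation generators under fixed seeds.
FF <- default_forcefield()

random_sequence <- function(L) {
  paste(sample(phfold:::amino_acids(), L, replace = TRUE), collapse = "")
}

random_conformation <- function(topo, ff = FF) {
  dih <- cbind(runif(topo$L, -180, 180), runif(topo$L, -180, 180))
  build_conformation(topo, dih, ff)
}

# rigid-body motion: random rotation (QR of a Gaussian matrix, det +1) plus
# translation, applied to a coordinate matrix
random_rigid_motion <- function(X) {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t(Q %*% t(X)) + matrix(rnorm(3, sd = 5), nrow(X), 3, byrow = TRUE)
}

dh_params <- function(ff = FF) {
  list(dw = ff$dh$dw, dp = ff$dh$dp, s = ff$dh$s, coulomb = ff$dh$coulomb)
}

# independent superposition oracle: Horn's closed-form quaternion method
# (different algorithm from the package's SVD-based Kabsch fit)
horn_rmsd <- function(A, B) {
  n <- nrow(A)
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  M <- crossprod(B, A)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,        -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(A^2) + sum(B^2) - 2 * lambda) / n)
}
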