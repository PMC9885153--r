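test_that("Mie potential has the stated depth, zero crossing and tail", {
  p <- list(eps = 1, r0 = 4, n = 12, m = 6)
  expect_equal(mie_energy(p$r0, p), -1)
  gR0 <- (p$m / p$n)^(1 / (p$n - p$m)) * p$r0
  expect_lt(abs(mie_energy(gR0, p)), 1e-10)
  # (12,6) at r = 2 r0: m/(n-m) (1/2)^12 - n/(n-m) (1/2)^6
  expect_equal(mie_energy(2 * p$r0, p), -0.031005859375, tolerance = 1e-12)
  expect_error(mie_energy(-1, p), "r > 0")
})

test_that("Mie minimum and zero-crossing relations hold across exponents", {
  set.seed(3)
  for (n in c(8, 10, 12, 14)) {
    for (m in c(4, 5, 6)) {
      p <- list(eps = runif(1, 0.1, 2), r0 = runif(1, 2, 6), n = n, m = m)
      opt <- optimize(function(r) mie_energy(r, p),
                      c(0.3 * p$r0, 3 * p$r0), tol = 1e-10)
      expect_equal(opt$minimum, p$r0, tolerance = 1e-4)
      expect_equal(opt$objective, -p$eps, tolerance = 1e-8)
      gR0 <- (m / n)^(1 / (n - m)) * p$r0
      expect_lt(abs(mie_energy(gR0, p)), 1e-10)
      expect_lt(gR0, p$r0)
    }
  }
})

test_that("repulsive-only Mie keeps the core and clamps the well", {
  p <- list(eps = 1, r0 = 4, n = 12, m = 6, repulsive_only = TRUE)
  gR0 <- (6 / 12)^(1 / 6) * 4
  expect_gt(mie_energy(0.8 * gR0, p), 0)            # core unchanged
  expect_equal(mie_energy(p$r0, p), 0)              # well clamped to zero
  expect_equal(mie_energy(10, p), 0)
})

test_that("flat-bottomed well is zero inside, quadratic outside, periodic", {
  eps <- 0.005
  expect_equal(local_energy(-60, -90, -30, eps), 0)
  expect_equal(local_energy(-30, -90, -30, eps), 0)      # boundary
  expect_equal(local_energy(-20, -90, -30, eps), eps * 100)
  # periodic shorter arc: -179 is 89 degrees from -90 the direct way,
  # but only 151 degrees from -30 through +180; brute force over both arcs
  for (x in c(-179, 150, 178)) {
    d_direct <- abs(c(x - (-90), x - (-30)))
    d_wrap <- 360 - d_direct
    d_min <- min(pmin(d_direct, d_wrap))
    expect_equal(local_energy(x, -90, -30, eps), eps * d_min^2)
  }
  expect_equal(local_energy(-179, -90, -30, eps), eps * 89^2)
})

test_that("well penalty is continuous across the bounds", {
  eps <- 0.005
  h <- 1e-6
  for (b in c(-90, -30)) {
    inside <- local_energy(b + ifelse(b == -90, h, -h), -90, -30, eps)
    outside <- local_energy(b + ifelse(b == -90, -h, h), -90, -30, eps)
    expect_lt(abs(inside - outside), 1e-8)
  }
})

test_that("hydrogen-bond radial term bottoms out at sigma", {
  hb <- list(sigma = 1.8, depth = 1)
  expect_equal(hbond_radial(1.8, hb), -1)
  expect_lt(abs(hbond_radial(50, hb)), 1e-10)
  expect_lt(hbond_radial(50, hb), 0)                 # approaches 0 from below
  expect_gt(hbond_radial(0.9 * 1.8, hb), 0)          # steep repulsive side
  opt <- optimize(function(r) hbond_radial(r, hb), c(0.5, 10), tol = 1e-8)
  expect_equal(opt$minimum, 1.8, tolerance = 1e-6)
  expect_equal(opt$objective, -1, tolerance = 1e-10)
  # direct evaluation cross-check at an off-minimum point
  r <- 2.2
  expect_equal(hbond_radial(r, hb), 5 * (1.8 / r)^12 - 6 * (1.8 / r)^10)
})

test_that("hydrogen-bond angular factor is cos^2 past 90 degrees", {
  expect_equal(hbond_angular(180), 1)
  expect_equal(hbond_angular(90), 0)
  expect_equal(hbond_angular(120), 0.25)
  expect_equal(hbond_angular(45), 0)
  expect_lt(hbond_angular(90 + 1e-4), 1e-6)          # continuity at cutoff
})

test_that("helical H-bond network is detected with the separation rule", {
  topo <- parse_sequence(strrep("A", 15), ff = FF)
  helix <- build_conformation(topo, cbind(rep(-57, 15), rep(-47, 15)), FF)
  out <- hbond_pairwise(helix, topo, FF)
  helical <- out$hbonds$donor - out$hbonds$acceptor == 4
  expect_equal(sum(helical), 11)
  expect_true(all(abs(out$hbonds$donor - out$hbonds$acceptor) >= 4))
  expect_lt(out$energy, 0)
  # independent geometric oracle: distance + angle criterion
  idx <- topo$idx
  geo <- sum(vapply(1:11, function(i) {
    r <- sqrt(sum((helix$coords[idx$O[i], ] -
                     helix$coords[idx$H[i + 4], ])^2))
    a <- phfold:::vertex_angle(helix$coords[idx$N[i + 4], ],
                               helix$coords[idx$H[i + 4], ],
                               helix$coords[idx$O[i], ])
    r < 2.5 && a > 90
  }, TRUE))
  expect_equal(sum(helical), geo)
})

test_that("extended chains have no H-bonds and short separations are excluded", {
  topo <- parse_sequence(strrep("A", 12), ff = FF)
  ext <- build_conformation(topo, cbind(rep(-150, 12), rep(150, 12)), FF)
  out <- hbond_pairwise(ext, topo, FF)
  expect_equal(nrow(out$hbonds), 0)
  expect_lt(abs(out$energy), 1e-3)
  # residues 3 apart never appear regardless of geometry
  topo5 <- parse_sequence(strrep("A", 5), ff = FF)
  hel5 <- build_conformation(topo5, cbind(rep(-57, 5), rep(-47, 5)), FF)
  out5 <- hbond_pairwise(hel5, topo5, FF)
  expect_true(all(abs(out5$hbonds$donor - out5$hbonds$acceptor) >= 4))
})

test_that("cooperative term rewards helical and sheet ladder patterns only", {
  sig <- FF$hbond$sigma
  mk <- function(d, a, r = sig) data.frame(donor = d, acceptor = a, r = r)
  # consecutive helical bonds at the radial minimum: weight * 1
  hb2 <- rbind(mk(5, 1), mk(6, 2))
  expect_equal(hbond_cooperative(hb2, FF), FF$hbond$eps_alpha_coop)
  # (i+3, j+3) matches neither pattern
  expect_equal(hbond_cooperative(rbind(mk(5, 1), mk(8, 4)), FF), 0)
  # antiparallel ladder (i+2, j-2)
  expect_equal(hbond_cooperative(rbind(mk(4, 11), mk(6, 9)), FF),
               FF$hbond$eps_beta_coop)
  # parallel ladder (i+2, j+2)
  expect_equal(hbond_cooperative(rbind(mk(4, 11), mk(6, 13)), FF),
               FF$hbond$eps_beta_coop)
  # Gaussian factor decays away from sigma
  off <- rbind(mk(5, 1, sig + 1), mk(6, 2, sig + 1))
  expect_equal(hbond_cooperative(off, FF),
               FF$hbond$eps_alpha_coop * exp(-1), tolerance = 1e-12)
  # ideal helix produces a chain of alpha-cooperative pairs
  topo <- parse_sequence(strrep("A", 15), ff = FF)
  helix <- build_conformation(topo, cbind(rep(-57, 15), rep(-47, 15)), FF)
  hbs <- hbond_pairwise(helix, topo, FF)$hbonds
  expect_lt(hbond_cooperative(hbs, FF), 0)
})

test_that("energy report components are additive and deterministic", {
  set.seed(4)
  topo <- parse_sequence("KAERWSQIK", ff = FF)
  conf <- random_conformation(topo)
  rep1 <- sopep_energy(conf, topo, FF)
  rep2 <- sopep_energy(conf, topo, FF)
  expect_identical(rep1$e_total, rep2$e_total)
  expect_equal(rep1$e_total,
               rep1$e_local + rep1$e_nonbonded + rep1$e_hb_pairwise +
                 rep1$e_hb_coop + rep1$e_dh, tolerance = 1e-8)
})

test_that("total energy is invariant under rigid rotation and translation", {
  set.seed(5)
  topo <- parse_sequence("MKRWEDFA", ff = FF)
  cs <- assign_charges(topo, 7.4, 0.15, FF)
  conf <- random_conformation(topo)
  e0 <- total_energy(conf, topo, FF, cs)$e_total
  for (rep in 1:3) {
    moved <- conf
    moved$coords <- random_rigid_motion(conf$coords)
    e1 <- total_energy(moved, topo, FF, cs)$e_total
    expect_equal(e1, e0, tolerance = 1e-8)
  }
})

test_that("ideal helix scores below the extended chain for (A)15", {
  topo <- parse_sequence(strrep("A", 15), ff = FF)
  helix <- build_conformation(topo, cbind(rep(-57, 15), rep(-47, 15)), FF)
  ext <- build_conformation(topo, cbind(rep(-150, 15), rep(150, 15)), FF)
  expect_lt(sopep_energy(helix, topo, FF)$e_total,
            sopep_energy(ext, topo, FF)$e_total)
})

test_that("C++ kernel reproduces the R reference energy", {
  set.seed(6)
  for (rep in 1:4) {
    topo <- parse_sequence(random_sequence(sample(5:12, 1)),
                           n_blocked = rep %% 2 == 0, ff = FF)
    cs <- assign_charges(topo, sample(c(3.6, 7.4, 12), 1), 0.15, FF)
    conf <- random_conformation(topo)
    er <- total_energy(conf, topo, FF, cs)
    ec <- phfold:::cpp_total_energy(conf, topo, FF, cs)
    expect_equal(ec$e_local, er$e_local, tolerance = 1e-8)
    expect_equal(ec$e_nonbonded, er$e_nonbonded, tolerance = 1e-8)
    expect_equal(ec$e_hb_pairwise, er$e_hb_pairwise, tolerance = 1e-8)
    expect_equal(ec$e_hb_coop, er$e_hb_coop, tolerance = 1e-8)
    expect_equal(ec$e_dh, er$e_dh, tolerance = 1e-8)
  }
})

test_that("moving a two-residue pair apart weakens the non-bonded term", {
  topo <- parse_sequence("GG", ff = FF)
  conf <- build_conformation(topo, cbind(rep(180, 2), rep(180, 2)), FF)
  e1 <- sopep_energy(conf, topo, FF)
  expect_true(is.finite(e1$e_total))
  far <- conf
  ctr <- matrix(colMeans(conf$coords), nrow(conf$coords), 3, byrow = TRUE)
  far$coords <- (conf$coords - ctr) * 2 + ctr
  e2 <- sopep_energy(far, topo, FF)
  expect_lt(abs(e2$e_nonbonded), abs(e1$e_nonbonded))
})
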