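test_that("sigmoidal dielectric has the stated limits and midrange value", {
  d <- list(dw = 78, dp = 2, s = 0.6)
  expect_equal(sigmoidal_dielectric(0, d), 2)
  expect_equal(sigmoidal_dielectric(1e6, d), 78, tolerance = 1e-6)
  # independent arithmetic at r = 5: 78 - 76 (4.5 + 3 + 1) e^-3
  expect_equal(sigmoidal_dielectric(5, d), 78 - 76 * 8.5 * exp(-3),
               tolerance = 1e-12)
  expect_equal(sigmoidal_dielectric(5, d), 45.8376, tolerance = 1e-3)
})

test_that("dielectric is strictly increasing and bounded on a dense grid", {
  d <- list(dw = 78, dp = 2, s = 0.6)
  r <- seq(0, 60, by = 0.01)
  eps <- sigmoidal_dielectric(r, d)
  expect_true(all(diff(eps) > 0))
  expect_true(all(eps >= 2 & eps <= 78))
})

test_that("Henderson-Hasselbalch charges titrate correctly", {
  topo <- parse_sequence("KKKK", ff = FF)
  cs <- assign_charges(topo, 10.5, 0.15, FF)       # at the lysine pKa
  expect_equal(cs$q[topo$idx$SC[2]], 0.5)
  cs2 <- assign_charges(topo, 7.4, 0.15, FF)
  expect_equal(cs2$q[topo$idx$SC[2]], 1 / (1 + 10^(7.4 - 10.5)))
  expect_equal(cs2$q[topo$idx$SC[2]], 0.99921, tolerance = 1e-5)
  topoD <- parse_sequence("DDDD", ff = FF)
  csD <- assign_charges(topoD, 3.9, 0.15, FF)      # at the aspartate pKa
  expect_equal(csD$q[topoD$idx$SC[2]], -0.5)
  expect_error(assign_charges(topo, 15, 0.15, FF), "pH")
})

test_that("charge magnitude is monotone in pH with saturating limits", {
  topo <- parse_sequence("KD", ff = FF)
  ph <- seq(1, 13.5, by = 0.5)
  qK <- vapply(ph, function(p)
    assign_charges(topo, p, 0.15, FF)$q[topo$idx$SC[1]], 0)
  qD <- vapply(ph, function(p)
    assign_charges(topo, p, 0.15, FF)$q[topo$idx$SC[2]], 0)
  expect_true(all(diff(qK) < 0))                   # base discharges with pH
  expect_true(all(diff(qD) < 0))                   # acid gains negative charge
  expect_lt(abs(assign_charges(topo, 13.5, 0.15, FF)$q[topo$idx$SC[1]]),
            1e-3)
  expect_gt(assign_charges(topo, 7.5, 0.15, FF)$q[topo$idx$SC[1]], 0.999)
})

test_that("blocked termini carry no charge", {
  blocked <- parse_sequence(strrep("K", 15), n_blocked = TRUE,
                            c_blocked = TRUE, ff = FF)
  cs <- assign_charges(blocked, 7.4, 0.15, FF)
  expect_equal(sum(abs(cs$q) > 1e-6), 15)          # side chains only
  expect_equal(cs$q[blocked$idx$N[1]], 0)
  expect_equal(cs$q[blocked$idx$C[15]], 0)
  free <- parse_sequence(strrep("K", 15), ff = FF)
  csf <- assign_charges(free, 7.4, 0.15, FF)
  expect_equal(sum(abs(csf$q) > 1e-6), 17)         # plus both termini
  expect_gt(csf$q[free$idx$N[1]], 0)
  expect_lt(csf$q[free$idx$C[15]], 0)
})

test_that("Debye length follows the aqueous formula with a no-salt cap", {
  expect_equal(debye_length(0.15), 3.04 / sqrt(0.15), tolerance = 1e-12)
  expect_equal(debye_length(0.15), 7.85, tolerance = 1e-2)
  expect_equal(debye_length(1.0), 3.04)
  expect_equal(debye_length(0), 1e4)
  expect_error(debye_length(-0.1), "non-negative")
})

test_that("shift calibration reproduces the crossing construction", {
  d <- dh_params()
  l <- debye_length(0.15)
  pm <- mie_pair_params(FF, "SC_K", "SC_E")
  fs <- fit_shift(pm, 1, l, d, 4)
  # the crossing sits on the repulsive branch at E_Mie = +k
  expect_equal(mie_energy(fs$crossing_r, pm), 4, tolerance = 1e-4)
  # the shifted DH magnitude equals k there (dielectric at unshifted r)
  e <- d$coulomb * exp(-(fs$crossing_r + fs$shift) / l) /
    (sigmoidal_dielectric(fs$crossing_r, d) * (fs$crossing_r + fs$shift))
  expect_equal(e, 4, tolerance = 1e-4)
  # independent dense-grid root scan for the shift
  grid <- seq(-0.9 * fs$crossing_r, 20, by = 1e-4)
  vals <- d$coulomb * exp(-(fs$crossing_r + grid) / l) /
    (sigmoidal_dielectric(fs$crossing_r, d) * (fs$crossing_r + grid)) - 4
  best <- grid[which.min(abs(vals))]
  expect_equal(fs$shift, best, tolerance = 2e-4)
  expect_error(fit_shift(pm, 0, l, d, 4), "non-zero")
})

test_that("a pair already crossing at k gets (near) zero shift", {
  d <- dh_params()
  l <- debye_length(0.15)
  pm <- mie_pair_params(FF, "SC_K", "SC_K")
  rc <- phfold:::bisect(function(r) mie_energy(r, pm) - 4,
                        1e-3 * pm$r0, pm$gR0)
  qq <- 4 * sigmoidal_dielectric(rc, d) * rc * exp(rc / l) / d$coulomb
  fs <- fit_shift(pm, qq, l, d, 4)
  expect_lt(abs(fs$shift), 1e-3)
})

test_that("DH pair energy respects sign, zero and screening contracts", {
  d <- dh_params()
  fs <- list(shift = 0.5, crossing_r = 3)
  e_pp <- dh_pair_energy(6, 1, 1, fs$shift, fs$crossing_r, 7.85, d)
  e_pm <- dh_pair_energy(6, 1, -1, fs$shift, fs$crossing_r, 7.85, d)
  expect_gt(e_pp, 0)
  expect_lt(e_pm, 0)
  expect_equal(e_pm, -e_pp)
  expect_equal(dh_pair_energy(6, 0, 1, fs$shift, fs$crossing_r, 7.85, d), 0)
  # increasing ionic strength (shorter Debye length) weakens the energy
  ls <- vapply(c(0.01, 0.05, 0.15, 0.5, 1), debye_length, 0)
  es <- vapply(ls, function(l)
    dh_pair_energy(6, 1, 1, fs$shift, fs$crossing_r, l, d), 0)
  expect_true(all(diff(es) < 0))
  # below the crossing the magnitude is clamped at k
  expect_equal(dh_pair_energy(0.5, 1, 1, 0, 3, 7.85, d, k = 4), 4)
  expect_equal(dh_pair_energy(0.5, 1, -1, 0, 3, 7.85, d, k = 4), -4)
  expect_error(dh_pair_energy(0, 1, 1, 0, 3, 7.85, d), "r > 0")
})

test_that("calibrated pairs cross Mie at k and DH energy there equals k", {
  topo <- parse_sequence("KEKEK", ff = FF)
  cs <- dh_calibrate(assign_charges(topo, 7.4, 0.15, FF), topo, FF)
  p <- cs$pairs
  expect_true(all(is.finite(p$shift)))
  for (pair in list(c(1, 2), c(1, 3), c(2, 4))) {
    a <- pair[1]; b <- pair[2]
    i <- p$cidx[a]; j <- p$cidx[b]
    e <- dh_pair_energy(p$crossing[a, b], cs$q[i], cs$q[j], p$shift[a, b],
                        p$crossing[a, b], cs$debye_length, dh_params(),
                        FF$dh$k_cross)
    expect_equal(abs(e), FF$dh$k_cross, tolerance = 1e-3)
  }
})

test_that("sequence-separation weighting applies the 10/2 ratio", {
  # charges on residues 1 and 10 of a poly-K chain: separation 9 is in the
  # far class by default; raising the cutoff moves the identical geometry
  # into the near class, scaling the total by w_near / w_far = 5
  topo <- parse_sequence(strrep("K", 10), n_blocked = TRUE, c_blocked = TRUE,
                         ff = FF)
  conf <- build_conformation(topo, cbind(rep(-150, 10), rep(150, 10)), FF)
  cs <- assign_charges(topo, 7.4, 0.15, FF)
  keep <- c(topo$idx$SC[1], topo$idx$SC[10])
  cs$q[setdiff(seq_len(topo$n_particles), keep)] <- 0
  e_far <- dh_total_energy(conf, topo, cs, FF)
  ff_near <- FF
  ff_near$dh$separation_cutoff <- 20
  cs2 <- assign_charges(topo, 7.4, 0.15, FF)
  cs2$q[setdiff(seq_len(topo$n_particles), keep)] <- 0
  e_near <- dh_total_energy(conf, topo, cs2, ff_near)
  expect_equal(e_near / e_far, FF$dh$w_near / FF$dh$w_far, tolerance = 1e-9)
})

test_that("like-charged chains have positive DH energy; neutral chains zero", {
  topo <- parse_sequence(strrep("K", 15), n_blocked = TRUE, c_blocked = TRUE,
                         ff = FF)
  conf <- build_conformation(topo, cbind(rep(-150, 15), rep(150, 15)), FF)
  cs <- assign_charges(topo, 7.4, 0, FF)
  expect_gt(dh_total_energy(conf, topo, cs, FF), 0)
  cs0 <- assign_charges(topo, 7.4, 0, FF)
  cs0$q[] <- 0
  expect_equal(dh_total_energy(conf, topo, cs0, FF), 0)
})

test_that("DH total energy is invariant under rigid motion", {
  set.seed(8)
  topo <- parse_sequence("KEDRH", ff = FF)
  conf <- random_conformation(topo)
  cs <- assign_charges(topo, 6.5, 0.15, FF)
  e0 <- dh_total_energy(conf, topo, cs, FF)
  moved <- conf
  moved$coords <- random_rigid_motion(conf$coords)
  expect_equal(dh_total_energy(moved, topo, cs, FF), e0, tolerance = 1e-8)
})

test_that("pH toggles the charged flag driving repulsive-only Mie", {
  topo <- parse_sequence("KKKK", ff = FF)
  low <- phfold:::charged_sc_flags(topo, assign_charges(topo, 7.4, 0.15, FF),
                                   FF)
  high <- phfold:::charged_sc_flags(topo, assign_charges(topo, 13.5, 0.15, FF),
                                    FF)
  sc <- topo$particles$kind == "SC"
  expect_true(all(low[sc]))                         # protonated lysines
  expect_false(any(high[sc]))                       # deprotonated at pH 13.5
  expect_false(any(low[!sc]))                       # backbone never flagged
})
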