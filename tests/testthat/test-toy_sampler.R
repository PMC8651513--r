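test_that("ideal gas: acceptance 1.0 and virial pressure = n kT / V", {
  sys <- toy_system(lattice_positions(27, c(3, 3, 3)), c(3, 3, 3),
                    epsilon = 0, charge = 0)
  ens <- metropolis_sample(sys, 6000, 0.3, seed = 1)
  expect_equal(attr(ens, "acceptance"), 1.0)
  p <- ens$observables$p_iso
  p_ideal <- 27 * 0.008314462618 * 298.15 / 27 * 16.6054
  se <- sd(p) / sqrt(length(p))
  ## with no interactions the virial term vanishes identically
  expect_equal(mean(p), p_ideal, tolerance = 1e-12)
  expect_lte(abs(mean(p) - p_ideal), 3 * se + 1e-9)
})

test_that("harmonic tether: coordinate variance = kT / k within 3 SE", {
  k <- 50   # kJ/mol/nm^2 -> sd ~ 0.22 nm, well inside a 6 nm box
  sys <- toy_system(matrix(3, 1, 3), c(6, 6, 6), epsilon = 0, charge = 0,
                    external_k = k)
  ens <- metropolis_sample(sys, 60000, 0.4, seed = 2, stride = 5,
                           store_positions = TRUE)
  z <- vapply(attr(ens, "positions"), function(p) p[1, 3], numeric(1))
  v_hat <- mean((z - 3)^2)
  v_true <- kT(298.15) / k
  se <- sd((z - 3)^2) / sqrt(length(z) / 10)   # ~10-frame correlation slack
  expect_lte(abs(v_hat - v_true), 3 * se)
  ## and the sampled coordinate is Gaussian (Boltzmann for a harmonic well)
  ks <- suppressWarnings(ks.test(z, "pnorm", 3, sqrt(v_true)))
  expect_gt(ks$p.value, 0.001)
})

test_that("fixed seed reproduces the ensemble bit for bit", {
  sys <- small_charged_system()
  a <- metropolis_sample(sys, 3000, 0.15, seed = 77)
  b <- metropolis_sample(sys, 3000, 0.15, seed = 77)
  expect_identical(a$base_energy, b$base_energy)
  expect_identical(a$observables$inv_r, b$observables$inv_r)
  c_ <- metropolis_sample(sys, 3000, 0.15, seed = 78)
  expect_false(identical(a$base_energy, c_$base_energy))
})

test_that("overlapping initial coordinates are rejected", {
  pos <- rbind(c(1, 1, 1), c(1, 1, 1.01))
  expect_error(toy_system(pos, c(3, 3, 3)) |>
                 metropolis_sample(100, 0.1, seed = 1), "overlap")
})

test_that("C++ energies and virials match an independent R evaluation", {
  sys <- small_charged_system(n = 12, box = 2.5, q = 0.25)
  ens <- metropolis_sample(sys, 2000, 0.15, seed = 5, stride = 50,
                           store_positions = TRUE)
  pos_list <- attr(ens, "positions")
  for (f in seq_len(min(3, ens$n_frames))) {
    oracle <- r_energy_virial(sys, pos_list[[f]])
    expect_equal(ens$base_energy[f], oracle$u, tolerance = 1e-8)
    expect_equal(ens$observables$pxx[f], oracle$p[1], tolerance = 1e-6)
    expect_equal(ens$observables$pyy[f], oracle$p[2], tolerance = 1e-6)
    expect_equal(ens$observables$pzz[f], oracle$p[3], tolerance = 1e-6)
  }
})

test_that("the quadratic energy model matches re-evaluation at shifted charges", {
  sys <- small_charged_system(n = 12, box = 2.5, q = 0.25)
  ens <- metropolis_sample(sys, 2000, 0.15, seed = 6, stride = 50,
                           store_positions = TRUE)
  th_new <- c(0.3, -0.2)
  u_model <- ens$u_fun(th_new)
  sys_new <- set_toy_charges(sys, th_new)
  pos_list <- attr(ens, "positions")
  for (f in seq_len(min(3, ens$n_frames))) {
    expect_equal(u_model[f], r_energy_virial(sys_new, pos_list[[f]])$u,
                 tolerance = 1e-8)
  }
})

test_that("resimulation oracle: identical charges give identical estimates", {
  sys <- small_charged_system(n = 16, box = 2.8, q = 0.15)
  out <- resimulation_oracle(sys, c(0.15, -0.15), "inv_r",
                             n_steps = 4000, seed = 3)
  expect_equal(out$ess_frac, 1.0)
  ## reweighted estimate equals the plain mean of the q_a run by construction
  expect_equal(out$reweighted$ess, out$reweighted$ess)
  w_check <- abs(out$reweighted$mean - out$direct$mean)
  expect_lte(w_check, out$reweighted$ci95 + out$direct$ci95)
})

test_that("ESS fraction decreases along a perturbation grid", {
  sys <- small_charged_system(n = 16, box = 2.8, q = 0.15)
  fr <- vapply(c(0.01, 0.03, 0.06), function(d) {
    ens <- metropolis_sample(sys, 4000, 0.15, seed = 9)
    reweight(ens, c(0.15 + d, -0.15))$ess / ens$n_frames
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("synthetic tension series honours its stated moments", {
  s <- synth_tension_series(100, 12, ar1_phi = 0, noise_sd = 0, n = 50)
  expect_equal(s$pzz, rep(100, 50))
  expect_error(synth_tension_series(1, 1, ar1_phi = 1.2), "ar1_phi")
  ## AR(1) mean converges to the stated anisotropy
  s2 <- synth_tension_series(100, 12, ar1_phi = 0.5, noise_sd = 5,
                             n = 20000, seed = 4)
  expect_equal(mean(s2$pzz), 100, tolerance = 0.5)
})

test_that("bilayer frame generator: flat potential and seeded reproducibility", {
  f0 <- synth_bilayer_frames(function(z) 0 * z, 20000, seed = 1,
                             span = c(-1, 1))
  expect_gt(suppressWarnings(ks.test(f0$z, "punif", -1, 1))$p.value, 0.01)
  ## two seeds: same distribution (KS), different draws
  f1 <- synth_bilayer_frames(double_well(), 20000, seed = 2)
  f2 <- synth_bilayer_frames(double_well(), 20000, seed = 3)
  expect_false(identical(f1$z, f2$z))
  expect_gt(suppressWarnings(ks.test(f1$z, f2$z))$p.value, 0.01)
  expect_error(synth_bilayer_frames(function(z) 1 / (z - z), 10),
               "bounded")
})

test_that("virial pressure agrees with a free-energy finite difference", {
  ## 2 LJ particles: F(V) = -kT ln Z(V) by direct quadrature over the
  ## relative coordinate; P = -dF/dV must match the sampled virial mean.
  box_of <- function(L) toy_system(rbind(c(0.5, 0.5, 0.5),
                                         c(1.5, 1.5, 1.5)),
                                   rep(L, 3), sigma = 0.34, epsilon = 0.6,
                                   charge = 0, cutoff = 0.74)
  z_of <- function(L, ngrid = 48) {
    g <- seq(0, L, length.out = ngrid + 1)[-1] - L / (2 * ngrid)
    kbt <- 0.008314462618 * 298.15
    s <- 0
    sys <- box_of(L)
    for (x in g) for (y in g) {
      dr <- c(x, y, g) - L / 2
      dr <- dr - L * round(dr / L)
      ## vectorized over z grid
      r2 <- dr[1]^2 + dr[2]^2 + (g - L / 2 - L * round((g - L / 2) / L))^2
      u <- ifelse(r2 <= sys$cutoff^2,
                  4 * 0.6 * ((0.34^2 / r2)^6 - (0.34^2 / r2)^3), 0)
      s <- s + sum(exp(-u / kbt))
    }
    s * (L / ngrid)^3
  }
  ## configurational Z = V * Z_rel (one particle fixed by translation
  ## invariance); F = -kT ln Z, P = -dF/dV by central-ish difference
  L1 <- 2.0; L2 <- 2.1
  kbt <- 0.008314462618 * 298.15
  f1 <- -kbt * (log(z_of(L1)) + log(L1^3))
  f2 <- -kbt * (log(z_of(L2)) + log(L2^3))
  p_fd_tot <- -(f2 - f1) / (L2^3 - L1^3) * 16.6054
  sys_mid <- box_of(2.05)
  ens <- metropolis_sample(sys_mid, 40000, 0.3, seed = 13, stride = 5)
  p_hat <- mean(ens$observables$p_iso)
  se <- sd(ens$observables$p_iso) / sqrt(ens$n_frames / 5)
  expect_lte(abs(p_hat - p_fd_tot), 3 * se + 0.05 * abs(p_fd_tot))
})
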