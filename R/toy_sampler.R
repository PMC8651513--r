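## Toy statistical-mechanics fixtures: a Metropolis sampler for small
## charged LJ systems, plus generators for synthetic tension series and
## PMF-bearing particle distributions. This is the MD-free test bed; it
## validates estimators and the optimizer, not force-field physics
## (minimum-image truncated Coulomb, no Ewald).

#' Define a toy charged Lennard-Jones system
#'
#' @param positions n x 3 matrix of starting coordinates (nm); wrapped into
#'   the box.
#' @param box Length-3 box vector (nm), periodic with minimum image.
#' @param sigma,epsilon Per-particle LJ parameters (nm, kJ/mol); recycled.
#' @param charge Per-particle charges (e).
#' @param charge_map Integer per particle: particles sharing a positive
#'   label share one free charge parameter; 0 marks a fixed (frozen) charge.
#' @param temperature Temperature in K.
#' @param cutoff Interaction cutoff (nm).
#' @param external_k Optional harmonic tether to the box centre
#'   (kJ/mol/nm^2); the 1D/3D harmonic special cases are exactly solvable
#'   and used as sampler oracles.
#' @return A `toy_system`.
#' @export
toy_system <- function(positions, box, sigma = 0.34, epsilon = 0.4,
                       charge = 0, charge_map = 0L, temperature = 298.15,
                       cutoff = min(box) / 2, external_k = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0))
  n <- nrow(positions)
  sigma <- rep_len(sigma, n)
  epsilon <- rep_len(epsilon, n)
  charge <- rep_len(charge, n)
  charge_map <- rep_len(as.integer(charge_map), n)
  if (any(epsilon > 0) && min(box) <= 2 * max(sigma[epsilon > 0])) {
    stop("toy_system: box must exceed twice the largest LJ sigma")
  }
  ## charges within one map group must agree (they are one parameter)
  for (g in setdiff(unique(charge_map), 0L)) {
    if (diff(range(charge[charge_map == g])) > 1e-12) {
      stop("toy_system: particles sharing charge_map label ", g,
           " carry different charges")
    }
  }
  structure(list(positions = positions %% matrix(box, n, 3, byrow = TRUE),
                 box = as.numeric(box), sigma = sigma, epsilon = epsilon,
                 charge = charge, charge_map = charge_map,
                 temperature = temperature, cutoff = cutoff,
                 external_k = external_k),
            class = "toy_system")
}

#' Lattice starting positions for a toy system
#'
#' Particles on a cubic lattice, the standard non-overlapping start.
#'
#' @param n Number of particles.
#' @param box Length-3 box (nm).
#' @return n x 3 matrix.
#' @export
lattice_positions <- function(n, box) {
  m <- ceiling(n^(1 / 3))
  g <- seq(0.5, m - 0.5) / m
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))[seq_len(n), , drop = FALSE]
  sweep(grid, 2, box, `*`)
}

#' Sample a toy system with Metropolis Monte Carlo
#'
#' Single-particle displacement Metropolis at fixed temperature. Per stored
#' frame the run records the exact decomposition of the potential energy in
#' the free charge parameters (so that energies and their charge-derivatives
#' can be evaluated for any charge vector), the diagonal virial pressure at
#' the sampling charges (bar), and configuration-only observables
#' (`inv_r`, `inv_r_g<k>`: inverse pair-distance sums overall and per charge
#' group). Fixed seed gives a bit-identical ensemble.
#'
#' @param sys A [toy_system()].
#' @param n_steps Total Metropolis moves.
#' @param step_size Maximum per-coordinate displacement (nm).
#' @param seed Integer seed for the sampler's own RNG.
#' @param stride Moves between stored frames.
#' @param burn_in_frac Fraction of moves discarded before storing.
#' @param store_positions Keep per-frame coordinates.
#' @return An [ensemble()] with observables `inv_r`, `inv_r_g*`, `pxx`,
#'   `pyy`, `pzz`, `p_iso`, `anisotropy` and attribute `acceptance`.
#' @export
metropolis_sample <- function(sys, n_steps, step_size, seed, stride = 10,
                              burn_in_frac = 0.2, store_positions = FALSE) {
  stopifnot(inherits(sys, "toy_system"), n_steps > 0, step_size > 0)
  burn_in <- floor(burn_in_frac * n_steps)
  res <- .mc_run_cpp(sys$positions, sys$box, sys$sigma, sys$epsilon,
                     sys$charge_map, sys$charge, sys$temperature,
                     as.integer(n_steps), step_size, as.integer(stride),
                     as.integer(burn_in), sys$cutoff, sys$external_k,
                     as.integer(seed), store_positions)
  ng <- res$n_groups
  theta0 <- numeric(ng)
  for (g in seq_len(ng)) theta0[g] <- sys$charge[sys$charge_map == g][1]
  names(theta0) <- if (ng > 0) paste0("g", seq_len(ng)) else character(0)
  obs <- list(
    inv_r = res$inv_r,
    pxx = res$pxx, pyy = res$pyy, pzz = res$pzz,
    p_iso = (res$pxx + res$pyy + res$pzz) / 3,
    anisotropy = res$pzz - (res$pxx + res$pyy) / 2)
  if (ng > 0) {
    for (g in seq_len(ng)) obs[[paste0("inv_r_g", g)]] <- res$inv_r_g[, g]
  }
  ens <- ensemble_quadratic(
    beta = 1 / kT(sys$temperature), theta = theta0,
    c0 = res$c0, B = res$B, M = res$M, base_energy = res$u_base,
    observables = obs)
  attr(ens, "acceptance") <- res$acceptance
  attr(ens, "seed") <- as.integer(seed)
  if (store_positions) {
    n <- nrow(sys$positions)
    attr(ens, "positions") <- lapply(seq_len(res$n_frames), function(f) {
      res$positions[seq_len(n) + (f - 1) * n, , drop = FALSE]
    })
  }
  ens
}

#' Direct-resimulation oracle for reweighting
#'
#' Samples the toy system at charges `theta_a`, reweights the named
#' observable to `theta_b`, and independently resamples at `theta_b`
#' to compute the same mean directly. Agreement of the two estimates (within
#' their combined confidence intervals) validates the importance-reweighting
#' estimator.
#'
#' @param sys A [toy_system()]; its charges are the `theta_a` state.
#' @param theta_b Free-parameter vector to perturb to.
#' @param obs_key Observable name.
#' @param n_steps,step_size,stride Sampler settings (see
#'   [metropolis_sample()]). The default run length is chosen so that the
#'   20 bootstrap blocks are longer than the observable correlation time,
#'   keeping the confidence intervals calibrated.
#' @param seed Integer seed; the two runs use `seed` and `seed + 1`.
#' @param ess_floor Minimum ESS fraction for the reweighted estimate.
#' @return List with `direct` and `reweighted`, each `(mean, ci95)`, plus
#'   `ess_frac`.
#' @export
resimulation_oracle <- function(sys, theta_b, obs_key, n_steps = 150000,
                                step_size = 0.15, stride = 20, seed = 1,
                                ess_floor = 0.2) {
  ens_a <- metropolis_sample(sys, n_steps, step_size, seed = seed,
                             stride = stride)
  w <- reweight(ens_a, theta_b)
  rw <- reweighted_mean_ci(ens_a, obs_key, w, ess_floor = ess_floor,
                           seed = seed + 1000L)
  sys_b <- set_toy_charges(sys, theta_b)
  ens_b <- metropolis_sample(sys_b, n_steps, step_size, seed = seed + 1L,
                             stride = stride)
  dm <- reweighted_mean_ci(ens_b, obs_key, uniform_weights(ens_b),
                           seed = seed + 2000L)
  list(direct = dm, reweighted = rw,
       ess_frac = w$ess / ens_a$n_frames)
}

#' Set the free charges of a toy system
#'
#' @param sys A [toy_system()].
#' @param theta Vector of free group charges, in group-label order.
#' @return The modified system.
#' @export
set_toy_charges <- function(sys, theta) {
  ng <- max(sys$charge_map)
  stopifnot(length(theta) == ng)
  for (g in seq_len(ng)) sys$charge[sys$charge_map == g] <- theta[g]
  sys
}

#' Synthetic pressure-anisotropy (tension) series
#'
#' AR(1) series of the pressure anisotropy `pzz - (pxx + pyy)/2` around a
#' stated mean, with constant box length, for which the analytic tension is
#' `0.1 * (lz / 2) * mean_anisotropy` mN/m.
#'
#' @param mean_anisotropy Mean anisotropy (bar).
#' @param lz Box length along z (nm).
#' @param ar1_phi AR(1) coefficient, |phi| < 1.
#' @param noise_sd Innovation standard deviation (bar).
#' @param n Number of frames.
#' @param seed Integer seed.
#' @param dt Frame spacing (ns).
#' @return A [tension_series()] with attribute `analytic_mNm`.
#' @export
synth_tension_series <- function(mean_anisotropy, lz, ar1_phi = 0,
                                 noise_sd = 0, n = 1000, seed = 1,
                                 dt = 0.1) {
  stopifnot(abs(ar1_phi) < 1, n >= 2)
  a <- numeric(n)
  if (noise_sd > 0) {
    set.seed(seed)
    innov <- stats::rnorm(n, 0, noise_sd)
    ## stationary start
    a[1] <- mean_anisotropy + innov[1] / sqrt(1 - ar1_phi^2)
    for (i in 2:n) {
      a[i] <- mean_anisotropy + ar1_phi * (a[i - 1] - mean_anisotropy) +
        innov[i]
    }
  } else {
    a[] <- mean_anisotropy
  }
  ## realize as pzz = anisotropy, pxx = pyy = 0
  s <- tension_series(time = seq_len(n) * dt - dt, pxx = rep(0, n),
                      pyy = rep(0, n), pzz = a, lz = rep(lz, n))
  attr(s, "analytic_mNm") <- recharge_constants$mNm_per_barnm *
    (lz / 2) * mean_anisotropy
  s
}

#' Synthetic bilayer-normal particle frames with a planted PMF
#'
#' Draws z-coordinates from the Boltzmann distribution of a supplied
#' potential by inverse-CDF sampling on a fine grid; x and y are uniform in
#' the box. The potential is the recovery target for the Boltzmann-inversion
#' pipeline.
#'
#' @param pmf_fun Function z (nm) -> potential (kcal/mol), bounded on
#'   `span`.
#' @param n_particles Particles per frame.
#' @param n_frames Number of frames.
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @param span z-range sampled (nm), centred on the midplane at 0.
#' @param box_xy Lateral box size (nm).
#' @param resname,atomname Labels attached to the particles so density /
#'   hydration selections work.
#' @param mass Per-particle mass (g/mol).
#' @param grid_n Grid resolution of the inverse CDF.
#' @return Frame table: data.frame(frame, resname, atomname, x, y, z, mass).
#' @export
synth_bilayer_frames <- function(pmf_fun, n_particles, n_frames = 1,
                                 temperature = 298.15, seed = 1,
                                 span = c(-2.5, 2.5), box_xy = 6,
                                 resname = "OIL", atomname = "C2",
                                 mass = 885.43, grid_n = 4096) {
  kt <- kT(temperature, "kcal")
  zg <- seq(span[1], span[2], length.out = grid_n)
  v <- pmf_fun(zg)
  if (any(!is.finite(v))) stop("pmf_fun must be bounded on span")
  dens <- exp(-(v - min(v)) / kt)
  cdf <- cumsum(dens)
  cdf <- cdf / cdf[length(cdf)]
  set.seed(seed)
  ntot <- n_particles * n_frames
  u <- stats::runif(ntot)
  z <- stats::approx(cdf, zg, xout = u, rule = 2, ties = "ordered")$y
  data.frame(
    frame = rep(seq_len(n_frames), each = n_particles),
    resname = resname, atomname = atomname,
    x = stats::runif(ntot, 0, box_xy),
    y = stats::runif(ntot, 0, box_xy),
    z = z, mass = mass,
    stringsAsFactors = FALSE)
}
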