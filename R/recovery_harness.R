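## Hidden-truth parameter-recovery harness on the toy sampler: the desk-
## scale stand-in for the published sample-and-refine protocol. A small
## charged LJ fluid with two equivalence groups of opposite charge defines
## the "molecule"; training targets are ensemble means of configuration
## observables computed at hidden truth charges.

#' Charge set of the built-in recovery toy
#'
#' 24 particles: 6 "A" atoms sharing one free charge, 6 "B" atoms sharing
#' the opposite free charge, and 12 frozen neutral "F" atoms. Net charge 0;
#' with equal multiplicities, neutrality ties the two free parameters to
#' theta_B = -theta_A, one effective degree of freedom -- the smallest
#' structure exhibiting every constraint the refinement must respect.
#'
#' @param q_a Charge of the A group (e); B gets `-q_a`.
#' @return A [charge_set()].
#' @export
toy_recovery_charge_set <- function(q_a = 0.3) {
  names <- c(paste0("A", 1:6), paste0("B", 1:6), paste0("F", 1:12))
  charges <- c(rep(q_a, 6), rep(-q_a, 6), rep(0, 12))
  groups <- c(rep(1L, 6), rep(7L, 6), 13:24)
  frozen <- c(rep(FALSE, 12), rep(TRUE, 12))
  charge_set(names, charges, reference_charges = charges, groups = groups,
             frozen = frozen, net_charge = 0)
}

## toy_system realizing a recovery charge set
toy_recovery_system <- function(cs, box = c(3, 3, 3),
                                temperature = 298.15) {
  n <- length(cs$atom_names)
  map <- integer(n)
  map[startsWith(cs$atom_names, "A")] <- 1L
  map[startsWith(cs$atom_names, "B")] <- 2L
  toy_system(lattice_positions(n, box), box = box,
             sigma = 0.34, epsilon = 0.4, charge = cs$charges,
             charge_map = map, temperature = temperature)
}

#' Build the toy parameter-recovery harness
#'
#' Samples the toy at hidden truth charges to define training targets (mean
#' and block-bootstrap 95% CI of per-group inverse-distance observables),
#' then returns a perturbed start and a sampler contract, ready for
#' [run_optimization()].
#'
#' @param seed Integer master seed.
#' @param q_truth_a Hidden truth charge of the A group (e). The default
#'   0.2 e keeps contact pairs a few kT deep, so single-particle moves mix
#'   on the run length; run lengths are chosen so the 0.05 e start offset
#'   shifts the target observables by well over their combined CIs.
#' @param perturb Starting offset added to the A group (and subtracted from
#'   B, preserving neutrality), in e.
#' @param n_steps_target Metropolis moves of the long truth run defining
#'   the targets.
#' @param n_steps_cycle Moves per per-cycle sampling run.
#' @param step_size Metropolis displacement (nm).
#' @param stride Moves between stored frames.
#' @return List `(q_truth, q_start, targets, sampler, theta_truth)`.
#' @export
toy_recovery_harness <- function(seed = 1L, q_truth_a = 0.2,
                                 perturb = 0.05, n_steps_target = 800000,
                                 n_steps_cycle = 400000, step_size = 0.16,
                                 stride = 20) {
  q_truth <- toy_recovery_charge_set(q_truth_a)
  sys_truth <- toy_recovery_system(q_truth)
  ens_truth <- metropolis_sample(sys_truth, n_steps_target, step_size,
                                 seed = split_seed(seed, 1L),
                                 stride = stride)
  obs_keys <- c("inv_r_g1", "inv_r_g2")
  targets <- lapply(seq_along(obs_keys), function(i) {
    est <- reweighted_mean_ci(ens_truth, obs_keys[i],
                              uniform_weights(ens_truth),
                              seed = split_seed(seed, 100L + i))
    target_spec(system = "TOY", property = "IT", exp_mean = est$mean,
                ci95 = est$ci95, scale = 1, obs_key = obs_keys[i])
  })

  q_start <- q_truth
  q_start$charges <- q_truth$charges +
    c(rep(perturb, 6), rep(-perturb, 6), rep(0, 12))
  q_start$reference_charges <- q_start$charges
  validate_charge_set(q_start)

  sampler <- function(cs, cycle_seed) {
    sys <- toy_recovery_system(cs)
    ens <- metropolis_sample(sys, n_steps_cycle, step_size,
                             seed = cycle_seed, stride = stride)
    ens$base_charges <- cs
    list(TOY = ens)
  }
  list(q_truth = q_truth, q_start = q_start, targets = targets,
       sampler = sampler,
       theta_truth = as.numeric(free_parameters(q_truth)))
}
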