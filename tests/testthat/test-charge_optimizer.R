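mk_target <- function(mean, ci, scale = 1, key = "inv_r_g1",
                      system = "TOY") {
  target_spec(system, "IT", exp_mean = mean, ci95 = ci, scale = scale,
              obs_key = key)
}

test_that("objective: perfect fit is zero; worked single-target arithmetic", {
  q <- charge_set(c("a", "b"), c(0.1, -0.1))
  tg <- list(mk_target(30.6, 2.4, scale = 0.040))
  expect_equal(objective(tg, 30.6, q, q, lambda = 0), 0)
  ## model 33.0 vs 30.6 +/- 2.4 with scale 0.040:
  ## (0.040 * 2.4 / 2.4)^2 = 0.0016
  expect_equal(objective(tg, 33.0, q, q, lambda = 0), 0.0016,
               tolerance = 1e-12)
  expect_error(objective(tg, NA_real_, q, q), "missing model mean")
  expect_error(objective(tg, numeric(0), q, q), "one model mean")
})

test_that("doubling every ci95 quarters the data term", {
  q <- charge_set(c("a", "b"), c(0.1, -0.1))
  set.seed(10)
  for (rep in 1:10) {
    means <- runif(3, 10, 40)
    exps <- runif(3, 10, 40)
    cis <- runif(3, 0.5, 3)
    scales <- runif(3, 0.01, 1)
    t1 <- lapply(1:3, function(i) mk_target(exps[i], cis[i], scales[i]))
    t2 <- lapply(1:3, function(i) mk_target(exps[i], 2 * cis[i], scales[i]))
    expect_equal(objective(t2, means, q, q), objective(t1, means, q, q) / 4,
                 tolerance = 1e-12)
  }
})

test_that("regularization adds lambda * sum((q - q_ref)^2) over free atoms", {
  q_ref <- charge_set(c("a", "b", "f"), c(0.1, -0.1, 0),
                      frozen = c(FALSE, FALSE, TRUE))
  q <- q_ref
  q$charges <- c(0.15, -0.15, 0)
  q$reference_charges <- q$charges   # keep frozen invariant satisfied
  tg <- list(mk_target(1, 1))
  expect_equal(objective(tg, 1, q, q_ref, lambda = 2),
               2 * (0.05^2 + 0.05^2), tolerance = 1e-12)
})

test_that("CI overlap reproduces the published qualitative verdicts", {
  ## refined model vs experiment: 31.2 +/- 1.4 against 30.6 +/- 2.4
  ok <- ci_overlap_converged(list(mean = 31.2, ci95 = 1.4),
                             list(mean = 30.6, ci95 = 2.4))
  expect_true(ok$converged)
  ## legacy model: 17.3 +/- 2.0 against 30.6 +/- 2.4 fails
  bad <- ci_overlap_converged(list(mean = 17.3, ci95 = 2.0),
                              list(mean = 30.6, ci95 = 2.4))
  expect_false(bad$converged)
  ## touching endpoints count as overlap (closed intervals)
  touch <- ci_overlap_converged(list(mean = 1.5, ci95 = 0.5),
                                list(mean = 2.5, ci95 = 0.5))
  expect_true(touch$converged)
  ## vector form: converged only when every target overlaps
  mix <- ci_overlap_converged(list(mean = c(31.2, 17.3), ci95 = c(1.4, 2)),
                              list(mean = c(30.6, 30.6), ci95 = c(2.4, 2.4)))
  expect_false(mix$converged)
  expect_identical(mix$overlap, c(TRUE, FALSE))
})

test_that("optimizer presets carry the published per-cycle caps", {
  expect_equal(optimizer_config("C36-c")$cap_per_cycle, 0.005)
  expect_equal(optimizer_config("C36-p")$cap_per_cycle, 0.02)
})

test_that("a zero cap leaves the charges untouched", {
  h <- toy_recovery_harness(seed = 4, n_steps_target = 40000,
                            n_steps_cycle = 20000)
  ens <- h$sampler(h$q_start, 11)
  cfg <- optimizer_config(cap_per_cycle = 0, seed = 4)
  rep <- optimization_cycle(ens, h$targets, h$q_start, cfg)
  expect_identical(rep$charges_after$charges, h$q_start$charges)
})

test_that("one cycle respects cap, neutrality, equivalence and frozen mask", {
  h <- toy_recovery_harness(seed = 5, n_steps_target = 120000,
                            n_steps_cycle = 120000)
  ens <- h$sampler(h$q_start, 21)
  for (cap in c(0.005, 0.02)) {
    cfg <- optimizer_config(cap_per_cycle = cap, seed = 5)
    rep <- optimization_cycle(ens, h$targets, h$q_start, cfg)
    after <- rep$charges_after
    dq <- delta_charges(h$q_start, after)
    expect_lte(max(abs(dq)), cap + 1e-12)
    expect_equal(sum(after$charges), 0, tolerance = 1e-9)
    expect_equal(diff(after$charges[1:2]), 0)   # equivalence group intact
    expect_true(all(dq[after$frozen] == 0))
    ## the cycle moves downhill on the data term from a mismatched start
    expect_gt(max(abs(dq)), 0)
  }
})

test_that("single C36-c cycle bounds every charge change by 0.005 e", {
  h <- toy_recovery_harness(seed = 6, n_steps_target = 40000,
                            n_steps_cycle = 40000)
  ens <- h$sampler(h$q_start, 31)
  cfg <- optimizer_config(preset = "C36-c", seed = 6)
  rep <- optimization_cycle(ens, h$targets, h$q_start, cfg)
  expect_lte(max(abs(delta_charges(rep$charges_before,
                                   rep$charges_after))), 0.005 + 1e-12)
})

test_that("an already-convergent start performs zero cycles", {
  h <- toy_recovery_harness(seed = 7, n_steps_target = 40000,
                            n_steps_cycle = 20000)
  wide <- lapply(h$targets, function(t) {
    t$ci95 <- 100   # experimental bands so wide anything overlaps
    t
  })
  cfg <- optimizer_config(cap_per_cycle = 0.02, max_cycles = 5, seed = 7)
  res <- run_optimization(h$sampler, wide, h$q_start, cfg)
  expect_true(res$converged)
  expect_equal(res$n_cycles, 0)
  expect_identical(res$charges$charges, h$q_start$charges)
})

test_that("overwhelming regularization pins the charges at the reference", {
  h <- toy_recovery_harness(seed = 8, n_steps_target = 40000,
                            n_steps_cycle = 40000)
  ens <- h$sampler(h$q_start, 41)
  ## reference distinct from the start, reachable within the cap
  q_ref <- h$q_start
  q_ref$charges <- q_ref$charges + c(rep(0.01, 6), rep(-0.01, 6), rep(0, 12))
  cfg <- optimizer_config(cap_per_cycle = 0.05, seed = 8,
                          regularization_weight = 1e8, max_inner = 60)
  rep <- optimization_cycle(ens, h$targets, h$q_start, cfg, q_ref = q_ref)
  expect_equal(rep$charges_after$charges, q_ref$charges, tolerance = 1e-3)
})

test_that("toy recovery: objective decreases and the protocol converges", {
  h <- toy_recovery_harness(seed = 9)
  cfg <- optimizer_config(cap_per_cycle = 0.02, max_cycles = 10, seed = 9)
  res <- run_optimization(h$sampler, h$targets, h$q_start, cfg)
  expect_true(res$converged)
  expect_lte(res$n_cycles, 10)
  ## every emitted report satisfies the structural constraints
  for (rep in res$reports) {
    expect_lte(max(abs(delta_charges(rep$charges_before,
                                     rep$charges_after))), 0.02 + 1e-12)
    expect_equal(sum(rep$charges_after$charges), 0, tolerance = 1e-9)
  }
  ## final free charges moved toward the hidden truth
  d0 <- abs(free_parameters(h$q_start)[1] - h$theta_truth[1])
  d1 <- abs(free_parameters(res$charges)[1] - h$theta_truth[1])
  expect_lt(d1, d0)
})

test_that("with exact targets and a generous cap the truth is recovered", {
  ## average recovered parameter over seeds lands within 0.01 e of truth
  ths <- vapply(1:4, function(s) {
    h <- toy_recovery_harness(seed = 100 + s)
    cfg <- optimizer_config(cap_per_cycle = 0.05, max_cycles = 6,
                            seed = 100 + s)
    q <- h$q_start
    for (cyc in 1:3) {
      ens <- h$sampler(q, recharge:::split_seed(100 + s, cyc))
      rep <- optimization_cycle(ens, h$targets, q, cfg, cycle_index = cyc)
      q <- rep$charges_after
    }
    free_parameters(q)[1]
  }, numeric(1))
  expect_lt(abs(mean(ths) - 0.2), 0.01)
})

test_that("target tables round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(system = c("TOG", "DOG"), property = c("IT", "IT"),
                   exp_mean = c(30.6, 17.2), ci95 = c(2.4, 1.4),
                   scale = c(0.040, 0.040),
                   obs_key = c("tension", "tension"))
  write.csv(df, f, row.names = FALSE)
  tg <- read_targets(f)
  expect_length(tg, 2)
  expect_equal(tg[[2]]$ci95, 1.4)
  expect_equal(tg[[1]]$scale, 0.040)
})

test_that("the 8% relative-uncertainty rule fills the CI column", {
  expect_equal(relative_ci95(17.2), 1.376)
  expect_equal(round(relative_ci95(17.2), 1), 1.4)
})
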