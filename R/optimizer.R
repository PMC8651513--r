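## Iterative regularized charge refinement: weighted least-squares mismatch
## against experimental targets, gradients by thermodynamic reweighting,
## hard per-cycle caps, equivalence/neutrality projection, and
## confidence-interval-overlap stopping.

#' Define one experimental training target
#'
#' Mirrors one row of a training-target table: a system, the property
#' (interfacial tension, surface tension, or density), its experimental mean
#' and 95% confidence half-width, a dimensionless scaling factor that brings
#' all targets to a similar order of magnitude, and the ensemble observable
#' that realizes the property in simulation.
#'
#' @param system System name (e.g. `"TOG"`, `"DOG"`).
#' @param property One of `"IT"`, `"ST"`, `"density"`.
#' @param exp_mean Experimental mean (mN/m or g/cm^3).
#' @param ci95 Experimental 95% CI half-width, same units; must be positive.
#' @param scale Dimensionless scaling factor (> 0).
#' @param obs_key Ensemble observable realizing the property.
#' @return A `target_spec`.
#' @export
target_spec <- function(system, property = c("IT", "ST", "density"),
                        exp_mean, ci95, scale = 1, obs_key) {
  property <- match.arg(property)
  stopifnot(ci95 > 0, scale > 0)
  structure(list(system = system, property = property,
                 exp_mean = exp_mean, ci95 = ci95, scale = scale,
                 obs_key = obs_key),
            class = "target_spec")
}

#' Estimate a 95% CI half-width as a relative uncertainty
#'
#' The uncertainty-assignment rule used for targets lacking replicated
#' experimental measurements: the half-width is a fixed fraction of the mean
#' (8% by default, matching the rule used to fill the training table).
#'
#' @param exp_mean Experimental mean.
#' @param rel Relative uncertainty (default 0.08).
#' @return CI half-width in the units of `exp_mean`.
#' @export
relative_ci95 <- function(exp_mean, rel = 0.08) {
  stopifnot(exp_mean > 0, rel > 0)
  rel * exp_mean
}

#' Read a training-target table
#'
#' CSV (columns system, property, exp_mean, ci95, scale, obs_key) or a
#' TOML/JSON file with a `targets` array of tables.
#'
#' @param path File path.
#' @return List of [target_spec()] objects.
#' @export
read_targets <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  } else {
    cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
           else parse_toml_subset(readLines(path, warn = FALSE))
    cfg$targets
  }
  lapply(rows, function(r) {
    target_spec(r$system, r$property, as.numeric(r$exp_mean),
                as.numeric(r$ci95), as.numeric(r$scale), r$obs_key)
  })
}

#' Optimizer configuration
#'
#' Presets encode the two published protocols: `"C36-c"` caps any per-cycle
#' partial-charge change at 0.005 e; `"C36-p"` at 0.02 e.
#'
#' @param preset `"C36-c"`, `"C36-p"` or `"custom"`.
#' @param cap_per_cycle Hard per-atom cap on |q - q(cycle start)| in e
#'   (overrides the preset when given).
#' @param regularization_weight Quadratic penalty strength lambda per free
#'   charge.
#' @param max_cycles Maximum outer (resampling) cycles.
#' @param ess_floor Minimum effective-sample-size fraction before inner
#'   steps stop trusting reweighting.
#' @param max_inner Maximum inner gradient steps per cycle.
#' @param step_init Initial inner step: the largest per-charge move along
#'   the negative gradient (e); adapted by the backtracking line search.
#' @param n_blocks,n_boot Block-bootstrap settings for model CIs.
#' @param seed Integer master seed; all stochastic pieces derive from it.
#' @return An `optimizer_config`.
#' @export
optimizer_config <- function(preset = c("custom", "C36-c", "C36-p"),
                             cap_per_cycle = NULL,
                             regularization_weight = 0,
                             max_cycles = 10, ess_floor = 0.2,
                             max_inner = 40, step_init = 0.01,
                             n_blocks = 20, n_boot = 400, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(cap_per_cycle)) {
    cap_per_cycle <- switch(preset, "C36-c" = 0.005, "C36-p" = 0.02,
                            "custom" = 0.02)
  }
  stopifnot(cap_per_cycle >= 0, regularization_weight >= 0, max_cycles >= 0)
  structure(list(preset = preset, cap_per_cycle = cap_per_cycle,
                 regularization_weight = regularization_weight,
                 max_cycles = max_cycles, ess_floor = ess_floor,
                 max_inner = max_inner, step_init = step_init,
                 n_blocks = n_blocks, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Weighted least-squares objective with charge regularization
#'
#' \deqn{F = \sum_t ( s_t (m_t - E_t) / c_t )^2 +
#'   \lambda \sum_k (q_k - q^{ref}_k)^2,}
#' where the second sum runs over the free charges. Target weights are thus
#' inversely proportional to the experimental uncertainties, with the scale
#' factors equalizing the orders of magnitude of heterogeneous properties.
#'
#' @param targets List of [target_spec()].
#' @param model_means Named (or ordered) numeric vector, one model mean per
#'   target.
#' @param q,q_ref `charge_set`s (current and regularization reference).
#' @param lambda Regularization weight.
#' @return Scalar objective value.
#' @export
objective <- function(targets, model_means, q, q_ref,
                      lambda = 0) {
  if (length(model_means) != length(targets)) {
    stop("validation error: need one model mean per target")
  }
  if (any(!is.finite(model_means))) {
    stop("validation error: missing model mean")
  }
  data_term <- sum(vapply(seq_along(targets), function(i) {
    t <- targets[[i]]
    (t$scale * (model_means[i] - t$exp_mean) / t$ci95)^2
  }, numeric(1)))
  reg <- 0
  if (lambda > 0) {
    free <- !q$frozen
    reg <- lambda * sum((q$charges[free] - q_ref$charges[free])^2)
  }
  data_term + reg
}

#' Confidence-interval overlap convergence test
#'
#' Target t is satisfied when the closed model interval `[m - c, m + c]`
#' intersects the closed experimental interval `[M - C, M + C]`; the
#' protocol has converged when every target overlaps.
#'
#' @param model Data frame or list with per-target `mean` and `ci95`.
#' @param experimental Same shape, experimental values.
#' @return List `(converged, overlap)` where `overlap` is a per-target
#'   logical vector.
#' @export
ci_overlap_converged <- function(model, experimental) {
  m <- as.numeric(model$mean); c_ <- as.numeric(model$ci95)
  M <- as.numeric(experimental$mean); C_ <- as.numeric(experimental$ci95)
  stopifnot(length(m) == length(M), all(c_ > 0), all(C_ > 0))
  overlap <- (m - c_) <= (M + C_) & (M - C_) <= (m + c_)
  list(converged = all(overlap), overlap = overlap)
}

## model means/CIs for every target from its system's ensemble under theta
model_estimates <- function(ensembles, targets, thetas, cfg, seed) {
  out <- data.frame(mean = numeric(length(targets)),
                    ci95 = numeric(length(targets)),
                    ess = numeric(length(targets)))
  for (i in seq_along(targets)) {
    t <- targets[[i]]
    ens <- ensembles[[t$system]]
    if (is.null(ens)) stop("no ensemble for system ", t$system)
    w <- reweight(ens, thetas[[t$system]])
    est <- reweighted_mean_ci(ens, t$obs_key, w, n_blocks = cfg$n_blocks,
                              n_boot = cfg$n_boot, ess_floor = 0,
                              seed = split_seed(seed, i))
    out$mean[i] <- est$mean
    out$ci95[i] <- max(est$ci95, .Machine$double.eps)
    out$ess[i] <- w$ess
  }
  out
}

## objective and its gradient w.r.t. the free group parameters, by
## reweighting each system ensemble to the trial point
objective_and_gradient <- function(ensembles, targets, q, q_ref, cfg) {
  theta <- free_parameters(q)
  mult <- attr(theta, "multiplicity")
  lambda <- cfg$regularization_weight
  means <- numeric(length(targets))
  grad <- numeric(length(theta))
  min_ess_frac <- Inf
  weights_cache <- list()
  for (i in seq_along(targets)) {
    t <- targets[[i]]
    ens <- ensembles[[t$system]]
    key <- t$system
    if (is.null(weights_cache[[key]])) {
      weights_cache[[key]] <- reweight(ens, as.numeric(theta))
    }
    w <- weights_cache[[key]]
    min_ess_frac <- min(min_ess_frac, w$ess / ens$n_frames)
    means[i] <- sum(w$weights * ens$observables[[t$obs_key]])
    dmean <- observable_gradient(ens, t$obs_key, as.numeric(theta), w = w)
    resid <- t$scale^2 * (means[i] - t$exp_mean) / t$ci95^2
    grad <- grad + 2 * resid * dmean
  }
  if (lambda > 0) {
    grad <- grad + 2 * lambda * mult *
      (as.numeric(theta) - free_parameters(q_ref))
  }
  fval <- objective(targets, means, q, q_ref, lambda)
  list(value = fval, gradient = grad, means = means,
       min_ess_frac = min_ess_frac)
}

#' One refinement cycle on fixed ensembles
#'
#' Projected gradient descent with backtracking line search on the
#' regularized objective, using reweighted estimates from the supplied
#' (fixed) ensembles. After every accepted step the charges are projected
#' onto the equivalence groups, net-charge conservation, and the per-cycle
#' box cap. Inner iteration stops when the effective sample size of any
#' ensemble at the trial point falls below the floor, or when the step
#' converges.
#'
#' @param ensembles Named list of [ensemble()]s, one per target system,
#'   sampled at `q_current`.
#' @param targets List of [target_spec()].
#' @param q_current `charge_set` at cycle start.
#' @param cfg An [optimizer_config()].
#' @param q_ref Regularization reference (default: the set's own reference
#'   charges).
#' @param cycle_index Bookkeeping index stored in the report.
#' @return A `cycle_report`: charges before/after, per-target model mean,
#'   CI, residual and overlap flag, objective value, and per-system ESS.
#' @export
optimization_cycle <- function(ensembles, targets, q_current, cfg,
                               q_ref = NULL, cycle_index = 1L) {
  stopifnot(inherits(cfg, "optimizer_config"))
  if (is.null(q_ref)) {
    q_ref <- q_current
    q_ref$charges <- q_current$reference_charges
  }
  anchor <- q_current$charges
  cap <- cfg$cap_per_cycle
  q <- q_current

  if (cap > 0) {
    step <- cfg$step_init
    cur <- objective_and_gradient(ensembles, targets, q, q_ref, cfg)
    for (it in seq_len(cfg$max_inner)) {
      g <- cur$gradient
      if (any(!is.finite(g))) {
        stop("gradient non-finite at inner step ", it, "; aborting cycle")
      }
      gmax <- max(abs(g))
      if (gmax < 1e-12) break
      improved <- FALSE
      for (bt in 1:12) {
        ## step is the largest per-charge move (e) along -gradient
        trial_theta <- free_parameters(q) - (step / gmax) * g
        q_try <- set_free_parameters(q, trial_theta, validate = FALSE)
        q_try <- project_constraints(q_try, cap = cap, anchor = anchor)
        nxt <- try(objective_and_gradient(ensembles, targets, q_try, q_ref,
                                          cfg), silent = TRUE)
        if (!inherits(nxt, "try-error") && is.finite(nxt$value) &&
            nxt$value < cur$value - 1e-14) {
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
      moved <- sqrt(sum((free_parameters(q_try) - free_parameters(q))^2))
      q <- q_try
      cur <- nxt
      ## reweighting-validity guard: never walk past the ESS floor
      if (nxt$min_ess_frac < cfg$ess_floor) break
      if (moved < 1e-10) break   # projection pinned against the cap
      step <- step * 1.5
    }
  }

  master <- split_seed(cfg$seed, 7919L + cycle_index)
  thetas <- stats::setNames(
    rep(list(as.numeric(free_parameters(q))), length(ensembles)),
    names(ensembles))
  est <- model_estimates(ensembles, targets, thetas, cfg, master)
  exp_tab <- data.frame(
    mean = vapply(targets, `[[`, numeric(1), "exp_mean"),
    ci95 = vapply(targets, `[[`, numeric(1), "ci95"))
  ov <- ci_overlap_converged(est, exp_tab)
  lambda <- cfg$regularization_weight
  rep <- structure(list(
    cycle_index = cycle_index,
    charges_before = q_current, charges_after = q,
    targets = data.frame(
      system = vapply(targets, `[[`, character(1), "system"),
      property = vapply(targets, `[[`, character(1), "property"),
      model_mean = est$mean, model_ci95 = est$ci95,
      exp_mean = exp_tab$mean, exp_ci95 = exp_tab$ci95,
      residual = est$mean - exp_tab$mean,
      overlap = ov$overlap),
    objective = objective(targets, est$mean, q, q_ref, lambda),
    converged = ov$converged,
    ess = est$ess), class = "cycle_report")
  validate_cycle_report(rep, cap)
  rep
}

## every emitted charge set must satisfy cap, neutrality, equivalence, frozen
validate_cycle_report <- function(rep, cap) {
  before <- rep$charges_before; after <- rep$charges_after
  validate_charge_set(after)
  dq <- abs(after$charges - before$charges)
  if (any(dq[!after$frozen] > cap + 1e-9)) {
    stop("cycle_report: per-cycle cap violated (max |dq| = ",
         format(max(dq)), " e, cap ", cap, " e)")
  }
  if (any(dq[after$frozen] > 0)) {
    stop("cycle_report: frozen atoms were moved")
  }
  invisible(rep)
}

#' @export
print.cycle_report <- function(x, ...) {
  cat(sprintf("<cycle_report> cycle %d, objective %.6g, %s\n",
              x$cycle_index, x$objective,
              if (x$converged) "converged" else "not converged"))
  print(x$targets, digits = 4)
  invisible(x)
}

#' Run the full sample-and-refine protocol
#'
#' Alternates fresh sampling (via the supplied sampler contract) with
#' [optimization_cycle()] until the confidence intervals of all targets
#' overlap the experimental ones, or `max_cycles` is exhausted. If the
#' initial charges are already convergent, zero cycles are performed.
#'
#' @param sampler Function `(charge_set, cycle_seed) -> named list of
#'   ensembles` (one per target system) sampled at those charges.
#' @param targets List of [target_spec()].
#' @param q_init Starting `charge_set`.
#' @param cfg An [optimizer_config()].
#' @param q_ref Regularization reference (default: `q_init`'s reference
#'   charges).
#' @return List `(charges, reports, converged, n_cycles)`.
#' @export
run_optimization <- function(sampler, targets, q_init, cfg, q_ref = NULL) {
  q <- q_init
  reports <- list()
  converged <- FALSE
  exp_tab <- data.frame(
    mean = vapply(targets, `[[`, numeric(1), "exp_mean"),
    ci95 = vapply(targets, `[[`, numeric(1), "ci95"))
  for (cycle in seq_len(cfg$max_cycles + 1L)) {
    ensembles <- sampler(q, split_seed(cfg$seed, cycle))
    thetas <- stats::setNames(
      rep(list(as.numeric(free_parameters(q))), length(ensembles)),
      names(ensembles))
    est <- model_estimates(ensembles, targets, thetas, cfg,
                           split_seed(cfg$seed, 104729L + cycle))
    ov <- ci_overlap_converged(est, exp_tab)
    if (ov$converged) {
      converged <- TRUE
      break
    }
    if (cycle > cfg$max_cycles) break
    rep <- optimization_cycle(ensembles, targets, q, cfg, q_ref = q_ref,
                              cycle_index = cycle)
    reports[[length(reports) + 1L]] <- rep
    q <- rep$charges_after
  }
  list(charges = q, reports = reports, converged = converged,
       n_cycles = length(reports))
}
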