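## Ensemble container and thermodynamic reweighting: importance weights
## w_i ∝ exp(-beta ΔU_i) on a fixed sampled ensemble, weighted means with
## block-bootstrap confidence intervals, and charge-gradients of observables
## via the covariance (fluctuation) formula.

#' Construct an ensemble of sampled frames
#'
#' An `ensemble` bundles per-frame observables with an energy-model contract:
#' `u_fun(theta)` returns the per-frame potential energy (kJ/mol) at free
#' charge parameters `theta`, and `dudq_fun(theta)` the per-frame derivative
#' matrix (kJ/mol/e, frames x parameters). Only energies and their charge
#' derivatives are required: charges are the sole varied parameters.
#'
#' @param beta Inverse temperature 1/(kB T) in mol/kJ.
#' @param theta Named numeric vector of free charge parameters at which the
#'   frames were sampled.
#' @param observables Named list of per-frame numeric series.
#' @param u_fun,dudq_fun Energy model (see Details).
#' @param base_energy Per-frame energies at `theta`; checked against
#'   `u_fun(theta)` to 1e-8 kJ/mol.
#' @param base_charges Optional [charge_set()] the parameters map onto.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(beta, theta, observables, u_fun, dudq_fun,
                     base_energy, base_charges = NULL) {
  n <- length(base_energy)
  if (n < 2) stop("ensemble: need at least 2 frames")
  lens <- vapply(observables, length, integer(1))
  if (any(lens != n)) {
    stop("ensemble: observable series with wrong length: ",
         paste(names(observables)[lens != n], collapse = ", "))
  }
  u0 <- u_fun(theta)
  if (max(abs(u0 - base_energy)) > 1e-8) {
    stop("ensemble: u_fun(theta) does not reproduce base energies ",
         "(max deviation ", format(max(abs(u0 - base_energy))), " kJ/mol)")
  }
  structure(list(n_frames = n, beta = beta, theta = theta,
                 observables = observables, u_fun = u_fun,
                 dudq_fun = dudq_fun, base_energy = base_energy,
                 base_charges = base_charges),
            class = "ensemble")
}

## Ensemble whose energy is quadratic in theta:
## U_f(theta) = c0_f + B_f . theta + theta' M_f theta  (M symmetric).
ensemble_quadratic <- function(beta, theta, c0, B, M, base_energy,
                               observables, base_charges = NULL) {
  B <- as.matrix(B)
  M <- as.matrix(M)
  ng <- length(theta)
  u_fun <- function(th) {
    th <- as.numeric(th)
    if (ng == 0) return(c0)
    quad <- if (ng == 1) M[, 1] * th^2
            else as.numeric(M %*% as.numeric(outer(th, th)))
    c0 + as.numeric(B %*% th) + quad
  }
  dudq_fun <- function(th) {
    th <- as.numeric(th)
    if (ng == 0) return(matrix(0, length(c0), 0))
    g <- B
    for (k in seq_len(ng)) {
      Mk <- M[, (k - 1) * ng + seq_len(ng), drop = FALSE]
      g[, k] <- g[, k] + 2 * as.numeric(Mk %*% th)
    }
    colnames(g) <- names(theta)
    g
  }
  ensemble(beta, theta, observables, u_fun, dudq_fun, base_energy,
           base_charges)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames, %d free parameters, %d observables\n",
              x$n_frames, length(x$theta), length(x$observables)))
  invisible(x)
}

## Accept either a free-parameter vector or a charge_set; validate that a
## charge_set only moves free atoms relative to the ensemble's base set.
resolve_theta <- function(ens, q_new) {
  if (inherits(q_new, "charge_set")) {
    if (!is.null(ens$base_charges)) {
      base <- ens$base_charges
      if (!identical(q_new$atom_names, base$atom_names)) {
        stop("validation error: atom names differ from the ensemble's base")
      }
      moved <- which(q_new$charges != base$charges & base$frozen)
      if (length(moved)) {
        stop("validation error: perturbation touches frozen atoms: ",
             paste(base$atom_names[moved], collapse = ", "))
      }
    }
    theta <- free_parameters(q_new)
    if (length(theta) != length(ens$theta)) {
      stop("validation error: free-parameter count differs from ensemble")
    }
    as.numeric(theta)
  } else {
    if (length(q_new) != length(ens$theta)) {
      stop("validation error: expected ", length(ens$theta), " parameters")
    }
    as.numeric(q_new)
  }
}

#' Importance weights for a charge perturbation
#'
#' Computes per-frame log-weights `-beta * (U(x_i; q_new) - U(x_i; q_base))`,
#' normalized with the log-sum-exp guard, together with the Kish effective
#' sample size `ESS = 1 / sum(w_i^2)`.
#'
#' @param ens An [ensemble()].
#' @param q_new New free-parameter vector or `charge_set` differing from the
#'   base only on free atoms.
#' @return A `weight_vector`: `weights` (sum to 1), `log_unnormalized`,
#'   `ess`.
#' @export
reweight <- function(ens, q_new) {
  theta <- resolve_theta(ens, q_new)
  u_new <- ens$u_fun(theta)
  if (any(!is.finite(u_new))) {
    stop("non-finite energy at frame ", which(!is.finite(u_new))[1])
  }
  logw <- -ens$beta * (u_new - ens$base_energy)
  m <- max(logw)
  w <- exp(logw - m)
  w <- w / sum(w)
  structure(list(weights = w, log_unnormalized = logw, ess = 1 / sum(w^2)),
            class = "weight_vector")
}

#' Uniform weights for an ensemble
#'
#' @param ens An [ensemble()] (or a frame count).
#' @return A `weight_vector` with `ess = n`.
#' @export
uniform_weights <- function(ens) {
  n <- if (inherits(ens, "ensemble")) ens$n_frames else as.integer(ens)
  structure(list(weights = rep(1 / n, n), log_unnormalized = rep(0, n),
                 ess = n),
            class = "weight_vector")
}

#' Weighted mean and block-bootstrap confidence interval
#'
#' The point estimate is the importance-weighted mean. The confidence
#' interval comes from a moving-block bootstrap over frames (contiguous
#' blocks resampled with replacement, weights renormalized per resample),
#' which respects the autocorrelation of the underlying dynamics. Refuses
#' to extrapolate when the effective sample size falls below the floor.
#'
#' @param ens An [ensemble()].
#' @param obs_key Observable name.
#' @param w A `weight_vector` (default uniform).
#' @param n_blocks Number of contiguous blocks (default 20).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level.
#' @param ess_floor Minimum ESS as a fraction of the frame count; below it a
#'   condition of class `recharge_resample_required` is raised, signalling
#'   that fresh sampling, not extrapolation, is needed.
#' @param seed Integer seed for the bootstrap.
#' @return List `(mean, ci95, ess)`.
#' @export
reweighted_mean_ci <- function(ens, obs_key, w = uniform_weights(ens),
                               n_blocks = 20, n_boot = 1000, conf = 0.95,
                               ess_floor = 0.2, seed = 1L) {
  if (!obs_key %in% names(ens$observables)) {
    stop("validation error: unknown observable '", obs_key, "'")
  }
  o <- ens$observables[[obs_key]]
  n <- ens$n_frames
  if (w$ess < ess_floor * n) {
    stop(structure(class = c("recharge_resample_required", "error",
                             "condition"),
                   list(message = sprintf(
                     "resample required: ESS %.1f below floor %.1f (%d frames)",
                     w$ess, ess_floor * n, n), call = sys.call())))
  }
  mean_hat <- sum(w$weights * o)
  n_blocks <- max(2L, min(as.integer(n_blocks), n))
  block_len <- floor(n / n_blocks)
  usable <- block_len * n_blocks
  starts0 <- seq(1L, usable, by = block_len)
  rng <- local_rng(seed)
  reps <- numeric(n_boot)
  wo <- w$weights * o
  ## block sums of weights and weighted observables: resampling blocks is
  ## then a draw of block indices
  bw <- vapply(starts0, function(s) sum(w$weights[s:(s + block_len - 1)]),
               numeric(1))
  bwo <- vapply(starts0, function(s) sum(wo[s:(s + block_len - 1)]),
                numeric(1))
  for (r in seq_len(n_boot)) {
    pick <- sample_int(rng, n_blocks, n_blocks)
    sw <- sum(bw[pick])
    reps[r] <- if (sw > 0) sum(bwo[pick]) / sw else NA_real_
  }
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(mean = mean_hat, ci95 = (qs[2] - qs[1]) / 2, ess = w$ess)
}

#' Charge-gradient of a reweighted observable mean
#'
#' Uses the exact fluctuation formula for importance-weighted averages,
#' `d<O>/dq_k = -beta * ( <O * dU/dq_k>_w - <O>_w <dU/dq_k>_w )`,
#' with averages taken under the weight vector for the evaluation point.
#' Derivatives of atoms sharing an equivalence group are carried by the
#' group's single free parameter.
#'
#' @param ens An [ensemble()].
#' @param obs_key Observable name.
#' @param q Evaluation point (free-parameter vector or `charge_set`);
#'   defaults to the base parameters.
#' @param w Optional precomputed `weight_vector` for `q`.
#' @return Named numeric vector, one derivative per free parameter.
#' @export
observable_gradient <- function(ens, obs_key, q = ens$theta, w = NULL) {
  if (!obs_key %in% names(ens$observables)) {
    stop("validation error: unknown observable '", obs_key, "'")
  }
  if (is.null(ens$dudq_fun)) {
    stop("contract error: ensemble exposes no dU/dq channel")
  }
  theta <- resolve_theta(ens, q)
  if (is.null(w)) w <- reweight(ens, theta)
  o <- ens$observables[[obs_key]]
  d <- ens$dudq_fun(theta)
  mo <- sum(w$weights * o)
  md <- as.numeric(crossprod(w$weights, d))
  mod <- as.numeric(crossprod(w$weights, o * d))
  g <- -ens$beta * (mod - mo * md)
  names(g) <- names(ens$theta)
  g
}

## -- small deterministic RNG helpers ---------------------------------------
## A splittable xorshift-style generator independent of R's global RNG, so
## library internals never disturb user-level set.seed() state.
local_rng <- function(seed) {
  state <- as.double((as.integer(seed) %% 2147483647L))
  if (state <= 0) state <- state + 2147483646
  env <- new.env(parent = emptyenv())
  env$state <- state
  env
}

## Lehmer / Park-Miller minimal standard generator on doubles.
rng_next <- function(rng) {
  rng$state <- (rng$state * 48271) %% 2147483647
  rng$state / 2147483647
}

sample_int <- function(rng, n, size) {
  vapply(seq_len(size), function(i) {
    as.integer(floor(rng_next(rng) * n)) + 1L
  }, integer(1))
}

## derive a child seed from a parent seed and a stream index (kept < 2^31)
split_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 69069 + as.double(stream) * 40503 + 1) %%
               2147483647)
}
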