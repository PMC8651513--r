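# shared fixtures, built in code at test time

# minimal 3-atom topology; charges default to a neutral (0.4, -0.8, 0.4)
write_tiny_itp <- function(path, charges = c(0.4, -0.8, 0.4),
                           names = c("C1", "O1", "C2")) {
  lines <- c(
    "; minimal test topology",
    "[ moleculetype ]",
    "; name  nrexcl",
    "TST     3",
    "",
    "[ atoms ]",
    ";  nr  type  resnr residue atom cgnr   charge     mass",
    sprintf("   %d   CTL2     1    TST   %s    %d   %10.6f   12.0110  ; arm",
            seq_along(charges), names, seq_along(charges), charges),
    "",
    "[ bonds ]",
    "  1  2  1",
    "  2  3  1")
  writeLines(lines, path)
  path
}

write_sidecar_toml <- function(path) {
  writeLines(c(
    "# charge structure sidecar",
    "net_charge = 0",
    'equivalence_groups = [ [ "C1", "C2" ] ]',
    'frozen = [ "O1" ]'), path)
  path
}

# hand-built two-frame ensemble with linear energy model U = e0 + theta * d
two_frame_ensemble <- function(beta = 1, e0 = c(0, 0), d = c(0, 0),
                               obs = list(o = c(0, 3)), theta = 0) {
  ensemble(beta = beta, theta = c(g1 = theta), observables = obs,
           u_fun = function(th) e0 + as.numeric(th) * d,
           dudq_fun = function(th) matrix(d, ncol = 1,
                                          dimnames = list(NULL, "g1")),
           base_energy = e0 + theta * d)
}

# symmetric double well (kcal/mol): minima at +/- z0 with V = 0, barrier at 0
double_well <- function(barrier = 3.5, z0 = 1.5) {
  function(z) barrier * ((z / z0)^2 - 1)^2
}

# default small charged LJ fluid for estimator tests
small_charged_system <- function(n = 16, box = 2.5, q = 0.3) {
  toy_system(lattice_positions(n, rep(box, 3)), rep(box, 3),
             charge = rep(c(q, -q), length.out = n),
             charge_map = rep(c(1L, 2L), length.out = n))
}

# independent R-side energy/virial oracle for one frame of a toy system
r_energy_virial <- function(sys, pos) {
  n <- nrow(pos)
  f <- 138.935458
  u <- 0
  w <- c(0, 0, 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dr <- pos[i, ] - pos[j, ]
      dr <- dr - sys$box * round(dr / sys$box)
      r2 <- sum(dr^2)
      if (r2 > sys$cutoff^2) next
      r <- sqrt(r2)
      sig <- (sys$sigma[i] + sys$sigma[j]) / 2
      eps <- sqrt(sys$epsilon[i] * sys$epsilon[j])
      dudr <- 0
      if (eps > 0) {
        sr6 <- (sig^2 / r2)^3
        u <- u + 4 * eps * (sr6^2 - sr6)
        dudr <- -4 * eps * (12 * sr6^2 - 6 * sr6) / r
      }
      qq <- sys$charge[i] * sys$charge[j]
      u <- u + f * qq / r
      dudr <- dudr - f * qq / r2
      w <- w + (-dudr) * dr^2 / r
    }
  }
  if (sys$external_k > 0) {
    for (i in seq_len(n)) {
      u <- u + 0.5 * sys$external_k * sum((pos[i, ] - sys$box / 2)^2)
    }
  }
  V <- prod(sys$box)
  kbt <- 0.008314462618 * sys$temperature
  list(u = u, p = (n * kbt + w) / V * 16.6054)
}
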