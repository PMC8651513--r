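## Lateral density profiles along the bilayer normal, Boltzmann-inversion
## PMFs, flip-flop barrier extraction, and replica aggregation.

#' Lateral density profile along z
#'
#' Histograms the z-coordinates of the selected atoms into uniform bins
#' (default width 0.07 nm, half-open intervals `[lo, hi)`), averaged over
#' frames and mass-weighted by default. With `center = "phosphate"` each
#' frame is first recentered so that the midpoint between the two phosphate
#' density peaks (one per leaflet) sits at z = 0, removing slab drift.
#'
#' @param frames Frame table: data.frame(frame, resname, atomname, x, y, z,
#'   mass).
#' @param selection List with any of `resname`, `atomname`; atoms matching
#'   all given fields are selected. A bare character string is shorthand for
#'   an atom-name selection.
#' @param bin_width Bin width (nm), default 0.07.
#' @param span z-range of the profile (nm); defaults to the data range
#'   padded by one bin.
#' @param center `"none"` or `"phosphate"`.
#' @param phosphate_atom Atom name defining the leaflet peaks when
#'   recentering.
#' @param weight `"mass"` or `"count"`.
#' @return A `density_profile`: data.frame(z, density) with attributes
#'   `bin_width`, `selection`, `n_frames`. Density is per unit z per frame
#'   (so `sum(density) * bin_width` equals selected mass or count per
#'   frame).
#' @export
lateral_density_profile <- function(frames, selection, bin_width = 0.07,
                                    span = NULL,
                                    center = c("none", "phosphate"),
                                    phosphate_atom = "P",
                                    weight = c("mass", "count")) {
  center <- match.arg(center)
  weight <- match.arg(weight)
  if (is.character(selection)) selection <- list(atomname = selection)
  sel <- rep(TRUE, nrow(frames))
  if (!is.null(selection$resname)) {
    sel <- sel & frames$resname %in% selection$resname
  }
  if (!is.null(selection$atomname)) {
    sel <- sel & frames$atomname %in% selection$atomname
  }
  if (!any(sel)) stop("empty selection")
  ids <- sort(unique(frames$frame))

  z <- frames$z
  if (center == "phosphate") {
    for (f in ids) {
      in_f <- frames$frame == f
      pz <- z[in_f & frames$atomname == phosphate_atom]
      if (length(pz) < 2) stop("phosphate recentering needs P atoms")
      ## midpoint between the two leaflet peaks: split at the median
      mid <- (stats::median(pz[pz >= stats::median(pz)]) +
                stats::median(pz[pz < stats::median(pz)])) / 2
      z[in_f] <- z[in_f] - mid
    }
  }
  zsel <- z[sel]
  wsel <- if (weight == "mass") frames$mass[sel] else rep(1, sum(sel))
  if (is.null(span)) {
    span <- range(zsel) + c(-bin_width, bin_width)
  }
  lo <- span[1]
  nb <- ceiling((span[2] - lo) / bin_width)
  bin <- floor((zsel - lo) / bin_width) + 1
  keep <- bin >= 1 & bin <= nb
  dens <- numeric(nb)
  agg <- tapply(wsel[keep], bin[keep], sum)
  dens[as.integer(names(agg))] <- agg
  dens <- dens / (bin_width * length(ids))
  structure(data.frame(z = lo + (seq_len(nb) - 0.5) * bin_width,
                       density = dens),
            class = c("density_profile", "data.frame"),
            bin_width = bin_width, selection = selection,
            n_frames = length(ids))
}

#' Boltzmann inversion of a density profile
#'
#' `pmf(z) = -kB T ln( rho(z) / rho_max )` in kcal/mol, anchored so the
#' minimum over defined bins is zero. Bins with zero density are undefined
#' and masked as `NA` (not zero).
#'
#' @param p A `density_profile` (or data.frame with `z`, `density`).
#' @param temperature Temperature (K), default 298.15.
#' @return A `pmf_curve`: data.frame(z, pmf) with attributes `bin_width`,
#'   `temperature`, `reference_convention = "min_zero"`.
#' @export
boltzmann_invert <- function(p, temperature = 298.15) {
  rho <- p$density
  if (all(rho <= 0)) stop("all-zero density profile")
  kt <- kT(temperature, "kcal")
  pmf <- rep(NA_real_, length(rho))
  pos <- rho > 0
  pmf[pos] <- -kt * log(rho[pos] / max(rho[pos]))
  pmf[pos] <- pmf[pos] - min(pmf[pos])
  structure(data.frame(z = p$z, pmf = pmf),
            class = c("pmf_curve", "data.frame"),
            bin_width = if (!is.null(attr(p, "bin_width")))
              attr(p, "bin_width") else stats::median(diff(p$z)),
            temperature = temperature,
            reference_convention = "min_zero")
}

#' Flip-flop barrier from a PMF curve
#'
#' Default convention: barrier = pmf at the bilayer midplane (z = 0) minus
#' the PMF minimum within the membrane span. The `"max"` convention uses the
#' PMF maximum within the span instead of the midplane value (the two
#' coincide for well-formed symmetric profiles). Optionally also returns the
#' surface-access cost, pmf at the phosphate peak position minus the
#' minimum.
#'
#' @param p A `pmf_curve`.
#' @param span z-range (nm) searched for the minimum (and maximum), default
#'   the full curve.
#' @param midplane Midplane position (nm), default 0.
#' @param convention `"midplane"` or `"max"`.
#' @param phosphate_z Optional z of the phosphate density peak for the
#'   surface-access cost.
#' @return List `(barrier, z_min, surface_cost)` in kcal/mol.
#' @export
flip_flop_barrier <- function(p, span = range(p$z), midplane = 0,
                              convention = c("midplane", "max"),
                              phosphate_z = NULL) {
  convention <- match.arg(convention)
  in_span <- p$z >= span[1] & p$z <= span[2] & !is.na(p$pmf)
  if (!any(in_span)) stop("PMF undefined everywhere in span")
  vmin <- min(p$pmf[in_span])
  z_min <- p$z[in_span][which.min(p$pmf[in_span])]
  top <- if (convention == "midplane") {
    i <- which.min(abs(p$z - midplane))
    if (is.na(p$pmf[i])) stop("midplane bin is masked (zero density)")
    p$pmf[i]
  } else {
    max(p$pmf[in_span])
  }
  surface <- NA_real_
  if (!is.null(phosphate_z)) {
    j <- which.min(abs(p$z - phosphate_z))
    if (!is.na(p$pmf[j])) surface <- p$pmf[j] - vmin
  }
  list(barrier = top - vmin, z_min = z_min, surface_cost = surface)
}

#' Aggregate replica PMF curves
#'
#' Re-anchors each replica at zero minimum, then takes the bin-wise mean and
#' sample standard deviation. Barrier statistics are propagated as the mean
#' and SD of the per-replica barriers (not the barrier of the mean curve).
#'
#' @param curves List of >= 2 `pmf_curve`s on identical binning.
#' @param span,midplane,convention Passed to [flip_flop_barrier()] for the
#'   per-replica barrier statistics.
#' @return A `pmf_curve` with columns z, pmf (the replica mean),
#'   `replica_mean`, `replica_sd`, and attributes `barrier_mean`,
#'   `barrier_sd`, `n_replicas`.
#' @export
replica_aggregate <- function(curves, span = NULL, midplane = 0,
                              convention = "midplane") {
  stopifnot(length(curves) >= 2)
  z0 <- curves[[1]]$z
  for (cv in curves[-1]) {
    if (length(cv$z) != length(z0) || max(abs(cv$z - z0)) > 1e-9) {
      stop("binning mismatch between replicas")
    }
  }
  if (is.null(span)) span <- range(z0)
  anchored <- lapply(curves, function(cv) {
    cv$pmf <- cv$pmf - min(cv$pmf, na.rm = TRUE)
    cv
  })
  mat <- do.call(cbind, lapply(anchored, `[[`, "pmf"))
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  barriers <- vapply(anchored, function(cv) {
    flip_flop_barrier(cv, span = span, midplane = midplane,
                      convention = convention)$barrier
  }, numeric(1))
  structure(data.frame(z = z0, pmf = m, replica_mean = m, replica_sd = s),
            class = c("pmf_curve", "data.frame"),
            bin_width = attr(curves[[1]], "bin_width"),
            temperature = attr(curves[[1]], "temperature"),
            reference_convention = "min_zero",
            barrier_mean = mean(barriers),
            barrier_sd = stats::sd(barriers),
            n_replicas = length(curves))
}
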