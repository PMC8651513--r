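## Mechanical-route tension from pressure-tensor series, running/blocking
## averages with Student-t confidence intervals, oil-core water content,
## and hydration-based equilibration detection.

#' Pressure-tensor / box-length time series
#'
#' @param time Per-frame time (ns), strictly increasing.
#' @param pxx,pyy,pzz Pressure-tensor diagonals (bar).
#' @param lz Box length along z (nm), positive.
#' @return A `tension_series` (data.frame subclass).
#' @export
tension_series <- function(time, pxx, pyy, pzz, lz) {
  n <- length(time)
  stopifnot(length(pxx) == n, length(pyy) == n, length(pzz) == n,
            length(lz) == n, all(lz > 0))
  if (n >= 2 && any(diff(time) <= 0)) {
    stop("tension_series: time must be strictly increasing")
  }
  structure(data.frame(time = time, pxx = pxx, pyy = pyy, pzz = pzz,
                       lz = lz),
            class = c("tension_series", "data.frame"))
}

#' Read a GROMACS .xvg table
#'
#' Skips `#` and `@` comment lines and parses the whitespace-separated
#' numeric columns.
#'
#' @param path File path.
#' @param col_names Optional column names.
#' @return data.frame of numeric columns.
#' @export
read_xvg <- function(path, col_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("read_xvg: no data rows in ", path)
  df <- utils::read.table(text = lines[keep])
  if (!is.null(col_names)) names(df) <- col_names
  df
}

#' Kirkwood-Irving tension from a pressure-tensor series
#'
#' For a z-normal slab with two interfaces,
#' `gamma_i = (lz_i / 2) * (pzz_i - (pxx_i + pyy_i) / 2)` in bar nm,
#' converted to mN/m with the exact factor 0.1. The 1/2 prefactor accounts
#' for the two interfaces of the periodic slab; the box length is taken
#' per-frame inside the average.
#'
#' @param s A [tension_series()].
#' @param frame_range Optional integer range (indices) to average over.
#' @return List `(gamma, mean)`: the per-frame tension series (mN/m) over
#'   the full input, and its mean over `frame_range`.
#' @export
kirkwood_irving_tension <- function(s, frame_range = NULL) {
  stopifnot(inherits(s, "tension_series"))
  if (is.null(frame_range)) frame_range <- seq_len(nrow(s))
  if (length(frame_range) == 0) stop("empty frame range")
  gamma <- recharge_constants$mNm_per_barnm * (s$lz / 2) *
    (s$pzz - (s$pxx + s$pyy) / 2)
  list(gamma = gamma, mean = mean(gamma[frame_range]))
}

#' Running and blocking averages with a Student-t confidence interval
#'
#' The running average is the cumulative mean of the series. Blocks are
#' consecutive windows of `block_duration` (an incomplete trailing block is
#' dropped); the confidence interval over the block means is
#' `t_{(1+conf)/2, n-1} * s / sqrt(n)`.
#'
#' @param x Numeric series.
#' @param time Per-frame time (ns); defaults to frame index.
#' @param block_duration Block length in the units of `time` (default 100,
#'   i.e. 100 ns blocks).
#' @param conf Confidence level.
#' @return List `(running, block_means, block_time, mean, ci95, n_blocks)`;
#'   `ci95` is `NA` (with a warning condition recorded in `ci_defined`)
#'   when fewer than 2 complete blocks exist.
#' @export
running_and_block_stats <- function(x, time = seq_along(x) - 1,
                                    block_duration = 100, conf = 0.95) {
  stopifnot(length(x) == length(time), block_duration > 0)
  running <- cumsum(x) / seq_along(x)
  t0 <- time[1]
  idx <- floor((time - t0) / block_duration)
  ## drop the incomplete trailing block: block b is complete when the series
  ## reaches its right edge (minus one sampling interval)
  dt <- if (length(time) >= 2) stats::median(diff(time)) else 0
  t_end <- time[length(time)]
  complete_ids <- Filter(function(b) {
    t_end >= t0 + (b + 1) * block_duration - dt - 1e-9
  }, unique(idx))
  complete_ids <- as.numeric(complete_ids)
  block_means <- vapply(complete_ids, function(b) mean(x[idx == b]),
                        numeric(1))
  nb <- length(block_means)
  if (nb >= 2) {
    tcrit <- stats::qt((1 + conf) / 2, df = nb - 1)
    ci <- tcrit * stats::sd(block_means) / sqrt(nb)
    ci_defined <- TRUE
  } else {
    ci <- NA_real_
    ci_defined <- FALSE
  }
  list(running = running, block_means = block_means,
       block_time = t0 + (complete_ids + 0.5) * block_duration,
       mean = mean(block_means), ci95 = ci, n_blocks = nb,
       ci_defined = ci_defined)
}

## mass histogram of a selection along z with periodic wrap
z_mass_profile <- function(z, mass, box_z, bin_width) {
  z <- z %% box_z
  nb <- max(1L, round(box_z / bin_width))
  bw <- box_z / nb
  bin <- pmin(floor(z / bw), nb - 1) + 1
  dens <- numeric(nb)
  agg <- tapply(mass, bin, sum)
  dens[as.integer(names(agg))] <- agg
  list(density = dens / bw, centers = (seq_len(nb) - 0.5) * bw, bw = bw)
}

## contiguous (periodically wrapped) run of bins >= threshold containing the
## peak bin; returns logical mask
core_mask <- function(dens, threshold) {
  nb <- length(dens)
  peak <- which.max(dens)
  ok <- dens >= threshold
  if (!ok[peak]) return(rep(FALSE, nb))
  mask <- rep(FALSE, nb)
  i <- peak
  repeat {
    mask[i] <- TRUE
    j <- if (i == nb) 1L else i + 1L
    if (j == peak || !ok[j] || mask[j]) break
    i <- j
  }
  i <- peak
  repeat {
    j <- if (i == 1L) nb else i - 1L
    if (j == peak || !ok[j] || mask[j]) break
    mask[j] <- TRUE
    i <- j
  }
  mask
}

#' Water content inside the oil core
#'
#' Per frame, builds the oil mass-density profile along z (periodic slab),
#' defines the oil core as the contiguous region where the oil density is at
#' least 50% of its plateau value, counts the water molecules whose oxygen
#' lies inside the core, and reports `1000 * water mass / oil mass` in
#' g water per kg oil. The plateau is the median density of the bins at or
#' above half the peak density (a Gibbs-dividing-surface style boundary).
#'
#' @param frames Frame table: data.frame(frame, resname, atomname, x, y, z,
#'   mass).
#' @param oil_resnames Residue names forming the oil phase.
#' @param water_resname Water residue name.
#' @param box_z Box length along z (nm).
#' @param bin_width Profile bin width (nm), default 0.07.
#' @param core_frac Core threshold as a fraction of the plateau density.
#' @param time Optional per-frame times (ns); defaults to frame index.
#' @param water_molar_mass Mass assigned per detected water oxygen (g/mol).
#' @return A `hydration_series` data.frame: time, water_mass_in_core,
#'   oil_mass, content (g/kg).
#' @export
water_in_oil_content <- function(frames, oil_resnames, water_resname,
                                 box_z, bin_width = 0.07, core_frac = 0.5,
                                 time = NULL,
                                 water_molar_mass =
                                   recharge_constants$water_molar_mass) {
  stopifnot(all(c("frame", "resname", "atomname", "x", "y", "z", "mass")
                %in% names(frames)))
  ids <- sort(unique(frames$frame))
  if (is.null(time)) time <- seq_along(ids) - 1
  rows <- lapply(seq_along(ids), function(k) {
    fr <- frames[frames$frame == ids[k], ]
    oil <- fr[fr$resname %in% oil_resnames, ]
    wat <- fr[fr$resname == water_resname &
                grepl("^O", fr$atomname), ]
    if (nrow(oil) == 0) stop("no oil atoms in frame ", ids[k])
    prof <- z_mass_profile(oil$z, oil$mass, box_z, bin_width)
    plateau_bins <- prof$density >= 0.5 * max(prof$density)
    plateau <- stats::median(prof$density[plateau_bins])
    mask <- core_mask(prof$density, core_frac * plateau)
    if (!any(mask)) stop("no contiguous oil core found (not a slab system)")
    wbin <- pmin(floor((wat$z %% box_z) / prof$bw),
                 length(mask) - 1) + 1
    inside <- if (nrow(wat)) mask[wbin] else logical(0)
    wmass <- sum(inside) * water_molar_mass
    omass <- sum(oil$mass)
    c(wmass, omass)
  })
  mat <- do.call(rbind, rows)
  structure(data.frame(time = time, water_mass_in_core = mat[, 1],
                       oil_mass = mat[, 2],
                       content = 1000 * mat[, 1] / mat[, 2]),
            class = c("hydration_series", "data.frame"))
}

#' Detect equilibration from a hydration (or any) series
#'
#' Slides a window of fixed duration along the series; a window is converged
#' when the magnitude of its fitted linear trend over the window,
#' `|slope| * window`, is below `slope_tol` times the window mean. Returns
#' the earliest converged window start. The region after that time is the
#' one that should feed mean-tension estimation.
#'
#' @param h A `hydration_series`, or a data.frame with `time` and the column
#'   named by `value_col`.
#' @param window Window duration (ns), default 100.
#' @param slope_tol Relative slope tolerance, default 0.05.
#' @param value_col Column to analyze (default `"content"`).
#' @return List `(converged, time)`; `time` is `NA` when never converged.
#' @export
detect_equilibration <- function(h, window = 100, slope_tol = 0.05,
                                 value_col = "content") {
  t <- h$time
  y <- h[[value_col]]
  stopifnot(length(t) == length(y))
  if (max(t) - min(t) < window) {
    stop("series shorter than the detection window")
  }
  starts <- t[t <= max(t) - window + 1e-9]
  for (s in starts) {
    sel <- t >= s & t <= s + window + 1e-9
    if (sum(sel) < 3) next
    fit <- stats::lm.fit(cbind(1, t[sel]), y[sel])
    slope <- fit$coefficients[2]
    m <- mean(y[sel])
    if (abs(slope) * window < slope_tol * abs(m)) {
      return(list(converged = TRUE, time = s))
    }
  }
  list(converged = FALSE, time = NA_real_)
}
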