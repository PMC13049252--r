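#' Golden-angle rotation schedule
#'
#' Cumulative per-frame rotation angles for a single spiral arm rotated by a
#' fixed increment between consecutive inversion times. Frame 1 is unrotated;
#' frame \eqn{i} is rotated by \eqn{(i-1)\times} the increment. The default
#' increment is the golden angle, 137.51 degrees, which gives near-uniform
#' angular coverage of k-space for any number of frames.
#'
#' @param n_frames number of frames (>= 1).
#' @param increment_deg rotation increment between consecutive frames, in
#'   degrees. Default 137.51 (golden angle).
#' @return An object of class \code{ga_schedule} with elements
#'   \code{n_frames}, \code{increment_deg} and \code{angles_deg} (cumulative
#'   angles, frame 1 at 0).
#' @examples
#' sch <- golden_angle_schedule(55)
#' sch$angles_deg[2]            # 137.51
#' fold_angle_deg(sch$angles_deg[55])  # 134.46: seam between frame 55 and 1
#' @export
golden_angle_schedule <- function(n_frames, increment_deg = 137.51) {
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 1 ||
      n_frames != round(n_frames))
    stop("'n_frames' must be a positive integer")
  structure(list(
    n_frames = as.integer(n_frames),
    increment_deg = increment_deg,
    angles_deg = increment_deg * (seq_len(n_frames) - 1)
  ), class = "ga_schedule")
}

#' Fold an angle to its minimal distance from 0 degrees
#'
#' Reduces an angle modulo 360 and returns the minimal angular distance to 0,
#' in [0, 180]. Used to quantify the angular seam between the last and first
#' frame of a periodically padded golden-angle series.
#'
#' @param angle_deg angle(s) in degrees.
#' @return folded angle(s) in [0, 180] degrees.
#' @export
fold_angle_deg <- function(angle_deg) {
  a <- angle_deg %% 360
  pmin(a, 360 - a)
}

#' @export
print.ga_schedule <- function(x, ...) {
  cat(sprintf("Golden-angle schedule: %d frames, increment %.2f deg\n",
              x$n_frames, x$increment_deg))
  cat(sprintf("  frame %d cumulative angle: %.2f deg (folded %.2f deg)\n",
              x$n_frames, x$angles_deg[x$n_frames],
              fold_angle_deg(x$angles_deg[x$n_frames])))
  invisible(x)
}

#' Variable-density spiral sampling profile
#'
#' Radial undersampling profile for the spiral readout: the central
#' \code{full_sample_fraction} of k-space is fully sampled (reduction factor
#' 1), the region beyond \code{outer_fraction} is undersampled by
#' \code{outer_reduction}, and the reduction factor ramps linearly with
#' radius in between (continuous at both knots).
#'
#' @param full_sample_fraction radius fraction below which sampling is at the
#'   Nyquist density. Default 0.15.
#' @param outer_fraction radius fraction above which the reduction factor is
#'   constant at \code{outer_reduction}. Default 0.50.
#' @param outer_reduction undersampling factor in the outer region. Default 5.
#' @return An object of class \code{vd_profile}.
#' @export
vd_profile <- function(full_sample_fraction = 0.15, outer_fraction = 0.50,
                       outer_reduction = 5.0) {
  stopifnot(full_sample_fraction > 0, outer_fraction > full_sample_fraction,
            outer_fraction <= 1, outer_reduction >= 1)
  structure(list(full_sample_fraction = full_sample_fraction,
                 outer_fraction = outer_fraction,
                 outer_reduction = outer_reduction),
            class = "vd_profile")
}

#' Radial reduction factor of a variable-density profile
#'
#' @param r_fraction radius as a fraction of the maximal k-space radius, in
#'   [0, 1]. Vectorized.
#' @param profile a \code{\link{vd_profile}}.
#' @return the local undersampling (reduction) factor at each radius.
#' @examples
#' p <- vd_profile()
#' reduction_factor(c(0.10, 0.325, 0.60), p)  # 1, 3, 5
#' @export
reduction_factor <- function(r_fraction, profile = vd_profile()) {
  if (any(r_fraction < 0 | r_fraction > 1))
    stop("'r_fraction' must lie in [0, 1]")
  f0 <- profile$full_sample_fraction
  f1 <- profile$outer_fraction
  rmax <- profile$outer_reduction
  ramp <- 1 + (r_fraction - f0) / (f1 - f0) * (rmax - 1)
  pmin(pmax(ramp, 1), rmax)
}

#' Design a variable-density center-out spiral arm
#'
#' Constant-angular-velocity Archimedean spiral whose local radial pitch
#' (k-space distance between successive revolutions) equals the profile's
#' reduction factor times the Nyquist pitch \eqn{1/\mathrm{FOV}}. Coordinates
#' are in cycles per field of view, so the Nyquist radius is
#' \eqn{\mathrm{matrix}/2} with \eqn{\mathrm{matrix} = \mathrm{FOV}/\Delta x}.
#' Gradient-hardware slew and amplitude limits are deliberately not modeled:
#' the arm is a sampling geometry, not a gradient waveform.
#'
#' The radius obeys \eqn{dr/d\phi = R(r/k_{max})/(2\pi)} (in cycles/FOV) and
#' is integrated on a fine azimuthal grid, then resampled at \code{n_samples}
#' uniformly spaced azimuthal positions (constant angular velocity). The
#' final sample lands exactly on the Nyquist radius.
#'
#' @param fov_mm field of view in mm (default 180).
#' @param res_mm in-plane resolution in mm (default 1.0).
#' @param n_samples samples along the arm. The default, 4800, corresponds to
#'   a 12 ms readout at a 2.5 us dwell time.
#' @param profile a \code{\link{vd_profile}}.
#' @param readout_ms readout duration in ms (metadata; used by the
#'   off-resonance model). Default 12.
#' @return An object of class \code{spiral_trajectory} with the base arm:
#'   \code{kx}, \code{ky} (cycles/FOV), \code{dcf} (density compensation),
#'   \code{t_ms} (sample times), plus \code{fov_mm}, \code{res_mm},
#'   \code{matrix}, \code{readout_ms}, \code{profile}.
#' @export
design_vd_spiral <- function(fov_mm = 180, res_mm = 1.0, n_samples = 4800,
                             profile = vd_profile(), readout_ms = 12) {
  stopifnot(fov_mm > 0, res_mm > 0, n_samples >= 16)
  matrix_size <- round(fov_mm / res_mm)
  kmax <- matrix_size / 2

  # integrate dr/dphi = R(r/kmax) / (2*pi) on a fine phi grid (RK2)
  n_fine <- 200000L
  r <- numeric(n_fine)
  phi <- numeric(n_fine)
  dphi <- 0.05
  i <- 1L
  while (r[i] < kmax && i < n_fine) {
    k1 <- reduction_factor(min(r[i] / kmax, 1), profile) / (2 * pi)
    rmid <- r[i] + 0.5 * dphi * k1
    k2 <- reduction_factor(min(rmid / kmax, 1), profile) / (2 * pi)
    r[i + 1L] <- r[i] + dphi * k2
    phi[i + 1L] <- phi[i] + dphi
    i <- i + 1L
  }
  if (r[i] < kmax) stop("spiral integration did not reach the Nyquist radius")
  # trim and clamp the endpoint exactly onto kmax
  frac <- (kmax - r[i - 1L]) / (r[i] - r[i - 1L])
  phi_max <- phi[i - 1L] + frac * dphi
  r <- r[seq_len(i)]; phi <- phi[seq_len(i)]
  r[i] <- kmax; phi[i] <- phi_max

  # constant angular velocity: uniform phi samples
  phi_s <- seq(0, phi_max, length.out = n_samples)
  r_s <- stats::approx(phi, r, xout = phi_s, rule = 2)$y
  r_s[n_samples] <- kmax

  # feasibility: consecutive radial spacing must not exceed the local
  # reduction-scaled Nyquist spacing (1 cycle/FOV per revolution)
  dr <- diff(r_s)
  allowed <- reduction_factor(pmin(r_s[-1] / kmax, 1), profile)
  bad <- which(dr > allowed + 1e-9)
  if (length(bad))
    stop(sprintf(
      "sample budget infeasible: radial spacing exceeds the allowed pitch near |k| = %.1f cycles/FOV (radius fraction %.2f)",
      r_s[bad[1]], r_s[bad[1]] / kmax))

  structure(list(
    kx = r_s * cos(phi_s),
    ky = r_s * sin(phi_s),
    r = r_s,
    t_ms = seq(0, readout_ms, length.out = n_samples),
    dcf = .analytic_dcf(r_s, matrix_size),
    fov_mm = fov_mm, res_mm = res_mm, matrix = matrix_size,
    readout_ms = readout_ms, profile = profile
  ), class = "spiral_trajectory")
}

# Analytic annular-area density compensation: w ~ |k| * d|k|/ds with a
# small-radius floor, normalized so sum(w) equals the full Cartesian k-space
# area matrix^2 (a centered point source then reconstructs at its true
# amplitude under the 1/N^2-scaled adjoint).
.analytic_dcf <- function(r, matrix_size) {
  n <- length(r)
  if (all(r == 0)) stop("degenerate trajectory: all samples at k = 0")
  dr <- numeric(n)
  dr[2:(n - 1)] <- (r[3:n] - r[1:(n - 2)]) / 2
  dr[1] <- r[2] - r[1]
  dr[n] <- r[n] - r[n - 1]
  w <- r * pmax(dr, 0)
  # floor: the innermost samples share the area of the central disk
  floor_w <- max(w) * 1e-3
  ctr <- which(r < max(r) * 5e-3)
  if (length(ctr)) {
    disk <- pi * max(r[ctr], r[2])^2
    w[ctr] <- pmax(w[ctr], disk / length(ctr))
  }
  w <- pmax(w, floor_w)
  w * (matrix_size^2 / sum(w))
}

#' Density-compensation weights for a trajectory
#'
#' Returns the per-sample density-compensation weights of a spiral arm,
#' computed analytically from the annular area element \eqn{|k|\,d|k|} with a
#' small-radius floor, normalized so that the weighted adjoint of a centered
#' point source recovers its amplitude (weights sum to \eqn{N^2}).
#'
#' @param traj a \code{\link{design_vd_spiral}} trajectory.
#' @return numeric vector of non-negative weights, one per sample.
#' @export
density_compensation <- function(traj) {
  stopifnot(inherits(traj, "spiral_trajectory"))
  if (all(traj$r == 0)) stop("degenerate trajectory: all samples at k = 0")
  traj$dcf
}

#' Rotate a base arm to every frame of a golden-angle schedule
#'
#' @param traj base arm from \code{\link{design_vd_spiral}}.
#' @param schedule a \code{\link{golden_angle_schedule}}.
#' @return list with \code{coords}: \code{n_frames x n_samples x 2} array of
#'   (kx, ky), and the schedule. Rotation is counter-clockwise in the
#'   (kx, ky) plane.
#' @export
rotate_arm <- function(traj, schedule) {
  stopifnot(inherits(traj, "spiral_trajectory"),
            inherits(schedule, "ga_schedule"))
  nf <- schedule$n_frames
  ns <- length(traj$kx)
  coords <- array(0, dim = c(nf, ns, 2))
  for (f in seq_len(nf)) {
    th <- schedule$angles_deg[f] * pi / 180
    coords[f, , 1] <- cos(th) * traj$kx - sin(th) * traj$ky
    coords[f, , 2] <- sin(th) * traj$kx + cos(th) * traj$ky
  }
  list(coords = coords, schedule = schedule)
}

#' Effective acceleration factor of a variable-density acquisition
#'
#' Ratio of the Nyquist-dense sample count of the covered k-space disk to the
#' number of acquired samples in one arm. Reported as a diagnostic; the exact
#' value depends on the sampling-density convention.
#'
#' @param traj a \code{\link{design_vd_spiral}} trajectory.
#' @return a single number, the effective acceleration.
#' @export
effective_acceleration <- function(traj) {
  stopifnot(inherits(traj, "spiral_trajectory"))
  nyquist_samples <- pi * (traj$matrix / 2)^2
  nyquist_samples / length(traj$kx)
}
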