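GAMMA_HZ_PER_UT <- 42.577478518  # proton gyromagnetic ratio, Hz/uT

#' Hyperbolic-secant adiabatic inversion pulse
#'
#' Amplitude- and frequency-modulated adiabatic full-passage pulse:
#' \eqn{B_1(t) = B_{1,max}\,\mathrm{sech}(\beta\tau)},
#' \eqn{\Delta f(t) = -(BW/2)\tanh(\beta\tau)} with \eqn{\tau = 2t/T - 1}.
#' The dimensionless truncation \eqn{\beta} is set so the envelope falls to
#' 1\% of its peak at the pulse edges; the frequency sweep spans the stated
#' bandwidth, which fixes the effective \eqn{\mu = \pi\,BW\,/\,\beta_{rad}}
#' of the classical HS parameterization.
#'
#' @param duration_ms pulse duration (default 13.3).
#' @param peak_b1_ut peak B1 amplitude in microtesla (default 13.5).
#' @param bandwidth_hz inversion bandwidth / frequency sweep in Hz
#'   (default 1202).
#' @param n_timepoints waveform samples (default 2001; odd, so a sample
#'   lands exactly on the pulse center).
#' @return object of class \code{hs_pulse} with the complex B1 waveform
#'   (\code{b1_ut}, amplitude with phase modulation applied), the time grid
#'   \code{t_ms}, and shape parameters \code{beta}, \code{mu}.
#' @export
hs_pulse <- function(duration_ms = 13.3, peak_b1_ut = 13.5,
                     bandwidth_hz = 1202, n_timepoints = 2001) {
  beta <- acosh(1 / 0.01)            # sech(beta) = 0.01 truncation
  t_ms <- seq(0, duration_ms, length.out = n_timepoints)
  tau <- 2 * t_ms / duration_ms - 1
  amp <- peak_b1_ut / cosh(beta * tau)
  # frequency sweep: from +BW/2 down to -BW/2
  freq_hz <- -(bandwidth_hz / 2) * tanh(beta * tau)
  # phase = 2*pi * integral of freq
  dt_s <- (duration_ms / 1000) / (n_timepoints - 1)
  phase <- 2 * pi * cumsum(c(0, (freq_hz[-1] + freq_hz[-n_timepoints]) / 2)) * dt_s
  beta_rad_s <- beta / (duration_ms / 2000)   # rad/s over the half-duration
  structure(list(
    duration_ms = duration_ms, peak_b1_ut = peak_b1_ut,
    bandwidth_hz = bandwidth_hz, n_timepoints = as.integer(n_timepoints),
    beta = beta, mu = pi * bandwidth_hz / beta_rad_s,
    t_ms = t_ms, b1_ut = amp * exp(1i * phase), freq_hz = freq_hz
  ), class = "hs_pulse")
}

#' Bloch simulation of an RF pulse
#'
#' Hard-pulse (piecewise-constant rotation) propagation of the Bloch
#' equations: at each waveform step the magnetization rotates about the
#' effective field \eqn{(\gamma B_{1,x}, \gamma B_{1,y}, \Delta\omega)} in
#' the rotating frame, with optional T1/T2 relaxation applied between steps.
#' Without relaxation the propagation is norm-preserving to machine
#' precision.
#'
#' @param b1_ut complex B1 waveform in microtesla, uniformly sampled.
#' @param t_ms time grid of the waveform (must be uniform).
#' @param freq_offset_hz off-resonance of the spin in Hz (default 0).
#' @param t1_ms,t2_ms relaxation times; \code{Inf} (default) disables
#'   relaxation.
#' @param m_initial initial magnetization 3-vector (default c(0, 0, 1)).
#' @return final magnetization 3-vector (Mx, My, Mz), M0 = 1 units.
#' @export
bloch_simulate <- function(b1_ut, t_ms, freq_offset_hz = 0,
                           t1_ms = Inf, t2_ms = Inf,
                           m_initial = c(0, 0, 1)) {
  nt <- length(b1_ut)
  stopifnot(length(t_ms) == nt, nt >= 2)
  dt <- diff(t_ms)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("waveform time grid must be uniform")
  dt_s <- dt[1] / 1000
  m <- as.numeric(m_initial)
  e1 <- if (is.finite(t1_ms)) exp(-dt[1] / t1_ms) else 1
  e2 <- if (is.finite(t2_ms)) exp(-dt[1] / t2_ms) else 1
  wz <- 2 * pi * freq_offset_hz                  # rad/s
  gam <- 2 * pi * GAMMA_HZ_PER_UT                # rad/s per uT
  # midpoint B1 over each of the nt-1 intervals spanned by the waveform
  b1_mid <- (b1_ut[-1] + b1_ut[-nt]) / 2
  for (i in seq_len(nt - 1L)) {
    wx <- gam * Re(b1_mid[i])
    wy <- gam * Im(b1_mid[i])
    w <- sqrt(wx^2 + wy^2 + wz^2)
    if (w > 0) {
      ang <- -w * dt_s   # left-handed precession about the effective field
      ax <- wx / w; ay <- wy / w; az <- wz / w
      ca <- cos(ang); sa <- sin(ang)
      dot <- ax * m[1] + ay * m[2] + az * m[3]
      crossx <- ay * m[3] - az * m[2]
      crossy <- az * m[1] - ax * m[3]
      crossz <- ax * m[2] - ay * m[1]
      m <- c(ca * m[1] + sa * crossx + (1 - ca) * dot * ax,
             ca * m[2] + sa * crossy + (1 - ca) * dot * ay,
             ca * m[3] + sa * crossz + (1 - ca) * dot * az)
    }
    if (e1 < 1 || e2 < 1)
      m <- c(m[1] * e2, m[2] * e2, 1 + (m[3] - 1) * e1)
  }
  m
}

#' Inversion profile of an adiabatic pulse
#'
#' Bloch-simulated longitudinal magnetization after the pulse over a grid of
#' off-resonance frequencies and B1 amplitude scales.
#'
#' @param pulse an \code{\link{hs_pulse}}.
#' @param offsets_hz vector of off-resonance frequencies.
#' @param b1_scales vector of B1 amplitude scale factors.
#' @return object of class \code{inversion_profile}: matrix \code{mz}
#'   (offsets x scales) of Mz/M0, plus the grids.
#' @export
inversion_profile <- function(pulse, offsets_hz = 0, b1_scales = 1) {
  stopifnot(length(offsets_hz) >= 1, length(b1_scales) >= 1)
  mz <- matrix(0, length(offsets_hz), length(b1_scales))
  for (j in seq_along(b1_scales)) {
    wf <- pulse$b1_ut * b1_scales[j]
    for (i in seq_along(offsets_hz))
      mz[i, j] <- bloch_simulate(wf, pulse$t_ms, offsets_hz[i])[3]
  }
  structure(list(mz = mz, offsets_hz = offsets_hz, b1_scales = b1_scales,
                 pulse = pulse),
            class = "inversion_profile")
}

#' Inversion efficiency from a profile
#'
#' \eqn{-M_z/M_0} at zero offset and nominal B1 (1.0 = perfect inversion).
#'
#' @param profile an \code{\link{inversion_profile}} whose grids include
#'   0 Hz and scale 1.
#' @return efficiency in [-1, 1].
#' @export
inversion_efficiency <- function(profile) {
  i <- which.min(abs(profile$offsets_hz))
  j <- which.min(abs(profile$b1_scales - 1))
  -profile$mz[i, j]
}

#' WET pre-saturation pulse train
#'
#' Four-flip-angle saturation train designed to null longitudinal
#' magnetization robustly over a wide T1 range (400-4200 ms) and against B1
#' error. Sub-pulses are modeled as non-selective rectangular rotations.
#'
#' @param flip_angles_deg flip angles in order (default c(89, 98, 82, 157)).
#' @param subpulse_duration_ms duration of each sub-pulse (default 4.2).
#' @param interpulse_delay_ms delay between sub-pulses during which T1
#'   recovery acts (default 0: effectively instantaneous train).
#' @return object of class \code{wet_train}.
#' @export
wet_train <- function(flip_angles_deg = c(89, 98, 82, 157),
                      subpulse_duration_ms = 4.2, interpulse_delay_ms = 0) {
  stopifnot(length(flip_angles_deg) == 4)
  structure(list(flip_angles_deg = flip_angles_deg,
                 subpulse_duration_ms = subpulse_duration_ms,
                 interpulse_delay_ms = interpulse_delay_ms),
            class = "wet_train")
}

#' Residual longitudinal magnetization after a WET train
#'
#' Propagates Mz through the four rotations with T1 recovery over each
#' sub-pulse duration plus inter-pulse delay (transverse magnetization is
#' assumed spoiled between sub-pulses, as in the sequence). With
#' instantaneous pulses and zero delay the residual reduces to the product
#' of cosines of the flip angles.
#'
#' @param train a \code{\link{wet_train}}.
#' @param t1_ms longitudinal relaxation time (vectorized).
#' @param instantaneous if TRUE, ignore all durations/delays (closed-form
#'   product-of-cosines regime). Default FALSE.
#' @return residual Mz/M0 after the train (same length as \code{t1_ms}).
#' @export
wet_residual <- function(train, t1_ms, instantaneous = FALSE) {
  stopifnot(all(t1_ms > 0))
  out <- numeric(length(t1_ms))
  for (i in seq_along(t1_ms)) {
    mz <- 1
    for (p in seq_along(train$flip_angles_deg)) {
      mz <- mz * cos(train$flip_angles_deg[p] * pi / 180)
      if (!instantaneous) {
        trec <- train$subpulse_duration_ms + train$interpulse_delay_ms
        if (p < length(train$flip_angles_deg))
          mz <- 1 + (mz - 1) * exp(-trec / t1_ms[i])
      }
    }
    out[i] <- mz
  }
  out
}

#' Export an RF waveform as a two-column text table
#'
#' @param pulse an \code{\link{hs_pulse}}.
#' @param path output file.
#' @return invisibly, the data frame written (time_ms, amplitude_ut,
#'   phase_rad).
#' @export
write_waveform <- function(pulse, path) {
  df <- data.frame(time_ms = pulse$t_ms,
                   amplitude_ut = abs(pulse$b1_ut),
                   phase_rad = Arg(pulse$b1_ut))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
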