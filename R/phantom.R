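#' Inversion-time schedule
#'
#' The Look-Locker TI grid: \code{n_acquired} TIs used for T1 fitting plus
#' \code{n_appended} extra TIs acquired at the end of the shot (used only to
#' stabilize the temporal boundary of the reconstruction) and
#' \code{n_prepended} pseudo-frames prepended with inverted k-space sign
#' during periodic padding. TI values follow
#' \eqn{TI_i = TI_1 + (i-1)\,\Delta TI}.
#'
#' @param first_ti_ms first inversion time in ms (default 50).
#' @param delta_ti_ms TI increment in ms (default 200).
#' @param n_acquired TIs used for fitting (default 50).
#' @param n_appended extra acquired TIs (default 5).
#' @param n_prepended pseudo-frames prepended during padding (default 4).
#' @return An object of class \code{ti_schedule}; element \code{ti_values_ms}
#'   holds the acquired + appended TIs.
#' @examples
#' sch <- ti_schedule()
#' sch$ti_values_ms[55]   # 10850
#' sch$n_padded           # 59
#' @export
ti_schedule <- function(first_ti_ms = 50, delta_ti_ms = 200,
                        n_acquired = 50, n_appended = 5, n_prepended = 4) {
  stopifnot(first_ti_ms > 0, delta_ti_ms > 0, n_acquired >= 1,
            n_appended >= 0, n_prepended >= 0, n_prepended <= n_appended + n_acquired)
  n_shot <- n_acquired + n_appended
  structure(list(
    first_ti_ms = first_ti_ms, delta_ti_ms = delta_ti_ms,
    n_acquired = as.integer(n_acquired), n_appended = as.integer(n_appended),
    n_prepended = as.integer(n_prepended),
    n_shot = as.integer(n_shot),
    n_padded = as.integer(n_prepended + n_shot),
    ti_values_ms = first_ti_ms + (seq_len(n_shot) - 1) * delta_ti_ms
  ), class = "ti_schedule")
}

#' @export
print.ti_schedule <- function(x, ...) {
  cat(sprintf(
    "TI schedule: %d acquired + %d appended TIs (%g..%g ms, step %g ms); %d prepended -> %d padded frames\n",
    x$n_acquired, x$n_appended, x$first_ti_ms,
    x$ti_values_ms[x$n_shot], x$delta_ti_ms, x$n_prepended, x$n_padded))
  invisible(x)
}

#' Digital vessel phantom
#'
#' A 2D slice phantom emulating an axial neck slice: circular flowing-blood
#' vessels (each with its own T1) embedded in a smooth elliptical static
#' background. Vessel pixels are rasterized by the pixel-center-in-circle
#' rule. Vessels carry integer labels 1, 2, ... ; background label is 0.
#'
#' @param matrix image matrix size N (square).
#' @param fov_mm field of view in mm.
#' @param vessels list of vessels, each a list with \code{center_mm}
#'   (c(x, y), mm offsets from the FOV center), \code{radius_mm}, and
#'   \code{t1_ms} (blood T1).
#' @param background_t1_ms T1 of the static background tissue (default 1200).
#' @param background_m0 equilibrium magnetization of background (default 1).
#' @param blood_m0 equilibrium magnetization of blood (default 1).
#' @param background_texture relative amplitude in [0, 1] of the smooth
#'   deterministic background heterogeneity (default 1). The background T1
#'   varies smoothly between 0.25x and 1x \code{background_t1_ms}, emulating
#'   the fat / muscle / gland composition of a real neck slice: short-T1
#'   tissue recovers to a brighter saturation plateau, giving the static
#'   anatomical structure that frame-to-frame registration anchors on (a
#'   perfectly uniform background leaves nothing to register on). A mild
#'   (10\%) M0 modulation is applied with an independent pattern. Set 0 for
#'   a uniform background.
#' @return An object of class \code{digital_phantom} with \code{t1_map_ms},
#'   \code{m0_map}, \code{vessel_labels}, \code{matrix}, \code{fov_mm}.
#' @export
make_phantom <- function(matrix = 96, fov_mm = 180,
                         vessels = list(), background_t1_ms = 1200,
                         background_m0 = 1, blood_m0 = 1,
                         background_texture = 1) {
  n <- as.integer(matrix)
  res <- fov_mm / n
  ctr <- floor(n / 2)                 # 0-based center pixel index
  px <- (0:(n - 1) - ctr) * res       # pixel-center coordinates, mm
  X <- outer(rep(1, n), px)           # [y, x]
  Y <- outer(px, rep(1, n))

  # elliptical "neck" background covering ~80% of the FOV
  a <- 0.42 * fov_mm; b <- 0.34 * fov_mm
  inside <- (X / a)^2 + (Y / b)^2 <= 1
  # smooth deterministic tissue heterogeneity (fixed sinusoid mixtures, no
  # RNG): u in [0,1] drives a T1 mixture, v a mild M0 modulation
  u <- 0.5 + 0.5 * tanh(
    1.5 * (0.6 * sin(2 * pi * X / 47 + 1.1) * cos(2 * pi * Y / 61 + 0.4) +
           0.4 * cos(2 * pi * (X + Y) / 83 + 2.0) +
           0.3 * sin(2 * pi * (X - 0.5 * Y) / 39 + 0.7)))
  v <- sin(2 * pi * X / 71 + 0.3) * sin(2 * pi * Y / 53 + 1.9)
  t1 <- matrix(0, n, n); m0 <- matrix(0, n, n)
  t1[inside] <- (background_t1_ms *
                   (1 - 0.75 * background_texture * u))[inside]
  m0[inside] <- (background_m0 *
                   (1 + 0.1 * background_texture * v))[inside]
  labels <- matrix(0L, n, n)

  for (v in seq_along(vessels)) {
    vs <- vessels[[v]]
    stopifnot(vs$radius_mm > 0)
    if (any(abs(vs$center_mm) + vs$radius_mm > fov_mm / 2))
      stop("vessel extends outside the field of view")
    mask <- (X - vs$center_mm[1])^2 + (Y - vs$center_mm[2])^2 <= vs$radius_mm^2
    if (any(labels[mask] != 0L)) stop("vessels overlap")
    labels[mask] <- as.integer(v)
    t1[mask] <- vs$t1_ms
    m0[mask] <- if (is.null(vs$m0)) blood_m0 else vs$m0
  }
  structure(list(t1_map_ms = t1, m0_map = m0, vessel_labels = labels,
                 matrix = n, fov_mm = fov_mm, res_mm = res,
                 background_t1_ms = background_t1_ms, vessels = vessels),
            class = "digital_phantom")
}

#' Acquisition parameters for the simulation
#'
#' @param slice_thickness_mm imaging slice thickness (default 5).
#' @param blood_velocity_cm_s nominal through-plane blood velocity used for
#'   the inflow-refresh check (default 15).
#' @param inversion_efficiency inversion efficiency of the adiabatic pulse in
#'   [0, 1]; 1 means perfect inversion of inflowing blood (default 1).
#' @param noise_sigma per-sample standard deviation of the complex Gaussian
#'   k-space noise (each of real/imaginary parts; default 0).
#' @param seed RNG seed governing all stochastic draws (default 1).
#' @param presat_delay_ms delay between the background pre-saturation and the
#'   inversion pulse, used only by the exact-first-frame background mode
#'   (default 150; the protocol literature quotes both 150 and 200 ms).
#' @param background_mode \code{"plateau"} (default): static tissue sits at
#'   the saturation-recovery plateau \eqn{M_0(1-e^{-\Delta TI/T_1})} in every
#'   frame. \code{"exact_first"}: the first frame instead reflects recovery
#'   over \code{presat_delay_ms + first TI} since pre-saturation.
#' @param magnitude_mode if TRUE the simulated image series is returned as
#'   magnitude; default FALSE (signed real longitudinal signal).
#' @return object of class \code{acq_params}; element \code{inflow_ok} flags
#'   whether \eqn{\Delta TI > THK / v} holds so each excitation sees fully
#'   refreshed inflowing spins.
#' @export
acq_params <- function(slice_thickness_mm = 5, blood_velocity_cm_s = 15,
                       inversion_efficiency = 1.0, noise_sigma = 0,
                       seed = 1, presat_delay_ms = 150,
                       background_mode = c("plateau", "exact_first"),
                       magnitude_mode = FALSE) {
  background_mode <- match.arg(background_mode)
  stopifnot(inversion_efficiency >= 0, inversion_efficiency <= 1,
            noise_sigma >= 0)
  structure(list(slice_thickness_mm = slice_thickness_mm,
                 blood_velocity_cm_s = blood_velocity_cm_s,
                 inversion_efficiency = inversion_efficiency,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 presat_delay_ms = presat_delay_ms,
                 background_mode = background_mode,
                 magnitude_mode = magnitude_mode),
            class = "acq_params")
}

#' Check the inflow-refresh condition
#'
#' Flowing blood is modeled as fully refreshed between excitations, which
#' requires \eqn{\Delta TI > THK / v}: during one TI increment the blood
#' column must traverse the slice.
#'
#' @param schedule a \code{\link{ti_schedule}}.
#' @param acq an \code{\link{acq_params}}.
#' @return logical.
#' @export
inflow_condition <- function(schedule, acq) {
  (schedule$delta_ti_ms / 1000) >
    (acq$slice_thickness_mm / 10) / acq$blood_velocity_cm_s
}

#' Simulate the ground-truth inversion-recovery image series
#'
#' Vessel pixels follow full inversion recovery,
#' \eqn{M(TI) = M_0 (1 - (1+\epsilon) e^{-TI/T_1})} with \eqn{\epsilon} the
#' inversion efficiency (for \eqn{\epsilon = 1}, \eqn{M_{init} = -M_0}):
#' every excitation sees freshly inflowing blood that experienced only the
#' inversion pulse, so the recovery curve is sampled cleanly at each TI.
#' Static background pixels are held at the saturation-recovery plateau
#' \eqn{M_0(1 - e^{-\Delta TI/T_1})} by the repeated 90-degree excitations
#' (plus pre-saturation before the first frame).
#'
#' @param phantom a \code{\link{make_phantom}} object.
#' @param schedule a \code{\link{ti_schedule}}.
#' @param acq an \code{\link{acq_params}}.
#' @return An \code{\link{image_series}} of \code{n_shot} real-valued frames
#'   (signed longitudinal signal, or magnitude if \code{acq$magnitude_mode}).
#' @export
simulate_ir_series <- function(phantom, schedule, acq = acq_params()) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(schedule, "ti_schedule"))
  if (!inflow_condition(schedule, acq))
    warning("inflow condition delta_TI > THK/v violated: blood will not be fully refreshed between excitations; the refresh model is optimistic")
  n <- phantom$matrix
  nf <- schedule$n_shot
  t1 <- phantom$t1_map_ms
  m0 <- phantom$m0_map
  vess <- phantom$vessel_labels > 0L
  eps <- acq$inversion_efficiency
  dat <- array(0, dim = c(nf, n, n))
  bgplateau <- ifelse(t1 > 0, m0 * (1 - exp(-schedule$delta_ti_ms / t1)), 0)
  for (f in seq_len(nf)) {
    ti <- schedule$ti_values_ms[f]
    fr <- bgplateau
    fr[vess] <- m0[vess] * (1 - (1 + eps) * exp(-ti / t1[vess]))
    if (acq$background_mode == "exact_first" && f == 1L) {
      trec <- acq$presat_delay_ms + ti
      bg1 <- ifelse(t1 > 0, m0 * (1 - exp(-trec / t1)), 0)
      fr[!vess] <- bg1[!vess]
    }
    dat[f, , ] <- fr
  }
  if (acq$magnitude_mode) dat <- abs(dat)
  image_series(dat, fov_mm = phantom$fov_mm, res_mm = phantom$res_mm,
               frame_roles = rep(c("acquired", "appended"),
                                 c(schedule$n_acquired, schedule$n_appended)))
}

#' Simulated coil sensitivity maps
#'
#' Smooth complex sensitivities: Gaussian amplitude lobes centered on
#' \code{n_coils} points around the FOV boundary, each with a smooth linear
#' phase ramp of distinct orientation. For \code{n_coils = 1} a uniform unit
#' sensitivity is returned.
#'
#' @param matrix image matrix size N.
#' @param n_coils number of coils (>= 1).
#' @param lobe_fwhm_frac Gaussian lobe FWHM as a fraction of the FOV
#'   (default 1.1, broad lobes so coil-combined coverage is even).
#' @return object of class \code{coil_maps}: \code{maps} is a
#'   \code{n_coils x N x N} complex array.
#' @export
make_coil_maps <- function(matrix = 96, n_coils = 4, lobe_fwhm_frac = 1.1) {
  n <- as.integer(matrix)
  stopifnot(n_coils >= 1)
  maps <- array(0 + 0i, dim = c(n_coils, n, n))
  if (n_coils == 1L) {
    maps[1, , ] <- 1 + 0i
  } else {
    ctr <- floor(n / 2)
    u <- (0:(n - 1) - ctr) / n          # [-0.5, 0.5) FOV units
    X <- outer(rep(1, n), u); Y <- outer(u, rep(1, n))
    sigma <- lobe_fwhm_frac / 2.355
    for (c in seq_len(n_coils)) {
      th <- 2 * pi * (c - 1) / n_coils
      cx <- 0.55 * cos(th); cy <- 0.55 * sin(th)
      amp <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sigma^2))
      phase <- 2 * pi * (0.35 * (X * cos(th + 1) + Y * sin(th + 1))) + th / 3
      maps[c, , ] <- amp * exp(1i * phase)
    }
    # normalize so RSS is O(1)
    rss <- sqrt(apply(abs(maps)^2, c(2, 3), sum))
    maps <- maps / mean(rss)
  }
  structure(list(maps = maps, n_coils = as.integer(n_coils), matrix = n),
            class = "coil_maps")
}

#' Root-sum-of-squares of coil sensitivities
#' @param coils a \code{\link{make_coil_maps}} object.
#' @return N x N matrix.
#' @export
coil_rss <- function(coils) {
  sqrt(apply(abs(coils$maps)^2, c(2, 3), sum))
}

#' Simulate multi-coil single-arm-per-frame spiral k-space
#'
#' Forward encoding \eqn{k_{f,c} = F_f(S_c \odot I_f) + n} with \eqn{F_f} the
#' non-uniform Fourier transform along frame f's rotated spiral arm and n
#' i.i.d. complex Gaussian noise. Noise draws are independent across frames,
#' coils and samples; one seed governs everything via deterministically
#' derived per-frame substreams. Optionally applies off-resonance phase
#' accrual \eqn{e^{-2\pi i\, b_0(x)\, t}} inside the (exact, slow) forward
#' model when a B0 map is supplied.
#'
#' @param truth an \code{\link{image_series}} (ground truth frames).
#' @param coils a \code{\link{make_coil_maps}} object.
#' @param traj base arm from \code{\link{design_vd_spiral}}.
#' @param schedule a \code{\link{ti_schedule}} (supplies rotation count).
#' @param acq an \code{\link{acq_params}} (noise sigma and seed).
#' @param b0_map_hz optional N x N off-resonance map; when given, the forward
#'   model is evaluated with time-resolved phase accrual (slow; intended for
#'   small matrices / deblurring validation).
#' @return object of class \code{kspace_series}: \code{data} is
#'   \code{frames x coils x samples} complex; \code{frame_signs} all +1;
#'   plus the embedded schedule, trajectory and rotation angles.
#' @export
simulate_kspace <- function(truth, coils, traj, schedule, acq = acq_params(),
                            b0_map_hz = NULL) {
  stopifnot(inherits(truth, "image_series"), inherits(coils, "coil_maps"),
            inherits(traj, "spiral_trajectory"),
            inherits(schedule, "ti_schedule"))
  nf <- dim(truth$data)[1]
  n <- dim(truth$data)[2]
  if (nf != schedule$n_shot)
    stop("truth frame count does not match the schedule's acquired+appended count")
  if (coils$matrix != n) stop("coil map matrix does not match image matrix")
  ga <- golden_angle_schedule(nf)
  rot <- rotate_arm(traj, ga)
  ns <- length(traj$kx)
  nc <- coils$n_coils
  dat <- array(0 + 0i, dim = c(nf, nc, ns))
  for (f in seq_len(nf)) {
    pl <- nufft_plan(rot$coords[f, , 1], rot$coords[f, , 2], n)
    img_f <- matrix(truth$data[f, , ], n, n)
    for (c in seq_len(nc)) {
      src <- matrix(coils$maps[c, , ], n, n) * img_f
      if (is.null(b0_map_hz)) {
        dat[f, c, ] <- nufft_forward(src, pl)
      } else {
        dat[f, c, ] <- .forward_offres(src, rot$coords[f, , 1],
                                       rot$coords[f, , 2], b0_map_hz,
                                       traj$t_ms)
      }
    }
    if (acq$noise_sigma > 0) {
      set.seed((acq$seed * 1000003L + f) %% .Machine$integer.max)
      nz <- complex(real = stats::rnorm(nc * ns, sd = acq$noise_sigma),
                    imaginary = stats::rnorm(nc * ns, sd = acq$noise_sigma))
      dat[f, , ] <- dat[f, , ] + matrix(nz, nc, ns)
    }
  }
  structure(list(data = dat, frame_signs = rep(1, nf), schedule = schedule,
                 traj = traj, angles_deg = ga$angles_deg,
                 frame_roles = rep(c("acquired", "appended"),
                                   c(schedule$n_acquired, schedule$n_appended))),
            class = "kspace_series")
}

# exact forward model with off-resonance phase accrual (direct NUDFT + time-
# segmented phase); slow, used for small-scale deblurring validation
.forward_offres <- function(image, kx, ky, b0_map_hz, t_ms) {
  n <- nrow(image)
  nseg <- 16L
  edges <- seq(min(t_ms), max(t_ms), length.out = nseg + 1L)
  mids <- (edges[-1] + edges[-(nseg + 1L)]) / 2
  out <- complex(length(kx))
  for (s in seq_len(nseg)) {
    sel <- t_ms >= edges[s] & (t_ms <= edges[s + 1L])
    if (s < nseg) sel <- sel & t_ms < edges[s + 1L]
    if (!any(sel)) next
    ph <- exp(-2i * pi * b0_map_hz * (mids[s] / 1000))
    out[sel] <- nudft_forward(image * ph, kx[sel], ky[sel])
  }
  out
}
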