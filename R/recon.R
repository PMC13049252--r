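#' Image-series container
#'
#' @param data \code{frames x N x N} numeric or complex array.
#' @param fov_mm,res_mm geometry metadata.
#' @param frame_roles per-frame tag in \code{c("prepended", "acquired",
#'   "appended")}; defaults to all \code{"acquired"}.
#' @return object of class \code{image_series}.
#' @export
image_series <- function(data, fov_mm = NA, res_mm = NA, frame_roles = NULL) {
  stopifnot(length(dim(data)) == 3)
  nf <- dim(data)[1]
  if (is.null(frame_roles)) frame_roles <- rep("acquired", nf)
  stopifnot(length(frame_roles) == nf,
            all(frame_roles %in% c("prepended", "acquired", "appended")))
  structure(list(data = data, fov_mm = fov_mm, res_mm = res_mm,
                 frame_roles = frame_roles),
            class = "image_series")
}

#' Drop prepended/appended frames from a series
#'
#' @param series an \code{\link{image_series}}.
#' @return an \code{\link{image_series}} with only the acquired frames.
#' @export
unpad_series <- function(series) {
  keep <- series$frame_roles == "acquired"
  image_series(series$data[keep, , , drop = FALSE], series$fov_mm,
               series$res_mm, rep("acquired", sum(keep)))
}

#' Sign-inverted periodic frame padding of a k-space series
#'
#' Prepends copies of the last \code{n_prepended} shot frames except the very
#' last (for the default schedule: frames 52-55 of 55) to the beginning of
#' the series with their k-space data multiplied by -1, yielding the padded
#' series (59 frames by default). The inversion-recovery signal is close to
#' antiperiodic across the seam: frame 55's magnetization is near +M0 while a
#' frame before TI = 0 would be near -M0, and the golden-angle increment is
#' nearly preserved across the seam (134.46 deg vs 137.51 deg), so the padded
#' series continues both the signal evolution and the rotation pattern. The
#' extra frames stabilize the temporal total-variation regularizer at the
#' series boundary and are excluded from T1 fitting.
#'
#' @param kspace a \code{\link{simulate_kspace}} (or compatible) series with
#'   \code{n_acquired + n_appended} frames.
#' @return padded \code{kspace_series}: \code{frame_signs} is -1 for the
#'   prepended frames; rotation angles are carried over from the source
#'   frames; \code{frame_roles} gains \code{"prepended"} entries.
#' @export
pad_frames <- function(kspace) {
  stopifnot(inherits(kspace, "kspace_series"))
  sch <- kspace$schedule
  nf <- dim(kspace$data)[1]
  if (nf != sch$n_shot)
    stop(sprintf("expected %d (acquired+appended) frames, got %d",
                 sch$n_shot, nf))
  np <- sch$n_prepended
  if (np == 0L) return(kspace)
  src <- (nf - np):(nf - 1L)            # e.g. frames 52..55 when np=4, nf=55
  src <- src + 1L
  dat <- array(0 + 0i, dim = c(np + nf, dim(kspace$data)[2], dim(kspace$data)[3]))
  dat[seq_len(np), , ] <- -kspace$data[src, , ]
  dat[np + seq_len(nf), , ] <- kspace$data
  structure(list(
    data = dat,
    frame_signs = c(rep(-1, np), rep(1, nf)),
    schedule = sch, traj = kspace$traj,
    angles_deg = c(kspace$angles_deg[src], kspace$angles_deg),
    frame_roles = c(rep("prepended", np), kspace$frame_roles),
    source_frames = c(src, seq_len(nf))
  ), class = "kspace_series")
}

#' Remove padding from a k-space series
#' @param kspace padded \code{kspace_series}.
#' @return the acquired+appended frames only.
#' @export
unpad_kspace <- function(kspace) {
  keep <- kspace$frame_roles != "prepended"
  structure(list(data = kspace$data[keep, , , drop = FALSE],
                 frame_signs = kspace$frame_signs[keep],
                 schedule = kspace$schedule, traj = kspace$traj,
                 angles_deg = kspace$angles_deg[keep],
                 frame_roles = kspace$frame_roles[keep]),
            class = "kspace_series")
}

#' Multi-frame multi-coil SENSE encoding operator
#'
#' Builds the linear operator \eqn{E: I \mapsto \{F_f(S_c \odot I_f)\}} for a
#' frame series, with per-frame NUFFT plans for the rotated spiral arms, and
#' its exact adjoint. Exposes \code{forward(series_array)} and
#' \code{adjoint(kspace_array)} closures plus \code{adjoint_dcf} (density
#' compensated, 1/N^2-scaled coil-combined adjoint used as the gridding
#' baseline and solver initialization).
#'
#' @param kspace a \code{kspace_series} (padded or not) supplying trajectory,
#'   angles and dimensions.
#' @param coils a \code{\link{make_coil_maps}} object.
#' @param method \code{"nufft"} (fast gridding, default) or \code{"nudft"}
#'   (exact direct summation; grids up to 64).
#' @return an object of class \code{encoding_operator}.
#' @export
encoding_operator <- function(kspace, coils, method = c("nufft", "nudft")) {
  method <- match.arg(method)
  nf <- dim(kspace$data)[1]
  nc <- coils$n_coils
  n <- coils$matrix
  traj <- kspace$traj
  ns <- length(traj$kx)
  coords <- vector("list", nf)
  plans <- vector("list", nf)
  for (f in seq_len(nf)) {
    th <- kspace$angles_deg[f] * pi / 180
    kx <- cos(th) * traj$kx - sin(th) * traj$ky
    ky <- sin(th) * traj$kx + cos(th) * traj$ky
    coords[[f]] <- cbind(kx, ky)
    if (method == "nufft") plans[[f]] <- nufft_plan(kx, ky, n)
  }
  smat <- lapply(seq_len(nc), function(c) matrix(coils$maps[c, , ], n, n))
  fw1 <- function(img, f) {
    if (method == "nufft") nufft_forward(img, plans[[f]])
    else nudft_forward(img, coords[[f]][, 1], coords[[f]][, 2])
  }
  ad1 <- function(s, f) {
    if (method == "nufft") nufft_adjoint(s, plans[[f]])
    else nudft_adjoint(s, coords[[f]][, 1], coords[[f]][, 2], n)
  }
  forward <- function(series_arr) {
    out <- array(0 + 0i, dim = c(nf, nc, ns))
    for (f in seq_len(nf)) {
      img <- matrix(series_arr[f, , ], n, n)
      for (c in seq_len(nc)) out[f, c, ] <- fw1(smat[[c]] * img, f)
    }
    out
  }
  adjoint <- function(ksp_arr) {
    out <- array(0 + 0i, dim = c(nf, n, n))
    for (f in seq_len(nf)) {
      acc <- matrix(0 + 0i, n, n)
      for (c in seq_len(nc))
        acc <- acc + Conj(smat[[c]]) * ad1(ksp_arr[f, c, ], f)
      out[f, , ] <- acc
    }
    out
  }
  adjoint_dcf <- function(ksp_arr) {
    w <- traj$dcf
    out <- array(0 + 0i, dim = c(nf, n, n))
    rssq <- apply(abs(coils$maps)^2, c(2, 3), sum)
    rssq[rssq == 0] <- 1
    for (f in seq_len(nf)) {
      acc <- matrix(0 + 0i, n, n)
      for (c in seq_len(nc))
        acc <- acc + Conj(smat[[c]]) * ad1(w * ksp_arr[f, c, ], f)
      out[f, , ] <- acc / (n^2) / rssq
    }
    out
  }
  structure(list(forward = forward, adjoint = adjoint,
                 adjoint_dcf = adjoint_dcf, n_frames = nf, n_coils = nc,
                 matrix = n, n_samples = ns, method = method),
            class = "encoding_operator")
}

#' Temporal total-variation operator (forward differences along frames)
#'
#' @param series_arr \code{frames x N x N} array (>= 2 frames).
#' @return \code{(frames-1) x N x N} array of frame differences.
#' @export
temporal_tv <- function(series_arr) {
  nf <- dim(series_arr)[1]
  if (is.null(nf) || nf < 2) stop("temporal TV needs at least 2 frames")
  series_arr[2:nf, , , drop = FALSE] - series_arr[1:(nf - 1), , , drop = FALSE]
}

#' Adjoint of the temporal total-variation operator
#'
#' Negative temporal divergence: the exact conjugate transpose of
#' \code{\link{temporal_tv}}.
#'
#' @param diff_arr \code{(frames-1) x N x N} array.
#' @return \code{frames x N x N} array.
#' @export
temporal_tv_adjoint <- function(diff_arr) {
  nd <- dim(diff_arr)[1]
  n1 <- dim(diff_arr)[2]; n2 <- dim(diff_arr)[3]
  out <- array(0, dim = c(nd + 1, n1, n2))
  if (is.complex(diff_arr)) out <- out + 0i
  out[1, , ] <- -diff_arr[1, , ]
  if (nd >= 2)
    out[2:nd, , ] <- diff_arr[1:(nd - 1), , , drop = FALSE] -
      diff_arr[2:nd, , , drop = FALSE]
  out[nd + 1, , ] <- diff_arr[nd, , ]
  out
}

#' Reconstruction configuration
#'
#' @param lambda_tv weight of the temporal total-variation penalty relative
#'   to the normalized data-fidelity scale (default 0.1).
#' @param max_iters maximum conjugate-gradient iterations (default 60).
#' @param tv_epsilon smoothing constant of the l1 surrogate
#'   \eqn{\sum\sqrt{|d|^2+\epsilon^2}}, as a fraction of the normalized
#'   signal scale (default 1e-6).
#' @param grad_tol relative gradient-norm stopping tolerance (default 1e-5).
#' @param data_scale_mode \code{"p98"} (default): k-space is scaled so the
#'   density-compensated adjoint image has unit 98th-percentile magnitude,
#'   making \code{lambda_tv} scale-free; \code{"none"}: no normalization.
#' @return object of class \code{recon_config}.
#' @export
recon_config <- function(lambda_tv = 0.1, max_iters = 60, tv_epsilon = 1e-6,
                         grad_tol = 1e-5, data_scale_mode = c("p98", "none")) {
  stopifnot(lambda_tv >= 0, tv_epsilon > 0, max_iters >= 1)
  structure(list(lambda_tv = lambda_tv, max_iters = as.integer(max_iters),
                 tv_epsilon = tv_epsilon, grad_tol = grad_tol,
                 data_scale_mode = match.arg(data_scale_mode)),
            class = "recon_config")
}

#' k-t sparse SENSE reconstruction
#'
#' Minimizes \eqn{\|k - SFI\|_2^2 + \lambda\,\|TV_{TI}(I)\|_1} over the image
#' series I, with the l1 term smoothed as \eqn{\sum\sqrt{|d|^2+\epsilon^2}},
#' by nonlinear conjugate gradient (Polak-Ribiere) with backtracking line
#' search. The solver is deterministic: fixed inputs give bit-identical
#' output. Initialization is the density-compensated adjoint.
#'
#' @param kspace a (typically padded) \code{kspace_series}.
#' @param coils a \code{\link{make_coil_maps}} object.
#' @param cfg a \code{\link{recon_config}}.
#' @param op optionally a prebuilt \code{\link{encoding_operator}} (reused
#'   across reconstructions of the same geometry).
#' @param verbose print objective every 10 iterations.
#' @return an \code{\link{image_series}} of complex frames (padded length),
#'   with attributes \code{objective_trace} (numeric vector) and
#'   \code{data_scale}.
#' @export
solve_ktsparse <- function(kspace, coils, cfg = recon_config(), op = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(kspace, "kspace_series"))
  if (is.null(op)) op <- encoding_operator(kspace, coils)
  nf <- op$n_frames
  k <- kspace$data
  # scale normalization so lambda has a fixed meaning
  init <- op$adjoint_dcf(k)
  scale <- 1
  if (cfg$data_scale_mode == "p98") {
    scale <- stats::quantile(abs(init), 0.98, names = FALSE)
    if (scale <= 0) scale <- 1
  }
  k <- k / scale
  x <- init / scale
  lam <- cfg$lambda_tv
  eps2 <- cfg$tv_epsilon^2
  # Parseval factor: the unnormalized transform satisfies ||F I||^2 =
  # N^2 ||I||^2 on a full grid, so the data fidelity is expressed in image
  # units to make lambda a scale-free weight between fidelity and TV
  fsc <- 1 / op$matrix^2

  objfun <- function(res, d) {
    fsc * sum(abs(res)^2) + lam * sum(sqrt(abs(d)^2 + eps2))
  }
  gradfun <- function(res, d) {
    g <- op$adjoint(res)
    gt <- temporal_tv_adjoint(d / sqrt(abs(d)^2 + eps2))
    2 * fsc * g + lam * gt
  }

  Ex <- op$forward(x)
  res <- Ex - k
  d <- temporal_tv(x)
  obj <- objfun(res, d)
  trace <- obj
  g <- gradfun(res, d)
  g0n <- sqrt(sum(abs(g)^2))
  dir <- -g
  Edir <- op$forward(dir)
  Ddir <- temporal_tv(dir)

  for (it in seq_len(cfg$max_iters)) {
    # backtracking line search along dir; E and D of x updated incrementally
    gdotd <- Re(sum(Conj(g) * dir))
    t0 <- 1
    # scale initial step to the problem (exact minimizer of the quadratic part)
    denom <- 2 * fsc * sum(abs(Edir)^2)
    if (denom > 0) t0 <- max(-gdotd / denom, 1e-12)
    alpha <- t0
    ok <- FALSE
    for (ls in 1:20) {
      obj_new <- objfun(res + alpha * Edir, d + alpha * Ddir)
      if (obj_new <= obj + 1e-4 * alpha * gdotd) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) {
      if (obj_new > obj) break  # no further descent representable
    }
    x <- x + alpha * dir
    Ex <- Ex + alpha * Edir
    res <- Ex - k
    d <- d + alpha * Ddir
    obj <- objfun(res, d)
    trace <- c(trace, obj)
    g_new <- gradfun(res, d)
    gn <- sqrt(sum(abs(g_new)^2))
    if (verbose && it %% 10 == 0)
      message(sprintf("iter %3d  obj %.6g  |g| %.3g", it, obj, gn))
    if (gn < cfg$grad_tol * g0n) { g <- g_new; break }
    beta <- max(0, Re(sum(Conj(g_new) * (g_new - g))) / sum(abs(g)^2))
    dir <- -g_new + beta * dir
    g <- g_new
    if (Re(sum(Conj(g) * dir)) >= 0) dir <- -g  # restart if not descent
    Edir <- op$forward(dir)
    Ddir <- temporal_tv(dir)
  }
  out <- image_series(x * scale, fov_mm = kspace$traj$fov_mm,
                      res_mm = kspace$traj$res_mm,
                      frame_roles = kspace$frame_roles)
  attr(out, "objective_trace") <- trace
  attr(out, "data_scale") <- scale
  out
}

#' Density-compensated adjoint (gridding) reconstruction
#'
#' The non-iterative baseline: coil-combined, density-compensated adjoint
#' NUFFT of each frame. Also used to initialize \code{\link{solve_ktsparse}}.
#'
#' @inheritParams solve_ktsparse
#' @return an \code{\link{image_series}} of complex frames.
#' @export
recon_adjoint <- function(kspace, coils, op = NULL) {
  if (is.null(op)) op <- encoding_operator(kspace, coils)
  image_series(op$adjoint_dcf(kspace$data), fov_mm = kspace$traj$fov_mm,
               res_mm = kspace$traj$res_mm, frame_roles = kspace$frame_roles)
}

#' Align global phase and take the signed-real part of a complex series
#'
#' Inversion-recovery fitting needs signed signal. The reconstruction is
#' complex; the per-pixel background phase is estimated from the last frame
#' (blood near equilibrium, everything positive) and conjugated away from all
#' frames, after which the real part carries the signed longitudinal signal.
#'
#' @param series complex \code{\link{image_series}}.
#' @param reference_frame frame index supplying the phase map (default: last
#'   frame).
#' @return real-valued \code{\link{image_series}}.
#' @export
signed_real_series <- function(series, reference_frame = NULL) {
  dat <- series$data
  nf <- dim(dat)[1]
  if (is.null(reference_frame)) reference_frame <- nf
  ref <- dat[reference_frame, , ]
  ph <- exp(-1i * Arg(ref))
  ph[abs(ref) == 0] <- 1 + 0i
  out <- array(0, dim = dim(dat))
  for (f in seq_len(nf)) out[f, , ] <- Re(dat[f, , ] * ph)
  image_series(out, series$fov_mm, series$res_mm, series$frame_roles)
}

#' Frequency-segmented off-resonance deblurring
#'
#' Spiral readouts blur off-resonant spins because phase accrues along the
#' readout time, which for a center-out spiral maps monotonically onto the
#' k-space radius. The correction demodulates each frame at \code{n_bins}
#' frequencies spanning the B0 map's range using the time-vs-radius kernel
#' derived from the trajectory, reconstructs each demodulated copy, and
#' combines them per pixel by linear interpolation at the local off-resonance
#' frequency. At zero offset the correction is an exact identity.
#'
#' @param series an \code{\link{image_series}} (complex or real frames).
#' @param b0_map_hz N x N off-resonance map in Hz.
#' @param traj the spiral trajectory used for acquisition (supplies the
#'   time-vs-radius mapping).
#' @param n_bins number of demodulation frequencies (default 9).
#' @return deblurred \code{\link{image_series}}.
#' @export
deblur_offres <- function(series, b0_map_hz, traj, n_bins = 9) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  dat <- series$data
  nf <- dim(dat)[1]; n <- dim(dat)[2]
  if (!all(dim(b0_map_hz) == c(n, n)))
    stop("b0 map matrix does not match image matrix")
  f_lo <- min(b0_map_hz); f_hi <- max(b0_map_hz)
  if (f_hi == f_lo) { f_lo <- f_lo - 0.5; f_hi <- f_hi + 0.5 }
  freqs <- seq(f_lo, f_hi, length.out = max(n_bins, 2))
  if (n_bins == 1) freqs <- rep(mean(c(f_lo, f_hi)), 2)

  # time map on the Cartesian grid of the frame's FFT: t(|k|) from the arm
  ctr <- floor(n / 2)
  kxg <- outer(rep(1, n), 0:(n - 1) - ctr)
  kyg <- outer(0:(n - 1) - ctr, rep(1, n))
  kr <- sqrt(kxg^2 + kyg^2)
  tmap_ms <- stats::approx(traj$r, traj$t_ms, xout = pmin(kr, max(traj$r)),
                           rule = 2)$y
  tmap_ms <- matrix(tmap_ms, n, n)
  # fftshifted version matching stats::fft of a centered image
  shift_idx <- ((0:(n - 1) + ctr) %% n) + 1L
  tmap_f <- tmap_ms[shift_idx, shift_idx]

  out <- array(if (is.complex(dat)) 0 + 0i else 0, dim = dim(dat))
  nb <- length(freqs)
  for (f in seq_len(nf)) {
    img <- matrix(dat[f, , ], n, n)
    wasreal <- !is.complex(img)
    K <- stats::fft(img)
    cand <- array(0 + 0i, dim = c(nb, n, n))
    for (b in seq_len(nb)) {
      Kb <- K * exp(2i * pi * freqs[b] * (tmap_f / 1000))
      cand[b, , ] <- stats::fft(Kb, inverse = TRUE) / (n * n)
    }
    # per-pixel linear interpolation at the local frequency
    pos <- (b0_map_hz - freqs[1]) / (freqs[nb] - freqs[1]) * (nb - 1) + 1
    pos <- pmin(pmax(pos, 1), nb)
    lo <- pmin(floor(pos), nb - 1); w <- pos - lo
    res <- matrix(0 + 0i, n, n)
    for (b in seq_len(nb)) {
      sel_lo <- lo == b
      if (any(sel_lo)) {
        cb <- matrix(cand[b, , ], n, n)
        cb1 <- matrix(cand[min(b + 1, nb), , ], n, n)
        res[sel_lo] <- (1 - w[sel_lo]) * cb[sel_lo] + w[sel_lo] * cb1[sel_lo]
      }
    }
    out[f, , ] <- if (wasreal) Re(res) else res
  }
  image_series(out, series$fov_mm, series$res_mm, series$frame_roles)
}
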