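#' Rigid frame-to-frame registration of an image series
#'
#' Registers each frame to its predecessor over a small square region around
#' the target vessel (default 20 x 20 mm) using a rigid transform
#' (translation + rotation), mean-squared-error metric on magnitude images,
#' and fixed-step gradient descent with step halving on non-improvement.
#' Per-frame transforms are composed cumulatively so every frame is aligned
#' to frame 1, then the full frames are resampled with bilinear
#' interpolation.
#'
#' @param series an \code{\link{image_series}}.
#' @param roi_center c(row, col) pixel coordinates of the region center.
#' @param roi_mm region size in mm (default c(20, 20)).
#' @param max_iters optimizer iterations per frame pair (default 60).
#' @return list with \code{series} (resampled \code{\link{image_series}})
#'   and \code{transforms}: per-frame c(tx, ty, theta_deg) mapping each
#'   frame into frame 1's coordinates (frame 1 is identity).
#' @export
register_frames <- function(series, roi_center, roi_mm = c(20, 20),
                            max_iters = 60) {
  dat <- series$data
  nf <- dim(dat)[1]; n <- dim(dat)[2]
  if (nf < 2) stop("registration needs at least 2 frames")
  res_mm <- if (is.na(series$res_mm)) 1 else series$res_mm
  half <- pmax(1, round(roi_mm / res_mm / 2))
  r0 <- roi_center[1]; c0 <- roi_center[2]
  rows <- (r0 - half[1]):(r0 + half[1])
  cols <- (c0 - half[2]):(c0 + half[2])
  if (min(rows) < 1 || max(rows) > n || min(cols) < 1 || max(cols) > n)
    stop("registration ROI extends outside the image")

  mag <- abs(dat)
  # crop to the ROI plus a margin covering the optimizer's capture range:
  # the metric never looks outside it, so resampling the full frame per
  # objective evaluation would be wasted work
  m <- 8L
  cr <- max(1, min(rows) - m):min(n, max(rows) + m)
  cc <- max(1, min(cols) - m):min(n, max(cols) + m)
  rsub <- match(rows, cr); csub <- match(cols, cc)
  psub <- c(r0 - cr[1] + 1, c0 - cc[1] + 1)
  sm <- vector("list", nf)
  for (f in seq_len(nf)) sm[[f]] <- .smooth3(matrix(mag[f, , ], n, n))[cr, cc]
  transforms <- matrix(0, nf, 3)
  pair_prev <- c(0, 0, 0)
  for (f in 2:nf) {
    tf <- .register_pair(sm[[f - 1]], sm[[f]], rsub, csub, psub, max_iters)
    # temporal consistency: an apparent frame-to-frame motion must be
    # corroborated by registering across the skipped predecessor, otherwise
    # it is an isolated false match (low-contrast frame, rotating
    # undersampling artifacts) and reverts to identity
    if (f >= 3 && any(tf != 0)) {
      skip <- .register_pair(sm[[f - 2]], sm[[f]], rsub, csub, psub,
                             max_iters)
      pred <- .compose_rigid(pair_prev, tf, c(r0, c0))
      if (max(abs(skip[1:2] - pred[1:2])) > 0.5 ||
          abs(skip[3] - pred[3]) > 1)
        tf <- c(0, 0, 0)
    }
    pair_prev <- tf
    transforms[f, ] <- .compose_rigid(transforms[f - 1, ], tf, c(r0, c0))
  }
  out <- array(if (is.complex(dat)) 0 + 0i else 0, dim = dim(dat))
  out[1, , ] <- dat[1, , ]
  for (f in 2:nf)
    out[f, , ] <- .resample_rigid(matrix(dat[f, , ], n, n), transforms[f, ],
                                  c(r0, c0))
  list(series = image_series(out, series$fov_mm, series$res_mm,
                             series$frame_roles),
       transforms = transforms)
}

# optimize (tx, ty, theta_deg) minimizing MSE of resampled moving vs fixed in
# the ROI; regular-step gradient descent: move along the normalized gradient
# with the current step length, halve the step whenever the move fails to
# improve, stop when the step underflows
.register_pair <- function(fixed, moving, rows, cols, pivot, max_iters) {
  # z-normalized MSE (equivalent to maximizing normalized cross-correlation):
  # consecutive inversion-recovery frames differ in global intensity as the
  # signal recovers, which biases a raw-MSE metric toward brightness-
  # compensating shifts; normalization removes that confound
  fz <- as.vector(fixed[rows, cols])
  fz <- (fz - mean(fz)) / stats::sd(fz)
  obj <- function(p) {
    m <- .resample_rigid(moving, p, pivot)
    mz <- as.vector(m[rows, cols])
    s <- stats::sd(mz)
    if (s == 0) return(2)
    mz <- (mz - mean(mz)) / s
    mean((mz - fz)^2)
  }
  # coarse integer-translation search to step over local ripples; a jump is
  # accepted only on a clear improvement so a flat noisy landscape does not
  # produce spurious integer shifts
  p <- c(0, 0, 0)
  f0 <- obj(p)
  fcur <- f0
  for (dr in -3:3) for (dc in -3:3) {
    f <- obj(c(dr, dc, 0))
    if (f < 0.8 * f0 && f < fcur) { p <- c(dr, dc, 0); fcur <- f }
  }
  step <- 0.25                # px / deg
  min_step <- 1e-3
  h <- c(0.02, 0.02, 0.02)
  # minimum meaningful improvement: moves along flat (ill-constrained)
  # directions whose only gain is noise-level must not be accepted, or an
  # unconstrained parameter (e.g. rotation of a near-symmetric ROI) random-
  # walks away from identity
  thr <- 1e-3 * f0
  for (it in seq_len(max_iters)) {
    g <- numeric(3)
    for (j in 1:3) {
      pp <- p; pp[j] <- pp[j] + h[j]
      pm <- p; pm[j] <- pm[j] - h[j]
      g[j] <- (obj(pp) - obj(pm)) / (2 * h[j])
    }
    gn <- sqrt(sum(g^2))
    if (gn < 1e-14) break
    pnew <- p - step * g / gn
    fnew <- obj(pnew)
    if (fnew < fcur - thr) {
      p <- pnew; fcur <- fnew
    } else {
      step <- step / 2
      if (step < min_step) break
    }
  }
  # cyclic per-coordinate polish: the joint normalized gradient can starve a
  # parameter whose gradient magnitude is much smaller (rotation vs shifts);
  # small steps keep the polish from wandering on a noise-dominated landscape
  steps <- c(0.05, 0.05, 0.05)
  for (round in 1:20) {
    moved <- FALSE
    for (j in 1:3) {
      repeat {
        improved <- FALSE
        for (s in c(steps[j], -steps[j])) {
          pp <- p; pp[j] <- pp[j] + s
          f <- obj(pp)
          if (f < fcur - thr) { p <- pp; fcur <- f; improved <- TRUE; moved <- TRUE; break }
        }
        if (!improved) break
      }
      steps[j] <- steps[j] / 2
    }
    if (max(steps) < min_step && !moved) break
  }
  # parsimony per coordinate: a parameter whose removal costs no meaningful
  # part of the achieved improvement is fitting noise (e.g. rotation of a
  # near-symmetric ROI is unidentifiable) and reverts to zero
  # rotation needs stronger evidence than the shifts: from a small patch it
  # is near-unidentifiable and overfits noise readily
  par_thr <- c(0.02, 0.02, 0.10) * f0
  for (j in c(3, 1, 2)) {
    if (p[j] == 0) next
    ptest <- p; ptest[j] <- 0
    if (obj(ptest) - fcur <= par_thr[j]) { p <- ptest; fcur <- obj(ptest) }
  }
  # reliability gate: if the optimized transform explains no meaningful part
  # of the initial mismatch, the ROI carries no registrable structure for
  # this pair (e.g. the vessel is near its inversion null) and the honest
  # answer is "no detectable motion"
  if (f0 - fcur < 0.1 * f0) return(c(0, 0, 0))
  # sub-resolution deadband: inversion recovery itself shifts the apparent
  # vessel centroid by fractions of a pixel as the signal re-emerges through
  # its null (point-spread and partial-volume physics, not motion); pair
  # corrections below the deadband would track that creep and corrupt the
  # signal curve, so frame-to-frame motion smaller than 0.3 px / 0.3 deg is
  # treated as undetectable
  if (max(abs(p[1:2])) < 0.3 && abs(p[3]) < 0.3) return(c(0, 0, 0))
  p
}

# compose two rigid transforms (both about the same pivot):
# result maps moving -> frame1 given t1 (prev frame -> frame1) and
# t2 (moving -> prev frame)
.compose_rigid <- function(t1, t2, pivot) {
  th1 <- t1[3] * pi / 180; th2 <- t2[3] * pi / 180
  # x' = R1 (R2 x + d2) + d1 = R1 R2 x + (R1 d2 + d1), all about the pivot
  R1 <- matrix(c(cos(th1), sin(th1), -sin(th1), cos(th1)), 2, 2)
  d2 <- c(t2[1], t2[2])
  d <- as.vector(R1 %*% d2) + c(t1[1], t1[2])
  c(d[1], d[2], t1[3] + t2[3])
}

# resample image under rigid transform p = (tx_rows, ty_cols, theta_deg)
# about the pivot; output(x) = input(R^-1 (x - pivot) - t + pivot), bilinear
.resample_rigid <- function(img, p, pivot) {
  n1 <- nrow(img); n2 <- ncol(img)
  th <- -p[3] * pi / 180
  rr <- outer(seq_len(n1) - pivot[1], rep(1, n2))
  cc <- outer(rep(1, n1), seq_len(n2) - pivot[2])
  sr <- cos(th) * rr - sin(th) * cc - p[1] + pivot[1]
  sc <- sin(th) * rr + cos(th) * cc - p[2] + pivot[2]
  .bilinear(img, sr, sc)
}

# separable 1-2-1 binomial smoothing (noise suppression for the metric only)
.smooth3 <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  up <- img[c(1, 1:(n1 - 1)), ]; dn <- img[c(2:n1, n1), ]
  img <- (up + 2 * img + dn) / 4
  lf <- img[, c(1, 1:(n2 - 1))]; rt <- img[, c(2:n2, n2)]
  (lf + 2 * img + rt) / 4
}

.bilinear <- function(img, sr, sc) {
  n1 <- nrow(img); n2 <- ncol(img)
  r0 <- pmin(pmax(floor(sr), 1), n1 - 1)
  c0 <- pmin(pmax(floor(sc), 1), n2 - 1)
  fr <- sr - r0; fc <- sc - c0
  idx <- function(r, c) img[cbind(as.vector(r), as.vector(c))]
  out <- (1 - fr) * (1 - fc) * idx(r0, c0) +
         (1 - fr) * fc * idx(r0, c0 + 1) +
         fr * (1 - fc) * idx(r0 + 1, c0) +
         fr * fc * idx(r0 + 1, c0 + 1)
  outside <- sr < 1 | sr > n1 | sc < 1 | sc > n2
  out[outside] <- 0
  matrix(out, n1, n2)
}

#' FWHM-style vessel segmentation
#'
#' Grows a region from a seed pixel over all 4-connected pixels whose
#' intensity is at least \code{threshold} times the peak intensity of the
#' seed's bright region. The peak is refined iteratively: the region is
#' regrown until the maximum inside it stabilizes, so the threshold is
#' relative to the vessel's own peak, not the seed value.
#'
#' @param image 2D magnitude frame.
#' @param seed c(row, col) seed pixel inside the vessel.
#' @param threshold fraction of the peak (default 0.7).
#' @return object of class \code{vessel_roi}: logical \code{mask},
#'   \code{seed}, \code{threshold}, \code{peak}, \code{n_pixels}.
#' @export
segment_fwhm <- function(image, seed, threshold = 0.7) {
  n1 <- nrow(image); n2 <- ncol(image)
  stopifnot(seed[1] >= 1, seed[1] <= n1, seed[2] >= 1, seed[2] <= n2)
  if (image[seed[1], seed[2]] <= 0)
    stop("seed pixel has non-positive intensity")
  peak <- image[seed[1], seed[2]]
  mask <- .flood4(image >= threshold * peak, seed)
  repeat {
    newpeak <- max(image[mask])
    if (newpeak <= peak) break
    peak <- newpeak
    # regrow from the region's peak pixel: the raised threshold may exclude
    # the original seed, but the bright core remains connected to the peak
    top <- which(mask & image == newpeak, arr.ind = TRUE)[1, ]
    newmask <- .flood4(image >= threshold * peak, top)
    if (!any(newmask)) break
    mask <- newmask
  }
  if (!mask[seed[1], seed[2]]) {
    # keep the seed's own component at the final threshold if disconnected
    if (image[seed[1], seed[2]] >= threshold * peak)
      mask <- mask | .flood4(image >= threshold * peak, seed)
  }
  structure(list(mask = mask, seed = seed, threshold = threshold,
                 peak = peak, n_pixels = sum(mask)),
            class = "vessel_roi")
}

# 4-connected flood fill of 'ok' starting at seed
.flood4 <- function(ok, seed) {
  n1 <- nrow(ok); n2 <- ncol(ok)
  mask <- matrix(FALSE, n1, n2)
  if (!ok[seed[1], seed[2]]) return(mask)
  stack <- matrix(seed, 1, 2)
  mask[seed[1], seed[2]] <- TRUE
  while (nrow(stack) > 0) {
    cur <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- cur[1] + d[1]; c <- cur[2] + d[2]
      if (r >= 1 && r <= n1 && c >= 1 && c <= n2 && ok[r, c] && !mask[r, c]) {
        mask[r, c] <- TRUE
        stack <- rbind(stack, c(r, c))
      }
    }
  }
  mask
}

#' Three-parameter inversion-recovery T1 fit
#'
#' Nonlinear least squares of \eqn{M(TI) = M_0 + (M_{init} - M_0)
#' e^{-TI/T_1}} (Levenberg-Marquardt) with multi-start initialization over
#' T1 in {300, 800, 1600, 2400} ms to cover pre- and post-contrast regimes.
#' The 95\% confidence interval on T1 is linearized (Jacobian covariance at
#' the solution, t-quantile); a fit whose CI width is >= 100 ms is flagged
#' excluded. Signals are fitted as signed-real values; set
#' \code{magnitude_data = TRUE} to restore polarity first (sign flip before
#' the fitted zero-crossing).
#'
#' @param signal per-TI signal values (ROI mean), acquired frames only.
#' @param tis_ms inversion times matching \code{signal}, or a
#'   \code{\link{ti_schedule}} (its acquired TIs are used).
#' @param magnitude_data if TRUE, polarity is restored before fitting.
#' @param exclusion_ci_ms CI-width exclusion threshold (default 100).
#' @return object of class \code{t1_fit}: \code{t1_ms}, \code{m0},
#'   \code{minit}, \code{r_squared}, \code{ci95_halfwidth_ms},
#'   \code{excluded}, \code{converged}.
#' @export
fit_ir_t1 <- function(signal, tis_ms, magnitude_data = FALSE,
                      exclusion_ci_ms = 100) {
  if (inherits(tis_ms, "ti_schedule"))
    tis_ms <- tis_ms$ti_values_ms[seq_len(tis_ms$n_acquired)]
  stopifnot(length(signal) == length(tis_ms), length(signal) >= 4)

  if (magnitude_data) {
    # restore polarity: flip signs before the minimum-magnitude TI chosen by
    # the best of the candidate polarity patterns
    best <- NULL
    for (iz in seq_along(signal)) {
      s <- abs(signal)
      if (iz > 1) s[1:(iz - 1)] <- -s[1:(iz - 1)]
      f <- .fit_ir_core(s, tis_ms)
      if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
    }
    fit <- best
  } else {
    fit <- .fit_ir_core(signal, tis_ms)
  }

  if (is.null(fit)) {
    return(structure(list(t1_ms = NA_real_, m0 = NA_real_, minit = NA_real_,
                          r_squared = NA_real_, ci95_halfwidth_ms = Inf,
                          excluded = TRUE, converged = FALSE),
                     class = "t1_fit"))
  }
  ci_half <- fit$ci95_halfwidth_ms
  structure(list(t1_ms = fit$t1, m0 = fit$m0, minit = fit$minit,
                 r_squared = fit$r2, ci95_halfwidth_ms = ci_half,
                 excluded = is.na(ci_half) || 2 * ci_half >= exclusion_ci_ms,
                 converged = TRUE),
            class = "t1_fit")
}

.fit_ir_core <- function(signal, tis_ms) {
  df <- data.frame(ti = tis_ms, y = signal)
  scale <- max(abs(signal))
  if (scale == 0) return(NULL)
  best <- NULL
  for (t1_0 in c(300, 800, 1600, 2400)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ m0 + (minit - m0) * exp(-ti / t1), data = df,
        start = list(m0 = max(signal), minit = min(signal), t1 = t1_0),
        lower = c(-10 * scale, -10 * scale, 1),
        upper = c(10 * scale, 10 * scale, 1e5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      co <- stats::coef(fit)
      se <- tryCatch(sqrt(diag(stats::vcov(fit)))["t1"],
                     error = function(e) NA_real_)
      dfree <- length(signal) - 3
      tss <- sum((signal - mean(signal))^2)
      best <- list(t1 = unname(co["t1"]), m0 = unname(co["m0"]),
                   minit = unname(co["minit"]), rss = rss,
                   r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                   ci95_halfwidth_ms =
                     unname(stats::qt(0.975, dfree) * se))
    }
  }
  best
}

#' @export
print.t1_fit <- function(x, ...) {
  cat(sprintf("IR T1 fit: T1 = %.1f ms (95%% CI half-width %.1f ms)%s\n",
              x$t1_ms, x$ci95_halfwidth_ms,
              if (x$excluded) "  [EXCLUDED]" else ""))
  cat(sprintf("  M0 = %.4g, Minit = %.4g, R^2 = %.5f\n",
              x$m0, x$minit, x$r_squared))
  invisible(x)
}

#' Apply the confidence-interval exclusion rule to a set of fits
#'
#' Fits whose 95\% confidence interval on T1 is at least
#' \code{threshold_ms} wide are flagged as excluded (low fitting
#' confidence, typically small vessels).
#'
#' @param fits list of \code{\link{fit_ir_t1}} results.
#' @param threshold_ms CI width threshold in ms (default 100).
#' @return list with \code{retained}, \code{excluded} (lists of fits) and a
#'   \code{report} data frame (n_total, n_retained, n_excluded).
#' @export
exclude_low_confidence <- function(fits, threshold_ms = 100) {
  wide <- vapply(fits, function(f)
    is.na(f$ci95_halfwidth_ms) || 2 * f$ci95_halfwidth_ms >= threshold_ms,
    logical(1))
  list(retained = fits[!wide], excluded = fits[wide],
       report = data.frame(n_total = length(fits),
                           n_retained = sum(!wide),
                           n_excluded = sum(wide)))
}

#' Method-comparison statistics (regression + Bland-Altman)
#'
#' Pearson correlation, least-squares regression of b on a, and
#' Bland-Altman agreement on paired percent differences
#' \eqn{100\,(b-a)/\mathrm{mean}(a,b)}: mean bias and 1.96-SD limits of
#' agreement.
#'
#' @param t1_a,t1_b equal-length paired measurements (n >= 3).
#' @return object of class \code{comparison_stats}: \code{pearson_r},
#'   \code{slope}, \code{intercept}, \code{bias_percent}, \code{loa}
#'   (lower, upper), \code{n}.
#' @export
compare_methods <- function(t1_a, t1_b) {
  stopifnot(length(t1_a) == length(t1_b), length(t1_a) >= 3)
  if (stats::sd(t1_a) == 0 || stats::sd(t1_b) == 0)
    stop("zero-variance input: correlation undefined")
  fit <- stats::lm(t1_b ~ t1_a)
  pd <- 100 * (t1_b - t1_a) / ((t1_a + t1_b) / 2)
  bias <- mean(pd)
  s <- stats::sd(pd)
  structure(list(pearson_r = stats::cor(t1_a, t1_b),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 bias_percent = bias,
                 loa = c(bias - 1.96 * s, bias + 1.96 * s),
                 n = length(t1_a)),
            class = "comparison_stats")
}

#' @export
print.comparison_stats <- function(x, ...) {
  cat(sprintf("Method comparison (n = %d): r = %.3f, slope = %.3f, intercept = %.1f\n",
              x$n, x$pearson_r, x$slope, x$intercept))
  cat(sprintf("  Bland-Altman bias = %.2f%%, limits of agreement [%.2f%%, %.2f%%]\n",
              x$bias_percent, x$loa[1], x$loa[2]))
  invisible(x)
}
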