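test_that("golden-angle schedule follows the cumulative-increment law", {
  expect_equal(golden_angle_schedule(1)$angles_deg, 0)
  sch <- golden_angle_schedule(55)
  expect_equal(sch$angles_deg[2], 137.51)
  expect_equal(sch$angles_deg[55], 7425.54, tolerance = 1e-12)
  expect_equal(fold_angle_deg(sch$angles_deg[55]), 134.46, tolerance = 1e-9)
  expect_equal(length(sch$angles_deg), 55)
  expect_equal(sch$angles_deg, 137.51 * (0:54))
  expect_error(golden_angle_schedule(0), "positive")
  expect_error(golden_angle_schedule(-3), "positive")
})

test_that("golden-angle coverage is near-uniform for any frame count", {
  # three-distance theorem: gaps take at most three values; for the golden
  # angle the worst max/min gap ratio is the squared golden ratio (~2.62),
  # achieved away from Fibonacci counts; at a Fibonacci count (55) the
  # ratio drops to the golden ratio itself
  for (n in c(10, 55, 100)) {
    a <- sort(golden_angle_schedule(n)$angles_deg %% 360)
    gaps <- diff(c(a, a[1] + 360))
    expect_lte(length(unique(round(gaps, 6))), 3)
    expect_lt(max(gaps) / min(gaps), 3)
  }
  a55 <- sort(golden_angle_schedule(55)$angles_deg %% 360)
  g55 <- diff(c(a55, a55[1] + 360))
  expect_lt(max(g55) / min(g55), 1.7)
})

test_that("seam between last padded-source frame and frame 1 nearly preserves the increment", {
  sch <- golden_angle_schedule(55)
  seam <- fold_angle_deg(sch$angles_deg[55] - sch$angles_deg[1])
  expect_lt(abs(seam - 137.51), 4)
})

test_that("variable-density reduction factor is piecewise linear with the stated knots", {
  p <- vd_profile()
  expect_equal(reduction_factor(0.10, p), 1)
  expect_equal(reduction_factor(0.15, p), 1)
  expect_equal(reduction_factor(0.325, p), 3)
  expect_equal(reduction_factor(0.50, p), 5)
  expect_equal(reduction_factor(0.60, p), 5)
  # continuity at both knots
  expect_equal(reduction_factor(0.15 + 1e-9, p), 1, tolerance = 1e-6)
  expect_equal(reduction_factor(0.50 - 1e-9, p), 5, tolerance = 1e-6)
  expect_error(reduction_factor(-0.1, p), "\\[0, 1\\]")
  expect_error(reduction_factor(1.2, p), "\\[0, 1\\]")
})

test_that("spiral arm is center-out, monotone in radius, and reaches Nyquist", {
  traj <- design_vd_spiral(180, 180 / 96, n_samples = 4800)
  r <- sqrt(traj$kx^2 + traj$ky^2)
  expect_equal(r[1], 0)
  expect_true(all(diff(r) >= -1e-9))
  expect_equal(r[length(r)], 48)          # matrix/2
  expect_equal(max(r), 48)
})

test_that("spiral radial pitch follows the variable-density profile", {
  traj <- design_vd_spiral(180, 180 / 96, n_samples = 4800)
  # pitch = radius gained per revolution, measured from the arm itself
  phi <- seq(0, 2 * pi * 30, length.out = length(traj$kx))  # not used; use r
  r <- traj$r
  # angular position along arm is uniform; find revolution boundaries by
  # unwrapped angle
  ang <- atan2(traj$ky, traj$kx)
  unw <- ang + 2 * pi * cumsum(c(0, diff(ang) < -pi))
  pitch_at <- function(frac) {
    target <- frac * 48
    i <- which.min(abs(r - target))
    j <- which.min(abs(unw - (unw[i] + 2 * pi)))
    r[j] - r[i]
  }
  expect_equal(pitch_at(0.05), 1, tolerance = 0.1)     # Nyquist pitch, cycles/FOV
  expect_equal(pitch_at(0.8), 5, tolerance = 0.15)     # 5x at the rim
  expect_equal(pitch_at(0.8) / pitch_at(0.05), 5, tolerance = 0.15)
})

test_that("uniform-density profile gives the Nyquist-dense spiral limit", {
  p <- vd_profile(full_sample_fraction = 0.5, outer_fraction = 0.9,
                  outer_reduction = 1 + 1e-9)
  traj <- design_vd_spiral(180, 180 / 32, n_samples = 2000, profile = p)
  r <- traj$r
  ang <- atan2(traj$ky, traj$kx)
  unw <- ang + 2 * pi * cumsum(c(0, diff(ang) < -pi))
  i <- which.min(abs(r - 8))
  j <- which.min(abs(unw - (unw[i] + 2 * pi)))
  expect_equal(r[j] - r[i], 1, tolerance = 0.05)       # 1/FOV per revolution
})

test_that("infeasible sample budgets are rejected with the violated band named", {
  expect_error(design_vd_spiral(180, 1, n_samples = 30), "radius")
})

test_that("rotating an arm forward and back restores it to floating tolerance", {
  traj <- design_vd_spiral(180, 180 / 32, n_samples = 600)
  sch <- golden_angle_schedule(3, increment_deg = 51.7)
  rot <- rotate_arm(traj, sch)
  th <- -sch$angles_deg[3] * pi / 180
  kx_back <- cos(th) * rot$coords[3, , 1] - sin(th) * rot$coords[3, , 2]
  ky_back <- sin(th) * rot$coords[3, , 1] + cos(th) * rot$coords[3, , 2]
  expect_lt(max(abs(kx_back - traj$kx)) / max(abs(traj$kx)), 1e-12)
  expect_lt(max(abs(ky_back - traj$ky)) / max(abs(traj$ky)), 1e-12)
  # frame f equals frame 1 rotated by angles[f]
  expect_equal(rot$coords[1, , 1], traj$kx)
})

test_that("density compensation matches the annular-area law away from the center", {
  traj <- design_vd_spiral(180, 180 / 96, n_samples = 4800)
  w <- density_compensation(traj)
  expect_true(all(w >= 0))
  r <- traj$r; dr <- c(diff(r), NA)
  # oracle: w proportional to |k| d|k| (annular area element)
  mid <- which(r > 10 & r < 40)
  ratio <- w[mid] / (r[mid] * dr[mid])
  expect_lt(stats::sd(ratio) / mean(ratio), 0.05)
  # rim/center weight ratio tracks the local pitch ratio
  i_in <- which.min(abs(r - 5)); i_out <- which.min(abs(r - 45))
  expect_equal((w[i_out] / r[i_out]) / (w[i_in] / r[i_in]), 5,
               tolerance = 0.2)
})

test_that("density-compensated adjoint recovers a centered point source", {
  n <- 32
  traj <- design_vd_spiral(180, 180 / n, n_samples = 1200)
  w <- density_compensation(traj)
  # point source at the matrix center: all k-space samples equal its amplitude
  amp <- 2.5
  s <- rep(amp + 0i, length(traj$kx))
  img <- nudft_adjoint(w * s, traj$kx, traj$ky, n) / n^2
  peak <- which(abs(img) == max(abs(img)), arr.ind = TRUE)
  ctr <- floor(n / 2) + 1
  expect_equal(as.vector(peak[1, ]), c(ctr, ctr))      # zero pixel error
  expect_equal(Mod(img[ctr, ctr]), amp, tolerance = 0.05)
})

test_that("degenerate all-zero trajectories are rejected", {
  traj <- design_vd_spiral(180, 180 / 32, n_samples = 600)
  traj$r <- traj$r * 0
  expect_error(density_compensation(traj), "degenerate")
})

test_that("effective acceleration reports Nyquist-per-acquired sample count", {
  traj <- design_vd_spiral(180, 1, n_samples = 4800)
  expect_equal(effective_acceleration(traj), pi * 90^2 / 4800)
  expect_gt(effective_acceleration(traj), 5)
})
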