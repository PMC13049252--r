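test_that("direct NUDFT obeys DFT identities on small grids", {
  n <- 16
  d <- matrix(0 + 0i, n, n); d[floor(n / 2) + 1, floor(n / 2) + 1] <- 1
  set.seed(1)
  kx <- runif(100, -8, 8); ky <- runif(100, -8, 8)
  expect_equal(Mod(nudft_forward(d, kx, ky)), rep(1, 100), tolerance = 1e-12)
  u <- matrix(1 + 0i, n, n)
  expect_equal(nudft_forward(u, 0, 0), complex(real = n * n),
               tolerance = 1e-9)
  big <- matrix(0 + 0i, 65, 65)
  expect_error(nudft_forward(big, 0, 0), "fast")
  expect_error(nudft_adjoint(1 + 0i, 0, 0, 65), "fast")
})

test_that("fast gridding NUFFT matches the direct oracle", {
  set.seed(2)
  n <- 16
  img <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  rr <- sqrt(runif(300)) * n / 2; th <- runif(300, 0, 2 * pi)
  kx <- rr * cos(th); ky <- rr * sin(th)
  pl <- nufft_plan(kx, ky, n)
  s_fast <- nufft_forward(img, pl)
  s_exact <- nudft_forward(img, kx, ky)
  expect_lt(max(Mod(s_fast - s_exact)) / max(Mod(s_exact)), 1e-3)
  y <- complex(real = rnorm(300), imaginary = rnorm(300))
  a_fast <- nufft_adjoint(y, pl)
  a_exact <- nudft_adjoint(y, kx, ky, n)
  expect_lt(max(Mod(a_fast - a_exact)) / max(Mod(a_exact)), 1e-3)
})

test_that("forward and adjoint transforms are exact conjugate-transpose pairs", {
  set.seed(3)
  n <- 16
  img <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  rr <- sqrt(runif(200)) * n / 2; th <- runif(200, 0, 2 * pi)
  kx <- rr * cos(th); ky <- rr * sin(th)
  y <- complex(real = rnorm(200), imaginary = rnorm(200))
  nrm <- sqrt(sum(Mod(img)^2)) * sqrt(sum(Mod(y)^2))
  pl <- nufft_plan(kx, ky, n)
  lhs <- sum(Conj(y) * nufft_forward(img, pl))
  rhs <- sum(Conj(nufft_adjoint(y, pl)) * img)
  expect_lt(Mod(lhs - rhs) / nrm, 1e-6)
  lhs2 <- sum(Conj(y) * nudft_forward(img, kx, ky))
  rhs2 <- sum(Conj(nudft_adjoint(y, kx, ky, n)) * img)
  expect_lt(Mod(lhs2 - rhs2) / nrm, 1e-6)
})

test_that("the multi-coil encoding operator passes the adjoint test", {
  st <- small_study()
  op <- encoding_operator(st$ksp, st$coils)
  set.seed(4)
  nf <- op$n_frames; n <- op$matrix
  x <- array(complex(real = rnorm(nf * n * n),
                     imaginary = rnorm(nf * n * n)), dim = c(nf, n, n))
  y <- array(complex(real = rnorm(nf * op$n_coils * op$n_samples),
                     imaginary = rnorm(nf * op$n_coils * op$n_samples)),
             dim = c(nf, op$n_coils, op$n_samples))
  lhs <- sum(Conj(y) * op$forward(x))
  rhs <- sum(Conj(op$adjoint(y)) * x)
  expect_lt(Mod(lhs - rhs) / (sqrt(sum(Mod(x)^2)) * sqrt(sum(Mod(y)^2))),
            1e-6)
})

test_that("sign-inverted periodic padding has the specified layout", {
  st <- small_study()       # 8 acquired + 2 appended, 2 prepended
  pad <- pad_frames(st$ksp)
  expect_equal(dim(pad$data)[1], 12)
  expect_equal(pad$frame_signs, c(-1, -1, rep(1, 10)))
  # prepended frame 1 is the negated source frame 9 (= nf - np)
  expect_true(all(pad$data[1, , ] + st$ksp$data[9, , ] == 0))
  expect_true(all(pad$data[2, , ] + st$ksp$data[10, , ] == 0))
  # trajectory angles carried over from the source frames
  expect_equal(pad$angles_deg[1:2], st$ksp$angles_deg[9:10])
  expect_equal(pad$angles_deg[3:12], st$ksp$angles_deg)
  # round trip is bitwise
  expect_identical(unpad_kspace(pad)$data, st$ksp$data)
  expect_error(pad_frames(pad), "frames")
})

test_that("default-protocol padding yields 59 frames", {
  sch <- ti_schedule()
  expect_equal(sch$n_shot + sch$n_prepended, 59)
})

test_that("temporal TV operator and adjoint are exact companions", {
  set.seed(5)
  x <- array(rnorm(6 * 4 * 4), dim = c(6, 4, 4))
  d <- temporal_tv(x)
  expect_equal(dim(d)[1], 5)
  # constant series differentiates to zero
  cst <- array(2.2, dim = c(6, 4, 4))
  expect_true(all(temporal_tv(cst) == 0))
  # a single bumped frame yields exactly two nonzero differences
  bump <- cst; bump[3, 2, 2] <- 2.2 + 0.7
  db <- temporal_tv(bump)
  expect_equal(sum(db != 0), 2)
  expect_equal(sort(db[db != 0]), c(-0.7, 0.7))
  # adjoint identity
  y <- array(rnorm(5 * 4 * 4), dim = c(5, 4, 4))
  expect_lt(abs(sum(d * y) - sum(x * temporal_tv_adjoint(y))), 1e-10)
  expect_error(temporal_tv(array(1, dim = c(1, 4, 4))), "2 frames")
})

test_that("with no regularization and full Cartesian sampling the solver inverts exactly", {
  n <- 16
  grid <- expand.grid(kx = -8:7, ky = -8:7)
  traj <- structure(list(kx = grid$kx, ky = grid$ky,
                         r = sqrt(grid$kx^2 + grid$ky^2),
                         t_ms = seq(0, 12, length.out = 256),
                         dcf = rep(1, 256), fov_mm = 16, res_mm = 1,
                         matrix = n, readout_ms = 12, profile = NULL),
                    class = "spiral_trajectory")
  sch <- ti_schedule(n_acquired = 2, n_appended = 0, n_prepended = 0)
  set.seed(6)
  imgs <- array(complex(real = rnorm(2 * n * n),
                        imaginary = rnorm(2 * n * n)), dim = c(2, n, n))
  dat <- array(0 + 0i, dim = c(2, 1, 256))
  for (f in 1:2)
    dat[f, 1, ] <- nudft_forward(matrix(imgs[f, , ], n, n), grid$kx, grid$ky)
  ksp <- structure(list(data = dat, frame_signs = c(1, 1), schedule = sch,
                        traj = traj, angles_deg = c(0, 0),
                        frame_roles = rep("acquired", 2)),
                   class = "kspace_series")
  coils <- make_coil_maps(n, 1)
  op <- encoding_operator(ksp, coils, method = "nudft")
  rec <- solve_ktsparse(ksp, coils, recon_config(lambda_tv = 0), op = op)
  expect_lt(nrmse(rec$data, imgs), 1e-6)
})

test_that("the solver is deterministic and monotone in its objective", {
  st <- small_study(noise_sigma = 1, seed = 9)
  pad <- pad_frames(st$ksp)
  cfg <- recon_config(max_iters = 15)
  r1 <- solve_ktsparse(pad, st$coils, cfg)
  r2 <- solve_ktsparse(pad, st$coils, cfg)
  expect_identical(r1$data, r2$data)
  tr <- attr(r1, "objective_trace")
  expect_true(all(diff(tr) <= 1e-9 * tr[1]))
})

test_that("iterative reconstruction beats the gridding baseline", {
  st <- small_study()       # noiseless
  pad <- pad_frames(st$ksp)
  op <- encoding_operator(pad, st$coils)
  rec <- solve_ktsparse(pad, st$coils, recon_config(max_iters = 30), op = op)
  adj <- recon_adjoint(pad, st$coils, op = op)
  truth_acq <- st$truth$data[1:8, , ]
  rec_acq <- unpad_series(signed_real_series(rec))$data
  adj_acq <- unpad_series(signed_real_series(adj))$data
  expect_lt(nrmse(rec_acq, truth_acq), nrmse(adj_acq, truth_acq))
})

test_that("stronger temporal TV weights monotonically quiet the background", {
  st <- small_study(noise_sigma = 1, seed = 12)
  pad <- pad_frames(st$ksp)
  op <- encoding_operator(pad, st$coils)
  bg <- st$phm$vessel_labels == 0 & st$phm$m0_map > 0
  tvar <- function(lam) {
    rec <- solve_ktsparse(pad, st$coils,
                          recon_config(lambda_tv = lam, max_iters = 25),
                          op = op)
    sr <- unpad_series(signed_real_series(rec))$data
    mean(apply(sr, c(2, 3), stats::var)[bg])
  }
  v <- c(tvar(0), tvar(0.1), tvar(1))
  expect_gt(v[1], v[2])
  expect_gt(v[2], v[3])
})

test_that("phase alignment restores signed-real inversion recovery", {
  st <- small_study()
  pad <- pad_frames(st$ksp)
  rec <- solve_ktsparse(pad, st$coils, recon_config(max_iters = 30))
  sr <- unpad_series(signed_real_series(rec))
  v <- st$phm$vessel_labels == 1
  sig <- vapply(1:8, function(f) mean(sr$data[f, , ][v]), numeric(1))
  truth <- vapply(1:8, function(f) mean(st$truth$data[f, , ][v]), numeric(1))
  expect_lt(sig[1], 0)              # early TI is inverted
  expect_gt(sig[8], 0)              # late TI recovered
  expect_equal(sign(sig), sign(truth))
})

test_that("off-resonance deblurring is identity at zero offset", {
  st <- small_study()
  ser <- image_series(st$truth$data[1:2, , ] + 0i)
  out <- deblur_offres(ser, matrix(0, 32, 32), st$traj, n_bins = 9)
  expect_lt(max(Mod(out$data - ser$data)), 1e-8)
  expect_error(deblur_offres(ser, matrix(0, 32, 32), st$traj, n_bins = 0),
               "n_bins")
  expect_error(deblur_offres(ser, matrix(0, 16, 16), st$traj, 9), "matrix")
})

test_that("uniform off-resonance reduces to exact single-frequency demodulation", {
  st <- small_study()
  n <- 32; df <- 40
  ser <- image_series(st$truth$data[1, , , drop = FALSE] + 0i)
  out <- deblur_offres(ser, matrix(df, n, n), st$traj, n_bins = 9)
  # independent closed-form demodulation oracle on the Cartesian spectrum
  ctr <- floor(n / 2)
  kr <- sqrt(outer(rep(1, n), (0:(n - 1) - ctr))^2 +
             outer((0:(n - 1) - ctr), rep(1, n))^2)
  tmap <- matrix(stats::approx(st$traj$r, st$traj$t_ms,
                               pmin(kr, max(st$traj$r)), rule = 2)$y, n, n)
  sh <- ((0:(n - 1) + ctr) %% n) + 1
  K <- stats::fft(matrix(ser$data[1, , ], n, n))
  oracle <- stats::fft(K * exp(2i * pi * df * (tmap[sh, sh] / 1000)),
                       inverse = TRUE) / (n * n)
  expect_lt(max(Mod(out$data[1, , ] - oracle)), 1e-6)
})

test_that("deblurring restores most of an off-resonant point source", {
  n <- 32
  traj <- design_vd_spiral(180, 180 / n, n_samples = 1200)
  w <- density_compensation(traj)
  delta <- matrix(0 + 0i, n, n)
  ctr <- floor(n / 2) + 1
  delta[ctr, ctr] <- 1
  blur_recon <- function(b0) {
    s <- spiralT1:::.forward_offres(delta, traj$kx, traj$ky,
                                    matrix(b0, n, n), traj$t_ms)
    nudft_adjoint(w * s, traj$kx, traj$ky, n) / n^2
  }
  on_res <- blur_recon(0)
  off <- blur_recon(50)
  expect_lt(Mod(off[ctr, ctr]), 0.9 * Mod(on_res[ctr, ctr]))  # blur is real
  ser <- image_series(array(off, dim = c(1, n, n)))
  fix <- deblur_offres(ser, matrix(50, n, n), traj, n_bins = 9)
  expect_gte(Mod(fix$data[1, ctr, ctr]), 0.9 * Mod(on_res[ctr, ctr]))
})
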