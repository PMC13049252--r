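test_that("TI schedule arithmetic matches the protocol", {
  sch <- ti_schedule()
  expect_equal(sch$ti_values_ms[1], 50)
  expect_equal(sch$ti_values_ms[2], 250)
  expect_equal(sch$ti_values_ms[55], 10850)
  expect_equal(sch$n_shot, 55)
  expect_equal(sch$n_padded, 59)
  expect_equal(sch$ti_values_ms,
               50 + (seq_len(55) - 1) * 200)
})

test_that("phantom rasterization covers the expected vessel area", {
  # 3 mm vessel at 1 mm resolution: ~ pi * 9 = 28 pixels (+/- boundary)
  phm <- make_phantom(64, 64,
                      list(list(center_mm = c(0, 0), radius_mm = 3,
                                t1_ms = 1650)), 1200)
  expect_true(abs(sum(phm$vessel_labels == 1) - pi * 9) <= 5)
  expect_true(all(phm$t1_map_ms[phm$m0_map > 0] > 0))
})

test_that("phantom labels vessels distinctly and rejects overlap", {
  phm0 <- make_phantom(48, 180, list(), 1200)
  expect_true(all(phm0$vessel_labels == 0L))
  phm2 <- make_phantom(96, 180,
                       list(list(center_mm = c(-28, 12), radius_mm = 5, t1_ms = 1650),
                            list(center_mm = c(28, 12), radius_mm = 5, t1_ms = 1650)),
                       1200)
  expect_setequal(unique(as.vector(phm2$vessel_labels)), c(0L, 1L, 2L))
  expect_error(
    make_phantom(96, 180,
                 list(list(center_mm = c(0, 0), radius_mm = 6, t1_ms = 1650),
                      list(center_mm = c(4, 0), radius_mm = 6, t1_ms = 1800)),
                 1200), "overlap")
  expect_error(
    make_phantom(96, 180,
                 list(list(center_mm = c(88, 0), radius_mm = 6, t1_ms = 1650)),
                 1200), "field of view")
})

test_that("inflow inversion-recovery signal follows the closed forms", {
  # uniform background so the stated background T1 applies everywhere
  phm <- make_phantom(32, 180,
                      list(list(center_mm = c(0, 0), radius_mm = 12,
                                t1_ms = 1650)), 1200,
                      background_texture = 0)
  v <- phm$vessel_labels == 1
  bg <- !v & phm$m0_map > 0
  # TI grid hitting the zero crossing of T1 = 1650 ms exactly
  sch <- ti_schedule(first_ti_ms = 1650 * log(2), delta_ti_ms = 200,
                     n_acquired = 4, n_appended = 0, n_prepended = 0)
  ser <- simulate_ir_series(phm, sch, acq_params())
  expect_lt(max(abs(ser$data[1, , ][v])), 1e-12)       # null at T1 ln 2
  sch2 <- ti_schedule(first_ti_ms = 50, n_acquired = 5, n_appended = 0,
                      n_prepended = 0)
  ser2 <- simulate_ir_series(phm, sch2, acq_params())
  expect_equal(mean(ser2$data[1, , ][v]), 1 - 2 * exp(-50 / 1650),
               tolerance = 1e-12)                       # -0.9397 M0
  # background sits at the saturation plateau in every frame
  plateau <- 1 - exp(-200 / 1200)                       # 0.1535 M0
  for (f in 1:5)
    expect_equal(unique(round(ser2$data[f, , ][bg], 12)), round(plateau, 12))
})

test_that("noiseless simulator output closes with the three-parameter fitter", {
  phm <- make_phantom(32, 180,
                      list(list(center_mm = c(-30, 10), radius_mm = 10,
                                t1_ms = 1650),
                           list(center_mm = c(30, -10), radius_mm = 10,
                                t1_ms = 2000)), 1200)
  sch <- ti_schedule()
  ser <- simulate_ir_series(phm, sch, acq_params())
  for (v in 1:2) {
    m <- phm$vessel_labels == v
    sig <- vapply(seq_len(50), function(f) mean(ser$data[f, , ][m]),
                  numeric(1))
    fit <- fit_ir_t1(sig, sch)
    true_t1 <- phm$vessels[[v]]$t1_ms
    expect_lt(abs(fit$t1_ms - true_t1) / true_t1, 0.001)
  }
})

test_that("partial inversion efficiency scales the recovery amplitude", {
  phm <- make_phantom(32, 180,
                      list(list(center_mm = c(0, 0), radius_mm = 12,
                                t1_ms = 1650)), 1200, background_texture = 0)
  sch <- ti_schedule(n_acquired = 3, n_appended = 0, n_prepended = 0)
  ser <- simulate_ir_series(phm, sch,
                            acq_params(inversion_efficiency = 0.9))
  v <- phm$vessel_labels == 1
  expect_equal(mean(ser$data[1, , ][v]), 1 - 1.9 * exp(-50 / 1650),
               tolerance = 1e-12)
})

test_that("inflow-refresh condition flags slow flow", {
  sch <- ti_schedule()
  expect_true(inflow_condition(sch, acq_params(blood_velocity_cm_s = 15)))
  # 5 mm slice, 200 ms spacing: refresh needs v > 2.5 cm/s
  expect_false(inflow_condition(sch, acq_params(blood_velocity_cm_s = 2)))
  phm <- make_phantom(16, 180, list(), 1200)
  expect_warning(
    simulate_ir_series(phm, sch, acq_params(blood_velocity_cm_s = 2)),
    "inflow")
})

test_that("coil maps are smooth with bounded coverage variation", {
  c1 <- make_coil_maps(32, 1)
  expect_true(all(c1$maps[1, , ] == 1 + 0i))
  c8 <- make_coil_maps(32, 8)
  rss <- coil_rss(c8)
  expect_lt(max(rss) / min(rss), 3)
  # smoothness: largest pixel-to-pixel change of any coil map
  gmax <- 0
  for (k in 1:8) {
    m <- c8$maps[k, , ]
    gmax <- max(gmax, max(Mod(diff(m))), max(Mod(t(diff(t(m))))))
  }
  expect_lt(gmax, 0.25)
})

test_that("k-space simulation obeys the forward-model contracts", {
  st <- small_study()
  # zero truth, zero noise: all-zero k-space
  zer <- st$truth; zer$data <- zer$data * 0
  k0 <- simulate_kspace(zer, st$coils, st$traj, st$sch, st$acq)
  expect_true(all(k0$data == 0))
  # DC dominance: uniform image, unit coil
  uni <- image_series(array(1, dim = c(st$sch$n_shot, 32, 32)),
                      frame_roles = st$truth$frame_roles)
  k1 <- simulate_kspace(uni, make_coil_maps(32, 1), st$traj, st$sch, st$acq)
  expect_equal(which.max(Mod(k1$data[1, 1, ])), 1L)     # k = 0 sample
  expect_equal(Mod(k1$data[1, 1, 1]), 32^2, tolerance = 1e-3)
  # linearity at sigma = 0
  sc <- st$truth; sc$data <- 3.7 * sc$data
  k3 <- simulate_kspace(sc, st$coils, st$traj, st$sch, st$acq)
  expect_equal(k3$data, 3.7 * st$ksp$data, tolerance = 1e-12)
})

test_that("a fixed seed reproduces noisy k-space bit for bit", {
  st1 <- small_study(noise_sigma = 1, seed = 42)
  st2 <- small_study(noise_sigma = 1, seed = 42)
  expect_identical(st1$ksp$data, st2$ksp$data)
  st3 <- small_study(noise_sigma = 1, seed = 43)
  expect_false(identical(st3$ksp$data, st1$ksp$data))
})

test_that("complex noise is calibrated to the requested sigma", {
  sch <- ti_schedule(n_acquired = 1, n_appended = 0, n_prepended = 0)
  phm <- make_phantom(16, 180, list(), 1200)
  traj <- design_vd_spiral(180, 180 / 16, n_samples = 1000)
  zer <- image_series(array(0, dim = c(1, 16, 16)))
  ksp <- simulate_kspace(zer, make_coil_maps(16, 1), traj, sch,
                         acq_params(noise_sigma = 1.5, seed = 7))
  expect_equal(stats::sd(Re(ksp$data)), 1.5, tolerance = 0.05 * 1.5)
  expect_equal(stats::sd(Im(ksp$data)), 1.5, tolerance = 0.05 * 1.5)
})
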