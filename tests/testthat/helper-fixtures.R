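# shared fixtures and independent oracles, all built in code

# asymmetric high-contrast analytic image with structure inside a 20 px ROI
# around the center, used for known-transform registration recovery. The
# rigid transform p = (tx_rows, ty_cols, theta_deg) about `pivot` is applied
# by evaluating the analytic function at transformed coordinates, so the
# injected motion carries no interpolation blur.
reg_fixture <- function(n = 96, p = c(0, 0, 0), pivot = c(48, 48)) {
  rows <- outer(seq_len(n), rep(1, n))
  cols <- outer(rep(1, n), seq_len(n))
  th <- -p[3] * pi / 180
  sr <- cos(th) * (rows - pivot[1]) - sin(th) * (cols - pivot[2]) -
    p[1] + pivot[1]
  sc <- sin(th) * (rows - pivot[1]) + cos(th) * (cols - pivot[2]) -
    p[2] + pivot[2]
  ctr <- floor(n / 2) + 1
  Y <- sr - ctr; X <- sc - ctr          # centered offsets (row = Y, col = X)
  img <- 0.2
  for (k in 1:6) {
    cx <- 7 * cos(k); cy <- 7 * sin(k * 2)
    img <- img + exp(-((X - cx)^2 + (Y - cy)^2) / (2 + k))
  }
  img + 0.3 * exp(-(X^2 + Y^2) / 2000)
}

# brute-force grid-search T1 oracle: 1 ms grid over T1 with the linear
# subproblem (M0, Minit - M0) solved exactly at each grid point
grid_t1_oracle <- function(signal, tis_ms, t1_grid = seq(500, 3500, by = 1)) {
  best_t1 <- NA; best_rss <- Inf
  for (t1 in t1_grid) {
    e <- exp(-tis_ms / t1)
    Xd <- cbind(1, e)
    beta <- solve(crossprod(Xd), crossprod(Xd, signal))
    rss <- sum((signal - Xd %*% beta)^2)
    if (rss < best_rss) { best_rss <- rss; best_t1 <- t1 }
  }
  best_t1
}

# IR signal model evaluated directly (independent of the fitter)
ir_model <- function(ti, m0, minit, t1) m0 + (minit - m0) * exp(-ti / t1)

# tiny reconstruction study shared by solver tests: 32 x 32, 8 + 2 acquired
# + 2 prepended frames, 4 coils
small_study <- function(noise_sigma = 0, seed = 1, vessels = NULL,
                        background_texture = 1) {
  if (is.null(vessels))
    vessels <- list(list(center_mm = c(-30, 10), radius_mm = 12,
                         t1_ms = 1650))
  sch <- ti_schedule(n_acquired = 8, n_appended = 2, n_prepended = 2)
  phm <- make_phantom(32, 180, vessels, 1200,
                      background_texture = background_texture)
  traj <- design_vd_spiral(180, 180 / 32, n_samples = 600)
  coils <- make_coil_maps(32, 4)
  acq <- acq_params(noise_sigma = noise_sigma, seed = seed)
  truth <- simulate_ir_series(phm, sch, acq)
  ksp <- simulate_kspace(truth, coils, traj, sch, acq)
  list(sch = sch, phm = phm, traj = traj, coils = coils, acq = acq,
       truth = truth, ksp = ksp)
}

nrmse <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
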