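test_that("charge increments follow e_i * dz_i / Lz for slab residents", {
  slab <- slab_region(-4.5, 16.5)  # Lz = 21
  # one Na+ moving +2.1 A inside the slab
  na <- traj_from_z(cbind(c(5, 7.1)))
  expect_equal(charge_increments(na, slab)$series$dQ[2], 2.1 / 21)
  # charge scaling: Ca2+ contributes twice the transported charge
  ca <- traj_from_z(cbind(c(5, 7.1)), species = "CA")
  expect_equal(charge_increments(ca, slab)$series$dQ[2], 2 * 2.1 / 21)
  # an anion moving up transports negative charge
  cl <- traj_from_z(cbind(c(5, 7.1)), species = "CL")
  expect_equal(charge_increments(cl, slab)$series$dQ[2], -2.1 / 21)
  # outside at both frames: no contribution (here the whole path misses the
  # slab, which also raises the all-zero warning)
  out <- traj_from_z(cbind(c(-10, -8)))
  expect_warning(ct_out <- charge_increments(out, slab), "does not overlap")
  expect_equal(ct_out$series$dQ[2], 0)
  expect_warning(charge_increments(traj_from_z(cbind(c(100, 101))), slab),
                 "does not overlap")
  expect_error(charge_increments(traj_from_z(cbind(5)), slab), "2 frames")
})

test_that("a full slab traversal transports exactly one ionic charge", {
  slab <- slab_region(-4.5, 16.5)
  # monotone path from z1 to z2, always inside: telescoping sum = e_i
  path <- seq(-4.5, 16.5, length.out = 64)
  ct <- charge_increments(traj_from_z(cbind(path)), slab)
  expect_equal(sum(ct$series$dQ[-1]), 1, tolerance = 1e-12)
  ct_ca <- charge_increments(traj_from_z(cbind(path), species = "CA"), slab)
  expect_equal(sum(ct_ca$series$dQ[-1]), 2, tolerance = 1e-12)
  # cumulative Q is the running sum, starting at 0
  expect_equal(ct$series$Q, c(0, cumsum(ct$series$dQ[-1])))
})

test_that("the clip rule credits fractional transport of boundary crossers", {
  slab <- slab_region(0, 10)
  # ion jumps from below the slab to its interior: only the inside part counts
  cross_in <- traj_from_z(cbind(c(-5, 5)))
  expect_equal(charge_increments(cross_in, slab, "clip")$series$dQ[2], 0.5)
  # the literal both-frames rule ignores the same jump
  expect_equal(charge_increments(cross_in, slab)$series$dQ[2], 0)
  # one jump across the whole slab still transports exactly e_i
  across <- traj_from_z(cbind(c(-5, 15)))
  expect_equal(charge_increments(across, slab, "clip")$series$dQ[2], 1)
})

test_that("sign symmetry: reflecting z negates dQ, leaves MSD and DQ alone", {
  set.seed(33)
  z <- matrix(cumsum(rnorm(400, sd = 1)) + 6, ncol = 1)
  z <- (z %% 20) - 2  # keep near the slab with some exits
  traj <- traj_from_z(z)
  mirror <- traj_from_z(-z)
  slab <- slab_region(-2, 18)
  slab_m <- slab_region(-18, 2)
  ct <- charge_increments(traj, slab)
  ct_m <- charge_increments(mirror, slab_m)
  expect_equal(ct_m$series$dQ[-1], -ct$series$dQ[-1], tolerance = 1e-12)
  m <- charge_msd(ct, 0.25); mm <- charge_msd(ct_m, 0.25)
  expect_equal(mm$msd$msd, m$msd$msd, tolerance = 1e-12)
  expect_equal(fit_dq(mm)$DQ, fit_dq(m)$DQ, tolerance = 1e-12)
})

test_that("the FFT charge MSD equals the brute-force double loop", {
  set.seed(101)
  dQ <- rnorm(500, sd = 0.05)
  ct <- transport_from_dq(dQ)
  m <- charge_msd(ct, max_lag_fraction = 0.3)
  expect_equal(m$msd$msd, msd_direct(ct$series$Q, m$msd$lag_frames),
               tolerance = 1e-9)
  expect_equal(m$msd$n_origins, length(ct$series$Q) - m$msd$lag_frames)
})

test_that("degenerate charge series give the expected MSDs", {
  ct0 <- transport_from_dq(rep(0, 100))
  m0 <- charge_msd(ct0)
  expect_true(all(m0$msd$msd == 0))
  # deterministic drift Q = c t: quadratic MSD, flagged by a poor linear fit
  ctd <- transport_from_dq(rep(0.2, 2000))
  md <- charge_msd(ctd)
  expect_equal(md$msd$msd, (0.2 * md$msd$lag)^2, tolerance = 1e-9)
  expect_error(charge_msd(ct0, 0), "max_lag_fraction")
  expect_error(charge_msd(ct0, 1.5), "max_lag_fraction")
  expect_error(charge_msd(transport_from_dq(rep(0, 5))), "at least 10")
})

test_that("DQ fitting recovers an exact line and rejects bad windows", {
  lags <- 1:100
  m <- structure(list(msd = data.frame(lag = lags, lag_frames = lags,
                                       msd = 2 * 0.003 * lags + 0.1,
                                       n_origins = 1000 - lags)),
                 class = "charge_msd")
  f <- fit_dq(m)
  expect_equal(f$DQ, 0.003, tolerance = 1e-12)
  expect_equal(f$intercept, 0.1, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_dq(m, window = c(0.99, 1.0)), "fewer than 5")
  m$msd$msd <- 10 - 0.01 * lags
  expect_error(fit_dq(m), "negative MSD slope")
})

test_that("a seeded random-walk charge series returns its known DQ", {
  set.seed(2024)
  sigma <- 0.02; dt <- 1
  dQ <- rnorm(1e5, sd = sigma)
  DQ0 <- sigma^2 / (2 * dt)  # MSD(k) = k sigma^2 = 2 DQ0 (k dt)
  # delta-correlated increments: the MSD is linear from lag 1, so a short
  # lag budget minimises estimator variance without bias
  f <- fit_dq(charge_msd(transport_from_dq(dQ, dt), max_lag_fraction = 0.01))
  expect_lt(abs(f$DQ - DQ0) / DQ0, 0.20)
  expect_gt(f$r_squared, 0.9)
})

test_that("non-interacting ions superpose in the collective estimate", {
  set.seed(55)
  dQ1 <- rnorm(5e4, sd = 0.03)
  dQ2 <- rnorm(5e4, sd = 0.05)
  f1 <- fit_dq(charge_msd(transport_from_dq(dQ1), 0.01))
  f2 <- fit_dq(charge_msd(transport_from_dq(dQ2), 0.01))
  f12 <- fit_dq(charge_msd(transport_from_dq(dQ1 + dQ2), 0.01))
  DQ_sum <- f1$DQ + f2$DQ
  expect_lt(abs(f12$DQ - DQ_sum) / DQ_sum, 0.25)
})

test_that("linear-response IV is exactly linear with slope G", {
  iv <- predict_iv(conductance_to_dq(23.06, 300), 300,
                   voltages = seq(-40, 40, 10))
  expect_equal(iv$G, 23.06, tolerance = 1e-9)
  expect_equal(iv$points$I_pA[iv$points$V_mV == 0], 0)
  # refitting a line through the points returns G to machine precision
  slope <- coef(lm(I_pA ~ V_mV, iv$points))[["V_mV"]]
  expect_equal(slope * 1e3, 23.06, tolerance = 1e-10)
})

test_that("frozen ions produce zero transport and zero conductance", {
  traj <- traj_from_z(matrix(5, 200, 2))
  ct <- charge_increments(traj, slab_region(-4.5, 16.5))
  expect_true(all(ct$series$dQ[-1] == 0))
  m <- charge_msd(ct)
  expect_true(all(m$msd$msd == 0))
  f <- fit_dq(m)
  expect_equal(f$DQ, 0)
  expect_equal(predict_iv(f$DQ, 300, -20)$points$I_pA, 0)
})

test_that("the pipeline conductance matches the closed form for free ions", {
  # non-interacting diffusers on a periodic domain: the analytic slab value
  # is G = nbar e^2 D / (Lz^2 kB T); the pipeline must land within 25%
  cfg <- langevin_config(potential_flat(), D = 0.5, dt = 0.05,
                         n_steps = 1e5, save_stride = 1L, seed = 71,
                         domain = c(-21, 21), boundary = "periodic",
                         ions = c("NA" = 8))
  traj <- simulate_ions(cfg)
  slab <- slab_region(-4.5, 16.5)
  res <- conductance_pipeline(traj, slab, T = 300, max_lag_fraction = 0.01)
  nbar <- mean(occupancy_trace(traj, "NA", slab)$trace$count)
  DQ_theory <- nbar * 0.5 / slab$Lz^2  # e^2/ps
  G_theory <- dq_to_conductance(DQ_theory, 300)
  expect_lt(abs(res$G - G_theory) / G_theory, 0.25)
  # brute-force oracle: summing per-ion transport series reproduces dQ
  z <- matrix(traj$data$z, ncol = 8, byrow = TRUE)
  per_ion <- sapply(seq_len(8), function(i) {
    ti <- traj_from_z(z[, i, drop = FALSE], box = traj$box)
    charge_increments(ti, slab)$series$dQ[-1]
  })
  expect_equal(rowSums(per_ion), res$transport$series$dQ[-1],
               tolerance = 1e-12)
})
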