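test_that("occupancy counts species ions in the closed slab interval", {
  region <- slab_region(-4.5, 16.5)
  inside <- traj_from_z(matrix(5, 10, 1))
  tr <- occupancy_trace(inside, "NA", region)
  expect_equal(tr$trace$count, rep(1L, 10))
  # boundary values belong to the slab (closed interval)
  edge <- traj_from_z(matrix(c(-4.5, 16.5), 1, 2))
  expect_equal(occupancy_trace(edge, "NA", region)$trace$count, 2L)
  just_out <- traj_from_z(matrix(c(-4.51, 16.51), 1, 2))
  expect_equal(occupancy_trace(just_out, "NA", region)$trace$count, 0L)
  # absent species -> a constant-zero trace, not an error
  expect_equal(occupancy_trace(inside, "CA", region)$trace$count, rep(0L, 10))
})

test_that("occupancy is invariant to id relabeling and time shifts", {
  set.seed(9)
  z <- matrix(runif(60, -10, 20), 20, 3)
  t1 <- occupancy_trace(traj_from_z(z), "NA", slab_region())
  swapped <- traj_from_z(z[, c(3, 1, 2)])
  t2 <- occupancy_trace(swapped, "NA", slab_region())
  expect_equal(t1$trace$count, t2$trace$count)
  shifted <- traj_from_z(z, times = 100 + (0:19) * 2)
  t3 <- occupancy_trace(shifted, "NA", slab_region())
  expect_equal(t1$trace$count, t3$trace$count)
})

test_that("occupancy statistics summarize mean, histogram and dwell times", {
  const2 <- structure(list(trace = data.frame(time = 0:99,
                                              count = rep(2L, 100))),
                      class = "occupancy_trace")
  s <- occupancy_stats(const2)
  expect_equal(s$mean, 2)
  expect_equal(s$histogram, c("2" = 100L))
  expect_equal(s$dwell$frames[s$dwell$count == 2], 100L)
  expect_equal(s$dwell$ps[s$dwell$count == 2], 100)

  alt <- structure(list(trace = data.frame(time = 0:9,
                                           count = rep(c(0L, 1L), 5))),
                   class = "occupancy_trace")
  sa <- occupancy_stats(alt)
  expect_equal(sa$mean, 0.5)
  expect_equal(max(sa$dwell$frames[sa$dwell$count == 1]), 1L)

  # concatenation: histograms add
  both <- structure(list(trace = data.frame(
    time = 0:109, count = c(rep(2L, 100), rep(c(0L, 1L), 5)))),
    class = "occupancy_trace")
  sb <- occupancy_stats(both)
  expect_equal(sum(sb$histogram), 110L)
  expect_equal(sb$histogram[["2"]], 100L)
  expect_equal(sb$histogram[["0"]], 5L)
  expect_error(occupancy_stats(structure(
    list(trace = data.frame(time = numeric(), count = integer())),
    class = "occupancy_trace")), "empty")
})

test_that("a staged multi-ion bound state shows constant slab occupancy", {
  # deep harmonic trap inside the slab with short-ranged repulsion keeps
  # three sodium ions resident, the knock-on-like stacked configuration
  cfg <- langevin_config(
    potential_harmonic(2.0, 6), D = 0.3, dt = 0.01, n_steps = 2e4,
    save_stride = 10L, seed = 14, domain = c(-4, 16), ions = c("NA" = 3),
    pair_repulsion = list(amplitude = 3, range = 1.0))
  traj <- simulate_ions(cfg)
  tr <- occupancy_trace(traj, "NA", slab_region(-4.5, 16.5))
  expect_true(all(tr$trace$count == 3L))
})

test_that("coordination fixtures reproduce exact category counts", {
  na_cut <- cutoff_scheme_for("NA")
  expect_equal(na_cut$oxygen, 3.2)
  expect_equal(na_cut$chloride, 3.5)

  fx <- make_coordination_fixture(
    "NA", data.frame(species = "OW", count = 6, distance = 2.35), seed = 2)
  prof <- coordination_profile(fx, "NA", na_cut)
  b <- prof$profile[prof$profile$visited, ]
  expect_equal(b$water_O, 6)
  expect_equal(b$total_O, 6)
  expect_equal(b$acidic_O, 0)
  expect_equal(b$chloride, 0)

  # an oxygen at 3.30 A is outside the 3.2 A sodium-oxygen cutoff
  fx_far <- make_coordination_fixture(
    "NA", data.frame(species = "OW", count = 1, distance = 3.30), seed = 2)
  pf <- coordination_profile(fx_far, "NA", na_cut)
  expect_equal(pf$profile$water_O[pf$profile$visited], 0)
  # ...but inside a 3.5 A cutoff
  pf2 <- coordination_profile(fx_far, "NA", cutoff_scheme(3.5, 3.5))
  expect_equal(pf2$profile$water_O[pf2$profile$visited], 1)
})

test_that("calcium shells partition into categories that sum to total_O", {
  fx <- make_coordination_fixture(
    "CA", data.frame(species = c("OW", "OD", "CL"), count = c(4, 3, 1),
                     distance = c(2.4, 2.3, 3.4)), z = 6.5, seed = 6)
  prof <- coordination_profile(fx, "CA", cutoff_scheme_for("CA"))
  b <- prof$profile[prof$profile$visited, ]
  expect_equal(b$water_O, 4)
  expect_equal(b$acidic_O, 3)
  expect_equal(b$other_protein_O, 0)
  expect_equal(b$total_O, 7)
  expect_equal(b$chloride, 1)
  # category additivity holds in every visited bin
  v <- prof$profile$visited
  expect_equal(prof$profile$total_O[v],
               prof$profile$water_O[v] + prof$profile$acidic_O[v] +
                 prof$profile$other_protein_O[v], tolerance = 1e-12)
})

test_that("coordination counts grow monotonically with the cutoff", {
  fx <- make_coordination_fixture(
    "NA", data.frame(species = c("OW", "OP"), count = c(5, 2),
                     distance = c(2.4, 3.3)), seed = 10)
  cuts <- c(2.0, 2.5, 3.0, 3.4, 4.0)
  totals <- vapply(cuts, function(co) {
    p <- coordination_profile(fx, "NA", cutoff_scheme(co, co))
    sum(p$profile$total_O[p$profile$visited])
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  expect_equal(totals[1], 0)
  expect_equal(totals[length(totals)], 7)
})

test_that("unknown partner labels are rejected by name", {
  d <- data.frame(time = 0, id = 1:2, species = c("NA", "QQ"),
                  charge = c(1, 0), x = 0, y = c(0, 2), z = 0)
  traj <- ion_trajectory(d)
  expect_error(coordination_profile(traj, "NA", cutoff_scheme_for("NA")),
               "QQ")
})
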