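test_that("localization scenes are seed-reproducible and conserve counts", {
  p <- synapse_scene_params(seed = 5)
  a <- make_localization_scene(p)
  b <- make_localization_scene(p)
  expect_identical(a, b)
  d <- make_localization_scene(synapse_scene_params(seed = 6))
  expect_false(identical(a$locs, d$locs))
  expect_equal(nrow(a$locs), sum(a$truth$molecules$run_length))
})

test_that("accessory radial law follows the Beta model", {
  # Beta(1, 1) is uniform on the normalized radius
  u <- make_localization_scene(synapse_scene_params(
    edge_alpha = 1, edge_beta = 1, n_mol_accessory = 5000, seed = 2))
  r <- u$truth$molecules$r_frac[u$truth$molecules$channel == "accessory"]
  expect_gt(stats::ks.test(r, "punif")$p.value, 0.01)

  # Beta(8, 2) puts its mode at 7/8, inside the 80-100% ring of the true
  # border
  e <- make_localization_scene(synapse_scene_params(
    edge_alpha = 8, edge_beta = 2, n_mol_accessory = 2000,
    blink_run_length = 1, precision_sigma = 0, seed = 3))
  acc <- e$locs[e$locs$channel == "accessory", ]
  pr <- ring_density_profile(e$truth$ez_border, acc)
  expect_equal(which.max(pr$density), 5L)  # 80-100% ring
})

test_that("zero noise and unit run length reproduce molecule positions", {
  sc <- make_localization_scene(synapse_scene_params(
    precision_sigma = 0, blink_run_length = 1, seed = 8))
  expect_equal(nrow(sc$locs), nrow(sc$truth$molecules))
  mol <- sc$truth$molecules[sc$truth$loc_molecule, ]
  expect_equal(sc$locs$x, mol$x)
  expect_equal(sc$locs$y, mol$y)
})

test_that("scene parameters are validated", {
  expect_error(synapse_scene_params(psd_radius = -1))
  expect_error(synapse_scene_params(edge_alpha = 0), "edge_alpha")
  expect_error(synapse_scene_params(blink_run_length = 0.5), ">= 1")
  expect_error(dynamics_scene_params(duration = 2, frame_interval = 5),
               "at least one frame")
  expect_error(dynamics_scene_params(lifetime_mix = c(0.5, 15, 1.5)),
               "mean_short")
})

test_that("dynamics scenes decompose into their motion components", {
  still <- make_dynamics_scene(dynamics_scene_params(
    n_antero = 0, n_retro = 0, seed = 4))
  expect_equal(still$movie, still$components$stationary)

  dyn <- make_dynamics_scene(dynamics_scene_params(seed = 4))
  expect_equal(dyn$movie,
               dyn$components$stationary + dyn$components$anterograde +
                 dyn$components$retrograde)
})

test_that("event-stream lifetimes follow the exponential mixture", {
  dyn <- make_dynamics_scene(dynamics_scene_params(n_events = 1000, seed = 10))
  lt <- dyn$events$lifetime_min
  # mixture CDF at 3 min: 0.5 * P(Exp(1.5) < 3) + 0.5 * P(Exp(15) < 3)
  expected <- 0.5 * (1 - exp(-3 / 1.5)) + 0.5 * (1 - exp(-3 / 15))
  expect_lt(abs(mean(lt < 3) - expected), 0.05)
})

test_that("noiseless FRAP traces match the closed-form recovery", {
  tr <- simulate_frap_trace(A = 0.5, K = 0.1, noise_sd = 0)
  nf <- normalize_frap(tr)
  expect_equal(nf$F[nf$t == 10], 0.5 * (1 - exp(-1)), tolerance = 1e-12)
  # acquisition photobleaching on the reference channel is divided out
  tb <- simulate_frap_trace(A = 0.5, K = 0.2, acq_bleach_per_frame = 0.02)
  nb <- normalize_frap(tb)
  truth <- 0.5 * (1 - exp(-0.2 * nb$t))
  expect_lt(max(abs(nb$F - truth)), 0.01)
})
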