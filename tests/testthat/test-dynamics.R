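test_that("kymographs sample the path with max projection across width", {
  # static movie: every row identical
  mov <- array(0, c(10, 5, 40))
  mov[, 3, ] <- rep(sin(seq_len(40)) + 2, each = 10)
  k <- build_kymograph(mov)
  expect_true(all(apply(k, 2, function(col) max(col) - min(col)) == 0))

  # a spot moving at v px/frame draws a line of slope v
  mov2 <- array(0, c(20, 5, 60))
  for (t in 1:20) mov2[t, 3, 5 + 2 * (t - 1)] <- 1
  k2 <- build_kymograph(mov2)
  expect_equal(apply(k2, 1, which.max), seq(5, by = 2, length.out = 20))

  # width-3 band over a single-pixel-wide track equals the width-1 result
  expect_equal(build_kymograph(mov2, line_width_px = 3),
               build_kymograph(mov2, line_width_px = 1))

  expect_error(build_kymograph(mov2, path = cbind(c(1, 100), c(3, 3))),
               "outside")
})

test_that("Fourier filter separates directions and conserves energy", {
  dyn <- make_dynamics_scene(dynamics_scene_params(seed = 2))
  k <- build_kymograph(dyn$movie)
  f <- fourier_direction_filter(k)
  recon <- f$stationary + f$anterograde + f$retrograde
  expect_lt(sum((recon - k)^2) / sum(k^2), 1e-12)  # Parseval partition

  E <- function(x) sum((x - mean(x))^2)
  ks <- build_kymograph(dyn$components$stationary)
  fs <- fourier_direction_filter(ks)
  expect_gt(stats::cor(as.vector(fs$stationary), as.vector(ks)), 0.95)
  expect_lt((sum(fs$anterograde^2) + sum(fs$retrograde^2)) / sum(ks^2), 0.05)

  ka <- build_kymograph(dyn$components$anterograde)
  fa <- fourier_direction_filter(ka)
  expect_gt(sum(fa$anterograde^2) / E(ka), 0.8)
  expect_lt(sum(fa$retrograde^2) / E(ka), 0.1)

  kr <- build_kymograph(dyn$components$retrograde)
  fr <- fourier_direction_filter(kr)
  expect_gt(sum(fr$retrograde^2) / E(kr), 0.8)
  expect_lt(sum(fr$anterograde^2) / E(kr), 0.1)

  k[1, 1] <- NA
  expect_error(fourier_direction_filter(k), "non-finite")
  expect_error(fourier_direction_filter(matrix(1, 4, 4)), "8 x 8")
})

test_that("intensity CV matches hand values and recovers the true level", {
  expect_equal(trace_cv(rep(7, 10)), 0)
  expect_equal(trace_cv(c(1, 3)), sqrt(2) / 2)
  expect_error(trace_cv(c(-3, 1)), "mean")
  expect_error(trace_cv(5), "2 samples")

  set.seed(15)
  est <- replicate(20, trace_cv(rnorm(60, 100, 6)))
  expect_lt(abs(mean(est) - 0.06), 0.02)
})

test_that("track linking follows stationary and separated spots", {
  det <- data.frame(frame = 0:19, x = 100, y = 100)
  ts <- link_tracks(det, max_link = 500, frame_interval = 1 / 3)
  expect_equal(nrow(ts$summary), 1)
  expect_equal(ts$summary$lifetime_min, 20 / 3)

  two <- rbind(data.frame(frame = 0:9, x = 0, y = 0),
               data.frame(frame = 0:9, x = 2000, y = 0))
  ts2 <- link_tracks(two, max_link = 500)
  expect_equal(nrow(ts2$summary), 2)
  expect_true(all(ts2$summary$n == 10))
})

test_that("linked lifetimes match ground-truth events within one frame", {
  dyn <- make_dynamics_scene(dynamics_scene_params(seed = 3))
  ts <- link_tracks(dyn$detections, max_link = 500,
                    frame_interval = 5 / 60)
  # map each track to its (majority) generating event
  purity <- vapply(seq_along(ts$tracks), function(i) {
    ev <- ts$tracks[[i]]$event
    max(table(ev)) / length(ev)
  }, numeric(1))
  expect_gt(mean(purity == 1), 0.95)

  dt <- 5 / 60
  ok <- 0; n <- 0
  for (i in seq_along(ts$tracks)) {
    if (purity[i] < 1) next
    ev <- ts$tracks[[i]]$event[1]
    truth <- dyn$events[ev, ]
    f0 <- ceiling(truth$onset_min / dt)
    f1 <- min(floor((truth$onset_min + truth$lifetime_min) / dt),
              max(dyn$detections$frame))
    n <- n + 1
    if (abs(ts$summary$lifetime_min[i] - (f1 - f0 + 1) * dt) <= dt) ok <- ok + 1
  }
  expect_gt(ok / n, 0.95)
})

test_that("lifetime classes use strict 3 and 9 minute boundaries", {
  cls <- lifetime_classify(c(1, 2, 10, 12))
  expect_equal(cls$frac_short, 0.5)
  expect_equal(cls$frac_intermediate, 0)
  expect_equal(cls$frac_persistent, 0.5)
  expect_true(cls$stable)

  exactly3 <- lifetime_classify(c(3, 9))
  expect_equal(exactly3$frac_intermediate, 1)  # both boundaries exclusive
  expect_false(exactly3$stable)

  # censored tracks: excluded unless their observed span already persists
  cen <- lifetime_classify(c(1, 10, 5), censored = c(TRUE, TRUE, FALSE))
  expect_equal(cen$n_classified, 2)
  expect_equal(cen$frac_persistent, 0.5)
  expect_true(cen$stable)
})

test_that("mixture lifetimes recover the closed-form short fraction", {
  dyn <- make_dynamics_scene(dynamics_scene_params(n_events = 1000, seed = 7))
  cls <- lifetime_classify(dyn$events$lifetime_min)
  expected <- 0.5 * (1 - exp(-2)) + 0.5 * (1 - exp(-0.2))
  expect_lt(abs(cls$frac_short - expected), 0.05)
})

test_that("movies round-trip through TIFF stacks", {
  dyn <- make_dynamics_scene(dynamics_scene_params(seed = 6, duration = 60))
  f <- withr::local_tempfile(fileext = ".tif")
  p <- write_movie_tiff(dyn$movie, f)
  back <- read_movie_tiff(f, scale = attr(p, "scale"))
  expect_equal(dim(back), dim(dyn$movie))
  expect_lt(max(abs(back - dyn$movie)) / max(dyn$movie), 1e-6)
})
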