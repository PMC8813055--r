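test_that("dbscan matches the brute-force density-expansion oracle", {
  # dense disc at the standard parameters: one cluster, no noise
  set.seed(1)
  th <- runif(150, 0, 2 * pi); r <- 100 * sqrt(runif(150))
  disc <- cbind(r * cos(th), r * sin(th))
  lab <- dbscan_cluster(disc, dbscan_params(0.2, 100))
  expect_equal(unique(lab), 1L)

  # points pairwise farther than eps are all noise
  grid <- as.matrix(expand.grid(x = seq(0, 2000, 500), y = seq(0, 2000, 500)))
  expect_true(all(dbscan_cluster(grid, dbscan_params(0.05, 2)) == 0L))

  # random scenes against the independent oracle, up to relabeling
  for (seed in 1:8) {
    sc <- random_dbscan_scene(seed, n_max = 300)
    lab <- dbscan_cluster(sc$pts, dbscan_params(sc$eps_nm / 1000, sc$min_pts))
    ora <- brute_dbscan(sc$pts, sc$eps_nm, sc$min_pts)
    expect_identical(canonical_labels(lab), canonical_labels(ora))
  }
})

test_that("cluster borders: convex hull and concave alpha-shape", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  hull <- cluster_border(sq[c(2, 4, 1, 3), ])
  expect_equal(polygon_area(hull), 100 * 100)
  expect_equal(nrow(hull), 4)

  set.seed(2)
  th <- runif(2000, 0, 2 * pi); r <- 150 * sqrt(runif(2000))
  disc <- cbind(r * cos(th), r * sin(th))
  expect_lt(abs(polygon_area(cluster_border(disc)) / (pi * 150^2) - 1), 0.05)

  # C-shaped sample: the alpha-shape hugs the opening, the hull bridges it
  set.seed(3)
  thc <- runif(500, 0.4, 2 * pi - 0.4)
  rc <- runif(500, 70, 100)
  cshape <- cbind(rc * cos(thc), rc * sin(thc))
  concave <- cluster_border(cshape, "concave", alpha = 35)
  expect_lt(polygon_area(concave), polygon_area(cluster_border(cshape)))

  expect_error(cluster_border(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(cluster_border(cbind(1:5, 2 * (1:5))), "collinear")
})

test_that("signed distances follow the inside-negative convention", {
  square <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  expect_equal(border_to_centroid_distance(square, c(150, 50)), 50)
  expect_equal(border_to_centroid_distance(square, c(50, 50)), -50)
  expect_equal(border_to_centroid_distance(square, c(0, 50)), 0)

  circle <- ellipse_polygon(c(0, 0), 100, 100, n = 256)
  expect_equal(distance_to_border(rbind(c(0, 0)), circle), -100,
               tolerance = 1e-3)
  expect_equal(as.numeric(distance_to_border(rbind(circle[1, ]), circle)), 0)
})

test_that("signed distance equals the densified-edge oracle within 0.5 nm", {
  for (seed in c(11, 12)) {
    poly <- random_star_polygon(seed)
    set.seed(seed + 100)
    pts <- cbind(runif(120, -160, 160), runif(120, -160, 160))
    got <- distance_to_border(pts, poly)
    want <- brute_signed_distance(pts, poly)
    expect_lt(max(abs(got - want)), 0.5)
    expect_true(all(sign(got) == sign(want) | abs(want) < 0.5))
  }
})

test_that("FWTM recovers closed-form Gaussian widths", {
  set.seed(6)
  iso <- cbind(rnorm(1e4, 0, 50), rnorm(1e4, 0, 50))
  fw <- fwtm_dimensions(iso)
  expected <- 2 * sqrt(2 * log(10)) * 50
  expect_lt(abs(mean(fw) / expected - 1), 0.04)
  expect_lt(abs(fw[1] / expected - 1), 0.06)
  expect_lt(abs(fw[2] / expected - 1), 0.06)

  aniso <- cbind(rnorm(1e4, 0, 100), rnorm(1e4, 0, 25))
  fa <- fwtm_dimensions(aniso)
  expect_lt(abs(fa[1] / fa[2] - 4), 0.4)   # ratio of closed forms
  expect_gte(fa[1], fa[2])

  expect_equal(fwtm_dimensions(matrix(5, 20, 2)), c(0, 0))
})

test_that("primary/secondary classification is by size with distance ties", {
  expect_equal(classify_primary_secondary(c(40e3, 7e3)),
               c("primary", "secondary"))
  expect_equal(classify_primary_secondary(30e3), "primary")
  expect_equal(classify_primary_secondary(c(10e3, 10e3),
                                          dist_to_psd = c(50, 10)),
               c("secondary", "primary"))
})

test_that("ring area fractions are analytic and polygon-independent", {
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  r <- scaled_rings(sq)
  expect_equal(r$area_fraction[1], 0.2^2 / 1.6^2)          # 0.015625
  expect_equal(r$area_fraction[5], (1 - 0.8^2) / 1.6^2)    # 0.140625
  expect_equal(sum(r$area_fraction), 1)
  for (seed in 31:35) {
    poly <- random_star_polygon(seed)
    rr <- scaled_rings(poly)
    expect_lt(max(abs(rr$computed_area_fraction / rr$area_fraction - 1)), 1e-6)
  }
})

test_that("ring density profiles are flat for uniform, peaked for edge laws", {
  poly <- random_star_polygon(41)
  pts <- uniform_in_polygon(1e4, scale_polygon(poly, 1.6), seed = 42)
  pr <- ring_density_profile(poly, pts)
  expect_true(all(abs(pr$density - 0.125) < 0.02))
  expect_equal(sum(pr$density), 1)
  expect_lte(sum(pr$loc_fraction), 1)

  cen <- polygon_centroid(poly)
  atc <- ring_density_profile(poly, matrix(rep(cen, 20), ncol = 2, byrow = TRUE))
  expect_equal(atc$density, c(1, rep(0, 7)))

  expect_error(ring_density_profile(poly, rbind(c(1e6, 1e6))), "outermost")
})

test_that("a cluster's own members lie inside its border on average", {
  sc <- make_localization_scene(synapse_scene_params(seed = 12))
  ez <- sc$locs[sc$locs$channel == "ez", ]
  lab <- dbscan_cluster(ez, dbscan_params(0.2, 100))
  cs <- build_cluster_set(ez, lab)
  mem <- cbind(ez$x, ez$y)[lab == cs$clusters$cluster[1], ]
  expect_lt(mean(distance_to_border(mem, cs$borders[[1]])), 0)
})
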