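test_that("Feret dimensions match hand geometry", {
  line <- matrix(FALSE, 5, 20)
  line[3, 6:15] <- TRUE                     # 1 x 10 px
  expect_equal(feret_dimensions(line, 0.04), c(0.4, 0.04))

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(feret_dimensions(one, 0.04), c(0.04, 0.04))

  xs <- 1:60
  disc <- outer((xs - 30)^2, (xs - 30)^2, "+") <= 10^2
  fer <- feret_dimensions(disc, 1)
  expect_lt(abs(fer[1] - 20), 1.2)
  expect_lt(abs(fer[2] - 20), 1.2)

  expect_error(feret_dimensions(matrix(FALSE, 3, 3)), "empty")
})

test_that("Feret length equals brute-force max pairwise boundary distance", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- rasterize_discs(cbind(runif(3, 2, 6), runif(3, 2, 6)),
                         runif(3, 0.3, 0.9), img_px = 100, px_um = 0.08)
    lab <- label_components(m)
    big <- lab == which.max(tabulate(lab[lab > 0]))
    b <- endozone:::.boundary_pixels(big)
    dmax <- max(stats::dist(b))
    expect_equal(feret_dimensions(big, 1)[1], dmax + 1)
  }
})

test_that("circularity separates discs, lines and squares", {
  xs <- 1:120
  disc <- outer((xs - 60)^2, (xs - 60)^2, "+") <= 50^2
  expect_gte(circularity(disc), 0.9)

  line <- matrix(FALSE, 5, 30); line[3, 6:25] <- TRUE
  expect_lt(circularity(line), 0.3)

  square <- function(n) { m <- matrix(FALSE, n + 10, n + 10); m[6:(5 + n), 6:(5 + n)] <- TRUE; m }
  c20 <- circularity(square(20)); c80 <- circularity(square(80))
  expect_lt(abs(c80 - pi / 4), abs(c20 - pi / 4))  # converges to pi/4
  expect_lt(abs(c80 - pi / 4), 0.04)

  # rotation by 90 degrees and translation leave circularity unchanged
  blob <- rasterize_discs(rbind(c(1.5, 1.2), c(2.0, 1.4)), c(0.5, 0.3),
                          img_px = 80, px_um = 0.05)
  expect_equal(circularity(t(blob)[ncol(blob):1, ]), circularity(blob))
  shifted <- matrix(FALSE, 90, 90); shifted[6:85, 6:85] <- blob[1:80, 1:80]
  expect_equal(circularity(shifted), circularity(blob))
})

test_that("association scoring counts overlapping components", {
  # one punctum fully inside the ROI disc
  m <- rasterize_discs(c(2, 2), 0.1, img_px = 100, px_um = 0.04)
  a <- associate_ez_psd(rbind(c(2, 2)), m, roi_diameter_um = 0.79)
  expect_equal(a$fraction, 1)
  expect_equal(a$per_psd$count, 1)

  # punctum centered outside the disc but overlapping its rim is positive
  rim <- rasterize_discs(c(2 + 0.395 + 0.05, 2), 0.1, img_px = 100, px_um = 0.04)
  expect_equal(associate_ez_psd(rbind(c(2, 2)), rim, 0.79)$fraction, 1)
  # and far away is negative
  far <- rasterize_discs(c(3.5, 2), 0.1, img_px = 100, px_um = 0.04)
  expect_equal(associate_ez_psd(rbind(c(2, 2)), far, 0.79)$fraction, 0)

  expect_error(associate_ez_psd(matrix(0, 0, 2), m), "no PSD centers")
})

test_that("association equals brute-force per-component disc test", {
  sc <- make_mask_scene(seed = 13)
  got <- associate_ez_psd(sc$psd_centers, sc$mask)
  lab <- label_components(sc$mask)
  fg <- which(sc$mask, arr.ind = TRUE)
  pos <- cbind(fg[, 2] * 0.04, fg[, 1] * 0.04)
  brute <- vapply(seq_len(nrow(sc$psd_centers)), function(i) {
    d2 <- (pos[, 1] - sc$psd_centers[i, 1])^2 + (pos[, 2] - sc$psd_centers[i, 2])^2
    length(unique(lab[fg][d2 <= 0.395^2]))
  }, numeric(1))
  expect_equal(got$per_psd$count, brute)
  # every constructed associated synapse is detected
  expect_true(all(got$per_psd$positive[sc$truth]))
})

test_that("association fraction is monotone in ROI diameter", {
  sc <- make_mask_scene(seed = 14)
  ds <- c(0.3, 0.5, 0.69, 0.79, 0.89, 1.2)
  fr <- vapply(ds, function(d) {
    associate_ez_psd(sc$psd_centers, sc$mask, d)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("punctum shape table covers every component", {
  m <- rasterize_discs(rbind(c(1, 1), c(3, 3)), c(0.2, 0.4),
                       img_px = 120, px_um = 0.04)
  sh <- punctum_shapes(m)
  expect_equal(nrow(sh), 2)
  expect_true(all(sh$feret_length_um >= sh$feret_width_um))
  expect_true(all(sh$circularity > 0 & sh$circularity <= 1))
  expect_equal(sh$area_um2, sh$n_px * 0.04^2)
})
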