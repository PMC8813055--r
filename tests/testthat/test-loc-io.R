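test_that("localization CSV round trips through dialects, nm canonical", {
  tab <- loc_table(frame = c(0, 0, 1), x = c(10.5, 20, 30),
                   y = c(1, 2, 3), precision = c(5, 10, 12),
                   channel = "ez")
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tab, f1)
  back <- read_localizations(f1, loc_dialect(channel = "channel"))
  expect_equal(back$x, tab$x)
  expect_equal(back$y, tab$y)
  expect_equal(back$frame, tab$frame)
  expect_equal(back$precision, tab$precision)

  # micrometre dialect: 0.2 um becomes 200 nm
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x_um,y_um", "0,0.2,0.1"), f2)
  um <- read_localizations(f2, loc_dialect(x = "x_um", y = "y_um",
                                           precision = NULL, xy_unit = "um"))
  expect_equal(um$x, 200)
  expect_equal(um$y, 100)

  # renamed column mapped by the dialect reads identically
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x_nm,y [nm],uncertainty [nm]",
               "0,10.5,1,5", "0,20,2,10", "1,30,3,12"), f3)
  renamed <- read_localizations(f3, loc_dialect(x = "x_nm"))
  expect_equal(renamed$x, back$x)
  expect_equal(renamed$y, back$y)
})

test_that("malformed localization CSVs raise informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,y [nm]", "0,1"), f)
  expect_error(read_localizations(f), "missing mandatory column")
  writeLines(c("frame,x [nm],y [nm]", "0,1,2", "1,oops,4"), f)
  expect_error(read_localizations(f, loc_dialect(precision = NULL)),
               "row 2")
})

test_that("precision filter keeps the boundary and matches a recount", {
  tab <- loc_table(0:2, 1:3, 1:3, precision = c(5, 15, 25))
  expect_equal(nrow(precision_filter(tab, 15)), 2)   # 15 nm inclusive
  expect_equal(precision_filter(tab, Inf), tab)
  expect_error(precision_filter(tab, -1), "> 0")

  set.seed(4)
  prec <- runif(1000, 0, 30)
  big <- loc_table(rep(0, 1000), runif(1000), runif(1000), precision = prec)
  expect_equal(nrow(precision_filter(big, 15)), sum(prec <= 15))
})

test_that("ROI cropping is closed and matches brute-force point-in-box", {
  tab <- loc_table(rep(0, 3), c(0, 500, 2000), c(0, 0, 0), precision = 5)
  roi <- roi_set(c(500, 0), width = 1000, height = 1000)
  cropped <- crop_to_roi(tab, roi)
  expect_equal(cropped$x, c(0, 500))  # x = 0 sits exactly on the edge

  set.seed(9)
  n <- 500
  tab2 <- loc_table(rep(0, n), runif(n, -1000, 1000), runif(n, -1000, 1000),
                    precision = 5)
  roi2 <- roi_set(c(100, -50), width = 700, height = 400)
  keep <- abs(tab2$x - 100) <= 350 & abs(tab2$y + 50) <= 200
  expect_equal(nrow(crop_to_roi(tab2, roi2)), sum(keep))

  everything <- roi_set(c(0, 0), width = 1e6, height = 1e6)
  expect_equal(crop_to_roi(tab2, everything), tab2)
})

test_that("consecutive-frame merging collapses runs and conserves counts", {
  # one molecule blinking for 5 frames collapses to one localization
  run <- loc_table(0:4, rep(100, 5), rep(200, 5), precision = 5)
  m <- merge_consecutive(run, 30)
  expect_equal(nrow(m), 1)
  expect_equal(m$frame, 0)
  expect_equal(m$n_merged, 5L)
  expect_equal(m$x, 100)
  expect_equal(m$precision, 5 / sqrt(5))

  # distinct molecules 1 um apart never merge
  two <- loc_table(c(0, 1), c(0, 1000), c(0, 0), precision = 5)
  expect_equal(nrow(merge_consecutive(two, 30)), 2)
})

test_that("merging recovers molecule counts on blinking scenes, idempotently", {
  sc <- make_localization_scene(synapse_scene_params(
    blink_run_length = 4, precision_sigma = 5, seed = 21))
  expect_equal(nrow(sc$locs), sum(sc$truth$molecules$run_length))
  m1 <- merge_consecutive(sc$locs, 30)
  n_true <- nrow(sc$truth$molecules)
  expect_lt(abs(nrow(m1) / n_true - 1), 0.05)
  expect_equal(sum(m1$n_merged), nrow(sc$locs))  # conservation
  m2 <- merge_consecutive(m1, 30)
  expect_equal(m2, m1)                           # idempotence
})
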