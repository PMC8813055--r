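test_that("FRAP normalization guards against unbleached or corrupt traces", {
  t <- c(seq(-2, -1 / 3, by = 1 / 3), seq(0, 5, by = 1 / 3))
  flat <- frap_trace(t, roi = rep(100, length(t)),
                     background = rep(20, length(t)),
                     reference = rep(120, length(t)))
  expect_error(normalize_frap(flat), "no bleach")

  bad <- frap_trace(t, roi = rep(100, length(t)),
                    background = rep(20, length(t)),
                    reference = rep(10, length(t)))
  expect_error(normalize_frap(bad), "reference")

  expect_error(frap_trace(c(-1, 0, 1), 1:3, 1:3, 1:3), "post-bleach")
  expect_error(frap_trace(c(-1, -1, 0, 1, 2), 1:5, 1:5, 1:5),
               "strictly increasing")
})

test_that("identity normalization returns the raw recovery", {
  t <- c(seq(-2, -1 / 3, by = 1 / 3), seq(0, 19, by = 1 / 3))
  rec <- ifelse(t < 0, 1, 0.6 * (1 - exp(-0.2 * pmax(t, 0))))
  tr <- frap_trace(t, roi = rec, background = rep(0, length(t)),
                   reference = rep(1, length(t)))
  nf <- normalize_frap(tr)
  expect_equal(nf$F, 0.6 * (1 - exp(-0.2 * nf$t)), tolerance = 1e-12)
})

test_that("noiseless fits recover parameters to solver tolerance", {
  for (ps in list(c(A = 0.758, tau = 13), c(A = 0.38, tau = 36.2),
                  c(A = 0.9, tau = 5))) {
    tr <- simulate_frap_trace(A = ps[["A"]], K = 1 / ps[["tau"]])
    fit <- fit_frap(normalize_frap(tr), recovery_at = 20)
    expect_true(fit$converged)
    expect_equal(fit$A, ps[["A"]], tolerance = 1e-6)
    expect_equal(fit$tau, ps[["tau"]], tolerance = 1e-6)
    expect_equal(fit$recovery_at[["t20"]],
                 ps[["A"]] * (1 - exp(-20 / ps[["tau"]])), tolerance = 1e-6)
  }
  # an identically flat series fits a zero mobile fraction
  zero <- data.frame(t = seq(0, 19, by = 0.5), F = 0)
  expect_equal(fit_frap(zero)$A, 0, tolerance = 1e-8)
})

test_that("fits are invariant to time-unit rescaling", {
  tr <- simulate_frap_trace(A = 0.6, K = 0.15)
  nf <- normalize_frap(tr)
  f_min <- fit_frap(nf)
  f_sec <- fit_frap(data.frame(t = nf$t * 60, F = nf$F))
  expect_equal(f_sec$A, f_min$A, tolerance = 1e-6)
  expect_equal(f_sec$K, f_min$K / 60, tolerance = 1e-9)
})

test_that("noisy fits are accurate at the fast-recovery regime", {
  # sigma = 0.05 replicates at the shaft parameters; the mean estimate is
  # close to truth (the slow spine regime is not identifiable on this
  # window - see the methods vignette)
  sch <- frap_schedule("clca")
  tp <- sch[sch >= 0]
  set.seed(31)
  est <- t(replicate(100, {
    Fv <- 0.758 * (1 - exp(-tp / 13)) + rnorm(length(tp), 0, 0.05)
    f <- fit_frap(data.frame(t = tp, F = Fv))
    c(f$A, f$tau)
  }))
  expect_lt(abs(mean(est[, 1]) - 0.758), 0.06)
  expect_lt(abs(mean(est[, 2]) - 13) / 13, 0.15)
})
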