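# FRAP normalization and single-exponential recovery fitting:
# I(t) = A * (1 - exp(-K * t)) with mobile fraction A and rate K
# (time constant tau = 1/K).

#' Construct a raw FRAP trace
#'
#' @param t acquisition times in minutes; baseline times negative, `t = 0`
#'   is the first post-bleach frame. Strictly increasing; at least 3
#'   post-bleach points.
#' @param roi,background,reference raw mean intensities per timepoint for
#'   the bleached ROI, a background region, and an unbleached reference
#'   region (for acquisition-photobleaching correction).
#' @return a `frap_trace` data.frame.
#' @export
frap_trace <- function(t, roi, background, reference) {
  n <- length(t)
  stopifnot(length(roi) == n, length(background) == n, length(reference) == n)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing", call. = FALSE)
  if (sum(t >= 0) < 3) stop("need at least 3 post-bleach points", call. = FALSE)
  structure(data.frame(t = t, roi = roi, background = background,
                       reference = reference),
            class = c("frap_trace", "data.frame"))
}

#' Normalize a FRAP trace (double normalization)
#'
#' Background subtraction and reference-region bleaching correction:
#' `ratio(t) = (roi - background) / (reference - background)`, divided by
#' the mean pre-bleach ratio. The bleach frame (`t = 0`, first post-bleach
#' point) re-zeroes the scale: `F(t) = (I_norm(t) - I_norm(0)) /
#' (1 - I_norm(0))`, so `F` runs from 0 just after the bleach toward the
#' mobile fraction, and residual post-bleach intensity is divided out.
#'
#' @param trace a [frap_trace()].
#' @param min_bleach_depth minimum required bleach depth `1 - I_norm(0)`;
#'   below this the trace is considered unbleached and an error is raised.
#' @return data.frame with post-bleach `t` (minutes) and normalized
#'   intensity `F`.
#' @export
normalize_frap <- function(trace, min_bleach_depth = 0.05) {
  if (any(trace$reference <= trace$background)) {
    stop("reference intensity at or below background: corrupt trace",
         call. = FALSE)
  }
  ratio <- (trace$roi - trace$background) / (trace$reference - trace$background)
  pre <- trace$t < 0
  if (!any(pre)) stop("baseline window is empty", call. = FALSE)
  inorm <- ratio / mean(ratio[pre])
  post <- trace$t >= 0
  i0 <- inorm[post][1]
  depth <- 1 - i0
  if (depth < min_bleach_depth) {
    stop("no bleach detected: post-bleach intensity within baseline",
         call. = FALSE)
  }
  data.frame(t = trace$t[post], F = (inorm[post] - i0) / depth)
}

#' Fit single-exponential FRAP recovery
#'
#' Nonlinear least squares of `F(t) = A * (1 - exp(-K * t))` over the
#' post-bleach points, A bounded to the physical range [0, `upper_A`]
#' (default 1.2) and K > 0; all points weighted equally (the non-uniform
#' acquisition schedule is not reweighted).
#' Initialization: A0 = final value, K0 = 1 / (time of half rise).
#'
#' @param normalized data.frame with `t` (min) and `F`, from
#'   [normalize_frap()] (or any normalized recovery series in [-0.2, 1.3]).
#' @param recovery_at reference time(s) in minutes at which recovery is
#'   reported (default 20).
#' @param upper_A upper bound on the mobile fraction.
#' @return a `frap_fit` list: `A` (mobile fraction), `K` (1/min), `tau`
#'   (min), `recovery_at` (fitted curve value at `recovery_at`),
#'   `recovery_raw` (nearest measured datapoint), `rss`, `converged`,
#'   and `message` when not converged.
#' @export
fit_frap <- function(normalized, recovery_at = 20, upper_A = 1.2) {
  t <- normalized$t; Fv <- normalized$F
  if (length(t) < 3) stop("need at least 3 post-bleach points", call. = FALSE)
  if (stats::sd(Fv) < 1e-12) {
    # constant series: A equals the level (K unidentifiable)
    A <- max(0, mean(Fv))
    return(structure(list(A = A, K = NA_real_, tau = NA_real_,
                          recovery_at = setNames(rep(A, length(recovery_at)),
                                                 paste0("t", recovery_at)),
                          recovery_raw = setNames(rep(mean(Fv), length(recovery_at)),
                                                  paste0("t", recovery_at)),
                          rss = 0, converged = TRUE, message = NULL),
                     class = "frap_fit"))
  }
  A0 <- min(max(Fv[length(Fv)], 0.05), upper_A - 0.05)
  half_idx <- which(Fv >= A0 / 2)
  t_half <- if (length(half_idx) && t[half_idx[1]] > 0) t[half_idx[1]] else
    stats::median(t[t > 0])
  K0 <- 1 / max(t_half, 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      Fv ~ A * (1 - exp(-K * t)),
      start = list(A = A0, K = K0),
      lower = c(A = 0, K = 1e-6), upper = c(A = upper_A, K = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(A = NA_real_, K = NA_real_, tau = NA_real_,
                          recovery_at = setNames(rep(NA_real_, length(recovery_at)),
                                                 paste0("t", recovery_at)),
                          recovery_raw = NA_real_, rss = NA_real_,
                          converged = FALSE, message = conditionMessage(fit)),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  A <- unname(cf["A"]); K <- unname(cf["K"])
  rec_fit <- setNames(A * (1 - exp(-K * recovery_at)),
                      paste0("t", recovery_at))
  rec_raw <- setNames(vapply(recovery_at, function(tt) {
    Fv[which.min(abs(t - tt))]
  }, numeric(1)), paste0("t", recovery_at))
  structure(list(A = A, K = K, tau = 1 / K,
                 recovery_at = rec_fit, recovery_raw = rec_raw,
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 message = NULL),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (!x$converged) {
    cat("FRAP fit did not converge:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("FRAP fit: A = %.3f (mobile fraction), K = %.4f /min, tau = %.1f min\n",
              x$A, x$K, x$tau))
  for (nm in names(x$recovery_at)) {
    cat(sprintf("  recovery at %s min: %.1f%% (fitted), %.1f%% (raw point)\n",
                sub("^t", "", nm), 100 * x$recovery_at[[nm]],
                100 * x$recovery_raw[[nm]]))
  }
  invisible(x)
}
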