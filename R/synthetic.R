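# Synthetic ground-truth scenes for every pipeline stage: SMLM localization
# scenes (PSD + EZ + accessory channel with a parametric edge-enrichment
# law), line movies for kymographs, lifetime event streams and FRAP traces.
# All generators are seeded and bit-reproducible.

#' Parameters for a synthetic two-structure SMLM scene
#'
#' Describes one synapse: a circular PSD, an elliptical endocytic zone (EZ)
#' displaced from the PSD border, and an accessory-protein channel whose
#' radial placement follows a Beta law on the normalized centroid-to-border
#' radius (`r = R(theta) * Beta(edge_alpha, edge_beta)`), giving analytic
#' control over edge enrichment. Defaults are at the scale of measured EZs
#' (~225 x 145 nm, area ~35e3 nm^2) next to a ~300 nm PSD.
#'
#' @param psd_center PSD center (x, y) in nm.
#' @param psd_radius PSD radius in nm (> 0).
#' @param ez_offset displacement (nm) of the EZ centroid from the PSD border
#'   anchor point (the border point in the +x direction); the ~10 nm default
#'   matches the measured mean border-to-centroid separation of EZs.
#' @param ez_shape list with semi-axes `a`, `b` (nm) and rotation `theta`
#'   (rad) of the elliptical EZ.
#' @param n_mol_psd,n_mol_ez,n_mol_accessory ground-truth molecule counts per
#'   channel (each molecule emits a blinking run of localizations).
#' @param edge_alpha,edge_beta Beta shape parameters (> 0) of the accessory
#'   radial law; (1, 1) is uniform in radius fraction, (8, 2) peaks at
#'   r = 7/8 (mode (alpha - 1) / (alpha + beta - 2)).
#' @param precision_sigma localization noise SD in nm (>= 0); also written to
#'   the precision column.
#' @param blink_run_length mean consecutive-frame run length per molecule
#'   (geometric, >= 1).
#' @param n_frames number of acquisition frames.
#' @param seed RNG seed; identical seeds give bit-identical scenes.
#' @return a `synapse_scene_params` list.
#' @export
synapse_scene_params <- function(psd_center = c(0, 0), psd_radius = 150,
                                 ez_offset = c(10.6, 0),
                                 ez_shape = list(a = 112.3, b = 73.25, theta = 0),
                                 n_mol_psd = 300, n_mol_ez = 300,
                                 n_mol_accessory = 200,
                                 edge_alpha = 8, edge_beta = 2,
                                 precision_sigma = 5, blink_run_length = 2,
                                 n_frames = 2000, seed = 1L) {
  stopifnot(psd_radius > 0, ez_shape$a > 0, ez_shape$b > 0)
  if (n_mol_psd < 0 || n_mol_ez < 0 || n_mol_accessory < 0) {
    stop("molecule counts must be >= 0", call. = FALSE)
  }
  if (edge_alpha <= 0 || edge_beta <= 0) {
    stop("edge_alpha and edge_beta must be > 0", call. = FALSE)
  }
  if (precision_sigma < 0) stop("precision_sigma must be >= 0", call. = FALSE)
  if (blink_run_length < 1) stop("blink_run_length must be >= 1", call. = FALSE)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  structure(list(psd_center = psd_center, psd_radius = psd_radius,
                 ez_offset = ez_offset, ez_shape = ez_shape,
                 n_mol_psd = n_mol_psd, n_mol_ez = n_mol_ez,
                 n_mol_accessory = n_mol_accessory,
                 edge_alpha = edge_alpha, edge_beta = edge_beta,
                 precision_sigma = precision_sigma,
                 blink_run_length = blink_run_length,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "synapse_scene_params")
}

# ellipse border radius along absolute direction theta from its center
.ellipse_radius <- function(shape, theta) {
  phi <- theta - shape$theta
  shape$a * shape$b / sqrt((shape$b * cos(phi))^2 + (shape$a * sin(phi))^2)
}

.uniform_disc <- function(n, center, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

.uniform_ellipse <- function(n, center, shape) {
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x0 <- shape$a * r * cos(th); y0 <- shape$b * r * sin(th)
  cbind(center[1] + x0 * cos(shape$theta) - y0 * sin(shape$theta),
        center[2] + x0 * sin(shape$theta) + y0 * cos(shape$theta))
}

#' Generate a synthetic SMLM localization scene with ground truth
#'
#' Draws molecule positions for the three channels (`"psd"`, `"ez"`,
#' `"accessory"`), then emits each molecule as a run of localizations over
#' consecutive frames (geometric run length with mean `blink_run_length`),
#' jittered by `precision_sigma` per axis. Accessory molecules are placed at
#' `center + r * R(theta) * (cos theta, sin theta)` with `theta` uniform and
#' `r ~ Beta(edge_alpha, edge_beta)`, where `R(theta)` is the EZ border
#' radius in that direction.
#'
#' @param params a [synapse_scene_params()].
#' @return list with `locs` (a [loc_table()]) and `truth`: true borders
#'   (`psd_border`, `ez_border` polygons), centers, the per-molecule table
#'   (`molecules`) and the localization-to-molecule map (`loc_molecule`,
#'   aligned with `locs` rows).
#' @export
make_localization_scene <- function(params) {
  stopifnot(inherits(params, "synapse_scene_params"))
  set.seed(params$seed)
  anchor <- params$psd_center + c(params$psd_radius, 0)
  ez_center <- anchor + params$ez_offset

  psd_xy <- .uniform_disc(params$n_mol_psd, params$psd_center, params$psd_radius)
  ez_xy <- .uniform_ellipse(params$n_mol_ez, ez_center, params$ez_shape)
  th <- stats::runif(params$n_mol_accessory, 0, 2 * pi)
  rfrac <- stats::rbeta(params$n_mol_accessory, params$edge_alpha, params$edge_beta)
  Rth <- .ellipse_radius(params$ez_shape, th)
  acc_xy <- cbind(ez_center[1] + rfrac * Rth * cos(th),
                  ez_center[2] + rfrac * Rth * sin(th))

  mol <- data.frame(
    molecule = seq_len(params$n_mol_psd + params$n_mol_ez + params$n_mol_accessory),
    channel = rep(c("psd", "ez", "accessory"),
                  c(params$n_mol_psd, params$n_mol_ez, params$n_mol_accessory)),
    x = c(psd_xy[, 1], ez_xy[, 1], acc_xy[, 1]),
    y = c(psd_xy[, 2], ez_xy[, 2], acc_xy[, 2]),
    r_frac = c(rep(NA_real_, params$n_mol_psd + params$n_mol_ez), rfrac)
  )
  m <- nrow(mol)
  run_len <- if (params$blink_run_length == 1) rep(1L, m) else {
    1L + stats::rgeom(m, prob = 1 / params$blink_run_length)
  }
  run_len <- pmin(run_len, params$n_frames)
  start <- vapply(run_len, function(L) {
    sample.int(params$n_frames - L + 1L, 1L) - 1L
  }, integer(1))
  mol$run_length <- run_len
  mol$start_frame <- start

  idx <- rep(seq_len(m), run_len)
  frames <- start[idx] + unlist(lapply(run_len, seq_len)) - 1L
  nloc <- length(idx)
  locs <- loc_table(
    frame = frames,
    x = mol$x[idx] + stats::rnorm(nloc, 0, params$precision_sigma),
    y = mol$y[idx] + stats::rnorm(nloc, 0, params$precision_sigma),
    precision = params$precision_sigma,
    channel = mol$channel[idx]
  )
  # loc_table sorts by channel/frame; reapply the same ordering to the map
  ord <- order(mol$channel[idx], frames)
  truth <- list(
    psd_center = params$psd_center,
    ez_center = ez_center,
    psd_border = ellipse_polygon(params$psd_center, params$psd_radius,
                                 params$psd_radius),
    ez_border = ellipse_polygon(ez_center, params$ez_shape$a, params$ez_shape$b,
                                params$ez_shape$theta),
    molecules = mol,
    loc_molecule = idx[ord]
  )
  list(locs = locs, truth = truth)
}

#' Parameters for a synthetic live-imaging scene
#'
#' A short line-scan movie (for kymographs) with stationary and directed
#' puncta, an appearance/disappearance event stream with a two-component
#' exponential lifetime mixture, and FRAP trace parameters. Defaults match
#' a 5 s / 5 min clathrin acquisition with shaft-like intensity fluctuation
#' (CV 0.06) and the short/long lifetime split.
#'
#' @param n_stationary,n_antero,n_retro particle counts.
#' @param velocity_um_min speed of moving particles (um/min, magnitude;
#'   anterograde move toward +x, retrograde toward -x).
#' @param intensity_cv_true per-particle relative intensity fluctuation SD.
#' @param lifetime_mix `c(p_short, mean_short, mean_long)` of the exponential
#'   lifetime mixture, minutes; requires `0 <= p_short <= 1` and
#'   `mean_short < mean_long`.
#' @param n_events number of events in the lifetime stream.
#' @param frame_interval frame interval in seconds (> 0).
#' @param duration movie duration in seconds (>= frame_interval).
#' @param event_duration duration of the event stream in minutes.
#' @param px_nm pixel size along the line (nm).
#' @param n_px line length in pixels.
#' @param frap_params list(A, K, noise_sd) for the bundled FRAP trace;
#'   K in 1/min.
#' @param seed RNG seed.
#' @return a `dynamics_scene_params` list.
#' @export
dynamics_scene_params <- function(n_stationary = 5, n_antero = 2, n_retro = 2,
                                  velocity_um_min = 1.2,
                                  intensity_cv_true = 0.06,
                                  lifetime_mix = c(0.5, 1.5, 15),
                                  n_events = 200,
                                  frame_interval = 5, duration = 300,
                                  event_duration = 20,
                                  px_nm = 100, n_px = 128,
                                  frap_params = list(A = 0.758, K = 1 / 13,
                                                     noise_sd = 0),
                                  seed = 1L) {
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (duration < frame_interval) {
    stop("duration must be at least one frame_interval", call. = FALSE)
  }
  p <- lifetime_mix
  if (p[1] < 0 || p[1] > 1) stop("p_short must be in [0, 1]", call. = FALSE)
  if (p[2] >= p[3]) stop("mean_short must be < mean_long", call. = FALSE)
  structure(list(n_stationary = n_stationary, n_antero = n_antero,
                 n_retro = n_retro, velocity_um_min = velocity_um_min,
                 intensity_cv_true = intensity_cv_true,
                 lifetime_mix = p, n_events = n_events,
                 frame_interval = frame_interval, duration = duration,
                 event_duration = event_duration,
                 px_nm = px_nm, n_px = n_px, frap_params = frap_params,
                 seed = as.integer(seed)),
            class = "dynamics_scene_params")
}

# render Gaussian spots (sigma_px wide) on an n_px line; positions in px
.render_line <- function(positions, intensities, n_px, sigma_px = 1.5) {
  line <- numeric(n_px)
  xs <- seq_len(n_px)
  for (k in seq_along(positions)) {
    line <- line + intensities[k] * exp(-(xs - positions[k])^2 / (2 * sigma_px^2))
  }
  line
}

#' Generate a synthetic live-imaging scene with ground truth
#'
#' Builds a line movie (frames x 5 px x line length) as the sum of a
#' stationary component (background + fluctuating stationary spots) and
#' anterograde / retrograde components (directed spots, no background), an
#' event stream with two-exponential lifetimes, and one FRAP trace on the
#' standard acquisition schedule. The per-component movies are the ground
#' truth for the kymograph direction filter.
#'
#' @param params a [dynamics_scene_params()].
#' @return list with `movie` (t, y, x array), `components` (stationary /
#'   anterograde / retrograde arrays of the same shape), `events`
#'   (data.frame with onset, lifetime in minutes, x, y in nm), `detections`
#'   (per-frame detection table for track linking), `frap` (a
#'   [frap_trace()]), and `truth` (parameter echo and per-particle tracks).
#' @export
make_dynamics_scene <- function(params) {
  stopifnot(inherits(params, "dynamics_scene_params"))
  set.seed(params$seed)
  nt <- floor(params$duration / params$frame_interval) + 1L
  n_px <- params$n_px
  bg <- 10
  v_px_frame <- params$velocity_um_min * 1000 / 60 * params$frame_interval /
    params$px_nm

  dims <- c(nt, 5L, n_px)
  stat_mov <- array(bg, dims)
  ant_mov <- array(0, dims)
  ret_mov <- array(0, dims)

  add_particle <- function(mov, x0, v) {
    I0 <- 100
    flick <- 1 + stats::rnorm(nt, 0, params$intensity_cv_true)
    for (t in seq_len(nt)) {
      x <- x0 + v * (t - 1)
      if (x < -5 || x > n_px + 5) next
      mov[t, 3, ] <- mov[t, 3, ] + .render_line(x, I0 * flick[t], n_px)
    }
    mov
  }
  for (k in seq_len(params$n_stationary)) {
    stat_mov <- add_particle(stat_mov, stats::runif(1, 10, n_px - 10), 0)
  }
  for (k in seq_len(params$n_antero)) {
    ant_mov <- add_particle(ant_mov, stats::runif(1, 5, n_px / 3), v_px_frame)
  }
  for (k in seq_len(params$n_retro)) {
    ret_mov <- add_particle(ret_mov, stats::runif(1, 2 * n_px / 3, n_px - 5),
                            -v_px_frame)
  }
  movie <- stat_mov + ant_mov + ret_mov

  # lifetime event stream (minutes)
  mix <- params$lifetime_mix
  short <- stats::runif(params$n_events) < mix[1]
  lifetimes <- ifelse(short, stats::rexp(params$n_events, 1 / mix[2]),
                      stats::rexp(params$n_events, 1 / mix[3]))
  onset <- stats::runif(params$n_events, 0, params$event_duration)
  events <- data.frame(
    event = seq_len(params$n_events),
    onset_min = onset, lifetime_min = lifetimes,
    x = stats::runif(params$n_events, 0, 20000),
    y = stats::runif(params$n_events, 0, 20000),
    from_short = short
  )
  detections <- .events_to_detections(events, params)

  frap <- simulate_frap_trace(A = params$frap_params$A,
                              K = params$frap_params$K,
                              noise_sd = params$frap_params$noise_sd)

  list(movie = movie,
       components = list(stationary = stat_mov, anterograde = ant_mov,
                         retrograde = ret_mov),
       events = events, detections = detections, frap = frap,
       truth = list(params = params, v_px_frame = v_px_frame))
}

# rasterize the event stream onto the event-stream clock (frame_interval s)
.events_to_detections <- function(events, params) {
  dt_min <- params$frame_interval / 60
  n_frames <- floor(params$event_duration / dt_min) + 1L
  rows <- lapply(seq_len(nrow(events)), function(i) {
    f0 <- ceiling(events$onset_min[i] / dt_min)
    f1 <- floor((events$onset_min[i] + events$lifetime_min[i]) / dt_min)
    f1 <- min(f1, n_frames - 1L)
    if (f1 < f0) return(NULL)
    fr <- f0:f1
    data.frame(frame = fr,
               x = events$x[i] + stats::rnorm(length(fr), 0, 20),
               y = events$y[i] + stats::rnorm(length(fr), 0, 20),
               intensity = 100, event = events$event[i])
  })
  out <- do.call(rbind, rows)
  out[order(out$frame), , drop = FALSE]
}

#' FRAP acquisition time schedule
#'
#' Times in minutes relative to the bleach: a 2 min baseline at 20 s
#' intervals (negative times), then for the clathrin protocol 3 min at 20 s,
#' 12 min at 60 s and 4 min at 120 s intervals (19 min total recovery); the
#' accessory-protein protocol is 3 min at 20 s plus 7 min at 60 s. t = 0 is
#' the first post-bleach frame.
#'
#' @param type `"clca"` (19 min recovery) or `"accessory"` (10 min).
#' @return numeric vector of times in minutes, baseline negative.
#' @export
frap_schedule <- function(type = c("clca", "accessory")) {
  type <- match.arg(type)
  baseline <- seq(-2, -1 / 3, by = 1 / 3)
  post <- if (type == "clca") {
    c(seq(0, 3, by = 1 / 3), seq(4, 15, by = 1), c(17, 19))
  } else {
    c(seq(0, 3, by = 1 / 3), seq(4, 10, by = 1))
  }
  c(baseline, post)
}

#' Simulate a raw FRAP trace
#'
#' Generates raw ROI / background / reference intensity channels for a
#' single-exponential recovery `A * (1 - exp(-K * t))` with optional
#' acquisition photobleaching applied to both ROI and reference (so the
#' double normalization in [normalize_frap()] cancels it) and additive
#' Gaussian noise on the normalized scale.
#'
#' @param A mobile fraction (0-1.2).
#' @param K recovery rate, 1/min.
#' @param noise_sd additive noise SD on the normalized ROI intensity.
#' @param schedule acquisition times (min), from [frap_schedule()].
#' @param bleach_frac fraction of ROI intensity removed by the bleach (1 =
#'   complete bleach).
#' @param acq_bleach_per_frame fractional intensity loss per acquired frame
#'   (photobleaching of the whole field), e.g. 0.02.
#' @param background,ref_level,roi_level raw intensity levels.
#' @param seed optional RNG seed for the noise.
#' @return a [frap_trace()].
#' @export
simulate_frap_trace <- function(A, K, noise_sd = 0,
                                schedule = frap_schedule("clca"),
                                bleach_frac = 1, acq_bleach_per_frame = 0,
                                background = 20, ref_level = 120,
                                roi_level = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- schedule
  fade <- (1 - acq_bleach_per_frame)^(seq_along(t) - 1)
  rec <- ifelse(t < 0, 1, (1 - bleach_frac) + bleach_frac * A * (1 - exp(-K * pmax(t, 0))))
  rec <- rec + stats::rnorm(length(t), 0, noise_sd)
  frap_trace(
    t = t,
    roi = background + (roi_level - background) * rec * fade,
    background = rep(background, length(t)),
    reference = background + (ref_level - background) * fade
  )
}
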