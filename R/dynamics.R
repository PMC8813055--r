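# Time-lapse analyses: kymograph construction along a path, Fourier-domain
# separation into stationary / anterograde / retrograde components,
# intensity coefficient of variation, greedy track linking and lifetime
# classification.

#' Build a kymograph along a path
#'
#' One row per timepoint; columns are arc-length samples (1 px spacing)
#' along the path. Intensity at each sample is the maximum over a
#' perpendicular band of `line_width_px` pixels, so a wide line over a thin
#' track equals the thin-line result.
#'
#' @param movie numeric array `(t, y, x)`, or a matrix `(t, x)` for an
#'   already-extracted line movie (then `path` is ignored).
#' @param path 2-column matrix of (x, y) pixel waypoints of the polyline;
#'   default: horizontal line through the middle row.
#' @param line_width_px odd integer band width (pixels).
#' @return matrix `(t, arc)` of class `kymograph`.
#' @export
build_kymograph <- function(movie, path = NULL, line_width_px = 1) {
  if (is.matrix(movie)) {
    return(structure(movie, class = c("kymograph", class(movie))))
  }
  stopifnot(length(dim(movie)) == 3)
  nt <- dim(movie)[1]; ny <- dim(movie)[2]; nx <- dim(movie)[3]
  if (is.null(path)) {
    path <- cbind(x = c(1, nx), y = rep((ny + 1) / 2, 2))
  }
  if (any(path[, 1] < 1 | path[, 1] > nx | path[, 2] < 1 | path[, 2] > ny)) {
    stop("path lies outside the movie frame", call. = FALSE)
  }
  # sample the polyline at ~1 px spacing
  samp <- NULL
  for (s in seq_len(nrow(path) - 1)) {
    a <- path[s, ]; b <- path[s + 1, ]
    len <- sqrt(sum((b - a)^2))
    tseq <- seq(0, 1, length.out = max(2, ceiling(len) + 1))
    if (s > 1) tseq <- tseq[-1]
    seg <- cbind(a[1] + tseq * (b[1] - a[1]), a[2] + tseq * (b[2] - a[2]))
    normal <- c(-(b[2] - a[2]), b[1] - a[1]) / max(len, 1e-9)
    samp <- rbind(samp, cbind(seg, matrix(normal, nrow(seg), 2, byrow = TRUE)))
  }
  half <- (line_width_px - 1) / 2
  offs <- if (half > 0) seq(-half, half) else 0
  kymo <- matrix(0, nt, nrow(samp))
  for (k in seq_len(nrow(samp))) {
    vals <- matrix(-Inf, nt, length(offs))
    for (oi in seq_along(offs)) {
      xx <- round(samp[k, 1] + offs[oi] * samp[k, 3])
      yy <- round(samp[k, 2] + offs[oi] * samp[k, 4])
      if (xx < 1 || xx > nx || yy < 1 || yy > ny) next
      vals[, oi] <- movie[, yy, xx]
    }
    kymo[, k] <- apply(vals, 1, max)
  }
  structure(kymo, class = c("kymograph", "matrix", "array"))
}

#' Fourier direction filtering of a kymograph
#'
#' 2D FFT decomposition into three frequency-domain bands: the stationary
#' component is the inverse transform of the temporal-frequency band
#' `|f_t| <= band_t` (vertical structures, plus the zero-spatial-frequency
#' column); the anterograde and retrograde components are the two remaining
#' quadrant pairs, split by the sign of `f_x * f_t` (a feature moving toward
#' +x concentrates its energy on `f_t = -v f_x`, i.e. `f_x * f_t < 0`).
#' The masks partition the spectrum, so the three components sum exactly to
#' the input (Parseval-complete). Components are returned unclipped.
#'
#' The default `band_t = 0` keeps only the temporally constant plane in the
#' stationary component: with the short acquisitions typical here (~60
#' frames at 5 s), a band of even one bin absorbs a large share of slow
#' directed motion, while truly stationary structures are constant in time
#' up to intensity flicker, which splits symmetrically (and therefore
#' harmlessly) between the two motion components.
#'
#' @param kymo matrix `(t, x)`, at least 8 x 8.
#' @param band_t half-width of the stationary temporal-frequency band, in
#'   frequency bins (default 0: the zero-frequency plane only).
#' @return list: `stationary`, `anterograde`, `retrograde` matrices.
#' @export
fourier_direction_filter <- function(kymo, band_t = 0) {
  if (!all(is.finite(kymo))) stop("kymograph contains non-finite values", call. = FALSE)
  nt <- nrow(kymo); nx <- ncol(kymo)
  if (nt < 8 || nx < 8) stop("kymograph must be at least 8 x 8", call. = FALSE)
  F <- stats::fft(kymo)
  sf <- function(n) { i <- 0:(n - 1); ifelse(i <= n / 2, i, i - n) }
  ft <- matrix(sf(nt), nt, nx)
  fx <- matrix(sf(nx), nt, nx, byrow = TRUE)
  stat_mask <- abs(ft) <= band_t | fx == 0
  ant_mask <- !stat_mask & (fx * ft < 0)
  ret_mask <- !stat_mask & (fx * ft > 0)
  # f_t = Nyquist with f_x != 0 has ambiguous sign; fold into stationary so
  # the three masks stay an exact partition
  leftover <- !(stat_mask | ant_mask | ret_mask)
  stat_mask <- stat_mask | leftover
  inv <- function(mask) Re(stats::fft(F * mask, inverse = TRUE)) / (nt * nx)
  list(stationary = inv(stat_mask), anterograde = inv(ant_mask),
       retrograde = inv(ret_mask))
}

#' Coefficient of variation of an intensity trace
#'
#' Sample SD divided by mean; the fluctuation measure distinguishing
#' rapidly exchanging shaft structures (CV ~ 0.06) from stable spine
#' structures (CV ~ 0.02).
#'
#' @param trace numeric vector, >= 2 samples, positive mean.
#' @return CV (dimensionless).
#' @export
trace_cv <- function(trace) {
  if (length(trace) < 2) stop("need at least 2 samples", call. = FALSE)
  m <- mean(trace)
  if (m <= 0) stop("trace mean must be > 0", call. = FALSE)
  stats::sd(trace) / m
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame assignment: at each frame, the
#' globally closest (track tail, detection) pairs within `max_link` are
#' linked first; unmatched detections start new tracks. Tracks may bridge
#' up to `max_gap_frames` missed frames. Each detection joins at most one
#' track. Greedy linking is adequate for sparse, well-separated puncta; it
#' is not an optimal (LAP) assignment.
#'
#' @param detections data.frame with columns frame, x, y and optionally
#'   intensity; positions in any consistent length unit.
#' @param max_link maximum linking distance (same unit as x, y).
#' @param max_gap_frames gap closing (0 = none).
#' @param frame_interval frame interval in minutes (lifetimes =
#'   `(last - first + 1) * frame_interval`).
#' @return a `track_set`: list with `tracks` (list of per-track data.frames)
#'   and `summary` (track, first, last, n, lifetime_min, censored_start,
#'   censored_end).
#' @export
link_tracks <- function(detections, max_link, max_gap_frames = 0L,
                        frame_interval = 1) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  det <- detections[order(detections$frame), , drop = FALSE]
  n <- nrow(det)
  track_id <- integer(n)
  tail_x <- numeric(0); tail_y <- numeric(0)
  tail_frame <- integer(0); tail_track <- integer(0)
  next_id <- 1L
  frames <- sort(unique(det$frame))
  idx_by_frame <- split(seq_len(n), factor(det$frame, levels = frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- idx_by_frame[[fi]]
    alive <- which(tail_frame >= f - 1L - max_gap_frames & tail_frame < f)
    taken_row <- rep(FALSE, length(rows))
    if (length(alive) && length(rows)) {
      d <- outer(det$x[rows], tail_x[alive], "-")^2 +
           outer(det$y[rows], tail_y[alive], "-")^2
      repeat {
        k <- which.min(d)
        if (!length(k) || d[k] > max_link^2) break
        ri <- (k - 1L) %% length(rows) + 1L
        ci <- (k - 1L) %/% length(rows) + 1L
        track_id[rows[ri]] <- tail_track[alive[ci]]
        taken_row[ri] <- TRUE
        d[ri, ] <- Inf; d[, ci] <- Inf
      }
    }
    for (ri in which(!taken_row)) {
      track_id[rows[ri]] <- next_id
      next_id <- next_id + 1L
    }
    for (ri in seq_along(rows)) {
      r <- rows[ri]; id <- track_id[r]
      at <- match(id, tail_track)
      if (is.na(at)) {
        tail_track <- c(tail_track, id)
        tail_x <- c(tail_x, det$x[r]); tail_y <- c(tail_y, det$y[r])
        tail_frame <- c(tail_frame, f)
      } else {
        tail_x[at] <- det$x[r]; tail_y[at] <- det$y[r]
        tail_frame[at] <- f
      }
    }
  }
  fmin <- min(frames); fmax <- max(frames)
  groups <- split(seq_len(n), track_id)
  tracks <- lapply(groups, function(g) det[g, , drop = FALSE])
  summary <- do.call(rbind, lapply(seq_along(groups), function(k) {
    g <- groups[[k]]
    f0 <- min(det$frame[g]); f1 <- max(det$frame[g])
    data.frame(track = as.integer(names(groups)[k]), first = f0, last = f1,
               n = length(g),
               lifetime_min = (f1 - f0 + 1) * frame_interval,
               censored_start = f0 == fmin, censored_end = f1 == fmax)
  }))
  structure(list(tracks = tracks, summary = summary), class = "track_set")
}

#' Classify lifetimes into short / intermediate / persistent
#'
#' Short: strictly less than `short_max` (default 3 min); persistent:
#' strictly greater than `persistent_min` (default 9 min); intermediate
#' otherwise — the boundaries are exclusive, so a lifetime of exactly 3 min
#' is intermediate. Censored tracks (alive at the movie start or end) have
#' unknown total lifetimes: they are counted as persistent if their observed
#' span already exceeds `persistent_min`, and excluded from the
#' classification otherwise. The per-synapse `stable` flag is TRUE when at
#' least one track is persistent.
#'
#' @param lifetimes numeric vector of lifetimes (minutes, >= 0).
#' @param censored logical vector (same length) marking censored tracks;
#'   NULL = none.
#' @param short_max,persistent_min class boundaries (minutes).
#' @return list: frac_short, frac_intermediate, frac_persistent,
#'   n_classified, stable.
#' @export
lifetime_classify <- function(lifetimes, censored = NULL,
                              short_max = 3, persistent_min = 9) {
  stopifnot(all(lifetimes >= 0))
  if (is.null(censored)) censored <- rep(FALSE, length(lifetimes))
  persistent <- lifetimes > persistent_min
  keep <- !censored | persistent
  lt <- lifetimes[keep]
  cls <- ifelse(lt < short_max, "short",
                ifelse(lt > persistent_min, "persistent", "intermediate"))
  n <- length(lt)
  list(frac_short = if (n) mean(cls == "short") else NA_real_,
       frac_intermediate = if (n) mean(cls == "intermediate") else NA_real_,
       frac_persistent = if (n) mean(cls == "persistent") else NA_real_,
       n_classified = n,
       stable = any(persistent))
}
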