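# Localization-table I/O and SMLM preprocessing: CSV dialects, run merging
# of consecutive-frame detections, precision filtering, ROI cropping.
# Canonical units are nm; frames are 0-based integers; all boundary
# conditions are closed (<=, inside-or-on).

#' Construct a localization table
#'
#' The canonical per-molecule detection table: one row per localization with
#' 0-based frame index, position in nm, optional localization precision
#' (the SD of the fitted position, nm) and a channel label.
#'
#' @param frame integer vector, 0-based frame indices (>= 0).
#' @param x,y numeric positions in nm.
#' @param precision numeric localization precision in nm (> 0), or NA.
#' @param channel character channel labels.
#' @param n_merged integer, number of raw detections merged into each row
#'   (1 for raw tables; filled by [merge_consecutive()]).
#' @return a `data.frame` of class `loc_table`, sorted by channel then frame
#'   (row order preserved within a frame).
#' @export
loc_table <- function(frame, x, y, precision = NA_real_, channel = "ch1",
                      n_merged = 1L) {
  n <- length(x)
  stopifnot(length(y) == n, length(frame) == n)
  if (any(frame < 0)) stop("frame indices must be >= 0", call. = FALSE)
  if (any(!is.na(precision) & precision < 0)) {
    stop("precision must be >= 0 where present", call. = FALSE)
  }
  tab <- data.frame(
    frame = as.integer(frame), x = as.numeric(x), y = as.numeric(y),
    precision = rep_len(as.numeric(precision), n),
    channel = rep_len(as.character(channel), n),
    n_merged = rep_len(as.integer(n_merged), n)
  )
  ord <- order(tab$channel, tab$frame)  # stable: preserves order within frame
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("loc_table", "data.frame")
  tab
}

#' Describe a localization CSV dialect
#'
#' Maps column names and units of an on-disk CSV onto the canonical table.
#' Covers ThunderSTORM-like exports (`"x [nm]"`, `"uncertainty [nm]"`) and
#' simple generic layouts; pixel units need `px_nm`.
#'
#' @param frame,x,y,precision,channel column names in the file; `precision`
#'   and `channel` may be NULL if absent.
#' @param xy_unit one of "nm", "um", "px" for the position columns.
#' @param px_nm pixel size in nm (required when `xy_unit = "px"`).
#' @return a `loc_dialect` list.
#' @export
loc_dialect <- function(frame = "frame", x = "x [nm]", y = "y [nm]",
                        precision = "uncertainty [nm]", channel = NULL,
                        xy_unit = c("nm", "um", "px"), px_nm = NULL) {
  xy_unit <- match.arg(xy_unit)
  if (xy_unit == "px" && is.null(px_nm)) {
    stop("px_nm is required when xy_unit = 'px'", call. = FALSE)
  }
  structure(list(frame = frame, x = x, y = y, precision = precision,
                 channel = channel, xy_unit = xy_unit, px_nm = px_nm),
            class = "loc_dialect")
}

.unit_factor <- function(dialect) {
  switch(dialect$xy_unit, nm = 1, um = 1000, px = dialect$px_nm)
}

.numeric_column <- function(raw, name) {
  v <- suppressWarnings(as.numeric(raw[[name]]))
  bad <- which(is.na(v) & !is.na(raw[[name]]) & raw[[name]] != "")
  if (length(bad)) {
    stop(sprintf("non-numeric value in column '%s' at data row %d", name, bad[1]),
         call. = FALSE)
  }
  v
}

#' Read a localization CSV
#'
#' @param path CSV file with a header row.
#' @param dialect a [loc_dialect()] describing column names and units.
#' @return a [loc_table()] in canonical nm units.
#' @export
read_localizations <- function(path, dialect = loc_dialect()) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("frame", "x", "y")) {
    if (!(dialect[[col]] %in% names(raw))) {
      stop(sprintf("missing mandatory column '%s' in %s", dialect[[col]], path),
           call. = FALSE)
    }
  }
  f <- .unit_factor(dialect)
  prec <- if (!is.null(dialect$precision) && dialect$precision %in% names(raw)) {
    .numeric_column(raw, dialect$precision) * f
  } else NA_real_
  chan <- if (!is.null(dialect$channel) && dialect$channel %in% names(raw)) {
    as.character(raw[[dialect$channel]])
  } else "ch1"
  nm <- if ("n_merged" %in% names(raw)) as.integer(raw$n_merged) else 1L
  loc_table(
    frame = .numeric_column(raw, dialect$frame),
    x = .numeric_column(raw, dialect$x) * f,
    y = .numeric_column(raw, dialect$y) * f,
    precision = prec, channel = chan, n_merged = nm
  )
}

#' Write a localization table as CSV (nm units)
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  out <- data.frame(
    frame = table$frame,
    `x [nm]` = table$x, `y [nm]` = table$y,
    `uncertainty [nm]` = table$precision,
    channel = table$channel, n_merged = table$n_merged,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge localizations detected in consecutive frames
#'
#' Blinking fluorophores are detected as runs of localizations over
#' consecutive frames. Within each channel, localizations in successive
#' frames closer than `merge_radius` are linked into one run (greedy
#' nearest-neighbour, one detection per run per frame) and each run is
#' collapsed to a single localization at the precision-weighted mean
#' position. The output frame is the first frame of the run and the output
#' precision is the pooled SD of the weighted mean,
#' `1 / sqrt(sum(1 / precision_i^2))` (equal weights when precisions are
#' missing or zero). `n_merged` records the run length, so the operation is
#' idempotent: a merged row occupies its full frame span and can only link
#' to detections in the frame after the span ends — links the first pass
#' would already have made.
#'
#' @param table a [loc_table()], sorted by frame within channel.
#' @param merge_radius linking radius in nm (> 0). Default 30 nm.
#' @param max_gap number of missed frames a run may bridge (0 = strictly
#'   consecutive frames only).
#' @return a [loc_table()] with one row per run.
#' @export
merge_consecutive <- function(table, merge_radius = 30, max_gap = 0L) {
  if (!is.numeric(merge_radius) || merge_radius <= 0) {
    stop("merge_radius must be > 0", call. = FALSE)
  }
  pieces <- lapply(split(seq_len(nrow(table)), table$channel), function(idx) {
    .merge_channel(table[idx, , drop = FALSE], merge_radius, as.integer(max_gap))
  })
  out <- do.call(rbind, pieces)
  # canonical order (content-determined), so repeated merging is identical
  out <- out[order(out$channel, out$frame, out$x, out$y), , drop = FALSE]
  loc_table(out$frame, out$x, out$y, out$precision, out$channel, out$n_merged)
}

.merge_channel <- function(tab, radius, max_gap) {
  n <- nrow(tab)
  if (n == 0) return(tab)
  run_id <- integer(n)
  # active runs: index of the row currently representing each run's tail
  tail_x <- numeric(0); tail_y <- numeric(0)
  tail_last <- integer(0); tail_run <- integer(0); tail_raw <- logical(0)
  next_run <- 1L
  frames <- sort(unique(tab$frame))
  idx_by_frame <- split(seq_len(n), factor(tab$frame, levels = frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    rows <- idx_by_frame[[fi]]
    alive <- tail_last >= f - 1L - max_gap & tail_last < f
    cand_runs <- which(alive)
    taken_row <- rep(FALSE, length(rows))
    taken_run <- rep(FALSE, length(cand_runs))
    # a link joins two raw (unmerged) detections: rows that already
    # represent a completed blink run (n_merged > 1) neither extend a run
    # nor accept extensions -- this is what makes merging idempotent
    linkable <- tab$n_merged[rows] == 1L
    if (length(cand_runs) && any(linkable)) {
      d <- outer(tab$x[rows], tail_x[cand_runs], "-")^2 +
           outer(tab$y[rows], tail_y[cand_runs], "-")^2
      d[!linkable, ] <- Inf
      d[, !tail_raw[cand_runs]] <- Inf
      repeat {
        k <- which.min(d)
        if (!length(k) || d[k] > radius^2) break
        ri <- (k - 1L) %% length(rows) + 1L
        ci <- (k - 1L) %/% length(rows) + 1L
        run_id[rows[ri]] <- tail_run[cand_runs[ci]]
        taken_row[ri] <- TRUE; taken_run[ci] <- TRUE
        d[ri, ] <- Inf; d[, ci] <- Inf
      }
    }
    for (ri in which(!taken_row)) {
      run_id[rows[ri]] <- next_run
      next_run <- next_run + 1L
    }
    # update tails: a linked or new row becomes its run's tail; its span end
    # is frame + n_merged - 1 (merged rows occupy their full original span)
    for (ri in seq_along(rows)) {
      r <- rows[ri]; rid <- run_id[r]
      span_end <- tab$frame[r] + tab$n_merged[r] - 1L
      at <- match(rid, tail_run)
      if (is.na(at)) {
        tail_run <- c(tail_run, rid)
        tail_x <- c(tail_x, tab$x[r]); tail_y <- c(tail_y, tab$y[r])
        tail_last <- c(tail_last, span_end)
        tail_raw <- c(tail_raw, tab$n_merged[r] == 1L)
      } else {
        tail_x[at] <- tab$x[r]; tail_y[at] <- tab$y[r]
        tail_last[at] <- span_end
        tail_raw[at] <- tab$n_merged[r] == 1L
      }
    }
  }
  groups <- split(seq_len(n), run_id)
  res <- lapply(groups, function(g) {
    if (length(g) == 1L) {  # untouched rows pass through bit-identically
      return(tab[g, c("frame", "x", "y", "precision", "channel", "n_merged")])
    }
    prec <- tab$precision[g]
    w <- if (all(is.finite(prec)) && all(prec > 0)) 1 / prec^2 else rep(1, length(g))
    w <- w / sum(w)
    pooled <- if (all(is.finite(prec)) && all(prec > 0)) {
      1 / sqrt(sum(1 / prec^2))
    } else if (all(is.finite(prec))) {
      mean(prec) / sqrt(length(g))
    } else NA_real_
    data.frame(
      frame = min(tab$frame[g]),
      x = sum(w * tab$x[g]), y = sum(w * tab$y[g]),
      precision = pooled, channel = tab$channel[g][1],
      n_merged = sum(tab$n_merged[g])
    )
  })
  do.call(rbind, res)
}

#' Filter localizations by precision
#'
#' Retains rows whose localization precision is at or below `cutoff`
#' (boundary inclusive). The standard post-merge quality cut in SMLM; the
#' default 15 nm matches common dSTORM practice.
#'
#' @param table a [loc_table()] with a precision column.
#' @param cutoff precision cutoff in nm (> 0). `Inf` is the identity.
#' @return filtered [loc_table()], row order preserved.
#' @export
precision_filter <- function(table, cutoff = 15) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (all(is.na(table$precision))) {
    stop("table has no precision values to filter on", call. = FALSE)
  }
  keep <- !is.na(table$precision) & table$precision <= cutoff
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a set of rectangular or circular ROIs
#'
#' @param centers n x 2 matrix of ROI centers (nm).
#' @param width,height box dimensions (nm), or
#' @param radius circle radius (nm); give either box or radius.
#' @param labels unique ROI labels.
#' @return a `roi_set` list.
#' @export
roi_set <- function(centers, width = NULL, height = width, radius = NULL,
                    labels = NULL) {
  centers <- rbind(centers)
  n <- nrow(centers)
  if (is.null(labels)) labels <- paste0("roi", seq_len(n))
  if (anyDuplicated(labels)) stop("ROI labels must be unique", call. = FALSE)
  if (is.null(radius)) {
    if (is.null(width) || any(width <= 0) || any(height <= 0)) {
      stop("ROI sizes must be > 0", call. = FALSE)
    }
  } else if (any(radius <= 0)) stop("ROI sizes must be > 0", call. = FALSE)
  structure(list(centers = centers, width = width, height = height,
                 radius = radius, labels = labels),
            class = "roi_set")
}

#' Crop a localization table to one ROI
#'
#' Retains rows whose position lies inside or on the ROI boundary (closed
#' region). An empty result is a valid empty table, not an error.
#'
#' @param table a [loc_table()].
#' @param roi a [roi_set()].
#' @param which index or label of the ROI to crop to.
#' @return cropped [loc_table()].
#' @export
crop_to_roi <- function(table, roi, which = 1L) {
  if (is.character(which)) which <- match(which, roi$labels)
  cx <- roi$centers[which, 1]; cy <- roi$centers[which, 2]
  keep <- if (!is.null(roi$radius)) {
    r <- rep_len(roi$radius, nrow(roi$centers))[which]
    (table$x - cx)^2 + (table$y - cy)^2 <= r^2
  } else {
    w <- rep_len(roi$width, nrow(roi$centers))[which]
    h <- rep_len(roi$height, nrow(roi$centers))[which]
    abs(table$x - cx) <= w / 2 & abs(table$y - cy) <= h / 2
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read an ROI set as JSON
#' @param roi a [roi_set()].
#' @param path JSON path.
#' @return `path` (write) or a `roi_set` (read).
#' @export
write_roi_set <- function(roi, path) {
  jsonlite::write_json(
    list(centers = roi$centers, width = roi$width, height = roi$height,
         radius = roi$radius, labels = roi$labels),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_set(centers = matrix(unlist(obj$centers), ncol = 2),
          width = obj$width, height = obj$height, radius = obj$radius,
          labels = obj$labels)
}
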