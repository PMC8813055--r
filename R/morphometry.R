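# Pixel-mask morphometry of clathrin puncta at confocal/STED resolution:
# connected components, Feret (caliper) dimensions, circularity, and
# PSD-association scoring with fixed-diameter circular ROIs.
# Masks are logical matrices indexed [row = y, col = x]; pixel centers sit
# at integer coordinates (col, row).

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 0, 0, 1); dc <- c(0, -1, 1, 0)
  }
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || labels[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    labels[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      rr <- p[1] + dr; cc <- p[2] + dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      for (k in which(ok)) {
        if (mask[rr[k], cc[k]] && labels[rr[k], cc[k]] == 0L) {
          labels[rr[k], cc[k]] <- cur
          stack[[length(stack) + 1L]] <- c(rr[k], cc[k])
        }
      }
    }
  }
  labels
}

# boundary pixels: foreground with at least one 4-neighbor outside the mask
# (or on the image edge); returns (x = col, y = row) centers
.boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)]
  idx <- which(mask & !inner, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

# Moore-neighbor contour tracing with Jacob's stopping criterion.
# Returns the closed contour path through boundary pixel centers (x, y);
# path length in pixel units is the perimeter estimate.
.trace_contour <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1) return(cbind(x = idx[1, 2], y = idx[1, 1]))
  # start: topmost pixel of leftmost column containing foreground
  j0 <- min(idx[, 2]); i0 <- min(idx[idx[, 2] == j0, 1])
  # clockwise Moore neighborhood (dr, dc) starting west
  nb <- cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
              dc = c(-1, -1, 0, 1, 1, 1, 0, -1))
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j]
  path <- list(c(i0, j0))
  cur <- c(i0, j0)
  back_dir <- 1L  # we "entered" from the west
  first_next <- NULL
  repeat {
    found <- FALSE
    for (s in seq_len(8)) {
      d <- (back_dir - 1L + s - 1L) %% 8L + 1L
      ni <- cur[1] + nb[d, 1]; nj <- cur[2] + nb[d, 2]
      if (inside(ni, nj)) {
        # new backtrack: the neighbor direction just before the hit,
        # expressed from the new pixel
        prev_d <- (d - 2L) %% 8L + 1L
        bi <- cur[1] + nb[prev_d, 1]; bj <- cur[2] + nb[prev_d, 2]
        rel <- c(bi - ni, bj - nj)
        back_dir <- which(nb[, 1] == rel[1] & nb[, 2] == rel[2])
        cur <- c(ni, nj)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel handled above; safety
    if (cur[1] == i0 && cur[2] == j0) {
      if (is.null(first_next)) first_next <- path[[2]]
      # Jacob: stop when re-entering the start heading the same way
      if (length(path) > 2) break
    }
    path[[length(path) + 1L]] <- cur
    if (is.null(first_next) && length(path) == 2) first_next <- path[[2]]
    if (length(path) > 8 * sum(mask) + 8) break  # safety bound
  }
  m <- do.call(rbind, path)
  cbind(x = m[, 2], y = m[, 1])
}

# perimeter of a mask in pixel units: length of the traced closed contour
.mask_perimeter_px <- function(mask) {
  ct <- .trace_contour(mask)
  if (nrow(ct) < 2) return(0)
  closed <- rbind(ct, ct[1, ])
  sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
}

#' Feret (caliper) dimensions of a mask
#'
#' Length is the maximum Feret diameter: the largest pairwise distance
#' between boundary pixel centers plus one pixel (accounting for pixel
#' extent). Width is the minimum caliper width over all orientations
#' (rotating calipers on the convex hull of boundary centers) plus one
#' pixel.
#'
#' @param mask logical matrix containing a single object.
#' @param px_um pixel size in um.
#' @return `c(length, width)` in um.
#' @export
feret_dimensions <- function(mask, px_um = 0.04) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  b <- .boundary_pixels(mask)
  if (nrow(b) == 1) return(c(px_um, px_um))
  pts <- unique(b)
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  # max pairwise distance over hull points
  dmax <- 0
  for (i in seq_len(nrow(hull))) {
    d2 <- (hull[, 1] - hull[i, 1])^2 + (hull[, 2] - hull[i, 2])^2
    dmax <- max(dmax, sqrt(max(d2)))
  }
  # min caliper width: for each hull edge, max distance of hull points to it
  if (nrow(hull) < 3) {
    wmin <- 0  # collinear object
  } else {
    wmin <- Inf
    m <- nrow(hull)
    for (i in seq_len(m)) {
      a <- hull[i, ]; bb <- hull[i %% m + 1, ]
      e <- bb - a; len <- sqrt(sum(e^2))
      if (len == 0) next
      d <- abs((hull[, 1] - a[1]) * e[2] - (hull[, 2] - a[2]) * e[1]) / len
      wmin <- min(wmin, max(d))
    }
  }
  c((dmax + 1) * px_um, (wmin + 1) * px_um)
}

#' Circularity of a mask
#'
#' `4 * pi * area / perimeter^2` with the area as the pixel count and the
#' perimeter as the length of the traced 8-connected boundary contour
#' through pixel centers; clipped to at most 1. A single-pixel object is
#' defined as perfectly circular.
#'
#' @param mask logical matrix containing a single object.
#' @return circularity ratio in (0, 1].
#' @export
circularity <- function(mask) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  p <- .mask_perimeter_px(mask)
  if (p == 0) return(1)
  min(1, 4 * pi * sum(mask) / p^2)
}

#' Shape metrics for every punctum in a mask
#'
#' @param mask logical matrix (possibly several objects).
#' @param px_um pixel size in um.
#' @param connectivity component connectivity (8 default).
#' @return data.frame: component, n_px, area_um2, feret_length_um,
#'   feret_width_um, circularity.
#' @export
punctum_shapes <- function(mask, px_um = 0.04, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(ids)) stop("empty mask", call. = FALSE)
  do.call(rbind, lapply(ids, function(id) {
    m <- lab == id
    fer <- feret_dimensions(m, px_um)
    data.frame(component = id, n_px = sum(m),
               area_um2 = sum(m) * px_um^2,
               feret_length_um = fer[1], feret_width_um = fer[2],
               circularity = circularity(m))
  }))
}

#' Score EZ-PSD association with fixed-diameter circular ROIs
#'
#' A circular region of fixed diameter is centered on each PSD; the synapse
#' is positive if at least one connected component of the clathrin (or
#' endocytic-protein) mask overlaps the closed disc partially or completely.
#' Also returns the number of distinct overlapping components per PSD
#' (CCSs per synapse).
#'
#' @param psd_centers n x 2 matrix of PSD centers in um (x, y).
#' @param mask logical matrix of puncta.
#' @param roi_diameter_um ROI diameter in um, in `[0.1, 2]`; default 0.79
#'   (midpoint of the 0.69-0.89 um range used in practice).
#' @param px_um pixel size in um.
#' @param connectivity component connectivity.
#' @return list: `fraction` of positive synapses, `per_psd` data.frame
#'   (x, y, count, positive).
#' @export
associate_ez_psd <- function(psd_centers, mask, roi_diameter_um = 0.79,
                             px_um = 0.04, connectivity = 8) {
  psd_centers <- rbind(psd_centers)
  if (nrow(psd_centers) == 0) stop("no PSD centers provided", call. = FALSE)
  if (roi_diameter_um < 0.1 || roi_diameter_um > 2) {
    stop("roi_diameter_um must be in [0.1, 2]", call. = FALSE)
  }
  lab <- label_components(mask, connectivity)
  fg <- which(mask, arr.ind = TRUE)
  px_x <- fg[, 2] * px_um; px_y <- fg[, 1] * px_um
  px_lab <- lab[fg]
  r <- roi_diameter_um / 2
  per <- lapply(seq_len(nrow(psd_centers)), function(i) {
    d2 <- (px_x - psd_centers[i, 1])^2 + (px_y - psd_centers[i, 2])^2
    comps <- unique(px_lab[d2 <= r^2])
    data.frame(x = psd_centers[i, 1], y = psd_centers[i, 2],
               count = length(comps), positive = length(comps) > 0)
  })
  per <- do.call(rbind, per)
  list(fraction = mean(per$positive), per_psd = per)
}

#' Rasterize discs into a binary mask (synthetic morphometry scenes)
#'
#' @param centers_um n x 2 disc centers (um).
#' @param radius_um disc radii (recycled).
#' @param img_px image size in pixels (square).
#' @param px_um pixel size (um).
#' @return logical matrix; a pixel is foreground if its center lies in a
#'   disc (closed).
#' @export
rasterize_discs <- function(centers_um, radius_um, img_px = 512, px_um = 0.04) {
  centers_um <- rbind(centers_um)
  radius_um <- rep_len(radius_um, nrow(centers_um))
  xs <- (1:img_px) * px_um
  mask <- matrix(FALSE, img_px, img_px)
  for (i in seq_len(nrow(centers_um))) {
    dx2 <- (xs - centers_um[i, 1])^2  # columns = x
    dy2 <- (xs - centers_um[i, 2])^2  # rows = y
    mask <- mask | (outer(dy2, dx2, "+") <= radius_um[i]^2)
  }
  mask
}

#' Synthetic mask scene for association scoring
#'
#' Places PSD centers at random; a known fraction get a clathrin punctum
#' within the association ROI, the rest get one far outside it.
#'
#' @param n_psd number of synapses.
#' @param p_associated ground-truth associated fraction.
#' @param roi_diameter_um ROI diameter used downstream (placement margin).
#' @param punctum_radius_um punctum radius (um).
#' @param img_px,px_um image geometry.
#' @param seed RNG seed.
#' @return list: `psd_centers` (um), `mask`, `truth` (per-synapse logical).
#' @export
make_mask_scene <- function(n_psd = 24, p_associated = 0.75,
                            roi_diameter_um = 0.79, punctum_radius_um = 0.12,
                            img_px = 512, px_um = 0.04, seed = 1L) {
  set.seed(seed)
  ext <- img_px * px_um
  margin <- roi_diameter_um + 4 * punctum_radius_um
  centers <- cbind(stats::runif(n_psd, margin, ext - margin),
                   stats::runif(n_psd, margin, ext - margin))
  assoc <- stats::runif(n_psd) < p_associated
  th <- stats::runif(n_psd, 0, 2 * pi)
  near_d <- stats::runif(n_psd, 0, roi_diameter_um / 2 * 0.8)
  far_d <- roi_diameter_um / 2 + punctum_radius_um + 0.15 +
    stats::runif(n_psd, 0, 0.1)
  d <- ifelse(assoc, near_d, far_d)
  puncta <- centers + cbind(d * cos(th), d * sin(th))
  mask <- rasterize_discs(puncta, punctum_radius_um, img_px, px_um)
  list(psd_centers = centers, mask = mask, truth = assoc)
}
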