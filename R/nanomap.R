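# Nanoscale cluster geometry: DBSCAN clustering of localization maps,
# border polygon extraction, signed distances, FWTM dimensions,
# primary/secondary classification and border-scaled ring density profiles.

#' DBSCAN parameters
#'
#' The two regimes used on synaptic localization maps are
#' `dbscan_params(0.2, 100)` (PSD / EZ border definition) and
#' `dbscan_params(0.35, 50)` (endocytic-protein channels). `eps` is in
#' micrometers; localization coordinates are nm, so it is converted
#' internally (0.2 um = 200 nm — the only physically sensible scale for
#' structures of ~150-250 nm).
#'
#' @param eps_um neighborhood radius in um (> 0).
#' @param min_pts minimum number of localizations in an eps-neighborhood
#'   (self included) for a core point (>= 1).
#' @return a `dbscan_params` list.
#' @export
dbscan_params <- function(eps_um = 0.2, min_pts = 100) {
  if (!is.numeric(eps_um) || eps_um <= 0) stop("eps_um must be > 0", call. = FALSE)
  if (min_pts < 1) stop("min_pts must be >= 1", call. = FALSE)
  structure(list(eps_um = eps_um, min_pts = as.integer(min_pts)),
            class = "dbscan_params")
}

#' DBSCAN clustering of 2D localizations
#'
#' Standard density-based clustering: a core point has at least `min_pts`
#' neighbors within `eps` (itself included); clusters are maximal
#' density-connected sets of core points plus the border points within `eps`
#' of them. Clusters are numbered by discovery order under the input point
#' ordering, and a border point reachable from several clusters is assigned
#' to the first-discovered one — a deterministic tie-break.
#'
#' @param points n x 2 matrix (nm), or a [loc_table()] (x, y used).
#' @param params a [dbscan_params()].
#' @return integer vector of cluster labels; 0 = noise.
#' @export
dbscan_cluster <- function(points, params = dbscan_params()) {
  pts <- if (inherits(points, "loc_table")) cbind(points$x, points$y) else rbind(points)
  n <- nrow(pts)
  if (n < 1) stop("at least one point required", call. = FALSE)
  eps <- params$eps_um * 1000
  eps2 <- eps^2
  x <- pts[, 1]; y <- pts[, 2]
  neighbors <- vector("list", n)
  n_nb <- integer(n)
  for (i in seq_len(n)) {
    nb <- which((x - x[i])^2 + (y - y[i])^2 <= eps2)
    neighbors[[i]] <- nb
    n_nb[i] <- length(nb)
  }
  core <- n_nb >= params$min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- i
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      nb <- neighbors[[p]]
      grow <- nb[core[nb] & labels[nb] == 0L]
      labels[grow] <- cl
      queue <- c(queue, grow)
    }
  }
  # border points: first-discovered (smallest-label) cluster among core
  # neighbors
  for (i in seq_len(n)) {
    if (core[i] || labels[i] != 0L) next
    nb <- neighbors[[i]]
    cand <- labels[nb][core[nb]]
    if (length(cand)) labels[i] <- min(cand)
  }
  labels
}

#' Border polygon of one cluster
#'
#' The cluster outline used for all downstream geometry: by default the
#' convex hull of the member localizations (the full "100% polyshape");
#' optionally a concave alpha-shape for non-convex clusters.
#'
#' @param points n x 2 matrix of member localizations (nm).
#' @param method `"convex"` (default) or `"concave"`.
#' @param alpha alpha-shape disc radius in nm (required for `"concave"`).
#' @return polygon matrix (CCW vertices, nm).
#' @export
cluster_border <- function(points, method = c("convex", "concave"), alpha = NULL) {
  method <- match.arg(method)
  pts <- if (inherits(points, "loc_table")) cbind(points$x, points$y) else rbind(points)
  if (method == "convex") convex_hull_polygon(pts)
  else {
    if (is.null(alpha)) stop("alpha (nm) is required for the concave border",
                             call. = FALSE)
    alpha_shape_polygon(pts, alpha)
  }
}

#' Build a cluster set from labeled localizations
#'
#' Per-cluster border polygon, centroid (of the border polygon), area and
#' FWTM dimensions.
#'
#' @param points n x 2 matrix (nm) or a [loc_table()].
#' @param labels cluster labels from [dbscan_cluster()] (0 = noise).
#' @param border_method,alpha passed to [cluster_border()].
#' @param min_cluster_size clusters with fewer points are skipped.
#' @return a `cluster_set`: list with `clusters` (data.frame: cluster, n,
#'   centroid_x/y, area_nm2, fwtm_length_nm, fwtm_width_nm), `borders`
#'   (named list of polygons) and `labels`.
#' @export
build_cluster_set <- function(points, labels, border_method = "convex",
                              alpha = NULL, min_cluster_size = 10) {
  pts <- if (inherits(points, "loc_table")) cbind(points$x, points$y) else rbind(points)
  ids <- sort(setdiff(unique(labels), 0L))
  rows <- list(); borders <- list()
  for (id in ids) {
    mem <- pts[labels == id, , drop = FALSE]
    if (nrow(mem) < min_cluster_size) next
    border <- cluster_border(mem, border_method, alpha)
    cen <- polygon_centroid(border)
    fwtm <- fwtm_dimensions(mem)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = id, n = nrow(mem),
      centroid_x = cen[1], centroid_y = cen[2],
      area_nm2 = polygon_area(border),
      fwtm_length_nm = fwtm[1], fwtm_width_nm = fwtm[2]
    )
    borders[[as.character(id)]] <- border
  }
  structure(list(clusters = do.call(rbind, rows), borders = borders,
                 labels = labels),
            class = "cluster_set")
}

#' Signed border-to-centroid distance
#'
#' Distance from a cluster centroid (e.g. the EZ center) to the border of a
#' reference polygon (e.g. the PSD outline). The magnitude is the minimum
#' Euclidean distance to the boundary; the sign is positive when the
#' centroid lies outside the polygon and negative inside.
#'
#' @param border polygon matrix (nm).
#' @param centroid query point (x, y) in nm.
#' @return signed distance in nm.
#' @export
border_to_centroid_distance <- function(border, centroid) {
  if (nrow(border) < 3) stop("degenerate polygon", call. = FALSE)
  as.numeric(distance_to_border(rbind(centroid), border))
}

#' Signed distance of points to a border polygon
#'
#' Negative inside the border, positive outside, zero on it — so a
#' population histogram of an edge-enriched protein peaks around 0.
#'
#' @param points n x 2 matrix (nm) or [loc_table()].
#' @param border polygon matrix (nm).
#' @return numeric vector of signed distances (nm).
#' @export
distance_to_border <- function(points, border) {
  pts <- if (inherits(points, "loc_table")) cbind(points$x, points$y) else rbind(points)
  d <- point_to_polygon_distance(pts, border)
  inside <- point_in_polygon(pts, border)
  ifelse(inside, -d, d)
}

#' Full width at tenth maximum along principal axes
#'
#' Projects the localizations onto their two principal (covariance) axes,
#' histograms each projection (`bin_nm`-wide bins, Gaussian-smoothed with SD
#' `smooth_sigma_bins` bins) and measures the width of the region where the
#' smoothed profile is at least 10% of its maximum, with linear
#' interpolation at the crossings. For a Gaussian cluster of SD sigma the
#' expected FWTM is `2 * sqrt(2 * log(10)) * sigma ~= 4.29 * sigma`.
#'
#' @param points n x 2 matrix (nm).
#' @param bin_nm histogram bin width (nm).
#' @param smooth_sigma_bins smoothing kernel SD in bins.
#' @return `c(length, width)` in nm, length >= width.
#' @export
fwtm_dimensions <- function(points, bin_nm = 5, smooth_sigma_bins = 2) {
  pts <- rbind(points)
  if (nrow(pts) < 1) stop("empty cluster", call. = FALSE)
  ctr <- colMeans(pts)
  centered <- sweep(pts, 2, ctr)
  if (all(abs(centered) < 1e-12)) return(c(0, 0))
  ev <- eigen(stats::cov(centered), symmetric = TRUE)$vectors
  proj <- centered %*% ev
  w <- vapply(1:2, function(k) .fwtm_1d(proj[, k], bin_nm, smooth_sigma_bins),
              numeric(1))
  c(max(w), min(w))
}

.fwtm_1d <- function(v, bin_nm, sigma_bins, frac = 0.1) {
  if (diff(range(v)) < 1e-12) return(0)
  pad <- 4 * sigma_bins * bin_nm
  breaks <- seq(min(v) - pad - bin_nm, max(v) + pad + bin_nm, by = bin_nm)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  if (sigma_bins > 0) {
    half <- ceiling(4 * sigma_bins)
    kern <- stats::dnorm(-half:half, sd = sigma_bins)
    kern <- kern / sum(kern)
    h <- stats::filter(c(rep(0, half), h, rep(0, half)), kern, sides = 2)
    h <- as.numeric(h[(half + 1):(half + length(breaks) - 1)])
  }
  if (all(h == 0)) stop("empty histogram", call. = FALSE)
  centers <- breaks[-length(breaks)] + bin_nm / 2
  thr <- frac * max(h)
  above <- which(h >= thr)
  lo <- above[1]; hi <- above[length(above)]
  # linear interpolation at the two threshold crossings
  left <- if (lo > 1 && h[lo] > h[lo - 1]) {
    centers[lo - 1] + (thr - h[lo - 1]) / (h[lo] - h[lo - 1]) * bin_nm
  } else centers[lo]
  right <- if (hi < length(h) && h[hi] > h[hi + 1]) {
    centers[hi] + (h[hi] - thr) / (h[hi] - h[hi + 1]) * bin_nm
  } else centers[hi]
  right - left
}

#' Classify clathrin structures at one synapse as primary / secondary
#'
#' Among the clathrin clusters associated with one PSD, the largest (by
#' border area) is the primary structure (the EZ); all others are secondary
#' (endocytic-vesicle scale). Exact area ties are broken by proximity to the
#' PSD border (nearer wins).
#'
#' @param areas per-cluster areas (nm^2), or a `cluster_set` (areas taken
#'   from it).
#' @param dist_to_psd optional per-cluster distance to the PSD border (nm),
#'   used only to break area ties.
#' @return character vector: `"primary"` / `"secondary"`.
#' @export
classify_primary_secondary <- function(areas, dist_to_psd = NULL) {
  if (inherits(areas, "cluster_set")) areas <- areas$clusters$area_nm2
  n <- length(areas)
  if (n < 1) stop("at least one cluster required", call. = FALSE)
  best <- which(areas == max(areas))
  if (length(best) > 1 && !is.null(dist_to_psd)) {
    best <- best[which.min(dist_to_psd[best])]
  } else {
    best <- best[1]
  }
  out <- rep("secondary", n)
  out[best] <- "primary"
  out
}

#' Border-scaled concentric rings and their analytic area fractions
#'
#' Scales the border polygon about its centroid by each edge fraction; ring
#' k is the region between scales `edges[k]` and `edges[k + 1]`. Because a
#' homothety scales any simple polygon's area by the square of the factor,
#' the area fraction of ring k relative to the full ringed region is
#' `(edges[k+1]^2 - edges[k]^2) / max(edges)^2`, independent of the polygon.
#' The standard profile uses five inward rings (0-20 ... 80-100% of the
#' border) and three outward rings (100-120, 120-140, 140-160%).
#'
#' @param border simple polygon matrix (nm).
#' @param edges strictly increasing scale fractions starting at 0;
#'   default `seq(0, 1.6, by = 0.2)`.
#' @return list with `outer` (list of scaled polygons, one per edge > 0),
#'   `area_fraction` (analytic, sums to 1), `computed_area_fraction` (from
#'   polygon areas, for verification) and `edges`.
#' @export
scaled_rings <- function(border, edges = seq(0, 1.6, by = 0.2)) {
  if (!is_simple_polygon(border)) stop("border polygon is not simple", call. = FALSE)
  if (any(diff(edges) <= 0) || edges[1] != 0) {
    stop("edges must start at 0 and be strictly increasing", call. = FALSE)
  }
  cen <- polygon_centroid(border)
  scales <- edges[-1]
  polys <- lapply(scales, function(f) scale_polygon(border, f, cen))
  areas <- vapply(polys, polygon_area, numeric(1))
  ring_area <- diff(c(0, areas))
  area_fraction <- diff(edges^2) / max(edges)^2
  list(outer = polys, edges = edges,
       area_fraction = area_fraction,
       computed_area_fraction = ring_area / areas[length(areas)])
}

#' Ring density profile of a query channel around one border
#'
#' Each query localization is assigned a normalized radial scale: the ratio
#' of its centroid distance to the border radius in its direction (1 = on
#' the border). Scales are binned into the border-scaled rings; the
#' localization fraction per ring (denominator: localizations within the
#' outermost ring) is divided by the ring's area fraction and the resulting
#' density vector renormalized (unit sum by default) so that uniformly
#' spread localizations give a flat profile of 1/8.
#'
#' @param border simple polygon (nm); must be star-shaped about its centroid
#'   (convex borders always are).
#' @param points query localizations, n x 2 matrix (nm) or [loc_table()].
#' @param edges ring edges as in [scaled_rings()].
#' @param normalize `"sum"` (density sums to 1, default) or `"max"`.
#' @return a `ring_profile` data.frame: ring, inner, outer, n, loc_fraction,
#'   area_fraction, density.
#' @export
ring_density_profile <- function(border, points, edges = seq(0, 1.6, by = 0.2),
                                 normalize = c("sum", "max")) {
  normalize <- match.arg(normalize)
  pts <- if (inherits(points, "loc_table")) cbind(points$x, points$y) else rbind(points)
  rings <- scaled_rings(border, edges)
  cen <- polygon_centroid(border)
  R <- ray_border_radius(pts, border, cen)
  r <- sqrt((pts[, 1] - cen[1])^2 + (pts[, 2] - cen[2])^2)
  scale <- ifelse(r == 0, 0, r / R)
  inside <- !is.na(scale) & scale <= max(edges)
  if (!any(inside)) stop("no localizations within the outermost ring", call. = FALSE)
  bin <- cut(scale[inside], breaks = edges, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(bin))
  loc_fraction <- counts / sum(counts)
  dens <- loc_fraction / rings$area_fraction
  dens <- if (normalize == "sum") dens / sum(dens) else dens / max(dens)
  structure(data.frame(
    ring = seq_along(counts),
    inner = edges[-length(edges)], outer = edges[-1],
    n = counts, loc_fraction = loc_fraction,
    area_fraction = rings$area_fraction, density = dens
  ), class = c("ring_profile", "data.frame"))
}

#' Average ring profiles across structures
#'
#' Population profiles are the arithmetic mean of per-structure profiles.
#'
#' @param profiles list of `ring_profile`s with identical edges.
#' @return a `ring_profile` data.frame of means.
#' @export
average_ring_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  out <- profiles[[1]]
  out$n <- rowMeans(sapply(profiles, `[[`, "n"))
  out$loc_fraction <- rowMeans(sapply(profiles, `[[`, "loc_fraction"))
  out$density <- rowMeans(sapply(profiles, `[[`, "density"))
  out
}
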