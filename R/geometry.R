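# Planar polygon primitives used by the nanoscale geometry layer.
# Polygons are numeric matrices with columns (x, y) in nm, vertices in
# counter-clockwise order, not closed (first vertex not repeated).

#' Signed area of a polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly numeric matrix with columns x, y.
#' @return signed area in squared input units.
#' @keywords internal
polygon_area_signed <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Unsigned polygon area
#' @inheritParams polygon_area_signed
#' @return area (>= 0).
#' @export
polygon_area <- function(poly) abs(polygon_area_signed(poly))

#' Polygon centroid (area-weighted)
#' @inheritParams polygon_area_signed
#' @return numeric length-2 (x, y).
#' @export
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * max(abs(poly)) ^ 2) {
    return(c(mean(x), mean(y)))  # degenerate: fall back to vertex mean
  }
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Force counter-clockwise vertex order
#' @keywords internal
ensure_ccw <- function(poly) {
  if (polygon_area_signed(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

#' Scale a polygon about a fixed point
#'
#' Homothety with factor `f` about `center` (default: the polygon centroid).
#' Areas scale by f^2, which is what makes border-scaled ring area fractions
#' polygon-independent.
#'
#' @param poly polygon matrix.
#' @param f scale factor (> 0 for a proper polygon; 0 collapses to the center).
#' @param center point to scale about; defaults to `polygon_centroid(poly)`.
#' @return scaled polygon.
#' @export
scale_polygon <- function(poly, f, center = polygon_centroid(poly)) {
  sweep(sweep(poly, 2, center, "-") * f, 2, center, "+")
}

#' Point-in-polygon test (closed region)
#'
#' Ray casting with an explicit on-boundary check, so points lying on the
#' border count as inside (closed-region convention used throughout).
#'
#' @param pts n x 2 matrix of query points.
#' @param poly polygon matrix.
#' @param tol boundary tolerance in input units.
#' @return logical vector of length n.
#' @export
point_in_polygon <- function(pts, poly, tol = 1e-9) {
  pts <- rbind(pts)  # accept a bare length-2 vector
  n <- nrow(pts)
  vx <- poly[, 1]; vy <- poly[, 2]
  m <- length(vx)
  jx <- c(vx[m], vx[-m]); jy <- c(vy[m], vy[-m])
  px <- pts[, 1]; py <- pts[, 2]
  crossings <- integer(n)
  for (e in seq_len(m)) {  # vectorized over points, looped over edges
    straddle <- (vy[e] > py) != (jy[e] > py)
    if (!any(straddle)) next
    xcut <- (jx[e] - vx[e]) * (py - vy[e]) / (jy[e] - vy[e]) + vx[e]
    crossings <- crossings + as.integer(straddle & px < xcut)
  }
  inside <- (crossings %% 2L) == 1L
  on_edge <- point_to_polygon_distance(pts, poly) <= tol
  inside | on_edge
}

#' Minimum distance from points to a polygon boundary
#'
#' @param pts n x 2 matrix of query points.
#' @param poly polygon matrix.
#' @return numeric vector of unsigned distances.
#' @export
point_to_polygon_distance <- function(pts, poly) {
  pts <- rbind(pts)
  m <- nrow(poly)
  a <- poly
  b <- poly[c(2:m, 1), , drop = FALSE]
  ex <- b[, 1] - a[, 1]; ey <- b[, 2] - a[, 2]
  len2 <- ex^2 + ey^2
  len2[len2 == 0] <- 1  # zero-length edge: distance to its single point
  d2 <- rep(Inf, nrow(pts))
  for (e in seq_len(m)) {  # vectorized over points, looped over edges
    wx <- pts[, 1] - a[e, 1]; wy <- pts[, 2] - a[e, 2]
    t <- pmin(1, pmax(0, (wx * ex[e] + wy * ey[e]) / len2[e]))
    dx <- wx - t * ex[e]; dy <- wy - t * ey[e]
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

#' Border radius along rays from a center
#'
#' For each query point, intersects the ray from `center` through the point
#' with the polygon boundary and returns the distance from the center to the
#' nearest crossing. For polygons star-shaped about `center` (all convex
#' borders qualify) this is the border radius R(theta) in the point's
#' direction.
#'
#' @param pts n x 2 matrix; points defining ray directions.
#' @param poly polygon matrix.
#' @param center ray origin; defaults to the polygon centroid.
#' @return numeric vector; NA for points coincident with the center
#'   (direction undefined — callers treat these as scale 0).
#' @keywords internal
ray_border_radius <- function(pts, poly, center = polygon_centroid(poly)) {
  pts <- rbind(pts)
  m <- nrow(poly)
  a <- poly
  e <- poly[c(2:m, 1), , drop = FALSE] - a  # edge vectors
  ax <- a[, 1] - center[1]; ay <- a[, 2] - center[2]
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  nz <- r > 0
  ux <- ifelse(nz, dx / r, 0); uy <- ifelse(nz, dy / r, 0)
  best <- rep(Inf, nrow(pts))
  for (ei in seq_len(m)) {  # vectorized over points, looped over edges
    denom <- ux * e[ei, 2] - uy * e[ei, 1]
    ok <- abs(denom) > 1e-12
    t <- (ax[ei] * e[ei, 2] - ay[ei] * e[ei, 1]) / denom  # distance along ray
    u <- (ax[ei] * uy - ay[ei] * ux) / denom              # position along edge
    hit <- ok & t > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9
    best <- ifelse(hit & t < best, t, best)
  }
  out <- rep(NA_real_, nrow(pts))
  out[nz & is.finite(best)] <- best[nz & is.finite(best)]
  out
}

#' Convex hull polygon of a 2D point set
#'
#' @param pts n x 2 matrix.
#' @return polygon matrix (CCW). Errors if fewer than 3 distinct
#'   non-collinear points.
#' @export
convex_hull_polygon <- function(pts) {
  pts <- unique(rbind(pts))
  if (nrow(pts) < 3) {
    stop("degenerate cluster: fewer than 3 distinct points", call. = FALSE)
  }
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  if (nrow(poly) < 3 || polygon_area(poly) == 0) {
    stop("degenerate cluster: points are collinear", call. = FALSE)
  }
  ensure_ccw(poly)
}

#' Alpha-shape (concave) boundary polygon
#'
#' Direct pair-circle construction: an edge between two points at distance
#' <= 2*alpha lies on the alpha-shape boundary iff at least one of the two
#' discs of radius alpha through both endpoints contains no other point.
#' Boundary edges are then walked into a closed loop (the longest loop is
#' returned if the shape has several). Quadratic in the number of points;
#' intended for per-cluster point counts (hundreds to a few thousand).
#'
#' @param pts n x 2 matrix.
#' @param alpha disc radius, in the same units as the points.
#' @return polygon matrix (CCW).
#' @export
alpha_shape_polygon <- function(pts, alpha) {
  pts <- unique(rbind(pts))
  n <- nrow(pts)
  if (n < 3) stop("degenerate cluster: fewer than 3 distinct points", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  x <- pts[, 1]; y <- pts[, 2]
  edges <- NULL
  for (i in seq_len(n - 1)) {
    dxi <- x[-seq_len(i)] - x[i]; dyi <- y[-seq_len(i)] - y[i]
    d2 <- dxi^2 + dyi^2
    cand <- which(d2 <= (2 * alpha)^2 & d2 > 0)
    for (k in cand) {
      j <- i + k
      mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
      h2 <- alpha^2 - d2[k] / 4
      if (h2 < 0) next
      h <- sqrt(h2); dlen <- sqrt(d2[k])
      # unit normal to the chord
      nx <- -(y[j] - y[i]) / dlen; ny <- (x[j] - x[i]) / dlen
      for (s in c(1, -1)) {
        cx <- mx + s * h * nx; cy <- my + s * h * ny
        dd <- (x - cx)^2 + (y - cy)^2
        dd[c(i, j)] <- Inf
        if (min(dd) >= alpha^2 * (1 - 1e-9)) {
          edges <- rbind(edges, c(i, j))
          break
        }
      }
    }
  }
  if (is.null(edges) || nrow(edges) < 3) {
    stop("alpha too small: no closed alpha-shape boundary; increase alpha",
         call. = FALSE)
  }
  # walk boundary edges into loops; keep the longest
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  used <- matrix(FALSE, nrow(edges), 1)
  ekey <- paste(edges[, 1], edges[, 2])
  edge_used <- setNames(rep(FALSE, nrow(edges)), ekey)
  mark_used <- function(i, j) {
    k <- paste(min(i, j), max(i, j))
    hit <- which(names(edge_used) == k & !edge_used)
    if (length(hit)) edge_used[hit[1]] <<- TRUE
  }
  is_used <- function(i, j) {
    k <- paste(min(i, j), max(i, j))
    all(edge_used[names(edge_used) == k])
  }
  best <- NULL
  for (start in seq_len(n)) {
    if (!length(adj[[start]])) next
    nxt <- adj[[start]][!vapply(adj[[start]], function(j) is_used(start, j), logical(1))]
    if (!length(nxt)) next
    loop <- c(start)
    prev <- start; cur <- nxt[1]; mark_used(start, cur)
    repeat {
      loop <- c(loop, cur)
      cands <- setdiff(adj[[cur]], prev)
      cands <- cands[!vapply(cands, function(j) is_used(cur, j), logical(1))]
      if (cur == start && length(loop) > 3) break
      if (!length(cands)) {
        if (start %in% adj[[cur]] && length(loop) >= 3) loop <- c(loop, start)
        break
      }
      # prefer the continuation closest in direction travelled (keeps thin
      # shapes from short-circuiting across the interior)
      if (length(cands) > 1) {
        dir0 <- pts[cur, ] - pts[prev, ]
        ang <- vapply(cands, function(j) {
          d1 <- pts[j, ] - pts[cur, ]
          sum(dir0 * d1) / (sqrt(sum(dir0^2)) * sqrt(sum(d1^2)) + 1e-12)
        }, numeric(1))
        cands <- cands[order(-ang)]
      }
      prev <- cur; cur <- cands[1]; mark_used(prev, cur)
      if (cur == start) { loop <- c(loop, start); break }
    }
    if (length(loop) >= 4 && loop[1] == loop[length(loop)]) {
      verts <- loop[-length(loop)]
      if (is.null(best) || length(verts) > nrow(best)) {
        best <- pts[verts, , drop = FALSE]
      }
    }
  }
  if (is.null(best) || nrow(best) < 3 || polygon_area(best) == 0) {
    stop("alpha-shape boundary could not be closed; increase alpha", call. = FALSE)
  }
  ensure_ccw(best)
}

#' Test whether a polygon is simple (no self-intersections)
#' @keywords internal
is_simple_polygon <- function(poly) {
  m <- nrow(poly)
  if (m < 3) return(FALSE)
  a <- poly
  b <- poly[c(2:m, 1), , drop = FALSE]
  seg_intersect <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (j == i || j == i %% m + 1 || i == j %% m + 1) next
      if (seg_intersect(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Regular polygon approximation of an ellipse
#'
#' @param center (x, y).
#' @param a,b semi-axes.
#' @param theta rotation (rad).
#' @param n number of vertices.
#' @return polygon matrix (CCW).
#' @export
ellipse_polygon <- function(center, a, b, theta = 0, n = 96) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(phi); y0 <- b * sin(phi)
  cbind(center[1] + x0 * cos(theta) - y0 * sin(theta),
        center[2] + x0 * sin(theta) + y0 * cos(theta))
}
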