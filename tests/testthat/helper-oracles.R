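# Independent oracles, written before the implementations they check.

# Brute-force DBSCAN by full distance matrix + fixpoint component growth
# (a different code path from the package's neighbor-list queue expansion).
# Border points go to the smallest label among their core neighbors.
brute_dbscan <- function(pts, eps_nm, min_pts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  nb <- D <= eps_nm
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    labels[i] <- cl
    repeat {
      members <- labels == cl
      reach <- core & labels == 0L & apply(nb[, members, drop = FALSE], 1, any)
      if (!any(reach)) break
      labels[reach] <- cl
    }
  }
  for (i in which(!core & labels == 0L)) {
    cand <- labels[nb[i, ] & core]
    if (length(cand)) labels[i] <- min(cand)
  }
  labels
}

# canonical relabeling by first occurrence (noise stays 0)
canonical_labels <- function(lab) {
  pos <- lab != 0L
  u <- unique(lab[pos])
  out <- lab
  out[pos] <- match(lab[pos], u)
  out
}

# random clustered DBSCAN scene: gaussian blobs + uniform noise, <= n_max pts
random_dbscan_scene <- function(seed, n_max = 500) {
  set.seed(seed)
  k <- sample(1:4, 1)
  pts <- NULL
  for (j in seq_len(k)) {
    nj <- sample(40:120, 1)
    c0 <- runif(2, 100, 900)
    s <- runif(1, 20, 60)
    pts <- rbind(pts, cbind(rnorm(nj, c0[1], s), rnorm(nj, c0[2], s)))
  }
  pts <- rbind(pts, cbind(runif(50, 0, 1000), runif(50, 0, 1000)))
  if (nrow(pts) > n_max) pts <- pts[seq_len(n_max), , drop = FALSE]
  list(pts = pts,
       eps_nm = runif(1, 30, 80),
       min_pts = sample(5:20, 1))
}

# Signed distance oracle: min distance over a densified boundary sampling,
# sign by winding angle (both independent of the package's segment
# projection + ray casting).
brute_signed_distance <- function(pts, poly, spacing = 0.4) {
  m <- nrow(poly)
  bnd <- NULL
  for (e in seq_len(m)) {
    a <- poly[e, ]; b <- poly[e %% m + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2, ceiling(len / spacing) + 1))
    bnd <- rbind(bnd, cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2])))
  }
  vapply(seq_len(nrow(pts)), function(i) {
    d <- sqrt(min((bnd[, 1] - pts[i, 1])^2 + (bnd[, 2] - pts[i, 2])^2))
    # winding angle
    vx <- poly[, 1] - pts[i, 1]; vy <- poly[, 2] - pts[i, 2]
    wx <- c(vx[-1], vx[1]); wy <- c(vy[-1], vy[1])
    ang <- sum(atan2(vx * wy - vy * wx, vx * wx + vy * wy))
    if (abs(ang) > pi) -d else d
  }, numeric(1))
}

# random star-shaped polygon (simple by construction)
random_star_polygon <- function(seed, n_vert = 12, r_min = 40, r_max = 130) {
  set.seed(seed)
  th <- sort(runif(n_vert, 0, 2 * pi))
  r <- runif(n_vert, r_min, r_max)
  cbind(r * cos(th), r * sin(th))
}

# uniform points inside a polygon by rejection sampling
uniform_in_polygon <- function(n, poly, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bb <- apply(poly, 2, range)
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    cand <- cbind(runif(4 * n, bb[1, 1], bb[2, 1]),
                  runif(4 * n, bb[1, 2], bb[2, 2]))
    out <- rbind(out, cand[point_in_polygon(cand, poly), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
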