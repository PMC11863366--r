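# Shared helpers: independent brute-force oracles and fixture plumbing.
# The oracles deliberately use different algorithms than the package
# internals (vectorized R point-triangle distances; ray-casting parity for
# the inside test; all-pairs minimum-image distances for clustering).

# concatenate two systems into one (atom ids and residue ids re-offset)
combine_systems <- function(a, b) {
  stopifnot(n_frames(a) == n_frames(b))
  na <- nrow(a$atoms)
  nr <- max(a$atoms$resid)
  bb <- b$atoms
  bb$id <- bb$id + na
  bb$resid <- bb$resid + nr
  out <- a
  out$atoms <- rbind(a$atoms, bb)
  for (k in seq_along(a$frames))
    out$frames[[k]]$xyz <- rbind(a$frames[[k]]$xyz, b$frames[[k]]$xyz)
  out
}

# distances from many points to one triangle (a, b, c), vectorized
tri_dist_many <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a
  ap <- sweep(p, 2, a)
  d1 <- ap %*% ab; d2 <- ap %*% ac
  bp <- sweep(p, 2, b)
  d3 <- bp %*% ab; d4 <- bp %*% ac
  cp <- sweep(p, 2, c)
  d5 <- cp %*% ab; d6 <- cp %*% ac
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  n <- nrow(p)
  q <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set_q <- function(mask, pts) {
    mask <- mask & !done
    if (any(mask)) {
      q[mask, ] <<- pts[mask, , drop = FALSE]
      done[mask] <<- TRUE
    }
  }
  onesA <- matrix(a, n, 3, byrow = TRUE)
  set_q(d1 <= 0 & d2 <= 0, onesA)
  set_q(d3 >= 0 & d4 <= d3, matrix(b, n, 3, byrow = TRUE))
  v <- drop(d1 / (d1 - d3))
  set_q(vc <= 0 & d1 >= 0 & d3 <= 0, onesA + outer(v, ab))
  set_q(d6 >= 0 & d5 <= d6, matrix(c, n, 3, byrow = TRUE))
  w <- drop(d2 / (d2 - d6))
  set_q(vb <= 0 & d2 >= 0 & d6 <= 0, onesA + outer(w, ac))
  w2 <- drop((d4 - d3) / ((d4 - d3) + (d5 - d6)))
  set_q(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
        matrix(b, n, 3, byrow = TRUE) + outer(w2, c - b))
  denom <- drop(1 / (va + vb + vc))
  vv <- drop(vb) * denom; ww <- drop(vc) * denom
  set_q(rep(TRUE, n), onesA + outer(vv, ab) + outer(ww, ac))
  sqrt(rowSums((p - q)^2))
}

# ray-casting parity inside test (independent of the package's half-space
# and point-location tests); direction chosen away from edge alignments
ray_inside <- function(mesh_points, facets, p,
                       dir = c(0.5377315, 0.7326534, 0.4173308)) {
  dir <- dir / sqrt(sum(dir^2))
  n <- nrow(p)
  crossings <- integer(n)
  for (f in seq_len(nrow(facets))) {
    a <- mesh_points[facets[f, 1], ]
    b <- mesh_points[facets[f, 2], ]
    c <- mesh_points[facets[f, 3], ]
    e1 <- b - a; e2 <- c - a
    h <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * h)
    if (abs(det) < 1e-12) next
    s <- sweep(p, 2, a)
    u <- (s %*% h) / det
    qv <- cbind(s[, 2] * e1[3] - s[, 3] * e1[2],
                s[, 3] * e1[1] - s[, 1] * e1[3],
                s[, 1] * e1[2] - s[, 2] * e1[1])
    v <- (qv %*% dir) / det
    tt <- (qv %*% e2) / det
    hit <- u >= 0 & v >= 0 & (u + v) <= 1 & tt > 0
    crossings <- crossings + as.integer(hit)
  }
  crossings %% 2L == 1L
}

# brute-force signed distance to a triangulated closed surface
oracle_signed_distance <- function(mesh, p) {
  d <- rep(Inf, nrow(p))
  for (f in seq_len(nrow(mesh$facets))) {
    d <- pmin(d, tri_dist_many(p, mesh$points[mesh$facets[f, 1], ],
                               mesh$points[mesh$facets[f, 2], ],
                               mesh$points[mesh$facets[f, 3], ]))
  }
  inside <- ray_inside(mesh$points, mesh$facets, p)
  ifelse(inside, -d, d)
}

# all-pairs minimum-image distance matrix
min_image_dist <- function(xyz, box) {
  n <- nrow(xyz)
  D2 <- matrix(0, n, n)
  for (j in 1:3) {
    d <- outer(xyz[, j], xyz[, j], "-")
    d <- d - box[j] * round(d / box[j])
    D2 <- D2 + d^2
  }
  sqrt(D2)
}

# single-linkage components from a distance matrix (plain R union-find)
oracle_components <- function(D, cutoff) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n))
      if (D[i, j] <= cutoff) {
        a <- find(i); b <- find(j)
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
  vapply(seq_len(n), find, 0L)
}

# random well-spread point cloud for hull tests
random_cloud <- function(n, r = 10, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * r * runif(n)^(1 / 3)
  sweep(v, 2, c(r, r, r), "+")
}

# jittered spherical shell: every point extreme, so a hull of ~2n facets
random_shell <- function(n, r = 10, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * r * (1 + 0.002 * runif(n))
  sweep(v, 2, c(r, r, r), "+")
}
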