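# Independent brute-force oracles and small geometric fixtures used across the
# suite. Everything here is deliberately naive (O(N^2), triple enumeration) so
# it cannot share code paths with the implementation it checks.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# O(N^2) mean-kNN-distance outlier mask
bf_sor_mask <- function(P, k, std_ratio) {
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  dbar <- unname(apply(D, 1, function(r) mean(sort(r)[seq_len(k)])))
  dbar <= mean(dbar) + std_ratio * sd(dbar)
}

# connected components of the <= eps proximity graph (matrix power free: BFS)
bf_components <- function(P, eps) {
  n <- nrow(P)
  A <- as.matrix(dist(P)) <= eps
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    front <- s
    comp[s] <- cur
    while (length(front)) {
      nxt <- which(apply(A[front, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cur
      front <- nxt
    }
  }
  comp
}

# two labelings describe the same partition (up to renaming)?
same_partition <- function(a, b) {
  all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}

# hull volume by facet enumeration: every triple whose plane has all points on
# one side is a hull facet; sum tetrahedra volumes about the centroid.
# Assumes general position (no 4 coplanar hull points).
bf_hull_volume <- function(P, tol = 1e-10) {
  n <- nrow(P)
  ctr <- colMeans(P)
  vol <- 0
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        nrm <- cross3(P[j, ] - P[i, ], P[k, ] - P[i, ])
        if (sum(nrm^2) < 1e-24) next
        d <- as.vector(P %*% nrm) - sum(nrm * P[i, ])
        if (all(d <= tol) || all(d >= -tol)) {
          vol <- vol + abs(det(rbind(P[i, ] - ctr, P[j, ] - ctr, P[k, ] - ctr))) / 6
        }
      }
    }
  }
  vol
}

# crown rectangle by brute force over all point-pair directions
bf_crown <- function(xy) {
  n <- nrow(xy)
  best <- c(0, 0, 0) # L^2, i, j
  for (i in 1:(n - 1)) {
    d2 <- (xy[(i + 1):n, 1] - xy[i, 1])^2 + (xy[(i + 1):n, 2] - xy[i, 2])^2
    j <- which.max(d2)
    if (d2[j] > best[1]) best <- c(d2[j], i, i + j)
  }
  L <- sqrt(best[1])
  if (L == 0) return(c(L = 0, W = 0, C = 0))
  dir <- (xy[best[3], ] - xy[best[2], ]) / L
  perp <- c(-dir[2], dir[1])
  W <- diff(range(xy %*% perp))
  c(L = L, W = W, C = L * W)
}

# flat rectangular ribbon along an arbitrary direction
make_ribbon <- function(n = 600, length = 10, width = 1,
                        dir = c(1, 0, 0), up = c(0, 0, 1), origin = c(0, 0, 0),
                        jitter = 0) {
  dir <- dir / sqrt(sum(dir^2))
  side <- cross3(dir, up)
  side <- side / sqrt(sum(side^2))
  s <- runif(n, 0, length)
  v <- runif(n, -width / 2, width / 2)
  P <- outer(s, dir) + outer(v, side)
  P <- sweep(P, 2, origin, `+`)
  if (jitter > 0) P <- P + matrix(rnorm(3 * n, 0, jitter), ncol = 3)
  tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3])
}

make_cylinder <- function(n = 2000, radius = 1, height = 10) {
  a <- runif(n, 0, 2 * pi)
  tibble::tibble(x = radius * cos(a), y = radius * sin(a),
                 z = runif(n, 0, height))
}

make_sphere <- function(n = 3000, radius = 5) {
  P <- matrix(rnorm(3 * n), ncol = 3)
  P <- P / sqrt(rowSums(P^2)) * radius
  tibble::tibble(x = P[, 1], y = P[, 2], z = P[, 3])
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# quiet noiseless test scene
quiet_scene <- function(stage = "seedling", seed = 3, ...) {
  spec <- stage_preset(stage, "moderate", seed = seed, true_scale = 1,
                       tilt_deg = 0, noise_sd = 0, outlier_frac = 0, ...)
  generate_scene(spec)
}

cloud_coords <- function(cl) cbind(cl$x, cl$y, cl$z)
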