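# Fixtures are built in code; the oracles here are deliberately naive
# (voxel-counting loops, O(n^2) searches) and independent of the package's
# production implementations.

# Digital sphere mask of diameter d: voxel centres within d/2 of the origin.
make_sphere_mask <- function(d, spacing = c(0.5, 0.5, 0.5), pad = 3) {
  n <- ceiling(d / spacing) + 2 * pad
  n <- n + 1 - (n %% 2)
  xs <- (seq_len(n[1]) - (n[1] + 1) / 2) * spacing[1]
  ys <- (seq_len(n[2]) - (n[2] + 1) / 2) * spacing[2]
  zs <- (seq_len(n[3]) - (n[3] + 1) / 2) * spacing[3]
  q <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  nodule_mask((q <= (d / 2)^2) + 0L, spacing)
}

# Axis-aligned (or in-plane rotated) digital ellipsoid with semi-axes a, b, c.
make_ellipsoid_mask <- function(a, b, c, spacing = c(0.5, 0.5, 0.5),
                                angle = 0, pad = 3) {
  r <- max(a, b, c)
  n <- ceiling(2 * r / spacing) + 2 * pad
  n <- n + 1 - (n %% 2)
  xs <- (seq_len(n[1]) - (n[1] + 1) / 2) * spacing[1]
  ys <- (seq_len(n[2]) - (n[2] + 1) / 2) * spacing[2]
  zs <- (seq_len(n[3]) - (n[3] + 1) / 2) * spacing[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  xr <- g$x * cos(angle) + g$y * sin(angle)
  yr <- -g$x * sin(angle) + g$y * cos(angle)
  q <- (xr / a)^2 + (yr / b)^2 + (g$z / c)^2
  nodule_mask(array((q <= 1) + 0L, n), spacing)
}

# Sphere with thin axial radial spikes (in the equatorial plane).
make_spiked_sphere_mask <- function(d, spike_len, spacing = c(0.5, 0.5, 0.5),
                                    n_spikes = 4) {
  pad <- ceiling(spike_len / spacing[1]) + 3
  m <- make_sphere_mask(d, spacing, pad = pad)
  dims <- dim(m$values)
  ctr <- (dims + 1) / 2
  kz <- ctr[3]
  angles <- seq(0, 2 * pi, length.out = n_spikes + 1)[-(n_spikes + 1)] + 0.3
  for (ang in angles) {
    u <- c(cos(ang), sin(ang))
    for (t in seq(0, d / 2 + spike_len, by = min(spacing[1:2]) / 2)) {
      i <- round(ctr[1] + t * u[1] / spacing[1])
      j <- round(ctr[2] + t * u[2] / spacing[2])
      if (i >= 1 && i <= dims[1] && j >= 1 && j <= dims[2]) {
        m$values[i, j, kz] <- 1L
      }
    }
  }
  m
}

# Random connected blob: union of a few overlapping spheres.
make_blob_mask <- function(seed, spacing = c(1, 1, 1), n_lobes = 4) {
  set.seed(seed)
  n <- c(20, 20, 20)
  xs <- seq_len(n[1]) * spacing[1]
  ys <- seq_len(n[2]) * spacing[2]
  zs <- seq_len(n[3]) * spacing[3]
  arr <- array(FALSE, n)
  ctr <- c(mean(xs), mean(ys), mean(zs))
  prev <- ctr
  for (l in seq_len(n_lobes)) {
    c1 <- prev + runif(3, -3, 3) * spacing
    r <- runif(1, 2, 5) * mean(spacing)
    q <- outer(outer((xs - c1[1])^2, (ys - c1[2])^2, "+"), (zs - c1[3])^2, "+")
    arr <- arr | (q <= r^2)
    prev <- c1
  }
  if (!any(arr)) arr[10, 10, 10] <- TRUE
  nodule_mask(arr + 0L, spacing)
}

# O(n^2) brute-force maximal axial diameter over every footprint corner.
brute_pairwise_diameter <- function(mask) {
  arr <- mask$values > 0
  sp <- mask$spacing
  best <- 0
  for (k in seq_len(dim(arr)[3])) {
    ij <- which(matrix(arr[, , k], dim(arr)[1], dim(arr)[2]), arr.ind = TRUE)
    if (nrow(ij) == 0) next
    corners <- NULL
    for (r in seq_len(nrow(ij))) {
      cx <- (ij[r, 1] - 1) * sp[1]
      cy <- (ij[r, 2] - 1) * sp[2]
      corners <- rbind(corners,
                       cbind(cx + c(-0.5, -0.5, 0.5, 0.5) * sp[1],
                             cy + c(-0.5, 0.5, -0.5, 0.5) * sp[2]))
    }
    for (p in seq_len(nrow(corners))) {
      d <- sqrt((corners[, 1] - corners[p, 1])^2 +
                  (corners[, 2] - corners[p, 2])^2)
      best <- max(best, d)
    }
  }
  best
}

# Brute-force voxel count by explicit triple loop.
brute_volume <- function(mask) {
  arr <- mask$values
  cnt <- 0
  for (i in seq_len(dim(arr)[1]))
    for (j in seq_len(dim(arr)[2]))
      for (k in seq_len(dim(arr)[3]))
        if (arr[i, j, k] > 0) cnt <- cnt + 1
  cnt * prod(mask$spacing)
}

# O(n_pos * n_neg) pair-counting AUC oracle.
brute_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small cohort configuration used across tests (coarse voxels keep renders
# cheap; geometry-sensitive tests build their own masks instead).
tiny_cohort_config <- function(seed = 1, n = 60, ...) {
  cohort_config(n_participants = n, voxel_spacing_mm = c(2, 2, 2),
                seed = seed, ...)
}
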