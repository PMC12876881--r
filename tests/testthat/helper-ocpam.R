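# Shared helpers for the ocpam test suite.

# Dice coefficient of truth label `id` against its best-overlapping
# segmentation label.
diceBest <- function(truth_lab, seg_lab, id) {
  sel <- truth_lab == id
  tgt <- seg_lab[sel]
  tgt <- tgt[tgt > 0L]
  if (!length(tgt)) return(0)
  b <- as.integer(names(which.max(table(tgt))))
  2 * sum(sel & seg_lab == b) / (sum(sel) + sum(seg_lab == b))
}

# A small speckled single-sphere OCM volume with its truth mask.
makeSphereVolume <- function(radius_um = 25, spacing = c(2.52, 2.52, 2.52),
                             pad_um = 25, base = 0.55, seed = 1) {
  set.seed(seed)
  field <- rep(2 * (radius_um + pad_um), 3)
  dims <- as.integer(round(field / spacing))
  ctr <- field / 2
  a <- array(0.02 + 0.015 * abs(rnorm(prod(dims))), dims)
  zz <- ((seq_len(dims[1])) - 1) * spacing[1]
  yy <- ((seq_len(dims[2])) - 1) * spacing[2]
  xx <- ((seq_len(dims[3])) - 1) * spacing[3]
  inside <- outer(outer((zz - ctr[1])^2, (yy - ctr[2])^2, "+"),
                  (xx - ctr[3])^2, "+") <= radius_um^2
  a[inside] <- base * (0.7 + 0.6 * runif(sum(inside)))
  list(vol = Volume3D(a, spacing, "OCM", 3L),
       truth = array(as.integer(inside), dims))
}

# Brute-force GLCM pair enumeration oracle (symmetric, both voxels in ROI).
oracleGlcm <- function(levels, offset, ng) {
  d <- dim(levels)
  m <- matrix(0, ng, ng)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    l1 <- levels[z, y, x]
    if (l1 == 0L) next
    zz <- z + offset[1]; yy <- y + offset[2]; xx <- x + offset[3]
    if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3])
      next
    l2 <- levels[zz, yy, xx]
    if (l2 == 0L) next
    m[l1, l2] <- m[l1, l2] + 1
    m[l2, l1] <- m[l2, l1] + 1
  }
  m
}

# Brute-force GLRLM run enumeration oracle: maximal same-level runs along the
# direction; runs break at the ROI boundary (level 0).
oracleGlrlm <- function(levels, offset, ng) {
  d <- dim(levels)
  maxlen <- sum(d)
  m <- matrix(0, ng, maxlen)
  inb <- function(p) all(p >= 1) && all(p <= d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    l1 <- levels[z, y, x]
    if (l1 == 0L) next
    prev <- c(z, y, x) - offset
    if (inb(prev) && levels[prev[1], prev[2], prev[3]] == l1) next
    len <- 1L
    cur <- c(z, y, x) + offset
    while (inb(cur) && levels[cur[1], cur[2], cur[3]] == l1) {
      len <- len + 1L
      cur <- cur + offset
    }
    m[l1, len] <- m[l1, len] + 1
  }
  m
}

# Brute-force optimal assignment by permutation enumeration (n <= 6).
oracleAssign <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  best_p <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best - 1e-12) {
      best <- s
      best_p <- p
    }
  }
  list(perm = best_p, cost = best)
}

# Fabricate summarizeMask-style records from SceneTruth ellipsoids for one
# day (volumes and bboxes computed analytically from the ellipsoid geometry).
recordsFromTruth <- function(truth, day) {
  e <- truth$ellipsoids[truth$ellipsoids$day == day, ]
  sp <- truth$spacing_um
  data.frame(label = e$id, day = day,
             volume_um3 = 4 / 3 * pi * e$az * e$ay * e$ax,
             cz = e$cz, cy = e$cy, cx = e$cx,
             bbox_z0 = (e$cz - e$az) / sp[1], bbox_z1 = (e$cz + e$az) / sp[1],
             bbox_y0 = (e$cy - e$ay) / sp[2], bbox_y1 = (e$cy + e$ay) / sp[2],
             bbox_x0 = (e$cx - e$ax) / sp[3], bbox_x1 = (e$cx + e$ax) / sp[3],
             n_voxels = NA_integer_)
}
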