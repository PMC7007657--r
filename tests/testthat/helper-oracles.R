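# Brute-force oracles, written independently of the package internals:
# direct per-voxel loops and all-pairs distances, used to pin down the
# fast implementations on small inputs.

iso_grid <- function(shape, spacing = c(1, 1, 1)) {
  voxel_grid(shape, spacing)
}

random_mask <- function(shape, p = 0.2, seed = 1, spacing = c(1, 1, 1),
                        label = "other") {
  set.seed(seed)
  occ <- array(stats::runif(prod(shape)) < p, shape)
  structure_mask(occ, voxel_grid(shape, spacing), label)
}

sphere_mask <- function(r_mm, spacing = c(1, 1, 1), pad = 3,
                        label = "other") {
  shape <- ceiling(2 * (r_mm + pad) / spacing) + 1
  grid <- voxel_grid(shape, spacing)
  ctr <- (shape - 1) / 2 * spacing
  cs <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
  occ <- outer(outer((cs[[1]] - ctr[1])^2, (cs[[2]] - ctr[2])^2, "+"),
               (cs[[3]] - ctr[3])^2, "+") <= r_mm^2
  structure_mask(occ, grid, label)
}

# surface voxels by explicit neighbour scan
bf_surface <- function(occ) {
  d <- dim(occ)
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!occ[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (q in nb) {
      outside <- any(q < 1) || any(q > d)
      if (outside || !occ[q[1], q[2], q[3]]) {
        out[i, j, k] <- TRUE
        break
      }
    }
  }
  out
}

# all-pairs min distance from each test surface voxel to ref surface voxels
bf_surface_distances <- function(test, ref) {
  sp <- test$grid$spacing
  ts <- which(bf_surface(test$occupancy), arr.ind = TRUE)
  rs <- which(bf_surface(ref$occupancy), arr.ind = TRUE)
  tmm <- sweep(ts - 1, 2, sp, "*")
  rmm <- sweep(rs - 1, 2, sp, "*")
  apply(tmm, 1, function(p) min(sqrt(colSums((t(rmm) - p)^2))))
}

bf_msd <- function(test, ref, mode = "symmetric") {
  d1 <- bf_surface_distances(test, ref)
  if (mode == "directed") return(mean(d1))
  mean(c(d1, bf_surface_distances(ref, test)))
}

bf_hd <- function(test, ref) {
  max(max(bf_surface_distances(test, ref)),
      max(bf_surface_distances(ref, test)))
}

# Euler characteristic by explicit unique-cell enumeration: every occupied
# voxel contributes 8 vertices, 12 edges, 6 faces and 1 cube, identified by
# their lattice coordinates; shared cells are deduplicated with unique().
bf_euler <- function(occ) {
  idx <- which(occ, arr.ind = TRUE)
  verts <- edges <- faces <- character(0)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1)
      verts <- c(verts, paste(i + di, j + dj, k + dk))
    for (dj in 0:1) for (dk in 0:1)
      edges <- c(edges, paste("x", i, j + dj, k + dk))
    for (di in 0:1) for (dk in 0:1)
      edges <- c(edges, paste("y", i + di, j, k + dk))
    for (di in 0:1) for (dj in 0:1)
      edges <- c(edges, paste("z", i + di, j + dj, k))
    faces <- c(faces, paste("xy", i, j, k), paste("xy", i, j, k + 1),
               paste("xz", i, j, k), paste("xz", i, j + 1, k),
               paste("yz", i, j, k), paste("yz", i + 1, j, k))
  }
  length(unique(verts)) - length(unique(edges)) +
    length(unique(faces)) - nrow(idx)
}

# exact two-sided signed-rank p by enumeration of all 2^n sign patterns
bf_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(W <= w + 1e-9), mean(W >= w - 1e-9)))
}

# independent re-binning of projected deviations
bf_project <- function(positions, distances, box, axes, n) {
  acc <- matrix(0, n[1], n[2])
  cnt <- matrix(0L, n[1], n[2])
  for (q in seq_along(distances)) {
    ij <- integer(2)
    for (a in 1:2) {
      lo <- box["min", axes[a]]
      ext <- box["max", axes[a]] - lo
      ij[a] <- if (ext <= 0) 1L
      else min(n[a], max(1L, floor((positions[q, axes[a]] - lo) / ext *
                                     n[a]) + 1L))
    }
    acc[ij[1], ij[2]] <- acc[ij[1], ij[2]] + distances[q]
    cnt[ij[1], ij[2]] <- cnt[ij[1], ij[2]] + 1L
  }
  list(mean = ifelse(cnt > 0, acc / cnt, NA_real_), count = cnt)
}

tiny_cohort_config <- function(n_patients = 2, seed = 11, ...) {
  cohort_config(n_patients = n_patients, resolution = "reduced",
                seed = seed, ...)
}
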