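# Independent brute-force oracles used to validate the package's compiled
# primitives. These are deliberately slow, literal implementations that share
# no code path with the implementation under test.

# neighbor offsets for a given dimensionality/connectivity
neighbor_offsets <- function(ndim, connectivity) {
  grid <- as.matrix(do.call(expand.grid, rep(list(-1:1), ndim)))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  full <- if (ndim == 2) 8L else 26L
  if (connectivity == full) grid else grid[rowSums(abs(grid)) == 1, , drop = FALSE]
}

# queue-based flood fill, one component at a time, scan order
flood_fill_label <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- neighbor_offsets(length(d), connectivity)
  labels <- array(0L, dim = d)
  nextl <- 0L
  coords <- which(mask, arr.ind = TRUE)  # storage order = implementation's scan order
  for (k in seq_len(nrow(coords))) {
    p0 <- coords[k, ]
    if (labels[matrix(p0, 1)] != 0L) next
    nextl <- nextl + 1L
    queue <- list(p0)
    labels[matrix(p0, 1)] <- nextl
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (i in seq_len(nrow(offs))) {
        q <- p + offs[i, ]
        if (any(q < 1) || any(q > d)) next
        qm <- matrix(q, 1)
        if (mask[qm] && labels[qm] == 0L) {
          labels[qm] <- nextl
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  labels
}

# exact nearest-background distance by exhaustive search over background voxels
brute_edt <- function(mask) {
  d <- dim(mask)
  out <- array(0, dim = d)
  fg <- which(mask, arr.ind = TRUE)
  bg <- which(!mask, arr.ind = TRUE)
  if (nrow(fg) == 0) return(out)
  stopifnot(nrow(bg) > 0)
  for (k in seq_len(nrow(fg))) {
    dif <- sweep(bg, 2, fg[k, ])
    out[matrix(fg[k, ], 1)] <- sqrt(min(rowSums(dif^2)))
  }
  out
}

# exhaustive Otsu: scan all 255 splits, minimize weighted within-class variance
brute_otsu <- function(image) {
  v <- as.integer(round(image))
  n <- length(v)
  best_t <- NA_integer_
  best_w <- Inf
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    vl <- if (length(lo) > 1) var(lo) * (length(lo) - 1) / length(lo) else 0
    vh <- if (length(hi) > 1) var(hi) * (length(hi) - 1) / length(hi) else 0
    w <- (length(lo) * vl + length(hi) * vh) / n
    if (w < best_w - 1e-12) {
      best_w <- w
      best_t <- t
    }
  }
  best_t
}

# random blobby binary mask: union of a few random boxes/balls plus salt
random_mask <- function(dims, p_salt = 0.02, n_blobs = 3) {
  m <- array(runif(prod(dims)) < p_salt, dim = dims)
  for (b in seq_len(n_blobs)) {
    ctr <- sapply(dims, function(n) runif(1, 1, n))
    r <- runif(1, 1, max(2, min(dims) / 3))
    grid <- which(array(TRUE, dims), arr.ind = TRUE)
    d2 <- rowSums(sweep(grid, 2, ctr)^2)
    m[grid[d2 < r^2, , drop = FALSE]] <- TRUE
  }
  m
}

# cylinder mask along the axial axis: in-plane disk of radius r voxels
cylinder_mask <- function(nz = 24, side = 33, r = 8, centre = NULL) {
  if (is.null(centre)) centre <- c((side + 1) %/% 2, (side + 1) %/% 2)
  rr <- matrix(rep(1:side, side), side, side)
  cc <- t(rr)
  disk <- (rr - centre[1])^2 + (cc - centre[2])^2 < r^2
  m <- array(FALSE, c(nz, side, side))
  for (z in 1:nz) m[z, , ] <- disk
  attr(m, "voxel_size_um") <- 10
  m
}

# canal-tree geometries of the standard suite, by configuration code
.suite_tree_for_tests <- function(code) toothct:::.suite_canal_tree(code)

# tiny solid-tooth phantom helpers for single-slice tests: a bright annulus
# (tooth ring) with dark interior on dark background
annulus_slice <- function(n = 41, r_outer = 15, r_inner = 6,
                          gray_ring = 200, gray_dark = 10) {
  ctr <- (n + 1) / 2
  rr <- matrix(rep(1:n, n), n, n)
  cc <- t(rr)
  d2 <- (rr - ctr)^2 + (cc - ctr)^2
  img <- matrix(gray_dark, n, n)
  img[d2 < r_outer^2 & d2 >= r_inner^2] <- gray_ring
  img
}
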