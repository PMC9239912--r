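# Independent brute-force oracles used to check the vectorized
# implementations. These deliberately use per-voxel enumeration, not the
# array-shift machinery of the package.

offsets_for <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d2 <- rowSums(g^2)
  keep <- switch(as.character(connectivity),
                 "6" = d2 == 1, "18" = d2 >= 1 & d2 <= 2, "26" = d2 >= 1)
  unname(g[keep, , drop = FALSE])
}

# interface = wm voxels (gm excluded) with >= 1 gm neighbor; per-voxel loop
oracle_interface <- function(gm_data, wm_data, connectivity) {
  d <- dim(gm_data)
  offs <- offsets_for(connectivity)
  out <- array(FALSE, dim = d)
  idx <- which(wm_data & !gm_data)
  for (v in idx) {
    p0 <- arrayInd(v, d)
    for (r in seq_len(nrow(offs))) {
      p <- p0 + offs[r, ]
      if (all(p >= 1L) && all(p <= d) && gm_data[p[1], p[2], p[3]]) {
        out[v] <- TRUE
        break
      }
    }
  }
  out
}

# nearest labeled voxel within radius (world mm); ties -> smallest label
oracle_nearest_label <- function(parc_data, affine, vox0, radius_mm) {
  lab_idx <- which(parc_data > 0L)
  if (length(lab_idx) == 0L) return(0L)
  vox <- arrayInd(lab_idx, dim(parc_data)) - 1L
  w <- cbind(vox, 1) %*% t(affine[1:3, ])
  w0 <- as.vector(affine[1:3, ] %*% c(vox0, 1))
  dist <- sqrt(rowSums(sweep(w, 2L, w0)^2))
  ok <- dist <= radius_mm + 1e-9
  if (!any(ok)) return(0L)
  dmin <- min(dist[ok])
  cand <- parc_data[lab_idx[ok][dist[ok] <= dmin + 1e-12]]
  min(cand)
}

random_mask <- function(shape, p, grid = voxel_grid(shape)) {
  binary_mask(array(stats::runif(prod(shape)) < p, dim = shape), grid)
}

# small phantom used across tests
tiny_phantom <- function(seed = 1L, ...)
  make_phantom(phantom_spec(shape = c(16L, 16L, 16L), wm_radius = 4,
                            shell_thickness = 2, n_parcels = 3L,
                            seed = seed, ...))

# compound-symmetry correlation target (PSD for rho in (-1/(N-1), 1))
cs_corr <- function(N, rho) {
  C <- matrix(rho, N, N)
  diag(C) <- 1
  C
}
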