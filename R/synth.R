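# Synthetic phantoms and tables with analytically known ground truth. These
# stand in for T1w-derived masks, denoised BOLD, probabilistic-tractography
# counts and the manual QC study design, so every pipeline stage is testable
# without imaging data. They emulate geometry and sampling structure, not MRI
# physics (no distortion, motion, or partial volume).

#' Specification of the synthetic brain phantom
#'
#' The phantom is a solid white matter ellipsoid wrapped in a gray matter
#' shell; the shell is parcellated into angular sectors split by hemisphere
#' (x below the grid center = left), so ROI adjacency, hemispheres and
#' centroids are all analytically known.
#'
#' @param shape grid shape (3 integers, default 24^3).
#' @param wm_radius white matter core radius in voxels (default 6).
#' @param shell_thickness gray matter shell thickness in voxels (>= 1,
#'   default 3).
#' @param n_parcels angular parcels per hemisphere (default 4).
#' @param n_lesions number of spherical white matter lesion blobs
#'   (default 0).
#' @param lesion_radius lesion blob radius in voxels (default 1.5).
#' @param voxel_size_mm isotropic voxel size (default 1 mm).
#' @param seed random seed used for lesion placement.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24L, 24L, 24L), wm_radius = 6,
                         shell_thickness = 3, n_parcels = 4L,
                         n_lesions = 0L, lesion_radius = 1.5,
                         voxel_size_mm = 1, seed = 1L) {
  shape <- as.integer(shape)
  if (shell_thickness < 1) stop("'shell_thickness' must be >= 1")
  if (n_parcels < 1L) stop("'n_parcels' must be >= 1")
  if (wm_radius + shell_thickness >= min(shape) / 2)
    stop("core plus shell must fit inside the grid")
  structure(list(shape = shape, wm_radius = wm_radius,
                 shell_thickness = shell_thickness,
                 n_parcels = as.integer(n_parcels),
                 n_lesions = as.integer(n_lesions),
                 lesion_radius = lesion_radius,
                 voxel_size_mm = voxel_size_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the synthetic phantom
#'
#' Builds the tissue masks, the sector parcellation, the parcellation table
#' and the ground-truth seeding interface. The interface (white matter voxels
#' adjacent to gray matter) is derived here by direct per-voxel neighbor
#' enumeration — independent of [extract_interface()]'s shift-based
#' implementation, so the two can check each other.
#'
#' @param spec a [phantom_spec()].
#' @param connectivity neighborhood for the ground-truth interface
#'   (default 26).
#' @return List: `gm`, `wm`, `lesions` ([binary_mask()]), `parcellation`
#'   ([label_volume()] on the gray shell), `table` ([parcellation_table()]),
#'   `interface_truth` ([binary_mask()]), `grid`.
#' @export
make_phantom <- function(spec, connectivity = 26L) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  d <- spec$shape
  grid <- voxel_grid(d, diag(c(rep(spec$voxel_size_mm, 3), 1)))
  ctr <- (d - 1) / 2
  ax <- array(rep(seq_len(d[1]) - 1, times = d[2] * d[3]), dim = d)
  ay <- array(rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]), dim = d)
  az <- array(rep(seq_len(d[3]) - 1, each = d[1] * d[2]), dim = d)
  r <- sqrt((ax - ctr[1])^2 + (ay - ctr[2])^2 + (az - ctr[3])^2)
  wm_data <- r <= spec$wm_radius
  gm_data <- r > spec$wm_radius & r <= spec$wm_radius + spec$shell_thickness

  # angular sectors in the (y, z) plane, hemispheres split on x
  theta <- atan2(az - ctr[3], ay - ctr[2])          # [-pi, pi)
  sector <- pmin(floor((theta + pi) / (2 * pi) * spec$n_parcels),
                 spec$n_parcels - 1)
  left <- ax < ctr[1]
  lab <- array(0L, dim = d)
  lab[gm_data] <- as.integer(sector[gm_data] + 1L +
                               ifelse(left[gm_data], 0L, spec$n_parcels))
  n_roi <- 2L * spec$n_parcels
  table <- parcellation_table(
    seq_len(n_roi),
    c(sprintf("sector_L_%02d", seq_len(spec$n_parcels)),
      sprintf("sector_R_%02d", seq_len(spec$n_parcels))),
    rep(c("L", "R"), each = spec$n_parcels),
    rep(TRUE, n_roi))

  lesions_data <- array(FALSE, dim = d)
  if (spec$n_lesions > 0L) {
    set.seed(spec$seed)
    wm_vox <- which(wm_data)
    pick <- arrayInd(sample(wm_vox, spec$n_lesions), d) - 1L
    for (i in seq_len(spec$n_lesions)) {
      dist <- sqrt((ax - pick[i, 1])^2 + (ay - pick[i, 2])^2 +
                   (az - pick[i, 3])^2)
      lesions_data <- lesions_data | (dist <= spec$lesion_radius & wm_data)
    }
  }

  # ground truth by brute-force neighbor enumeration
  offs <- neighbor_offsets(connectivity)
  truth <- array(FALSE, dim = d)
  wm_idx <- which(wm_data & !gm_data)
  vox <- arrayInd(wm_idx, d)
  for (i in seq_len(nrow(offs))) {
    p <- sweep(vox, 2L, offs[i, ], "+")
    ok <- p[, 1] >= 1L & p[, 1] <= d[1] & p[, 2] >= 1L & p[, 2] <= d[2] &
          p[, 3] >= 1L & p[, 3] <= d[3]
    lin <- (p[ok, 3] - 1L) * d[1] * d[2] + (p[ok, 2] - 1L) * d[1] + p[ok, 1]
    hit <- wm_idx[ok][gm_data[lin]]
    truth[hit] <- TRUE
  }

  list(gm = binary_mask(gm_data, grid), wm = binary_mask(wm_data, grid),
       lesions = binary_mask(lesions_data, grid),
       parcellation = label_volume(lab, grid), table = table,
       interface_truth = binary_mask(truth, grid), grid = grid)
}

#' Simulate a BOLD series with planted ROI correlation structure
#'
#' Latent per-ROI signals are drawn from a zero-mean multivariate normal with
#' the requested correlation matrix; every voxel gets its ROI's latent signal
#' plus iid Gaussian noise plus a baseline offset of 100 (so tSNR is finite
#' and positive, as in scanner-scaled data). Unlabeled voxels get noise plus
#' offset only.
#'
#' @param labeled_gm a [label_volume()].
#' @param roi_correlation N x N symmetric positive-semidefinite matrix with
#'   unit diagonal, rows matching the sorted nonzero labels.
#' @param T_ number of timepoints.
#' @param noise_sd voxelwise noise standard deviation (default 1).
#' @param tr repetition time in seconds (default 1).
#' @param seed random seed.
#' @return A [bold_series()].
#' @export
make_bold <- function(labeled_gm, roi_correlation, T_ = 200L, noise_sd = 1,
                      tr = 1, seed = 1L) {
  C <- as.matrix(roi_correlation)
  if (max(abs(C - t(C))) > 1e-8) stop("correlation target must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-8)
    stop("correlation target must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation target must be positive semidefinite")
  labs <- sort(unique(labeled_gm$data[labeled_gm$data > 0L]))
  if (length(labs) != nrow(C))
    stop("correlation target must be ", length(labs), " x ", length(labs),
         " to match the labels present")
  set.seed(seed)
  lat <- MASS::mvrnorm(T_, mu = rep(0, nrow(C)),
                       Sigma = C + diag(1e-10, nrow(C)))
  d <- dim(labeled_gm$data)
  data <- array(stats::rnorm(prod(d) * T_, sd = noise_sd) + 100,
                dim = c(d, T_))
  flat <- matrix(data, nrow = prod(d), ncol = T_)
  lab <- as.vector(labeled_gm$data)
  for (k in seq_along(labs)) {
    sel <- lab == labs[k]
    flat[sel, ] <- flat[sel, ] + rep(lat[, k], each = sum(sel))
  }
  bold_series(array(flat, dim = c(d, T_)), labeled_gm$grid, tr = tr)
}

#' Simulate streamline counts from a known connection-probability matrix
#'
#' Each seed ROI sends `streamlines_per_seed` streamlines allocated
#' multinomially across target ROIs according to its row of `true_prob`; the
#' remaining probability mass is a "not accepted" bin (streamlines lost to
#' exclusion masks or premature termination). Waytotal is the number sent per
#' seed.
#'
#' @param true_prob N x N matrix of connection probabilities, row sums <= 1;
#'   diagonal should be 0.
#' @param streamlines_per_seed streamlines sent per seed ROI (default 5000).
#' @param seed random seed.
#' @return A [streamline_counts()].
#' @export
make_counts <- function(true_prob, streamlines_per_seed = 5000L, seed = 1L) {
  P <- as.matrix(true_prob)
  if (nrow(P) != ncol(P)) stop("'true_prob' must be square")
  if (any(P < 0) || anyNA(P)) stop("probabilities must be non-negative")
  rs <- rowSums(P)
  if (any(rs > 1 + 1e-9))
    stop("row sums of 'true_prob' must be <= 1 (remainder = lost streamlines)")
  N <- nrow(P)
  set.seed(seed)
  counts <- matrix(0, N, N)
  for (i in seq_len(N)) {
    draw <- stats::rmultinom(1L, streamlines_per_seed, c(P[i, ], 1 - rs[i]))
    counts[i, ] <- draw[seq_len(N)]
  }
  streamline_counts(counts, rep(streamlines_per_seed, N))
}

#' Simulate a subject-by-IDP table with a planted latent effect
#'
#' Emulates the manual-QC study design: subjects in ordinal rating groups,
#' IDP vectors equal to (group score) x (effect size) x (planted salience
#' pattern) plus iid Gaussian noise. Group scores are equally spaced in
#' [-1, 1] across rating levels, so the association between ratings and IDPs
#' is rank-1 by construction; `effect_size = 0` yields an exact null.
#'
#' @param n_per_group subjects per rating level (vector; its length sets the
#'   number of levels, named 1..k).
#' @param planted_salience length-p pattern of IDP loadings.
#' @param effect_size scalar effect magnitude in noise-SD units (default 1).
#' @param noise_sd iid noise SD (default 1).
#' @param seed random seed.
#' @return List with `idps` (n x p matrix, columns `idp_01`...),
#'   `ratings` (integer vector), `planted_salience` (normalized).
#' @export
make_idp_ratings <- function(n_per_group, planted_salience, effect_size = 1,
                             noise_sd = 1, seed = 1L) {
  k <- length(n_per_group)
  if (k < 2L) stop("at least 2 rating groups are required")
  p <- length(planted_salience)
  if (p < 1L) stop("'planted_salience' must be non-empty")
  sal <- planted_salience / sqrt(sum(planted_salience^2))
  scores <- seq(-1, 1, length.out = k)
  ratings <- rep(seq_len(k), times = n_per_group)
  n <- length(ratings)
  set.seed(seed)
  X <- outer(scores[ratings] * effect_size, sal) +
    matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  colnames(X) <- sprintf("idp_%02d", seq_len(p))
  list(idps = X, ratings = ratings, planted_salience = sal)
}
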