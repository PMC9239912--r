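# Parcellated BOLD time-series extraction, Pearson functional connectivity
# and the functional image-derived phenotypes (tSNR, motion, FC summaries).

#' 4D BOLD series on a voxel grid
#'
#' @param data 4D numeric array (x, y, z, time) with at least 2 timepoints.
#' @param grid a [voxel_grid()] for the spatial dimensions.
#' @param tr repetition time in seconds (> 0).
#' @return Object of class `bold_series`.
#' @export
bold_series <- function(data, grid, tr = 1) {
  if (length(dim(data)) != 4L) stop("'data' must be a 4D array")
  if (!identical(as.integer(dim(data)[1:3]), grid$shape))
    stop("BOLD spatial shape does not match grid shape")
  if (dim(data)[4] < 2L) stop("BOLD series needs at least 2 timepoints")
  if (!is.numeric(tr) || tr <= 0) stop("'tr' must be a positive time in s")
  structure(list(grid = grid, data = data, tr = tr), class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat("<bold_series> ", paste(dim(x$data)[1:3], collapse = " x "),
      " voxels x ", dim(x$data)[4], " timepoints, TR = ", x$tr, " s\n",
      sep = "")
  invisible(x)
}

#' Extract mean ROI time series from a BOLD series
#'
#' For every ROI in the parcellation table, the unweighted mean BOLD signal
#' over the voxels carrying its label is computed at each timepoint. ROIs with
#' no voxels are kept as all-`NA` columns flagged invalid, preserving matrix
#' dimensions for downstream compatibility.
#'
#' @param bold a [bold_series()].
#' @param labeled a [label_volume()] on the same grid.
#' @param table a [parcellation_table()]; columns follow its order.
#' @return Object of class `roi_timeseries`: list with `values` (T x N
#'   matrix, columns named by ROI), `roi_indices`, `valid`, `tr`.
#' @export
extract_roi_timeseries <- function(bold, labeled, table) {
  stop_if_grid_mismatch(bold$grid, labeled$grid, "BOLD and label volumes")
  dims <- dim(bold$data)
  T_ <- dims[4]
  nvox <- prod(dims[1:3])
  flat <- matrix(bold$data, nrow = nvox, ncol = T_)
  lab <- as.vector(labeled$data)
  N <- nrow(table)
  values <- matrix(NA_real_, nrow = T_, ncol = N,
                   dimnames = list(NULL, table$name))
  valid <- logical(N)
  for (k in seq_len(N)) {
    sel <- lab == table$index[k]
    if (any(sel)) {
      values[, k] <- colMeans(flat[sel, , drop = FALSE])
      valid[k] <- TRUE
    }
  }
  structure(list(values = values, roi_indices = table$index, valid = valid,
                 tr = bold$tr), class = "roi_timeseries")
}

#' Pearson functional connectivity matrix
#'
#' Pairwise Pearson correlation between all ROI mean time series. Pairs
#' involving an invalid (empty) or zero-variance ROI are `NA`; the diagonal is
#' 1 for valid ROIs. Dimensions always match the parcellation, so the matrix
#' aligns with the structural connectome.
#'
#' @param ts a `roi_timeseries` from [extract_roi_timeseries()].
#' @return Object of class `fc_matrix`: list with `values` (N x N, in
#'   \[-1, 1\] or `NA`), `roi_indices`, `valid`.
#' @export
pearson_fc <- function(ts) {
  if (nrow(ts$values) < 3L)
    stop("at least 3 timepoints are required for correlation")
  N <- ncol(ts$values)
  ok <- ts$valid & apply(ts$values, 2L, function(v)
    all(is.finite(v)) && stats::sd(v) > 0)
  vals <- matrix(NA_real_, N, N,
                 dimnames = list(colnames(ts$values), colnames(ts$values)))
  if (any(ok)) {
    r <- stats::cor(ts$values[, ok, drop = FALSE])
    r[r > 1] <- 1; r[r < -1] <- -1
    vals[ok, ok] <- r
  }
  diag(vals)[!ok] <- NA_real_
  structure(list(values = vals, roi_indices = ts$roi_indices, valid = ok),
            class = "fc_matrix")
}

#' Temporal signal-to-noise ratio
#'
#' Per voxel, tSNR = temporal mean / temporal sample standard deviation
#' (denominator n - 1). Voxels with zero temporal variance get `NA` in the
#' map and are excluded from the summary, which reports the mean and median
#' tSNR over the mask.
#'
#' @param bold a [bold_series()] with at least 2 timepoints.
#' @param mask a non-empty [binary_mask()] on the same grid.
#' @return List with `map` (3D array) and `summary` (named vector: `mean`,
#'   `median`, `n_voxels`).
#' @export
tsnr <- function(bold, mask) {
  stop_if_grid_mismatch(bold$grid, mask$grid, "BOLD and mask")
  if (!any(mask$data)) stop("mask is empty")
  dims <- dim(bold$data)
  flat <- matrix(bold$data, nrow = prod(dims[1:3]), ncol = dims[4])
  mu <- rowMeans(flat)
  sdv <- sqrt(rowSums((flat - mu)^2) / (dims[4] - 1L))
  map <- mu / sdv
  map[sdv == 0] <- NA_real_
  map <- array(map, dim = dims[1:3])
  v <- map[mask$data]
  v <- v[is.finite(v)]
  list(map = map,
       summary = c(mean = mean(v), median = stats::median(v),
                   n_voxels = length(v)))
}

#' Read FSL-layout motion parameters
#'
#' Six whitespace-separated columns per frame: three rotations (radians)
#' followed by three translations (mm).
#'
#' @param path text file path.
#' @return T x 6 numeric matrix with columns `rot_x..rot_z`, `trans_x..trans_z`.
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L || !is.numeric(m) || anyNA(m))
    stop("motion parameter file must have 6 numeric columns")
  colnames(m) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  m
}

#' Framewise displacement from motion parameters
#'
#' Frame-to-frame head displacement: the sum of absolute translation
#' differences plus the sum of absolute rotation differences converted to arc
#' length on a sphere of `head_radius_mm`. The first frame has displacement 0
#' by convention; summaries are over frames 2..T.
#'
#' @param motion T x 6 matrix (rotations in radians then translations in mm),
#'   as from [read_motion_params()].
#' @param head_radius_mm sphere radius for the rotation arc length
#'   (default 50 mm).
#' @return List with `fd` (length-T vector, mm), `mean`, `max`.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L || !is.numeric(motion) || anyNA(motion))
    stop("'motion' must be a numeric T x 6 matrix")
  if (nrow(motion) < 2L) stop("at least 2 frames are required")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 4:6, drop = FALSE]) +
               head_radius_mm * rowSums(d[, 1:3, drop = FALSE]))
  list(fd = fd, mean = mean(fd[-1L]), max = max(fd[-1L]))
}

#' Summary phenotypes of the functional connectivity distribution
#'
#' Summary statistics over the valid off-diagonal upper triangle of the FC
#' matrix: center, spread, shape (population-moment skewness and excess
#' kurtosis) and sign proportions. Degenerate FC distributions (compressed
#' range, strong positive shift) flag residual artifacts.
#'
#' @param fc an `fc_matrix` from [pearson_fc()] with >= 2 valid ROIs.
#' @return Named numeric vector: `fc_mean`, `fc_median`, `fc_sd`, `fc_min`,
#'   `fc_max`, `fc_range`, `fc_skewness`, `fc_kurtosis`, `fc_prop_positive`,
#'   `fc_prop_gt_0.5`, `fc_n_pairs`.
#' @export
fc_summaries <- function(fc) {
  if (sum(fc$valid) < 2L) stop("at least 2 valid ROIs are required")
  v <- fc$values[upper.tri(fc$values)]
  v <- v[is.finite(v)]
  m2 <- mean((v - mean(v))^2)
  skew <- if (m2 > 0) mean((v - mean(v))^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - mean(v))^4) / m2^2 - 3 else 0
  c(fc_mean = mean(v), fc_median = stats::median(v), fc_sd = stats::sd(v),
    fc_min = min(v), fc_max = max(v), fc_range = max(v) - min(v),
    fc_skewness = skew, fc_kurtosis = kurt,
    fc_prop_positive = mean(v > 0), fc_prop_gt_0.5 = mean(abs(v) > 0.5),
    fc_n_pairs = length(v))
}

#' Write ROI time series as TSV
#'
#' One row per timepoint, one column per ROI (header = ROI names); invalid
#' ROIs are written as `NA`.
#'
#' @param ts a `roi_timeseries`.
#' @param path output path.
#' @export
write_roi_timeseries <- function(ts, path) {
  utils::write.table(ts$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a functional connectivity matrix as whitespace-delimited text
#'
#' @param fc an `fc_matrix`.
#' @param path output path.
#' @param na string used for missing entries (default "NaN", which both TVB
#'   and numpy parse).
#' @export
write_fc_matrix <- function(fc, path, na = "NaN") {
  write_matrix_txt(fc$values, path, na = na)
}
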