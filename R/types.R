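#' Voxel grid: shape, spacing and voxel-to-world affine
#'
#' A `voxel_grid` ties a 3D array shape to world (scanner) coordinates through
#' a 4x4 affine in millimetres, following the NIfTI convention: world
#' coordinates of the voxel at 0-based index (i, j, k) are
#' `affine %*% c(i, j, k, 1)`, in RAS mm.
#'
#' @param shape integer vector of length 3, all >= 1.
#' @param affine 4x4 invertible voxel-to-world matrix (mm). Defaults to the
#'   identity (1 mm isotropic, origin at voxel 0,0,0).
#' @return An object of class `voxel_grid` with fields `shape`, `affine` and
#'   `voxel_size` (column norms of the affine's 3x3 block, mm).
#' @export
voxel_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  vsize <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(shape = shape, affine = affine, voxel_size = vsize),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s are not on the same voxel grid", what))
  invisible(TRUE)
}

#' Binary tissue mask on a voxel grid
#'
#' @param data 3D logical (or coercible) array matching `grid$shape`.
#' @param grid a [voxel_grid()].
#' @return Object of class `binary_mask` with fields `grid` and `data`.
#' @export
binary_mask <- function(data, grid) {
  data <- array(as.logical(data), dim = dim(data))
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("mask data shape does not match grid shape")
  if (anyNA(data)) stop("mask data must not contain NA")
  structure(list(grid = grid, data = data), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", sum(x$data), " / ", length(x$data), " voxels set\n",
      sep = "")
  invisible(x)
}

#' Integer ROI label volume on a voxel grid
#'
#' Value 0 means background / unlabeled; positive labels index ROIs in a
#' [parcellation_table()].
#'
#' @param data 3D non-negative integer array matching `grid$shape`.
#' @param grid a [voxel_grid()].
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(data, grid) {
  data <- array(as.integer(round(data)), dim = dim(data))
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("label data shape does not match grid shape")
  if (anyNA(data) || any(data < 0L))
    stop("labels must be non-negative integers")
  structure(list(grid = grid, data = data), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(x$data[x$data > 0L]))
  cat("<label_volume> ", length(labs), " labels on ",
      paste(x$grid$shape, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Parcellation look-up table
#'
#' Maps ROI indices to names, hemispheres and cortical flags. The on-disk
#' format is a tab-separated file with header
#' `index<TAB>name<TAB>hemisphere<TAB>cortical`, hemisphere in {L, R, M},
#' cortical in {0, 1}.
#'
#' @param index positive unique integers.
#' @param name unique non-empty ROI names.
#' @param hemisphere one of "L", "R", "M" per ROI.
#' @param cortical logical (or 0/1) per ROI.
#' @return A `data.frame` of class `parcellation_table`.
#' @export
parcellation_table <- function(index, name,
                               hemisphere = rep("M", length(index)),
                               cortical = rep(TRUE, length(index))) {
  index <- as.integer(index)
  name <- as.character(name)
  hemisphere <- toupper(as.character(hemisphere))
  cortical <- as.logical(as.integer(as.logical(cortical)))
  if (any(is.na(index)) || any(index <= 0L)) stop("indices must be positive")
  if (anyDuplicated(index)) stop("ROI indices must be unique")
  if (any(!nzchar(name))) stop("ROI names must be non-empty")
  if (anyDuplicated(name)) stop("ROI names must be unique")
  if (!all(hemisphere %in% c("L", "R", "M")))
    stop("hemisphere must be one of L, R, M")
  if (length(name) != length(index) || length(hemisphere) != length(index) ||
      length(cortical) != length(index))
    stop("all columns must have the same length")
  structure(
    data.frame(index = index, name = name, hemisphere = hemisphere,
               cortical = cortical, stringsAsFactors = FALSE),
    class = c("parcellation_table", "data.frame"))
}

#' Read / write a parcellation look-up table
#'
#' @param path file path of the tab-separated table.
#' @return [read_parcellation_table()]: a [parcellation_table()].
#' @export
read_parcellation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("index", "name", "hemisphere", "cortical")
  if (!all(need %in% names(df)))
    stop("look-up table must have columns: ", paste(need, collapse = ", "))
  parcellation_table(df$index, df$name, df$hemisphere, df$cortical)
}

#' @param table a [parcellation_table()].
#' @rdname read_parcellation_table
#' @export
write_parcellation_table <- function(table, path) {
  out <- data.frame(index = table$index, name = table$name,
                    hemisphere = table$hemisphere,
                    cortical = as.integer(table$cortical))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 0-based voxel indices (n x 3) of TRUE / nonzero entries of a 3D array
voxel_indices <- function(data) {
  idx <- which(if (is.logical(data)) data else data != 0)
  arrayInd(idx, dim(data)) - 1L
}

# world coordinates (n x 3 mm) for 0-based voxel index rows
voxels_to_world <- function(vox, affine) {
  if (nrow(vox) == 0L) return(matrix(numeric(0), 0L, 3L))
  h <- cbind(vox, 1)
  t(affine[1:3, , drop = FALSE] %*% t(h))
}
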