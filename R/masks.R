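# Tissue-mask refinement, GM labeling and the GM/WM interface used to seed
# tractography. All operations require their inputs on one shared voxel grid;
# registration is the caller's job.

# Integer neighbor offsets for 6/18/26-connectivity (3D).
neighbor_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d2 <- rowSums(g^2)
  keep <- switch(as.character(connectivity),
                 "6" = d2 == 1, "18" = d2 >= 1 & d2 <= 2, "26" = d2 >= 1)
  unname(g[keep, , drop = FALSE])
}

# result[i,j,k] <- a[i+dx, j+dy, k+dz], padded with `fill` outside the array
shift_array <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src_lo <- pmax(1L, 1L + off); src_hi <- pmin(d, d + off)
  if (any(src_lo > src_hi)) return(out)
  dst_lo <- src_lo - off; dst_hi <- src_hi - off
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    a[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  out
}

#' Merge a subcortical segmentation into the gray matter mask
#'
#' Model-based subcortical segmentations are more reliable than
#' intensity-based tissue classification for deep gray structures; their
#' voxels are added to the gray matter mask by voxelwise union.
#'
#' @param gm,subcortical [binary_mask()] objects on the same grid.
#' @return The union as a [binary_mask()].
#' @export
merge_subcortical <- function(gm, subcortical) {
  stop_if_grid_mismatch(gm$grid, subcortical$grid, "gm and subcortical masks")
  binary_mask(gm$data | subcortical$data, gm$grid)
}

#' Reassign white-matter-lesion voxels from gray to white matter
#'
#' White matter lesions are routinely misclassified as gray matter by
#' T1-based segmentation. Given a lesion mask, lesion voxels are removed from
#' the gray matter mask and the ones that were in gray matter are added back
#' to the white matter mask.
#'
#' @param gm,wm,lesions [binary_mask()] objects on the same grid.
#' @return A list with refined `gm` and `wm` masks.
#' @export
reassign_lesions <- function(gm, wm, lesions) {
  stop_if_grid_mismatch(gm$grid, wm$grid, "gm and wm masks")
  stop_if_grid_mismatch(gm$grid, lesions$grid, "gm and lesion masks")
  moved <- gm$data & lesions$data
  list(gm = binary_mask(gm$data & !lesions$data, gm$grid),
       wm = binary_mask(wm$data | moved, wm$grid))
}

#' Label the gray matter mask with parcellation ROI indices
#'
#' Each gray matter voxel takes the parcellation label at its position.
#' Gray matter voxels the registered parcellation misses (label 0) may be
#' filled from the nearest labeled voxel within `fill_radius_mm` (Euclidean
#' distance in world mm); at equal distance the smallest label wins. With the
#' default radius 0 no filling happens. Voxels outside gray matter are 0.
#'
#' @param gm a [binary_mask()].
#' @param parcellation a [label_volume()] co-registered on the same grid.
#' @param fill_radius_mm non-negative search radius in mm (default 0).
#' @return A [label_volume()] nonzero only inside the gray matter mask.
#' @export
label_gray_matter <- function(gm, parcellation, fill_radius_mm = 0) {
  stop_if_grid_mismatch(gm$grid, parcellation$grid, "gm mask and parcellation")
  if (fill_radius_mm < 0) stop("'fill_radius_mm' must be >= 0")
  out <- parcellation$data
  out[!gm$data] <- 0L
  if (fill_radius_mm > 0) {
    A <- gm$grid$affine[1:3, 1:3]
    vs <- gm$grid$voxel_size
    r <- ceiling(fill_radius_mm / vs)
    g <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2],
                               dz = -r[3]:r[3]))
    dist <- sqrt(colSums((A %*% t(g))^2))
    keep <- dist <= fill_radius_mm + 1e-9 & dist > 0
    g <- g[keep, , drop = FALSE]; dist <- dist[keep]
    # visit offsets shell by shell so the nearest labeled voxel wins;
    # within one shell take the minimum candidate label
    for (d in sort(unique(dist))) {
      todo <- gm$data & out == 0L
      if (!any(todo)) break
      shell <- which(abs(dist - d) < 1e-12)
      cand <- array(NA_integer_, dim = dim(out))
      for (s in shell) {
        nb <- shift_array(parcellation$data, g[s, ], 0L)
        upd <- todo & nb > 0L & (is.na(cand) | nb < cand)
        cand[upd] <- nb[upd]
      }
      hit <- !is.na(cand)
      out[hit] <- cand[hit]
    }
  }
  label_volume(out, gm$grid)
}

#' Extract the gray-matter/white-matter interface
#'
#' The interface is the layer of white matter voxels having at least one gray
#' matter neighbor under the chosen 3D connectivity; labeled per ROI it
#' provides the seed and target masks for probabilistic tractography. Voxels
#' flagged as both gray and white matter are treated as gray matter and
#' excluded from the interface.
#'
#' @param gm,wm [binary_mask()] objects on the same grid.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A [binary_mask()], a subset of `wm`.
#' @export
extract_interface <- function(gm, wm, connectivity = 26L) {
  stop_if_grid_mismatch(gm$grid, wm$grid, "gm and wm masks")
  offs <- neighbor_offsets(connectivity)
  wm_eff <- wm$data & !gm$data  # gm takes precedence on overlap
  touched <- array(FALSE, dim = dim(wm_eff))
  for (i in seq_len(nrow(offs)))
    touched <- touched | shift_array(gm$data, offs[i, ], FALSE)
  binary_mask(wm_eff & touched, wm$grid)
}

#' Label interface voxels from adjacent gray matter
#'
#' Each interface voxel takes the majority ROI label among its labeled gray
#' matter neighbors under the chosen connectivity; ties are broken toward the
#' smallest label index. Interface voxels with no labeled gray matter
#' neighbor stay 0.
#'
#' @param interface a [binary_mask()] as from [extract_interface()].
#' @param labeled_gm a [label_volume()] of the labeled gray matter.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A [label_volume()] nonzero only on interface voxels.
#' @export
label_interface <- function(interface, labeled_gm, connectivity = 26L) {
  stop_if_grid_mismatch(interface$grid, labeled_gm$grid,
                        "interface and labeled gm")
  offs <- neighbor_offsets(connectivity)
  idx <- which(interface$data)
  out <- array(0L, dim = dim(interface$data))
  if (length(idx) > 0L) {
    vox <- arrayInd(idx, dim(interface$data))
    d <- dim(interface$data)
    nb <- matrix(0L, nrow = length(idx), ncol = nrow(offs))
    for (i in seq_len(nrow(offs))) {
      p <- sweep(vox, 2L, offs[i, ], "+")
      ok <- p[, 1] >= 1L & p[, 1] <= d[1] & p[, 2] >= 1L & p[, 2] <= d[2] &
            p[, 3] >= 1L & p[, 3] <= d[3]
      lin <- (p[ok, 3] - 1L) * d[1] * d[2] + (p[ok, 2] - 1L) * d[1] + p[ok, 1]
      nb[ok, i] <- labeled_gm$data[lin]
    }
    out[idx] <- apply(nb, 1L, function(v) {
      v <- v[v > 0L]
      if (length(v) == 0L) return(0L)
      tab <- table(v)
      # which.max on a table returns the first (numerically smallest) label
      as.integer(names(tab)[which.max(tab)])
    })
  }
  label_volume(out, interface$grid)
}

#' Per-ROI centroids in world coordinates
#'
#' The centroid of each ROI is the mean of the world coordinates (affine
#' applied to 0-based voxel indices) of all voxels carrying its label. ROIs
#' absent from the label volume get `NA` coordinates and `missing = TRUE`.
#'
#' @param labeled a [label_volume()].
#' @param table a [parcellation_table()]; output rows follow its order.
#' @return `data.frame` with columns `index`, `name`, `x`, `y`, `z`,
#'   `n_voxels`, `missing`.
#' @export
roi_centroids <- function(labeled, table) {
  res <- data.frame(index = table$index, name = table$name,
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    n_voxels = 0L, missing = TRUE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(table))) {
    vox <- voxel_indices(labeled$data == table$index[k])
    if (nrow(vox) > 0L) {
      w <- voxels_to_world(vox, labeled$grid$affine)
      res[k, c("x", "y", "z")] <- colMeans(w)
      res$n_voxels[k] <- nrow(vox)
      res$missing[k] <- FALSE
    }
  }
  res
}

#' Per-ROI voxel counts and volumes
#'
#' @inheritParams roi_centroids
#' @return `data.frame` with columns `index`, `name`, `n_voxels`,
#'   `volume_mm3` (count times voxel volume from the grid affine).
#' @export
roi_volumes <- function(labeled, table) {
  vol_per_voxel <- abs(det(labeled$grid$affine[1:3, 1:3]))
  maxlab <- max(c(table$index, 1L))
  counts <- tabulate(labeled$data[labeled$data > 0L], nbins = maxlab)
  n <- counts[table$index]
  data.frame(index = table$index, name = table$name, n_voxels = n,
             volume_mm3 = n * vol_per_voxel, stringsAsFactors = FALSE)
}
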