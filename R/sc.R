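# Structural connectivity: ingest streamline-count matrices from
# probabilistic tractography, normalize to connection probabilities,
# symmetrize, summarize, and export in TheVirtualBrain zip layout.

# Numbers are written with %.17g so that export -> read -> export round trips
# are byte-identical (doubles survive the text representation exactly).
fmt_num <- function(x, na = "NaN") {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- na
  out
}

write_matrix_txt <- function(m, path, na = "NaN") {
  lines <- apply(m, 1L, function(r) paste(fmt_num(r, na = na), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop("ragged matrix in ", path, ": row ", which(ncols != ncols[1])[1],
         " has ", ncols[which(ncols != ncols[1])[1]], " entries, expected ",
         ncols[1])
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  bad <- is.na(vals) & unlist(rows) != "NaN" & unlist(rows) != "NA"
  if (any(bad))
    stop("non-numeric entry '", unlist(rows)[bad][1], "' in ", path)
  matrix(vals, nrow = length(rows), byrow = TRUE)
}

#' Streamline counts from probabilistic tractography
#'
#' ROI-by-ROI streamline counts (row = seed ROI, column = target ROI) plus
#' the per-seed number of successfully sent streamlines ("waytotal").
#'
#' @param counts N x N non-negative integer matrix.
#' @param waytotal N non-negative integers, one per seed ROI.
#' @param roi_indices optional N parcellation indices (default 1..N).
#' @return Object of class `streamline_counts`.
#' @export
streamline_counts <- function(counts, waytotal, roi_indices = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("'counts' must be square")
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  waytotal <- as.numeric(waytotal)
  if (length(waytotal) != nrow(counts))
    stop("'waytotal' length must match the number of seed ROIs")
  if (any(waytotal < 0) || anyNA(waytotal))
    stop("waytotal entries must be non-negative")
  if (any(rowSums(counts) > waytotal + 1e-9))
    warning("row sums of counts exceed waytotal for ",
            sum(rowSums(counts) > waytotal + 1e-9), " seed ROI(s)")
  if (is.null(roi_indices)) roi_indices <- seq_len(nrow(counts))
  structure(list(counts = counts, waytotal = waytotal,
                 roi_indices = as.integer(roi_indices)),
            class = "streamline_counts")
}

#' Read streamline counts and waytotals from tractography text output
#'
#' @param counts_file whitespace-delimited N x N matrix file.
#' @param waytotal_file text file with N waytotal values (one per line or
#'   whitespace-separated).
#' @return A [streamline_counts()] object.
#' @export
read_counts <- function(counts_file, waytotal_file) {
  if (!file.exists(waytotal_file))
    stop("waytotal file not found: ", waytotal_file)
  counts <- read_matrix_txt(counts_file)
  wt <- scan(waytotal_file, what = numeric(), quiet = TRUE)
  if (length(wt) != nrow(counts))
    stop("waytotal has ", length(wt), " entries but counts matrix has ",
         nrow(counts), " seed rows")
  streamline_counts(counts, wt)
}

#' Normalize streamline counts to connection probabilities
#'
#' The weights matrix is the streamline-count matrix divided by the total
#' number of streamlines successfully sent from the seed ROIs — a single
#' scalar, so entries estimate the probability of each connection among all
#' sent streamlines. `per_seed = TRUE` instead divides each row by its own
#' waytotal (an alternative reading of "from the seed ROIs").
#'
#' @param sc a [streamline_counts()].
#' @param per_seed divide rows by per-seed waytotals instead of the grand
#'   total (default `FALSE`).
#' @return N x N numeric matrix with entries in \[0, 1\].
#' @export
normalize_weights <- function(sc, per_seed = FALSE) {
  if (per_seed) {
    wt <- sc$waytotal
    if (any(wt == 0)) stop("per-seed normalization requires waytotal > 0")
    return(sc$counts / wt)
  }
  total <- sum(sc$waytotal)
  if (total <= 0) stop("total waytotal must be positive")
  sc$counts / total
}

#' Symmetrize a directed connectivity matrix
#'
#' Streamline directionality is not meaningful, so the two directed estimates
#' for each ROI pair are combined. The diagonal (self-connections) is forced
#' to zero.
#'
#' @param m square numeric matrix.
#' @param method "mean" (default), "max" or "sum".
#' @return Symmetric matrix with zero diagonal.
#' @export
symmetrize <- function(m, method = c("mean", "max", "sum")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("'m' must be square")
  out <- switch(method,
                mean = (m + t(m)) / 2,
                max = pmax(m, t(m)),
                sum = m + t(m))
  diag(out) <- 0
  out
}

#' Symmetrize a tract-length matrix consistently with the weights
#'
#' Lengths are averaged over the two directions when both produced
#' streamlines, taken from the single nonzero direction otherwise, and forced
#' to zero wherever the symmetrized weight is zero (no connection means no
#' length estimate).
#'
#' @param lengths square matrix of directed mean tract lengths (mm).
#' @param weights_sym symmetrized weights matrix of the same shape.
#' @return Symmetric length matrix, zero diagonal.
#' @export
symmetrize_lengths <- function(lengths, weights_sym) {
  lengths <- as.matrix(lengths)
  if (!all(dim(lengths) == dim(weights_sym)))
    stop("'lengths' and 'weights_sym' must have the same shape")
  lt <- t(lengths)
  both <- lengths > 0 & lt > 0
  out <- pmax(lengths, lt)              # covers the single-direction case
  out[both] <- ((lengths + lt) / 2)[both]
  out[weights_sym == 0] <- 0
  diag(out) <- 0
  out
}

#' Assemble a connectome
#'
#' Bundles symmetric weights and tract lengths with per-ROI metadata and
#' centroids. Invariants (symmetry, zero diagonal, non-negative entries,
#' lengths zero where weights are zero) are validated.
#'
#' @param weights,tract_lengths N x N symmetric matrices, zero diagonal.
#' @param table a [parcellation_table()] with N rows.
#' @param centroids N x 3 matrix of world coordinates (mm) or a
#'   [roi_centroids()] data frame.
#' @return Object of class `connectome`.
#' @export
connectome <- function(weights, tract_lengths, table, centroids) {
  weights <- as.matrix(weights)
  tract_lengths <- as.matrix(tract_lengths)
  N <- nrow(table)
  if (!all(dim(weights) == N) || !all(dim(tract_lengths) == N))
    stop("matrices must be N x N with N = number of ROIs in the table")
  if (max(abs(weights - t(weights))) > 1e-9 ||
      max(abs(tract_lengths - t(tract_lengths))) > 1e-9)
    stop("weights and tract_lengths must be symmetric")
  if (any(diag(weights) != 0) || any(diag(tract_lengths) != 0))
    stop("diagonals must be zero")
  if (any(weights < 0) || any(tract_lengths < 0))
    stop("weights and tract lengths must be non-negative")
  if (any(tract_lengths[weights == 0] != 0))
    stop("tract lengths must be zero where weights are zero")
  if (is.data.frame(centroids))
    centroids <- as.matrix(centroids[, c("x", "y", "z")])
  centroids <- as.matrix(centroids)
  if (!all(dim(centroids) == c(N, 3L)))
    stop("'centroids' must be N x 3")
  rownames(weights) <- colnames(weights) <- table$name
  rownames(tract_lengths) <- colnames(tract_lengths) <- table$name
  structure(list(weights = weights, tract_lengths = tract_lengths,
                 table = table, centroids = centroids), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  N <- nrow(x$weights)
  dens <- mean(x$weights[upper.tri(x$weights)] > 0)
  cat("<connectome> ", N, " ROIs, density ", signif(dens, 3), "\n", sep = "")
  invisible(x)
}

#' Structural connectome summary phenotypes
#'
#' Density of the upper triangle overall and split by hemisphere pairing
#' (inter-hemispheric sparsity is a sensitive marker of registration /
#' seeding failures), disconnected ROI count, and moments of the nonzero
#' weights on a log10 scale.
#'
#' @param conn a [connectome()].
#' @param table a [parcellation_table()]; defaults to the one in `conn`.
#' @return Named numeric vector: `sc_density`, `sc_density_interhemi`,
#'   `sc_density_intra_left`, `sc_density_intra_right`, `sc_n_disconnected`,
#'   `sc_log10w_mean`, `sc_log10w_median`, `sc_log10w_sd`, `sc_w_min`,
#'   `sc_w_max`.
#' @export
sc_summaries <- function(conn, table = conn$table) {
  w <- conn$weights
  N <- nrow(w)
  if (N < 2L) stop("at least 2 ROIs are required")
  hemi <- table$hemisphere
  ut <- upper.tri(w)
  pair_hemi_i <- matrix(hemi, N, N)        # row ROI hemisphere
  pair_hemi_j <- matrix(hemi, N, N, byrow = TRUE)
  inter <- ut & ((pair_hemi_i == "L" & pair_hemi_j == "R") |
                 (pair_hemi_i == "R" & pair_hemi_j == "L"))
  intra_l <- ut & pair_hemi_i == "L" & pair_hemi_j == "L"
  intra_r <- ut & pair_hemi_i == "R" & pair_hemi_j == "R"
  dens <- function(sel) if (any(sel)) mean(w[sel] > 0) else NA_real_
  nz <- w[ut][w[ut] > 0]
  lw <- log10(nz)
  c(sc_density = dens(ut),
    sc_density_interhemi = dens(inter),
    sc_density_intra_left = dens(intra_l),
    sc_density_intra_right = dens(intra_r),
    sc_n_disconnected = sum(rowSums(w) == 0),
    sc_log10w_mean = if (length(lw)) mean(lw) else NA_real_,
    sc_log10w_median = if (length(lw)) stats::median(lw) else NA_real_,
    sc_log10w_sd = if (length(lw) > 1) stats::sd(lw) else NA_real_,
    sc_w_min = if (length(nz)) min(nz) else NA_real_,
    sc_w_max = if (length(nz)) max(nz) else NA_real_)
}

sanitize_roi_name <- function(name) gsub("[[:space:]]+", "_", name)

#' Export a connectome as a TheVirtualBrain connectivity zip
#'
#' Writes the five-file archive TVB imports without further processing:
#' `weights.txt` and `tract_lengths.txt` (N x N whitespace-delimited),
#' `centres.txt` (`name x y z` per ROI, mm), `hemispheres.txt` (0 = left,
#' 1 = right; midline ROIs are written 0) and `cortical.txt` (0/1). Row order
#' is the parcellation-table order in every file. ROI names containing
#' whitespace are sanitized with underscores so `centres.txt` keeps exactly
#' four columns.
#'
#' @param conn a [connectome()]; all centroids must be finite.
#' @param path output `.zip` path.
#' @return `path`, invisibly.
#' @export
export_tvb_zip <- function(conn, path) {
  bad <- !apply(is.finite(conn$centroids), 1L, all)
  if (any(bad))
    stop("missing centroids for ROI(s): ",
         paste(conn$table$name[bad], collapse = ", "))
  tmp <- tempfile("tvb_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  write_matrix_txt(conn$weights, file.path(tmp, "weights.txt"))
  write_matrix_txt(conn$tract_lengths, file.path(tmp, "tract_lengths.txt"))
  nm <- sanitize_roi_name(conn$table$name)
  writeLines(paste(nm,
                   fmt_num(conn$centroids[, 1]),
                   fmt_num(conn$centroids[, 2]),
                   fmt_num(conn$centroids[, 3])),
             file.path(tmp, "centres.txt"))
  writeLines(as.character(as.integer(conn$table$hemisphere == "R")),
             file.path(tmp, "hemispheres.txt"))
  writeLines(as.character(as.integer(conn$table$cortical)),
             file.path(tmp, "cortical.txt"))
  files <- c("weights.txt", "tract_lengths.txt", "centres.txt",
             "hemispheres.txt", "cortical.txt")
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE), files, root = tmp,
           mode = "cherry-pick")
  invisible(path)
}

#' Read a TheVirtualBrain connectivity zip back into a connectome
#'
#' @param path zip archive written by [export_tvb_zip()] (or TVB-compatible).
#' @return A [connectome()]; hemispheres map 1 to "R" and 0 to "L", cortical
#'   flags are restored from `cortical.txt`.
#' @export
read_tvb_zip <- function(path) {
  tmp <- tempfile("tvb_read_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  zip::unzip(path, exdir = tmp)
  need <- c("weights.txt", "tract_lengths.txt", "centres.txt",
            "hemispheres.txt", "cortical.txt")
  missing <- need[!file.exists(file.path(tmp, need))]
  if (length(missing))
    stop("archive is missing: ", paste(missing, collapse = ", "))
  w <- read_matrix_txt(file.path(tmp, "weights.txt"))
  tl <- read_matrix_txt(file.path(tmp, "tract_lengths.txt"))
  cen <- utils::read.table(file.path(tmp, "centres.txt"),
                           col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  hemi <- scan(file.path(tmp, "hemispheres.txt"), what = integer(),
               quiet = TRUE)
  cort <- scan(file.path(tmp, "cortical.txt"), what = integer(), quiet = TRUE)
  tab <- parcellation_table(seq_len(nrow(cen)), cen$name,
                            ifelse(hemi == 1L, "R", "L"), cort)
  connectome(w, tl, tab, as.matrix(cen[, c("x", "y", "z")]))
}
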