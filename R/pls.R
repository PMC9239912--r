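# Mean-centered partial least squares relating imaging-derived phenotypes
# (IDPs) to ordinal QC ratings. The cross-block covariance is formed as the
# grand-mean-centered matrix of rating-group means of z-scored IDPs; its SVD
# yields latent variables (IDP saliences, rating design contrasts, singular
# values). Significance comes from rating permutations, reliability from
# within-group bootstrap resampling (bootstrap ratio = salience / SE).

# -- internal helpers --------------------------------------------------------

# column z-score with sample SD; zero-variance columns become all-zero
zscore_cols <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  Z <- sweep(X, 2L, mu, "-")
  sdv_safe <- ifelse(sdv > 0, sdv, 1)
  Z <- sweep(Z, 2L, sdv_safe, "/")
  Z[, sdv == 0] <- 0
  Z
}

impute_col_median <- function(X) {
  nas <- which(colSums(is.na(X)) > 0L)
  for (j in nas) {
    v <- X[, j]
    if (all(is.na(v))) stop("IDP column ", j, " is entirely missing")
    v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    X[, j] <- v
  }
  X
}

check_ratings <- function(ratings, min_size = 2L) {
  f <- factor(ratings)
  sizes <- table(f)
  if (nlevels(f) < 2L)
    stop("at least 2 rating groups are required")
  small <- names(sizes)[sizes < min_size]
  if (length(small))
    stop("rating group(s) with fewer than ", min_size, " subjects: ",
         paste(small, collapse = ", "))
  f
}

# group means of Z by rating, centered on the unweighted grand mean of groups
group_center <- function(Z, f) {
  G <- rowsum(Z, f) / as.vector(table(f))
  sweep(G, 2L, colMeans(G), "-")
}

# -- exported operations -----------------------------------------------------

#' Prepare the mean-centered group matrix for PLS
#'
#' Missing IDP entries are imputed by their column median, columns are
#' z-scored over all subjects (IDPs have incommensurate units), per-rating
#' group means are computed, and the unweighted grand mean of the group means
#' is subtracted from every column. The SVD of the resulting g x p matrix is
#' the mean-centered PLS.
#'
#' @param idps n x p numeric matrix of IDP values (missing allowed), columns
#'   named by IDP.
#' @param ratings length-n ordinal QC ratings (each level needs >= 2
#'   subjects).
#' @return g x p matrix, rows named by rating level, with attribute `groups`
#'   (levels) and `group_sizes`.
#' @export
pls_prepare <- function(idps, ratings) {
  idps <- as.matrix(idps)
  if (nrow(idps) != length(ratings))
    stop("'ratings' length must equal the number of IDP rows")
  f <- check_ratings(ratings)
  Z <- zscore_cols(impute_col_median(idps))
  M <- group_center(Z, f)
  attr(M, "groups") <- levels(f)
  attr(M, "group_sizes") <- as.vector(table(f))
  M
}

#' Singular value decomposition of the cross-block covariance
#'
#' Thin SVD of the prepared group matrix. Latent variables (LVs) are ordered
#' by decreasing singular value; because grand-mean centering removes one
#' degree of freedom across the g rows, L = min(g - 1, p) LVs are retained.
#' Sign convention: the largest-magnitude design salience of each LV is made
#' positive. The percentage of cross-block covariance explained by LV l is
#' 100 s_l^2 / sum(s^2), summing to 100 over the retained LVs.
#'
#' @param M g x p finite matrix from [pls_prepare()].
#' @return List with `saliences` (p x L IDP weights), `design_saliences`
#'   (g x L rating contrasts), `singular_values` (length L, non-increasing),
#'   `pct_covariance` (length L, sums to 100).
#' @export
pls_svd <- function(M) {
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("'M' must be finite")
  g <- nrow(M); p <- ncol(M)
  L <- min(g - 1L, p)
  if (L < 1L) stop("need at least 2 groups and 1 IDP")
  s <- svd(M, nu = L, nv = L)
  d <- s$d[seq_len(L)]
  U <- s$u; V <- s$v
  for (l in seq_len(L)) {             # deterministic sign: top design loading > 0
    a <- abs(U[, l])
    top <- which(a >= max(a) - 1e-12)[1L]   # ties -> first group
    if (U[top, l] < 0) {
      U[, l] <- -U[, l]; V[, l] <- -V[, l]
    }
  }
  tot <- sum(d^2)
  pct <- if (tot > 0) 100 * d^2 / tot else rep(0, L)
  rownames(V) <- colnames(M); rownames(U) <- rownames(M)
  list(saliences = V, design_saliences = U, singular_values = d,
       pct_covariance = pct)
}

#' Permutation test for latent-variable significance
#'
#' QC ratings are shuffled across subjects without replacement (IDP rows
#' fixed), the group-mean matrix and its SVD are recomputed, and each
#' observed singular value is compared with its matched-position null
#' distribution: p_l = (1 + #\{perm s_l >= observed s_l\}) / (1 + n_perm).
#' Column z-scores do not depend on the rating labels, so they are computed
#' once. `statistic = "max"` compares every observed value against the
#' maximum permuted singular value instead (familywise-style).
#'
#' @inheritParams pls_prepare
#' @param n_perm number of permutations (>= 1, default 1000).
#' @param seed integer seed for reproducible shuffles.
#' @param statistic "per_lv" (default) or "max".
#' @return List with `perm_p` (length L), `observed` singular values,
#'   `n_perm`.
#' @export
permutation_test <- function(idps, ratings, n_perm = 1000L, seed = 1L,
                             statistic = c("per_lv", "max")) {
  statistic <- match.arg(statistic)
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  idps <- as.matrix(idps)
  f <- check_ratings(ratings)
  Z <- zscore_cols(impute_col_median(idps))
  obs <- pls_svd(structure(group_center(Z, f), dimnames = NULL))
  L <- length(obs$singular_values)
  n <- length(f)
  exceed <- integer(L)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    fp <- f[sample.int(n)]
    d <- svd(group_center(Z, fp), nu = 0L, nv = 0L)$d[seq_len(L)]
    if (statistic == "max")
      exceed <- exceed + as.integer(max(d) >= obs$singular_values)
    else
      exceed <- exceed + as.integer(d >= obs$singular_values)
  }
  list(perm_p = (1 + exceed) / (1 + n_perm),
       observed = obs$singular_values, n_perm = as.integer(n_perm))
}

# Procrustes rotation aligning bootstrap design saliences to the originals
procrustes_rotation <- function(Ub, U) {
  s <- svd(crossprod(Ub, U))
  s$u %*% t(s$v)
}

#' Bootstrap ratios for salience reliability
#'
#' Subjects are resampled with replacement within each rating class; the full
#' preparation (impute, z-score, group means, centering) and SVD are re-run
#' per resample. Bootstrap saliences are aligned to the original solution by
#' orthogonal Procrustes rotation of the design saliences (axis flips and
#' rotations between resamples are not meaningful). The bootstrap ratio (BSR)
#' of an IDP is its original salience divided by the element-wise standard
#' deviation of the aligned bootstrap saliences; under approximate normality
#' it reads as a Z-score, with |BSR| >= 2 conventionally deemed reliable.
#' Elements with zero bootstrap SE get an infinite BSR (flagged, not an
#' error).
#'
#' @inheritParams pls_prepare
#' @param n_boot number of bootstrap resamples (default 500).
#' @param seed integer seed.
#' @param align "procrustes" (default) or "sign" (per-LV sign matching only).
#' @return List with `bootstrap_ratios` (p x L), `se` (p x L), `n_boot`.
#' @export
bootstrap_ratios <- function(idps, ratings, n_boot = 500L, seed = 1L,
                             align = c("procrustes", "sign")) {
  align <- match.arg(align)
  idps <- as.matrix(idps)
  f <- check_ratings(ratings)
  obs <- pls_svd(pls_prepare(idps, ratings))
  L <- length(obs$singular_values)
  p <- ncol(idps)
  by_group <- split(seq_along(f), f)
  set.seed(seed)
  acc <- array(NA_real_, dim = c(p, L, n_boot))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(by_group, function(i)
      i[sample.int(length(i), length(i), replace = TRUE)]), use.names = FALSE)
    Zb <- zscore_cols(impute_col_median(idps[idx, , drop = FALSE]))
    Mb <- group_center(Zb, f[idx])
    sb <- svd(Mb, nu = L, nv = L)
    Ub <- sb$u; Vb <- sb$v
    if (align == "procrustes") {
      R <- procrustes_rotation(Ub, obs$design_saliences)
      Vb <- Vb %*% R
    } else {
      for (l in seq_len(L))
        if (sum(Ub[, l] * obs$design_saliences[, l]) < 0) Vb[, l] <- -Vb[, l]
    }
    acc[, , b] <- Vb
  }
  se <- apply(acc, c(1L, 2L), stats::sd)
  bsr <- obs$saliences / se
  bsr[se == 0] <- sign(obs$saliences[se == 0]) * Inf
  dimnames(bsr) <- dimnames(se) <- dimnames(obs$saliences)
  list(bootstrap_ratios = bsr, se = se, n_boot = as.integer(n_boot))
}

#' Fit the full PLS QC-validation model
#'
#' Runs [pls_prepare()], [pls_svd()], [permutation_test()] and
#' [bootstrap_ratios()] with one seed and bundles the results.
#'
#' @inheritParams pls_prepare
#' @param n_perm permutations for significance (default 1000).
#' @param n_boot bootstrap resamples for reliability (default 500).
#' @param seed integer seed controlling both resampling streams.
#' @param statistic permutation statistic, see [permutation_test()].
#' @return Object of class `pls_model`: `saliences`, `design_saliences`,
#'   `singular_values`, `pct_covariance`, `perm_p`, `bootstrap_ratios`, `se`,
#'   `groups`, `group_sizes`, `n_permutations`, `n_bootstrap`, `seed`.
#' @export
pls_qc <- function(idps, ratings, n_perm = 1000L, n_boot = 500L, seed = 1L,
                   statistic = c("per_lv", "max")) {
  statistic <- match.arg(statistic)
  M <- pls_prepare(idps, ratings)
  fit <- pls_svd(M)
  perm <- permutation_test(idps, ratings, n_perm = n_perm, seed = seed,
                           statistic = statistic)
  boot <- bootstrap_ratios(idps, ratings, n_boot = n_boot, seed = seed + 1L)
  structure(c(fit,
              list(perm_p = perm$perm_p,
                   bootstrap_ratios = boot$bootstrap_ratios, se = boot$se,
                   groups = attr(M, "groups"),
                   group_sizes = attr(M, "group_sizes"),
                   n_permutations = as.integer(n_perm),
                   n_bootstrap = as.integer(n_boot),
                   seed = as.integer(seed))),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$singular_values), " latent variable(s), ",
      length(x$groups), " rating groups\n", sep = "")
  df <- data.frame(LV = seq_along(x$singular_values),
                   singular_value = signif(x$singular_values, 4),
                   pct_covariance = round(x$pct_covariance, 1),
                   perm_p = signif(x$perm_p, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' IDPs reliably expressing a latent variable
#'
#' @param model a `pls_model` from [pls_qc()].
#' @param lv latent-variable index (default 1).
#' @param threshold absolute bootstrap-ratio cutoff (default 2).
#' @return `data.frame` of reliable IDPs (`idp`, `salience`, `bsr`) sorted by
#'   |BSR| descending.
#' @export
reliable_idps <- function(model, lv = 1L, threshold = 2) {
  L <- length(model$singular_values)
  if (lv < 1L || lv > L) stop("'lv' must be between 1 and ", L)
  bsr <- model$bootstrap_ratios[, lv]
  sel <- which(abs(bsr) >= threshold)
  sel <- sel[order(abs(bsr[sel]), decreasing = TRUE)]
  nm <- rownames(model$saliences)
  if (is.null(nm)) nm <- paste0("idp_", seq_len(nrow(model$saliences)))
  data.frame(idp = nm[sel], salience = model$saliences[sel, lv],
             bsr = bsr[sel], row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a subject-by-IDP table with ratings
#'
#' TSV with one row per subject, an ordinal rating column, and the remaining
#' numeric columns treated as IDPs. An optional `subject` column is carried
#' through as row names.
#'
#' @param path TSV path.
#' @param rating_col rating column name (default "rating").
#' @return List with `idps` (matrix), `ratings`, `subjects`.
#' @export
read_idp_table <- function(path, rating_col = "rating") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!rating_col %in% names(df))
    stop("no '", rating_col, "' column in ", path)
  ratings <- df[[rating_col]]
  subjects <- if ("subject" %in% names(df)) as.character(df$subject)
              else as.character(seq_len(nrow(df)))
  drop <- c(rating_col, "subject")
  idps <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
  if (!is.numeric(idps)) stop("IDP columns must be numeric")
  rownames(idps) <- subjects
  list(idps = idps, ratings = ratings, subjects = subjects)
}

#' Write PLS results as TSV + JSON
#'
#' `saliences.tsv` holds per-IDP saliences, bootstrap SEs and ratios for each
#' LV; `pls_summary.json` holds singular values, covariance percentages and
#' permutation p-values.
#'
#' @param model a `pls_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pls_results <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- length(model$singular_values)
  nm <- rownames(model$saliences)
  if (is.null(nm)) nm <- paste0("idp_", seq_len(nrow(model$saliences)))
  out <- data.frame(idp = nm, stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    out[[paste0("salience_lv", l)]] <- model$saliences[, l]
    out[[paste0("se_lv", l)]] <- model$se[, l]
    out[[paste0("bsr_lv", l)]] <- model$bootstrap_ratios[, l]
  }
  utils::write.table(out, file.path(dir, "saliences.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(singular_values = model$singular_values,
         pct_covariance = model$pct_covariance,
         perm_p = model$perm_p,
         groups = model$groups, group_sizes = model$group_sizes,
         n_permutations = model$n_permutations,
         n_bootstrap = model$n_bootstrap, seed = model$seed),
    file.path(dir, "pls_summary.json"), digits = NA, auto_unbox = FALSE)
  invisible(dir)
}
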