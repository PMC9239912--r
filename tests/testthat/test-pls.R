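test_that("pls_prepare centers group means of z-scored columns", {
  # two groups with identical IDP means vanish after centering
  idps <- rbind(c(1, 10), c(3, 30), c(1, 10), c(3, 30))
  M <- pls_prepare(idps, c(1, 1, 2, 2))
  expect_equal(unname(M), matrix(0, 2, 2), ignore_attr = TRUE)

  # group means +1 / -1 on one z-scored IDP
  x <- c(2, 2, 0, 0)
  z <- (x - mean(x)) / stats::sd(x)
  M2 <- pls_prepare(matrix(x, ncol = 1), c(1, 1, 2, 2))
  gdiff <- mean(z[1:2])                 # = +gm after centering
  expect_equal(unname(M2), rbind(gdiff, -gdiff), ignore_attr = TRUE)

  # centering identity: columns of M average to zero
  set.seed(51)
  X <- matrix(stats::rnorm(60 * 5), 60, 5)
  r <- rep(1:3, each = 20)
  M3 <- pls_prepare(X, r)
  expect_equal(colMeans(M3), rep(0, 5), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(pls_prepare(X, rep(1, 60)), "2 rating groups")
  expect_error(pls_prepare(X, c(rep(1, 59), 2)), "fewer than 2")
})

test_that("missing IDP entries are median-imputed before z-scoring", {
  X <- matrix(c(1, 2, NA, 4, 10, 20, 30, 40), ncol = 2)
  Ximp <- X; Ximp[3, 1] <- stats::median(c(1, 2, 4))
  M <- pls_prepare(X, c(1, 1, 2, 2))
  M2 <- pls_prepare(Ximp, c(1, 1, 2, 2))
  expect_equal(M, M2)
  expect_error(pls_prepare(matrix(NA_real_, 4, 1), c(1, 1, 2, 2)),
               "entirely missing")
})

test_that("pls_svd solves the analytic 2x2 case and reconstructs", {
  M <- rbind(c(1, 0), c(-1, 0))
  fit <- pls_svd(M)
  expect_equal(fit$singular_values, sqrt(2), tolerance = 1e-12)
  expect_equal(unname(fit$saliences[, 1]), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(fit$design_saliences[, 1]),
               c(1 / sqrt(2), -1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(fit$pct_covariance, 100)

  zero <- pls_svd(matrix(0, 3, 4))
  expect_equal(zero$singular_values, rep(0, 2))

  set.seed(52)
  M2 <- matrix(stats::rnorm(5 * 9), 5, 9)
  M2 <- sweep(M2, 2, colMeans(M2))      # mimic centering rank loss
  fit2 <- pls_svd(M2)
  recon <- fit2$design_saliences %*% diag(fit2$singular_values) %*%
    t(fit2$saliences)
  expect_equal(unname(recon), unname(M2), tolerance = 1e-10)
  expect_equal(sum(fit2$pct_covariance), 100, tolerance = 1e-9)
  expect_true(all(diff(fit2$singular_values) <= 1e-12))
  # sign convention: strongest design loading positive per LV
  tops <- apply(fit2$design_saliences, 2, function(u) u[which.max(abs(u))])
  expect_true(all(tops > 0))

  expect_error(pls_svd(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("singular values are invariant to subject and column permutation", {
  set.seed(53)
  X <- matrix(stats::rnorm(80 * 6), 80, 6)
  r <- rep(1:4, each = 20)
  f1 <- pls_svd(pls_prepare(X, r))

  perm <- sample(80)
  f2 <- pls_svd(pls_prepare(X[perm, ], r[perm]))
  expect_equal(f2$singular_values, f1$singular_values, tolerance = 1e-10)

  cp <- sample(6)
  f3 <- pls_svd(pls_prepare(X[, cp], r))
  expect_equal(f3$singular_values, f1$singular_values, tolerance = 1e-10)
  expect_equal(abs(unname(f3$saliences)), abs(unname(f1$saliences[cp, ])),
               tolerance = 1e-8)
})

test_that("permutation p follows the add-one count formula and its bounds", {
  # overwhelming effect: observed s1 should beat every permutation
  sim <- make_idp_ratings(c(10, 10), planted_salience = c(1, 0, 0),
                          effect_size = 50, noise_sd = 0.1, seed = 54)
  out <- permutation_test(sim$idps, sim$ratings, n_perm = 200, seed = 55)
  expect_equal(out$perm_p[1], 1 / 201)

  # boundary: n_perm = 1 against a null dataset gives p in {1/2, 1}
  null <- make_idp_ratings(c(6, 6), planted_salience = c(1, 1),
                           effect_size = 0, seed = 56)
  o1 <- permutation_test(null$idps, null$ratings, n_perm = 1, seed = 57)
  expect_true(all(o1$perm_p %in% c(0.5, 1)))

  o2 <- permutation_test(null$idps, null$ratings, n_perm = 50, seed = 58)
  expect_true(all(o2$perm_p >= 1 / 51 & o2$perm_p <= 1))
  # reproducible under a fixed seed
  o3 <- permutation_test(null$idps, null$ratings, n_perm = 50, seed = 58)
  expect_identical(o2$perm_p, o3$perm_p)
  expect_error(permutation_test(null$idps, rep(1, 12), n_perm = 10),
               "2 rating groups")
})

test_that("bootstrap ratios flag zero-variance saliences and stay aligned", {
  # deterministic data: identical subjects within group -> every resample
  # reproduces the same M, SE = 0, BSR flagged infinite
  X <- rbind(matrix(rep(c(1, 0), each = 4), 4, 2),
             matrix(rep(c(-1, 0), each = 4), 4, 2))
  r <- rep(1:2, each = 4)
  suppressWarnings(out <- bootstrap_ratios(X, r, n_boot = 20, seed = 59))
  expect_true(all(out$se[1, ] == 0))
  expect_true(is.infinite(out$bootstrap_ratios[1, 1]))

  # two seeds agree in sign after alignment on a planted effect
  sim <- make_idp_ratings(c(30, 30, 30), planted_salience = c(1, -1, 0, 0),
                          effect_size = 2, seed = 60)
  b1 <- bootstrap_ratios(sim$idps, sim$ratings, n_boot = 100, seed = 61)
  b2 <- bootstrap_ratios(sim$idps, sim$ratings, n_boot = 100, seed = 62)
  expect_equal(sign(b1$bootstrap_ratios[1:2, 1]),
               sign(b2$bootstrap_ratios[1:2, 1]))
  expect_error(bootstrap_ratios(X, c(1, rep(2, 7)), n_boot = 5),
               "fewer than 2")
})

test_that("reliable_idps thresholds and orders by |BSR|", {
  model <- structure(list(
    singular_values = c(2, 1),
    saliences = matrix(c(0.5, -0.6, 0.1, 0, 0, 0), ncol = 2,
                       dimnames = list(c("a", "b", "c"), NULL)),
    bootstrap_ratios = matrix(c(2.5, -3.1, 0.4, 0, 0, 0), ncol = 2,
                              dimnames = list(c("a", "b", "c"), NULL))),
    class = "pls_model")
  top <- reliable_idps(model, lv = 1, threshold = 2)
  expect_equal(top$idp, c("b", "a"))
  expect_equal(nrow(reliable_idps(model, 1, threshold = 0)), 3)
  expect_equal(nrow(reliable_idps(model, 1, threshold = Inf)), 0)
  expect_error(reliable_idps(model, lv = 5), "between 1 and")
})

test_that("pls_qc bundles a reproducible model and writes results", {
  sim <- make_idp_ratings(c(15, 15, 15), planted_salience = c(1, 0, 0, 0, 0),
                          effect_size = 1.5, seed = 63)
  m1 <- pls_qc(sim$idps, sim$ratings, n_perm = 50, n_boot = 50, seed = 64)
  m2 <- pls_qc(sim$idps, sim$ratings, n_perm = 50, n_boot = 50, seed = 64)
  expect_identical(m1$perm_p, m2$perm_p)
  expect_identical(m1$bootstrap_ratios, m2$bootstrap_ratios)
  expect_equal(length(m1$singular_values), 2)   # min(g - 1, p)
  expect_equal(sum(m1$pct_covariance), 100, tolerance = 1e-9)
  expect_true(all(m1$perm_p >= 1 / 51 & m1$perm_p <= 1))

  dir <- withr::local_tempdir()
  write_pls_results(m1, dir)
  expect_true(file.exists(file.path(dir, "saliences.tsv")))
  js <- jsonlite::read_json(file.path(dir, "pls_summary.json"))
  expect_equal(length(js$singular_values), 2)

  # IDP table round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(subject = seq_along(sim$ratings), rating = sim$ratings,
                   sim$idps, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_idp_table(tsv)
  expect_equal(unname(back$idps), unname(sim$idps), tolerance = 1e-6)
  expect_equal(back$ratings, sim$ratings)
})
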