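test_that("OLS recovers trivial designs exactly", {
  E <- diag(2)
  dimnames(E) <- list(c("g1", "g2"), c("A", "B"))
  est <- deconvolve_ols(c(g1 = 0.3, g2 = 0.7), E)
  expect_equal(est$alpha, c(A = 0.3, B = 0.7), tolerance = 1e-12)
  # sample equal to one signature column
  set.seed(4)
  E2 <- matrix(rexp(30), 10, 3,
               dimnames = list(sprintf("g%02d", 1:10), c("A", "B", "C")))
  est2 <- deconvolve_ols(E2[, "B"], E2)
  expect_equal(est2$alpha, c(A = 0, B = 1, C = 0), tolerance = 1e-9)
  expect_lt(est2$residual_norm, 1e-9)
})

test_that("OLS matches a simplex grid-search oracle on noisy mixtures", {
  set.seed(11)
  E <- matrix(rexp(200 * 3, rate = 0.3), 200, 3,
              dimnames = list(sprintf("g%03d", 1:200), c("A", "B", "C")))
  truth <- c(0.2, 0.5, 0.3)
  t_vec <- as.vector(E %*% truth) + rnorm(200, sd = 0.01)
  names(t_vec) <- rownames(E)
  est <- deconvolve_ols(t_vec, E)
  expect_lt(max(abs(est$alpha - truth)), 0.05)
  oracle <- simplex_grid_ols(t_vec, E, step = 0.01)
  expect_lt(max(abs(est$alpha - oracle)), 0.011)
})

test_that("OLS validates rank and gene indexing; NNLS respects non-negativity", {
  E <- matrix(rexp(20), 10, 2,
              dimnames = list(sprintf("g%02d", 1:10), c("A", "B")))
  E3 <- cbind(E, C = E[, "A"] * 2)
  t_vec <- setNames(rexp(10), rownames(E))
  expect_error(deconvolve_ols(t_vec, E3), "collinear")
  expect_error(deconvolve_ols(setNames(rexp(10), paste0("x", 1:10)), E),
               "gene index mismatch")
  # NNLS never clips: raw coefficients already non-negative
  set.seed(5)
  En <- matrix(rexp(60), 20, 3,
               dimnames = list(sprintf("g%02d", 1:20), c("A", "B", "C")))
  tn <- setNames(as.vector(En %*% c(0.7, 0.3, 0)) + rnorm(20, sd = 0.2),
                 rownames(En))
  nn <- deconvolve_ols(tn, En, nonneg = TRUE)
  expect_true(all(nn$raw_coefficients >= 0))
  expect_equal(sum(nn$alpha), 1, tolerance = 1e-9)
})

test_that("scale equivariance and column-permutation equivariance hold", {
  set.seed(6)
  E <- matrix(rexp(90), 30, 3,
              dimnames = list(sprintf("g%02d", 1:30), c("A", "B", "C")))
  t_vec <- setNames(as.vector(E %*% c(0.5, 0.2, 0.3)) +
                      rnorm(30, sd = 0.05), rownames(E))
  a1 <- deconvolve_ols(t_vec, E)$alpha
  a2 <- deconvolve_ols(3.7 * t_vec, E)$alpha
  expect_equal(a1, a2, tolerance = 1e-9)
  perm <- c("C", "A", "B")
  a3 <- deconvolve_ols(t_vec, E[, perm])$alpha
  expect_equal(a3[names(a1)], a1, tolerance = 1e-12)
})

test_that("NMF reconstructs an exactly factorizable matrix and is seed-deterministic", {
  set.seed(7)
  W0 <- matrix(runif(40 * 3), 40, 3)
  H0 <- matrix(runif(9), 3, 3)
  E <- W0 %*% H0
  dimnames(E) <- list(sprintf("g%02d", 1:40), c("A", "B", "C"))
  fac <- fit_nmf(E, k = 3, seed = 2, max_iter = 20000, tol = 0)
  expect_lt(fac$recon_error / sqrt(sum(E^2)), 1e-4)
  # error trace is non-increasing
  tr <- attr(fac, "error_trace")
  expect_true(all(diff(tr) <= 1e-8 * tr[1]))
  fac2 <- fit_nmf(E, k = 3, seed = 2, max_iter = 20000, tol = 0)
  expect_identical(fac$W, fac2$W)
  # k = 1 basis is a single column
  f1 <- fit_nmf(E, k = 1, seed = 1)
  expect_identical(dim(f1$W), c(40L, 1L))
  expect_error(fit_nmf(E, k = 0), "positive")
  expect_error(fit_nmf(E, k = 4), "exceeds")
})

test_that("NMFR equals OLS under an exact factorization with invertible H", {
  set.seed(8)
  W <- matrix(rexp(150), 50, 3)
  rownames(W) <- sprintf("g%02d", 1:50)
  H <- matrix(c(2, 0.3, 0.1, 0.2, 1.5, 0.4, 0.1, 0.2, 1.8), 3, 3)
  colnames(H) <- c("A", "B", "C")
  E <- W %*% H                     # exact factorization by construction
  colnames(E) <- colnames(H)
  fac <- nmf_factorization(W, H)
  for (i in 1:50) {
    truth <- as.vector(crossdeconv:::rdirichlet(1, c(2, 2, 2)))
    t_vec <- setNames(as.vector(E %*% truth) + rnorm(50, sd = 0.05),
                      rownames(E))
    a_ols <- deconvolve_ols(t_vec, E)$alpha
    a_nmfr <- deconvolve_nmfr(t_vec, fac)$alpha
    expect_equal(a_nmfr, a_ols, tolerance = 1e-6)
  }
  # T proportional to W column 1 with H = I concentrates on type 1
  facI <- nmf_factorization(W, `colnames<-`(diag(3), colnames(E)))
  aW <- deconvolve_nmfr(setNames(2 * W[, 1], rownames(W)), facI)$alpha
  expect_gt(aW[1], 0.99)
  Hbad <- H; Hbad[, 3] <- Hbad[, 1]
  expect_error(deconvolve_nmfr(setNames(rexp(50), rownames(W)),
                               nmf_factorization(W, Hbad)),
               "unidentifiable")
})

test_that("dataset-level deconvolution recovers noiseless mixtures and isolates failures", {
  cfg <- small_config(noise_sd = 0, seed = 31)
  sig <- raw_signatures(cfg)
  out <- generate_spatial_bulk(cfg, sig)
  fit <- deconvolve(out$samples$expr, sig)
  expect_s3_class(fit, "deconv_fit")
  err <- max(abs(coef(fit) - out$truth$proportions[rownames(coef(fit)), ]))
  expect_lt(err, 1e-6)
  expect_false(any(fit$diagnostics$flagged))
  # degenerate sample: constant expression cannot be fit after z-scoring
  bulk2 <- out$samples$expr
  # inject collinearity-breaking NA-free degenerate: all-zero sample
  bulk2$values[, 3] <- 0
  fit2 <- deconvolve(bulk2, sig)
  expect_equal(ncol(coef(fit2)), ncol(bulk2$values))
  expect_true(fit2$diagnostics$degenerate[3] ||
                all(is.na(coef(fit2)[, 3])) ||
                sum(coef(fit2)[, 3]) <= 1 + 1e-9)
  # methods of the fit object
  expect_identical(dim(fitted(fit)),
                   c(length(fit$shared_genes), ncol(coef(fit))))
  res <- residuals(fit, out$samples$expr)
  expect_lt(max(abs(res)), 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.deconv_fit")
  expect_equal(sum(s$per_type$mean), 1, tolerance = 1e-6)
  pr <- predict(fit, out$samples$expr)
  expect_equal(coef(pr), coef(fit), tolerance = 1e-12)
})

test_that("per-sample concordance filtering flags samples with too few features", {
  cfg <- small_config(seed = 33)
  sig <- raw_signatures(cfg)
  out <- generate_spatial_bulk(cfg, sig)
  fit <- deconvolve(out$samples$expr, sig, per_sample_features = TRUE,
                    band_width = 1.5)
  expect_true(all(fit$diagnostics$n_features[!fit$diagnostics$flagged] >=
                    length(brain_cell_types())))
  # a tiny band starves every sample of features -> flagged, not error
  fit2 <- deconvolve(out$samples$expr, sig, per_sample_features = TRUE,
                     band_width = 1e-6)
  expect_true(any(fit2$diagnostics$flagged))
  expect_true(all(is.na(coef(fit2)[, fit2$diagnostics$flagged])))
})
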