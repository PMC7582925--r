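#' Estimate cell-type proportions for one sample by least squares
#'
#' Fits the linear mixture model T = sum_i E_i a_i + e for one bulk
#' sample T over the signature columns E_i. With `nonneg = FALSE`
#' (default) the fit is ordinary least squares and negative
#' coefficients are clipped to zero afterwards; with `nonneg = TRUE`
#' non-negative least squares is solved directly. In both cases the
#' clipped coefficients are renormalized to sum to one so proportions
#' are comparable across samples.
#'
#' @param t_vec Named numeric vector: the bulk sample, indexed by the
#'   genes of `E`.
#' @param E A [signature_matrix()] (or plain genes x types matrix with
#'   dimnames) with >= 2 cell types and at least as many genes as
#'   types.
#' @param nonneg Solve NNLS instead of OLS-with-clipping.
#' @return An object of class `"proportion_estimate"`: list with
#'   `alpha` (named, >= 0, sums to 1 unless degenerate),
#'   `raw_coefficients`, `residual_norm` (L2 norm of the raw-fit
#'   residual), `method`, and `degenerate` (TRUE when every raw
#'   coefficient was <= 0).
#' @export
deconvolve_ols <- function(t_vec, E, nonneg = FALSE) {
  Em <- if (inherits(E, "signature_matrix")) E$values else E
  stopifnot(is.matrix(Em), ncol(Em) >= 2L, nrow(Em) >= ncol(Em))
  if (!is.null(names(t_vec))) {
    if (!all(rownames(Em) %in% names(t_vec)))
      stop("gene index mismatch between sample and signatures")
    t_vec <- t_vec[rownames(Em)]
  } else if (length(t_vec) != nrow(Em)) {
    stop("gene index mismatch between sample and signatures")
  }
  qrE <- qr(Em)
  if (qrE$rank < ncol(Em)) {
    dep <- colnames(Em)[qrE$pivot[(qrE$rank + 1L):ncol(Em)]]
    stop("rank-deficient signature matrix; collinear column(s): ",
         paste(dep, collapse = ", "))
  }
  if (nonneg) {
    fit <- pracma::lsqnonneg(Em, as.numeric(t_vec))
    raw <- stats::setNames(fit$x, colnames(Em))
    resid_norm <- sqrt(sum((t_vec - Em %*% raw)^2))
    method <- "NNLS"
  } else {
    raw <- stats::setNames(qr.coef(qrE, as.numeric(t_vec)), colnames(Em))
    resid_norm <- sqrt(sum(qr.resid(qrE, as.numeric(t_vec))^2))
    method <- "OLS"
  }
  clipped <- pmax(raw, 0)
  degenerate <- sum(clipped) <= 0
  alpha <- if (degenerate) clipped else clipped / sum(clipped)
  structure(list(alpha = alpha, raw_coefficients = raw,
                 residual_norm = resid_norm, method = method,
                 degenerate = degenerate),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("<proportion_estimate> method=%s residual_norm=%.4g%s\n",
              x$method, x$residual_norm,
              if (x$degenerate) " [degenerate]" else ""))
  print(round(x$alpha, 4))
  invisible(x)
}

#' Construct an NMF factorization object
#'
#' Wraps a basis W (genes x k) and loadings H (k x cell types), e.g.
#' from [fit_nmf()] or supplied directly.
#' @param W,H Non-negative matrices with matching inner dimension.
#' @param shift Per-column shift that was applied to make the source
#'   signature matrix non-negative (default zeros).
#' @param recon_error Frobenius reconstruction error of `W %*% H`
#'   against the (shifted) source matrix, if known.
#' @return List of class `"nmf_factorization"`.
#' @export
nmf_factorization <- function(W, H, shift = NULL, recon_error = NA_real_) {
  stopifnot(is.matrix(W), is.matrix(H), ncol(W) == nrow(H),
            all(W >= 0), all(H >= 0))
  if (is.null(shift)) shift <- stats::setNames(numeric(ncol(H)), colnames(H))
  structure(list(W = W, H = H, k = ncol(W), shift = shift,
                 recon_error = recon_error),
            class = "nmf_factorization")
}

#' Non-negative matrix factorization of a signature matrix
#'
#' Factorizes E ~ W H with k non-negative components by multiplicative
#' updates under the Frobenius objective, from a seeded random
#' initialization. If E has negative entries (e.g. z-scored
#' signatures), each column is first shifted up by its minimum; the
#' shift is recorded on the result. The reconstruction error is
#' non-increasing over iterations; iteration stops when the relative
#' error change falls below `tol` or after `max_iter` iterations.
#'
#' @param E A [signature_matrix()] or plain matrix (genes x types).
#' @param k Number of components (1 <= k <= number of cell types).
#' @param seed RNG seed for the initialization.
#' @param max_iter,tol Convergence controls.
#' @return An [nmf_factorization()] with an `error_trace` attribute.
#' @export
fit_nmf <- function(E, k, seed = 1L, max_iter = 1000L, tol = 1e-6) {
  Em <- if (inherits(E, "signature_matrix")) E$values else E
  if (k <= 0) stop("k must be positive")
  if (k > ncol(Em)) stop("k exceeds the number of cell types")
  shift <- pmin(apply(Em, 2L, min), 0)
  V <- sweep(Em, 2L, shift, "-")
  eps <- 1e-12
  trace <- numeric(0)
  out <- with_seed(seed, {
    W <- matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H <- matrix(stats::runif(k * ncol(V), 0.1, 1), k, ncol(V))
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      err <- sqrt(sum((V - W %*% H)^2))
      trace <- c(trace, err)
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
    list(W = W, H = H, err = err)
  })
  rownames(out$W) <- rownames(Em)
  colnames(out$H) <- colnames(Em)
  fac <- nmf_factorization(out$W, out$H, shift = -shift,
                           recon_error = out$err)
  attr(fac, "error_trace") <- trace
  fac
}

#' Estimate proportions through an NMF basis (NMF regression)
#'
#' Fits the bulk sample on the k-component basis W by least squares
#' (coefficients beta), then recovers cell-type proportions by solving
#' H alpha = beta in the least-squares sense, clipping negatives and
#' renormalizing to the simplex. With k equal to the number of cell
#' types, an exact factorization and invertible H, this reproduces the
#' OLS proportions.
#'
#' @param t_vec Named numeric vector over the genes of `fac$W`.
#' @param fac An [nmf_factorization()] fitted on the same gene set.
#' @return A `"proportion_estimate"` with `method = "NMFR"` and the
#'   basis coefficients in `$beta`.
#' @export
deconvolve_nmfr <- function(t_vec, fac) {
  stopifnot(inherits(fac, "nmf_factorization"))
  W <- fac$W; H <- fac$H
  if (!is.null(names(t_vec)) && !is.null(rownames(W))) {
    if (!all(rownames(W) %in% names(t_vec)))
      stop("gene index mismatch between sample and factorization")
    t_vec <- t_vec[rownames(W)]
  }
  if (qr(H)$rank < ncol(H))
    stop("unidentifiable proportions: H is rank-deficient")
  bfit <- stats::lm.fit(W, as.numeric(t_vec))
  beta <- bfit$coefficients
  resid_norm <- sqrt(sum(bfit$residuals^2))
  raw <- stats::setNames(stats::lm.fit(H, beta)$coefficients, colnames(H))
  clipped <- pmax(raw, 0)
  degenerate <- sum(clipped) <= 0
  alpha <- if (degenerate) clipped else clipped / sum(clipped)
  structure(list(alpha = alpha, raw_coefficients = raw, beta = beta,
                 residual_norm = resid_norm, method = "NMFR",
                 degenerate = degenerate),
            class = "proportion_estimate")
}

#' Deconvolve a whole dataset of bulk samples
#'
#' The central fitting function of the package: estimates cell-type
#' proportions for every sample of a bulk expression matrix against a
#' signature matrix, by OLS (default), NNLS, or NMF regression.
#' Optionally applies per-sample rank-concordance feature selection
#' before solving, as in the full cross-species workflow. Samples for
#' which fewer features survive than there are cell types are flagged
#' and reported as missing rather than aborting the run.
#'
#' @param bulk An `expr_matrix` of bulk samples (the workflow z-scores
#'   samples first; see [zscore_samples()]).
#' @param signatures A [signature_matrix()] on the same gene
#'   identifiers.
#' @param method `"ols"`, `"nnls"`, or `"nmfr"`.
#' @param per_sample_features Apply [concordance_select()] of every
#'   signature column against each sample (union of survivors) before
#'   solving.
#' @param band_width Concordance band when `per_sample_features` is
#'   TRUE.
#' @param k NMF components for `method = "nmfr"` (default: number of
#'   cell types).
#' @param seed Seed for the NMF initialization.
#' @return An object of class `"deconv_fit"` with components
#'   `proportions` (cell types x samples), `diagnostics` (data.frame:
#'   sample_id, n_features, residual_norm, degenerate, flagged),
#'   `signatures`, `method`, `call`.
#' @seealso [coef.deconv_fit()], [summary.deconv_fit()],
#'   [predict.deconv_fit()]
#' @export
deconvolve <- function(bulk, signatures,
                       method = c("ols", "nnls", "nmfr"),
                       per_sample_features = FALSE, band_width = 0.9,
                       k = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(bulk, "expr_matrix"),
            inherits(signatures, "signature_matrix"))
  shared <- intersect(bulk$gene_ids, signatures$gene_ids)
  if (length(shared) == 0L)
    stop("no shared genes between bulk and signatures")
  Em <- signatures$values[shared, , drop = FALSE]
  types <- colnames(Em)
  cts <- ncol(Em)
  if (is.null(k)) k <- cts
  fac <- if (method == "nmfr" && !per_sample_features)
    fit_nmf(Em, k = k, seed = seed) else NULL
  n <- length(bulk$sample_ids)
  props <- matrix(NA_real_, nrow = cts, ncol = n,
                  dimnames = list(types, bulk$sample_ids))
  diag_df <- data.frame(sample_id = bulk$sample_ids,
                        n_features = NA_integer_,
                        residual_norm = NA_real_,
                        degenerate = FALSE, flagged = FALSE,
                        stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    t_all <- bulk$values[shared, j]
    genes_j <- shared
    if (per_sample_features) {
      kept <- lapply(types, function(ct)
        concordance_select(Em[, ct], t_all, band_width = band_width))
      genes_j <- shared[sort(unique(unlist(kept)))]
    }
    if (length(genes_j) < cts) {
      diag_df$flagged[j] <- TRUE
      diag_df$n_features[j] <- length(genes_j)
      next
    }
    Ej <- Em[genes_j, , drop = FALSE]
    est <- tryCatch({
      switch(method,
             ols = deconvolve_ols(t_all[genes_j], Ej, nonneg = FALSE),
             nnls = deconvolve_ols(t_all[genes_j], Ej, nonneg = TRUE),
             nmfr = {
               fj <- if (is.null(fac)) fit_nmf(Ej, k = k, seed = seed)
                 else fac
               deconvolve_nmfr(t_all[genes_j], fj)
             })
    }, error = function(e) e)
    if (inherits(est, "error")) {
      diag_df$flagged[j] <- TRUE
      diag_df$n_features[j] <- length(genes_j)
      next
    }
    props[, j] <- est$alpha[types]
    diag_df$n_features[j] <- length(genes_j)
    diag_df$residual_norm[j] <- est$residual_norm
    diag_df$degenerate[j] <- est$degenerate
  }
  structure(list(proportions = props, diagnostics = diag_df,
                 signatures = signatures, shared_genes = shared,
                 method = method, call = match.call()),
            class = "deconv_fit")
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf("<deconv_fit> %s: %d samples x %d cell types (%d flagged)\n",
              toupper(x$method), ncol(x$proportions), nrow(x$proportions),
              sum(x$diagnostics$flagged)))
  invisible(x)
}

#' Extract the estimated proportion matrix
#' @param object A `deconv_fit`.
#' @param ... Unused.
#' @return Numeric matrix, cell types x samples.
#' @export
coef.deconv_fit <- function(object, ...) object$proportions

#' Summarize a deconvolution fit
#' @param object A `deconv_fit`.
#' @param ... Unused.
#' @return A list of class `"summary.deconv_fit"` with per-type
#'   proportion summaries and diagnostic counts.
#' @export
summary.deconv_fit <- function(object, ...) {
  p <- object$proportions
  per_type <- data.frame(
    cell_type = rownames(p),
    mean = rowMeans(p, na.rm = TRUE),
    sd = apply(p, 1L, stats::sd, na.rm = TRUE),
    min = apply(p, 1L, min, na.rm = TRUE),
    max = apply(p, 1L, max, na.rm = TRUE),
    row.names = NULL)
  out <- list(method = object$method, n_samples = ncol(p),
              n_flagged = sum(object$diagnostics$flagged),
              mean_residual_norm =
                mean(object$diagnostics$residual_norm, na.rm = TRUE),
              per_type = per_type)
  class(out) <- "summary.deconv_fit"
  out
}

#' @export
print.summary.deconv_fit <- function(x, ...) {
  cat(sprintf("Deconvolution by %s over %d samples (%d flagged)\n",
              toupper(x$method), x$n_samples, x$n_flagged))
  cat(sprintf("Mean residual L2 norm: %.4g\n", x$mean_residual_norm))
  print(transform(x$per_type, mean = round(mean, 4), sd = round(sd, 4),
                  min = round(min, 4), max = round(max, 4)))
  invisible(x)
}

#' Reconstructed expression under the fitted proportions
#' @param object A `deconv_fit`.
#' @param ... Unused.
#' @return Genes x samples matrix E alpha (NA columns for flagged
#'   samples).
#' @export
fitted.deconv_fit <- function(object, ...) {
  E <- object$signatures$values[object$shared_genes, , drop = FALSE]
  E %*% object$proportions
}

#' Residuals of a deconvolution fit
#'
#' Requires the bulk matrix the model was fitted to.
#' @param object A `deconv_fit`.
#' @param bulk The `expr_matrix` passed to [deconvolve()].
#' @param ... Unused.
#' @return Genes x samples residual matrix on the shared gene set.
#' @export
residuals.deconv_fit <- function(object, bulk, ...) {
  stopifnot(inherits(bulk, "expr_matrix"))
  bulk$values[object$shared_genes, , drop = FALSE] - fitted(object)
}

#' Deconvolve new samples with the signatures of an existing fit
#' @param object A `deconv_fit`.
#' @param newdata An `expr_matrix` of new bulk samples.
#' @param ... Passed on to [deconvolve()].
#' @return A new `deconv_fit`.
#' @export
predict.deconv_fit <- function(object, newdata, ...) {
  deconvolve(newdata, object$signatures, method = object$method, ...)
}

#' Plot a deconvolution fit
#'
#' Scatter of the samples in the first two principal components of the
#' estimated proportion matrix, optionally colored by a per-sample
#' grouping (e.g. major brain region).
#' @param x A `deconv_fit`.
#' @param color_by Optional factor/character vector, one per sample.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.deconv_fit <- function(x, color_by = NULL, ...) {
  p <- x$proportions
  ok <- colSums(is.na(p)) == 0
  pc <- stats::prcomp(t(p[, ok, drop = FALSE]))
  col <- 1L
  if (!is.null(color_by)) col <- as.integer(as.factor(color_by[ok])) + 1L
  graphics::plot(pc$x[, 1L], pc$x[, 2L], col = col,
                 xlab = "PC1", ylab = "PC2", pch = 19, ...)
  if (!is.null(color_by))
    graphics::legend("topright", legend = levels(as.factor(color_by[ok])),
                     col = seq_len(nlevels(as.factor(color_by[ok]))) + 1L,
                     pch = 19, cex = 0.8)
  invisible(pc)
}
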