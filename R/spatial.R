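#' Nearest-neighbor maximum smoothing of proportion maps
#'
#' For every sample and cell type, replaces the proportion by the
#' maximum over the `n_neighbors` spatially closest samples (3-D
#' Euclidean distance, the sample itself included). Improves the
#' visibility of sparsely detected cell types; the output is
#' intentionally not renormalized (visualization-oriented), so smoothed
#' values are >= the originals.
#'
#' @param props Numeric matrix, cell types x samples.
#' @param coords Numeric matrix, samples x 3 (same sample order).
#' @param n_neighbors Neighborhood size including self (default 5).
#' @return Smoothed matrix of the same shape.
#' @export
smooth_proportions <- function(props, coords, n_neighbors = 5) {
  stopifnot(is.matrix(props), is.matrix(coords),
            ncol(props) == nrow(coords), ncol(coords) == 3L,
            all(is.finite(coords)))
  n <- ncol(props)
  if (n < n_neighbors)
    stop("fewer samples than n_neighbors")
  d <- as.matrix(stats::dist(coords))
  out <- props
  for (j in seq_len(n)) {
    nb <- order(d[j, ])[seq_len(n_neighbors)]
    out[, j] <- apply(props[, nb, drop = FALSE], 1L, max)
  }
  out
}

#' PCA + K-means clustering of samples by cell-type composition
#'
#' Projects samples onto principal components of the proportion matrix
#' and clusters the scores with K-means (k = 3 by default, matching the
#' three major brain regions), with seeded multi-restart
#' initialization.
#'
#' @param props Numeric matrix, cell types x samples.
#' @param k Number of clusters (default 3).
#' @param seed RNG seed for the K-means restarts.
#' @param nstart Number of K-means restarts (default 10).
#' @return List with `labels` (integer cluster per sample), `pca`
#'   (samples x 2 matrix of the first two PC scores, for plotting), and
#'   `kmeans` (the full [stats::kmeans()] object).
#' @export
cluster_regions <- function(props, k = 3, seed = 1L, nstart = 10) {
  stopifnot(is.matrix(props))
  n <- ncol(props)
  if (k > n) stop("k exceeds the number of samples")
  x <- t(props)
  if (all(apply(x, 2L, stats::sd) == 0))
    stop("no variation: all samples identical")
  pc <- stats::prcomp(x)
  scores <- pc$x
  km <- with_seed(seed,
                  stats::kmeans(scores, centers = k, nstart = nstart))
  p2 <- scores[, seq_len(min(2L, ncol(scores))), drop = FALSE]
  list(labels = stats::setNames(km$cluster, colnames(props)),
       pca = p2, kmeans = km)
}

#' Score clusters against true region labels
#'
#' Chooses the bijective cluster-to-region assignment maximizing
#' accuracy over all k! permutations (exact for k = 3), then reports
#' overall accuracy and per-region sensitivity (TP / (TP + FN)) and
#' specificity (TN / (TN + FP)).
#'
#' @param labels Integer/character cluster labels.
#' @param true_regions Character region labels, same length.
#' @return List of class `"cluster_score"`: `accuracy`, `sensitivity`
#'   and `specificity` (named per region), and `assignment` (cluster ->
#'   region).
#' @export
score_clusters <- function(labels, true_regions) {
  if (length(labels) != length(true_regions))
    stop("labels and true_regions differ in length")
  regions <- sort(unique(true_regions))
  cl <- sort(unique(as.character(labels)))
  if (length(cl) > length(regions))
    stop("more clusters than region levels")
  perms <- perms_of(regions)
  best_acc <- -1; best_map <- NULL
  for (p in perms) {
    map <- stats::setNames(p[seq_along(cl)], cl)
    acc <- mean(map[as.character(labels)] == true_regions)
    if (acc > best_acc) { best_acc <- acc; best_map <- map }
  }
  pred <- best_map[as.character(labels)]
  sens <- spec <- stats::setNames(numeric(length(regions)), regions)
  for (r in regions) {
    tp <- sum(pred == r & true_regions == r)
    fn <- sum(pred != r & true_regions == r)
    tn <- sum(pred != r & true_regions != r)
    fp <- sum(pred == r & true_regions != r)
    sens[r] <- tp / (tp + fn)
    spec[r] <- tn / (tn + fp)
  }
  structure(list(accuracy = best_acc, sensitivity = sens,
                 specificity = spec, assignment = best_map),
            class = "cluster_score")
}

perms_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in perms_of(x[-i])) out <- c(out, list(c(x[i], p)))
  out
}

#' @export
print.cluster_score <- function(x, ...) {
  cat(sprintf("<cluster_score> accuracy %.3f\n", x$accuracy))
  print(round(rbind(sensitivity = x$sensitivity,
                    specificity = x$specificity), 3))
  invisible(x)
}

#' MANOVA confounder analysis of clustering scores
#'
#' Fits a multivariate analysis of variance with sensitivity and
#' specificity as joint responses and the supplied factors (input
#' dataset, donor, region) as predictors; reports a Pillai-trace
#' p-value per factor.
#'
#' @param scores data.frame with numeric columns `sensitivity`,
#'   `specificity` and the factor columns named in `factors`.
#' @param factors Character vector of factor column names (default
#'   `c("dataset", "donor", "region")`).
#' @return Named numeric vector of p-values, one per factor.
#' @export
manova_confounders <- function(scores,
                               factors = c("dataset", "donor", "region")) {
  stopifnot(all(c("sensitivity", "specificity", factors) %in%
                  names(scores)))
  for (f in factors) {
    scores[[f]] <- as.factor(scores[[f]])
    if (nlevels(scores[[f]]) < 2L)
      stop("factor '", f, "' has a single level")
  }
  if (nrow(scores) <= sum(vapply(factors,
                                 function(f) nlevels(scores[[f]]) - 1L,
                                 integer(1))) + 2L)
    stop("too few replicates for MANOVA")
  fml <- stats::as.formula(paste("cbind(sensitivity, specificity) ~",
                                 paste(factors, collapse = " + ")))
  fit <- stats::manova(fml, data = scores)
  sm <- tryCatch(summary(fit, test = "Pillai"),
                 error = function(e)
                   stop("singular within-group covariance: ",
                        conditionMessage(e)))
  tab <- sm$stats
  p <- tab[factors, "Pr(>F)"]
  stats::setNames(as.numeric(p), factors)
}

# Per-donor location-mean composition vectors over shared locations,
# concatenated across cell types.
donor_location_means <- function(props, meta) {
  donors <- unique(meta$donor)
  shared <- Reduce(intersect,
                   lapply(donors, function(d)
                     unique(meta$location[meta$donor == d])))
  if (length(shared) == 0L) stop("no shared anatomic locations")
  mats <- lapply(donors, function(d) {
    m <- vapply(shared, function(loc) {
      idx <- meta$donor == d & meta$location == loc
      rowMeans(props[, meta$sample_id[idx], drop = FALSE])
    }, numeric(nrow(props)))
    m  # types x locations
  })
  names(mats) <- donors
  mats
}

#' Donor-to-donor consistency of spatial composition maps
#'
#' For each donor, the mean composition per anatomic location is
#' computed over that donor's samples (and, when several estimate sets
#' are supplied, averaged across them); donors are then compared by
#' Pearson correlation over the concatenated (location x cell type)
#' vector. A negative control is built by randomly selecting a donor,
#' randomly reordering that donor's locations, and averaging the
#' shuffled donor's PCC with every real donor; the shuffle is repeated
#' `n_shuffles` times.
#'
#' @param props Proportion matrix (cell types x samples) or list of
#'   such matrices on the same samples (one per input reference set).
#' @param meta data.frame with columns `sample_id`, `location`,
#'   `donor`.
#' @param n_shuffles Number of random-donor shuffles (default 100).
#' @param seed RNG seed.
#' @return List with `pcc` (donors x donors correlation matrix),
#'   `mean_real_pcc` (mean off-diagonal PCC), and `random_pcc`
#'   (numeric, one mean control PCC per shuffle).
#' @export
donor_consistency <- function(props, meta, n_shuffles = 100, seed = 1L) {
  if (is.list(props) && !is.matrix(props))
    props <- Reduce(`+`, props) / length(props)
  donors <- unique(meta$donor)
  if (length(donors) < 2L) stop("need >= 2 donors")
  mats <- donor_location_means(props, meta)
  if (ncol(mats[[1L]]) < 2L)
    stop("need >= 2 shared anatomic locations")
  vecs <- vapply(mats, as.vector, numeric(length(mats[[1L]])))
  pcc <- stats::cor(vecs)
  off <- pcc[upper.tri(pcc)]
  random_pcc <- with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    d <- sample(donors, 1L)
    m <- mats[[d]][, sample(ncol(mats[[d]]))]
    v <- as.vector(m)
    mean(vapply(donors, function(o) stats::cor(v, as.vector(mats[[o]])),
                numeric(1))[donors != d])
  }, numeric(1)))
  list(pcc = pcc, mean_real_pcc = mean(off), random_pcc = random_pcc)
}

#' Cross-dataset cell-type correlations with BH-FDR
#'
#' Compares proportion estimates of the same bulk samples obtained from
#' different input reference datasets. Two columns are comparable
#' ("same type") when the sets of canonical cell types they cover are
#' identical under `type_map` (so a merged "cortical neuron" column is
#' comparable only to another merged column). For every dataset pair
#' and every covered-set present in either dataset, the Pearson
#' correlation across samples is computed when both sides have the
#' column, and reported as missing otherwise. BH false-discovery-rate
#' q-values are computed across all computed correlations.
#'
#' @param estimates Named list of proportion matrices (cell types x
#'   samples) sharing sample ids.
#' @param type_map Named list (per dataset) of named lists: column name
#'   -> character vector of canonical types covered. Defaults to the
#'   identity (each column covers itself).
#' @return data.frame: dataset_a, dataset_b, cell_type, pcc, p, q,
#'   missing.
#' @export
crossdataset_correlations <- function(estimates, type_map = NULL) {
  stopifnot(is.list(estimates), length(estimates) >= 2L,
            !is.null(names(estimates)))
  ds <- names(estimates)
  shared <- Reduce(intersect, lapply(estimates, colnames))
  if (length(shared) == 0L) stop("no shared samples across estimates")
  covered <- lapply(ds, function(d) {
    types <- rownames(estimates[[d]])
    tm <- type_map[[d]]
    lapply(stats::setNames(types, types), function(t)
      sort(if (!is.null(tm) && !is.null(tm[[t]])) tm[[t]] else t))
  })
  names(covered) <- ds
  key <- function(set) paste(set, collapse = " + ")
  rows <- list()
  for (i in seq_len(length(ds) - 1L)) for (j in (i + 1L):length(ds)) {
    keys_i <- vapply(covered[[i]], key, "")
    keys_j <- vapply(covered[[j]], key, "")
    for (kk in union(keys_i, keys_j)) {
      ti <- names(keys_i)[keys_i == kk]
      tj <- names(keys_j)[keys_j == kk]
      if (length(ti) == 1L && length(tj) == 1L) {
        x <- estimates[[i]][ti, shared]
        y <- estimates[[j]][tj, shared]
        ct <- tryCatch(stats::cor.test(x, y), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_a = ds[i], dataset_b = ds[j], cell_type = kk,
          pcc = if (is.null(ct)) NA_real_ else unname(ct$estimate),
          p = if (is.null(ct)) NA_real_ else ct$p.value,
          missing = is.null(ct), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          dataset_a = ds[i], dataset_b = ds[j], cell_type = kk,
          pcc = NA_real_, p = NA_real_, missing = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out
}
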