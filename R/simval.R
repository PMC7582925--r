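#' Stratified 50/50 cell split
#'
#' Splits an annotated cell population into two disjoint halves,
#' stratified by cell type: round(fraction * n_t) cells of each type go
#' to the test side. Used to build pseudo-bulk mixtures on one half
#' while signatures come from the other.
#'
#' @param annot data.frame with columns `cell_id`, `cell_type`.
#' @param fraction Fraction of each type assigned to the test side
#'   (default 0.5).
#' @param seed RNG seed.
#' @return List with `train` and `test` character vectors of cell ids.
#' @export
split_cells <- function(annot, fraction = 0.5, seed = 1L) {
  counts <- table(annot$cell_type)
  if (any(counts < 2L))
    stop("cell type(s) with a single cell: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  test <- with_seed(seed, unlist(lapply(names(counts), function(t) {
    ids <- annot$cell_id[annot$cell_type == t]
    n_test <- round(fraction * length(ids))
    sample(ids, n_test)
  }), use.names = FALSE))
  train <- setdiff(annot$cell_id, test)
  if (length(test) == 0L || length(train) == 0L)
    stop("empty side: fraction leaves one half without cells")
  list(train = train, test = test)
}

#' Aggregate cells into a pseudo-bulk sample
#'
#' @param ref An `expr_matrix` of single cells.
#' @param cells Cell ids to aggregate.
#' @param annot data.frame with columns `cell_id`, `cell_type`.
#' @return List with `t_vec` (named per-gene mean over the cells) and
#'   `alpha` (named true composition: per-type cell-count fraction).
#' @export
make_pseudobulk <- function(ref, cells, annot) {
  stopifnot(inherits(ref, "expr_matrix"))
  if (length(cells) == 0L) stop("no cells to aggregate")
  if (!all(cells %in% ref$sample_ids))
    stop("unknown cell id(s): ",
         paste(utils::head(setdiff(cells, ref$sample_ids), 3),
               collapse = ", "))
  t_vec <- rowMeans(ref$values[, cells, drop = FALSE])
  ct <- annot$cell_type[match(cells, annot$cell_id)]
  tab <- table(factor(ct, levels = unique(annot$cell_type)))
  alpha <- stats::setNames(as.vector(tab) / length(cells), names(tab))
  list(t_vec = t_vec, alpha = alpha)
}

# Draw one mixture from the test half: a random number of cells per
# type (uniform over 1..available) so compositions vary across
# mixtures.
draw_mixture_cells <- function(annot, test_ids) {
  types <- unique(annot$cell_type)
  unlist(lapply(types, function(t) {
    ids <- intersect(annot$cell_id[annot$cell_type == t], test_ids)
    n <- sample.int(length(ids), 1L)
    sample(ids, n)
  }), use.names = FALSE)
}

#' Pseudo-bulk simulation validation of the deconvolution methods
#'
#' For each repeat: split the annotated cells 50/50 (stratified),
#' build cell-type signatures on the train half, draw `n_mixtures`
#' pseudo-bulk mixtures with varying composition from the test half,
#' estimate proportions with each method, and record the per-type
#' Pearson correlation between true and estimated proportions across
#' the mixtures. With two methods, a paired Wilcoxon signed-rank test
#' over the per-repeat mean PCCs compares them.
#'
#' @param ref An `expr_matrix` of single cells (raw counts).
#' @param annot data.frame with columns `cell_id`, `cell_type`.
#' @param methods Character subset of `c("ols", "nnls", "nmfr")`.
#' @param zscore Follow the workflow's normalization: z-score the
#'   reference cells before building signatures and z-score every
#'   pseudo-bulk mixture before fitting (default TRUE). Set FALSE to
#'   validate on the raw count scale.
#' @param n_repeats Number of split repeats (>= 2).
#' @param n_mixtures Mixtures per repeat (>= 3; PCC needs >= 3 points).
#' @param genes Optional gene subset for the signatures.
#' @param seed RNG seed.
#' @param max_attempts Re-draws allowed when a split loses a type.
#' @return List of class `"simval_run"` with `pcc` (data.frame: repeat,
#'   method, cell_type, pcc), `per_repeat_mean` (matrix repeats x
#'   methods), and `comparison_p` (paired Wilcoxon p, or NA with a
#'   single method).
#' @export
run_validation <- function(ref, annot, methods = c("ols", "nmfr"),
                           n_repeats = 100, n_mixtures = 30,
                           genes = ref$gene_ids, seed = 1L,
                           zscore = TRUE, max_attempts = 10L) {
  stopifnot(n_repeats >= 2, n_mixtures >= 3)
  methods <- match.arg(methods, c("ols", "nnls", "nmfr"),
                       several.ok = TRUE)
  types <- unique(annot$cell_type)
  sig_ref <- if (zscore) suppressWarnings(zscore_samples(ref)) else ref
  zvec <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  rows <- vector("list", n_repeats * length(methods))
  per_repeat <- matrix(NA_real_, n_repeats, length(methods),
                       dimnames = list(NULL, methods))
  ri <- 0L
  for (rep_i in seq_len(n_repeats)) {
    res <- with_seed(seed + rep_i, {
      split <- NULL
      for (att in seq_len(max_attempts)) {
        sp <- split_cells(annot, 0.5, seed = seed + rep_i * 1000L + att)
        tr_t <- unique(annot$cell_type[annot$cell_id %in% sp$train])
        te_t <- unique(annot$cell_type[annot$cell_id %in% sp$test])
        if (setequal(tr_t, types) && setequal(te_t, types)) {
          split <- sp; break
        }
      }
      if (is.null(split))
        stop("a cell type kept vanishing from one split side")
      sig <- build_signatures(sig_ref,
                              annot[annot$cell_id %in% split$train, ],
                              genes = genes)
      Em <- sig$values[, types, drop = FALSE]
      mix <- lapply(seq_len(n_mixtures), function(i) {
        cells <- draw_mixture_cells(annot, split$test)
        m <- make_pseudobulk(ref, cells, annot)
        if (zscore) m$t_vec <- stats::setNames(zvec(m$t_vec),
                                               names(m$t_vec))
        m
      })
      true_m <- vapply(mix, function(m) m$alpha[types],
                       numeric(length(types)))
      fac <- if ("nmfr" %in% methods)
        fit_nmf(Em, k = ncol(Em), seed = seed + rep_i) else NULL
      est <- lapply(methods, function(meth) {
        vapply(mix, function(m) {
          a <- switch(meth,
                      ols = deconvolve_ols(m$t_vec[rownames(Em)], Em)$alpha,
                      nnls = deconvolve_ols(m$t_vec[rownames(Em)], Em,
                                            nonneg = TRUE)$alpha,
                      nmfr = deconvolve_nmfr(m$t_vec[rownames(Em)],
                                             fac)$alpha)
          a[types]
        }, numeric(length(types)))
      })
      names(est) <- methods
      list(true_m = true_m, est = est)
    })
    for (mi in seq_along(methods)) {
      pcc <- vapply(seq_along(types), function(ti)
        suppressWarnings(stats::cor(res$true_m[ti, ],
                                    res$est[[mi]][ti, ])),
        numeric(1))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(rep = rep_i, method = methods[mi],
                               cell_type = types, pcc = pcc,
                               stringsAsFactors = FALSE)
      per_repeat[rep_i, mi] <- mean(pcc, na.rm = TRUE)
    }
  }
  comparison_p <- NA_real_
  if (length(methods) >= 2L)
    comparison_p <- stats::wilcox.test(per_repeat[, 1L], per_repeat[, 2L],
                                       paired = TRUE, exact = FALSE)$p.value
  structure(list(pcc = do.call(rbind, rows), per_repeat_mean = per_repeat,
                 methods = methods, comparison_p = comparison_p),
            class = "simval_run")
}

#' @export
print.simval_run <- function(x, ...) {
  cat("<simval_run>\n")
  for (m in x$methods)
    cat(sprintf("  %s: median per-type PCC %.3f\n", m,
                stats::median(x$pcc$pcc[x$pcc$method == m], na.rm = TRUE)))
  if (!is.na(x$comparison_p))
    cat(sprintf("  paired Wilcoxon p (%s vs %s): %.3g\n",
                x$methods[1L], x$methods[2L], x$comparison_p))
  invisible(x)
}
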