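#' Construct a mouse-human homolog map
#'
#' @param pairs data.frame with columns `mouse_gene`, `human_gene`.
#' @param policy `"one-to-one"` (default; any gene appearing in more
#'   than one pair is an error) or `"first-match"` (later pairs for an
#'   already-seen mouse gene are dropped).
#' @return A list of class `"homolog_map"`.
#' @export
homolog_map <- function(pairs, policy = c("one-to-one", "first-match")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(pairs),
            all(c("mouse_gene", "human_gene") %in% names(pairs)))
  pairs <- pairs[, c("mouse_gene", "human_gene")]
  pairs[] <- lapply(pairs, as.character)
  if (policy == "one-to-one") {
    dup <- c(pairs$mouse_gene[duplicated(pairs$mouse_gene)],
             pairs$human_gene[duplicated(pairs$human_gene)])
    if (length(dup))
      stop("ambiguous homolog: ", paste(unique(dup), collapse = ", "))
  } else {
    pairs <- pairs[!duplicated(pairs$mouse_gene), ]
  }
  structure(list(pairs = pairs, policy = policy), class = "homolog_map")
}

#' Read a homolog map from a two-column TSV
#' @param path TSV with columns mouse_symbol, human_symbol (header
#'   optional names; first column mouse, second human).
#' @param policy See [homolog_map()].
#' @return A `homolog_map`.
#' @export
read_homolog_map <- function(path, policy = "one-to-one") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("mouse_gene", "human_gene")
  homolog_map(df, policy = policy)
}

#' Noise-model gene selection
#'
#' Fits an ordinary least-squares regression of log(CV) on log(mean)
#' across expressed genes of a single-cell count matrix and selects
#' genes lying above the fitted trend (positive residual), i.e. genes
#' more variable than expected at their expression level -- the
#' standard mean-CV noise-model selection for scRNA-seq.
#'
#' @param ref An `expr_matrix` of raw counts (cells in columns).
#' @param residual_threshold Keep genes with residual strictly greater
#'   than this (default 0).
#' @return List with `genes` (selected gene ids) and `fit` (a
#'   `noise_model_fit`: per-gene mean, cv, residual, and the regression
#'   slope/intercept).
#' @export
noise_model_select <- function(ref, residual_threshold = 0) {
  stopifnot(inherits(ref, "expr_matrix"))
  if (ref$state != "raw")
    stop("noise model requires raw counts")
  v <- ref$values
  mu <- rowMeans(v)
  sdv <- sqrt(rowMeans(sweep(v, 1L, mu, "-")^2))
  expressed <- mu > 0 & sdv > 0
  if (sum(expressed) == 0L) stop("no expressed genes")
  if (sum(expressed) < 10L)
    warning("fewer than 10 expressed genes; noise-model fit is unstable")
  cv <- sdv[expressed] / mu[expressed]
  lx <- log(mu[expressed]); ly <- log(cv)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  resid <- stats::setNames(rep(NA_real_, nrow(v)), ref$gene_ids)
  resid[expressed] <- fit$residuals
  genes <- ref$gene_ids[expressed][fit$residuals > residual_threshold]
  fit_obj <- structure(list(
    mean = stats::setNames(mu, ref$gene_ids),
    cv = stats::setNames(ifelse(mu > 0, sdv / mu, NA_real_), ref$gene_ids),
    residual = resid,
    intercept = unname(fit$coefficients[1L]),
    slope = unname(fit$coefficients[2L])), class = "noise_model_fit")
  list(genes = genes, fit = fit_obj)
}

# Vectorized one-way F statistic of every gene (row) across groups.
# Equivalent to anova(lm(gene ~ group)) per gene; vectorized across the
# genome as is conventional for expression screens.
oneway_f_rows <- function(v, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- length(group)
  if (k < 2L) stop("relevance undefined: need >= 2 cell types")
  gm <- rowMeans(v)
  ssb <- numeric(nrow(v)); ssw <- numeric(nrow(v))
  for (lev in levels(group)) {
    idx <- group == lev
    m_l <- rowMeans(v[, idx, drop = FALSE])
    ssb <- ssb + sum(idx) * (m_l - gm)^2
    ssw <- ssw + rowSums((v[, idx, drop = FALSE] - m_l)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- msb / msw
  f[msw == 0 & msb == 0] <- 0
  f[msw == 0 & msb > 0] <- Inf
  f
}

#' Minimum-redundancy maximum-relevance gene selection
#'
#' Greedy mRMR with the difference criterion: relevance of a gene is
#' its one-way F statistic across cell types; redundancy is the mean
#' absolute Pearson correlation with the genes already selected. The
#' first pick maximizes relevance; each later pick maximizes
#' (relevance - redundancy). Ties are broken by input order.
#'
#' @param ref An `expr_matrix` (cells in columns).
#' @param annot data.frame with columns `cell_id`, `cell_type` covering
#'   every column of `ref`.
#' @param n_select Number of genes to select.
#' @param candidates Optional subset of gene ids to select from
#'   (default: all genes of `ref`).
#' @return Character vector of selected gene ids, in selection order.
#' @export
mrmr_select <- function(ref, annot, n_select, candidates = ref$gene_ids) {
  stopifnot(inherits(ref, "expr_matrix"))
  candidates <- intersect(candidates, ref$gene_ids)
  if (n_select > length(candidates))
    stop("n_select exceeds number of candidate genes")
  if (n_select <= 0L) return(character(0))
  group <- annot$cell_type[match(ref$sample_ids, annot$cell_id)]
  if (anyNA(group)) stop("annotation missing for some cells")
  if (length(unique(group)) < 2L) stop("relevance undefined: single cell type")
  v <- ref$values[candidates, , drop = FALSE]
  relevance <- oneway_f_rows(v, group)
  # correlations on the cell axis, computed once
  vt <- t(v)
  p <- length(candidates)
  selected <- integer(0)
  red_sum <- numeric(p)
  avail <- rep(TRUE, p)
  # genes with undefined relevance (constant across all cells) never win
  relevance[is.nan(relevance) | is.na(relevance)] <- -Inf
  for (step in seq_len(n_select)) {
    score <- if (length(selected) == 0L) relevance
      else relevance - red_sum / length(selected)
    score[!avail] <- -Inf
    pick <- which.max(score)   # which.max takes the first tie
    selected <- c(selected, pick)
    avail[pick] <- FALSE
    if (step < n_select) {
      r <- suppressWarnings(as.vector(stats::cor(vt, vt[, pick])))
      r[is.na(r)] <- 0
      red_sum <- red_sum + abs(r)
    }
  }
  candidates[selected]
}

#' Match mouse and human genes through a homolog map
#'
#' @param mouse_genes,human_genes Character vectors of gene symbols.
#' @param map A [homolog_map()].
#' @return data.frame with columns `mouse_gene`, `human_gene`, ordered
#'   by the mouse input order; empty (zero rows) when nothing matches.
#' @export
match_homologs <- function(mouse_genes, human_genes, map) {
  stopifnot(inherits(map, "homolog_map"))
  p <- map$pairs[map$pairs$mouse_gene %in% mouse_genes &
                   map$pairs$human_gene %in% human_genes, ]
  p <- p[order(match(p$mouse_gene, mouse_genes)), ]
  rownames(p) <- NULL
  if (nrow(p) == 0L)
    message("no homologous matches found")
  p
}

rank_z <- function(x) {
  r <- rank(x, ties.method = "average")
  mu <- mean(r)
  s <- sqrt(mean((r - mu)^2))
  if (s == 0) return(rep(0, length(x)))
  (r - mu) / s
}

#' Rank-concordance gene selection
#'
#' Ranks a signature vector and a sample vector over a shared gene
#' list, z-scores the two rank vectors (population SD, average ranks
#' for ties), and retains genes whose rank z-scores differ by at most
#' `band_width`. Being rank-based, the selection is invariant to any
#' strictly monotone transform of either vector and symmetric in its
#' two arguments.
#'
#' @param signature_values,sample_values Numeric vectors over the same
#'   paired gene list (length >= 3).
#' @param band_width Band in z-scored-rank units (default 0.9).
#' @return Integer vector: indices of retained genes (named when the
#'   inputs are named).
#' @export
concordance_select <- function(signature_values, sample_values,
                               band_width = 0.9) {
  if (length(signature_values) != length(sample_values))
    stop("length mismatch between signature and sample vectors")
  if (length(signature_values) < 3L)
    stop("need at least 3 paired genes")
  if (band_width <= 0) stop("band_width must be positive")
  d <- abs(rank_z(signature_values) - rank_z(sample_values))
  keep <- which(d <= band_width)
  if (!is.null(names(signature_values)))
    names(keep) <- names(signature_values)[keep]
  keep
}

#' Four-stage feature selection
#'
#' Composes the full gene-filtering pipeline for one bulk sample:
#' (1) noise-model selection on the mouse reference counts;
#' (2) mRMR reduction across cell types; (3) homolog matching against
#' the human gene space; (4) rank-concordance banding of each cell-type
#' signature against the sample, with the final set the union
#' (optionally intersection) over cell-type signatures. Each stage only
#' removes genes.
#'
#' @param mouse_ref `expr_matrix` of mouse raw counts.
#' @param annot Cell-type annotation of `mouse_ref`.
#' @param human_sample Named numeric vector: one bulk sample indexed by
#'   human gene id.
#' @param map A [homolog_map()].
#' @param residual_threshold Noise-model stage threshold.
#' @param n_mrmr Genes retained by the mRMR stage.
#' @param band_width Concordance band (default 0.9).
#' @param combine `"union"` (default) or `"intersection"` across
#'   cell-type signatures.
#' @return List with `pairs` (data.frame mouse_gene/human_gene of the
#'   final set) and `stage_counts` (named integer vector of surviving
#'   genes after each stage).
#' @export
select_features <- function(mouse_ref, annot, human_sample, map,
                            residual_threshold = 0, n_mrmr = 200,
                            band_width = 0.9,
                            combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  nm <- noise_model_select(mouse_ref, residual_threshold)
  if (length(nm$genes) == 0L)
    stop("no features survive stage: noise model")
  n_mrmr <- min(n_mrmr, length(nm$genes))
  sel <- mrmr_select(mouse_ref, annot, n_mrmr, candidates = nm$genes)
  if (length(sel) == 0L) stop("no features survive stage: mRMR")
  pairs <- match_homologs(sel, names(human_sample), map)
  if (nrow(pairs) == 0L)
    stop("no features survive stage: homolog matching")
  sig <- build_signatures(mouse_ref, annot, genes = pairs$mouse_gene)
  samp <- human_sample[pairs$human_gene]
  kept <- lapply(colnames(sig$values), function(ct)
    concordance_select(sig$values[pairs$mouse_gene, ct], samp,
                       band_width = band_width))
  idx <- if (combine == "union") sort(unique(unlist(kept)))
    else sort(Reduce(intersect, kept))
  if (length(idx) == 0L)
    stop("no features survive stage: concordance")
  counts <- c(noise_model = length(nm$genes), mrmr = length(sel),
              homolog = nrow(pairs), concordance = length(idx))
  list(pairs = pairs[idx, , drop = FALSE], stage_counts = counts)
}
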