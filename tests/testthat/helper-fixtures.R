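# Shared fixtures: everything is generated in code at test time.

small_config <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 200, cells_per_type = 30,
                   markers_per_type = 10, n_samples_per_region = 5,
                   seed = seed)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# tiny expression matrix with hand-set values
tiny_expr <- function(values, species = "human", state = "raw") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, species = species, state = state)
}

# raw-scale signatures for a config, on human gene ids
raw_signatures <- function(cfg) {
  ref <- generate_reference(cfg, "mouse", "MusNG")
  translate_signature(build_signatures(ref$expr, ref$annotation),
                      generate_homolog_map(cfg), "human")
}

# brute-force simplex grid search: minimize ||t - E a|| over the
# 3-simplex at the given resolution
simplex_grid_ols <- function(t_vec, E, step = 0.01) {
  best <- NULL; best_err <- Inf
  for (a1 in seq(0, 1, step)) for (a2 in seq(0, 1 - a1, step)) {
    a <- c(a1, a2, 1 - a1 - a2)
    err <- sum((t_vec - E %*% a)^2)
    if (err < best_err) { best_err <- err; best <- a }
  }
  best
}

# O(n^2) nearest-neighbor max-smoothing oracle
smooth_oracle <- function(props, coords, n_neighbors) {
  n <- ncol(props)
  out <- props
  for (j in seq_len(n)) {
    d2 <- colSums((t(coords) - coords[j, ])^2)
    nb <- order(d2)[seq_len(n_neighbors)]
    for (i in seq_len(nrow(props))) out[i, j] <- max(props[i, nb])
  }
  out
}

# parent-chain walk oracle for major-region assignment
parent_chain_major <- function(h, id) {
  cur <- id
  while (!is.na(cur)) {
    if (cur %in% h$roots) return(cur)
    cur <- h$parent_of[[cur]]
  }
  "other"
}

# hand-computed BH step-up
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# exhaustive greedy mRMR oracle (difference criterion, F relevance,
# mean |r| redundancy), independent re-implementation via lm/anova
mrmr_oracle <- function(v, group, n_select) {
  p <- nrow(v)
  relevance <- vapply(seq_len(p), function(i) {
    fit <- stats::anova(stats::lm(v[i, ] ~ factor(group)))
    f <- fit[["F value"]][1L]
    if (is.na(f)) -Inf else f
  }, numeric(1))
  selected <- integer(0)
  for (s in seq_len(n_select)) {
    score <- vapply(seq_len(p), function(i) {
      if (i %in% selected) return(-Inf)
      if (length(selected) == 0L) return(relevance[i])
      red <- mean(vapply(selected, function(j) {
        r <- suppressWarnings(stats::cor(v[i, ], v[j, ]))
        if (is.na(r)) 0 else abs(r)
      }, numeric(1)))
      relevance[i] - red
    }, numeric(1))
    selected <- c(selected, which.max(score))
  }
  selected
}
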