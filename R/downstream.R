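#' Construct a brain-region hierarchy
#'
#' An anatomical tree given as a node table. Each node except roots has
#' exactly one parent; cycles are rejected.
#'
#' @param nodes data.frame with columns `id`, `name`, `parent` (`NA`
#'   for the tree root).
#' @param roots The branch roots of interest (default cerebrum,
#'   brainstem, cerebellum).
#' @return A list of class `"region_hierarchy"`.
#' @export
region_hierarchy <- function(nodes,
                             roots = c("cerebrum", "brainstem",
                                       "cerebellum")) {
  stopifnot(is.data.frame(nodes),
            all(c("id", "parent") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate region ids")
  known <- c(nodes$id, NA)
  if (!all(nodes$parent %in% known))
    stop("parent(s) not in tree: ",
         paste(setdiff(nodes$parent, known), collapse = ", "))
  # acyclicity: walk each node to a root, bounded by tree size
  parent_of <- stats::setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    cur <- id
    for (step in seq_len(nrow(nodes) + 1L)) {
      cur <- parent_of[[cur]]
      if (is.na(cur)) break
      if (cur == id || step > nrow(nodes)) stop("cycle in hierarchy at ", id)
    }
  }
  if (!all(roots %in% nodes$id))
    stop("root(s) of interest missing from tree: ",
         paste(setdiff(roots, nodes$id), collapse = ", "))
  structure(list(nodes = nodes, roots = roots,
                 parent_of = parent_of),
            class = "region_hierarchy")
}

#' Read a region hierarchy from a two-column parent TSV
#' @param path TSV with header columns id, parent (parent empty or NA
#'   at the root); an optional `name` column is carried through.
#' @param roots Passed to [region_hierarchy()].
#' @return A `region_hierarchy`.
#' @export
read_region_hierarchy <- function(path, roots = c("cerebrum", "brainstem",
                                                  "cerebellum")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (is.null(df$name)) df$name <- df$id
  region_hierarchy(df[, c("id", "name", "parent")], roots = roots)
}

#' Assign a region to its major brain region
#'
#' Breadth-first search from each root of interest; returns the root
#' whose subtree contains the region, or `"other"` for regions outside
#' all subtrees of interest.
#'
#' @param h A [region_hierarchy()].
#' @param region_id Region id(s) present in the tree.
#' @return Character vector of major-region labels.
#' @export
assign_major_region <- function(h, region_id) {
  stopifnot(inherits(h, "region_hierarchy"))
  unknown <- setdiff(region_id, h$nodes$id)
  if (length(unknown))
    stop("unknown region id(s): ", paste(unknown, collapse = ", "))
  membership <- stats::setNames(rep("other", nrow(h$nodes)), h$nodes$id)
  for (root in h$roots) {
    frontier <- root
    while (length(frontier)) {
      membership[frontier] <- root
      frontier <- h$nodes$id[h$nodes$parent %in% frontier]
    }
  }
  unname(membership[region_id])
}

#' Mean projection volume per major brain region
#'
#' Per tracer experiment, the connectivity measure is the sum of the
#' injection-site and target-site volumes; experiments are mapped to
#' major regions through the hierarchy and averaged. Experiments
#' falling outside the three major subtrees ("other") are excluded.
#'
#' @param connectivity data.frame with columns `region_id`,
#'   `injection_volume`, `target_volume` (volumes in mm^3, >= 0).
#' @param h A [region_hierarchy()].
#' @return Named numeric vector: mean volume per major region.
#' @export
projection_volume <- function(connectivity, h) {
  stopifnot(all(c("region_id", "injection_volume", "target_volume") %in%
                  names(connectivity)))
  if (any(connectivity$injection_volume < 0 |
            connectivity$target_volume < 0))
    stop("negative projection volume")
  major <- assign_major_region(h, connectivity$region_id)
  vol <- connectivity$injection_volume + connectivity$target_volume
  keep <- major != "other"
  means <- tapply(vol[keep], factor(major[keep], levels = h$roots), mean)
  empty <- h$roots[is.na(means)]
  if (length(empty))
    stop("no experiments in region(s): ", paste(empty, collapse = ", "))
  stats::setNames(as.numeric(means), h$roots)
}

#' Neuron to non-neuron proportion ratio
#'
#' @param alpha Named proportion vector (or a `proportion_estimate`).
#' @param neuron_types Cell types counted as neurons (default the
#'   three neuron types).
#' @return The ratio sum(neuron) / sum(non-neuron); `NA` (flagged
#'   undefined) when the non-neuron sum is zero.
#' @export
neuron_ratio <- function(alpha, neuron_types = neuron_cell_types()) {
  if (inherits(alpha, "proportion_estimate")) alpha <- alpha$alpha
  stopifnot(!is.null(names(alpha)))
  if (!all(neuron_types %in% names(alpha)))
    stop("neuron_types not a subset of the cell types")
  num <- sum(alpha[neuron_types])
  den <- sum(alpha[setdiff(names(alpha), neuron_types)])
  if (den <= 0) return(NA_real_)
  num / den
}

#' Adjust an mRNA ratio for neural projection volume
#'
#' Divides the mRNA-derived neuron/non-neuron ratio by the region's
#' mean projection volume, correcting for the larger per-cell mRNA
#' footprint of long-projection neurons.
#'
#' @param ratio mRNA neuron/non-neuron ratio(s).
#' @param region_volume Mean projection volume(s) (> 0), recycled.
#' @return Adjusted ratio(s).
#' @export
adjust_ratio <- function(ratio, region_volume) {
  if (any(region_volume <= 0)) stop("region volume must be positive")
  ratio / region_volume
}

#' Reconcile mRNA-derived ratios with nuclei counts
#'
#' The nuclei-based neuron/non-neuron ratio per region is
#' NeuN+ / (DAPI+ - NeuN+). Each mRNA ratio estimate (one per dataset,
#' donor, region combination) is correlated against the nuclei ratio of
#' its region, before and after projection-volume adjustment; two-sided
#' p-values come from the t-distribution ([stats::cor.test()]).
#'
#' @param ratios data.frame with columns `major_region` and `ratio`
#'   (one row per dataset/donor/region estimate).
#' @param nuclei data.frame with columns `major_region`, `dapi`,
#'   `neun`.
#' @param volumes Named numeric: mean projection volume per major
#'   region.
#' @return List with `pcc_unadjusted`, `p_unadjusted`, `pcc_adjusted`,
#'   `p_adjusted`, and the working table in `$data`.
#' @export
reconcile_with_nuclei <- function(ratios, nuclei, volumes) {
  stopifnot(all(c("major_region", "ratio") %in% names(ratios)),
            all(c("major_region", "dapi", "neun") %in% names(nuclei)))
  if (any(nuclei$neun > nuclei$dapi) || any(nuclei$neun <= 0))
    stop("invalid nuclei counts: need 0 < NeuN+ <= DAPI+")
  nuc_ratio <- stats::setNames(
    nuclei$neun / (nuclei$dapi - nuclei$neun), nuclei$major_region)
  d <- ratios
  d$nuclei_ratio <- nuc_ratio[d$major_region]
  d$volume <- volumes[d$major_region]
  d$adjusted <- adjust_ratio(d$ratio, d$volume)
  d <- d[stats::complete.cases(d[, c("ratio", "nuclei_ratio",
                                     "adjusted")]), ]
  if (nrow(d) < 3L) stop("need >= 3 matched points for correlation")
  un <- stats::cor.test(d$nuclei_ratio, d$ratio)
  ad <- stats::cor.test(d$nuclei_ratio, d$adjusted)
  list(pcc_unadjusted = unname(un$estimate), p_unadjusted = un$p.value,
       pcc_adjusted = unname(ad$estimate), p_adjusted = ad$p.value,
       data = d)
}

#' One-way ANOVA of a quantity across brain regions
#'
#' @param values Numeric vector.
#' @param regions Grouping labels, same length.
#' @return The F-test p-value.
#' @export
anova_by_region <- function(values, regions) {
  regions <- as.factor(regions)
  if (nlevels(regions) < 2L) stop("need >= 2 regions")
  if (any(table(regions) < 2L))
    stop("region(s) with a single value: ",
         paste(names(which(table(regions) < 2L)), collapse = ", "))
  fit <- stats::aov(values ~ regions)
  summary(fit)[[1L]][["Pr(>F)"]][1L]
}

#' Correlate cell-type proportions with AD clinical traits
#'
#' Pearson correlation of each cell type of interest against each of
#' the clinical/neuropathological traits (CDR, Plaque Mean, Braak
#' stage) across samples, with two-sided p-values. Constant traits or
#' proportions yield a flagged undefined correlation rather than an
#' error.
#'
#' @param props Proportion matrix, cell types x samples.
#' @param traits data.frame with columns `sample_id`, `CDR`,
#'   `PlaqueMean`, `BBS`.
#' @param cell_types Cell types to report (default the three neuron
#'   types plus microglia).
#' @return data.frame: cell_type, trait, pcc, p, undefined.
#' @export
ad_trait_correlations <- function(props, traits,
                                  cell_types = c(neuron_cell_types(),
                                                 "microglia")) {
  stopifnot(all(c("sample_id", "CDR", "PlaqueMean", "BBS") %in%
                  names(traits)))
  shared <- intersect(colnames(props), traits$sample_id)
  if (length(shared) < 3L) stop("need >= 3 samples with complete traits")
  if (!all(cell_types %in% rownames(props)))
    stop("cell type(s) absent from proportions: ",
         paste(setdiff(cell_types, rownames(props)), collapse = ", "))
  tr <- traits[match(shared, traits$sample_id), ]
  trait_names <- c("CDR", "PlaqueMean", "BBS")
  rows <- list()
  for (ct in cell_types) for (tn in trait_names) {
    x <- props[ct, shared]
    y <- tr[[tn]]
    undef <- stats::sd(x) == 0 || stats::sd(y) == 0 ||
      any(is.na(x)) || any(is.na(y))
    if (undef) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, trait = tn, pcc = NA_real_, p = NA_real_,
        undefined = TRUE, stringsAsFactors = FALSE)
    } else {
      htest <- stats::cor.test(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ct, trait = tn, pcc = unname(htest$estimate),
        p = htest$p.value, undefined = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
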