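#' The nine reference brain cell types
#'
#' Cell types and subtypes resolved by the deconvolution workflow:
#' three neuronal types and six non-neuronal types.
#' @return Character vector of length 9.
#' @export
brain_cell_types <- function() {
  c("interneuron", "S1 pyramidal", "CA1 pyramidal", "oligodendrocyte",
    "microglia", "astrocyte", "endothelial", "ependymal", "mural")
}

#' Neuronal cell types
#' @return Character vector: the three neuron types.
#' @export
neuron_cell_types <- function() {
  c("interneuron", "S1 pyramidal", "CA1 pyramidal")
}

glial_cell_types <- function() setdiff(brain_cell_types(), neuron_cell_types())

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Small deterministic string hash, used to decorrelate the RNG streams
# of differently-labelled datasets drawn from one config seed.
str_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 1000003
  as.integer(h)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = k, ncol = n)
  zero <- colSums(g) == 0
  if (any(zero)) g[, zero] <- 1 / k
  sweep(g, 2L, colSums(g), "/")
}

default_regions <- function() {
  # location, major region, and a composition vector over the 9 types
  # (interneuron, S1 pyr, CA1 pyr, oligo, microglia, astro, endo,
  # ependymal, mural). Cerebral locations are neuron-rich, brainstem is
  # glia/endothelial-rich, cerebellum oligodendrocyte/astrocyte-rich --
  # coarse caricatures of the known regional enrichments.
  comp <- function(...) {
    v <- c(...)
    v / sum(v)
  }
  list(
    list(location = "frontal cortex", major_region = "cerebrum",
         composition = comp(14, 38, 4, 10, 6, 14, 6, 2, 6)),
    list(location = "temporal cortex", major_region = "cerebrum",
         composition = comp(18, 32, 6, 12, 6, 12, 6, 2, 6)),
    list(location = "hippocampus", major_region = "cerebrum",
         composition = comp(12, 8, 36, 10, 6, 14, 6, 2, 6)),
    list(location = "midbrain", major_region = "brainstem",
         composition = comp(6, 4, 2, 26, 10, 18, 20, 6, 8)),
    list(location = "pons", major_region = "brainstem",
         composition = comp(4, 4, 2, 30, 10, 16, 20, 6, 8)),
    list(location = "medulla", major_region = "brainstem",
         composition = comp(4, 2, 2, 28, 12, 16, 22, 6, 8)),
    list(location = "cerebellar cortex", major_region = "cerebellum",
         composition = comp(26, 6, 2, 18, 4, 28, 6, 4, 6)),
    list(location = "cerebellar nuclei", major_region = "cerebellum",
         composition = comp(22, 6, 2, 22, 4, 28, 6, 4, 6)),
    list(location = "vermis", major_region = "cerebellum",
         composition = comp(28, 4, 2, 16, 4, 30, 6, 4, 6))
  )
}

#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic study: reference size and
#' marker structure, per-dataset missing cell types, the spatial region
#' map with per-region compositions, and noise levels. Defaults emulate
#' the structure of the real study's inputs: a complete mouse reference,
#' a neurons-only human reference ("HumN"-like, all glial types
#' missing), a small human reference missing one type ("HumNG"-like),
#' and bulk samples from nine anatomic locations across the three major
#' brain regions.
#'
#' @param n_genes Number of genes.
#' @param cell_types Ordered cell-type labels (default the nine brain
#'   types of [brain_cell_types()]).
#' @param cells_per_type Cells simulated per present cell type.
#' @param markers_per_type Marker genes per cell type; the first
#'   `markers_per_type * length(cell_types)` genes are markers, in
#'   type-blocks.
#' @param marker_fold Mean fold-elevation of a marker gene in its own
#'   type (> 1 for informative markers).
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 degrades to Poisson.
#' @param dropout_rate Probability that a count is zeroed (dropout).
#' @param missing_types Named list: dataset label -> character vector of
#'   absent cell types.
#' @param regions List of `list(location, major_region, composition)`
#'   records; each composition is a probability vector over
#'   `cell_types`.
#' @param n_samples_per_region Bulk samples per (donor, location).
#' @param n_donors Number of bulk donors (i.i.d. replicates of the
#'   region map).
#' @param coord_noise SD of the 3-D coordinate jitter around each
#'   location's center (arbitrary units).
#' @param noise_sd SD of the additive Gaussian noise on bulk expression,
#'   as a fraction of the mean signature scale.
#' @param dirichlet_concentration Concentration of the Dirichlet from
#'   which per-sample compositions are drawn around their region's
#'   composition; larger = tighter. May be a vector, one per donor, to
#'   emulate an atypical donor.
#' @param unmapped_fraction Fraction of genes dropped from the
#'   mouse-human homolog map.
#' @param seed Integer seed; all generators derive their RNG streams
#'   from it deterministically.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_genes = 600,
                         cell_types = brain_cell_types(),
                         cells_per_type = 100,
                         markers_per_type = 20,
                         marker_fold = 5,
                         dispersion = 0.4,
                         dropout_rate = 0.3,
                         missing_types = list(
                           HumN = glial_cell_types(),
                           HumNG = "ependymal"),
                         regions = default_regions(),
                         n_samples_per_region = 10,
                         n_donors = 2,
                         coord_noise = 0.5,
                         noise_sd = 0.05,
                         dirichlet_concentration = 100,
                         unmapped_fraction = 0,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), cell_types = cell_types,
              cells_per_type = as.integer(cells_per_type),
              markers_per_type = as.integer(markers_per_type),
              marker_fold = marker_fold, dispersion = dispersion,
              dropout_rate = dropout_rate, missing_types = missing_types,
              regions = regions,
              n_samples_per_region = as.integer(n_samples_per_region),
              n_donors = as.integer(n_donors), coord_noise = coord_noise,
              noise_sd = noise_sd,
              dirichlet_concentration = dirichlet_concentration,
              unmapped_fraction = unmapped_fraction, seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, cfg$markers_per_type >= 0,
            cfg$marker_fold >= 1, cfg$dispersion >= 0,
            cfg$dropout_rate >= 0, cfg$dropout_rate <= 1,
            cfg$coord_noise >= 0, cfg$noise_sd >= 0,
            all(cfg$dirichlet_concentration > 0),
            cfg$unmapped_fraction >= 0, cfg$unmapped_fraction < 1)
  if (cfg$markers_per_type * length(cfg$cell_types) > cfg$n_genes)
    stop("markers_per_type x |cell_types| exceeds n_genes")
  for (mt in cfg$missing_types)
    if (!all(mt %in% cfg$cell_types))
      stop("missing_types contains unknown cell type(s): ",
           paste(setdiff(mt, cfg$cell_types), collapse = ", "))
  for (r in cfg$regions) {
    comp <- r$composition
    if (length(comp) != length(cfg$cell_types))
      stop("composition length mismatch in region ", r$location)
    if (any(comp < 0) || abs(sum(comp) - 1) > 1e-9)
      stop("composition of region '", r$location,
           "' is not on the simplex")
  }
  invisible(cfg)
}

# Gene identifiers: mouse uses title case, human upper case; the
# homolog map is identity on the uppercased symbol.
gene_symbols <- function(n, species = c("human", "mouse")) {
  species <- match.arg(species)
  base <- sprintf("gene%04d", seq_len(n))
  if (species == "human") toupper(base)
  else paste0("Gene", sprintf("%04d", seq_len(n)))
}

#' Marker-gene assignment implied by a config
#'
#' @param config A [synth_config()].
#' @return Named character vector, gene index -> cell type, `NA` for
#'   non-marker genes; names are human-style gene symbols.
#' @export
marker_assignment <- function(config) {
  k <- length(config$cell_types)
  assign <- rep(NA_character_, config$n_genes)
  if (config$markers_per_type > 0)
    assign[seq_len(config$markers_per_type * k)] <-
      rep(config$cell_types, each = config$markers_per_type)
  names(assign) <- gene_symbols(config$n_genes, "human")
  assign
}

# Per-gene baseline expected counts, shared across species so that
# homologous genes carry transferable signal (log-normal baseline).
gene_baseline <- function(config) {
  with_seed(config$seed + 7L,
            exp(stats::rnorm(config$n_genes, mean = log(3), sd = 1)))
}

# Expected count of gene g in a cell of type t.
expected_means <- function(config) {
  base <- gene_baseline(config)
  k <- length(config$cell_types)
  mu <- matrix(base, nrow = config$n_genes, ncol = k)
  assign <- marker_assignment(config)
  for (j in seq_len(k)) {
    idx <- which(assign == config$cell_types[j])
    mu[idx, j] <- mu[idx, j] * config$marker_fold
  }
  colnames(mu) <- config$cell_types
  mu
}

#' Generate a single-cell reference dataset
#'
#' Draws per-cell counts from a negative binomial whose mean is the
#' gene's log-normal baseline, elevated by `marker_fold` in the marker
#' genes of the cell's type, then applies dropout zeros. Cell types
#' listed in `config$missing_types[[dataset]]` are absent, emulating
#' human references that lack part of the cell-type repertoire.
#'
#' @param config A [synth_config()].
#' @param species `"mouse"` or `"human"`.
#' @param dataset Dataset label (keys `missing_types` and the RNG
#'   stream).
#' @return List with `expr` (an `expr_matrix` of raw counts) and
#'   `annotation` (data.frame with columns `cell_id`, `cell_type`).
#' @export
generate_reference <- function(config, species = c("mouse", "human"),
                               dataset = species) {
  species <- match.arg(species)
  validate_synth_config(config)
  if (config$cells_per_type == 0L) stop("empty reference")
  missing <- config$missing_types[[dataset]]
  if (!all(missing %in% config$cell_types))
    stop("missing_types not a subset of cell_types")
  types <- setdiff(config$cell_types, missing)
  if (length(types) == 0L) stop("all cell types missing from '", dataset, "'")
  mu <- expected_means(config)[, types, drop = FALSE]
  n_cells <- config$cells_per_type * length(types)
  cell_type <- rep(types, each = config$cells_per_type)
  counts <- with_seed(config$seed + str_hash(paste(species, dataset)), {
    m <- matrix(0, nrow = config$n_genes, ncol = n_cells)
    for (j in seq_len(n_cells)) {
      mj <- mu[, cell_type[j]]
      m[, j] <- if (config$dispersion > 0)
        stats::rnbinom(config$n_genes, mu = mj,
                       size = 1 / config$dispersion)
      else stats::rpois(config$n_genes, lambda = mj)
    }
    if (config$dropout_rate > 0)
      m[matrix(stats::runif(length(m)) < config$dropout_rate,
               nrow = nrow(m))] <- 0
    m
  })
  cell_id <- sprintf("%s_c%04d", dataset, seq_len(n_cells))
  expr <- expression_matrix(counts, gene_symbols(config$n_genes, species),
                            cell_id, species = species, state = "raw")
  list(expr = expr,
       annotation = data.frame(cell_id = cell_id, cell_type = cell_type,
                               stringsAsFactors = FALSE))
}

#' Generate the mouse-human homolog map for a config
#'
#' Identity on the uppercased gene symbol, with a configurable fraction
#' of genes left unmapped (drawn at random under the config seed).
#'
#' @param config A [synth_config()].
#' @return A [homolog_map()] with one-to-one policy.
#' @export
generate_homolog_map <- function(config) {
  mouse <- gene_symbols(config$n_genes, "mouse")
  human <- gene_symbols(config$n_genes, "human")
  keep <- seq_len(config$n_genes)
  if (config$unmapped_fraction > 0) {
    drop_n <- floor(config$unmapped_fraction * config$n_genes)
    drop <- with_seed(config$seed + 13L,
                      sample(config$n_genes, drop_n))
    keep <- setdiff(keep, drop)
  }
  homolog_map(data.frame(mouse_gene = mouse[keep], human_gene = human[keep],
                         stringsAsFactors = FALSE))
}

region_centers <- function(config) {
  majors <- unique(vapply(config$regions, `[[`, "", "major_region"))
  base <- matrix(c(0, 0, 0, 30, 0, 0, 0, 30, 0, 15, 15, 20),
                 ncol = 3, byrow = TRUE)
  centers <- lapply(seq_along(config$regions), function(i) {
    r <- config$regions[[i]]
    m <- match(r$major_region, majors)
    within <- ((i - 1) %% 3)
    base[(m - 1) %% 4 + 1, ] + within * c(3, 2, -2)
  })
  names(centers) <- vapply(config$regions, `[[`, "", "location")
  centers
}

#' Generate spatially-annotated bulk samples with known composition
#'
#' Each sample's expression is a linear mixture of the signature columns
#' under a composition drawn from a Dirichlet centered on its region's
#' composition vector, plus additive Gaussian noise (clamped at zero so
#' raw bulk expression stays non-negative). Donors are i.i.d. replicates
#' of the same region map; per-donor Dirichlet concentrations can differ
#' to emulate an atypical donor. 3-D coordinates are Gaussian blobs
#' around per-location centers.
#'
#' @param config A [synth_config()].
#' @param signatures A [signature_matrix()] on the raw (non-negative)
#'   scale containing every cell type used in the region compositions.
#' @param seed Optional override of `config$seed`.
#' @return List with `samples` (a `spatial_samples` object: `expr`, an
#'   `expr_matrix`, and `meta`, a data.frame of sample_id, x, y, z,
#'   location, major_region, donor) and `truth` (a `ground_truth`
#'   object).
#' @export
generate_spatial_bulk <- function(config, signatures, seed = config$seed) {
  validate_synth_config(config)
  if (length(config$regions) == 0L) stop("region list empty")
  stopifnot(inherits(signatures, "signature_matrix"))
  if (!all(config$cell_types %in% colnames(signatures$values)))
    stop("signatures lack cell type(s): ",
         paste(setdiff(config$cell_types, colnames(signatures$values)),
               collapse = ", "))
  E <- signatures$values[, config$cell_types, drop = FALSE]
  centers <- region_centers(config)
  conc <- rep_len(config$dirichlet_concentration, config$n_donors)
  scale_ref <- mean(abs(E))
  out <- with_seed(seed, {
    rows <- list(); alphas <- list(); exprs <- list()
    idx <- 0L
    for (d in seq_len(config$n_donors)) {
      for (r in config$regions) {
        a <- rdirichlet(config$n_samples_per_region,
                        conc[d] * pmax(r$composition, 1e-8))
        for (j in seq_len(config$n_samples_per_region)) {
          idx <- idx + 1L
          t_vec <- as.vector(E %*% a[, j])
          if (config$noise_sd > 0)
            t_vec <- t_vec + stats::rnorm(length(t_vec),
                                          sd = config$noise_sd * scale_ref)
          exprs[[idx]] <- pmax(t_vec, 0)
          alphas[[idx]] <- a[, j]
          xyz <- centers[[r$location]] +
            stats::rnorm(3, sd = config$coord_noise)
          rows[[idx]] <- data.frame(
            sample_id = sprintf("D%02d_s%04d", d, idx),
            x = xyz[1], y = xyz[2], z = xyz[3],
            location = r$location, major_region = r$major_region,
            donor = sprintf("D%02d", d), stringsAsFactors = FALSE)
        }
      }
    }
    list(meta = do.call(rbind, rows),
         values = do.call(cbind, exprs),
         alpha = do.call(cbind, alphas))
  })
  colnames(out$values) <- out$meta$sample_id
  rownames(out$values) <- rownames(E)
  colnames(out$alpha) <- out$meta$sample_id
  rownames(out$alpha) <- config$cell_types
  expr <- expression_matrix(out$values, species = "human", state = "raw")
  samples <- structure(list(expr = expr, meta = out$meta),
                       class = "spatial_samples")
  truth <- structure(list(
    proportions = out$alpha,
    region_assignment = stats::setNames(out$meta$major_region,
                                        out$meta$sample_id),
    location = stats::setNames(out$meta$location, out$meta$sample_id),
    donor = stats::setNames(out$meta$donor, out$meta$sample_id),
    marker_assignment = marker_assignment(config)),
    class = "ground_truth")
  list(samples = samples, truth = truth)
}

#' Generate a synthetic brain-region hierarchy
#'
#' A small anatomical tree: one root, the three major regions beneath
#' it, the config's locations as children of their major region, a
#' nested sub-division under each location, and one branch ("white
#' matter tracts") outside the three major subtrees.
#'
#' @param config A [synth_config()].
#' @return A [region_hierarchy()].
#' @export
generate_region_hierarchy <- function(config) {
  majors <- unique(vapply(config$regions, `[[`, "", "major_region"))
  id <- "brain"; name <- "brain"; parent <- NA_character_
  for (m in majors) { id <- c(id, m); name <- c(name, m); parent <- c(parent, "brain") }
  for (r in config$regions) {
    id <- c(id, r$location); name <- c(name, r$location)
    parent <- c(parent, r$major_region)
    sub <- paste0(r$location, " / core")
    id <- c(id, sub); name <- c(name, sub); parent <- c(parent, r$location)
  }
  id <- c(id, "white matter tracts"); name <- c(name, "white matter tracts")
  parent <- c(parent, "brain")
  region_hierarchy(data.frame(id = id, name = name, parent = parent,
                              stringsAsFactors = FALSE),
                   roots = majors)
}

#' Generate connectivity experiments and nuclei counts
#'
#' Projection volumes are drawn with region-specific means (largest in
#' the cerebrum, smallest in the cerebellum, echoing long-range cortical
#' projections). Nuclei counts are constructed so that, per major
#' region, (mRNA neuron/non-neuron ratio) is approximately (nuclei
#' ratio) x (mean projection volume)^`coupling`: at `coupling = 1` the
#' mRNA signal over-represents neurons in proportion to their projection
#' volume; at `coupling = 0` nuclei and mRNA ratios coincide up to
#' noise.
#'
#' @param config A [synth_config()].
#' @param truth A `ground_truth` from [generate_spatial_bulk()].
#' @param coupling Non-negative exponent tying mRNA ratios to
#'   projection volume.
#' @param n_experiments_per_region Tracer experiments drawn per
#'   anatomic location.
#' @param nuclei_noise SD of the multiplicative log-normal noise on the
#'   nuclei ratio.
#' @param seed Optional override of `config$seed`.
#' @return List with `connectivity` (data.frame: region_id,
#'   injection_volume, target_volume), `nuclei` (data.frame:
#'   major_region, dapi, neun) and `volume_means` (named numeric, the
#'   per-major-region generative mean volumes).
#' @export
generate_connectivity_nuclei <- function(config, truth, coupling = 1,
                                         n_experiments_per_region = 20,
                                         nuclei_noise = 0.05,
                                         seed = config$seed) {
  stopifnot(coupling >= 0)
  majors <- unique(vapply(config$regions, `[[`, "", "major_region"))
  if (!all(unique(truth$region_assignment) %in% majors))
    stop("unknown region label: ",
         paste(setdiff(unique(truth$region_assignment), majors),
               collapse = ", "))
  vol_mean <- stats::setNames(c(8, 2.5, 0.8)[seq_along(majors)], majors)
  neuron <- intersect(neuron_cell_types(), rownames(truth$proportions))
  mrna_ratio <- vapply(majors, function(m) {
    p <- rowMeans(truth$proportions[, truth$region_assignment == m,
                                    drop = FALSE])
    sum(p[neuron]) / sum(p[setdiff(names(p), neuron)])
  }, numeric(1))
  out <- with_seed(seed + 101L, {
    conn <- do.call(rbind, lapply(config$regions, function(r) {
      v <- vol_mean[[r$major_region]]
      data.frame(
        region_id = r$location,
        injection_volume = stats::rlnorm(n_experiments_per_region,
                                         log(v / 2), 0.25),
        target_volume = stats::rlnorm(n_experiments_per_region,
                                      log(v / 2), 0.25),
        stringsAsFactors = FALSE)
    }))
    ratio <- mrna_ratio / vol_mean^coupling *
      stats::rlnorm(length(majors), 0, nuclei_noise)
    dapi <- round(stats::rlnorm(length(majors), log(5e5), 0.1))
    neun <- pmin(round(dapi * ratio / (1 + ratio)), dapi - 1)
    list(conn = conn,
         nuclei = data.frame(major_region = majors, dapi = dapi,
                             neun = pmax(neun, 1),
                             stringsAsFactors = FALSE))
  })
  list(connectivity = out$conn, nuclei = out$nuclei,
       volume_means = vol_mean)
}

#' Generate an Alzheimer's-disease cohort with trait-linked composition
#'
#' Each sample carries a latent severity s ~ U(0,1). The three clinical
#' traits (CDR, Plaque Mean, Braak stage) are independent monotone noisy
#' transforms of s. Cell-type composition shifts linearly in s: the
#' three neuron types lose proportion and microglia gains, with total
#' shift controlled by `severity_effect`; bulk expression is mixed from
#' the signatures as in [generate_spatial_bulk()].
#'
#' @param config A [synth_config()].
#' @param signatures A raw-scale [signature_matrix()] with all 9 types.
#' @param n_samples Cohort size (>= 3).
#' @param severity_effect Non-negative total proportion shift between
#'   s = 0 and s = 1 (0 = traits unrelated to composition).
#' @param seed RNG seed.
#' @return List with `expr` (bulk `expr_matrix`), `traits` (data.frame:
#'   sample_id, CDR, PlaqueMean, BBS), and `truth` (a `ground_truth`).
#' @export
generate_ad_cohort <- function(config, signatures, n_samples = 500,
                               severity_effect = 0.25,
                               seed = config$seed) {
  stopifnot(severity_effect >= 0)
  if (n_samples < 3) stop("n_samples < 3: correlation undefined")
  stopifnot(inherits(signatures, "signature_matrix"))
  E <- signatures$values[, config$cell_types, drop = FALSE]
  types <- config$cell_types
  neuron <- neuron_cell_types()
  # cortical baseline: neuron-rich, modest glia
  base <- stats::setNames(c(.16, .28, .10, .12, .06, .12, .07, .03, .06),
                          brain_cell_types())[types]
  base <- base / sum(base)
  # direction of the severity shift: neurons down, microglia up,
  # remainder spread over the other types so the shift sums to zero
  dirv <- stats::setNames(numeric(length(types)), types)
  dirv[intersect(neuron, types)] <- -c(0.35, 0.35, 0.30)
  dirv["microglia"] <- 0.7
  others <- setdiff(types, c(neuron, "microglia"))
  dirv[others] <- 0.3 / length(others)
  scale_ref <- mean(abs(E))
  out <- with_seed(seed + 211L, {
    s <- stats::runif(n_samples)
    cdr_latent <- s + stats::rnorm(n_samples, sd = 0.15)
    cdr <- c(0, 0.5, 1, 2, 3)[
      findInterval(cdr_latent, c(0.2, 0.4, 0.6, 0.8)) + 1L]
    plaque <- pmax(20 * s + stats::rnorm(n_samples, sd = 3), 0)
    bbs <- pmin(pmax(round(6 * s + stats::rnorm(n_samples, sd = 0.8)), 0), 6)
    conc <- rep_len(config$dirichlet_concentration, 1L)
    alpha <- vapply(seq_len(n_samples), function(i) {
      comp <- pmax(base + severity_effect * (s[i] - 0.5) * dirv, 1e-6)
      comp <- comp / sum(comp)
      rdirichlet(1, conc * comp)[, 1]
    }, numeric(length(types)))
    vals <- E %*% alpha
    if (config$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals),
                                         sd = config$noise_sd * scale_ref),
                            nrow = nrow(vals))
    list(s = s, cdr = cdr, plaque = plaque, bbs = bbs,
         alpha = alpha, vals = pmax(vals, 0))
  })
  ids <- sprintf("AD_s%04d", seq_len(n_samples))
  colnames(out$vals) <- ids; rownames(out$vals) <- rownames(E)
  rownames(out$alpha) <- types; colnames(out$alpha) <- ids
  expr <- expression_matrix(out$vals, species = "human", state = "raw")
  traits <- data.frame(sample_id = ids, CDR = out$cdr,
                       PlaqueMean = out$plaque, BBS = out$bbs,
                       stringsAsFactors = FALSE)
  truth <- structure(list(proportions = out$alpha,
                          severity = stats::setNames(out$s, ids),
                          marker_assignment = marker_assignment(config)),
                     class = "ground_truth")
  list(expr = expr, traits = traits, truth = truth)
}

#' Simulate a cluster-score table for confounder analysis
#'
#' Emulates the per-(dataset, donor, region) sensitivity/specificity
#' table produced by region clustering, with an additive region effect
#' and i.i.d. Gaussian noise; used to study which factors a MANOVA can
#' detect.
#'
#' @param n_datasets,n_donors Number of levels of the two nuisance
#'   factors.
#' @param regions Region labels.
#' @param region_effect Sensitivity/specificity offset applied to the
#'   regions (spread evenly around zero across the levels).
#' @param noise_sd SD of the Gaussian noise on both responses.
#' @param seed RNG seed.
#' @return data.frame with columns dataset, donor, region, sensitivity,
#'   specificity.
#' @export
simulate_score_table <- function(n_datasets = 3, n_donors = 6,
                                 regions = c("cerebrum", "brainstem",
                                             "cerebellum"),
                                 region_effect = 0.1, noise_sd = 0.05,
                                 seed = 1L) {
  g <- expand.grid(dataset = paste0("ds", seq_len(n_datasets)),
                   donor = paste0("D", seq_len(n_donors)),
                   region = regions, stringsAsFactors = FALSE)
  off <- stats::setNames(
    region_effect * (seq_along(regions) - mean(seq_along(regions))),
    regions)
  with_seed(seed, {
    g$sensitivity <- pmin(pmax(
      0.8 + off[g$region] + stats::rnorm(nrow(g), sd = noise_sd), 0), 1)
    g$specificity <- pmin(pmax(
      0.9 + off[g$region] + stats::rnorm(nrow(g), sd = noise_sd), 0), 1)
  })
  rownames(g) <- NULL
  g
}

#' Simulate per-(dataset, donor, region) neuron-ratio estimates
#'
#' Emulates the replicate structure of the ratio-reconciliation
#' analysis: for each major region the true mRNA neuron/non-neuron
#' ratio (from the generator truth) is observed once per (dataset,
#' donor) combination with multiplicative log-normal estimation noise.
#'
#' @param truth A `ground_truth` from [generate_spatial_bulk()].
#' @param n_datasets,n_donors Replicate structure (default 3 x 6, the
#'   18-estimate layout).
#' @param est_noise SD of the log-normal estimation noise.
#' @param seed RNG seed.
#' @return data.frame with columns dataset, donor, major_region, ratio.
#' @export
simulate_ratio_estimates <- function(truth, n_datasets = 3, n_donors = 6,
                                     est_noise = 0.15, seed = 1L) {
  majors <- unique(truth$region_assignment)
  neuron <- intersect(neuron_cell_types(), rownames(truth$proportions))
  true_ratio <- vapply(majors, function(m) {
    p <- rowMeans(truth$proportions[, truth$region_assignment == m,
                                    drop = FALSE])
    sum(p[neuron]) / sum(p[setdiff(names(p), neuron)])
  }, numeric(1))
  g <- expand.grid(dataset = paste0("ds", seq_len(n_datasets)),
                   donor = paste0("D", seq_len(n_donors)),
                   major_region = majors, stringsAsFactors = FALSE)
  g$ratio <- with_seed(seed,
    true_ratio[g$major_region] * stats::rlnorm(nrow(g), 0, est_noise))
  rownames(g) <- NULL
  g
}
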