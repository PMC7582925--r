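test_that("the default cell-type list is the nine brain types", {
  expect_identical(brain_cell_types(),
                   c("interneuron", "S1 pyramidal", "CA1 pyramidal",
                     "oligodendrocyte", "microglia", "astrocyte",
                     "endothelial", "ependymal", "mural"))
  cfg <- synth_config()
  expect_identical(cfg$cell_types, brain_cell_types())
  # HumN-like misses every glial type; HumNG-like misses at least one
  expect_setequal(cfg$missing_types$HumN,
                  setdiff(brain_cell_types(), neuron_cell_types()))
  expect_gte(length(cfg$missing_types$HumNG), 1L)
  for (r in cfg$regions) {
    expect_true(all(r$composition >= 0))
    expect_equal(sum(r$composition), 1, tolerance = 1e-9)
  }
})

test_that("reference generation honors missing types and config errors", {
  cfg <- small_config()
  mus <- generate_reference(cfg, "mouse", "MusNG")
  expect_setequal(unique(mus$annotation$cell_type), brain_cell_types())
  hn <- generate_reference(cfg, "human", "HumN")
  expect_setequal(unique(hn$annotation$cell_type), neuron_cell_types())
  expect_true(all(hn$expr$values >= 0))
  expect_error(generate_reference(small_config(cells_per_type = 0)),
               "empty reference")
  expect_error(synth_config(n_genes = 50, markers_per_type = 10),
               "exceeds n_genes")
})

test_that("generators are seed-deterministic", {
  cfg <- small_config(seed = 42)
  r1 <- generate_reference(cfg, "mouse", "MusNG")
  r2 <- generate_reference(cfg, "mouse", "MusNG")
  expect_identical(r1$expr$values, r2$expr$values)
  sig <- raw_signatures(cfg)
  b1 <- generate_spatial_bulk(cfg, sig)
  b2 <- generate_spatial_bulk(cfg, sig)
  expect_identical(b1$samples$expr$values, b2$samples$expr$values)
  expect_identical(b1$truth$proportions, b2$truth$proportions)
})

test_that("marker genes have strictly higher expected mean in their own type", {
  cfg <- small_config(marker_fold = 4)
  mu <- crossdeconv:::expected_means(cfg)
  assign <- marker_assignment(cfg)
  for (t in cfg$cell_types) {
    idx <- which(unname(assign) == t)
    other <- setdiff(seq_len(ncol(mu)), match(t, colnames(mu)))
    expect_true(all(mu[idx, t] > apply(mu[idx, other, drop = FALSE], 1, max)))
  }
  # no-signal case: marker_fold = 1 makes all type means identical
  mu0 <- crossdeconv:::expected_means(small_config(marker_fold = 1))
  expect_true(all(mu0 == mu0[, 1]))
})

test_that("spatial bulk: truth on simplex, regions separated, donors agree", {
  cfg <- small_config(seed = 7)
  sig <- raw_signatures(cfg)
  out <- generate_spatial_bulk(cfg, sig)
  a <- out$truth$proportions
  expect_equal(unname(colSums(a)), rep(1, ncol(a)), tolerance = 1e-9)
  expect_true(all(a >= 0))
  expect_true(all(out$samples$expr$values >= 0))
  # between-major-region composition distance exceeds within-region
  reg <- out$truth$region_assignment
  cent <- sapply(unique(reg), function(r)
    rowMeans(a[, reg == r, drop = FALSE]))
  between <- min(dist(t(cent)))
  within <- max(vapply(unique(reg), function(r) {
    aa <- a[, reg == r, drop = FALSE]
    mean(sqrt(colSums((aa - rowMeans(aa))^2)))
  }, numeric(1)))
  expect_gt(between, within)
  # two donors from one region map agree per region within sampling error
  d <- out$truth$donor
  for (r in unique(reg)) {
    m1 <- rowMeans(a[, reg == r & d == "D01", drop = FALSE])
    m2 <- rowMeans(a[, reg == r & d == "D02", drop = FALSE])
    expect_lt(max(abs(m1 - m2)), 0.15)
  }
})

test_that("noiseless concentrated limit reproduces E times the region composition", {
  cfg <- small_config(noise_sd = 0, coord_noise = 0,
                      dirichlet_concentration = 1e9,
                      n_samples_per_region = 2, n_donors = 1)
  sig <- raw_signatures(cfg)
  out <- generate_spatial_bulk(cfg, sig)
  comp <- cfg$regions[[1]]$composition
  expected <- as.vector(sig$values[, cfg$cell_types] %*% comp)
  got <- out$samples$expr$values[, 1]
  expect_equal(unname(got), expected, tolerance = 1e-3)
})

test_that("connectivity/nuclei generator couples ratios to volume as configured", {
  cfg <- small_config(seed = 11)
  sig <- raw_signatures(cfg)
  truth <- generate_spatial_bulk(cfg, sig)$truth
  cn1 <- generate_connectivity_nuclei(cfg, truth, coupling = 1,
                                      nuclei_noise = 0)
  cn0 <- generate_connectivity_nuclei(cfg, truth, coupling = 0,
                                      nuclei_noise = 0)
  nr <- function(cn) cn$nuclei$neun / (cn$nuclei$dapi - cn$nuclei$neun)
  neuron <- neuron_cell_types()
  mrna <- vapply(cn1$nuclei$major_region, function(m) {
    p <- rowMeans(truth$proportions[, truth$region_assignment == m,
                                    drop = FALSE])
    sum(p[neuron]) / sum(p[setdiff(names(p), neuron)])
  }, numeric(1))
  # coupling 0: nuclei ratio tracks the mRNA ratio directly
  expect_equal(unname(nr(cn0)), unname(mrna), tolerance = 0.02)
  # coupling 1: nuclei ratio = mRNA ratio / volume mean
  expect_equal(unname(nr(cn1)),
               unname(mrna / cn1$volume_means[cn1$nuclei$major_region]),
               tolerance = 0.02)
  expect_error(
    generate_connectivity_nuclei(
      cfg, structure(list(proportions = truth$proportions,
                          region_assignment =
                            setNames(rep("spine", ncol(truth$proportions)),
                                     colnames(truth$proportions))),
                     class = "ground_truth")),
    "unknown region")
})

test_that("AD cohort: traits are monotone in severity and shift composition", {
  cfg <- small_config(seed = 3)
  sig <- raw_signatures(cfg)
  ad <- generate_ad_cohort(cfg, sig, n_samples = 300,
                           severity_effect = 0.3, seed = 9)
  # the three traits are positively rank-correlated via latent severity
  expect_gt(cor(ad$traits$CDR, ad$traits$BBS, method = "spearman"), 0.3)
  expect_gt(cor(ad$traits$CDR, ad$traits$PlaqueMean,
                method = "spearman"), 0.3)
  expect_gt(cor(ad$traits$PlaqueMean, ad$traits$BBS,
                method = "spearman"), 0.3)
  # neuron truth falls with severity, microglia rises
  s <- ad$truth$severity
  expect_lt(cor(colSums(ad$truth$proportions[neuron_cell_types(), ]), s), 0)
  expect_gt(cor(ad$truth$proportions["microglia", ], s), 0)
  expect_error(generate_ad_cohort(cfg, sig, n_samples = 2),
               "correlation undefined")
})

test_that("null AD cohort has near-zero expected trait correlations", {
  cfg <- small_config(seed = 5)
  sig <- raw_signatures(cfg)
  ad <- generate_ad_cohort(cfg, sig, n_samples = 400,
                           severity_effect = 0, seed = 13)
  r <- cor(ad$truth$proportions["microglia", ], ad$traits$CDR)
  expect_lt(abs(r), 0.12)
})
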