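test_that("major-region assignment agrees with a parent-chain oracle", {
  cfg <- small_config()
  h <- generate_region_hierarchy(cfg)
  for (id in h$nodes$id)
    expect_identical(assign_major_region(h, id),
                     parent_chain_major(h, id))
  expect_identical(assign_major_region(h, "cerebrum"), "cerebrum")
  expect_identical(assign_major_region(h, "hippocampus / core"),
                   "cerebrum")
  expect_identical(assign_major_region(h, "white matter tracts"), "other")
  expect_error(assign_major_region(h, "nonexistent"), "unknown region")
  # random trees: BFS matches parent-chain walking
  set.seed(3)
  for (rep in 1:5) {
    n <- 30
    parent <- c(NA, "cerebrum", "brainstem", "cerebellum",
                sample(c("r1", "r2", "r3", "r4"), n - 4, TRUE))
    ids <- c("root", "cerebrum", "brainstem", "cerebellum",
             paste0("n", 5:n))
    # attach the first generation to known nodes
    parent[2:4] <- "root"
    parent[5:8] <- sample(c("cerebrum", "brainstem", "cerebellum",
                            "root"), 4, TRUE)
    ids[5:8] <- c("r1", "r2", "r3", "r4")
    ht <- region_hierarchy(data.frame(id = ids, name = ids,
                                      parent = parent))
    for (id in ids)
      expect_identical(assign_major_region(ht, id),
                       parent_chain_major(ht, id))
  }
  expect_error(region_hierarchy(data.frame(id = c("a", "b", "cerebrum",
                                                  "brainstem",
                                                  "cerebellum"),
                                           parent = c("b", "a", NA, NA,
                                                      NA))),
               "cycle")
})

test_that("projection volume averages injection + target per major region", {
  cfg <- small_config()
  h <- generate_region_hierarchy(cfg)
  conn <- data.frame(
    region_id = c("frontal cortex", "frontal cortex", "pons",
                  "cerebellar cortex", "white matter tracts"),
    injection_volume = c(1, 3, 2, 0.5, 100),
    target_volume = c(1, 3, 3, 0.3, 100))
  v <- projection_volume(conn, h)
  expect_equal(v[["cerebrum"]], mean(c(2, 6)))
  expect_equal(v[["brainstem"]], 5)
  expect_equal(v[["cerebellum"]], 0.8)   # "other" experiments excluded
  expect_error(projection_volume(conn[1:2, ], h), "no experiments")
})

test_that("neuron ratio and volume adjustment behave as documented", {
  alpha <- setNames(rep(1 / 9, 9), brain_cell_types())
  expect_equal(neuron_ratio(alpha), 0.5)   # 3 neuron / 6 non-neuron types
  a2 <- setNames(c(0.4, 0.1, 0.1, rep(0.4 / 6, 6)), brain_cell_types())
  expect_equal(neuron_ratio(a2), 1.5)
  a3 <- setNames(c(1 / 3, 1 / 3, 1 / 3, rep(0, 6)), brain_cell_types())
  expect_true(is.na(neuron_ratio(a3)))     # all-neuron: undefined, no error
  expect_equal(adjust_ratio(1.5, 3), 0.5)
  expect_equal(adjust_ratio(2.2, 1), 2.2)
  expect_error(adjust_ratio(1, 0), "positive")
})

test_that("volume adjustment improves nuclei agreement when coupling = 1", {
  cfg <- small_config(seed = 51)
  sig <- raw_signatures(cfg)
  truth <- generate_spatial_bulk(cfg, sig)$truth
  cn <- generate_connectivity_nuclei(cfg, truth, coupling = 1)
  h <- generate_region_hierarchy(cfg)
  vols <- projection_volume(cn$connectivity, h)
  ratios <- simulate_ratio_estimates(truth, seed = 5)
  rec <- reconcile_with_nuclei(ratios, cn$nuclei, vols)
  expect_gt(rec$pcc_adjusted, rec$pcc_unadjusted)
  expect_lt(rec$p_adjusted, 0.01)
  # invariance to a global volume rescale
  rec2 <- reconcile_with_nuclei(ratios, cn$nuclei, vols * 7)
  expect_equal(rec2$pcc_adjusted, rec$pcc_adjusted, tolerance = 1e-12)
  # equal volumes: adjustment is a constant divisor, PCCs match
  rec3 <- reconcile_with_nuclei(ratios, cn$nuclei,
                                setNames(rep(2, 3), names(vols)))
  expect_equal(rec3$pcc_adjusted, rec3$pcc_unadjusted, tolerance = 1e-12)
  # perfect linear relation gives PCC 1
  lin <- data.frame(major_region = rep(cn$nuclei$major_region, 2))
  nuc_r <- cn$nuclei$neun / (cn$nuclei$dapi - cn$nuclei$neun)
  lin$ratio <- 3 * rep(nuc_r, 2)
  recl <- reconcile_with_nuclei(lin, cn$nuclei,
                                setNames(rep(1, 3),
                                         cn$nuclei$major_region))
  expect_equal(recl$pcc_unadjusted, 1, tolerance = 1e-12)
  expect_error(reconcile_with_nuclei(lin[1:2, ], cn$nuclei,
                                     vols), ">= 3 matched points")
})

test_that("end-to-end: deconvolution-based ratios favor adjustment under coupling", {
  cfg <- small_config(seed = 55, n_donors = 2)
  sig <- raw_signatures(cfg)
  out <- generate_spatial_bulk(cfg, sig)
  cn <- generate_connectivity_nuclei(cfg, out$truth, coupling = 1)
  h <- generate_region_hierarchy(cfg)
  vols <- projection_volume(cn$connectivity, h)
  fit <- deconvolve(zscore_samples(out$samples$expr), sig)
  meta <- out$samples$meta
  props <- coef(fit)
  rows <- do.call(rbind, lapply(unique(meta$donor), function(d)
    do.call(rbind, lapply(unique(meta$major_region), function(r) {
      ids <- meta$sample_id[meta$donor == d & meta$major_region == r]
      data.frame(donor = d, major_region = r,
                 ratio = mean(vapply(ids, function(s)
                   neuron_ratio(props[, s]), numeric(1)), na.rm = TRUE))
    }))))
  rec <- reconcile_with_nuclei(rows, cn$nuclei, vols)
  expect_gt(rec$pcc_adjusted, rec$pcc_unadjusted)
})

test_that("one-way ANOVA: F = t^2 identity and sensitivity to mean shifts", {
  set.seed(21)
  x <- c(rnorm(12), rnorm(12, 0.5))
  g <- rep(c("a", "b"), each = 12)
  p_aov <- anova_by_region(x, g)
  p_t <- t.test(x ~ g, var.equal = TRUE)$p.value
  expect_equal(p_aov, p_t, tolerance = 1e-12)
  y <- c(rnorm(15), rnorm(15, 5), rnorm(15, 10))
  expect_lt(anova_by_region(y, rep(c("a", "b", "c"), each = 15)), 1e-3)
  expect_error(anova_by_region(c(1, 2, 3), c("a", "a", "b")),
               "single value")
  # calibration under equal means
  ps <- vapply(1:300, function(i) {
    set.seed(5000 + i)
    anova_by_region(rnorm(30), rep(c("a", "b", "c"), each = 10))
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("AD trait correlations report the expected sign pattern and flag degenerates", {
  cfg <- small_config(seed = 61)
  sig <- raw_signatures(cfg)
  ad <- generate_ad_cohort(cfg, sig, n_samples = 300,
                           severity_effect = 0.3, seed = 2)
  tab <- ad_trait_correlations(ad$truth$proportions, ad$traits)
  neuron_rows <- tab$cell_type %in% neuron_cell_types()
  expect_true(all(tab$pcc[neuron_rows] < 0))
  expect_true(all(tab$pcc[tab$cell_type == "microglia"] > 0))
  # constant trait flagged undefined
  tr2 <- ad$traits; tr2$CDR <- 1
  tab2 <- ad_trait_correlations(ad$truth$proportions, tr2)
  expect_true(all(tab2$undefined[tab2$trait == "CDR"]))
  expect_error(ad_trait_correlations(ad$truth$proportions,
                                     ad$traits[1:2, ]), ">= 3 samples")
})

test_that("shipped example files load through the readers", {
  hf <- system.file("extdata", "example_hierarchy.tsv",
                    package = "crossdeconv")
  h <- read_region_hierarchy(hf)
  expect_identical(assign_major_region(h, "CA1"), "cerebrum")
  expect_identical(assign_major_region(h, "white matter tracts"), "other")
  mf <- system.file("extdata", "example_homologs.tsv",
                    package = "crossdeconv")
  m <- read_homolog_map(mf)
  expect_equal(nrow(m$pairs), 10)
  expect_identical(m$pairs$human_gene[m$pairs$mouse_gene == "Gfap"],
                   "GFAP")
})
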