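test_that("max smoothing matches the O(n^2) oracle and its invariants", {
  set.seed(12)
  n <- 60
  props <- matrix(runif(9 * n), 9, n,
                  dimnames = list(brain_cell_types(), sprintf("s%02d", 1:n)))
  coords <- matrix(rnorm(n * 3), n, 3)
  sm <- smooth_proportions(props, coords, 5)
  expect_equal(sm, smooth_oracle(props, coords, 5))
  expect_true(all(sm >= props))           # self included in neighborhood
  const <- matrix(0.5, 9, n, dimnames = dimnames(props))
  expect_equal(smooth_proportions(const, coords, 5), const)
  # a high spike propagates to neighbors that count it among their 5 NN
  props2 <- matrix(0, 2, 20,
                   dimnames = list(c("a", "b"), sprintf("s%02d", 1:20)))
  coords2 <- matrix(rnorm(60), 20, 3)
  props2[1, 7] <- 1
  sm2 <- smooth_proportions(props2, coords2, 5)
  d <- as.matrix(dist(coords2))
  receivers <- which(vapply(1:20, function(j)
    7 %in% order(d[j, ])[1:5], logical(1)))
  expect_true(all(sm2[1, receivers] == 1))
  expect_true(all(sm2[1, -receivers] == 0))
  expect_error(smooth_proportions(props2[, 1:3], coords2[1:3, ], 5),
               "fewer samples")
})

test_that("PCA + K-means separates distinct composition blobs deterministically", {
  cfg <- small_config(seed = 23, dirichlet_concentration = 300)
  sig <- raw_signatures(cfg)
  out <- generate_spatial_bulk(cfg, sig)
  props <- out$truth$proportions
  cl <- cluster_regions(props, k = 3, seed = 5)
  sc <- score_clusters(cl$labels, out$truth$region_assignment)
  expect_gte(sc$accuracy, 0.95)
  cl2 <- cluster_regions(props, k = 3, seed = 5)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(ncol(cl$pca), 2L)
  expect_error(cluster_regions(matrix(0.5, 3, 10,
    dimnames = list(letters[1:3], letters[11:20]))), "no variation")
  expect_error(cluster_regions(props[, 1:2], k = 3), "exceeds")
})

test_that("cluster scoring picks the best assignment and is relabeling-invariant", {
  truth <- rep(c("cerebrum", "brainstem", "cerebellum"), each = 10)
  labels <- rep(c(2, 3, 1), each = 10)
  sc <- score_clusters(labels, truth)
  expect_equal(sc$accuracy, 1)
  expect_true(all(sc$sensitivity == 1) && all(sc$specificity == 1))
  relabeled <- c(3, 1, 2)[labels]
  sc2 <- score_clusters(relabeled, truth)
  expect_equal(sc2$accuracy, sc$accuracy)
  expect_equal(sc2$sensitivity, sc$sensitivity)
  # random labels on balanced 3-class data: accuracy of the best
  # permutation concentrates a little above 1/3
  set.seed(9)
  accs <- replicate(300, score_clusters(sample(1:3, 30, TRUE),
                                        truth)$accuracy)
  expect_gt(mean(accs), 1 / 3)
  expect_lt(mean(accs), 0.55)
})

test_that("MANOVA detects an injected region effect and stays calibrated under the null", {
  tab <- simulate_score_table(region_effect = 0.1, noise_sd = 0.05,
                              seed = 31)
  p <- manova_confounders(tab)
  expect_lt(p[["region"]], 0.05)
  expect_gt(p[["dataset"]], 0.05)
  expect_gt(p[["donor"]], 0.05)
  # null calibration: p-values roughly uniform over replicates
  ps <- vapply(1:200, function(i)
    manova_confounders(simulate_score_table(region_effect = 0,
                                            noise_sd = 0.05,
                                            seed = 1000 + i))[["region"]],
    numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  bad <- simulate_score_table(seed = 1)
  bad$dataset <- "only"
  expect_error(manova_confounders(bad), "single level")
})

test_that("donor consistency beats the shuffled-donor control on shared maps", {
  cfg <- small_config(seed = 41, n_donors = 3)
  sig <- raw_signatures(cfg)
  out <- generate_spatial_bulk(cfg, sig)
  dc <- donor_consistency(out$truth$proportions, out$samples$meta,
                          n_shuffles = 50, seed = 2)
  expect_equal(diag(dc$pcc), rep(1, 3), ignore_attr = TRUE)
  expect_gt(dc$mean_real_pcc, mean(dc$random_pcc))
  # identical donors correlate perfectly
  meta2 <- out$samples$meta
  p2 <- out$truth$proportions
  d1 <- meta2$donor == "D01"
  p2[, meta2$sample_id[meta2$donor == "D02"]] <-
    p2[, meta2$sample_id[d1]]
  dc2 <- donor_consistency(p2[, meta2$sample_id[meta2$donor %in%
                                                  c("D01", "D02")]],
                           meta2[meta2$donor %in% c("D01", "D02"), ],
                           n_shuffles = 5, seed = 1)
  expect_equal(dc2$pcc[1, 2], 1, tolerance = 1e-12)
  expect_error(donor_consistency(p2, meta2[meta2$donor == "D01", ]),
               ">= 2 donors")
})

test_that("cross-dataset correlations resolve merged types and count 23 of 27", {
  set.seed(13)
  n <- 40
  types <- brain_cell_types()
  base <- matrix(runif(9 * n), 9, n,
                 dimnames = list(types, sprintf("s%02d", 1:n)))
  noisy <- function() pmax(base + matrix(rnorm(9 * n, sd = 0.05), 9, n), 0)
  full1 <- noisy(); full2 <- noisy()
  merged <- noisy()
  merged_m <- rbind(`cortical neuron` = colSums(
    merged[c("interneuron", "S1 pyramidal"), ]),
    merged[setdiff(types, c("interneuron", "S1 pyramidal")), ])
  ests <- list(ds1 = full1, ds2 = full2, ds3 = merged_m)
  tm <- list(ds3 = list(`cortical neuron` = c("interneuron",
                                              "S1 pyramidal")))
  out <- crossdataset_correlations(ests, tm)
  expect_equal(sum(!out$missing), 23)   # 9 + 7 + 7 resolvable
  expect_true(all(out$q[!out$missing] <= 1))
  # identical matrices correlate at 1 for every same-type pair
  out2 <- crossdataset_correlations(list(a = base, b = base))
  expect_equal(out2$pcc[!out2$missing], rep(1, 9), tolerance = 1e-12)
  # BH-FDR matches the hand-computed step-up on its own p-values
  ok <- !is.na(out$p)
  expect_equal(out$q[ok], bh_oracle(out$p[ok]), tolerance = 1e-12)
  expect_error(crossdataset_correlations(
    list(a = base, b = `colnames<-`(base, paste0("x", 1:n)))),
    "no shared samples")
})

test_that("BH-FDR of (0.01, 0.02, 0.03) is 0.03 for all three", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # monotone non-decreasing in sorted p order, bounded by 1
  set.seed(2)
  p <- runif(50)
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))
  expect_equal(q, bh_oracle(p), tolerance = 1e-12)
})
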