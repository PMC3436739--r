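# Synthetic benchmark generator: configurations, dissimilarities, trees.

test_that("L-shape construction: spacing, corner, determinism", {
  tr <- makeConfiguration(4, 3, spacing = 1, jitter = 0)
  expect_equal(length(tr$unit_ids), 7L)
  # consecutive same-arm points at distance exactly 1
  arm1 <- tr$xyz[tr$arm == "arm1", ]
  d1 <- sqrt(rowSums(diff(arm1)^2))
  expect_equal(unname(d1), rep(1, 3))
  arm2 <- tr$xyz[tr$arm == "arm2", ]
  d2 <- sqrt(rowSums(diff(arm2)^2))
  expect_equal(unname(d2), rep(1, 2))
  # exactly one point sits on both arm axes (the shared corner)
  on_both <- abs(tr$xyz[, "x"]) < 1e-12 & abs(tr$xyz[, "y"]) < 1e-12
  expect_equal(sum(on_both), 1L)
  # arms are perpendicular
  expect_equal(unname(crossprod(arm1[4, ] - arm1[1, ],
                                arm2[3, ] - tr$xyz[on_both, ])[1, 1]), 0)
  # determinism under jitter
  a <- makeConfiguration(5, 4, jitter = 0.2, seed = 7)
  b <- makeConfiguration(5, 4, jitter = 0.2, seed = 7)
  expect_identical(a$xyz, b$xyz)
  expect_error(makeConfiguration(2, 1), "at least 4")
})

test_that("noiseless dissimilarities are exactly affine in true distance", {
  tr <- makeConfiguration(7, 5, jitter = 0.1, seed = 3)
  D <- noisyDissimilarities(tr, intercept = 0, slope = 1, noise_sd = 0)
  Dt <- as.matrix(dist(tr$xyz))
  expect_equal(D, Dt / max(Dt), tolerance = 1e-12)
  ag <- distanceAgreement(D, Dt)
  expect_equal(ag$r_squared, 1, tolerance = 1e-12)
  # embedding recovers the truth up to similarity transform
  emb <- classicalMDS(D, k = 3)
  fit <- procrustesFit(emb, tr$xyz)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(emb$Pk, 1, tolerance = 1e-9)
})

test_that("dissimilarities are symmetric, in [0,1], zero-diagonal, seeded", {
  tr <- makeConfiguration(6, 4, jitter = 0, seed = 1)
  D <- noisyDissimilarities(tr, intercept = 0.2, slope = 1, noise_sd = 0.3,
                            seed = 11)
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(diag(D) == 0))
  expect_equal(max(D), 1)
  D2 <- noisyDissimilarities(tr, intercept = 0.2, slope = 1, noise_sd = 0.3,
                             seed = 11)
  expect_identical(D, D2)
})

test_that("recovered-vs-true correlation degrades monotonically with noise", {
  tr <- makeConfiguration(7, 5, jitter = 0, seed = 2)
  Dt <- as.matrix(dist(tr$xyz))
  mean_r2 <- vapply(c(0.05, 0.3, 1.2), function(ns) {
    mean(vapply(1:25, function(rep) {
      D <- noisyDissimilarities(tr, intercept = 0, slope = 1,
                                noise_sd = ns, seed = 1000 * ns + rep)
      emb <- suppressWarnings(classicalMDS(D, k = 3))
      distanceAgreement(configurationDistances(emb), Dt)$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("zero rate dispersion collapses all unit trees onto the species tree", {
  tr <- makeConfiguration(4, 2, jitter = 0, seed = 5)
  trees <- simulateRateCorrelatedTrees(tr, n_species = 20, sigma_rate = 0,
                                       seed = 8)
  expect_length(trees, 6L)
  ref <- trees[[1]]$tree
  for (ft in trees) {
    expect_identical(ft$tree$edge, ref$edge)
    expect_equal(ft$tree$edge.length, ref$edge.length, tolerance = 1e-15)
  }
  vecs <- lapply(trees, patristicVector)
  set <- suppressWarnings(assembleVectorSet(vecs, min_vector_count = 1,
                                            min_units_per_species = 1,
                                            min_shared_species = 0))
  resid <- correctedVectors(set)
  expect_true(all(abs(resid) < 1e-10))
})

test_that("simulated trees are seed-deterministic and dropout thins coverage", {
  tr <- makeConfiguration(4, 2, jitter = 0, seed = 5)
  a <- simulateRateCorrelatedTrees(tr, n_species = 25, sigma_rate = 0.5,
                                   dropout = 0.2, seed = 14)
  b <- simulateRateCorrelatedTrees(tr, n_species = 25, sigma_rate = 0.5,
                                   dropout = 0.2, seed = 14)
  for (i in seq_along(a))
    expect_identical(ape::write.tree(a[[i]]$tree),
                     ape::write.tree(b[[i]]$tree))
  sizes <- vapply(a, function(ft) length(ft$tree$tip.label), integer(1))
  expect_true(any(sizes < 25))
  expect_true(all(sizes >= 4))
})

test_that("a global rate process is removed by the averaged-reference projection", {
  # corr_length far beyond the configuration extent: all units share one
  # rate process, so corrected correlations should collapse toward zero
  tr <- makeConfiguration(4, 3, jitter = 0, seed = 6)
  offdiag <- function(m) m[upper.tri(m)]
  raw_r <- c(); corr_r <- c()
  for (seed in 1:6) {
    trees <- simulateRateCorrelatedTrees(tr, n_species = 40,
                                         sigma_rate = 0.6,
                                         corr_length = 1e6, seed = seed)
    vecs <- lapply(trees, patristicVector)
    set <- suppressWarnings(assembleVectorSet(vecs, min_vector_count = 1,
                                              min_units_per_species = 1,
                                              min_shared_species = 0))
    raw <- cor(set$values, method = "spearman")
    raw_r <- c(raw_r, mean(offdiag(raw)))
    cm <- coevolutionMatrix(set)
    corr_r <- c(corr_r, mean(offdiag(cm$rho)))
  }
  expect_gt(mean(raw_r), 0.8)            # uncorrected vectors mirror heavily
  expect_lt(abs(mean(corr_r)), 0.25)     # projection strips the shared signal
})

test_that("tree sets round-trip through Newick files and the manifest", {
  tr <- makeConfiguration(4, 2, jitter = 0, seed = 9)
  trees <- simulateRateCorrelatedTrees(tr, n_species = 15, sigma_rate = 0.3,
                                       seed = 10)
  dir <- withr::local_tempdir()
  manifest <- writeTreeSet(trees, dir)
  df <- read.table(manifest, sep = "\t", header = TRUE)
  expect_equal(df$unit, tr$unit_ids)
  back <- readFamilyTree(df$path[1], unit_id = df$unit[1],
                         leaf_pattern = NULL)
  expect_equal(sort(back$tree$tip.label), sort(trees[[1]]$tree$tip.label))
  expect_equal(patristicVector(back), patristicVector(trees[[1]]),
               tolerance = 1e-9)
})
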