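# Tree reading, patristic distance extraction, and vector-set assembly.

test_that("newick parsing extracts species from leaf labels", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A_homo:0.1,B_mus:0.2);", f)
  ft <- readFamilyTree(f, unit_id = "toy")
  expect_s3_class(ft, "FamilyTree")
  expect_setequal(ft$tree$tip.label, c("homo", "mus"))
  expect_equal(unname(ft$leaf_to_species[c("A_homo", "B_mus")]),
               c("homo", "mus"))
  v <- patristicVector(ft)
  expect_equal(unname(v["homo|mus"]), 0.3)
})

test_that("NHX annotation blocks are stripped before parsing", {
  f <- withr::local_tempfile(fileext = ".nhx")
  writeLines("(1_homo:0.1[&&NHX:S=hs],2_mus:0.2[&&NHX:S=mm]):0.0[&&NHX:D=N];",
             f)
  ft <- readFamilyTree(f, unit_id = "nhx")
  expect_setequal(ft$tree$tip.label, c("homo", "mus"))
  expect_equal(unname(patristicVector(ft)["homo|mus"]), 0.3)
})

test_that("duplicate species and unmatchable leaf labels are errors", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A_homo:0.1,B_homo:0.2);", f)
  expect_error(readFamilyTree(f, unit_id = "dup"), "duplicate species")
  writeLines("(nounderscore:0.1,B_mus:0.2);", f)
  expect_error(readFamilyTree(f, unit_id = "bad"), "leaf_pattern")
})

test_that("negative branch lengths are clamped to zero with a warning", {
  tr <- ape::read.tree(text = "((a:0.1,b:-0.001):0.2,c:0.3);")
  expect_warning(ft <- familyTree(tr, "neg", leaf_pattern = NULL),
                 "negative branch")
  expect_true(all(ft$tree$edge.length >= 0))
})

test_that("read/write round-trip preserves patristic distances to 1e-9", {
  set.seed(42)
  tr <- ape::rtree(20)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, file = f)
  ft <- readFamilyTree(f, unit_id = "rt", leaf_pattern = NULL)
  expect_equal(ape::cophenetic.phylo(ft$tree)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr), tolerance = 1e-9)
})

test_that("patristic distances match a brute-force shortest-path oracle", {
  set.seed(7)
  for (rep in 1:3) {
    tr <- ape::rtree(15)
    ft <- familyTree(tr, "bf", leaf_pattern = NULL)
    v <- patristicVector(ft)
    D <- bruteForcePatristic(tr)
    sp <- sort(rownames(D))
    pairs <- t(combn(sp, 2L))
    expect_equal(unname(v[pairKeyT(pairs)]),
                 unname(D[pairs]), tolerance = 1e-12)
  }
})

test_that("star tree with unit terminal branches gives all distances 2", {
  tr <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  v <- patristicVector(familyTree(tr, "star", leaf_pattern = NULL))
  expect_true(all(abs(v - 2) < 1e-12))
})

test_that("patristic distance is a root-invariant metric", {
  set.seed(11)
  tr <- ape::rtree(12)
  ft <- familyTree(tr, "m", leaf_pattern = NULL)
  v1 <- patristicVector(ft)
  expect_true(all(v1 >= 0))
  # re-rooting changes nothing
  tr2 <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[5],
                   resolve.root = TRUE)
  v2 <- patristicVector(familyTree(tr2, "m", leaf_pattern = NULL))
  expect_equal(as.numeric(v2[names(v1)]), as.numeric(v1), tolerance = 1e-9)
  # triangle inequality on every species triple
  D <- bruteForcePatristic(tr)
  sp <- rownames(D)
  for (trip in combn(length(sp), 3L, simplify = FALSE)) {
    i <- trip[1]; j <- trip[2]; k <- trip[3]
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("identity filters keep every pair and species", {
  set0 <- randomVectorSet(n_units = 5, n_species = 8, seed = 3,
                          mask_prob = 0.3, min_vector_count = 1,
                          min_units_per_species = 1)
  expect_equal(length(set0$species), 8L)
  expect_equal(nrow(set0$values), choose(8, 2))
})

test_that("species below the per-species unit threshold lose all pairs", {
  set.seed(5)
  species <- sprintf("sp%02d", 1:10)
  pairs <- t(combn(species, 2L))
  vectors <- lapply(1:10, function(u) {
    vals <- runif(nrow(pairs), 0.5, 2)
    # species sp01 occurs in only 3 of 10 units
    if (u > 3) vals[pairs[, 1] == "sp01" | pairs[, 2] == "sp01"] <- NA
    speciesPairVector(vals, pairs, unit_id = paste0("u", u))
  })
  set <- suppressWarnings(assembleVectorSet(
    vectors, min_vector_count = 1, min_units_per_species = 8,
    min_shared_species = 0))
  expect_false("sp01" %in% set$species)
  expect_false(any(grepl("sp01", rownames(set$values))))
  expect_true("sp01" %in% set$attrition$species_dropped)
})

test_that("raising min_vector_count never adds pairs (monotone filter)", {
  for (seed in 1:5) {
    sets <- lapply(c(2, 3, 4), function(mv)
      randomVectorSet(n_units = 6, n_species = 10, seed = seed,
                      mask_prob = 0.4, min_vector_count = mv))
    idx <- lapply(sets, function(s) rownames(s$values))
    expect_true(all(idx[[2]] %in% idx[[1]]))
    expect_true(all(idx[[3]] %in% idx[[2]]))
  }
})

test_that("low shared-species unit pairs warn but do not error", {
  set.seed(9)
  species <- sprintf("sp%02d", 1:12)
  pairs <- t(combn(species, 2L))
  mk <- function(id, keep) {
    vals <- runif(nrow(pairs), 0.5, 2)
    vals[!(pairs[, 1] %in% keep & pairs[, 2] %in% keep)] <- NA
    speciesPairVector(vals, pairs, unit_id = id)
  }
  vectors <- list(mk("a", species[1:6]), mk("b", species[7:12]),
                  mk("c", species))
  expect_warning(
    set <- assembleVectorSet(vectors, min_vector_count = 1,
                             min_units_per_species = 1,
                             min_shared_species = 3),
    "share fewer than 3 species")
  expect_s3_class(set, "VectorSet")
})

test_that("fewer than two vectors is an error", {
  v <- randomVectorSet(n_units = 2, n_species = 6, seed = 1, mask_prob = 0)
  expect_error(assembleVectorSet(list()), "at least 2")
})

test_that("long-format export contains one row per present pair", {
  set <- randomVectorSet(n_units = 4, n_species = 7, seed = 2,
                         mask_prob = 0.25)
  df <- writeVectorSet(set)
  expect_named(df, c("unit", "species_a", "species_b", "distance"))
  expect_equal(nrow(df), sum(!is.na(set$values)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeVectorSet(set, f)
  back <- read.table(f, sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(df))
})
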