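# Synthetic benchmark generator: ground-truth L-shaped configurations,
# noisy dissimilarities, and species trees with distance-correlated
# branch-rate multipliers. Everything is seed-deterministic.

#' Ground-truth L-shaped configuration
#'
#' Generates a two-armed ("L-shaped") arrangement of unit centers emulating
#' the geometry of a two-arm protein complex: `n_arm1` points along the
#' x axis and `n_arm2` points along the y axis, both emanating from a shared
#' corner at the origin (the corner point itself belongs to arm 1), at the
#' given spacing and with isotropic Gaussian jitter.
#'
#' @param n_arm1,n_arm2 points per arm; `n_arm1 + n_arm2 >= 4`.
#' @param spacing distance between consecutive points on an arm (arbitrary
#'   units, default 1).
#' @param jitter standard deviation of the Gaussian jitter applied to every
#'   coordinate (default 0).
#' @param seed integer seed (used only when `jitter > 0`).
#' @return an object of class `"GroundTruth"`: list with `xyz` (n x 3
#'   matrix, rownames `u01`, `u02`, ...), `unit_ids`, `arm` (factor
#'   `"arm1"`/`"arm2"`), `geometry`.
#' @export
makeConfiguration <- function(n_arm1 = 7L, n_arm2 = 5L, spacing = 1,
                              jitter = 0, seed = 1L) {
  if (n_arm1 + n_arm2 < 4L) stop("need at least 4 units", call. = FALSE)
  stopifnot(n_arm1 >= 1L, n_arm2 >= 0L, spacing > 0)
  xyz1 <- cbind(x = (seq_len(n_arm1) - 1L) * spacing, y = 0, z = 0)
  xyz2 <- if (n_arm2 > 0L)
    cbind(x = 0, y = seq_len(n_arm2) * spacing, z = 0)
  else matrix(numeric(0), 0L, 3L)
  xyz <- rbind(xyz1, xyz2)
  n <- nrow(xyz)
  ids <- sprintf("u%02d", seq_len(n))
  rownames(xyz) <- ids
  colnames(xyz) <- c("x", "y", "z")
  if (jitter > 0) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv))
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(3L * n, sd = jitter), n, 3L)
  }
  structure(list(xyz = xyz, unit_ids = ids,
                 arm = factor(rep(c("arm1", "arm2"), c(n_arm1, n_arm2))),
                 geometry = "L-shape"),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth (", x$geometry, "): ", length(x$unit_ids), " units (",
      paste(table(x$arm), collapse = " + "), ")\n", sep = "")
  invisible(x)
}

#' Noisy affine dissimilarities from a ground-truth configuration
#'
#' Emulates the empirical linear relation between co-evolutionary and
#' physical distance: `d_ij = intercept + slope * |x_i - x_j| + e_ij` with
#' i.i.d. Gaussian noise on the upper triangle, clipped at 0, mirrored to a
#' symmetric zero-diagonal matrix, and rescaled to `[0, 1]`.
#'
#' @param truth a `"GroundTruth"` (see [makeConfiguration()]) or an n x 3
#'   coordinate matrix with unit rownames.
#' @param intercept,slope affine map from physical distance to
#'   dissimilarity; `slope > 0`.
#' @param noise_sd Gaussian noise standard deviation (same units as the
#'   affine map output).
#' @param seed integer seed.
#' @return symmetric dissimilarity matrix in `[0, 1]`.
#' @export
noisyDissimilarities <- function(truth, intercept = 0, slope = 1,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(slope > 0, noise_sd >= 0)
  xyz <- if (inherits(truth, "GroundTruth")) truth$xyz else as.matrix(truth)
  D <- as.matrix(stats::dist(xyz))
  d <- intercept + slope * D
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv))
    set.seed(seed)
    n <- nrow(D)
    E <- matrix(0, n, n)
    E[upper.tri(E)] <- stats::rnorm(n * (n - 1L) / 2L, sd = noise_sd)
    d <- d + E + t(E)
  }
  d <- pmax(d, 0)
  diag(d) <- 0
  mx <- max(d)
  if (mx > 0) d <- d / mx
  d
}

#' Species trees with distance-correlated branch-rate multipliers
#'
#' Generates the mirror-tree signal from first principles: one pure-birth
#' species tree with `n_species` leaves is simulated, and each unit `u`
#' receives a copy in which branch `e` has length
#' `base(e) * exp(z_u(e))`, where for every branch the vector `z(e)` over
#' units is multivariate normal with covariance
#' `Sigma_uv = sigma_rate^2 * exp(-|x_u - x_v| / corr_length)`.
#' Physically close units thus share correlated rate excursions, which is
#' exactly the signal the phylogeny-corrected correlation recovers. Species
#' coverage can be thinned at random per unit to emulate missing orthologs.
#'
#' @param truth a `"GroundTruth"` configuration.
#' @param n_species number of species in the pure-birth tree (default 60).
#' @param birth_rate per-lineage speciation rate (default 1).
#' @param sigma_rate lognormal standard deviation of the branch-rate
#'   multipliers (default 0.5); 0 gives all units the species tree exactly.
#' @param corr_length distance scale of the rate-correlation decay; default
#'   one third of the configuration's largest extent.
#' @param dropout per-unit probability that a species is dropped
#'   (default 0); at least 4 species are always retained.
#' @param seed integer seed.
#' @return list of `"FamilyTree"` objects, one per unit of `truth`.
#' @export
simulateRateCorrelatedTrees <- function(truth, n_species = 60L,
                                        birth_rate = 1, sigma_rate = 0.5,
                                        corr_length = NULL, dropout = 0,
                                        seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"), n_species >= 4L,
            birth_rate > 0, sigma_rate >= 0, dropout >= 0, dropout < 1)
  Dx <- as.matrix(stats::dist(truth$xyz))
  if (is.null(corr_length)) corr_length <- max(Dx) / 3
  stopifnot(corr_length > 0)
  n_units <- length(truth$unit_ids)

  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = .GlobalEnv))
  set.seed(seed)
  sp_tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  sp_tree$tip.label <- sprintf("s%03d", seq_len(n_species))
  n_edges <- nrow(sp_tree$edge)

  if (sigma_rate > 0) {
    Sigma <- sigma_rate^2 * exp(-Dx / corr_length)
    L <- t(chol(Sigma + diag(1e-12, n_units)))
    Z <- L %*% matrix(stats::rnorm(n_units * n_edges), n_units, n_edges)
  } else {
    Z <- matrix(0, n_units, n_edges)
  }

  trees <- vector("list", n_units)
  names(trees) <- truth$unit_ids
  for (u in seq_len(n_units)) {
    tr <- sp_tree
    tr$edge.length <- tr$edge.length * exp(Z[u, ])
    if (dropout > 0) {
      drop <- tr$tip.label[stats::runif(n_species) < dropout]
      keep_n <- n_species - length(drop)
      if (keep_n < 4L)
        drop <- utils::head(drop, n_species - 4L)
      if (length(drop)) tr <- ape::drop.tip(tr, drop)
    }
    trees[[u]] <- familyTree(tr, unit_id = truth$unit_ids[u],
                             leaf_pattern = NULL, min_leaves = 4L)
  }
  trees
}

#' Write simulated family trees and a manifest
#'
#' Serializes a list of family trees as Newick files plus a two-column
#' manifest (`unit`, `path`) so the set can be consumed by the pipeline
#' like any real input.
#'
#' @param trees list of `"FamilyTree"` objects.
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
writeTreeSet <- function(trees, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(trees))
  for (i in seq_along(trees)) {
    ft <- trees[[i]]
    paths[i] <- file.path(dir, paste0(ft$unit_id, ".nwk"))
    ape::write.tree(ft$tree, file = paths[i])
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(unit = vapply(trees, `[[`, character(1), "unit_id"),
               path = paths),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
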