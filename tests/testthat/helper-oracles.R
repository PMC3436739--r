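# Independent oracles and fixture builders used across the suite.

# Brute-force patristic distances: shortest paths on the tree graph by
# depth-first traversal from every tip, independent of ape's cophenetic.
bruteForcePatristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  adj <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  D <- matrix(0, n_tip, n_tip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (start in seq_len(n_tip)) {
    dist_to <- rep(NA_real_, n_node)
    dist_to[start] <- 0
    stack <- start
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1L]; w <- adj[[v]][r, 2L]
        if (is.na(dist_to[u])) {
          dist_to[u] <- dist_to[v] + w
          stack <- c(stack, u)
        }
      }
    }
    D[start, ] <- dist_to[seq_len(n_tip)]
  }
  D
}

# Canonical "a|b" pair keys for a 2-column species-pair matrix.
pairKeyT <- function(pairs) {
  a <- pairs[, 1L]; b <- pairs[, 2L]
  swap <- a > b
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
}

# Naive Spearman: average ranks by hand, then textbook Pearson.
naiveSpearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Quaternion-parameterized numeric minimizer of the similarity-Procrustes
# objective sum |y_i - s R(q) x_i|^2 (configurations already centered).
quatRotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3L, 3L, byrow = TRUE)
}

quatProcrustesRmsd <- function(X, Y, allow_reflection = TRUE,
                               n_restart = 20L, seed = 99L) {
  X <- sweep(X, 2L, colMeans(X))
  Y <- sweep(Y, 2L, colMeans(Y))
  obj <- function(q, Xm) {
    R <- quatRotation(q)
    XR <- Xm %*% t(R)               # rows transformed by R
    s <- sum(XR * Y) / sum(Xm^2)
    sum((Y - s * XR)^2)
  }
  configs <- list(X)
  if (allow_reflection) {
    Xr <- X
    Xr[, 3L] <- -Xr[, 3L]
    configs <- c(configs, list(Xr))
  }
  set.seed(seed)
  best <- Inf
  for (Xm in configs) {
    for (r in seq_len(n_restart)) {
      q0 <- stats::rnorm(4L)
      fit <- stats::optim(q0, obj, Xm = Xm, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14))
      best <- min(best, fit$value)
    }
  }
  sqrt(best / nrow(X))
}

# Minimal synthetic PDB writer: one ATOM record per row of `atoms`
# (data.frame with elety, resid, chain, resno, x, y, z, optional alt/occ).
writeSyntheticPDB <- function(atoms, path) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    alt <- if (!is.null(a$alt) && nzchar(a$alt)) a$alt else " "
    occ <- if (!is.null(a$occ)) a$occ else 1
    sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
            i, a$elety, alt, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, occ, 0, substr(a$elety, 1L, 1L))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Random masked vector set over a fixed species universe: a VectorSet built
# from perturbed copies of a base patristic-like vector.
randomVectorSet <- function(n_units = 6L, n_species = 12L, seed = 1L,
                            mask_prob = 0.2, min_vector_count = 2L,
                            min_units_per_species = 1L) {
  set.seed(seed)
  species <- sprintf("sp%02d", seq_len(n_species))
  pairs <- t(utils::combn(species, 2L))
  base <- stats::runif(nrow(pairs), 0.5, 2)
  vectors <- lapply(seq_len(n_units), function(u) {
    vals <- base * exp(stats::rnorm(nrow(pairs), sd = 0.3))
    vals[stats::runif(nrow(pairs)) < mask_prob] <- NA
    speciesPairVector(vals, pairs, unit_id = sprintf("unit%02d", u))
  })
  suppressWarnings(assembleVectorSet(
    vectors, min_vector_count = min_vector_count,
    min_units_per_species = min_units_per_species,
    min_shared_species = 0L))
}

# Arm-separation check used by the end-to-end benchmark: mean between-arm
# embedded distance exceeds mean within-arm distance.
armSeparation <- function(points, arm) {
  D <- as.matrix(stats::dist(points))
  b <- mean(D[arm == "arm1", arm == "arm2"])
  w1 <- D[arm == "arm1", arm == "arm1"]
  w2 <- D[arm == "arm2", arm == "arm2"]
  w <- mean(c(w1[upper.tri(w1)], w2[upper.tri(w2)]))
  b > w
}
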