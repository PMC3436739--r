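# Correlation -> dissimilarity transform, classical MDS with the P_k
# goodness-of-fit, and a permutation null for 3D embeddability.

#' Transform a co-evolutionary correlation matrix to dissimilarities
#'
#' Applies the linear transform `d' = 1 - rho` (so that negative rate
#' correlations count as negative evidence of proximity) and, when `rescale`
#' is on, `d = d' / max(d')`, placing the dissimilarities in `[0, 1]` with
#' the largest off-diagonal entry equal to 1. The diagonal is forced to 0.
#'
#' @param R a `"CoevolutionMatrix"` (see [coevolutionMatrix()]) or a square
#'   symmetric correlation matrix with unit dimnames.
#' @param rescale logical; rescale to `[0, 1]` (default `TRUE`).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
toDissimilarity <- function(R, rescale = TRUE) {
  rho <- if (inherits(R, "CoevolutionMatrix")) R$rho else R
  checkSquareSymmetric(rho, "correlation matrix")
  off <- rho
  diag(off) <- 1
  if (anyNA(off)) {
    idx <- which(is.na(off) & upper.tri(off), arr.ind = TRUE)
    bad <- paste0(rownames(off)[idx[, 1L]], "~", colnames(off)[idx[, 2L]])
    stop("undefined correlation for unit pair(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "",
         "; drop the units or impute before embedding", call. = FALSE)
  }
  d <- 1 - rho
  diag(d) <- 0
  if (rescale) {
    mx <- max(d)
    if (mx > 0) d <- d / mx
  }
  d
}

#' Classical multidimensional scaling
#'
#' Embeds a dissimilarity matrix in `k` dimensions by classical (Torgerson)
#' MDS: the squared dissimilarities are double-centered,
#' `B = -1/2 J D^2 J` with `J = I - n^-1 11'`, and `B` is
#' eigendecomposed; coordinates are `Q_+ Lambda_+^{1/2}` over the largest
#' `min(k, number of positive eigenvalues)` eigenvalues. If fewer than `k`
#' eigenvalues are positive, the trailing coordinate columns are zero and a
#' warning is raised.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal and unit
#'   dimnames (see [toDissimilarity()]).
#' @param k number of embedding dimensions (default 3); requires
#'   `nrow(D) >= k + 1`.
#' @param eig_policy denominator policy for the [goodnessOfFit()] reported
#'   alongside the embedding; see that function.
#' @return an object of class `"EmbeddingResult"`: list with `points`
#'   (n x k coordinates, centered, rownames = unit ids), `eig` (all n
#'   eigenvalues, descending), `Pk`, `k`, `eig_policy`, `unit_ids`.
#' @export
classicalMDS <- function(D, k = 3L,
                         eig_policy = c("absolute", "positive", "raw")) {
  eig_policy <- match.arg(eig_policy)
  checkSquareSymmetric(D, "dissimilarity matrix")
  if (anyNA(D)) stop("dissimilarity matrix contains NA", call. = FALSE)
  if (any(D < 0)) stop("dissimilarity matrix has negative entries",
                       call. = FALSE)
  n <- nrow(D)
  if (n < k + 1L)
    stop("need at least k + 1 = ", k + 1L, " units, got ", n, call. = FALSE)
  B <- doubleCenter(D)
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values                      # descending by construction
  # eigenvalues within rounding of zero do not define coordinates
  npos <- sum(ev > 1e-8 * max(abs(ev)))
  kk <- min(k, npos)
  X <- matrix(0, n, k, dimnames = list(rownames(D), paste0("x", seq_len(k))))
  if (kk > 0L)
    X[, seq_len(kk)] <- e$vectors[, seq_len(kk), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(kk)]), kk)
  if (kk < k)
    warning("only ", npos, " positive eigenvalue(s); trailing ",
            k - kk, " coordinate column(s) are zero")
  structure(list(points = X, eig = ev,
                 Pk = goodnessOfFit(ev, k, eig_policy),
                 k = k, eig_policy = eig_policy, unit_ids = rownames(D)),
            class = "EmbeddingResult")
}

# B = -1/2 J D^2 J, symmetrized against rounding.
doubleCenter <- function(D) {
  D2 <- D^2
  rm <- rowMeans(D2)
  B <- -0.5 * (sweep(sweep(D2, 1L, rm), 2L, rm) + mean(D2))
  (B + t(B)) / 2
}

#' Goodness-of-fit of a cMDS configuration
#'
#' Computes
#' \deqn{P_k = \frac{\sum_{i=1}^{k} g(\lambda_i)}{\sum_{i=1}^{n-1} g(\lambda_i)},}
#' the fraction of eigenvalue mass of the double-centered matrix captured by
#' the first `k` dimensions. With non-Euclidean input some eigenvalues are
#' negative and the eigenvalue mass needs a policy `g`:
#' `"absolute"` (default) uses `g(l) = |l|`, matching the goodness-of-fit
#' criterion of [stats::cmdscale()]; `"positive"` uses `g(l) = max(l, 0)`;
#' `"raw"` uses `g(l) = l` (the literal eigenvalue-ratio formula). The
#' policy is applied to numerator and denominator alike, so under
#' `"absolute"` and `"positive"` the statistic is monotone non-decreasing
#' in `k`; for the usual case where the top `k` eigenvalues are positive,
#' the numerator equals their plain sum under every policy. `P_k` is
#' invariant under uniform scaling of the dissimilarities.
#'
#' @param eigenvalues numeric eigenvalues in descending order (from
#'   [classicalMDS()]).
#' @param k number of retained dimensions.
#' @param policy denominator policy (see above).
#' @return scalar `P_k`.
#' @export
goodnessOfFit <- function(eigenvalues, k,
                          policy = c("absolute", "positive", "raw")) {
  policy <- match.arg(policy)
  ev <- sort(eigenvalues, decreasing = TRUE)
  n <- length(ev)
  stopifnot(k >= 1L, k <= n)
  g <- switch(policy,
              absolute = abs,
              positive = function(x) pmax(x, 0),
              raw      = identity)
  den <- sum(g(ev[seq_len(n - 1L)]))  # the centering null eigenvalue drops out
  if (den <= 0) stop("non-positive P_k denominator", call. = FALSE)
  sum(g(ev[seq_len(k)])) / den
}

#' @export
print.EmbeddingResult <- function(x, ...) {
  cat("EmbeddingResult: ", length(x$unit_ids), " units in ", x$k,
      "D, P_", x$k, " = ", round(x$Pk, 4),
      " (eigenvalue policy: ", x$eig_policy, ")\n", sep = "")
  invisible(x)
}

#' Pairwise Euclidean distances of an embedding or configuration
#'
#' @param x an `"EmbeddingResult"` or a coordinate matrix with unit
#'   rownames.
#' @return symmetric Euclidean distance matrix.
#' @export
configurationDistances <- function(x) {
  pts <- if (inherits(x, "EmbeddingResult")) x$points else as.matrix(x)
  as.matrix(stats::dist(pts))
}

#' Permutation null for the embeddability of a dissimilarity matrix
#'
#' Tests whether a dissimilarity matrix fits a `k`-dimensional configuration
#' better than chance. Each replicate permutes the `n(n-1)/2` upper-triangle
#' entries uniformly at random, mirrors them into a symmetric zero-diagonal
#' matrix (preserving the value multiset while destroying geometric
#' structure), embeds it with [classicalMDS()], and records `P_k`. The
#' empirical upper-tail p-value counts the observed value among the samples:
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param D symmetric dissimilarity matrix (zero diagonal, unit dimnames).
#' @param n_perm number of permutation replicates (>= 100).
#' @param seed integer seed; the null sample is fully reproducible from it.
#' @param k embedding dimension (default 3).
#' @param eig_policy denominator policy passed to [goodnessOfFit()].
#' @return an object of class `"PermutationNull"`: list with `n_perm`,
#'   `seed`, `null_Pk` (sampled values), `mean`, `sd`, `observed`,
#'   `p_value`, `k`, `eig_policy`.
#' @export
permutationNull <- function(D, n_perm = 1000L, seed = 1L, k = 3L,
                            eig_policy = c("absolute", "positive", "raw")) {
  eig_policy <- match.arg(eig_policy)
  checkSquareSymmetric(D, "dissimilarity matrix")
  n <- nrow(D)
  if (n < 4L) stop("need at least 4 units for a permutation null",
                   call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  ut <- upper.tri(D)
  vals <- D[ut]
  observed <- goodnessOfFit(eigen(doubleCenter(D), symmetric = TRUE,
                                  only.values = TRUE)$values,
                            k, eig_policy)
  P <- matrix(0, n, n)
  null_Pk <- numeric(n_perm)
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    P[ut] <- sample(vals)
    Ps <- P + t(P)
    ev <- eigen(doubleCenter(Ps), symmetric = TRUE, only.values = TRUE)$values
    null_Pk[b] <- goodnessOfFit(ev, k, eig_policy)
  }
  p_value <- (1 + sum(null_Pk >= observed)) / (1 + n_perm)
  structure(list(n_perm = n_perm, seed = seed, null_Pk = null_Pk,
                 mean = mean(null_Pk), sd = stats::sd(null_Pk),
                 observed = observed, p_value = p_value, k = k,
                 eig_policy = eig_policy),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat("PermutationNull: observed P_", x$k, " = ", round(x$observed, 4),
      ", null ", round(x$mean, 4), " +/- ", round(x$sd, 4),
      " (", x$n_perm, " permutations, seed ", x$seed, ")\n",
      "  empirical p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write unit-center coordinates as a pseudo-PDB file
#'
#' Writes one HETATM record per unit center so a configuration can be
#' inspected in standard molecular-graphics tools. Unit names are carried in
#' the residue-name field (truncated to 3 characters) and the full name in a
#' trailing remark table.
#'
#' @param coords n x 3 coordinate matrix with unit rownames (Angstrom or
#'   arbitrary units).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePseudoPDB <- function(coords, path) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, !is.null(rownames(coords)))
  units <- rownames(coords)
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    sprintf("HETATM%5d  CA  %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, substr(units[i], 1L, 3L), i,
            coords[i, 1L], coords[i, 2L], coords[i, 3L])
  }, character(1))
  remarks <- sprintf("REMARK 999 UNIT %4d %s", seq_along(units), units)
  writeLines(c(remarks, lines, "END"), path)
  invisible(path)
}
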