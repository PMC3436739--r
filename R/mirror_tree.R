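# Phylogeny correction by orthogonal projection and the co-evolutionary
# correlation matrix (mirror-tree with averaged-reference correction).

#' Averaged reference distance vector
#'
#' Derives the reference vector representing the shared species phylogeny
#' directly from the set of patristic distance vectors: for every species
#' pair in the common index, the reference distance is the arithmetic mean
#' of the distances of the units in which that pair is present.
#'
#' Using the within-complex average (rather than an external species tree)
#' also removes rate covariation shared by the whole complex, focusing the
#' residual signal on between-subunit differences.
#'
#' @param set a `"VectorSet"` (see [assembleVectorSet()]).
#' @return named numeric vector on the set's pair index (pair keys `"a|b"`).
#' @export
referenceVector <- function(set) {
  stopifnot(inherits(set, "VectorSet"))
  rowMeans(set$values, na.rm = TRUE)
}

#' Remove the shared-phylogeny signal from one distance vector
#'
#' Projects a patristic distance vector `v` orthogonally on the reference
#' vector `p` and returns the residual
#' \deqn{v^* = v - \frac{p^T v}{p^T p}\, p,}
#' which is orthogonal to `p`. With ragged species coverage the inner
#' products are computed over the pairs present in `v` only, so the
#' orthogonality contract holds per vector.
#'
#' @param v named numeric vector of distances (`NA` = absent pair), e.g. one
#'   column of a `"VectorSet"` or a `"SpeciesPairVector"`.
#' @param p reference vector sharing `v`'s pair index (see
#'   [referenceVector()]).
#' @return numeric vector of residual distances (may be negative), `NA`
#'   where `v` is absent; attribute `unit_id` is carried over when present.
#' @export
projectOut <- function(v, p) {
  if (is.null(names(v)) || is.null(names(p)))
    stop("v and p must be named by species-pair keys", call. = FALSE)
  if (!all(names(v) %in% names(p)))
    stop("v contains pairs absent from the reference vector", call. = FALSE)
  p <- p[names(v)]
  pres <- !is.na(v) & !is.na(p)
  pp <- sum(p[pres]^2)
  if (pp <= 0)
    stop("degenerate reference vector: p'p = 0 on the present pairs",
         call. = FALSE)
  coef <- sum(p[pres] * v[pres]) / pp
  out <- v
  out[pres] <- v[pres] - coef * p[pres]
  out[!pres] <- NA_real_
  attr(out, "species") <- NULL
  class(out) <- NULL
  attr(out, "unit_id") <- attr(v, "unit_id")
  out
}

#' Phylogeny-corrected residual vectors of a set
#'
#' Applies [projectOut()] to every unit vector of a set against a common
#' reference.
#'
#' @param set a `"VectorSet"`.
#' @param p reference vector; defaults to [referenceVector()] of the set.
#' @return pairs x units numeric matrix of residuals (`NA` = absent).
#' @export
correctedVectors <- function(set, p = referenceVector(set)) {
  stopifnot(inherits(set, "VectorSet"))
  out <- set$values
  for (j in seq_len(ncol(out))) {
    out[, j] <- projectOut(set$values[, j], p)
  }
  out
}

#' Co-evolutionary correlation matrix (mirror-tree)
#'
#' Correlates every pair of phylogeny-corrected distance vectors by Spearman
#' rank correlation over their jointly present species pairs, yielding the
#' units' co-evolutionary similarity. Ties receive average ranks. Cells with
#' fewer than 2 joint observations, or where either residual vector has zero
#' variance, are reported as `NA` (undefined), never as 0: a zero would
#' inject false evidence of independence.
#'
#' @param set a `"VectorSet"` with at least 2 units.
#' @param p reference vector; defaults to [referenceVector()] of the set.
#' @return an object of class `"CoevolutionMatrix"`: list with `rho`
#'   (symmetric Spearman matrix, unit diagonal), `n_pairs` (symmetric
#'   matrix of joint species-pair counts) and `unit_ids`.
#' @export
coevolutionMatrix <- function(set, p = referenceVector(set)) {
  stopifnot(inherits(set, "VectorSet"))
  n <- length(set$unit_ids)
  if (n < 2L) stop("need at least 2 units", call. = FALSE)
  resid <- correctedVectors(set, p)
  rho <- matrix(NA_real_, n, n, dimnames = list(set$unit_ids, set$unit_ids))
  np <- matrix(0L, n, n, dimnames = dimnames(rho))
  pres <- !is.na(resid)
  np[] <- crossprod(pres)
  diag(rho) <- 1
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      joint <- pres[, i] & pres[, j]
      m <- sum(joint)
      if (m < 2L) next
      x <- resid[joint, i]
      y <- resid[joint, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      r <- stats::cor(x, y, method = "spearman")
      rho[i, j] <- rho[j, i] <- r
    }
  }
  structure(list(rho = rho, n_pairs = np, unit_ids = set$unit_ids),
            class = "CoevolutionMatrix")
}

#' @export
print.CoevolutionMatrix <- function(x, ...) {
  n <- length(x$unit_ids)
  off <- x$rho[upper.tri(x$rho)]
  cat("CoevolutionMatrix: ", n, " units, ", sum(!is.na(off)), "/",
      length(off), " defined correlations\n", sep = "")
  if (any(!is.na(off)))
    cat("  rho range: [", round(min(off, na.rm = TRUE), 3), ", ",
        round(max(off, na.rm = TRUE), 3), "]\n", sep = "")
  invisible(x)
}

#' Write / read a square labelled matrix as TSV
#'
#' The interchange dialect is a tab-delimited square matrix with unit
#' identifiers as both the first row and the first column (the dialect of
#' published supplementary co-evolutionary distance matrices).
#'
#' @param m square numeric matrix with dimnames.
#' @param path file path.
#' @return `readMatrixTSV` returns the matrix; `writeMatrixTSV` its input,
#'   invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  checkSquareSymmetric(m, "matrix")
  df <- data.frame(unit = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1L, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  checkSquareSymmetric(m, basename(path))
  m
}
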