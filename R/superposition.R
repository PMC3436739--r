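# Similarity Procrustes superposition of the inferred configuration onto a
# reference topology, plus the agreement statistics used to judge it.

#' Procrustes superposition with isometric scaling
#'
#' Fits a labelled configuration `C` onto a reference `T` by translation,
#' rotation (optionally reflection) and isometric scaling. Points are
#' matched by unit id; both configurations are centered; the rotation comes
#' from the singular-value decomposition of the cross-covariance matrix; the
#' optimal scale is applied to `C`. When `allow_reflection` is off and the
#' optimal orthogonal transform is improper, the sign of the smallest
#' singular direction is flipped to force a proper rotation.
#'
#' The residual is summarized as
#' \deqn{\mathrm{rmsd}(T, C) = \sqrt{\sum_i |t_i - c_i|^2 / n}}
#' by default; `rmsd_denominator = "n2"` divides by `n^2` instead (a
#' sensitivity alternative corresponding to a literal reading of some
#' typeset formulas).
#'
#' @param C configuration to fit: n x d matrix with unit rownames, or an
#'   `"EmbeddingResult"`.
#' @param T_ref reference: a `"ReferenceTopology"` or n x d matrix with
#'   unit rownames. At least 3 shared units are required.
#' @param allow_reflection logical (default `TRUE`): cMDS output chirality
#'   is arbitrary, so reflections are explored by default.
#' @param scale logical (default `TRUE`): apply the optimal isometric scale.
#' @param rmsd_denominator `"n"` (default) or `"n2"`.
#' @return an object of class `"SuperpositionResult"`: list with
#'   `rotation` (d x d orthogonal), `scale`, `translations` (centers of `C`
#'   and `T`), `rmsd`, `fitted` (transformed `C` in the frame of `T`),
#'   `reference` (matched reference coordinates), `reflection_used`,
#'   `rmsd_denominator`, `unit_ids`.
#' @export
procrustesFit <- function(C, T_ref, allow_reflection = TRUE, scale = TRUE,
                          rmsd_denominator = c("n", "n2")) {
  rmsd_denominator <- match.arg(rmsd_denominator)
  Cm <- if (inherits(C, "EmbeddingResult")) C$points else as.matrix(C)
  Tm <- if (inherits(T_ref, "ReferenceTopology")) T_ref$centers
        else as.matrix(T_ref)
  shared <- intersect(rownames(Cm), rownames(Tm))
  if (length(shared) < 3L)
    stop("need at least 3 shared units, got ", length(shared),
         call. = FALSE)
  Cm <- Cm[shared, , drop = FALSE]
  Tm <- Tm[shared, , drop = FALSE]
  if (ncol(Cm) != ncol(Tm))
    stop("configurations have different dimensionality", call. = FALSE)
  n <- length(shared)
  cc <- colMeans(Cm); ct <- colMeans(Tm)
  X <- sweep(Cm, 2L, cc)
  Y <- sweep(Tm, 2L, ct)
  if (qr(X)$rank < ncol(X) || qr(Y)$rank < ncol(Y))
    warning("rank-deficient (collinear/coplanar) configuration; ",
            "fit is not unique")
  M <- crossprod(X, Y)                       # d x d cross-covariance
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  reflection_used <- det(R) < 0
  if (!allow_reflection && reflection_used) {
    flip <- diag(ncol(Cm))
    flip[ncol(Cm), ncol(Cm)] <- -1           # flip smallest singular direction
    R <- sv$u %*% flip %*% t(sv$v)
    reflection_used <- FALSE
    trace_term <- sum(sv$d * diag(flip))
  } else {
    trace_term <- sum(sv$d)
  }
  ssX <- sum(X^2)
  s <- if (scale) trace_term / ssX else 1
  if (s <= 0) {
    warning("non-positive optimal scale; clamping to a tiny positive value")
    s <- .Machine$double.eps
  }
  fitted <- s * X %*% R
  resid2 <- sum((Y - fitted)^2)
  denom <- if (rmsd_denominator == "n") n else n^2
  fitted_abs <- sweep(fitted, 2L, ct, `+`)
  rownames(fitted_abs) <- shared
  structure(list(rotation = R, scale = s,
                 translations = list(C = cc, T = ct),
                 rmsd = sqrt(resid2 / denom),
                 fitted = fitted_abs,
                 reference = Tm,
                 reflection_used = reflection_used,
                 rmsd_denominator = rmsd_denominator,
                 unit_ids = shared),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat("SuperpositionResult: ", length(x$unit_ids), " units, rmsd = ",
      format(x$rmsd, digits = 5), " (denominator ", x$rmsd_denominator,
      "), scale = ", format(x$scale, digits = 5),
      if (x$reflection_used) ", reflection used" else "", "\n", sep = "")
  invisible(x)
}

#' Rotate a configuration into its principal-axis frame
#'
#' Centers the configuration and rotates it so that the coordinate axes are
#' the principal components in decreasing-variance order. The sign of each
#' axis is fixed by making the largest-magnitude loading of its principal
#' vector positive, so the orientation is reproducible.
#'
#' @param C n x d coordinate matrix with unit rownames, or an
#'   `"EmbeddingResult"`.
#' @return coordinate matrix in the principal-axis frame, with the rotation
#'   matrix in attribute `"rotation"`.
#' @export
pcaReorient <- function(C) {
  X <- if (inherits(C, "EmbeddingResult")) C$points else as.matrix(C)
  if (nrow(X) < 3L) stop("need at least 3 points", call. = FALSE)
  Xc <- sweep(X, 2L, colMeans(X))
  pc <- prcomp(Xc, center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  out <- Xc %*% rot
  colnames(out) <- paste0("PC", seq_len(ncol(out)))
  rownames(out) <- rownames(X)
  attr(out, "rotation") <- rot
  out
}

#' Per-axis agreement between a fitted and a reference configuration
#'
#' For each coordinate axis, the squared Pearson correlation between the
#' predicted and reference coordinates of matched units, with a two-sided
#' p-value from the t distribution on n - 2 degrees of freedom. Both
#' configurations should be expressed in the same (typically PCA-reoriented)
#' frame first.
#'
#' @param fitted a `"SuperpositionResult"`, or n x d matrix with unit
#'   rownames.
#' @param T_ref reference coordinates (`"ReferenceTopology"` or matrix); if
#'   `fitted` is a `"SuperpositionResult"` its stored matched reference is
#'   the default.
#' @return data frame with columns `axis`, `r_squared`, `p_value`, `n`.
#' @export
axisCorrelations <- function(fitted, T_ref = NULL) {
  if (inherits(fitted, "SuperpositionResult")) {
    F_ <- fitted$fitted
    if (is.null(T_ref)) T_ref <- fitted$reference
  } else F_ <- as.matrix(fitted)
  Tm <- if (inherits(T_ref, "ReferenceTopology")) T_ref$centers
        else as.matrix(T_ref)
  shared <- intersect(rownames(F_), rownames(Tm))
  if (length(shared) < 3L) stop("need at least 3 shared units",
                                call. = FALSE)
  F_ <- F_[shared, , drop = FALSE]
  Tm <- Tm[shared, , drop = FALSE]
  out <- lapply(seq_len(ncol(F_)), function(j) {
    ct <- stats::cor.test(F_[, j], Tm[, j])
    data.frame(axis = j, r_squared = unname(ct$estimate)^2,
               p_value = ct$p.value, n = length(shared))
  })
  do.call(rbind, out)
}

#' Regression agreement between two distance matrices
#'
#' Pearson regression of the upper-triangle entries of `D_a` on those of
#' `D_b` over a unit subset: the workhorse behind "co-evolutionary distance
#' versus physical distance" comparisons. The p-value treats the pairs as
#' independent observations (as is conventional for these regressions); a
#' Mantel permutation p-value over unit relabelings is available as a
#' supplementary output.
#'
#' @param D_a,D_b symmetric matrices with unit dimnames covering `subset`.
#' @param subset unit ids to restrict to (default: shared units).
#' @param mantel integer; if > 0, also compute a Mantel permutation p-value
#'   with this many permutations.
#' @param seed seed for the Mantel permutations.
#' @return data frame with columns `axis` (`"pairwise-distances"`),
#'   `r_squared`, `p_value`, `n` (number of pairs), plus `mantel_p` when
#'   requested.
#' @export
distanceAgreement <- function(D_a, D_b, subset = NULL, mantel = 0L,
                              seed = 1L) {
  checkSquareSymmetric(D_a, "D_a")
  checkSquareSymmetric(D_b, "D_b")
  if (is.null(subset)) subset <- intersect(rownames(D_a), rownames(D_b))
  if (length(subset) < 3L) stop("subset must contain at least 3 units",
                                call. = FALSE)
  miss <- c(setdiff(subset, rownames(D_a)), setdiff(subset, rownames(D_b)))
  if (length(miss)) stop("unit(s) not covered by both matrices: ",
                         paste(unique(miss), collapse = ", "),
                         call. = FALSE)
  A <- D_a[subset, subset]
  B <- D_b[subset, subset]
  ut <- upper.tri(A)
  a <- A[ut]; b <- B[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a distance vector", call. = FALSE)
  ct <- stats::cor.test(a, b)
  out <- data.frame(axis = "pairwise-distances",
                    r_squared = unname(ct$estimate)^2,
                    p_value = ct$p.value, n = sum(ut))
  if (mantel > 0L) {
    obs <- stats::cor(a, b)
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = .GlobalEnv))
    set.seed(seed)
    n <- length(subset)
    null <- replicate(mantel, {
      p <- sample.int(n)
      stats::cor(A[p, p][ut], b)
    })
    out$mantel_p <- (1 + sum(abs(null) >= abs(obs))) / (1 + mantel)
  }
  out
}
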