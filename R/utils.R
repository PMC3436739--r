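# Shared helpers: canonical species-pair indexing and matrix validation.

#' Canonical species-pair keys
#'
#' Builds the canonical (lexicographically sorted) key for one or more
#' unordered species pairs. Keys have the form `"a|b"` with `a < b`.
#'
#' @param a,b character vectors of species identifiers (recycled).
#' @return character vector of pair keys.
#' @keywords internal
pairKey <- function(a, b) {
  swap <- a > b
  key1 <- ifelse(swap, b, a)
  key2 <- ifelse(swap, a, b)
  paste(key1, key2, sep = "|")
}

# All unordered pairs of a sorted species vector, as a 2-column character
# matrix in canonical (lexicographic) order.
allPairs <- function(species) {
  species <- sort(unique(species))
  if (length(species) < 2L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("species_a", "species_b"))))
  }
  idx <- utils::combn(length(species), 2L)
  cbind(species_a = species[idx[1L, ]], species_b = species[idx[2L, ]])
}

# Validate a square symmetric numeric matrix with matching dimnames.
checkSquareSymmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop(name, " must be a square numeric matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(name, " must have unit identifiers as dimnames", call. = FALSE)
  if (!identical(rownames(m), colnames(m)))
    stop(name, " row and column names differ", call. = FALSE)
  finite <- m[is.finite(m)]
  scale <- max(abs(finite), 1)
  if (max(abs(m - t(m)), na.rm = TRUE) > tol * scale)
    stop(name, " is not symmetric", call. = FALSE)
  invisible(m)
}

# Align a labelled coordinate matrix (rownames = unit ids) to a unit order.
alignUnits <- function(x, units, what = "configuration") {
  if (is.null(rownames(x)))
    stop(what, " must have unit identifiers as rownames", call. = FALSE)
  missing <- setdiff(units, rownames(x))
  if (length(missing))
    stop(what, " lacks units: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x[units, , drop = FALSE]
}
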