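# Per-family trees -> species-level patristic distance vectors -> jointly
# indexed vector set with the coverage filters of the mirror-tree protocol.

#' Read a per-family phylogenetic tree
#'
#' Reads one gene/family tree from a Newick or NHX file and maps every leaf
#' label to a species identifier. NHX annotation blocks (`[&&NHX:...]`, or
#' any bracketed comment) are stripped before parsing, so only topology and
#' branch lengths are retained.
#'
#' @param path path to a Newick or NHX tree file.
#' @param unit_id name of the family unit (e.g. a subunit symbol). Defaults
#'   to the file name without extension.
#' @param leaf_pattern regular expression with exactly one capture group
#'   extracting the species token from a leaf label. The default matches the
#'   common `"<number>_<species>"` convention (everything after the first
#'   underscore is the species).
#' @param min_leaves minimum number of leaves required (default 2).
#'
#' @details Branch lengths must be non-negative: tiny negative lengths (as
#'   emitted by some tree programs) are clamped to 0 with a warning. Two
#'   leaves mapping to the same species is an error, because a single
#'   ortholog per species is assumed upstream.
#'
#' @return an object of class `"FamilyTree"`: a list with elements
#'   `unit_id`, `tree` (an [ape::phylo] whose tip labels are species
#'   identifiers) and `leaf_to_species` (named character vector, original
#'   leaf label -> species).
#' @seealso [patristicVector()], [assembleVectorSet()]
#' @export
readFamilyTree <- function(path, unit_id = NULL,
                           leaf_pattern = "^[^_]*_(.+)$",
                           min_leaves = 2L) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  # strip NHX/Newick comment blocks before handing to the parser
  txt <- gsub("\\[[^]]*\\]", "", txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("could not parse tree file: ", path, call. = FALSE)
  if (is.null(unit_id))
    unit_id <- sub("\\.[^.]*$", "", basename(path))
  familyTree(tree, unit_id = unit_id, leaf_pattern = leaf_pattern,
             min_leaves = min_leaves)
}

#' Construct a FamilyTree from an ape phylo object
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param unit_id family unit name.
#' @param leaf_pattern regex with one capture group extracting the species
#'   token from each tip label, or `NULL` if tip labels already are species
#'   identifiers.
#' @param min_leaves minimum number of leaves (default 2).
#' @return a `"FamilyTree"` object; see [readFamilyTree()].
#' @export
familyTree <- function(tree, unit_id, leaf_pattern = NULL, min_leaves = 2L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree for unit '", unit_id, "' has no branch lengths", call. = FALSE)
  if (length(tree$tip.label) < min_leaves)
    stop("tree for unit '", unit_id, "' has fewer than ", min_leaves,
         " leaves", call. = FALSE)
  if (any(tree$edge.length < 0)) {
    n_neg <- sum(tree$edge.length < 0)
    warning("unit '", unit_id, "': clamping ", n_neg,
            " negative branch length(s) to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  labels <- tree$tip.label
  if (is.null(leaf_pattern)) {
    species <- labels
  } else {
    m <- regexec(leaf_pattern, labels)
    hit <- vapply(m, function(x) length(x) >= 2L && x[1L] != -1L, logical(1))
    if (!all(hit))
      stop("unit '", unit_id, "': leaf label(s) do not match leaf_pattern: ",
           paste(utils::head(labels[!hit], 5L), collapse = ", "),
           call. = FALSE)
    species <- vapply(regmatches(labels, m), `[`, character(1), 2L)
  }
  if (anyDuplicated(species)) {
    dup <- unique(species[duplicated(species)])
    stop("unit '", unit_id, "': duplicate species after leaf mapping: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  tree$tip.label <- species
  structure(list(unit_id = unit_id, tree = tree,
                 leaf_to_species = stats::setNames(species, labels)),
            class = "FamilyTree")
}

#' @export
print.FamilyTree <- function(x, ...) {
  cat("FamilyTree '", x$unit_id, "': ", length(x$tree$tip.label),
      " species\n", sep = "")
  invisible(x)
}

#' Patristic distance vector of a family tree
#'
#' Computes, for every unordered pair of species in the tree, the patristic
#' distance: the sum of branch lengths along the unique path connecting the
#' two leaves. The result is independent of root placement.
#'
#' @param ft a `"FamilyTree"` (see [readFamilyTree()]).
#' @return an object of class `"SpeciesPairVector"`: a named numeric vector
#'   of distances (substitutions/site), named by canonical pair keys
#'   `"a|b"` with `a < b`, sorted lexicographically, with attributes
#'   `unit_id` and `species`.
#' @export
patristicVector <- function(ft) {
  stopifnot(inherits(ft, "FamilyTree"))
  dm <- ape::cophenetic.phylo(ft$tree)
  species <- sort(rownames(dm))
  pairs <- allPairs(species)
  values <- dm[cbind(pairs[, 1L], pairs[, 2L])]
  speciesPairVector(values, pairs, unit_id = ft$unit_id)
}

#' Construct a SpeciesPairVector
#'
#' @param values numeric distances, one per pair (`NA` = pair absent).
#' @param pairs 2-column character matrix of species pairs.
#' @param unit_id family unit name.
#' @return a `"SpeciesPairVector"`.
#' @export
speciesPairVector <- function(values, pairs, unit_id) {
  stopifnot(is.numeric(values), nrow(pairs) == length(values))
  keys <- pairKey(pairs[, 1L], pairs[, 2L])
  ord <- order(keys)
  values <- values[ord]
  keys <- keys[ord]
  if (anyDuplicated(keys))
    stop("duplicate species pairs in vector for unit '", unit_id, "'",
         call. = FALSE)
  present <- !is.na(values)
  if (any(values[present] < 0))
    stop("negative patristic distance in unit '", unit_id, "'",
         call. = FALSE)
  if (any(!is.finite(values[present])))
    stop("non-finite patristic distance in unit '", unit_id, "'",
         call. = FALSE)
  pairs_sorted <- pairs[ord, , drop = FALSE]
  structure(stats::setNames(values, keys), unit_id = unit_id,
            species = sort(unique(c(pairs_sorted[present, , drop = FALSE]))),
            class = "SpeciesPairVector")
}

#' @export
print.SpeciesPairVector <- function(x, ...) {
  cat("SpeciesPairVector '", attr(x, "unit_id"), "': ",
      sum(!is.na(x)), "/", length(x), " pairs present\n", sep = "")
  invisible(x)
}

#' Assemble distance vectors into a jointly indexed set
#'
#' Builds the common canonical species-pair index over a collection of
#' patristic distance vectors and applies the coverage filters of the
#' mirror-tree protocol: species occurring in fewer than
#' `min_units_per_species` units are dropped first, then species pairs
#' present in fewer than `min_vector_count` vectors are dropped. Unit pairs
#' sharing fewer than `min_shared_species` species trigger a warning (not an
#' error), since their correlations rest on few observations.
#'
#' @param vectors list of `"SpeciesPairVector"` objects (length >= 2).
#' @param min_vector_count minimum number of vectors a species pair must be
#'   present in (default 5).
#' @param min_units_per_species minimum number of units a species must occur
#'   in (default 8).
#' @param min_shared_species warn threshold on shared species between unit
#'   pairs (default 15).
#' @param merge_map optional named list recording groups of upstream unit
#'   ids that were concatenated into single units (e.g. three neighbouring
#'   membrane subunits merged into one tree); bookkeeping only.
#'
#' @return an object of class `"VectorSet"`: list with `values` (pairs x
#'   units numeric matrix, `NA` = absent, rownames = pair keys), `pairs`
#'   (2-column character matrix), `species` (retained species universe),
#'   `unit_ids`, `merge_map`, and `attrition` (species/pairs dropped).
#' @export
assembleVectorSet <- function(vectors, min_vector_count = 5L,
                              min_units_per_species = 8L,
                              min_shared_species = 15L,
                              merge_map = NULL) {
  if (length(vectors) < 2L)
    stop("need at least 2 distance vectors", call. = FALSE)
  ok <- vapply(vectors, inherits, logical(1), "SpeciesPairVector")
  if (!all(ok)) stop("all elements must be SpeciesPairVector", call. = FALSE)
  unit_ids <- vapply(vectors, attr, character(1), "unit_id")
  if (anyDuplicated(unit_ids))
    stop("duplicate unit ids: ",
         paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", "),
         call. = FALSE)

  sp_lists <- lapply(vectors, attr, "species")
  universe <- sort(unique(unlist(sp_lists)))
  n_units_per_species <- vapply(
    universe, function(s) sum(vapply(sp_lists, function(x) s %in% x,
                                     logical(1))), integer(1))
  keep_species <- universe[n_units_per_species >= min_units_per_species]
  dropped_species <- setdiff(universe, keep_species)

  pairs <- allPairs(keep_species)
  if (nrow(pairs) == 0L)
    stop("no species pairs left after the per-species filter", call. = FALSE)
  keys <- pairKey(pairs[, 1L], pairs[, 2L])

  values <- matrix(NA_real_, nrow = length(keys), ncol = length(unit_ids),
                   dimnames = list(keys, unit_ids))
  for (j in seq_along(vectors)) {
    v <- vectors[[j]]
    hit <- intersect(names(v), keys)
    values[hit, j] <- v[hit]
  }

  n_vec_per_pair <- rowSums(!is.na(values))
  keep_pair <- n_vec_per_pair >= min_vector_count
  dropped_pairs <- sum(!keep_pair)
  values <- values[keep_pair, , drop = FALSE]
  pairs <- pairs[keep_pair, , drop = FALSE]
  if (nrow(values) == 0L)
    stop("empty species-pair index after filtering", call. = FALSE)

  # shared-species diagnostic per unit pair
  sp_per_unit <- lapply(seq_along(vectors), function(j) {
    pres <- rownames(values)[!is.na(values[, j])]
    unique(c(pairs[match(pres, rownames(values)), ]))
  })
  low <- character(0)
  if (length(unit_ids) >= 2L) {
    cmb <- utils::combn(length(unit_ids), 2L)
    shared <- apply(cmb, 2L, function(ij)
      length(intersect(sp_per_unit[[ij[1L]]], sp_per_unit[[ij[2L]]])))
    bad <- shared < min_shared_species
    if (any(bad))
      low <- paste0(unit_ids[cmb[1L, bad]], "~", unit_ids[cmb[2L, bad]],
                    " (", shared[bad], ")")
  }
  if (length(low))
    warning("unit pair(s) share fewer than ", min_shared_species,
            " species: ", paste(utils::head(low, 10L), collapse = ", "),
            if (length(low) > 10L) ", ..." else "")

  structure(list(values = values, pairs = pairs, species = keep_species,
                 unit_ids = unit_ids,
                 merge_map = merge_map,
                 attrition = list(species_dropped = dropped_species,
                                  pairs_dropped = dropped_pairs)),
            class = "VectorSet")
}

#' @export
print.VectorSet <- function(x, ...) {
  cat("VectorSet: ", length(x$unit_ids), " units, ", nrow(x$values),
      " species pairs over ", length(x$species), " species\n", sep = "")
  cat("  attrition: ", length(x$attrition$species_dropped),
      " species dropped, ", x$attrition$pairs_dropped, " pairs dropped\n",
      sep = "")
  invisible(x)
}

#' Export a VectorSet as a long-format table
#'
#' Writes one row per (unit, species pair) with a finite distance, as a
#' tab-delimited table with columns `unit`, `species_a`, `species_b`,
#' `distance`.
#'
#' @param set a `"VectorSet"`.
#' @param path output file path; if `NULL`, the data frame is returned
#'   without writing.
#' @return the long-format data frame, invisibly when written.
#' @export
writeVectorSet <- function(set, path = NULL) {
  stopifnot(inherits(set, "VectorSet"))
  idx <- which(!is.na(set$values), arr.ind = TRUE)
  df <- data.frame(unit = set$unit_ids[idx[, 2L]],
                   species_a = set$pairs[idx[, 1L], 1L],
                   species_b = set$pairs[idx[, 1L], 2L],
                   distance = set$values[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$unit, df$species_a, df$species_b), , drop = FALSE]
  rownames(df) <- NULL
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
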