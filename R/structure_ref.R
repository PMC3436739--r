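# Reference quaternary topology: per-subunit centers from a crystal
# structure and the physical distance matrix between them.

#' Per-subunit center coordinates from a structure file
#'
#' Approximates the mass center of each subunit as the unweighted mean of
#' the C-beta coordinates of its residues (C-alpha for glycine, and C-alpha
#' as fallback where C-beta is missing; the number of fallbacks is
#' reported). Chains are mapped to named units through `chain_map`; units
#' mapped to several chains (merged units) pool the residues of all member
#' chains before averaging, i.e. the center is residue-count weighted.
#'
#' Only the first model is used, the highest-occupancy alternate location is
#' kept per atom, and hetero residues are skipped.
#'
#' @param structure path to a PDB file, or a [bio3d::read.pdb] object.
#' @param chain_map data frame (or path to a two-column tab/space-delimited
#'   table, see [readChainMap()]) with columns `chain` and `unit`; several
#'   rows may share a `unit` to merge chains.
#' @return an object of class `"ReferenceTopology"`: list with `centers`
#'   (n x 3 matrix in Angstrom, rownames = unit ids), `n_residues`,
#'   `n_ca_fallback` (per unit), and `source`.
#' @export
subunitCenters <- function(structure, chain_map) {
  if (is.character(structure)) {
    src <- structure
    pdb <- bio3d::read.pdb(structure, multi = FALSE, rm.alt = FALSE,
                           verbose = FALSE)
  } else {
    src <- "pdb object"
    pdb <- structure
  }
  if (!inherits(pdb, "pdb")) stop("not a PDB structure", call. = FALSE)
  if (is.character(chain_map) && length(chain_map) == 1L)
    chain_map <- readChainMap(chain_map)
  stopifnot(is.data.frame(chain_map),
            all(c("chain", "unit") %in% names(chain_map)))

  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  missing_chains <- setdiff(chain_map$chain, unique(atoms$chain))
  if (length(missing_chains))
    stop("chain(s) not in structure: ",
         paste(missing_chains, collapse = ", "), call. = FALSE)

  units <- unique(chain_map$unit)
  centers <- matrix(NA_real_, length(units), 3L,
                    dimnames = list(units, c("x", "y", "z")))
  n_res <- stats::setNames(integer(length(units)), units)
  n_fb <- stats::setNames(integer(length(units)), units)
  for (u in units) {
    chains <- chain_map$chain[chain_map$unit == u]
    sel <- atoms[atoms$chain %in% chains, , drop = FALSE]
    xyz <- residueAnchors(sel)
    if (nrow(xyz$coords) == 0L)
      stop("unit '", u, "' has no usable residue in chains ",
           paste(chains, collapse = ","), call. = FALSE)
    centers[u, ] <- colMeans(xyz$coords)
    n_res[u] <- nrow(xyz$coords)
    n_fb[u] <- xyz$n_fallback
  }
  structure(list(centers = centers, n_residues = n_res,
                 n_ca_fallback = n_fb, source = src),
            class = "ReferenceTopology")
}

# One anchor coordinate per residue: CB, CA for glycine, CA fallback when CB
# is absent. Highest-occupancy altloc wins.
residueAnchors <- function(atoms) {
  atoms <- atoms[atoms$elety %in% c("CA", "CB"), , drop = FALSE]
  if (nrow(atoms) == 0L)
    return(list(coords = matrix(numeric(0), 0L, 3L), n_fallback = 0L))
  # resolve altlocs: keep the highest occupancy per (chain, resno, insert, elety)
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert), atoms$elety)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key),
                        function(i) i[which.max(occ[i])]), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]
  rkey <- paste(atoms$chain, atoms$resno,
                ifelse(is.na(atoms$insert), "", atoms$insert))
  coords <- matrix(NA_real_, 0L, 3L)
  n_fallback <- 0L
  for (res in split(atoms, factor(rkey, levels = unique(rkey)))) {
    is_gly <- res$resid[1L] == "GLY"
    row <- if (!is_gly && any(res$elety == "CB")) {
      res[res$elety == "CB", , drop = FALSE][1L, ]
    } else if (any(res$elety == "CA")) {
      if (!is_gly) n_fallback <- n_fallback + 1L
      res[res$elety == "CA", , drop = FALSE][1L, ]
    } else next
    coords <- rbind(coords, c(row$x, row$y, row$z))
  }
  list(coords = coords, n_fallback = n_fallback)
}

#' Read a chain-to-unit mapping table
#'
#' @param path two-column whitespace/tab-delimited text file with header
#'   columns `chain` and `unit` (lines starting with `#` are comments).
#' @return data frame with columns `chain` and `unit`.
#' @export
readChainMap <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("chain", "unit") %in% names(df)))
    stop("chain map needs columns 'chain' and 'unit'", call. = FALSE)
  df
}

#' @export
print.ReferenceTopology <- function(x, ...) {
  cat("ReferenceTopology: ", nrow(x$centers), " units from ", x$source,
      "\n", sep = "")
  if (sum(x$n_ca_fallback) > 0)
    cat("  C-alpha fallbacks (missing C-beta): ", sum(x$n_ca_fallback),
        " residues\n", sep = "")
  invisible(x)
}

#' Physical distance matrix of a reference topology
#'
#' Euclidean distances (Angstrom) between unit centers.
#'
#' @param topology a `"ReferenceTopology"` (see [subunitCenters()]) or an
#'   n x 3 coordinate matrix with unit rownames.
#' @return symmetric distance matrix.
#' @export
physicalDistances <- function(topology) {
  centers <- if (inherits(topology, "ReferenceTopology"))
    topology$centers else as.matrix(topology)
  as.matrix(stats::dist(centers))
}

#' Write / read a reference topology as TSV
#'
#' Columns: `unit`, `x`, `y`, `z` (Angstrom).
#'
#' @param topology a `"ReferenceTopology"` or coordinate matrix.
#' @param path file path.
#' @return `readTopologyTSV` returns an n x 3 matrix with unit rownames.
#' @export
writeTopologyTSV <- function(topology, path) {
  centers <- if (inherits(topology, "ReferenceTopology"))
    topology$centers else as.matrix(topology)
  df <- data.frame(unit = rownames(centers), x = centers[, 1L],
                   y = centers[, 2L], z = centers[, 3L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTopologyTSV
#' @export
readTopologyTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"unit" %in% names(df))
    stop("coordinate table needs a 'unit' column", call. = FALSE)
  cols <- if (all(c("x", "y", "z") %in% names(df))) c("x", "y", "z")
          else setdiff(names(df), "unit")
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$unit
  m
}
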