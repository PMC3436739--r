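# End-to-end orchestration: config-driven run of
# trees -> vectors -> correlation -> embedding -> superposition,
# with deterministic machine-readable reports.

#' Read a pipeline run configuration
#'
#' Configurations are YAML with sections `trees` (manifest path,
#' `leaf_pattern`), `filters` (`min_vector_count`, `min_units_per_species`,
#' `min_shared_species`), `merges`, `embedding` (`k`, `rescale`,
#' `eigenvalue_policy`), `reference` (`structure`, `chain_map`),
#' `procrustes` (`allow_reflection`, `rmsd_denominator`), `permutations`
#' (`n_perm`, `seed`) and `subsets` (named unit lists; `~` means "all
#' units"). Missing sections take the defaults documented in the stage
#' functions.
#'
#' @param path path to a YAML config file.
#' @return a named list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "RunConfig", path = path)
}

cfgGet <- function(cfg, section, key, default) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

#' Run the full co-evolutionary topology pipeline
#'
#' Executes, in order: tree reading and patristic distance extraction,
#' vector-set assembly with the coverage filters, phylogeny correction and
#' Spearman correlation, dissimilarity transform and classical MDS per
#' configured subset, optional permutation null, and — when a reference
#' structure is configured — Procrustes superposition with rmsd, per-axis
#' correlations and distance-versus-distance regressions.
#'
#' All matrices, coordinates and a machine-readable `report.json` (with a
#' provenance block: input hashes, seeds and policy flags) are written to
#' `out_dir`. Reruns with the same config and inputs produce byte-identical
#' reports.
#'
#' @param config a `"RunConfig"` (see [readRunConfig()]), a path to one, or
#'   an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @param verbose print stage progress (default `TRUE`).
#' @return the report, invisibly (a named list mirroring `report.json`).
#' @export
runPipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[coevotopo] ", ...)

  manifest_path <- config$trees$manifest
  if (is.null(manifest_path))
    stop("config error in stage 'trees': no manifest given", call. = FALSE)
  manifest <- utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  if (!all(c("unit", "path") %in% names(manifest)))
    stop("manifest needs columns 'unit' and 'path'", call. = FALSE)
  # relative tree paths resolve against the manifest location
  rel <- !file.exists(manifest$path)
  manifest$path[rel] <- file.path(dirname(manifest_path), manifest$path[rel])
  leaf_pattern <- config$trees$leaf_pattern

  say("reading ", nrow(manifest), " family trees")
  trees <- lapply(seq_len(nrow(manifest)), function(i)
    withStage("trees", manifest$unit[i],
              readFamilyTree(manifest$path[i], unit_id = manifest$unit[i],
                             leaf_pattern = leaf_pattern)))
  vectors <- lapply(trees, function(tr)
    withStage("distances", tr$unit_id, patristicVector(tr)))

  say("assembling vector set")
  set <- withStage("assemble", NA, assembleVectorSet(
    vectors,
    min_vector_count = cfgGet(config, "filters", "min_vector_count", 5L),
    min_units_per_species = cfgGet(config, "filters",
                                   "min_units_per_species", 8L),
    min_shared_species = cfgGet(config, "filters", "min_shared_species",
                                15L),
    merge_map = config$merges))
  writeVectorSet(set, file.path(out_dir, "vectors.tsv"))
  say(length(set$unit_ids), " units, ", nrow(set$values),
      " species pairs retained (", length(set$attrition$species_dropped),
      " species, ", set$attrition$pairs_dropped, " pairs dropped)")

  say("correlating corrected vectors")
  cm <- withStage("correlate", NA, coevolutionMatrix(set))
  writeMatrixTSV(cm$rho, file.path(out_dir, "rho.tsv"))
  writeMatrixTSV(cm$n_pairs + 0, file.path(out_dir, "n_pairs.tsv"))

  k <- cfgGet(config, "embedding", "k", 3L)
  rescale <- cfgGet(config, "embedding", "rescale", TRUE)
  policy <- cfgGet(config, "embedding", "eigenvalue_policy", "absolute")
  D_all <- withStage("embed", NA, toDissimilarity(cm, rescale = rescale))
  writeMatrixTSV(D_all, file.path(out_dir, "dissimilarity.tsv"))

  subsets <- config$subsets
  if (is.null(subsets)) subsets <- list(all = NULL)
  units <- set$unit_ids
  embeddings <- list()
  for (s in names(subsets)) {
    sel <- subsets[[s]]
    if (is.null(sel)) sel <- units
    unknown <- setdiff(sel, units)
    if (length(unknown))
      stop("config error in stage 'embed', subset '", s,
           "': unknown unit(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    D_s <- D_all[sel, sel]
    emb <- withStage("embed", s, classicalMDS(D_s, k = k,
                                              eig_policy = policy))
    utils::write.table(
      data.frame(unit = rownames(emb$points), emb$points),
      file.path(out_dir, paste0("coordinates_", s, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writePseudoPDB(scaleTo(emb$points, 100),
                   file.path(out_dir, paste0("centers_", s, ".pdb")))
    embeddings[[s]] <- emb
    say("subset '", s, "': ", length(sel), " units, P_", k, " = ",
        round(emb$Pk, 4))
  }

  perm <- NULL
  if (!is.null(config$permutations)) {
    np <- cfgGet(config, "permutations", "n_perm", 1000L)
    ps <- cfgGet(config, "permutations", "seed", 1L)
    say("permutation null (", np, " replicates)")
    perm <- withStage("permutation", NA,
                      permutationNull(D_all, n_perm = np, seed = ps, k = k,
                                      eig_policy = policy))
  }

  superp <- list()
  if (!is.null(config$reference)) {
    say("reading reference structure")
    topo <- withStage("reference", NA,
                      subunitCenters(config$reference$structure,
                                     config$reference$chain_map))
    writeTopologyTSV(topo, file.path(out_dir, "reference_topology.tsv"))
    Dphys <- physicalDistances(topo)
    writeMatrixTSV(Dphys, file.path(out_dir, "physical_distances.tsv"))
    allow_ref <- cfgGet(config, "procrustes", "allow_reflection", TRUE)
    denom <- cfgGet(config, "procrustes", "rmsd_denominator", "n")
    for (s in names(embeddings)) {
      emb <- embeddings[[s]]
      shared <- intersect(emb$unit_ids, rownames(topo$centers))
      if (length(shared) < 3L) next
      fit <- withStage("superpose", s,
                       procrustesFit(emb, topo,
                                     allow_reflection = allow_ref,
                                     rmsd_denominator = denom))
      frame <- pcaReorient(fit$fitted)
      ref_frame <- sweep(fit$reference, 2L, colMeans(fit$reference)) %*%
        attr(frame, "rotation")
      rownames(ref_frame) <- rownames(fit$reference)
      ax <- axisCorrelations(frame, ref_frame)
      da <- distanceAgreement(D_all, Dphys, subset = shared)
      superp[[s]] <- list(
        rmsd = fit$rmsd, scale = fit$scale,
        reflection_used = fit$reflection_used, n_units = length(shared),
        axis_correlations = ax, distance_agreement = da)
      say("subset '", s, "': rmsd = ", round(fit$rmsd, 2))
    }
  }

  report <- list(
    provenance = list(
      config = unclass(config),
      inputs = inputHashes(config, manifest),
      policies = list(eigenvalue_policy = policy,
                      rescale = rescale, k = k,
                      allow_reflection = cfgGet(config, "procrustes",
                                                "allow_reflection", TRUE),
                      rmsd_denominator = cfgGet(config, "procrustes",
                                                "rmsd_denominator", "n")),
      seeds = list(permutations = cfgGet(config, "permutations", "seed",
                                         NULL))),
    attrition = list(
      n_units = length(set$unit_ids),
      n_species = length(set$species),
      n_species_pairs = nrow(set$values),
      species_dropped = length(set$attrition$species_dropped),
      pairs_dropped = set$attrition$pairs_dropped,
      n_unit_pairs = length(set$unit_ids) * (length(set$unit_ids) - 1L) / 2L),
    embeddings = lapply(embeddings, function(e)
      list(n = length(e$unit_ids), k = e$k, Pk = e$Pk,
           eigenvalues = e$eig)),
    permutation_null = if (!is.null(perm))
      list(n_perm = perm$n_perm, seed = perm$seed, mean = perm$mean,
           sd = perm$sd, observed = perm$observed, p_value = perm$p_value),
    superposition = superp)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "columns")
  say("report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}

# Wrap a stage computation so failures name the stage and offending unit.
withStage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e) {
    where <- if (is.na(id) || is.null(id)) "" else paste0(", unit/subset '",
                                                          id, "'")
    stop("stage '", stage, "'", where, ": ", conditionMessage(e),
         call. = FALSE)
  })
}

# Uniformly scale a coordinate matrix so its largest extent is `extent`.
scaleTo <- function(X, extent) {
  rng <- max(as.matrix(stats::dist(X)))
  if (rng > 0) X * (extent / rng) else X
}

inputHashes <- function(config, manifest) {
  files <- c(manifest$path,
             config$reference$structure, config$reference$chain_map)
  files <- files[!is.null(files) & file.exists(files)]
  as.list(tools::md5sum(files))
}
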