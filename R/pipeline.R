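#' Read a pipeline configuration
#'
#' YAML key-value file. Recognized keys: input paths (\code{studies},
#' \code{detections}, \code{homologs}, \code{annotation}, \code{chrom_sizes},
#' \code{markers}, \code{gene_sets}, \code{edges}), \code{out_dir}, and the
#' analysis constants \code{flank} (bp, default 500000),
#' \code{cm_half_width} (cM, default 10), \code{q} (default 0.995),
#' \code{classes} (subphenotype classes to stratify, default all three),
#' \code{network_max_size} (default 35) and \code{seed}. Defaults equal the
#' method's published constants.
#'
#' @param path YAML config file
#' @param overrides named list overriding config values
#' @return a \code{PipelineConfig} list
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(flank = 500000, cm_half_width = 10, q = 0.995,
                   classes = .PHENOTYPE_CLASSES, network_max_size = 35,
                   seed = 1L, out_dir = "ce_output")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  if (is.null(cfg$studies) || is.null(cfg$detections)) {
    stop("config must name the studies and detections tables")
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full convergent-evidence pipeline
#'
#' Executes load -> region-to-gene mapping (when markers and an annotation are
#' supplied) -> homolog translation -> layer weighting -> CE scoring ->
#' ranking -> top-quantile selection -> subphenotype stratification ->
#' enrichment -> network construction, and writes TSV outputs plus a JSON run
#' manifest. Identical inputs and config produce identical outputs.
#'
#' @param config a \code{PipelineConfig} from \code{\link{readPipelineConfig}},
#'   or a path to the YAML file
#' @return invisibly, the output directory
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  db <- readStudyDatabase(config$studies, config$detections)
  dropped <- NULL
  if (!is.null(config$markers)) {
    if (is.null(config$annotation) || is.null(config$chrom_sizes)) {
      stop("stage genome_mapping: markers given without annotation/chrom_sizes")
    }
    sizes <- readChromSizes(config$chrom_sizes)
    ann <- readGeneAnnotation(config$annotation, sizes)
    mk <- readMarkers(config$markers)
    md <- markerDetections(mk, ann, sizes, flank = config$flank,
                           halfWidthCM = config$cm_half_width)
    dropped <- md$dropped
    if (nrow(md$dropped)) {
      message(sprintf("genome_mapping: dropped %d marker(s) with no genes within boundaries",
                      nrow(md$dropped)))
    }
    if (!is.null(md$detections)) {
      det0 <- do.call(rbind, lapply(evidenceLayers(db)$layer_id, function(id) {
        ly <- evidenceLayers(db)
        i <- match(id, ly$layer_id)
        data.frame(study_id = ly$study_id[i], evidence_kind = ly$layer_kind[i],
                   dataset_id = ly$dataset_id[i],
                   molecule = detections(db)[[id]], stringsAsFactors = FALSE)
      }))
      db <- .assembleDB(studies(db), rbind(det0, md$detections))
    }
  }

  hom <- if (!is.null(config$homologs)) readHomologTable(config$homologs) else NULL
  db <- harmonizeMolecules(db, hom)
  unmapped <- attr(db, "unmapped")
  db <- scoreAllLayers(db)
  writeWeights(db, file.path(out, "weights.tsv"))

  mat <- buildDetectionMatrix(db)
  ranked <- ceRankTable(db, mat)
  writeRanks(ranked, file.path(out, "ranks.tsv"))
  top <- selectTopQuantile(ranked, config$q)
  writeRanks(top, file.path(out, "top_set.tsv"))

  classCounts <- list()
  for (cl in config$classes) {
    strat <- stratifiedRank(db, cl, mat)
    writeRanks(strat, file.path(out, sprintf("ranks_%s.tsv", cl)))
    topCl <- selectTopQuantile(strat, config$q)
    writeRanks(topCl, file.path(out, sprintf("top_set_%s.tsv", cl)))
    classCounts[[cl]] <- list(n_molecules = nrow(strat), n_top = nrow(topCl))
  }

  if (!is.null(config$gene_sets)) {
    sets <- readGMT(config$gene_sets)
    enr <- fisherEnrichment(top$molecule, sets,
                            universe = molecules(db)$identifier, adjust = TRUE)
    utils::write.table(as.data.frame(enr), file.path(out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(config$edges)) {
    nets <- buildNetworks(top$molecule, readEdgeList(config$edges),
                          maxSize = config$network_max_size)
    writeNetworks(nets, file.path(out, "networks.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ceRank")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config = unclass(config),
    config_hash = unname(tools::md5sum(config$studies)),
    n_studies = nrow(studies(db)),
    n_layers = nrow(evidenceLayers(db)),
    n_molecules = nrow(molecules(db)),
    n_unmapped = sum(unmapped$n_unmapped),
    n_top = nrow(top),
    n_dropped_markers = if (is.null(dropped)) 0L else nrow(dropped),
    classes = classCounts
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
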