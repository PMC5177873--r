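#' Configuration for the synthetic study-database generator
#'
#' Defaults emulate the composition of the curated database the method was
#' designed for: 35 human, 55 songbird and 15 other-animal studies; human
#' gene-mapping studies contributing paired association and linkage layers;
#' a molecule universe of several thousand symbols; a small planted-signal
#' set detected with elevated probability; and a many-to-many homolog map
#' with a configurable unmappable fraction.
#'
#' @param nStudies named integer vector: studies per species group
#' @param nGeneMapping named integer vector: gene-mapping studies per species
#'   group (each contributes both an association and a linkage layer)
#' @param sampleSizeRange list with elements \code{gene_mapping} and
#'   \code{other}, each \code{c(min, max)}
#' @param universeSize number of gene symbols in the molecule universe
#' @param nBiomarkers number of biomarker molecules added to the universe
#' @param nPlanted number of planted signal genes
#' @param pSignal per-layer detection probability of a planted gene
#' @param pNoise per-layer detection probability of a background molecule
#' @param homologErrorRate fraction of background genes per non-human species
#'   left out of the homolog table (unmappable)
#' @param manyToManyRate fraction of non-human source genes carrying a second
#'   human homolog
#' @param phenotypePreciseProb probability a study used the precise phenotype
#' @param classProbs named probabilities of membership in each subphenotype
#'   class (memberships independent; resampled until non-empty)
#' @param seed integer seed fixing all randomness
#' @return a validated \code{SyntheticConfig} list
#' @export
syntheticConfig <- function(nStudies = c(human = 35, songbird = 55, other_animal = 15),
                            nGeneMapping = c(human = 10, songbird = 0, other_animal = 1),
                            sampleSizeRange = list(gene_mapping = c(12L, 1000L),
                                                   other = c(4L, 120L)),
                            universeSize = 5000,
                            nBiomarkers = 5,
                            nPlanted = 40,
                            pSignal = 0.3,
                            pNoise = 0.01,
                            homologErrorRate = 0.1,
                            manyToManyRate = 0.05,
                            phenotypePreciseProb = 0.3,
                            classProbs = c(listening = 0.55, ability = 0.35,
                                           practice = 0.45),
                            seed = 1L) {
  cfg <- list(nStudies = nStudies, nGeneMapping = nGeneMapping,
              sampleSizeRange = sampleSizeRange, universeSize = universeSize,
              nBiomarkers = nBiomarkers, nPlanted = nPlanted,
              pSignal = pSignal, pNoise = pNoise,
              homologErrorRate = homologErrorRate,
              manyToManyRate = manyToManyRate,
              phenotypePreciseProb = phenotypePreciseProb,
              classProbs = classProbs, seed = as.integer(seed))
  probs <- c(pSignal, pNoise, homologErrorRate, manyToManyRate,
             phenotypePreciseProb, classProbs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(.SPECIES_GROUPS %in% names(nStudies))) {
    stop("nStudies needs entries for human, songbird and other_animal")
  }
  if (any(nGeneMapping[names(nStudies)] > nStudies)) {
    stop("nGeneMapping cannot exceed nStudies per species group")
  }
  if (nPlanted > universeSize) stop("nPlanted cannot exceed universeSize")
  class(cfg) <- "SyntheticConfig"
  cfg
}

.nativeId <- function(species, gene) {
  paste0(substr(species, 1, 2), "_", tolower(gene))
}

#' Generate a synthetic study database
#'
#' Detection is independent Bernoulli per (layer, molecule): planted genes
#' are detected with \code{pSignal}, background molecules with \code{pNoise}.
#' Non-human layers report species-native identifiers resolvable through the
#' generated homolog table except for a configured unmappable fraction of
#' background genes. A layer that would come out empty receives one forced
#' background detection, since empty layers are load errors. Deterministic
#' given the config seed.
#'
#' @param config a \code{\link{syntheticConfig}}
#' @param dir optional directory; when given, studies.tsv, detections.tsv and
#'   homologs.tsv are written there
#' @return invisibly, a list with \code{studies}, \code{detections},
#'   \code{homologs} (data.frames), \code{planted}, \code{universe} and
#'   \code{biomarkers}
#' @export
generateStudyDatabase <- function(config, dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$universeSize))
  biomarkers <- utils::head(defaultBiomarkers(), config$nBiomarkers)
  planted <- sort(sample(genes, config$nPlanted))
  background <- setdiff(genes, planted)

  # study metadata
  rows <- list()
  for (sp in .SPECIES_GROUPS) {
    n <- config$nStudies[[sp]]
    if (n == 0) next
    gm <- seq_len(n) <= config$nGeneMapping[[sp]]
    grp <- ifelse(gm, "gene_mapping", "other")
    rng <- config$sampleSizeRange
    size <- ifelse(gm,
                   sample(rng$gene_mapping[1]:rng$gene_mapping[2], n, replace = TRUE),
                   sample(rng$other[1]:rng$other[2], n, replace = TRUE))
    kinds <- ifelse(gm, "association,linkage",
                    sample(c("expression", "other_molecular"), n,
                           replace = TRUE, prob = c(0.6, 0.4)))
    classes <- vapply(seq_len(n), function(i) {
      repeat {
        inc <- stats::runif(3) < config$classProbs
        if (any(inc)) return(paste(names(config$classProbs)[inc], collapse = ","))
      }
    }, "")
    rows[[sp]] <- data.frame(
      study_id = sprintf("%s_%03d", sp, seq_len(n)),
      species_group = sp, study_group = grp,
      phenotype_precise = as.integer(stats::runif(n) < config$phenotypePreciseProb),
      phenotype_classes = classes, sample_size = size, evidence_kinds = kinds,
      stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, rows)
  rownames(st) <- NULL

  # homolog table: every gene has a native id per non-human species, except
  # an unmappable background fraction; some source genes gain a second human
  # homolog (many-to-many)
  hom <- list()
  mappedBg <- list(human = background)
  for (sp in c("songbird", "other_animal")) {
    unmappable <- sample(background,
                         round(config$homologErrorRate * length(background)))
    mappedBg[[sp]] <- setdiff(background, unmappable)
    mapped <- setdiff(genes, unmappable)
    tab <- data.frame(species = sp, source_id = .nativeId(sp, mapped),
                      human_symbol = mapped, stringsAsFactors = FALSE)
    extra <- sample(mapped, round(config$manyToManyRate * length(mapped)))
    if (length(extra)) {
      tab <- rbind(tab, data.frame(
        species = sp, source_id = .nativeId(sp, extra),
        human_symbol = sample(genes, length(extra), replace = TRUE),
        stringsAsFactors = FALSE))
    }
    hom[[sp]] <- unique(tab)
  }
  homologs <- do.call(rbind, hom)
  rownames(homologs) <- NULL

  # detections, one layer per declared evidence kind
  det <- list()
  for (i in seq_len(nrow(st))) {
    sp <- st$species_group[i]
    for (kind in strsplit(st$evidence_kinds[i], ",")[[1]]) {
      hit <- c(planted[stats::runif(length(planted)) < config$pSignal],
               background[stats::runif(length(background)) < config$pNoise])
      if (kind == "other_molecular" && length(biomarkers)) {
        hit <- c(hit, biomarkers[stats::runif(length(biomarkers)) < 0.2])
      }
      if (length(hit) == 0) hit <- sample(mappedBg[[sp]], 1)
      isBio <- hit %in% biomarkers
      out <- hit
      if (sp != "human") out[!isBio] <- .nativeId(sp, hit[!isBio])
      det[[length(det) + 1]] <- data.frame(
        study_id = st$study_id[i], evidence_kind = kind, dataset_id = "1",
        molecule = out, stringsAsFactors = FALSE)
    }
  }
  detections <- do.call(rbind, det)
  rownames(detections) <- NULL

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(st, file.path(dir, "studies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(detections, file.path(dir, "detections.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(homologs, file.path(dir, "homologs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(list(studies = st, detections = detections, homologs = homologs,
                 planted = planted, universe = c(genes, biomarkers),
                 biomarkers = biomarkers))
}

#' Generate a toy annotation, chromosome table and marker set
#'
#' Builds non-overlapping, evenly spaced gene models on toy chromosomes plus
#' markers placed mid-chromosome, so the genes recoverable from a window are
#' enumerable by hand. Deterministic given the seed.
#'
#' @param nChrom number of chromosomes
#' @param genesPerChrom gene models per chromosome (0 allowed)
#' @param geneLength gene length in bp
#' @param spacing start-to-start distance between consecutive genes in bp
#' @param markersPerChrom association markers placed per chromosome
#' @param seed integer seed
#' @param dir optional directory; writes genes.gff3, chrom.sizes, markers.tsv
#' @return invisibly, a list with \code{annotation} (GRanges),
#'   \code{chromLengths} and \code{markers}
#' @export
generateAnnotation <- function(nChrom = 2, genesPerChrom = 20,
                               geneLength = 10000, spacing = 100000,
                               markersPerChrom = 2, seed = 1L, dir = NULL) {
  if (spacing <= geneLength) stop("spacing must exceed geneLength (non-overlapping models)")
  set.seed(as.integer(seed))
  chroms <- paste0("chr", seq_len(nChrom))
  chromLen <- stats::setNames(
    rep(max(1, genesPerChrom) * spacing + spacing, nChrom), chroms)
  grs <- list()
  markers <- list()
  for (ci in seq_len(nChrom)) {
    if (genesPerChrom > 0) {
      starts <- spacing * (seq_len(genesPerChrom) - 1) + 1
      ends <- starts + geneLength - 1
      if (any(ends > chromLen[ci])) stop("gene model beyond chromosome length")
      grs[[ci]] <- GenomicRanges::GRanges(
        chroms[ci], IRanges::IRanges(starts, ends),
        gene = sprintf("%s_G%03d", toupper(chroms[ci]), seq_len(genesPerChrom)))
    }
    if (markersPerChrom > 0) {
      pos <- sort(sample(seq_len(chromLen[ci]), markersPerChrom))
      markers[[ci]] <- data.frame(
        study_id = "synthetic_gm", evidence_kind = "association",
        chromosome = chroms[ci], position_bp = pos,
        peak_cm = NA_real_, start_bp = NA_real_, end_bp = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  ann <- if (length(grs)) do.call(c, grs) else {
    empty <- GenomicRanges::GRanges()
    empty$gene <- character(0)
    empty
  }
  GenomeInfoDb::seqlevels(ann) <- chroms
  GenomeInfoDb::seqlengths(ann) <- chromLen
  mk <- if (length(markers)) do.call(rbind, markers) else NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gff <- ann
    gff$Name <- gff$gene
    gff$type <- "gene"
    rtracklayer::export(gff, file.path(dir, "genes.gff3"), format = "gff3")
    utils::write.table(data.frame(names(chromLen), unname(chromLen)),
                       file.path(dir, "chrom.sizes"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (!is.null(mk)) {
      utils::write.table(mk, file.path(dir, "markers.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  invisible(list(annotation = ann, chromLengths = chromLen, markers = mk))
}

# run one replicate of the generate -> weight -> score -> rank chain and
# return planted-recovery statistics
.recoveryOnce <- function(config) {
  sim <- generateStudyDatabase(config)
  db <- .assembleDB(.parseStudies(sim$studies), sim$detections)
  db <- harmonizeMolecules(db, sim$homologs)
  db <- scoreAllLayers(db)
  mat <- buildDetectionMatrix(db)
  ranked <- rankMolecules(ceScores(mat, layerWeights(db)),
                          stats::setNames(as.integer(Matrix::colSums(mat)),
                                          colnames(mat)))
  top <- ranked$molecule[seq_len(min(config$nPlanted, nrow(ranked)))]
  isPlanted <- ranked$molecule %in% sim$planted
  list(recovery = sum(sim$planted %in% top) / config$nPlanted,
       meanRankPlanted = mean(ranked$rank[isPlanted]),
       meanRankBackground = if (any(!isPlanted)) mean(ranked$rank[!isPlanted])
                            else NA_real_,
       nLayers = nrow(evidenceLayers(db)),
       nMolecules = nrow(ranked))
}

#' Planted-signal recovery experiment
#'
#' For each replicate: generate a synthetic database, weight its layers,
#' compute CE scores, rank, and take the top K molecules with K equal to the
#' number of planted signal genes. Reports the fraction of planted genes
#' recovered in the top-K set (with a normal-approximation confidence
#' interval over replicates) and the mean rank of planted vs background
#' molecules.
#'
#' @param config a \code{\link{syntheticConfig}}; requires
#'   \code{pSignal > pNoise}
#' @param nReplicates number of independent replicates (seeds
#'   \code{config$seed + 0:(n-1)})
#' @return list with \code{meanRecovery}, \code{ci} (95\%),
#'   \code{perReplicate}, \code{meanRankPlanted}, \code{meanRankBackground},
#'   \code{nLayers}, \code{nMolecules}, \code{nReplicates}
#' @export
recoveryExperiment <- function(config, nReplicates = 20) {
  stopifnot(inherits(config, "SyntheticConfig"), nReplicates >= 1)
  if (config$pSignal <= config$pNoise) {
    stop("recovery requires pSignal > pNoise")
  }
  reps <- lapply(seq_len(nReplicates) - 1L, function(off) {
    cfg <- config
    cfg$seed <- config$seed + off
    .recoveryOnce(cfg)
  })
  rec <- vapply(reps, `[[`, numeric(1), "recovery")
  se <- if (nReplicates > 1) stats::sd(rec) / sqrt(nReplicates) else 0
  list(meanRecovery = mean(rec),
       ci = c(max(0, mean(rec) - 1.96 * se), min(1, mean(rec) + 1.96 * se)),
       perReplicate = rec,
       meanRankPlanted = mean(vapply(reps, `[[`, numeric(1), "meanRankPlanted")),
       meanRankBackground = mean(vapply(reps, `[[`, numeric(1), "meanRankBackground")),
       nLayers = reps[[1]]$nLayers,
       nMolecules = reps[[1]]$nMolecules,
       nReplicates = nReplicates)
}
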