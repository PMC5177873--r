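#' Controlled vocabulary of non-gene biomarkers
#'
#' Hormones and neurotransmitters tracked alongside genes in the ranking
#' (e.g. cortisol, dopamine). Matching is case-insensitive; the canonical
#' form is lower-case.
#'
#' @return character vector of canonical biomarker names
#' @export
defaultBiomarkers <- function() {
  c("cortisol", "dopamine", "noradrenalin", "adrenaline", "estradiol",
    "serotonin", "testosterone", "oxytocin", "prolactin", "vasopressin",
    "acetylcholine", "gaba", "glutamate")
}

#' Normalize molecule identifiers
#'
#' Gene symbols are whitespace-stripped and upper-cased (HGNC convention);
#' identifiers matching the biomarker vocabulary (case-insensitively) are
#' typed as biomarkers and kept in their canonical lower-case form.
#' Duplicates collapse after normalization, preserving first appearance.
#'
#' @param rawIdentifiers character vector of reported identifiers
#' @param biomarkerVocabulary canonical lower-case biomarker names
#' @return data.frame with columns \code{identifier} and \code{kind}
#'   (\code{"gene"} or \code{"biomarker"})
#' @examples
#' normalizeMolecules(c("egr1", "EGR1 ", "Cortisol"))
#' @export
normalizeMolecules <- function(rawIdentifiers,
                               biomarkerVocabulary = defaultBiomarkers()) {
  ids <- trimws(as.character(rawIdentifiers))
  if (any(is.na(ids) | ids == "")) {
    stop("empty molecule identifier encountered")
  }
  lower <- tolower(ids)
  isBio <- lower %in% tolower(biomarkerVocabulary)
  norm <- ifelse(isBio, lower, toupper(ids))
  keep <- !duplicated(norm)
  data.frame(identifier = norm[keep],
             kind = ifelse(isBio[keep], "biomarker", "gene"),
             stringsAsFactors = FALSE)
}

.splitList <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) {
    v <- trimws(v)
    v[v != ""]
  })
}

.parseStudies <- function(st) {
  required <- c("study_id", "species_group", "study_group", "phenotype_precise",
                "phenotype_classes", "sample_size", "evidence_kinds")
  miss <- setdiff(required, names(st))
  if (length(miss)) {
    stop("studies table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(st$study_id)) {
    dup <- unique(st$study_id[duplicated(st$study_id)])
    stop("duplicate study_id: ", paste(dup, collapse = ", "))
  }
  data.frame(
    study_id = as.character(st$study_id),
    species_group = as.character(st$species_group),
    study_group = as.character(st$study_group),
    phenotype_precise = as.integer(st$phenotype_precise) == 1L,
    phenotype_classes = I(.splitList(st$phenotype_classes)),
    sample_size = suppressWarnings(as.integer(st$sample_size)),
    evidence_kinds = I(.splitList(st$evidence_kinds)),
    stringsAsFactors = FALSE
  )
}

# Shared constructor: studies df (parsed) + detections df -> EvidenceDB.
# One layer per (study, evidence_kind, dataset_id) with detections; every
# declared evidence kind must have at least one detection row.
.assembleDB <- function(studies, det) {
  required <- c("study_id", "evidence_kind", "molecule")
  miss <- setdiff(required, names(det))
  if (length(miss)) {
    stop("detections table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(det$dataset_id)) det$dataset_id <- "1"
  det$dataset_id <- as.character(det$dataset_id)
  det$dataset_id[is.na(det$dataset_id) | det$dataset_id == ""] <- "1"
  unknown <- setdiff(det$study_id, studies$study_id)
  if (length(unknown)) {
    stop("detection rows reference unknown study_id: ",
         paste(unique(unknown), collapse = ", "))
  }
  mol <- trimws(as.character(det$molecule))
  if (any(is.na(mol) | mol == "")) stop("empty molecule identifier in detections")
  det$molecule <- mol

  declared <- studies$evidence_kinds
  names(declared) <- studies$study_id
  badKind <- !mapply(function(s, k) k %in% declared[[s]],
                     det$study_id, det$evidence_kind)
  if (any(badKind)) {
    i <- which(badKind)[1]
    stop(sprintf("detection for study %s uses undeclared evidence kind %s",
                 det$study_id[i], det$evidence_kind[i]))
  }
  # every declared kind needs detections somewhere
  seen <- unique(det[c("study_id", "evidence_kind")])
  for (i in seq_len(nrow(studies))) {
    sid <- studies$study_id[i]
    missing <- setdiff(declared[[sid]], seen$evidence_kind[seen$study_id == sid])
    if (length(missing)) {
      stop(sprintf("empty detected set for declared layer: study %s, kind %s",
                   sid, paste(missing, collapse = ", ")))
    }
  }

  key <- paste(det$study_id, det$evidence_kind, det$dataset_id, sep = ".")
  grp <- split(det$molecule, key)
  # deterministic layer order: by study order, then kind, then dataset
  ord <- order(match(det$study_id, studies$study_id),
               match(det$evidence_kind, .EVIDENCE_KINDS),
               det$dataset_id)
  layerIds <- unique(key[ord])
  meta <- det[match(layerIds, key), c("study_id", "evidence_kind", "dataset_id")]
  layers <- data.frame(
    layer_id = layerIds,
    study_id = meta$study_id,
    layer_kind = meta$evidence_kind,
    dataset_id = meta$dataset_id,
    weight = NA_real_,
    stringsAsFactors = FALSE
  )
  detList <- lapply(grp[layerIds], unique)
  new("EvidenceDB", studies = studies, layers = layers,
      detections = detList,
      molecules = data.frame(identifier = character(0), kind = character(0),
                             stringsAsFactors = FALSE))
}

#' Load a study/evidence-layer database from TSV files
#'
#' Reads the study metadata table and the per-detection table and splits each
#' study into evidence layers: one layer per (study, evidence kind, dataset)
#' combination that has detections. A study reporting both association and
#' linkage results therefore yields two layers, and a study with several
#' independent datasets (via the optional \code{dataset_id} column) yields one
#' layer per dataset. Layer weights are unset until
#' \code{\link{scoreAllLayers}}.
#'
#' @param studiesPath TSV with columns study_id, species_group, study_group,
#'   phenotype_precise (0/1), phenotype_classes (comma-joined),
#'   sample_size (integer or NA), evidence_kinds (comma-joined)
#' @param detectionsPath TSV with columns study_id, evidence_kind,
#'   dataset_id (optional, default "1"), molecule; one row per detection
#' @return an \code{\linkS4class{EvidenceDB}} with unweighted layers and raw
#'   (untranslated) molecule identifiers
#' @export
readStudyDatabase <- function(studiesPath, detectionsPath) {
  st <- utils::read.delim(studiesPath, colClasses = "character",
                          stringsAsFactors = FALSE)
  det <- utils::read.delim(detectionsPath, colClasses = "character",
                           stringsAsFactors = FALSE)
  .assembleDB(.parseStudies(st), det)
}

#' @describeIn readStudyDatabase load the same schema from one JSON document
#'   with top-level arrays \code{studies} and \code{detections}
#' @param jsonPath path to the JSON document
#' @export
readStudyDatabaseJSON <- function(jsonPath) {
  doc <- jsonlite::fromJSON(jsonPath, simplifyDataFrame = TRUE)
  if (is.null(doc$studies) || is.null(doc$detections)) {
    stop("JSON database needs top-level 'studies' and 'detections' arrays")
  }
  .assembleDB(.parseStudies(doc$studies), doc$detections)
}

#' Write an EvidenceDB back to its TSV representation
#'
#' Inverse of \code{\link{readStudyDatabase}}: reloading the written files
#' yields an identical study and layer set.
#'
#' @param db an \code{EvidenceDB}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths to studies.tsv and detections.tsv
#' @export
writeStudyDatabase <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- studies(db)
  out <- data.frame(
    study_id = st$study_id,
    species_group = st$species_group,
    study_group = st$study_group,
    phenotype_precise = as.integer(st$phenotype_precise),
    phenotype_classes = vapply(st$phenotype_classes, paste, "", collapse = ","),
    sample_size = ifelse(is.na(st$sample_size), "NA", as.character(st$sample_size)),
    evidence_kinds = vapply(st$evidence_kinds, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  ly <- evidenceLayers(db)
  det <- do.call(rbind, lapply(seq_len(nrow(ly)), function(i) {
    data.frame(study_id = ly$study_id[i], evidence_kind = ly$layer_kind[i],
               dataset_id = ly$dataset_id[i],
               molecule = detections(db)[[ly$layer_id[i]]],
               stringsAsFactors = FALSE)
  }))
  sPath <- file.path(dir, "studies.tsv")
  dPath <- file.path(dir, "detections.tsv")
  utils::write.table(out, sPath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(det, dPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(studies = sPath, detections = dPath))
}

#' Harmonize molecule identifiers across species
#'
#' Translates detections from non-human studies to human gene symbols through
#' the homolog table (every homolog of a source gene is kept), normalizes all
#' identifiers, and materializes the molecule table of the database. Human
#' studies pass through translation unchanged. Identifiers without any homolog
#' are dropped and counted per layer in the unmapped report.
#'
#' @param db an \code{EvidenceDB} with raw identifiers
#' @param homologTable data.frame from \code{\link{readHomologTable}}, or NULL
#'   when the database is human-only
#' @param biomarkerVocabulary see \code{\link{normalizeMolecules}}
#' @return the \code{EvidenceDB} with translated, normalized detections and a
#'   populated molecule table; the per-layer unmapped report is attached as
#'   \code{metadata} attribute \code{unmapped} (data.frame layer_id,
#'   n_input, n_unmapped)
#' @export
harmonizeMolecules <- function(db, homologTable = NULL,
                               biomarkerVocabulary = defaultBiomarkers()) {
  ly <- evidenceLayers(db)
  st <- studies(db)
  species <- st$species_group[match(ly$study_id, st$study_id)]
  det <- detections(db)
  report <- data.frame(layer_id = ly$layer_id,
                       n_input = lengths(det[ly$layer_id]),
                       n_unmapped = 0L, stringsAsFactors = FALSE)
  nonHuman <- species != "human"
  if (any(nonHuman) && is.null(homologTable)) {
    warning("non-human studies present but no homolog table supplied; ",
            "all their gene identifiers will be unmapped")
  }
  # pre-split the table by species so per-layer translation stays cheap
  bySpecies <- if (is.null(homologTable)) list() else
    split(homologTable, homologTable$species)
  newDet <- vector("list", nrow(ly))
  names(newDet) <- ly$layer_id
  for (i in seq_len(nrow(ly))) {
    id <- ly$layer_id[i]
    tr <- translateToHuman(species[i], det[[id]], bySpecies[[species[i]]],
                           biomarkerVocabulary = biomarkerVocabulary)
    report$n_unmapped[i] <- tr$nUnmapped
    if (length(tr$human) == 0) {
      stop(sprintf("layer %s has no molecules left after homolog translation", id))
    }
    newDet[[id]] <- normalizeMolecules(tr$human, biomarkerVocabulary)$identifier
  }
  allMol <- normalizeMolecules(unlist(newDet, use.names = FALSE),
                               biomarkerVocabulary)
  allMol <- allMol[order(allMol$identifier), , drop = FALSE]
  rownames(allMol) <- NULL
  out <- new("EvidenceDB", studies = st, layers = ly,
             detections = newDet, molecules = allMol)
  attr(out, "unmapped") <- report
  out
}

#' Build the binary detection matrix
#'
#' Materializes the layers-by-molecules indicator matrix consumed by
#' \code{\link{ceScores}}: entry (i, g) is 1 when layer i detected molecule g,
#' else 0. Repeated mentions within a layer collapse to a single 1.
#'
#' @param db a harmonized \code{EvidenceDB} (see
#'   \code{\link{harmonizeMolecules}})
#' @return a sparse \code{dgCMatrix} with layer_ids as rownames and molecule
#'   identifiers as colnames
#' @export
buildDetectionMatrix <- function(db) {
  ly <- evidenceLayers(db)
  mol <- molecules(db)$identifier
  if (length(mol) == 0) stop("molecule table empty; run harmonizeMolecules first")
  det <- detections(db)
  rows <- rep.int(seq_len(nrow(ly)), lengths(det[ly$layer_id]))
  ids <- unlist(det[ly$layer_id], use.names = FALSE)
  cols <- match(ids, mol)
  if (anyNA(cols)) {
    bad <- which(is.na(cols))[1]
    stop(sprintf("detected identifier '%s' (layer %s) absent from molecule table",
                 ids[bad], ly$layer_id[rows[bad]]))
  }
  m <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(nrow(ly), length(mol)),
                            dimnames = list(ly$layer_id, mol))
  # collapse any repeated (layer, molecule) pairs to a single indicator
  m@x[] <- 1
  methods::as(m, "CsparseMatrix")
}
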