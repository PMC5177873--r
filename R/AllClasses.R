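#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.SPECIES_GROUPS <- c("human", "songbird", "other_animal")
.STUDY_GROUPS <- c("gene_mapping", "other")
.EVIDENCE_KINDS <- c("association", "linkage", "expression", "other_molecular")
.PHENOTYPE_CLASSES <- c("listening", "ability", "practice")

#' EvidenceDB: a curated study/evidence-layer database
#'
#' Container for the three tables the convergent-evidence analysis consumes:
#' study metadata, vote-casting evidence layers, and the per-layer detected
#' molecule sets. Layers are created one per (study, evidence kind, dataset)
#' combination with detections; weights are unset (\code{NA}) until
#' \code{\link{scoreAllLayers}} is applied.
#'
#' @slot studies data.frame with columns \code{study_id},
#'   \code{species_group} (human/songbird/other_animal), \code{study_group}
#'   (gene_mapping/other, the two sample-size scaling pools),
#'   \code{phenotype_precise} (logical), \code{phenotype_classes} (list of
#'   character, non-empty subsets of listening/ability/practice),
#'   \code{sample_size} (positive integer or NA), \code{evidence_kinds}
#'   (list of character).
#' @slot layers data.frame with columns \code{layer_id}, \code{study_id},
#'   \code{layer_kind}, \code{dataset_id}, \code{weight} plus, after scoring,
#'   the weight-component audit columns.
#' @slot detections named list (by \code{layer_id}) of character vectors of
#'   molecule identifiers detected by each layer.
#' @slot molecules data.frame with columns \code{identifier} and \code{kind}
#'   (gene/biomarker); empty until identifiers are harmonized.
#'
#' @seealso \code{\link{readStudyDatabase}}, \code{\link{harmonizeMolecules}},
#'   \code{\link{buildDetectionMatrix}}
#' @export
setClass("EvidenceDB",
  representation(
    studies = "data.frame",
    layers = "data.frame",
    detections = "list",
    molecules = "data.frame"
  )
)

.validEvidenceDB <- function(object) {
  msg <- character(0)
  st <- object@studies
  ly <- object@layers
  if (anyDuplicated(st$study_id)) {
    dup <- unique(st$study_id[duplicated(st$study_id)])
    msg <- c(msg, sprintf("duplicate study_id: %s", paste(dup, collapse = ", ")))
  }
  if (!all(st$species_group %in% .SPECIES_GROUPS)) {
    msg <- c(msg, "species_group must be one of human, songbird, other_animal")
  }
  if (!all(st$study_group %in% .STUDY_GROUPS)) {
    msg <- c(msg, "study_group must be gene_mapping or other")
  }
  if (any(lengths(st$phenotype_classes) == 0)) {
    msg <- c(msg, "every study needs at least one phenotype class")
  }
  if (!all(unlist(st$phenotype_classes) %in% .PHENOTYPE_CLASSES)) {
    msg <- c(msg, "phenotype classes must be listening, ability or practice")
  }
  if (!all(unlist(st$evidence_kinds) %in% .EVIDENCE_KINDS)) {
    msg <- c(msg, "unknown evidence kind")
  }
  gm <- st$study_group == "gene_mapping"
  if (any(gm)) {
    ok <- vapply(st$evidence_kinds[gm], function(k) {
      all(k %in% c("association", "linkage"))
    }, logical(1))
    if (!all(ok)) {
      msg <- c(msg, "gene_mapping studies may only carry association/linkage evidence")
    }
  }
  ss <- st$sample_size
  if (any(!is.na(ss) & ss <= 0)) msg <- c(msg, "sample_size must be positive")
  if (nrow(ly)) {
    if (anyDuplicated(ly$layer_id)) msg <- c(msg, "duplicate layer_id")
    if (!all(ly$study_id %in% st$study_id)) {
      bad <- setdiff(ly$study_id, st$study_id)
      msg <- c(msg, sprintf("layer references unknown study_id: %s",
                            paste(bad, collapse = ", ")))
    }
    if (!all(ly$layer_kind %in% .EVIDENCE_KINDS)) msg <- c(msg, "unknown layer_kind")
    if (!setequal(names(object@detections), ly$layer_id)) {
      msg <- c(msg, "detections must be keyed by layer_id, one entry per layer")
    }
    if (any(lengths(object@detections) == 0)) {
      empty <- names(object@detections)[lengths(object@detections) == 0]
      msg <- c(msg, sprintf("empty detected set for layer(s): %s",
                            paste(empty, collapse = ", ")))
    }
    w <- ly$weight
    if (any(!is.na(w) & (w <= 0 | w > 1))) {
      msg <- c(msg, "layer weights must lie in (0, 1]")
    }
  }
  mo <- object@molecules
  if (nrow(mo) && anyDuplicated(mo$identifier)) {
    msg <- c(msg, "molecule identifiers must be unique after normalization")
  }
  if (length(msg)) msg else TRUE
}

setValidity("EvidenceDB", .validEvidenceDB)

#' @describeIn EvidenceDB compact summary of database composition
#' @param object an \code{EvidenceDB}
#' @export
setMethod("show", "EvidenceDB", function(object) {
  st <- object@studies
  cat(sprintf("EvidenceDB with %d studies, %d evidence layers\n",
              nrow(st), nrow(object@layers)))
  if (nrow(st)) {
    comp <- table(factor(st$species_group, levels = .SPECIES_GROUPS))
    cat("  species: ", paste(sprintf("%s=%d", names(comp), comp), collapse = ", "),
        "\n", sep = "")
  }
  nw <- sum(!is.na(object@layers$weight))
  cat(sprintf("  weighted layers: %d/%d\n", nw, nrow(object@layers)))
  if (nrow(object@molecules)) {
    cat(sprintf("  molecules: %d (%d genes, %d biomarkers)\n",
                nrow(object@molecules),
                sum(object@molecules$kind == "gene"),
                sum(object@molecules$kind == "biomarker")))
  } else {
    cat("  molecules: not yet harmonized (see harmonizeMolecules)\n")
  }
  invisible(NULL)
})
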