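#' Per-study sample-size factors
#'
#' Sample sizes are linearly rescaled to [0.8, 1] within each of the two
#' study pools (gene-mapping studies vs all other studies): the smallest
#' sample in a pool scores 0.8, the largest 1.0. When a pool has a single
#' study or all sizes are equal, the factor is 1.0 (no information to
#' penalize). A missing sample size scores the floor 0.8 with a warning.
#'
#' @param studies the studies data.frame of an \code{EvidenceDB}
#' @return named numeric vector of size factors keyed by study_id
#' @export
sizeScores <- function(studies) {
  ss <- studies$sample_size
  if (any(!is.na(ss) & ss <= 0)) stop("sample sizes must be positive")
  out <- rep(NA_real_, nrow(studies))
  for (g in unique(studies$study_group)) {
    idx <- which(studies$study_group == g)
    s <- ss[idx]
    known <- !is.na(s)
    if (any(known)) {
      lo <- min(s[known]); hi <- max(s[known])
      f <- if (hi == lo) rep(1.0, sum(known)) else 0.8 + 0.2 * (s[known] - lo) / (hi - lo)
      out[idx[known]] <- f
    }
    if (any(!known)) {
      warning(sprintf("missing sample size for study group '%s' (%d studies): scoring floor 0.8",
                      g, sum(!known)))
      out[idx[!known]] <- 0.8
    }
  }
  stats::setNames(out, studies$study_id)
}

#' Weight components for one evidence layer
#'
#' The layer's custom score is the product of three self-importance factors,
#' each in [0.8, 1]: phenotype precision (1 when the study used precisely the
#' trait of interest, else 0.8), homology conversion (1 for human studies,
#' 0.8 otherwise), and the linearly scaled sample-size factor. Linkage layers
#' from a study that also contributes an association layer are additionally
#' multiplied by 0.9. Weights therefore lie in [0.8^3, 1] = [0.512, 1] without
#' the linkage penalty.
#'
#' @param phenotypePrecise logical, did the study use the precise phenotype
#' @param speciesGroup human, songbird or other_animal
#' @param layerKind association, linkage, expression or other_molecular
#' @param sizeFactor sample-size factor in [0.8, 1]
#' @param hasPairedAssociation does the same study contribute an association
#'   layer (triggers the 0.9 multiplier on linkage layers only)
#' @return list with phenotype_factor, homology_factor, size_factor,
#'   linkage_multiplier and their product \code{weight}
#' @export
layerWeight <- function(phenotypePrecise, speciesGroup, layerKind, sizeFactor,
                        hasPairedAssociation = FALSE) {
  if (is.na(sizeFactor) || sizeFactor < 0.8 || sizeFactor > 1) {
    stop("sizeFactor must lie in [0.8, 1]")
  }
  pf <- if (isTRUE(phenotypePrecise)) 1.0 else 0.8
  hf <- if (identical(speciesGroup, "human")) 1.0 else 0.8
  lm <- if (identical(layerKind, "linkage") && isTRUE(hasPairedAssociation)) 0.9 else 1.0
  list(phenotype_factor = pf, homology_factor = hf, size_factor = sizeFactor,
       linkage_multiplier = lm, weight = pf * hf * sizeFactor * lm)
}

#' Attach custom scores to all evidence layers
#'
#' Computes every layer's weight from its study's metadata and stores the
#' component audit record on the layer table. Deterministic regardless of row
#' order.
#'
#' @param db an \code{EvidenceDB}
#' @return the \code{EvidenceDB} with weighted layers; the layer table gains
#'   columns phenotype_factor, homology_factor, size_factor,
#'   linkage_multiplier and weight
#' @export
scoreAllLayers <- function(db) {
  st <- studies(db)
  ly <- evidenceLayers(db)
  if (nrow(ly) == 0) return(db)
  sf <- sizeScores(st)
  i <- match(ly$study_id, st$study_id)
  hasAssoc <- ly$study_id %in% ly$study_id[ly$layer_kind == "association"]
  comp <- lapply(seq_len(nrow(ly)), function(k) {
    layerWeight(st$phenotype_precise[i[k]], st$species_group[i[k]],
                ly$layer_kind[k], sf[[ly$study_id[k]]],
                hasPairedAssociation = hasAssoc[k])
  })
  for (col in c("phenotype_factor", "homology_factor", "size_factor",
                "linkage_multiplier", "weight")) {
    ly[[col]] <- vapply(comp, `[[`, numeric(1), col)
  }
  methods::initialize(db, layers = ly)
}

#' Write the per-layer weight audit table
#'
#' @param db a weighted \code{EvidenceDB}
#' @param path output TSV path
#' @return invisibly, the path
#' @export
writeWeights <- function(db, path) {
  ly <- evidenceLayers(db)
  cols <- c("layer_id", "phenotype_factor", "homology_factor", "size_factor",
            "linkage_multiplier", "weight")
  miss <- setdiff(cols, names(ly))
  if (length(miss)) stop("layers are unweighted; run scoreAllLayers first")
  utils::write.table(ly[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
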