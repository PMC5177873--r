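#' Convergent-evidence scores
#'
#' For each molecule g the CE score is the weighted arithmetic mean of its
#' binary detection indicators over the analyzed layers:
#' \deqn{CE_g = \sum_i w_i e_{gi} / \sum_i w_i}
#' where \eqn{w_i} is the layer's custom score and \eqn{e_{gi}} is 1 when
#' layer i detected molecule g.
#'
#' @param mat detection matrix from \code{\link{buildDetectionMatrix}}
#'   (layers in rows)
#' @param weights named numeric vector of layer weights keyed by layer_id;
#'   must cover every row of \code{mat}
#' @return named numeric vector of scores in [0, 1], one per molecule
#' @export
ceScores <- function(mat, weights) {
  ids <- rownames(mat)
  if (is.null(names(weights)) || !all(ids %in% names(weights))) {
    miss <- if (is.null(names(weights))) ids else setdiff(ids, names(weights))
    stop("missing weight for layer(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  w <- as.numeric(weights[ids])
  if (anyNA(w)) stop("NA weight for layer(s): ",
                     paste(ids[is.na(w)], collapse = ", "))
  tot <- sum(w)
  if (tot <= 0) stop("total layer weight must be positive")
  s <- as.numeric(Matrix::crossprod(mat, w)) / tot
  stats::setNames(s, colnames(mat))
}

#' Rank molecules by CE score
#'
#' Sorted by score descending; ties broken by raw detection count descending,
#' then identifier ascending, so the ranking is deterministic across runs and
#' platforms.
#'
#' @param scores named numeric vector from \code{\link{ceScores}}
#' @param nDetected named integer vector of per-molecule detection counts
#'   (number of layers); defaults to zero-count tie-breaks when omitted
#' @return \code{S4Vectors::DataFrame} with columns molecule, score, rank,
#'   n_layers_detected
#' @export
rankMolecules <- function(scores, nDetected = NULL) {
  if (length(scores) == 0) stop("empty score map")
  mol <- names(scores)
  if (is.null(nDetected)) nDetected <- stats::setNames(integer(length(mol)), mol)
  cnt <- as.integer(nDetected[mol])
  cnt[is.na(cnt)] <- 0L
  ord <- order(-scores, -cnt, mol, method = "radix")
  S4Vectors::DataFrame(
    molecule = mol[ord],
    score = unname(scores[ord]),
    rank = seq_along(mol),
    n_layers_detected = cnt[ord]
  )
}

#' Select the top quantile of a ranking
#'
#' The "top q quantile" rule is operationalized as the first
#' \code{ceiling((1 - q) * N)} molecules of the deterministic ranking, which
#' is tie-robust: 7895 molecules at q = 0.995 give a 40-molecule top set.
#'
#' @param ranked a ranking from \code{\link{rankMolecules}}
#' @param q quantile in (0, 1); default 0.995
#' @return the top rows of \code{ranked}
#' @export
selectTopQuantile <- function(ranked, q = 0.995) {
  if (!is.numeric(q) || length(q) != 1 || is.na(q) || q <= 0 || q >= 1) {
    stop("q must lie strictly between 0 and 1")
  }
  n <- nrow(ranked)
  # guard the product against floating-point drift (1 - 0.95 is not exact)
  k <- ceiling((1 - q) * n - sqrt(.Machine$double.eps))
  k <- max(1L, min(n, as.integer(k)))
  ranked[seq_len(k), , drop = FALSE]
}

# per-molecule counts of distinct studies, optionally restricted to a
# study subset; used for the Table-2-style count columns
.studyCounts <- function(db, mat, studyIds) {
  ly <- evidenceLayers(db)
  keep <- ly$study_id %in% studyIds
  if (!any(keep)) return(stats::setNames(integer(ncol(mat)), colnames(mat)))
  sub <- mat[ly$layer_id[keep], , drop = FALSE]
  sid <- ly$study_id[keep]
  # count distinct studies with >= 1 detecting layer
  agg <- rowsum((as.matrix(sub) > 0) + 0, group = sid)
  stats::setNames(as.integer(colSums(agg > 0)), colnames(mat))
}

#' Full CE ranking table with species and subphenotype counts
#'
#' Builds the publication-style ranking: CE score, rank, number of layers
#' detected, and counts of distinct studies by species group and by
#' subphenotype class.
#'
#' @param db a weighted, harmonized \code{EvidenceDB}
#' @param mat optional precomputed detection matrix
#' @return \code{S4Vectors::DataFrame}, one row per molecule in rank order
#' @export
ceRankTable <- function(db, mat = buildDetectionMatrix(db)) {
  st <- studies(db)
  scores <- ceScores(mat, layerWeights(db))
  nDet <- stats::setNames(as.integer(Matrix::colSums(mat)), colnames(mat))
  ranked <- rankMolecules(scores, nDet)
  mol <- molecules(db)
  ranked$kind <- mol$kind[match(ranked$molecule, mol$identifier)]
  for (sp in .SPECIES_GROUPS) {
    cnt <- .studyCounts(db, mat, st$study_id[st$species_group == sp])
    ranked[[paste0("n_", sp)]] <- unname(cnt[ranked$molecule])
  }
  for (cl in .PHENOTYPE_CLASSES) {
    inClass <- vapply(st$phenotype_classes, function(p) cl %in% p, logical(1))
    cnt <- .studyCounts(db, mat, st$study_id[inClass])
    ranked[[paste0("n_", cl)]] <- unname(cnt[ranked$molecule])
  }
  ranked
}

#' Subphenotype-stratified CE ranking
#'
#' Restricts the analysis to layers whose parent study includes the given
#' subphenotype class, recomputes the weight denominator over that subset
#' only, drops molecules with no detection in the subset, and ranks. Scores
#' are comparable within a stratum, not across strata.
#'
#' @param db a weighted, harmonized \code{EvidenceDB}
#' @param class one of listening, ability, practice
#' @param mat optional precomputed detection matrix
#' @return \code{S4Vectors::DataFrame} ranking of the stratum
#' @export
stratifiedRank <- function(db, class, mat = buildDetectionMatrix(db)) {
  class <- match.arg(class, .PHENOTYPE_CLASSES)
  st <- studies(db)
  ly <- evidenceLayers(db)
  inClass <- vapply(st$phenotype_classes, function(p) class %in% p, logical(1))
  keep <- ly$study_id %in% st$study_id[inClass]
  if (!any(keep)) stop(sprintf("no evidence layers in phenotype class '%s'", class))
  sub <- mat[ly$layer_id[keep], , drop = FALSE]
  sub <- sub[, Matrix::colSums(sub) > 0, drop = FALSE]
  if (ncol(sub) == 0) stop(sprintf("no detections in phenotype class '%s'", class))
  scores <- ceScores(sub, layerWeights(db)[ly$layer_id[keep]])
  nDet <- stats::setNames(as.integer(Matrix::colSums(sub)), colnames(sub))
  rankMolecules(scores, nDet)
}

#' Write a ranking table as TSV
#'
#' Scores are rounded to 3 decimals at output only.
#'
#' @param ranked a DataFrame from \code{\link{ceRankTable}},
#'   \code{\link{rankMolecules}} or \code{\link{stratifiedRank}}
#' @param path output path
#' @return invisibly, the path
#' @export
writeRanks <- function(ranked, path) {
  df <- as.data.frame(ranked)
  df$score <- sprintf("%.3f", df$score)
  front <- intersect(c("rank", "molecule", "kind", "score", "n_layers_detected"),
                     names(df))
  df <- df[c(front, setdiff(names(df), front))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
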