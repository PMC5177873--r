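#' Read a many-to-many homolog translation table
#'
#' @param path TSV with columns species, source_id, human_symbol; one row per
#'   homolog pair. Human symbols are normalized (upper-case, trimmed) on read;
#'   duplicate triples collapse.
#' @return data.frame(species, source_id, human_symbol)
#' @export
readHomologTable <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "source_id", "human_symbol"), names(tab))
  if (length(miss)) {
    stop("homolog table missing column(s): ", paste(miss, collapse = ", "))
  }
  tab$species <- trimws(tab$species)
  tab$source_id <- trimws(tab$source_id)
  tab$human_symbol <- toupper(trimws(tab$human_symbol))
  unique(tab[c("species", "source_id", "human_symbol")])
}

#' Translate molecule identifiers to human gene symbols
#'
#' Human inputs pass through unchanged. Each non-human identifier expands to
#' all of its human homologs in the table; identifiers with no mapping are
#' dropped and counted. Biomarkers (hormones, neurotransmitters) are kept as
#' such in every species. The output is deduplicated.
#'
#' @param species species group of the reporting study
#'   (human/songbird/other_animal)
#' @param identifiers character vector of reported identifiers
#' @param homologTable data.frame from \code{\link{readHomologTable}} (may be
#'   NULL for human input)
#' @param biomarkerVocabulary see \code{\link{normalizeMolecules}}
#' @return list with \code{human} (deduplicated human identifiers),
#'   \code{nUnmapped} and \code{unmapped} (the dropped source identifiers)
#' @export
translateToHuman <- function(species, identifiers, homologTable = NULL,
                             biomarkerVocabulary = defaultBiomarkers()) {
  ids <- trimws(as.character(identifiers))
  if (any(is.na(ids) | ids == "")) stop("empty identifier in translation input")
  if (identical(species, "human")) {
    return(list(human = unique(ids), nUnmapped = 0L, unmapped = character(0)))
  }
  isBio <- tolower(ids) %in% tolower(biomarkerVocabulary)
  out <- as.list(ids)
  unmapped <- character(0)
  if (any(!isBio)) {
    if (is.null(homologTable) || nrow(homologTable) == 0) {
      unmapped <- ids[!isBio]
      out[!isBio] <- list(character(0))
    } else {
      sub <- homologTable[homologTable$species == species, , drop = FALSE]
      hits <- split(sub$human_symbol, sub$source_id)
      for (i in which(!isBio)) {
        h <- hits[[ids[i]]]
        if (is.null(h)) {
          unmapped <- c(unmapped, ids[i])
          out[[i]] <- character(0)
        } else {
          out[[i]] <- h
        }
      }
    }
  }
  human <- unique(unlist(out, use.names = FALSE))
  list(human = human, nUnmapped = length(unique(unmapped)),
       unmapped = unique(unmapped))
}
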