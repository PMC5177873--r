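#' Accessors for EvidenceDB
#'
#' @param x an \code{EvidenceDB}
#' @param value replacement value
#' @return \code{studies} and \code{evidenceLayers} return data.frames;
#'   \code{detections} a named list of character vectors; \code{molecules} a
#'   data.frame of harmonized identifiers; \code{layerWeights} a named numeric
#'   vector keyed by layer_id.
#' @name EvidenceDB-accessors
NULL

#' @rdname EvidenceDB-accessors
#' @export
setGeneric("studies", function(x) standardGeneric("studies"))

#' @rdname EvidenceDB-accessors
#' @export
setGeneric("evidenceLayers", function(x) standardGeneric("evidenceLayers"))

#' @rdname EvidenceDB-accessors
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname EvidenceDB-accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname EvidenceDB-accessors
#' @export
setGeneric("layerWeights", function(x) standardGeneric("layerWeights"))

#' @rdname EvidenceDB-accessors
#' @export
setGeneric("layerWeights<-", function(x, value) standardGeneric("layerWeights<-"))

#' @rdname EvidenceDB-accessors
#' @export
setMethod("studies", "EvidenceDB", function(x) x@studies)

#' @rdname EvidenceDB-accessors
#' @export
setMethod("evidenceLayers", "EvidenceDB", function(x) x@layers)

#' @rdname EvidenceDB-accessors
#' @export
setMethod("detections", "EvidenceDB", function(x) x@detections)

#' @rdname EvidenceDB-accessors
#' @export
setMethod("molecules", "EvidenceDB", function(x) x@molecules)

#' @rdname EvidenceDB-accessors
#' @export
setMethod("layerWeights", "EvidenceDB", function(x) {
  stats::setNames(x@layers$weight, x@layers$layer_id)
})

#' @rdname EvidenceDB-accessors
#' @export
setReplaceMethod("layerWeights", "EvidenceDB", function(x, value) {
  if (is.null(names(value)) || !setequal(names(value), x@layers$layer_id)) {
    stop("replacement weights must be named by layer_id, one per layer")
  }
  x@layers$weight <- unname(value[x@layers$layer_id])
  validObject(x)
  x
})
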