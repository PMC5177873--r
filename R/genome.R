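#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

#' Read a chromosome-length table
#'
#' @param path two-column chrom.sizes file (chromosome, length in bp),
#'   no header
#' @return named numeric vector of lengths
#' @export
readChromSizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  if (any(tab$length < 1)) stop("chromosome lengths must be positive")
  stats::setNames(tab$length, tab$chrom)
}

#' Load a gene annotation as GRanges
#'
#' Accepts GFF3 (gene-type features; symbol from the Name or gene_name
#' attribute) or BED (name column). BED's 0-based half-open coordinates are
#' converted to the 1-based inclusive convention used throughout. Strand is
#' ignored.
#'
#' @param path annotation file (.gff3/.gff or .bed)
#' @param chromLengths named vector from \code{\link{readChromSizes}}
#' @return \code{GRanges} with a \code{gene} metadata column and seqlengths set
#' @export
readGeneAnnotation <- function(path, chromLengths) {
  ext <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path)
  if (ext %in% c("gff3", "gff")) {
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    nm <- if (!is.null(gr$Name)) as.character(gr$Name)
          else if (!is.null(gr$gene_name)) as.character(gr$gene_name)
          else as.character(gr$ID)
  } else {
    nm <- as.character(gr$name)
  }
  if (anyNA(nm) || any(nm == "")) stop("annotation records without gene symbols")
  if (anyDuplicated(nm)) {
    stop("duplicate gene symbols in annotation: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- GenomicRanges::GRanges(
    seqnames = as.character(GenomicRanges::seqnames(gr)),
    ranges = IRanges::ranges(gr)
  )
  out$gene <- nm
  bad <- setdiff(as.character(GenomicRanges::seqnames(out)), names(chromLengths))
  if (length(bad)) stop("annotation chromosomes absent from length table: ",
                        paste(bad, collapse = ", "))
  GenomeInfoDb::seqlevels(out) <- names(chromLengths)
  GenomeInfoDb::seqlengths(out) <- chromLengths
  over <- GenomicRanges::end(out) >
    chromLengths[as.character(GenomicRanges::seqnames(out))]
  if (any(over)) stop("gene(s) extend beyond chromosome length: ",
                      paste(out$gene[over], collapse = ", "))
  out
}

.clampInterval <- function(chrom, start, end, chromLengths) {
  if (!chrom %in% names(chromLengths)) {
    stop(sprintf("unknown chromosome '%s'", chrom))
  }
  L <- unname(chromLengths[chrom])
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(max(1, start), min(L, end)))
}

#' Association window around a marker
#'
#' The candidate region for an associated marker is the symmetric window of
#' \code{flank} bp on each side (default 500 kb), clamped to the chromosome.
#' Coordinates are 1-based inclusive.
#'
#' @param chrom chromosome name
#' @param position marker position in bp (>= 1)
#' @param flank window half-width in bp; default 500000
#' @param chromLengths named vector of chromosome lengths
#' @return a single-range \code{GRanges}
#' @export
associationWindow <- function(chrom, position, flank = 500000, chromLengths) {
  if (position < 1) stop("marker position must be >= 1")
  .clampInterval(chrom, position - flank, position + flank, chromLengths)
}

#' Linkage interval from genetic-map coordinates
#'
#' When a linkage result reports only a peak in centimorgans, the region is
#' translated to physical coordinates with the 1 cM = 1 Mb convention: the
#' interval covers \code{half_width_cm} on each side of the peak.
#'
#' @param peakCM peak position in cM (>= 0)
#' @param halfWidthCM half-width in cM (> 0)
#' @param chrom chromosome name
#' @param chromLengths named vector of chromosome lengths
#' @return a single-range \code{GRanges}
#' @export
linkageIntervalFromCM <- function(peakCM, halfWidthCM, chrom, chromLengths) {
  if (!is.numeric(halfWidthCM) || halfWidthCM <= 0) {
    stop("halfWidthCM must be positive")
  }
  if (peakCM < 0) stop("peakCM must be >= 0")
  .clampInterval(chrom, round((peakCM - halfWidthCM) * 1e6),
                 round((peakCM + halfWidthCM) * 1e6), chromLengths)
}

#' Genes overlapping a genomic interval
#'
#' Returns every annotated gene overlapping the region by at least 1 bp on
#' the same chromosome, sorted by start position then symbol. An empty result
#' is not an error: markers in gene deserts are dropped by the caller.
#'
#' @param region a single-range \code{GRanges}
#' @param annotation gene \code{GRanges} from \code{\link{readGeneAnnotation}}
#' @return character vector of gene symbols (possibly empty)
#' @export
genesInInterval <- function(region, annotation) {
  hits <- GenomicRanges::findOverlaps(region, annotation, minoverlap = 1,
                                      ignore.strand = TRUE)
  g <- annotation[S4Vectors::subjectHits(hits)]
  ord <- order(GenomicRanges::start(g), g$gene)
  g$gene[ord]
}

#' Read a marker table
#'
#' @param path TSV with columns study_id, evidence_kind, chromosome and
#'   either position_bp (association markers) or peak_cm or start_bp/end_bp
#'   (linkage regions); absent fields left empty/NA
#' @return data.frame of markers
#' @export
readMarkers <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("study_id", "evidence_kind", "chromosome"), names(tab))
  if (length(miss)) stop("marker table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("position_bp", "peak_cm", "start_bp", "end_bp")) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_real_
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  tab
}

#' Expand markers to gene detections
#'
#' Converts each association marker to its ±flank window and each linkage
#' record to its physical interval (reported bp bounds when available,
#' otherwise the cM peak at 1 cM = 1 Mb), extracts overlapping genes, and
#' emits detection rows ready to append to a detections table. Markers whose
#' region contains no gene are dropped and reported.
#'
#' @param markers data.frame from \code{\link{readMarkers}}
#' @param annotation gene \code{GRanges}
#' @param chromLengths named vector of chromosome lengths
#' @param flank association window half-width in bp; default 500000
#' @param halfWidthCM linkage half-width in cM when only a peak is reported;
#'   default 10
#' @return list with \code{detections} (data.frame study_id, evidence_kind,
#'   dataset_id, molecule) and \code{dropped} (marker rows with no genes)
#' @export
markerDetections <- function(markers, annotation, chromLengths,
                             flank = 500000, halfWidthCM = 10) {
  rows <- vector("list", nrow(markers))
  dropped <- integer(0)
  for (i in seq_len(nrow(markers))) {
    m <- markers[i, ]
    region <- if (identical(m$evidence_kind, "association")) {
      associationWindow(m$chromosome, m$position_bp, flank, chromLengths)
    } else if (!is.na(m$start_bp) && !is.na(m$end_bp)) {
      .clampInterval(m$chromosome, m$start_bp, m$end_bp, chromLengths)
    } else {
      linkageIntervalFromCM(m$peak_cm, halfWidthCM, m$chromosome, chromLengths)
    }
    genes <- genesInInterval(region, annotation)
    if (length(genes) == 0) {
      dropped <- c(dropped, i)
      next
    }
    rows[[i]] <- data.frame(study_id = m$study_id,
                            evidence_kind = m$evidence_kind,
                            dataset_id = "1", molecule = genes,
                            stringsAsFactors = FALSE)
  }
  list(detections = do.call(rbind, rows),
       dropped = markers[dropped, , drop = FALSE])
}
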