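chromLens <- c(chr4 = 1e7)

test_that("association windows are +/-flank and clamp at chromosome bounds", {
  w <- associationWindow("chr4", 1e6, 5e5, chromLens)
  expect_equal(GenomicRanges::start(w), 5e5)
  expect_equal(GenomicRanges::end(w), 15e5)
  expect_equal(GenomicRanges::width(w), 2 * 5e5 + 1)
  # clamped at start and at end
  expect_equal(GenomicRanges::start(associationWindow("chr4", 2e5, 5e5, chromLens)), 1)
  expect_equal(GenomicRanges::end(associationWindow("chr4", 2e5, 5e5, chromLens)), 7e5)
  hi <- associationWindow("chr4", 99e5, 5e5, chromLens)
  expect_equal(c(GenomicRanges::start(hi), GenomicRanges::end(hi)), c(94e5, 1e7))
  expect_error(associationWindow("chrZZ", 1e6, 5e5, chromLens), "chromosome")
})

test_that("cM positions convert at exactly 1 cM = 1 Mb", {
  iv <- linkageIntervalFromCM(50, 10, "chr4", c(chr4 = 1e8))
  expect_equal(GenomicRanges::start(iv), 4e7)
  expect_equal(GenomicRanges::end(iv), 6e7)
  lo <- linkageIntervalFromCM(5, 10, "chr4", c(chr4 = 1e8))
  expect_equal(GenomicRanges::start(lo), 1)
  expect_equal(GenomicRanges::end(lo), 1.5e7)
  expect_error(linkageIntervalFromCM(50, 0, "chr4", c(chr4 = 1e8)), "positive")
})

makeAnnotation <- function(starts, ends, chrom = "chr1", len = 1e6,
                           genes = sprintf("g%02d", seq_along(starts))) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  gr$gene <- genes
  GenomeInfoDb::seqlengths(gr) <- setNames(len, chrom)
  gr
}

test_that("interval gene extraction uses 1 bp inclusive overlap", {
  ann <- makeAnnotation(c(150, 201, 200), c(300, 400, 250),
                        genes = c("A", "B", "C"))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  # B starts just past the inclusive end; C touches it at one bp
  expect_equal(genesInInterval(region, ann), c("A", "C"))
  desert <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600))
  expect_equal(genesInInterval(desert, ann), character(0))
})

test_that("interval extraction matches an exhaustive scan on random fixtures", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    starts <- sort(sample(1:9e5, n))
    ends <- pmin(1e6, starts + sample(1e3:5e4, n, replace = TRUE))
    ann <- makeAnnotation(starts, ends)
    qs <- sample(1:9e5, 1)
    qe <- min(1e6, qs + sample(1e3:2e5, 1))
    region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(qs, qe))
    got <- genesInInterval(region, ann)
    # O(n) oracle: inclusive-coordinate overlap
    keep <- starts <= qe & ends >= qs
    expected <- ann$gene[keep][order(starts[keep], ann$gene[keep])]
    expect_equal(got, expected)
  }
})

test_that("enlarging the flank never removes a gene (monotonicity)", {
  set.seed(11)
  starts <- sort(sample(1:9e5, 30))
  ann <- makeAnnotation(starts, pmin(1e6, starts + 2e4))
  lens <- c(chr1 = 1e6)
  for (pos in sample(1:9e5, 10)) {
    g1 <- genesInInterval(associationWindow("chr1", pos, 1e4, lens), ann)
    g2 <- genesInInterval(associationWindow("chr1", pos, 8e4, lens), ann)
    expect_true(all(g1 %in% g2))
  }
})

test_that("annotation files round-trip through GFF3 with length validation", {
  dir <- tempfile()
  sim <- generateAnnotation(nChrom = 1, genesPerChrom = 10, geneLength = 1e4,
                            spacing = 1e5, markersPerChrom = 1, seed = 3,
                            dir = dir)
  sizes <- readChromSizes(file.path(dir, "chrom.sizes"))
  ann <- readGeneAnnotation(file.path(dir, "genes.gff3"), sizes)
  expect_equal(length(ann), 10)
  expect_equal(sort(ann$gene), sort(sim$annotation$gene))
  expect_equal(GenomicRanges::start(ann), GenomicRanges::start(sim$annotation))
  # marker mid-gene grid: hand enumeration of a +/-500 kb window
  mid <- 450001 # inside gene 5's block, window covers genes 1..10 partially
  genes <- genesInInterval(associationWindow("chr1", mid, 5e5, sizes), ann)
  starts <- GenomicRanges::start(sim$annotation)
  expected <- sim$annotation$gene[starts <= mid + 5e5 &
                                  (starts + 1e4 - 1) >= mid - 5e5]
  expect_setequal(genes, expected)
})

test_that("marker expansion drops gene-desert markers and keeps the rest", {
  ann <- makeAnnotation(c(1000, 5000), c(1999, 5999), genes = c("A", "B"))
  lens <- c(chr1 = 1e6)
  mk <- data.frame(study_id = "s1", evidence_kind = "association",
                   chromosome = "chr1",
                   position_bp = c(1500, 5500, 900000),
                   peak_cm = NA_real_, start_bp = NA_real_, end_bp = NA_real_,
                   stringsAsFactors = FALSE)
  res <- markerDetections(mk, ann, lens, flank = 1000)
  expect_equal(sort(unique(res$detections$molecule)), c("A", "B"))
  expect_equal(nrow(res$dropped), 1)
  expect_equal(res$dropped$position_bp, 900000)
})
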