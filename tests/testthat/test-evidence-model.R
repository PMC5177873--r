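test_that("layer splitting follows study structure", {
  db <- loadToyDB()
  expect_s4_class(db, "EvidenceDB")
  expect_equal(nrow(studies(db)), 3)
  # hs1 reports association + linkage -> two layers sharing one study_id
  ly <- evidenceLayers(db)
  expect_equal(nrow(ly), 4)
  expect_equal(sum(ly$study_id == "hs1"), 2)
  expect_setequal(ly$layer_kind[ly$study_id == "hs1"],
                  c("association", "linkage"))
  expect_true(all(is.na(ly$weight)))
})

test_that("multi-dataset studies yield one layer per dataset", {
  st <- data.frame(study_id = "s1", species_group = "songbird",
                   study_group = "other", phenotype_precise = 0L,
                   phenotype_classes = "listening", sample_size = 8L,
                   evidence_kinds = "expression", stringsAsFactors = FALSE)
  det <- data.frame(study_id = "s1", evidence_kind = "expression",
                    dataset_id = c("d1", "d2", "d3"),
                    molecule = c("a", "b", "c"), stringsAsFactors = FALSE)
  dir <- tempfile(); dir.create(dir)
  write.table(st, file.path(dir, "s.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(det, file.path(dir, "d.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  db <- readStudyDatabase(file.path(dir, "s.tsv"), file.path(dir, "d.tsv"))
  expect_equal(nrow(evidenceLayers(db)), 3)
  expect_equal(unique(evidenceLayers(db)$study_id), "s1")
})

test_that("loader rejects malformed databases", {
  st <- toyStudies()
  det <- toyDetections()
  dir <- tempfile(); dir.create(dir)
  wr <- function(s, d) {
    write.table(s, file.path(dir, "s.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(d, file.path(dir, "d.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    readStudyDatabase(file.path(dir, "s.tsv"), file.path(dir, "d.tsv"))
  }
  expect_error(wr(rbind(st, st[1, ]), det), "hs1")
  badDet <- det; badDet$study_id[1] <- "ghost"
  expect_error(wr(st, badDet), "ghost")
  # declared linkage kind with no detection rows
  expect_error(wr(st, det[det$evidence_kind != "linkage", ]),
               "empty detected set")
})

test_that("molecule normalization collapses case and types biomarkers", {
  m <- normalizeMolecules(c("egr1", "EGR1 ", "Cortisol"))
  expect_equal(m$identifier, c("EGR1", "cortisol"))
  expect_equal(m$kind, c("gene", "biomarker"))
  expect_error(normalizeMolecules(c("EGR1", "")), "empty")
})

test_that("detection matrix is binary with per-layer deduplication", {
  db <- toyWeightedDB()
  mat <- buildDetectionMatrix(db)
  expect_equal(dim(mat), c(4, nrow(molecules(db))))
  expect_true(all(mat@x %in% c(0, 1)))
  # matrix total equals sum of deduplicated per-layer detection counts
  expect_equal(sum(mat), sum(lengths(detections(db))))
  # EGR1 reported by hs1 association, hs2 (as "egr1") and sb1 (via homolog)
  expect_equal(sum(mat[, "EGR1"]), 3)
})

test_that("database round-trips through its TSV representation", {
  db <- toyWeightedDB()
  dir <- tempfile()
  writeStudyDatabase(db, dir)
  db2 <- readStudyDatabase(file.path(dir, "studies.tsv"),
                           file.path(dir, "detections.tsv"))
  expect_equal(studies(db2), studies(db))
  ly <- evidenceLayers(db)[c("layer_id", "study_id", "layer_kind", "dataset_id")]
  expect_equal(evidenceLayers(db2)[names(ly)], ly)
  expect_equal(detections(db2), detections(db))
})

test_that("JSON and TSV loaders agree on the same database", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(studies = toyStudies(),
                            detections = toyDetections()),
                       path, auto_unbox = TRUE)
  dbJ <- readStudyDatabaseJSON(path)
  dbT <- loadToyDB()
  expect_equal(studies(dbJ), studies(dbT))
  expect_equal(detections(dbJ), detections(dbT))
})

test_that("layer count matches a brute-force recount on random databases", {
  set.seed(42)
  for (rep in 1:5) {
    cfg <- syntheticConfig(
      nStudies = c(human = sample(3:8, 1), songbird = sample(3:8, 1),
                   other_animal = sample(1:4, 1)),
      nGeneMapping = c(human = sample(0:2, 1), songbird = 0, other_animal = 0),
      universeSize = 300, nPlanted = 10, seed = rep)
    sim <- generateStudyDatabase(cfg)
    dir <- tempfile(); dir.create(dir)
    write.table(sim$studies, file.path(dir, "s.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$detections, file.path(dir, "d.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    db <- readStudyDatabase(file.path(dir, "s.tsv"), file.path(dir, "d.tsv"))
    # brute-force: distinct (study, kind, dataset) combinations with rows
    expected <- nrow(unique(sim$detections[c("study_id", "evidence_kind",
                                             "dataset_id")]))
    expect_equal(nrow(evidenceLayers(db)), expected)
  }
})
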