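# in-code fixtures shared across the suite

# three-study toy database: one human gene-mapping study with paired
# association + linkage layers, one precise human expression study, one
# songbird expression study
toyStudies <- function() {
  data.frame(
    study_id = c("hs1", "hs2", "sb1"),
    species_group = c("human", "human", "songbird"),
    study_group = c("gene_mapping", "other", "other"),
    phenotype_precise = c(1L, 1L, 0L),
    phenotype_classes = c("ability", "listening,practice", "practice"),
    sample_size = c(100L, 20L, 10L),
    evidence_kinds = c("association,linkage", "expression", "expression"),
    stringsAsFactors = FALSE
  )
}

toyDetections <- function() {
  data.frame(
    study_id = c("hs1", "hs1", "hs1", "hs2", "hs2", "sb1", "sb1"),
    evidence_kind = c("association", "association", "linkage", "expression",
                      "expression", "expression", "expression"),
    dataset_id = "1",
    molecule = c("EGR1", "FOS", "SNCA", "egr1", "Cortisol", "sb_egr1", "sb_bdnf"),
    stringsAsFactors = FALSE
  )
}

toyHomologs <- function() {
  data.frame(
    species = c("songbird", "songbird", "songbird"),
    source_id = c("sb_egr1", "sb_bdnf", "sb_bdnf"),
    human_symbol = c("EGR1", "BDNF", "BDNF2"),
    stringsAsFactors = FALSE
  )
}

writeToyDatabase <- function(dir = tempfile("toydb")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(toyStudies(), file.path(dir, "studies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(toyDetections(), file.path(dir, "detections.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(toyHomologs(), file.path(dir, "homologs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir
}

loadToyDB <- function(dir = writeToyDatabase()) {
  readStudyDatabase(file.path(dir, "studies.tsv"),
                    file.path(dir, "detections.tsv"))
}

# weighted + harmonized toy database ready for scoring
toyWeightedDB <- function() {
  db <- loadToyDB()
  db <- harmonizeMolecules(db, toyHomologs())
  scoreAllLayers(db)
}

# random detection matrix with named dims, for oracle-equivalence checks
randomDetectionMatrix <- function(nLayers, nMolecules, p = 0.1) {
  m <- Matrix::Matrix(
    matrix(rbinom(nLayers * nMolecules, 1, p), nLayers, nMolecules,
           dimnames = list(sprintf("L%03d", seq_len(nLayers)),
                           sprintf("M%04d", seq_len(nMolecules)))),
    sparse = TRUE)
  m
}

# per-molecule loop oracle for the weighted vote count
ceScoreOracle <- function(mat, w) {
  sapply(colnames(mat), function(g) {
    e <- as.numeric(mat[, g])
    sum(w[rownames(mat)] * e) / sum(w[rownames(mat)])
  })
}

# brute-force hypergeometric upper-tail P(X >= k)
hyperTailOracle <- function(k, m, N, n) {
  js <- k:min(m, n)
  if (k > min(m, n)) return(0)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}
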