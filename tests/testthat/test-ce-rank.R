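test_that("CE score is the weighted mean of detection indicators", {
  mat <- Matrix::Matrix(rbind(L1 = c(1, 1, 0),
                              L2 = c(1, 0, 0),
                              L3 = c(0, 0, 0)), sparse = TRUE)
  colnames(mat) <- c("A", "B", "C")
  w <- c(L1 = 1.0, L2 = 0.8, L3 = 0.5)
  s <- ceScores(mat, w)
  expect_equal(unname(s["A"]), 1.8 / 2.3)
  expect_equal(unname(s["B"]), 1.0 / 2.3)
  expect_equal(unname(s["C"]), 0)
  # full support scores exactly 1
  ones <- mat; ones[] <- 1
  expect_equal(unname(ceScores(ones, w)), rep(1, 3))
  expect_error(ceScores(mat, w[1:2]), "missing weight")
  expect_error(ceScores(mat, c(L1 = 0, L2 = 0, L3 = 0)), "positive")
})

test_that("vectorized scores equal the per-molecule loop oracle", {
  set.seed(13)
  for (rep in 1:10) {
    nL <- sample(5:60, 1); nM <- sample(10:300, 1)
    mat <- randomDetectionMatrix(nL, nM)
    w <- setNames(runif(nL, 0.5, 1), rownames(mat))
    expect_equal(ceScores(mat, w), ceScoreOracle(mat, w), tolerance = 1e-12)
  }
})

test_that("scores are invariant to rescaling all weights", {
  set.seed(21)
  mat <- randomDetectionMatrix(40, 200)
  w <- setNames(runif(40, 0.5, 1), rownames(mat))
  base <- ceScores(mat, w)
  for (c in c(0.1, 10)) {
    expect_equal(ceScores(mat, w * c), base, tolerance = 1e-12)
  }
})

test_that("uniform weights reduce CE to unweighted vote counting", {
  set.seed(22)
  mat <- randomDetectionMatrix(30, 100)
  w <- setNames(rep(0.7, 30), rownames(mat))
  expect_equal(ceScores(mat, w),
               setNames(as.numeric(Matrix::colSums(mat)) / 30, colnames(mat)),
               tolerance = 1e-12)
})

test_that("adding a detection raises a score; adding an empty layer lowers it", {
  mat <- Matrix::Matrix(rbind(L1 = c(1, 0), L2 = c(0, 1)), sparse = TRUE)
  colnames(mat) <- c("A", "B")
  w <- c(L1 = 0.9, L2 = 0.6)
  s0 <- ceScores(mat, w)
  mat2 <- mat; mat2["L2", "A"] <- 1
  expect_gt(ceScores(mat2, w)["A"], s0["A"])
  mat3 <- Matrix::Matrix(rbind(L1 = c(1, 0), L2 = c(0, 1), L3 = c(0, 0)),
                         sparse = TRUE)
  colnames(mat3) <- c("A", "B")
  expect_lt(ceScores(mat3, c(w, L3 = 0.8))["A"], s0["A"])
})

test_that("ranking is deterministic: score, then count, then name", {
  ranked <- rankMolecules(c(A = 0.5, B = 0.5, C = 0.2), c(A = 3, B = 2, C = 1))
  expect_equal(ranked$molecule, c("A", "B", "C"))
  expect_equal(ranked$rank, 1:3)
  # equal scores and counts: lexicographic
  r2 <- rankMolecules(c(Y = 0.4, X = 0.4), c(Y = 2, X = 2))
  expect_equal(r2$molecule, c("X", "Y"))
  expect_equal(rankMolecules(c(Z = 0.1))$rank, 1L)
  expect_error(rankMolecules(numeric(0)), "empty")
})

test_that("top-quantile selection takes ceil((1-q)N) molecules", {
  scores <- setNames(runif(1000), sprintf("M%04d", 1:1000))
  ranked <- rankMolecules(scores)
  expect_equal(nrow(selectTopQuantile(ranked, 0.95)), 50)
  expect_equal(nrow(selectTopQuantile(ranked[1:200, ], 0.995)), 1)
  expect_error(selectTopQuantile(ranked, 1), "between 0 and 1")
  expect_error(selectTopQuantile(ranked, 0), "between 0 and 1")
})

test_that("stratified ranking restricts layers and its denominator", {
  db <- toyWeightedDB()
  mat <- buildDetectionMatrix(db)
  # hs2 is in both listening and practice: its layer serves both strata
  li <- stratifiedRank(db, "listening", mat)
  pr <- stratifiedRank(db, "practice", mat)
  expect_true("CORTISOL" %in% toupper(li$molecule) ||
              "cortisol" %in% li$molecule)
  # ability stratum contains only hs1's gene-mapping molecules
  ab <- stratifiedRank(db, "ability", mat)
  expect_setequal(ab$molecule, c("EGR1", "FOS", "SNCA"))
  # molecules undetected in a stratum are absent from it
  expect_false("SNCA" %in% li$molecule)
  # denominator is the stratum's own weight total
  ly <- evidenceLayers(db)
  abLayers <- ly[ly$study_id == "hs1", ]
  expect_equal(ab$score[ab$molecule == "EGR1"],
               abLayers$weight[abLayers$layer_kind == "association"] /
                 sum(abLayers$weight))
  expect_error(stratifiedRank(db, "nonsense"))
})

test_that("one-class databases stratify to the global ranking", {
  st <- toyStudies()
  st$phenotype_classes <- "practice"
  dir <- tempfile(); dir.create(dir)
  write.table(st, file.path(dir, "s.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(toyDetections(), file.path(dir, "d.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  db <- readStudyDatabase(file.path(dir, "s.tsv"), file.path(dir, "d.tsv"))
  db <- scoreAllLayers(harmonizeMolecules(db, toyHomologs()))
  mat <- buildDetectionMatrix(db)
  strat <- stratifiedRank(db, "practice", mat)
  glob <- rankMolecules(ceScores(mat, layerWeights(db)),
                        setNames(as.integer(Matrix::colSums(mat)), colnames(mat)))
  expect_equal(as.data.frame(strat), as.data.frame(glob))
})

test_that("rank table counts distinct studies by species and class", {
  db <- toyWeightedDB()
  tab <- ceRankTable(db)
  egr1 <- tab[tab$molecule == "EGR1", ]
  # EGR1: hs1 association + hs2 expression + sb1 homolog
  expect_equal(egr1$n_human, 2L)
  expect_equal(egr1$n_songbird, 1L)
  expect_equal(egr1$n_other_animal, 0L)
  expect_equal(egr1$n_ability, 1L)   # hs1 only
  expect_equal(egr1$n_listening, 1L) # hs2
  expect_equal(egr1$n_practice, 2L)  # hs2 + sb1
  # scores round to 3 decimals at output only
  path <- tempfile(fileext = ".tsv")
  writeRanks(tab, path)
  out <- read.delim(path, colClasses = "character")
  expect_true(all(grepl("^[0-9]+\\.[0-9]{3}$", out$score)))
})
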