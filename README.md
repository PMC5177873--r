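# ceRank

Convergent-evidence gene prioritization by weighted vote counting.

## What it is for

Some phenotypes — musical traits, and similarly amorphous behavioural or
neuropsychiatric traits — accumulate molecular evidence across study designs
that cannot be pooled on a common effect-size scale: GWAS and linkage scans,
candidate-gene tests, songbird and rodent expression experiments, hormone
measurements. `ceRank` is for analysts who have curated such a study
collection and want a principled, reproducible ranking of the genes and
biomarkers those studies convergently implicate.

Each study contributes one or more binary *evidence layers* (a gene-mapping
study with both association and linkage results contributes two). Layer *i*
carries a custom weight

    w_i = phenotype_factor × homology_factor × size_factor × linkage_multiplier

with each self-importance factor in [0.8, 1] (precise phenotype, human
study, and largest-in-pool sample size score 1.0; the floors score 0.8) and
a 0.9 multiplier on linkage layers paired with an association layer from the
same study — so unpaired weights span [0.512, 1]. A molecule's
convergent-evidence score is the weighted mean of its detection indicators,

    CE_g = Σ_i w_i · e_gi / Σ_i w_i ∈ [0, 1],

molecules are ranked (score, then detection count, then name), the top
⌈(1−q)·N⌉ are selected (q = 0.995 by default), the analysis repeats within
listening / ability / practice subphenotype strata, and the top set is
characterized by Fisher-exact over-representation and a triangle-seeded,
node-disjoint interaction-network builder (35-node cap). Association markers
map to genes via ±500 kb windows, linkage peaks via 1 cM = 1 Mb; non-human
molecules translate through a user-supplied many-to-many homolog table.

## Worked example

```r
library(ceRank)

# a synthetic study collection: 16 studies, 2 of them gene-mapping with
# paired association + linkage layers; 12 planted signal genes
cfg <- syntheticConfig(nStudies = c(human = 6, songbird = 8, other_animal = 2),
                       nGeneMapping = c(human = 2, songbird = 0, other_animal = 0),
                       universeSize = 500, nPlanted = 12, seed = 7)
sim <- generateStudyDatabase(cfg, dir = "simdb")

db <- readStudyDatabase("simdb/studies.tsv", "simdb/detections.tsv")
db
#> EvidenceDB with 16 studies, 18 evidence layers
#>   species: human=6, songbird=8, other_animal=2
#>   weighted layers: 0/18
#>   molecules: not yet harmonized (see harmonizeMolecules)

db <- harmonizeMolecules(db, readHomologTable("simdb/homologs.tsv"))
db <- scoreAllLayers(db)
range(evidenceLayers(db)$weight)
#> [1] 0.5195294 1.0000000

mat <- buildDetectionMatrix(db)
head(ceRankTable(db, mat), 3)
#>   molecule     score rank n_layers_detected kind n_human n_songbird ...
#> 1   G00298 0.4917564    1                 9 gene       4          3
#> 2   G00103 0.4433762    2                 7 gene       4          1
#> 3   G00415 0.3932249    3                 7 gene       3          4
```

The top-ranked molecule was detected by 9 of the 18 layers (4 human and 3
songbird studies among them) and collects 49% of the total vote weight; its
score is below 1 because most layers did not report it. `stratifiedRank(db,
"listening", mat)` re-ranks within the listening-class layers only, and
`selectTopQuantile(...)`, `fisherEnrichment(...)` and `buildNetworks(...)`
take the analysis through to the characterized top set. For a file-driven
run, `runPipeline("config.yaml")` executes the whole chain and writes
`weights.tsv`, `ranks.tsv`, per-class rankings, `enrichment.tsv`,
`networks.tsv` and a JSON run manifest; `inst/scripts/ce-pipeline.R` is a
thin shell wrapper around it.

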