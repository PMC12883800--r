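# fscchange

Vegetation cover type classification and change detection at the forest
sub-compartment (FSC) scale.

An FSC is the basic operational polygon unit of forest inventory — an
internally homogeneous stand, typically 5–20 ha, carrying attributes such as
area and vegetation cover type. Monitoring when an FSC's cover type changes
(Arbor ↔ Shrub ↔ Bamboo ↔ Bare ↔ Other) is how forest managers keep inventory
databases current, but manual interpretation of two-epoch imagery is slow and
subjective. `fscchange` implements a polygon-level, post-classification
change detection pipeline for 10 m multispectral imagery:

1. **Patch extraction** — for each FSC polygon, a fixed 5×5-pixel window
   (50 m × 50 m) centered on the pixel nearest the polygon's interior anchor
   point (the geometric centroid, or a guaranteed-interior point for concave
   polygons). FSCs larger than 3,000 m² (strict inequality) are
   training-eligible; smaller ones are kept for prediction but flagged
   out-of-distribution.
2. **Features** — per-patch means of bands B2/B3/B4/B8 (optionally B11/B12);
   ten vegetation indices (NDVI, EVI, NBRI, SAVI, RVI, DVI, NDBI, BGRVI,
   GNDVI, NDWI) evaluated on the band means; eight gray-level co-occurrence
   matrix (GLCM) texture metrics (MEAN, VAR, HOM, CON, DIS, ENT, ENE, COR) at
   32 gray levels, distance 1, averaged over the symmetric 4-angle set.
3. **Feature selection** — gradient-boosted-tree gain importance computed
   separately for the spectral group (bands + indices) and the texture group,
   with the smallest prefix reaching 85% cumulative contribution selected per
   group.
4. **Classifiers** — random forest (50 trees, depth 8) and RBF-kernel SVM
   (C = 100) baselines, a two-hidden-layer backpropagation network (BPNN:
   ReLU, softmax, full-batch Adam, 300 epochs), and the core **PSO-BPNN**: a
   particle swarm (inertia weight decayed 0.9 → 0.4, c1 = c2 = 1.5) first
   searches the hidden-layer sizes (16–128) and learning rate (0.001–0.1) by
   validation loss after a short proxy training, then optimizes the initial
   weight vector of the chosen architecture before the full training run.
5. **Change detection and evaluation** — per-FSC label comparison across
   epochs, K×K transition matrices (rows = earlier epoch) with retention and
   conversion rates, confusion-matrix metrics (overall accuracy, macro
   precision/recall/F1, Cohen's kappa), change-detection rate against a
   reference change set, and Clark–Evans nearest-neighbor-index clustering of
   change locations.

Because real FSC inventories are not publicly distributable, the package
includes a first-class synthetic scene generator (`generateScenePair()`):
Voronoi tessellation with a heavy-tailed area distribution, five class
signatures with distinct band means and distinct spatial autocorrelation
(so Arbor and Bamboo separate mainly by texture), and a configurable fraction
of injected label changes — giving an end-to-end testbed with known ground
truth.

## Worked example

```r
library(fscchange)

pair <- generateScenePair(sceneConfig(gridShape = c(280, 280), nFsc = 800,
                                      changeFraction = 0.1, seed = 3))
tab1 <- featureTable(pair$epoch1, pair$fsc)   # one row per FSC
tab2 <- featureTable(pair$epoch2, pair$fsc)

use <- which(tab1$valid)
sp  <- trainTestSplit(tab1$label[use], tab1$in_distribution[use], seed = 1)
tr  <- use[sp$train]; te <- use[sp$test]
fc  <- featureColumns(tab1)

model <- trainPsoBpnn(tab1[tr, fc], tab1$label[tr],
                      psoStage1 = psoConfig(swarmSize = 8, iterations = 6, seed = 1),
                      psoStage2 = psoConfig(swarmSize = 8, iterations = 6, seed = 2),
                      proxyEpochs = 25, finalEpochs = 300, seed = 1)

teID <- te[tab1$in_distribution[te]]
pred <- predictClasses(model, tab1[teID, fc])
m <- classificationMetrics(confusionCounts(tab1$label[teID], pred$labels))
round(c(OA = m$OA, kappa = m$kappa), 3)
#>    OA kappa
#> 0.961 0.938

ok <- which(tab1$valid & tab2$valid)
ids <- fscIds(pair$fsc)
rec <- compareEpochs(
  setNames(predictClasses(model, tab1[ok, fc])$labels, ids[ok]),
  setNames(predictClasses(model, tab2[ok, fc])$labels, ids[ok]))
labs <- fscLabels(pair$fsc)
dr <- detectionRate(ids[labs$e1 != labs$e2], rec$fsc_id[rec$changed])
unlist(dr)
#> detected   missed     rate
#>   66.000   14.000    0.825
```

The holdout overall accuracy (0.961) and kappa (0.938) say the classifier
recovers the five cover types on training-scale polygons; the detection rate
says 66 of the 80 injected cover-type changes were flagged by comparing the
two epochs' predicted labels.

A printed county-scale transition table ships with the package and
illustrates the rate functions:

```r
tab <- read.csv(system.file("extdata", "transitions_2019_2020.csv",
                            package = "fscchange"), check.names = FALSE)
counts <- as.matrix(tab[, -1]); rownames(counts) <- tab$from
storage.mode(counts) <- "integer"
tm <- new("TransitionMatrix", counts = counts, classOrder = rownames(counts),
          epochPair = c("2019", "2020"))
round(retentionRate(tm, "Arbor"), 2)            #> 99.7
round(conversionRate(tm, "Bamboo", "Arbor"), 2) #> 0.18
```

## Command line

A thin wrapper over the stage functions lives at `inst/cli/fscchange.R`:

```sh
Rscript inst/cli/fscchange.R all --config run.yaml --seed 1 --out out/
```

Subcommands `simulate`, `features`, `select`, `train`, `classify`, `change`,
`evaluate` run individual stages; each writes a manifest with a config hash
and refuses stale upstream artifacts. Exit codes: 0 success, 2 config error,
3 data error, 4 runtime error.

## Vignette

`vignettes/fsc-change-detection.Rmd` documents the model and its assumptions,
every tunable parameter with its default and rationale, what the synthetic
scenes do and do not emulate, and the numerical edge-case conventions.
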