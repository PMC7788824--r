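# seqchrom

Does preexisting chromatin explain where an induced transcription factor
binds, beyond what DNA sequence already explains?

When a TF is induced in a cell type where it was previously absent, its
binding sites divide into those predictable from sequence alone and those
that additionally depend on the chromatin landscape that preceded
induction. **seqchrom** models this question directly with an *additive
bimodal* neural network: a CNN–LSTM sequence sub-network and a CNN–LSTM
chromatin sub-network each produce a bounded scalar, and the two are
combined linearly on the logit scale,

```
logit P(bound) = b0 + bS * phiS(sequence) + bC * phiC(chromatin).
```

Because the modalities interact only through this sum, every prediction
decomposes **exactly** into a sequence contribution (`seqscore = bS*phiS`)
and a chromatin contribution (`chromscore = bC*phiC`) — a two-dimensional
latent space in which bound sites can be classified as sequence-driven or
chromatin-driven without any post-hoc approximation.

The package provides:

* **Data handling** — FASTA genomes, peak calls, bedGraph coverage into
  Bioconductor containers (`DNAStringSet`, `GRanges`, `RleList`); window
  tiling, depth-normalized binned tag matrices, accessibility assignment.
* **Networks** — the two sub-networks and the sequence-only baseline,
  built on an engine implemented in the package (hand-derived
  backpropagation, C++ inner loops); no external deep-learning framework.
* **Training** — accessibility-matched batch samplers with audited
  contracts; two-stage transfer (train sequence-only, freeze the trunk
  below the last two dense layers, then train chromatin + combiner); the
  combiner warm-starts at the donor solution and a one-standard-error
  rule keeps the sequence-only solution unless chromatin clearly helps
  on validation data.
* **Evaluation** — chromosome-holdout splits, tie-aware PR curves,
  auPRC, recall-at-FPR, a conjugate Beta recall posterior, exact paired
  Wilcoxon model comparison.
* **Interpretation** — the exact latent embedding; integrated-gradients
  sequence attribution with saliency-hill extraction and k-mer
  clustering; in-silico motif multiplicity and flank scans.
* **Synthetic data** — a generator with known ground truth (motif CAGSTG,
  accessibility domains, a compensation rule that makes inaccessible
  bound sites carry more motifs) plus a `chromatin_noise` falsification
  preset; text-only, byte-reproducible fixtures.
* **CLI** — `inst/scripts/seqchrom` with `simulate`, `prepare`,
  `train-seq`, `train-bimodal`, `kfold`, `evaluate`, `embed`,
  `attribute`, `scan-multiplicity`, `scan-flanks`.

## Worked example

Simulate a small study (three 200 kb chromosomes), hold out one
chromosome each for validation and test, and run the two-stage protocol.
Everything below is actual output.

```r
library(seqchrom)

sim <- simulateDataset(simConfig("tiny", chromLength = 200000L), seed = 401L)
sp  <- simSplit(sim, testChrom = "chrS3", valChrom = "chrS2", trainStep = 100L)
sp$train
#> ChromDataset: 1902 windows x 500 bp, 10 bins x 2 tracks
#>   labels: unbound=1724, bound=178, ambiguous=0
#>   accessible: 571 of 1902

seqRun <- trainSequenceNetwork(
  sp$train, sp$val,
  config = seqSubnetConfig("tiny", nFilters = 8L, denseSizes = c(8L, 4L),
                           lstmUnits = 8L),
  seed = 401L, epochs = 8L, batchSize = 64L, posFrac = 0.5, lr = 3e-3)

bimRun <- transferAndTrainBimodal(
  seqRun, sp$train, sp$val,
  chrConfig = chrSubnetConfig(nFilters = 4L, lstmUnits = 4L, denseSize = 4L),
  seed = 401L, epochs = 5L, batchSize = 64L, posFrac = 0.5, lr = 3e-3)
runHistory(bimRun)
#>   epoch trainLoss   valAuprc
#> 1     0        NA 0.07420251   <- warm start = sequence-only solution
#> 2     1 0.6889003 0.08234228
#> 3     2 0.6916602 0.09778365
#> 4     3 0.6966555 0.10537975
#> 5     4 0.6882544 0.11359317
#> 6     5 0.6899637 0.12715614
```

The chromatin tracks are informative in this preset, so validation auPRC
climbs away from the warm start. On the held-out chromosome:

```r
y <- as.numeric(bindingLabels(sp$test) == "bound")
auprc(predictProb(trainedModel(seqRun), seqOneHot(sp$test)), y)
#> sequence-only test auPRC: 0.066
auprc(predictProb(trainedModel(bimRun), sp$test), y)
#> bimodal test auPRC:       0.16

ev <- evaluateModel(trainedModel(bimRun), sp$test, fpr = 0.05)
#> recall at FPR 0.05: 0.211 (posterior mode 0.211, 95% CI 0.087-0.437)
```

Every prediction decomposes exactly into its two latent coordinates:

```r
emb <- latentEmbed(trainedModel(bimRun), sp$test)
emb
#> LatentEmbedding: 380 windows; max additivity residual 4.09e-16
head(as.data.frame(emb)[bindingLabels(sp$test) == "bound",
                        c("seqscore", "chromscore", "prob")], 3)
#>       seqscore    chromscore      prob
#> 27 -0.05483206 -0.0318934775 0.4784204
#> 40 -0.07767720  0.0001459143 0.4807151
#> 59 -0.01332507 -0.0004993770 0.4966323
```

`extractSpCp(emb)` then pulls out the sequence-preferring and
chromatin-preferring quartiles of bound sites, and
`attributeWindows()` / `findHills()` / `clusterHills()` recover the
planted CAGSTG motif from integrated-gradients saliency.

## The falsification control

The benchmark headline (see `scripts/acceptance.R`) trains on the
`default` preset (six 300 kb chromosomes, informative chromatin) and on
`chromatin_noise` (identical track marginals, decoupled from binding).
Under the frozen conditions used by the test suite (simulation seed 1,
training seed 7, test chrS6, validation chrS5, 20 sequence / 12 bimodal
epochs):

| preset | seq auPRC | bimodal auPRC | delta |
|---|---|---|---|
| default | 0.080 | 0.220 | **+0.140** |
| chromatin_noise | 0.397 | 0.397 | **0.000** |

On noise tracks the one-standard-error selection rule keeps the
warm-start checkpoint (`bC = 0`), so the bimodal model degrades exactly
to its own sequence baseline instead of overfitting the noise.

The motif-compensation block of the test suite trains its own donor for
30 sequence epochs (same seeds, same architecture): on the default
preset the sequence stage learns slowly — accessible windows bound
without a motif act as label noise inside matched batches — and at the
20-epoch cutoff the trunk does not yet track motif count. At 30 epochs
it does (test auPRC 0.274, bimodal 0.308), and the latent embedding
separates bound-inaccessible windows (median seqscore 1.22) from
bound-accessible ones (−1.02), recovering the planted compensation.

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "seqchrom",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The test suite includes a property-based acceptance file
(`tests/testthat/test-acceptance.R`): exact additivity, closed-form
cross-entropy and recall posterior, brute-force PR-metric oracles,
sampler contracts, bitwise freeze verification, the two preset deltas
above, motif-compensation recovery, integrated-gradients axioms, motif
family clustering, and byte-level reproducibility. `acceptance.json`
records the principal quantities of the headline computation (preset
auPRCs and deltas, combiner weights, additivity residual, seqscore
medians by accessibility, recall posterior, multiplicity-scan medians,
attribution summary) for the seed you pass; all sub-seeds are derived
from `--seed`, so the script's simulation differs from the fixed-seed
table above. At some seeds the sequence stage alone is strong enough
that the chromatin gain on the default preset stays inside one standard
error of the warm start, and the selection rule then reports the
sequence baseline (`bC = 0`, delta 0) there as well — the conservative
bias of one-SE selection, not a failure of the tracks.

See the vignette (`vignettes/bimodal-binding-methods.Rmd`) for the
modeling rationale: the additive commitment, pool-width choice at desk
scale, the warm start and one-SE selection rule, sampler contracts, and
the generator's compensation structure.
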