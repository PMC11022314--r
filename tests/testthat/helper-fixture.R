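# Shared end-to-end fixture: a synthetic taxonomy of 6 genera x 3 species
# (200 kbp genomes, 2% within-genus divergence), a genus-level model
# trained on 2 species per genus at 5x coverage of 1 kbp subsequences, and
# noisy 5 kbp reads for both training species and the held-out species.
# Built lazily once per test run and cached; all seeds fixed.

fixtureEnv <- new.env(parent = emptyenv())

e2eFixture <- function() {
  if (!is.null(fixtureEnv$fx)) return(fixtureEnv$fx)
  baseSeed <- 101L
  sim <- simulateTaxonomy(nGenera = 6, speciesPerGenus = 3,
                          genomeLength = 200000, divergence = 0.02,
                          seed = baseSeed)
  split <- holdoutSplit(sim$taxonomy, 1, seed = baseSeed + 1L)
  index <- buildKmerIndex(6)
  inGenomes <- sim$genomes[split$inDb]
  train <- buildTrainingSet(inGenomes, sim$taxonomy, index, "genus",
                            seqLength = 1000, coverage = 5,
                            seed = baseSeed + 2L)
  val <- buildTrainingSet(inGenomes, sim$taxonomy, index, "genus",
                          seqLength = 1000, coverage = 1,
                          seed = baseSeed + 3L)
  model <- trainClassifier(train$x, train$labels, val$x, val$labels, k = 6,
                           hiddenDims = c(128L, 64L), batchSize = 128L,
                           learningRate = 3e-3, maxEpochs = 60L,
                           patience = 5L, seed = baseSeed + 4L)
  fixtureEnv$fx <- list(sim = sim, split = split, index = index,
                        train = train, val = val, model = model,
                        baseSeed = baseSeed)
  fixtureEnv$fx
}

# k-mer-size and coverage trend experiments on the fixture taxonomy:
# train genus-level models for k in 3..6 (5x coverage) and for coverage
# 1x at k = 6, and score each on noisy ~1 kbp validation reads.
trendExperiments <- function() {
  if (!is.null(fixtureEnv$trend)) return(fixtureEnv$trend)
  fx <- e2eFixture()
  b <- fx$baseSeed
  inGenomes <- fx$sim$genomes[fx$split$inDb]
  genusLab <- genusOf(fx$sim$taxonomy, fx$split$inDb)

  sampleLabelled <- function(coverage, seed) {
    set.seed(seed)
    parts <- lapply(names(inGenomes), function(sp) {
      smp <- sampleSequences(inGenomes[[sp]], seqLength = 1000,
                             coverage = coverage)
      data.frame(sequence = smp$sequence, genus = unname(genusLab[sp]))
    })
    do.call(rbind, parts)
  }
  train <- sampleLabelled(5, b + 10L)
  val <- sampleLabelled(1, b + 11L)
  noisyVal <- corruptReads(
    Biostrings::DNAStringSet(setNames(val$sequence,
                                      sprintf("v%05d", seq_len(nrow(val))))),
    accuracy = 0.95, seed = b + 12L)
  truth <- setNames(val$genus, names(noisyVal))
  genera <- sort(unique(val$genus))

  scoreModel <- function(model) {
    preds <- classifyReads(noisyVal, model)
    readLevelMetrics(preds, truth)$summary[["f1"]]
  }
  fitOn <- function(x, labels, xv, lv, k, seed) {
    trainClassifier(x, labels, xv, lv, k = k, hiddenDims = c(128L, 64L),
                    batchSize = 128L, learningRate = 3e-3,
                    maxEpochs = 40L, patience = 5L, seed = seed)
  }

  f1ByK <- vapply(3:6, function(k) {
    idx <- buildKmerIndex(k)
    xt <- kmerProfileMatrix(train$sequence, idx)
    xv <- kmerProfileMatrix(val$sequence, idx)
    lt <- factor(train$genus, levels = genera)
    lv <- factor(val$genus, levels = genera)
    scoreModel(fitOn(xt, lt, xv, lv, k, b + 20L + k))
  }, 0)
  names(f1ByK) <- 3:6

  train1 <- sampleLabelled(1, b + 30L)
  idx6 <- buildKmerIndex(6)
  f1Cov1 <- scoreModel(fitOn(
    kmerProfileMatrix(train1$sequence, idx6),
    factor(train1$genus, levels = genera),
    kmerProfileMatrix(val$sequence, idx6),
    factor(val$genus, levels = genera), 6, b + 31L))

  fixtureEnv$trend <- list(f1ByK = f1ByK, f1Cov1 = f1Cov1,
                           f1Cov5 = unname(f1ByK["6"]))
  fixtureEnv$trend
}

# Noisy long reads drawn from given species' genomes; names encode the
# source species as "<species>.rN".
fixtureReads <- function(fx, species, nPerSpecies = 20, readLength = 5000,
                         accuracy = 0.95, seed = 1L) {
  reads <- character(0)
  for (i in seq_along(species)) {
    sp <- species[i]
    genome <- fx$sim$genomes[[sp]]
    cov <- nPerSpecies * readLength / length(genome)
    smp <- sampleSequences(genome, seqLength = readLength, coverage = cov,
                           seed = seed + i)
    reads <- c(reads, setNames(smp$sequence,
                               sprintf("%s.r%03d", sp, seq_len(nrow(smp)))))
  }
  corruptReads(Biostrings::DNAStringSet(reads), accuracy = accuracy,
               seed = seed + length(species) + 1L)
}

# Genus-level read metrics for predictions whose read ids encode the
# source species.
fixtureGenusMetrics <- function(fx, preds) {
  species <- sub("\\.r[0-9]+$", "", preds$read_id)
  truth <- setNames(unname(genusOf(fx$sim$taxonomy, species)),
                    preds$read_id)
  readLevelMetrics(preds, truth)
}
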