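test_that("read-level metrics match the hand-computed confusion matrix", {
  truth <- setNames(rep(c("A", "B"), each = 10), paste0("r", 1:20))
  pred <- c(rep("A", 8), rep("UNCLASSIFIED", 2),  # reads of A
            rep("B", 9), "A")                     # reads of B
  preds <- data.frame(read_id = paste0("r", 1:20), predicted_taxon = pred)
  rep <- readLevelMetrics(preds, truth)
  a <- rep$perTaxon[rep$perTaxon$taxon == "A", ]
  expect_equal(a$sensitivity, 0.8)
  expect_equal(a$precision, 8 / 9)
  expect_equal(a$f1, 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9), tolerance = 1e-9)
  expect_equal(a$f1, 0.8421, tolerance = 1e-4)
  expect_identical(a$unclassified, 2L)
  expect_equal(rep$summary[["percent_classified"]], 90)

  perfect <- data.frame(read_id = names(truth),
                        predicted_taxon = unname(truth))
  s <- readLevelMetrics(perfect, truth)$summary
  expect_equal(unname(s[c("sensitivity", "precision", "f1")]), c(1, 1, 1))

  none <- data.frame(read_id = names(truth),
                     predicted_taxon = "UNCLASSIFIED")
  s0 <- readLevelMetrics(none, truth)$summary
  expect_equal(unname(s0[c("sensitivity", "precision", "f1")]), c(0, 0, 0))

  bad <- data.frame(read_id = "zzz", predicted_taxon = "A")
  expect_error(readLevelMetrics(bad, truth), "absent from truth")
})

test_that("metric bounds and the F1 harmonic-mean identity hold under fuzzing", {
  set.seed(70)
  taxa <- c("t1", "t2", "t3", "t4")
  for (i in 1:200) {
    n <- sample(5:60, 1)
    truth <- setNames(sample(taxa, n, replace = TRUE), paste0("r", 1:n))
    preds <- data.frame(
      read_id = names(truth),
      predicted_taxon = sample(c(taxa, "UNCLASSIFIED"), n, replace = TRUE))
    rep <- readLevelMetrics(preds, truth)
    pt <- rep$perTaxon[rep$perTaxon$n_reads > 0, ]
    stopifnot(nrow(pt) >= 1)
    expect_true(all(pt$sensitivity >= 0 & pt$sensitivity <= 1))
    expect_true(all(pt$precision >= 0 & pt$precision <= 1))
    hm <- ifelse(pt$precision + pt$sensitivity == 0, 0,
                 2 * pt$precision * pt$sensitivity /
                   (pt$precision + pt$sensitivity))
    expect_equal(pt$f1, hm, tolerance = 1e-9)
  }
})

makePools <- function(nSpecies, poolSize, readLength = 100, seed = 80) {
  set.seed(seed)
  pools <- lapply(seq_len(nSpecies), function(i)
    Biostrings::DNAStringSet(replicate(poolSize, randomDna(readLength))))
  names(pools) <- sprintf("sp%02d", seq_len(nSpecies))
  pools
}

test_that("mock communities have the requested size, reads and determinism", {
  pools <- makePools(5, 1000)
  mock <- buildMockCommunity(pools, nSpeciesRange = c(3, 3),
                             maxReads = 1000, seed = 81)
  comp <- mockComposition(mock)
  expect_identical(nrow(comp), 3L)
  expect_identical(length(mockReads(mock)), 1000L)
  expect_identical(sum(comp$n_sampled), 1000L)
  expect_equal(sum(comp$abundance), 1, tolerance = 1e-9)
  # read conservation: sampled reads per species == min(alloc, available)
  expect_true(all(comp$n_sampled <= comp$n_available))
  # truth covers every read
  expect_identical(sort(names(mockReads(mock))), sort(names(mockTruth(mock))))

  mock2 <- buildMockCommunity(pools, nSpeciesRange = c(3, 3),
                              maxReads = 1000, seed = 81)
  expect_identical(mockComposition(mock2), comp)
  expect_identical(as.character(mockReads(mock2)),
                   as.character(mockReads(mock)))
})

test_that("log-distributed abundances span the configured dynamic range", {
  pools <- makePools(25, 30)
  # small pools: exhaustion is expected and irrelevant to the abundances
  mock <- suppressWarnings(
    buildMockCommunity(pools, nSpeciesRange = c(20, 20),
                       maxReads = 600, seed = 82))
  ab <- sort(mockComposition(mock)$abundance, decreasing = TRUE)
  expect_equal(ab[1] / ab[20], 100, tolerance = 1e-6)
  expect_gt(ab[1] / ab[20], 10)  # spans over an order of magnitude
})

test_that("exhausted pools are taken whole with a warning", {
  pools <- makePools(3, 5)
  expect_warning(
    mock <- buildMockCommunity(pools, nSpeciesRange = c(3, 3),
                               maxReads = 30, seed = 83),
    "exhausted")
  comp <- mockComposition(mock)
  expect_true(all(comp$n_sampled <= 5))
  expect_identical(length(mockReads(mock)), sum(comp$n_sampled))
})

test_that("community thresholds give the expected minimum read counts and nest", {
  tax <- TaxonomyTable(data.frame(
    genome_id = sprintf("s%d", 1:6), species_id = sprintf("s%d", 1:6),
    genus_id = c("gA", "gA", "gB", "gC", "gD", "gE")))
  # 100000 reads: genus counts straddling the 1/100/1000 minimums
  counts <- c(gA = 40000, gB = 900, gC = 99, gD = 1)
  pred <- rep(names(counts), counts)
  pred <- c(pred, rep("UNCLASSIFIED", 100000 - length(pred)))
  preds <- data.frame(read_id = sprintf("r%06d", seq_along(pred)),
                      predicted_taxon = pred)
  truth <- setNames(rep("s1", length(pred)), preds$read_id)
  truth[] <- "s1"  # true composition: only genus gA
  rep <- communityMetrics(preds, truth, tax)
  pt <- rep$perThreshold
  expect_equal(pt$min_reads, c(1, 100, 1000))
  expect_identical(rep$detected[["0.001"]], c("gA", "gB", "gC", "gD"))
  expect_identical(rep$detected[["0.1"]], c("gA", "gB"))
  expect_identical(rep$detected[["1"]], "gA")
  # nesting: higher thresholds detect subsets
  expect_true(all(rep$detected[["1"]] %in% rep$detected[["0.1"]]))
  expect_true(all(rep$detected[["0.1"]] %in% rep$detected[["0.001"]]))
  # sensitivity 1 at every threshold (gA always detected), precision rises
  expect_equal(pt$sensitivity, c(1, 1, 1))
  expect_equal(pt$precision, c(1 / 4, 1 / 2, 1))
  expect_equal(rep$percentClassified, 100 * (40000 + 900 + 99 + 1) / 1e5)
  expect_error(communityMetrics(preds[0, ], truth, tax), "empty")
})

test_that("species-level predictions can be evaluated at genus rank", {
  tax <- TaxonomyTable(data.frame(
    genome_id = c("s1", "s2"), species_id = c("s1", "s2"),
    genus_id = c("gA", "gA")))
  preds <- data.frame(read_id = c("r1", "r2", "r3"),
                      predicted_taxon = c("s1", "s2", "UNCLASSIFIED"))
  truth <- setNames(c("s1", "s1", "s2"), preds$read_id)
  rep <- communityMetrics(preds, truth, tax, thresholds = 50,
                          predictionLevel = "species")
  expect_identical(rep$detected[["50"]], "gA")
  expect_equal(rep$perThreshold$sensitivity, 1)
})

test_that("stratification groups species by in-database congener counts", {
  tax <- TaxonomyTable(data.frame(
    genome_id = sprintf("s%d", 1:10),
    species_id = sprintf("s%d", 1:10),
    genus_id = c("g1", "g1",                 # g1: 1 in-db + 1 test
                 "g2", "g2", "g2", "g2",     # g2: 3 in-db + 1 test
                 "g3", "g3", "g3", "g3")))   # g3 handled below
  tax2 <- TaxonomyTable(data.frame(
    genome_id = sprintf("s%d", 1:16), species_id = sprintf("s%d", 1:16),
    genus_id = c("g1", "g1", "g2", "g2", "g2", "g2",
                 rep("g3", 6), rep("g4", 4))))
  perSpecies <- data.frame(
    species_id = c("s2", "s6", "s12"),
    f1 = c(0.5, 0.7, 0.9))
  inDb <- c("s1", "s3", "s4", "s5", sprintf("s%d", 7:11))
  out <- stratifyByGenusSize(perSpecies, tax2, inDb)
  expect_identical(out$group,
                   c("exactly one", "two or three", "more than three"))
  expect_equal(out$f1, c(0.5, 0.7, 0.9))
  expect_identical(out$n_species, c(1L, 1L, 1L))
})
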