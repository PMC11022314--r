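#' Read-level sensitivity, precision and F1
#'
#' Per-taxon confusion metrics for a set of read predictions against a
#' ground truth. For a taxon t, sensitivity is the proportion of reads
#' truly from t that were predicted t (unclassified reads count as
#' misses); precision is the proportion of reads predicted t that are
#' truly from t; F1 is their harmonic mean (0 when both are 0). Taxa with
#' no truth reads (predicted-only taxa) are excluded from the sensitivity
#' and F1 averages; macro averages are unweighted means over taxa.
#'
#' @param predictions data.frame with columns `read_id` and
#'   `predicted_taxon` (as from [classifyReads()]); `"UNCLASSIFIED"`
#'   marks unclassified reads.
#' @param truth Named character vector mapping read_id to true taxon, or a
#'   data.frame with columns `read_id` and `taxon`.
#' @return List with `perTaxon` (data.frame: taxon, n_reads, tp, fp, fn,
#'   unclassified, sensitivity, precision, f1), and `summary` (mean
#'   sensitivity, precision, f1 over truth taxa, plus
#'   `percent_classified`).
#' @examples
#' truth <- setNames(rep(c("A", "B"), each = 2), paste0("r", 1:4))
#' preds <- data.frame(read_id = paste0("r", 1:4),
#'                     predicted_taxon = c("A", "A", "B", "UNCLASSIFIED"))
#' readLevelMetrics(preds, truth)$summary
#' @export
readLevelMetrics <- function(predictions, truth) {
  if (is.data.frame(truth)) {
    if (!all(c("read_id", "taxon") %in% names(truth)))
      stop("'truth' data.frame needs columns read_id and taxon")
    truth <- setNames(as.character(truth$taxon),
                      as.character(truth$read_id))
  }
  ids <- as.character(predictions$read_id)
  if (!all(ids %in% names(truth)))
    stop("prediction(s) for read ids absent from truth: ",
         paste(head(setdiff(ids, names(truth)), 3), collapse = ", "))
  pred <- as.character(predictions$predicted_taxon)
  tru <- unname(truth[ids])

  truthTaxa <- sort(unique(tru))
  predTaxa <- setdiff(sort(unique(pred)), "UNCLASSIFIED")
  allTaxa <- union(truthTaxa, predTaxa)
  perTaxon <- do.call(rbind, lapply(allTaxa, function(t) {
    nReads <- sum(tru == t)
    tp <- sum(tru == t & pred == t)
    fp <- sum(tru != t & pred == t)
    fn <- nReads - tp
    unc <- sum(tru == t & pred == "UNCLASSIFIED")
    sens <- if (nReads > 0) tp / nReads else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (!is.na(sens) && (prec + sens) > 0)
      2 * prec * sens / (prec + sens) else if (is.na(sens)) NA_real_ else 0
    data.frame(taxon = t, n_reads = nReads, tp = tp, fp = fp, fn = fn,
               unclassified = unc, sensitivity = sens, precision = prec,
               f1 = f1, stringsAsFactors = FALSE)
  }))
  withTruth <- perTaxon$n_reads > 0
  summary <- c(sensitivity = mean(perTaxon$sensitivity[withTruth]),
               precision = mean(perTaxon$precision[withTruth]),
               f1 = mean(perTaxon$f1[withTruth]),
               percent_classified = 100 * mean(pred != "UNCLASSIFIED"))
  list(perTaxon = perTaxon, summary = summary)
}

#' MockCommunity: a pseudo-mock community with known composition
#'
#' An in-silico mixture of reads from isolates with a known species
#' composition, for community-level (detection) benchmarking.
#'
#' @slot composition data.frame: `species_id`, `abundance` (relative,
#'   summing to 1 over selected species), `n_sampled`, `n_available`.
#' @slot reads Named [Biostrings::DNAStringSet] of sampled reads.
#' @slot truth Named character vector read_id -> species_id.
#' @slot seed Seed used to build the community.
#' @seealso [buildMockCommunity()], [communityMetrics()]
#' @export
setClass("MockCommunity",
  representation(composition = "data.frame", reads = "DNAStringSet",
                 truth = "character", seed = "integer"))

#' @describeIn MockCommunity-class Display a summary.
#' @param object A `MockCommunity`.
#' @export
setMethod("show", "MockCommunity", function(object) {
  cat("MockCommunity:", nrow(object@composition), "species,",
      length(object@reads), "reads; abundance range ",
      signif(min(object@composition$abundance), 3), "-",
      signif(max(object@composition$abundance), 3), "\n")
})

#' Build a pseudo-mock community from per-species read pools
#'
#' Draws a community size S uniformly from `nSpeciesRange`, selects S
#' species uniformly from the pools, assigns log-distributed relative
#' abundances (abundance of the i-th ranked species proportional to
#' `10^(-i * delta)` with `delta` chosen so the most/least abundant ratio
#' equals `dynamicRange`), and draws `min(maxReads, total available)`
#' reads by multinomial allocation across species, sampling without
#' replacement within each pool. If a pool cannot supply its allocation,
#' the whole pool is taken and a warning is recorded in the composition
#' table (`n_sampled < allocation`).
#'
#' @param pools Named list mapping species_id to a
#'   [Biostrings::DNAStringSet] of reads.
#' @param nSpeciesRange Integer range (low, high) for the community size;
#'   default c(20, 34).
#' @param maxReads Maximum total reads to sample (default 100000).
#' @param dynamicRange Ratio of most- to least-abundant species under the
#'   log-spaced scheme (default 100).
#' @param seed Integer seed.
#' @return A [MockCommunity-class].
#' @export
buildMockCommunity <- function(pools, nSpeciesRange = c(20, 34),
                               maxReads = 100000, dynamicRange = 100,
                               seed = 1) {
  stopifnot(is.list(pools), length(nSpeciesRange) == 2,
            nSpeciesRange[1] >= 1, nSpeciesRange[2] >= nSpeciesRange[1],
            maxReads >= nSpeciesRange[2], dynamicRange >= 1)
  if (length(pools) < nSpeciesRange[2])
    stop("need at least ", nSpeciesRange[2], " species pools")
  set.seed(seed)
  sizes <- seq(nSpeciesRange[1], nSpeciesRange[2])
  s <- sizes[sample.int(length(sizes), 1L)]
  species <- sort(sample(names(pools), s))
  ## log-spaced abundances over the requested dynamic range, assigned in
  ## random order so rank is not tied to species name
  delta <- if (s > 1) log10(dynamicRange) / (s - 1) else 0
  ab <- 10^(-(seq_len(s) - 1) * delta)
  ab <- ab / sum(ab)
  ab <- ab[sample.int(s)]
  avail <- vapply(pools[species], length, 0L)
  total <- min(maxReads, sum(avail))
  alloc <- as.vector(stats::rmultinom(1L, total, ab))
  sampled <- pmin(alloc, avail)
  if (any(sampled < alloc))
    warning("pool(s) exhausted; sampled all available reads for: ",
            paste(species[sampled < alloc], collapse = ", "))
  readsList <- vector("list", s)
  truth <- character(0)
  for (i in seq_len(s)) {
    pool <- pools[[species[i]]]
    take <- sample.int(length(pool), sampled[i])
    r <- pool[take]
    names(r) <- sprintf("%s_read%05d", species[i], seq_len(sampled[i]))
    readsList[[i]] <- r
    truth <- c(truth, setNames(rep(species[i], sampled[i]), names(r)))
  }
  reads <- do.call(c, readsList)
  new("MockCommunity",
      composition = data.frame(species_id = species, abundance = ab,
                               n_sampled = sampled, n_available = avail,
                               stringsAsFactors = FALSE),
      reads = reads, truth = truth, seed = as.integer(seed))
}

#' @describeIn MockCommunity-class The sampled reads.
#' @param x A `MockCommunity`.
#' @export
setGeneric("mockReads", function(x) standardGeneric("mockReads"))

#' @describeIn MockCommunity-class Reads accessor.
#' @export
setMethod("mockReads", "MockCommunity", function(x) x@reads)

#' @describeIn MockCommunity-class read_id -> species truth map.
#' @export
setGeneric("mockTruth", function(x) standardGeneric("mockTruth"))

#' @describeIn MockCommunity-class Truth accessor.
#' @export
setMethod("mockTruth", "MockCommunity", function(x) x@truth)

#' @describeIn MockCommunity-class Known composition table.
#' @export
setGeneric("mockComposition", function(x) standardGeneric("mockComposition"))

#' @describeIn MockCommunity-class Composition accessor.
#' @export
setMethod("mockComposition", "MockCommunity", function(x) x@composition)

#' Community-level (detection) metrics for a mock community
#'
#' A genus is called present at percentage threshold p if its cumulative
#' classified-read count is at least `p`% of the total number of reads in
#' the dataset (so for 100000 reads the thresholds 0.001/0.1/1% require at
#' least 1/100/1000 reads). Sensitivity, precision and F1 are computed for
#' the detected genus set against the true genus set of the community at
#' each threshold; detected sets are nested across thresholds by
#' construction.
#'
#' @param predictions data.frame from [classifyReads()]; predicted taxa
#'   must be genus ids, or species ids resolvable through `taxonomy`.
#' @param mock A [MockCommunity-class], or a named character truth vector
#'   read_id -> species_id.
#' @param taxonomy A [TaxonomyTable-class] used to map species to genus
#'   (for the truth, and for predictions when `predictionLevel =
#'   "species"`).
#' @param thresholds Percentage thresholds in (0, 100); default
#'   `c(0.001, 0.1, 1)`.
#' @param predictionLevel Rank of `predicted_taxon`: `"genus"` (default)
#'   or `"species"`.
#' @return List with `perThreshold` (data.frame: threshold_pct,
#'   min_reads, n_detected, tp, fp, fn, sensitivity, precision, f1),
#'   `detected` (list of detected genus sets per threshold),
#'   `percentClassified`, and `trueGenera`.
#' @export
communityMetrics <- function(predictions, mock, taxonomy,
                             thresholds = c(0.001, 0.1, 1),
                             predictionLevel = c("genus", "species")) {
  predictionLevel <- match.arg(predictionLevel)
  stopifnot(is(taxonomy, "TaxonomyTable"))
  if (any(thresholds <= 0) || any(thresholds >= 100))
    stop("'thresholds' must be percentages in (0, 100)")
  if (nrow(predictions) == 0L) stop("empty prediction set")
  truth <- if (is(mock, "MockCommunity")) mock@truth else mock
  trueGenera <- sort(unique(unname(genusOf(taxonomy,
                                           unique(unname(truth))))))
  nTotal <- nrow(predictions)
  pred <- as.character(predictions$predicted_taxon)
  classified <- pred != "UNCLASSIFIED"
  predGenus <- pred[classified]
  if (predictionLevel == "species" && length(predGenus))
    predGenus <- unname(genusOf(taxonomy, predGenus))
  counts <- table(predGenus)

  thresholds <- sort(thresholds)
  detected <- list()
  rows <- lapply(thresholds, function(p) {
    minReads <- p / 100 * nTotal
    det <- names(counts)[counts >= minReads]
    detected[[as.character(p)]] <<- det
    tp <- length(intersect(det, trueGenera))
    fp <- length(setdiff(det, trueGenera))
    fn <- length(setdiff(trueGenera, det))
    sens <- if (length(trueGenera)) tp / length(trueGenera) else NA_real_
    prec <- if (length(det)) tp / length(det) else 0
    f1 <- if ((sens + prec) > 0) 2 * sens * prec / (sens + prec) else 0
    data.frame(threshold_pct = p, min_reads = ceiling(minReads),
               n_detected = length(det), tp = tp, fp = fp, fn = fn,
               sensitivity = sens, precision = prec, f1 = f1)
  })
  list(perThreshold = do.call(rbind, rows), detected = detected,
       percentClassified = 100 * mean(classified),
       trueGenera = trueGenera)
}

#' Stratify per-species results by the number of in-database congeners
#'
#' Groups out-of-database test species by how many species of the same
#' genus are in the reference database — "exactly one", "two or three",
#' or "more than three" — and averages the supplied per-species metrics
#' within each group. Classifier sensitivity for novel species typically
#' grows with the number of reference congeners.
#'
#' @param perSpecies data.frame with a `species_id` column and numeric
#'   metric columns (e.g. sensitivity, precision, f1).
#' @param taxonomy A [TaxonomyTable-class] covering all tested species.
#' @param inDbSpecies Character vector of species ids present in the
#'   reference database.
#' @return data.frame with one row per non-empty group: `group`,
#'   `n_species`, and the group means of each metric column.
#' @export
stratifyByGenusSize <- function(perSpecies, taxonomy, inDbSpecies) {
  stopifnot(is(taxonomy, "TaxonomyTable"),
            "species_id" %in% names(perSpecies))
  genus <- genusOf(taxonomy, perSpecies$species_id)
  inDbGenus <- unname(genusOf(taxonomy, inDbSpecies))
  nRefs <- vapply(genus, function(g) sum(inDbGenus == g), 0L)
  group <- cut(nRefs, breaks = c(-Inf, 1.5, 3.5, Inf),
               labels = c("exactly one", "two or three", "more than three"))
  if (any(nRefs == 0))
    warning("species with no in-database congener grouped as 'exactly one'")
  metricCols <- names(perSpecies)[vapply(perSpecies, is.numeric, TRUE)]
  out <- lapply(split(seq_len(nrow(perSpecies)), group), function(i) {
    if (!length(i)) return(NULL)
    cbind(data.frame(n_species = length(i)),
          as.data.frame(lapply(perSpecies[i, metricCols, drop = FALSE],
                               mean, na.rm = TRUE)))
  })
  keep <- !vapply(out, is.null, TRUE)
  res <- do.call(rbind, out[keep])
  data.frame(group = names(out)[keep], res, row.names = NULL,
             stringsAsFactors = FALSE)
}
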