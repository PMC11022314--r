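#' Split a read into non-overlapping chunks
#'
#' Consecutive windows of `chunkLength` bases from position 0; the final
#' remainder is kept only if it is at least `minLastChunk` bases (very
#' short chunks have sparse k-mer profiles and add noise to the vote). A
#' read shorter than `chunkLength` but at least `minLastChunk` yields one
#' chunk (itself); a read shorter than `minLastChunk` yields no chunks.
#'
#' @param seq A single DNA string.
#' @param chunkLength Chunk size in bases (default 1000, matching the
#'   training sequence length).
#' @param minLastChunk Minimum length for the final remainder chunk
#'   (default 500).
#' @return Character vector of chunks (possibly empty).
#' @examples
#' nchar(chunkRead(strrep("A", 3500)))  # 1000 1000 1000 500
#' @export
chunkRead <- function(seq, chunkLength = 1000, minLastChunk = 500) {
  if (minLastChunk <= 0 || minLastChunk > chunkLength)
    stop("'minLastChunk' must be in (0, chunkLength]")
  seq <- sanitizeSequence(seq)
  if (length(seq) != 1L) stop("'seq' must be a single sequence")
  len <- nchar(seq)
  if (len < minLastChunk) return(character(0))
  nFull <- len %/% chunkLength
  starts <- seq_len(nFull) * chunkLength - chunkLength + 1L
  ends <- starts + chunkLength - 1L
  rem <- len - nFull * chunkLength
  if (rem >= minLastChunk) {
    starts <- c(starts, nFull * chunkLength + 1L)
    ends <- c(ends, len)
  }
  if (!length(starts)) return(seq)  # len in [minLastChunk, chunkLength)
  substring(seq, starts, ends)
}

#' Majority vote over per-chunk class probabilities
#'
#' Each chunk votes for its argmax class; the class with the most votes
#' wins, ties broken by the highest mean probability (over all chunks)
#' among the tied classes, residual exact ties by the lowest class index.
#' The confidence score is, under the default `"mean_prob"` semantics, the
#' mean probability of the winning class across all chunks (consistent
#' with the tie-break being defined on mean probability); under
#' `"vote_fraction"` it is the fraction of chunks voting for the winner.
#' If the score falls below `threshold` the read is reported as
#' `UNCLASSIFIED` (with the score still attached).
#'
#' @param probs Matrix of per-chunk class probabilities (chunks x classes),
#'   optionally with class names as column names.
#' @param threshold Minimum score to call a classification (default 0.5).
#' @param scoreMethod `"mean_prob"` (default) or `"vote_fraction"`.
#' @return List with `taxon` (class name or `"UNCLASSIFIED"`), `score`,
#'   and `winner` (the winning class index regardless of thresholding).
#' @export
voteChunks <- function(probs, threshold = 0.5,
                       scoreMethod = c("mean_prob", "vote_fraction")) {
  scoreMethod <- match.arg(scoreMethod)
  probs <- as.matrix(probs)
  if (nrow(probs) < 1L) stop("no chunks to vote over")
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  votes <- max.col(probs, ties.method = "first")
  tallies <- tabulate(votes, nbins = ncol(probs))
  meanProbs <- colMeans(probs)
  tied <- which(tallies == max(tallies))
  winner <- tied[which.max(meanProbs[tied])]  # which.max: lowest index wins residual ties
  score <- switch(scoreMethod,
                  mean_prob = meanProbs[winner],
                  vote_fraction = tallies[winner] / nrow(probs))
  classNames <- colnames(probs)
  if (is.null(classNames)) classNames <- as.character(seq_len(ncol(probs)))
  list(taxon = if (score >= threshold) classNames[winner] else "UNCLASSIFIED",
       score = unname(score), winner = winner)
}

#' Classify long reads by chunked majority voting
#'
#' Segments each read into non-overlapping chunks, profiles every chunk
#' with the model's canonical k-mer index and normalisation mode, runs
#' batched forward passes, and aggregates per-chunk probabilities into one
#' prediction per read via [voteChunks()]. Reads too short to yield a
#' chunk are reported with status `too_short` and taxon `UNCLASSIFIED`.
#' Output order equals input order.
#'
#' @param reads Named [Biostrings::DNAStringSet] or character vector of
#'   reads.
#' @param model A [ClassifierModel-class].
#' @param chunkLength,minLastChunk See [chunkRead()].
#' @param probThreshold Confidence cutoff below which a read is reported
#'   unclassified (default 0.5).
#' @param batchSize Number of chunks per forward pass.
#' @param scoreMethod See [voteChunks()].
#' @return data.frame with columns `read_id`, `predicted_taxon`, `score`,
#'   `n_chunks`, `status` (`classified`/`unclassified`/`too_short`).
#' @export
classifyReads <- function(reads, model, chunkLength = 1000,
                          minLastChunk = 500, probThreshold = 0.5,
                          batchSize = 2048, scoreMethod = "mean_prob") {
  stopifnot(is(model, "ClassifierModel"))
  ids <- unname(names(reads))
  reads <- sanitizeSequence(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
  if (length(reads) == 0L) {
    warning("no reads to classify")
    return(emptyPredictions())
  }
  index <- buildKmerIndex(model@k)
  chunks <- lapply(reads, chunkRead, chunkLength = chunkLength,
                   minLastChunk = minLastChunk)
  nChunks <- lengths(chunks)
  flat <- unlist(chunks, use.names = FALSE)
  ## drop chunks that cannot be profiled (shorter than k or all-ambiguous)
  probsAll <- matrix(numeric(0), 0, length(model@labelMap))
  if (length(flat)) {
    x <- kmerProfileMatrix(flat, index, normalize = model@normalize,
                           allowDegenerate = TRUE)
    probsAll <- matrix(NA_real_, nrow(x), length(model@labelMap))
    ok <- attr(x, "nValid") > 0L
    for (s in seq(1L, nrow(x), by = batchSize)) {
      rows <- s:min(s + batchSize - 1L, nrow(x))
      probsAll[rows, ] <- predictProbs(model, x[rows, , drop = FALSE])
    }
    probsAll[!ok, ] <- NA_real_
  }
  colnames(probsAll) <- model@labelMap

  n <- length(reads)
  taxon <- character(n); score <- rep(NA_real_, n)
  chunksUsed <- integer(n); status <- character(n)
  offset <- 0L
  for (i in seq_len(n)) {
    p <- probsAll[seq_len(nChunks[i]) + offset, , drop = FALSE]
    offset <- offset + nChunks[i]
    p <- p[stats::complete.cases(p), , drop = FALSE]
    if (nrow(p) == 0L) {
      taxon[i] <- "UNCLASSIFIED"; chunksUsed[i] <- 0L
      status[i] <- "too_short"
    } else {
      v <- voteChunks(p, threshold = probThreshold,
                      scoreMethod = scoreMethod)
      taxon[i] <- v$taxon; score[i] <- v$score; chunksUsed[i] <- nrow(p)
      status[i] <- if (v$taxon == "UNCLASSIFIED") "unclassified"
                   else "classified"
    }
  }
  data.frame(read_id = ids, predicted_taxon = taxon, score = score,
             n_chunks = chunksUsed, status = status,
             stringsAsFactors = FALSE)
}

emptyPredictions <- function() {
  data.frame(read_id = character(0), predicted_taxon = character(0),
             score = numeric(0), n_chunks = integer(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' Write / read a predictions TSV
#' @param predictions data.frame as returned by [classifyReads()].
#' @param path Output path.
#' @return `writePredictions` returns `path` invisibly; `readPredictions`
#'   the data.frame.
#' @export
writePredictions <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) stop("predictions file not found: ", path)
  read.delim(path, colClasses = c(read_id = "character",
                                  predicted_taxon = "character"))
}
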