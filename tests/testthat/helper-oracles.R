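# Independent brute-force oracles, deliberately written with naive string
# manipulation so they share no code path with the implementation.

oracleRevcomp <- function(w) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(w, "")[[1]]]), collapse = "")
}

# Count distinct canonical k-mers by full enumeration.
oracleCanonicalCount <- function(k) {
  alphabet <- c("A", "C", "G", "T")
  grids <- rep(list(alphabet), k)
  all <- do.call(paste0, expand.grid(grids, stringsAsFactors = FALSE))
  canon <- vapply(all, function(w) min(w, oracleRevcomp(w)), "")
  length(unique(canon))
}

# Count canonical k-mers of a sequence one window at a time.
oracleProfile <- function(seq, k) {
  n <- nchar(seq) - k + 1
  counts <- list()
  for (i in seq_len(n)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    cw <- min(w, oracleRevcomp(w))
    counts[[cw]] <- (counts[[cw]] %||% 0) + 1
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Majority vote, naive restatement: most argmax votes; ties by highest
# mean probability over all chunks; residual ties by lowest class index;
# then the threshold on the winner's mean probability.
oracleVote <- function(probs, threshold) {
  nClasses <- ncol(probs)
  votes <- integer(nClasses)
  for (r in seq_len(nrow(probs))) {
    best <- 1
    for (c in seq_len(nClasses)) if (probs[r, c] > probs[r, best]) best <- c
    votes[best] <- votes[best] + 1
  }
  means <- colMeans(probs)
  candidates <- which(votes == max(votes))
  winner <- candidates[1]
  for (c in candidates) if (means[c] > means[winner]) winner <- c
  score <- means[winner]
  list(winner = winner,
       label = if (score >= threshold) as.character(winner) else "UNCLASSIFIED",
       score = score)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
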