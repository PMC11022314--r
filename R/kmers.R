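#' KmerIndex: a canonical k-mer feature space
#'
#' A `KmerIndex` fixes the k-mer length `k` and enumerates the canonical
#' k-mers over the DNA alphabet, i.e. the lexicographic minima of each
#' k-mer/reverse-complement pair. It maps every one of the `4^k` k-mers to
#' the feature position of its canonical representative, so that profiles
#' computed against the index are identical for a sequence and its reverse
#' complement.
#'
#' For even k there are `4^(k/2)` reverse-complement palindromes, hence
#' `(4^k - 4^(k/2))/2 + 4^(k/2)` canonical k-mers (2080 for k = 6); for odd
#' k there are none and the count is `4^k / 2`.
#'
#' @slot k k-mer length.
#' @slot kmers Character vector of canonical k-mers, lexicographically
#'   sorted; each entry is less than or equal to its reverse complement.
#' @slot positions Integer vector of length `4^k` giving, for the i-th
#'   k-mer in lexicographic order, the 1-based position of its canonical
#'   representative in `kmers`.
#'
#' @seealso [buildKmerIndex()], [kmerProfile()]
#' @export
setClass("KmerIndex",
  representation(k = "integer", kmers = "character", positions = "integer"))

setValidity("KmerIndex", function(object) {
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 1L)
    return("'k' must be a single positive integer")
  if (length(object@positions) != 4^k)
    return("'positions' must have length 4^k")
  if (any(object@positions < 1L) ||
      any(object@positions > length(object@kmers)))
    return("'positions' must index into 'kmers'")
  TRUE
})

#' @describeIn KmerIndex-class Number of canonical k-mers (feature
#'   dimension).
#' @param x,object A `KmerIndex`.
#' @export
setMethod("length", "KmerIndex", function(x) length(x@kmers))

#' @describeIn KmerIndex-class Display a summary.
#' @export
setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex of", length(object@kmers), "canonical", paste0(object@k, "-mers"),
      "(feature space over", 4^object@k, "k-mers)\n")
})

#' @describeIn KmerIndex-class k-mer length of an index or model.
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @describeIn KmerIndex-class k-mer length.
#' @export
setMethod("kmerSize", "KmerIndex", function(x) x@k)

#' @describeIn KmerIndex-class The canonical k-mer strings, in feature
#'   order.
#' @export
setGeneric("canonicalKmers", function(x) standardGeneric("canonicalKmers"))

#' @describeIn KmerIndex-class Canonical k-mer strings.
#' @export
setMethod("canonicalKmers", "KmerIndex", function(x) x@kmers)

DNA_BASES4 <- c("A", "C", "G", "T")

## 2-bit codes: A=0, C=1, G=2, T=3; lexicographic order == numeric order.
## Reverse complement of a code: reverse the k base-4 digits, complementing
## each (digit -> 3 - digit).
revcompCodes <- function(codes, k) {
  rc <- numeric(length(codes))
  x <- codes
  for (i in seq_len(k)) {
    digit <- x %% 4
    rc <- rc * 4 + (3 - digit)
    x <- x %/% 4
  }
  rc
}

codesToKmers <- function(codes, k) {
  out <- character(length(codes))
  x <- codes
  chars <- matrix("", nrow = length(codes), ncol = k)
  for (i in k:1) {
    chars[, i] <- DNA_BASES4[x %% 4 + 1]
    x <- x %/% 4
  }
  do.call(paste0, asplit(chars, 2))
}

#' Build a canonical k-mer index
#'
#' Enumerates all `4^k` DNA k-mers, folds each onto the lexicographic
#' minimum of itself and its reverse complement, and returns the resulting
#' canonical feature space. Deterministic for a given `k`.
#'
#' @param k k-mer length, an integer between 1 and 12. The default, 6,
#'   balances error robustness (short k-mers overlap few sequencing errors)
#'   against feature resolution.
#' @return A [KmerIndex-class] object.
#' @examples
#' idx <- buildKmerIndex(6)
#' length(idx)  # 2080
#' @export
buildKmerIndex <- function(k = 6L) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1 || k > 12)
    stop("'k' must be a single integer between 1 and 12")
  k <- as.integer(k)
  codes <- seq(0, 4^k - 1)
  rc <- revcompCodes(codes, k)
  canon <- pmin(codes, rc)
  uniq <- codes[codes <= rc]          # already sorted ascending
  positions <- findInterval(canon, uniq)
  new("KmerIndex", k = k, kmers = codesToKmers(uniq, k),
      positions = as.integer(positions))
}

#' Canonical form of a k-mer
#'
#' Returns the lexicographically smaller of a k-mer and its reverse
#' complement. Vectorised and idempotent.
#'
#' @param x Character vector of DNA k-mers (A/C/G/T only; case-insensitive,
#'   U is read as T).
#' @return Character vector of canonical k-mers.
#' @examples
#' canonicalKmer(c("TTTTTT", "ACGCGT"))
#' @export
canonicalKmer <- function(x) {
  x <- sanitizeSequence(x)
  if (any(grepl("[^ACGT]", x)))
    stop("k-mers must contain only A/C/G/T bases")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  ifelse(x <= rc, x, rc)
}

## Uppercase and map the RNA alphabet onto DNA; ambiguity codes are left
## as-is and handled downstream (profiled windows containing them are
## skipped).
sanitizeSequence <- function(x) {
  chartr("U", "T", toupper(as.character(x)))
}

#' KmerProfile: canonical k-mer counts of one sequence
#'
#' Fixed-length numeric feature vector of canonical k-mer counts (raw or
#' normalised to frequencies) for a single sequence, together with the
#' number of valid windows that produced it.
#'
#' @slot counts Numeric vector, one entry per canonical k-mer of the
#'   originating index, named by k-mer.
#' @slot nValid Number of k-length windows consisting solely of A/C/G/T;
#'   windows containing ambiguity codes are skipped.
#' @slot normalized Whether `counts` were divided by `nValid`.
#' @slot k k-mer length.
#' @seealso [kmerProfile()]
#' @export
setClass("KmerProfile",
  representation(counts = "numeric", nValid = "integer",
                 normalized = "logical", k = "integer"))

setValidity("KmerProfile", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  s <- sum(object@counts)
  if (!object@normalized && abs(s - object@nValid) > 1e-9)
    return("raw counts must sum to the number of valid windows")
  if (object@normalized && object@nValid > 0L && abs(s - 1) > 1e-9)
    return("normalized counts must sum to 1")
  TRUE
})

#' @describeIn KmerProfile-class The count/frequency vector.
#' @param x,object A `KmerProfile`.
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))

#' @describeIn KmerProfile-class Count vector accessor.
#' @export
setMethod("kmerCounts", "KmerProfile", function(x) x@counts)

#' @describeIn KmerProfile-class Number of valid (unambiguous) windows.
#' @export
setGeneric("validWindows", function(x) standardGeneric("validWindows"))

#' @describeIn KmerProfile-class Valid-window count accessor.
#' @export
setMethod("validWindows", "KmerProfile", function(x) x@nValid)

#' @describeIn KmerProfile-class Whether the profile is normalised.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @describeIn KmerProfile-class Normalisation flag accessor.
#' @export
setMethod("isNormalized", "KmerProfile", function(x) x@normalized)

#' @describeIn KmerProfile-class Display a summary.
#' @export
setMethod("show", "KmerProfile", function(object) {
  cat("KmerProfile (k =", object@k, "):", length(object@counts), "features,",
      object@nValid, "valid windows,",
      if (object@normalized) "normalized\n" else "raw counts\n")
})

#' Canonical k-mer profile of a sequence
#'
#' Slides a window of width `k` along the sequence with step 1 and counts
#' each window at the feature position of its canonical k-mer. Windows
#' containing any non-A/C/G/T character are skipped and do not count as
#' valid. Counting is case-insensitive and U is read as T.
#'
#' @param seq A DNA string (character scalar or [Biostrings::DNAString]).
#' @param index A [KmerIndex-class].
#' @param normalize Divide counts by the number of valid windows (default
#'   `TRUE`). Normalised frequencies make profiles comparable across
#'   sequence lengths, which matters for the short final chunk of a read.
#' @return A [KmerProfile-class].
#' @examples
#' idx <- buildKmerIndex(6)
#' p <- kmerProfile("ACGTACGT", idx, normalize = FALSE)
#' validWindows(p)  # 3
#' @export
kmerProfile <- function(seq, index, normalize = TRUE) {
  stopifnot(is(index, "KmerIndex"))
  seq <- sanitizeSequence(seq)
  if (length(seq) != 1L) stop("'seq' must be a single sequence")
  if (nchar(seq) < index@k)
    stop("sequence is shorter than k; no k-mer windows exist")
  m <- kmerProfileMatrix(seq, index, normalize = normalize,
                         allowDegenerate = !normalize)
  nv <- attr(m, "nValid")[1L]
  if (nv == 0L && normalize)
    stop("degenerate profile: no unambiguous k-mer window in sequence")
  new("KmerProfile", counts = setNames(m[1L, ], index@kmers),
      nValid = as.integer(nv), normalized = normalize, k = index@k)
}

#' Canonical k-mer profiles of many sequences
#'
#' Vectorised workhorse behind [kmerProfile()]: profiles a set of sequences
#' into a dense matrix with one row per sequence and one column per
#' canonical k-mer.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet].
#' @param index A [KmerIndex-class].
#' @param normalize Divide each row by its number of valid windows.
#' @param allowDegenerate Keep rows with zero valid windows (as all-zero
#'   rows) instead of raising an error.
#' @return Numeric matrix (sequences x canonical k-mers) with attribute
#'   `nValid`, the per-row count of valid windows.
#' @export
kmerProfileMatrix <- function(seqs, index, normalize = TRUE,
                              allowDegenerate = FALSE) {
  stopifnot(is(index, "KmerIndex"))
  if (!is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(sanitizeSequence(seqs))
  if (any(Biostrings::width(seqs) < index@k))
    stop("all sequences must be at least k bases long")
  raw <- Biostrings::oligonucleotideFrequency(seqs, width = index@k)
  ## fold the 4^k columns onto canonical positions
  folded <- t(rowsum(t(raw), group = index@positions, reorder = TRUE))
  nValid <- as.integer(rowSums(folded))
  if (normalize) {
    if (any(nValid == 0L) && !allowDegenerate)
      stop("degenerate profile: sequence without unambiguous k-mer windows")
    folded <- folded / pmax(nValid, 1L)
  }
  colnames(folded) <- index@kmers
  rownames(folded) <- names(seqs)
  attr(folded, "nValid") <- nValid
  folded
}

#' Read sequences from FASTA or FASTQ
#'
#' Convenience reader returning a [Biostrings::DNAStringSet]; the format is
#' taken from the file extension unless given. Gzip-compressed input is
#' handled transparently.
#'
#' @param path Path to a FASTA/FASTQ file (optionally .gz).
#' @param format `"auto"` (default, by extension), `"fasta"` or `"fastq"`.
#' @return A named [Biostrings::DNAStringSet].
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  ## FASTA headers: keep the id token only
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}
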