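#' TaxonomyTable: genome -> species -> genus mapping
#'
#' Two-rank taxonomy backing training-set construction and evaluation.
#' Every genome belongs to exactly one species and every species to exactly
#' one genus.
#'
#' @slot table data.frame with character columns `genome_id`, `species_id`,
#'   `genus_id`, one row per genome.
#' @seealso [readTaxonomy()], [simulateTaxonomy()]
#' @export
setClass("TaxonomyTable", representation(table = "data.frame"))

setValidity("TaxonomyTable", function(object) {
  tab <- object@table
  need <- c("genome_id", "species_id", "genus_id")
  if (!all(need %in% names(tab)))
    return("table must have columns genome_id, species_id, genus_id")
  if (any(!nzchar(unlist(tab[need]))) || anyNA(tab[need]))
    return("taxonomy ids must be non-empty and non-missing")
  if (anyDuplicated(tab$genome_id))
    return("each genome_id must appear exactly once")
  g <- tapply(tab$genus_id, tab$species_id, function(x) length(unique(x)))
  if (any(g > 1L))
    return("each species must map to exactly one genus")
  TRUE
})

#' Construct a TaxonomyTable
#' @param table data.frame with columns `genome_id`, `species_id`,
#'   `genus_id`.
#' @return A [TaxonomyTable-class].
#' @export
TaxonomyTable <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  for (cl in c("genome_id", "species_id", "genus_id"))
    if (cl %in% names(table)) table[[cl]] <- as.character(table[[cl]])
  new("TaxonomyTable", table = table)
}

#' @describeIn TaxonomyTable-class Display a summary.
#' @param object,x A `TaxonomyTable`.
#' @export
setMethod("show", "TaxonomyTable", function(object) {
  tab <- object@table
  cat("TaxonomyTable:", nrow(tab), "genomes,",
      length(unique(tab$species_id)), "species,",
      length(unique(tab$genus_id)), "genera\n")
})

#' @describeIn TaxonomyTable-class Underlying data.frame.
#' @export
setMethod("as.data.frame", "TaxonomyTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' @describeIn TaxonomyTable-class Genus of each given species.
#' @param species Character vector of species ids.
#' @export
genusOf <- function(x, species) {
  stopifnot(is(x, "TaxonomyTable"))
  map <- x@table[!duplicated(x@table$species_id), ]
  idx <- match(species, map$species_id)
  if (anyNA(idx))
    stop("unknown species id(s): ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  setNames(map$genus_id[idx], species)
}

#' Taxon label for each genome at a rank
#' @param x A [TaxonomyTable-class].
#' @param genomes Character vector of genome ids.
#' @param level `"species"` or `"genus"`.
#' @return Named character vector of taxon ids.
#' @export
taxonOfGenome <- function(x, genomes, level = c("species", "genus")) {
  stopifnot(is(x, "TaxonomyTable"))
  level <- match.arg(level)
  idx <- match(genomes, x@table$genome_id)
  if (anyNA(idx))
    stop("genome id(s) missing from taxonomy: ",
         paste(unique(genomes[is.na(idx)]), collapse = ", "))
  col <- if (level == "species") "species_id" else "genus_id"
  setNames(x@table[[col]][idx], genomes)
}

#' Read / write a taxonomy TSV
#'
#' The TSV has a header and columns `genome_id`, `species_id`, `genus_id`.
#'
#' @param path Path to the TSV file.
#' @return [readTaxonomy()] returns a [TaxonomyTable-class].
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  TaxonomyTable(read.delim(path, colClasses = "character"))
}

#' @rdname readTaxonomy
#' @param x A [TaxonomyTable-class].
#' @export
writeTaxonomy <- function(x, path) {
  stopifnot(is(x, "TaxonomyTable"))
  write.table(x@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a two-rank taxonomy with controlled divergence
#'
#' Draws one i.i.d. ancestor genome per genus from the base composition,
#' then derives each species genome from its genus ancestor by independent
#' per-site substitution at the given rate (substituting to one of the
#' three other bases uniformly). Genomes of different genera are therefore
#' unrelated (~75% mismatch), while congeneric species differ at roughly
#' twice the divergence rate — a controlled stand-in for a reference
#' database with known within-genus structure.
#'
#' @param nGenera Number of genera.
#' @param speciesPerGenus Species per genus (one genome per species).
#' @param genomeLength Genome length in bases.
#' @param divergence Per-base substitution probability between a genus
#'   ancestor and each species genome, in \[0, 0.3\].
#' @param baseComposition Probabilities over A, C, G, T; must sum to 1.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `genomes` (named [Biostrings::DNAStringSet], one
#'   entry per species genome) and `taxonomy` (a [TaxonomyTable-class]).
#' @examples
#' sim <- simulateTaxonomy(nGenera = 2, speciesPerGenus = 2,
#'                         genomeLength = 1000, seed = 1)
#' sim$taxonomy
#' @export
simulateTaxonomy <- function(nGenera = 6, speciesPerGenus = 3,
                             genomeLength = 200000, divergence = 0.02,
                             baseComposition = rep(0.25, 4), seed = NULL) {
  stopifnot(nGenera >= 1, speciesPerGenus >= 1, genomeLength >= 1)
  if (divergence < 0 || divergence > 0.3)
    stop("'divergence' must be in [0, 0.3]")
  if (length(baseComposition) != 4 || any(baseComposition < 0) ||
      abs(sum(baseComposition) - 1) > 1e-6)
    stop("'baseComposition' must be 4 probabilities summing to 1")
  if (!is.null(seed)) set.seed(seed)

  gW <- max(2L, nchar(as.character(nGenera)))
  sW <- max(2L, nchar(as.character(speciesPerGenus)))
  genomes <- character(0)
  rows <- vector("list", nGenera * speciesPerGenus)
  r <- 0L
  for (g in seq_len(nGenera)) {
    ancestor <- sample.int(4L, genomeLength, replace = TRUE,
                           prob = baseComposition)
    genus <- sprintf("g%0*d", gW, g)
    for (s in seq_len(speciesPerGenus)) {
      child <- ancestor
      if (divergence > 0) {
        hit <- which(runif(genomeLength) < divergence)
        if (length(hit))
          ## substitute to one of the 3 other bases, uniformly
          child[hit] <- ((child[hit] - 1L + sample.int(3L, length(hit),
                                                       replace = TRUE)) %% 4L) + 1L
      }
      species <- sprintf("%s_s%0*d", genus, sW, s)
      r <- r + 1L
      rows[[r]] <- data.frame(genome_id = species, species_id = species,
                              genus_id = genus, stringsAsFactors = FALSE)
      genomes[species] <- paste(DNA_BASES4[child], collapse = "")
    }
  }
  list(genomes = Biostrings::DNAStringSet(genomes),
       taxonomy = TaxonomyTable(do.call(rbind, rows)))
}

#' Sample fixed-length subsequences from a genome at a target coverage
#'
#' Draws `round(coverage * G / seqLength)` subsequences of length
#' `seqLength` from a genome of length `G`, with start positions uniform
#' (with replacement) over all valid offsets; the forward strand is used as
#' stored — canonical k-mer profiling downstream is strand-symmetric
#' anyway. Multi-contig genomes are sampled within contigs, each contig
#' contributing in proportion to its number of valid start offsets.
#'
#' @param genome A single DNA string, or a [Biostrings::DNAStringSet] of
#'   the genome's contigs.
#' @param seqLength Subsequence length in bases (default 1000).
#' @param coverage Target fold-coverage (sampled bases / genome length).
#' @param seed Optional integer seed.
#' @return data.frame with columns `contig`, `start` (0-based) and
#'   `sequence`; zero rows (with a warning) if no contig is at least
#'   `seqLength` long.
#' @export
sampleSequences <- function(genome, seqLength = 1000, coverage = 5,
                            seed = NULL) {
  stopifnot(seqLength >= 1, coverage > 0)
  if (!is.null(seed)) set.seed(seed)
  if (!is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(sanitizeSequence(genome))
  if (is.null(names(genome)))
    names(genome) <- sprintf("contig%d", seq_along(genome))
  widths <- Biostrings::width(genome)
  usable <- widths >= seqLength
  if (!any(usable)) {
    warning("genome shorter than seqLength; skipping")
    return(data.frame(contig = character(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  genome <- genome[usable]
  widths <- widths[usable]
  n <- round(coverage * sum(widths) / seqLength)
  if (n == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  nOffsets <- widths - seqLength + 1L
  contig <- sample.int(length(genome), n, replace = TRUE,
                       prob = nOffsets / sum(nOffsets))
  start <- floor(runif(n) * nOffsets[contig])   # 0-based
  seqs <- as.character(Biostrings::subseq(genome[contig], start = start + 1L,
                                          width = seqLength))
  data.frame(contig = names(genome)[contig], start = as.integer(start),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Build a labelled k-mer profile training set
#'
#' Samples fixed-length subsequences from every genome at the requested
#' coverage, profiles them against the canonical k-mer index, and labels
#' each row with its genome's taxon at the requested rank. Class order is
#' deterministic: labels are a factor whose levels are the sorted taxon
#' ids.
#'
#' @param genomes Named [Biostrings::DNAStringSet] (or list of DNA strings /
#'   DNAStringSets, one element per genome; multi-contig genomes allowed).
#'   Names are genome ids and must all be present in `taxonomy`.
#' @param taxonomy A [TaxonomyTable-class].
#' @param index A [KmerIndex-class].
#' @param labelLevel `"species"` or `"genus"`.
#' @param seqLength,coverage Passed to [sampleSequences()].
#' @param normalize Normalise profiles to frequencies (default `TRUE`).
#' @param seed Optional integer seed.
#' @return A list with `x` (profile matrix, rows = sampled subsequences),
#'   `labels` (factor of taxon ids, sorted levels), and `sources`
#'   (data.frame: genome_id, contig, start).
#' @export
buildTrainingSet <- function(genomes, taxonomy, index,
                             labelLevel = c("species", "genus"),
                             seqLength = 1000, coverage = 5,
                             normalize = TRUE, seed = NULL) {
  labelLevel <- match.arg(labelLevel)
  stopifnot(is(taxonomy, "TaxonomyTable"), is(index, "KmerIndex"))
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    stop("'genomes' must be named by genome id")
  taxa <- taxonOfGenome(taxonomy, names(genomes), level = labelLevel)
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(names(genomes), function(id) {
    smp <- sampleSequences(genomes[[id]], seqLength = seqLength,
                           coverage = coverage)
    if (nrow(smp)) smp$genome_id <- id
    smp
  })
  parts <- parts[vapply(parts, nrow, 0L) > 0]
  if (!length(parts)) stop("no genome yielded any training subsequence")
  smp <- do.call(rbind, parts)
  x <- kmerProfileMatrix(smp$sequence, index, normalize = normalize)
  labels <- factor(taxa[smp$genome_id], levels = sort(unique(taxa)))
  rownames(x) <- sprintf("%s_%06d", smp$genome_id, seq_len(nrow(smp)))
  list(x = x, labels = labels,
       sources = data.frame(genome_id = smp$genome_id, contig = smp$contig,
                            start = smp$start, stringsAsFactors = FALSE))
}

#' Hold out species per genus for out-of-database testing
#'
#' Uniformly selects `nHoldout` species in each genus to leave out of the
#' reference database; reads simulated from held-out species test
#' genus-level generalisation to novel species.
#'
#' @param taxonomy A [TaxonomyTable-class].
#' @param nHoldout Species to hold out per genus (0 allowed).
#' @param seed Optional integer seed.
#' @return List with character vectors `inDb` and `outDb` of species ids;
#'   disjoint, jointly covering all species.
#' @export
holdoutSplit <- function(taxonomy, nHoldout = 1, seed = NULL) {
  stopifnot(is(taxonomy, "TaxonomyTable"), nHoldout >= 0)
  if (!is.null(seed)) set.seed(seed)
  tab <- taxonomy@table[!duplicated(taxonomy@table$species_id), ]
  bySize <- split(tab$species_id, tab$genus_id)
  if (nHoldout > 0 && any(vapply(bySize, length, 0L) <= nHoldout))
    stop("every genus must have more than ", nHoldout,
         " species to hold ", nHoldout, " out")
  out <- unlist(lapply(bySize, function(sp) {
    if (nHoldout == 0) character(0)
    else sample(sp, nHoldout)
  }), use.names = FALSE)
  list(inDb = sort(setdiff(tab$species_id, out)), outDb = sort(out))
}
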