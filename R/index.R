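# Reference catalog and the unitig-based k-mer index.

#' Reference catalog
#'
#' An ordered set of reference sequences (quantified transcripts first-class,
#' decoys flagged), the unit over which the unitig index is built. Decoy and
#' non-decoy sequences share one k-mer space; the flag is consulted only at
#' fragment classification time.
#'
#' @slot seqs named character vector of uppercase nucleotide sequences.
#' @slot isDecoy logical vector parallel to `seqs`.
#' @slot dupMap named character vector mapping removed duplicate transcript
#'   names to their retained representative (empty when none were removed).
#' @export
setClass("ReferenceCatalog",
  representation(seqs = "character", isDecoy = "logical",
                 dupMap = "character"),
  prototype(seqs = character(), isDecoy = logical(), dupMap = character()))

setValidity("ReferenceCatalog", function(object) {
  if (length(object@seqs) != length(object@isDecoy))
    return("seqs and isDecoy lengths differ")
  nm <- names(object@seqs)
  if (length(object@seqs) > 0 && (is.null(nm) || any(!nzchar(nm))))
    return("all sequences must be named")
  if (anyDuplicated(nm)) return("reference names must be unique")
  if (any(nchar(object@seqs) == 0L)) return("zero-length reference sequence")
  TRUE
})

#' Build a reference catalog from transcripts and optional decoys
#'
#' Duplicate handling follows the indexing convention of keeping duplicate
#' transcripts by default; with `keepDuplicates = FALSE` exactly one
#' representative (the first in input order) of each identical-sequence group
#' is retained and the removed-to-representative map is stored in the
#' catalog. A transcript whose sequence is identical to a decoy sequence is
#' rejected as an input error (decoy precedence would otherwise be
#' ambiguous).
#'
#' @param transcripts named character vector or `DNAStringSet` of transcript
#'   sequences.
#' @param decoys optional named character vector or `DNAStringSet` of decoy
#'   sequences.
#' @param config an [IndexConfig-class] object (only `keepDuplicates` is
#'   consulted here).
#' @return A [ReferenceCatalog-class] with transcripts first, decoys after.
#' @export
referenceCatalog <- function(transcripts, decoys = NULL,
                             config = indexConfig()) {
  tx <- toupper(asSeqVector(transcripts))
  if (is.null(names(tx)) || any(!nzchar(names(tx))))
    stop("transcripts must be named")
  if (anyDuplicated(names(tx))) stop("transcript names must be unique")
  dupMap <- character()
  if (!config@keepDuplicates) {
    rep1 <- !duplicated(tx)
    reps <- names(tx)[rep1][match(tx[!rep1], tx[rep1])]
    dupMap <- setNames(reps, names(tx)[!rep1])
    tx <- tx[rep1]
  }
  dc <- character()
  if (!is.null(decoys) && length(decoys) > 0) {
    dc <- toupper(asSeqVector(decoys))
    if (is.null(names(dc)) || any(!nzchar(names(dc))))
      stop("decoys must be named")
    if (any(tx %in% dc))
      stop("transcript sequence identical to a decoy sequence; ",
           "remove one of the two (decoy precedence is not defined)")
  }
  new("ReferenceCatalog",
      seqs = c(tx, dc),
      isDecoy = c(rep(FALSE, length(tx)), rep(TRUE, length(dc))),
      dupMap = dupMap)
}

#' @describeIn ReferenceCatalog-class reference names, transcripts first.
#' @param x,object a `ReferenceCatalog`.
#' @export
refNames <- function(x) names(x@seqs)

#' @describeIn ReferenceCatalog-class sequence lengths.
#' @export
refLengths <- function(x) setNames(nchar(x@seqs), names(x@seqs))

#' @describeIn ReferenceCatalog-class logical decoy flags.
#' @export
isDecoy <- function(x) setNames(x@isDecoy, names(x@seqs))

#' @describeIn ReferenceCatalog-class the sequences as a character vector.
#' @export
refSequences <- function(x) x@seqs

setMethod("show", "ReferenceCatalog", function(object) {
  cat("ReferenceCatalog with", sum(!object@isDecoy), "transcripts and",
      sum(object@isDecoy), "decoy sequences\n")
  if (length(object@dupMap))
    cat(" ", length(object@dupMap), "duplicate transcripts collapsed\n")
})

#' Unitig k-mer index
#'
#' The compacted de Bruijn graph of the catalog sequences (split at N runs),
#' with a canonical k-mer to (unitig, offset) map rebuilt deterministically
#' from the unitigs, and a per-unitig occurrence table giving every
#' (reference ordinal, offset, orientation) at which the unitig occurs.
#'
#' @slot k k-mer length.
#' @slot catalog the indexed [ReferenceCatalog-class].
#' @slot unitigs character vector of unitig sequences (canonical form).
#' @slot occPtr integer CSR offsets into the occurrence columns, length
#'   `length(unitigs) + 1`.
#' @slot occRef,occPos,occStrand occurrence columns: 1-based reference
#'   ordinal is `occRef + 1`; `occPos` is the 0-based offset of the unitig
#'   occurrence; `occStrand` is 0 for forward, 1 for reverse complement.
#' @slot version serialization format version.
#' @export
setClass("UnitigIndex",
  representation(k = "integer", catalog = "ReferenceCatalog",
                 unitigs = "character", occPtr = "integer",
                 occRef = "integer", occPos = "integer",
                 occStrand = "integer", version = "character"),
  prototype(version = "1"))

setValidity("UnitigIndex", function(object) {
  if (length(object@occPtr) != length(object@unitigs) + 1L)
    return("occPtr length must be length(unitigs) + 1")
  if (any(nchar(object@unitigs) < object@k))
    return("unitig shorter than k")
  nOcc <- length(object@occRef)
  if (length(object@occPos) != nOcc || length(object@occStrand) != nOcc)
    return("occurrence columns have unequal lengths")
  TRUE
})

#' @describeIn UnitigIndex-class the k-mer length of an index.
#' @param x,object a `UnitigIndex`.
#' @export
kmerSize <- function(x) x@k

#' @describeIn UnitigIndex-class number of unitigs.
#' @export
nUnitigs <- function(x) length(x@unitigs)

#' @describeIn UnitigIndex-class the indexed catalog.
#' @export
indexCatalog <- function(x) x@catalog

setMethod("show", "UnitigIndex", function(object) {
  cat("UnitigIndex: k =", object@k, "|", length(object@unitigs),
      "unitigs |", length(object@occRef), "occurrences\n")
  show(object@catalog)
})

# internal: the plain-list view handed to the C++ routines
indexAsList <- function(x) {
  list(k = x@k, unitigs = x@unitigs, occPtr = x@occPtr, occRef = x@occRef,
       occPos = x@occPos, occStrand = x@occStrand)
}

#' Build the unitig index over a reference catalog
#'
#' Unitigs are maximal non-branching paths of the compacted de Bruijn graph
#' of the union of catalog sequences; k-mers are canonicalized (lexicographic
#' minimum of forward and reverse complement) and never span an N.
#' Construction is deterministic: repeated builds of the same catalog yield
#' identical objects. Sequences shorter than k contribute no k-mers and are
#' un-anchorable (a notice is emitted).
#'
#' @param catalog a [ReferenceCatalog-class].
#' @param config an [IndexConfig-class]; `config@k` sets the k-mer length.
#' @return A [UnitigIndex-class].
#' @export
buildIndex <- function(catalog, config = indexConfig()) {
  validObject(catalog)
  validObject(config)
  k <- config@k
  if (all(nchar(catalog@seqs) < k))
    stop("k = ", k, " exceeds the length of every catalog sequence")
  short <- nchar(catalog@seqs) < k
  if (any(short))
    message(sum(short), " sequence(s) shorter than k are un-anchorable")
  raw <- cpp_build_index(unname(catalog@seqs), k)
  new("UnitigIndex", k = k, catalog = catalog,
      unitigs = raw$unitigs, occPtr = raw$occPtr, occRef = raw$occRef,
      occPos = raw$occPos, occStrand = raw$occStrand, version = "1")
}

#' Save / load an index directory
#'
#' The on-disk layout is plain text: `catalog.tsv` (name, length, decoy
#' flag), `refs.fa` and `unitigs.fa` FASTA files, `occ.tsv` (the occurrence
#' table) and `info.json` (k, version). The k-mer map is not stored; it is
#' rebuilt deterministically from the unitigs on load.
#'
#' @param index a [UnitigIndex-class].
#' @param dir directory to create or read.
#' @return `saveIndex`: `dir`, invisibly. `loadIndex`: a `UnitigIndex`.
#' @export
saveIndex <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cat_df <- data.frame(name = refNames(index@catalog),
                       length = unname(refLengths(index@catalog)),
                       decoy = as.integer(index@catalog@isDecoy))
  write.table(cat_df, file.path(dir, "catalog.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeFasta(index@catalog@seqs, file.path(dir, "refs.fa"))
  writeFasta(setNames(index@unitigs,
                      paste0("u", seq_along(index@unitigs) - 1L)),
             file.path(dir, "unitigs.fa"))
  occ <- data.frame(unitig = rep(seq_along(index@unitigs) - 1L,
                                 diff(index@occPtr)),
                    ref = index@occRef, pos = index@occPos,
                    strand = index@occStrand)
  write.table(occ, file.path(dir, "occ.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (length(index@catalog@dupMap)) {
    write.table(data.frame(removed = names(index@catalog@dupMap),
                           representative = unname(index@catalog@dupMap)),
                file.path(dir, "duplicates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(k = index@k, version = index@version),
                       file.path(dir, "info.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "info.json"))
  cat_df <- read.table(file.path(dir, "catalog.tsv"), sep = "\t",
                       header = TRUE, colClasses = c("character", "integer",
                                                     "integer"))
  seqs <- as.character(readFasta(file.path(dir, "refs.fa")))
  names(seqs) <- cat_df$name
  dupMap <- character()
  dupPath <- file.path(dir, "duplicates.tsv")
  if (file.exists(dupPath)) {
    dd <- read.table(dupPath, sep = "\t", header = TRUE,
                     colClasses = "character")
    dupMap <- setNames(dd$representative, dd$removed)
  }
  catalog <- new("ReferenceCatalog", seqs = seqs,
                 isDecoy = cat_df$decoy == 1L, dupMap = dupMap)
  unitigs <- as.character(readFasta(file.path(dir, "unitigs.fa")))
  occ <- read.table(file.path(dir, "occ.tsv"), sep = "\t", header = TRUE)
  occPtr <- cumsum(c(0L, tabulate(occ$unitig + 1L, nbins = length(unitigs))))
  new("UnitigIndex", k = as.integer(info$k), catalog = catalog,
      unitigs = unname(unitigs), occPtr = as.integer(occPtr),
      occRef = as.integer(occ$ref), occPos = as.integer(occ$pos),
      occStrand = as.integer(occ$strand),
      version = as.character(info$version))
}
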