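# Readers and writers for the standard formats the pipeline touches.
# Internal coordinates are 0-based half-open throughout the package;
# conversion to SAM/GTF 1-based conventions happens only at (de)serialization.

#' Read a FASTA file
#'
#' Sequences are uppercased; multi-line records are concatenated. Gzip input
#' is accepted transparently.
#'
#' @param path path to a FASTA (optionally gzipped) file.
#' @return A named [Biostrings::DNAStringSet] in file order.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ds <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(ds) == 0L)) {
    bad <- names(ds)[Biostrings::width(ds) == 0L][1L]
    stop("empty sequence for record '", bad, "' in ", path)
  }
  if (is.null(names(ds)) || any(!nzchar(names(ds))))
    stop("FASTA record with empty name in ", path)
  # keep only the first whitespace-delimited token of each header
  names(ds) <- sub("\\s.*$", "", names(ds))
  ds <- Biostrings::DNAStringSet(toupper(as.character(ds)))
  ds
}

#' Write sequences to FASTA
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to a FASTQ (optionally gzipped) file.
#' @return A named [Biostrings::DNAStringSet]; per-base qualities are carried
#'   in `mcols(x)$qualities` as a `BStringSet`.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param seqs named character vector or `DNAStringSet` of read sequences.
#' @param path output path (".gz" suffix compresses).
#' @param qualities optional character vector of quality strings; defaults to
#'   a constant Phred 35 ("D") per base.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(seqs, path, qualities = NULL) {
  sq <- asSeqVector(seqs)
  if (is.null(qualities))
    qualities <- vapply(nchar(sq), function(n)
      paste(rep("D", n), collapse = ""), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(sq), "\n", sq, "\n+\n", qualities), con)
  invisible(path)
}

#' Check that mate names agree
#'
#' Mate names must be identical after stripping `/1` and `/2` suffixes.
#'
#' @param names1,names2 read name vectors for the two ends.
#' @return `TRUE`, invisibly; errors otherwise.
#' @export
checkMatePairs <- function(names1, names2) {
  s1 <- sub("/[12]$", "", names1)
  s2 <- sub("/[12]$", "", names2)
  if (length(s1) != length(s2) || any(s1 != s2))
    stop("mate names disagree after stripping /1 and /2 suffixes")
  invisible(TRUE)
}

#' Read exon records from a GTF file
#'
#' Only features with type `exon` are returned. GTF's 1-based closed
#' coordinates are converted to 0-based half-open.
#'
#' @param path path to a GTF file.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `transcript_id`, `gene_id` and `strand`, in file order.
#' @export
readGtfExons <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), transcript_id = character(),
                      gene_id = character(), strand = character()))
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("exon record without transcript_id attribute in ", path)
  gid <- if (is.null(gr$gene_id)) rep(NA_character_, length(gr)) else gr$gene_id
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    transcript_id = gr$transcript_id,
    gene_id = gid,
    strand = as.character(BiocGenerics::strand(gr)))
}

# ---------------------------------------------------------------------------
# SAM (plain text)
# ---------------------------------------------------------------------------

samColumns <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                "rnext", "pnext", "tlen", "seq", "qual")

#' Read a plain-text SAM file
#'
#' @param path path to a SAM file.
#' @return A list with `header` (character vector of `@` lines) and
#'   `alignments`, a data.frame with the eleven mandatory columns (`pos`
#'   1-based as in SAM) plus a `tags` column holding the tab-joined optional
#'   fields of each record.
#' @export
readSam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(body) == 0L) {
    aln <- data.frame(matrix(character(), ncol = 11,
                             dimnames = list(NULL, samColumns)))
    aln$flag <- integer(); aln$pos <- integer()
    aln$mapq <- integer(); aln$tags <- character()
    return(list(header = hdr, alignments = aln))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop("SAM record with fewer than 11 fields at line ",
         which(nf < 11L)[1L])
  get <- function(i) vapply(parts, `[[`, character(1), i)
  aln <- data.frame(
    qname = get(1), flag = as.integer(get(2)), rname = get(3),
    pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
    rnext = get(7), pnext = as.integer(get(8)), tlen = as.integer(get(9)),
    seq = get(10), qual = get(11))
  aln$tags <- vapply(parts, function(p)
    if (length(p) > 11L) paste(p[12:length(p)], collapse = "\t") else "",
    character(1))
  list(header = hdr, alignments = aln)
}

#' Extract an optional SAM tag
#'
#' @param alignments the `alignments` data.frame from [readSam()].
#' @param tag two-letter tag name, e.g. `"MD"`.
#' @return Character vector of tag values (`NA` where absent); integer tags
#'   (`i` type) are converted to integer.
#' @export
samTag <- function(alignments, tag) {
  pat <- paste0("(^|\t)", tag, ":([AifZHB]):([^\t]*)")
  m <- regmatches(alignments$tags, regexec(pat, alignments$tags))
  type <- vapply(m, function(x) if (length(x)) x[3] else NA_character_,
                 character(1))
  val <- vapply(m, function(x) if (length(x)) x[4] else NA_character_,
                character(1))
  if (all(is.na(type) | type == "i")) return(as.integer(val))
  val
}

#' Write alignments to a plain-text SAM file
#'
#' Mapped records whose `rname` is not a known reference are rejected.
#' Decoy-flagged records (a logical `decoy` column) are emitted with the
#' `XT:A:D` tag appended to their optional fields.
#'
#' @param refLengths named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @param alignments data.frame with the mandatory SAM columns (as produced
#'   by [readSam()]); optional columns `tags` (tab-joined optional fields)
#'   and `decoy` (logical).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(refLengths, alignments, path) {
  mapped <- !bitwAnd(alignments$flag, 4L)
  bad <- mapped & !(alignments$rname %in% c(names(refLengths), "*"))
  if (any(bad))
    stop("alignment to unknown reference '",
         alignments$rname[bad][1L], "'")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(refLengths), "\tLN:", refLengths))
  tags <- if ("tags" %in% names(alignments)) alignments$tags else
    rep("", nrow(alignments))
  if ("decoy" %in% names(alignments)) {
    d <- alignments$decoy
    tags[d] <- ifelse(nzchar(tags[d]), paste0(tags[d], "\tXT:A:D"), "XT:A:D")
  }
  body <- paste(alignments$qname, alignments$flag, alignments$rname,
                alignments$pos, alignments$mapq, alignments$cigar,
                alignments$rnext, alignments$pnext, alignments$tlen,
                alignments$seq, alignments$qual, sep = "\t")
  body <- ifelse(nzchar(tags), paste(body, tags, sep = "\t"), body)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CIGAR + MD reconciliation
# ---------------------------------------------------------------------------

# split a CIGAR string into (length, op) pairs
cigarOps <- function(cigar) {
  if (is.na(cigar) || cigar == "*") stop("record has no CIGAR")
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (m[1] == -1L || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

# tokenize an MD tag into a stream of per-base events:
# "m" match, "x" mismatch, "d" deleted reference base
mdStream <- function(md) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  if (paste(toks, collapse = "") != md) stop("malformed MD tag: ", md)
  out <- character(0)
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) out <- c(out, rep("m", as.integer(t)))
    else if (startsWith(t, "^")) out <- c(out, rep("d", nchar(t) - 1L))
    else out <- c(out, "x")
  }
  out
}

#' Reconcile a CIGAR string with its MD tag into per-base events
#'
#' Produces one event per query base (`MATCH`, `MISMATCH`, `INSERTION`,
#' `SOFTCLIP`) plus zero-query-length `DELETION` events for deleted
#' reference bases. `N` (intron skip), `H` and `P` operations consume no
#' query bases and yield no events.
#'
#' @param cigar CIGAR string of a mapped record.
#' @param md MD tag value, or `NULL` when mismatches need not be
#'   distinguished (all `M` bases are then reported as `MATCH`).
#' @return Character vector of events in alignment order.
#' @export
parseCigarMd <- function(cigar, md = NULL) {
  co <- cigarOps(cigar)
  mdv <- if (!is.null(md) && !is.na(md)) mdStream(md) else NULL
  events <- character(0)
  mi <- 1L  # cursor into the MD stream
  takeMd <- function(n, wantDel) {
    if (is.null(mdv)) return(NULL)
    if (mi + n - 1L > length(mdv))
      stop("MD tag shorter than CIGAR implies (cigar=", cigar, ", md=", md, ")")
    got <- mdv[mi:(mi + n - 1L)]
    if (wantDel && any(got != "d"))
      stop("MD tag inconsistent with CIGAR deletion (cigar=", cigar,
           ", md=", md, ")")
    if (!wantDel && any(got == "d"))
      stop("MD deletion where CIGAR expects aligned bases (cigar=", cigar,
           ", md=", md, ")")
    mi <<- mi + n
    got
  }
  for (i in seq_along(co$op)) {
    n <- co$len[i]
    switch(co$op[i],
      S = { events <- c(events, rep("SOFTCLIP", n)) },
      I = { events <- c(events, rep("INSERTION", n)) },
      M = {
        got <- takeMd(n, wantDel = FALSE)
        if (is.null(got)) events <- c(events, rep("MATCH", n))
        else events <- c(events, ifelse(got == "m", "MATCH", "MISMATCH"))
      },
      `=` = { takeMd(n, wantDel = FALSE); events <- c(events, rep("MATCH", n)) },
      X = { takeMd(n, wantDel = FALSE); events <- c(events, rep("MISMATCH", n)) },
      D = { takeMd(n, wantDel = TRUE); events <- c(events, rep("DELETION", n)) },
      N = NULL, H = NULL, P = NULL,
      stop("unsupported CIGAR op: ", co$op[i]))
  }
  if (!is.null(mdv) && mi <= length(mdv))
    stop("MD tag longer than CIGAR implies (cigar=", cigar, ", md=", md, ")")
  events
}
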