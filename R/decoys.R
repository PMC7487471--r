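# Decoy-sequence extraction: hard-mask annotated exons, locate genomic
# segments sequence-similar to transcripts (minimizer seeding + minhash
# Jaccard identity estimation), merge per chromosome, extract and
# concatenate.

#' Hard-mask exonic bases in a genome
#'
#' Every base covered by an exon interval is replaced with `N`; all other
#' bases are unchanged. Length-preserving and idempotent.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param exons data.frame from [readGtfExons()] (0-based half-open
#'   intervals).
#' @return Named character vector of masked chromosome sequences.
#' @export
maskExons <- function(genome, exons) {
  g <- asSeqVector(genome)
  if (nrow(exons) > 0 && !all(exons$chrom %in% names(g)))
    stop("exon on unknown chromosome: ",
         setdiff(exons$chrom, names(g))[1L])
  for (ch in unique(exons$chrom)) {
    e <- exons[exons$chrom == ch, , drop = FALSE]
    if (any(e$start < 0L | e$end > nchar(g[[ch]])))
      stop("exon interval outside chromosome ", ch)
    r <- charToRaw(g[[ch]])
    for (i in seq_len(nrow(e)))
      if (e$end[i] > e$start[i])
        r[(e$start[i] + 1L):e$end[i]] <- charToRaw("N")
    g[[ch]] <- rawToChar(r)
  }
  g
}

# identity sketch of a sequence: the full canonical k-mer hash set (window
# width 1 makes every k-mer a minimizer), or its bottom-sketchSize minhash
# when a sketch size is configured. The sparser minimizerWindow winnowing is
# used only to seed candidate windows.
identitySketch <- function(seq, config) {
  mm <- cpp_minimizers(seq, config@sketchK, 1L)
  h <- unique(mm$hash)
  if (config@sketchSize > 0L && length(h) > config@sketchSize)
    h <- sort(h)[seq_len(config@sketchSize)]
  h
}

# Mash relation: Jaccard j of canonical k-mer sketches to identity estimate
jaccardToIdentity <- function(j, k) {
  ifelse(j <= 0, -Inf, 1 + (1 / k) * log(2 * j / (1 + j)))
}

#' Map transcript segments against a masked genome
#'
#' Each transcript is cut into consecutive segments of `segmentSize` bases
#' (a final remainder of at least half a segment is kept). For each segment,
#' candidate genomic windows are located through shared `(sketchK,
#' minimizerWindow)` minimizers; the best-supported window's identity to the
#' segment is then estimated from the Jaccard `j` of the two canonical
#' k-mer hash sets (bottom-`sketchSize` minhash sketches when a sketch size
#' is configured) via the Mash relation `1 + (1/k) * ln(2j / (1+j))`. The
#' best window per segment is reported when the estimate reaches
#' `minIdentity`.
#'
#' @param transcripts named character vector (or `DNAStringSet`) of spliced
#'   transcript sequences.
#' @param maskedGenome named character vector of exon-masked chromosomes
#'   (from [maskExons()]).
#' @param config a [DecoyConfig-class].
#' @return A data.frame of segment hits: `transcript_id`, `seg_start`,
#'   `seg_end` (on the transcript), `chrom`, `gstart`, `gend` (0-based
#'   half-open on the genome) and `estimated_identity`.
#' @export
mapSegments <- function(transcripts, maskedGenome, config = decoyConfig()) {
  tx <- asSeqVector(transcripts)
  g <- asSeqVector(maskedGenome)
  if (length(tx) == 0L || length(g) == 0L)
    stop("transcripts and masked genome must be non-empty")
  segLen <- config@segmentSize
  # genome minimizers, one lookup table per chromosome
  gmin <- lapply(g, cpp_minimizers, k = config@sketchK,
                 w = config@minimizerWindow)
  hits <- list()
  for (t in names(tx)) {
    L <- nchar(tx[[t]])
    starts <- seq(0L, max(0L, L - segLen), by = segLen)
    ends <- pmin(starts + segLen, L)
    # final remainder of at least segLen/2
    last <- max(ends)
    if (L - last >= segLen / 2) {
      starts <- c(starts, last)
      ends <- c(ends, L)
    }
    keep <- ends - starts >= segLen / 2
    starts <- starts[keep]; ends <- ends[keep]
    for (si in seq_along(starts)) {
      seg <- substr(tx[[t]], starts[si] + 1L, ends[si])
      smm <- cpp_minimizers(seg, config@sketchK, config@minimizerWindow)
      if (length(smm$hash) == 0L) next
      sketchA <- identitySketch(seg, config)
      best <- NULL
      for (ch in names(g)) {
        gm <- gmin[[ch]]
        shared <- smm$hash %in% gm$hash
        if (!any(shared)) next
        # candidate window starts from minimizer diagonals
        idx <- gm$hash %in% smm$hash
        gpos <- gm$pos[idx]
        ghash <- gm$hash[idx]
        spos <- smm$pos[match(ghash, smm$hash)]
        diags <- gpos - spos
        cand <- sort(unique(diags))
        wlen <- ends[si] - starts[si]
        supp <- vapply(cand, function(s0)
          length(unique(ghash[gpos >= s0 & gpos < s0 + wlen])), integer(1))
        s0 <- cand[which.max(supp)]
        s0 <- min(max(0L, s0), max(0L, nchar(g[[ch]]) - wlen))
        win <- substr(g[[ch]], s0 + 1L, s0 + wlen)
        sketchB <- identitySketch(win, config)
        # an N-dominated window cannot carry a credible identity estimate
        if (length(sketchB) < length(sketchA) / 2) next
        j <- length(intersect(sketchA, sketchB)) /
          length(union(sketchA, sketchB))
        ident <- jaccardToIdentity(j, config@sketchK)
        if (is.null(best) || ident > best$ident)
          best <- list(chrom = ch, s0 = s0, wlen = wlen, ident = ident)
      }
      if (!is.null(best) && best$ident >= config@minIdentity) {
        hits[[length(hits) + 1L]] <- data.frame(
          transcript_id = t, seg_start = starts[si], seg_end = ends[si],
          chrom = best$chrom, gstart = best$s0,
          gend = best$s0 + best$wlen,
          estimated_identity = min(1, best$ident))
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(transcript_id = character(), seg_start = integer(),
                      seg_end = integer(), chrom = character(),
                      gstart = integer(), gend = integer(),
                      estimated_identity = numeric()))
  do.call(rbind, hits)
}

#' Merge segment hits per chromosome and extract decoy sequences
#'
#' Genomic hit intervals are unioned per chromosome (overlapping or adjacent
#' intervals merged) and the corresponding unmasked genome sequence is
#' concatenated, in coordinate order, into one decoy record named after the
#' chromosome.
#'
#' @param hits data.frame from [mapSegments()].
#' @param genome named character vector of the original (unmasked)
#'   chromosomes.
#' @param pad bases of flanking genome added to each hit interval before
#'   merging (clamped to chromosome bounds); see
#'   [DecoyConfig-class]`@extractionPad`.
#' @return A list with `decoys` (named character vector, one record per
#'   chromosome with hits) and `bed` (data.frame `chrom`, `start`, `end` of
#'   the merged intervals, 0-based half-open).
#' @export
mergeAndExtract <- function(hits, genome, pad = 0L) {
  g <- asSeqVector(genome)
  if (nrow(hits) > 0 && !all(hits$chrom %in% names(g)))
    stop("hit on unknown chromosome: ", setdiff(hits$chrom, names(g))[1L])
  decoys <- character()
  bed <- list()
  for (ch in names(g)) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    if (nrow(h) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(
      start = pmax(h$gstart - pad, 0L) + 1L,
      end = pmin(h$gend + pad, nchar(g[[ch]]))))
    starts <- BiocGenerics::start(ir) - 1L
    ends <- BiocGenerics::end(ir)
    decoys[[ch]] <- paste(substring(g[[ch]], starts + 1L, ends),
                          collapse = "")
    bed[[length(bed) + 1L]] <- data.frame(chrom = ch, start = starts,
                                          end = ends)
  }
  list(decoys = decoys,
       bed = if (length(bed)) do.call(rbind, bed) else
         data.frame(chrom = character(), start = integer(),
                    end = integer()))
}

#' Extract decoy sequences for a transcriptome
#'
#' The full extraction pipeline: hard-mask annotated exons, map transcript
#' segments against the masked genome at `segmentSize`/`minIdentity`
#' (defaults 500 bp, 80%), merge per chromosome and extract one decoy
#' record per chromosome from the unmasked genome.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosomes.
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   transcripts.
#' @param exons exon annotation data.frame ([readGtfExons()]).
#' @param config a [DecoyConfig-class].
#' @return A list with `decoys`, `bed` and the raw `hits`.
#' @export
makeDecoys <- function(genome, transcripts, exons, config = decoyConfig()) {
  masked <- maskExons(genome, exons)
  hits <- mapSegments(transcripts, masked, config)
  out <- mergeAndExtract(hits, genome, pad = config@extractionPad)
  c(out, list(hits = hits))
}

#' Write intervals to BED3
#'
#' @param bed data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(bed, path) {
  write.table(bed[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
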