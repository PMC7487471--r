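# Phase 5: score-only extension alignment, the alignment cache, the minimum
# valid score threshold, and the decoy decision rule.

#' Extension alignment score of a read end along a chain
#'
#' The score is the sum of exact-match contributions of the chain anchors,
#' optimal affine-gap global alignment scores of the inter-anchor gaps, and
#' free-end extension scores of the read prefix before the first anchor and
#' suffix after the last anchor. Only the score is computed, never an
#' alignment path (no CIGAR).
#'
#' @param read the (oriented) read sequence: for a reverse-complement chain
#'   pass the reverse-complemented read.
#' @param refSeq the full reference sequence the chain lies on.
#' @param chainAnchors data.frame with `read_start`, `ref_start`, `length`
#'   (oriented-read coordinates, as produced by [mapReadEnd()]).
#' @param params an [AlignParams-class].
#' @return The alignment score (numeric scalar).
#' @export
extensionScore <- function(read, refSeq, chainAnchors,
                           params = alignParams()) {
  cpp_extension_score(read, refSeq,
                      as.integer(chainAnchors$read_start),
                      as.integer(chainAnchors$ref_start),
                      as.integer(chainAnchors$length),
                      params@match, params@mismatch, params@gapOpen,
                      params@gapExtend, params@bandPad)
}

#' Create an alignment cache
#'
#' A per-read memo keyed by the reference substring a read end is predicted
#' to align to (plus end, orientation and relative anchor layout). Lookups
#' never change a returned score; the cache only avoids recomputing the
#' identical extension alignment, e.g. across duplicate transcripts.
#'
#' @return An environment with fields `map` (the memo), `computed` and
#'   `hits` (counters).
#' @export
newAlignmentCache <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(parent = emptyenv())
  e$computed <- 0L
  e$hits <- 0L
  e
}

#' Extension score with memoization
#'
#' Identical to [extensionScore()]; a second call with an identical
#' reference substring (and end/orientation/anchor layout) performs no
#' dynamic programming, observable through the cache's `computed` counter.
#'
#' @inheritParams extensionScore
#' @param cache an environment from [newAlignmentCache()], scoped to the
#'   current read; pass `NULL` to disable caching.
#' @param end read end identifier (1 or 2), part of the cache key.
#' @param orientation chain orientation (0/1), part of the cache key.
#' @return The alignment score (numeric scalar).
#' @export
cachedExtensionScore <- function(cache, read, refSeq, chainAnchors,
                                 params = alignParams(), end = 1L,
                                 orientation = 0L) {
  if (is.null(cache))
    return(extensionScore(read, refSeq, chainAnchors, params))
  lo <- min(chainAnchors$ref_start) -
    (min(chainAnchors$read_start) + params@bandPad)
  hi <- max(chainAnchors$ref_start + chainAnchors$length) +
    (nchar(read) + params@bandPad)
  lo <- max(0L, lo)
  hi <- min(nchar(refSeq), hi)
  key <- paste(end, orientation, substr(refSeq, lo + 1L, hi),
               paste(chainAnchors$read_start,
                     chainAnchors$ref_start - lo,
                     chainAnchors$length, collapse = ";"),
               sep = "|")
  hit <- get0(key, envir = cache$map, inherits = FALSE)
  if (!is.null(hit)) {
    cache$hits <- cache$hits + 1L
    return(hit)
  }
  s <- extensionScore(read, refSeq, chainAnchors, params)
  cache$computed <- cache$computed + 1L
  assign(key, s, envir = cache$map)
  s
}

#' Classify a fragment from its scored mappings
#'
#' The minimum valid alignment score is `minScoreFraction` times the maximum
#' obtainable score (`match` times the fragment's total base count). The
#' decoy rule is applied on raw best scores: if the best score to any decoy
#' strictly exceeds the best score to any non-decoy reference, every mapping
#' of the fragment is invalid and the fragment's status is `DECOY`.
#' Otherwise decoy mappings are filtered out and the surviving non-decoy
#' mappings at or above the threshold are kept (`ALIGNED`), or the fragment
#' is `UNALIGNED` if none survive.
#'
#' @param scored data.frame of candidate mappings with columns `score`
#'   (fragment-level alignment score) and `is_decoy` (logical); further
#'   columns are carried through to the survivors.
#' @param totalBases total number of sequenced bases in the fragment (both
#'   ends for paired reads).
#' @param params an [AlignParams-class].
#' @return A list with `status` (one of `"ALIGNED"`, `"DECOY"`,
#'   `"UNALIGNED"`), `survivors` (data.frame, non-empty iff aligned),
#'   `best_txome_score` and `best_decoy_score` (`NA` when no such mapping).
#' @export
classifyFragment <- function(scored, totalBases, params = alignParams()) {
  bestTx <- if (any(!scored$is_decoy)) max(scored$score[!scored$is_decoy])
            else NA_real_
  bestDecoy <- if (any(scored$is_decoy)) max(scored$score[scored$is_decoy])
               else NA_real_
  threshold <- params@minScoreFraction * params@match * totalBases
  if (!is.na(bestDecoy) && (is.na(bestTx) || bestDecoy > bestTx))
    return(list(status = "DECOY", survivors = scored[0, , drop = FALSE],
                best_txome_score = bestTx, best_decoy_score = bestDecoy))
  surv <- scored[!scored$is_decoy & scored$score >= threshold, ,
                 drop = FALSE]
  list(status = if (nrow(surv) > 0L) "ALIGNED" else "UNALIGNED",
       survivors = surv, best_txome_score = bestTx,
       best_decoy_score = bestDecoy)
}

#' Run selective alignment over a read set
#'
#' Executes all five phases per fragment against the index and classifies
#' each fragment as `ALIGNED`, `DECOY` or `UNALIGNED`. Decoy-status
#' fragments contribute nothing downstream; their best decoy locus is
#' retained for SAM emission.
#'
#' @param reads1 named character vector (or `DNAStringSet`) of first-end
#'   reads.
#' @param reads2 second-end reads, or `NULL` for a single-end library.
#' @param index a [UnitigIndex-class].
#' @param chain a [ChainParams-class].
#' @param pairing a [PairingPolicy-class].
#' @param aln an [AlignParams-class].
#' @param useCache enable the per-read alignment cache (on/off equivalent by
#'   construction; off recomputes every extension alignment).
#' @return An object of class `saRun`: a list with `fragments` (data.frame:
#'   `name`, `status`, `best_txome_score`, `best_decoy_score`, plus the best
#'   decoy locus columns), `mappings` (data.frame of surviving non-decoy
#'   mappings: `fragment` index, `name`, `ref` ordinal, `ref_name`,
#'   0-based predicted start positions `pos1`/`pos2`, `orientation1`,
#'   `dovetail`, `score`, `score1`, `score2`) and `metadata` (fragment
#'   counts per status, number of decoy-best fragments, extension
#'   alignments computed, cache hits).
#' @export
runSelectiveAlignment <- function(reads1, reads2 = NULL, index,
                                  chain = chainParams(),
                                  pairing = pairingPolicy(),
                                  aln = alignParams(), useCache = TRUE) {
  r1 <- asSeqVector(reads1)
  nm <- names(r1)
  if (is.null(nm)) nm <- paste0("frag", seq_along(r1))
  r2 <- if (is.null(reads2)) character(0) else asSeqVector(reads2)
  if (length(r2) > 0 && length(r2) != length(r1))
    stop("reads1 and reads2 must have equal length")
  if (length(r2) > 0 && !is.null(names(r2))) checkMatePairs(nm, names(r2))
  params <- paramsAsList(chain = chain, pairing = pairing, aln = aln,
                         useCache = useCache)
  res <- cpp_run_fragments(unname(r1), unname(r2), indexAsList(index),
                           unname(index@catalog@seqs),
                           unname(index@catalog@isDecoy), params)
  statusLevels <- c("ALIGNED", "DECOY", "UNALIGNED")
  fragments <- data.frame(
    name = nm,
    status = factor(statusLevels[res$status + 1L], levels = statusLevels),
    best_txome_score = res$best_txome_score,
    best_decoy_score = res$best_decoy_score,
    decoy_ref = res$decoy_ref,
    decoy_pos1 = res$decoy_pos1,
    decoy_pos2 = res$decoy_pos2,
    decoy_orientation1 = res$decoy_orientation1)
  mp <- res$mappings
  mappings <- data.frame(
    fragment = mp$fragment,
    name = nm[mp$fragment],
    ref = mp$ref,
    ref_name = refNames(index@catalog)[mp$ref],
    pos1 = mp$pos1, pos2 = mp$pos2,
    orientation1 = mp$orientation1,
    dovetail = mp$dovetail == 1L,
    score = mp$score, score1 = mp$score1, score2 = mp$score2)
  metadata <- list(
    n_fragments = length(r1),
    paired = length(r2) > 0,
    n_aligned = sum(res$status == 0L),
    n_decoy = sum(res$status == 1L),
    n_unaligned = sum(res$status == 2L),
    alignments_computed = res$alignments_computed,
    cache_hits = res$cache_hits)
  structure(list(fragments = fragments, mappings = mappings,
                 metadata = metadata), class = "saRun")
}

#' @export
print.saRun <- function(x, ...) {
  md <- x$metadata
  cat("Selective alignment run:", md$n_fragments, "fragments (",
      if (md$paired) "paired-end" else "single-end", ")\n")
  cat("  ALIGNED:", md$n_aligned, " DECOY:", md$n_decoy,
      " UNALIGNED:", md$n_unaligned, "\n")
  cat("  extension alignments computed:", md$alignments_computed,
      "; cache hits:", md$cache_hits, "\n")
  invisible(x)
}

#' Write surviving mappings (and decoy records) to SAM
#'
#' Emits one record per surviving mapping per end; fragments whose best
#' alignment was to a decoy are emitted at their best decoy locus with the
#' `XT:A:D` tag. Scores are carried in `AS:i`; the number of reported loci
#' per fragment in `NH:i`. No CIGAR is computed by selective alignment, so a
#' nominal full-length match CIGAR is written.
#'
#' @param run an `saRun` from [runSelectiveAlignment()].
#' @param index the [UnitigIndex-class] the run used.
#' @param reads1,reads2 the read sequences given to the run.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
writeMappingsSam <- function(run, index, reads1, reads2 = NULL, path) {
  r1 <- asSeqVector(reads1)
  r2 <- if (is.null(reads2)) NULL else asSeqVector(reads2)
  paired <- !is.null(r2)
  recs <- list()
  addRec <- function(qname, flag, rname, pos0, seq, score, nh, decoy) {
    recs[[length(recs) + 1L]] <<- data.frame(
      qname = qname, flag = flag, rname = rname, pos = pos0 + 1L,
      mapq = 255L, cigar = paste0(nchar(seq), "M"), rnext = "*",
      pnext = 0L, tlen = 0L, seq = seq, qual = "*",
      tags = paste0("AS:i:", as.integer(round(score)), "\tNH:i:", nh),
      decoy = decoy)
  }
  mp <- run$mappings
  if (nrow(mp) > 0) {
    nh <- table(mp$fragment)
    for (i in seq_len(nrow(mp))) {
      f <- mp$fragment[i]
      n <- as.integer(nh[as.character(f)])
      o1 <- mp$orientation1[i]
      flag1 <- (if (paired) 1L + 64L else 0L) + (if (!is.na(o1) && o1 == 1L) 16L else 0L)
      if (!is.na(mp$pos1[i]))
        addRec(mp$name[i], flag1, mp$ref_name[i], mp$pos1[i], r1[f],
               mp$score1[i], n, FALSE)
      if (paired && !is.na(mp$pos2[i])) {
        flag2 <- 1L + 128L + (if (!is.na(o1) && o1 == 0L) 16L else 0L)
        addRec(mp$name[i], flag2, mp$ref_name[i], mp$pos2[i], r2[f],
               mp$score2[i], n, FALSE)
      }
    }
  }
  fr <- run$fragments
  dec <- which(fr$status == "DECOY")
  rn <- refNames(index@catalog)
  for (f in dec) {
    o1 <- fr$decoy_orientation1[f]
    if (!is.na(fr$decoy_pos1[f]))
      addRec(fr$name[f],
             (if (paired) 1L + 64L else 0L) + (if (!is.na(o1) && o1 == 1L) 16L else 0L),
             rn[fr$decoy_ref[f]], fr$decoy_pos1[f], r1[f],
             fr$best_decoy_score[f], 1L, TRUE)
    if (paired && !is.na(fr$decoy_pos2[f]))
      addRec(fr$name[f], 1L + 128L + (if (!is.na(o1) && o1 == 0L) 16L else 0L),
             rn[fr$decoy_ref[f]], fr$decoy_pos2[f], r2[f],
             fr$best_decoy_score[f], 1L, TRUE)
  }
  aln <- if (length(recs)) do.call(rbind, recs) else
    data.frame(qname = character(), flag = integer(), rname = character(),
               pos = integer(), mapq = integer(), cigar = character(),
               rnext = character(), pnext = integer(), tlen = integer(),
               seq = character(), qual = character(), tags = character(),
               decoy = logical())
  writeSam(refLengths(index@catalog), aln, path)
  invisible(path)
}
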