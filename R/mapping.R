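# Phases 1-3 of selective alignment, exposed per phase. All coordinates are
# 0-based half-open. Orientation is 0 (forward) or 1 (reverse complement);
# for reverse-complement anchor groups, read coordinates refer to positions
# on the reverse-complemented read so that co-linearity holds in both
# coordinates.

#' Collect uni-MEMs between a read and the index
#'
#' Maximal exact matches between the read and single unitigs: a k-mer hit is
#' extended until the end of the unitig, the end of the read, or a mismatch
#' terminates it; the search then resumes one position past the last
#' anchored k-mer start. Reads shorter than k yield an empty result with a
#' notice.
#'
#' @param read read sequence (character).
#' @param index a [UnitigIndex-class].
#' @return A data.frame with columns `read_start` (0-based), `length`,
#'   `unitig_id` (1-based), `unitig_offset` (0-based start of the matched
#'   unitig interval) and `orientation` (0 = read matches the unitig
#'   forward, 1 = reverse complement), in read order.
#' @export
collectUnimems <- function(read, index) {
  if (nchar(read) < index@k) {
    message("read shorter than k = ", index@k, "; no uni-MEMs")
    return(data.frame(read_start = integer(), length = integer(),
                      unitig_id = integer(), unitig_offset = integer(),
                      orientation = integer()))
  }
  as.data.frame(cpp_collect_unimems(read, indexAsList(index)))
}

#' Project uni-MEMs to reference anchors and collate by (reference, orientation)
#'
#' Each uni-MEM yields one anchor per occurrence of its unitig; the anchor
#' orientation is the uni-MEM orientation composed with the occurrence
#' orientation. For reverse-complement groups, `read_start` is reflected to
#' the reverse-complemented read's coordinates.
#'
#' @param unimems data.frame from [collectUnimems()].
#' @param readLen length of the read the uni-MEMs came from.
#' @param index a [UnitigIndex-class].
#' @return A data.frame with columns `ref` (1-based ordinal into the
#'   catalog), `orientation`, `read_start`, `ref_start`, `length`, grouped by
#'   (ref, orientation) and sorted within groups.
#' @export
projectAndCollate <- function(unimems, readLen, index) {
  as.data.frame(cpp_project_collate(
    as.integer(unimems$read_start), as.integer(unimems$length),
    as.integer(unimems$unitig_id), as.integer(unimems$unitig_offset),
    as.integer(unimems$orientation), as.integer(readLen),
    indexAsList(index)))
}

#' Pre-chaining hit filter
#'
#' Drops every (reference, orientation) group whose total anchor bases fall
#' below `tauPre` times the best group's. Disabled by default (identity).
#'
#' @param anchors collated anchor data.frame from [projectAndCollate()].
#' @param params a [ChainParams-class].
#' @return The filtered anchor data.frame.
#' @export
filterBeforeChaining <- function(anchors, params = chainParams()) {
  if (!params@preFilterEnabled || nrow(anchors) == 0L) return(anchors)
  grp <- paste(anchors$ref, anchors$orientation)
  tot <- tapply(anchors$length, grp, sum)
  keep <- names(tot)[tot >= params@tauPre * max(tot)]
  anchors[grp %in% keep, , drop = FALSE]
}

#' Compact exactly adjacent anchors
#'
#' Anchors of one (reference, orientation) group that are directly adjacent
#' on both the read and the reference (fragmentation from uni-MEM
#' termination at unitig ends) are merged; total matched bases are
#' conserved and the operation is idempotent.
#'
#' @param anchors data.frame with `read_start`, `ref_start`, `length` for a
#'   single (reference, orientation) group.
#' @return The compacted, sorted anchor data.frame.
#' @export
compactAnchors <- function(anchors) {
  as.data.frame(cpp_compact_anchors(as.integer(anchors$read_start),
                                    as.integer(anchors$ref_start),
                                    as.integer(anchors$length)))
}

#' Chain anchors with the co-linear chaining dynamic program
#'
#' Anchors are sorted by reference start; `f(i) = w_i + max(0, max_j f(j) -
#' cost(j, i))` over admissible predecessors `j` (strictly increasing read
#' and reference starts, gaps at most `maxAnchorGap`), where `w_i` is the
#' anchor length and `cost` combines the gap difference penalty
#' `gapLinearCoeff * d + gapLogCoeff * log2(d + 1)` with a one-per-base
#' penalty for overlapped spans. All chains achieving the maximum group
#' score are returned (capped at `maxChains`, deterministic order).
#'
#' @param anchors compacted anchor data.frame for one group.
#' @param params a [ChainParams-class].
#' @return A list with `score` (the optimal chaining score), `anchors` (the
#'   sorted anchor data.frame the chains index into) and `chains` (a list of
#'   integer index vectors, each a co-optimal chain).
#' @export
chainAnchors <- function(anchors, params = chainParams()) {
  if (nrow(anchors) == 0L)
    return(list(score = 0, anchors = anchors, chains = list()))
  res <- cpp_chain_anchors(as.integer(anchors$read_start),
                           as.integer(anchors$ref_start),
                           as.integer(anchors$length),
                           params@gapLinearCoeff, params@gapLogCoeff,
                           params@maxAnchorGap, params@maxChains)
  list(score = res$score,
       anchors = data.frame(read_start = res$read_start,
                            ref_start = res$ref_start,
                            length = res$length),
       chains = res$chains)
}

#' Post-chaining score filter
#'
#' Keeps chains whose score is at least `tauPost` times the best chain score
#' across all groups of the read end. Enabled by default. The best-scoring
#' chain is never removed.
#'
#' @param chains data.frame of chains with a `score` column (one row per
#'   chain, any grouping columns preserved).
#' @param params a [ChainParams-class].
#' @return The filtered data.frame.
#' @export
filterAfterChaining <- function(chains, params = chainParams()) {
  if (!params@postFilterEnabled || nrow(chains) == 0L) return(chains)
  chains[chains$score >= params@tauPost * max(chains$score), , drop = FALSE]
}

#' Map one read end: phases 1-3 combined
#'
#' Runs uni-MEM collection, projection/collation, the optional pre-chaining
#' filter, compaction, chaining and the post-chaining filter, returning every
#' surviving chain of the read end.
#'
#' @param read read sequence (character).
#' @param index a [UnitigIndex-class].
#' @param params a [ChainParams-class].
#' @return A list of chains; each has `ref` (1-based ordinal), `orientation`,
#'   `score`, `window_lo`/`window_hi` (predicted reference window of the full
#'   read) and `anchors` (data.frame in oriented-read coordinates).
#' @export
mapReadEnd <- function(read, index, params = chainParams()) {
  res <- cpp_map_read_end(read, indexAsList(index),
                          unname(index@catalog@seqs),
                          paramsAsList(chain = params))
  lapply(seq_along(res$ref), function(i)
    list(ref = res$ref[i], orientation = res$orientation[i],
         score = res$score[i], window_lo = res$window_lo[i],
         window_hi = res$window_hi[i],
         anchors = as.data.frame(res$anchors[[i]])))
}
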