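# Phase 4: merge the chains of the two read ends into fragment-level
# mapping candidates under orientation, insert-size, orphan and dovetail
# policies.

chainsAsColumns <- function(chains) {
  list(ref = vapply(chains, `[[`, integer(1), "ref"),
       orientation = vapply(chains, `[[`, integer(1), "orientation"),
       score = vapply(chains, `[[`, numeric(1), "score"),
       lo = vapply(chains, `[[`, integer(1), "window_lo"),
       hi = vapply(chains, `[[`, integer(1), "window_hi"))
}

#' Merge paired-end chains into fragment mappings
#'
#' For each reference, every (forward, reverse-complement) chain combination
#' is emitted that satisfies the pairing constraints: opposite orientations,
#' the leftmost position of the reverse-complement end at or right of the
#' leftmost position of the forward end (otherwise the pair is a dovetail),
#' and a fragment span of at most `maxFragmentLen`. Dovetails are included
#' only when allowed and always rank strictly below every non-dovetailed
#' mapping. When one end has no chains at all, the fragment is discarded
#' unless orphans are allowed (see [mergeOrphanOrSingle()]).
#'
#' @param leftChains,rightChains chain lists from [mapReadEnd()] for the two
#'   read ends.
#' @param policy a [PairingPolicy-class].
#' @return A data.frame with one row per fragment mapping: `ref`, `chain1`,
#'   `chain2` (indices into the input chain lists), `dovetail`,
#'   `pair_chain_score`, `fragment_start`, `fragment_end`; ordered
#'   non-dovetail first, then by descending pair score, reference ordinal
#'   and position.
#' @export
mergePairs <- function(leftChains, rightChains, policy = pairingPolicy()) {
  empty <- data.frame(ref = integer(), chain1 = integer(),
                      chain2 = integer(), dovetail = logical(),
                      pair_chain_score = numeric(),
                      fragment_start = integer(), fragment_end = integer())
  if (length(leftChains) == 0L || length(rightChains) == 0L) {
    if (!policy@allowOrphans) return(empty)
    return(mergeOrphanOrSingle2(leftChains, rightChains, policy))
  }
  a <- chainsAsColumns(leftChains)
  b <- chainsAsColumns(rightChains)
  res <- cpp_merge_pairs(a$ref, a$orientation, a$score, a$lo, a$hi,
                         b$ref, b$orientation, b$score, b$lo, b$hi,
                         policy@maxFragmentLen, policy@allowDovetails)
  as.data.frame(res)
}

# orphan emission for both ends, used by mergePairs when one side is empty
mergeOrphanOrSingle2 <- function(leftChains, rightChains, policy) {
  rbind(mergeOrphanOrSingle(leftChains, policy, end = 1L),
        mergeOrphanOrSingle(rightChains, policy, end = 2L))
}

#' Mappings from a single read end (single-end library or permitted orphan)
#'
#' One fragment mapping per surviving chain; never dovetailed. For a paired
#' fragment with only one mapped end this yields an empty result unless the
#' policy allows orphans.
#'
#' @param chains chain list from [mapReadEnd()].
#' @param policy a [PairingPolicy-class].
#' @param end which read end the chains belong to (1 or 2); recorded in the
#'   `chain1`/`chain2` columns.
#' @param singleEnd set to `TRUE` for a single-end library, where the orphan
#'   policy does not apply.
#' @return A data.frame with the same columns as [mergePairs()].
#' @export
mergeOrphanOrSingle <- function(chains, policy = pairingPolicy(), end = 1L,
                                singleEnd = FALSE) {
  empty <- data.frame(ref = integer(), chain1 = integer(),
                      chain2 = integer(), dovetail = logical(),
                      pair_chain_score = numeric(),
                      fragment_start = integer(), fragment_end = integer())
  if (length(chains) == 0L) return(empty)
  if (!singleEnd && !policy@allowOrphans) return(empty)
  cc <- chainsAsColumns(chains)
  out <- data.frame(
    ref = cc$ref,
    chain1 = if (end == 1L) seq_along(chains) else NA_integer_,
    chain2 = if (end == 2L) seq_along(chains) else NA_integer_,
    dovetail = FALSE,
    pair_chain_score = cc$score,
    fragment_start = cc$lo,
    fragment_end = cc$hi)
  out[order(-out$pair_chain_score, out$ref, out$fragment_start), ,
      drop = FALSE]
}
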