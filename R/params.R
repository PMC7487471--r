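# Parameter classes. Defaults mirror the configuration under which the method
# is normally run: k = 23 with duplicate transcripts kept, pre-chaining filter
# disabled at tau = 0.65, post-chaining filter enabled at tau' = 0.65, minimum
# valid alignment score 0.65 of the maximum obtainable, insert size bound
# 1000, orphan and dovetail mappings disallowed, decoy segments of 500 bp at
# 80% minimum identity, 4 range-factorization bins.

#' Index construction parameters
#'
#' @slot k k-mer length used for the unitig index (default 23).
#' @slot keepDuplicates if `TRUE` (default), transcripts with identical
#'   sequence are all retained in the reference catalog; otherwise one
#'   representative per identical-sequence group is kept.
#' @export
setClass("IndexConfig",
  representation(k = "integer", keepDuplicates = "logical"),
  prototype(k = 23L, keepDuplicates = TRUE))

setValidity("IndexConfig", function(object) {
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L ||
      object@k > 31L)
    return("k must be a single integer in [1, 31]")
  if (length(object@keepDuplicates) != 1L || is.na(object@keepDuplicates))
    return("keepDuplicates must be TRUE or FALSE")
  TRUE
})

#' @param k k-mer length.
#' @param keepDuplicates keep duplicate transcript sequences?
#' @return An `IndexConfig` object.
#' @rdname IndexConfig-class
#' @export
indexConfig <- function(k = 23L, keepDuplicates = TRUE) {
  new("IndexConfig", k = as.integer(k), keepDuplicates = keepDuplicates)
}

#' Anchor chaining parameters
#'
#' Controls phases 2-3 of selective alignment: the optional pre-chaining hit
#' filter (a transcript/orientation group is dropped when its total anchor
#' bases fall below `tauPre` times the best group's), the chaining dynamic
#' program's gap cost `gapLinearCoeff * d + gapLogCoeff * log2(d + 1)` where
#' `d` is the difference between read gap and reference gap, and the
#' post-chaining filter that drops chains scoring below `tauPost` times the
#' best chain score for the read end.
#'
#' @slot tauPre fraction for the pre-chaining filter (default 0.65).
#' @slot preFilterEnabled whether the pre-chaining filter runs (default FALSE).
#' @slot tauPost fraction for the post-chaining filter (default 0.65).
#' @slot postFilterEnabled whether the post-chaining filter runs (default TRUE).
#' @slot gapLinearCoeff linear gap cost per base (default 0.01 * k = 0.23).
#' @slot gapLogCoeff logarithmic gap cost coefficient (default 0.5).
#' @slot maxAnchorGap largest read/reference gap joinable by a chain (bases).
#' @slot maxChains cap on co-optimal chains propagated per read end.
#' @export
setClass("ChainParams",
  representation(tauPre = "numeric", preFilterEnabled = "logical",
                 tauPost = "numeric", postFilterEnabled = "logical",
                 gapLinearCoeff = "numeric", gapLogCoeff = "numeric",
                 maxAnchorGap = "integer", maxChains = "integer"),
  prototype(tauPre = 0.65, preFilterEnabled = FALSE,
            tauPost = 0.65, postFilterEnabled = TRUE,
            gapLinearCoeff = 0.23, gapLogCoeff = 0.5,
            maxAnchorGap = 1000L, maxChains = 200L))

setValidity("ChainParams", function(object) {
  if (object@tauPre <= 0 || object@tauPre > 1) return("tauPre must be in (0, 1]")
  if (object@tauPost <= 0 || object@tauPost > 1) return("tauPost must be in (0, 1]")
  if (object@maxAnchorGap < 1L) return("maxAnchorGap must be positive")
  if (object@maxChains < 1L) return("maxChains must be positive")
  TRUE
})

#' @param tauPre,preFilterEnabled,tauPost,postFilterEnabled,gapLinearCoeff,gapLogCoeff,maxAnchorGap,maxChains
#'   see the corresponding slots.
#' @return A `ChainParams` object.
#' @rdname ChainParams-class
#' @export
chainParams <- function(tauPre = 0.65, preFilterEnabled = FALSE,
                        tauPost = 0.65, postFilterEnabled = TRUE,
                        gapLinearCoeff = 0.23, gapLogCoeff = 0.5,
                        maxAnchorGap = 1000L, maxChains = 200L) {
  new("ChainParams", tauPre = tauPre, preFilterEnabled = preFilterEnabled,
      tauPost = tauPost, postFilterEnabled = postFilterEnabled,
      gapLinearCoeff = gapLinearCoeff, gapLogCoeff = gapLogCoeff,
      maxAnchorGap = as.integer(maxAnchorGap),
      maxChains = as.integer(maxChains))
}

#' Paired-end merging policy
#'
#' @slot maxFragmentLen maximum allowed fragment span on the reference
#'   (default 1000, matching the usual insert-size bound).
#' @slot allowOrphans emit mappings for fragments with only one mapped end
#'   (default FALSE; the fragment is discarded).
#' @slot allowDovetails allow pairs whose reverse-complement end starts
#'   upstream of the forward end (default FALSE). When allowed, dovetailed
#'   mappings rank strictly below every non-dovetailed mapping.
#' @export
setClass("PairingPolicy",
  representation(maxFragmentLen = "integer", allowOrphans = "logical",
                 allowDovetails = "logical"),
  prototype(maxFragmentLen = 1000L, allowOrphans = FALSE,
            allowDovetails = FALSE))

setValidity("PairingPolicy", function(object) {
  if (object@maxFragmentLen < 1L) return("maxFragmentLen must be positive")
  TRUE
})

#' @param maxFragmentLen,allowOrphans,allowDovetails see the slots.
#' @return A `PairingPolicy` object.
#' @rdname PairingPolicy-class
#' @export
pairingPolicy <- function(maxFragmentLen = 1000L, allowOrphans = FALSE,
                          allowDovetails = FALSE) {
  new("PairingPolicy", maxFragmentLen = as.integer(maxFragmentLen),
      allowOrphans = allowOrphans, allowDovetails = allowDovetails)
}

#' Extension alignment scoring parameters
#'
#' Score-only affine-gap alignment of each read end around its chain anchors.
#' A gap of length L costs `gapOpen + gapExtend * L`. The maximum obtainable
#' score for a fragment is `match` times its total base count; mappings
#' scoring below `minScoreFraction` of that maximum are discarded.
#'
#' @slot match per-base match score (default 2).
#' @slot mismatch per-base mismatch score (default -4).
#' @slot gapOpen gap opening cost, positive (default 5).
#' @slot gapExtend per-base gap extension cost, positive (default 3).
#' @slot minScoreFraction minimum valid score as a fraction of the maximum
#'   obtainable alignment score (default 0.65).
#' @slot bandPad extra reference bases allowed around read flanks in the
#'   extension DP (default 8).
#' @export
setClass("AlignParams",
  representation(match = "numeric", mismatch = "numeric", gapOpen = "numeric",
                 gapExtend = "numeric", minScoreFraction = "numeric",
                 bandPad = "integer"),
  prototype(match = 2, mismatch = -4, gapOpen = 5, gapExtend = 3,
            minScoreFraction = 0.65, bandPad = 8L))

setValidity("AlignParams", function(object) {
  if (object@match <= 0) return("match must be positive")
  if (object@mismatch > 0) return("mismatch must be <= 0")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    return("gap costs must be non-negative")
  if (object@minScoreFraction <= 0 || object@minScoreFraction > 1)
    return("minScoreFraction must be in (0, 1]")
  TRUE
})

#' @param match,mismatch,gapOpen,gapExtend,minScoreFraction,bandPad see slots.
#' @return An `AlignParams` object.
#' @rdname AlignParams-class
#' @export
alignParams <- function(match = 2, mismatch = -4, gapOpen = 5, gapExtend = 3,
                        minScoreFraction = 0.65, bandPad = 8L) {
  new("AlignParams", match = match, mismatch = mismatch, gapOpen = gapOpen,
      gapExtend = gapExtend, minScoreFraction = minScoreFraction,
      bandPad = as.integer(bandPad))
}

#' Decoy extraction parameters
#'
#' @slot segmentSize transcript segment size in bases (default 500).
#' @slot minIdentity minimum estimated identity for a reported segment hit
#'   (default 0.80).
#' @slot sketchK k-mer size of the minimizer sketch (default 16).
#' @slot minimizerWindow minimizer window length in k-mers (default 10).
#' @slot sketchSize number of smallest minimizer hashes kept per segment;
#'   0 (the default) keeps the full winnowed minimizer set.
#' @slot extractionPad bases of flanking genome added to each merged hit
#'   interval before extraction (default half a segment): a hit locates
#'   similar sequence only at segment resolution, so flanks narrower than
#'   half a segment may belong to the similar locus without being
#'   detectable as their own hit.
#' @export
setClass("DecoyConfig",
  representation(segmentSize = "integer", minIdentity = "numeric",
                 sketchK = "integer", minimizerWindow = "integer",
                 sketchSize = "integer", extractionPad = "integer"),
  prototype(segmentSize = 500L, minIdentity = 0.80, sketchK = 16L,
            minimizerWindow = 10L, sketchSize = 0L, extractionPad = 250L))

setValidity("DecoyConfig", function(object) {
  if (object@minIdentity <= 0 || object@minIdentity > 1)
    return("minIdentity must be in (0, 1]")
  if (object@segmentSize < object@sketchK)
    return("segmentSize must be at least sketchK")
  if (object@extractionPad < 0L) return("extractionPad must be >= 0")
  TRUE
})

#' @param segmentSize,minIdentity,sketchK,minimizerWindow,sketchSize,extractionPad
#'   see the slots.
#' @return A `DecoyConfig` object.
#' @rdname DecoyConfig-class
#' @export
decoyConfig <- function(segmentSize = 500L, minIdentity = 0.80, sketchK = 16L,
                        minimizerWindow = 10L, sketchSize = 0L,
                        extractionPad = segmentSize %/% 2L) {
  new("DecoyConfig", segmentSize = as.integer(segmentSize),
      minIdentity = minIdentity, sketchK = as.integer(sketchK),
      minimizerWindow = as.integer(minimizerWindow),
      sketchSize = as.integer(sketchSize),
      extractionPad = as.integer(extractionPad))
}

#' Quantification parameters
#'
#' @slot rangeFactorizationBins number of equal-width bins used to quantize
#'   conditional weights when forming range-factorized equivalence classes
#'   (default 4; 1 disables factorization).
#' @slot maxIters EM iteration cap (default 10000).
#' @slot relTol relative-change convergence tolerance (default 1e-8).
#' @export
setClass("QuantConfig",
  representation(rangeFactorizationBins = "integer", maxIters = "integer",
                 relTol = "numeric"),
  prototype(rangeFactorizationBins = 4L, maxIters = 10000L, relTol = 1e-8))

setValidity("QuantConfig", function(object) {
  if (object@rangeFactorizationBins < 1L) return("bins must be >= 1")
  if (object@maxIters < 1L) return("maxIters must be >= 1")
  if (object@relTol <= 0) return("relTol must be positive")
  TRUE
})

#' @param rangeFactorizationBins,maxIters,relTol see the slots.
#' @return A `QuantConfig` object.
#' @rdname QuantConfig-class
#' @export
quantConfig <- function(rangeFactorizationBins = 4L, maxIters = 10000L,
                        relTol = 1e-8) {
  new("QuantConfig",
      rangeFactorizationBins = as.integer(rangeFactorizationBins),
      maxIters = as.integer(maxIters), relTol = relTol)
}

# flatten parameter objects into the list consumed by the C++ runner
paramsAsList <- function(chain = chainParams(), pairing = pairingPolicy(),
                         aln = alignParams(), useCache = TRUE) {
  list(
    gap_linear_coeff = chain@gapLinearCoeff,
    gap_log_coeff = chain@gapLogCoeff,
    max_anchor_gap = chain@maxAnchorGap,
    max_chains = chain@maxChains,
    tau_pre = chain@tauPre,
    pre_filter_enabled = chain@preFilterEnabled,
    tau_post = chain@tauPost,
    post_filter_enabled = chain@postFilterEnabled,
    match = aln@match,
    mismatch = aln@mismatch,
    gap_open = aln@gapOpen,
    gap_extend = aln@gapExtend,
    band_pad = aln@bandPad,
    min_score_fraction = aln@minScoreFraction,
    max_fragment_len = pairing@maxFragmentLen,
    allow_orphans = pairing@allowOrphans,
    allow_dovetails = pairing@allowDovetails,
    use_cache = useCache)
}
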