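# Reduction of aligned fragments to (range-factorized) equivalence classes
# and abundance estimation with a plain EM.

#' Equivalence class table
#'
#' Sufficient statistics for quantification: fragments grouped by the set of
#' transcripts they align to and, with range factorization, by the quantized
#' pattern of their conditional assignment weights.
#'
#' @slot labels list of sorted integer vectors (1-based transcript ordinals).
#' @slot weights list of numeric vectors parallel to `labels`, each
#'   non-negative and summing to 1.
#' @slot counts numeric vector of fragment counts per class.
#' @slot nTranscripts number of quantified transcripts.
#' @export
setClass("EquivalenceClassTable",
  representation(labels = "list", weights = "list", counts = "numeric",
                 nTranscripts = "integer"))

setValidity("EquivalenceClassTable", function(object) {
  if (length(object@labels) != length(object@weights) ||
      length(object@labels) != length(object@counts))
    return("labels, weights and counts must have equal length")
  for (i in seq_along(object@labels)) {
    l <- object@labels[[i]]
    w <- object@weights[[i]]
    if (length(l) != length(w)) return("label/weight length mismatch")
    if (is.unsorted(l, strictly = TRUE)) return("labels must be sorted, unique")
    if (any(w < 0) || abs(sum(w) - 1) > 1e-6)
      return("weights must be non-negative and sum to 1")
  }
  if (any(object@counts < 1)) return("class counts must be >= 1")
  TRUE
})

setMethod("show", "EquivalenceClassTable", function(object) {
  cat("EquivalenceClassTable:", length(object@counts), "classes,",
      sum(object@counts), "fragments,", object@nTranscripts,
      "transcripts\n")
})

#' Build (range-factorized) equivalence classes from an alignment run
#'
#' Per fragment, the conditional weight of each surviving mapping is the
#' softmax of its alignment score (temperature `1/match`, so equal-best
#' mappings share weight equally and worse mappings decay with score
#' difference); weights of mappings to the same transcript are summed.
#' Fragments are grouped by transcript label set and, when
#' `rangeFactorizationBins > 1`, by the per-transcript pattern of weights
#' quantized into that many equal bins of the unit interval. Class weights are the
#' means of member fragments' weights, renormalized.
#'
#' @param run an `saRun` from [runSelectiveAlignment()] (only `ALIGNED`
#'   fragments contribute).
#' @param config a [QuantConfig-class].
#' @param match the match score used by the run (sets the softmax
#'   temperature).
#' @return An [EquivalenceClassTable-class].
#' @export
buildEqClasses <- function(run, config = quantConfig(), match = 2) {
  mp <- run$mappings
  bins <- config@rangeFactorizationBins
  classes <- new.env(parent = emptyenv())
  if (nrow(mp) > 0) {
    ord <- order(mp$fragment, mp$ref)
    mp <- mp[ord, , drop = FALSE]
    split_idx <- split(seq_len(nrow(mp)), mp$fragment)
    for (idx in split_idx) {
      refs <- mp$ref[idx]
      sc <- mp$score[idx]
      w <- exp((sc - max(sc)) * match)
      # sum weights of multiple mappings to one transcript
      agg <- rowsum(w, refs)
      label <- as.integer(rownames(agg))
      w <- as.numeric(agg) / sum(agg)
      o <- order(label)
      label <- label[o]; w <- w[o]
      binPat <- if (bins > 1L) pmin(floor(w * bins), bins - 1L) else
        rep(0L, length(w))
      key <- paste(paste(label, collapse = ","),
                   paste(binPat, collapse = ","), sep = "|")
      cur <- get0(key, envir = classes, inherits = FALSE)
      if (is.null(cur))
        assign(key, list(label = label, wsum = w, n = 1L), envir = classes)
      else
        assign(key, list(label = label, wsum = cur$wsum + w,
                         n = cur$n + 1L), envir = classes)
    }
  }
  keys <- sort(ls(classes))
  labels <- vector("list", length(keys))
  weights <- vector("list", length(keys))
  counts <- numeric(length(keys))
  for (i in seq_along(keys)) {
    cl <- get(keys[i], envir = classes)
    labels[[i]] <- cl$label
    weights[[i]] <- cl$wsum / sum(cl$wsum)
    counts[i] <- cl$n
  }
  new("EquivalenceClassTable", labels = labels, weights = weights,
      counts = counts,
      nTranscripts = if (length(labels)) max(unlist(labels)) else 0L)
}

#' Effective transcript lengths
#'
#' `efflen = max(1, length - meanFragLen + 1)`: the number of distinct
#' fragment start positions a transcript offers.
#'
#' @param lengths named integer vector of transcript lengths.
#' @param meanFragLen mean fragment length of the library.
#' @return Named numeric vector of effective lengths.
#' @export
effectiveLengths <- function(lengths, meanFragLen) {
  if (meanFragLen <= 0) {
    warning("non-positive mean fragment length; using raw lengths")
    return(pmax(1, as.numeric(lengths)))
  }
  setNames(pmax(1, as.numeric(lengths) - meanFragLen + 1), names(lengths))
}

#' EM abundance estimation over equivalence classes
#'
#' Standard EM on the class-level likelihood: the E-step allocates each
#' class count across its transcripts proportionally to
#' `weight * abundance / efflen`; the M-step renormalizes. Initialization is
#' uniform; iteration stops when the largest relative change in estimated
#' counts falls below `relTol` or at `maxIters`. The class log-likelihood is
#' non-decreasing across iterations and total counts are conserved exactly.
#'
#' @param eqc an [EquivalenceClassTable-class].
#' @param effLens named numeric vector of effective lengths for all
#'   quantified transcripts (names define the output order; ordinals in
#'   `eqc` index into this vector).
#' @param config a [QuantConfig-class].
#' @return A data.frame (`AbundanceEstimate`): `Name`, `Length` (the
#'   supplied effective-length basis is not echoed; see [quantify()] for the
#'   full table), `EffectiveLength`, `NumReads`, `TPM`, plus attribute
#'   `logLik` (trajectory of the class log-likelihood).
#' @export
emQuantify <- function(eqc, effLens, config = quantConfig()) {
  nTx <- length(effLens)
  if (eqc@nTranscripts > nTx)
    stop("equivalence classes reference transcripts beyond effLens")
  nm <- names(effLens)
  if (length(eqc@counts) == 0L) {
    warning("no equivalence classes; returning all-zero estimate")
    out <- data.frame(Name = nm, EffectiveLength = as.numeric(effLens),
                      NumReads = 0, TPM = 0)
    attr(out, "logLik") <- numeric(0)
    return(out)
  }
  # sparse class-by-transcript weight matrix
  ci <- rep(seq_along(eqc@labels), lengths(eqc@labels))
  ti <- unlist(eqc@labels)
  wv <- unlist(eqc@weights)
  W <- Matrix::sparseMatrix(i = ci, j = ti, x = wv,
                            dims = c(length(eqc@counts), nTx))
  cnt <- eqc@counts
  total <- sum(cnt)
  alpha <- rep(total / nTx, nTx)
  ll <- numeric(0)
  el <- as.numeric(effLens)
  for (iter in seq_len(config@maxIters)) {
    eta <- alpha / el
    A <- W %*% Matrix::Diagonal(x = eta)       # class x tx allocation weights
    rs <- Matrix::rowSums(A)
    ll <- c(ll, sum(cnt * log(rs)))
    alloc <- Matrix::crossprod(A / rs, cnt)    # E-step totals per transcript
    newAlpha <- as.numeric(alloc)
    delta <- max(abs(newAlpha - alpha) / pmax(alpha, 1e-8))
    alpha <- newAlpha
    if (delta < config@relTol) break
  }
  tpmRaw <- alpha / el
  tpm <- tpmRaw / sum(tpmRaw) * 1e6
  out <- data.frame(Name = nm, EffectiveLength = el, NumReads = alpha,
                    TPM = tpm)
  attr(out, "logLik") <- ll
  out
}

#' Quantify a read set against an index
#'
#' Convenience pipeline: selective alignment, equivalence-class reduction
#' and EM estimation, returning a quant.sf-style table over the non-decoy
#' catalog entries.
#'
#' @inheritParams runSelectiveAlignment
#' @param quant a [QuantConfig-class].
#' @param meanFragLen assumed mean fragment length for effective lengths
#'   (default 250).
#' @return A list with `abundance` (data.frame: `Name`, `Length`,
#'   `EffectiveLength`, `TPM`, `NumReads`), `eqClasses`, `run` and
#'   `metadata`.
#' @export
quantify <- function(reads1, reads2 = NULL, index,
                     chain = chainParams(), pairing = pairingPolicy(),
                     aln = alignParams(), quant = quantConfig(),
                     meanFragLen = 250, useCache = TRUE) {
  run <- runSelectiveAlignment(reads1, reads2, index, chain = chain,
                               pairing = pairing, aln = aln,
                               useCache = useCache)
  eqc <- buildEqClasses(run, config = quant, match = aln@match)
  txNames <- refNames(index@catalog)[!index@catalog@isDecoy]
  txLens <- refLengths(index@catalog)[!index@catalog@isDecoy]
  el <- effectiveLengths(txLens, meanFragLen)
  ab <- emQuantify(eqc, el, config = quant)
  abundance <- data.frame(Name = txNames, Length = as.integer(txLens),
                          EffectiveLength = ab$EffectiveLength,
                          TPM = ab$TPM, NumReads = ab$NumReads)
  list(abundance = abundance, eqClasses = eqc, run = run,
       metadata = c(run$metadata, list(mean_frag_len = meanFragLen)))
}

#' Write a quant.sf-style abundance table
#'
#' @param abundance the `abundance` data.frame from [quantify()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQuantSf <- function(abundance, path) {
  write.table(abundance[, c("Name", "Length", "EffectiveLength", "TPM",
                            "NumReads")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an equivalence-class dump
#'
#' One line per class: count, number of transcripts, transcript ordinals and
#' weights.
#'
#' @param eqc an [EquivalenceClassTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEqClasses <- function(eqc, path) {
  lines <- vapply(seq_along(eqc@counts), function(i)
    paste(c(eqc@counts[i], length(eqc@labels[[i]]), eqc@labels[[i]],
            signif(eqc@weights[[i]], 8)), collapse = "\t"), character(1))
  writeLines(c(paste(eqc@nTranscripts, length(eqc@counts), sep = "\t"),
               lines), path)
  invisible(path)
}
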