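# Shared fixtures and independent oracles for the test suite.
# Oracles never call the code paths they check: chaining is verified against
# exhaustive chain enumeration, extension scores against
# Biostrings::pairwiseAlignment, index lookups against naive substring scans.

rcStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

randomSeqStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---------------------------------------------------------------------------
# chaining oracle: exhaustive DFS over all admissible co-linear anchor chains
# ---------------------------------------------------------------------------

chainTransitionCost <- function(aj, ai, params) {
  # aj, ai: lists/rows with read_start, ref_start, length
  if (ai$read_start <= aj$read_start || ai$ref_start <= aj$ref_start)
    return(NULL)
  dr <- ai$read_start - (aj$read_start + aj$length)
  dg <- ai$ref_start - (aj$ref_start + aj$length)
  if (dr > params@maxAnchorGap || dg > params@maxAnchorGap) return(NULL)
  d <- abs(dr - dg)
  cost <- if (d > 0)
    params@gapLinearCoeff * d + params@gapLogCoeff * log2(d + 1) else 0
  cost + max(0, -dr, -dg)
}

# maximum chain score over every admissible ordered subset of anchors
bruteForceChainScore <- function(anchors, params = chainParams()) {
  n <- nrow(anchors)
  if (n == 0) return(0)
  rows <- lapply(seq_len(n), function(i) as.list(anchors[i, ]))
  best <- 0
  extend <- function(i, score) {
    best <<- max(best, score)
    for (j in seq_len(n)) {
      cost <- chainTransitionCost(rows[[i]], rows[[j]], params)
      if (!is.null(cost)) extend(j, score + rows[[j]]$length - cost)
    }
  }
  for (i in seq_len(n)) extend(i, rows[[i]]$length)
  best
}

randomAnchorInstance <- function(nAnchors, readLen = 150, refLen = 400) {
  data.frame(
    read_start = sample.int(readLen - 15, nAnchors, replace = TRUE) - 1L,
    ref_start = sample.int(refLen - 15, nAnchors, replace = TRUE) - 1L,
    length = sample(5:15, nAnchors, replace = TRUE))
}

# ---------------------------------------------------------------------------
# alignment oracle: full fitting alignment (read global, reference local)
# ---------------------------------------------------------------------------

fittingAlignmentScore <- function(read, refSeq, params = alignParams()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params@match, mismatch = params@mismatch)
  Biostrings::pairwiseAlignment(
    pattern = read, subject = refSeq, type = "global-local",
    substitutionMatrix = mat, gapOpening = params@gapOpen,
    gapExtension = params@gapExtend, scoreOnly = TRUE)
}

# Build a read from a reference window by applying an edit script, returning
# the read together with its true exact-match anchors (maximal match runs of
# at least minAnchor bases, in absolute reference coordinates).
editedReadInstance <- function(refSeq, winStart, winLen, nEdits,
                               minAnchor = 23L) {
  ref <- substr(refSeq, winStart + 1L, winStart + winLen)
  edits <- sort(sample.int(winLen - 10L, nEdits))
  # keep edits at least 3 bases apart so ops do not collide
  if (length(edits) > 1) edits <- edits[c(TRUE, diff(edits) >= 3)]
  readParts <- character(0)
  anchors <- list()
  rp <- 0L  # read cursor
  gp <- 0L  # window cursor
  flushRun <- function(runLen) {
    if (runLen > 0) {
      readParts[[length(readParts) + 1L]] <<-
        substr(ref, gp + 1L, gp + runLen)
      if (runLen >= minAnchor)
        anchors[[length(anchors) + 1L]] <<- data.frame(
          read_start = rp, ref_start = winStart + gp, length = runLen)
      rp <<- rp + runLen
      gp <<- gp + runLen
    }
  }
  for (e in edits) {
    flushRun(e - gp)
    if (gp >= winLen - 2L) break
    op <- sample(c("sub", "ins", "del"), 1)
    if (op == "sub") {
      base <- substr(ref, gp + 1L, gp + 1L)
      readParts[[length(readParts) + 1L]] <-
        sample(setdiff(c("A", "C", "G", "T"), base), 1)
      rp <- rp + 1L
      gp <- gp + 1L
    } else if (op == "ins") {
      len <- sample(1:2, 1)
      readParts[[length(readParts) + 1L]] <- randomSeqStr(len)
      rp <- rp + len
    } else {
      gp <- gp + sample(1:2, 1)
    }
  }
  flushRun(winLen - gp)
  list(read = paste(readParts, collapse = ""),
       anchors = do.call(rbind, anchors))
}

# ---------------------------------------------------------------------------
# index oracle: naive substring occurrence scan
# ---------------------------------------------------------------------------

naiveKmerOccurrences <- function(kmer, seqs) {
  out <- list()
  krc <- rcStr(kmer)
  for (r in seq_along(seqs)) {
    s <- seqs[[r]]
    L <- nchar(s)
    k <- nchar(kmer)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    subs <- substring(s, starts, starts + k - 1L)
    for (p in starts[subs == kmer])
      out[[length(out) + 1L]] <- data.frame(ref = r, pos = p - 1L,
                                            strand = 0L)
    if (krc != kmer)
      for (p in starts[subs == krc])
        out[[length(out) + 1L]] <- data.frame(ref = r, pos = p - 1L,
                                              strand = 1L)
  }
  if (length(out) == 0)
    return(data.frame(ref = integer(), pos = integer(), strand = integer()))
  res <- do.call(rbind, out)
  res[order(res$ref, res$pos, res$strand), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# SAM / CIGAR+MD generator with known per-base events
# ---------------------------------------------------------------------------

# Random alignment of a read against a reference window; returns the CIGAR,
# MD and the true event vector as parseCigarMd should report it. MD emits a
# (possibly zero) match count before every feature and at the end, as
# samtools calmd does.
randomCigarMdInstance <- function(readLen = 60) {
  events <- character(0)
  cig <- character(0)
  md <- character(0)
  mdRun <- 0L
  pushRun <- function() {
    md[[length(md) + 1L]] <<- as.character(mdRun)
    mdRun <<- 0L
  }
  left <- readLen
  sc1 <- sample(0:5, 1)
  if (sc1 > 0) {
    cig <- c(cig, paste0(sc1, "S"))
    events <- c(events, rep("SOFTCLIP", sc1))
    left <- left - sc1
  }
  while (left > 3) {
    op <- sample(c("M", "X", "I", "D"), 1,
                 prob = c(0.7, 0.1, 0.1, 0.1))
    if (op == "M") {
      n <- sample(1:min(20, left), 1)
      cig <- c(cig, paste0(n, "M"))
      events <- c(events, rep("MATCH", n))
      mdRun <- mdRun + n
      left <- left - n
    } else if (op == "X") {
      cig <- c(cig, "1M")
      events <- c(events, "MISMATCH")
      pushRun()
      md <- c(md, sample(c("A", "C", "G", "T"), 1))
      left <- left - 1L
    } else if (op == "I") {
      n <- sample(1:3, 1)
      cig <- c(cig, paste0(n, "I"))
      events <- c(events, rep("INSERTION", n))
      left <- left - n
    } else {
      n <- sample(1:3, 1)
      cig <- c(cig, paste0(n, "D"))
      events <- c(events, rep("DELETION", n))
      pushRun()
      md <- c(md, paste0("^", randomSeqStr(n)))
    }
  }
  if (left > 0) {
    cig <- c(cig, paste0(left, "M"))
    events <- c(events, rep("MATCH", left))
    mdRun <- mdRun + left
  }
  pushRun()
  list(cigar = paste(cig, collapse = ""), md = paste(md, collapse = ""),
       events = events)
}

# minimal SAM alignment row
samRow <- function(qname, flag, rname, pos, cigar, seq = "*", md = NULL,
                   mapq = 60L) {
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = mapq, cigar = cigar,
             rnext = "*", pnext = 0L, tlen = 0L, seq = seq, qual = "*",
             tags = if (is.null(md)) "" else paste0("MD:Z:", md))
}

# small shared simulated experiment (cached per test session)
tinyExperiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateExperiment(simConfig(seed = 301, nGenes = 15,
                                             nFragments = 300))
    cache
  }
})
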