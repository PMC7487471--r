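# Oracle alignment curation: compare transcriptomic alignments from one
# aligner against genomic alignments from another by matched-base score and
# remove fragments whose genomic alignment is strictly better. Also the
# indel-ratio analysis of variant transcriptomes.

#' Matched-base score of a SAM record
#'
#' Every matched base scores 1; soft clips, mismatches, insertions and
#' deletions score 0. Intron skips (`N`) consume reference only and are
#' neither penalized nor rewarded.
#'
#' @param cigar CIGAR string of a mapped record.
#' @param md its MD tag (may be `NA`/`NULL` when the record has no
#'   mismatches to distinguish).
#' @return Integer matched-base count.
#' @export
mdMatchScore <- function(cigar, md = NULL) {
  sum(parseCigarMd(cigar, md) == "MATCH")
}

# fragment id = qname; per-end best matched-base score, summed over ends.
# Ends are distinguished by the first/second-of-pair flag bits; unmapped
# records contribute 0. Secondary/supplementary records participate in the
# per-end maximum.
fragmentScores <- function(alignments) {
  if (nrow(alignments) == 0L)
    return(numeric(0))
  mapped <- bitwAnd(alignments$flag, 4L) == 0L
  aln <- alignments[mapped, , drop = FALSE]
  if (nrow(aln) == 0L) return(numeric(0))
  md <- samTag(aln, "MD")
  sc <- vapply(seq_len(nrow(aln)), function(i)
    mdMatchScore(aln$cigar[i], md[i]), numeric(1))
  end <- ifelse(bitwAnd(aln$flag, 128L) > 0L, 2L, 1L)
  key <- paste(aln$qname, end)
  perEnd <- tapply(sc, key, max)
  qn <- sub(" [12]$", "", names(perEnd))
  tapply(as.numeric(perEnd), qn, sum)
}

mappedFragments <- function(alignments) {
  if (nrow(alignments) == 0L) return(character(0))
  unique(alignments$qname[bitwAnd(alignments$flag, 4L) == 0L])
}

#' Select candidate fragments for oracle filtering
#'
#' Candidates are exactly the fragments mapped to the transcriptome by the
#' first aligner and to the genome by the second, but which the second
#' aligner did not project to the transcriptome.
#'
#' @param bt2Txome,starTxome,starGenome `alignments` data.frames (from
#'   [readSam()]): transcriptomic alignments of the first aligner,
#'   transcriptome-projected and genomic alignments of the second.
#' @return Character vector of candidate fragment ids.
#' @export
selectCandidates <- function(bt2Txome, starTxome, starGenome) {
  inBt2 <- mappedFragments(bt2Txome)
  inStarTx <- mappedFragments(starTxome)
  inStarG <- mappedFragments(starGenome)
  setdiff(intersect(inBt2, inStarG), inStarTx)
}

#' Filter spurious transcriptomic alignments using a genomic aligner
#'
#' For each candidate fragment (see [selectCandidates()]), the best
#' matched-base score of its transcriptomic records and of its genomic
#' records are compared; if the genomic score is strictly greater the
#' fragment's records are removed, otherwise (equal or higher transcriptomic
#' quality) they are retained. Non-candidate fragments pass through
#' untouched.
#'
#' @inheritParams selectCandidates
#' @return A list with `alignments` (the filtered transcriptomic
#'   data.frame) and `decisions` (data.frame: `fragment`,
#'   `best_txome_score`, `best_genome_score`, `verdict` in
#'   `RETAIN`/`REMOVE`/`NOT_CANDIDATE`).
#' @export
oracleFilter <- function(bt2Txome, starTxome, starGenome) {
  dupCheck <- function(aln, what) {
    if (nrow(aln) == 0L) return(invisible())
    primary <- bitwAnd(aln$flag, 4L) == 0L & bitwAnd(aln$flag, 256L) == 0L &
      bitwAnd(aln$flag, 2048L) == 0L
    p <- aln[primary, , drop = FALSE]
    end <- ifelse(bitwAnd(p$flag, 128L) > 0L, 2L, 1L)
    if (anyDuplicated(paste(p$qname, end)))
      stop("duplicate primary records per (fragment, end) in ", what)
  }
  dupCheck(bt2Txome, "transcriptomic input")
  dupCheck(starGenome, "genomic input")
  cand <- selectCandidates(bt2Txome, starTxome, starGenome)
  txScores <- fragmentScores(bt2Txome)
  gScores <- fragmentScores(starGenome)
  allFrags <- unique(bt2Txome$qname)
  verdict <- setNames(rep("NOT_CANDIDATE", length(allFrags)), allFrags)
  bt <- setNames(rep(NA_real_, length(allFrags)), allFrags)
  bg <- bt
  for (f in cand) {
    bt[f] <- if (f %in% names(txScores)) txScores[[f]] else 0
    bg[f] <- if (f %in% names(gScores)) gScores[[f]] else 0
    verdict[f] <- if (bg[f] > bt[f]) "REMOVE" else "RETAIN"
  }
  remove <- names(verdict)[verdict == "REMOVE"]
  list(alignments = bt2Txome[!(bt2Txome$qname %in% remove), , drop = FALSE],
       decisions = data.frame(fragment = allFrags,
                              best_txome_score = unname(bt),
                              best_genome_score = unname(bg),
                              verdict = unname(verdict)))
}

#' Indel ratio between a reference transcript and its variant copy
#'
#' A minimal-edit-cost global alignment is computed (ties broken toward
#' substitutions, so isolated variants are recovered as planted) and the
#' ratio is the total inserted plus deleted bases divided by the reference
#' transcript length. Substitutions contribute nothing.
#'
#' @param referenceTx,variantTx nucleotide sequences (character).
#' @return The indel ratio (numeric scalar).
#' @export
indelRatio <- function(referenceTx, variantTx) {
  if (nchar(referenceTx) == 0L || nchar(variantTx) == 0L)
    stop("sequences must be non-empty")
  if (referenceTx == variantTx) return(0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    pattern = variantTx, subject = referenceTx, type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1.01)
  ins <- sum(BiocGenerics::width(
    Biostrings::indel(Biostrings::pattern(aln))[[1]]))
  del <- sum(BiocGenerics::width(
    Biostrings::indel(Biostrings::subject(aln))[[1]]))
  (ins + del) / nchar(referenceTx)
}

#' Cumulative accuracy-difference profile over indel-ratio-ranked transcripts
#'
#' Transcripts are sorted in descending order of indel ratio; at cumulative
#' prefixes growing by `step` transcripts, the difference in Spearman
#' correlation with the truth between two quantification runs (typically a
#' default configuration and an indel-disallowing "strict" variant) is
#' evaluated.
#'
#' @param ratios named numeric vector of per-transcript indel ratios.
#' @param truth named numeric vector of true abundances.
#' @param est,estStrict named numeric vectors of estimated abundances for
#'   the two configurations.
#' @param step prefix increment in transcripts (default 1000).
#' @return A data.frame with `n` (prefix size) and `delta`
#'   (`cor(est, truth) - cor(estStrict, truth)`, Spearman, on the prefix).
#' @export
rankByIndelRatio <- function(ratios, truth, est, estStrict, step = 1000L) {
  ord <- names(sort(ratios, decreasing = TRUE))
  n <- length(ord)
  sizes <- unique(c(seq(min(step, n), n, by = step), n))
  delta <- vapply(sizes, function(s) {
    ids <- ord[seq_len(s)]
    d1 <- suppressWarnings(cor(est[ids], truth[ids], method = "spearman"))
    d2 <- suppressWarnings(cor(estStrict[ids], truth[ids],
                               method = "spearman"))
    d1 - d2
  }, numeric(1))
  data.frame(n = sizes, delta = delta)
}
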