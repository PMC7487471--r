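# Oracle alignment curation: MD-tag matched-base scoring, candidate
# selection, filtering, and the indel-ratio analysis.

test_that("matched-base scoring counts only MATCH events", {
  expect_equal(mdMatchScore("50M", "50"), 50)
  expect_equal(mdMatchScore("10S40M", "40"), 40)
  expect_equal(mdMatchScore("50M", "20A29"), 49)
  # spliced genomic alignments: N neither penalized nor rewarded
  expect_equal(mdMatchScore("20M500N30M", "50"), 50)
  expect_equal(mdMatchScore("20M2I28M", "48"), 48)
  # conservation: matches + clipped + mismatched + inserted = read length
  set.seed(461)
  for (i in 1:40) {
    inst <- randomCigarMdInstance(60)
    ev <- parseCigarMd(inst$cigar, inst$md)
    expect_equal(mdMatchScore(inst$cigar, inst$md) +
                   sum(ev %in% c("SOFTCLIP", "MISMATCH", "INSERTION")),
                 60)
  }
})

test_that("candidate selection is the stated three-way set difference", {
  bt2 <- rbind(samRow("f1", 0L, "t1", 1L, "50M", md = "50"),
               samRow("f2", 0L, "t1", 1L, "50M", md = "50"),
               samRow("f3", 0L, "t2", 1L, "50M", md = "50"))
  starTx <- samRow("f1", 0L, "t1", 1L, "50M", md = "50")
  starG <- rbind(samRow("f1", 0L, "chr1", 1L, "50M", md = "50"),
                 samRow("f2", 0L, "chr1", 1L, "50M", md = "50"))
  cand <- selectCandidates(bt2, starTx, starG)
  expect_equal(cand, "f2")  # in bt2 + genome, not projected to txome
})

test_that("oracle filtering removes exactly fragments with strictly better genomic alignments", {
  # candidate with equal scores is retained; strictly better genomic removed
  bt2 <- rbind(samRow("keep", 0L, "t1", 1L, "50M", md = "50"),
               samRow("drop", 0L, "t1", 1L, "50M", md = "20A20C8"),
               samRow("pass", 0L, "t2", 1L, "50M", md = "50"))
  starTx <- samRow("pass", 0L, "t2", 1L, "50M", md = "50")
  starG <- rbind(samRow("keep", 0L, "chr1", 1L, "50M", md = "50"),
                 samRow("drop", 0L, "chr1", 1L, "50M", md = "50"))
  out <- oracleFilter(bt2, starTx, starG)
  expect_setequal(out$alignments$qname, c("keep", "pass"))
  v <- setNames(out$decisions$verdict, out$decisions$fragment)
  expect_equal(v[["keep"]], "RETAIN")   # equal quality kept
  expect_equal(v[["drop"]], "REMOVE")
  expect_equal(v[["pass"]], "NOT_CANDIDATE")
  # output is a subset of the input, non-candidates verbatim
  expect_true(all(out$alignments$qname %in% bt2$qname))

  dup <- rbind(bt2, samRow("keep", 0L, "t9", 9L, "50M", md = "50"))
  expect_error(oracleFilter(dup, starTx, starG), "duplicate")
})

test_that("indel ratio equals planted indel bases over reference length", {
  set.seed(462)
  refTx <- randomSeqStr(100)
  expect_equal(indelRatio(refTx, refTx), 0)

  # one 3-bp deletion and one 2-bp insertion, far apart -> 5 / 100
  var <- paste0(substr(refTx, 1, 20), substr(refTx, 24, 60),
                "TT" , substr(refTx, 61, 100))
  # guard against accidental ambiguity in the random context
  expect_equal(indelRatio(refTx, var), 0.05)

  subsOnly <- selalign:::mutateSubstitutions(refTx, 0.05)
  expect_equal(indelRatio(refTx, subsOnly), 0)
})

test_that("variant manifests and indel ratios agree transcript by transcript", {
  sim <- tinyExperiment()
  vt <- makeVariantTranscriptome(sim$transcriptome,
                                 simConfig(seed = 463, snvRate = 0.01,
                                           indelRate = 0.004))
  for (txid in names(sim$transcriptome)) {
    m <- vt$manifest[vt$manifest$transcript_id == txid &
                       vt$manifest$type %in% c("INS", "DEL"), ]
    want <- sum(m$len) / nchar(sim$transcriptome[[txid]])
    got <- indelRatio(sim$transcriptome[[txid]], vt$variants[[txid]])
    expect_equal(got, want, info = txid)
  }
})

test_that("cumulative indel-ratio profiles behave as constructed", {
  ratios <- setNames(seq(0.5, 0.01, length.out = 50), paste0("t", 1:50))
  truth <- setNames(exp(rnorm(50)), names(ratios))
  # identical estimates: delta identically zero
  prof0 <- rankByIndelRatio(ratios, truth, truth, truth, step = 10)
  expect_true(all(prof0$delta == 0))
  # only the top-ratio transcripts are misquantified by the strict variant
  strict <- truth
  strict[paste0("t", 1:10)] <- rev(strict[paste0("t", 1:10)])
  prof <- rankByIndelRatio(ratios, truth, truth, strict, step = 10)
  expect_equal(prof$n, c(10, 20, 30, 40, 50))
  expect_equal(which.max(prof$delta), 1L)
  expect_lt(prof$delta[5], prof$delta[1])  # dilution toward zero
  # step larger than n gives a single point
  one <- rankByIndelRatio(ratios, truth, truth, strict, step = 100)
  expect_equal(nrow(one), 1L)
})

test_that("oracle filtering separates transcriptomic from intronic reads end to end", {
  # reads half from transcripts (perfect transcriptomic records), half from
  # intronic loci (2-mismatch transcriptomic records, perfect genomic ones)
  txFrag <- paste0("tx", 1:10)
  inFrag <- paste0("in", 1:10)
  bt2 <- do.call(rbind, c(
    lapply(txFrag, function(f) samRow(f, 0L, "t1", 1L, "76M", md = "76")),
    lapply(inFrag, function(f)
      samRow(f, 0L, "t1", 1L, "76M", md = "30A20C24"))))
  starTx <- do.call(rbind, lapply(txFrag, function(f)
    samRow(f, 0L, "t1", 1L, "76M", md = "76")))
  starG <- do.call(rbind, c(
    lapply(txFrag, function(f) samRow(f, 0L, "chr1", 1L, "76M", md = "76")),
    lapply(inFrag, function(f)
      samRow(f, 0L, "chr1", 500L, "76M", md = "76"))))
  out <- oracleFilter(bt2, starTx, starG)
  expect_setequal(out$alignments$qname, txFrag)
  expect_setequal(out$decisions$fragment[out$decisions$verdict == "REMOVE"],
                  inFrag)
})
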