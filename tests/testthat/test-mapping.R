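# Phases 1-3: uni-MEM collection, projection/collation, filters, compaction,
# chaining.

test_that("uni-MEMs are maximal exact matches with the stated termination rules", {
  set.seed(421)
  t1 <- randomSeqStr(80)
  idx <- buildIndex(referenceCatalog(c(t1 = t1)), indexConfig(k = 11))

  # a read equal to an indexed non-repetitive sequence is one uni-MEM
  um <- collectUnimems(t1, idx)
  expect_equal(nrow(um), 1L)
  expect_equal(um$read_start, 0L)
  expect_equal(um$length, 80L)

  # a mismatch splits the matches; each piece is maximal
  read <- t1
  substr(read, 40, 40) <- if (substr(t1, 40, 40) == "A") "C" else "A"
  um2 <- collectUnimems(read, idx)
  expect_true(any(um2$read_start == 0L & um2$length == 39L))
  expect_true(any(um2$read_start + um2$length == 80L & um2$read_start >= 40L))
  # matched substrings are exact
  for (i in seq_len(nrow(um2))) {
    sub <- substr(read, um2$read_start[i] + 1L,
                  um2$read_start[i] + um2$length[i])
    expect_true(grepl(sub, t1, fixed = TRUE) ||
                  grepl(rcStr(sub), t1, fixed = TRUE))
  }

  # all-N reads and reads shorter than k produce no uni-MEMs
  expect_equal(nrow(collectUnimems(strrep("N", 40), idx)), 0L)
  expect_message(short <- collectUnimems("ACGT", idx), "shorter")
  expect_equal(nrow(short), 0L)
})

test_that("projection expands occurrences and handles reverse complements", {
  set.seed(422)
  shared <- randomSeqStr(30)
  t1 <- paste0(randomSeqStr(20), shared, randomSeqStr(15))
  t2 <- paste0(shared, randomSeqStr(25))
  idx <- buildIndex(referenceCatalog(c(t1 = t1, t2 = t2)),
                    indexConfig(k = 11))
  um <- collectUnimems(shared, idx)
  anchors <- projectAndCollate(um, nchar(shared), idx)
  expect_setequal(unique(anchors$ref), c(1L, 2L))
  expect_true(any(anchors$ref == 1L & anchors$ref_start == 20L))
  expect_true(any(anchors$ref == 2L & anchors$ref_start == 0L))

  # an RC read yields RC-orientation anchors whose coordinates verify
  # against a naive search of the reverse-complemented read
  rcRead <- rcStr(shared)
  umRc <- collectUnimems(rcRead, idx)
  aRc <- projectAndCollate(umRc, nchar(rcRead), idx)
  expect_true(all(aRc$orientation == 1L))
  for (i in seq_len(nrow(aRc))) {
    refSeq <- c(t1, t2)[aRc$ref[i]]
    seg <- substr(refSeq, aRc$ref_start[i] + 1L,
                  aRc$ref_start[i] + aRc$length[i])
    oriented <- rcStr(rcRead)  # anchors live on the reverse-complemented read
    expect_equal(substr(oriented, aRc$read_start[i] + 1L,
                        aRc$read_start[i] + aRc$length[i]), seg)
  }

  empty <- projectAndCollate(um[0, ], nchar(shared), idx)
  expect_equal(nrow(empty), 0L)
})

test_that("the pre-chaining filter respects its threshold and default", {
  anchors <- data.frame(ref = c(1L, 2L, 3L), orientation = 0L,
                        read_start = 0L, ref_start = 0L,
                        length = c(100L, 70L, 60L))
  on <- filterBeforeChaining(anchors, chainParams(preFilterEnabled = TRUE))
  expect_setequal(on$ref, c(1L, 2L))  # threshold 0.65 * 100
  off <- filterBeforeChaining(anchors)  # disabled by default
  expect_equal(off, anchors)
  single <- filterBeforeChaining(anchors[1, ],
                                 chainParams(preFilterEnabled = TRUE))
  expect_equal(nrow(single), 1L)
})

test_that("compaction merges exactly adjacent anchors, conserves bases, is idempotent", {
  a <- data.frame(read_start = c(0L, 5L), ref_start = c(10L, 15L),
                  length = c(5L, 5L))
  m <- compactAnchors(a)
  expect_equal(m, data.frame(read_start = 0L, ref_start = 10L, length = 10L))

  gap <- data.frame(read_start = c(0L, 5L), ref_start = c(10L, 16L),
                    length = c(5L, 5L))
  expect_equal(nrow(compactAnchors(gap)), 2L)

  three <- data.frame(read_start = c(0L, 5L, 10L),
                      ref_start = c(10L, 15L, 20L), length = c(5L, 5L, 4L))
  m3 <- compactAnchors(three)
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$length, 14L)
  expect_equal(compactAnchors(m3), m3)

  set.seed(423)
  for (i in 1:20) {
    inst <- randomAnchorInstance(sample(2:8, 1))
    out <- compactAnchors(inst)
    expect_equal(sum(out$length), sum(inst$length))
    expect_equal(compactAnchors(out), out)
  }
})

test_that("chaining matches exhaustive enumeration on small instances", {
  p <- chainParams()
  one <- data.frame(read_start = 0L, ref_start = 0L, length = 30L)
  expect_equal(chainAnchors(one, p)$score, 30)

  co <- data.frame(read_start = c(0L, 12L), ref_start = c(0L, 12L),
                   length = c(10L, 10L))
  res <- chainAnchors(co, p)
  expect_equal(res$score, 20)  # equal read and ref gaps: d = 0, no cost

  set.seed(424)
  for (i in 1:60) {
    inst <- randomAnchorInstance(sample(2:8, 1))
    got <- chainAnchors(inst, p)$score
    want <- bruteForceChainScore(inst, p)
    expect_equal(got, want, tolerance = 1e-9, info = paste("case", i))
  }
})

test_that("the post-chaining filter keeps the argmax and applies tau'", {
  ch <- data.frame(ref = 1:3, score = c(100, 70, 60))
  kept <- filterAfterChaining(ch)
  expect_equal(kept$score, c(100, 70))
  expect_equal(filterAfterChaining(ch[3, ])$score, 60)
  allEq <- data.frame(ref = 1:3, score = c(50, 50, 50))
  expect_equal(nrow(filterAfterChaining(allEq)), 3L)
  off <- filterAfterChaining(ch, chainParams(postFilterEnabled = FALSE))
  expect_equal(nrow(off), 3L)
})

test_that("error-free reads from indexed transcripts chain to their true locus", {
  sim <- tinyExperiment()
  idx <- buildIndex(referenceCatalog(sim$transcriptome))
  set.seed(425)
  ords <- setNames(seq_along(sim$transcriptome), names(sim$transcriptome))
  for (i in 1:25) {
    txid <- sample(names(sim$transcriptome), 1)
    src <- sim$transcriptome[[txid]]
    pos <- sample.int(nchar(src) - 99L, 1) - 1L
    read <- substr(src, pos + 1L, pos + 100L)
    chains <- mapReadEnd(read, idx)
    expect_gt(length(chains), 0L)
    best <- which.max(vapply(chains, `[[`, numeric(1), "score"))
    hit <- vapply(chains, function(ch)
      ch$ref == ords[[txid]] && ch$score == chains[[best]]$score &&
        ch$window_lo == pos, logical(1))
    expect_true(any(hit), info = paste(txid, pos))
  }
})
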