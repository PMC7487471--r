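# Reference catalog, duplicate handling, and the unitig k-mer index.

test_that("duplicate transcripts are kept or collapsed per configuration", {
  tx <- c(t1 = "ACGTACGT", t2 = "ACGTACGT", t3 = "ACGGACGT")
  keep <- referenceCatalog(tx, config = indexConfig(k = 4))
  expect_equal(refNames(keep), c("t1", "t2", "t3"))

  drop <- referenceCatalog(tx, config = indexConfig(k = 4,
                                                    keepDuplicates = FALSE))
  expect_equal(refNames(drop), c("t1", "t3"))
  expect_equal(drop@dupMap, c(t2 = "t1"))

  expect_error(
    referenceCatalog(c(t1 = "ACGTAC"), decoys = c(d1 = "ACGTAC")),
    "decoy")
})

test_that("index construction resolves every reference k-mer to its true occurrence set", {
  set.seed(411)
  for (rep in 1:8) {
    k <- sample(c(5L, 7L, 11L), 1)
    nSeq <- sample(2:8, 1)
    seqs <- vapply(sample(30:200, nSeq, replace = TRUE), randomSeqStr,
                   character(1))
    # inject sharing: one sequence embeds a window of another, one is an RC
    if (nSeq >= 3) {
      seqs[2] <- paste0(substr(seqs[1], 5, 5 + k + 6), seqs[2])
      seqs[3] <- rcStr(seqs[1])
    }
    names(seqs) <- paste0("s", seq_len(nSeq))
    idx <- buildIndex(referenceCatalog(seqs), indexConfig(k = k))
    # query every k-mer of every reference through the index
    for (r in seq_len(nSeq)) {
      L <- nchar(seqs[r])
      for (p in sample(seq_len(L - k + 1L), min(12, L - k + 1L))) {
        kmer <- substr(seqs[r], p, p + k - 1L)
        truth <- naiveKmerOccurrences(kmer, seqs)
        um <- collectUnimems(kmer, idx)
        expect_gte(nrow(um), 1L)
        got <- projectAndCollate(um[1, , drop = FALSE], k, idx)
        # forward-orientation occurrence set of this kmer as a read
        gotSet <- data.frame(ref = got$ref,
                             pos = got$ref_start,
                             strand = got$orientation)
        gotSet <- gotSet[order(gotSet$ref, gotSet$pos, gotSet$strand), ]
        expect_equal(unname(as.matrix(gotSet)), unname(as.matrix(truth)),
                     info = paste("k =", k, "kmer", kmer))
      }
    }
  }
})

test_that("unitigs are maximal and cover branching examples correctly", {
  # shared suffix induces a branch: the shared unitig occurs in both refs
  idx <- buildIndex(referenceCatalog(c(t1 = "AAAACCC", t2 = "TTTACCC")),
                    indexConfig(k = 4))
  shared <- which(vapply(idx@unitigs, function(u)
    grepl("ACCC", u) || grepl(rcStr("ACCC"), u), logical(1)))
  expect_length(shared, 1L)
  occ <- idx@occRef[(idx@occPtr[shared] + 1L):idx@occPtr[shared + 1L]]
  expect_setequal(occ, c(0L, 1L))

  # a sequence and its reverse complement share one unitig set with
  # opposite occurrence orientations
  s <- randomSeqStr(60)
  idx2 <- buildIndex(referenceCatalog(c(a = s, b = rcStr(s))),
                     indexConfig(k = 7))
  expect_equal(length(idx2@unitigs), 1L)
  expect_equal(sort(idx2@occStrand), c(0L, 1L))

  # maximality: a sequence whose canonical (k-1)-mers are all distinct has a
  # single non-branching path, so it must come back as exactly one unitig
  set.seed(412)
  k <- 7L
  repeat {
    lin <- randomSeqStr(40)
    subs <- substring(lin, 1:(40 - k + 2), (k - 1):40)
    canon <- pmin(subs, vapply(subs, rcStr, character(1)))
    if (!anyDuplicated(canon)) break
  }
  idx3 <- buildIndex(referenceCatalog(c(t = lin)), indexConfig(k = k))
  expect_true(identical(idx3@unitigs, lin) ||
                identical(idx3@unitigs, rcStr(lin)))
})

test_that("index construction is deterministic and splits at N runs", {
  set.seed(413)
  seqs <- setNames(vapply(rep(120, 5), randomSeqStr, character(1)),
                   paste0("s", 1:5))
  i1 <- buildIndex(referenceCatalog(seqs), indexConfig(k = 9))
  i2 <- buildIndex(referenceCatalog(seqs), indexConfig(k = 9))
  expect_identical(serialize(i1, NULL), serialize(i2, NULL))

  withN <- c(x = paste0(substr(seqs[1], 1, 40), "NNNN",
                        substr(seqs[2], 1, 40)))
  idx <- buildIndex(referenceCatalog(withN), indexConfig(k = 9))
  # no unitig may contain an N and no k-mer spans the N run
  expect_false(any(grepl("N", idx@unitigs)))
  um <- collectUnimems(paste0(substr(seqs[1], 31, 40), "NNNN"), idx)
  expect_true(all(um$read_start + um$length <= 10))

  expect_error(buildIndex(referenceCatalog(c(s = "ACGT")),
                          indexConfig(k = 23)), "k")
})

test_that("index save/load round-trips through the directory layout", {
  sim <- tinyExperiment()
  idx <- buildIndex(referenceCatalog(sim$transcriptome))
  dir <- withr::local_tempdir()
  saveIndex(idx, dir)
  expect_true(all(file.exists(file.path(dir, c("catalog.tsv", "refs.fa",
                                               "unitigs.fa", "occ.tsv",
                                               "info.json")))))
  back <- loadIndex(dir)
  expect_equal(back@k, idx@k)
  expect_equal(back@unitigs, idx@unitigs)
  expect_equal(back@occPtr, idx@occPtr)
  expect_equal(back@occRef, idx@occRef)
  expect_equal(refSequences(back@catalog), refSequences(idx@catalog))
  expect_equal(isDecoy(back@catalog), isDecoy(idx@catalog))
})
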