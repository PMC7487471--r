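# Phase 5: extension alignment scoring, caching, thresholding, the decoy
# rule, and the full per-fragment pipeline.

test_that("extension scores reproduce hand-computable cases", {
  set.seed(441)
  ref <- randomSeqStr(300)
  read <- substr(ref, 101, 200)
  full <- data.frame(read_start = 0L, ref_start = 100L, length = 100L)
  expect_equal(extensionScore(read, ref, full), 200)

  # one substitution: 99 matches + 1 mismatch = 198 - 4 = 194
  mut <- read
  substr(mut, 50, 50) <- if (substr(read, 50, 50) == "A") "C" else "A"
  anch <- data.frame(read_start = c(0L, 50L), ref_start = c(100L, 150L),
                     length = c(49L, 50L))
  expect_equal(extensionScore(mut, ref, anch), 194)
  expect_equal(fittingAlignmentScore(mut, ref), 194)

  # a 2-base deletion in the read: 98 matches - (5 + 2 * 3) = 185
  del <- paste0(substr(read, 1, 50), substr(read, 53, 100))
  anchD <- data.frame(read_start = c(0L, 50L), ref_start = c(100L, 152L),
                      length = c(50L, 48L))
  expect_equal(extensionScore(del, ref, anchD), 185)
  expect_equal(fittingAlignmentScore(del, ref), 185)

  expect_error(extensionScore(read, ref,
                              data.frame(read_start = 0L, ref_start = 290L,
                                         length = 100L)),
               "bounds")
})

test_that("extension scoring equals the full fitting-alignment oracle", {
  set.seed(442)
  checked <- 0
  while (checked < 40) {
    refSeq <- randomSeqStr(400)
    winLen <- sample(80:200, 1)
    winStart <- sample.int(400 - winLen, 1) - 1L
    inst <- editedReadInstance(refSeq, winStart, winLen, sample(0:5, 1))
    if (is.null(inst$anchors)) next
    got <- extensionScore(inst$read, refSeq, inst$anchors)
    want <- fittingAlignmentScore(inst$read, refSeq)
    expect_equal(got, want, info = paste("case", checked))
    checked <- checked + 1
  }
})

test_that("the alignment cache changes work, never results", {
  set.seed(443)
  ref <- randomSeqStr(200)
  read <- substr(ref, 51, 150)
  anch <- data.frame(read_start = 0L, ref_start = 50L, length = 100L)
  cache <- newAlignmentCache()
  s1 <- cachedExtensionScore(cache, read, ref, anch)
  s2 <- cachedExtensionScore(cache, read, ref, anch)
  expect_equal(s1, s2)
  expect_equal(cache$computed, 1L)
  expect_equal(cache$hits, 1L)
  # a different reference substring is a different computation
  ref2 <- paste0(substr(ref, 1, 60), randomSeqStr(140))
  s3 <- cachedExtensionScore(cache, read, ref2, anch)
  expect_equal(cache$computed, 2L)
  # disabled cache returns identical scores
  expect_equal(cachedExtensionScore(NULL, read, ref, anch), s1)
})

test_that("fragment classification applies the decoy rule and score threshold", {
  p <- alignParams()
  # strictly greater decoy score invalidates everything
  dec <- classifyFragment(
    data.frame(score = c(150, 140), is_decoy = c(TRUE, FALSE)), 100, p)
  expect_equal(dec$status, "DECOY")
  expect_equal(nrow(dec$survivors), 0L)

  # ties go to the transcriptome; decoy mappings are filtered out
  tie <- classifyFragment(
    data.frame(score = c(150, 150), is_decoy = c(TRUE, FALSE)), 100, p)
  expect_equal(tie$status, "ALIGNED")
  expect_false(any(tie$survivors$is_decoy))

  # paired 2x100 bp: max 400, threshold 260; a 250 mapping fails
  low <- classifyFragment(
    data.frame(score = 250, is_decoy = FALSE), 200, p)
  expect_equal(low$status, "UNALIGNED")
  high <- classifyFragment(
    data.frame(score = 260, is_decoy = FALSE), 200, p)
  expect_equal(high$status, "ALIGNED")
})

test_that("error-free simulated reads align to their true locus; noise does not", {
  sim <- tinyExperiment()
  cfg0 <- simConfig(seed = 302, nGenes = 15, nFragments = 100, errorRate = 0)
  rd <- simulateReads(sim$transcriptome, cfg0)
  idx <- buildIndex(referenceCatalog(sim$transcriptome))
  run <- runSelectiveAlignment(rd$reads1, rd$reads2, idx)
  expect_equal(run$metadata$n_aligned, 100L)
  ords <- setNames(seq_along(sim$transcriptome), names(sim$transcriptome))
  trueRef <- ords[rd$truth$origin_id]
  hit <- vapply(seq_len(100), function(f)
    any(run$mappings$ref[run$mappings$fragment == f] == trueRef[f]),
    logical(1))
  expect_true(all(hit))

  set.seed(444)
  junk1 <- setNames(vapply(rep(100, 30), randomSeqStr, character(1)),
                    paste0("j", 1:30))
  junk2 <- setNames(vapply(rep(100, 30), randomSeqStr, character(1)),
                    paste0("j", 1:30))
  noise <- runSelectiveAlignment(junk1, junk2, idx)
  expect_equal(noise$metadata$n_unaligned, 30L)
})

test_that("the cache and decoy monotonicity invariants hold on a mixed sample", {
  cfg <- simConfig(seed = 303, nGenes = 12, nFragments = 250,
                   nUnannotatedCopies = 5, unannotatedIdentity = 0.9,
                   fracUnannotated = 0.25)
  sim <- simulateExperiment(cfg)
  dec <- makeDecoys(sim$genome, sim$transcriptome, sim$exons)
  idxPlain <- buildIndex(referenceCatalog(sim$transcriptome))
  idxDecoy <- buildIndex(referenceCatalog(sim$transcriptome,
                                          decoys = dec$decoys))

  runOn <- runSelectiveAlignment(sim$reads1, sim$reads2, idxDecoy,
                                 useCache = TRUE)
  runOff <- runSelectiveAlignment(sim$reads1, sim$reads2, idxDecoy,
                                  useCache = FALSE)
  keep <- setdiff(names(runOn$metadata),
                  c("alignments_computed", "cache_hits"))
  expect_identical(runOn$fragments, runOff$fragments)
  expect_identical(runOn$mappings, runOff$mappings)
  expect_identical(runOn$metadata[keep], runOff$metadata[keep])
  expect_lte(runOn$metadata$alignments_computed,
             runOff$metadata$alignments_computed)

  # adding decoys never increases ALIGNED fragments, never changes the
  # score of a retained non-decoy mapping
  runPlain <- runSelectiveAlignment(sim$reads1, sim$reads2, idxPlain)
  expect_lte(runOn$metadata$n_aligned, runPlain$metadata$n_aligned)
  key <- function(m) paste(m$fragment, m$ref_name, m$pos1)
  common <- intersect(key(runOn$mappings), key(runPlain$mappings))
  sOn <- setNames(runOn$mappings$score, key(runOn$mappings))[common]
  sPl <- setNames(runPlain$mappings$score, key(runPlain$mappings))[common]
  expect_equal(sOn, sPl)
})

test_that("SAM emission tags decoy fragments and round-trips", {
  cfg <- simConfig(seed = 304, nGenes = 10, nFragments = 80,
                   nUnannotatedCopies = 4, unannotatedIdentity = 0.9,
                   fracUnannotated = 0.4)
  sim <- simulateExperiment(cfg)
  dec <- makeDecoys(sim$genome, sim$transcriptome, sim$exons)
  idx <- buildIndex(referenceCatalog(sim$transcriptome,
                                     decoys = dec$decoys))
  run <- runSelectiveAlignment(sim$reads1, sim$reads2, idx)
  expect_gt(run$metadata$n_decoy, 0L)
  p <- withr::local_tempfile(fileext = ".sam")
  writeMappingsSam(run, idx, sim$reads1, sim$reads2, p)
  back <- readSam(p)
  xt <- samTag(back$alignments, "XT")
  decoyFrags <- run$fragments$name[run$fragments$status == "DECOY"]
  expect_setequal(unique(back$alignments$qname[!is.na(xt) & xt == "D"]),
                  decoyFrags[decoyFrags %in% back$alignments$qname])
  alignedFrags <- run$fragments$name[run$fragments$status == "ALIGNED"]
  expect_true(all(is.na(xt[back$alignments$qname %in% alignedFrags])))
})
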