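# Synthetic-data generator: determinism, internal consistency, truth tables.

test_that("genome/annotation generation is deterministic and self-consistent", {
  cfg <- simConfig(seed = 481, nGenes = 8)
  a <- makeGenomeAndAnnotation(cfg)
  b <- makeGenomeAndAnnotation(cfg)
  expect_identical(a, b)

  # splicing the genome by the annotation reproduces the transcriptome
  spliced <- spliceTranscripts(a$genome, a$exons)
  expect_identical(spliced[names(a$transcriptome)], a$transcriptome)
  # exon intervals of one transcript do not overlap
  for (txid in unique(a$exons$transcript_id)) {
    e <- a$exons[a$exons$transcript_id == txid, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }

  single <- makeGenomeAndAnnotation(simConfig(seed = 482, nGenes = 3,
                                              exonsPerGene = c(1, 1)))
  # zero introns: every plus-strand transcript is a genomic substring
  for (txid in names(single$transcriptome)) {
    e <- single$exons[single$exons$transcript_id == txid, ]
    if (e$strand[1] == "+")
      expect_true(grepl(single$transcriptome[[txid]],
                        single$genome[[e$chrom[1]]], fixed = TRUE))
  }
})

test_that("planted copies land intergenically at the target identity", {
  cfg <- simConfig(seed = 483, nGenes = 10, nUnannotatedCopies = 6,
                   unannotatedIdentity = 0.9)
  sim <- plantUnannotatedCopies(makeGenomeAndAnnotation(cfg), cfg)
  expect_equal(nrow(sim$plants), 6L)
  expect_true(all(abs(sim$plants$realized_identity - 0.9) < 0.03))
  # plants are disjoint from every exon
  for (i in seq_len(nrow(sim$plants))) {
    p <- sim$plants[i, ]
    e <- sim$exons[sim$exons$chrom == p$chrom, ]
    expect_true(all(e$end <= p$start | e$start >= p$end))
    # the genome carries the planted sequence at the manifest interval
    expect_equal(substr(sim$genome[[p$chrom]], p$start + 1L, p$end),
                 sim$plantSeqs[[p$plant_id]])
  }
  # annotation splicing still intact (plants replace intergenic bases only)
  spliced <- spliceTranscripts(sim$genome, sim$exons)
  expect_identical(spliced[names(sim$transcriptome)], sim$transcriptome)

  none <- plantUnannotatedCopies(makeGenomeAndAnnotation(cfg),
                                 simConfig(seed = 483, nGenes = 10))
  expect_identical(none$genome, makeGenomeAndAnnotation(cfg)$genome)
})

test_that("variant transcriptomes list every planted event and respect rates", {
  sim <- tinyExperiment()
  cfg0 <- simConfig(seed = 484, snvRate = 0, indelRate = 0)
  vt0 <- makeVariantTranscriptome(sim$transcriptome, cfg0)
  expect_identical(vt0$variants, sim$transcriptome)
  expect_equal(nrow(vt0$manifest), 0L)

  cfg <- simConfig(seed = 485, snvRate = 0.01, indelRate = 0.003)
  v1 <- makeVariantTranscriptome(sim$transcriptome, cfg)
  v2 <- makeVariantTranscriptome(sim$transcriptome, cfg)
  expect_identical(v1, v2)
  # length bookkeeping: ins minus del equals the length change
  for (txid in names(sim$transcriptome)) {
    m <- v1$manifest[v1$manifest$transcript_id == txid, ]
    dl <- sum(m$len[m$type == "INS"]) - sum(m$len[m$type == "DEL"])
    expect_equal(nchar(v1$variants[[txid]]) -
                   nchar(sim$transcriptome[[txid]]), dl)
  }
  # events respect the minimum spacing per transcript
  for (txid in unique(v1$manifest$transcript_id)) {
    m <- v1$manifest[v1$manifest$transcript_id == txid, ]
    if (nrow(m) > 1) {
      m <- m[order(m$pos), ]
      ends <- m$pos + ifelse(m$type == "DEL", m$len, 1L)
      expect_true(all(m$pos[-1] - ends[-nrow(m)] >= 0))
    }
  }
})

test_that("read simulation conserves truth counts and respects error settings", {
  sim <- tinyExperiment()
  cfg <- simConfig(seed = 486, nFragments = 2000, errorRate = 0)
  rd <- simulateReads(sim$transcriptome, cfg)
  expect_equal(nrow(rd$truth), 2000L)
  expect_equal(sum(rd$txCounts), 2000)
  expect_equal(unname(rd$txCounts["t001"]),
               sum(rd$truth$origin_id == "t001"))
  # error-free reads are exact (possibly reverse-complemented) substrings
  set.seed(487)
  for (i in sample(2000, 30)) {
    src <- sim$transcriptome[[rd$truth$origin_id[i]]]
    expect_true(grepl(rd$reads1[[i]], src, fixed = TRUE))
    expect_true(grepl(rcStr(rd$reads2[[i]]), src, fixed = TRUE))
  }
  # per-transcript counts near the binomial expectation (3 sigma)
  pTop <- rd$abundance
  exp_ <- 2000 * pTop
  sd_ <- sqrt(2000 * pTop * (1 - pTop))
  expect_true(all(abs(rd$txCounts - exp_) <= pmax(3 * sd_, 1)))

  # same seed: byte-identical reads; different read seed keeps the truth
  rd2 <- simulateReads(sim$transcriptome, cfg)
  expect_identical(rd, rd2)
  rdErr <- simulateReads(sim$transcriptome,
                         simConfig(seed = 486, nFragments = 2000,
                                   errorRate = 0.1))
  mm <- mean(vapply(1:200, function(i) {
    a <- strsplit(rd$reads1[[i]], "")[[1]]
    b <- strsplit(rdErr$reads1[[i]], "")[[1]]
    mean(a != b)
  }, numeric(1)))
  expect_gt(mm, 0.05)
})

test_that("the full generator writes coherent files for the CLI surface", {
  cfg <- simConfig(seed = 488, nGenes = 6, nFragments = 50,
                   nUnannotatedCopies = 2, fracUnannotated = 0.2)
  sim <- simulateExperiment(cfg, variant = TRUE)
  dir <- withr::local_tempdir()
  writeFasta(sim$genome, file.path(dir, "genome.fa"))
  writeGtf(sim$exons, file.path(dir, "annotation.gtf"))
  writeFasta(sim$transcriptome, file.path(dir, "txome.fa"))
  writeFastq(sim$reads1, file.path(dir, "reads_1.fq.gz"))
  backG <- readFasta(file.path(dir, "genome.fa"))
  backE <- readGtfExons(file.path(dir, "annotation.gtf"))
  spliced <- spliceTranscripts(asSeqs <- setNames(as.character(backG),
                                                  names(backG)), backE)
  expect_identical(spliced[names(sim$transcriptome)], sim$transcriptome)
})
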