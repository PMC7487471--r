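# Equivalence classes and EM abundance estimation.

# assemble a minimal saRun-shaped object from a mapping table
fakeRun <- function(mp) {
  structure(list(mappings = mp,
                 fragments = data.frame(),
                 metadata = list()), class = "saRun")
}

mpRow <- function(fragment, ref, score) {
  data.frame(fragment = fragment, name = paste0("f", fragment), ref = ref,
             ref_name = paste0("t", ref), pos1 = 0L, pos2 = 0L,
             orientation1 = 0L, dovetail = FALSE, score = score,
             score1 = score / 2, score2 = score / 2)
}

test_that("equivalence classes group by label and quantized weight pattern", {
  # 5 unique fragments on t1 plus 3 fragments equally best on {t1, t2}
  mp <- rbind(do.call(rbind, lapply(1:5, mpRow, ref = 1L, score = 400)),
              do.call(rbind, lapply(6:8, function(f)
                rbind(mpRow(f, 1L, 400), mpRow(f, 2L, 400)))))
  eqc <- buildEqClasses(fakeRun(mp))
  expect_equal(length(eqc@counts), 2L)
  i1 <- which(vapply(eqc@labels, identical, logical(1), 1L))
  i12 <- which(vapply(eqc@labels, identical, logical(1), c(1L, 2L)))
  expect_equal(eqc@counts[i1], 5)
  expect_equal(eqc@counts[i12], 3)
  expect_equal(eqc@weights[[i1]], 1)
  expect_equal(eqc@weights[[i12]], c(0.5, 0.5))

  # distinct weight patterns stay distinct at bins = 4 ...
  mkW <- function(f, s1, s2) rbind(mpRow(f, 1L, s1), mpRow(f, 2L, s2))
  # softmax weights (0.9, 0.1) vs (0.55, 0.45): score gaps ln(9)/2, ln(11/9)/2
  mpW <- rbind(mkW(1L, 400, 400 - log(9) / 2),
               mkW(2L, 400, 400 - log(11 / 9) / 2))
  eq4 <- buildEqClasses(fakeRun(mpW), quantConfig(rangeFactorizationBins = 4))
  expect_equal(length(eq4@counts), 2L)
  # ... and collapse at bins = 1
  eq1 <- buildEqClasses(fakeRun(mpW), quantConfig(rangeFactorizationBins = 1))
  expect_equal(length(eq1@counts), 1L)
  expect_equal(eq1@counts, 2)
})

test_that("EM reproduces analytic fixed points", {
  el <- c(t1 = 500, t2 = 500)
  # unique assignment is a fixed point: counts exactly
  eqc <- new("EquivalenceClassTable",
             labels = list(1L, 2L), weights = list(1, 1),
             counts = c(5, 7), nTranscripts = 2L)
  ab <- emQuantify(eqc, el)
  expect_equal(ab$NumReads, c(5, 7))
  expect_equal(sum(ab$TPM), 1e6, tolerance = 1e-9)

  # symmetric sharing: (15, 15) by symmetry
  eqs <- new("EquivalenceClassTable",
             labels = list(1L, 2L, c(1L, 2L)),
             weights = list(1, 1, c(0.5, 0.5)),
             counts = c(10, 10, 10), nTranscripts = 2L)
  ab2 <- emQuantify(eqs, el)
  expect_equal(ab2$NumReads, c(15, 15), tolerance = 1e-6)

  # fully ambiguous class under uniform initialization: split evenly
  amb <- new("EquivalenceClassTable",
             labels = list(c(1L, 2L)), weights = list(c(0.5, 0.5)),
             counts = 10, nTranscripts = 2L)
  ab3 <- emQuantify(amb, el)
  expect_equal(ab3$NumReads, c(5, 5))

  expect_warning(z <- emQuantify(new("EquivalenceClassTable", labels = list(),
                                     weights = list(), counts = numeric(),
                                     nTranscripts = 0L), el),
                 "zero")
  expect_equal(z$NumReads, c(0, 0))
})

test_that("EM conserves counts and its log-likelihood never decreases", {
  set.seed(471)
  nTx <- 30
  el <- setNames(runif(nTx, 200, 1500), paste0("t", seq_len(nTx)))
  labels <- lapply(1:40, function(i)
    sort(sample.int(nTx, sample(1:4, 1))))
  weights <- lapply(labels, function(l) {
    w <- runif(length(l)); w / sum(w)
  })
  eqc <- new("EquivalenceClassTable", labels = labels, weights = weights,
             counts = as.numeric(sample(1:50, 40, replace = TRUE)),
             nTranscripts = as.integer(nTx))
  ab <- emQuantify(eqc, el)
  expect_equal(sum(ab$NumReads), sum(eqc@counts), tolerance = 1e-6)
  ll <- attr(ab, "logLik")
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("range factorization is inert when all fragments map uniquely", {
  mp <- do.call(rbind, lapply(1:20, function(f)
    mpRow(f, ref = (f %% 3L) + 1L, score = 400)))
  e1 <- buildEqClasses(fakeRun(mp), quantConfig(rangeFactorizationBins = 1))
  e4 <- buildEqClasses(fakeRun(mp), quantConfig(rangeFactorizationBins = 4))
  el <- c(t1 = 300, t2 = 300, t3 = 300)
  expect_equal(emQuantify(e1, el)$NumReads, emQuantify(e4, el)$NumReads)
})

test_that("effective lengths follow the start-position formula", {
  expect_equal(unname(effectiveLengths(c(t = 1000L), 200)), 801)
  expect_equal(unname(effectiveLengths(c(t = 100L), 200)), 1)
  expect_warning(raw <- effectiveLengths(c(t = 100L), 0), "fragment")
  expect_equal(unname(raw), 100)
})

test_that("quant tables and equivalence-class dumps serialize", {
  sim <- tinyExperiment()
  idx <- buildIndex(referenceCatalog(sim$transcriptome))
  q <- quantify(sim$reads1, sim$reads2, idx)
  expect_equal(sum(q$abundance$NumReads), q$metadata$n_aligned,
               tolerance = 1e-6)
  sf <- withr::local_tempfile(fileext = ".sf")
  writeQuantSf(q$abundance, sf)
  back <- read.table(sf, header = TRUE, sep = "\t")
  expect_equal(back$Name, q$abundance$Name)
  expect_equal(back$NumReads, q$abundance$NumReads, tolerance = 1e-6)
  eq <- withr::local_tempfile(fileext = ".txt")
  writeEqClasses(q$eqClasses, eq)
  expect_equal(length(readLines(eq)), length(q$eqClasses@counts) + 1L)
})
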