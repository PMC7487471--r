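# Synthetic-data generation: annotated multi-gene genomes, planted
# unannotated loci similar to transcripts, variant transcriptomes (SNVs +
# indels), and substitution-error paired-end reads with a truth table.
# Every operation is deterministic under the configured seed; each draws
# from its own RNG stream derived from (seed, operation name), so adding
# plants does not perturb read simulation.

#' Simulation parameters
#'
#' Defaults describe a small but structurally realistic experiment: 2
#' chromosomes carrying multi-exon genes, 100-bp paired reads with
#' fragment length N(250, 25) and a 0.5% substitution error rate, log-normal
#' expression, SNV/indel rates in the range observed between inbred mouse
#' strains and the reference, and unannotated loci planted at 90% identity.
#'
#' @slot seed integer RNG seed.
#' @slot nGenes number of genes (one transcript per gene).
#' @slot nChromosomes chromosomes the genes are distributed over.
#' @slot exonsPerGene,exonLength,intronLength,intergenicLength integer
#'   ranges (length-2 vectors) sampled uniformly.
#' @slot nUnannotatedCopies transcript copies planted intergenically.
#' @slot unannotatedIdentity target identity of planted copies.
#' @slot snvRate,indelRate per-base variant event rates for the variant
#'   transcriptome; indel lengths are 1 + geometric (mean 2).
#' @slot minVariantSpacing minimum bases between variant events (keeps the
#'   planted edit script the unique minimal alignment).
#' @slot readLength,fragMean,fragSd,errorRate,nFragments read simulation
#'   parameters.
#' @slot fracUnannotated fraction of fragments drawn from planted loci.
#' @slot abundanceMeanlog,abundanceSdlog log-normal expression parameters.
#' @export
setClass("SimConfig",
  representation(seed = "integer", nGenes = "integer",
                 nChromosomes = "integer", exonsPerGene = "integer",
                 exonLength = "integer", intronLength = "integer",
                 intergenicLength = "integer",
                 nUnannotatedCopies = "integer",
                 unannotatedIdentity = "numeric", snvRate = "numeric",
                 indelRate = "numeric", minVariantSpacing = "integer",
                 readLength = "integer", fragMean = "numeric",
                 fragSd = "numeric", errorRate = "numeric",
                 nFragments = "integer", fracUnannotated = "numeric",
                 abundanceMeanlog = "numeric", abundanceSdlog = "numeric"),
  prototype(seed = 1L, nGenes = 50L, nChromosomes = 2L,
            exonsPerGene = c(2L, 6L), exonLength = c(120L, 400L),
            intronLength = c(60L, 400L), intergenicLength = c(1500L, 3000L),
            nUnannotatedCopies = 0L, unannotatedIdentity = 0.9,
            snvRate = 0.007, indelRate = 0.0015, minVariantSpacing = 10L,
            readLength = 100L, fragMean = 250, fragSd = 25,
            errorRate = 0.005, nFragments = 10000L, fracUnannotated = 0,
            abundanceMeanlog = 0, abundanceSdlog = 1))

setValidity("SimConfig", function(object) {
  rates <- c(object@unannotatedIdentity, object@snvRate, object@indelRate,
             object@errorRate, object@fracUnannotated)
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
  if (object@nGenes < 1L) return("nGenes must be positive")
  if (object@readLength < 1L) return("readLength must be positive")
  TRUE
})

#' @param ... slot values overriding the defaults (see slots).
#' @return A `SimConfig` object.
#' @rdname SimConfig-class
#' @export
simConfig <- function(...) {
  args <- list(...)
  intSlots <- c("seed", "nGenes", "nChromosomes", "exonsPerGene",
                "exonLength", "intronLength", "intergenicLength",
                "nUnannotatedCopies", "minVariantSpacing", "readLength",
                "nFragments")
  for (s in intersect(names(args), intSlots)) args[[s]] <- as.integer(args[[s]])
  do.call(new, c(list("SimConfig"), args))
}

# derive an op-scoped RNG seed below 2^31
opSeed <- function(seed, op) {
  (as.numeric(seed) * 1000003 + sum(utf8ToInt(op)) * 7919) %% 2147483647
}

randSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate an annotated genome and its transcriptome
#'
#' Genes (one spliced transcript each) are laid on chromosomes separated by
#' intergenic spacers; exon records are emitted in GTF-compatible form and
#' splicing the genome by the annotation reproduces the transcriptome
#' byte-for-byte (see [spliceTranscripts()]).
#'
#' @param config a [SimConfig-class].
#' @return A list with `genome` (named character), `exons` (data.frame as
#'   from [readGtfExons()]), `transcriptome` (named character) and
#'   `intergenic` (data.frame of intergenic intervals available for
#'   planting).
#' @export
makeGenomeAndAnnotation <- function(config = simConfig()) {
  set.seed(opSeed(config@seed, "genome"))
  chromGene <- rep(seq_len(config@nChromosomes),
                   length.out = config@nGenes)
  genome <- character(config@nChromosomes)
  names(genome) <- paste0("chr", seq_len(config@nChromosomes))
  exons <- list()
  tx <- character()
  intergenic <- list()
  for (ci in seq_len(config@nChromosomes)) {
    pos <- 0L
    seqParts <- character()
    addSpacer <- function() {
      len <- rint(1, config@intergenicLength)
      seqParts[[length(seqParts) + 1L]] <<- randSeq(len)
      intergenic[[length(intergenic) + 1L]] <<- data.frame(
        chrom = names(genome)[ci], start = pos, end = pos + len)
      pos <<- pos + len
    }
    addSpacer()
    for (gi in which(chromGene == ci)) {
      nEx <- rint(1, config@exonsPerGene)
      exLens <- rint(nEx, config@exonLength)
      inLens <- if (nEx > 1) rint(nEx - 1, config@intronLength) else integer()
      strand <- sample(c("+", "-"), 1)
      txid <- sprintf("t%03d", gi)
      gid <- sprintf("g%03d", gi)
      exSeqs <- character(nEx)
      for (e in seq_len(nEx)) {
        exSeqs[e] <- randSeq(exLens[e])
        seqParts[[length(seqParts) + 1L]] <- exSeqs[e]
        exons[[length(exons) + 1L]] <- data.frame(
          chrom = names(genome)[ci], start = pos, end = pos + exLens[e],
          transcript_id = txid, gene_id = gid, strand = strand)
        pos <- pos + exLens[e]
        if (e < nEx) {
          seqParts[[length(seqParts) + 1L]] <- randSeq(inLens[e])
          pos <- pos + inLens[e]
        }
      }
      spliced <- paste(exSeqs, collapse = "")
      tx[[txid]] <- if (strand == "+") spliced else revComp(spliced)
      addSpacer()
    }
    genome[ci] <- paste(seqParts, collapse = "")
  }
  list(genome = genome, exons = do.call(rbind, exons), transcriptome = tx,
       intergenic = do.call(rbind, intergenic))
}

#' Splice a genome by exon annotation
#'
#' Reconstructs each transcript by concatenating its exon substrings in
#' genomic order, reverse-complementing minus-strand transcripts.
#'
#' @param genome named character vector of chromosomes.
#' @param exons exon data.frame (0-based half-open).
#' @return Named character vector of transcript sequences.
#' @export
spliceTranscripts <- function(genome, exons) {
  out <- character()
  for (txid in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == txid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    s <- paste(substring(genome[[e$chrom[1]]], e$start + 1L, e$end),
               collapse = "")
    out[[txid]] <- if (e$strand[1] == "-") revComp(s) else s
  }
  out
}

# substitute bases at the given rate; returns the mutated string
mutateSubstitutions <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Plant mutated transcript copies at unannotated loci
#'
#' Copies of randomly chosen transcripts, mutated by substitutions to the
#' target identity, replace intergenic sequence in place (annotation
#' coordinates are unaffected and plants are disjoint from all exons by
#' construction). Realized identities are recorded per plant.
#'
#' @param sim output of [makeGenomeAndAnnotation()].
#' @param config a [SimConfig-class] (`nUnannotatedCopies`,
#'   `unannotatedIdentity`).
#' @return `sim` with the modified `genome` plus `plants`, a data.frame
#'   manifest (`plant_id`, `transcript_id`, `chrom`, `start`, `end`,
#'   `target_identity`, `realized_identity`) and `plantSeqs`, the planted
#'   sequences themselves.
#' @export
plantUnannotatedCopies <- function(sim, config = simConfig()) {
  set.seed(opSeed(config@seed, "plants"))
  nP <- config@nUnannotatedCopies
  manifest <- data.frame(plant_id = character(), transcript_id = character(),
                         chrom = character(), start = integer(),
                         end = integer(), target_identity = numeric(),
                         realized_identity = numeric())
  plantSeqs <- character()
  if (nP == 0L) return(c(sim, list(plants = manifest, plantSeqs = plantSeqs)))
  genome <- sim$genome
  avail <- sim$intergenic
  pad <- 20L
  # each planted locus resembles a distinct transcript (sampling with
  # replacement only when more plants than transcripts are requested)
  txPool <- names(sim$transcriptome)
  txPick <- sample(txPool, nP, replace = nP > length(txPool))
  for (p in seq_len(nP)) {
    txid <- txPick[p]
    src <- sim$transcriptome[[txid]]
    L <- nchar(src)
    roomy <- which(avail$end - avail$start >= L + 2L * pad)
    if (length(roomy) == 0L) {
      warning("no intergenic room left for plant ", p, "; stopping early")
      break
    }
    iv <- sample(roomy, 1)
    maxOff <- avail$end[iv] - pad - L
    off <- sample(seq(avail$start[iv] + pad, maxOff), 1)
    mut <- mutateSubstitutions(src, 1 - config@unannotatedIdentity)
    ch <- avail$chrom[iv]
    g <- genome[[ch]]
    genome[[ch]] <- paste0(substr(g, 1, off),
                           mut,
                           substr(g, off + L + 1L, nchar(g)))
    ident <- mean(strsplit(src, "")[[1]] == strsplit(mut, "")[[1]])
    pid <- sprintf("plant%03d", p)
    manifest <- rbind(manifest, data.frame(
      plant_id = pid, transcript_id = txid, chrom = ch, start = off,
      end = off + L, target_identity = config@unannotatedIdentity,
      realized_identity = ident))
    plantSeqs[[pid]] <- mut
    # split the used interval so later plants cannot overlap
    used <- avail[iv, ]
    avail <- avail[-iv, , drop = FALSE]
    avail <- rbind(avail,
                   data.frame(chrom = ch, start = used$start, end = off),
                   data.frame(chrom = ch, start = off + L, end = used$end))
  }
  out <- sim
  out$genome <- genome
  out$intergenic <- avail
  c(out, list(plants = manifest, plantSeqs = plantSeqs))
}

#' Generate a variant copy of a transcriptome (SNVs + indels)
#'
#' Variant events are planted per transcript at the configured per-base
#' rates, with a minimum spacing between events and a margin from the
#' transcript ends so that the planted edit script is the unique
#' minimal-cost alignment; [indelRatio()] on (reference, variant) then
#' reproduces the manifest's indel totals exactly. Indel lengths are
#' 1 + geometric with mean 2.
#'
#' @param transcriptome named character vector of reference transcripts.
#' @param config a [SimConfig-class] (`snvRate`, `indelRate`,
#'   `minVariantSpacing`).
#' @return A list with `variants` (named character) and `manifest`
#'   (data.frame: `transcript_id`, `pos` 0-based on the reference, `type`
#'   in SNV/INS/DEL, `len`, `alt`).
#' @export
makeVariantTranscriptome <- function(transcriptome, config = simConfig()) {
  set.seed(opSeed(config@seed, "variants"))
  spacing <- config@minVariantSpacing
  manifest <- list()
  variants <- character()
  for (txid in names(transcriptome)) {
    ref <- transcriptome[[txid]]
    L <- nchar(ref)
    nEvents <- rbinom(1, L, config@snvRate + config@indelRate)
    ev <- data.frame(pos = integer(), type = character(), len = integer(),
                     alt = character())
    if (nEvents > 0) {
      cand <- sort(sample.int(L - 2L * spacing, nEvents,
                              replace = FALSE) + spacing)
      lastEnd <- -spacing
      for (p in cand) {
        if (p - lastEnd < spacing) next
        isSnv <- runif(1) < config@snvRate /
          (config@snvRate + config@indelRate)
        if (isSnv) {
          refBase <- substr(ref, p + 1L, p + 1L)
          alt <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1)
          ev <- rbind(ev, data.frame(pos = p, type = "SNV", len = 1L,
                                     alt = alt))
          lastEnd <- p + 1L
        } else {
          len <- 1L + rgeom(1, 0.5)
          if (runif(1) < 0.5) {
            ev <- rbind(ev, data.frame(pos = p, type = "INS",
                                       len = len, alt = randSeq(len)))
            lastEnd <- p + 1L
          } else {
            if (p + len + spacing > L) next
            ev <- rbind(ev, data.frame(pos = p, type = "DEL", len = len,
                                       alt = ""))
            lastEnd <- p + len
          }
        }
      }
    }
    # apply right-to-left so earlier coordinates stay valid
    var <- ref
    if (nrow(ev) > 0) {
      for (i in rev(seq_len(nrow(ev)))) {
        p <- ev$pos[i]
        if (ev$type[i] == "SNV")
          var <- paste0(substr(var, 1, p), ev$alt[i],
                        substr(var, p + 2L, nchar(var)))
        else if (ev$type[i] == "INS")
          var <- paste0(substr(var, 1, p + 1L), ev$alt[i],
                        substr(var, p + 2L, nchar(var)))
        else
          var <- paste0(substr(var, 1, p),
                        substr(var, p + ev$len[i] + 1L, nchar(var)))
      }
      ev$transcript_id <- txid
      manifest[[length(manifest) + 1L]] <- ev
    }
    variants[[txid]] <- var
  }
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(pos = integer(), type = character(), len = integer(),
               alt = character(), transcript_id = character())
  list(variants = variants,
       manifest = manifest[, c("transcript_id", "pos", "type", "len",
                               "alt")])
}

#' Simulate paired-end reads with a truth table
#'
#' Fragment origins are drawn multinomially from the supplied (or log-normal
#' sampled) abundances over the transcript sources, with an optional
#' fraction drawn uniformly from unannotated planted loci. Fragment lengths
#' are normal (truncated to the read length and source length); positions are
#' uniform; both mates receive independent per-base substitution errors.
#' The abundance vector is drawn from its own RNG stream, so varying only
#' the seed of the read stream preserves it (replicate designs).
#'
#' @param sources named character vector of transcript sequences.
#' @param config a [SimConfig-class].
#' @param truth optional named numeric vector of relative abundances over
#'   `sources`; drawn log-normal when `NULL`.
#' @param unannotated optional named character vector of planted locus
#'   sequences; `config@fracUnannotated` of fragments originate here.
#' @return A list with `reads1`, `reads2` (named character vectors),
#'   `truth` (data.frame per fragment: `fragment`, `origin_class`
#'   (`TRANSCRIPT`/`UNANNOTATED_LOCUS`), `origin_id`, `origin_pos`,
#'   `frag_len`), `txCounts` (named true fragment counts per transcript)
#'   and `abundance` (the relative abundance vector used).
#' @export
simulateReads <- function(sources, config = simConfig(), truth = NULL,
                          unannotated = NULL) {
  sources <- asSeqVector(sources)
  if (is.null(truth)) {
    set.seed(opSeed(config@seed, "abundance"))
    truth <- setNames(rlnorm(length(sources), config@abundanceMeanlog,
                             config@abundanceSdlog), names(sources))
  }
  truth <- truth / sum(truth)
  set.seed(opSeed(config@seed, "reads"))
  rl <- config@readLength
  usable <- nchar(sources) >= rl
  if (any(!usable)) {
    warning(sum(!usable), " source(s) shorter than the read length skipped")
    truth <- truth[usable] / sum(truth[usable])
    sources <- sources[usable]
  }
  nFrag <- config@nFragments
  fromPlant <- if (!is.null(unannotated) && length(unannotated) > 0 &&
                   config@fracUnannotated > 0)
    runif(nFrag) < config@fracUnannotated else rep(FALSE, nFrag)
  originId <- character(nFrag)
  originId[!fromPlant] <- sample(names(sources), sum(!fromPlant),
                                 replace = TRUE, prob = truth)
  if (any(fromPlant))
    originId[fromPlant] <- sample(names(unannotated), sum(fromPlant),
                                  replace = TRUE)
  allSeqs <- c(sources, if (!is.null(unannotated)) asSeqVector(unannotated))
  srcLen <- nchar(allSeqs)[match(originId, names(allSeqs))]
  fragLen <- pmin(pmax(rl, round(rnorm(nFrag, config@fragMean,
                                       config@fragSd))), srcLen)
  pos <- floor(runif(nFrag) * (srcLen - fragLen + 1))
  names1 <- sprintf("frag%06d", seq_len(nFrag))
  src <- allSeqs[match(originId, names(allSeqs))]
  m1 <- substring(src, pos + 1L, pos + rl)
  m2raw <- substring(src, pos + fragLen - rl + 1L, pos + fragLen)
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(m2raw)))
  if (config@errorRate > 0) {
    addErr <- function(v) vapply(v, mutateSubstitutions,
                                 character(1), rate = config@errorRate,
                                 USE.NAMES = FALSE)
    m1 <- addErr(m1)
    m2 <- addErr(m2)
  }
  txCounts <- table(factor(originId[!fromPlant], levels = names(sources)))
  list(reads1 = setNames(m1, names1), reads2 = setNames(m2, names1),
       truth = data.frame(
         fragment = names1,
         origin_class = ifelse(fromPlant, "UNANNOTATED_LOCUS", "TRANSCRIPT"),
         origin_id = originId, origin_pos = pos, frag_len = fragLen),
       txCounts = setNames(as.numeric(txCounts), names(sources)),
       abundance = truth)
}

#' Run the full synthetic-experiment generator
#'
#' Genome + annotation, optional unannotated plants, optional variant
#' transcriptome, and reads with truth, in one call.
#'
#' @param config a [SimConfig-class].
#' @param variant also generate a variant transcriptome?
#' @param readsFrom which transcriptome the reads are simulated from:
#'   `"reference"` (default) or `"variant"`.
#' @return A list combining the outputs of the individual generators.
#' @export
simulateExperiment <- function(config = simConfig(), variant = FALSE,
                               readsFrom = c("reference", "variant")) {
  readsFrom <- match.arg(readsFrom)
  sim <- makeGenomeAndAnnotation(config)
  sim <- plantUnannotatedCopies(sim, config)
  if (variant || readsFrom == "variant") {
    vt <- makeVariantTranscriptome(sim$transcriptome, config)
    sim$variantTranscriptome <- vt$variants
    sim$variantManifest <- vt$manifest
  }
  srcTx <- if (readsFrom == "variant") sim$variantTranscriptome else
    sim$transcriptome
  rd <- simulateReads(srcTx, config, unannotated = sim$plantSeqs)
  c(sim, rd)
}

#' Write exon annotation to GTF
#'
#' @param exons exon data.frame (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(exons, path) {
  lines <- sprintf(
    "%s\tselalign\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id)
  writeLines(lines, path)
  invisible(path)
}
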