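---
title: "Selective alignment with decoys: model, parameters, and design notes"
author: "selalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective alignment with decoys: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selalign)
```

## The model

RNA-seq abundance estimation treats each sequenced fragment as a draw from
a mixture over transcripts: the probability of observing fragment $f$ is
$\sum_t \eta_t \, P(f \mid t)$, where $\eta_t$ is proportional to transcript
abundance times effective length. Everything upstream of the estimator
exists to decide, per fragment, *which* transcripts are plausible origins
and with what conditional weight — and, crucially, whether the fragment
plausibly originates from annotated transcription at all.

Selective alignment makes that decision in five phases per fragment, on an
index holding transcripts *and* decoy sequences in one k-mer space:

1. **uni-MEM collection.** The index is a compacted de Bruijn graph:
   unitigs are maximal non-branching paths over canonical k-mers
   (lexicographic minimum of a k-mer and its reverse complement), built
   from catalog sequences split at `N` runs. A uni-MEM is a maximal exact
   match between a read and a single unitig, found by k-mer lookup and
   base-by-base extension until a unitig end, the read end, or a mismatch.
   After a termination the search resumes one position past the last
   anchored k-mer start, which guarantees no maximal match is skipped at
   the cost of a bounded number of extra lookups.
2. **Projection and collation.** Each uni-MEM expands to one exact-match
   anchor per occurrence of its unitig; anchors are grouped by (reference,
   orientation). For reverse-complement groups, read coordinates are
   reflected onto the reverse-complemented read so co-linearity holds in
   both coordinates. An optional pre-chaining filter discards groups whose
   total anchor bases fall below $\tau M$ ($\tau = 0.65$; off by default —
   we count *bases* rather than anchor counts because base count is
   monotone in evidence and insensitive to uni-MEM fragmentation at unitig
   boundaries).
3. **Chaining.** Anchors are compacted (runs exactly adjacent on read and
   reference merged) and chained with the classical co-linear chaining
   dynamic program: $f(i) = w_i + \max(0, \max_j f(j) - \mathrm{cost}(j,i))$
   with gap cost $a\,d + b\log_2(d{+}1)$ on the difference $d$ between read
   gap and reference gap, and a once-per-base penalty for overlapped spans.
   All co-optimal chains are kept (capped at 200, deterministic order); a
   post-chaining filter drops chains below $\tau' S$ of the read end's best
   score ($\tau' = 0.65$, on by default).
4. **Pair merging.** Chains of the two ends merge when they lie on the same
   reference with opposite orientations, the reverse-complement end starts
   at or right of the forward end (otherwise the pair is a *dovetail*), and
   the fragment span is at most 1000 bases. Orphans (one end unmapped) and
   dovetails are disallowed by default; when dovetails are allowed they
   rank strictly below every concordant mapping and enter scoring only if
   no concordant candidate exists.
5. **Extension scoring and the decoy rule.** Each candidate is scored —
   score only, never a CIGAR — as the sum of exact-match contributions plus
   optimal affine-gap alignment of the inter-anchor gaps (global) and of
   the read flanks (free leading/trailing reference bases within a padded
   window). A per-read cache keyed by the target substring avoids repeating
   identical alignments, e.g. across duplicate transcripts. The minimum
   valid score is 0.65 of the maximum obtainable score (match score times
   fragment base count). If the best score to a decoy *strictly* exceeds
   the best score to any transcript, the fragment is status `DECOY` and
   contributes nothing downstream; ties go to the transcriptome.

Aligned fragments become **range-factorized equivalence classes**: per
fragment, mapping weights are a softmax over alignment scores (temperature
$1/\mathrm{match}$, so equal-best mappings split evenly and each additional
mismatch suppresses a mapping by $e^{12}$ under default scores), summed per
transcript, and quantized into 4 equal bins so that fragments with the same
transcript set but different weight profiles occupy different classes.
A plain EM then maximizes the class-level likelihood (uniform
initialization, relative tolerance $10^{-8}$, cap 10 000 iterations); counts
are conserved exactly at every iteration and the log-likelihood trajectory
is returned for inspection. TPM uses effective lengths
$\max(1, \ell_t - \bar{\ell}_{\mathrm{frag}} + 1)$.

## Decoy extraction

Decoys answer the question "is there genomic sequence, outside annotated
exons, that resembles a transcript closely enough to attract its reads?"
All exon bases are hard-masked with `N`; transcripts are cut into 500-bp
segments (a trailing remainder of at least half a segment is kept; shorter
transcripts yield no segments); candidate genomic windows are located by
shared (16, 10)-minimizers; and the best-supported window's identity is
estimated from the Jaccard $j$ of the full canonical 16-mer hash sets via
the Mash relation $\mathrm{id} = 1 + \ln(2j/(1{+}j))/k$. Windows reaching
80% estimated identity are reported, merged per chromosome (overlapping or
adjacent intervals unioned), padded by half a segment, and the underlying
*unmasked* sequence is concatenated into one decoy record per chromosome.

Two choices here were genuinely open:

* **Identity from full k-mer sets, not a 64-hash sketch.** At the 80%
  reporting boundary a 64-hash minhash sketch shares only one or two hashes
  in expectation, so the estimate is dominated by Poisson noise; the sparse
  minimizer set (~90 hashes per segment) shares about 7. The full canonical
  k-mer sets share about 20 at 85% identity, which keeps per-segment recall
  above 0.95 there while still reporting nothing at 50% identity. The
  minimizers are retained for what they are good at — locating the
  candidate window. A sketch size remains configurable for users who want
  the cheaper estimator. Windows whose k-mer set is smaller than half the
  segment's are rejected: an `N`-dominated window has a tiny hash union,
  which can inflate the Jaccard past the threshold while carrying no real
  similarity.
* **Padding merged intervals by half a segment before extraction.** A
  segment hit locates similarity only at segment resolution: a similar
  locus whose final partial segment was below the tiling threshold extends
  past the last hit, and fragments from that tail would otherwise find no
  decoy at all. Padding into genic flanks is safe because the decoy rule
  requires a *strictly* greater decoy score — a decoy that merely ties a
  transcript never claims its reads. Measured on planted loci at 90%
  identity, padding raises the fraction of plant-origin fragments
  classified `DECOY` from 0.87 to over 0.99 without touching any
  transcript-origin fragment.

## Oracle curation and the indel ratio

Given transcriptomic alignments from one aligner and genomic alignments
from another, fragments mapped to the transcriptome and to the genome but
*not* projected to the transcriptome by the second aligner are candidates
for removal. Both alignments are scored by matched bases only — 1 per
match, 0 for soft clips, mismatches, and indels, with intron skips (`N`)
neither penalized nor rewarded — by reconciling the CIGAR string with the
MD tag. Per end, the maximum over that end's records is taken (secondary
records participate) and ends are summed; the fragment's transcriptomic
records are removed only when the genomic score is strictly greater, so
equal-quality transcriptomic alignments are retained.

The indel ratio of a variant transcript is the total inserted plus deleted
bases in a minimal-edit-cost global alignment against its reference,
divided by the reference length. Ties are broken toward substitutions
(gap cost 1.01 per base against mismatch cost 1), so an isolated planted
indel is never re-explained as a substitution cluster.

## What the generator emulates — and what it does not

The synthetic-data module generates, under a single seed: an annotated
multi-gene genome (multi-exon genes on both strands, intergenic spacers;
splicing the genome by the annotation reproduces the transcriptome
byte-for-byte), planted unannotated loci (substitution-mutated transcript
copies replacing intergenic sequence in place, each resembling a *distinct*
transcript — the segment mapper reports one best window per segment, so two
plants of one transcript could never both be recalled), variant
transcriptomes (SNVs at 0.7%/bp and indels at 0.15%/bp, lengths
1 + geometric with mean 2, a 10-bp minimum spacing between events so the
planted edit script is the unique minimal alignment and the indel ratio
reproduces the manifest exactly), and paired-end reads (100 bp, fragment
length normal(250, 25), uniform substitution errors, constant Phred 35
qualities, log-normal expression). Each operation draws from its own RNG
stream derived from (seed, operation name), so adding plants does not
perturb read simulation. The variant rates are of the order observed
between inbred mouse strains and their reference; the error rate (0.5% by
default, 1% in the recovery experiments) brackets typical short-read
platforms.

What passing tests on these data do **not** show about real data: the
generator draws reference sequence uniformly at random, so it contains no
paralogous gene families, no repeat elements, no GC or positional coverage
bias, no fragment-length/position terms in the conditional probabilities
(both uniform here, as quantification holds inference fixed to a plain EM),
no quality-aware scoring, and no spliced (intron-spanning) alignment —
selective alignment is deliberately not splice-aware, which is why decoy
alignments are only reported when they are contiguous. Multi-mapping in
these simulations arises almost entirely from deliberately duplicated or
planted sequence rather than from the pervasive isoform sharing of real
transcriptomes, so recovery correlations here are upper bounds on what any
method would achieve on real annotation.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; 1-based
  conventions appear only in SAM/GTF (de)serialization.
* Canonical k-mers make the index strand-symmetric at half the table size.
  For odd k (default 23; tests use 5–11) no k-mer is its own reverse
  complement. The walk is additionally cut wherever two *consecutive*
  k-mers share a canonical form: self-reverse-complement repeats (e.g.
  `AT` alternations) would otherwise place one k-mer at two offsets of a
  single unitig. Even k can create palindromic k-mers and is rejected with
  an explicit error if a duplicate placement arises.
* Chaining ties in the DP are enumerated toward smaller reference starts;
  co-optimality is exact equality of the DP value (enumeration uses a
  $10^{-9}$ slack only to absorb floating-point addition order).
* Extension DP flanks use a window of flank length + 8 reference bases;
  inter-anchor gaps are aligned exactly (they are short by construction).
  Reads hanging off a reference end pay gap costs for the overhang.
* The decoy comparison uses raw best scores, before the 0.65 threshold is
  applied to the survivors: a fragment that aligns poorly everywhere but
  best to a decoy is reported as `DECOY`, not `UNALIGNED`, which matches
  the rule's purpose of flagging fragments better explained elsewhere.
* Degenerate inputs: reads shorter than k map nowhere (with a notice);
  all-`N` reads produce no k-mers; transcripts shorter than k are indexed
  but un-anchorable; an empty equivalence-class table yields an all-zero
  estimate with a warning; a transcript identical in sequence to a decoy
  is rejected at catalog construction because precedence would be
  undefined.
* A fragment with one mapped end is discarded under the default
  no-orphan policy even if the mapped end is perfect; this mirrors the
  normalization applied to the external aligners the method is compared
  against.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
sizes chosen to exercise every code path while staying comfortable on one
core: oracle-equivalence checks use 500 random instances each; cache
soundness uses 10 000 fragments against a deliberately duplicated
transcriptome; the decoy experiments use 40 genes, 12 planted loci and
3 000 fragments; the extraction sweep plants 20 loci per identity in
{0.95, 0.85, 0.80, 0.70, 0.50}; abundance recovery uses 200 transcripts and
50 000 paired fragments at 1% error; the variant comparison uses 200
transcripts and 20 000 fragments. These sizes give recovery correlations
within a few thousandths of 1 and binomially tight classification rates;
they are not a performance benchmark.

## Known limitations

Beyond the generator's idealizations listed above: the hash-table index
trades the memory economy of succinct data structures for simplicity, so
genome-scale decoy sets (the mode where the whole genome is the decoy) are
feasible only at desk scale; abundance uncertainty (bootstrap/posterior
sampling) and bias correction are out of scope; and the conditional-weight
softmax is a stand-in for richer per-fragment probability models — it is
exposed through the match-score temperature rather than hidden, and with
range factorization at 4 bins its effect on the sufficient statistics is
what the tests exercise.
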