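---
title: "Classifying graft and host cellular barcodes with xenosplit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying graft and host cellular barcodes with xenosplit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenosplit)
```

## The model

Sequencing a xenograft sample yields reads from two species: the graft
(e.g. human tumor cells) and the host (e.g. mouse stroma and immune
cells). In droplet single-cell protocols every read pair carries a
cellular barcode on R1 and cDNA on R2, so contamination acts at the level
of whole barcodes: a barcode is a graft cell, a contaminating host cell,
or a cross-species doublet. `xenosplit` decides which, using only k-mer
composition — no alignment — in two steps.

**The index.** Let $G$ and $H$ be the sets of canonical $k$-mers of the
graft and host references. A canonical $k$-mer is
$\min(s, \mathrm{revcomp}(s))$ under lexicographic order, which makes
membership strand-neutral: a read and its reverse complement always carry
the same canonical $k$-mers, so sequencing strand never influences
classification. The index stores the partition
$\{G \setminus H,\; H \setminus G,\; G \cap H\}$; the three collections
are disjoint by construction and their union covers both genomes, which
the package asserts as a class invariant.

**Read classes.** For a read, count its valid (ACGT-only) $k$-mers in
each collection: $n_g$ graft-specific, $n_h$ host-specific, $n_s$ shared,
$n_u$ unindexed. The read's class is

| condition | class |
|---|---|
| $n_g > 0$ and $n_h = 0$ | graft |
| $n_h > 0$ and $n_g = 0$ | host |
| $n_g > 0$ and $n_h > 0$ | ambiguous |
| $n_g = n_h = 0$, $n_s > 0$ | both |
| otherwise | neither |

This is the minimal decision rule consistent with the class names: a read
is unambiguously assigned exactly when it has species-specific evidence
from one species only. Reads shorter than $k$, or whose $k$-mers are all
novel (sequencing errors, unindexed sequence), are `neither`. We make no
attempt to reproduce the internal evidence thresholds of binary k-mer
classifiers at the byte level; an optional `minSpecific` knob (default 1)
lets users require more than one specific $k$-mer before calling a
species, but the default keeps the pure rule.

**Barcode fractions.** Per barcode $b$,
$\mathrm{fraction\_host}(b) = n_{host}(b) / n_{total}(b)$ with
$n_{total}$ counting **all** reads of the barcode over the five classes
— not only the classified ones. Using the all-reads denominator means a
barcode with many ambiguous or unmapped reads cannot masquerade as pure.

**Extraction.** Step B selects barcodes whose host fraction lies in a
closed interval $[\ell, u]$ and streams out the corresponding pairs of
one class. Both endpoints are inclusive, reading "at most 10%" as $\le$
and "at least 90%" as $\ge$. Selection is always expressed on the host
fraction axis; the graft-side phrasing is its complement and deliberately
not a second code path. The output contains only the graft-classified (or
host-classified) reads of the selected barcodes: ambiguous, both and
neither reads are dropped with the rest of their class, which is what
makes the filtered FASTQ safe for a single-species aligner.

## Parameters that matter

* `k` (default **25**, range 3–31): the species-specificity/robustness
  trade-off. Longer $k$-mers are more species-specific but more fragile
  to sequencing errors (one substitution invalidates up to $k$ window
  positions). 25 is the convention of k-mer based read-deconvolution
  tools and fits in a 2-bit-packed 64-bit word, which is how the index
  and the scanner encode $k$-mers internally.
* `BarcodeGeometry` (`barcodeStart`, `barcodeLength`, 1-based inclusive):
  where the barcode sits on R1, e.g. positions 1–16 for 10x Chromium v3.
  UMI bases are carried through verbatim and never deduplicated —
  deduplication belongs downstream of alignment.
* Thresholds: `[0, 0.1]` (graft) and `[0.9, 1]` (host) are sensible
  defaults for a clearly bimodal host-fraction distribution; tighten them
  for aggressive purification, widen them if the reference genomes are
  distant and classification is clean.

## Numerical and edge-case choices

* Lowercase (soft-masked) reference bases are uppercased and kept;
  $k$-mers containing any non-ACGT symbol are skipped entirely, both in
  the index and in reads. This is the simplest deterministic rule and
  makes masked references and N-containing reads behave predictably.
* Barcodes containing N (or too-short R1) are discarded and counted in
  the run log, never error-corrected: the tool operates before
  whitelisting, and correction is the cell caller's job.
* All text outputs are byte-reproducible: $k$-mer files are byte-sorted,
  barcode tables are sorted by barcode in byte order with fractions fixed
  at 6 decimals, and gzip streams carry no timestamps. Equal inputs give
  byte-identical outputs, which the test suite asserts with checksums.
* Boundary selection ($\mathrm{fraction\_host} = u$ exactly) is decided
  on fractions recomputed from the integer counts, so CSV rounding cannot
  flip an inclusive bound.
* FASTQ streaming is chunked (50 000 pairs per chunk by default); memory
  scales with the number of distinct barcodes, not with read count.
  Record pairing is verified chunk-wise (equal counts, matching headers
  ignoring `/1`/`/2` and read-number suffixes) and violations are fatal
  with the offending record index.

## What the simulator emulates — and what it does not

`simulateExperiment()` generates the study design the package is
validated on: two uniform-random references (default 2 × 100 kb) with an
optional leading block of the host genome copied from the graft
(`sharedFraction`, a stand-in for interspecies sequence conservation);
barcodes assigned graft / host / doublet identities (defaults: 1:1
graft:host with a 5% doublet rate, emulating a balanced mixed-species
experiment with contaminating host cells); per-read source genomes drawn
from the barcode's true host mixing proportion (doublets uniform on
[0.3, 0.7], placing them inside the excluded interval of the default
regimes); and per-base substitution errors (default 0.5%). Defaults of 90
bp reads and 16 bp barcodes mirror a 10x v3-like library.

It deliberately does **not** model transcriptome structure (reads are
genomic, uniformly placed), UMI duplication, ambient RNA, indels, or
quality-score variation. Passing tests therefore demonstrate the
correctness of the classification and filtering machinery under known
truth — not that any particular $k$ or threshold is optimal for a given
real tissue, where conserved transcripts inflate the `both`/`ambiguous`
classes and the host-fraction distribution is less cleanly bimodal.

Substitution-only errors are enough here because k-mer membership is what
is under test: an indel, like a substitution, simply invalidates the
windows covering it.

## Problem sizes used in the checks

The package validates itself at desk scale, chosen so the full suite runs
in minutes on one CPU: oracle comparisons use two 10 kb genomes
($k = 11$) and 1 000 reads of 60 bp against a brute-force oracle that
scans the genome strings directly; the end-to-end study uses the
simulator defaults above (80 000 read pairs, $k = 25$). Real human+mouse
indexes need tens of gigabytes of RAM and are out of scope for the
in-memory hash index used here; the serialized index format (sorted
$k$-mer text per class plus metadata) is designed for inspection and
reproducibility, not for full-genome scale. Succinct index structures
(FM-indexes, Bloom filters) are a known limitation, not a goal.

## Known limitations

* No rescue of `ambiguous` reads (e.g. by alignment) and no
  multiplet detection beyond interval exclusion.
* No barcode error correction; a barcode one substitution away from a
  whitelisted one is simply discarded when a whitelist is supplied.
* Closely related host/graft pairs shrink the species-specific k-mer
  sets; users should inspect the `both`/`ambiguous` totals in the run log
  before trusting tight thresholds.
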