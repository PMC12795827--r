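---
title: "Methods: binding-site localization and competitive cis-regulation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site localization and competitive cis-regulation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genome-wide in vitro binding assays such as DAP-seq report *binding
regions* — peaks, typically longer than 150 bp — while the DNA word a
transcription factor (TF) actually recognizes is usually shorter than
20 bp. Questions about the *mutual arrangement* of binding sites (BSs) in
a promoter (do two TFs contend for one spot? do they sit side by side?)
therefore cannot be answered from peaks alone. `compcis` closes that gap:
it localizes motif-level BSs inside peak-level binding regions on gene
5'-regulatory sequences, links TF regulators to differentially expressed
target genes (DEGs) that mediate enriched Gene Ontology (GO) biological
processes, and from the arrangement of the localized BSs calls candidate
*competitive* and *cooperative* regulation.

The regulator vocabulary follows the standard four-class scheme combining
a TF's own expression response with its predicted mode of regulation:
up-regulated activator (UA), up-regulated suppressor (US), down-regulated
activator (DA) and down-regulated suppressor (DS). UA/US form the
stimulus-activated "A" subnetwork, DA/DS the repressed "R" subnetwork.

## Promoters and coordinates

The 5'-regulatory region of a gene is the `L` bases immediately upstream
of its transcription start site (TSS): TSS-relative positions
`[-L, -1]`, excluding the TSS base itself (the upstream interval is
half-open at the TSS). `L` is one of 500, 1000, 2000 or 2500 bp; the
driver's default is 1,000 bp. Internally all intervals are 0-based
half-open (BED convention); displayed genomic coordinates are 1-based
inclusive and TSS-relative coordinates use the no-zero convention (the
base before the TSS is −1, the TSS base is +1; there is no 0). Promoters
of minus-strand genes are reverse-complemented so every promoter sequence
reads 5'→3' along its gene. Promoters that would cross a contig edge are
truncated rather than dropped, which keeps the gene universe stable for
enrichment. Multi-isoform TSS selection is out of scope: one TSS per gene,
taken from the `gene` feature of the annotation.

## Motif model and score calibration

Motifs enter as position frequency matrices (JASPAR raw counts, or
MEME-minimal probabilities converted back to counts via `nsites`). The
position weight matrix adds a total pseudocount `alpha = 1` distributed in
proportion to the background `b` and scores in log2-odds ("bits"):

$$ w_{i}(n) = \log_2 \frac{(c_i(n) + \alpha\, b_n)\, /\, \sum_m (c_i(m) + \alpha\, b_m)}{b_n}. $$

All scores live on a fixed grid of 1/1000 bit: weights are rounded to
integers on that grid, and scanning, cutoff calibration and the testing
oracle share that one score definition, so "exact" has a precise meaning.

No scanning threshold is inherited from the literature here; the default
is distribution-calibrated. `calibrate_cutoff()` computes the full score
distribution of a random background word by dynamic programming over
positions and returns the smallest grid score whose tail probability
`P(score >= cutoff)` is at most `p_scan` (default `1e-4`). Ties at the
cutoff are included. For very short motifs the consensus itself can be
more probable than `p_scan` (e.g. `4^-6 > 1e-4` under a uniform
background); the cutoff then falls back to the maximum score with a
warning, and downstream rate checks use the *attained* tail probability,
not the nominal one. An alternative fraction-of-maximum style threshold
can be emulated by passing `p_scan = 1`, but the calibrated default is
preferred because it behaves consistently across motif widths.

The scanning background defaults to the nucleotide composition of the
scanned promoter set (reducing false positives in AT-rich plant
promoters), with a uniform option. The composition is symmetrized over
complementary bases (A with T, C with G) so that a single calibrated
cutoff is valid on both strands; both strands of every promoter window are
scanned, overlapping hits of one TF are all reported (downstream overlap
analysis needs every placement), and each hit records its gene-relative
orientation (sense/antisense), genomic strand, matched word as read on the
matched strand, and both genomic and TSS-relative spans. Ambiguity codes
(N) contribute 0 bits at their position.

`compare_motifs()` is deliberately lightweight — the maximum column-wise
Pearson correlation over all offsets (aligned width ≥ 4) and both
orientations. It is a convenience check for "did we find the same
motif?", not a statistically calibrated motif comparison; E-value style
motif matching is explicitly out of scope.

## Linking regulators to targets

Peak sets come per TF, tagged with the library dialect: `col` (native
genomic DNA) or `colamp` (PCR-amplified, demethylated DNA). Per set the
top 2,000 peaks by height are kept (ties broken deterministically by
coordinate), and by default only `col` sets are used — both behaviors are
configurable. A peak becomes a *binding region* of a gene when it overlaps
the gene's promoter by at least 1 bp (configurable); a scan hit becomes a
localized *binding site* when its span is fully contained in a same-TF
binding region on the same gene (a partial-overlap mode exists behind a
flag; containment is the default reading of localizing a BS "in" a
region).

The DEG list is tested for GO biological-process over-representation with
the one-sided hypergeometric tail, `p = P(X >= k)` for a term annotating
`K` of `N` universe genes with `k` of `n` DEGs. The threshold, 0.001 by
default, applies to raw p-values; a Benjamini–Hochberg mode is available
behind a flag since the upstream convention does not state an adjustment.
The universe defaults to every gene in the annotation table and is
overridable. Annotations are consumed as-is, assumed pre-propagated up the
GO graph — no ontology traversal is performed. Regulator–target pairs are
then formed for every (TF, gene) with at least one localized BS on a DEG
annotated to at least one enriched term, and two result tables are
written: block 1 (one row per target gene, with GO terms and evidence
codes, regulator TFs with families, and per-BS sequence, TSS-relative
coordinates and strand) and block 4 (one row per gene × GO term × TF ×
BS, with 1-based inclusive genomic coordinates and the genomic strand).

## Competition and cooperation calls

Within each target gene the localized BSs are clustered by single linkage
under the relation "overlap fraction > 0.8", where the overlap fraction of
two spans is the intersection length divided by the *shorter* span length
(the shorter-span denominator captures shared-core competition between
motifs of unequal width; the bound is strict). Strand is ignored —
competition is for the DNA locus — though strands are reported. A cluster
is a competition candidate if it carries sites of at least two TFs whose
own-expression directions include both up and down; every
opposite-direction pair whose sites directly exceed the overlap bound is
reported, so multi-TF clusters yield all their competing pairs.

Mechanisms are interpreted with effector-domain activities: after the
stimulus the up-regulated TF displaces the down-regulated one at the
shared site, so a weaker incoming activator with a down-regulated target
is labelled `suppression_by_weak_activator_replacement`, a stronger
incoming activator with an up-regulated target
`activation_by_strong_activator_replacement`; contradictory orderings are
honestly labelled `unexplained` (such cases exist in real data), and
candidates lacking activity data `insufficient_activity_data`.

Cooperation detection is an explicit extension of the same machinery: site
pairs of two distinct TFs in one subnetwork that do *not* meet the
competition overlap criterion, lie within a 50 bp gap (a package default,
not a literature constant), and where at least one TF's predicted mode
contradicts its measured effector activity — the signature of a partner
converting an activator into a repressor. Competition and cooperation are
mutually exclusive per site pair by construction.

`summarize_candidates()` tallies candidate genes by direction category
(down, up, bidirectional across experiments — genes responding in opposite
directions in two experiments form their own category), reports the total
and, given the number of suppressor-regulated genes, that total as a
percentage rounded to the nearest integer, plus per-family and
per-superclass tallies of the competing pairs.

## The synthetic universe and what it shows

`generate_fixture()` emits a complete seeded input set — genome FASTA,
GFF3, MEME motifs, per-TF dialect-tagged BED peak sets, DEG/GO/TF-metadata
TSVs — plus a ground-truth manifest, so every stage has an oracle. The
default scale is 2 chromosomes × 100 kb, 60 genes (alternating strands),
8 TFs with motif widths 6–10, `L = 1000`, peaks of 150–300 bp jittered
around planted sites, 10 down- and 10 up-DEGs in a 60-gene universe, and
one GO term built to be enriched far below the 0.001 threshold. These
sizes keep exhaustive oracles (all `4^w` words for `w <= 8`) and the full
test suite fast while preserving the structure of real inputs.

Design points worth knowing:

* **Planted sites are exact consensus words** (sharp 85-vs-5 count
  columns), so recovery is threshold-robust; the calibrated-cutoff
  behavior on near-misses is exercised separately by the score
  distribution itself.
* **Competition clusters use 1-shifted consensus pairs**: the second TF's
  word is the first word shifted by one position, so two exact words can
  physically co-occupy one locus at overlap `(w-1)/w > 0.8` of the
  shorter site. Decoys are a 2-shifted pair (overlap `6/8 = 0.75`, below
  the bound, with opposite directions) and a 1-shifted pair of two
  same-direction TFs (overlap 0.9, concordant).
* **Consensus panels are screened**: random panels are redrawn until no
  TF's word (either orientation) can lie across another TF's planted word
  at > 0.8 overlap with too few mismatches to be rejected by the
  calibrated cutoff (two mismatches for opposite-direction TF pairs, one
  otherwise). This makes manifest recovery exact rather than
  almost-surely-exact.
* **Fourteen genes stay pristine** (no plantings), so false-positive hit
  counts can be compared to the calibrated tail probability as a binomial
  check uncontaminated by shift-partner words.
* **Off-peak decoy sites** are planted with only `colamp` coverage; a
  `col`-filtered run must drop them at localization, which is how the
  dialect filter is validated end to end.

What passing on this universe does *not* show: the generator draws i.i.d.
background sequence, plants exact-match sites and builds clean peaks. Real
promoters have repeats and composition structure, real motifs are degenerate,
and real peaks have noisy boundaries — so recovery rates here are upper
bounds on real-data behavior, and the pipeline's value on real data rests
on the calibrated statistics, not on these recoveries.

## Numerical choices and degenerate inputs

* Score discretization: 1/1000 bit; this grid *defines* exactness for the
  dynamic program and its enumeration oracle (probabilities are compared
  at 1e-12, since float sums depend on association order).
* Ties: at the score cutoff, included; in top-peak selection, broken by
  (chrom, start); among multiple containing regions, the widest supports
  the site.
* Zero-length spans are rejected in overlap computations; promoters
  shorter than a motif are skipped per motif with a message; genes whose
  annotation lacks a strand are excluded with a warning; duplicate gene
  ids are an error.
* All outputs are deterministic functions of the inputs: re-running a
  configuration reproduces block and candidate files byte for byte.

## Limitations

* Activator/suppressor modes are taken from upstream metadata, not
  inferred here.
* No GO graph reasoning, GAF parsing or term collapsing.
* Cooperation calling operationalizes a described mechanism with a
  package-chosen window; treat its candidates as hypotheses ranked below
  competition candidates, whose criteria are fully specified.
* Whether a BS must overlap the promoter-restricted part of its peak or
  the whole peak is ambiguous upstream; the whole peak is used, with
  containment against the promoter enforced separately.
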