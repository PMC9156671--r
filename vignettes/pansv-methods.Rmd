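---
title: "Methods: structural-variant analysis of pangenome graphs with pansv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural-variant analysis of pangenome graphs with pansv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pansv)
```

`pansv` analyses structural variation (SV) in reference-backed pangenome
graphs of the kind produced by iterative assembly-to-graph construction,
where each assembly either follows existing sequence or, when it diverges by
more than 50 bp, adds new nodes that open *bubbles* — source–sink subgraphs
whose interior paths are the alleles at one variant site. This vignette
documents the models and procedures, the parameters that matter, the
numerical choices, what the simulator does and does not emulate, and the
design decisions taken where the design was genuinely open.

## Graph model and bubble detection

A `pangenome_graph` holds segments tagged with origin sample, origin offset
and rank (rank 0 = the reference backbone, which must tile each chromosome
contiguously) plus oriented links. Bubble detection operates on the
oriented-copy digraph (each segment contributes a forward and a reverse
copy; each link induces its reverse-complement mirror), so graphs with
reverse-orientation links are handled even though inversion *calling* is out
of scope.

`detect_superbubbles()` finds, for every forward rank-0 segment, the minimal
superbubble starting there, using a frontier search that only visits a node
once all of its parents have been visited. This construction guarantees the
defining properties directly: every path from the entry reaches the exit,
interior nodes are reachable only between entry and exit, and the interior
is acyclic. Sites are reported only when entry and exit are forward rank-0
segments and at least two distinct allele paths exist (a plain chain is not
a variant site). Nested bubbles are suppressed — only outermost sites are
reported, matching the flat per-bubble analyses this package feeds — so
reported interiors are disjoint. The detector is validated against an
independent brute-force oracle (exhaustive path enumeration over every
ordered node pair) on hundreds of random graphs in the test suite.

Bubble coordinates project onto the backbone: `ref_start` is the end of the
entry segment, `ref_end` the start of the exit segment, so
`ref_end - ref_start` equals the reference-allele interior length. The
reference path (forward rank-0 interior, or the direct edge when the
interior is empty) is always allele 0.

**SV typing.** Each non-reference allele is typed by the same 50 bp
threshold that governs graph divergence: `INS` when the reference interior
is short (< 50 bp) and the alternate long (>= 50 bp), `DEL` in the mirror
case, `COMPLEX` otherwise. No separate typing threshold is introduced
because none is established for this graph construction; the threshold is
exposed as `min_len` should one be wanted.

## Haplotype walks and the allele matrix

Walk files use a six-column BED dialect (`chrom, start, end, source, sink,
path`), with `"."` marking a missing walk and a permissive reader flag for
real callers that append extra columns. `build_allele_matrix()` keys walks
by `(chrom, ref_start, ref_end)`; an entry is the index of the walk's path
among the distinct paths observed at that bubble (reference = 0). Records
matching no bubble are dropped with a warning count; multiple records for
one site and assembly are *ambiguous* and treated as missing, as are absent
records. `filter_complete()` removes sites missing in any assembly — the
completeness filter applied before gene-overlap work — and is idempotent.

## Discordance, UPGMA and topology classes

The pairwise distance between assemblies is the count of *mutually
exclusive bubbles*: sites where both walks are present but take different
paths. Multi-allelic sites count once regardless of how much the paths
differ. Missing handling is pairwise-complete so partially phased assemblies
still contribute; a `normalize` option divides by the per-pair number of
jointly non-missing sites (the raw count is the default because the
downstream classification is scale-invariant either way).

`upgma()` is implemented directly rather than through `hclust` because its
contract needs two guarantees `hclust` does not make: merge heights are
*half* the mean inter-cluster distance (so ultrametric inputs are recovered
exactly, heights included), and ties break deterministically by the
lexicographically smallest member label. On tie-free inputs it agrees with
average-linkage `hclust` (asserted in tests); `ape::rcoal` trees serve as
exact-recovery oracles.

`classify_topology()` encodes the five-taxon question asked of the SV
dendrograms: with outgroups peeling off in the fixed order (`G` outermost,
then `N`), which of the three ingroup taxa (`O`, `P`, `B`) splits first?
Any violation of the outgroup order returns `OTHER`. The classification is
validated against a clade-membership check over all 105 labelled rooted
binary five-leaf topologies.

## Consensus between SV sets

`match_sv_sets()` matches two sorted catalogues greedily left-to-right: same
chromosome, same type, start positions within `breakpoint_tolerance`
(default 100 bp) and length ratio (shorter/longer, with length =
max(ref_len, alt_len)) at least `length_ratio_min` (default 0.9) — standard
SV-benchmarking practice; both knobs are carried into every report. Greedy
matching is deterministic; tests bound its cost against optimal bipartite
matching (igraph) at >= 99% equal cardinality on adversarially dense random
sets. `score_agreement()` reports precision, recall and F1 as percentages
(empty test set scores 0 by convention; an empty truth set is an error).
`shared_fractions()` clusters records from many sets into sites by single
linkage over cross-set matches (graph components) and tabulates which
label subsets contain each site — the UpSet-style sharing table.

## Coding-sequence depletion test

The null model re-places every bubble uniformly on its chromosome: a
1-based start drawn from `[1, chromosome length - bubble length]`,
preserving the per-chromosome length multiset exactly. Permuted bubbles may
overlap one another — deliberately no rejection or spacing, which differs
from common shuffling tools but is the plain uniform model. Overlap is
half-open interval intersection; the observed statistic is the number of
distinct (bubble, gene) pairs with >= 1 bp CDS overlap, with per-bubble
overlap bp retained.

The one-sided Wilcoxon signed-rank test asks whether real bubbles overlap
CDS *less* than re-placed ones. The pairing unit was a genuinely open
choice, and the implemented default pairs **per bubble**: each real
bubble's overlap bp against the same bubble's overlap bp at its re-placed
position (first replicate). Under the null the two positions are
exchangeable, so the differences are symmetric about zero and the test is
calibrated — measured at 5.0% rejection at nominal 5% over 500 null
simulations in the acceptance suite. The superficially natural alternative
— pairing the observed *total* against each replicate total — is provided
(`pairing = "replicate"`) but is anti-conservative: its differences all
share the single observed total, so the test treats highly correlated
differences as independent and rejects whenever the observed total falls
slightly below the replicate median. A per-chromosome pairing
(`pairing = "chromosome"`) is also available for genomes with many
chromosomes. Zero differences are dropped (the usual signed-rank
convention); the exact null distribution is used for up to 25 untied
non-zero pairs, the normal approximation with continuity correction above.
An empirical permutation p-value
`(1 + #{replicate totals <= observed}) / (n_replicates + 1)` is always
reported alongside; the two p-values are distinct calibrated tests, so they
can disagree in borderline runs (~6% of null simulations at these sizes).
The default replicate count is 1000 (configurable); the acceptance
experiments use 200 replicates with 300 bubbles and 100 genes on a 2 Mb
chromosome, sizes chosen to mirror the gene-overlap density of a real
genome-wide analysis, where hundreds of genes overlap bubbles.

## Coding consequences

Only the portion of an SV overlapping CDS counts toward the coding change:
a deletion contributes minus its CDS-overlapped bases, an insertion (net
gain) deposits its gained bases at a point and counts in full whenever its
interval touches CDS. This restriction is the only reading under which a
36 bp CDS-contained deletion generalises to -12 residues while intronic
ends of the same SV stay silent. A change divisible by 3 is in-frame
(`aa_change = change / 3`, exact by construction); otherwise frameshift. A
deletion-like SV containing the gene's whole span is `GENE_SPANNING_DEL`.
Amino-acid magnitudes are strand-independent.

VNTR expansions convert copy-number change to residues
(`copies x motif / 3`) when the motif length is divisible by 3; the
simulator draws motifs from 6–90 bp with half of them multiples of 3
precisely to exercise both the in-frame and frameshift branches.
Domain-unit accounting (e.g. bp per zinc finger) is left to the caller as a
motif-length argument rather than hard-coded biology.

Depth-based copy number is `round(mean depth over region / baseline) - 1`,
floored at 0, ties rounded away from zero; the raw ratio is reported
alongside because long-read platforms routinely disagree by one copy, so a
+/- 1 band is inherent to the estimator. The baseline defaults to the
median of same-chromosome windows outside the region.

## Assembly QC

NG50 uses the expected genome size (not assembly size) as denominator; PG50
is the same computation on haplotype-phased block lengths and can only
decrease under refinement. QV is the Phred-scaled base-error rate, capped
at 99 (flagged) when zero errors are observed; the error count itself is an
input, not estimated here. Telomere/satellite completeness counts repeat
bases clipped to terminal windows — 10 kb for distal telomeres; the
proximal satellite window is 5 Mb by default because acrocentric
chromosomes carry their centromere at the proximal end and no published
window exists (configurable). The end-to-end rule is inclusive: >= 50 kb
proximal satellite *and* >= 500 bp distal telomere. Coverage dropouts are
maximal runs of consecutive windows below 1x, counted once per run, never
across chromosome boundaries.

## The synthetic-data generator

`sim_config()` defaults define the study conditions: five assemblies
(`O, B, P, N, G`) on the ultrametric tree
`((((P:0.1,B:0.1):0.15,O:0.25):0.35,N:0.6):0.4,G:1.0)` — an outgroup-heavy
shape (G far out, N intermediate, three close taurine-like leaves) — two
5 Mb chromosomes, and `sv_rate = 1e-5` events/bp/unit branch length, giving
~300 planted SVs (Poisson per branch, rate x branch length x genome size).
Carrier sets are exactly the clades below each branch (infinite-sites on
branches; no homoplasy by default). SV lengths follow a geometric law
shifted to the 50 bp divergence minimum with mean 500 bp, matching the
heavy right tail of real bubble sizes at desk scale. Insertions are planted
as small-anchor replacements (a 1–49 bp reference anchor replaced by
anchor + insert) so every bubble retains a non-empty reference interval;
deletions are direct-edge skips; VNTR events expand an existing motif copy.
Placement is uniform with >= 50 bp spacing and 200 bp end margins, with
bounded retries (an overcrowded chromosome raises an error suggesting a
lower `sv_rate`).

Annotation tracks carry planted signal: genes with fixed 150 bp CDS blocks
(always in frame), per-assembly satellite/telomere blocks whose sizes cross
the end-to-end thresholds with the configured probabilities
(`p_satellite = 0.75`, `p_telomere = 0.6`, chosen so the expected
end-to-end fraction is realistic for long-read assemblies of acrocentric
genomes), ~1.5 gaps per chromosome, contig and phase-block length tables,
and 10 kb depth tracks (normal noise, CV 0.08) in which planted CNV regions
scale carrier depth by 1 + additional copies. Per-assembly base-error
counts correspond to QV ~ U(40, 50), the realistic long-read assembly
range.

`emit_replicates()` emulates the order sensitivity of iterative graph
construction: each replicate independently perturbs every SV with
probability `noise` — half dropped, half split into two roughly half-length
events 10 bp apart. Split pieces fail the default 0.9 length-ratio
consensus gate, so expected recall against the truth catalogue is exactly
`1 - noise`. This noise knob is an acknowledged abstraction: the real
mechanism (alignment order, palindromic sequence) cannot be emulated
without alignment.

What the simulator does *not* emulate — and what passing tests therefore do
not show about real data: nucleotide-level sequence (segments carry lengths,
not sequences, so no realistic repeat content), homoplasy and recurrent SVs
(available behind a flag in spirit but off by default), nested or
overlapping bubbles, inversions and translocations, genotyping error
correlated with SV class, and reference bias. Results on real graphs depend
on minigraph's own behaviour in ways no planted-truth test can certify.

## Determinism and problem sizes

Every stochastic entry point takes a seed; `run_pipeline()` fans a single
global seed out to stages via a counter-based derivation
(`derive_seed(seed, k)`), so whole runs are byte-reproducible. The
simulator and permutation code restore the caller's RNG stream.

Test-suite problem sizes are the package's own validation design: 500
random graphs of <= 12 segments for the detector-vs-oracle equivalence, 100
simulator seeds (~300 SVs each) for planted-topology recovery (>= 95%
required; 100% observed), 500 null seeds x 200 permutation replicates for
calibration of the depletion test (3–7% band), 40 seeds x 3 avoidance
strengths for its power curve, and 20 seeds x 4 noise levels for consensus
recall. These sizes keep the full suite in the minutes range on one CPU
while leaving the statistical assertions well inside their bands.

## Known limitations

* Inversion and translocation typing are out of scope; reverse-orientation
  links are traversed but alleles are compared as oriented segment
  sequences only.
* Allele identity is exact path identity — no tolerance for alternative
  traversals of equal content, mirroring node-level calls.
* Greedy consensus matching can (rarely, < 1% of dense random cases) be one
  match short of optimal.
* The depletion test conditions on the observed bubble set; it does not
  model uncertainty in bubble detection itself.
* NG50/PG50/QV consume length and error-count tables; k-mer based
  estimation of those inputs is outside the package.
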