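---
title: "orgkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orgkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgkit)
```

## The problem orgkit addresses

Plant organelle genomes — above all conifer mitogenomes — are structurally
restless molecules. A single circular mitochondrial chromosome of around a
megabase can be mostly noncoding, riddled with dispersed repeats that
mediate recombination, carry fragments copied in from the plastid genome
(MIPTs), and break ancestral gene order so thoroughly that introns which
were once spliced in cis end up trans-spliced from scattered loci. The
plastome of the same plant, having lost the canonical large inverted
repeat, typically retains a short IR (~1.2 kb) whose recombination flips
the region between the copies, so two genome conformations ("form A" and
"form B") coexist in one individual. On top of the structural dynamics,
organelle transcripts are rewritten by C-to-U RNA editing at hundreds of
sites, creating start codons, premature stops, and a biased spectrum of
amino-acid changes.

orgkit implements the measurement side of this biology as a reusable,
tested pipeline: repeat landscapes, IR/isomer analysis with long-read
classification, MIPT and chimeric-ORF scanning, empirical editing calling
with codon-consequence classification, cluster/intron structural scoring,
and the phylogenomic bookkeeping (supermatrices, topology conflict, the
PHI recombination test) used downstream of such genome projects. A seeded
synthetic-data module generates every input with known ground truth, so
the whole pipeline is testable end to end without downloads.

## Coordinates and circularity

Internally every interval is 0-based half-open; GFF3 I/O converts to
1-based inclusive. Topology is always explicit. Window scans on circular
genomes run on a doubled-sequence view of length 2L and deduplicate hits
modulo L, keeping results invariant under rotation of the (arbitrary)
origin — a property the tests assert directly. Gene models store exons in
*transcription* order, which is what allows one structure to describe
cis-spliced, origin-wrapping and trans-spliced genes alike.

## Repeat discovery

`find_dispersed_repeats()` seeds exact 20-mers on the genome against
itself and its reverse complement, merges seeds per (anti)diagonal,
extends to maximal exact matches, then chains collinear blocks across
short mismatch gaps (≤ 100 bp) and rescores the chained span by direct
comparison, so diverged copies (point mutations) emerge as single units
with an identity fraction. Defaults: `min_len = 30` (the conventional
floor for organelle repeat reporting), `min_identity = 0.90`. `min_len`
below the seed size is refused rather than silently unreliable. The size
classes in `summarize_repeats()` are large `> 1000`, intermediate
`100–1000` (both bounds inclusive), small `< 100`; class counts are of
repeat *units* (single-linkage clusters of pairs with ≥ 90 % reciprocal
locus overlap), while `total_repeat_bp` is the union of loci, never
double-counted. The whole exact-match layer is verified against an
O(L²) brute-force shift-comparison oracle.

`find_inverted_repeat_pair()` returns the longest inverted pair that
partitions the circle into two arcs (LSC/SSC assigned by length) and
returns `NULL` — an explicit absence result, not an error — when no
inverted repeat of `min_len` (default 100 bp) exists.

## Similarity scanning (MIPTs, chimeric ORFs)

Local alignment is delegated to NCBI BLAST+ (`task=blastn`), the engine
family this analysis conventionally uses; orgkit owns thresholds,
circular handling and merging. MIPT defaults follow the conventional
filter triple `length ≥ 50 bp`, `identity ≥ 0.80`, `E ≤ 1e-10`; merged
fragments overlap-reduce on the mitogenome before counting. Two caveats
discovered during testing are worth recording: a 50 bp hit at 80–85 %
identity is *beyond* 1e-10 in organelle-scale search spaces by
Karlin–Altschul arithmetic, and local alignment trims mutated fragment
ends below the nominal length — so the stringent default triple cannot,
even in principle, recover every borderline planting. The recall
properties are therefore tested with relaxed `min_len`/E parameters
(which the functions expose), while the default thresholds are asserted
to exclude sub-50-bp plantings. The seed size is 7 by default because a
50 bp fragment at the identity floor can lack any clean 11-mer.

ORF discovery scans all six frames with an ATG start, stop-terminated,
longest-per-stop, honoring origin wrap; chimera evidence against
annotated genes uses `≥ 30 bp` at `≥ 90 %` identity (`E ≤ 1e-3`), with an
ORF never allowed to serve as evidence for the gene it overlaps.

## RNA-editing calling

`pileup_genes()` reduces BAM (Rsamtools; MAPQ ≥ 20, base quality ≥ 20,
multi-mappers excluded via the MAPQ filter) or a pre-tabulated pileup to
coding-strand base counts per spliced-CDS position. `call_c_to_u()` calls
a site iff the reference is C, depth ≥ 10 and T/(depth−N) ≥ 0.10; no
other mismatch class is ever called. The thresholds are empirical-calling
decisions — the underlying studies typically state none — and both are
parameters; published totals at other thresholds should be treated as
threshold-sensitive. tRNA/rRNA/intron positions are outside the default
caller scope (the pileup is built over CDS models).

Consequences come from the codon before/after the single C→T: `silent`,
`missense`, `stop_gain`, plus the first-codon specials `start_gain`
(codon becomes ATG) and `start_codon_edit` (first codon edited to
something else, e.g. GCG→GTG). Edits that keep an annotated stop a stop
are silent. Codon changes are counted per distinct codon (two edits in
one codon are one codon change), which is why per-gene "changes" can be
fewer than sites. The classifier is checked against an oracle that
rebuilds and diffs entire proteins on 10,000 random cases.

## Isomer construction and read classification

`build_alternative_form()` reverse-complements the arc strictly between
the two IR copies. Because the IR itself is identical in both forms, only
the unique single-copy flanks are informative, so
`classify_isoform_reads()` matches 15-mers of four 200 bp anchors (the
single-copy sequence abutting each IR end) and asks which flanks a read
connects across the IR at the expected spacing (tolerance
`0.25·spacing + 100` bp for indel noise; ≥ 3 clean k-mers per side).
A read supporting different forms at different junctions is reported as
`chimeric` — the within-molecule recombination signature — never dropped.
Reads spanning no junction are `ambiguous` by construction, including any
read shorter than a junction span. The mixing ratio estimator uses a
Wilson 95 % interval over informative reads only. Anchor length 200 bp is
an ONT-scale choice: long enough to be unique on a screened background,
short relative to real read lengths.

## Structural evolution scoring

A gene cluster is retained iff its genes are consecutive on the circle
(no other catalog gene intervening), in catalog order or exactly
reversed, on one strand, with gaps ≤ `max_gap` (default 5 kb — a
decision, exposed as a flag). Clusters with absent genes are
`unevaluable`, not lost, and both retained and lost lists are reported so
either reading of a published count can be checked. The packaged
14-cluster catalog is a documented stand-in (see the file header):
membership of the ancestral set is cited from supplementary literature
that the package cannot ship, so only the three clusters named in the
primary text are authoritative; the scorer itself is catalog-agnostic.

Introns are cis iff adjacent exons share a strand, follow reading order
(shorter-arc logic on circles; a forward gap exceeding half the circle is
treated as "behind"), and lie within `max_intron_span` (default 50 kb).
Trans verdicts always carry an evidence code (`strand_switch`,
`order_violation`, `distance_exceeded`) so calls are auditable.

## Supermatrices, conflict, and the PHI test

`concatenate_alignments()` tiles partitions in input order, pads missing
taxa with `?`, and asserts on every build that the column count equals
the partition-width sum. Trees are compared unrooted via nontrivial
bipartitions; the Robinson–Foulds distance is the count of splits unique
to either tree (verified against a brute-force bipartition oracle and
phangorn).

The PHI statistic is the mean *refined incompatibility* over pairs of
parsimony-informative sites within `window_w = 100` alignment positions
of each other. For one pair, refined incompatibility is the minimum
number of extra mutations needed to fit both sites on a single tree,
computed as `e − v + c` on the bipartite state graph (edges = observed
joint states); a binary four-gamete pair scores exactly 1, any
tree-compatible pair 0. Gaps and ambiguity codes are excluded per pair.
Under recombination nearby sites are *more* compatible than distant ones,
so significance is the lower tail: the observed mean is compared with the
distribution obtained by permuting the assignment of informative-site
columns to positions. The analytic p-value uses the exact first two
permutation moments of this Mantel-type statistic (derived from the
2/3/4-shared-index decomposition and verified against Monte-Carlo moments
in the tests); the Monte-Carlo p uses `(1 + #{T ≤ T_obs})/(n_perm + 1)`
with a fixed seed, making it bit-reproducible.

## The synthetic-data module: what it does and does not establish

Generators are pure functions of `(seed, parameters)` — identical calls
give byte-identical files. Backgrounds are rejection-sampled so that no
direct or inverted repeat of ≥ 30 bp exists except what is planted;
planted features get mismatch-forced flanking bases so chance extension
cannot lengthen them. Stated-world defaults follow the biology the
package targets: mitogenome-like GC 0.45–0.459, plastome-like 0.383,
IR-plastome geometry LSC + IR + SSC + IR′, editing plans of ~100 sites at
fraction 0.9, depth 100, 0.5 % uniform sequencing error, log-normal
long-read lengths with 60/40 substitution/indel errors, Jukes–Cantor
block alignments (single-topology = recombination-free null).

What a green test on this world establishes: the algorithms implement
their contracts exactly (coordinates, thresholds, counting rules,
statistics) and recover planted truth under calibrated noise. What it
does not establish: performance on real data's unmodelled structure —
context-dependent ONT error profiles, paralogous mapping artifacts in
pileups, repeat families with internal substructure, alignment error in
supermatrices. The deposited-record acceptance checks (genome length, GC,
IR geometry, repeat and MIPT totals of the published genomes) require the
GenBank records themselves; in offline builds those computations are
exercised on synthetic stand-ins constructed to the published geometry
and are labelled as such in the test suite.

## Numerical and degenerate-input choices

* `gc_content` excludes N from the denominator and errors on all-N input.
* Composition fractions resolve biotype overlap by priority
  CDS > rRNA > tRNA > noncoding, so they sum to 1.
* `find_inverted_repeat_pair` returns `NULL` (absence), `phi_test`
  returns an explicit `uninformative` result below 2 informative sites,
  and `estimate_isoform_ratio` returns `NA` with counts when no read is
  informative — callers never need to catch exceptions for ordinary
  negative results.
* Repeat pair lists are canonically ordered (locus A ≤ locus B;
  by start, then length descending) for deterministic output.
* Ties between equally long IR candidates resolve to the first in
  canonical order whose copies partition the circle.
* The permutation p-value has resolution `1/(n_perm + 1)`; analytic and
  permutation p agree closely on null simulations (tested).

## Known limitations

* Similarity scanning requires the BLAST+ binaries on `PATH`.
* The IR finder assumes exactly one IR pair dominates; plastomes with
  multiple near-equal inverted duplications would need manual review.
* The editing caller does not model strand-specific sequencing error or
  U-to-C editing (not part of the target biology).
* Multi-isomer reconstruction from large mitogenome repeat families
  (subgenomic circles) is out of scope; only the two-form plastome case
  is modelled.
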