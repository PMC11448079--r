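---
title: "Comparative mobilome analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mobilome analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mobilome` compares the mobile-genetic-element content of two nearly
identical bacterial genome assemblies — the setting of a wildtype strain and
a laboratory mutant that have diverged by transposition, recombination and
little else. The package answers five questions: which known insertion
sequences (IS elements) are present and how many times; whether the genomes
carry a miniature inverted-repeat transposable element (MITE) and which
transposase family could mobilize it; how the two assemblies differ
structurally (inversions, strain-specific insertions, intra-genome
duplications); what each insertion difference does to genes; and whether
those differences coincide with differential expression. A deterministic
simulator generates strain pairs with known truth so that every stage is
testable without external data.

# Coordinate conventions

All coordinates are 1-based inclusive, both in memory and on disk — the
IRanges/Biostrings convention this implementation is built on and the
convention of GFF3 itself. An annotated feature at residues 859–1053 spans
`1053 - 859 + 1 = 195` nucleotides. Insertion *sites* are reported as the
position of the first base after the insertion junction: an insertion "at
site s" sits between positions `s - 1` and `s`.

Element occurrences **exclude** the target-site duplication (TSD): the TSD
is host sequence duplicated on insertion, so a 187-nt MITE with an 8-nt TSD
occupies 187 nt, flanked by two 8-nt copies of the target. A strain-specific
*insertion difference*, by contrast, is reported as the full sequence gained
by the carrier — element plus one TSD copy (195 nt for that MITE) — placed
leftmost. The two conventions differ by exactly one TSD copy; both are
reported so neither is hidden. This also explains why a PCR product across
such a locus grows by element+TSD, not by the element alone.

# Element cataloguing

`match_library()` is a seed-and-extend search: exact 13-mers tiled along
each library element nominate candidate loci; each candidate window is then
scored by local alignment of the element against the window
(`Biostrings::pairwiseAlignment`, match +1 / mismatch −1, gap open 5,
extend 2). A hit reports `identity` (aligned matches / element length) and
`coverage` (aligned element fraction); defaults `min_identity = 0.90`,
`min_coverage = 0.5`. Significance is deliberately expressed as these two
deterministic thresholds rather than an alignment e-value: on a 5-Mb genome
the 0.90-identity cutoff is far beyond what chance produces, the behaviour
is reproducible bit-for-bit, and the thresholds map directly onto the ">90%
identity" language used when curating IS hits by hand.

`dedupe_overlaps()` removes redundancy: whenever two hits overlap by at
least half the shorter hit's span, the shorter one (ties: lower identity,
then rightmost) is dropped. Removal is simultaneous over all pairs of the
input — a dominated hit is removed even when its dominator is itself
dominated — which makes the filter order-independent and idempotent; this
mirrors how nested fragments of long elements are struck from a hand-curated
list.

`count_copies()` in exact mode counts non-overlapping occurrences of a
sequence on either strand, leftmost-greedy, collapsing identical intervals
found on both strands (palindromes) so nothing is double-counted.

# MITE discovery

`find_high_copy_repeats()` mines exact high-copy repeats with k-mer
anchoring (k = 21): every k-mer is counted over both strands, positions
whose k-mer reaches the copy threshold are merged into maximal runs, and
each run is trimmed to its *modal-count core*. The trim matters: a k-mer
that crosses a repeat boundary is shared only by the subset of copies whose
flanking bases happen to agree, so its count falls below the modal
(interior) count; trimming to the mode recovers the repeat unit exactly
instead of a unit blurred by one or two chance flank bases. Exact-match
mining is appropriate for a young, homogeneous MITE family whose copies are
identical; diverged homologs are a job for `match_library()` at relaxed
identity, not for the miner. Defaults (80–500 nt, ≥ 5 copies) bracket the
canonical MITE size range.

Each candidate is then characterized:

* `detect_tsd()` returns the largest window w in 2..16 for which the w
  bases left of the locus equal the w bases right of it. Loci too close to
  a contig end raise an error distinct from "absent".
* `detect_tir()` finds the longest ungapped alignment of the 5′ prefix
  against the reverse complement of the 3′ suffix with ≤ 2 substitutions
  (minimum 7 nt) — "imperfect" terminal inverted repeats are expected.
* `scan_orfs()` scans all six frames, ATG starts only, stop included in the
  span, one ORF per stop (the first ATG after the previous stop), minimum
  span 30 nt.
* `fold_score()` scores hairpin potential by Nussinov base-pair
  maximization (Watson–Crick plus G·U, minimum loop 3, T read as U). This
  is a structural proxy, not a thermodynamic model: it reports how much of
  the element can pair in a nested structure, which is the property MITE
  descriptions appeal to when they show a stem-loop fold.

`classify_mite()` applies the four defining criteria in a fixed order and
reports the first failure: terminal inverted repeat present; at least one
locus with a TSD; no ORF ≥ 600 nt (non-autonomy — 600 nt is well below any
transposase yet above incidental short ORFs); copy number ≥ 5.

`link_family()` implements the trans-mobilization argument: a MITE is moved
by an autonomous element with matching ends. A transposase family is linked
when both termini of a catalogued element match the MITE's 9-nt TIR seed
(≤ 1 mismatch per terminus, element read in its own orientation) **and**
the element's own TSD length at that locus equals the MITE's modal TSD
length. The TSD-length clause is what rejects look-alike termini from a
family with different target chemistry; several qualifying families are all
reported and flagged ambiguous.

# Genome differencing

`build_anchors()` matches every k-mer (k = 21, odd so no k-mer is its own
reverse complement) that occurs exactly once in each genome, counting both
strands, and merges co-linear matches into maximal exact anchors (constant
diagonal, step ≤ k so the merged interval is exactly identical). Between
two ~99.9%-identical assemblies, unique anchors tile essentially every
single-copy position; repeats — the interesting parts — fall between
anchors by construction.

**Inversions.** Runs of inverted-orientation anchors spanning ≥ 10 kb seed
calls. A called interval is then refined to the *maximal inverted
interval*: boundaries are pushed outward while the base left of the
interval in genome A still complements the base right of the interval in
genome B, and vice versa. For an inversion mediated by recombination
between inverted repeat copies, this interval runs from the start of the
left repeat copy to the end of the right one — the entire segment that maps
onto its own reverse complement. The convention is chosen because the
anchored run itself overshoots into the flanking repeat by up to k−1
(junction k-mers match in inverted orientation), so "outermost anchored
base" is not a stable coordinate, whereas the maximal interval is unique up
to chance single-base pairings at its edges. The flanking repeat is then
measured as the interval's own terminal inverted repeat and its genome-wide
copy number counted in each genome (only when ≥ 20 nt, to avoid
meaninglessly counting 1–2 nt "repeats").

**Insertions.** Between adjacent same-orientation anchors, a gap ≥ 50 nt in
one genome with a gap of |g| ≤ 10 nt in the other is an insertion in the
gapped genome. A *negative* gap in the non-carrier — the two anchors
overlap — is the signature of a target-site duplication: the caller shifts
the interval leftmost by the overlap, so the reported carrier interval
contains element plus one TSD copy and its length is the full length
gained. Gaps large in both genomes with *differing* content are reported as
`complex` rather than forced into either class; gaps whose content is
identical (or reverse-complement-identical, across an inversion) are the
anchor shadow of a shared repeat and are not differences at all. Inserted
sequences are labelled with a catalog element when one occurs as an exact
substring covering all but ≤ 2 TSD-lengths of the insert.

**Duplications.** `find_self_duplication()` merges runs of k-mers that
recur elsewhere in the genome and pairs regions ≥ 20 kb with their other
occurrences. Detection is driven by exact k-mer runs, so reported copies
are identical (identity 1.0); copies diverged below 100% fragment into
adjacent shorter calls rather than one long one — adequate for flagging
assembly-scale duplications, not a general segmental-duplication caller.

# Genic impact

`classify_insertion()` calls a site intragenic iff the junction lies
strictly inside a CDS; a junction at a CDS's exact boundary is intergenic
at distance 0 (an element "just before" a gene is not inside it).
Overlapping CDS at a site are all reported and flagged ambiguous.

`split_products()` models translation of an interrupted transcript:
product 1 runs from the original start to the first in-frame stop at or
after the junction; product 2 is the longest ATG-initiated ORF (≥ 30 nt)
in the remainder — the convention under which a re-annotation pipeline
would call the two halves of a split gene. A CDS whose product 1 never
reaches a stop is flagged run-through rather than silently truncated.

`cds_delta()` re-runs frame extension through the mutated sequence until
the first in-frame stop and reports the signed change in CDS span. Note a
structural fact: because old and new spans are both whole numbers of
codons, the delta is always a multiple of 3; published "coding region grew
by N nt" figures with N not divisible by 3 must come from annotation
boundary arithmetic rather than frame logic, and cannot be reproduced by
any in-frame model.

# Expression overlay

TPM is the within-sample normalization `TPM_i = (c_i/l_i)/Σ_j(c_j/l_j) ×
10^6`; the module consumes per-gene TPM tables (long format: gene, strain,
timepoint, replicate, tpm) and never touches reads.

Strain contrasts use Welch's unequal-variance t-test on the TPM values,
per gene and per timepoint, with Benjamini–Hochberg adjustment within each
timepoint (timepoints are tested separately, so each is its own family).
"t-test" alone underdetermines the variant; Welch is the safer default for
heteroscedastic TPMs at n = 2. Zero-variance groups — frequent when n = 2
TPM values tie — are handled with a variance floor `ε = 10⁻⁸·mean²` rather
than dropped; two zero-variance groups with equal means give p = 1. Fold
change is computed on replicate means with a pseudocount of 1 TPM, and a
gene is significant when fold change ≥ 2 **and** q ≤ 0.05, both inclusive.

A design-level limitation follows from n = 2 with Welch's test, and users
should understand it before trusting any "not significant" call: when one
group's variance dominates (as it must when a large multiplicative effect
scales the noise), the Satterthwaite degrees of freedom approach 1 and the
two-sided p-value behaves like 2/(πt); with replicate CV 0.1 the statistic
itself is bounded near √2/CV ≈ 14 however large the effect, so p rarely
falls below ~0.01 and almost never below 0.001. After BH correction across
even a few hundred genes, per-timepoint recall of true large effects is
therefore poor *by design of the experiment being emulated*, not by a flaw
in the test. Genuine power requires more replication (e.g. pooling
timepoints within a temperature condition to n = 4) — which changes the
testing scheme and is left to the user's judgement. The package's own
calibration (acceptance script) reports both the null flag fraction (which
is controlled) and the recall at 4× effects (which is honestly low).

`overlay_expression()` joins each insertion difference to the genes it
could plausibly affect: the hit gene for intragenic insertions (always),
plus up to 4 downstream genes within 5 kb whose transcription points away
from the site (polar-effect candidates: plus-strand genes starting after
the site, minus-strand genes ending before it), plus both immediate
neighbors. One row per (difference, gene), summarizing each gene's
strongest DE result across timepoints.

# In-silico PCR

`find_primer_sites()` locates primer annealing sites on both strands,
allowing a configurable number of substitutions but requiring the 3′
terminal bases (default 3) to match exactly — mismatches under the
polymerase's feet abort extension. `predict_amplicons()` pairs every
plus-strand site of one primer with every downstream minus-strand site of
the other within 10 kb, in both primer orderings, and reports product
length measured from the forward primer's 5′ base through the reverse
primer's 5′ base inclusive — the gel-facing convention that includes both
primer footprints. Defaults are zero mismatches: validation primers are
designed to exact template.

# The synthetic strain pair

`simulate_genome_pair()` builds the study conditions as planted truth. The
default specification is a 1-Mb i.i.d. backbone at GC 0.43 (the
cyanobacterial range) carrying 200 non-overlapping protein-coding genes
(ATG + stop-free codons + stop, 300–3000 nt, both strands), into which are
inserted, with TSD duplication where the family makes one:

* a 187-nt MITE (TIR seed `GGCTCTTCG`, 8-nt TSD): 31 shared copies plus 2
  mutant-specific ones, one inside a 1044-nt sulfate-binding-protein-like
  gene at codon boundary 858, one inside a livG-like gene — 31 wildtype /
  33 mutant;
* an ISL3-like 1215-nt transposase with the same termini and TSD length
  (the designated mobilizer), 3 shared copies;
* an IS1634-like 1746-nt element: 8 shared + 2 mutant-specific (one placed
  intergenically upstream of a four-gene same-strand cluster);
* an IS200-like 444-nt TIR-less, TSD-less transposase gene: 13 shared +
  3 wildtype-specific (two intragenic) + 1 mutant-specific — 16/14;
* an IS1-like 737-nt element: 5 shared + 1 wildtype-specific upstream of an
  uncharacterized-protein/MBL-fold gene pair — 6/5;
* a 10-kb cassette in 3 copies — one forward at the left boundary of a
  ~200-kb segment, one inverted at its right boundary, one distal — with
  the spanned segment reverse-complemented in the mutant (the geometry
  recombination between inverted repeats produces).

1 Mb and ~200 kb are the package's chosen working scale: large enough that
unique-k-mer anchoring, repeat mining and the catalog behave as they would
at replicon scale, small enough that the whole recovery suite runs in
about a minute.

The generator enforces three classes of *structural guards*, all properties
of real planted features rather than tuning: the base outside a would-be
TSD must differ from the base after the site (so the detected TSD length is
exactly the planted one, not accidentally longer); element termini must not
share their first/last base with the flanking host sequence (no
microhomology, so the leftmost-normalized insertion interval an
anchor-based caller reports coincides bit-exactly with the plan); and the
inversion's inner and outer boundary bases must not chance-pair (so the
maximal inverted interval stops exactly at the cassette pair). Without the
guards every convention above still holds, but recovered coordinates can
differ from planted ones by 1–2 bases of genuinely ambiguous placement.

Expression tables draw per-gene lognormal baselines (meanlog 3, sdlog 1.2 —
median ~20 TPM with a realistically long tail), multiply in strain effects
(sulfate-cluster derepression 8×, silencing downstream of the mutant
IS1634 0.1×, derepression behind the absent wildtype IS1 10×), add
multiplicative replicate noise at CV 0.1 with n = 2 replicates at four
timepoints, and renormalize each sample to 10⁶.

What the simulator does **not** emulate — and what green tests therefore do
not demonstrate about real data: sequence divergence between element copies
(real IS families are rarely bit-identical), backbone repeats beyond the
planted ones, composition bias and Markov structure, assembly errors and
contig breaks, circular replicons (genomes are treated as linear; wraparound
features are not searched), and count-level expression noise
(TPM tables are taken as given, as the analysis itself does). All
randomness flows from the single spec seed; the same seed gives
byte-identical output.

# Degenerate inputs and tie-breaks

Empty genomes yield empty hit sets, not errors; empty element sequences are
errors. Palindromic matches are collapsed before counting. Anchors
containing N are excluded; parsing rejects ambiguity codes other than N
outright so that exact matching stays well defined. GFF records with end <
start are skipped with a warning, not fatal. Ties in overlap
de-duplication break by identity then leftmost start then input order, so
the filter is a function of the input set only. `flag_de` skips (with a
message) genes lacking two replicates in either strain.

# Known limitations

* The catalog's aligner scores substitutions well but long indels poorly;
  it is a detector for ≥ 90%-identity element copies, not a general
  homology search.
* Exact-repeat mining misses MITE families whose copies have diverged;
  cross-strain homologs at > 90% identity should be sought with
  `match_library()` using a discovered element as the query.
* Insertions inside an inverted segment of the partner genome are not
  called (the generator plants differences outside the inversion for this
  reason); handling nested rearrangements would require chaining inverted
  anchor runs.
* The duplication caller reports identical copies only.
* Statistical power at n = 2 is intrinsically poor (see above); the
  overlay's `significant` column inherits that.
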