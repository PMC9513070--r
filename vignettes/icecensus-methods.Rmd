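---
title: "Methods: detecting and comparing integrative conjugative elements with icecensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing integrative conjugative elements with icecensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icecensus)
```

## Scope and model

`icecensus` implements an in silico census of integrative mobile genetic
elements in sets of closely related bacterial genomes of the
*Streptomyces* type: large linear chromosomes whose central core carries
the conserved gene complement, flanked by variable terminal arms. The
element classes follow the standard signature-module logic:

* **ICE** — integrative and conjugative element: site-specific integrase
  (tyrosine or serine family), relaxase, type IV coupling protein and a
  VirB4-family T4SS ATPase. All four modules present.
* **IME** — integrative mobilizable element: relaxase (with or without an
  integrase) but no VirB4; transfer depends on a helper element.
* **AICE** — actinomycete ICE: transfer through a single FtsK/SpoIIIE-like
  TraB pore instead of a T4SS; signature genes *int*, *rep*, *traB*.
* **DICE / DAICE** — defective derivatives: a DICE retains VirB4 but has
  lost at least one of integrase/coupling/relaxase; a DAICE retains *traB*
  but has lost *rep* and/or a functional integrase (including integrases
  interrupted by a transposon insertion).
* **remnant** — repeat-bounded relic with cargo and at most a truncated
  integrase; carries no transfer function and is not blindly detectable by
  signature screening.

Classification is a pure function of the detected role set
(`classify_from_roles()`), asserted exhaustively in the test suite over all
role subsets. A candidate combining a TraB module with a VirB4 module at
one locus is reported as ambiguous with both tentative classes rather than
forced into either.

## Two-way signature detection

Detection runs two routes and takes their union with a role-consistency
check (profile hits win conflicts on score):

1. **Profile scoring.** Each role has a position-specific log-odds profile
   (bits against background residue frequencies, pseudocounts proportional
   to background) built from a small seed alignment with
   `build_profile()`. Scanning is ungapped anchoring with free terminal
   overhangs and a minimum overlap of 60 columns, not a full profile-HMM
   Viterbi: the synthetic signatures and any imported real hits
   (`import_domtbl()` accepts HMMER3 `--domtblout` tables) do not require
   gapped profile alignment, and the anchored score separates true
   signatures from background by hundreds of bits at the identities the
   generator emulates. The default acceptance threshold of 30 bits with a
   60-column minimum overlap keeps the expected number of background
   false positives across a population of ~10^4 proteins far below one
   while detecting TraB fragments down to 139 aa.
2. **Similarity search.** Smith–Waterman local alignment (BLOSUM62, gap
   open 10, extend 1, in compiled code) of canonical seed proteins against
   the proteome, with percent-identity (default 30) and query-coverage
   (default 0.80) cutoffs, behind a shared-4-mer prescreen.

Profile score thresholds are configuration values with calibrated
defaults of this package, not literature values.

## Candidate grouping

Hits on one replicon are chained left-to-right (gap cap 120 kb) and a
chain is closed after each *transfer-module terminator*: a traB hit, a
virb4 hit, or a coupling-protein hit not closely followed by virb4. This
encodes the canonical module order of integrative elements — recombination
module at the att-proximal edge, transfer pore distal — and is what
resolves tandem (accretion) stacks into individual candidates. Orphan
candidates without any transfer role are dropped unless repeat-anchored
(remnant logic). Span caps of 50 kb (TraB-anchored) and 120 kb (ICE-type)
bound the chaining; the planted maxima are 36.2 kb and ~100 kb.

## Direct-repeat delimitation

Elements are delimited by the target-site duplication created on
integration. `find_flanking_repeats()` pairs a window upstream of the
signature anchor with a window downstream (default 5 kb each, widened to
40 kb when the narrow window yields nothing significant, as happens when
an element has lost its att-proximal signature genes), seeds diagonals
with exact 8-mers, and scans each seeded diagonal for its best interval
under a mismatch-penalised score (match +1, mismatch −3) subject to the
minimum length (10 nt) and a 5% mismatch-rate bound.

Numerical choices worth stating:

* **Ranking** is by score, then fewer mismatches, then the innermost pair,
  then leftmost. Ranking by raw length would let any mismatch-budget
  extension of the true duplication outrank the exact duplication, and
  preferring outermost pairs would collapse accretion stacks into one
  span; the innermost identical pair is the one the element's own
  integrase would recombine.
* **Chance control.** A repeat is accepted only if the expected number of
  equally good chance alignments in the searched windows
  (`repeat_chance_expectation()`, binomial model) is at most 10⁻³. The
  per-base match probability is set to 0.3 rather than 0.25 because
  protein-coding DNA is compositionally biased; this is deliberately
  conservative. In 5-kb windows this corresponds to a ~20-nt floor for
  de novo repeats.
* **att anchoring.** Repeats below the chance floor are kept only when a
  copy overlaps the 3' 30 nt of an annotated tRNA — the biological prior
  that tRNA 3' ends are att sites. Such repeats are flagged
  `att_anchored`. Duplications shorter than the 8-nt seed (reported in
  real data down to 2 nt, where they were delimited manually by
  cross-strain comparison) are below the blind detection floor of this —
  and any single-genome — approach; the generator supports planting them
  and `delineate_element()` accepts them when supplied.
* **Bounds convention** is `include_one_repeat` (left copy inside, right
  copy outside), so excising the bounds restores an intact site;
  the alternatives differ by exactly the repeat length(s).
* The per-diagonal optimisation enumerates intervals inside candidate
  segments delimited by prefix-score minima; with a zero mismatch budget
  it reduces exactly to maximal runs, which is also the setting used for
  the brute-force equivalence property in the tests.

Extrachromosomal filtering then discards TraB-anchored candidates on
plasmids that lack flanking repeats (divergent plasmid-native TraB
systems), while a plasmid-borne candidate with a complete ICE module set
is kept.

## TraB families and trees

Pairwise global identities use Needleman–Wunsch with affine gaps
(BLOSUM62, 10/1) in compiled code; identity is matches over all alignment
columns including gap columns, which keeps the measure symmetric and
bounded. Families are single-linkage connected components at 95%
identity — the connected-component reading matches a threshold drawn on a
phylogenetic clustering — with deterministic numbering by first member in
input order. The neighbor-joining implementation is the standard
Saitou–Nei agglomeration on distances `(100 − identity)/100`; negative
branch estimates are clamped to zero with the excess moved to the sibling
branch. `ape` is used in the test suite only, as an independent oracle for
topology comparisons.

## Cargo and pseudogenization

Cargo genes are all CDS within the element bounds minus detected
signature genes and mobility-module products recognised by annotation
keywords (excisionase, spread, conjugal transfer, replication initiator,
...). Unique-gene counting deduplicates by exact protein-sequence
equality. Pseudogenization is operationalised as protein length < 150 aa;
`pseudogene_stats()` reports the short fraction against a genome-wide
baseline. Functional categories come from a priority-ordered keyword table
over the nine-category vocabulary (metabolism, DNA metabolism, resistance,
regulation, phage, toxin/antitoxin, signaling, transposase, hypothetical),
applied to cargo of at least 150 aa; a hook for an external hit table
filtered at E < 10⁻⁶ and coverage > 80% replaces database-wide homology
search, which is out of scope. Transposases count as cargo (they are a
cargo category), while the transposase interrupting an integrase also
triggers the DAICE flag.

## Population comparisons

* `build_matrix()` encodes presence/absence per strain of each
  `(family, site)` locus (class-based for ICE-type elements).
* `detect_accretion()` groups adjacent elements (gap ≤ 1 kb) with
  near-identical repeats into events and flags a remnant when one further
  identical repeat copy lies just upstream of the stack; insertion sites
  of stacked elements are inherited from the outermost left repeat copy,
  which is the one that overlaps the original tRNA.
* `core_arm_localization()` assigns chromosomal elements to core or arm by
  midpoint against configured arm sizes (2.4 Mb left / 1.4 Mb right at
  full scale, scaled proportionally). The functional/defective roll-up is
  a configuration mapping; the default counts ICE and AICE as functional
  and places IMEs — mobilizable but transfer-dependent — with the
  defective/dependent classes, so that "functional elements in the arms"
  means autonomously conjugative ones.
* `fitch_gain_loss()` computes small parsimony per locus with Sankoff
  dynamic programming over the two states (exact on multifurcating
  trees); the root state minimises the change count, ties are reported as
  ambiguous instead of being forced to loss, and gains/losses are counted
  on one minimal labelling.

## The synthetic population generator

Validation runs on synthetic populations built by
`generate_population()` from declarative blueprints rather than on real
assemblies. The packaged `reference_population()` blueprint encodes the
census composition the package reproduces: 11 strains whose cladogram contains the
RLB1-9/S1A1-3/S1A1-8 and RLB3-6/S1D4-23/S1A1-7 clades; 43 AICEs + 8
DAICEs = 51 chromosomal traB anchors in 19 TraB families (7 singletons,
member identity ≥ 97% within families, ≤ 90% between; TraB lengths 139–738
aa with four short tripartite TraB–ParM–ATP/GTP arrangements); insertion
sites 36 tRNA / 14 CDS / 1 intergenic; DAICE defects six *rep* losses, one
integrase loss, one transposon-interrupted integrase; two identical 87-CDS
chromosomal ICEs with 93-nt duplications at tRNA-Thr plus one
plasmid-borne ICE; three DICE types occurring 11+4+3 = 18 times; an IME in
the 8 strains outside one clade (one copy arm-located); a conserved
accretion remnant at tRNA-Arg in all strains with stacks of up to three
elements; three decayed remnants with 30-aa integrase fragments; and four
divergent plasmid TraB genes without repeats. AICE cargo pools hold 445
distinct proteins (223 < 150 aa) partitioned across the 19 families, each
family's full pool carried by at least one AICE member and subsets by the
others; the chromosomal ICE carries 81 cargo genes (19 short) among its
87 CDS.

Generator mechanics and their rationale:

* **Desk scale.** Chromosomes default to 900 kb (not 10–12 Mb) with arms
  of 180/105 kb — the 2.4/1.4 Mb arms scaled by the same factor — so the
  full population generates and analyses in about a minute while
  preserving every structural relationship. Full scale is a blueprint
  parameter. ICE-type spans are likewise kept at the tens-of-kb scale
  (the 87-CDS ICE is ~70 kb; AICE spans fall in the 11.9–36.2 kb range
  typical of AICEs).
* **Background genes**: spacers of 50–300 bp; protein lengths log-normal
  around a 280-aa median, with a 7% short (< 150 aa) fraction emulating
  the genome-wide pseudogene baseline. Coding sequences are reverse
  translations of the generated proteins with randomly sampled synonymous
  codons — a fixed codon choice would convert every shared amino-acid run
  between two genes into an identical DNA stretch and flood the repeat
  finder with spurious "duplications".
* **Signature proteins** are identity-targeted mutants
  (`mutate_to_identity()`, verified against the package's own global
  aligner and adjusted into a ±0.5-point band) of one packaged synthetic
  canonical seed per role, so profile and similarity detection have a
  real, controllable target. Instance identities are drawn in 78–92%.
* **Target-site duplication**: planting at point p duplicates the
  `tsd_length` nt upstream, so bounds `[p − l, p + |E|)` follow the
  include-one-repeat convention and excision restores the site; in
  accretion stacks members are planted left to right at the right edge of
  the previous attR, which reproduces the shared-repeat geometry. The
  three bases immediately outside each repeat copy are forced to
  mismatch their counterparts: without this, chance single-base
  extensions would shift roughly a third of recovered boundaries by a few
  bases and exact bound recovery would be unattainable at any seed.
  Planted TSD lengths run from 20 to 94 nt (93 for the ICEs, 46 for the
  tRNA-Val pair); the rlmN-inserted element receives a 20-nt duplication
  rather than a shorter one because an 11-mer inside a CDS is
  indistinguishable from chance in 5-kb windows.
* **Determinism**: one seed determines the population byte-for-byte;
  composition (class counts, families, sites) is identical across seeds
  by construction, which is what makes exact-census validation meaningful
  for any seed.

What passing on synthetic data does *not* show: real annotations are
noisier than the generator's (pseudogene calls, missed short CDS, frame
errors), real signature proteins are more divergent than 78–92% mutants of
a single seed, real repeats can be shorter than the blind detection floor,
and real populations contain confounders (prophages, IS expansions,
genomic islands without transfer genes) that the generator does not plant.
The detection thresholds are therefore calibrated defaults, not measured
error rates for real genomes.

## Problem sizes used in validation

The packaged population (11 strains × 900 kb plus five plasmids, 98
planted records) generates in well under a minute and the full pipeline
runs in a few minutes on one core; the brute-force repeat oracle runs on
100 window pairs of 120–320 bp; parsimony is cross-checked by exhaustive
enumeration on the 11-leaf cladogram; neighbor joining on 50 random trees
of up to 12 taxa. These sizes were chosen so the whole validation suite is
a desk-scale computation.

## Known limitations

* Blind detection needs at least one intact signature protein above the
  profile threshold; fully decayed remnants are only found via
  repeat-anchored scanning next to detected elements; fully isolated
  remnants are only identifiable by cross-genome comparison, which is out
  of scope.
* The repeat finder reports one best interval per seeded diagonal; two
  distinct qualifying repeats on the same diagonal (possible in principle
  in highly repetitive regions) would shadow each other.
* Circular replicons are handled linearly; a repeat spanning the origin
  of a circular plasmid would be missed. No inverted-repeat search.
* The two-way union currently resolves role conflicts by score only; no
  synteny-based arbitration.
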