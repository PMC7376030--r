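---
title: "Plastome structure, repeats and marker power: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome structure, repeats and marker power: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomics)
```

This vignette documents the models behind each stage of `plastomics`,
the parameters that matter, and the design decisions taken where more
than one defensible choice existed. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Coordinates

All coordinates are 0-based half-open `[start, end)` internally and in
every TSV the package writes. GenBank's 1-based inclusive locations are
converted at the parsing boundary and nowhere else; this removes the
classic off-by-one ambiguity from junction distances and fragment
lengths. On circular records a feature part may wrap the origin, encoded
as `end > genome length` and interpreted modulo the length.

## Quadripartite structure detection

The LSC/IRb/SSC/IRa architecture is located as the maximal-length pair
of disjoint intervals whose sequences are exact reverse complements.
The search seeds with shared k-mers (k = 25, capped at the minimum IR
length) between the sequence and its reverse complement, merges anchors
along diagonals, and extends each candidate to its maximal exact match;
an extension whose two copies would overlap is trimmed to the longest
disjoint sub-pair. Circularity is handled by scanning the doubled
sequence and de-duplicating candidates modulo the genome length. Ties
are broken by greater length, then smaller first-copy start, then
smaller second-copy start — the same rule the brute-force oracle in the
test suite applies, so equality checks are exact.

Defaults: `min_ir_length = 1000` bp and exact copies
(`max_mismatch_rate = 0`), because plastome IRs are near-identical;
a positive mismatch rate extends through isolated mismatches but never
through runs of ten or more, and is deliberately non-default. Plastomes
that have lost an IR return an explicit no-structure result rather than
an error.

The partition is reported in canonical orientation — LSC first from
coordinate 0, then IRb, SSC, IRa. The longer inter-IR arc is the LSC.
On unannotated input the strand is chosen so the LSC string is
lexicographically smallest; annotated records keep their deposited
orientation, and features are rotated with the sequence so junction
reports can be read directly against them.

Junction reports give, per junction, either the gene spanning it (with
the bp split on each side) or the nearest gene on each side with its
distance; distance 0 means the gene ends exactly at the junction. A
gene spanning a single-copy/IR junction leaves its IR-internal fragment
duplicated at the mirrored position of the opposite IR, which is exactly
the boundary-pseudogene pattern; `call_boundary_pseudogenes()` computes
those mirrored fragment coordinates and lengths.

Counting conventions for IR-duplicated genes are left to callers:
duplicated copies are kept as distinct features distinguished by
coordinates, because published gene totals are ambiguous about whether
duplicates count once or twice, and no operation here needs to decide.

## SSR mining

`find_ssrs()` reports maximal perfect tracts of 1–6 bp motifs reaching
the per-class minimum copy numbers; the defaults are the MISA settings
mono-12, di-6, tri-5, tetra-5, penta-4, hexa-4. The scan is
periodicity-based: for motif length m, the boolean vector
`seq[i] == seq[i+m]` is run-length encoded; a TRUE run of length t
starting at i marks a periodic stretch of t+m bases anchored at its
leftmost position, holding `floor((t+m)/m)` complete copies. Reporting
rules, each of which the exhaustive oracle in the tests reimplements
independently:

* tracts are anchored at the leftmost position of the periodic run, and
  the interval covers complete copies only (`length = motif × copies`);
* a tract satisfying several motif interpretations is reported once,
  under the shortest primitive motif (a motif that is itself a
  repetition of a shorter unit is never reported);
* motifs are reported as observed on the given strand — A-runs and
  T-runs are distinct classes, as they are in MISA output;
* runs containing N are excluded; a shorter-motif run wholly inside a
  reported longer-motif tract is suppressed; duplicate intervals are
  de-duplicated.

Compound SSRs (adjacent tracts of different motifs) are reported as
separate perfect loci; only perfect repeats are in scope.

## Dispersed repeats

Four classes are searched: forward (same strand, same orientation),
palindromic (reverse complement), reverse (reversed only) and
complement (complemented only), with REPuter's parameterization as
defaults (minimum size 30, at most 3 mismatches).

The matching semantics needed a concrete decision. Budget-style
"maximal window with ≤ e mismatches" definitions always spend the whole
mismatch budget: any window maximal under that rule extends into
flanking sequence until it accumulates e + 1 mismatches, so a planted
repeat with fewer mismatches is never itself maximal and exact
planted-coordinate recovery is impossible. `plastomics` therefore
defines a reported pair as a **maximal chain of exact runs**: every run
at least `chain_min` (default 10) bases, consecutive runs separated by
exactly one mismatching position, at most `max_mismatch` mismatches
crossed in total. A chance extension past a planted boundary would need
a ≥10 bp exact match immediately after a mismatch on the same diagonal
(probability 4⁻¹⁰ per position), so planted repeats are recovered at
exactly their planted coordinates, and the definition has a clean
all-diagonal brute-force oracle. Reproducing REPuter's own maximal
mismatch-repeat enumeration is an explicit non-goal; repeats whose
mismatches cluster closer than `chain_min` are reported piecewise.

Pairs contained in a longer reported pair of the same class are
suppressed, identical-interval self matches are dropped, and the
genome-scale IR pair itself is excluded from the report when a
partition is supplied (it is architecture, not a dispersed repeat). The
k-mer seed length equals `chain_min`, which is why `min_size < 8` is
rejected as unsound.

## Tandem repeats

Candidate periods are proposed from the distances between recurring
7-mers (a tract of period p repeats its k-mers at lag p); a period needs
at least five supporting lags, which a minimal scoreable tract always
has and chance lags essentially never do. For each candidate period the
lag-p identity vector is segmented: exact runs are merged across
mismatch gaps only when the run beyond the gap more than pays for it
under the scoring weights, and each merged segment is then trimmed to
its best-scoring sub-window (Kadane over the run/gap decomposition,
+2 per matching base, −9 per crossed mismatch — the cost of losing a
match and paying a mismatch). The tract is scored against its per-phase
majority consensus (ties broken alphabetically, for determinism) under
the published weights +2/−7/−7, with minimum score 80 and maximum
period 500. A perfect tandem of total length ℓ scores exactly 2ℓ; each
isolated point mutation costs 9. Overlapping reports are merged keeping
the higher score, then the smaller period, which also collapses
harmonics (a period-p tract rediscovered at 2p, 3p, …).

This is an acknowledged simplification of Tandem Repeats Finder: the
published weights and thresholds are preserved, but the probabilistic
wraparound-alignment model selection is not reproduced, no indels are
modeled inside tracts, and counts on real accessions are reported, not
asserted equal to TRF output.

## Nucleotide diversity and total mutations

`compute_pi()` is the average over all unordered sequence pairs of the
proportion of differing analyzed sites; `compute_eta()` sums, over
analyzed sites, the number of distinct nucleotides minus one. Analyzed
sites are columns with no gap and no N in any row — complete deletion,
the DnaSP default, chosen because it keeps η well-defined per column;
pairwise deletion would make the two statistics use different site
sets. An alignment with zero analyzable columns returns NA with a
warning, never 0, since "no usable data" and "no divergence" must stay
distinguishable.

π is carried at full precision and also rounded to 4 decimals for
display, matching the convention of published hotspot tables. "Region
length" is reported as the alignment length including gap columns, with
the gap-free `sites_used` reported separately; published tables do not
state which convention they use, so the choice is documented here and
real-data equality is not asserted anywhere. Ranking sorts ascending by
π (hotspot tables print their twenty most divergent regions in
ascending order), breaking ties by η descending and then by label, and
attaches class-level mean π values. Alignment itself is consumed
(aligned FASTA), never computed; ragged input is rejected.

## Discriminating power

For a genotype column with class frequencies pᵢ over N varieties,

D_j = 1 − Σᵢ pᵢ (N pᵢ − 1)/(N − 1),

which is algebraically the probability that two varieties drawn without
replacement differ in genotype — the pair-counting identity
1 − Σᵢ nᵢ(nᵢ−1) / (N(N−1)) that the tests verify on random columns.
D_j is 0 iff one class remains and 1 iff all genotypes are distinct,
and splitting any class (a refinement, which is how SNV haplotypes
relate to cpSSR size classes) can only increase it.

N is the number of non-missing entries at that locus (per-locus N),
which keeps Σpᵢ = 1 exact; published work does not state its
missing-data handling, so a fixed panel-wide N remains available as an
argument. cpSSR genotypes are integer fragment sizes with no binning by
default. SNV haplotypes use all variable columns of a locus jointly:
gap-containing columns are removed, variable columns (more than one
distinct non-N base) are concatenated per variety in coordinate order,
and a variety with N at any variable column is marked missing — per
locus there is one multi-site haplotype genotype, not one D_j per SNV.
The polymorphism screen keeps loci with at least 2 classes and reports
the retained fraction as a percentage of the screened loci; where a
published percentage disagrees with that ratio, both numbers can simply
be shown side by side, and neither is asserted.

## Composition

GC denominators exclude N (scopes above 10% N are flagged); the IR
scope pools IRa and IRb. Codon usage counts all annotated CDS on their
coding strand, dropping a non-multiple-of-3 remainder with a warning;
RSCU is count over synonymous-family mean under the standard genetic
code (the plastid code differs only in start-codon policy, which is not
exercised); stop codons are tallied but given no RSCU.

## The synthetic-data generator

`make_plastome()` builds `LSC + IRb + SSC + revcomp(IRb)` over a random
background made repeat-free by construction: periodic tracts at or
above the SSR thresholds are broken by point substitutions, and all
15-mers are made unique within the core and against its reverse
complement. That guarantees no unplanted SSR, prevents spurious IR
anchors, and makes chance dispersed/tandem hits vanishingly unlikely
(a chance dispersed chain would need a ≥10 bp exact diagonal repeat
adjacent to further solid runs). Planted elements get broken flanks so
each is maximal at exactly its planted coordinates — for tandems the
flank must differ from *every* tract character at its phase across
harmonic periods, mutations included, or a shifted harmonic window can
outscore the planted tract; the generator enforces this. The IR
junctions are likewise broken so the detected IR pair is exactly the
planted one. Generation ends with a self-check that re-scans the
sequence and insists the SSR census equals the plan.

Default region sizes (LSC 9,000, IR 2,600, SSC 1,900 bp) are a ~1:10
scale model of a rosaceous plastome, preserving the LSC > IR > SSC
proportions; tests that only need structure use smaller genomes
(LSC ≈ 2,000–3,000 bp) to keep the suite fast, and those sizes are the
package's own choice of test economy. Default per-class per-site
mutation probabilities (coding 0.0027, intron 0.004, IGS 0.0055, rRNA
0, tRNA 0.001) were set once so that expected pairwise divergence
(≈ 2μ for small μ under the star-shaped, no-multiple-hit model) matches
the order observed among congeneric plastomes — IGS a few-fold above
coding, rRNA invariant. Substitutions are uniform over the three
alternative bases, a Jukes–Cantor-like choice made in the absence of
any model claim to mirror. Clades are simulated as independent
per-taxon substitutions from one ancestor (a star phylogeny);
`planted_mutations` instead places an exact number of single-hit
substitutions at distinct sites, making η equal the planted count by
construction. Variety panels draw genotype classes from specified
frequency vectors; with `refine` set, SNV haplotypes split each cpSSR
class into up to three subclasses, so D_j(SNV) ≥ D_j(cpSSR) holds by
construction and the comparison logic can be tested against a known
direction.

What the generator does **not** emulate, and what passing tests
therefore do not show about real data: realistic base composition
(plastomes are ~63% AT; backgrounds here are uniform), gene density and
real gene content, indel processes and alignment error, IR
expansion/contraction along a phylogeny, recombination, multiple hits
at a site, and sequencing artifacts. Conclusions about real accessions
rest on the deterministic definitions of each statistic, not on the
simulations; `check_reference_accession()` exists to confirm the
structural quantities on the deposited rose plastome record once a copy
is available locally (the record is not redistributed with the
package).

## Numerical and degenerate-input choices

* IR tie-breaks: greater length, then smaller first-copy start, then
  smaller second-copy start; overlapping extensions trim keeping the
  left part of the first copy.
* Tandem consensus ties break alphabetically; overlap merges keep
  higher score, then smaller period.
* All percentages print to 2 decimals, π and D_j to 4, full precision
  retained internally.
* Zero analyzable alignment columns, fewer than two non-missing
  genotypes, and unannotated records asked for region classes all
  produce flagged NA values or errors with instructions — never silent
  zeros.
* Sequences of only N are rejected by structure detection;
  `min_ir_length < 25` and dispersed `min_size < 8` are rejected as
  unsound for seeding.

## Pipeline and interfaces

`run_pipeline()` executes requested stages in dependency order on one
genome and writes per-stage TSVs (each with a header comment naming the
0-based half-open convention) plus a versioned `summary.json`; reruns
are byte-identical. Configuration defaults equal the published
parameter sets of every stage and are asserted by a golden test;
`read_config()` merges YAML overrides over them. As an R package, the
exported functions and this vignette are the primary interface;
`scripts/acceptance.R` is the reproducibility entry point, and the
problem sizes it uses (100 oracle sequences, 50 plastomes, 60 scans of
10 kb, 1,000 genotype columns, 200 clade replicates) are the package's
standing choice for a ~1-minute verification run.
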