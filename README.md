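# plastomics

Comparative chloroplast (plastid) genome analysis and molecular-marker
evaluation in R.

Angiosperm plastomes are circular molecules of roughly 107–218 kb with a
conserved quadripartite architecture: a large and a small single-copy
region (LSC, SSC) separated by a pair of inverted repeats (IRa/IRb).
Expansion and contraction of the IRs moves genes across the four
junctions (JLB, JSB, JSA, JLA) and creates truncated duplicates —
boundary pseudogenes such as *rps19*Ψ and *ycf1*Ψ in rosaceous
plastomes. Because the plastome is uniparentally inherited and
structurally stable, its microsatellites (cpSSRs) and the single
nucleotide variations (SNVs) in their flanking sequence are attractive
markers for cultivar identification and DNA profiling, for example in
ornamental roses where dense pedigrees make varieties hard to separate
morphologically.

`plastomics` implements the full desk side of such a study as tested,
reusable functions:

* **Structure** — detection of the maximal disjoint inverted-repeat pair
  on the circular genome (k-mer anchors against the reverse complement,
  chained and extended to maximal exact matches), canonical
  LSC–IRb–SSC–IRa rotation, junction gene-distance reports, and boundary
  pseudogene calls with the IR-mirrored fragment coordinates.
* **Repeats** — perfect SSR mining at the MISA minimum repeat counts
  (mono-12, di-6, tri-5, tetra-5, penta-4, hexa-4); dispersed repeats in
  the four REPuter-style classes (forward, palindromic, reverse,
  complement; minimum size 30, up to 3 mismatches); tandem repeats under
  Tandem Repeats Finder weights (+2 match, −7 mismatch, −7 indel;
  minimum score 80, maximum period 500); and per-region summaries.
* **Diversity** — per-region nucleotide diversity and total number of
  mutations from multiple alignments, with complete deletion of gap/N
  columns, and hotspot-style ranking with class-level means:

  π = average over unordered sequence pairs of (pairwise differences at
  analyzed sites) / (analyzed sites);
  η = Σ over analyzed sites of (distinct nucleotides at the site − 1).

* **Markers** — genotype tables (varieties × loci) for cpSSR fragment
  sizes and SNV flanking haplotypes, and the per-locus discriminating
  power

  D_j = 1 − C_j = 1 − Σᵢ pᵢ (N pᵢ − 1)/(N − 1),

  the probability that two varieties drawn without replacement differ in
  genotype at locus j (equivalently 1 − concordant pairs / all pairs).
* **Composition** — GC content per region and codon usage / RSCU /
  third-position base composition from annotated CDS.
* **Synthetic data** — a generator of plastome-like genomes on
  repeat-free backgrounds with planted IRs, SSRs, dispersed and tandem
  repeats, junction-spanning genes, simulated clades and variety panels,
  all with exact ground truth, so every stage is testable offline.

## Worked example

```r
library(plastomics)

sp <- synth_spec(seed = 7,
  planted_ssrs = data.frame(motif = c("A", "AT"), copies = c(12, 6),
                            region = "LSC"))
mp <- make_plastome(sp)
part <- detect_inverted_repeats(mp$record)
part
#> <region_partition> 16,100 bp: LSC 9000 | IRb 2600 | SSC 1900 | IRa 2600

find_ssrs(mp$record)
#>   motif copies start  end length
#> 1    AT      6   956  968     12
#> 2     A     12  5753 5765     12

junction_report(part)[1:2, c("junction", "gene", "split_left", "split_right")]
#>   junction gene split_left split_right
#> 1      JLB  jgA        400         120
#> 2      JSB  jgB        150         350
```

The partition recovers the planted 9,000/2,600/1,900/2,600 bp layout
exactly; the two planted SSRs are the only loci reported, at their
planted coordinates; and the junction report shows the two planted
junction-spanning genes with their bp split on each side of the
boundary (the 120 bp of `jgA` inside IRb is what
`call_boundary_pseudogenes()` mirrors into IRa as a pseudogene
fragment).

Marker comparison on a simulated 93-variety panel, where SNV haplotypes
refine the cpSSR size classes:

```r
pan <- make_panel(sp)
compare_marker_classes(pan$ssr, pan$snv)$summary
#>   class   mean    min max
#> 1 cpSSR 0.5260 0.0000   1
#> 2   SNV 0.7292 0.4984   1
```

As expected for a refinement, D_j of the SNV haplotypes dominates D_j of
the fragment sizes at every locus.

Real accessions flow through the same functions: `read_genbank()` /
`read_fasta()` produce the annotated record, and
`check_reference_accession()` recomputes the headline structural
quantities of the deposited miniature-rose plastome (region lengths,
per-region GC, SSR census, longest intron) from a locally downloaded
copy of the GenBank record.

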