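---
title: "polygbs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polygbs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

polygbs implements a reference-free genotyping-by-sequencing (GBS) workflow
for mapping populations, aimed at species — especially allopolyploids —
without a genome assembly. This vignette explains the models and rules each
stage implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
several reasonable choices existed.

## The problem

GBS sequences a reduced representation of the genome: fragments produced by a
rare-cutter/frequent-cutter double digest (here PstI/MspI), size-selected to
roughly 300–800 bp and sequenced paired-end (150 bp). With no reference
genome, loci must be assembled from the reads themselves; in an
allotetraploid (AABB) there is the added risk of collapsing homoeologous loci
from the two subgenomes into a single apparent locus. For an F2 population,
genotypes must further distinguish heterozygotes from homozygotes, which is
only possible with adequate per-locus read depth — the pipeline is therefore
deliberately *imputation-free*: cells without evidence stay missing rather
than being guessed.

## Reference construction

1. **Demultiplexing** (`demultiplex()`): a forward read is accepted only if
   it starts with a known inline barcode immediately followed by the PstI
   remnant `TGCAG`. Matching is exact and longest-barcode-first (prefix-nested
   barcode sets resolve deterministically). Reverse reads are not checked for
   the second enzyme's site. Barcode error correction is out of scope.
2. **Trimming** (`trim_equalize()`): barcodes, the site remnant, a fixed
   error-prone 3' tail (default 5 bp) and per-barcode equalisation bases are
   removed so that *every* forward read has one length (130 bp for 150-bp
   reads and barcodes up to 10 nt) and every reverse read another (145 bp).
   Fixed-length trimming replaces quality-based trimming: it is deterministic
   and equal read length is a hard prerequisite of stack clustering.
3. **Pair joining** (`join_reads()`): overlapping pairs are merged (longest
   overlap with mismatch fraction ≤ 0.25, per-base quality tie-break) and
   padded 3' with `A`s to the joined length; non-overlapping pairs are joined
   as forward + reverse-complemented reverse with **no** separator. The
   junction offset (= forward length) is tracked through clustering because
   deletion alleles generate spurious SNP calls exactly at the two
   junction-flanking positions (see below). In the 300–800 bp size window
   with 150-bp reads, pairs essentially never overlap, so the joined path
   dominates; the merge path exists for shorter size windows and is fully
   unit-tested.
4. **Within-sample stacks** (`build_stacks()`, parameters `m = 2, M = 1,
   N = 1`): identical reads form stacks (≥ `m` reads), stacks within `M`
   mismatches merge by single-linkage connected components with per-position
   majority consensus (ties to the alphabetically smallest base), and
   leftover reads attach as secondary members to a *unique* nearest stack
   within `N` mismatches (distance ties discard the read). Single-linkage
   components were chosen over pairing heuristics because they are
   deterministic and order-independent; the unit tests pin the whole
   behaviour to a brute-force oracle.
5. **Across-sample clustering** (`asustacks()`): all samples' stack
   consensuses are pooled and clustered with the identical algorithm at
   `m = 1`. Each cross-sample cluster records which samples contributed —
   its *presence count*. This avoids a known failure mode of clustering
   tools that drop high-depth loci as presumed repeats.
6. **Reference filtering** (`build_reference()`): clusters present in fewer
   than `presence_pct` of samples (default 50%) are removed, then tags with
   ≥ `identity_pct` (default 98%) pairwise identity are collapsed to a
   single representative. The collapse is the key polyploid/heterozygosity
   safeguard: if the two alleles of one locus form separate tags, reads from
   heterozygous individuals split between them and both score as homozygous.
   Collapsing is transitive (connected components), keeping the
   highest-presence tag (ties: smallest tag id); identity is computed
   directly (Hamming for equal lengths, end-free alignment otherwise) rather
   than through a BLAST e-value, which keeps it deterministic and
   dependency-free.

## Genotype scoring

`count_alleles()` assigns every joined read to the unique nearest reference
tag within 3 mismatches (ungapped; ties discard the read) and calls variant
sites per tag column: at least two bases at pooled depth ≥ 2, with the
alternate base at ≥ 5% of the pooled column depth. The 5% prefilter stands in
for the error models of a full variant caller — with pooled depths in the
thousands, raw sequencing error alone reaches depth 2 at most columns — and
sits well below the 10% allele-frequency filter applied afterwards, so it
never decides a marker's fate. Alternatively, `ingest_vcf()` accepts VCFs
(with `FORMAT/AD`) produced by an external caller against the written
reference; multiallelic records are dropped, indels are treated like SNPs.

Site filters, in order:

* `filter_af()`: pooled alternate-allele frequency within [0.10, 0.90],
  boundaries inclusive. Pooled (not per-sample) frequency is used; in an F2
  the pooled frequency of a real biallelic site is near 0.5.
* `remove_adjacent()`: sites at offset distance exactly 1 on the same tag are
  removed (both members, whole runs) — adjacent calls are predominantly
  misalignment artifacts. "Adjacent" means distance exactly 1.
* `remove_junction_flanking()`: for artificially joined tags, sites at
  offsets `junction − 1` and `junction` are removed. A 1-bp deletion allele
  shifts one extra base past the read end, which lands at the junction and
  creates a spurious call there; 2-bp deletions create adjacent pairs caught
  by the previous filter.

`score_genotype()` maps allelic depths to codes with the ratio
`r = AD_ref/AD_alt`: total depth < 8 → `-` (missing); `r ≥ 10` → `A`
(homozygous parent-1); `r ≤ 0.10` → `B`; `4 < r < 10` → `D` (ambiguous
A-or-H); `0.1 < r < 0.25` → `C` (ambiguous B-or-H); anything else → `H`.
Boundary ratios are evaluated on integer cross-products, so `r = 4`, `0.25`
fall to `H` and `r = 10`, `0.1` to `A`/`B` exactly, with no floating-point
drift; the gaps in the printed bands (`[0.25, 4]` plus the boundary points)
all fall to `H` ("other ratios"). `AD_alt = 0` means `r = +Inf` → `A`.

Markers are kept only where the parents score as homozygous for different
alleles ({A, B}), with polarity flipped (A↔B, C↔D) when parent 1 carries the
alternate allele; markers missing in > 30% of samples or with definitive-call
balance outside [0.10, 0.90] are dropped, then samples missing > 30%.

## Matrix consolidation and deduplication

Genotype codes carry *allele-set* semantics over the three true F2 states
(`A`={P1hom}, `H`={het}, `B`={P2hom}, `D`={P1hom,het}, `C`={P2hom,het},
`-`=all). Consolidating the SNPs of one tag into one marker is then simply
set intersection per sample — one rule that reproduces every scenario of the
worked 12-column example, flags exactly the conflicting combinations (A+B,
A+C, A+H, B+H, B+D) as `F`, and resolves combinations the example does not
list (e.g. C+D → H) consistently. One caveat is documented rather than
hidden: for a tag whose codes are all ambiguous (`C` and `D` only, no `H`),
intersection yields `H`, whereas "retain the scores" would keep the
ambiguity; the intersection is what the algebra implies and is applied
uniformly. Tags whose conflict fraction across progeny reaches 20% are
removed (both subgenomes aligning to one tag); surviving `F` cells become
missing. Duplicated samples merge with the same intersection rule, counting
empty intersections as disagreements.

For mapping, cosegregating markers are reduced to one representative: markers
sorted by ascending penalty (C/D cost 1, missing/F cost 2; ties by id) join
the first earlier representative whose vector is compatible (non-empty
intersection at every sample). Compatibility rather than strict equality is
used so that the penalty ordering is meaningful — under strict equality all
members of a class would have identical penalties and the "smallest penalty"
rule would be vacuous. The scan order guarantees each representative has
minimal penalty in its class, and two markers differing by a definitive
A-vs-B call anywhere never merge.

## Linkage mapping

`estimate_two_point()` maximises the standard no-interference F2 two-locus
likelihood in the recombination fraction r, marginalising each ambiguous code
over its allele set — so `C`, `D` and `-` contribute partial information
instead of being discarded. Each of the 49 ordered code-pair probabilities is
a quadratic in r (sum over gamete haplotypes), which makes the all-pairs scan
(`two_point_all()`) one matrix product over an r grid (step 0.0025) followed
by local refinement of the best grid cell to tolerance 1e-6; boundary maxima
at r = 0 and r = 0.5 are checked explicitly. LOD is the log10 ratio against
r = 0.5. Pairs with fewer than 10 jointly informative samples are flagged
unreliable.

Groups form by single linkage over edges with LOD ≥ 6 and r ≤ 0.35;
singletons are reported separately. Ordering within a group is a
deterministic greedy seriation — farthest-pair endpoints, repeated cheapest
insertion minimising the sum of adjacent r, then 2-opt segment reversals and
window-3/window-4 permutation ("ripple") passes. This is explicitly an
approximation of multipoint maximum-likelihood ordering: it uses only
two-point estimates, and is labelled as such in the map printout. The 2-opt
pass matters in practice; without it the insertion heuristic can assemble a
terminal block of the chromosome at the wrong end of the path. Orientation is
canonicalised (first marker id < last), positions are cumulative Kosambi
distances `d = 25 ln((1+2r)/(1−2r))` cM over adjacent r.

Quality control mirrors the error-detection idea of classical multipoint
mappers: for each progeny the minimal crossover count explaining the ordered
codes is computed by dynamic programming over allele sets, and an interior
marker scores a double-recombination event whenever deleting it lowers that
count by two. Markers exceeding 4 events are pruned iteratively (worst first,
ties by id, recount after each removal). We use the crossover-delta
definition because it is exactly what a minimal-recombination oracle
computes; a simpler "common flank genotype" shortcut misses configurations
such as (H, A, B), where the flanks share no genotype yet the middle marker
still forces two extra crossovers. Consecutive markers with no progeny whose
codes are provably recombinant (disjoint allele sets) share a cosegregation
bin, and dedup members re-attach at their representative's position and bin.

A 1:2:1 segregation screen (`segregation_screen()`, chi-square, α = 0.01) is
available but not applied by default: distorted markers can be genuine, and
the decision to hold them out and re-add them is a curation step, not an
algorithm.

## Subgenome assignment

Reads from diploid progenitor accessions (the A-genome donor) are processed
through the same trim/join path and matched to reference tags within 4
mismatches (`progenitor_hits()`). A tag is *present* when hit in at least 2
of the 3 accessions, *absent* when hit in none; single-accession hits are
ambiguous and excluded as evidence. For each linkage group,
`assign_subgenome()` computes the fraction f of informative tags that are
present and scans the ordered presence pattern for change points (binary
segmentation minimising Bernoulli deviance; a split needs ≥ 5 tags per
segment and a fraction difference ≥ 0.25; at most 2 breakpoints). A group is
called **A** when f ≥ 0.30 with no accepted change point, **B** when
f ≤ 0.05 with none, and **mixed** otherwise — a change point overrides the
overall fraction because an A or B call means the pattern holds along the
group's *entire length*; a mixed call with breakpoints is the signature of a
homoeologous translocation. The thresholds 0.30/0.05 are operating points for
what is, in the field, a visual judgement; they are parameters, and with the
default generator settings (1% progenitor divergence, 4-mismatch hits) the
observed fractions sit near 1 and 0, far from both.

`detect_dosage()` classifies progeny over a marker region by the ratio of
their median total depth to the cohort's per-marker median: ≤ 0.25 (or ≥ 80%
of region markers without reads) → deleted, ≥ 1.75 → duplicated. This is the
compensated deletion/duplication pattern produced when a translocation
heterozygote segregates: progeny missing one homoeologous segment carry two
copies of the partner segment, roughly doubling its read depth.

## The synthetic-data generator

`simulate_gbs()` generates the whole experiment from one seed: a random A
subgenome; B = A mutated at 5% (safely beyond the 1-mismatch clustering and
the 98% collapse radius, so homoeologs never merge); parent 2 = parent 1
mutated at 0.2% (≈ 0.55 expected SNPs per 275-bp tag); three progenitor
accessions at 1% from A. Defaults: 2 homoeologous chromosome pairs of 1 Mbp,
60 F2 progeny, mean depth 30, error rate 0.2%, 150 cM per chromosome.
Digestion finds PstI/MspI sites with fill-in-aware cut geometry (fragments
read `TGCAG…` from the rare-cutter end), keeps 300–800 bp fragments with at
least one PstI end, and orients them 5'→3' from that end. Meiosis is
Haldane: Poisson crossovers (mean `map_length_cm/100` per gamete), uniform
positions, no interference — Kosambi enters this package only as a distance
transform, not as a meiosis model. Reads are drawn per haplotype as
Poisson(depth/2), carry the sample's barcode plus remnant, and receive
uniform substitution errors. A haplotype yields reads for a fragment only if
its own parent's digest retains it, so restriction-site polymorphisms become
presence/absence variation naturally. Because all mutation is
substitution-only, every genome stays coordinate-aligned, and every read id
encodes (sample, fragment, haplotype) so downstream calls can be audited
against truth. Default barcodes use a checksum base (pairwise Hamming
distance ≥ 2, like real GBS barcode sets), so a single sequencing error in
the barcode rejects the read instead of silently reassigning it to another
sample.

An optional reciprocal homoeologous translocation swaps chromosome tails
between one A/B pair. Carried by *both* parents it models a lineage-level
rearrangement relative to the progenitor — fixed in the cross, invisible to
mapping, but flipping the progenitor-presence pattern at the breakpoint; that
is the configuration used to validate breakpoint detection end to end.
Dosage-variant progeny are generated by `simulate_dosage_variant()`, which
applies copy-number 0/2 scaling to a progeny's depths over a region; the
meiosis of an actual translocation heterozygote (cross-type pairing,
unbalanced gametes) is not modelled.

What the generator does **not** emulate — and what passing tests therefore do
not demonstrate about real data: indel sequencing errors and indel alleles
(indels enter only through the VCF path), PCR duplicates and chimeric
ligation artifacts, per-cycle quality profiles, uneven sample representation,
repeat families beyond the two subgenomes, residual heterozygosity in the
parents, and bulk F2:3 sampling noise. Real data will show lower genotype
recovery and noisier maps than the synthetic benchmarks.

## Numerical and scale choices

All tie-breaks are deterministic (alphabetical base in consensus ties,
smallest id elsewhere) and inputs are canonically sorted before clustering,
so every stage is order-independent; runs are byte-identical under a fixed
seed, with the RNG kinds pinned for portability. The test suite validates the
full default-scale experiment (2 × 1 Mbp pairs, 60 progeny, ≈ 0.75 M read
pairs, ≈ 430 loci, a few minutes on one core) plus a 0.6-Mbp translocation
run (genetic length scaled proportionally, 90 cM, so marker density per cM
stays at the default); unit tests run on 150–200 kbp single-pair
configurations and on
brute-force-checkable instances (≤ 30 reads for clustering, ≤ 5 markers for
crossover counting, 61 × 61 depth grids for scoring). Known limitations:
ungapped read↔tag matching (a read with an indel relative to its tag is
dropped or mismatch-scored rather than gap-aligned), greedy ordering below
multipoint-ML accuracy on noisy data, and no multi-enzyme (> 2) digest
support.
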