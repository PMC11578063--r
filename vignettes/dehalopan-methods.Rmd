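---
title: "Methods: comparative pangenomics of organohalide-respiring bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative pangenomics of organohalide-respiring bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Organohalide-respiring bacteria such as *Dehalobacter* respire by reductively
removing halogens from chlorinated substrates.  The enzyme family doing this
work — reductive dehalogenases, whose catalytic subunit is RdhA — is large
(tens of paralogues per genome), fast-evolving, and frequently mobilized
between lineages.  Three intertwined questions recur when comparing such
genomes:

1. **Which lineages are distinct species?**  Average nucleotide identity
   (ANI) at the conventional 95% cutoff partitions a genus into species-level
   clades.
2. **How is the RdhA repertoire organized?**  RdhA proteins are classified
   into orthologue groups (OGs) at a 90% amino-acid identity cutoff with
   phylogenetic support, and their genomic clusters compared across genomes.
3. **Which genes moved horizontally?**  Discordance between an OG's gene
   tree and the species clades, and high-identity genomic islands shared by
   divergent genomes, both point to horizontal gene transfer (HGT).

`dehalopan` implements this pipeline end to end and pairs it with a
pangenome simulator whose outputs carry complete ground truth, so every
analysis stage has a recovery test that needs no downloads.

# The simulator and what it emulates

`simulate_pangenome()` evolves a fixed root layout — core genes, RDase gene
clusters, and intergenic spacers on one circular contig — along a species
tree under Jukes–Cantor substitution.  Genes and spacers alike diverge with
branch length, so whole-genome nucleotide identity tracks tree path length:
the default tree (terminal branches 0.004, clade stems 0.03 expected
substitutions/site) yields ~99% within-clade and ~93% between-clade
identity, emulating a genus whose clades sit just either side of the 95%
species line.  Specific choices:

* **Coding realism where it matters.**  Genes are random codon sequences,
  ATG-initiated and TAA-terminated with no internal stops; rdhA genes carry
  two planted CXXCXXXC iron–sulphur motifs.  Start/stop codons and motif
  cysteines are frozen during evolution, and substitutions creating internal
  stops are repaired, so planted genes always remain minable.  The repair
  and freezing bias realized divergence by well under half a percent, which
  the Jukes–Cantor property test absorbs in its tolerance.
* **Exact identity arithmetic.**  `mutate_to_identity()` substitutes an
  exact site count without indels, so threshold tests (90.0% vs 89.5%
  identity; 9,999 vs 10,001 bp gaps) are sharp, not statistical.
  Orthologue-group ancestors within an RDase cluster are derived from one
  cluster ancestor at 80–90% identity each, which places between-OG
  identities in the 60–85% band while within-OG identity stays ≥ 90%.
* **The island replaces the intergenic span.**  The mobile island (by
  default ~20 kb: an rdhA + anchor-protein pair, transposase / integrase /
  relaxase / recombinase cargo, and dichloromethane-cassette-like genes) is
  spliced immediately 3′ of a hotspot anchor core gene, occupying the whole
  interval between two core genes.  The true island is therefore exactly the
  inter-core-gene interval, so bound recovery can be tested for equality
  rather than overlap.  Recipient copies diverge from the donor's by exact
  substitution at the configured identity (default 98.5%).
* **Determinism.**  Every random draw runs in a stream derived by hashing
  the global seed with a stable key (branch label, genome id, island copy),
  so outputs are byte-identical for a seed and independent of evaluation
  order.
* **What it does not emulate.**  No indels by default, no recombination
  within genes, no codon-usage or GC-content realism, no rearrangements, no
  assembly fragmentation.  A passing recovery test shows the algorithms are
  correct under substitution-dominated divergence with known truth; it does
  not certify behaviour on real assemblies with indels, repeats and
  annotation noise.

Problem sizes are deliberately desk-scale — 40–90 kb genomes, 30–50 core
genes, 4–9 genomes per fixture — chosen so the full recovery suite runs in
minutes on one CPU while still exercising every code path.

# RdhA mining

`screen_candidates()` retains a translated CDS iff, in fixed order: length
≥ 200 aa; at least one CXXCXXXC motif (all start positions counted,
overlaps allowed); not a pseudogene; not truncated (the annotation's partial
flag — the field's "truncated genes" exclusion is not otherwise defined);
and, when a reference panel is supplied, best panel identity ≥ 25% over
≥ 50% coverage.  The panel step is a deliberate desk-scale surrogate for a
profile-HMM domain search: it needs no external database, and at these
divergences the motif + length filters carry most of the discriminative
load.  Rejections carry exactly the first failing reason so tallies are
reproducible.

# Orthologue groups

Pairwise identity is computed from a global alignment with free end gaps
(BLOSUM62, gap open 11, extend 1): matches divided by aligned columns, with
terminal-gap columns excluded by construction.  We prefer this over local
(BLAST-style) identity because full-length RdhA comparisons are the use
case and end-gap-free global identity is stable to terminal extensions;
the definition is documented so users can reconcile against local-identity
numbers.

`assign_ogs()` takes single-linkage components at ≥ 90% — the graph
realization of "within 90% identity" — and numbers them by (size, smallest
member), lettering singletons lexicographically (assignment order for
singleton letters is not derivable from prior art, so we fix lexicographic
order).  `curate_partition()` then merges label pairs that interleave on a
neighbour-joining tree: the minimal clan (smallest edge-defined leaf set)
spanned by one label captures members of the other, i.e. neither comprises
a single unique clade.  The minimal-clan formulation is root-free, which
matters because midpoint or outgroup rooting can inflate a label's apparent
clade when the only outside leaves are themselves nested.  Merge records
keep the minimum cross identity but do not enforce a floor.

Trees are neighbour-joining on Poisson-corrected distances
`d = -(19/20) ln(1 - (20/19) p)`; `p ≥ 0.95` (where the correction
diverges) is capped at 0.9499 with a warning.  Bootstrap support comes from
column resampling of the cluster alignment (or whole-gene resampling for the
concatenated species tree, respecting gene-level correlation).
Neighbour-joining stands in for maximum-likelihood inference deliberately:
downstream logic consumes only topology (clans, clades), and every tree
consumer accepts an externally computed Newick for users who want ML trees.

`detect_umbrellas()` walks one node rootward of each label's clade and
emits the covered labels as an umbrella when all leaves under the parent
stay above 75% pairwise identity; only maximal umbrellas are kept.  The
one-step limit is intentional — umbrellas describe the immediate
neighbourhood of an OG, not arbitrary ancestors.

`clade_concordance()` restricts the gene tree to one OG and tests each
genome clade (≥ 2 members) for monophyly, using the clan definition on
unrooted trees.  Zero violations reads as vertical descent; any violation
flags an HGT candidate.  This screen is the in-scope surrogate for full
species-tree-aware reconciliation with explicit
duplication/transfer/loss costs, which is out of scope.

# ANI and species

`directional_ani()` is an ANIb-style fragment scheme: the query is chopped
into 1020 bp windows, each window's best local alignment against the
reference (both strands) is scored, and windows are retained at ≥ 30%
identity and ≥ 70% coverage; ANI is the mean retained identity.  Both
directions are computed for every pair and the symmetric summary is their
mean (the direction reduction is not fixed by convention, so the choice is
recorded and a median option exists).  The alignment backend is pluggable:
`blastn` (the engine ANIb itself uses) when available, exact dynamic
programming otherwise, with an equivalence test on 10 kb inputs.
`delineate_species()` takes single-linkage components at ≥ 95%.

Numerical notes: self-ANI is exactly 100; fragments with no retained hit
propagate as missing; genomes sharing no retained fragment report `NA` with
aligned fraction 0 rather than an arbitrary low value.

# Core pangenome

`cluster_genes()` connects proteins at ≥ 50% identity over ≥ 80% of the
shorter sequence and takes connected components — with the simulator's
identity gaps (within-family ≥ 80%, between < 50%) this coincides with
Markov clustering, which remains a noted extension.  An inverted 4-mer
index prescreens pairs (Jaccard ≥ 0.03) before alignment; unrelated
proteins share essentially no 4-mers, so the screen cannot sever true
edges at these identities.  Cluster alignments use a center-star aligner
(anchor on the longest member, merge pairwise gap patterns); for
substitution-only simulated data the members are equal-length and the
"alignment" is a direct stack.  We chose the in-package center-star over
shelling out to an external aligner to keep the pipeline self-contained
and deterministic; it is not a general-purpose MSA and would be the first
thing to swap for indel-rich real data.

Homogeneity scores operationalize two alignment diagnostics: *geometric*
homogeneity is 1 minus the mean per-column fraction of member pairs
disagreeing in gap/non-gap state, and *functional* homogeneity is the mean
per-column frequency of the modal residue among non-gap members.  These
formulas are documented and unit-tested as this package's definitions; they
follow the parenthetical descriptions used with pangenome tooling but are
not claimed numerically identical to any external implementation.  Marker
selection ranks single-copy core clusters by (geometric descending,
functional ascending) — clean alignments whose residues still vary enough
to resolve strains — and takes the top *n* (42 by the field's convention;
the exact cutoffs behind that 42 are not published, so selection is
rank-based with *n* as a parameter).

# Synteny and islands

`find_rdh_clusters()` applies the 10 kb adjacency rule with gaps measured
between feature boundaries (end to start, exclusive) — the stricter reading
of "within 10 kb of each other"; the gap definition is config-exposed.
Truncation flags mark clusters whose outermost member lies within the gap
limit of a contig end, since such clusters may continue past an assembly
break.  `link_clusters()` emits solid links for same-OG pairs (> 90%) and
dashed umbrella-tier links for pairs sharing an umbrella at 75–90%; each
member links to at most one counterpart per tier, best identity first, ties
to the smaller index.  `synteny_conservation()` counts conserved adjacencies
orientation-free, so whole-cluster reversals score as colinear.

`delimit_island()` spans from the inner boundary of the nearest single-copy
core gene upstream of the query to the inner boundary of the nearest one
downstream (a flag switches to gene-inclusive bounds); missing flanks
extend to the contig end and are flagged open.  `compare_islands()`
fragments one island into 1 kb windows, takes each window's best local hit
in the other island, and chains consecutive retained windows into shared
blocks (≥ 1 kb at ≥ 90% identity by default) — a greedy realization of
local-alignment chaining that is exact enough at desk scale and avoids
quadratic whole-island dynamic programming.  `mge_tally()` classifies
enclosed genes by versioned product-text keywords (transposon/IS;
conjugative/phage; other recombinase — the bare word "recombinase" falls in
the third bin so the first two stay specific); tallies are keyword
estimates, and model-based mobile-element classifiers are explicitly out of
scope.

# Degenerate inputs and tie-breaks

* All-N sequences make GC content an error, not a number; windows without
  G or C report skew 0.
* Internal stops in a CDS flag the protein rather than failing translation;
  minus-strand features are reverse-complemented before translation
  (bacterial code, table 11; GTG/TTG starts render as M at position 1 only).
* Lowercase bases and non-N ambiguity codes normalize to N with a warning,
  keeping downstream counts deterministic.
* OG numbering, singleton lettering, species labels and cluster ids are all
  derived from sorted member ids, so outputs are invariant to input order.
* Identity 2% between proteins would imply an infinite Poisson distance;
  the cap at p = 0.9499 keeps neighbour joining defined and warns.

# Interface

The package is a set of pipeable functions over tibbles (sequences ride in
`Biostrings` containers, trees in `ape` `phylo` objects), with
`tidy()`/`glance()` methods on partitions and ANI tables and `plot_*()`
functions for the main result types.  There is no shell entry point: an
analysis session — or the two scripts under `scripts/` — is the intended
interface.

# Known limitations

* The identity definition (global, free end gaps) will differ from local
  BLAST identity for partially overlapping proteins; comparisons against
  databases built on local identity need care at the 90% boundary.
* Connected-component clustering can chain families through bridging
  sequences at borderline identity where Markov clustering would split
  them; the simulator's identity gaps avoid this regime, real data may not.
* The center-star aligner degrades on indel-rich clusters.
* Keyword MGE tallies undercount genes annotated only as hypothetical
  proteins — as most genes in real nested recombinase islands are.
* The concordance screen detects topological discordance only; transfers
  between sister taxa that preserve clade monophyly are invisible to it.
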