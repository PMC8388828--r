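---
title: "Methods: virus-host linkage and community structure in vireco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virus-host linkage and community structure in vireco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vireco)
```

## What the package computes

vireco implements the bespoke computational stages of a freshwater
spring-system virus ecology workflow as tested, composable functions:

1. **Virus-host prediction.** Three independent evidence searches link an
   environmental viral contig to candidate prokaryotic hosts: CRISPR
   spacers extracted from host genomes are searched against the viral
   contigs; viral tRNA genes are searched against host genomes; and the
   viral contigs themselves are searched against host genomes for regions
   of sequence homology. Each surviving hit adds points to the candidate
   taxon — 3 for a CRISPR match, 2 for a homology match, 1 for a shared
   tRNA — and the top-scoring taxon is the putative host.
2. **Phage phylogenomics.** Complete phage genomes are dereplicated,
   compared all-versus-all at the protein level, placed in a
   neighbor-joining tree built from a shared-gene Dice distance, and cut
   into lineages at node-depth cutoffs.
3. **Community structure.** Reads are mapped to contigs with a minimum
   identity rule; a contig is "present" in a sample only when enough of
   its length is covered; abundances are normalized by contig length and
   library size; features are partitioned by which sites or seasons share
   them; communities are compared with Bray-Curtis dissimilarity and the
   Mantel permutation test.

Everything runs against a synthetic-data generator that plants ground
truth, so every stage has a parameter-recovery test with a known answer.

## Evidence filters and the consensus score

A hit must satisfy **every** cutoff of its filter; unset cutoffs are
ignored (`filter_hits()`):

| search | min identity | min query coverage | max mismatches | min length | max E |
|---|---|---|---|---|---|
| CRISPR spacer vs virus | 80% | 100% | 1 | — | 1 |
| viral tRNA vs host | 90% | 95% | 10 | 60 bp | 0.001 |
| virus vs host (homology) | 50% | — | — | 300 bp | 0.001 |

Scoring is **per evidence type, not per hit** (`score_consensus()`): a
taxon supported by one or fifty CRISPR-passing hits gains 3 points either
way. We read the scoring rule as a predicate ("was there a CRISPR
match?"); per-hit accumulation would let many marginal homology HSPs
outvote a single decisive CRISPR link, inverting the intended weighting.
The per-hit variant remains available via `per_hit = TRUE`.

Exact score ties are reported as **unresolved** (`tie = TRUE`, all tied
taxa listed) rather than broken arbitrarily: no tie-breaking rule is part
of the method, and silently preferring one taxon would fabricate a
biological claim. The canonical tie is a 3-vs-3 conflict between a
CRISPR-supported taxon and a taxon supported by homology plus a shared
tRNA.

## The alignment engine

All searches run on one affine-gap Smith-Waterman core (Rcpp) with
blastn-style defaults: match +2, mismatch −3, gap open 5, gap extend 2
(protein searches use BLOSUM62 with 11/1). Multiple alignments per pair
are recovered Waterman-Eggert style: after each optimal local alignment
is reported its subject span is masked and the matrix is re-solved, so
reported HSPs never overlap on the subject.

Percent identity counts matches over all alignment columns (gap columns
in the denominator), and query coverage is the single-HSP query span over
the query length — both the BLAST tabular conventions. Whether the
original analyses used HSP-merged coverage is unknowable from the method
description; single-HSP coverage is the simplest reading and is what the
filters see. Coordinates are 1-based inclusive, with `sstart > send`
encoding minus-strand hits.

**E-values** use the Karlin-Altschul form `bit = (λ·S − ln K)/ln 2`,
`E = m·n·2^(−bit)`, with fixed published ungapped nucleotide constants
(λ = 1.33, K = 0.621; protein λ = 0.267, K = 0.041) and the raw `m·n`
search space. These constants are not matched to the +2/−3 scoring regime
(the method source never states its parameterization), which makes short
spurious seed matches look more significant than BLAST would report.
This is deliberate and harmless here: the E-value cutoffs (≤ 1, ≤ 0.001)
are so loose relative to genuine evidence hits (planted protospacers,
tRNAs and homologous segments score hundreds of bits) that filter
outcomes are insensitive to the parameterization — asserted by the
boundary-sweep and panel tests rather than assumed.

**Seeded search.** The default search mode seeds on exact 12-mers,
clusters seeds by diagonal, and solves only padded windows around seed
clusters; `mode = "exhaustive"` solves the full matrix. The window
padding (`min(max query length, 150) + 50`) guarantees the two modes
return identical hit sets for queries up to 150 residues — covering
spacers, tRNAs and reads — and the equivalence is asserted on 200 random
planted instances restricted, as the guarantee is stated, to hits that
pass some downstream evidence filter. For longer queries (whole viral
contigs) the seeded mode is a heuristic, but any homology hit that can
pass the 300 bp/50% filter at these scores produces dense seed clusters,
so in practice nothing filter-relevant is lost. Sparse one-to-two-seed
clusters of long queries get reduced padding (80 bp): they are noise and
need only a short extension margin.

## CRISPR array detection

The detector (`find_arrays()`) is CRT-style: it seeds on exact 8-mers
recurring at an admissible period (repeat 21-48 bp, spacer 18-72 bp,
within a 500 bp window), extends the anchor pair with a small mismatch
budget, chains additional copies at the same period (≥ 3 copies at ≥ 75%
identity to the anchor), refines boundaries against all copies, and
accepts arrays whose copies each reach 85% identity to the column-wise
consensus. Degenerate tandem repeats — period minus repeat length below
the spacer minimum — are rejected, since spacers must be unique sequence
for host linking to mean anything. All thresholds live in
`crispr_config()` because the upstream method is described only as a
custom script; the defaults are conventional, not recovered from any
source.

Boundary refinement grows the repeat only through columns on which **all**
copies agree and then trims until the two outermost columns are both
unanimous. The two-column rule matters: a single spacer column on which
all copies coincidentally agree (probability 1/64 with four copies of
uniform background) can otherwise freeze the boundary mid-spacer. The
generator meets the detector halfway: planted spacers are adjusted so
that the columns immediately flanking each repeat are never unanimous,
which is exactly the condition under which planted boundaries are
information-theoretically recoverable. Substitution noise of up to two
per repeat copy shifts boundaries by a column or two but never the array
count, which is what the robustness property asserts.

## Dice distance, neighbor joining, lineages

The phylogenomic distance between genomes A and B is
`d(A,B) = 1 − 2·S(A,B) / (S(A,A) + S(B,B))` where `S(X,Y)` sums the
fractional amino-acid identity of best-reciprocal protein pairs whose
best local alignment reaches E ≤ 10⁻³. This identity-weighted
shared-gene count makes `S(A,A)` equal the proteome size, giving clean
closed forms (identical proteomes d = 0, disjoint d = 1, half-shared
equal-size proteomes d = 0.5) that the tests pin down. The exact
weighting used by the lineage framework this mirrors is defined in prior
work (a bitscore-weighted variant); the identity weighting is this
package's default because it is exactly testable, and the distance is
documented as a semimetric — the triangle inequality is not guaranteed
and not asserted.

Trees are standard Saitou-Nei neighbor joining (via ape) midpoint-rooted
(via phangorn); negative branch-length estimates are clamped to zero with
the deficit moved to the adjacent edge. Node depth is summed branch
length from the root — real-valued cutoffs imply path length, not node
count. For each cutoff the lineage roots are the shallowest nodes at or
beyond the cutoff; leaves whose whole root path stays below it become
singletons. Because depth is monotone along root-to-leaf paths,
assignments at a deeper cutoff always nest inside shallower ones
(property-tested on random trees). No numeric cutoffs ship as
scientifically meaningful defaults — the original cutoffs belong to the
cited lineage framework — so `assign_lineages()` requires the user's
cutoff list.

## Read mapping, presence, partitions

A read is judged by its single best-scoring hit; the 90% identity rule is
then applied to that hit, so a long low-identity alignment is not rescued
by a trimmed high-identity fragment of itself, and reads with tied best
hits on different contigs are discarded as ambiguous. Covered bases are
the union of mapped intervals (IRanges), presence requires ≥ 75% of the
contig length covered, and abundance is
`reads / (contig kb) / (library millions)` with absent contigs set to 0.

Membership partitions pool replicates by union — a feature is "in" a site
(or season) if detected in any replicate there — while read fractions
stay per-sample; this mirrors plots that draw per-sample bars but define
sharing at the site level. Site partitions use the seven-way power set of
three sites; season partitions use the four reported categories (all
seasons; spring/winter/fall exactly; a single season; any other two- or
three-season set). Detection is count > 0 for amplicon features; for
viral contigs the caller supplies abundances that already respect the
presence rule, which is how the coverage rule (applied only to viral
contigs in the source workflow) enters the partition. Per-sample category
fractions are computed over reads belonging to detected features, and sum
to 1 by construction.

Bray-Curtis dissimilarity and the Mantel test are delegated to vegan —
the field-standard implementations, and the ones the original workflow
itself used — behind thin wrappers that enforce label agreement, seed the
permutation null, and return tidy objects. The Mantel p-value is the
standard `(1 + #{permuted r ≥ observed}) / (1 + permutations)`, whose
null uniformity the acceptance suite verifies at 999 permutations across
200 seeds. Relative abundance here is plain column normalization; the
original workflow's variance-stabilizing normalization of amplicon counts
is a named external package and is out of scope, a documented divergence.

## The synthetic generator

`sim_design()` fixes the study layout: three sites (head, mixed, river) ×
four seasons × three replicates. The generator plants, with full truth
records: CRISPR arrays (default one per host, four copies of a 28 bp
repeat separated by unique 32 bp spacers), tRNA genes (literal 72 bp
marked sequences — the pipeline consumes tRNA annotations, it does not
detect tRNAs), protospacers with an exact substitution count, shared
tRNAs, homologous segments (default 400 bp at 90% identity), uniformly
placed substitution-only reads calibrated so the expected covered
fraction `1 − exp(−n·L_read/L_contig)` hits the target, and log-normal
(μ = 0, σ = 1) community counts rescaled to fixed library sizes within a
designed site/season membership.

Background sequence is i.i.d. uniform ACGT, which maximizes the contrast
of planted signal and keeps spurious-hit rates predictable; mutations are
substitutions only, keeping identity and mismatch arithmetic exact for
filter-boundary tests. Host genomes default to 20 kb and viral genomes to
5 kb — large enough that every planted element sits in a realistic sea of
background for the seeded search and CRISPR detector, small enough that
the 50-virus × 10-host recovery panel runs in about a minute. What the
generator does **not** emulate: real genome composition (GC skew, codon
structure, repeat families), sequencing error profiles (quality scores,
indels), covariance-model-realistic tRNAs, or abundance correlation
structure between sites. Passing recovery tests therefore demonstrate
that the implementation honors its stated rules and recovers planted
signal, not that the cutoffs are optimal for real metagenomes.

## Numerical choices and degenerate inputs

- Tie-breaking of equal-scoring hits is fixed: higher score, lower query
  start, lower subject start, then lexicographic subject id.
- Empty queries or subjects yield empty hit tables, not errors; an empty
  host set yields a warning and no evidence.
- All-zero samples are an error naming the sample (Bray-Curtis), as is a
  genome with no proteins (Dice) and a label mismatch (Mantel).
- All simulator outputs are pure functions of `(design, seed)`; per-genome
  streams are derived from the master seed so individual genomes can be
  regenerated independently.
- Problem sizes in the shipped tests: 200 random search instances for the
  seeded-vs-exhaustive equivalence, a 16-array recovery panel and 20
  random 50 kb genomes for the CRISPR detector, a 50-virus/10-host
  prediction panel, 30 random 4-8 leaf trees for neighbor joining, and
  200 null replicates × 999 permutations for Mantel calibration. These
  sizes make the full suite run in a few minutes while keeping every
  statistical check comfortably powered.

## Known limitations

- The seeded search guarantee is formal only for queries ≤ 150 residues;
  for whole-contig homology searches it is a well-behaved heuristic.
- The Karlin-Altschul constants are not fitted to the scoring matrix;
  reported E-values are internally consistent but not comparable to
  BLAST output digit-for-digit.
- Repeat boundary recovery is exact only when boundary columns are
  distinguishable from spacer sequence — guaranteed for generated data,
  approximate for real arrays.
- Dereplication is greedy longest-first; cluster membership near the 95%
  identity boundary can depend on representative choice among equal-length
  ties (cluster counts are order-invariant, representatives need not be).
- Lineage labels are stable within a tree but arbitrary across trees.
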