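---
title: "Methods: mining CGTases and CM-CD gene clusters with cdmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining CGTases and CM-CD gene clusters with cdmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmine)
```

# Scope and model

Cyclomaltodextrin glucanotransferases (CGTases, EC 2.4.1.19) convert starch
to cyclodextrins by intramolecular transglycosylation. They belong to
glycoside hydrolase family 13 (clan GH-H), whose members share a TIM-barrel
catalytic domain with conserved sequence regions (CSR) I--VII. CSR II, III
and IV carry the acidic catalytic triad (nucleophile Asp, acid/base Glu,
transition-state Asp), with an invariant Arg two residues before the
nucleophile. Two features distinguish CGTases from alpha-amylases at the
sequence level: an aromatic Tyr/Phe at the center of CSR V (replaced by a
non-aromatic residue in amylases) and a hydrophobic pair (H1 in the
GSISNWN-like motif upstream of CSR V, H2 inside CSR III) required for the
cyclization reaction. Canonical CGTases are five-domain proteins
(ABCDE~CBM20~, roughly 700 residues); Gram-negative enzymes lack the D
domain (ABCE~CBM20~), archaeal enzymes replace CBM20 with an E~arch~
domain, and a recently recognized thermophilic group consists of the bare
three-domain ABC core (about 520 residues) with a lipoprotein signal
peptide. Genomes that encode such enzymes can carry a carbohydrate
metabolism via cyclodextrins (CM-CD) gene cluster: the CGTase, an mdxEFG
sugar ABC-importer cassette immediately downstream of it, cytoplasmic
degradation enzymes (cyclodextrinase, glucoamylase, glucan phosphorylase),
EMP glycolysis genes, and a large set of co-encoded accessory genes, with a
promiscuous MsmX ATPase encoded away from the cluster.

`cdmine` implements this mining workflow as testable desk-scale stages:
signal-peptide detection, CSR coordinate transfer and enzyme
classification, architecture calling, percent-identity novelty filtering,
distance phylogenetics, and cluster/promoter detection, plus a synthetic
generator that plants all of the above with known truth.

# Coordinate conventions

Protein positions are 1-based on the precursor sequence as provided
(position 1 is the initiator Met), matching the field's convention of
citing triad residues in precursor numbering. Genome features are 1-based
inclusive, GFF3 dialect. Ambiguity code `X` is accepted by the scanners
(it scores zero in profiles) but rejected by the mass/pI calculator,
because an ambiguous residue has no mass. The pKa set behind the
isoelectric point is a single pinned EMBOSS-style table; pI values are
table-dependent, so the table is part of the package contract rather than
an option.

# The SPII (lipoprotein) signal-peptide detector

The detector is a transparent rule model rather than a trained classifier:
reproducibility without weights was the design goal. A call requires

* a candidate Cys at position 15--35 (the lipobox cysteine that becomes
  lipid-anchored; cleavage is immediately before it, so
  `signal_len = cys_pos - 1`);
* n-region (residues 2--6) net charge of at least +1, counting K/R as +1
  and D/E as -1;
* h-region (residue 7 up to three residues before the Cys) mean
  Kyte--Doolittle hydropathy of at least 1.0;
* lipobox classes -3 in {L,V,I,F,A}, -2 in {A,S,T,V,I,G,F}, -1 in {G,A,S}.

The -3 class deliberately includes Phe: the canonical [LVI][ASTVIG][GAS]C
box would reject naturally occurring boxes of the form ...F-S-G-C that the
three-domain CGTases use, while the widened class still rejects random
sequence in practice (the generator additionally guarantees its negative
controls are clean). The lowest qualifying Cys wins, which makes the
detector deterministic and mirrors cleavage at the first lipobox.
Whether relaxation of the hydropathy threshold can only add calls is kept
as a tested invariant.

# CSR transfer and enzyme classification

Rather than searching each short CSR motif independently (which invites
off-domain hits), a query is first anchored by one global alignment
(BLOSUM62, affine gaps 11/1) to the best of four packaged reference seeds,
and all CSR spans and diagnostic slots are transferred through the
alignment columns. The seeds are synthetic consensus proteins built in
code: a shared catalytic-core motif layout embedded in seed-specific
background, one seed per architecture. The three-domain seed realizes the
canonical precursor coordinates of the thermophilic ABC enzymes --- signal
residues 1--21 with Cys22, GSISNWN at 199--205 (H1 Trp204), CSR V center
Phe216, triad Asp250/Glu279/Asp351 with Arg248 at -2, H2 Met281, C domain
434--524 --- so coordinate arithmetic is exact without vendoring any real
accession. Packaging synthetic seeds keeps the repository self-contained
and the tests download-free; the cost is that anchoring real proteins
would require adding real seeds through the same `reference_seed`
structure, which is the intended extension point.

The anchor is accepted when the alignment score divided by the smaller
self-alignment score reaches 0.15. Composition-preserving shuffles of the
seeds score at most about -0.03 under this normalization, while
substitution-only mutants remain above 0.2 down to roughly 38% identity;
0.15 therefore separates the twilight zone from noise with margin on both
sides. Per-CSR profile scores (add-one smoothed counts over the seed
annotations against a uniform background) are re-evaluated in a +/-5
residue slack window, keeping the mapped position unless a strictly better
start exists; slots that land on alignment gaps are reported absent.

Classification is a decision table over the report: complete D/E/D triad
with aromatic CSR V center and H1 in {F,W,Y}, H2 in {F,Y,M} is
`CGTASE_LIKE`; complete triad with non-aromatic center is
`ALPHA_AMYLASE_LIKE`; an incomplete triad with at least four CSR hits is
`GH13_OTHER`; anything else `NOT_GH13`. A single point mutation at the
CSR V center flips the first two labels in both directions, which is kept
as a tested invariant. Maltogenic starch-acting enzymes are not given a
separate label: no residue rule distinguishes them, so they are left to
the phylogenetic stage.

# Architecture calling

The catalytic core end is the mapped position of the anchored seed's
C-domain end. Tails shorter than 40 residues are `ABC` (the smallest real
appended domain, CBM20 at about 90--100 residues, is far larger; the
three-domain enzymes have tail length 0). CBM20 and E~arch~ profile hits
over the tail decide the rest, with the D domain detected by spacer
length: no D-specific motif is published, so a CBM20 hit at least 60
residues from the core implies the ~90-residue connecting D domain
(`ABCDE_CBM20`), closer hits mean the D-less `ABCE_CBM20`. The tail-hit
acceptance threshold of 0.2 log-odds units per column lies between the
random-sequence expectation (slightly negative per column) and the
per-column score of genuine segments diverged to about 40% identity. When
both tail profiles fire, the higher score wins; an exact tie is `OTHER`
with a warning.

# Pairwise identity and the novelty filter

Global Needleman--Wunsch alignment with BLOSUM62 and affine penalties
(open 11, extend 1) backs all identity computations; identity is counted
over aligned columns and coverage over query residues placed, so a global
alignment reports 100% query coverage by construction, matching the
"identity at full query coverage" reporting convention. The novelty filter
discards a query when its best identity against the reference set strictly
exceeds 45%; equality keeps the query. The original screen used an
E-value cutoff against a live database; no database statistics exist at
desk scale, so the in-repo substitute is the normalized-score anchor
described above, and the 45% rule is applied exactly as stated. Agreement
between this NW identity and heuristic-search identities from web tools is
expected only to within a few points.

# Distance phylogenetics

Tree building uses Poisson-corrected distances, `d = -ln(1 - p)` with `p`
the mismatch proportion over shared non-gap columns (pairs at `p >= 0.95`
are clamped with a warning), and neighbor-joining agglomeration; negative
branch lengths are clamped to zero. This replaces maximum-likelihood
WAG+G inference deliberately: the quantities this package asserts ---
monophyly of planted families and bootstrap support of deep splits --- are
recoverable by NJ at a fraction of the cost and with no model-fitting
machinery; an ML tree can be substituted wherever a `phylo` object is
consumed. Bootstrap support resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and counts the original unrooted
bipartitions; supports travel as internal-node labels through Newick.
Monophyly is an exact bipartition test (trivial splits are monophyletic by
definition). Trees are unrooted; outgroup rooting is display-level.
No column trimming is applied before distance computation by default,
since no trimming rule is part of the procedure being modelled.

# Cluster and promoter detection

Roles are assigned by best global-alignment score against one packaged
exemplar per role, accepted at identity >= 30% and coverage >= 70%; MdxE
candidates are additionally checked for a lipobox Cys, reported as a flag.
The CORE role chain {CGTase, MdxE, MdxF, MdxG, CDase, GP} is the minimal
synthesis-transport-degradation logic present in all known clusters of
this type; glucoamylase and the EMP genes (Pgi, PfkA, PykF) are
EXTENDED-tier evidence because at least one real cluster lacks Pgi. A
40-gene sliding window (the published cluster spans 30 genes; 40 allows
insertions without merging unrelated loci) emits windows containing the
CORE chain; overlapping windows are merged and trimmed to the first and
last role-bearing gene, so flanking role-less genes never pad a call.
Cassette adjacency requires the three mdx genes consecutive on one strand
with at most one intervening gene, and `cgt_upstream` records the cassette
starting within one gene downstream of a CGTase gene. Accessory genes are
annotated but never gate a call. MsmX hits are reported genome-wide with a
`distal` flag. No formal minimal gene set for these clusters is published;
the CORE/EXTENDED tiers are this package's operationalization of the
pattern common to the known clusters.

Promoter boxes are scored with 6-column PWMs trained on the two deduced
box pairs (TGCACT/TAATAT and TTTCGA/CATATT) plus the sigma-A consensus
(TTGACA/TATAAT), add-one smoothed. A hit is a pair of boxes each scoring
at least 2.3 log-odds units with a spacer of 15--19 nt. The threshold
admits every training box (the weakest scores 2.30) while leaving random
200-nt windows empty in over 90% of draws; hits are returned best-first,
so chance sub-threshold pairings never displace a planted promoter.

# The synthetic generator

`build_synthetic_genome()` is the package's study-condition fixture, not a
tuning dial. Its defaults plant:

* a 30-gene cld-style cluster (CGTase, mdxEFG cassette immediately
  downstream on one strand, CDase/GA/GP, Pgi/PfkA/PykF, twenty accessory
  genes) on contig A with TGCACT-17bp-TAATAT planted upstream of the
  CGTase gene;
* a decoy cluster missing the MdxF core role, and a distal msmX gene, on
  contig B;
* a three-domain identity ladder at 98/80/45/38% to the packaged ABC
  seed (the reported identity levels among the mined family), and
  tail-bearing architecture variants at 98/80/60%;
* the four classification decoys (CSR V flip, triad knockout, truncation
  inside domain B, full shuffle).

Cluster gene identities follow the reported values where one is printed
(MdxE/F/G 40%, CDase 88%, MsmX 64%, CldA-like 98%) and 60% --- a
mid-range homology a curator would call safely detectable --- where none
is. Mutation is substitution-only so that position-level truths stay
exact; planted CGTases keep their signal peptide and diagnostic slots
protected through mutation, and every protein meant to carry no signal
peptide is post-processed so that no chance lipobox survives (absence is
then true by construction, which is what a ground-truth table requires).
Reverse translation uses one fixed codon per residue and seeded random
intergenic sequence, making fixtures byte-identical per seed. What the
generator does not emulate: indels (an indel-enabled path would invalidate
exact coordinate truths and is deliberately excluded from those
assertions), codon-usage or GC realism, overlapping genes, and regulatory
structure beyond the planted boxes. Passing round-trips on these fixtures
therefore demonstrates correctness of the pipeline's logic under
controlled divergence, not performance on real proteomes with indels,
fragmented assemblies, or compositional bias.

# Problem sizes and numerical choices

The default fixture holds 81 genes across two contigs (about 40 kb), which
exercises every stage in roughly a minute of alignment work; phylogenetic
property checks use families of 4--8 taxa with 100--300 columns and 100
bootstrap replicates, and alignment-score checks enumerate all affine-gap
alignments for sequences up to length 8. Ties are broken deterministically
throughout (first-qualifying Cys, lexicographic NJ joins as provided by
the agglomerator, mapped-position preference in CSR re-scoring). Degenerate
inputs have defined behavior: empty sequences error, absent signal
peptides and failed anchors are values rather than errors, saturated
distances clamp with a warning, and an empty proteome yields an empty
report.

# Known limitations

Anchoring real (non-synthetic) proteins requires adding real reference
seeds; the packaged synthetic seeds define coordinates but not real
sequence diversity. The CSR profiles are built from four annotations and
are diagnostic, not discriminative across all of GH13. NJ on Poisson
distances underestimates divergent branch lengths relative to WAG+G, so
branch lengths should be read comparatively. The promoter model is a
two-box PWM with a hard spacer window and does not model UP elements or
extended -10 boxes.
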