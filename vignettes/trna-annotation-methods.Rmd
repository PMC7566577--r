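---
title: "Methods: cloverleaf numbering, unusual-pair detection and base-pair geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cloverleaf numbering, unusual-pair detection and base-pair geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnaclover)
```

This vignette documents how `trnaclover` works: the structural model behind
the numbering, the feature definitions, the geometry module, what the
synthetic generator does and does not emulate, and the numerical and design
choices a maintainer would want spelled out.

## The cloverleaf model

A cytosolic tRNA gene is modelled as the classic cloverleaf: an acceptor
(amino-acid) stem of 6–7 bp closing the molecule, a 2-nt connector (positions
8–9), a dihydrouridine (D) arm of 3–4 bp with a 7–11 nt loop, a single
residue 26, an anticodon arm of 4–5 bp with exactly a 7-nt loop, a variable
region of 3–23 nt, a thymine (T) arm of 4–5 bp with exactly a 7-nt loop, a
discriminator residue 73 and, when present, the 3′ CCA. Gene predictions are
normally CCA-less, so labels 74–76 are simply absent and the discriminator is
the last residue.

Structures come from one of two routes:

* **`parse_dotbracket()`** consumes a secondary structure already computed
  (e.g. by tRNAscan-SE) in plain parenthesis dialect, validates that the
  bracket tree is a cloverleaf (one outer helix, three inner hairpin helices
  in D/AC/T order, with an optional fourth helix accepted as a long variable
  arm and flagged), and checks the connector, loop and stem sizes. A single
  1×1 internal mismatch inside a stem is merged so that a stem with one
  mismatched position is still one stem.
* **`fold_cloverleaf()`** performs a template-constrained exhaustive search:
  every admissible combination of acceptor span (7 then 6), D span (4 then
  3), AC span (5 then 4), T span (5 then 4), D-loop length (7–11) and 3′
  tail (discriminator only, or +CCA when the sequence ends in CCA) whose
  implied variable-region length lands in 3–23 is scored. The score is +2
  per Watson–Crick pair, +1 per GoU/UoG wobble, and +3 for each conserved
  anchor found at its label-predicted index: U8, A14, G18, G19, U33, G53,
  U54, U55, C56 (T54 arrives as U after normalization). A stem position
  that fails to pair contributes nothing but is tolerated as long as the
  stem keeps its minimum number of real pairs — acceptor 6, D 3, AC 4, T 4;
  below these the layout is invalid, and a sequence with no valid layout is
  a fold failure that carries the best partial score. There is no
  thermodynamic model: the aim is reliable annotation of sequences that are
  already known to be tRNA genes, not structure prediction of arbitrary RNA.

Determinism matters for a pipeline whose outputs are compared across runs,
so ties are broken by a fixed cascade: highest score, most acceptor pairs,
longest acceptor span, leftmost D stem, then the lexicographically smallest
layout tuple. The full enumeration is small (at most a few hundred layouts
per sequence), so folding a gene costs about 15 ms.

## Canonical numbering

`assign_numbering()` maps each residue to the standard yeast tRNA-Phe
position labels. The fixed parts are 1–7 / 66–72 (acceptor), 8–9, 10–13 /
22–25 (D stem; a 3-bp D stem uses 10–12 / 23–25, skipping 13 and 22), 26,
27–31 / 39–43 (AC stem), 32–38 (AC loop, anticodon at 34–36), 49–53 / 61–65
(T stem), 54–60 (T loop), 73 (+74–76 for CCA). For the rarer 4-bp AC and T
stems the outermost labels (27/43, 49/65) are dropped; a 6-bp acceptor is
numbered 1–6 / 67–72.

Two regions have variable length and need a policy:

* **D loop.** The base loop of 7 is labelled 14, 15, 16, 18, 19, 20, 21;
  each extra residue adds 17, then 17a, then 20a, then 20b. G18/G19 are
  located first by searching the loop for a GG whose flanks admit the
  canonical counts (3–5 residues before, 2–4 after); the surplus labels are
  then distributed on the side the anchor dictates. Without a usable GG the
  split falls back to the fixed counts. Label 17 marks the "extra U17"
  feature, so its presence/absence must be well defined; this policy makes
  it so.
* **Variable region.** Position 48 is a tertiary-pair partner and must
  always exist, so length 3 uses {44, 45, 48}, length 4 adds 47, length 5
  is the full 44–48, and longer regions insert e1…e19 between 45 and 46.
  The deterministic drop order (46 first, then 47) and the e-label placement
  are a declared convention of this package — alignment databases do not
  publish a gap-column rule for long arms, so some convention is required;
  this one keeps 47 (a synthetase contact in several systems) as long as
  possible.

## Diagnostic pairs and feature flags

`extract_profile()` reads fifteen named pairs (3:70, the five AC-stem pairs
27:43…31:39, the tertiary pairs 15:48, 54:58, 16:59, 13:22, 26:44, 18:55,
19:56, 8:14 and the T-stem closer 53:61) and ten single positions (9, 17,
20, 21, 32, 33, 37, 38, 60, 73). Pairs are classified over the 16 ordered
dinucleotides with the alignment symbols `-`, `=`, `o`, `/` (and `?` when a
label is absent). Orientation is preserved: G30oU40 and U30oG40 are
different classes, and only the former raises `F_30o40`, because the two
orientations displace different partners into the major groove and are not
functionally interchangeable at a ribosome contact. Both render as `o`.

The flags are deliberately narrow transcriptions of the features of
interest: `F_3o70` (wobble with G at 3), `F_30o40` (wobble with G at 30),
`F_15_48_RR` (purine at 15 **and** A at 48 — a pyrimidine 15 with purine 48,
as in eukaryotic tRNA-Cys C15=G48, is recorded but flagged false),
`F_54_58_AA` (A at both 54 and 58), `F_extraU17` (label 17 present and U),
`F_R60` (purine at 60). Modified bases are handled upstream:
`normalize_modomics()` collapses MODOMICS codes to parent bases (D→U, I→A,
Ψ/P→U, T→U, extensible as data), so a gene-level A34 is reported as the
AGC-like (inosine-read) anticodon class and G30oΨ40 raises `F_30o40`
because Ψ's parent is U.

## Aggregation

`filter_by_score()` keeps records at or above the analysis threshold
(default 60.0; the comparison is inclusive, a documented choice) and flags
dropped records under 55.0 as possible pseudogenes. `crosstab()` groups by
any subset of taxon / isotype / anticodon class; by default a record with
*n* gene copies contributes *n* to every count, since gene-copy numbers are
part of the source data — pass `weight_by_gene_copies = FALSE` to count
records. `cooccurrence()` builds the 2×2 table of two flags per record
(unweighted: co-occurrence is a property of a gene, not of its copy number)
and reports the phi coefficient, left undefined when a margin is zero.
Whether strict co-occurrence should be assessed per gene or per isodecoder
consensus is a genuine choice; this package computes it per gene, and the
per-isodecoder view is derivable by collapsing profiles on the anticodon
before calling `cooccurrence()`.

## Base-pair geometry

The four standard bases are embedded as literal planar coordinates in the
standard reference-frame convention (Olson et al. 2001, J Mol Biol
313:229–237), each including its C1′. Internal consistency is asserted by
tests: all covalent bonds within 2.0 Å, and the frame's defining property
that reflecting a complement across the x-axis closes Watson–Crick H-bonds
at 2.87–3.02 Å.

`build_ideal_pair()` positions a second base against the first by a
deterministic multi-start rigid-body optimization in the plane: template
H-bond distances are pulled to 2.9 Å, the inferred donor/acceptor hydrogen
directions (outward bisectors of the bonded neighbours) are aligned with
each bond, and non-bonded overlap below 2.8 Å is penalized. Twelve evenly
spaced rotational starts per mirror image are refined with BFGS; converged
placements must have every H-bond within 0.05 Å of target, and among those
with the requested cis/trans orientation the lowest-residual one wins. The
multi-start grid exists because a two-bond template leaves a one-parameter
family of distance-satisfying placements; the angular terms select the
chemically correct member, and the fixed start grid makes the outcome
reproducible to machine precision.

Templates cover the canonical cis WC/WC pairs and the GoU wobble, the trans
WC/WC (reverse WC) pairs G/C, A/U and A/A seen at 15/48, and the trans
WC/Hoogsteen pairs of the T loop. One template detail is worth recording:
the *trans* WC/Hoogsteen U·A pair (the reverse Hoogsteen of T54/A58) bonds
through N3(U)–N7(A) and **O2**(U)–N6(A); the O4 variant of the same atoms
closes the *cis* Hoogsteen pair instead (C1′–C1′ 8.53 Å), which the
orientation filter rejects. With O2 the built pair measures 9.77 Å, and the
A·A variant (N6–N7, N1–N6) measures 12.54 Å — matching the published values
for these families (9.8 and 12.5 Å).

`classify_lw()` works on any coordinates (built or from PDB via
`read_pdb_residues()`/bio3d): H-bonds are heavy-atom donor–acceptor contacts
at 2.4–3.5 Å whose inferred donor angle is at least 110°; each H-bonded atom
votes for its edge, with border atoms (N6/O6 between WC and Hoogsteen,
C2-amino/O2 between WC and Sugar) counting for both adjoining edges and the
tie-break WC > Hoogsteen > Sugar — this keeps bifurcated pairs such as
G15/G48 classifiable. Orientation is the sign of the dot product of the two
glycosidic-bond vectors projected perpendicular to the pairing axis (|angle|
< 90° means cis): the standard operational definition, stated so it is
testable. A pair with no H-bond in range is reported unpaired, not an error.

## The synthetic generator

`generate_gene_set()` emulates the input ecology of tRNA gene databases:
per-isotype scaffolds carrying the conserved anchors, stems sampled as
complementary random duplexes, diagnostic positions overwritten according to
sampled feature flags, tRNAscan-SE-like scores drawn from a normal
distribution (default mean 72, sd 6, on the scale where 60 is the analysis
threshold and 55 the pseudogene caution), gene-copy counts (60/20/10/10%
for 1–4 copies), and introns inserted after position 37 — the canonical
eukaryotic tRNA intron site — with length 8–20. Default D-loop lengths are
7–10 and variable regions 4–5, the common range for type-I tRNAs. The
enforced linkage option drives `F_15_48_RR` and `F_54_58_AA` from a single
Bernoulli draw per gene, reproducing their strict co-occurrence; with it
off they are independent. One master seed derives per-gene substreams by
counter, so outputs are byte-identical across runs and gene *i* is stable
under changes of `n_genes`.

Two generator choices favour testability over realism, deliberately:

* scaffolds containing any reverse-complement 6-mer match not explained by
  the true stems are rejected and resampled, so no alternative duplex can
  tie the true layout and fold recovery is exact;
* non-anchor D-loop positions avoid G, so the GG used to place 18/19 is
  unambiguous.

Real data are messier: mismatched and shifted stems, modified-base
sequencing artefacts, truncated predictions, genuine alternative structures.
Passing the recovery tests therefore demonstrates that the annotation logic
is correct on well-formed cloverleafs, not that folding is robust to
arbitrary genomic noise — for real data the dot-bracket route with
tRNAscan-SE structures is the recommended path, and per-record failures are
always reported, never dropped.

The presets encode the branch patterns as configuration: `mammal` (AGC-like:
both purine–purine pairs, WC 30–40; YGC-like: G30oU40 only), `insect`
(AGC-like: all three unusual pairs) and `fungi` (none). All alanine classes
keep `F_3o70` at probability 1, and the context features (extra U17, R60)
accompany the purine–purine pairs wherever those are switched on.

## Problem sizes and numerical notes

The shipped test suite exercises 1,000-gene recovery runs (fold + numbering
and flag recovery), 120-gene preset pattern checks, 300–1,000-gene linkage
checks, and the full template round-trip of the geometry module; the whole
suite runs in under two minutes on one core. The acceptance script
recomputes the two T-loop C1′–C1′ distances from scratch.

Numerical edge cases handled explicitly: sequences outside 60–100 nt are
rejected before folding; an anticodon loop that is not exactly 7 nt makes
numbering (and hence the profile) undefined rather than silently shifted;
intron bounds are validated against the raw sequence and splicing is
idempotent; empty inputs produce empty outputs (not errors) everywhere in
the aggregation layer; and the phi coefficient is reported as absent rather
than NaN when a margin is zero.

## Known limitations

* No energy model: a sequence whose true structure deviates from the
  cloverleaf template (armless mitochondrial tRNAs, permuted tRNAs,
  pseudoknots) will either fail to fold or be forced into the template.
* Long variable arms are parsed and flagged from dot-brackets, but arms
  longer than the e-label range (19 insertions) cannot be numbered.
* The geometry module models isolated base pairs in a plane; it does not
  model stacking, backbone strain or the helical context of a pair.
* Taxon assignment relies on a user-supplied species-to-taxon table; there
  is no taxonomy service integration by design.
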