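---
title: "Methods: comparative analysis of organellar group II introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of organellar group II introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`intronscape` implements a desk-scale comparative pipeline for organellar
group II introns: family definition, rule-based secondary-structure and
intron-encoded-protein (IEP) annotation, occurrence-frequency analysis, and
phylogenetic congruence between intron RNA scaffolds and their IEPs. Because
the interesting claims of such an analysis (label recovery, congruence,
dual origin of homing-endonuclease lineages) can only be verified against
known truth, the package ships a seeded synthetic cohort generator whose
output every downstream stage is tested on. This vignette records the models,
parameter choices and their rationale, the numerical conventions, and what
the synthetic experiments do and do not demonstrate about real data.

## The data model

An intron occurrence is a row of a cohort table: RNA sequence, dot-bracket
secondary structure, host gene, insertion site (1-based reference-gene
coordinate `s`; the intron sits between positions `s` and `s+1`), genome id,
and upstream/downstream exon flanks taken from annotated exons. Introns are
named `gene-site` (`cox1-686`), genes with internal hyphens are parsed from
the last hyphen, and an intron *family* is the set of introns at an identical
insertion site that are also sequence-homologous. Genomes are DNA; introns
are handled internally in the RNA alphabet (`T` is converted on load), and
all motif patterns are defined over RNA.

## The synthetic cohort generator

### Architecture of a template

Each family template is an ordered list of named *parts* (sequence +
dot-bracket + substitution-rate class). The canonical layout is: optional 5'
linker, the GUGCGA boundary motif, DI (a large multi-branch domain carrying
the EBS loops and accessory stem-loops Ia/IC2/ID2/ID2a/IE), DII, the
DII–DIII junction tetramer, DIII, optionally DIIIa (giving the seven-domain
architecture), DIV (an 8-bp stem whose interior loop hosts the ORF), the
DIV–DV junction dimer, a fixed canonical 34-nt DV shared by all templates,
DVI with a bulged branch-point adenosine 8 nt from the intron 3' end, and an
AY terminal dinucleotide.

Diagnostic content is planted per family: the tetramer is drawn from
BVGA\\RRGA for IIA1 and RRGA\\BVGA for IIA2 (so subgroup truth is never
ambiguous unless the user plants an ambiguous motif); IIB1/IIB2 dimers are
drawn from YW and RG; IIB templates draw a tetramer matching neither IIA
pattern (rejection sampling). EBS1/EBS2 are 6-nt hairpin loops inside DI set
to the reverse complement of the exon IBS1 (positions −6…−1) and IBS2
(−12…−7) windows; EBS3 is the first base of the 3'-most single-stranded
stretch of DI, complementary to the first downstream exon base. `lose_EBS2`
replaces the EBS2 loop with bases that pair with IBS2 neither by
Watson–Crick nor by G·U wobble, so the loss is unambiguous at emission time.

Two deliberate geometric choices keep rule-based detection well-posed:
every DI hairpin loop other than the EBS loops is 4 nt (shorter than an EBS
window, so it can never enter the 6-nt scans), and the only unpaired DVI
position within 6–10 nt of the 3' end is the branch-point bulge itself. A
residual false-recovery path remains for `lose_EBS2` introns: the EBS1 loop
is an unavoidable 6-nt single-stranded window and accidentally complements
IBS2 at the permissive 4/6 threshold in roughly 3% of random interfaces
(more with wobble scoring enabled); this is reported as found and is the
price of the permissive threshold, not a generator defect.

ORFs are planted in the DIV loop: RT/M proteins are 450 codons with the
catalytic `[YF]xDD` motif (as YADD) and two conserved RT block pentapeptides
(`GLSQG`, `PRKHS`); LHE proteins are 200 codons with two exact LAGLIDADG
copies 105 aa apart. The RT block pentapeptides are the conserved blocks *of
the synthetic protein model*; on real proteins a profile-based annotation
would replace this motif table (shipped, versioned, in
`extdata/iep_motifs.tsv`). `orf_premature_stop` plants an internal stop
(codon 200 for RT/M, codon 70 for LHE, inside the motif-anchored core);
`orf_absent` replaces the ORF with a short loop.

### Evolution

Sequences evolve by a single-parameter (Jukes–Cantor-like) point
substitution process; structures (dot-brackets) are carried along unchanged,
which is the generator's ground-truth convention rather than a thermodynamic
claim. Two levels of divergence are simulated:

* **Family level.** All templates derive from one ancestral scaffold evolved
  along a fixed-backbone family tree — (IIB-like, ((IIA1, IIA2), (IIB1,
  IIB2))) with IEP-type subclades inside each subgroup and seeded coalescent
  topologies within groups, ultrametric with depth 1. The default family
  divergence is 0.25 substitutions/site: far enough for family-level
  phylogenetics, close enough that the conserved core stays alignable.
  LHE lineages within a subgroup share a scaffold ancestor, reflecting
  invasion of a single ancestral lineage; an `invasion_donor` grafts the
  donor's evolved LHE ORF into the recipient's DIV while leaving the
  recipient's scaffold untouched, producing the dual-origin signal without
  perturbing RNA history.
* **Species level.** Present copies evolve along a seeded Yule species tree
  (`ape::rphylo`, birth rate 1), with rates expressed as expected
  substitutions/site across the tree depth (defaults 0.05 for scaffold and
  ORF). Presence of a family in a species is an independent Bernoulli draw —
  occurrence frequency is treated as a marginal summary, not a gain/loss
  process on the tree.

Constrained sites — terminal motifs, junction tetramer/dimer, DV, EBS loops
and the matching exon IBS windows, and IEP motif codons — evolve at 0.1× the
nominal rate (`protect_factor`), emulating the purifying selection that makes
these features diagnostic in the first place; the branch-point position is
protected one factor further. ORFs additionally evolve under selection
against nonsense changes: a substitution creating a new stop codon is
reverted (planted stops are kept). Without this the classification
invariants would be statements about drift, not about the annotation rules.

Yule trees routinely contain internal edges of near-zero length; these are
bipartitions that *no* finite alignment can resolve, so recovery experiments
(coevolution congruence, bootstrap calibration) condition the species tree
on a minimum internal edge of 5% of tree depth (`min_edge_frac`, rejection
sampling, seeded). Unconditioned trees remain the default everywhere else.

The translation table defaults to the standard code (table 1) and is
configurable, since the genetic code of organellar ORFs varies by lineage
and the source annotations do not pin one down.

### Default study conditions

The default cohort is 20 species × 12 mitochondrial families spanning the
observed lineage mix: IIA1 with and without DIIIa (+IE), IIA2, IIB1-RT/M,
IIB1-LHE with the 5' linker coupled to branch-point loss (and EBS2 loss),
IIB2-RT/M, IIB2-LHE with two independent invasions (one IIB1, one IIB2
donor→recipient pair), and a ubiquitous, IEP-less, heavily degenerated
IIB-like family. Presence probabilities span 0.10–1.00, covering the broad
(>40%) to narrow (<15%) occurrence classes. A 450-nt conserved DI core
extension (`extra_scaffold`, three 150-nt hairpins shared by all families)
provides the alignable columns for family-level phylogenetics; 2000 nt is
used in the coevolution experiments, which need that many retained columns.
The linker, when planted, is uniform on 2–10 nt ("short"); DV is a fixed
34-nt element shared across templates.

## Annotation rules and numerical conventions

* **Domain layout** — top-level helices of the dot-bracket, 5'→3'. Six →
  DI…DVI; seven with the extra element fourth → DIIIa. Five or eight
  helices are flagged `noncanonical` and labelled by anchoring DI/DII from
  the 5' end and DV/DVI from the 3' end (those are the positionally
  invariant elements); fewer than five or more than eight is an error.
* **Junctions** — the tetramer is the 4 unpaired nt immediately 3' of the
  DII closing pair; the dimer the 2 unpaired nt immediately 5' of DV. The
  subgroup decision order is: IIA tetramer (both-match → `ambiguous-IIA`,
  resolvable by a caller-supplied clade prior, mirroring resolution by
  external evidence); then the IIB dimer (YW/RG are disjoint at position 1);
  then the IIB-like rule — no IEP, length < 800 nt (calibrated to the
  ~615-nt IEP-less exemplar family), and ≥ 2 core features absent among
  {canonical 5' motif, branch point, EBS1, EBS2}; else unclassified. Domain
  Ia presence is recorded as supporting, never deciding, evidence for IIB2.
* **Terminal elements** — GUGCGA searched in the first 15 nt with ≤ 1
  mismatch (`variant`); the motif offset is the linker length; the 3' test
  is IUPAC AY on the last two bases.
* **Branch point** — an unpaired A within DVI at 6–10 nt from the 3' end
  (distance 1 = last base); among several candidates the one closest to the
  canonical −8 is reported.
* **EBS–IBS** — single-stranded stretches of DI are scanned for the best
  antiparallel complement of each IBS; EBS1 requires ≥ 5/6, EBS2 ≥ 4/6
  (thresholds are operational choices — presence/loss is qualitative in the
  source material), EBS3 is a 1-nt exact complement searched in the 3'-most
  single-stranded stretch. G·U wobble scoring is off by default. Ties go to
  the leftmost best window.
* **IEP** — ORFs are stop-to-stop spans of ≥ 100 codons (`min_codons`; no
  number is prescribed upstream, 100 excludes junk without excluding any
  real IEP class) in the three forward frames of DIV, each also reported
  from its first AUG; reverse frames are not searched (IEPs are
  sense-encoded in DIV in all described cases). Typing uses the full frame
  translation (stops as mismatches), so remnants interrupted by premature
  stops still count as evidence; such below-threshold evidence is surfaced
  as `remnant_candidates` without judging. LHE requires two LAGLIDADG
  copies (≤ 3 mismatches each) spaced 80–150 aa; RT/M requires `[YF]xDD`
  plus ≥ 1 RT block; both → higher score with a conflict flag. The expected
  core is the motif-anchored span ± 20 aa, with the 5' pad clipped at the
  last stop before the first anchor — the conserved core of a protein
  cannot extend upstream of its reading frame's boundary, and without the
  clip an intact ORF would be graded degenerated whenever a junk codon
  upstream of the initiator happens to be a stop. Intact = one span covers
  the core; degenerated = evidence without such a span; absent = neither.
* **Families** — the upstream flank is aligned locally to the reference
  host gene (match +2, mismatch −3, gap open −5, gap extend −2); the site
  is the reference coordinate of the last aligned flank base. Mapping
  identity is measured over the *full flank length* (< 60% → unmappable),
  so a short perfect local match on an unrelated reference does not count.
  Co-sited introns cluster by single linkage at ≥ 60% global identity
  relative to the shorter sequence (no threshold is prescribed upstream;
  60% over ≥ 50% of the shorter sequence is the package default and
  configurable); non-homologous co-sited clusters get `.2`, `.3` suffixes by
  decreasing size. Equal-length pairs take a gap-free fast path (the
  generator introduces no indels).
* **Member search** — seed-and-extend with 11-nt exact words, gapped local
  extension around diagonal clusters, and an ungapped Karlin–Altschul-style
  E-value (λ = 0.625, K = 0.41 for +2/−3); hits pass at E ≤ 1e−5 and query
  coverage ≥ 30%. Bit-for-bit parity with any BLAST build is explicitly not
  promised — the cutoff semantics are what is preserved.
* **Occurrence** — percent of genomes per compartment (mt and cp
  denominators separate), one-decimal rounding for display; classes broad
  (> 40%), narrow (< 15%), intermediate, computed on the unrounded value.
* **Consensus** — per alignment column the most frequent non-gap base;
  gap-majority columns dropped (a strict-majority reading of the rule); ties
  broken alphabetically (A < C < G < U) and recorded, mirroring the
  black-dot display convention.
* **Phylogenetics** — maximum-likelihood inference is out of scope by
  design; NJ on p/JC69 distances (pairwise deletion; JC69 undefined at
  p ≥ 0.75, flagged `Inf`) with classical column bootstrap preserves the
  topological claims (clade membership, congruence) the analysis rests on.
  NJ ties are broken by the lexicographically smallest cluster-label pair;
  negative branch lengths are clamped to zero with a note. Congruence is
  the Robinson–Foulds distance on non-trivial bipartitions; monophyly is
  assessed after rooting on an outgroup leaf. Support is mapped only onto
  bipartitions of the point-estimate tree. Within a family the RT/M tree is
  built from the ORF nucleotide alignment (1353 columns) rather than the
  450-aa protein — the congruence experiments are specified at ≥ 2000
  retained columns and the amino-acid alignment alone under-resolves short
  internal edges; both alignments are returned.
* **Hotspot masking** — `default_hotspot_regions()` derives the excluded
  regions (5' terminal sequence, accessory DI elements, EBS loops, DIIIa,
  DII/DIII loop regions, the DIV interior) from a template's layout; for
  family representatives the conserved-core concatenation is the equivalent
  construction and is gap-free by design. Exact coordinates are
  cohort-specific and must come from the layout annotation.
* **Statistics** — two-way ANOVA uses Type-II sums of squares (the real
  cohorts are unbalanced; on balanced data Type II equals the textbook
  decomposition, which is what the tests pin down), with Tukey–Kramer HSD on
  non-empty cell means (pairwise harmonic-mean cell sizes). A factor with
  one level reduces to one-way with a warning. Logo information content is
  2 − H bits with no small-sample correction by default, keeping the 0- and
  2-bit bounds exact; the e(n) correction is a flag.

## What the synthetic experiments show — and what they do not

Passing the recovery experiments shows that the annotation rules invert the
generator exactly at zero divergence and degrade gracefully at realistic
divergence; that the family rule (site + homology) reproduces a known
partition; that NJ is exact on additive matrices; and that coevolved
scaffold/ORF pairs yield congruent trees while grafted LHE ORFs produce
exactly the dual-origin pattern (combined LHE set non-monophyletic, each
donor–recipient clade monophyletic). They do not show that the rules are
complete for real organellar introns: the generator has no indels (so
alignment is trivial by construction and the center-star path is rarely
exercised), no thermodynamic structure (dot-brackets are truth, not
prediction), idealised motif placement, a single genetic code by default,
and protein motifs matched to the synthetic model rather than to profile
databases. Occurrence is Bernoulli rather than phylogenetic gain/loss, so
occurrence classes test arithmetic, not evolutionary process. Insertion-site
logos on synthetic cohorts have high background conservation because family
members share one exon context.

## Problem sizes

Test-suite and acceptance experiments use 12 families × 20 species (label
recovery), 8 species × ~4.5-kb introns × 20 seeds (coevolution), 6 species
× 12 families × 10 seeds (dual origin), 100 random 6–10-taxon trees (NJ
exactness), 1000 replicates (ANOVA null calibration, consensus oracle).
These sizes were chosen so every experiment has unambiguous expected
behaviour while the whole suite runs in about a minute.
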