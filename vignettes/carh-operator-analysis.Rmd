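---
title: "Methods: CarH/CarA operator discovery and binding analysis"
author: "carscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CarH/CarA operator discovery and binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carscan)
```

## Background

CarH is a coenzyme-B12 (5'-deoxyadenosylcobalamin, AdoCbl)-dependent
photoreceptor and transcriptional repressor of bacterial carotenoid
synthesis genes. In the dark the AdoCbl-bound protein binds an operator
that overlaps the promoter of the carotenogenic gene cluster; light
photolyses the cobalt--carbon bond, disassembles the oligomer and
releases the DNA. Its B12-independent paralogue CarA represses the same
promoter and is instead antagonised by the CarS antirepressor. Both
proteins share an N-terminal MerR-type winged-helix DNA-binding domain
(DBD) and a C-terminal cobalamin-binding domain (CBD), and both
recognise operators built from tandem 11-bp direct repeats with the
consensus 5'-nnnnTnnACAn-3'.

carscan implements, as reusable and tested functions, the computational
core of this analysis: motif-based CarH/CarA classification of protein
sequences, discovery of tandem-repeat operators in promoter windows, a
cooperative dimer-occupancy model of gel-shift bands and footprint
geometry, Hill fitting of EMSA titrations, SEC mass calibration, and
qRT-PCR normalisation. Seeded generators produce every input the
pipeline consumes, with recorded ground truth, so the whole chain is
testable without genome downloads or gel images.

## Promoter windows and coordinates

Operator searches are restricted to the region between positions -150
and +25 relative to the annotated translation start codon. Promoter
numbering in bacteriology has no position 0: -1 abuts +1, so the default
window is 175 nt, and `extract_promoter_window()` records the window
index of the +1 base (`offset_of_plus1`). Windows are always reported
5'→3' on the gene's coding strand; for minus-strand genes the sequence
is the reverse complement of the genomic slice. Windows that run off a
contig edge are clipped and flagged (`truncated = TRUE`) rather than
rejected, because draft genomes routinely truncate intergenic regions.
Coordinates follow the GFF3 convention (1-based, inclusive) throughout.

## Homologue classification

Three degenerate motifs carry the classification signal:

* `Wx9EH` — Trp, nine arbitrary residues, Glu-His. The Trp contacts the
  upper axial adenosyl group of AdoCbl; the motif is intact in CarH and
  has lost its Trp (and flanking residues) in CarA.
* `B12_binding` — D/E-x-H-x2-G/P-x41-S-x-T/V-x22--27-G-G, the classic
  cobalamin-binding motif of the Rossmann module, whose His supplies the
  lower axial ligand. The spacers are taken literally: x41 exact, x22--27
  bounded. Both are configurable; widening a bound can only add matches
  (a property the test suite checks), so the defaults are the most
  conservative reading.
* `RxWERRY` — the DNA-recognition-helix motif conserved in the DBDs of
  both CarH and CarA.

The decision rule in `classify_homolog()` is the co-occurrence
criterion: no B12 motif → `non_member`; B12 + Wx9EH → `CarH`; B12 +
RxWERRY without Wx9EH → `CarA`; anything else → `ambiguous`. We do not
attempt to locate the residual "EH" that CarA retains: two fixed
residues are far too common to anchor without a structural alignment, so
absence of the full Wx9EH is the discriminator. Sequences outside the
accepted homologue size range (286--330 aa) keep their label but are
flagged (`passed_filters = FALSE`); the same applies to the optional
identity filter (>= 29% best identity against user-supplied reference
sequences). Database E-values are out of scope here because no database
search is performed.

The matcher explores every admissible spacer length at every start
position, so overlapping matches and same-start matches of different
lengths are all reported. `X` in a query is tolerated by spacers and
never satisfies a fixed residue.

Pairwise identities (`pairwise_identity()`) come from global
Needleman--Wunsch alignment with BLOSUM62 and affine gaps (opening 10,
extension 0.5 — conventional protein-alignment defaults), with identity
counted over aligned columns excluding terminal gaps; the alignment
engine resolves traceback ties deterministically, so identity matrices
are reproducible run to run. The DBD/CBD boundary is never annotated per
homologue, so `split_domains()` uses a declared heuristic: the DBD ends
a fixed wing allowance (default 30 residues, configurable) after the
RxWERRY hit, and the CBD starts at the next residue. This is a modelling
choice, not an inference from data.

## Operator scanning

The repeat grammar is specified at three nested levels, reconciling the
two printed notations for the consensus (the bracketed
N4-T-N3-C[C][G] / N4-T-N2-RCR[G] form and the body consensus
nnnnTnnACAn, which disagree at positions 9--11 if brackets are read as
fixed bases):

| pattern    | constraints                  | role                        |
|------------|------------------------------|-----------------------------|
| `loose`    | T5, C9                       | run membership              |
| `strict`   | T5, R8, C9, R10 (R = A/G)    | >= 1 required per operator  |
| `DR_label` | T5, A8, C9, A10 (TnnACA)     | DR vs dr labelling          |

With these defaults DR ⊂ strict ⊂ loose, which the test suite verifies
over all 4^6 variable cores. A `"methods_literal"` preset that reads the
brackets as literal fixed bases is also shipped
(`repeat_pattern_preset("methods_literal")`); the choice is a
configuration, not a code change.

`scan_tandem_repeats()` reports every maximal run of contiguous
(step 11; tandem means abutting, a max gap is configurable but defaults
to 0) loose-matching 11-mers with at least `min_repeats` units (default
3, matching the smallest experimentally mapped operators) and at least
one strict unit. Units are labelled `DR` when TnnACA is fully conserved
and `dr` otherwise, giving arrangement strings such as
`DR1-dr2-DR3-DR4-dr5`. Overlapping candidate runs in different registers
are resolved deterministically: more strict matches, then more DR
labels, then leftmost. Scanning is on the gene's coding strand, where
the biology places these operators relative to the promoter.
`build_pfm()` exports position-frequency matrices and a consensus (ties
as IUPAC codes) for external logo rendering.

## Cooperative dimer occupancy, bands and footprints

Each repressor dimer engages two *tandem* intact repeats, one DBD per
repeat; a stable upper ("double") gel-shift complex needs two dimers and
hence at least four engageable repeats. `enumerate_occupancy()`
enumerates all non-overlapping placements; `predict_bands()` maps the
maximum load onto the observable band category:

* `double` — two simultaneous full dimers possible (>= 4 repeats in
  suitable layout);
* `single_plus_weak_upper` — one full dimer plus a partial single-DBD
  placement (three contiguous intact repeats). Partial placements exist
  in the model only to explain the weak upper band on three-repeat
  probes; they never count towards the stable double criterion;
* `single` — exactly one full dimer, no partial extension;
* `none` — no two adjacent intact repeats (mutating the central repeat
  of a three-repeat probe abolishes binding entirely).

`predict_footprints()` converts an occupancy configuration to footprint
geometry in probe coordinates: one short hydroxyl-radical protection
tract per engaged repeat per strand, centred in the repeat (width
default 3 nt, the upper end of the observed 2--3 nt tracts), with
adjacent tract centres 11 nt apart — one helical turn, i.e. binding to
one face of the duplex; a DNase I protection span covering the engaged
repeats plus a margin (default 4 nt per side); and exonuclease III
arrest positions just outside the engaged block, +4 nt downstream of
the 3' edge on the sense strand and -3 nt upstream of the 5' edge on
the antisense strand (the midpoint of the observed 2--4 nt range). All
offsets are configurable since the experiments report ranges; the
"weak" versus "strong" arrest distinction is qualitative and is not
modelled.

## Hill fitting of EMSA titrations

Fraction bound is estimated from free-DNA depletion,
f = 1 - I_free/I_free,0, clipped to [0, 1], and fitted with the
three-parameter Hill equation

  f([P]) = A [P]^h / (KD^h + [P]^h)

estimating the amplitude A, the apparent dissociation constant KD (nM;
the protein concentration at half-maximal binding) and the Hill
coefficient h. A free amplitude rather than a baseline offset is the
adopted reading of "3-parameter": gel-shift curves start at zero bound
fraction by construction, while incomplete saturation is common.
Parameters are bounded: 0 < A <= 1.05 (a small allowance above full
binding for quantification noise), KD > 0, 0.1 < h <= 6.

Optimisation is Levenberg--Marquardt least squares started from a fixed
grid (KD0 at the concentration nearest half-maximum, the geometric
mid-concentration, the top concentration and twice the top
concentration; h0 from 0.5 to 6 in steps of 0.5; A0 = max f), keeping
the start with the lowest residual sum of squares, ties to the earliest
start. A single fixed start is not sufficient here: on sparse
seven-point titrations with steep cooperativity the objective has local
optima in which one LM run can stall (for instance against the
amplitude bound), and a deterministic start grid removes those failures
without introducing any randomness. Fits are therefore exactly
reproducible; no random restarts are used. `fit_hill()` returns a
classed model object with `print`, `summary`, `coef`, `predict`,
`fitted`, `residuals`, `plot` and `simulate` methods.

## SEC calibration and oligomer calls

The column calibration is the log-linear line log10(Mr) = 8.1537 -
0.2316 Ve. Units are not printed with the line; the adopted reading is
log base 10, Mr in daltons and Ve in ml, which yields plausible masses
(about 30--240 kDa) across the 12--18 ml working range of an analytical
10/30 gel-filtration column — any other reading gives physically absurd
values. Both constants and the trusted Ve range (default 8--20 ml,
outside which queries warn) are configurable. `call_oligomer()` divides
apparent by protomer mass and reports the nearest positive integer with
a +/-25% tolerance flag — generous because SEC masses of non-globular
proteins deviate substantially (an apo dimer of a 35 kDa protomer runs
at ~59 kDa, 16% below 2x).

## qRT-PCR normalisation

`relative_expression()` implements the comparative Cq method with a
reference gene (rpoD in the source experiments) and a baseline
condition (dark with vitamin B12 present): fold =
2^-(dCq - mean dCq_baseline), with the mean and standard error over
replicates per condition.

## Synthetic data: what it emulates and what it does not

The generators are pure functions of (configuration, seed):

* `gen_promoter()` — 175-nt windows at 0.68 GC (mid-range of the 66--75%
  GC genomes this emulates), with a planted contiguous repeat run at a
  recorded offset. DR units conserve TnnACA; dr units carry exactly one
  mismatch (configurable) at a TnnACA position whose mutation keeps the
  loose pattern (positions 8 or 10 — mutating 5 or 9 would eject the
  unit from the run, contradicting the dr definition); `mutated` units
  break the loose pattern for probe-style layouts. Backgrounds are
  rejection-sampled until a scan of the window returns exactly the
  planted call(s), so spurious runs cannot contaminate ground truth;
  the rejection budget errors out with advice to change seed.
* `gen_protein()` — 286--330 aa sequences planting RxWERRY, Wx9EH and
  the B12 motif in DBD→CBD order with spacers randomised within the
  printed bounds; the CarA variant substitutes the Wx9EH Trp, the
  non-member omits the B12 motif. Sequences are rejection-sampled until
  the classifier returns the intended label, closing the loop between
  generator and classifier.
* `gen_emsa_curve()` — Hill-model curves at the gel-shift titration
  series (0.1--100 nM) with additive Gaussian noise clipped to [0, 1].
  No noise magnitude is published for band quantification; sigma = 0.03
  is a declared default chosen as a typical densitometry error, not an
  inferred one.
* `gen_sec_trace()` — Gaussian elution peaks centred at the volume
  implied by inverting the calibration for n x protomer mass.
* `gen_mini_genome()` — one contig per gene, genes on alternating
  strands, planted operators inside the -150..+25 windows, written as
  standard FASTA/GFF3.

What the generators do **not** emulate: phylogenetic covariance among
homologues, codon structure and amino-acid composition bias, real gel
images (band intensities are inputs, not pixels), column peak tailing,
and operator context effects such as overlapping promoter elements.
Passing the ground-truth-closure tests therefore demonstrates internal
consistency of scanner, classifier and fitters under the stated noise
models — not performance on real genomes, where repeat degeneracy and
annotation errors are harsher than anything generated here.

## Numerical choices and degenerate inputs

* Scanner tie-breaks (strict count, DR count, leftmost) and alignment
  traceback make all reports deterministic.
* `fit_hill()` refuses curves with fewer than 4 points, all-equal or
  all-zero responses; `binding_curve()` enforces positive
  concentrations and fractions in [0, 1].
* SEC round-trips Ve → Mr → Ve to 1e-9 ml; the calibration slope must
  be positive so mass is strictly decreasing in elution volume.
* PFM consensus ties are reported as IUPAC ambiguity codes rather than
  resolved arbitrarily.
* Empty FASTA files warn and return an empty set; empty records are
  errors naming the offending header. Features with start > end or off
  the contig are rejected; contigs missing from the FASTA produce
  per-feature error rows in `scan_genome()` so one bad feature does not
  abort a genome report.

## Problem sizes in the test suite

The shipped tests run the scanner-versus-enumeration comparison on 500
random windows, the motif matcher against a sliding-window oracle on
1000 random proteins, the repeat-pattern nesting over all 4096 variable
cores, the noise-free Hill recovery grid over KD in {5, 35, 200} nM x h
in {1, 2, 3}, 200 noisy titration replicates at sigma = 0.03, and
ground-truth closure on 100 seeded generator runs — sizes chosen so the
whole suite completes in a couple of minutes on a single CPU while
exercising every code path the properties cover.

## Known limitations

* Classification rests entirely on the printed motif grammar; genuinely
  divergent homologues whose motifs drift outside the literal patterns
  (e.g. a spacer of 40 or 42 in the x41 stretch) are not recovered
  unless the bounds are relaxed in configuration.
* The occupancy model is combinatorial, not thermodynamic: it predicts
  band categories, not concentration-dependent band intensities, and
  the antirepressor is representable only as "binding abolished".
* The DBD/CBD split is a heuristic; domain-wise identities inherit its
  uncertainty.
* Scanning defaults to the coding strand of annotated genes; divergent
  promoter pairs sharing one intergenic region should be scanned from
  both flanking genes.
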