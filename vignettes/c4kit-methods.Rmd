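---
title: "Methods behind c4kit: enzyme typing, gene complements, and tree-sample summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind c4kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4kit)
```

## What the package models

C4 photosynthesis concentrates CO2 around RubisCO by first fixing it into a
four-carbon acid via phosphoenolpyruvate carboxylase (PEPC). The pathway comes
in three biochemical subtypes (NADP-ME, NAD-ME, PCK) that share two enzymes —
PEPC and pyruvate orthophosphate dikinase (PPDK) — plus a small set of
subtype-specific ones (malate dehydrogenases, malic enzymes,
aminotransferases, PEP carboxykinase). Surveys of C4-related genes in algal
transcriptomes rest on a handful of operational rules, and `c4kit` implements
those rules as tested, reusable operations:

1. **PEPC typing.** A PEPC is *bacterial-type* (BTPC) when its C-terminal
   tetrapeptide is `(R/K)NTG` and *plant-type* (PTPC) when it is `QNTG`;
   sequences with neither motif (archaeal and cryptophyte PEPCs, for
   instance) stay `unclassified`. Exactly the last four residues are
   examined, after stripping a terminal stop.
2. **C4-diagnostic site.** C4-type enzymes carry a serine at the position
   homologous to PTPC position 774; non-photosynthetic ones carry an alanine
   there. The site is located by optimal global alignment of the query
   against a coordinate reference, and the two verdicts (terminus type, site
   type) are deliberately independent: brown-algal BTPCs with the C4-type
   serine are a real observation the classifier must be able to express.
3. **PPDK versus PEPS.** Genuine PPDK carries an N-terminal
   nucleotide-binding domain; sequences lacking it (including "PPDK"
   annotations in public cyanobacterial records) behave like PEP synthetase
   (PEPS). The discriminator searches configurable signature motifs inside
   N-terminal windows; matching both classes is conservatively `ambiguous`.
4. **Gene complements.** Sequences are assigned to enzyme families against a
   labeled reference panel by alignment identity, tallied into an
   organism-by-enzyme inventory, and each organism is scored complete or
   incomplete per C4 subtype against required-enzyme sets.
5. **Tree-sample summaries.** Posterior-like collections of trees are
   summarized through burn-in, bipartition frequencies, majority-rule
   consensus with supports, and the average standard deviation of split
   frequencies (ASDSF) between independent runs; a neighbor-joining
   constructor and a sister-group origin-assignment procedure close the loop
   from sequences to an inferred prokaryotic donor lineage.

## Reading and filtering inputs

FASTA headers use a pipe-delimited dialect defined by this package
(`id|organism|taxon_group[|enzyme_label]`), since sequence archives carry no
standard metadata slot for taxon groups. Unknown groups map to `other` with a
warning rather than failing a whole file. FASTQ quality is fixed at Phred+33
with no autodetection — one fewer silent failure mode.

The transcriptome read filter discards a read when *more than* 10% of its
bases fall below Q20 or *more than* 5% are `N`. Both thresholds are strict
inequalities — that is how "more than" reads — so boundary reads (exactly
10% low-quality, exactly 5% N) are kept. The filter is idempotent, and with
both maxima at 1.0 it keeps everything.

```{r filter}
reads <- gen_reads(n = 5, length = 100, low_q_fraction = 0.10,
                   n_fraction = 0.05, seed = 1)
filter_reads(reads)$n_discarded   # boundary reads survive
```

## Alignment choices

Classification and distances rest on optimal global pairwise alignment
(Needleman–Wunsch with affine gaps, Gotoh's three-state recursion, written in
C++). A multiple-alignment program would be the classical choice for
figure-style alignments, but pairwise optimal alignment is deterministic,
oracle-testable (its score can be checked against exhaustive enumeration on
short strings), and sufficient for the two things the classifiers need:
mapping one reference position onto a query, and computing identities for
distance matrices.

Numerical conventions, all testable and fixed:

* Default scheme BLOSUM62 with gap open 11 / extend 1 — the community
  convention; a gap of length $L$ costs $11 + L$. `X` scores 0 against
  everything.
* Traceback tie-breaking prefers diagonal, then a gap in the second
  sequence, then a gap in the first, so outputs are byte-stable.
* Identity is computed over columns where both sequences have a residue,
  which excludes terminal gaps from the denominator.
* Distances are `1 - identity`; the matrix is symmetric with a zero
  diagonal by construction.

The diagnostic-site caller uses the strict mapped column by default
(`window = 0`). Because "position 774 *or those around it*" is how the site
is described in the literature, an optional `window = k` mode reports the
nearest mapped residue within ±k reference positions when the exact column
falls in a deletion; the strict mode stays the default for determinism. The
bundled coordinate reference is a synthetic 960-residue construct with the
serine at 774 (`default_pepc_reference()`); the published numbering's actual
reference sequence is not recoverable from text sources, so any real
reference can be supplied through `diagnostic_site_spec()`.

The PPDK/PEPS signature defaults are likewise synthetic exact-string motifs
matched to the package's generator. Published figures show the signatures as
shaded alignment columns, not machine-readable strings; users analysing real
data must supply their own transcription via `signature_spec()`.

## The synthetic-data generators

Every generator is a pure function of its spec, including the seed: the RNG
is seeded locally and restored, so two calls with one spec are
byte-identical and no hidden global state leaks between stages.

* `gen_protein_family()` grows a family from one ancestor (uniform over the
  20 standard residues, or a supplied base sequence) with i.i.d. per-site
  substitutions; planted features — terminal tetrapeptide, diagnostic
  residue, signature — are written after mutation and never touched by it,
  so at `mutation_rate = 0` every planted class is recovered with accuracy
  1.0 (the zero-noise baseline the tests pin).
* `gen_reads()` plants exact counts: `round(length × fraction)` low-quality
  bases (Q15 against a Q35 background) and `N` bases at seeded positions.
* `gen_tree_samples()` emits a base topology, each tree perturbed by one
  random nearest-neighbour interchange with a stated probability. NNI is the
  smallest topology move, which keeps the expected split frequencies
  tractable: a split survives every sample that is unperturbed, so its
  frequency is ≥ 1 − perturbation probability.
* `gen_origin_scenario()` simulates one root sequence diverging into the
  three prokaryote groups, with the eukaryotic sequences descending from the
  declared donor's ancestor. Branch divergence $d$ (substitutions/site)
  becomes a per-site substitution probability $1 - e^{-d}$. Defaults —
  root-to-group 0.6, within-group 0.05, donor-to-eukaryote 0.2, length 300,
  3 sequences per prokaryote group, 4 eukaryotes — keep the donor signal
  clearly above the noise while leaving room for occasional failures, which
  is what a recovery-rate benchmark needs. Divergence high enough to push
  expected identity below 10% triggers a saturation warning.

What the generators do *not* emulate: indels (alignment robustness to gaps
is exercised only through engineered deletions), rate heterogeneity across
sites, compositional bias, codon structure, and real phylogenetic depth.
Passing recovery tests therefore shows the rules and plumbing are correct,
not that the classifiers would resolve hard real-world cases.

## Tree-sample bookkeeping

The sampling-schedule arithmetic is exact: a run of $G$ generations sampled
every $s$ generations yields $\lfloor G/s \rfloor$ trees plus one for the
initial state — 5,000,000 and 100 give 50,001. Burn-in discards the first
$\lfloor f \cdot n \rfloor$ trees (the common summarizer convention; with
50,001 trees and $f = 0.25$, 12,500 go and 37,501 remain).

Splits are keyed canonically by the sorted leaf side containing the
lexicographically smallest leaf, so tables are byte-stable and complementary
clades collapse to one key. Majority-rule consensus retains splits with
frequency strictly above the threshold (default 0.5; two topologies at
exactly 50/50 give a star tree), which guarantees compatibility, and
attaches frequencies as supports. ASDSF averages the two-run sample standard
deviation of each split's frequency over splits reaching 0.10 in at least
one run — 0.10 being the standard reporting convention.

`nj_tree()` wraps the standard neighbor-joining agglomeration (exact on
additive matrices) and clamps negative branch lengths to zero.

## Origin assignment

Reading a donor lineage off a gene tree is usually done by eye; here it is a
defined operation. The tree is midpoint-rooted (the deterministic choice
available without an outgroup; unit branch lengths are assumed if none are
present), and the procedure takes the smallest clade containing every leaf
of the eukaryotic group of interest plus at least one prokaryote leaf. The
prokaryote groups present in that clade name the donor — several groups give
`mixed`. Over a tree sample, the modal donor's sample fraction is its
support. The end-to-end benchmark (simulate → align → distances → NJ →
assign) recovers a proteobacterial or cyanobacterial donor in well over 90%
of seeded replicates at divergence 0.2.

## Problem sizes used by the test suite

The suite favours small, exactly checkable instances: alignment scores are
verified against exhaustive enumeration on 200 random pairs of length ≤ 8;
bipartition and consensus counts against brute-force split containment on
sets of ten five-leaf trees; NJ against 100 random additive 5–8-taxon
matrices; the convergence twin uses two runs of 5,000 eight-taxon trees; the
origin benchmark 50 replicates per donor. These sizes make every expected
value computable by an independent route while keeping a full run of the
suite under a minute.

## Known limitations

* Family assignment against a panel is a stand-in for database search; it
  has no E-value statistics, and the default `min_identity = 0.35` is a
  plain identity threshold, not a significance cutoff.
* Cofactor (NAD/NADP) and compartment (cytosolic/mitochondrial) variant
  labels are consumed as input metadata; inferring them (targeting-signal
  prediction, tree position) is out of scope.
* The default subtype definitions (NADP-ME: PEPC, PPDK, MDH-NADP, ME-NADP;
  NAD-ME: PEPC, PPDK, AST-cyt, AST-mit, MDH-NAD, ME-NAD, ALT; PCK: PEPC,
  PPDK, PCK, AST-cyt) follow standard C4 biochemistry, but published
  per-subtype gene lists vary; the sets are fully overridable for this
  reason.
* Consensus supports are split-sample frequencies; the package takes no
  position on bootstrap-versus-posterior semantics.
* `unclassified` covers every PEPC without a recognized tetrapeptide; no
  finer typing of C3-like or C3–C4 intermediate PTPCs is attempted, as no
  operational sequence rule for them exists.
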