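---
title: "Decomposing the evolutionary origin of regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the evolutionary origin of regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elemevo)
```

## The problem

Transcriptional silencers and enhancers are short regulatory DNA elements.
When such an element overlaps a protein-coding ORF — as the 38-bp exonic
silencer of the human *SMIM45* locus overlaps the C-terminal end of its
68-aa microprotein — every base plays two roles at once, and the question
"why is this base conserved?" has more than one possible answer.  This
package implements a decomposition of that question into mechanizable parts:

1. **Codon-constraint overlay.** Given the reading frame, each base is a
   first/second codon position (where almost any change alters the amino
   acid, so conservation is explainable by selection on the protein), a
   wobble position (where changes are usually synonymous), or outside the
   ORF.
2. **Cross-species invariance.** A base is *invariant* when every compared
   ortholog carries the identical base at the homologous column.  Combining
   the two gives the tripartite classification: `codon_fixed_invariant`
   (the "cultivator" signal — a pre-existing protein fixing element bases),
   `wobble_invariant` (conservation the protein cannot explain: the
   signature of constraint on the element itself), pre/post-ORF invariant,
   and `variable`.
3. **Nearest-neighbor GC bias.** The extant bases flanking invariant
   positions are tabulated; a G/C excess among them is the footprint of
   GC-biased mutation accumulating around constrained anchors.
4. **Composition.** GC fraction and overlapping single-strand CpG counts,
   with an enrichment probability for the CpG count.
5. **Proto-elements.** Maximal invariant runs — deeply conserved stretches
   that are candidates for the nucleation sequence from which an element
   matured (e.g. the 11-mer `CCTCTGCAGCC` at positions 121–131 of
   silencer b).
6. **Dating.** Pairwise global percent identity against a ladder of dated
   orthologs converts into presence/twilight/absence verdicts and an
   origination age bracket; identical-ortholog search gives the *completion
   species* (the most anciently diverged species already carrying the exact
   modern sequence).

Everything operates on 1-based inclusive coordinates; "G6" always means
"base G at position 6".  Input is uppercased; `N` is treated as unknown — it
never matches in identity or invariance and is excluded from composition
denominators.

## Alignment model

Pairwise alignment is Needleman–Wunsch with affine gaps (Gotoh's three-state
DP), implemented in C++.  Defaults follow the common DNA convention:
match +5, mismatch −4, gap open 10, gap extend 0.5, with a gap run of length
$k$ costing $10 + 0.5(k-1)$.  Percent identity is
$100\,n_\mathrm{identical}/n_\mathrm{columns}$ with the denominator counting
*all* columns, gap columns included — the convention of the classical global
pairwise tools.  The traceback is deterministic: ties prefer the diagonal,
then a gap in the second sequence, then a gap in the first.  A
`end_gaps_free` flag waives terminal gap penalties for locating a short
element inside a longer genomic region; unlike some overlap-mode tools we
require at least one aligned column, so two unrelated sequences get a
(meaningless, strongly negative) score rather than an empty alignment.
The source publication does not state the scoring parameters behind its
printed identities, so externally derived identities (78%, 45%, 40%) are
treated as approximate expectations, not test targets; `origination_call()`
accepts such identities directly as a table.

## Dating thresholds

The "twilight zone" of sequence identity is never quantified in the source
analyses, so the defaults here are an explicit package convention: *present*
at ≥ 55% identity, *absent* at ≤ 45%.  They bracket the qualitative
judgments the analyses rely on (78% clearly homologous; 40–45% clearly not)
and are echoed in every result object.  Raising the present threshold can
only shrink the present set, so the origination bracket's lower bound never
moves older — a property the tests exercise.  A species with no locatable
ortholog is `no_data`, never `absent`.

## The nearest-neighbor table and the published 12/13

`neighbor_bias_table()` emits one row per (invariant position, side) whose
neighbor exists and is not itself invariant.  The published 13-row table for
the exonic silencer selects one side per base; the package reproduces its
content from the shipped printed table (`printed_neighbor_table()`) and
separately recomputes every neighbor from the sequence.  One printed entry
(the 3′ neighbor of G22, printed T23) disagrees with the extant base at
position 23 (C); `evaluate_printed_neighbors()` reports both and flags the
mismatch rather than overriding either.  The 12/13 G/C summary is therefore
computed over the *printed* rows; extant lookup would give 13/13.

Under `policy = "exclude_forced"` a neighbor at codon position 1 or 2 whose
base admits no synonymous alternative (computed per codon from the standard
genetic code) is excluded from the summary, the only mechanizable reading of
"neighbors fixed by selection are excluded".  The default remains `"all"`
because the published table itself includes first-position bases of
degenerate codons.

## CpG cluster models

Two nulls are shipped for the CpG count.  `binomial_tail` models the number
of CpG-bearing adjacent pairs as $X \sim \mathrm{Binomial}(L-1,\;
\hat f_C \hat f_G)$ with mononucleotide frequencies from the sequence
itself, and reports $P(X \ge k)$.  `shuffle_null` permutes the residues
(preserving base counts exactly; seed mandatory) and reports the fraction of
shuffles reaching the observed count.  The two nulls are close but not
identical — the permutation fixes the base counts that the binomial only
fixes in expectation — so their p-values agree to within a few parts in a
thousand, not to Monte-Carlo precision; the tests assert agreement within
0.005 absolute.  Worth stating plainly: for silencer b the observed 13 CpGs
sit *below* the independence expectation (≈ 26 of 191 pairs at
$\hat f_C \hat f_G \approx 0.14$), so the upper-tail probability is near 1.
CpG depletion relative to mononucleotide expectation is the genomic norm;
the high *absolute* CpG and GC content of the silencer is the biologically
relevant observation, and it is carried by the raw counts (5, 13, 18 CpGs;
27/38 and 143/192 G+C), which are what the package tests.  Published GC
percentages (70%/73%) round differently than direct counts and are not test
surfaces, and no published cluster probability is reproduced because its
model is unstated.

## The forward simulator

`simulate_ladder()` provides ground truth for every analysis stage without
any external data.  It evolves an ancestral element independently along each
branch of a star phylogeny (one branch per species, length = divergence age
in My) — a deliberate simplification matching how the analyses compare each
species to the reference independently.  Per non-frozen site the number of
substitution events is Poisson($\mu t$), applied sequentially; there is no
rate heterogeneity.  Three constraint classes exist: *frozen* positions
never mutate; with `purifying = TRUE` proposed changes at codon positions
1/2 that alter the amino acid are rejected (wobble changes are always
admitted, even the occasionally non-synonymous ones — the constraint
modelled is on positions 1/2 only); everything else is free.

At the immediate neighbors of frozen positions the replacement base is drawn
so that an accepted change is G or C with probability exactly `beta`
(`neighbor_gc_bias`, default 0.92 — a strong bias of the size suggested by
observed neighbor tables): uniform over $\{G,C\}$ minus the current base
with probability beta, uniform over the remaining non-G/C alternatives
otherwise.  This makes the G/C indicator of every qualifying substitution an
i.i.d. Bernoulli(beta) draw, so `recover_beta()` — the fraction of recorded
frozen-neighbor changes producing G/C, with an exact Clopper–Pearson
interval — is an unbiased, calibrated estimator.  A kernel that proposed
"G or C with probability beta, else uniform over all three alternatives"
would leave extra G/C mass in the unbiased branch and make beta
unidentifiable from accepted changes; the package deliberately uses the
identifiable kernel.  Rates (`mu`, and `indel_rate`, default 0) are
simulator conventions for testing, not estimates of nature.

Indels, when enabled, are 1–3 bp, never delete frozen positions, stay out of
the ORF under purifying selection, and the true alignment to the ancestor is
retained.  `truth_alignment()` projects members onto ancestral coordinates
(insertions dropped, deletions as gaps) so the conservation stages can be
tested without alignment inference — important because inferred free-end-gap
alignments of strongly diverged members can misassign columns, which is an
honest property of alignment, not of the simulator.

## What the tests do and do not show

Study conditions used by the seeded tests: beta-recovery coverage uses 200
replicates of a 90-bp element with 30 frozen positions, four species at
25–100 Mya and $\mu = 0.01$/site/My, giving 108–176 qualifying
substitutions per replicate; the 95% interval covered beta = 0.9 in 194 of
200 replicates.  Saturation recovery uses $\mu = 0.05$ over ten species to
500 Mya, where every free site has mutated somewhere and the invariant set
equals the frozen set exactly.  The proto-element recovery freezes positions
121–131 of the real silencer-b sequence over eight species to 120 Mya at
$\mu = 0.03$.

The simulator emulates per-site substitution with known constraint classes
and neighbor bias.  It does not model CpG hypermutability, rate
heterogeneity, selection coefficients beyond accept/reject, coalescent
effects, or a bifurcating tree; passing recovery tests therefore show the
analysis stages are correct *given* the generative assumptions, not that
real ortholog data satisfies those assumptions.  Conversely, all published
in-locus counts (lengths, CpG counts, overlay counts, the neighbor table,
the proto-element location, the motif hits) are recomputed from the packaged
printed sequences with no simulation involved;
`reproduce_printed_checks()` runs that entire battery and reports a
machine-readable pass/fail table.

## Degenerate inputs and tie-breaks

A reading frame may start at any position; trailing 1–2 bases that do not
complete a codon are `post_orf`, and a frame with no complete codon yields
an empty peptide.  Codons containing `N` translate to `X`.  Invariant-run
ties are reported 5′-most first.  Tandem-repeat copies are compared to the
*first* copy (not a consensus) for determinism, only whole copies extend an
array, and the scan caps unit length at 20 bp by default (the search is
quadratic in unit length; the cap is configurable).  Motif patterns are a
deliberately small language — fixed bases and bounded repeats such as
`TAAT T{2,6} GT` — and at each start position the longest match is taken.

## Known limitations

Multiple-alignment *inference* is out of scope (alignments are consumed from
files, produced by the simulator, or built pairwise); there is no local
alignment mode, no E-value style significance for identities, no
ancestral-state reconstruction (neighbor bases are read from extant
sequence), no CpG-island caller, and no transposable-element annotation —
element and repeat coordinates are accepted as input.  Species divergence
ages are taken verbatim from the input ladder.
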