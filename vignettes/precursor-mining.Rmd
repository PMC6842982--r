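---
title: "Screening cyclic-peptide precursor genes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening cyclic-peptide precursor genes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclominer)
```

# The screening model

`cyclominer` targets ribosomally synthesized, head-to-tail cyclized plant
peptides (orbitides / *Caryophyllaceae*-type cyclic peptides). The model
is deliberately minimal:

* The mature ring is built from the 20 proteinogenic L-amino acids joined
  only by backbone amide bonds. A ring of $n$ residues therefore has up
  to $2n$ linear readings ($n$ ring-opening positions $\times$ 2
  directions); symmetric rings have fewer (cyclo-[AAAA] has one).
* The ring is excised *unmodified* from a precursor protein, so one of
  the ring-openings must appear verbatim in the translated proteome.
  Screening all six reading frames of an assembled transcriptome for
  exact matches to every opening is then a complete search: recall is
  100% by construction under the model's assumptions, and the practical
  question is only specificity (how many spurious exact matches a random
  proteome background yields).
* A genuine precursor hit sits inside an intact ORF with a plausible
  mRNA context: an ATG-initiated coding sequence with the core flanked by
  a leader peptide and a C-terminal recognition sequence, a 3′ UTR, often
  a polyadenylation signal, and a poly(A) tail in oligo(dT)-primed
  assemblies.

What the model excludes — and therefore what this package cannot find —
are rings containing non-proteinogenic or posttranslationally modified
residues, side-chain (cyclotide-style) cyclization topologies, and
precursors whose core differs from the mature ring by even one residue
(the search is exact by design; see *Limitations*).

Both ring-opening directions are screened by default even though
ribosomal synthesis fixes the N-to-C direction. The stored residue order
of a structurally elucidated ring is an arbitrary reading, so
direction-blind screening avoids committing to one; `include_reverse =
FALSE` restricts to forward rotations when the encoded direction is
known.

## Ring identity

Two linear peptides encode the same ring iff one is a rotation of the
other or of its reversal. `canonical_cyclic()` picks the
lexicographically smallest string over that class (plain byte-order
comparison of one-letter codes as the tie-break), giving a canonical name
usable as a dictionary key. This is how predicted mutant rings are
compared: cyclo-[IFGGLPFPP] and any of its 17 other readings canonicalize
identically.

# The screen, step by step

**Six-frame translation** uses the standard nuclear genetic code (the
targets are plant nuclear genes; no alternative tables are offered).
Frames $+k$ translate the transcript at offset $k-1$; frames $-k$
translate the reverse complement at the same offsets. Stops are kept as
`*`; any codon containing `N` translates to `X`, which can never match a
pattern — an ambiguous assembly position conservatively suppresses a
match rather than inventing one.

**Pattern search** reports every occurrence of every pattern in every
frame, overlapping occurrences included. The implementation uses
zero-width regex lookahead for overlap handling; the normative definition
is the naive positional scan, and the test suite holds the two equal on
randomized transcriptomes. Patterns shorter than 3 residues are rejected
by default (`min_pattern_len`): a dipeptide matches a random 300-residue
frame with probability near 1 and the hit list becomes noise.

**Coordinates.** Internally everything is 0-based half-open; every
user-facing table is 1-based inclusive, and minus-strand hits and CDSs
are reported in forward-strand transcript coordinates with a strand flag,
so downstream tools see a single coordinate system per contig.

**ORF extension.** The precursor ORF is the *maximal* ORF containing the
core: from the hit, scan upstream in frame to the furthest ATG not
separated from the core by an in-frame stop, then downstream to the first
in-frame stop. Truncation at either end returns a reject with reason
(`no-start`, `no-stop`) rather than a partial candidate; assemblies
commonly contain 5′-truncated contigs and silently emitting a shortened
precursor would corrupt downstream family alignments. Internal
methionines in the leader are common (the prePhHB leader has one), which
is why the rule takes the *furthest* upstream ATG in the stop-bounded
window, not the nearest.

**mRNA features.** The poly(A) tail is measured first, as the maximal run
of terminal A's (capped so it never reaches into the CDS), and the 3′ UTR
is measured excluding it; the two are reported separately because they
are distinct biological features and because a tail boundary is an
assembly artifact as much as a biological one. The polyadenylation signal
is matched as the literal heptamer `AATAAAA` — the variant seen in the
prePhHB 3′ UTR — rather than the canonical `AATAAA` hexamer; the
`signal` argument of `annotate_mrna_features()` accepts the hexamer for
general use. Published component lengths for gene models of this kind are
not always internally consistent with the stated total cDNA length, so
the candidate table reports components only and never a recomputed total.

# Indel consequence prediction

`mutation_event()` follows the coordinate convention used when such
variants are described: 1-based positions counted from the A of the ATG,
an insertion's span giving the positions the new bases occupy *in the
mutant* ORF, a deletion's span the removed positions in the wild type.
This is the only reading under which a 3-base event can be reported at a
3-position span in either sequence.

A consequence of taking stated positions literally is that an insertion
span need not respect codon boundaries. For the prePhHB-type variants —
a 3-bp insertion around ORF positions 54–56 reported to add one Phe, and
a 3-bp deletion at 61–63 removing one Pro — the deletion is codon-aligned
and reproduces the −Pro outcome at any codon choice, while a Phe-codon
insertion occupying exactly 54–56 straddles two codons and cannot yield a
gained Phe for *any* choice of wild-type codons (the new codon formed at
the junction is `TCx`, serine). The reported residue-level outcome
(+1 Phe, ring cyclo-[IFGGLPFPP]) corresponds to a codon-aligned insertion
between the first and second Pro codons of the core (positions 58–60). We
treat residue-level outcomes as the ground truth — they are what mass
spectrometry of the predicted rings would test — so the package's example
analyses and tests place the Phe insertion codon-aligned, while
`apply_indel()` itself honors any stated span, codon-aligned or not. The
signed precursor-length change, which is what an in-frame 3-nt event
determines independent of position, is +1 either way.

Residue-level diffs are computed by anchoring the longest common prefix
and suffix of the wild-type and mutant translations — deterministic, and
exact for single clean events. Frameshifts (indel length $\not\equiv 0
\bmod 3$), start loss, premature stops, and deletions straddling a core
boundary all void the predicted cyclic product rather than guessing; the
prediction object carries explicit flags for each. Predicted rings are
labeled predictions: they are hypotheses about what a mutant allele could
encode, not observed metabolites.

The core codon interval must be supplied explicitly (`core_span_nt`);
inferring it from a peptide-level match would silently pick the wrong
copy in precursors with repeated cores. Insertions at the exact 5′ edge
of the core are attributed to the leader and shift the core; insertions
strictly inside (including flush with the last core codon) grow it. The
rule is arbitrary at the edge but deterministic and flagged.

# Peptide masses

Residue masses are fixed constants (monoisotopic and average, 5-decimal
precision) rather than a dependency: the module needs exactly twenty
numbers plus water (18.010565 / 18.0153 Da) and the proton (1.007276 Da).
A linear peptide is the residue sum plus one water; head-to-tail
cyclization forms a lactam and loses that water, so a cyclic peptide is
the bare residue sum — hence invariant under rotation and reversal, a
property the tests exercise. `mz(m, z)` is $(m + z \cdot 1.007276)/z$.

One cautionary computation the package surfaces: the 35-residue prePhHB
precursor has an average neutral mass near 3710 Da, while its
triply-protonated ion sits near $m/z$ 1237.8 — numerically close to
values sometimes quoted as a "molecular weight" for such peptides. Both
numbers are computed; neither is asserted as the other.

# Precursor similarity and trees

The homology module supports family-level comparison of short precursor
proteins: Needleman–Wunsch global alignment with a simple
match/mismatch/gap scheme (+1/−1/−2 by default; deterministic traceback,
ties diagonal > up > left), all-pairs percent identity, p-distance
matrices, and neighbor-joining trees. A simple scheme is the default
because published comparisons of these very short, low-complexity
precursors are typically manual alignments, where a substitution matrix
buys little; `global_align()` accepts one via `submat` for users who want
it. Progressive multiple alignment is out of scope — all-pairs identity
plus NJ covers the intended use.

NJ itself and Newick serialization are delegated to `ape` (negative
branch lengths clamped to zero with a warning); bootstrap resampling is
by alignment columns with a mandatory seed — there is deliberately no
wall-clock default, so every tree is reproducible from its config.
Support values are the percentage of replicate trees containing each
internal bipartition. Bootstrap requires pre-aligned (equal-length)
input; p-distances on aligned rows ignore double-gap columns and count
gap-versus-residue as a mismatch.

# The synthetic fixture generator

Real unigene assemblies for this kind of screen are rarely depositable in
a test suite, so `generate_fixture()` builds one: i.i.d. random
background nucleotides at a stated GC fraction (default 0.42, typical of
plant transcript GC content), with precursor genes planted on either
strand. Default planted-gene architecture mirrors the prePhHB mRNA: 63-nt
5′ UTR, ATG + 13-residue leader + core + 14-residue follower + TAA
(108-nt CDS for an octapeptide core), 152-nt 3′ UTR with one `AATAAAA`,
28-nt poly(A) tail; the default spec plants 5 such genes among 50
transcripts of 300–1500 nt. Two constructions make the truth set exact
rather than probable:

* the last in-frame codon of the 5′ UTR is a stop, pinning the maximal
  ORF to the planted ATG regardless of what the random UTR contains;
* every finished transcript is screened post hoc with the naive six-frame
  scan and regenerated under an incremented sub-seed on any accidental
  ring-opening match, extra polyadenylation signal, or tail-confusing
  terminal base. Planted recall is therefore 100% and decoy false
  positives 0 on every fixture, by construction.

Structured decoy kinds probe specific failure modes: `shuffled-core`
(composition preserved, order destroyed), `core-with-internal-stop` (the
core matches but sits behind an in-frame stop with no start codon, so ORF
extension must reject it), and `core-split-across-frames` (a 1-nt
insertion inside the core codons destroys the in-frame match).

What the generator does *not* emulate — and hence what passing tests do
not demonstrate about real data — includes repeat structure and
low-complexity background (i.i.d. bases understate spurious-match rates
in repeat-rich transcripts), assembly artifacts (chimeras, truncations,
strand-ambiguous contigs), sequencing error, and realistic expression
structure. Results on real assemblies depend on assembly quality in ways
the fixtures cannot capture.

# Reproducibility and problem sizes

Every stochastic operation takes an explicit seed (fixture generation,
bootstrap, seeded codon choice); nothing falls back to wall-clock
entropy. The test suite exercises randomized properties at sizes chosen
to probe the algorithms rather than the hardware: 1000-case involution
and round-trip properties for sequence primitives, 100 random
transcriptomes for search-vs-naive-scan equivalence, brute-force
alignment cross-checks at lengths ≤ 5, ring-canonicalization equivalence
by exhaustive enumeration over a 3-letter alphabet at lengths ≤ 5, NJ
additivity recovery at 4–8 taxa, and end-to-end fixture screens of 20–50
transcripts. Acceptance-style computations rebuild their inputs from
scratch at run time.

# Known limitations

* Exact matching only: a single core substitution in the organism, or
  one miscalled base producing a residue change in the assembly,
  defeats the screen. Degenerate-codon nucleotide search and approximate
  peptide matching are deliberately out of scope.
* Transcript-level gene models only; no introns, no genome coordinates.
* The maximal-ORF start rule can overcall the leader when a true
  precursor uses a downstream ATG in an unbroken upstream frame.
* Mass computations cover unmodified peptides; no posttranslational
  modifications, isotope envelopes, or fragment prediction.
* NJ trees of very short precursors carry little signal per column;
  bootstrap percentages on such alignments should be read accordingly.
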