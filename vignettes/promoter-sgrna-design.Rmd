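---
title: "Promoter-specific sgRNA design for CRISPRa: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-specific sgRNA design for CRISPRa: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterguide)
```

## The design problem

CRISPR activation recruits a nuclease-dead Cas9 fused to a transactivation
domain (dCas9::VP64) to a gene's promoter; activation is strongest when the
guide binds a window roughly 50–400 bp upstream of the transcription start
site. In *C. elegans* this window cannot be read off gene annotations:
most mRNAs are trans-spliced to a spliced-leader RNA, which replaces the
native 5′ end and hides the true TSS. The design procedure therefore
*consumes* a table of experimentally defined representative TSSs
(stage-resolved, embryonic and/or adult) and never attempts to infer TSSs
itself.

The pipeline is a deterministic chain of five steps per gene — TSS
selection, window arithmetic, candidate enumeration, dual scoring,
filter/rank/label — plus two satellites: scramble-control generation and
an in-silico reconstruction of the sgRNA expression-vector cloning.

## TSS selection and window arithmetic

Each gene may carry one representative TSS per stage. When both stages are
present the adult TSS wins; a duplicated (gene, stage) pair is refused at
parse time rather than silently tie-broken, because "representative" is
meaningful only if unique. The preference rule is applied literally; a
`stages = "both"` flag designs for every stage separately when a library
for both developmental contexts is wanted.

"Offset *k* upstream" means the base *k* positions 5′ of the TSS on the
gene's strand, with the TSS itself at offset 0. The window covers offsets
50..400 inclusive — 351 bp — so on a plus-strand gene with TSS at
position *t* it is `[t − 400, t − 50]`, and mirrored for minus-strand
genes. All external coordinates are 1-based inclusive, the convention in
which plasmid maps and primer designs are written. Windows that would run
off a chromosome end are clamped with a warning (an honest partial window
is more useful than a refusal); a window entirely outside the chromosome
is an error naming the gene.

## Candidate enumeration

A candidate is any 20-mer whose protospacer lies **entirely** inside the
window and whose immediately 3′-adjacent 3-mer matches NGG, on either
strand. Two boundary decisions deserve spelling out:

* The PAM may extend up to 3 bp outside the window on either side. The
  protospacer is the functional binding determinant; anchoring it inside
  the window while letting the PAM poke out is the conservative reading of
  "select target sequences from this region", and restricting the
  allowance to one side would arbitrarily exclude minus-strand candidates
  at one window edge.
* Candidates overlapping an ambiguous base (`N`) in protospacer or PAM are
  dropped silently; scoring unknown bases would be guesswork.

Enumeration is vectorised over window positions, but its contract is
exhaustive-scan equality, which the test suite enforces against an
independent per-position brute-force oracle on 1000 random windows.

## On-target model

The on-target score is a position-weight logistic model over a 30-mer
context: 4 nt of 5′ flank, the protospacer (positions 5–24), the PAM
(25–27), and 3 nt of 3′ flank,

$$\mathrm{score} = 100 \cdot \sigma\!\Big(\beta_0 + \sum_{(p,x)\,\in\,\text{matched}} w_{p,x}\Big),$$

with single-nucleotide and dinucleotide features anchored at 30-mer
positions. The score is therefore always in (0, 100), deterministic, and
monotone in every matched weight — properties the tests pin down with
closed-form anchors (null model → 50; a single unit weight → 100·σ(1)).

The shipped default table is this package's own construction following the
qualitative preferences of published SpCas9 activity models (G strongly
favoured and C disfavoured at the PAM-proximal protospacer end, pyrimidine
runs penalised, a mild PAM-variable-base effect, small flank terms). It is
deliberately a documented stand-in, not a re-fit: published libraries were
scored with external web tools whose exact rule set is not reproducible
bit-for-bit, and the model here is pluggable (`load_on_target_model()`
accepts any table with the same layout) so any backend honouring the
[0, 100] contract can be swapped in. Candidates whose 30-mer context would
cross a chromosome end are skipped and counted in the run report rather
than scored on padded sequence.

## Off-target search and specificity score

Every genomic 20-mer within 4 mismatches of the guide (Hamming distance;
no bulges) that is NGG-adjacent — optionally also NAG — on either strand
counts as a near-match. The search is an exhaustive vectorised scan over
raw bytes of both strands; at the genome sizes this toolkit targets
(synthetic fixtures and single-digit-megabase test genomes) an index
structure would add code without measurable benefit, and the exhaustive
form makes the oracle-equality contract trivial to state. `N` never
matches anything.

Each near-match site is penalised by

$$\mathrm{penalty} = 100 \cdot \prod_{p \in M} (1 - W[p]) \cdot D \cdot \frac{1}{m^2},
\qquad D = \frac{1}{\frac{19 - \bar d}{19}\cdot 4 + 1},$$

where $M$ is the set of mismatch positions (1 = PAM-distal), $W$ the
per-position mismatch weight vector, $m = |M|$, and $\bar d$ the mean
pairwise distance between mismatch positions ($D = 1$ for $m < 2$ — the
degenerate case is defined as no damping). The shipped $W$ is the
experimentally derived SpCas9 position-weight vector in common use by
specificity scorers (seed-region mismatches cost most; $W[1] = 0$,
$W[20] = 0.583$). The guide's aggregate specificity is

$$100 \cdot \frac{100}{100 + \sum_h \mathrm{penalty}(h)},$$

over all hits excluding the guide's own locus (identified by exact
coordinates). This is 100 exactly when the promoter site is the genome's
only NGG-adjacent near-match, and strictly decreases with every additional
hit. The filter threshold (> 50) is applied to *this* score; equivalence
with any external tool's numbers is not claimed.

## Filtering, ranking, labels

Strict mode keeps candidates with on-target **and** specificity scores
strictly above 50; permissive mode keeps everything and flags the
threshold test, for workflows that prefer "preferably above 50" as
guidance rather than a gate. Ranking is a total order — on-target score
descending, then specificity, then smaller TSS offset, then protospacer
lexicographically — so reruns are reproducible to the byte. Labels render
the on-target score rounded half-up, zero-padded to two digits and clamped
at 99 so the prefix is always exactly two characters, then an underscore
and the protospacer.

## Scramble controls

Negative-control guides are random 20-mers constrained to exactly 50% GC
(ten G/C draws placed at random positions). A draw is rejected if the
genome contains any 20-mer within 4 mismatches on either strand —
PAM-agnostic, deliberately stricter than requiring a PAM, standing in for
a "no significant similarity" search against the genome. Generation is
deterministic in `(n, seed, genome)`; rejected draws are kept in an audit
attribute. A configurable attempt cap turns a pathological genome
(one that rejects essentially every draw) into a loud error instead of an
endless loop.

## Cloning simulation

The vector-engineering module reproduces the sgRNA expression-vector
construction scheme as string surgery with explicit enzyme geometry:

* **Backbone derivation** deletes an inclusive coordinate range (default
  1982–2204, the bidirectional-T7 region of the 2790-bp parent) and
  inserts the 18-nt EcoRI–HindIII–PstI linker, yielding 2585 bp; the
  length identity `new = old − deletion + linker` is property-tested over
  random inputs.
* **Digestion** models each enzyme as a recognition sequence plus top- and
  bottom-strand cut offsets. Both 5′ and 3′ overhangs are supported —
  PstI, one of the two BioBrick insertion enzymes, leaves a 3′ overhang,
  so a 5′-only engine could not represent the cassette insertion at all.
  Type IIS enzymes (BsaI, BbsI) cut outside their recognition sites, on
  either strand, with circular topology handled by origin-wrapping.
* **Ligation** joins fragment ends that agree in overhang type (5′/3′),
  lie on opposite strands, and carry identical overhang sequence;
  assembly into a circle must consume every fragment, be unambiguous at
  every join, and is invariant to duplex input order when overhangs are
  unique. Digest–ligate cycles conserve total base count.
* **Golden gate** digests, discards every fragment still carrying a
  recognition site (the slot dropouts), and reassembles backbone plus
  annealed spacer duplexes; the product provably contains no residual
  site. Oligo design simply prepends each slot's 4-nt 5′ overhangs to the
  protospacer and its reverse complement.
* **BioBrick validation** reports internal EcoRI/XbaI/SpeI/PstI
  occurrences with positions and checks the prefix/suffix flanks.

True plasmid and cassette sequences are not bundled. `synthetic_l4440()`
builds a length-faithful 2790-bp circular placeholder (scrubbed of all
registry sites, with a sentinel motif filling the to-be-deleted region so
its removal is verifiable), and `synthetic_cassette()` builds a
structurally faithful dual-slot payload — EcoRI prefix, two type IIS slots
with distinct non-palindromic overhangs, PstI suffix. The cassette filler
is drawn from {A, C, T} only: every registered recognition site contains a
G, so junctions between filler and designed elements can never create an
unintended site. Both generators are labelled synthetic and exist for
arithmetic and assembly testing; users supply real sequences for real
cloning.

## Synthetic fixtures

`generate_fixture()` builds a single-chromosome genome with `n_genes` TSSs
on alternating strands (2 kb apart, 1 kb margins), a stage-resolved TSS
table (every third gene also carries an embryonic TSS 100 bp from the
adult one, exercising the preference rule), and a truth manifest. PAM
density is engineered per window:

* `saturated` plants PAMs so candidate starts occur every 8 bp across the
  window **including both boundary candidates** — one whose distal base
  sits exactly 400 bp and one whose proximal base sits exactly 50 bp
  upstream. The literal alternative (a candidate start at *every*
  position) forces homopolymer-G windows, which would make every guide an
  off-target of every other and defeat the scoring stage; tiling with
  exact boundary coverage preserves everything the saturation is meant to
  test.
* `none` scrubs the window (±3 bp) of GG/CC dinucleotides so no NGG
  survives on either strand.
* Planted off-targets copy a designated gene's first candidate, apply an
  exact number of substitutions at spread positions, append a TGG PAM, and
  write the copies into intergenic sequence at recorded coordinates.

What the fixtures do **not** emulate: real base composition and repeat
structure, chromatin context, multi-chromosome genomes, and genuine TSS
uncertainty. Passing tests on fixtures therefore demonstrate algorithmic
correctness — coordinate arithmetic, scan completeness, score formulas,
determinism — not biological performance of any particular guide.

## Numerical and scale choices

Scores are serialised at 4 decimal places in the library TSV, which
round-trips exactly. Default problem sizes keep the whole suite
desk-scale: oracle-equality property tests run 1000 random instances per
scan (110-bp windows, 260-bp genomes), the scramble acceptance check uses
a 50-kb genome with n = 20, and the pipeline acceptance run uses a
10-gene saturated fixture (~22-kb genome, several hundred guides). These
sizes were chosen as the smallest at which the properties are
non-trivially exercised; all scale linearly if raised. Random draws always
flow through an explicitly passed seed, and both the fixture generator and
the scramble generator restore the caller's RNG state.

## Known limitations

* The on-target weight table is a stand-in calibrated to qualitative
  preferences, not a validated efficiency predictor; treat absolute scores
  as a ranking device.
* Off-target matching is Hamming-only; bulged (indel) off-targets are out
  of scope, as are alignment-based searches.
* The cloning engine supports fully double-stranded, sticky- or blunt-end
  chemistry only — no partial digests, no nicking enzymes, no Gateway
  recombination (reagent-kit chemistry with nothing to compute beyond
  concatenation).
* Guide pairing for dual-cassette vectors is left to the user (the obvious
  convenience is "top two ranked"); no synergy model is implied.
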