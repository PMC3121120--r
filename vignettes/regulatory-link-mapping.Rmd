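---
title: "Mapping regulatory links between genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping regulatory links between genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reglinkmap)
```

## The mapping model

A transcriptional regulatory network is a set of signed links: a
transcription factor (TF), a target gene (TG), and a regulation type,
activation (`positive`) or repression (`negative`). `reglinkmap`
transfers such a network from a *source* genome, where it is known, to a
*target* genome, where only sequence-level data are assumed, in three
steps, followed by an expression-based confirmation step.

**TF mapping.** A source TF maps to every target sequence it is
sufficiently similar to (set `TFbl`). The working assumption is that
sequence similarity preserves function only approximately, so two
refinements are offered: keep a pair only if both sides carry the same
protein *family* annotation (`TFf`), or the same *subfamily* annotation
(`TFsf`). Annotations are inputs (e.g. exported from a PANTHER-style
signature scan); the package never runs a signature scanner itself.
Refinement is a positive concordance test: a pair where either side is
unannotated is dropped, not passed through. Because subfamilies are
nested within families (the annotation reader enforces this), the sets
are always nested: `TFsf ⊆ TFf ⊆ TFbl`.

**TG mapping.** Target genes may or may not code for proteins, so family
concordance is not available. Instead, five constructions are supported:
similarity alone (`TGbl`); presence of a TFBS motif on the gene sequence
(`TGbs`) or on promoter sequences (`TGpr`; `TGgalf` is the same scan run
with an externally *discovered* motif set); and similarity combined with
presence of a motif of the regulating TF (`TGblbs`). The motif-only sets
carry no homology information: their entries are target sequences, not
(source TG, target) pairs.

**Integration.** For each source link, the motifs of its TF are first
located in the *source* TG; links whose source TG contains none of its
regulator's motifs cannot be carried by this method and are dropped with
a count (a real phenomenon in curated networks, not an error). The
motifs that are present form the set `M`. Every mapped target TF of the
link's TF is then combined with every candidate target gene containing
at least one motif of `M`. For `TGbl`/`TGblbs` the candidates are the
homologs of the link's own TG; for the motif-only sets every entry is a
candidate. The predicted link inherits the source sign and records its
supporting motifs and its provenance (`TFsf-TGblbs`, `TFf-TGpr`, ...).
The homology-free pairing is deliberate: it reproduces the combinatorial
explosion of links that motivates preferring `TGblbs` for link transfer
even though motif-only sets recover more individual genes.

Predicted links that coincide on (target TF, target TG, sign) within one
run are collapsed, with supporting-motif sets unioned and the
lexicographically first source pair retained, so an output never
contains duplicate target edges of one provenance.

**Confirmation.** Each predicted link is scored against each expression
experiment using the ternary calls of its TF and TG:

| TF call | TG call | positive link | negative link |
|---|---|---|---|
| expressed | expressed | Confirming | Contradictory |
| expressed | not expressed | Contradictory | Confirming |
| not expressed | expressed | Neutral | Confirming |
| not expressed | not expressed | Ignored | Contradictory |
| any absent | any absent | Ignored | Ignored |

With per-link counts *c* (Confirming), *x* (Contradictory) and *n*
(Neutral), a link is **verified** when `c > w_x·x + w_n·n` (default
weights 2 and 1): Confirming evidence must outweigh not only the
contradictions but also the neutral observations, damping outliers in
small experiment sets. Independently, links fall into ratio tiers
comparing *c* against multiples of *x*: `c ≥ 3x`, `3x > c ≥ 2x`,
`2x > c ≥ x`, `x > c`. A link with `c = x = n = 0` has no usable data
(`no_data`) and is excluded from the "links analyzed" total; the four
tiers partition the analyzed links exactly.

This is a counting procedure, not a hypothesis test, by design: the
intended regime is a non-model organism with a few dozen experiments,
far too few for network inference, and no multiple-testing machinery is
appropriate for a deterministic rule table.

## Tunable parameters

* `scoring_scheme(match = 1, mismatch = -1, gap = -2)` — the built-in
  local aligner's scores (dimensionless, per aligned position; the gap
  penalty is linear). The aligner is a desk-scale stand-in for an
  external similarity search; hit tables in the 12-column tabular
  dialect can be ingested instead and used identically.
* `min_score` (alignment score units) — the hit-reporting threshold of
  `find_similar()`. There is no universal default that is meaningful
  across sequence lengths; the pipeline default of 50 suits the
  synthetic scenarios (see below), and real runs should set it, or use
  an external aligner with its own statistics.
* `max_evalue = 1e-5` — the e-value filter for similarity-based mapping.
  A conventional stringent choice; prior work on cross-species TF
  mapping shows the threshold matters as much as the choice of source
  organism, so it is exposed everywhere (`--evalue` on the command
  line). The built-in aligner's `evalue` column is the monotone
  surrogate `exp(-score)`, flagged by an `evalue_surrogate` attribute;
  it is valid only for ranking within one run, never across databases.
* `strands = "both"` — motifs are scanned on both strands by default
  (binding sites are double-stranded features); coordinates are always
  reported on the forward strand, 0-based half-open.
* `tier_config()` — the confirmation weights (`contradictory_weight = 2`,
  `neutral_weight = 1`) and ratio multiples (`ratio_high = 3`,
  `ratio_mid = 2`). Boundary conventions are also exposed
  (`verified_strict`, `tier_lower_inclusive`) because published
  descriptions of such tier schemes do not pin down every boundary; the
  defaults use a strict `>` for the verified test and `≥` at tier lower
  bounds, which is the only combination under which the published tier
  counts we ship as reference data sum exactly to their "links
  analyzed" totals for the nucleotide-sequence-based link sets. The
  promoter-based columns of that table do not sum under *any* fixed
  convention we tested, so the package does not force agreement there.

## Numerical and semantic choices

* **IUPAC matching is subset semantics.** A sequence letter matches a
  motif letter only if every base it denotes is admitted by the motif
  letter. The practical consequence: `N`-runs in draft assemblies match
  only a motif `N`, never a concrete motif letter, preventing spurious
  motif presence in low-quality regions. (Set-intersection semantics,
  as used by some scanners, would match `N` against everything.)
* **Alignment tie-breaks.** Among equal-scoring local alignments the
  one with the smallest (query start, subject start), then the
  shortest, is reported, making outputs deterministic. A best score of
  zero is the empty alignment with spans `[0, 0)` and identity 0.
* **Coordinates.** Hit tables use the 1-based inclusive convention of
  the tabular dialect; all motif occurrences are 0-based half-open.
  Expression numeric mode calls a gene expressed when its value is
  `>= threshold` (inclusive boundary), and an empty cell is `absent`.
* **Unknown genes.** A link whose TF or TG is missing from the
  expression matrix behaves as absent in every experiment and therefore
  lands in `no_data`; missingness never silently becomes evidence.
* **Degenerate inputs.** Empty hit tables, empty motif sets and empty
  networks flow through every stage as empty results, not errors; the
  hard errors are reserved for malformed files (wrong column counts,
  illegal residues or tokens, duplicate ids) and for provenance
  mismatches between mapping sets, which abort integration.

## What the synthetic generator emulates

`generate_scenario()` builds a paired source/target bundle with known
truth: random source TF/TG sequences; concrete (unambiguous) consensus
motifs per TF; a network wiring each TF to dedicated TGs (one regulator
per generated TG — chosen so that per-link expression patterns can be
drawn without conflicting writes to a shared gene's calls); one planted
motif instance of the regulator in each linked source TG; target
homologs produced by per-base substitution at `substitution_rate`, with
the planted motif re-planted intact for conserved links and actively
scrubbed for links that were eligible but not conserved (so the truth
table is exact, and end-to-end recovery equals the realized
conservation rate); unrelated decoy sequences, a fraction of which are
annotated to a real TF family but never the matching subfamily; and a
ternary expression matrix in which conserved links draw Confirming
patterns with probability `p_confirm_true` and Contradictory with
`p_contradict_true` per experiment, all other genes being independent
50/50 coin flips, with an `absent` mask overlaid at `p_absent`.

Two generator details are worth making explicit. The probability that a
link's TF is called expressed is `p_confirm_true + p_contradict_true`,
which is what makes the positive-sign class marginals achievable
exactly. For negative-sign links every non-absent call combination is
either Confirming or Contradictory — there is no Neutral cell — so the
residual probability mass is realized as an absent TG call (an Ignored
experiment). Defaults (`n_tf = 10`, `n_tg = 50`, `seq_len_tg = 500`,
`motif_len = 8`, `substitution_rate = 0.05`,
`frac_link_conserved = 0.6`, `n_experiments = 43`,
`p_confirm_true = 0.8`, `p_contradict_true = 0.1`) describe a
deliberately small regime in which homologs are clearly separable from
background by the built-in aligner (`min_score = 100` in the packaged
examples) and the expression matrix is the size a non-model organism
might realistically have.

What the generator does **not** emulate: insertions/deletions, gene
duplication and codon structure (homologs differ by substitutions
only); motif degeneracy in the planted motifs (concrete consensus
strings keep the truth table exact); nucleosome occupancy or any notion
of active versus occluded binding sites; indirect or feed-forward
regulation; and correlated experimental conditions (experiments are
exchangeable). A pipeline that passes all synthetic tests is therefore
validated for its logic and arithmetic, not for the biological error
modes of real genomes — with real data, binding sites may be present
but inactive, motifs may be missing from genuine targets, and
similarity thresholds interact with genome composition.

## Problem sizes used by the test suite

The unit and acceptance tests run the default scenario (10 TFs, 50 TGs,
70 target sequences, 43 experiments) for end-to-end checks, 100
miniature scenarios (3 TFs, 9 TGs, 80–120 bp) for set-inclusion
properties, 2000 random motif/sequence pairs against a regex-expansion
oracle, and exhaustive plus randomized short sequence pairs (length ≤ 8)
against a brute-force alignment enumerator. Oracle implementations live
in the test helpers and share no code with the package internals.

## Known limitations

Only transcriptional regulation is mapped; post-transcriptional control
is out of scope. Links whose source TG lacks its regulator's motif
cannot be transferred and are only counted. The built-in aligner is a
quadratic-time Smith–Waterman without heuristic seeding, intended for
desk-scale inputs (hundreds of sequences of hundreds of bases); for
genome-scale runs, bring external hit tables. Motifs are consensus
strings, not position weight matrices, and no background-model p-values
are attached to occurrences.
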