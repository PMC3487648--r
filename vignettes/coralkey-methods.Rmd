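---
title: "How coralkey models, validates and inverts a polytomous identification key"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How coralkey models, validates and inverts a polytomous identification key}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralkey)
```

## The problem

A taxonomic identification key is a decision graph. Each numbered
*couplet* confronts the user with two or more contrasting character
statements (*leads*); choosing a lead either moves to another couplet or
ends at a taxon. Keys in the systematics literature are printed as flat
numbered tables, which makes them easy to typeset and hard to compute
with: nothing checks that every couplet is reachable, that no lead
dangles, or that a taxon said to be "keyed two or even three times"
really can be reached along every one of its variant paths.

coralkey gives such keys a typed, validated data structure and the
operations a practitioner actually needs: stepping through an
identification, replaying or reconstructing paths, deriving a
multi-access (polyclave) view, and exporting the graph. Its flagship
dataset is a complete genus-level key to the Recent azooxanthellate
Scleractinia — the deep- and cold-water stony corals — covering 120
genera and 7 additional subgenera in 111 couplets.

## The data model

An `identification_key` holds a title, a source citation, a root couplet
id, and an ordered collection of couplets. Each couplet has a positive
integer id (the printed couplet number; never renumbered) and at least
two leads labelled `a`, `b`, `c`, … in order. Each lead carries its
character statement *verbatim* and exactly one target: a couplet id or a
`taxon_terminal`.

The printed key decorates terminals with metadata, and the model keeps
that metadata out of the statement text:

* **Geographic ranges** in brackets (e.g. `[Atl. + IWP + Ant.]`) become
  the terminal's `regions` vector. The source key is explicit that
  ranges are informational, never diagnostic, so they are excluded from
  all identification logic; `taxa_by_region()` exposes them as a
  browsing aid only.
* **The asterisk** marking genera with both azooxanthellate and
  zooxanthellate representatives becomes the logical
  `apozooxanthellate` flag.
* **"(in part)"** becomes `in_part`. Taxon identity is the pair
  (genus, subgenus-or-null); "(in part)" never creates a new taxon, only
  an extra terminal for the same one.
* **Figure tags** (`F2` …) and **parenthetical family annotations**
  ("Rhizangiidae", "Micrabaciidae", "Turbinoliidae, in part") are stored
  as structured fields; the annotation rides the lead that prints it and
  is echoed onto the couplet it points to.

Nominotypical subgenera are stored exactly as printed: the builtin key
writes *Caryophyllia (Caryophyllia)*, so the model stores `subgenus =
"Caryophyllia"`, and a bare *Crispatotrochus* stores `subgenus = NULL`.

The on-disk format is a small JSON dialect (schema shipped at
`inst/extdata/key-document.schema.json`; unknown fields are rejected).
`parse_key()` and `serialize_key()` are exact inverses on valid keys,
and serialization is canonical, so equal keys produce byte-identical
documents.

## Validation

`validate_key()` reports findings instead of throwing: errors E1
(unresolved reference), E2 (cycle), E3 (couplet unreachable from the
root), E4 (fewer than two leads), E5 (label discipline); warnings W1
(a non-root couplet entered by ≠ 1 lead, i.e. deviation from tree shape)
and W2 (one taxon flagged apozooxanthellate at some terminals but not
others); infos I1 (taxa keyed at more than one terminal) and I2 (region
tokens outside the controlled vocabulary). A key is *clean* when it has
no errors; W1 deliberately stays a warning because a key that merges
paths (a DAG) is unusual but not wrong. Cycle and reachability checks
are delegated to igraph on the couplet graph.

The census convention deserves a note. `key_census()` counts
`distinct_genera` over all terminals and defines `additional_subgenera`
as the sum over genera of (subgenus pairs − 1): a genus's first
(nominotypical) subgenus is not "additional". Under this convention the
builtin key counts 120 genera and 7 additional subgenera from its 13
named pairs, matching how its source publication announces itself; the
raw pair count is exposed alongside.

## Traversal and path semantics

A session is a value: `run_session(key, answers)` applies an ordered
answer vector from the root and returns either a completed path or the
pending couplet with its options. There is no hidden state, so any
partial session resumes by appending answers — this is what makes
identification reproducible and testable. Path length counts decisions
(edges), not couplets visited.

`paths_to_taxon()` reconstructs paths by walking parent links from each
terminal back to the root (on a DAG, all parent combinations are
expanded), while `enumerate_paths()` walks forward exhaustively.
The two meet in the replay property: every reconstructed path, replayed
through `run_session()`, must reach its own terminal. The builtin key
has 136 terminal leads for its 127 distinct taxa (eight taxa are keyed
twice and *Caryophyllia (Caryophyllia)* three times, at couplets 51, 84
and 111), and all 136 replays succeed — the computable form of the
source key's promise that every variant of a genus keys correctly.

## The multi-access view

The printed key's characters exist only as lead contrasts — there is no
independent character ontology — so coralkey treats a "character" as a
(couplet, lead) pair and never parses statement text. `derive_matrix()`
classifies each taxon × character cell from the exhaustive path set:

* `R` (required): every path of the taxon takes that lead;
* `X` (excluded): every path passes the couplet but via another lead;
* `·` (inapplicable): some path never meets the couplet, or variants
  disagree.

`filter_taxa()` is the order-free complement: the user asserts lead
choices for any subset of couplets (at most one per couplet — a specimen
shows one state per contrast; uncertainty is modelled by omitting the
assertion, not by multi-asserting). A taxon survives while *any* of its
variant paths is compatible with every assertion, which makes filtering
monotone: adding assertions can only shrink the candidate set.
Geographic ranges are never assertable.

## The synthetic key generator

`generate_key()` exists so the engine's properties can be tested on
thousands of keys rather than one. It grows a uniformly random tree of
couplets, draws each couplet's arity from branching weights whose
default is the builtin key's observed distribution (101 of 111 couplets
dichotomous, the rest 3–7 leads), fills open slots with taxa from a
synthetic pool, and reuses an already-placed taxon with probability
`multiplicity_rate` to emulate variable, multiply-keyed taxa (defaults
to 0; the property suites exercise rates up to 0.4, bracketing the
builtin key's 8 multiply-keyed taxa out of 127). Generation is seeded
and deterministic — one config, one byte-identical document — and the
RNG algorithm identifier and seed are recorded in the document
metadata. Generated keys are trees, matching the builtin key's shape;
statements are random coral-morphology word salad, deliberately not
biologically coherent.

What generated keys do **not** emulate: correlated characters, the
uneven depth profile of a hand-built key, polytomies placed where a
character is naturally multi-state, or real nomenclature. Passing the
property suites therefore demonstrates the *engine's* correctness on
arbitrary well-formed keys, not anything about coral morphology; the
claims about the Scleractinia key are carried by the dataset tests and
the acceptance script, which run against the shipped encoding itself.

`inject_defect()` inverts the generator's guarantees: each of its five
defects (cycle, dangling reference, orphan couplet, single-lead couplet,
duplicate label) is constructed to trip exactly one error code and no
other, so the validator's detection rate is measurable without
ambiguity.

## Numerical and encoding choices

* Couplet ids are the printed 1-based integers; document order is
  authoritative for lead ordering; nothing is renumbered.
* Statements are stored byte-for-byte as printed, including internal
  parentheticals, an occasional printing quirk (couplet 82's
  "only10 septa"), and UTF-8 such as "Pourtalès Plan". Two terminals
  print the same figure label (102f and 111b both say `F21`); the
  encoding preserves this rather than correcting it.
* Region tokens are kept as printed and normalized only for matching:
  the controlled vocabulary maps the printed variants `I–P`, `Subant.`,
  `IWP.` and `SW. Pac.` to their canonical tokens. `Cosmopolitan`
  implies presence in all three oceans, but that implication is
  vocabulary metadata, never silently expanded into membership — the
  package refuses to invent distributional claims.
* The bibliography of previously published species-level keys stores
  subjects and citations verbatim (including their opaque bracketed
  reference markup); the "(T)" tabular-key marker is parsed into a
  logical flag.
* DOT export truncates edge labels at 40 characters with an ellipsis and
  puts the full statement in the tooltip: readable graphs, lossless
  data.

## Problem sizes in the test and acceptance suites

The property suites run the generator at 1–30 couplets, which is past
the point where every structural situation the engine distinguishes
(polytomy up to 7, reuse, deep chains) occurs, while keeping exhaustive
oracles trivial: soundness over hundreds of seeds, round-trip identity
over 500 keys plus the builtin one, defect detection over 200
injections, and single-assertion filter queries checked against an
independently written brute-force enumerator over 200 keys (several
thousand queries). The builtin key itself is small enough (111 couplets,
246 leads) that every dataset check runs exhaustively.

## Limitations

* No fuzzy or error-tolerant identification: an answer is taken as
  given.
* No character weighting, and no construction of an optimised
  replacement key from the character matrix.
* No import/export of DELTA or SDD descriptive-data formats.
* The glossary of morphological terms and the plate figures belong to
  the printed work; the package stores only figure *labels*.
* Bibliographic citations are not resolved to full references or DOIs.
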