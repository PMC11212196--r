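---
title: "Template-guided curation of atom-mapped reaction datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-guided curation of atom-mapped reaction datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxncurate)
```

## The problem

Large reaction databases accumulate three characteristic defects: reactant
molecules that were never recorded (a Pauson–Khand entry without its carbon
monoxide), products that are structurally inconsistent with their reactants,
and atom-to-atom mappings that pair the wrong atoms — an artefact of the
neural mappers used to annotate unmapped data.  All three corrupt any model
trained on the data, and all three can be attacked with the same instrument:
the *generic reaction template*, the minimal graph signature of a chemical
transformation, harvested from the dataset itself.

`rxncurate` implements a two-stage protocol.  Stage one extracts a generic
retrosynthetic template from every record, merges duplicates by graph
isomorphism, and discards rare templates.  Stage two applies the surviving
templates back to each record's products: if some template regenerates a
reactant set containing the recorded reactants, the record is kept (and its
reactants replaced, which restores omissions and repairs the mapping);
otherwise it is removed.

## Generic templates

A template is extracted in the retro direction at radius 0.  The *reaction
centre* is the set of mapped atoms incident to a bond whose order changes
between the two sides, plus atoms whose hydrogen count or formal charge
changes, plus atoms bonded to leaving or incoming groups.  Centre atoms keep
only their element and map number; aromaticity, degree, chirality, hydrogen
counts, charges and cis/trans labels are all erased.  Leaving-group atoms
(reactant atoms that never reach the product) are kept with their bonds.
For a Grignard-type aryl addition the result is

```
[#6:1]-[#6:2]-[#8:3]>>Br-[#6:1].[#6:2]=[#8:3]
```

read right-to-left: an aryl bromide and a carbonyl combine into C–C–O.

Three special cases widen the signature where erasing everything would lose
the chemistry:

* **radical reactions** — when any centre atom carries unpaired electrons,
  hydrogen counts on centre atoms are retained (`[#6H3:1]`), since H counts
  are what distinguishes a radical from its closed-shell parent;
* **charge transfer** — when a centre atom changes formal charge, charges
  are retained (`[#8-:2]`);
* **disjoint centres** — when centre atoms fall into several fragments of
  one product molecule (ring openings), the atoms on unweighted shortest
  paths between the fragments are added, and nothing else.  When several
  shortest paths exist we include exactly one, chosen by a deterministic
  breadth-first search over ascending atom indices; the choice is arbitrary
  but reproducible.

### Canonical map renumbering

Emitted templates renumber maps 1…k by a deterministic depth-first
traversal of the product pattern rooted at the atom with the lowest atomic
number (ties broken by canonical rank).  This makes textual equality
meaningful for templates extracted from different records of one family.

### Canonicalization and filtering

Two templates describe the same transformation when their product patterns
and their reactant patterns are graph isomorphic under node labels
(element, plus any H/charge specification) and edge labels (bond order),
ignoring map numbers.  Such pairs are merged; the representative is the
member with the **fewest bond changes** — the principle of minimum chemical
distance.  A mapping error never removes bond changes from a correctly
mapped family member, it adds spurious ones, so the minimum-change member
is the correctly mapped one.  Ties are broken by the lexicographically
smallest serialization, making the merge order-independent.  Duplicate
input reactions (identical canonical serializations) count once toward
frequency, so one duplicated erroneous record cannot pass the filter.

Templates seen **5 times or fewer** are then removed (the `min_frequency`
default; exposed as a knob because the right value plausibly depends on
dataset size).  Rare transformations are more likely extraction artefacts
of broken records than real chemistry.

## Template-guided curation

Templates are applied to each record's products in descending frequency
order.  Every embedding of the product pattern (VF2 subgraph isomorphism
with element node colours and bond-order edge colours) yields a candidate
reactant multiset: pattern bonds are cut, reactant-pattern bonds and
leaving groups attached, all unmatched product atoms carried through with
their maps.

Hydrogen counts on rewritten atoms are re-derived from a **valence table**:
every count compatible with an allowed valence of the element/charge state
is enumerated as a separate candidate (neutral sulfur allows 2 or 6 bonds,
so a one-bond sulfur yields 1-H and 5-H variants; the enumeration is capped
at 64 variants per fragment, far above anything organic chemistry
produces).  A template that explicitly specifies a hydrogen count (the
radical case) overrides the table.  The default table covers
B, C, N(±), O(±), F, Cl, Br, I, P{3,5}, S{2,6}, Si, Se and the common
monovalent/divalent metals; unknown elements fail loudly rather than guess.

A candidate is accepted when the recorded reactants form a **sub-multiset**
of the candidate (mapping-agnostic canonical keys; multiset rather than set
because multiplicities are informative and the stricter reading is safer).
The first accepted candidate of the first (most frequent) matching template
wins; within one template candidates are ordered by fewest added heavy
atoms, then canonical key — a minimal-repair rule.  Among a template's
candidates we first look for one that reproduces the record exactly
(`validated`); only if none does do we take the minimal repair
(`repaired`).  Without this preference, symmetric products (benzhydrol has
two equivalent aryl cuts) would be "repaired" into a map-permuted copy of
themselves.  Records no template matches are `removed`.

Frequency-ordering is a real trade-off: when several leaving groups serve
the same transformation (bromide vs fluoride coupling), a record missing
its fluoride reactant is restored with the *bromide* — the more frequent
template — and exact recovery fails.  The benchmark below reproduces this
effect; it is the main reason missing-reactant recovery trails the other
two repair rates on diverse data.

### Stereochemistry and by-products

Rewritten atoms lose stereo annotations.  For curated molecules whose
constitution matches an original reactant, an exact colored-graph
isomorphism transfers tetrahedral parities and double-bond cis/trans
labels back; when the molecule has automorphisms the first isomorphism
found is used, which is safe precisely because automorphic atoms are
indistinguishable.  Newly added fragments stay stereo-free — a restored
phosphite's P-chirality simply cannot be inferred from a generic template.

Optionally, leaving-group fragments are capped with hydrogens (one per
lost bond-order unit, plus charge neutralization) and appended to the
product side as electroneutral by-products, after which heavy atoms
balance exactly.  This is a bookkeeping simplification, not a mechanism
claim.

## The condensed graph of reaction

The CGR superposes both sides under the mapping: nodes are atoms keyed by
map number, edges carry `(order_before, order_after)` with 0 encoding an
absent bond, so the changed-edge set *is* the reaction-centre bond set.
Two equality notions coexist and are deliberately distinct:

* `cgr_equal()` — strict, map-preserving; used to decide whether curation
  changed the mapping of a given record (both sides share the same product,
  so map keys align);
* `cgr_isomorphic()` — identity of the transformation up to renaming of
  map numbers, via colored graph isomorphism on the full superposition
  graph (including unmapped side-only atoms).  Benchmark scoring of
  map-swap repairs uses this notion: a curated record's maps are derived
  from its (relabelled) product and can never be literally identical to
  the pristine ones, but the transformation they describe can be.

## The synthetic benchmark: its stated world

The fixture generator emulates three single-step families with distinct
templates — aryl-halide carbonyl addition, Williamson-type etherification,
amide formation from an acyl halide — with substituent pools (para
substituents, alkyl chain lengths 1–5) giving ≥ 25 distinct members per
(family, leaving group).  Reactions are built with correct maps by
construction.  A second configuration with two leaving groups per family
(Br favoured 0.65/0.35) creates competing templates.

Noise injection corrupts `floor(ratio · n)` records (benchmark ratios:
9–60%; 15% is the desk-scale default), one error each, drawn uniformly by
default:

* **missing reactant** — one reactant molecule deleted uniformly;
* **structural modification** — one of four product edits uniformly at a
  uniformly chosen valid site: add C or O at an H-bearing atom by a single
  bond (the minimal always-valid edit), or substitute a C by O or N where
  valences permit;
* **map swap** — transpose two product map numbers, guarded so the swap
  changes the transformation itself (`cgr_isomorphic` to the pristine CGR
  must fail): swapping symmetry-equivalent atoms would be a chemical
  no-op and poison the labels.  We do not restrict swaps to centre atoms;
  real mappers err near centres more often, but any CGR-changing swap is a
  genuine error.

Scoring: missing-reactant success = curated reactant multiset equals the
pristine one (mapping-agnostic); structural detection = record removed;
map curation = curated CGR isomorphic to pristine CGR; residual proportion
= surviving records / total.

What a green benchmark does and does not establish: the generator produces
clean single-product, fully mapped reactions with a handful of
transformations, so near-100% recovery there demonstrates the machinery is
sound, not that a real patent- or registry-derived dataset would be
recovered at those rates — real data adds mapper noise, multi-step
entries, exotic valences and dozens of competing leaving groups, which is
why exact missing-reactant recovery is expected to trail structural
detection and map curation substantially on such data (the
competing-leaving-group fixture reproduces the mechanism).

## Numerical and design choices

* **Canonical ranking** is Morgan-style iterative refinement of
  (element, charge, H count, aromaticity, degree, incident bond orders),
  with residual ties broken by promoting the lowest-index member of the
  lowest tied class.  Refinement-tied atoms in molecules of this size are
  symmetry-equivalent in practice, so the choice does not affect the
  string; pathological regular graphs where this fails do not occur in
  reaction data of this kind.
* **Hydrogens are implicit**; explicit-H atoms fold into counts at parse
  (free H₂ survives as its own molecule and is then a spectator by the
  no-heavy-atom-contribution rule).  Isotope labels are stripped on ingest.
* **Agents above the arrow** are kept as spectators and never merged into
  reactants; whether the original protocol merged them is unknowable from
  the outside, and keeping them separate is reversible
  (`reinstate_spectators()`).
* **Determinism**: template order (frequency desc, then string), candidate
  order (added heavy atoms, then key), BFS tie-breaks and fixed seeds make
  the whole pipeline reproducible byte-for-byte.
* **Validated vs repaired**: records whose best candidate equals the
  original exactly are `validated` and passed through untouched.
* Reactions whose product contains an element absent from the reactants
  (a C where the reactants have O at the mapped position) extract a
  template like any other, but no surviving library template matches them,
  so they are removed downstream — which is the desired outcome.

## Limitations

* Multi-step entries are out of scope: a record combining two consecutive
  single-step transformations matches no single-step template and is
  removed, not decomposed.
* Rare but valid chemistry below the frequency threshold is pruned along
  with the noise; the threshold is a blunt instrument.
* Aromaticity is taken from the input notation (lowercase/bond symbols),
  not re-perceived; kekulized input and aromatic input of the same molecule
  get different keys.  Use one convention per dataset.
* The mapping corrected by curation is the template's mapping; atoms
  outside the template (carried through) keep whatever maps the record had.
* Stereo transfer requires an exact constitution match; molecules altered
  at their stereocentre's neighbourhood lose the annotation with a warning.
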