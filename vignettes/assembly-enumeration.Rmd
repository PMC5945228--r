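---
title: "Enumerating and scoring quaternary assemblies from crystal lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating and scoring quaternary assemblies from crystal lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qslattice)
```

## The problem

An X-ray crystal structure embeds the biologically functional oligomer in a
lattice full of incidental crystal contacts; roughly one contact in six is
biologically relevant. Deciding which contacts constitute the biological
assembly is not a per-interface question: the engaged interfaces must
jointly tile the lattice into consistent, symmetric, finite complexes.
`qslattice` makes that global decision. It represents the crystal as a
periodic lattice graph, enumerates every *topologically valid* assembly
under four formal rules, and ranks the candidates with a probabilistic
score derived from per-interface evolutionary and geometric indicators.

## The lattice graph

Nodes are the chain copies of one unit cell, labelled `chain_operator`
(e.g. `A_1`; the identity is always operator 1). Edges are pairwise
interfaces, labelled by an interface-type id and by an integer translation
vector — the difference in Miller indices between the two participating
chains. The finite multigraph therefore encodes the infinite crystal:
edges with non-zero translations reach into neighbouring cells, and a
self-loop on `A_1` with translation `(1,0,0)` is a chain touching its own
lattice translate. Interface *types* are equivalence classes of contacts:
two interfaces of the same unordered entity pair belong to one type when
their entity-level residue–residue contact sets overlap (Jaccard at least
`sim_cutoff`, single linkage). Same-entity contacts whose contact sets are
nearly symmetric under transposition (both partners using the same face)
are *isologous* — the face-to-face association across a 2-fold axis;
face-to-back contacts are *heterologous* and can only close through cyclic
symmetry.

## The four rules

A *superassembly* is a choice of engaged interface types; its assemblies
are the connected components of the engaged subgraph.

1. **Full coverage** — every chain belongs to exactly one assembly
   (automatic, components partition the nodes).
2. **Uniform composition** — all instances of a type are engaged together
   (by construction, engagement is per type).
3. **Isomorphism** — assemblies sharing an entity must be isomorphic as
   entity/type-labelled graphs. This outlaws lattices in which a dimer
   exists in some places and a monomer of the same protein elsewhere:
   a complex that is stable in solution cannot occur in only part of the
   lattice. Assemblies with orthogonal stoichiometries (no shared entity)
   are exempt, which permits true co-crystals.
4. **Closed symmetry** — no combination of engaged interface operators may
   produce a non-zero pure translation. Operationally: every cycle of the
   engaged subgraph (Paton fundamental cycle basis, self-loops counting as
   length-1 cycles) must have zero net translation. A violating cycle is
   an infinite fiber, which crystallises only in pathological cases.

Rule 4 failures are *monotone*: adding more engaged types cannot cancel a
translation-carrying cycle, so any failing subset prunes its entire
power-set subtree. The isomorphism rule is not monotone in general, so it
is evaluated per subset and never prunes; equality with an unpruned brute
force over all subsets is asserted in the test suite on hundreds of random
graphs. The all-monomer superassembly (nothing engaged) is always valid.

Two consequences of the rules are worth stating. Valid assemblies are
point-group symmetric (cyclic, dihedral, tetrahedral, octahedral or
icosahedral), and heteromeric assemblies of a *crystal* have equal copy
numbers of their entities. The second consequence relies on chirality:
on an abstract lattice graph, unconstrained by geometry, a 2:1
pseudosymmetric component can satisfy all four rules. The package accepts
such graphs (they model the documented exceptions — pseudosymmetry,
uneven heteromers) and the point-group classifier labels them `"none"`.

## Interface scoring

Each interface is measured by its buried surface area,
`BSA = ASA(A) + ASA(B) − ASA(AB)`, with accessible surface areas computed
by the Shrake–Rupley method (probe 1.4 Å, 960 points per atom on a
deterministic golden-section spiral, so areas and interface ids are
bit-reproducible without any RNG). Interface residues bury area; those
with burial fraction `bsa/asa ≥ 0.95` form the interface *core*.

Two indicators feed the classifier:

* **gm** — the geometry score, the number of core residues over both
  sides. Large, tightly packed cores indicate biological interfaces.
* **cs** — the core–surface score. Sequence entropy is computed per
  alignment column over a 6-class reduced amino-acid alphabet
  (`{ACILMV} {DE} {FHWY} {GP} {KR} {NQST}`, natural log, gaps excluded).
  `cs` is a Z-score of the mean core entropy against a null distribution
  built by sampling the same number of residues from the protein surface
  10,000 times (without replacement within a draw, seeded). Conserved
  cores give strongly negative `cs`.

The probability that an interface is biologically relevant is the trained
logistic model

$$p(gm, cs) = \frac{1}{1 + e^{-(-3.9 + 0.31\,gm - 2.1\,cs)}}.$$

Per interface *type*, `p_i` is the unweighted mean of its member
interfaces. When no alignment is available the package falls back to
`cs = 0` (flagging the score `gm_only`), or accepts user-supplied
probabilities per type or per interface — the same entry point that lets
abstract lattice-graph JSON files bypass geometry entirely.

## Scoring superassemblies

Treating engagement of each type as an independent binary event,

$$P(s_1,\dots,s_n) = \prod_i \left[p_i\, I(s_i) + (1-p_i)(1-I(s_i))\right].$$

The product deliberately runs over interface *types*, not instances: an
instance-level product would bias scores towards high-order cyclic
assemblies, whose single interface type has many copies. Invalid
combinations carry zero probability, so the raw mass over valid
superassemblies can be below one; a final normalization divides by the
valid total (the raw values are also kept in the report). Superassemblies
that differ only by *induced* interfaces — interfaces whose removal leaves
the assembly connected — describe the same quaternary structure; they are
detected by comparing the multisets of assembly stoichiometries and
merged, reporting the most-engaged member with the group's summed
probability. The reported probability is the confidence that the call is
correct, not a measure of the assembly's physical stability. Exact rank-1
ties prefer the smaller assembly (for association equilibria the smaller,
more stable species is the safer call).

## Point groups

With coordinates available, the detector collects all crystal isometries
(proper space-group rotation plus an integer lattice shift) that map an
assembly's chain set onto itself entity-preservingly, each chain matching
within an RMSD tolerance of 2 Å, and classifies the rotation group by its
order and axis structure (all axes parallel gives `Cn`; order `2k` with a
`k`-fold principal axis gives `Dk`; orders 12/24/60 with maximal element
orders 3/4/5 give `T`/`O`/`I`). For abstract graph input a documented
topological heuristic is used instead: one (meta-)chain is `C1`, a single
engaged constitutive type gives a cyclic group of the chain count, several
types with an even count give a dihedral group, and uneven heteromers are
`"none"`. The heuristic cannot distinguish, e.g., `C4` from `D2` for a
tetramer built from two types without geometry; reports from graph input
should be read accordingly.

## Entity contraction

Heteromers are reduced to homomeric graphs by greedily contracting the
inter-entity interface type with the highest probability (tie-break:
largest mean area). A type is only contracted when its solo engagement
passes rules 3 and 4; the contracted meta-nodes absorb the internal cell
offsets, and remaining edge translations are adjusted by the offset
difference of their endpoints, which preserves every validity verdict and
the relative scores. The contraction-based enumerator branches exactly —
either the greedy type is engaged (contract and recurse) or it is not
(delete it and recurse) — so its output provably equals direct
enumeration; the suite asserts this equality on random three-entity
fixtures.

## Synthetic fixtures

All tests run on deterministic synthetic data. The canned lattice graphs
reproduce each topological regime the method must distinguish: a
crystallographic C2 dimer; an infinite fiber, built both as a bare
translation self-contact and as the deceptive "capped" arrangement in
which the asymmetric-unit dimer looks like an isolated block yet uniform
composition chains its instances into a fiber; a lattice whose C2 dimer is
not isomorphic throughout the crystal (dimer plus leftover monomer); a D3
hexamer with an induced interface type; and an A–B heterodimer for
contraction. Their geometric twins are minimal mmCIF crystals of rigid
pseudo-atom clouds (1.9 Å spheres, one residue per atom) placed so that
the end-to-end pipeline reproduces the abstract graph exactly. Random
graph fixtures (seeded, byte-reproducible) drive the oracle comparisons:
unpruned brute force for the enumeration, an independent supercell-growth
expansion for rule 4, and igraph's VF2 on a simple-graph encoding for the
labelled isomorphism. What the fixtures do not emulate — real side-chain
packing, solvation, crystallographic disorder, weak micro-contacts at
scale — limits what passing tests show about real crystals: they validate
the topology engine and the scoring algebra, not the empirical accuracy of
the logistic classifier, whose coefficients are taken as published.

## Numerical choices and degenerate inputs

* Interfaces burying less than 35 Å² are dropped as micro-contacts before
  graph construction (noise for topology; configurable).
* Edge orientation is canonical — the lower `(chain, operator)` endpoint
  is the source, self-loop translations have a positive leading
  component — and reversing an edge negates its translation.
* The clustering threshold (Jaccard 0.3), isologous transpose threshold
  (0.8), core burial cutoff (0.95) and surface relative-ASA cutoff (5%,
  against the residue extracted in isolation) are configuration values
  with these defaults.
* Entropy uses the natural log; the base only rescales `cs` jointly with
  the trained coefficients, so it must not be changed independently of
  them.
* A Z-score null with zero spread (constant entropies) is flagged
  `degenerate` and scored `cs = 0`; an empty core or an undersized surface
  pool is flagged `unscorable`.
* Ties in interface numbering (equal areas) break lexicographically by
  chain, operator and shift; ties in the rank-1 probability prefer the
  smaller assembly.
* The enumeration guard refuses more than 32 interface types; real
  lattices stay far below after the area floor, and heteromers contract
  first.
* Problem sizes in the suite: random-graph oracles run at up to 6
  interface types and 4 chains (200 graphs for the brute-force equality,
  50 for the rule-4 oracle, 20 for contraction), which keeps the full
  suite under a minute while exercising every rule path.

## Known limitations

* The four rules are enforced strictly; genuinely asymmetric biological
  assemblies (pseudosymmetric heteromers, filaments) are rejected by
  design and will be reported as smaller valid assemblies.
* MSAs are consumed, not built: homolog search and redundancy filtering
  are the caller's responsibility, and without an alignment the score
  degrades to the geometry indicator alone.
* The mmCIF/PDB reader covers the records this method needs (cell,
  symmetry, entities, heavy-atom sites) for standard dialects; it is not
  a general-purpose crystallographic parser.
* Point-group labels from abstract graphs are heuristic (see above).
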