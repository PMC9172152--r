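---
title: "chemkit: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemkit: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemkit)
```

This vignette documents the chemistry model the package implements, the
numerical and algorithmic choices that were genuinely open, and what the
test battery does and does not demonstrate.

## The molecular graph and its electron model

A `Structure` is a graph of atoms and bonds with stable 0-based integer
indices assigned in SMILES reading order and never reused after deletion.
Hydrogens are explicit nodes once parsing completes; drawing, matching and
fingerprinting ignore them on demand. Each atom carries formal charge,
tetrahedral chirality (`@`/`@@` interpreted against the SMILES neighbour
order, stored as `chiral_order`), and an electron-shell table.

Valency is assigned per atom as the smallest tabulated valency that is at
least the bond-order sum plus explicit hydrogens (sulphur 2/4/6,
phosphorus 3/5, carbon 4, and so on, shifted by formal charge for the
common organic ions). The shell table then distributes the valence
electrons: lone pairs occupy the lowest orbitals pairwise and one electron
per bond is promoted into a singly occupied orbital, expanding into d
orbitals for third-period elements. This is where chemistry validation
bites: a neutral nitrogen written with five bonds needs five singly
occupied orbitals but has only four (2s + three 2p), so the structure is
rejected — unless it is a nitro group, in which case one N=O double bond
is reinterpreted as single with O⁻/N⁺ charges and the valency becomes 4.
Hybridisation is the steric number (σ neighbours + lone pairs) mapped to
s/sp/sp2/sp3/sp3d/sp3d2.

**Aromatic bond orders.** A lowercase SMILES atom's bonds contribute a
non-integer 1.5 each to its bond-order sum. We resolve the sum per atom:
if the count of aromatic bonds (as order 1 each, plus other bonds and
explicit hydrogens) already equals an allowed valency, the atom is a
lone-pair donor and contributes no π bond (pyrrole N–H, furan O,
thiophene S); otherwise one π bond is added (benzene carbons, pyridine N,
ring-fusion carbons). This reproduces "1.5 rounded up" for the common
two-bond aromatic carbon while giving fusion carbons 4 rather than
ceil(4.5) = 5 and leaving heteroatom donors at their true valency.

## Rings, aromaticity, kekulisation

All elementary cycles are enumerated with a rooted depth-first search in
Johnson's style (each cycle found exactly once after orientation
deduplication); cycles shorter than three atoms cannot occur in a simple
graph. A guard (default 10⁶ cycles, `options(chemkit.cycle_limit = ...)`)
rejects fullerene-like inputs whose cycle count explodes. The SSSR is a
minimum cycle basis: candidates sorted by size, ties broken toward the
lexicographically smallest sorted atom-index tuple (pure determinism — any
tie-break yields a valid basis), added greedily under GF(2) independence
in bond space until the cyclomatic number of rings is collected.

Aromaticity is evaluated per SSSR ring, recursively, with Hückel's 4n+2
rule in its odd-count form: a ring whose atoms are all sp2 — or sp3 with a
delocalisable lone pair — is aromatic when (double bonds + contributed
lone pairs) is odd. The hybridisation screen doubles as the planarity
criterion; no geometric test is applied. "Locally kekulised" counting is
implemented as: existing in-ring double bonds are counted as-is, then
free sp2 atoms (no π bond yet, spare valency) along the ring are paired by
a greedy alternation that starts just after a non-free atom when one
exists. At most one lone pair per atom counts; exocyclic double bonds
contribute nothing. Rings that become evaluable only after a neighbour
ring was aromatised are caught by iterating to a fixed point (at most
|SSSR| rounds, since each round either marks a new ring or stops).
Aromatic cycles sharing a bond merge into aromatic systems holding the
pooled π electrons (1 per double-bond atom, 2 per lone-pair donor).

Kekulisation runs Edmonds' blossom maximum matching over each system's
1-electron contributors; matched bonds become double, the rest single.
Donors stay unmatched by construction. A system whose contributors admit
no perfect matching is not chemically realisable and raises an error (this
is how `c1ccc1` is rejected).

## 2D depiction

Coordinates are in bond-length units (1.0 = one bond) on mathematical
axes (y up); the SVG back end flips y at serialisation and scales to 50 px
per bond with font ≈ 0.42 and line width ≈ 0.06 of a bond length, so the
ratios are constant across drawings of any size.

Ring systems are placed as rigid units. Simple and overlapping systems
compose regular polygons: a fused ring is reflected across the shared
edge, a spiro ring placed on the far side of the shared atom. Bridged
systems (rings sharing more than two atoms, atoms in three or more rings,
or touching another bridged ring) start on a circle and are refined by
Kamada–Kawai as implemented in igraph — we deliberately reuse the
established force-spring implementation rather than writing a second
one — then rigidly rotated so the system's centroid points away from its
attachment atom. Chains continue at one bond length with 120° zigzag
angles; four-neighbour atoms use 90°, except the case of exactly two
depth-1 branches, which get the 120/90/60 arrangement with the two longest
branches (measured as longest-path depth; subtree size was the considered
alternative) placed opposite. Declared cis/trans configurations are
enforced from the bond objects by mirroring the far side's freshly placed
children when needed; wrongly depicted ring stereobonds are fixed by
mirroring the reference neighbour with the smallest protruding side chain
(heavy-atom subtree count), each bond's neighbour moved at most once, and
a `ChiralityError` is raised when no depiction exists.

Clashes are pairs of non-bonded drawn atoms closer than 0.5 × the mean
bond length (strict less-than). Finetuning finds, per clash, the rotatable
bond nearest the centre of the shortest path between the clashing atoms —
bonds in cycles, stereo-restricted double bonds and their immediate
neighbours are unrotatable — and evaluates all 12 rotations at 30°
increments of the smaller side, keeping the clash-minimising angle with
ties broken toward the smallest rotation. Because 0° is always a
candidate, the clash count cannot increase.

Wedges: each chiral centre receives one wedge bond, preferring bonds whose
far atom neighbours at most one chiral centre, then acyclic bonds, then
the shortest branch. The up/down direction is derived from a signed
volume: in-plane neighbours at z = 0, the wedge neighbour at z = ±1, and —
the one subtle convention — an undrawn implicit hydrogen at the z opposite
the wedge, which is exactly how a MOL V2000 reader reconstructs the
centre, keeping the SVG and the MOL file telling the same story. Hydrogens
are suppressed in drawings and MOL output; heteroatom hydrogen counts are
folded into the atom label (e.g. "NH", "OH").

## Substructure matching

Hydrogens are ignored throughout. Two screens run before any embedding:
the element-count screen and a per-atom local-environment screen requiring
each query atom's (bond type, neighbour element) multiset to be contained
in some candidate's. The depth-first embedding is seeded at the query atom
with the fewest candidates in the parent — the concrete reading we chose
for "most diverse connectivity", with ties to the lowest index — and
extends along query adjacency, so each new atom is constrained by a mapped
neighbour. Matches are collapsed to one per matched atom set
(symmetry-equivalent embeddings are not repeated; `all_mappings = TRUE`
returns them all). Tetrahedral checks map the query's neighbour order into
the parent and compare permutation parity, with at most one phantom slot
(the query's hydrogen) filled by the parent's uncovered neighbour;
ambiguous phantom arrangements cannot contradict and pass. Defined query
stereo requires defined parent stereo; undefined query stereo matches
anything.

## Fingerprints

Identifiers are murmur32 digests of canonical strings — a fixed,
platform-independent 32-bit hash, never R's internal hashing. The initial
invariant covers heavy-neighbour count, valence, atomic number, standard
atomic weight (2 decimals; isotopes are deliberately not distinguished,
so "weight" is a per-element constant — the one place where the model and
an isotope-aware reading of atomic weight are in tension), charge,
hydrogen count and ring membership. Each iteration rehashes an atom with
its sorted (bond-order tag, neighbour identifier) pairs. We use the bond
order as the neighbour tag: the other candidate reading, a graph distance
measured from the current iteration's centre, is constantly 1 for direct
neighbours and carries no information. Chiral centres contribute a
spelling-invariant tag — the @/@@ flag re-expressed against the neighbour
order sorted by current identifiers — so two SMILES spellings of one
molecule hash identically while enantiomers differ. Deduplication removes
repeated identifiers and aliases spanning the same atom set (keeping the
smaller radius, then the smaller identifier). Bit vectors set bit
`id mod length` (default 1024) and carry a legend mapping each set bit to
a representative environment rendered as a SMILES-like fragment.

## Reactions

Edits default to `cap = "H"`: hydrogens fill the valences the edit opened,
and the structure is refreshed (revalidated) immediately; `cap = "none"`
defers both so multi-step reactions can stage intermediate states, which
is how the built-in ketoreduction works (π electrons removed, bond set
single, hybridisations updated, one H added to each of C and O, one
refresh). Hydrolysis attaches the hydroxyl to the acyl side — the end of
the bond carrying a doubly bonded oxygen — and the hydrogen to the leaving
side; condensation is its inverse and re-indexes the second structure's
atoms after the first's. The ketoreduction leaves the new alcohol's
configuration undefined (the enzyme-specific stereo outcome is outside the
model; a `stereo` parameter reserves the hook).

## The molecule generator

`generate_test_smiles` assembles random molecular graphs — not strings —
and writes them with the package's own writer, so everything it emits
parses by construction. The backbone is a random tree over {C 7/11, N
1/11, O 2/11, S 1/11} with occasional double bonds; feature motifs add an
extra ring-closing bond (ring sizes 3–7), a fused benzene or pyridine, a
charged group (O⁻ or N⁺), a halogenated stereocentre (CHFCl with random
@/@@), or a stereo-restricted double bond with random cis/trans. Defaults
(10 molecules, 4–12 heavy atoms, all features on) reflect the small
drug-like molecules the kit's own worked examples use; each enabled
feature is forced into at least one molecule per batch. What the generator
emulates is syntactic and chemical variety — rings, aromatics, charges,
both stereo kinds — under guaranteed validity; what it does not emulate is
the distribution of real natural products (macrocycles, dense ring
fusion, peptidic repeats), so green round-trip and drawing tests
demonstrate correctness of the machinery, not readability of vancomycin.

## Problem sizes and tolerances in the test battery

The suite round-trips 1000 generated molecules plus a 50-entry curated
set (verified against RDKit's isomeric canonical SMILES, mirroring the
MOL-file check that uses RDKit as the independent reader); compares ring
perception with a subset-enumeration oracle on 200 random graphs of 6–14
nodes (full minimum-basis comparison at ≤ 11 nodes, where the oracle is
exhaustive yet fast); checks kekulisation against brute-force maximum
matching; checks the substructure matcher against exhaustive embedding
enumeration on pairs of up to 12 heavy atoms; and asserts finetuning
monotonicity on 500 generated drawings. These sizes keep the whole suite
under a few minutes on one core while exercising every code path; they
are choices of the package, not limits of the algorithms.

## Known limitations

No SMARTS, reaction SMILES, atom mapping, canonical-SMILES guarantee,
isotopes, radicals, 3D geometry, or aromatic (non-kekulised) depiction.
Macrocycles are drawn as regular polygons, not honeycombs, which favours
seeing cyclisation sites over mimicking 3D architecture. Cycle
enumeration is exponential on cage molecules; the guard turns that into a
clear error. Hypervalent chlorine/bromine/iodine are accepted (valencies
1/3/5/7) but rarely exercised.
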