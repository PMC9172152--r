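# chemkit

A dependency-light cheminformatics kit for R, aimed at bio- and
cheminformaticians who need basic chemical processing — reading SMILES,
drawing a molecule, highlighting a substructure, fingerprint similarity,
simple in-silico reactions — without pulling in a heavyweight toolkit.
It is written with natural-product chemistry in mind: large, heavily
cyclised, stereochemistry-rich molecules.

Everything is built on one data structure: a molecular graph whose nodes
are atoms (with formal charge, tetrahedral chirality, electron shells)
and whose edges are bonds (single/double/triple/quadruple/aromatic, with
cis/trans marks on double bonds). Parsing a SMILES string validates the
chemistry down to the electron level — an atom whose bonds cannot be
satisfied by any achievable valency raises a `StructureError` rather than
producing a silently wrong molecule.

## What it does

* **SMILES reading and writing** (`parse_smiles`, `write_smiles`).
  Valencies are selected as the smallest achievable value that covers the
  bond-order sum (S: 2/4/6, P: 3/5, ...); implicit hydrogens are
  materialised as graph atoms; the nitro-group tolerance rewrites
  pentavalent nitrogen `N(=O)=O` as `[N+]([O-])=O`. Output is kekulised
  and preserves charge, chirality (`@`/`@@`) and cis/trans marks.
* **Ring perception and aromaticity** (`find_sssr`, `detect_aromaticity`).
  All elementary cycles (Johnson-style enumeration), a minimum cycle
  basis (SSSR), then recursive per-ring evaluation of Hückel's 4n+2 rule:
  a planar ring is aromatic when its double bonds plus delocalisable lone
  pairs sum to an odd count. Fused aromatic rings pool their π electrons
  in aromatic systems.
* **Kekulisation** (`kekulise`) by Edmonds' blossom maximum matching over
  each aromatic system's π-contributing atoms.
* **2D structure diagrams** (`layout_molecule`, `render`,
  `write_molfile`). Regular-polygon geometry for simple and overlapping
  (fused/spiro) rings, Kamada–Kawai force-spring refinement for bridged
  ring systems, 120°/90°/60° chain angles by branch depth, declared
  cis/trans geometry enforced, stereo wedges placed by priority rules, and
  a clash-resolution "finetuning" step that rotates acyclic bonds in 30°
  increments. Output: SVG, PNG, MDL MOL V2000.
* **Substructure matching** (`find_substructure_matches`,
  `highlight_substructure`): element-count and local-environment
  pre-filters, seeded depth-first embedding, then tetrahedral and
  cis/trans stereo checks (each independently toggleable). Matches can be
  highlighted in any colour (hex codes or names).
* **ECFP fingerprints** (`ecfp`, `tanimoto`, `to_bit_vectors`): iterated
  32-bit atom-environment hashes (default radius 2 = ECFP-4) with a
  chirality-aware, spelling-invariant update; Tanimoto/Jaccard similarity
  `|A∩B|/|A∪B|`; foldable bit vectors (default length 1024) with a
  substructure legend.
* **Reactions** (`target_definition`, `find_targets`, `break_bond`,
  `make_bond`, `add_atom`, `remove_atom`, `split_disconnected`,
  `hydrolyse`, `condense`, `ketoreduce`): reaction targets are defined as
  a substructure SMILES plus atom indices (`target_definition("C(=O)NC",
  0, 2)` is a peptide bond); every edit is revalidated against the
  valence model.
* **A seeded molecule generator** (`generate_test_smiles`) and a CLI
  (`system.file("cli", "chemkit", package = "chemkit")`) with `draw`,
  `molfile`, `search`, `fingerprint`, `similarity`, `react`, `roundtrip`
  and `generate` subcommands.

## Worked example

```r
library(chemkit)

aspirin <- parse_smiles("CC(=O)Oc1ccccc1C(=O)O")
aspirin
#> <chemkit structure: 21 atoms (13 heavy), 21 bonds>
length(aspirin$rings$sssr)                      # 1 ring in the SSSR
aspirin$aromatic_systems[[1]]$pi_electrons      # 6 pi electrons (aromatic)
write_smiles(aspirin)
#> [1] "CC(=O)OC1=CC=CC=C1C(=O)O"

salicylate <- parse_smiles("O=C(O)c1ccccc1O")
tanimoto(ecfp(aspirin), ecfp(salicylate))
#> [1] 0.4666667

ester <- target_definition("C(=O)OC", 0, 2, name = "ester bond")
hits <- find_targets(ester, aspirin)            # exactly 1 ester bond
products <- hydrolyse(aspirin, hits[[1]])
sapply(products, write_smiles)
#> [1] "CC(=O)O"              "OC1=CC=CC=C1C(=O)O"

d <- draw_molecule(aspirin, "aspirin.svg")      # clash-free 2D depiction
nrow(detect_clashes(d))
#> [1] 0
```

The hydrolysis splits aspirin into acetic acid and salicylic acid, both
revalidated against the valence model; the Tanimoto similarity of 0.467
reflects the shared salicylate scaffold.

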