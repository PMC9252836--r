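# rnatangle

Detection and classification of **entanglements of structural elements in
RNA 3D structures**.

Large RNA structures — determined experimentally or predicted *in silico* —
can contain arrangements in which one structural element threads through
the surface spanned on another. Because base pairing defines the closed
boundary, these arrangements are distinct from topological knots of the
backbone alone. Some of them are genuine functional motifs: in viral
exoribonuclease-resistant RNAs (xrRNAs) and in the SARS-CoV-2 frameshifting
element, the 5′ end of the chain threads a ring closed by pseudoknotted
base pairs (a *knot-like fold*). Others — a strand piercing the middle of a
helix, or two loops linked like chain links — are almost always artifacts
of 3D-structure prediction or reconstruction, and screening for them is a
cheap way to eliminate non-physical models.

`rnatangle` is for structural bioinformaticians who want that screen as a
reproducible, scriptable tool: it reads a PDB or PDBx/mmCIF file, derives
the secondary structure geometrically, partitions the molecule into
elements, and reports every entanglement with its class, the elements
involved, and the exact puncture sites.

## The method

1. **Cleaning.** Non-RNA chains, surplus atoms of modified residues, and
   incomplete nucleotides are removed (each removal is logged).
2. **Secondary structure.** Canonical pairs (A-U, G-C, G-U wobble) are
   detected from geometry: C1′–C1′ distance in [8.5, 12] Å, hydrogen-bond
   donor/acceptor ring atoms within 3.5 Å (+1 Å tolerance), base planes
   within 65°. Pseudoknot *orders* are assigned by iteratively extracting
   maximum-cardinality non-crossing subsets: order 0 is the core, order
   k ≥ 1 the k-th pseudoknot layer. The result is rendered in extended
   dot-bracket notation (`()`, `[]`, `{}`, `<>`, `Aa`…).
3. **Elements.** At each level k, only order-k pairs count as paired.
   Closed elements are **loops (L)** — cycles closed by pairs — and
   **dinucleotide steps (D)** — quadrilaterals bounded by two adjacent
   stacked pairs. Open elements are **single strands (S)**: maximal
   unpaired runs not enclosed by any order-k pair.
4. **Geometry.** Every element gets a polygonal chain through its P and
   C4′ atoms; closed boundaries are bridged at each closing pair by the
   base centers of mass, and the resulting ring is covered with a triangle
   mesh (centroid fan + recursive longest-edge refinement). Punctures are
   found with the Möller–Trumbore segment–triangle test.
5. **Classification.** For an element pair at one level, punctures in one
   direction only make a **lasso** `X(Y)`; punctures both ways make an
   **interlace** `X&Y`. Extra punctures append dots: `L(S..)` is a loop
   whose surface a single strand crosses three times. Level 0 gives
   *primary* entanglements; levels k ≥ 1 give *higher-order* ones.

## Worked example

The package generates its own test structures with provable ground truth.
The `knotlike_pseudoknot` fixture is a synthetic stand-in for an xrRNA-like
knot-like fold: a core helix is crossed by two pseudoknotted pairs whose
ring is threaded by the 5′ end:

```r
library(rnatangle)
fx <- rna_fixture("knotlike_pseudoknot")
sc <- entanglement_scan(fx$model)
print(sc)
#> Entanglement scan of synthetic:knotlike_pseudoknot (model 1)
#>   60 residues, 5 canonical pairs, max pseudoknot order 1
#>   levels analyzed: 0, 1
#>   1 entanglement(s):
#>     [1] level 1 lasso L(S): L G33-C49 punctured by S G1-G31 (1 puncture)
```

The loop closed by the first-order pair G33-C49 is lassoed over the
5′-end single strand G1-G31; the puncture falls on the chain segment
between the C4′ atom of residue 2 and the P atom of residue 3. With
`pseudoknots = "ignore"` the same structure reports no entanglement —
knot-like folds are visible only when pseudoknots are accepted (the
default). The secondary structure shows the order-1 layer in square
brackets:

```r
cat(to_extended_dotbracket(sc$secondary))
#> >A
#> GAAAAAAAAAAAAAAAAAAAAAAAAAAAAAGGGAAAGGGAAAAAAAAACCAAAACCCAAA
#> ...............................[[...(((.........]]....)))...
```

`summary(sc)` tabulates counts per class split into primary and
higher-order rows; `plot(sc)` draws an arc diagram with entangled elements
marked. Real structures are scanned the same way:
`entanglement_scan("structure.cif")`.

A command-line front end for batch screening lives in
`inst/scripts/rnaentangle.R`:

```sh
Rscript inst/scripts/rnaentangle.R run model1.pdb model2.cif --out results/
```

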