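---
title: "Detecting entanglements of structural elements in RNA 3D structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting entanglements of structural elements in RNA 3D structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatangle)
```

## The problem

An *entanglement* is an arrangement in which the polygonal chain of one
RNA structural element punctures the surface spanned on the boundary of
another, *closed* element. Unlike a backbone knot, the closed boundary is
defined by base pairing: a **loop (L)** is a cycle closed by canonical
pairs, a **dinucleotide step (D)** is the quadrilateral bounded by two
adjacent stacked pairs, and a **single strand (S)** is a coherent
unpaired fragment (a dangling end or an exterior linker). Two topologies
are distinguished: in a **lasso**, coded `X(Y)`, one element only
punctures and the other is only punctured; in an **interlace**, coded
`X&Y`, both puncture each other. Extra punctures beyond the first are
appended as dots — `L(S..)` is a loop whose surface a single strand
crosses three times. Since a single strand spans no surface, codes of the
form `S(...)` cannot occur.

Knot-like folds of viral xrRNAs and of the coronavirus frameshifting
element are, in this classification, *higher-order* `L(S)` lassos: the
punctured ring is closed by pseudoknotted pair(s), and the 5′ end threads
it. Interlaces and lassos such as `D(S)` — a strand piercing the middle
of a helix — are instead strong indicators of a non-physical model.

## Pipeline

### Cleaning

`clean_rna_structure()` keeps a chain when more than half of its residues
are standard ribonucleotides, mapped modified ribonucleotides, or carry an
O2′ atom; this tolerates heavily modified chains while rejecting DNA and
protein. Within kept chains, non-nucleotide residues (waters, ions) are
dropped; mapped modified residues lose atoms absent from the parent
ribonucleotide template ("surplus atoms"); residues missing C4′, the
glycosidic base nitrogen, or a non-terminal P are removed as incomplete.
Alternate locations are resolved on read to the highest-occupancy
conformer (ties: first label alphabetically) — a deliberate choice that
makes the geometry single-valued, recorded in the cleaning report because
entanglements can also arise from genuine alternative conformations.
Hydrogens are dropped; no downstream stage uses them.

### Canonical pairs and pseudoknot orders

The pair detector is geometric, with three gates (all tunable via
`pairing_params()`): C1′–C1′ distance in [8.5, 12.0] Å; hydrogen-bond
donor/acceptor ring-atom distance (purine N1 to pyrimidine N3 for
Watson–Crick pairs, the two wobble contacts for G-U) at most 3.5 Å with
1.0 Å tolerance; angle between base-plane normals (from an SVD of the
ring atoms) at most 65°. These values reproduce canonical pairing
exactly on ideal geometry and are conventional mid-range choices for
experimental structures. When one residue passes the gates with two
partners, the smaller hydrogen-bond distance wins, deterministically.

Pseudoknot orders follow the minimal-layering idea: order 0 is a
maximum-cardinality non-crossing subset of the pairs (dynamic programming
over endpoint intervals; ties broken toward the pair with the smaller 5′
index, then the smaller 3′ index), and each order k ≥ 1 is the maximum
non-crossing subset of what remains. Exact agreement with any particular
published order-assignment heuristic is *not* promised — where several
maximum subsets exist, the tie-break decides — but maximality of the
extracted layer is enforced and is tested against exhaustive subset
enumeration for small inputs. The extended dot-bracket rendering uses one
alphabet per order: `()`, `[]`, `{}`, `<>`, then `Aa`, `Bb`, ….

### Elements, level by level

The analysis runs separately for each level k (0 up to the maximum order,
capped by `order_cap`, or level 0 only when `pseudoknots = "ignore"`). At
level k *only* order-k pairs count as paired; every other residue is
treated as unpaired, so core residues can end up embedded inside a
higher-order loop and vice versa. Loops are cycles closed by order-k
pairs — hairpin, internal, and multibranch loops all report simply as L,
since the classification uses only the L/S/D vocabulary. Every two
adjacent stacked pairs (i,j), (i+1,j−1) form one D step (a helix of n
pairs yields n−1 overlapping steps); strict adjacency is required, so a
step never spans a bulge. Single strands are maximal unpaired runs not
enclosed by any order-k pair, split at chain boundaries. Loops whose
boundary exceeds `max_loop_length` residues (default 40, which bounds
triangulation cost; the option matters mostly for loops that include
pseudoknotted pairs) are not closed elements — their interior unpaired
runs join the open set instead. Elements from different levels are never
tested against each other.

### Geometry

Polygonal chains connect, per residue in 5′→3′ order, the selected
backbone atoms (default P then C4′; P omitted at a 5′ terminus). A closed
boundary is bridged at every closing pair by the two base centers of mass
(plain centroids of the base ring atoms by default; a mass-weighted
variant is available), giving one closed ring per L or D.

Meshes are built by a centroid fan — one triangle per boundary edge, apex
at the ring centroid — followed by recursive longest-edge midpoint
subdivision until no edge exceeds `edge_target` (default 2.0 Å, capped at
8 levels). Midpoints are cached and shared, boundary edges subdivide
consistently, and the union of triangles is unchanged by refinement, so
puncture verdicts must be (and are, by test) identical at edge targets
2.0, 1.0, and 0.5 Å. Non-planar rings are meshed as-is from the fan;
rings whose points are collinear within tolerance raise a degenerate-mesh
condition and the element is skipped with a warning.

Punctures use the Möller–Trumbore segment–triangle test with a 1e-9
determinant gate and 1e-7 barycentric tolerance, segment parameter
restricted to [0, 1]. Three rules keep counts meaningful:

* **Self-exclusion** — a segment with an endpoint in a residue of the
  mesh's own element (closing pairs included) is skipped; physically
  shared backbone cannot entangle with itself.
* **Hit merging** — hits within 0.05 Å collapse to one puncture, so a
  crossing on a shared edge of adjacent triangles is counted once.
* **Overlap guard** — a crossing whose chain segment has an endpoint
  within 0.2 Å of a mesh vertex is discarded; overlapping atoms in
  defective models otherwise masquerade as punctures.

Both directions of every closed–closed element pair are tested
explicitly; one direction positive makes a lasso, both make an interlace.
Reports are per element pair (the puncture list is attached), and two
reports that share a closing pair of the punctured element and the same
partner element are merged, keeping the one with more punctures — this
deduplicates the overlap between a helix's terminal D step and the loop
it also closes.

## The synthetic generator

`rna_fixture()` builds toy structures whose ground truth is provable from
the construction itself, not from the detector: stems are ideal G-C pair
templates stacked at 4.5 Å rise (large enough that cross-rung candidates
fail the hydrogen-bond gate), loops are rings of fixed ~7 Å radius whose
sampling density is the `loop_size`, unpaired residues are adenines so no
spurious canonical candidate can exist, and threading strands are
polylines whose plane crossings inside the designed ring polygon are
counted by independent arithmetic (point-in-polygon ray casting) before
the fixture is returned — an infeasible design stops with an error.
Families cover a clean hairpin, lassos with 1–3 punctures, linked hairpin
loops (interlace), a pseudoknotted knot-like fold (one order-1 `L(S)`,
detected only when pseudoknots are accepted), and a contaminated file for
the cleaning stage. The knot-like family doubles as a synthetic stand-in
for the xrRNA fold, reproducing its named anatomy: ring closed by
G33-C49 of the first order, threading 5′ strand ending at G31, puncture
between C4′ of residue 2 and P of residue 3.

What the fixtures deliberately do **not** emulate: realistic backbone
torsions, sugar puckers, base stacking distances, crowding, or
experimental noise. Passing the fixture grid therefore demonstrates the
*geometric and combinatorial correctness* of the pipeline — pair gates on
ideal geometry, order assignment, element decomposition, mesh building,
puncture counting, classification — but not robustness to the messiness
of real coordinates. Gaussian-jitter tests (`perturb_structure()`) cover
small perturbations (verdicts are stable at 0.1 Å noise); at 5 Å the
pairing gates legitimately fail and only pipeline completion is asserted.

## Numerical and design choices

* Residue numbering in all reports is the author numbering of the source
  file; internal indices are contiguous and 0-based per chain.
* The pair-detector tie-break (smallest hydrogen-bond sum) and the
  order-assignment tie-break (smallest i, then j) make the whole pipeline
  deterministic; two runs on the same input produce byte-identical
  output, which the suite asserts.
* Interlace codes order elements L before D, then by first residue; dots
  after each symbol count that element's extra punctures (`L.&L`). A
  multi-puncture interlace never occurs in the fixture families and is an
  extension of the dot syntax chosen so codes stay machine-parsable
  (`parse_class_code()` inverts `class_code()` exactly).
* Single strands of length 1 are kept as elements but skipped for
  geometry when fewer than two chain points exist.
* The 50 MB input guard mirrors common server-side limits and is
  configurable.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline roughly
a thousand times: a fixture grid of four entangled families × loop sizes
6–20 × 20 seeds of random rigid motions (the knot-like family from size
8, where its core helix clears the linker by construction), 10⁴ random
segment–triangle oracle cases, and 60 random pair sets of up to 12 pairs
against exhaustive enumeration. These sizes keep a complete run in the
minutes range on one CPU while exercising every code path; they are
sampling density choices, not limits of the method — the pipeline itself
is O(segments × triangles) per element pair and handles full-size RNAs.

## Known limitations

* Non-canonical pairs (Leontis–Westhof families beyond Watson–Crick and
  wobble) are not detected; a loop closed only by non-canonical pairs is
  invisible to the decomposition.
* The order assignment can differ from other tools' layering when maximum
  non-crossing subsets tie; element decomposition, and hence detected
  entanglements, can shift accordingly at higher orders.
* The centroid-fan mesh of a strongly non-planar ring is one of many
  possible spanning surfaces; puncture counts through wildly warped loops
  depend on that choice. Refinement stability is verified, surface-choice
  invariance cannot be.
* Cross-level element pairs are by design not tested, so an arrangement
  entangling a core element with a pseudoknot-layer element is reported
  only as seen from whichever single level shows it.
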