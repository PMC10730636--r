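---
title: "Perceiving chemical structures from crystallographic geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceiving chemical structures from crystallographic geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifchem)
```

## The problem

A crystal structure determination yields a unit cell, a space group, and the
fractional coordinates of an asymmetric unit. Chemistry — which atoms are
bonded, with what order, where the formal charges sit — is implied by the
geometry rather than recorded. `cifchem` makes that chemistry explicit in two
stages: restoring a *stoichiometrically correct molecular ensemble* from the
crystallographic description, and assigning a chemical structure to it from
interatomic distances, angles and element identities. The result is validated
and serialized into the formats downstream cheminformatics tools consume.

## Ensemble restoration

Every atom site is imaged under every symmetry operator; images of the same
site closer than `merge_tol` (default 0.01 Å) are merged, which handles
special positions by distance rather than by symbolic site multiplicity — the
simplest rule that is exact for idealized fixtures and robust to rounded
coordinates.

Positional disorder is resolved before expansion: within each disorder
assembly exactly one group is kept, chosen by (1) highest summed occupancy,
(2) most atoms, (3) lexicographically lesser group name. Only the final
tie-break is documented behaviour of the workflow this package models; the
occupancy-first ordering is the natural extension (a majority conformer is a
better representative). Sites where different elements share one position
(within 0.5 Å) mark the entry as compositionally disordered; the entry is
flagged and kept, because silently picking one element would misstate the
composition. Partially occupied sites are retained at full weight in the
formula — over-representation is preferred to silent deletion, and the
formula-compatibility criterion downstream catches the discrepancy.

Entities are grown breadth-first over the bonding relation, following bonds
into neighbouring unit cells. If growth reconnects to an already included
image of the same unit-cell atom under a different lattice shift, the entity
is periodic — a polymer. It is truncated to one period, capped at
`max_polymer_atoms` (400, matching the reference workflow's invocation), and
rejected by perception with an explicit error, since a finite bond graph
cannot faithfully represent it.

Crystallographic independence, not chemical identity, defines distinctness:
two symmetry-equivalent copies of a molecule collapse to one representative
(multiplicities are divided by their overall greatest common divisor), while
two independent molecules with identical connectivity stay separate — they
sit in different environments and may be different conformers. Racemates are
not enumerated; the space-group number is recorded so callers can test for
non-Sohncke groups.

## The bond-length distribution classes

Bond order assignment is driven by Gaussian models of previously observed
bond lengths, keyed by (element pair, order, π-electron context of the two
atoms). The bundled table (`inst/extdata/bond_classes.tsv`) is **rebuilt from
standard reference bond lengths**, not from a database corpus: the algorithm
depends only on the table's shape and Gaussian semantics, and the table is
replaceable via `load_bond_classes()`. The π context is approximated as the
pair of atomic π-electron counts; `count` records the (here nominal) number
of underlying observations. Because the table is approximate, its σ values
are deliberately generous (0.01–0.035 Å).

The table carries no dedicated classes for delocalized (aromatic) bonds.
Kekulé-assigned ring bonds sit between the single- and double-bond means by
construction (benzene's 1.39 Å is ~4σ from both), so the 3σ bond-length
validation **skips delocalized bonds**; with dedicated aromatic classes this
exclusion would be unnecessary.

## The six assignment steps

1. **Connectivity.** Atoms are bonded when
   `d ≤ min(r_A + r_B + tolerance, max_bond_cutoff)` with Cordero-style
   covalent radii, `tolerance = 0.4` Å, and an absolute cap
   `max_bond_cutoff = 4.0` Å. The cap is expressed as an absolute length
   (rather than a multiple of a shortest plausible bond) so that legitimate
   long contacts — alkali-halide pairs near 3 Å, K–C coordination near
   3.2 Å — survive while any pathological radius sum is still bounded. A
   preflight screen aborts perception on steric clashes
   (`d < 0.5 × (r_A + r_B)`) or atoms whose neighbour count already exceeds
   their maximum valence: both guarantee a wrong structure, so the entry is
   excluded rather than misdescribed.

2. **Metal bonds.** Every bond with a metal endpoint becomes a zero-order
   coordination bond, excluded from valence and charge bookkeeping. No
   attempt is made to pick covalent orders for metals; η⁵/η⁶ hapticity falls
   out naturally because every coordinated ring atom within bonding distance
   is connected to the metal.

3. **Unambiguous orders.** A bond receives an order when exactly one
   candidate is compatible: |z| ≤ 3 against the best achievable-context
   class, free valence at both ends, and endpoint geometry admitting the
   order. Geometry gates: a 3-coordinate atom is sp²-compatible when the RMS
   out-of-plane angle of its bonds is below `planarity_gate = 10°` (15°
   pyramidalization fails the gate, 10° passes); a 2-coordinate atom is
   sp-compatible above `sp_gate = 160°`. Candidate classes are filtered by
   the π counts each endpoint could still achieve, which is what makes an
   isolated 1.22 Å C–O unambiguous (an order-1 assignment would require a π
   context the carbonyl carbon cannot reach). Bonds on rings whose atoms are
   all π-capable, sp²-compatible and valence-open are deferred to step 5's
   matching instead of being fixed greedily — a 1.43 Å cyclopentadienyl bond
   looks like a plain single bond in isolation.

4. **Functional groups.** Length-driven templates assign patterns whose
   bonds are individually ambiguous: azide (two-double vs single+triple form
   chosen by the smaller Σz², the triple on the shorter contact), the
   oxo-centre family (nitro, nitrate, carboxylate, carbonate, sulfonate,
   sulfate, phosphate: `n_doubles = v_eff(centre) − σ-count`, doubles on the
   shortest terminal chalcogen contacts, ties to the lower atom index), and
   isocyanide. Templates may override step-3 orders within the group; after
   assignment no conversion to a standard tautomer or resonance form is
   attempted — the representation follows the observed geometry.

5. **Kekulé assignment.** Each deferred ring system receives a perfect
   matching of its π subgraph (matched edges double, others single, all
   flagged delocalized). Matchings are enumerated exhaustively for systems of
   ≤ `kekule_max_system = 18` atoms; the objective is lexicographic —
   fewest introduced charges first (weight 10⁶ per unmatched atom), then
   Σz² over all ring bonds — and ties resolve toward the lowest atom index,
   so output is deterministic. Unmatched atoms take a −1 charge when the
   element admits it: a C₅ ring yields exactly one carbanion. Even rings
   normally match perfectly and stay neutral; when the later charge balance
   leaves an entity with a positive residual (e.g. two K⁺ whose only
   oxidation state is +1 around a C₈H₈ ring), the ring is re-matched with the
   required number of charge carriers, reproducing the cyclooctatetraenide
   2− convention. Without such a forcing context an even delocalized ring
   remains neutral — deciding "dianion" from geometry alone is not possible.

6. **Deviant bonds, then formal charges.** Remaining unresolved bonds
   between π-capable atoms get the best-ranked order ignoring geometry gates
   (never overriding earlier assignments). Non-metal charges follow valence
   bookkeeping over order-≥1 bonds plus attached hydrogens; zero-order bonds
   are ignored, so a carbene carbon σ-bonded only to two hydrogens and
   coordinated to a metal carries −2. Electron deficits become anions when
   the atom (a) has a zero-order bond to a metal, (b) is electronegative
   with only single bonds (halides, thiolates, alkoxides), (c) neighbours a
   positive centre (azide/isocyanide termini), or (d) is electronegative and
   shares an entity with a metal; otherwise an odd deficit sets the radical
   flag (CH₃•, NO). This precedence is a heuristic: it reproduces the
   ferrocene, carbene, halide, azide and NO cases, but a charge/radical
   ambiguity in an entity with no metal and no positive centre defaults to
   the radical reading. Metal charges then balance the summed ligand charge
   of their entity, restricted to enumerated oxidation states (the most even
   exact combination; nearest-admissible otherwise, leaving the imbalance to
   the ensemble-charge check).

## Validation

The six geometry checks flag, never fix. Expected π counts are derived from
coordination number and geometry as *sets* (a planar 3-coordinate atom may
have 0 or 1 π electron; a terminal atom is unconstrained), which avoids
false positives where geometry genuinely cannot decide. The bond-geometry
check shares the perception gates and flags doubles twisted beyond
`torsion_threshold = 25°` or between two pyramidal centres — lengths play no
role there. The 3σ length rule requires both the deviation *and* a
better-fitting alternative order, so an unusual but uniquely attributable
bond is not flagged. The six entry-level criteria mark entries as valid or
not; nothing is dropped, mirroring a curated-database workflow where
downstream consumers decide what to exclude.

## What the fixtures do and do not establish

Fixtures are idealized, seedless gas-phase-like geometries in large P1 boxes
(benzene, eclipsed ferrocene, azide salts with both printed distance
regimes, an ion pair, a cyclooctatetraenide salt, two independent waters, an
inversion-completed dimer, and deliberate defects: clash, overvalence, 1-D
polymer, positional disorder, Fe/Co compositional disorder). They emulate the
scenarios the conventions are defined by — they do **not** exhibit thermal
noise, realistic packing, hydrogen-position uncertainty or the long tail of
bonding situations in real determinations. A green test therefore
establishes that the algorithms implement the stated conventions and
tie-breaks exactly, not that corpus-scale success rates would be reproduced.

## Numerical choices

* Fractional coordinates wrap to [0, 1); orthogonalization puts *a* along x,
  *b* in the xy-plane.
* `merge_tol = 0.01` Å (special positions), `clash_factor = 0.5`,
  `tolerance = 0.4` Å, `max_bond_cutoff = 4.0` Å, `sigma_threshold = 3`,
  `planarity_gate = 10°` (RMS out-of-plane), `sp_gate = 160°`,
  `torsion_threshold = 25°`, `max_polymer_atoms = 400`.
* All tie-breaks are deterministic (lowest atom index, then site label);
  identical inputs give byte-identical outputs everywhere, including the
  SMILES writer, whose Morgan-style invariant ranking is deterministic but
  intentionally not aligned with any external canonicalization.
* Degenerate inputs: zero-length cells, angles outside (0°, 180°) and
  non-positive-definite metrics are rejected at construction; a σ ≤ 0 bond
  class is a value error; an empty matching problem records a delocalization
  issue instead of failing.

## Known limitations

* The bundled class table is small and approximate; uncommon element pairs
  fall back to single bonds (the no-data signal).
* Charge-vs-radical resolution outside the four heuristic cases defaults to
  radical; organic salts without metals or positive centres can be
  misassigned and will then trip the radical or ensemble-charge checks.
* Metal oxidation-state enumerations are the common chemical states, not an
  exhaustive reference; exotic states surface as atom-charge issues.
* V2000 output uses `M  CHG` property lines only (the legacy charge column
  is not written); readers that ignore property blocks will see neutral
  atoms.
* The DWAR header is the minimal column-property block DataWarrior needs to
  recognize the SMILES column, not the full native header dialect.
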