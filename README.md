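# cifchem

Chemical entity perception from small-molecule crystallographic data.

Crystal structure determinations record unit cells, symmetry operators and
atomic coordinates — not bonds, bond orders or formal charges. `cifchem`
derives that chemical information from the geometry alone, so that
crystallographic entries (organic, inorganic and organometallic alike) can be
expressed in the formats cheminformatics tooling expects: MDL Molfile
V2000/V3000, SDF, TSV/DWAR tables and SMILES. It is aimed at curators and
data scientists who need machine-readable chemistry for crystal-structure
collections, and at anyone building training or screening sets from
experimentally determined 3D coordinates.

## What it does

1. **Ensemble restoration.** The asymmetric unit is expanded with the
   crystallographic symmetry operators, special-position duplicates are
   merged, positional disorder is resolved to a representative conformation
   (highest summed occupancy, then atom count, then lexicographically lesser
   group name), and covalently connected networks are traced across lattice
   translations into a *stoichiometrically correct molecular ensemble* — the
   minimal grouping of all molecular entities in their correct ratio.
   Entities that reconnect to their own lattice images are polymers and are
   rejected downstream with an explicit error.

2. **Structure assignment** in six steps: (i) connectivity from covalent
   radii, `d ≤ min(r_A + r_B + tol, cutoff)`; (ii) unambiguous higher-order
   bonds, ranked by the z-score `z = (d − μ)/σ` against Gaussian bond-length
   distribution classes keyed by element pair, order and π-electron context;
   (iii) length-driven functional-group templates (azide, nitro, carboxylate,
   sulfonate, phosphate, isocyanide, ...); (iv) Kekulé assignment of aromatic
   ring systems via a perfect matching of the ring π subgraph minimizing
   Σz², introducing formal charges only when unavoidable; (v) higher orders
   for geometrically deviant bonds; (vi) formal charges by valence
   bookkeeping. Bonds involving metal atoms (Z in [3,4] ∪ [11,13] ∪ [19,31] ∪
   [37,51] ∪ [55,84] ∪ [87,103]) are never resolved: they become **zero-order
   coordination bonds**, ignored in charge bookkeeping, so ferrocene is an
   Fe²⁺ centre with ten zero-order Fe–C bonds and one carbanion per
   cyclopentadienyl ring.

3. **Validation.** Six molecular-geometry checks (π-electron counts against
   geometry, bond-type vs angles/torsions, the 3σ bond-length rule with a
   better-fitting-alternative clause, radicals, per-element allowed charges,
   ensemble charge neutrality) plus six entry-level data-quality criteria
   (structure issues, declared-vs-computed formula compatibility, provenance,
   compositional disorder, maintainer markup, manual review). Failing entries
   are marked, never dropped.

## Worked example

```r
library(cifchem)

desc <- make_ferrocene()        # idealized eclipsed ferrocene in a P1 box
ens  <- build_ensemble(desc)    # stoichiometric ensemble (1 entity, 21 atoms)
st   <- perceive(ens)           # six-step structure assignment + validation

table(ifelse(st$bonds$order == 0, "coordination (0)", st$bonds$order))
#>                1                2 coordination (0)
#>               16                4               10

st$atoms[st$atoms$charge != 0, c("element", "charge")]
#>    element charge
#> 1       Fe      2
#> 6        C     -1
#> 16      C      -1

sum(st$atoms$charge)   #> 0   (the ensemble is neutral)
nrow(st$issues)        #> 0   (all six geometry checks clean)

judge_entry(st$issues, ens)$overall_valid
#> TRUE

to_smiles(st, scope = "ligands")
#> [1] "[Fe+2]"          "[CH-]1C=CC=C1"   "[CH-]1C=CC=C1"
```

The ten Fe–C contacts are zero-order coordination bonds (type 8 in V2000
output, type 9 in V3000); each C₅H₅ ring keeps two C=C double bonds and one
carbanion, and the +2 iron charge balances the two ring anions.

## Command line

```sh
Rscript -e 'cifchem::cifchem_cli()' perceive entry.cif          # SDF on stdout
Rscript -e 'cifchem::cifchem_cli()' perceive --tsv-output --print-dwar-header entry.cif
Rscript -e 'cifchem::cifchem_cli()' perceive --smiles-scope=ligands entry.cif
Rscript -e 'cifchem::cifchem_cli()' validate entry.cif          # verdict table
Rscript -e 'cifchem::cifchem_cli()' fixtures out/               # fixture CIFs
```

(The same wrapper ships as `inst/exec/cifchem`.) A run report in the
processed / excluded:polymer / excluded:clash / excluded:overvalence /
excluded:capacity / failed:parse taxonomy goes to stderr; exit status is 0
iff nothing failed to parse.

## Scope notes

Synthetic, idealized fixtures stand in for real database entries; corpus-wide
statistics are out of scope. See `vignettes/perception-methods.Rmd` for the
model, parameter defaults, numerical choices and known limitations.
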