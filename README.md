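# dfgout

Chimeric template ensembles for modelling protein kinases in inactive
DFG-out conformations.

## The problem

Kinase inhibitors of type II bind the inactive "DFG-out" state, in which
the side chains of the conserved Asp-Phe-Gly motif flip and open a
hydrophobic back pocket next to the ATP site. DFG-out structures are
strongly under-represented in the PDB relative to DFG-in structures, so
structure-based design against this state usually has no experimental
structure to start from. The conformational plasticity of the DFG-out
state is captured well by a small set of discrete states of three
binding-site-forming elements:

* **A-loop** (activation loop): *closed type 2*, *open DFG-out*,
  *closed A-under-P*;
* **P-loop** (glycine-rich loop): *collapsed*, *stretched*;
* **alphaC-helix**: *alphaC-in*, *alphaC-inter*, *alphaC-out*.

`dfgout` implements the two pieces needed to turn this taxonomy into
modelling inputs:

1. **Geometric classifiers** that assign the four element classes of any
   kinase catalytic domain from distances, backbone dihedrals and
   C-alpha pseudotorsions, addressed in the common residue numbering of
   the PKAC-alpha structure 1ATP (catalytic Lys = 72, alphaC Glu = 91,
   DFG = 184-186). The alphaC rule is the classical salt-bridge
   criterion: *in* if the minimal Lys72-NZ to Glu91-OE1/OE2 distance
   d <= 4 A, *out* if d >= 8.5 A, and in between the Glu chi dihedral
   decides (*inter* if chi <= 100 deg). The P-loop rule evaluates four
   observables (psi at 49 and 56, the C-alpha pseudotorsion over 55-58,
   and the 54-170 C-alpha distance) and assigns a class when at least 3
   of the 4 fall in that class's intervals. The A-loop rule is a
   conjunction of the two pseudotorsions around the DFG motif
   (windows 182-185 and 184-187) with the 160-189 C-alpha distance.

2. **Chimeric template construction**: for one kinase, the C-lobe core
   of a DFG-in acceptor structure is fused with the N-lobe of one of six
   donors (one per P-loop x alphaC combination) and the A-loop of one of
   three donors (one per A-loop class), after rigid Kabsch superposition
   of each donor onto the acceptor over the common C-lobe core backbone.
   The Cartesian product gives **18 chimeric templates per kinase**,
   numbered HM 1-18 (A-loop fastest, then alphaC, then P-loop), each
   emitted as a provenance-tagged PDB plus a target-to-template
   alignment in PIR and aligned-FASTA formats, ready for any downstream
   comparative-modelling engine.

A synthetic-fixture module (`make_scaffold`, `make_labeled_grid`,
`make_donor_library`) builds kinase-like scaffolds whose classifier
observables are posed to exact target values, so the whole pipeline is
testable without downloading a single structure.

## Worked example

```r
library(dfgout)

cfg <- default_config()

# a synthetic DFG-in acceptor and a complete labelled donor library
acceptor <- make_acceptor(cfg, seed = 2)
library_ <- make_donor_library(cfg, seed = 1)

classify_structure(acceptor, cfg)
#> conformation: dfg=in aloop=open_dfg_out ploop=stretched alphac=in

man <- build_ensemble(reference_profile()$sequence, acceptor, library_,
                      cfg, out_dir = "ensemble_out")
man
#> ensemble_manifest [synthetic_acceptor]: 18/18 templates built (ensemble_out)

man$records[1:3, c("model_type_index", "aloop", "ploop", "alphac", "pdb")]
#> # A tibble: 3 × 5
#>   model_type_index aloop        ploop     alphac pdb
#>              <int> <chr>        <chr>     <chr>  <chr>
#> 1                1 closed_type2 collapsed in     hm_01.pdb
#> 2                2 open_dfg_out collapsed in     hm_02.pdb
#> 3                3 closed_a_under_p collapsed in hm_03.pdb

# the emitted templates classify back to their specification
classify_batch(file.path("ensemble_out", "hm_12.pdb"))[, c("aloop","ploop","alphac")]
#> closed_a_under_p  stretched  in
```

The 18 rows of `man$records` are the HM 1-18 template types; each has a
PDB file with REMARK 99 provenance records (which residue ranges came
from the acceptor C-lobe, the N-lobe donor and the A-loop donor), a PIR
alignment and an aligned-FASTA alignment. `n_clashes` counts heavy-atom
contacts across segments closer than 2.5 A after relief;
`junction_ok` reports whether every splice junction is covalently
plausible (C-N <= 2.5 A).

With real structures, replace the synthetic objects:

```r
acceptor <- number_domain(select_chain(read_structure("my_dfg_in.pdb"), "A"))
```

and build the donor library from DFG-out PDB depositions (the library
validator re-classifies every donor and rejects mislabelled entries).
A thin command-line interface is installed as `exec/dfgout`
(`classify`, `build-ensemble`, `match`, `make-fixtures`).

For acceptor selection the useful criteria are high resolution, a clean
DFG-in state, resolved A- and P-loops, and preferably an ATP or
ATP-analogue complex.

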