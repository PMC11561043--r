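# cogmap

Ligands captured in enzyme crystal structures are often not the molecules
the enzyme turns over in vivo — analogues, fragments, buffer components
and crystallization additives all end up in binding sites. `cogmap` maps
the *bound entities* observed in structures to their *cognate ligands*
(the substrates, products and cofactors of the annotated reactions),
classifies how protein domains share each ligand's binding interface,
profiles the chemical breadth of what a domain family binds, completes
partial Enzyme Commission (EC) annotations of protein chains from the
cognate evidence, and exports everything as a property graph in
bulk-import flat files.

It is aimed at structural bioinformaticians and cheminformaticians who
have per-structure ligand tables (SMILES), per-residue domain–ligand
contact tables, and chain-level EC annotations, and want a reproducible
pipeline from those inputs to domain–cognate mappings.

## The core score

Similarity between a bound entity and a candidate cognate is the PARITY
score (Proportion of Atoms Residing in Identical Topology) over
heavy-atom 2D graphs:

```
PARITY(A, B) = |MCS(A, B)| / (N_A + N_B − |MCS(A, B)|)
```

where the maximum common substructure (MCS) is connected, atoms match on
element identity, and bond order/aromaticity/charge are ignored. The MCS
search is a branch-and-bound backtracking written in C++ with a per-pair
timeout; timed-out pairs are flagged, never silently reported as exact. A
match is retained when its score reaches the calibrated threshold of 0.4
— the level a typical pair of randomly chosen ligands does not reach —
and the highest-scoring cognate(s) per bound entity carry an `is_best`
flag.

Domain–ligand interaction modes are assigned from each domain's share of
a ligand's contacts: `exclusive` (only domain), `dominant` (≥ 90%),
`major` (10–90%, sole nonminor), `major_partner` (≥ 50%, shared),
`partner` (10 – < 50%), `minor` (< 10%), after discarding domain–ligand
pairs supported by fewer than three residues. Domain families with
nonminor interactions to four or more cognates are *promiscuous*, and
split into *specialized* (mean pairwise MACCS Tanimoto ≥ 0.575) versus
*generalized*.

## Worked example

```r
library(cogmap)

wm <- worked_example_molecules()
parity_score(wm$catechol, wm$chlorocatechol)
#> <parity> score = 0.8889 (|MCS| = 8)
parity_score(wm$hexylglutathione, wm$lactoylglutathione)
#> <parity> score = 0.8214 (|MCS| = 23)
```

Catechol and 3-chlorocatechol share all 8 of catechol's heavy atoms, so
the score is 8/(8+9−8) = 0.89: a confident cognate match. The
glutathione conjugates share the 20-atom glutathione core plus a 3-atom
S-linked chain (the thioester carbonyl matching a methylene — bond order
is deliberately ignored), giving 23/28 = 0.82.

The same pipeline end-to-end on a generated fixture:

```r
fx <- generate_fixture_tables(fixture_spec(n_structures = 6, seed = 1))
ia <- assign_interaction_modes(filter_min_residues(fx$contacts))
table(ia$mode)
#>      dominant     exclusive         major major_partner         minor
#>             1             8             1             3             3
#>       partner
#>             1

bound <- parse_ligands(tibble::tibble(id = fx$bound$ligand_instance,
                                      smiles = fx$bound$smiles))
mt  <- match_bound_to_cognates(bound, fx$cognates)   # threshold 0.4
asg <- assign_specific_ec(fx$chains, ia, mt, fx$cognates)
asg[, c("structure_id", "partial_ec", "assigned_ec", "status")]
#>   structure_id partial_ec assigned_ec status
#> 1 STR001       1.1.1.-    <NA>        excluded_has_specific
#> 2 STR002       1.1.1.-    <NA>        excluded_has_specific
#> 3 STR003       1.1.1.-    1.1.1.3     assigned
#> 4 STR004       1.1.1.-    1.1.1.4     assigned
#> 5 STR005       1.1.1.-    1.1.1.5     assigned
#> 6 STR006       1.1.1.-    1.1.1.6     assigned

g <- build_graph(chains = fx$chains, interactions = ia, matches = mt,
                 cognates = fx$cognates, bound = fx$bound)
g
#> <cogmap_graph> 43 nodes (BoundEntity, CognateLigand, Domain, EC,
#>   ProteinChain, Structure), 94 edges (CONTAINS, HAS_DOMAIN,
#>   IN_EC_CLASS, INTERACTS_WITH, MAPS_TO)
write_flatfiles(g, "graph_out", interactions = ia, matches = mt)
```

Chains annotated with the partial class `1.1.1.-` are completed to the
specific EC whose cognate is the unique best match of the bound evidence;
chains that already carry a specific EC alongside the partial are
excluded. `write_flatfiles()` emits Neo4j-admin-import-style CSVs
(`nodes/`, `relationships/`) plus per-domain-database distribution TSVs
and a manifest; `load_graph()` reads them back into an identical graph.

A thin command-line front end with the same operations
(`make-fixture`, `calibrate`, `classify-contacts`, `match-cognates`,
`complete-ec`, `profile-domains`, `build-graph`) is installed at
`inst/cli/cogmap`.

See `vignettes/cogmap-methods.Rmd` for the model, parameter and design
discussion.

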