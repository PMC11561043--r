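---
title: "Methods: cognate ligand mapping and domain-ligand interaction profiling"
author: "cogmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cognate ligand mapping and domain-ligand interaction profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmap)
```

## The problem

Ligands observed in deposited enzyme structures are frequently not the
molecules the enzyme acts on in vivo: crystallization additives, substrate
analogues, fragments and ions all appear in binding sites. `cogmap`
connects what is *seen* in a structure to what the enzyme plausibly
*binds in function* — its cognate ligands (substrates, products,
cofactors) — and then uses those connections to characterize protein
domains and to sharpen incomplete enzyme annotations. The end product is
a property graph (structures, chains, domains, bound entities, cognate
ligands, EC classes) emitted as bulk-import flat files.

## PARITY similarity

The core primitive is the PARITY score (Proportion of Atoms Residing in
Identical Topology) between two small molecules, computed on their 2D
heavy-atom graphs:

$$\mathrm{PARITY}(A, B) = \frac{|\mathrm{MCS}(A, B)|}{N_A + N_B - |\mathrm{MCS}(A, B)|}$$

where $|\mathrm{MCS}|$ is the atom count of the connected maximum common
substructure, atoms match on element identity only, and bond order,
aromaticity and formal charge are ignored. The Jaccard normalization
makes the score 1 exactly when the heavy-atom graphs are isomorphic and 0
when no element-matched connected fragment is shared. The bond-order
blindness is deliberate: a thioester carbonyl carbon and a thioether
methylene should count as the same topological position when comparing a
bound analogue against a cognate thioester, and the two worked examples
shipped with the package (`worked_example_molecules()`) exercise exactly
that case:

* catechol vs 3-chlorocatechol: $|\mathrm{MCS}| = 8$, score $8/9 = 0.89$;
* S-hexylglutathione vs (R)-S-lactoylglutathione: $|\mathrm{MCS}| = 23$,
  score $23/28 = 0.82$.

The search engine is a branch-and-bound McGregor-style backtracking over
pair extensions with an element-count upper bound, written in C++. A
per-pair wall-clock timeout (default 10 s) guards against pathological
pairs; a timed-out result carries the best score found so far and an
explicit `timed_out` flag, and timed-out pairs never compete for
best-cognate status. A `match_rings` option restricts ring bonds to match
ring bonds; it is off by default because the shipped worked examples do
not require it, and it is exposed because the strictness is a genuine
modelling choice, not a correctness issue.

One corner of the atom-count normalization is worth stating plainly: two
same-sized molecules that differ by a single ring closure (hexane vs
cyclohexane) share all atoms as a connected common substructure and thus
score 1.0 despite not being isomorphic. This is a property of atom-based
MCS similarity itself, not of this implementation; the synthetic cognate
vocabularies generated by the package avoid planting such pairs, and the
`match_rings` flag removes the degeneracy where it matters.

### Parsing

SMILES handling (sanitization, canonicalization, hydrogen stripping) is
delegated to OpenBabel through ChemmineR/ChemmineOB. Multi-fragment
inputs (salts) keep the largest fragment by heavy-atom count, ties broken
by the lexicographically smallest canonical SMILES. Molecules that fail
sanitation are excluded from batch operations with a warning rather than
aborting a run, because a single malformed entry in a large ligand table
should not kill a pipeline.

## Threshold calibration

A similarity threshold separates plausible cognate matches from chance
resemblance. Following the random-pair protocol, `sample_random_pairs()`
draws replicate sets of uniformly random non-self ligand pairs (defaults:
5 sets of 2000 pairs, the scale used to set the published threshold) and
`calibrate_threshold()` takes the 95th percentile of each set's score
distribution (linear interpolation between order statistics), averages
the percentiles, adds an additive margin of 0.10 and rounds to one
decimal. The additive reading of "10% above" is used because a mean 95th
percentile of 0.29 then yields the published threshold of 0.4, whereas a
multiplicative reading (0.29 × 1.1 = 0.319) would not; both semantics are
available via `margin_type`.

The reference value of 0.29 was measured against the full PDB Chemical
Component Dictionary, which this package deliberately does not download;
the shipped `fixture_ligand_library()` (217 molecules built from
homologous series, substituted benzenes and small rings) is chemically
much narrower, so its random-pair percentile is higher (about 0.8). What
the package guarantees — and what the tests assert — is the procedure:
bit-reproducibility under a fixed seed and percentile stability across
seeds, not the corpus-dependent constant.

## Contact filtering and interaction modes

Per-residue contact tables (one row per contacting residue per domain per
bound-ligand instance, as produced upstream by arpeggio-style contact
detection) are filtered and classified:

1. **Minimum-residue filter.** A (domain, ligand) pair supported by fewer
   than 3 distinct residues is discarded as spurious; a ligand whose
   every domain partner is discarded disappears entirely. The cutoff is
   applied per pair so that both peripheral ligands and sparse
   single-domain touches are removed by one rule.
2. **Contact fractions.** Each surviving domain's share of the ligand's
   total contacts is computed on contact counts (not residue counts),
   independently within each domain database (a CATH domain and a Pfam
   domain never share a denominator). By default fractions are
   renormalized over surviving domains; the pre-filter denominators are
   available via `prefilter_contacts`.
3. **Modes.** A single contacting domain is `exclusive`. Otherwise a
   domain under 10% is `minor`; if exactly one domain is nonminor it is
   `dominant` (≥ 90%) or `major`; with two or more nonminor domains each
   is `major_partner` (≥ 50%) or `partner`. Boundaries follow the printed
   inequalities literally (0.10, 0.50, 0.90 all inclusive on the upper
   label), so a 50/50 interface yields two major partners.

The Gini index of a ligand's domain contact fractions
(mean-absolute-difference form, `gini()`) quantifies how unequally an
interface is shared; it is 0 for a perfectly shared interface and
$(n-1)/n$ when one domain holds everything.

`combinatorial_interactions()` extracts ligand instances bound in a
nonminor manner by more than one domain (with at least one retained
cognate match), keyed by the sorted multiset of domain families —
duplicates retained, so a homodimer contributing the same family twice is
distinguishable from a heterodimeric interface.

## Cognate matching and EC completion

`match_bound_to_cognates()` scores every bound entity against every
cognate and keeps matches at or above the threshold (default 0.4,
inclusive; a strict-inequality switch exists because the figure text and
the running text of the source protocol disagree on the boundary). All
retained matches are kept — the package does not force a single cognate —
and the maximal-score match(es) per bound entity are flagged `is_best`,
ties included. A perfect match is a score of exactly 1.0.

For a protein chain annotated with a partial EC (e.g. `3.2.1.-`),
`assign_specific_ec()`:

1. excludes chains that also carry a specific EC (`excluded_has_specific`);
2. expands the partial over the EC universe of the cognate table;
3. collects, per bound entity reached through a *nonminor* interaction of
   that chain, the best-scoring in-class cognates (best selected within
   the class by default; `best_within_class = FALSE` selects globally
   first);
4. intersects the candidate EC sets across bound entities: a single
   surviving EC is `assigned`, several survivors or a conflicting empty
   intersection is `ambiguous`, no evidence at all is `no_candidates`.

Assignments supported solely by score-1.0 matches are flagged
`perfect_support`. Requiring the *EC set* (not the cognate set) to be a
singleton means two different cognates unique to the same activity still
assign cleanly.

## Domain profiles and chemical space

`build_domain_profiles()` aggregates, per domain family, the distinct
cognate ligands reached through nonminor interactions and retained
matches (best and non-best alike). Four or more cognates make a family
*promiscuous* — below that, a domain binding the cofactor, substrate and
product of one reaction would be flagged spuriously. Promiscuous families
are `specialized` when the mean pairwise MACCS-166 Tanimoto similarity of
their cognate set is at least 0.575 (the strict random-pair threshold;
0.431 is the permissive alternative, reported but not used for the
boundary), otherwise `generalized`. `ec_diversity()` counts distinct
complete ECs over the chains on which a family has matched nonminor
interactions — specialized families typically show far fewer ECs than
generalized ones.

For chemical-space maps, `cluster_cognate_space()` embeds MACCS
fingerprints in 2D and k-means-clusters the embedding, choosing k by
maximal mean silhouette width over a range (default 2–20). The embedding
is classical multidimensional scaling of Tanimoto (Jaccard) distances:
the embedding is a presentation layer, the scientifically load-bearing
output is the silhouette-selected k, and MDS keeps that choice
deterministic without a stochastic embedding step. Clustering the raw
166-bit fingerprints instead is available via `space = "fingerprint"`.
MACCS keys come from OpenBabel's 166-key SMARTS set; absolute bit
patterns differ from other toolkits' MACCS implementations, but all
similarity comparisons inside the package use the same keys throughout.

## Graph export

`build_graph()` assembles six node labels (Structure, ProteinChain,
Domain, BoundEntity, CognateLigand, EC) and five edge types (CONTAINS,
HAS_DOMAIN, INTERACTS_WITH with mode and fraction, MAPS_TO with score and
best flag, IN_EC_CLASS) with namespaced, globally unique node ids, and
validates referential integrity before returning. `write_flatfiles()`
emits one RFC 4180 CSV per label and per type with Neo4j
admin-import-style typed headers (`node_id:ID`, `:LABEL`, `:START_ID`,
`:END_ID`, `:TYPE`), plus per-database distribution TSVs
(domain/bound-entity, domain/cognate, ligand/cognate similarity) and a
manifest. All property values are serialized as strings and row order is
sorted, so `load_graph()` is an exact inverse — the tests assert identity
on node and edge multisets, including values containing commas and
quotes.

## The synthetic fixture generator

`generate_fixture_tables()` plants ground truth that the pipeline must
recover exactly:

* **Evidence ligands** (chain A): each structure's bound entity is
  chemically identical to a cognate unique to one EC inside the partial
  class `1.1.1.-`. Cognates are small chain molecules with a unique
  (terminal group, chain length) combination, so no two cognates are
  isomorphic and the planted cognate is always the unique best match,
  while homologues still pass the threshold as realistic decoys.
* **Mode ligands** (chain B, deliberately unannotated): catechol bound by
  1–4 domain families with contact counts realizing a planted fraction
  vector; chain B carries no EC annotation so mode plants cannot leak
  into EC completion. Default planted vectors cover all six modes
  including the 50/50 boundary.
* **Noise**: a 2-residue spurious domain contact per structure that the
  minimum-residue filter must remove.
* A fraction of chains carry both the partial and the specific EC and
  must be excluded from completion.

What the fixtures do *not* emulate: real contact geometry (counts are
constructed, not measured from coordinates), the chemical breadth of the
PDB ligand corpus (the library is built from a handful of series, so
corpus-level constants such as the 0.29 random-pair percentile or the
published 15.7% specialized fraction are out of reach by design), and
glycan or multi-residue bound entities. Passing tests therefore
demonstrate the correctness of the machinery — filtering, classification,
matching, completion, export — under controlled conditions, not the
reproduction of corpus-wide statistics.

## Problem sizes and numerical choices

The shipped tests run the calibration at the protocol scale (5 sets of
2000 pairs over the 217-molecule library, 5 seeds), EC completion on a
50-chain fixture, mode classification exhaustively over every composition
of 100% into up to 4 domains at a 0.01 step, and flat-file round trips
over 100 randomized graphs. Percentiles use R's type-7 quantile
(interpolation between order statistics). Fraction sums are checked to
1 ± 1e-9; similarity scores are stored at full precision and rounded only
for presentation (figures print 2 decimals). Cluster labels are relabeled
contiguously from 0 in order of first appearance so that repeated runs
under one seed are identical.

## Known limitations

* PARITY is purely 2D-topological; stereochemistry, tautomers and charge
  states are invisible to it.
* The score-1.0 degeneracy for same-size molecules differing by one ring
  closure, discussed above.
* OpenBabel's MACCS keys are not bit-compatible with other toolkits;
  Tanimoto values are internally consistent but not directly comparable
  to values computed elsewhere.
* EC completion trusts the cognate table's EC memberships; a cognate
  mapped to the wrong EC upstream propagates into assignments.
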