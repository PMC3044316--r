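---
title: "Validating and complementing curated pathway models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and complementing curated pathway models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwaylint)
```

## The data model

A pathway model is a bipartite graph in the Petri-net tradition: *entities*
are places (species whose token count stands for concentration),
*processes* are transitions (biological events), and *connectors* are
role-typed arcs. Four roles exist — substrate (`InputProcessBiological`),
inhibitor (`InputInhibitorBiological`), activator
(`InputAssociationBiological`) and product (`OutputProcessBiological`); the
first three form the *input* family. A process/entity pair may be
unconnected or joined by exactly one connector, giving five valid
connection configurations.

Entities carry a class (`Protein`, `Dna`, `mRNA`, `SmallMolecule`,
`Complex`, all subclasses of the root `Entity`), an optional cell-component
term (`CC_*`), a set of feature-type terms (`FT_*`, post-translational
modification states), a set of unification xrefs (`DB:ACCESSION` strings
identifying the underlying molecule; two xrefs are the same molecule iff
database and accession match after case normalization), and — for
complexes — a list of component entity ids. Processes carry a mandatory
biological-event term (`ME_*`). Stoichiometric coefficients live on the
*connector*, not the entity: an entity may enter different processes with
different coefficients, and a rule that speaks of "the coefficient of the
substrate" reads the coefficient of that entity's substrate connector in
that process. Vocabularies are open-world: unknown terms load with a
notice, and the constraint table decides which events have rules.

The native serialization is a small JSON dialect (`model_id`, `entities[]`,
`processes[]`, `connectors[]`; camel-case record keys, explicit defaults,
records sorted by id) chosen so that saves are byte-stable and
`read_pathway_model(write_pathway_model(m))` is the identity. Simulation
attributes (initial values, kinetics) are preserved as opaque annotations;
no rule reads them. GraphML export is provided for inspection only.

## Rule semantics

Rules are event-condition-action records. The 36 criterion-2 rules are
*reactive*: each is triggered by the biological-event term of a process and
evaluates a declarative condition against that process's neighbourhood.
The criterion-1 and criterion-3 rules are *condition-action*: they scan the
whole model. Criteria 1 and 2 only report; only the three criterion-3
rules mutate, and only through `complement_model()` — `validate_pathway()`
is pure and reports what a complementation pass would do.

Conditions are composed from a fixed clause vocabulary rather than a
general description-logic reasoner: cardinality-on-role (min/max),
class-of-entity (quantified *all* or *at least one*, respecting the class
hierarchy), property requirements (feature term, cell-component term or
term set or mere presence, integer stoichiometry value or range, xref
presence), and cross-role property relationships (*same* for xrefs,
*different* for cell components). This covers every constructor the
printed rules use (intersection, union, negation, someValues, min/max
cardinality) while staying declarative and table-driven.

Clauses are evaluated in a fixed order — cardinality, type, property,
relationship — and a role whose required participants are entirely absent
*suppresses* the downstream clauses on that role: if the substrate is
missing, the model gets one `MISSING_INPUTPROCESS` warning, not an
additional complaint about the missing substrate's location and xref.
When a role is over-populated (two substrates where one is allowed) the
downstream clauses still run, against all entities on the role. One
warning is emitted per violated clause; several offending entities of one
clause are listed in a single warning. Warning categories distinguish the
*wrong* and *not defined* variants throughout (`WRONG_TYPE` vs
`MISSING_TYPE`, `WRONG_CELLCOMPONENT` vs `MISSING_CELLCOMPONENT`, …). For
type clauses the assignment is: offenders typed with the bare root class
are "not defined", anything else is "wrong". For xref relationships, a
side with no xrefs at all yields `MISSING_UNIFICATIONXREF` and no identity
comparison is attempted; disjoint xref sets on identified sides yield
`WRONG_UNIFICATIONXREF`.

## The constraint table

The 36 event constraints ship as a versioned JSON table
(`inst/extdata/event_constraints.json`) in five groups — 11 cardinality/type
rules, 15 modification (feature-property) rules, 3 stoichiometry rules, 3
cell-component rules, 4 type-plus-location rules. Each record carries a
provenance tag. Nine rules reproduce printed rule text exactly (DNA
binding, acetylation, autophosphorylation, the three
dimerization-family rules, internalization, translocation's
different-location requirement, transcription). The remainder are
*synthesized*: reconstructed from the group templates and the documented
warning taxonomy, and deliberately overridable by a user table
(`load_constraint_table()`; constraints loaded without explicit provenance
are tagged `user`). Notable synthesized choices:

* Binding: ≥ 2 substrates, exactly one `Complex` product. Dissociation is
  its mirror: one `Complex` substrate, ≥ 2 products.
* Translation: ≥ 1 input including an `mRNA`, one `Protein` product in the
  cytoplasm. Gene expression: one `Protein` product with *some* location.
  Nuclear export: nucleoplasm → cytoplasm with matching xrefs.
* Degradation events (`ME_ProteasomeDegradation`, `ME_UnknownDegradation`)
  allow 0–1 products; whether their product list must be empty is not
  specified anywhere, so the permissive reading was chosen.
* Autocleavage sits in group 1 with an exactly-one-input clause (a
  self-event needs no enzyme), mirroring autophosphorylation's printed
  input clause in group 2.

The group-2 rules are driven by a feature map (event → feature term),
total on group 2 and not injective (phosphorylation and
autophosphorylation both map to `FT_Phosphorylated`). Most terms are the
past participle of the event; `FT_Active`/`FT_Inactive` for
unknown-(in)activation are documented defaults, not attested vocabulary.
The printed modification rule binds one existential over a product that
has the feature *and* the matching xref; the table decomposes this into
two clauses (some product has the feature; some substrate/product pair
shares an xref), which is marginally weaker when a process has several
products — a deliberate trade for declarativity, invisible on single-product
processes.

Stoichiometry is assumed integral (every printed threshold is an integer),
and cell-component comparison is exact term equality — no term hierarchy
is defined, so none is invented.

## Complementation

`find_starting_entities()` implements "never produced" as a universal over
the entity's connectors, which holds vacuously for isolated entities: an
isolated species gets a production process, which is also what a
simulation needs. Detection runs entirely on the input model before any
mutation (*simultaneous semantics*): the binding process added for a
starting complex does not stop the complex's components from receiving
their own production processes in the same pass. A starting complex whose
component list is empty cannot receive the binding action as written; it
falls back to unknown production with a provenance note rather than
failing, keeping complementation total. New node ids are deterministic
functions of the target entity id (`<id>__unknown_production`,
`<id>__binding`, `<id>__unknown_degradation`), so diffs are reproducible.
Added nodes carry structure only — no invented kinetics or initial values;
parameterization is downstream work. The degradation condition checks for
an existing `ME_UnknownDegradation` sink only, as printed; treating
proteasome degradation as a sink is available behind
`include_proteasome = TRUE` because the stricter reading double-degrades
proteins that already have a proteasome pathway.

These choices make complementation idempotent (each rule's action
falsifies its own condition), conservative (nothing is removed or
re-typed), and total (afterwards no starting or undegraded species
remain) — all three are property-tested.

## The synthetic generator

`make_clean_model()` builds, for each requested event, a process whose
participants provably satisfy the shipped constraint: required roles are
populated at their minimum cardinality, type specs set classes, property
specs set locations/features/coefficients, relationship specs assign
shared xrefs or distinct compartments, and produced complexes record their
substrates as components. Every process owns its participant entities, so
processes compose without interference. Random fixtures draw events with
frequencies weighted to resemble a realistic curation workload, where
binding, phosphorylation, activation and expression events dominate;
the proportions are indicative, not asserted. Generation is a pure
function of (palette, n, seed), using integer sampling only.

`inject_violations()` plants an exact number of violations per warning
category, each on a distinct process, by minimal edits (clone a
participant, drop a connector, perturb a class/term/coefficient, add a
duplicate-pair connector), choosing edits whose side effects cannot
trigger neighbouring clauses; the result is verified post hoc by running
the validator and comparing counts, and an unachievable plan is an error
rather than a silent shortfall.

What the generator does *not* emulate: shared entities across processes
(real models reuse species heavily), literature-derived topology, realistic
display names, or partially annotated entities beyond the planted defects.
Passing the property suites therefore demonstrates the rules' logical
behaviour — detection, non-masking, boundary exactness — not recall on any
particular real curation corpus.

The test suite exercises, among others: a coefficient sweep 1–40 against
the dimerization/oligomerization/polymerization boundaries; constructive
soundness and single-defect mutation completeness for all 36 events and
all 15 warning categories; engine-vs-brute-force-oracle equality on 100
random fixtures of ≈ 200 nodes (65 processes) with randomized violation
loads; and complementation laws on 10 random 25-process fixtures — sizes
chosen to keep the full suite in the low minutes on one CPU while giving
each property a few thousand process evaluations.

## Known limitations

* The validator reports; it never repairs criterion-1/2 findings. Choosing
  the correct connector or event term needs the underlying publication.
* Synthesized constraints are best-effort reconstructions; a curation
  group with its own conventions should review and override them via a
  user constraint table.
* No OWL/RDF parsing, SPARQL, SBML/BioPAX conversion, or event-term
  hierarchy; xref resolution against live databases is out of scope — xrefs
  are compared syntactically.
* A process failing several clauses of one rule yields several warnings
  (per-clause counting); corpora counted per-process will report lower
  totals for the same models.
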